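# Shared fixtures: all built in code, deterministic under fixed seeds.

# Tiny amplicon whose 12 bp CDS is hand-checkable: ATG GCT TGG TAA
toy_reference <- function() {
  reference_amplicon(paste0("AAAACC", "ATGGCTTGGTAA", "GGTTAA"), 7, 18)
}

# Small random reference for module tests (300 bp CDS, 40 bp flanks)
small_reference <- function(seed = 5L) {
  synthetic_reference(cds_length = 300L, flank = 40L, seed = seed)
}

# Brute-force per-position base tally, the independent oracle for count_bases:
# walks every fragment position by position.
oracle_count_bases <- function(fragments, ref) {
  A <- nchar(ref$sequence)
  counts <- matrix(0L, nrow = A, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  ref_chars <- strsplit(ref$sequence, "")[[1]]
  for (i in seq_len(nrow(fragments))) {
    span <- fragments$start[i]:fragments$end[i]
    bases <- ref_chars[span]
    if (fragments$subs[i] != "") {
      for (sub in strsplit(fragments$subs[i], ";", fixed = TRUE)[[1]]) {
        p <- as.integer(sub("^(\\d+):.*$", "\\1", sub))
        a <- sub("^.*>", "", sub)
        bases[match(p, span)] <- a
      }
    }
    for (j in seq_along(span)) {
      counts[span[j], bases[j]] <- counts[span[j], bases[j]] + 1L
    }
  }
  counts
}

# Random count table over an amplicon: independent Poisson coverage split
# among bases with a dominant reference base.
random_count_table <- function(ref, seed, mean_cov = 200, mut_frac = 0.02) {
  A <- nchar(ref$sequence)
  ref_chars <- strsplit(ref$sequence, "")[[1]]
  lambscan:::with_seed(seed, {
    counts <- matrix(rpois(A * 4L, mean_cov * mut_frac / 3), A, 4L,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    counts[cbind(seq_len(A), match(ref_chars, c("A", "C", "G", "T")))] <-
      rpois(A, mean_cov)
    out <- data.frame(position = seq_len(A), ref_base = ref_chars, counts,
                      stringsAsFactors = FALSE)
    class(out) <- c("count_table", "data.frame")
    attr(out, "ref_sequence") <- ref$sequence
    out
  })
}

# The full default synthetic experiment, run once per test session and shared
# across acceptance checks (several minutes of compute).
.experiment_cache <- new.env(parent = emptyenv())
cached_default_experiment <- function() {
  if (is.null(.experiment_cache$res)) {
    t0 <- Sys.time()
    .experiment_cache$res <- run_experiment(experiment_config(seed = 1L),
                                            verbose = FALSE)
    .experiment_cache$minutes <-
      as.numeric(difftime(Sys.time(), t0, units = "mins"))
  }
  .experiment_cache$res
}
cached_experiment_minutes <- function() .experiment_cache$minutes
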