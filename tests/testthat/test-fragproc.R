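test_that("collapse groups identical pairs and applies the raw-count filter", {
  reads <- data.table::data.table(
    r1 = c(rep("ACGTACGT", 7), rep("TTTTCCCC", 3)),
    r2 = c(rep("GGGGAAAA", 7), rep("CCCCGGGG", 3))
  )
  out <- collapse_and_filter(reads, min_raw = 5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$raw_count, 7L)
  expect_equal(out$r1, "ACGTACGT")
  expect_equal(attr(out, "n_below_min_raw"), 1L)

  # min_raw = 1 keeps every unique pair
  all_pairs <- collapse_and_filter(reads, min_raw = 1)
  expect_equal(nrow(all_pairs), 2L)
  expect_equal(sum(all_pairs$raw_count), 10L)

  # empty output is permitted
  none <- collapse_and_filter(reads, min_raw = 100)
  expect_equal(nrow(none), 0L)
})

test_that("fixed duplication of 5 loses nothing to the filter", {
  ref <- small_reference()
  lib <- generate_library(ref, library_spec(200, 0.005, seed = 8))
  sim <- simulate_reads(lib, lib$abundance, ref,
    sequencing_spec(n_fragments = 2000, per_base_error = 0,
                    dup_min = 5, dup_mean_extra = 0, frag_len_max = 200,
                    seed = 9))
  pairs <- collapse_and_filter(sim$reads, min_raw = 5)
  expect_equal(attr(pairs, "n_below_min_raw"), 0L)
  expect_equal(sum(pairs$raw_count), nrow(sim$reads))
})

test_that("pair merging handles exact overlaps, disagreements and non-overlaps", {
  frag <- "ACGTACGTGGATCCTTAACCGGTTAGCTAGCT"  # 32 bp
  r1 <- substr(frag, 1, 26)
  r2 <- revcomp(substr(frag, 7, 32))  # 20 bp overlap
  pairs <- data.table::data.table(
    r1 = r1, r2 = r2,
    q1 = strrep("I", 26), q2 = strrep("I", 26), raw_count = 6L
  )
  m <- merge_pairs(pairs, min_overlap = 10)
  expect_equal(nrow(m$segments), 1L)
  expect_true(m$segments$merged)
  expect_equal(m$segments$seq, frag)

  # non-overlapping mates: two segments sharing the pair's raw count
  far1 <- substr(frag, 1, 12)
  far2 <- revcomp(substr(frag, 21, 32))
  pairs2 <- data.table::data.table(
    r1 = far1, r2 = far2,
    q1 = strrep("I", 12), q2 = strrep("I", 12), raw_count = 8L
  )
  m2 <- merge_pairs(pairs2, min_overlap = 10)
  expect_equal(nrow(m2$segments), 2L)
  expect_true(all(!m2$segments$merged))
  expect_equal(m2$segments$seq, c(far1, revcomp(far2)))
  expect_equal(m2$segments$raw_count, c(8L, 8L))

  # overlap disagreement resolved toward the higher-quality base,
  # and toward read 1 on quality ties; the disagreement sits early in the
  # overlap so read 1's 3'-terminal bases still anchor the merge
  r2_err <- r2
  old23 <- substr(r2_err, 23, 23)
  substr(r2_err, 23, 23) <- setdiff(c("A", "C", "G", "T"), old23)[1]
  base_at <- function(s, i) substr(s, i, i)
  pos_in_r2f <- 26 - 23 + 1     # revcomp flips coordinates
  tie <- data.table::data.table(
    r1 = r1, r2 = r2_err,
    q1 = strrep("I", 26), q2 = strrep("I", 26), raw_count = 6L
  )
  mt <- merge_pairs(tie, min_overlap = 10)
  expect_true(mt$segments$merged)
  expect_equal(mt$segments$seq, frag)  # read 1 wins the tie

  hi2 <- data.table::data.table(
    r1 = r1, r2 = r2_err,
    q1 = strrep("#", 26), q2 = strrep("I", 26), raw_count = 6L  # q2 higher
  )
  mh <- merge_pairs(hi2, min_overlap = 10)
  expect_true(mh$segments$merged)
  expect_false(identical(mh$segments$seq, frag))
  expect_equal(base_at(mh$segments$seq, 6 + pos_in_r2f),
               base_at(revcomp(r2_err), pos_in_r2f))
})

test_that("alignment finds offsets, substitutions and strand", {
  ref <- small_reference()
  # spec example translated to 1-based inclusive coordinates:
  # an exact 60 bp reference substring at offset 101 spans 101..160
  seq0 <- substr(ref$sequence, 101, 160)
  al <- align_fragments(seq0, ref)
  expect_true(al$alignments$aligned)
  expect_equal(al$alignments$start, 101L)
  expect_equal(al$alignments$end, 160L)
  expect_equal(al$alignments$n_mismatch, 0L)
  expect_equal(nrow(al$substitutions), 0L)

  # one substitution at amplicon position 131
  seq1 <- seq0
  old <- substr(seq1, 31, 31)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(seq1, 31, 31) <- new
  al1 <- align_fragments(seq1, ref)
  expect_equal(al1$alignments$start, 101L)
  expect_equal(al1$alignments$n_mismatch, 1L)
  expect_equal(al1$substitutions$pos, 131L)
  expect_equal(al1$substitutions$ref, old)
  expect_equal(al1$substitutions$alt, new)

  # strand symmetry: the reverse complement aligns identically
  alrc <- align_fragments(revcomp(seq1), ref)
  expect_equal(alrc$alignments$start, 101L)
  expect_equal(alrc$alignments$strand, "-")
  expect_equal(alrc$substitutions$pos, al1$substitutions$pos)
  expect_equal(alrc$substitutions$alt, al1$substitutions$alt)

  # garbage is rejected and counted, not errored
  junk <- paste(rep("ACGT", 15), collapse = "")
  alj <- align_fragments(junk, ref)
  expect_false(alj$alignments$aligned)

  # mismatch fraction above the ceiling is rejected
  noisy <- seq0
  for (p in seq(2, 40, 4)) {
    substr(noisy, p, p) <- setdiff(c("A", "C", "G", "T"), substr(noisy, p, p))[1]
  }
  expect_false(align_fragments(noisy, ref, max_mismatch_frac = 0.1)$alignments$aligned)
})

test_that("strand of input reads does not change base counts", {
  ref <- small_reference()
  lib <- generate_library(ref, library_spec(100, 0.01, seed = 3))
  sim <- simulate_reads(lib, lib$abundance, ref,
    sequencing_spec(n_fragments = 800, per_base_error = 0, frag_len_max = 150,
                    seed = 4))
  proc_fwd <- process_sample(sim$reads, ref)
  swapped <- data.table::data.table(r1 = sim$reads$r2, r2 = sim$reads$r1)
  proc_rev <- process_sample(swapped, ref)
  expect_equal(proc_fwd$counts[, c("A", "C", "G", "T")],
               proc_rev$counts[, c("A", "C", "G", "T")])
})

test_that("deduplication groups fragments by (start, end, substitutions)", {
  al <- data.table::data.table(
    seq_id = 1:4,
    start = c(10L, 10L, 10L, 30L),
    end = c(60L, 60L, 60L, 80L),
    strand = "+",
    n_mismatch = c(0L, 0L, 1L, 0L),
    aligned = TRUE
  )
  subs <- data.table::data.table(seq_id = 3L, pos = 20L, ref = "A", alt = "G")
  fr <- dedup_fragments(al, subs, raw_count = c(5L, 7L, 6L, 9L))
  expect_equal(nrow(fr), 3L)  # same span w/o subs collapses; with subs distinct
  plain <- fr[fr$start == 10 & fr$subs == "", ]
  expect_equal(plain$raw_count, 12L)
  withsub <- fr[fr$subs != "", ]
  expect_equal(withsub$subs, "20:A>G")
  expect_equal(withsub$n_sub, 1L)
})

test_that("dedup count equals distinct ground-truth events when error-free", {
  ref <- small_reference()
  lib <- generate_library(ref, library_spec(150, 0.002, seed = 6))
  # short fragments so that every pair merges and end k-mers are clean
  sim <- simulate_reads(lib, lib$abundance, ref,
    sequencing_spec(n_fragments = 1000, per_base_error = 0,
                    frag_len_max = 140, dup_min = 5, dup_mean_extra = 0,
                    seed = 7))
  proc <- process_sample(sim$reads, ref)
  truth_events <- unique(sim$truth[, c("variant_id", "start", "end")])
  # distinct genotype-resolved events: same (start,end) from variants with the
  # same local substitutions collapse; count via truth substitution signatures
  key <- merge(sim$truth, sim$truth_subs, by = "fragment_id", all.x = TRUE)
  key <- data.table::as.data.table(key)
  sig <- key[, list(
    sig = paste(paste0(pos[!is.na(pos)], alt[!is.na(pos)]), collapse = ";")
  ), by = c("fragment_id", "start", "end")]
  n_truth <- nrow(unique(sig[, c("start", "end", "sig")]))
  # a both-end seed failure can drop the odd mutation-dense fragment; every
  # drop is logged, and each can remove at most one ground-truth event
  n_unaligned <- unname(proc$drops["unaligned"])
  expect_lte(n_unaligned, 2L)
  expect_gte(nrow(proc$fragments), n_truth - n_unaligned)
  expect_lte(nrow(proc$fragments), n_truth)
})

test_that("count_bases matches the brute-force oracle and conserves coverage", {
  ref <- small_reference()
  # trivial cases first
  f1 <- data.table::data.table(start = 1L, end = 10L, subs = "",
                               n_sub = 0L, raw_count = 3L)
  ct <- count_bases(f1, ref)
  refb <- strsplit(ref$sequence, "")[[1]]
  m <- as.matrix(ct[, c("A", "C", "G", "T")])
  expect_equal(unname(m[cbind(1:10, match(refb[1:10], c("A","C","G","T")))]),
               rep(1L, 10))  # one count per covered position, not raw_count
  expect_equal(sum(m), 10L)

  f2 <- rbind(f1, data.table::data.table(
    start = 5L, end = 15L, subs = sprintf("7:%s>%s", refb[7],
      setdiff(c("A","C","G","T"), refb[7])[1]), n_sub = 1L, raw_count = 1L))
  ct2 <- count_bases(f2, ref)
  m2 <- as.matrix(ct2[, c("A", "C", "G", "T")])
  alt7 <- setdiff(c("A","C","G","T"), refb[7])[1]
  expect_equal(unname(m2[7, refb[7]]), 1L)
  expect_equal(unname(m2[7, alt7]), 1L)

  # oracle equivalence on a simulated set (<= 1000 fragments)
  lib <- generate_library(ref, library_spec(120, 0.01, seed = 12))
  sim <- simulate_reads(lib, lib$abundance, ref,
    sequencing_spec(n_fragments = 900, per_base_error = 0, frag_len_max = 150,
                    seed = 13))
  proc <- process_sample(sim$reads, ref)
  expect_lte(nrow(proc$fragments), 1000)
  oracle <- oracle_count_bases(proc$fragments, ref)
  expect_equal(as.matrix(proc$counts[, c("A", "C", "G", "T")]),
               oracle, ignore_attr = TRUE)

  # conservation: per-position base counts sum to fragment coverage
  cov <- integer(nchar(ref$sequence))
  for (i in seq_len(nrow(proc$fragments))) {
    sp <- proc$fragments$start[i]:proc$fragments$end[i]
    cov[sp] <- cov[sp] + 1L
  }
  expect_equal(unname(rowSums(as.matrix(proc$counts[, c("A","C","G","T")]))),
               cov)

  expect_error(count_bases(data.table::data.table(
    start = 1L, end = 10L, subs = "50:A>C", n_sub = 1L, raw_count = 1L), ref),
    "outside its fragment span")
})

test_that("consensus filtering suppresses sequencing errors below the raw rate", {
  ref <- small_reference()
  wt <- generate_library(ref, library_spec(10, 0, seed = 1))  # wild type only
  err <- 0.005
  sim <- simulate_reads(wt, wt$abundance, ref,
    sequencing_spec(n_fragments = 2500, per_base_error = err,
                    dup_min = 6, dup_mean_extra = 2, frag_len_max = 150,
                    seed = 14))
  proc <- process_sample(sim$reads, ref)
  # every surviving mismatch is a false mutation (library is wild type)
  est <- estimate_mutation_rate(proc$fragments, ref, cds_only = FALSE)
  expect_lt(est$rate, err / 10)
})

test_that("mutation-rate estimator recovers the planted rate (error-free)", {
  ref <- synthetic_reference()
  lib <- generate_library(ref, library_spec(5000, 0.0052, seed = 15))
  sim <- simulate_reads(lib, lib$abundance, ref,
    sequencing_spec(n_fragments = 20000, per_base_error = 0,
                    dup_min = 1, dup_mean_extra = 0, seed = 16))
  proc <- process_sample(sim$reads, ref, min_raw = 1)
  # with unit duplication the raw multiplicity of a unique fragment is its
  # physical fragment count, so raw weighting tallies each fragment once
  est <- estimate_mutation_rate(proc$fragments, ref, weight_by_raw = TRUE)
  expect_lt(abs(est$rate - 0.0052), 3 * est$se)
})
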