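#' Error-prone PCR library specification
#'
#' @param n_variants Number of variants to draw.
#' @param per_base_rate Per-nucleotide substitution probability in `[0, 1)`.
#'   The high- and low-mutagenesis libraries of the assay correspond to
#'   0.0052 and 0.00063.
#' @param substitution_spectrum 4x4 row-stochastic matrix (rows/columns in
#'   A,C,G,T order, zero diagonal) giving the distribution of the substituted
#'   base conditional on the reference base; defaults to uniform over the
#'   three non-reference bases.
#' @param seed Integer seed.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n_variants, per_base_rate,
                         substitution_spectrum = NULL, seed = 1L) {
  stopifnot(n_variants >= 1, per_base_rate >= 0, per_base_rate < 1)
  if (is.null(substitution_spectrum)) {
    substitution_spectrum <- matrix(1 / 3, 4, 4,
      dimnames = list(BASES, BASES)
    )
    diag(substitution_spectrum) <- 0
  }
  stopifnot(
    identical(dim(substitution_spectrum), c(4L, 4L)),
    all(abs(rowSums(substitution_spectrum) - 1) < 1e-8),
    all(diag(substitution_spectrum) == 0)
  )
  structure(
    list(
      n_variants = as.integer(n_variants),
      per_base_rate = per_base_rate,
      substitution_spectrum = substitution_spectrum,
      seed = as.integer(seed)
    ),
    class = "library_spec"
  )
}

#' Generate an error-prone PCR variant library
#'
#' Each CDS base mutates independently with probability `per_base_rate`; the
#' substituted base is drawn from the spectrum row of the reference base.
#' Initial variant abundances are uniform. Mutations are recorded in 1-based
#' CDS coordinates.
#'
#' @param ref A [reference_amplicon()].
#' @param spec A [library_spec()].
#' @return An object of class `variant_library`: a list with `mutations`
#'   (data.table of `variant_id`, `pos`, `ref`, `alt`), `n_variants`,
#'   `abundance` (uniform, sums to 1) and `cds_length`.
#' @export
generate_library <- function(ref, spec) {
  stopifnot(inherits(ref, "reference_amplicon"), inherits(spec, "library_spec"))
  L <- cds_length(ref)
  N <- spec$n_variants
  cds_chars <- strsplit(cds_sequence(ref), "")[[1]]
  mut <- with_seed(spec$seed, {
    n_mut <- rbinom(N, L, spec$per_base_rate)
    which_mut <- which(n_mut > 0L)
    pos_list <- lapply(which_mut, function(i) sample.int(L, n_mut[i]))
    pos <- unlist(pos_list, use.names = FALSE)
    variant_id <- rep(which_mut, n_mut[which_mut])
    if (length(pos) == 0L) {
      data.table::data.table(
        variant_id = integer(0), pos = integer(0),
        ref = character(0), alt = character(0)
      )
    } else {
      ref_base <- cds_chars[pos]
      ref_idx <- match(ref_base, BASES)
      cum <- t(apply(spec$substitution_spectrum, 1L, cumsum))
      u <- runif(length(pos))
      alt_idx <- max.col(u <= cum[ref_idx, , drop = FALSE], ties.method = "first")
      data.table::data.table(
        variant_id = variant_id, pos = pos,
        ref = ref_base, alt = BASES[alt_idx]
      )
    }
  })
  data.table::setkey(mut, variant_id, pos)
  structure(
    list(
      mutations = mut,
      n_variants = N,
      abundance = rep(1 / N, N),
      cds_length = L,
      spec = spec
    ),
    class = "variant_library"
  )
}

#' @export
print.variant_library <- function(x, ...) {
  cat(sprintf(
    "<variant_library> %d variants, %.3f mutations/variant (rate %.2g over %d bp)\n",
    x$n_variants, nrow(x$mutations) / x$n_variants,
    x$spec$per_base_rate, x$cds_length
  ))
  invisible(x)
}

#' Mean mutational load of a library
#'
#' @param library A [generate_library()] result.
#' @return Mean number of substitutions per variant.
#' @export
mutation_load <- function(library) {
  nrow(library$mutations) / library$n_variants
}

#' Ground-truth fitness model for the two selections
#'
#' Assigns an effect in `[0, 1]` to every possible CDS substitution:
#' a shared stability cost (the common mechanism through which most mutations
#' affect both phenotypes), a lambda-binding effect confined to a designated
#' "loop" residue window (standing in for extracellular loop L6, the
#' determinant of phage binding), and a maltodextrin-pore effect confined to a
#' pore-lining window. Synonymous mutations have all effects zero; nonsense
#' mutations null both traits by rule.
#'
#' @param ref A [reference_amplicon()].
#' @param loop_residues Residue window carrying lambda-specific binding
#'   effects (default 240:260).
#' @param loop_hit_prob Probability that a missense mutation in the loop
#'   window disrupts lambda binding (default 0.5).
#' @param loop_effect_range Range of the binding effect for hits (default
#'   `c(0.9, 1)`: loss of receptor binding blocks infection almost
#'   completely, matching the full resistance of individually assayed loop
#'   mutants).
#' @param pore_residues Residue window carrying maltodextrin-specific pore
#'   effects (default 80:100).
#' @param pore_hit_prob,pore_effect_range As for the loop window (defaults
#'   0.3 and `c(0.5, 1)`).
#' @param stability_shape Beta shape parameters of the continuous
#'   distribution of stability costs for missense (and stop-loss) mutations
#'   (default `c(0.5, 1.8)`: mode at zero, mean about 0.22, with roughly
#'   14% of costs above 0.5 -- consistent with the minority of missense
#'   mutations that confer resistance).
#' @param seed Integer seed.
#' @return Object of class `fitness_model`: data.table over all CDS
#'   substitutions with per-mutation effects and annotation.
#' @export
fitness_model <- function(ref,
                          loop_residues = 240:260,
                          loop_hit_prob = 0.5,
                          loop_effect_range = c(0.9, 1),
                          pore_residues = 80:100,
                          pore_hit_prob = 0.3,
                          pore_effect_range = c(0.5, 1),
                          stability_shape = c(0.5, 1.8),
                          seed = 99L) {
  tab <- data.table::as.data.table(all_cds_mutations(ref))
  n <- nrow(tab)
  with_seed(seed, {
    ## shared stability cost: a continuous distribution of fitness effects
    ## with its mode at zero and a minority of strongly destabilising costs
    cost <- stats::rbeta(n, stability_shape[1], stability_shape[2])
    missense <- tab$effect_class == "missense"
    stop_loss <- tab$effect_class == "stop_loss"
    tab$stability_cost <- ifelse(missense | stop_loss, cost, 0)

    lam <- numeric(n)
    in_loop <- missense & tab$residue %in% loop_residues
    hit <- in_loop & runif(n) < loop_hit_prob
    lam[hit] <- runif(sum(hit), loop_effect_range[1], loop_effect_range[2])
    tab$lambda_binding_effect <- lam

    pore <- numeric(n)
    in_pore <- missense & tab$residue %in% pore_residues
    phit <- in_pore & runif(n) < pore_hit_prob
    pore[phit] <- runif(sum(phit), pore_effect_range[1], pore_effect_range[2])
    tab$malt_pore_effect <- pore
  })
  structure(
    list(effects = tab, loop_residues = loop_residues, pore_residues = pore_residues),
    class = "fitness_model"
  )
}

#' @export
print.fitness_model <- function(x, ...) {
  cat(sprintf(
    "<fitness_model> %d possible substitutions; loop window %d-%d, pore window %d-%d\n",
    nrow(x$effects), min(x$loop_residues), max(x$loop_residues),
    min(x$pore_residues), max(x$pore_residues)
  ))
  invisible(x)
}

#' Trait fitness of variants
#'
#' Multiplicative aggregation: the variant's fitness for a trait is the
#' product over its mutations of (1 - effect); any nonsense mutation nulls
#' both traits; the wild type is (1, 1).
#'
#' @param library A [generate_library()] result.
#' @param model A [fitness_model()].
#' @return data.table with one row per variant: `variant_id`,
#'   `f_lambda_sensitivity`, `f_malt`, both in `[0, 1]`.
#' @export
variant_fitness <- function(library, model) {
  eff <- model$effects[, c("pos", "alt", "effect_class",
                           "stability_cost", "lambda_binding_effect",
                           "malt_pore_effect")]
  mut <- merge(library$mutations, eff, by = c("pos", "alt"), all.x = TRUE)
  if (anyNA(mut$stability_cost)) stop("library mutation missing from fitness model")
  agg <- mut[, list(
    f_lam = prod((1 - stability_cost) * (1 - lambda_binding_effect)),
    f_mal = prod((1 - stability_cost) * (1 - malt_pore_effect)),
    nons = any(effect_class == "nonsense")
  ), by = "variant_id"]
  out <- data.table::data.table(
    variant_id = seq_len(library$n_variants),
    f_lambda_sensitivity = 1,
    f_malt = 1
  )
  out[agg$variant_id, "f_lambda_sensitivity"] <- ifelse(agg$nons, 0, agg$f_lam)
  out[agg$variant_id, "f_malt"] <- ifelse(agg$nons, 0, agg$f_mal)
  out[]
}

#' Trait fitness of a single variant genotype
#'
#' @param mutations Data frame of the variant's mutations (`pos`, `ref`,
#'   `alt`, CDS coordinates); zero rows is the wild type.
#' @param model A [fitness_model()].
#' @param ref A [reference_amplicon()].
#' @return Named numeric of length 2: `f_lambda_sensitivity`, `f_malt`.
#' @export
trait_fitness <- function(mutations, model, ref) {
  if (nrow(mutations) == 0) {
    return(c(f_lambda_sensitivity = 1, f_malt = 1))
  }
  if (any(mutations$pos < 1 | mutations$pos > cds_length(ref))) {
    stop("mutation outside the coding sequence")
  }
  if (anyDuplicated(mutations$pos)) stop("duplicate mutation positions in variant")
  ann <- annotate_mutations(mutations, ref)
  eff <- merge(
    data.table::as.data.table(ann),
    model$effects[, c("pos", "alt", "stability_cost",
                      "lambda_binding_effect", "malt_pore_effect")],
    by = c("pos", "alt")
  )
  if (any(ann$effect_class == "nonsense")) {
    return(c(f_lambda_sensitivity = 0, f_malt = 0))
  }
  c(
    f_lambda_sensitivity = prod((1 - eff$stability_cost) * (1 - eff$lambda_binding_effect)),
    f_malt = prod((1 - eff$stability_cost) * (1 - eff$malt_pore_effect))
  )
}

#' Single-mutant ground truth
#'
#' The trait fitness each mutation would have in an otherwise wild-type
#' background; the simulator's stand-in for assaying each mutation
#' individually.
#'
#' @param model A [fitness_model()].
#' @return data.table keyed by mutation with `f_lambda_sensitivity` and
#'   `f_malt` columns.
#' @export
single_mutant_truth <- function(model) {
  tab <- data.table::copy(model$effects)
  nons <- tab$effect_class == "nonsense"
  tab$f_lambda_sensitivity <- ifelse(
    nons, 0, (1 - tab$stability_cost) * (1 - tab$lambda_binding_effect)
  )
  tab$f_malt <- ifelse(
    nons, 0, (1 - tab$stability_cost) * (1 - tab$malt_pore_effect)
  )
  tab[]
}

#' Simulate growth competition under a selective condition
#'
#' Expected post-selection frequency is proportional to
#' `pre * 2^(generations * w)`, where `w` is the condition-appropriate
#' relative growth rate: for the lambda condition `w = 1 - f_lambda_sensitivity`
#' (resistant variants grow; sensitive ones are killed by phage), for the
#' maltodextrin condition `w = f_malt` (transport-competent variants grow),
#' and `w = 1` for all variants in the control media. A finite bottleneck
#' resamples the population multinomially.
#'
#' @param library A [generate_library()] result (supplies abundances).
#' @param fitness [variant_fitness()] table for the library.
#' @param condition One of `"lambda"`, `"malt"`, `"control"`.
#' @param generations Number of doublings of an unimpaired variant.
#' @param bottleneck Population size of the multinomial resample; `Inf` for
#'   the deterministic expectation.
#' @param seed Integer seed (used only with a finite bottleneck).
#' @param abundance Optional abundance vector overriding the library's.
#' @return Numeric vector of post-selection frequencies summing to 1.
#' @export
simulate_selection <- function(library, fitness,
                               condition = c("lambda", "malt", "control"),
                               generations = 10, bottleneck = Inf,
                               seed = NULL, abundance = NULL) {
  condition <- match.arg(condition)
  if (generations < 0) stop("generations must be non-negative")
  if (bottleneck <= 0) stop("bottleneck must be positive")
  pre <- if (is.null(abundance)) library$abundance else abundance
  stopifnot(abs(sum(pre) - 1) < 1e-6)
  w <- switch(condition,
    lambda = 1 - fitness$f_lambda_sensitivity,
    malt = fitness$f_malt,
    control = rep(1, length(pre))
  )
  post <- pre * 2^(generations * w)
  post <- post / sum(post)
  if (is.finite(bottleneck)) {
    post <- with_seed(seed, {
      counts <- rmultinom(1, size = as.integer(bottleneck), prob = post)[, 1]
      counts / sum(counts)
    })
  }
  post
}

#' Sequencing specification
#'
#' Tagmentation and paired-end sequencing parameters. Fragment lengths are
#' drawn from a log-normal (rounded, truncated) with median
#' `exp(frag_len_meanlog)`; the default median of 63 bp matches Tn5
#' tagmentation of the amplicon. Each unique fragment is sequenced as
#' `dup_min + Poisson(dup_mean_extra)` identical raw read pairs (PCR
#' duplication), and sequencing errors are injected per raw read at
#' `per_base_error`.
#'
#' @param n_fragments Number of tagmentation fragments per sample.
#' @param read_length Read length of each mate (default 75).
#' @param frag_len_meanlog,frag_len_sdlog Log-normal parameters (defaults
#'   `log(63)` and 0.6).
#' @param frag_len_min,frag_len_max Truncation bounds (defaults 20 and 250).
#' @param per_base_error Per-base sequencing error probability (default 5e-4).
#' @param dup_min,dup_mean_extra Raw-read duplication: minimum copies and
#'   Poisson mean of extra copies (defaults 5 and 2).
#' @param seed Integer seed.
#' @return Object of class `sequencing_spec`.
#' @export
sequencing_spec <- function(n_fragments = 50000L, read_length = 75L,
                            frag_len_meanlog = log(63), frag_len_sdlog = 0.6,
                            frag_len_min = 20L, frag_len_max = 250L,
                            per_base_error = 5e-4,
                            dup_min = 5L, dup_mean_extra = 2,
                            seed = 1L) {
  stopifnot(
    n_fragments >= 1, read_length >= 10,
    per_base_error >= 0, per_base_error < 1,
    frag_len_min >= 1, frag_len_max >= frag_len_min,
    dup_min >= 1, dup_mean_extra >= 0
  )
  structure(
    list(
      n_fragments = as.integer(n_fragments),
      read_length = as.integer(read_length),
      frag_len_meanlog = frag_len_meanlog,
      frag_len_sdlog = frag_len_sdlog,
      frag_len_min = as.integer(frag_len_min),
      frag_len_max = as.integer(frag_len_max),
      per_base_error = per_base_error,
      dup_min = as.integer(dup_min),
      dup_mean_extra = dup_mean_extra,
      seed = as.integer(seed)
    ),
    class = "sequencing_spec"
  )
}

#' Materialise full variant amplicon sequences
#'
#' @param library A [generate_library()] result.
#' @param ref A [reference_amplicon()].
#' @return Character vector of length `n_variants`.
#' @export
build_variant_sequences <- function(library, ref) {
  seqs <- rep(ref$sequence, library$n_variants)
  mut <- library$mutations
  if (nrow(mut) > 0) {
    amp_pos <- cds_to_amplicon(ref, mut$pos)
    ## substr<- is elementwise-vectorised over sequences and positions, but
    ## one variant can carry several mutations; apply one mutation per pass
    dt <- data.table::data.table(v = mut$variant_id, p = amp_pos, a = mut$alt)
    dt[, rank := seq_len(.N), by = "v"]
    for (r in seq_len(max(dt$rank))) {
      sel <- dt[dt$rank == r]
      s <- seqs[sel$v]
      substr(s, sel$p, sel$p) <- sel$a
      seqs[sel$v] <- s
    }
  }
  seqs
}

## inject substitution errors into reads at a per-base rate, one error per
## pass so multiple errors per read are supported
inject_errors <- function(x, rate) {
  if (rate <= 0 || length(x) == 0) return(x)
  n_err <- rbinom(length(x), nchar(x), rate)
  while (any(n_err > 0L)) {
    sel <- which(n_err > 0L)
    pos <- floor(runif(length(sel)) * nchar(x[sel])) + 1L
    cur <- substr(x[sel], pos, pos)
    new <- BASES[floor(runif(length(sel)) * 4) + 1L]
    same <- new == cur
    while (any(same)) {
      new[same] <- BASES[floor(runif(sum(same)) * 4) + 1L]
      same <- new == cur
    }
    xs <- x[sel]
    substr(xs, pos, pos) <- new
    x[sel] <- xs
    n_err[sel] <- n_err[sel] - 1L
  }
  x
}

#' Simulate tagmentation fragments and paired-end reads
#'
#' Draws fragments from the post-selection population (variant chosen
#' proportional to abundance, start uniform, length from the spec's
#' distribution), emits a read pair covering the two fragment ends, replicates
#' each pair per the duplication distribution, and injects per-base
#' sequencing errors independently into every raw read. Ground-truth fragment
#' records (true variant, span and library substitutions) are returned
#' alongside for oracle tests.
#'
#' @param library A [generate_library()] result.
#' @param abundance Post-selection abundance vector (sums to 1).
#' @param ref A [reference_amplicon()].
#' @param spec A [sequencing_spec()].
#' @param variant_seqs Optional precomputed [build_variant_sequences()]
#'   cache; when absent, fragment sequences are built directly from the
#'   reference plus each fragment's substitutions, which keeps memory flat
#'   for very large libraries.
#' @return List with `reads` (data.table `r1`, `r2`, `q1`, `q2`), `truth`
#'   (data.table `fragment_id`, `variant_id`, `start`, `end` in 1-based
#'   inclusive amplicon coordinates) and `truth_subs` (data.table
#'   `fragment_id`, `pos` (amplicon), `ref`, `alt` of library substitutions
#'   carried by each fragment).
#' @export
simulate_reads <- function(library, abundance, ref, spec, variant_seqs = NULL) {
  stopifnot(inherits(spec, "sequencing_spec"))
  A <- nchar(ref$sequence)
  if (spec$frag_len_max > A) stop("fragment length bound exceeds the amplicon")
  with_seed(spec$seed, {
    n <- spec$n_fragments
    vid <- sample.int(library$n_variants, n, replace = TRUE, prob = abundance)
    len <- as.integer(pmin(
      pmax(round(rlnorm(n, spec$frag_len_meanlog, spec$frag_len_sdlog)),
           spec$frag_len_min),
      spec$frag_len_max
    ))
    start <- floor(runif(n) * (A - len + 1)) + 1L
    end <- start + len - 1L
    truth0 <- data.table::data.table(
      fragment_id = seq_len(n), variant_id = vid, start = start, end = end
    )
    mut <- library$mutations
    if (nrow(mut) > 0) {
      m <- data.table::data.table(
        variant_id = mut$variant_id,
        pos = cds_to_amplicon(ref, mut$pos),
        ref = mut$ref, alt = mut$alt
      )
      data.table::setkey(m, variant_id)
      truth_subs <- m[truth0,
        on = c("variant_id", "pos>=start", "pos<=end"),
        nomatch = NULL,
        list(fragment_id = i.fragment_id, pos = x.pos, ref = x.ref, alt = x.alt)
      ]
      data.table::setorderv(truth_subs, c("fragment_id", "pos"))
    } else {
      truth_subs <- data.table::data.table(
        fragment_id = integer(0), pos = integer(0),
        ref = character(0), alt = character(0)
      )
    }
    if (is.null(variant_seqs)) {
      ## fragment = reference window with the carried substitutions applied
      frag <- substring(ref$sequence, start, end)
      if (nrow(truth_subs) > 0) {
        ts <- data.table::copy(truth_subs)
        ts[, off := pos - start[fragment_id] + 1L]
        ts[, rank := seq_len(.N), by = "fragment_id"]
        for (r in seq_len(max(ts$rank))) {
          sel <- ts[ts$rank == r]
          f <- frag[sel$fragment_id]
          substr(f, sel$off, sel$off) <- sel$alt
          frag[sel$fragment_id] <- f
        }
      }
    } else {
      frag <- substring(variant_seqs[vid], start, end)
    }
    rl <- spec$read_length
    r1 <- substring(frag, 1L, pmin(rl, len))
    r2 <- revcomp(substring(frag, pmax(1L, len - rl + 1L), len))

    d <- spec$dup_min + rpois(n, spec$dup_mean_extra)
    idx <- rep(seq_len(n), d)
    r1 <- inject_errors(r1[idx], spec$per_base_error)
    r2 <- inject_errors(r2[idx], spec$per_base_error)
    ## base qualities are uniform in the simulation, so the reads table
    ## carries no quality columns; downstream steps fill a constant quality
    reads <- data.table::data.table(r1 = r1, r2 = r2)
    list(reads = reads, truth = truth0, truth_subs = truth_subs)
  })
}

#' Write paired reads to FASTQ
#'
#' @param reads data.table as returned in `simulate_reads()$reads`.
#' @param path1,path2 Output FASTQ paths for mate 1 and mate 2 (Phred+33).
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  ids <- sprintf("pair%07d", seq_len(nrow(reads)))
  q1 <- if ("q1" %in% names(reads)) reads$q1 else strrep("I", nchar(reads$r1))
  q2 <- if ("q2" %in% names(reads)) reads$q2 else strrep("I", nchar(reads$r2))
  s1 <- Biostrings::DNAStringSet(reads$r1)
  names(s1) <- ids
  s2 <- Biostrings::DNAStringSet(reads$r2)
  names(s2) <- ids
  Biostrings::writeXStringSet(s1, path1, format = "fastq",
    qualities = Biostrings::BStringSet(q1))
  Biostrings::writeXStringSet(s2, path2, format = "fastq",
    qualities = Biostrings::BStringSet(q2))
  invisible(c(path1, path2))
}

#' Read paired FASTQ files
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return data.table with `r1`, `r2`, `q1`, `q2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  f1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  f2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(f1) != length(f2)) stop("mate files differ in read count")
  data.table::data.table(
    r1 = as.character(f1),
    r2 = as.character(f2),
    q1 = as.character(S4Vectors::mcols(f1)$qualities),
    q2 = as.character(S4Vectors::mcols(f2)$qualities)
  )
}

#' Write the variant-level ground truth as TSV
#'
#' One row per variant: its substitutions as a `pos:ref>alt` list (1-based
#' CDS coordinates), its abundance and its two trait fitnesses.
#'
#' @param library A [generate_library()] result.
#' @param fitness Matching [variant_fitness()] table.
#' @param path Output TSV path.
#' @param header Optional provenance header line.
#' @export
write_library_truth <- function(library, fitness, path, header = NULL) {
  mut <- library$mutations
  sig <- mut[, list(
    mutations = paste(sprintf("%d:%s>%s", pos, ref, alt), collapse = ";")
  ), by = "variant_id"]
  out <- data.table::data.table(variant_id = seq_len(library$n_variants))
  out <- merge(out, sig, by = "variant_id", all.x = TRUE)
  out$mutations[is.na(out$mutations)] <- ""
  out$abundance <- library$abundance
  out$f_lambda_sensitivity <- fitness$f_lambda_sensitivity
  out$f_malt <- fitness$f_malt
  write_tsv(out, path, header)
}
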