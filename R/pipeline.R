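#' Configuration for a full synthetic experiment
#'
#' Bundles every parameter of the simulated study: the reference, the
#' ground-truth fitness model, one error-prone library per selection (the
#' high-mutagenesis library, 0.52% per base, competes against phage lambda;
#' the low-mutagenesis library, 0.063% per base, competes for maltodextrin
#' utilisation), the growth model, the sequencing layout of 3 biological x 2
#' technical replicates, and the scoring and classification parameters.
#' Every stochastic stage derives its own seed from the global `seed` via
#' [derive_seed()], so a config reruns byte-identically.
#'
#' Defaults are desk-scale: libraries of 400,000 (lambda) and 20,000 (malt)
#' variants and 500,000 tagmentation fragments per sequencing sample. Library
#' sizes keep several variant backgrounds behind every scoreable mutation, as
#' in the full-scale experiment, so that marginal per-mutation scores average
#' over co-occurring mutations.
#'
#' @param seed Global integer seed.
#' @param n_bio,n_tech Biological and technical replicate counts (3 and 2).
#' @param lambda_n_variants,malt_n_variants Library sizes per selection.
#' @param lambda_rate,malt_rate Per-base mutagenesis rates.
#' @param generations_lambda,generations_malt Doublings of an unimpaired
#'   variant in each selection (default 9 for both: cultures are diluted
#'   1:500 into the selection, so an unimpaired variant doubles about
#'   log2(500) = 9 times before the culture saturates).
#' @param bottleneck Multinomial resample size after selection (1e6).
#' @param n_fragments_lambda,n_fragments_malt Tagmentation fragments per
#'   sequencing sample in each arm.
#' @param per_base_error Sequencing error rate per base.
#' @param frag_len_sdlog Log-normal sdlog of the fragment length
#'   distribution (median fixed at 63 bp).
#' @param pseudocount,min_mean_ctrl Scoring parameters (0.1 and 5).
#' @param thresholds A [threshold_config()].
#' @param t_lambda_refined Stringent lambda threshold used for
#'   lambda-resistant Mal+ candidate discovery (0.35).
#' @param model_args Extra arguments passed to [fitness_model()].
#' @param reference Optional [reference_amplicon()]; defaults to
#'   [synthetic_reference()].
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              n_bio = 3L, n_tech = 2L,
                              lambda_n_variants = 400000L,
                              malt_n_variants = 20000L,
                              lambda_rate = 0.0052,
                              malt_rate = 0.00063,
                              generations_lambda = 9,
                              generations_malt = 9,
                              bottleneck = 1e6,
                              n_fragments_lambda = 500000L,
                              n_fragments_malt = 500000L,
                              per_base_error = 5e-4,
                              frag_len_sdlog = 0.9,
                              pseudocount = 0.1,
                              min_mean_ctrl = 5,
                              thresholds = threshold_config(),
                              t_lambda_refined = 0.35,
                              model_args = list(),
                              reference = NULL) {
  structure(
    list(
      seed = as.integer(seed),
      n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
      lambda_n_variants = as.integer(lambda_n_variants),
      malt_n_variants = as.integer(malt_n_variants),
      lambda_rate = lambda_rate, malt_rate = malt_rate,
      generations_lambda = generations_lambda,
      generations_malt = generations_malt,
      bottleneck = bottleneck,
      n_fragments_lambda = as.integer(n_fragments_lambda),
      n_fragments_malt = as.integer(n_fragments_malt),
      per_base_error = per_base_error,
      frag_len_sdlog = frag_len_sdlog,
      pseudocount = pseudocount,
      min_mean_ctrl = min_mean_ctrl,
      thresholds = thresholds,
      t_lambda_refined = t_lambda_refined,
      model_args = model_args,
      reference = reference
    ),
    class = "experiment_config"
  )
}

## simulate and process all replicates of one selection; returns the
## per-replicate enrichment tables plus processing diagnostics
simulate_selection_arm <- function(config, ref, model, selection,
                                   verbose = TRUE) {
  seed <- config$seed
  is_lam <- selection == "lambda"
  lib <- generate_library(ref, library_spec(
    n_variants = if (is_lam) config$lambda_n_variants else config$malt_n_variants,
    per_base_rate = if (is_lam) config$lambda_rate else config$malt_rate,
    seed = derive_seed(seed, paste0("library_", selection))
  ))
  fit <- variant_fitness(lib, model)
  gens <- if (is_lam) config$generations_lambda else config$generations_malt
  enr <- list()
  counts <- list()
  drops <- list()
  frag_counts <- list()
  for (b in seq_len(config$n_bio)) {
    ab_sel <- simulate_selection(lib, fit, selection,
      generations = gens, bottleneck = config$bottleneck,
      seed = derive_seed(seed, paste0("select_", selection), b)
    )
    ab_ctrl <- simulate_selection(lib, fit, "control",
      generations = gens, bottleneck = config$bottleneck,
      seed = derive_seed(seed, paste0("control_", selection), b)
    )
    for (t in seq_len(config$n_tech)) {
      rep_id <- sprintf("%d.%d", b, t)
      idx <- (b - 1L) * config$n_tech + t
      sample_counts <- lapply(
        c(sel = "sel", ctrl = "ctrl"),
        function(arm) {
          sspec <- sequencing_spec(
            n_fragments = if (is_lam) config$n_fragments_lambda else config$n_fragments_malt,
            per_base_error = config$per_base_error,
            frag_len_sdlog = config$frag_len_sdlog,
            seed = derive_seed(seed, paste0("reads_", selection, "_", arm), idx)
          )
          sim <- simulate_reads(lib,
            if (arm == "sel") ab_sel else ab_ctrl,
            ref, sspec
          )
          proc <- tryCatch(
            process_sample(sim$reads, ref),
            error = function(e) {
              stop(sprintf(
                "stage fragproc failed for selection %s replicate %s (%s): %s",
                selection, rep_id, arm, conditionMessage(e)
              ))
            }
          )
          proc
        }
      )
      if (verbose) {
        message(sprintf(
          "[%s %s] %d / %d unique fragments (sel/ctrl)",
          selection, rep_id,
          nrow(sample_counts$sel$fragments), nrow(sample_counts$ctrl$fragments)
        ))
      }
      enr[[rep_id]] <- compute_enrichment(
        sample_counts$sel$counts, sample_counts$ctrl$counts,
        ref, pseudocount = config$pseudocount
      )
      counts[[rep_id]] <- list(
        sel = sample_counts$sel$counts,
        ctrl = sample_counts$ctrl$counts
      )
      drops[[rep_id]] <- rbind(
        sel = sample_counts$sel$drops,
        ctrl = sample_counts$ctrl$drops
      )
      frag_counts[[rep_id]] <- c(
        sel = nrow(sample_counts$sel$fragments),
        ctrl = nrow(sample_counts$ctrl$fragments)
      )
    }
  }
  list(
    library = lib, fitness = fit, enrichments = enr,
    counts = counts, drops = drops, frag_counts = frag_counts
  )
}

#' Run the full synthetic experiment in memory
#'
#' Simulates both selections end to end (library, growth competition,
#' tagmentation sequencing), processes every sample through the fragment
#' consensus chain, scores both selections, and derives the phenotype-level
#' analyses: calls, Gaussian-intersection threshold on the maltodextrin
#' anchors, KS tests, the Mal+/Mal- ratio curve, per-residue summaries,
#' joint-classifier accuracy, and the lambda-resistant Mal+ candidate set at
#' the refined threshold.
#'
#' @param config An [experiment_config()].
#' @param verbose Emit per-replicate progress messages (default TRUE).
#' @return A list of class `experiment_result`; see the elements written by
#'   [run_pipeline()].
#' @export
run_experiment <- function(config, verbose = TRUE) {
  ref <- if (is.null(config$reference)) synthetic_reference() else config$reference
  model <- do.call(fitness_model, c(
    list(ref = ref, seed = derive_seed(config$seed, "model")),
    config$model_args
  ))
  arms <- list()
  scores <- list()
  averaged <- list()
  for (selection in c("lambda", "malt")) {
    arm <- simulate_selection_arm(config, ref, model, selection, verbose)
    enr_all <- bind_enrichments(arm$enrichments)
    enr_filt <- filter_by_input(enr_all, min_mean_ctrl = config$min_mean_ctrl)
    sc <- scale_to_functional(enr_filt, ref, selection = selection)
    arms[[selection]] <- arm
    scores[[selection]] <- sc
    averaged[[selection]] <- average_replicates(sc)
  }
  calls <- call_phenotypes(averaged$lambda, averaged$malt, config$thresholds)

  mal_avg <- averaged$malt
  gauss <- tryCatch(
    gaussian_intersection_threshold(
      mal_avg$mean_F[mal_avg$effect_class == "synonymous"],
      mal_avg$mean_F[mal_avg$effect_class == "nonsense"]
    ),
    error = function(e) NA_real_
  )
  lam_avg <- averaged$lambda
  ks <- list(
    malt_missense_vs_syn = ks_compare(
      mal_avg$mean_F[mal_avg$effect_class == "missense"],
      mal_avg$mean_F[mal_avg$effect_class == "synonymous"]
    ),
    malt_nonsense_vs_syn = ks_compare(
      mal_avg$mean_F[mal_avg$effect_class == "nonsense"],
      mal_avg$mean_F[mal_avg$effect_class == "synonymous"]
    ),
    lambda_missense_vs_syn = ks_compare(
      lam_avg$mean_F[lam_avg$effect_class == "missense"],
      lam_avg$mean_F[lam_avg$effect_class == "synonymous"]
    )
  )
  ratio_curve <- mal_ratio_curve(calls,
    thresholds = seq(0, 1, by = 0.05),
    t_malt = config$thresholds$t_malt
  )
  candidates <- calls[
    calls$effect_class == "missense" &
      !is.na(calls$F_lambda) & !is.na(calls$F_malt) &
      calls$F_lambda < config$t_lambda_refined &
      calls$F_malt >= config$thresholds$t_malt,
  ]
  accuracy <- classification_accuracy(calls)
  structure(
    list(
      config = config,
      reference = ref,
      model = model,
      truth = single_mutant_truth(model),
      libraries = list(lambda = arms$lambda$library, malt = arms$malt$library),
      counts = list(lambda = arms$lambda$counts, malt = arms$malt$counts),
      drops = list(lambda = arms$lambda$drops, malt = arms$malt$drops),
      scores = scores,
      averaged = averaged,
      replicate_correlation = list(
        lambda = replicate_correlation(scores$lambda),
        malt = replicate_correlation(scores$malt)
      ),
      calls = calls,
      gaussian_intersection = gauss,
      ks = ks,
      ratio_curve = ratio_curve,
      candidates = candidates,
      accuracy = accuracy
    ),
    class = "experiment_result"
  )
}

#' Run the pipeline and write its output tables
#'
#' Executes [run_experiment()] and writes the output tables (scores for each
#' selection, phenotype calls, ratio curve, per-residue summaries, a
#' per-sample fragment/drop summary) plus per-sample count tables and a
#' markdown report to `outdir`. Every TSV carries a provenance header naming
#' the config hash and seed.
#'
#' @param config An [experiment_config()].
#' @param outdir Output directory (created if needed).
#' @param verbose Progress messages.
#' @return The [run_experiment()] result, invisibly.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  res <- run_experiment(config, verbose = verbose)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("config=%s seed=%d", config_hash(config), config$seed)
  for (selection in c("lambda", "malt")) {
    write_tsv(res$averaged[[selection]],
      file.path(outdir, sprintf("scores_%s.tsv", selection)), hdr)
    cdir <- file.path(outdir, "counts", selection)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    for (rep_id in names(res$counts[[selection]])) {
      for (arm in c("sel", "ctrl")) {
        write_tsv(res$counts[[selection]][[rep_id]][[arm]],
          file.path(cdir, sprintf("counts_%s_%s.tsv", rep_id, arm)), hdr)
      }
    }
  }
  frag_rows <- list()
  for (selection in c("lambda", "malt")) {
    for (rep_id in names(res$drops[[selection]])) {
      d <- res$drops[[selection]][[rep_id]]
      for (arm in rownames(d)) {
        frag_rows[[length(frag_rows) + 1L]] <- data.frame(
          selection = selection, replicate = rep_id, arm = arm,
          raw_reads = d[arm, "raw_reads"],
          unique_pairs = d[arm, "unique_pairs"],
          pairs_below_min_raw = d[arm, "pairs_below_min_raw"],
          merged = d[arm, "merged"],
          unmerged_segments = d[arm, "unmerged_segments"],
          discarded_overlap = d[arm, "discarded_overlap"],
          unaligned = d[arm, "unaligned"]
        )
      }
    }
  }
  write_tsv(do.call(rbind, frag_rows),
            file.path(outdir, "fragments_summary.tsv"), hdr)
  write_tsv(res$calls, file.path(outdir, "calls.tsv"), hdr)
  write_tsv(res$ratio_curve, file.path(outdir, "ratio_curve.tsv"), hdr)
  write_tsv(per_residue_summary(res$averaged$lambda),
    file.path(outdir, "per_residue_lambda.tsv"), hdr)
  write_tsv(per_residue_summary(res$averaged$malt),
    file.path(outdir, "per_residue_malt.tsv"), hdr)
  writeLines(make_report(res), file.path(outdir, "report.md"))
  invisible(res)
}

#' Summarise an experiment as a markdown report
#'
#' @param res An `experiment_result` from [run_experiment()].
#' @return Character vector of markdown lines.
#' @export
make_report <- function(res) {
  med <- function(avg, cls) {
    stats::median(avg$mean_F[avg$effect_class == cls])
  }
  lines <- c(
    "# Synthetic dual-selection scan: summary",
    "",
    sprintf("Config `%s`, seed %d.", config_hash(res$config), res$config$seed),
    "",
    "## Score anchors (median mean-F by class)",
    "",
    "| selection | synonymous | missense | nonsense |",
    "|---|---|---|---|",
    sprintf("| lambda | %.3f | %.3f | %.3f |",
      med(res$averaged$lambda, "synonymous"),
      med(res$averaged$lambda, "missense"),
      med(res$averaged$lambda, "nonsense")),
    sprintf("| malt | %.3f | %.3f | %.3f |",
      med(res$averaged$malt, "synonymous"),
      med(res$averaged$malt, "missense"),
      med(res$averaged$malt, "nonsense")),
    "",
    sprintf("Mean pairwise replicate correlation: lambda %.3f, malt %.3f.",
      res$replicate_correlation$lambda, res$replicate_correlation$malt),
    "",
    "## Distribution comparisons",
    "",
    sprintf("- KS malt missense vs synonymous: D = %.3f, p = %.3g",
      res$ks$malt_missense_vs_syn$D, res$ks$malt_missense_vs_syn$p),
    sprintf("- KS malt nonsense vs synonymous: D = %.3f, p = %.3g",
      res$ks$malt_nonsense_vs_syn$D, res$ks$malt_nonsense_vs_syn$p),
    sprintf("- KS lambda missense vs synonymous: D = %.3f, p = %.3g",
      res$ks$lambda_missense_vs_syn$D, res$ks$lambda_missense_vs_syn$p),
    sprintf("- Gaussian intersection of malt synonymous/nonsense: %s",
      if (is.na(res$gaussian_intersection)) "not estimable"
      else sprintf("F = %.3f", res$gaussian_intersection)),
    "",
    sprintf("Joint classifier accuracy on synonymous + nonsense: %.1f%%.",
      100 * res$accuracy),
    "",
    "## Mal+/Mal- ratio by lambda threshold",
    "",
    "| F_lambda threshold | n Mal+ | n Mal- | ratio |",
    "|---|---|---|---|",
    sprintf("| %.2f | %d | %d | %s |",
      res$ratio_curve$threshold,
      res$ratio_curve$n_mal_plus, res$ratio_curve$n_mal_minus,
      ifelse(is.na(res$ratio_curve$ratio), "NA",
             sprintf("%.2f", res$ratio_curve$ratio))),
    "",
    sprintf(
      "## lambda-resistant Mal+ candidates (F_lambda < %.2f, F_malt >= %.2f)",
      res$config$t_lambda_refined, res$config$thresholds$t_malt
    ),
    "",
    if (nrow(res$candidates) == 0) {
      "Zero candidates."
    } else {
      sprintf("%d candidate mutations at %d residues.",
        nrow(res$candidates), length(unique(res$candidates$residue)))
    }
  )
  lines
}
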