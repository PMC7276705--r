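#' Per-mutation log2 enrichment between selection and control
#'
#' For every CDS position and every non-reference base, computes
#' `E = log2(((C_sel_mut + p) / (C_sel_wt + p)) / ((C_ctrl_mut + p) / (C_ctrl_wt + p)))`
#' where the wild-type count is the count of the reference base at that
#' position and `p` is the pseudocount applied to all counts (default 0.1),
#' keeping every E finite.
#'
#' @param sel,ctrl `count_table`s from [count_bases()] for the selected and
#'   control populations; they must share the reference.
#' @param ref A [reference_amplicon()].
#' @param pseudocount Added to all four counts (default 0.1).
#' @return data.table with one row per candidate mutation: `pos` (1-based
#'   CDS coordinate), `ref`, `alt`, `sel_count`, `ctrl_count`, `E`.
#' @export
compute_enrichment <- function(sel, ctrl, ref, pseudocount = 0.1) {
  if (!identical(sel$ref_base, ctrl$ref_base) ||
      !identical(attr(sel, "ref_sequence"), attr(ctrl, "ref_sequence"))) {
    stop("selection and control count tables disagree on the reference")
  }
  idx <- seq(ref$cds_start, ref$cds_end)
  ref_base <- sel$ref_base[idx]
  selm <- as.matrix(sel[idx, BASES])
  ctrlm <- as.matrix(ctrl[idx, BASES])
  ref_col <- match(ref_base, BASES)
  sel_wt <- selm[cbind(seq_along(idx), ref_col)]
  ctrl_wt <- ctrlm[cbind(seq_along(idx), ref_col)]
  ## the three non-reference base columns at each position
  alt_cols <- matrix(0L, nrow = length(ref_col), ncol = 3L)
  for (r in 1:4) {
    hit <- ref_col == r
    alt_cols[hit, ] <- matrix(setdiff(1:4, r), sum(hit), 3L, byrow = TRUE)
  }
  rows <- lapply(1:3, function(j) {
    alt_col <- alt_cols[, j]
    data.table::data.table(
      pos = seq_along(idx),
      ref = ref_base,
      alt = BASES[alt_col],
      sel_count = selm[cbind(seq_along(idx), alt_col)],
      ctrl_count = ctrlm[cbind(seq_along(idx), alt_col)],
      sel_wt = sel_wt,
      ctrl_wt = ctrl_wt
    )
  })
  out <- data.table::rbindlist(rows)
  p <- pseudocount
  out$E <- log2(((out$sel_count + p) / (out$sel_wt + p)) /
                ((out$ctrl_count + p) / (out$ctrl_wt + p)))
  data.table::setorderv(out, c("pos", "alt"))
  out[, c("pos", "ref", "alt", "sel_count", "ctrl_count", "E")][]
}

#' Bind per-replicate enrichment tables
#'
#' @param enr_list Named list of [compute_enrichment()] tables, one per
#'   replicate.
#' @return Single data.table with a `replicate` column.
#' @export
bind_enrichments <- function(enr_list) {
  if (is.null(names(enr_list))) names(enr_list) <- as.character(seq_along(enr_list))
  data.table::rbindlist(enr_list, idcol = "replicate")
}

#' Filter mutations by control-library representation
#'
#' Mutations whose mean control fragment count across replicates is below
#' `min_mean_ctrl` are removed; an average of five or more control counts is
#' the default requirement.
#'
#' @param enr Multi-replicate enrichment table from [bind_enrichments()]
#'   (a single-replicate table also works).
#' @param min_mean_ctrl Minimum mean control count (default 5; the boundary
#'   value itself is retained).
#' @return The filtered table.
#' @export
filter_by_input <- function(enr, min_mean_ctrl = 5) {
  enr <- data.table::as.data.table(enr)
  keep <- enr[, list(mean_ctrl = mean(ctrl_count)), by = c("pos", "ref", "alt")]
  keep <- keep[keep$mean_ctrl >= min_mean_ctrl]
  merge(enr, keep[, c("pos", "ref", "alt")], by = c("pos", "ref", "alt"))[]
}

#' Scale enrichments to functional scores
#'
#' Linear rescaling anchored on the per-replicate medians of the synonymous
#' and nonsense mutations so that the median synonymous score is 1 (function
#' retained) and the median nonsense score is 0 (function lost):
#' `F = (E - median(E_stop)) / (median(E_syn) - median(E_stop))`.
#' Stop-loss mutations are scored but excluded from both anchor sets.
#'
#' The same anchoring convention is applied to both selections. For the
#' maltodextrin selection, `malt_formula = "as-printed"` instead applies the
#' swapped form `F = (E - median(E_syn)) / (median(E_stop) - median(E_syn))`
#' (which maps the synonymous median to 0), provided for comparison only.
#'
#' @param enr Enrichment table (optionally multi-replicate) after
#'   [filter_by_input()].
#' @param ref A [reference_amplicon()].
#' @param selection `"lambda"` or `"malt"` (a label carried into the output).
#' @param malt_formula `"anchored"` (default) or `"as-printed"`.
#' @return data.table of per-replicate scores: mutation key, annotation,
#'   `replicate`, `E`, `F`, `selection`.
#' @export
scale_to_functional <- function(enr, ref, selection = c("lambda", "malt"),
                                malt_formula = c("anchored", "as-printed")) {
  selection <- match.arg(selection)
  malt_formula <- match.arg(malt_formula)
  enr <- data.table::as.data.table(enr)
  if (!"replicate" %in% names(enr)) enr$replicate <- "1"
  ann <- annotate_mutations(
    unique(enr[, c("pos", "ref", "alt")]), ref
  )
  enr <- merge(enr, data.table::as.data.table(ann),
               by = c("pos", "ref", "alt"))
  scale_one <- function(E, effect_class, rep_id) {
    syn <- E[effect_class == "synonymous"]
    stp <- E[effect_class == "nonsense"]
    if (length(syn) == 0 || length(stp) == 0) {
      stop(sprintf("replicate %s lacks synonymous or nonsense anchors", rep_id))
    }
    med_syn <- median(syn)
    med_stp <- median(stp)
    if (med_syn == med_stp) {
      stop(sprintf("degenerate anchors in replicate %s: medians coincide", rep_id))
    }
    if (selection == "malt" && malt_formula == "as-printed") {
      (E - med_syn) / (med_stp - med_syn)
    } else {
      (E - med_stp) / (med_syn - med_stp)
    }
  }
  enr[, F := scale_one(E, effect_class, replicate[1L]), by = "replicate"]
  enr$selection <- selection
  data.table::setorderv(enr, c("pos", "alt", "replicate"))
  enr[]
}

#' Average functional scores across replicates
#'
#' Arithmetic mean of F over the replicates in which each mutation was
#' scored, with the replicate count reported.
#'
#' @param scores Per-replicate score table from [scale_to_functional()].
#' @return data.table with one row per mutation: key, annotation, `mean_F`,
#'   `n_replicates`, `selection`.
#' @export
average_replicates <- function(scores) {
  scores <- data.table::as.data.table(scores)
  out <- scores[, list(
    mean_F = mean(F),
    n_replicates = .N,
    effect_class = effect_class[1L],
    residue = residue[1L],
    ref_aa = ref_aa[1L],
    alt_aa = alt_aa[1L],
    selection = selection[1L]
  ), by = c("pos", "ref", "alt")]
  data.table::setorderv(out, c("pos", "alt"))
  out[]
}

#' Pearson correlation between score replicates
#'
#' Mean pairwise Pearson correlation of F over mutations shared between
#' replicate pairs; the replicate-concordance diagnostic used to choose the
#' input-count threshold.
#'
#' @param scores Per-replicate score table.
#' @return Mean pairwise correlation (NA if fewer than 2 replicates).
#' @export
replicate_correlation <- function(scores) {
  scores <- data.table::as.data.table(scores)
  wide <- data.table::dcast(
    scores, pos + ref + alt ~ replicate, value.var = "F"
  )
  reps <- setdiff(names(wide), c("pos", "ref", "alt"))
  if (length(reps) < 2) return(NA_real_)
  cm <- stats::cor(as.matrix(wide[, reps, with = FALSE]),
                   use = "pairwise.complete.obs")
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}
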