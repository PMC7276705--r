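#' Phenotype-call threshold configuration
#'
#' @param t_lambda Threshold on mean F_lambda below which a mutation is
#'   called lambda-resistant (default 0.5; the refined estimate from
#'   individual assays is 0.35).
#' @param t_malt Threshold on mean F_malt at or above which a mutation is
#'   called Mal+ (default 0.5).
#' @param t_joint Threshold on the two-score mean for the joint
#'   functional/nonfunctional call (default 0.5).
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(t_lambda = 0.5, t_malt = 0.5, t_joint = 0.5) {
  vals <- c(t_lambda, t_malt, t_joint)
  stopifnot(all(vals > -1), all(vals < 2))
  structure(
    list(t_lambda = t_lambda, t_malt = t_malt, t_joint = t_joint),
    class = "threshold_config"
  )
}

#' Call lambda-sensitivity, Mal and joint phenotypes
#'
#' A mutation is called `sensitive` iff its mean F_lambda is at or above
#' `t_lambda` (resistant otherwise), `Mal+` iff mean F_malt is at or above
#' `t_malt`, and `functional` iff the mean of the two scores is at or above
#' `t_joint`. A score exactly at a threshold counts as the functional side.
#' Mutations present in only one score table receive the available
#' single-trait call; their joint call is `NA`.
#'
#' @param scores_lambda,scores_malt Averaged score tables from
#'   [average_replicates()].
#' @param cfg A [threshold_config()].
#' @return data.table with mutation key, both mean scores, `lambda_call`,
#'   `malt_call`, `joint_call` and `effect_class`.
#' @export
call_phenotypes <- function(scores_lambda, scores_malt, cfg = threshold_config()) {
  keycols <- c("pos", "ref", "alt", "effect_class", "residue")
  lam <- data.table::as.data.table(scores_lambda)[, c(keycols, "mean_F"), with = FALSE]
  data.table::setnames(lam, "mean_F", "F_lambda")
  mal <- data.table::as.data.table(scores_malt)[, c(keycols, "mean_F"), with = FALSE]
  data.table::setnames(mal, "mean_F", "F_malt")
  calls <- merge(lam, mal, by = keycols, all = TRUE)
  calls$lambda_call <- ifelse(is.na(calls$F_lambda), NA_character_,
    ifelse(calls$F_lambda >= cfg$t_lambda, "sensitive", "resistant")
  )
  calls$malt_call <- ifelse(is.na(calls$F_malt), NA_character_,
    ifelse(calls$F_malt >= cfg$t_malt, "Mal+", "Mal-")
  )
  joint <- (calls$F_lambda + calls$F_malt) / 2
  calls$joint_call <- ifelse(is.na(joint), NA_character_,
    ifelse(joint >= cfg$t_joint, "functional", "nonfunctional")
  )
  data.table::setorderv(calls, c("pos", "alt"))
  calls[]
}

#' Threshold from the intersection of two fitted Gaussians
#'
#' Fits each class by a moment-matched Gaussian (sample mean and standard
#' deviation) and returns the point between the two means where the fitted
#' densities are equal. With equal variances this is the midpoint of the
#' means; otherwise the pdf-equality condition is a quadratic whose root
#' between the means is returned.
#'
#' @param scores_a,scores_b Numeric score samples for the two classes (each
#'   needs at least two distinct values).
#' @return The threshold (scalar).
#' @export
gaussian_intersection_threshold <- function(scores_a, scores_b) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    stop("each class needs at least two values")
  }
  m1 <- mean(scores_a); s1 <- stats::sd(scores_a)
  m2 <- mean(scores_b); s2 <- stats::sd(scores_b)
  if (s1 == 0 || s2 == 0) {
    stop("zero variance in a class; consider the midpoint of the means instead")
  }
  lo <- min(m1, m2); hi <- max(m1, m2)
  if (abs(s1 - s2) < 1e-12 * max(s1, s2)) {
    return((m1 + m2) / 2)
  }
  ## equal log-densities: quadratic a x^2 + b x + c = 0
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(s2 / s1)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("fitted densities do not intersect between the means")
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside) == 0) {
    stop("no density intersection between the class means")
  }
  inside[which.min(abs(inside - (m1 + m2) / 2))]
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Standard two-sample KS test on the empirical CDFs with the asymptotic
#' p-value.
#'
#' @param scores_a,scores_b Non-empty numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_compare <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    stop("empty sample")
  }
  res <- suppressWarnings(stats::ks.test(scores_a, scores_b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Mal+/Mal- ratio across a grid of lambda-score thresholds
#'
#' For each threshold `t`, restricts to missense mutations with
#' `F_lambda < t` (strictly below, i.e. lambda-resistant at that threshold)
#' and reports how many are Mal+ (`F_malt >= t_malt`) versus Mal-, and their
#' ratio. Only mutations with both scores are counted. A zero denominator
#' yields `NA` with the counts still reported.
#'
#' @param calls Output of [call_phenotypes()] (or any table with `F_lambda`,
#'   `F_malt`, `effect_class`).
#' @param thresholds Numeric grid of F_lambda thresholds.
#' @param t_malt Mal+ threshold (default 0.5).
#' @return data.frame with `threshold`, `n_mal_plus`, `n_mal_minus`, `ratio`.
#' @export
mal_ratio_curve <- function(calls, thresholds = seq(0, 1, by = 0.05),
                            t_malt = 0.5) {
  d <- calls[calls$effect_class == "missense" &
               !is.na(calls$F_lambda) & !is.na(calls$F_malt), ]
  res <- lapply(thresholds, function(t) {
    below <- d[d$F_lambda < t, ]
    n_pos <- sum(below$F_malt >= t_malt)
    n_neg <- sum(below$F_malt < t_malt)
    data.frame(
      threshold = t,
      n_mal_plus = n_pos,
      n_mal_minus = n_neg,
      ratio = if (n_neg == 0) NA_real_ else n_pos / n_neg
    )
  })
  do.call(rbind, res)
}

#' Mean functional score per residue
#'
#' @param scores Averaged score table from [average_replicates()].
#' @return data.table with `residue`, `mean_F` (mean of per-mutation mean
#'   scores at the residue) and `n_mutations`.
#' @export
per_residue_summary <- function(scores) {
  scores <- data.table::as.data.table(scores)
  out <- scores[, list(mean_F = mean(mean_F), n_mutations = .N), by = "residue"]
  data.table::setorderv(out, "residue")
  out[]
}

#' Joint-classifier accuracy on the control classes
#'
#' Fraction of synonymous mutations called functional plus nonsense
#' mutations called nonfunctional, over the union of the two classes (the
#' mutations whose true class is known by construction).
#'
#' @param calls Output of [call_phenotypes()]; rows without a joint call are
#'   ignored.
#' @return Accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(calls) {
  d <- calls[calls$effect_class %in% c("synonymous", "nonsense") &
               !is.na(calls$joint_call), ]
  if (nrow(d) == 0) stop("no synonymous or nonsense mutations with joint calls")
  correct <- (d$effect_class == "synonymous" & d$joint_call == "functional") |
    (d$effect_class == "nonsense" & d$joint_call == "nonfunctional")
  mean(correct)
}
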