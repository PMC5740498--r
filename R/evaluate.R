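# Clinical-comparison utilities: diploid genotype scoring for recessive
# disease, rank-based group comparison, precision-recall analysis with low
# scores treated as the pathogenic class, and the reference-bracketing rule
# used to classify variants of uncertain significance.

#' Diploid score of a genotype
#'
#' For a recessive phenotype a subject's functional capacity is driven by
#' the better-functioning allele, so the diploid score is the maximum of the
#' two allele scores.
#'
#' @param score_a,score_b Finite allele scores (vectorized).
#' @return Pairwise maxima.
#' @export
diploid_score <- function(score_a, score_b) {
  stopifnot(all(is.finite(score_a)), all(is.finite(score_b)))
  pmax(score_a, score_b)
}

#' Mann-Whitney U statistic
#'
#' `U` counts the pairs `(a, b)` across the two groups in which the first
#' group's value is the lower one, with ties contributing 1/2. The reported
#' p-value uses the two-sided normal approximation with tie and continuity
#' corrections; `U` itself is exact.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return list with `U`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  na <- length(group_a); nb <- length(group_b)
  cmp <- outer(group_a, group_b, function(a, b)
    (a < b) + 0.5 * (a == b))
  U <- sum(cmp)
  allv <- c(group_a, group_b)
  ties <- table(allv)
  n <- na + nb
  mu <- na * nb / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_term)
  z <- if (sigma2 > 0) (abs(U - mu) - 0.5) / sqrt(sigma2) else 0
  p <- if (sigma2 > 0) 2 * pnorm(-max(z, 0)) else 1
  list(U = U, p_value = min(p, 1), n_a = na, n_b = nb)
}

#' Precision-recall curve and area under it
#'
#' Sweeps a threshold over the unique scores. With
#' `orientation = "low"` (default) a variant is called positive (e.g.
#' damaging) when its score is at or below the threshold; `"high"` reverses
#' the direction. The area under the curve is the step-wise sum of precision
#' times recall increment (no interpolation).
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) vector; `TRUE` marks the positive class.
#' @param orientation `"low"` if low scores indicate the positive class.
#' @return list with `curve` (data.frame `threshold`, `precision`,
#'   `recall`) and `auc`.
#' @export
precision_recall <- function(scores, labels,
                             orientation = c("low", "high")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) stop("need both classes")
  s <- if (orientation == "low") -scores else scores
  thr <- sort(unique(s))
  n_pos <- sum(labels)
  rows <- lapply(rev(thr), function(t0) {
    called <- s >= t0
    tp <- sum(called & labels)
    data.frame(threshold = if (orientation == "low") -t0 else t0,
               precision = tp / max(sum(called), 1L),
               recall = tp / n_pos)
  })
  curve <- do.call(rbind, rows)
  rec <- c(0, curve$recall)
  auc <- sum(curve$precision * diff(rec))
  list(curve = curve, auc = auc)
}

#' Classify a variant score against reference anchors
#'
#' Reference-bracketing rule: a score strictly below both the highest score
#' among known pathogenic variants and the lowest score among putatively
#' benign reference (e.g. population) variants is called `"damaging"`; a
#' score strictly above both anchors is `"benign"`; anything else is
#' `"uncertain"`.
#'
#' @param score Scores to classify (vectorized).
#' @param max_pathogenic_score Highest score among known pathogenic
#'   variants.
#' @param min_reference_score Lowest score among reference variants.
#' @return Character vector in `{"damaging", "uncertain", "benign"}`.
#' @export
classify_by_references <- function(score, max_pathogenic_score,
                                   min_reference_score) {
  stopifnot(is.finite(max_pathogenic_score), is.finite(min_reference_score))
  lo <- min(max_pathogenic_score, min_reference_score)
  hi <- max(max_pathogenic_score, min_reference_score)
  ifelse(score < lo, "damaging", ifelse(score > hi, "benign", "uncertain"))
}

#' Read a clinical variant table
#'
#' Tab-separated with columns `variant` (e.g. `"D94A"`), `score`, and
#' optionally `maf`, `dms_call`, `indication`, `label`.
#'
#' @param path File path.
#' @return data.frame with parsed `position`, `wt_aa`, `mut_aa` columns
#'   appended.
#' @export
read_clinical_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "score") %in% names(df)))
    stop("clinical table needs 'variant' and 'score' columns")
  cbind(df, parse_variant_string(df$variant))
}
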