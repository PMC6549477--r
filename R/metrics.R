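# Binary confusion metrics, threshold-free curves (AUPR, AUC) and the
# five standard multi-label metrics.

#' Binary classification metrics from confusion counts
#'
#' Precision, accuracy, recall, specificity and Matthews correlation
#' coefficient.  A metric whose denominator is zero is returned as
#' `NA` (undefined) rather than raising an error.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Named list with `precision`, `acc`, `recall`, `specificity`,
#'   `mcc`.
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(precision   = div(tp, tp + fp),
       acc         = div(tp + tn, tp + fp + tn + fn),
       recall      = div(tp, tp + fn),
       specificity = div(tn, tn + fp),
       mcc         = if (mcc_den == 0) NA_real_ else
                       (tp * tn - fp * fn) / mcc_den)
}

#' Confusion counts at a score threshold
#'
#' @param scores Numeric vector.
#' @param labels Binary vector of the same length.
#' @param threshold Call cutoff; a call is `score >= threshold`.
#' @return Named list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  call <- scores >= threshold
  y <- labels != 0
  list(tp = sum(call & y), fp = sum(call & !y),
       tn = sum(!call & !y), fn = sum(!call & y))
}

#' Area under the precision-recall curve
#'
#' Step integral of precision over recall across all distinct score
#' thresholds (descending).  Requires both classes present.  When all
#' scores are tied the curve is the single point (recall 1, precision =
#' prevalence), so the area equals the prevalence.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector.
#' @return AUPR in \[0, 1\].
#' @export
pr_curve_aupr <- function(scores, labels) {
  y <- as.numeric(labels != 0)
  if (sum(y) == 0 || sum(1 - y) == 0) {
    stop("validation error: AUPR needs both classes present",
         call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  cum_tp <- cumsum(y)
  n_pos <- sum(y)
  # threshold boundaries: last index of each distinct score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- cum_tp[last] / last
  rec <- cum_tp[last] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney rank identity with average ranks for
#' ties.
#'
#' @inheritParams pr_curve_aupr
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- labels != 0
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("validation error: AUC needs both classes present",
         call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multi-label evaluation metrics
#'
#' Hamming loss (fraction of wrong binary calls at 0.5), one-error
#' (fraction of instances where no relevant label attains the top
#' score), coverage (0-based: mean of the worst rank over relevant
#' labels minus one), ranking loss (fraction of relevant/irrelevant
#' label pairs ordered wrongly, ties counting one half) and average
#' precision.  Within-instance score ties are handled by the
#' "greater-or-equal" rank convention (`rank(l) = #\{labels with score
#' >= score(l)\}`), which keeps every metric order-independent and
#' preserves the perfect-score identities.  Instances with no relevant
#' label are skipped for the rank-based metrics; their count is
#' attached as attribute `n_skipped`.
#'
#' @param scores Numeric matrix, instances x labels.
#' @param labels Binary matrix of the same shape.
#' @return Named list `hamming_loss`, `one_error`, `coverage`,
#'   `ranking_loss`, `average_precision` with attribute `n_skipped`.
#' @export
multilabel_metrics <- function(scores, labels) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (!all(dim(scores) == dim(labels))) {
    stop("validation error: score and label shapes differ", call. = FALSE)
  }
  hamming <- mean((scores >= 0.5) != (labels != 0))

  one_err <- cov <- rloss <- ap <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, ]; y <- labels[i, ] != 0
    if (!any(y)) { n_skipped <- n_skipped + 1L; next }
    ge_rank <- vapply(s, function(v) sum(s >= v), numeric(1))
    one_err <- c(one_err, as.numeric(max(s[y]) < max(s)))
    cov <- c(cov, max(ge_rank[y]) - 1)
    if (any(!y)) {
      sr <- s[y]; si <- s[!y]
      wrong <- sum(outer(sr, si, `<`)) + 0.5 * sum(outer(sr, si, `==`))
      rloss <- c(rloss, wrong / (length(sr) * length(si)))
    }
    ap <- c(ap, mean(vapply(which(y), function(l) {
      sum(s[y] >= s[l]) / sum(s >= s[l])
    }, numeric(1))))
  }
  if (n_skipped > 0) {
    message(n_skipped, " instance(s) without relevant labels skipped ",
            "for rank-based metrics")
  }
  structure(
    list(hamming_loss = hamming,
         one_error = if (length(one_err)) mean(one_err) else NA_real_,
         coverage = if (length(cov)) mean(cov) else NA_real_,
         ranking_loss = if (length(rloss)) mean(rloss) else NA_real_,
         average_precision = if (length(ap)) mean(ap) else NA_real_),
    n_skipped = n_skipped)
}

#' Full evaluation report for scored pairs
#'
#' Binary metrics at the threshold plus AUC and AUPR on a flat vector
#' of scores and labels.
#'
#' @inheritParams confusion_counts
#' @return Named list of metrics.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_counts(scores, labels, threshold)
  c(binary_metrics(cc$tp, cc$fp, cc$tn, cc$fn),
    list(auc = roc_auc(scores, labels),
         aupr = pr_curve_aupr(scores, labels)))
}
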