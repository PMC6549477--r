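# Multi-label k-nearest-neighbour classifier.
#
# For each label l the model stores the Laplace-smoothed prior
#   P(H1_l) = (s + sum_i y_i(l)) / (2s + n)
# and, from the count tables c_l[j] (number of training instances
# CARRYING label l with exactly j positive neighbours for l among their
# k nearest, excluding themselves) and c'_l[j] (likewise among instances
# NOT carrying l),
#   P(E_j | H1_l) = (s + c_l[j])  / (s(k+1) + sum_i c_l[i])
#   P(E_j | H0_l) = (s + c'_l[j]) / (s(k+1) + sum_i c'_l[i]),
# so the tables sum to the positive and negative instance counts
# respectively.  A test instance with C positive neighbours for l is
# scored by the normalized two-hypothesis posterior
#   P(H1)P(E_C|H1) / (P(H1)P(E_C|H1) + P(H0)P(E_C|H0)),
# which lies in [0,1]; the MAP hard label is score >= 0.5.

euclid_dist <- function(a, b = a) {
  as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                      nrow(a) + seq_len(nrow(b)),
                                      drop = FALSE]
}

# k nearest rows of `train` for each row of `x`; ties at the k-th
# distance broken by ascending train-row index.  `exclude_self = TRUE`
# skips neighbour j == i (leave-one-out during fitting).
knn_index <- function(dmat, k, exclude_self = FALSE) {
  n <- ncol(dmat)
  avail <- n - if (exclude_self) 1L else 0L
  if (k > avail) {
    stop("configuration error: k = ", k, " exceeds the ", avail,
         " available neighbours", call. = FALSE)
  }
  idx <- vapply(seq_len(nrow(dmat)), function(i) {
    d <- dmat[i, ]
    if (exclude_self) d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k))
  if (k == 1) matrix(idx, ncol = 1) else t(idx)
}

#' Fit an MLKNN model
#'
#' @param train_features Numeric matrix, one row per instance.
#' @param train_labels Binary (0/1) matrix, same number of rows, one
#'   column per label.
#' @param k Neighbour count (default 10, the canonical MLKNN setting).
#' @param s Laplace smoothing factor (default 1).
#' @return Object of class `mlknn` holding priors, posterior tables,
#'   the count tables and the training data.
#' @export
mlknn_fit <- function(train_features, train_labels, k = 10, s = 1) {
  x <- as.matrix(train_features)
  y <- as.matrix(train_labels)
  storage.mode(y) <- "double"
  if (nrow(x) != nrow(y)) {
    stop("validation error: feature and label row counts differ",
         call. = FALSE)
  }
  if (any(!(y %in% c(0, 1)))) {
    stop("validation error: labels must be binary", call. = FALSE)
  }
  n <- nrow(x); q <- ncol(y)
  nn <- knn_index(euclid_dist(x), k, exclude_self = TRUE)

  # C[i, l]: positive neighbours of instance i for label l
  C <- matrix(0L, n, q)
  for (i in seq_len(n)) C[i, ] <- as.integer(colSums(y[nn[i, ], ,
                                                       drop = FALSE]))

  c1 <- t(vapply(seq_len(q), function(l) {
    tabulate(C[y[, l] == 1, l] + 1L, nbins = k + 1L)
  }, integer(k + 1L)))                        # q x (k+1): c_l[j]
  c0 <- t(vapply(seq_len(q), function(l) {
    tabulate(C[y[, l] == 0, l] + 1L, nbins = k + 1L)
  }, integer(k + 1L)))                        # q x (k+1): c'_l[j]

  prior_h1 <- (s + colSums(y)) / (s * 2 + n)
  post_h1 <- (s + c1) / (s * (k + 1) + rowSums(c1))
  post_h0 <- (s + c0) / (s * (k + 1) + rowSums(c0))

  structure(list(k = k, s = s, n = n, q = q,
                 train_features = x, train_labels = y,
                 prior_h1 = prior_h1, posterior_h1 = post_h1,
                 posterior_h0 = post_h0, c1 = c1, c0 = c0),
            class = "mlknn")
}

#' Membership counts of test instances
#'
#' Counts, per label, how many of an instance's k nearest training
#' neighbours carry the label; values lie in `[0, k]`.
#'
#' @param model A fitted `mlknn` model.
#' @param instance_features Numeric vector (one instance) or matrix.
#' @return Integer matrix, instances x labels.
#' @export
membership_counts <- function(model, instance_features) {
  stopifnot(inherits(model, "mlknn"))
  x <- instance_features
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$train_features)) {
    stop("validation error: feature dimension mismatch", call. = FALSE)
  }
  dmat <- euclid_dist(x, model$train_features)
  nn <- knn_index(dmat, model$k)
  C <- vapply(seq_len(nrow(x)), function(i) {
    as.integer(colSums(model$train_labels[nn[i, ], , drop = FALSE]))
  }, integer(model$q))
  if (model$q == 1) matrix(C, ncol = 1) else t(C)
}

#' Predict label scores for test instances
#'
#' @param model A fitted `mlknn` model.
#' @param test_features Numeric matrix (or vector for one instance).
#' @return Numeric matrix in \[0, 1\], instances x labels: the
#'   normalized two-hypothesis posterior; the MAP hard label is
#'   `score >= 0.5`.
#' @export
mlknn_predict <- function(model, test_features) {
  C <- membership_counts(model, test_features)
  m <- nrow(C); q <- model$q
  out <- matrix(0, m, q)
  for (l in seq_len(q)) {
    p1 <- model$prior_h1[l] * model$posterior_h1[l, C[, l] + 1L]
    p0 <- (1 - model$prior_h1[l]) * model$posterior_h0[l, C[, l] + 1L]
    out[, l] <- p1 / (p1 + p0)
  }
  out
}

#' @export
print.mlknn <- function(x, ...) {
  cat("MLKNN model: n =", x$n, " labels =", x$q,
      " k =", x$k, " s =", x$s, "\n")
  invisible(x)
}
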