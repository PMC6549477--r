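# Weighted-scoring ensemble of per-feature MLKNN base predictors.
#
# For each of the four feature kinds, five MLKNN models are fitted on
# five internal folds of the training drugs; each candidate simplex
# weight vector is scored by the AUPR of the weighted out-of-fold score
# matrix over eligible (drug, disease) cells, and the maximizer is kept.
# Final predictions average the five fold models per feature and combine
# the four feature score matrices by the tuned weights.

#' Enumerate the simplex weight grid
#'
#' All non-negative weight vectors of length `m` with entries that are
#' multiples of `step` and sum to 1, plus the exact uniform vector
#' (appended so that full ties can resolve to uniform weights even when
#' `1/m` is not a multiple of `step`).
#'
#' @param m Number of weights.
#' @param step Grid resolution; `1/step` must be (near-)integer.
#' @return Numeric matrix, one candidate per row, in deterministic
#'   lexicographic enumeration order.
#' @export
simplex_grid <- function(m, step = 0.1) {
  units <- round(1 / step)
  if (abs(units * step - 1) > 1e-9 || units < 1) {
    stop("validation error: 1/step must be a positive integer",
         call. = FALSE)
  }
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, ncol = 1))
    do.call(rbind, lapply(0:total, function(i) {
      cbind(i, compositions(total - i, parts - 1))
    }))
  }
  grid <- compositions(units, m) / units
  grid <- rbind(grid, rep(1 / m, m))
  grid[!duplicated(round(grid, 12)), , drop = FALSE]
}

# Internal 5-fold assignment stratified by per-drug positive-label
# cardinality bands (0, 1-2, >=3).  Returns an integer fold id per drug.
make_folds <- function(labels, nfold, seed) {
  n <- nrow(labels)
  if (nfold > n) {
    stop("configuration error: more folds than drugs", call. = FALSE)
  }
  card <- rowSums(labels)
  band <- cut(card, c(-Inf, 0.5, 2.5, Inf), labels = FALSE)
  draw <- function(sd) {
    fold <- integer(n)
    withr::with_seed(sd, {
      for (b in unique(band)) {
        idx <- which(band == b)
        fold[idx] <- rep_len(seq_len(nfold), length(idx))[sample.int(length(idx))]
      }
    })
    fold
  }
  ok <- function(fold) {
    all(vapply(seq_len(nfold), function(f) {
      sum(labels[fold != f, ]) >= 1
    }, logical(1)))
  }
  fold <- draw(seed)
  if (!ok(fold)) fold <- draw(seed + 1000003L)
  if (!ok(fold)) {
    stop("degenerate labels: an internal fold has no positive labels ",
         "after one redraw", call. = FALSE)
  }
  fold
}

#' Average and spread of a five-fold model group
#'
#' Cell-wise mean and population standard deviation of the score
#' matrices produced by the five fold models of one feature kind.
#'
#' @param group List of exactly five fitted `mlknn` models.
#' @param test_features Feature matrix to score.
#' @return List with matrices `mean` and `sd`.
#' @export
feature_group_score <- function(group, test_features) {
  if (length(group) != 5) {
    stop("configuration error: a feature group must hold exactly 5 models",
         call. = FALSE)
  }
  scores <- lapply(group, mlknn_predict, test_features = test_features)
  mean_m <- Reduce(`+`, scores) / 5
  var_m <- Reduce(`+`, lapply(scores, function(s) (s - mean_m)^2)) / 5
  list(mean = mean_m, sd = sqrt(var_m))
}

#' Weighted combination of score matrices
#'
#' @param score_matrices List of m equal-shape numeric matrices.
#' @param weights Length-m simplex vector (non-negative, sums to 1
#'   within 1e-9).
#' @return The cell-wise weighted sum.
#' @export
combine_scores <- function(score_matrices, weights) {
  if (length(score_matrices) != length(weights)) {
    stop("validation error: need one weight per score matrix",
         call. = FALSE)
  }
  if (any(weights < -1e-9) || abs(sum(weights) - 1) > 1e-9) {
    stop("validation error: weights must lie on the unit simplex",
         call. = FALSE)
  }
  dims <- lapply(score_matrices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("validation error: score matrices differ in shape", call. = FALSE)
  }
  Reduce(`+`, Map(`*`, score_matrices, weights))
}

#' Tune ensemble weights by internal cross-validated AUPR
#'
#' Fits, per feature kind, one MLKNN model on each of five internal
#' folds of the drugs; exhaustively searches the simplex grid for the
#' weight vector whose combined out-of-fold score matrix maximizes AUPR
#' over eligible (drug, disease) cells.  Fitness ties are broken toward
#' the uniform vector, then by enumeration order.
#'
#' @param ds A `genodrug_dataset` with at least `nfold` drugs.
#' @param k,s MLKNN neighbour count and smoothing factor.
#' @param grid_step Simplex grid resolution (default 0.1: 286 candidates
#'   for four features, plus the uniform vector).
#' @param nfold Number of internal folds (default 5).
#' @param seed Integer seed controlling the fold draw.
#' @param points Database point table for the features.
#' @return Object of class `genodrug_ensemble`: base predictors (one
#'   five-model group per feature kind), tuned `weights`, achieved
#'   `fitness` (internal CV AUPR), fold assignment and out-of-fold
#'   scores.
#' @export
tune_weights <- function(ds, k = 10, s = 1, grid_step = 0.1, nfold = 5,
                         seed = 1, points = default_point_table()) {
  stopifnot(inherits(ds, "genodrug_dataset"))
  core <- tune_core(feats = build_feature_matrices(ds, points),
                    labels = indication_matrix(ds) * 1,
                    elig = eligible_matrix(ds),
                    k = k, s = s, grid_step = grid_step, nfold = nfold,
                    seed = seed)
  structure(
    c(core,
      list(k = k, s = s, grid_step = grid_step, nfold = nfold,
           seed = seed, points = validate_point_table(points),
           diseases = ds$diseases, drug_order = ds$drug_order)),
    class = "genodrug_ensemble")
}

# Fold fitting, out-of-fold scoring and simplex search over arbitrary
# feature matrices; shared by tune_weights and tests.
tune_core <- function(feats, labels, elig, k, s, grid_step, nfold,
                      seed) {
  n <- nrow(labels)
  fold <- make_folds(labels, nfold, seed)

  base <- vector("list", length(feats))
  names(base) <- names(feats)
  oof <- lapply(feats, function(f) matrix(NA_real_, n, ncol(labels)))
  for (fk in names(feats)) {
    base[[fk]] <- vector("list", nfold)
    for (f in seq_len(nfold)) {
      tr <- fold != f
      model <- mlknn_fit(feats[[fk]][tr, , drop = FALSE],
                         labels[tr, , drop = FALSE], k = k, s = s)
      base[[fk]][[f]] <- model
      oof[[fk]][!tr, ] <- mlknn_predict(model,
                                        feats[[fk]][!tr, , drop = FALSE])
    }
  }

  y <- labels[elig]
  if (sum(y) < 1 || sum(1 - y) < 1) {
    stop("degenerate labels: eligible cells are single-class",
         call. = FALSE)
  }
  cand <- simplex_grid(length(feats), grid_step)
  fitness <- vapply(seq_len(nrow(cand)), function(i) {
    comb <- combine_scores(oof, cand[i, ])
    pr_curve_aupr(comb[elig], y)
  }, numeric(1))

  best <- which(fitness >= max(fitness) - 1e-12)
  if (length(best) > 1) {
    d2u <- rowSums((cand[best, , drop = FALSE] - 1 / length(feats))^2)
    best <- best[d2u <= min(d2u) + 1e-12]
  }
  best <- best[1]

  list(base_predictors = base,
       weights = stats::setNames(cand[best, ], names(feats)),
       fitness = fitness[best],
       feature_kinds = names(feats),
       fold = fold, oof = oof)
}

#' @export
print.genodrug_ensemble <- function(x, ...) {
  cat("genodrug ensemble:", length(x$feature_kinds),
      "feature kinds x", x$nfold, "fold models; k =", x$k,
      " s =", x$s, "\n")
  cat("  weights:",
      paste(sprintf("%s=%.3f", x$feature_kinds, x$weights),
            collapse = " "), "\n")
  cat("  internal CV AUPR:", format(x$fitness, digits = 4), "\n")
  invisible(x)
}

# Per-fold combined score matrices for a dataset, plus mean and sd.
ensemble_scores <- function(model, ds) {
  if (!identical(ds$diseases, model$diseases)) {
    stop("validation error: dataset diseases differ from the model's",
         call. = FALSE)
  }
  feats <- build_feature_matrices(ds, model$points)
  per_fold <- lapply(seq_len(model$nfold), function(f) {
    mats <- lapply(model$feature_kinds, function(fk) {
      mlknn_predict(model$base_predictors[[fk]][[f]], feats[[fk]])
    })
    combine_scores(mats, model$weights)
  })
  mean_m <- Reduce(`+`, per_fold) / model$nfold
  var_m <- Reduce(`+`, lapply(per_fold, function(s) (s - mean_m)^2)) /
    model$nfold
  dimnames(mean_m) <- list(ds$drug_order, ds$diseases)
  list(mean = mean_m, sd = sqrt(var_m))
}

#' Predict drug-disease activities with a tuned ensemble
#'
#' Scores every eligible (drug, disease) pair of `ds` by averaging the
#' per-fold combined score matrices, and calls a pair active when its
#' score reaches the threshold.
#'
#' @param object A `genodrug_ensemble` from [tune_weights()].
#' @param ds A `genodrug_dataset` whose disease list matches the model's.
#' @param threshold Score cutoff in \[0, 1\] (default 0.5).
#' @param ... Unused.
#' @return data.frame `drug_id`, `disease_id`, `score`, `sd`, `call`,
#'   eligible pairs only, sorted by descending score.
#' @export
predict.genodrug_ensemble <- function(object, ds, threshold = 0.5, ...) {
  stopifnot(threshold >= 0, threshold <= 1)
  sc <- ensemble_scores(object, ds)
  elig <- eligible_matrix(ds)
  idx <- which(elig, arr.ind = TRUE)
  out <- data.frame(drug_id = rownames(elig)[idx[, 1]],
                    disease_id = colnames(elig)[idx[, 2]],
                    score = sc$mean[idx], sd = sc$sd[idx],
                    stringsAsFactors = FALSE)
  out$call <- out$score >= threshold
  out <- out[order(-out$score, out$drug_id, out$disease_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
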