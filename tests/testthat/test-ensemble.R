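test_that("simplex grid enumerates the expected candidates", {
  # step 0.5 over two weights: (0,1), (0.5,0.5), (1,0)
  g <- simplex_grid(2, 0.5)
  expect_equal(nrow(g), 3)
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
  # four weights at step 0.1: 286 compositions + the uniform vector
  g4 <- simplex_grid(4, 0.1)
  expect_equal(nrow(g4), 287)
  expect_true(any(apply(g4, 1, function(w) all(w == 0.25))))
  expect_error(simplex_grid(2, 0.3), "validation error")
})

test_that("group scoring averages five fold models", {
  p <- withr::with_seed(1, list(x = matrix(runif(40), 20, 2),
                                y = matrix(rbinom(40, 1, 0.4), 20, 2)))
  m <- mlknn_fit(p$x, p$y, k = 3, s = 1)
  # five identical models: zero spread
  gs <- feature_group_score(rep(list(m), 5), p$x)
  expect_lt(max(gs$sd), 1e-12)
  expect_equal(gs$mean, mlknn_predict(m, p$x))
  expect_error(feature_group_score(rep(list(m), 4), p$x),
               "configuration error")

  # mean/sd match element-wise recomputation over distinct models
  models <- lapply(1:5, function(i) {
    withr::with_seed(i, mlknn_fit(p$x + matrix(runif(40), 20, 2) * 0.5,
                                  p$y, k = 3, s = 1))
  })
  gs2 <- feature_group_score(models, p$x)
  mats <- lapply(models, mlknn_predict, test_features = p$x)
  expect_equal(gs2$mean, Reduce(`+`, mats) / 5)
  expect_equal(gs2$sd,
               sqrt(Reduce(`+`, lapply(mats,
                                       function(s) (s - gs2$mean)^2)) / 5))
})

test_that("combine_scores is a validated convex combination", {
  a <- matrix(0, 2, 2); b <- matrix(1, 2, 2)
  expect_equal(combine_scores(list(a, b), c(0.5, 0.5)),
               matrix(0.5, 2, 2))
  expect_equal(combine_scores(list(b, a, a, a), c(1, 0, 0, 0)), b)
  expect_error(combine_scores(list(a, b), c(0.7, 0.5)),
               "simplex")
  expect_error(combine_scores(list(a, matrix(1, 3, 2)), c(0.5, 0.5)),
               "shape")

  # convexity: ensemble score bounded by the per-feature extremes
  mats <- withr::with_seed(2, lapply(1:4, function(i)
    matrix(runif(30), 5, 6)))
  comb <- combine_scores(mats, c(0.1, 0.2, 0.3, 0.4))
  lo <- Reduce(pmin, mats); hi <- Reduce(pmax, mats)
  expect_true(all(comb >= lo - 1e-12 & comb <= hi + 1e-12))
})

test_that("weight tuning puts the largest weight on the informative feature", {
  withr::with_seed(20, {
    n <- 200; q <- 8
    labels <- matrix(rbinom(n * q, 1, 0.1), n, q)
    informative <- labels * 2 + matrix(runif(n * q), n, q)
    feats <- list(inf = informative,
                  n1 = matrix(runif(n * q), n, q),
                  n2 = matrix(runif(n * q), n, q),
                  n3 = matrix(runif(n * q), n, q))
  })
  elig <- matrix(TRUE, 200, 8)
  core <- genodrug:::tune_core(feats, labels, elig, k = 10, s = 1,
                               grid_step = 0.1, nfold = 5, seed = 1)
  expect_equal(names(which.max(core$weights)), "inf")
  # weights sit on the simplex
  expect_equal(sum(core$weights), 1, tolerance = 1e-9)
})

test_that("identical features fall back to uniform weights", {
  withr::with_seed(4, {
    f <- matrix(runif(40 * 3), 40, 3)
    labels <- matrix(rbinom(120, 1, 0.3), 40, 3)
  })
  feats <- list(a = f, b = f, c = f, d = f)
  core <- genodrug:::tune_core(feats, labels, matrix(TRUE, 40, 3),
                               k = 3, s = 1, grid_step = 0.1,
                               nfold = 5, seed = 2)
  expect_equal(unname(core$weights), rep(0.25, 4))
})

test_that("the tuned ensemble dominates its corner predictors", {
  ds <- generate_corpus(sim_config(seed = 31))$dataset
  model <- tune_weights(ds, k = 10, seed = 31)
  elig <- genodrug:::eligible_matrix(ds)
  y <- (genodrug:::indication_matrix(ds) * 1)[elig]
  for (fk in model$feature_kinds) {
    corner <- pr_curve_aupr(model$oof[[fk]][elig], y)
    expect_gte(model$fitness, corner)
  }
})

test_that("prediction is a thresholded, sorted view over eligible pairs", {
  ds <- generate_corpus(sim_config(n_genes = 80, n_diseases = 8,
                                   n_drugs = 40, seed = 12))$dataset
  model <- tune_weights(ds, k = 5, seed = 12)

  # threshold 0 calls every eligible pair; an impossible threshold none
  all_called <- predict(model, ds, threshold = 0)
  expect_equal(nrow(all_called), nrow(eligible_pairs(ds)))
  expect_true(all(all_called$call))
  expect_true(all(diff(all_called$score) <= 0))
  none <- predict(model, ds, threshold = 1)
  expect_true(sum(none$call) <= sum(none$score >= 1))

  # calls equal an independently recombined threshold sweep
  sc <- genodrug:::ensemble_scores(model, ds)
  elig <- genodrug:::eligible_matrix(ds)
  thr <- stats::median(all_called$score)
  preds <- predict(model, ds, threshold = thr)
  key <- paste(preds$drug_id, preds$disease_id)
  manual <- which(elig, arr.ind = TRUE)
  manual_key <- paste(rownames(elig)[manual[, 1]],
                      colnames(elig)[manual[, 2]])
  manual_call <- sc$mean[manual] >= thr
  expect_setequal(key[preds$call], manual_key[manual_call])
})

test_that("tuning is reproducible and serializes losslessly", {
  ds <- generate_corpus(sim_config(n_genes = 80, n_diseases = 8,
                                   n_drugs = 40, seed = 8))$dataset
  m1 <- tune_weights(ds, k = 5, seed = 3)
  m2 <- tune_weights(ds, k = 5, seed = 3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, ds), predict(m2, ds))

  path <- withr::local_tempfile(fileext = ".json")
  write_model(m1, path)
  m3 <- read_model(path)
  expect_equal(m3$weights, m1$weights)
  p1 <- predict(m1, ds); p3 <- predict(m3, ds)
  expect_equal(p3$score, p1$score, tolerance = 1e-12)
  # an arbitrary JSON file is rejected
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "other"}', bad)
  expect_error(read_model(bad), "format error")
})
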