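# End-to-end pipeline and model artifact (de)serialization.

MODEL_FORMAT <- "genodrug-ensemble"
MODEL_FORMAT_VERSION <- 1L

#' Write an ensemble model as a structured text artifact
#'
#' JSON with a format tag, the tuned weights and every fold model's
#' priors, posterior/count tables and training data, plus a fingerprint
#' (dimensions and rounded checksums) of the training matrices.
#'
#' @param model A `genodrug_ensemble`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "genodrug_ensemble"))
  ser_mlknn <- function(m) {
    list(k = m$k, s = m$s, n = m$n, q = m$q,
         train_features = m$train_features,
         train_labels = m$train_labels,
         prior_h1 = m$prior_h1,
         posterior_h1 = m$posterior_h1, posterior_h0 = m$posterior_h0,
         c1 = m$c1, c0 = m$c0)
  }
  obj <- list(
    format = MODEL_FORMAT, format_version = MODEL_FORMAT_VERSION,
    k = model$k, s = model$s, grid_step = model$grid_step,
    nfold = model$nfold, seed = model$seed,
    feature_kinds = model$feature_kinds,
    weights = as.list(model$weights),
    fitness = model$fitness,
    fold = model$fold,
    points = as.list(model$points),
    diseases = model$diseases, drug_order = model$drug_order,
    fingerprint = list(
      n_drugs = length(model$drug_order),
      n_diseases = length(model$diseases),
      checksum = round(sum(vapply(model$base_predictors[[1]],
                                  function(m) sum(m$train_features),
                                  numeric(1))), 6)),
    base_predictors = lapply(model$base_predictors,
                             function(group) lapply(group, ser_mlknn)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read an ensemble model artifact
#'
#' @param path File written by [write_model()].
#' @return A `genodrug_ensemble`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop("format error: not a ", MODEL_FORMAT, " artifact", call. = FALSE)
  }
  as_mat <- function(rows) {
    do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  }
  de_mlknn <- function(m) {
    structure(list(k = m$k, s = m$s, n = m$n, q = m$q,
                   train_features = as_mat(m$train_features),
                   train_labels = as_mat(m$train_labels),
                   prior_h1 = unlist(m$prior_h1, use.names = FALSE),
                   posterior_h1 = as_mat(m$posterior_h1),
                   posterior_h0 = as_mat(m$posterior_h0),
                   c1 = as_mat(m$c1), c0 = as_mat(m$c0)),
              class = "mlknn")
  }
  structure(
    list(base_predictors = lapply(obj$base_predictors,
                                  function(g) lapply(g, de_mlknn)),
         weights = unlist(obj$weights),
         fitness = obj$fitness,
         feature_kinds = unlist(obj$feature_kinds, use.names = FALSE),
         k = obj$k, s = obj$s, grid_step = obj$grid_step,
         nfold = obj$nfold, seed = obj$seed,
         fold = unlist(obj$fold, use.names = FALSE),
         points = validate_point_table(unlist(obj$points)),
         diseases = unlist(obj$diseases, use.names = FALSE),
         drug_order = unlist(obj$drug_order, use.names = FALSE)),
    class = "genodrug_ensemble")
}

#' Read a flat key-value run configuration
#'
#' YAML mapping of scalar keys (input paths, `k`, `s`, `grid_step`,
#' `threshold`, `seed`, `n_perm`, `out_dir`).  Unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("associations", "drug_targets", "indications", "ohnologs",
             "out_dir", "k", "s", "grid_step", "threshold", "seed",
             "n_perm", "nfold", "points")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("format error: unknown config key(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(proc.time()["elapsed"]) - t0))
}

#' Run the full scoring-and-prediction pipeline
#'
#' Loads (or takes) a corpus, computes druggability scores and the four
#' feature matrices, tunes the MLKNN ensemble by internal CV AUPR,
#' predicts all eligible pairs, evaluates the out-of-fold scores, and
#' writes every artifact plus a run manifest into `out_dir`.
#'
#' @param ds A `genodrug_dataset`, or `NULL` to load from the four
#'   paths.
#' @param assoc_path,drugs_path,indications_path,ohnolog_path Input
#'   TSVs (ignored when `ds` is given).
#' @param out_dir Artifact directory (created).
#' @param k,s,grid_step,nfold,threshold,seed Model parameters; see
#'   [tune_weights()] and [predict.genodrug_ensemble()].
#' @param points Database point table.
#' @return Invisibly, a list with the model, predictions, evaluation
#'   and artifact paths.
#' @export
run_pipeline <- function(ds = NULL, assoc_path = NULL, drugs_path = NULL,
                         indications_path = NULL, ohnolog_path = NULL,
                         out_dir, k = 10, s = 1, grid_step = 0.1,
                         nfold = 5, threshold = 0.5, seed = 1,
                         points = default_point_table()) {
  stopifnot(threshold >= 0, threshold <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(proc.time()["elapsed"])
  if (is.null(ds)) {
    ds <- load_dataset(assoc_path, drugs_path, indications_path,
                       ohnolog_path)
  }
  stage_msg("load", t0)

  t0 <- as.numeric(proc.time()["elapsed"])
  scores <- score_all(ds, points)
  write_tsv_canonical(
    data.frame(gene_id = scores$gene_id, disease_id = scores$disease_id,
               score = as.character(scores$score),
               stringsAsFactors = FALSE),
    file.path(out_dir, "scores.tsv"))
  ft <- feature_table(ds, points)
  write_tsv_canonical(
    data.frame(drug_id = ft$drug_id, disease_id = ft$disease_id,
               f1 = as.character(ft$f1),
               f2 = formatC(ft$f2, digits = 10, format = "g"),
               f3 = as.character(ft$f3),
               f4 = formatC(ft$f4, digits = 10, format = "g"),
               stringsAsFactors = FALSE),
    file.path(out_dir, "features.tsv"))
  stage_msg("score+features", t0)

  t0 <- as.numeric(proc.time()["elapsed"])
  model <- tune_weights(ds, k = k, s = s, grid_step = grid_step,
                        nfold = nfold, seed = seed, points = points)
  write_model(model, file.path(out_dir, "model.json"))
  stage_msg("train", t0)

  t0 <- as.numeric(proc.time()["elapsed"])
  preds <- predict(model, ds, threshold = threshold)
  write_tsv_canonical(
    data.frame(drug_id = preds$drug_id, disease_id = preds$disease_id,
               score = formatC(preds$score, digits = 10, format = "g"),
               sd = formatC(preds$sd, digits = 10, format = "g"),
               call = as.character(preds$call),
               stringsAsFactors = FALSE),
    file.path(out_dir, "predictions.tsv"))
  stage_msg("predict", t0)

  t0 <- as.numeric(proc.time()["elapsed"])
  elig <- eligible_matrix(ds)
  labels <- indication_matrix(ds) * 1
  oof_comb <- combine_scores(model$oof, model$weights)
  flat <- evaluate_scores(oof_comb[elig], labels[elig], threshold)
  ml <- multilabel_metrics(ifelse(elig, oof_comb, 0), labels)
  evaluation <- c(stats::setNames(unlist(flat),
                                  paste0("cv_", names(flat))),
                  stats::setNames(unlist(ml), paste0("cv_", names(ml))),
                  cv_fitness_aupr = model$fitness)
  write_tsv_canonical(
    data.frame(metric = names(evaluation),
               value = formatC(evaluation, digits = 10, format = "g"),
               stringsAsFactors = FALSE),
    file.path(out_dir, "evaluation.tsv"))
  stage_msg("evaluate", t0)

  manifest <- c(
    package = "genodrug",
    version = as.character(utils::packageVersion("genodrug")),
    format = paste0(MODEL_FORMAT, "/", MODEL_FORMAT_VERSION),
    n_drugs = length(ds$drug_order), n_diseases = length(ds$diseases),
    n_genes = length(ds$genes),
    k = k, s = s, grid_step = grid_step, nfold = nfold,
    threshold = threshold, seed = seed,
    n_unscorable_indications = attr(pair_labels(ds), "n_unscorable"))
  writeLines(paste0(names(manifest), "=", manifest),
             file.path(out_dir, "manifest.txt"))

  invisible(list(dataset = ds, model = model, predictions = preds,
                 evaluation = evaluation, out_dir = out_dir))
}
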