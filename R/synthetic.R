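# Synthetic corpus generator with a planted logistic indication model.
#
# Gene-disease associations are drawn independently per source database;
# drug targets are sampled uniformly; eligible (drug, disease) pairs are
# indicated with probability
#   plogis(base_logit + effect_beta1 * f1/36 + effect_beta3 * f3),
# so the therapeutic signal rises monotonically with both the summed
# druggability score of targeted disease genes and their ohnolog
# coverage -- the two headline drivers the features are built on.

#' Simulation configuration
#'
#' Defaults describe a mid-sized corpus: 300 genes, 25 diseases, 200
#' drugs, per-database inclusion probabilities giving roughly 19
#' associated genes per disease, 30% of genes in ohnolog pairs, 2-12
#' targets per drug, a baseline indication rate of `plogis(-3)` (about
#' 4.7%, the scale of genetics-implicated clinically-active ratios in
#' real corpora) and positive planted effects.
#'
#' @param n_genes,n_diseases,n_drugs Corpus dimensions.
#' @param db_inclusion_probs Named 8-vector of per-database
#'   (gene, disease) association probabilities.
#' @param ohnolog_fraction Fraction of genes belonging to ohnolog pairs.
#' @param targets_min,targets_max Uniform bounds on targets per drug.
#' @param effect_beta1 Log-odds slope on the scaled first feature
#'   (f1/36).
#' @param effect_beta3 Log-odds slope on the third feature (ohnolog
#'   count).
#' @param base_logit Intercept of the planted logistic model.
#' @param approved_given_clinical Probability an indicated pair is
#'   APPROVED rather than CLINICAL.
#' @param indication_universe `"eligible"` (default) plants indications
#'   on eligible pairs only -- the universe the classifier scores;
#'   `"all"` draws them over every (drug, disease) pair, making
#'   indication status independent of the target structure (the null
#'   corpus used to calibrate the permutation test).
#' @param seed Integer seed; generation is fully reproducible.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300, n_diseases = 25, n_drugs = 200,
                       db_inclusion_probs = c(CLINVAR = 0.010,
                                              OMIM = 0.009,
                                              HGMD = 0.008,
                                              ORPHANET = 0.007,
                                              GWASDB = 0.007,
                                              INTREPID = 0.006,
                                              GAD = 0.006,
                                              DISGENET = 0.012),
                       ohnolog_fraction = 0.30,
                       targets_min = 2, targets_max = 12,
                       effect_beta1 = 2.0, effect_beta3 = 0.5,
                       base_logit = -3.0,
                       approved_given_clinical = 0.25,
                       indication_universe = c("eligible", "all"),
                       seed = 1) {
  indication_universe <- match.arg(indication_universe)
  cfg <- list(n_genes = n_genes, n_diseases = n_diseases,
              n_drugs = n_drugs,
              db_inclusion_probs = db_inclusion_probs,
              ohnolog_fraction = ohnolog_fraction,
              targets_min = targets_min, targets_max = targets_max,
              effect_beta1 = effect_beta1, effect_beta3 = effect_beta3,
              base_logit = base_logit,
              approved_given_clinical = approved_given_clinical,
              indication_universe = indication_universe,
              seed = as.integer(seed))
  stopifnot(n_genes >= 1, n_diseases >= 1, n_drugs >= 1,
            all(db_inclusion_probs >= 0), all(db_inclusion_probs <= 1),
            ohnolog_fraction >= 0, ohnolog_fraction <= 1,
            targets_min >= 1, targets_max >= targets_min,
            targets_max <= n_genes,
            approved_given_clinical >= 0, approved_given_clinical <= 1)
  if (is.null(names(cfg$db_inclusion_probs)) ||
      !setequal(names(cfg$db_inclusion_probs), db_sources())) {
    stop("validation error: db_inclusion_probs must be named by the ",
         "eight source databases", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic corpus with known ground truth
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a `genodrug_dataset`) and `truth`, a
#'   data.frame of the pairs in the indication universe with their
#'   planted probability `p_indicated` and the drawn `indicated` /
#'   `approved` outcomes.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  diseases <- sprintf("dis%03d", seq_len(config$n_diseases))
  drugs <- sprintf("drug%04d", seq_len(config$n_drugs))

  withr::with_seed(config$seed, {
    # associations: independent Bernoulli per database and cell
    assoc <- do.call(rbind, lapply(db_sources(), function(db) {
      hit <- which(matrix(stats::runif(config$n_genes *
                                         config$n_diseases),
                          config$n_genes) <
                     config$db_inclusion_probs[[db]],
                   arr.ind = TRUE)
      if (nrow(hit) == 0) return(NULL)
      data.frame(gene_id = genes[hit[, 1]],
                 disease_id = diseases[hit[, 2]],
                 source_db = db, stringsAsFactors = FALSE)
    }))
    if (is.null(assoc) || nrow(assoc) == 0) {
      stop("generation error: no gene-disease associations drawn",
           call. = FALSE)
    }

    # ohnolog pairs over a random subset of genes
    n_members <- 2 * floor(config$ohnolog_fraction * config$n_genes / 2)
    ohno <- if (n_members >= 2) {
      m <- sample(genes, n_members)
      data.frame(gene_a = m[seq(1, n_members, 2)],
                 gene_b = m[seq(2, n_members, 2)],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_a = character(), gene_b = character(),
                 stringsAsFactors = FALSE)
    }

    # drug target sets, uniform sizes without replacement
    sizes <- sample(config$targets_min:config$targets_max,
                    config$n_drugs, replace = TRUE)
    targets <- data.frame(
      drug_id = rep(drugs, sizes),
      gene_id = unlist(lapply(sizes, function(sz) sample(genes, sz))),
      stringsAsFactors = FALSE)

    ds0 <- new_dataset(assoc, targets,
                       data.frame(drug_id = character(),
                                  disease_id = character(),
                                  status = character(),
                                  stringsAsFactors = FALSE),
                       ohno)
    fm <- build_feature_matrices(ds0)
    elig <- eligible_matrix(ds0)
    if (sum(elig) == 0) {
      stop("generation error: configuration yields no eligible pairs",
           call. = FALSE)
    }
    universe <- if (config$indication_universe == "eligible") {
      elig
    } else {
      elig | TRUE
    }
    p <- stats::plogis(config$base_logit +
                         config$effect_beta1 * fm$f1 / 36 +
                         config$effect_beta3 * fm$f3)
    idx <- which(universe, arr.ind = TRUE)
    pv <- p[idx]
    indicated <- stats::runif(length(pv)) < pv
    approved <- indicated &
      stats::runif(length(pv)) < config$approved_given_clinical

    truth <- data.frame(
      drug_id = rownames(universe)[idx[, 1]],
      disease_id = colnames(universe)[idx[, 2]],
      p_indicated = pv, indicated = indicated, approved = approved,
      stringsAsFactors = FALSE)
    truth <- truth[order(truth$drug_id, truth$disease_id), ]
    rownames(truth) <- NULL

    ind <- truth[truth$indicated, c("drug_id", "disease_id")]
    ind$status <- ifelse(truth$approved[truth$indicated],
                         "APPROVED", "CLINICAL")
    ds <- new_dataset(assoc, targets, ind, ohno)
    list(dataset = ds, truth = truth)
  })
}

#' Minimal hand-written corpus
#'
#' A five-drug corpus whose first agent targets exactly two genes
#' associated with one disease, recorded in Clinvar and DisGeNET
#' respectively, so its first two features evaluate to 9 and 0.125.
#' Includes ohnolog pairs, an indication for a non-eligible pair (to
#' exercise the unscorable-positive path) and enough positives for a
#' five-fold internal split.
#'
#' @return A `genodrug_dataset`.
#' @export
fixture_minimal <- function() {
  assoc <- data.frame(
    gene_id    = c("g01", "g02", "g03", "g03", "g03", "g04", "g04",
                   "g05"),
    disease_id = c("dz1", "dz1", "dz2", "dz2", "dz1", "dz1", "dz2",
                   "dz2"),
    source_db  = c("CLINVAR", "DISGENET", "OMIM", "HGMD", "GAD",
                   "GWASDB", "ORPHANET", "INTREPID"),
    stringsAsFactors = FALSE)
  targets <- data.frame(
    drug_id = c("agentA", "agentA", "agentB", "agentC", "agentC",
                "agentC", "agentD", "agentD", "agentE"),
    gene_id = c("g01", "g02", "g03", "g01", "g03", "g04", "g05", "g06",
                "g07"),
    stringsAsFactors = FALSE)
  indications <- data.frame(
    drug_id    = c("agentA", "agentB", "agentC", "agentE"),
    disease_id = c("dz1", "dz2", "dz1", "dz1"),
    status     = c("CLINICAL", "APPROVED", "APPROVED", "CLINICAL"),
    stringsAsFactors = FALSE)
  ohno <- data.frame(gene_a = c("g01", "g03"),
                     gene_b = c("g04", "g05"),
                     stringsAsFactors = FALSE)
  new_dataset(assoc, targets, indications, ohno)
}
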