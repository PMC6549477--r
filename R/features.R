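# The four disease-indexed drug features.  For a drug i and disease l,
# with G(i,l) the set of targeted genes genetically associated with l:
#   f1 = sum of druggability scores over G(i,l)
#   f2 = f1 / (|G(i,l)| * 36), the normalized average score
#   f3 = number of genes in G(i,l) that are ohnolog members
#   f4 = f3 / |G(i,l)|
# All four are 0 when the drug targets no gene of the disease.

#' Feature 1: summed druggability score of targeted disease genes
#'
#' For the worked reference case -- an agent targeting two genes
#' associated with one disease, recorded in Clinvar (8 points) and
#' DisGeNET (1 point) respectively -- the value is 9.
#'
#' @param ds A `genodrug_dataset`.
#' @param scores Output of [score_all()] (or `NULL` to compute with the
#'   default point table).
#' @param drug_id,disease_id Pair to evaluate; unknown drug is a lookup
#'   error.
#' @return Non-negative integer.
#' @export
f1_score_sum <- function(ds, scores = NULL, drug_id, disease_id) {
  targets <- lookup_targets(ds, drug_id)
  if (is.null(scores)) scores <- score_all(ds)
  hit <- scores$disease_id == disease_id & scores$gene_id %in% targets
  as.integer(sum(scores$score[hit]))
}

lookup_targets <- function(ds, drug_id) {
  targets <- ds$drugs[[drug_id]]
  if (is.null(targets)) {
    stop("lookup error: unknown drug ", drug_id, call. = FALSE)
  }
  targets
}

#' Feature 2: normalized average druggability score
#'
#' `f1 / (n * 36)` where `n` is the number of targeted disease genes and
#' 36 is the maximum attainable single-gene score under the default
#' point table.  Returns 0 when `n = 0`.  The reference case (f1 = 9
#' over two disease genes) gives 9 / (2 x 36) = 0.125.
#'
#' @param f1 Feature-1 value.
#' @param n_disease_genes_targeted Number of targeted genes associated
#'   with the disease.
#' @param max_score Normalization constant (default 36).
#' @return Value in \[0, 1\].
#' @export
f2_norm_avg <- function(f1, n_disease_genes_targeted, max_score = 36) {
  stopifnot(n_disease_genes_targeted >= 0)
  if (n_disease_genes_targeted == 0) return(0)
  f1 / (n_disease_genes_targeted * max_score)
}

#' Features 3 and 4: ohnolog coverage of targeted disease genes
#'
#' @inheritParams f1_score_sum
#' @return Named numeric vector `c(count = f3, ratio = f4)`; the ratio
#'   denominator is the number of targeted disease genes (0/0 gives 0).
#' @export
f3_f4_ohnolog <- function(ds, drug_id, disease_id) {
  targets <- lookup_targets(ds, drug_id)
  am <- assoc_matrix(ds)
  dz_genes <- rownames(am)[am[, disease_id]]
  tg <- intersect(targets, dz_genes)
  f3 <- length(intersect(tg, ds$ohnologs$members))
  c(count = f3, ratio = if (length(tg) == 0) 0 else f3 / length(tg))
}

#' Build all four drug-by-disease feature matrices
#'
#' @param ds A `genodrug_dataset`.
#' @param points Database point table.
#' @param max_score Normalization constant for f2 (default 36).
#' @return Named list of four numeric matrices (`f1`, `f2`, `f3`, `f4`),
#'   each `n` drugs x `q` diseases, rows in `ds$drug_order` and columns
#'   in `ds$diseases`.
#' @export
build_feature_matrices <- function(ds, points = default_point_table(),
                                   max_score = 36) {
  tm <- target_matrix(ds)              # drugs x genes
  am <- assoc_matrix(ds)               # genes x diseases
  sm <- score_matrix(ds, points)       # genes x diseases
  ohno <- as.numeric(rownames(am) %in% ds$ohnologs$members)

  f1 <- tm %*% sm
  cnt <- tm %*% am                     # targeted disease genes per cell
  f3 <- tm %*% (am * ohno)
  f2 <- ifelse(cnt > 0, f1 / (cnt * max_score), 0)
  f4 <- ifelse(cnt > 0, f3 / cnt, 0)
  dn <- list(ds$drug_order, ds$diseases)
  lapply(list(f1 = f1, f2 = f2, f3 = f3, f4 = f4),
         function(m) { dimnames(m) <- dn; m })
}

#' Export features as a long-format table
#'
#' One row per (drug, disease) pair with a non-zero eligible link (f1
#' >= 1); all-zero cells are omitted.
#'
#' @inheritParams build_feature_matrices
#' @return data.frame with columns `drug_id`, `disease_id`,
#'   `f1`, `f2`, `f3`, `f4`.
#' @export
feature_table <- function(ds, points = default_point_table()) {
  fm <- build_feature_matrices(ds, points)
  idx <- which(fm$f1 > 0, arr.ind = TRUE)
  out <- data.frame(drug_id = rownames(fm$f1)[idx[, 1]],
                    disease_id = colnames(fm$f1)[idx[, 2]],
                    f1 = fm$f1[idx], f2 = fm$f2[idx],
                    f3 = fm$f3[idx], f4 = fm$f4[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$drug_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
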