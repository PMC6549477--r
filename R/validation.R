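# Corpus-validation statistics: set similarity (Tanimoto), concept
# similarity (Lin), GO-term functional distance (Czekanowski-Dice), the
# degree-preserving permutation test for drug-target associations,
# stratified clinically-active-ratio curves and disease gene-profile
# rank correlation.

#' Tanimoto coefficient from set sizes
#'
#' `n_ab / (n_a + n_b - n_ab)` for two sets of sizes `n_a`, `n_b` with
#' `n_ab` shared members.
#'
#' @param n_a,n_b,n_ab Set and intersection sizes.
#' @return Coefficient in \[0, 1\].
#' @export
tanimoto <- function(n_a, n_b, n_ab) {
  if (n_ab > min(n_a, n_b) || n_a + n_b - n_ab <= 0 ||
      any(c(n_a, n_b, n_ab) < 0)) {
    stop("validation error: inconsistent set sizes", call. = FALSE)
  }
  n_ab / (n_a + n_b - n_ab)
}

# ---- ontology / Lin similarity --------------------------------------

#' Build an ontology for Lin similarity
#'
#' @param df data.frame with columns `concept_id`, `parent_ids`
#'   (comma-joined, empty for roots) and `probability` (occurrence
#'   probability in (0, 1\], non-decreasing from child to ancestor).
#' @return Object of class `genodrug_ontology` with the parent map,
#'   probabilities and a memoized ancestor closure.
#' @export
as_ontology <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("concept_id", "parent_ids", "probability")) {
    if (is.null(df[[col]])) {
      stop("format error: ontology missing column ", col, call. = FALSE)
    }
  }
  ids <- df$concept_id
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate concept_id", call. = FALSE)
  }
  prob <- stats::setNames(as.numeric(df$probability), ids)
  if (any(is.na(prob)) || any(prob <= 0) || any(prob > 1)) {
    stop("validation error: probabilities must lie in (0, 1]",
         call. = FALSE)
  }
  parents <- stats::setNames(lapply(df$parent_ids, function(p) {
    p <- trimws(strsplit(p, ",", fixed = TRUE)[[1]])
    p[nzchar(p)]
  }), ids)
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown) > 0) {
    stop("validation error: unknown parent concept(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # ancestor closure (self included); also detects cycles
  anc <- stats::setNames(vector("list", length(ids)), ids)
  get_anc <- function(id, path = character()) {
    if (id %in% path) {
      stop("validation error: ontology contains a cycle at ", id,
           call. = FALSE)
    }
    if (!is.null(anc[[id]])) return(anc[[id]])
    a <- id
    for (p in parents[[id]]) {
      a <- union(a, get_anc(p, c(path, id)))
    }
    anc[[id]] <<- a
    a
  }
  for (id in ids) get_anc(id)
  for (id in ids) {
    if (any(prob[parents[[id]]] < prob[[id]] - 1e-12)) {
      stop("validation error: parent probability below child at ", id,
           call. = FALSE)
    }
  }
  structure(list(parents = parents, probability = prob, ancestors = anc),
            class = "genodrug_ontology")
}

#' Load an ontology TSV
#'
#' @param path TSV with columns `concept_id`, `parent_ids`,
#'   `probability`.
#' @return A `genodrug_ontology`.
#' @export
load_ontology <- function(path) {
  as_ontology(read_tsv_table(path,
                             c("concept_id", "parent_ids", "probability")))
}

#' Lin concept similarity
#'
#' Information-content similarity `IC(lcs) / (IC(c1) + IC(c2))` with
#' `IC = -log(probability)` and the least common subsumer chosen as the
#' shared ancestor (self included) with maximal IC.  By default the
#' formula is applied exactly as stated, so `Lin(c, c) = 0.5`; set
#' `canonical = TRUE` for the classical `2 * IC(lcs)` numerator, under
#' which self-similarity is 1.
#'
#' @param c1,c2 Concept ids.
#' @param ontology A `genodrug_ontology`.
#' @param canonical Use the factor-2 numerator (default `FALSE`).
#' @return Similarity, or `NA` if the concepts share no ancestor or
#'   both have zero information content.
#' @export
lin_similarity <- function(c1, c2, ontology, canonical = FALSE) {
  stopifnot(inherits(ontology, "genodrug_ontology"))
  for (cc in c(c1, c2)) {
    if (is.null(ontology$ancestors[[cc]])) {
      stop("lookup error: unknown concept ", cc, call. = FALSE)
    }
  }
  common <- intersect(ontology$ancestors[[c1]], ontology$ancestors[[c2]])
  if (length(common) == 0) return(NA_real_)
  ic <- -log(ontology$probability)
  ic_lcs <- max(ic[common])
  den <- ic[[c1]] + ic[[c2]]
  if (den == 0) return(NA_real_)
  (if (canonical) 2 else 1) * ic_lcs / den
}

#' Czekanowski-Dice distance between GO-term sets
#'
#' `|A xor B| / (|A u B| + |A n B|)`: 0 for identical non-empty sets,
#' 1 for disjoint sets.
#'
#' @param go_a,go_b Character vectors of term ids.
#' @return Distance in \[0, 1\], or `NA` when both sets are empty.
#' @export
czekanowski_dice <- function(go_a, go_b) {
  a <- unique(go_a); b <- unique(go_b)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  u <- union(a, b); i <- intersect(a, b)
  (length(u) - length(i)) / (length(u) + length(i))
}

# ---- clinically active ratios ---------------------------------------

#' Clinically-active and approved ratios of a pair subset
#'
#' Fractions of the given eligible pairs whose drug-disease activity is
#' clinically supported (CLINICAL or APPROVED) and approved,
#' respectively.
#'
#' @param ds A `genodrug_dataset`.
#' @param pair_subset data.frame with columns `drug_id`, `disease_id`;
#'   must be a subset of [eligible_pairs()].
#' @return Named numeric vector `c(clinical = , approved = )`; `NA`s for
#'   an empty subset.
#' @export
clinically_active_ratio <- function(ds, pair_subset) {
  if (nrow(pair_subset) == 0) {
    return(c(clinical = NA_real_, approved = NA_real_))
  }
  ep <- pair_labels(ds)
  key <- paste(pair_subset$drug_id, pair_subset$disease_id, sep = "\r")
  ekey <- paste(ep$drug_id, ep$disease_id, sep = "\r")
  hit <- match(key, ekey)
  if (any(is.na(hit))) {
    stop("validation error: pair_subset contains non-eligible pairs",
         call. = FALSE)
  }
  status <- ep$status[hit]
  c(clinical = mean(status != "NONE"),
    approved = mean(status == "APPROVED"))
}

#' Permutation test for drug-target association quality
#'
#' Shuffles the gene column of the drug-target table (preserving each
#' drug's number of target slots and the global target multiset),
#' recomputes the clinically-active ratio over the permuted eligible
#' pairs, and reports the empirical p-value
#' `(1 + #\{null >= observed\}) / (1 + n_perm)` -- never zero, so with
#' 10,000 permutations the smallest attainable p is 1/10001.
#'
#' @param ds A `genodrug_dataset`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; the same seed reproduces the identical
#'   null distribution.
#' @return List with `observed`, `null` (length `n_perm`) and `p`.
#' @export
permutation_test <- function(ds, n_perm = 10000, seed = 1) {
  stopifnot(n_perm >= 1)
  am <- assoc_matrix(ds) * 1            # genes x diseases
  im <- indication_matrix(ds)           # drugs x diseases
  gvec <- unlist(ds$drugs, use.names = FALSE)
  dvec <- rep(seq_along(ds$drugs), lengths(ds$drugs))
  gidx <- match(gvec, ds$genes)

  ratio_for <- function(gene_idx) {
    cover <- rowsum(am[gene_idx, , drop = FALSE], dvec)
    elig <- cover > 0                  # covered drugs x diseases
    drows <- sort(unique(dvec))
    ne <- sum(elig)
    if (ne == 0) return(0)
    sum(im[drows, , drop = FALSE] & elig) / ne
  }

  observed <- ratio_for(gidx)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) ratio_for(sample(gidx)),
           numeric(1))
  })
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}

# ---- stratified ratio curves ----------------------------------------

#' Clinically-active-ratio curve across evidence strata
#'
#' Bins every eligible pair by a genetics-derived stratifier --
#' `TARGET_COUNT` (number of targeted disease genes),
#' `DRUGGABILITY_SCORE_BIN` (summed druggability score, feature f1) or
#' `OHNOLOG_COVERAGE` / `TOPGENE_COVERAGE` (number of targeted
#' ohnologous disease genes, feature f3) -- and reports per-bin pair
#' counts, clinically-active and approved ratios, plus a monotone-trend
#' statistic (Spearman correlation of bin index with the clinical
#' ratio over non-empty bins).
#'
#' @param ds A `genodrug_dataset`.
#' @param stratifier One of `"TARGET_COUNT"`, `"DRUGGABILITY_SCORE_BIN"`,
#'   `"OHNOLOG_COVERAGE"`, `"TOPGENE_COVERAGE"`.
#' @param bins Numeric break vector covering the stratifier range
#'   (passed to [cut()]); `NULL` picks quartile-based breaks so bins
#'   carry comparable pair mass (the top bin pools the sparse tail,
#'   whose zero-inflated ratios would otherwise bias the trend).
#' @param points Database point table (used for the score stratifier).
#' @return List with `curve` (data.frame `stratum`, `n_pairs`,
#'   `clinically_active_ratio`, `approved_ratio`; empty bins keep
#'   `n_pairs = 0` and `NA` ratios) and `trend` (Spearman statistic).
#' @export
stratified_ratio_curve <- function(ds,
                                   stratifier = c("TARGET_COUNT",
                                                  "DRUGGABILITY_SCORE_BIN",
                                                  "OHNOLOG_COVERAGE",
                                                  "TOPGENE_COVERAGE"),
                                   bins = NULL,
                                   points = default_point_table()) {
  stratifier <- match.arg(stratifier)
  ep <- pair_labels(ds)
  fm <- build_feature_matrices(ds, points)
  idx <- cbind(match(ep$drug_id, ds$drug_order),
               match(ep$disease_id, ds$diseases))
  value <- switch(stratifier,
    TARGET_COUNT = (target_matrix(ds) %*% assoc_matrix(ds))[idx],
    DRUGGABILITY_SCORE_BIN = fm$f1[idx],
    OHNOLOG_COVERAGE = fm$f3[idx],
    TOPGENE_COVERAGE = fm$f3[idx])

  if (is.null(bins)) {
    br <- unique(stats::quantile(value, c(0.25, 0.5, 0.75), type = 1))
    bins <- unique(c(min(value) - 0.5, br + 0.5, max(value) + 0.5))
  }
  if (min(value) < min(bins) || max(value) > max(bins)) {
    stop("validation error: bins do not cover the stratifier range",
         call. = FALSE)
  }
  stratum <- cut(value, bins, include.lowest = TRUE)
  lev <- levels(stratum)
  curve <- do.call(rbind, lapply(seq_along(lev), function(b) {
    in_bin <- which(as.integer(stratum) == b)
    if (length(in_bin) == 0) {
      return(data.frame(stratum = lev[b], n_pairs = 0L,
                        clinically_active_ratio = NA_real_,
                        approved_ratio = NA_real_,
                        stringsAsFactors = FALSE))
    }
    st <- ep$status[in_bin]
    data.frame(stratum = lev[b], n_pairs = length(in_bin),
               clinically_active_ratio = mean(st != "NONE"),
               approved_ratio = mean(st == "APPROVED"),
               stringsAsFactors = FALSE)
  }))
  nonempty <- curve$n_pairs > 0
  trend <- if (sum(nonempty) >= 2) {
    suppressWarnings(stats::cor(which(nonempty),
                                curve$clinically_active_ratio[nonempty],
                                method = "spearman"))
  } else {
    NA_real_
  }
  list(curve = curve, trend = trend)
}

#' Spearman correlation of two disease gene profiles
#'
#' Correlates the druggability-score vectors of two diseases over the
#' union of their scored genes (genes absent from one profile score 0).
#'
#' @param scores Output of [score_all()].
#' @param disease_a,disease_b Disease ids.
#' @return Spearman rho in \[-1, 1\]; `NA` when the union holds fewer
#'   than 3 genes or either profile is constant.
#' @export
disease_profile_correlation <- function(scores, disease_a, disease_b) {
  pa <- scores[scores$disease_id == disease_a, ]
  pb <- scores[scores$disease_id == disease_b, ]
  genes <- union(pa$gene_id, pb$gene_id)
  if (length(genes) < 3) return(NA_real_)
  va <- stats::setNames(rep(0, length(genes)), genes)
  vb <- va
  va[pa$gene_id] <- pa$score
  vb[pb$gene_id] <- pb$score
  suppressWarnings(stats::cor(va, vb, method = "spearman"))
}
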