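# Database quality points and the per-(gene, disease) druggability score:
# the sum of quality points over the distinct source databases recording
# the association.

#' Default database point table
#'
#' Quality points for the eight source databases, ranked by their
#' empirical clinically-active ratios: Clinvar gets the highest score
#' (eight points) down to DisGeNET with one point.  A gene recorded in
#' all eight databases for one disease reaches the maximum single-gene
#' score of 36 (= 8 + 7 + ... + 1), the constant used to normalize the
#' second drug feature.
#'
#' @return Named integer vector mapping source database to points.
#' @export
default_point_table <- function() {
  c(CLINVAR = 8L, OMIM = 7L, HGMD = 6L, ORPHANET = 5L,
    GWASDB = 4L, INTREPID = 3L, GAD = 2L, DISGENET = 1L)
}

validate_point_table <- function(points) {
  if (is.null(names(points)) || any(!nzchar(names(points)))) {
    stop("point table must be a named vector", call. = FALSE)
  }
  names(points) <- toupper(names(points))
  unknown <- setdiff(names(points), db_sources())
  if (length(unknown) > 0) {
    stop("unknown source_db in point table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(points)) || any(points < 1) ||
      any(points != round(points))) {
    stop("point table values must be unique-keyed positive integers",
         call. = FALSE)
  }
  stats::setNames(as.integer(points), names(points))
}

#' Load a database point table override
#'
#' @param path TSV file with columns `source_db`, `points`.
#' @return Named integer vector usable wherever a point table is taken.
#' @export
load_point_table <- function(path) {
  df <- read_tsv_table(path, c("source_db", "points"))
  validate_point_table(stats::setNames(as.numeric(df$points),
                                       toupper(df$source_db)))
}

# genes x diseases numeric score matrix (0 where no association)
score_matrix <- function(ds, points = default_point_table()) {
  points <- validate_point_table(points)
  uncovered <- setdiff(unique(ds$associations$source_db), names(points))
  if (length(uncovered) > 0) {
    stop("point table does not cover source database(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, length(ds$genes), length(ds$diseases),
              dimnames = list(ds$genes, ds$diseases))
  a <- ds$associations  # triples already unique
  if (nrow(a) > 0) {
    idx <- cbind(match(a$gene_id, ds$genes),
                 match(a$disease_id, ds$diseases))
    for (i in seq_len(nrow(a))) {
      m[idx[i, 1], idx[i, 2]] <- m[idx[i, 1], idx[i, 2]] +
        points[[a$source_db[i]]]
    }
  }
  m
}

#' Druggability scores for every recorded (gene, disease) pair
#'
#' For each distinct (gene, disease) pair in the corpus, sums the quality
#' points of the distinct source databases recording it.  Each database
#' counts at most once per pair, so duplicates and row order in the input
#' never change a score.
#'
#' @param ds A `genodrug_dataset`.
#' @param points Point table (named integer vector); defaults to
#'   [default_point_table()].
#' @return data.frame with columns `gene_id`, `disease_id`, `score`,
#'   one row per recorded pair, sorted.
#' @export
score_all <- function(ds, points = default_point_table()) {
  m <- score_matrix(ds, points)
  idx <- which(m > 0, arr.ind = TRUE)
  out <- data.frame(gene_id = rownames(m)[idx[, 1]],
                    disease_id = colnames(m)[idx[, 2]],
                    score = as.integer(m[idx]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Druggability score of one (gene, disease) pair
#'
#' @inheritParams score_all
#' @param gene_id,disease_id Pair to score; must have at least one
#'   recorded association (a score of 0 is never produced -- an absent
#'   pair is a lookup error).
#' @return Integer score >= 1.
#' @export
score_gene_disease <- function(ds, gene_id, disease_id,
                               points = default_point_table()) {
  a <- ds$associations
  hit <- a$gene_id == gene_id & a$disease_id == disease_id
  if (!any(hit)) {
    stop("lookup error: no association recorded for (", gene_id, ", ",
         disease_id, ")", call. = FALSE)
  }
  points <- validate_point_table(points)
  dbs <- unique(a$source_db[hit])
  uncovered <- setdiff(dbs, names(points))
  if (length(uncovered) > 0) {
    stop("point table does not cover source database(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  sum(points[dbs])
}
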