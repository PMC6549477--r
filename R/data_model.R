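# Domain types and readers/writers for the tabular corpus:
# gene-disease associations (with source database), drug target sets,
# drug-indication records, and ohnolog gene pairs.

#' Recognized disease-gene source databases
#'
#' The eight source databases a gene-disease association may carry, in
#' decreasing order of default quality points (see
#' [default_point_table()]).
#'
#' @return Character vector of the eight database codes.
#' @export
db_sources <- function() {
  c("CLINVAR", "OMIM", "HGMD", "ORPHANET",
    "GWASDB", "INTREPID", "GAD", "DISGENET")
}

read_tsv_table <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[required_cols]
}

#' Assemble and validate a corpus
#'
#' Builds a `genodrug_dataset` from in-memory tables, enforcing all
#' invariants: valid source databases, unique association triples
#' (duplicates dropped with a message), non-empty drug target sets,
#' indication statuses in \{CLINICAL, APPROVED\} (an APPROVED record for a
#' pair supersedes a CLINICAL one), and symmetric deduplicated ohnolog
#' pairs.  Drug and disease orderings are lexicographic so every derived
#' matrix is reproducible.
#'
#' @param associations data.frame with columns `gene_id`, `disease_id`,
#'   `source_db`.
#' @param drug_targets data.frame with columns `drug_id`, `gene_id`.
#' @param indications data.frame with columns `drug_id`, `disease_id`,
#'   `status` (may have zero rows).
#' @param ohnologs data.frame with columns `gene_a`, `gene_b` (may have
#'   zero rows).
#' @return An object of class `genodrug_dataset`: a list with elements
#'   `associations`, `drugs` (named list of target-gene vectors),
#'   `indications`, `ohnologs` (list with `pairs` and `members`),
#'   `diseases`, `drug_order`, `genes`.
#' @export
new_dataset <- function(associations, drug_targets, indications, ohnologs) {
  associations <- as.data.frame(associations, stringsAsFactors = FALSE)
  drug_targets <- as.data.frame(drug_targets, stringsAsFactors = FALSE)
  indications  <- as.data.frame(indications,  stringsAsFactors = FALSE)
  ohnologs     <- as.data.frame(ohnologs,     stringsAsFactors = FALSE)

  # -- associations ----------------------------------------------------
  for (col in c("gene_id", "disease_id", "source_db")) {
    if (is.null(associations[[col]])) {
      stop("format error: associations missing column ", col, call. = FALSE)
    }
  }
  associations$source_db <- toupper(associations$source_db)
  bad <- !(associations$source_db %in% db_sources())
  if (any(bad)) {
    lines <- utils::head(which(bad), 5L)
    stop("validation error: unknown source_db token(s) ",
         paste(unique(associations$source_db[bad]), collapse = ", "),
         " at association row(s) ", paste(lines, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(associations$gene_id)) ||
      any(!nzchar(associations$disease_id))) {
    stop("validation error: empty gene_id or disease_id in associations",
         call. = FALSE)
  }
  n0 <- nrow(associations)
  associations <- unique(associations)
  ndup <- n0 - nrow(associations)
  if (ndup > 0) {
    message("deduplicated ", ndup, " association row(s)")
  }

  # -- drug targets ----------------------------------------------------
  for (col in c("drug_id", "gene_id")) {
    if (is.null(drug_targets[[col]])) {
      stop("format error: drug_targets missing column ", col, call. = FALSE)
    }
  }
  if (nrow(drug_targets) == 0) {
    stop("validation error: no drug-target records", call. = FALSE)
  }
  empty <- is.na(drug_targets$gene_id) | !nzchar(drug_targets$gene_id)
  if (any(empty)) {
    stop("validation error: empty target gene for drug(s) ",
         paste(unique(drug_targets$drug_id[empty]), collapse = ", "),
         call. = FALSE)
  }
  drug_targets <- unique(drug_targets)
  drugs <- lapply(split(drug_targets$gene_id, drug_targets$drug_id),
                  function(g) sort(unique(g)))
  drug_order <- sort(names(drugs))
  drugs <- drugs[drug_order]

  # -- indications -----------------------------------------------------
  for (col in c("drug_id", "disease_id", "status")) {
    if (is.null(indications[[col]])) {
      stop("format error: indications missing column ", col, call. = FALSE)
    }
  }
  if (nrow(indications) > 0) {
    indications$status <- toupper(indications$status)
    badst <- !(indications$status %in% c("CLINICAL", "APPROVED"))
    if (any(badst)) {
      stop("validation error: unknown indication status ",
           paste(unique(indications$status[badst]), collapse = ", "),
           call. = FALSE)
    }
    # APPROVED supersedes CLINICAL for the same pair
    key <- paste(indications$drug_id, indications$disease_id, sep = "\r")
    rank <- ifelse(indications$status == "APPROVED", 2L, 1L)
    keep <- tapply(seq_len(nrow(indications)), key,
                   function(i) i[which.max(rank[i])])
    indications <- indications[sort(unlist(keep, use.names = FALSE)), ,
                               drop = FALSE]
  }

  # -- ohnologs --------------------------------------------------------
  for (col in c("gene_a", "gene_b")) {
    if (is.null(ohnologs[[col]])) {
      stop("format error: ohnologs missing column ", col, call. = FALSE)
    }
  }
  if (nrow(ohnologs) > 0) {
    if (any(ohnologs$gene_a == ohnologs$gene_b)) {
      stop("validation error: ohnolog pair with identical genes",
           call. = FALSE)
    }
    a <- pmin(ohnologs$gene_a, ohnologs$gene_b)
    b <- pmax(ohnologs$gene_a, ohnologs$gene_b)
    pairs <- unique(data.frame(gene_a = a, gene_b = b,
                               stringsAsFactors = FALSE))
  } else {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  }
  members <- sort(unique(c(pairs$gene_a, pairs$gene_b)))

  diseases <- sort(unique(c(associations$disease_id,
                            indications$disease_id)))
  genes <- sort(unique(c(associations$gene_id, drug_targets$gene_id,
                         members)))

  associations <- associations[order(associations$gene_id,
                                     associations$disease_id,
                                     associations$source_db), ,
                               drop = FALSE]
  rownames(associations) <- NULL
  if (nrow(indications) > 0) {
    indications <- indications[order(indications$drug_id,
                                     indications$disease_id), ,
                               drop = FALSE]
  }
  rownames(indications) <- NULL
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL

  structure(
    list(associations = associations,
         drugs        = drugs,
         indications  = indications,
         ohnologs     = list(pairs = pairs, members = members),
         diseases     = diseases,
         drug_order   = drug_order,
         genes        = genes),
    class = "genodrug_dataset")
}

#' Load a corpus from four tab-separated files
#'
#' Reads `associations.tsv` (`gene_id`, `disease_id`, `source_db`),
#' `drug_targets.tsv` (`drug_id`, `gene_id`), `indications.tsv`
#' (`drug_id`, `disease_id`, `status`) and `ohnologs.tsv`
#' (`gene_a`, `gene_b`), then validates via [new_dataset()].
#'
#' @param assoc_path,drugs_path,indications_path,ohnolog_path File paths.
#' @return A `genodrug_dataset`.
#' @export
load_dataset <- function(assoc_path, drugs_path, indications_path,
                         ohnolog_path) {
  new_dataset(
    associations = read_tsv_table(assoc_path,
                                  c("gene_id", "disease_id", "source_db")),
    drug_targets = read_tsv_table(drugs_path, c("drug_id", "gene_id")),
    indications  = read_tsv_table(indications_path,
                                  c("drug_id", "disease_id", "status")),
    ohnologs     = read_tsv_table(ohnolog_path, c("gene_a", "gene_b")))
}

write_tsv_canonical <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0)
               do.call(paste, c(unname(as.list(df)), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a corpus back to canonical TSV files
#'
#' Emits the four tables with sorted rows, fixed column order and `\n`
#' line endings, so that write -> load -> write is byte-identical.
#'
#' @param ds A `genodrug_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "genodrug_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tg <- data.frame(
    drug_id = rep(names(ds$drugs), lengths(ds$drugs)),
    gene_id = unlist(ds$drugs, use.names = FALSE),
    stringsAsFactors = FALSE)
  paths <- c(
    associations = write_tsv_canonical(ds$associations,
                                       file.path(dir, "associations.tsv")),
    drug_targets = write_tsv_canonical(tg,
                                       file.path(dir, "drug_targets.tsv")),
    indications  = write_tsv_canonical(ds$indications,
                                       file.path(dir, "indications.tsv")),
    ohnologs     = write_tsv_canonical(ds$ohnologs$pairs,
                                       file.path(dir, "ohnologs.tsv")))
  invisible(paths)
}

#' @export
print.genodrug_dataset <- function(x, ...) {
  cat("genodrug corpus:",
      length(x$drug_order), "drugs,",
      length(x$diseases), "diseases,",
      length(x$genes), "genes\n")
  cat("  associations:", nrow(x$associations),
      " indications:", nrow(x$indications),
      " ohnolog pairs:", nrow(x$ohnologs$pairs), "\n")
  invisible(x)
}

# ---- internal matrix views ------------------------------------------

# genes x diseases logical: any source database records the pair
assoc_matrix <- function(ds) {
  m <- matrix(FALSE, length(ds$genes), length(ds$diseases),
              dimnames = list(ds$genes, ds$diseases))
  a <- unique(ds$associations[c("gene_id", "disease_id")])
  m[cbind(a$gene_id, a$disease_id)] <- TRUE
  m
}

# drugs x genes 0/1 target incidence
target_matrix <- function(ds) {
  m <- matrix(0, length(ds$drug_order), length(ds$genes),
              dimnames = list(ds$drug_order, ds$genes))
  m[cbind(rep(names(ds$drugs), lengths(ds$drugs)),
          unlist(ds$drugs, use.names = FALSE))] <- 1
  m
}

# drugs x diseases logical indication matrix; clinical includes approved
indication_matrix <- function(ds, approved_only = FALSE) {
  m <- matrix(FALSE, length(ds$drug_order), length(ds$diseases),
              dimnames = list(ds$drug_order, ds$diseases))
  ind <- ds$indications
  if (approved_only) ind <- ind[ind$status == "APPROVED", , drop = FALSE]
  ind <- ind[ind$drug_id %in% ds$drug_order, , drop = FALSE]
  if (nrow(ind) > 0) m[cbind(ind$drug_id, ind$disease_id)] <- TRUE
  m
}

# drugs x diseases logical: drug targets >=1 gene associated with disease
eligible_matrix <- function(ds) {
  (target_matrix(ds) %*% assoc_matrix(ds)) > 0
}

#' Eligible (drug, disease) pairs
#'
#' A pair is eligible when the drug targets at least one gene genetically
#' associated with the disease (via any source database).  Eligible pairs
#' are the universe of positives and negatives: positives are eligible
#' pairs carrying an indication, negatives the rest.
#'
#' @param ds A `genodrug_dataset`.
#' @return data.frame with columns `drug_id`, `disease_id`, sorted.
#' @export
eligible_pairs <- function(ds) {
  stopifnot(inherits(ds, "genodrug_dataset"))
  e <- eligible_matrix(ds)
  idx <- which(e, arr.ind = TRUE)
  out <- data.frame(drug_id = rownames(e)[idx[, 1]],
                    disease_id = colnames(e)[idx[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$drug_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Eligible pairs with training labels
#'
#' Annotates each eligible pair with its indication status and binary
#' label (1 for CLINICAL or APPROVED).  Indications for non-eligible
#' pairs (the drug treats the disease but targets none of its genes) are
#' retained in the corpus but excluded here; their count is attached as
#' attribute `n_unscorable`.
#'
#' @param ds A `genodrug_dataset`.
#' @return data.frame with columns `drug_id`, `disease_id`, `status`
#'   (`NONE`, `CLINICAL` or `APPROVED`) and `label` (0/1); attribute
#'   `n_unscorable` counts indications outside the eligible set.
#' @export
pair_labels <- function(ds) {
  ep <- eligible_pairs(ds)
  key <- paste(ep$drug_id, ep$disease_id, sep = "\r")
  ikey <- paste(ds$indications$drug_id, ds$indications$disease_id,
                sep = "\r")
  status <- rep("NONE", nrow(ep))
  hit <- match(key, ikey)
  status[!is.na(hit)] <- ds$indications$status[hit[!is.na(hit)]]
  ep$status <- status
  ep$label <- as.integer(status != "NONE")
  attr(ep, "n_unscorable") <- sum(!(ikey %in% key))
  ep
}
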