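test_that("Tanimoto coefficient follows the set-size formula", {
  expect_equal(tanimoto(5, 5, 5), 1)
  expect_equal(tanimoto(3, 4, 0), 0)
  expect_equal(tanimoto(3, 4, 2), 0.4)
  expect_error(tanimoto(2, 2, 3), "validation error")
  expect_error(tanimoto(0, 0, 0), "validation error")
  # symmetry, and 1 iff identical
  for (case in list(c(4, 7, 2), c(5, 5, 4))) {
    expect_equal(tanimoto(case[1], case[2], case[3]),
                 tanimoto(case[2], case[1], case[3]))
    expect_lt(tanimoto(case[1], case[2], case[3]), 1)
  }
})

toy_ontology <- function() {
  as_ontology(data.frame(
    concept_id = c("root", "a", "b", "c", "d"),
    parent_ids = c("", "root", "root", "a", "a,b"),
    probability = c(1, 0.4, 0.5, 0.1, 0.2),
    stringsAsFactors = FALSE))
}

test_that("Lin similarity uses the max-IC common subsumer", {
  ont <- toy_ontology()
  # as printed: self-similarity is 1/2
  expect_equal(lin_similarity("c", "c", ont), 0.5)
  # canonical option restores self-similarity 1
  expect_equal(lin_similarity("c", "c", ont, canonical = TRUE), 1)
  # lcs at the root has zero information content
  expect_equal(lin_similarity("a", "b", ont), 0)
  # brute-force ancestor enumeration on the toy DAG
  for (pair in list(c("c", "d"), c("a", "d"), c("b", "d"))) {
    anc <- function(id) {
      out <- id
      repeat {
        parents <- unlist(ont$parents[out])
        new <- setdiff(parents, out)
        if (length(new) == 0) break
        out <- c(out, new)
      }
      out
    }
    common <- intersect(anc(pair[1]), anc(pair[2]))
    ic <- -log(ont$probability)
    want <- max(ic[common]) / (ic[[pair[1]]] + ic[[pair[2]]])
    expect_equal(lin_similarity(pair[1], pair[2], ont), want)
  }
  # no common ancestor -> undefined
  ont2 <- as_ontology(data.frame(
    concept_id = c("x", "y"), parent_ids = c("", ""),
    probability = c(0.5, 0.5)))
  expect_true(is.na(lin_similarity("x", "y", ont2)))
})

test_that("ontology validation rejects cycles and bad probabilities", {
  expect_error(as_ontology(data.frame(
    concept_id = c("a", "b"), parent_ids = c("b", "a"),
    probability = c(0.5, 0.5))), "cycle")
  expect_error(as_ontology(data.frame(
    concept_id = "a", parent_ids = "", probability = 0)), "probabilit")
  # child probability may not exceed the parent's
  expect_error(as_ontology(data.frame(
    concept_id = c("p", "c"), parent_ids = c("", "p"),
    probability = c(0.1, 0.5))), "parent probability")
  # round trip through the TSV reader
  dir <- withr::local_tempdir()
  writeLines(c("concept_id\tparent_ids\tprobability",
               "root\t\t1", "a\troot\t0.4"),
             file.path(dir, "ontology.tsv"))
  ont <- load_ontology(file.path(dir, "ontology.tsv"))
  expect_equal(lin_similarity("a", "a", ont, canonical = TRUE), 1)
})

test_that("Czekanowski-Dice distance follows the symmetric difference", {
  expect_equal(czekanowski_dice(c("a", "b"), c("a", "b")), 0)
  expect_equal(czekanowski_dice(c("a"), c("b")), 1)
  expect_equal(czekanowski_dice(c("a", "b", "c"), c("b", "c", "d")),
               2 / (4 + 2))
  expect_true(is.na(czekanowski_dice(character(), character())))
})

test_that("clinically active ratios count statuses over a subset", {
  ds <- make_toy_dataset()
  ep <- eligible_pairs(ds)
  # the toy corpus: t1-d1 CLINICAL, t2-d2 APPROVED among eligible pairs
  r <- clinically_active_ratio(ds, ep)
  n <- nrow(ep)
  expect_equal(unname(r["clinical"]), 2 / n)
  expect_equal(unname(r["approved"]), 1 / n)
  expect_lte(r["approved"], r["clinical"])

  # 4-pair subset with one clinical-only and one approved
  sub <- ep[match(c(paste("t1", "d1"), paste("t2", "d2"),
                    paste("t1", "d2"), paste("t2", "d1")),
                  paste(ep$drug_id, ep$disease_id)), ]
  expect_equal(unname(clinically_active_ratio(ds, sub)),
               c(0.5, 0.25))

  # empty subset is undefined, foreign pairs are rejected
  expect_true(all(is.na(clinically_active_ratio(ds, ep[0, ]))))
  expect_error(clinically_active_ratio(
    ds, data.frame(drug_id = "t4", disease_id = "d1")),
    "non-eligible")

  # hand count on a generated fixture
  gen <- generate_corpus(sim_config(n_genes = 60, n_diseases = 8,
                                    n_drugs = 25, seed = 14))
  ds2 <- gen$dataset
  ep2 <- eligible_pairs(ds2)
  r2 <- clinically_active_ratio(ds2, ep2)
  key <- paste(ep2$drug_id, ep2$disease_id)
  ikey <- paste(ds2$indications$drug_id, ds2$indications$disease_id)
  akey <- ikey[ds2$indications$status == "APPROVED"]
  expect_equal(unname(r2["clinical"]), mean(key %in% ikey))
  expect_equal(unname(r2["approved"]), mean(key %in% akey))
})

test_that("permutation preserves degrees and is seed-deterministic", {
  ds <- make_toy_dataset()
  p1 <- permutation_test(ds, n_perm = 50, seed = 9)
  p2 <- permutation_test(ds, n_perm = 50, seed = 9)
  expect_identical(p1$null, p2$null)
  expect_identical(p1$p, p2$p)
  expect_equal(length(p1$null), 50)
  expect_gte(p1$p, 1 / 51)

  # the shuffle reassigns the same multiset of genes over the same
  # per-drug slot counts
  gvec <- unlist(ds$drugs, use.names = FALSE)
  dvec <- rep(names(ds$drugs), lengths(ds$drugs))
  withr::with_seed(9, {
    for (r in 1:5) {
      perm <- sample(gvec)
      expect_identical(sort(perm), sort(gvec))
      expect_identical(lengths(split(perm, dvec)),
                       lengths(split(gvec, dvec)))
    }
  })
})

test_that("permutation p-values are calibrated on null corpora", {
  # indications drawn independently of targets: p should be uniform
  ps <- vapply(1:120, function(i) {
    permutation_test(generate_corpus(null_corpus_config(i))$dataset,
                     n_perm = 99, seed = 5000 + i)$p
  }, numeric(1))
  rej <- mean(ps <= 0.05)
  # binomial 99% band around 0.05 at 120 reps
  bounds <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / 120)
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("ratio curves aggregate and detect planted trends", {
  ds <- generate_corpus(sim_config(seed = 77))$dataset
  # single bin reduces to the overall clinically active ratio
  ep <- pair_labels(ds)
  one <- stratified_ratio_curve(ds, "TARGET_COUNT",
                                bins = c(-0.5, Inf))
  expect_equal(one$curve$n_pairs, nrow(ep))
  expect_equal(one$curve$clinically_active_ratio,
               unname(clinically_active_ratio(ds, ep)["clinical"]))

  # planted positive effect: positive trend across all stratifiers
  for (st in c("TARGET_COUNT", "DRUGGABILITY_SCORE_BIN",
               "OHNOLOG_COVERAGE")) {
    rc <- stratified_ratio_curve(ds, st)
    expect_gt(rc$trend, 0)
    expect_true(all(rc$curve$approved_ratio <=
                      rc$curve$clinically_active_ratio, na.rm = TRUE))
  }
  # TOPGENE_COVERAGE is the ohnolog proxy
  expect_equal(stratified_ratio_curve(ds, "TOPGENE_COVERAGE")$curve,
               stratified_ratio_curve(ds, "OHNOLOG_COVERAGE")$curve)

  # empty bins are emitted with undefined ratios
  rc2 <- stratified_ratio_curve(ds, "TARGET_COUNT",
                                bins = c(-0.5, 1.5, 90, 100))
  expect_equal(rc2$curve$n_pairs[3], 0)
  expect_true(is.na(rc2$curve$clinically_active_ratio[3]))
  # bins must cover the range
  expect_error(stratified_ratio_curve(ds, "TARGET_COUNT",
                                      bins = c(0.5, 1.5)),
               "cover")
})

test_that("disease gene profiles correlate by rank over the gene union", {
  sc <- data.frame(
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
    disease_id = rep(c("da", "db"), each = 3),
    score = c(8, 5, 2, 16, 10, 4))
  expect_equal(disease_profile_correlation(sc, "da", "db"), 1)

  rev <- data.frame(
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
    disease_id = rep(c("da", "db"), each = 3),
    score = c(8, 5, 2, 2, 5, 8))
  expect_equal(disease_profile_correlation(rev, "da", "db"), -1)

  # six-gene fixture vs direct rank arithmetic
  six <- data.frame(
    gene_id = rep(paste0("g", 1:6), 2),
    disease_id = rep(c("da", "db"), each = 6),
    score = c(9, 3, 7, 1, 5, 2, 4, 8, 2, 9, 1, 6))
  got <- disease_profile_correlation(six, "da", "db")
  want <- stats::cor(rank(c(9, 3, 7, 1, 5, 2)),
                     rank(c(4, 8, 2, 9, 1, 6)))
  expect_equal(got, want)

  # under 3 genes in the union is undefined
  tiny <- data.frame(gene_id = c("g1", "g2"),
                     disease_id = c("da", "db"), score = c(3, 4))
  expect_true(is.na(disease_profile_correlation(tiny, "da", "db")))
})
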