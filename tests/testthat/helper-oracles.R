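# Independent, loop-based oracles used to cross-check the vectorized
# implementations, plus small corpus builders.

# Literal transcription of the MLKNN fitting equations: leave-one-out
# neighbour sets, label-conditioned count tables, Laplace-smoothed
# priors and posteriors.
oracle_mlknn_fit <- function(x, y, k, s) {
  n <- nrow(x); q <- ncol(y)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  }
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    dd <- d[i, ]
    dd[i] <- Inf
    nbr[[i]] <- order(dd, seq_len(n))[seq_len(k)]
  }
  C <- matrix(0L, n, q)
  for (i in seq_len(n)) {
    for (l in seq_len(q)) C[i, l] <- sum(y[nbr[[i]], l])
  }
  prior <- numeric(q)
  c1 <- c0 <- matrix(0L, q, k + 1)
  for (l in seq_len(q)) {
    prior[l] <- (s + sum(y[, l])) / (s * 2 + n)
    for (j in 0:k) {
      c1[l, j + 1] <- sum(y[, l] == 1 & C[, l] == j)
      c0[l, j + 1] <- sum(y[, l] == 0 & C[, l] == j)
    }
  }
  post1 <- post0 <- matrix(0, q, k + 1)
  for (l in seq_len(q)) {
    for (j in 0:k) {
      post1[l, j + 1] <- (s + c1[l, j + 1]) / (s * (k + 1) + sum(c1[l, ]))
      post0[l, j + 1] <- (s + c0[l, j + 1]) / (s * (k + 1) + sum(c0[l, ]))
    }
  }
  list(x = x, y = y, k = k, s = s, prior = prior,
       c1 = c1, c0 = c0, post1 = post1, post0 = post0)
}

oracle_mlknn_predict <- function(om, xt) {
  m <- nrow(xt); q <- ncol(om$y); n <- nrow(om$x)
  out <- matrix(0, m, q)
  for (t in seq_len(m)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((xt[t, ] - om$x[j, ])^2))
    nbr <- order(d, seq_len(n))[seq_len(om$k)]
    for (l in seq_len(q)) {
      C <- sum(om$y[nbr, l])
      p1 <- om$prior[l] * om$post1[l, C + 1]
      p0 <- (1 - om$prior[l]) * om$post0[l, C + 1]
      out[t, l] <- p1 / (p1 + p0)
    }
  }
  out
}

# AUPR by an explicit sweep over every distinct threshold.
oracle_aupr <- function(scores, labels) {
  y <- as.numeric(labels != 0)
  prec <- rec <- numeric(0)
  for (th in sort(unique(scores), decreasing = TRUE)) {
    call <- scores >= th
    tp <- sum(call & y == 1)
    prec <- c(prec, tp / sum(call))
    rec <- c(rec, tp / sum(y))
  }
  sum(diff(c(0, rec)) * prec)
}

# Multi-label metrics by explicit per-instance rank enumeration
# (assumes distinct scores within each instance).
oracle_multilabel <- function(scores, labels) {
  n <- nrow(scores)
  one <- cov <- rl <- ap <- numeric(0)
  for (i in seq_len(n)) {
    s <- scores[i, ]; y <- labels[i, ] != 0
    if (!any(y)) next
    rk <- match(seq_along(s), order(-s))   # rank of each label
    one <- c(one, as.numeric(!y[which.min(rk)]))
    cov <- c(cov, max(rk[y]) - 1)
    if (any(!y)) {
      bad <- 0
      for (a in which(y)) for (b in which(!y)) bad <- bad + (rk[a] > rk[b])
      rl <- c(rl, bad / (sum(y) * sum(!y)))
    }
    ap_i <- numeric(0)
    for (l in which(y)) ap_i <- c(ap_i, sum(y[rk <= rk[l]]) / rk[l])
    ap <- c(ap, mean(ap_i))
  }
  list(hamming_loss = mean((scores >= 0.5) != (labels != 0)),
       one_error = mean(one), coverage = mean(cov),
       ranking_loss = mean(rl), average_precision = mean(ap))
}

# A tiny deterministic corpus, larger than fixture_minimal, for
# data-model and feature tests.
make_toy_dataset <- function() {
  assoc <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gD", "gD", "gE"),
    disease_id = c("d1", "d2", "d1", "d1", "d2", "d1", "d2", "d2"),
    source_db = c("CLINVAR", "OMIM", "OMIM", "HGMD", "GAD", "DISGENET",
                  "GWASDB", "INTREPID"),
    stringsAsFactors = FALSE)
  targets <- data.frame(
    drug_id = c("t1", "t1", "t2", "t2", "t3", "t4"),
    gene_id = c("gA", "gB", "gC", "gD", "gE", "gF"),
    stringsAsFactors = FALSE)
  ind <- data.frame(drug_id = c("t1", "t2"),
                    disease_id = c("d1", "d2"),
                    status = c("CLINICAL", "APPROVED"),
                    stringsAsFactors = FALSE)
  ohno <- data.frame(gene_a = c("gA", "gC"), gene_b = c("gD", "gE"),
                     stringsAsFactors = FALSE)
  new_dataset(assoc, targets, ind, ohno)
}

# Null-corpus generator for permutation-test calibration: indications
# independent of the target structure.
null_corpus_config <- function(seed) {
  sim_config(
    n_genes = 80, n_diseases = 10, n_drugs = 50,
    db_inclusion_probs = c(CLINVAR = 0.02, OMIM = 0.018, HGMD = 0.016,
                           ORPHANET = 0.014, GWASDB = 0.014,
                           INTREPID = 0.012, GAD = 0.012,
                           DISGENET = 0.024),
    targets_min = 3, targets_max = 8,
    effect_beta1 = 0, effect_beta3 = 0, base_logit = -2.2,
    indication_universe = "all", seed = seed)
}
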