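# Cross-omic associations: cis/trans mapping, alteration statistics,
# transfer feature selection + classifier, Kaplan-Meier/log-rank.

make_cna_expr <- function(n_genes = 40, n_samples = 30, cis = 1:10,
                          slope = 1, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  cn <- matrix(sample(0:4, n_genes * n_samples, TRUE), n_genes, n_samples,
               dimnames = list(genes, samples))
  expr <- matrix(rnorm(n_genes * n_samples, 10), n_genes, n_samples,
                 dimnames = list(genes, samples))
  expr[cis, ] <- expr[cis, ] + slope * cn[cis, ]
  list(cna = omics_matrix(cn + 0, "raw_intensity", "cna_gene"),
       mrna = omics_matrix(expr, "log2", "mrna"))
}

test_that("cis mapping finds a perfect monotone relationship with rho 1", {
  d <- make_cna_expr(slope = 0)
  # gene G01 expression is a monotone function of its own copy number (shared
  # tie structure, so the rank correlation is exactly 1)
  d$mrna$values["G01", ] <- 2^d$cna$values["G01", ]
  res <- cis_trans_map(d$cna, mrna = d$mrna, fdr = 0.1)
  rec <- res$records[res$records$cna_gene == "G01", ]
  expect_equal(rec$rho, 1)
  expect_true(rec$is_cis)
  expect_lt(rec$q, 0.1)
  expect_error(cis_trans_map(subset_omics(d$cna, samples = 1:5),
                             mrna = subset_omics(d$mrna, samples = 1:5)),
               "10 shared")
})

test_that("planted cis genes are recovered and the null FDP is controlled", {
  d <- make_cna_expr(n_genes = 400, n_samples = 60, cis = 1:80, slope = 0.6,
                     seed = 3)
  res <- cis_trans_map(d$cna, mrna = d$mrna, fdr = 0.1)
  sig <- res$summary$cis_significant$mrna
  cis_genes <- sprintf("G%02d", 1:80)  # names exceed 2 digits above 99
  cis_genes <- feature_ids(d$cna)[1:80]
  recovered <- mean(cis_genes %in% sig)
  fdp <- length(setdiff(sig, cis_genes)) / max(1, length(sig))
  expect_gte(recovered, 0.9)
  expect_lte(fdp, 0.15)
  # pure-null matrix keeps the false-discovery proportion near the target
  d0 <- make_cna_expr(n_genes = 600, n_samples = 60, cis = 1, slope = 0, seed = 9)
  res0 <- cis_trans_map(d0$cna, mrna = d0$mrna, fdr = 0.1)
  expect_lte(length(res0$summary$cis_significant$mrna) / 600, 0.15)
})

test_that("trans families are scored per copy-number gene when requested", {
  d <- make_cna_expr(seed = 5)
  res <- cis_trans_map(d$cna, mrna = d$mrna, trans_genes = "G01")
  tr <- res$records[!res$records$is_cis, ]
  expect_true(all(tr$cna_gene == "G01"))
  expect_false("G01" %in% tr$target_feature)
  expect_equal(nrow(tr), nrow(d$mrna$values) - 1)
})

test_that("Spearman statistics are invariant under monotone transforms", {
  d <- make_cna_expr(seed = 7)
  res1 <- cis_trans_map(d$cna, mrna = d$mrna)
  d$mrna$values <- exp(d$mrna$values / 3)  # strictly monotone
  res2 <- cis_trans_map(d$cna, mrna = d$mrna)
  expect_equal(res1$records$rho, res2$records$rho)
  expect_equal(res1$records$p, res2$records$p)
})

test_that("alteration frequencies and Fisher co-occurrence are exact", {
  calls <- matrix("none", 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  calls["g1", c("a", "b")] <- "mutation"
  am <- alteration_matrix(calls)
  freq <- alteration_frequencies(am)
  expect_equal(freq$frequency[freq$gene == "g1"], 2 / 3)
  expect_equal(freq$frequency[freq$gene == "g2"], 0)
  expect_equal(freq$gene[1], "g1")  # sorted by decreasing frequency

  # [[5,0],[0,5]] -> p = 2 / C(10,5)
  calls2 <- matrix("none", 2, 10,
                   dimnames = list(c("A", "B"), sprintf("s%d", 1:10)))
  calls2["A", 1:5] <- "amplification"
  calls2["B", 1:5] <- "loh"
  co <- cooccurrence_fisher(alteration_matrix(calls2), "A", "B")
  expect_equal(co$p, 2 / choose(10, 5), tolerance = 1e-12)
  # independence: [[4,4],[4,4]] -> p = 1
  calls3 <- matrix("none", 2, 16,
                   dimnames = list(c("A", "B"), sprintf("s%d", 1:16)))
  calls3["A", 1:8] <- "mutation"
  calls3["B", c(1:4, 9:12)] <- "mutation"
  expect_equal(cooccurrence_fisher(alteration_matrix(calls3), "A", "B")$p, 1)
  # symmetry in gene order
  expect_equal(cooccurrence_fisher(alteration_matrix(calls2), "B", "A")$p, co$p)
  expect_error(cooccurrence_fisher(alteration_matrix(calls2), "A", "ZZ"), "ZZ")
  # exhaustive enumeration oracle over all tables with fixed margins
  set.seed(15)
  for (trial in 1:10) {
    n <- sample(8:20, 1)
    a <- runif(n) < 0.5; b <- runif(n) < 0.5
    cl <- matrix("none", 2, n, dimnames = list(c("A", "B"), sprintf("s%d", 1:n)))
    cl["A", a] <- "mutation"; cl["B", b] <- "mutation"
    p_pkg <- cooccurrence_fisher(alteration_matrix(cl), "A", "B")$p
    # enumerate P(table) for all feasible cell counts with the same margins
    ra <- sum(a); rb <- sum(b)
    probs <- vapply(max(0, ra + rb - n):min(ra, rb), function(x) {
      choose(rb, x) * choose(n - rb, ra - x) / choose(n, ra)
    }, 0)
    obs <- sum(a & b) - max(0, ra + rb - n) + 1
    p_exact <- sum(probs[probs <= probs[obs] * (1 + 1e-7)])
    expect_equal(p_pkg, p_exact, tolerance = 1e-9, info = paste("trial", trial))
  }
})

test_that("transfer feature selection applies the FDR and fold-change filter", {
  set.seed(20)
  genes <- sprintf("g%d", 1:200)
  v <- matrix(rnorm(200 * 30, 10, 0.5), 200, 30,
              dimnames = list(genes, sprintf("s%d", 1:30)))
  labels <- setNames(rep(c("A", "B", "C"), each = 10), colnames(v))
  v[1:20, labels == "A"] <- v[1:20, labels == "A"] + 2      # |log2FC| 2 > 1
  v[21:40, labels == "B"] <- v[21:40, labels == "B"] + 0.5  # below FC filter
  m <- small_matrix(v)
  sel <- select_transfer_features(m, labels, fdr = 0.01, min_abs_fc = 2)
  expect_true(all(sprintf("g%d", 1:20) %in% sel))
  expect_false(any(sprintf("g%d", 21:40) %in% sel))
  expect_gte(mean(!sprintf("g%d", 41:200) %in% sel), 0.95)  # null specificity
  # vacuous thresholds return everything; identical classes return nothing
  expect_setequal(select_transfer_features(m, labels, fdr = 1, min_abs_fc = 1),
                  genes)
  v0 <- matrix(rnorm(50 * 12, 10), 50, 12,
               dimnames = list(sprintf("n%d", 1:50), sprintf("s%d", 1:12)))
  lab0 <- setNames(rep(c("A", "B"), each = 6), colnames(v0))
  expect_lte(length(select_transfer_features(small_matrix(v0), lab0)), 2)
  expect_error(select_transfer_features(m, labels[1:5]), "missing")
})

test_that("the subtype classifier reaches F1 = 1 on separable data, chance on null", {
  set.seed(30)
  v <- matrix(rnorm(40 * 45, 10, 0.3), 40, 45,
              dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:45)))
  labels <- setNames(rep(c("A", "B", "C"), each = 15), colnames(v))
  v[1:5, labels == "A"] <- v[1:5, labels == "A"] + 4
  v[6:10, labels == "B"] <- v[6:10, labels == "B"] + 4
  m <- small_matrix(v)
  fit <- fit_subtype_classifier(m, labels, sprintf("g%d", 1:10), seed = 1)
  expect_equal(fit$macro_f1, 1.0)
  # determinism: same seed reproduces the split and scores
  fit2 <- fit_subtype_classifier(m, labels, sprintf("g%d", 1:10), seed = 1)
  expect_identical(fit$test_samples, fit2$test_samples)
  expect_equal(fit$macro_f1, fit2$macro_f1)
  # prediction depends only on the selected features
  v2 <- v; v2[11:40, ] <- v2[11:40, ] + matrix(rnorm(30 * 45, 0, 5), 30)
  expect_equal(as.character(predict(fit, small_matrix(v2))),
               as.character(predict(fit, m)))
  # permuted labels: macro F1 near chance
  f1s <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    perm <- setNames(sample(labels), names(labels))
    fit_subtype_classifier(m, perm, sprintf("g%d", 1:10), seed = s,
                           n_trees = 100)$macro_f1
  }, 0)
  expect_lt(abs(mean(f1s) - 1 / 3), 0.15)
})

test_that("Kaplan-Meier product-limit and log-rank behave on hand oracles", {
  # times 1, 2, 3+, 4, 5 with one censor: S(4) = (4/5)(3/4)(1/2)
  st <- sample_table(data.frame(
    sample_id = sprintf("s%d", 1:10), plex_id = "p", channel_id = 1:10,
    is_pooled_reference = FALSE,
    os_time = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
    os_event = c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1)))
  groups <- setNames(rep(c("g1", "g2"), each = 5), st$sample_id)
  res <- km_logrank(st, groups, "os")
  surv_at4 <- summary(res$fit, times = 4)$surv
  expect_equal(surv_at4, rep((4 / 5) * (3 / 4) * (1 / 2), 2), tolerance = 1e-12)
  # identical groups: chi-square 0, p 1
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)
  expect_error(km_logrank(st, groups[1:5], "os"), "2 groups")
})

test_that("log-rank detects a 3x hazard ratio in most simulated cohorts", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    t1 <- rexp(100, 0.1); t2 <- rexp(100, 0.3)
    cens <- runif(200, 0, quantile(c(t1, t2), 0.9))
    st <- sample_table(data.frame(
      sample_id = sprintf("s%d", 1:200), plex_id = "p", channel_id = 1:200,
      is_pooled_reference = FALSE,
      os_time = pmin(c(t1, t2), cens), os_event = as.integer(c(t1, t2) <= cens)))
    groups <- setNames(rep(c("a", "b"), each = 100), st$sample_id)
    km_logrank(st, groups, "os")$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
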