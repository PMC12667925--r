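# Preprocessing chain: filter boundary, KNN semantics vs brute force,
# scale-transform arithmetic, IRS batch removal, TMM oracles, Welch+BH.

test_that("missingness filter applies the >= 30% valid rule at the boundary", {
  v <- matrix(rnorm(300), 3, 100,
              dimnames = list(c("f29", "f30", "full"), sprintf("s%d", 1:100)))
  v[1, 1:71] <- NA  # 29 valid
  v[2, 1:70] <- NA  # 30 valid
  m <- small_matrix(v)
  kept <- feature_ids(filter_missing(m, 0.30))
  expect_identical(kept, c("f30", "full"))
  expect_identical(filter_missing(m, 1)$values, v["full", , drop = FALSE])
  full <- small_matrix(matrix(1:6 + 0, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z"))))
  expect_identical(filter_missing(full)$values, full$values)
  expect_error(filter_missing(m, 0), "min_valid_frac")
  expect_error(filter_missing(m, 1.2), "min_valid_frac")
})

test_that("KNN imputation honors k=1 semantics and never touches observed cells", {
  v <- rbind(A = c(1, 2, NA, 4),
             B = c(1.1, 2.1, 5.0, 4.1),
             C = c(9, 9, 9, 9))
  colnames(v) <- sprintf("s%d", 1:4)
  m <- small_matrix(v)
  out <- knn_impute(m, k = 1)
  expect_equal(out$values["A", "s3"], 5.0)  # nearest feature B's value
  obs <- !is.na(v)
  expect_identical(out$values[obs], v[obs])
  # no missing cells: identity
  expect_identical(knn_impute(small_matrix(v[2:3, ]))$values, v[2:3, ])
  # all-missing feature is an error
  v2 <- v; v2["A", ] <- NA
  expect_error(knn_impute(small_matrix(v2)), "A")
})

test_that("KNN imputation matches exhaustive search on a toy matrix", {
  set.seed(31)
  v <- matrix(rnorm(24, 10), 6, 4,
              dimnames = list(sprintf("f%d", 1:6), sprintf("s%d", 1:4)))
  v[cbind(c(1, 3, 5), c(2, 4, 1))] <- NA
  for (k in c(1, 2, 3)) {
    expect_equal(knn_impute(small_matrix(v), k = k)$values,
                 orc_knn_impute(v, k), info = paste("k =", k))
  }
})

test_that("sample loading normalization equalizes column sums to the grand mean", {
  v <- matrix(c(10, 30, 60, 100, 80, 120), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- small_matrix(v, "raw_intensity")
  sl <- sample_loading_normalize(m)
  expect_equal(unname(sl$factors), c(2, 2 / 3))  # sums 100, 300 -> target 200
  expect_equal(unname(colSums(sl$matrix$values)), c(200, 200))
  # already equal sums: identity
  v2 <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sl2 <- sample_loading_normalize(small_matrix(v2, "raw_intensity"))
  expect_equal(unname(sl2$factors), c(1, 1))
  expect_equal(sl2$matrix$values, v2)
  # idempotence and relative spread
  sl3 <- sample_loading_normalize(sl$matrix)
  expect_equal(sl3$matrix$values, sl$matrix$values)
  spread <- diff(range(colSums(sl$matrix$values))) / mean(colSums(sl$matrix$values))
  expect_lt(spread, 1e-9)
  v[, 1] <- 0
  expect_error(sample_loading_normalize(small_matrix(v, "raw_intensity")), "zero")
})

test_that("IRS equalizes reference means per feature across plexes", {
  # feature with reference means 100 (plex A) and 200 (plex B)
  v <- rbind(f1 = c(100, 110, 100, 200, 190, 200),
             f2 = c(50, 55, 50, 50, 45, 50))
  colnames(v) <- c("a1", "a2", "refA", "b1", "b2", "refB")
  st <- sample_table(data.frame(
    sample_id = colnames(v), plex_id = rep(c("A", "B"), each = 3),
    channel_id = rep(1:3, 2),
    is_pooled_reference = colnames(v) %in% c("refA", "refB")))
  out <- irs_correct(small_matrix(v, "raw_intensity"), st)
  g <- sqrt(100 * 200)
  expect_equal(unname(out$factors[1, ]), c(g / 100, g / 200))
  expect_equal(out$matrix$values["f1", "refA"], out$matrix$values["f1", "refB"])
  expect_equal(out$matrix$values["f1", "a1"], 100 * sqrt(2), tolerance = 1e-12)
  # single plex: identity
  one <- irs_correct(small_matrix(v[, 1:3], "raw_intensity"), st[1:3, ])
  expect_equal(one$matrix$values, v[, 1:3])
  # idempotence
  twice <- irs_correct(out$matrix, st)
  expect_equal(twice$matrix$values, out$matrix$values)
  # feature absent from a plex's references becomes missing there
  v2 <- v; v2["f2", "refB"] <- NA
  out2 <- irs_correct(small_matrix(v2, "raw_intensity"), st)
  expect_true(all(is.na(out2$matrix$values["f2", c("b1", "b2", "refB")])))
  expect_false(anyNA(out2$matrix$values["f2", c("a1", "a2", "refA")]))
  # plex without reference
  st2 <- st; st2$is_pooled_reference[6] <- FALSE
  expect_error(irs_correct(small_matrix(v, "raw_intensity"), st2),
               "pooled-reference")
})

test_that("IRS removes planted between-plex reference variance on a cohort", {
  coh <- simulate_cohort(small_config(seed = 3, missing_rate = 0))
  refs <- coh$samples$sample_id[coh$samples$is_pooled_reference]
  pre_var <- mean(apply(log2(coh$protein$values[, refs]), 1, var))
  sl <- sample_loading_normalize(coh$protein)
  irs <- irs_correct(sl$matrix, coh$samples)
  post_var <- mean(apply(log2(irs$matrix$values[, refs]), 1, var))
  expect_lt(post_var, 0.01 * pre_var)
})

test_that("TMM factors satisfy closed forms and match the naive oracle", {
  set.seed(11)
  base <- matrix(2^rnorm(40, 10), 20, 2,
                 dimnames = list(sprintf("f%d", 1:20), c("s1", "s2")))
  base[, 2] <- base[, 1]
  ident <- tmm_normalize(small_matrix(base, "raw_intensity"))
  expect_equal(unname(ident$factors), c(1, 1))
  # column B = 2 x column A: factor ratio exactly 2 (constant M, trim vacuous)
  v <- base; v[, 2] <- 2 * v[, 1]
  tm <- tmm_normalize(small_matrix(v, "raw_intensity"))
  expect_equal(unname(tm$factors["s2"] / tm$factors["s1"]), 2, tolerance = 1e-9)
  # geometric mean of factors is 1; applying TMM twice equals applying once
  expect_equal(prod(tm$factors), 1, tolerance = 1e-12)
  again <- tmm_normalize(tm$matrix)
  expect_equal(unname(again$factors), c(1, 1), tolerance = 1e-9)
  # naive-loop oracle agreement on a 500 x 8 random matrix
  set.seed(12)
  big <- matrix(2^(rnorm(4000, 10, 1.5)), 500, 8,
                dimnames = list(sprintf("f%d", 1:500), sprintf("s%d", 1:8)))
  big <- sweep(big, 2, runif(8, 0.5, 2), `*`)
  tmb <- tmm_normalize(small_matrix(big, "raw_intensity"))
  expect_equal(unname(tmb$factors), orc_tmm_factors(big), tolerance = 1e-12)
  expect_error(tmm_normalize(small_matrix(big - 2^10, "log2")), "raw")
})

test_that("TMM factors track edgeR's trimmed mean on equal-loading data", {
  skip_if_not_installed("edgeR")
  set.seed(13)
  x <- matrix(2^(rnorm(3000, 12, 1)), 500, 6,
              dimnames = list(sprintf("f%d", 1:500), sprintf("s%d", 1:6)))
  x <- sweep(x, 2, mean(colSums(x)) / colSums(x), `*`)  # equal column sums
  mine <- tmm_normalize(small_matrix(x, "raw_intensity"))
  ref <- which.min(abs(colSums(x) - mean(colSums(x))))
  ef <- edgeR::calcNormFactors(x, method = "TMM", refColumn = ref,
                               doWeighting = FALSE)
  ef <- ef / exp(mean(log(ef)))
  expect_equal(unname(mine$factors), unname(ef), tolerance = 0.02)
})

test_that("Welch differential abundance matches t.test and the BH formula", {
  set.seed(21)
  v <- matrix(rnorm(10 * 12, 20), 10, 12,
              dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:12)))
  v[1, 1:6] <- v[1, 1:6] + 3
  m <- small_matrix(v)
  da <- differential_abundance(m, sprintf("s%d", 1:6), sprintf("s%d", 7:12))
  for (i in c(1, 5, 9)) {
    tt <- t.test(v[i, 1:6], v[i, 7:12])
    expect_equal(da$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(da$log2fc[i], unname(diff(-tt$estimate)), tolerance = 1e-12)
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  expect_equal(da$q, p.adjust(da$p, "BH"))
  # identical groups: fc 0 and p 1 for constant-difference features
  v2 <- matrix(rep(c(1, 2, 3, 4), each = 8), 4, 8, byrow = TRUE,
               dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:8)))
  da2 <- differential_abundance(small_matrix(v2), sprintf("s%d", 1:4),
                                sprintf("s%d", 5:8))
  expect_equal(da2$log2fc, rep(0, 4))
  expect_equal(da2$p, rep(1, 4))
  expect_error(differential_abundance(m, "s1", sprintf("s%d", 2:4)), "2 samples")
})

test_that("the DE stage is calibrated: ~5% type I error and >=95% power at 2 SD", {
  set.seed(77)
  n <- 20; p <- 1000; shifted <- 1:100
  v <- matrix(rnorm(p * 2 * n, 20, 1), p, 2 * n,
              dimnames = list(sprintf("f%d", 1:p), sprintf("s%d", 1:(2 * n))))
  v[shifted, 1:n] <- v[shifted, 1:n] + 2  # 2 pooled SDs
  da <- differential_abundance(small_matrix(v), sprintf("s%d", 1:n),
                               sprintf("s%d", (n + 1):(2 * n)))
  power <- mean(da$q[shifted] < 0.05)
  type1 <- mean(da$p[-shifted] < 0.05)
  expect_gte(power, 0.95)
  expect_lt(abs(type1 - 0.05), 0.02)
})

test_that("the full chain removes plex structure while keeping subtype structure", {
  coh <- simulate_cohort(small_config(seed = 5))
  norm <- normalize_tmt(coh$protein, coh$samples)
  expect_lte(nrow(norm$matrix$values), nrow(coh$protein$values))
  expect_false(anyNA(norm$matrix$values))
  tum <- coh$samples$sample_id[!coh$samples$is_pooled_reference]
  x <- t(norm$matrix$values[, tum])
  d <- dist(x)
  plex <- coh$samples$plex_id[match(tum, coh$samples$sample_id)]
  subt <- coh$truth$labels[tum]
  sil_plex <- mean(cluster::silhouette(as.integer(factor(plex)), d)[, 3])
  sil_subt <- mean(cluster::silhouette(as.integer(factor(subt)), d)[, 3])
  expect_lt(abs(sil_plex), 0.1)
  expect_gt(sil_subt, 0.05)
  expect_gt(sil_subt, sil_plex)
})
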