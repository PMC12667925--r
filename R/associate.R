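# Cross-omic association stages: cis/trans copy-number-expression mapping,
# alteration frequencies and co-occurrence, DE-filtered subtype transfer,
# and Kaplan-Meier survival stratification.

spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4) return(c(rho = NA_real_, p = NA_real_))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  rho <- stats::cor(rx, ry)
  if (is.na(rho) || abs(rho) >= 1) {
    p <- if (is.na(rho)) NA_real_ else 0
    return(c(rho = rho, p = p))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))  # t approximation, as cor.test
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Cis (and optional trans) copy-number-expression correlation map
#'
#' For every gene present in both the copy-number matrix and an expression
#' layer, computes the Spearman correlation between its copy number and its
#' own expression (cis). Optionally, for genes in `trans_genes`, correlations
#' against all other features (trans). BH correction runs separately within
#' the cis family and within each copy-number gene's trans family.
#'
#' @param cna `omics_matrix` of gene-level copy-number values.
#' @param mrna,protein Expression `omics_matrix` objects (either may be
#'   `NULL`); gene IDs shared with `cna` define the cis pairs.
#' @param fdr Significance threshold on q; default 0.1.
#' @param trans_genes Optional character vector of copy-number genes for
#'   which trans correlations are computed.
#' @return List with `records` (data frame: `cna_gene`, `target_feature`,
#'   `level`, `rho`, `p`, `q`, `is_cis`) and `summary` (cis counts at
#'   `q < fdr` per level and their overlap).
#' @export
cis_trans_map <- function(cna, mrna = NULL, protein = NULL, fdr = 0.1,
                          trans_genes = NULL) {
  layers <- list()
  if (!is.null(mrna)) layers$mrna <- mrna
  if (!is.null(protein)) layers$protein <- protein
  if (!length(layers)) stop("need at least one expression layer", call. = FALSE)
  recs <- list()
  for (lv in names(layers)) {
    expr <- layers[[lv]]
    shared_s <- intersect(sample_ids(cna), sample_ids(expr))
    if (length(shared_s) < 10) {
      stop("fewer than 10 shared samples for level ", lv, call. = FALSE)
    }
    genes <- intersect(feature_ids(cna), feature_ids(expr))
    cn <- cna$values[genes, shared_s, drop = FALSE]
    ex <- expr$values[genes, shared_s, drop = FALSE]
    st <- t(vapply(seq_along(genes), function(i) spearman_test(cn[i, ], ex[i, ]),
                   c(rho = 0, p = 0)))
    cis <- data.frame(cna_gene = genes, target_feature = genes, level = lv,
                      rho = st[, "rho"], p = st[, "p"],
                      q = stats::p.adjust(st[, "p"], "BH"), is_cis = TRUE,
                      row.names = NULL, stringsAsFactors = FALSE)
    recs[[paste0("cis_", lv)]] <- cis
    for (g in intersect(trans_genes, feature_ids(cna))) {
      targets <- setdiff(feature_ids(expr), g)
      stt <- t(vapply(targets, function(tg) {
        spearman_test(cna$values[g, shared_s], expr$values[tg, shared_s])
      }, c(rho = 0, p = 0)))
      recs[[paste0("trans_", lv, "_", g)]] <- data.frame(
        cna_gene = g, target_feature = targets, level = lv,
        rho = stt[, "rho"], p = stt[, "p"],
        q = stats::p.adjust(stt[, "p"], "BH"), is_cis = FALSE,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  cis_sig <- lapply(names(layers), function(lv) {
    with(records, cna_gene[is_cis & level == lv & !is.na(q) & q < fdr])
  })
  names(cis_sig) <- names(layers)
  summary <- list(fdr = fdr,
                  n_cis_significant = lengths(cis_sig),
                  cis_overlap = if (length(cis_sig) == 2)
                    length(intersect(cis_sig[[1]], cis_sig[[2]])) else NA_integer_,
                  cis_significant = cis_sig)
  list(records = records, summary = summary)
}

#' Alteration frequency per gene
#'
#' @param alts An `alteration_matrix`.
#' @return Data frame (`gene`, `n_altered`, `frequency`), sorted by
#'   decreasing frequency; frequency is the fraction of samples with any
#'   non-`none` call.
#' @export
alteration_frequencies <- function(alts) {
  calls <- alts$calls
  if (!ncol(calls)) stop("alteration matrix has no samples", call. = FALSE)
  n_alt <- rowSums(calls != "none")
  out <- data.frame(gene = rownames(calls), n_altered = n_alt,
                    frequency = n_alt / ncol(calls), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$gene), ]
}

#' Fisher exact test of alteration co-occurrence for a gene pair
#'
#' @param alts An `alteration_matrix`.
#' @param gene_a,gene_b Gene names present in the matrix.
#' @return List with `table` (2x2 altered/unaltered counts), `odds_ratio`
#'   (conditional MLE) and `p` (two-sided).
#' @export
cooccurrence_fisher <- function(alts, gene_a, gene_b) {
  calls <- alts$calls
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(calls)) stop("gene absent: ", g, call. = FALSE)
  }
  a <- calls[gene_a, ] != "none"
  b <- calls[gene_b, ] != "none"
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)),
               dnn = c(gene_a, gene_b))
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Select subtype-transfer features by differential expression
#'
#' Union over one-vs-rest contrasts of features passing `q < fdr` and
#' linear fold change `> min_abs_fc` in absolute value (i.e.
#' `|log2FC| > log2(min_abs_fc)`), the filter used to build a transferable
#' subtype classifier.
#'
#' @param expr A log2 `omics_matrix`.
#' @param labels Named vector of class labels covering the samples.
#' @param fdr BH threshold; default 0.01.
#' @param min_abs_fc Linear fold-change threshold; default 2.
#' @return Character vector of selected feature IDs.
#' @export
select_transfer_features <- function(expr, labels, fdr = 0.01, min_abs_fc = 2) {
  labels <- labels[sample_ids(expr)]
  if (anyNA(labels)) stop("labels missing for some samples", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 3)) stop("every class needs >= 3 samples", call. = FALSE)
  sel <- character()
  for (cl in classes) {
    da <- differential_abundance(expr,
                                 sample_ids(expr)[labels == cl],
                                 sample_ids(expr)[labels != cl])
    sel <- union(sel, da$feature[!is.na(da$q) & da$q < fdr &
                                   abs(da$log2fc) > log2(min_abs_fc)])
  }
  sel
}

#' Train and evaluate a subtype-transfer classifier
#'
#' Random-forest classifier on the selected features with a stratified
#' train/test split; `mtry` is chosen by stratified k-fold cross-validation
#' on the training portion, and held-out performance is reported as
#' macro-averaged F1. The fitted model predicts labels for any matrix
#' carrying the feature set.
#'
#' @param expr A log2 `omics_matrix`.
#' @param labels Named vector of class labels.
#' @param features Feature subset to use (e.g. from
#'   [select_transfer_features()]).
#' @param train_frac Training fraction; default 0.7.
#' @param n_folds Cross-validation folds for `mtry` selection; default 10.
#' @param seed Integer seed (split, folds, forest).
#' @param n_trees Forest size; default 500.
#' @return List of class `subtype_classifier`: `model`, `features`,
#'   `per_class_f1`, `macro_f1`, `test_samples`, `mtry`.
#' @export
fit_subtype_classifier <- function(expr, labels, features, train_frac = 0.7,
                                   n_folds = 10, seed = 1L, n_trees = 500) {
  miss <- setdiff(features, feature_ids(expr))
  if (length(miss)) stop("features absent from matrix: ", miss[1], call. = FALSE)
  labels <- factor(labels[sample_ids(expr)])
  x <- t(expr$values[features, , drop = FALSE])
  set.seed(seed)
  tr <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    sample(ix, max(1, round(train_frac * length(ix))))
  }))
  if (length(unique(labels[tr])) < nlevels(labels) ||
      length(unique(labels[-tr])) < nlevels(labels)) {
    stop("a class is absent from the train or test split", call. = FALSE)
  }
  # stratified k-fold CV over a small mtry grid
  p <- length(features)
  grid <- unique(pmax(1, round(c(sqrt(p) / 2, sqrt(p), sqrt(p) * 2))))
  folds <- integer(length(tr))
  for (ix in split(seq_along(tr), labels[tr])) {
    folds[ix] <- rep_len(seq_len(n_folds), length(ix))[sample(length(ix))]
  }
  cv_err <- vapply(grid, function(mt) {
    errs <- vapply(seq_len(n_folds), function(f) {
      hold <- tr[folds == f]
      fit_on <- setdiff(tr, hold)
      if (!length(hold) || length(unique(labels[fit_on])) < nlevels(labels)) {
        return(NA_real_)
      }
      rf <- randomForest::randomForest(x[fit_on, , drop = FALSE],
                                       labels[fit_on], mtry = mt,
                                       ntree = max(100, n_trees %/% 5))
      mean(predict(rf, x[hold, , drop = FALSE]) != labels[hold])
    }, 0)
    mean(errs, na.rm = TRUE)
  }, 0)
  mtry <- grid[which.min(cv_err)]
  model <- randomForest::randomForest(x[tr, , drop = FALSE], labels[tr],
                                      mtry = mtry, ntree = n_trees)
  test <- setdiff(seq_along(labels), tr)
  pred <- predict(model, x[test, , drop = FALSE])
  f1 <- macro_f1(labels[test], pred)
  structure(list(model = model, features = features,
                 per_class_f1 = f1$per_class, macro_f1 = f1$macro_f1,
                 test_samples = rownames(x)[test], mtry = mtry, seed = seed),
            class = "subtype_classifier")
}

#' Predict subtype labels with a fitted transfer classifier
#'
#' @param object A `subtype_classifier`.
#' @param newdata An `omics_matrix` carrying the classifier's feature set.
#' @param ... Unused.
#' @return Named factor of predicted labels.
#' @export
predict.subtype_classifier <- function(object, newdata, ...) {
  x <- t(newdata$values[object$features, , drop = FALSE])
  stats::predict(object$model, x)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param samples A `sample_table` with survival columns.
#' @param groups Named vector of group labels (sample_id -> group).
#' @param endpoint `"os"` or `"rfs"`.
#' @return List with `fit` (a `survival::survfit` object), `chi2`, `df`,
#'   `p`, and `n_groups`.
#' @export
km_logrank <- function(samples, groups, endpoint = c("os", "rfs")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  ids <- intersect(samples$sample_id, names(groups))
  df <- data.frame(time = samples[[tcol]][match(ids, samples$sample_id)],
                   event = samples[[ecol]][match(ids, samples$sample_id)],
                   group = factor(unname(groups[ids])))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$group)) < 2) {
    stop("need at least 2 groups with survival data", call. = FALSE)
  }
  if (any(df$time < 0)) stop("negative survival times", call. = FALSE)
  if (sum(df$event) < 1) stop("no events observed", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  df_chi <- length(sd_$n) - 1
  list(fit = fit, chi2 = unname(sd_$chisq), df = df_chi,
       p = stats::pchisq(sd_$chisq, df_chi, lower.tail = FALSE),
       n_groups = length(sd_$n))
}
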