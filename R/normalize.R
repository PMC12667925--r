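# TMT preprocessing chain: missingness filter -> KNN imputation -> sample
# loading normalization -> internal reference scaling -> TMM median centering,
# plus a Welch-t differential abundance stage.

#' Filter features by fraction of valid values
#'
#' Retains exactly the features observed in at least `min_valid_frac` of
#' samples (a feature valid in 29 of 100 samples at the default 0.30 is
#' dropped; 30 of 100 is retained).
#'
#' @param m An `omics_matrix`.
#' @param min_valid_frac Minimum fraction of non-missing values, in (0, 1].
#' @return Filtered `omics_matrix`, row order preserved.
#' @export
filter_missing <- function(m, min_valid_frac = 0.30) {
  if (min_valid_frac <= 0 || min_valid_frac > 1) {
    stop("min_valid_frac must be in (0, 1]", call. = FALSE)
  }
  frac <- rowMeans(!is.na(m$values))
  subset_omics(m, features = which(frac >= min_valid_frac))
}

#' K-nearest-neighbor imputation of missing values
#'
#' For each missing cell, the imputed value is the mean over the `k` nearest
#' features (Euclidean distance on jointly observed samples, scaled by the
#' number of shared observations) that are observed at that sample. Observed
#' values are never altered. Falls back to the feature's own mean when no
#' neighbor shares observations.
#'
#' @param m An `omics_matrix` on the log2 scale.
#' @param k Number of neighbors; default 10.
#' @return An `omics_matrix` with no missing values.
#' @export
knn_impute <- function(m, k = 10) {
  if (m$scale_tag != "log2") stop("impute on the log2 scale", call. = FALSE)
  x <- m$values
  if (!anyNA(x)) return(m)
  n_obs <- rowSums(!is.na(x))
  if (any(n_obs == 0)) {
    stop("feature with no observed values (filter first): ",
         rownames(x)[n_obs == 0][1], call. = FALSE)
  }
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  sq <- x0^2
  shared <- tcrossprod(obs * 1)                # number of jointly observed samples
  cross <- tcrossprod(x0)
  a <- sq %*% t(obs)                           # sum_i x_i^2 over shared
  d2 <- a + t(a) - 2 * cross
  d2[d2 < 0] <- 0
  dist <- sqrt(d2 / shared)                    # scaled Euclidean; NaN when none shared
  diag(dist) <- Inf
  out <- x
  for (i in which(rowSums(!obs) > 0)) {
    di <- dist[i, ]
    ord <- order(di, na.last = NA)             # drops no-overlap neighbors
    for (s in which(!obs[i, ])) {
      cand <- ord[obs[ord, s]]
      if (length(cand)) {
        out[i, s] <- mean(x[cand[seq_len(min(k, length(cand)))], s])
      } else {
        out[i, s] <- mean(x[i, obs[i, ]])
      }
    }
  }
  omics_matrix(out, m$scale_tag, m$feature_kind)
}

#' Sample loading normalization
#'
#' Rescales each sample column so that all column totals (over observed
#' values) equal the grand mean of the original totals — the assumption that
#' equal protein amounts were labeled per TMT channel.
#'
#' @param m An `omics_matrix` on the raw intensity scale.
#' @return List with `matrix` (the rescaled `omics_matrix`) and `factors`
#'   (per-sample multipliers).
#' @export
sample_loading_normalize <- function(m) {
  if (m$scale_tag != "raw_intensity") {
    stop("sample loading normalization operates on raw intensities", call. = FALSE)
  }
  sums <- colSums(m$values, na.rm = TRUE)
  if (any(sums == 0)) {
    stop("sample column sums to zero: ", colnames(m$values)[sums == 0][1],
         call. = FALSE)
  }
  factors <- mean(sums) / sums
  out <- sweep(m$values, 2, factors, `*`)
  list(matrix = omics_matrix(out, m$scale_tag, m$feature_kind),
       factors = factors)
}

#' Internal reference scaling across TMT plexes
#'
#' Per feature, each plex's values are scaled by `g / r_p`, where `r_p` is
#' the mean of that plex's pooled-reference channels and `g` the geometric
#' mean of the `r_p` over plexes where the feature is observed in a
#' reference. After correction, reference means agree across plexes for each
#' feature. Features absent from all references of a plex have that plex's
#' values set to missing (conservative: not guessed).
#'
#' @param m An `omics_matrix` on the raw intensity scale containing both
#'   tumor and pooled-reference channels.
#' @param samples A `sample_table` covering the matrix's samples with
#'   `plex_id` and `is_pooled_reference`.
#' @return List with `matrix` (corrected `omics_matrix`) and `factors`
#'   (feature-by-plex scale matrix).
#' @export
irs_correct <- function(m, samples) {
  if (m$scale_tag != "raw_intensity") {
    stop("IRS operates on raw intensities", call. = FALSE)
  }
  idx <- match(sample_ids(m), samples$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         sample_ids(m)[is.na(idx)][1], call. = FALSE)
  }
  plex <- samples$plex_id[idx]
  is_ref <- samples$is_pooled_reference[idx]
  plexes <- unique(plex)
  for (pl in plexes) {
    if (!any(is_ref & plex == pl)) {
      stop("plex without pooled-reference channel: ", pl, call. = FALSE)
    }
  }
  ref_means <- vapply(plexes, function(pl) {
    rowMeans(m$values[, is_ref & plex == pl, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m$values)))
  ref_means <- matrix(ref_means, nrow = nrow(m$values))
  ref_means[is.nan(ref_means) | ref_means <= 0] <- NA
  g <- exp(rowMeans(log(ref_means), na.rm = TRUE))
  fac <- g / ref_means                         # feature x plex; NA where no reference
  colnames(fac) <- plexes
  out <- m$values
  for (j in seq_along(plexes)) {
    cols <- which(plex == plexes[j])
    out[, cols] <- out[, cols, drop = FALSE] * fac[, j]
  }
  list(matrix = omics_matrix(out, m$scale_tag, m$feature_kind), factors = fac)
}

#' Trimmed mean of M-values normalization
#'
#' Computes per-sample scale factors against a reference column (the column
#' whose total is closest to the mean total): log2 ratios (M) are trimmed by
#' `logratio_trim` on each tail and mean intensities (A) by `sum_trim` on
#' each tail; the factor is `2^mean(M)` over the doubly-trimmed features,
#' rescaled so factors have geometric mean 1. Columns are divided by their
#' factors.
#'
#' @param m An `omics_matrix` with positive raw intensities (missing allowed;
#'   only jointly observed features enter each comparison).
#' @param logratio_trim Tail fraction trimmed on M; default 0.30.
#' @param sum_trim Tail fraction trimmed on A; default 0.05.
#' @return List with `matrix` (normalized `omics_matrix`), `factors`
#'   (per-sample divisors) and `ref_sample`.
#' @export
tmm_normalize <- function(m, logratio_trim = 0.30, sum_trim = 0.05) {
  if (m$scale_tag != "raw_intensity") {
    stop("TMM operates on raw intensities", call. = FALSE)
  }
  if (any(m$values <= 0, na.rm = TRUE)) {
    stop("TMM requires positive values", call. = FALSE)
  }
  x <- m$values
  sums <- colSums(x, na.rm = TRUE)
  ref <- which.min(abs(sums - mean(sums)))
  factors <- vapply(seq_len(ncol(x)), function(j) {
    tmm_factor(x[, j], x[, ref], logratio_trim, sum_trim)
  }, 0)
  factors <- factors / geometric_mean(factors)
  out <- sweep(x, 2, factors, `/`)
  list(matrix = omics_matrix(out, m$scale_tag, m$feature_kind),
       factors = stats::setNames(factors, colnames(x)),
       ref_sample = colnames(x)[ref])
}

tmm_factor <- function(obs, ref, logratio_trim, sum_trim) {
  keep <- !is.na(obs) & !is.na(ref)
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2(obs / ref)
  A <- 0.5 * log2(obs * ref)
  finite <- is.finite(M) & is.finite(A)
  M <- M[finite]; A <- A[finite]
  if (!length(M)) return(1)
  if (max(M) - min(M) < 1e-10) return(2^mean(M))  # constant ratio: trim vacuous
  loM <- stats::quantile(M, logratio_trim); hiM <- stats::quantile(M, 1 - logratio_trim)
  loA <- stats::quantile(A, sum_trim); hiA <- stats::quantile(A, 1 - sum_trim)
  keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
  if (!any(keep2)) return(2^mean(M))
  2^mean(M[keep2])
}

#' Welch-t differential abundance between two sample groups
#'
#' Per feature: `log2FC = mean(group_a) - mean(group_b)`, Welch's two-sample
#' t-test p-value, Benjamini-Hochberg q over all tested features. Stands in
#' for count-model differential expression, which does not transfer to TMT
#' log intensities.
#'
#' @param m An `omics_matrix` on the log2 scale.
#' @param group_a,group_b Character vectors of sample IDs, each of size >= 2.
#' @return Data frame with columns `feature`, `log2fc`, `t`, `p`, `q`.
#' @export
differential_abundance <- function(m, group_a, group_b) {
  if (m$scale_tag != "log2") stop("differential abundance expects log2 data",
                                  call. = FALSE)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  xa <- m$values[, group_a, drop = FALSE]
  xb <- m$values[, group_b, drop = FALSE]
  na_ <- rowSums(!is.na(xa)); nb_ <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- apply(xa, 1, stats::var, na.rm = TRUE)
  vb <- apply(xb, 1, stats::var, na.rm = TRUE)
  se2 <- va / na_ + vb / nb_
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.na(p) & se2 == 0] <- 1   # constant-difference features carry no evidence
  data.frame(feature = feature_ids(m), log2fc = ma - mb, t = tstat, p = p,
             q = stats::p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the full TMT preprocessing chain
#'
#' Fixed stage order: missingness filter, log2 + KNN imputation, sample
#' loading normalization, internal reference scaling, TMM. Returns log2 data
#' with pooled-reference channels retained (drop them with [subset_omics()]
#' for downstream analysis) and a per-stage report.
#'
#' @param m Raw-intensity `omics_matrix` with tumor and reference channels.
#' @param samples A `sample_table`.
#' @param min_valid_frac Passed to [filter_missing()].
#' @param knn_k Passed to [knn_impute()].
#' @return List with `matrix` (log2 `omics_matrix`) and `report`
#'   (stage-by-stage feature/sample counts and normalization factors).
#' @export
normalize_tmt <- function(m, samples, min_valid_frac = 0.30, knn_k = 10) {
  report <- list(input = dim(m$values),
                 params = list(min_valid_frac = min_valid_frac, knn_k = knn_k))
  f <- filter_missing(m, min_valid_frac)
  report$after_filter <- dim(f$values)
  imp <- knn_impute(to_log2(f), k = knn_k)
  sl <- sample_loading_normalize(to_intensity(imp))
  report$sl_factors <- sl$factors
  irs <- irs_correct(sl$matrix, samples)
  report$irs_factors <- irs$factors
  tmm <- tmm_normalize(irs$matrix)
  report$tmm_factors <- tmm$factors
  report$tmm_ref <- tmm$ref_sample
  list(matrix = to_log2(tmm$matrix), report = report)
}
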