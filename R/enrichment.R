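# Single-sample GSEA, preranked GSEA, and hypergeometric over-representation,
# sharing one rank-weighted running-sum engine. The same engine serves
# pathway scores, immune/stemness/cell-cycle signatures, and site-centric
# PTM signatures (via expand_sites in the kinase module).

# Weighted running-enrichment statistic for one ordered profile.
# `values` are sorted decreasing; in-set steps are |value|^weight normalized
# to sum 1, out-of-set steps are uniform decrements. Returns the full running
# series, its signed sum ("area under RES") and the max-deviation ES.
running_enrichment <- function(values, in_set, weight) {
  n <- length(values)
  w <- abs(values)^weight
  w_in <- sum(w[in_set])
  n_out <- n - sum(in_set)
  step <- ifelse(in_set,
                 if (w_in > 0) w / w_in else 0,
                 -1 / n_out)
  res <- cumsum(step)
  list(res = res, area = sum(res), es = res[which.max(abs(res))])
}

#' Single-sample GSEA scores
#'
#' Per sample, features are ranked by (optionally log-transformed) abundance
#' and each gene set is scored by the area under the weighted running
#' enrichment curve, with in-set increments weighted by `|rank value|^weight`
#' and out-of-set decrements uniform. Default parameters: `weight = 0.75`,
#' `min_overlap = 3`, per-set z-scoring across samples (the normalized
#' enrichment score), and a log transform for raw-intensity inputs.
#'
#' @param m A complete (imputed) `omics_matrix`.
#' @param sets A `gene_set_collection`.
#' @param weight Rank-weight exponent; default 0.75.
#' @param min_overlap Minimum features shared between a set and the matrix;
#'   smaller sets are omitted with a warning. Default 3.
#' @param norm `"z_score"` (per-set across samples) or `"none"`.
#' @param sample_norm `"log"` (log-transform raw intensities; log2 inputs
#'   pass through) or `"none"`.
#' @return set-by-sample numeric score matrix.
#' @export
ssgsea_scores <- function(m, sets, weight = 0.75, min_overlap = 3,
                          norm = c("z_score", "none"),
                          sample_norm = c("log", "none")) {
  norm <- match.arg(norm)
  sample_norm <- match.arg(sample_norm)
  x <- m$values
  if (anyNA(x)) {
    all_missing <- colSums(!is.na(x)) == 0
    if (any(all_missing)) {
      stop("sample with no observed values: ",
           colnames(x)[all_missing][1], call. = FALSE)
    }
    stop("ssGSEA requires a complete matrix; impute first", call. = FALSE)
  }
  if (sample_norm == "log" && m$scale_tag == "raw_intensity") {
    x <- log2(x + 1)
  }
  feats <- rownames(x)
  overlaps <- lapply(sets$sets, function(s) intersect(s, feats))
  keep <- lengths(overlaps) >= min_overlap
  if (any(!keep)) {
    warning(sprintf("%d set(s) below min_overlap = %d omitted: %s",
                    sum(!keep), min_overlap,
                    paste(utils::head(names(overlaps)[!keep], 5), collapse = ", ")))
  }
  overlaps <- overlaps[keep]
  scores <- matrix(NA_real_, length(overlaps), ncol(x),
                   dimnames = list(names(overlaps), colnames(x)))
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j], decreasing = TRUE)
    v <- x[ord, j]
    fo <- feats[ord]
    for (i in seq_along(overlaps)) {
      in_set <- fo %in% overlaps[[i]]
      scores[i, j] <- running_enrichment(v, in_set, weight)$area
    }
  }
  if (norm == "z_score" && ncol(scores) > 1) {
    mu <- rowMeans(scores)
    sd_ <- apply(scores, 1, stats::sd)
    sd_[sd_ == 0] <- 1  # degenerate sets (no contrast across samples) stay 0
    scores <- (scores - mu) / sd_
  }
  scores
}

#' Preranked gene set enrichment
#'
#' Classic weighted Kolmogorov-Smirnov enrichment on a ranked feature list
#' (e.g., fold changes between groups): ES is the maximum deviation of the
#' running sum; p-values come from feature-label permutations, NES divides
#' ES by the mean |ES| of same-sign permutations, and q is BH across sets.
#'
#' @param ranked Named numeric vector (feature -> ranking statistic); no
#'   duplicate names, finite values.
#' @param sets A `gene_set_collection`.
#' @param weight Rank-weight exponent; default 1.
#' @param n_perm Number of permutations; default 1000.
#' @param min_overlap Sets with smaller overlap are omitted.
#' @param seed Integer seed for the permutations.
#' @return Data frame with `set_name`, `es`, `nes`, `p`, `q`, `n_overlap`,
#'   `direction`.
#' @export
preranked_gsea <- function(ranked, sets, weight = 1, n_perm = 1000,
                           min_overlap = 3, seed = 1L) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked))) {
    stop("`ranked` must be a named vector without duplicates", call. = FALSE)
  }
  if (any(!is.finite(ranked))) stop("ranks must be finite", call. = FALSE)
  ord <- order(ranked, decreasing = TRUE)
  v <- ranked[ord]
  feats <- names(v)
  overlaps <- lapply(sets$sets, function(s) intersect(s, feats))
  keep <- lengths(overlaps) >= min_overlap
  overlaps <- overlaps[keep]
  if (!length(overlaps)) {
    return(data.frame(set_name = character(), es = numeric(), nes = numeric(),
                      p = numeric(), q = numeric(), n_overlap = integer(),
                      direction = integer()))
  }
  es <- vapply(overlaps, function(ov) {
    running_enrichment(v, feats %in% ov, weight)$es
  }, 0)
  set.seed(seed)
  sizes <- sort(unique(lengths(overlaps)))
  perm_es <- matrix(NA_real_, n_perm, length(sizes),
                    dimnames = list(NULL, sizes))
  for (b in seq_len(n_perm)) {
    for (sz in sizes) {
      in_set <- logical(length(v))
      in_set[sample(length(v), sz)] <- TRUE
      perm_es[b, as.character(sz)] <- running_enrichment(v, in_set, weight)$es
    }
  }
  p <- nes <- numeric(length(es))
  for (i in seq_along(es)) {
    pe <- perm_es[, as.character(length(overlaps[[i]]))]
    same <- pe[sign(pe) == sign(es[i])]
    if (!length(same)) same <- abs(pe)
    p[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
    nes[i] <- es[i] / mean(abs(same))
  }
  data.frame(set_name = names(overlaps), es = es, nes = nes, p = p,
             q = stats::p.adjust(p, "BH"), n_overlap = lengths(overlaps),
             direction = sign(es), row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Per set: upper-tail hypergeometric probability of observing at least the
#' actual overlap between the hit list and the set within the universe;
#' Benjamini-Hochberg q across sets.
#'
#' @param hits Character vector of features of interest (must lie within
#'   `universe`).
#' @param universe Character vector: the background.
#' @param sets A `gene_set_collection` (members outside the universe are
#'   ignored).
#' @return Data frame with `set_name`, `n_set`, `n_overlap`, `expected`,
#'   `p`, `q`.
#' @export
ora_test <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  stray <- setdiff(hits, universe)
  if (length(stray)) {
    stop("hits outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    ov <- length(intersect(members, hits))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, n_set = K, n_overlap = ov,
               expected = n * K / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}
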