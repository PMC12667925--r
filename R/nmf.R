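# Consensus NMF subtype discovery: top-MAD feature selection on the merged
# proteome + phosphoproteome matrix, Frobenius NMF with many random restarts,
# consensus co-clustering, and cophenetic/silhouette rank selection.

#' Build the non-negative NMF input from protein and phosphosite matrices
#'
#' Row-concatenates the two log2 matrices (features prefixed `prot|` /
#' `phos|`), keeps the `top_n` rows with the highest mean absolute deviation,
#' median-centers each retained row, and splits it into its positive and
#' negative parts (two non-negative rows), the standard device for running
#' NMF on signed log-scale data. `(pos - neg)` reconstructs the centered
#' input exactly.
#'
#' @param protein,phospho Normalized log2 `omics_matrix` objects over the
#'   same sample set (either may be `NULL` to use one layer only).
#' @param top_n Number of rows retained by MAD ranking; clamped with a
#'   warning when fewer rows are available.
#' @return Non-negative numeric matrix with `2 * top_n` rows.
#' @export
prepare_nmf_input <- function(protein, phospho = NULL, top_n = 500) {
  if (top_n < 2) stop("top_n must be >= 2", call. = FALSE)
  parts <- list()
  if (!is.null(protein)) {
    stopifnot(protein$scale_tag == "log2")
    v <- protein$values
    rownames(v) <- paste0("prot|", rownames(v))
    parts$prot <- v
  }
  if (!is.null(phospho)) {
    stopifnot(phospho$scale_tag == "log2")
    v <- phospho$values
    rownames(v) <- paste0("phos|", rownames(v))
    parts$phos <- v
  }
  if (!length(parts)) stop("no input matrices", call. = FALSE)
  if (length(parts) == 2 &&
      !setequal(colnames(parts[[1]]), colnames(parts[[2]]))) {
    stop("protein and phospho matrices cover different sample sets",
         call. = FALSE)
  }
  if (length(parts) == 2) parts[[2]] <- parts[[2]][, colnames(parts[[1]]), drop = FALSE]
  merged <- do.call(rbind, parts)
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  mads <- apply(merged, 1, mean_abs_deviation)
  keep <- order(mads, decreasing = TRUE)
  keep <- keep[mads[keep] > 0]
  if (length(keep) < top_n) {
    warning(sprintf("only %d variable features available (top_n = %d)",
                    length(keep), top_n))
    top_n <- length(keep)
  }
  sel <- merged[keep[seq_len(top_n)], , drop = FALSE]
  centered <- sel - apply(sel, 1, stats::median)
  pos <- pmax(centered, 0)
  neg <- pmax(-centered, 0)
  rownames(pos) <- paste0(rownames(sel), "+")
  rownames(neg) <- paste0(rownames(sel), "-")
  rbind(pos, neg)
}

#' Frobenius NMF by multiplicative updates
#'
#' Minimizes `||V - WH||_F` with Lee-Seung multiplicative updates from a
#' random uniform initialization; the objective trace is non-increasing.
#'
#' @param V Non-negative numeric matrix.
#' @param k Factorization rank, `2 <= k < min(dim(V))` (rank 1 allowed for
#'   exact low-rank checks).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum update sweeps; default 2000.
#' @param tol Relative objective-change stopping tolerance; default 1e-6.
#' @return List of class `nmf_fit`: `W`, `H`, `objective_trace`,
#'   `iterations`, `seed`.
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000, tol = 1e-6) {
  if (any(V < 0)) stop("V must be non-negative", call. = FALSE)
  if (k < 1 || k >= min(dim(V))) stop("invalid rank k", call. = FALSE)
  set.seed(seed)
  W <- matrix(stats::runif(nrow(V) * k), nrow(V), k)
  H <- matrix(stats::runif(k * ncol(V)), k, ncol(V))
  fit <- .nmf_mu_cpp(V, W, H, as.integer(max_iter), tol, TRUE)
  colnames(fit$H) <- colnames(V)
  structure(list(W = fit$W, H = fit$H, objective_trace = fit$trace,
                 iterations = fit$iterations, seed = seed),
            class = "nmf_fit")
}

#' Consensus clustering over NMF restarts
#'
#' Runs `n_init` random-restart factorizations, assigns each sample to its
#' argmax H row, and averages the co-clustering indicators into a consensus
#' matrix. Final labels cut an average-linkage dendrogram of `1 - consensus`
#' into `k` groups; the cophenetic correlation compares consensus distances
#' with dendrogram cophenetic distances, and the silhouette uses the same
#' `1 - consensus` dissimilarity.
#'
#' @param V Non-negative matrix (see [prepare_nmf_input()]).
#' @param k Rank / number of clusters.
#' @param n_init Number of random restarts; default 1000 (use fewer for
#'   exploratory runs).
#' @param seed Integer seed.
#' @param max_iter,tol Per-restart update budget; restarts only need a
#'   stable argmax, not full convergence.
#' @return List of class `consensus_result`: `k`, `consensus`, `labels`,
#'   `cophenetic`, `mean_silhouette`, `n_init`, `degenerate`.
#' @export
consensus_cluster <- function(V, k, n_init = 1000, seed = 1L,
                              max_iter = 200, tol = 1e-4) {
  if (n_init < 1) stop("n_init must be >= 1", call. = FALSE)
  n <- ncol(V)
  if (k >= n) stop("k must be below the number of samples", call. = FALSE)
  set.seed(seed)
  inits <- lapply(seq_len(n_init), function(i) {
    list(W = matrix(stats::runif(nrow(V) * k), nrow(V), k),
         H = matrix(stats::runif(k * n), k, n))
  })
  consensus <- .nmf_consensus_cpp(V, inits, as.integer(max_iter), tol)
  dimnames(consensus) <- list(colnames(V), colnames(V))
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  coph_d <- stats::cophenetic(hc)
  degenerate <- stats::sd(d) == 0
  coph <- if (degenerate) NA_real_ else stats::cor(d, coph_d)
  sil <- if (degenerate || length(unique(labels)) < 2) {
    NA_real_
  } else {
    mean(cluster::silhouette(labels, dmatrix = 1 - consensus)[, "sil_width"])
  }
  structure(list(k = k, consensus = consensus, labels = labels,
                 cophenetic = coph, mean_silhouette = sil, n_init = n_init,
                 degenerate = degenerate),
            class = "consensus_result")
}

#' Survey factorization ranks
#'
#' Runs [consensus_cluster()] for each rank in `k_range` and tabulates the
#' cophenetic correlation and mean silhouette per rank — the two
#' reproducibility metrics used to pick the cluster number.
#'
#' @param V Non-negative matrix.
#' @param k_range Integer vector of ranks; default `2:7`.
#' @param n_init,seed,max_iter,tol Passed to [consensus_cluster()].
#' @return List of class `rank_survey`: `table` (data frame of k,
#'   cophenetic, mean_silhouette, min_class_size, degenerate) and `results`
#'   (the per-k `consensus_result`s).
#' @export
rank_survey <- function(V, k_range = 2:7, n_init = 200, seed = 1L,
                        max_iter = 200, tol = 1e-4) {
  if (!length(k_range)) stop("empty k_range", call. = FALSE)
  results <- lapply(k_range, function(k) {
    consensus_cluster(V, k, n_init = n_init, seed = seed + k,
                      max_iter = max_iter, tol = tol)
  })
  tab <- data.frame(
    k = k_range,
    cophenetic = vapply(results, `[[`, 0, "cophenetic"),
    mean_silhouette = vapply(results, `[[`, 0, "mean_silhouette"),
    min_class_size = vapply(results, function(r) min(table(r$labels)), 0),
    degenerate = vapply(results, `[[`, TRUE, "degenerate"))
  structure(list(table = tab, results = stats::setNames(results, k_range)),
            class = "rank_survey")
}

#' Choose the cluster number and assign subtype labels
#'
#' Default rule: candidate k's have a cophenetic correlation within
#' `drop_tol` of the maximum over the surveyed range and a smallest class of
#' at least `min_class` samples; among those, k's whose mean silhouette falls
#' more than `sil_tol` below the candidates' best silhouette are discarded
#' (both reproducibility metrics back the choice, as when a cophenetic
#' plateau would otherwise push k past the stable solution); the chosen k is
#' the largest survivor. `k_override` bypasses the rule. Labels are
#' relabeled by decreasing class size (P1 largest) — names are nominal,
#' never ordered quantities.
#'
#' @param survey A `rank_survey`.
#' @param k_override Optional fixed k.
#' @param drop_tol Cophenetic tolerance below the max; default 0.05.
#' @param min_class Minimum class size; default 5.
#' @param sil_tol Silhouette tolerance below the candidates' best; default 0.1.
#' @return List with `chosen_k`, `labels` (named character vector `P1..Pk`)
#'   and `rule` (how k was chosen).
#' @export
assign_subtypes <- function(survey, k_override = NULL, drop_tol = 0.05,
                            min_class = 5, sil_tol = 0.1) {
  tab <- survey$table
  if (!nrow(tab)) stop("empty survey", call. = FALSE)
  if (!is.null(k_override)) {
    if (!k_override %in% tab$k) stop("k_override not in surveyed range", call. = FALSE)
    chosen <- k_override
    rule <- "override"
  } else {
    best <- max(tab$cophenetic, na.rm = TRUE)
    ok <- !is.na(tab$cophenetic) & tab$cophenetic >= best - drop_tol &
      tab$min_class_size >= min_class
    if (!any(ok)) {
      stop("no k satisfies min_class = ", min_class,
           "; consider k_override or a smaller min_class", call. = FALSE)
    }
    sil <- tab$mean_silhouette
    if (any(ok & !is.na(sil))) {
      best_sil <- max(sil[ok], na.rm = TRUE)
      ok <- ok & !is.na(sil) & sil >= best_sil - sil_tol
    }
    chosen <- max(tab$k[ok])
    rule <- "cophenetic_silhouette"
  }
  res <- survey$results[[as.character(chosen)]]
  sizes <- sort(table(res$labels), decreasing = TRUE)
  remap <- stats::setNames(sprintf("P%d", seq_along(sizes)), names(sizes))
  labels <- remap[as.character(res$labels)]
  names(labels) <- names(res$labels)
  list(chosen_k = chosen, labels = labels, rule = rule)
}
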