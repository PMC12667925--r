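# Kinase activity inference from phosphosite fold changes: site-centric
# expansion of multi-site features and a substrate-set z-score against the
# global site fold-change distribution (KSEA-style).

#' Expand multi-site phosphosite rows into single-site entities
#'
#' Feature IDs encode protein plus site list, e.g. `P12345_S10;T14`. Rows
#' carrying several sites are duplicated to one row per (protein, site) with
#' identical values; collisions with an existing single-site row are
#' averaged (with a message).
#'
#' @param phospho An `omics_matrix` with `feature_kind = "phosphosite"`.
#' @return A site-centric `omics_matrix`.
#' @export
expand_sites <- function(phospho) {
  ids <- feature_ids(phospho)
  us <- regexpr("_", ids, fixed = TRUE)
  if (any(us < 0)) {
    stop("unparseable phosphosite ID (no protein_site separator): ",
         ids[us < 0][1], call. = FALSE)
  }
  prot <- substr(ids, 1, us - 1)
  sites <- strsplit(substring(ids, us + 1), ";", fixed = TRUE)
  bad <- vapply(sites, function(s) length(s) == 0 ||
                  any(!grepl("^[A-Z][0-9]+[a-z0-9]*$", s)), TRUE)
  if (any(bad)) {
    stop("unparseable site annotation in feature ID: ", ids[bad][1],
         call. = FALSE)
  }
  n_rep <- lengths(sites)
  new_ids <- paste(rep(prot, n_rep), unlist(sites), sep = "_")
  vals <- phospho$values[rep(seq_along(ids), n_rep), , drop = FALSE]
  rownames(vals) <- new_ids
  if (anyDuplicated(new_ids)) {
    message("averaging ", sum(duplicated(new_ids)),
            " duplicated site entities after expansion")
    grp <- factor(new_ids, levels = unique(new_ids))
    vals <- apply(vals, 2, function(col) tapply(col, grp, mean, na.rm = TRUE))
    vals[is.nan(vals)] <- NA
    rownames(vals) <- levels(grp)
  }
  omics_matrix(vals, phospho$scale_tag, "phosphosite")
}

#' Kinase activity scores from substrate-site fold changes
#'
#' For each kinase with at least `min_sites` annotated substrate sites
#' present in the fold-change profile:
#' `z = (mean substrate FC - mean of all site FCs) * sqrt(m) / SD of all
#' site FCs`, with a two-sided normal p-value and BH q across kinases.
#' Duplicate (kinase, substrate, site) annotations are deduplicated on load;
#' negating all fold changes negates every z exactly.
#'
#' @param site_fc Named numeric vector: site ID -> log2 fold change.
#' @param ks A `kinase_substrate_map`.
#' @param min_sites Minimum substrate sites per reported kinase; default 3.
#' @return Data frame with `kinase_id`, `z`, `n_substrate_sites`,
#'   `mean_site_fc`, `p`, `q`, sorted by decreasing |z|.
#' @export
kinase_scores <- function(site_fc, ks, min_sites = 3) {
  if (is.null(names(site_fc))) stop("site_fc must be named", call. = FALSE)
  if (any(!is.finite(site_fc))) stop("fold changes must be finite", call. = FALSE)
  ks <- ks[ks$site %in% names(site_fc), , drop = FALSE]
  if (!nrow(ks)) {
    stop("no overlap between kinase-substrate map and fold-change profile",
         call. = FALSE)
  }
  mu <- mean(site_fc)
  sd_all <- stats::sd(site_fc)
  rows <- lapply(split(ks$site, ks$kinase), function(sites) {
    sites <- unique(sites)
    m <- length(sites)
    if (m < min_sites) return(NULL)
    msub <- mean(site_fc[sites])
    z <- if (sd_all == 0) 0 else (msub - mu) * sqrt(m) / sd_all
    data.frame(n_substrate_sites = m, mean_site_fc = msub, z = z)
  })
  keep <- !vapply(rows, is.null, TRUE)
  if (!any(keep)) {
    return(data.frame(kinase_id = character(), z = numeric(),
                      n_substrate_sites = integer(), mean_site_fc = numeric(),
                      p = numeric(), q = numeric()))
  }
  out <- do.call(rbind, rows[keep])
  out <- data.frame(kinase_id = names(rows)[keep], out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$q <- stats::p.adjust(out$p, "BH")
  out[order(-abs(out$z)), c("kinase_id", "z", "n_substrate_sites",
                            "mean_site_fc", "p", "q")]
}
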