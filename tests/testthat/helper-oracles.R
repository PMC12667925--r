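# Independent naive oracles: plain scans over expanded per-base-ish runs,
# written without reusing any package internals.

# expand a sample's segments into per-chromosome ordered lists
.orc_by_chrom <- function(p) {
  lapply(split(p, p$chrom, drop = TRUE), function(d) d[order(d$start), ])
}

orc_merge_runs <- function(df, state_of) {
  # scan segments in order, building maximal runs of touching equal-state pieces
  runs <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    st <- state_of(df[i, ])
    if (!is.null(cur) && cur$end == df$start[i] && identical(cur$state, st)) {
      cur$end <- df$end[i]
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- list(start = df$start[i], end = df$end[i], state = st)
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

orc_ploidy_wgd <- function(p, genome) {
  auto <- genome$chrom[genome$is_autosome]
  p <- p[p$chrom %in% auto, ]
  num <- 0; den <- 0; major2 <- 0
  for (i in seq_len(nrow(p))) {
    l <- p$end[i] - p$start[i]
    num <- num + l * p$total_cn[i]
    den <- den + l
    if (p$major_cn[i] >= 2) major2 <- major2 + l
  }
  glen <- sum(as.numeric(genome$length[genome$is_autosome]))
  list(ploidy = num / den, wgd = major2 / glen > 0.5)
}

orc_cin <- function(p, genome) {
  auto <- genome$chrom[genome$is_autosome]
  p <- p[p$chrom %in% auto, ]
  g <- l <- h <- 0
  for (chrom_df in .orc_by_chrom(p)) {
    runs <- orc_merge_runs(chrom_df, function(r) c(r$total_cn, r$major_cn, r$minor_cn))
    for (r in runs) {
      if (r$state[1] > 2) g <- g + 1
      if (r$state[1] < 2) l <- l + 1
      if (r$state[3] == 0 && r$state[1] >= 1) h <- h + 1
    }
  }
  list(n_gain = g, n_loss = l, n_loh_segments = h, cin = g + l + h)
}

orc_hrd_loh <- function(p, genome, min_len = 15e6) {
  auto <- genome$chrom[genome$is_autosome]
  p <- p[p$chrom %in% auto, ]
  count <- 0
  for (chrom in unique(p$chrom)) {
    df <- p[p$chrom == chrom, ]
    df <- df[order(df$start), ]
    clen <- genome$length[genome$chrom == chrom]
    runs <- orc_merge_runs(df, function(r) r$minor_cn == 0 && r$total_cn >= 1)
    for (r in runs) {
      if (isTRUE(r$state) && (r$end - r$start) > min_len &&
          !(r$start <= 0 && r$end >= clen)) {
        count <- count + 1
      }
    }
  }
  count
}

orc_lst <- function(p, genome, min_seg = 10e6, max_gap = 3e6, smooth = 3e6) {
  auto <- genome[genome$is_autosome, ]
  count <- 0
  for (ci in seq_len(nrow(auto))) {
    for (arm in list(c(0, auto$cen_start[ci]), c(auto$cen_end[ci], auto$length[ci]))) {
      df <- p[p$chrom == auto$chrom[ci] & p$end > arm[1] & p$start < arm[2], ]
      if (!nrow(df)) next
      df$start <- pmax(df$start, arm[1]); df$end <- pmin(df$end, arm[2])
      df <- df[order(df$start), ]
      runs <- orc_merge_runs(df, function(r) r$total_cn)
      # smoothing: repeatedly remove the first short run, rejoin equal flanks
      repeat {
        short <- which(vapply(runs, function(r) r$end - r$start < smooth, TRUE))
        if (!length(short)) break
        runs <- runs[-short[1]]
        j <- 1
        while (j < length(runs)) {
          if (identical(runs[[j]]$state, runs[[j + 1]]$state)) {
            runs[[j]]$end <- runs[[j + 1]]$end
            runs <- runs[-(j + 1)]
          } else j <- j + 1
        }
      }
      if (length(runs) < 2) next
      for (j in seq_len(length(runs) - 1)) {
        a <- runs[[j]]; b <- runs[[j + 1]]
        if (!identical(a$state, b$state) &&
            (a$end - a$start) >= min_seg && (b$end - b$start) >= min_seg &&
            (b$start - a$end) <= max_gap) {
          count <- count + 1
        }
      }
    }
  }
  count
}

orc_tai <- function(p, genome, min_len = 0) {
  auto <- genome[genome$is_autosome, ]
  count <- 0
  for (ci in seq_len(nrow(auto))) {
    df <- p[p$chrom == auto$chrom[ci], ]
    if (!nrow(df)) next
    df <- df[order(df$start), ]
    clen <- auto$length[ci]
    runs <- orc_merge_runs(df, function(r) r$major_cn != r$minor_cn)
    for (r in runs) {
      if (!isTRUE(r$state)) next
      touches <- r$start <= 0 || r$end >= clen
      whole <- r$start <= 0 && r$end >= clen
      crosses <- r$start < auto$cen_start[ci] && r$end > auto$cen_end[ci]
      if (touches && !whole && !crosses && (r$end - r$start) > min_len) {
        count <- count + 1
      }
    }
  }
  count
}

# ---------------------------------------------------------------------------

# brute-force weighted running sum for ssGSEA (area statistic)
orc_ssgsea_area <- function(values, set_members, weight) {
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  nm <- names(values)[ord]
  hit <- nm %in% set_members
  wsum <- sum(abs(v[hit])^weight)
  miss_n <- sum(!hit)
  running <- 0
  area <- 0
  for (i in seq_along(v)) {
    if (hit[i]) running <- running + abs(v[i])^weight / wsum
    else running <- running - 1 / miss_n
    area <- area + running
  }
  unname(area)
}

# brute-force preranked ES (max deviation)
orc_gsea_es <- function(values, set_members, weight) {
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  nm <- names(values)[ord]
  hit <- nm %in% set_members
  wsum <- sum(abs(v[hit])^weight)
  miss_n <- sum(!hit)
  running <- 0
  best <- 0
  for (i in seq_along(v)) {
    if (hit[i]) running <- running + abs(v[i])^weight / wsum
    else running <- running - 1 / miss_n
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}

# exhaustive nearest-neighbor imputation on a small matrix
orc_knn_impute <- function(x, k) {
  out <- x
  for (i in seq_len(nrow(x))) {
    for (s in which(is.na(x[i, ]))) {
      d <- rep(Inf, nrow(x))
      for (j in seq_len(nrow(x))) {
        if (j == i) next
        shared <- which(!is.na(x[i, ]) & !is.na(x[j, ]))
        if (!length(shared)) next
        d[j] <- sqrt(mean((x[i, shared] - x[j, shared])^2))
      }
      cand <- order(d)
      cand <- cand[is.finite(d[cand]) & !is.na(x[cand, s])]
      if (length(cand)) {
        out[i, s] <- mean(x[cand[seq_len(min(k, length(cand)))], s])
      } else {
        out[i, s] <- mean(x[i, ], na.rm = TRUE)
      }
    }
  }
  out
}

# plain-loop trimmed mean of M-values factor
orc_tmm_factors <- function(x, logratio_trim = 0.30, sum_trim = 0.05) {
  sums <- colSums(x, na.rm = TRUE)
  ref <- which.min(abs(sums - mean(sums)))
  f <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j]) & !is.na(x[, ref])
    M <- log2(x[ok, j] / x[ok, ref])
    A <- 0.5 * log2(x[ok, j] * x[ok, ref])
    if (max(M) - min(M) < 1e-10) { f[j] <- 2^mean(M); next }
    keep <- M >= quantile(M, logratio_trim) & M <= quantile(M, 1 - logratio_trim) &
      A >= quantile(A, sum_trim) & A <= quantile(A, 1 - sum_trim)
    f[j] <- 2^mean(M[keep])
  }
  f / exp(mean(log(f)))
}
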