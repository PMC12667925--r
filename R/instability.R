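# Allele-specific copy-number instability scoring.
#
# All scores operate on merged segments: adjacent touching segments with the
# same (total, major, minor) state are one segment. Sex chromosomes are
# excluded by default; the whole-genome-doubling rule is defined on the
# autosomal genome and the other scores follow it for consistency.

#' Extract one sample's segments
#'
#' @param segs A `segment_profiles` data frame.
#' @param sample_id Sample to extract.
#' @return Data frame of that sample's segments, ordered by chrom/start.
#' @export
sample_segments <- function(segs, sample_id) {
  out <- as.data.frame(segs)[segs$sample == sample_id, , drop = FALSE]
  if (!nrow(out)) stop("no segments for sample ", sample_id, call. = FALSE)
  out[order(out$chrom, out$start), ]
}

# Merge adjacent touching segments with identical state. `state_cols` defines
# which columns constitute the state (total only for LST, all three else).
merge_adjacent <- function(df, state_cols = c("total_cn", "major_cn", "minor_cn")) {
  if (nrow(df) < 2) return(df)
  df <- df[order(df$chrom, df$start), ]
  key <- do.call(paste, c(df[state_cols], sep = "\r"))
  new_run <- c(TRUE, !(df$chrom[-1] == df$chrom[-nrow(df)] &
                         df$start[-1] == df$end[-nrow(df)] &
                         key[-1] == key[-nrow(df)]))
  run <- cumsum(new_run)
  out <- df[new_run, , drop = FALSE]
  out$end <- as.vector(tapply(df$end, factor(run, levels = unique(run)), max))
  rownames(out) <- NULL
  out
}

restrict_autosomes <- function(df, genome) {
  auto <- genome$chrom[genome$is_autosome]
  df[df$chrom %in% auto, , drop = FALSE]
}

#' Ploidy and whole-genome doubling call
#'
#' Ploidy is the segment-length-weighted mean total copy number over autosomal
#' segments. A tumor is called whole-genome doubled when more than 50% of the
#' autosomal genome carries a major copy number of 2 or more.
#'
#' @param p One sample's segments (data frame as from [sample_segments()]).
#' @param genome A `genome_build`.
#' @return List with `ploidy`, `wgd` (logical) and `coverage` (fraction of
#'   the autosomal genome covered by segments; should be at least 0.5 for the
#'   call to be meaningful — a warning is raised below that).
#' @export
ploidy_wgd <- function(p, genome) {
  p <- restrict_autosomes(p, genome)
  if (!nrow(p)) stop("no autosomal segments", call. = FALSE)
  len <- p$end - p$start
  auto_len <- sum(as.numeric(genome$length[genome$is_autosome]))
  coverage <- sum(len) / auto_len
  if (coverage < 0.5) {
    warning(sprintf("segments cover only %.1f%% of the autosomal genome",
                    100 * coverage))
  }
  list(ploidy = sum(len * p$total_cn) / sum(len),
       wgd = sum(len[p$major_cn >= 2]) / auto_len > 0.5,
       coverage = coverage)
}

#' Chromosomal instability score
#'
#' Counts, over merged autosomal segments: gains (total copy number > 2),
#' losses (total < 2), and LOH segments (minor copy number 0 with at least
#' one copy retained). `cin` is their sum; by default a segment contributes
#' to every category it satisfies (a single-copy LOH segment counts as both
#' a loss and an LOH event), switchable to exclusive counting.
#'
#' @param p One sample's segments.
#' @param genome A `genome_build` (for autosome restriction); `NULL` scores
#'   all chromosomes present.
#' @param exclusive If `TRUE`, each segment counts once with precedence
#'   gain > loss > loh.
#' @return List with `n_gain`, `n_loss`, `n_loh_segments`, `cin`.
#' @export
cin_score <- function(p, genome = NULL, exclusive = FALSE) {
  if (!is.null(genome)) p <- restrict_autosomes(p, genome)
  p <- merge_adjacent(p)
  gain <- p$total_cn > 2
  loss <- p$total_cn < 2
  loh <- p$minor_cn == 0 & p$total_cn >= 1
  if (exclusive) {
    loh <- loh & !gain & !loss
  }
  out <- list(n_gain = sum(gain), n_loss = sum(loss), n_loh_segments = sum(loh))
  out$cin <- out$n_gain + out$n_loss + out$n_loh_segments
  out
}

# Maximal runs of touching segments all satisfying `flag`; returns one row per
# run with chrom, start, end.
maximal_runs <- function(df, flag) {
  df <- df[flag, , drop = FALSE]
  if (!nrow(df)) return(df[c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start), ]
  new_run <- c(TRUE, !(df$chrom[-1] == df$chrom[-nrow(df)] &
                         df$start[-1] == df$end[-nrow(df)]))
  run <- cumsum(new_run)
  out <- df[new_run, c("chrom", "start", "end"), drop = FALSE]
  out$end <- as.vector(tapply(df$end, factor(run, levels = unique(run)), max))
  rownames(out) <- NULL
  out
}

#' HRD-LOH component: large interstitial LOH regions
#'
#' Counts maximal LOH runs (minor copy number 0, total at least 1) longer
#' than `min_len` that do not span an entire chromosome.
#'
#' @param p One sample's segments.
#' @param genome A `genome_build`.
#' @param min_len Minimum run length in bp; default 15 Mb (runs must exceed
#'   it strictly).
#' @return Integer count.
#' @export
hrd_loh_count <- function(p, genome, min_len = 15e6) {
  p <- restrict_autosomes(p, genome)
  p <- merge_adjacent(p)
  runs <- maximal_runs(p, p$minor_cn == 0 & p$total_cn >= 1)
  if (!nrow(runs)) return(0L)
  chrom_len <- genome$length[match(runs$chrom, genome$chrom)]
  whole <- runs$start <= 0 & runs$end >= chrom_len
  sum(runs$end - runs$start > min_len & !whole)
}

# Clip segments to an interval, dropping empties.
clip_to <- function(df, lo, hi) {
  df <- df[df$end > lo & df$start < hi, , drop = FALSE]
  if (nrow(df)) {
    df$start <- pmax(df$start, lo)
    df$end <- pmin(df$end, hi)
  }
  df
}

# Smooth an arm's total-copy-number runs: repeatedly drop runs shorter than
# smooth_len and re-merge flanking runs that share a total state (the dropped
# run becomes a gap, tracked so junction distances remain correct).
smooth_arm_runs <- function(runs, smooth_len) {
  repeat {
    if (nrow(runs) == 0) return(runs)
    short <- which(runs$end - runs$start < smooth_len)
    if (!length(short)) return(runs)
    runs <- runs[-short[1], , drop = FALSE]
    # re-merge same-state neighbors across any gap left behind
    if (nrow(runs) >= 2) {
      i <- 1
      while (i < nrow(runs)) {
        if (runs$total_cn[i] == runs$total_cn[i + 1]) {
          runs$end[i] <- runs$end[i + 1]
          runs <- runs[-(i + 1), , drop = FALSE]
        } else {
          i <- i + 1
        }
      }
    }
  }
}

#' LST component: large-scale state transitions
#'
#' Counts, per chromosome arm, junctions between consecutive segments of
#' differing total copy number where both flanking segments are at least
#' `min_seg` long and the distance between them is at most `max_gap`.
#' Segments shorter than `smooth_len` are removed first, with flanking
#' same-state segments re-merged (scar smoothing).
#'
#' @param p One sample's segments.
#' @param genome A `genome_build`.
#' @param min_seg Minimum flank length; default 10 Mb.
#' @param max_gap Maximum junction gap; default 3 Mb.
#' @param smooth_len Segments shorter than this are smoothed away; default 3 Mb.
#' @return Integer count.
#' @export
lst_count <- function(p, genome, min_seg = 10e6, max_gap = 3e6, smooth_len = 3e6) {
  arms <- genome_arms(genome)
  arms <- arms[arms$is_autosome, , drop = FALSE]
  p <- restrict_autosomes(p, genome)
  total <- 0L
  for (i in seq_len(nrow(arms))) {
    seg <- clip_to(p[p$chrom == arms$chrom[i], , drop = FALSE],
                   arms$start[i], arms$end[i])
    if (nrow(seg) < 2) next
    runs <- merge_adjacent(seg, state_cols = "total_cn")
    runs <- smooth_arm_runs(runs, smooth_len)
    if (nrow(runs) < 2) next
    for (j in seq_len(nrow(runs) - 1)) {
      gap <- runs$start[j + 1] - runs$end[j]
      if (runs$total_cn[j] != runs$total_cn[j + 1] &&
          runs$end[j] - runs$start[j] >= min_seg &&
          runs$end[j + 1] - runs$start[j + 1] >= min_seg &&
          gap <= max_gap) {
        total <- total + 1L
      }
    }
  }
  total
}

#' TAI component: telomeric allelic imbalance
#'
#' Counts maximal allelic-imbalance runs (major != minor copy number) that
#' touch a telomere (start at position 0 or end at the chromosome end), do
#' not cross the centromere (a run crosses only if it spans the whole
#' centromere interval; ending inside or exactly at its edge does not count
#' as crossing), do not span the entire chromosome, and are longer than
#' `min_len`.
#'
#' @param p One sample's segments.
#' @param genome A `genome_build`.
#' @param min_len Minimum run length in bp; default 0 (any length).
#' @return Integer count.
#' @export
tai_count <- function(p, genome, min_len = 0) {
  p <- restrict_autosomes(p, genome)
  p <- merge_adjacent(p)
  runs <- maximal_runs(p, p$major_cn != p$minor_cn)
  if (!nrow(runs)) return(0L)
  g <- genome[match(runs$chrom, genome$chrom), ]
  telomeric <- runs$start <= 0 | runs$end >= g$length
  whole <- runs$start <= 0 & runs$end >= g$length
  crosses_cen <- runs$start < g$cen_start & runs$end > g$cen_end
  sum(telomeric & !whole & !crosses_cen & runs$end - runs$start > min_len)
}

#' Full instability score panel for one sample
#'
#' Assembles ploidy, the whole-genome-doubling call, CIN components, and the
#' three homologous-recombination-deficiency scar components. The HRD score
#' is their plain sum: `hrd = hrd_loh + lst + tai`.
#'
#' @param p One sample's segments.
#' @param genome A `genome_build`.
#' @param ... Passed through to the component scorers
#'   ([hrd_loh_count()], [lst_count()], [tai_count()]).
#' @return One-row data frame with columns `ploidy`, `wgd`, `n_gain`,
#'   `n_loss`, `n_loh_segments`, `cin`, `hrd_loh`, `lst`, `tai`, `hrd`.
#' @export
hrd_score <- function(p, genome, ...) {
  pw <- ploidy_wgd(p, genome)
  cs <- cin_score(p, genome)
  hl <- hrd_loh_count(p, genome)
  ls <- lst_count(p, genome)
  ta <- tai_count(p, genome)
  data.frame(ploidy = pw$ploidy, wgd = pw$wgd,
             n_gain = cs$n_gain, n_loss = cs$n_loss,
             n_loh_segments = cs$n_loh_segments, cin = cs$cin,
             hrd_loh = hl, lst = ls, tai = ta, hrd = hl + ls + ta)
}

#' Instability scores for a whole cohort
#'
#' @param segs A `segment_profiles` data frame covering one or more samples.
#' @param genome A `genome_build`.
#' @return Data frame with one row per sample (column `sample_id` first).
#' @export
score_instability <- function(segs, genome) {
  ids <- unique(segs$sample)
  rows <- lapply(ids, function(s) {
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          hrd_score(sample_segments(segs, s), genome))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
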