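#' Construct allele-specific copy-number segment profiles
#'
#' Segments are stored as one data frame for the whole cohort, with
#' 0-based half-open coordinates internally. On disk (see [read_segments()])
#' coordinates are 1-based inclusive, the FACETS/SEG convention.
#'
#' @param df Data frame with columns `sample`, `chrom`, `start`, `end`
#'   (0-based half-open), `total_cn`, `major_cn`, `minor_cn`.
#' @return An object of class `segment_profiles` (a validated data frame).
#' @export
segment_profiles <- function(df) {
  req <- c("sample", "chrom", "start", "end", "total_cn", "major_cn", "minor_cn")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[req]
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop(sprintf("segment with end <= start: %s %s [%d, %d)", df$sample[i],
                 df$chrom[i], df$start[i], df$end[i]), call. = FALSE)
  }
  cn <- df[c("total_cn", "major_cn", "minor_cn")]
  if (any(cn < 0) || any(cn != round(cn))) {
    stop("copy numbers must be non-negative integers", call. = FALSE)
  }
  if (any(df$major_cn < df$minor_cn)) {
    i <- which(df$major_cn < df$minor_cn)[1]
    stop(sprintf("major_cn < minor_cn at %s %s [%d, %d)", df$sample[i],
                 df$chrom[i], df$start[i], df$end[i]), call. = FALSE)
  }
  if (any(df$major_cn + df$minor_cn != df$total_cn)) {
    i <- which(df$major_cn + df$minor_cn != df$total_cn)[1]
    stop(sprintf("major_cn + minor_cn != total_cn at %s %s [%d, %d)", df$sample[i],
                 df$chrom[i], df$start[i], df$end[i]), call. = FALSE)
  }
  df <- df[order(df$sample, df$chrom, df$start), ]
  rownames(df) <- NULL
  # overlap check within each sample-chromosome after sorting
  grp <- paste(df$sample, df$chrom, sep = "\r")
  same <- grp[-1] == grp[-nrow(df)]
  if (nrow(df) > 1 && any(same & df$start[-1] < df$end[-nrow(df)])) {
    i <- which(same & df$start[-1] < df$end[-nrow(df)])[1] + 1L
    stop(sprintf("overlapping segments for %s on %s near position %d",
                 df$sample[i], df$chrom[i], df$start[i]), call. = FALSE)
  }
  class(df) <- c("segment_profiles", "data.frame")
  df
}

#' Read a SEG-style allele-specific segment table
#'
#' Expects columns `sample`, `chrom`, `start`, `end`, `total_cn`, `major_cn`,
#' `minor_cn` with 1-based inclusive coordinates, as produced downstream of
#' FACETS. Coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path Path to a tab-delimited file.
#' @return A `segment_profiles` object.
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "start", "end", "total_cn", "major_cn", "minor_cn")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$start <- df$start - 1L  # 1-based inclusive -> 0-based half-open
  segment_profiles(df)
}

#' Write segment profiles as a SEG-style table
#'
#' Inverse of [read_segments()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive.
#'
#' @param segs A `segment_profiles` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path) {
  out <- as.data.frame(segs)
  out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genome build table
#'
#' Chromosome lengths and centromere intervals, used for arm decomposition in
#' LST counting, the telomere/centromere rules of TAI, and the autosomal
#' denominator of the whole-genome-doubling call.
#'
#' @param df Data frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end`, `is_autosome` (logical or 0/1).
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(df) {
  req <- c("chrom", "length", "cen_start", "cen_end", "is_autosome")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[req]
  df$is_autosome <- as.logical(df$is_autosome)
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome names", call. = FALSE)
  bad <- !(df$cen_start > 0 & df$cen_end > df$cen_start & df$length > df$cen_end)
  if (any(bad)) {
    stop("invalid centromere interval for ", df$chrom[which(bad)[1]],
         " (need 0 < cen_start < cen_end < length)", call. = FALSE)
  }
  rownames(df) <- df$chrom
  class(df) <- c("genome_build", "data.frame")
  df
}

#' Read a genome build table from TSV
#'
#' @param path Path to a tab-delimited file with columns `chrom`, `length`,
#'   `cen_start`, `cen_end`, `is_autosome`. A GRCh37-like build ships with the
#'   package: `system.file("extdata", "genome_grch37.tsv", package = "lmsproteo")`.
#' @return A `genome_build` object.
#' @export
read_genome_build <- function(path) {
  genome_build(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Chromosome arm intervals of a genome build
#'
#' The p arm runs from 0 to the centromere start, the q arm from the
#' centromere end to the chromosome end (0-based half-open).
#'
#' @param genome A `genome_build`.
#' @return Data frame with columns `chrom`, `arm`, `start`, `end`,
#'   `is_autosome`.
#' @export
genome_arms <- function(genome) {
  data.frame(
    chrom = rep(genome$chrom, 2L),
    arm = rep(c("p", "q"), each = nrow(genome)),
    start = c(rep(0, nrow(genome)), genome$cen_end),
    end = c(genome$cen_start, genome$length),
    is_autosome = rep(genome$is_autosome, 2L),
    stringsAsFactors = FALSE
  )
}
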