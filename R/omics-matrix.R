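#' Construct an omics matrix
#'
#' The basic container for feature-by-sample abundance data: a numeric matrix
#' with unique feature row names and sample column names, a scale tag and a
#' feature kind. Missing values are represented as `NA` and tracked implicitly
#' as the missingness mask.
#'
#' @param values Numeric matrix with rownames (feature IDs) and colnames
#'   (sample IDs). `NA` entries denote missing measurements.
#' @param scale_tag Either `"raw_intensity"` (non-negative intensities) or
#'   `"log2"`.
#' @param feature_kind One of `"protein"`, `"phosphosite"`, `"mrna"`,
#'   `"cna_gene"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values,
                         scale_tag = c("raw_intensity", "log2"),
                         feature_kind = c("protein", "phosphosite", "mrna", "cna_gene")) {
  scale_tag <- match.arg(scale_tag)
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  }
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f)) {
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (scale_tag == "raw_intensity" && any(values < 0, na.rm = TRUE)) {
    stop("raw_intensity values must be non-negative", call. = FALSE)
  }
  structure(list(values = values, scale_tag = scale_tag, feature_kind = feature_kind),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples [%s, %s], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$feature_kind, x$scale_tag,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an omics matrix
#' @param m An `omics_matrix`.
#' @return Character vector of IDs.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Subset an omics matrix by features and/or samples
#'
#' @param m An `omics_matrix`.
#' @param features,samples Character or integer indices; `NULL` keeps all.
#' @return An `omics_matrix`.
#' @export
subset_omics <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  omics_matrix(v, m$scale_tag, m$feature_kind)
}

#' Convert between raw-intensity and log2 scales
#'
#' `to_log2()` is the identity on log2 matrices; on raw intensities it applies
#' `log2(x)` (zeros become missing). `to_intensity()` inverts it.
#'
#' @param m An `omics_matrix`.
#' @return An `omics_matrix` on the requested scale.
#' @export
to_log2 <- function(m) {
  if (m$scale_tag == "log2") return(m)
  v <- m$values
  v[!is.na(v) & v <= 0] <- NA
  v <- log2(v)
  omics_matrix(v, "log2", m$feature_kind)
}

#' @rdname to_log2
#' @export
to_intensity <- function(m) {
  if (m$scale_tag == "raw_intensity") return(m)
  omics_matrix(2^m$values, "raw_intensity", m$feature_kind)
}

#' Read a delimited feature-by-sample matrix
#'
#' First column holds feature IDs, the header row sample IDs. Empty cells or
#' the literal `NA` denote missing values.
#'
#' @param path Path to a TSV (or `sep`-delimited) file.
#' @param scale_tag,feature_kind Passed to [omics_matrix()].
#' @param sep Field separator; default tab.
#' @return An `omics_matrix` preserving file row/column order.
#' @export
read_matrix <- function(path, scale_tag = "log2", feature_kind = "protein", sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate feature IDs in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells[cells == ""] <- NA_character_
  suppressWarnings(num <- array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                 ids[bad[1, 1]], colnames(cells)[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(cells))
  omics_matrix(num, scale_tag, feature_kind)
}

#' Write an omics matrix as delimited text
#'
#' @param m An `omics_matrix`.
#' @param path Output path.
#' @param sep Field separator; default tab.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(feature_id = feature_ids(m), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
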