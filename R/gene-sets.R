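#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (set members). Members are
#'   deduplicated: membership is a set.
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all sets must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name: ",
         names(sets)[duplicated(names(sets))][1], call. = FALSE)
  }
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (any(lengths(sets) == 0)) {
    stop("empty set: ", names(sets)[lengths(sets) == 0][1], call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %s\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are silently deduplicated.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(sets = stats::setNames(list(), character()),
                          descriptions = character()),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name in GMT: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  gene_set_collection(sets, desc)
}

#' Write gene sets in GMT format
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a kinase-substrate map
#'
#' @param df Data frame with columns `kinase`, `substrate`, `site`. Duplicate
#'   (kinase, substrate, site) triples are dropped.
#' @return An object of class `kinase_substrate_map`.
#' @export
kinase_substrate_map <- function(df) {
  req <- c("kinase", "substrate", "site")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- unique(as.data.frame(df)[req])
  rownames(df) <- NULL
  class(df) <- c("kinase_substrate_map", "data.frame")
  df
}

#' Read a kinase-substrate map from a 3-column TSV
#'
#' @param path Path to a tab-delimited file with columns `kinase`,
#'   `substrate`, `site`.
#' @return A `kinase_substrate_map`.
#' @export
read_kinase_substrate_map <- function(path) {
  kinase_substrate_map(utils::read.table(path, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE))
}
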