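#' Validate a sample metadata table
#'
#' Cohort attributes per sample: TMT plex/channel assignment, pooled-reference
#' flag, optional subtype label, tumor status, primary/metastasis pairing, and
#' survival endpoints (overall and recurrence-free survival as nonnegative
#' time + 0/1 event).
#'
#' @param df Data frame with at least `sample_id`, `plex_id`, `channel_id`,
#'   `is_pooled_reference`; optionally `subtype_label`, `tumor_status`,
#'   `pair_id`, `os_time`, `os_event`, `rfs_time`, `rfs_event`.
#' @return The validated data frame with class `sample_table`.
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "plex_id", "channel_id", "is_pooled_reference")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1],
         call. = FALSE)
  }
  df$is_pooled_reference <- as.logical(df$is_pooled_reference)
  has_ref <- tapply(df$is_pooled_reference, df$plex_id, any)
  if (any(df$is_pooled_reference) && !all(has_ref)) {
    stop("plex without a pooled-reference channel: ",
         names(has_ref)[!has_ref][1], call. = FALSE)
  }
  for (ev in c("os_event", "rfs_event")) {
    if (ev %in% names(df) && !all(df[[ev]] %in% c(0, 1, NA))) {
      stop(ev, " must be 0/1", call. = FALSE)
    }
  }
  for (tm in c("os_time", "rfs_time")) {
    if (tm %in% names(df) && any(df[[tm]] < 0, na.rm = TRUE)) {
      stop(tm, " must be nonnegative", call. = FALSE)
    }
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-delimited file; see [sample_table()] for columns.
#' @return A `sample_table`.
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Construct a gene-by-sample alteration call matrix
#'
#' Oncoprint-style categorical calls. When a gene has multiple event types in
#' one sample, callers must collapse them first (see
#' [collapse_alteration_calls()]).
#'
#' @param calls Character matrix (genes x samples) with entries in
#'   `none`, `mutation`, `amplification`, `deep_deletion`, `loh`.
#' @param provenance Optional free-form provenance tag.
#' @return An object of class `alteration_matrix`.
#' @export
alteration_matrix <- function(calls, provenance = "") {
  lv <- c("none", "mutation", "amplification", "deep_deletion", "loh")
  if (!is.matrix(calls) || !is.character(calls)) {
    stop("`calls` must be a character matrix", call. = FALSE)
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("`calls` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(calls)) || anyDuplicated(colnames(calls))) {
    stop("duplicate gene or sample IDs", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(calls)), lv)
  if (length(bad)) stop("unknown call: ", bad[1], call. = FALSE)
  structure(list(calls = calls, provenance = provenance),
            class = "alteration_matrix")
}

#' Collapse multiple event types into one oncoprint call
#'
#' Precedence when a gene carries several events in one sample:
#' mutation > deep_deletion > amplification > loh. The full multi-event list
#' should be retained by the caller as provenance.
#'
#' @param events Character vector of event types for one (gene, sample) cell.
#' @return A single call string.
#' @export
collapse_alteration_calls <- function(events) {
  prec <- c("mutation", "deep_deletion", "amplification", "loh")
  hit <- prec[prec %in% events]
  if (length(hit)) hit[1] else "none"
}
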