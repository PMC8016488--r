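#' Read protein sequences from a FASTA file
#'
#' Parses (possibly line-wrapped) FASTA into a tibble of records in file
#' order. The record id is the first whitespace-delimited token of the header;
#' the remainder becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id`, `description`, `sequence`.
#' @details An empty file yields an empty tibble with a warning; a record with
#'   an empty sequence is an error naming the record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: '%s'", path))
  empty <- tibble::tibble(id = character(), description = character(),
                          sequence = character())
  if (file.size(path) == 0L) {
    warning(sprintf("FASTA file '%s' is empty", path), call. = FALSE)
    return(empty)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
    return(empty)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop(sprintf("record '%s' has an empty sequence", id[which(widths == 0L)[1]]))
  }
  tibble::tibble(id = unname(id), description = unname(description),
                 sequence = unname(as.character(set)))
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble or data frame with `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nchar(desc) > 0, paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a sequence-to-group label table
#'
#' Two-column tab-separated table with a header line: sequence id and
#' orthologous-group id.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `id`, `group`.
#' @details A duplicated sequence id is an error.
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2L) stop(sprintf("label table '%s' needs two columns (id, group)", path))
  tab <- tibble::tibble(id = tab[[1]], group = tab[[2]])
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id(s) in label table: %s",
                 paste(utils::head(unique(dup), 5), collapse = ", ")))
  }
  tab
}

#' Write a sequence-to-group label table
#'
#' @param labels Tibble with columns `id`, `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels[, c("id", "group")], path, progress = FALSE)
  invisible(path)
}

# Warn about label ids that have no sequence; error on sequences semantics
# are left to callers. Returns labels restricted to ids present in records.
match_labels <- function(labels, records) {
  missing <- setdiff(labels$id, records$id)
  if (length(missing) > 0L) {
    warning(sprintf("%d label id(s) absent from the FASTA input (e.g. '%s')",
                    length(missing), missing[1]), call. = FALSE)
  }
  labels[labels$id %in% records$id, , drop = FALSE]
}

#' Write group assignments to a prediction table
#'
#' Four-column tab-separated table with a header: sequence id, assigned group
#' (or the literal `"unassigned"`), confidence (rank-1 softmax probability)
#' and model name. Row order equals input order.
#'
#' @param results Tibble with columns `id`, `group`, `confidence`, `model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(results, path) {
  readr::write_tsv(results[, c("id", "group", "confidence", "model")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `id`, `group`, `confidence`, `model`.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), group = readr::col_character(),
    confidence = readr::col_double(), model = readr::col_character()),
    progress = FALSE)
}
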