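# Model archive: a single diffable text file bundling configuration, group
# label map, alphabet ordering and named weight arrays. Values are written
# with 17 significant digits, so save -> load -> save is bit-stable.

ARCHIVE_MAGIC <- "ognet-archive v1"

format_values <- function(v, per_line = 6L) {
  s <- sprintf("%.17g", as.vector(v))
  n <- length(s)
  starts <- seq(1L, n, by = per_line)
  vapply(starts, function(i) {
    paste(s[i:min(i + per_line - 1L, n)], collapse = " ")
  }, character(1))
}

#' Save a model archive
#'
#' Writes configuration, label map, alphabet ordering and all weight arrays
#' (including batch-norm running statistics for the baseline variant) to a
#' single plain-text file.
#'
#' @param model An `og_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  cfg <- model$config
  lines <- c(
    ARCHIVE_MAGIC,
    "@config",
    as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)),
    "@labels",
    as.character(jsonlite::toJSON(model$label_map$group_ids)),
    "@alphabet",
    paste(model$alphabet$symbols, collapse = ""),
    sprintf("@weights %d", length(model$weights))
  )
  for (nm in names(model$weights)) {
    v <- model$weights[[nm]]
    header <- if (is.matrix(v)) {
      sprintf(">%s mat %d %d", nm, nrow(v), ncol(v))
    } else {
      sprintf(">%s vec %d", nm, length(v))
    }
    lines <- c(lines, header, format_values(v))
  }
  lines <- c(lines, "@end")
  writeLines(lines, path)
  invisible(path)
}

#' Load a model archive
#'
#' Reads an archive written by [save_model()], verifying that every weight
#' array is present with the shape the configuration implies and that the
#' label map matches the number of output groups.
#'
#' @param path Path to the archive.
#' @return An `og_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model archive not found: '%s'", path))
  lines <- readLines(path)
  if (length(lines) < 8L || lines[1] != ARCHIVE_MAGIC) {
    stop(sprintf("'%s' is not a model archive (bad magic line)", path))
  }
  sect <- function(tag) {
    i <- which(lines == tag)
    if (length(i) != 1L) stop(sprintf("archive is missing the %s section", tag))
    i
  }
  cj <- jsonlite::fromJSON(lines[sect("@config") + 1L])
  config <- model_config(
    variant = cj$variant, n_groups = cj$n_groups,
    embedding_dim = cj$embedding_dim, filter_sizes = cj$filter_sizes,
    filters_per_size = cj$filters_per_size, dropout = cj$dropout,
    hidden_units = cj$hidden_units, fixed_length = cj$fixed_length,
    alphabet_size = cj$alphabet_size, name = cj$name
  )
  group_ids <- jsonlite::fromJSON(lines[sect("@labels") + 1L])
  if (length(group_ids) != config$n_groups) {
    stop(sprintf("label map has %d groups but the configuration expects %d",
                 length(group_ids), config$n_groups))
  }
  label_map <- og_label_map(group_ids)
  symbols <- strsplit(lines[sect("@alphabet") + 1L], "")[[1]]
  alphabet <- if (identical(symbols, extended_alphabet()$symbols)) {
    extended_alphabet()
  } else if (identical(symbols, baseline_alphabet()$symbols)) {
    baseline_alphabet()
  } else {
    structure(list(symbols = symbols,
                   index_of = stats::setNames(seq_along(symbols), symbols),
                   padding_index = 0L, ambiguity_table = list()),
              class = "og_alphabet")
  }

  wline <- grep("^@weights ", lines)
  if (length(wline) != 1L) stop("archive is missing the @weights section")
  weights <- list()
  i <- wline + 1L
  while (i <= length(lines) && lines[i] != "@end") {
    if (!startsWith(lines[i], ">")) {
      stop(sprintf("malformed archive near line %d: expected a weight header", i))
    }
    parts <- strsplit(sub("^>", "", lines[i]), " ")[[1]]
    nm <- parts[1]
    j <- i + 1L
    while (j <= length(lines) && !startsWith(lines[j], ">") && lines[j] != "@end") {
      j <- j + 1L
    }
    vals <- scan(text = lines[(i + 1L):(j - 1L)], what = double(), quiet = TRUE)
    if (parts[2] == "mat") {
      r <- as.integer(parts[3]); c <- as.integer(parts[4])
      if (length(vals) != r * c) {
        stop(sprintf("weight '%s': expected %d values, found %d", nm, r * c,
                     length(vals)))
      }
      weights[[nm]] <- matrix(vals, r, c)
    } else {
      n <- as.integer(parts[3])
      if (length(vals) != n) {
        stop(sprintf("weight '%s': expected %d values, found %d", nm, n,
                     length(vals)))
      }
      weights[[nm]] <- vals
    }
    i <- j
  }

  expected <- weight_shapes(config)$shapes
  for (nm in names(expected)) {
    if (is.null(weights[[nm]])) stop(sprintf("archive is missing weight '%s'", nm))
    sh <- expected[[nm]]
    actual <- if (is.matrix(weights[[nm]])) dim(weights[[nm]])
    else c(length(weights[[nm]]), 1L)
    if (!identical(as.integer(actual), as.integer(sh))) {
      stop(sprintf("weight '%s' has shape %s but the configuration expects %s",
                   nm, paste(actual, collapse = "x"), paste(sh, collapse = "x")))
    }
  }
  extra <- setdiff(names(weights), names(expected))
  if (length(extra) > 0L) {
    stop(sprintf("archive contains unexpected weight(s): %s",
                 paste(extra, collapse = ", ")))
  }
  structure(
    list(config = config, label_map = label_map, alphabet = alphabet,
         weights = weights[names(expected)], history = NULL, trained = TRUE),
    class = "og_model"
  )
}
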