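# Confidence-thresholded group assignment over arbitrary FASTA input.

#' Assign sequences to orthologous groups
#'
#' Runs the network over the input sequences and assigns each one to its
#' rank-1 group if the softmax probability reaches the confidence threshold,
#' and to the literal `"unassigned"` otherwise. The rank-1 probability is
#' reported either way, so results can be re-thresholded without re-running
#' inference. Output order equals input order and does not depend on
#' `batch_size` (pooling is masked to each sequence's own windows).
#'
#' @param model An `og_model` or the path to a model archive.
#' @param records Tibble with `id`, `sequence` (e.g. from [read_fasta()]), or
#'   the path to a FASTA file.
#' @param threshold Assignment confidence threshold in [0, 1]; default 0.99.
#'   With `threshold = 0` every sequence is assigned (pure argmax).
#' @param batch_size Sequences scored per forward pass.
#' @return Tibble with columns `id`, `group`, `confidence`, `model`.
#' @export
assign_groups <- function(model, records, threshold = 0.99, batch_size = 64L) {
  stopifnot(threshold >= 0, threshold <= 1, batch_size >= 1)
  if (is.character(model)) model <- load_model(model)
  if (is.character(records)) records <- read_fasta(records)
  empty <- tibble::tibble(id = character(), group = character(),
                          confidence = numeric(), model = character())
  if (nrow(records) == 0L) {
    warning("no input sequences; returning an empty prediction table",
            call. = FALSE)
    return(empty)
  }
  cfg <- model$config
  enc <- encode_records(records)
  keep <- rep(TRUE, length(enc))
  if (cfg$variant == "deepfam") {
    lens <- vapply(enc, function(e) e$length, integer(1))
    keep <- lens <= cfg$fixed_length
    if (!all(keep)) {
      warning(sprintf(
        "discarded %d sequence(s) longer than the fixed input length %d",
        sum(!keep), cfg$fixed_length), call. = FALSE)
    }
    if (!any(keep)) return(empty)
  }
  idx <- which(keep)
  chunks <- split(idx, ceiling(seq_along(idx) / batch_size))
  rows <- lapply(chunks[order(as.integer(names(chunks)))], function(ch) {
    batch <- pad_and_batch(enc[ch], min_length = max(cfg$filter_sizes))
    probs <- predict_proba(forward(model, batch, training = FALSE))
    top <- max.col(probs, ties.method = "first")
    conf <- probs[cbind(seq_along(ch), top)]
    gid <- model$label_map$group_ids[top]
    tibble::tibble(
      id = records$id[ch],
      group = ifelse(conf >= threshold, gid, "unassigned"),
      confidence = conf,
      model = cfg$name
    )
  })
  dplyr::bind_rows(rows)
}

#' Histogram of assignment confidences
#'
#' 100 bins of width 0.01 over [0, 1]; bins are half-open `[x, x + 0.01)`
#' except the last, which is closed at 1.
#'
#' @param results Prediction tibble from [assign_groups()] (uses its
#'   `confidence` column), or a numeric vector of confidences.
#' @return Tibble of class `og_confhist` with columns `lower`, `upper`,
#'   `count`; counts sum to the number of sequences.
#' @export
confidence_histogram <- function(results) {
  conf <- if (is.data.frame(results)) results$confidence else results
  if (length(conf) == 0L) stop("no confidences to histogram")
  stopifnot(all(conf >= 0), all(conf <= 1))
  edges <- (0:100) / 100
  bin <- findInterval(conf, edges, rightmost.closed = TRUE)  # 1.0 in last bin
  counts <- tabulate(bin, nbins = 100L)
  out <- tibble::tibble(
    lower = seq(0, 0.99, by = 0.01),
    upper = seq(0.01, 1, by = 0.01),
    count = counts
  )
  class(out) <- c("og_confhist", class(out))
  out
}
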