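# Imbalance-aware assignment metrics and the in-model / out-model confidence
# analysis for the open-set rejection threshold.

#' Score group assignments against ground truth
#'
#' Computes classification accuracy (fraction of correct assignments among all
#' sequences) and macro-averaged precision and recall: per-group precision and
#' recall are computed from the confusion matrix and averaged unweighted over
#' the groups present in the truth, so rare groups count as much as large
#' ones. `"unassigned"` predictions count as incorrect for accuracy, as missed
#' members (false negatives) for recall, and as non-predictions for precision.
#' A group that is never predicted has precision 0.
#'
#' @param predictions Tibble with `id`, `group` (e.g. from [assign_groups()]).
#' @param truth Tibble with `id`, `group`, or a named character vector. Every
#'   predicted id must have a truth label.
#' @return An object of class `og_score`: `accuracy`, `macro_precision`,
#'   `macro_recall`, `n`, and a `per_group` tibble (group, precision, recall,
#'   support).
#' @examples
#' pred <- tibble::tibble(id = as.character(1:5),
#'                        group = c("g0", "g1", "g1", "g1", "g2"))
#' truth <- tibble::tibble(id = as.character(1:5),
#'                         group = c("g0", "g0", "g1", "g1", "g2"))
#' s <- score_assignments(pred, truth)
#' s$accuracy         # 0.8
#' s$macro_precision  # 8/9
#' s$macro_recall     # 5/6
#' @export
score_assignments <- function(predictions, truth) {
  if (is.data.frame(truth)) truth <- stats::setNames(truth$group, truth$id)
  missing <- setdiff(predictions$id, names(truth))
  if (length(missing) > 0L) {
    stop(sprintf("no truth label for id(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  pred <- predictions$group
  true <- unname(truth[predictions$id])
  groups <- sort(unique(true))
  per_group <- lapply(groups, function(g) {
    tp <- sum(pred == g & true == g)
    fp <- sum(pred == g & true != g)
    fn <- sum(true == g & pred != g)
    tibble::tibble(
      group = g,
      precision = if (tp + fp == 0L) 0 else tp / (tp + fp),
      recall = tp / (tp + fn),
      support = tp + fn
    )
  })
  per_group <- dplyr::bind_rows(per_group)
  structure(
    list(accuracy = mean(pred == true),
         macro_precision = mean(per_group$precision),
         macro_recall = mean(per_group$recall),
         n = length(pred),
         per_group = per_group),
    class = "og_score"
  )
}

#' @export
print.og_score <- function(x, ...) {
  cat(sprintf(
    "<og_score> n=%d accuracy=%.4f macro_precision=%.4f macro_recall=%.4f (%d groups)\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall, nrow(x$per_group)))
  invisible(x)
}

#' Write a metrics report
#'
#' Writes the summary metrics and the per-group table as TSV files.
#'
#' @param score An `og_score`.
#' @param path Output path for the summary; the per-group table goes to
#'   `<path>` with suffix `.per_group.tsv` unless `per_group_path` is given.
#' @param per_group_path Optional explicit path for the per-group table.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(score, path, per_group_path = NULL) {
  readr::write_tsv(glance.og_score(score), path, progress = FALSE)
  if (is.null(per_group_path)) {
    per_group_path <- paste0(sub("\\.tsv$", "", path), ".per_group.tsv")
  }
  readr::write_tsv(score$per_group, per_group_path, progress = FALSE)
  invisible(path)
}

#' Compare assignment confidences of in-model and out-model sequences
#'
#' Scores two sets of sequences with the same model: sequences whose true
#' group is covered by the model's label map (in-model) and sequences from
#' groups the model has never seen (out-model). A well-calibrated open-set
#' classifier gives in-model sequences much higher rank-1 confidences, so the
#' two histograms separate and a confidence threshold can reject most
#' out-model inputs.
#'
#' @param model An `og_model` or archive path.
#' @param in_records,out_records Tibbles with `id`, `sequence`.
#' @param out_truth Tibble with `id`, `group` for the out-model records; their
#'   groups must be disjoint from the model's label map (checked).
#' @param threshold Confidence threshold used for the above/below counts.
#' @param batch_size Sequences per forward pass.
#' @return An object of class `og_inout`: `in_hist`, `out_hist`
#'   (confidence histograms, bin width 0.01), a `summary` tibble (set, n,
#'   n_above, n_below, median_confidence) and the `threshold`.
#' @export
in_out_model_analysis <- function(model, in_records, out_records, out_truth,
                                  threshold = 0.99, batch_size = 64L) {
  if (is.character(model)) model <- load_model(model)
  overlap <- intersect(unique(out_truth$group), model$label_map$group_ids)
  if (length(overlap) > 0L) {
    stop(sprintf("out-model group(s) overlap the model's label map: %s",
                 paste(utils::head(overlap, 5), collapse = ", ")))
  }
  pred_in <- assign_groups(model, in_records, threshold = threshold,
                           batch_size = batch_size)
  pred_out <- assign_groups(model, out_records, threshold = threshold,
                            batch_size = batch_size)
  summarize_set <- function(pred, set) {
    tibble::tibble(set = set, n = nrow(pred),
                   n_above = sum(pred$confidence >= threshold),
                   n_below = sum(pred$confidence < threshold),
                   median_confidence = stats::median(pred$confidence))
  }
  structure(
    list(in_hist = confidence_histogram(pred_in),
         out_hist = confidence_histogram(pred_out),
         summary = dplyr::bind_rows(summarize_set(pred_in, "in_model"),
                                    summarize_set(pred_out, "out_model")),
         threshold = threshold),
    class = "og_inout"
  )
}

#' @export
print.og_inout <- function(x, ...) {
  cat(sprintf("<og_inout> threshold=%.2f\n", x$threshold))
  print(x$summary)
  invisible(x)
}

#' Export the learned amino-acid embedding
#'
#' One row per residue symbol of the model's alphabet (the padding row is
#' excluded); values are the embedding weights as trained.
#'
#' @param model An `og_model` of the `"ognet"` variant, or an archive path.
#' @return Tibble with a `symbol` column and `e1 ... eD` value columns.
#' @export
export_embeddings <- function(model) {
  if (is.character(model)) model <- load_model(model)
  if (model$config$variant != "ognet") {
    stop("the baseline variant has no learned embedding to export")
  }
  emb <- model$weights$embedding[-1, , drop = FALSE]  # drop padding row
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  dplyr::bind_cols(tibble::tibble(symbol = model$alphabet$symbols),
                   tibble::as_tibble(emb))
}
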