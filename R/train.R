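# Dataset preparation (population filtering, stratified splitting) and the
# optimization loop: Adam on the softmax cross-entropy with a learning rate
# decayed by 25% after each epoch, keeping the epoch with the highest
# validation accuracy.

#' Remove groups below a minimum population
#'
#' Groups with fewer than `threshold` member sequences are removed entirely
#' (down to singletons, such groups cannot be split into train/validation/test
#' partitions, and very small groups are not learnable).
#'
#' @param labels Tibble with columns `id`, `group`.
#' @param threshold Minimum members per retained group (>= 1). Published
#'   experiments use 100, 250 or 500; synthetic runs typically use smaller
#'   values.
#' @return List with `labels` (retained rows), `removed` (tibble of removed
#'   groups and their sequence counts) and `threshold`.
#' @export
filter_min_population <- function(labels, threshold) {
  stopifnot(threshold >= 1)
  counts <- dplyr::count(labels, .data$group, name = "n_sequences")
  keep <- counts$group[counts$n_sequences >= threshold]
  if (length(keep) == 0L) {
    stop(sprintf("no group reaches the minimum population of %d", threshold))
  }
  removed <- counts[!(counts$group %in% keep), , drop = FALSE]
  list(labels = labels[labels$group %in% keep, , drop = FALSE],
       removed = removed, threshold = as.integer(threshold))
}

# Largest-remainder allocation of n items to the ratios, then enforce at
# least one item per partition by taking from the largest partition.
allocate_partition <- function(n, ratios) {
  q <- n * ratios
  f <- floor(q)
  rem <- n - sum(f)
  if (rem > 0) {
    ord <- order(q - f, decreasing = TRUE)  # ties broken by partition order
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  while (any(f == 0)) {
    f[which.max(f)] <- f[which.max(f)] - 1
    f[which(f == 0)[1]] <- 1
  }
  as.integer(f)
}

#' Stratified train/validation/test split
#'
#' Within every group, member ids are shuffled (seeded) and allocated to the
#' three partitions by largest-remainder rounding of `ratio * group size`,
#' with each partition receiving at least one member. The default ratios are
#' 81% / 9% / 10%.
#'
#' @param labels Tibble with columns `id`, `group`; every group must have at
#'   least 3 members (use [filter_min_population()] first).
#' @param ratios Named numeric vector `c(train=, validation=, test=)`,
#'   positive and summing to 1.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return Tibble with columns `id`, `group`, `split` (factor with levels
#'   train, validation, test).
#' @export
stratified_split <- function(labels,
                             ratios = c(train = 0.81, validation = 0.09, test = 0.10),
                             seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-8)
  counts <- table(labels$group)
  small <- names(counts)[counts < 3L]
  if (length(small) > 0L) {
    stop(sprintf(
      "group(s) with fewer than 3 members cannot be split (e.g. '%s'); apply filter_min_population() first",
      small[1]))
  }
  with_seed(seed, {
    parts <- lapply(split(labels$id, labels$group), function(ids) {
      ids <- resample(ids, length(ids))
      sizes <- allocate_partition(length(ids), ratios)
      # assign in shuffled order: first block train, then validation, then test
      tibble::tibble(id = ids,
                     split = rep(c("train", "validation", "test"), times = sizes))
    })
    out <- dplyr::bind_rows(parts)
    out <- dplyr::left_join(out, labels[, c("id", "group")], by = "id")
    out$split <- factor(out$split, levels = c("train", "validation", "test"))
    out[, c("id", "group", "split")]
  })
}

#' Training configuration
#'
#' @param learning_rate Initial Adam learning rate (default 0.01).
#' @param lr_decay Multiplicative learning-rate decay per epoch (default 0.75,
#'   i.e. a 25% decrease after each epoch).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Number of epochs to run; the returned model is the
#'   checkpoint with the highest validation accuracy (ties: earliest epoch).
#' @param seed Integer seed controlling shuffling and dropout.
#' @return An object of class `og_training_config`.
#' @export
training_config <- function(learning_rate = 0.01, lr_decay = 0.75,
                            batch_size = 64L, max_epochs = 15L, seed = 1L) {
  stopifnot(learning_rate > 0, lr_decay > 0, lr_decay <= 1, batch_size >= 1,
            max_epochs >= 1)
  structure(list(learning_rate = learning_rate, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "og_training_config")
}

#' Learning-rate schedule
#'
#' @param config An `og_training_config`.
#' @param epochs 0-based epoch indices.
#' @return `learning_rate * lr_decay^epochs`.
#' @examples
#' lr_schedule(training_config(), 0:3)  # 0.01 0.0075 0.005625 0.00421875
#' @export
lr_schedule <- function(config, epochs) {
  config$learning_rate * config$lr_decay^epochs
}

# Adam with default moment parameters; state holds first/second moments and
# the step counter. Only trainable arrays are updated.
adam_init <- function(weights, names) {
  zeros <- lapply(weights[names], function(w) w * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

# Encode records once; returns a named list of og_encoded keyed by id.
encode_records <- function(records, alphabet = extended_alphabet()) {
  enc <- lapply(seq_len(nrow(records)), function(i) {
    encode_sequence(list(id = records$id[i], sequence = records$sequence[i]),
                    alphabet)
  })
  names(enc) <- records$id
  enc
}

run_training_batch <- function(model, enc, ids, class_idx, lr, adam, trainables) {
  cfg <- model$config
  seqs <- enc[ids]
  labels <- class_idx[ids]
  if (cfg$variant == "ognet") {
    batch <- pad_and_batch(seqs, min_length = max(cfg$filter_sizes))
    res <- cpp_ognet_pass(model$weights, batch$matrix, batch$lengths,
                          cfg$filter_sizes, cfg$dropout, TRUE,
                          as.integer(labels), TRUE)
  } else {
    X <- onehot_batch(seqs, cfg$fixed_length)
    res <- cpp_deepfam_pass(model$weights, X, cfg$filter_sizes, cfg$dropout,
                            TRUE, as.integer(labels), TRUE, 1e-5, 0.1)
    for (nm in names(res$running_stats)) {
      model$weights[[nm]] <- as.vector(res$running_stats[[nm]])
    }
  }
  if (!is.finite(res$loss)) {
    stop(sprintf("non-finite training loss (%g); try a lower learning rate",
                 res$loss))
  }
  grads <- res$grads
  # coerce 1-column gradients back to vectors to match weight storage
  for (nm in trainables) {
    if (!is.matrix(model$weights[[nm]])) grads[[nm]] <- as.vector(grads[[nm]])
  }
  upd <- adam_step(model$weights, grads, adam, lr)
  model$weights <- upd$weights
  list(model = model, adam = upd$state, loss = res$loss)
}

# Argmax accuracy on a set of ids, evaluated in minibatches (eval mode).
evaluate_accuracy <- function(model, enc, ids, class_idx, batch_size) {
  correct <- 0L
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_size))) {
    batch <- pad_and_batch(enc[chunk],
                           min_length = max(model$config$filter_sizes))
    logits <- forward(model, batch, training = FALSE)
    pred <- max.col(logits, ties.method = "first") - 1L
    correct <- correct + sum(pred == class_idx[chunk])
  }
  correct / length(ids)
}

#' Train a network on labelled sequences
#'
#' Minimizes the softmax cross-entropy with Adam (default moment parameters),
#' shuffling the training set every epoch, multiplying the learning rate by
#' `lr_decay` after each epoch, and returning the weights from the epoch with
#' the highest validation accuracy (ties broken toward the earliest epoch).
#'
#' For the `"deepfam"` variant, sequences longer than the configured fixed
#' input length are discarded with a warning before training.
#'
#' @param model An `og_model` from [build_model()]; its label map must cover
#'   every group present in the training labels.
#' @param records Tibble with `id`, `sequence`.
#' @param labels Tibble with `id`, `group` covering all train/validation ids.
#' @param split Tibble from [stratified_split()] (columns `id`, `split`), or a
#'   list with elements `train` and `validation` holding id vectors.
#' @param control An `og_training_config`.
#' @param quiet Suppress per-epoch progress messages.
#' @return The trained `og_model`, with a `history` tibble (epoch, learning
#'   rate, mean training loss, validation accuracy) and `best_epoch` attribute.
#' @export
train_model <- function(model, records, labels, split,
                        control = training_config(), quiet = FALSE) {
  cfg <- model$config
  if (is.data.frame(split)) {
    train_ids <- split$id[split$split == "train"]
    val_ids <- split$id[split$split == "validation"]
  } else {
    train_ids <- split$train
    val_ids <- split$validation
  }
  if (length(val_ids) == 0L) stop("validation set is empty")
  lab <- stats::setNames(labels$group, labels$id)
  missing_groups <- setdiff(unique(lab[c(train_ids, val_ids)]),
                            model$label_map$group_ids)
  if (length(missing_groups) > 0L) {
    stop(sprintf("label map does not cover group(s): %s",
                 paste(utils::head(missing_groups, 5), collapse = ", ")))
  }
  class_idx <- model$label_map$index_of[lab]
  names(class_idx) <- names(lab)

  enc <- encode_records(records[records$id %in% c(train_ids, val_ids), ,
                                drop = FALSE])
  if (cfg$variant == "deepfam") {
    lens <- vapply(enc, function(e) e$length, integer(1))
    too_long <- names(enc)[lens > cfg$fixed_length]
    if (length(too_long) > 0L) {
      warning(sprintf(
        "discarded %d sequence(s) longer than the fixed input length %d",
        length(too_long), cfg$fixed_length), call. = FALSE)
      train_ids <- setdiff(train_ids, too_long)
      val_ids <- setdiff(val_ids, too_long)
    }
  }

  trainables <- trainable_names(cfg)
  adam <- adam_init(model$weights, trainables)
  history <- vector("list", control$max_epochs)
  best <- list(acc = -Inf, weights = model$weights, epoch = NA_integer_)

  with_seed(control$seed, {
    for (epoch in seq_len(control$max_epochs) - 1L) {
      lr <- lr_schedule(control, epoch)
      ids <- resample(train_ids, length(train_ids))
      losses <- c()
      for (chunk in split(ids, ceiling(seq_along(ids) / control$batch_size))) {
        step <- run_training_batch(model, enc, chunk, class_idx, lr, adam,
                                   trainables)
        model <- step$model
        adam <- step$adam
        losses <- c(losses, step$loss)
      }
      val_acc <- evaluate_accuracy(model, enc, val_ids, class_idx,
                                   control$batch_size)
      history[[epoch + 1L]] <- tibble::tibble(
        epoch = epoch, learning_rate = lr, train_loss = mean(losses),
        validation_accuracy = val_acc)
      if (!quiet) {
        message(sprintf("epoch %d: lr=%.6g loss=%.4f val_acc=%.4f",
                        epoch, lr, mean(losses), val_acc))
      }
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, weights = model$weights,
                     epoch = epoch)
      }
    }
  })
  model$weights <- best$weights
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

#' Write a per-epoch training history table
#'
#' @param model A trained `og_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history")
  readr::write_tsv(model$history, path, progress = FALSE)
  invisible(path)
}
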