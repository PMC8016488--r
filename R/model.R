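# Network construction: configuration, label map, weight allocation,
# self-normalizing initialization, parameter counting and the forward pass.

#' Network configuration
#'
#' Architecture hyperparameters for the two supported variants:
#'
#' * `"ognet"` — learned 26-symbol amino-acid embedding into R^D (default
#'   D = 10), 1-D convolutions with SELU activations, masked adaptive
#'   max-pooling over each sequence's valid windows, dropout, and a softmax
#'   output layer placed directly after pooling (no hidden layer). Handles
#'   arbitrary sequence lengths; sequences shorter than the largest filter are
#'   zero-padded to it.
#' * `"deepfam"` — fixed-length pseudo one-hot input (21 columns), 1-D
#'   convolutions with batch normalization and ReLU, 1-max pooling over the
#'   full fixed-length row, a ReLU hidden layer, dropout, and a softmax
#'   output. Sequences longer than `fixed_length` are discarded.
#'
#' Defaults follow the published parametrizations: filter sizes 8, 12, 16, 20,
#' 24, 28, 32, 36 for both variants; 150 filters per size and no hidden layer
#' for `"ognet"`; 250 filters per size and 2000 hidden units for the best
#' `"deepfam"` parametrization (`parametrization = "light"` selects 150
#' filters and 1500 hidden units); dropout 0.3; fixed input length 1000 for
#' the baseline.
#'
#' @param variant `"ognet"` or `"deepfam"`.
#' @param n_groups Number of output groups (>= 2).
#' @param embedding_dim Embedding dimension D (ognet only; default 10).
#' @param filter_sizes Strictly increasing integer filter sizes.
#' @param filters_per_size Filters per size F.
#' @param dropout Dropout probability in [0, 1).
#' @param hidden_units Hidden-layer width H (deepfam only; 0 for ognet).
#' @param fixed_length Fixed input length (deepfam only).
#' @param parametrization `"best"` or `"light"` (deepfam defaults).
#' @param alphabet_size Residue alphabet size (26 for the extended alphabet).
#' @param name Model name recorded in prediction tables.
#' @return An object of class `og_config`.
#' @export
model_config <- function(variant = c("ognet", "deepfam"), n_groups,
                         embedding_dim = 10L,
                         filter_sizes = c(8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L),
                         filters_per_size = NULL, dropout = 0.3,
                         hidden_units = NULL, fixed_length = 1000L,
                         parametrization = c("best", "light"),
                         alphabet_size = 26L, name = NULL) {
  variant <- match.arg(variant)
  parametrization <- match.arg(parametrization)
  if (is.null(filters_per_size)) {
    filters_per_size <- if (variant == "ognet") 150L
    else if (parametrization == "light") 150L else 250L
  }
  if (is.null(hidden_units)) {
    hidden_units <- if (variant == "ognet") 0L
    else if (parametrization == "light") 1500L else 2000L
  }
  if (is.null(name)) name <- variant
  cfg <- list(
    variant = variant,
    alphabet_size = as.integer(alphabet_size),
    embedding_dim = as.integer(embedding_dim),
    filter_sizes = as.integer(filter_sizes),
    filters_per_size = as.integer(filters_per_size),
    dropout = dropout,
    n_groups = as.integer(n_groups),
    hidden_units = as.integer(hidden_units),
    fixed_length = as.integer(fixed_length),
    name = name
  )
  validate_config(cfg)
  structure(cfg, class = "og_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$embedding_dim >= 1,
    all(cfg$filter_sizes >= 1),
    all(diff(cfg$filter_sizes) > 0),
    cfg$filters_per_size >= 1,
    cfg$dropout >= 0, cfg$dropout < 1,
    cfg$n_groups >= 2,
    cfg$alphabet_size >= 1
  )
  if (cfg$variant == "ognet" && cfg$hidden_units != 0) {
    stop("the ognet variant has no hidden layer (hidden_units must be 0)")
  }
  if (cfg$variant == "deepfam") {
    stopifnot(cfg$hidden_units >= 1,
              cfg$fixed_length >= max(cfg$filter_sizes))
  }
  invisible(cfg)
}

#' Bijection between group identifiers and output indices
#'
#' @param group_ids Character vector of unique group identifiers; the given
#'   ordering is preserved and persisted with the model.
#' @return An `og_label_map` with `group_ids` and a named 0-based `index_of`.
#' @export
og_label_map <- function(group_ids) {
  group_ids <- as.character(group_ids)
  if (anyDuplicated(group_ids)) stop("group ids must be unique")
  structure(
    list(group_ids = group_ids,
         index_of = stats::setNames(seq_along(group_ids) - 1L, group_ids)),
    class = "og_label_map"
  )
}

# Expected shapes of all weight arrays for a config; buffers are the
# batch-norm running statistics (not trained).
weight_shapes <- function(cfg) {
  F <- cfg$filters_per_size
  nK <- length(cfg$filter_sizes)
  shapes <- list()
  buffers <- character()
  if (cfg$variant == "ognet") {
    shapes$embedding <- c(cfg$alphabet_size + 1L, cfg$embedding_dim)
    for (k in cfg$filter_sizes) {
      shapes[[paste0("conv_w_", k)]] <- c(k * cfg$embedding_dim, F)
      shapes[[paste0("conv_b_", k)]] <- c(F, 1L)
    }
    shapes$out_w <- c(nK * F, cfg$n_groups)
    shapes$out_b <- c(cfg$n_groups, 1L)
  } else {
    for (k in cfg$filter_sizes) {
      shapes[[paste0("conv_w_", k)]] <- c(k * 21L, F)
      shapes[[paste0("conv_b_", k)]] <- c(F, 1L)
      shapes[[paste0("bn_gamma_", k)]] <- c(F, 1L)
      shapes[[paste0("bn_beta_", k)]] <- c(F, 1L)
      shapes[[paste0("bn_rmean_", k)]] <- c(F, 1L)
      shapes[[paste0("bn_rvar_", k)]] <- c(F, 1L)
      buffers <- c(buffers, paste0("bn_rmean_", k), paste0("bn_rvar_", k))
    }
    shapes$hidden_w <- c(nK * F, cfg$hidden_units)
    shapes$hidden_b <- c(cfg$hidden_units, 1L)
    shapes$out_w <- c(cfg$hidden_units, cfg$n_groups)
    shapes$out_b <- c(cfg$n_groups, 1L)
  }
  list(shapes = shapes, buffers = buffers)
}

trainable_names <- function(cfg) {
  ws <- weight_shapes(cfg)
  setdiff(names(ws$shapes), ws$buffers)
}

#' Count trainable parameters of a configuration
#'
#' Closed form matching the allocated weight arrays. For the embedding
#' variant: `(A+1)*D + sum_i F*(K_i*D + 1) + (|K|*F)*C + C`, where the extra
#' embedding row is the (frozen) padding row. For the baseline:
#' `sum_i F*(K_i*21 + 1) + |K|*2F + (|K|*F)*H + H + H*C + C` (batch-norm
#' scale/shift are trainable; running statistics are buffers and not counted).
#'
#' @param config An `og_config`.
#' @return Integer parameter count.
#' @examples
#' cfg <- model_config("ognet", n_groups = 4, embedding_dim = 2,
#'                     filter_sizes = 2, filters_per_size = 3)
#' count_parameters(cfg)  # 85
#' @export
count_parameters <- function(config) {
  F <- config$filters_per_size
  K <- config$filter_sizes
  nK <- length(K)
  C <- config$n_groups
  if (config$variant == "ognet") {
    D <- config$embedding_dim
    (config$alphabet_size + 1L) * D + sum(F * (K * D + 1L)) +
      (nK * F) * C + C
  } else {
    H <- config$hidden_units
    sum(F * (K * 21L + 1L)) + nK * 2L * F + (nK * F) * H + H + H * C + C
  }
}

#' Build a network with self-normalizing initialization
#'
#' Allocates all weight arrays for the configuration and initializes them:
#' convolution and affine weights from N(0, 1/fan_in), biases zero, embedding
#' rows standard normal (unit expected square norm per dimension) with the
#' padding row fixed at zero; batch-norm scale 1 / shift 0, running mean 0 /
#' variance 1 (baseline variant).
#'
#' @param config An `og_config`.
#' @param label_map An `og_label_map` with exactly `n_groups` entries.
#' @param seed Integer seed for the initialization draw.
#' @return An object of class `og_model`.
#' @export
build_model <- function(config, label_map, seed = 1L) {
  validate_config(config)
  if (length(label_map$group_ids) != config$n_groups) {
    stop(sprintf("label map has %d groups but config expects %d",
                 length(label_map$group_ids), config$n_groups))
  }
  ws <- weight_shapes(config)
  weights <- lapply(names(ws$shapes), function(nm) {
    sh <- ws$shapes[[nm]]
    if (sh[2] == 1L) numeric(sh[1]) else matrix(0, sh[1], sh[2])
  })
  names(weights) <- names(ws$shapes)
  alphabet <- if (config$variant == "ognet") extended_alphabet() else baseline_alphabet()
  model <- structure(
    list(config = config, label_map = label_map, alphabet = alphabet,
         weights = weights, history = NULL, trained = FALSE),
    class = "og_model"
  )
  initialize_self_normalizing(model, seed = seed)
}

#' Re-draw weights with the self-normalizing initialization
#'
#' Convolution and affine weights are drawn from a normal law with mean 0 and
#' variance 1/fan_in; biases are set to zero; embedding entries are standard
#' normal with the padding row kept at zero. This drives post-SELU activations
#' toward zero mean and unit variance at initialization.
#'
#' @param model An `og_model`.
#' @param seed Integer seed; identical seeds give identical weights.
#' @return The model with freshly initialized weights.
#' @export
initialize_self_normalizing <- function(model, seed = 1L) {
  cfg <- model$config
  F <- cfg$filters_per_size
  nK <- length(cfg$filter_sizes)
  in_channels <- if (cfg$variant == "ognet") cfg$embedding_dim else 21L
  with_seed(seed, {
    w <- model$weights
    if (cfg$variant == "ognet") {
      emb <- matrix(stats::rnorm((cfg$alphabet_size + 1L) * cfg$embedding_dim),
                    cfg$alphabet_size + 1L, cfg$embedding_dim)
      emb[1, ] <- 0  # padding row, frozen at zero
      w$embedding <- emb
    }
    for (k in cfg$filter_sizes) {
      fan_in <- k * in_channels
      w[[paste0("conv_w_", k)]] <- matrix(
        stats::rnorm(fan_in * F, sd = sqrt(1 / fan_in)), fan_in, F)
      w[[paste0("conv_b_", k)]] <- numeric(F)
      if (cfg$variant == "deepfam") {
        w[[paste0("bn_gamma_", k)]] <- rep(1, F)
        w[[paste0("bn_beta_", k)]] <- numeric(F)
        w[[paste0("bn_rmean_", k)]] <- numeric(F)
        w[[paste0("bn_rvar_", k)]] <- rep(1, F)
      }
    }
    nfeat <- nK * F
    if (cfg$variant == "ognet") {
      w$out_w <- matrix(stats::rnorm(nfeat * cfg$n_groups, sd = sqrt(1 / nfeat)),
                        nfeat, cfg$n_groups)
      w$out_b <- numeric(cfg$n_groups)
    } else {
      H <- cfg$hidden_units
      w$hidden_w <- matrix(stats::rnorm(nfeat * H, sd = sqrt(1 / nfeat)), nfeat, H)
      w$hidden_b <- numeric(H)
      w$out_w <- matrix(stats::rnorm(H * cfg$n_groups, sd = sqrt(1 / H)),
                        H, cfg$n_groups)
      w$out_b <- numeric(cfg$n_groups)
    }
    model$weights <- w
    model
  })
}

#' Forward pass: encoded batch to group logits
#'
#' For the `"ognet"` variant, pooling is masked to each sequence's valid
#' convolution windows, so the logits of a sequence do not depend on the
#' amount of trailing padding or on its batch companions. Dropout is active
#' only when `training = TRUE`.
#'
#' @param model An `og_model`.
#' @param batch An `og_batch` from [pad_and_batch()] (extended-alphabet
#'   integer encoding for both variants; the baseline converts to its
#'   fixed-length pseudo one-hot input internally).
#' @param training Logical; enables dropout (and, for the baseline,
#'   batch-statistics normalization and running-statistics updates).
#' @return Numeric logits matrix (batch x n_groups), columns named by group.
#' @export
forward <- function(model, batch, training = FALSE) {
  cfg <- model$config
  if (cfg$variant == "ognet") {
    res <- cpp_ognet_pass(model$weights, batch$matrix, batch$lengths,
                          cfg$filter_sizes, cfg$dropout, training,
                          integer(0), FALSE)
  } else {
    seqs <- lapply(seq_along(batch$lengths), function(b) {
      list(indices = batch$matrix[b, seq_len(batch$lengths[b])],
           length = batch$lengths[b])
    })
    X <- onehot_batch(seqs, cfg$fixed_length)
    res <- cpp_deepfam_pass(model$weights, X, cfg$filter_sizes, cfg$dropout,
                            training, integer(0), FALSE, 1e-5, 0.1)
  }
  logits <- res$logits
  colnames(logits) <- model$label_map$group_ids
  logits
}

#' Softmax probabilities from logits
#'
#' Numerically stable row-wise softmax. Each row sums to 1; the argmax of the
#' probabilities equals the argmax of the logits.
#'
#' @param logits Numeric matrix of finite logits.
#' @return Probability matrix of the same shape.
#' @examples
#' predict_proba(matrix(c(0, 0), 1))          # 0.5 0.5
#' predict_proba(matrix(log(c(1, 3)), 1))     # 0.25 0.75
#' @export
predict_proba <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  m <- apply(logits, 1, max)
  e <- exp(sweep(logits, 1, m))
  sweep(e, 1, rowSums(e), "/")
}

#' @export
print.og_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<og_model '%s'> variant=%s groups=%d filters=%dx%d params=%d %s\n",
              cfg$name, cfg$variant, cfg$n_groups, length(cfg$filter_sizes),
              cfg$filters_per_size, count_parameters(cfg),
              if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

#' @export
print.og_config <- function(x, ...) {
  cat(sprintf("<og_config> %s: D=%d K={%s} F=%d dropout=%.2f groups=%d",
              x$variant, x$embedding_dim,
              paste(x$filter_sizes, collapse = ","), x$filters_per_size,
              x$dropout, x$n_groups))
  if (x$variant == "deepfam") {
    cat(sprintf(" hidden=%d fixed_length=%d", x$hidden_units, x$fixed_length))
  }
  cat("\n")
  invisible(x)
}
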