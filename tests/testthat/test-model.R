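test_that("default configurations reproduce the published parametrizations", {
  og <- model_config("ognet", n_groups = 10)
  expect_identical(og$embedding_dim, 10L)
  expect_identical(og$filter_sizes, c(8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L))
  expect_identical(og$filters_per_size, 150L)
  expect_identical(og$hidden_units, 0L)
  expect_equal(og$dropout, 0.3)
  # feature vector size |K| * F
  m <- build_model(og, og_label_map(paste0("g", 1:10)), seed = 1)
  expect_identical(nrow(m$weights$out_w), 8L * 150L)

  best <- model_config("deepfam", n_groups = 10)
  expect_identical(length(best$filter_sizes) * best$filters_per_size, 2000L)
  expect_identical(best$hidden_units, 2000L)
  expect_identical(best$fixed_length, 1000L)
  light <- model_config("deepfam", n_groups = 10, parametrization = "light")
  expect_identical(light$filters_per_size, 150L)
  expect_identical(light$hidden_units, 1500L)
})

test_that("config invariants are enforced", {
  expect_error(model_config("ognet", n_groups = 10, hidden_units = 5),
               "no hidden layer")
  expect_error(model_config("ognet", n_groups = 1))
  expect_error(model_config("ognet", n_groups = 5,
                            filter_sizes = c(8L, 8L, 12L)))
  expect_error(model_config("deepfam", n_groups = 5, fixed_length = 10L))
})

test_that("embedding has one frozen zero row for padding", {
  m <- build_model(tiny_ognet_config(), tiny_label_map(), seed = 4)
  expect_identical(dim(m$weights$embedding), c(27L, 4L))
  expect_true(all(m$weights$embedding[1, ] == 0))
  expect_true(any(m$weights$embedding[-1, ] != 0))
})

test_that("count_parameters matches the closed form and brute force", {
  toy <- model_config("ognet", n_groups = 4, embedding_dim = 2,
                      filter_sizes = 2L, filters_per_size = 3L)
  expect_identical(count_parameters(toy), 85L)  # 54 + 3*5 + 3*4 + 4

  # doubling F doubles the convolution and classifier terms only
  toy2 <- model_config("ognet", n_groups = 4, embedding_dim = 2,
                       filter_sizes = 2L, filters_per_size = 6L)
  emb <- (26 + 1) * 2
  expect_identical(count_parameters(toy2) - emb,
                   2L * (count_parameters(toy) - emb) - 4L)  # out_b not doubled

  brute_force <- function(cfg) {
    m <- build_model(cfg, og_label_map(paste0("g", seq_len(cfg$n_groups))),
                     seed = 1)
    sum(vapply(ognet:::trainable_names(cfg),
               function(nm) length(m$weights[[nm]]), numeric(1)))
  }
  expect_identical(brute_force(model_config("ognet", n_groups = 7)),
                   as.numeric(count_parameters(model_config("ognet", n_groups = 7))))
  expect_identical(brute_force(tiny_deepfam_config()),
                   as.numeric(count_parameters(tiny_deepfam_config())))
})

test_that("logits are invariant to trailing padding and batch companions", {
  m <- build_model(tiny_ognet_config(), tiny_label_map(), seed = 8)
  recs <- random_records(6, seed = 21)
  enc <- lapply(recs$sequence, encode_sequence)

  solo <- forward(m, pad_and_batch(enc[1]))
  heavily_padded <- pad_and_batch(enc[1], min_length = 500)
  expect_identical(dim(heavily_padded$matrix), c(1L, 500L))
  expect_equal(forward(m, heavily_padded), solo, tolerance = 1e-5)

  together <- forward(m, pad_and_batch(enc))
  expect_equal(together[1, , drop = FALSE], solo, tolerance = 1e-5)

  # permuting batch rows permutes logit rows identically
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  permuted <- forward(m, pad_and_batch(enc[perm]))
  expect_equal(permuted, together[perm, ], tolerance = 1e-12)
})

test_that("each filter size K yields L - K + 1 convolution units", {
  cfg <- tiny_ognet_config()  # K = {2, 3}, F = 2
  m <- build_model(cfg, tiny_label_map(), seed = 8)
  batch <- pad_and_batch(list(encode_sequence(strrep("AC", 25))),
                         min_length = 3)
  acts <- ognet:::cpp_ognet_activations(m$weights, batch$matrix,
                                        batch$lengths, cfg$filter_sizes)
  expect_length(acts, ((50 - 2 + 1) + (50 - 3 + 1)) * 2L)
})

test_that("very short sequences give finite logits via zero-padding to K", {
  m <- build_model(tiny_ognet_config(), tiny_label_map(), seed = 8)
  one <- forward(m, pad_and_batch(list(encode_sequence("M"))))
  expect_true(all(is.finite(one)))
  expect_identical(dim(one), c(1L, 3L))
})

test_that("out-of-alphabet indices are rejected by the forward pass", {
  m <- build_model(tiny_ognet_config(), tiny_label_map(), seed = 8)
  batch <- pad_and_batch(list(encode_sequence("ACDEF")))
  batch$matrix[1, 2] <- 99L
  expect_error(forward(m, batch), "alphabet range")
})

test_that("predict_proba is a row-stochastic softmax preserving the argmax", {
  expect_equal(as.vector(predict_proba(matrix(c(0, 0), 1))), c(0.5, 0.5))
  expect_equal(as.vector(predict_proba(matrix(log(c(1, 3)), 1))), c(0.25, 0.75))
  ognet:::with_seed(5, {
    z <- matrix(rnorm(40, sd = 5), 8, 5)
    p <- predict_proba(z)
    expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
    expect_identical(max.col(p), max.col(z))
    expect_true(all(p > 0))
  })
})

test_that("analytic gradients match finite differences (ognet)", {
  cfg <- tiny_ognet_config()
  m <- build_model(cfg, tiny_label_map(), seed = 7)
  enc <- lapply(c("ACDEFGHIK", "MNPQ", "WYV"), encode_sequence)
  batch <- pad_and_batch(enc, min_length = 3)
  labels <- c(0L, 2L, 1L)
  loss_fn <- function(w) {
    ognet:::cpp_ognet_pass(w, batch$matrix, batch$lengths, cfg$filter_sizes,
                           0, TRUE, labels, FALSE)$loss
  }
  res <- ognet:::cpp_ognet_pass(m$weights, batch$matrix, batch$lengths,
                                cfg$filter_sizes, 0, TRUE, labels, TRUE)
  eps <- 1e-6
  for (nm in names(res$grads)) {
    w <- m$weights[[nm]]
    num <- numeric(length(w))
    for (j in seq_along(w)) {
      wp <- m$weights; wp[[nm]][j] <- w[j] + eps
      wm <- m$weights; wm[[nm]][j] <- w[j] - eps
      num[j] <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
    }
    expect_equal(as.vector(res$grads[[nm]]), num, tolerance = 1e-5,
                 label = paste("gradient of", nm))
  }
})

test_that("analytic gradients match finite differences (deepfam, batch norm)", {
  cfg <- tiny_deepfam_config()
  m <- build_model(cfg, tiny_label_map(), seed = 9)
  enc <- lapply(c("ACDEFGHIK", "MNPQ", "WYV"), encode_sequence)
  X <- ognet:::onehot_batch(enc, cfg$fixed_length)
  labels <- c(0L, 2L, 1L)
  loss_fn <- function(w) {
    ognet:::cpp_deepfam_pass(w, X, cfg$filter_sizes, 0, TRUE, labels, FALSE,
                             1e-5, 0.1)$loss
  }
  res <- ognet:::cpp_deepfam_pass(m$weights, X, cfg$filter_sizes, 0, TRUE,
                                  labels, TRUE, 1e-5, 0.1)
  eps <- 1e-6
  for (nm in names(res$grads)) {
    w <- m$weights[[nm]]
    num <- numeric(length(w))
    for (j in seq_along(w)) {
      wp <- m$weights; wp[[nm]][j] <- w[j] + eps
      wm <- m$weights; wm[[nm]][j] <- w[j] - eps
      num[j] <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
    }
    expect_equal(as.vector(res$grads[[nm]]), num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("model archives round trip bit-stably and validate shapes", {
  dir <- withr::local_tempdir()
  m <- build_model(tiny_ognet_config(), tiny_label_map(), seed = 12)
  recs <- random_records(4, seed = 31)
  before <- assign_groups(m, recs, threshold = 0)

  p1 <- file.path(dir, "m1.ognet")
  p2 <- file.path(dir, "m2.ognet")
  save_model(m, p1)
  loaded <- load_model(p1)
  save_model(loaded, p2)
  expect_identical(readLines(p1), readLines(p2))  # bit-stable round trip
  expect_equal(assign_groups(loaded, recs, threshold = 0), before)

  # tampered weight shape
  tampered <- loaded
  tampered$weights$out_w <- tampered$weights$out_w[, 1:2]
  p3 <- file.path(dir, "m3.ognet")
  tampered$config$n_groups <- 3L  # config still claims 3 groups
  save_model(tampered, p3)
  expect_error(load_model(p3), "out_w")

  # missing weight component
  lines <- readLines(p1)
  start <- grep("^>out_b ", lines)
  nxt <- grep("^(>|@end)", lines)
  stop_at <- min(nxt[nxt > start]) - 1L
  p4 <- file.path(dir, "m4.ognet")
  writeLines(lines[-(start:stop_at)], p4)
  expect_error(load_model(p4), "out_b")

  # label map inconsistent with group count
  lines5 <- readLines(p1)
  lines5[grep("^@labels$", lines5) + 1L] <- '["g0","g1"]'
  p5 <- file.path(dir, "m5.ognet")
  writeLines(lines5, p5)
  expect_error(load_model(p5), "label map")
})
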