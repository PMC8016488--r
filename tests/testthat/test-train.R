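test_that("minimum-population filtering removes whole groups", {
  labs <- tibble::tibble(
    id = sprintf("s%d", 1:8),
    group = c(rep("a", 5), rep("b", 2), "c"))
  f <- filter_min_population(labs, 2)
  expect_identical(sort(unique(f$labels$group)), c("a", "b"))
  expect_identical(nrow(f$labels), 7L)
  expect_identical(f$removed$group, "c")
  expect_identical(f$removed$n_sequences, 1L)

  expect_identical(filter_min_population(labs, 1)$labels, labs)
  expect_error(filter_min_population(labs, 6), "no group")
})

test_that("stratified split allocates 81/9/10 with largest remainders", {
  labs <- tibble::tibble(id = sprintf("s%03d", 1:100), group = "g")
  sp <- stratified_split(labs, seed = 3)
  expect_identical(as.integer(table(sp$split)), c(81L, 9L, 10L))

  tiny <- tibble::tibble(id = c("a", "b", "c"), group = "g")
  sp3 <- stratified_split(tiny, seed = 3)
  expect_identical(as.integer(table(sp3$split)), c(1L, 1L, 1L))

  two <- tibble::tibble(id = c("a", "b"), group = "g")
  expect_error(stratified_split(two, seed = 1), "filter_min_population")
})

test_that("splits are disjoint, exhaustive, stratified and seed-stable", {
  ognet:::with_seed(17, {
    sizes <- sample(3:40, 12, replace = TRUE)
    labs <- tibble::tibble(
      id = sprintf("s%04d", seq_len(sum(sizes))),
      group = rep(sprintf("g%02d", seq_along(sizes)), times = sizes))
  })
  sp1 <- stratified_split(labs, seed = 7)
  sp2 <- stratified_split(labs, seed = 7)
  sp3 <- stratified_split(labs, seed = 8)
  expect_identical(sp1, sp2)
  expect_identical(sort(sp1$id), sort(labs$id))
  expect_identical(anyDuplicated(sp1$id), 0L)
  # every group represented in all three partitions
  rep_tab <- table(sp1$group, sp1$split)
  expect_true(all(rep_tab >= 1))
  # different seed: same partition sizes per group, different permutation
  expect_identical(table(sp3$group, sp3$split), rep_tab)
  expect_false(identical(sp1$id[sp1$split == "test"],
                         sp3$id[sp3$split == "test"]))
})

test_that("the learning-rate schedule decays by 25% per epoch", {
  expect_equal(lr_schedule(training_config(), 0:3),
               c(0.01, 0.0075, 0.005625, 0.00421875))
})

test_that("self-normalizing initialization draws N(0, 1/fan_in) weights", {
  cfg <- model_config("ognet", n_groups = 4, embedding_dim = 10,
                      filter_sizes = 20L, filters_per_size = 500L)
  m <- build_model(cfg, og_label_map(paste0("g", 1:4)), seed = 31)
  w <- m$weights$conv_w_20  # 200 x 500 = 1e5 weights, fan_in = 200
  expect_equal(stats::var(as.vector(w)), 1 / 200, tolerance = 0.05)
  expect_equal(mean(as.vector(w)), 0, tolerance = 3 * sqrt(1 / 200 / 1e5))
  expect_true(all(m$weights$conv_b_20 == 0))
  expect_true(all(m$weights$out_b == 0))
  m2 <- build_model(cfg, og_label_map(paste0("g", 1:4)), seed = 31)
  expect_identical(m$weights, m2$weights)
})

test_that("training loss decreases when overfitting a repeated batch", {
  data <- separable_dataset(per_group = 8, seed = 9)
  split <- stratified_split(data$labels, seed = 9)
  lmap <- og_label_map(sort(unique(data$labels$group)))
  m <- train_model(build_model(tiny_ognet_config(n_groups = 2), lmap, seed = 9),
                   data$records, data$labels, split,
                   training_config(max_epochs = 3, batch_size = 16, seed = 9),
                   quiet = TRUE)
  expect_true(all(diff(m$history$train_loss) < 0))
  expect_identical(m$history$learning_rate, lr_schedule(training_config(), 0:2))
})

test_that("a linearly separable toy problem is learned within 5 epochs", {
  fx <- small_trained_model()
  train_ids <- fx$split$id[fx$split$split == "train"]
  pred <- assign_groups(fx$model, fx$data$records[fx$data$records$id %in%
                                                    train_ids, ],
                        threshold = 0)
  s <- score_assignments(pred, fx$data$labels)
  expect_identical(s$accuracy, 1)
  expect_equal(max(fx$model$history$validation_accuracy), 1)
  # the returned checkpoint is the best epoch on validation data
  expect_gte(fx$model$history$validation_accuracy[fx$model$best_epoch + 1],
             max(fx$model$history$validation_accuracy))
})

test_that("training is reproducible under fixed seeds", {
  data <- separable_dataset(per_group = 6, seed = 13)
  split <- stratified_split(data$labels, seed = 13)
  lmap <- og_label_map(sort(unique(data$labels$group)))
  run <- function() {
    train_model(build_model(tiny_ognet_config(n_groups = 2, dropout = 0.3),
                            lmap, seed = 13),
                data$records, data$labels, split,
                training_config(max_epochs = 2, batch_size = 8, seed = 13),
                quiet = TRUE)
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("the baseline discards sequences longer than its fixed length", {
  data <- separable_dataset(per_group = 8, seed = 15)
  # shrink the fixed length below some sequence lengths (60-90 range)
  cfg <- model_config("deepfam", n_groups = 2, filter_sizes = c(2L, 3L),
                      filters_per_size = 2L, hidden_units = 4L,
                      fixed_length = 75L)
  lmap <- og_label_map(sort(unique(data$labels$group)))
  lens <- nchar(data$records$sequence)
  expect_true(any(lens > 75) && any(lens <= 75))  # both cases present
  # keep validation ids short so only training sequences are discarded
  short <- data$records$id[lens <= 75]
  val_ids <- vapply(split(short, data$labels$group[match(short, data$labels$id)]),
                    `[`, character(1), 1)
  split_list <- list(train = setdiff(data$records$id, val_ids),
                     validation = unname(val_ids))
  expect_warning(
    train_model(build_model(cfg, lmap, seed = 15), data$records, data$labels,
                split_list,
                training_config(max_epochs = 1, batch_size = 8, seed = 15),
                quiet = TRUE),
    "discarded")
})

test_that("training aborts cleanly when the label map is incomplete", {
  data <- separable_dataset(per_group = 6, seed = 19)
  split <- stratified_split(data$labels, seed = 19)
  wrong_map <- og_label_map(c("SOG0001", "SOMETHINGELSE"))
  m <- build_model(tiny_ognet_config(n_groups = 2), wrong_map, seed = 19)
  expect_error(
    train_model(m, data$records, data$labels, split,
                training_config(max_epochs = 1, seed = 19), quiet = TRUE),
    "label map does not cover")
})
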