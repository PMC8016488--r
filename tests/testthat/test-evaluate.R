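test_that("the worked confusion-matrix example is reproduced exactly", {
  truth <- tibble::tibble(id = as.character(1:5),
                          group = c("g0", "g0", "g1", "g1", "g2"))
  pred <- tibble::tibble(id = as.character(1:5),
                         group = c("g0", "g1", "g1", "g1", "g2"))
  s <- score_assignments(pred, truth)
  expect_identical(s$accuracy, 0.8)
  expect_equal(s$macro_precision, 8 / 9)
  expect_equal(s$macro_recall, 5 / 6)
  expect_identical(s$per_group$support, c(2L, 2L, 1L))
})

test_that("perfect and degenerate predictions give boundary metrics", {
  truth <- tibble::tibble(id = as.character(1:6),
                          group = rep(c("a", "b"), each = 3))
  perfect <- score_assignments(truth, truth)
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$macro_precision, 1)
  expect_identical(perfect$macro_recall, 1)

  none <- truth
  none$group <- "unassigned"
  s <- score_assignments(none, truth)
  expect_identical(s$accuracy, 0)
  expect_identical(s$macro_recall, 0)
  expect_identical(s$macro_precision, 0)  # never-predicted groups score 0
})

test_that("score matches an independent confusion-matrix oracle", {
  ognet:::with_seed(202, {
    for (i in 1:25) {
      n_groups <- sample(2:6, 1)
      n <- sample(5:60, 1)
      groups <- paste0("g", seq_len(n_groups))
      true <- sample(groups, n, replace = TRUE)
      pred <- sample(c(groups, "unassigned"), n, replace = TRUE)
      ids <- as.character(seq_len(n))
      s <- score_assignments(tibble::tibble(id = ids, group = pred),
                             tibble::tibble(id = ids, group = true))
      o <- oracle_metrics(pred, true)
      expect_equal(s$accuracy, o$accuracy)
      expect_equal(s$macro_precision, o$macro_precision)
      expect_equal(s$macro_recall, o$macro_recall)
    }
  })
})

test_that("macro metrics are invariant to relabeling and row order", {
  ognet:::with_seed(77, {
    true <- sample(c("a", "b", "c"), 40, replace = TRUE)
    pred <- sample(c("a", "b", "c", "unassigned"), 40, replace = TRUE)
  })
  ids <- as.character(1:40)
  s <- score_assignments(tibble::tibble(id = ids, group = pred),
                         tibble::tibble(id = ids, group = true))
  relabel <- c(a = "zebra", b = "yak", c = "xerus", unassigned = "unassigned")
  s2 <- score_assignments(tibble::tibble(id = ids, group = unname(relabel[pred])),
                          tibble::tibble(id = ids, group = unname(relabel[true])))
  expect_equal(s$macro_precision, s2$macro_precision)
  expect_equal(s$macro_recall, s2$macro_recall)
  expect_equal(s$accuracy, s2$accuracy)

  shuffle <- sample(40)
  s3 <- score_assignments(tibble::tibble(id = ids[shuffle], group = pred[shuffle]),
                          tibble::tibble(id = ids, group = true))
  expect_equal(s3$accuracy, s$accuracy)
})

test_that("a prediction without a truth label is an error", {
  pred <- tibble::tibble(id = c("a", "b"), group = c("g", "g"))
  truth <- tibble::tibble(id = "a", group = "g")
  expect_error(score_assignments(pred, truth), "no truth label")
})

test_that("embedding export has one row per residue symbol", {
  m <- build_model(model_config("ognet", n_groups = 3, filters_per_size = 2L),
                   tiny_label_map(), seed = 51)
  emb <- export_embeddings(m)
  expect_identical(nrow(emb), 26L)
  expect_identical(ncol(emb), 11L)  # symbol + D = 10 values
  expect_identical(emb$symbol, extended_alphabet()$symbols)
  expect_equal(as.matrix(emb[, -1]), m$weights$embedding[-1, ],
               ignore_attr = TRUE)
  df <- build_model(tiny_deepfam_config(), tiny_label_map(), seed = 51)
  expect_error(export_embeddings(df), "no learned embedding")
})

test_that("in/out-model analysis enforces disjointness and counts add up", {
  fx <- small_trained_model()
  in_recs <- fx$data$records[1:10, ]
  out_recs <- random_records(12, seed = 61)
  out_truth <- tibble::tibble(id = out_recs$id, group = "XOG1")
  res <- in_out_model_analysis(fx$model, in_recs, out_recs, out_truth,
                               threshold = 0.99)
  expect_identical(res$summary$n_above + res$summary$n_below, res$summary$n)
  expect_identical(res$summary$n, c(10L, 12L))
  expect_identical(sum(res$in_hist$count), 10L)
  expect_identical(sum(res$out_hist$count), 12L)

  bad_truth <- tibble::tibble(id = out_recs$id, group = "SOG0001")
  expect_error(
    in_out_model_analysis(fx$model, in_recs, out_recs, bad_truth),
    "overlap")
})

test_that("tidiers and plots expose model and score results", {
  fx <- small_trained_model()
  h <- generics::tidy(fx$model)
  expect_identical(names(h), c("epoch", "learning_rate", "train_loss",
                               "validation_accuracy"))
  g <- generics::glance(fx$model)
  expect_identical(g$variant, "ognet")
  expect_identical(g$n_parameters, count_parameters(fx$model$config))

  pred <- assign_groups(fx$model, fx$data$records[1:10, ], threshold = 0)
  s <- score_assignments(pred, fx$data$labels)
  expect_identical(generics::tidy(s), s$per_group)
  expect_identical(generics::glance(s)$accuracy, s$accuracy)

  expect_s3_class(ggplot2::autoplot(fx$model), "ggplot")
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
  expect_s3_class(ggplot2::autoplot(confidence_histogram(pred)), "ggplot")
})
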