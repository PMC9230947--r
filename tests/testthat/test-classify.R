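test_that("sequence assembly pads, truncates, and masks as stated", {
  f10 <- fake_features(10)
  s <- assemble_sequence(f10, 16, label = "neutral")
  expect_equal(dim(s$rows), c(16, 74))
  expect_equal(sum(s$mask), 10)
  expect_true(all(s$rows[11:16, ] == 0))

  f20 <- fake_features(20)
  s2 <- assemble_sequence(f20, 16)
  expect_equal(sum(s2$mask), 16)

  # truncation keeps the highest-prominence rows in original order
  f <- fake_features(6)
  f$prominence <- c(10, 90, 20, 80, 30, 70)
  s3 <- assemble_sequence(f, 3)
  expect_equal(s3$rows[1:3, 1], f$x[c(2, 4, 6)])

  expect_warning(s0 <- assemble_sequence(f10[0, ], 8), "all-padding")
  expect_equal(sum(s0$mask), 0)
})

test_that("the cell-state update obeys its limit cases exactly", {
  c_prev <- c(0.3, -1.2, 4)
  cand <- c(1, 2, 3)
  expect_identical(lstm_cell_state(1, 0, c_prev, cand), c_prev)
  expect_identical(lstm_cell_state(0, 1, c_prev, cand), cand)
  # generic update is the elementwise convex-free combination
  expect_equal(lstm_cell_state(0.5, 0.25, c_prev, cand),
               0.5 * c_prev + 0.25 * cand)
  expect_error(lstm_cell_state(1.5, 0, c_prev, cand), "\\[0, 1\\]")
})

test_that("model construction is deterministic and outputs probabilities", {
  cfg <- train_config(c("a", "b", "c"), max_landmarks = 6, hidden_size = 8,
                      conv_channels = c(4), rng_seed = 5)
  m1 <- suppressMessages(build_model(cfg))
  m2 <- suppressMessages(build_model(cfg))
  expect_identical(m1$params, m2$params)
  expect_gt(m1$param_count, 0)

  seqs <- fake_sequence_dataset(2, max_landmarks = 6, seed = 2)
  pr <- predict(m1, seqs)
  expect_equal(rowSums(as.matrix(pr[, 1:3])), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pr$.pred %in% c("a", "b", "c")))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- train_config(c("a", "b"), max_landmarks = 3, hidden_size = 4,
                      conv_channels = c(2), feature_len = 8, rng_seed = 3)
  m <- suppressMessages(build_model(cfg))
  withr::with_seed(4, {
    X <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
    mask <- matrix(1, 3, 3)
    mask[3, 3] <- 0  # exercise the padding path
    y <- c(1L, 2L, 1L)
  })
  lg <- facemark:::nn_loss_grads(m, X, mask, y)
  eps <- 1e-5
  probe <- function(path, idx) {
    set_leaf <- function(p, v) {
      if (length(path) == 2) p[[path[[1]]]][[path[[2]]]] <- v
      if (length(path) == 3) p[[path[[1]]]][[path[[2]]]][[path[[3]]]] <- v
      p
    }
    leaf <- Reduce(`[[`, path, m$params)
    mp <- m
    leaf[idx] <- leaf[idx] + eps
    mp$params <- set_leaf(m$params, leaf)
    lp <- facemark:::nn_loss_grads(mp, X, mask, y)$loss
    leaf[idx] <- leaf[idx] - 2 * eps
    mp$params <- set_leaf(m$params, leaf)
    lm_ <- facemark:::nn_loss_grads(mp, X, mask, y)$loss
    num <- (lp - lm_) / (2 * eps)
    ana <- Reduce(`[[`, path, lg$grads)[idx]
    expect_equal(ana, num, tolerance = 1e-4,
                 info = paste(unlist(path), collapse = "/"))
  }
  withr::with_seed(6, {
    for (path in list(list("out", "W"), list("out", "b"),
                      list("lstm", "Wx"), list("lstm", "Wh"), list("lstm", "b"),
                      list("conv", 1L, "W"), list("conv", 1L, "b"))) {
      leaf <- Reduce(`[[`, path, m$params)
      for (idx in sample(length(leaf), min(4, length(leaf)))) probe(path, idx)
    }
  })
})

test_that("training separates shifted classes and refuses degenerate input", {
  seqs <- fake_sequence_dataset(20, max_landmarks = 8, seed = 9)
  cfg <- train_config(c("classA", "classB"), max_landmarks = 8,
                      hidden_size = 8, conv_channels = c(4), epochs = 15,
                      batch_size = 8, learning_rate = 0.01, rng_seed = 9)
  test_idx <- seq(1, 40, by = 4)
  m <- suppressMessages(build_model(cfg)) |> train_model(seqs[-test_idx])
  h <- tidy(m)
  expect_equal(nrow(h), 15)
  expect_lt(h$loss[5], h$loss[1])  # loss decreases on separable data
  ev <- evaluate_model(m, seqs[test_idx])
  expect_gt(ev$accuracy, 0.9)
  expect_equal(sum(ev$confusion), length(test_idx))

  # training twice from the same seed reproduces the history exactly
  m2 <- suppressMessages(build_model(cfg)) |> train_model(seqs[-test_idx])
  expect_identical(tidy(m2), h)

  onecls <- seqs[1:20]
  expect_error(train_model(suppressMessages(build_model(cfg)), onecls),
               "two classes")
  bad <- seqs
  bad[[1]]$label <- "notaclass"
  expect_error(train_model(suppressMessages(build_model(cfg)), bad),
               "class_names")
})

test_that("metrics match hand computation on a 3-class toy confusion", {
  truth <- c(rep("a", 4), rep("b", 3), rep("c", 3))
  pred <- c("a", "a", "b", "c", "b", "b", "a", "c", "c", "c")
  ev <- classification_metrics(truth, pred, c("a", "b", "c"))
  # confusion: a -> (2,1,1); b -> (1,2,0); c -> (0,0,3)
  expect_equal(unname(ev$confusion["a", ]), c(2, 1, 1))
  expect_equal(unname(rowSums(ev$confusion)), c(4, 3, 3))  # row sums = support
  expect_equal(ev$accuracy, 7 / 10)
  ma <- ev$metrics[ev$metrics$class == "a", ]
  expect_equal(ma$precision, 2 / 3)  # 2 of 3 predicted-a are true a
  expect_equal(ma$recall, 2 / 4)
  expect_equal(ma$f1, 2 * (2 / 3) * (1 / 2) / ((2 / 3) + (1 / 2)))
  mc <- ev$metrics[ev$metrics$class == "c", ]
  expect_equal(mc$precision, 3 / 4)  # 4 predicted c, 3 truly c
  expect_equal(mc$recall, 1)

  # perfect predictions give all-1 metrics
  perfect <- classification_metrics(truth, truth, c("a", "b", "c"))
  expect_true(all(perfect$metrics$precision == 1))
  expect_true(all(perfect$metrics$recall == 1))
  expect_equal(perfect$accuracy, 1)
  expect_error(evaluate_model(
    suppressMessages(build_model(train_config(c("a", "b")))), list()
  ), "empty")
})

test_that("tidiers expose history and summary rows", {
  cfg <- train_config(c("classA", "classB"), max_landmarks = 4, hidden_size = 4,
                      conv_channels = c(2), epochs = 2, batch_size = 4,
                      rng_seed = 1)
  m <- suppressMessages(build_model(cfg))
  expect_equal(nrow(tidy(m)), 0)
  g <- glance(m)
  expect_equal(g$epochs_trained, 0)
  expect_equal(g$parameters, m$param_count)
  seqs <- fake_sequence_dataset(4, max_landmarks = 4, seed = 3)
  m <- train_model(m, seqs)
  expect_equal(glance(m)$epochs_trained, 2)
  ev <- evaluate_model(m, seqs)
  expect_equal(nrow(tidy(ev)), 2)
  expect_true(all(c("accuracy", "macro_f1", "n") %in% names(glance(ev))))
})
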