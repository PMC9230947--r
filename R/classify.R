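#' Training configuration for the emotion classifier
#'
#' @param class_names Emotion labels the model predicts (>= 2).
#' @param max_landmarks Sequence length: landmark rows per image after
#'   padding/truncation.
#' @param hidden_size LSTM hidden units.
#' @param conv_channels Channels of the 1-D convolutional layers applied
#'   along each landmark's 74-value feature axis (kernel 3, ReLU, max
#'   pool 2 after each layer).
#' @param epochs,batch_size,learning_rate Optimization settings (Adam,
#'   categorical cross-entropy).
#' @param rng_seed Seed for weight initialization and batch shuffling.
#' @param feature_len Per-landmark feature length (74 = x, y + 72 HOG
#'   values).
#' @return A list of class `train_config`.
#' @export
train_config <- function(class_names, max_landmarks = 64, hidden_size = 64,
                         conv_channels = c(32, 64), epochs = 30,
                         batch_size = 32, learning_rate = 1e-3,
                         rng_seed = 1L, feature_len = 74) {
  stopifnot(length(class_names) >= 1, max_landmarks >= 1, hidden_size >= 1,
            all(conv_channels >= 1), epochs >= 1, batch_size >= 1,
            learning_rate > 0, feature_len >= 4)
  structure(list(
    class_names = as.character(class_names),
    max_landmarks = as.integer(max_landmarks),
    hidden_size = as.integer(hidden_size),
    conv_channels = as.integer(conv_channels),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, rng_seed = as.integer(rng_seed),
    feature_len = as.integer(feature_len)
  ), class = "train_config")
}

#' Assemble one image's landmark features into a fixed-length sequence
#'
#' Rows beyond `max_landmarks` are dropped lowest-prominence first (the
#' method's own saliency measure) while preserving detection order among
#' the kept rows; missing rows are zero-padded and flagged in the mask.
#'
#' @param features Tibble from [landmark_features()] (columns `x`, `y`,
#'   `d1`..`d72`, optionally `prominence`).
#' @param max_landmarks Fixed sequence length.
#' @param label Optional emotion label.
#' @param image_id Optional identifier.
#' @return List of class `feature_sequence`: `rows`
#'   (`max_landmarks x 74` matrix), `mask` (logical), `label`,
#'   `image_id`.
#' @export
assemble_sequence <- function(features, max_landmarks = 64,
                              label = NA_character_,
                              image_id = NA_character_) {
  cols <- c("x", "y", paste0("d", 1:72))
  if (!nrow(features)) {
    warn(sprintf("no landmarks for image %s: all-padding sequence", image_id))
    m <- matrix(0, max_landmarks, 74)
  } else {
    keep <- seq_len(nrow(features))
    if (nrow(features) > max_landmarks) {
      rank_by <- if ("prominence" %in% names(features)) {
        -features$prominence
      } else {
        seq_len(nrow(features))
      }
      keep <- sort(order(rank_by)[seq_len(max_landmarks)])
    }
    m <- matrix(0, max_landmarks, 74)
    m[seq_along(keep), ] <- as.matrix(features[keep, cols])
  }
  n_real <- if (nrow(features)) min(nrow(features), max_landmarks) else 0L
  structure(list(
    rows = m,
    mask = seq_len(max_landmarks) <= n_real,
    label = label, image_id = image_id
  ), class = "feature_sequence")
}

#' Standard LSTM cell-state update
#'
#' `c_t = f_t * c_{t-1} + i_t * c~_t`: the forget gate scales the prior
#' long-term memory and the input gate scales the candidate state. With
#' `f = 1, i = 0` the cell carries over unchanged; with `f = 0, i = 1` it
#' becomes the candidate.
#'
#' @param f_t,i_t Forget and input gate activations in `[0, 1]`.
#' @param c_prev Prior cell state.
#' @param c_tilde Candidate cell state.
#' @return The new cell state.
#' @export
lstm_cell_state <- function(f_t, i_t, c_prev, c_tilde) {
  if (any(f_t < 0 | f_t > 1) || any(i_t < 0 | i_t > 1)) {
    abort("gate activations must lie in [0, 1]")
  }
  f_t * c_prev + i_t * c_tilde
}

#' Build the CNN + LSTM emotion classifier
#'
#' Per landmark (timestep), 1-D convolutions (kernel 3, same padding,
#' ReLU, max-pool 2) run along the 74-value feature axis and are
#' flattened; an LSTM then consumes the landmark sequence, and its final
#' hidden state feeds a dense softmax over the class names. Weights are
#' initialized deterministically from `rng_seed`; the parameter count is
#' reported at build time.
#'
#' @param config A [train_config()].
#' @return A list of class `facemark_model` (untrained).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "train_config"))
  with_seed(config$rng_seed, {
    params <- list(conv = list(), lstm = NULL, out = NULL)
    len <- config$feature_len
    cin <- 1L
    for (cout in config$conv_channels) {
      sd <- sqrt(2 / (3 * cin))
      params$conv[[length(params$conv) + 1]] <- list(
        W = array(rnorm(3 * cin * cout, 0, sd), c(3, cin, cout)),
        b = numeric(cout)
      )
      len <- len %/% 2L
      cin <- cout
    }
    if (len < 1) abort("too many conv/pool layers for the feature length")
    D <- len * cin
    H <- config$hidden_size
    b_lstm <- numeric(4 * H)
    b_lstm[H + 1:H] <- 1  # forget-gate bias: remember by default
    params$lstm <- list(
      Wx = matrix(rnorm(D * 4 * H, 0, 1 / sqrt(D)), D, 4 * H),
      Wh = matrix(rnorm(H * 4 * H, 0, 1 / sqrt(H)), H, 4 * H),
      b = b_lstm
    )
    K <- length(config$class_names)
    params$out <- list(W = matrix(rnorm(H * K, 0, 1 / sqrt(H)), H, K),
                       b = numeric(K))
    n_par <- length(unlist(params))
    inform(sprintf("facemark model built: %d parameters (conv %s, D=%d, H=%d, K=%d)",
                   n_par, paste(config$conv_channels, collapse = "/"), D, H, K))
    structure(list(config = config, params = params, flat_dim = D,
                   param_count = n_par, history = NULL, fitted = FALSE),
              class = "facemark_model")
  })
}

## ---- network internals (forward / backward) --------------------------------

sigm <- function(x) 1 / (1 + exp(-x))

conv_forward <- function(A, W, b) {
  d <- dim(A)
  R <- d[1]; L <- d[2]; cin <- d[3]; cout <- dim(W)[3]
  Ap <- array(0, c(R, L + 2, cin))
  Ap[, 2:(L + 1), ] <- A
  Zm <- matrix(b, R * L, cout, byrow = TRUE)
  for (kk in 1:3) {
    S <- Ap[, kk:(kk + L - 1), , drop = FALSE]
    dim(S) <- c(R * L, cin)
    Zm <- Zm + S %*% matrix(W[kk, , ], cin, cout)
  }
  array(Zm, c(R, L, cout))
}

conv_backward <- function(A, W, dZ) {
  d <- dim(A)
  R <- d[1]; L <- d[2]; cin <- d[3]; cout <- dim(W)[3]
  dZm <- dZ
  dim(dZm) <- c(R * L, cout)
  Ap <- array(0, c(R, L + 2, cin))
  Ap[, 2:(L + 1), ] <- A
  dAp <- array(0, c(R, L + 2, cin))
  dW <- array(0, dim(W))
  for (kk in 1:3) {
    S <- Ap[, kk:(kk + L - 1), , drop = FALSE]
    dim(S) <- c(R * L, cin)
    dW[kk, , ] <- crossprod(S, dZm)
    dS <- dZm %*% t(matrix(W[kk, , ], cin, cout))
    dim(dS) <- c(R, L, cin)
    dAp[, kk:(kk + L - 1), ] <- dAp[, kk:(kk + L - 1), , drop = FALSE] + dS
  }
  list(dA = dAp[, 2:(L + 1), , drop = FALSE], dW = dW, db = colSums(dZm))
}

maxpool_forward <- function(A) {
  L <- dim(A)[2]
  Lp <- L %/% 2L
  A1 <- A[, seq(1, 2 * Lp, 2), , drop = FALSE]
  A2 <- A[, seq(2, 2 * Lp, 2), , drop = FALSE]
  list(out = pmax(A1, A2), take1 = A1 >= A2, L_in = L)
}

maxpool_backward <- function(dOut, take1, L_in) {
  d <- dim(dOut)
  dIn <- array(0, c(d[1], L_in, d[3]))
  dIn[, seq(1, 2 * d[2], 2), ] <- dOut * take1
  dIn[, seq(2, 2 * d[2], 2), ] <- dOut * !take1
  dIn
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass over a batch. X: N x T x F array; mask: N x T in {0,1}.
nn_forward <- function(model, X, mask) {
  p <- model$params
  cfg <- model$config
  N <- dim(X)[1]; Tn <- dim(X)[2]; Fn <- dim(X)[3]
  R <- N * Tn
  A <- X
  dim(A) <- c(R, Fn)
  A <- array(A, c(R, Fn, 1))
  conv_cache <- vector("list", length(p$conv))
  for (l in seq_along(p$conv)) {
    Z <- conv_forward(A, p$conv[[l]]$W, p$conv[[l]]$b)
    Arelu <- pmax(Z, 0)
    pool <- maxpool_forward(Arelu)
    conv_cache[[l]] <- list(A_in = A, Z = Z, take1 = pool$take1, L_in = pool$L_in)
    A <- pool$out
  }
  D <- dim(A)[2] * dim(A)[3]
  Phi <- A
  dim(Phi) <- c(R, D)
  H <- cfg$hidden_size
  h <- matrix(0, N, H)
  cc <- matrix(0, N, H)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- Phi[(t - 1) * N + seq_len(N), , drop = FALSE]
    z <- Xt %*% p$lstm$Wx + h %*% p$lstm$Wh +
      matrix(p$lstm$b, N, 4 * H, byrow = TRUE)
    i_g <- sigm(z[, seq_len(H), drop = FALSE])
    f_g <- sigm(z[, H + seq_len(H), drop = FALSE])
    g_g <- tanh(z[, 2 * H + seq_len(H), drop = FALSE])
    o_g <- sigm(z[, 3 * H + seq_len(H), drop = FALSE])
    c_new <- lstm_cell_state(f_g, i_g, cc, g_g)
    h_new <- o_g * tanh(c_new)
    m <- mask[, t]
    steps[[t]] <- list(Xt = Xt, h_prev = h, c_prev = cc, i = i_g, f = f_g,
                       g = g_g, o = o_g, c_new = c_new, m = m)
    h <- m * h_new + (1 - m) * h
    cc <- m * c_new + (1 - m) * cc
  }
  logits <- h %*% p$out$W + matrix(p$out$b, N, ncol(p$out$W), byrow = TRUE)
  list(probs = softmax_rows(logits), h_final = h,
       conv_cache = conv_cache, steps = steps, Phi = Phi,
       dims = c(N = N, T = Tn, F = Fn, D = D))
}

# Cross-entropy loss and full gradients for one batch. y: integer class
# index per sample.
nn_loss_grads <- function(model, X, mask, y) {
  p <- model$params
  fw <- nn_forward(model, X, mask)
  N <- fw$dims[["N"]]; Tn <- fw$dims[["T"]]; D <- fw$dims[["D"]]
  H <- model$config$hidden_size
  K <- ncol(p$out$W)
  onehot <- matrix(0, N, K)
  onehot[cbind(seq_len(N), y)] <- 1
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(N), y)], 1e-12)))

  dlogits <- (fw$probs - onehot) / N
  g <- list(conv = vector("list", length(p$conv)),
            lstm = list(Wx = 0 * p$lstm$Wx, Wh = 0 * p$lstm$Wh, b = 0 * p$lstm$b),
            out = list(W = crossprod(fw$h_final, dlogits), b = colSums(dlogits)))
  dh <- dlogits %*% t(p$out$W)
  dc <- matrix(0, N, H)
  dPhi <- matrix(0, N * Tn, D)
  for (t in rev(seq_len(Tn))) {
    s <- fw$steps[[t]]
    m <- s$m
    dh_new <- m * dh
    dh_skip <- (1 - m) * dh
    dc_new <- m * dc
    dc_skip <- (1 - m) * dc
    tc <- tanh(s$c_new)
    do_g <- dh_new * tc
    dc_new <- dc_new + dh_new * s$o * (1 - tc^2)
    df <- dc_new * s$c_prev
    di <- dc_new * s$g
    dg <- dc_new * s$i
    dc <- dc_new * s$f + dc_skip
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_g * s$o * (1 - s$o))
    g$lstm$Wx <- g$lstm$Wx + crossprod(s$Xt, dz)
    g$lstm$Wh <- g$lstm$Wh + crossprod(s$h_prev, dz)
    g$lstm$b <- g$lstm$b + colSums(dz)
    dPhi[(t - 1) * N + seq_len(N), ] <- dz %*% t(p$lstm$Wx)
    dh <- dz %*% t(p$lstm$Wh) + dh_skip
  }
  lastc <- if (length(model$config$conv_channels)) {
    model$config$conv_channels[length(model$config$conv_channels)]
  } else {
    1L
  }
  dA <- array(dPhi, c(N * Tn, D / lastc, lastc))
  for (l in rev(seq_along(p$conv))) {
    cch <- fw$conv_cache[[l]]
    dRelu <- maxpool_backward(dA, cch$take1, cch$L_in)
    dZ <- dRelu * (cch$Z > 0)
    cb <- conv_backward(cch$A_in, p$conv[[l]]$W, dZ)
    g$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dA
  }
  list(loss = loss, grads = g, probs = fw$probs)
}

# Recursive Adam update over the nested parameter list.
adam_step <- function(params, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        if (is.null(nm) || nm == "") next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      if (is.null(names(p))) {
        for (k in seq_along(p)) {
          r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
          out$p[[k]] <- r$p; out$m[[k]] <- r$m; out$v[[k]] <- r$v
        }
      }
      out
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mh <- m2 / (1 - beta1^step)
      vh <- v2 / (1 - beta2^step)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  upd(params, grads, state$m, state$v)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

# Stack feature sequences into the arrays the network consumes.
sequences_to_arrays <- function(dataset, cfg) {
  N <- length(dataset)
  Tn <- cfg$max_landmarks
  Fn <- cfg$feature_len
  X <- array(0, c(N, Tn, Fn))
  mask <- matrix(0, N, Tn)
  labels <- character(N)
  for (i in seq_len(N)) {
    s <- dataset[[i]]
    stopifnot(inherits(s, "feature_sequence"))
    nr <- min(nrow(s$rows), Tn)
    X[i, seq_len(nr), ] <- s$rows[seq_len(nr), seq_len(Fn)]
    mask[i, seq_len(nr)] <- as.numeric(s$mask[seq_len(nr)])
    labels[i] <- s$label
  }
  list(X = X, mask = mask, labels = labels)
}

#' Train the emotion classifier
#'
#' Mini-batch Adam on categorical cross-entropy; deterministic given the
#' config seed (single-threaded). Per-epoch loss and training accuracy
#' are recorded in the model's history.
#'
#' @param model An untrained (or previously trained) [build_model()]
#'   result.
#' @param dataset List of labelled [assemble_sequence()] results covering
#'   at least two classes.
#' @param epochs Override of the config's epoch count.
#' @return The fitted `facemark_model` with a `history` tibble
#'   (`epoch`, `loss`, `accuracy`).
#' @export
train_model <- function(model, dataset, epochs = NULL) {
  stopifnot(inherits(model, "facemark_model"))
  cfg <- model$config
  arr <- sequences_to_arrays(dataset, cfg)
  y <- match(arr$labels, cfg$class_names)
  if (anyNA(y)) abort("dataset contains labels outside the config's class_names")
  if (length(unique(y)) < 2) abort("training needs at least two classes present")
  epochs <- epochs %||% cfg$epochs
  N <- length(y)
  state <- list(m = zero_like(model$params), v = zero_like(model$params))
  hist <- vector("list", epochs)
  step <- 0L
  with_seed(cfg$rng_seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      losses <- c()
      correct <- 0L
      for (b0 in seq(1, N, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, N)]
        lg <- nn_loss_grads(model,
                            arr$X[idx, , , drop = FALSE],
                            arr$mask[idx, , drop = FALSE],
                            y[idx])
        step <- step + 1L
        r <- adam_step(model$params, lg$grads, state, cfg$learning_rate, step)
        model$params <- r$p
        state$m <- r$m
        state$v <- r$v
        losses <- c(losses, lg$loss * length(idx))
        correct <- correct + sum(max.col(lg$probs, ties.method = "first") == y[idx])
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, loss = sum(losses) / N,
                                   accuracy = correct / N)
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model$fitted <- TRUE
  model
}

#' Predict emotions for feature sequences
#'
#' @param object A trained `facemark_model`.
#' @param dataset A single `feature_sequence` or a list of them.
#' @param ... Unused.
#' @return Tibble with one row per sequence: per-class probability
#'   columns (`.prob_<class>`) and the argmax `.pred`.
#' @export
predict.facemark_model <- function(object, dataset, ...) {
  if (inherits(dataset, "feature_sequence")) dataset <- list(dataset)
  arr <- sequences_to_arrays(dataset, object$config)
  fw <- nn_forward(object, arr$X, arr$mask)
  probs <- fw$probs
  colnames(probs) <- paste0(".prob_", object$config$class_names)
  out <- tibble::as_tibble(probs)
  out$.pred <- object$config$class_names[max.col(probs, ties.method = "first")]
  out
}

#' Evaluate the classifier on a labelled dataset
#'
#' Standard one-vs-rest precision, recall and F1 per class, overall
#' accuracy, and the confusion matrix (rows = true class).
#'
#' @param model Trained `facemark_model`.
#' @param dataset Non-empty list of labelled feature sequences.
#' @return List of class `facemark_evaluation`: `metrics` (per-class
#'   tibble), `confusion` (matrix), `accuracy`.
#' @export
evaluate_model <- function(model, dataset) {
  if (!length(dataset)) abort("cannot evaluate on an empty dataset")
  preds <- predict(model, dataset)
  truth <- vapply(dataset, function(s) s$label, character(1))
  classification_metrics(truth, preds$.pred, model$config$class_names)
}

#' Classification metrics from labelled predictions
#'
#' @param truth,predicted Character vectors of true and predicted labels.
#' @param classes Full label set (fixes the confusion-matrix order).
#' @return List of class `facemark_evaluation`: per-class `metrics`
#'   tibble, `confusion` matrix (rows = true class), overall `accuracy`.
#' @export
#' @examples
#' classification_metrics(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
classification_metrics <- function(truth, predicted, classes) {
  conf <- table(factor(truth, classes), factor(predicted, classes))
  conf <- matrix(conf, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  metrics <- purrr::map_dfr(seq_along(classes), function(k) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = classes[k], support = tp + fn,
                   precision = prec, recall = rec, f1 = f1)
  })
  structure(list(metrics = metrics, confusion = conf,
                 accuracy = sum(diag(conf)) / sum(conf)),
            class = "facemark_evaluation")
}

## ---- broom-style methods ----------------------------------------------------

#' @exportS3Method generics::tidy
tidy.facemark_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = double(),
                                accuracy = double())
}

#' @exportS3Method generics::glance
glance.facemark_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    parameters = x$param_count,
    classes = length(x$config$class_names),
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_accuracy = if (is.null(h)) NA_real_ else h$accuracy[nrow(h)]
  )
}

#' @exportS3Method generics::tidy
tidy.facemark_evaluation <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.facemark_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_f1 = mean(x$metrics$f1),
                 n = sum(x$confusion))
}

#' @exportS3Method ggplot2::autoplot
autoplot.facemark_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "training history")
}

#' @export
print.facemark_model <- function(x, ...) {
  cat(sprintf("<facemark_model> %s, %d parameters, classes: %s\n",
              if (x$fitted) "fitted" else "untrained", x$param_count,
              paste(x$config$class_names, collapse = ", ")))
  invisible(x)
}

#' @export
print.facemark_evaluation <- function(x, ...) {
  cat(sprintf("<facemark_evaluation> accuracy %.3f on %d sequences\n",
              x$accuracy, sum(x$confusion)))
  print(x$metrics)
  invisible(x)
}
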