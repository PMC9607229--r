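# Deep regressors -------------------------------------------------------------
#
# Natively implemented 1-D CNN and LSTM scalar regressors with analytic
# backpropagation (C++ core) and Adam training. The winning configurations are
# the defaults: CNN with two blocks of 8 filters of length 10 plus a
# 10-neuron fully connected layer; LSTM with a single 150-unit layer. Both use
# dropout p = 0.5 and L2 regularization lambda = 1e-4, trained with Adam at an
# initial learning rate of 0.01 under a mean-square-error loss.

#' CNN architecture specification
#'
#' @param n_filters number of filters per convolution block.
#' @param filter_length temporal filter length per block.
#' @param fc_neurons width of the fully connected layer before the linear
#'   output.
#' @param dropout_p dropout probability (applied once, before the fully
#'   connected layer).
#' @return list of class `cnn_spec`.
#' @export
cnn_spec <- function(n_filters = c(8, 8), filter_length = c(10, 10),
                     fc_neurons = 10, dropout_p = 0.5) {
  if (length(n_filters) != length(filter_length))
    stop("`n_filters` and `filter_length` must align", call. = FALSE)
  if (any(n_filters < 1) || any(filter_length < 1) || fc_neurons < 1)
    stop("filters, lengths and fc width must be >= 1", call. = FALSE)
  structure(list(n_filters = as.integer(n_filters),
                 filter_length = as.integer(filter_length),
                 fc_neurons = as.integer(fc_neurons), dropout_p = dropout_p),
            class = "cnn_spec")
}

#' LSTM architecture specification
#'
#' @param hidden vector of hidden sizes, one per recurrent layer.
#' @param fc_neurons optional fully connected layer width (0 = none; the scalar
#'   output layer is always present).
#' @param dropout_p dropout probability after each recurrent layer.
#' @return list of class `lstm_spec`.
#' @export
lstm_spec <- function(hidden = 150, fc_neurons = 0, dropout_p = 0.5) {
  if (length(hidden) < 1 || any(hidden < 1))
    stop("`hidden` must list at least one positive layer size", call. = FALSE)
  structure(list(hidden = as.integer(hidden), fc_neurons = as.integer(fc_neurons),
                 dropout_p = dropout_p),
            class = "lstm_spec")
}

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# minimum window length a CNN spec admits (each block needs >= filter_length
# samples, pooling halves the length)
cnn_min_window <- function(spec) {
  need <- 1
  for (i in rev(seq_along(spec$n_filters)))
    need <- 2 * need + spec$filter_length[i] - 1
  need
}

#' Build an untrained CNN regressor
#'
#' Layer sequence: `[conv -> ReLU -> average pool(2)]` per block, dropout,
#' fully connected layer, scalar linear output. Convolution runs along time
#' with the 25 estimator channels as input feature maps, valid padding, Glorot
#' initialization.
#'
#' @param spec a [cnn_spec()].
#' @param n_channels input channels.
#' @param window window length, samples.
#' @param seed initialization seed.
#' @return object of class `ee_cnn` / `ee_model`; `$param_count` reports the
#'   number of trainable parameters.
#' @export
build_cnn <- function(spec = cnn_spec(), n_channels = 25, window = 300, seed = 1L) {
  minw <- cnn_min_window(spec)
  if (window < minw)
    stop(sprintf("window of %d samples is too short after pooling; this spec needs >= %d",
                 window, minw), call. = FALSE)
  with_seed(seed, {
    lcur <- window; cin <- n_channels
    conv_w <- list(); conv_b <- list()
    for (i in seq_along(spec$n_filters)) {
      k <- spec$filter_length[i]; f <- spec$n_filters[i]
      # (k * cin) x f matrix, rows grouped by tap
      w <- matrix(glorot(k * cin, k * f, c(k * cin, f)), k * cin, f)
      conv_w[[i]] <- w
      conv_b[[i]] <- rep(0, f)
      lcur <- (lcur - k + 1) %/% 2
      cin <- f
    }
    nfeat <- lcur * cin
    params <- list(conv_w = conv_w, conv_b = conv_b,
                   fc_w = matrix(glorot(nfeat, spec$fc_neurons), nfeat, spec$fc_neurons),
                   fc_b = rep(0, spec$fc_neurons),
                   out_w = as.numeric(glorot(spec$fc_neurons, 1)),
                   out_b = 0)
    structure(list(kind = "cnn", spec = spec, n_channels = n_channels,
                   window = window, n_features = nfeat, params = params,
                   param_count = sum(vapply(rapply(params, length, how = "unlist"),
                                            identity, numeric(1)))),
              class = c("ee_cnn", "ee_model"))
  })
}

#' Build an untrained LSTM regressor
#'
#' Consumes a `window x n_channels` sequence and emits one scalar from the
#' final step's hidden state, optionally through a ReLU fully connected layer.
#' Gate order is input/forget/candidate/output; forget-gate biases start at 1.
#'
#' @param spec an [lstm_spec()].
#' @param n_channels input channels.
#' @param window sequence length, samples.
#' @param seed initialization seed.
#' @return object of class `ee_lstm` / `ee_model`.
#' @export
build_lstm <- function(spec = lstm_spec(), n_channels = 25, window = 300, seed = 1L) {
  with_seed(seed, {
    cin <- n_channels
    wx <- list(); wh <- list(); bg <- list()
    for (l in seq_along(spec$hidden)) {
      h <- spec$hidden[l]
      wx[[l]] <- cbind(glorot(cin, h), glorot(cin, h), glorot(cin, h), glorot(cin, h))
      wh[[l]] <- cbind(glorot(h, h), glorot(h, h), glorot(h, h), glorot(h, h))
      b <- rep(0, 4 * h); b[(h + 1):(2 * h)] <- 1
      bg[[l]] <- b
      cin <- h
    }
    htop <- spec$hidden[length(spec$hidden)]
    if (spec$fc_neurons > 0) {
      fc_w <- matrix(glorot(htop, spec$fc_neurons), htop, spec$fc_neurons)
      fc_b <- rep(0, spec$fc_neurons)
      nout <- spec$fc_neurons
    } else {
      fc_w <- matrix(0, 0, 0); fc_b <- numeric(0); nout <- htop
    }
    params <- list(wx = wx, wh = wh, bg = bg, fc_w = fc_w, fc_b = fc_b,
                   out_w = as.numeric(glorot(nout, 1)), out_b = 0)
    structure(list(kind = "lstm", spec = spec, n_channels = n_channels,
                   window = window, params = params,
                   param_count = sum(vapply(rapply(params, length, how = "unlist"),
                                            identity, numeric(1)))),
              class = c("ee_lstm", "ee_model"))
  })
}

#' Training configuration
#'
#' Defaults follow the reference regime: Adam with initial learning rate 0.01,
#' mean-square-error loss, L2 penalty `lambda = 1e-4`, 1000 epochs. Reduced
#' epoch counts are appropriate for desk-scale runs.
#'
#' @param learning_rate Adam step size.
#' @param l2_lambda L2 penalty weight on all weight matrices (biases excluded);
#'   the penalty `lambda * sum(w^2)` is added to the loss.
#' @param epochs training epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param seed seed governing shuffling and dropout masks.
#' @param stop_loss optional early-stop threshold on the epoch training loss.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, l2_lambda = 1e-4, epochs = 1000,
                         batch_size = 128, seed = 1L, stop_loss = NULL) {
  assert_scalar_num(learning_rate, "learning_rate", lower = 1e-12)
  assert_scalar_num(epochs, "epochs", lower = 1)
  assert_scalar_num(l2_lambda, "l2_lambda", lower = 0)
  structure(list(learning_rate = learning_rate, l2_lambda = l2_lambda,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), stop_loss = stop_loss),
            class = "train_config")
}

# reshape windows [b, t, c] of an (n, L, C) array into the (L*B) x C layout the
# C++ core expects (row t*B + b)
stack_windows <- function(x, idx) {
  xb <- x[idx, , , drop = FALSE]
  b <- dim(xb)[1]; l <- dim(xb)[2]; ch <- dim(xb)[3]
  matrix(xb, b * l, ch)
}

drop_mask <- function(nrow, ncol, p) {
  if (p <= 0) return(matrix(1, nrow, ncol))
  matrix((runif(nrow * ncol) >= p) / (1 - p), nrow, ncol)
}

model_pass <- function(model, xmat, b, y, masks, l2, training, want_grad) {
  p <- model$params
  if (model$kind == "cnn")
    cnn_pass(p$conv_w, p$conv_b, p$fc_w, p$fc_b, p$out_w, p$out_b,
             xmat, b, y, masks, l2, training, want_grad)
  else
    lstm_pass(p$wx, p$wh, p$bg, p$fc_w, p$fc_b, p$out_w, p$out_b,
              xmat, b, y, masks, l2, training, want_grad)
}

make_masks <- function(model, b) {
  p <- model$spec$dropout_p
  if (model$kind == "cnn") drop_mask(b, model$n_features, p)
  else lapply(model$spec$hidden, function(h) drop_mask(b, h, p))
}

#' Train a regressor with Adam
#'
#' Mini-batch Adam on the mean-square error plus L2 penalty. Fully seeded:
#' identical (model, dataset, config) reproduce identical loss histories.
#' Aborts with learning-rate guidance if the loss becomes non-finite.
#'
#' @param model an `ee_model` from [build_cnn()] / [build_lstm()].
#' @param dataset a `windowed_dataset`.
#' @param config a [train_config()].
#' @return the trained model, with `$history` (per-epoch mean training loss).
#' @export
train_regressor <- function(model, dataset, config = train_config()) {
  n <- dim(dataset$x)[1]
  if (n < 1) stop("dataset is empty", call. = FALSE)
  if (dim(dataset$x)[2] != model$window || dim(dataset$x)[3] != model$n_channels)
    stop(sprintf("window shape %d x %d does not match the model's %d x %d",
                 dim(dataset$x)[2], dim(dataset$x)[3],
                 model$window, model$n_channels), call. = FALSE)
  # parameters and gradients travel as one flat vector; the C++ passes see the
  # structured list via relist on the model's skeleton
  skeleton <- model$params
  theta <- unlist(skeleton, use.names = FALSE)
  mstate <- numeric(length(theta))
  vstate <- numeric(length(theta))
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- numeric(config$epochs)
  nepoch <- config$epochs
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tot <- 0
      for (bi in batches) {
        bsz <- length(bi)
        xm <- stack_windows(dataset$x, bi)
        masks <- make_masks(model, bsz)
        model$params <- utils::relist(theta, skeleton)
        res <- model_pass(model, xm, bsz, dataset$y[bi], masks,
                          config$l2_lambda, training = TRUE, want_grad = TRUE)
        if (!is.finite(res$loss))
          stop("training loss became non-finite; lower `learning_rate` ",
               "(e.g. 10x) or check target scaling", call. = FALSE)
        g <- unlist(res$grads, use.names = FALSE)
        step <- step + 1L
        mstate <- beta1 * mstate + (1 - beta1) * g
        vstate <- beta2 * vstate + (1 - beta2) * g * g
        mhat <- mstate / (1 - beta1^step)
        vhat <- vstate / (1 - beta2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
        tot <- tot + res$loss * bsz
      }
      history[epoch] <- tot / n
      if (!is.null(config$stop_loss) && history[epoch] < config$stop_loss) {
        nepoch <- epoch
        break
      }
    }
  })
  model$params <- utils::relist(theta, skeleton)
  model$history <- history[seq_len(nepoch)]
  model
}

#' Predict energy expenditure for windows
#'
#' Deterministic forward pass (no dropout); the model is not mutated.
#'
#' @param object a trained `ee_model`.
#' @param newdata a `windowed_dataset` or an `(n, window, channels)` array.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return numeric vector of EE estimates (W/kg), one per window.
#' @export
predict.ee_model <- function(object, newdata, batch_size = 512, ...) {
  x <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  if (length(dim(x)) != 3 || dim(x)[2] != object$window ||
      dim(x)[3] != object$n_channels)
    stop(sprintf("expected windows of shape %d x %d",
                 object$window, object$n_channels), call. = FALSE)
  n <- dim(x)[1]
  out <- numeric(n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1L)
    xm <- stack_windows(x, idx)
    res <- model_pass(object, xm, length(idx), numeric(length(idx)),
                      make_masks(object, 0L),
                      0, training = FALSE, want_grad = FALSE)
    out[idx] <- res$pred
  }
  out
}

#' A trivial mean-predicting stub regressor
#'
#' Predicts the training-set mean target for every window. Useful for pipeline
#' bookkeeping checks (fold construction, leakage) where no learning is needed.
#'
#' @return object of class `ee_stub` / `ee_model_stub`.
#' @export
stub_regressor <- function() {
  structure(list(kind = "stub", mean_y = NA_real_), class = "ee_stub")
}

#' @export
train_stub <- function(model, dataset) {
  model$mean_y <- mean(dataset$y)
  model
}

#' @export
predict.ee_stub <- function(object, newdata, ...) {
  n <- if (inherits(newdata, "windowed_dataset")) dim(newdata$x)[1] else dim(newdata)[1]
  rep(object$mean_y, n)
}

#' The benchmarked architecture search grid
#'
#' LSTM: single layers of 10/50/100/150/200 units, a two-layer 150+50 variant,
#' and the best single layer with an added fully connected layer. CNN: filter
#' lengths 5/10/15, 8 or 16 filters, one or two convolution blocks, fully
#' connected widths 10 or 50.
#'
#' @return named list of `cnn_spec` / `lstm_spec` objects.
#' @export
architecture_grid <- function() {
  grid <- list()
  for (h in c(10, 50, 100, 150, 200))
    grid[[sprintf("lstm_%d", h)]] <- lstm_spec(hidden = h)
  grid[["lstm_150_50"]] <- lstm_spec(hidden = c(150, 50))
  grid[["lstm_150_fc10"]] <- lstm_spec(hidden = 150, fc_neurons = 10)
  for (k in c(5, 10, 15)) for (f in c(8, 16)) for (nb in 1:2) for (fc in c(10, 50)) {
    nm <- sprintf("cnn_k%d_f%d_b%d_fc%d", k, f, nb, fc)
    grid[[nm]] <- cnn_spec(n_filters = rep(f, nb), filter_length = rep(k, nb),
                           fc_neurons = fc)
  }
  grid
}

#' Build a model from any spec
#' @param spec a `cnn_spec` or `lstm_spec`.
#' @param n_channels,window input geometry.
#' @param seed initialization seed.
#' @return an `ee_model`.
#' @export
build_regressor <- function(spec, n_channels = 25, window = 300, seed = 1L) {
  if (inherits(spec, "cnn_spec")) build_cnn(spec, n_channels, window, seed)
  else if (inherits(spec, "lstm_spec")) build_lstm(spec, n_channels, window, seed)
  else stop("`spec` must be a cnn_spec or lstm_spec", call. = FALSE)
}
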