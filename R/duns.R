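# Deep unified networks (DUNs).
#
# A mesh-like feed-forward architecture that is vertically deep but
# horizontally shallow. K stacked "data units" h_1..h_K are produced by
# harmonizing units that fuse the raw input with the previous data unit:
#
#   h_1 = act(V_1 x + c_1)
#   h_k = act(U_k h_{k-1} + V_k x + c_k),  k = 2..K
#
# A per-sample attention unit maps the input to a point on the K-simplex,
#   a(x) = softmax(W_a x + b_a),   sum_k a_k = 1,  a_k in [0, 1],
# the layers are mixed as z = sum_k a_k h_k, and a single decision unit
# produces the risk, yhat = sigmoid(w . z + b). There are only two
# horizontal hops from any data unit to the output (mix, then decide), which
# keeps gradients short no matter how deep the vertical stack is; the
# attention weights report, per sample, how much nonlinearity (layer depth)
# the prediction drew on. Training is mini-batch SGD with classical momentum
# on mean binary cross-entropy, with inverted dropout on the input and on
# every data unit.

ACTIVATIONS <- list(
  sigmoid  = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(z, a) a * (1 - a)),
  tanh     = list(f = tanh,
                  df = function(z, a) 1 - a^2),
  softplus = list(f = function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
                  df = function(z, a) 1 / (1 + exp(-z))),
  softsign = list(f = function(z) z / (1 + abs(z)),
                  df = function(z, a) 1 / (1 + abs(z))^2)
)

#' DUNs hyper-parameter configuration
#'
#' Defaults follow the tuned operating point reported for this architecture
#' on EMR readmission data: five data-unit layers of 759 neurons, sigmoid
#' activation, input/inner dropout of about 0.4, and SGD with learning rate
#' 0.01, momentum 0.9 and batch size 100.
#'
#' @param n_layers Number of data-unit layers K (typical search range 2-5).
#' @param n_neurons Neurons per data unit (typical search range 100-1000).
#' @param activation One of `"sigmoid"`, `"tanh"`, `"softplus"`,
#'   `"softsign"`.
#' @param dropout_input,dropout_inner Dropout rates for the input and for
#'   each data unit (typical search range 0.001-0.5).
#' @param learning_rate,momentum,batch_size SGD settings.
#' @param n_epochs Training epochs (typical search range 20-100).
#' @param seed Seed for weight init, dropout masks and epoch shuffling.
#' @return A list of class `duns_config`.
#' @export
duns_config <- function(n_layers = 5L, n_neurons = 759L,
                        activation = c("sigmoid", "tanh", "softplus",
                                       "softsign"),
                        dropout_input = 0.397, dropout_inner = 0.433,
                        learning_rate = 0.01, momentum = 0.9,
                        batch_size = 100L, n_epochs = 100L, seed = 1L) {
  activation <- match.arg(activation)
  n_layers <- check_count(n_layers, "n_layers")
  n_neurons <- check_count(n_neurons, "n_neurons")
  n_epochs <- check_count(n_epochs, "n_epochs", positive = FALSE)
  batch_size <- check_count(batch_size, "batch_size")
  check_probability(dropout_input, "dropout_input")
  check_probability(dropout_inner, "dropout_inner")
  check_positive(learning_rate, "learning_rate")
  if (momentum < 0 || momentum >= 1) {
    stop("configuration error: `momentum` must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_layers = n_layers, n_neurons = n_neurons,
                 activation = activation, dropout_input = dropout_input,
                 dropout_inner = dropout_inner,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = batch_size, n_epochs = n_epochs,
                 seed = as.integer(seed)),
            class = "duns_config")
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), nrow = n_in)
}

#' Initialize DUNs parameters
#'
#' Draws all learnable weights (harmonizing units, attention unit, decision
#' unit) from symmetric uniform distributions scaled by fan-in/fan-out,
#' deterministically for a given seed.
#'
#' @param config A [duns_config()].
#' @param input_dim Number of input features p (>= 1).
#' @return A list of class `duns_params` with elements `V` (list of p x m),
#'   `U` (list of m x m, `U[[1]]` is NULL), `c` (list of biases), `Wa`
#'   (p x K), `ba`, `w` (m), `b`, and `config`.
#' @export
init_duns <- function(config, input_dim) {
  if (!inherits(config, "duns_config")) stop("config must be a duns_config")
  p <- check_count(input_dim, "input_dim")
  K <- config$n_layers; m <- config$n_neurons
  with_seed(config$seed, {
    V <- lapply(seq_len(K), function(k) glorot(p, m))
    U <- c(list(NULL), lapply(seq_len(K - 1), function(k) glorot(m, m)))
    cb <- lapply(seq_len(K), function(k) numeric(m))
    structure(list(
      V = V, U = U, c = cb,
      Wa = glorot(p, K), ba = numeric(K),
      w = stats::runif(m, -sqrt(6 / (m + 1)), sqrt(6 / (m + 1))), b = 0,
      input_dim = p, config = config
    ), class = "duns_params")
  })
}

# Forward pass keeping the caches backprop needs. Dropout masks are drawn
# from the current RNG stream when train_mode is TRUE (inverted dropout).
duns_forward_cache <- function(params, x, train_mode = FALSE) {
  cfg <- params$config
  K <- cfg$n_layers
  act <- ACTIVATIONS[[cfg$activation]]
  x <- as.matrix(x)
  if (ncol(x) != params$input_dim) {
    stop("shape mismatch: expected ", params$input_dim, " input features, got ",
         ncol(x), call. = FALSE)
  }
  n <- nrow(x)
  xd <- x
  mask_x <- NULL
  if (train_mode && cfg$dropout_input > 0) {
    mask_x <- matrix(stats::rbinom(n * ncol(x), 1, 1 - cfg$dropout_input),
                     nrow = n) / (1 - cfg$dropout_input)
    xd <- x * mask_x
  }
  H <- Z <- masks <- vector("list", K)
  for (k in seq_len(K)) {
    z <- xd %*% params$V[[k]]
    if (k > 1) z <- z + H[[k - 1]] %*% params$U[[k]]
    z <- sweep(z, 2, params$c[[k]], "+")
    h <- act$f(z)
    Z[[k]] <- z
    if (train_mode && cfg$dropout_inner > 0) {
      mk <- matrix(stats::rbinom(length(h), 1, 1 - cfg$dropout_inner),
                   nrow = n) / (1 - cfg$dropout_inner)
      masks[[k]] <- mk
      h <- h * mk
    }
    H[[k]] <- h
  }
  logits <- sweep(xd %*% params$Wa, 2, params$ba, "+")
  logits <- logits - apply(logits, 1, max)          # stable softmax
  A <- exp(logits)
  A <- A / rowSums(A)
  zmix <- matrix(0, n, cfg$n_neurons)
  for (k in seq_len(K)) zmix <- zmix + A[, k] * H[[k]]
  s <- drop(zmix %*% params$w) + params$b
  prob <- 1 / (1 + exp(-s))
  list(prob = prob, A = A, H = H, Z = Z, zmix = zmix, s = s, xd = xd,
       mask_x = mask_x, masks = masks)
}

#' DUNs forward pass
#'
#' @param params A `duns_params` object.
#' @param x Numeric matrix (rows are samples, columns in `[0, 1]`).
#' @param train_mode Apply dropout (training) or use expectation scaling
#'   (inference, the default).
#' @return A list with `prob` (predicted readmission probability per row) and
#'   `attention` (rows x layers matrix; each row is on the simplex).
#' @export
duns_forward <- function(params, x, train_mode = FALSE) {
  fw <- duns_forward_cache(params, x, train_mode = train_mode)
  list(prob = fw$prob, attention = fw$A)
}

# Analytic gradients of mean binary cross-entropy for one batch. Reuses a
# cache from duns_forward_cache so dropout masks are shared.
duns_gradients <- function(params, x, y, cache = NULL, train_mode = FALSE) {
  cfg <- params$config
  K <- cfg$n_layers
  act <- ACTIVATIONS[[cfg$activation]]
  if (is.null(cache)) cache <- duns_forward_cache(params, x, train_mode)
  n <- length(cache$prob)
  ds <- (cache$prob - y) / n                       # dL/ds, s = w.z + b
  g <- list(V = vector("list", K), U = vector("list", K),
            c = vector("list", K))
  g$w <- drop(crossprod(cache$zmix, ds))
  g$b <- sum(ds)
  dZmix <- outer(ds, params$w)                     # n x m
  dA <- matrix(0, n, K)
  dH <- vector("list", K)
  for (k in seq_len(K)) {
    dA[, k] <- rowSums(dZmix * cache$H[[k]])
    dH[[k]] <- cache$A[, k] * dZmix
  }
  dLog <- cache$A * (dA - rowSums(dA * cache$A))   # softmax backward
  g$Wa <- crossprod(cache$xd, dLog)
  g$ba <- colSums(dLog)
  dX <- NULL
  for (k in rev(seq_len(K))) {
    dh <- dH[[k]]
    if (!is.null(cache$masks[[k]])) dh <- dh * cache$masks[[k]]
    dz <- dh * act$df(cache$Z[[k]],
                      if (is.null(cache$masks[[k]])) cache$H[[k]]
                      else act$f(cache$Z[[k]]))
    g$V[[k]] <- crossprod(cache$xd, dz)
    g$c[[k]] <- colSums(dz)
    if (k > 1) {
      g$U[[k]] <- crossprod(cache$H[[k - 1]], dz)
      dH[[k - 1]] <- dH[[k - 1]] + dz %*% t(params$U[[k]])
    }
  }
  g$U[[1]] <- NULL_GRAD
  g
}

NULL_GRAD <- structure(list(), class = "null_grad")

# flatten/unflatten for the generic SGD loop and finite-difference checks
duns_flatten <- function(p) {
  unlist(list(V = p$V, U = p$U[-1], c = p$c, Wa = p$Wa, ba = p$ba,
              w = p$w, b = p$b), use.names = FALSE)
}

duns_unflatten <- function(params, theta) {
  K <- params$config$n_layers
  pos <- 1L
  take <- function(n) {
    out <- theta[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  for (k in seq_len(K)) {
    params$V[[k]][] <- take(length(params$V[[k]]))
  }
  for (k in seq_len(K)[-1]) {
    params$U[[k]][] <- take(length(params$U[[k]]))
  }
  for (k in seq_len(K)) params$c[[k]][] <- take(length(params$c[[k]]))
  params$Wa[] <- take(length(params$Wa))
  params$ba[] <- take(length(params$ba))
  params$w[] <- take(length(params$w))
  params$b <- take(1L)
  params
}

duns_flatten_grad <- function(g) {
  unlist(list(V = g$V, U = g$U[-1], c = g$c, Wa = g$Wa, ba = g$ba,
              w = g$w, b = g$b), use.names = FALSE)
}

bce_loss <- function(prob, y, eps = 1e-12) {
  prob <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(prob) + (1 - y) * log(1 - prob))
}

# Shared mini-batch SGD-with-momentum loop over a flattened parameter
# vector. grad_fn(params, xb, yb) must return a flat gradient; forward_fn
# scores the full training set for the history.
sgd_train <- function(params, x, y, config, grad_fn, forward_fn,
                      flatten, unflatten) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 1) stop("at least one batch of data is required", call. = FALSE)
  theta <- flatten(params)
  vel <- numeric(length(theta))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        auc = numeric(0))
  if (config$n_epochs == 0) {
    return(list(params = params, history = history))
  }
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$n_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        g <- grad_fn(params, x[idx, , drop = FALSE], y[idx])
        vel <- config$momentum * vel - config$learning_rate * g
        theta <- theta + vel
        params <- unflatten(params, theta)
      }
      prob <- forward_fn(params, x)
      loss <- bce_loss(prob, y)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss at epoch ", epoch,
             "); try a smaller learning rate", call. = FALSE)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = loss,
                                  auc = auc_scores(prob, y)))
    }
  })
  list(params = params, history = history)
}

#' Train a DUNs model
#'
#' Mini-batch stochastic gradient descent with classical momentum on mean
#' binary cross-entropy; dropout is active during training and replaced by
#' expectation scaling at inference. Epoch shuffling and dropout masks are
#' seeded, so a fixed seed yields an identical training trajectory.
#'
#' @param params From [init_duns()] (or a previously trained model to
#'   continue).
#' @param x Feature matrix in `[0, 1]`.
#' @param y Binary outcome vector.
#' @param config Optional [duns_config()] overriding `params$config` for the
#'   optimizer settings.
#' @return A list of class `duns_fit`: `params` (trained), `history`
#'   (per-epoch training loss and AUC).
#' @export
train_duns <- function(params, x, y, config = NULL) {
  cfg <- if (is.null(config)) params$config else config
  fit <- sgd_train(
    params, x, y, cfg,
    grad_fn = function(p, xb, yb)
      duns_flatten_grad(duns_gradients(p, xb, yb, train_mode = TRUE)),
    forward_fn = function(p, xx) duns_forward_cache(p, xx)$prob,
    flatten = duns_flatten, unflatten = duns_unflatten
  )
  structure(list(params = fit$params, history = fit$history),
            class = "duns_fit")
}

#' Per-layer attention summaries
#'
#' Column-wise summaries of the attention matrix over a sample of inputs:
#' the per-layer mean, standard deviation and quartiles of the attention
#' weight. Because each row lies on the simplex, the layer means sum to 1.
#'
#' @param params A `duns_params` (trained or not).
#' @param x Nonempty input matrix.
#' @return Data frame with one row per layer: `layer`, `mean`, `sd`, `q25`,
#'   `median`, `q75`.
#' @export
layer_importance <- function(params, x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty input", call. = FALSE)
  A <- duns_forward(params, x)$attention
  data.frame(
    layer = seq_len(ncol(A)),
    mean = colMeans(A),
    sd = apply(A, 2, stats::sd),
    q25 = apply(A, 2, stats::quantile, 0.25),
    median = apply(A, 2, stats::median),
    q75 = apply(A, 2, stats::quantile, 0.75)
  )
}

#' Serialize a trained model to JSON
#'
#' Writes the configuration and all named weight arrays to a single JSON
#' container readable by [load_model()].
#'
#' @param fit A `duns_fit`, `maxout_fit`, or bare parameter list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path) {
  params <- if (!is.null(fit$params)) fit$params else fit
  cls <- class(params)[1]
  theta <- switch(cls,
    duns_params = duns_flatten(params),
    maxout_params = maxout_flatten(params),
    stop("cannot serialize objects of class ", cls, call. = FALSE))
  jsonlite::write_json(
    list(class = cls, config = unclass(params$config),
         input_dim = params$input_dim, theta = theta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model written by [save_model()]
#' @param path JSON file path.
#' @return The parameter list (`duns_params` or `maxout_params`).
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cfgv <- obj$config
  if (obj$class == "duns_params") {
    cfg <- duns_config(cfgv$n_layers, cfgv$n_neurons, cfgv$activation,
                       cfgv$dropout_input, cfgv$dropout_inner,
                       cfgv$learning_rate, cfgv$momentum, cfgv$batch_size,
                       cfgv$n_epochs, cfgv$seed)
    duns_unflatten(init_duns(cfg, obj$input_dim), obj$theta)
  } else {
    cfg <- maxout_config(cfgv$n_layers, cfgv$n_neurons,
                         cfgv$n_maxout_pieces, cfgv$activation,
                         cfgv$dropout_input, cfgv$dropout_inner,
                         cfgv$learning_rate, cfgv$momentum, cfgv$batch_size,
                         cfgv$n_epochs, cfgv$seed)
    maxout_unflatten(init_maxout(cfg, obj$input_dim), obj$theta)
  }
}
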