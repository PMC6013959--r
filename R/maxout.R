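# Maxout networks.
#
# Feed-forward nets whose inner neurons take the maximum over a group of
# affine "pieces" before the layer activation; with one piece per neuron the
# network reduces to a plain DNN. Shares the SGD-with-momentum training loop
# with the DUNs module.

#' Maxout network hyper-parameter configuration
#'
#' Defaults follow the tuned operating point reported for maxout networks on
#' EMR readmission data: three inner layers of 914 neurons with three pieces
#' per neuron, sigmoid activation, dropout about 0.45/0.39, and the same SGD
#' settings as DUNs.
#'
#' @param n_layers Inner layers (typical search range 2-5).
#' @param n_neurons Neurons per layer (typical search range 100-1000).
#' @param n_maxout_pieces Affine pieces per neuron (search range 2-5; 1
#'   recovers a plain DNN).
#' @inheritParams duns_config
#' @return A list of class `maxout_config`.
#' @export
maxout_config <- function(n_layers = 3L, n_neurons = 914L,
                          n_maxout_pieces = 3L,
                          activation = c("sigmoid", "tanh", "softplus",
                                         "softsign"),
                          dropout_input = 0.446, dropout_inner = 0.394,
                          learning_rate = 0.01, momentum = 0.9,
                          batch_size = 100L, n_epochs = 22L, seed = 1L) {
  activation <- match.arg(activation)
  cfg <- duns_config(n_layers, n_neurons, activation, dropout_input,
                     dropout_inner, learning_rate, momentum, batch_size,
                     n_epochs, seed)
  cfg$n_maxout_pieces <- check_count(n_maxout_pieces, "n_maxout_pieces")
  class(cfg) <- "maxout_config"
  cfg
}

#' Initialize maxout network parameters
#'
#' @param config A [maxout_config()].
#' @param input_dim Number of input features (>= 1).
#' @return A list of class `maxout_params`: `W` (list of d_in x m x pieces
#'   arrays), `b` (list of m x pieces matrices), output head `w`, `b_out`.
#' @export
init_maxout <- function(config, input_dim) {
  if (!inherits(config, "maxout_config")) stop("config must be a maxout_config")
  p <- check_count(input_dim, "input_dim")
  K <- config$n_layers; m <- config$n_neurons; q <- config$n_maxout_pieces
  with_seed(config$seed, {
    dims_in <- c(p, rep(m, K - 1))
    W <- lapply(dims_in, function(d) {
      s <- sqrt(6 / (d + m))
      array(stats::runif(d * m * q, -s, s), dim = c(d, m, q))
    })
    b <- lapply(seq_len(K), function(k) matrix(0, m, q))
    structure(list(W = W, b = b,
                   w = stats::runif(m, -sqrt(6 / (m + 1)), sqrt(6 / (m + 1))),
                   b_out = 0, input_dim = p, config = config),
              class = "maxout_params")
  })
}

maxout_forward_cache <- function(params, x, train_mode = FALSE) {
  cfg <- params$config
  act <- ACTIVATIONS[[cfg$activation]]
  K <- cfg$n_layers; m <- cfg$n_neurons; q <- cfg$n_maxout_pieces
  x <- as.matrix(x)
  if (ncol(x) != params$input_dim) {
    stop("shape mismatch: expected ", params$input_dim,
         " input features, got ", ncol(x), call. = FALSE)
  }
  n <- nrow(x)
  h <- x
  mask_x <- NULL
  if (train_mode && cfg$dropout_input > 0) {
    mask_x <- matrix(stats::rbinom(length(h), 1, 1 - cfg$dropout_input),
                     nrow = n) / (1 - cfg$dropout_input)
    h <- h * mask_x
  }
  inputs <- argmax <- Zmax <- H <- masks <- vector("list", K)
  for (k in seq_len(K)) {
    inputs[[k]] <- h
    d_in <- dim(params$W[[k]])[1]
    zq <- lapply(seq_len(q), function(j)
      h %*% matrix(params$W[[k]][, , j], d_in, m) +
        matrix(params$b[[k]][, j], n, m, byrow = TRUE))
    zmax <- zq[[1]]
    amax <- matrix(1L, n, m)
    if (q > 1) {
      for (j in 2:q) {
        upd <- zq[[j]] > zmax
        zmax[upd] <- zq[[j]][upd]
        amax[upd] <- j
      }
    }
    hk <- act$f(zmax)
    Zmax[[k]] <- zmax
    argmax[[k]] <- amax
    if (train_mode && cfg$dropout_inner > 0) {
      mk <- matrix(stats::rbinom(length(hk), 1, 1 - cfg$dropout_inner),
                   nrow = n) / (1 - cfg$dropout_inner)
      masks[[k]] <- mk
      hk <- hk * mk
    }
    H[[k]] <- hk
    h <- hk
  }
  s <- drop(h %*% params$w) + params$b_out
  prob <- 1 / (1 + exp(-s))
  list(prob = prob, inputs = inputs, argmax = argmax, Zmax = Zmax, H = H,
       masks = masks, s = s)
}

#' Maxout network forward pass
#'
#' Each inner-layer neuron computes the maximum of its affine pieces, the
#' layer activation is applied to that maximum, and a sigmoid head produces
#' the probability. With `n_maxout_pieces = 1` the output is identical to a
#' plain feed-forward network with the same weights.
#'
#' @inheritParams duns_forward
#' @return A list with `prob`.
#' @export
maxout_forward <- function(params, x, train_mode = FALSE) {
  list(prob = maxout_forward_cache(params, x, train_mode)$prob)
}

maxout_gradients <- function(params, x, y, train_mode = FALSE) {
  cfg <- params$config
  act <- ACTIVATIONS[[cfg$activation]]
  K <- cfg$n_layers; q <- cfg$n_maxout_pieces
  cache <- maxout_forward_cache(params, x, train_mode)
  n <- length(cache$prob)
  ds <- (cache$prob - y) / n
  g <- list(W = vector("list", K), b = vector("list", K))
  g$w <- drop(crossprod(cache$H[[K]], ds))
  g$b_out <- sum(ds)
  dh <- outer(ds, params$w)
  for (k in rev(seq_len(K))) {
    if (!is.null(cache$masks[[k]])) dh <- dh * cache$masks[[k]]
    a_nodrop <- if (is.null(cache$masks[[k]])) cache$H[[k]]
      else act$f(cache$Zmax[[k]])
    dz <- dh * act$df(cache$Zmax[[k]], a_nodrop)
    gW <- array(0, dim = dim(params$W[[k]]))
    gb <- matrix(0, nrow = nrow(params$b[[k]]), ncol = q)
    dprev <- matrix(0, nrow = n, ncol = nrow(params$W[[k]]))
    d_in <- dim(params$W[[k]])[1]
    m <- dim(params$W[[k]])[2]
    for (j in seq_len(q)) {
      sel <- (cache$argmax[[k]] == j) * dz     # route to argmax piece
      gW[, , j] <- crossprod(cache$inputs[[k]], sel)
      gb[, j] <- colSums(sel)
      dprev <- dprev + sel %*% t(matrix(params$W[[k]][, , j], d_in, m))
    }
    g$W[[k]] <- gW
    g$b[[k]] <- gb
    dh <- dprev
  }
  g
}

maxout_flatten <- function(p) {
  unlist(list(W = p$W, b = p$b, w = p$w, b_out = p$b_out), use.names = FALSE)
}

maxout_flatten_grad <- function(g) {
  unlist(list(W = g$W, b = g$b, w = g$w, b_out = g$b_out), use.names = FALSE)
}

maxout_unflatten <- function(params, theta) {
  pos <- 1L
  take <- function(n) {
    out <- theta[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  for (k in seq_along(params$W)) params$W[[k]][] <- take(length(params$W[[k]]))
  for (k in seq_along(params$b)) params$b[[k]][] <- take(length(params$b[[k]]))
  params$w[] <- take(length(params$w))
  params$b_out <- take(1L)
  params
}

#' Train a maxout network
#'
#' Same optimizer and seeding contract as [train_duns()].
#'
#' @inheritParams train_duns
#' @param params From [init_maxout()].
#' @return A list of class `maxout_fit`: `params`, `history`.
#' @export
train_maxout <- function(params, x, y, config = NULL) {
  cfg <- if (is.null(config)) params$config else config
  fit <- sgd_train(
    params, x, y, cfg,
    grad_fn = function(p, xb, yb)
      maxout_flatten_grad(maxout_gradients(p, xb, yb, train_mode = TRUE)),
    forward_fn = function(p, xx) maxout_forward_cache(p, xx)$prob,
    flatten = maxout_flatten, unflatten = maxout_unflatten
  )
  structure(list(params = fit$params, history = fit$history),
            class = "maxout_fit")
}
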