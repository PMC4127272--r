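# Autoassociative feed-forward bottleneck coder.
#
# A sequence is cut into chunks of length n, normalized into [-1, 1], and
# passed through a single-hidden-layer network: hidden H = tansig(W_enc x)
# with k <= n units (the compressed representation), output y = W_dec h
# (linear, no activation). Weights are initialized from the data Gram
# matrix — its top-k unit eigenvectors, the implementable reading of the
# Hebbian outer-product construction — and refined by least-mean-square
# backpropagation with the classic stopping rule: error goal 0.1 or 50
# epochs.

#' Chunk a sequence and normalize it into \[-1, 1\]
#'
#' Nonnegative streams are mapped symmetrically about zero,
#' `x -> 2 x / s_max - 1`, so the full intensity range spans \[-1, 1\];
#' signed streams (quantized wavelet coefficients) are scaled `x / s_max`.
#' The final chunk is zero-padded and the pad count recorded.
#'
#' @param s Numeric vector (a flat value stream).
#' @param n Chunk length, `>= 2`.
#' @param s_max Positive normalization scale (for pixel streams, the
#'   maximum representable value 255).
#' @param signed `TRUE` for streams containing negatives. Default: detected
#'   from the data.
#' @return A list with `chunks` (an `n x n_chunks` matrix, one chunk per
#'   column), `pad` (zeros appended to the final chunk), `n`, `s_max`,
#'   `signed`, `length` (source length).
#' @export
chunk_and_normalize <- function(s, n, s_max, signed = any(s < 0)) {
  if (!is_count(n) || n < 2) stop_argument("chunk length n must be an integer >= 2")
  if (!is.numeric(s_max) || length(s_max) != 1L || is.na(s_max) || s_max <= 0) {
    stop_argument("normalization scale s_max must be positive")
  }
  if (length(s) == 0L) stop_argument("sequence must be nonempty")
  n <- as.integer(n)
  z <- if (signed) s / s_max else 2 * s / s_max - 1
  if (max(abs(z)) > 1 + 1e-12) {
    stop_argument("normalization scale s_max = %g too small: |normalized value| reaches %g",
                  s_max, max(abs(z)))
  }
  n_chunks <- as.integer(ceiling(length(z) / n))
  pad <- n * n_chunks - length(z)
  chunks <- matrix(c(z, numeric(pad)), nrow = n, ncol = n_chunks)
  list(chunks = chunks, pad = pad, n = n, s_max = s_max, signed = signed,
       length = length(s))
}

denormalize_stream <- function(z, s_max, signed) {
  if (signed) z * s_max else (z + 1) * s_max / 2
}

nn_activation <- function(z, hidden) if (hidden == "tansig") tanh(z) else z

#' Initialize encoder/decoder weights from the data Gram matrix
#'
#' Forms the chunk outer-product (Gram) matrix `sum_i x_i x_i^T` and takes
#' its top-`k` unit eigenvectors as the rows of the encoder; the decoder is
#' the transpose. Eigenvector signs follow a deterministic convention (the
#' largest-magnitude entry is positive), so initialization is reproducible.
#'
#' @param chunks An `n x n_chunks` matrix from [chunk_and_normalize()], or
#'   the list it returns.
#' @param k Hidden size, `1 <= k <= n`; the compression knob.
#' @param seed Integer recorded in the model (initialization itself is
#'   deterministic).
#' @param hidden Hidden activation, `"tansig"` (default) or `"linear"`.
#' @param goal Training stop threshold on mean squared reconstruction
#'   error (default 0.1).
#' @param max_epochs Training epoch cap (default 50).
#' @return An object of class `sbpn_nn_model`.
#' @export
init_weights_hebbian <- function(chunks, k, seed = 1L, hidden = "tansig",
                                 goal = 0.1, max_epochs = 50L) {
  if (is.list(chunks)) chunks <- chunks$chunks
  if (!is.matrix(chunks) || ncol(chunks) < 1L) {
    stop_argument("chunks must be an n x n_chunks matrix with at least one chunk")
  }
  n <- nrow(chunks)
  if (!is_count(k) || k > n) {
    stop_argument("hidden size k must be an integer in [1, n = %d]", n)
  }
  k <- as.integer(k)
  if (!hidden %in% c("tansig", "linear")) {
    stop_argument("hidden activation must be 'tansig' or 'linear'")
  }
  G <- chunks %*% t(chunks)
  eig <- eigen(G, symmetric = TRUE)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  W_enc <- t(V)
  model <- structure(
    list(n = n, k = k, W_enc = W_enc, W_dec = t(W_enc), hidden = hidden,
         output = "linear", goal = goal, max_epochs = as.integer(max_epochs),
         learning_rate = 0.05, seed = as.integer(seed), trained = FALSE,
         error = NA_real_),
    class = "sbpn_nn_model"
  )
  check_model_finite(model, "initialization")
  model
}

check_model_finite <- function(model, stage) {
  if (!all(is.finite(model$W_enc)) || !all(is.finite(model$W_dec))) {
    stop_training("non-finite weights after %s", stage)
  }
  invisible(model)
}

#' @export
print.sbpn_nn_model <- function(x, ...) {
  cat(sprintf("<sbpn_nn_model> n=%d k=%d hidden=%s %s (mse=%s)\n",
              x$n, x$k, x$hidden,
              if (x$trained) "trained" else "untrained",
              format(x$error, digits = 4)))
  invisible(x)
}

model_forward <- function(model, X) {
  H <- nn_activation(model$W_enc %*% X, model$hidden)
  list(H = H, Y = model$W_dec %*% H)
}

model_mse <- function(model, X) {
  mean((model_forward(model, X)$Y - X)^2)
}

# Exact least-squares refit of the decoder for fixed hidden responses:
# minimizes the same least-mean-square objective as the gradient step.
refit_decoder <- function(H, X, ridge = 1e-10) {
  G <- H %*% t(H)
  diag(G) <- diag(G) + ridge * max(1, max(abs(diag(G))))
  t(solve(G, H %*% t(X)))
}

#' Train the bottleneck coder by least-mean-square backpropagation
#'
#' Full-batch autoassociative training (target = input): each epoch takes a
#' backtracking gradient step on the encoder weights followed by an exact
#' least-squares refit of the decoder — both descent steps on the mean
#' squared reconstruction error. Training stops as soon as the error
#' reaches `goal` (default 0.1) or after `max_epochs` (default 50) epochs,
#' and is fully deterministic, so identical inputs give bit-identical
#' weights. The returned error never exceeds the initial error.
#'
#' @param model An `sbpn_nn_model` from [init_weights_hebbian()].
#' @param chunks Chunk matrix (or [chunk_and_normalize()] list).
#' @param goal,max_epochs,learning_rate Optional overrides of the model's
#'   training parameters.
#' @return The trained model, with `error` (final MSE), `epochs_run` and
#'   `error_history` fields.
#' @export
train <- function(model, chunks, goal = model$goal,
                  max_epochs = model$max_epochs,
                  learning_rate = model$learning_rate) {
  if (!inherits(model, "sbpn_nn_model")) stop_argument("not an sbpn_nn_model")
  if (is.list(chunks)) chunks <- chunks$chunks
  if (!is.matrix(chunks) || ncol(chunks) < 1L) stop_argument("chunks must be nonempty")
  if (nrow(chunks) != model$n) {
    stop_shape("chunk length %d does not match model n = %d", nrow(chunks), model$n)
  }
  X <- chunks
  N <- ncol(X)
  err <- model_mse(model, X)
  if (!is.finite(err)) stop_training("non-finite error at epoch 0")
  history <- err
  if (err <= goal) {
    model$error <- err
    model$epochs_run <- 0L
    model$error_history <- history
    model$trained <- TRUE
    return(model)
  }
  lr <- learning_rate
  epoch <- 0L
  while (epoch < max_epochs && err > goal) {
    epoch <- epoch + 1L
    fwd <- model_forward(model, X)
    E <- fwd$Y - X
    dH <- crossprod(model$W_dec, E)
    dZ <- if (model$hidden == "tansig") dH * (1 - fwd$H^2) else dH
    g_enc <- (2 / (model$n * N)) * dZ %*% t(X)
    # backtracking: shrink the step until the epoch does not increase error
    improved <- FALSE
    for (try in 1:30) {
      cand <- model
      cand$W_enc <- model$W_enc - lr * g_enc
      Hc <- nn_activation(cand$W_enc %*% X, cand$hidden)
      cand$W_dec <- refit_decoder(Hc, X)
      cand_err <- mean((cand$W_dec %*% Hc - X)^2)
      if (!is.finite(cand_err)) {
        stop_training("training diverged (non-finite error) at epoch %d", epoch)
      }
      if (cand_err <= err) {
        model <- cand
        err <- cand_err
        lr <- lr * 1.2
        improved <- TRUE
        break
      }
      lr <- lr / 2
    }
    if (!improved) {
      # gradient step rejected even at tiny rate: decoder refit alone
      Hc <- nn_activation(model$W_enc %*% X, model$hidden)
      W_dec2 <- refit_decoder(Hc, X)
      err2 <- mean((W_dec2 %*% Hc - X)^2)
      if (is.finite(err2) && err2 < err) {
        model$W_dec <- W_dec2
        err <- err2
      } else {
        history <- c(history, err)
        break
      }
    }
    history <- c(history, err)
  }
  check_model_finite(model, sprintf("epoch %d", epoch))
  model$error <- err
  model$epochs_run <- epoch
  model$error_history <- history
  model$learning_rate <- lr
  model$trained <- TRUE
  model
}

#' Encode chunks to hidden-layer codes
#'
#' `H = tansig(W_enc x)` per chunk; the hidden vectors are the compressed
#' representation.
#'
#' @param model An `sbpn_nn_model`.
#' @param chunks Chunk matrix or [chunk_and_normalize()] list (its `pad` is
#'   carried into the code).
#' @param pad Pad count of the final chunk (overridden by a list input).
#' @return An object of class `sbpn_hidden_code`: list with `H` (`k x
#'   n_chunks`), `n_chunks`, `pad`.
#' @export
nn_encode <- function(model, chunks, pad = 0L) {
  if (!inherits(model, "sbpn_nn_model")) stop_argument("not an sbpn_nn_model")
  if (is.list(chunks)) {
    pad <- chunks$pad
    chunks <- chunks$chunks
  }
  if (nrow(chunks) != model$n) {
    stop_shape("chunk length %d does not match model n = %d", nrow(chunks), model$n)
  }
  H <- nn_activation(model$W_enc %*% chunks, model$hidden)
  structure(list(H = H, n_chunks = ncol(H), pad = as.integer(pad)),
            class = "sbpn_hidden_code")
}

#' Decode hidden codes back to a sequence
#'
#' `y = W_dec h` per chunk (linear output), concatenated, stripped of the
#' final chunk's padding, denormalized by `s_max`, and — for integer value
#' streams — clipped to the declared value range and rounded.
#'
#' @param model An `sbpn_nn_model`.
#' @param code An `sbpn_hidden_code`.
#' @param s_max,signed Normalization parameters used on the encode side.
#' @param length_out Original (unpadded) sequence length.
#' @param integerize If `TRUE` (default), round to integers.
#' @param vrange Optional `c(min, max)` clip range for decoded values.
#' @return Numeric vector of length `length_out`.
#' @export
nn_decode <- function(model, code, s_max, signed = FALSE, length_out = NULL,
                      integerize = TRUE, vrange = NULL) {
  if (!inherits(model, "sbpn_nn_model")) stop_argument("not an sbpn_nn_model")
  if (!inherits(code, "sbpn_hidden_code")) stop_argument("not an sbpn_hidden_code")
  if (nrow(code$H) != model$k) {
    stop_corrupt("hidden code has %d units per chunk, model expects k = %d",
                 nrow(code$H), model$k)
  }
  if (code$pad >= model$n || code$pad < 0L) {
    stop_corrupt("pad count %d inconsistent with chunk length %d",
                 code$pad, model$n)
  }
  y <- as.vector(model$W_dec %*% code$H)
  total <- model$n * code$n_chunks - code$pad
  if (is.null(length_out)) length_out <- total
  if (length_out != total) {
    stop_corrupt("code covers %d values but %d were requested", total, length_out)
  }
  y <- y[seq_len(length_out)]
  y <- denormalize_stream(y, s_max, signed)
  if (!is.null(vrange)) y <- pmin(pmax(y, vrange[1]), vrange[2])
  if (integerize) y <- round_half_away(y)
  y
}

# 8-bit uniform quantization of hidden codes over the tansig range [-1, 1].
hidden_quantize <- function(H) {
  q <- as.integer(round(pmin(pmax((as.vector(H) + 1) * 127.5, 0), 255)))
  as.raw(q)
}

hidden_dequantize <- function(bytes, k, n_chunks) {
  if (length(bytes) != k * n_chunks) {
    stop_corrupt("hidden code block has %d bytes, expected %d (k=%d x %d chunks)",
                 length(bytes), k * n_chunks, k, n_chunks)
  }
  matrix(as.integer(bytes) / 127.5 - 1, nrow = k, ncol = n_chunks)
}
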