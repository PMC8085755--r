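# Bidirectional LSTM sequence classifier: forward pass, backpropagation
# through time, and Adam updates, in base R matrix code. Inputs are arrays
# (batch x time x features); the classifier head concatenates the final
# hidden states of the two directions and applies a dense logistic layer.
#
# Gate layout in the fused weight matrices is [i | f | g | o] (input, forget,
# cell candidate, output), so W is D x 4H, U is H x 4H, b length 4H.

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Parameter initialization: uniform(-k, k) with k = 1/sqrt(H) (the standard
# recurrent-net scheme), forget-gate bias raised to 1 to keep early memory.
.init_params <- function(D, H) {
  k <- 1 / sqrt(H)
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  dir_par <- function() {
    b <- stats::runif(4 * H, -k, k)
    b[(H + 1):(2 * H)] <- 1
    list(W = ru(D, 4 * H), U = ru(H, 4 * H), b = b)
  }
  list(fwd = dir_par(), bwd = dir_par(),
       w_out = ru(2 * H, 1), b_out = stats::runif(1, -k, k),
       D = D, H = H)
}

# One direction's unrolled forward pass. X: B x T x D. Returns the final
# hidden state and the per-step activations needed for backprop.
.lstm_dir_forward <- function(X, p, reverse = FALSE) {
  B <- dim(X)[1]; T <- dim(X)[2]; H <- ncol(p$U)/4L
  order_t <- if (reverse) T:1 else 1:T
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  cache <- vector("list", T)
  for (s in seq_len(T)) {
    t <- order_t[s]
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, dim(X)[3])
    A <- xt %*% p$W + h %*% p$U + matrix(p$b, B, 4 * H, byrow = TRUE)
    i <- .sigmoid(A[, 1:H, drop = FALSE])
    f <- .sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- c
    c <- f * c_prev + i * g
    tc <- tanh(c)
    h_prev <- h
    h <- o * tc
    cache[[s]] <- list(t = t, x = xt, i = i, f = f, g = g, o = o,
                       c = c, c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(h_last = h, cache = cache, order_t = order_t)
}

# Full forward pass. Returns probabilities and all caches.
.net_forward <- function(X, params) {
  fw <- .lstm_dir_forward(X, params$fwd, reverse = FALSE)
  bw <- .lstm_dir_forward(X, params$bwd, reverse = TRUE)
  hcat <- cbind(fw$h_last, bw$h_last)
  z <- drop(hcat %*% params$w_out) + params$b_out
  list(p = .sigmoid(z), z = z, hcat = hcat, fw = fw, bw = bw)
}

# Backprop through one direction given the gradient of the loss w.r.t. its
# final hidden state.
.lstm_dir_backward <- function(p, cache, dh_last) {
  T <- length(cache); H <- ncol(p$U)/4L
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dh <- dh_last; dc <- dh * 0
  for (s in T:1) {
    cc <- cache[[s]]
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$x, dA)
    dU <- dU + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dh <- dA %*% t(p$U)
    dc <- dc * cc$f
  }
  list(W = dW, U = dU, b = db)
}

# Mean binary cross-entropy and its gradient at the logit.
.bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

# Gradients of mean BCE w.r.t. every parameter, for one batch.
.net_backward <- function(X, y, params, fwdpass) {
  B <- dim(X)[1]; H <- params$H
  dz <- (fwdpass$p - y) / B                      # d(mean BCE)/dz
  dw_out <- crossprod(fwdpass$hcat, matrix(dz, ncol = 1))
  db_out <- sum(dz)
  dhcat <- matrix(dz, ncol = 1) %*% t(params$w_out)
  g_f <- .lstm_dir_backward(params$fwd, fwdpass$fw$cache,
                            dhcat[, 1:H, drop = FALSE])
  g_b <- .lstm_dir_backward(params$bwd, fwdpass$bw$cache,
                            dhcat[, (H + 1):(2 * H), drop = FALSE])
  list(fwd = g_f, bwd = g_b, w_out = dw_out, b_out = db_out)
}

# --- Adam -------------------------------------------------------------------

.flatten_grads <- function(g) {
  c(as.numeric(g$fwd$W), as.numeric(g$fwd$U), g$fwd$b,
    as.numeric(g$bwd$W), as.numeric(g$bwd$U), g$bwd$b,
    as.numeric(g$w_out), g$b_out)
}

.flatten_params <- function(p) {
  c(as.numeric(p$fwd$W), as.numeric(p$fwd$U), p$fwd$b,
    as.numeric(p$bwd$W), as.numeric(p$bwd$U), p$bwd$b,
    as.numeric(p$w_out), p$b_out)
}

.unflatten_params <- function(v, D, H) {
  take <- local({
    at <- 0L
    function(n) { out <- v[(at + 1L):(at + n)]; at <<- at + n; out }
  })
  dir_par <- function() list(W = matrix(take(D * 4 * H), D, 4 * H),
                             U = matrix(take(H * 4 * H), H, 4 * H),
                             b = take(4 * H))
  fwd <- dir_par(); bwd <- dir_par()
  list(fwd = fwd, bwd = bwd,
       w_out = matrix(take(2 * H), 2 * H, 1), b_out = take(1),
       D = D, H = H)
}

# Minibatch Adam on the BiLSTM. x: N x T x D array, y: 0/1 vector.
# RNG state on entry determines init and batch order; seed handling is the
# caller's job.
.fit_bilstm <- function(x, y, hidden_size, learning_rate, epochs, batch_size,
                        params = NULL, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  N <- dim(x)[1]; D <- dim(x)[3]
  if (is.null(params)) params <- .init_params(D, hidden_size)
  theta <- .flatten_params(params)
  m <- v <- numeric(length(theta))
  step <- 0L
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(N)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, N, by = batch_size)) {
      bi <- idx[b0:min(b0 + batch_size - 1L, N)]
      Xb <- x[bi, , , drop = FALSE]; yb <- y[bi]
      params <- .unflatten_params(theta, D, params$H)
      fp <- .net_forward(Xb, params)
      g <- .flatten_grads(.net_backward(Xb, yb, params, fp))
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^step)
      vhat <- v / (1 - beta2^step)
      theta <- theta - learning_rate * mhat / (sqrt(vhat) + eps)
      ep_loss <- ep_loss + .bce(fp$p, yb); nb <- nb + 1L
    }
    loss_hist[ep] <- ep_loss / max(nb, 1L)
  }
  params <- .unflatten_params(theta, D, params$H)
  list(params = params, loss = loss_hist)
}

# Forward-only scoring of an N x T x D array, in batches to bound memory.
.score_bilstm <- function(x, params, batch_size = 256L) {
  N <- dim(x)[1]
  out <- numeric(N)
  for (b0 in seq(1L, N, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, N)
    out[bi] <- .net_forward(x[bi, , , drop = FALSE], params)$p
  }
  out
}
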