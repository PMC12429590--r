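# Minimal dense neural-network machinery: 2-layer perceptrons with manual
# gradients, inverted dropout, and an Adam optimizer over nested parameter
# lists. Pure R; model sizes here are small enough that BLAS matmuls
# dominate and no compiled code is needed.

init_mlp <- function(d_in, d_h, d_out) {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  list(W1 = he(d_in, d_h), b1 = numeric(d_h),
       W2 = he(d_h, d_out), b2 = numeric(d_out))
}

addb <- function(M, b) sweep(M, 2, b, "+")

# Inverted dropout mask (already scaled by 1/(1-rate)); NULL when inactive.
drop_mask <- function(nr, nc, rate, training) {
  if (!training || rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1, 1 - rate) / (1 - rate), nr, nc)
}

mlp_forward <- function(p, X, rate = 0, training = FALSE) {
  H <- relu(addb(X %*% p$W1, p$b1))
  M <- drop_mask(nrow(H), ncol(H), rate, training)
  Hd <- if (is.null(M)) H else H * M
  list(out = addb(Hd %*% p$W2, p$b2), X = X, H = H, Hd = Hd, M = M)
}

mlp_backward <- function(p, fw, dOut) {
  gW2 <- t(fw$Hd) %*% dOut
  gb2 <- colSums(dOut)
  dHd <- dOut %*% t(p$W2)
  dH <- if (is.null(fw$M)) dHd else dHd * fw$M
  dPre <- dH * (fw$H > 0)
  gW1 <- t(fw$X) %*% dPre
  gb1 <- colSums(dPre)
  list(g = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       dX = dPre %*% t(p$W1))
}

tree_zero <- function(p) if (is.list(p)) lapply(p, tree_zero) else p * 0

adam_init <- function(par) list(m = tree_zero(par), v = tree_zero(par), t = 0)

# One Adam step with classic (coupled) L2 weight decay added to gradients.
adam_step <- function(par, grads, state, lr, wd = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  t <- state$t + 1
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      g <- g + wd * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- rec(par, grads, state$m, state$v)
  list(par = r$p, state = list(m = r$m, v = r$v, t = t))
}

cosine_lr <- function(lr0, epoch, max_epochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(1, max_epochs)))
}
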