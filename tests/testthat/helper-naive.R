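# Naive double-precision reference implementation of the 3Conv 2D network
# (plain R loops), used as the independent oracle for the compute backend.

naive_conv2d <- function(Xc, Wmat, b, kernel) {
  cin <- dim(Xc)[1]; E <- dim(Xc)[2]; T_ <- dim(Xc)[3]
  cout <- ncol(Wmat)
  plo <- floor((kernel - 1) / 2)
  out <- array(0, dim = c(cout, E, T_))
  for (co in 1:cout) for (e in 1:E) for (t in 1:T_) {
    acc <- b[co]
    for (k2 in 0:(kernel[2] - 1)) for (k1 in 0:(kernel[1] - 1)) {
      k <- k1 + kernel[1] * k2
      ee <- e + k1 - plo[1]; tt <- t + k2 - plo[2]
      if (ee >= 1 && ee <= E && tt >= 1 && tt <= T_)
        acc <- acc + sum(Wmat[k * cin + (1:cin), co] * Xc[, ee, tt])
    }
    out[co, e, t] <- acc
  }
  pmax(out, 0)
}

naive_pool2d <- function(A, p) {
  cout <- dim(A)[1]; E <- dim(A)[2]; T_ <- dim(A)[3]
  Eo <- E %/% p[1]; To <- T_ %/% p[2]
  out <- array(0, dim = c(cout, Eo, To))
  for (c in 1:cout) for (e in 1:Eo) for (t in 1:To)
    out[c, e, t] <- max(A[c, ((e - 1) * p[1] + 1):(e * p[1]),
                          ((t - 1) * p[2] + 1):(t * p[2])])
  out
}

# forward pass of 3Conv-2D for one parameter list (dropout inactive)
naive_3conv_logits <- function(params, Xs) {
  E <- dim(Xs)[1]; T_ <- dim(Xs)[2]; N <- dim(Xs)[3]
  logits <- matrix(0, N, 2)
  for (n in 1:N) {
    a1 <- naive_conv2d(array(Xs[, , n], dim = c(1, E, T_)),
                       params[[2]]$W, params[[2]]$b, c(5, 5))
    a2 <- naive_conv2d(a1, params[[4]]$W, params[[4]]$b, c(3, 3))
    a3 <- naive_pool2d(a2, c(2, 2))
    a4 <- naive_conv2d(a3, params[[6]]$W, params[[6]]$b, c(3, 3))
    Eo <- dim(a4)[2]; To <- dim(a4)[3]; S <- Eo * To
    f <- numeric(64 * S)
    for (c in 1:64) for (t in 1:To) for (e in 1:Eo)
      f[(c - 1) * S + (e - 1) + Eo * (t - 1) + 1] <- a4[c, e, t]
    h <- pmax(as.numeric(t(params[[9]]$W) %*% f + params[[9]]$b), 0)
    logits[n, ] <- as.numeric(t(params[[11]]$W) %*% h + params[[11]]$b)
  }
  logits
}

naive_3conv_loss <- function(params, Xs, y) {
  lg <- naive_3conv_logits(params, Xs)
  p <- t(apply(lg, 1, function(z) { z <- exp(z - max(z)); z / sum(z) }))
  mean(-log(p[cbind(seq_len(nrow(p)), y + 1)]))
}
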