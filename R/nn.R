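## Minimal CNN machinery in vectorised base R (no deep-learning library is
## available offline). Convolution is im2col + matrix multiply; max pooling
## compares stride-shifted submatrices; the optimiser is adaptive-moment SGD.
## Tensors are H x W x C arrays; kernels are kh x kw x C_in x C_out.

## gather-index matrix for im2col: rows index (di, dj, c) in kernel flatten
## order, columns index output positions (column-major). Valid convolution,
## stride 1.
im2col_index <- function(h, w, ch, kh, kw) {
  oh <- h - kh + 1L; ow <- w - kw + 1L
  di <- rep(seq_len(kh), times = kw * ch)
  dj <- rep(rep(seq_len(kw), each = kh), times = ch)
  cc <- rep(seq_len(ch), each = kh * kw)
  off <- (cc - 1L) * h * w + (dj - 1L) * h + (di - 1L)
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  base <- (oj - 1L) * h + oi
  list(idx = outer(off, base, `+`), oh = oh, ow = ow)
}

conv_fwd <- function(x, wmat, bias, idx_info) {
  cols <- matrix(x[idx_info$idx], nrow = nrow(idx_info$idx))
  out <- crossprod(cols, wmat)                      # (oh*ow) x C_out
  out <- sweep(out, 2L, bias, `+`)
  list(out = array(out, dim = c(idx_info$oh, idx_info$ow, ncol(wmat))), cols = cols)
}

conv_bwd <- function(dout, cols, wmat, idx_info, xdim) {
  f <- dim(dout)[3]
  dmat <- matrix(dout, ncol = f)                    # (oh*ow) x C_out
  dw <- cols %*% dmat
  db <- colSums(dmat)
  dcols <- wmat %*% t(dmat)                         # (kh*kw*C_in) x (oh*ow)
  dx <- numeric(prod(xdim))
  ## col2im: within one row of the index matrix (fixed kernel offset) all
  ## input positions are distinct, so accumulation is a plain indexed add
  for (r in seq_len(nrow(dcols))) {
    ii <- idx_info$idx[r, ]
    dx[ii] <- dx[ii] + dcols[r, ]
  }
  list(dx = array(dx, dim = xdim), dw = dw, db = db)
}

relu <- function(x) pmax(x, 0)

## max pool over all channels at once; `arg` holds linear indices into the
## full input array (used by the backward pass)
pool_fwd <- function(x, f, s) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; nc <- d[3]
  oh <- (h - f) %/% s + 1L; ow <- (w - f) %/% s + 1L
  ri <- seq.int(1L, by = s, length.out = oh)
  ci <- seq.int(1L, by = s, length.out = ow)
  chan_off <- rep((seq_len(nc) - 1L) * h * w, each = oh * ow)
  best <- array(-Inf, dim = c(oh, ow, nc))
  arg <- array(0L, dim = c(oh, ow, nc))
  for (dj in seq_len(f)) for (di in seq_len(f)) {
    rr <- ri + di - 1L; cc <- ci + dj - 1L
    sub <- x[rr, cc, , drop = FALSE]
    lin <- array(outer(rr, (cc - 1L) * h, `+`), dim = c(oh, ow, nc)) + chan_off
    upd <- sub > best
    best[upd] <- sub[upd]
    arg[upd] <- lin[upd]
  }
  list(out = best, arg = arg)
}

pool_bwd <- function(dout, arg, xdim, f = 2L, s = 2L) {
  dx <- numeric(prod(xdim))
  if (s >= f) {                          # non-overlapping windows: argmaxes unique
    dx[as.vector(arg)] <- as.vector(dout)
  } else {
    acc <- rowsum(as.vector(dout), group = as.vector(arg))
    dx[as.integer(rownames(acc))] <- acc
  }
  array(dx, dim = xdim)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = array(0, dim = dim(p) %||% length(p)),
                                  v = array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-10) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g * g
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
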