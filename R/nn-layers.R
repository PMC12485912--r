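# Minimal neural-network engine for the sequence-to-expression surrogate.
# All heavy lifting is im2col + BLAS matrix products, so a desk-scale model
# trains in minutes on one CPU. Layers: dilated 1-d convolution (zero
# padding, odd kernels), GELU, within-trunk average pooling, global average
# pooling over positions, layer normalization, dense layers, ReLU.
# Optimizer: AdamW with linear warm-up and cosine decay.

.idx_cache <- new.env(parent = emptyenv())

# gather indices for a dilated conv over B stacked individual blocks of
# length L; pad positions map to row B*L + 1 (a zero row appended later)
.conv_index <- function(L, k, d, B) {
  key <- paste(L, k, d, B, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  if (k %% 2L == 0L) stop("kernel sizes must be odd")
  off <- d * (seq_len(k) - (k + 1L) %/% 2L)
  pos <- seq_len(L)
  idx1 <- outer(pos, off, `+`)                 # L x k, NA out of block
  idx1[idx1 < 1L | idx1 > L] <- NA_integer_
  idx <- idx1[rep(seq_len(L), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * L, each = L)
  idx[is.na(idx)] <- B * L + 1L
  .idx_cache[[key]] <- idx
  idx
}

.im2col <- function(A, idx, k) {
  Apad <- rbind(A, 0)
  C <- ncol(A)
  out <- matrix(0, nrow(A), k * C)
  for (j in seq_len(k))
    out[, ((j - 1L) * C + 1L):(j * C)] <- Apad[idx[, j], , drop = FALSE]
  out
}

.col2im <- function(dCol, idx, k, C, n_rows) {
  dA <- matrix(0, n_rows + 1L, C)
  for (j in seq_len(k)) {
    tgt <- idx[, j]
    blk <- dCol[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    real <- tgt <= n_rows                     # drop pad rows
    dA[tgt[real], ] <- dA[tgt[real], , drop = FALSE] + blk[real, , drop = FALSE]
  }
  dA[seq_len(n_rows), , drop = FALSE]
}

.gelu <- function(x) x * pnorm(x)
.gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

.avgpool_fwd <- function(A, w) {
  n <- nrow(A) %/% w
  vapply(seq_len(ncol(A)),
         function(c) colMeans(matrix(A[, c], nrow = w)), numeric(n))
}

.avgpool_bwd <- function(dP, w) dP[rep(seq_len(nrow(dP)), each = w), ,
                                   drop = FALSE] / w

.layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, gamma, `*`) + rep(beta, each = nrow(x)),
       xhat = xhat, inv = inv)
}

.layernorm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
}

# ---- parameter initialization ------------------------------------------

.init_params <- function(cfg) {
  tk <- cfg$trunk
  p <- list()
  c_in <- 4L
  for (i in seq_along(tk$channels)) {
    k <- tk$kernels[i]; c_out <- tk$channels[i]
    p[[paste0("conv", i, ".W")]] <-
      matrix(rnorm(k * c_in * c_out, sd = sqrt(2 / (k * c_in))),
             k * c_in, c_out)
    p[[paste0("conv", i, ".b")]] <- numeric(c_out)
    c_in <- c_out
  }
  fdim <- c_in + cfg$cov_dim
  p[["ln.gamma"]] <- rep(1, fdim)
  p[["ln.beta"]] <- numeric(fdim)
  h <- cfg$head_hidden
  p[["fc1.W"]] <- matrix(rnorm(fdim * h, sd = sqrt(2 / fdim)), fdim, h)
  p[["fc1.b"]] <- numeric(h)
  p[["fc2.W"]] <- matrix(rnorm(h, sd = sqrt(1 / h)), h, 1)
  p[["fc2.b"]] <- 0
  p
}

# center the head output at init: after global pooling the inter-individual
# signal rides on a large static pattern, so the raw initial output is an
# arbitrary constant; absorbing it into the final bias saves the optimizer
# hundreds of updates
.center_output <- function(params, cfg, ref_oh) {
  X <- ref_oh
  cov0 <- if (cfg$cov_dim > 0L) matrix(0, 1, cfg$cov_dim) else NULL
  fw <- .nn_forward(params, cfg, X, 1L, cov0)
  params[["fc2.b"]] <- params[["fc2.b"]] - fw$out
  params
}

# post-LayerNorm feature matrix (input of the MLP head) for a set of
# individuals, batched
.nn_features <- function(params, cfg, batch_fn, ids, cov_std = NULL,
                         chunk = 64L) {
  out <- NULL
  for (s in seq(1L, length(ids), by = chunk)) {
    sel <- ids[s:min(s + chunk - 1L, length(ids))]
    X <- batch_fn(sel)
    fw <- .nn_forward(params, cfg, X, length(sel),
                      cov = if (is.null(cov_std)) NULL else
                        cov_std[sel, , drop = FALSE], keep_cache = TRUE)
    out <- rbind(out, fw$cache$ln$out)
  }
  rownames(out) <- ids
  out
}

# Head warm-start: closed-form ridge fit of a linear read-out on the frozen
# trunk's post-LayerNorm features, embedded exactly into the MLP head via a
# +/- ReLU unit pair (ReLU(wx) - ReLU(-wx) = wx); the remaining hidden
# units keep their random first-layer weights but start with zero output
# weight, so joint AdamW fine-tuning can recruit them. The ridge penalty is
# chosen by validation R^2. Mirrors training the new head on the frozen
# pre-trained trunk before joint fine-tuning.
.head_warmstart <- function(params, cfg, F_tr, y_tr, F_va, y_va,
                            lambdas = 10^seq(-8, 0, length.out = 9)) {
  xbar <- colMeans(F_tr)
  xsd <- apply(F_tr, 2, sd)
  xsd[xsd < 1e-12] <- 1
  Xc <- sweep(sweep(F_tr, 2, xbar), 2, xsd, `/`)
  Vc <- sweep(sweep(F_va, 2, xbar), 2, xsd, `/`)
  ybar <- mean(y_tr)
  S <- crossprod(Xc) / nrow(Xc)
  cv <- crossprod(Xc, y_tr - ybar) / nrow(Xc)
  best <- NULL
  for (lam in lambdas) {
    ws <- tryCatch(solve(S + lam * diag(ncol(S)), cv),
                   error = function(e) NULL)
    if (is.null(ws)) next
    pv <- as.vector(Vc %*% ws) + ybar
    r2 <- 1 - sum((y_va - pv)^2) / sum((y_va - mean(y_va))^2)
    if (is.null(best) || r2 > best$r2) best <- list(w = ws, r2 = r2)
  }
  if (is.null(best)) return(params)
  w <- as.numeric(best$w) / xsd          # back to unstandardized features
  h <- cfg$head_hidden
  params[["fc1.W"]][, 1] <- w
  params[["fc1.W"]][, 2] <- -w
  params[["fc1.b"]][1:2] <- 0
  params[["fc2.W"]][] <- 0
  params[["fc2.W"]][1, 1] <- 1
  params[["fc2.W"]][2, 1] <- -1
  params[["fc2.b"]] <- ybar - sum(w * xbar)
  params
}

# ---- forward / backward ------------------------------------------------

# Xbig: (B*L) x 4 matrix, rows individual-major; cov: B x c or NULL
.nn_forward <- function(params, cfg, Xbig, B, cov = NULL,
                        keep_cache = FALSE) {
  tk <- cfg$trunk
  L <- cfg$L
  A <- Xbig
  Lc <- L
  conv_cache <- if (keep_cache) vector("list", length(tk$channels))
  for (i in seq_along(tk$channels)) {
    k <- tk$kernels[i]; d <- tk$dilations[i]
    Z <- .cpp_conv_fwd(A, params[[paste0("conv", i, ".W")]],
                       params[[paste0("conv", i, ".b")]], B, Lc, k, d)
    H <- .cpp_gelu_fwd(Z)
    w <- tk$pools[i]
    out <- if (w > 1L) .cpp_avgpool_fwd(H, w) else H
    if (keep_cache)
      conv_cache[[i]] <- list(A_in = A, Z = Z, Lc = Lc)
    A <- out
    Lc <- Lc %/% max(w, 1L)
  }
  P <- rowsum(A, rep(seq_len(B), each = Lc), reorder = FALSE) / Lc
  feats <- if (!is.null(cov)) cbind(P, cov) else P
  ln <- .layernorm_fwd(feats, params[["ln.gamma"]], params[["ln.beta"]])
  z1 <- sweep(ln$out %*% params[["fc1.W"]], 2, params[["fc1.b"]], `+`)
  r1 <- pmax(z1, 0)
  out <- as.vector(r1 %*% params[["fc2.W"]]) + params[["fc2.b"]]
  res <- list(out = out)
  if (keep_cache)
    res$cache <- list(conv = conv_cache, A_final = A, Lc = Lc, P = P,
                      feats = feats, ln = ln, z1 = z1, r1 = r1, B = B,
                      cov_dim = if (is.null(cov)) 0L else ncol(cov))
  res
}

.nn_backward <- function(params, cfg, cache, dout) {
  g <- list()
  B <- cache$B
  dout <- matrix(dout, ncol = 1)
  g[["fc2.W"]] <- crossprod(cache$r1, dout)
  g[["fc2.b"]] <- sum(dout)
  dr1 <- dout %*% t(params[["fc2.W"]])
  dz1 <- dr1 * (cache$z1 > 0)
  g[["fc1.W"]] <- crossprod(cache$ln$out, dz1)
  g[["fc1.b"]] <- colSums(dz1)
  dln_out <- dz1 %*% t(params[["fc1.W"]])
  lb <- .layernorm_bwd(dln_out, cache$ln, params[["ln.gamma"]])
  g[["ln.gamma"]] <- lb$dgamma
  g[["ln.beta"]] <- lb$dbeta
  n_ch <- ncol(cache$P)
  dP <- lb$dx[, seq_len(n_ch), drop = FALSE]
  Lc <- cache$Lc
  dA <- dP[rep(seq_len(B), each = Lc), , drop = FALSE] / Lc
  tk <- cfg$trunk
  for (i in rev(seq_along(tk$channels))) {
    cc <- cache$conv[[i]]
    w <- tk$pools[i]
    dH <- if (w > 1L) .cpp_avgpool_bwd(dA, w) else dA
    dZ <- .cpp_gelu_bwd(cc$Z, dH)
    cb <- .cpp_conv_bwd(cc$A_in, dZ, params[[paste0("conv", i, ".W")]],
                        B, cc$Lc, tk$kernels[i], tk$dilations[i], i > 1L)
    g[[paste0("conv", i, ".W")]] <- cb$dW
    g[[paste0("conv", i, ".b")]] <- as.numeric(cb$db)
    if (i > 1L) dA <- cb$dX
  }
  g
}

# ---- optimizer ---------------------------------------------------------

.adamw_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamw_step <- function(params, grads, state, lr, wd = 0.01,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    decay <- if (grepl("\\.W$", nm)) wd * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - lr * (upd + decay)
  }
  list(params = params, state = state)
}

#' Learning-rate schedule: linear warm-up, then cosine decay to zero
#'
#' The rate rises linearly over the first `warmup` fraction of optimizer
#' updates to `peak`, then follows a half-cosine down to exactly 0 at the
#' final update.
#'
#' @param step current optimizer update (1-based)
#' @param total total number of optimizer updates
#' @param peak peak learning rate
#' @param warmup warm-up fraction of total updates
#' @return learning rate at `step`
#' @export
lr_schedule <- function(step, total, peak = 1e-4, warmup = 0.1) {
  w <- warmup * total
  ifelse(step <= w, peak * step / w,
         peak * 0.5 * (1 + cos(pi * (step - w) / (total - w))))
}

# global-norm gradient clipping (stabilizer for small batches)
.clip_grads <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  grads
}
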