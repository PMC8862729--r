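# Reverse-mode gradients for the encoder, the MLM head, and a small Adam
# optimizer operating directly on the nested parameter structure.

numeric_part <- function(params) {
  params[c("token", "pos", "layers", "mlm_W", "mlm_b")]
}

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(k)
      do.call(tree_map, c(list(f), lapply(trees, `[[`, k))))
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

tree_sum <- function(tree, f = identity) {
  if (is.list(tree)) sum(vapply(tree, tree_sum, numeric(1), f = f))
  else sum(f(tree))
}

zero_grads <- function(params) tree_map(function(x) x * 0, numeric_part(params))

#' Squared L2 norm of all model parameters
#'
#' @param params A \code{"model_params"}.
#' @return Scalar sum of squares over every trainable weight.
#' @export
param_sq_norm <- function(params) tree_sum(numeric_part(params), function(x) x^2)

layer_norm_backward <- function(dY, ln, g) {
  Dn <- ncol(dY)
  dxhat <- sweep(dY, 2, g, `*`)
  rs <- rowSums(dxhat)
  rx <- rowSums(dxhat * ln$xhat)
  dX <- (dxhat - rs / Dn - ln$xhat * rx / Dn) * ln$inv
  list(dX = dX, dg = colSums(dY * ln$xhat), db = colSums(dY))
}

# dZ: gradient of the loss w.r.t. the final embedding Z.
# Returns a gradient tree matching numeric_part(params); mlm head grads zero.
transformer_backward <- function(dZ, cache, params) {
  config <- params$config
  D <- config$D; H <- config$H; Hd <- config$head_dim
  scale <- sqrt(D)
  grads <- zero_grads(params)
  dX <- dZ
  for (l in rev(seq_len(config$n_layers))) {
    lp <- params$layers[[l]]
    lc <- cache$layers[[l]]
    gl <- grads$layers[[l]]
    # X2 = LN2(R2) (optional)
    if (config$use_layernorm) {
      lb <- layer_norm_backward(dX, lc$ln2, lp$ln2_g)
      dR2 <- lb$dX; gl$ln2_g <- gl$ln2_g + lb$dg; gl$ln2_b <- gl$ln2_b + lb$db
    } else dR2 <- dX
    # R2 = X1 + FFN(X1)
    dFout <- dR2
    dHact <- dFout %*% t(lp$W2)
    gl$W2 <- gl$W2 + t(lc$Hact) %*% dFout
    gl$b2 <- gl$b2 + colSums(dFout)
    dHpre <- dHact * gelu_grad(lc$Hpre)
    gl$W1 <- gl$W1 + t(lc$X1) %*% dHpre
    gl$b1 <- gl$b1 + colSums(dHpre)
    dX1 <- dHpre %*% t(lp$W1)
    if (config$use_residual) dX1 <- dX1 + dR2
    # X1 = LN1(R1) (optional)
    if (config$use_layernorm) {
      lb <- layer_norm_backward(dX1, lc$ln1, lp$ln1_g)
      dR1 <- lb$dX; gl$ln1_g <- gl$ln1_g + lb$dg; gl$ln1_b <- gl$ln1_b + lb$db
    } else dR1 <- dX1
    # R1 = X_in + Concat %*% Wo
    dC <- dR1
    gl$Wo <- gl$Wo + t(lc$concat) %*% dC
    dConcat <- dC %*% t(lp$Wo)
    X_in <- lc$X_in
    dX_in <- if (config$use_residual) dR1 else matrix(0, nrow(dR1), D)
    for (h in seq_len(H)) {
      hc <- lc$heads[[h]]
      dHead <- dConcat[, ((h - 1L) * Hd + 1L):(h * Hd), drop = FALSE]
      dA <- dHead %*% t(hc$V)
      dV <- t(hc$A) %*% dHead
      dS <- hc$A * (dA - rowSums(dA * hc$A))
      dQ <- (dS %*% hc$K) / scale
      dK <- (t(dS) %*% hc$Q) / scale
      gl$Wq[[h]] <- gl$Wq[[h]] + t(X_in) %*% dQ
      gl$Wk[[h]] <- gl$Wk[[h]] + t(X_in) %*% dK
      gl$Wv[[h]] <- gl$Wv[[h]] + t(X_in) %*% dV
      dX_in <- dX_in + dQ %*% t(lp$Wq[[h]]) + dK %*% t(lp$Wk[[h]]) +
               dV %*% t(lp$Wv[[h]])
    }
    grads$layers[[l]] <- gl
    dX <- dX_in
  }
  # X0 = token[tokens] + pos[1..n]
  tokens <- cache$tokens
  n <- length(tokens)
  for (t in seq_len(n)) {
    grads$token[tokens[t] + 1L, ] <- grads$token[tokens[t] + 1L, ] + dX[t, ]
  }
  grads$pos[seq_len(n), ] <- grads$pos[seq_len(n), ] + dX
  grads
}

grads_add <- function(a, b) tree_map(`+`, a, b)
grads_scale <- function(a, s) tree_map(function(x) x * s, a)

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 5e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  new_num <- tree_map(`-`, numeric_part(params), upd)
  params[names(new_num)] <- new_num
  list(params = params, state = state)
}
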