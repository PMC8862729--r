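VOCAB <- c(A = 0L, C = 1L, G = 2L, U = 3L, MASK = 4L, PAD = 5L)
N_BASES <- 4L

#' Encoder configuration
#'
#' Hyperparameters of the transformer encoder. Defaults follow the published
#' architecture where stated (embedding width 120, six layers); head count,
#' feed-forward width and activation were tuned by the original authors and
#' not reported, so the defaults here (12 heads, 4x width, GELU) are declared
#' choices, all configurable.
#'
#' @param D Embedding width (default 120).
#' @param n_layers Number of transformer layers (default 6).
#' @param H Attention heads (default 12).
#' @param ffn_dim Feed-forward hidden width (default \code{4 * D}).
#' @param max_len Maximum sequence length (default 440).
#' @param head_dim Per-head projection width. The default \code{D} follows
#'   the literal DxD per-head statement; set \code{D / H} for the
#'   conventional split.
#' @param use_residual,use_layernorm Enable residual connections and
#'   post-block layer normalization (default \code{TRUE}; may be disabled
#'   for unit-level analysis).
#' @return A list of class \code{"model_config"}.
#' @export
model_config <- function(D = 120L, n_layers = 6L, H = 12L, ffn_dim = 4L * D,
                         max_len = 440L, head_dim = D,
                         use_residual = TRUE, use_layernorm = TRUE) {
  stopifnot(D > 0, n_layers >= 1, H >= 1, max_len >= 1, head_dim > 0,
            ffn_dim > 0)
  structure(list(D = as.integer(D), n_layers = as.integer(n_layers),
                 H = as.integer(H), ffn_dim = as.integer(ffn_dim),
                 max_len = as.integer(max_len), head_dim = as.integer(head_dim),
                 use_residual = isTRUE(use_residual),
                 use_layernorm = isTRUE(use_layernorm)),
            class = "model_config")
}

#' Initialize model parameters
#'
#' Draws all trainable weights (token and position tables, per-layer
#' attention and feed-forward weights, layer-norm affine parameters, and the
#' masked-language-modelling head) from scaled Gaussians. Uses R's global
#' RNG; call \code{set.seed()} first for reproducibility.
#'
#' @param config A \code{"model_config"}.
#' @param init_sd Standard deviation of weight initialization (default 0.08).
#' @return A list of class \code{"model_params"}.
#' @export
init_params <- function(config, init_sd = 0.08) {
  D <- config$D; Hd <- config$head_dim; H <- config$H; Fd <- config$ffn_dim
  rmat <- function(r, c, sd = init_sd) matrix(stats::rnorm(r * c, sd = sd), r, c)
  layers <- lapply(seq_len(config$n_layers), function(l) {
    list(Wq = lapply(seq_len(H), function(h) rmat(D, Hd)),
         Wk = lapply(seq_len(H), function(h) rmat(D, Hd)),
         Wv = lapply(seq_len(H), function(h) rmat(D, Hd)),
         Wo = rmat(H * Hd, D),
         W1 = rmat(D, Fd), b1 = numeric(Fd),
         W2 = rmat(Fd, D), b2 = numeric(D),
         ln1_g = rep(1, D), ln1_b = numeric(D),
         ln2_g = rep(1, D), ln2_b = numeric(D))
  })
  structure(list(token = rmat(length(VOCAB), D, sd = 0.5),
                 pos = rmat(config$max_len, D, sd = 0.5),
                 layers = layers,
                 mlm_W = rmat(D, N_BASES), mlm_b = numeric(N_BASES),
                 config = config),
            class = "model_params")
}

#' Tokenize an RNA sequence
#'
#' Fixed vocabulary order \code{A=0, C=1, G=2, U=3, MASK=4, PAD=5}.
#'
#' @param residues RNA residue string over \code{A/C/G/U} (normalize
#'   upstream with \code{read_fasta} conventions).
#' @param max_len Maximum admissible length.
#' @return Integer vector of 0-based token ids.
#' @export
tokenize <- function(residues, max_len = 440L) {
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) > max_len)
    stop("sequence length ", length(chars), " exceeds max_len ", max_len)
  ids <- VOCAB[chars]
  if (any(is.na(ids))) stop("non-ACGU residue in sequence")
  unname(ids)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layer_norm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, g, `*`) + matrix(b, nrow(X), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Transformer forward pass
#'
#' Maps a token id sequence to the per-base embedding matrix Z. The input to
#' the first layer is the element-wise sum of the token embedding and the
#' position embedding. Each layer applies multi-head scaled dot-product
#' self-attention (scale \code{sqrt(D)}), concatenation and an output
#' projection, then a position-wise feed-forward network, with residual
#' connections and post-norm layer normalization (configurable). PAD
#' positions, if present, are excluded from attention as keys.
#'
#' @param tokens Integer vector of 0-based token ids.
#' @param params A \code{"model_params"}.
#' @param keep_cache Keep intermediate activations for backpropagation and
#'   attention-map extraction.
#' @return If \code{keep_cache} is \code{FALSE}, the n x D embedding matrix
#'   Z; otherwise a list with \code{Z} and \code{cache}.
#' @export
transformer_forward <- function(tokens, params, keep_cache = FALSE) {
  config <- params$config
  n <- length(tokens)
  if (n == 0L) stop("empty token sequence")
  if (n > config$max_len) stop("sequence longer than max_len")
  D <- config$D; H <- config$H; scale <- sqrt(D)
  pad_mask <- tokens == VOCAB[["PAD"]]
  X <- params$token[tokens + 1L, , drop = FALSE] +
       params$pos[seq_len(n), , drop = FALSE]
  cache <- list(tokens = tokens, X0 = X, layers = vector("list", config$n_layers))
  for (l in seq_len(config$n_layers)) {
    lp <- params$layers[[l]]
    lc <- list(X_in = X, heads = vector("list", H))
    concat <- matrix(0, n, H * config$head_dim)
    for (h in seq_len(H)) {
      Q <- X %*% lp$Wq[[h]]
      K <- X %*% lp$Wk[[h]]
      V <- X %*% lp$Wv[[h]]
      S <- (Q %*% t(K)) / scale
      if (any(pad_mask)) S[, pad_mask] <- -Inf
      A <- softmax_rows(S)
      concat[, ((h - 1L) * config$head_dim + 1L):(h * config$head_dim)] <- A %*% V
      lc$heads[[h]] <- list(Q = Q, K = K, V = V, A = A)
    }
    C <- concat %*% lp$Wo
    lc$concat <- concat
    R1 <- if (config$use_residual) X + C else C
    if (config$use_layernorm) {
      ln1 <- layer_norm(R1, lp$ln1_g, lp$ln1_b)
      X1 <- ln1$out
      lc$ln1 <- ln1
    } else X1 <- R1
    lc$R1 <- R1; lc$X1 <- X1
    Hpre <- X1 %*% lp$W1 + matrix(lp$b1, n, config$ffn_dim, byrow = TRUE)
    Hact <- gelu(Hpre)
    Fout <- Hact %*% lp$W2 + matrix(lp$b2, n, D, byrow = TRUE)
    R2 <- if (config$use_residual) X1 + Fout else Fout
    if (config$use_layernorm) {
      ln2 <- layer_norm(R2, lp$ln2_g, lp$ln2_b)
      X2 <- ln2$out
      lc$ln2 <- ln2
    } else X2 <- R2
    lc$Hpre <- Hpre; lc$Hact <- Hact; lc$R2 <- R2
    cache$layers[[l]] <- lc
    X <- X2
  }
  if (any(!is.finite(X))) stop("non-finite values in embedding")
  if (keep_cache) list(Z = X, cache = cache) else X
}

#' Embed an RNA sequence
#'
#' Convenience wrapper: tokenize then run the encoder.
#'
#' @param residues RNA residue string.
#' @param params A \code{"model_params"}.
#' @return n x D embedding matrix Z.
#' @export
embed_sequence <- function(residues, params) {
  transformer_forward(tokenize(residues, params$config$max_len), params)
}

#' Attention map of a sequence
#'
#' Per-position attention mass: each head's softmax attention rows are
#' summed over heads and query positions, giving one non-negative value per
#' key position. The total mass equals \code{n * H} since every softmax row
#' sums to one. By default the map is taken from the final transformer
#' layer.
#'
#' @param tokens Integer vector of 0-based token ids.
#' @param params A \code{"model_params"}.
#' @param layer Layer index in \code{1..n_layers} (default: final layer).
#' @return Numeric vector of length n.
#' @export
attention_map <- function(tokens, params, layer = params$config$n_layers) {
  config <- params$config
  if (layer < 1 || layer > config$n_layers) stop("invalid layer index")
  fwd <- transformer_forward(tokens, params, keep_cache = TRUE)
  heads <- fwd$cache$layers[[layer]]$heads
  m <- numeric(length(tokens))
  for (h in seq_along(heads)) m <- m + colSums(heads[[h]]$A)
  m
}
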