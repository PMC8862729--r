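#' Affine gap scoring parameters
#'
#' A run of L consecutive gap columns in the same direction scores
#' \code{open + extend * (L - 1)}: the first column of a run carries the
#' opening score. Defaults follow the published setting (open -1,
#' extend -0.1).
#'
#' @param open Gap opening score (<= 0).
#' @param extend Gap extension score (<= 0).
#' @return A list of class \code{"gap_params"}.
#' @export
gap_params <- function(open = -1, extend = -0.1) {
  stopifnot(open <= 0, extend <= 0)
  structure(list(open = open, extend = extend), class = "gap_params")
}

#' Score an alignment against a score matrix
#'
#' The alignment score f is the sum of the match scores \code{omega[i, j]}
#' over matched columns plus the affine gap cost of every maximal run of
#' same-direction gap columns.
#'
#' @param omega n x m score matrix.
#' @param gaps A \code{"gap_params"}.
#' @param y A \code{"pairwise_alignment"} with \code{n} and \code{m}
#'   matching \code{dim(omega)}.
#' @return Scalar alignment score.
#' @export
alignment_score <- function(omega, gaps, y) {
  if (y$n != nrow(omega) || y$m != ncol(omega))
    stop("alignment dimensions do not match the score matrix")
  f <- 0
  prev <- "match"
  for (k in seq_along(y$i)) {
    if (!is.na(y$i[k]) && !is.na(y$j[k])) {
      f <- f + omega[y$i[k], y$j[k]]
      prev <- "match"
    } else {
      cur <- if (is.na(y$j[k])) "gap_b" else "gap_a"
      f <- f + if (identical(prev, cur)) gaps$extend else gaps$open
      prev <- cur
    }
  }
  f
}

#' Global alignment by affine-gap Needleman-Wunsch
#'
#' Three-state dynamic programming (match, gap-in-second, gap-in-first)
#' maximizing the alignment score f over all global alignments; quadratic
#' time in the sequence lengths. Traceback ties are broken deterministically:
#' match over gap-in-second over gap-in-first. Terminal gaps are penalized
#' like internal ones.
#'
#' @param omega n x m score matrix (e.g. the cosine score matrix of two
#'   embedded sequences).
#' @param gaps A \code{"gap_params"}.
#' @return A list of class \code{"alignment_result"} with \code{alignment}
#'   (a \code{"pairwise_alignment"}) and \code{score}.
#' @export
nw_affine <- function(omega, gaps = gap_params()) {
  n <- nrow(omega); m <- ncol(omega)
  if (is.null(n) || n == 0L || m == 0L) stop("empty score matrix")
  op <- gaps$open; ex <- gaps$extend
  NEG <- -Inf
  # state 1 = M (match), 2 = X (gap in second, consumes i), 3 = Y (gap in first)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  pM <- matrix(0L, n + 1L, m + 1L)
  pX <- matrix(0L, n + 1L, m + 1L)
  pY <- matrix(0L, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n >= 1) {
    X[2, 1] <- op; pX[2, 1] <- 1L
    if (n >= 2) for (i in 2:n) { X[i + 1L, 1] <- X[i, 1] + ex; pX[i + 1L, 1] <- 2L }
  }
  if (m >= 1) {
    Y[1, 2] <- op; pY[1, 2] <- 1L
    if (m >= 2) for (j in 2:m) { Y[1, j + 1L] <- Y[1, j] + ex; pY[1, j + 1L] <- 3L }
  }
  best3 <- function(a, b, c) {
    # first maximum in preference order M > X > Y
    if (a >= b && a >= c) list(v = a, p = 1L)
    else if (b >= c) list(v = b, p = 2L)
    else list(v = c, p = 3L)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      bm <- best3(M[i, j], X[i, j], Y[i, j])
      M[i + 1L, j + 1L] <- omega[i, j] + bm$v
      pM[i + 1L, j + 1L] <- bm$p
      bx <- best3(M[i, j + 1L] + op, X[i, j + 1L] + ex, Y[i, j + 1L] + op)
      X[i + 1L, j + 1L] <- bx$v
      pX[i + 1L, j + 1L] <- bx$p
      by <- best3(M[i + 1L, j] + op, X[i + 1L, j] + op, Y[i + 1L, j] + ex)
      Y[i + 1L, j + 1L] <- by$v
      pY[i + 1L, j + 1L] <- by$p
    }
  }
  fin <- best3(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- fin$p
  i <- n; j <- m
  ci <- integer(0); cj <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      ci <- c(i, ci); cj <- c(j, cj)
      state <- pM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ci <- c(i, ci); cj <- c(NA_integer_, cj)
      state <- pX[i + 1L, j + 1L]
      i <- i - 1L
    } else {
      ci <- c(NA_integer_, ci); cj <- c(j, cj)
      state <- pY[i + 1L, j + 1L]
      j <- j - 1L
    }
  }
  structure(list(alignment = pairwise_alignment(ci, cj), score = fin$v),
            class = "alignment_result")
}

#' Structural alignment of two RNA sequences
#'
#' Embeds both sequences with the encoder, builds the cosine score matrix
#' and runs affine-gap Needleman-Wunsch over it.
#'
#' @param a,b RNA residue strings.
#' @param params A \code{"model_params"}.
#' @param gaps A \code{"gap_params"}.
#' @return An \code{"alignment_result"} with an extra \code{aligned_rows}
#'   field (the two gapped strings).
#' @export
align_pair <- function(a, b, params, gaps = gap_params()) {
  om <- omega(embed_sequence(a, params), embed_sequence(b, params))
  res <- nw_affine(om, gaps)
  res$aligned_rows <- alignment_rows(res$alignment, a, b)
  res
}

#' Alignment accuracy against a reference
#'
#' Counts are over matched position pairs (i, j) only; gap columns are
#' ignored. Sensitivity is TP over the number of reference pairs, PPV is TP
#' over the number of predicted pairs, and F1 is their harmonic mean (0 when
#' both are 0).
#'
#' @param pred,ref \code{"pairwise_alignment"} objects over the same
#'   sequence pair.
#' @return A list with \code{tp}, \code{sensitivity}, \code{ppv}, \code{f1}.
#' @export
alignment_metrics <- function(pred, ref) {
  if (pred$n != ref$n || pred$m != ref$m)
    stop("alignments are over different sequence pairs")
  mp <- matched_pairs(pred); mr <- matched_pairs(ref)
  kp <- paste(mp[, 1], mp[, 2]); kr <- paste(mr[, 1], mr[, 2])
  tp <- length(intersect(kp, kr))
  sen <- if (length(kr) > 0) tp / length(kr) else 0
  ppv <- if (length(kp) > 0) tp / length(kp) else 0
  f1 <- if (sen + ppv > 0) 2 * sen * ppv / (sen + ppv) else 0
  list(tp = tp, sensitivity = sen, ppv = ppv, f1 = f1)
}
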