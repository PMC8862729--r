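#' Cosine score matrix between two embedded sequences
#'
#' \code{omega[i, j]} is the cosine similarity between embedding row i of
#' the first sequence and row j of the second; every entry lies in
#' \code{[-1, 1]}.
#'
#' @param Z,Zp Embedding matrices (n x D and m x D).
#' @return n x m score matrix.
#' @export
omega <- function(Z, Zp) {
  Z <- rbind(Z); Zp <- rbind(Zp)
  nz <- sqrt(rowSums(Z^2)); nzp <- sqrt(rowSums(Zp^2))
  if (any(nz == 0)) stop("zero-norm embedding row at position ",
                         which(nz == 0)[1], " of first sequence")
  if (any(nzp == 0)) stop("zero-norm embedding row at position ",
                          which(nzp == 0)[1], " of second sequence")
  (Z / nz) %*% t(Zp / nzp)
}

#' Margin penalty parameters
#'
#' Per-pair penalties of the structured margin: \code{delta_fn} for each
#' reference matched pair missing from the prediction, \code{delta_fp} for
#' each predicted matched pair absent from the reference. Defaults follow
#' the published grid-searched values (0.05 and 0.1).
#'
#' @param delta_fn,delta_fp Non-negative penalties.
#' @return A list of class \code{"margin_params"}.
#' @export
margin_params <- function(delta_fn = 0.05, delta_fp = 0.1) {
  stopifnot(delta_fn >= 0, delta_fp >= 0)
  structure(list(delta_fn = delta_fn, delta_fp = delta_fp),
            class = "margin_params")
}

#' Structured margin between two alignments
#'
#' \code{delta_fn} times the number of matched pairs in \code{y} but not in
#' \code{yhat}, plus \code{delta_fp} times the number of matched pairs in
#' \code{yhat} but not in \code{y}. Counts are over matched position pairs
#' only; gap columns do not enter.
#'
#' @param y,yhat \code{"pairwise_alignment"} objects over the same pair.
#' @param margin A \code{"margin_params"}.
#' @return Non-negative scalar.
#' @export
margin_delta <- function(y, yhat, margin = margin_params()) {
  if (y$n != yhat$n || y$m != yhat$m)
    stop("alignments are over different sequence pairs")
  my <- matched_pairs(y); mh <- matched_pairs(yhat)
  ky <- paste(my[, 1], my[, 2]); kh <- paste(mh[, 1], mh[, 2])
  margin$delta_fn * length(setdiff(ky, kh)) +
    margin$delta_fp * length(setdiff(kh, ky))
}

#' Loss-augmented decoding
#'
#' Finds the alignment maximizing \code{f(yhat) + Delta(y, yhat)}. Because
#' the margin decomposes over matched pairs, this is an affine-gap
#' Needleman-Wunsch on modified match scores: \code{omega[i, j] + delta_fp}
#' for pairs not in the reference and \code{omega[i, j] - delta_fn} for
#' reference pairs; the constant \code{delta_fn * |matched(y)|} is added to
#' the optimum.
#'
#' @param omega n x m score matrix.
#' @param gaps A \code{"gap_params"}.
#' @param y Reference \code{"pairwise_alignment"}.
#' @param margin A \code{"margin_params"}.
#' @return A list with \code{yhat} (the decoded alignment) and
#'   \code{objective} (\code{f(yhat) + Delta(y, yhat)}).
#' @export
loss_augmented_decode <- function(omega, gaps, y, margin = margin_params()) {
  if (y$n != nrow(omega) || y$m != ncol(omega))
    stop("reference alignment does not match the score matrix")
  my <- matched_pairs(y)
  om2 <- omega + margin$delta_fp
  if (nrow(my) > 0)
    om2[my] <- omega[my] - margin$delta_fn
  res <- nw_affine(om2, gaps)
  list(yhat = res$alignment,
       objective = res$score + margin$delta_fn * nrow(my))
}

#' Structured hinge loss of one training instance
#'
#' Embeds both sequences, builds the cosine score matrix, decodes the
#' loss-augmented alignment and reports the structured hinge
#' \code{f(yhat) + Delta(y, yhat) - f(y)} plus the L2 regularization term
#' \code{lambda * ||w||^2} over all model parameters.
#'
#' @param a,b RNA residue strings.
#' @param y Reference \code{"pairwise_alignment"} between them.
#' @param params A \code{"model_params"}.
#' @param margin A \code{"margin_params"}.
#' @param gaps A \code{"gap_params"}.
#' @param lambda L2 regularization weight.
#' @return A list of class \code{"sal_loss_report"} with \code{f_ref},
#'   \code{f_hat}, \code{delta}, \code{hinge}, \code{reg}, \code{total}.
#' @export
sal_loss <- function(a, b, y, params, margin = margin_params(),
                     gaps = gap_params(), lambda = 1e-4) {
  Z <- embed_sequence(a, params)
  Zp <- embed_sequence(b, params)
  om <- omega(Z, Zp)
  f_ref <- alignment_score(om, gaps, y)
  dec <- loss_augmented_decode(om, gaps, y, margin)
  f_hat <- alignment_score(om, gaps, dec$yhat)
  delta <- margin_delta(y, dec$yhat, margin)
  hinge <- f_hat + delta - f_ref
  reg <- lambda * param_sq_norm(params)
  structure(list(f_ref = f_ref, f_hat = f_hat, delta = delta,
                 hinge = hinge, reg = reg, total = hinge + reg,
                 yhat = dec$yhat),
            class = "sal_loss_report")
}

# Gradient of omega-level hinge coefficients back to the two embeddings.
# coef is a sparse set of (i, j, c) with c = +1 for pairs matched in yhat
# only and -1 for pairs matched in y only.
omega_backward <- function(Z, Zp, pairs_ij, coefs) {
  nz <- sqrt(rowSums(Z^2)); nzp <- sqrt(rowSums(Zp^2))
  U <- Z / nz; V <- Zp / nzp
  dZ <- matrix(0, nrow(Z), ncol(Z))
  dZp <- matrix(0, nrow(Zp), ncol(Zp))
  for (k in seq_len(NROW(pairs_ij))) {
    i <- pairs_ij[k, 1]; j <- pairs_ij[k, 2]; cc <- coefs[k]
    w <- sum(U[i, ] * V[j, ])
    dZ[i, ] <- dZ[i, ] + cc * (V[j, ] - w * U[i, ]) / nz[i]
    dZp[j, ] <- dZp[j, ] + cc * (U[i, ] - w * V[j, ]) / nzp[j]
  }
  list(dZ = dZ, dZp = dZp)
}

# Structured-hinge subgradient for one (a, b, y) instance: the decoded yhat
# is treated as fixed within the step.
sal_instance_grad <- function(a, b, y, params, margin = margin_params(),
                              gaps = gap_params(), lambda = 1e-4) {
  fa <- transformer_forward(tokenize(a, params$config$max_len), params,
                            keep_cache = TRUE)
  fb <- transformer_forward(tokenize(b, params$config$max_len), params,
                            keep_cache = TRUE)
  om <- omega(fa$Z, fb$Z)
  f_ref <- alignment_score(om, gaps, y)
  dec <- loss_augmented_decode(om, gaps, y, margin)
  f_hat <- alignment_score(om, gaps, dec$yhat)
  delta <- margin_delta(y, dec$yhat, margin)
  hinge <- f_hat + delta - f_ref
  my <- matched_pairs(y); mh <- matched_pairs(dec$yhat)
  ky <- paste(my[, 1], my[, 2]); kh <- paste(mh[, 1], mh[, 2])
  plus <- mh[!(kh %in% ky), , drop = FALSE]   # in yhat only: d f_hat
  minus <- my[!(ky %in% kh), , drop = FALSE]  # in y only: -d f_ref
  both <- rbind(plus, minus)
  coefs <- c(rep(1, NROW(plus)), rep(-1, NROW(minus)))
  grads <- zero_grads(params)
  if (NROW(both) > 0) {
    ob <- omega_backward(fa$Z, fb$Z, both, coefs)
    grads <- grads_add(transformer_backward(ob$dZ, fa$cache, params),
                       transformer_backward(ob$dZp, fb$cache, params))
  }
  if (lambda > 0) {
    reg_grad <- tree_map(function(x) 2 * lambda * x, numeric_part(params))
    grads <- grads_add(grads, reg_grad)
  }
  list(hinge = hinge, reg = lambda * param_sq_norm(params),
       grads = grads, delta = delta)
}

#' One epoch of structural alignment learning
#'
#' Per-instance Adam updates of the structured hinge plus L2 regularization
#' over a shuffled pass of the training pairs. Each instance is a list with
#' residue strings \code{a}, \code{b} and a reference alignment \code{y}.
#'
#' @param pairs List of training instances.
#' @param params A \code{"model_params"}.
#' @param state Adam state or \code{NULL}.
#' @param margin A \code{"margin_params"}.
#' @param gaps A \code{"gap_params"}.
#' @param lambda L2 weight (default 1e-4).
#' @param lr Learning rate.
#' @return List with updated \code{params}, \code{state}, mean \code{hinge}
#'   and mean \code{reg}.
#' @export
train_sal_epoch <- function(pairs, params, state = NULL,
                            margin = margin_params(), gaps = gap_params(),
                            lambda = 1e-4, lr = 5e-3) {
  if (length(pairs) == 0L) stop("empty SAL dataset")
  if (is.null(state)) state <- adam_init(params)
  hinges <- regs <- numeric(length(pairs))
  ord <- sample.int(length(pairs))
  for (k in seq_along(ord)) {
    p <- pairs[[ord[k]]]
    res <- sal_instance_grad(p$a, p$b, p$y, params, margin, gaps, lambda)
    hinges[k] <- res$hinge; regs[k] <- res$reg
    st <- adam_step(params, res$grads, state, lr = lr)
    params <- st$params; state <- st$state
  }
  list(params = params, state = state, hinge = mean(hinges), reg = mean(regs))
}

#' Mean structured hinge over a set of pairs (no updates)
#'
#' @param pairs List of instances as in \code{train_sal_epoch}.
#' @param params A \code{"model_params"}.
#' @param margin,gaps Margin and gap parameters.
#' @return Mean hinge.
#' @export
sal_eval <- function(pairs, params, margin = margin_params(),
                     gaps = gap_params()) {
  mean(vapply(pairs, function(p)
    sal_loss(p$a, p$b, p$y, params, margin, gaps, lambda = 0)$hinge,
    numeric(1)))
}
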