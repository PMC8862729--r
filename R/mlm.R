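#' Masking policy for masked language modelling
#'
#' Defaults follow the BERT-style recipe: 15\% of positions are selected;
#' of these, 80\% are replaced by the MASK token, 10\% are substituted with
#' one of the other three bases, and 10\% are kept unchanged.
#'
#' @param select_rate Fraction of positions selected.
#' @param mask_action,random_action,keep_action Action probabilities for a
#'   selected position; must sum to 1.
#' @return A list of class \code{"mask_policy"}.
#' @export
mask_policy <- function(select_rate = 0.15, mask_action = 0.8,
                        random_action = 0.1, keep_action = 0.1) {
  stopifnot(select_rate > 0, select_rate <= 1,
            abs(mask_action + random_action + keep_action - 1) < 1e-9)
  structure(list(select_rate = select_rate, mask_action = mask_action,
                 random_action = random_action, keep_action = keep_action),
            class = "mask_policy")
}

#' Corrupt a sequence under a masking policy
#'
#' Selects \code{max(1, round(select_rate * n))} positions uniformly without
#' replacement and applies one action per position: replace with MASK,
#' substitute with one of the other three bases (never the original), or
#' keep. Uses R's global RNG.
#'
#' @param residues RNA residue string.
#' @param policy A \code{"mask_policy"}.
#' @return A list of class \code{"masked_instance"} with \code{input_tokens},
#'   \code{target_tokens} (0-based ids) and \code{selected} (1-based
#'   positions, sorted).
#' @export
apply_mask <- function(residues, policy = mask_policy()) {
  tokens <- tokenize(residues, max_len = .Machine$integer.max)
  n <- length(tokens)
  if (n == 0L) stop("empty sequence")
  k <- max(1L, round(policy$select_rate * n))
  selected <- sort(sample.int(n, k))
  input <- tokens
  u <- stats::runif(k)
  for (s in seq_len(k)) {
    pos <- selected[s]
    if (u[s] < policy$mask_action) {
      input[pos] <- VOCAB[["MASK"]]
    } else if (u[s] < policy$mask_action + policy$random_action) {
      others <- setdiff(0:3, tokens[pos])
      input[pos] <- others[sample.int(3L, 1L)]
    } # else keep
  }
  structure(list(input_tokens = input, target_tokens = tokens,
                 selected = selected),
            class = "masked_instance")
}

#' Size of the expanded pre-training set
#'
#' The pre-training set takes a fixed number of copies of every sequence,
#' each with its own mask pattern, so its size is
#' \code{copies * n_sequences}.
#'
#' @param n_sequences Number of input sequences.
#' @param copies Copies per sequence (default 10).
#' @return Integer count of masked instances.
#' @export
pretraining_set_size <- function(n_sequences, copies = 10L) {
  stopifnot(copies >= 1, n_sequences >= 0)
  as.numeric(copies) * as.numeric(n_sequences)
}

#' Build the masked pre-training set
#'
#' Takes \code{copies} copies of each sequence and applies an independent
#' mask pattern to each copy; patterns are drawn once and kept fixed.
#'
#' @param seqs Named character vector of residue strings.
#' @param copies Copies per sequence (default 10).
#' @param policy A \code{"mask_policy"}.
#' @return List of \code{"masked_instance"} objects of length
#'   \code{copies * length(seqs)}.
#' @export
build_pretraining_set <- function(seqs, copies = 10L, policy = mask_policy()) {
  stopifnot(copies >= 1)
  if (length(seqs) == 0L) return(list())
  out <- vector("list", length(seqs) * copies)
  k <- 0L
  for (s in seqs) {
    for (cp in seq_len(copies)) {
      k <- k + 1L
      out[[k]] <- apply_mask(s, policy)
    }
  }
  out
}

#' Cross-entropy loss over selected positions
#'
#' Softmax cross-entropy averaged over the selected positions only, the
#' standard masked-language-modelling objective.
#'
#' @param logits Matrix with one row per selected position and one column
#'   per base (4 columns).
#' @param targets 0-based base ids, one per row of \code{logits}.
#' @return Non-negative scalar mean cross-entropy.
#' @export
mlm_loss <- function(logits, targets) {
  logits <- rbind(logits)
  if (nrow(logits) == 0L) stop("empty selection")
  stopifnot(nrow(logits) == length(targets), all(targets %in% 0:3))
  shifted <- logits - apply(logits, 1, max)
  logZ <- log(rowSums(exp(shifted)))
  picked <- shifted[cbind(seq_len(nrow(logits)), targets + 1L)]
  mean(logZ - picked)
}

# Forward + gradient of the MLM objective for one masked instance.
# Returns loss and the parameter gradient tree.
mlm_instance_grad <- function(instance, params) {
  fwd <- transformer_forward(instance$input_tokens, params, keep_cache = TRUE)
  sel <- instance$selected
  Zs <- fwd$Z[sel, , drop = FALSE]
  logits <- Zs %*% params$mlm_W +
    matrix(params$mlm_b, length(sel), N_BASES, byrow = TRUE)
  targets <- instance$target_tokens[sel]
  loss <- mlm_loss(logits, targets)
  P <- softmax_rows(logits)
  onehot <- matrix(0, length(sel), N_BASES)
  onehot[cbind(seq_along(sel), targets + 1L)] <- 1
  dlogits <- (P - onehot) / length(sel)
  dZ <- matrix(0, nrow(fwd$Z), ncol(fwd$Z))
  dZ[sel, ] <- dlogits %*% t(params$mlm_W)
  grads <- transformer_backward(dZ, fwd$cache, params)
  grads$mlm_W <- grads$mlm_W + t(Zs) %*% dlogits
  grads$mlm_b <- grads$mlm_b + colSums(dlogits)
  list(loss = loss, grads = grads)
}

#' Evaluate mean MLM loss over a set of masked instances
#'
#' @param instances List of \code{"masked_instance"} objects.
#' @param params A \code{"model_params"}.
#' @return Mean cross-entropy.
#' @export
mlm_eval <- function(instances, params) {
  mean(vapply(instances, function(inst) {
    Z <- transformer_forward(inst$input_tokens, params)
    sel <- inst$selected
    logits <- Z[sel, , drop = FALSE] %*% params$mlm_W +
      matrix(params$mlm_b, length(sel), N_BASES, byrow = TRUE)
    mlm_loss(logits, inst$target_tokens[sel])
  }, numeric(1)))
}

#' One epoch of MLM training
#'
#' Runs per-instance Adam updates over a shuffled pass of the instances.
#'
#' @param instances List of \code{"masked_instance"} objects.
#' @param params A \code{"model_params"}.
#' @param state Adam state (from \code{adam_init}) or \code{NULL}.
#' @param lr Learning rate.
#' @return List with updated \code{params}, \code{state} and the epoch mean
#'   \code{loss}.
#' @export
train_mlm_epoch <- function(instances, params, state = NULL, lr = 5e-3) {
  if (length(instances) == 0L) stop("empty MLM dataset")
  if (is.null(state)) state <- adam_init(params)
  losses <- numeric(length(instances))
  ord <- sample.int(length(instances))
  for (k in seq_along(ord)) {
    res <- mlm_instance_grad(instances[[ord[k]]], params)
    losses[k] <- res$loss
    st <- adam_step(params, res$grads, state, lr = lr)
    params <- st$params; state <- st$state
  }
  list(params = params, state = state, loss = mean(losses))
}
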