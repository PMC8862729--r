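#' Soft symmetric alignment similarity
#'
#' Whole-sequence similarity s-hat between two embedded sequences: an
#' attention-weighted average of the per-base cosine similarities. With
#' \code{alpha[i, j]} the softmax of \code{omega[i, ]} over j and
#' \code{beta[i, j]} the softmax of \code{omega[, j]} over i, the weights
#' are \code{a = alpha + beta - alpha * beta} and
#' \code{s_hat = sum(a * omega) / sum(a)}. Swapping the arguments exchanges
#' alpha and beta, so s-hat is symmetric.
#'
#' @param Z,Zp Embedding matrices.
#' @return A list of class \code{"ssa_breakdown"} with \code{omega},
#'   \code{alpha}, \code{beta}, \code{a}, \code{A} and \code{s_hat}.
#' @export
ssa_similarity <- function(Z, Zp) {
  om <- omega(Z, Zp)
  ea <- exp(om - apply(om, 1, max))
  alpha <- ea / rowSums(ea)
  eb <- exp(sweep(om, 2, apply(om, 2, max)))
  beta <- sweep(eb, 2, colSums(eb), `/`)
  a <- alpha + beta - alpha * beta
  A <- sum(a)
  structure(list(omega = om, alpha = alpha, beta = beta, a = a, A = A,
                 s_hat = sum(a * om) / A),
            class = "ssa_breakdown")
}

#' Pairwise soft-symmetric-alignment similarity matrix
#'
#' Embeds every sequence once and computes s-hat for all pairs (including
#' self-similarities on the diagonal).
#'
#' @param seqs Named character vector of residue strings (length >= 2).
#' @param params A \code{"model_params"}.
#' @return A symmetric N x N matrix with sequence ids as dimnames.
#' @export
similarity_matrix <- function(seqs, params) {
  N <- length(seqs)
  if (N < 2) stop("need at least two sequences")
  Zs <- lapply(seqs, embed_sequence, params = params)
  S <- matrix(0, N, N, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(N)) {
    for (j in i:N) {
      s <- ssa_similarity(Zs[[i]], Zs[[j]])$s_hat
      S[i, j] <- s; S[j, i] <- s
    }
  }
  S
}

#' Spectral clustering of similarity-matrix rows
#'
#' Treats each row of the similarity matrix as an N-dimensional feature
#' vector. A non-negative affinity between rows is built with a Gaussian
#' kernel on row Euclidean distances (bandwidth = median pairwise distance),
#' followed by normalized-Laplacian spectral clustering: the top k
#' eigenvectors of \code{D^-1/2 W D^-1/2} are row-normalized and clustered
#' with k-means. s-hat itself can be negative, which is why it is not used
#' directly as the affinity.
#'
#' @param sim N x N similarity matrix.
#' @param k Number of clusters (1 <= k <= N).
#' @param seed Integer seed controlling the k-means initialization.
#' @return Integer vector of cluster labels in \code{1..k}, named by the
#'   matrix dimnames.
#' @export
spectral_cluster <- function(sim, k, seed = 1L) {
  N <- nrow(sim)
  if (k < 1 || k > N) stop("k must be between 1 and N")
  if (k == 1) return(stats::setNames(rep(1L, N), rownames(sim)))
  d <- as.matrix(stats::dist(sim))
  bw <- stats::median(d[upper.tri(d)])
  if (!is.finite(bw) || bw <= 0) bw <- 1
  W <- exp(-(d^2) / (2 * bw^2))
  diag(W) <- 0
  deg <- pmax(rowSums(W), 1e-12)
  L <- W / sqrt(deg) / rep(sqrt(deg), each = N)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 20, iter.max = 100)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  stats::setNames(as.integer(km$cluster), rownames(sim))
}

#' Clustering agreement metrics
#'
#' Pair-counting agreement between a predicted clustering and reference
#' family labels: over all unordered item pairs, TP counts pairs of the same
#' reference family placed in the same predicted cluster, TN pairs of
#' different families in different clusters, FP pairs of different families
#' in the same cluster, FN pairs of the same family in different clusters.
#' Reports the Rand index \code{RI = (TP + TN) / total}, its chance
#' expectation \code{E = ((TP+FP)(TP+FN) + (TN+FP)(TN+FN)) / total}, the
#' adjusted Rand index \code{ARI = (TP + TN - E) / (total - E)}, and the
#' entropy-based homogeneity and completeness.
#'
#' @param pred,ref Label vectors of equal length (any label type).
#' @return A list with \code{tp}, \code{tn}, \code{fp}, \code{fn},
#'   \code{ri}, \code{e}, \code{ari}, \code{homogeneity},
#'   \code{completeness}.
#' @export
clustering_metrics <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("label vectors differ in length")
  N <- length(pred)
  if (N < 2) stop("need at least two items")
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      same_ref <- ref[i] == ref[j]
      same_pred <- pred[i] == pred[j]
      if (same_ref && same_pred) tp <- tp + 1L
      else if (!same_ref && !same_pred) tn <- tn + 1L
      else if (!same_ref && same_pred) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  total <- tp + tn + fp + fn
  ri <- (tp + tn) / total
  e <- ((tp + fp) * (tp + fn) + (tn + fp) * (tn + fn)) / total
  ari <- if (total - e == 0) 0 else (tp + tn - e) / (total - e)
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  cond_ent <- function(x, given) {
    # H(x | given)
    h <- 0
    for (g in unique(given)) {
      sel <- given == g
      p <- table(x[sel]) / sum(sel)
      h <- h - sum(sel) / length(x) * sum(p * log(p))
    }
    h
  }
  h_ref <- ent(ref); h_pred <- ent(pred)
  homogeneity <- if (h_ref == 0) 1 else 1 - cond_ent(ref, pred) / h_ref
  completeness <- if (h_pred == 0) 1 else 1 - cond_ent(pred, ref) / h_pred
  list(tp = tp, tn = tn, fp = fp, fn = fn, ri = ri, e = e, ari = ari,
       homogeneity = homogeneity, completeness = completeness)
}
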