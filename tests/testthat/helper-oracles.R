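# Shared fixtures and independent oracles used across the suite.

tiny_config <- function(...) {
  model_config(D = 8L, n_layers = 2L, H = 2L, head_dim = 4L, ffn_dim = 16L,
               max_len = 60L, ...)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# every global alignment of sequences of lengths n, m, as (i, j) vectors
# with NA marking gaps; plain recursion, independent of the DP
all_alignments <- function(n, m) {
  rec <- function(i, j) {
    if (i == n && j == m) return(list(list(i = integer(0), j = integer(0))))
    out <- list()
    if (i < n && j < m) {
      for (tail in rec(i + 1, j + 1))
        out[[length(out) + 1L]] <- list(i = c(i + 1L, tail$i),
                                        j = c(j + 1L, tail$j))
    }
    if (i < n) {
      for (tail in rec(i + 1, j))
        out[[length(out) + 1L]] <- list(i = c(i + 1L, tail$i),
                                        j = c(NA_integer_, tail$j))
    }
    if (j < m) {
      for (tail in rec(i, j + 1))
        out[[length(out) + 1L]] <- list(i = c(NA_integer_, tail$i),
                                        j = c(j + 1L, tail$j))
    }
    out
  }
  lapply(rec(0L, 0L), function(al) pairwise_alignment(al$i, al$j))
}

# brute-force optimum of f (plus optionally the margin against y) by
# scoring every alignment
enum_best_score <- function(omega, gaps, y = NULL, margin = NULL) {
  best <- -Inf
  for (al in all_alignments(nrow(omega), ncol(omega))) {
    s <- alignment_score(omega, gaps, al)
    if (!is.null(y)) s <- s + margin_delta(y, al, margin)
    if (s > best) best <- s
  }
  best
}

random_alignment <- function(n, m) {
  i <- integer(0); j <- integer(0)
  a <- 0L; b <- 0L
  while (a < n || b < m) {
    moves <- c(if (a < n && b < m) "match",
               if (a < n) "gapb",
               if (b < m) "gapa")
    mv <- sample(moves, 1L)
    if (mv == "match") {
      a <- a + 1L; b <- b + 1L; i <- c(i, a); j <- c(j, b)
    } else if (mv == "gapb") {
      a <- a + 1L; i <- c(i, a); j <- c(j, NA_integer_)
    } else {
      b <- b + 1L; i <- c(i, NA_integer_); j <- c(j, b)
    }
  }
  pairwise_alignment(i, j)
}

# pair-counting ARI written independently (contingency-table form)
brute_ari <- function(pred, ref) {
  tab <- table(pred, ref)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(pred))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(0)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

small_family_spec <- function(name = "fam", ...) {
  family_spec(name, "..((((....))))..", n_members = 4L,
              substitution_rate = 0.2, indel_rate = 0.1, ...)
}

# the scaled-down pre-training study is shared by several tests; run it once
.study_cache <- new.env(parent = emptyenv())
run_scaled_study_cached <- function() {
  if (is.null(.study_cache$res)) .study_cache$res <- run_scaled_study(seed = 1L)
  .study_cache$res
}
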