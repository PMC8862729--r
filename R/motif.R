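#' Call sequence motifs from an attention map
#'
#' Positions whose attention mass exceeds \code{mean(M) + threshold_sd *
#' sd(M)} are flagged; maximal runs of flagged positions of length at least
#' \code{min_len} are reported as motif calls, in position order.
#'
#' @param residues RNA residue string of length n.
#' @param M Attention map (numeric vector of length n).
#' @param min_len Minimum run length (default 3).
#' @param threshold_sd Threshold in standard deviations above the mean
#'   (default 1).
#' @return A data frame with columns \code{start}, \code{end},
#'   \code{subsequence}, \code{mean_salience}; zero rows when nothing is
#'   called.
#' @export
call_motifs <- function(residues, M, min_len = 3L, threshold_sd = 1.0) {
  n <- nchar(residues)
  if (length(M) != n) stop("attention map length differs from sequence length")
  thr <- mean(M) + threshold_sd * stats::sd(M)
  if (is.na(thr)) thr <- mean(M)  # length-1 map
  flagged <- M > thr
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  chars <- strsplit(residues, "")[[1]]
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$subsequence <- vapply(seq_len(nrow(out)), function(k)
    paste(chars[out$start[k]:out$end[k]], collapse = ""), character(1))
  out$mean_salience <- vapply(seq_len(nrow(out)), function(k)
    mean(M[out$start[k]:out$end[k]]), numeric(1))
  out
}

#' Call motifs for a sequence with the model's attention map
#'
#' Computes the attention map from the chosen transformer layer (final by
#' default) and calls motifs on it.
#'
#' @param residues RNA residue string.
#' @param params A \code{"model_params"}.
#' @param layer Transformer layer to read the map from.
#' @param min_len,threshold_sd Passed to \code{call_motifs}.
#' @return As \code{call_motifs}.
#' @export
find_motifs <- function(residues, params, layer = params$config$n_layers,
                        min_len = 3L, threshold_sd = 1.0) {
  M <- attention_map(tokenize(residues, params$config$max_len), params, layer)
  call_motifs(residues, M, min_len = min_len, threshold_sd = threshold_sd)
}
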