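#' Parse a dot-bracket secondary structure
#'
#' Matches parentheses with a stack; pseudoknot-free structures only.
#'
#' @param s String over \code{( ) .}.
#' @return An object of class \code{"secondary_structure"}: list with
#'   \code{dotbracket} and \code{pairs}, a two-column integer matrix of
#'   \code{(p, q)} base pairs with \code{p < q}.
#' @export
parse_dotbracket <- function(s) {
  chars <- strsplit(s, "")[[1]]
  if (any(!chars %in% c("(", ")", ".")))
    stop("dot-bracket string may contain only '(', ')' and '.'")
  stack <- integer(0)
  p <- integer(0); q <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets: unmatched ')' at ", k)
      p <- c(p, stack[length(stack)])
      q <- c(q, k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L)
    stop("unbalanced brackets: unmatched '(' at ", stack[length(stack)])
  ord <- order(p)
  structure(list(dotbracket = s,
                 pairs = cbind(p = p[ord], q = q[ord])),
            class = "secondary_structure")
}

#' Serialize a pair set back to dot-bracket
#'
#' @param pairs Two-column matrix of \code{(p, q)} pairs.
#' @param n Structure length.
#' @return Dot-bracket string.
#' @export
dotbracket_string <- function(pairs, n) {
  chars <- rep(".", n)
  if (NROW(pairs) > 0) {
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Label every position with its secondary-structure context
#'
#' Assigns each position one of the six canonical substructure categories:
#' paired positions are \code{stem-pair}; unpaired positions are classified
#' by the innermost enclosing base pair — a loop closed by a pair with no
#' nested pairs is a \code{hairpin-loop}, with exactly one nested pair a
#' \code{bulge-or-internal-loop}, with two or more a
#' \code{multibranch-loop}. Unpaired positions outside all pairs are
#' \code{external-5prime} before the first paired base and
#' \code{external-3prime} otherwise.
#'
#' @param ss A \code{"secondary_structure"}.
#' @return Character vector of labels, one per position.
#' @export
annotate_substructures <- function(ss) {
  stopifnot(inherits(ss, "secondary_structure"))
  n <- nchar(ss$dotbracket)
  labels <- character(n)
  pairs <- ss$pairs
  if (NROW(pairs) == 0) return(rep("external-5prime", n))
  paired <- logical(n)
  paired[pairs] <- TRUE
  labels[paired] <- "stem-pair"
  first_paired <- min(pairs)
  last_paired <- max(pairs)
  # children count per pair: pairs directly nested inside it
  enclosing <- function(i) {
    # innermost pair (p, q) with p < i < q
    cand <- pairs[pairs[, 1] < i & pairs[, 2] > i, , drop = FALSE]
    if (NROW(cand) == 0) return(NULL)
    cand[which.min(cand[, 2] - cand[, 1]), ]
  }
  n_children <- function(pq) {
    inner <- pairs[pairs[, 1] > pq[1] & pairs[, 2] < pq[2], , drop = FALSE]
    if (NROW(inner) == 0) return(0L)
    # direct children: inner pairs not nested in another inner pair
    direct <- vapply(seq_len(NROW(inner)), function(k) {
      p <- inner[k, 1]; q <- inner[k, 2]
      !any(inner[, 1] < p & inner[, 2] > q)
    }, logical(1))
    sum(direct)
  }
  for (i in which(!paired)) {
    enc <- enclosing(i)
    if (is.null(enc)) {
      labels[i] <- if (i < first_paired) "external-5prime" else "external-3prime"
    } else {
      nc <- n_children(enc)
      labels[i] <- if (nc == 0L) "hairpin-loop"
                   else if (nc == 1L) "bulge-or-internal-loop"
                   else "multibranch-loop"
    }
  }
  labels
}
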