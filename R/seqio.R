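#' Read RNA sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file and normalizes each record to the RNA
#' alphabet: sequences are upper-cased and T is converted to U. Records
#' containing characters outside \code{A/C/G/U} after normalization are
#' handled according to \code{on_unknown}: dropped with a warning naming the
#' offending record (default), or rejected with an error.
#'
#' @param path Path to a FASTA file.
#' @param on_unknown Either \code{"skip"} (drop offending records with a
#'   warning) or \code{"error"}.
#' @return A named character vector; names are record ids, values are RNA
#'   residue strings over \code{A/C/G/U}.
#' @export
read_fasta <- function(path, on_unknown = c("skip", "error")) {
  on_unknown <- match.arg(on_unknown)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids))) stop("malformed FASTA header in ", path)
  # keep only the first whitespace-delimited token of each header
  ids <- vapply(strsplit(ids, "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  ok <- !grepl("[^ACGU]", seqs)
  if (any(!ok)) {
    bad <- ids[!ok]
    msg <- paste0("records with unknown bases: ", paste(bad, collapse = ", "))
    if (on_unknown == "error") stop(msg)
    warning(msg)
  }
  out <- seqs[ok]
  names(out) <- ids[ok]
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a Stockholm 1.0 multiple alignment
#'
#' Parses aligned rows and, when present, the \code{#=GC SS_cons} consensus
#' secondary-structure line. Both \code{.} and \code{-} in sequence rows are
#' treated as gaps (and normalized to \code{-}). SS_cons bracket aliases
#' \code{<>}, \code{[]}, \code{\{\}} are normalized to \code{()};
#' pseudoknot letters (Aa, Bb, ...) are replaced by \code{.} with a warning,
#' since the downstream model has no notion of pseudoknots.
#'
#' @param path Path to a Stockholm file.
#' @return An object of class \code{"msa"}: a list with \code{rows} (named
#'   character vector of gapped strings over \code{A/C/G/U/-}),
#'   \code{ss_cons} (normalized dot-bracket string or \code{NULL}) and
#'   \code{n_columns}.
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) stop("Stockholm file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM 1\\.0", lines[[1]]))
    stop("missing Stockholm header in ", path)
  rows <- character(0)
  ss <- NULL
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || identical(ln, "//")) next
    if (startsWith(ln, "#=GC")) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) >= 3 && parts[2] == "SS_cons") {
        ss <- paste0(if (is.null(ss)) "" else ss, parts[3])
      }
      next
    }
    if (startsWith(ln, "#")) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed alignment row: ", ln)
    id <- parts[1]
    prev <- if (id %in% names(rows)) rows[[id]] else ""
    rows[[id]] <- paste0(prev, parts[2])
  }
  if (length(rows) == 0L) stop("no alignment rows in ", path)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("alignment rows of unequal length in ", path)
  gapped <- toupper(rows)
  gapped <- chartr("T.", "U-", gapped)
  bad <- grepl("[^ACGU-]", gapped)
  if (any(bad)) stop("unexpected characters in rows: ",
                     paste(names(gapped)[bad], collapse = ", "))
  if (!is.null(ss)) {
    if (nchar(ss) != widths[[1]]) stop("SS_cons length differs from row length")
    ss <- normalize_ss_cons(ss)
  }
  structure(list(rows = gapped, ss_cons = ss, n_columns = unname(widths[[1]])),
            class = "msa")
}

# WUSS-style consensus structure -> plain dot-bracket
normalize_ss_cons <- function(ss) {
  out <- chartr("<>[]{}", "()()()", ss)
  out <- gsub("[,_:~.-]", ".", out)
  if (grepl("[A-Za-z]", out)) {
    warning("pseudoknot letters in SS_cons dropped (treated as unpaired)")
    out <- gsub("[A-Za-z]", ".", out)
  }
  if (grepl("[^().]", out)) stop("unrecognized SS_cons characters")
  out
}

#' Write a multiple alignment in Stockholm 1.0 format
#'
#' @param msa An \code{"msa"} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_stockholm <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  w <- max(nchar(names(msa$rows)), 12L)
  lines <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", w, names(msa$rows), msa$rows))
  if (!is.null(msa$ss_cons))
    lines <- c(lines, sprintf("%-*s %s", w, "#=GC SS_cons", msa$ss_cons))
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Remove gaps from an alignment row
#'
#' @param row Gapped string over \code{A/C/G/U/-}.
#' @return The ungapped residue string.
#' @export
dealign <- function(row) gsub("-", "", row, fixed = TRUE)

#' Construct a pairwise alignment object
#'
#' A pairwise alignment is an ordered list of columns, each a matched pair
#' \code{(i, j)}, or a gap column \code{(i, NA)} / \code{(NA, j)}. The
#' \code{i} indices cover \code{1..n} exactly once in increasing order, and
#' likewise \code{j} over \code{1..m}.
#'
#' @param i,j Integer vectors of equal length with \code{NA} marking gaps.
#' @return An object of class \code{"pairwise_alignment"} with fields
#'   \code{i}, \code{j}, \code{n}, \code{m}.
#' @export
pairwise_alignment <- function(i, j) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j))
  if (any(is.na(i) & is.na(j))) stop("column with gaps in both sequences")
  ii <- i[!is.na(i)]; jj <- j[!is.na(j)]
  n <- length(ii); m <- length(jj)
  if (n > 0 && !identical(ii, seq_len(n)))
    stop("i indices must cover 1..n in increasing order")
  if (m > 0 && !identical(jj, seq_len(m)))
    stop("j indices must cover 1..m in increasing order")
  structure(list(i = i, j = j, n = n, m = m), class = "pairwise_alignment")
}

#' Matched position pairs of an alignment
#'
#' @param y A \code{"pairwise_alignment"}.
#' @return A two-column integer matrix of matched \code{(i, j)} pairs.
#' @export
matched_pairs <- function(y) {
  keep <- !is.na(y$i) & !is.na(y$j)
  cbind(i = y$i[keep], j = y$j[keep])
}

#' Extract a pairwise alignment from a multiple alignment
#'
#' Projects an MSA onto two of its rows: columns gapped in both rows are
#' dropped; the rest become matched or gap columns with 1-based ungapped
#' positions.
#'
#' @param msa An \code{"msa"} object.
#' @param id_a,id_b Row identifiers.
#' @return A \code{"pairwise_alignment"}.
#' @export
extract_pairwise <- function(msa, id_a, id_b) {
  stopifnot(inherits(msa, "msa"))
  for (id in c(id_a, id_b))
    if (!id %in% names(msa$rows)) stop("id not found in alignment: ", id)
  a <- strsplit(msa$rows[[id_a]], "")[[1]]
  b <- strsplit(msa$rows[[id_b]], "")[[1]]
  ia <- cumsum(a != "-")
  ib <- cumsum(b != "-")
  keep <- a != "-" | b != "-"
  i <- ifelse(a != "-", ia, NA_integer_)[keep]
  j <- ifelse(b != "-", ib, NA_integer_)[keep]
  pairwise_alignment(i, j)
}

#' Render a pairwise alignment as two gapped strings
#'
#' @param y A \code{"pairwise_alignment"}.
#' @param a,b Residue strings of the two sequences.
#' @return Character vector of two gapped strings.
#' @export
alignment_rows <- function(y, a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == y$n, length(cb) == y$m)
  ra <- ifelse(is.na(y$i), "-", ca[ifelse(is.na(y$i), 1L, y$i)])
  rb <- ifelse(is.na(y$j), "-", cb[ifelse(is.na(y$j), 1L, y$j)])
  c(paste(ra, collapse = ""), paste(rb, collapse = ""))
}

#' Write a pairwise alignment as a TSV of columns
#'
#' Columns \code{i} and \code{j}, one row per alignment column, with
#' \code{"-"} marking gaps.
#'
#' @param y A \code{"pairwise_alignment"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_alignment_tsv <- function(y, path) {
  df <- data.frame(i = ifelse(is.na(y$i), "-", y$i),
                   j = ifelse(is.na(y$j), "-", y$j))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
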