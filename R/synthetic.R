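# Synthetic RNA families: members are sampled from a random consensus
# sequence consistent with a known secondary structure, with per-position
# substitutions (compensatory at paired columns), and single-base indels
# restricted to loop columns so that the consensus structure stays
# well-defined for every member. The generating MSA records the true
# homology columns, giving exact reference alignments for free.

WC_PAIRS <- matrix(c("A", "U", "U", "A", "C", "G", "G", "C"),
                   ncol = 2, byrow = TRUE)

#' Specification of a synthetic RNA family
#'
#' @param name Family name (used as the id prefix of members).
#' @param consensus_structure Dot-bracket string defining the consensus
#'   secondary structure (and the consensus length).
#' @param n_members Number of member sequences.
#' @param substitution_rate Per-position substitution probability. At paired
#'   columns with \code{compensatory = TRUE} a substitution replaces the
#'   whole pair with a different Watson-Crick pair.
#' @param indel_rate Per-loop-position probability of an indel (split evenly
#'   between a single-base deletion and a single-base insertion after the
#'   position).
#' @param compensatory Keep Watson-Crick pairing at all paired columns in
#'   every member (default \code{TRUE}).
#' @param identity_target Optional \code{c(low, high)} band; members are
#'   rejection-sampled until all pairwise identities fall inside it.
#' @param motif_len Length of a family-conserved sequence motif: a
#'   contiguous run of loop columns kept invariant (no substitutions or
#'   indels) in every member, emulating the conserved boxes real ncRNA
#'   families carry (C/D box, T-loop). 0 disables it.
#' @return A list of class \code{"family_spec"}.
#' @export
family_spec <- function(name, consensus_structure, n_members = 6L,
                        substitution_rate = 0.15, indel_rate = 0.05,
                        compensatory = TRUE, identity_target = NULL,
                        motif_len = 0L) {
  ss <- parse_dotbracket(consensus_structure)
  stopifnot(n_members >= 2, substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, motif_len >= 0)
  if (!is.null(identity_target))
    stopifnot(length(identity_target) == 2, identity_target[1] < identity_target[2])
  structure(list(name = name, ss = ss,
                 consensus_len = nchar(consensus_structure),
                 n_members = as.integer(n_members),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 compensatory = isTRUE(compensatory),
                 identity_target = identity_target,
                 motif_len = as.integer(motif_len)),
            class = "family_spec")
}

sample_consensus <- function(ss, len) {
  chars <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
  for (k in seq_len(NROW(ss$pairs))) {
    wc <- WC_PAIRS[sample.int(4L, 1L), ]
    chars[ss$pairs[k, 1]] <- wc[1]
    chars[ss$pairs[k, 2]] <- wc[2]
  }
  chars
}

# longest runs of consecutive loop columns, for placing conserved motifs
pick_motif_cols <- function(loop_cols, motif_len) {
  if (motif_len == 0L || length(loop_cols) == 0L) return(integer(0))
  runs <- split(loop_cols, cumsum(c(1, diff(loop_cols) != 1)))
  runs <- runs[vapply(runs, length, integer(1)) >= motif_len]
  if (length(runs) == 0L)
    stop("no loop run long enough for a motif of length ", motif_len)
  run <- runs[[sample.int(length(runs), 1L)]]
  start <- sample.int(length(run) - motif_len + 1L, 1L)
  run[start:(start + motif_len - 1L)]
}

# One member draw: per-consensus-column residue ("" = deleted) plus inserted
# bases after each column.
sample_member <- function(consensus, spec, loop_cols, pair_of,
                          motif_cols = integer(0)) {
  L <- spec$consensus_len
  cols <- consensus
  done <- logical(L)
  done[motif_cols] <- TRUE
  for (p in seq_len(L)) {
    if (done[p]) next
    q <- pair_of[p]
    if (!is.na(q) && spec$compensatory) {
      if (stats::runif(1) < spec$substitution_rate) {
        cur <- paste0(cols[p], cols[q])
        alt <- WC_PAIRS[paste0(WC_PAIRS[, 1], WC_PAIRS[, 2]) != cur, ,
                        drop = FALSE]
        wc <- alt[sample.int(nrow(alt), 1L), ]
        cols[p] <- wc[1]; cols[q] <- wc[2]
      }
      done[p] <- TRUE; done[q] <- TRUE
    } else {
      if (stats::runif(1) < spec$substitution_rate)
        cols[p] <- sample(setdiff(c("A", "C", "G", "U"), cols[p]), 1L)
      done[p] <- TRUE
    }
  }
  ins <- rep("", L)
  for (p in setdiff(loop_cols, motif_cols)) {
    u <- stats::runif(1)
    if (u < spec$indel_rate / 2) {
      cols[p] <- ""
    } else if (u < spec$indel_rate) {
      ins[p] <- sample(c("A", "C", "G", "U"), 1L)
    }
  }
  list(cols = cols, ins = ins)
}

member_identity <- function(a, b) {
  shared <- a$cols != "" & b$cols != ""
  if (!any(shared)) return(0)
  mean(a$cols[shared] == b$cols[shared])
}

#' Generate a synthetic RNA family
#'
#' Samples a consensus sequence consistent with the spec's structure
#' (Watson-Crick pairs at paired columns), then draws members with
#' substitutions and loop-restricted indels. Uses R's global RNG; call
#' \code{set.seed()} first for reproducible families.
#'
#' @param spec A \code{"family_spec"}.
#' @param max_tries Rejection-sampling budget per member when
#'   \code{identity_target} is set.
#' @return A list of class \code{"synthetic_family"} with \code{spec},
#'   \code{consensus}, \code{members} (named residue strings), \code{msa}
#'   (an \code{"msa"} with SS_cons) and \code{truth_pairs} (reference
#'   \code{"pairwise_alignment"}s keyed \code{"idA|idB"}).
#' @export
generate_family <- function(spec, max_tries = 500L) {
  stopifnot(inherits(spec, "family_spec"))
  L <- spec$consensus_len
  pair_of <- rep(NA_integer_, L)
  if (NROW(spec$ss$pairs) > 0) {
    pair_of[spec$ss$pairs[, 1]] <- spec$ss$pairs[, 2]
    pair_of[spec$ss$pairs[, 2]] <- spec$ss$pairs[, 1]
  }
  loop_cols <- which(is.na(pair_of))
  consensus <- sample_consensus(spec$ss, L)
  motif_cols <- pick_motif_cols(loop_cols, spec$motif_len)
  drawn <- list()
  for (k in seq_len(spec$n_members)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- sample_member(consensus, spec, loop_cols, pair_of, motif_cols)
      if (is.null(spec$identity_target)) { ok <- TRUE; break }
      ids <- vapply(drawn, member_identity, numeric(1), b = cand)
      if (all(ids >= spec$identity_target[1] & ids <= spec$identity_target[2])) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not draw member ", k, " inside the identity band; ",
                  "adjust substitution_rate or the band")
    drawn[[k]] <- cand
  }
  ids <- sprintf("%s_%d", spec$name, seq_len(spec$n_members))
  # assemble the MSA: consensus columns, then per-member private insert
  # columns after each consensus column
  nM <- spec$n_members
  col_chars <- list()
  ss_chars <- character(0)
  ss_cons_vec <- strsplit(spec$ss$dotbracket, "")[[1]]
  for (p in seq_len(L)) {
    col <- vapply(drawn, function(m) if (m$cols[p] == "") "-" else m$cols[p],
                  character(1))
    col_chars[[length(col_chars) + 1L]] <- col
    ss_chars <- c(ss_chars, ss_cons_vec[p])
    for (mi in seq_len(nM)) {
      if (drawn[[mi]]$ins[p] != "") {
        col <- rep("-", nM)
        col[mi] <- drawn[[mi]]$ins[p]
        col_chars[[length(col_chars) + 1L]] <- col
        ss_chars <- c(ss_chars, ".")
      }
    }
  }
  mat <- do.call(cbind, col_chars)
  rows <- apply(mat, 1, paste, collapse = "")
  names(rows) <- ids
  msa <- structure(list(rows = rows,
                        ss_cons = paste(ss_chars, collapse = ""),
                        n_columns = ncol(mat)),
                   class = "msa")
  members <- vapply(rows, dealign, character(1))
  names(members) <- ids
  truth <- list()
  for (i in seq_len(nM - 1L)) {
    for (j in (i + 1L):nM) {
      truth[[paste(ids[i], ids[j], sep = "|")]] <-
        extract_pairwise(msa, ids[i], ids[j])
    }
  }
  structure(list(spec = spec, consensus = paste(consensus, collapse = ""),
                 motif_cols = motif_cols,
                 members = members, msa = msa, truth_pairs = truth),
            class = "synthetic_family")
}

#' Sequence identity of a reference pair
#'
#' Fraction of matched columns of the reference alignment at which the two
#' residues agree (the standard identity definition for identity-stratified
#' alignment benchmarks).
#'
#' @param y Reference \code{"pairwise_alignment"}.
#' @param a,b Residue strings.
#' @return Identity in \code{[0, 1]}.
#' @export
pair_identity <- function(y, a, b) {
  mp <- matched_pairs(y)
  if (NROW(mp) == 0) return(0)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca[mp[, 1]] == cb[mp[, 2]])
}

#' Build an identity-stratified pairwise alignment benchmark
#'
#' Generates each family and emits every member pair with its reference
#' alignment, measured sequence identity and identity bin. Families can be
#' assigned to a disjoint train/test split by name.
#'
#' @param specs List of \code{"family_spec"} objects.
#' @param bins Identity bin edges (default \code{c(0, 0.4, 0.6, 0.8, 1)}).
#' @param test_families Character vector of family names forming the test
#'   split (must be a subset of the spec names).
#' @return A list of class \code{"benchmark"} with \code{families} (the
#'   generated \code{"synthetic_family"} objects, named), \code{pairs}
#'   (data frame: family, id_a, id_b, identity, bin, split) and
#'   \code{truth} (reference alignments keyed \code{"idA|idB"}).
#' @export
make_benchmark <- function(specs, bins = c(0, 0.4, 0.6, 0.8, 1),
                           test_families = character(0)) {
  if (length(specs) < 1) stop("need at least one family spec")
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (!all(test_families %in% names(specs)))
    stop("unknown test family name")
  fams <- lapply(specs, generate_family)
  rows <- list(); truth <- list()
  for (fam in fams) {
    split <- if (fam$spec$name %in% test_families) "test" else "train"
    for (key in names(fam$truth_pairs)) {
      idab <- strsplit(key, "|", fixed = TRUE)[[1]]
      y <- fam$truth_pairs[[key]]
      idy <- pair_identity(y, fam$members[[idab[1]]], fam$members[[idab[2]]])
      bin <- cut(idy, breaks = bins, include.lowest = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam$spec$name, id_a = idab[1], id_b = idab[2],
        identity = idy, bin = as.character(bin), split = split)
      truth[[key]] <- y
    }
  }
  structure(list(families = fams, pairs = do.call(rbind, rows), truth = truth),
            class = "benchmark")
}

#' Write a benchmark's fixture files
#'
#' Writes per-family FASTA and Stockholm files plus a pairs table, the
#' plain-text forms used by the command-line interface.
#'
#' @param benchmark A \code{"benchmark"}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fam in benchmark$families) {
    write_fasta(fam$members, file.path(dir, paste0(fam$spec$name, ".fasta")))
    write_stockholm(fam$msa, file.path(dir, paste0(fam$spec$name, ".sto")))
  }
  utils::write.table(benchmark$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
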