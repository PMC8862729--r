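test_that("FASTA reading normalizes T to U and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT", ">y", "ggUUa"), f)
  got <- read_fasta(f)
  expect_identical(got, c(x = "ACGU", y = "GGUUA"))
})

test_that("records with unknown bases are skipped with a warning naming them", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGN", ">y", "ACGU"), f)
  expect_warning(got <- read_fasta(f), "x")
  expect_identical(names(got), "y")
  expect_error(read_fasta(f, on_unknown = "error"), "x")
})

test_that("FASTA write/read round-trips 50 random sequences", {
  set.seed(1)
  seqs <- vapply(1:50, function(k) random_seq(sample(10:60, 1)), character(1))
  names(seqs) <- sprintf("seq%02d", 1:50)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("Stockholm parsing handles rows, gaps and SS_cons", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "a A-CG", "b AUC-", "//"), f)
  msa <- read_stockholm(f)
  expect_equal(msa$n_columns, 4)
  expect_identical(unname(msa$rows), c("A-CG", "AUC-"))

  writeLines(c("# STOCKHOLM 1.0", "a AACCGG", "b AACCGG",
               "#=GC SS_cons <<..>>", "//"), f)
  msa <- read_stockholm(f)
  ss <- parse_dotbracket(msa$ss_cons)
  expect_equal(ss$pairs, cbind(p = c(1, 2), q = c(6, 5)))

  writeLines(c("a A-CG", "b AUC-"), f)
  expect_error(read_stockholm(f), "header")
  writeLines(c("# STOCKHOLM 1.0", "a A-CG", "b AUC", "//"), f)
  expect_error(read_stockholm(f), "unequal")
})

test_that("generated families round-trip through Stockholm column-identically", {
  set.seed(42)
  for (k in 1:5) {
    fam <- generate_family(small_family_spec(paste0("f", k)))
    f <- withr::local_tempfile(fileext = ".sto")
    write_stockholm(fam$msa, f)
    back <- read_stockholm(f)
    expect_identical(back$rows, fam$msa$rows)
    expect_identical(back$ss_cons, fam$msa$ss_cons)
  }
})

test_that("pairwise extraction maps gapped rows to matched and gap columns", {
  msa <- structure(list(rows = c(a = "A-CG", b = "AUC-"), ss_cons = NULL,
                        n_columns = 4L), class = "msa")
  y <- extract_pairwise(msa, "a", "b")
  expect_equal(y$i, c(1L, NA, 2L, 3L))
  expect_equal(y$j, c(1L, 2L, 3L, NA))

  msa2 <- structure(list(rows = c(a = "A--", b = "A--"), ss_cons = NULL,
                         n_columns = 3L), class = "msa")
  y2 <- extract_pairwise(msa2, "a", "b")
  expect_equal(y2$i, 1L)
  expect_equal(y2$j, 1L)
  expect_error(extract_pairwise(msa, "a", "zz"), "not found")
})

test_that("all pairs of a random MSA satisfy alignment invariants and dealign", {
  set.seed(7)
  fam <- generate_family(family_spec("inv", "..(((...)))..((...)).",
                                     n_members = 6, substitution_rate = 0.3,
                                     indel_rate = 0.3))
  ids <- names(fam$members)
  for (i in 1:5) for (j in (i + 1):6) {
    y <- extract_pairwise(fam$msa, ids[i], ids[j])  # constructor validates
    expect_s3_class(y, "pairwise_alignment")
    expect_equal(y$n, nchar(fam$members[[ids[i]]]))
    expect_equal(y$m, nchar(fam$members[[ids[j]]]))
    rows <- alignment_rows(y, fam$members[[ids[i]]], fam$members[[ids[j]]])
    expect_identical(dealign(rows[1]), unname(fam$members[[ids[i]]]))
    expect_identical(dealign(rows[2]), unname(fam$members[[ids[j]]]))
  }
})

test_that("dot-bracket parsing matches brackets and rejects unbalanced input", {
  expect_equal(parse_dotbracket("((..))")$pairs, cbind(p = c(1, 2), q = c(6, 5)))
  expect_error(parse_dotbracket("("), "unbalanced")
  expect_error(parse_dotbracket(")("), "unbalanced")
  expect_error(parse_dotbracket("(x)"), "only")
})

test_that("random structures re-serialize from their pair sets", {
  set.seed(11)
  rand_struct <- function(n) {
    # random balanced dot-bracket by stack simulation
    chars <- character(n)
    open <- 0
    for (k in seq_len(n)) {
      can_close <- open > 0
      can_open <- (n - k) > open   # room to close everything later
      choice <- sample(c(if (can_open) "(", if (can_close) ")", "."), 1)
      chars[k] <- choice
      if (choice == "(") open <- open + 1
      if (choice == ")") open <- open - 1
    }
    while (open > 0) { chars <- c(chars, ")"); open <- open - 1 }
    paste(chars, collapse = "")
  }
  for (k in 1:100) {
    s <- rand_struct(sample(5:30, 1))
    ss <- parse_dotbracket(s)
    expect_identical(dotbracket_string(ss$pairs, nchar(s)), s)
  }
})

test_that("substructure annotation labels the six contexts correctly", {
  expect_equal(annotate_substructures(parse_dotbracket("((...))")),
               c("stem-pair", "stem-pair", "hairpin-loop", "hairpin-loop",
                 "hairpin-loop", "stem-pair", "stem-pair"))
  lab <- annotate_substructures(parse_dotbracket(".((...))."))
  expect_equal(lab[1], "external-5prime")
  expect_equal(lab[9], "external-3prime")
  lab2 <- annotate_substructures(parse_dotbracket("((.((...))))"))
  expect_equal(lab2[3], "bulge-or-internal-loop")
  # multibranch: loop enclosed by a pair with two child helices
  lab3 <- annotate_substructures(parse_dotbracket("((.((..))..((..)).))"))
  expect_equal(lab3[3], "multibranch-loop")
  expect_equal(lab3[c(10, 11)], rep("multibranch-loop", 2))
})

test_that("every position gets exactly one label and paired positions are stems", {
  set.seed(3)
  s <- "..((((..((...))..((...))..))))..((...)).."
  ss <- parse_dotbracket(s)
  lab <- annotate_substructures(ss)
  expect_length(lab, nchar(s))
  expect_false(any(is.na(lab) | lab == ""))
  paired <- sort(as.vector(ss$pairs))
  expect_true(all(lab[paired] == "stem-pair"))
  expect_true(all(lab[-paired] != "stem-pair"))
})
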