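test_that("the score matrix holds cosines with their closed-form values", {
  v <- c(1, 2, 3)
  expect_equal(omega(rbind(v), rbind(v))[1, 1], 1.0)
  expect_equal(omega(rbind(c(1, 0)), rbind(c(0, 1)))[1, 1], 0.0)
  expect_equal(omega(rbind(c(1, 1)), rbind(c(1, 0)))[1, 1], 1 / sqrt(2))
  set.seed(1)
  om <- omega(matrix(rnorm(40), 8, 5), matrix(rnorm(30), 6, 5))
  expect_true(all(abs(om) <= 1 + 1e-9))
  expect_error(omega(rbind(c(0, 0)), rbind(v)), "zero-norm")
})

test_that("alignment scores add match scores and affine gap runs", {
  gaps <- gap_params()
  om <- diag(3)
  y <- pairwise_alignment(1:3, 1:3)
  expect_equal(alignment_score(om, gaps, y), 3)
  om2 <- matrix(0.9, 2, 1)
  y2 <- pairwise_alignment(c(1L, 2L), c(1L, NA))
  expect_equal(alignment_score(om2, gaps, y2), 0.9 - 1)
  # a run of three same-direction gap columns: open + 2 * extend
  om3 <- matrix(1, 4, 1)
  y3 <- pairwise_alignment(c(1L, 2L, 3L, 4L), c(1L, NA, NA, NA))
  expect_equal(alignment_score(om3, gaps, y3), 1 - 1.2)
  # direction change re-opens the gap
  om4 <- matrix(-3, 1, 1)
  y4 <- pairwise_alignment(c(1L, NA), c(NA, 1L))
  expect_equal(alignment_score(om4, gaps, y4), -2)
})

test_that("the margin counts missed and spurious matched pairs", {
  y <- pairwise_alignment(1:3, 1:3)
  expect_equal(margin_delta(y, y), 0)
  yhat <- pairwise_alignment(c(1L, 2L, NA, 3L), c(1L, NA, 2L, 3L))
  # reference pairs {11,22,33}; predicted {11,33}: 1 missed
  expect_equal(margin_delta(y, yhat), 0.05)
  # worked case: 2 missed, 2 spurious
  y2 <- pairwise_alignment(c(1L, 2L, 3L, NA), c(1L, 2L, 3L, 4L))
  y2hat <- pairwise_alignment(c(1L, NA, 2L, 3L), c(1L, 2L, 3L, 4L))
  expect_equal(margin_delta(y2, y2hat), 0.05 * 2 + 0.1 * 2)
  # symmetric when the two penalties coincide
  mp <- margin_params(delta_fn = 0.07, delta_fp = 0.07)
  expect_equal(margin_delta(y2, y2hat, mp), margin_delta(y2hat, y2, mp))
})

test_that("margins agree with brute-force set counting on random alignments", {
  set.seed(2)
  mp <- margin_params()
  for (k in 1:50) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    y <- random_alignment(n, m)
    yhat <- random_alignment(n, m)
    ky <- apply(matched_pairs(y), 1, paste, collapse = ",")
    kh <- apply(matched_pairs(yhat), 1, paste, collapse = ",")
    brute <- 0.05 * sum(!(ky %in% kh)) + 0.1 * sum(!(kh %in% ky))
    expect_equal(margin_delta(y, yhat, mp), brute)
  }
})

test_that("zero margins reduce loss-augmented decoding to plain alignment", {
  set.seed(3)
  om <- matrix(rnorm(12), 3, 4)
  y <- random_alignment(3, 4)
  dec <- loss_augmented_decode(om, gap_params(), y,
                               margin_params(delta_fn = 0, delta_fp = 0))
  plain <- nw_affine(om, gap_params())
  expect_identical(dec$yhat$i, plain$alignment$i)
  expect_identical(dec$yhat$j, plain$alignment$j)
})

test_that("loss-augmented decoding attains the exhaustive optimum", {
  set.seed(4)
  gaps <- gap_params()
  mp <- margin_params()
  for (k in 1:60) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    om <- matrix(rnorm(n * m), n, m)
    y <- random_alignment(n, m)
    dec <- loss_augmented_decode(om, gaps, y, mp)
    attained <- alignment_score(om, gaps, dec$yhat) +
      margin_delta(y, dec$yhat, mp)
    best <- enum_best_score(om, gaps, y, mp)
    expect_equal(attained, best, tolerance = 1e-9)
    expect_equal(dec$objective, best, tolerance = 1e-9)
  }
})

test_that("a large miss penalty makes the decoder keep reference matches", {
  y <- pairwise_alignment(1:2, 1:2)
  om <- matrix(0, 2, 2)
  mp <- margin_params(delta_fn = 0.3, delta_fp = 0.1)
  dec <- loss_augmented_decode(om, gap_params(), y, mp)
  expect_equal(matched_pairs(dec$yhat), cbind(i = 1:2, j = 1:2))
  best <- enum_best_score(om, gap_params(), y, mp)
  expect_equal(dec$objective, best, tolerance = 1e-9)
})

test_that("the structured hinge is non-negative on random instances", {
  set.seed(5)
  gaps <- gap_params(); mp <- margin_params()
  for (k in 1:200) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    om <- matrix(runif(n * m, -1, 1), n, m)
    y <- random_alignment(n, m)
    dec <- loss_augmented_decode(om, gaps, y, mp)
    hinge <- alignment_score(om, gaps, dec$yhat) + margin_delta(y, dec$yhat, mp) -
      alignment_score(om, gaps, y)
    expect_gte(hinge, -1e-9)
  }
})

test_that("the per-instance loss report is coherent in its limits", {
  set.seed(6)
  cfg <- tiny_config()
  p <- init_params(cfg)
  a <- "ACGUAC"; b <- "ACGAC"
  y <- nw_affine(omega(embed_sequence(a, p), embed_sequence(b, p)))$alignment
  # the model's own optimal alignment as reference, lambda = 0: the hinge is
  # only the margin slack, and total has no regularization part
  rep0 <- sal_loss(a, b, y, p, lambda = 0)
  expect_gte(rep0$hinge, -1e-9)
  expect_equal(rep0$total, rep0$hinge)
  expect_equal(rep0$reg, 0)
  rep1 <- sal_loss(a, b, y, p, lambda = 1e-4)
  expect_equal(rep1$reg, 1e-4 * param_sq_norm(p))
  expect_equal(rep1$total, rep1$hinge + rep1$reg)
})

test_that("the hinge subgradient matches central differences with the decode frozen", {
  set.seed(7)
  cfg <- tiny_config()
  p <- init_params(cfg)
  a <- "ACGUACG"; b <- "AGGUAC"
  y <- random_alignment(7, 6)
  g <- rnaembed:::sal_instance_grad(a, b, y, p, lambda = 0)
  yhat <- loss_augmented_decode(
    omega(embed_sequence(a, p), embed_sequence(b, p)), gap_params(), y)$yhat
  frozen_loss <- function(pp) {
    om <- omega(embed_sequence(a, pp), embed_sequence(b, pp))
    alignment_score(om, gap_params(), yhat) - alignment_score(om, gap_params(), y)
  }
  eps <- 1e-5
  for (probe in 1:3) {
    idx <- sample(length(p$token), 1)
    p1 <- p; p1$token[idx] <- p1$token[idx] + eps
    p2 <- p; p2$token[idx] <- p2$token[idx] - eps
    num <- (frozen_loss(p1) - frozen_loss(p2)) / (2 * eps)
    expect_equal(g$grads$token[idx], num, tolerance = 1e-4)
  }
})

test_that("a few SAL steps on synthetic pairs reduce the mean hinge", {
  set.seed(8)
  fam <- generate_family(family_spec("t", "..((((....))))..((...))",
                                     n_members = 6, substitution_rate = 0.3,
                                     indel_rate = 0.2))
  cfg <- model_config(D = 24L, n_layers = 2L, H = 4L, head_dim = 6L,
                      ffn_dim = 48L, max_len = 60L)
  p <- init_params(cfg)
  pairs <- sample_family_pairs(list(fam), pairs_per_family = 10)
  before <- sal_eval(pairs, p)
  st <- NULL
  for (e in 1:3) {
    res <- train_sal_epoch(pairs, p, st, lr = 5e-3)
    p <- res$params; st <- res$state
  }
  after <- sal_eval(pairs, p)
  expect_lt(after, before)
})
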