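test_that("surprisal and entropy reproduce closed-form hand values", {
  u8 <- distribution(letters[1:8], rep(1 / 8, 8))
  expect_equal(surprisal(u8, "c"), 3)
  expect_equal(entropy(u8), 3)

  point <- distribution(c("only", "never"), c(1, 0))
  expect_equal(surprisal(point, "only"), 0)
  expect_equal(entropy(point), 0)
  expect_identical(surprisal(point, "never"), Inf)

  bern <- distribution(c("stay", "switch"), c(.95, .05))
  expect_equal(entropy(bern), -.95 * log2(.95) - .05 * log2(.05))

  expect_error(surprisal(u8, "zz"), "alphabet")
  expect_equal(entropy(u8, base = "nats"), 3 * log(2))
})

test_that("joint validation enforces shape, positivity and near-unit mass", {
  expect_error(discrete_joint(matrix(1, 2, 2)), "3-d")
  bad <- array(1 / 8, dim = c(2, 2, 2)); bad[1] <- -bad[1]
  expect_error(discrete_joint(bad), ">= 0")
  off <- array(1 / 8 + 1e-6, dim = c(2, 2, 2))
  expect_error(discrete_joint(off), "sums to")
  near <- array((1 + 5e-10) / 8, dim = c(2, 2, 2))
  expect_equal(sum(discrete_joint(near)$pmf), 1) # renormalised
})

test_that("contrast on the stop-light joint reproduces the worked example", {
  joint <- markov_joint(stoplight_chain(), "predictive", 1, 1)
  expect_equal(round(contrast_from_joint(joint, b = "GREEN", c = "RED"), 2), 2.95)
  expect_equal(round(contrast_from_joint(joint, b = "RED", c = "RED"), 2), 0.02)
})

test_that("contrast is zero when target is independent of source given context", {
  # p(a, b, c) = p(a | c) p(b | c) p(c): ratio is identically 1
  set.seed(11)
  for (rep in 1:5) {
    pa_c <- matrix(runif(12, .1, 1), 3, 4); pa_c <- sweep(pa_c, 2, colSums(pa_c), "/")
    pb_c <- matrix(runif(8, .1, 1), 2, 4); pb_c <- sweep(pb_c, 2, colSums(pb_c), "/")
    pc <- runif(4, .1, 1); pc <- pc / sum(pc)
    pmf <- array(0, dim = c(3, 2, 4))
    for (ci in 1:4) pmf[, , ci] <- outer(pa_c[, ci], pb_c[, ci]) * pc[ci]
    j <- discrete_joint(pmf)
    for (bi in 1:2) {
      for (ci in 1:4) {
        expect_equal(contrast_from_joint(j, j$source_labels[bi], j$context_labels[ci]), 0,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("contrast matches the independent brute-force triple sum", {
  set.seed(101)
  for (rep in 1:20) {
    j <- random_joint(3, 3, 3)
    bi <- sample(3, 1); ci <- sample(3, 1)
    expect_equal(
      contrast_from_joint(j, j$source_labels[bi], j$context_labels[ci]),
      brute_contrast(j$pmf, bi, ci),
      tolerance = 1e-12
    )
  }
})

test_that("degenerate conditioning events raise the contract errors", {
  # a coherent joint cannot violate absolute continuity (p(a, b, c) > 0
  # forces p(a | c) > 0), so the reachable degeneracy is a zero-probability
  # conditioning event, which must be an explicit error naming (b, c)
  pmf <- array(c(0, .5, 0, 0, 0, 0, .5, 0), dim = c(2, 2, 2))
  j <- discrete_joint(pmf)
  expect_error(contrast_from_joint(j, j$source_labels[2], j$context_labels[1]),
               "zero probability")
  expect_error(contrast_from_joint(j, "nope", j$context_labels[1]), "alphabet")
})

test_that("expected contrast weights and conditional mutual information agree with direct sums", {
  set.seed(202)
  for (rep in 1:10) {
    j <- random_joint(3, 4, 2)
    pmf <- j$pmf
    ci <- sample(2, 1)
    p_c <- sum(pmf[, , ci])
    p_b_c <- apply(pmf[, , ci], 2, sum) / p_c
    direct <- sum(vapply(1:4, function(bi) {
      p_b_c[bi] * contrast_from_joint(j, j$source_labels[bi], j$context_labels[ci])
    }, numeric(1)))
    expect_equal(expected_contrast(j, "source", j$context_labels[ci]), direct,
                 tolerance = 1e-12)
    expect_equal(expected_contrast(j, "both"), brute_cmi(pmf), tolerance = 1e-12)
  }
})

test_that("expected contrast vanishes for a fully independent joint", {
  pmf <- array(1, dim = c(3, 2, 4))
  pmf <- pmf / sum(pmf)
  j <- discrete_joint(pmf)
  expect_equal(expected_contrast(j, "context", j$source_labels[1]), 0)
  expect_equal(expected_contrast(j, "source", j$context_labels[2]), 0)
  expect_equal(expected_contrast(j, "both"), 0)
})

test_that("relabeling any axis leaves every value unchanged", {
  set.seed(303)
  j <- random_joint(3, 3, 3)
  perm_a <- sample(3); perm_b <- sample(3); perm_c <- sample(3)
  j2 <- discrete_joint(
    j$pmf[perm_a, perm_b, perm_c],
    j$target_labels[perm_a], j$source_labels[perm_b], j$context_labels[perm_c]
  )
  for (b in j$source_labels) {
    for (c in j$context_labels) {
      expect_equal(contrast_from_joint(j, b, c), contrast_from_joint(j2, b, c),
                   tolerance = 1e-12)
    }
  }
  expect_equal(expected_contrast(j, "both"), expected_contrast(j2, "both"),
               tolerance = 1e-12)
})

test_that("contrast is not additive over a split source", {
  # I(A; (b1, b2) | c) != I(A; b1 | c) + I(A; b2 | b1, c) for a generic joint:
  # build the compound-source joint explicitly over B = (B1, B2)
  set.seed(404)
  na <- 2; nb <- 2; nc <- 1
  pmf4 <- array(runif(na * nb * nb * nc, .05, 1), dim = c(na, nb, nb, nc))
  pmf4 <- pmf4 / sum(pmf4)
  # joint over compound source (b1, b2)
  j_pair <- discrete_joint(array(pmf4, dim = c(na, nb * nb, nc)))
  lhs <- contrast_from_joint(j_pair, j_pair$source_labels[1], j_pair$context_labels[1])
  # I(A; b1 | c): marginalise b2
  j_b1 <- discrete_joint(array(apply(pmf4, c(1, 2, 4), sum), dim = c(na, nb, nc)))
  term1 <- contrast_from_joint(j_b1, j_b1$source_labels[1], j_b1$context_labels[1])
  # I(A; b2 | b1, c): fold b1 into the context axis
  j_b2 <- discrete_joint(array(aperm(pmf4, c(1, 3, 2, 4)), dim = c(na, nb, nb * nc)))
  term2 <- contrast_from_joint(j_b2, j_b2$source_labels[1], j_b2$context_labels[1])
  expect_gt(abs(lhs - (term1 + term2)), 1e-6)
})

test_that("discrete joints round-trip through JSON", {
  set.seed(505)
  j <- random_joint(2, 3, 4)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_joint(j, path)
  j2 <- read_joint(path)
  expect_equal(j2$pmf, j$pmf, tolerance = 1e-15, ignore_attr = TRUE)
  expect_identical(j2$source_labels, j$source_labels)
})

test_that("Monte-Carlo contrast is deterministic, unbiased at zero, and matches the Gaussian closed form", {
  ld <- function(a) dnorm(a, log = TRUE)
  same1 <- mc_contrast_continuous(ld, ld, function(n) rnorm(n), n = 2000, seed = 9)
  same2 <- mc_contrast_continuous(ld, ld, function(n) rnorm(n), n = 2000, seed = 9)
  expect_identical(same1$estimate, same2$estimate) # bit-identical under same seed
  expect_equal(same1$estimate, 0)

  ld1 <- function(a) dnorm(a, mean = 1, log = TRUE)
  mc <- mc_contrast_continuous(ld1, ld, function(n) rnorm(n, mean = 1),
                               n = 1e5, seed = 10)
  closed <- gaussian_kl(1, matrix(1), 0, matrix(1)) # 1/2 nat in bits
  expect_equal(closed, 0.5 / log(2))
  expect_lt(abs(mc$estimate - closed), 3 * mc$std_error)
  expect_error(mc_contrast_continuous(ld, ld, function(n) rnorm(n), n = 1, seed = 1),
               ">= 2")
})
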