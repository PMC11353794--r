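test_that("DTMC estimation matches a hand count of transitions", {
  # R,R,G,R: departures from R are R->R and R->G; G departs once to R
  m <- estimate_dtmc(list(c("R", "R", "G", "R")), pseudocount = 0)
  expect_equal(m$P["R", "R"], .5)
  expect_equal(m$P["G", "R"], .5)
  expect_equal(m$P["R", "G"], 1)
  expect_equal(m$P["G", "G"], 0)

  one <- estimate_dtmc(list(rep("A", 10)))
  expect_equal(unname(one$P), matrix(1))

  expect_error(estimate_dtmc(list(c("A", "B"))), "zero departures")
  sm <- estimate_dtmc(list(c("A", "B")), pseudocount = .5)
  expect_equal(colSums(sm$P), c(A = 1, B = 1))
})

test_that("DTMC estimation recovers a known chain from a long seeded path", {
  P <- matrix(c(.7, .2, .1, .1, .6, .3, .2, .3, .5), 3)
  truth <- dtmc_model(P, c("lo", "mid", "hi"))
  path <- simulate(truth, nsim = 1e5, seed = 2024)
  est <- estimate_dtmc(list(path), alphabet = truth$alphabet)
  expect_lt(max(abs(est$P - truth$P)), .01)
})

test_that("stationary distribution satisfies its defining residuals", {
  sym <- dtmc_model(matrix(c(.8, .2, .2, .8), 2))
  expect_equal(unname(sym$pi), c(.5, .5))

  set.seed(31)
  for (rep in 1:10) {
    m <- random_dtmc(4)
    expect_lt(max(abs(m$P %*% m$pi - m$pi)), 1e-12)
    expect_true(all(m$pi > 0))
  }

  cm <- random_ctmc(4)
  expect_lt(max(abs(cm$Q %*% cm$pi)), 1e-12)

  # reducible chain: no stationary distribution
  P2 <- diag(2)
  expect_warning(m2 <- dtmc_model(P2), "reducible")
  expect_error(stationary_distribution(m2), "reducible")
  # periodic chain: no unique limit
  P3 <- matrix(c(0, 1, 1, 0), 2)
  expect_warning(m3 <- dtmc_model(P3), "periodic")
  expect_error(stationary_distribution(m3), "periodic")
})

test_that("reverse matrix follows the elementwise formula and is column stochastic", {
  sym <- dtmc_model(matrix(c(.8, .2, .2, .8), 2))
  expect_equal(reverse_matrix(sym), sym$P) # reversible chain

  set.seed(32)
  m <- random_dtmc(4)
  R <- reverse_matrix(m)
  for (jj in 1:4) {
    for (kk in 1:4) {
      expect_equal(R[jj, kk], m$pi[jj] * m$P[kk, jj] / m$pi[kk], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
  expect_lt(max(abs(colSums(R) - 1)), 1e-12)
})

test_that("the stop-light chain reproduces the worked one-step values", {
  light <- stoplight_chain()
  expect_equal(round(dtmc_contrast(light, "predictive", x = "RED", y = "GREEN"), 2), 2.95)
  expect_equal(round(dtmc_contrast(light, "predictive", x = "RED", y = "RED"), 2), 0.02)
})

test_that("connective variants are exactly zero for any Markov chain", {
  set.seed(33)
  for (rep in 1:20) {
    m <- random_dtmc(sample(2:5, 1))
    syms <- sample(m$alphabet, 3, replace = TRUE)
    j <- sample(1:3, 1); k <- sample(1:3, 1)
    expect_identical(
      dtmc_contrast(m, "connective", x = syms[1], y = syms[2], z = syms[3], j = j, k = k), 0)
    expect_identical(
      dtmc_contrast(m, "b-connective", x = syms[1], y = syms[2], z = syms[3], j = j, k = k), 0)
  }
})

test_that("all six closed forms match the definitional joint oracle", {
  set.seed(34)
  for (rep in 1:20) {
    m <- random_dtmc(sample(2:6, 1))
    j <- sample(1:3, 1); k <- sample(1:3, 1)
    x <- sample(m$alphabet, 1); y <- sample(m$alphabet, 1); z <- sample(m$alphabet, 1)
    for (v in contrast_variants()) {
      jt <- markov_joint(m, v, j, k)
      bc <- variant_bc(v, x, y, z)
      expect_lt(abs(
        dtmc_contrast(m, v, x = x, y = y, z = z, j = j, k = k) -
          contrast_from_joint(jt, bc[["b"]], bc[["c"]])
      ), 1e-10)
    }
  }
})

test_that("backward variants equal forward variants on the time-reversed chain", {
  set.seed(35)
  for (rep in 1:10) {
    m <- random_dtmc(4)
    rev <- dtmc_model(reverse_matrix(m), m$alphabet)
    expect_equal(unname(rev$pi), unname(m$pi), tolerance = 1e-9)
    x <- sample(m$alphabet, 1); y <- sample(m$alphabet, 1); z <- sample(m$alphabet, 1)
    j <- sample(1:2, 1); k <- sample(1:2, 1)
    expect_lt(abs(
      dtmc_contrast(m, "b-predictive", y = y, z = z, j = j, k = k) -
        dtmc_contrast(rev, "predictive", x = z, y = y, j = k, k = j)
    ), 1e-10)
    expect_lt(abs(
      dtmc_contrast(m, "b-reflective", x = x, z = z, j = j, k = k) -
        dtmc_contrast(rev, "reflective", x = z, z = x, j = k, k = j)
    ), 1e-10)
  }
})

test_that("DTMC profiles are pointwise-consistent and respect boundaries", {
  set.seed(36)
  m <- random_dtmc(3)
  s <- simulate(m, nsim = 12, seed = 5)
  prof <- markov_profile(m, s, "predictive", j = 1, k = 1)
  expect_equal(nrow(prof), 10) # N - 2 rows for j = k = 1
  sv <- s$value
  for (r in seq_len(nrow(prof))) {
    n <- prof$event_index[r]
    expect_equal(
      prof$value_bits[r],
      dtmc_contrast(m, "predictive", x = sv[n - 1], y = sv[n], j = 1, k = 1)
    )
  }

  # i.i.d. chain: every column of P identical => predictive profile is zero
  p <- c(.5, .3, .2)
  iid <- dtmc_model(matrix(rep(p, 3), 3), c("a", "b", "c"))
  prof0 <- markov_profile(iid, c("a", "b", "c", "a", "b"), "predictive")
  expect_equal(prof0$value_bits, rep(0, 3), tolerance = 1e-12)

  expect_error(markov_profile(m, c(m$alphabet[1], "ZZ"), "predictive"), "event 2")
})
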