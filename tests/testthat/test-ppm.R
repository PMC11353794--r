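abra <- function() strsplit("abracadabra", "")[[1]]

test_that("PPM training stores the hand-tallied context counts", {
  m <- train_ppm(list(abra()), order_bound = 1)
  cnt <- contrastinfo:::ppm_counts(m, "a")
  expect_equal(cnt[order(names(cnt))], c(b = 2, c = 1, d = 1))
  cnt0 <- contrastinfo:::ppm_counts(m, character(0))
  expect_equal(cnt0[order(names(cnt0))], c(a = 5, b = 2, c = 1, d = 1, r = 2))

  m0 <- train_ppm(list(abra()), order_bound = 0)
  expect_null(contrastinfo:::ppm_counts(m0, "a"))

  # retraining is idempotent
  m2 <- train_ppm(list(abra()), order_bound = 1)
  expect_equal(ppm_predict(m2, "a")$probs, ppm_predict(m, "a")$probs)
})

test_that("PPM-C predictions reproduce the hand-computed escape cascade", {
  m <- train_ppm(list(abra()), order_bound = 1)
  p <- ppm_predict(m, "a")
  probs <- stats::setNames(p$probs, p$labels)
  # order 1, context 'a': followers b:2, c:1, d:1 (n = 4, d = 3), escape 3/7;
  # order 0: counts a:5 b:2 r:2 c:1 d:1 (n = 11, d = 5), escape 5/16 to
  # uniform over 5 symbols
  p0 <- function(s, cnt) cnt / 16 + (5 / 16) * (1 / 5)
  expect_equal(probs[["b"]], 2 / 7 + (3 / 7) * p0("b", 2))
  expect_equal(probs[["a"]], 0 + (3 / 7) * p0("a", 5))
  expect_equal(sum(p$probs), 1, tolerance = 1e-12)

  # unseen context at every order: uniform over the alphabet
  m1 <- train_ppm(list(c("x", "y")), order_bound = 2, alphabet = c("x", "y", "z"))
  pu <- ppm_predict(m1, c("z", "z"))
  # order-2/1 contexts unseen; order 0 still applies, so not uniform; a truly
  # unseen model path is order bound 0 with a symbol never counted:
  expect_equal(sum(pu$probs), 1, tolerance = 1e-12)
  expect_true(all(pu$probs > 0))
})

test_that("every prediction is a positive distribution summing to one", {
  set.seed(81)
  m <- random_dtmc(4)
  corpus <- lapply(1:5, function(i) simulate(m, nsim = 100, seed = i))
  pm <- train_ppm(corpus, order_bound = 3)
  for (rep in 1:20) {
    ctx <- sample(m$alphabet, sample(0:4, 1), replace = TRUE)
    p <- ppm_predict(pm, ctx)
    expect_equal(sum(p$probs), 1, tolerance = 1e-12)
    expect_true(all(p$probs > 0))
  }
  expect_error(ppm_predict(pm, "QQ"), "alphabet")
})

test_that("profiles are pointwise-consistent, bounded and finite", {
  m <- train_ppm(list(abra()), order_bound = 2)
  prof <- ppm_profiles(m, abra())
  expect_equal(nrow(prof), 11)
  # information content equals -log2 of the predicted probability
  for (n in c(1, 4, 9)) {
    ctx <- if (n == 1) character(0) else abra()[max(1, n - 2):(n - 1)]
    p <- ppm_predict(m, ctx)
    expect_equal(prof$information_content[n],
                 surprisal(p, abra()[n]), tolerance = 1e-12)
    expect_equal(prof$entropy[n], entropy(p), tolerance = 1e-12)
  }
  expect_true(all(is.finite(unlist(prof[-1]))))
  expect_true(all(prof$predictive_contrast >= 0))
  expect_true(all(prof$predictive_contrast <= prof$information_content + 1e-12))
  expect_error(ppm_profiles(m, c("a", "Z")), "event 2")
})

test_that("order-0 models give constant entropy and expected contrast", {
  m0 <- train_ppm(list(abra()), order_bound = 0)
  prof <- ppm_profiles(m0, abra())
  expect_equal(diff(range(prof$entropy)), 0)
  expect_equal(diff(range(prof$expected_predictive_contrast)), 0)
  # with no usable context the future is independent of the present
  expect_equal(max(prof$predictive_contrast), 0, tolerance = 1e-12)
})

test_that("linked viewpoints form the Cartesian-product stream", {
  a <- c("p1", "p2", "p1")
  b <- c("du1", "du1", "du2")
  lv <- link_viewpoints(a, b)
  expect_equal(lv, c("p1+du1", "p2+du1", "p1+du2"))
  expect_lte(length(unique(lv)), length(unique(a)) * length(unique(b)))
  self <- link_viewpoints(a, a)
  expect_equal(length(self), 3)
  expect_true(all(self %in% c("p1+p1", "p2+p2")))
  expect_error(link_viewpoints(a, b[1:2]), "lengths differ")

  # independent streams: linked order-0 entropy ~ sum of component entropies
  set.seed(82)
  s1 <- sample(letters[1:3], 4000, replace = TRUE, prob = c(.5, .3, .2))
  s2 <- sample(LETTERS[1:4], 4000, replace = TRUE)
  h <- function(s) brute_entropy(table(s) / length(s))
  expect_lt(abs(h(link_viewpoints(s1, s2)) - (h(s1) + h(s2))), .05)
})

test_that("correlation matches the direct textbook formulas", {
  set.seed(83)
  x <- rnorm(50); y <- .6 * x + rnorm(50)
  got <- correlate_profiles(x, y)
  pearson <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rx <- rank(x); ry <- rank(y)
  spearman <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$pearson, pearson, tolerance = 1e-12)
  expect_equal(got$spearman, spearman, tolerance = 1e-12)

  expect_equal(correlate_profiles(x, x)[c("pearson", "spearman")],
               list(pearson = 1, spearman = 1))
  expect_equal(correlate_profiles(x, -x)[c("pearson", "spearman")],
               list(pearson = -1, spearman = -1))
  # non-finite pairs are excluded and counted
  x2 <- c(x, Inf); y2 <- c(y, 1)
  got2 <- correlate_profiles(x2, y2)
  expect_equal(got2$n_excluded, 1)
  expect_equal(got2$pearson, pearson, tolerance = 1e-12)
  expect_error(correlate_profiles(rep(1, 5), 1:5), "variance")
})

test_that("an order-1 PPM contrast profile approaches the exact chain profile with corpus size", {
  P <- matrix(c(.7, .2, .1, .15, .7, .15, .1, .3, .6), 3)
  chain <- dtmc_model(P, c("lo", "mid", "hi"))
  test_seq <- simulate(chain, nsim = 120, seed = 900)
  exact <- markov_profile(chain, test_seq, "predictive", j = 1, k = 1)
  gaps <- vapply(c(400, 3200, 25600), function(nsym) {
    corpus <- list(simulate(chain, nsim = nsym, seed = nsym + 1))
    pm <- train_ppm(corpus, order_bound = 1, alphabet = chain$alphabet)
    prof <- ppm_profiles(pm, test_seq)
    # align: chain profile covers events 2..N-1; PPM contrast at event n
    # predicts the next event from context ending at n
    mean(abs(prof$predictive_contrast[exact$event_index] - exact$value_bits))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], gaps[1] / 2)
})
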