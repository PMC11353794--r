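# Fixture generators shared across the suite. All randomness is seeded by the
# caller via withr-free local seeding (set.seed inside test blocks).

# random strictly positive joint pmf over (na, nb, nc)
random_joint <- function(na = 3, nb = 3, nc = 3) {
  pmf <- array(stats::runif(na * nb * nc, min = .05, max = 1), dim = c(na, nb, nc))
  discrete_joint(pmf / sum(pmf))
}

# random irreducible aperiodic chain (all entries positive)
random_dtmc <- function(n = 3) {
  P <- matrix(stats::runif(n * n, min = .05, max = 1), n, n)
  dtmc_model(sweep(P, 2, colSums(P), "/"))
}

# random CTMC with strictly positive off-diagonal rates
random_ctmc <- function(n = 3) {
  Q <- matrix(stats::runif(n * n, min = .1, max = 1), n, n)
  diag(Q) <- 0
  diag(Q) <- -colSums(Q)
  ctmc_model(Q)
}

# autocovariance of an MA(2) process (exactly zero beyond lag 2, so any
# truncation is a valid PSD Toeplitz covariance)
ma2_gamma <- function(theta1 = .9, theta2 = .5, sigma2 = 1, L = 5) {
  g <- c(1 + theta1^2 + theta2^2, theta1 * (1 + theta2), theta2, rep(0, L - 2))
  sigma2 * g
}

# the two-state stop-light chain: stay .95, switch .05
stoplight_chain <- function() {
  dtmc_model(matrix(c(.95, .05, .05, .95), 2), c("RED", "GREEN"))
}

# Independent brute-force evaluation of I(A; b | c) by explicit scalar loops
# over the definitional triple-normalised sum. Deliberately written without
# any vectorised shortcuts so it shares nothing with the package path.
brute_contrast <- function(pmf, bi, ci) {
  p_bc <- 0
  for (ai in seq_len(dim(pmf)[1])) p_bc <- p_bc + pmf[ai, bi, ci]
  p_c <- 0
  for (ai in seq_len(dim(pmf)[1])) {
    for (bj in seq_len(dim(pmf)[2])) p_c <- p_c + pmf[ai, bj, ci]
  }
  total <- 0
  for (ai in seq_len(dim(pmf)[1])) {
    p_a_bc <- pmf[ai, bi, ci] / p_bc
    p_ac <- 0
    for (bj in seq_len(dim(pmf)[2])) p_ac <- p_ac + pmf[ai, bj, ci]
    p_a_c <- p_ac / p_c
    if (p_a_bc > 0) total <- total + p_a_bc * log2(p_a_bc / p_a_c)
  }
  total
}

# brute-force conditional mutual information I(A; B | C) in bits
brute_cmi <- function(pmf) {
  total <- 0
  for (ci in seq_len(dim(pmf)[3])) {
    p_c <- sum(pmf[, , ci])
    if (p_c == 0) next
    for (bi in seq_len(dim(pmf)[2])) {
      for (ai in seq_len(dim(pmf)[1])) {
        p_abc <- pmf[ai, bi, ci]
        if (p_abc == 0) next
        p_a_c <- sum(pmf[ai, , ci]) / p_c
        p_b_c <- sum(pmf[, bi, ci]) / p_c
        p_ab_c <- p_abc / p_c
        total <- total + p_abc * log2(p_ab_c / (p_a_c * p_b_c))
      }
    }
  }
  total
}

# entropy of a probability vector in bits (direct formula)
brute_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# symbol lookup for variant role testing: for the window (x, y, z), return
# the (source, context) symbols the variant conditions on
variant_bc <- function(variant, x, y, z) {
  roles <- switch(variant,
    "predictive"   = c("y", "x"),
    "connective"   = c("x", "y"),
    "reflective"   = c("z", "x"),
    "b-predictive" = c("y", "z"),
    "b-connective" = c("z", "y"),
    "b-reflective" = c("x", "z")
  )
  vals <- c(x = x, y = y, z = z)
  c(b = vals[[roles[1]]], c = vals[[roles[2]]])
}

# minimal single-track MIDI writer used only to exercise the reader
vlq_bytes <- function(x) {
  if (x < 128) return(as.raw(x))
  c(as.raw(bitwOr(128L, x %/% 128L)), as.raw(x %% 128L))
}

write_test_midi <- function(path, notes, durations_ticks, division = 96) {
  track <- raw(0)
  for (i in seq_along(notes)) {
    track <- c(track, vlq_bytes(0), as.raw(c(0x90, notes[i], 64)),
               vlq_bytes(durations_ticks[i]), as.raw(c(0x80, notes[i], 0)))
  }
  track <- c(track, vlq_bytes(0), as.raw(c(0xFF, 0x2F, 0x00)))
  hdr <- c(charToRaw("MThd"), as.raw(c(0, 0, 0, 6, 0, 0, 0, 1)),
           writeBin(as.integer(division), raw(), size = 2, endian = "big"))
  trk <- c(charToRaw("MTrk"),
           writeBin(length(track), raw(), size = 4, endian = "big"), track)
  writeBin(c(hdr, trk), path)
  invisible(path)
}
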