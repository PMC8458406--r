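test_that("uniform frequencies yield zero couplings", {
  aln <- aln_from_strings(c("ACDEF", "GHIKL"))
  fr <- compute_frequencies(aln, pseudocount = 1)  # pure prior: no correlations
  m <- infer_mean_field(fr)
  expect_s3_class(m, "potts_model")
  expect_equal(m$gauge, "zero_sum")
  expect_lt(max(abs(m$J)), 1e-8)
})

test_that("a positively associated column pair gets a positive coupling", {
  # columns 1 and 2 co-occur as AA / CC far more often than AC / CA
  strings <- c(rep("AA", 40), rep("CC", 40), rep("AC", 10), rep("CA", 10))
  aln <- aln_from_strings(strings)
  fr <- compute_frequencies(aln, NULL, pseudocount = 0.2)
  m <- infer_mean_field(fr)
  A <- encode_sequence("A"); C <- encode_sequence("C")
  blk <- coupling_block(m, 1, 2)
  expect_gt(blk[A, A], 0)
  expect_gt(blk[C, C], 0)
  # gauge-invariant association: coupling log-odds ratio favors AA/CC
  expect_gt(blk[A, A] + blk[C, C] - blk[A, C] - blk[C, A], 0)
  # oracle: the inferred model's own 2-site Boltzmann distribution, computed
  # by exhaustive enumeration, shows the same positive association
  bz <- enumerate_boltzmann(m)
  pk <- function(s1, s2) bz$p[bz$states[, 1] == s1 & bz$states[, 2] == s2]
  expect_gt(pk(A, A) * pk(C, C), pk(A, C) * pk(C, A))
})

test_that("mean-field inversion requires regularisation", {
  aln <- aln_from_strings(c("AC", "AD"))
  fr <- compute_frequencies(aln, pseudocount = 0)
  expect_error(infer_mean_field(fr), "pseudocount")
})

test_that("Hamiltonian evaluation matches explicit summation", {
  expect_equal(evaluate_log_probability(potts_zero(4), c(1L, 5L, 21L, 3L)), 0)
  # L = 2, q = 2 hand-checkable model
  q <- 2L
  J <- matrix(0, 4, 4); J[1, 3] <- 1.5; J[3, 1] <- 1.5  # e_12(1,1) = 1.5
  J[2, 4] <- -0.5; J[4, 2] <- -0.5                      # e_12(2,2) = -0.5
  h <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)              # h_i(A)
  m <- potts_model(J, h, gauge = "raw", alphabet = c("A", "C"))
  expect_equal(evaluate_log_probability(m, c(1L, 1L)), 1.5 + 0.1 + 0.2)
  expect_equal(evaluate_log_probability(m, c(2L, 2L)), -0.5 + 0.3 + 0.4)
  expect_equal(evaluate_log_probability(m, c(1L, 2L)), 0.1 + 0.4)
  # random model agrees with the loop oracle
  mr <- rand_potts(5, 4, seed = 3)
  s <- c(2L, 4L, 1L, 3L, 2L)
  expect_equal(evaluate_log_probability(mr, s), oracle_hamiltonian(mr, s))
  expect_error(evaluate_log_probability(mr, c(1L, 2L)), "length")
})

test_that("zero-sum gauge conversion preserves the Boltzmann distribution", {
  m <- rand_potts(3, 3, seed = 9)
  mz <- to_zero_sum_gauge(m)
  # zero-sum invariants
  for (i in 1:2) for (j in (i + 1):3) {
    blk <- coupling_block(mz, i, j)
    expect_lt(max(abs(rowSums(blk))), 1e-8)
    expect_lt(max(abs(colSums(blk))), 1e-8)
  }
  expect_lt(max(abs(rowSums(mz$h))), 1e-8)
  # full enumeration over all 27 sequences
  b1 <- enumerate_boltzmann(m)
  b2 <- enumerate_boltzmann(mz)
  expect_lt(max(abs(b1$p - b2$p)), 1e-8)
  # idempotence
  mzz <- to_zero_sum_gauge(mz)
  expect_lt(max(abs(mzz$J - mz$J)), 1e-12)
  expect_lt(max(abs(mzz$h - mz$h)), 1e-12)
  # constant coupling block centres to zero
  q <- 3L; Jc <- matrix(0, 6, 6)
  Jc[1:3, 4:6] <- 2.5; Jc[4:6, 1:3] <- 2.5
  mc <- to_zero_sum_gauge(potts_model(Jc, matrix(0, 2, 3), gauge = "raw",
                                      alphabet = c("A", "C", "D")))
  expect_lt(max(abs(mc$J)), 1e-12)
})

test_that("Hamiltonian differences are gauge invariant", {
  m <- rand_potts(4, 5, seed = 21)
  mz <- to_zero_sum_gauge(m)
  set.seed(1)
  for (r in 1:20) {
    s1 <- sample.int(5L, 4L, replace = TRUE)
    s2 <- sample.int(5L, 4L, replace = TRUE)
    d1 <- evaluate_log_probability(m, s1) - evaluate_log_probability(m, s2)
    d2 <- evaluate_log_probability(mz, s1) - evaluate_log_probability(mz, s2)
    expect_equal(d1, d2, tolerance = 1e-8)
  }
})

test_that("pair ranking finds the planted pair and matches the two-site DI oracle", {
  # all-zero couplings: DI identically zero
  L <- 4; q <- 3
  aln <- aln_from_strings(c("ACDA", "CADC"))
  fr <- compute_frequencies(aln, pseudocount = 1)
  z <- potts_zero(L, 21L)
  rp0 <- rank_pairs(z, fr, metric = "direct_information")
  expect_equal(rp0$score, rep(0, nrow(rp0)), tolerance = 1e-10)

  # single planted coupled pair ranks first under both metrics
  q <- 4L; Lp <- 5L
  J <- matrix(0, Lp * q, Lp * q)
  ri <- (2L - 1L) * q; rj <- (4L - 1L) * q
  B <- diag(q) * 2 - 0.5
  J[ri + 1:q, rj + 1:q] <- B; J[rj + 1:q, ri + 1:q] <- t(B)
  mp <- to_zero_sum_gauge(potts_model(J, matrix(0, Lp, q), gauge = "raw",
                                      alphabet = c("A", "C", "D", "E")))
  frp <- list(fi = matrix(1 / q, Lp, q), L = Lp, q = q, pseudocount = 0.5)
  class(frp) <- "freq_model"
  for (metric in c("direct_information", "frobenius_apc")) {
    rp <- rank_pairs(mp, frp, metric = metric)
    expect_equal(c(rp$i[1], rp$j[1]), c(2L, 4L))
  }

  # DI equals mutual information of the exhaustively enumerated two-site joint
  set.seed(8)
  e <- matrix(rnorm(9, sd = 0.8), 3, 3)
  h1 <- rnorm(3); h2 <- rnorm(3)
  joint <- exp(outer(h1, h2, `+`) + e); joint <- joint / sum(joint)
  f1 <- rowSums(joint); f2 <- colSums(joint)
  Jm <- matrix(0, 6, 6); Jm[1:3, 4:6] <- e; Jm[4:6, 1:3] <- t(e)
  m2 <- potts_model(Jm, matrix(0, 2, 3), gauge = "raw", alphabet = c("A", "C", "D"))
  fr2 <- structure(list(fi = rbind(f1, f2), L = 2L, q = 3L, pseudocount = 0.5),
                   class = "freq_model")
  di <- rank_pairs(m2, fr2, metric = "direct_information")$score[1]
  mi <- sum(joint * log(joint / outer(f1, f2)))
  expect_equal(di, mi, tolerance = 1e-6)

  expect_error(rank_pairs(mp, frp, metric = "nonsense"))
})

test_that("ranking is orientation independent, deterministic, and truncatable", {
  fx <- rand_potts(6, 3, seed = 33)
  frx <- structure(list(fi = matrix(1 / 3, 6, 3), L = 6L, q = 3L, pseudocount = 0.5),
                   class = "freq_model")
  fwd <- rank_pairs(fx, frx, metric = "frobenius_apc",
                    restrict_to = cbind(c(1, 2, 3), c(4, 5, 6)))
  rev <- rank_pairs(fx, frx, metric = "frobenius_apc",
                    restrict_to = cbind(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(as.data.frame(fwd), as.data.frame(rev))
  expect_true(all(diff(fwd$score) <= 0))
  expect_equal(nrow(rank_pairs(fx, frx, metric = "frobenius_apc", top_k = 2)), 2L)
})

test_that("null alignments show shrinking maximum pair scores as M grows", {
  maxes <- sapply(c(100L, 400L, 1600L), function(M) {
    set.seed(M)
    aln <- msa_alignment(matrix(sample.int(21L, M * 8L, replace = TRUE), M, 8L))
    fit <- mfdca(aln, identity_threshold = 0.8, pseudocount = 0.5)
    max(rank_pairs(fit, metric = "frobenius_apc")$score)
  })
  expect_true(all(diff(maxes) < 0))
})
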