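make_scan_toy <- function(seed = 1, L = 10L, q = 21L, dbm = 1:4) {
  set.seed(seed)
  p <- module_partition(dbm, L)
  mz <- to_zero_sum_gauge(rand_potts(L, q, scale = 0.3))
  pairs <- as.data.frame(inter_module_pairs(p))
  cm <- contact_map(rbind(c(5, 6), c(6, 7), c(8, 9)))
  h <- build_hybrid(sample.int(20L, L, TRUE), sample.int(20L, L, TRUE), p)
  list(p = p, m = mz, pairs = pairs, cm = cm, h = h,
       mask = exclusion_mask(p$dbm_columns, "dbm"))
}

test_that("single scan enumerates 19 substitutions per scannable LBM column", {
  toy <- make_scan_toy()
  res <- scan_single(toy$h, toy$m, toy$pairs, toy$cm, toy$p, toy$mask)
  expect_s3_class(res, "scan_result")
  expect_equal(nrow(res), length(toy$p$lbm_columns) * 19L)
  expect_equal(sort(res$rank), seq_len(nrow(res)))
  expect_true(!is.unsorted(res$delta_c))
  # scores tie out against score_with_deltas for a spot-checked row
  row <- res[17, ]
  mut <- toy$h
  mut$seq[row$columns] <- encode_sequence(substr(row$label, nchar(row$label),
                                                nchar(row$label)))
  sp <- score_with_deltas(mut, toy$h, toy$m, toy$pairs, toy$cm, toy$p)
  expect_equal(row$delta_c, sp$delta_c, tolerance = 1e-9)
  expect_equal(row$delta_sf, sp$delta_sf, tolerance = 1e-9)

  # wild-type gap columns are skipped
  h2 <- toy$h; h2$seq[6] <- 21L
  res2 <- scan_single(h2, toy$m, toy$pairs, toy$cm, toy$p, toy$mask)
  expect_equal(nrow(res2), (length(toy$p$lbm_columns) - 1L) * 19L)
})

test_that("zero couplings produce all-zero deltas in lexicographic order", {
  toy <- make_scan_toy()
  z <- potts_zero(10L, 21L)
  res <- scan_single(toy$h, z, toy$pairs, toy$cm, toy$p, toy$mask)
  expect_equal(res$delta_c, rep(0, nrow(res)))
  expect_equal(res$label, sort(res$label))
})

test_that("a dominant favorable coupling is found first by the scanner", {
  L <- 10L; q <- 21L
  p <- module_partition(1:4, L)
  J <- matrix(0, L * q, L * q)
  # strong favorable coupling reachable by mutating column 7 to state 2
  J[(1 - 1) * q + 1, (7 - 1) * q + 2] <- 5
  J[(7 - 1) * q + 2, (1 - 1) * q + 1] <- 5
  mz <- to_zero_sum_gauge(potts_model(J, matrix(0, L, q), gauge = "raw"))
  h <- build_hybrid(rep(1L, L), rep(1L, L), p)
  res <- scan_single(h, mz, as.data.frame(inter_module_pairs(p)),
                     contact_map(matrix(numeric(0), 0, 2)), p,
                     exclusion_mask(p$dbm_columns, "dbm"))
  expect_equal(res$columns[1], 7L)
  expect_equal(substr(res$label[1], nchar(res$label[1]), nchar(res$label[1])), "C")
})

test_that("scan determinism: identical inputs give identical output", {
  toy <- make_scan_toy()
  r1 <- scan_single(toy$h, toy$m, toy$pairs, toy$cm, toy$p, toy$mask)
  r2 <- scan_single(toy$h, toy$m, toy$pairs, toy$cm, toy$p, toy$mask)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("multi-mutation scan matches brute-force enumeration on a toy", {
  toy <- make_scan_toy(seed = 3)
  full_beam <- length(toy$p$lbm_columns) * 19L
  res2 <- scan_multi(toy$h, 2L, toy$m, toy$pairs, toy$cm, toy$p, toy$mask,
                     beam = full_beam)
  singles <- scan_single(toy$h, toy$m, toy$pairs, toy$cm, toy$p, toy$mask)
  # best pair's additive delta equals the best sum of two distinct-column singles
  best_by_col <- tapply(singles$delta_c, singles$columns, min)
  expect_equal(res2$delta_c[1], sum(sort(best_by_col)[1:2]), tolerance = 1e-9)
  # no candidate repeats a column
  cols <- strsplit(res2$columns, ",")
  expect_true(all(vapply(cols, function(x) !anyDuplicated(x), TRUE)))
  # additive path equals full rescoring for 50 random candidate sets
  set.seed(14)
  for (r in sample(nrow(res2), 50)) {
    parts <- strsplit(res2$label[r], "/", fixed = TRUE)[[1]]
    cset <- as.integer(strsplit(res2$columns[r], ",")[[1]])
    mut <- toy$h
    mut$seq[cset] <- encode_sequence(substr(parts, nchar(parts), nchar(parts)))
    full <- compatibility_score(mut$seq, toy$m, toy$pairs, toy$p) -
      compatibility_score(toy$h$seq, toy$m, toy$pairs, toy$p)
    expect_equal(res2$delta_c[r], full, tolerance = 1e-9)
    # delta SF is recomputed exactly, never assumed additive
    full_sf <- structural_fitness_score(mut$seq, toy$m, toy$cm) -
      structural_fitness_score(toy$h$seq, toy$m, toy$cm)
    expect_equal(res2$delta_sf[r], full_sf, tolerance = 1e-9)
  }
  expect_error(scan_multi(toy$h, 4L, toy$m, toy$pairs, toy$cm, toy$p, toy$mask),
               "k must be 2 or 3")
  expect_error(scan_multi(toy$h, 3L, toy$m, toy$pairs, toy$cm, toy$p, toy$mask,
                          beam = 2L), "beam")
})

test_that("enlarging the beam never worsens the best multi-mutant found", {
  toy <- make_scan_toy(seed = 8)
  best <- sapply(c(20L, 40L, 80L, 114L), function(b) {
    scan_multi(toy$h, 2L, toy$m, toy$pairs, toy$cm, toy$p, toy$mask,
               beam = b)$delta_c[1]
  })
  expect_true(all(diff(best) <= 1e-12))
})

test_that("triple scan shortlists two candidates sharing a double prefix", {
  toy <- make_scan_toy(seed = 5)
  res3 <- scan_multi(toy$h, 3L, toy$m, toy$pairs, toy$cm, toy$p, toy$mask,
                     beam = 25L)
  sl <- shortlist_triples(res3)
  expect_lte(nrow(sl), 2L)
  expect_equal(sl$label[1], res3$label[1])
  if (nrow(sl) == 2L) {
    shared <- intersect(strsplit(sl$label[1], "/")[[1]],
                        strsplit(sl$label[2], "/")[[1]])
    expect_length(shared, 2L)
  }
})

test_that("the SF gray-region filter keeps only structurally sound candidates", {
  # six-row hand-worked table
  tab <- data.frame(label = paste0("M", 1:6), columns = 1:6,
                    delta_c = c(-3, -2.5, -2, -1, -0.5, 1),
                    delta_sf = c(2, -1, -0.2, 0.1, -2, 0),
                    c_score = NA_real_, sf_score = c(-3, -6, -5.2, -4.9, -7, -5))
  scan <- structure(tab, reference_c = -10, reference_sf = -5, k = 1L,
                    class = c("scan_result", "data.frame"))
  # flag off: plain truncation
  off <- select_candidates(scan, require_sf_improvement = FALSE, top_n = 3)
  expect_equal(off$label, c("M1", "M2", "M3"))
  # flag on: rows with sf_score <= -5 survive, then top-2 by delta C
  on <- select_candidates(scan, require_sf_improvement = TRUE, top_n = 2)
  expect_equal(on$label, c("M2", "M3"))
  expect_equal(on$rank, 1:2)
  # nothing survives
  worst <- scan; worst$sf_score <- 0
  expect_warning(res <- select_candidates(worst), "no candidates")
  expect_equal(nrow(res), 0L)
})

test_that("the pocket mask excludes DBM plus ligand-contact columns from scans", {
  toy <- make_scan_toy()
  m0 <- build_pocket_mask(integer(0), toy$p)
  expect_setequal(m0$excluded_columns, toy$p$dbm_columns)
  m1 <- build_pocket_mask(c(3L, 6L, 9L), toy$p)  # overlaps DBM at 3
  expect_setequal(m1$excluded_columns, c(1:4, 6L, 9L))
  expect_equal(sum(m1$excluded_columns == 3L), 1L)
  res <- scan_single(toy$h, toy$m, toy$pairs, toy$cm, toy$p, m1)
  expect_false(any(res$columns %in% c(6L, 9L)))
  expect_equal(nrow(res), (length(toy$p$lbm_columns) - 2L) * 19L)
})
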