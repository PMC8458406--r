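# Shared fixtures and independent oracles for the test suite.

# Random symmetric Potts model (raw gauge) with dense Gaussian couplings.
rand_potts <- function(L, q, scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- matrix(0, L * q, L * q)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      B <- matrix(rnorm(q * q, sd = scale), q, q)
      J[((i - 1L) * q + 1L):(i * q), ((j - 1L) * q + 1L):(j * q)] <- B
      J[((j - 1L) * q + 1L):(j * q), ((i - 1L) * q + 1L):(i * q)] <- t(B)
    }
  }
  potts_model(J, matrix(rnorm(L * q, sd = scale), L, q), gauge = "raw",
              alphabet = aa_alphabet()[seq_len(q)])
}

# Independent naive-loop oracle for the negated coupling sum over a pair set:
# explicit loop over rows, block extraction, scalar indexing. Never vectorised
# the way the implementation is.
oracle_pair_sum <- function(seq, model, pairs) {
  pairs <- as.data.frame(pairs)
  tot <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    tot <- tot + coupling_block(model, i, j)[seq[i], seq[j]]
  }
  -tot
}

# Exhaustive Hamiltonian by explicit double loop (oracle for
# evaluate_log_probability and gauge checks).
oracle_hamiltonian <- function(model, s) {
  tot <- 0
  L <- model$L
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) tot <- tot + coupling_block(model, i, j)[s[i], s[j]]
  }
  tot + sum(sapply(seq_len(L), function(i) model$h[i, s[i]]))
}

# Enumerate the full Boltzmann distribution of a small model (q^L sequences).
enumerate_boltzmann <- function(model) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(model$q)), model$L)))
  H <- apply(grid, 1L, function(s) evaluate_log_probability(model, as.integer(s)))
  p <- exp(H - max(H)); p <- p / sum(p)
  list(states = grid, p = p)
}

# Alignment built from explicit letter strings.
aln_from_strings <- function(strings, ids = NULL) {
  mat <- do.call(rbind, lapply(strings, function(s) encode_sequence(strsplit(s, "")[[1L]])))
  msa_alignment(mat, ids)
}

# The acceptance-scale planted scenario and its fit, built once per test run.
.fixture_env <- new.env(parent = emptyenv())
planted_fixture <- function() {
  if (is.null(.fixture_env$sc)) {
    sc <- make_planted_scenario(L = 60L, q = 21L, n_dbm_columns = 12L,
                                planted_pair_count = 5L, coupling_strength = 2,
                                n_sequences = 5000L, seed = 11L)
    fit <- mfdca(sc$sampled_alignment)
    .fixture_env$sc <- sc
    .fixture_env$fit <- fit
  }
  list(sc = .fixture_env$sc, fit = .fixture_env$fit)
}

# Sign agreement between true and inferred couplings on the planted pairs'
# active 2x2 state blocks (both models in zero-sum gauge).
planted_sign_agreement <- function(true_model, fit_model, planted_pairs) {
  hits <- 0L; tot <- 0L
  for (k in seq_len(nrow(planted_pairs))) {
    i <- planted_pairs$i[k]; j <- planted_pairs$j[k]
    tb <- coupling_block(true_model, i, j)[1:2, 1:2]
    ib <- coupling_block(fit_model, i, j)[1:2, 1:2]
    hits <- hits + sum(sign(tb) == sign(ib))
    tot <- tot + 4L
  }
  hits / tot
}

precision_at_k <- function(ranked_pairs, truth_pairs, k) {
  truth <- paste(pmin(truth_pairs$i, truth_pairs$j),
                 pmax(truth_pairs$i, truth_pairs$j))
  found <- paste(ranked_pairs$i[seq_len(k)], ranked_pairs$j[seq_len(k)])
  mean(found %in% truth)
}

# Minimal hand-written PDB: one CA atom per residue at given coordinates.
write_min_pdb <- function(xyz, path = tempfile(fileext = ".pdb"),
                          chain = "A", resid = "ALA", extra_lines = NULL) {
  n <- nrow(xyz)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, resid, chain, i, xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, "")
  writeLines(c(lines, extra_lines, "TER", "END"), path)
  path
}
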