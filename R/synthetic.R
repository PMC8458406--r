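#' Gibbs-sample an alignment from a Potts model
#'
#' Single-site heat-bath (Gibbs) sampling from the Boltzmann distribution
#' \eqn{P(S) \propto \exp\{\sum_{i<j} e_{ij}(s_i,s_j) + \sum_i h_i(s_i)\}}.
#' One chain is run; the first kept sample follows \code{burn_in} full
#' sweeps and successive kept samples are separated by \code{thin} sweeps.
#' Fully deterministic given \code{seed}.
#'
#' @param model A \code{"potts_model"} (any gauge).
#' @param n Number of sequences to draw.
#' @param seed Integer seed (NULL leaves R's RNG state alone).
#' @param burn_in Burn-in sweeps, default 1000.
#' @param thin Sweeps between kept samples, default 10.
#' @return A \code{\link{msa_alignment}} with n rows.
#' @export
sample_potts <- function(model, n, seed = NULL, burn_in = 1000L, thin = 10L) {
  stopifnot(inherits(model, "potts_model"))
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (burn_in < 1L || thin < 1L) stop("burn_in and thin must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  init <- sample.int(model$q, model$L, replace = TRUE)
  mat <- .cpp_gibbs_sample(model$J, model$h, init, as.integer(n),
                           as.integer(burn_in), as.integer(thin))
  # pad alphabet in case q < 21 toy models are decoded later
  aln <- msa_alignment(mat, paste0("sample", seq_len(n)))
  aln$q <- model$q
  aln
}

#' Build a planted two-subfamily design scenario
#'
#' Constructs a sparse Potts model over L columns (the first
#' \code{n_dbm_columns} form the DBM) in which \code{planted_pair_count}
#' inter-module pairs carry strong couplings encoding two mutually exclusive
#' compatible state combinations: DBM state X pairs favorably with LBM state
#' a and DBM state Y with LBM state b, while the cross combinations (X,b)
#' and (Y,a) are penalised. This is the minimal structure reproducing the
#' biology the design loop targets: two coevolved subfamilies whose modules
#' are individually fine but mutually incompatible when hybridised, and
#' whose hybrids are rescuable by single LBM substitutions.
#'
#' Fields raise the probability of the two active states at planted columns
#' so that sampled alignments actually exercise the planted couplings.
#'
#' @param L Alignment length (default 60).
#' @param q States (default 21).
#' @param n_dbm_columns DBM size (default 12).
#' @param planted_pair_count Number of planted inter-module pairs (default 5).
#' @param coupling_strength Planted coupling magnitude (default 2).
#' @param n_sequences Alignment size to sample (default 5000).
#' @param seed Random seed.
#' @param field_strength Field bonus on the two active states at planted
#'   columns (default 2).
#' @param burn_in,thin Passed to \code{\link{sample_potts}}.
#' @return Object of class \code{"planted_scenario"}: list with
#'   \code{true_model} (zero-sum gauge), \code{planted_pairs} (data.frame
#'   i, j), \code{partition}, \code{compatible_states} (per pair, the
#'   favorable (X,a)/(Y,b) combinations), \code{parent_x}, \code{parent_y}
#'   (encoded parent sequences of the two subfamilies),
#'   \code{sampled_alignment}, \code{seed}.
#' @export
make_planted_scenario <- function(L = 60L, q = 21L, n_dbm_columns = 12L,
                                  planted_pair_count = 5L,
                                  coupling_strength = 2,
                                  n_sequences = 5000L, seed = 1L,
                                  field_strength = 2,
                                  burn_in = 1000L, thin = 10L) {
  n_lbm <- L - n_dbm_columns
  if (planted_pair_count > n_dbm_columns * n_lbm) {
    stop("more planted pairs than available inter-module pairs", call. = FALSE)
  }
  set.seed(seed)
  partition <- module_partition(seq_len(n_dbm_columns), L)
  # spread planted pairs over distinct columns as far as counts allow
  di <- partition$dbm_columns[1L + (seq_len(planted_pair_count) - 1L) %% n_dbm_columns]
  lj <- partition$lbm_columns[1L + (seq_len(planted_pair_count) - 1L) %% n_lbm]
  X <- 1L; Y <- 2L; a <- 1L; b <- 2L  # states A/C on both sides

  J <- matrix(0, L * q, L * q)
  h <- matrix(0, L, q)
  s <- coupling_strength
  for (k in seq_len(planted_pair_count)) {
    ri <- (di[k] - 1L) * q; rj <- (lj[k] - 1L) * q
    J[ri + X, rj + a] <- J[ri + X, rj + a] + s
    J[ri + Y, rj + b] <- J[ri + Y, rj + b] + s
    J[ri + X, rj + b] <- J[ri + X, rj + b] - s
    J[ri + Y, rj + a] <- J[ri + Y, rj + a] - s
    J[rj + a, ri + X] <- J[ri + X, rj + a]
    J[rj + b, ri + Y] <- J[ri + Y, rj + b]
    J[rj + b, ri + X] <- J[ri + X, rj + b]
    J[rj + a, ri + Y] <- J[ri + Y, rj + a]
  }
  for (col in unique(c(di, lj))) h[col, c(X, Y)] <- field_strength
  true_model <- to_zero_sum_gauge(potts_model(J, h, gauge = "raw",
                                              alphabet = aa_alphabet()[seq_len(q)]))
  aln <- sample_potts(true_model, n_sequences, seed = seed + 1L,
                      burn_in = burn_in, thin = thin)

  # subfamily parents: consensus background, active states at planted columns
  bg <- apply(aln$matrix, 2L, function(colv) which.max(tabulate(colv, q)))
  parent_x <- parent_y <- as.integer(bg)
  parent_x[di] <- X; parent_x[lj] <- a
  parent_y[di] <- Y; parent_y[lj] <- b

  structure(list(
    true_model = true_model,
    planted_pairs = data.frame(i = di, j = lj),
    partition = partition,
    compatible_states = data.frame(i = di, j = lj,
                                   dbm_state_x = rep(X, length(di)),
                                   lbm_state_a = rep(a, length(di)),
                                   dbm_state_y = rep(Y, length(di)),
                                   lbm_state_b = rep(b, length(di))),
    parent_x = parent_x, parent_y = parent_y,
    sampled_alignment = aln, seed = seed),
    class = "planted_scenario")
}

#' @export
print.planted_scenario <- function(x, ...) {
  cat(sprintf(paste0("Planted design scenario: L = %d, %d DBM columns, ",
                     "%d planted inter-module pairs, %d sampled sequences (seed %d)\n"),
              x$true_model$L, length(x$partition$dbm_columns),
              nrow(x$planted_pairs), nrow(x$sampled_alignment$matrix), x$seed))
  invisible(x)
}

#' Write a minimal toy PDB chain realizing a banded contact set
#'
#' Places one CA atom per residue on a straight line at the given spacing,
#' so the contact set at a cutoff is exactly the set of residue pairs within
#' \code{floor(cutoff / spacing)} chain steps (strict inequality at the
#' cutoff). If \code{contact_pairs} is supplied it is checked against that
#' band; geometries not realizable on the line layout are rejected.
#'
#' @param L Number of residues.
#' @param spacing Distance between consecutive residues in Angstrom.
#' @param contact_pairs Optional two-column matrix of required contacts
#'   (1-based residue indices) to verify at \code{cutoff}.
#' @param cutoff Cutoff used for the verification (default 10).
#' @param path Output path; default a tempfile.
#' @return The path of the written PDB file (attribute
#'   \code{"contacts"}: the band contact set as a two-column matrix).
#' @export
make_toy_structure <- function(L, spacing = 4, contact_pairs = NULL,
                               cutoff = 10, path = tempfile(fileext = ".pdb")) {
  steps <- seq_len(L)
  band <- which(outer(steps, steps, function(a, b) {
    a < b & abs(a - b) * spacing < cutoff
  }), arr.ind = TRUE)
  band <- band[order(band[, 1L], band[, 2L]), , drop = FALSE]
  if (!is.null(contact_pairs)) {
    cp <- as.matrix(contact_pairs)
    want <- if (nrow(cp)) paste(pmin(cp[, 1], cp[, 2]), pmax(cp[, 1], cp[, 2])) else character(0)
    have <- if (nrow(band)) paste(band[, 1L], band[, 2L]) else character(0)
    if (!setequal(want, have)) {
      stop("requested contact set is not realizable on a linear chain at this spacing",
           call. = FALSE)
    }
  }
  lines <- vapply(seq_len(L), function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, (i - 1) * spacing, 0, 0)
  }, "")
  writeLines(c(lines, "TER", "END"), path)
  attr(path, "contacts") <- unname(band)
  path
}
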