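#' Construct a Potts model
#'
#' The global sequence model assigns a sequence S probability proportional to
#' \eqn{\exp\{\sum_{i<j} e_{ij}(A_i, A_j) + \sum_i h_i(A_i)\}}. Couplings are
#' stored as an (L*q) x (L*q) symmetric block matrix \code{J} whose (i, j)
#' block holds \eqn{e_{ij}(A,B)} (so \code{J} satisfies
#' \eqn{e_{ij}(A,B) = e_{ji}(B,A)} by matrix symmetry); diagonal blocks are
#' zero. Fields are an L x q matrix \code{h}.
#'
#' @param J (L*q) x (L*q) symmetric numeric matrix with zero diagonal blocks.
#' @param h L x q numeric matrix of fields.
#' @param gauge One of \code{"raw"}, \code{"reference_state"}, \code{"zero_sum"}.
#' @param alphabet State labels (length q).
#' @return Object of class \code{"potts_model"}.
#' @export
potts_model <- function(J, h, gauge = c("raw", "reference_state", "zero_sum"),
                        alphabet = aa_alphabet()[seq_len(ncol(h))]) {
  gauge <- match.arg(gauge)
  L <- nrow(h); q <- ncol(h)
  if (!is.matrix(J) || nrow(J) != L * q || ncol(J) != L * q) {
    stop("J must be an (L*q) x (L*q) matrix", call. = FALSE)
  }
  if (max(abs(J - t(J))) > 1e-10) stop("coupling matrix must be symmetric", call. = FALSE)
  for (i in seq_len(L)) {
    rows <- ((i - 1L) * q + 1L):(i * q)
    if (max(abs(J[rows, rows])) > 1e-10) {
      stop("diagonal coupling blocks must be zero", call. = FALSE)
    }
  }
  structure(list(J = J, h = h, gauge = gauge, L = L, q = q, alphabet = alphabet),
            class = "potts_model")
}

#' Zero (null) Potts model
#' @param L Number of positions.
#' @param q Number of states (default 21).
#' @return A \code{"potts_model"} with all couplings and fields zero, in
#'   zero-sum gauge (trivially).
#' @export
potts_zero <- function(L, q = aa_nstates()) {
  potts_model(matrix(0, L * q, L * q), matrix(0, L, q), gauge = "zero_sum")
}

#' Extract one coupling block
#' @param model A \code{"potts_model"}.
#' @param i,j Positions (i != j).
#' @return q x q matrix \eqn{e_{ij}(A,B)}.
#' @export
coupling_block <- function(model, i, j) {
  q <- model$q
  model$J[((i - 1L) * q + 1L):(i * q), ((j - 1L) * q + 1L):(j * q)]
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("Potts model: L = %d, q = %d, gauge = %s\n", x$L, x$q, x$gauge))
  invisible(x)
}

#' Potts Hamiltonian (log-probability up to a constant)
#'
#' Returns \eqn{\sum_{i<j} e_{ij}(s_i, s_j) + \sum_i h_i(s_i)}; the
#' log-partition function is not computed, so values are comparable between
#' sequences under the same model but are not normalised log-probabilities.
#'
#' @param model A \code{"potts_model"}.
#' @param seq Integer vector of length L with codes in 1..q.
#' @return Numeric scalar.
#' @export
evaluate_log_probability <- function(model, seq) {
  stopifnot(inherits(model, "potts_model"))
  if (length(seq) != model$L) {
    stop("sequence length ", length(seq), " does not match model L = ", model$L,
         call. = FALSE)
  }
  if (any(seq < 1L | seq > model$q)) stop("invalid state codes", call. = FALSE)
  idx <- (seq_len(model$L) - 1L) * model$q + seq
  # diagonal blocks are zero, J symmetric: sum over i<j = total/2
  sum(model$J[idx, idx]) / 2 + sum(model$h[cbind(seq_len(model$L), seq)])
}

#' Convert a Potts model to the zero-sum (Ising) gauge
#'
#' Re-parameterises couplings and fields so that every coupling block has
#' zero row and column means and every field row has zero mean, leaving all
#' Hamiltonian differences between sequences (hence the Boltzmann
#' distribution) unchanged. A fixed gauge makes the coupling-sum scores
#' C(S) and SF(S) well-defined absolute numbers.
#'
#' @param model A \code{"potts_model"} in any gauge.
#' @return A \code{"potts_model"} with \code{gauge = "zero_sum"}.
#' @export
to_zero_sum_gauge <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L; q <- model$q
  J <- model$J
  h <- model$h
  for (i in seq_len(L - 1L)) {
    ri <- ((i - 1L) * q + 1L):(i * q)
    for (j in (i + 1L):L) {
      rj <- ((j - 1L) * q + 1L):(j * q)
      B <- J[ri, rj]
      rm <- rowMeans(B); cm <- colMeans(B); mm <- mean(B)
      Bz <- B - outer(rm, rep(1, q)) - outer(rep(1, q), cm) + mm
      J[ri, rj] <- Bz
      J[rj, ri] <- t(Bz)
      # absorb the centred-out parts into the fields (constants dropped)
      h[i, ] <- h[i, ] + rm
      h[j, ] <- h[j, ] + cm
    }
  }
  h <- h - rowMeans(h)
  potts_model(J, h, gauge = "zero_sum", alphabet = model$alphabet)
}
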