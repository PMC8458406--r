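#' Pseudocount-regularised site and pair frequencies
#'
#' Computes weighted empirical single-site frequencies \eqn{f_i(A)} and pair
#' frequencies \eqn{f_{ij}(A,B)}, blended with a uniform prior controlled by
#' the relative pseudocount \eqn{\lambda}:
#' \deqn{f_i(A) = (1-\lambda)\,\hat f_i(A) + \lambda/q, \qquad
#'       f_{ij}(A,B) = (1-\lambda)\,\hat f_{ij}(A,B) + \lambda/q^2 \ (i \ne j).}
#' Diagonal blocks are \eqn{f_{ii}(A,B) = f_i(A)\,\delta_{AB}}, the convention
#' required by the mean-field inversion.
#'
#' @param aln A \code{\link{msa_alignment}}.
#' @param weights A \code{"seq_weights"} object from \code{\link{compute_weights}},
#'   or NULL for uniform weights.
#' @param pseudocount Relative pseudocount \eqn{\lambda} in [0, 1]. Default 0.5,
#'   the standard mean-field DCA choice.
#' @return Object of class \code{"freq_model"}: list with \code{fi} (L x q),
#'   \code{fij} ((L*q) x (L*q) block matrix, block (i,j) holding
#'   \eqn{f_{ij}(A,B)}), \code{pseudocount}, \code{L}, \code{q}.
#' @export
compute_frequencies <- function(aln, weights = NULL, pseudocount = 0.5) {
  stopifnot(inherits(aln, "msa_alignment"))
  if (!(pseudocount >= 0 && pseudocount <= 1)) {
    stop("pseudocount must lie in [0, 1]", call. = FALSE)
  }
  M <- nrow(aln$matrix); L <- aln$L; q <- aln$q
  w <- if (is.null(weights)) rep(1, M) else {
    stopifnot(inherits(weights, "seq_weights"))
    if (length(weights$w) != M) stop("weights do not match alignment rows", call. = FALSE)
    weights$w
  }
  w <- w / sum(w)
  lam <- pseudocount

  # one-hot encoding X: M x (L*q); column (i-1)*q + a indicates state a at site i
  X <- matrix(0, M, L * q)
  idx <- rep((seq_len(L) - 1L) * q, each = M) + as.vector(aln$matrix)
  X[cbind(rep(seq_len(M), times = L), idx)] <- 1

  fi_hat <- crossprod(X, w)                     # (L*q) x 1
  fi <- matrix((1 - lam) * fi_hat + lam / q, L, q, byrow = TRUE)

  sw <- sqrt(w)
  fij_hat <- crossprod(X * sw)                  # t(X) %*% diag(w) %*% X
  fij <- (1 - lam) * fij_hat + lam / q^2
  # diagonal blocks: f_ii(A,B) = f_i(A) * delta_AB
  for (i in seq_len(L)) {
    rows <- ((i - 1L) * q + 1L):(i * q)
    fij[rows, rows] <- diag(fi[i, ], q, q)
  }
  structure(list(fi = fi, fij = fij, pseudocount = lam, L = L, q = q),
            class = "freq_model")
}

#' Symmetric access to a pair-frequency block
#' @param freqs A \code{"freq_model"}.
#' @param i,j Column indices.
#' @return q x q matrix \eqn{f_{ij}(A,B)}.
#' @export
pair_frequency <- function(freqs, i, j) {
  q <- freqs$q
  freqs$fij[((i - 1L) * q + 1L):(i * q), ((j - 1L) * q + 1L):(j * q)]
}

#' @export
print.freq_model <- function(x, ...) {
  cat(sprintf("Frequency model: L = %d, q = %d, pseudocount = %.3f\n",
              x$L, x$q, x$pseudocount))
  invisible(x)
}
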