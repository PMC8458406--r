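#' Mean-field inversion of the Potts model
#'
#' Builds the connected-correlation matrix
#' \eqn{C_{(i,A),(j,B)} = f_{ij}(A,B) - f_i(A) f_j(B)} over q-1 states per
#' position (the gap state is dropped as reference, the standard mean-field
#' DCA convention), inverts it, and reads couplings off as
#' \eqn{e_{ij}(A,B) = -(C^{-1})_{(i,A),(j,B)}} for \eqn{i \ne j}. Fields are
#' recovered self-consistently in the reference-state gauge,
#' \eqn{h_i(A) = \log f_i(A)/f_i(q) - \sum_{j \ne i} \sum_B e_{ij}(A,B) f_j(B)},
#' and the whole model is then converted to the zero-sum gauge.
#'
#' @param freqs A \code{"freq_model"} from \code{\link{compute_frequencies}};
#'   its pseudocount must be positive so the correlation matrix is invertible.
#' @return A \code{"potts_model"} in zero-sum gauge.
#' @export
infer_mean_field <- function(freqs) {
  stopifnot(inherits(freqs, "freq_model"))
  L <- freqs$L; q <- freqs$q
  if (freqs$pseudocount <= 0) {
    stop("mean-field inversion needs pseudocount > 0 ",
         "(raise the pseudocount to regularise the correlation matrix)",
         call. = FALSE)
  }
  keep <- as.vector(outer(seq_len(q - 1L), (seq_len(L) - 1L) * q, `+`))
  fi_flat <- as.vector(t(freqs$fi))          # (L*q), position-major
  C <- freqs$fij[keep, keep] - tcrossprod(fi_flat[keep])
  invC <- tryCatch(solve(C), error = function(e) {
    stop("correlation matrix is singular; raise the pseudocount", call. = FALSE)
  })
  E <- matrix(0, L * q, L * q)
  E[keep, keep] <- -invC
  # zero out diagonal blocks (self-couplings are gauge artefacts)
  for (i in seq_len(L)) {
    rows <- ((i - 1L) * q + 1L):(i * q)
    E[rows, rows] <- 0
  }
  E <- (E + t(E)) / 2

  # fields in the reference-state gauge (gap state q as reference)
  h <- log(freqs$fi / freqs$fi[, q])
  for (i in seq_len(L)) {
    rows <- ((i - 1L) * q + 1L):(i * q)
    h[i, ] <- h[i, ] - E[rows, , drop = FALSE] %*% fi_flat
  }
  model <- potts_model(E, h, gauge = "reference_state")
  to_zero_sum_gauge(model)
}

#' Fit a mean-field DCA (Potts) model to a protein family alignment
#'
#' One-stop fitting front end: computes sequence weights, pseudocount
#' regularised frequencies, the mean-field coupling inversion, and the
#' zero-sum gauge conversion. This is the model behind the compatibility
#' score C(S) and structural fitness score SF(S) used to design hybrid
#' repressors.
#'
#' @param aln A \code{\link{msa_alignment}} (or a path to a FASTA file).
#' @param identity_threshold Reweighting identity threshold, default 0.8.
#' @param pseudocount Relative pseudocount lambda, default 0.5.
#' @param keep_frequencies Keep the full pair-frequency matrix in the fit
#'   object (needed by \code{\link{rank_pairs}}; ~\code{(Lq)^2} doubles).
#' @return Object of class \code{"mfdca_fit"} with elements \code{model}
#'   (zero-sum gauge \code{"potts_model"}), \code{weights}, \code{freqs},
#'   \code{Meff}, \code{aln_ids}, and the call.
#' @seealso \code{\link{rank_pairs}}, \code{\link{compatibility_score}},
#'   \code{\link{scan_single}}
#' @export
mfdca <- function(aln, identity_threshold = 0.8, pseudocount = 0.5,
                  keep_frequencies = TRUE) {
  if (is.character(aln)) aln <- read_alignment(aln, "fasta")
  stopifnot(inherits(aln, "msa_alignment"))
  w <- compute_weights(aln, identity_threshold)
  fr <- compute_frequencies(aln, w, pseudocount)
  model <- infer_mean_field(fr)
  if (!keep_frequencies) fr$fij <- NULL
  structure(list(model = model, weights = w, freqs = fr, Meff = w$Meff,
                 M = nrow(aln$matrix), aln_ids = aln$ids,
                 call = match.call()),
            class = "mfdca_fit")
}

#' @export
print.mfdca_fit <- function(x, ...) {
  cat("Mean-field DCA fit\n")
  cat(sprintf("  alignment: M = %d sequences, L = %d columns, q = %d\n",
              x$M, x$model$L, x$model$q))
  cat(sprintf("  effective sequences Meff = %.1f (identity threshold %.2f)\n",
              x$Meff, x$weights$identity_threshold))
  cat(sprintf("  pseudocount = %.2f, gauge = %s\n",
              x$freqs$pseudocount, x$model$gauge))
  invisible(x)
}

#' @export
summary.mfdca_fit <- function(object, n_top = 10L, ...) {
  fn <- .frobenius_scores(object$model)
  sc <- .apply_apc(fn)
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  ord <- order(sc[ut], -ut[, 1L], -ut[, 2L], decreasing = TRUE)
  top <- data.frame(i = ut[ord[seq_len(min(n_top, nrow(ut)))], 1L],
                    j = ut[ord[seq_len(min(n_top, nrow(ut)))], 2L],
                    score = sc[ut][ord[seq_len(min(n_top, nrow(ut)))]])
  out <- list(fit = object, top_pairs = top)
  class(out) <- "summary.mfdca_fit"
  out
}

#' @export
print.summary.mfdca_fit <- function(x, ...) {
  print(x$fit)
  cat("  strongest coevolving pairs (APC-corrected Frobenius norm):\n")
  print(x$top_pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn mfdca Extract fitted Potts parameters: a list with the
#'   coupling block matrix \code{J} and the field matrix \code{h}.
#' @param object,x An \code{"mfdca_fit"}.
#' @param ... Unused.
#' @export
coef.mfdca_fit <- function(object, ...) {
  list(J = object$model$J, h = object$model$h)
}

#' Score sequences under a fitted DCA model
#'
#' Returns the Potts Hamiltonian (log-probability up to the unknown
#' log-partition constant) of each sequence; differences between sequences
#' are gauge-invariant log-odds under the fitted family model.
#'
#' @param object An \code{"mfdca_fit"}.
#' @param newdata A \code{\link{msa_alignment}}, an integer matrix of encoded
#'   sequences (rows), or a single integer vector.
#' @param ... Unused.
#' @return Numeric vector of Hamiltonian values.
#' @export
predict.mfdca_fit <- function(object, newdata, ...) {
  mat <- if (inherits(newdata, "msa_alignment")) newdata$matrix
         else if (is.matrix(newdata)) newdata
         else matrix(as.integer(newdata), nrow = 1L)
  apply(mat, 1L, function(s) evaluate_log_probability(object$model, as.integer(s)))
}

#' Simulate alignments from a fitted DCA model
#'
#' Gibbs-samples sequences from the fitted Potts distribution (see
#' \code{\link{sample_potts}}).
#'
#' @param object An \code{"mfdca_fit"}.
#' @param nsim Number of sequences.
#' @param seed Random seed.
#' @param burn_in,thin Gibbs sweeps before the first kept sample and between
#'   kept samples.
#' @param ... Unused.
#' @return A \code{\link{msa_alignment}}.
#' @export
simulate.mfdca_fit <- function(object, nsim = 1L, seed = NULL,
                               burn_in = 1000L, thin = 10L, ...) {
  sample_potts(object$model, n = nsim, seed = seed,
               burn_in = burn_in, thin = thin)
}

#' Plot the coevolving-pair score map of a DCA fit
#'
#' Displays the APC-corrected Frobenius coupling strength for every column
#' pair as an image; strong off-diagonal entries are putative coevolving
#' (often contacting) pairs.
#'
#' @param x An \code{"mfdca_fit"}.
#' @param ... Passed to \code{graphics::image}.
#' @export
plot.mfdca_fit <- function(x, ...) {
  fn <- .apply_apc(.frobenius_scores(x$model))
  graphics::image(seq_len(x$model$L), seq_len(x$model$L), fn,
                  xlab = "alignment column", ylab = "alignment column",
                  main = "Coevolving pair strength (Frobenius, APC)", ...)
  invisible(x)
}
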