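#' Sequence reweighting and effective sequence count
#'
#' Down-weights redundant sequences: each sequence m receives weight
#' \eqn{w_m = 1 / |\{m' : \mathrm{identity}(m, m') \ge \theta\}|}, where the
#' neighbourhood includes m itself, and the effective number of sequences is
#' \eqn{M_{eff} = \sum_m w_m}. Identity is the fraction of matching columns
#' over all L columns; a shared gap counts as a match.
#'
#' @param aln A \code{\link{msa_alignment}}.
#' @param identity_threshold Fractional identity at or above which two
#'   sequences are pooled. Default 0.8, the standard mean-field DCA choice.
#' @return Object of class \code{"seq_weights"}: list with \code{w} (per
#'   sequence, in (0, 1]), \code{Meff}, \code{identity_threshold}.
#' @export
compute_weights <- function(aln, identity_threshold = 0.8) {
  stopifnot(inherits(aln, "msa_alignment"))
  if (!(identity_threshold > 0 && identity_threshold < 1)) {
    stop("identity_threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  if (nrow(aln$matrix) == 0L) stop("empty alignment", call. = FALSE)
  w <- .cpp_sequence_weights(aln$matrix, identity_threshold)
  structure(list(w = as.numeric(w), Meff = sum(w),
                 identity_threshold = identity_threshold),
            class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat(sprintf("Sequence weights: M = %d, Meff = %.2f (identity threshold %.2f)\n",
              length(x$w), x$Meff, x$identity_threshold))
  invisible(x)
}

#' Export sequence weights as a two-column TSV (id, weight)
#'
#' @param weights A \code{"seq_weights"} object.
#' @param aln The alignment the weights were computed from (for ids).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_weights <- function(weights, aln, path) {
  stopifnot(inherits(weights, "seq_weights"), inherits(aln, "msa_alignment"))
  utils::write.table(data.frame(id = aln$ids, weight = weights$w),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
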