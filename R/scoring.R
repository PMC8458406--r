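.assert_zero_sum <- function(model) {
  if (!inherits(model, "potts_model") || model$gauge != "zero_sum") {
    stop("scores are only defined in the zero-sum gauge; ",
         "call to_zero_sum_gauge() first", call. = FALSE)
  }
}

.seq_of <- function(x) {
  if (inherits(x, "hybrid_sequence")) x$seq else as.integer(x)
}

# sum of coupling entries e_ij(s_i, s_j) over a pair table
.coupling_sum <- function(seq, model, ii, jj) {
  if (length(ii) == 0L) return(0)
  q <- model$q
  sum(model$J[cbind((ii - 1L) * q + seq[ii], (jj - 1L) * q + seq[jj])])
}

#' Inter-module compatibility score C(S)
#'
#' \deqn{C(S) = -\sum_{(i,j) \in \mathrm{top\ pairs}} e_{ij}(A_i, A_j)}
#' summed over the top-ranked coevolving DBM x LBM pairs. A more negative
#' score than the original hybrid's indicates a more compatible DBM/LBM
#' combination. Couplings must be in zero-sum gauge so the absolute value is
#' well defined.
#'
#' @param seq Encoded sequence (or \code{"hybrid_sequence"}).
#' @param model A zero-sum-gauge \code{"potts_model"}.
#' @param top_pairs A \code{"pair_scores"} table (or two-column pair matrix);
#'   every pair must straddle the module boundary.
#' @param partition A \code{\link{module_partition}}.
#' @return Numeric scalar C(S).
#' @export
compatibility_score <- function(seq, model, top_pairs, partition) {
  .assert_zero_sum(model)
  stopifnot(inherits(partition, "module_partition"))
  s <- .seq_of(seq)
  if (length(s) != model$L) stop("sequence length mismatch", call. = FALSE)
  tp <- as.data.frame(top_pairs)
  in_dbm_i <- tp$i %in% partition$dbm_columns
  in_dbm_j <- tp$j %in% partition$dbm_columns
  if (any(in_dbm_i == in_dbm_j)) {
    stop("compatibility pairs must all be inter-module (one DBM, one LBM endpoint)",
         call. = FALSE)
  }
  -.coupling_sum(s, model, tp$i, tp$j)
}

#' Structural fitness score SF(S)
#'
#' \deqn{SF(S) = -\sum_{(i,j) \in \mathrm{contacts}} e_{ij}(A_i, A_j)}
#' summed over residue pairs in physical contact (< 10 Angstrom in the
#' reference crystal structure). Relative to the original hybrid, a less
#' negative score flags a mutation that disrupts intra-module coevolutionary
#' constraints; a more negative score suggests a structurally favorable
#' substitution.
#'
#' @param seq Encoded sequence (or \code{"hybrid_sequence"}).
#' @param model A zero-sum-gauge \code{"potts_model"}.
#' @param contacts A \code{\link{contact_map}}.
#' @return Numeric scalar SF(S).
#' @export
structural_fitness_score <- function(seq, model, contacts) {
  .assert_zero_sum(model)
  s <- .seq_of(seq)
  if (length(s) != model$L) stop("sequence length mismatch", call. = FALSE)
  cm <- as.data.frame(contacts)
  -.coupling_sum(s, model, cm$i, cm$j)
}

#' Score a mutant against its original hybrid
#'
#' Computes C(S) and SF(S) for both sequences and the deltas
#' (mutant - original); negative deltas are improvements.
#'
#' @param mutant,original Encoded sequences or \code{"hybrid_sequence"}s of
#'   equal length.
#' @param model Zero-sum-gauge \code{"potts_model"}.
#' @param top_pairs Ranked inter-module pairs (see
#'   \code{\link{compatibility_score}}).
#' @param contacts A \code{\link{contact_map}}.
#' @param partition A \code{\link{module_partition}}.
#' @return Object of class \code{"score_pair"}: list with \code{c_score},
#'   \code{sf_score}, \code{reference_c}, \code{reference_sf},
#'   \code{delta_c}, \code{delta_sf}.
#' @export
score_with_deltas <- function(mutant, original, model, top_pairs, contacts,
                              partition) {
  sm <- .seq_of(mutant); so <- .seq_of(original)
  if (length(sm) != length(so)) stop("mutant/original length mismatch", call. = FALSE)
  c_mut <- compatibility_score(sm, model, top_pairs, partition)
  c_ref <- compatibility_score(so, model, top_pairs, partition)
  sf_mut <- structural_fitness_score(sm, model, contacts)
  sf_ref <- structural_fitness_score(so, model, contacts)
  structure(list(c_score = c_mut, sf_score = sf_mut,
                 reference_c = c_ref, reference_sf = sf_ref,
                 delta_c = c_mut - c_ref, delta_sf = sf_mut - sf_ref),
            class = "score_pair")
}

#' @export
print.score_pair <- function(x, ...) {
  cat(sprintf("C(S) = %.4f (ref %.4f, dC = %+.4f)\nSF(S) = %.4f (ref %.4f, dSF = %+.4f)\n",
              x$c_score, x$reference_c, x$delta_c,
              x$sf_score, x$reference_sf, x$delta_sf))
  invisible(x)
}

#' Write scores as TSV rows
#' @param scores Data frame of score rows (e.g. a scan result).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
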