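#' Exclusion mask for the mutational scanner
#'
#' @param excluded_columns Integer MSA columns no mutation may touch.
#' @param reason One reason per column: \code{"dbm"}, \code{"ligand_pocket"}
#'   or \code{"user"} (recycled).
#' @return Object of class \code{"exclusion_mask"}.
#' @export
exclusion_mask <- function(excluded_columns = integer(0), reason = "user") {
  excluded_columns <- as.integer(excluded_columns)
  reason <- rep(match.arg(reason, c("dbm", "ligand_pocket", "user"), several.ok = TRUE),
                length.out = length(excluded_columns))
  keep <- !duplicated(excluded_columns)
  structure(list(excluded_columns = excluded_columns[keep], reason = reason[keep]),
            class = "exclusion_mask")
}

#' Combine masks / build the ligand-pocket exclusion mask
#'
#' The design loop never proposes DBM mutations (the module is small and
#' largely DNA-contacting), and can additionally prohibit mutations at
#' columns contacting the effector ligand.
#'
#' @param contacts_to_ligand Integer columns in direct ligand contact.
#' @param partition A \code{\link{module_partition}} (its DBM columns are
#'   always excluded).
#' @return An \code{\link{exclusion_mask}} covering DBM plus pocket columns.
#' @export
build_pocket_mask <- function(contacts_to_ligand = integer(0), partition) {
  stopifnot(inherits(partition, "module_partition"))
  cols <- c(partition$dbm_columns, as.integer(contacts_to_ligand))
  reasons <- c(rep("dbm", length(partition$dbm_columns)),
               rep("ligand_pocket", length(contacts_to_ligand)))
  keep <- !duplicated(cols)
  structure(list(excluded_columns = cols[keep], reason = reasons[keep]),
            class = "exclusion_mask")
}

# delta of SF(S) when columns `cols` change from states in `s` to `s_new`,
# exact: only contacts incident to a mutated column change their term.
.delta_score_pairs <- function(s, s_new_states, cols, model, ii, jj) {
  touched <- (ii %in% cols) | (jj %in% cols)
  if (!any(touched)) return(0)
  s2 <- s
  s2[cols] <- s_new_states
  before <- .coupling_sum(s, model, ii[touched], jj[touched])
  after <- .coupling_sum(s2, model, ii[touched], jj[touched])
  -(after - before)
}

.as_pair_cols <- function(tab) {
  tab <- as.data.frame(tab)
  list(i = as.integer(tab$i), j = as.integer(tab$j))
}

#' Single-mutation scan of a hybrid's ligand-binding module
#'
#' Proposes every substitution (19 non-gap, non-wild-type states) at every
#' non-excluded LBM column, scores each candidate's change in compatibility
#' \eqn{\Delta C} and structural fitness \eqn{\Delta SF} relative to the
#' input hybrid, and ranks candidates by ascending \eqn{\Delta C} (most
#' negative = most favorable). Columns whose wild type is a gap are skipped
#' (deletion design is out of scope).
#'
#' @param h A \code{"hybrid_sequence"} (or encoded sequence).
#' @param model Zero-sum-gauge \code{"potts_model"}.
#' @param top_pairs Ranked inter-module pairs (support of C(S)).
#' @param contacts A \code{\link{contact_map}} (support of SF(S)).
#' @param partition A \code{\link{module_partition}}.
#' @param mask An \code{\link{exclusion_mask}}; DBM columns are always
#'   excluded regardless of the mask.
#' @param numbering Optional \code{\link{numbering_map}} for reference-style
#'   labels (K57V); defaults to MSA-column labels.
#' @return Object of class \code{"scan_result"}: data.frame with columns
#'   \code{label}, \code{columns}, \code{delta_c}, \code{delta_sf},
#'   \code{c_score}, \code{sf_score}, \code{rank}; attributes
#'   \code{reference_c}, \code{reference_sf}, \code{k}.
#' @export
scan_single <- function(h, model, top_pairs, contacts, partition,
                        mask = exclusion_mask(), numbering = NULL) {
  .assert_zero_sum(model)
  stopifnot(inherits(partition, "module_partition"))
  s <- .seq_of(h)
  q <- model$q
  tp <- .as_pair_cols(top_pairs)
  cm <- .as_pair_cols(contacts)
  ref_c <- compatibility_score(s, model, top_pairs, partition)
  ref_sf <- structural_fitness_score(s, model, contacts)

  cand_cols <- setdiff(partition$lbm_columns, mask$excluded_columns)
  cand_cols <- cand_cols[s[cand_cols] != q]  # skip wild-type gaps
  if (length(cand_cols) == 0L) stop("no scannable LBM columns remain", call. = FALSE)

  rows <- vector("list", length(cand_cols) * (q - 2L))
  n <- 0L
  for (col in cand_cols) {
    wt <- s[col]
    for (a in setdiff(seq_len(q - 1L), wt)) {
      dc <- .delta_score_pairs(s, a, col, model, tp$i, tp$j)
      dsf <- .delta_score_pairs(s, a, col, model, cm$i, cm$j)
      lab <- if (is.null(numbering)) {
        paste0(decode_sequence(wt), col, decode_sequence(a))
      } else {
        mutation_to_label(mutation(col, wt, a), numbering)
      }
      n <- n + 1L
      rows[[n]] <- data.frame(label = lab, columns = col,
                              delta_c = dc, delta_sf = dsf,
                              c_score = ref_c + dc, sf_score = ref_sf + dsf)
    }
  }
  out <- do.call(rbind, rows[seq_len(n)])
  .finish_scan(out, ref_c, ref_sf, k = 1L)
}

.finish_scan <- function(out, ref_c, ref_sf, k) {
  ord <- order(out$delta_c, out$label)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, reference_c = ref_c, reference_sf = ref_sf, k = k,
            class = c("scan_result", "data.frame"))
}

#' @export
print.scan_result <- function(x, n = 10L, ...) {
  cat(sprintf("Mutational scan (%d-mutation sets): %d candidates, reference C = %.4f, SF = %.4f\n",
              attr(x, "k"), nrow(x), attr(x, "reference_c"), attr(x, "reference_sf")))
  print(utils::head(as.data.frame(x), n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Multi-mutation scan built from top single mutations
#'
#' Builds candidate k-sets (k = 2 or 3) from the top \code{beam} single
#' mutations at pairwise-distinct columns. Because C(S) contains only
#' DBM x LBM coupling terms, \eqn{\Delta C} of a set of LBM mutations is
#' exactly the sum of its singles' \eqn{\Delta C}; \eqn{\Delta SF} is
#' recomputed exactly on the mutated sequence, since mutations at mutually
#' contacting columns interact.
#'
#' @inheritParams scan_single
#' @param k Number of simultaneous mutations, 2 or 3.
#' @param beam How many top single mutations to combine (default 50).
#' @return A \code{"scan_result"} whose \code{label} joins the single labels
#'   with \code{"/"} and whose \code{columns} lists the mutated columns.
#' @export
scan_multi <- function(h, k, model, top_pairs, contacts, partition,
                       mask = exclusion_mask(), beam = 50L, numbering = NULL) {
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3", call. = FALSE)
  if (beam < k) stop("beam must be at least k", call. = FALSE)
  singles <- scan_single(h, model, top_pairs, contacts, partition, mask, numbering)
  top <- utils::head(as.data.frame(singles), beam)
  if (length(unique(top$columns)) < k) {
    stop("fewer than k distinct columns among the beam singles", call. = FALSE)
  }
  s <- .seq_of(h)
  cm <- .as_pair_cols(contacts)
  ref_c <- attr(singles, "reference_c")
  ref_sf <- attr(singles, "reference_sf")
  muts_state <- encode_sequence(substr(top$label, nchar(top$label), nchar(top$label)))

  combs <- utils::combn(nrow(top), k)
  keep <- apply(combs, 2L, function(ix) length(unique(top$columns[ix])) == k)
  combs <- combs[, keep, drop = FALSE]
  nres <- ncol(combs)
  lab <- character(nres); colstr <- character(nres)
  dc <- numeric(nres); dsf <- numeric(nres)
  for (t in seq_len(nres)) {
    ix <- combs[, t]
    ix <- ix[order(top$columns[ix])]
    cols <- top$columns[ix]
    dc[t] <- sum(top$delta_c[ix])          # exact: C has only DBM x LBM terms
    dsf[t] <- .delta_score_pairs(s, muts_state[ix], cols, model, cm$i, cm$j)
    lab[t] <- paste(top$label[ix], collapse = "/")
    colstr[t] <- paste(cols, collapse = ",")
  }
  out <- data.frame(label = lab, columns = colstr, delta_c = dc, delta_sf = dsf,
                    c_score = ref_c + dc, sf_score = ref_sf + dsf)
  .finish_scan(out, ref_c, ref_sf, k = k)
}

#' Filter scan candidates by the structural-fitness rule
#'
#' Implements the gray-region rule: keep only candidates whose SF(S) is at
#' least as favorable (i.e. \code{sf_score <= reference_sf}) as the original
#' hybrid's, then truncate to the best \code{top_n} by \eqn{\Delta C}.
#'
#' @param scan A \code{"scan_result"}.
#' @param reference_sf SF(S) of the original hybrid (default: taken from the
#'   scan's attribute).
#' @param require_sf_improvement Apply the SF filter (default TRUE).
#' @param top_n Keep at most this many candidates (default all).
#' @return A filtered, re-ranked \code{"scan_result"} (may be empty, with a
#'   warning).
#' @export
select_candidates <- function(scan, reference_sf = attr(scan, "reference_sf"),
                              require_sf_improvement = TRUE, top_n = Inf) {
  stopifnot(inherits(scan, "scan_result"))
  out <- as.data.frame(scan)
  if (require_sf_improvement) out <- out[out$sf_score <= reference_sf, , drop = FALSE]
  if (nrow(out) == 0L) warning("no candidates satisfy the SF filter")
  out <- utils::head(out[order(out$delta_c, out$label), , drop = FALSE],
                     if (is.finite(top_n)) top_n else nrow(out))
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, reference_c = attr(scan, "reference_c"),
            reference_sf = attr(scan, "reference_sf"), k = attr(scan, "k"),
            class = c("scan_result", "data.frame"))
}

#' Shortlist two triple mutants sharing a double prefix
#'
#' Convenience report mirroring the design practice of carrying two
#' triple-mutation candidates that share two of their three mutations: the
#' best triple, plus the best other triple sharing exactly two singles with
#' it.
#'
#' @param triples A k = 3 \code{"scan_result"} from \code{\link{scan_multi}}.
#' @return A two-row (or one-row, if no partner exists) \code{"scan_result"}.
#' @export
shortlist_triples <- function(triples) {
  stopifnot(inherits(triples, "scan_result"), attr(triples, "k") == 3L)
  df <- as.data.frame(triples)
  if (nrow(df) == 0L) return(triples)
  parts <- strsplit(df$label, "/", fixed = TRUE)
  first <- parts[[1L]]
  partner <- which(vapply(parts, function(p) length(intersect(p, first)) == 2L,
                          TRUE))
  pick <- c(1L, partner[1L])
  pick <- pick[!is.na(pick)]
  out <- df[pick, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, reference_c = attr(triples, "reference_c"),
            reference_sf = attr(triples, "reference_sf"), k = 3L,
            class = c("scan_result", "data.frame"))
}
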