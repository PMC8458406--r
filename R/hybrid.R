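#' Define the DBM/LBM module partition of the alignment columns
#'
#' LacI-family repressors split into a small N-terminal DNA-binding module
#' (DBM, roughly the first 47 residues: helix-turn-helix plus the start of
#' the hinge) and the C-terminal ligand-binding module (LBM) that carries the
#' effector pocket and drives the allosteric response. The partition is given
#' in MSA column coordinates and must cover every column exactly once.
#'
#' @param dbm_columns Integer vector of DBM columns.
#' @param L Total number of alignment columns; LBM = complement of DBM.
#' @param lbm_columns Optionally the LBM columns explicitly (must then be the
#'   exact complement of \code{dbm_columns} in 1..L).
#' @return Object of class \code{"module_partition"} with sorted
#'   \code{dbm_columns}, \code{lbm_columns}, \code{L}.
#' @export
module_partition <- function(dbm_columns, L, lbm_columns = NULL) {
  dbm_columns <- sort(unique(as.integer(dbm_columns)))
  if (is.null(lbm_columns)) {
    lbm_columns <- setdiff(seq_len(L), dbm_columns)
  } else {
    lbm_columns <- sort(unique(as.integer(lbm_columns)))
  }
  if (length(intersect(dbm_columns, lbm_columns)) > 0L) {
    stop("DBM and LBM columns must be disjoint", call. = FALSE)
  }
  if (!setequal(c(dbm_columns, lbm_columns), seq_len(L))) {
    stop("partition must cover all ", L, " columns exactly once", call. = FALSE)
  }
  structure(list(dbm_columns = dbm_columns, lbm_columns = lbm_columns, L = L),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d DBM + %d LBM columns (L = %d)\n",
              length(x$dbm_columns), length(x$lbm_columns), x$L))
  invisible(x)
}

#' Assemble a hybrid (chimeric) repressor sequence
#'
#' Takes the DBM columns from one parent and the LBM columns from another,
#' mirroring the experimental module-swapping strategy (hybrids are named
#' DBM-LBM, e.g. LacI-RbsR = LacI DBM + RbsR LBM).
#'
#' @param dbm_parent_seq,lbm_parent_seq Encoded integer sequences of length L.
#' @param partition A \code{\link{module_partition}}.
#' @param dbm_parent,lbm_parent Optional parent identifiers for bookkeeping.
#' @return Object of class \code{"hybrid_sequence"}: list with \code{seq},
#'   \code{dbm_parent}, \code{lbm_parent}, \code{mutations} (empty list).
#' @export
build_hybrid <- function(dbm_parent_seq, lbm_parent_seq, partition,
                         dbm_parent = "dbm_parent", lbm_parent = "lbm_parent") {
  stopifnot(inherits(partition, "module_partition"))
  L <- partition$L
  if (length(dbm_parent_seq) != L || length(lbm_parent_seq) != L) {
    stop("parent sequences must have length L = ", L, call. = FALSE)
  }
  s <- integer(L)
  s[partition$dbm_columns] <- as.integer(dbm_parent_seq[partition$dbm_columns])
  s[partition$lbm_columns] <- as.integer(lbm_parent_seq[partition$lbm_columns])
  structure(list(seq = s, dbm_parent = dbm_parent, lbm_parent = lbm_parent,
                 mutations = list()),
            class = "hybrid_sequence")
}

#' @export
print.hybrid_sequence <- function(x, ...) {
  labs <- vapply(x$mutations, `[[`, "", "label")
  cat(sprintf("Hybrid sequence %s-%s (L = %d)%s\n", x$dbm_parent, x$lbm_parent,
              length(x$seq),
              if (length(labs)) paste0(", mutations: ", paste(labs, collapse = "/"))
              else ""))
  invisible(x)
}

#' Construct a point mutation
#'
#' @param column 1-based MSA column.
#' @param wild_type,mutant Integer state codes (mutant may not be the gap).
#' @param label Human-readable label, e.g. \code{"K57V"} in reference-protein
#'   numbering.
#' @return Object of class \code{"mutation"}.
#' @export
mutation <- function(column, wild_type, mutant, label = NULL) {
  column <- as.integer(column); wild_type <- as.integer(wild_type)
  mutant <- as.integer(mutant)
  if (wild_type == mutant) stop("mutation must change the state", call. = FALSE)
  if (mutant == aa_nstates()) stop("gap is not a proposable mutant state", call. = FALSE)
  if (is.null(label)) {
    label <- paste0(decode_sequence(wild_type), column, decode_sequence(mutant))
  }
  structure(list(column = column, wild_type = wild_type, mutant = mutant,
                 label = label),
            class = "mutation")
}

#' Apply point mutations to a hybrid sequence
#'
#' Each mutation's stated wild type must match the current residue at its
#' column (a mismatch signals stale numbering) and mutated columns must be
#' pairwise distinct.
#'
#' @param h A \code{"hybrid_sequence"}.
#' @param muts List of \code{\link{mutation}} objects (or a single one).
#' @return The mutated \code{"hybrid_sequence"}; mutation list appended.
#' @export
apply_mutations <- function(h, muts) {
  stopifnot(inherits(h, "hybrid_sequence"))
  if (inherits(muts, "mutation")) muts <- list(muts)
  if (length(muts) == 0L) return(h)
  cols <- vapply(muts, `[[`, 0L, "column")
  if (anyDuplicated(cols)) stop("duplicate mutated column", call. = FALSE)
  for (m in muts) {
    cur <- h$seq[m$column]
    if (cur != m$wild_type) {
      stop(sprintf("wild-type mismatch at column %d: sequence has %s, mutation %s expects %s",
                   m$column, decode_sequence(cur), m$label,
                   decode_sequence(m$wild_type)), call. = FALSE)
    }
    h$seq[m$column] <- m$mutant
  }
  h$mutations <- c(h$mutations, muts)
  h
}

#' Build a reference-numbering map
#'
#' Maps reference-protein residue numbers (e.g. LacI numbering used in
#' labels like K57V) to MSA columns: column c of the alignment row is
#' assigned the next residue number whenever the row is non-gap there.
#'
#' @param aln_row Encoded sequence (the reference protein's alignment row).
#' @param first_residue Residue number of the first non-gap position.
#' @return Named integer vector: names are residue numbers, values columns.
#' @export
numbering_map <- function(aln_row, first_residue = 1L) {
  nongap <- which(aln_row != aa_nstates())
  stats::setNames(nongap, seq_along(nongap) + first_residue - 1L)
}

#' Parse a mutation label against a numbering map and sequence
#'
#' Resolves labels like \code{"K57A"}: residue 57 of the reference numbering
#' is looked up in \code{numbering} to find the MSA column, and the stated
#' wild-type letter is validated against \code{aln_row} at that column.
#'
#' @param label String of the form \code{<aa><number><aa>}.
#' @param numbering Named integer vector from \code{\link{numbering_map}}.
#' @param aln_row Encoded sequence the wild type is checked against.
#' @return A \code{\link{mutation}}.
#' @export
label_to_mutation <- function(label, numbering, aln_row) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", label))[[1L]]
  if (length(m) != 4L) stop("malformed mutation label: ", label, call. = FALSE)
  pos <- m[3L]
  if (!pos %in% names(numbering)) {
    stop("residue ", pos, " not present in the numbering map", call. = FALSE)
  }
  col <- numbering[[pos]]
  wt <- encode_sequence(m[2L]); mut <- encode_sequence(m[4L])
  if (aln_row[col] != wt) {
    stop(sprintf("wild-type mismatch for %s: sequence has %s at column %d",
                 label, decode_sequence(aln_row[col]), col), call. = FALSE)
  }
  mutation(col, wt, mut, label = toupper(label))
}

#' Format a mutation back into reference numbering
#' @param mut A \code{\link{mutation}}.
#' @param numbering Named integer vector from \code{\link{numbering_map}}.
#' @return Label string such as \code{"K57A"}.
#' @export
mutation_to_label <- function(mut, numbering) {
  hit <- names(numbering)[match(mut$column, numbering)]
  if (is.na(hit)) stop("column ", mut$column, " has no reference number", call. = FALSE)
  paste0(decode_sequence(mut$wild_type), hit, decode_sequence(mut$mutant))
}
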