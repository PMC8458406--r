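#' Parse the protein residues of one chain from a PDB file
#'
#' Reads ATOM records of the requested chain via \pkg{bio3d}, drops HETATM
#' records (waters and ligands), keeps standard amino-acid residues only, and
#' resolves alternate locations by highest occupancy (first listed on ties).
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; default NULL picks the first protein chain.
#' @return Object of class \code{"residue_coords"}: a data.frame of atoms
#'   (\code{chain}, \code{resno}, \code{resid}, \code{elety}, \code{x},
#'   \code{y}, \code{z}) plus attributes \code{resno} (ordered unique residue
#'   numbers) and \code{sequence} (one-letter residue sequence).
#' @export
parse_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% rownames(bio3d::aa.table), , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard protein residues in file", call. = FALSE)
  if (is.null(chain)) chain <- at$chain[[1L]]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found", call. = FALSE)

  # altloc: per (resno, atom name) keep highest occupancy, then first listed
  at$o[is.na(at$o)] <- 1
  key <- paste(at$resno, at$elety)
  ord <- order(key, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$elety)), , drop = FALSE]
  at <- at[order(at$resno), , drop = FALSE]

  resno <- unique(at$resno)
  res3 <- at$resid[match(resno, at$resno)]
  seq1 <- bio3d::aa321(res3)
  out <- at[, c("chain", "resno", "resid", "elety", "x", "y", "z")]
  rownames(out) <- NULL
  structure(out, resno = resno, sequence = seq1, class = c("residue_coords", "data.frame"))
}

#' Explicit structure-residue to MSA-column mapping
#'
#' @param resno Structure residue numbers.
#' @param column Matching MSA columns (same length).
#' @return Object of class \code{"column_mapping"}: data.frame
#'   (\code{resno}, \code{column}), injective both ways.
#' @export
column_mapping <- function(resno, column) {
  resno <- as.integer(resno); column <- as.integer(column)
  if (length(resno) != length(column)) stop("lengths differ", call. = FALSE)
  if (anyDuplicated(resno) || anyDuplicated(column)) {
    stop("mapping must be injective in both directions", call. = FALSE)
  }
  structure(data.frame(resno = resno, column = column),
            class = c("column_mapping", "data.frame"))
}

#' Map structure residues onto MSA columns by sequence alignment
#'
#' Aligns the chain's one-letter sequence against the ungapped sequence of a
#' named MSA row (global alignment, BLOSUM62 via \pkg{Biostrings}) and
#' propagates the row's residue-to-column correspondence. Avoids silent
#' misnumbering when the crystal construct and the alignment row differ at
#' termini or loops.
#'
#' @param coords A \code{"residue_coords"} from \code{\link{parse_structure}}.
#' @param aln A \code{\link{msa_alignment}}.
#' @param row_id Identifier of the MSA row corresponding to the structure.
#' @return A \code{\link{column_mapping}}.
#' @export
map_structure_columns <- function(coords, aln, row_id) {
  stopifnot(inherits(coords, "residue_coords"), inherits(aln, "msa_alignment"))
  ridx <- match(row_id, aln$ids)
  if (is.na(ridx)) stop("row '", row_id, "' not in alignment", call. = FALSE)
  row <- aln$matrix[ridx, ]
  nongap_cols <- which(row != aa_nstates())
  row_seq <- paste(decode_sequence(row[nongap_cols]), collapse = "")
  str_seq <- paste(attr(coords, "sequence"), collapse = "")
  pa <- Biostrings::pairwiseAlignment(str_seq, row_seq, type = "global",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  p_chr <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s_chr <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  pi <- 0L; si <- 0L
  res_out <- integer(0); col_out <- integer(0)
  for (k in seq_along(p_chr)) {
    if (p_chr[k] != "-") pi <- pi + 1L
    if (s_chr[k] != "-") si <- si + 1L
    if (p_chr[k] != "-" && s_chr[k] != "-" && p_chr[k] == s_chr[k]) {
      res_out <- c(res_out, attr(coords, "resno")[pi])
      col_out <- c(col_out, nongap_cols[si])
    }
  }
  if (length(res_out) == 0L) stop("no residues could be mapped", call. = FALSE)
  column_mapping(res_out, col_out)
}

#' Construct a contact map directly from column pairs
#'
#' @param pairs Two-column matrix/data.frame of MSA column pairs.
#' @param cutoff Distance cutoff in Angstrom the map is declared at.
#' @param distance Optional per-pair distances.
#' @param atom_rule,sequence_separation_min Provenance metadata.
#' @return Object of class \code{"contact_map"}: data.frame (\code{i},
#'   \code{j}, \code{distance}) with i < j, no self-pairs; attributes
#'   \code{cutoff}, \code{atom_rule}, \code{sequence_separation_min}.
#' @export
contact_map <- function(pairs, cutoff = 10,
                        distance = NULL,
                        atom_rule = "min_heavy_atom",
                        sequence_separation_min = 1L) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) {
    df <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  } else {
    i <- pmin(pairs[, 1L], pairs[, 2L]); j <- pmax(pairs[, 1L], pairs[, 2L])
    if (any(i == j)) stop("contact map cannot contain self-pairs", call. = FALSE)
    if (is.null(distance)) distance <- rep(NA_real_, length(i))
    keep <- !duplicated(cbind(i, j))
    df <- data.frame(i = as.integer(i[keep]), j = as.integer(j[keep]),
                     distance = distance[keep])
    df <- df[order(df$i, df$j), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, cutoff = cutoff, atom_rule = atom_rule,
            sequence_separation_min = as.integer(sequence_separation_min),
            class = c("contact_map", "data.frame"))
}

#' Extract residue-residue contacts from a structure
#'
#' A pair of MSA columns {i, j} is a contact iff both residues appear in the
#' mapping, their structure-position separation is at least
#' \code{sequence_separation_min}, and the inter-residue distance under the
#' atom rule is strictly below \code{cutoff}. The default rule,
#' \code{min_heavy_atom}, is the minimum over all heavy-atom pairs;
#' \code{c_alpha} and \code{c_beta} use single atoms (CB falls back to CA for
#' glycine).
#'
#' @param coords A \code{"residue_coords"}.
#' @param mapping A \code{\link{column_mapping}}.
#' @param cutoff Distance cutoff in Angstrom (default 10, the published
#'   contact rule for the LacI reference structure).
#' @param atom_rule One of \code{"min_heavy_atom"}, \code{"c_alpha"},
#'   \code{"c_beta"}.
#' @param sequence_separation_min Minimum |resno_i - resno_j| (default 1:
#'   self excluded, adjacent residues kept).
#' @param exclude_pairs Optional two-column matrix of MSA column pairs to
#'   drop (e.g. pairs spanning the module boundary).
#' @return A \code{\link{contact_map}} in MSA column coordinates.
#' @export
extract_contacts <- function(coords, mapping, cutoff = 10,
                             atom_rule = c("min_heavy_atom", "c_alpha", "c_beta"),
                             sequence_separation_min = 1L,
                             exclude_pairs = NULL) {
  atom_rule <- match.arg(atom_rule)
  stopifnot(inherits(coords, "residue_coords"), inherits(mapping, "column_mapping"))
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (nrow(mapping) == 0L) stop("empty structure-to-column mapping", call. = FALSE)

  at <- as.data.frame(coords)
  at <- at[at$resno %in% mapping$resno, , drop = FALSE]
  # hydrogens excluded under every rule
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  if (atom_rule == "c_alpha") {
    at <- at[at$elety == "CA", , drop = FALSE]
  } else if (atom_rule == "c_beta") {
    has_cb <- unique(at$resno[at$elety == "CB"])
    at <- at[(at$elety == "CB") | (at$elety == "CA" & !(at$resno %in% has_cb)), ,
             drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no atoms left under rule ", atom_rule, call. = FALSE)

  xyz <- as.matrix(at[, c("x", "y", "z")])
  d_at <- as.matrix(stats::dist(xyz))
  res <- at$resno
  resno_u <- sort(unique(res))
  n <- length(resno_u)
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  for (a in seq_len(n - 1L)) {
    ra <- which(res == resno_u[a])
    for (b in (a + 1L):n) {
      if (abs(resno_u[b] - resno_u[a]) < sequence_separation_min) next
      dmin <- min(d_at[ra, which(res == resno_u[b]), drop = FALSE])
      if (dmin < cutoff) {
        ii <- c(ii, resno_u[a]); jj <- c(jj, resno_u[b]); dd <- c(dd, dmin)
      }
    }
  }
  ci <- mapping$column[match(ii, mapping$resno)]
  cj <- mapping$column[match(jj, mapping$resno)]
  cm <- contact_map(cbind(ci, cj), cutoff = cutoff, distance = dd,
                    atom_rule = atom_rule,
                    sequence_separation_min = sequence_separation_min)
  if (!is.null(exclude_pairs) && nrow(cm) > 0L) {
    ex <- as.matrix(exclude_pairs)
    exk <- paste(pmin(ex[, 1L], ex[, 2L]), pmax(ex[, 1L], ex[, 2L]))
    keep <- !(paste(cm$i, cm$j) %in% exk)
    cm <- contact_map(cbind(cm$i, cm$j)[keep, , drop = FALSE],
                      cutoff = cutoff, distance = cm$distance[keep],
                      atom_rule = atom_rule,
                      sequence_separation_min = sequence_separation_min)
  }
  cm
}

#' Write a contact map as TSV (1-based MSA columns: i, j, distance)
#' @param contacts A \code{\link{contact_map}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(as.data.frame(contacts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
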