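#' Amino-acid alphabet used throughout the package
#'
#' Twenty standard amino acids followed by the gap symbol, so the Potts state
#' space has q = 21 with the gap as the last (21st) state. Ambiguous or
#' non-standard residue letters (X, B, Z, J, U, O) and both gap glyphs
#' (\code{-} and \code{.}) are mapped to the gap state, keeping q fixed at 21
#' as is standard in direct coupling analysis.
#'
#' @return Character vector of length 21; the gap symbol \code{"-"} is last.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' Number of Potts states (20 amino acids + gap)
#' @return Integer, 21.
#' @export
aa_nstates <- function() 21L

.aa_code_table <- function() {
  ab <- aa_alphabet()
  code <- stats::setNames(seq_along(ab), ab)
  # everything unknown collapses onto the gap state
  extra <- stats::setNames(rep(code[["-"]], 8L),
                           c("X", "B", "Z", "J", "U", "O", ".", "*"))
  c(code, extra)
}

#' Encode amino-acid letters as integer Potts states
#'
#' @param letters Character vector of single letters (any case).
#' @return Integer vector of codes in 1..21 (21 = gap).
#' @export
encode_sequence <- function(letters) {
  tab <- .aa_code_table()
  up <- toupper(letters)
  codes <- tab[up]
  codes[is.na(codes)] <- tab[["-"]]
  as.integer(codes)
}

#' Decode integer Potts states back to letters
#' @param codes Integer vector in 1..21.
#' @return Character vector of letters.
#' @export
decode_sequence <- function(codes) {
  stopifnot(all(codes >= 1L & codes <= aa_nstates()))
  aa_alphabet()[codes]
}

#' Construct an encoded alignment object
#'
#' @param mat Integer matrix, M sequences x L columns, codes in 1..21.
#' @param ids Character vector of M unique sequence identifiers.
#' @return An object of class \code{"msa_alignment"} with fields
#'   \code{matrix}, \code{ids}, \code{L}, \code{q}, \code{alphabet}.
#' @export
msa_alignment <- function(mat, ids = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (nrow(mat) == 0L) stop("empty alignment: no sequences", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  if (length(ids) != nrow(mat)) stop("ids length must match row count", call. = FALSE)
  if (any(mat < 1L | mat > aa_nstates())) {
    stop("alignment codes must lie in 1..", aa_nstates(), call. = FALSE)
  }
  structure(list(matrix = mat, ids = as.character(ids),
                 L = ncol(mat), q = aa_nstates(), alphabet = aa_alphabet()),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("Encoded protein alignment: %d sequences x %d columns (q = %d)\n",
              nrow(x$matrix), x$L, x$q))
  invisible(x)
}

#' @export
dim.msa_alignment <- function(x) dim(x$matrix)

#' Read a protein family alignment
#'
#' Reads FASTA (via Biostrings) or Stockholm format, upper-cases residues,
#' collapses \code{.}/\code{-} and non-standard letters onto the single gap
#' state, and integer-encodes the result.
#'
#' @param path Path to the alignment file.
#' @param format \code{"fasta"} or \code{"stockholm"}.
#' @return A \code{\link{msa_alignment}} object.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(recs))
    seqs <- as.character(recs)
  } else {
    parsed <- .read_stockholm(path)
    ids <- parsed$ids
    seqs <- parsed$seqs
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment records have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  L <- lens[[1L]]
  if (L == 0L) stop("alignment has zero columns", call. = FALSE)
  mat <- matrix(encode_sequence(unlist(strsplit(seqs, "", fixed = TRUE))),
                nrow = length(seqs), ncol = L, byrow = TRUE)
  msa_alignment(mat, ids)
}

# Minimal Stockholm 1.0 reader: sequence lines only, wrapped blocks
# concatenated per id; markup (#=) and terminator (//) ignored.
.read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  seq_lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//")]
  if (length(seq_lines) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  parts <- regmatches(seq_lines, regexpr("^\\S+", seq_lines))
  body <- trimws(sub("^\\S+\\s+", "", seq_lines))
  if (any(!nzchar(body))) stop("malformed Stockholm sequence line", call. = FALSE)
  ids <- unique(parts)
  seqs <- vapply(ids, function(id) paste(body[parts == id], collapse = ""), "")
  list(ids = ids, seqs = unname(seqs))
}

#' Write an alignment as FASTA
#'
#' @param aln A \code{\link{msa_alignment}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "msa_alignment"))
  seqs <- apply(aln$matrix, 1L, function(r) paste(decode_sequence(r), collapse = ""))
  writeLines(paste0(">", aln$ids, "\n", seqs), path)
  invisible(path)
}
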