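#' Construct a plastome alignment
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (alphabet \code{A,C,G,T,N,-}; case-insensitive), or a
#'   \code{\link[Biostrings]{DNAStringSet}}.
#' @param reference name of the reference taxon; defaults to the first row.
#' @return a \code{\linkS4class{PlastomeAlignment}}.
#' @examples
#' aln <- PlastomeAlignment(c(ref = "ACGT-A", alt = "ACTTCA"))
#' referencePositions(aln)
#' @export
PlastomeAlignment <- function(seqs, reference = NULL) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  seqs <- toupper(unlist(seqs))
  if (is.null(reference)) reference <- names(seqs)[1L]
  methods::new("PlastomeAlignment", seqs = seqs, reference = reference)
}

#' Read a gapped FASTA alignment
#'
#' @param file path to an aligned FASTA file (gap character \code{-}).
#' @param reference reference taxon name (default: first record).
#' @return a \code{\linkS4class{PlastomeAlignment}}.
#' @export
readPlastomeAlignment <- function(file, reference = NULL) {
  PlastomeAlignment(readDNAStringSet(file), reference = reference)
}

#' Write an alignment as gapped FASTA
#'
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @param file output path.
#' @export
writePlastomeAlignment <- function(aln, file) {
  writeXStringSet(DNAStringSet(aln@seqs), file)
  invisible(file)
}

#' Alignment as a character matrix (taxa x columns)
#'
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @return character matrix with taxon rownames.
#' @export
alignmentMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln@seqs, "", fixed = TRUE))
  rownames(m) <- names(aln@seqs)
  m
}

#' Reference taxon of an alignment
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @export
referenceTaxon <- function(aln) aln@reference

#' Map alignment columns to 1-based reference positions
#'
#' Non-gap columns of the reference row receive their ungapped 1-based
#' position; columns where the reference is gapped (insertions relative to
#' the reference) receive the position of the preceding reference base
#' (0 before the first), so insertion events anchor to the reference base
#' they follow.
#'
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @return list with \code{position} (integer per column) and \code{is_ref}
#'   (logical: TRUE where the reference row is ungapped).
#' @export
referencePositions <- function(aln) {
  ref <- strsplit(aln@seqs[[aln@reference]], "", fixed = TRUE)[[1L]]
  is_ref <- ref != "-"
  list(position = cumsum(is_ref), is_ref = is_ref)
}

#' Ungapped sequence of one taxon
#' @param aln a \code{\linkS4class{PlastomeAlignment}}.
#' @param taxon taxon name; defaults to the reference.
#' @export
ungappedSequence <- function(aln, taxon = referenceTaxon(aln)) {
  if (!taxon %in% names(aln@seqs)) stop("unknown taxon: ", taxon)
  gsub("-", "", aln@seqs[[taxon]], fixed = TRUE)
}
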