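# CircularGenome constructor, accessors and circular coordinate
# arithmetic.  All coordinates are 1-based inclusive on the H strand.

#' Create a CircularGenome
#'
#' @param id accession string.
#' @param seq H-strand sequence (A/C/G/T/N), or `NULL` for
#'   feature-table-only mode.
#' @param length declared molecule length; defaults to `nchar(seq)`.
#' @param circular logical topology flag.
#' @return a [CircularGenome-class] object.
#' @examples
#' circularGenome("toy", "ACGTACGT")
#' circularGenome("tableonly", length = 16815)
#' @export
circularGenome <- function(id, seq = NULL, length = NULL, circular = TRUE) {
  if (is.null(seq) && is.null(length))
    .stopf("need a sequence or a declared length")
  seq <- if (is.null(seq)) character(0) else toupper(as.character(seq))
  if (is.null(length)) length <- nchar(seq)
  new("CircularGenome", id = as.character(id), seq = seq,
      length = as.integer(length), circular = isTRUE(circular))
}

#' @describeIn circularGenome accession id.
#' @param x a CircularGenome.
#' @export
genomeID <- function(x) x@id

#' @describeIn circularGenome declared length in bp.
#' @export
genomeLength <- function(x) x@length

#' @describeIn circularGenome H-strand sequence (errors in
#'   feature-table-only mode).
#' @export
genomeSeq <- function(x) {
  if (!hasSequence(x))
    .stopf("genome '%s' is in feature-table-only mode: no sequence available",
           x@id)
  x@seq
}

#' @describeIn circularGenome TRUE when a sequence is present.
#' @export
hasSequence <- function(x) length(x@seq) == 1L

#' @describeIn circularGenome circular-topology flag.
#' @export
isCircular <- function(x) x@circular

#' Extract a (possibly origin-crossing) span of a circular genome
#'
#' When `start > end` and the genome is circular the span wraps through
#' the origin.  `strand = "L"` returns the reverse complement (the
#' light-strand reading).
#'
#' @param genome a [CircularGenome-class] with sequence.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"H"` or `"L"`.
#' @return character; the requested subsequence.
#' @export
genomeSpan <- function(genome, start, end, strand = "H") {
  s <- genomeSeq(genome)
  n <- genomeLength(genome)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < 1L || start > n || end > n)
    .stopf("span %d-%d outside genome [1, %d]", start, end, n)
  if (start <= end) {
    out <- substr(s, start, end)
  } else {
    if (!isCircular(genome))
      .stopf("span %d-%d wraps the origin but genome is not circular",
             start, end)
    out <- paste0(substr(s, start, n), substr(s, 1L, end))
  }
  if (strand == "L") out <- revComp(out) else out
  out
}
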