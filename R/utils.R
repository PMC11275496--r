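# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# the 64 codons in TCAG-by-position order, DNA and RNA alphabets
DNA_CODONS <- local({
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
})
RNA_CODONS <- gsub("T", "U", DNA_CODONS, fixed = TRUE)

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGTN")
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round-half-up at d decimals; R's round() is round-half-even, which does
# not match how mitogenome report tables are conventionally printed.
roundHalfUp <- function(x, d = 2) {
  sign(x) * floor(abs(x) * 10^d + 0.5 + 1e-9) / 10^d
}

# Split a string into a character vector of single bases.
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Preserve and restore the caller's RNG state around seeded generation.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
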