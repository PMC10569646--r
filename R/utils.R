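# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' @param x single DNA string (IUPAC codes allowed).
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## codon -> residue lookup for the standard genetic code (table 1)
CODON_TABLE <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

## translate a DNA string with the standard code; ambiguous codons -> X,
## stops rendered '*'. Trailing partial codon silently dropped.
translate_dna <- function(dna) {
  n <- nchar(dna)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - n %% 3L - 2L, by = 3L)
  aa <- CODON_TABLE()[substring(toupper(dna), starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## substring by 0-based half-open interval (vectorized over start/end)
substr0 <- function(x, start, end) substring(x, start + 1L, end)

## split a protein string into a character vector of residues
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

## replace anything outside the 20 standard residues (and *) by X
sanitize_protein <- function(x) {
  gsub(sprintf("[^%s*X]", paste(AA_STANDARD, collapse = "")), "X",
       toupper(x))
}

## run a block of code under a temporary RNG seed, restoring global state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## random DNA at a given GC content
rand_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## random protein (uniform over the 20 standard residues)
rand_protein <- function(n) paste(sample(AA_STANDARD, n, replace = TRUE),
                                  collapse = "")
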