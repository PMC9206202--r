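#' The single-letter encoding alphabet
#'
#' Clinical text is encoded over a nine-letter alphabet:
#' `P` phenotype, `A` attribute trigger, `C` punctuation, `O` other
#' (unmatched) text, `S` specimen, `L` analyte, `N` number, `U` unit,
#' `R` lab-result direction word. A tenth symbol, `X`, is reserved for
#' masking motif sites during sequential discovery and is never produced
#' by the encoder.
#'
#' @format A character vector of the nine encoder letters.
#' @export
PHENOSSU_ALPHABET <- c("P", "A", "C", "O", "S", "L", "N", "U", "R")

# letters a lexicon entry may carry (N is normally produced by the number
# grammar but an explicit lexicon entry is legal)
LEXICON_LETTERS <- c("P", "A", "C", "S", "L", "N", "U", "R")

MASK_LETTER <- "X"

ALPHABET_INDEX <- stats::setNames(seq_along(PHENOSSU_ALPHABET), PHENOSSU_ALPHABET)

#' @keywords internal
letters_to_codes <- function(letters_chr) {
  codes <- ALPHABET_INDEX[strsplit(letters_chr, "", fixed = TRUE)[[1]]]
  unname(codes) # NA where masked
}

#' @keywords internal
codes_to_letters <- function(codes) {
  paste(PHENOSSU_ALPHABET[codes], collapse = "")
}

# Evaluate expressions with a private, seeded RNG stream, leaving the
# caller's .Random.seed untouched.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
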