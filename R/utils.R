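# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never disturb user-level randomness.
with_rng_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(as.integer(seed))
    force(code)
}

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences (IUPAC letters allowed).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
    if (length(x) == 0) return(character(0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# stopifnot() with a readable message
fail_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)
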