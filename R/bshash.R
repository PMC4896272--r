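# The bisulfite-aware, Hamming-aware de Bruijn hash function and its bit
# machinery.  Fingerprints are w-bit unsigned integers carried as doubles
# (exact for w <= 32); sequence position 0 maps to the most significant bit.

#' Hash parameters
#'
#' Bundles the seed length `m` (bases) and the fingerprint width `w` (bits)
#' of the de Bruijn hash function.  The construction requires `w <= m`:
#' shorter patterns are rejected rather than padded.
#'
#' @param m seed (pattern) length in bases, `m >= 1`.
#' @param w fingerprint width in bits, `1 <= w <= min(m, 32)`.
#' @return an object of class `HashParams`.
#' @examples
#' hash_params(30, 12)
#' @export
hash_params <- function(m, w) {
    fail_if(!is_count(m) || m < 1, "m must be a positive integer")
    fail_if(!is_count(w) || w < 1, "w must be a positive integer")
    fail_if(w > m, "the fingerprint width w must not exceed the seed length m")
    fail_if(w > 32, "fingerprint widths above 32 bits are not supported")
    structure(list(m = as.integer(m), w = as.integer(w)), class = "HashParams")
}

#' @export
print.HashParams <- function(x, ...) {
    cat(sprintf("HashParams: seed length m = %d, fingerprint width w = %d bits\n",
                x$m, x$w))
    invisible(x)
}

#' Default fingerprint width for a reference of length n
#'
#' `min(32, max(12, ceiling(log2(n)) + 2))`: wide enough that the
#' direct-address bucket table stays sparse, capped at the memory-word
#' size.  User-overridable everywhere a `HashParams` is accepted.
#'
#' @param n reference length in bases.
#' @return integer width in bits.
#' @export
default_w <- function(n) {
    fail_if(!is_count(n) || n < 2, "n must be an integer >= 2")
    min(32L, max(12L, as.integer(ceiling(log2(as.numeric(n)))) + 2L))
}

#' Binary encoding of a DNA string
#'
#' Maps each base to one bit: `C` and `T` encode 0, `G` and `A` encode 1,
#' so the encoding (and everything built on it) is invariant under both
#' bisulfite-induced substitution patterns, C-to-T and G-to-A.  Read as a
#' binary number (position 0 most significant), the bits give the integer
#' extension of the encoding to strings.
#'
#' @param seq DNA string over `{A,C,G,T}` (N characters must have been
#'   randomized upstream, see [preprocess_reference()]).
#' @return integer vector of 0/1 bits, one per base.
#' @examples
#' encode_alpha("ACGT")  # 1 0 1 0
#' @export
encode_alpha <- function(seq) {
    fail_if(!is.character(seq) || length(seq) != 1, "seq must be a single string")
    if (nchar(seq) == 0) return(integer(0))
    .cpp_encode_alpha(seq)
}

#' Fingerprint of a length-m pattern
#'
#' Splits the bit encoding of `P` into length-`w` blocks -- all blocks
#' except the last are non-overlapping and taken from the start; the last
#' is taken from the end and may overlap its predecessor -- and XORs them
#' together.  The resulting hash is de Bruijn (overlap-preserving),
#' Hamming-aware (patterns at Hamming distance `k` have fingerprints
#' within `2k` bit flips) and bisulfite-aware (invariant under C-to-T and
#' G-to-A substitution).
#'
#' @param P DNA string of length exactly `params$m`.
#' @param params a [hash_params()] object.
#' @return an object of class `Fingerprint` with fields `value` (numeric,
#'   exact w-bit unsigned integer) and `width`.
#' @examples
#' fingerprint("ACGTCA", hash_params(6, 3))   # value 4 = bits 100
#' @export
fingerprint <- function(P, params) {
    fail_if(!inherits(params, "HashParams"), "params must be a HashParams object")
    fail_if(!is.character(P) || length(P) != 1, "P must be a single string")
    fail_if(nchar(P) != params$m,
            sprintf("pattern length %d does not match the seed length m = %d",
                    nchar(P), params$m))
    new_fingerprint(.cpp_fingerprint(P, params$w), params$w)
}

#' @rdname fingerprint
#' @description `fingerprints()` is the vectorized form used for bulk
#'   work (index construction checks, exhaustive property suites): it
#'   takes a character vector of patterns and returns the plain numeric
#'   fingerprint values.
#' @export
fingerprints <- function(P, params) {
    fail_if(!inherits(params, "HashParams"), "params must be a HashParams object")
    fail_if(!all(nchar(P) == params$m),
            "all patterns must have length equal to the seed length m")
    .cpp_fingerprint_batch(P, params$w)
}

new_fingerprint <- function(value, width) {
    structure(list(value = as.numeric(value), width = as.integer(width)),
              class = "Fingerprint")
}

#' @export
print.Fingerprint <- function(x, ...) {
    bits <- paste(fingerprint_bits(x), collapse = "")
    cat(sprintf("Fingerprint: %s (%.0f) [w = %d]\n", bits, x$value, x$width))
    invisible(x)
}

#' @rdname fingerprint
#' @param x a `Fingerprint`.
#' @return `fingerprint_bits()`: integer vector of the `width` bits, most
#'   significant first.
#' @export
fingerprint_bits <- function(x) {
    fail_if(!inherits(x, "Fingerprint"), "x must be a Fingerprint")
    as.integer(floor(x$value / 2^((x$width - 1):0)) %% 2)
}

#' Hash of a whole text
#'
#' The global hash of `T` is the unique bit-string of length `n - m + w`
#' whose every `w`-bit window at bit `i` equals the fingerprint of the
#' length-`m` substring of `T` starting at `i` -- well-defined because the
#' hash function preserves suffix-prefix overlaps.
#'
#' @param T DNA string of length `n >= m` over `{A,C,G,T}`.
#' @inheritParams fingerprint
#' @return integer vector of 0/1 bits of length `n - m + w`.
#' @examples
#' global_hash("AACGT", hash_params(3, 2))  # 0 1 1 1
#' @export
global_hash <- function(T, params) {
    fail_if(!inherits(params, "HashParams"), "params must be a HashParams object")
    fail_if(!is.character(T) || length(T) != 1, "T must be a single string")
    fail_if(nchar(T) < params$m, "text shorter than the seed length m")
    fail_if(!grepl("^[ACGTacgt]*$", T), "text contains characters outside {A,C,G,T}")
    .cpp_global_hash(T, params$m, params$w)
}

#' Hamming ball around a fingerprint
#'
#' Enumerates every `width`-bit value within the given XOR (Hamming)
#' radius of the center, i.e. the candidate fingerprints that must be
#' probed when searching a pattern with up to `radius/2` base mismatches.
#' The enumeration order is fixed -- by flip count, then by lexicographic
#' flip positions with position 0 the most significant bit -- so that
#' downstream alignment output is reproducible.
#'
#' @param center a `Fingerprint`, or a plain numeric value (then `width`
#'   is required).
#' @param radius maximum number of bit flips, `0 <= radius <= width`.
#' @param width fingerprint width when `center` is numeric.
#' @return numeric vector of fingerprint values; its length is
#'   `sum(choose(width, 0:radius))`.
#' @examples
#' hamming_ball(fingerprint("ACGT", hash_params(4, 4)), 1)
#' @export
hamming_ball <- function(center, radius, width = NULL) {
    if (inherits(center, "Fingerprint")) {
        width <- center$width
        center <- center$value
    }
    fail_if(is.null(width), "width is required when center is not a Fingerprint")
    fail_if(!is_count(radius) || radius < 0 || radius > width,
            "radius must be an integer in [0, width]")
    .cpp_hamming_ball(as.numeric(center), as.integer(width), as.integer(radius))
}
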