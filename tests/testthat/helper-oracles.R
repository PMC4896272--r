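# Independent oracles used across the suite.  They deliberately share no
# code with the package's compiled search path: plain R arithmetic on the
# printed formulas.

# pure-R fingerprint: XOR of the leading non-overlapping w-blocks of the
# alpha bits with the final block at offset m - w
r_fingerprint <- function(P, w) {
    a <- ifelse(strsplit(P, "")[[1]] %in% c("G", "A"), 1L, 0L)
    m <- length(a)
    nb <- ceiling(m / w)
    block_val <- function(off) sum(a[(off + 1):(off + w)] * 2^((w - 1):0))
    v <- 0
    for (b in seq_len(nb - 1) - 1) v <- bitwXor(v, block_val(b * w))
    bitwXor(v, block_val(m - w))
}

# all 4^m DNA strings of length m (position 0 = first character)
all_patterns <- function(m) {
    g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), m))
    # column 1 varies fastest; reorder so the first character is the most
    # significant digit of the pattern id
    do.call(paste0, rev(g))
}

popcount4 <- function(x) {
    pc <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)
    pc[x + 1L]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# convert a subset of C positions to T (or G to A) in a string
convert_bases <- function(s, from, to, which_pos) {
    ch <- strsplit(s, "")[[1]]
    ch[which_pos][ch[which_pos] == from] <- to
    paste(ch, collapse = "")
}
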