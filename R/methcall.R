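# Methylation calling: genomic Cs and Gs are marked in a rank-supported
# bit-vector; strand-specific conversion counts live in two blocked,
# capacity-growing counter arrays addressed in rank space; beta scores and
# context annotations are derived on demand.

#' Mark cytosines (both strands) in a rank bit-vector
#'
#' Bit `i` is set iff reference base `i` is `C` or `G`.  `rank(i)` (the
#' number of set bits before position `i`) maps genomic positions to the
#' dense counter index space in constant time, via cumulative counts
#' sampled every 512 bits plus in-block popcounts.
#'
#' @param ref an `EncodedReference` (or, for [rank_bitvector()], any
#'   logical vector of bits).
#' @return an object of class `RankBitVector`.
#' @export
build_cg_bitvector <- function(ref) {
    fail_if(!inherits(ref, "EncodedReference"), "ref must be an EncodedReference")
    ptr <- .cpp_rankbv_from_text(ref$text)
    info <- .cpp_rankbv_info(ptr)
    structure(list(ptr = ptr, n = info$n, total = info$total),
              class = "RankBitVector")
}

#' @rdname build_cg_bitvector
#' @param bits logical vector.
#' @export
rank_bitvector <- function(bits) {
    ptr <- .cpp_rankbv_from_bits(bits)
    info <- .cpp_rankbv_info(ptr)
    structure(list(ptr = ptr, n = info$n, total = info$total),
              class = "RankBitVector")
}

#' @rdname build_cg_bitvector
#' @param bv a `RankBitVector`.
#' @param i 0-based positions; for `bv_rank`, in `[0, n]` (rank counts set
#'   bits strictly before `i`); for `bv_bit`, in `[0, n)`.
#' @return `bv_rank()`/`bv_bit()`: numeric / logical vector.
#' @export
bv_rank <- function(bv, i) {
    fail_if(!inherits(bv, "RankBitVector"), "bv must be a RankBitVector")
    .cpp_rankbv_rank(bv$ptr, as.numeric(i))
}

#' @rdname build_cg_bitvector
#' @export
bv_bit <- function(bv, i) {
    fail_if(!inherits(bv, "RankBitVector"), "bv must be a RankBitVector")
    .cpp_rankbv_get(bv$ptr, as.numeric(i))
}

#' @export
print.RankBitVector <- function(x, ...) {
    cat(sprintf("RankBitVector: %d bits, %d set\n", x$n, x$total))
    invisible(x)
}

#' Block-compressed counter pair
#'
#' Two counter arrays (primary = unconverted, converted) of `n` counters
#' each, stored in blocks of `bl` counters bit-packed at the block's
#' capacity.  All blocks start at capacity 1 bit; whenever a counter would
#' exceed its block's capacity the block is rebuilt with capacity + 1, so
#' storage tracks the local coverage maximum.  With `bl` at least the read
#' length a counter is incremented at most once per read, hence a block is
#' rebuilt at most once per read and updates stay linear in the input.
#'
#' @param n number of counters per array (the rank-space size, i.e. the
#'   number of marked cytosines).
#' @param bl block length in counters (default 256).
#' @return an object of class `CompressedCounters`.
#' @export
new_counters <- function(n, bl = 256L) {
    fail_if(!is_count(n) || n < 0, "n must be a non-negative integer")
    fail_if(!is_count(bl) || bl < 1, "bl must be a positive integer")
    structure(list(ptr = .cpp_counters_new(as.numeric(n), as.integer(bl)),
                   n = as.numeric(n), bl = as.integer(bl)),
              class = "CompressedCounters")
}

#' @rdname new_counters
#' @param counters a `CompressedCounters`.
#' @param rank_index 0-based counter indices in `[0, n)` (vectorized).
#' @param which `"primary"` or `"converted"` (recycled along
#'   `rank_index`).
#' @export
counter_increment <- function(counters, rank_index,
                              which = c("primary", "converted")) {
    fail_if(!inherits(counters, "CompressedCounters"),
            "counters must be a CompressedCounters")
    wh <- match(match.arg(which, several.ok = TRUE), c("primary", "converted")) - 1L
    .cpp_counters_inc(counters$ptr, as.numeric(rank_index),
                      rep_len(wh, length(rank_index)))
    invisible(counters)
}

#' @rdname new_counters
#' @export
counter_value <- function(counters, rank_index,
                          which = c("primary", "converted")) {
    fail_if(!inherits(counters, "CompressedCounters"),
            "counters must be a CompressedCounters")
    wh <- match(match.arg(which), c("primary", "converted")) - 1L
    .cpp_counters_get(counters$ptr, as.numeric(rank_index), wh)
}

#' @rdname new_counters
#' @return `counters_info()`: list with `n`, `bl`, total block `rebuilds`
#'   and the per-block capacities of both arrays.
#' @export
counters_info <- function(counters) {
    fail_if(!inherits(counters, "CompressedCounters"),
            "counters must be a CompressedCounters")
    .cpp_counters_info(counters$ptr)
}

#' @export
print.CompressedCounters <- function(x, ...) {
    info <- counters_info(x)
    cat(sprintf("CompressedCounters: %d counters x2, bl = %d, %d block rebuild(s)\n",
                as.integer(info$n), info$bl, as.integer(info$rebuilds)))
    invisible(x)
}

#' Accumulate conversion counts from alignments
#'
#' For every kept alignment and every genomic position under it marked in
#' the C/G bit-vector, the matching strand counter is updated: fwd-CT
#' alignments inform genomic Cs (read `C` counts as primary, read `T` as
#' converted), rev-GA alignments inform genomic Gs (read `G` primary,
#' read `A` converted); all other read bases are ignored.  Unmapped
#' records are skipped silently; reads with multiple best placements are
#' skipped by default (they are usually discarded before methylation
#' reconstruction); reads not overlapping an (extended) target interval
#' can be discarded when targets are supplied.
#'
#' @param alignments an alignment `data.table` ([align_reads()] output) or
#'   a SAM file path.
#' @param ref the `EncodedReference` aligned against.
#' @param discard_multiple drop multiple-status reads (default TRUE).
#' @param min_mapq optional MAPQ-like gate: drops `multiple` reads when
#'   `> 0` (kept for CLI parity; the table carries no finer score).
#' @param targets optional [target_set()] used with `discard_off_target`.
#' @param discard_off_target drop reads that do not overlap any extended
#'   target interval.
#' @param bl counter block length (default 256).
#' @return an object of class `MethylationCounts`: list with the
#'   `RankBitVector`, the `CompressedCounters`, the reference and
#'   book-keeping counts.
#' @export
process_alignments <- function(alignments, ref, discard_multiple = TRUE,
                               min_mapq = NULL, targets = NULL,
                               discard_off_target = FALSE, bl = 256L) {
    fail_if(!inherits(ref, "EncodedReference"), "ref must be an EncodedReference")
    if (is.character(alignments)) alignments <- parse_sam(alignments, ref)
    a <- data.table::as.data.table(alignments)
    fail_if(!all(stats::na.omit(a$contig) %in% ref$contigs$name),
            "alignments reference a contig unknown to the reference")
    n_total <- nrow(a)
    a <- a[status != "unmapped"]
    n_multiple <- sum(a$status == "multiple")
    if (isTRUE(discard_multiple) || (!is.null(min_mapq) && min_mapq > 0))
        a <- a[status == "unique"]
    n_off <- 0L
    if (isTRUE(discard_off_target)) {
        fail_if(is.null(targets), "discard_off_target requires targets")
        keep <- reads_on_target(a, targets)
        n_off <- sum(!keep)
        a <- a[keep]
    }
    bv <- build_cg_bitvector(ref)
    counters <- new_counters(bv$total, bl = bl)
    upd <- if (nrow(a) > 0)
        .cpp_count_alignments(bv$ptr, counters$ptr, ref$text,
                              a$seq_fwd, a$gpos,
                              match(a$mode, MODE_LABELS) - 1L)
    else list(primary_updates = 0, converted_updates = 0)
    structure(list(ref = ref, bitvector = bv, counters = counters,
                   n_alignments = n_total, n_used = nrow(a),
                   n_multiple_skipped = n_multiple, n_off_target = n_off,
                   updates = upd),
              class = "MethylationCounts")
}

#' @export
print.MethylationCounts <- function(x, ...) {
    cat(sprintf(
        "MethylationCounts: %d/%d alignments used, %d cytosines tracked\n",
        x$n_used, x$n_alignments, as.integer(x$bitvector$total)))
    invisible(x)
}

#' Methylation score
#'
#' `beta = count_primary / (count_primary + count_converted)`: the
#' fraction of informative read bases supporting methylation at a
#' cytosine.  Undefined (NA) at zero coverage.
#'
#' @param count_primary,count_converted non-negative counts (vectorized).
#' @return numeric vector in `[0, 1]` with NA where both counts are 0.
#' @examples
#' beta_score(3, 1)  # 0.75
#' @export
beta_score <- function(count_primary, count_converted) {
    fail_if(any(count_primary < 0) || any(count_converted < 0),
            "counts must be non-negative")
    tot <- count_primary + count_converted
    ifelse(tot > 0, count_primary / tot, NA_real_)
}

#' Binary methylation call
#'
#' A cytosine is called methylated iff its beta score is strictly greater
#' than the threshold (default 0.5); beta exactly at the threshold is
#' called unmethylated.
#'
#' @param beta_value beta scores (no NAs: filter zero-coverage sites
#'   first).
#' @param threshold strict decision threshold (default 0.5).
#' @return logical vector.
#' @export
call_status <- function(beta_value, threshold = 0.5) {
    fail_if(anyNA(beta_value),
            "undefined beta (zero coverage): filter before calling")
    beta_value > threshold
}

#' Cytosine context (CpG / CHG / CHH)
#'
#' Standard plant/mammal context rule on the strand of the cytosine: CpG
#' when followed by G, CHG when the second next base is G (H = A, C or T
#' in between), CHH otherwise; mirrored on the reverse complement for
#' `-`-strand cytosines (genomic Gs).  Positions with fewer than two
#' following bases inside their contig fall back to CHH and are flagged in
#' the `truncated` attribute.
#'
#' @param ref an `EncodedReference`.
#' @param position 0-based position(s) in the concatenated text; must hold
#'   `C` (`+` strand) or `G` (`-` strand).
#' @param strand `"+"` or `"-"` (recycled).
#' @return character vector in `{"CpG","CHG","CHH"}` with a logical
#'   `truncated` attribute.
#' @export
classify_context <- function(ref, position, strand) {
    fail_if(!inherits(ref, "EncodedReference"), "ref must be an EncodedReference")
    n <- length(position)
    strand <- rep_len(strand, n)
    base <- substring(ref$text, position + 1, position + 1)
    bad <- (strand == "+" & base != "C") | (strand == "-" & base != "G")
    fail_if(any(bad), sprintf(
        "position %d does not hold a %s-strand cytosine",
        position[which(bad)[1]], strand[which(bad)[1]]))
    ci <- contig_index_of(ref, position)
    cstart <- ref$contigs$start[ci]
    cend <- cstart + ref$contigs$length[ci]
    out <- character(n)
    truncated <- logical(n)
    plus <- strand == "+"
    b1 <- substring(ref$text, position + 2, position + 2)
    b2 <- substring(ref$text, position + 3, position + 3)
    p1 <- substring(ref$text, position, position)
    p2 <- substring(ref$text, position - 1, position - 1)
    # + strand: look downstream; - strand: look upstream at complements
    full <- ifelse(plus, position + 2 < cend, position - 2 >= cstart)
    one <- ifelse(plus, position + 1 < cend, position - 1 >= cstart)
    nxt <- ifelse(plus, b1, p1)          # neighbour toward 3' of the C
    nxt2 <- ifelse(plus, b2, p2)
    hitG <- ifelse(plus, nxt == "G", nxt == "C")   # complement on -
    hitG2 <- ifelse(plus, nxt2 == "G", nxt2 == "C")
    out <- ifelse(one & hitG, "CpG",
                  ifelse(full & hitG2, "CHG", "CHH"))
    truncated <- (!one) | (!full & !(one & hitG))
    out[!one] <- "CHH"
    attr(out, "truncated") <- truncated
    out
}

#' Per-cytosine methylation table
#'
#' Expands a [process_alignments()] result into one record per marked
#' cytosine on both strands: position, strand (`+` for genomic C, `-` for
#' G), context, counts, coverage and beta.
#'
#' @param counts a `MethylationCounts`.
#' @return a `data.table` with columns `contig`, `pos` (0-based), `gpos`,
#'   `strand`, `context`, `count_primary`, `count_converted`, `coverage`,
#'   `beta` (NA at zero coverage), ordered by genomic position.
#' @export
methylation_records <- function(counts) {
    fail_if(!inherits(counts, "MethylationCounts"),
            "counts must be a MethylationCounts")
    ref <- counts$ref
    gpos <- as.integer(gregexpr("[CG]", ref$text)[[1]]) - 1L
    if (length(gpos) == 1 && gpos[1] == -2L) gpos <- integer(0)  # no match
    strand <- ifelse(substring(ref$text, gpos + 1, gpos + 1) == "C", "+", "-")
    dump <- .cpp_counters_dump(counts$counters$ptr)
    loc <- global_to_contig(ref, gpos)
    ctx <- classify_context(ref, gpos, strand)
    dt <- data.table::data.table(
        contig = loc$contig, pos = loc$pos, gpos = gpos, strand = strand,
        context = as.character(ctx),
        count_primary = dump$primary, count_converted = dump$converted)
    dt[, coverage := count_primary + count_converted]
    dt[, beta := beta_score(count_primary, count_converted)]
    dt
}
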