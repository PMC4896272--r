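# Seed-and-extend alignment of directional BS reads against the dB-hash
# index.  Candidates come from bucket lookups over the 2k-radius Hamming
# ball around the seed fingerprint; verification is ungapped and
# bisulfite-aware, so conversion-induced mismatches carry no penalty.

#' Alignment parameters
#'
#' @param seed_errors maximum Hamming mismatches `k` tolerated in the seed
#'   (the tool's `--seed-errors`; default 2).
#' @param seed_length seed length `m` in bases (the tool's `--bl`; default
#'   30).  Must equal the `m` the index was built with.
#' @param max_mismatches full-read mismatch budget: either an integer or a
#'   fraction of the read length (default 0.05, i.e. `ceiling(0.05 * len)`).
#' @param insert_min,insert_max proper-pair insert-size bounds for FR
#'   orientation (defaults 100 and 600).
#' @param tie_cap maximum number of tied best placements retained per read
#'   (reporting and mate rescue only; the total count is always exact).
#' @return an object of class `AlignParams`.
#' @export
align_params <- function(seed_errors = 2L, seed_length = 30L,
                         max_mismatches = 0.05,
                         insert_min = 100L, insert_max = 600L,
                         tie_cap = 64L) {
    fail_if(!is_count(seed_errors) || seed_errors < 0, "seed_errors must be >= 0")
    fail_if(!is_count(seed_length) || seed_length < 1, "seed_length must be >= 1")
    fail_if(!is.numeric(max_mismatches) || max_mismatches < 0,
            "max_mismatches must be a non-negative number")
    fail_if(insert_min > insert_max, "insert_min must not exceed insert_max")
    structure(list(seed_errors = as.integer(seed_errors),
                   seed_length = as.integer(seed_length),
                   max_mismatches = max_mismatches,
                   insert_min = as.integer(insert_min),
                   insert_max = as.integer(insert_max),
                   tie_cap = as.integer(tie_cap)),
              class = "AlignParams")
}

# per-read total mismatch budget
resolve_max_mm <- function(params, len) {
    mm <- params$max_mismatches
    if (mm < 1) as.integer(ceiling(mm * len)) + integer(length(len)) * 0L
    else rep(as.integer(mm), length(len))
}

#' Bisulfite-aware base comparison
#'
#' In `fwd-CT` mode a genomic `C` may legitimately read as `T`
#' (unmethylated, converted); in `rev-GA` mode a genomic `G` may read as
#' `A`.  The rule is asymmetric: a genomic `T` under a read `C` is a
#' mismatch.
#'
#' @param genome_base,read_base single bases in `{A,C,G,T}` (vectorized).
#' @param mode `"CT"` (forward conversion pattern) or `"GA"`.
#' @return logical vector: does the read base match under the rule?
#' @examples
#' bs_match("C", "T", "CT")  # TRUE
#' bs_match("T", "C", "CT")  # FALSE
#' @export
bs_match <- function(genome_base, read_base, mode = c("CT", "GA")) {
    mode <- match.arg(mode)
    g <- toupper(genome_base); r <- toupper(read_base)
    fail_if(!all(g %in% BASES) || !all(r %in% BASES),
            "bases must be in {A,C,G,T}")
    if (mode == "CT") g == r | (g == "C" & r == "T")
    else              g == r | (g == "G" & r == "A")
}

check_align_params <- function(index, params) {
    fail_if(!inherits(index, "DBHashIndex"), "index must be a DBHashIndex")
    fail_if(!inherits(params, "AlignParams"), "params must be an AlignParams")
    fail_if(params$seed_length != index$params$m,
            sprintf("params$seed_length (%d) must match the index seed length (%d)",
                    params$seed_length, index$params$m))
    fail_if(2L * params$seed_errors > index$params$w,
            sprintf("Hamming-ball radius 2k = %d exceeds the fingerprint width w = %d",
                    2L * params$seed_errors, index$params$w))
    invisible(TRUE)
}

MODE_LABELS <- c("CT", "GA")
STATUS_LABELS <- c("unique", "multiple", "unmapped")

# Convert a C++ result list into the package-wide alignment table.
aln_table <- function(res, index, ids, mate, seqs, quals, paired) {
    ref <- index$reference
    mode <- ifelse(is.na(res$mode), NA_character_, MODE_LABELS[res$mode + 1L])
    status <- STATUS_LABELS[res$status + 1L]
    gp <- res$gpos
    ci <- ifelse(is.na(gp), NA_integer_, contig_index_of(ref, gp))
    rev <- res$rev
    seq_fwd <- seqs
    flip <- !is.na(rev) & rev
    if (any(flip)) seq_fwd[flip] <- revcomp(seqs[flip])
    qual_fwd <- quals
    if (any(flip)) qual_fwd[flip] <- vapply(quals[flip], function(q)
        intToUtf8(rev(utf8ToInt(q))), character(1))
    data.table::data.table(
        read_id = ids, mate = mate,
        contig = ref$contigs$name[ci],
        pos = ifelse(is.na(gp), NA_integer_, gp - ref$contigs$start[ci]),
        gpos = gp,
        strand = ifelse(is.na(rev), NA_character_, ifelse(rev, "-", "+")),
        mode = mode, mism = res$mism, status = status, nbest = res$nbest,
        proper = if (is.null(res$proper)) rep(NA, length(ids)) else res$proper,
        rescued = if (is.null(res$rescued)) rep(FALSE, length(ids)) else res$rescued,
        seq = seqs, seq_fwd = seq_fwd, qual = qual_fwd,
        len = nchar(seqs), paired = paired)
}

#' Align a batch of reads
#'
#' For each read the seed (the first `m` bases of the sequence matched
#' against the forward text) is fingerprinted; all buckets in the
#' 2k-radius Hamming ball are probed; every candidate position is verified
#' with at most `k` bisulfite-aware mismatches in the seed and at most
#' `max_mismatches` over the whole read (ungapped).  First mates are tried
#' as-is in fwd-CT mode and reverse-complemented in rev-GA mode; second
#' mates of a directional pair the other way around.  The best alignment
#' minimizes the mismatch count; `status` is `unique` when exactly one
#' placement attains it, `multiple` for ties (the leftmost is reported),
#' `unmapped` otherwise.  Alignments crossing a contig boundary of the
#' concatenated text are discarded during verification.
#'
#' @param index a [build_index()] result.
#' @param seqs character vector of read sequences.
#' @param ids read names (default `read1..readN`).
#' @param quals base-quality strings (carried through, never scored).
#' @param mate2 logical (scalar or per read): treat as second mates.
#' @param params an [align_params()] object.
#' @return a `data.table` with one row per read: `read_id`, `mate`,
#'   `contig`, `pos` (0-based), `gpos`, `strand`, `mode`, `mism`,
#'   `status`, `nbest`, `proper`, `rescued`, `seq`, `seq_fwd`
#'   (forward-strand projection), `qual`, `len`, `paired`.
#' @export
align_reads <- function(index, seqs, ids = NULL, quals = NULL, mate2 = FALSE,
                        params = align_params()) {
    check_align_params(index, params)
    n <- length(seqs)
    if (is.null(ids)) ids <- paste0("read", seq_len(n))
    if (is.null(quals)) quals <- strrep("I", nchar(seqs))
    mate2 <- rep_len(as.logical(mate2), n)
    short <- nchar(seqs) < index$params$m
    if (any(short))
        warning(sprintf("%d read(s) shorter than the seed length %d reported unmapped",
                        sum(short), index$params$m))
    res <- .cpp_align_batch(seqs, mate2, index$reference$text,
                            index$bucket_start, index$positions,
                            index$params$m, index$params$w, params$seed_errors,
                            resolve_max_mm(params, nchar(seqs)),
                            index$reference$contigs$start,
                            index$reference$contigs$length,
                            params$tie_cap, FALSE)
    aln_table(res, index, ids, ifelse(mate2, 2L, 1L), seqs, quals, FALSE)
}

#' @rdname align_reads
#' @param seq a single read sequence.
#' @export
align_read <- function(index, seq, ids = NULL, quals = NULL, mate2 = FALSE,
                       params = align_params()) {
    align_reads(index, seq, ids = ids, quals = quals, mate2 = mate2,
                params = params)
}

#' Align read pairs from a directional library
#'
#' Each mate is aligned independently ([align_reads()] semantics, mate 2
#' with the second-mate mode combination); a pair is marked `proper` when
#' both mates are uniquely placed on the same fragment strand (mode) in FR
#' orientation with an insert within the configured bounds.  When exactly
#' one mate is unique and the other has tied best placements, the tie
#' consistent with the unique mate is promoted (mate rescue, flagged in
#' `rescued`).
#'
#' @inheritParams align_reads
#' @param seqs1,seqs2 first/second mate sequences (same length).
#' @param quals1,quals2 quality strings.
#' @return a `data.table` as in [align_reads()] with two rows per pair
#'   (mate 1 then mate 2, interleaved), `proper` filled.
#' @export
align_pairs <- function(index, seqs1, seqs2, ids = NULL,
                        quals1 = NULL, quals2 = NULL,
                        params = align_params()) {
    check_align_params(index, params)
    fail_if(length(seqs1) != length(seqs2), "mate vectors differ in length")
    n <- length(seqs1)
    if (is.null(ids)) ids <- paste0("pair", seq_len(n))
    if (is.null(quals1)) quals1 <- strrep("I", nchar(seqs1))
    if (is.null(quals2)) quals2 <- strrep("I", nchar(seqs2))
    short <- nchar(seqs1) < index$params$m | nchar(seqs2) < index$params$m
    if (any(short))
        warning(sprintf("%d mate(s) shorter than the seed length %d reported unmapped",
                        sum(short), index$params$m))
    res <- .cpp_align_pairs(seqs1, seqs2, index$reference$text,
                            index$bucket_start, index$positions,
                            index$params$m, index$params$w, params$seed_errors,
                            resolve_max_mm(params, nchar(seqs1)),
                            resolve_max_mm(params, nchar(seqs2)),
                            index$reference$contigs$start,
                            index$reference$contigs$length,
                            params$tie_cap, params$insert_min, params$insert_max)
    t1 <- aln_table(list(gpos = res$gpos1, mode = res$mode1, mism = res$mism1,
                         status = res$status1, nbest = res$nbest1, rev = res$rev1,
                         proper = res$proper, rescued = res$rescued1),
                    index, ids, 1L, seqs1, quals1, TRUE)
    t2 <- aln_table(list(gpos = res$gpos2, mode = res$mode2, mism = res$mism2,
                         status = res$status2, nbest = res$nbest2, rev = res$rev2,
                         proper = res$proper, rescued = res$rescued2),
                    index, ids, 2L, seqs2, quals2, TRUE)
    out <- rbind(t1, t2)
    data.table::setorder(out, read_id, mate)
    out[order(match(read_id, ids), mate)]
}

#' @rdname align_pairs
#' @param read1,read2 single mate sequences.
#' @export
align_pair <- function(index, read1, read2, ids = NULL,
                       quals1 = NULL, quals2 = NULL, params = align_params()) {
    align_pairs(index, read1, read2, ids = ids, quals1 = quals1,
                quals2 = quals2, params = params)
}

#' Read a FASTQ file
#'
#' Plain or gzip-compressed, via [Biostrings::readDNAStringSet()].
#'
#' @param path FASTQ(.gz) path.
#' @return list with `ids`, `seqs`, `quals` (character vectors).
#' @export
read_fastq <- function(path) {
    fail_if(!file.exists(path), sprintf("FASTQ file not found: %s", path))
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    list(ids = sub("\\s.*$", "", names(x)),
         seqs = unname(as.character(x)),
         quals = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write a FASTQ file
#'
#' @param ids,seqs,quals read names, sequences and quality strings.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = grepl("\\.gz$", path))
    invisible(path)
}
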