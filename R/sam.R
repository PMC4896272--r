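# SAM text output and input.  Ungapped alignments only: CIGAR is always
# <len>M for mapped reads.  The conversion mode (fwd-CT vs rev-GA fragment
# strand) travels in the custom ZM tag, the uniqueness class in ZS.

SAM_PAIRED <- 1L; SAM_PROPER <- 2L; SAM_UNMAPPED <- 4L; SAM_MUNMAPPED <- 8L
SAM_REVERSE <- 16L; SAM_MREVERSE <- 32L; SAM_FIRST <- 64L; SAM_SECOND <- 128L

#' Write alignments as SAM
#'
#' Emits a valid SAM file: `@HD`/`@SQ` headers from the contig table,
#' 1-based `POS`, FLAG bits for pairing/strand/unmapped, ungapped CIGAR,
#' `NM` (bisulfite-aware mismatch count), `ZM` (conversion mode `CT`/`GA`)
#' and `ZS` (uniqueness class) tags.  `SEQ`/`QUAL` are stored on the
#' forward reference strand per SAM convention.
#'
#' @param alignments an alignment `data.table` from [align_reads()] /
#'   [align_pairs()].
#' @param ref the `EncodedReference` the alignments refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref, path) {
    fail_if(!inherits(ref, "EncodedReference"), "ref must be an EncodedReference")
    a <- data.table::as.data.table(alignments)
    fail_if(!all(stats::na.omit(a$contig) %in% ref$contigs$name),
            "alignments reference contigs absent from the reference")
    # mate-view columns (groups of 2 rows share a read_id for pairs)
    a[, `:=`(m_unmapped = rev(status == "unmapped"), m_strand = rev(strand),
             m_pos = rev(pos), m_contig = rev(contig), m_gpos = rev(gpos),
             m_len = rev(len), has_mate = .N == 2L), by = read_id]
    unm <- a$status == "unmapped"
    flag <- integer(nrow(a))
    p <- a$paired & a$has_mate
    flag <- flag + ifelse(p, SAM_PAIRED, 0L) +
        ifelse(p & a$proper %in% TRUE, SAM_PROPER, 0L) +
        ifelse(unm, SAM_UNMAPPED, 0L) +
        ifelse(p & a$m_unmapped, SAM_MUNMAPPED, 0L) +
        ifelse(!unm & a$strand == "-", SAM_REVERSE, 0L) +
        ifelse(p & !a$m_unmapped & a$m_strand %in% "-", SAM_MREVERSE, 0L) +
        ifelse(p & a$mate == 1L, SAM_FIRST, 0L) +
        ifelse(p & a$mate == 2L, SAM_SECOND, 0L)
    rname <- ifelse(unm, "*", a$contig)
    pos1 <- ifelse(unm, 0L, a$pos + 1L)
    mapq <- ifelse(a$status == "unique", 60L, 0L)
    cigar <- ifelse(unm, "*", paste0(a$len, "M"))
    both <- p & !unm & !a$m_unmapped
    rnext <- ifelse(both, "=", "*")
    pnext <- ifelse(both, a$m_pos + 1L, 0L)
    samec <- both & a$contig == a$m_contig
    span <- pmax(a$gpos + a$len, a$m_gpos + a$m_len) - pmin(a$gpos, a$m_gpos)
    tlen <- ifelse(samec,
                   ifelse(a$gpos < a$m_gpos | (a$gpos == a$m_gpos & a$mate == 1L),
                          span, -span),
                   0L)
    tags <- paste0(ifelse(unm, "", sprintf("NM:i:%d\tZM:Z:%s\t", a$mism, a$mode)),
                   "ZS:Z:", a$status)
    body <- paste(a$read_id, flag, rname, pos1, mapq, cigar, rnext, pnext,
                  ifelse(is.na(tlen), 0L, tlen), a$seq_fwd, a$qual, tags,
                  sep = "\t")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", ref$contigs$name, ref$contigs$length),
             sprintf("@PG\tID:bsdbh\tPN:bsdbh\tVN:%s",
                     as.character(utils::packageVersion("bsdbh"))))
    writeLines(c(hdr, body), path)
    a[, c("m_unmapped", "m_strand", "m_pos", "m_contig", "m_gpos", "m_len",
          "has_mate") := NULL]
    invisible(path)
}

sam_tag <- function(lines, tag, pattern) {
    m <- regmatches(lines, regexpr(paste0(tag, ":..?:", pattern), lines))
    out <- rep(NA_character_, length(lines))
    out[regexpr(paste0(tag, ":..?:"), lines) > 0] <- sub("^.*:", "", m)
    out
}

#' Read a SAM file back into an alignment table
#'
#' Understands the subset of SAM this package writes (and any ungapped
#' SAM with the mandatory columns).  The conversion mode is taken from the
#' `ZM` tag when present and otherwise inferred from the strand and mate
#' flags of the directional protocol.
#'
#' @param path SAM path (or a character vector of SAM lines).
#' @param ref the `EncodedReference` the file was aligned against.
#' @return an alignment `data.table` (see [align_reads()]).
#' @export
parse_sam <- function(path, ref) {
    fail_if(!inherits(ref, "EncodedReference"), "ref must be an EncodedReference")
    lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
    body <- lines[!startsWith(lines, "@")]
    body <- body[nzchar(body)]
    f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:11)
    flag <- as.integer(f[[2]])
    unm <- bitwAnd(flag, SAM_UNMAPPED) > 0L
    contig <- ifelse(unm | f[[3]] == "*", NA_character_, f[[3]])
    known <- stats::na.omit(unique(contig))
    fail_if(!all(known %in% ref$contigs$name),
            sprintf("SAM references unknown contig(s): %s",
                    paste(setdiff(known, ref$contigs$name), collapse = ", ")))
    pos <- ifelse(unm, NA_integer_, as.integer(f[[4]]) - 1L)
    strand <- ifelse(unm, NA_character_,
                     ifelse(bitwAnd(flag, SAM_REVERSE) > 0L, "-", "+"))
    mate <- ifelse(bitwAnd(flag, SAM_SECOND) > 0L, 2L, 1L)
    mode <- sam_tag(body, "ZM", "[A-Z]+")
    infer <- is.na(mode) & !unm
    mode[infer] <- ifelse(xor(strand[infer] == "-", mate[infer] == 2L), "GA", "CT")
    mode[unm] <- NA_character_
    status <- sam_tag(body, "ZS", "[a-z]+")
    nofb <- is.na(status)
    status[nofb] <- ifelse(unm[nofb], "unmapped",
                           ifelse(as.integer(f[[5]][nofb]) > 0L, "unique", "multiple"))
    nm <- suppressWarnings(as.integer(sam_tag(body, "NM", "[0-9]+")))
    gpos <- ifelse(unm, NA_integer_,
                   contig_to_global(ref, ifelse(is.na(contig), ref$contigs$name[1], contig),
                                    ifelse(is.na(pos), 0L, pos)))
    gpos[unm] <- NA_integer_
    seq_fwd <- f[[10]]
    flip <- !unm & strand == "-"
    sq <- seq_fwd
    sq[flip] <- revcomp(seq_fwd[flip])
    data.table::data.table(
        read_id = f[[1]], mate = mate, contig = contig, pos = pos, gpos = gpos,
        strand = strand, mode = mode, mism = nm, status = status,
        nbest = NA_integer_,
        proper = bitwAnd(flag, SAM_PROPER) > 0L,
        rescued = FALSE,
        seq = sq, seq_fwd = seq_fwd, qual = f[[11]],
        len = nchar(seq_fwd),
        paired = bitwAnd(flag, SAM_PAIRED) > 0L)
}
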