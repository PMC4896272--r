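# Target-enrichment support: BED intervals, symmetric flank extension,
# clipping, merging, on-target tests and enrichment statistics.

#' Build a target set
#'
#' Intervals are 0-based half-open.  Each interval is extended
#' symmetrically by `flank` bases (to account for coverage tails), clipped
#' at contig bounds and merged with any overlapping neighbour before use.
#'
#' @param intervals a data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open), or a `GRanges`.
#' @param flank symmetric extension in bases (default 0).
#' @param ref optional `EncodedReference` used to clip at contig ends and
#'   to reject unknown contigs.
#' @return an object of class `TargetSet` with merged `intervals` and the
#'   recorded `flank`.
#' @export
target_set <- function(intervals, flank = 0L, ref = NULL) {
    if (methods::is(intervals, "GRanges")) {
        intervals <- data.frame(
            contig = as.character(GenomicRanges::seqnames(intervals)),
            start = GenomicRanges::start(intervals) - 1L,
            end = GenomicRanges::end(intervals),
            stringsAsFactors = FALSE)
    }
    dt <- data.table::as.data.table(intervals[, c("contig", "start", "end")])
    fail_if(nrow(dt) == 0, "empty target set")
    fail_if(any(dt$end <= dt$start), "targets must satisfy start < end")
    dt[, `:=`(start = pmax(0L, as.integer(start) - as.integer(flank)),
              end = as.integer(end) + as.integer(flank))]
    if (!is.null(ref)) {
        fail_if(!all(dt$contig %in% ref$contigs$name),
                "target contig absent from the reference")
        lim <- ref$contigs$length[match(dt$contig, ref$contigs$name)]
        dt[, end := pmin(end, lim)]
    }
    # merge overlapping intervals per contig
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        dt$contig, IRanges::IRanges(dt$start + 1L, dt$end)))
    merged <- data.table::data.table(
        contig = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr))
    data.table::setorder(merged, contig, start)
    structure(list(intervals = merged, flank = as.integer(flank)),
              class = "TargetSet")
}

#' @rdname target_set
#' @param path BED file path (0-based half-open, first three columns
#'   used).
#' @export
read_targets <- function(path, flank = 0L, ref = NULL) {
    fail_if(!file.exists(path), sprintf("BED file not found: %s", path))
    gr <- rtracklayer::import(path, format = "BED")
    target_set(gr, flank = flank, ref = ref)
}

#' @export
print.TargetSet <- function(x, ...) {
    cat(sprintf("TargetSet: %d merged interval(s), %d bases (flank %d)\n",
                nrow(x$intervals), sum(x$intervals$end - x$intervals$start),
                x$flank))
    invisible(x)
}

targets_granges <- function(targets) {
    GenomicRanges::GRanges(targets$intervals$contig,
                           IRanges::IRanges(targets$intervals$start + 1L,
                                            targets$intervals$end))
}

# which mapped alignment rows overlap >= 1 base of an (extended) target
reads_on_target <- function(aln, targets) {
    fail_if(!inherits(targets, "TargetSet"), "targets must be a TargetSet")
    keep <- rep(TRUE, nrow(aln))
    mapped <- !is.na(aln$pos)
    if (!any(mapped)) return(keep)
    gr <- GenomicRanges::GRanges(aln$contig[mapped],
                                 IRanges::IRanges(aln$pos[mapped] + 1L,
                                                  aln$pos[mapped] + aln$len[mapped]))
    keep[mapped] <- IRanges::overlapsAny(gr, targets_granges(targets))
    keep
}

#' Target-enrichment statistics
#'
#' Computes (a) the fraction of aligned bases falling inside the
#' (extended, merged) targets, (b) the mean coverage over target
#' positions, and (c) the mean coverage at each distance `1..max_distance`
#' from the nearest target edge on both flanks -- the profile used to
#' decide how far targets should be side-extended.
#'
#' @param alignments alignment `data.table` or SAM path.
#' @param ref the `EncodedReference`.
#' @param targets a non-empty [target_set()].
#' @param max_distance largest flank distance profiled (default 500).
#' @return an object of class `TargetStats`: list with
#'   `on_target_fraction`, `mean_coverage_on_target`, `distance_profile`
#'   (data.frame `distance`, `mean_coverage`, `n_positions`) and totals.
#' @export
target_stats <- function(alignments, ref, targets, max_distance = 500L) {
    fail_if(!inherits(targets, "TargetSet"), "targets must be a TargetSet")
    fail_if(nrow(targets$intervals) == 0, "empty target set")
    if (is.character(alignments)) alignments <- parse_sam(alignments, ref)
    a <- data.table::as.data.table(alignments)[!is.na(pos)]
    fail_if(nrow(a) == 0, "no mapped alignments")
    gr <- GenomicRanges::GRanges(a$contig, IRanges::IRanges(a$pos + 1L,
                                                            a$pos + a$len))
    tgt <- targets_granges(targets)
    ov <- GenomicRanges::findOverlaps(gr, tgt)
    inter <- IRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                 tgt[S4Vectors::subjectHits(ov)])
    on_bases <- sum(as.numeric(GenomicRanges::width(inter)))
    tot_bases <- sum(as.numeric(a$len))
    clen <- stats::setNames(ref$contigs$length, ref$contigs$name)
    cov <- GenomicRanges::coverage(gr, width = clen)
    # mean coverage over target positions
    tsum <- 0; twidth <- 0
    ti <- targets$intervals
    for (ct in unique(ti$contig)) {
        rng <- IRanges::IRanges(ti[contig == ct]$start + 1L, ti[contig == ct]$end)
        v <- IRanges::Views(cov[[ct]], rng)
        tsum <- tsum + sum(as.numeric(IRanges::viewSums(v)))
        twidth <- twidth + sum(IRanges::width(rng))
    }
    # coverage as a function of distance from the nearest target edge
    prof <- vector("list", max_distance)
    covs <- lapply(stats::setNames(nm = names(cov)), function(ct) as.integer(cov[[ct]]))
    for (d in seq_len(max_distance)) {
        vals <- numeric(0)
        for (ct in unique(ti$contig)) {
            iv <- ti[contig == ct]
            pts <- c(iv$start - d + 1L, iv$end + d)  # 1-based flank points
            pts <- pts[pts >= 1L & pts <= clen[[ct]]]
            if (!length(pts)) next
            # keep only points whose distance to the NEAREST target is d
            dd <- point_target_distance(pts, iv$start + 1L, iv$end)
            pts <- pts[dd == d]
            if (length(pts)) vals <- c(vals, covs[[ct]][pts])
        }
        prof[[d]] <- data.frame(distance = d,
                                mean_coverage = if (length(vals)) mean(vals) else NA_real_,
                                n_positions = length(vals))
    }
    structure(list(on_target_fraction = on_bases / tot_bases,
                   mean_coverage_on_target = tsum / twidth,
                   distance_profile = do.call(rbind, prof),
                   n_targets = nrow(ti), target_bases = twidth,
                   aligned_bases = tot_bases),
              class = "TargetStats")
}

# distance from 1-based points to the nearest [start1, end1] interval
# (0 inside); intervals sorted and disjoint
point_target_distance <- function(pts, start1, end1) {
    vapply(pts, function(p) {
        inside <- any(p >= start1 & p <= end1)
        if (inside) return(0L)
        as.integer(min(abs(c(p - end1, start1 - p))))
    }, integer(1))
}

#' @export
print.TargetStats <- function(x, ...) {
    cat(sprintf(
        "TargetStats: %.2f%% of aligned bases on target; mean on-target coverage %.2f (%d targets, %d bases)\n",
        100 * x$on_target_fraction, x$mean_coverage_on_target,
        x$n_targets, x$target_bases))
    invisible(x)
}
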