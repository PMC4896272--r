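# Evaluation harness: mapping accuracy against simulated read origins and
# methylation-call accuracy against the simulated binary methylome.

#' Evaluate mapping accuracy against simulated truth
#'
#' A unique alignment is counted correct iff its contig and conversion
#' mode match the simulated origin and its position is within `tolerance`
#' bases of the true one (the 50-base default absorbs clipped/shifted
#' placements).
#'
#' @param alignments alignment `data.table` or SAM path (then `ref` is
#'   required).
#' @param truth truth table from [simulate_reads()] (`read_id`, `mate`,
#'   `contig`, `pos`, `mode`) or a TSV path.
#' @param tolerance maximum absolute position error (default 50).
#' @param ref `EncodedReference`, needed only when `alignments` is a SAM
#'   path.
#' @return list with `unique_fraction` (uniques / all reads),
#'   `correct_fraction` (correct / uniques) and the underlying counts.
#' @export
evaluate_mapping <- function(alignments, truth, tolerance = 50L, ref = NULL) {
    if (is.character(alignments)) {
        fail_if(is.null(ref), "parsing a SAM path requires ref")
        alignments <- parse_sam(alignments, ref)
    }
    if (is.character(truth)) truth <- data.table::fread(truth)
    a <- data.table::as.data.table(alignments)
    tr <- data.table::as.data.table(truth)
    fail_if(!all(a$read_id %in% tr$read_id),
            "alignment read id(s) missing from the truth table")
    m <- tr[a, on = c("read_id", "mate"),
            .(read_id, mate, status,
              contig = i.contig, pos = i.pos, mode = i.mode,
              truth_contig = contig, truth_pos = pos, truth_mode = mode)]
    fail_if(anyNA(m$truth_pos), "truth table does not cover every aligned read")
    n_total <- nrow(m)
    u <- m[status == "unique"]
    correct <- u$contig == u$truth_contig & u$mode == u$truth_mode &
        abs(u$pos - u$truth_pos) <= tolerance
    list(unique_fraction = nrow(u) / n_total,
         correct_fraction = if (nrow(u)) mean(correct) else NA_real_,
         n_reads = n_total, n_unique = nrow(u),
         n_correct = sum(correct))
}

#' Evaluate methylation calls against simulated truth
#'
#' Only cytosines with coverage at least `min_coverage` enter the
#' accuracy denominator; a site is called methylated iff beta is strictly
#' greater than `threshold`, and the call is correct iff it equals the
#' simulated binary state.
#'
#' @param records a [methylation_records()] table (all cytosines, both
#'   strands).
#' @param truth a [simulate_methylome()] table for the same genome.
#' @param min_coverage minimum informative coverage (default 3).
#' @param threshold strict call threshold (default 0.5).
#' @return list with `covered_fraction` (coverage >= min over all
#'   cytosines), `accuracy` (correct calls among covered) and counts.
#' @export
evaluate_methylation <- function(records, truth, min_coverage = 3L,
                                 threshold = 0.5) {
    r <- data.table::as.data.table(records)
    tr <- data.table::as.data.table(truth)
    m <- r[tr, on = c("gpos", "strand"),
           .(gpos, strand, coverage, beta, methylated)]
    m[is.na(coverage), coverage := 0]
    n_all <- nrow(m)
    cov <- m[coverage >= min_coverage]
    correct <- call_status(cov$beta, threshold) == cov$methylated
    list(covered_fraction = nrow(cov) / n_all,
         accuracy = if (nrow(cov)) mean(correct) else NA_real_,
         n_cytosines = n_all, n_covered = nrow(cov),
         n_correct = sum(correct))
}
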