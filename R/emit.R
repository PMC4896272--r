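# Annotation output: Bismark-compatible cov, BED, and a documented EPP
# dialect, each optionally gzip-compressed on the fly.

num_str <- function(x, digits = 6) {
    out <- as.character(round(x, digits))
    out[is.na(x)] <- "NA"
    out
}

#' Write methylation annotations
#'
#' Formats:
#' \describe{
#'   \item{cov}{Bismark coverage dialect: `contig, pos1, pos1,
#'     100*beta, count_primary, count_converted` (tab-separated, 1-based,
#'     covered cytosines only).}
#'   \item{bed}{0-based half-open: `contig, start, end, context, beta,
#'     strand, count_primary, count_converted`; `beta` is `.` at zero
#'     coverage; all cytosines are reported.}
#'   \item{epp}{a fixed-column dialect (the upstream format is not
#'     publicly specified; this one is documented here): `contig, pos1,
#'     strand, context, count_primary, coverage, beta`; all cytosines are
#'     reported, `beta` is `NA` at zero coverage.}
#' }
#'
#' @param records a [methylation_records()] table.
#' @param path output path.
#' @param format `"cov"`, `"bed"` or `"epp"`.
#' @param compress `"none"` or `"gzip"` (applied on the fly).
#' @param on_target_only restrict output to cytosines inside `targets`.
#' @param targets a [target_set()], required when `on_target_only`.
#' @return `path`, invisibly.
#' @export
emit_methylation <- function(records, path, format = c("cov", "bed", "epp"),
                             compress = c("none", "gzip"),
                             on_target_only = FALSE, targets = NULL) {
    format <- match.arg(format)
    compress <- match.arg(compress)
    r <- data.table::as.data.table(records)
    if (isTRUE(on_target_only)) {
        fail_if(is.null(targets), "on_target_only requires targets")
        gr <- GenomicRanges::GRanges(r$contig,
                                     IRanges::IRanges(r$pos + 1L, r$pos + 1L))
        r <- r[IRanges::overlapsAny(gr, targets_granges(targets))]
    }
    lines <- switch(format,
        cov = {
            rc <- r[coverage > 0]
            paste(rc$contig, rc$pos + 1L, rc$pos + 1L, num_str(100 * rc$beta),
                  rc$count_primary, rc$count_converted, sep = "\t")
        },
        bed = paste(r$contig, r$pos, r$pos + 1L, r$context,
                    ifelse(is.na(r$beta), ".", num_str(r$beta)),
                    r$strand, r$count_primary, r$count_converted, sep = "\t"),
        epp = paste(r$contig, r$pos + 1L, r$strand, r$context,
                    r$count_primary, r$coverage, num_str(r$beta), sep = "\t"))
    con <- if (compress == "gzip") gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Read a Bismark-style cov file back
#'
#' @param path cov(.gz) path.
#' @return `data.table` with `contig`, `pos` (0-based), `meth_percent`,
#'   `count_primary`, `count_converted`, `coverage`, `beta`.
#' @export
parse_cov <- function(path) {
    fail_if(!file.exists(path), sprintf("cov file not found: %s", path))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (!length(lines))
        return(data.table::data.table(contig = character(0), pos = integer(0),
                                      meth_percent = numeric(0),
                                      count_primary = numeric(0),
                                      count_converted = numeric(0),
                                      coverage = numeric(0), beta = numeric(0)))
    f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
    dt <- data.table::data.table(
        contig = f[[1]], pos = as.integer(f[[2]]) - 1L,
        meth_percent = as.numeric(f[[4]]),
        count_primary = as.numeric(f[[5]]), count_converted = as.numeric(f[[6]]))
    dt[, coverage := count_primary + count_converted]
    dt[, beta := beta_score(count_primary, count_converted)]
    dt
}
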