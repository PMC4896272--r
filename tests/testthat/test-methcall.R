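# Methylation calling: rank bit-vector, compressed counters, counting,
# beta scores, contexts, output formats, target statistics.

test_that("the C/G bit-vector marks and ranks correctly", {
    ref <- preprocess_reference(c(c = "AACGT"))
    bv <- build_cg_bitvector(ref)
    expect_identical(bv_bit(bv, 0:4), c(FALSE, FALSE, TRUE, TRUE, FALSE))
    expect_equal(bv_rank(bv, 5), 2)
    expect_equal(bv_rank(bv, 0), 0)

    set.seed(61)
    reftxt <- random_dna(50000)
    rbv <- build_cg_bitvector(preprocess_reference(c(c = reftxt)))
    bits <- strsplit(reftxt, "")[[1]] %in% c("C", "G")
    ii <- sample(0:50000, 1000)
    expect_equal(bv_rank(rbv, ii),
                 vapply(ii, function(i) sum(bits[seq_len(i)]), numeric(1)))
    expect_error(bv_rank(rbv, 50001), "out of")
})

test_that("compressed counters grow capacity and stay exact", {
    cnt <- new_counters(600, bl = 256)
    counter_increment(cnt, rep(7, 3), "primary")
    expect_equal(counter_value(cnt, 7, "primary"), 3)
    info <- counters_info(cnt)
    expect_equal(info$capacity_primary[1], 2)   # 1 -> 2 bits to hold 3
    expect_equal(info$capacity_primary[2], 1)   # untouched block unchanged
    expect_equal(counter_value(cnt, 8, "primary"), 0)   # isolation
    expect_equal(counter_value(cnt, 7, "converted"), 0)

    # 1e5 randomized increments over 4 blocks against a plain-array oracle
    set.seed(62)
    n <- 1024L
    cnt2 <- new_counters(n, bl = 256)
    oracle <- matrix(0, nrow = n, ncol = 2)
    idx <- sample(0:(n - 1), 1e5, replace = TRUE,
                  prob = runif(n)^2)          # skewed to force rebuilds
    wh <- sample(c("primary", "converted"), 1e5, replace = TRUE)
    counter_increment(cnt2, idx[wh == "primary"], "primary")
    counter_increment(cnt2, idx[wh == "converted"], "converted")
    for (j in seq_len(1e5)) oracle[idx[j] + 1, (wh[j] == "converted") + 1] <-
        oracle[idx[j] + 1, (wh[j] == "converted") + 1] + 1
    expect_equal(counter_value(cnt2, 0:(n - 1), "primary"), oracle[, 1])
    expect_equal(counter_value(cnt2, 0:(n - 1), "converted"), oracle[, 2])
    info2 <- counters_info(cnt2)
    expect_true(all(2^info2$capacity_primary >
                        vapply(split(oracle[, 1], (0:(n - 1)) %/% 256), max,
                               numeric(1))))
    expect_error(counter_increment(cnt2, n, "primary"), "range")
})

test_that("counting is gated by the bit-vector and the conversion mode", {
    ref <- preprocess_reference(c(c1 = "AACGT"))
    mkaln <- function(seq, pos, mode, strand) data.table::data.table(
        read_id = "r", mate = 1L, contig = "c1", pos = pos, gpos = pos,
        strand = strand, mode = mode, mism = 0L, status = "unique",
        nbest = 1L, proper = NA, rescued = FALSE, seq = seq, seq_fwd = seq,
        qual = strrep("I", nchar(seq)), len = nchar(seq), paired = FALSE)
    # fwd-CT read "ACG" at position 1: informs the C at position 2 only
    # (the G at position 3 belongs to the reverse strand)
    cc <- process_alignments(mkaln("ACG", 1L, "CT", "+"), ref)
    expect_equal(counter_value(cc$counters, 0, "primary"), 1)  # rank(2) = 0
    expect_equal(counter_value(cc$counters, 1, "primary"), 0)
    # converted read "ATG": T under the genomic C
    cc2 <- process_alignments(mkaln("ATG", 1L, "CT", "+"), ref)
    expect_equal(counter_value(cc2$counters, 0, "converted"), 1)
    expect_equal(counter_value(cc2$counters, 0, "primary"), 0)
    # rev-GA alignment informs the genomic G
    cc3 <- process_alignments(mkaln("ACG", 1L, "GA", "-"), ref)
    expect_equal(counter_value(cc3$counters, 1, "primary"), 1)
    expect_equal(counter_value(cc3$counters, 0, "primary"), 0)
    cc4 <- process_alignments(mkaln("AAG", 1L, "GA", "-"), ref)
    expect_equal(counter_value(cc4$counters, 1, "converted"), 0)  # pos 3 read G
    expect_equal(counter_value(cc4$counters, 0, "converted"), 0)
    # read under A/T positions changes nothing
    cc5 <- process_alignments(mkaln("AA", 0L, "CT", "+"), ref)
    expect_equal(sum(counter_value(cc5$counters, 0:1, "primary")) +
                     sum(counter_value(cc5$counters, 0:1, "converted")), 0)
    # unknown contig errors
    bad <- mkaln("ACG", 1L, "CT", "+")
    bad$contig <- "zz"
    expect_error(process_alignments(bad, ref), "contig")
})

test_that("beta and call_status implement the printed formulas", {
    expect_equal(beta_score(3, 1), 0.75)
    expect_equal(beta_score(0, 5), 0)
    expect_true(is.na(beta_score(0, 0)))
    expect_equal(beta_score(c(3, 0, 0), c(1, 5, 0)), c(0.75, 0, NA))
    expect_false(call_status(0.5))          # strictly greater
    expect_true(call_status(0.5000001))
    expect_false(call_status(0))
    expect_error(call_status(NA_real_), "undefined")
})

test_that("context classification follows the standard CpG/CHG/CHH rule", {
    ref <- function(s) preprocess_reference(c(c = s))
    expect_equal(as.character(classify_context(ref("ACGT"), 1, "+")), "CpG")
    expect_equal(as.character(classify_context(ref("ACAGT"), 1, "+")), "CHG")
    expect_equal(as.character(classify_context(ref("ACAAT"), 1, "+")), "CHH")
    # minus strand mirrors on the reverse complement
    expect_equal(as.character(classify_context(ref("ACGT"), 2, "-")), "CpG")
    expect_equal(as.character(classify_context(ref("AACAG"), 4, "-")), "CHG")
    expect_equal(as.character(classify_context(ref("CTAGA"), 3, "-")), "CHH")
    expect_equal(as.character(classify_context(ref("TTTGA"), 3, "-")), "CHH")
    # contig-end fallback with flag
    x <- classify_context(ref("AAC"), 2, "+")
    expect_equal(as.character(x), "CHH")
    expect_true(attr(x, "truncated"))
    expect_error(classify_context(ref("ACGT"), 0, "+"), "cytosine")
})

test_that("methylation records conserve counts and round-trip through cov", {
    set.seed(71)
    g <- simulate_genome(8000, 0.45, rng_seed = 72)
    ref <- preprocess_reference(g, rng_seed = 72)
    meth <- simulate_methylome(ref, rng_seed = 73)
    sim <- simulate_reads(ref, meth, coverage = 8, read_length = 80,
                          conversion_efficiency = 1, error_rate = 0,
                          rng_seed = 74)
    idx <- build_index(ref)
    aln <- align_pairs(idx, sim$reads1, sim$reads2, ids = sim$ids)
    counts <- process_alignments(aln, ref)
    rec <- methylation_records(counts)
    expect_true(all(rec$beta >= 0 & rec$beta <= 1, na.rm = TRUE))
    expect_equal(nrow(rec), counts$bitvector$total)
    # conservation: total counted bases equal the informative read bases
    u <- aln[aln$status == "unique"]
    informative <- sum(vapply(seq_len(nrow(u)), function(i) {
        gp <- u$gpos[i] + seq_len(u$len[i]) - 1L
        gb <- strsplit(substr(ref$text, u$gpos[i] + 1,
                              u$gpos[i] + u$len[i]), "")[[1]]
        rb <- strsplit(u$seq_fwd[i], "")[[1]]
        if (u$mode[i] == "CT") sum(gb == "C" & rb %in% c("C", "T"))
        else sum(gb == "G" & rb %in% c("G", "A"))
    }, numeric(1)))
    expect_equal(sum(rec$count_primary) + sum(rec$count_converted), informative)
    # block rebuilds are bounded by the number of reads (bl >= read length)
    expect_lte(counters_info(counts$counters)$rebuilds, nrow(u))
    # cov round trip
    covf <- tempfile(fileext = ".cov")
    emit_methylation(rec, covf, format = "cov")
    back <- parse_cov(covf)
    covered <- rec[rec$coverage > 0]
    expect_equal(nrow(back), nrow(covered))
    expect_equal(back$count_primary, as.numeric(covered$count_primary))
    expect_equal(back$count_converted, as.numeric(covered$count_converted))
    expect_equal(back$pos, covered$pos)
})

test_that("emit formats match their specifications, with gzip on the fly", {
    rec <- data.table::data.table(
        contig = "contig1", pos = 2L, gpos = 2L, strand = "+",
        context = "CpG", count_primary = 3, count_converted = 1,
        coverage = 4, beta = 0.75)
    f <- tempfile()
    emit_methylation(rec, f, format = "cov")
    expect_identical(readLines(f), "contig1\t3\t3\t75\t3\t1")
    # zero-coverage cytosines are absent from cov output
    rec0 <- rbind(rec, data.table::data.table(
        contig = "contig1", pos = 5L, gpos = 5L, strand = "-",
        context = "CHH", count_primary = 0, count_converted = 0,
        coverage = 0, beta = NA_real_))
    emit_methylation(rec0, f, format = "cov")
    expect_length(readLines(f), 1L)
    emit_methylation(rec0, f, format = "bed")
    expect_identical(readLines(f),
                     c("contig1\t2\t3\tCpG\t0.75\t+\t3\t1",
                       "contig1\t5\t6\tCHH\t.\t-\t0\t0"))
    emit_methylation(rec0, f, format = "epp")
    expect_identical(readLines(f),
                     c("contig1\t3\t+\tCpG\t3\t4\t0.75",
                       "contig1\t6\t-\tCHH\t0\t0\tNA"))
    fgz <- tempfile(fileext = ".gz")
    emit_methylation(rec0, fgz, format = "cov", compress = "gzip")
    con <- gzfile(fgz, "rt")
    emit_methylation(rec0, f, format = "cov")
    expect_identical(readLines(con), readLines(f))
    close(con)
})

test_that("target statistics reflect known geometry", {
    # 2000 bp contig, one target [500, 700); reads of length 50 only inside
    ref <- preprocess_reference(c(c = random_dna(2000)), rng_seed = 81)
    starts <- seq(500L, 650L, by = 10L)
    aln <- data.table::data.table(
        read_id = paste0("r", seq_along(starts)), mate = 1L, contig = "c",
        pos = starts, gpos = starts, strand = "+", mode = "CT", mism = 0L,
        status = "unique", nbest = 1L, proper = NA, rescued = FALSE,
        seq = strrep("A", 50), seq_fwd = strrep("A", 50),
        qual = strrep("I", 50), len = 50L, paired = FALSE)
    tgt <- target_set(data.frame(contig = "c", start = 500L, end = 700L),
                      ref = ref)
    st <- target_stats(aln, ref, tgt, max_distance = 120L)
    expect_equal(st$on_target_fraction, 1.0)
    expect_equal(st$mean_coverage_on_target,
                 sum(aln$len) / 200)     # all bases inside the 200 bp target
    prof <- st$distance_profile
    expect_true(all(prof$mean_coverage[prof$distance > 50] == 0))
    # a read hanging over the right edge leaves a coverage tail that dies
    # out beyond the read length
    over <- data.table::copy(aln)[1]
    over$read_id <- "edge"; over$pos <- 680L; over$gpos <- 680L
    st2 <- target_stats(rbind(aln, over), ref, tgt, max_distance = 120L)
    prof2 <- st2$distance_profile
    expect_true(all(prof2$mean_coverage[prof2$distance <= 30] > 0))
    expect_true(all(prof2$mean_coverage[prof2$distance > 50] == 0))
    expect_lt(st2$on_target_fraction, 1.0)
    expect_error(target_stats(aln, ref, target_set(
        data.frame(contig = "c", start = 1, end = 1)), 10), "start < end")

    # flank extension rescues off-target reads; merging joins neighbours
    off <- data.table::copy(aln)[1]
    off$pos <- 420L; off$gpos <- 420L
    expect_false(reads_on_target(off, tgt))
    tgt2 <- target_set(data.frame(contig = "c", start = 500L, end = 700L),
                       flank = 50L, ref = ref)
    expect_true(reads_on_target(off, tgt2))
    m <- target_set(data.frame(contig = c("c", "c"), start = c(100L, 220L),
                               end = c(200L, 300L)), flank = 20L, ref = ref)
    expect_equal(nrow(m$intervals), 1L)
    expect_equal(m$intervals$start, 80L)
    expect_equal(m$intervals$end, 320L)
})

test_that("off-target reads can be discarded and output restricted", {
    ref <- preprocess_reference(c(c = paste0(strrep("A", 100), "CG",
                                             strrep("A", 98), "CG",
                                             strrep("A", 98))), rng_seed = 9)
    mk <- function(id, pos) data.table::data.table(
        read_id = id, mate = 1L, contig = "c", pos = pos, gpos = pos,
        strand = "+", mode = "CT", mism = 0L, status = "unique", nbest = 1L,
        proper = NA, rescued = FALSE, seq = "CG", seq_fwd = "CG", qual = "II",
        len = 2L, paired = FALSE)
    aln <- rbind(mk("in", 100L), mk("out", 200L))
    tgt <- target_set(data.frame(contig = "c", start = 90L, end = 110L),
                      ref = ref)
    cc <- process_alignments(aln, ref, targets = tgt,
                             discard_off_target = TRUE)
    expect_equal(cc$n_used, 1L)
    expect_equal(cc$n_off_target, 1L)
    rec <- methylation_records(cc)
    expect_equal(rec[rec$gpos == 100]$count_primary, 1)
    expect_equal(rec[rec$gpos == 200]$count_primary, 0)
    fon <- tempfile()
    emit_methylation(rec, fon, format = "bed", on_target_only = TRUE,
                     targets = tgt)
    expect_length(readLines(fon), 2L)   # the on-target C and G only
    expect_error(emit_methylation(rec, fon, format = "bed",
                                  on_target_only = TRUE), "targets")
})
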