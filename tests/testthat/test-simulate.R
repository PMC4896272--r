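# Directional BS-seq simulator and evaluation harness.

test_that("simulate_genome is reproducible and hits the GC target", {
    g1 <- simulate_genome(10000, 0.5, rng_seed = 7)
    g2 <- simulate_genome(10000, 0.5, rng_seed = 7)
    expect_identical(as.character(g1), as.character(g2))
    s <- as.character(g1)[[1]]
    gc <- sum(strsplit(s, "")[[1]] %in% c("C", "G"))
    # binomial 3 sigma bound around 0.5
    expect_lt(abs(gc - 5000), 3 * sqrt(10000 * 0.25))
    expect_error(simulate_genome(500), "1 kbp")
    fa <- tempfile(fileext = ".fa")
    simulate_genome(2000, rng_seed = 1, path = fa)
    expect_identical(as.character(Biostrings::readDNAStringSet(fa))[[1]],
                     as.character(simulate_genome(2000, rng_seed = 1))[[1]])
})

test_that("simulate_methylome draws context-dependent Bernoulli states", {
    ref <- preprocess_reference(simulate_genome(20000, 0.5, rng_seed = 8))
    all1 <- simulate_methylome(ref, 1, 1, rng_seed = 9)
    expect_true(all(all1$methylated))
    expect_equal(nrow(all1),
                 sum(strsplit(ref$text, "")[[1]] %in% c("C", "G")))
    all0 <- simulate_methylome(ref, 0, 0, rng_seed = 9)
    expect_false(any(all0$methylated))
    half <- simulate_methylome(ref, 0.5, 0.5, rng_seed = 10)
    m <- sum(half$methylated); n <- nrow(half)
    expect_lt(abs(m - n / 2), 3 * sqrt(n * 0.25))
    # states are defined for every C and G, both strands
    expect_setequal(unique(half$strand), c("+", "-"))
    expect_true(all(half$context %in% c("CpG", "CHG", "CHH")))
})

test_that("full conversion of an unmethylated genome leaves no fwd-CT cytosine", {
    ref <- preprocess_reference(simulate_genome(5000, 0.5, rng_seed = 11))
    meth0 <- simulate_methylome(ref, 0, 0, rng_seed = 12)
    sim <- simulate_reads(ref, meth0, coverage = 2, read_length = 60,
                          conversion_efficiency = 1, error_rate = 0,
                          rng_seed = 13)
    watson1 <- sim$reads1[sim$truth[mate == 1]$mode == "CT"]
    expect_false(any(grepl("C", watson1)))
    # and the mates of Crick fragments (also C->T converted in read space)
    crick2 <- sim$reads2[sim$truth[mate == 2]$mode == "GA"]
    expect_false(any(grepl("G", crick2)))
})

test_that("null conversion reproduces the untreated genome fragments", {
    ref <- preprocess_reference(simulate_genome(5000, 0.5, rng_seed = 14))
    meth0 <- simulate_methylome(ref, 0, 0, rng_seed = 15)
    sim <- simulate_reads(ref, meth0, coverage = 2, read_length = 50,
                          conversion_efficiency = 0, error_rate = 0,
                          rng_seed = 16)
    tr <- sim$truth[mate == 1]
    for (i in seq_len(5)) {
        frag <- substr(ref$text, tr$pos[i] + 1, tr$pos[i] + 50)
        got <- if (tr$mode[i] == "CT") sim$reads1[i] else revcomp(sim$reads1[i])
        expect_identical(got, frag)
    }
})

test_that("read count matches the requested coverage", {
    ref <- preprocess_reference(simulate_genome(100000, 0.4, rng_seed = 17))
    meth <- simulate_methylome(ref, rng_seed = 18)
    sim <- simulate_reads(ref, meth, coverage = 20, read_length = 100,
                          rng_seed = 19)
    total <- sum(nchar(sim$reads1)) + sum(nchar(sim$reads2))
    expect_lt(abs(total - 2e6) / 2e6, 0.01)
})

test_that("identical seeds give byte-identical FASTQ output", {
    ref <- preprocess_reference(simulate_genome(3000, 0.4, rng_seed = 20))
    meth <- simulate_methylome(ref, rng_seed = 21)
    f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
    s1 <- simulate_reads(ref, meth, coverage = 3, read_length = 60,
                         rng_seed = 22, fastq1 = f1)
    s2 <- simulate_reads(ref, meth, coverage = 3, read_length = 60,
                         rng_seed = 22, fastq1 = f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(s1$truth, s2$truth)
    # and FASTQ written gzipped decompresses to the same records
    fgz <- tempfile(fileext = ".fastq.gz")
    simulate_reads(ref, meth, coverage = 3, read_length = 60,
                   rng_seed = 22, fastq1 = fgz)
    rt <- read_fastq(fgz)
    expect_identical(rt$seqs, unname(s1$reads1))
    expect_identical(rt$ids, unname(s1$ids))
})

test_that("evaluate_mapping applies the contig+mode+tolerance rule", {
    truth <- data.table::data.table(
        read_id = c("a", "b", "c", "d"), mate = 1L, contig = "c",
        pos = c(100L, 100L, 100L, 100L), mode = "CT")
    mkaln <- function(id, pos, mode, status = "unique") data.table::data.table(
        read_id = id, mate = 1L, contig = "c", pos = pos, gpos = pos,
        strand = "+", mode = mode, mism = 0L, status = status, nbest = 1L,
        proper = NA, rescued = FALSE, seq = "A", seq_fwd = "A", qual = "I",
        len = 1L, paired = FALSE)
    aln <- rbind(mkaln("a", 150L, "CT"),          # +50: correct
                 mkaln("b", 151L, "CT"),          # +51: incorrect
                 mkaln("c", 100L, "GA"),          # wrong mode: incorrect
                 mkaln("d", 100L, "CT", "multiple"))
    ev <- evaluate_mapping(aln, truth, tolerance = 50)
    expect_equal(ev$unique_fraction, 3 / 4)
    expect_equal(ev$correct_fraction, 1 / 3)
    expect_error(evaluate_mapping(mkaln("zz", 1L, "CT"), truth), "missing")
})

test_that("evaluate_methylation gates on coverage and uses the strict rule", {
    truth <- data.table::data.table(
        gpos = c(0L, 1L, 2L), strand = "+", methylated = c(TRUE, TRUE, FALSE))
    rec <- data.table::data.table(
        gpos = c(0L, 1L, 2L), strand = "+",
        count_primary = c(2, 2, 0), count_converted = c(0, 2, 4))
    rec[, coverage := count_primary + count_converted]
    rec[, beta := beta_score(count_primary, count_converted)]
    ev <- evaluate_methylation(rec, truth, min_coverage = 3)
    # site 0 has coverage 2: excluded; site 1 beta = 0.5 vs methylated:
    # an error under the strict rule; site 2 beta = 0: correct
    expect_equal(ev$covered_fraction, 2 / 3)
    expect_equal(ev$accuracy, 1 / 2)
    expect_equal(ev$n_covered, 2L)
})

test_that("the noise-free pipeline recovers every covered state exactly", {
    g <- simulate_genome(15000, 0.42, rng_seed = 23)
    ref <- preprocess_reference(g, rng_seed = 23)
    meth <- simulate_methylome(ref, rng_seed = 24)
    sim <- simulate_reads(ref, meth, coverage = 6, read_length = 80,
                          conversion_efficiency = 1, error_rate = 0,
                          rng_seed = 25)
    idx <- build_index(ref)
    aln <- align_pairs(idx, sim$reads1, sim$reads2, ids = sim$ids)
    counts <- process_alignments(aln, ref)
    rec <- methylation_records(counts)
    ev <- evaluate_methylation(rec, meth, min_coverage = 1)
    expect_equal(ev$accuracy, 1.0)
    evm <- evaluate_mapping(aln, sim$truth)
    expect_equal(evm$correct_fraction, 1.0)
})
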