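# Seed-and-extend alignment over the dB-hash index.

small_index <- function(text, m = 3, w = 2, name = "c1") {
    build_index(preprocess_reference(stats::setNames(text, name)),
                hash_params(m, w))
}

test_that("bs_match applies the asymmetric conversion rules", {
    expect_true(bs_match("C", "T", "CT"))    # unmethylated, converted
    expect_false(bs_match("T", "C", "CT"))   # conversion is one-way
    expect_true(bs_match("G", "A", "GA"))
    expect_false(bs_match("A", "G", "GA"))
    expect_true(all(bs_match(c("A", "C", "G", "T"), c("A", "C", "G", "T"), "CT")))
    expect_false(bs_match("C", "T", "GA"))
    expect_error(bs_match("N", "A", "CT"), "A,C,G,T")
})

test_that("align_read finds exact and bisulfite-converted placements", {
    idx <- small_index("AACGT")
    par <- align_params(seed_errors = 0, seed_length = 3, max_mismatches = 0)
    a <- align_read(idx, "ACG", params = par)
    # the read matches at position 1 fwd-CT and, reverse-complemented
    # (CGT), at position 2 rev-GA: two tied placements, leftmost reported
    expect_identical(a$pos, 1L)
    expect_identical(a$mode, "CT")
    expect_identical(a$mism, 0L)
    expect_identical(a$status, "multiple")
    expect_identical(a$nbest, 2L)

    # C->T conversion costs nothing: read ATGG over genomic ACGG
    idx2 <- small_index("TTACGGTT", m = 4, w = 3)
    b <- align_read(idx2, "ATGG",
                    params = align_params(0, 4, 0))
    expect_identical(b$pos, 2L)
    expect_identical(b$mism, 0L)
    expect_identical(b$mode, "CT")

    # reverse-strand G->A placement
    d <- align_read(idx2, revcomp("ACGG"),
                    params = align_params(0, 4, 0))
    expect_identical(d$pos, 2L)
    expect_identical(d$mode, "GA")
})

test_that("short reads come back unmapped with a warning", {
    idx <- small_index("ACGTACGTAC", m = 6, w = 4)
    expect_warning(a <- align_read(idx, "ACG",
                                   params = align_params(2, 6, 2)),
                   "shorter")
    expect_identical(a$status, "unmapped")
})

test_that("align_read equals the brute-force scan on random instances", {
    set.seed(31)
    reftxt <- random_dna(2000)
    ref <- preprocess_reference(c(c = reftxt))
    pp <- hash_params(20, 12)
    idx <- build_index(ref, pp)
    par <- align_params(seed_errors = 1, seed_length = 20, max_mismatches = 3)
    # reads sampled from the text with planted mutations, plus their
    # reverse complements and pure noise
    n <- 60
    starts <- sample(0:(2000 - 50), n)
    reads <- vapply(starts, function(s) {
        r <- substr(reftxt, s + 1, s + 50)
        ch <- strsplit(r, "")[[1]]
        nmut <- sample(0:3, 1)
        pos <- sample(50, nmut)
        for (p in pos) ch[p] <- sample(c("A", "C", "G", "T"), 1)
        paste(ch, collapse = "")
    }, character(1))
    reads <- c(reads, revcomp(reads[1:20]), replicate(10, random_dna(50)))
    got <- align_reads(idx, reads, params = par)
    oracle <- bsdbh:::.cpp_bruteforce_align(
        reads, rep(FALSE, length(reads)), ref$text, pp$m, par$seed_errors,
        rep(3L, length(reads)), ref$contigs$start, ref$contigs$length, 1000L)
    expect_identical(got$status,
                     c("unique", "multiple", "unmapped")[oracle$status + 1L])
    mapped <- got$status != "unmapped"
    expect_identical(got$gpos[mapped], oracle$gpos[mapped])
    expect_identical(got$mism[mapped], oracle$mism[mapped])
    expect_identical(got$nbest[mapped], oracle$nbest[mapped])
})

test_that("align_pairs marks FR same-fragment-strand pairs proper", {
    set.seed(33)
    g <- simulate_genome(5000, 0.5, rng_seed = 41)
    ref <- preprocess_reference(g, rng_seed = 41)
    meth <- simulate_methylome(ref, rng_seed = 42)
    sim <- simulate_reads(ref, meth, coverage = 4, read_length = 60,
                          insert_mean = 300, insert_sd = 0,
                          conversion_efficiency = 1, error_rate = 0,
                          rng_seed = 43)
    idx <- build_index(ref)
    par <- align_params()
    aln <- align_pairs(idx, sim$reads1, sim$reads2, ids = sim$ids, params = par)
    u <- aln[aln$status == "unique"]
    expect_gt(mean(aln$proper), 0.95)
    # proper pairs: mates on the same fragment strand, opposite orientations
    prop <- aln[aln$proper & aln$status == "unique"]
    bothm <- prop[, .N, by = "read_id"][N == 2L]$read_id
    pp2 <- prop[prop$read_id %in% bothm]
    m1 <- pp2[pp2$mate == 1L][order(read_id)]
    m2 <- pp2[pp2$mate == 2L][order(read_id)]
    expect_true(all(m1$mode == m2$mode))
    expect_true(all(m1$strand != m2$strand))
    tlen <- abs(ifelse(m1$mode == "CT",
                       m2$gpos + m2$len - m1$gpos,
                       m1$gpos + m1$len - m2$gpos))
    expect_true(all(tlen >= par$insert_min & tlen <= par$insert_max))
})

test_that("a pair with one unmapped mate is not proper but still reported", {
    idx <- small_index("ACGTACGTACGTACGTACGT", m = 6, w = 3)
    par <- align_params(seed_errors = 0, seed_length = 6, max_mismatches = 0,
                        insert_min = 6, insert_max = 30)
    a <- align_pair(idx, "ACGTAC", strrep("T", 6), params = par)
    expect_identical(a$status[a$mate == 2L], "unmapped")
    expect_false(any(a$proper))
    expect_false(a$status[a$mate == 1L] == "unmapped")
})

test_that("SAM output follows conventions and parses back", {
    idx <- small_index("TTACGGTTAA", m = 4, w = 3)
    par <- align_params(0, 4, 0)
    aln <- align_reads(idx, c("ACGG", "CCCC"), ids = c("r1", "r2"), params = par)
    expect_identical(aln$pos[1], 2L)
    sam <- tempfile(fileext = ".sam")
    write_sam(aln, idx$reference, sam)
    lines <- readLines(sam)
    expect_true(any(startsWith(lines, "@SQ\tSN:c1\tLN:10")))
    body <- lines[!startsWith(lines, "@")]
    f1 <- strsplit(body[1], "\t")[[1]]
    expect_identical(f1[4], "3")          # 0-based 2 -> POS 3
    expect_identical(f1[6], "4M")
    expect_true("NM:i:0" %in% f1)
    f2 <- strsplit(body[2], "\t")[[1]]
    expect_identical(f2[2], "4")          # unmapped flag
    expect_identical(f2[4], "0")
    back <- parse_sam(sam, idx$reference)
    expect_identical(back$pos, aln$pos)
    expect_identical(back$status, aln$status)
    expect_identical(back$mode, aln$mode)
    expect_error(write_sam(data.table::data.table(aln)[, contig := "nope"],
                           idx$reference, tempfile()), "absent")
})

test_that("alignment is deterministic across repeated runs", {
    set.seed(55)
    g <- simulate_genome(3000, 0.4, rng_seed = 51)
    ref <- preprocess_reference(g, rng_seed = 51)
    meth <- simulate_methylome(ref, rng_seed = 52)
    sim <- simulate_reads(ref, meth, coverage = 3, read_length = 70,
                          rng_seed = 53)
    idx <- build_index(ref)
    a1 <- align_pairs(idx, sim$reads1, sim$reads2, ids = sim$ids)
    a2 <- align_pairs(idx, sim$reads1, sim$reads2, ids = sim$ids)
    expect_identical(a1, a2)
    s1 <- tempfile(); s2 <- tempfile()
    write_sam(a1, ref, s1); write_sam(a2, ref, s2)
    expect_identical(readLines(s1), readLines(s2))
})
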