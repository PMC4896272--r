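# Synthetic directional BS-seq data: random genome, binary per-cytosine
# methylome, paired reads with bisulfite conversion failures and uniform
# sequencing errors, plus the ground truth needed for evaluation.
#
# The generator emulates a directional library: each fragment derives from
# the Watson or Crick strand with equal probability; read 1 reads the
# bisulfite-converted fragment strand from its 5' end (C-to-T pattern on
# that strand), read 2 the complementary strand (G-to-A pattern).  Every
# unmethylated cytosine of the fragment strand converts to T independently
# with probability `conversion_efficiency`; methylated cytosines never
# convert.  Substitution errors are uniform and applied after conversion.

#' Simulate a random genome
#'
#' @param length genome length in bases (>= 1000).
#' @param gc_content target GC fraction (default 0.36, human-like).
#' @param rng_seed integer seed; identical seeds give identical genomes.
#' @param name contig name.
#' @param path optional FASTA output path.
#' @return a [Biostrings::DNAStringSet] with one contig.
#' @export
simulate_genome <- function(length, gc_content = 0.36, rng_seed = 1L,
                            name = "sim_1", path = NULL) {
    fail_if(!is_count(length) || length < 1000,
            "genome length must be an integer >= 1000 (1 kbp)")
    fail_if(!is.numeric(gc_content) || gc_content < 0 || gc_content > 1,
            "gc_content must be in [0, 1]")
    probs <- c((1 - gc_content) / 2, gc_content / 2,
               gc_content / 2, (1 - gc_content) / 2)
    seq <- with_rng_seed(rng_seed, paste(
        sample(BASES, length, replace = TRUE, prob = probs), collapse = ""))
    out <- Biostrings::DNAStringSet(stats::setNames(seq, name))
    if (!is.null(path)) Biostrings::writeXStringSet(out, path)
    out
}

as_reference <- function(genome, rng_seed = 1L) {
    if (inherits(genome, "EncodedReference")) genome
    else preprocess_reference(genome, rng_seed = rng_seed)
}

#' Simulate a binary methylome
#'
#' Independent Bernoulli methylation state for every cytosine on both
#' strands, with context-dependent rates: CpG cytosines are methylated
#' with probability `p_meth_cpg`, all others with `p_meth_non_cpg`.
#' Binary states keep "correctly called" well-defined under the strict
#' beta > 0.5 rule.
#'
#' @param genome an `EncodedReference`, `DNAStringSet` or FASTA path.
#' @param p_meth_cpg methylation probability in CpG context (default 0.8).
#' @param p_meth_non_cpg probability elsewhere (default 0.05).
#' @param rng_seed integer seed.
#' @return `data.table` with one row per cytosine: `gpos` (0-based global),
#'   `contig`, `pos`, `strand`, `context`, `methylated` (logical).
#' @export
simulate_methylome <- function(genome, p_meth_cpg = 0.8, p_meth_non_cpg = 0.05,
                               rng_seed = 2L) {
    fail_if(p_meth_cpg < 0 || p_meth_cpg > 1 || p_meth_non_cpg < 0 ||
                p_meth_non_cpg > 1, "probabilities must be in [0, 1]")
    ref <- as_reference(genome)
    gpos <- as.integer(gregexpr("[CG]", ref$text)[[1]]) - 1L
    if (length(gpos) == 1 && gpos[1] == -2L) gpos <- integer(0)
    strand <- ifelse(substring(ref$text, gpos + 1, gpos + 1) == "C", "+", "-")
    ctx <- as.character(classify_context(ref, gpos, strand))
    p <- ifelse(ctx == "CpG", p_meth_cpg, p_meth_non_cpg)
    st <- with_rng_seed(rng_seed, stats::rbinom(length(gpos), 1L, p) == 1L)
    loc <- global_to_contig(ref, gpos)
    data.table::data.table(gpos = gpos, contig = loc$contig, pos = loc$pos,
                           strand = strand, context = ctx, methylated = st)
}

# collapse a code matrix (1..4 = ACGT) to strings, one per row
codes_to_strings <- function(mat) {
    cols <- lapply(seq_len(ncol(mat)), function(j) BASES[mat[, j]])
    do.call(paste0, cols)
}

#' Simulate directional BS-seq reads
#'
#' Fragments are drawn uniformly (per contig, proportionally to contig
#' length), assigned to the Watson or Crick strand with equal probability
#' and bisulfite-converted as described above; each mate's conversion and
#' error draws are independent.  Read origins (contig, 0-based leftmost
#' forward-strand position of each mate, fragment conversion mode) are
#' encoded in the read names (`id:contig:pos1:pos2:mode`) and returned as
#' a truth table.
#'
#' @inheritParams simulate_methylome
#' @param methylome a [simulate_methylome()] table over the same genome.
#' @param coverage target mean base coverage (e.g. 24.6).
#' @param read_length read length in bases (default 100).
#' @param paired paired-end library (default TRUE).
#' @param insert_mean,insert_sd fragment-length normal draw (defaults 300
#'   and 50); fragments are clipped to `[read_length, contig length]`.
#' @param conversion_efficiency probability that an unmethylated cytosine
#'   is converted (default 0.98).
#' @param error_rate uniform substitution error probability per base
#'   (default 0.01).
#' @param rng_seed integer seed.
#' @param fastq1,fastq2 optional FASTQ(.gz) output paths.
#' @param truth_path optional TSV output path for the truth table.
#' @return list with `ids`, `reads1`, `quals1`, `reads2`, `quals2` (NULL
#'   when unpaired), `truth` (`data.table`: `read_id`, `mate`, `contig`,
#'   `pos`, `mode`) and the resolved `params`.
#' @export
simulate_reads <- function(genome, methylome, coverage, read_length = 100L,
                           paired = TRUE, insert_mean = 300, insert_sd = 50,
                           conversion_efficiency = 0.98, error_rate = 0.01,
                           rng_seed = 3L, fastq1 = NULL, fastq2 = NULL,
                           truth_path = NULL) {
    ref <- as_reference(genome)
    fail_if(!is.numeric(coverage) || coverage <= 0, "coverage must be > 0")
    fail_if(read_length > min(ref$contigs$length),
            "read_length exceeds the shortest contig")
    fail_if(conversion_efficiency < 0 || conversion_efficiency > 1,
            "conversion_efficiency must be in [0, 1]")
    fail_if(error_rate < 0 || error_rate > 1, "error_rate must be in [0, 1]")
    L <- as.integer(read_length)
    n <- ref$n
    codes <- match(strsplit(ref$text, "", fixed = TRUE)[[1]], BASES)
    st_plus <- rep(NA, n)   # methylation state of + strand Cs
    st_minus <- rep(NA, n)  # of - strand Gs
    mp <- methylome[strand == "+"]; mm <- methylome[strand == "-"]
    st_plus[mp$gpos + 1L] <- mp$methylated
    st_minus[mm$gpos + 1L] <- mm$methylated
    npair <- max(1L, as.integer(round(coverage * n / ((if (paired) 2 else 1) * L))))
    res <- with_rng_seed(rng_seed, {
        ci <- sample.int(nrow(ref$contigs), npair, replace = TRUE,
                         prob = ref$contigs$length)
        clen <- ref$contigs$length[ci]
        cstart <- ref$contigs$start[ci]
        watson <- runif(npair) < 0.5
        flen <- if (paired) {
            pmin(clen, pmax(L, as.integer(round(rnorm(npair, insert_mean, insert_sd)))))
        } else rep(L, npair)
        s <- cstart + floor(runif(npair) * (clen - flen + 1))  # global 0-based
        e <- s + flen
        # forward-projected spans: A = [s, s+L), B = [e-L, e)
        idxA <- outer(s, 0:(L - 1L), "+") + 1L
        baseA <- matrix(codes[idxA], nrow = npair)
        convert <- function(basemat, idxmat) {
            # Watson rows: unmethylated C (code 2) -> T (4)
            # Crick rows:  unmethylated G (code 3) -> A (1)
            wrow <- matrix(watson, nrow = npair, ncol = L)
            isC <- basemat == 2L & wrow
            isG <- basemat == 3L & !wrow
            candC <- which(isC & !is.na(st_plus[idxmat]) & !st_plus[idxmat])
            candG <- which(isG & !is.na(st_minus[idxmat]) & !st_minus[idxmat])
            basemat[candC[runif(length(candC)) < conversion_efficiency]] <- 4L
            basemat[candG[runif(length(candG)) < conversion_efficiency]] <- 1L
            if (error_rate > 0) {
                err <- which(runif(length(basemat)) < error_rate)
                basemat[err] <- ((basemat[err] - 1L +
                                      sample.int(3L, length(err), replace = TRUE)) %% 4L) + 1L
            }
            basemat
        }
        baseA <- convert(baseA, idxA)
        strA <- codes_to_strings(baseA)
        if (paired) {
            idxB <- outer(e - L, 0:(L - 1L), "+") + 1L
            baseB <- convert(matrix(codes[idxB], nrow = npair), idxB)
            # reverse complement of span B, rowwise
            strB_rc <- codes_to_strings((5L - baseB)[, L:1, drop = FALSE])
        }
        list(ci = ci, watson = watson, s = s, e = e, strA = strA,
             strB_rc = if (paired) strB_rc else NULL)
    })
    contig <- ref$contigs$name[res$ci]
    cstart <- ref$contigs$start[res$ci]
    mode <- ifelse(res$watson, "CT", "GA")
    if (paired) {
        pos1 <- ifelse(res$watson, res$s, res$e - L) - cstart
        pos2 <- ifelse(res$watson, res$e - L, res$s) - cstart
        reads1 <- ifelse(res$watson, res$strA, res$strB_rc)
        reads2 <- ifelse(res$watson, res$strB_rc, res$strA)
    } else {
        pos1 <- res$s - cstart
        pos2 <- NA_integer_
        # single-end Crick reads are the reverse complement of their span
        reads1 <- ifelse(res$watson, res$strA,
                         revcomp(res$strA))
        reads2 <- NULL
    }
    ids <- sprintf("sr%07d:%s:%d:%s", seq_len(length(res$s)), contig,
                   pos1, mode)
    if (paired) ids <- sprintf("sr%07d:%s:%d:%d:%s", seq_len(length(res$s)),
                               contig, pos1, pos2, mode)
    quals <- strrep("I", L)
    truth <- data.table::data.table(read_id = ids, mate = 1L, contig = contig,
                                    pos = as.integer(pos1), mode = mode)
    if (paired)
        truth <- rbind(truth,
                       data.table::data.table(read_id = ids, mate = 2L,
                                              contig = contig,
                                              pos = as.integer(pos2), mode = mode))
    if (!is.null(fastq1)) write_fastq(ids, reads1, rep(quals, length(ids)), fastq1)
    if (paired && !is.null(fastq2))
        write_fastq(ids, reads2, rep(quals, length(ids)), fastq2)
    if (!is.null(truth_path))
        data.table::fwrite(truth, truth_path, sep = "\t")
    list(ids = ids, reads1 = reads1, quals1 = rep(quals, length(ids)),
         reads2 = reads2,
         quals2 = if (paired) rep(quals, length(ids)) else NULL,
         truth = truth,
         params = list(coverage = coverage, read_length = L, paired = paired,
                       insert_mean = insert_mean, insert_sd = insert_sd,
                       conversion_efficiency = conversion_efficiency,
                       error_rate = error_rate, rng_seed = rng_seed,
                       n_fragments = length(res$s)))
}
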