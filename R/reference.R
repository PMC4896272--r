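# Reference pre-processing: contigs are concatenated into one text and all
# N (and any other non-ACGT) characters are replaced by random bases drawn
# with a recorded seed, as the index has no symbol for them.

#' Load and encode a reference genome
#'
#' Reads a (possibly multi-contig, wrapped, gzipped) FASTA file,
#' concatenates the contigs in file order into a single text and replaces
#' every character outside `{A,C,G,T}` (undefined bases, end markers) by a
#' base drawn uniformly at random with the recorded seed, so the result is
#' reproducible.  The per-contig coordinate map is retained for reporting.
#'
#' @param fasta_source path to a FASTA file, a
#'   [Biostrings::DNAStringSet], or a named character vector of contig
#'   sequences.
#' @param rng_seed integer seed used for the N randomization.
#' @return an object of class `EncodedReference`: list with `text` (single
#'   string over ACGT), `contigs` (data.frame `name`, `start` 0-based,
#'   `length`), `rng_seed`, `n`.
#' @examples
#' ref <- preprocess_reference(c(chr1 = "ACNGT"), rng_seed = 7)
#' ref$contigs
#' @export
preprocess_reference <- function(fasta_source, rng_seed = 1L) {
    fail_if(!is_count(rng_seed), "rng_seed must be an integer")
    if (is.character(fasta_source) && length(fasta_source) == 1 &&
        is.null(names(fasta_source))) {
        fail_if(!file.exists(fasta_source),
                sprintf("FASTA file not found: %s", fasta_source))
        seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_source),
                         error = function(e) stop("malformed FASTA: ",
                                                  conditionMessage(e), call. = FALSE))
        seqs <- as.character(seqs)
        # FASTA headers may carry descriptions; keep the first word
        names(seqs) <- sub("\\s.*$", "", names(seqs))
    } else if (methods::is(fasta_source, "DNAStringSet")) {
        seqs <- as.character(fasta_source)
    } else if (is.character(fasta_source)) {
        seqs <- fasta_source
        fail_if(length(seqs) == 0, "empty reference: no contigs found")
        if (is.null(names(seqs)))
            names(seqs) <- paste0("contig", seq_along(seqs))
    } else {
        stop("fasta_source must be a FASTA path, DNAStringSet or character vector",
             call. = FALSE)
    }
    fail_if(length(seqs) == 0, "empty reference: no contigs found")
    fail_if(any(nchar(seqs) == 0), "empty reference contig")
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    text <- paste(seqs, collapse = "")
    bad <- gregexpr("[^ACGT]", text)[[1]]
    if (bad[1] != -1L) {
        repl <- with_rng_seed(rng_seed,
                              sample(BASES, length(bad), replace = TRUE))
        chars <- strsplit(text, "", fixed = TRUE)[[1]]
        chars[bad] <- repl
        text <- paste(chars, collapse = "")
    }
    contigs <- data.frame(name = unname(names(seqs)),
                          start = as.integer(cumsum(c(0L, lens[-length(lens)]))),
                          length = as.integer(unname(lens)),
                          stringsAsFactors = FALSE)
    rownames(contigs) <- NULL
    structure(list(text = text, contigs = contigs,
                   rng_seed = as.integer(rng_seed), n = sum(lens)),
              class = "EncodedReference")
}

#' @export
print.EncodedReference <- function(x, ...) {
    cat(sprintf("EncodedReference: %d contig(s), %d bases (rng_seed %d)\n",
                nrow(x$contigs), x$n, x$rng_seed))
    invisible(x)
}

# global 0-based position -> contig index (1-based row of ref$contigs)
contig_index_of <- function(ref, gpos) {
    findInterval(gpos, ref$contigs$start)
}

# global 0-based positions -> (contig name, 0-based contig position)
global_to_contig <- function(ref, gpos) {
    ci <- contig_index_of(ref, gpos)
    list(contig = ref$contigs$name[ci],
         pos = gpos - ref$contigs$start[ci])
}

# (contig name, 0-based position) -> global position
contig_to_global <- function(ref, contig, pos) {
    ci <- match(contig, ref$contigs$name)
    fail_if(anyNA(ci), "unknown contig name")
    ref$contigs$start[ci] + pos
}
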