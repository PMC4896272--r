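# The dB-hash index: the reference text plus a direct-address CSR table
# mapping each w-bit fingerprint to the ascending list of text positions
# whose m-window hashes to it.

MAX_INDEX_W <- 26L  # 2^w + 1 bucket offsets must stay desk-scale

#' Build a dB-hash index over an encoded reference
#'
#' Computes the fingerprint of every length-`m` window of the concatenated
#' text and stores, for each of the `2^w` possible fingerprints, the
#' ascending list of window positions.  Every position in
#' `[0, n - m]` lands in exactly one bucket, so a pattern occurring in the
#' text is always retrievable through its own fingerprint (no false
#' negatives).
#'
#' @param ref an [preprocess_reference()] result.
#' @param params a [hash_params()] object; defaults to seed length 30 and
#'   [default_w()] of the reference length.
#' @return an object of class `DBHashIndex`.
#' @examples
#' ref <- preprocess_reference(c(c1 = "AACGT"))
#' idx <- build_index(ref, hash_params(3, 2))
#' lookup(idx, 3)   # positions hashing to bits 11
#' @export
build_index <- function(ref, params = NULL) {
    fail_if(!inherits(ref, "EncodedReference"), "ref must be an EncodedReference")
    if (is.null(params)) params <- hash_params(30L, default_w(ref$n))
    fail_if(!inherits(params, "HashParams"), "params must be a HashParams object")
    fail_if(ref$n < params$m, "reference shorter than the seed length m")
    fail_if(params$w > MAX_INDEX_W,
            sprintf("bucket table for w = %d would exceed desk scale (max w = %d)",
                    params$w, MAX_INDEX_W))
    b <- .cpp_build_buckets(ref$text, params$m, params$w)
    structure(list(params = params, reference = ref,
                   bucket_start = b$bucket_start, positions = b$positions),
              class = "DBHashIndex")
}

#' @export
print.DBHashIndex <- function(x, ...) {
    cat(sprintf(
        "DBHashIndex: m = %d, w = %d; %d positions over %d buckets (%d contigs, n = %d)\n",
        x$params$m, x$params$w, length(x$positions),
        length(x$bucket_start) - 1L, nrow(x$reference$contigs), x$reference$n))
    invisible(x)
}

#' Query a fingerprint bucket
#'
#' @param index a [build_index()] result.
#' @param g a `Fingerprint` (its width must equal the index width) or a
#'   plain numeric fingerprint value.
#' @return ascending integer vector of 0-based text positions whose
#'   m-window fingerprint equals `g`; empty for absent fingerprints.
#' @export
lookup <- function(index, g) {
    fail_if(!inherits(index, "DBHashIndex"), "index must be a DBHashIndex")
    w <- index$params$w
    if (inherits(g, "Fingerprint")) {
        fail_if(g$width != w,
                sprintf("fingerprint width %d does not match index width %d",
                        g$width, w))
        g <- g$value
    }
    fail_if(!is.numeric(g) || length(g) != 1 || is.na(g) || g < 0 || g >= 2^w,
            "fingerprint value outside the index codomain")
    from <- index$bucket_start[g + 1] + 1L
    to <- index$bucket_start[g + 2]
    if (to < from) integer(0) else index$positions[from:to]
}

INDEX_MAGIC <- charToRaw("DBHI")
INDEX_VERSION <- 1L

#' Persist / restore a dB-hash index
#'
#' The container is a small versioned binary file (magic `DBHI`,
#' little-endian 4-byte integers) holding the hash parameters, the contig
#' table, the randomization seed, the bucket table and the encoded text.
#' `load_index(save_index(x))` reproduces the index exactly.
#'
#' @param index a `DBHashIndex`.
#' @param path file path.
#' @return `save_index()`: `path`, invisibly.  `load_index()`: the restored
#'   `DBHashIndex`.
#' @export
save_index <- function(index, path) {
    fail_if(!inherits(index, "DBHashIndex"), "index must be a DBHashIndex")
    con <- file(path, "wb")
    on.exit(close(con))
    wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
    writeBin(INDEX_MAGIC, con)
    wi(INDEX_VERSION)
    wi(c(index$params$m, index$params$w,
         index$reference$rng_seed, index$reference$n,
         nrow(index$reference$contigs)))
    for (i in seq_len(nrow(index$reference$contigs))) {
        nm <- charToRaw(index$reference$contigs$name[i])
        wi(length(nm)); writeBin(nm, con)
        wi(c(index$reference$contigs$start[i], index$reference$contigs$length[i]))
    }
    wi(length(index$bucket_start)); wi(index$bucket_start)
    wi(length(index$positions)); wi(index$positions)
    writeBin(charToRaw(index$reference$text), con)
    invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
    fail_if(!file.exists(path), sprintf("index file not found: %s", path))
    con <- file(path, "rb")
    on.exit(close(con))
    ri <- function(k) {
        v <- readBin(con, "integer", n = k, size = 4L, endian = "little")
        fail_if(length(v) != k, "truncated index file")
        v
    }
    magic <- readBin(con, "raw", n = 4L)
    fail_if(length(magic) != 4L || !identical(magic, INDEX_MAGIC),
            "not a dB-hash index file (bad magic)")
    ver <- ri(1)
    fail_if(ver != INDEX_VERSION, sprintf("unsupported index version %d", ver))
    hdr <- ri(5)
    m <- hdr[1]; w <- hdr[2]; rng_seed <- hdr[3]; n <- hdr[4]; nc <- hdr[5]
    contigs <- vector("list", nc)
    for (i in seq_len(nc)) {
        nl <- ri(1)
        nm <- readBin(con, "raw", n = nl)
        fail_if(length(nm) != nl, "truncated index file")
        sl <- ri(2)
        contigs[[i]] <- data.frame(name = rawToChar(nm), start = sl[1],
                                   length = sl[2], stringsAsFactors = FALSE)
    }
    contigs <- do.call(rbind, contigs)
    nb <- ri(1); bucket_start <- ri(nb)
    np <- ri(1); positions <- ri(np)
    traw <- readBin(con, "raw", n = n)
    fail_if(length(traw) != n, "truncated index file")
    ref <- structure(list(text = rawToChar(traw), contigs = contigs,
                          rng_seed = rng_seed, n = n),
                     class = "EncodedReference")
    structure(list(params = hash_params(m, w), reference = ref,
                   bucket_start = bucket_start, positions = positions),
              class = "DBHashIndex")
}
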