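#' @include AllGenerics.R
#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement
#' @useDynLib strainscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.check_k <- function(k) {
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k <= 1L || k > 31L)
        stop("k must be a single integer in (1, 31]")
    if (k %% 2L == 0L)
        stop("k must be odd (even k allows canonical ties with ",
             "self-reverse-complementary k-mers)")
    k
}

.as_read_strings <- function(reads) {
    if (is(reads, "XStringSet")) return(as.character(reads))
    if (is.character(reads)) {
        looks_like_file <- length(reads) > 0L &&
            all(grepl("\\.(fa|fasta|fna|fq|fastq)(\\.gz)?$", reads,
                      ignore.case = TRUE))
        if (looks_like_file && all(file.exists(reads))) {
            seqs <- unlist(lapply(reads, function(f) {
                fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", f,
                                 ignore.case = TRUE)) "fastq" else "fasta"
                as.character(readDNAStringSet(f, format = fmt))
            }))
            return(unname(seqs))
        }
        return(reads)
    }
    stop("reads must be a character vector, an XStringSet, or FASTA/FASTQ paths")
}

#' Canonicalize k-mers
#'
#' Maps each window to the lexicographically smaller of itself and its
#' reverse complement under A < C < G < T, giving a strand-neutral k-mer
#' identity. Windows containing any non-ACGT symbol return `NA`, which
#' callers interpret as "skip this window".
#'
#' @param x character vector of DNA windows (any length; case-insensitive).
#' @return character vector of canonical forms, `NA` where ambiguous.
#' @examples
#' canonicalizeKmer(c("CGT", "ACG", "ANA"))  # "ACG" "ACG" NA
#' @export
canonicalizeKmer <- function(x) {
    if (is(x, "XStringSet")) x <- as.character(x)
    cpp_canonicalize(as.character(x))
}

#' Count canonical k-mers in reads
#'
#' Slides a window of length k over every read and increments the count of
#' the window's canonical form. Windows containing an ambiguous base are
#' skipped entirely. Results are independent of read order and of how the
#' reads are split across files.
#'
#' @param reads character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or paths to FASTA/FASTQ files
#'   (gzip-transparent).
#' @param k odd integer k-mer length, 1 < k <= 31; the pipeline default
#'   is 27.
#' @param sampleId sample label stored in the result.
#' @return a [KmerTable].
#' @examples
#' countKmers("ACGTACGT", k = 3)  # ACG x4, GTA x2
#' @export
countKmers <- function(reads, k = 27L, sampleId = "sample") {
    k <- .check_k(k)
    reads <- .as_read_strings(reads)
    res <- cpp_count_kmers(reads, k)
    counts <- res$count
    names(counts) <- res$kmer
    new("KmerTable", k = k, counts = counts,
        sampleId = as.character(sampleId)[1L])
}

#' k-mer histogram of a KmerTable
#'
#' Tabulates, for each occurrence count c, the number of distinct k-mers
#' with that count. The histogram's values sum to the number of distinct
#' k-mers in the table.
#'
#' @param table a [KmerTable].
#' @return a [KmerHistogram].
#' @examples
#' kmerHistogram(countKmers("ACGTACGT", k = 3))  # c=2:1, c=4:1
#' @export
kmerHistogram <- function(table) {
    stopifnot(is(table, "KmerTable"))
    if (!length(table@counts))
        return(new("KmerHistogram", occ = integer(0), n = numeric(0)))
    tab <- table(table@counts)
    new("KmerHistogram", occ = as.integer(names(tab)),
        n = as.numeric(tab))
}

#' Infer the genome-membership threshold T from a k-mer histogram
#'
#' Sequencing errors produce a large mass of low-count k-mers while true
#' genomic k-mers cluster around the coverage peak; the two modes are
#' separated by a valley. T is chosen as the occurrence count c in
#' `[2, c_peak]` minimising the histogram, where `c_peak` is the location
#' of the histogram maximum over c >= 3 (the coverage peak). Ties break
#' toward smaller c. Occurrence counts absent from the histogram are
#' treated as 0 only when flanked by occupied counts on both sides,
#' otherwise excluded. When the histogram is monotone decreasing (no
#' coverage peak), the fallback T = 3 is returned with a low-confidence
#' flag.
#'
#' @param histogram a [KmerHistogram]; must be non-empty.
#' @return list with integer `threshold` and logical `lowConfidence`.
#' @examples
#' # error mode at c = 1, valley at c = 4, coverage peak at c = 30
#' h <- new("KmerHistogram", occ = 1:30,
#'          n = c(1e6, 1e5, 2e4, 1.5e4, 1.8e4,
#'                2e4 + (6:30 - 6) / 24 * 7e4))
#' inferThreshold(h)$threshold  # 4
#' @export
inferThreshold <- function(histogram) {
    stopifnot(is(histogram, "KmerHistogram"))
    occ <- histogram@occ
    n <- histogram@n
    if (!length(occ)) stop("cannot infer a threshold from an empty histogram")

    # monotone-decreasing spectrum (counts >= 2): no coverage peak
    i2 <- which(occ >= 2L)
    if (!length(i2) || all(diff(n[i2]) <= 0) && all(diff(n) <= 0))
        return(list(threshold = 3L, lowConfidence = TRUE))

    i3 <- which(occ >= 3L)
    if (!length(i3))
        return(list(threshold = 3L, lowConfidence = TRUE))
    c_peak <- occ[i3][which.max(n[i3])]
    if (c_peak <= 2L)
        return(list(threshold = 3L, lowConfidence = TRUE))

    # candidate grid [2, c_peak]; missing counts are 0 only when flanked
    grid <- 2:c_peak
    val <- rep(NA_real_, length(grid))
    hit <- match(grid, occ)
    val[!is.na(hit)] <- n[hit[!is.na(hit)]]
    flanked <- grid > min(occ) & grid < max(occ)
    val[is.na(hit) & flanked] <- 0
    keep <- !is.na(val)
    if (!any(keep))
        return(list(threshold = 3L, lowConfidence = TRUE))
    grid <- grid[keep]; val <- val[keep]
    Tval <- grid[which.min(val)]  # which.min ties break toward smaller c
    list(threshold = as.integer(Tval), lowConfidence = FALSE)
}

#' Thresholded k-mer set of one individual
#'
#' A k-mer belongs to the individual's genome when its occurrence count is
#' at least T.
#'
#' @param table a [KmerTable].
#' @param threshold integer T >= 1, or `NULL` to infer it from the
#'   histogram with [inferThreshold()].
#' @return an [IndividualKmerSet].
#' @examples
#' tab <- countKmers("ACGTACGT", k = 3)
#' members(individualSet(tab, threshold = 3))  # "ACG"
#' @export
individualSet <- function(table, threshold = NULL) {
    stopifnot(is(table, "KmerTable"))
    lowconf <- FALSE
    if (is.null(threshold)) {
        inf <- inferThreshold(kmerHistogram(table))
        threshold <- inf$threshold
        lowconf <- inf$lowConfidence
    }
    threshold <- as.integer(threshold)
    if (length(threshold) != 1L || is.na(threshold) || threshold < 1L)
        stop("threshold must be a single integer >= 1")
    mem <- names(table@counts)[table@counts >= threshold]
    new("IndividualKmerSet", k = table@k, members = as.character(mem),
        threshold = threshold, lowConfidence = lowconf,
        sampleId = table@sampleId)
}

#' Serialize a KmerTable or KmerHistogram to TSV
#'
#' `writeKmerTable()` writes sorted (kmer, count) rows; `writeHistogram()`
#' writes (c, n_kmers) rows. Both are plain TSV with a header, suitable as
#' test goldens.
#'
#' @param x a [KmerTable] or [KmerHistogram].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeKmerTable <- function(x, path) {
    stopifnot(is(x, "KmerTable"))
    df <- data.frame(kmer = names(x@counts), count = unname(x@counts))
    df <- df[order(df$kmer), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeKmerTable
#' @export
writeHistogram <- function(x, path) {
    stopifnot(is(x, "KmerHistogram"))
    utils::write.table(data.frame(c = x@occ, n_kmers = x@n), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
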