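#' @import methods
#' @importClassesFrom GenomicRanges GRanges CompressedGRangesList
NULL

#' KmerTable: canonical k-mer occurrence counts for one sample
#'
#' Holds the exact occurrence count of every distinct canonical k-mer seen
#' in the reads of one individual. Keys are canonical: each stored k-mer is
#' the lexicographically smaller of itself and its reverse complement
#' (A < C < G < T), so counting is strand-neutral.
#'
#' @slot k odd integer k-mer length (default pipeline value 27).
#' @slot counts named integer vector, names are canonical k-mers, values
#'   are occurrence counts (>= 1).
#' @slot sampleId character scalar identifying the sequenced individual.
#'
#' @seealso [countKmers()], [kmerHistogram()], [individualSet()]
#' @export
setClass("KmerTable",
    representation(k = "integer", counts = "integer", sampleId = "character"))

setValidity("KmerTable", function(object) {
    msg <- NULL
    k <- object@k
    if (length(k) != 1L || is.na(k) || k < 3L || k %% 2L == 0L)
        msg <- c(msg, "k must be a single odd integer >= 3")
    cts <- object@counts
    if (length(cts)) {
        if (is.null(names(cts)))
            msg <- c(msg, "counts must be named by k-mer")
        else {
            if (any(nchar(names(cts)) != k))
                msg <- c(msg, "all k-mer keys must have length k")
            if (any(cts < 1L))
                msg <- c(msg, "all counts must be >= 1")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' KmerHistogram: k-mer occurrence-count spectrum
#'
#' The histogram plots, for each occurrence count c, the number of distinct
#' canonical k-mers observed exactly c times. Its shape (error peak near
#' c = 1, valley, genomic coverage peak) drives threshold inference.
#'
#' @slot occ integer vector of occurrence counts c (>= 1, strictly
#'   increasing).
#' @slot n numeric vector, number of distinct k-mers with count c.
#'
#' @seealso [kmerHistogram()], [inferThreshold()]
#' @export
setClass("KmerHistogram", representation(occ = "integer", n = "numeric"))

setValidity("KmerHistogram", function(object) {
    msg <- NULL
    if (length(object@occ) != length(object@n))
        msg <- c(msg, "occ and n must have equal length")
    if (length(object@occ)) {
        if (any(object@occ < 1L)) msg <- c(msg, "occurrence counts must be >= 1")
        if (is.unsorted(object@occ, strictly = TRUE))
            msg <- c(msg, "occ must be strictly increasing")
        if (any(object@n < 0)) msg <- c(msg, "histogram values must be >= 0")
    }
    if (is.null(msg)) TRUE else msg
})

#' IndividualKmerSet: thresholded k-mer set of one individual
#'
#' A k-mer is attributed to an individual's genome when its occurrence
#' count in that individual's reads reaches the threshold T, which
#' separates sequencing-error k-mers (low counts) from genomic k-mers
#' (counts near the coverage peak).
#'
#' @slot k odd integer k-mer length.
#' @slot members character vector of canonical k-mers with count >= T.
#' @slot threshold integer, the threshold T that was applied.
#' @slot lowConfidence logical; TRUE when T came from the fallback rule
#'   because the histogram showed no coverage peak.
#' @slot sampleId character scalar.
#'
#' @seealso [individualSet()], [inferThreshold()]
#' @export
setClass("IndividualKmerSet",
    representation(k = "integer", members = "character",
                   threshold = "integer", lowConfidence = "logical",
                   sampleId = "character"))

setValidity("IndividualKmerSet", function(object) {
    msg <- NULL
    if (length(object@threshold) != 1L || object@threshold < 1L)
        msg <- c(msg, "threshold must be a single integer >= 1")
    if (length(object@members) && any(nchar(object@members) != object@k))
        msg <- c(msg, "all members must have length k")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (is.null(msg)) TRUE else msg
})

#' StrainAggregate: per-k-mer (i, j) membership counters over two strains
#'
#' For every k-mer present in at least one individual, the pair (i, j)
#' records how many individuals of strain A and strain B possess it. The
#' summary matrix tabulates the number of distinct k-mers per (i, j) cell;
#' the (0, 0) cell is structurally zero and never materialised.
#'
#' @slot k odd integer k-mer length.
#' @slot kmers character vector of canonical k-mers (union over all
#'   individuals).
#' @slot countA,countB integer vectors parallel to kmers: number of
#'   individuals of each strain whose thresholded set contains the k-mer.
#' @slot strainNames character of length 2 (A then B).
#' @slot nIndividuals integer of length 2: cohort sizes N_A, N_B.
#' @slot summary (N_A + 1) x (N_B + 1) numeric matrix of k-mer counts per
#'   (i, j) cell, dimnames "0".."N".
#'
#' @seealso [aggregateStrains()], [strainSet()]
#' @export
setClass("StrainAggregate",
    representation(k = "integer", kmers = "character",
                   countA = "integer", countB = "integer",
                   strainNames = "character", nIndividuals = "integer",
                   summary = "matrix"))

setValidity("StrainAggregate", function(object) {
    msg <- NULL
    n <- length(object@kmers)
    if (length(object@countA) != n || length(object@countB) != n)
        msg <- c(msg, "countA/countB must parallel kmers")
    if (length(object@strainNames) != 2L || length(object@nIndividuals) != 2L)
        msg <- c(msg, "exactly two strains required")
    if (n) {
        if (any(object@countA < 0L) || any(object@countA > object@nIndividuals[1L]))
            msg <- c(msg, "countA out of [0, N_A]")
        if (any(object@countB < 0L) || any(object@countB > object@nIndividuals[2L]))
            msg <- c(msg, "countB out of [0, N_B]")
        if (any(object@countA + object@countB == 0L))
            msg <- c(msg, "(0,0) k-mers must not be stored")
    }
    sm <- object@summary
    if (!all(dim(sm) == object@nIndividuals + 1L))
        msg <- c(msg, "summary must be (N_A+1) x (N_B+1)")
    else if (sum(sm) - sm[1L, 1L] != n)
        msg <- c(msg, "summary cells (excluding (0,0)) must sum to |kmers|")
    if (is.null(msg)) TRUE else msg
})

#' StrainKmerSet: strain-level k-mer membership
#'
#' A k-mer belongs to a strain when it belongs to at least m individual
#' genomes of that strain (the pipeline default is m = 3, e.g. at least 3
#' of 10 or 3 of 8 individuals).
#'
#' @slot strain character scalar, strain name.
#' @slot k odd integer k-mer length.
#' @slot members character vector of canonical k-mers.
#' @slot minIndividuals integer m.
#'
#' @seealso [strainSet()], [scanReference()]
#' @export
setClass("StrainKmerSet",
    representation(strain = "character", k = "integer",
                   members = "character", minIndividuals = "integer"))

#' ReferenceScan: per-contig presence/absence masks for one strain
#'
#' Produced by sliding a window of length k along the reference and
#' querying each canonical window against a strain k-mer set. A reference
#' base is `present` when at least one window containing it is in the set;
#' unmarked bases within scannable sequence are the altered base pairs.
#' Bases covered only by windows containing ambiguous symbols (or within
#' contigs shorter than k) are `unscannable` and excluded from calling.
#'
#' @slot k odd integer.
#' @slot strain character scalar, the strain queried.
#' @slot masks named list (one element per contig); each element is a list
#'   with logical vectors `presence` and `scannable` (length = contig
#'   length) and `absentStart` and `validStart` (length = contig length -
#'   k + 1, or 0 for short contigs).
#'
#' @seealso [scanReference()], [callAlteredRuns()], [callInsertions()]
#' @export
setClass("ReferenceScan",
    representation(k = "integer", strain = "character", masks = "list"))

setValidity("ReferenceScan", function(object) {
    msg <- NULL
    for (nm in names(object@masks)) {
        m <- object@masks[[nm]]
        L <- length(m$presence)
        nw <- max(0L, L - object@k + 1L)
        if (length(m$scannable) != L ||
            length(m$absentStart) != nw || length(m$validStart) != nw)
            msg <- c(msg, sprintf("mask lengths inconsistent for contig '%s'", nm))
    }
    if (is.null(msg)) TRUE else msg
})

#' GeneModels: minimal gene models from a GFF3 annotation
#'
#' Per gene: the full genomic span, the coding span (first to last coding
#' base over all transcripts) and the exon union (union of exon intervals
#' over all transcripts). All ranges are 1-based closed [GenomicRanges]
#' conventions; external BED/TSV output converts to 0-based half-open.
#'
#' @slot genes [GenomicRanges::GRanges] with mcols `gene_id` and `symbol`,
#'   ordered by (contig, start).
#' @slot coding named [GenomicRanges::GRanges] (may omit non-coding genes).
#' @slot exons named [GenomicRanges::GRangesList] of reduced exon unions.
#'
#' @seealso [loadAnnotation()], [countByGene()]
#' @export
setClass("GeneModels",
    representation(genes = "GRanges", coding = "GRanges",
                   exons = "CompressedGRangesList"))
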