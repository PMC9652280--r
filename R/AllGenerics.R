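#' @include AllClasses.R
NULL

#' Accessors for strainscan classes
#'
#' `kmerSize()` returns k; `kmerCounts()` the named count vector of a
#' [KmerTable]; `members()` the k-mer set of an [IndividualKmerSet] or
#' [StrainKmerSet]; `threshold()` the applied threshold T; `sampleId()` the
#' sample identifier; `summaryMatrix()` the (i, j) cell-count matrix of a
#' [StrainAggregate].
#'
#' @param x a strainscan object.
#' @return the slot value; see Details of each class.
#' @name accessors
#' @aliases kmerSize kmerCounts members threshold sampleId summaryMatrix
#' @examples
#' tab <- countKmers("ACGTACGT", k = 3)
#' kmerSize(tab)
#' kmerCounts(tab)
NULL

#' @rdname accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname accessors
#' @importFrom IRanges members
#' @export
members <- IRanges::members
#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("summaryMatrix", function(x) standardGeneric("summaryMatrix"))

#' @rdname accessors
setMethod("kmerSize", "KmerTable", function(x) x@k)
#' @rdname accessors
setMethod("kmerSize", "IndividualKmerSet", function(x) x@k)
#' @rdname accessors
setMethod("kmerSize", "StrainAggregate", function(x) x@k)
#' @rdname accessors
setMethod("kmerSize", "StrainKmerSet", function(x) x@k)
#' @rdname accessors
setMethod("kmerSize", "ReferenceScan", function(x) x@k)
#' @rdname accessors
setMethod("kmerCounts", "KmerTable", function(x) x@counts)
#' @rdname accessors
setMethod("members", "IndividualKmerSet", function(x, i) x@members)
#' @rdname accessors
setMethod("members", "StrainKmerSet", function(x, i) x@members)
#' @rdname accessors
setMethod("threshold", "IndividualKmerSet", function(x) x@threshold)
#' @rdname accessors
setMethod("sampleId", "KmerTable", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "IndividualKmerSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("summaryMatrix", "StrainAggregate", function(x) x@summary)

setMethod("show", "KmerTable", function(object) {
    cat(sprintf("KmerTable: sample '%s', k = %d, %d distinct k-mers, total mass %.0f\n",
        object@sampleId, object@k, length(object@counts),
        sum(as.numeric(object@counts))))
})

setMethod("show", "KmerHistogram", function(object) {
    cat(sprintf("KmerHistogram: %d occupied occurrence counts, %.0f distinct k-mers\n",
        length(object@occ), sum(object@n)))
    if (length(object@occ)) {
        hd <- utils::head(data.frame(c = object@occ, n.kmers = object@n), 5L)
        print(hd, row.names = FALSE)
    }
})

setMethod("show", "IndividualKmerSet", function(object) {
    cat(sprintf("IndividualKmerSet: sample '%s', k = %d, T = %d%s, %d members\n",
        object@sampleId, object@k, object@threshold,
        if (isTRUE(object@lowConfidence)) " (low confidence)" else "",
        length(object@members)))
})

setMethod("show", "StrainAggregate", function(object) {
    cat(sprintf("StrainAggregate: %s (N = %d) vs %s (N = %d), k = %d\n",
        object@strainNames[1L], object@nIndividuals[1L],
        object@strainNames[2L], object@nIndividuals[2L], object@k))
    cat(sprintf("  %d aggregated k-mers\n", length(object@kmers)))
})

setMethod("show", "StrainKmerSet", function(object) {
    cat(sprintf("StrainKmerSet: strain '%s', k = %d, m >= %d, %d members\n",
        object@strain, object@k, object@minIndividuals,
        length(object@members)))
})

setMethod("show", "ReferenceScan", function(object) {
    tot <- sum(vapply(object@masks, function(m) length(m$presence), 0))
    alt <- sum(vapply(object@masks,
        function(m) sum(m$scannable & !m$presence), 0))
    cat(sprintf("ReferenceScan vs strain '%s': k = %d, %d contigs, %.0f bp, %.0f altered bp\n",
        object@strain, object@k, length(object@masks), tot, alt))
})

setMethod("show", "GeneModels", function(object) {
    cat(sprintf("GeneModels: %d genes (%d with CDS) on %d contigs\n",
        length(object@genes), length(object@coding),
        length(unique(as.character(GenomicRanges::seqnames(object@genes))))))
})
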