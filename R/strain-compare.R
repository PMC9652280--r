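#' @include kmer-engine.R
#' @importFrom GenomicRanges GRanges seqnames start end width mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Rle DataFrame mcols<- queryHits
#' @importFrom BiocGenerics sort strand
NULL

#' Aggregate individual k-mer sets into two-strain (i, j) counters
#'
#' Builds one table over the union of all individual k-mer sets, recording
#' for each k-mer the pair (i, j): the number of strain-A individuals and
#' the number of strain-B individuals whose thresholded set contains it.
#' The summary matrix counts distinct k-mers per (i, j) cell; the (0, 0)
#' cell is structurally empty (such k-mers are never stored).
#'
#' @param setsA,setsB lists of [IndividualKmerSet] for strain A / strain B;
#'   all sets must share the same k.
#' @param strainNames character of length 2 naming the strains.
#' @return a [StrainAggregate].
#' @examples
#' mk <- function(m, id) new("IndividualKmerSet", k = 3L, members = m,
#'                           threshold = 1L, lowConfidence = FALSE,
#'                           sampleId = id)
#' agg <- aggregateStrains(list(mk(c("AAA", "AAC"), "a1"), mk("AAA", "a2")),
#'                         list(mk("AAC", "b1"), mk(c("AAC", "AAG"), "b2")))
#' summaryMatrix(agg)
#' @export
aggregateStrains <- function(setsA, setsB,
                             strainNames = c("strainA", "strainB")) {
    sets <- c(setsA, setsB)
    if (!length(sets)) stop("at least one individual set is required")
    ok <- vapply(sets, function(s) is(s, "IndividualKmerSet"), TRUE)
    if (!all(ok)) stop("inputs must be IndividualKmerSet objects")
    ks <- vapply(sets, kmerSize, 0L)
    if (length(unique(ks)) != 1L)
        stop("all individual sets must share the same k (found: ",
             paste(unique(ks), collapse = ", "), ")")
    k <- ks[1L]
    nA <- length(setsA); nB <- length(setsB)

    univ <- unique(c(unlist(lapply(setsA, members), use.names = FALSE),
                     unlist(lapply(setsB, members), use.names = FALSE)))
    univ <- sort(univ)
    cA <- integer(length(univ))
    for (s in setsA) {
        idx <- match(members(s), univ)
        cA[idx] <- cA[idx] + 1L
    }
    cB <- integer(length(univ))
    for (s in setsB) {
        idx <- match(members(s), univ)
        cB[idx] <- cB[idx] + 1L
    }
    sm <- table(factor(cA, levels = 0:nA), factor(cB, levels = 0:nB))
    sm <- matrix(as.numeric(sm), nrow = nA + 1L,
                 dimnames = list(0:nA, 0:nB))
    new("StrainAggregate", k = k, kmers = univ, countA = cA, countB = cB,
        strainNames = as.character(strainNames),
        nIndividuals = c(nA, nB), summary = sm)
}

#' Strain-level k-mer set from an aggregate
#'
#' A k-mer belongs to the strain when it belongs to at least m individual
#' genomes of that strain. With m = 1 this is the union of the strain's
#' individual sets, with m = N the intersection; the pipeline default
#' m = 3 tolerates per-individual dropouts and private absences.
#'
#' @param aggregate a [StrainAggregate].
#' @param strain strain name (one of the aggregate's two strains) or
#'   index 1/2.
#' @param m integer minimum number of individuals, 1 <= m <= N_strain.
#' @return a [StrainKmerSet].
#' @export
strainSet <- function(aggregate, strain, m = 3L) {
    stopifnot(is(aggregate, "StrainAggregate"))
    if (is.numeric(strain)) {
        idx <- as.integer(strain)
    } else {
        idx <- match(strain, aggregate@strainNames)
    }
    if (is.na(idx) || idx < 1L || idx > 2L)
        stop("unknown strain: ", strain)
    m <- as.integer(m)
    N <- aggregate@nIndividuals[idx]
    if (length(m) != 1L || is.na(m) || m < 1L || m > N)
        stop(sprintf("m must be in [1, %d] for strain '%s'", N,
                     aggregate@strainNames[idx]))
    cnt <- if (idx == 1L) aggregate@countA else aggregate@countB
    new("StrainKmerSet", strain = aggregate@strainNames[idx],
        k = aggregate@k, members = aggregate@kmers[cnt >= m],
        minIndividuals = m)
}

.as_contig_strings <- function(reference) {
    if (is(reference, "DNAStringSet")) {
        out <- as.character(reference)
    } else if (is(reference, "DNAString")) {
        out <- structure(as.character(reference), names = "seq1")
    } else if (is.character(reference) && length(reference) == 1L &&
               file.exists(reference)) {
        out <- as.character(readDNAStringSet(reference))
    } else if (is.character(reference)) {
        out <- reference
        if (is.null(names(out)))
            names(out) <- paste0("contig", seq_along(out))
    } else stop("reference must be a DNAStringSet, FASTA path or character")
    # FASTA descriptions: keep the first word as the contig name
    names(out) <- sub("\\s.*$", "", names(out))
    out
}

#' Scan a reference genome against a strain k-mer set
#'
#' Slides a window of length k along each contig and queries the window's
#' canonical form against the strain set. Where the query succeeds, all k
#' covered base pairs are marked present. Windows containing ambiguous
#' bases are treated as absent; bases covered by no ambiguity-free window
#' (N runs, contig ends of short contigs) are flagged unscannable and take
#' part in neither altered-bp nor insertion calling.
#'
#' @param reference a [Biostrings::DNAStringSet], named character vector of
#'   contig sequences, or FASTA path.
#' @param strainSet a [StrainKmerSet].
#' @return a [ReferenceScan].
#' @seealso [callAlteredRuns()], [callInsertions()], [alteredBasepairs()]
#' @export
scanReference <- function(reference, strainSet) {
    stopifnot(is(strainSet, "StrainKmerSet"))
    contigs <- .as_contig_strings(reference)
    k <- strainSet@k
    masks <- lapply(contigs, function(s) {
        if (nchar(s) < k) {
            list(presence = rep(FALSE, nchar(s)),
                 scannable = rep(FALSE, nchar(s)),
                 absentStart = logical(0), validStart = logical(0))
        } else {
            r <- cpp_scan_presence(s, strainSet@members, k)
            list(presence = r$presence, scannable = r$scannable,
                 absentStart = r$absentStart, validStart = r$validStart)
        }
    })
    new("ReferenceScan", k = k, strain = strainSet@strain, masks = masks)
}

#' Altered, present and unscannable base-pair totals of a scan
#'
#' Altered base pairs are scannable reference bases covered by no window
#' present in the strain set.
#'
#' @param scan a [ReferenceScan].
#' @return data.frame with one row per contig: contig, length, present,
#'   altered, unscannable.
#' @export
alteredBasepairs <- function(scan) {
    stopifnot(is(scan, "ReferenceScan"))
    rows <- lapply(names(scan@masks), function(nm) {
        m <- scan@masks[[nm]]
        data.frame(contig = nm, length = length(m$presence),
                   present = sum(m$presence),
                   altered = sum(m$scannable & !m$presence),
                   unscannable = sum(!m$scannable))
    })
    do.call(rbind, rows)
}

.runs_true <- function(x) {
    # maximal runs of TRUE; returns 1-based start/end (closed) matrix
    if (!length(x) || !any(x)) return(cbind(start = integer(0), end = integer(0)))
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
}

#' Call variants as maximal runs of altered base pairs
#'
#' A variant is a maximal block of consecutive altered base pairs: a
#' single-base substitution yields a length-1 run, a deletion of L bases a
#' length-L run, a substituted block a run of the block length. Unscannable
#' bases terminate runs but are not themselves called.
#'
#' @param scan a [ReferenceScan].
#' @return a [GenomicRanges::GRanges] (1-based closed coordinates) with
#'   mcols `vclass = "altered_run"` and `length` (run length in bp),
#'   sorted by (contig, start). Use [writeVariantsBed()] for 0-based
#'   half-open BED output.
#' @export
callAlteredRuns <- function(scan) {
    stopifnot(is(scan, "ReferenceScan"))
    grs <- lapply(names(scan@masks), function(nm) {
        m <- scan@masks[[nm]]
        runs <- .runs_true(m$scannable & !m$presence)
        if (!nrow(runs)) return(GRanges(character(0), IRanges()))
        GRanges(nm, IRanges(start = unname(runs[, "start"]),
                            end = unname(runs[, "end"])))
    })
    gr <- suppressWarnings(do.call(c, grs))
    mcols(gr)$vclass <- rep("altered_run", length(gr))
    mcols(gr)$length <- width(gr)
    sort(gr, ignore.strand = TRUE)
}

#' Call insertion signatures from absent k-mer runs
#'
#' An insertion in the strain relative to the reference breaks the k - 1
#' reference windows spanning the insertion junction while every reference
#' base stays covered by flanking windows. Such events appear as maximal
#' runs of absent window starts whose covered reference span contains zero
#' altered base pairs; they are reported as zero-width junction calls at
#' the end of the covered span, carrying the absent-run length. Absent
#' runs that overlap altered base pairs are explained by the altered-run
#' call and are not reported; runs containing ambiguity-broken windows are
#' excluded as unscannable.
#'
#' @param scan a [ReferenceScan].
#' @return a zero-width [GenomicRanges::GRanges] with mcols
#'   `vclass = "insertion"` and `length` (absent-run length; k - 1 for a
#'   clean isolated insertion).
#' @export
callInsertions <- function(scan) {
    stopifnot(is(scan, "ReferenceScan"))
    k <- scan@k
    grs <- lapply(names(scan@masks), function(nm) {
        m <- scan@masks[[nm]]
        runs <- .runs_true(m$absentStart)
        if (!nrow(runs))
            return(GRanges(character(0), IRanges(), runLength = integer(0)))
        altered <- m$scannable & !m$presence
        keep <- logical(nrow(runs))
        for (i in seq_len(nrow(runs))) {
            s <- runs[i, "start"]; e <- runs[i, "end"]
            if (!all(m$validStart[s:e])) next        # unscannable run
            span <- s:(e + k - 1L)                   # covered ref bases
            if (!any(altered[span])) keep[i] <- TRUE
        }
        runs <- runs[keep, , drop = FALSE]
        if (!nrow(runs))
            return(GRanges(character(0), IRanges(), runLength = integer(0)))
        # zero-width junction after base run_start + k - 2 (1-based):
        # GRanges encodes width 0 as start = end + 1
        junction <- unname(runs[, "start"]) + k - 1L
        GRanges(nm, IRanges(start = junction, width = 0L),
                runLength = unname(runs[, "end"] - runs[, "start"]) + 1L)
    })
    gr <- suppressWarnings(do.call(c, grs))
    len <- mcols(gr)$runLength
    mcols(gr) <- NULL
    mcols(gr)$vclass <- rep("insertion", length(gr))
    mcols(gr)$length <- len
    sort(gr, ignore.strand = TRUE)
}

#' Write variant calls as BED (0-based half-open)
#'
#' Altered runs become intervals `[start0, end0)`; zero-width insertion
#' calls become `start0 == end0` junction records. Columns: chrom, start,
#' end, name (vclass), score (length in bp).
#'
#' @param variants a GRanges from [callAlteredRuns()] / [callInsertions()]
#'   (or their concatenation).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantsBed <- function(variants, path) {
    stopifnot(is(variants, "GRanges"))
    start0 <- start(variants) - 1L
    end0 <- end(variants)          # closed end == half-open end; width-0 ok
    df <- data.frame(chrom = as.character(seqnames(variants)),
                     start = start0, end = pmax(end0, start0),
                     name = mcols(variants)$vclass,
                     score = mcols(variants)$length)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write the (i, j) summary matrix as TSV
#'
#' Long-format rows (i, j, n_kmers) for every occupied cell, mirroring a
#' two-strain k-mer membership summary table.
#'
#' @param aggregate a [StrainAggregate].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryTsv <- function(aggregate, path) {
    stopifnot(is(aggregate, "StrainAggregate"))
    sm <- aggregate@summary
    df <- expand.grid(i = as.integer(rownames(sm)),
                      j = as.integer(colnames(sm)))
    df$n_kmers <- as.vector(sm)
    df <- df[df$n_kmers > 0 & !(df$i == 0 & df$j == 0), , drop = FALSE]
    df <- df[order(df$i, df$j), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
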