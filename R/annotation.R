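#' @include strain-compare.R
#' @importFrom GenomicRanges GRanges GRangesList reduce findOverlaps
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom rtracklayer import export
NULL

#' Load gene models from a GFF3 annotation
#'
#' Reads gene, mRNA/transcript, exon and CDS features and derives, per
#' gene: the genomic span, the coding span (first to last coding base over
#' all transcripts) and the exon union (reduced union of exon intervals
#' over all transcripts). Genes are ordered by (contig, start). GFF3's
#' 1-based inclusive coordinates are kept in the returned GRanges; BED/TSV
#' exports convert to 0-based half-open.
#'
#' @param gff3 path to a GFF3 file.
#' @return a [GeneModels] object.
#' @export
loadAnnotation <- function(gff3) {
    gr <- rtracklayer::import(gff3, format = "gff3")
    type <- as.character(gr$type)
    genes <- gr[type == "gene"]
    if (!length(genes)) {
        return(new("GeneModels",
            genes = GRanges(gene_id = character(0), symbol = character(0)),
            coding = GRanges(),
            exons = GRangesList()))
    }
    gid <- as.character(genes$ID)
    sym <- if (!is.null(genes$Name)) as.character(genes$Name) else gid
    sym[is.na(sym)] <- gid[is.na(sym)]

    # map transcript -> gene for Parent resolution
    tx <- gr[type %in% c("mRNA", "transcript")]
    tx2gene <- structure(vapply(tx$Parent, function(p) as.character(p)[1L], ""),
                         names = as.character(tx$ID))

    .gene_of <- function(feats) {
        par <- vapply(feats$Parent, function(p)
            if (length(p)) as.character(p)[1L] else NA_character_, "")
        ifelse(par %in% gid, par, unname(tx2gene[par]))
    }

    exons <- gr[type == "exon"]
    cds <- gr[type == "CDS"]
    exon_gene <- .gene_of(exons)
    cds_gene <- .gene_of(cds)
    if (any(is.na(exon_gene)) || any(is.na(cds_gene)))
        stop("exon/CDS feature with unresolvable gene parent")

    # validate: CDS inside its gene span
    for (i in seq_along(cds)) {
        g <- match(cds_gene[i], gid)
        if (as.character(seqnames(cds))[i] != as.character(seqnames(genes))[g] ||
            start(cds)[i] < start(genes)[g] || end(cds)[i] > end(genes)[g])
            stop(sprintf("CDS feature '%s' lies outside its gene '%s'",
                         if (!is.null(cds$ID)) as.character(cds$ID)[i] else i,
                         cds_gene[i]))
    }

    o <- order(as.character(seqnames(genes)), start(genes))
    genes <- genes[o]; gid <- gid[o]; sym <- sym[o]

    gout <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                    strand = BiocGenerics::strand(genes))
    mcols(gout)$gene_id <- gid
    mcols(gout)$symbol <- sym

    coding_list <- lapply(gid, function(g) {
        ci <- which(cds_gene == g)
        if (!length(ci)) return(NULL)
        GRanges(as.character(seqnames(cds))[ci[1L]],
                IRanges(min(start(cds)[ci]), max(end(cds)[ci])))
    })
    keep <- !vapply(coding_list, is.null, TRUE)
    coding <- if (any(keep)) {
        x <- suppressWarnings(do.call(c, coding_list[keep]))
        names(x) <- gid[keep]
        x
    } else GRanges()

    exon_union <- lapply(gid, function(g) {
        ei <- which(exon_gene == g)
        if (!length(ei)) return(GRanges())
        reduce(GRanges(as.character(seqnames(exons))[ei],
                       IRanges(start(exons)[ei], end(exons)[ei])))
    })
    names(exon_union) <- gid

    new("GeneModels", genes = gout, coding = coding,
        exons = GRangesList(exon_union))
}

.region_ranges <- function(models, region) {
    gid <- mcols(models@genes)$gene_id
    switch(region,
        gene = {
            x <- models@genes
            out <- stats::setNames(lapply(seq_along(x), function(i)
                GRanges(as.character(seqnames(x))[i],
                        IRanges(start(x)[i], end(x)[i]))), gid)
            as(out, "GRangesList")
        },
        coding = {
            out <- stats::setNames(
                lapply(gid, function(g)
                    if (g %in% names(models@coding))
                        models@coding[g] else GRanges()),
                gid)
            as(out, "GRangesList")
        },
        exons = {
            out <- stats::setNames(lapply(gid, function(g)
                models@exons[[g]]), gid)
            as(out, "GRangesList")
        },
        stop("unknown region '", region,
             "'; expected gene, coding or exons"))
}

.altered_in_ranges <- function(scan, rgs) {
    # total altered bp of one scan within a GRanges of (disjoint) intervals
    tot <- 0L
    for (i in seq_along(rgs)) {
        nm <- as.character(seqnames(rgs))[i]
        m <- scan@masks[[nm]]
        if (is.null(m))
            stop("gene on contig '", nm, "' absent from the reference scan")
        s <- max(1L, start(rgs)[i]); e <- min(length(m$presence), end(rgs)[i])
        if (e >= s)
            tot <- tot + sum(m$scannable[s:e] & !m$presence[s:e])
    }
    tot
}

#' Per-gene altered-bp and variant counts with per-Mbp rates
#'
#' For each gene and each region (full gene span, coding span, exon
#' union), counts the altered base pairs falling inside the region and the
#' variant calls intersecting it, and normalises both by region length to
#' per-Mbp rates (count / length x 1e6). A variant overlapping a region
#' partially counts once; zero-width insertion calls count when their
#' junction lies strictly inside the region and contribute no altered bp.
#' Variants spanning two genes are counted in both.
#'
#' @param scan a [ReferenceScan].
#' @param variants GRanges of variant calls (altered runs and/or
#'   insertions, as returned by [callAlteredRuns()]/[callInsertions()]).
#' @param models a [GeneModels].
#' @return data.frame with one row per gene x region: gene_id, symbol,
#'   region, region_length, altered_bp, variants, altered_bp_per_mbp,
#'   variants_per_mbp.
#' @export
countByGene <- function(scan, variants, models) {
    stopifnot(is(scan, "ReferenceScan"), is(variants, "GRanges"),
              is(models, "GeneModels"))
    gid <- mcols(models@genes)$gene_id
    sym <- mcols(models@genes)$symbol
    is_ins <- mcols(variants)$vclass == "insertion"

    rows <- list()
    for (region in c("gene", "coding", "exons")) {
        rgs <- .region_ranges(models, region)
        for (i in seq_along(gid)) {
            rg <- rgs[[i]]
            len <- sum(width(rg))
            if (!length(rg) || len == 0L) {
                rows[[length(rows) + 1L]] <- data.frame(
                    gene_id = gid[i], symbol = sym[i], region = region,
                    region_length = 0L, altered_bp = 0L, variants = 0L,
                    altered_bp_per_mbp = NA_real_,
                    variants_per_mbp = NA_real_)
                next
            }
            abp <- .altered_in_ranges(scan, rg)
            # altered runs: any overlap counts the call once
            nv <- 0L
            if (any(!is_ins)) {
                hits <- findOverlaps(variants[!is_ins], rg,
                                     ignore.strand = TRUE)
                nv <- nv + length(unique(S4Vectors::queryHits(hits)))
            }
            # insertions: junction strictly inside the region. A zero-width
            # call at junction j0 (0-based) sits between 1-based bases j0
            # and j0 + 1; strictly inside [s1, e1] means s1 <= j0 < e1,
            # i.e. both flanking bases are in the region.
            if (any(is_ins)) {
                ins <- variants[is_ins]
                j0 <- start(ins) - 1L
                cnt <- vapply(seq_along(ins), function(q) {
                    nm <- as.character(seqnames(ins))[q]
                    any(as.character(seqnames(rg)) == nm &
                        start(rg) <= j0[q] & j0[q] < end(rg))
                }, TRUE)
                nv <- nv + sum(cnt)
            }
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = gid[i], symbol = sym[i], region = region,
                region_length = len, altered_bp = abp, variants = nv,
                altered_bp_per_mbp = abp / len * 1e6,
                variants_per_mbp = nv / len * 1e6)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Genes heavily altered in one strain and unchanged in the other
#'
#' Selects genes whose per-Mbp rate in strain A reaches `minRate` while the
#' strain-B rate stays at or below `maxRate`, for the chosen region and
#' metric. Swapping the two record sets gives the symmetric contrast.
#'
#' @param recordsA,recordsB per-gene data.frames from [countByGene()] for
#'   the two strains (aligned on gene_id).
#' @param region one of "gene", "coding", "exons".
#' @param metric "variants" or "altered_bp" (per-Mbp rates are compared).
#' @param minRate minimum strain-A rate (per Mbp) for inclusion.
#' @param maxRate maximum strain-B rate (per Mbp) for inclusion.
#' @return data.frame (gene_id, symbol, rateA, rateB) sorted by rateA
#'   descending.
#' @export
differentialGenes <- function(recordsA, recordsB, region = "exons",
                              metric = c("variants", "altered_bp"),
                              minRate = 1, maxRate = 0) {
    metric <- match.arg(metric)
    if (!region %in% c("gene", "coding", "exons"))
        stop("unknown region '", region, "'")
    col <- paste0(sub("altered_bp", "altered_bp", metric), "_per_mbp")
    a <- recordsA[recordsA$region == region, , drop = FALSE]
    b <- recordsB[recordsB$region == region, , drop = FALSE]
    b <- b[match(a$gene_id, b$gene_id), , drop = FALSE]
    if (any(is.na(b$gene_id)))
        stop("records are not aligned on gene ids")
    rateA <- a[[col]]; rateB <- b[[col]]
    keep <- !is.na(rateA) & !is.na(rateB) & rateA >= minRate & rateB <= maxRate
    out <- data.frame(gene_id = a$gene_id[keep], symbol = a$symbol[keep],
                      rateA = rateA[keep], rateB = rateB[keep])
    out[order(-out$rateA), , drop = FALSE]
}

#' Export a deduplicated gene-symbol list
#'
#' One symbol per line, sorted and deduplicated — the input format of
#' multi-protein lookup tools of protein-association databases.
#'
#' @param symbols character vector of gene symbols (no whitespace).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportGeneList <- function(symbols, path) {
    symbols <- as.character(symbols)
    if (any(grepl("\\s", symbols)))
        stop("gene symbols must not contain whitespace")
    writeLines(sort(unique(symbols)), path)
    invisible(path)
}

#' Write per-gene records as TSV (0-based half-open region lengths kept)
#'
#' @param records data.frame from [countByGene()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneRecords <- function(records, path) {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
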