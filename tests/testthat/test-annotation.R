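write_gff <- function(lines) {
    f <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", lines), f)
    f
}

test_that("annotation loading derives spans, coding spans and exon unions", {
    f <- write_gff(c(
        "c1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1;Name=SYM1",
        "c1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
        "c1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=t1",
        "c1\tsrc\texon\t301\t400\t.\t+\t.\tID=e2;Parent=t1",
        "c1\tsrc\tCDS\t151\t380\t.\t+\t0\tID=c1f;Parent=t1"))
    gm <- loadAnnotation(f)
    g <- gm@genes
    expect_identical(GenomicRanges::start(g), 101L)
    expect_identical(GenomicRanges::end(g), 400L)
    expect_identical(S4Vectors::mcols(g)$symbol, "SYM1")
    expect_identical(sum(GenomicRanges::width(gm@exons[["g1"]])), 200L)
    expect_identical(GenomicRanges::start(gm@coding["g1"]), 151L)
    expect_identical(GenomicRanges::end(gm@coding["g1"]), 380L)
})

test_that("exon unions merge overlapping transcripts; empty annotation is valid", {
    f <- write_gff(c(
        "c1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1;Name=S1",
        "c1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
        "c1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t2;Parent=g1",
        "c1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=t1",
        "c1\tsrc\texon\t151\t250\t.\t+\t.\tID=e2;Parent=t2"))
    gm <- loadAnnotation(f)
    expect_identical(sum(GenomicRanges::width(gm@exons[["g1"]])), 150L)
    expect_length(loadAnnotation(write_gff(character(0)))@genes, 0L)
})

test_that("a CDS outside its gene is rejected with the feature named", {
    f <- write_gff(c(
        "c1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1;Name=S1",
        "c1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
        "c1\tsrc\texon\t101\t400\t.\t+\t.\tID=e1;Parent=t1",
        "c1\tsrc\tCDS\t90\t200\t.\t+\t0\tID=badcds;Parent=t1"))
    expect_error(loadAnnotation(f), "badcds")
})

make_models <- function(gene_start1, gene_end1, exon_df = NULL) {
    genes <- data.frame(gene_id = "g1", symbol = "S1", contig = "chr1",
                        start = gene_start1, end = gene_end1)
    if (is.null(exon_df))
        exon_df <- data.frame(gene_id = "g1", start = gene_start1,
                              end = gene_end1)
    f <- tempfile(fileext = ".gff3")
    makeAnnotation(genes, exon_df, f)
    loadAnnotation(f)
}

test_that("per-gene counts follow the intersection rules", {
    # exon [0,100) 0-based = [1,100] 1-based; altered run [10,13) inside
    pres <- rep(TRUE, 200); pres[11:13] <- FALSE
    sc <- manual_scan(pres, k = 5)
    vars <- callAlteredRuns(sc)
    gm <- make_models(1, 100)
    rec <- countByGene(sc, vars, gm)
    ex <- rec[rec$region == "exons", ]
    expect_identical(ex$altered_bp, 3L)
    expect_identical(ex$variants, 1L)
    # partial overlap [95,105) 0-based: 5 altered bp inside, 1 variant
    pres2 <- rep(TRUE, 200); pres2[96:105] <- FALSE
    sc2 <- manual_scan(pres2, k = 5)
    rec2 <- countByGene(sc2, callAlteredRuns(sc2), gm)
    ex2 <- rec2[rec2$region == "exons", ]
    expect_identical(ex2$altered_bp, 5L)
    expect_identical(ex2$variants, 1L)
})

test_that("per-Mbp rates reproduce counts exactly", {
    pres <- rep(TRUE, 1200); pres[c(500, 700)] <- FALSE
    sc <- manual_scan(pres, k = 5)
    gm <- make_models(1, 1000)
    rec <- countByGene(sc, callAlteredRuns(sc), gm)
    for (i in seq_len(nrow(rec))) {
        expect_equal(rec$altered_bp_per_mbp[i] * rec$region_length[i] / 1e6,
                     rec$altered_bp[i], tolerance = 1e-12)
        expect_equal(rec$variants_per_mbp[i] * rec$region_length[i] / 1e6,
                     rec$variants[i], tolerance = 1e-12)
    }
    ex <- rec[rec$region == "exons", ]
    expect_equal(ex$altered_bp_per_mbp, 2 / 1000 * 1e6)
})

test_that("insertions count only when the junction is strictly inside a region", {
    k <- 5L
    mkins <- function(run_start0) {
        astart <- rep(FALSE, 196)
        astart[run_start0 + 1:(k - 1)] <- TRUE
        callInsertions(manual_scan(rep(TRUE, 200), k = k,
                                   absentStart = astart))
    }
    gm <- make_models(51, 100)   # region 0-based [50, 100)
    sc <- manual_scan(rep(TRUE, 200), k = k)
    inside <- mkins(70 - k + 1)      # junction at 0-based 70
    at_left <- mkins(50 - k + 1)     # junction at region start boundary
    at_right <- mkins(99 - k + 1)    # junction just before region end
    rec_in <- countByGene(sc, inside, gm)
    rec_l <- countByGene(sc, at_left, gm)
    rec_r <- countByGene(sc, at_right, gm)
    ex <- function(r) r[r$region == "exons", ]
    expect_identical(ex(rec_in)$variants, 1L)
    expect_identical(ex(rec_in)$altered_bp, 0L)
    expect_identical(ex(rec_l)$variants, 0L)      # boundary: not strictly inside
    expect_identical(ex(rec_r)$variants, 1L)
    expect_error(countByGene(sc, inside,
        make_models(1, 100)), NA)
    # gene on a contig missing from the scan errors
    genes <- data.frame(gene_id = "g9", symbol = "S9", contig = "nope",
                        start = 1, end = 50)
    exons <- data.frame(gene_id = "g9", start = 1, end = 50)
    f <- tempfile(fileext = ".gff3")
    makeAnnotation(genes, exons, f)
    expect_error(countByGene(sc, inside, loadAnnotation(f)), "nope")
})

test_that("region nesting holds: exon counts bounded by gene counts", {
    set.seed(61)
    pres <- rep(TRUE, 2000)
    pres[sample(2000, 60)] <- FALSE
    sc <- manual_scan(pres, k = 5)
    genes <- data.frame(gene_id = "g1", symbol = "S1", contig = "chr1",
                        start = 201, end = 1800)
    exons <- data.frame(gene_id = c("g1", "g1"), start = c(301, 1001),
                        end = c(600, 1500))
    f <- tempfile(fileext = ".gff3")
    makeAnnotation(genes, exons, f)
    gm <- loadAnnotation(f)
    rec <- countByGene(sc, callAlteredRuns(sc), gm)
    byreg <- stats::setNames(rec$altered_bp, rec$region)
    expect_lte(byreg[["exons"]], byreg[["coding"]])
    expect_lte(byreg[["coding"]], byreg[["gene"]])
})

test_that("differential gene selection applies both rate thresholds", {
    rec <- function(rates) data.frame(
        gene_id = paste0("g", seq_along(rates)),
        symbol = paste0("S", seq_along(rates)), region = "exons",
        region_length = 1000L, altered_bp = 0L,
        variants = as.integer(rates / 1000),
        altered_bp_per_mbp = 0, variants_per_mbp = rates)
    a <- rec(c(5000, 0, 200)); b <- rec(c(0, 0, 500))
    out <- differentialGenes(a, b, region = "exons", metric = "variants",
                             minRate = 1, maxRate = 0)
    expect_identical(out$gene_id, "g1")   # g2 zero in both; g3 high in B
    expect_error(differentialGenes(a, b, region = "promoter"), "unknown region")
})

test_that("gene-symbol lists are deduplicated, sorted and validated", {
    f <- tempfile()
    exportGeneList(c("g2", "g1", "g1"), f)
    expect_identical(readLines(f), c("g1", "g2"))
    f2 <- tempfile()
    exportGeneList(character(0), f2)
    expect_identical(readLines(f2), character(0))
    expect_error(exportGeneList("bad symbol", tempfile()), "whitespace")
})
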