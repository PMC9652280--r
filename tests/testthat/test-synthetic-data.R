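test_that("reference simulation is seed-deterministic with controlled GC", {
    r1 <- makeReference(1000, seed = 1)
    r2 <- makeReference(1000, seed = 1)
    expect_identical(as.character(r1), as.character(r2))
    expect_false(identical(as.character(makeReference(1000, seed = 2)),
                           as.character(r1)))
    # gc = 0: A/T alphabet only
    at <- as.character(makeReference(500, gc = 0, seed = 3))
    expect_false(grepl("[GC]", at))
    # observed GC within a binomial bound at n = 100000
    g <- as.character(makeReference(100000, gc = 0.41, seed = 4))
    gcobs <- nchar(gsub("[AT]", "", g)) / nchar(g)
    expect_lt(abs(gcobs - 0.41), 0.02)
    expect_error(makeReference(50, k = 27), "4k")
    # multi-contig split
    rm <- makeReference(1001, nContigs = 3, seed = 5)
    expect_identical(unname(Biostrings::width(rm)), c(335L, 333L, 333L))
})

test_that("planted variants reproduce the strain genome via the truth table", {
    ref <- makeReference(3000, seed = 11)
    # empty spec: identity
    p0 <- plantVariants(ref, seed = 1)
    expect_identical(as.character(p0$genome), as.character(ref))
    expect_identical(nrow(p0$truth), 0L)
    # one deletion shortens the genome by its length
    pd <- plantVariants(ref, nDeletions = 1, indelLengthRange = c(5, 5),
                        k = 11, seed = 2)
    expect_identical(nchar(as.character(pd$genome)),
                     nchar(as.character(ref)) - 5L)
    # one substitution: genomes differ at exactly one position
    ps <- plantVariants(ref, nSubstitutions = 1, k = 11, seed = 3)
    a <- strsplit(as.character(ref), "")[[1]]
    b <- strsplit(as.character(ps$genome), "")[[1]]
    expect_identical(sum(a != b), 1L)
    expect_identical(which(a != b) - 1L, ps$truth$ref_start)
})

test_that("truth application reconstructs the planted genome for random specs", {
    set.seed(303)
    for (rep in 1:100) {
        seed <- sample.int(1e6, 1)
        ref <- makeReference(sample(1500:3000, 1), seed = seed, k = 9)
        pl <- plantVariants(ref, nSubstitutions = sample(0:3, 1),
                            nDeletions = sample(0:2, 1),
                            nInsertions = sample(0:2, 1),
                            indelLengthRange = c(2, 6), k = 9,
                            seed = seed + 1)
        expect_identical(as.character(applyVariants(ref, pl$truth)),
                         as.character(pl$genome))
        expect_false(is.unsorted(pl$truth$ref_start))
    }
})

test_that("unsatisfiable spacing is rejected with the constraint named", {
    ref <- makeReference(200, k = 9, seed = 2)
    expect_error(plantVariants(ref, nSubstitutions = 50, k = 9, seed = 1),
                 "spacing")
})

test_that("read simulation honours the count formula and strand/error model", {
    g <- makeReference(10000, seed = 21)
    reads <- simulateReads(g, coverage = 30, readLength = 100, seed = 1)
    expect_length(reads, 3000L)  # ceil(30 * 10000 / 100)
    expect_true(all(Biostrings::width(reads) == 100L))
    # determinism
    reads2 <- simulateReads(g, coverage = 30, readLength = 100, seed = 1)
    expect_identical(as.character(reads), as.character(reads2))
    # error-free reads are exact substrings of the genome or its revcomp
    gs <- as.character(g[[1]]); rc <- revcomp_chr(gs)
    for (r in as.character(reads[1:150]))
        expect_true(grepl(r, gs, fixed = TRUE) || grepl(r, rc, fixed = TRUE))
    # both strands are used
    fwd_hits <- vapply(as.character(reads[1:150]), function(r)
        grepl(r, gs, fixed = TRUE), TRUE)
    expect_true(any(fwd_hits) && !all(fwd_hits))
    expect_error(simulateReads(g, coverage = 0), "positive")
    expect_error(simulateReads(g, coverage = 1, readLength = 20000),
                 "read length")
})

test_that("substitution errors occur at the configured i.i.d. rate", {
    # homopolymer genome: mismatches are directly countable per read
    g <- c(chrA = strrep("A", 10000))
    reads <- simulateReads(g, coverage = 100, readLength = 100,
                           errorRate = 0.01, seed = 9)
    expect_length(reads, 10000L)
    base_counts <- Biostrings::letterFrequency(reads, c("A", "T"))
    mism <- 100 - pmax(base_counts[, "A"], base_counts[, "T"])
    # binomial mean 1.0, +/- 5 sigma of the mean over 10000 reads
    expect_lt(abs(mean(mism) - 1.0), 0.05)
})

test_that("toy annotations round-trip and reject invalid gene structures", {
    genes <- data.frame(gene_id = "g1", symbol = "S1", contig = "c1",
                        start = 101, end = 400)
    exons <- data.frame(gene_id = "g1", start = c(101, 301),
                        end = c(200, 400))
    f <- tempfile(fileext = ".gff3")
    makeAnnotation(genes, exons, f, contigLengths = c(c1 = 1000))
    gm <- loadAnnotation(f)
    expect_identical(GenomicRanges::start(gm@genes), 101L)
    expect_identical(GenomicRanges::end(gm@genes), 400L)
    expect_identical(sum(GenomicRanges::width(gm@exons[["g1"]])), 200L)
    # zero genes: valid empty annotation body
    f0 <- tempfile(fileext = ".gff3")
    makeAnnotation(genes[0, ], exons[0, ], f0)
    expect_length(loadAnnotation(f0)@genes, 0L)
    # overlapping exons within one transcript
    bad <- data.frame(gene_id = "g1", start = c(101, 150), end = c(200, 250))
    expect_error(makeAnnotation(genes, bad, tempfile()), "overlapping")
    # exon outside gene span
    out <- data.frame(gene_id = "g1", start = 50, end = 120)
    expect_error(makeAnnotation(genes, out, tempfile()), "outside")
    # gene beyond contig end
    expect_error(makeAnnotation(genes, exons, tempfile(),
                                contigLengths = c(c1 = 300)), "fit")
})

test_that("FASTQ output round-trips through a standard reader", {
    g <- makeReference(2000, seed = 31)
    reads <- simulateReads(g, coverage = 2, readLength = 50, seed = 1)
    f <- tempfile(fileext = ".fastq")
    writeReadsFastq(reads, f)
    back <- Biostrings::readDNAStringSet(f, format = "fastq")
    expect_identical(as.character(back), as.character(reads))
})

test_that("cohort simulation is byte-reproducible from its configuration", {
    cfg <- list(referenceLength = 8000, nPerStrain = c(2, 2), coverage = 5,
                readLength = 80,
                variantsA = list(nSubstitutions = 3, nDeletions = 1,
                                 nInsertions = 1),
                variantsB = list(nSubstitutions = 2, nDeletions = 0,
                                 nInsertions = 0),
                nGenes = 2, seed = 77)
    d1 <- file.path(tempdir(), "cohort_run1")
    d2 <- file.path(tempdir(), "cohort_run2")
    unlink(c(d1, d2), recursive = TRUE)
    do.call(simulateCohort, c(cfg, list(dir = d1)))
    do.call(simulateCohort, c(cfg, list(dir = d2)))
    f1 <- list.files(d1, full.names = TRUE)
    f2 <- list.files(d2, full.names = TRUE)
    expect_identical(basename(f1), basename(f2))
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    # truth TSV uses 0-based half-open coordinates
    tr <- utils::read.table(file.path(d1, "truth_strainA.tsv"),
                            header = TRUE, sep = "\t")
    expect_identical(tr$ref_end - tr$ref_start,
                     ifelse(tr$vclass == "insertion", 0L, tr$length))
})
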