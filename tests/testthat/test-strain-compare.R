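# canonical 3-mers used as schematic set members
X <- "AAA"; Y <- "AAC"; Z <- "AAG"

test_that("aggregation tracks per-strain (i, j) counters and the summary matrix", {
    agg <- aggregateStrains(list(iks(c(X, Y)), iks(X)),
                            list(iks(Y), iks(c(Y, Z))))
    ij <- stats::setNames(paste(agg@countA, agg@countB), agg@kmers)
    expect_identical(ij[[X]], "2 0")
    expect_identical(ij[[Y]], "1 2")
    expect_identical(ij[[Z]], "0 1")
    sm <- summaryMatrix(agg)
    expect_identical(sm["2", "0"], 1)
    expect_identical(sm["1", "2"], 1)
    expect_identical(sm["0", "1"], 1)
    expect_identical(sum(sm) - sm["0", "0"], 3)
    # empty sets
    agg0 <- aggregateStrains(list(iks(character(0))), list(iks(character(0))))
    expect_length(agg0@kmers, 0L)
    # mixed k is rejected
    expect_error(aggregateStrains(list(iks(X, k = 3)),
                                  list(iks("AAAAA", k = 5))), "same k")
})

test_that("summary cells (excluding (0,0)) conserve the union cardinality", {
    set.seed(99)
    univ <- unique(canonicalizeKmer(vapply(1:60, function(i) random_dna(5), "")))
    for (rep in 1:20) {
        nA <- sample(1:4, 1); nB <- sample(1:4, 1)
        sA <- lapply(seq_len(nA), function(i)
            iks(sample(univ, sample(0:length(univ), 1)), k = 5))
        sB <- lapply(seq_len(nB), function(i)
            iks(sample(univ, sample(0:length(univ), 1)), k = 5))
        agg <- aggregateStrains(sA, sB)
        sm <- summaryMatrix(agg)
        un <- unique(c(unlist(lapply(sA, members)), unlist(lapply(sB, members))))
        expect_identical(sum(sm) - sm["0", "0"], as.numeric(length(un)))
    }
})

test_that("strain sets honour the at-least-m-of-N rule", {
    agg <- aggregateStrains(list(iks(c(X, Y)), iks(X)),
                            list(iks(Y), iks(c(Y, Z))))
    expect_identical(members(strainSet(agg, "strainA", 2)), X)
    expect_setequal(members(strainSet(agg, "strainA", 1)), c(X, Y))   # union
    expect_identical(members(strainSet(agg, "strainA", 2)), X)        # intersection (N=2)
    expect_setequal(members(strainSet(agg, "strainB", 1)), c(Y, Z))
    expect_identical(members(strainSet(agg, "strainB", 2)), Y)
    expect_error(strainSet(agg, "strainA", 3), "m must be")
    expect_error(strainSet(agg, "nope", 1), "unknown strain")
})

test_that("reference scanning marks k covered base pairs per present window", {
    ref <- c(chr1 = "ACGTACGTAC")
    allk <- names(kmerCounts(countKmers(ref, k = 3)))
    # full strain set: identity, zero altered bp
    full <- new("StrainKmerSet", strain = "A", k = 3L, members = allk,
                minIndividuals = 1L)
    expect_identical(alteredBasepairs(scanReference(ref, full))$altered, 0L)
    # remove GTA: windows 2,3,6,7 (0-based) absent; altered bp exactly {8,9}
    noGTA <- new("StrainKmerSet", strain = "A", k = 3L,
                 members = setdiff(allk, "GTA"), minIndividuals = 1L)
    sc <- scanReference(ref, noGTA)
    expect_identical(which(!sc@masks$chr1$presence) - 1L, c(8L, 9L))
    expect_identical(which(sc@masks$chr1$absentStart) - 1L,
                     c(2L, 3L, 6L, 7L))
    # contig shorter than k: all-absent presence, empty start mask
    sc2 <- scanReference(c(tiny = "AC"), noGTA)
    expect_identical(sc2@masks$tiny$presence, c(FALSE, FALSE))
    expect_length(sc2@masks$tiny$absentStart, 0L)
})

test_that("presence masks equal the brute-force substring-search oracle", {
    set.seed(13)
    for (rep in 1:10) {
        L <- sample(300:2000, 1)
        ref <- random_dna(L)
        strain <- ref
        # random edits: substitutions, deletions, insertions
        for (e in 1:sample(1:4, 1)) {
            p <- sample(50:(nchar(strain) - 60), 1)
            type <- sample(c("sub", "del", "ins"), 1)
            if (type == "sub") substr(strain, p, p + 3) <- random_dna(4)
            else if (type == "del")
                strain <- paste0(substr(strain, 1, p),
                                 substr(strain, p + 6, nchar(strain)))
            else strain <- paste0(substr(strain, 1, p), random_dna(5),
                                  substr(strain, p + 1, nchar(strain)))
        }
        k <- 11L
        sset <- new("StrainKmerSet", strain = "S", k = k,
                    members = names(kmerCounts(countKmers(strain, k))),
                    minIndividuals = 1L)
        sc <- scanReference(c(c1 = ref), sset)
        expect_identical(sc@masks$c1$presence, oracle_presence(ref, strain, k))
    }
})

test_that("altered runs are maximal blocks with conserved total length", {
    pres <- rep(TRUE, 60)
    pres[c(11, 12, 13, 51)] <- FALSE   # 0-based altered {10,11,12,50}
    sc <- manual_scan(pres, k = 5)
    runs <- callAlteredRuns(sc)
    expect_identical(GenomicRanges::start(runs) - 1L, c(10L, 50L))
    expect_identical(GenomicRanges::end(runs), c(13L, 51L))
    expect_identical(S4Vectors::mcols(runs)$length, c(3L, 1L))
    expect_identical(sum(S4Vectors::mcols(runs)$length), sum(!pres))
    # no altered positions -> empty
    expect_length(callAlteredRuns(manual_scan(rep(TRUE, 30), k = 5)), 0L)
    # unscannable bases are not called altered
    sc2 <- manual_scan(pres, k = 5, scannable = c(rep(FALSE, 12), rep(TRUE, 48)))
    runs2 <- callAlteredRuns(sc2)
    expect_identical(GenomicRanges::start(runs2) - 1L, c(12L, 50L))
})

test_that("insertion calls require altered-free absent runs", {
    k <- 5L
    pres <- rep(TRUE, 40)
    astart <- rep(FALSE, 36)
    astart[11:14] <- TRUE   # 0-based absent run [10,13], span bases 10..17
    sc <- manual_scan(pres, k = k, absentStart = astart)
    ins <- callInsertions(sc)
    expect_length(ins, 1L)
    expect_identical(GenomicRanges::start(ins) - 1L, 10L + k - 1L)  # junction
    expect_identical(GenomicRanges::width(ins), 0L)
    expect_identical(S4Vectors::mcols(ins)$length, 4L)
    # absent run overlapping altered bp is not an insertion
    pres2 <- pres; pres2[16] <- FALSE
    sc2 <- manual_scan(pres2, k = k, absentStart = astart)
    expect_length(callInsertions(sc2), 0L)
    # no absent starts -> empty
    expect_length(callInsertions(manual_scan(pres, k = k)), 0L)
})

test_that("growing the strain set never increases the altered bp count", {
    set.seed(21)
    ref <- random_dna(1500)
    allk <- names(kmerCounts(countKmers(ref, 11L)))
    base <- sample(allk, floor(length(allk) * 0.6))
    grow <- c(base, sample(setdiff(allk, base), 30))
    alt <- function(mem) sum(alteredBasepairs(scanReference(c(r = ref),
        new("StrainKmerSet", strain = "S", k = 11L, members = mem,
            minIndividuals = 1L)))$altered)
    expect_gte(alt(base), alt(grow))
    expect_gte(alt(grow), alt(allk))
    expect_identical(alt(allk), 0L)
})

test_that("swapping strain labels swaps the scan outputs", {
    set.seed(33)
    ref <- random_dna(800)
    memA <- names(kmerCounts(countKmers(substr(ref, 1, 500), 9L)))
    memB <- names(kmerCounts(countKmers(substr(ref, 300, 800), 9L)))
    mk <- function(m, nm) new("StrainKmerSet", strain = nm, k = 9L,
                              members = m, minIndividuals = 1L)
    scAB <- list(A = scanReference(c(r = ref), mk(memA, "A")),
                 B = scanReference(c(r = ref), mk(memB, "B")))
    scBA <- list(B = scanReference(c(r = ref), mk(memB, "B")),
                 A = scanReference(c(r = ref), mk(memA, "A")))
    expect_identical(scAB$A@masks, scBA$A@masks)
    expect_identical(scAB$B@masks, scBA$B@masks)
    expect_false(identical(scAB$A@masks, scAB$B@masks))
})

test_that("BED export writes 0-based half-open intervals", {
    pres <- rep(TRUE, 30); pres[11:13] <- FALSE
    sc <- manual_scan(pres, k = 5)
    runs <- callAlteredRuns(sc)
    ins <- callInsertions(manual_scan(rep(TRUE, 30), k = 5,
        absentStart = c(rep(FALSE, 5), rep(TRUE, 4), rep(FALSE, 17))))
    f <- tempfile(fileext = ".bed")
    writeVariantsBed(suppressWarnings(c(runs, ins)), f)
    bed <- utils::read.table(f, sep = "\t")
    expect_identical(bed$V2, c(10L, 9L))        # 0-based starts
    expect_identical(bed$V3, c(13L, 9L))        # half-open ends; width 0 junction
    expect_identical(bed$V4, c("altered_run", "insertion"))
    expect_identical(bed$V5, c(3L, 4L))
})
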