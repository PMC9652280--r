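# Independent brute-force oracles, deliberately implemented with plain R
# string handling (no shared code with the package's C++ engine).

revcomp_chr <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# dictionary-based canonical k-mer counting by direct window enumeration
oracle_count_kmers <- function(seqs, k) {
    env <- new.env(hash = TRUE)
    for (s in seqs) {
        L <- nchar(s)
        if (L < k) next
        for (i in seq_len(L - k + 1L)) {
            w <- substr(s, i, i + k - 1L)
            if (grepl("[^ACGT]", w)) next
            rc <- revcomp_chr(w)
            cw <- if (w <= rc) w else rc
            cur <- env[[cw]]
            env[[cw]] <- if (is.null(cur)) 1L else cur + 1L
        }
    }
    keys <- sort(ls(env))
    stats::setNames(vapply(keys, function(kk) env[[kk]], 0L), keys)
}

# presence mask by substring search of each reference window against the
# strain genome and its reverse complement
oracle_presence <- function(ref_contig, strain_genome, k) {
    L <- nchar(ref_contig)
    pres <- rep(FALSE, L)
    if (L < k) return(pres)
    rc_genome <- revcomp_chr(strain_genome)
    for (i in seq_len(L - k + 1L)) {
        w <- substr(ref_contig, i, i + k - 1L)
        if (grepl("[^ACGT]", w)) next
        if (grepl(w, strain_genome, fixed = TRUE) ||
            grepl(w, rc_genome, fixed = TRUE))
            pres[i:(i + k - 1L)] <- TRUE
    }
    pres
}

random_dna <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# IndividualKmerSet from an explicit member list (for aggregate tests)
iks <- function(members, k = 3L, id = "s") {
    new("IndividualKmerSet", k = as.integer(k),
        members = as.character(members), threshold = 1L,
        lowConfidence = FALSE, sampleId = id)
}

# ReferenceScan with hand-built masks on a single contig
manual_scan <- function(presence, k, absentStart = NULL, scannable = NULL,
                        contig = "chr1", strain = "A") {
    L <- length(presence)
    nw <- max(0L, L - k + 1L)
    if (is.null(scannable)) scannable <- rep(TRUE, L)
    if (is.null(absentStart)) absentStart <- rep(FALSE, nw)
    new("ReferenceScan", k = as.integer(k), strain = strain,
        masks = stats::setNames(list(list(
            presence = presence, scannable = scannable,
            absentStart = absentStart, validStart = rep(TRUE, nw))), contig))
}

# expected per-gene counts computed directly from a planted truth table
# (interval arithmetic independent of the scan/count code paths)
truth_region_counts <- function(truth, region_start1, region_end1) {
    region_start1 <- as.integer(region_start1)
    region_end1 <- as.integer(region_end1)
    abp <- 0L; nvar <- 0L
    for (i in seq_len(nrow(truth))) {
        v <- truth[i, ]
        if (v$vclass == "insertion") {
            j0 <- v$ref_start   # 0-based junction
            if (region_start1 <= j0 && j0 < region_end1) nvar <- nvar + 1L
        } else {
            s1 <- v$ref_start + 1L; e1 <- v$ref_start + v$length
            ov <- min(e1, region_end1) - max(s1, region_start1) + 1L
            if (ov > 0L) {
                nvar <- nvar + 1L
                abp <- abp + ov
            }
        }
    }
    list(altered_bp = abp, variants = nvar)
}
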