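#' @include annotation.R
#' @importFrom Biostrings DNAString matchPattern
NULL

#' Restriction enzyme descriptor
#'
#' @slot name enzyme name.
#' @slot site IUPAC recognition sequence (top strand).
#' @slot cutOffset top-strand cut offset within the site (0-based; a cut
#'   offset of 2 for site GRCGYC means GR^CGYC).
#' @export
setClass("RestrictionEnzyme",
    representation(name = "character", site = "character",
                   cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
    msg <- NULL
    if (!nchar(object@site)) msg <- c(msg, "empty recognition site")
    if (!grepl("^[ACGTRYSWKMBDHVN]+$", object@site))
        msg <- c(msg, "site must be IUPAC nucleotide codes")
    if (object@cutOffset < 0L || object@cutOffset > nchar(object@site))
        msg <- c(msg, "cut offset outside the site")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "RestrictionEnzyme", function(object) {
    s <- object@site
    cat(sprintf("RestrictionEnzyme %s: %s^%s\n", object@name,
        substr(s, 1L, object@cutOffset),
        substr(s, object@cutOffset + 1L, nchar(s))))
})

#' @describeIn restrictionEnzyme BsaHI (GR^CGYC), the default enzyme of
#'   the PRKAG3 RFLP assay. Its degenerate site is its own reverse
#'   complement, so top-strand scanning finds every site.
#' @export
bsaHI <- function() restrictionEnzyme("BsaHI", "GRCGYC", 2L)

#' Construct a restriction enzyme
#'
#' @param name enzyme name.
#' @param site IUPAC recognition sequence.
#' @param cutOffset 0-based top-strand cut offset within the site.
#' @return a [RestrictionEnzyme].
#' @examples
#' bsaHI()
#' @export
restrictionEnzyme <- function(name, site, cutOffset) {
    new("RestrictionEnzyme", name = as.character(name),
        site = toupper(as.character(site)),
        cutOffset = as.integer(cutOffset))
}

.one_seq <- function(x, what = "sequence") {
    if (is(x, "DNAString")) return(as.character(x))
    if (is(x, "DNAStringSet")) {
        if (length(x) != 1L) stop(what, " must be a single sequence")
        return(as.character(x[[1L]]))
    }
    if (is.character(x) && length(x) == 1L) return(toupper(x))
    stop(what, " must be a single DNA sequence")
}

.revcomp_chr <- function(x)
    as.character(reverseComplement(DNAString(x)))

#' In-silico PCR
#'
#' Searches the template (both orientations) for an exact match of the
#' forward primer followed downstream by an exact match of the reverse
#' complement of the reverse primer, and returns the smallest product not
#' exceeding `maxProduct`. The amplicon spans from the first base of the
#' forward-primer site to the last base of the reverse-primer site.
#'
#' @param template template sequence (DNAString, single-sequence
#'   DNAStringSet or character).
#' @param forward,reverse primer sequences, 5' to 3', ACGT only.
#' @param maxProduct maximum product length in bp.
#' @return character scalar, the amplicon sequence (5' to 3' with respect
#'   to the forward primer), with attributes `start`, `end` (1-based on
#'   the matched orientation) and `orientation` ("+" or "-").
#' @details Errors: "no amplification" when no primer pair orientation
#'   yields a product within `maxProduct`; an ambiguity error when several
#'   distinct loci give products of the same minimal length.
#' @examples
#' fwd <- "ACGTACGTAC"; rev <- "TTGGCCAATT"
#' tmpl <- paste0("GG", fwd, strrep("A", 40), as.character(
#'   Biostrings::reverseComplement(Biostrings::DNAString(rev))), "CC")
#' nchar(inSilicoPCR(tmpl, fwd, rev))  # 10 + 40 + 10
#' @export
inSilicoPCR <- function(template, forward, reverse, maxProduct = 5000L) {
    tmpl <- .one_seq(template, "template")
    forward <- .one_seq(forward, "forward primer")
    reverse <- .one_seq(reverse, "reverse primer")
    if (!grepl("^[ACGT]+$", forward) || !grepl("^[ACGT]+$", reverse))
        stop("primers must be plain ACGT sequences")
    rc_rev <- .revcomp_chr(reverse)

    scan_orient <- function(subject, orient) {
        subj <- DNAString(subject)
        f <- BiocGenerics::start(matchPattern(DNAString(forward), subj))
        r <- BiocGenerics::end(matchPattern(DNAString(rc_rev), subj))
        out <- list()
        for (fs in f) for (re in r) {
            len <- re - fs + 1L
            if (len >= nchar(forward) + nchar(reverse) && len <= maxProduct)
                out[[length(out) + 1L]] <-
                    list(start = fs, end = re, len = len, orient = orient,
                         seq = substr(subject, fs, re))
        }
        out
    }
    cand <- c(scan_orient(tmpl, "+"),
              scan_orient(.revcomp_chr(tmpl), "-"))
    if (!length(cand)) stop("no amplification")
    lens <- vapply(cand, `[[`, 0L, "len")
    best <- cand[lens == min(lens)]
    seqs <- vapply(best, `[[`, "", "seq")
    if (length(unique(seqs)) > 1L) {
        loci <- vapply(best, function(x)
            sprintf("%s:%d-%d", x$orient, x$start, x$end), "")
        stop("ambiguous amplification: products of equal length at loci ",
             paste(loci, collapse = ", "))
    }
    amp <- best[[1L]]
    structure(amp$seq, start = amp$start, end = amp$end,
              orientation = amp$orient)
}

#' Restriction digest of an amplicon
#'
#' Scans the top strand for the enzyme's IUPAC recognition site and cuts
#' at `site start + cut offset`. Fragment lengths are returned 5' to 3'
#' and always sum to the amplicon length; an amplicon without a site
#' yields a single full-length fragment.
#'
#' @param amplicon DNA sequence (character/DNAString), ACGT only.
#' @param enzyme a [RestrictionEnzyme]; default BsaHI.
#' @return integer vector of fragment lengths, 5' to 3'.
#' @examples
#' digestAmplicon(paste0("AAAA", "GACGCC", "AAAA"))  # 6 8
#' @export
digestAmplicon <- function(amplicon, enzyme = bsaHI()) {
    amp <- .one_seq(amplicon, "amplicon")
    if (!grepl("^[ACGT]*$", amp))
        stop("amplicon must be a plain ACGT sequence")
    if (!nchar(amp)) return(integer(0))
    hits <- matchPattern(DNAString(enzyme@site), DNAString(amp),
                         fixed = FALSE)
    cuts0 <- BiocGenerics::start(hits) - 1L + enzyme@cutOffset
    cuts0 <- sort(unique(cuts0[cuts0 > 0L & cuts0 < nchar(amp)]))
    as.integer(diff(c(0L, cuts0, nchar(amp))))
}

.rflp_patterns <- list(
    "I/I" = c(436L, 109L),
    "V/V" = c(317L, 119L, 109L),
    "I/V" = c(436L, 317L, 119L, 109L))

#' Classify an RFLP band pattern into a PRKAG3 genotype
#'
#' Compares the observed band set (unique fragment lengths; gel semantics,
#' order and multiplicity ignored) against the three diagnostic patterns:
#' I/I = 436 + 109 bp, V/V = 317 + 119 + 109 bp, I/V = all four bands.
#' Anything else is "unclassified".
#'
#' @param bands numeric vector of observed fragment lengths (bp), or a
#'   list of two such vectors (one per allele), whose union is classified.
#' @param tolerance permitted per-band length deviation in bp (default 0,
#'   appropriate for in-silico digests).
#' @return one of "V/V", "I/I", "I/V", "unclassified".
#' @examples
#' classifyGenotype(c(436, 109))             # "I/I"
#' classifyGenotype(list(c(436, 109), c(317, 119, 109)))  # "I/V"
#' @export
classifyGenotype <- function(bands, tolerance = 0) {
    if (is.list(bands)) bands <- unlist(bands)
    bands <- sort(unique(as.numeric(bands)), decreasing = TRUE)
    if (!length(bands) || any(bands <= 0))
        return("unclassified")
    for (g in names(.rflp_patterns)) {
        pat <- sort(.rflp_patterns[[g]], decreasing = TRUE)
        if (length(pat) == length(bands) &&
            all(abs(pat - bands) <= tolerance))
            return(g)
    }
    "unclassified"
}

#' PRKAG3 RFLP assay primers
#'
#' The published assay primer pair, 5' to 3'.
#' @return named character vector with elements `forward` and `reverse`.
#' @export
prkag3Primers <- function() {
    c(forward = "ACCAGCAGCCTTAGATCTGGAACAAATGTG",
      reverse = "TTCCTTCCTCCGCCTGTCCTCTTCTTACTT")
}

#' Synthetic PRKAG3-like RFLP template pair
#'
#' The published assay is defined only by its primers, the 545 bp product
#' and the BsaHI band patterns (V allele 317/119/109 bp; I allele 436/109
#' bp; the causal nucleotide is not public). This constructor builds a
#' SYNTHETIC template pair that satisfies exactly those constraints: a
#' 545 bp amplicon flanked by the primer sites, one BsaHI site cutting at
#' position 317 whose final codon is GTC (valine) and one cutting at 436.
#' The I allele carries the single-base edit GTC -> ATC (Val -> Ile) that
#' ablates the first site, mirroring the codon-199 polymorphism mechanism.
#' The sequences are NOT the GenBank PRKAG3 record; they are deterministic
#' synthetic stand-ins for exercising the assay logic.
#'
#' @param flank bp of synthetic flanking sequence added on each side of
#'   the amplicon (so that primer search is non-trivial).
#' @return a [Biostrings::DNAStringSet] with elements
#'   `allele_V_synthetic` and `allele_I_synthetic`.
#' @examples
#' tpl <- rflpReferenceTemplate()
#' amp <- inSilicoPCR(tpl[["allele_V_synthetic"]], prkag3Primers()["forward"],
#'                    prkag3Primers()["reverse"])
#' nchar(amp)             # 545
#' digestAmplicon(amp)    # 317 119 109
#' @export
rflpReferenceTemplate <- function(flank = 80L) {
    pr <- prkag3Primers()
    fwd <- unname(pr["forward"])
    rc_rev <- .revcomp_chr(unname(pr["reverse"]))
    # A/T-only filler: cannot form a BsaHI site (which needs G and C) and
    # cannot recreate the GC-containing primer sequences
    at_fill <- function(n) paste(rep_len(c("A", "T", "A", "A", "T", "T"), n),
                                 collapse = "")
    # amplicon layout (0-based): [0,30) fwd, site A [315,321) = GACGTC
    # (cut 317, codon GTC = Val), site B [434,440) = GGCGCC (cut 436),
    # [515,545) rc(reverse)
    seg1 <- at_fill(315L - 30L)
    seg2 <- at_fill(434L - 321L)
    seg3 <- at_fill(515L - 440L)
    ampV <- paste0(fwd, seg1, "GACGTC", seg2, "GGCGCC", seg3, rc_rev)
    stopifnot(nchar(ampV) == 545L)
    ampI <- ampV
    substr(ampI, 319L, 319L) <- "A"   # GTC -> ATC at the valine codon
    fl <- at_fill(flank)
    out <- Biostrings::DNAStringSet(c(
        allele_V_synthetic = paste0(fl, ampV, fl),
        allele_I_synthetic = paste0(fl, ampI, fl)))
    out
}

#' Apply a single-base edit to a template
#'
#' Utility for representing a user-specified point substitution (such as a
#' site-ablating SNP) on a template sequence.
#'
#' @param template DNA sequence (character/DNAString/1-sequence set).
#' @param pos 1-based position of the edit.
#' @param base replacement base (A/C/G/T).
#' @return character scalar, the edited sequence.
#' @export
applyPointEdit <- function(template, pos, base) {
    s <- .one_seq(template, "template")
    pos <- as.integer(pos)
    base <- toupper(as.character(base))
    if (pos < 1L || pos > nchar(s)) stop("edit position outside template")
    if (!base %in% c("A", "C", "G", "T")) stop("base must be one of ACGT")
    substr(s, pos, pos) <- base
    s
}
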