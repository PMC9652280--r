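#' @include genotyping.R
#' @importFrom Biostrings writeXStringSet
NULL

# run expr under a private RNG stream so callers' RNG state is untouched
.with_seed <- function(seed, expr) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be a finite integer")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Simulate a random reference genome
#'
#' Bases are drawn i.i.d. with the configured GC fraction (G and C
#' equiprobable, likewise A and T). Fully reproducible from the seed.
#'
#' @param length total reference length in bp (split evenly over contigs);
#'   must be at least 4k.
#' @param nContigs number of contigs.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param k k-mer length the reference is meant to be scanned with (used
#'   only for the minimum-length check).
#' @return a named [Biostrings::DNAStringSet].
#' @export
makeReference <- function(length, nContigs = 1L, gc = 0.41, seed = 1L,
                          k = 27L) {
    length <- as.integer(length)
    nContigs <- as.integer(nContigs)
    if (length < 4L * k)
        stop("reference length must be at least 4k (", 4L * k, " bp)")
    if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
    sizes <- rep(length %/% nContigs, nContigs)
    sizes[1L] <- sizes[1L] + length %% nContigs
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- .with_seed(seed, lapply(sizes, function(n)
        paste(sample(names(probs), n, replace = TRUE, prob = probs),
              collapse = "")))
    names(seqs) <- paste0("contig", seq_len(nContigs))
    Biostrings::DNAStringSet(unlist(seqs))
}

.rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# positions (0-based) with pairwise gap >= minGap within [margin, L-margin)
.place_positions <- function(L, n, minGap, margin) {
    if (n == 0L) return(integer(0))
    usable <- L - 2L * margin - (n - 1L) * minGap
    if (usable < 0L)
        stop(sprintf(paste0("cannot place %d variants with spacing %d and ",
             "end margin %d in a contig of %d bp (need >= %d bp)"),
             n, minGap, margin, L, 2L * margin + (n - 1L) * minGap))
    extras <- sort(sample.int(usable + 1L, n, replace = TRUE) - 1L)
    margin + (seq_len(n) - 1L) * minGap + extras
}

#' Plant substitutions, deletions and insertions into a reference
#'
#' Derives a strain genome from the reference by planting variants of the
#' three classes at positions separated by at least `spacing` reference bp
#' and at least `2k` bp from contig ends, so each variant leaves an
#' isolated, analytically exact k-mer signature. Substituted bases differ
#' from the reference at every position, and substituted/inserted sequence
#' is rejection-sampled so that none of the novel strain k-mers collides
#' with a k-mer already present in the reference.
#'
#' @param reference a [Biostrings::DNAStringSet] (or named character).
#' @param nSubstitutions,nDeletions,nInsertions variant counts per class.
#' @param subLengthRange integer range of substitution lengths (default
#'   single-base).
#' @param indelLengthRange integer range of deletion/insertion lengths.
#' @param spacing minimum distance between planted variant start positions
#'   (reference bp); default 2k guarantees non-interacting signatures.
#' @param k k-mer length the signatures are designed for.
#' @param seed integer seed.
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `truth`,
#'   a data.frame with columns contig, ref_start (0-based), vclass
#'   ("substitution"/"deletion"/"insertion"), length, alt_seq, sorted by
#'   (contig, ref_start). Applying `truth` to the reference with
#'   [applyVariants()] reproduces `genome` exactly.
#' @export
plantVariants <- function(reference, nSubstitutions = 0L, nDeletions = 0L,
                          nInsertions = 0L, subLengthRange = c(1L, 1L),
                          indelLengthRange = c(2L, 10L), spacing = NULL,
                          k = 27L, seed = 1L) {
    contigs <- .as_contig_strings(reference)
    k <- .check_k(k)
    if (is.null(spacing)) spacing <- 2L * k
    n_total <- nSubstitutions + nDeletions + nInsertions
    ref_kmers <- local({
        res <- cpp_count_kmers(unname(contigs), k)
        res$kmer
    })

    if (n_total == 0L)
        return(list(genome = Biostrings::DNAStringSet(contigs),
                    truth = .empty_truth()))

    .with_seed(seed, {
        # distribute variants over contigs proportional to length
        Ls <- nchar(contigs)
        ci <- sort(sample(seq_along(contigs), n_total, replace = TRUE,
                          prob = Ls / sum(Ls)))
        classes <- sample(rep(c("substitution", "deletion", "insertion"),
                              c(nSubstitutions, nDeletions, nInsertions)))
        maxlen <- max(c(subLengthRange, indelLengthRange))
        # deletions may shift by up to maxShift to dodge boundary-ambiguous
        # junctions; the gap and margin budgets absorb the worst case so
        # the spacing and contig-end guarantees survive any shift
        maxShift <- max(maxlen, 4L * k)
        minGap <- spacing + maxlen + 2L * maxShift
        margin <- 2L * k + maxShift

        truth <- list()
        idx <- 0L
        for (cc in seq_along(contigs)) {
            n_here <- sum(ci == cc)
            if (!n_here) next
            pos <- .place_positions(Ls[cc], n_here, minGap, margin)
            for (p in pos) {
                idx <- idx + 1L
                vclass <- classes[idx]
                len <- if (vclass == "substitution")
                    .sample_range(subLengthRange)
                else .sample_range(indelLengthRange)
                planted <- .plant_one(contigs[[cc]], p, len, vclass, k,
                                      ref_kmers, maxShift = maxShift)
                truth[[idx]] <- data.frame(
                    contig = names(contigs)[cc], ref_start = planted$p,
                    vclass = vclass, length = len, alt_seq = planted$alt)
            }
        }
        truth <- do.call(rbind, truth)
        truth <- truth[order(truth$contig, truth$ref_start), , drop = FALSE]
        rownames(truth) <- NULL
        list(genome = applyVariants(contigs, truth), truth = truth)
    })
}

.empty_truth <- function()
    data.frame(contig = character(0), ref_start = integer(0),
               vclass = character(0), length = integer(0),
               alt_seq = character(0))

# rejection-sample alt sequence: every substituted base differs from the
# reference and no novel strain window recreates a reference k-mer;
# NULL when no collision-free content is found at this position
.sample_alt <- function(ctg, p, len, vclass, k, ref_kmers) {
    for (try in seq_len(50L)) {
        if (vclass == "substitution") {
            ref_bases <- strsplit(substr(ctg, p + 1L, p + len), "")[[1L]]
            alt <- vapply(ref_bases, function(b)
                sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
            alt <- paste(alt, collapse = "")
            region <- paste0(substr(ctg, p - k + 2L, p), alt,
                             substr(ctg, p + len + 1L, p + len + k - 1L))
        } else {  # insertion before reference base p
            alt <- .rand_bases(len)
            region <- paste0(substr(ctg, p - k + 2L, p), alt,
                             substr(ctg, p + 1L, p + k - 1L))
        }
        novel <- cpp_count_kmers(region, k)$kmer
        if (!length(novel) || !any(novel %in% ref_kmers))
            return(alt)
    }
    NULL
}

# uniform draw from an inclusive integer range (robust to lo == hi)
.sample_range <- function(range) {
    lo <- as.integer(range[1L]); hi <- as.integer(range[2L])
    if (lo >= hi) lo else (lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

# plant one variant at (or near) 0-based position p so that no k-mer of
# the edited strain neighbourhood coincides with a reference k-mer: the
# signature then is analytically exact. Content is resampled where it is
# free (substitution/insertion); the position is shifted by 0, +1, -1, ...
# where content alone cannot avoid a collision (always for deletions,
# whose content is fixed; occasionally for short substitutions at small k,
# which have few alternative alleles).
.plant_one <- function(ctg, p, len, vclass, k, ref_kmers, maxShift = 10L) {
    offsets <- c(0L, as.vector(rbind(seq_len(maxShift), -seq_len(maxShift))))
    L <- nchar(ctg)
    for (off in offsets) {
        q <- p + off
        if (q < 2L * k || q + len > L - 2L * k) next
        if (vclass == "deletion") {
            junction <- paste0(substr(ctg, q - k + 2L, q),
                               substr(ctg, q + len + 1L, q + len + k - 1L))
            jk <- cpp_count_kmers(junction, k)$kmer
            if (!any(jk %in% ref_kmers))
                return(list(p = q, alt = ""))
        } else {
            alt <- .sample_alt(ctg, q, len, vclass, k, ref_kmers)
            if (!is.null(alt)) return(list(p = q, alt = alt))
        }
    }
    stop("could not plant a collision-free ", vclass, " near position ", p)
}

#' Apply a planted-variant truth table to a reference
#'
#' Reconstructs the strain genome from the reference and the truth list;
#' the inverse of what [plantVariants()] promises.
#'
#' @param reference [Biostrings::DNAStringSet] or named character.
#' @param truth truth data.frame (see [plantVariants()]).
#' @return a [Biostrings::DNAStringSet].
#' @export
applyVariants <- function(reference, truth) {
    contigs <- .as_contig_strings(reference)
    out <- contigs
    for (nm in names(contigs)) {
        tt <- truth[truth$contig == nm, , drop = FALSE]
        if (!nrow(tt)) next
        tt <- tt[order(tt$ref_start), , drop = FALSE]
        s <- contigs[[nm]]
        pieces <- character(0)
        cursor <- 0L  # 0-based, bases [0, cursor) already emitted
        for (i in seq_len(nrow(tt))) {
            p <- tt$ref_start[i]
            pieces <- c(pieces, substr(s, cursor + 1L, p))
            if (tt$vclass[i] == "substitution") {
                pieces <- c(pieces, tt$alt_seq[i])
                cursor <- p + tt$length[i]
            } else if (tt$vclass[i] == "deletion") {
                cursor <- p + tt$length[i]
            } else {  # insertion before base p
                pieces <- c(pieces, tt$alt_seq[i])
                cursor <- p
            }
        }
        pieces <- c(pieces, substr(s, cursor + 1L, nchar(s)))
        out[[nm]] <- paste(pieces, collapse = "")
    }
    Biostrings::DNAStringSet(out)
}

#' Simulate shotgun reads from a genome
#'
#' Draws `ceiling(coverage x genome length / read length)` reads uniformly
#' from both strands with i.i.d. substitution errors. Single-end only: a
#' paired-end run is emulated as two independent single-end passes, which
#' is equivalent for k-mer content.
#'
#' @param genome [Biostrings::DNAStringSet] or named character.
#' @param coverage mean fold-coverage (> 0).
#' @param readLength read length in bp (<= shortest contig).
#' @param errorRate per-base substitution error probability.
#' @param seed integer seed.
#' @return a named [Biostrings::DNAStringSet] of reads.
#' @export
simulateReads <- function(genome, coverage, readLength = 100L,
                          errorRate = 0, seed = 1L) {
    contigs <- .as_contig_strings(genome)
    if (coverage <= 0) stop("coverage must be positive")
    readLength <- as.integer(readLength)
    Ls <- nchar(contigs)
    if (readLength > max(Ls)) stop("read length exceeds genome length")
    usable <- which(Ls >= readLength)
    total <- sum(Ls)
    n <- as.integer(ceiling(coverage * total / readLength))

    .with_seed(seed, {
        w <- Ls[usable] - readLength + 1L
        ci <- usable[sample.int(length(usable), n, replace = TRUE,
                                prob = w / sum(w))]
        starts <- floor(stats::runif(n) * (Ls[ci] - readLength + 1L)) + 1L
        reads <- character(n)
        for (cc in unique(ci)) {
            sel <- ci == cc
            reads[sel] <- substring(contigs[[cc]], starts[sel],
                                    starts[sel] + readLength - 1L)
        }
        if (errorRate > 0) {
            nerr <- stats::rbinom(1L, n * readLength, errorRate)
            if (nerr > 0L) {
                loc <- sample.int(n * readLength, nerr)
                ri <- (loc - 1L) %/% readLength + 1L
                pi <- (loc - 1L) %% readLength + 1L
                for (e in seq_len(nerr)) {
                    b <- substr(reads[ri[e]], pi[e], pi[e])
                    nb <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
                    substr(reads[ri[e]], pi[e], pi[e]) <- nb
                }
            }
        }
        rev <- stats::runif(n) < 0.5
        out <- Biostrings::DNAStringSet(reads)
        if (any(rev)) out[rev] <- reverseComplement(out[rev])
        names(out) <- sprintf("read_%06d", seq_len(n))
        out
    })
}

#' Write reads as FASTQ with a fixed quality symbol
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output FASTQ path (".gz" suffix gzips transparently).
#' @param quality single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path, quality = "I") {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    seqs <- as.character(reads)
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
    lines <- rbind(paste0("@", ids), seqs, "+",
                   vapply(nchar(seqs), function(n)
                       strrep(quality, n), ""))
    writeLines(as.vector(lines), con)
    invisible(path)
}

#' Write a toy GFF3 annotation
#'
#' Emits gene, mRNA, exon and CDS features (one transcript per gene; CDS
#' identical to the exons) in 1-based inclusive GFF3 coordinates. The
#' output round-trips through [loadAnnotation()].
#'
#' @param genes data.frame with columns gene_id, symbol, contig, start,
#'   end (1-based inclusive) and optionally strand.
#' @param exons data.frame with columns gene_id, start, end (1-based
#'   inclusive); exons of one gene must lie within the gene span and must
#'   not overlap each other.
#' @param path output GFF3 path.
#' @param contigLengths optional named integer vector for
#'   `##sequence-region` headers and bounds checking.
#' @return `path`, invisibly.
#' @export
makeAnnotation <- function(genes, exons, path, contigLengths = NULL) {
    if (!all(c("gene_id", "symbol", "contig", "start", "end") %in%
             names(genes)))
        stop("genes must have columns gene_id, symbol, contig, start, end")
    if (nrow(genes) && !all(c("gene_id", "start", "end") %in% names(exons)))
        stop("exons must have columns gene_id, start, end")
    strand <- if ("strand" %in% names(genes)) genes$strand
              else rep("+", nrow(genes))
    lines <- "##gff-version 3"
    if (!is.null(contigLengths))
        lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                                  names(contigLengths),
                                  as.integer(contigLengths)))
    for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        if (!is.null(contigLengths)) {
            cl <- contigLengths[[g$contig]]
            if (is.null(cl) || g$end > cl || g$start < 1L)
                stop("gene '", g$gene_id, "' does not fit its contig")
        }
        ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
        ex <- ex[order(ex$start), , drop = FALSE]
        if (nrow(ex)) {
            if (any(ex$start < g$start) || any(ex$end > g$end))
                stop("exon outside gene span for gene '", g$gene_id, "'")
            if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
                stop("overlapping exons within gene '", g$gene_id, "'")
        }
        tid <- paste0(g$gene_id, ".t1")
        lines <- c(lines,
            sprintf("%s\tstrainscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                    g$contig, g$start, g$end, strand[i], g$gene_id,
                    g$symbol),
            sprintf("%s\tstrainscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                    g$contig, g$start, g$end, strand[i], tid, g$gene_id))
        for (j in seq_len(nrow(ex))) {
            lines <- c(lines,
                sprintf("%s\tstrainscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                        g$contig, ex$start[j], ex$end[j], strand[i], tid,
                        j, tid),
                sprintf("%s\tstrainscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
                        g$contig, ex$start[j], ex$end[j], strand[i], tid,
                        j, tid))
        }
    }
    writeLines(lines, path)
    invisible(path)
}

#' Write a planted-variant truth table as TSV
#'
#' Coordinates are 0-based half-open on the reference (`ref_start`,
#' `ref_end = ref_start + length` for substitutions/deletions;
#' `ref_end = ref_start` for insertions).
#'
#' @param truth truth data.frame from [plantVariants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthTsv <- function(truth, path) {
    ref_end <- ifelse(truth$vclass == "insertion", truth$ref_start,
                      truth$ref_start + truth$length)
    df <- data.frame(contig = truth$contig, ref_start = truth$ref_start,
                     ref_end = ref_end, vclass = truth$vclass,
                     length = truth$length, alt_seq = truth$alt_seq)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Simulate a complete two-strain cohort with planted ground truth
#'
#' Builds a random reference, derives one genome per strain with disjoint
#' planted variants, simulates per-individual reads (optionally with
#' individual-private variants to exercise the at-least-m-of-N rule),
#' writes a toy annotation and machine-readable truth tables, and returns
#' everything both in memory and (optionally) on disk as
#' FASTA/FASTQ/GFF3/TSV. All outputs are byte-reproducible from the
#' configuration.
#'
#' @param referenceLength,nContigs,gc reference parameters (see
#'   [makeReference()]).
#' @param nPerStrain integer of length 2: individuals per strain.
#' @param coverage,readLength,errorRate read-simulation parameters; the
#'   defaults mirror a 30-fold, 100 bp, error-free validation regime.
#' @param variantsA,variantsB named lists with elements nSubstitutions,
#'   nDeletions, nInsertions giving planted counts per strain.
#' @param indelLengthRange,spacing,k see [plantVariants()].
#' @param nGenes number of toy genes to annotate (2 exons each).
#' @param privateRate expected number of private variants per individual
#'   (substitutions; 0 disables within-strain polymorphism).
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param dir output directory, or `NULL` to skip writing files.
#' @return list with components `reference`, `genomes` (per strain),
#'   `truth` (per strain), `reads` (list of per-individual
#'   DNAStringSets, names "A1", ..., "B1", ...), `genes`, `exons`,
#'   and `paths` (when `dir` is given).
#' @export
simulateCohort <- function(referenceLength = 100000L, nContigs = 1L,
                           gc = 0.41, nPerStrain = c(4L, 4L),
                           coverage = 30, readLength = 100L,
                           errorRate = 0,
                           variantsA = list(nSubstitutions = 20L,
                                            nDeletions = 5L,
                                            nInsertions = 5L),
                           variantsB = list(nSubstitutions = 0L,
                                            nDeletions = 0L,
                                            nInsertions = 0L),
                           indelLengthRange = c(2L, 10L), spacing = NULL,
                           k = 27L, nGenes = 5L, privateRate = 0,
                           seed = 1L, dir = NULL) {
    seed <- as.integer(seed)
    ref <- makeReference(referenceLength, nContigs, gc, seed = seed, k = k)

    plant <- function(v, s) plantVariants(ref,
        nSubstitutions = v$nSubstitutions, nDeletions = v$nDeletions,
        nInsertions = v$nInsertions, indelLengthRange = indelLengthRange,
        spacing = spacing, k = k, seed = s)
    pA <- plant(variantsA, seed + 101L)
    pB <- plant(variantsB, seed + 202L)

    reads <- list()
    ids <- character(0)
    for (strain in c("A", "B")) {
        genome <- if (strain == "A") pA$genome else pB$genome
        N <- nPerStrain[if (strain == "A") 1L else 2L]
        for (i in seq_len(N)) {
            sub_seed <- seed + 1000L * match(strain, c("A", "B")) + i
            g <- genome
            if (privateRate > 0) {
                npriv <- .with_seed(sub_seed + 5000L,
                                    stats::rpois(1L, privateRate))
                if (npriv > 0L)
                    g <- plantVariants(genome, nSubstitutions = npriv,
                                       spacing = spacing, k = k,
                                       seed = sub_seed + 7000L)$genome
            }
            id <- paste0(strain, i)
            ids <- c(ids, id)
            reads[[id]] <- simulateReads(g, coverage, readLength,
                                         errorRate, seed = sub_seed)
        }
    }

    # toy annotation: nGenes evenly spaced genes with 2 exons each
    L1 <- nchar(as.character(ref[[1L]]))
    genes <- exons <- NULL
    if (nGenes > 0L) {
        span <- L1 %/% (nGenes + 1L)
        glen <- max(200L, span %/% 2L)
        gstart <- pmin((seq_len(nGenes)) * span - glen %/% 2L, L1 - glen)
        genes <- data.frame(gene_id = sprintf("gene%02d", seq_len(nGenes)),
                            symbol = sprintf("GENE%02d", seq_len(nGenes)),
                            contig = names(ref)[1L],
                            start = gstart, end = gstart + glen - 1L)
        e1 <- data.frame(gene_id = genes$gene_id, start = genes$start,
                         end = genes$start + glen %/% 3L)
        e2 <- data.frame(gene_id = genes$gene_id,
                         start = genes$end - glen %/% 3L, end = genes$end)
        exons <- rbind(e1, e2)
    }

    out <- list(reference = ref,
                genomes = list(A = pA$genome, B = pB$genome),
                truth = list(A = pA$truth, B = pB$truth),
                reads = reads, genes = genes, exons = exons)

    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        paths <- list(reference = file.path(dir, "reference.fa"),
                      gff3 = file.path(dir, "annotation.gff3"))
        writeXStringSet(ref, paths$reference)
        writeXStringSet(pA$genome, file.path(dir, "strainA_genome.fa"))
        writeXStringSet(pB$genome, file.path(dir, "strainB_genome.fa"))
        writeTruthTsv(pA$truth, file.path(dir, "truth_strainA.tsv"))
        writeTruthTsv(pB$truth, file.path(dir, "truth_strainB.tsv"))
        if (!is.null(genes))
            makeAnnotation(genes, exons, paths$gff3,
                           contigLengths = stats::setNames(
                               Biostrings::width(ref), names(ref)))
        paths$reads <- stats::setNames(
            file.path(dir, paste0(ids, ".fastq")), ids)
        for (id in ids) writeReadsFastq(reads[[id]], paths$reads[[id]])
        out$paths <- paths
    }
    out
}
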