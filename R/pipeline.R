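#' @include synthetic-data.R
NULL

.stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
    attr(res, ".elapsed") <- proc.time()[["elapsed"]] - t0
    res
}

.norm_config <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a list or a YAML file path")
    config$k <- as.integer(config$k %||% 27L)
    config$m <- config$m %||% list()
    config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full two-strain comparison pipeline
#'
#' Executes count -> threshold -> individual sets -> aggregate -> strain
#' sets -> reference scan (each strain) -> altered-run and insertion
#' calls -> per-gene aggregation -> differential gene lists, and writes
#' BED, TSV, gene-list and manifest files to the output directory. Any
#' stage error aborts with the stage name and the offending sample.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{k}{k-mer length (default 27).}
#'     \item{reference}{reference FASTA path (or a DNAStringSet).}
#'     \item{gff3}{annotation path (optional; skips per-gene stages when
#'       absent).}
#'     \item{strains}{named list of exactly two strains; each strain is a
#'       named list of samples, each sample a list with `fastq` (vector of
#'       paths or a DNAStringSet) and optional `sex`.}
#'     \item{m}{named list / scalar: per-strain minimum individuals
#'       (default 3).}
#'     \item{thresholds}{optional named list of per-sample T overrides.}
#'     \item{subset}{optional sex label; only samples with that `sex`
#'       are used.}
#'     \item{outdir}{output directory.}
#'   }
#' @return invisibly, a list with the in-memory stage products
#'   (`aggregate`, `strainSets`, `scans`, `variants`, `geneRecords`,
#'   `differential`) and `manifest`.
#' @export
runCompare <- function(config) {
    config <- .norm_config(config)
    k <- config$k
    if (length(config$strains) != 2L)
        stop("config must declare exactly two strains")
    strain_names <- names(config$strains)
    outdir <- config$outdir %||% stop("config$outdir is required")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    t_start <- Sys.time()

    # per-individual thresholded sets
    sets <- list()
    for (sn in strain_names) {
        samples <- config$strains[[sn]]
        if (!is.null(config$subset)) {
            keep <- vapply(samples, function(s)
                identical(s$sex, config$subset), TRUE)
            samples <- samples[keep]
        }
        if (!length(samples))
            stop("no samples left for strain '", sn, "' after subsetting")
        sets[[sn]] <- lapply(names(samples), function(id) {
            .stage(paste0("count/", id), {
                tab <- countKmers(samples[[id]]$fastq, k = k, sampleId = id)
                Tov <- config$thresholds[[id]]
                individualSet(tab, threshold = Tov)
            })
        })
    }

    get_m <- function(pos) {
        m <- config$m
        if (is.null(m) || !length(m)) return(3L)
        if (!is.list(m) && length(m) == 1L) return(as.integer(m))
        v <- if (strain_names[pos] %in% names(m)) m[[strain_names[pos]]]
             else if (length(m) >= pos) m[[pos]] else NULL
        as.integer(v %||% 3L)
    }
    mA <- get_m(1L); mB <- get_m(2L)
    if (mA > length(sets[[1L]]) || mB > length(sets[[2L]]))
        stop("m exceeds the number of samples after subsetting")

    agg <- .stage("aggregate",
        aggregateStrains(sets[[1L]], sets[[2L]], strainNames = strain_names))
    writeSummaryTsv(agg, file.path(outdir, "summary_ij.tsv"))

    ref <- config$reference %||% stop("config$reference is required")
    strain_sets <- list(strainSet(agg, 1L, mA), strainSet(agg, 2L, mB))
    names(strain_sets) <- strain_names

    scans <- list(); variants <- list()
    for (sn in strain_names) {
        scans[[sn]] <- .stage(paste0("scan/", sn),
                              scanReference(ref, strain_sets[[sn]]))
        altered <- callAlteredRuns(scans[[sn]])
        ins <- callInsertions(scans[[sn]])
        variants[[sn]] <- suppressWarnings(c(altered, ins))
        writeVariantsBed(variants[[sn]],
                         file.path(outdir, paste0("variants_", sn, ".bed")))
    }

    gene_records <- NULL; differential <- NULL
    if (!is.null(config$gff3)) {
        models <- .stage("annotation", loadAnnotation(config$gff3))
        gene_records <- lapply(strain_names, function(sn)
            .stage(paste0("genes/", sn),
                   countByGene(scans[[sn]], variants[[sn]], models)))
        names(gene_records) <- strain_names
        for (sn in strain_names)
            writeGeneRecords(gene_records[[sn]],
                             file.path(outdir, paste0("genes_", sn, ".tsv")))
        differential <- differentialGenes(gene_records[[1L]],
                                          gene_records[[2L]],
                                          region = "exons",
                                          metric = "variants")
        exportGeneList(differential$symbol,
                       file.path(outdir, "differential_genes.txt"))
    }

    manifest <- list(
        config = list(k = k, m = stats::setNames(list(mA, mB), strain_names),
                      subset = config$subset,
                      strains = lapply(config$strains, names)),
        started = format(t_start), finished = format(Sys.time()),
        version = as.character(utils::packageVersion("strainscan")),
        checksums = as.list(tools::md5sum(list.files(outdir,
            full.names = TRUE, pattern = "\\.(bed|tsv|txt)$"))))
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

    invisible(list(aggregate = agg, strainSets = strain_sets, scans = scans,
                   variants = variants, geneRecords = gene_records,
                   differential = differential, manifest = manifest))
}

#' Genotype template sequences by in-silico PCR and restriction digest
#'
#' One row per template record: amplicon length, digest band lengths and
#' the classified genotype. Templates that do not amplify are flagged
#' (`genotype = "no_amplification"`) rather than fatal.
#'
#' @param templates FASTA path or [Biostrings::DNAStringSet].
#' @param out optional TSV output path.
#' @param forward,reverse primer sequences (defaults: the PRKAG3 assay
#'   primers).
#' @param enzyme a [RestrictionEnzyme] (default BsaHI).
#' @param tolerance band-length tolerance for classification (bp).
#' @return data.frame with columns sample, amplicon_length, bands
#'   (comma-separated, descending), genotype.
#' @export
runGenotype <- function(templates, out = NULL,
                        forward = prkag3Primers()["forward"],
                        reverse = prkag3Primers()["reverse"],
                        enzyme = bsaHI(), tolerance = 0) {
    if (is.character(templates) && length(templates) == 1L &&
        file.exists(templates))
        templates <- readDNAStringSet(templates)
    if (is.character(templates))
        templates <- Biostrings::DNAStringSet(templates)
    ids <- names(templates)
    if (is.null(ids)) ids <- paste0("template", seq_along(templates))
    rows <- lapply(seq_along(templates), function(i) {
        amp <- tryCatch(inSilicoPCR(templates[[i]], forward, reverse),
                        error = function(e) NULL)
        if (is.null(amp))
            return(data.frame(sample = ids[i], amplicon_length = NA_integer_,
                              bands = "", genotype = "no_amplification"))
        bands <- sort(unique(digestAmplicon(amp, enzyme)),
                      decreasing = TRUE)
        data.frame(sample = ids[i], amplicon_length = nchar(amp),
                   bands = paste(bands, collapse = ","),
                   genotype = classifyGenotype(bands, tolerance))
    })
    res <- do.call(rbind, rows)
    if (length(templates) == 0L)
        res <- data.frame(sample = character(0),
                          amplicon_length = integer(0),
                          bands = character(0), genotype = character(0))
    if (!is.null(out)) {
        utils::write.table(res, out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    res
}
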