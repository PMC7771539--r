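## Pipeline front end: one configuration drives reproducible runs of the
## five subcommands (design, barcode, simulate, count, ci). The Rscript
## wrapper in inst/scripts/barseq-cli.R exposes the same entry point from a
## shell; the exported functions remain the primary interface.

pkgVersionString <- function() {
    as.character(utils::packageVersion("BarSeqTools"))
}

provenanceLines <- function(config, seed) {
    cfg <- if (is.character(config)) unname(tools::md5sum(config)) else "inline"
    c(sprintf("BarSeqTools %s", pkgVersionString()),
      sprintf("config md5: %s", cfg),
      sprintf("seed: %s", if (is.null(seed)) "none" else seed))
}

#' Run a pipeline subcommand from a configuration
#'
#' The configuration is a flat YAML file (or an equivalent named list);
#' explicit arguments override config entries. Every stochastic subcommand
#' requires a seed. All outputs carry a provenance comment header (tool
#' version, config checksum, seed). Validation failures raise errors
#' before any output is written.
#'
#' Subcommands: \code{barcode} (strain list to barcode library),
#' \code{design} (genome + gene table to oligo sheets, scar FASTA and
#' mutant genome), \code{simulate} (competition scenario to FASTQ + truth),
#' \code{count} (sample sheet to counts TSV), \code{ci} (counts TSV to CI
#' TSV).
#'
#' @param subcommand one of \code{"design"}, \code{"barcode"},
#'   \code{"simulate"}, \code{"count"}, \code{"ci"}.
#' @param config path to a YAML config file, or a named list.
#' @param overrides named list of config overrides (win over the file).
#' @return invisibly, a list of the paths written.
#' @export
runPipeline <- function(subcommand, config, overrides = list()) {
    subcommand <- match.arg(subcommand,
                            c("design", "barcode", "simulate", "count", "ci"))
    configPath <- if (is.character(config)) config else NULL
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    cfg[names(overrides)] <- overrides
    outDir <- cfg$output_dir %||% "."
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    prov <- provenanceLines(configPath %||% cfg, cfg$seed)
    switch(subcommand,
        barcode = runBarcodeCmd(cfg, outDir, prov),
        design = runDesignCmd(cfg, outDir, prov),
        simulate = runSimulateCmd(cfg, outDir, prov),
        count = runCountCmd(cfg, outDir, prov),
        ci = runCICmd(cfg, outDir, prov))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

requireCfg <- function(cfg, keys, subcommand) {
    miss <- keys[!keys %in% names(cfg)]
    if (length(miss))
        stop(sprintf("config-error: subcommand '%s' requires: %s",
                     subcommand, paste(miss, collapse = ", ")))
}

requireFile <- function(path, what) {
    if (!file.exists(path))
        stop(sprintf("missing-file: %s '%s' does not exist", what, path))
}

runBarcodeCmd <- function(cfg, outDir, prov) {
    requireCfg(cfg, c("strains", "seed"), "barcode")
    set.seed(as.integer(cfg$seed))
    lib <- buildBarcodeLibrary(cfg$strains,
                               minDistance = cfg$min_distance %||% 3L)
    path <- file.path(outDir, "barcode_library.tsv")
    writeBarcodeLibrary(lib, path)
    invisible(list(library = path))
}

runDesignCmd <- function(cfg, outDir, prov) {
    requireCfg(cfg, c("genome_fasta", "gene_table", "barcode_library"),
               "design")
    requireFile(cfg$genome_fasta, "genome FASTA")
    requireFile(cfg$gene_table, "gene table")
    requireFile(cfg$barcode_library, "barcode library")
    genome <- readGenomeFasta(cfg$genome_fasta)
    targets <- readGeneTable(cfg$gene_table)
    lib <- readBarcodeLibrary(cfg$barcode_library)
    linkers <- defaultLinkerSet()
    paths <- list()
    mutant <- genome
    scars <- list()
    for (nm in names(targets)) {
        if (!nm %in% strainNames(lib))
            stop(sprintf("config-error: no barcode for gene '%s'", nm))
        os <- designOligos(genome, targets[[nm]],
                           annealLen = cfg$anneal_len %||% 22L,
                           linkers = linkers)
        p <- file.path(outDir, paste0("oligos_", nm, ".tsv"))
        writeOligoSheet(os, p, provenance = prov)
        paths[[paste0("oligos_", nm)]] <- p
        scar <- assembleBarScar(barcodes(lib)[[nm]], linkers)
        scars[[nm]] <- scar
        mutant <- applyDeletion(mutant, targets[[nm]], scar)
    }
    scarPath <- file.path(outDir, "scars.fasta")
    writeScarFasta(scars, scarPath)
    mutPath <- file.path(outDir, "mutant_genome.fasta")
    writeGenomeFasta(mutant, mutPath)
    invisible(c(paths, list(scars = scarPath, mutant = mutPath)))
}

runSimulateCmd <- function(cfg, outDir, prov) {
    requireCfg(cfg, c("barcode_library", "strains", "seed"), "simulate")
    requireFile(cfg$barcode_library, "barcode library")
    lib <- readBarcodeLibrary(cfg$barcode_library)
    seed <- as.integer(cfg$seed)
    comp <- competitionScenario(
        strains = cfg$strains,
        inputFreqs = if (is.null(cfg$input_freqs))
            rep(1 / length(cfg$strains), length(cfg$strains))
            else as.numeric(cfg$input_freqs),
        fitness = if (is.null(cfg$fitness))
            rep(1, length(cfg$strains)) else as.numeric(cfg$fitness),
        generations = cfg$generations %||% 15,
        bottleneck = cfg$bottleneck %||% NA,
        seed = seed)
    seqsc <- sequencingScenario(
        readsPerSample = cfg$reads_per_sample %||% 50000L,
        readLength = cfg$read_length %||% 250L,
        substitutionRate = cfg$substitution_rate %||% 0,
        revcompFraction = cfg$revcomp_fraction %||% 0.5,
        seed = seed)
    res <- simulateExperiment(comp, seqsc, lib, outDir,
                              gzip = isTRUE(cfg$gzip))
    invisible(list(sampleSheet = file.path(outDir, "samples.tsv"),
                   truth = file.path(outDir, "truth.tsv")))
}

runCountCmd <- function(cfg, outDir, prov) {
    requireCfg(cfg, c("barcode_library", "sample_sheet"), "count")
    requireFile(cfg$barcode_library, "barcode library")
    requireFile(cfg$sample_sheet, "sample sheet")
    lib <- readBarcodeLibrary(cfg$barcode_library)
    pattern <- defaultFlankPattern(
        maxFlankMismatches = cfg$max_flank_mismatches %||% 0L,
        searchRevcomp = cfg$search_revcomp %||% TRUE)
    counts <- countSamples(cfg$sample_sheet, lib, pattern)
    if (isTRUE(cfg$merge_replicates)) counts <- mergeCounts(counts)
    path <- file.path(outDir, "counts.tsv")
    writeCountsTable(counts, path, provenance = prov)
    invisible(list(counts = path))
}

runCICmd <- function(cfg, outDir, prov) {
    requireCfg(cfg, c("counts_table", "wt_strains", "input_sample"), "ci")
    requireFile(cfg$counts_table, "counts table")
    counts <- readCountsTable(cfg$counts_table)
    if (!is.null(cfg$exclude_strains))
        counts <- filterStrains(counts, cfg$exclude_strains)
    ci <- competitiveIndex(counts, wtStrains = cfg$wt_strains,
                           inputSample = cfg$input_sample,
                           outputSamples = cfg$output_samples,
                           pseudocount = isTRUE(cfg$pseudocount))
    path <- file.path(outDir, "ci.tsv")
    writeCITable(ci, path, provenance = prov)
    invisible(list(ci = path))
}
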