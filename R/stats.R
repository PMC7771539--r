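#' Per-sample relative frequencies
#'
#' RF of strain i in sample s is its count divided by the sample's total
#' over included strains. By default \code{"_other"} is excluded from both
#' numerator rows and the denominator, so frequencies describe the library
#' strains only.
#'
#' @param counts a \code{\linkS4class{BarSeqCounts}} or plain counts
#'   matrix.
#' @param includeOther keep the \code{"_other"} row and include it in
#'   denominators.
#' @return numeric matrix of relative frequencies; every column sums to 1.
#'   Attribute \code{"includeOther"} records the denominator policy.
#' @export
relativeFrequencies <- function(counts, includeOther = FALSE) {
    m <- countsMatrix(counts)
    if (!includeOther && OTHER_LABEL %in% rownames(m))
        m <- m[rownames(m) != OTHER_LABEL, , drop = FALSE]
    tot <- colSums(m)
    if (any(tot == 0))
        stop("zero total count in sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    rf <- sweep(m, 2L, tot, "/")
    structure(rf, includeOther = includeOther)
}

countsMatrix <- function(counts) {
    if (is(counts, "BarSeqCounts")) assay(counts, "counts")
    else if (is.matrix(counts)) counts
    else stop("counts must be a BarSeqCounts or a matrix")
}

#' Drop strains from a counts table before analysis
#'
#' Removes the given strains (e.g. mutants still being validated) and
#' recomputes the per-sample flank-bearing totals so conservation still
#' holds. Names not present are warned about, not errors.
#'
#' @param counts a \code{\linkS4class{BarSeqCounts}}.
#' @param exclude character vector of strain names to drop.
#' @return a \code{\linkS4class{BarSeqCounts}} without the excluded rows.
#' @export
filterStrains <- function(counts, exclude) {
    stopifnot(is(counts, "BarSeqCounts"))
    if (length(exclude) == 0L) return(counts)
    m <- assay(counts, "counts")
    absent <- setdiff(exclude, rownames(m))
    if (length(absent))
        warning("strain(s) not in table: ", paste(absent, collapse = ", "))
    drop <- rownames(m) %in% setdiff(exclude, OTHER_LABEL)
    removed <- colSums(m[drop, , drop = FALSE])
    kept <- m[!drop, , drop = FALSE]
    cd <- colData(counts)
    cd$readsWithFlanks <- cd$readsWithFlanks - removed
    cd$readsTotal <- cd$readsTotal - removed
    new("BarSeqCounts",
        SummarizedExperiment(assays = list(counts = kept), colData = cd))
}

#' Competitive index per strain and output sample
#'
#' CI = log10 [ (RF_mutant / mean RF_WT)_output / (RF_mutant /
#' mean RF_WT)_input ], with the arithmetic mean over the wild-type
#' reference strains. Wild-type strains themselves receive CI values
#' against the wild-type average, serving as neutrality controls. A strain
#' with zero output count is censored: its reported CI is the value
#' obtained with a 0.5-count pseudocount and is flagged as an upper bound
#' (\code{censored = TRUE}). With \code{pseudocount = TRUE} the pseudocount
#' value is reported unflagged instead.
#'
#' @param counts a \code{\linkS4class{BarSeqCounts}} (technical replicates
#'   already merged).
#' @param wtStrains names of the wild-type reference strains (non-empty).
#' @param inputSample column name of the input library.
#' @param outputSamples column names of output samples (default: all
#'   columns except the input).
#' @param includeOther denominator policy passed to
#'   \code{\link{relativeFrequencies}}.
#' @param pseudocount report plain 0.5-pseudocount CIs instead of
#'   censoring flags.
#' @return data.frame with columns \code{strain}, \code{sample}, \code{CI},
#'   \code{censored}, \code{inputRF}, \code{outputRF}, ordered by sample
#'   then library strain order.
#' @examples
#' ## input RFs 0.25/0.25, output mutant 0.10 vs WT mean 0.30:
#' ## CI = log10((0.10/0.30)/(0.25/0.25)) = -0.477
#' @export
competitiveIndex <- function(counts, wtStrains, inputSample,
                             outputSamples = NULL, includeOther = FALSE,
                             pseudocount = FALSE) {
    m <- countsMatrix(counts)
    if (length(wtStrains) == 0L)
        stop("wtStrains must be non-empty")
    if (!all(wtStrains %in% rownames(m)))
        stop("wild-type strain(s) missing from counts: ",
             paste(setdiff(wtStrains, rownames(m)), collapse = ", "))
    if (!inputSample %in% colnames(m))
        stop(sprintf("input sample '%s' not in counts", inputSample))
    if (is.null(outputSamples))
        outputSamples <- setdiff(colnames(m), inputSample)
    rf <- relativeFrequencies(m, includeOther = includeOther)
    strains <- rownames(rf)
    if (!all(wtStrains %in% strains))
        stop("wild-type strains excluded by the denominator policy")

    ## pseudocount frequencies for the censoring floor
    m0 <- m[rownames(rf), , drop = FALSE]
    mPseudo <- m0
    mPseudo[mPseudo == 0] <- 0.5
    rfPseudo <- sweep(mPseudo, 2L, colSums(mPseudo), "/")

    wtAvg <- colMeans(rf[wtStrains, , drop = FALSE])
    if (wtAvg[inputSample] == 0)
        stop("zero wild-type average in the input sample")
    res <- do.call(rbind, lapply(outputSamples, function(s) {
        if (wtAvg[[s]] == 0)
            stop(sprintf("zero wild-type average in sample '%s'", s))
        inRF <- rf[, inputSample]
        outRF <- rf[, s]
        ci <- log10((outRF / wtAvg[[s]]) / (inRF / wtAvg[[inputSample]]))
        zero <- m0[, s] == 0
        if (any(zero)) {
            wtAvgP <- mean(rfPseudo[wtStrains, s])
            inP <- rfPseudo[, inputSample]
            ciP <- log10((rfPseudo[, s] / wtAvgP) /
                         (inP / mean(rfPseudo[wtStrains, inputSample])))
            ci[zero] <- ciP[zero]
        }
        data.frame(strain = strains, sample = s, CI = unname(ci),
                   censored = if (pseudocount) FALSE else unname(zero),
                   inputRF = unname(inRF), outputRF = unname(outRF),
                   stringsAsFactors = FALSE)
    }))
    rownames(res) <- NULL
    res
}

#' Write a competitive-index table
#'
#' Deterministic row order (sample then library strain order), tab
#' delimited, round-trippable with \code{read.delim}.
#'
#' @param ci data.frame from \code{\link{competitiveIndex}}.
#' @param path file path.
#' @param provenance optional comment lines.
#' @export
writeCITable <- function(ci, path, provenance = NULL) {
    con <- file(path, "wb")
    on.exit(close(con))
    if (!is.null(provenance))
        writeLines(paste0("# ", provenance), con, useBytes = TRUE)
    utils::write.table(ci, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Polarity ratio from RT-qPCR Ct values
#'
#' Relative expression of each gene g in strain s is
#' 2^-(Ct(g,s) - Ct(reference,s)); the mutant's fold change per gene is its
#' relative expression over the wild type's (the 2^-ddCt method); and the
#' polarity ratio is the fold change of the gene downstream of the deletion
#' divided by that of the upstream gene. A ratio near 1 indicates no polar
#' effect.
#'
#' @param ct data.frame with columns \code{strain}, \code{gene}, \code{ct}
#'   (technical replicates may appear as repeated rows and are averaged).
#' @param mutant,wildtype strain names.
#' @param upstreamGene,downstreamGene genes flanking the deletion in the
#'   operon.
#' @param referenceGene normalization gene (default \code{"rpoD"}).
#' @return the polarity ratio (positive numeric).
#' @examples
#' ct <- expand.grid(strain = c("wt", "mut"),
#'                   gene = c("rpoD", "up", "down"),
#'                   stringsAsFactors = FALSE)
#' ct$ct <- 20
#' polarityRatio(ct, "mut", "wt", "up", "down")  # 1
#' @export
polarityRatio <- function(ct, mutant, wildtype, upstreamGene,
                          downstreamGene, referenceGene = "rpoD") {
    need <- c("strain", "gene", "ct")
    if (!all(need %in% colnames(ct)))
        stop("ct table needs columns: ", paste(need, collapse = ", "))
    meanCt <- function(strain, gene) {
        v <- ct$ct[ct$strain == strain & ct$gene == gene]
        if (length(v) == 0L)
            stop(sprintf("missing Ct for strain '%s', gene '%s'",
                         strain, gene))
        if (any(v <= 0)) stop("Ct values must be positive")
        mean(v)
    }
    rel <- function(gene, strain)
        2^-(meanCt(strain, gene) - meanCt(strain, referenceGene))
    fold <- function(gene) rel(gene, mutant) / rel(gene, wildtype)
    fold(downstreamGene) / fold(upstreamGene)
}
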