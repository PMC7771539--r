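## Shared fixtures, all generated in code.

suppressPackageStartupMessages(library(SummarizedExperiment))

## Random non-stop codon sequence of `nCodons` codons.
randomORFBody <- function(nCodons) {
    stops <- c("TAA", "TAG", "TGA")
    all64 <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                               b2 = c("A", "C", "G", "T"),
                               b3 = c("A", "C", "G", "T")), 1, paste0,
                   collapse = "")
    ok <- setdiff(all64, stops)
    paste(sample(ok, nCodons, replace = TRUE), collapse = "")
}

randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## 10-kb toy replicon with a 900-nt ORF (ATG + 298 codons + TAA) at
## 1-based [4001, 4900].
makeToyGenome <- function(seed = 11L, strand = "+") {
    set.seed(seed)
    orf <- paste0("ATG", randomORFBody(298L), "TAA")
    stopifnot(nchar(orf) == 900L)
    up <- randomDNA(4000L)
    down <- randomDNA(5100L)
    gene <- if (strand == "+") orf else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
    genome <- c(chr1 = paste0(up, gene, down))
    list(genome = genome,
         target = geneTarget("chr1", 4001L, 4900L, strand, "toyA"),
         orf = orf)
}

## Seven-strain library (3 wild-type references + 4 mutants).
makeSevenStrainLibrary <- function(seed = 99L) {
    set.seed(seed)
    buildBarcodeLibrary(c(paste0("WT", 1:3), paste0("mut", 1:4)))
}

## Independent one-line CI oracle working directly on a counts matrix
## (columns: samples; "_other" row excluded by the caller).
ciOracle <- function(m, strain, wt, inS, outS) {
    rfIn <- m[, inS] / sum(m[, inS])
    rfOut <- m[, outS] / sum(m[, outS])
    log10((rfOut[strain] / mean(rfOut[wt])) /
          (rfIn[strain] / mean(rfIn[wt])))
}

## Delta-method variance of a CI estimate from multinomial read sampling:
## CI = log10(f_m) - log10(mean f_wt) per sample, summed over the two
## samples. Includes the negative mutant/WT covariance term.
ciSamplingSD <- function(fIn, fOut, strain, wt, nReads) {
    oneSample <- function(f) {
        fm <- f[strain]
        W <- mean(f[wt])
        varFm <- fm * (1 - fm) / nReads
        k <- length(wt)
        covSum <- 0
        for (i in wt) for (j in wt)
            covSum <- covSum + (if (i == j) f[i] * (1 - f[i]) else
                                -f[i] * f[j]) / nReads
        varW <- covSum / k^2
        covMW <- -fm * W / nReads
        (varFm / fm^2 + varW / W^2 - 2 * covMW / (fm * W)) / log(10)^2
    }
    sqrt(oneSample(fIn) + oneSample(fOut))
}

## Write a small FASTQ from read sequences.
writeTestFastq <- function(reads, path, gz = FALSE) {
    con <- if (gz) gzfile(path, "wb") else file(path, "wb")
    ids <- sprintf("@r%d", seq_along(reads))
    qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    writeLines(as.vector(rbind(ids, reads, "+", qual)), con, useBytes = TRUE)
    close(con)
    path
}
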