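#' Culture volume for 1:1 strain mixing
#'
#' Volume (in microliters) of a culture at the given optical density that
#' contributes an equal number of cells to a multiplexed input library:
#' volume = (1.25 / OD600) x 50.
#'
#' @param od600 positive optical density at 600 nm.
#' @return volume in microliters.
#' @examples
#' mixVolume(0.5)   # 125
#' @export
mixVolume <- function(od600) {
    if (any(od600 <= 0)) stop("od600 must be positive")
    (1.25 / od600) * 50
}

#' Doublings implied by serial dilution and regrowth
#'
#' Each round of diluting 1:d and regrowing to the pre-dilution density
#' costs log2(d) doublings; two serial 1:181 rounds give ~15 generations.
#'
#' @param dilutionFactor dilution factor d > 1 (e.g. 181 for a 1:181
#'   dilution).
#' @param rounds number of serial dilution/regrowth rounds.
#' @return number of doublings, \code{rounds * log2(dilutionFactor)}.
#' @examples
#' generationsFromDilution(181, 2)  # ~15
#' @export
generationsFromDilution <- function(dilutionFactor, rounds = 1L) {
    if (any(dilutionFactor <= 1)) stop("dilutionFactor must be > 1")
    stopifnot(rounds >= 1L)
    rounds * log2(dilutionFactor)
}

#' Construct a CompetitionScenario
#'
#' @param strains strain names.
#' @param inputFreqs input frequencies (default equal); normalized to sum
#'   to 1.
#' @param fitness per-strain multiplicative growth factor per generation
#'   (default 1 for all).
#' @param generations doublings of the pool; the default 15 corresponds to
#'   two serial 1:181 dilution/regrowth rounds
#'   (\code{\link{generationsFromDilution}}).
#' @param bottleneck optional multinomial bottleneck size (\code{NA} for
#'   none).
#' @param seed integer seed for the bottleneck draw.
#' @return a \code{\linkS4class{CompetitionScenario}}.
#' @export
competitionScenario <- function(strains,
                                inputFreqs = rep(1 / length(strains),
                                                 length(strains)),
                                fitness = rep(1, length(strains)),
                                generations = 15, bottleneck = NA,
                                seed = 1L) {
    new("CompetitionScenario", strains = as.character(strains),
        inputFreqs = inputFreqs / sum(inputFreqs),
        fitness = fitness, generations = as.numeric(generations),
        bottleneck = as.integer(bottleneck), seed = as.integer(seed))
}

#' Construct a SequencingScenario
#'
#' @param readsPerSample reads to draw per sample.
#' @param readLength read length (default 250 nt).
#' @param substitutionRate i.i.d. per-base substitution rate (default 0).
#' @param revcompFraction fraction of reads emitted reverse-complemented
#'   (default 0.5: either mate of a 2 x 250 bp run can present the barcode
#'   locus in either orientation).
#' @param seed integer seed.
#' @return a \code{\linkS4class{SequencingScenario}}.
#' @export
sequencingScenario <- function(readsPerSample = 50000L, readLength = 250L,
                               substitutionRate = 0,
                               revcompFraction = 0.5, seed = 1L) {
    new("SequencingScenario", readsPerSample = as.integer(readsPerSample),
        readLength = as.integer(readLength),
        substitutionRate = substitutionRate,
        revcompFraction = revcompFraction, seed = as.integer(seed))
}

#' Simulate a pooled competition
#'
#' Deterministic exponential growth: each strain's weight is its input
#' frequency times fitness^generations; weights are renormalized to output
#' frequencies. If a bottleneck is set, a single multinomial draw of that
#' size is taken (seeded by the scenario seed) and the counts renormalized.
#'
#' @param scenario a \code{\linkS4class{CompetitionScenario}}.
#' @return named numeric vector of output frequencies summing to 1.
#' @examples
#' sc <- competitionScenario(c("a", "b"), fitness = c(2, 1), generations = 1)
#' simulateCompetition(sc)  # a=2/3, b=1/3
#' @export
simulateCompetition <- function(scenario) {
    stopifnot(is(scenario, "CompetitionScenario"))
    w <- scenario@inputFreqs * scenario@fitness^scenario@generations
    if (sum(w) <= 0) stop("all strain frequencies are zero after growth")
    f <- w / sum(w)
    if (!is.na(scenario@bottleneck)) {
        set.seed(scenario@seed)
        counts <- stats::rmultinom(1L, scenario@bottleneck, f)[, 1L]
        f <- counts / sum(counts)
    }
    stats::setNames(f, scenario@strains)
}

## Synthetic Illumina-style fixed parts of the amplicon. P5/P7 are the
## standard flow-cell adapters; head/tail are synthetic locus-specific
## priming regions (the real primer sequences are not distributed).
P5_ADAPTER <- "AATGATACGGCGACCACCGAGATCTACAC"
P7_ADAPTER <- "ATCTCGTATGCCGTCTTCTGCTTG"
AMPLICON_HEAD <- "TCGTCGGCAGCGTCAGATGT"  # synthetic read-1 priming region
AMPLICON_TAIL <- "GTCTCGTGGGCTCGGAGATG"  # synthetic read-2 priming region

#' Build a dual-indexed sequencing amplicon around a scar's barcode
#'
#' Concatenates P5 - i5 index - locus head - scar fragment (FRT remnant
#' through RL, containing spacer + barcode) - locus tail - i7 index - P7
#' and returns the sequence with its component layout. Two strains'
#' amplicons differ only within the barcode interval.
#'
#' @param scar a bar \code{\linkS4class{ScarSequence}}.
#' @param i5,i7 index sequences (8 nt by convention; any non-empty
#'   sequence accepted).
#' @param p5,p7,head,tail fixed adapter and priming sequences.
#' @return list with \code{seq} and \code{layout} (named \code{IRanges}).
#' @export
buildAmplicon <- function(scar, i5 = "ACGTACGT", i7 = "TGCATGCA",
                          p5 = P5_ADAPTER, p7 = P7_ADAPTER,
                          head = AMPLICON_HEAD, tail = AMPLICON_TAIL) {
    stopifnot(is(scar, "ScarSequence"))
    if (scarKind(scar) != "bar")
        stop("buildAmplicon expects a bar scar")
    if (any(!nzchar(c(i5, i7, p5, p7, head, tail))))
        stop("all amplicon components must be non-empty")
    off <- scarOffsets(scar)
    frag <- substr(scarSeq(scar), start(off["FRT"]), end(off["RL"]))
    parts <- c(P5 = p5, i5 = i5, head = head, scar = frag, tail = tail,
               i7 = i7, P7 = p7)
    list(seq = paste(parts, collapse = ""),
         layout = componentRanges(nchar(parts)))
}

#' Simulate amplicon sequencing reads
#'
#' Samples reads from per-strain amplicons proportional to the given
#' frequencies (or using exact per-strain counts), applies i.i.d.
#' substitution errors, reverse-complements the configured fraction of
#' reads, and writes standard 4-line FASTQ with constant quality. The true
#' per-strain read counts are returned as an oracle for tests.
#'
#' @param abundance named numeric vector: frequencies (summing to 1) or
#'   exact integer counts per strain.
#' @param scars named list of bar \code{\linkS4class{ScarSequence}}, one
#'   per strain in \code{abundance}.
#' @param scenario a \code{\linkS4class{SequencingScenario}}.
#' @param fastqPath output FASTQ path (".gz" suffix gzips); \code{NULL}
#'   returns reads in memory only.
#' @param exactCounts if \code{TRUE}, \code{abundance} is taken as exact
#'   per-strain read counts; otherwise counts are one multinomial draw of
#'   \code{readsPerSample} reads.
#' @return list with \code{trueCounts} (named integer vector),
#'   \code{reads} (character vector, emitted order) and \code{fastqPath}.
#' @export
simulateReads <- function(abundance, scars, scenario,
                          fastqPath = NULL, exactCounts = FALSE) {
    stopifnot(is(scenario, "SequencingScenario"))
    strains <- names(abundance)
    if (is.null(strains) || !all(strains %in% names(scars)))
        stop("abundance and scars must be named by the same strains")
    set.seed(scenario@seed)
    if (exactCounts) {
        counts <- as.integer(round(abundance))
    } else {
        counts <- stats::rmultinom(1L, scenario@readsPerSample,
                                   abundance / sum(abundance))[, 1L]
    }
    names(counts) <- strains

    amps <- vapply(strains, function(s) buildAmplicon(scars[[s]])$seq,
                   character(1))
    if (scenario@readLength < 54L)
        stop("read length shorter than the barcode window")

    readList <- lapply(strains, function(s) {
        n <- counts[[s]]
        if (n == 0L) return(character(0))
        template <- substr(amps[[s]], 1L,
                           min(scenario@readLength, nchar(amps[[s]])))
        reads <- rep(template, n)
        if (scenario@substitutionRate > 0) {
            L <- nchar(template)
            nMut <- stats::rbinom(1L, n * L, scenario@substitutionRate)
            if (nMut > 0L) {
                idx <- sample.int(n * L, nMut)
                ri <- (idx - 1L) %/% L + 1L
                pos <- (idx - 1L) %% L + 1L
                orig <- substring(reads[ri], pos, pos)
                bases <- c("A", "C", "G", "T")
                ## substitute to a uniformly chosen different base
                repl <- vapply(orig, function(b)
                    sample(setdiff(bases, b), 1L), character(1),
                    USE.NAMES = FALSE)
                for (k in seq_len(nMut))
                    substr(reads[ri[k]], pos[k], pos[k]) <- repl[k]
            }
        }
        reads
    })
    reads <- unlist(readList, use.names = FALSE)
    origin <- rep(strains, vapply(readList, length, integer(1)))
    ## interleave strains deterministically
    ord <- sample.int(length(reads))
    reads <- reads[ord]; origin <- origin[ord]
    if (scenario@revcompFraction > 0 && length(reads)) {
        flip <- stats::runif(length(reads)) < scenario@revcompFraction
        if (any(flip)) reads[flip] <- revcomp(reads[flip])
    }
    if (!is.null(fastqPath)) {
        ids <- sprintf("@read%06d %s", seq_along(reads), origin)
        qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
        con <- if (grepl("\\.gz$", fastqPath)) gzfile(fastqPath, "wb")
               else file(fastqPath, "wb")
        writeLines(as.vector(rbind(ids, reads, "+", qual)), con,
                   useBytes = TRUE)
        close(con)
    }
    list(trueCounts = counts, reads = reads, fastqPath = fastqPath)
}

#' Simulate a full competition experiment to FASTQ
#'
#' Runs \code{\link{simulateCompetition}} for the input and output
#' conditions, draws reads for both samples, and writes FASTQ files, a
#' sample sheet and a truth table of per-strain read counts.
#'
#' @param compScenario a \code{\linkS4class{CompetitionScenario}}.
#' @param seqScenario a \code{\linkS4class{SequencingScenario}}.
#' @param library a \code{\linkS4class{BarcodeLibrary}} covering the
#'   scenario's strains.
#' @param outDir output directory (created if needed).
#' @param gzip write gzip-compressed FASTQ.
#' @param linkers a \code{\linkS4class{LinkerSet}}.
#' @return list with \code{sampleSheet} (data.frame: sample, role,
#'   replicateGroup, fastq), \code{truth} (counts matrix strains x
#'   samples), and per-sample true frequencies.
#' @export
simulateExperiment <- function(compScenario, seqScenario, library,
                               outDir, gzip = FALSE,
                               linkers = defaultLinkerSet()) {
    stopifnot(is(library, "BarcodeLibrary"))
    strains <- compScenario@strains
    if (!all(strains %in% strainNames(library)))
        stop("scenario strains missing from barcode library")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    bc <- barcodes(library)
    scars <- lapply(bc[strains], assembleBarScar, linkers = linkers)
    names(scars) <- strains

    fIn <- stats::setNames(compScenario@inputFreqs, strains)
    fOut <- simulateCompetition(compScenario)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    paths <- file.path(outDir, paste0(c("input", "output"), ext))

    seqIn <- seqScenario; seqIn@seed <- seqScenario@seed
    simIn <- simulateReads(fIn, scars, seqIn, fastqPath = paths[1L])
    seqOut <- seqScenario; seqOut@seed <- seqScenario@seed + 1L
    simOut <- simulateReads(fOut, scars, seqOut, fastqPath = paths[2L])

    truth <- cbind(input = simIn$trueCounts, output = simOut$trueCounts)
    sheet <- data.frame(sample = c("input", "output"),
                        role = c("input", "output"),
                        replicateGroup = c("input", "output"),
                        fastq = paths, stringsAsFactors = FALSE)
    utils::write.table(sheet, file.path(outDir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(strain = rownames(truth), truth),
                       file.path(outDir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(sampleSheet = sheet, truth = truth,
         freqs = list(input = fIn, output = fOut))
}
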