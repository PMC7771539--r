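#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges IRanges
NULL

## Reserved row label for reads whose flanks are found but whose barcode is
## not in the library. Not a legal strain name.
OTHER_LABEL <- "_other"

#' BarcodeLibrary: strain-name to barcode map
#'
#' Ordered map from unique strain names to unique 18-nt barcodes, with a
#' configured pairwise Hamming-distance floor. Every barcode must be built
#' from six trimer-aligned VNN codons (first base A, C or G), which makes a
#' trimer-aligned stop codon impossible.
#'
#' @slot strains character vector of unique strain names (no \code{"_other"}).
#' @slot barcodes character vector of unique 18-nt barcodes, parallel to
#'   \code{strains}.
#' @slot minDistance single non-negative integer; if positive, all pairwise
#'   Hamming distances between barcodes are at least this value.
#' @exportClass BarcodeLibrary
setClass("BarcodeLibrary",
    representation(strains = "character", barcodes = "character",
                   minDistance = "integer"))

setValidity("BarcodeLibrary", function(object) {
    msg <- character()
    if (length(object@strains) != length(object@barcodes))
        msg <- c(msg, "strains and barcodes must have equal length")
    if (anyDuplicated(object@strains))
        msg <- c(msg, "strain names must be unique")
    if (anyDuplicated(object@barcodes))
        msg <- c(msg, "barcodes must be unique")
    if (OTHER_LABEL %in% object@strains)
        msg <- c(msg, sprintf("'%s' is a reserved strain name", OTHER_LABEL))
    if (length(object@minDistance) != 1L || is.na(object@minDistance) ||
        object@minDistance < 0L)
        msg <- c(msg, "minDistance must be a single non-negative integer")
    bad <- which(!vapply(object@barcodes,
                         function(b) validateBarcode(b)$valid, logical(1)))
    if (length(bad))
        msg <- c(msg, sprintf("invalid barcode(s) for strain(s): %s",
                              paste(object@strains[bad], collapse = ", ")))
    if (length(msg) == 0L && length(object@barcodes) > 1L &&
        object@minDistance > 0L) {
        d <- barcodeDistances(object@barcodes)
        if (min(d) < object@minDistance)
            msg <- c(msg, sprintf(
                "pairwise Hamming distance %d below floor %d",
                min(d), object@minDistance))
    }
    if (length(msg)) msg else TRUE
})

#' LinkerSet: fixed sequences shared by every barcoded deletion
#'
#' The constant sequence components of the deletion scar: forward-orientation
#' left linker (LL), right linker (RL), spacer, the FRT site that remains
#' after FLP excision, and the FRT-flanked erythromycin-resistance cassette
#' used in the marked (erm-bar) scar.
#'
#' @slot llFwd 32-nt forward left linker (reverse complement of the R1-LL
#'   primer extension).
#' @slot rl 33-nt right linker; its first 18 nt are the right flank used for
#'   barcode extraction from reads.
#' @slot spacer 18-nt spacer; the left flank used for barcode extraction.
#' @slot frtRemnant 34-nt FRT site remaining after FLP excision.
#' @slot ermCassette FRT-erm-FRT marked insert; begins and ends with
#'   \code{frtRemnant}.
#' @exportClass LinkerSet
setClass("LinkerSet",
    representation(llFwd = "character", rl = "character", spacer = "character",
                   frtRemnant = "character", ermCassette = "character"))

setValidity("LinkerSet", function(object) {
    msg <- character()
    if (nchar(object@llFwd) != 32L) msg <- c(msg, "llFwd must be 32 nt")
    if (nchar(object@rl) != 33L) msg <- c(msg, "rl must be 33 nt")
    if (nchar(object@spacer) != 18L) msg <- c(msg, "spacer must be 18 nt")
    if (nchar(object@frtRemnant) != 34L)
        msg <- c(msg, "frtRemnant must be 34 nt")
    if (!startsWith(object@ermCassette, object@frtRemnant) ||
        !endsWith(object@ermCassette, object@frtRemnant))
        msg <- c(msg, "ermCassette must begin and end with an FRT site")
    if (length(msg)) msg else TRUE
})

#' GeneTarget: a gene slated for in-frame deletion
#'
#' Coordinates are 1-based inclusive on the forward strand of the named
#' replicon; \code{strand} gives the coding orientation.
#'
#' @slot replicon replicon (chromosome/plasmid) identifier.
#' @slot start,end 1-based inclusive forward-strand coordinates of the ORF
#'   including start and stop codons; the width must be a multiple of 3 and
#'   at least 27 nt (start codon + at least one internal codon + the
#'   retained final seven codons).
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot name gene name.
#' @exportClass GeneTarget
setClass("GeneTarget",
    representation(replicon = "character", start = "integer", end = "integer",
                   strand = "character", name = "character"))

setValidity("GeneTarget", function(object) {
    msg <- character()
    w <- object@end - object@start + 1L
    if (object@start < 1L) msg <- c(msg, "start must be >= 1")
    if (w < 27L) msg <- c(msg, "gene must be at least 27 nt")
    if (w %% 3L != 0L) msg <- c(msg, "gene length must be divisible by 3")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' OligoSet: the eight deletion oligos for one gene target
#'
#' Holds F1, R1-LL, F2-RL, R2, FO, RO, FW and RW with their sequences
#' (5' to 3' as synthesized) and forward-strand anneal intervals, plus
#' predicted product sizes.
#'
#' @slot target the \code{\linkS4class{GeneTarget}} the oligos were designed
#'   for.
#' @slot oligos \code{DataFrame} with columns \code{name}, \code{sequence},
#'   \code{annealStart}, \code{annealEnd} (1-based inclusive, forward
#'   strand), \code{direction} (\code{"fwd"}/\code{"rev"} relative to the
#'   gene's coding orientation).
#' @slot products named numeric vector of predicted product lengths
#'   (\code{F1_R2}, \code{FO_RO}, \code{FW_RW}).
#' @exportClass OligoSet
setClass("OligoSet",
    representation(target = "GeneTarget", oligos = "DataFrame",
                   products = "numeric"))

#' ScarSequence: an assembled deletion scar with component offsets
#'
#' The unmarked \code{bar} scar is 138 bp: start codon ATG, 32-nt LL, 34-nt
#' FRT remnant, 18-nt spacer, 18-nt barcode, 33-nt RL, and carries no
#' trimer-aligned stop codon. The marked \code{erm_bar} scar replaces the
#' FRT remnant with the full FRT-erm-FRT cassette.
#'
#' @slot seq scar nucleotide sequence.
#' @slot offsets named \code{IRanges} (1-based inclusive) locating each
#'   component (\code{ATG}, \code{LL}, \code{FRT} or \code{cassette},
#'   \code{spacer}, \code{barcode}, \code{RL}) within \code{seq}.
#' @slot kind \code{"bar"} or \code{"erm_bar"}.
#' @exportClass ScarSequence
setClass("ScarSequence",
    representation(seq = "character", offsets = "IRanges", kind = "character"))

setValidity("ScarSequence", function(object) {
    msg <- character()
    if (!object@kind %in% c("bar", "erm_bar"))
        msg <- c(msg, "kind must be 'bar' or 'erm_bar'")
    off <- object@offsets
    if (is.null(names(off)) || anyDuplicated(names(off)))
        msg <- c(msg, "offsets must be uniquely named")
    if (length(off)) {
        if (min(IRanges::start(off)) != 1L ||
            max(IRanges::end(off)) != nchar(object@seq) ||
            sum(IRanges::width(off)) != nchar(object@seq))
            msg <- c(msg, "offsets must tile the scar without gaps/overlaps")
    }
    if (object@kind == "bar") {
        if (nchar(object@seq) != 138L)
            msg <- c(msg, "bar scar must be 138 bp")
        if (length(trimerStops(object@seq)))
            msg <- c(msg, "bar scar contains a trimer-aligned stop codon")
    }
    if (length(msg)) msg else TRUE
})

#' FlankPattern: how barcodes are located within reads
#'
#' A candidate barcode is the exact 18-nt window between a left-flank match
#' (the spacer sequence) and an immediately following right-flank match (the
#' first 18 nt of RL).
#'
#' @slot left 18-nt left flank (spacer).
#' @slot right 18-nt right flank (RL prefix).
#' @slot barcodeLen barcode window width (18).
#' @slot maxFlankMismatches maximum substitutions tolerated in each flank
#'   (default 0: exact literal match).
#' @slot searchRevcomp search the reverse complement of a read when the
#'   forward orientation has no hit (default \code{TRUE}).
#' @exportClass FlankPattern
setClass("FlankPattern",
    representation(left = "character", right = "character",
                   barcodeLen = "integer", maxFlankMismatches = "integer",
                   searchRevcomp = "logical"))

setValidity("FlankPattern", function(object) {
    msg <- character()
    if (nchar(object@left) != 18L) msg <- c(msg, "left flank must be 18 nt")
    if (nchar(object@right) != 18L) msg <- c(msg, "right flank must be 18 nt")
    if (object@barcodeLen < 1L) msg <- c(msg, "barcodeLen must be positive")
    if (object@maxFlankMismatches < 0L)
        msg <- c(msg, "maxFlankMismatches must be non-negative")
    if (length(msg)) msg else TRUE
})

#' BarSeqCounts: strains-by-samples barcode counts
#'
#' A \code{SummarizedExperiment} whose \code{counts} assay holds non-negative
#' integer read counts with one row per library strain plus the reserved
#' \code{"_other"} row, and whose \code{colData} carries per-sample read
#' accounting (\code{readsTotal}, \code{readsWithFlanks}). Conservation is
#' enforced: in each sample the strain counts plus \code{"_other"} equal
#' \code{readsWithFlanks}, which never exceeds \code{readsTotal}.
#'
#' @exportClass BarSeqCounts
setClass("BarSeqCounts", contains = "SummarizedExperiment")

setValidity("BarSeqCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "must have a 'counts' assay")
    cd <- SummarizedExperiment::colData(object)
    need <- c("readsTotal", "readsWithFlanks")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, "colData must have readsTotal and readsWithFlanks")
    if (!OTHER_LABEL %in% rownames(object))
        msg <- c(msg, sprintf("rows must include '%s'", OTHER_LABEL))
    if (length(msg) == 0L && ncol(object) > 0L) {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(m < 0) || any(m != round(m)))
            msg <- c(msg, "counts must be non-negative integers")
        else {
            tot <- colSums(m)
            if (any(tot != cd$readsWithFlanks))
                msg <- c(msg,
                    "column sums must equal readsWithFlanks (conservation)")
            if (any(cd$readsWithFlanks > cd$readsTotal))
                msg <- c(msg, "readsWithFlanks cannot exceed readsTotal")
        }
    }
    if (length(msg)) msg else TRUE
})

#' CompetitionScenario: a deterministic pooled-competition experiment
#'
#' Strains at chosen input frequencies grow for \code{generations} doublings
#' with per-strain multiplicative fitness per generation; an optional
#' multinomial bottleneck subsamples the population.
#'
#' @slot strains strain names.
#' @slot inputFreqs non-negative input frequencies summing to 1.
#' @slot fitness per-strain multiplicative growth factor per generation.
#' @slot generations non-negative number of doublings of the pool.
#' @slot bottleneck single positive integer (multinomial draw size) or
#'   \code{NA} for none.
#' @slot seed integer seed used for the bottleneck draw.
#' @exportClass CompetitionScenario
setClass("CompetitionScenario",
    representation(strains = "character", inputFreqs = "numeric",
                   fitness = "numeric", generations = "numeric",
                   bottleneck = "integer", seed = "integer"))

setValidity("CompetitionScenario", function(object) {
    msg <- character()
    n <- length(object@strains)
    if (length(object@inputFreqs) != n || length(object@fitness) != n)
        msg <- c(msg, "strains, inputFreqs, fitness must have equal length")
    if (any(object@inputFreqs < 0)) msg <- c(msg, "inputFreqs must be >= 0")
    if (abs(sum(object@inputFreqs) - 1) > 1e-12)
        msg <- c(msg, "inputFreqs must sum to 1")
    if (object@generations < 0) msg <- c(msg, "generations must be >= 0")
    if (!is.na(object@bottleneck) && object@bottleneck < 1L)
        msg <- c(msg, "bottleneck must be a positive integer or NA")
    if (length(msg)) msg else TRUE
})

#' SequencingScenario: amplicon sequencing of a competition sample
#'
#' @slot readsPerSample number of reads to draw per sample.
#' @slot readLength read length in nt (default 250, as for a 2 x 250 bp
#'   kit); must be at least 54 so a read can cover spacer + barcode + right
#'   flank.
#' @slot substitutionRate i.i.d. per-base substitution error rate in [0,1).
#' @slot revcompFraction fraction of reads emitted reverse-complemented.
#' @slot seed integer seed for all sampling.
#' @exportClass SequencingScenario
setClass("SequencingScenario",
    representation(readsPerSample = "integer", readLength = "integer",
                   substitutionRate = "numeric", revcompFraction = "numeric",
                   seed = "integer"))

setValidity("SequencingScenario", function(object) {
    msg <- character()
    if (object@readsPerSample < 1L)
        msg <- c(msg, "readsPerSample must be positive")
    if (object@readLength < 54L)
        msg <- c(msg, "readLength must be >= 54 (spacer+barcode+right flank)")
    if (object@substitutionRate < 0 || object@substitutionRate >= 1)
        msg <- c(msg, "substitutionRate must be in [0,1)")
    if (object@revcompFraction < 0 || object@revcompFraction > 1)
        msg <- c(msg, "revcompFraction must be in [0,1]")
    if (length(msg)) msg else TRUE
})
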