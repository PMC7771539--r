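## Fixed sequences of the barcoded-deletion system.
##
## The left linker is synthesized as a 32-nt extension on the R1 primer in
## reverse-complement orientation; LL_FWD below is its forward (scar)
## orientation. The spacer and the first 18 nt of RL flank the barcode in
## every scar and anchor its extraction from reads.

LL_RC_PRIMER <- "CTGGCGAAGCATATATAAGAAGCTCGTCTCGT"   # as on the R1-LL oligo
LL_FWD       <- "ACGAGACGAGCTTCTTATATATGCTTCGCCAG"   # revcomp(LL_RC_PRIMER)
RL_SEQ       <- "GACTTGACCTGGATGTCTCTACCCACAAGATCG"
SPACER_SEQ   <- "GCTCATGCACTTGATTCC"

## Canonical 34-nt minimal FRT site (13-bp repeat, 8-bp spacer, 13-bp
## inverted repeat). The exact post-excision remnant in the source system is
## not fixed by this package; this default is verified stop-free at
## trimer-aligned positions within the assembled scar and is configurable
## via defaultLinkerSet(frtRemnant=).
FRT_MINIMAL  <- "GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC"

## Synthetic stand-in for the erm coding region of the FRT-erm-FRT cassette
## (the real cassette sequence is not distributed). 900 nt, free of the
## spacer and flank sequences so it cannot confuse barcode extraction.
syntheticErmFiller <- function() {
    strrep("GAAGCTGCTACTGATCCTGTTAAAGCTCTG", 30L)
}

#' Default fixed-sequence set for scar assembly
#'
#' Returns the shared linker, spacer, FRT and cassette sequences used by all
#' barcoded deletions. The forward left linker is the reverse complement of
#' the 32-nt R1-LL primer extension; the first 18 nt of RL equal the
#' counting module's right flank and the spacer equals its left flank. The
#' erm cassette shipped here is a synthetic FRT-filler-FRT placeholder: its
#' FRT ends and length are what downstream code relies on, not its internal
#' composition.
#'
#' @param frtRemnant 34-nt FRT site remaining after FLP excision
#'   (default: canonical minimal FRT).
#' @param ermCassette FRT-erm-FRT marked insert; must begin and end with
#'   \code{frtRemnant}.
#' @return a \code{\linkS4class{LinkerSet}}.
#' @examples
#' ls <- defaultLinkerSet()
#' nchar(llFwd(ls))    # 32
#' @export
defaultLinkerSet <- function(frtRemnant = FRT_MINIMAL,
                             ermCassette = paste0(frtRemnant,
                                                  syntheticErmFiller(),
                                                  frtRemnant)) {
    new("LinkerSet", llFwd = LL_FWD, rl = RL_SEQ, spacer = SPACER_SEQ,
        frtRemnant = frtRemnant, ermCassette = ermCassette)
}

#' @rdname LinkerSet-accessors
#' @export
setGeneric("llFwd", function(x) standardGeneric("llFwd"))
#' @rdname LinkerSet-accessors
#' @export
setGeneric("rightLinker", function(x) standardGeneric("rightLinker"))
#' @rdname LinkerSet-accessors
#' @export
setGeneric("spacerSeq", function(x) standardGeneric("spacerSeq"))
#' @rdname LinkerSet-accessors
#' @export
setGeneric("frtRemnant", function(x) standardGeneric("frtRemnant"))
#' @rdname LinkerSet-accessors
#' @export
setGeneric("ermCassette", function(x) standardGeneric("ermCassette"))

#' Accessors for LinkerSet
#' @param x a \code{\linkS4class{LinkerSet}}.
#' @name LinkerSet-accessors
NULL

#' @rdname LinkerSet-accessors
#' @export
setMethod("llFwd", "LinkerSet", function(x) x@llFwd)
#' @rdname LinkerSet-accessors
#' @export
setMethod("rightLinker", "LinkerSet", function(x) x@rl)
#' @rdname LinkerSet-accessors
#' @export
setMethod("spacerSeq", "LinkerSet", function(x) x@spacer)
#' @rdname LinkerSet-accessors
#' @export
setMethod("frtRemnant", "LinkerSet", function(x) x@frtRemnant)
#' @rdname LinkerSet-accessors
#' @export
setMethod("ermCassette", "LinkerSet", function(x) x@ermCassette)

setMethod("show", "LinkerSet", function(object) {
    cat("LinkerSet\n")
    cat("  LL (fwd):   ", object@llFwd, "\n")
    cat("  RL:         ", object@rl, "\n")
    cat("  spacer:     ", object@spacer, "\n")
    cat("  FRT remnant:", object@frtRemnant, "\n")
    cat(sprintf("  erm cassette: %d nt (FRT...FRT)\n",
                nchar(object@ermCassette)))
})

## Fast character-level reverse complement.
revcomp <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}
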