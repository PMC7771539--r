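#' Design the eight deletion oligos for a gene target
#'
#' Produces F1, R1-LL, F2-RL, R2, FO, RO, FW and RW for one gene. F1 and R2
#' anneal 1 kb up- and downstream of the deletion junctions; R1 anneals from
#' the start codon going upstream and carries the 32-nt LL
#' reverse-complement extension; F2 anneals at the last seven codons going
#' downstream and carries the RL extension; FO and RO sit 500 bp outside F1
#' and R2; FW and RW amplify an internal fragment of 500-1000 bp where the
#' gene allows (shorter genes fall back to the full internal span with a
#' warning). Minus-strand genes are handled in coding orientation and
#' emitted oligo sequences are always written 5' to 3' as synthesized.
#'
#' @param genome named character vector or \code{DNAStringSet} of replicons.
#' @param target a \code{\linkS4class{GeneTarget}}.
#' @param annealLen oligo anneal length in nt; default 22, allowed 18-30.
#' @param armLen homology-arm length (distance from junction to F1/R2
#'   anneal start), default 1000.
#' @param outsideOffset additional offset of FO/RO beyond F1/R2, default
#'   500.
#' @param linkers a \code{\linkS4class{LinkerSet}} supplying the LL and RL
#'   extensions.
#' @return an \code{\linkS4class{OligoSet}}.
#' @export
designOligos <- function(genome, target, annealLen = 22L, armLen = 1000L,
                         outsideOffset = 500L,
                         linkers = defaultLinkerSet()) {
    annealLen <- as.integer(annealLen)
    if (annealLen < 18L || annealLen > 30L)
        stop("annealLen must be within [18, 30]")
    genome <- asGenomeVector(genome)
    chr <- genomeSeq(genome, target@replicon)
    L <- nchar(chr)
    minus <- target@strand == "-"
    ## work in the gene's coding orientation
    if (minus) {
        chr <- revcomp(chr)
        s <- L - target@end + 1L
        e <- L - target@start + 1L
    } else {
        s <- target@start
        e <- target@end
    }
    need <- armLen + outsideOffset
    if (s - 1L < need)
        stop(sprintf("upstream flank too short: need %d nt, have %d",
                     need, s - 1L))
    if (L - e < need)
        stop(sprintf("downstream flank too short: need %d nt, have %d",
                     need, L - e))
    sub <- function(a, b) substr(chr, a, b)

    ## anneal intervals in coding-orientation coordinates; direction is
    ## relative to the coding strand
    ivF1 <- c(s - armLen, s - armLen + annealLen - 1L)
    ivR1 <- c(s + 3L - annealLen, s + 2L)
    ivF2 <- c(e - 20L, e - 20L + annealLen - 1L)
    ivR2 <- c(e + armLen - annealLen + 1L, e + armLen)
    ivFO <- c(s - need, s - need + annealLen - 1L)
    ivRO <- c(e + need - annealLen + 1L, e + need)

    span <- c(s + 3L, e - 21L)          # internal deletable span
    spanLen <- span[2L] - span[1L] + 1L
    if (spanLen >= 1000L) {
        fwrw <- 1000L
    } else if (spanLen >= 500L) {
        fwrw <- spanLen
    } else {
        warning(sprintf(
            "gene %s: internal span %d nt < 500; FW/RW fall back to the ",
            target@name, spanLen), "full internal span")
        fwrw <- spanLen
    }
    ivFW <- c(span[1L], span[1L] + annealLen - 1L)
    ivRW <- c(span[1L] + fwrw - annealLen, span[1L] + fwrw - 1L)

    seqs <- c(
        F1    = sub(ivF1[1L], ivF1[2L]),
        R1_LL = paste0(LL_RC_PRIMER, revcomp(sub(ivR1[1L], ivR1[2L]))),
        F2_RL = paste0(rightLinker(linkers), sub(ivF2[1L], ivF2[2L])),
        R2    = revcomp(sub(ivR2[1L], ivR2[2L])),
        FO    = sub(ivFO[1L], ivFO[2L]),
        RO    = revcomp(sub(ivRO[1L], ivRO[2L])),
        FW    = sub(ivFW[1L], ivFW[2L]),
        RW    = revcomp(sub(ivRW[1L], ivRW[2L])))
    iv <- rbind(ivF1, ivR1, ivF2, ivR2, ivFO, ivRO, ivFW, ivRW)
    dir <- c("fwd", "rev", "fwd", "rev", "fwd", "rev", "fwd", "rev")
    ## map anneal intervals back to forward-strand coordinates
    if (minus) iv <- cbind(L - iv[, 2L] + 1L, L - iv[, 1L] + 1L)
    oligos <- DataFrame(
        name = names(seqs), sequence = unname(seqs),
        annealStart = as.integer(iv[, 1L]),
        annealEnd = as.integer(iv[, 2L]), direction = dir)
    products <- c(F1_R2 = (e - s + 1L) + 2L * armLen,
                  FO_RO = (e - s + 1L) + 2L * need,
                  FW_RW = fwrw)
    new("OligoSet", target = target, oligos = oligos, products = products)
}

#' @rdname OligoSet-accessors
#' @export
setGeneric("oligos", function(x) standardGeneric("oligos"))
#' @rdname OligoSet-accessors
#' @export
setGeneric("predictedProducts", function(x) standardGeneric("predictedProducts"))

#' Accessors for OligoSet
#' @param x an \code{\linkS4class{OligoSet}}.
#' @name OligoSet-accessors
NULL

#' @rdname OligoSet-accessors
#' @export
setMethod("oligos", "OligoSet", function(x) x@oligos)
#' @rdname OligoSet-accessors
#' @export
setMethod("predictedProducts", "OligoSet", function(x) x@products)

setMethod("show", "OligoSet", function(object) {
    cat(sprintf("OligoSet for %s (%d oligos)\n", object@target@name,
                nrow(object@oligos)))
    df <- as.data.frame(object@oligos)
    df$sequence <- ifelse(nchar(df$sequence) > 40,
                          paste0(substr(df$sequence, 1, 37), "..."),
                          df$sequence)
    print(df, row.names = FALSE)
    cat("predicted products (bp):",
        paste(names(object@products), object@products, sep = "=",
              collapse = ", "), "\n")
})
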