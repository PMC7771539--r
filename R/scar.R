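#' @importFrom IRanges IRanges start end width
NULL

#' Construct a GeneTarget
#'
#' @param replicon replicon identifier (must name a sequence in the genome
#'   FASTA).
#' @param start,end 1-based inclusive forward-strand ORF coordinates
#'   (including start and stop codons).
#' @param strand \code{"+"} or \code{"-"} coding orientation.
#' @param name gene name.
#' @return a \code{\linkS4class{GeneTarget}}.
#' @export
geneTarget <- function(replicon, start, end, strand = "+", name = "gene") {
    new("GeneTarget", replicon = as.character(replicon),
        start = as.integer(start), end = as.integer(end),
        strand = strand, name = as.character(name))
}

setMethod("show", "GeneTarget", function(object) {
    cat(sprintf("GeneTarget %s: %s:%d-%d(%s), %d nt\n", object@name,
                object@replicon, object@start, object@end, object@strand,
                object@end - object@start + 1L))
})

#' @rdname ScarSequence-accessors
#' @export
setGeneric("scarSeq", function(x) standardGeneric("scarSeq"))
#' @rdname ScarSequence-accessors
#' @export
setGeneric("scarOffsets", function(x) standardGeneric("scarOffsets"))
#' @rdname ScarSequence-accessors
#' @export
setGeneric("scarKind", function(x) standardGeneric("scarKind"))
#' @rdname ScarSequence-accessors
#' @export
setGeneric("scarBarcode", function(x) standardGeneric("scarBarcode"))

#' Accessors for ScarSequence
#' @param x a \code{\linkS4class{ScarSequence}}.
#' @name ScarSequence-accessors
NULL

#' @rdname ScarSequence-accessors
#' @export
setMethod("scarSeq", "ScarSequence", function(x) x@seq)
#' @rdname ScarSequence-accessors
#' @export
setMethod("scarOffsets", "ScarSequence", function(x) x@offsets)
#' @rdname ScarSequence-accessors
#' @export
setMethod("scarKind", "ScarSequence", function(x) x@kind)
#' @rdname ScarSequence-accessors
#' @export
setMethod("scarBarcode", "ScarSequence", function(x) {
    r <- x@offsets["barcode"]
    substr(x@seq, start(r), end(r))
})

setMethod("show", "ScarSequence", function(object) {
    cat(sprintf("ScarSequence (%s), %d bp\n", object@kind,
                nchar(object@seq)))
    off <- object@offsets
    for (i in seq_along(off))
        cat(sprintf("  %-8s [%d, %d]\n", names(off)[i], start(off)[i],
                    end(off)[i]))
})

## Build the named IRanges component map from component widths, in order.
componentRanges <- function(widths) {
    ends <- cumsum(widths)
    IRanges(start = c(1L, head(ends, -1L) + 1L), end = ends,
            names = names(widths))
}

#' Assemble the unmarked (bar) deletion scar
#'
#' Concatenates the start codon ATG, forward LL, the FRT remnant, the
#' spacer, the barcode and RL into the 138-bp in-frame scar. The barcode
#' occupies whole codons (scar codons 30-35), and the assembled scar is
#' checked to contain no trimer-aligned stop codon.
#'
#' @param barcode a valid 18-nt barcode (see \code{\link{validateBarcode}}).
#' @param linkers a \code{\linkS4class{LinkerSet}}.
#' @return a \code{\linkS4class{ScarSequence}} of kind \code{"bar"}.
#' @examples
#' set.seed(1)
#' scar <- assembleBarScar(generateBarcode())
#' nchar(scarSeq(scar))  # 138
#' @export
assembleBarScar <- function(barcode, linkers = defaultLinkerSet()) {
    v <- validateBarcode(barcode)
    if (!v$valid)
        stop("invalid barcode: ", paste(v$violations, collapse = "; "))
    parts <- c(ATG = "ATG", LL = llFwd(linkers), FRT = frtRemnant(linkers),
               spacer = spacerSeq(linkers), barcode = barcode,
               RL = rightLinker(linkers))
    new("ScarSequence", seq = paste(parts, collapse = ""),
        offsets = componentRanges(nchar(parts)), kind = "bar")
}

#' Assemble the marked (erm-bar) deletion scar
#'
#' As \code{\link{assembleBarScar}} but with the full FRT-erm-FRT cassette
#' in place of the single FRT remnant. FLP-simulated excision
#' (\code{\link{flpExcise}}) of the result reproduces the bar scar exactly.
#'
#' @inheritParams assembleBarScar
#' @return a \code{\linkS4class{ScarSequence}} of kind \code{"erm_bar"}.
#' @export
assembleErmBarScar <- function(barcode, linkers = defaultLinkerSet()) {
    v <- validateBarcode(barcode)
    if (!v$valid)
        stop("invalid barcode: ", paste(v$violations, collapse = "; "))
    parts <- c(ATG = "ATG", LL = llFwd(linkers),
               cassette = ermCassette(linkers),
               spacer = spacerSeq(linkers), barcode = barcode,
               RL = rightLinker(linkers))
    new("ScarSequence", seq = paste(parts, collapse = ""),
        offsets = componentRanges(nchar(parts)), kind = "erm_bar")
}

#' Simulate FLP excision of the erm cassette
#'
#' Replaces the FRT-erm-FRT cassette of an erm-bar scar with the single
#' post-excision FRT remnant, yielding the unmarked bar scar.
#'
#' @param scar a \code{\linkS4class{ScarSequence}} of kind \code{"erm_bar"}.
#' @param linkers the \code{\linkS4class{LinkerSet}} used at assembly.
#' @return the corresponding bar \code{\linkS4class{ScarSequence}}.
#' @export
flpExcise <- function(scar, linkers = defaultLinkerSet()) {
    stopifnot(is(scar, "ScarSequence"))
    if (scarKind(scar) != "erm_bar")
        stop("flpExcise expects an erm_bar scar")
    assembleBarScar(scarBarcode(scar), linkers)
}

#' Join fragments by splicing-by-overlap-extension
#'
#' Merges adjacent fragments at their unique terminal overlap of length at
#' least \code{minOverlap} (suffix of the left fragment equal to prefix of
#' the right). This models SOE-PCR fusion of the upstream arm, the marked
#' middle fragment and the downstream arm via their shared LL and RL
#' homology.
#'
#' @param fragments character vector of at least two sequences, in order.
#' @param minOverlap minimum overlap length (default 15).
#' @return the joined sequence; its length is the sum of fragment lengths
#'   minus the sum of overlaps.
#' @examples
#' soeJoin(c("AAAC", "ACGG"), minOverlap = 2)  # "AAACGG"
#' @export
soeJoin <- function(fragments, minOverlap = 15L) {
    stopifnot(length(fragments) >= 2L)
    joined <- fragments[1L]
    for (i in 2L:length(fragments)) {
        nxt <- fragments[i]
        kmax <- min(nchar(joined), nchar(nxt))
        ks <- minOverlap:kmax
        hit <- ks[substring(joined, nchar(joined) - ks + 1L) ==
                  substring(nxt, 1L, ks)]
        if (length(hit) == 0L)
            stop(sprintf(
                "no terminal overlap >= %d nt at junction %d/%d",
                minOverlap, i - 1L, i))
        if (length(hit) > 1L)
            stop(sprintf(
                "ambiguous overlap at junction %d/%d: lengths %s all match",
                i - 1L, i, paste(hit, collapse = ", ")))
        joined <- paste0(joined, substring(nxt, hit + 1L))
    }
    joined
}

#' Replace a gene body with a deletion scar
#'
#' Deletes the gene's internal span (everything between the retained start
#' codon and retained last seven codons) and inserts the scar minus its own
#' ATG, so the scar's start codon coincides with the gene's. Minus-strand
#' genes receive the scar in coding orientation (reverse complement on the
#' forward strand).
#'
#' @param genome named character vector or \code{DNAStringSet} of replicons.
#' @param target a \code{\linkS4class{GeneTarget}}.
#' @param scar a \code{\linkS4class{ScarSequence}} (bar or erm_bar).
#' @return the mutant genome as a named character vector. The mutated
#'   replicon's length is the original minus the gene length plus the scar
#'   length plus 21.
#' @export
applyDeletion <- function(genome, target, scar) {
    genome <- asGenomeVector(genome)
    chr <- genomeSeq(genome, target@replicon)
    s <- target@start; e <- target@end
    if (e > nchar(chr)) stop("gene coordinates exceed replicon length")
    insert <- substring(scarSeq(scar), 4L)  # scar without its ATG
    if (target@strand == "+") {
        ## internal span: after start codon, before last 7 codons
        delStart <- s + 3L; delEnd <- e - 21L
        mut <- paste0(substr(chr, 1L, delStart - 1L), insert,
                      substring(chr, delEnd + 1L))
    } else {
        ## coding start codon sits at [e-2, e]; last 7 codons at [s, s+20]
        delStart <- s + 21L; delEnd <- e - 3L
        mut <- paste0(substr(chr, 1L, delStart - 1L), revcomp(insert),
                      substring(chr, delEnd + 1L))
    }
    genome[[target@replicon]] <- mut
    unlist(genome)
}

#' Verify the in-frame structure of an applied deletion
#'
#' Locates the scar in a mutant genome via the left linker and reports
#' whether (i) the scar ORF begins with ATG, (ii) the scar plus the
#' retained 21 nt is a whole number of codons, (iii) the only stop codon in
#' the scar ORF is the gene's original terminal stop, and (iv) the scar
#' contributes 46 codons including the ATG. Violations are reported, not
#' raised.
#'
#' @param genome mutant genome (named character vector or
#'   \code{DNAStringSet}).
#' @param target the deleted \code{\linkS4class{GeneTarget}}.
#' @param linkers the \code{\linkS4class{LinkerSet}} used at assembly.
#' @return list with logical fields \code{startsWithATG}, \code{inFrame},
#'   \code{onlyTerminalStop}, \code{pass}; integers \code{scarCodons} and
#'   \code{stopPositions} (codon indices of stops within the scar ORF,
#'   excluding the terminal one).
#' @export
verifyInFrame <- function(genome, target, linkers = defaultLinkerSet()) {
    genome <- asGenomeVector(genome)
    chr <- genomeSeq(genome, target@replicon)
    if (target@strand == "-") chr <- revcomp(chr)
    ## scar ORF = ATG + LL + ... + RL, then the retained 21 nt ending in the
    ## original stop codon
    scarBody <- paste0(llFwd(linkers), ".*?", rightLinker(linkers))
    m <- regexpr(paste0("ATG", scarBody), chr, perl = TRUE)
    if (m == -1L)
        return(list(startsWithATG = FALSE, inFrame = FALSE,
                    onlyTerminalStop = FALSE, scarCodons = NA_integer_,
                    stopPositions = integer(), pass = FALSE))
    scarStart <- as.integer(m)
    scarLen <- attr(m, "match.length")
    orf <- substr(chr, scarStart, scarStart + scarLen + 21L - 1L)
    startsWithATG <- startsWith(orf, "ATG")
    inFrame <- nchar(orf) %% 3L == 0L
    stops <- trimerStops(orf)
    nCod <- nchar(orf) %/% 3L
    onlyTerminalStop <- identical(stops, nCod)
    list(startsWithATG = startsWithATG, inFrame = inFrame,
         onlyTerminalStop = onlyTerminalStop,
         scarCodons = scarLen %/% 3L,
         stopPositions = setdiff(stops, nCod),
         pass = startsWithATG && inFrame && onlyTerminalStop)
}

#' Frequency of a codon within its synonymous family
#'
#' Counts the query codon across a set of coding sequences and divides by
#' the count of all codons encoding the same amino acid (standard genetic
#' code).
#'
#' @param cdsSet character vector of CDS sequences, lengths divisible by 3.
#' @param query a single codon.
#' @return the fraction \code{count(query) / count(synonymous family)}.
#' @examples
#' codonFamilyUsage(c("CGTCGTCGTAGG"), "AGG")  # 0.25
#' @export
codonFamilyUsage <- function(cdsSet, query) {
    query <- toupper(query)
    if (!query %in% names(Biostrings::GENETIC_CODE))
        stop(sprintf("'%s' is not a valid codon", query))
    aa <- Biostrings::GENETIC_CODE[[query]]
    if (aa == "*")
        stop("stop codons have no amino-acid family")
    if (any(nchar(cdsSet) %% 3L != 0L))
        stop("all CDS lengths must be divisible by 3")
    codons <- unlist(lapply(cdsSet, function(s) {
        n <- nchar(s) %/% 3L
        substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    }))
    family <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
    famCount <- sum(codons %in% family)
    if (famCount == 0L)
        stop(sprintf("no codon encoding %s present in the CDS set", aa))
    sum(codons == query) / famCount
}

## --- genome helpers -------------------------------------------------------

asGenomeVector <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        v <- as.character(genome)
        return(as.list(v))
    }
    if (is.character(genome)) return(as.list(genome))
    if (is.list(genome)) return(genome)
    stop("genome must be a named character vector, list, or DNAStringSet")
}

genomeSeq <- function(genome, replicon) {
    if (!replicon %in% names(genome))
        stop(sprintf("replicon '%s' not found in genome", replicon))
    genome[[replicon]]
}
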