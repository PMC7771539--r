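#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 48 VNN codons
#'
#' All codons whose first base is A, C or G (IUPAC V). No stop codon is a
#' VNN codon, so a barcode built from trimer-aligned VNN codons can never
#' introduce an in-frame stop into the deletion scar. These are the forward
#' (scar-orientation) equivalents of the NNB trimers placed on the reverse
#' synthesis primer.
#'
#' @return character vector of the 48 codons, lexicographically sorted.
#' @examples
#' length(vnnCodons())          # 48
#' any(vnnCodons() %in% c("TAA", "TAG", "TGA"))  # FALSE
#' @export
vnnCodons <- function() {
    b <- c("A", "C", "G", "T")
    g <- expand.grid(p3 = b, p2 = b, p1 = c("A", "C", "G"),
                     stringsAsFactors = FALSE)
    sort(paste0(g$p1, g$p2, g$p3))
}

## Trimer-aligned stop codon positions (1-based codon index) in a sequence.
trimerStops <- function(seq) {
    n <- nchar(seq) %/% 3L
    if (n == 0L) return(integer())
    cod <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    which(cod %in% STOP_CODONS)
}

#' Generate semirandom 18-nt barcodes
#'
#' Draws each of the six trimer-aligned codons uniformly from the 48 VNN
#' codons, giving an 18-nt barcode guaranteed to be free of trimer-aligned
#' stop codons. Uses R's global random number stream: call
#' \code{set.seed()} first for reproducibility.
#'
#' @param n number of barcodes to generate.
#' @return character vector of \code{n} 18-nt barcodes.
#' @examples
#' set.seed(1)
#' generateBarcode()
#' @export
generateBarcode <- function(n = 1L) {
    stopifnot(n >= 1L)
    codons <- vnnCodons()
    m <- matrix(sample(codons, 6L * n, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m))
}

#' Validate a candidate barcode sequence
#'
#' Checks the barcode invariants: exactly 18 characters, alphabet
#' {A,C,G,T} (ambiguity codes are rejected), and every trimer-aligned
#' codon's first base in {A,C,G} so no codon can be a stop. Invalid input
#' yields a \code{FALSE} verdict with named violations, never an error.
#'
#' @param seq a single character string.
#' @return list with elements \code{valid} (logical) and \code{violations}
#'   (character vector naming position and rule for each failure).
#' @examples
#' validateBarcode(strrep("A", 18))$valid   # TRUE
#' validateBarcode(paste0("T", strrep("A", 17)))$violations
#' @export
validateBarcode <- function(seq) {
    viol <- character()
    if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
        return(list(valid = FALSE,
                    violations = "input must be a single character string"))
    }
    if (nchar(seq) != 18L)
        viol <- c(viol, sprintf("length %d, expected 18", nchar(seq)))
    bases <- strsplit(seq, "")[[1]]
    bad <- which(!bases %in% c("A", "C", "G", "T"))
    if (length(bad))
        viol <- c(viol, sprintf(
            "position %d: base '%s' not in {A,C,G,T}", bad, bases[bad]))
    if (nchar(seq) == 18L && length(bad) == 0L) {
        first <- bases[seq(1L, 16L, by = 3L)]
        badc <- which(first == "T")
        if (length(badc))
            viol <- c(viol, sprintf(
                "codon %d (position %d): first base T violates VNN",
                badc, 3L * badc - 2L))
    }
    list(valid = length(viol) == 0L, violations = viol)
}

## Pairwise Hamming distances between equal-length barcodes (upper triangle,
## as a numeric vector like dist()).
barcodeDistances <- function(barcodes) {
    m <- do.call(rbind, strsplit(barcodes, ""))
    n <- nrow(m)
    d <- integer(n * (n - 1L) / 2L)
    k <- 1L
    for (i in seq_len(n - 1L)) {
        di <- colSums(t(m[(i + 1L):n, , drop = FALSE]) != m[i, ])
        d[k:(k + n - i - 1L)] <- di
        k <- k + n - i
    }
    d
}

#' Build a barcode library for a set of strains
#'
#' Assigns one freshly generated barcode to each strain by rejection
#' sampling: a draw is kept only if it is distinct from, and at Hamming
#' distance at least \code{minDistance} from, every barcode already placed.
#' Deterministic under a fixed seed.
#'
#' @param strainNames unique strain names (\code{"_other"} is reserved).
#' @param minDistance pairwise Hamming-distance floor; the default 3 rejects
#'   single-substitution collisions. Use 0 for plain uniqueness.
#' @param maxAttempts rejection-sampling budget per strain; exceeding it
#'   raises an error stating that the distance floor is unsatisfiable.
#' @return a \code{\linkS4class{BarcodeLibrary}}.
#' @examples
#' set.seed(7)
#' lib <- buildBarcodeLibrary(paste0("strain", 1:7))
#' lib
#' @export
buildBarcodeLibrary <- function(strainNames, minDistance = 3L,
                                maxAttempts = 10000L) {
    stopifnot(length(strainNames) >= 1L)
    if (anyDuplicated(strainNames))
        stop("strain names must be unique")
    minDistance <- as.integer(minDistance)
    placed <- character(0)
    placedMat <- NULL
    for (s in strainNames) {
        ok <- FALSE
        for (attempt in seq_len(maxAttempts)) {
            b <- generateBarcode(1L)
            if (b %in% placed) next
            if (minDistance > 0L && length(placed)) {
                v <- strsplit(b, "")[[1]]
                dmin <- min(colSums(t(placedMat) != v))
                if (dmin < minDistance) next
            }
            ok <- TRUE
            break
        }
        if (!ok)
            stop(sprintf(paste0(
                "could not place a barcode for strain '%s' at Hamming ",
                "distance >= %d from %d existing barcodes within %d ",
                "attempts; lower minDistance or the strain count"),
                s, minDistance, length(placed), maxAttempts))
        placed <- c(placed, b)
        placedMat <- rbind(placedMat, strsplit(b, "")[[1]])
    }
    new("BarcodeLibrary", strains = as.character(strainNames),
        barcodes = placed, minDistance = minDistance)
}

#' @rdname BarcodeLibrary-accessors
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @rdname BarcodeLibrary-accessors
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' Accessors for BarcodeLibrary
#'
#' @param x a \code{\linkS4class{BarcodeLibrary}}.
#' @name BarcodeLibrary-accessors
NULL

#' @rdname BarcodeLibrary-accessors
#' @export
setMethod("strainNames", "BarcodeLibrary", function(x) x@strains)

#' @rdname BarcodeLibrary-accessors
#' @export
setMethod("barcodes", "BarcodeLibrary",
          function(x) stats::setNames(x@barcodes, x@strains))

#' @export
setMethod("length", "BarcodeLibrary", function(x) length(x@strains))

setMethod("show", "BarcodeLibrary", function(object) {
    cat(sprintf("BarcodeLibrary with %d strains (minDistance = %d)\n",
                length(object), object@minDistance))
    n <- min(length(object), 5L)
    for (i in seq_len(n))
        cat(sprintf("  %-20s %s\n", object@strains[i], object@barcodes[i]))
    if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                        length(object) - n))
})

#' Read and write barcode library TSV files
#'
#' The on-disk format is a two-column UTF-8 TSV with header line
#' \code{strain<TAB>barcode} and LF line endings. \code{"_other"} is a
#' reserved strain name and rejected on read. A write followed by a read and
#' rewrite is byte-identical.
#'
#' @param path file path.
#' @param lib a \code{\linkS4class{BarcodeLibrary}}.
#' @param minDistance distance floor to record (and check) on read.
#' @return \code{readBarcodeLibrary} returns a
#'   \code{\linkS4class{BarcodeLibrary}}; \code{writeBarcodeLibrary} returns
#'   \code{path} invisibly.
#' @export
readBarcodeLibrary <- function(path, minDistance = 0L) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             fileEncoding = "UTF-8")
    if (!identical(colnames(tab)[1:2], c("strain", "barcode")))
        stop("barcode library TSV must have header 'strain\\tbarcode'")
    if (OTHER_LABEL %in% tab$strain)
        stop(sprintf("'%s' is a reserved strain name and cannot appear in ",
                     OTHER_LABEL), "a barcode library")
    new("BarcodeLibrary", strains = tab$strain, barcodes = tab$barcode,
        minDistance = as.integer(minDistance))
}

#' @rdname readBarcodeLibrary
#' @export
writeBarcodeLibrary <- function(lib, path) {
    stopifnot(is(lib, "BarcodeLibrary"))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c("strain\tbarcode",
                 paste(lib@strains, lib@barcodes, sep = "\t")),
               con, sep = "\n", useBytes = TRUE)
    invisible(path)
}
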