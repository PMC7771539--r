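#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   assayNames
NULL

#' Default flank pattern for barcode extraction
#'
#' The left flank is the 18-nt spacer and the right flank is the first
#' 18 nt of the right linker; the barcode is the exact 18-nt window between
#' them.
#'
#' @param maxFlankMismatches substitutions tolerated in each flank
#'   (default 0: exact literal match, as real flanks are constant).
#' @param searchRevcomp also search the reverse complement of reads with no
#'   forward hit (default \code{TRUE}).
#' @param linkers a \code{\linkS4class{LinkerSet}}.
#' @return a \code{\linkS4class{FlankPattern}}.
#' @export
defaultFlankPattern <- function(maxFlankMismatches = 0L,
                                searchRevcomp = TRUE,
                                linkers = defaultLinkerSet()) {
    new("FlankPattern", left = spacerSeq(linkers),
        right = substr(rightLinker(linkers), 1L, 18L),
        barcodeLen = 18L,
        maxFlankMismatches = as.integer(maxFlankMismatches),
        searchRevcomp = searchRevcomp)
}

setMethod("show", "FlankPattern", function(object) {
    cat("FlankPattern\n")
    cat("  left :", object@left, "\n")
    cat("  right:", object@right, "\n")
    cat(sprintf("  barcodeLen %d, maxFlankMismatches %d, searchRevcomp %s\n",
                object@barcodeLen, object@maxFlankMismatches,
                object@searchRevcomp))
})

## Forward-orientation extraction on a character vector of reads.
## Returns list(candidate = chr (NA if none), multi = logical).
extractForward <- function(reads, pattern) {
    k <- pattern@maxFlankMismatches
    if (k == 0L) {
        re <- paste0(pattern@left, "([ACGTN]{", pattern@barcodeLen, "})",
                     pattern@right)
        m <- gregexpr(re, reads, perl = TRUE)
        cand <- rep(NA_character_, length(reads))
        multi <- logical(length(reads))
        hit <- vapply(m, function(x) x[1L] != -1L, logical(1))
        if (any(hit)) {
            cs <- vapply(m[hit], function(x)
                attr(x, "capture.start")[1L, 1L], numeric(1))
            cand[hit] <- substr(reads[hit], cs,
                                cs + pattern@barcodeLen - 1L)
            multi[hit] <- lengths(m[hit]) > 1L
        }
        list(candidate = cand, multi = multi)
    } else {
        extractForwardFuzzy(reads, pattern)
    }
}

## Mismatch-tolerant path: Biostrings pattern matching on the left flank,
## then a direct mismatch count on the right flank at the fixed offset.
extractForwardFuzzy <- function(reads, pattern) {
    k <- pattern@maxFlankMismatches
    bl <- pattern@barcodeLen
    fl <- nchar(pattern@left)
    dss <- Biostrings::DNAStringSet(reads)
    hits <- Biostrings::vmatchPattern(pattern@left, dss, max.mismatch = k,
                                      fixed = TRUE)
    rightChars <- strsplit(pattern@right, "")[[1]]
    rl <- length(rightChars)
    cand <- rep(NA_character_, length(reads))
    multi <- logical(length(reads))
    for (i in which(lengths(hits) > 0L)) {
        st <- sort(IRanges::start(hits[[i]]))
        found <- 0L
        for (p in st) {
            bStart <- p + fl
            rEnd <- bStart + bl + rl - 1L
            if (rEnd > nchar(reads[i])) next
            right <- substring(reads[i], bStart + bl, rEnd)
            mm <- sum(strsplit(right, "")[[1]] != rightChars)
            if (mm <= k) {
                found <- found + 1L
                if (found == 1L)
                    cand[i] <- substring(reads[i], bStart, bStart + bl - 1L)
            }
        }
        multi[i] <- found > 1L
    }
    list(candidate = cand, multi = multi)
}

#' Extract candidate barcodes from reads
#'
#' Returns the exact 18-nt window between the first left-flank match and an
#' immediately following right-flank match in each read, or \code{NA} when
#' no such window exists. When \code{searchRevcomp} is on, reads with no
#' forward-orientation hit are re-searched in reverse complement. Reads
#' with several distinct candidate windows contribute only their first;
#' the number of such reads is attached as attribute \code{"nMultiWindow"}.
#'
#' @param reads character vector of read sequences.
#' @param pattern a \code{\linkS4class{FlankPattern}}.
#' @return character vector of candidate barcodes (\code{NA} = none).
#' @examples
#' p <- defaultFlankPattern()
#' read <- paste0("AAA", p@left, strrep("ACG", 6), p@right, "TTT")
#' extractCandidateBarcode(read, p)
#' @export
extractCandidateBarcode <- function(reads, pattern = defaultFlankPattern()) {
    fw <- extractForward(reads, pattern)
    cand <- fw$candidate
    multi <- fw$multi
    if (pattern@searchRevcomp && anyNA(cand)) {
        miss <- which(is.na(cand))
        rc <- extractForward(revcomp(reads[miss]), pattern)
        cand[miss] <- rc$candidate
        multi[miss] <- multi[miss] | rc$multi
    }
    structure(cand, nMultiWindow = sum(multi))
}

#' Classify candidate barcodes against a library
#'
#' Exact-match lookup: a candidate found in the library yields its strain
#' name; a candidate absent from the library (including any containing N)
#' yields \code{"_other"}; \code{NA} candidates (no extractable window)
#' yield \code{NA} and are excluded from the counts table, appearing only
#' in the total read count.
#'
#' @param candidates character vector from
#'   \code{\link{extractCandidateBarcode}}.
#' @param library a \code{\linkS4class{BarcodeLibrary}}.
#' @return character vector of strain names, \code{"_other"}, or \code{NA}.
#' @export
classifyRead <- function(candidates, library) {
    stopifnot(is(library, "BarcodeLibrary"))
    idx <- match(candidates, library@barcodes)
    out <- library@strains[idx]
    out[is.na(idx) & !is.na(candidates)] <- OTHER_LABEL
    out
}

## Stream a 4-line FASTQ file (optionally gzipped) in chunks, calling
## fun(seqs) for each chunk of read sequences. Errors name the offending
## record. Constant memory in the number of reads.
streamFastq <- function(path, fun, chunkSize = 50000L) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    recordIndex <- 0L
    repeat {
        lines <- readLines(con, n = 4L * chunkSize)
        if (length(lines) == 0L) break
        if (length(lines) %% 4L != 0L)
            stop(sprintf("truncated FASTQ record %d in %s",
                         recordIndex + length(lines) %/% 4L + 1L, path))
        hdr <- lines[seq(1L, length(lines), by = 4L)]
        plus <- lines[seq(3L, length(lines), by = 4L)]
        bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
        if (length(bad))
            stop(sprintf("malformed FASTQ record %d in %s",
                         recordIndex + bad[1L], path))
        fun(lines[seq(2L, length(lines), by = 4L)])
        recordIndex <- recordIndex + length(lines) %/% 4L
    }
    recordIndex
}

#' Count barcodes in one sample
#'
#' Streams FASTQ file(s) (gzip accepted), extracts candidate barcodes,
#' classifies them against the library and returns one counts-table column
#' with its read accounting. Strain counts plus \code{"_other"} always
#' equal the number of reads in which both flanks were found.
#'
#' @param fastqFiles one or more FASTQ paths belonging to the same sample.
#' @param library a \code{\linkS4class{BarcodeLibrary}}.
#' @param pattern a \code{\linkS4class{FlankPattern}}.
#' @param chunkSize reads per streaming chunk.
#' @return list with \code{counts} (named integer vector: library strains
#'   then \code{"_other"}), \code{readsTotal} and \code{readsWithFlanks}.
#' @export
countSample <- function(fastqFiles, library, pattern = defaultFlankPattern(),
                        chunkSize = 50000L) {
    stopifnot(is(library, "BarcodeLibrary"))
    levels <- c(library@strains, OTHER_LABEL)
    acc <- stats::setNames(integer(length(levels)), levels)
    total <- 0L
    for (f in fastqFiles) {
        n <- streamFastq(f, function(seqs) {
            cand <- extractCandidateBarcode(seqs, pattern)
            cls <- classifyRead(cand, library)
            tab <- table(factor(cls, levels = levels))
            acc <<- acc + as.integer(tab)
        }, chunkSize = chunkSize)
        total <- total + n
    }
    list(counts = acc, readsTotal = total,
         readsWithFlanks = sum(acc))
}

#' Build a BarSeqCounts object from per-sample columns
#'
#' @param columns named list of \code{\link{countSample}} results, one per
#'   sample, in column order.
#' @param library the \code{\linkS4class{BarcodeLibrary}} used for
#'   counting.
#' @param colData optional extra per-sample annotation
#'   (\code{data.frame}).
#' @return a \code{\linkS4class{BarSeqCounts}}.
#' @export
barSeqCounts <- function(columns, library, colData = NULL) {
    m <- vapply(columns, `[[`, integer(length(library) + 1L), "counts")
    rownames(m) <- c(library@strains, OTHER_LABEL)
    cd <- DataFrame(
        readsTotal = vapply(columns, function(x)
            as.numeric(x$readsTotal), numeric(1)),
        readsWithFlanks = vapply(columns, function(x)
            as.numeric(x$readsWithFlanks), numeric(1)),
        row.names = names(columns))
    if (!is.null(colData)) cd <- cbind(cd, DataFrame(colData))
    new("BarSeqCounts",
        SummarizedExperiment(assays = list(counts = m), colData = cd))
}

#' Count all samples of a sample sheet
#'
#' The sample sheet is a data.frame (or TSV path) with columns
#' \code{sample}, \code{role} (\code{input}/\code{output}),
#' \code{replicateGroup} and \code{fastq}; several rows with the same
#' sample name contribute their FASTQ files to one column.
#'
#' @param sampleSheet data.frame or TSV path.
#' @param library a \code{\linkS4class{BarcodeLibrary}}.
#' @param pattern a \code{\linkS4class{FlankPattern}}.
#' @return a \code{\linkS4class{BarSeqCounts}} with \code{role} and
#'   \code{replicateGroup} in its \code{colData}.
#' @export
countSamples <- function(sampleSheet, library,
                         pattern = defaultFlankPattern()) {
    if (is.character(sampleSheet))
        sampleSheet <- utils::read.delim(sampleSheet, sep = "\t",
                                         stringsAsFactors = FALSE)
    need <- c("sample", "fastq")
    if (!all(need %in% colnames(sampleSheet)))
        stop("sample sheet needs columns: ", paste(need, collapse = ", "))
    missing <- !file.exists(sampleSheet$fastq)
    if (any(missing))
        stop("FASTQ file(s) not found: ",
             paste(sampleSheet$fastq[missing], collapse = ", "))
    samples <- unique(sampleSheet$sample)
    cols <- lapply(samples, function(s) {
        countSample(sampleSheet$fastq[sampleSheet$sample == s], library,
                    pattern)
    })
    names(cols) <- samples
    meta <- sampleSheet[match(samples, sampleSheet$sample),
                        intersect(c("role", "replicateGroup"),
                                  colnames(sampleSheet)), drop = FALSE]
    rownames(meta) <- samples
    barSeqCounts(cols, library,
                 colData = if (ncol(meta)) meta else NULL)
}

#' Merge technical replicates by summation
#'
#' Technical-replicate columns are summed into one column per biological
#' sample (count-level pooling); read accounting is summed alongside, so
#' conservation is preserved.
#'
#' @param counts a \code{\linkS4class{BarSeqCounts}}.
#' @param groups named character vector or factor mapping each existing
#'   column to its merged group; defaults to the \code{replicateGroup}
#'   colData column.
#' @return a merged \code{\linkS4class{BarSeqCounts}} with one column per
#'   group, in first-appearance order.
#' @export
mergeCounts <- function(counts, groups = NULL) {
    stopifnot(is(counts, "BarSeqCounts"))
    if (is.null(groups)) {
        if (!"replicateGroup" %in% colnames(colData(counts)))
            stop("no replicateGroup in colData and no groups given")
        groups <- stats::setNames(colData(counts)$replicateGroup,
                                  colnames(counts))
    }
    if (!all(colnames(counts) %in% names(groups)))
        stop("groups must cover every column: missing ",
             paste(setdiff(colnames(counts), names(groups)), collapse = ", "))
    if (!all(names(groups) %in% colnames(counts)))
        stop("groups reference missing column(s): ",
             paste(setdiff(names(groups), colnames(counts)), collapse = ", "))
    g <- as.character(groups[colnames(counts)])
    uniq <- unique(g)
    m <- assay(counts, "counts")
    merged <- vapply(uniq, function(u)
        as.integer(rowSums(m[, g == u, drop = FALSE])),
        integer(nrow(m)))
    rownames(merged) <- rownames(m)
    cd <- DataFrame(
        readsTotal = vapply(uniq, function(u)
            sum(colData(counts)$readsTotal[g == u]), numeric(1)),
        readsWithFlanks = vapply(uniq, function(u)
            sum(colData(counts)$readsWithFlanks[g == u]), numeric(1)),
        row.names = uniq)
    if ("role" %in% colnames(colData(counts)))
        cd$role <- vapply(uniq, function(u)
            colData(counts)$role[g == u][1L], character(1))
    new("BarSeqCounts",
        SummarizedExperiment(assays = list(counts = merged), colData = cd))
}

#' Read and write counts tables
#'
#' Tab-delimited, one row per strain in library order then \code{"_other"},
#' one column per sample. Read accounting is stored in comment lines
#' (\code{#readsTotal}, \code{#readsWithFlanks}) so a write/read round trip
#' preserves the object. Extra \code{# } comment lines may carry
#' provenance.
#'
#' @param counts a \code{\linkS4class{BarSeqCounts}}.
#' @param path file path.
#' @param provenance optional character vector of provenance lines to
#'   prepend as comments.
#' @return \code{readCountsTable} returns a
#'   \code{\linkS4class{BarSeqCounts}}; \code{writeCountsTable} returns
#'   \code{path} invisibly.
#' @export
writeCountsTable <- function(counts, path, provenance = NULL) {
    stopifnot(is(counts, "BarSeqCounts"))
    m <- assay(counts, "counts")
    con <- file(path, "wb")
    on.exit(close(con))
    lines <- character(0)
    if (!is.null(provenance)) lines <- paste0("# ", provenance)
    cd <- colData(counts)
    lines <- c(lines,
        paste(c("#readsTotal", cd$readsTotal), collapse = "\t"),
        paste(c("#readsWithFlanks", cd$readsWithFlanks), collapse = "\t"),
        paste(c("strain", colnames(m)), collapse = "\t"),
        vapply(seq_len(nrow(m)), function(i)
            paste(c(rownames(m)[i], m[i, ]), collapse = "\t"),
            character(1)))
    writeLines(lines, con, useBytes = TRUE)
    invisible(path)
}

#' @rdname writeCountsTable
#' @export
readCountsTable <- function(path) {
    lines <- readLines(path)
    isMeta <- startsWith(lines, "#")
    meta <- lines[isMeta]
    body <- lines[!isMeta]
    tab <- utils::read.delim(text = body, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab$strain
    storage.mode(m) <- "integer"
    getMeta <- function(key, default) {
        ln <- meta[startsWith(meta, key)]
        if (length(ln)) as.numeric(strsplit(ln[1L], "\t")[[1]][-1L])
        else default
    }
    rwf <- getMeta("#readsWithFlanks", colSums(m))
    rt <- getMeta("#readsTotal", rwf)
    cd <- DataFrame(readsTotal = rt, readsWithFlanks = rwf,
                    row.names = colnames(m))
    new("BarSeqCounts",
        SummarizedExperiment(assays = list(counts = m), colData = cd))
}
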