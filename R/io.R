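#' @importFrom Biostrings readDNAStringSet writeXStringSet
NULL

#' Read a genome FASTA into a named character vector
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}; sequence names
#' are truncated at the first whitespace so they match replicon ids in
#' gene tables.
#'
#' @param path FASTA path (gzip accepted).
#' @return named character vector of replicon sequences.
#' @export
readGenomeFasta <- function(path) {
    ss <- readDNAStringSet(path)
    names(ss) <- sub("\\s.*$", "", names(ss))
    as.character(ss)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of replicons.
#' @param path output path.
#' @export
writeGenomeFasta <- function(genome, path) {
    ss <- DNAStringSet(unlist(genome))
    writeXStringSet(ss, path)
    invisible(path)
}

#' Read a gene coordinate table
#'
#' TSV with columns \code{replicon}, \code{start}, \code{end},
#' \code{strand}, \code{name}; coordinates 1-based inclusive.
#'
#' @param path TSV path.
#' @return list of \code{\linkS4class{GeneTarget}} objects, named by gene.
#' @export
readGeneTable <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("replicon", "start", "end", "strand", "name")
    if (!all(need %in% colnames(tab)))
        stop("gene table needs columns: ", paste(need, collapse = ", "))
    targets <- lapply(seq_len(nrow(tab)), function(i)
        geneTarget(tab$replicon[i], tab$start[i], tab$end[i],
                   tab$strand[i], tab$name[i]))
    stats::setNames(targets, tab$name)
}

#' Write an oligo sheet
#'
#' One row per oligo: name, sequence, forward-strand anneal coordinates
#' (1-based inclusive), direction; predicted product sizes go into comment
#' lines.
#'
#' @param oligoSet an \code{\linkS4class{OligoSet}}.
#' @param path output TSV path.
#' @param provenance optional comment lines.
#' @export
writeOligoSheet <- function(oligoSet, path, provenance = NULL) {
    stopifnot(is(oligoSet, "OligoSet"))
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c(provenance,
             sprintf("predicted products (bp): %s",
                     paste(names(oligoSet@products), oligoSet@products,
                           sep = "=", collapse = ", ")))
    writeLines(paste0("# ", hdr), con, useBytes = TRUE)
    df <- as.data.frame(oligoSet@oligos)
    df$gene <- oligoSet@target@name
    utils::write.table(df[, c("gene", "name", "sequence", "annealStart",
                              "annealEnd", "direction")],
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write scars as FASTA
#'
#' @param scars named list of \code{\linkS4class{ScarSequence}}.
#' @param path output path.
#' @export
writeScarFasta <- function(scars, path) {
    seqs <- vapply(scars, scarSeq, character(1))
    writeGenomeFasta(seqs, path)
}
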