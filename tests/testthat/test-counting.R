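makePattern <- function(...) defaultFlankPattern(...)

test_that("extractCandidateBarcode returns the exact 18-nt window", {
    p <- makePattern()
    bc <- strrep("ACG", 6)
    read <- paste0("NNN", p@left, bc, p@right, "NNN")
    expect_identical(unname(extractCandidateBarcode(read, p)[1]), bc)
    # read without flanks
    expect_true(is.na(extractCandidateBarcode(strrep("A", 100), p)[1]))
    # 17-nt window is rejected: the window must be exactly 18
    bad <- paste0(p@left, strrep("C", 17), p@right)
    expect_true(is.na(extractCandidateBarcode(bad, p)[1]))
    # 19-nt window likewise
    bad19 <- paste0(p@left, strrep("C", 19), p@right)
    expect_true(is.na(extractCandidateBarcode(bad19, p)[1]))
})

test_that("reverse-complement reads are found only when searched", {
    p <- makePattern(searchRevcomp = TRUE)
    pNo <- makePattern(searchRevcomp = FALSE)
    bc <- strrep("GAT", 6)
    fwd <- paste0("AA", p@left, bc, p@right, "TT")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(fwd)))
    expect_identical(unname(extractCandidateBarcode(rc, p)[1]), bc)
    expect_true(is.na(extractCandidateBarcode(rc, pNo)[1]))
})

test_that("multiple candidate windows count once, first wins", {
    p <- makePattern()
    b1 <- strrep("ACG", 6); b2 <- strrep("GCA", 6)
    read <- paste0(p@left, b1, p@right, "AA", p@left, b2, p@right)
    cand <- extractCandidateBarcode(read, p)
    expect_identical(unname(cand[1]), b1)
    expect_equal(attr(cand, "nMultiWindow"), 1L)
})

test_that("flank mismatches are tolerated only when configured", {
    bc <- strrep("CTT", 6)
    p0 <- makePattern(maxFlankMismatches = 0L)
    left1 <- p0@left
    substr(left1, 4, 4) <- if (substr(left1, 4, 4) == "A") "C" else "A"
    read <- paste0("GG", left1, bc, p0@right, "GG")
    expect_true(is.na(extractCandidateBarcode(read, p0)[1]))
    p1 <- makePattern(maxFlankMismatches = 1L)
    expect_identical(unname(extractCandidateBarcode(read, p1)[1]), bc)
})

test_that("classifyRead maps candidates to strain, _other, or unextractable", {
    set.seed(51)
    lib <- buildBarcodeLibrary(c("s1", "s2"))
    bcs <- barcodes(lib)
    novel <- strrep("ACT", 6)
    stopifnot(!novel %in% bcs)
    cand <- c(bcs[["s1"]], novel, NA, paste0("N", substr(bcs[["s1"]], 2, 18)))
    cls <- classifyRead(cand, lib)
    expect_identical(cls, c("s1", "_other", NA, "_other"))
})

test_that("countSample recovers simulator truth exactly at error rate 0", {
    set.seed(53)
    lib <- buildBarcodeLibrary(paste0("s", 1:5))
    scars <- lapply(barcodes(lib), assembleBarScar)
    sc <- sequencingScenario(readsPerSample = 10000L, seed = 7L)
    f <- tempfile(fileext = ".fastq")
    sim <- simulateReads(stats::setNames(rep(0.2, 5), paste0("s", 1:5)),
                         scars, sc, fastqPath = f)
    col <- countSample(f, lib)
    expect_identical(col$counts[paste0("s", 1:5)], sim$trueCounts)
    expect_equal(col$counts[["_other"]], 0L)
    expect_equal(col$readsTotal, 10000L)
    # conservation
    expect_equal(sum(col$counts), col$readsWithFlanks)
    expect_lte(col$readsWithFlanks, col$readsTotal)
})

test_that("gzipped FASTQ and multi-file samples are supported", {
    set.seed(54)
    lib <- buildBarcodeLibrary(c("x", "y"))
    scars <- lapply(barcodes(lib), assembleBarScar)
    sc <- sequencingScenario(readsPerSample = 400L, seed = 8L)
    f1 <- tempfile(fileext = ".fastq.gz")
    f2 <- tempfile(fileext = ".fastq")
    sim1 <- simulateReads(c(x = 0.5, y = 0.5), scars, sc, fastqPath = f1)
    sim2 <- simulateReads(c(x = 1, y = 0), scars, sc, fastqPath = f2)
    col <- countSample(c(f1, f2), lib)
    expect_identical(col$counts[c("x", "y")],
                     sim1$trueCounts + sim2$trueCounts)
    expect_equal(col$readsTotal, 800L)
})

test_that("all-reverse-complement reads need searchRevcomp", {
    set.seed(55)
    lib <- buildBarcodeLibrary(c("x", "y"))
    scars <- lapply(barcodes(lib), assembleBarScar)
    sc <- sequencingScenario(readsPerSample = 300L, revcompFraction = 1,
                             seed = 9L)
    f <- tempfile(fileext = ".fastq")
    sim <- simulateReads(c(x = 0.5, y = 0.5), scars, sc, fastqPath = f)
    off <- countSample(f, lib, makePattern(searchRevcomp = FALSE))
    expect_equal(off$readsWithFlanks, 0L)
    on <- countSample(f, lib, makePattern(searchRevcomp = TRUE))
    expect_identical(on$counts[c("x", "y")], sim$trueCounts)
})

test_that("raising maxFlankMismatches never decreases reads with flanks", {
    set.seed(56)
    lib <- buildBarcodeLibrary(c("x", "y"))
    scars <- lapply(barcodes(lib), assembleBarScar)
    sc <- sequencingScenario(readsPerSample = 500L,
                             substitutionRate = 0.02, seed = 10L)
    f <- tempfile(fileext = ".fastq")
    simulateReads(c(x = 0.5, y = 0.5), scars, sc, fastqPath = f)
    rwf <- vapply(0:2, function(k)
        countSample(f, lib, makePattern(maxFlankMismatches = k))$readsWithFlanks,
        numeric(1))
    expect_true(all(diff(rwf) >= 0))
})

test_that("empty and malformed FASTQ are handled", {
    lib <- new("BarcodeLibrary", strains = "s1",
               barcodes = strrep("A", 18), minDistance = 0L)
    empty <- tempfile(fileext = ".fastq"); file.create(empty)
    col <- countSample(empty, lib)
    expect_equal(col$readsTotal, 0L)
    expect_true(all(col$counts == 0L))

    bad <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII", "r2-no-at", "ACGT", "+",
                 "IIII"), bad)
    expect_error(countSample(bad, lib), "record 2")
    trunc <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), trunc)
    expect_error(countSample(trunc, lib), "truncated")
})

test_that("BarSeqCounts enforces conservation and mergeCounts preserves it", {
    set.seed(57)
    lib <- buildBarcodeLibrary(paste0("s", 1:3))
    mkCol <- function(counts, extra = 0L)
        list(counts = stats::setNames(as.integer(counts),
                                      c(paste0("s", 1:3), "_other")),
             readsTotal = sum(counts) + extra,
             readsWithFlanks = sum(counts))
    cols <- list(a1 = mkCol(c(10, 20, 30, 5), 2L),
                 a2 = mkCol(c(10, 20, 30, 5), 2L),
                 a3 = mkCol(c(10, 20, 30, 5), 2L),
                 b = mkCol(c(1, 2, 3, 0)))
    bsc <- barSeqCounts(cols, lib)
    expect_s4_class(bsc, "BarSeqCounts")
    merged <- mergeCounts(bsc, groups = c(a1 = "A", a2 = "A", a3 = "A",
                                          b = "B"))
    m <- assay(merged, "counts")
    # three identical technical replicates sum to triple totals
    expect_equal(unname(m[, "A"]), c(30L, 60L, 90L, 15L))
    expect_equal(unname(colData(merged)["A", "readsWithFlanks"]), 195)
    expect_equal(unname(colData(merged)["A", "readsTotal"]), 201)
    # merge of disjoint singletons is the identity on counts
    ident <- mergeCounts(bsc, groups = c(a1 = "a1", a2 = "a2", a3 = "a3",
                                         b = "b"))
    expect_equal(assay(ident, "counts"), assay(bsc, "counts"))
    # conservation violations are rejected at construction
    badCols <- list(a = mkCol(c(1, 1, 1, 0)))
    badCols$a$readsWithFlanks <- 99L
    expect_error(barSeqCounts(badCols, lib), "conservation")
    expect_error(mergeCounts(bsc, groups = c(a1 = "A")), "cover")
})

test_that("counts tables round trip through TSV", {
    set.seed(58)
    lib <- buildBarcodeLibrary(paste0("s", 1:3))
    cols <- list(
        in1 = list(counts = stats::setNames(c(5L, 6L, 7L, 1L),
                                            c(paste0("s", 1:3), "_other")),
                   readsTotal = 25L, readsWithFlanks = 19L))
    bsc <- barSeqCounts(cols, lib)
    f <- tempfile(fileext = ".tsv")
    writeCountsTable(bsc, f, provenance = "test run")
    back <- readCountsTable(f)
    expect_equal(assay(back, "counts"), assay(bsc, "counts"))
    expect_equal(colData(back)$readsTotal, 25)
    expect_equal(colData(back)$readsWithFlanks, 19)
})
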