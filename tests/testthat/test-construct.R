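test_that("the forward left linker is the reverse complement of the printed primer extension", {
    # independent oracle: Biostrings reverse complement of the printed
    # R1-LL extension
    expected <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString("CTGGCGAAGCATATATAAGAAGCTCGTCTCGT")))
    expect_identical(llFwd(defaultLinkerSet()), expected)
})

test_that("linker constants tie construct design to read counting", {
    ls <- defaultLinkerSet()
    p <- defaultFlankPattern()
    expect_identical(p@left, spacerSeq(ls))
    expect_identical(p@right, substr(rightLinker(ls), 1, 18))
    expect_equal(nchar(frtRemnant(ls)), 34L)
})

test_that("bar scar layout tiles 138 bp without gaps and holds its parts", {
    set.seed(2)
    for (i in 1:10) {
        bc <- generateBarcode()
        scar <- assembleBarScar(bc)
        s <- scarSeq(scar)
        expect_equal(nchar(s), 138L)
        off <- scarOffsets(scar)
        expect_equal(sum(IRanges::width(off)), 138L)
        expect_equal(min(IRanges::start(off)), 1L)
        expect_equal(max(IRanges::end(off)), 138L)
        # barcode occupies whole codons: 0-based offset 87 divisible by 3
        expect_equal((IRanges::start(off["barcode"]) - 1L) %% 3L, 0L)
        expect_identical(substr(s, 70, 87), spacerSeq(defaultLinkerSet()))
        expect_identical(substr(s, 88, 105), bc)
        expect_identical(substr(s, 106, 123),
                         substr(rightLinker(defaultLinkerSet()), 1, 18))
        expect_length(BarSeqTools:::trimerStops(s), 0L)
    }
})

test_that("scar assembly rejects invalid barcodes", {
    expect_error(assembleBarScar(strrep("A", 17)), "invalid barcode")
    expect_error(assembleBarScar(paste0("TAA", strrep("A", 15))),
                 "invalid barcode")
})

test_that("erm-bar scar excises to the bar scar exactly", {
    set.seed(31)
    ls <- defaultLinkerSet()
    for (i in 1:20) {
        bc <- generateBarcode()
        marked <- assembleErmBarScar(bc, ls)
        bar <- assembleBarScar(bc, ls)
        expect_identical(scarSeq(flpExcise(marked, ls)), scarSeq(bar))
        # length identity: erm_bar - bar == cassette - FRT remnant
        expect_equal(nchar(scarSeq(marked)) - nchar(scarSeq(bar)),
                     nchar(ermCassette(ls)) - nchar(frtRemnant(ls)))
        # spacer/barcode/RL intervals identical relative to scar end
        offM <- scarOffsets(marked); offB <- scarOffsets(bar)
        for (comp in c("spacer", "barcode", "RL")) {
            expect_equal(nchar(scarSeq(marked)) - IRanges::start(offM[comp]),
                         nchar(scarSeq(bar)) - IRanges::start(offB[comp]))
        }
    }
})

test_that("soeJoin merges at unique terminal overlaps", {
    expect_identical(soeJoin(c("AAAC", "ACGG"), minOverlap = 2), "AAACGG")
    expect_error(soeJoin(c("AAAA", "CCCC"), minOverlap = 2), "no terminal")
    expect_error(soeJoin(c("GAAAA", "AAAAG"), minOverlap = 2), "ambiguous")
})

test_that("soeJoin reconstructs randomly fragmented sequences", {
    set.seed(41)
    for (i in 1:200) {
        n <- sample(200:500, 1)
        s <- randomDNA(n)
        a <- sample(50:(n %/% 2), 1)
        b <- sample((a + 40):(n - 40), 1)
        ov1 <- sample(20:35, 1); ov2 <- sample(20:35, 1)
        frags <- c(substr(s, 1, a + ov1 - 1),
                   substr(s, a, b + ov2 - 1),
                   substr(s, b, n))
        expect_identical(soeJoin(frags, minOverlap = 20L), s)
    }
})

test_that("SOE of up-arm, marked middle and down-arm forms the ~3-kb mutagenic fragment", {
    set.seed(42)
    toy <- makeToyGenome()
    ls <- defaultLinkerSet()
    bc <- generateBarcode()
    chr <- toy$genome[["chr1"]]
    s <- 4001L; e <- 4900L
    up <- paste0(substr(chr, s - 1000L, s + 2L), llFwd(ls))
    middle <- substring(scarSeq(assembleErmBarScar(bc, ls)), 4L)
    down <- paste0(rightLinker(ls), substr(chr, e - 20L, e + 1000L))
    joined <- soeJoin(c(up, middle, down), minOverlap = 20L)
    # joined length = sum of fragments minus the LL (32) and RL (33)
    # overlaps; lands near 3 kb
    expect_equal(nchar(joined),
                 nchar(up) + nchar(middle) + nchar(down) - 32L - 33L)
    expect_gt(nchar(joined), 2900L)
    expect_lt(nchar(joined), 3300L)
    expect_equal(length(gregexpr(bc, joined, fixed = TRUE)[[1]]), 1L)
})

test_that("designOligos places anneal sites at the stated offsets", {
    toy <- makeToyGenome()
    os <- designOligos(toy$genome, toy$target)
    ol <- as.data.frame(oligos(os))
    rownames(ol) <- ol$name
    expect_equal(ol["F1", "annealStart"], 3001L)
    expect_equal(ol["FO", "annealStart"], 2501L)
    expect_equal(ol["R2", "annealEnd"], 5900L)
    expect_equal(ol["RO", "annealEnd"], 6400L)
    # R1-LL starts with the printed 32-nt extension; F2-RL starts with RL
    expect_true(startsWith(ol["R1_LL", "sequence"],
                           "CTGGCGAAGCATATATAAGAAGCTCGTCTCGT"))
    expect_true(startsWith(ol["F2_RL", "sequence"],
                           rightLinker(defaultLinkerSet())))
    # FW/RW product for a 900-nt gene lies in [500, 876]
    expect_gte(predictedProducts(os)[["FW_RW"]], 500)
    expect_lte(predictedProducts(os)[["FW_RW"]], 876)
    expect_equal(predictedProducts(os)[["F1_R2"]], 900 + 2000)
})

test_that("oligo anneal sequences match the genome at their coordinates", {
    toy <- makeToyGenome()
    chr <- toy$genome[["chr1"]]
    ol <- as.data.frame(oligos(designOligos(toy$genome, toy$target)))
    for (i in seq_len(nrow(ol))) {
        region <- substr(chr, ol$annealStart[i], ol$annealEnd[i])
        anneal <- sub("^CTGGCGAAGCATATATAAGAAGCTCGTCTCGT|^GACTTGACCTGGATGTCTCTACCCACAAGATCG",
                      "", ol$sequence[i])
        if (ol$direction[i] == "rev")
            region <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(region)))
        expect_identical(anneal, region)
    }
})

test_that("designOligos errors when a flank is too short", {
    set.seed(13)
    genome <- c(chr1 = paste0(randomDNA(800),
                              "ATG", randomORFBody(298), "TAA",
                              randomDNA(5000)))
    target <- geneTarget("chr1", 801L, 1700L, "+", "early")
    expect_error(designOligos(genome, target), "upstream flank too short")
})

test_that("minus-strand genes get coding-orientation oligos", {
    plus <- makeToyGenome(seed = 11L, strand = "+")
    minus <- makeToyGenome(seed = 11L, strand = "-")
    olP <- as.data.frame(oligos(designOligos(plus$genome, plus$target)))
    olM <- as.data.frame(oligos(designOligos(minus$genome, minus$target)))
    # same synthesized primer landscape is impossible (different flanks),
    # but R1_LL must still anneal across the coding-strand start codon and
    # carry the printed extension
    expect_true(startsWith(olM[olM$name == "R1_LL", "sequence"],
                           "CTGGCGAAGCATATATAAGAAGCTCGTCTCGT"))
    # F1 anneal interval sits 1 kb downstream of the gene end on the
    # forward strand (upstream in coding orientation)
    expect_equal(olM[olM$name == "F1", "annealEnd"], 4900L + 1000L)
})

test_that("applyDeletion performs exact in-frame surgery", {
    set.seed(6)
    toy <- makeToyGenome()
    bc <- generateBarcode()
    scar <- assembleBarScar(bc)
    mut <- applyDeletion(toy$genome, toy$target, scar)
    # 900-nt gene, 138-bp scar: replicon shrinks by 900 - 138 - 21 = 741
    expect_equal(nchar(mut[["chr1"]]), nchar(toy$genome[["chr1"]]) - 741L)
    # direct string surgery oracle
    chr <- toy$genome[["chr1"]]
    expected <- paste0(substr(chr, 1, 4003), substring(scarSeq(scar), 4),
                       substring(chr, 4880))
    expect_identical(mut[["chr1"]], expected)
    # spacer+barcode occurs at exactly one locus
    hits <- gregexpr(paste0(spacerSeq(defaultLinkerSet()), bc),
                     mut[["chr1"]], fixed = TRUE)[[1]]
    expect_equal(length(hits), 1L)
    expect_gt(hits[1], 0L)
})

test_that("minus-strand deletion inserts the scar in gene orientation", {
    set.seed(6)
    toy <- makeToyGenome(strand = "-")
    bc <- generateBarcode()
    scar <- assembleBarScar(bc)
    mut <- applyDeletion(toy$genome, toy$target, scar)
    expect_equal(nchar(mut[["chr1"]]), nchar(toy$genome[["chr1"]]) - 741L)
    # forward strand carries the reverse complement of the scar body
    rcIns <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substring(scarSeq(scar), 4))))
    expect_equal(length(gregexpr(rcIns, mut[["chr1"]],
                                 fixed = TRUE)[[1]]), 1L)
    expect_true(verifyInFrame(mut, toy$target)$pass)
})

test_that("verifyInFrame passes a correct deletion and reports violations", {
    set.seed(7)
    toy <- makeToyGenome()
    scar <- assembleBarScar(generateBarcode())
    mut <- applyDeletion(toy$genome, toy$target, scar)
    rep <- verifyInFrame(mut, toy$target)
    expect_true(rep$pass)
    expect_equal(rep$scarCodons, 46L)
    expect_length(rep$stopPositions, 0L)

    # a stop forced into the barcode region is caught (bypass validation
    # by string surgery on the mutant genome)
    badScar <- scarSeq(scar)
    substr(badScar, 88, 90) <- "TAA"
    bad <- mut
    bad[["chr1"]] <- sub(scarSeq(scar), badScar, bad[["chr1"]], fixed = TRUE)
    repBad <- verifyInFrame(bad, toy$target)
    expect_false(repBad$pass)
    expect_true(length(repBad$stopPositions) > 0)

    # truncating the scar by 1 nt breaks the frame
    trunc <- mut
    trunc[["chr1"]] <- sub(scarSeq(scar), substr(scarSeq(scar), 1, 137),
                           trunc[["chr1"]], fixed = TRUE)
    expect_false(verifyInFrame(trunc, toy$target)$inFrame)
})

test_that("codonFamilyUsage counts within the synonymous family", {
    expect_equal(codonFamilyUsage("CGTCGTCGT", "CGT"), 1.0)
    # Arg codons {CGT x3, AGG x1} -> AGG at 0.25
    expect_equal(codonFamilyUsage("CGTCGTCGTAGG", "AGG"), 0.25)
    expect_error(codonFamilyUsage("CGTCGT", "TAA"), "stop")
    expect_error(codonFamilyUsage("CGTCGT", "XYZ"), "not a valid codon")
    expect_error(codonFamilyUsage("CGTC", "CGT"), "divisible by 3")
    expect_error(codonFamilyUsage("AAAAAA", "CGT"), "no codon encoding")
})
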