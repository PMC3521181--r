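test_that("blockWindow places the hairpin window from the palindrome", {
    tmpl <- canonicalTag1Template()   # palindrome at 19..44
    expect_equal(blockWindow(tmpl, SimParams()), c(17L, 35L))
    expect_equal(blockWindow(tmpl, SimParams(blockLead = 0L)), c(19L, 35L))
    # non-palindromic filler after the tag: no window
    expect_null(blockWindow(paste0(ditagSequences()$tag1,
                                   "ACGGATTCAGCTTAGCATCGATTACA"),
                            SimParams()))
    # stem below the minimum does not trigger blocking
    expect_null(blockWindow(tmpl, SimParams(minStem = 28L)))
})

test_that("with blocking disabled, reads copy the template exactly", {
    tmpl <- ditagTemplates(50, seed = 2)
    reads <- simulateReads(tmpl, blockingEnabled = FALSE, seed = 3)
    expect_equal(unname(as.character(readBases(reads))),
                 unname(substr(as.character(insertSeqs(tmpl)), 1, 35)))
    expect_true(all(is.na(truthBlockStart(reads))))
})

test_that("blocked positions emit uniform random bases at the floor QV", {
    n <- 6000
    tmpl <- canonicalTag1Template()[rep(1, n)]
    p <- SimParams()
    reads <- simulateReads(tmpl, p, seed = 17)
    expect_true(all(truthBlockStart(reads) == 17L))
    truth <- as.matrix(Biostrings::subseq(insertSeqs(tmpl), 1, 35))
    acc <- colMeans(as.matrix(readBases(reads)) == truth)
    expect_true(all(acc[1:16] == 1))
    se <- sqrt(0.25 * 0.75 / n)
    expect_true(all(abs(acc[17:35] - 0.25) < 3 * se))
    qv <- readQvs(reads)
    expect_true(all(qv[, 17:35] == p@qvFloor))
    expect_true(all(qv >= p@qvFloor & qv <= p@qvMax))
    # mean profile non-increasing from the decay onset onwards
    prof <- colMeans(qv)
    expect_true(all(diff(prof[(17 - p@qvDecayStart):35]) <= 0))
})

test_that("simulation is bit-reproducible for a fixed seed", {
    tmpl <- ditagTemplates(100, seed = 9)
    r1 <- simulateReads(tmpl, seed = 21)
    r2 <- simulateReads(tmpl, seed = 21)
    r3 <- simulateReads(tmpl, seed = 22)
    f1 <- tempfile(); f2 <- tempfile()
    writeReadsFastq(r1, f1); writeReadsFastq(r2, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(readQvs(r1), readQvs(r2))
    expect_identical(beadStatus(r1), beadStatus(r2))
    expect_false(identical(as.character(readBases(r1)),
                           as.character(readBases(r3))))
})

test_that("bead failure matches the null and blocked probabilities", {
    n <- 8000
    p <- SimParams()
    reads <- simulateReads(canonicalTag1Template()[rep(1, n)], p, seed = 31)
    tab <- beadRatioTable(reads)
    gb <- tab$fracBest + tab$fracGood
    onset <- 17 - p@qvDecayStart               # decay begins at position 13
    clear <- tab$posHi < onset
    seBase <- sqrt(p@pBadBase * (1 - p@pBadBase) / n)
    expect_true(all(abs(gb[clear] - (1 - p@pBadBase)) < 3 * seBase))
    inBlock <- tab$posLo >= 17
    seBlock <- sqrt(p@pBadBlock * (1 - p@pBadBlock) / n)
    expect_true(all(abs(gb[inBlock] - (1 - p@pBadBlock)) < 3 * seBlock))
})

test_that("simulateLibrary writes FASTQ and a complete bead table", {
    out <- tempfile()
    tmpl <- ditagTemplates(40, seed = 12)
    reads <- simulateLibrary(tmpl, SimParams(), outDir = out, prefix = "run",
                             csfasta = TRUE, seed = 13)
    fq <- Biostrings::readDNAStringSet(file.path(out, "run.fastq"),
                                       format = "fastq")
    expect_equal(length(fq), 40L)
    expect_true(all(BiocGenerics::width(fq) == 35L))
    beads <- read.delim(file.path(out, "run_beads.tsv"))
    expect_equal(nrow(beads), 35L)
    expect_equal(unique(rowSums(beads[, c("nBest", "nGood", "nBad")])), 40)
    cs <- readLines(file.path(out, "run.csfasta"))
    expect_equal(length(cs), 80L)
    expect_true(all(nchar(cs[seq(2, 80, 2)]) == 36L))   # primer base + colors
    # color decoding recovers the base-space read
    expect_identical(decodeColorspace(substr(cs[2], 2, 36), substr(cs[2], 1, 1)),
                     unname(as.character(readBases(reads))[1]))
})

test_that("both strands are sequenced: Tag1- and Tag2-led reads appear", {
    tmpl <- ditagTemplates(200, jitterProbs = c(1, 0, 0), seed = 14)
    reads <- simulateReads(tmpl, blockingEnabled = FALSE, seed = 15)
    prefixes <- substr(as.character(readBases(reads)), 1, 17)
    expect_true(any(prefixes == substr(ditagSequences()$tag1, 1, 17)))
    expect_true(any(prefixes == ditagSequences()$tag2AsRead))
})

test_that("templates shorter than the read length are rejected", {
    tmpl <- ditagTemplates(2, seed = 16)
    expect_error(simulateReads(tmpl, SimParams(readLength = 70L)),
                 "at least readLength")
})
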