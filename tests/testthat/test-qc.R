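test_that("filterReads applies the rules in fixed order", {
    cleanTag <- paste0(ditagSequences()$tag1, "ACGGATTCAGCTTAGCA")
    withN <- sub("G", "N", cleanTag)
    polyA <- strrep("A", 35)
    withPrimer <- paste0("TT", ditagSequences()$m13Forward,
                         strrep("AC", 8))          # 17-bp M13F >= 15
    nAndPolyA <- paste0("N", strrep("A", 34))      # fails two rules
    res <- filterReads(c(cleanTag, withN, polyA, withPrimer, nAndPolyA),
                       QcConfig())
    expect_equal(as.character(res$reason),
                 c("pass", "has_n", "homopolymer", "primer", "has_n"))
    expect_equal(res$keep, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("homopolymer rule is a run-length threshold", {
    base <- "GGCAATGGCACCATCGCTAC"
    run14 <- paste0(base, strrep("T", 14))
    run15 <- paste0(base, strrep("T", 15))
    cfg <- QcConfig()
    expect_true(filterReads(run14, cfg)$keep)
    expect_equal(as.character(filterReads(run15, cfg)$reason), "homopolymer")
    # threshold is configurable
    expect_false(filterReads(run14, QcConfig(homopolymerMinRun = 10L))$keep)
})

test_that("runQc conserves reads, attributes reasons, and is idempotent", {
    tmpl <- ditagTemplates(60, seed = 41)
    reads <- simulateReads(tmpl, blockingEnabled = FALSE, seed = 42)
    qc <- runQc(reads)
    expect_equal(nRaw(qc$summary), 60)
    expect_equal(nQualified(qc$summary), 60)   # clean simulated reads pass

    # plant disjoint failures by editing read bases directly
    dirty <- reads
    chars <- as.matrix(readBases(dirty))
    chars[1, 5] <- "N"; chars[2, 7] <- "N"                      # 2 x has_n
    chars[3, ] <- "A"                                           # homopolymer
    chars[4, 1:17] <- strsplit(ditagSequences()$m13Forward, "")[[1]]  # primer
    planted <- methods::initialize(dirty,
        bases = Biostrings::DNAStringSet(apply(chars, 1, paste, collapse = "")))
    qc2 <- runQc(planted)
    expect_equal(nRaw(qc2$summary),
                 nQualified(qc2$summary) + sum(rejectedCounts(qc2$summary)))
    expect_equal(unname(rejectedCounts(qc2$summary)[c("has_n", "homopolymer",
                                                      "primer")]),
                 c(2, 1, 1))
    # surviving order preserved
    expect_equal(templateIds(qc2$qualified), templateIds(reads)[-(1:4)])
    # idempotence: QC of its own output changes nothing
    qc3 <- runQc(qc2$qualified)
    expect_equal(nQualified(qc3$summary), length(qc2$qualified))
    expect_identical(as.character(readBases(qc3$qualified)),
                     as.character(readBases(qc2$qualified)))
})

test_that("empty read sets give all-zero summaries", {
    reads <- simulateReads(ditagTemplates(2, seed = 1), seed = 2)[integer(0)]
    qc <- runQc(reads)
    expect_equal(nRaw(qc$summary), 0)
    expect_equal(sum(rejectedCounts(qc$summary)), 0)
})

test_that("QV cutoff masking shows the floor dichotomy", {
    n <- 300
    reads <- simulateReads(canonicalTag1Template()[rep(1, n)], seed = 43)
    blocked <- 17:35
    m8 <- applyQvCutoff(reads, 8)
    chars <- as.matrix(readBases(m8))
    expect_true(all(chars[, blocked] == "N"))     # all in-block masked at 8
    m7 <- applyQvCutoff(reads, 7)
    expect_true(all(as.matrix(readBases(m7))[, blocked] != "N"))
    m0 <- applyQvCutoff(reads, 0)
    expect_identical(as.character(readBases(m0)),
                     as.character(readBases(reads)))
    # masking never alters QVs or lengths
    expect_identical(readQvs(m8), readQvs(reads))
    expect_equal(unique(BiocGenerics::width(readBases(m8))), 35L)
})

test_that("mean-QV read rejection works as the alternative cutoff mode", {
    reads <- simulateReads(canonicalTag1Template()[rep(1, 50)], seed = 44)
    clean <- simulateReads(ditagTemplates(50, seed = 45),
                           blockingEnabled = FALSE, seed = 46)
    cfg <- QcConfig(qvCutoff = 25L, dropReads = TRUE)
    resBlocked <- filterReads(reads, cfg)     # blocked reads: mean QV ~ 18
    resClean <- filterReads(clean, cfg)       # clean reads: mean QV ~ 33
    expect_true(all(as.character(resBlocked$reason) == "qv"))
    expect_true(all(resClean$keep))
})
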