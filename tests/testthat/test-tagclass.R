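test_that("sortAndCountPrefixes sorts and conserves multiplicities", {
    reads <- c(rep(paste0(ditagSequences()$tag1, strrep("G", 17)), 3),
               paste0("AAAACCCCGGGGTTTTAC", strrep("G", 17)))
    tab <- sortAndCountPrefixes(reads, k = 18)
    expect_equal(nrow(tab), 2L)
    expect_equal(tab$prefix[1], "AAAACCCCGGGGTTTTAC")   # lexicographic order
    expect_equal(tab$count, c(1L, 3L))
    expect_equal(sum(tab$count), 4L)
    expect_equal(nrow(sortAndCountPrefixes(character(0))), 0L)
    expect_error(sortAndCountPrefixes("ACGT", k = 18), "shorter than")
})

test_that("blocked Tag1 reads share their first 16 prefix bases with Tag1", {
    reads <- simulateReads(canonicalTag1Template()[rep(1, 1000)], seed = 51)
    tab <- sortAndCountPrefixes(reads, k = 18)
    top <- tab$prefix[which.max(tab$count)]
    expect_identical(substr(top, 1, 16), substr(ditagSequences()$tag1, 1, 16))
})

test_that("classifyReads anchors at the read start with Hamming tolerance", {
    tag1 <- ditagSequences()$tag1
    tag2r <- ditagSequences()$tag2AsRead
    filler <- function(k) strrep("G", k)
    mut <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
    reads <- c(paste0(tag1, filler(17)),                 # exact tag1
               paste0(tag2r, filler(18)),                # exact tag2
               paste0(mut(tag1, 4, "T"), filler(17)),    # 1 mismatch: partial
               paste0(mut(mut(tag1, 4, "T"), 9, "A"), filler(17)),  # 2: out
               paste0("T", tag1, filler(16)))            # 5' extra base: out
    cls <- classifyReads(reads)
    expect_equal(as.character(cls),
                 c("tag1", "tag2", "tag1", "unclassified", "unclassified"))
    # exact-only mode
    cls0 <- classifyReads(reads, TagPatterns(maxMismatch = 0L))
    expect_equal(as.character(cls0),
                 c("tag1", "tag2", "unclassified", "unclassified",
                   "unclassified"))
})

test_that("random reads are essentially never tag-classified", {
    set.seed(52)
    reads <- vapply(1:500, function(i) randomDna(35), character(1))
    expect_true(all(classifyReads(reads) == "unclassified"))
})

test_that("classification recovers ground truth without blocking", {
    tmpl <- ditagTemplates(400, jitterProbs = c(1, 0, 0), seed = 53)
    reads <- simulateReads(tmpl, blockingEnabled = FALSE, seed = 54)
    expect_equal(as.character(classifyReads(reads)), trueTag(tmpl))
    # 5'-offset templates are unclassified by design (anchored matching)
    off <- ditagTemplates(300, jitterProbs = c(0, 0.5, 0.5), seed = 55)
    readsOff <- simulateReads(off, blockingEnabled = FALSE, seed = 56)
    expect_true(all(classifyReads(readsOff) == "unclassified"))
})

test_that("library statistics reproduce known-count arithmetic", {
    stats <- LibraryStats(116094828, 110694180, 44334569, 34723418)
    tab <- statsTable(stats)
    expect_equal(tab$count[5], 79057987)
    expect_equal(tab$percentage[3], 40.05)
    expect_equal(tab$percentage[4], 31.37)
    expect_equal(tab$percentage[5], 71.42)

    zero <- statsTable(LibraryStats(10, 10, 0, 0))
    expect_equal(zero$percentage[3:5], c(0, 0, 0))
    none <- statsTable(LibraryStats(10, 0, 0, 0))
    expect_true(all(is.na(none$percentage)))      # undefined, not an error
    all1 <- statsTable(LibraryStats(10, 8, 8, 0))
    expect_equal(all1$percentage[3], 100)
})

test_that("percentage parts sum to the total within rounding slack", {
    set.seed(57)
    for (i in 1:50) {
        q <- sample(1000:10^6, 1)
        t1 <- sample(0:q, 1); t2 <- sample(0:(q - t1), 1)
        tab <- statsTable(LibraryStats(q + 10, q, t1, t2))
        expect_lte(abs(tab$percentage[5] -
                       (tab$percentage[3] + tab$percentage[4])), 0.011)
    }
})

test_that("libraryStats classifies a simulated library end to end", {
    tmpl <- ditagTemplates(300, jitterProbs = c(1, 0, 0), seed = 58)
    reads <- simulateReads(tmpl, blockingEnabled = FALSE, seed = 59)
    stats <- libraryStats(350, reads)
    tab <- statsTable(stats)
    expect_equal(tab$count[1], 350)
    expect_equal(tab$count[2], 300)
    expect_equal(tab$count[5], 300)               # all reads classified
    expect_equal(tab$percentage[5], 100)
    f <- tempfile(); writeLibraryStats(stats, f)
    expect_equal(nrow(read.delim(f)), 5L)
})
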