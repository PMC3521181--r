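test_that("revComp handles the printed sequences and edge cases", {
    expect_identical(revComp("CCACGACCGCTGAGGTT"), "AACCTCAGCGGTCGTGG")
    expect_identical(revComp(""), "")
    pal <- "AGTCGGAGTCTGCGCAGACTCCGACT"
    expect_identical(revComp(pal), pal)
    expect_identical(revComp("acgt"), "ACGT")     # lowercase normalized
    expect_identical(revComp("ANT"), "ANT")       # N maps to N
    expect_error(revComp("ACXT"), "position 3")
})

test_that("revComp is an involution agreeing with an independent oracle", {
    set.seed(42)
    for (len in c(1, 2, 17, 61, 200)) {
        s <- randomDna(len, withN = TRUE)
        expect_identical(revComp(revComp(s)), s)
        expect_identical(revComp(s), rcOracle(s))
    }
})

test_that("isPalindrome follows the reverse-complement definition", {
    expect_true(isPalindrome("AGTCGGAGTCTGCGCAGACTCCGACT"))
    expect_false(isPalindrome("GGCAATGGCACCATCGCT"))   # Tag1
    expect_true(isPalindrome("AT"))
    expect_false(isPalindrome("ATA"))                  # odd length
    expect_false(isPalindrome("ANNT"))                 # N never pairs
    expect_false(isPalindrome(""))
})

test_that("scanPalindromes finds the unique maximal hit in the construct", {
    hits <- scanPalindromes(CONSTRUCT, minLen = 8)
    expect_equal(length(hits), 1L)
    expect_equal(BiocGenerics::start(hits), 19L)
    expect_equal(BiocGenerics::end(hits), 44L)
    expect_equal(BiocGenerics::width(hits), 26L)
    seq <- S4Vectors::mcols(hits)$seq
    expect_true(isPalindrome(seq))
    # maximality: one-base extension breaks the property
    expect_false(isPalindrome(substr(CONSTRUCT, 18, 45)))
})

test_that("scanPalindromes handles degenerate inputs and validates minLen", {
    expect_equal(length(scanPalindromes("AAAA", minLen = 4)), 0L)
    hit <- scanPalindromes("GAATTC", minLen = 4)
    expect_equal(as.data.frame(hit)[, c("start", "end")],
                 data.frame(start = 1L, end = 6L))
    expect_equal(length(scanPalindromes("", minLen = 4)), 0L)
    expect_error(scanPalindromes("GAATTC", minLen = 5), "even")
    expect_error(scanPalindromes("GAATTC", minLen = 2), "even integer >= 4")
})

test_that("scanPalindromes agrees with the brute-force enumerator", {
    set.seed(7)
    cases <- c(lapply(c(20, 50, 120, 200), randomDna),
               lapply(c(60, 150), randomDna, withN = TRUE),
               list(CONSTRUCT))
    for (s in cases) {
        for (minLen in c(4L, 8L)) {
            got <- as.data.frame(scanPalindromes(s, minLen))
            exp <- brutePalindromes(s, minLen)
            expect_equal(got$start, exp$start)
            expect_equal(got$end, exp$end)
            # every hit is a palindrome and maximal
            if (nrow(got)) {
                expect_true(all(isPalindrome(got$seq)))
                for (i in seq_len(nrow(got))) {
                    st <- got$start[i]; en <- got$end[i]
                    if (st > 1 && en < nchar(s))
                        expect_false(isPalindrome(substr(s, st - 1, en + 1)))
                }
            }
        }
    }
})

test_that("scanner coordinates agree with an independent library implementation", {
    set.seed(19)
    cases <- c(CONSTRUCT, "GAATTC", vapply(c(80, 160), randomDna, character(1)))
    for (s in cases) {
        got <- as.data.frame(scanPalindromes(s, minLen = 8))
        ref <- Biostrings::findPalindromes(Biostrings::DNAString(s),
                                           min.armlength = 4,
                                           max.looplength = 0)
        expect_equal(got$start, BiocGenerics::start(ref))
        expect_equal(got$end, BiocGenerics::end(ref))
    }
})

test_that("FASTA scanning emits correct BED with per-record coordinates", {
    fa <- tempfile(fileext = ".fa")
    # wrapped lines, an empty record, and two records with the same sequence
    writeLines(c(">rec1 some description",
                 substring(CONSTRUCT, c(1, 31, 61), c(30, 60, 61)),
                 ">empty", "",
                 ">rec2", CONSTRUCT), fa)
    bed <- tempfile(fileext = ".bed")
    gr <- scanFastaPalindromes(fa, minLen = 8, bedOut = bed)
    expect_equal(length(gr), 2L)
    expect_equal(as.character(GenomicRanges::seqnames(gr)), c("rec1", "rec2"))
    lines <- readLines(bed)
    expect_equal(length(lines), 2L)
    f1 <- strsplit(lines[1], "\t")[[1]]
    # 1-based [19,44] -> 0-based half-open [18,44)
    expect_equal(f1[1:6], c("rec1", "18", "44", "PAL26", "26", "."))
    f2 <- strsplit(lines[2], "\t")[[1]]
    expect_equal(f2[2:3], f1[2:3])   # identical coords, distinct names
    expect_error(scanFastaPalindromes(tempfile(), 8), "cannot read FASTA")
})
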