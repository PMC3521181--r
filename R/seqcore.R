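#' @importFrom Biostrings readDNAStringSet
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

# Normalize a DNA string to uppercase A/C/G/T/N, rejecting anything else
# with the 1-based position of the first offending character.
.checkDna <- function(x, what = "sequence") {
    if (length(x) != 1L || is.na(x))
        stop("'", what, "' must be a single non-NA character string")
    x <- toupper(x)
    bad <- regexpr("[^ACGTN]", x)
    if (bad != -1L)
        stop("invalid character '", substr(x, bad, bad), "' in ", what,
             " at position ", bad)
    x
}

.asDnaChar <- function(x, what = "sequence") {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    vapply(unname(x), .checkDna, character(1), what = what, USE.NAMES = FALSE)
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick reverse complement over the alphabet A/C/G/T/N (N maps to
#' N). The operation is an involution: applying it twice returns the input.
#'
#' @param x Character vector of DNA sequences (lowercase accepted and
#'   normalized), or a \linkS4class{DNAString}/\linkS4class{DNAStringSet}.
#'
#' @return Character vector of reverse complements (character input), or an
#'   object of the input class.
#'
#' @examples
#' revComp("CCACGACCGCTGAGGTT")   # "AACCTCAGCGGTCGTGG"
#' revComp("AGTCGGAGTCTGCGCAGACTCCGACT")  # a palindrome: returns itself
#' @export
revComp <- function(x) {
    if (is(x, "XString") || is(x, "XStringSet"))
        return(reverseComplement(x))
    x <- .asDnaChar(x)
    if (!length(x)) return(character(0))
    out <- as.character(reverseComplement(DNAStringSet(x)))
    unname(out)
}

#' Test whether sequences are perfect palindromes
#'
#' A DNA palindrome reads identically 5' to 3' on both strands, i.e. equals
#' its own reverse complement. Only non-empty, even-length sequences over
#' A/C/G/T qualify; N never pairs, so any N-containing sequence returns
#' FALSE (not an error), as does any odd-length one.
#'
#' @param x Character vector of DNA sequences, or DNAString(Set).
#' @return Logical vector.
#' @examples
#' isPalindrome("AGTCGGAGTCTGCGCAGACTCCGACT")  # TRUE (26-bp palindrome)
#' isPalindrome("GGCAATGGCACCATCGCT")          # FALSE (Tag1)
#' isPalindrome("AT")                          # TRUE
#' @export
isPalindrome <- function(x) {
    x <- .asDnaChar(x)
    if (!length(x)) return(logical(0))
    n <- nchar(x)
    ok <- n > 0L & n %% 2L == 0L & !grepl("N", x, fixed = TRUE)
    ok[ok] <- x[ok] == revComp(x[ok])
    unname(ok)
}

# Complement lookup used by the scanner; N (and anything unexpected)
# deliberately has no partner.
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Find all maximal perfect palindromes in a sequence
#'
#' Scans a sequence for every maximal, perfect (ungapped, mismatch-free,
#' zero-loop) reverse-complement palindromic substring of at least
#' \code{minLen} bases. A hit is maximal when extending it by one base on
#' both sides either breaks the palindrome property or runs off the
#' sequence. Overlapping maximal hits are all reported; windows containing
#' N are never palindromic.
#'
#' Implementation expands around each of the n-1 even centers, so each
#' center contributes at most one (maximal) hit.
#'
#' @param x A single DNA sequence (character or DNAString).
#' @param minLen Minimum hit length; must be an even integer >= 4.
#' @return An \linkS4class{IRanges} of 1-based inclusive hit coordinates,
#'   sorted by start, with metadata column \code{seq} (the hit sequence).
#' @examples
#' construct <- fullSeq(defaultConstruct())
#' scanPalindromes(construct, minLen = 8)  # one 26-bp hit at [19, 44]
#' scanPalindromes("GAATTC", minLen = 4)   # the EcoRI site, full length
#' @export
scanPalindromes <- function(x, minLen = 8L) {
    if (length(minLen) != 1L || is.na(minLen) || minLen < 4L || minLen %% 2L != 0L)
        stop("'minLen' must be a single even integer >= 4")
    x <- .asDnaChar(x, "sequence")
    n <- nchar(x)
    starts <- integer(0); ends <- integer(0)
    if (n >= minLen) {
        ch <- strsplit(x, "", fixed = TRUE)[[1L]]
        comp <- unname(.COMP[ch])          # NA for N
        for (i in seq_len(n - 1L)) {
            # expand around the center between positions i and i+1
            k <- 0L
            while (i - k >= 1L && i + 1L + k <= n &&
                   !is.na(comp[i + 1L + k]) && ch[i - k] == comp[i + 1L + k])
                k <- k + 1L
            if (2L * k >= minLen) {
                starts <- c(starts, i - k + 1L)
                ends <- c(ends, i + k)
            }
        }
    }
    o <- order(starts, ends)
    hits <- IRanges(start = starts[o], end = ends[o])
    mcols(hits)$seq <- if (length(o)) substring(x, starts[o], ends[o])
                       else character(0)
    hits
}

#' Scan a FASTA file for palindromes, optionally writing BED
#'
#' Runs [scanPalindromes()] on every record of a (possibly multi-record,
#' line-wrapped) FASTA file and returns the hits as a
#' \linkS4class{GRanges}, ordered by record then start. Coordinates follow
#' the usual conventions: 1-based inclusive in the returned object, 0-based
#' half-open in the BED file.
#'
#' @param fasta Path to a FASTA file.
#' @param minLen Minimum palindrome length (even, >= 4).
#' @param bedOut Optional path; if given, hits are written as BED6 with
#'   name \code{PAL<len>}, score = length and strand ".".
#' @return A \linkS4class{GRanges} with metadata columns \code{name} and
#'   \code{score}, invisibly when \code{bedOut} is given.
#' @export
scanFastaPalindromes <- function(fasta, minLen = 8L, bedOut = NULL) {
    recs <- tryCatch(readDNAStringSet(fasta),
                     error = function(e) stop("cannot read FASTA '", fasta,
                                              "': ", conditionMessage(e)))
    names(recs) <- sub("\\s.*$", "", names(recs))
    all <- lapply(seq_along(recs), function(i) {
        hits <- tryCatch(scanPalindromes(as.character(recs[[i]]), minLen),
                         error = function(e) stop("record '", names(recs)[i],
                                                  "': ", conditionMessage(e)))
        data.frame(rec = rep(names(recs)[i], length(hits)),
                   start = BiocGenerics::start(hits),
                   end = BiocGenerics::end(hits))
    })
    all <- do.call(rbind, all)
    if (is.null(all))
        all <- data.frame(rec = character(0), start = integer(0),
                          end = integer(0))
    gr <- GRanges(seqnames = factor(all$rec, levels = unique(names(recs))),
                  ranges = IRanges(all$start, all$end), strand = "*",
                  name = paste0("PAL", all$end - all$start + 1L),
                  score = all$end - all$start + 1L)
    if (!is.null(bedOut)) {
        rtracklayer::export(gr, bedOut, format = "BED")
        return(invisible(gr))
    }
    gr
}
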