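#' Construct tag-matching patterns
#'
#' @param tag1 5'-anchored Tag1 pattern (default: the printed 18-mer).
#' @param tag2 5'-anchored as-read Tag2 pattern (default: the reverse
#'   complement of the printed Tag2, the strand actually sequenced).
#' @param maxMismatch Hamming tolerance for a "partial" match (default 1).
#' @return A \linkS4class{TagPatterns}.
#' @examples
#' TagPatterns()
#' TagPatterns(maxMismatch = 0L)  # exact matches only
#' @export
TagPatterns <- function(tag1 = ditagSequences()$tag1,
                        tag2 = ditagSequences()$tag2AsRead,
                        maxMismatch = 1L) {
    new("TagPatterns", tag1 = .checkDna(tag1, "tag1"),
        tag2 = .checkDna(tag2, "tag2"),
        maxMismatch = as.integer(maxMismatch))
}

setMethod("show", "TagPatterns", function(object) {
    cat("TagPatterns (anchored, <=", object@maxMismatch, "mismatch):\n")
    cat("  tag1:", object@tag1, "\n  tag2:", object@tag2, "(as read)\n")
})

.readSeqs <- function(x) {
    if (is(x, "SblReadSet")) as.character(x@bases)
    else if (is(x, "XStringSet")) as.character(x)
    else vapply(x, .checkDna, character(1), what = "read", USE.NAMES = FALSE)
}

#' Sort and count leading k-mers
#'
#' First two steps of the classification procedure: extract the leading
#' \code{k} bases of every read, sort lexicographically, and count each
#' unique prefix. Counts sum to the number of reads.
#'
#' @param x Reads (\linkS4class{SblReadSet}, DNAStringSet or character).
#' @param k Prefix length (default 18).
#' @return data.frame with \code{prefix} (sorted) and \code{count}.
#' @export
sortAndCountPrefixes <- function(x, k = 18L) {
    seqs <- .readSeqs(x)
    short <- which(nchar(seqs) < k)
    if (length(short))
        stop("read(s) shorter than k = ", k, ": ",
             paste(utils::head(short, 5L), collapse = ", "))
    if (!length(seqs))
        return(data.frame(prefix = character(0), count = integer(0)))
    tab <- table(substr(seqs, 1L, k))
    out <- data.frame(prefix = names(tab), count = as.integer(tab))
    out[order(out$prefix, method = "radix"), , drop = FALSE]
}

# per-position mismatch count of anchored prefixes against one pattern
.anchoredMismatches <- function(seqs, pattern) {
    k <- nchar(pattern)
    d <- integer(length(seqs))
    for (j in seq_len(k))
        d <- d + (substr(seqs, j, j) != substr(pattern, j, j))
    d[nchar(seqs) < k] <- NA_integer_
    d
}

#' Classify reads by anchored tag match
#'
#' Aligns each read's leading bases against Tag1 (18 bp) and as-read Tag2
#' (17 bp) at zero offset -- reads carrying extra 5' bases deliberately do
#' not match -- and classifies to the tag within \code{maxMismatch}
#' Hamming mismatches. If both tags match, the smaller mismatch count
#' wins; an exact tie is left unclassified.
#'
#' @param x Reads (\linkS4class{SblReadSet}, DNAStringSet or character),
#'   each at least 18 bp.
#' @param patterns A \linkS4class{TagPatterns}.
#' @return Factor with levels \code{tag1}, \code{tag2},
#'   \code{unclassified}.
#' @examples
#' classifyReads(paste0(ditagSequences()$tag1, "ACGTACGTACGTACGTA"))
#' @export
classifyReads <- function(x, patterns = TagPatterns()) {
    seqs <- .readSeqs(x)
    if (!length(seqs))
        return(factor(character(0), levels = c("tag1", "tag2", "unclassified")))
    if (any(nchar(seqs) < 18L))
        stop("all reads must be at least 18 bp for classification")
    mm <- patterns@maxMismatch
    d1 <- .anchoredMismatches(seqs, patterns@tag1)
    d2 <- .anchoredMismatches(seqs, patterns@tag2)
    cls <- rep("unclassified", length(seqs))
    cls[d1 <= mm & (d2 > mm | d1 < d2)] <- "tag1"
    cls[d2 <= mm & (d1 > mm | d2 < d1)] <- "tag2"
    factor(cls, levels = c("tag1", "tag2", "unclassified"))
}

# half-up rounding to 2 decimals, matching the usual rendering of
# percentage tables
.pctHalfUp <- function(count, denom) {
    if (denom == 0) return(NA_real_)
    floor(100 * count / denom * 100 + 0.5) / 100
}

#' Compute library statistics
#'
#' Classifies qualified reads and assembles the library-level statistics:
#' raw and qualified counts, Tag1-/Tag2-containing counts, their total,
#' and percentages relative to qualified reads (half-up rounded to two
#' decimals).
#'
#' @param rawCount Number of raw reads before QC.
#' @param qualified Qualified reads (\linkS4class{SblReadSet},
#'   DNAStringSet or character).
#' @param patterns A \linkS4class{TagPatterns}.
#' @return A \linkS4class{LibraryStats}.
#' @seealso [LibraryStats()] to build the object from known counts.
#' @export
libraryStats <- function(rawCount, qualified, patterns = TagPatterns()) {
    cls <- classifyReads(qualified, patterns)
    LibraryStats(rawReads = rawCount, qualifiedReads = length(cls),
                 tag1Reads = sum(cls == "tag1"), tag2Reads = sum(cls == "tag2"))
}

#' @rdname LibraryStats-class
#' @param rawReads,qualifiedReads,tag1Reads,tag2Reads Read counts.
#' @export
LibraryStats <- function(rawReads, qualifiedReads, tag1Reads, tag2Reads)
    new("LibraryStats", rawReads = as.numeric(rawReads),
        qualifiedReads = as.numeric(qualifiedReads),
        tag1Reads = as.numeric(tag1Reads), tag2Reads = as.numeric(tag2Reads))

#' @describeIn LibraryStats-class render the statistics table: one row per
#'   quantity with count and percentage (of qualified reads; \code{NA} when
#'   no qualified reads).
#' @param x A LibraryStats.
#' @export
setMethod("statsTable", "LibraryStats", function(x) {
    q <- x@qualifiedReads
    total <- x@tag1Reads + x@tag2Reads
    data.frame(
        reads = c("Raw reads", "Qualified reads", "Tag1-containing reads",
                  "Tag2-containing reads",
                  "Total of Tag1/Tag2-containing reads"),
        count = c(x@rawReads, q, x@tag1Reads, x@tag2Reads, total),
        percentage = c(NA_real_, NA_real_, .pctHalfUp(x@tag1Reads, q),
                       .pctHalfUp(x@tag2Reads, q), .pctHalfUp(total, q)))
})

#' Write library statistics as TSV
#'
#' @param x A \linkS4class{LibraryStats}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeLibraryStats <- function(x, path) {
    write.table(statsTable(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    invisible(path)
}

setMethod("show", "LibraryStats", function(object) {
    tab <- statsTable(object)
    tab$percentage <- ifelse(is.na(tab$percentage), "",
                             sprintf("%.2f%%", tab$percentage))
    cat("Library statistics\n")
    print(tab, row.names = FALSE)
})
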