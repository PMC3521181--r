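# The five-primer two-base interrogation schedule of SOLiD-style
# sequencing-by-ligation: each ligation cycle reads a dinucleotide and then
# leaps three bases (period 5); successive primers are shifted by one base.
# Position 0 is the final adaptor base; reported reads cover positions
# 1..35.

.PRIMER_OFFSETS <- c(1L, 0L, 4L, 3L, 2L)

#' Dinucleotide positions interrogated by a primer at a ligation cycle
#'
#' Under the two-base schedule, primer p (start offset s_p with
#' s_1..s_5 = 1, 0, 4, 3, 2) at cycle c interrogates template positions
#' (s_p + 5(c-1), s_p + 5(c-1) + 1). Position 0 is the last adaptor base.
#'
#' @param primer Integer in 1..5.
#' @param cycle Integer cycle number (>= 1).
#' @return Integer vector of the two interrogated positions.
#' @examples
#' primerPositions(1, 2)  # (6, 7)
#' primerPositions(3, 3)  # (14, 15)
#' primerPositions(4, 3)  # (13, 14)
#' @export
primerPositions <- function(primer, cycle) {
    if (length(primer) != 1L || is.na(primer) || !primer %in% 1:5)
        stop("'primer' must be a single integer in 1..5")
    if (length(cycle) != 1L || is.na(cycle) || cycle < 1L)
        stop("'cycle' must be a single integer >= 1")
    lo <- .PRIMER_OFFSETS[primer] + 5L * (as.integer(cycle) - 1L)
    c(lo, lo + 1L)
}

#' Per-position interrogation counts of the full schedule
#'
#' Enumerates every (primer, cycle) dinucleotide and tallies how often each
#' template position is interrogated. With the standard 5 primers and 7
#' cycles the union is exactly positions 0..35, with positions 1..34
#' interrogated twice and the boundary positions 0 and 35 once (70
#' interrogations in total).
#'
#' @param nPrimers Number of primers (default 5).
#' @param nCycles Number of ligation cycles.
#' @return Named integer vector mapping position to interrogation count
#'   (empty for \code{nCycles = 0}).
#' @examples
#' cov <- coverageMap(5, 7)
#' sum(cov)                       # 70 interrogations
#' sum(as.integer(names(cov)) > 0)  # 35 template positions
#' @export
coverageMap <- function(nPrimers = 5L, nCycles = 7L) {
    if (nCycles < 0L) stop("'nCycles' must be >= 0")
    if (nPrimers < 1L || nPrimers > 5L) stop("'nPrimers' must be in 1..5")
    if (nCycles == 0L) return(integer(0))
    pos <- unlist(lapply(seq_len(nPrimers), function(p)
        unlist(lapply(seq_len(nCycles), function(cc) primerPositions(p, cc)))))
    tab <- table(pos)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
}

# 2-bit base codes; the standard rotation-invariant two-base code is the
# XOR of consecutive codes (identical pair -> 0; A/C, G/T -> 1;
# A/G, C/T -> 2; A/T, C/G -> 3).
.BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' Encode a base sequence in two-base color space
#'
#' Converts bases to the color string a ligation sequencer reports: color i
#' encodes the transition from the previous base (starting with the primer
#' base) to the current one under the standard rotation-invariant code.
#'
#' @param x DNA sequence without N (color of an N transition is undefined).
#' @param primerBase Single base preceding the first template base
#'   (default "T", the usual adaptor-terminal base).
#' @param code Optional 4x4 integer matrix overriding the standard code;
#'   rows/columns ordered A, C, G, T.
#' @return Character string over \{0, 1, 2, 3\} of the same length as
#'   \code{x}.
#' @examples
#' encodeColorspace("AAAA", primerBase = "A")  # "0000"
#' encodeColorspace("AC", primerBase = "A")    # "01"
#' @export
encodeColorspace <- function(x, primerBase = "T", code = NULL) {
    x <- .asDnaChar(x)
    if (grepl("N", x, fixed = TRUE))
        stop("sequence contains N at position ",
             regexpr("N", x, fixed = TRUE), "; color undefined")
    primerBase <- .asDnaChar(primerBase, "primerBase")
    if (nchar(primerBase) != 1L || primerBase == "N")
        stop("'primerBase' must be a single A/C/G/T base")
    ch <- strsplit(paste0(primerBase, x), "", fixed = TRUE)[[1L]]
    codes <- .BASE_CODE[ch]
    n <- length(codes) - 1L
    if (n == 0L) return("")
    cols <- if (is.null(code)) {
        bitwXor(codes[-length(codes)], codes[-1L])
    } else {
        vapply(seq_len(n), function(i)
            code[codes[i] + 1L, codes[i + 1L] + 1L], integer(1))
    }
    paste(cols, collapse = "")
}

#' Decode a color string back to bases
#'
#' Inverse of [encodeColorspace()] under the standard code: given the primer
#' base, each color determines the next base uniquely, so encoding then
#' decoding round-trips.
#'
#' @param colors Character string over \{0, 1, 2, 3\}.
#' @param primerBase Single base that preceded the first color.
#' @return Character DNA string.
#' @examples
#' decodeColorspace(encodeColorspace("GGCAAT", "T"), "T")  # "GGCAAT"
#' @export
decodeColorspace <- function(colors, primerBase = "T") {
    if (length(colors) != 1L || grepl("[^0-3]", colors))
        stop("'colors' must be a single string over 0-3")
    primerBase <- .asDnaChar(primerBase, "primerBase")
    cols <- as.integer(strsplit(colors, "", fixed = TRUE)[[1L]])
    bases <- names(.BASE_CODE)
    cur <- .BASE_CODE[primerBase]
    out <- character(length(cols))
    for (i in seq_along(cols)) {
        cur <- bitwXor(cur, cols[i])
        out[i] <- bases[cur + 1L]
    }
    paste(out, collapse = "")
}
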