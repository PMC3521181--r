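# Independent oracles and fixtures, deliberately implemented without the
# package's own primitives.

# the printed 61-bp ditag construct (Tag1 + 26-bp palindrome + Tag2)
CONSTRUCT <- "GGCAATGGCACCATCGCTAGTCGGAGTCTGCGCAGACTCCGACTCCACGACCGCTGAGGTT"

# reverse complement by character table + reversal
rcOracle <- function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
}

# O(n^3) enumeration of all maximal perfect palindromic substrings
brutePalindromes <- function(s, minLen) {
    n <- nchar(s)
    isPal <- function(sub) nchar(sub) > 0L && nchar(sub) %% 2L == 0L &&
        !grepl("N", sub, fixed = TRUE) && sub == rcOracle(sub)
    hits <- NULL
    for (st in seq_len(n)) for (en in seq(st, n)) {
        L <- en - st + 1L
        if (L %% 2L != 0L || L < minLen) next
        if (!isPal(substr(s, st, en))) next
        if (st > 1L && en < n && isPal(substr(s, st - 1L, en + 1L))) next
        hits <- rbind(hits, data.frame(start = st, end = en, width = L))
    }
    if (is.null(hits)) data.frame(start = integer(0), end = integer(0),
                                  width = integer(0)) else hits
}

randomDna <- function(n, withN = FALSE) {
    ab <- c("A", "C", "G", "T", if (withN) "N")
    probs <- if (withN) c(rep(0.2375, 4), 0.05) else rep(0.25, 4)
    paste(sample(ab, n, replace = TRUE, prob = probs), collapse = "")
}

canonicalTag1Template <- function() {
    ditagTemplates(1, jitterProbs = c(1, 0, 0), bothStrands = FALSE, seed = 1)
}
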