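#' @importFrom graphics barplot legend lines abline
NULL

#' Per-position mean quality profile
#'
#' Arithmetic mean quality value at each read position over all reads
#' (the per-base quality view a QC tool draws for a run).
#'
#' @param x An \linkS4class{SblReadSet}; must contain at least one read.
#' @param qvFloor Instrument floor QV recorded in the profile (default 7).
#' @return A \linkS4class{QvProfile}.
#' @export
perPositionQv <- function(x, qvFloor = 7L) {
    stopifnot(is(x, "SblReadSet"))
    if (length(x) == 0L) stop("cannot profile an empty read set")
    new("QvProfile", meanQv = unname(colMeans(x@qvs)),
        nReads = length(x), qvFloor = as.integer(qvFloor))
}

setMethod("show", "QvProfile", function(object) {
    cat("QvProfile over", object@nReads, "reads,",
        length(object@meanQv), "positions (floor QV",
        paste0(object@qvFloor, ")\n"))
    cat("  mean QV:", paste(round(object@meanQv, 1), collapse = " "), "\n")
})

#' Detect the floor breakpoint of a quality profile
#'
#' The smallest position p such that the mean QV is within \code{eps} of
#' the floor at p and at every later position (a suffix condition, robust
#' to the decay ramp preceding the collapse). In the default simulation of
#' the palindromic library this is position 17, a couple of bases before
#' the palindrome.
#'
#' @param profile A \linkS4class{QvProfile}.
#' @param eps Tolerance above the floor (default 0.25).
#' @return Integer position, or \code{NA} if the profile never settles at
#'   the floor.
#' @export
detectBreakpoint <- function(profile, eps = 0.25) {
    stopifnot(is(profile, "QvProfile"))
    atFloor <- profile@meanQv <= profile@qvFloor + eps
    # suffix of positions that are all at the floor
    n <- length(atFloor)
    suffixOk <- rev(cumprod(rev(atFloor))) == 1
    if (!any(suffixOk)) return(NA_integer_)
    which(suffixOk)[1L]
}

#' Good/best bead-ratio table
#'
#' Per-(primer, cycle) fractions of best, good and bad beads, annotated
#' with the interrogated template positions. The run-quality indicator is
#' the good+best fraction; its first decline marks where probe ligation
#' starts failing.
#'
#' @param x An \linkS4class{SblReadSet} or a counts data.frame from
#'   [beadStatusCounts()]. All 35 (primer, cycle) pairs of the standard
#'   5x7 schedule must be present.
#' @return data.frame with columns primer, cycle, posLo, posHi, nBeads,
#'   fracBest, fracGood, fracBad; fractions sum to 1 per row.
#' @seealso [firstDecline()]
#' @export
beadRatioTable <- function(x) {
    counts <- if (is(x, "SblReadSet")) beadStatusCounts(x) else x
    stopifnot(is.data.frame(counts))
    expected <- expand.grid(cycle = 1:7, primer = 1:5)
    have <- paste0("P", counts$primer, "C", counts$cycle)
    want <- paste0("P", expected$primer, "C", expected$cycle)
    missing <- setdiff(want, have)
    if (length(missing))
        stop("missing (primer, cycle) pairs: ", paste(missing, collapse = ", "))
    pos <- t(vapply(seq_len(nrow(counts)), function(i)
        primerPositions(counts$primer[i], counts$cycle[i]), integer(2)))
    n <- counts$nBest + counts$nGood + counts$nBad
    out <- data.frame(primer = counts$primer, cycle = counts$cycle,
                      posLo = pos[, 1L], posHi = pos[, 2L], nBeads = n,
                      fracBest = counts$nBest / n,
                      fracGood = counts$nGood / n,
                      fracBad = counts$nBad / n)
    out[order(out$primer, out$cycle), , drop = FALSE]
}

#' First decline of the good+best bead fraction
#'
#' Finds the earliest ligation cycle at which any primer's good+best
#' fraction falls below \code{threshold}, and reports the offending
#' (primer, cycle) rows of that cycle.
#'
#' @param table A bead-ratio table from [beadRatioTable()].
#' @param threshold Good+best fraction below which a pair counts as
#'   declined (default 0.9).
#' @return data.frame of the declined rows at the earliest declining
#'   cycle (zero rows if none declines).
#' @export
firstDecline <- function(table, threshold = 0.9) {
    gb <- table$fracBest + table$fracGood
    low <- gb < threshold
    if (!any(low)) return(table[0, , drop = FALSE])
    firstCycle <- min(table$cycle[low])
    table[low & table$cycle == firstCycle, , drop = FALSE]
}

#' Write a quality profile as TSV
#'
#' @param profile A \linkS4class{QvProfile}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeQvProfile <- function(profile, path) {
    stopifnot(is(profile, "QvProfile"))
    write.table(data.frame(position = seq_along(profile@meanQv),
                           mean_qv = profile@meanQv, n = profile@nReads),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Plot the per-position mean quality curve
#'
#' @param profile A \linkS4class{QvProfile}.
#' @param ... Passed to [plot()].
#' @return Invisibly, the profile.
#' @export
plotQvProfile <- function(profile, ...) {
    stopifnot(is(profile, "QvProfile"))
    plot(seq_along(profile@meanQv), profile@meanQv, type = "b", pch = 16,
         xlab = "Read position (bp)", ylab = "Mean quality value",
         ylim = c(0, max(profile@meanQv) + 2), ...)
    abline(h = profile@qvFloor, lty = 2, col = "grey40")
    invisible(profile)
}

#' Plot stacked bead-status fractions per primer and cycle
#'
#' @param table A bead-ratio table from [beadRatioTable()].
#' @param ... Passed to [barplot()].
#' @return Invisibly, the table.
#' @export
plotBeadRatios <- function(table, ...) {
    ord <- order(table$primer, table$cycle)
    m <- t(as.matrix(table[ord, c("fracGood", "fracBest", "fracBad")]))
    colnames(m) <- paste0("P", table$primer[ord], "C", table$cycle[ord])
    barplot(m, col = c("steelblue", "firebrick", "darkgreen"), las = 2,
            ylab = "Fraction of beads", ...)
    legend("topright", c("good", "best", "bad"), bty = "n",
           fill = c("steelblue", "firebrick", "darkgreen"))
    invisible(table)
}
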