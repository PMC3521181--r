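# Accessor generics. Kept minimal: one generic per user-facing slot view.

#' @export
setGeneric("fullSeq", function(x) standardGeneric("fullSeq"))
#' @export
setGeneric("tag1Seq", function(x) standardGeneric("tag1Seq"))
#' @export
setGeneric("tag2Seq", function(x) standardGeneric("tag2Seq"))
#' @export
setGeneric("palindromeSeq", function(x) standardGeneric("palindromeSeq"))

#' @export
setGeneric("insertSeqs", function(x) standardGeneric("insertSeqs"))
#' @export
setGeneric("endOffsets", function(x) standardGeneric("endOffsets"))
#' @export
setGeneric("templateOrigin", function(x) standardGeneric("templateOrigin"))
#' @export
setGeneric("trueTag", function(x) standardGeneric("trueTag"))

#' @export
setGeneric("readBases", function(x) standardGeneric("readBases"))
#' @export
setGeneric("readQvs", function(x) standardGeneric("readQvs"))
#' @export
setGeneric("beadStatus", function(x) standardGeneric("beadStatus"))
#' @export
setGeneric("templateIds", function(x) standardGeneric("templateIds"))
#' @export
setGeneric("truthBlockStart", function(x) standardGeneric("truthBlockStart"))

#' @export
setGeneric("nRaw", function(x) standardGeneric("nRaw"))
#' @export
setGeneric("nQualified", function(x) standardGeneric("nQualified"))
#' @export
setGeneric("rejectedCounts", function(x) standardGeneric("rejectedCounts"))

#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
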