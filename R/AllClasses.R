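#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end strand
#' @importFrom IRanges IRanges
NULL

#' The five gene-relative region windows
#'
#' Names of the strand-aware windows tested around every gene: the gene
#' body, three upstream tiers (0-20, 20-50, 50-100 kb from the TSS) and
#' 0-20 kb downstream of the gene end.
#' @format character vector of length 5.
#' @export
REGION_WINDOWS <- c("GENE_BODY", "UP_0_20", "UP_20_50", "UP_50_100", "DOWN_0_20")

#' Paired somatic breakends
#'
#' A set of somatic structural variants, each a pair of genomic breakends
#' with retained-side orientations and the sample (donor) they were called
#' in. Orientation follows the BEDPE breakend convention used throughout the
#' package: strand \code{"+"} means the retained (fused) segment lies at
#' coordinates at or below the breakend position on that chromosome;
#' \code{"-"} means it extends toward higher coordinates. Each breakend is
#' stored as a width-1 \linkS4class{GRanges} whose strand carries the
#' orientation.
#'
#' @slot first GRanges of first breakends (width 1, strand = orientation).
#' @slot second GRanges of mate breakends (width 1, strand = orientation).
#' @slot sampleId character vector of per-SV sample identifiers.
#' @slot svClass optional character vector of SV class labels ("" if unknown).
#'
#' @seealso [readBedpe()], [assignBreakpoints()]
#' @export
setClass("BreakendPairSet",
    representation(
        first    = "GRanges",
        second   = "GRanges",
        sampleId = "character",
        svClass  = "character"
    )
)

setValidity("BreakendPairSet", function(object) {
    n <- length(object@first)
    msg <- character()
    if (length(object@second) != n || length(object@sampleId) != n ||
        length(object@svClass) != n)
        msg <- c(msg, "slots must have equal length")
    if (n > 0L) {
        if (any(GenomicRanges::width(object@first) != 1L) ||
            any(GenomicRanges::width(object@second) != 1L))
            msg <- c(msg, "breakends must be width-1 positions")
        if (any(strand(object@first) == "*") ||
            any(strand(object@second) == "*"))
            msg <- c(msg, "breakend orientations must be '+' or '-'")
        sn1 <- S4Vectors::decode(seqnames(object@first))
        sn2 <- S4Vectors::decode(seqnames(object@second))
        same <- levels(sn1)[as.integer(sn1)] == levels(sn2)[as.integer(sn2)] &
                start(object@first) == start(object@second)
        if (any(same))
            msg <- c(msg, "the two breakends of a pair must differ")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a BreakendPairSet
#'
#' @param chrom1,pos1,orient1 first breakend: chromosome, 1-based position,
#'   retained-side orientation ("+" or "-").
#' @param chrom2,pos2,orient2 mate breakend fields.
#' @param sampleId sample identifier per SV.
#' @param svClass optional class label per SV (e.g. "DEL", "TRA").
#' @return A \linkS4class{BreakendPairSet}.
#' @examples
#' bp <- BreakendPairSet("chrA", 1000, "+", "chrB", 5000, "-", sampleId = "s1")
#' length(bp)
#' @export
BreakendPairSet <- function(chrom1, pos1, orient1, chrom2, pos2, orient2,
                            sampleId, svClass = NULL) {
    n <- length(pos1)
    if (is.null(svClass)) svClass <- rep("", n)
    new("BreakendPairSet",
        first  = GRanges(chrom1, IRanges(pos1, width = 1L), strand = orient1),
        second = GRanges(chrom2, IRanges(pos2, width = 1L), strand = orient2),
        sampleId = as.character(sampleId),
        svClass  = as.character(svClass))
}

#' @describeIn BreakendPairSet-class number of breakend pairs
#' @param x a BreakendPairSet
#' @export
setMethod("length", "BreakendPairSet", function(x) length(x@first))

#' @export
setMethod("show", "BreakendPairSet", function(object) {
    cat(class(object), "with", length(object), "breakend pairs from",
        length(unique(object@sampleId)), "samples\n")
    if (length(object) > 0L) {
        i <- seq_len(min(3L, length(object)))
        cat(paste0("  ", object@sampleId[i], ": ",
            seqnames(object@first)[i], ":", start(object@first)[i],
            "(", strand(object@first)[i], ") -- ",
            seqnames(object@second)[i], ":", start(object@second)[i],
            "(", strand(object@second)[i], ")", collapse = "\n"), "\n")
        if (length(object) > 3L) cat("  ...\n")
    }
})

#' @rdname breakendAccessors
#' @export
setGeneric("firstBreakend", function(x) standardGeneric("firstBreakend"))
#' @rdname breakendAccessors
#' @export
setGeneric("secondBreakend", function(x) standardGeneric("secondBreakend"))
#' @rdname breakendAccessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname breakendAccessors
#' @export
setGeneric("svClass", function(x) standardGeneric("svClass"))

#' Accessors for BreakendPairSet
#'
#' @param x a \linkS4class{BreakendPairSet}
#' @return \code{firstBreakend}/\code{secondBreakend} return width-1
#'   \linkS4class{GRanges} whose strand is the retained-side orientation;
#'   \code{sampleIds} and \code{svClass} return character vectors.
#' @name breakendAccessors
NULL

#' @rdname breakendAccessors
#' @export
setMethod("firstBreakend", "BreakendPairSet", function(x) x@first)
#' @rdname breakendAccessors
#' @export
setMethod("secondBreakend", "BreakendPairSet", function(x) x@second)
#' @rdname breakendAccessors
#' @export
setMethod("sampleIds", "BreakendPairSet", function(x) x@sampleId)
#' @rdname breakendAccessors
#' @export
setMethod("svClass", "BreakendPairSet", function(x) x@svClass)

#' @export
setMethod("[", "BreakendPairSet", function(x, i, j, ..., drop = TRUE) {
    new("BreakendPairSet", first = x@first[i], second = x@second[i],
        sampleId = x@sampleId[i], svClass = x@svClass[i])
})

#' Binary SV event matrix as a SummarizedExperiment
#'
#' Gene x sample indicators of "at least one SV breakpoint in the window",
#' one assay per gene-relative window (\code{GENE_BODY}, \code{UP_0_20},
#' \code{UP_20_50}, \code{UP_50_100}, \code{DOWN_0_20}). Rows carry the gene
#' ranges; \code{rowData} holds per-window SV-positive sample counts
#' (\code{n_<window>}) and testability flags (\code{testable_<window>},
#' true when the count reaches \code{min_sv_samples}, stored in
#' \code{metadata()}).
#'
#' @seealso [buildEventMatrix()], [svEvents()], [testableGenes()]
#' @export
setClass("SVEventExperiment",
    contains = "RangedSummarizedExperiment")

setValidity("SVEventExperiment", function(object) {
    msg <- character()
    nm <- SummarizedExperiment::assayNames(object)
    if (!all(REGION_WINDOWS %in% nm))
        msg <- c(msg, paste("assays must include:",
                            paste(REGION_WINDOWS, collapse = ", ")))
    for (w in intersect(REGION_WINDOWS, nm)) {
        a <- SummarizedExperiment::assay(object, w)
        if (!all(a %in% c(0L, 1L)))
            msg <- c(msg, paste0("assay '", w, "' must be binary"))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname SVEventExperiment-class
#' @param x an SVEventExperiment
#' @param window one of the five region windows
#' @return \code{svEvents} returns the binary gene x sample indicator matrix
#'   for \code{window}.
#' @export
setGeneric("svEvents", function(x, window) standardGeneric("svEvents"))

#' @rdname SVEventExperiment-class
#' @export
setMethod("svEvents", "SVEventExperiment", function(x, window) {
    window <- match.arg(window, REGION_WINDOWS)
    SummarizedExperiment::assay(x, window)
})

#' @rdname SVEventExperiment-class
#' @return \code{nSvSamples} returns the per-gene count of SV-positive
#'   samples in \code{window}; \code{testableGenes} the gene ids meeting the
#'   testability threshold there.
#' @export
setGeneric("nSvSamples", function(x, window) standardGeneric("nSvSamples"))

#' @rdname SVEventExperiment-class
#' @export
setMethod("nSvSamples", "SVEventExperiment", function(x, window) {
    window <- match.arg(window, REGION_WINDOWS)
    stats::setNames(
        SummarizedExperiment::rowData(x)[[paste0("n_", window)]],
        rownames(x))
})

#' @rdname SVEventExperiment-class
#' @export
setGeneric("testableGenes", function(x, window) standardGeneric("testableGenes"))

#' @rdname SVEventExperiment-class
#' @export
setMethod("testableGenes", "SVEventExperiment", function(x, window) {
    window <- match.arg(window, REGION_WINDOWS)
    rownames(x)[SummarizedExperiment::rowData(x)[[paste0("testable_", window)]]]
})

#' @export
setMethod("show", "SVEventExperiment", function(object) {
    cat(class(object), ":", nrow(object), "genes x", ncol(object),
        "samples;", "min_sv_samples =", metadata(object)$min_sv_samples, "\n")
    for (w in REGION_WINDOWS) {
        nt <- sum(SummarizedExperiment::rowData(object)[[paste0("testable_", w)]])
        cat(sprintf("  %-10s %5d testable genes\n", w, nt))
    }
})
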