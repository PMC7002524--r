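#' Strand-aware gene-relative analysis windows
#'
#' For each gene, the five regions tested throughout the pipeline: the gene
#' body, 0-20 kb / 20-50 kb / 50-100 kb upstream of the TSS, and 0-20 kb
#' downstream of the gene end. "Upstream" and "downstream" follow the gene's
#' strand (TSS = start for "+", end for "-"); windows are clipped at the
#' chromosome origin. Boundaries are half-open in genome coordinates, so a
#' breakpoint exactly 20 kb upstream belongs to the 20-50 kb window.
#'
#' @param genes GRanges of genes (named, stranded), e.g. from
#'   [readGeneAnnotation()].
#' @param sizes numeric vector \code{c(up1, up2, up3, down)} of window
#'   breaks in bp; defaults 20/50/100 kb upstream tiers and 20 kb
#'   downstream.
#' @return A GRanges with one range per (gene, window), metadata columns
#'   \code{gene_id} and \code{window}. Empty windows (fully clipped) are
#'   dropped.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 105000),
#'                             strand = "+", gene_id = "G1")
#' names(g) <- "G1"
#' geneWindows(g)
#' @export
geneWindows <- function(genes, sizes = c(20000, 50000, 100000, 20000)) {
    stopifnot(length(sizes) == 4L, all(diff(sizes[1:3]) > 0))
    ids <- if (!is.null(names(genes))) names(genes) else genes$gene_id
    chr <- as.character(seqnames(genes))
    st <- start(genes); en <- end(genes)
    pos <- as.character(strand(genes)) == "+"
    # 0-based anchor coordinates: TSS and gene end in half-open terms
    tss0 <- ifelse(pos, st - 1L, en)
    end0 <- ifelse(pos, en, st - 1L)
    u1 <- sizes[1L]; u2 <- sizes[2L]; u3 <- sizes[3L]; d1 <- sizes[4L]
    win0 <- function(lo, hi) { # 0-based half-open [lo, hi)
        lo <- pmax(lo, 0)
        data.frame(lo = lo, hi = hi)
    }
    mk <- list(
        GENE_BODY = win0(st - 1L, en),
        UP_0_20   = ifelse2(pos, win0(tss0 - u1, tss0), win0(tss0, tss0 + u1)),
        UP_20_50  = ifelse2(pos, win0(tss0 - u2, tss0 - u1),
                                 win0(tss0 + u1, tss0 + u2)),
        UP_50_100 = ifelse2(pos, win0(tss0 - u3, tss0 - u2),
                                 win0(tss0 + u2, tss0 + u3)),
        DOWN_0_20 = ifelse2(pos, win0(end0, end0 + d1),
                                 win0(end0 - d1, end0)))
    out <- lapply(REGION_WINDOWS, function(w) {
        b <- mk[[w]]
        keep <- b$hi > b$lo
        if (!any(keep)) return(GRanges())
        gr <- GRanges(chr[keep], IRanges(b$lo[keep] + 1L, b$hi[keep]))
        gr$gene_id <- ids[keep]
        gr$window <- w
        gr
    })
    res <- suppressWarnings(do.call(c, out))
    names(res) <- NULL
    res
}

# row-wise ifelse over two data.frames of window bounds
ifelse2 <- function(test, yes, no) {
    data.frame(lo = ifelse(test, yes$lo, no$lo),
               hi = ifelse(test, yes$hi, no$hi))
}

#' Assign SV breakends to gene windows
#'
#' Each breakend of each pair is tested independently against every gene's
#' five windows. A breakend inside the body of gene g is assigned to
#' GENE_BODY for g only -- it is excluded from g's upstream/downstream sets
#' -- but may still hit windows of other genes. Breakends on chromosomes
#' absent from the annotation are skipped with a warning.
#'
#' @param pairs a \linkS4class{BreakendPairSet}.
#' @param genes named, stranded GRanges of genes.
#' @param sizes window breaks, see [geneWindows()].
#' @return data.frame with columns \code{gene_id}, \code{window},
#'   \code{sample_id}, \code{chrom}, \code{pos} (1-based breakend base),
#'   \code{orient}, \code{pair_index}, \code{which_end}. One row per
#'   (breakend, gene, window) assignment.
#' @export
assignBreakpoints <- function(pairs, genes, sizes = c(20000, 50000, 100000, 20000)) {
    wins <- geneWindows(genes, sizes)
    b1 <- granges(firstBreakend(pairs)); b2 <- granges(secondBreakend(pairs))
    bends <- GRanges(
        c(as.character(seqnames(b1)), as.character(seqnames(b2))),
        IRanges(c(start(b1), start(b2)), width = 1L))
    n <- length(pairs)
    meta <- data.frame(
        sample_id = rep(sampleIds(pairs), 2L),
        orient = c(as.character(strand(firstBreakend(pairs))),
                   as.character(strand(secondBreakend(pairs)))),
        pair_index = rep(seq_len(n), 2L),
        which_end = rep(c(1L, 2L), each = n))
    known <- as.character(seqnames(bends)) %in% GenomeInfoDb::seqlevels(genes)
    if (!all(known)) {
        warning(sum(!known), " breakend(s) on chromosomes absent from the ",
                "annotation were skipped")
        bends <- bends[known]
        meta <- meta[known, , drop = FALSE]
    }
    hits <- GenomicRanges::findOverlaps(bends, wins, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    out <- data.frame(
        gene_id = wins$gene_id[si],
        window = wins$window[si],
        sample_id = meta$sample_id[qi],
        chrom = as.character(seqnames(bends))[qi],
        pos = start(bends)[qi],
        orient = meta$orient[qi],
        pair_index = meta$pair_index[qi],
        which_end = meta$which_end[qi],
        stringsAsFactors = FALSE)
    # exclusion rule: a breakend in the body of g contributes no UP/DOWN for g
    inbody <- paste(out$gene_id, qi)[out$window == "GENE_BODY"]
    drop <- out$window != "GENE_BODY" & paste(out$gene_id, qi) %in% inbody
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build the binary SV event matrix
#'
#' Collapses breakend-level assignments into per (gene, window, sample)
#' presence/absence indicators, with testability flags per the rule that a
#' (gene, window) needs at least \code{min_sv_samples} SV-positive samples
#' to enter the regression analyses.
#'
#' @param assignments output of [assignBreakpoints()].
#' @param genes named GRanges of genes (defines row order).
#' @param samples character vector of sample ids (defines column order), or
#'   a sample table from [readSampleTable()].
#' @param min_sv_samples testability threshold (default 3).
#' @return An \linkS4class{SVEventExperiment}.
#' @export
buildEventMatrix <- function(assignments, genes, samples, min_sv_samples = 3L) {
    if (is.data.frame(samples)) samples <- samples$sample_id
    ids <- if (!is.null(names(genes))) names(genes) else genes$gene_id
    unknown <- setdiff(unique(assignments$sample_id), samples)
    if (length(unknown))
        stop("assignments reference unknown samples: ",
             paste(utils::head(unknown, 3L), collapse = ", "))
    assays <- list()
    rd <- S4Vectors::DataFrame(row.names = ids)
    for (w in REGION_WINDOWS) {
        a <- matrix(0L, nrow = length(ids), ncol = length(samples),
                    dimnames = list(ids, samples))
        sub <- assignments[assignments$window == w, , drop = FALSE]
        if (nrow(sub) > 0L)
            a[cbind(match(sub$gene_id, ids), match(sub$sample_id, samples))] <- 1L
        assays[[w]] <- a
        rd[[paste0("n_", w)]] <- as.integer(rowSums(a))
        rd[[paste0("testable_", w)]] <- rowSums(a) >= min_sv_samples
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, rowRanges = genes,
        colData = S4Vectors::DataFrame(sample_id = samples,
                                       row.names = samples))
    SummarizedExperiment::rowData(se) <- cbind(
        SummarizedExperiment::rowData(se), rd)
    out <- methods::new("SVEventExperiment", se)
    metadata(out)$min_sv_samples <- as.integer(min_sv_samples)
    out
}

#' Does a breakend's mate orientation retain the gene side?
#'
#' For an SV breakend 0-20 kb upstream of a gene, tests whether the retained
#' (fused) side of that breakend contains the gene: for a "+" strand gene
#' the downstream (higher-coordinate, TSS-containing) sequence must be
#' retained, i.e. orientation "-"; for a "-" strand gene the mirror,
#' orientation "+". Only such "distal-side" breakpoints qualify for the
#' enhancer-translocation analyses.
#'
#' @param pairs a \linkS4class{BreakendPairSet}.
#' @param gene a single-range GRanges with strand.
#' @param which_end 1 or 2: which breakend of each pair lies near the gene.
#' @return logical vector, one per pair.
#' @export
matePointsAway <- function(pairs, gene, which_end = 1L) {
    stopifnot(length(gene) == 1L)
    near <- if (which_end == 1L) firstBreakend(pairs) else secondBreakend(pairs)
    w <- geneWindows(gene)
    up <- w[w$window == "UP_0_20"]
    ok <- GenomicRanges::countOverlaps(granges(near), up,
                                       ignore.strand = TRUE) > 0L
    if (!all(ok))
        stop("breakend(s) not in UP_0_20 of gene ",
             if (!is.null(names(gene))) names(gene) else gene$gene_id,
             ": pair ", which(!ok)[1L])
    need <- if (as.character(strand(gene)) == "+") "-" else "+"
    as.character(strand(near)) == need
}
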