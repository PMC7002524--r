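#' Enhancers upstream of an unaltered gene
#'
#' Counts enhancer elements overlapping (any bp) the strand-aware interval
#' of length \code{window} immediately upstream of the TSS, and the
#' distance from the TSS to the proximal edge of the closest overlapping
#' element.
#'
#' @param gene single-range stranded GRanges.
#' @param enhancers GRanges of enhancer elements.
#' @param window upstream span in bp (default 0.5 Mb).
#' @return list with \code{count} and \code{nearest_distance} (NA when
#'   count is 0).
#' @export
nativeEnhancerStats <- function(gene, enhancers, window = 500000) {
    stopifnot(length(gene) == 1L)
    pos <- as.character(strand(gene)) == "+"
    tss0 <- if (pos) start(gene) - 1L else end(gene) # 0-based TSS
    lo <- if (pos) max(tss0 - window, 0) else tss0
    hi <- if (pos) tss0 else tss0 + window
    if (hi <= lo) return(list(count = 0L, nearest_distance = NA_real_))
    win <- GRanges(seqnames(gene), IRanges(lo + 1L, hi))
    ov <- enhancers[suppressWarnings(GenomicRanges::countOverlaps(
        enhancers, win, ignore.strand = TRUE)) > 0L]
    if (length(ov) == 0L) return(list(count = 0L, nearest_distance = NA_real_))
    d <- if (pos) tss0 - end(ov) else start(ov) - 1L - tss0
    list(count = length(ov), nearest_distance = max(0, min(d)))
}

# retained 0.5 Mb interval adjacent to a mate breakend, per orientation:
# '+' retains coordinates <= pos, '-' retains coordinates >= pos.
.retained_window <- function(chrom, pos, orient, window) {
    pos0 <- pos - 1L # 0-based breakend base start
    if (orient == "+") {
        lo <- max(pos0 - window, 0); hi <- pos0
    } else {
        lo <- pos0; hi <- pos0 + window
    }
    if (hi <= lo) return(GRanges())
    GRanges(chrom, IRanges(lo + 1L, hi))
}

#' Enhancers juxtaposed near a gene by one rearrangement
#'
#' For an SV whose near breakend lies 0-20 kb upstream of the gene with the
#' gene-side sequence retained (see [matePointsAway()]), counts the
#' enhancer elements in the \code{window}-length interval on the retained
#' side of the mate breakend -- the enhancers the rearrangement would place
#' upstream of the gene.
#'
#' @param pairs a \linkS4class{BreakendPairSet} (qualifying SVs for one
#'   gene).
#' @param gene single-range stranded GRanges.
#' @param enhancers GRanges of enhancer elements.
#' @param window retained span in bp (default 0.5 Mb).
#' @param which_end which breakend of each pair is the near-gene one
#'   (default 1).
#' @param include_retained_native also count native enhancers retained
#'   between the near breakend and the TSS (default FALSE, matching a
#'   literal "0.5 Mb upstream of the rearrangement breakpoint" count).
#' @return integer vector of juxtaposed enhancer counts, one per pair.
#' @export
juxtaposedEnhancerCount <- function(pairs, gene, enhancers, window = 500000,
                                    which_end = 1L,
                                    include_retained_native = FALSE) {
    away <- matePointsAway(pairs, gene, which_end)
    if (!all(away))
        stop("mate orientation does not retain the gene side for pair ",
             which(!away)[1L])
    near <- if (which_end == 1L) firstBreakend(pairs) else secondBreakend(pairs)
    mate <- if (which_end == 1L) secondBreakend(pairs) else firstBreakend(pairs)
    out <- integer(length(pairs))
    for (i in seq_along(out)) {
        win <- .retained_window(as.character(seqnames(mate))[i],
                                start(mate)[i],
                                as.character(strand(mate))[i], window)
        cnt <- if (length(win)) sum(suppressWarnings(
            GenomicRanges::countOverlaps(enhancers, win,
                                         ignore.strand = TRUE)) > 0L) else 0L
        if (include_retained_native) {
            pos <- as.character(strand(gene)) == "+"
            tss0 <- if (pos) start(gene) - 1L else end(gene)
            b0 <- start(near)[i] - 1L
            lo <- min(b0, tss0); hi <- max(b0, tss0)
            if (hi > lo) {
                nat <- GRanges(seqnames(gene), IRanges(lo + 1L, hi))
                cnt <- cnt + sum(suppressWarnings(GenomicRanges::countOverlaps(
                    enhancers, nat, ignore.strand = TRUE)) > 0L)
            }
        }
        out[i] <- cnt
    }
    out
}

# distance from a mate breakend to the proximal edge of the nearest
# enhancer inside its retained window; NA if none.
.mate_nearest_distance <- function(chrom, pos, orient, enhancers, window) {
    win <- .retained_window(chrom, pos, orient, window)
    if (length(win) == 0L) return(NA_real_)
    ov <- enhancers[suppressWarnings(GenomicRanges::countOverlaps(
        enhancers, win, ignore.strand = TRUE)) > 0L]
    if (length(ov) == 0L) return(NA_real_)
    pos0 <- pos - 1L
    d <- if (orient == "+") pos0 - end(ov) else start(ov) - 1L - pos0
    max(0, min(d))
}

#' Per-breakpoint enhancer-translocation records for a cohort
#'
#' Scans every SV with a breakend 0-20 kb upstream of a gene whose mate
#' orientation retains the gene side, and records for each the juxtaposed
#' enhancer count at the mate, the native upstream count, and the native
#' and post-rearrangement nearest-enhancer distances.
#'
#' @param genes named stranded GRanges.
#' @param pairs a \linkS4class{BreakendPairSet} for the cohort.
#' @param enhancers GRanges of enhancer elements.
#' @param window enhancer span in bp (default 0.5 Mb).
#' @param include_retained_native see [juxtaposedEnhancerCount()].
#' @return data.frame with one row per qualifying (gene, breakend):
#'   \code{gene_id}, \code{sample_id}, \code{pair_index}, \code{which_end},
#'   \code{breakend_pos}, \code{tss_to_breakend}, \code{juxtaposed_count},
#'   \code{native_count}, \code{native_nearest_distance},
#'   \code{new_nearest_distance} (NA when the retained window holds no
#'   enhancer).
#' @export
hijackRecords <- function(genes, pairs, enhancers, window = 500000,
                          include_retained_native = FALSE) {
    # mates on gene-free chromosomes are expected here; only the near-gene
    # UP_0_20 assignments are consumed
    asn <- suppressWarnings(assignBreakpoints(pairs, genes))
    asn <- asn[asn$window == "UP_0_20", , drop = FALSE]
    if (nrow(asn) == 0L) return(.empty_hijack_df())
    gstrand <- stats::setNames(as.character(strand(genes)), names(genes))
    # keep only breakends whose orientation retains the gene side
    away <- asn$orient == ifelse(gstrand[asn$gene_id] == "+", "-", "+")
    asn <- asn[away, , drop = FALSE]
    if (nrow(asn) == 0L) return(.empty_hijack_df())

    f <- firstBreakend(pairs); s <- secondBreakend(pairs)
    mate_of <- function(field) ifelse(asn$which_end == 1L,
        field(s)[asn$pair_index], field(f)[asn$pair_index])
    mchrom <- mate_of(function(x) as.character(seqnames(x)))
    mpos <- mate_of(start)
    morient <- mate_of(function(x) as.character(strand(x)))
    mpos0 <- mpos - 1
    lo0 <- ifelse(morient == "+", pmax(mpos0 - window, 0), mpos0)
    hi0 <- ifelse(morient == "+", mpos0, mpos0 + window)
    nonempty <- hi0 > lo0
    wgr <- GRanges(mchrom[nonempty],
                   IRanges(lo0[nonempty] + 1, hi0[nonempty]))
    jx <- integer(nrow(asn))
    md <- rep(NA_real_, nrow(asn))
    if (length(wgr)) {
        hits <- suppressWarnings(
            GenomicRanges::findOverlaps(enhancers, wgr,
                                        ignore.strand = TRUE))
        qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
        jx[nonempty] <- tabulate(si, length(wgr))
        if (length(qi)) {
            rowi <- which(nonempty)[si]
            d <- ifelse(morient[rowi] == "+",
                        mpos0[rowi] - end(enhancers)[qi],
                        start(enhancers)[qi] - 1 - mpos0[rowi])
            d <- pmax(d, 0)
            agg <- tapply(d, rowi, min)
            md[as.integer(names(agg))] <- as.numeric(agg)
        }
    }
    # native stats once per gene
    ug <- unique(asn$gene_id)
    nat <- lapply(ug, function(g) nativeEnhancerStats(genes[g], enhancers,
                                                      window))
    names(nat) <- ug
    natc <- vapply(nat, `[[`, 0L, "count")[asn$gene_id]
    natd <- vapply(nat, `[[`, 0, "nearest_distance")[asn$gene_id]
    pos <- gstrand[asn$gene_id] == "+"
    tss0 <- ifelse(pos, start(genes)[match(asn$gene_id, names(genes))] - 1,
                   end(genes)[match(asn$gene_id, names(genes))])
    tssdist <- abs(tss0 - (asn$pos - 1))
    if (include_retained_native) {
        b0 <- asn$pos - 1
        rl0 <- pmin(b0, tss0); rh0 <- pmax(b0, tss0)
        ok <- rh0 > rl0
        if (any(ok)) {
            ngr <- GRanges(asn$chrom[ok], IRanges(rl0[ok] + 1, rh0[ok]))
            nh <- suppressWarnings(GenomicRanges::findOverlaps(
                enhancers, ngr, ignore.strand = TRUE))
            jx[ok] <- jx[ok] + tabulate(S4Vectors::subjectHits(nh),
                                        length(ngr))
        }
    }
    res <- data.frame(
        gene_id = asn$gene_id, sample_id = asn$sample_id,
        pair_index = asn$pair_index, which_end = asn$which_end,
        breakend_pos = asn$pos, tss_to_breakend = tssdist,
        juxtaposed_count = jx, native_count = natc,
        native_nearest_distance = natd,
        new_nearest_distance = tssdist + md,
        stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

.empty_hijack_df <- function() {
    data.frame(gene_id = character(), sample_id = character(),
               pair_index = integer(), which_end = integer(),
               breakend_pos = integer(), tss_to_breakend = numeric(),
               juxtaposed_count = integer(), native_count = integer(),
               native_nearest_distance = numeric(),
               new_nearest_distance = numeric(), stringsAsFactors = FALSE)
}

#' Paired t-test of juxtaposed vs native enhancer counts per gene
#'
#' For genes with at least \code{min_breakpoints} qualifying breakpoints,
#' compares the enhancers juxtaposed by each rearrangement with the count
#' for the unaltered gene (the native count is constant per gene, so this
#' equals a one-sample t-test on the differences). Positive t means the
#' SVs bring in more enhancers than the gene natively has.
#'
#' @param records output of [hijackRecords()].
#' @param min_breakpoints minimum qualifying breakpoints per gene
#'   (default 7).
#' @return data.frame per gene: \code{gene_id}, \code{n_breakpoints},
#'   \code{mean_juxtaposed}, \code{native_count}, \code{t}, \code{p},
#'   \code{direction} (+1/-1/0), \code{degenerate} flag (zero variance of
#'   differences).
#' @export
perGeneEnhancerTest <- function(records, min_breakpoints = 7L) {
    out <- lapply(split(records, records$gene_id), function(r) {
        if (nrow(r) < min_breakpoints) return(NULL)
        d <- r$juxtaposed_count - r$native_count
        if (stats::sd(d) == 0) {
            tt <- if (mean(d) == 0) 0 else NA_real_
            return(data.frame(gene_id = r$gene_id[1L],
                              n_breakpoints = nrow(r),
                              mean_juxtaposed = mean(r$juxtaposed_count),
                              native_count = r$native_count[1L],
                              t = tt, p = NA_real_,
                              direction = sign(mean(d)), degenerate = TRUE))
        }
        ht <- stats::t.test(r$juxtaposed_count, r$native_count, paired = TRUE)
        data.frame(gene_id = r$gene_id[1L], n_breakpoints = nrow(r),
                   mean_juxtaposed = mean(r$juxtaposed_count),
                   native_count = r$native_count[1L],
                   t = unname(ht$statistic), p = ht$p.value,
                   direction = sign(unname(ht$statistic)),
                   degenerate = FALSE)
    })
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(gene_id = character(), n_breakpoints = integer(),
                          mean_juxtaposed = numeric(),
                          native_count = numeric(), t = numeric(),
                          p = numeric(), direction = numeric(),
                          degenerate = logical())
    rownames(res) <- NULL
    res
}

#' Paired t-test of nearest-enhancer distance changes per gene
#'
#' Considers only rearrangements whose near breakend lies strictly between
#' the TSS and the gene's native nearest upstream enhancer, and whose
#' retained mate window contains at least one enhancer. The
#' post-rearrangement distance is (TSS to breakend) + (mate breakend to its
#' nearest retained enhancer). Negative t means the rearrangements bring
#' enhancers closer to the gene.
#'
#' @param records output of [hijackRecords()].
#' @param min_breakpoints minimum qualifying breakpoints per gene
#'   (default 5).
#' @return data.frame per gene: \code{gene_id}, \code{n_breakpoints},
#'   \code{mean_new_distance}, \code{native_nearest_distance}, \code{t},
#'   \code{p}, \code{degenerate} flag.
#' @export
nearestDistanceChange <- function(records, min_breakpoints = 5L) {
    r <- records[!is.na(records$native_nearest_distance) &
                 !is.na(records$new_nearest_distance) &
                 records$tss_to_breakend > 0 &
                 records$tss_to_breakend <
                     records$native_nearest_distance, , drop = FALSE]
    out <- lapply(split(r, r$gene_id), function(x) {
        if (nrow(x) < min_breakpoints) return(NULL)
        d <- x$new_nearest_distance - x$native_nearest_distance
        if (stats::sd(d) == 0)
            return(data.frame(gene_id = x$gene_id[1L],
                              n_breakpoints = nrow(x),
                              mean_new_distance = mean(x$new_nearest_distance),
                              native_nearest_distance =
                                  x$native_nearest_distance[1L],
                              t = if (mean(d) == 0) 0 else NA_real_,
                              p = NA_real_, degenerate = TRUE))
        ht <- stats::t.test(x$new_nearest_distance,
                            x$native_nearest_distance, paired = TRUE)
        data.frame(gene_id = x$gene_id[1L], n_breakpoints = nrow(x),
                   mean_new_distance = mean(x$new_nearest_distance),
                   native_nearest_distance = x$native_nearest_distance[1L],
                   t = unname(ht$statistic), p = ht$p.value,
                   degenerate = FALSE)
    })
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(gene_id = character(), n_breakpoints = integer(),
                          mean_new_distance = numeric(),
                          native_nearest_distance = numeric(), t = numeric(),
                          p = numeric(), degenerate = logical())
    rownames(res) <- NULL
    res
}

#' Cohort summary of per-gene enhancer-translocation tests
#'
#' @param per_gene output of [perGeneEnhancerTest()] (or
#'   [nearestDistanceChange()]).
#' @param alpha significance threshold (default 0.01).
#' @return list with the \code{t} vector (histogram-ready), \code{n_genes},
#'   \code{n_significant}, \code{n_positive}/\code{n_negative} significant
#'   counts and \code{fraction_significant}.
#' @export
cohortEnhancerSummary <- function(per_gene, alpha = 0.01) {
    if (nrow(per_gene) == 0L)
        return(list(t = numeric(), n_genes = 0L, n_significant = 0L,
                    n_positive = 0L, n_negative = 0L,
                    fraction_significant = NA_real_))
    sig <- !is.na(per_gene$p) & per_gene$p < alpha
    list(t = per_gene$t, n_genes = nrow(per_gene),
         n_significant = sum(sig),
         n_positive = sum(sig & per_gene$t > 0),
         n_negative = sum(sig & per_gene$t < 0),
         fraction_significant = mean(sig))
}
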