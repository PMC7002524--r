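suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# a small named, stranded gene set
makeGenes <- function(starts, ends = NULL, strands = "+", chrom = "chr1",
                      ids = sprintf("G%02d", seq_along(starts))) {
    if (is.null(ends)) ends <- starts  # caller widens via end(g) <-
    g <- GRanges(chrom, IRanges(starts, ends), strand = strands)
    g$gene_id <- ids
    names(g) <- ids
    g
}

# brute-force window assignment oracle, written from the window definitions
# in plain 0-based arithmetic, independent of geneWindows()/findOverlaps
bruteForceAssign <- function(pairs, genes) {
    f <- firstBreakend(pairs); s <- secondBreakend(pairs)
    bends <- data.frame(
        chrom = c(as.character(seqnames(f)), as.character(seqnames(s))),
        pos0 = c(start(f), start(s)) - 1,
        sample = rep(sampleIds(pairs), 2))
    out <- list()
    for (gi in seq_along(genes)) {
        gchrom <- as.character(seqnames(genes))[gi]
        s0 <- start(genes)[gi] - 1; e0 <- end(genes)[gi]
        pos <- as.character(strand(genes))[gi] == "+"
        tss <- if (pos) s0 else e0
        dwn <- if (pos) e0 else s0
        iv <- if (pos) list(
            GENE_BODY = c(s0, e0),
            UP_0_20   = c(tss - 20000, tss),
            UP_20_50  = c(tss - 50000, tss - 20000),
            UP_50_100 = c(tss - 100000, tss - 50000),
            DOWN_0_20 = c(dwn, dwn + 20000)
        ) else list(
            GENE_BODY = c(s0, e0),
            UP_0_20   = c(tss, tss + 20000),
            UP_20_50  = c(tss + 20000, tss + 50000),
            UP_50_100 = c(tss + 50000, tss + 100000),
            DOWN_0_20 = c(dwn - 20000, dwn)
        )
        for (bi in seq_len(nrow(bends))) {
            if (bends$chrom[bi] != gchrom) next
            p0 <- bends$pos0[bi]
            inbody <- p0 >= iv$GENE_BODY[1] && p0 < iv$GENE_BODY[2]
            for (w in names(iv)) {
                lo <- max(iv[[w]][1], 0); hi <- iv[[w]][2]
                if (p0 >= lo && p0 < hi) {
                    if (w != "GENE_BODY" && inbody) next
                    out[[length(out) + 1L]] <- data.frame(
                        gene_id = names(genes)[gi], window = w,
                        sample_id = bends$sample[bi], pos = p0 + 1)
                }
            }
        }
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(gene_id = character(), window = character(),
                          sample_id = character(), pos = integer())
    res[order(res$gene_id, res$window, res$sample_id, res$pos), ,
        drop = FALSE]
}

# normalize assignBreakpoints output for comparison with the oracle
normalizeAssign <- function(a) {
    a <- a[order(a$gene_id, a$window, a$sample_id, a$pos),
           c("gene_id", "window", "sample_id", "pos")]
    rownames(a) <- NULL
    a
}

# brute-force count of enhancers with any overlap of 0-based [lo0, hi0)
bruteForceEnhCount <- function(enhancers, chrom, lo0, hi0) {
    es0 <- start(enhancers) - 1; ee0 <- end(enhancers)
    sum(as.character(seqnames(enhancers)) == chrom & es0 < hi0 & ee0 > lo0)
}

# random breakend pair set on given chromosomes
randomPairs <- function(n, chroms, maxpos, nsamples = 20, seed = 1) {
    set.seed(seed)
    BreakendPairSet(
        chrom1 = sample(chroms, n, TRUE),
        pos1 = sample.int(maxpos, n, TRUE),
        orient1 = sample(c("+", "-"), n, TRUE),
        chrom2 = sample(chroms, n, TRUE),
        pos2 = sample.int(maxpos, n, TRUE) + maxpos,
        orient2 = sample(c("+", "-"), n, TRUE),
        sampleId = sprintf("S%03d", sample.int(nsamples, n, TRUE)))
}

# tiny cohort used across tests (cached per session)
tinyCohort <- local({
    co <- NULL
    function() {
        if (is.null(co))
            co <<- simulateCohort(simConfig(nSamples = 60, nGenes = 20,
                                            seed = 99))
        co
    }
})
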