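#' Configuration for the synthetic cohort generator
#'
#' Holds every knob of [simulateCohort()]. The defaults state a cohort in
#' the mold of a pan-cancer integration study at desk scale: 200 tumors
#' across 5 cancer types, genes laid out 2 Mb apart on simulated
#' chromosomes (so neighboring analysis windows never collide), a 2%
#' per-gene per-sample chance of a nearby breakpoint, planted driver genes
#' with 30 SV-positive samples and a 2 log2-unit expression effect, copy
#' number confounded with SV status (amplification to >= 5 copies in 30% of
#' SV-positive samples, 0.5 log2 units per copy), unit residual SD on the
#' log2 scale, enhancer elements at 40 per Mb (about 20 per 0.5 Mb window),
#' and methylation probes whose logit-beta values shift by +1 in
#' SV-positive samples for the methylation-coupled genes.
#'
#' @slot nSamples,nGenes,nCancerTypes cohort dimensions.
#' @slot driverGenes data.frame(gene_id, window, log2fc, n_sv_samples) of
#'   planted effects.
#' @slot svRate per-gene per-sample breakpoint probability for non-driver
#'   genes.
#' @slot ampGivenSV probability an SV co-occurs with amplification.
#' @slot bgAmpRate background amplification rate without SV.
#' @slot gammaCN log2 expression units per gene copy.
#' @slot noiseSd residual SD of log2 expression.
#' @slot methCoupledGenes gene ids with an SV-linked methylation shift
#'   (NA = use the driver genes).
#' @slot methDeltaLogit logit-beta shift in SV-positive samples.
#' @slot methLogitSd per-sample logit-beta SD.
#' @slot methExprSlope log2 expression change per logit-beta unit for
#'   silenced genes (negative coupling; applied to \code{silencedFraction}
#'   of genes).
#' @slot silencedFraction fraction of genes with methylation-silenced
#'   expression.
#' @slot distalFraction fraction of upstream breakends oriented so the
#'   gene side is retained (mate "points away").
#' @slot enhancerDensity enhancer elements per Mb.
#' @slot geneLength,geneSpacing,genesPerChrom,chromPad layout of the
#'   simulated genome, bp.
#' @slot seed integer seed; a fixed seed makes the output bit-identical.
#' @export
setClass("SimConfig", representation(
    nSamples = "integer", nGenes = "integer", nCancerTypes = "integer",
    driverGenes = "data.frame", svRate = "numeric", ampGivenSV = "numeric",
    bgAmpRate = "numeric", gammaCN = "numeric", noiseSd = "numeric",
    methCoupledGenes = "character", methDeltaLogit = "numeric",
    methLogitSd = "numeric", methExprSlope = "numeric",
    silencedFraction = "numeric", distalFraction = "numeric",
    enhancerDensity = "numeric", geneLength = "numeric",
    geneSpacing = "numeric", genesPerChrom = "integer", chromPad = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    pr <- c(svRate = object@svRate, ampGivenSV = object@ampGivenSV,
            bgAmpRate = object@bgAmpRate,
            silencedFraction = object@silencedFraction,
            distalFraction = object@distalFraction)
    bad <- pr < 0 | pr > 1
    if (any(bad))
        msg <- c(msg, paste0(names(pr)[bad][1L], " must be in [0, 1]"))
    if (object@nSamples < 2L || object@nGenes < 1L ||
        object@nCancerTypes < 1L)
        msg <- c(msg, "cohort dimensions must be positive")
    if (!all(is.finite(object@driverGenes$log2fc)))
        msg <- c(msg, "driver effect sizes must be finite")
    if (nrow(object@driverGenes) &&
        !all(object@driverGenes$window %in% REGION_WINDOWS))
        msg <- c(msg, "driver windows must be one of the five region windows")
    # every analysis window must fit inside the gene's slot
    if (object@chromPad < 100000 + object@geneLength ||
        object@geneSpacing < 2 * 100000 + object@geneLength)
        msg <- c(msg, paste("analysis windows do not fit the simulated",
                            "chromosome layout (increase chromPad/geneSpacing)"))
    if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nSamples,nGenes,nCancerTypes,driverGenes,svRate,ampGivenSV,bgAmpRate
#'   see slots.
#' @param gammaCN,noiseSd,methCoupledGenes,methDeltaLogit,methLogitSd see
#'   slots.
#' @param methExprSlope,silencedFraction,distalFraction,enhancerDensity see
#'   slots.
#' @param geneLength,geneSpacing,genesPerChrom,chromPad,seed see slots.
#' @return \code{simConfig} returns a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSamples = 50, nGenes = 20, seed = 7)
#' @export
simConfig <- function(nSamples = 200, nGenes = 100, nCancerTypes = 5,
                      driverGenes = NULL, svRate = 0.02, ampGivenSV = 0.3,
                      bgAmpRate = 0.01, gammaCN = 0.5, noiseSd = 1,
                      methCoupledGenes = NA_character_, methDeltaLogit = 1,
                      methLogitSd = 1, methExprSlope = 0.3,
                      silencedFraction = 0.7, distalFraction = 1,
                      enhancerDensity = 40, geneLength = 10000,
                      geneSpacing = 2e6, genesPerChrom = 50L,
                      chromPad = 1e6, seed = 1L) {
    if (identical(driverGenes, "none"))
        driverGenes <- data.frame(gene_id = character(),
                                  window = character(), log2fc = numeric(),
                                  n_sv_samples = integer(),
                                  stringsAsFactors = FALSE)
    if (is.null(driverGenes))
        driverGenes <- data.frame(
            gene_id = sprintf("G%04d", seq_len(min(3L, nGenes))),
            window = c("UP_0_20", "GENE_BODY", "UP_20_50")[
                seq_len(min(3L, nGenes))],
            log2fc = c(2, 1.5, 1)[seq_len(min(3L, nGenes))],
            n_sv_samples = 30L, stringsAsFactors = FALSE)
    new("SimConfig", nSamples = as.integer(nSamples),
        nGenes = as.integer(nGenes), nCancerTypes = as.integer(nCancerTypes),
        driverGenes = driverGenes, svRate = svRate, ampGivenSV = ampGivenSV,
        bgAmpRate = bgAmpRate, gammaCN = gammaCN, noiseSd = noiseSd,
        methCoupledGenes = methCoupledGenes,
        methDeltaLogit = methDeltaLogit, methLogitSd = methLogitSd,
        methExprSlope = methExprSlope, silencedFraction = silencedFraction,
        distalFraction = distalFraction, enhancerDensity = enhancerDensity,
        geneLength = geneLength, geneSpacing = geneSpacing,
        genesPerChrom = as.integer(genesPerChrom), chromPad = chromPad,
        seed = as.integer(seed))
}

#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes x", object@nSamples,
        "samples,", object@nCancerTypes, "cancer types,",
        nrow(object@driverGenes), "driver genes, seed", object@seed, "\n")
})

# evaluate expr under a given seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) {
        if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
}

#' Simulate a complete cohort with known ground truth
#'
#' Generates, from one seed, every input the pipeline consumes: a gene
#' annotation on simulated chromosomes, an enhancer landscape, somatic
#' breakend pairs, an expression matrix, a copy-number matrix, a sample
#' table, a methylation matrix with probe map, and a truth table recording
#' every planted effect. Log2 expression of gene g in sample s follows
#' \deqn{baseline_g + typeOffset_{type(s)} + \gamma \cdot copies_{gs} +
#'   \beta_g \cdot sv_{gs} + \epsilon,\quad \epsilon \sim N(0, noiseSd),}
#' with an additional negative methylation coupling for the silenced gene
#' fraction. Breakends are placed uniformly within each gene's designated
#' window with the mate on a separate donor chromosome; for the
#' \code{distalFraction} of upstream breakends the orientation retains the
#' gene side.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{genes} (GRanges), \code{enhancers}
#'   (GRanges), \code{svs} (\linkS4class{BreakendPairSet}), \code{sv_truth}
#'   (binary gene x sample matrix of planted events), \code{expression},
#'   \code{copy_number} (matrices), \code{samples} (data.frame),
#'   \code{methylation} (list: \code{beta}, \code{probe_map}),
#'   \code{truth} (per-gene data.frame) and \code{config}.
#' @export
simulateCohort <- function(config) {
    methods::validObject(config)
    .with_seed(config@seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
    nG <- cfg@nGenes; nS <- cfg@nSamples
    gids <- sprintf("G%04d", seq_len(nG))
    sids <- sprintf("S%04d", seq_len(nS))

    # genome layout: genesPerChrom slots of geneSpacing bp per chromosome
    slot <- (seq_len(nG) - 1L) %% cfg@genesPerChrom
    chridx <- (seq_len(nG) - 1L) %/% cfg@genesPerChrom + 1L
    chrom <- sprintf("sim%02d", chridx)
    gstart <- cfg@chromPad + slot * cfg@geneSpacing + 1
    strand <- sample(c("+", "-"), nG, replace = TRUE)
    genes <- GRanges(chrom, IRanges(gstart, gstart + cfg@geneLength - 1),
                     strand = strand)
    genes$gene_id <- gids
    names(genes) <- gids
    # the donor chromosome carries mate breakends but no genes; keep it in
    # the annotation's chromosome namespace so assignment does not warn
    GenomeInfoDb::seqlevels(genes) <- c(GenomeInfoDb::seqlevels(genes),
                                        "simDonor")
    chromLen <- cfg@chromPad * 2 + cfg@genesPerChrom * cfg@geneSpacing
    donorLen <- chromLen

    # samples
    ctypes <- sprintf("type%02d", seq_len(cfg@nCancerTypes))
    samples <- data.frame(
        sample_id = sids,
        cancer_type = sample(ctypes, nS, replace = TRUE),
        stringsAsFactors = FALSE)
    rownames(samples) <- sids

    # per-gene SV parameters
    drv <- cfg@driverGenes
    missing_drv <- setdiff(drv$gene_id, gids)
    if (length(missing_drv))
        stop("driver gene ids outside the simulated gene set: ",
             paste(missing_drv, collapse = ", "))
    beta <- stats::setNames(rep(0, nG), gids)
    beta[drv$gene_id] <- drv$log2fc
    svwin <- stats::setNames(sample(REGION_WINDOWS, nG, replace = TRUE), gids)
    svwin[drv$gene_id] <- drv$window

    # binary SV events: drivers get exactly n_sv_samples positives
    sv <- matrix(stats::rbinom(nG * nS, 1L, cfg@svRate), nG, nS,
                 dimnames = list(gids, sids))
    for (i in seq_len(nrow(drv))) {
        g <- drv$gene_id[i]
        sv[g, ] <- 0L
        sv[g, sample(nS, min(drv$n_sv_samples[i], nS))] <- 1L
    }

    # breakend placement inside the designated window of each gene
    wins <- geneWindows(genes)
    key <- paste(wins$gene_id, wins$window)
    wrow <- match(paste(gids, svwin), key)
    wlo0 <- start(wins)[wrow] - 1; whi0 <- end(wins)[wrow]
    ev <- which(sv == 1L, arr.ind = TRUE)
    nev <- nrow(ev)
    if (nev > 0L) {
        gi <- ev[, 1L]
        pos0 <- floor(stats::runif(nev, wlo0[gi], whi0[gi]))
        pos1 <- as.integer(pos0) + 1L
        # near-breakend orientation: retain the gene side for distalFraction
        away_orient <- ifelse(strand[gi] == "+", "-", "+")
        flip <- stats::runif(nev) > cfg@distalFraction
        orient1 <- ifelse(flip, ifelse(away_orient == "+", "-", "+"),
                          away_orient)
        mate_pos <- as.integer(floor(stats::runif(
            nev, cfg@chromPad, donorLen - cfg@chromPad))) + 1L
        svs <- BreakendPairSet(
            chrom1 = chrom[gi], pos1 = pos1, orient1 = orient1,
            chrom2 = rep("simDonor", nev), pos2 = mate_pos,
            orient2 = sample(c("+", "-"), nev, replace = TRUE),
            sampleId = sids[ev[, 2L]],
            svClass = rep("TRA", nev))
    } else {
        svs <- BreakendPairSet(character(), integer(), character(),
                               character(), integer(), character(),
                               character())
    }

    # copy number: diploid background, amplification coupled to SV status
    cn <- matrix(pmax(0.5, 2 + stats::rnorm(nG * nS, 0, 0.15)), nG, nS,
                 dimnames = list(gids, sids))
    amp <- (sv == 1L & stats::runif(nG * nS) < cfg@ampGivenSV) |
           (sv == 0L & stats::runif(nG * nS) < cfg@bgAmpRate)
    cn[amp] <- 5 + stats::rexp(sum(amp), rate = 1)

    # methylation: one CpG-island probe (high variance) + one non-island
    coupled <- cfg@methCoupledGenes
    if (length(coupled) == 1L && is.na(coupled)) coupled <- drv$gene_id
    mu <- stats::rnorm(nG, 0, 1)
    lmeth <- matrix(mu, nG, nS) +
        matrix(stats::rnorm(nG * nS, 0, cfg@methLogitSd), nG, nS)
    lmeth <- lmeth + cfg@methDeltaLogit * sv * (gids %in% coupled)
    beta_island <- stats::plogis(lmeth)
    beta_other <- stats::plogis(
        matrix(mu, nG, nS) + matrix(stats::rnorm(nG * nS, 0, 0.3), nG, nS))
    probes <- c(sprintf("cg%04d_i", seq_len(nG)),
                sprintf("cg%04d_o", seq_len(nG)))
    meth_beta <- rbind(beta_island, beta_other)
    dimnames(meth_beta) <- list(probes, sids)
    probe_map <- data.frame(
        probe_id = probes,
        gene_id = rep(gids, 2L),
        cpg_island = rep(c(TRUE, FALSE), each = nG),
        stringsAsFactors = FALSE)

    # expression: additive log2 model with methylation silencing
    silenced <- stats::runif(nG) < cfg@silencedFraction
    baseline <- stats::rnorm(nG, 5, 1.5)
    toff <- stats::setNames(stats::rnorm(cfg@nCancerTypes, 0, 1), ctypes)
    z <- matrix(baseline, nG, nS) +
        matrix(toff[samples$cancer_type], nG, nS, byrow = TRUE) +
        cfg@gammaCN * cn + beta * sv +
        (-cfg@methExprSlope * silenced) * (lmeth - mu) +
        matrix(stats::rnorm(nG * nS, 0, cfg@noiseSd), nG, nS)
    expr <- pmax(2^z - 1, 0)
    dimnames(expr) <- list(gids, sids)

    # enhancer landscape across all chromosomes incl. the donor
    chroms <- c(unique(chrom), "simDonor")
    lens <- stats::setNames(rep(chromLen, length(chroms)), chroms)
    lens["simDonor"] <- donorLen
    enh <- suppressWarnings(do.call(c, lapply(chroms, function(ch) {
        k <- stats::rpois(1L, cfg@enhancerDensity * lens[ch] / 1e6)
        if (k == 0L) return(GRanges())
        s0 <- sort(as.integer(floor(stats::runif(k, 0, lens[ch] - 300))))
        GRanges(ch, IRanges(s0 + 1L, s0 + 200L))
    })))
    if (length(enh)) enh$element_id <- paste0("enh", seq_len(length(enh))) else enh$element_id <- character(0)

    truth <- data.frame(
        gene_id = gids, window = unname(svwin), beta = unname(beta),
        n_sv_samples = rowSums(sv),
        meth_coupled = gids %in% coupled,
        meth_delta = ifelse(gids %in% coupled, cfg@methDeltaLogit, 0),
        silenced = silenced, baseline = baseline,
        stringsAsFactors = FALSE)

    list(genes = genes, enhancers = enh, svs = svs, sv_truth = sv,
         expression = expr, copy_number = cn, samples = samples,
         methylation = list(beta = meth_beta, probe_map = probe_map),
         truth = truth, config = cfg)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits genes.bed, enhancers.bed, svs.bedpe, expression.tsv,
#' copy_number.tsv, samples.tsv, methylation.tsv, probe_map.tsv and
#' truth.tsv under \code{dir}; all files re-read through the package's
#' readers.
#'
#' @param cohort output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeGeneBed(cohort$genes, p("genes.bed"))
    writeEnhancerBed(cohort$enhancers, p("enhancers.bed"))
    writeBedpe(cohort$svs, p("svs.bedpe"))
    writeMatrixTSV(cohort$expression, p("expression.tsv"), "gene_id")
    writeMatrixTSV(cohort$copy_number, p("copy_number.tsv"), "gene_id")
    utils::write.table(cohort$samples, p("samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeMatrixTSV(cohort$methylation$beta, p("methylation.tsv"), "probe_id")
    utils::write.table(cohort$methylation$probe_map, p("probe_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$truth, p("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out <- c(genes = p("genes.bed"), enhancers = p("enhancers.bed"),
             svs = p("svs.bedpe"), expression = p("expression.tsv"),
             copy_number = p("copy_number.tsv"), samples = p("samples.tsv"),
             methylation = p("methylation.tsv"),
             probe_map = p("probe_map.tsv"), truth = p("truth.tsv"))
    invisible(out)
}

#' Plant an enhancer-hijack locus with exact enhancer counts
#'
#' Builds a single gene, an enhancer landscape with exactly
#' \code{k_enhancers_native} elements in the 0.5 Mb upstream of the TSS and
#' exactly \code{k_enhancers_donor} in the 0.5 Mb retained window at the
#' mate breakend on a donor chromosome, plus decoy elements outside both
#' windows, and one qualifying breakend pair (near breakend 0-20 kb
#' upstream, gene side retained).
#'
#' @param gene_id id of the planted gene.
#' @param k_enhancers_native,k_enhancers_donor planted enhancer counts
#'   (>= 0).
#' @param seed integer seed.
#' @param window enhancer span in bp (default 0.5 Mb).
#' @return list with \code{gene} (GRanges), \code{enhancers} (GRanges),
#'   \code{pair} (\linkS4class{BreakendPairSet} of length 1) and
#'   \code{truth} (the planted counts).
#' @export
simulateHijackLocus <- function(gene_id = "GENE_H", k_enhancers_native = 21,
                                k_enhancers_donor = 30, seed = 1L,
                                window = 500000) {
    stopifnot(k_enhancers_native >= 0, k_enhancers_donor >= 0)
    .with_seed(seed, {
        gstart <- 2000001
        glen <- 10000
        gene <- GRanges("chrH", IRanges(gstart, gstart + glen - 1),
                        strand = "+")
        gene$gene_id <- gene_id
        names(gene) <- gene_id
        tss0 <- gstart - 1 # 0-based TSS
        place <- function(chrom, lo0, hi0, k) {
            if (k == 0L) return(GRanges())
            s0 <- as.integer(floor(stats::runif(k, lo0, hi0 - 150)))
            GRanges(chrom, IRanges(s0 + 1L, s0 + 100L))
        }
        native <- place("chrH", tss0 - window, tss0 - 150, k_enhancers_native)
        mate_pos0 <- 2000000 # donor breakend, orientation '+': retains below
        donor <- place("chrD", mate_pos0 - window, mate_pos0 - 150,
                       k_enhancers_donor)
        decoys <- suppressWarnings(
            c(place("chrH", tss0 + glen + 50000, tss0 + glen + 200000, 5L),
              place("chrH", tss0 - window - 300000,
                    tss0 - window - 1000, 5L),
              place("chrD", mate_pos0 + 10000, mate_pos0 + 200000, 5L)))
        enh <- sort(suppressWarnings(c(native, donor, decoys)))
        if (length(enh)) enh$element_id <- paste0("enh", seq_len(length(enh))) else enh$element_id <- character(0)
        near_pos0 <- tss0 - as.integer(floor(stats::runif(1, 1000, 19000)))
        pair <- BreakendPairSet("chrH", near_pos0 + 1L, "-",
                                "chrD", mate_pos0 + 1L, "+",
                                sampleId = "sim1", svClass = "TRA")
        list(gene = gene, enhancers = enh, pair = pair,
             truth = list(native = as.integer(k_enhancers_native),
                          donor = as.integer(k_enhancers_donor)))
    })
}
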