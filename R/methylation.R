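#' Logit transform of methylation beta values
#'
#' Beta values are clamped to [eps, 1 - eps] before taking
#' \code{log(beta / (1 - beta))}, so boundary values stay finite.
#'
#' @param beta numeric vector/matrix of beta values in [0, 1].
#' @param eps clamp margin (default 0.001).
#' @return logit-transformed values, same shape as input.
#' @export
logitMeth <- function(beta, eps = 0.001) {
    if (any(beta < 0 | beta > 1, na.rm = TRUE))
        stop("beta values must lie in [0, 1]")
    b <- pmin(pmax(beta, eps), 1 - eps)
    if (is.matrix(beta)) b <- matrix(b, nrow(beta), ncol(beta),
                                     dimnames = dimnames(beta))
    log(b / (1 - b))
}

#' Select one CpG-island probe per gene
#'
#' Among probes flagged as mapping to a CpG island, picks per gene the
#' probe with the highest beta-value variance across samples; ties break on
#' the lexicographically smaller probe id. Genes with no eligible probe are
#' omitted.
#'
#' @param beta probes x samples beta matrix.
#' @param probe_map data.frame with \code{probe_id}, \code{gene_id},
#'   \code{cpg_island} (logical or 0/1).
#' @return named character vector: gene_id -> probe_id.
#' @export
selectProbePerGene <- function(beta, probe_map) {
    stopifnot(all(c("probe_id", "gene_id", "cpg_island") %in%
                  colnames(probe_map)))
    pm <- probe_map[as.logical(probe_map$cpg_island) &
                    probe_map$probe_id %in% rownames(beta), , drop = FALSE]
    if (nrow(pm) == 0L) return(stats::setNames(character(), character()))
    v <- apply(beta[pm$probe_id, , drop = FALSE], 1L, stats::var)
    pm <- pm[order(pm$gene_id, -v, pm$probe_id), , drop = FALSE]
    pick <- pm[!duplicated(pm$gene_id), , drop = FALSE]
    stats::setNames(pick$probe_id, pick$gene_id)
}

#' Methylation-expression and methylation-SV correlations for one gene
#'
#' Pearson correlations of logit methylation with log2 expression and with
#' the binary SV indicator, with t-statistics from
#' \code{t = r * sqrt((n - 2) / (1 - r^2))}.
#'
#' @param expr_vec raw expression values per sample.
#' @param meth_vec beta values per sample (same samples).
#' @param sv_vec optional binary SV indicator per sample; the
#'   methylation-SV correlation is only reported when at least
#'   \code{min_sv_samples} samples are SV-positive.
#' @param pseudocount for [logTransform()].
#' @param eps for [logitMeth()].
#' @param min_sv_samples testability threshold on the SV side (default 3).
#' @return one-row data.frame: \code{n}, \code{r_expr_meth},
#'   \code{t_expr_meth}, \code{r_meth_sv}, \code{t_meth_sv},
#'   \code{status} ("ok" or "degenerate" when a vector has zero variance).
#' @export
methCorrelate <- function(expr_vec, meth_vec, sv_vec = NULL,
                          pseudocount = 1, eps = 0.001,
                          min_sv_samples = 3L) {
    keep <- is.finite(expr_vec) & is.finite(meth_vec)
    if (!is.null(sv_vec)) keep <- keep & is.finite(sv_vec)
    x <- logTransform(expr_vec[keep], pseudocount)
    m <- logitMeth(meth_vec[keep], eps)
    n <- sum(keep)
    if (n < 3L) stop("need at least 3 samples with complete measurements")
    rt <- function(a, b) {
        if (stats::sd(a) == 0 || stats::sd(b) == 0)
            return(c(NA_real_, NA_real_))
        r <- stats::cor(a, b)
        c(r, r * sqrt((n - 2) / (1 - r^2)))
    }
    em <- rt(x, m)
    ms <- c(NA_real_, NA_real_)
    if (!is.null(sv_vec) && sum(sv_vec[keep]) >= min_sv_samples)
        ms <- rt(m, as.numeric(sv_vec[keep]))
    data.frame(n = n, r_expr_meth = em[1L], t_expr_meth = em[2L],
               r_meth_sv = ms[1L], t_meth_sv = ms[2L],
               status = if (anyNA(em)) "degenerate" else "ok",
               stringsAsFactors = FALSE)
}

#' Cohort-wide methylation integration
#'
#' Selects one CpG-island probe per gene, then computes per gene the
#' expression-methylation and methylation-SV correlations of
#' [methCorrelate()], using the SV events of one window (0-20 kb upstream
#' by default).
#'
#' @param beta probes x samples beta matrix.
#' @param probe_map probe annotation, see [selectProbePerGene()].
#' @param expr genes x samples expression matrix (raw scale).
#' @param events optional \linkS4class{SVEventExperiment} for the SV side.
#' @param window SV window (default \code{"UP_0_20"}).
#' @param ... passed to [methCorrelate()].
#' @return data.frame with \code{gene_id}, \code{probe_id} and the
#'   [methCorrelate()] columns, one row per gene with an eligible probe and
#'   expression data.
#' @export
correlateMethylation <- function(beta, probe_map, expr, events = NULL,
                                 window = "UP_0_20", ...) {
    sel <- selectProbePerGene(beta, probe_map)
    genes <- intersect(names(sel), rownames(expr))
    samples <- intersect(colnames(beta), colnames(expr))
    ev <- NULL
    if (!is.null(events)) {
        samples <- intersect(samples, colnames(events))
        ev <- svEvents(events, window)
    }
    rows <- lapply(genes, function(g) {
        sv <- if (!is.null(ev) && g %in% rownames(ev)) ev[g, samples] else NULL
        r <- methCorrelate(expr[g, samples], beta[sel[[g]], samples], sv, ...)
        cbind(data.frame(gene_id = g, probe_id = sel[[g]],
                         stringsAsFactors = FALSE), r)
    })
    res <- do.call(rbind, rows)
    if (is.null(res))
        res <- data.frame(gene_id = character(), probe_id = character(),
                          n = integer(), r_expr_meth = numeric(),
                          t_expr_meth = numeric(), r_meth_sv = numeric(),
                          t_meth_sv = numeric(), status = character())
    rownames(res) <- NULL
    res
}

#' Shift test of methylation-expression correlations for a gene subset
#'
#' Two-sample t-test comparing the expression-methylation correlation
#' t-statistics of a gene subset (typically the SV-over-expressed genes)
#' against the full background distribution. The subset remains part of
#' the background, mirroring how the two distributions are compared.
#'
#' @param results output of [correlateMethylation()].
#' @param oe_genes character vector of subset gene ids (must all be in
#'   \code{results}).
#' @return list with \code{t}, \code{p} (two-sided), \code{mean_subset},
#'   \code{mean_background}, \code{n_subset}, \code{n_background}.
#' @export
subsetShiftTest <- function(results, oe_genes) {
    if (!all(oe_genes %in% results$gene_id))
        stop("subset genes missing from results: ",
             paste(utils::head(setdiff(oe_genes, results$gene_id), 3L),
                   collapse = ", "))
    bg <- results$t_expr_meth[!is.na(results$t_expr_meth)]
    sub <- results$t_expr_meth[results$gene_id %in% oe_genes &
                               !is.na(results$t_expr_meth)]
    if (length(sub) < 2L || length(bg) < 2L)
        stop("need at least 2 usable genes in subset and background")
    ht <- stats::t.test(sub, bg)
    list(t = unname(ht$statistic), p = ht$p.value,
         mean_subset = mean(sub), mean_background = mean(bg),
         n_subset = length(sub), n_background = length(bg))
}
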