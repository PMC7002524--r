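#' Conservative multiple-testing arithmetic for the region-window analyses
#'
#' Computes the upper bound on the number of genes that could arise by
#' chance across the tested region windows,
#' \code{bound = n_regions * alpha * n_genes}, and the corresponding global
#' FDR percentage \code{100 * bound / n_significant}.
#'
#' @param n_regions number of region windows tested (1 for a single-window
#'   analysis, 5 for the full set).
#' @param alpha nominal p-value threshold.
#' @param n_genes number of genes tested (in at least one region for the
#'   global bound, or in the single region).
#' @param n_significant number of genes called significant.
#' @return list with \code{bound} and \code{global_fdr_percent} (NA when
#'   \code{n_significant} is 0).
#' @examples
#' multipleTestingReport(5, 0.001, 20859, 1575)   # bound 104.3, FDR ~6.6%
#' multipleTestingReport(1, 0.001, 6257, 384)     # ~6.3 expected, FDR ~1.6%
#' @export
multipleTestingReport <- function(n_regions, alpha, n_genes, n_significant) {
    stopifnot(n_regions >= 1, alpha >= 0, n_genes >= 1, n_significant >= 0)
    bound <- n_regions * alpha * n_genes
    fdr <- if (n_significant > 0) 100 * bound / n_significant else NA_real_
    list(bound = bound, global_fdr_percent = fdr)
}

#' Run the full integrative pipeline on a cohort
#'
#' Orchestrates annotate -> associate -> permute -> enhancers ->
#' methylation -> report over in-memory cohort objects (typically from
#' [simulateCohort()] or assembled from the package readers), optionally
#' writing the stage outputs as TSV/JSON under \code{out_dir}. Stages with
#' missing inputs are skipped and logged.
#'
#' @param cohort list with \code{genes}, \code{svs}, \code{expression},
#'   \code{samples}, and optionally \code{copy_number}, \code{enhancers},
#'   \code{methylation} (list of \code{beta} + \code{probe_map}).
#' @param out_dir optional output directory for assoc.tsv,
#'   permutation.json, hijack.tsv, per_gene_enhancers.tsv, methcorr.tsv and
#'   report.json.
#' @param min_sv_samples testability threshold (default 3).
#' @param alpha nominal significance threshold (default 0.001).
#' @param n_perm permutations for the null calibration (default 1000; set
#'   0 to skip).
#' @param enhancer_window retained/upstream enhancer span (default 0.5 Mb).
#' @param min_bp_enhancer_test,min_bp_distance_test per-gene breakpoint
#'   minima for the enhancer tests (defaults 7 and 5).
#' @param seed seed for the permutation stage.
#' @return list of class \code{"svPipelineReport"} with elements
#'   \code{events}, \code{association}, \code{significant_counts} (per
#'   window x model), \code{permutation}, \code{hijack_records},
#'   \code{enhancer_tests}, \code{distance_tests}, \code{methylation},
#'   \code{ranked_genes} (Table-1-style top genes by full-model t),
#'   \code{multiple_testing} and \code{log}.
#' @export
runPipeline <- function(cohort, out_dir = NULL, min_sv_samples = 3L,
                        alpha = 0.001, n_perm = 1000,
                        enhancer_window = 500000,
                        min_bp_enhancer_test = 7L, min_bp_distance_test = 5L,
                        seed = 1L) {
    log <- character()
    note <- function(...) log <<- c(log, paste0(...))

    asn <- assignBreakpoints(cohort$svs, cohort$genes)
    note("annotate: ", nrow(asn), " breakend-window assignments from ",
         length(cohort$svs), " SVs and ", length(cohort$genes), " genes")
    events <- buildEventMatrix(asn, cohort$genes, cohort$samples,
                               min_sv_samples)
    assoc <- associateExpression(events, cohort$expression, cohort$samples,
                                 copies = cohort$copy_number)
    if (is.null(assoc)) {
        assoc <- data.frame(gene_id = character(), window = character(),
                            n_sv_samples = integer(), model = character(),
                            slope = numeric(), t = numeric(), p = numeric(),
                            df = numeric(), status = character(),
                            q = numeric())
        note("associate: no testable genes")
    } else {
        note("associate: ", length(unique(assoc$gene_id)), " genes tested; ",
             sum(assoc$status != "ok"), " gene-window-model fits flagged")
    }
    sig <- with(assoc, table(window[status == "ok" & p < alpha],
                             model[status == "ok" & p < alpha]))
    counts <- matrix(0L, length(REGION_WINDOWS), 3L,
                     dimnames = list(REGION_WINDOWS,
                                     c("SV_ONLY", "SV_TYPE", "SV_TYPE_CN")))
    if (length(sig)) counts[rownames(sig), colnames(sig)] <-
        as.integer(sig)

    perm <- NULL
    if (n_perm > 0 &&
        length(testableGenes(events, "UP_0_20")) > 0L) {
        perm <- permutationNull(events, cohort$expression, cohort$samples,
                                copies = cohort$copy_number,
                                n_perm = n_perm, alpha = alpha, seed = seed)
        note("permute: mean ", round(perm$mean, 2), " significant of ",
             perm$n_testable, " testable vs observed ", perm$observed_count)
    } else note("permute: skipped")

    hij <- etest <- dtest <- NULL
    if (!is.null(cohort$enhancers)) {
        hij <- hijackRecords(cohort$genes, cohort$svs, cohort$enhancers,
                             enhancer_window)
        etest <- perGeneEnhancerTest(hij, min_bp_enhancer_test)
        dtest <- nearestDistanceChange(hij, min_bp_distance_test)
        note("enhancers: ", nrow(hij), " qualifying breakpoints; ",
             nrow(etest), " genes in the count test, ", nrow(dtest),
             " in the distance test")
    } else note("enhancers: skipped (no enhancer input)")

    methres <- NULL
    if (!is.null(cohort$methylation)) {
        methres <- correlateMethylation(cohort$methylation$beta,
                                        cohort$methylation$probe_map,
                                        cohort$expression, events)
        note("methylation: ", nrow(methres), " gene-probe correlations")
    } else note("methylation: skipped (no methylation input)")

    full <- assoc[assoc$model == "SV_TYPE_CN" & assoc$status == "ok", ,
                  drop = FALSE]
    ranked <- full[order(full$p), c("gene_id", "window", "n_sv_samples",
                                    "slope", "t", "p", "q")]
    rownames(ranked) <- NULL

    n_any <- length(unique(assoc$gene_id))
    sig_any <- length(unique(full$gene_id[full$p < alpha]))
    mt <- if (n_any > 0)
        multipleTestingReport(length(REGION_WINDOWS), alpha, n_any,
                              sig_any) else NULL

    report <- structure(list(
        events = events, association = assoc, significant_counts = counts,
        permutation = perm, hijack_records = hij, enhancer_tests = etest,
        distance_tests = dtest, methylation = methres,
        ranked_genes = ranked, multiple_testing = mt, alpha = alpha,
        log = log), class = "svPipelineReport")

    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(assoc, file.path(out_dir, "assoc.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(perm))
            jsonlite::write_json(unclass(perm),
                                 file.path(out_dir, "permutation.json"),
                                 auto_unbox = TRUE, digits = NA)
        if (!is.null(hij))
            utils::write.table(hij, file.path(out_dir, "hijack.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(etest))
            utils::write.table(etest,
                               file.path(out_dir, "per_gene_enhancers.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(methres))
            utils::write.table(methres, file.path(out_dir, "methcorr.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(significant_counts = as.data.frame.matrix(counts),
                 multiple_testing = mt, log = log),
            file.path(out_dir, "report.json"), auto_unbox = TRUE,
            digits = NA)
    }
    report
}

#' @export
print.svPipelineReport <- function(x, ...) {
    cat("Integrative SV-expression pipeline report\n")
    cat("Significant genes per window (p <", x$alpha, "):\n")
    print(x$significant_counts)
    if (!is.null(x$permutation)) print(x$permutation)
    if (!is.null(x$enhancer_tests))
        cat("Enhancer count tests:", nrow(x$enhancer_tests), "genes\n")
    if (!is.null(x$methylation))
        cat("Methylation correlations:", nrow(x$methylation), "genes\n")
    if (nrow(x$ranked_genes))
        cat("Top gene:", x$ranked_genes$gene_id[1L], "(",
            x$ranked_genes$window[1L], ", t =",
            round(x$ranked_genes$t[1L], 2), ")\n")
    invisible(x)
}
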