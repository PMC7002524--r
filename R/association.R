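#' Log2 transform of expression values
#'
#' @param expr non-negative expression matrix or vector (FPKM-UQ-like).
#' @param pseudocount positive offset added before taking log2 (default 1).
#' @return log2(expr + pseudocount), same shape as the input.
#' @export
logTransform <- function(expr, pseudocount = 1) {
    stopifnot(pseudocount > 0)
    if (any(expr < 0, na.rm = TRUE))
        stop("expression values must be non-negative")
    log2(expr + pseudocount)
}

# Residualize y against the column space of Q (thin Q from qr);
# Q may have 0 columns.
.resid_Q <- function(y, Q) {
    if (NCOL(Q) == 0L) return(y)
    y - Q %*% crossprod(Q, y)
}

# OLS t-test of the coefficient on `x` in lm(y ~ Z + x), by residualization.
# Zq: thin Q factor of the covariate block (including intercept), rankZ its
# rank. Returns slope, t, p, df and flags.
.sv_coef_test <- function(y, x, Zq, rankZ) {
    n <- length(y)
    ry <- .resid_Q(y, Zq)
    rx <- .resid_Q(x, Zq)
    sxx <- sum(rx^2)
    df <- n - rankZ - 1L
    if (sxx < 1e-10 * max(1, sum(x^2)) || df < 1L)
        return(list(slope = NA_real_, t = NA_real_, p = NA_real_,
                    df = df, status = "non-estimable"))
    slope <- sum(rx * ry) / sxx
    sse <- sum((ry - slope * rx)^2)
    if (sse <= 1e-12 * max(1, sum(ry^2)))
        return(list(slope = slope, t = NA_real_, p = NA_real_,
                    df = df, status = "degenerate"))
    se <- sqrt(sse / df / sxx)
    tt <- slope / se
    list(slope = slope, t = tt, p = 2 * stats::pt(-abs(tt), df),
         df = df, status = "ok")
}

# Thin Q factor of cbind(1, model.matrix(~type)) style covariate blocks.
.covariate_Q <- function(n, cancer_type = NULL) {
    X <- matrix(1, n, 1L)
    if (!is.null(cancer_type)) {
        f <- as.factor(cancer_type)
        # reference level: most frequent type (inference on SV is invariant)
        f <- stats::relevel(f, ref = names(which.max(table(f))))
        if (nlevels(f) > 1L)
            X <- cbind(X, stats::model.matrix(~f)[, -1L, drop = FALSE])
    }
    qrX <- qr(X)
    list(Q = qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE], rank = qrX$rank)
}

#' Fit the three nested SV-expression models for one gene
#'
#' Ordinary least squares of log2 expression on a binary SV indicator,
#' under three model variants: SV only (\code{SV_ONLY}), SV plus cancer
#' type as a factor (\code{SV_TYPE}), and SV plus cancer type plus gene
#' copy number as a continuous covariate (\code{SV_TYPE_CN}). The reported
#' statistics are the SV coefficient (log2 expression units per event), its
#' t-statistic and two-sided p-value at residual degrees of freedom. With
#' no covariates the slope equals the difference of SV+ and SV- group
#' means. Designs in which the SV indicator is confounded with the
#' covariates are flagged \code{"non-estimable"}; zero residual variance is
#' flagged \code{"degenerate"}.
#'
#' @param y numeric vector of log2 expression values.
#' @param sv binary (0/1) SV event indicator.
#' @param cancer_type optional categorical covariate.
#' @param copies optional numeric copy-number covariate.
#' @return data.frame with one row per model variant: \code{model},
#'   \code{slope}, \code{t}, \code{p}, \code{df}, \code{status}.
#' @examples
#' fitModels(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
fitModels <- function(y, sv, cancer_type = NULL, copies = NULL) {
    n <- length(y)
    stopifnot(length(sv) == n,
              is.null(cancer_type) || length(cancer_type) == n,
              is.null(copies) || length(copies) == n)
    if (!all(sv %in% c(0, 1))) stop("sv must be a binary indicator")
    sv <- as.numeric(sv)
    q0 <- .covariate_Q(n, NULL)
    qt <- if (is.null(cancer_type)) q0 else .covariate_Q(n, cancer_type)
    res <- list(
        SV_ONLY = .sv_coef_test(y, sv, q0$Q, q0$rank),
        SV_TYPE = .sv_coef_test(y, sv, qt$Q, qt$rank))
    if (!is.null(copies)) {
        # extend the type block with the copy covariate
        rc <- .resid_Q(copies, qt$Q)
        nc <- sqrt(sum(rc^2))
        if (nc > 1e-8 * max(1, sqrt(sum(copies^2)))) {
            Q2 <- cbind(qt$Q, rc / nc); r2 <- qt$rank + 1L
        } else {
            Q2 <- qt$Q; r2 <- qt$rank
        }
        res$SV_TYPE_CN <- .sv_coef_test(y, sv, Q2, r2)
    } else {
        res$SV_TYPE_CN <- res$SV_TYPE
    }
    out <- do.call(rbind, lapply(names(res), function(m)
        data.frame(model = m, slope = res[[m]]$slope, t = res[[m]]$t,
                   p = res[[m]]$p, df = res[[m]]$df,
                   status = res[[m]]$status, stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
}

#' Genome-wide SV-expression association
#'
#' For every testable (gene, window) pair of an SV event matrix, fits the
#' three nested models of [fitModels()] and attaches Storey q-values per
#' (window, model) family.
#'
#' @param events an \linkS4class{SVEventExperiment}.
#' @param expr expression matrix (genes x samples, raw scale); only genes
#'   present in both inputs are tested.
#' @param sample_table data.frame with \code{sample_id} and
#'   \code{cancer_type} (see [readSampleTable()]).
#' @param copies optional copy-number matrix (genes x samples).
#' @param windows subset of region windows to test (default all five).
#' @param pseudocount for [logTransform()].
#' @param log_copies enter copy number as log2(copies + 1) instead of raw
#'   copies (default FALSE).
#' @return data.frame with columns \code{gene_id}, \code{window},
#'   \code{n_sv_samples}, \code{model}, \code{slope}, \code{t}, \code{p},
#'   \code{q}, \code{df}, \code{status}.
#' @export
associateExpression <- function(events, expr, sample_table, copies = NULL,
                                windows = REGION_WINDOWS, pseudocount = 1,
                                log_copies = FALSE) {
    windows <- match.arg(windows, REGION_WINDOWS, several.ok = TRUE)
    samples <- colnames(events)
    if (!all(samples %in% colnames(expr)))
        stop("expression matrix missing samples present in the event matrix")
    expr <- expr[, samples, drop = FALSE]
    if (!is.null(copies)) copies <- copies[, samples, drop = FALSE]
    ctype <- sample_table[samples, "cancer_type"]
    ly <- logTransform(expr, pseudocount)
    n <- length(samples)
    q0 <- .covariate_Q(n, NULL)
    qt <- .covariate_Q(n, ctype)
    out <- vector("list", length(windows))
    for (wi in seq_along(windows)) {
        w <- windows[wi]
        gids <- intersect(testableGenes(events, w), rownames(expr))
        if (!is.null(copies)) gids <- intersect(gids, rownames(copies))
        if (length(gids) == 0L) next
        ev <- svEvents(events, w)[gids, , drop = FALSE]
        storage.mode(ev) <- "double"
        yw <- ly[gids, , drop = FALSE]
        cn <- if (!is.null(copies)) {
            cm <- copies[gids, , drop = FALSE]
            if (log_copies) log2(cm + 1) else cm
        } else NULL
        fits <- list(
            SV_ONLY = .batch_fit(yw, ev, q0$Q, q0$rank),
            SV_TYPE = .batch_fit(yw, ev, qt$Q, qt$rank),
            SV_TYPE_CN = .batch_fit(yw, ev, qt$Q, qt$rank, cn))
        out[[wi]] <- do.call(rbind, lapply(names(fits), function(m) {
            f <- fits[[m]]
            data.frame(row.names = NULL, gene_id = gids, window = w,
                       n_sv_samples = as.integer(rowSums(ev)), model = m,
                       slope = unname(f$slope), t = unname(f$t),
                       p = unname(f$p), df = unname(f$df),
                       status = unname(f$status), stringsAsFactors = FALSE)
        }))
    }
    res <- do.call(rbind, out)
    if (is.null(res)) return(res)
    rownames(res) <- NULL
    res$q <- NA_real_
    for (w in unique(res$window)) for (m in unique(res$model)) {
        i <- which(res$window == w & res$model == m & res$status == "ok")
        if (length(i) >= 10L)
            res$q[i] <- storeyQvalues(res$p[i])$qvalues
    }
    res
}

#' Storey-Tibshirani q-values
#'
#' Estimates the proportion of true nulls pi0 by smoothing
#' \code{pi0(lambda) = mean(p > lambda) / (1 - lambda)} over a lambda grid
#' with a natural cubic spline (df = 3) and evaluating at the largest
#' lambda, clamped to (0, 1]. The q-value of p_i is the minimum over
#' \code{p_j >= p_i} of \code{pi0 * m * p_j / rank(p_j)}.
#'
#' @param p vector of p-values (at least 10).
#' @param lambda grid for the pi0 estimate (default 0.05 to 0.95 by 0.05).
#' @return list with \code{pi0} and \code{qvalues} (same order as \code{p}).
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
    if (length(p) == 0L) stop("empty p-value vector")
    if (length(p) < 10L) stop("need at least 10 p-values")
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(sp, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
    o <- order(p, decreasing = TRUE)
    qs <- pmin(1, cummin(pi0 * m * p[o] / seq(m, 1)))
    q <- numeric(m)
    q[o] <- qs
    list(pi0 = pi0, qvalues = q)
}

#' Permutation null for the SV-expression association
#'
#' Shuffles the sample labels of the whole SV event matrix (one random
#' permutation per replicate, preserving per-gene frequencies and
#' inter-gene co-occurrence) while expression and covariates stay fixed,
#' refits the full model (SV + cancer type + copy number) for every
#' testable gene in the chosen window, and counts genes significant at the
#' nominal threshold.
#'
#' @param events an \linkS4class{SVEventExperiment}.
#' @param expr expression matrix (raw scale).
#' @param sample_table sample metadata with \code{cancer_type}.
#' @param copies optional copy-number matrix.
#' @param window region window to permute (default \code{UP_0_20}).
#' @param n_perm number of permutations (default 1000).
#' @param alpha nominal p-value threshold (default 0.001).
#' @param seed integer seed; the permutation stream is private to this call.
#' @param per_gene if TRUE, shuffle each gene's events independently
#'   (sensitivity analysis; default FALSE).
#' @return list of class \code{"svPermutationNull"} with \code{counts}
#'   (per-permutation significant-gene counts), \code{mean}, \code{sd},
#'   \code{observed_count}, \code{n_testable}, \code{alpha}, \code{n_perm}.
#' @export
permutationNull <- function(events, expr, sample_table, copies = NULL,
                            window = "UP_0_20", n_perm = 1000,
                            alpha = 0.001, seed = 1L, per_gene = FALSE) {
    if (n_perm < 1L) stop("n_perm must be >= 1")
    window <- match.arg(window, REGION_WINDOWS)
    samples <- colnames(events)
    gids <- intersect(testableGenes(events, window), rownames(expr))
    if (!is.null(copies)) gids <- intersect(gids, rownames(copies))
    ev <- svEvents(events, window)[gids, samples, drop = FALSE]
    ly <- logTransform(expr[gids, samples, drop = FALSE])
    ctype <- sample_table[samples, "cancer_type"]
    cn <- if (!is.null(copies)) copies[gids, samples, drop = FALSE] else NULL
    obs <- .batch_sv_pvalues(ly, ev, ctype, cn)
    observed <- sum(obs < alpha, na.rm = TRUE)
    counts <- integer(n_perm)
    rng <- .private_rng(seed)
    for (b in seq_len(n_perm)) {
        perm <- rng$sample(length(samples))
        evp <- if (per_gene) {
            t(apply(ev, 1L, function(r) r[rng$sample(length(r))]))
        } else ev[, perm, drop = FALSE]
        pp <- .batch_sv_pvalues(ly, evp, ctype, cn)
        counts[b] <- sum(pp < alpha, na.rm = TRUE)
    }
    structure(list(counts = counts, mean = mean(counts),
                   sd = stats::sd(counts), observed_count = observed,
                   n_testable = length(gids), alpha = alpha,
                   n_perm = n_perm, window = window),
              class = "svPermutationNull")
}

#' @export
print.svPermutationNull <- function(x, ...) {
    cat("Permutation null (", x$window, "): ", x$n_perm, " permutations of ",
        x$n_testable, " testable genes at alpha = ", x$alpha, "\n",
        "  mean significant per permutation: ", round(x$mean, 2),
        " (sd ", round(x$sd, 2), ")\n",
        "  observed significant genes:      ", x$observed_count, "\n",
        sep = "")
    invisible(x)
}

# Vectorized per-gene OLS of the SV coefficient: log2 expression rows `ly`
# on event rows `ev` given the shared covariate Q factor, optionally
# extended per gene by a copy-number row of `cn`. Row-wise equivalent of
# .sv_coef_test (cross-checked in the tests).
.batch_fit <- function(ly, ev, Q, rankQ, cn = NULL) {
    n <- ncol(ly)
    ry <- ly - (ly %*% Q) %*% t(Q)
    rs <- ev - (ev %*% Q) %*% t(Q)
    df <- rep(n - rankQ - 1L, nrow(ly))
    if (!is.null(cn)) {
        rc <- cn - (cn %*% Q) %*% t(Q)
        cnorm2 <- rowSums(rc^2)
        usec <- cnorm2 > 1e-16 * pmax(1, rowSums(cn^2))
        cf <- function(rm) ifelse(usec,
            rowSums(rc * rm) / ifelse(usec, cnorm2, 1), 0)
        ry <- ry - cf(ry) * rc
        rs <- rs - cf(rs) * rc
        df <- df - as.integer(usec)
    }
    sxx <- rowSums(rs^2)
    est <- sxx > 1e-10 * pmax(1, rowSums(ev^2)) & df >= 1L
    slope <- ifelse(est, rowSums(rs * ry) / ifelse(est, sxx, 1), NA_real_)
    sse <- rowSums((ry - ifelse(is.na(slope), 0, slope) * rs)^2)
    dgn <- est & sse <= 1e-12 * pmax(1, rowSums(ry^2))
    se <- sqrt(sse / df / sxx)
    tt <- ifelse(est & !dgn, slope / se, NA_real_)
    p <- 2 * stats::pt(-abs(tt), df)
    status <- ifelse(!est, "non-estimable", ifelse(dgn, "degenerate", "ok"))
    list(slope = slope, t = tt, p = p, df = df, status = status)
}

# SV_TYPE_CN p-values only (permutation loop hot path)
.batch_sv_pvalues <- function(ly, ev, ctype, cn) {
    qt <- .covariate_Q(ncol(ly), ctype)
    .batch_fit(ly, ev, qt$Q, qt$rank, cn)$p
}

# Seed-private RNG so permutation streams never disturb the global state.
.private_rng <- function(seed) {
    env <- new.env()
    env$state <- local({
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
            globalenv()) else NULL
        set.seed(seed)
        st <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
            assign(".Random.seed", old, globalenv())
        st
    })
    list(sample = function(n) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
            globalenv()) else NULL
        assign(".Random.seed", env$state, globalenv())
        out <- sample.int(n)
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
            assign(".Random.seed", old, globalenv())
        out
    })
}

#' Alteration-class grouping of samples for one gene
#'
#' Assigns each sample to one label with precedence: amplification (copy
#' number >= \code{amp_copies}) first -- samples with both an SV breakpoint
#' and amplification go to the amplification group -- then SV windows, then
#' optional extra annotation flags, else \code{"unaltered"}. A sample with
#' breakpoints in several windows is labeled by the window whose breakend
#' lies closest to the gene (gene body distance 0, then actual bp distance
#' to the gene boundary).
#'
#' @param gene_id gene to group by.
#' @param assignments breakend assignments from [assignBreakpoints()].
#' @param genes named GRanges of genes.
#' @param copies copy-number matrix (genes x samples).
#' @param samples character vector of all sample ids.
#' @param extra_flags optional named list of logical vectors (per sample)
#'   applied, in order, after SV grouping (e.g. promoter mutation).
#' @param amp_copies amplification threshold (default 5 copies).
#' @return named character vector: sample -> group label.
#' @export
alterationGroups <- function(gene_id, assignments, genes, copies, samples,
                             extra_flags = NULL, amp_copies = 5) {
    if (is.data.frame(samples)) samples <- samples$sample_id
    lab <- stats::setNames(rep("unaltered", length(samples)), samples)
    a <- assignments[assignments$gene_id == gene_id, , drop = FALSE]
    if (nrow(a) > 0L) {
        g <- genes[gene_id]
        d <- ifelse(a$window == "GENE_BODY", 0,
                    pmin(abs(a$pos - start(g)), abs(a$pos - end(g))))
        a <- a[order(d), , drop = FALSE]
        first <- a[!duplicated(a$sample_id), , drop = FALSE]
        lab[first$sample_id] <- first$window
    }
    if (!is.null(extra_flags)) {
        for (fn in rev(names(extra_flags))) {
            fl <- extra_flags[[fn]]
            lab[samples %in% samples[fl] & lab == "unaltered"] <- fn
        }
    }
    if (gene_id %in% rownames(copies)) {
        amp <- samples[copies[gene_id, samples] >= amp_copies]
        lab[amp] <- "amplified"
    }
    lab
}

#' Mann-Whitney U tests of each alteration group against "unaltered"
#'
#' @param expr_vec named numeric vector of (raw or log) expression values,
#'   one per sample.
#' @param groups named group labels from [alterationGroups()].
#' @param reference reference group (default \code{"unaltered"}).
#' @return data.frame with \code{group}, \code{n}, \code{median},
#'   \code{p} (two-sided Mann-Whitney U vs reference), \code{low_n} flag
#'   for groups with fewer than 3 samples.
#' @export
groupTests <- function(expr_vec, groups, reference = "unaltered") {
    groups <- groups[names(expr_vec)]
    ref <- expr_vec[groups == reference]
    if (length(ref) == 0L) stop("empty reference group '", reference, "'")
    gs <- setdiff(unique(groups), reference)
    out <- lapply(gs, function(g) {
        v <- expr_vec[groups == g]
        p <- if (length(v) >= 1L)
            suppressWarnings(stats::wilcox.test(v, ref)$p.value) else NA_real_
        # fully tied comparisons degenerate to NaN: no evidence either way
        if (length(v) >= 1L && is.na(p)) p <- 1
        data.frame(group = g, n = length(v), median = stats::median(v),
                   p = p, low_n = length(v) < 3L, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(group = character(), n = integer(),
                          median = numeric(), p = numeric(),
                          low_n = logical())
    res
}
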