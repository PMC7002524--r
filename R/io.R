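#' Read a gene annotation (GTF or BED6)
#'
#' Parses gene-level records into a named \linkS4class{GRanges}. GTF input
#' (Ensembl dialect, 1-based closed coordinates) is restricted to features
#' with \code{type == "gene"}; BED6 input is taken as one gene per line with
#' the name column as gene id. Coordinates are held in standard
#' GRanges (1-based closed) form; BED's 0-based half-open intervals are
#' converted on the way in and restored on the way out by
#' [writeGeneBed()].
#'
#' @param path file to read.
#' @param format \code{"gtf"}, \code{"bed"}, or \code{"auto"} (by extension).
#' @return GRanges named by gene id, with a \code{gene_id} metadata column.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t99\t200\tGENE1\t0\t-", bed)
#' readGeneAnnotation(bed)
#' @export
readGeneAnnotation <- function(path, format = c("auto", "gtf", "bed")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
            "gtf" else "bed"
    }
    if (format == "gtf") {
        gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                       error = function(e) stop("GTF parse error in '", path,
                                                "': ", conditionMessage(e)))
        if ("type" %in% names(S4Vectors::mcols(gr)) &&
            any(gr$type == "gene"))
            gr <- gr[gr$type == "gene"]
        if (is.null(gr$gene_id))
            stop("GTF lacks gene_id attributes: ", path)
        ids <- as.character(gr$gene_id)
    } else {
        df <- tryCatch(
            utils::read.table(path, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE,
                              colClasses = c("character", "integer", "integer",
                                             "character", "character",
                                             "character")[seq_len(6)]),
            error = function(e) stop("BED parse error in '", path, "': ",
                                     conditionMessage(e)))
        if (ncol(df) < 6L)
            stop("BED gene annotation needs 6 columns (strand required): ",
                 path)
        bad <- which(df[[2]] >= df[[3]])
        if (length(bad))
            stop("BED line ", bad[1L], ": start must be < end")
        gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                      strand = df[[6]])
        ids <- df[[4]]
    }
    if (anyDuplicated(ids))
        stop("duplicate gene_id in annotation: ",
             paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
    if (any(as.character(strand(gr)) == "*"))
        stop("gene annotation must carry strand for every gene")
    gr$gene_id <- ids
    names(gr) <- ids
    gr
}

#' Write genes as BED6
#'
#' Inverse of [readGeneAnnotation()] for the BED dialect; intervals go out
#' 0-based half-open.
#'
#' @param genes GRanges with gene_id (as from [readGeneAnnotation()]).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneBed <- function(genes, path) {
    df <- data.frame(
        chrom = as.character(seqnames(genes)),
        start = start(genes) - 1L,
        end   = end(genes),
        name  = if (!is.null(genes$gene_id)) genes$gene_id else names(genes),
        score = 0L,
        strand = as.character(strand(genes)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read somatic SVs from BEDPE
#'
#' Expects 10+ tab-separated columns (chrom1, start1, end1, chrom2, start2,
#' end2, name, score, strand1, strand2); the sample id is taken from the
#' \code{name} column (or a later column via \code{sample_col}). Each
#' breakend is collapsed to the interval start (single-base breakend
#' convention); confidence intervals wider than 1 bp are ignored. Strand
#' columns are read as retained-side orientations: with the default
#' convention \code{"retained-left"}, \code{"+"} means the retained segment
#' lies at or below the breakend coordinate, \code{"-"} above it;
#' \code{"retained-right"} mirrors both strands for data sets using the
#' opposite dialect.
#'
#' @param path BEDPE file.
#' @param sample_col column index holding the sample id (default 7, the
#'   BEDPE name column).
#' @param orient_convention \code{"retained-left"} (default) or
#'   \code{"retained-right"}.
#' @return A \linkS4class{BreakendPairSet}.
#' @export
readBedpe <- function(path, sample_col = 7L,
                      orient_convention = c("retained-left", "retained-right")) {
    orient_convention <- match.arg(orient_convention)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L)
        return(BreakendPairSet(character(), integer(), character(),
                               character(), integer(), character(),
                               character()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 10L))
        stop("BEDPE line ", which(ncols < 10L)[1L],
             ": fewer than 10 columns")
    m <- do.call(rbind, fields)
    coordcols <- c(2L, 3L, 5L, 6L)
    co <- suppressWarnings(matrix(as.integer(m[, coordcols]), ncol = 4L))
    if (anyNA(co))
        stop("BEDPE line ",
             which(rowSums(is.na(co)) > 0L)[1L],
             ": non-integer coordinate")
    s1 <- m[, 9L]; s2 <- m[, 10L]
    if (!all(c(s1, s2) %in% c("+", "-")))
        stop("BEDPE strand columns must be '+' or '-'")
    if (orient_convention == "retained-right") {
        s1 <- ifelse(s1 == "+", "-", "+")
        s2 <- ifelse(s2 == "+", "-", "+")
    }
    # BEDPE is 0-based half-open; the breakend base is start+1 in 1-based
    BreakendPairSet(m[, 1L], co[, 1L] + 1L, s1,
                    m[, 4L], co[, 3L] + 1L, s2,
                    sampleId = m[, sample_col],
                    svClass = if (ncol(m) >= 11L) m[, 11L] else NULL)
}

#' Write a BreakendPairSet as BEDPE
#'
#' @param pairs a \linkS4class{BreakendPairSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBedpe <- function(pairs, path) {
    f <- firstBreakend(pairs); s <- secondBreakend(pairs)
    df <- data.frame(
        chrom1 = as.character(seqnames(f)), start1 = start(f) - 1L,
        end1 = start(f),
        chrom2 = as.character(seqnames(s)), start2 = start(s) - 1L,
        end2 = start(s),
        name = sampleIds(pairs), score = 0L,
        strand1 = as.character(strand(f)),
        strand2 = as.character(strand(s)),
        sv_class = svClass(pairs))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a genes/probes x samples TSV matrix
#'
#' First column = row ids, header = sample ids. Values are validated against
#' the declared domain: \code{"expression"} and \code{"copies"} require
#' finite values >= 0, \code{"beta"} requires values in [0, 1].
#'
#' @param path TSV file.
#' @param value_domain one of \code{"expression"}, \code{"copies"},
#'   \code{"beta"}.
#' @return numeric matrix with row and column names.
#' @export
readMatrixTSV <- function(path, value_domain = c("expression", "copies", "beta")) {
    value_domain <- match.arg(value_domain)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("matrix TSV needs row ids plus >=1 sample column")
    mat <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- as.character(df[[1L]])
    bad <- if (value_domain == "beta") {
        !is.finite(mat) | mat < 0 | mat > 1
    } else {
        !is.finite(mat) | mat < 0
    }
    if (any(bad)) {
        ij <- which(bad, arr.ind = TRUE)[1L, ]
        stop("value out of domain '", value_domain, "' at row '",
             rownames(mat)[ij[1L]], "', column '",
             colnames(mat)[ij[2L]], "': ", mat[ij[1L], ij[2L]])
    }
    mat
}

#' Write a matrix as TSV with a row-id first column
#'
#' @param mat numeric matrix with dimnames.
#' @param path output file.
#' @param id_name header of the row-id column.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(mat, path, id_name = "id") {
    df <- data.frame(rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- id_name
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read enhancer elements from BED
#'
#' @param path BED file (>=3 columns; column 4, when present, is the
#'   element id).
#' @return GRanges sorted by position, with an \code{element_id} column.
#' @export
readEnhancerBed <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(GRanges())
    gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
    gr$element_id <- if (ncol(df) >= 4L) as.character(df[[4]]) else
        paste0("enh", seq_len(nrow(df)))
    sort(gr)
}

#' Write enhancer elements as BED
#' @param enhancers GRanges with optional \code{element_id}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEnhancerBed <- function(enhancers, path) {
    df <- data.frame(as.character(seqnames(enhancers)),
                     start(enhancers) - 1L, end(enhancers),
                     if (!is.null(enhancers$element_id)) enhancers$element_id
                     else paste0("enh", seq_len(length(enhancers))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns \code{sample_id} and \code{cancer_type};
#' further columns are kept as annotation flags. When a \code{donor_id}
#' column is present and several samples share a donor, the
#' lexicographically first sample id is kept per donor (deterministic
#' stand-in for random profile selection).
#'
#' @param path TSV file.
#' @return data.frame keyed by \code{sample_id}.
#' @export
readSampleTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("sample_id", "cancer_type") %in% colnames(df)))
        stop("sample table needs sample_id and cancer_type columns")
    if ("donor_id" %in% colnames(df)) {
        df <- df[order(df$sample_id), , drop = FALSE]
        df <- df[!duplicated(df$donor_id), , drop = FALSE]
    }
    if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
    if (any(!nzchar(df$cancer_type))) stop("empty cancer_type")
    rownames(df) <- df$sample_id
    df
}
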