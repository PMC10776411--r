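#' Read a taxa-by-samples count table
#'
#' Reads a rectangular count matrix (taxon rows, sample columns) from a
#' delimited text file, or a sparse triplet file with columns
#' (taxon_id, sample_id, count). Entries must be non-negative integers.
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"tsv"}, \code{"csv"},
#'   \code{"triplet"}. With \code{"auto"} the format is inferred from the
#'   file extension (\code{.csv} is comma-separated, a 3-column header of
#'   taxon/sample/count is treated as triplet, anything else as TSV).
#' @param taxaAreRows logical; set \code{FALSE} if the rectangular file has
#'   samples as rows (the matrix is transposed after reading).
#' @return Integer matrix, taxa as rows, with unique dimnames.
#' @export
readCountTable <- function(path, format = c("auto", "tsv", "csv", "triplet"),
                           taxaAreRows = TRUE) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("count table file not found: ", path)
    if (format == "auto") {
        format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
                  else "tsv"
        hdr <- strsplit(readLines(path, n = 1L), if (format == "csv") "," else
                        "\t")[[1]]
        if (length(hdr) == 3L &&
            all(tolower(hdr) %in% c("taxon_id", "sample_id", "count")))
            format <- "triplet"
    }
    if (format == "triplet") {
        tri <- utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        if (ncol(tri) != 3L)
            stop("triplet count file must have exactly 3 columns")
        names(tri) <- c("taxon_id", "sample_id", "count")
        if (anyDuplicated(tri[, 1:2]))
            stop("duplicate (taxon, sample) pairs in triplet file")
        mat <- stats::xtabs(count ~ taxon_id + sample_id, data = tri)
        counts <- matrix(as.vector(mat), nrow = nrow(mat),
                         dimnames = list(rownames(mat), colnames(mat)))
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
                                row.names = NULL, check.names = FALSE,
                                stringsAsFactors = FALSE)
        rn <- as.character(df[[1L]])
        counts <- as.matrix(df[, -1L, drop = FALSE])
        rownames(counts) <- rn
        if (!taxaAreRows) counts <- t(counts)
    }
    validateCountTable(counts)
    storage.mode(counts) <- "integer"
    counts
}

#' Validate a count matrix
#'
#' Checks the count-table invariants: numeric, finite, non-negative integer
#' entries and unique, non-missing dimnames.
#'
#' @param counts matrix to check.
#' @return The input, invisibly, if valid; otherwise an error is thrown.
#' @export
validateCountTable <- function(counts) {
    if (!is.matrix(counts) || !is.numeric(counts))
        stop("counts must be a numeric matrix")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have taxon row names and sample column names")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate taxon labels in count table")
    if (anyDuplicated(colnames(counts)))
        stop("duplicate sample labels in count table")
    if (any(!is.finite(counts)))
        stop("counts must be finite")
    if (any(counts < 0))
        stop("counts must be non-negative")
    if (any(abs(counts - round(counts)) > 1e-8))
        stop("counts must be integers")
    invisible(counts)
}

#' Write a count table as TSV
#'
#' @param counts integer matrix, taxa as rows.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(counts, path) {
    validateCountTable(counts)
    df <- data.frame(taxon_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a delimited table whose first column contains sample identifiers.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame with sample ids as row names.
#' @export
readSampleMetadata <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate sample ids in metadata")
    out <- df[, -1L, drop = FALSE]
    rownames(out) <- ids
    out
}

#' Align a count table with sample metadata
#'
#' Takes the intersection of the two sample sets, preserving the count-table
#' order. Samples present in only one input are dropped with a warning; an
#' empty intersection is an error.
#'
#' @param counts taxa-by-samples matrix.
#' @param meta data.frame with sample ids as row names.
#' @return list with elements \code{counts} and \code{meta}, sample-aligned.
#' @export
alignSamples <- function(counts, meta) {
    common <- intersect(colnames(counts), rownames(meta))
    if (length(common) == 0L)
        stop("no samples shared between count table and metadata")
    droppedC <- setdiff(colnames(counts), common)
    droppedM <- setdiff(rownames(meta), common)
    if (length(droppedC) || length(droppedM))
        warning("dropping unmatched samples: ",
                paste(c(droppedC, droppedM), collapse = ", "))
    common <- colnames(counts)[colnames(counts) %in% common]
    list(counts = counts[, common, drop = FALSE],
         meta = meta[common, , drop = FALSE])
}

#' Build a fixed-effects design matrix
#'
#' Expands the named metadata variables into a design matrix with an
#' intercept. Categorical variables use treatment coding against a declared
#' reference level (default: first level in lexicographic order), so a
#' variable with s + 1 levels contributes s indicator columns.
#'
#' @param meta data.frame of sample metadata (samples as rows).
#' @param fixedTerms character vector of variable names, or a one-sided
#'   formula such as \code{~ exposure + covariate}.
#' @param reference named list/character vector mapping categorical variable
#'   names to their reference level.
#' @return list with elements \code{matrix} (n x p, first column the
#'   intercept), \code{columnNames}, \code{columnToVariable} (named character
#'   vector mapping design columns to source variables) and \code{terms}.
#' @export
buildDesign <- function(meta, fixedTerms, reference = NULL) {
    if (inherits(fixedTerms, "formula"))
        fixedTerms <- all.vars(fixedTerms)
    missingVars <- setdiff(fixedTerms, names(meta))
    if (length(missingVars))
        stop("variables absent from metadata: ",
             paste(missingVars, collapse = ", "))
    dat <- meta[, fixedTerms, drop = FALSE]
    for (v in fixedTerms) {
        if (anyNA(dat[[v]]))
            stop("missing values in model variable: ", v)
        if (is.character(dat[[v]]) || is.factor(dat[[v]]) ||
            is.logical(dat[[v]])) {
            f <- factor(as.character(dat[[v]]),
                        levels = sort(unique(as.character(dat[[v]]))))
            if (nlevels(f) < 2L)
                stop("categorical variable '", v, "' has a single level")
            ref <- reference[[v]]
            if (!is.null(ref)) {
                if (!ref %in% levels(f))
                    stop("reference level '", ref, "' not a level of '", v,
                         "'")
                f <- stats::relevel(f, ref = ref)
            }
            dat[[v]] <- f
        }
    }
    fml <- stats::as.formula(paste("~", paste(fixedTerms, collapse = " + ")))
    X <- stats::model.matrix(fml, data = dat)
    colnames(X)[1L] <- "(Intercept)"
    assign <- attr(X, "assign")
    colToVar <- c("(Intercept)", fixedTerms)[assign + 1L]
    names(colToVar) <- colnames(X)
    attr(X, "assign") <- NULL
    attr(X, "contrasts") <- NULL
    list(matrix = X, columnNames = colnames(X), columnToVariable = colToVar,
         terms = fixedTerms, data = dat)
}

#' Write per-taxon test results as TSV
#'
#' One row per taxon per contrast with the fixed column order
#' (taxon, contrast, lfc, se, W, p, q, passed_ss, structural_zero,
#' direction). An empty result set yields a header-only file.
#'
#' @param results data.frame as returned by \code{\link{testResults}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
    cols <- c("taxon", "contrast", "lfc", "se", "W", "p", "q", "passed_ss",
              "structural_zero", "direction")
    if (nrow(results) == 0L && !all(cols %in% names(results))) {
        results <- as.data.frame(setNames(
            lapply(cols, function(x) logical(0)), cols))
    }
    miss <- setdiff(cols, names(results))
    if (length(miss))
        stop("results table is missing columns: ", paste(miss, collapse = ", "))
    utils::write.table(results[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a results TSV written by \code{writeResults}
#'
#' @param path file path.
#' @return data.frame.
#' @export
readResults <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}
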