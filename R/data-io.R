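#' Construct an EdgeTable from endpoint vectors
#'
#' Symbols are uppercase-normalized, self-loops dropped, orientation
#' canonicalized (lexicographically smaller endpoint first) and duplicate
#' pairs collapsed, so `(A,B)` and `(B,A)` become one undirected edge.
#'
#' @param from,to character vectors of gene symbols, equal length.
#' @param quiet suppress the message reporting how many records were
#'   removed.
#' @return an [EdgeTable-class].
#' @examples
#' et <- EdgeTable(c("a", "B", "A", "A"), c("b", "A", "A", "B"))
#' numEdges(et)  # 1
#' @export
EdgeTable <- function(from, to, quiet = FALSE) {
    if (length(from) != length(to))
        npStop("netprop_format_error",
            "'from' and 'to' must have equal length")
    from <- normalizeSymbols(from)
    to <- normalizeSymbols(to)
    nIn <- length(from)
    loop <- from == to
    from <- from[!loop]; to <- to[!loop]
    lo <- pmin(from, to)
    hi <- pmax(from, to)
    key <- paste(lo, hi, sep = "\r")
    dup <- duplicated(key)
    lo <- lo[!dup]; hi <- hi[!dup]
    o <- order(lo, hi)
    if (!quiet && (sum(loop) || sum(dup)))
        message(sprintf(
            "EdgeTable: removed %d self-loop(s) and %d duplicate record(s) of %d",
            sum(loop), sum(dup), nIn))
    methods::new("EdgeTable", from = lo[o], to = hi[o])
}

#' Read an undirected edge list
#'
#' Parses a delimited text file with at least two columns (geneA, geneB);
#' extra columns (e.g. interaction confidence from a STRING export) are
#' ignored. `#` comment lines are skipped. Deduplication and self-loop
#' removal follow [EdgeTable()], so re-reading a written deduplicated edge
#' list is idempotent.
#'
#' @param path file path; tab-separated unless the extension is `.csv`.
#' @param quiet passed to [EdgeTable()].
#' @return an [EdgeTable-class].
#' @export
readEdgeList <- function(path, quiet = FALSE) {
    tab <- readDelimited(path, header = FALSE)
    if (!nrow(tab))
        npStop("netprop_empty_input_error", "edge list '%s' is empty", path)
    if (ncol(tab) < 2L)
        npStop("netprop_format_error",
            "edge list '%s' needs at least 2 columns, found %d",
            path, ncol(tab))
    EdgeTable(tab[[1L]], tab[[2L]], quiet = quiet)
}

#' Read an expression matrix with sample labels
#'
#' The expression file is delimited text with a header row of sample IDs
#' and gene symbols in the first column. The label file is a two-column
#' table `sample_id<TAB>{disease|normal}` covering every sample in the
#' matrix. See [ExpressionDataset()] for the normalization, duplicate and
#' missing-value rules applied after parsing.
#'
#' @param path expression file path (TSV, or CSV by `.csv` extension).
#' @param labelPath label file path.
#' @param missingPolicy `"drop_gene"` (default) or `"zero"`.
#' @return an [ExpressionDataset-class].
#' @export
readExpression <- function(path, labelPath,
                           missingPolicy = c("drop_gene", "zero")) {
    tab <- readDelimited(path, header = TRUE)
    if (ncol(tab) < 2L)
        npStop("netprop_format_error",
            "expression file '%s' needs gene and sample columns", path)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tab[[1L]])

    lab <- readDelimited(labelPath, header = FALSE)
    if (ncol(lab) < 2L)
        npStop("netprop_format_error",
            "label file '%s' needs 2 columns", labelPath)
    labels <- stats::setNames(as.character(lab[[2L]]),
                              as.character(lab[[1L]]))
    ExpressionDataset(m, labels, missingPolicy = missingPolicy)
}

#' Read a gene set (seed genes)
#'
#' One symbol per line; blank lines and `#` comments are allowed. Symbols
#' are uppercase-normalized and deduplicated.
#'
#' @param path file path.
#' @return character vector of unique normalized symbols.
#' @export
readGeneSet <- function(path) {
    if (!file.exists(path))
        npStop("netprop_input_error", "cannot read file '%s'", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    sym <- unique(normalizeSymbols(lines[nzchar(trimws(lines))]))
    if (!length(sym))
        npStop("netprop_empty_input_error",
            "gene set '%s' contains no symbols", path)
    sym
}

#' Write a ranked gene table
#'
#' Produces the ranking TSV with columns `rank`, `gene`, `score`,
#' `is_seed`, sorted by score descending with ties broken by gene symbol
#' ascending (the same stable rule used throughout the package). Scores
#' are printed with 6 significant digits.
#'
#' @param scores named numeric vector of final disease-risk scores.
#' @param seeds character vector of seed gene symbols (flags the `is_seed`
#'   column; genes are not removed — use [rankGenes()] for a candidates-only
#'   ranking).
#' @param path output file path.
#' @return the ranking data.frame, invisibly.
#' @export
writeRanking <- function(scores, seeds, path) {
    if (any(!is.finite(scores)))
        npStop("netprop_numeric_error", "scores must all be finite")
    rk <- rankGenes(scores, seeds, includeSeeds = TRUE)
    out <- rk
    out$score <- signif(out$score, 6L)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(rk)
}

#' @describeIn EdgeTable number of undirected edges.
#' @param x an `EdgeTable`.
#' @rdname numEdges
#' @export
setMethod("numEdges", "EdgeTable", function(x) length(x@from))

#' Vertices spanned by an edge table
#'
#' @param x an [EdgeTable-class] or [WeightedNetwork-class].
#' @return sorted character vector of vertex symbols.
#' @rdname vertexNames
#' @export
setMethod("vertexNames", "EdgeTable", function(x) {
    sort(unique(c(x@from, x@to)))
})

#' Edge table as a data.frame
#'
#' @param x an EdgeTable.
#' @param ... ignored.
#' @return data.frame with columns `from`, `to`.
#' @export
setMethod("as.data.frame", "EdgeTable", function(x, ...) {
    data.frame(from = x@from, to = x@to, stringsAsFactors = FALSE)
})

setMethod("show", "EdgeTable", function(object) {
    cat(sprintf("EdgeTable: %d undirected edges over %d vertices\n",
        numEdges(object), length(vertexNames(object))))
})
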