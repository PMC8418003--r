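#' Construct an ExpressionDataset from a matrix and sample labels
#'
#' Wraps a genes-by-samples expression matrix and a per-sample class label
#' into a validated [ExpressionDataset-class]. Gene symbols are
#' uppercase-normalized; duplicate gene rows are collapsed by their mean
#' (which preserves the class means the vertex weights are built from);
#' genes are ordered lexicographically.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample IDs). Values must be
#'   non-negative; inputs are assumed pre-normalized (FPKM-like or
#'   microarray intensities).
#' @param labels character or factor of length `ncol(values)` (or named by
#'   sample ID) with values `"disease"` / `"normal"`.
#' @param missingPolicy how to handle missing entries: `"drop_gene"`
#'   (default) removes any gene row containing `NA`; `"zero"` replaces `NA`
#'   with 0.
#' @return an [ExpressionDataset-class].
#' @examples
#' m <- matrix(runif(12, 1, 10), 3, 4,
#'     dimnames = list(c("TP53", "EGFR", "KRAS"), paste0("S", 1:4)))
#' ed <- ExpressionDataset(m, c("disease", "disease", "normal", "normal"))
#' exprValues(ed)
#' @export
ExpressionDataset <- function(values, labels,
                              missingPolicy = c("drop_gene", "zero")) {
    missingPolicy <- match.arg(missingPolicy)
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        npStop("netprop_input_error",
            "expression matrix needs gene rownames and sample colnames")
    storage.mode(values) <- "double"

    if (!is.null(names(labels))) {
        miss <- setdiff(colnames(values), names(labels))
        if (length(miss))
            npStop("netprop_label_error",
                "no label for sample(s): %s",
                paste(miss, collapse = ", "))
        labels <- labels[colnames(values)]
    } else if (length(labels) != ncol(values)) {
        npStop("netprop_label_error",
            "got %d labels for %d samples", length(labels), ncol(values))
    }
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("disease", "normal"))
    if (length(bad))
        npStop("netprop_label_error",
            "unknown sample class(es): %s", paste(bad, collapse = ", "))
    if (sum(labels == "disease") < 2L || sum(labels == "normal") < 2L)
        npStop("netprop_cardinality_error",
            "each class needs at least 2 samples (got %d disease, %d normal)",
            sum(labels == "disease"), sum(labels == "normal"))

    rownames(values) <- normalizeSymbols(rownames(values))
    if (missingPolicy == "zero") {
        values[is.na(values)] <- 0
    } else if (anyNA(values)) {
        keep <- rowSums(is.na(values)) == 0L
        values <- values[keep, , drop = FALSE]
        if (!nrow(values))
            npStop("netprop_empty_input_error",
                "no genes left after dropping rows with missing values")
    }
    if (anyDuplicated(rownames(values))) {
        grp <- rownames(values)
        values <- rowsum(values, grp) / as.vector(table(grp)[sort(unique(grp))])
    }
    values <- values[order(rownames(values)), , drop = FALSE]
    if (any(values < 0))
        npStop("netprop_input_error",
            "expression values must be non-negative")

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values),
        colData = S4Vectors::DataFrame(
            condition = factor(labels, levels = c("disease", "normal")),
            row.names = colnames(values)))
    methods::new("ExpressionDataset", se)
}

#' Expression matrix of an ExpressionDataset
#'
#' @param x an [ExpressionDataset-class].
#' @return numeric matrix, genes in rows.
#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionDataset", function(x) {
    SummarizedExperiment::assay(x, "expr")
})

#' Sample class labels
#'
#' @param x an [ExpressionDataset-class].
#' @return factor named by sample ID with levels `disease`, `normal`.
#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "ExpressionDataset", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$condition, colnames(x))
})

# expression submatrix restricted to one class
classMatrix <- function(x, class = c("disease", "normal")) {
    class <- match.arg(class)
    exprValues(x)[, sampleLabels(x) == class, drop = FALSE]
}

setMethod("show", "ExpressionDataset", function(object) {
    tab <- table(sampleLabels(object))
    cat(sprintf(
        "ExpressionDataset: %d genes x %d samples (%d disease, %d normal)\n",
        nrow(object), ncol(object), tab[["disease"]], tab[["normal"]]))
})
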