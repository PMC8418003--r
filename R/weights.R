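# Expression-based vertex and edge weights of the PPI network.
#
# Vertex weight: w(v) = mean expression in disease samples over mean in
# normal samples (pseudocount epsilon on both to keep the ratio finite).
# Edge weight: Pearson correlation of the two genes across the disease
# samples only, mapped to [0, 1] by a transform.

# ratio of class means, vectorized over genes
vertexWeightVec <- function(genes, data, epsilon = 1e-6) {
    mD <- rowMeans(classMatrix(data, "disease")[genes, , drop = FALSE])
    mN <- rowMeans(classMatrix(data, "normal")[genes, , drop = FALSE])
    (mD + epsilon) / (mN + epsilon)
}

# Pearson r per gene pair over disease samples, via the moment formula;
# genes with zero variance yield 0 (no co-expression evidence)
pairCorrelationVec <- function(from, to, data) {
    x <- classMatrix(data, "disease")
    if (ncol(x) < 2L)
        npStop("netprop_cardinality_error",
            "need >= 2 disease samples for edge weights, got %d", ncol(x))
    cx <- x - rowMeans(x)
    ss <- rowSums(cx * cx)
    num <- rowSums(cx[from, , drop = FALSE] * cx[to, , drop = FALSE])
    den <- sqrt(ss[from] * ss[to])
    r <- ifelse(den > 0, num / den, 0)
    # guard rounding just past +/-1
    unname(pmin(pmax(r, -1), 1))
}

applyTransform <- function(r, transform = c("abs", "clip_negative")) {
    transform <- match.arg(transform)
    if (transform == "abs") abs(r) else pmax(r, 0)
}

#' Differential-expression vertex weight
#'
#' Computes `w(v) = (mean_disease + epsilon) / (mean_normal + epsilon)`:
#' the ratio of a gene's average expression in disease samples to its
#' average in normal samples. The pseudocount `epsilon` keeps the ratio
#' finite when the normal-class mean is zero. The raw ratio (not a
#' log-ratio) is used.
#'
#' @param gene gene symbol(s), present in `data`.
#' @param data an [ExpressionDataset-class].
#' @param epsilon positive pseudocount on the data's scale (default
#'   `1e-6`).
#' @return positive finite numeric, one value per gene.
#' @export
vertexWeight <- function(gene, data, epsilon = 1e-6) {
    stopifnot(epsilon > 0)
    gene <- normalizeSymbols(gene)
    absent <- setdiff(gene, rownames(data))
    if (length(absent))
        npStop("netprop_lookup_error",
            "gene(s) absent from expression data: %s",
            paste(absent, collapse = ", "))
    vertexWeightVec(gene, data, epsilon)
}

#' Co-expression edge weight
#'
#' Pearson correlation between two genes computed across the disease
#' samples only, mapped into `[0, 1]`: `transform = "abs"` (default) takes
#' the magnitude, so anticorrelated pairs carry weight too;
#' `"clip_negative"` zeroes negative correlations. A gene with zero
#' variance across disease samples yields weight 0.
#'
#' @param u,v gene symbols present in `data`.
#' @param data an [ExpressionDataset-class] with at least 2 disease
#'   samples.
#' @param transform `"abs"` or `"clip_negative"`.
#' @return numeric in `[0, 1]`.
#' @export
edgeWeight <- function(u, v, data, transform = c("abs", "clip_negative")) {
    u <- normalizeSymbols(u); v <- normalizeSymbols(v)
    absent <- setdiff(c(u, v), rownames(data))
    if (length(absent))
        npStop("netprop_lookup_error",
            "gene(s) absent from expression data: %s",
            paste(absent, collapse = ", "))
    applyTransform(pairCorrelationVec(u, v, data), transform)
}

#' Assemble the expression-weighted network
#'
#' Combines an interaction edge list with an expression dataset into a
#' [WeightedNetwork-class]: vertices are the union of edge endpoints,
#' vertex weights are disease/normal mean ratios ([vertexWeight()]) and
#' edge weights are transformed disease-sample Pearson correlations
#' ([edgeWeight()]).
#'
#' Genes present in the network but absent from the expression matrix are
#' handled by `missingPolicy`: `"drop"` (default) removes the vertex and
#' its edges; `"neutral"` keeps it with `w(v) = 1` and zero-weight incident
#' edges.
#'
#' @param edges an [EdgeTable-class].
#' @param data an [ExpressionDataset-class].
#' @param transform edge-weight transform, see [edgeWeight()].
#' @param epsilon vertex-weight pseudocount, see [vertexWeight()].
#' @param missingPolicy `"drop"` or `"neutral"`.
#' @param quiet suppress the construction summary message.
#' @return a [WeightedNetwork-class].
#' @export
buildWeightedNetwork <- function(edges, data,
                                 transform = c("abs", "clip_negative"),
                                 epsilon = 1e-6,
                                 missingPolicy = c("drop", "neutral"),
                                 quiet = FALSE) {
    stopifnot(methods::is(edges, "EdgeTable"),
              methods::is(data, "ExpressionDataset"))
    transform <- match.arg(transform)
    missingPolicy <- match.arg(missingPolicy)
    if (!numEdges(edges))
        npStop("netprop_empty_input_error", "edge table is empty")

    vertices <- vertexNames(edges)
    covered <- vertices %in% rownames(data)
    nDroppedV <- 0L; nDroppedE <- 0L
    from <- edges@from; to <- edges@to

    if (missingPolicy == "drop" && any(!covered)) {
        keepV <- vertices[covered]
        keepE <- from %in% keepV & to %in% keepV
        nDroppedV <- sum(!covered)
        nDroppedE <- sum(!keepE)
        from <- from[keepE]; to <- to[keepE]
        vertices <- sort(unique(c(from, to)))
        if (!length(vertices))
            npStop("netprop_empty_network_error",
                "no vertices left after dropping genes without expression")
    }

    vw <- stats::setNames(rep(1, length(vertices)), vertices)
    meas <- vertices[vertices %in% rownames(data)]
    vw[meas] <- vertexWeightVec(meas, data, epsilon)

    ew <- numeric(length(from))
    bothMeas <- from %in% rownames(data) & to %in% rownames(data)
    if (any(bothMeas))
        ew[bothMeas] <- applyTransform(
            pairCorrelationVec(from[bothMeas], to[bothMeas], data),
            transform)

    if (!quiet)
        message(sprintf(
            "WeightedNetwork: %d vertices, %d edges (%d vertices, %d edges dropped without expression)",
            length(vertices), length(from), nDroppedV, nDroppedE))

    methods::new("WeightedNetwork",
        vertexWeights = vw,
        edges = data.frame(from = from, to = to, weight = ew,
            stringsAsFactors = FALSE))
}

#' Vertex symbols of a weighted network
#' @param x a [WeightedNetwork-class].
#' @rdname vertexNames
#' @export
setMethod("vertexNames", "WeightedNetwork", function(x) {
    names(x@vertexWeights)
})

#' Vertex weights w(v)
#' @param x a [WeightedNetwork-class].
#' @return named numeric vector of disease/normal expression ratios.
#' @rdname vertexWeights
#' @export
setMethod("vertexWeights", "WeightedNetwork", function(x) x@vertexWeights)

#' Edge weights w(u,v)
#' @param x a [WeightedNetwork-class].
#' @return data.frame with columns `from`, `to`, `weight`.
#' @rdname edgeWeights
#' @export
setMethod("edgeWeights", "WeightedNetwork", function(x) x@edges)

#' @rdname numEdges
#' @export
setMethod("numEdges", "WeightedNetwork", function(x) nrow(x@edges))

#' Number of vertices
#' @param x a [WeightedNetwork-class].
#' @rdname numVertices
#' @export
setMethod("numVertices", "WeightedNetwork", function(x) {
    length(x@vertexWeights)
})

setMethod("show", "WeightedNetwork", function(object) {
    cat(sprintf("WeightedNetwork: %d vertices, %d weighted edges\n",
        numVertices(object), numEdges(object)))
    cat(sprintf("  vertex weights: median %.3g [%.3g, %.3g]\n",
        stats::median(object@vertexWeights), min(object@vertexWeights),
        max(object@vertexWeights)))
    if (numEdges(object))
        cat(sprintf("  edge weights:   median %.3g [%.3g, %.3g]\n",
            stats::median(object@edges$weight), min(object@edges$weight),
            max(object@edges$weight)))
})

#' Dump network weights to TSV files for inspection
#'
#' @param network a [WeightedNetwork-class].
#' @param vertexPath,edgePath output paths; `NULL` skips that file.
#' @return invisible `NULL`.
#' @export
writeWeights <- function(network, vertexPath = NULL, edgePath = NULL) {
    if (!is.null(vertexPath))
        utils::write.table(
            data.frame(gene = vertexNames(network),
                weight = signif(vertexWeights(network), 6L)),
            vertexPath, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(edgePath)) {
        e <- edgeWeights(network)
        e$weight <- signif(e$weight, 6L)
        utils::write.table(e, edgePath, sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    invisible(NULL)
}
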