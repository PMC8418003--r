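# Fixtures are built in code; no data files.

# small expression dataset from a list of row vectors
exprFromRows <- function(rows,
                         labels = c("disease", "disease",
                                    "normal", "normal")) {
    m <- do.call(rbind, rows)
    colnames(m) <- paste0("S", seq_len(ncol(m)))
    ExpressionDataset(m, labels)
}

# WeightedNetwork straight from weights (bypasses expression data)
mkNetwork <- function(vertexWeights, edges) {
    if (nrow(edges)) {
        lo <- pmin(edges$from, edges$to)
        hi <- pmax(edges$from, edges$to)
        edges <- data.frame(from = lo, to = hi, weight = edges$weight,
            stringsAsFactors = FALSE)
    }
    methods::new("WeightedNetwork",
        vertexWeights = vertexWeights, edges = edges)
}

# random weighted network; may contain isolated vertices (zero columns)
randomNetwork <- function(n, nEdges, seed) {
    set.seed(seed)
    v <- sprintf("V%04d", seq_len(n))
    g <- igraph::sample_gnm(n, nEdges)
    el <- igraph::as_edgelist(g, names = FALSE)
    mkNetwork(
        stats::setNames(stats::runif(n, 0.2, 5), v),
        data.frame(from = v[el[, 1L]], to = v[el[, 2L]],
            weight = stats::runif(nrow(el)), stringsAsFactors = FALSE))
}

# Exhaustive pair-counting AUC oracle: each fold's held-out gene at
# integer rank r among n ranked genes is compared against every candidate
# position, ties (same rank) scoring half. Independent of rocAndAuc().
bruteForceAuc <- function(ranks, ns) {
    per <- mapply(function(r, n) {
        cand <- setdiff(seq_len(n), r)
        mean((cand > r) + 0.5 * (cand == r))
    }, ranks, ns)
    mean(per)
}

writeLinesTo <- function(lines, name) {
    p <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
        name)
    writeLines(lines, p)
    p
}
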