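# Synthetic planted-module benchmark generator.
#
# Emulates, at reduced scale, the structure the prioritization method
# assumes: a sparse undirected interaction network containing a module of
# "disease" genes with elevated within-module edge density, and an
# expression matrix in which those module genes are (a) differentially
# expressed between disease and normal samples (mean ratio = foldChange)
# and (b) co-expressed across disease samples through a shared latent
# factor (pairwise Pearson r = moduleCorrelation). The module doubles as
# the seed gene set, giving ground truth for cross-validation.

# extra within-module wiring probability on top of the background graph
MODULE_EDGE_DENSITY <- 0.3

#' Construct a SimulationSpec
#'
#' Defaults describe a benchmark small enough for seconds-scale tests:
#' 300 genes, ~900 edges, a 15-gene planted module, 30 + 30 samples,
#' twofold differential expression and 0.6 within-module co-expression.
#'
#' @param nGenes,nEdgesTarget,moduleSize,attachment network parameters;
#'   see [SimulationSpec-class].
#' @param nDiseaseSamples,nNormalSamples sample counts per class.
#' @param foldChange module disease/normal mean-expression ratio.
#' @param moduleCorrelation target within-module pairwise Pearson r across
#'   disease samples, in `[0, 1)`.
#' @param noiseSd,baselineMean expression noise SD and baseline mean
#'   (FPKM-like scale).
#' @param rngSeed integer seed; the network generator uses `rngSeed`, the
#'   expression generator `rngSeed + 1`.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(nGenes = 300L, nEdgesTarget = 900L,
                           moduleSize = 15L,
                           attachment = c("preferential", "erdos_renyi"),
                           nDiseaseSamples = 30L, nNormalSamples = 30L,
                           foldChange = 2, moduleCorrelation = 0.6,
                           noiseSd = 1, baselineMean = 5, rngSeed = 1L) {
    methods::new("SimulationSpec",
        nGenes = as.integer(nGenes),
        nEdgesTarget = as.integer(nEdgesTarget),
        moduleSize = as.integer(moduleSize),
        attachment = match.arg(attachment),
        nDiseaseSamples = as.integer(nDiseaseSamples),
        nNormalSamples = as.integer(nNormalSamples),
        foldChange = as.numeric(foldChange),
        moduleCorrelation = as.numeric(moduleCorrelation),
        noiseSd = as.numeric(noiseSd),
        baselineMean = as.numeric(baselineMean),
        rngSeed = as.integer(rngSeed))
}

setMethod("show", "SimulationSpec", function(object) {
    cat(sprintf(
        "SimulationSpec: %d genes, ~%d edges (%s), module of %d; %d+%d samples; foldChange %g, moduleCorrelation %g, seed %d\n",
        object@nGenes, object@nEdgesTarget, object@attachment,
        object@moduleSize, object@nDiseaseSamples, object@nNormalSamples,
        object@foldChange, object@moduleCorrelation, object@rngSeed))
})

geneUniverse <- function(spec) {
    sprintf("G%0*d", nchar(as.character(spec@nGenes)),
        seq_len(spec@nGenes))
}

#' Module (seed) genes of a simulation spec
#'
#' The planted module is the first `moduleSize` gene names; by vertex-label
#' symmetry of the generators this loses no generality, and it lets the
#' network and expression generators be called independently from the same
#' spec while agreeing on the module.
#'
#' @param spec a [SimulationSpec-class].
#' @return character vector of module gene symbols.
#' @export
moduleGenes <- function(spec) {
    geneUniverse(spec)[seq_len(spec@moduleSize)]
}

#' Generate the benchmark network
#'
#' Background topology comes from a preferential-attachment
#' (scale-free-like, as PPI networks are) or Erdos-Renyi model targeting
#' `nEdgesTarget` edges. The module is then planted by degree-preserving
#' double-edge swaps: for each desired within-module edge (drawn with
#' probability 0.3 per module pair, well above the background density),
#' one background edge incident to each endpoint is removed and the two
#' freed stubs are reconnected. Every vertex keeps its background degree,
#' so the module is enriched purely in its internal connectivity — a
#' column-normalized walk has a known degree bias, and planting by edge
#' addition would let topology alone separate the module even when its
#' expression carries no signal. Deterministic given `rngSeed`.
#'
#' @param spec a [SimulationSpec-class].
#' @return an [EdgeTable-class].
#' @export
generateNetwork <- function(spec) {
    stopifnot(methods::is(spec, "SimulationSpec"))
    methods::validObject(spec)
    set.seed(spec@rngSeed)
    genes <- geneUniverse(spec)
    n <- spec@nGenes

    g <- if (spec@attachment == "preferential") {
        igraph::sample_pa(n, m = max(1L, round(spec@nEdgesTarget / n)),
            directed = FALSE)
    } else {
        igraph::sample_gnm(n, spec@nEdgesTarget)
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    # shuffle vertex labels: under preferential attachment the low vertex
    # indices are the oldest (highest-degree) vertices, and the module must
    # not systematically land on hubs
    perm <- sample.int(n)
    el[] <- perm[el]

    modIdx <- seq_len(spec@moduleSize)
    if (length(modIdx) >= 2L) {
        pairs <- utils::combn(modIdx, 2L)
        want <- pairs[, stats::runif(ncol(pairs)) < MODULE_EDGE_DENSITY,
            drop = FALSE]
        el <- plantModuleBySwaps(el, want, modIdx, n)
    }
    EdgeTable(genes[el[, 1L]], genes[el[, 2L]], quiet = TRUE)
}

# Degree-preserving planting: for each desired module edge (a, b) not yet
# present, remove background edges (a, x) and (b, y) (x, y outside the
# module) and add (a, b) and (x, y). Pairs that cannot be swapped without
# creating duplicates are skipped.
plantModuleBySwaps <- function(el, want, modIdx, n) {
    key <- function(i, j) pmin(i, j) * (n + 1L) + pmax(i, j)
    edgeKeys <- new.env(hash = TRUE, parent = emptyenv())
    has <- function(i, j) !is.null(edgeKeys[[as.character(key(i, j))]])
    setEdge <- function(i, j, row) {
        edgeKeys[[as.character(key(i, j))]] <- row
    }
    dropEdge <- function(i, j) rm(list = as.character(key(i, j)),
        envir = edgeKeys)
    for (r in seq_len(nrow(el))) setEdge(el[r, 1L], el[r, 2L], r)

    adj <- vector("list", n)
    for (r in seq_len(nrow(el))) {
        adj[[el[r, 1L]]] <- c(adj[[el[r, 1L]]], el[r, 2L])
        adj[[el[r, 2L]]] <- c(adj[[el[r, 2L]]], el[r, 1L])
    }
    rmNb <- function(i, j) adj[[i]] <<- adj[[i]][adj[[i]] != j]

    for (p in seq_len(ncol(want))) {
        a <- want[1L, p]; b <- want[2L, p]
        if (has(a, b)) next
        candX <- setdiff(adj[[a]], modIdx)
        candY <- setdiff(adj[[b]], modIdx)
        if (!length(candX) || !length(candY)) next
        candX <- candX[sample.int(length(candX))]
        candY <- candY[sample.int(length(candY))]
        done <- FALSE
        for (x in candX) {
            if (done) break
            for (y in candY) {
                if (x == y || has(x, y)) next
                rowAX <- edgeKeys[[as.character(key(a, x))]]
                rowBY <- edgeKeys[[as.character(key(b, y))]]
                dropEdge(a, x); dropEdge(b, y)
                el[rowAX, ] <- c(a, b); setEdge(a, b, rowAX)
                el[rowBY, ] <- c(x, y); setEdge(x, y, rowBY)
                rmNb(a, x); rmNb(x, a); rmNb(b, y); rmNb(y, b)
                adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
                adj[[x]] <- c(adj[[x]], y); adj[[y]] <- c(adj[[y]], x)
                done <- TRUE
                break
            }
        }
    }
    el
}

#' Generate the benchmark expression matrix and seed set
#'
#' Background genes are `baselineMean` plus Gaussian noise in both
#' classes. Module genes keep that distribution in normal samples; in
#' disease samples their mean is multiplied by `foldChange` and their
#' noise mixes a per-sample latent factor shared by the whole module
#' (loading `sqrt(moduleCorrelation)`) with independent noise, so any two
#' module genes have expected pairwise Pearson r equal to
#' `moduleCorrelation` across disease samples. Values are clipped at
#' zero. Deterministic given `rngSeed` (stream `rngSeed + 1`; draw order:
#' the full noise matrix, then the latent factor).
#'
#' @param spec a [SimulationSpec-class].
#' @param edges optional [EdgeTable-class]; unused (the gene universe
#'   comes from `spec`), accepted for pipeline symmetry.
#' @return list with `data` (an [ExpressionDataset-class]) and `seeds`
#'   (the module gene symbols).
#' @export
generateExpression <- function(spec, edges = NULL) {
    stopifnot(methods::is(spec, "SimulationSpec"))
    methods::validObject(spec)
    set.seed(spec@rngSeed + 1L)
    genes <- geneUniverse(spec)
    nD <- spec@nDiseaseSamples; nN <- spec@nNormalSamples
    samples <- c(sprintf("D%03d", seq_len(nD)),
                 sprintf("N%03d", seq_len(nN)))
    labels <- rep(c("disease", "normal"), c(nD, nN))

    eps <- matrix(stats::rnorm(spec@nGenes * (nD + nN)),
        nrow = spec@nGenes, dimnames = list(genes, samples))
    z <- stats::rnorm(nD)

    x <- spec@baselineMean + spec@noiseSd * eps
    mod <- moduleGenes(spec)
    rho <- spec@moduleCorrelation
    dIdx <- seq_len(nD)
    x[mod, dIdx] <- spec@baselineMean * spec@foldChange +
        spec@noiseSd * (sqrt(rho) * matrix(z, nrow = length(mod),
                ncol = nD, byrow = TRUE) +
            sqrt(1 - rho) * eps[mod, dIdx, drop = FALSE])
    x <- pmax(x, 0)

    list(data = ExpressionDataset(x, labels), seeds = mod)
}

#' Write a complete benchmark bundle to disk
#'
#' Generates the network and expression data and writes the four files
#' the readers consume unchanged — `edges.tsv` (two-column edge list),
#' `expression.tsv` (header of sample IDs, gene symbols in column 1),
#' `labels.tsv` (sample, class) and `seeds.txt` (one symbol per line) —
#' plus `spec.yaml` echoing the generating parameters. Byte-identical
#' across runs with the same spec.
#'
#' @param spec a [SimulationSpec-class].
#' @param outDir output directory (created if needed).
#' @return invisible list with the file `paths` and the in-memory
#'   `edges`, `data`, `seeds`.
#' @export
generateBenchmark <- function(spec, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir))
        npStop("netprop_write_error", "cannot create directory '%s'", outDir)
    edges <- generateNetwork(spec)
    ge <- generateExpression(spec)

    paths <- list(
        edges = file.path(outDir, "edges.tsv"),
        expression = file.path(outDir, "expression.tsv"),
        labels = file.path(outDir, "labels.tsv"),
        seeds = file.path(outDir, "seeds.txt"),
        spec = file.path(outDir, "spec.yaml"))

    utils::write.table(as.data.frame(edges), paths$edges, sep = "\t",
        quote = FALSE, row.names = FALSE, col.names = FALSE)
    m <- exprValues(ge$data)
    utils::write.table(
        data.frame(gene = rownames(m), signif(m, 8L),
            check.names = FALSE),
        paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
    lab <- sampleLabels(ge$data)
    utils::write.table(data.frame(names(lab), as.character(lab)),
        paths$labels, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    writeLines(ge$seeds, paths$seeds)
    yaml::write_yaml(list(
        nGenes = spec@nGenes, nEdgesTarget = spec@nEdgesTarget,
        moduleSize = spec@moduleSize, attachment = spec@attachment,
        nDiseaseSamples = spec@nDiseaseSamples,
        nNormalSamples = spec@nNormalSamples,
        foldChange = spec@foldChange,
        moduleCorrelation = spec@moduleCorrelation,
        noiseSd = spec@noiseSd, baselineMean = spec@baselineMean,
        rngSeed = spec@rngSeed), paths$spec)

    invisible(list(paths = paths, edges = edges, data = ge$data,
        seeds = ge$seeds))
}
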