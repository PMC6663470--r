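#' Construct a GuidedGraph from an adjacency matrix
#'
#' @param adjacency symmetric nonnegative numeric matrix with zero diagonal.
#' @param nodeIds optional character vector of node identifiers; defaults to
#'   dimnames or "1".."N".
#' @param nodeClasses optional character vector of per-node class labels.
#' @return a validated [GuidedGraph].
#' @examples
#' A <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
#' g <- guidedGraph(A)
#' degrees(g)
#' @export
guidedGraph <- function(adjacency, nodeIds = NULL, nodeClasses = NULL) {
    adjacency <- as.matrix(adjacency)
    storage.mode(adjacency) <- "double"
    if (is.null(nodeIds)) {
        nodeIds <- if (!is.null(rownames(adjacency))) rownames(adjacency)
            else as.character(seq_len(nrow(adjacency)))
    }
    nodeIds <- as.character(nodeIds)
    dimnames(adjacency) <- list(nodeIds, nodeIds)
    new("GuidedGraph",
        nodeIds = nodeIds,
        nodeClass = if (is.null(nodeClasses)) character() else
            as.character(nodeClasses),
        adjacency = adjacency)
}

split_fields <- function(lines) {
    strsplit(trimws(lines), "[,[:space:]]+")
}

read_edge_list <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    if (!length(lines)) stop("empty edge list: ", path)
    tok <- split_fields(lines)
    # optional single header line: weight field (3rd) non-numeric, or a
    # two-column header with non-numeric-looking names like "src dst"
    first <- tok[[1]]
    has_header <- FALSE
    if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))))
        has_header <- TRUE
    if (length(first) == 2 &&
        all(tolower(first) %in% c("src", "dst", "source", "target", "from",
            "to", "node1", "node2")))
        has_header <- TRUE
    if (has_header) tok <- tok[-1]
    if (!length(tok)) stop("edge list has a header but no edges: ", path)
    nf <- lengths(tok)
    if (any(nf < 2 | nf > 3))
        stop("edge list rows must have 2 or 3 fields (src dst [weight])")
    src <- vapply(tok, `[`, character(1), 1L)
    dst <- vapply(tok, `[`, character(1), 2L)
    w <- vapply(tok, function(f)
        if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else 1.0,
        numeric(1))
    if (any(is.na(w))) stop("non-numeric edge weight in edge list")
    list(src = src, dst = dst, weight = w)
}

edges_to_adjacency <- function(src, dst, weight) {
    if (any(src == dst))
        stop("self-loop in edge list (node ",
             src[which(src == dst)[1]], ")")
    if (any(weight < 0)) stop("negative edge weight is not allowed")
    ids <- unique(c(rbind(src, dst)))  # first-appearance order
    n <- length(ids)
    i <- match(src, ids)
    j <- match(dst, ids)
    key <- paste(i, j)
    if (anyDuplicated(key))
        stop("duplicate edge in edge list: ",
             paste(src[duplicated(key)][1], dst[duplicated(key)][1]))
    # mirrored entries: same undirected edge written in both directions is
    # accepted only when the two weights agree
    lo <- pmin(i, j); hi <- pmax(i, j)
    ukey <- paste(lo, hi)
    if (anyDuplicated(ukey)) {
        dup <- ukey[duplicated(ukey)]
        for (k in unique(dup)) {
            wk <- weight[ukey == k]
            if (max(wk) - min(wk) > 0)
                stop("mirrored edge with unequal weights: nodes ",
                     sub(" ", "-", k))
        }
        keep <- !duplicated(ukey)
        i <- i[keep]; j <- j[keep]; weight <- weight[keep]
    }
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    A[cbind(i, j)] <- weight
    A[cbind(j, i)] <- weight
    A
}

read_dense_csv <- function(path) {
    raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    raw <- as.matrix(raw)
    is_num <- function(v) !any(is.na(suppressWarnings(as.numeric(v))))
    header_row <- !is_num(raw[1, -1, drop = TRUE])
    header_col <- !is_num(raw[-1, 1, drop = TRUE])
    ids <- NULL
    if (header_row && header_col) {
        ids <- as.character(raw[1, -1])
        raw <- raw[-1, -1, drop = FALSE]
    } else if (header_row) {
        ids <- as.character(raw[1, ])
        raw <- raw[-1, , drop = FALSE]
    } else if (header_col) {
        ids <- as.character(raw[, 1])
        raw <- raw[, -1, drop = FALSE]
    }
    A <- matrix(suppressWarnings(as.numeric(raw)), nrow(raw), ncol(raw))
    if (any(is.na(A))) stop("non-numeric entry in dense CSV adjacency")
    if (nrow(A) != ncol(A)) stop("dense CSV adjacency must be square")
    if (!is.null(ids)) dimnames(A) <- list(ids, ids)
    A
}

read_mtx <- function(path) {
    m <- Matrix::readMM(path)
    A <- as.matrix(m)
    # symmetric-kind MTX is expanded by readMM; a general-kind file storing
    # only one triangle is mirrored here
    if (max(abs(A - t(A))) > 1e-12) {
        if (all(A[lower.tri(A)] == 0) || all(A[upper.tri(A)] == 0)) {
            A <- A + t(A)
            diag(A) <- diag(A) / 2
        }
    }
    A
}

check_dense_adjacency <- function(A, tol = 1e-12) {
    if (max(abs(A - t(A))) > tol)
        stop("adjacency matrix is asymmetric beyond tolerance ", tol)
    A <- (A + t(A)) / 2
    if (any(diag(A) != 0)) stop("self-loops (nonzero diagonal) not allowed")
    if (any(A < 0)) stop("negative weights not allowed")
    A
}

#' Load an undirected weighted graph from disk
#'
#' Reads one of three formats: a whitespace/comma-separated edge list
#' (`src dst weight`, weight optional, one optional header line), a dense
#' CSV adjacency matrix (row/column ids optional), or Matrix Market
#' coordinate format (symmetric kind honored). Node order follows first
#' appearance in the file. Asymmetric dense input (beyond 1e-12), negative
#' weights, self-loops and duplicate edges are rejected.
#'
#' @param path input file.
#' @param format one of "edge_list", "dense_csv", "mtx".
#' @param metadataPath optional TSV with columns `node_id  class  label`;
#'   every graph node must be present.
#' @param binarize replace all positive weights by 1 (logical-OR
#'   binarization, the convention used for connectomes combining several
#'   connection types). With `binarize = FALSE` weights are kept as read.
#' @param dropIsolated remove zero-degree nodes instead of rejecting them.
#' @return a validated [GuidedGraph].
#' @export
loadGraph <- function(path, format = c("edge_list", "dense_csv", "mtx"),
                      metadataPath = NULL, binarize = FALSE,
                      dropIsolated = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    A <- switch(format,
        edge_list = {
            e <- read_edge_list(path)
            edges_to_adjacency(e$src, e$dst, e$weight)
        },
        dense_csv = check_dense_adjacency(read_dense_csv(path)),
        mtx = check_dense_adjacency(read_mtx(path))
    )
    if (binarize) A[A > 0] <- 1
    if (dropIsolated) {
        keep <- rowSums(A) > 0
        A <- A[keep, keep, drop = FALSE]
    }
    cls <- NULL
    if (!is.null(metadataPath)) {
        md <- utils::read.table(metadataPath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE,
                                colClasses = "character")
        if (!all(c("node_id", "class") %in% names(md)))
            stop("metadata must have columns node_id and class")
        ids <- if (!is.null(rownames(A))) rownames(A)
            else as.character(seq_len(nrow(A)))
        miss <- setdiff(ids, md$node_id)
        if (length(miss))
            stop("metadata missing node id(s): ",
                 paste(utils::head(miss, 5L), collapse = ", "))
        cls <- md$class[match(ids, md$node_id)]
    }
    guidedGraph(A, nodeClasses = cls)
}

#' Write a graph to disk
#'
#' Inverse of [loadGraph()] for the same three formats. Edge lists store
#' each undirected edge once (src dst weight, with header); MTX uses the
#' symmetric coordinate kind.
#'
#' @param g a [GuidedGraph].
#' @param path output file.
#' @param format one of "edge_list", "dense_csv", "mtx".
#' @return `path`, invisibly.
#' @export
writeGraph <- function(g, path, format = c("edge_list", "dense_csv", "mtx")) {
    format <- match.arg(format)
    A <- adjacencyMatrix(g)
    switch(format,
        edge_list = {
            idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
            df <- data.frame(src = nodeIds(g)[idx[, 1]],
                             dst = nodeIds(g)[idx[, 2]],
                             weight = A[idx])
            utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        },
        dense_csv = utils::write.table(A, path, sep = ",", quote = FALSE,
                                       col.names = NA),
        mtx = Matrix::writeMM(methods::as(
            Matrix::forceSymmetric(Matrix::Matrix(A, sparse = TRUE)),
            "symmetricMatrix"), path)
    )
    invisible(path)
}

#' Connected-component check
#'
#' @param g a [GuidedGraph].
#' @return list with `connected` (TRUE iff one component) and `labels`
#'   (integer component label per node, named by node id).
#' @export
validateConnectivity <- function(g) {
    ig <- igraph::graph_from_adjacency_matrix(adjacencyMatrix(g),
        mode = "undirected", weighted = TRUE)
    comp <- igraph::components(ig)
    labels <- as.integer(comp$membership)
    names(labels) <- nodeIds(g)
    list(connected = comp$no == 1L, labels = labels)
}

#' Symmetric normalization of a graph
#'
#' Computes A = D^{-1/2} Ar D^{-1/2} and L = I - A, where Ar is the raw
#' adjacency and D the diagonal degree matrix. Eigenvalues of L then lie
#' in [0, 2]. This normalization emphasizes topology over nodal degree.
#'
#' @param g a [GuidedGraph].
#' @return a [NormalizedOperators].
#' @examples
#' g <- guidedGraph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
#' adjacencyMatrix(normalizeGraph(g))  # all nonzero entries equal 1/2
#' @export
normalizeGraph <- function(g) {
    Araw <- adjacencyMatrix(g)
    d <- rowSums(Araw)
    if (any(d <= 0))
        stop("zero-degree node(s): ",
             paste(utils::head(nodeIds(g)[d <= 0], 5L), collapse = ", "))
    s <- 1 / sqrt(d)
    A <- Araw * tcrossprod(s)     # a_ij / sqrt(d_i d_j)
    A <- (A + t(A)) / 2
    L <- diag(nrow(A)) - A
    dimnames(L) <- dimnames(A)
    new("NormalizedOperators", adjacency = A, laplacian = L,
        nodeIds = nodeIds(g))
}

#' Generate a three-class modular test graph
#'
#' Planted-partition (stochastic block model) generator producing a
#' connected, undirected, unweighted graph with three node classes, edges
#' drawn independently with probability `pWithin` inside a class and
#' `pBetween` across classes. Regenerates until connected (at most 100
#' attempts). Deterministic for a fixed seed and parameters; the caller's
#' RNG state is left untouched.
#'
#' @param nPerClass integer vector of three class sizes. The default
#'   mirrors a 279-node connectome split into sensory, inter- and
#'   motoneuron classes of 76, 75 and 128 nodes.
#' @param pWithin within-class edge probability.
#' @param pBetween between-class edge probability.
#' @param seed integer RNG seed.
#' @return a [GuidedGraph] with node classes "sensory", "inter", "motor".
#' @export
synthModularGraph <- function(nPerClass = c(76L, 75L, 128L), pWithin = 0.3,
                              pBetween = 0.05, seed = 1L) {
    stopifnot(length(nPerClass) == 3, all(nPerClass >= 1),
              pWithin >= 0, pWithin <= 1, pBetween >= 0, pBetween <= 1)
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
        get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
    n <- sum(nPerClass)
    cls <- rep(c("sensory", "inter", "motor"), times = nPerClass)
    same <- outer(cls, cls, "==")
    p <- ifelse(same, pWithin, pBetween)
    ut <- upper.tri(p)
    for (attempt in seq_len(100L)) {
        A <- matrix(0, n, n)
        A[ut] <- as.numeric(stats::runif(sum(ut)) < p[ut])
        A <- A + t(A)
        if (all(rowSums(A) > 0)) {
            g <- guidedGraph(A, nodeIds = sprintf("n%03d", seq_len(n)),
                             nodeClasses = cls)
            if (validateConnectivity(g)$connected) return(g)
        }
    }
    stop("could not generate a connected graph in 100 attempts; ",
         "increase pWithin/pBetween")
}
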