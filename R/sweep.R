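resolve_focus <- function(g, focusSet) {
    n <- nNodes(g)
    idx <- if (is.character(focusSet)) {
        match(focusSet, nodeIds(g))
    } else if (is.logical(focusSet)) {
        if (length(focusSet) != n) stop("logical focusSet must have length N")
        which(focusSet)
    } else {
        as.integer(focusSet)
    }
    if (any(is.na(idx)) || any(idx < 1) || any(idx > n))
        stop("focusSet contains unknown nodes")
    idx <- sort(unique(idx))
    if (!length(idx)) stop("focusSet must be nonempty")
    idx
}

#' Focus sweep: guided-embedding trajectories
#'
#' Gradually reduces the cooperation weights of all nodes outside a focus
#' set from 1 to 0 over a grid of focus strengths t, computing the guided
#' spectrum at each step and projecting nodes on the eigenvectors with the
#' second and third largest eigenvalues (by default). Each step's 2-D
#' coordinates are Procrustes-aligned to the previous step's aligned frame
#' (chained alignment; reflections allowed, no centering or scaling), so a
#' node traces a continuous trajectory. Step 1 has t = 1, i.e. M = I: the
#' unguided adjacency embedding is the reference frame.
#'
#' @param g a connected [GuidedGraph].
#' @param focusSet node ids (character), indices (integer) or logical mask
#'   of the nodes whose weight stays at 1; must be a nonempty proper subset.
#' @param nSteps number of sweep steps (>= 2); the grid is
#'   `seq(1, 0, length.out = nSteps)`.
#' @param order criterion approximation as in [criterionMatrix()].
#' @param components eigenvector index pair for the embedding.
#' @return a [Trajectory].
#' @export
focusSweep <- function(g, focusSet, nSteps = 51L, order = "exact",
                       components = c(2L, 3L)) {
    nSteps <- as.integer(nSteps)
    if (nSteps < 2L) stop("nSteps must be >= 2")
    idx <- resolve_focus(g, focusSet)
    n <- nNodes(g)
    conn <- validateConnectivity(g)
    if (!conn$connected) stop("focus sweep requires a connected graph")
    ops <- normalizeGraph(g)
    basis <- spectralBasis(ops)
    sqrtL <- sqrtLaplacianExact(basis)
    Q <- if (is.numeric(order))
        sqrtLaplacianTaylor(ops, as.integer(order), basis = basis)@approx
        else NULL
    lab <- if (is.numeric(order)) paste0("K=", as.integer(order)) else order
    tGrid <- seq(1, 0, length.out = nSteps)
    coords <- vector("list", nSteps)
    transforms <- vector("list", nSteps)
    prev <- NULL
    for (i in seq_len(nSteps)) {
        m <- rep(tGrid[i], n)
        m[idx] <- 1
        C <- if (is.null(Q)) criterionMatrix(ops, m, order = order,
                                             sqrtL = sqrtL)
             else criterion_from_Q(Q, m)
        gs <- guidedSpectrum(C, m, sqrtL, approxOrder = lab,
                             nodeIds = nodeIds(g))
        X <- suppressWarnings(embedCoords(gs, components))
        if (is.null(prev)) {
            coords[[i]] <- X
            transforms[[i]] <- diag(2)
        } else {
            pa <- procrustesAlign(X, prev)
            coords[[i]] <- pa$aligned
            transforms[[i]] <- pa$rotation
        }
        prev <- coords[[i]]
    }
    cls <- nodeClasses(g)
    new("Trajectory", steps = tGrid, coords = coords,
        transforms = transforms, focusSet = idx, nodeIds = nodeIds(g),
        nodeClass = if (is.null(cls)) character() else cls)
}

#' Cluster focus nodes at the sweep end point
#'
#' k-means clustering (multiple restarts, seeded) of the focus nodes'
#' end-point embedding coordinates, with the number of clusters chosen by
#' maximal mean silhouette width over `kRange`.
#'
#' @param traj a [Trajectory].
#' @param kRange candidate cluster counts (each >= 2; silhouette is
#'   undefined for a single cluster).
#' @param seed integer RNG seed (restored on exit).
#' @param nStart number of k-means restarts.
#' @return list with `labels` (named integer vector over focus nodes),
#'   `k` (chosen), `silhouette` (mean width at the chosen k), and
#'   `silhouetteByK`.
#' @export
clusterEndpoint <- function(traj, kRange = 2:10, seed = 1L, nStart = 50L) {
    kRange <- sort(unique(as.integer(kRange)))
    if (any(kRange < 2L))
        stop("silhouette is undefined for k < 2; choose k >= 2")
    X <- traj@coords[[length(traj@steps)]][traj@focusSet, , drop = FALSE]
    if (nrow(X) <= max(kRange))
        kRange <- kRange[kRange < nrow(X)]
    if (!length(kRange))
        stop("fewer focus nodes than the smallest requested k")
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
        get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
    d <- stats::dist(X)
    fits <- lapply(kRange, function(k)
        stats::kmeans(X, centers = k, nstart = nStart, iter.max = 100L))
    sil <- vapply(seq_along(kRange), function(i) {
        sw <- cluster::silhouette(fits[[i]]$cluster, d)
        mean(sw[, "sil_width"])
    }, numeric(1))
    best <- which.max(sil)
    labels <- fits[[best]]$cluster
    names(labels) <- focusNodes(traj)
    names(sil) <- kRange
    list(labels = labels, k = kRange[best], silhouette = sil[best],
         silhouetteByK = sil)
}
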