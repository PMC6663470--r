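#' @rdname GuidedGraph-class
#' @export
setMethod("nodeIds", "GuidedGraph", function(x) x@nodeIds)

#' @rdname GuidedGraph-class
#' @export
setMethod("nodeClasses", "GuidedGraph", function(x) {
    if (length(x@nodeClass)) x@nodeClass else NULL
})

#' @rdname GuidedGraph-class
#' @export
setMethod("nNodes", "GuidedGraph", function(x) length(x@nodeIds))

#' @rdname GuidedGraph-class
#' @export
setMethod("adjacencyMatrix", "GuidedGraph", function(x) x@adjacency)

#' @rdname GuidedGraph-class
#' @export
setMethod("degrees", "GuidedGraph", function(x) {
    d <- rowSums(x@adjacency)
    names(d) <- x@nodeIds
    d
})

#' @rdname NormalizedOperators-class
#' @export
setMethod("adjacencyMatrix", "NormalizedOperators", function(x) x@adjacency)

#' @rdname NormalizedOperators-class
#' @export
setMethod("laplacianMatrix", "NormalizedOperators", function(x) x@laplacian)

#' @rdname NormalizedOperators-class
#' @export
setMethod("nNodes", "NormalizedOperators", function(x) nrow(x@adjacency))

#' @rdname NormalizedOperators-class
#' @export
setMethod("nodeIds", "NormalizedOperators", function(x) x@nodeIds)

#' @rdname SpectralBasis-class
#' @export
setMethod("eigenvalues", "SpectralBasis", function(x) x@values)

#' @rdname SpectralBasis-class
#' @export
setMethod("eigenvectors", "SpectralBasis", function(x) x@vectors)

#' @rdname SpectralBasis-class
#' @export
setMethod("nNodes", "SpectralBasis", function(x) nrow(x@vectors))

#' @rdname SpectralBasis-class
#' @export
setMethod("nodeIds", "SpectralBasis", function(x) x@nodeIds)

#' @rdname SlepianSet-class
#' @export
setMethod("slepianValues", "SlepianSet", function(x) x@values)

#' @rdname SlepianSet-class
#' @export
setMethod("slepianVectors", "SlepianSet", function(x) x@vectors)

#' @rdname SlepianSet-class
#' @export
setMethod("bandwidth", "SlepianSet", function(x) x@bandwidth)

#' @rdname SlepianSet-class
#' @export
setMethod("designType", "SlepianSet", function(x) x@design)

#' @rdname GuidedSpectrum-class
#' @export
setMethod("zetaValues", "GuidedSpectrum", function(x) x@zetas)

#' @rdname GuidedSpectrum-class
#' @export
setMethod("muEquiv", "GuidedSpectrum", function(x) x@muEquiv)

#' @rdname GuidedSpectrum-class
#' @export
setMethod("xiEquiv", "GuidedSpectrum", function(x) x@xiEquiv)

#' @rdname GuidedSpectrum-class
#' @export
setMethod("eigenvectors", "GuidedSpectrum", function(x) x@vectors)

#' @rdname GuidedSpectrum-class
#' @export
setMethod("nNodes", "GuidedSpectrum", function(x) nrow(x@vectors))

#' @rdname Trajectory-class
#' @export
setMethod("trajectorySteps", "Trajectory", function(x) x@steps)

#' @rdname Trajectory-class
#' @export
setMethod("trajectoryCoords", "Trajectory", function(x) x@coords)

#' @rdname Trajectory-class
#' @export
setMethod("focusNodes", "Trajectory", function(x) x@nodeIds[x@focusSet])

#' @rdname Trajectory-class
#' @export
setMethod("nodeIds", "Trajectory", function(x) x@nodeIds)

setMethod("show", "GuidedGraph", function(object) {
    A <- object@adjacency
    cat("GuidedGraph with", length(object@nodeIds), "nodes and",
        sum(A[upper.tri(A)] != 0), "edges\n")
    if (length(object@nodeClass)) {
        tab <- table(object@nodeClass)
        cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
    }
    w <- A[upper.tri(A)]
    w <- w[w != 0]
    if (length(w))
        cat("  weights in [", min(w), ",", max(w), "]\n")
})

setMethod("show", "NormalizedOperators", function(object) {
    cat("NormalizedOperators on", nrow(object@adjacency), "nodes",
        "(A = D^-1/2 Ar D^-1/2, L = I - A)\n")
})

setMethod("show", "SpectralBasis", function(object) {
    l <- object@values
    cat("SpectralBasis:", length(l), "Laplacian eigenpairs, lambda in [",
        format(min(l), digits = 4), ",", format(max(l), digits = 4), "]\n")
})

setMethod("show", "TaylorApprox", function(object) {
    cat("TaylorApprox of L^(1/2): order K =", object@order,
        ", Frobenius error d_K =", format(object@error, digits = 6), "\n")
})

setMethod("show", "SlepianSet", function(object) {
    cat("SlepianSet (", object@design, "): W =", object@bandwidth,
        "of N =", nrow(object@vectors),
        ", |S| =", sum(object@selection), "\n")
    v <- object@values
    cat("  values in [", format(min(v), digits = 4), ",",
        format(max(v), digits = 4), "]\n")
})

setMethod("show", "GuidedSpectrum", function(object) {
    z <- object@zetas
    cat("GuidedSpectrum (", object@approxOrder, "):", length(z),
        "eigenpairs, zeta in [", format(min(z), digits = 4), ",",
        format(max(z), digits = 4), "], m_max =",
        format(max(object@cooperation), digits = 4), "\n")
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory:", length(object@steps), "steps (t = 1 .. 0),",
        length(object@nodeIds), "nodes,",
        length(object@focusSet), "in focus\n")
})

#' Flatten a Trajectory to long format
#'
#' @param x a [Trajectory].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns step, t, node_id, class, focus, x, y.
#' @method as.data.frame Trajectory
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    n <- length(x@nodeIds)
    ns <- length(x@steps)
    cls <- if (length(x@nodeClass)) x@nodeClass else rep(NA_character_, n)
    focus <- seq_len(n) %in% x@focusSet
    do.call(rbind, lapply(seq_len(ns), function(i) {
        data.frame(
            step = i,
            t = x@steps[i],
            node_id = x@nodeIds,
            class = cls,
            focus = focus,
            x = x@coords[[i]][, 1],
            y = x@coords[[i]][, 2],
            stringsAsFactors = FALSE
        )
    }))
}

setMethod("as.data.frame", "Trajectory", as.data.frame.Trajectory)
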