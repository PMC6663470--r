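check_cooperation <- function(m, n) {
    m <- as.numeric(m)
    if (length(m) == 1L) m <- rep(m, n)
    if (length(m) != n)
        stop("cooperation vector length ", length(m), " != N = ", n)
    if (any(!is.finite(m)) || any(m < 0))
        stop("cooperation weights must be finite and nonnegative")
    m
}

#' Guided-embedding criterion matrix
#'
#' The guided criterion zeta = mu - xi (energy concentration minus modified
#' embedded distance, both weighted by the diagonal cooperation matrix M)
#' is the Rayleigh quotient of the symmetric matrix
#' \deqn{M - L^{1/2} M L^{1/2},}
#' computed here exactly or through Taylor approximations of L^{1/2}:
#' \describe{
#'   \item{exact}{M - L^{1/2} M L^{1/2}; for M = I this equals the
#'     normalized adjacency A exactly.}
#'   \item{linear}{(MA + AM)/2: each direct edge a_ij is reweighted by the
#'     average (m_i + m_j)/2 of the endpoint cooperation weights, so an edge
#'     survives at half weight when only one endpoint has weight 0.}
#'   \item{quadratic}{adds (MA^2 + A^2 M)/8 - AMA/4: length-2 paths i-l-j
#'     are reweighted by the endpoint weights and penalized by the weight
#'     m_l of the intermediate node.}
#'   \item{order K (integer)}{M - Q_K M Q_K with Q_K the order-K Taylor
#'     square root (square-root-first truncation, then symmetrized).}
#' }
#'
#' @param ops a [NormalizedOperators].
#' @param m nonnegative cooperation weights (diagonal of M); a scalar is
#'   recycled.
#' @param order "exact", "linear", "quadratic", or a positive integer K.
#' @param sqrtL optional precomputed exact L^{1/2} (only used by "exact").
#' @return symmetric N x N criterion matrix.
#' @examples
#' g <- synthModularGraph(c(5, 5, 5), 0.6, 0.2, seed = 1)
#' ops <- normalizeGraph(g)
#' max(abs(criterionMatrix(ops, 1) - adjacencyMatrix(ops)))  # ~0 at M = I
#' @export
criterionMatrix <- function(ops, m, order = "exact", sqrtL = NULL) {
    A <- adjacencyMatrix(ops)
    n <- nrow(A)
    m <- check_cooperation(m, n)
    if (is.numeric(order)) {
        K <- as.integer(order)
        Q <- sqrtLaplacianTaylor(ops, K, basis = NULL)@approx
        C <- diag(m) - Q %*% (m * Q)
    } else {
        order <- match.arg(order, c("exact", "linear", "quadratic"))
        C <- switch(order,
            exact = {
                if (is.null(sqrtL)) sqrtL <- sqrtLaplacianExact(
                    spectralBasis(ops))
                diag(m) - sqrtL %*% (m * sqrtL)
            },
            linear = A * outer(m, m, "+") / 2,
            quadratic = {
                A2 <- A %*% A
                A * outer(m, m, "+") / 2 +
                    A2 * outer(m, m, "+") / 8 - (A %*% (m * A)) / 4
            })
    }
    C <- symmetrize(C)
    dimnames(C) <- dimnames(A)
    C
}

# Order-K criterion as in sqrtLaplacianTaylor but reusing a precomputed
# Taylor square root (sweep-internal fast path).
criterion_from_Q <- function(Q, m) {
    symmetrize(diag(m) - Q %*% (m * Q))
}

#' Eigendecomposition of the guided criterion
#'
#' Diagonalizes a guided criterion matrix; eigenvalues zeta are sorted
#' decreasingly and must satisfy m_max >= zeta_1 and zeta_N >= -2 m_max
#' (a consequence of the normalized-Laplacian spectrum lying in [0, 2]).
#' Each eigenvector also gets its equivalent energy concentration
#' mu_k = g_k' M g_k and modified embedded distance
#' xi_k = g_k' L^{1/2} M L^{1/2} g_k, always measured against the exact
#' operators so that approximated spectra are assessed in one fixed frame.
#' For the exact criterion zeta_k = mu_k - xi_k.
#'
#' @param C criterion matrix from [criterionMatrix()].
#' @param m the cooperation weights used to build `C`.
#' @param sqrtL exact Laplacian square root (for the equivalent xi).
#' @param approxOrder label recorded in the result ("exact", "linear",
#'   "quadratic" or "K=<int>").
#' @param nodeIds optional node identifiers.
#' @return a [GuidedSpectrum].
#' @export
guidedSpectrum <- function(C, m, sqrtL, approxOrder = "exact",
                           nodeIds = NULL) {
    n <- nrow(C)
    m <- check_cooperation(m, n)
    if (max(abs(C - t(C))) > 1e-10) stop("criterion matrix must be symmetric")
    e <- eigen(symmetrize(C), symmetric = TRUE)    # descending
    G <- fix_signs(e$vectors)
    mmax <- max(m)
    if (e$values[1] > mmax + 1e-6 || e$values[n] < -2 * mmax - 1e-6)
        stop("eigenvalue bound violated: zeta must lie in [-2 m_max, m_max]")
    muv <- colSums(m * G^2)
    H <- sqrtL %*% G
    xiv <- colSums(m * H^2)
    ids <- if (is.null(nodeIds)) {
        if (!is.null(rownames(C))) rownames(C)
        else as.character(seq_len(n))
    } else nodeIds
    rownames(G) <- ids
    new("GuidedSpectrum", zetas = e$values, vectors = G, muEquiv = muv,
        xiEquiv = xiv, cooperation = m, approxOrder = as.character(approxOrder),
        nodeIds = ids)
}

#' One-call guided decomposition of a graph
#'
#' Normalizes the graph, builds the requested criterion matrix and
#' diagonalizes it.
#'
#' @param g a [GuidedGraph].
#' @param m cooperation weights (scalar recycled).
#' @param order as in [criterionMatrix()].
#' @return a [GuidedSpectrum].
#' @export
guidedDecomposition <- function(g, m, order = "exact") {
    ops <- normalizeGraph(g)
    basis <- spectralBasis(ops)
    sqrtL <- sqrtLaplacianExact(basis)
    m <- check_cooperation(m, nNodes(g))
    C <- criterionMatrix(ops, m, order = order, sqrtL = sqrtL)
    lab <- if (is.numeric(order)) paste0("K=", as.integer(order)) else order
    guidedSpectrum(C, m, sqrtL, approxOrder = lab, nodeIds = nodeIds(g))
}

#' Criterion-level approximation error
#'
#' Frobenius distance d_{K,M} between the exact criterion matrix and an
#' approximated one (linear, quadratic or order K) for the same cooperation
#' weights. Non-increasing in K, and shrinking as cooperation weights
#' approach zero.
#'
#' @param ops a [NormalizedOperators].
#' @param m cooperation weights.
#' @param order approximation order as in [criterionMatrix()].
#' @param sqrtL optional precomputed exact square root.
#' @return scalar Frobenius distance.
#' @export
criterionError <- function(ops, m, order, sqrtL = NULL) {
    if (is.null(sqrtL)) sqrtL <- sqrtLaplacianExact(spectralBasis(ops))
    exact <- criterionMatrix(ops, m, order = "exact", sqrtL = sqrtL)
    approx <- criterionMatrix(ops, m, order = order)
    norm(exact - approx, type = "F")
}

#' @rdname embedCoords
#' @export
setMethod("embedCoords", "GuidedSpectrum", function(x,
        components = c(2L, 3L)) {
    z <- zetaValues(x)
    components <- as.integer(components)
    if (length(components) != 2 || any(components < 1) ||
        any(components > length(z)))
        stop("components must be two valid eigenvector indices")
    gaps <- vapply(components, function(i) {
        others <- setdiff(seq_along(z), i)
        min(abs(z[i] - z[others]))
    }, numeric(1))
    if (any(gaps < 1e-10))
        warning("requested component(s) lie in a degenerate eigenvalue ",
                "cluster; the embedding plane is arbitrary within the ",
                "subspace")
    X <- eigenvectors(x)[, components, drop = FALSE]
    colnames(X) <- paste0("g", components)
    X
})

#' @rdname embedCoords
#' @export
setMethod("embedCoords", "SpectralBasis", function(x,
        components = c(2L, 3L)) {
    l <- eigenvalues(x)
    components <- as.integer(components)
    if (length(components) != 2 || any(components < 1) ||
        any(components > length(l)))
        stop("components must be two valid eigenvector indices")
    X <- eigenvectors(x)[, components, drop = FALSE]
    colnames(X) <- paste0("u", components)
    X
})

#' Orthogonal Procrustes alignment
#'
#' Finds the orthogonal matrix R (rotation or reflection; no centering, no
#' scaling) minimizing ||X R - Y||_F, via the SVD of X'Y. The origin of a
#' spectral embedding is meaningful and vector norms carry concentration
#' information, so only the rotational/reflective ambiguity of
#' eigendecompositions is removed.
#'
#' @param X coordinates to align (N x d).
#' @param Y reference coordinates (same shape, same node order).
#' @return list with `aligned` (X R), `rotation` (R), and `residual`
#'   (||XR - Y||_F).
#' @export
procrustesAlign <- function(X, Y) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    if (!all(dim(X) == dim(Y))) stop("X and Y must have identical shape")
    M <- crossprod(X, Y)
    if (max(abs(M)) == 0) {
        warning("rank-0 cross-product; returning identity transform")
        R <- diag(ncol(X))
    } else {
        sv <- svd(M)
        R <- sv$u %*% t(sv$v)
    }
    aligned <- X %*% R
    dimnames(aligned) <- dimnames(Y)
    list(aligned = aligned, rotation = R,
         residual = norm(aligned - Y, type = "F"))
}
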