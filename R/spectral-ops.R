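# Deterministic eigenvector sign convention: flip each column so that its
# largest-magnitude entry is positive; which.max breaks ties at the lowest
# index.
fix_signs <- function(V) {
    for (k in seq_len(ncol(V))) {
        i <- which.max(abs(V[, k]))
        if (V[i, k] < 0) V[, k] <- -V[, k]
    }
    V
}

symmetrize <- function(X) (X + t(X)) / 2

#' Eigendecomposition of the normalized Laplacian
#'
#' Returns the graph Fourier basis: orthonormal eigenvectors of L with
#' eigenvalues sorted increasingly (lambda_1 = 0 for a connected graph,
#' with eigenvector proportional to D^{1/2} 1). Column signs follow a
#' deterministic convention (largest-magnitude entry positive).
#'
#' @param ops a [NormalizedOperators].
#' @return a [SpectralBasis].
#' @export
spectralBasis <- function(ops) {
    L <- laplacianMatrix(ops)
    if (any(!is.finite(L))) stop("non-finite entries in Laplacian")
    e <- eigen(L, symmetric = TRUE)     # descending
    idx <- rev(seq_along(e$values))
    values <- e$values[idx]
    # snap floating-point dust at the spectrum edges: sqrt() amplifies an
    # eigenvalue error of 1e-16 at zero into 1e-8
    values[abs(values) < 1e-12] <- 0
    values[values > -1e-10 & values < 0] <- 0
    values[values > 2 & values < 2 + 1e-10] <- 2
    U <- fix_signs(e$vectors[, idx, drop = FALSE])
    rownames(U) <- nodeIds(ops)
    resid <- max(abs(L - U %*% (values * t(U))))
    if (resid > 1e-8)
        stop("eigendecomposition residual too large: ", resid)
    new("SpectralBasis", vectors = U, values = values, nodeIds = nodeIds(ops))
}

#' Graph Fourier transform and its inverse
#'
#' `gft` expands a graph signal in the Laplacian eigenbasis (x_hat = U' x);
#' `igft` reconstructs the signal (x = U x_hat). With an orthonormal basis
#' the pair is an exact round trip and preserves the 2-norm (Parseval).
#'
#' @param basis a [SpectralBasis].
#' @param x numeric vector of length N (for `gft`) or spectral coefficients
#'   (for `igft`).
#' @return numeric vector of length N.
#' @export
gft <- function(basis, x) {
    U <- eigenvectors(basis)
    if (length(x) != nrow(U))
        stop("signal length ", length(x), " does not match N = ", nrow(U))
    drop(crossprod(U, x))
}

#' @rdname gft
#' @export
igft <- function(basis, x) {
    U <- eigenvectors(basis)
    if (length(x) != ncol(U))
        stop("coefficient length ", length(x), " does not match N = ", ncol(U))
    drop(U %*% x)
}

#' Exact matrix square root of the normalized Laplacian
#'
#' L^{1/2} = U diag(sqrt(lambda)) U'. Eigenvalues in (-1e-10, 0) are clamped
#' to zero; anything below -1e-6 signals a numerically invalid basis.
#'
#' @param basis a [SpectralBasis].
#' @return symmetric positive semidefinite matrix with (L^{1/2})^2 = L.
#' @export
sqrtLaplacianExact <- function(basis) {
    l <- eigenvalues(basis)
    if (any(l < -1e-6))
        stop("negative eigenvalue ", min(l), " below tolerance -1e-6")
    l <- pmax(l, 0)
    U <- eigenvectors(basis)
    S <- symmetrize(U %*% (sqrt(l) * t(U)))
    dimnames(S) <- list(rownames(U), rownames(U))
    S
}

#' Taylor coefficients of the matrix square-root series
#'
#' The expansion L^{1/2} = I - sum_{k>=1} c_k A^k has coefficients
#' c_k = (2k)! / (2^{2k} (k!)^2 (2k-1)), all positive and strictly
#' decreasing (c_1 = 1/2, c_2 = 1/8, c_3 = 1/16, ...). Evaluated with the
#' multiplicative recurrence c_{k+1} = c_k (2k-1)/(2k+2), which avoids
#' factorial overflow up to k = 200 and beyond; each factor is an exact
#' rational, so accumulated error is O(k * eps).
#'
#' @param k positive integer (vectorized).
#' @return numeric vector of coefficients c_k.
#' @examples
#' taylorCoefficient(1:4)  # 1/2, 1/8, 1/16, 5/128
#' @export
taylorCoefficient <- function(k) {
    k <- as.integer(k)
    if (any(k <= 0)) stop("k must be a positive integer")
    kmax <- max(k)
    cs <- numeric(kmax)
    cs[1] <- 0.5
    if (kmax > 1)
        for (j in seq_len(kmax - 1))
            cs[j + 1] <- cs[j] * (2 * j - 1) / (2 * j + 2)
    cs[k]
}

# Signed scalar-series twin t_k = (-1)^(k-1) c_k of the expansion of
# sqrt(x) about 1 (internal; the matrix series absorbs the sign).
taylor_scalar_coefficient <- function(k) {
    (-1)^(k - 1) * taylorCoefficient(k)
}

#' Taylor approximation of the Laplacian square root
#'
#' Order-K truncation Q_K = I - sum_{k<=K} c_k A^k of the series for
#' L^{1/2}, together with the Frobenius distance d_K to the exact square
#' root. d_K is non-increasing in K; graphs with larger eigengaps in the
#' low band tend to have smaller d_K because near-zero eigenvalues dominate
#' the remainder.
#'
#' @param ops a [NormalizedOperators].
#' @param K truncation order, 1 <= K <= 10000.
#' @param basis optional precomputed [SpectralBasis] (used for the exact
#'   square root in the error term).
#' @return a [TaylorApprox].
#' @export
sqrtLaplacianTaylor <- function(ops, K, basis = NULL) {
    K <- as.integer(K)
    if (K < 1L) stop("K must be >= 1")
    if (K > 10000L) stop("K > 10000 is not supported")
    A <- adjacencyMatrix(ops)
    cs <- taylorCoefficient(seq_len(K))
    Ak <- diag(nrow(A))
    acc <- diag(nrow(A))
    for (k in seq_len(K)) {
        Ak <- Ak %*% A
        acc <- acc - cs[k] * Ak
    }
    acc <- symmetrize(acc)
    if (is.null(basis)) basis <- spectralBasis(ops)
    dK <- norm(sqrtLaplacianExact(basis) - acc, type = "F")
    new("TaylorApprox", order = K, coefficients = cs, approx = acc,
        error = dK)
}

#' Lagrange remainder bound for the square-root Taylor truncation
#'
#' Bounds d_K = ||L^{1/2} - Q_K||_F by sum_i |R_K(lambda_i)|, where R_K is
#' the Lagrange remainder of the scalar series of sqrt(x) about 1. The
#' (K+1)-th derivative is bounded by its supremum over the closed interval
#' between lambda_i and 1 (the conservative reading); since the derivative
#' magnitude of sqrt decreases in its argument, the supremum sits at the
#' interval end closest to zero. At lambda = 0, where the Lagrange form
#' degenerates, the exact scalar remainder 1 - sum_{k<=K} c_k is used (it
#' equals |sqrt(0) - Q_K(0)| exactly).
#'
#' @param basis a [SpectralBasis].
#' @param K truncation order.
#' @return scalar upper bound on d_K.
#' @export
taylorRemainderBound <- function(basis, K) {
    K <- as.integer(K)
    stopifnot(K >= 1L)
    l <- pmax(eigenvalues(basis), 0)
    cK1 <- taylorCoefficient(K + 1L)      # |f^(K+1)(1)| / (K+1)!
    tail_at_zero <- 1 - sum(taylorCoefficient(seq_len(K)))
    terms <- vapply(l, function(x) {
        if (x < 1e-12) return(tail_at_zero)
        y <- min(x, 1)                     # sup of |f^(K+1)| on [x,1] or [1,x]
        cK1 * y^(0.5 - (K + 1)) * abs(x - 1)^(K + 1)
    }, numeric(1))
    sum(terms)
}
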