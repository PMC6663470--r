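check_selection <- function(s, n) {
    s <- as.numeric(s)
    if (length(s) != n)
        stop("selection vector length ", length(s), " != N = ", n)
    if (!all(s %in% c(0, 1)))
        stop("selection vector must be binary (0/1)")
    s
}

#' Energy-concentration graph Slepians
#'
#' Bandlimited vectors maximizing the energy fraction mu = g'Sg / g'g inside
#' a selected node subset S, for signals restricted to the first W Laplacian
#' eigenvectors. Solved by eigendecomposition of the W x W concentration
#' matrix C = W' U' S U W; values mu_k in [0, 1] are returned decreasingly.
#' The vertex-domain vectors g_k = U g_hat_k are orthonormal over the whole
#' graph and orthogonal over S (g_k' S g_l = mu_k delta_kl). At full
#' bandwidth (W = N) the spectrum of C degenerates to the diagonal entries
#' of S: two flat subspaces at 1 and 0.
#'
#' @param basis a [SpectralBasis].
#' @param selection binary vector (1 = node selected), the diagonal of S.
#' @param W bandwidth, 1 <= W <= N.
#' @return a [SlepianSet] with design "concentration".
#' @export
concentrationSlepians <- function(basis, selection, W) {
    U <- eigenvectors(basis)
    n <- nrow(U)
    s <- check_selection(selection, n)
    W <- as.integer(W)
    if (W < 1L || W > n) stop("bandwidth W must be in 1..N")
    Uw <- U[, seq_len(W), drop = FALSE]
    C <- symmetrize(crossprod(Uw, s * Uw))
    e <- eigen(C, symmetric = TRUE)      # descending, as required for mu
    G <- fix_signs(Uw %*% e$vectors)
    rownames(G) <- nodeIds(basis)
    new("SlepianSet", design = "concentration", bandwidth = W,
        selection = s, vectors = G, values = e$values,
        nodeIds = nodeIds(basis))
}

#' Modified-embedded-distance graph Slepians
#'
#' Bandlimited vectors minimizing the localized smoothness
#' xi = g' L^{1/2} S L^{1/2} g / g'g, a "graph frequency" restricted to the
#' selected subset. Solved by eigendecomposition of the W x W block of
#' U' L^{1/2} S L^{1/2} U; values xi_k >= 0 are returned increasingly.
#' For S = I and W = N the operator reverts to L itself. On a connected
#' graph at full bandwidth the number of zero values equals the number of
#' zeros on the diagonal of S.
#'
#' @param basis a [SpectralBasis].
#' @param sqrtL exact Laplacian square root from [sqrtLaplacianExact()].
#' @param selection binary selection vector.
#' @param W bandwidth, 1 <= W <= N.
#' @return a [SlepianSet] with design "embedded_distance".
#' @export
embeddedDistanceSlepians <- function(basis, sqrtL, selection, W) {
    U <- eigenvectors(basis)
    n <- nrow(U)
    s <- check_selection(selection, n)
    W <- as.integer(W)
    if (W < 1L || W > n) stop("bandwidth W must be in 1..N")
    B <- sqrtL %*% U[, seq_len(W), drop = FALSE]   # L^{1/2} U_W
    Cemb <- symmetrize(crossprod(B, s * B))
    e <- eigen(Cemb, symmetric = TRUE)
    idx <- rev(seq_len(W))                          # ascending xi
    values <- e$values[idx]
    G <- fix_signs(U[, seq_len(W), drop = FALSE] %*%
                   e$vectors[, idx, drop = FALSE])
    rownames(G) <- nodeIds(basis)
    new("SlepianSet", design = "embedded_distance", bandwidth = W,
        selection = s, vectors = G, values = values,
        nodeIds = nodeIds(basis))
}

#' Degeneracy diagnostics for a Slepian spectrum
#'
#' Counts eigenvalues numerically equal to 0 and to 1. At full bandwidth on
#' a connected graph the concentration design degenerates into two flat
#' subspaces: |S| values at 1 and (N - |S|) values at 0; the
#' embedded-distance design has exactly (N - |S|) zero values.
#'
#' @param set a [SlepianSet] or [GuidedSpectrum].
#' @param tol classification tolerance (default 1e-8).
#' @return list with `nZero`, `nOne`, `nIntermediate`, `bandwidth`, `design`.
#' @export
degeneracyReport <- function(set, tol = 1e-8) {
    if (methods::is(set, "GuidedSpectrum")) {
        v <- zetaValues(set)
        design <- "guided"
        W <- length(v)
    } else {
        v <- slepianValues(set)
        design <- designType(set)
        W <- bandwidth(set)
    }
    nZero <- sum(abs(v) <= tol)
    nOne <- sum(abs(v - 1) <= tol)
    list(nZero = nZero, nOne = nOne,
         nIntermediate = length(v) - nZero - nOne,
         bandwidth = W, design = design)
}

#' Export a Slepian spectrum as a table
#'
#' One row per Slepian vector: index, value, and the energy fraction inside
#' the selected subset (for eigenspectrum plots).
#'
#' @param set a [SlepianSet].
#' @return data.frame with columns k, value, energy_in_S.
#' @export
slepianSpectrumTable <- function(set) {
    G <- slepianVectors(set)
    s <- set@selection
    data.frame(
        k = seq_along(slepianValues(set)),
        value = slepianValues(set),
        energy_in_S = colSums(s * G^2) / colSums(G^2)
    )
}
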