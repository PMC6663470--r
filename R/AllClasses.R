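#' @import methods
NULL

#' GuidedGraph: an undirected weighted graph with node metadata
#'
#' Container for the raw symmetric adjacency matrix of an undirected graph
#' together with node identifiers and optional node classes (e.g. neuron
#' types). Self-loops and negative weights are disallowed; every node must
#' have positive degree.
#'
#' @slot nodeIds character vector of unique node identifiers, in the order
#'   used by rows/columns of the adjacency matrix.
#' @slot nodeClass character vector of per-node class labels (length 0 when
#'   no metadata is attached).
#' @slot adjacency numeric N x N symmetric matrix of nonnegative edge
#'   weights with zero diagonal.
#'
#' @seealso [guidedGraph()], [loadGraph()], [normalizeGraph()]
#' @export
setClass("GuidedGraph",
    slots = c(
        nodeIds = "character",
        nodeClass = "character",
        adjacency = "matrix"
    )
)

setValidity("GuidedGraph", function(object) {
    A <- object@adjacency
    n <- length(object@nodeIds)
    msg <- character()
    if (!is.numeric(A) || nrow(A) != ncol(A))
        msg <- c(msg, "adjacency must be a square numeric matrix")
    else {
        if (nrow(A) != n)
            msg <- c(msg, "length(nodeIds) must equal matrix dimension")
        if (anyDuplicated(object@nodeIds))
            msg <- c(msg, "nodeIds must be unique")
        if (any(!is.finite(A)))
            msg <- c(msg, "adjacency contains non-finite values")
        else {
            if (max(abs(A - t(A))) > 1e-12)
                msg <- c(msg, "adjacency must be symmetric (tol 1e-12)")
            if (any(diag(A) != 0))
                msg <- c(msg, "self-loops are not allowed (nonzero diagonal)")
            if (any(A < 0))
                msg <- c(msg, "edge weights must be nonnegative")
            deg <- rowSums(A)
            if (any(deg <= 0)) {
                bad <- object@nodeIds[which(deg <= 0)]
                msg <- c(msg, paste0("zero-degree node(s): ",
                    paste(utils::head(bad, 5L), collapse = ", ")))
            }
        }
        nc <- length(object@nodeClass)
        if (nc != 0L && nc != n)
            msg <- c(msg, "nodeClass must be empty or one label per node")
    }
    if (length(msg)) msg else TRUE
})

#' NormalizedOperators: symmetrically normalized adjacency and Laplacian
#'
#' Holds A = D^{-1/2} A_raw D^{-1/2} and L = I - A for a [GuidedGraph].
#' Eigenvalues of L lie in [0, 2].
#'
#' @slot adjacency normalized adjacency matrix A.
#' @slot laplacian normalized Laplacian L = I - A.
#' @slot nodeIds node identifiers carried over from the graph.
#' @export
setClass("NormalizedOperators",
    slots = c(
        adjacency = "matrix",
        laplacian = "matrix",
        nodeIds = "character"
    )
)

setValidity("NormalizedOperators", function(object) {
    A <- object@adjacency
    L <- object@laplacian
    msg <- character()
    if (max(abs(A - t(A))) > 1e-12) msg <- c(msg, "A must be symmetric")
    if (max(abs(L - t(L))) > 1e-12) msg <- c(msg, "L must be symmetric")
    if (max(abs((diag(nrow(A)) - A) - L)) > 1e-12)
        msg <- c(msg, "L must equal I - A")
    if (length(msg)) msg else TRUE
})

#' SpectralBasis: eigenpairs of the normalized Laplacian
#'
#' Orthonormal eigenvectors (columns of `vectors`) and ascending eigenvalues
#' of the normalized Laplacian, defining the graph Fourier transform. For a
#' connected graph the first eigenvalue is 0 with eigenvector proportional
#' to D^{1/2} 1.
#'
#' @slot vectors orthonormal eigenvector matrix U (columns u_k).
#' @slot values eigenvalues sorted increasingly, in [0, 2].
#' @slot nodeIds node identifiers.
#' @export
setClass("SpectralBasis",
    slots = c(
        vectors = "matrix",
        values = "numeric",
        nodeIds = "character"
    )
)

setValidity("SpectralBasis", function(object) {
    U <- object@vectors
    l <- object@values
    msg <- character()
    if (ncol(U) != length(l))
        msg <- c(msg, "one eigenvalue per eigenvector required")
    if (is.unsorted(l, strictly = FALSE))
        msg <- c(msg, "eigenvalues must be sorted increasingly")
    if (length(l) && (min(l) < -1e-10 || max(l) > 2 + 1e-10))
        msg <- c(msg, "eigenvalues must lie in [0, 2] (tol 1e-10)")
    if (length(msg)) msg else TRUE
})

#' TaylorApprox: truncated Taylor series of the Laplacian square root
#'
#' Order-K truncation L^{1/2} ~ I - sum_{k<=K} c_k A^k with
#' c_k = (2k)! / (2^{2k} (k!)^2 (2k-1)), together with the Frobenius
#' distance to the exact square root.
#'
#' @slot order truncation order K >= 1.
#' @slot coefficients the coefficients c_1..c_K (all positive, decreasing).
#' @slot approx the approximation matrix I - sum c_k A^k.
#' @slot error Frobenius distance d_K to the exact L^{1/2}.
#' @export
setClass("TaylorApprox",
    slots = c(
        order = "integer",
        coefficients = "numeric",
        approx = "matrix",
        error = "numeric"
    )
)

setValidity("TaylorApprox", function(object) {
    msg <- character()
    if (object@order < 1L) msg <- c(msg, "order must be >= 1")
    if (length(object@coefficients) != object@order)
        msg <- c(msg, "need exactly `order` coefficients")
    if (any(object@coefficients <= 0))
        msg <- c(msg, "Taylor coefficients must all be positive")
    if (length(msg)) msg else TRUE
})

#' SlepianSet: a classical graph Slepian design
#'
#' Bandlimited vectors optimizing either energy concentration (eigenvalues
#' mu in [0,1], sorted decreasingly) or modified embedded distance
#' (eigenvalues xi >= 0, sorted increasingly) on a selected node subset.
#'
#' @slot design either "concentration" or "embedded_distance".
#' @slot bandwidth the bandlimit W (number of low-frequency Fourier modes).
#' @slot selection binary selection vector s (diagonal of S).
#' @slot vectors vertex-domain Slepian vectors g_k (N x W, orthonormal).
#' @slot values mu_k (descending) or xi_k (ascending).
#' @slot nodeIds node identifiers.
#' @export
setClass("SlepianSet",
    slots = c(
        design = "character",
        bandwidth = "integer",
        selection = "numeric",
        vectors = "matrix",
        values = "numeric",
        nodeIds = "character"
    )
)

setValidity("SlepianSet", function(object) {
    msg <- character()
    if (!object@design %in% c("concentration", "embedded_distance"))
        msg <- c(msg, "design must be 'concentration' or 'embedded_distance'")
    if (!all(object@selection %in% c(0, 1)))
        msg <- c(msg, "selection must be binary")
    if (object@bandwidth < 1L || object@bandwidth > nrow(object@vectors))
        msg <- c(msg, "bandwidth must lie in 1..N")
    if (ncol(object@vectors) != length(object@values))
        msg <- c(msg, "one value per Slepian vector required")
    if (length(msg)) msg else TRUE
})

#' GuidedSpectrum: eigenpairs of the guided embedding criterion
#'
#' Eigendecomposition of the guided criterion matrix M - L^{1/2} M L^{1/2}
#' (or a Taylor approximation of it). Eigenvalues zeta are sorted
#' decreasingly and satisfy m_max >= zeta_1 and zeta_N >= -2 m_max. Each
#' eigenvector additionally carries its equivalent energy concentration
#' mu_k = g_k' M g_k and modified embedded distance
#' xi_k = g_k' L^{1/2} M L^{1/2} g_k, always measured against the exact
#' operators.
#'
#' @slot zetas eigenvalues, decreasing.
#' @slot vectors orthonormal eigenvectors (columns).
#' @slot muEquiv equivalent energy concentration per eigenvector.
#' @slot xiEquiv equivalent modified embedded distance per eigenvector.
#' @slot cooperation the cooperation weights m (diagonal of M).
#' @slot approxOrder "exact", "linear", "quadratic", or "K=<int>".
#' @slot nodeIds node identifiers.
#' @export
setClass("GuidedSpectrum",
    slots = c(
        zetas = "numeric",
        vectors = "matrix",
        muEquiv = "numeric",
        xiEquiv = "numeric",
        cooperation = "numeric",
        approxOrder = "character",
        nodeIds = "character"
    )
)

setValidity("GuidedSpectrum", function(object) {
    msg <- character()
    if (is.unsorted(rev(object@zetas), strictly = FALSE))
        msg <- c(msg, "zetas must be sorted decreasingly")
    if (any(object@cooperation < 0))
        msg <- c(msg, "cooperation weights must be nonnegative")
    if (ncol(object@vectors) != length(object@zetas))
        msg <- c(msg, "one eigenvalue per eigenvector required")
    if (length(msg)) msg else TRUE
})

#' Trajectory: node positions across a focus sweep
#'
#' For a grid of focus strengths t from 1 down to 0, the 2-D embedding
#' coordinates of every node, each step Procrustes-aligned to the previous
#' step's aligned frame. Step 1 (t = 1, M = I) is the unguided reference.
#'
#' @slot steps focus strengths t, from 1 to 0.
#' @slot coords list of N x 2 aligned coordinate matrices, one per step.
#' @slot transforms list of 2 x 2 orthogonal alignment transforms.
#' @slot focusSet integer indices of the nodes held at weight 1.
#' @slot nodeIds node identifiers.
#' @slot nodeClass per-node class labels (may be empty).
#' @export
setClass("Trajectory",
    slots = c(
        steps = "numeric",
        coords = "list",
        transforms = "list",
        focusSet = "integer",
        nodeIds = "character",
        nodeClass = "character"
    )
)

setValidity("Trajectory", function(object) {
    msg <- character()
    if (length(object@coords) != length(object@steps))
        msg <- c(msg, "one coordinate matrix per step required")
    if (length(object@steps) && (object@steps[1] != 1 ||
        object@steps[length(object@steps)] != 0))
        msg <- c(msg, "steps must run from 1 to 0")
    if (!length(object@focusSet))
        msg <- c(msg, "focusSet must be nonempty")
    if (length(msg)) msg else TRUE
})
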