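#' @rdname GuidedGraph-class
#' @param x,object an object.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname GuidedGraph-class
#' @export
setGeneric("nodeClasses", function(x) standardGeneric("nodeClasses"))

#' @rdname GuidedGraph-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname GuidedGraph-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname GuidedGraph-class
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' @rdname NormalizedOperators-class
#' @param x an object.
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))

#' @rdname SpectralBasis-class
#' @param x an object.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname SpectralBasis-class
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname SlepianSet-class
#' @param x an object.
#' @export
setGeneric("slepianValues", function(x) standardGeneric("slepianValues"))

#' @rdname SlepianSet-class
#' @export
setGeneric("slepianVectors", function(x) standardGeneric("slepianVectors"))

#' @rdname SlepianSet-class
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))

#' @rdname SlepianSet-class
#' @export
setGeneric("designType", function(x) standardGeneric("designType"))

#' @rdname GuidedSpectrum-class
#' @param x an object.
#' @export
setGeneric("zetaValues", function(x) standardGeneric("zetaValues"))

#' @rdname GuidedSpectrum-class
#' @export
setGeneric("muEquiv", function(x) standardGeneric("muEquiv"))

#' @rdname GuidedSpectrum-class
#' @export
setGeneric("xiEquiv", function(x) standardGeneric("xiEquiv"))

#' @rdname Trajectory-class
#' @param x an object.
#' @export
setGeneric("trajectorySteps", function(x) standardGeneric("trajectorySteps"))

#' @rdname Trajectory-class
#' @export
setGeneric("trajectoryCoords", function(x) standardGeneric("trajectoryCoords"))

#' @rdname Trajectory-class
#' @export
setGeneric("focusNodes", function(x) standardGeneric("focusNodes"))

#' Embed nodes on two eigenvectors
#'
#' Project the nodes of a graph onto two eigenvectors of a spectral
#' decomposition, giving 2-D embedding coordinates. For a [GuidedSpectrum]
#' the components index eigenvectors by descending zeta (the default, c(2, 3),
#' matches the guided-embedding convention of using the second and third
#' largest eigenvalues). For a [SpectralBasis] (Laplacian-embedding baseline)
#' they index by ascending eigenvalue, so c(2, 3) selects the Fiedler vector
#' and the next one.
#'
#' @param x a [GuidedSpectrum] or [SpectralBasis].
#' @param components integer pair of eigenvector indices.
#' @return numeric N x 2 matrix of coordinates (rownames = node ids).
#' @export
setGeneric("embedCoords",
    function(x, components = c(2L, 3L)) standardGeneric("embedCoords"))
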