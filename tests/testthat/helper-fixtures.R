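# Fixtures and independent oracles shared across test files.

triangleGraph <- function() {
    guidedGraph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3),
                nodeIds = c("a", "b", "c"))
}

ringGraph <- function(n) {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
        j <- i %% n + 1
        A[i, j] <- 1
        A[j, i] <- 1
    }
    guidedGraph(A)
}

smallFixture <- function(seed = 1, nPerClass = c(10, 10, 10)) {
    synthModularGraph(nPerClass, pWithin = 0.5, pBetween = 0.1, seed = seed)
}

# Breadth-first-search component labeling, independent of igraph.
bfsComponents <- function(A) {
    n <- nrow(A)
    labels <- integer(n)
    comp <- 0L
    for (start in seq_len(n)) {
        if (labels[start] != 0L) next
        comp <- comp + 1L
        queue <- start
        labels[start] <- comp
        while (length(queue)) {
            v <- queue[1]
            queue <- queue[-1]
            nb <- which(A[v, ] > 0 & labels == 0L)
            labels[nb] <- comp
            queue <- c(queue, nb)
        }
    }
    labels
}

# Rayleigh-quotient extremum over a 2-D bandlimited subspace by dense
# angle-grid search: g(theta) = cos(theta) u1 + sin(theta) u2.
rayleighGridExtrema <- function(u1, u2, Q) {
    theta <- seq(0, pi, length.out = 20001)
    vals <- vapply(theta, function(th) {
        gv <- cos(th) * u1 + sin(th) * u2
        drop(crossprod(gv, Q %*% gv) / crossprod(gv))
    }, numeric(1))
    c(max = max(vals), min = min(vals))
}

# Brute-force 2-D orthogonal Procrustes: best rotation or reflection over a
# dense angle grid.
procrustesGridOracle <- function(X, Y) {
    theta <- seq(0, 2 * pi, length.out = 40001)
    best <- Inf
    for (refl in c(1, -1)) {
        for (th in theta) {
            R <- matrix(c(cos(th), sin(th), -refl * sin(th),
                          refl * cos(th)), 2, 2)
            r <- norm(X %*% R - Y, type = "F")
            if (r < best) best <- r
        }
    }
    best
}

# Independent PSD matrix square root via a classical Jacobi eigenvalue
# sweep (no LAPACK eigensolver involved).
jacobiSqrtm <- function(S, tol = 1e-14, maxSweeps = 100) {
    n <- nrow(S)
    V <- diag(n)
    for (sweep in seq_len(maxSweeps)) {
        off <- 0
        for (p in 1:(n - 1)) for (q in (p + 1):n) {
            off <- max(off, abs(S[p, q]))
            if (abs(S[p, q]) < tol) next
            theta <- 0.5 * atan2(2 * S[p, q], S[q, q] - S[p, p])
            cs <- cos(theta); sn <- sin(theta)
            R <- diag(n)
            R[p, p] <- cs; R[q, q] <- cs
            R[p, q] <- sn; R[q, p] <- -sn
            S <- t(R) %*% S %*% R
            V <- V %*% R
        }
        if (off < tol) break
    }
    l <- pmax(diag(S), 0)
    l[l < 1e-12] <- 0      # sqrt amplifies eigenvalue dust at zero
    V %*% (sqrt(l) * t(V))
}

expect_orthonormal <- function(V, tol = 1e-8) {
    expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), tol)
}
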