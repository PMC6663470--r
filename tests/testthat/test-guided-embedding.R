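test_that("exact criterion reduces to A at M = I and to 0 at M = 0", {
    for (seed in 1:5) {
        g <- smallFixture(seed = seed)
        ops <- normalizeGraph(g)
        sqrtL <- sqrtLaplacianExact(spectralBasis(ops))
        C1 <- criterionMatrix(ops, 1, order = "exact", sqrtL = sqrtL)
        expect_lt(max(abs(C1 - adjacencyMatrix(ops))), 1e-12)
        C0 <- criterionMatrix(ops, 0, order = "exact", sqrtL = sqrtL)
        expect_lt(max(abs(C0)), 1e-12)
    }
    expect_error(criterionMatrix(normalizeGraph(smallFixture(1)), -1),
                 "nonnegative")
})

test_that("exact criterion agrees with an alternate square-root route", {
    ops <- normalizeGraph(triangleGraph())
    m <- c(1, 1, 0)
    C <- criterionMatrix(ops, m, order = "exact")
    # oracle: Jacobi-sweep square root instead of the LAPACK eigen route
    Sdb <- jacobiSqrtm(laplacianMatrix(ops))
    Cdb <- diag(m) - Sdb %*% diag(m) %*% Sdb
    expect_equal(unname(C), unname((Cdb + t(Cdb)) / 2), tolerance = 1e-8)
})

test_that("linear criterion reweights edges by mean cooperation", {
    g <- smallFixture(seed = 2)
    n <- nNodes(g)
    ops <- normalizeGraph(g)
    A <- adjacencyMatrix(ops)
    set.seed(42)
    m <- runif(n)
    Clin <- criterionMatrix(ops, m, order = "linear")
    expect_equal(unname(Clin),
                 unname((diag(m) %*% A + A %*% diag(m)) / 2),
                 tolerance = 1e-14)
    i <- which(A > 0, arr.ind = TRUE)[1, ]
    expect_equal(Clin[i[1], i[2]],
                 A[i[1], i[2]] * (m[i[1]] + m[i[2]]) / 2)

    # an edge with one zero-weight endpoint survives at half weight
    m2 <- rep(1, n); m2[i[1]] <- 0
    Clin2 <- criterionMatrix(ops, m2, order = "linear")
    expect_equal(Clin2[i[1], i[2]], A[i[1], i[2]] / 2)

    # M = I keeps A unchanged
    expect_equal(unname(criterionMatrix(ops, 1, order = "linear")),
                 unname(A))
})

test_that("quadratic criterion reweights length-2 paths", {
    ops <- normalizeGraph(triangleGraph())
    A <- adjacencyMatrix(ops)
    m <- c(1, 1, 0)
    Cq <- criterionMatrix(ops, m, order = "quadratic")
    # hand-computed oracle: entry (i,j) is
    # a_ij (m_i+m_j)/2 + [sum_l a_il a_lj] (m_i+m_j)/8 - sum_l m_l a_il a_lj / 4
    oracle <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
        p2 <- sum(A[i, ] * A[, j])
        pen <- sum(m * A[i, ] * A[, j])
        oracle[i, j] <- A[i, j] * (m[i] + m[j]) / 2 +
            p2 * (m[i] + m[j]) / 8 - pen / 4
    }
    expect_equal(unname(Cq), unname((oracle + t(oracle)) / 2),
                 tolerance = 1e-14)
    # the (1,2) entry combines the direct edge with the penalized path via 3
    expect_equal(Cq[1, 2], 0.5 * 1 + 0.25 * 2 / 8 - 0, tolerance = 1e-14)

    # quadratic terms cancel at M = I
    g <- smallFixture(seed = 3)
    ops2 <- normalizeGraph(g)
    expect_equal(unname(criterionMatrix(ops2, 1, order = "quadratic")),
                 unname(adjacencyMatrix(ops2)), tolerance = 1e-12)
})

test_that("order-K criterion nests the linear form and converges", {
    g <- smallFixture(seed = 4)
    n <- nNodes(g)
    ops <- normalizeGraph(g)
    A <- adjacencyMatrix(ops)
    set.seed(7)
    m <- runif(n)

    # K = 1 with the cross term dropped is the linear form:
    # M - Q1 M Q1 = (MA + AM)/2 - A M A / 4 with Q1 = I - A/2
    C1 <- criterionMatrix(ops, m, order = 1L)
    cross <- A %*% diag(m) %*% A / 4
    expect_equal(unname(C1 + (cross + t(cross)) / 2),
                 unname(criterionMatrix(ops, m, order = "linear")),
                 tolerance = 1e-12)

    # d_{K,M} non-increasing in K, and the approximation hierarchy
    # linear >= quadratic >= order-20 across seeded fixtures
    for (seed in 1:20) {
        gs <- smallFixture(seed = seed)
        opss <- normalizeGraph(gs)
        set.seed(100 + seed)
        ms <- runif(nNodes(gs))
        sqrtL <- sqrtLaplacianExact(spectralBasis(opss))
        eK <- vapply(c(1L, 2L, 5L, 10L, 20L), function(K)
            criterionError(opss, ms, K, sqrtL = sqrtL), numeric(1))
        expect_true(all(diff(eK) <= 1e-10))
        eLin <- criterionError(opss, ms, "linear", sqrtL = sqrtL)
        eQuad <- criterionError(opss, ms, "quadratic", sqrtL = sqrtL)
        expect_lte(eQuad, eLin)
        expect_lte(eK[5], eQuad)
    }
})

test_that("guided spectrum has the adjacency limit and zeta = mu - xi", {
    # K3, M = I: adjacency spectrum {1, -1/2, -1/2}
    gs <- guidedDecomposition(triangleGraph(), 1)
    expect_equal(zetaValues(gs), c(1, -0.5, -0.5), tolerance = 1e-10)

    # M = 0: all zeta vanish
    gs0 <- guidedDecomposition(triangleGraph(), 0)
    expect_equal(zetaValues(gs0), rep(0, 3), tolerance = 1e-12)

    # Rayleigh-quotient consistency on a fixture with random M
    g <- smallFixture(seed = 6)
    set.seed(11)
    m <- runif(nNodes(g))
    gsm <- guidedDecomposition(g, m)
    expect_equal(zetaValues(gsm), muEquiv(gsm) - xiEquiv(gsm),
                 tolerance = 1e-8)
    expect_orthonormal(eigenvectors(gsm), tol = 1e-8)
})

test_that("zeta eigenvalue bounds hold on 50 seeded fixtures", {
    for (seed in 1:50) {
        g <- synthModularGraph(c(6, 6, 6), 0.5, 0.15, seed = seed)
        ops <- normalizeGraph(g)
        set.seed(500 + seed)
        m <- runif(18, 0, 3)
        gs <- guidedDecomposition(g, m)
        z <- zetaValues(gs)
        expect_lte(z[1], max(m) + 1e-8)
        expect_gte(z[length(z)], -2 * max(m) - 1e-8)
        # M = I criterion equals A and shares its spectrum
        C1 <- criterionMatrix(ops, 1,
            sqrtL = sqrtLaplacianExact(spectralBasis(ops)))
        expect_lt(max(abs(C1 - adjacencyMatrix(ops))), 1e-12)
    }
})

test_that("binary cooperation yields the outside-S zero subspace", {
    g <- synthModularGraph(c(20, 20, 20), 0.3, 0.08, seed = 9)
    n <- nNodes(g)
    m <- as.numeric(seq_len(n) <= 20)     # |S| = 20, z_S = 40
    gs <- guidedDecomposition(g, m)
    z <- zetaValues(gs)
    mid <- abs(z) < 1e-8
    # vectors with zeta ~ 0 in mid-spectrum are concentrated outside S:
    # both equivalent criteria vanish simultaneously
    expect_gte(sum(mid), n - 2 * sum(m))
    expect_true(all(muEquiv(gs)[mid] < 1e-6))
    expect_true(all(xiEquiv(gs)[mid] < 1e-6))
    # opposing objectives: few eigenvectors combine high mu with low xi
    good <- sum(muEquiv(gs) > 0.99 & xiEquiv(gs) < 0.01)
    expect_lte(good, sum(m) / 2)
})

test_that("embedding selects eigenvectors and flags degeneracy", {
    g <- smallFixture(seed = 10)
    gs <- guidedDecomposition(g, 1)
    ops <- normalizeGraph(g)

    # unguided embedding equals the adjacency eigenvector embedding
    X <- embedCoords(gs, c(2, 3))
    e <- eigen(adjacencyMatrix(ops), symmetric = TRUE)
    for (j in 1:2) {
        v <- e$vectors[, j + 1]
        expect_lt(min(max(abs(X[, j] - v)), max(abs(X[, j] + v))), 1e-8)
    }
    expect_false(isTRUE(all.equal(embedCoords(gs, c(1, 2)), X,
                                  check.attributes = FALSE)))
    expect_error(embedCoords(gs, c(0, 2)), "valid")

    # a degenerate requested pair triggers a warning (triangle: zeta2 = zeta3)
    gst <- guidedDecomposition(triangleGraph(), 1)
    expect_warning(embedCoords(gst, c(2, 3)), "degenerate")

    # Laplacian-embedding baseline of a ring lies on a circle
    ring <- ringGraph(24)
    bR <- spectralBasis(normalizeGraph(ring))
    XR <- embedCoords(bR, c(2, 3))
    radii <- sqrt(rowSums(XR^2))
    expect_lt(diff(range(radii)), 1e-10)
})

test_that("orthogonal Procrustes recovers planted transforms", {
    set.seed(21)
    X <- matrix(rnorm(60), 30, 2)

    idem <- procrustesAlign(X, X)
    expect_equal(idem$rotation, diag(2), tolerance = 1e-12)
    expect_lt(idem$residual, 1e-10)

    th <- runif(1, 0, 2 * pi)
    R0 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rec <- procrustesAlign(X, X %*% R0)
    expect_lt(rec$residual, 1e-10)
    expect_equal(rec$rotation, R0, tolerance = 1e-10)

    # reflections are allowed and recovered
    refl <- R0 %*% diag(c(1, -1))
    expect_lt(procrustesAlign(X, X %*% refl)$residual, 1e-10)

    # noisy targets: aligned residual <= unaligned, transform orthogonal,
    # and residual matches a dense angle-grid oracle
    for (trial in 1:20) {
        set.seed(300 + trial)
        Y <- X %*% R0 + matrix(rnorm(60, sd = 0.1), 30, 2)
        pa <- procrustesAlign(X, Y)
        expect_lte(pa$residual, norm(X - Y, "F") + 1e-12)
        expect_lt(max(abs(crossprod(pa$rotation) - diag(2))), 1e-10)
        if (trial <= 3)
            expect_equal(pa$residual, procrustesGridOracle(X, Y),
                         tolerance = 1e-4)
    }

    expect_warning(procrustesAlign(matrix(0, 5, 2), matrix(0, 5, 2)),
                   "rank-0")
})
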