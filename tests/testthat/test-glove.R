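test_that("weight function matches its closed form and is non-decreasing", {
    expect_equal(gloveWeight(15000), 1)
    expect_equal(gloveWeight(15000 / 16), 16^(-0.75))
    expect_equal(gloveWeight(15000 / 16), 0.125)
    expect_equal(gloveWeight(2e6), 1)
    grid <- gloveWeight(seq(1, 4e4, length.out = 200))
    expect_true(all(diff(grid) >= 0))
    expect_true(all(grid > 0 & grid <= 1))
    expect_error(gloveWeight(0), "positive")
    expect_error(gloveWeight(-3), "positive")
})

test_that("loss agrees with hand results and the double-loop oracle", {
    V <- 4L; D <- 3L
    zero <- new("GloveModel", W = matrix(0, V, D), Wc = matrix(0, V, D),
                b = numeric(V), bc = numeric(V), xMax = 10, alpha = 0.75,
                k = 1L, history = numeric(0))
    X1 <- Matrix::sparseMatrix(i = 1L, j = 2L, x = exp(1), dims = c(V, V))
    # all parameters zero, single entry X_12 = e: J = f(e) (1 - 0)^2
    expect_equal(gloveLoss(zero, X1), gloveWeight(exp(1), 10, 0.75))

    # a model that reproduces log X exactly has zero loss
    set.seed(1)
    Xs <- Matrix::sparseMatrix(i = c(1L, 2L, 3L), j = c(2L, 3L, 1L),
                               x = c(2, 5, 9), dims = c(V, V))
    fit <- zero
    fit@b <- c(log(2), log(5), log(9), 0)
    fit@bc <- numeric(V)
    # b_i covers rows 1..3 matched to their single context each: adjust so
    # w_i' w~_j + b_i + b~_j = log X_ij for the three nonzero entries
    expect_equal(gloveLoss(fit, Xs), 0, tolerance = 1e-12)

    set.seed(2)
    for (rep in 1:10) {
        m <- randomGloveModel(V, D)
        dense <- matrix(rpois(V * V, 1), V, V)
        Xr <- methods::as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
        expect_equal(gloveLoss(m, Xr),
                     refGloveLoss(m@W, m@Wc, m@b, m@bc, dense, m@xMax,
                                  m@alpha),
                     tolerance = 1e-10)
    }
})

test_that("analytic gradient matches central finite differences", {
    set.seed(3)
    for (rep in 1:5) {
        V <- 4L; D <- 2L
        m <- randomGloveModel(V, D)
        dense <- matrix(rpois(V * V, 1.2), V, V)
        X <- Matrix::Matrix(dense, sparse = TRUE)
        gr <- gloveGradient(m, X)
        expect_lt(max(abs(gr$dW - fdGloveSlot(m, X, "W"))), 1e-5)
        expect_lt(max(abs(gr$dWc - fdGloveSlot(m, X, "Wc"))), 1e-5)
        expect_lt(max(abs(gr$db - fdGloveSlot(m, X, "b"))), 1e-5)
        expect_lt(max(abs(gr$dbc - fdGloveSlot(m, X, "bc"))), 1e-5)
    }
})

test_that("training reduces the loss monotonically on a toy corpus", {
    set.seed(4)
    corp <- randomCorpus(4, 6, c(10, 12))
    X <- kmerCooccurrence(corp, windowDiameter = 3, vocabSizeOverride = 6L)
    fit <- trainGlove(X, dim = 4, xMax = 10, maxIters = 40, seed = 5)
    h <- fit@history
    expect_true(all(diff(h[1:10]) < 0))   # strictly decreasing early on
    expect_lt(h[length(h)], h[1])
})

test_that("training is deterministic and the padding row stays zero", {
    set.seed(6)
    corp <- randomCorpus(3, 5, c(8, 10))
    X <- kmerCooccurrence(corp, windowDiameter = 3, vocabSizeOverride = 5L)
    a <- trainGlove(X, dim = 3, xMax = 10, maxIters = 15, seed = 9)
    b <- trainGlove(X, dim = 3, xMax = 10, maxIters = 15, seed = 9)
    expect_identical(embeddingTable(a), embeddingTable(b))
    expect_false(identical(
        embeddingTable(a),
        embeddingTable(trainGlove(X, dim = 3, xMax = 10, maxIters = 15,
                                  seed = 10))))
    E <- embeddingTable(a)
    expect_equal(E[1L, ], rep(0, 3))
    expect_true(all(is.finite(E)))
    expect_equal(dim(E), c(6L, 3L))
})

test_that("embeddings separate co-occurrence communities", {
    set.seed(8)
    corp <- communityCorpus(V = 8L, nSeq = 60L, len = 40L)
    X <- kmerCooccurrence(corp, windowDiameter = 5, vocabSizeOverride = 8L)
    fit <- trainGlove(X, dim = 6, xMax = 20, maxIters = 120, seed = 21)
    E <- embeddingTable(fit)[-1L, ]
    cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    within <- c(); between <- c()
    for (i in 1:7) for (j in (i + 1):8) {
        cs <- cosine(E[i, ], E[j, ])
        if ((i <= 4) == (j <= 4)) within <- c(within, cs)
        else between <- c(between, cs)
    }
    expect_gt(mean(within), mean(between))
})

test_that("embedding text export round-trips", {
    set.seed(10)
    v <- kmerVocabulary(1)
    corp <- randomCorpus(3, 4, c(8, 10))
    X <- kmerCooccurrence(corp, windowDiameter = 3)
    fit <- trainGlove(X, dim = 3, xMax = 10, maxIters = 10, seed = 2)
    f <- tempfile()
    writeEmbedding(fit, v, f)
    E2 <- readEmbedding(f, v)
    expect_equal(E2, embeddingTable(fit), tolerance = 1e-6)
})
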