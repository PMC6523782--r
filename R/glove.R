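#' Global k-mer/k-mer co-occurrence matrix
#'
#' Counts, over the whole tokenized corpus, how often each k-mer appears in
#' the context window of each other k-mer. For every token position p and
#' every other position q with \eqn{|p-q| \le} radius (radius =
#' `floor(windowDiameter/2)`), `X[token_p, token_q]` is incremented; with
#' the default symmetric window and unit increments X is symmetric. Windows
#' never cross sequence boundaries. With `distanceWeighting = TRUE` the
#' increment is \eqn{1/|p-q|} instead of 1 (the weighting used by the
#' original GloVe corpus builder); with `symmetric = FALSE` only the left
#' context (q < p) is counted.
#'
#' @param corpus a [KmerCorpus-class] (or plain list of integer token
#'   vectors with attribute-free values in `[1, V]`).
#' @param windowDiameter total window extent (default 15, i.e. radius 7).
#' @param vocabSizeOverride vocabulary size V; defaults to `4^k` taken from
#'   the corpus.
#' @param distanceWeighting logical, increment by 1/distance.
#' @param symmetric logical, count right as well as left context.
#' @return A [CooccurrenceMatrix-class].
#' @export
kmerCooccurrence <- function(corpus, windowDiameter = 15L,
                             vocabSizeOverride = NULL,
                             distanceWeighting = FALSE, symmetric = TRUE) {
    if (is(corpus, "KmerCorpus")) {
        toks <- corpus@tokens
        k <- corpus@k
    } else {
        toks <- corpus
        k <- 1L
    }
    if (!length(toks)) stop("empty corpus")
    windowDiameter <- as.integer(windowDiameter)
    if (windowDiameter < 1L) stop("'windowDiameter' must be >= 1")
    radius <- max(1L, windowDiameter %/% 2L)
    V <- if (!is.null(vocabSizeOverride)) as.integer(vocabSizeOverride)
         else 4L^k
    ii <- vector("list", radius); jj <- vector("list", radius)
    ww <- vector("list", radius)
    for (d in seq_len(radius)) {
        # token pairs exactly d apart, per sequence, never crossing ends
        a <- lapply(toks, function(tk) {
            L <- length(tk)
            if (L <= d) return(NULL)
            cbind(tk[seq_len(L - d)], tk[(d + 1L):L])
        })
        a <- do.call(rbind, a)
        if (is.null(a)) next
        w <- if (distanceWeighting) rep(1 / d, nrow(a)) else rep(1, nrow(a))
        if (symmetric) {           # count both directions
            ii[[d]] <- c(a[, 1L], a[, 2L])
            jj[[d]] <- c(a[, 2L], a[, 1L])
            ww[[d]] <- c(w, w)
        } else {                   # left context only: X[p's token, q's token]
            ii[[d]] <- a[, 2L]
            jj[[d]] <- a[, 1L]
            ww[[d]] <- w
        }
    }
    i <- unlist(ii); j <- unlist(jj); w <- unlist(ww)
    counts <- if (length(i))
        Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(V, V))
    else
        Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(V, V))
    new("CooccurrenceMatrix", counts = methods::as(counts, "CsparseMatrix"),
        windowDiameter = windowDiameter, k = as.integer(round(log(V, 4))))
}

#' GloVe weight function
#'
#' The non-decreasing weight applied to each nonzero co-occurrence count in
#' the embedding loss: \eqn{f(x) = (x/x_{max})^\alpha} for
#' \eqn{x < x_{max}} and 1 otherwise. Defined for positive counts only
#' (zero-count pairs never enter the loss).
#'
#' @param x positive co-occurrence count(s).
#' @param xMax cutoff above which the weight saturates at 1 (default 15000).
#' @param alpha exponent in (0, 1] (default 0.75).
#' @return Numeric weights in (0, 1].
#' @export
gloveWeight <- function(x, xMax = 15000, alpha = 0.75) {
    if (any(x <= 0)) stop("weights are defined for positive counts only")
    ifelse(x < xMax, (x / xMax)^alpha, 1)
}

# one-off preprocessing of the nonzero structure: column-ordered sparse
# template plus aligned row/column/count vectors
.glovePrep <- function(X) {
    if (is(X, "CooccurrenceMatrix")) X <- X@counts
    Xs <- Matrix::drop0(methods::as(methods::as(X, "CsparseMatrix"),
                                    "generalMatrix"))
    V <- nrow(Xs)
    i <- Xs@i + 1L
    j <- rep.int(seq_len(V), diff(Xs@p))
    list(Xs = Xs, V = V, i = i, j = j, x = Xs@x,
         lin = if (as.double(V)^2 < 2^31) (j - 1L) * V + i else NULL)
}

# loss and full analytic gradient over the nonzero entries. The error
# terms come either from one dense V x V dot-product matrix (fast while
# V^2 stays modest) or from chunked row gathers; the gradient itself is
# sparse-times-dense algebra:
#   dW = M Wc, dWc = M^T W, db = rowSums(M), dbc = colSums(M)
# with M holding 2 f(X_ij) e_ij at the nonzero positions.
.gloveLossGrad <- function(W, Wc, b, bc, prep, xMax, alpha,
                           gradient = TRUE, chunk = 500000L) {
    V <- prep$V
    f <- gloveWeight(prep$x, xMax, alpha)
    if (!is.null(prep$lin) && as.double(V)^2 <= 2e8) {
        dots <- tcrossprod(W, Wc)[prep$lin]
    } else {
        n <- length(prep$x)
        dots <- numeric(n)
        for (s in seq.int(1L, n, by = chunk)) {
            idx <- s:min(s + chunk - 1L, n)
            dots[idx] <- rowSums(W[prep$i[idx], , drop = FALSE] *
                                 Wc[prep$j[idx], , drop = FALSE])
        }
    }
    e <- dots + b[prep$i] + bc[prep$j] - log(prep$x)
    J <- sum(f * e * e)
    if (!gradient) return(list(loss = J))
    M <- prep$Xs
    M@x <- 2 * f * e
    list(loss = J,
         dW = as.matrix(M %*% Wc),
         dWc = as.matrix(Matrix::crossprod(M, W)),
         db = Matrix::rowSums(M),
         dbc = Matrix::colSums(M))
}

#' GloVe loss
#'
#' Weighted least-squares objective of the embedding factorization:
#' \deqn{J = \sum_{X_{ij} \ne 0} f(X_{ij})\,(w_i^\top \tilde w_j + b_i +
#' \tilde b_j - \log X_{ij})^2}
#' summed over the nonzero co-occurrence entries only.
#'
#' @param model a [GloveModel-class].
#' @param X a [CooccurrenceMatrix-class] with V = `nrow(model@W)`.
#' @return Nonnegative scalar loss.
#' @export
gloveLoss <- function(model, X) {
    counts <- if (is(X, "CooccurrenceMatrix")) X@counts else X
    if (nrow(counts) != nrow(model@W))
        stop("dimension mismatch between model (V = ", nrow(model@W),
             ") and counts (V = ", nrow(counts), ")")
    prep <- .glovePrep(counts)
    .gloveLossGrad(model@W, model@Wc, model@b, model@bc, prep,
                   model@xMax, model@alpha, gradient = FALSE)$loss
}

#' Analytic gradient of the GloVe loss
#'
#' @inheritParams gloveLoss
#' @return A list with components `loss`, `dW`, `dWc`, `db`, `dbc`.
#' @export
gloveGradient <- function(model, X) {
    counts <- if (is(X, "CooccurrenceMatrix")) X@counts else X
    if (nrow(counts) != nrow(model@W))
        stop("dimension mismatch between model and counts")
    prep <- .glovePrep(counts)
    .gloveLossGrad(model@W, model@Wc, model@b, model@bc, prep,
                   model@xMax, model@alpha, gradient = TRUE)
}

#' Train k-mer embeddings by GloVe factorization
#'
#' Minimizes the weighted least-squares loss over the nonzero co-occurrence
#' entries with full-batch gradient iterations: per-parameter adaptive
#' steps (AdaGrad, the default) or plain gradient descent. Parameters are
#' initialized from a small uniform distribution under `seed`, so training
#' is deterministic.
#'
#' @param X a [CooccurrenceMatrix-class].
#' @param dim embedding dimension D (default 100).
#' @param xMax weight cutoff (default 15000).
#' @param alpha weight exponent (default 0.75).
#' @param maxIters full gradient iterations (default 3000).
#' @param learningRate step size (default 0.05, the customary AdaGrad rate
#'   for this loss; use something like 1e-4 with `optimizer = "sgd"`).
#' @param optimizer "adagrad" or "sgd".
#' @param seed integer RNG seed for initialization.
#' @return A [GloveModel-class]; extract vectors with [embeddingTable()].
#' @export
trainGlove <- function(X, dim = 100L, xMax = 15000, alpha = 0.75,
                       maxIters = 3000L, learningRate = 0.05,
                       optimizer = c("adagrad", "sgd"), seed = 1L) {
    optimizer <- match.arg(optimizer)
    counts <- if (is(X, "CooccurrenceMatrix")) X@counts else X
    V <- nrow(counts)
    prep <- .glovePrep(counts)
    if (!length(prep$x)) stop("co-occurrence matrix has no nonzero entries")
    set.seed(seed)
    D <- as.integer(dim)
    init <- function(n) (runif(n) - 0.5) / (D + 1)
    W <- matrix(init(V * D), V, D); Wc <- matrix(init(V * D), V, D)
    b <- init(V); bc <- init(V)
    eps <- 1e-8
    if (optimizer == "adagrad") {
        GW <- matrix(0, V, D); GWc <- matrix(0, V, D)
        Gb <- numeric(V); Gbc <- numeric(V)
    }
    history <- numeric(maxIters)
    for (it in seq_len(maxIters)) {
        g <- .gloveLossGrad(W, Wc, b, bc, prep, xMax, alpha)
        if (!is.finite(g$loss))
            stop("non-finite GloVe loss at iteration ", it)
        history[it] <- g$loss
        if (optimizer == "adagrad") {
            GW <- GW + g$dW^2;   W <- W - learningRate * g$dW / sqrt(GW + eps)
            GWc <- GWc + g$dWc^2; Wc <- Wc - learningRate * g$dWc / sqrt(GWc + eps)
            Gb <- Gb + g$db^2;   b <- b - learningRate * g$db / sqrt(Gb + eps)
            Gbc <- Gbc + g$dbc^2; bc <- bc - learningRate * g$dbc / sqrt(Gbc + eps)
        } else {
            W <- W - learningRate * g$dW
            Wc <- Wc - learningRate * g$dWc
            b <- b - learningRate * g$db
            bc <- bc - learningRate * g$dbc
        }
    }
    new("GloveModel", W = W, Wc = Wc, b = b, bc = bc, xMax = xMax,
        alpha = alpha, k = as.integer(round(log(V, 4))), history = history)
}

#' Extract the embedding table
#'
#' Returns the `(V+1) x D` matrix used by the classifier's lookup layer:
#' row 1 is the all-zero padding vector (token 0) and row `i + 1` is the
#' vector for k-mer index i. By default main and context vectors are summed
#' (the standard GloVe export); `combine = "main"` returns `W` alone.
#'
#' @param model a [GloveModel-class].
#' @param combine "sum" (w + w~) or "main" (w only).
#' @return Numeric matrix of dimension `(V+1) x D`.
#' @export
embeddingTable <- function(model, combine = c("sum", "main")) {
    combine <- match.arg(combine)
    E <- if (combine == "sum") model@W + model@Wc else model@W
    rbind(matrix(0, 1L, ncol(E)), E)
}

#' Export embeddings as plain-text word vectors
#'
#' One line per k-mer: the k-mer string followed by its D coordinates,
#' whitespace-separated (the conventional text word-vector format).
#'
#' @param model a [GloveModel-class].
#' @param vocab the matching [KmerVocabulary-class].
#' @param path output file.
#' @param combine passed to [embeddingTable()].
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(model, vocab, path, combine = "sum") {
    E <- embeddingTable(model, combine)[-1L, , drop = FALSE]
    lines <- paste(vocab@kmers,
                   apply(E, 1L, function(r) paste(format(r, digits = 8L),
                                                  collapse = " ")))
    writeLines(lines, path)
    invisible(path)
}

#' Read embeddings written by [writeEmbedding()]
#'
#' @param path text word-vector file.
#' @param vocab the matching [KmerVocabulary-class]; rows are reordered to
#'   vocabulary order and the zero padding row is prepended.
#' @return `(V+1) x D` embedding matrix.
#' @export
readEmbedding <- function(path, vocab) {
    lines <- strsplit(readLines(path), "[[:space:]]+")
    words <- vapply(lines, `[`, character(1L), 1L)
    E <- do.call(rbind, lapply(lines, function(f) as.numeric(f[-1L])))
    ord <- match(vocab@kmers, words)
    if (anyNA(ord)) stop("embedding file does not cover the vocabulary")
    rbind(matrix(0, 1L, ncol(E)), E[ord, , drop = FALSE])
}
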