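#' Construct a network configuration
#'
#' Defaults reproduce the reference architecture and optimization settings:
#' token length 1000, embedding dimension 100, 80 LSTM hidden units per
#' direction, convolution stages with 100/80/80 filters of kernel lengths
#' 10/8/8 and max-pool lengths 4/2/2, ReLU activations, direct flatten into
#' the logistic layer, SGD with learning rate 1e-4, batch size 128, at most
#' 12 epochs with early stopping (10% validation carve-out, patience 2).
#'
#' @param maxLen,embeddingDim,lstmHidden,convFilters,convKernels,poolSizes
#'   architecture settings; see [NetworkConfig-class].
#' @param useBlstm,useConv ablation switches; at least one must be TRUE.
#' @param denseWidth optional ReLU dense layer width (0 = direct flatten).
#' @param learningRate,batchSize,maxEpochs,valFraction,patience,optimizer
#'   optimization settings.
#' @param freezeEmbedding keep the embedding table fixed during training.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return A [NetworkConfig-class].
#' @export
networkConfig <- function(maxLen = 1000L, embeddingDim = 100L,
                          lstmHidden = 80L, convFilters = c(100L, 80L, 80L),
                          convKernels = c(10L, 8L, 8L),
                          poolSizes = c(4L, 2L, 2L), useBlstm = TRUE,
                          useConv = TRUE, denseWidth = 0L,
                          learningRate = 1e-4, batchSize = 128L,
                          maxEpochs = 12L, valFraction = 0.1,
                          patience = 2L, optimizer = "sgd",
                          freezeEmbedding = FALSE, seed = 1L) {
    if (!useBlstm && !useConv)
        stop("at most one of the BLSTM and convolution stages can be ablated")
    new("NetworkConfig", maxLen = as.integer(maxLen),
        embeddingDim = as.integer(embeddingDim),
        lstmHidden = as.integer(lstmHidden),
        convFilters = as.integer(convFilters),
        convKernels = as.integer(convKernels),
        poolSizes = as.integer(poolSizes), useBlstm = useBlstm,
        useConv = useConv, denseWidth = as.integer(denseWidth),
        learningRate = learningRate, batchSize = as.integer(batchSize),
        maxEpochs = as.integer(maxEpochs), valFraction = valFraction,
        patience = as.integer(patience), optimizer = optimizer,
        freezeEmbedding = freezeEmbedding, seed = as.integer(seed))
}

#' Per-stage output lengths of the convolution stack
#'
#' Applies the valid-convolution and non-overlapping pooling bookkeeping
#' \eqn{L_{out} = \lfloor (L_{in} - kernel + 1)/pool \rfloor} stage by
#' stage, starting from `maxLen`.
#'
#' @param config a [NetworkConfig-class].
#' @return Integer vector of time lengths after each stage.
#' @export
convOutputLengths <- function(config) {
    L <- config@maxLen
    out <- integer(length(config@convFilters))
    for (s in seq_along(config@convFilters)) {
        L <- (L - config@convKernels[s] + 1L) %/% config@poolSizes[s]
        out[s] <- L
    }
    out
}

.sigmoid <- function(x) plogis(x)

# ---- single-step LSTM cell (reference form, per-gate parameter lists) ----

#' One LSTM transition step
#'
#' Applies the gated transition: input gate
#' \eqn{i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i)}, control gate
#' \eqn{g_t = \tanh(W_g x_t + U_g h_{t-1} + b_g)}, forget gate
#' \eqn{f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f)}, cell
#' \eqn{c_t = i_t \odot g_t + f_t \odot c_{t-1}}, output gate
#' \eqn{o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o)}, hidden state
#' \eqn{h_t = o_t \odot \tanh(c_t)}.
#'
#' @param x input vector (length D_in).
#' @param hPrev,cPrev previous hidden and cell state vectors (length H).
#' @param params list with per-gate weights `Wi`, `Wg`, `Wf`, `Wo` (each
#'   H x D_in), recurrent weights `Ui`, `Ug`, `Uf`, `Uo` (each H x H) and
#'   biases `bi`, `bg`, `bf`, `bo` (each length H).
#' @return A list with `h` and `c`, each of length H.
#' @export
lstmStep <- function(x, hPrev, cPrev, params) {
    H <- length(hPrev)
    stopifnot(length(cPrev) == H)
    need <- c("Wi", "Wg", "Wf", "Wo", "Ui", "Ug", "Uf", "Uo",
              "bi", "bg", "bf", "bo")
    if (!all(need %in% names(params)))
        stop("params must contain ", paste(need, collapse = ", "))
    for (nm in c("Wi", "Wg", "Wf", "Wo"))
        if (!all(dim(params[[nm]]) == c(H, length(x))))
            stop("'", nm, "' must be H x D_in")
    for (nm in c("Ui", "Ug", "Uf", "Uo"))
        if (!all(dim(params[[nm]]) == c(H, H)))
            stop("'", nm, "' must be H x H")
    i <- .sigmoid(drop(params$Wi %*% x + params$Ui %*% hPrev) + params$bi)
    g <- tanh(drop(params$Wg %*% x + params$Ug %*% hPrev) + params$bg)
    f <- .sigmoid(drop(params$Wf %*% x + params$Uf %*% hPrev) + params$bf)
    c_t <- i * g + f * cPrev
    o <- .sigmoid(drop(params$Wo %*% x + params$Uo %*% hPrev) + params$bo)
    list(h = o * tanh(c_t), c = c_t)
}

# ---- batched internals -------------------------------------------------
# Parameters are a flat named list:
#   E                      (V+1) x D embedding (row 1 = padding, fixed 0)
#   fwW, fwU, fwb          forward LSTM, gates packed [i | g | f | o]
#   bwW, bwU, bwb          backward LSTM
#   conv<W/b><s>           stage s kernels array(kern, Cin, Cout) and bias
#   Wd, bd                 optional dense layer
#   beta, b0               logistic head

.gateBlocks <- function(H) list(i = 1:H, g = H + 1:H, f = 2L * H + 1:H,
                                o = 3L * H + 1:H)

# X: (B, L, D); returns step-ordered gate/state caches
.lstmForwardBatch <- function(X, W, U, b, reverse = FALSE) {
    B <- dim(X)[1L]; L <- dim(X)[2L]
    H <- nrow(U)
    torder <- if (reverse) L:1 else 1:L
    Bb <- matrix(b, B, 4L * H, byrow = TRUE)
    blk <- .gateBlocks(H)
    h <- matrix(0, B, H); cs <- matrix(0, B, H)
    I <- G <- Fg <- O <- Cs <- Tc <- Hs <- vector("list", L)
    for (u in seq_len(L)) {
        t <- torder[u]
        Xt <- X[, t, , drop = FALSE]
        dim(Xt) <- c(B, dim(X)[3L])
        A <- Xt %*% W + h %*% U + Bb
        i <- .sigmoid(A[, blk$i, drop = FALSE])
        g <- tanh(A[, blk$g, drop = FALSE])
        f <- .sigmoid(A[, blk$f, drop = FALSE])
        o <- .sigmoid(A[, blk$o, drop = FALSE])
        cs <- i * g + f * cs
        tc <- tanh(cs)
        h <- o * tc
        I[[u]] <- i; G[[u]] <- g; Fg[[u]] <- f; O[[u]] <- o
        Cs[[u]] <- cs; Tc[[u]] <- tc; Hs[[u]] <- h
    }
    list(I = I, G = G, Fg = Fg, O = O, Cs = Cs, Tc = Tc, Hs = Hs,
         torder = torder, H = H)
}

# A: (B, Lin, Cin); W: array(kern, Cin, Cout); returns pooled output + cache
.convForwardBatch <- function(A, W, bvec, pool) {
    B <- dim(A)[1L]; Lin <- dim(A)[2L]; Cin <- dim(A)[3L]
    kern <- dim(W)[1L]; Cout <- dim(W)[3L]
    if (Lin < kern)
        stop("input length ", Lin, " shorter than kernel ", kern)
    Lout1 <- Lin - kern + 1L
    P <- matrix(rep(bvec, each = B * Lout1), B * Lout1, Cout)
    for (m in seq_len(kern)) {
        As <- A[, m:(m + Lout1 - 1L), , drop = FALSE]
        dim(As) <- c(B * Lout1, Cin)
        P <- P + As %*% matrix(W[m, , ], Cin, Cout)
    }
    pre <- P
    dim(pre) <- c(B, Lout1, Cout)
    R <- pmax(pre, 0)
    L2 <- Lout1 %/% pool
    if (L2 < 1L)
        stop("pooling of length ", pool, " collapses a feature map of ",
             "length ", Lout1, " to nothing")
    cur <- R[, seq.int(1L, by = pool, length.out = L2), , drop = FALSE]
    arg <- array(1L, dim(cur))
    if (pool > 1L) for (q in 2:pool) {
        cand <- R[, seq.int(q, by = pool, length.out = L2), , drop = FALSE]
        upd <- cand > cur
        cur[upd] <- cand[upd]
        arg[upd] <- q
    }
    list(out = cur, pre = pre, arg = arg, Lout1 = Lout1, L2 = L2,
         pool = pool, kern = kern)
}

# full forward pass; training=TRUE keeps every intermediate for backprop
.forwardPass <- function(tokens, params, config, training = FALSE) {
    if (is.null(dim(tokens))) tokens <- matrix(tokens, nrow = 1L)
    B <- nrow(tokens); L <- ncol(tokens)
    D <- ncol(params$E)
    X <- params$E[tokens + 1L, , drop = FALSE]
    dim(X) <- c(B, L, D)
    cache <- if (training) list(tokens = tokens, X = X) else NULL
    if (config@useBlstm) {
        fw <- .lstmForwardBatch(X, params$fwW, params$fwU, params$fwb,
                                reverse = FALSE)
        bw <- .lstmForwardBatch(X, params$bwW, params$bwU, params$bwb,
                                reverse = TRUE)
        H <- fw$H
        if (config@useConv) {
            feat <- array(0, c(B, L, 2L * H))
            for (t in seq_len(L)) {
                feat[, t, 1:H] <- fw$Hs[[t]]
                feat[, t, H + 1:H] <- bw$Hs[[L - t + 1L]]
            }
        } else {
            feat <- cbind(fw$Hs[[L]], bw$Hs[[L]])
        }
        if (training) { cache$fw <- fw; cache$bw <- bw }
    } else {
        feat <- X
    }
    if (config@useConv) {
        convCaches <- vector("list", length(config@convFilters))
        A <- feat
        for (s in seq_along(config@convFilters)) {
            cc <- .convForwardBatch(A, params[[paste0("convW", s)]],
                                    params[[paste0("convb", s)]],
                                    config@poolSizes[s])
            if (training) { cc$input <- A; convCaches[[s]] <- cc }
            A <- cc$out
        }
        Z <- A
        dim(Z) <- c(B, prod(dim(A)[2:3]))
        if (training) { cache$conv <- convCaches; cache$feat <- feat }
    } else {
        Z <- feat
        if (training) cache$feat <- feat
    }
    if (config@denseWidth > 0L) {
        dpre <- Z %*% params$Wd +
            matrix(params$bd, B, config@denseWidth, byrow = TRUE)
        Zh <- pmax(dpre, 0)
        if (training) { cache$Z <- Z; cache$dpre <- dpre; cache$Zh <- Zh }
    } else {
        Zh <- Z
        if (training) cache$Z <- Z
    }
    logit <- drop(Zh %*% params$beta) + params$b0
    p <- .sigmoid(logit)
    if (any(!is.finite(p))) stop("non-finite activations in forward pass")
    list(p = p, logit = logit, cache = cache)
}

#' Bidirectional LSTM features for one token sequence
#'
#' Runs the model's forward LSTM over the (padded) token sequence and the
#' backward LSTM over the reversed sequence, time-aligning the backward
#' outputs, and stacks them: rows 1..H are the forward hidden states over
#' t = 1..L, rows H+1..2H the backward hidden states at the same t. Both
#' directions start from zero hidden and cell states.
#'
#' @param tokens integer token vector (0 = padding).
#' @param model a [ClassifierModel-class] with an active BLSTM stage.
#' @return Numeric matrix of dimension (2H) x L.
#' @export
blstmForward <- function(tokens, model) {
    if (!model@config@useBlstm)
        stop("model was built without a BLSTM stage")
    p <- model@params
    L <- length(tokens)
    D <- ncol(p$E)
    X <- p$E[as.integer(tokens) + 1L, , drop = FALSE]
    dim(X) <- c(1L, L, D)
    fw <- .lstmForwardBatch(X, p$fwW, p$fwU, p$fwb, reverse = FALSE)
    bw <- .lstmForwardBatch(X, p$bwW, p$bwU, p$bwb, reverse = TRUE)
    H <- fw$H
    out <- matrix(0, 2L * H, L)
    for (t in seq_len(L)) {
        out[1:H, t] <- fw$Hs[[t]][1L, ]
        out[H + 1:H, t] <- bw$Hs[[L - t + 1L]][1L, ]
    }
    out
}

#' One convolution / ReLU / max-pool stage
#'
#' Valid (no padding) one-dimensional cross-correlation along the time
#' axis, summing over input channels, plus a per-filter bias; ReLU; then
#' non-overlapping max-pooling of length `pool` with any trailing
#' remainder dropped, so \eqn{L_{out} = \lfloor (L_{in} - kern + 1)/pool
#' \rfloor}.
#'
#' @param features numeric matrix C_in x L_in (channels by time).
#' @param kernels numeric array of dimension (kern, C_in, C_out).
#' @param bias numeric vector of length C_out.
#' @param pool max-pool length (>= 1).
#' @return Numeric matrix C_out x L_out.
#' @export
convStageForward <- function(features, kernels, bias, pool = 1L) {
    Cin <- nrow(features); Lin <- ncol(features)
    if (dim(kernels)[2L] != Cin)
        stop("kernel channel dimension must match the input channels")
    A <- array(0, c(1L, Lin, Cin))
    A[1L, , ] <- t(features)
    cc <- .convForwardBatch(A, kernels, bias, as.integer(pool))
    out <- cc$out
    t(matrix(out, dim(out)[2L], dim(out)[3L]))
}

#' Predicted mRNA probability
#'
#' Runs the full forward pass and returns \eqn{p(y = 1 \mid x) =
#' \sigma(\beta^\top c_x + b_0)}, the probability that each transcript is
#' an mRNA. The complementary lncRNA probability is exactly
#' \eqn{1 - p(y=1\mid x)}; the predicted class is 1 when the probability
#' is at least 0.5.
#'
#' @param model a [ClassifierModel-class].
#' @param tokens integer token matrix (rows = transcripts, padded to the
#'   model's `maxLen`) or a single token vector.
#' @param batchSize forward-pass batch size.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predictProba <- function(model, tokens, batchSize = 256L) {
    if (is.null(dim(tokens))) tokens <- matrix(tokens, nrow = 1L)
    if (ncol(tokens) != model@config@maxLen)
        stop("tokens must be padded to maxLen = ", model@config@maxLen)
    n <- nrow(tokens)
    p <- numeric(n)
    for (s in seq.int(1L, n, by = batchSize)) {
        idx <- s:min(s + batchSize - 1L, n)
        p[idx] <- .forwardPass(tokens[idx, , drop = FALSE], model@params,
                               model@config)$p
    }
    names(p) <- rownames(tokens)
    p
}

# ---- initialization ----------------------------------------------------

.glorot <- function(n, fanIn, fanOut) {
    r <- sqrt(6 / (fanIn + fanOut))
    runif(n, -r, r)
}

#' Initialize classifier parameters
#'
#' Embedding rows come from the supplied (GloVe-pretrained) table; all
#' other weights are Glorot-uniform under `seed`. LSTM forget-gate biases
#' start at 1 (the usual stabilizing choice); every other bias starts at 0.
#' The padding embedding row is zero and stays zero throughout training.
#'
#' @param embedding `(V+1) x D` matrix, row 1 all zeros.
#' @param config a [NetworkConfig-class].
#' @param seed integer RNG seed (defaults to `config@seed`).
#' @return A [ClassifierModel-class] with untrained non-embedding weights.
#' @export
initClassifier <- function(embedding, config, seed = config@seed) {
    D <- config@embeddingDim
    if (ncol(embedding) != D)
        stop("embedding has ", ncol(embedding), " columns but config says D = ", D)
    if (any(embedding[1L, ] != 0))
        stop("embedding row 1 must be the zero padding vector")
    set.seed(seed)
    H <- config@lstmHidden
    params <- list(E = embedding)
    if (config@useBlstm) {
        for (dir in c("fw", "bw")) {
            W <- matrix(.glorot(D * 4L * H, D, H), D, 4L * H)
            U <- matrix(.glorot(H * 4L * H, H, H), H, 4L * H)
            b <- numeric(4L * H)
            b[.gateBlocks(H)$f] <- 1
            params[[paste0(dir, "W")]] <- W
            params[[paste0(dir, "U")]] <- U
            params[[paste0(dir, "b")]] <- b
        }
    }
    if (config@useConv) {
        Cin <- if (config@useBlstm) 2L * H else D
        Lc <- config@maxLen
        for (s in seq_along(config@convFilters)) {
            kern <- config@convKernels[s]; Cout <- config@convFilters[s]
            params[[paste0("convW", s)]] <-
                array(.glorot(kern * Cin * Cout, kern * Cin, Cout),
                      c(kern, Cin, Cout))
            params[[paste0("convb", s)]] <- numeric(Cout)
            Lc <- (Lc - kern + 1L) %/% config@poolSizes[s]
            if (Lc < 1L)
                stop("conv stage ", s, " leaves no time positions; ",
                     "increase maxLen or shrink kernels/pools")
            Cin <- Cout
        }
        dFlat <- Lc * Cin
    } else {
        dFlat <- 2L * H
    }
    if (config@denseWidth > 0L) {
        params$Wd <- matrix(.glorot(dFlat * config@denseWidth, dFlat,
                                    config@denseWidth),
                            dFlat, config@denseWidth)
        params$bd <- numeric(config@denseWidth)
        dHead <- config@denseWidth
    } else {
        dHead <- dFlat
    }
    params$beta <- .glorot(dHead, dHead, 1L)
    params$b0 <- 0
    new("ClassifierModel", params = params, config = config,
        k = as.integer(round(log(nrow(embedding) - 1L, 4))))
}


#' Save / load a classifier checkpoint
#'
#' Serializes every parameter array together with the full
#' [NetworkConfig-class] and the vocabulary k, so a reloaded model is
#' ready for [predictProba()].
#'
#' @param model a [ClassifierModel-class].
#' @param path checkpoint file.
#' @return `path` invisibly (`saveClassifier`); the restored
#'   [ClassifierModel-class] (`loadClassifier`).
#' @export
saveClassifier <- function(model, path) {
    saveRDS(list(params = model@params,
                 config = model@config, k = model@k), path)
    invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
    x <- readRDS(path)
    new("ClassifierModel", params = x$params, config = x$config, k = x$k)
}
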