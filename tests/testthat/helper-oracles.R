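# Independent reference implementations used as oracles. These are written
# as plain elementwise loops, deliberately sharing no code with the package.

# one LSTM transition, unit by unit, straight from the gate definitions
refLstmStep <- function(x, hPrev, cPrev, p) {
    H <- length(hPrev)
    h <- numeric(H); cc <- numeric(H)
    sig <- function(z) 1 / (1 + exp(-z))
    for (u in seq_len(H)) {
        i <- sig(sum(p$Wi[u, ] * x) + sum(p$Ui[u, ] * hPrev) + p$bi[u])
        g <- tanh(sum(p$Wg[u, ] * x) + sum(p$Ug[u, ] * hPrev) + p$bg[u])
        f <- sig(sum(p$Wf[u, ] * x) + sum(p$Uf[u, ] * hPrev) + p$bf[u])
        cc[u] <- i * g + f * cPrev[u]
        o <- sig(sum(p$Wo[u, ] * x) + sum(p$Uo[u, ] * hPrev) + p$bo[u])
        h[u] <- o * tanh(cc[u])
    }
    list(h = h, c = cc)
}

# valid 1-D cross-correlation + bias + ReLU + non-overlapping max-pool,
# via explicit triple loops; features Cin x Lin, kernels (kern, Cin, Cout)
refConvStage <- function(features, kernels, bias, pool) {
    Cin <- nrow(features); Lin <- ncol(features)
    kern <- dim(kernels)[1L]; Cout <- dim(kernels)[3L]
    L1 <- Lin - kern + 1L
    pre <- matrix(0, Cout, L1)
    for (co in seq_len(Cout))
        for (j in seq_len(L1)) {
            acc <- bias[co]
            for (m in seq_len(kern))
                for (ci in seq_len(Cin))
                    acc <- acc + features[ci, j + m - 1L] * kernels[m, ci, co]
            pre[co, j] <- max(0, acc)
        }
    L2 <- L1 %/% pool
    out <- matrix(0, Cout, L2)
    for (co in seq_len(Cout))
        for (j in seq_len(L2))
            out[co, j] <- max(pre[co, ((j - 1L) * pool + 1L):(j * pool)])
    out
}

# rank-based AUC: P(score_pos > score_neg) + 0.5 P(tie) over all pairs
refAuc <- function(labels, scores) {
    sp <- scores[labels == 1]; sn <- scores[labels == 0]
    tot <- 0
    for (a in sp) for (b in sn)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
}

# co-occurrence counts by enumerating every ordered in-window pair
refCooccurrence <- function(tokenList, V, radius) {
    X <- matrix(0, V, V)
    for (tk in tokenList) {
        L <- length(tk)
        for (p in seq_len(L))
            for (q in seq_len(L))
                if (p != q && abs(p - q) <= radius)
                    X[tk[p], tk[q]] <- X[tk[p], tk[q]] + 1
    }
    X
}

# GloVe objective by double loop over the dense count matrix
refGloveLoss <- function(W, Wc, b, bc, X, xMax, alpha) {
    V <- nrow(X)
    J <- 0
    for (i in seq_len(V)) for (j in seq_len(V)) {
        x <- X[i, j]
        if (x != 0) {
            f <- if (x < xMax) (x / xMax)^alpha else 1
            J <- J + f * (sum(W[i, ] * Wc[j, ]) + b[i] + bc[j] - log(x))^2
        }
    }
    J
}

# ---- random-instance builders -----------------------------------------

randomLstmParams <- function(H, Din) {
    rn <- function(n) rnorm(n) * 0.5
    list(Wi = matrix(rn(H * Din), H), Wg = matrix(rn(H * Din), H),
         Wf = matrix(rn(H * Din), H), Wo = matrix(rn(H * Din), H),
         Ui = matrix(rn(H * H), H), Ug = matrix(rn(H * H), H),
         Uf = matrix(rn(H * H), H), Uo = matrix(rn(H * H), H),
         bi = rn(H), bg = rn(H), bf = rn(H), bo = rn(H))
}

randomGloveModel <- function(V, D, xMax = 10, alpha = 0.75) {
    new("GloveModel", W = matrix(rnorm(V * D) * 0.3, V, D),
        Wc = matrix(rnorm(V * D) * 0.3, V, D), b = rnorm(V) * 0.3,
        bc = rnorm(V) * 0.3, xMax = xMax, alpha = alpha, k = 1L,
        history = numeric(0))
}

randomCorpus <- function(nSeq, V, lenRange = c(5L, 30L)) {
    toks <- lapply(seq_len(nSeq), function(i)
        sample.int(V, sample(lenRange[1L]:lenRange[2L], 1L), replace = TRUE))
    names(toks) <- paste0("s", seq_len(nSeq))
    new("KmerCorpus", tokens = toks, k = 1L, stride = 1L,
        labels = integer(0L))
}

# two-class token corpus with co-occurrence confined to communities
communityCorpus <- function(V = 8L, nSeq = 40L, len = 30L) {
    half <- V %/% 2L
    toks <- lapply(seq_len(nSeq), function(i) {
        comm <- if (i %% 2L == 0L) seq_len(half) else (half + 1L):V
        sample(comm, len, replace = TRUE)
    })
    names(toks) <- paste0("s", seq_len(nSeq))
    new("KmerCorpus", tokens = toks, k = 1L, stride = 1L,
        labels = integer(0L))
}

writeTempFasta <- function(lines) {
    f <- tempfile(fileext = ".fa")
    writeLines(lines, f)
    f
}

# central finite differences of a scalar function of a GloveModel slot
fdGloveSlot <- function(model, X, slot, eps = 1e-6) {
    cur <- slot(model, slot)
    out <- array(0, dim(cur) %||% length(cur))
    for (q in seq_along(cur)) {
        m1 <- model; m2 <- model
        slot(m1, slot)[q] <- cur[q] + eps
        slot(m2, slot)[q] <- cur[q] - eps
        out[q] <- (gloveLoss(m1, X) - gloveLoss(m2, X)) / (2 * eps)
    }
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
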