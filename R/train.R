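# Backward pass companions to the forward internals in network.R.
# Gradients are of the summed cross-entropy l = -sum_i log p(y_i | x_i).

.lstmBackwardBatch <- function(X, W, U, cache, dHext) {
    B <- dim(X)[1L]; L <- dim(X)[2L]; Din <- dim(X)[3L]
    H <- cache$H
    dW <- matrix(0, Din, 4L * H); dU <- matrix(0, H, 4L * H)
    db <- numeric(4L * H)
    dX <- array(0, dim(X))
    dhCarry <- matrix(0, B, H); dcCarry <- matrix(0, B, H)
    zero <- matrix(0, B, H)
    for (u in L:1) {
        dh <- dhCarry
        if (!is.null(dHext[[u]])) dh <- dh + dHext[[u]]
        i <- cache$I[[u]]; g <- cache$G[[u]]; f <- cache$Fg[[u]]
        o <- cache$O[[u]]; tc <- cache$Tc[[u]]
        cPrev <- if (u > 1L) cache$Cs[[u - 1L]] else zero
        hPrev <- if (u > 1L) cache$Hs[[u - 1L]] else zero
        do <- dh * tc
        dc <- dh * o * (1 - tc * tc) + dcCarry
        di <- dc * g
        dg <- dc * i
        df <- dc * cPrev
        dcCarry <- dc * f
        dA <- cbind(di * i * (1 - i), dg * (1 - g * g),
                    df * f * (1 - f), do * o * (1 - o))
        t_ <- cache$torder[u]
        Xt <- X[, t_, , drop = FALSE]
        dim(Xt) <- c(B, Din)
        dW <- dW + crossprod(Xt, dA)
        dU <- dU + crossprod(hPrev, dA)
        db <- db + colSums(dA)
        dhCarry <- dA %*% t(U)
        dXt <- dA %*% t(W)
        dX[, t_, ] <- dX[, t_, ] + dXt
    }
    list(dW = dW, dU = dU, db = db, dX = dX)
}

.convBackwardBatch <- function(cc, W, dOut) {
    A <- cc$input
    B <- dim(A)[1L]; Lin <- dim(A)[2L]; Cin <- dim(A)[3L]
    kern <- cc$kern; pool <- cc$pool
    Lout1 <- cc$Lout1; L2 <- cc$L2
    Cout <- dim(W)[3L]
    # un-pool: route each pooled gradient to its argmax position
    dR <- array(0, c(B, Lout1, Cout))
    for (q in seq_len(pool)) {
        idx <- seq.int(q, by = pool, length.out = L2)
        sub <- dR[, idx, , drop = FALSE]
        m <- cc$arg == q
        sub[m] <- dOut[m]
        dR[, idx, ] <- sub
    }
    dPre <- dR * (cc$pre > 0)
    dPmat <- dPre
    dim(dPmat) <- c(B * Lout1, Cout)
    db <- colSums(dPmat)
    dW <- array(0, dim(W))
    dA <- array(0, dim(A))
    for (m in seq_len(kern)) {
        As <- A[, m:(m + Lout1 - 1L), , drop = FALSE]
        dim(As) <- c(B * Lout1, Cin)
        dW[m, , ] <- crossprod(As, dPmat)
        dAs <- dPmat %*% t(matrix(W[m, , ], Cin, Cout))
        dim(dAs) <- c(B, Lout1, Cin)
        dA[, m:(m + Lout1 - 1L), ] <- dA[, m:(m + Lout1 - 1L), ] + dAs
    }
    list(dW = dW, db = db, dA = dA)
}

# full backward pass; fp = .forwardPass(..., training = TRUE) result
.backwardPass <- function(fp, y, params, config) {
    cache <- fp$cache
    B <- nrow(cache$tokens); L <- ncol(cache$tokens)
    grads <- list()
    dlogit <- fp$p - y                       # d l / d logit for summed CE
    Zh <- if (config@denseWidth > 0L) cache$Zh else cache$Z
    grads$beta <- drop(crossprod(Zh, dlogit))
    grads$b0 <- sum(dlogit)
    dZh <- outer(dlogit, params$beta)
    if (config@denseWidth > 0L) {
        dDpre <- dZh * (cache$dpre > 0)
        grads$Wd <- crossprod(cache$Z, dDpre)
        grads$bd <- colSums(dDpre)
        dZ <- dDpre %*% t(params$Wd)
    } else {
        dZ <- dZh
    }
    H <- config@lstmHidden
    if (config@useConv) {
        nS <- length(config@convFilters)
        last <- cache$conv[[nS]]
        dOut <- dZ
        dim(dOut) <- dim(last$out)
        for (s in nS:1) {
            cb <- .convBackwardBatch(cache$conv[[s]],
                                     params[[paste0("convW", s)]], dOut)
            grads[[paste0("convW", s)]] <- cb$dW
            grads[[paste0("convb", s)]] <- cb$db
            dOut <- cb$dA
        }
        dFeat <- dOut                        # (B, L, 2H) or (B, L, D)
    }
    if (config@useBlstm) {
        dHf <- vector("list", L); dHb <- vector("list", L)
        if (config@useConv) {
            for (t in seq_len(L)) {
                dHf[[t]] <- matrix(dFeat[, t, 1:H], B, H)
                dHb[[L - t + 1L]] <- matrix(dFeat[, t, H + 1:H], B, H)
            }
        } else {
            dHf[[L]] <- dZ[, 1:H, drop = FALSE]
            dHb[[L]] <- dZ[, H + 1:H, drop = FALSE]
        }
        fwB <- .lstmBackwardBatch(cache$X, params$fwW, params$fwU,
                                  cache$fw, dHf)
        bwB <- .lstmBackwardBatch(cache$X, params$bwW, params$bwU,
                                  cache$bw, dHb)
        grads$fwW <- fwB$dW; grads$fwU <- fwB$dU; grads$fwb <- fwB$db
        grads$bwW <- bwB$dW; grads$bwU <- bwB$dU; grads$bwb <- bwB$db
        dX <- fwB$dX + bwB$dX
    } else {
        dX <- dFeat
    }
    if (!config@freezeEmbedding) {
        D <- ncol(params$E)
        dXmat <- dX
        dim(dXmat) <- c(B * L, D)
        agg <- rowsum(dXmat, group = as.integer(cache$tokens) + 1L)
        dE <- matrix(0, nrow(params$E), D)
        dE[as.integer(rownames(agg)), ] <- agg
        dE[1L, ] <- 0                        # padding row never updated
        grads$E <- dE
    }
    grads
}

.crossEntropy <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the lncRNA/mRNA classifier
#'
#' Minimizes the summed cross-entropy \eqn{l = -\sum_i \log p(y_i \mid
#' x_i, \theta)} by mini-batch gradient descent over the padded token
#' matrix, with an early-termination strategy: a stratified
#' `valFraction` of the training rows is held out, and training stops once
#' the validation loss has failed to improve for `patience` consecutive
#' epochs; the parameters from the best validation epoch are kept.
#' Deterministic for a given `config@seed`.
#'
#' @param tokens integer matrix (transcripts x `maxLen`) from
#'   [padTruncate()].
#' @param labels binary vector (0 = lncRNA, 1 = mRNA), one per row.
#' @param embedding `(V+1) x D` embedding table from [embeddingTable()].
#' @param config a [NetworkConfig-class].
#' @return A list with `model` (a [ClassifierModel-class]) and `log` (a
#'   data.frame of per-epoch mean train/validation loss and accuracy).
#' @export
trainClassifier <- function(tokens, labels, embedding, config) {
    if (is.null(dim(tokens))) stop("'tokens' must be a matrix")
    if (nrow(tokens) != length(labels))
        stop("one label per token row is required")
    if (nrow(tokens) == 0L) stop("empty training set")
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2L)
        stop("training set contains a single class")
    if (ncol(tokens) != config@maxLen)
        stop("tokens must be padded to maxLen = ", config@maxLen)

    model <- initClassifier(embedding, config)   # seeds the RNG too
    params <- model@params

    # stratified validation carve-out
    n <- nrow(tokens)
    valIdx <- integer(0L)
    if (config@valFraction > 0) {
        for (cl in c(0L, 1L)) {
            idx <- which(labels == cl)
            nv <- max(1L, round(config@valFraction * length(idx)))
            valIdx <- c(valIdx, sample(idx, nv))
        }
        valIdx <- sort(valIdx)
    }
    trIdx <- setdiff(seq_len(n), valIdx)
    if (length(unique(labels[trIdx])) < 2L)
        stop("validation carve-out removed a whole class; lower valFraction")

    adam <- config@optimizer == "adam"
    if (adam) {
        mState <- lapply(params, function(p) p * 0)   # shape-preserving zeros
        vState <- mState
        b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; tAdam <- 0L
    }
    lr <- config@learningRate

    evalSet <- function(idx) {
        if (!length(idx)) return(c(loss = NA_real_, acc = NA_real_))
        loss <- 0; correct <- 0L
        for (s in seq.int(1L, length(idx), by = config@batchSize)) {
            rows <- idx[s:min(s + config@batchSize - 1L, length(idx))]
            p <- .forwardPass(tokens[rows, , drop = FALSE], params, config)$p
            loss <- loss + .crossEntropy(p, labels[rows])
            correct <- correct + sum((p >= 0.5) == (labels[rows] == 1L))
        }
        c(loss = loss / length(idx), acc = correct / length(idx))
    }

    logRows <- vector("list", config@maxEpochs)
    bestVal <- Inf; bestParams <- params; badEpochs <- 0L
    nEpochs <- 0L
    for (epoch in seq_len(config@maxEpochs)) {
        perm <- sample(trIdx)
        epochLoss <- 0; epochCorrect <- 0L
        for (s in seq.int(1L, length(perm), by = config@batchSize)) {
            rows <- perm[s:min(s + config@batchSize - 1L, length(perm))]
            fp <- .forwardPass(tokens[rows, , drop = FALSE], params, config,
                               training = TRUE)
            y <- labels[rows]
            epochLoss <- epochLoss + .crossEntropy(fp$p, y)
            epochCorrect <- epochCorrect + sum((fp$p >= 0.5) == (y == 1L))
            grads <- .backwardPass(fp, y, params, config)
            if (adam) {
                tAdam <- tAdam + 1L
                corr1 <- 1 - b1^tAdam; corr2 <- 1 - b2^tAdam
                for (nm in names(grads)) {
                    g <- grads[[nm]]
                    mState[[nm]] <- b1 * mState[[nm]] + (1 - b1) * g
                    vState[[nm]] <- b2 * vState[[nm]] + (1 - b2) * g * g
                    params[[nm]] <- params[[nm]] -
                        lr * (mState[[nm]] / corr1) /
                        (sqrt(vState[[nm]] / corr2) + epsA)
                }
            } else {
                for (nm in names(grads))
                    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
            }
            if (!config@freezeEmbedding) params$E[1L, ] <- 0
        }
        nEpochs <- epoch
        val <- evalSet(valIdx)
        logRows[[epoch]] <- data.frame(
            epoch = epoch, trainLoss = epochLoss / length(perm),
            trainAcc = epochCorrect / length(perm),
            valLoss = val[["loss"]], valAcc = val[["acc"]])
        if (length(valIdx)) {
            if (val[["loss"]] < bestVal - 1e-9) {
                bestVal <- val[["loss"]]; bestParams <- params
                badEpochs <- 0L
            } else {
                badEpochs <- badEpochs + 1L
                if (badEpochs >= config@patience) break
            }
        }
    }
    if (length(valIdx)) params <- bestParams
    model@params <- params
    list(model = model,
         log = do.call(rbind, logRows[seq_len(nEpochs)]))
}

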