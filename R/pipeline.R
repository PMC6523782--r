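#' Run the full discrimination pipeline
#'
#' Wires every stage end to end on a labelled transcript set: cleaning,
#' balanced 7:3 stratified splitting, k-mer tokenization, global
#' co-occurrence counting over the whole corpus (the embedding stage is
#' unsupervised, so it may see all sequences), GloVe embedding training,
#' padding/truncation, supervised network training on the training
#' partition, and evaluation on the held-out partition.
#'
#' @param records labelled `XStringSet` (e.g. from
#'   [simulateTranscripts()] or [readLabeledTranscripts()]).
#' @param k k-mer length (default 6).
#' @param stride sliding-window step (default `k`, non-overlapping).
#' @param windowDiameter co-occurrence window extent (default 15).
#' @param embeddingDim GloVe dimension D (default 100).
#' @param gloveIters GloVe iterations (default 3000).
#' @param xMax,alpha GloVe weight-function settings.
#' @param config a [NetworkConfig-class]; its `embeddingDim` must match.
#' @param trainFrac,balance passed to [balancedSplit()].
#' @param seed master seed; the split, GloVe and network stages derive
#'   their seeds from it.
#' @param minLen cleaning threshold in nucleotides.
#' @return A list with `metrics` (precision/recall/f1/accuracy/auroc on
#'   the test set), `roc`, `model`, `trainingLog`, `glove`, `split`, and
#'   `prob` (named test-set probabilities).
#' @export
runPipeline <- function(records, k = 6L, stride = k, windowDiameter = 15L,
                        embeddingDim = 100L, gloveIters = 3000L,
                        xMax = 15000, alpha = 0.75,
                        config = networkConfig(), trainFrac = 0.7,
                        balance = TRUE, seed = 1L, minLen = 200L) {
    if (config@embeddingDim != embeddingDim)
        stop("config@embeddingDim must equal 'embeddingDim'")
    clean <- cleanSequences(records, minLen = minLen)
    split <- balancedSplit(clean, trainFrac = trainFrac, balance = balance,
                           seed = seed)
    vocab <- kmerVocabulary(k)
    all <- c(split$train, split$test)
    corpus <- tokenizeSequences(all, vocab, stride = stride)
    X <- kmerCooccurrence(corpus, windowDiameter = windowDiameter)
    glove <- trainGlove(X, dim = embeddingDim, xMax = xMax, alpha = alpha,
                        maxIters = gloveIters, seed = seed + 1L)
    E <- embeddingTable(glove)
    nTrain <- length(split$train)
    tokensAll <- padTruncate(corpus, maxLen = config@maxLen)
    trainTok <- tokensAll[seq_len(nTrain), , drop = FALSE]
    testTok <- tokensAll[-seq_len(nTrain), , drop = FALSE]
    trainLab <- transcriptLabels(split$train)
    testLab <- transcriptLabels(split$test)
    fit <- trainClassifier(trainTok, trainLab, E, config)
    prob <- predictProba(fit$model, testTok)
    metrics <- evaluatePredictions(testLab, prob)
    list(metrics = metrics, roc = rocAuc(testLab, prob), model = fit$model,
         trainingLog = fit$log, glove = glove, split = split, prob = prob)
}

#' Sensitivity sweep over one hyperparameter
#'
#' Re-runs the pipeline for each value of one of `k`, `D` (embedding
#' dimension), `s` (window stride) or `maxLen`, on fixed splits and seeds,
#' and tabulates the held-out auROC. Sweeps over `k` or `s` retrain the
#' embedding (the vocabulary or corpus changes); a `maxLen` sweep reuses
#' the embedding and retrains only the network.
#'
#' @param records labelled `XStringSet`.
#' @param parameter one of `"k"`, `"D"`, `"s"`, `"maxLen"`.
#' @param values vector of values to try.
#' @param config base [NetworkConfig-class].
#' @param ... further arguments passed to [runPipeline()].
#' @return A data.frame with columns `parameter`, `value`, `auroc`,
#'   `accuracy`, `f1`.
#' @export
sweepParameter <- function(records, parameter = c("k", "D", "s", "maxLen"),
                           values, config = networkConfig(), ...) {
    parameter <- match.arg(parameter)
    base <- list(...)
    rows <- vector("list", length(values))
    for (vi in seq_along(values)) {
        v <- values[[vi]]
        args <- c(list(records = records, config = config), base)
        switch(parameter,
            k = { args$k <- v },
            D = {
                args$embeddingDim <- as.integer(v)
                cfg <- config; cfg@embeddingDim <- as.integer(v)
                args$config <- cfg
            },
            s = { args$stride <- v },
            maxLen = {
                cfg <- config; cfg@maxLen <- as.integer(v)
                args$config <- cfg
            })
        res <- tryCatch(do.call(runPipeline, args), error = function(e)
            stop("sweep aborted at ", parameter, " = ", v, ": ",
                 conditionMessage(e)))
        rows[[vi]] <- data.frame(parameter = parameter, value = v,
                                 auroc = res$metrics[["auroc"]],
                                 accuracy = res$metrics[["accuracy"]],
                                 f1 = res$metrics[["f1"]])
    }
    do.call(rbind, rows)
}
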