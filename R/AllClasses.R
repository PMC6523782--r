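#' @import methods
#' @importFrom Matrix sparseMatrix rowSums t
#' @importFrom stats rnorm runif rlnorm plogis setNames
#' @importFrom utils head write.table read.delim
NULL

#' KmerVocabulary: bijection between k-mers and integer indices
#'
#' Fixes the dictionary used for tokenization: every one of the \eqn{4^k}
#' k-mers over the alphabet A, C, T, G receives a unique integer index in
#' \eqn{[1, 4^k]}. Index 0 is never assigned; it is reserved for the padding
#' token whose embedding is the zero vector. The index of a k-mer is
#' \eqn{1 +} its base-4 value under the digit order A=0, C=1, T=2, G=3, so
#' for k = 2: "AA" is 1, "AC" is 2, "AT" is 3, "AG" is 4.
#'
#' @slot k integer, k-mer length.
#' @slot kmers character vector of length \eqn{4^k}; \code{kmers[i]} is the
#'   k-mer with index \code{i}.
#'
#' @seealso [kmerVocabulary()], [kmerIndex()], [kmerOf()]
#' @export
setClass("KmerVocabulary",
    representation(k = "integer", kmers = "character"),
    validity = function(object) {
        if (length(object@k) != 1L || object@k < 1L)
            return("'k' must be a single positive integer")
        if (length(object@kmers) != 4L^object@k)
            return(sprintf("vocabulary must contain exactly 4^k = %d k-mers",
                           4L^object@k))
        if (anyDuplicated(object@kmers))
            return("k-mer strings must be unique")
        TRUE
    })

#' KmerCorpus: tokenized transcript collection
#'
#' Holds the integer token sequences produced by sliding a window of length
#' k with step s over each cleaned transcript. Token values lie in
#' \eqn{[1, 4^k]}; a transcript of length n yields
#' \eqn{L = \lfloor (n-k)/s \rfloor + 1} tokens.
#'
#' @slot tokens named list of integer vectors, one per transcript.
#' @slot k integer k-mer length used.
#' @slot stride integer window step used.
#' @slot labels integer vector (0 = lncRNA, 1 = mRNA) aligned with
#'   \code{tokens}, or length zero when the corpus is unlabelled.
#'
#' @seealso [tokenizeSequences()], [padTruncate()]
#' @export
setClass("KmerCorpus",
    representation(tokens = "list", k = "integer", stride = "integer",
                   labels = "integer"),
    validity = function(object) {
        if (length(object@labels) &&
            length(object@labels) != length(object@tokens))
            return("'labels' must be empty or match the number of sequences")
        TRUE
    })

#' CooccurrenceMatrix: global k-mer/k-mer co-occurrence counts
#'
#' Sparse V x V matrix X whose entry \eqn{X_{ij}} counts how often k-mer j
#' occurs within the context window of k-mer i across the whole corpus.
#' With a symmetric window and unit increments the matrix is symmetric.
#' Windows never cross transcript boundaries.
#'
#' @slot counts a \code{dgCMatrix} of nonnegative counts.
#' @slot windowDiameter integer, total window extent; the context radius on
#'   each side is \code{floor(windowDiameter/2)}.
#' @slot k integer k-mer length of the underlying vocabulary.
#'
#' @seealso [kmerCooccurrence()], [trainGlove()]
#' @export
setClass("CooccurrenceMatrix",
    representation(counts = "Matrix", windowDiameter = "integer",
                   k = "integer"),
    validity = function(object) {
        d <- dim(object@counts)
        if (d[1L] != d[2L]) return("'counts' must be square")
        if (any(object@counts@x < 0)) return("counts must be nonnegative")
        TRUE
    })

#' GloveModel: parameters of the k-mer embedding factorization
#'
#' The model fitted by weighted least squares on the log co-occurrence
#' counts: main vectors \eqn{w_i}, context vectors \eqn{\tilde w_j}, and two
#' bias vectors, with the non-decreasing weight
#' \eqn{f(x) = (x/x_{max})^\alpha} capped at 1. The exported embedding row
#' for k-mer i is \eqn{w_i + \tilde w_i} by default.
#'
#' @slot W numeric V x D matrix of main k-mer vectors.
#' @slot Wc numeric V x D matrix of context k-mer vectors.
#' @slot b numeric length-V main biases.
#' @slot bc numeric length-V context biases.
#' @slot xMax numeric weight-function cutoff.
#' @slot alpha numeric weight-function exponent, in (0, 1].
#' @slot k integer k-mer length.
#' @slot history numeric vector of the loss at each training iteration.
#'
#' @seealso [trainGlove()], [gloveLoss()], [embeddingTable()]
#' @export
setClass("GloveModel",
    representation(W = "matrix", Wc = "matrix", b = "numeric",
                   bc = "numeric", xMax = "numeric", alpha = "numeric",
                   k = "integer", history = "numeric"),
    validity = function(object) {
        if (!all(dim(object@W) == dim(object@Wc)))
            return("'W' and 'Wc' must have identical dimensions")
        if (length(object@b) != nrow(object@W) ||
            length(object@bc) != nrow(object@W))
            return("bias lengths must equal nrow(W)")
        if (object@xMax <= 0) return("'xMax' must be positive")
        if (object@alpha <= 0 || object@alpha > 1)
            return("'alpha' must lie in (0, 1]")
        TRUE
    })

#' NetworkConfig: architecture and optimization settings
#'
#' Collects every tunable of the supervised classifier. Defaults are the
#' reference configuration: token sequences padded/truncated to 1000, 100-d
#' embeddings, 80 hidden units per LSTM direction, three convolution stages
#' with 100/80/80 filters of lengths 10/8/8 and max-pooling 4/2/2, learning
#' rate 1e-4, batch size 128, at most 12 epochs with early stopping.
#' \code{useBlstm}/\code{useConv} switch on the ablation variants.
#'
#' @slot maxLen integer fixed token length after padding/truncation.
#' @slot embeddingDim integer embedding dimension D.
#' @slot lstmHidden integer hidden size H per direction.
#' @slot convFilters integer vector of filter counts per stage.
#' @slot convKernels integer vector of kernel lengths per stage.
#' @slot poolSizes integer vector of max-pool lengths per stage.
#' @slot useBlstm logical; FALSE feeds embeddings straight into the
#'   convolution stack (no-BLSTM ablation).
#' @slot useConv logical; FALSE feeds the final BLSTM state into the head
#'   (no-convolution ablation).
#' @slot denseWidth integer; 0 flattens the last feature map directly into
#'   the logistic layer, > 0 inserts a ReLU dense layer of that width.
#' @slot learningRate numeric.
#' @slot batchSize integer.
#' @slot maxEpochs integer.
#' @slot valFraction numeric fraction of the training set held out for
#'   early stopping.
#' @slot patience integer epochs without validation improvement tolerated.
#' @slot optimizer character, "sgd" or "adam".
#' @slot freezeEmbedding logical; TRUE keeps the embedding table fixed.
#' @slot seed integer RNG seed governing initialization and batching.
#'
#' @seealso [networkConfig()], [trainClassifier()]
#' @export
setClass("NetworkConfig",
    representation(maxLen = "integer", embeddingDim = "integer",
                   lstmHidden = "integer", convFilters = "integer",
                   convKernels = "integer", poolSizes = "integer",
                   useBlstm = "logical", useConv = "logical",
                   denseWidth = "integer", learningRate = "numeric",
                   batchSize = "integer", maxEpochs = "integer",
                   valFraction = "numeric", patience = "integer",
                   optimizer = "character", freezeEmbedding = "logical",
                   seed = "integer"),
    validity = function(object) {
        nf <- length(object@convFilters)
        if (length(object@convKernels) != nf ||
            length(object@poolSizes) != nf)
            return("convFilters, convKernels and poolSizes must have equal length")
        if (object@maxLen < 1L) return("'maxLen' must be >= 1")
        if (!object@optimizer %in% c("sgd", "adam"))
            return("'optimizer' must be \"sgd\" or \"adam\"")
        if (object@valFraction < 0 || object@valFraction >= 1)
            return("'valFraction' must lie in [0, 1)")
        TRUE
    })

#' ClassifierModel: the trained lncRNA/mRNA discriminator
#'
#' Bundles every parameter of the supervised network (embedding table,
#' forward and backward LSTM cells, convolution stages, logistic head) with
#' the [NetworkConfig] that shaped it. Probabilities returned by
#' [predictProba()] are \eqn{p(y=1\mid x)} for the mRNA class;
#' \eqn{p(y=0\mid x) = 1 - p(y=1\mid x)} exactly.
#'
#' @slot params named list of parameter arrays (see [initClassifier()]).
#' @slot config a [NetworkConfig].
#' @slot k integer k-mer length of the vocabulary the model expects.
#'
#' @seealso [trainClassifier()], [predictProba()]
#' @export
setClass("ClassifierModel",
    representation(params = "list", config = "NetworkConfig", k = "integer"))

#' RocCurve: receiver operating characteristic
#'
#' ROC points (false positive rate on the horizontal axis, true positive
#' rate on the vertical axis) swept over all distinct score thresholds with
#' tie grouping, plus the trapezoidal area under the curve.
#'
#' @slot fpr numeric non-decreasing vector starting at 0 and ending at 1.
#' @slot tpr numeric vector of matching true positive rates.
#' @slot auroc numeric scalar in [0, 1].
#'
#' @seealso [rocAuc()]
#' @export
setClass("RocCurve",
    representation(fpr = "numeric", tpr = "numeric", auroc = "numeric"),
    validity = function(object) {
        if (length(object@fpr) != length(object@tpr))
            return("'fpr' and 'tpr' must have equal length")
        if (is.unsorted(object@fpr)) return("'fpr' must be non-decreasing")
        TRUE
    })

setMethod("show", "KmerVocabulary", function(object) {
    cat(sprintf("KmerVocabulary: k = %d, %d k-mers (A,C,T,G digit order)\n",
                object@k, length(object@kmers)))
    cat("  first entries:",
        paste(sprintf("%s=%d", head(object@kmers, 4L), 1:4), collapse = ", "),
        "\n")
})

setMethod("show", "KmerCorpus", function(object) {
    lens <- lengths(object@tokens)
    cat(sprintf("KmerCorpus: %d sequences, k = %d, stride = %d\n",
                length(object@tokens), object@k, object@stride))
    if (length(lens))
        cat(sprintf("  token lengths: min %d, median %.0f, max %d\n",
                    min(lens), stats::median(lens), max(lens)))
    if (length(object@labels))
        cat(sprintf("  labels: %d lncRNA (0), %d mRNA (1)\n",
                    sum(object@labels == 0L), sum(object@labels == 1L)))
})

setMethod("show", "CooccurrenceMatrix", function(object) {
    cat(sprintf(
        "CooccurrenceMatrix: V = %d (k = %d), window diameter %d\n",
        nrow(object@counts), object@k, object@windowDiameter))
    cat(sprintf("  %d nonzero entries, total count %.0f\n",
                length(object@counts@x), sum(object@counts@x)))
})

setMethod("show", "GloveModel", function(object) {
    cat(sprintf("GloveModel: V = %d, D = %d, xMax = %g, alpha = %g\n",
                nrow(object@W), ncol(object@W), object@xMax, object@alpha))
    if (length(object@history))
        cat(sprintf("  trained %d iterations, loss %.4g -> %.4g\n",
                    length(object@history), object@history[1L],
                    object@history[length(object@history)]))
})

setMethod("show", "NetworkConfig", function(object) {
    cat("NetworkConfig\n")
    cat(sprintf("  maxLen %d, embedding D %d, LSTM hidden %d/direction%s\n",
                object@maxLen, object@embeddingDim, object@lstmHidden,
                if (object@useBlstm) "" else " (BLSTM disabled)"))
    cat(sprintf("  conv filters %s, kernels %s, pools %s%s\n",
                paste(object@convFilters, collapse = "/"),
                paste(object@convKernels, collapse = "/"),
                paste(object@poolSizes, collapse = "/"),
                if (object@useConv) "" else " (conv disabled)"))
    cat(sprintf("  %s, lr %g, batch %d, <= %d epochs (patience %d)\n",
                object@optimizer, object@learningRate, object@batchSize,
                object@maxEpochs, object@patience))
})

setMethod("show", "ClassifierModel", function(object) {
    np <- sum(vapply(object@params, length, integer(1L)))
    cat(sprintf("ClassifierModel: k = %d, %d trainable values\n",
                object@k, np))
    show(object@config)
})

setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve: %d points, auROC = %.4f\n",
                length(object@fpr), object@auroc))
})
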