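.ALPHABET <- c("A", "C", "T", "G")  # digit order: A=0, C=1, T=2, G=3

#' Build the k-mer vocabulary
#'
#' Enumerates all \eqn{4^k} k-mers over the alphabet in the fixed digit
#' order A, C, T, G and assigns index \eqn{1 +} base-4 value, so the first
#' character is the most significant digit: for k = 2, "AA" = 1, "AC" = 2,
#' "AT" = 3, "AG" = 4, ..., "GG" = 16. Index 0 is reserved for padding.
#'
#' @param k k-mer length, between 1 and 10 (4^10 is the largest vocabulary
#'   this constructor will allocate).
#' @return A [KmerVocabulary-class].
#' @examples
#' v <- kmerVocabulary(2)
#' kmerIndex(v, c("AA", "AC", "AT", "AG"))
#' @export
kmerVocabulary <- function(k) {
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k < 1L || k > 10L)
        stop("'k' must be a single integer in [1, 10]")
    # expand.grid with the first position slowest-varying = most significant
    digits <- rev(expand.grid(rep(list(.ALPHABET), k),
                              stringsAsFactors = FALSE))
    kmers <- do.call(paste0, digits)
    new("KmerVocabulary", k = k, kmers = kmers)
}

#' @describeIn kmerVocabulary number of k-mers (4^k).
#' @param vocab a [KmerVocabulary-class].
#' @export
vocabSize <- function(vocab) length(vocab@kmers)

#' Map k-mer strings to integer indices
#'
#' @param vocab a [KmerVocabulary-class].
#' @param kmers character vector of k-mer strings.
#' @return Integer indices in \eqn{[1, 4^k]}.
#' @export
kmerIndex <- function(vocab, kmers) {
    idx <- .kmerIndexOf(kmers, vocab@k)
    if (anyNA(idx)) stop("not a valid k-mer for this vocabulary: ",
                         paste(head(kmers[is.na(idx)], 3L), collapse = ", "))
    idx
}

#' Map integer indices back to k-mer strings
#'
#' @param vocab a [KmerVocabulary-class].
#' @param index integer vector in \eqn{[1, 4^k]}.
#' @return Character vector of k-mers.
#' @export
kmerOf <- function(vocab, index) {
    if (any(index < 1L | index > vocabSize(vocab)))
        stop("index out of range [1, ", vocabSize(vocab), "]")
    vocab@kmers[index]
}

# base-4 digit value per character: A=0, C=1, T=2, G=3; NA for anything else
.baseDigits <- function(chars) {
    d <- match(chars, .ALPHABET) - 1L
    d
}

# vectorized k-mer string -> index (NA when any character is not ACTG)
.kmerIndexOf <- function(kmers, k) {
    if (!length(kmers)) return(integer(0L))
    if (any(nchar(kmers) != k)) stop("all k-mers must have length ", k)
    mat <- matrix(.baseDigits(unlist(strsplit(kmers, "", fixed = TRUE))),
                  nrow = k)
    pows <- 4^((k - 1L):0)
    as.integer(colSums(mat * pows) + 1)
}

# integer digit vector (0..3) for one sequence string; NA for non-ACTG
.seqDigits <- function(seq) {
    .baseDigits(strsplit(seq, "", fixed = TRUE)[[1L]])
}

#' Tokenize transcripts into k-mer index sequences
#'
#' Slides a window of length k with step `stride` along each sequence;
#' each window becomes the integer index of its k-mer. Trailing bases that
#' do not fill a complete window are discarded, so a sequence of length n
#' yields \eqn{L = \lfloor (n-k)/s \rfloor + 1} tokens.
#'
#' @param records an `XStringSet` or character vector of cleaned (ACTG
#'   only) sequences; labels in `mcols` are carried into the corpus.
#' @param vocab a [KmerVocabulary-class].
#' @param stride window step s (>= 1); defaults to k (non-overlapping
#'   windows).
#' @return A [KmerCorpus-class].
#' @examples
#' v <- kmerVocabulary(2)
#' tokenizeSequences(c(x = "AAACAC"), v, stride = 2)
#' @export
tokenizeSequences <- function(records, vocab, stride = vocab@k) {
    stride <- as.integer(stride)
    if (stride < 1L) stop("'stride' must be >= 1")
    k <- vocab@k
    labs <- if (methods::is(records, "XStringSet"))
        transcriptLabels(records) else integer(0L)
    ids <- names(records)
    seqs <- as.character(records)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    short <- nchar(seqs) < k
    if (any(short))
        stop("sequence(s) shorter than k = ", k, ": ",
             paste(head(ids[short], 3L), collapse = ", "))
    pows <- 4^((k - 1L):0)
    tokens <- lapply(seqs, function(s) {
        d <- .seqDigits(s)
        if (anyNA(d)) stop("sequence contains non-ACTG characters; run cleanSequences() first")
        n <- length(d)
        starts <- seq.int(1L, n - k + 1L, by = stride)
        if (k == 1L) return(d[starts] + 1L)
        idx <- outer(starts, 0L:(k - 1L), `+`)
        as.integer(matrix(d[idx], nrow = length(starts)) %*% pows + 1)
    })
    names(tokens) <- ids
    keptLabs <- if (length(labs) && !anyNA(labs)) as.integer(labs)
                else integer(0L)
    new("KmerCorpus", tokens = tokens, k = k, stride = stride,
        labels = keptLabs)
}

#' Pad or truncate token sequences to a fixed length
#'
#' Short sequences are right-filled with the padding token 0; long
#' sequences keep their first `maxLen` tokens (the 5' prefix). Idempotent
#' at a fixed `maxLen`.
#'
#' @param x an integer token vector, a list of such vectors, or a
#'   [KmerCorpus-class].
#' @param maxLen fixed output length (default 1000).
#' @return For a single vector, an integer vector of length `maxLen`;
#'   otherwise an n x `maxLen` integer matrix with one row per sequence.
#' @export
padTruncate <- function(x, maxLen = 1000L) {
    maxLen <- as.integer(maxLen)
    if (maxLen < 1L) stop("'maxLen' must be >= 1")
    pad1 <- function(v) {
        L <- length(v)
        if (L >= maxLen) v[seq_len(maxLen)] else c(v, integer(maxLen - L))
    }
    if (is(x, "KmerCorpus")) x <- x@tokens
    if (is.list(x)) {
        out <- matrix(0L, nrow = length(x), ncol = maxLen,
                      dimnames = list(names(x), NULL))
        for (i in seq_along(x)) out[i, ] <- pad1(as.integer(x[[i]]))
        out
    } else {
        pad1(as.integer(x))
    }
}

#' Write a tokenized corpus as plain text
#'
#' One sequence per line: the record id followed by its integer tokens,
#' whitespace-delimited — convenient for inspection and as an exchange
#' format for co-occurrence tooling.
#'
#' @param corpus a [KmerCorpus-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTokenCorpus <- function(corpus, path) {
    lines <- vapply(seq_along(corpus@tokens), function(i)
        paste(c(names(corpus@tokens)[i], corpus@tokens[[i]]),
              collapse = " "), character(1L))
    writeLines(lines, path)
    invisible(path)
}

#' Read a corpus written by [writeTokenCorpus()]
#'
#' @param path text file of id-plus-token lines.
#' @param k,stride tokenization settings to record on the corpus.
#' @return A [KmerCorpus-class] (unlabelled).
#' @export
readTokenCorpus <- function(path, k, stride = k) {
    fields <- strsplit(readLines(path), "[[:space:]]+")
    ids <- vapply(fields, `[`, character(1L), 1L)
    toks <- lapply(fields, function(f) as.integer(f[-1L]))
    names(toks) <- ids
    new("KmerCorpus", tokens = toks, k = as.integer(k),
        stride = as.integer(stride), labels = integer(0L))
}
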