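.STOP_CODONS <- c("TAA", "TAG", "TGA")

.senseCodons <- function() {
    all <- as.vector(outer(as.vector(outer(.ALPHABET, .ALPHABET, paste0)),
                           .ALPHABET, paste0))
    setdiff(all, .STOP_CODONS)
}

# codon usage at a given separation: mixture of the uniform sense-codon
# distribution and a GC-favouring table (weight ~ exp(#GC in codon))
.codonProbs <- function(separation, gcBias = 1) {
    codons <- .senseCodons()
    gc <- vapply(strsplit(codons, ""), function(ch) sum(ch %in% c("G", "C")),
                 numeric(1L))
    biased <- exp(gcBias * gc)
    biased <- biased / sum(biased)
    unif <- rep(1 / length(codons), length(codons))
    p <- (1 - separation) * unif + separation * biased
    names(p) <- codons
    p
}

#' Simulate labelled lncRNA/mRNA-like transcripts
#'
#' Generates two sequence classes whose separability is a single knob.
#' Class 0 ("lncRNA-like") sequences are i.i.d. nucleotides from
#' `baseComposition` with log-normal lengths. Class 1 ("mRNA-like")
#' sequences start from the same background but carry one planted open
#' reading frame: an ATG start codon, in-frame sense codons drawn from a
#' codon table interpolated between uniform codon usage and a GC-biased
#' table by `separation`, and a stop codon. The planted ORF length is
#' always a multiple of 3, covers about `orfFraction` of the transcript,
#' and is placed uniformly at random. Class-1 lengths interpolate
#' (log-linearly, by `separation`) from the class-0 median towards the
#' longer mRNA regime, so at `separation = 0` no ORF is planted and both
#' class-conditional distributions are identical; at `separation = 1` the
#' classes mimic the real lncRNA/mRNA contrast in both composition and
#' length. All outputs pass [cleanSequences()] unchanged (ACTG only,
#' >= 200 nt) and generation is deterministic for a given `seed`.
#'
#' @param nPerClass sequences per class.
#' @param separation class-separation knob in [0, 1].
#' @param seed integer RNG seed.
#' @param lncMedianLen,mrnaMedianLen median transcript lengths (nt) of the
#'   lncRNA background and of the fully separated mRNA class.
#' @param sdlog log-normal spread of lengths.
#' @param minLen,maxLen truncation bounds (nt) for the length draw.
#' @param orfFraction target fraction of an mRNA-like transcript covered
#'   by its planted ORF.
#' @param baseComposition named nucleotide probabilities (A, C, T, G).
#' @param gcBias strength of the GC preference in the biased codon table.
#' @return A labelled [Biostrings::DNAStringSet] (`label` metadata column:
#'   0 = lncRNA-like, 1 = mRNA-like) with the generator settings attached
#'   as the `"simParams"` attribute of its metadata.
#' @export
simulateTranscripts <- function(nPerClass, separation = 1, seed = 1L,
                                lncMedianLen = 900, mrnaMedianLen = 2500,
                                sdlog = 0.7, minLen = 200L, maxLen = 10000L,
                                orfFraction = 0.5,
                                baseComposition = c(A = 0.25, C = 0.25,
                                                    T = 0.25, G = 0.25),
                                gcBias = 1) {
    if (nPerClass < 1L) stop("'nPerClass' must be >= 1")
    if (separation < 0 || separation > 1)
        stop("'separation' must lie in [0, 1]")
    if (minLen < 12L || maxLen <= minLen)
        stop("infeasible length bounds")
    if (is.null(names(baseComposition)) ||
        !setequal(names(baseComposition), .ALPHABET))
        stop("'baseComposition' must be named with A, C, T, G")
    baseComposition <- baseComposition[.ALPHABET] / sum(baseComposition)
    set.seed(seed)

    drawLen <- function(n, median) {
        x <- rlnorm(n, meanlog = log(median), sdlog = sdlog)
        pmin(pmax(round(x), minLen), maxLen)
    }
    background <- function(len)
        paste(sample(.ALPHABET, len, replace = TRUE,
                     prob = baseComposition), collapse = "")

    lens0 <- drawLen(nPerClass, lncMedianLen)
    class0 <- vapply(lens0, background, character(1L))

    # class-1 length median interpolates towards the mRNA regime
    med1 <- exp((1 - separation) * log(lncMedianLen) +
                separation * log(mrnaMedianLen))
    lens1 <- drawLen(nPerClass, med1)
    if (separation == 0) {
        class1 <- vapply(lens1, background, character(1L))
    } else {
        codonP <- .codonProbs(separation, gcBias)
        codons <- names(codonP)
        class1 <- vapply(lens1, function(len) {
            s <- strsplit(background(len), "", fixed = TRUE)[[1L]]
            nCodon <- max(1L, floor(orfFraction * len / 3) - 2L)
            orfLen <- 3L * (nCodon + 2L)          # start + body + stop
            while (orfLen > len) {
                nCodon <- nCodon - 1L
                orfLen <- 3L * (nCodon + 2L)
            }
            at <- sample.int(len - orfLen + 1L, 1L)
            orf <- c("ATG",
                     sample(codons, nCodon, replace = TRUE, prob = codonP),
                     sample(.STOP_CODONS, 1L))
            s[at:(at + orfLen - 1L)] <-
                strsplit(paste(orf, collapse = ""), "", fixed = TRUE)[[1L]]
            paste(s, collapse = "")
        }, character(1L))
    }

    ids <- c(sprintf("lnc_%05d", seq_len(nPerClass)),
             sprintf("mrna_%05d", seq_len(nPerClass)))
    out <- Biostrings::DNAStringSet(c(class0, class1))
    names(out) <- ids
    md <- S4Vectors::DataFrame(label = rep(c(0L, 1L), each = nPerClass))
    S4Vectors::metadata(md) <- list(simParams = list(
        nPerClass = nPerClass, separation = separation, seed = seed,
        lncMedianLen = lncMedianLen, mrnaMedianLen = mrnaMedianLen,
        sdlog = sdlog, minLen = minLen, maxLen = maxLen,
        orfFraction = orfFraction,
        baseComposition = as.list(baseComposition), gcBias = gcBias))
    S4Vectors::mcols(out) <- md
    out
}

#' Write a simulated dataset to disk
#'
#' Emits the FASTA, an `id<TAB>label` TSV, and a plain-text sidecar
#' recording every generator parameter for provenance.
#'
#' @param records output of [simulateTranscripts()].
#' @param dir output directory (created if missing).
#' @param prefix file name stem.
#' @return Named character vector of the three paths, invisibly.
#' @export
writeSimulatedDataset <- function(records, dir, prefix = "synthetic") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, paste0(prefix, ".fa"))
    labels <- file.path(dir, paste0(prefix, "_labels.tsv"))
    sidecar <- file.path(dir, paste0(prefix, "_params.tsv"))
    writeTranscripts(records, fasta, labels)
    prm <- S4Vectors::metadata(S4Vectors::mcols(records))$simParams
    if (!is.null(prm)) {
        flat <- vapply(prm, function(v)
            paste(unlist(v), collapse = ","), character(1L))
        writeLines(paste(names(flat), flat, sep = "\t"), sidecar)
    }
    invisible(c(fasta = fasta, labels = labels, params = sidecar))
}

#' Class-averaged k-mer frequency divergence
#'
#' Total-variation distance between the mean k-mer frequency vectors of
#' the two classes; a scalar summary of how compositionally separated a
#' (simulated or real) labelled dataset is.
#'
#' @param records labelled `XStringSet`.
#' @param k k-mer length (default 6).
#' @return Numeric in [0, 1].
#' @export
kmerDivergence <- function(records, k = 6L) {
    labs <- transcriptLabels(records)
    vocab <- kmerVocabulary(k)
    corpus <- tokenizeSequences(records, vocab, stride = 1L)
    freq <- function(idx) {
        tab <- tabulate(unlist(corpus@tokens[idx], use.names = FALSE),
                        nbins = vocabSize(vocab))
        tab / sum(tab)
    }
    sum(abs(freq(which(labs == 0L)) - freq(which(labs == 1L)))) / 2
}
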