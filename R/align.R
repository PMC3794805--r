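#' @rdname globalAlign
#' @export
setClass("PairwiseHit",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", identity = "numeric",
                 alignedLength = "integer",
                 coverageA = "numeric", coverageB = "numeric"))

setMethod("show", "PairwiseHit", function(object) {
  cat(sprintf("PairwiseHit: score %.1f, identity %.3f, aligned length %d\n",
              object@score, object@identity, object@alignedLength))
  if (nchar(object@alignedA) <= 60) {
    cat(" ", object@alignedA, "\n ", object@alignedB, "\n")
  }
})

#' Alignment scoring schemes
#'
#' Protein alignments default to BLOSUM62 with gap open 10 / extend 1
#' (a gap of length k costs open + k*extend); nucleotide alignments to
#' match 2 / mismatch -3 / gap open 5 / extend 2, with N scored as a
#' mismatch against everything so that ambiguity never creates identity.
#'
#' @param type "protein" or "dna"
#' @param gapOpening,gapExtension gap penalties (positive costs)
#' @param substitutionMatrix optional custom matrix
#' @return a list used by \code{\link{globalAlign}} / \code{\link{localAlign}}
#' @export
alignScoring <- function(type = c("protein", "dna"), gapOpening = NULL,
                         gapExtension = NULL, substitutionMatrix = NULL) {
  type <- match.arg(type)
  if (is.null(substitutionMatrix)) {
    substitutionMatrix <- if (type == "protein") blosum62Matrix()
                          else dnaScoringMatrix()
  }
  list(type = type,
       matrix = substitutionMatrix,
       gapOpening = gapOpening %||% (if (type == "protein") 10 else 5),
       gapExtension = gapExtension %||% (if (type == "protein") 1 else 2))
}

blosum62Matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

dnaScoringMatrix <- function(match = 2, mismatch = -3) {
  m <- matrix(mismatch, 5L, 5L, dimnames = list(DNA5, DNA5))
  diag(m) <- match
  m["N", "N"] <- mismatch   # N never matches anything, including itself
  m
}

# Compute identity/coverage statistics from a pair of gapped strings.
# identity   = matches / columns excluding double-gap columns
# alignedLength = columns where BOTH sequences carry a residue
# coverage_x = residue-vs-residue aligned columns / full length of x
alignmentStats <- function(alnA, alnB, lenA, lenB, score) {
  if (!nzchar(alnA) && !nzchar(alnB)) {
    return(new("PairwiseHit", alignedA = "", alignedB = "", score = 0,
               identity = 0, alignedLength = 0L, coverageA = 0, coverageB = 0))
  }
  a <- strsplit(alnA, "", fixed = TRUE)[[1]]
  b <- strsplit(alnB, "", fixed = TRUE)[[1]]
  gapA <- a == "-"
  gapB <- b == "-"
  cols <- !(gapA & gapB)
  both <- !gapA & !gapB
  matches <- sum(both & a == b)
  new("PairwiseHit",
      alignedA = alnA, alignedB = alnB, score = score,
      identity = matches / sum(cols),
      alignedLength = sum(both),
      coverageA = sum(both) / lenA,
      coverageB = sum(both) / lenB)
}

checkAlignInputs <- function(a, b, scoring) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("alignment requires non-empty sequences")
  alA <- stringAlphabet(a); alB <- stringAlphabet(b)
  if (is.na(alA) || is.na(alB)) stop("sequence with unknown characters")
  if (is.null(scoring)) {
    # DNA-compatible strings are also valid protein strings; only treat the
    # pair as nucleotide when both sides look like nucleotide.
    type <- if (alA == "dna" && alB == "dna") "dna" else "protein"
    if (type == "protein" && (alA == "dna") != (alB == "dna") &&
        (nchar(a) >= 30 || nchar(b) >= 30)) {
      # long ACGT-only vs protein is almost surely a caller error
      stop("mixed alphabets: one sequence looks nucleotide, the other protein")
    }
    scoring <- alignScoring(type)
  } else {
    ok <- rownames(scoring$matrix)
    if (!all(seqChars(a) %in% ok) || !all(seqChars(b) %in% ok))
      stop("sequence characters outside the scoring matrix alphabet")
  }
  list(a = a, b = b, scoring = scoring)
}

runPairwise <- function(a, b, scoring, type) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = type,
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
  alignmentStats(as.character(Biostrings::alignedPattern(aln)),
                 as.character(Biostrings::alignedSubject(aln)),
                 nchar(a), nchar(b), Biostrings::score(aln))
}

#' Optimal pairwise alignment
#'
#' \code{globalAlign} computes the optimal Needleman-Wunsch global alignment
#' under an affine gap model; \code{localAlign} the optimal Smith-Waterman
#' local alignment, returning an empty alignment with score 0 when no
#' positive-scoring pair of substrings exists. The alignment engine is
#' \code{Biostrings::pairwiseAlignment}; identity, aligned length and
#' per-sequence coverage are derived from the aligned strings (identity over
#' all alignment columns, excluding columns where both sequences gap).
#'
#' @param a,b sequences (character or XString); both protein or both
#'   nucleotide
#' @param scoring a scheme from \code{\link{alignScoring}}; by default chosen
#'   from the sequence alphabet
#' @return a \code{PairwiseHit}
#' @export
globalAlign <- function(a, b, scoring = NULL) {
  x <- checkAlignInputs(a, b, scoring)
  runPairwise(x$a, x$b, x$scoring, "global")
}

#' @rdname globalAlign
#' @export
localAlign <- function(a, b, scoring = NULL) {
  x <- checkAlignInputs(a, b, scoring)
  hit <- runPairwise(x$a, x$b, x$scoring, "local")
  if (hit@score < 0) {
    # Smith-Waterman floor: no positive-scoring pair of substrings
    hit <- new("PairwiseHit", alignedA = "", alignedB = "", score = 0,
               identity = 0, alignedLength = 0L, coverageA = 0, coverageB = 0)
  }
  hit
}

# Vectorised alignment of many patterns against one subject; returns a
# data.frame of statistics. Used by the screening/redundancy/duplication
# stages where thousands of pairs are evaluated, so everything is computed
# from the engine's O(1) accessors: alignedLength = residue-vs-residue
# columns (nmatch + nmismatch); total columns = residues of both sequences
# in the aligned span minus alignedLength (for global alignments the span
# is the full sequences, so this correctly counts end-gap columns).
alignManyStats <- function(patterns, subject, scoring, type = "global") {
  if (!is.null(S4Vectors::mcols(patterns))) S4Vectors::mcols(patterns) <- NULL
  aln <- Biostrings::pairwiseAlignment(
    patterns, subject, type = type,
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
  lenA <- Biostrings::width(patterns)
  lenB <- nchar(as.character(subject))
  M <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  if (type == "global") {
    wA <- lenA
    wB <- rep(lenB, length(aln))
  } else {
    wA <- Biostrings::width(Biostrings::pattern(aln))
    wB <- Biostrings::width(Biostrings::subject(aln))
    empty <- M == 0L
    wA[empty] <- 0L; wB[empty] <- 0L
  }
  cols <- wA + wB - M
  data.frame(score = Biostrings::score(aln),
             identity = ifelse(cols > 0, Biostrings::nmatch(aln) / cols, 0),
             alignedLength = as.integer(M),
             coverageA = M / lenA, coverageB = M / lenB,
             row.names = NULL)
}
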