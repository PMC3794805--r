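#' @import methods
#' @importFrom stats runif rlnorm setNames cor
#' @importFrom utils read.delim write.table head tail
NULL

# 20-letter protein alphabet used throughout; X/B/Z are rejected on input.
AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
DNA5 <- c("A","C","G","T","N")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Package-level logging
#'
#' Stage functions log record counts at level "info" and per-record decisions
#' at level "debug". Verbosity is controlled by
#' \code{options(kinfamscan.verbose = )}: 0 silences everything, 1 (default)
#' prints info, 2 adds debug output.
#'
#' @param level "info" or "debug"
#' @param ... passed to \code{sprintf}
#' @return invisibly, the formatted message
#' @export
logMsg <- function(level = c("info", "debug"), ...) {
  level <- match.arg(level)
  v <- getOption("kinfamscan.verbose", 1L)
  txt <- sprintf(...)
  if ((level == "info" && v >= 1L) || (level == "debug" && v >= 2L))
    message("[", level, "] ", txt)
  invisible(txt)
}

# Derive a reproducible stage seed from the run seed; kept below 2^31.
subSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + sum(utf8ToInt(stage)) %% 1000L
}

# Evaluate expr with a local RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Random residue / nucleotide strings (generator + tests).
randProtein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
randDna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

seqChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

revComp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Classify a residue string: "dna" if it only uses ACGTN, "protein" if it
# only uses the 20 standard residues, otherwise NA. DNA-compatible strings
# are also protein-compatible, so "dna" is checked first.
stringAlphabet <- function(x) {
  ch <- unique(seqChars(x))
  if (all(ch %in% DNA5)) return("dna")
  if (all(ch %in% AA20)) return("protein")
  NA_character_
}

extdata <- function(file) {
  p <- system.file("extdata", file, package = "kinfamscan")
  if (!nzchar(p)) stop("packaged data file not found: ", file)
  p
}
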