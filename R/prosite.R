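#' @rdname parseProsite
#' @export
setClass("PrositePattern",
  representation(name = "character", pattern = "character",
                 regex = "character", elements = "list",
                 anchorStart = "logical", anchorEnd = "logical"))

setMethod("show", "PrositePattern", function(object) {
  cat("PrositePattern", object@name, ":", object@pattern, "\n")
})

#' Parse a PROSITE-style pattern into a compiled matcher
#'
#' Supports the PROSITE grammar used for kinase hallmark and subfamily
#' signature motifs: residue letters, \code{x} (any of the 20 standard
#' residues), \code{[..]} (one-of), \code{\{..\}} (none-of), \code{(n)} /
#' \code{(n,m)} repetition counts, \code{-} element separators, and the
#' \code{<} / \code{>} terminal anchors. \code{x} deliberately means "any
#' standard residue", not "unknown residue". A trailing period is tolerated.
#'
#' @param pattern pattern string, e.g. \code{"G-[TS]-P-x-[WF]-M-A-P-E-V"}
#' @param name label carried through match reports
#' @return a \code{PrositePattern} object
#' @export
parseProsite <- function(pattern, name = "pattern") {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  p <- sub("\\.$", "", pattern)
  anchorStart <- startsWith(p, "<")
  if (anchorStart) p <- substring(p, 2L)
  anchorEnd <- endsWith(p, ">")
  if (anchorEnd) p <- substring(p, 1L, nchar(p) - 1L)
  toks <- strsplit(p, "-", fixed = TRUE)[[1]]
  if (length(toks) == 0L || any(!nzchar(toks)))
    stop("malformed PROSITE pattern '", pattern, "': empty element")
  rxAny <- paste0("[", paste(AA20, collapse = ""), "]")
  elements <- vector("list", length(toks))
  pieces <- character(length(toks))
  m <- regexec("^(?:([A-Za-z])|\\[([A-Z]+)\\]|\\{([A-Z]+)\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$",
               toks)
  for (i in seq_along(toks)) {
    g <- regmatches(toks, m)[[i]]
    if (length(g) == 0L)
      stop("malformed PROSITE element '", toks[i], "' at position ", i,
           " in pattern '", pattern, "'")
    single <- g[2]; oneof <- g[3]; noneof <- g[4]
    nmin <- if (nzchar(g[5])) as.integer(g[5]) else 1L
    nmax <- if (nzchar(g[6])) as.integer(g[6]) else nmin
    if (nmax < nmin) stop("bad repetition in element ", i, " of '", pattern, "'")
    if (nzchar(single)) {
      single <- toupper(single)
      if (single == "X") {
        allowed <- AA20
        piece <- rxAny
      } else {
        if (!single %in% AA20)
          stop("unknown residue '", single, "' at element ", i, " of '", pattern, "'")
        allowed <- single
        piece <- single
      }
    } else if (nzchar(oneof)) {
      allowed <- strsplit(oneof, "")[[1]]
      if (!all(allowed %in% AA20))
        stop("unknown residue in [", oneof, "] at element ", i, " of '", pattern, "'")
      piece <- paste0("[", oneof, "]")
    } else {
      excl <- strsplit(noneof, "")[[1]]
      allowed <- setdiff(AA20, excl)
      if (length(allowed) == 0L)
        stop("empty residue class at element ", i, " of '", pattern, "'")
      piece <- paste0("[", paste(allowed, collapse = ""), "]")
    }
    rep <- if (nmin == 1L && nmax == 1L) "" else if (nmin == nmax)
      sprintf("{%d}", nmin) else sprintf("{%d,%d}", nmin, nmax)
    pieces[i] <- paste0(piece, rep)
    elements[[i]] <- list(allowed = allowed, min = nmin, max = nmax)
  }
  rx <- paste0(if (anchorStart) "^" else "", paste(pieces, collapse = ""),
               if (anchorEnd) "$" else "")
  new("PrositePattern", name = name, pattern = pattern, regex = rx,
      elements = elements, anchorStart = anchorStart, anchorEnd = anchorEnd)
}

#' Find all match positions of a PROSITE pattern
#'
#' Reports every match start, including overlapping matches (a lookahead
#' scan). For variable-repetition elements the longest match at each start is
#' reported.
#'
#' @param ppat a \code{PrositePattern}
#' @param seq a residue string, \code{AAString}, or length-1 XStringSet
#' @return data.frame with columns \code{start}, \code{end}, \code{match}
#' @export
prositeMatch <- function(ppat, seq) {
  s <- as.character(seq)
  if (length(s) != 1L) stop("prositeMatch expects a single sequence")
  rx <- paste0("(?=(", ppat@regex, "))")
  hit <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (hit[1L] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0)))
  starts <- as.integer(hit)
  lens <- attr(hit, "capture.length")[, 1L]
  data.frame(start = starts, end = starts + lens - 1L,
             match = substring(s, starts, starts + lens - 1L))
}

#' Test whether a pattern matches anywhere in each sequence
#'
#' @param ppat a \code{PrositePattern}
#' @param seqs character vector or XStringSet
#' @return named logical vector
#' @export
prositeHits <- function(ppat, seqs) {
  s <- as.character(seqs)
  setNames(grepl(ppat@regex, s, perl = TRUE), names(seqs))
}

# Sample one realization of a pattern (generator-side). Repetition counts
# are sampled uniformly between min and max; residues uniformly from the
# element's allowed set. Uses the current RNG stream.
prositeRealize <- function(ppat) {
  paste(vapply(ppat@elements, function(el) {
    n <- if (el$max > el$min) sample(el$min:el$max, 1L) else el$min
    if (n == 0L) return("")
    paste(sample(el$allowed, n, replace = TRUE), collapse = "")
  }, character(1)), collapse = "")
}

#' Load the packaged kinase hallmark patterns
#'
#' The three hallmark motifs (ATP-binding loop, serine/threonine active
#' site, and a catalytic kinase-domain motif) are operational patterns
#' shipped as configuration in \code{inst/extdata/hallmarks.yaml}; users can
#' substitute their own pattern file, e.g. to plug in a true profile
#' scanner's output.
#'
#' @param path YAML file with a \code{patterns} list of name/pattern entries
#' @return named list of \code{PrositePattern}
#' @export
hallmarkPatterns <- function(path = extdata("hallmarks.yaml")) {
  cfg <- yaml::read_yaml(path)
  pats <- lapply(cfg$patterns, function(p) parseProsite(p$pattern, p$name))
  names(pats) <- vapply(cfg$patterns, `[[`, character(1), "name")
  pats
}
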