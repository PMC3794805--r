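#' Call duplicated gene pairs
#'
#' Brute-force evaluation of every unordered gene pair with global
#' nucleotide alignment. A pair is reported when (1) the aligned region
#' covers more than \code{cov} of the longer gene (aligned length = columns
#' where both sequences carry a residue) and (2) its identity exceeds
#' \code{ident}; both thresholds are strict, so pairs at exactly 0.8 are
#' excluded. Pairs on the same chromosome within \code{linkage_window} bp
#' (distance between gene spans) are "tandem"; tightly linked pairs are
#' merged into a single duplication event by single-linkage, so a tandem
#' cluster of three mutually similar genes counts one event.
#'
#' @param cdnas named DNAStringSet of gene (cDNA) sequences
#' @param summary gene location table from \code{\link{geneStructures}}
#'   (gene_id, chromosome + exon spans) or an annotation table; needs
#'   columns gene_id, chromosome, start, end (start/end taken from the
#'   chains when absent)
#' @param cov,ident strict thresholds on coverage of the longer gene and on
#'   identity (defaults 0.8 / 0.8)
#' @param linkage_window tandem linkage distance in bp
#' @param scoring nucleotide scoring scheme
#' @return list with \code{pairs} (data.frame: gene_a, gene_b, identity,
#'   coverage_longer, distance, linkage, event_id) and \code{n_events}
#' @export
callDuplications <- function(cdnas, summary, cov = 0.8, ident = 0.8,
                             linkage_window = 250000L,
                             scoring = alignScoring("dna")) {
  n <- length(cdnas)
  if (n < 2L) stop("at least two genes are required")
  ids <- names(cdnas)
  lens <- Biostrings::width(cdnas)
  rows <- list()
  for (j in 2:n) {
    st <- alignManyStats(cdnas[1:(j - 1L)], cdnas[[j]], scoring, "global")
    covL <- st$alignedLength / pmax(lens[1:(j - 1L)], lens[j])
    hit <- which(covL > cov & st$identity > ident)
    for (i in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ids[i], gene_b = ids[j],
        identity = st$identity[i], coverage_longer = covL[i],
        row.names = NULL)
    }
  }
  if (!length(rows)) {
    logMsg("info", "callDuplications: no pairs above thresholds")
    return(list(pairs = data.frame(gene_a = character(0), gene_b = character(0),
                                   identity = numeric(0),
                                   coverage_longer = numeric(0),
                                   distance = numeric(0), linkage = character(0),
                                   event_id = character(0)),
                n_events = 0L))
  }
  pairs <- do.call(rbind, rows)
  dist <- mapply(function(a, b) {
    ia <- match(a, summary$gene_id); ib <- match(b, summary$gene_id)
    if (is.na(ia) || is.na(ib)) return(NA_real_)
    if (is.na(summary$chromosome[ia]) || is.na(summary$chromosome[ib]) ||
        summary$chromosome[ia] != summary$chromosome[ib]) return(Inf)
    max(0, max(summary$start[ia], summary$start[ib]) -
          min(summary$end[ia], summary$end[ib]))
  }, pairs$gene_a, pairs$gene_b)
  pairs$distance <- unname(dist)
  pairs$linkage <- ifelse(is.finite(dist) & dist <= linkage_window,
                          "tandem", "dispersed")
  # merge tightly linked pairs into events (single linkage over tandem pairs)
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  parent <- setNames(genes, genes)
  find <- function(g) { while (parent[[g]] != g) g <- parent[[g]]; g }
  tand <- which(pairs$linkage == "tandem")
  for (k in tand) {
    ra <- find(pairs$gene_a[k]); rb <- find(pairs$gene_b[k])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  pairs$event_id <- NA_character_
  clusters <- unique(vapply(pairs$gene_a[tand], find, character(1)))
  for (k in tand)
    pairs$event_id[k] <- paste0("T", match(find(pairs$gene_a[k]), clusters))
  disp <- which(pairs$linkage == "dispersed")
  pairs$event_id[disp] <- paste0("D", seq_along(disp))
  nEvents <- length(unique(pairs$event_id))
  logMsg("info", "callDuplications: %d pairs, %d events", nrow(pairs), nEvents)
  list(pairs = pairs, n_events = nEvents)
}

#' Annotate duplication events
#'
#' @param dup result of \code{\link{callDuplications}}
#' @param summary gene location table (gene_id, chromosome, start, end)
#' @return data.frame per event: event_id, members (comma string),
#'   chromosomes (comma string), min_distance (bp; Inf across chromosomes)
#' @export
annotateClusters <- function(dup, summary) {
  pairs <- dup$pairs
  if (nrow(pairs) == 0L)
    return(data.frame(event_id = character(0), members = character(0),
                      chromosomes = character(0), min_distance = numeric(0)))
  out <- lapply(split(pairs, pairs$event_id), function(p) {
    members <- sort(unique(c(p$gene_a, p$gene_b)))
    idx <- match(members, summary$gene_id)
    data.frame(event_id = p$event_id[1L],
               members = paste(members, collapse = ","),
               chromosomes = paste(unique(summary$chromosome[idx]), collapse = ","),
               min_distance = min(p$distance), row.names = NULL)
  })
  do.call(rbind, unname(out))
}
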