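# Exact-match exon chaining. Walks the cDNA against the locus sequence,
# extending maximal exact matches and re-anchoring across introns with
# 20-nt seeds. At each splice junction the exon boundary can be locally
# ambiguous (the cDNA may coincidentally match the first intron bases);
# candidates within the ambiguity window are disambiguated by requiring a
# canonical GT..AG intron, falling back to the least-overshoot boundary.
# Returns the exon intervals in locus coordinates; errors with
# "unresolvable structure" when the chain cannot cover 100% of the cDNA.
.chainExons <- function(cdna, locus, min_intron = 20L, seed_len = 20L) {
  cdna <- as.character(cdna); locus <- as.character(locus)
  cv <- seqChars(cdna); gv <- seqChars(locus)
  Lc <- length(cv); Lg <- length(gv)
  if (Lc < seed_len) stop("unresolvable structure: cDNA shorter than seed")
  firstHit <- function(kmer, from) {
    # all occurrence starts of kmer in locus at or after `from`
    m <- gregexpr(kmer, locus, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(integer(0))
    as.integer(m[m >= from])
  }
  runLen <- function(pc, pg) {
    n <- min(Lc - pc, Lg - pg) + 1L
    cmp <- cv[pc:(pc + n - 1L)] != gv[pg:(pg + n - 1L)]
    w <- which(cmp)
    if (length(w)) w[1L] - 1L else n
  }
  g0 <- firstHit(substring(cdna, 1L, seed_len), 1L)
  if (!length(g0)) stop("unresolvable structure: no anchor for cDNA start")
  pc <- 1L; pg <- g0[1L]
  exons <- NULL
  for (iter in seq_len(Lc)) {
    m <- runLen(pc, pg)
    if (m == 0L) stop("unresolvable structure: zero-length match")
    if (pc + m - 1L >= Lc) {
      exons <- rbind(exons, c(pg, pg + (Lc - pc)))
      pc <- Lc + 1L
      break
    }
    p <- pc + m  # first mismatching cDNA position
    ap <- min(p, Lc - seed_len + 1L)
    kmer <- substring(cdna, ap, ap + seed_len - 1L)
    found <- FALSE
    for (gap in firstHit(kmer, pg + 1L)) {
      gp <- gap + (p - ap)           # genomic position of cDNA p on new diagonal
      if (gp <= pg + m) next         # must lie beyond the current exon
      # backward extension: earliest boundary on the new diagonal
      e <- 0L
      while (p - e - 1L > pc && gp - e - 1L > 0L &&
             cv[p - e - 1L] == gv[gp - e - 1L]) e <- e + 1L
      bCand <- seq(p - e, p)
      ok <- vapply(bCand, function(b) {
        prevEnd <- pg + (b - 1L - pc)
        gbStart <- gp - (p - b)
        ilen <- gbStart - prevEnd - 1L
        ilen >= min_intron &&
          gv[prevEnd + 1L] == "G" && gv[prevEnd + 2L] == "T" &&
          gv[gbStart - 2L] == "A" && gv[gbStart - 1L] == "G"
      }, logical(1))
      b <- if (any(ok)) max(bCand[ok]) else {
        # non-canonical intron: least-overshoot boundary with a legal intron
        legal <- vapply(bCand, function(b) {
          gp - (p - b) - (pg + (b - 1L - pc)) - 1L >= min_intron
        }, logical(1))
        if (!any(legal)) next
        max(bCand[legal])
      }
      exons <- rbind(exons, c(pg, pg + (b - 1L - pc)))
      pc <- b; pg <- gp - (p - b)
      found <- TRUE
      break
    }
    if (!found) stop("unresolvable structure: no co-linear anchor after position ", pc)
  }
  if (pc != Lc + 1L) stop("unresolvable structure: incomplete cDNA coverage")
  rec <- paste(vapply(seq_len(nrow(exons)), function(k)
    substring(locus, exons[k, 1L], exons[k, 2L]), character(1)), collapse = "")
  if (!identical(rec, cdna)) stop("unresolvable structure: chain does not spell the cDNA")
  exons
}

#' Locate a cDNA on the genome by exact seeds
#'
#' 20-nt cDNA substrings (both orientations) are matched exactly against
#' every chromosome; the chromosome/strand with the highest number of
#' matching seeds wins. An N in either sequence never matches. Ties across
#' chromosome/strand combinations are flagged "ambiguous"; no hit anywhere
#' is "unplaced".
#'
#' Because near-identical paralogous loci (tandem duplicates) also attract
#' a fraction of the seeds, hits on the winning chromosome are clustered by
#' genomic gaps larger than \code{max_locus_gap}, and the cluster matching
#' the most distinct seeds is taken as the locus span. The gap threshold
#' must exceed the longest expected intron and stay below the distance
#' separating tandem loci.
#'
#' @param cdna a DNAString / character cDNA
#' @param genome DNAStringSet of chromosomes
#' @param seed_length seed size in nt (the >= 20 nt signature convention)
#' @param step spacing between seed start positions
#' @param max_locus_gap genomic gap (bp) that splits seed-hit clusters
#' @return list: chromosome, strand, start, end (approximate span of seed
#'   hits), status ("placed", "ambiguous", "unplaced")
#' @export
locateGene <- function(cdna, genome, seed_length = 20L, step = 5L,
                       max_locus_gap = 1500L) {
  s <- as.character(cdna)
  L <- nchar(s)
  if (L < seed_length) stop("cDNA shorter than the seed length")
  starts <- unique(c(seq(1L, L - seed_length + 1L, by = step), L - seed_length + 1L))
  mkDict <- function(x) {
    sd <- unique(substring(x, starts, starts + seed_length - 1L))
    sd <- sd[!grepl("N", sd, fixed = TRUE)]
    if (!length(sd)) return(NULL)
    Biostrings::PDict(Biostrings::DNAStringSet(sd))
  }
  dicts <- list(`+` = mkDict(s), `-` = mkDict(revComp(s)))
  hits <- matrix(0L, length(genome), 2L,
                 dimnames = list(names(genome), c("+", "-")))
  for (st in c("+", "-")) {
    if (is.null(dicts[[st]])) next
    cnt <- Biostrings::vcountPDict(dicts[[st]], genome)
    hits[, st] <- colSums(cnt > 0L)
  }
  top <- max(hits)
  if (top == 0L)
    return(list(chromosome = NA_character_, strand = NA_character_,
                start = NA_integer_, end = NA_integer_, status = "unplaced"))
  winners <- which(hits == top, arr.ind = TRUE)
  status <- if (nrow(winners) > 1L) "ambiguous" else "placed"
  chrom <- rownames(hits)[winners[1L, 1L]]
  strand <- colnames(hits)[winners[1L, 2L]]
  m <- Biostrings::matchPDict(dicts[[strand]], genome[[chrom]])
  nhits <- vapply(m, length, integer(1))
  seedIdx <- rep(seq_along(m), nhits)
  pos <- unlist(lapply(m, IRanges::start), use.names = FALSE)
  ends <- unlist(lapply(m, IRanges::end), use.names = FALSE)
  o <- order(pos)
  pos <- pos[o]; ends <- ends[o]; seedIdx <- seedIdx[o]
  cluster <- cumsum(c(1L, as.integer(diff(pos) > max_locus_gap)))
  distinct <- vapply(split(seedIdx, cluster), function(s) length(unique(s)),
                     integer(1))
  bestCl <- as.integer(names(distinct)[which.max(distinct)])
  sel <- cluster == bestCl
  list(chromosome = chrom, strand = strand,
       start = min(pos[sel]), end = max(ends[sel]), status = status)
}

#' Infer the exon/intron structure of one gene
#'
#' Locates the cDNA with \code{\link{locateGene}}, then chains maximal
#' exact matches between the cDNA and the locus (reverse-complemented
#' first for minus-strand loci). Genomic gaps of at least \code{min_intron}
#' between chained exons become introns; gaps on the cDNA side are not
#' allowed and the chain must cover the complete cDNA. Non-GT..AG introns
#' are accepted but counted in \code{noncanonical}.
#'
#' @param gene_id label carried into the result
#' @param cdna the transcript sequence
#' @param genome DNAStringSet of chromosomes
#' @param min_intron minimum intron length (nt)
#' @param pad extra genomic context around the located span
#' @return list ("ExonChain"): gene_id, chromosome, strand, exons (matrix of
#'   forward-strand start/end), exon_count, intron_lengths, noncanonical,
#'   status
#' @export
inferExons <- function(gene_id, cdna, genome, min_intron = 20L, pad = 50L) {
  loc <- locateGene(cdna, genome)
  if (loc$status == "unplaced")
    return(list(gene_id = gene_id, chromosome = NA_character_,
                strand = NA_character_, exons = NULL, exon_count = NA_integer_,
                intron_lengths = integer(0), noncanonical = NA_integer_,
                status = "unplaced"))
  chromLen <- Biostrings::width(genome)[match(loc$chromosome, names(genome))]
  from <- max(1L, loc$start - pad)
  to <- min(chromLen, loc$end + pad)
  region <- substring(as.character(genome[[loc$chromosome]]), from, to)
  work <- if (loc$strand == "+") region else revComp(region)
  ex <- tryCatch(.chainExons(as.character(cdna), work, min_intron),
                 error = function(e) e)
  if (inherits(ex, "error"))
    return(list(gene_id = gene_id, chromosome = loc$chromosome,
                strand = loc$strand, exons = NULL, exon_count = NA_integer_,
                intron_lengths = integer(0), noncanonical = NA_integer_,
                status = conditionMessage(ex)))
  rlen <- nchar(region)
  fwd <- if (loc$strand == "+")
    cbind(from - 1L + ex[, 1L], from - 1L + ex[, 2L])
  else cbind(from - 1L + (rlen - ex[, 2L] + 1L), from - 1L + (rlen - ex[, 1L] + 1L))
  fwd <- fwd[order(fwd[, 1L]), , drop = FALSE]
  introns <- if (nrow(fwd) > 1L) fwd[-1L, 1L] - fwd[-nrow(fwd), 2L] - 1L else integer(0)
  nc <- 0L
  if (nrow(fwd) > 1L) {
    chromSeq <- as.character(genome[[loc$chromosome]])
    for (k in seq_len(nrow(fwd) - 1L)) {
      i5 <- substring(chromSeq, fwd[k, 2L] + 1L, fwd[k, 2L] + 2L)
      i3 <- substring(chromSeq, fwd[k + 1L, 1L] - 2L, fwd[k + 1L, 1L] - 1L)
      canonical <- if (loc$strand == "+") i5 == "GT" && i3 == "AG"
                   else i3 == "AC" && i5 == "CT"
      if (!canonical) nc <- nc + 1L
    }
    if (nc > 0L)
      logMsg("debug", "%s: %d non-canonical intron boundaries", gene_id, nc)
  }
  list(gene_id = gene_id, chromosome = loc$chromosome, strand = loc$strand,
       exons = fwd, exon_count = nrow(fwd),
       intron_lengths = as.integer(introns), noncanonical = nc,
       status = "ok")
}

#' Infer gene structures for a transcript set
#'
#' @param cdnas named DNAStringSet of transcripts
#' @param genome DNAStringSet of chromosomes
#' @inheritParams inferExons
#' @return list with \code{chains} (list of ExonChain) and \code{summary}
#'   (data.frame: gene_id, chromosome, strand, exon_count, intron lengths as
#'   a comma string, status)
#' @export
geneStructures <- function(cdnas, genome, min_intron = 20L) {
  chains <- lapply(names(cdnas), function(g)
    inferExons(g, cdnas[[g]], genome, min_intron))
  names(chains) <- names(cdnas)
  summary <- do.call(rbind, lapply(chains, function(ch)
    data.frame(gene_id = ch$gene_id, chromosome = ch$chromosome,
               strand = ch$strand,
               start = if (is.null(ch$exons)) NA_integer_ else min(ch$exons[, 1L]),
               end = if (is.null(ch$exons)) NA_integer_ else max(ch$exons[, 2L]),
               exon_count = ch$exon_count,
               intron_lengths = paste(ch$intron_lengths, collapse = ","),
               noncanonical = ch$noncanonical, status = ch$status,
               row.names = NULL)))
  logMsg("info", "geneStructures: %d/%d genes resolved",
         sum(summary$status == "ok"), nrow(summary))
  list(chains = chains, summary = summary)
}

#' Per-chromosome gene counts and subfamily presence
#'
#' @param summary the summary data.frame from \code{\link{geneStructures}}
#' @param subfamilies optional named character vector gene_id -> subfamily
#' @return list with \code{counts} (named integer per chromosome, summing to
#'   the number of placed genes) and, when subfamilies are given,
#'   \code{presence} (chromosome x subfamily logical matrix)
#' @export
chromosomeDistribution <- function(summary, subfamilies = NULL) {
  placed <- summary[!is.na(summary$chromosome), ]
  counts <- table(placed$chromosome)
  out <- list(counts = setNames(as.integer(counts), names(counts)))
  if (!is.null(subfamilies)) {
    sf <- subfamilies[placed$gene_id]
    out$presence <- table(placed$chromosome, sf) > 0L
  }
  out
}

#' Export inferred structures as annotations
#'
#' @param chains ExonChain list from \code{\link{geneStructures}}
#' @return a GRanges suitable for \code{\link{writeAnnotations}}
#' @export
chainsToAnnotations <- function(chains) {
  ok <- Filter(function(ch) ch$status == "ok", chains)
  if (!length(ok)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(lapply(ok, function(ch)
    geneAnnotation(ch$gene_id, ch$chromosome, min(ch$exons[, 1L]),
                   max(ch$exons[, 2L]), ch$strand, ch$exons)))))
}
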