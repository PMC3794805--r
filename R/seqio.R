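#' Read a FASTA file with strict validation
#'
#' Reads protein or nucleotide FASTA into a Biostrings container. Sequence
#' ids are the first whitespace-delimited token of each header; the remainder
#' of the header is kept as a \code{description} metadata column. Sequences
#' are uppercased and internal whitespace is removed. The file must be
#' non-empty, ids must be unique, every sequence must be non-empty, and all
#' residues must belong to either the 20-letter protein alphabet or the
#' ACGTN nucleotide alphabet, consistently across the file.
#'
#' @param path path to a FASTA file (plain or gzipped)
#' @param alphabet "auto" detects the alphabet (nucleotide wins when every
#'   sequence is ACGTN-only); "protein" or "dna" force the container type
#' @return an \code{AAStringSet} or \code{DNAStringSet} named by id, with a
#'   \code{description} metadata column
#' @export
readFasta <- function(path, alphabet = c("auto", "protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  hdr <- names(raw)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(id))) stop("FASTA header with empty id in ", path)
  if (anyDuplicated(id))
    stop("duplicate id ", id[duplicated(id)][1L], " in ", path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id ", id[!nzchar(seqs)][1L])
  alph <- vapply(seqs, stringAlphabet, character(1), USE.NAMES = FALSE)
  if (anyNA(alph)) {
    bad <- id[is.na(alph)][1L]
    stop("sequence ", bad, " contains characters outside both alphabets")
  }
  type <- switch(alphabet,
    auto = if (all(alph == "dna")) "dna" else "protein",
    alphabet)
  if (type == "dna" && !all(alph == "dna"))
    stop("sequence ", id[alph != "dna"][1L], " is not a nucleotide sequence")
  out <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- id
  S4Vectors::mcols(out)$description <- desc
  logMsg("info", "readFasta: %d %s records from %s", length(out), type, path)
  out
}

#' Write sequences to FASTA
#'
#' Headers are \code{id description} when a \code{description} metadata
#' column is present and non-empty.
#'
#' @param x an XStringSet
#' @param path output path
#' @param width line-wrap width
#' @return \code{path}, invisibly
#' @export
writeFasta <- function(x, path, width = 70L) {
  y <- x
  d <- S4Vectors::mcols(x)$description
  if (!is.null(d) && any(nzchar(d)))
    names(y) <- ifelse(nzchar(d), paste(names(x), d), names(x))
  Biostrings::writeXStringSet(y, path, width = width)
  invisible(path)
}

#' Read single-end reads from 4-line FASTQ
#'
#' Quality lines are validated (same length as the sequence) and discarded:
#' downstream expression counting uses only the read sequence. Gzipped input
#' is handled transparently. An empty file yields an empty set; a truncated
#' or malformed record is an error naming the record index.
#'
#' @param path FASTQ path (optionally .gz)
#' @return a \code{DNAStringSet} named by read id
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n == 0L) return(Biostrings::DNAStringSet())
  if (n %% 4L != 0L)
    stop("truncated FASTQ record ", n %/% 4L + 1L, " in ", path)
  at <- lines[seq(1L, n, 4L)]
  sq <- toupper(lines[seq(2L, n, 4L)])
  pl <- lines[seq(3L, n, 4L)]
  qu <- lines[seq(4L, n, 4L)]
  bad <- which(!startsWith(at, "@"))
  if (length(bad)) stop("FASTQ record ", bad[1L], ": header does not start with '@'")
  bad <- which(!startsWith(pl, "+"))
  if (length(bad)) stop("FASTQ record ", bad[1L], ": separator line missing '+'")
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad))
    stop("FASTQ record ", bad[1L], ": sequence and quality lengths differ")
  bad <- which(grepl("[^ACGTN]", sq))
  if (length(bad))
    stop("FASTQ record ", bad[1L], ": non-ACGTN character in read")
  ids <- sub("\\s.*$", "", substring(at, 2L))
  out <- Biostrings::DNAStringSet(sq)
  names(out) <- ids
  logMsg("info", "readFastq: %d reads from %s", length(out), path)
  out
}

#' Write reads as 4-line FASTQ
#'
#' All qualities are written as the constant "I" (the generator's reads are
#' error-free, so qualities are placeholders). A \code{.gz} suffix triggers
#' gzip compression.
#'
#' @param x DNAStringSet of reads
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeFastq <- function(x, path) {
  sq <- as.character(x)
  qual <- vapply(nchar(sq), function(n) strrep("I", n), character(1))
  rec <- paste0("@", names(x), "\n", sq, "\n+\n", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

# ---- gene annotations -------------------------------------------------------

#' Construct a gene annotation
#'
#' One gene with its exon chain as a \code{GRanges}: a "gene" row spanning
#' the locus plus one "exon" row per exon, all in 1-based inclusive forward
#' coordinates (internally the package converts to 0-based half-open only
#' inside arithmetic helpers). Exons must be sorted, non-overlapping, and
#' contained in the gene span.
#'
#' @param gene_id gene identifier (no whitespace)
#' @param chromosome chromosome name
#' @param start,end 1-based inclusive gene span
#' @param strand "+" or "-"
#' @param exons two-column matrix (start, end) of exon intervals on the
#'   forward strand
#' @return a \code{GRanges} with \code{type}, \code{ID} and \code{Parent}
#'   metadata columns
#' @export
geneAnnotation <- function(gene_id, chromosome, start, end, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2L)
  stopifnot(length(gene_id) == 1L, !grepl("\\s", gene_id),
            start <= end, strand %in% c("+", "-"), nrow(exons) >= 1L)
  if (any(exons[, 1L] > exons[, 2L])) stop(gene_id, ": exon start > end")
  o <- order(exons[, 1L])
  if (!identical(o, seq_len(nrow(exons)))) stop(gene_id, ": exons not sorted")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop(gene_id, ": overlapping exons")
  if (exons[1L, 1L] < start || exons[nrow(exons), 2L] > end)
    stop(gene_id, ": exon outside gene span")
  gr <- GenomicRanges::GRanges(
    seqnames = chromosome,
    ranges = IRanges::IRanges(start = c(start, exons[, 1L]),
                              end = c(end, exons[, 2L])),
    strand = strand)
  n <- nrow(exons)
  S4Vectors::mcols(gr)$type <- c("gene", rep("exon", n))
  S4Vectors::mcols(gr)$ID <- c(gene_id, sprintf("%s.exon%02d", gene_id, seq_len(n)))
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    c(list(character(0)), rep(list(gene_id), n)))
  gr
}

#' Write gene annotations to GFF3
#'
#' @param annos a \code{GRanges} built from \code{\link{geneAnnotation}}
#'   (several may be concatenated with \code{c()}); an empty GRanges yields a
#'   header-only file
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeAnnotations <- function(annos, path) {
  if (length(annos) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rtracklayer::export(annos, path, format = "gff3")
  invisible(path)
}

#' Read gene annotations written by \code{writeAnnotations}
#'
#' @param path GFF3 path
#' @return a \code{GRanges} in the same layout as \code{\link{geneAnnotation}}
#' @export
readAnnotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(GenomicRanges::GRanges())
  keep <- c("type", "ID", "Parent")
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep]
  S4Vectors::mcols(gr)$type <- as.character(S4Vectors::mcols(gr)$type)
  gr
}

# Canonical per-gene view used by tests and the structure stage.
#' Tabulate annotations per gene
#'
#' @param annos GRanges of gene/exon rows
#' @return a data.frame with one row per gene: gene_id, chromosome, start,
#'   end, strand, exon_count, and list-columns exon_starts/exon_ends
#' @export
annotationTable <- function(annos) {
  m <- S4Vectors::mcols(annos)
  genes <- which(m$type == "gene")
  out <- lapply(genes, function(i) {
    gid <- m$ID[i]
    ex <- which(m$type == "exon" & vapply(m$Parent, function(p)
      length(p) == 1L && p == gid, logical(1)))
    ex <- ex[order(GenomicRanges::start(annos)[ex])]
    data.frame(gene_id = gid,
               chromosome = as.character(GenomicRanges::seqnames(annos)[i]),
               start = GenomicRanges::start(annos)[i],
               end = GenomicRanges::end(annos)[i],
               strand = as.character(GenomicRanges::strand(annos)[i]),
               exon_count = length(ex))
  })
  df <- do.call(rbind, out)
  df$exon_starts <- lapply(genes, function(i) {
    gid <- m$ID[i]
    ex <- which(m$type == "exon" & vapply(m$Parent, function(p)
      length(p) == 1L && p == gid, logical(1)))
    sort(GenomicRanges::start(annos)[ex])
  })
  df$exon_ends <- lapply(genes, function(i) {
    gid <- m$ID[i]
    ex <- which(m$type == "exon" & vapply(m$Parent, function(p)
      length(p) == 1L && p == gid, logical(1)))
    sort(GenomicRanges::end(annos)[ex])
  })
  df
}
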