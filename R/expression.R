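#' Build an exact-substring transcript index
#'
#' Supports querying which transcripts contain a read (or its reverse
#' complement) as an exact substring. Exact matching of >= 20-nt signatures
#' operationalizes unique read assignment; no mismatches are tolerated and
#' both orientations are searched because library strandedness is not
#' assumed.
#'
#' @param transcripts named DNAStringSet
#' @param min_length minimum read length accepted at query time (nt)
#' @return an index object for \code{\link{countUniqueReads}}
#' @export
buildReadIndex <- function(transcripts, min_length = 20L) {
  if (length(transcripts) == 0L) stop("no transcripts")
  structure(list(fwd = transcripts,
                 rc = Biostrings::reverseComplement(transcripts),
                 ids = names(transcripts),
                 min_length = as.integer(min_length)),
            class = "kinfam_read_index")
}

# For a character vector of distinct read sequences (all the same width),
# return an integer vector: number of transcripts containing each read in
# either orientation, plus the single transcript index when unique.
.matchWidthGroup <- function(seqs, index) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
  hitF <- Biostrings::vcountPDict(pd, index$fwd) > 0L
  hitR <- Biostrings::vcountPDict(pd, index$rc) > 0L
  hit <- hitF | hitR   # reads x transcripts
  nhit <- rowSums(hit)
  only <- rep(NA_integer_, length(seqs))
  u <- which(nhit == 1L)
  if (length(u)) only[u] <- apply(hit[u, , drop = FALSE], 1L, which.max)
  list(nhit = nhit, only = only)
}

#' Count uniquely aligned reads per transcript
#'
#' A read contributes one count to a transcript only when it matches that
#' transcript and no other (reads matching several transcripts are dropped
#' entirely, the strict reading of "uniquely aligned"). N is the total of
#' unique counts in the sample. Reads shorter than the index's
#' \code{min_length} are rejected and counted in \code{rejected}.
#'
#' @param reads DNAStringSet of reads (e.g. from \code{\link{readFastq}})
#' @param index from \code{\link{buildReadIndex}}
#' @return list: \code{C} (named integer per transcript), \code{N} (sum of
#'   C), \code{rejected} (reads below the length minimum),
#'   \code{multi} (reads matching more than one transcript)
#' @export
countUniqueReads <- function(reads, index) {
  stopifnot(inherits(index, "kinfam_read_index"))
  C <- setNames(integer(length(index$ids)), index$ids)
  w <- Biostrings::width(reads)
  short <- sum(w < index$min_length)
  if (short > 0L)
    logMsg("info", "countUniqueReads: rejected %d reads shorter than %d nt",
           short, index$min_length)
  keep <- as.character(reads[w >= index$min_length])
  multi <- 0L
  if (length(keep)) {
    tab <- table(keep)
    uniqSeqs <- names(tab)
    mult <- as.integer(tab)
    for (wd in unique(nchar(uniqSeqs))) {
      sel <- which(nchar(uniqSeqs) == wd)
      m <- .matchWidthGroup(uniqSeqs[sel], index)
      uni <- which(m$nhit == 1L)
      if (length(uni)) {
        add <- tapply(mult[sel][uni], m$only[uni], sum)
        ti <- as.integer(names(add))
        C[ti] <- C[ti] + as.integer(add)
      }
      multi <- multi + sum(mult[sel][m$nhit > 1L])
    }
  }
  N <- sum(C)
  logMsg("info", "countUniqueReads: N=%d unique, %d multi-mapping dropped",
         N, multi)
  list(C = C, N = N, rejected = short, multi = multi)
}

#' RPKM from unique counts
#'
#' RPKM = 1e6 * C / (N * L / 1e3), where C is the transcript's unique read
#' count, N the sample's total unique count and L the transcript length in
#' bases. Zero when the sample has no uniquely aligned reads.
#'
#' @param C unique read count(s)
#' @param N sample total unique count
#' @param L transcript length(s) in bases (> 0)
#' @return numeric RPKM value(s)
#' @export
rpkm <- function(C, N, L) {
  if (any(L <= 0)) stop("transcript length must be positive")
  stopifnot(all(C >= 0), length(N) == 1L, N >= 0)
  if (N == 0) return(C * 0)
  1e6 * C / (N * L / 1e3)
}

#' Quantify expression across tissue samples
#'
#' Counts uniquely aligned reads and computes RPKM per transcript for each
#' tissue's read set.
#'
#' @param transcripts named DNAStringSet
#' @param read_files named character vector tissue -> FASTQ path
#' @param min_length minimum read length (nt)
#' @return data.frame in long form: transcript_id, tissue, C, N, L, rpkm
#' @export
quantifyExpression <- function(transcripts, read_files, min_length = 20L) {
  index <- buildReadIndex(transcripts, min_length)
  L <- setNames(Biostrings::width(transcripts), names(transcripts))
  out <- lapply(names(read_files), function(t) {
    reads <- readFastq(read_files[[t]])
    cnt <- countUniqueReads(reads, index)
    data.frame(transcript_id = names(cnt$C), tissue = t,
               C = as.integer(cnt$C), N = cnt$N, L = as.integer(L[names(cnt$C)]),
               rpkm = rpkm(cnt$C, cnt$N, L[names(cnt$C)]), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Call expressed genes and ovule-stage preference
#'
#' A gene is expressed when it has at least \code{min_reads} uniquely
#' aligned reads in any tissue. The 0-DPA/3-DPA preference label compares
#' RPKM between the two ovule samples with strict inequality; equal values
#' give "equal".
#'
#' @param records long-form table from \code{\link{quantifyExpression}};
#'   all three tissues (leaf, ovule0, ovule3) must be present per gene
#' @param min_reads unique-read threshold for the expressed flag
#' @return data.frame: gene_id, expressed, preference
#' @export
callExpression <- function(records, min_reads = 1L) {
  need <- c("leaf", "ovule0", "ovule3")
  out <- lapply(split(records, records$transcript_id), function(r) {
    if (!all(need %in% r$tissue))
      stop(r$transcript_id[1L], ": missing tissue sample(s) ",
           paste(setdiff(need, r$tissue), collapse = ","))
    r0 <- r$rpkm[r$tissue == "ovule0"]; r3 <- r$rpkm[r$tissue == "ovule3"]
    data.frame(gene_id = r$transcript_id[1L],
               expressed = max(r$C) >= min_reads,
               preference = if (r0 > r3) "higher_0DPA"
                            else if (r3 > r0) "higher_3DPA" else "equal",
               row.names = NULL)
  })
  res <- do.call(rbind, unname(out))
  logMsg("info", "callExpression: %d/%d genes expressed",
         sum(res$expressed), nrow(res))
  res
}
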