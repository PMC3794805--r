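#' @rdname generateProteome
#' @export
setClass("FamilyTruth",
  representation(genes = "data.frame", expression = "matrix",
                 decoys = "character", config = "list"))

setMethod("show", "FamilyTruth", function(object) {
  cat("FamilyTruth:", nrow(object@genes), "planted family genes (",
      paste(names(table(object@genes$subfamily)),
            table(object@genes$subfamily), collapse = ", "),
      "),", length(object@decoys), "decoys\n")
})

#' @rdname generateProteome
#' @export
familyGenes <- function(truth) truth@genes

#' @rdname generateProteome
#' @export
trueExpression <- function(truth) truth@expression

#' @rdname generateProteome
#' @export
decoyIds <- function(truth) truth@decoys

# Kinase-domain scaffold layout shared by generator and documentation:
# a 130-residue block carrying the three hallmark realizations and the
# subfamily signature, embedded at a subfamily-dependent position.
.BLOCK <- list(len = 130L, atp = 7L, hrd = 59L, dfg = 89L, sig = 107L,
               sigWidth = 11L)

#' Generator configuration
#'
#' Assembles and validates the configuration for the synthetic cotton-like
#' dataset. Defaults follow the packaged paper profile: 12 ZIK + 22 MEKK +
#' 44 Raf family genes, 200 decoys, 18 unexpressed genes, 50-nt reads. When
#' no explicit \code{genes} table is supplied one is drawn deterministically
#' from the seed; \code{\link{paperProfileConfig}} loads the packaged
#' profile whose explicit table pins the published composition (exon counts
#' spanning 1..23, 11 genes on chromosome 6 and 3 on chromosome 10, 12
#' duplication pairs of which 2 tandem, and the 11/8 ovule contrast split).
#'
#' @param seed integer seed; every generator stage derives its RNG stream
#'   from it
#' @param n_zik,n_mekk,n_raf subfamily sizes
#' @param n_decoys number of decoy proteins; \code{near_miss_fraction} of
#'   them are "near-miss" kinases that pass the identity screen but lack a
#'   hallmark
#' @param n_unexpressed family genes with zero expression in all tissues
#' @param read_length read length in nt (must be >= 20, the minimum
#'   signature length used by the expression stage)
#' @param reads_per_sample reads simulated per tissue sample
#' @param exon_count_range,intron_length_range,min_intron,min_exon gene
#'   structure controls (nt)
#' @param duplication_pairs,n_tandem planted paralog pairs and how many of
#'   them are tandem
#' @param mutation_rate per-residue divergence of each family member from
#'   its subfamily ancestor (planted motifs are never mutated)
#' @param partner_divergence per-residue divergence between duplication
#'   partners (< 0.2 so pairs stay above the 80\% identity criterion)
#' @param ancestor_length named protein lengths per subfamily
#' @param chromosome_count,chromosome_length genome dimensions
#' @param linkage_window,tandem_gap tandem-linkage distance (bp) and the
#'   genomic gap range used when placing tandem partners
#' @param rpkm_meanlog,rpkm_sdlog,contrast_fold expression truth: log-normal
#'   RPKM parameters and the fold difference imposed on contrast genes
#' @param genes optional explicit gene table (data.frame with gene_id,
#'   subfamily, exon_count, chromosome, partner, tandem, expressed, contrast)
#' @param raf_higher_0dpa,raf_higher_3dpa sizes of the Raf ovule contrast
#'   classes when the gene table is auto-built
#' @return a validated config list of class "kinfam_config"
#' @export
generatorConfig <- function(seed = 1L, n_zik = 12L, n_mekk = 22L, n_raf = 44L,
                            n_decoys = 200L, near_miss_fraction = 0.1,
                            n_unexpressed = 18L,
                            read_length = 50L, reads_per_sample = 50000L,
                            exon_count_range = c(1L, 23L),
                            intron_length_range = c(60L, 300L),
                            min_intron = 20L, min_exon = 40L,
                            duplication_pairs = 12L, n_tandem = 2L,
                            mutation_rate = 0.25, partner_divergence = 0.04,
                            ancestor_length = c(ZIK = 380L, MEKK = 460L, Raf = 550L),
                            chromosome_count = 13L, chromosome_length = 350000L,
                            linkage_window = 250000L, tandem_gap = c(2000L, 6000L),
                            rpkm_meanlog = 3, rpkm_sdlog = 1, contrast_fold = 3,
                            genes = NULL,
                            raf_higher_0dpa = 11L, raf_higher_3dpa = 8L) {
  cfg <- list(seed = as.integer(seed), n_zik = as.integer(n_zik),
              n_mekk = as.integer(n_mekk), n_raf = as.integer(n_raf),
              n_decoys = as.integer(n_decoys),
              near_miss_fraction = near_miss_fraction,
              n_unexpressed = as.integer(n_unexpressed),
              read_length = as.integer(read_length),
              reads_per_sample = as.integer(reads_per_sample),
              exon_count_range = as.integer(exon_count_range),
              intron_length_range = as.integer(intron_length_range),
              min_intron = as.integer(min_intron), min_exon = as.integer(min_exon),
              duplication_pairs = as.integer(duplication_pairs),
              n_tandem = as.integer(n_tandem),
              mutation_rate = mutation_rate,
              partner_divergence = partner_divergence,
              ancestor_length = vapply(ancestor_length, as.integer, integer(1)),
              chromosome_count = as.integer(chromosome_count),
              chromosome_length = as.integer(chromosome_length),
              linkage_window = as.integer(linkage_window),
              tandem_gap = as.integer(tandem_gap),
              rpkm_meanlog = rpkm_meanlog, rpkm_sdlog = rpkm_sdlog,
              contrast_fold = contrast_fold,
              raf_higher_0dpa = as.integer(raf_higher_0dpa),
              raf_higher_3dpa = as.integer(raf_higher_3dpa))
  with(cfg, {
    stopifnot(n_zik >= 0, n_mekk >= 0, n_raf >= 0, n_decoys >= 0,
              n_unexpressed >= 0, reads_per_sample >= 0,
              mutation_rate >= 0, mutation_rate < 1,
              partner_divergence >= 0, partner_divergence < 0.2,
              chromosome_count >= 1, min_intron >= 4)
    if (read_length < 20L)
      stop("read_length must be >= 20 (minimum exact-match signature length)")
  })
  if (!setequal(names(cfg$ancestor_length), c("ZIK", "MEKK", "Raf")))
    stop("ancestor_length must name ZIK, MEKK and Raf")
  if (any(cfg$ancestor_length < .BLOCK$len + 20L))
    stop("ancestor proteins too short to host the kinase scaffold block")
  cfg$genes <- if (is.null(genes)) .buildGeneTable(cfg) else .checkGeneTable(cfg, genes)
  class(cfg) <- "kinfam_config"
  cfg
}

#' Load the packaged paper-profile generator configuration
#'
#' @param seed optional seed overriding the profile's default
#' @param path profile YAML (defaults to the packaged file)
#' @return a config list, as from \code{\link{generatorConfig}}
#' @export
paperProfileConfig <- function(seed = NULL, path = extdata("paper_profile.yaml")) {
  y <- yaml::read_yaml(path)
  genes <- do.call(rbind, lapply(y$genes, function(g)
    data.frame(gene_id = g$id, subfamily = g$subfamily,
               exon_count = as.integer(g$exons),
               chromosome = as.integer(g$chromosome),
               partner = g$partner %||% NA_character_,
               tandem = isTRUE(g$tandem),
               expressed = isTRUE(g$expressed),
               contrast = g$contrast %||% "none")))
  generatorConfig(seed = seed %||% y$seed,
                  n_zik = y$n_zik, n_mekk = y$n_mekk, n_raf = y$n_raf,
                  n_decoys = y$n_decoys, near_miss_fraction = y$near_miss_fraction,
                  n_unexpressed = y$n_unexpressed,
                  read_length = y$read_length,
                  reads_per_sample = y$reads_per_sample,
                  exon_count_range = unlist(y$exon_count_range),
                  intron_length_range = unlist(y$intron_length_range),
                  min_intron = y$min_intron, min_exon = y$min_exon,
                  duplication_pairs = y$duplication_pairs, n_tandem = y$n_tandem,
                  mutation_rate = y$mutation_rate,
                  partner_divergence = y$partner_divergence,
                  ancestor_length = unlist(y$ancestor_length),
                  chromosome_count = y$chromosome_count,
                  chromosome_length = y$chromosome_length,
                  linkage_window = y$linkage_window,
                  tandem_gap = unlist(y$tandem_gap),
                  rpkm_meanlog = y$rpkm_meanlog, rpkm_sdlog = y$rpkm_sdlog,
                  contrast_fold = y$contrast_fold,
                  genes = genes)
}

.checkGeneTable <- function(cfg, genes) {
  need <- c("gene_id", "subfamily", "exon_count", "chromosome", "partner",
            "tandem", "expressed", "contrast")
  stopifnot(all(need %in% names(genes)))
  counts <- table(factor(genes$subfamily, levels = c("ZIK", "MEKK", "Raf")))
  stopifnot(counts[["ZIK"]] == cfg$n_zik, counts[["MEKK"]] == cfg$n_mekk,
            counts[["Raf"]] == cfg$n_raf,
            sum(!genes$expressed) == cfg$n_unexpressed,
            all(genes$chromosome >= 1 & genes$chromosome <= cfg$chromosome_count))
  # duplication partners must be symmetric
  has <- !is.na(genes$partner)
  p <- setNames(genes$partner, genes$gene_id)
  stopifnot(all(p[p[has]] == genes$gene_id[has]),
            sum(has) == 2L * cfg$duplication_pairs)
  cds <- 3L * cfg$ancestor_length[genes$subfamily]
  if (any(genes$exon_count * cfg$min_exon > cds))
    stop("exon counts impossible at the configured protein lengths")
  genes
}

# Deterministic auto-built gene table for non-paper profiles.
.buildGeneTable <- function(cfg) {
  withSeed(subSeed(cfg$seed, "profile"), {
    n <- cfg$n_zik + cfg$n_mekk + cfg$n_raf
    ids <- sprintf("kin%03d", seq_len(n))
    sub <- c(rep("ZIK", cfg$n_zik), rep("MEKK", cfg$n_mekk), rep("Raf", cfg$n_raf))
    cdsLen <- 3L * cfg$ancestor_length[sub]
    maxEx <- pmin(cfg$exon_count_range[2L], cdsLen %/% cfg$min_exon)
    exon_count <- vapply(maxEx, function(m)
      sample(seq(cfg$exon_count_range[1L], m), 1L), integer(1))
    chrom <- sample(cfg$chromosome_count, n, replace = TRUE)
    partner <- rep(NA_character_, n); tandem <- rep(FALSE, n)
    if (cfg$duplication_pairs > 0L) {
      if (2L * cfg$duplication_pairs > n)
        stop("not enough family genes for the requested duplication pairs")
      # pair within subfamilies where possible
      pool <- sample(n)
      pool <- pool[order(sub[pool])]
      k <- 0L
      for (i in seq(1L, length(pool) - 1L)) {
        a <- pool[i]; b <- pool[i + 1L]
        if (k >= cfg$duplication_pairs) break
        if (!is.na(partner[a]) || !is.na(partner[b]) || sub[a] != sub[b]) next
        k <- k + 1L
        partner[a] <- ids[b]; partner[b] <- ids[a]
        if (k <= cfg$n_tandem) {
          tandem[c(a, b)] <- TRUE
          chrom[b] <- chrom[a]
        } else if (cfg$chromosome_count > 1L && chrom[a] == chrom[b]) {
          chrom[b] <- sample(setdiff(seq_len(cfg$chromosome_count), chrom[a]), 1L)
        }
        exon_count[b] <- exon_count[a]
      }
      if (k < cfg$duplication_pairs)
        stop("could not place all duplication pairs within subfamilies")
    }
    expressed <- rep(TRUE, n)
    if (cfg$n_unexpressed > 0L)
      expressed[sample(n, cfg$n_unexpressed)] <- FALSE
    contrast <- rep("none", n)
    rafExpr <- which(sub == "Raf" & expressed)
    want <- cfg$raf_higher_0dpa + cfg$raf_higher_3dpa
    if (want > 0L && length(rafExpr) >= want) {
      pick <- sample(rafExpr, want)
      contrast[pick[seq_len(cfg$raf_higher_0dpa)]] <- "higher0"
      contrast[pick[-seq_len(cfg$raf_higher_0dpa)]] <- "higher3"
    }
    data.frame(gene_id = ids, subfamily = sub, exon_count = exon_count,
               chromosome = chrom, partner = partner, tandem = tandem,
               expressed = expressed, contrast = contrast, row.names = NULL)
  })
}

# ---- proteome ---------------------------------------------------------------

# Mutate positions outside `mask` at the given per-residue rate; a mutated
# position receives a uniformly drawn different residue.
.mutateProtein <- function(res, rate, mask) {
  free <- setdiff(seq_along(res), mask)
  hit <- free[runif(length(free)) < rate]
  if (length(hit)) {
    res[hit] <- vapply(res[hit], function(r)
      sample(setdiff(AA20, r), 1L), character(1))
  }
  res
}

.sigPattern <- function(sigs, sf) sigs[[sf]]

# Sample a subfamily signature realization respecting motif precedence
# (ZIK > MEKK > Raf): the realization must not satisfy a higher-precedence
# pattern, so planted labels are recovered exactly by the classifier.
.sampleSignature <- function(sf, sigs) {
  if (sf == "ZIK") return("GTPEFMAPELY")
  for (i in 1:200) {
    r <- prositeRealize(sigs[[sf]])
    ok <- if (sf == "MEKK") !grepl(sigs$ZIK@regex, r, perl = TRUE)
          else !grepl(sigs$ZIK@regex, r, perl = TRUE) &&
               !grepl(sigs$MEKK@regex, r, perl = TRUE)
    if (ok) return(r)
  }
  stop("could not realize a precedence-safe ", sf, " signature")
}

# Assemble a protein from flank background + scaffold block at position p
# (1-based start within the protein). Returns residues and the motif mask.
.assembleProtein <- function(flank, block, p) {
  L <- length(flank) + length(block)
  res <- c(flank[seq_len(p - 1L)], block,
           if (p <= length(flank)) flank[p:length(flank)] else character(0))
  stopifnot(length(res) == L)
  motifs <- c(.BLOCK$atp:(.BLOCK$atp + 8L), .BLOCK$hrd:(.BLOCK$hrd + 9L),
              .BLOCK$dfg:(.BLOCK$dfg + 5L), .BLOCK$sig:(.BLOCK$sig + .BLOCK$sigWidth - 1L))
  list(res = res, mask = p - 1L + motifs)
}

# Allowed scaffold-block start window per subfamily: the kinase-domain
# midpoint (block offset ~36) must land in the first third for ZIK, the
# last third for Raf, anywhere for MEKK.
.blockWindow <- function(sf, L) {
  b <- .BLOCK$len
  mid <- 36L
  switch(sf,
    ZIK = c(5L, max(5L, L %/% 3L - mid - 10L)),
    Raf = c(min(L - b, 2L * L %/% 3L - mid + 10L), L - b),
    MEKK = c(1L, L - b + 1L))
}

.blockPosition <- function(sf, L) {
  w <- .blockWindow(sf, L)
  sample(w[1L]:w[2L], 1L)
}

#' Generate the synthetic proteome and its truth table
#'
#' Builds a proteome of planted kinase-family proteins plus decoys. Each
#' family protein carries a 130-residue kinase scaffold containing
#' realizations of the three configured hallmark patterns and exactly one
#' subfamily signature (ZIK members the literal GTPEFMAPELY; MEKK and Raf
#' members a per-gene realization of their consensus that never satisfies a
#' higher-precedence pattern). The scaffold sits N-terminally in ZIK
#' proteins, C-terminally in Raf proteins and uniformly in MEKK proteins.
#' Members diverge from per-subfamily ancestors by point mutation at
#' \code{mutation_rate}, never touching planted motifs; duplication partners
#' are near-copies of their mate at \code{partner_divergence}. Decoys are
#' random non-kinase proteins or "near-miss" kinases that resemble an
#' ancestor (so they pass the identity screen) but lack a hallmark.
#'
#' The returned truth table also fixes the expression truth (log-normal
#' RPKM for expressed genes, zero everywhere for unexpressed genes, and the
#' configured 0-DPA/3-DPA fold contrasts for Raf contrast genes) and the
#' per-gene exon length layout used later by \code{\link{generateGenome}}.
#'
#' @param config a \code{\link{generatorConfig}} list
#' @return list with \code{proteome} (AAStringSet, shuffled family + decoys),
#'   \code{queries} (AAStringSet of subfamily ancestors) and \code{truth}
#'   (a \code{FamilyTruth})
#' @export
generateProteome <- function(config) {
  stopifnot(inherits(config, "kinfam_config"))
  sigs <- subfamilySignatures()
  marks <- hallmarkPatterns()
  genes <- config$genes
  withSeed(subSeed(config$seed, "proteome"), {
    # per-subfamily ancestors: flank background + scaffold block
    anc <- list()
    for (sf in c("ZIK", "MEKK", "Raf")) {
      L <- config$ancestor_length[[sf]]
      flank <- sample(AA20, L - .BLOCK$len, replace = TRUE)
      block <- sample(AA20, .BLOCK$len, replace = TRUE)
      block[.BLOCK$atp:(.BLOCK$atp + 8L)] <- seqChars(prositeRealize(marks$atp_binding))
      block[.BLOCK$hrd:(.BLOCK$hrd + 9L)] <- seqChars(prositeRealize(marks$st_active_site))
      block[.BLOCK$dfg:(.BLOCK$dfg + 5L)] <- seqChars(prositeRealize(marks$kinase_domain))
      sig <- .sampleSignature(sf, sigs)
      block[.BLOCK$sig:(.BLOCK$sig + nchar(sig) - 1L)] <- seqChars(sig)
      anc[[sf]] <- list(flank = flank, block = block, L = L)
    }
    # query set: ancestor variants spanning each subfamily's block window,
    # the way a real query collection spans domain arrangements
    qseqs <- character(0)
    for (sf in names(anc)) {
      a <- anc[[sf]]
      w <- .blockWindow(sf, a$L)
      pos <- unique(as.integer(round(seq(w[1L], w[2L], length.out = 3L))))
      for (k in seq_along(pos)) {
        asm <- .assembleProtein(a$flank, a$block, pos[k])
        qseqs[sprintf("ancestor_%s_%d", sf, k)] <- paste(asm$res, collapse = "")
      }
    }
    queries <- Biostrings::AAStringSet(qseqs)

    seqs <- setNames(character(nrow(genes)), genes$gene_id)
    blockPos <- setNames(integer(nrow(genes)), genes$gene_id)
    masks <- vector("list", nrow(genes)); names(masks) <- genes$gene_id
    order <- seq_len(nrow(genes))
    # generate pair leaders before their partners
    done <- character(0)
    for (i in order) {
      gid <- genes$gene_id[i]
      if (gid %in% done) next
      sf <- genes$subfamily[i]
      a <- anc[[sf]]
      for (try in 1:50) {
        p <- .blockPosition(sf, a$L)
        sig <- .sampleSignature(sf, sigs)
        block <- a$block
        block[.BLOCK$sig:(.BLOCK$sig + .BLOCK$sigWidth - 1L)] <-
          c(seqChars(sig), sample(AA20, .BLOCK$sigWidth - nchar(sig), replace = TRUE))
        asm <- .assembleProtein(a$flank, block, p)
        res <- .mutateProtein(asm$res, config$mutation_rate, asm$mask)
        if (.plantedOk(res, sf, sigs, marks)) break
        if (try == 50L) stop("could not plant ", gid)
      }
      seqs[gid] <- paste(res, collapse = "")
      blockPos[gid] <- p; masks[[gid]] <- asm$mask
      done <- c(done, gid)
      mate <- genes$partner[i]
      if (!is.na(mate) && !(mate %in% done)) {
        for (try in 1:50) {
          res2 <- .mutateProtein(res, config$partner_divergence, asm$mask)
          if (.plantedOk(res2, sf, sigs, marks)) break
          if (try == 50L) stop("could not plant partner ", mate)
        }
        seqs[mate] <- paste(res2, collapse = "")
        blockPos[mate] <- p; masks[[mate]] <- asm$mask
        done <- c(done, mate)
      }
    }

    # decoys: near-miss kinases first, then random proteins
    nNear <- round(config$n_decoys * config$near_miss_fraction)
    decoys <- character(config$n_decoys)
    if (config$n_decoys > 0L) names(decoys) <- sprintf("dec%03d", seq_len(config$n_decoys))
    sfCycle <- rep(c("ZIK", "MEKK", "Raf"), length.out = max(nNear, 1L))
    for (d in seq_len(config$n_decoys)) {
      if (d <= nNear) {
        a <- anc[[sfCycle[d]]]
        for (try in 1:100) {
          p <- sample(1L:(a$L - .BLOCK$len + 1L), 1L)
          asm <- .assembleProtein(a$flank, a$block, p)
          res <- .mutateProtein(asm$res, config$mutation_rate, asm$mask)
          # break one hallmark (the active-site loop) and the signature
          res[p - 1L + (.BLOCK$hrd:(.BLOCK$hrd + 9L))] <-
            sample(setdiff(AA20, c("H", "D")), 10L, replace = TRUE)
          res[p - 1L + (.BLOCK$sig:(.BLOCK$sig + .BLOCK$sigWidth - 1L))] <-
            sample(setdiff(AA20, c("M", "A", "P")), .BLOCK$sigWidth, replace = TRUE)
          s <- paste(res, collapse = "")
          if (!prositeHits(marks$st_active_site, s) &&
              !all(vapply(marks, prositeHits, logical(1), seqs = s))) break
          if (try == 100L) stop("could not build near-miss decoy")
        }
        decoys[d] <- s
      } else {
        for (try in 1:100) {
          s <- randProtein(sample(250:600, 1L))
          if (!all(vapply(marks, prositeHits, logical(1), seqs = s))) break
        }
        decoys[d] <- s
      }
    }

    # expression truth
    tissues <- c("leaf", "ovule0", "ovule3")
    expr <- matrix(0, nrow(genes), 3L,
                   dimnames = list(genes$gene_id, tissues))
    for (i in seq_len(nrow(genes))) {
      if (!genes$expressed[i]) next
      base <- rlnorm(3L, config$rpkm_meanlog, config$rpkm_sdlog)
      if (genes$contrast[i] == "higher0") base[2L] <- base[3L] * config$contrast_fold
      if (genes$contrast[i] == "higher3") base[3L] <- base[2L] * config$contrast_fold
      expr[i, ] <- base
    }

    # exon length layout: partition the CDS into exon_count pieces >= min_exon
    cdsLen <- 3L * config$ancestor_length[genes$subfamily]
    exonLens <- vector("list", nrow(genes)); names(exonLens) <- genes$gene_id
    for (i in seq_len(nrow(genes))) {
      gid <- genes$gene_id[i]; mate <- genes$partner[i]
      if (!is.na(mate) && !is.null(exonLens[[mate]])) {
        exonLens[[gid]] <- exonLens[[mate]]; next
      }
      k <- genes$exon_count[i]
      extra <- cdsLen[i] - k * config$min_exon
      if (extra < 0L) stop(gid, ": exon layout impossible at this CDS length")
      add <- if (k == 1L) extra else as.integer(stats::rmultinom(1L, extra, rep(1, k)))
      exonLens[[gid]] <- config$min_exon + add
    }

    gtab <- genes
    gtab$protein_length <- nchar(seqs[gtab$gene_id])
    gtab$cds_length <- as.integer(cdsLen)
    gtab$block_pos <- blockPos[gtab$gene_id]
    gtab$exon_lengths <- I(exonLens[gtab$gene_id])
    truth <- new("FamilyTruth", genes = gtab, expression = expr,
                 decoys = names(decoys) %||% character(0), config = unclass(config))

    all <- c(seqs, decoys)
    all <- all[sample(length(all))]
    proteome <- Biostrings::AAStringSet(all)
    S4Vectors::mcols(proteome)$description <- rep("", length(proteome))
    logMsg("info", "generateProteome: %d family + %d decoy proteins",
           length(seqs), length(decoys))
    list(proteome = proteome, queries = queries, truth = truth)
  })
}

# Post-generation assertion that a planted protein keeps all hallmarks and
# classifies to its planted subfamily under motif precedence.
.plantedOk <- function(res, sf, sigs, marks) {
  s <- paste(res, collapse = "")
  if (!all(vapply(marks, prositeHits, logical(1), seqs = s))) return(FALSE)
  hit <- vapply(sigs, prositeHits, logical(1), seqs = s)
  names(hit)[which(hit)[1L]] == sf && hit[[sf]]
}

# ---- genome -----------------------------------------------------------------

codonTable <- function(path = extdata("codon_table.tsv")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$codon, tab$residue)
}

# Deterministic reverse translation with the packaged one-codon-per-residue
# table, so protein -> CDS is reproducible.
reverseTranslate <- function(protein, codons = codonTable()) {
  paste(codons[seqChars(protein)], collapse = "")
}

.randomIntron <- function(len) {
  stopifnot(len >= 4L)
  paste0("GT", randDna(len - 4L), "AG")
}

# Build one gene's genomic sequence from its CDS, exon lengths and intron
# lengths; returns the sequence and transcript-orientation exon offsets.
.buildGeneSeq <- function(cds, exonLens, intronLens) {
  stopifnot(sum(exonLens) == nchar(cds),
            length(intronLens) == length(exonLens) - 1L)
  ends <- cumsum(exonLens)
  starts <- c(1L, head(ends, -1L) + 1L)
  parts <- character(2L * length(exonLens) - 1L)
  off <- matrix(0L, length(exonLens), 2L)
  pos <- 0L
  for (k in seq_along(exonLens)) {
    ex <- substring(cds, starts[k], ends[k])
    parts[2L * k - 1L] <- ex
    off[k, ] <- c(pos + 1L, pos + exonLens[k])
    pos <- pos + exonLens[k]
    if (k < length(exonLens)) {
      parts[2L * k] <- .randomIntron(intronLens[k])
      pos <- pos + intronLens[k]
    }
  }
  list(seq = paste(parts, collapse = ""), offsets = off)
}

#' Generate the synthetic genome, annotations and cDNAs
#'
#' Reverse-translates every planted protein with the packaged deterministic
#' codon table, splits the CDS into the truth exon layout separated by
#' random GT..AG introns, and places the genes without overlap on their
#' assigned chromosomes (tandem duplication partners adjacently, within the
#' linkage window). Strands are random; minus-strand genes are inserted as
#' reverse complements with forward-strand exon coordinates recorded. Each
#' gene's structure is checked to be unambiguously recoverable by exact
#' cDNA-to-genome chaining (introns are resampled in the rare case a splice
#' junction would be ambiguous).
#'
#' @param truth \code{FamilyTruth} from \code{\link{generateProteome}},
#'   together with the proteome it describes
#' @param proteome the AAStringSet returned by \code{\link{generateProteome}}
#' @param config the generator configuration
#' @return list with \code{genome} (DNAStringSet of chromosomes),
#'   \code{annotations} (GRanges), \code{cdnas} (DNAStringSet, transcript
#'   orientation) and the updated \code{truth}
#' @export
generateGenome <- function(truth, proteome, config) {
  genes <- truth@genes
  codons <- codonTable()
  withSeed(subSeed(config$seed, "genome"), {
    cds <- setNames(vapply(genes$gene_id, function(g)
      reverseTranslate(as.character(proteome[[g]]), codons), character(1)),
      genes$gene_id)
    built <- list()
    for (i in seq_len(nrow(genes))) {
      gid <- genes$gene_id[i]
      exonLens <- genes$exon_lengths[[i]]
      for (try in 1:20) {
        intronLens <- if (length(exonLens) > 1L)
          sample(seq(config$intron_length_range[1L], config$intron_length_range[2L]),
                 length(exonLens) - 1L, replace = TRUE) else integer(0)
        gs <- .buildGeneSeq(cds[gid], exonLens, intronLens)
        ch <- tryCatch(.chainExons(cds[gid], gs$seq, config$min_intron),
                       error = function(e) NULL)
        ok <- !is.null(ch) && nrow(ch) == length(exonLens) &&
          all(ch[, 1L] == gs$offsets[, 1L]) && all(ch[, 2L] == gs$offsets[, 2L])
        if (ok) break
        if (try == 20L) stop(gid, ": could not build unambiguous gene structure")
      }
      built[[gid]] <- c(gs, list(introns = intronLens))
    }

    chromNames <- sprintf("Chr%02d", seq_len(config$chromosome_count))
    chromSeqs <- setNames(character(config$chromosome_count), chromNames)
    annos <- list()
    loci <- data.frame(gene_id = genes$gene_id, start = NA_integer_,
                       end = NA_integer_, strand = NA_character_)
    strandPick <- setNames(sample(c("+", "-"), nrow(genes), replace = TRUE),
                           genes$gene_id)
    # tandem partners share their mate's strand for a clean head-to-tail pair
    for (cc in seq_len(config$chromosome_count)) {
      onC <- which(genes$chromosome == cc)
      units <- list()
      seen <- character(0)
      for (i in onC) {
        gid <- genes$gene_id[i]
        if (gid %in% seen) next
        mate <- genes$partner[i]
        if (!is.na(mate) && genes$tandem[i] && mate %in% genes$gene_id[onC]) {
          units[[length(units) + 1L]] <- c(gid, mate)
          seen <- c(seen, gid, mate)
        } else {
          units[[length(units) + 1L]] <- gid
          seen <- c(seen, gid)
        }
      }
      if (length(units)) units <- units[sample(length(units))]
      unitLen <- vapply(units, function(u) {
        sum(vapply(u, function(g) nchar(built[[g]]$seq), integer(1))) +
          if (length(u) == 2L) config$tandem_gap[2L] else 0L
      }, integer(1))
      nGaps <- length(units) + 1L
      minGap <- 1000L
      slack <- config$chromosome_length - sum(unitLen) - nGaps * minGap
      if (slack < 0L) stop("chromosome ", chromNames[cc],
                           " too short for its ", length(units), " genes")
      u <- runif(nGaps)
      gaps <- minGap + floor(u / sum(u) * slack)
      parts <- character(0); pos <- 0L
      for (k in seq_along(units)) {
        parts <- c(parts, randDna(gaps[k])); pos <- pos + gaps[k]
        for (g in units[[k]]) {
          gseq <- built[[g]]$seq
          strand <- strandPick[g]
          ins <- if (strand == "+") gseq else revComp(gseq)
          parts <- c(parts, ins)
          gstart <- pos + 1L; gend <- pos + nchar(gseq)
          off <- built[[g]]$offsets
          fwd <- if (strand == "+") cbind(gstart - 1L + off[, 1L], gstart - 1L + off[, 2L])
                 else cbind(gend + 1L - off[, 2L], gend + 1L - off[, 1L])
          fwd <- fwd[order(fwd[, 1L]), , drop = FALSE]
          annos[[g]] <- geneAnnotation(g, chromNames[cc], gstart, gend, strand, fwd)
          j <- match(g, loci$gene_id)
          loci$start[j] <- gstart; loci$end[j] <- gend; loci$strand[j] <- strand
          pos <- pos + nchar(gseq)
          if (length(units[[k]]) == 2L && g == units[[k]][1L]) {
            tg <- sample(seq(config$tandem_gap[1L], config$tandem_gap[2L]), 1L)
            parts <- c(parts, randDna(tg)); pos <- pos + tg
          }
        }
      }
      tailLen <- config$chromosome_length - pos
      parts <- c(parts, randDna(tailLen))
      chromSeqs[cc] <- paste(parts, collapse = "")
    }

    genome <- Biostrings::DNAStringSet(chromSeqs)
    annotations <- if (length(annos))
      suppressWarnings(do.call(c, unname(annos[genes$gene_id])))
    else GenomicRanges::GRanges()
    cdnas <- Biostrings::DNAStringSet(cds)
    gtab <- genes
    gtab$locus_start <- loci$start; gtab$locus_end <- loci$end
    gtab$strand <- loci$strand
    gtab$intron_lengths <- I(lapply(genes$gene_id, function(g) built[[g]]$introns))
    truth@genes <- gtab
    logMsg("info", "generateGenome: %d genes on %d chromosomes",
           nrow(genes), config$chromosome_count)
    list(genome = genome, annotations = annotations, cdnas = cdnas, truth = truth)
  })
}

# ---- reads ------------------------------------------------------------------

#' Simulate tissue read sets from the expression truth
#'
#' For each tissue, \code{reads_per_sample} error-free single-end reads are
#' drawn from uniform positions on the family transcripts with multiplicity
#' proportional to true RPKM x transcript length (so genes with zero truth
#' RPKM receive no reads), in random orientation. The realized per-transcript
#' read counts are returned; they sum to \code{reads_per_sample} per tissue.
#'
#' @param cdnas DNAStringSet of family transcripts
#' @param truth \code{FamilyTruth} carrying the expression matrix
#' @param config generator configuration
#' @param out_dir directory for \code{reads_<tissue>.fastq.gz}
#' @return list with \code{counts} (gene x tissue realized read counts) and
#'   \code{files} (named FASTQ paths)
#' @export
simulateReads <- function(cdnas, truth, config, out_dir) {
  expr <- truth@expression
  stopifnot(all(rownames(expr) %in% names(cdnas)))
  if (min(Biostrings::width(cdnas)) < config$read_length)
    stop("read_length exceeds the shortest transcript")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tissues <- colnames(expr)
  L <- setNames(Biostrings::width(cdnas), names(cdnas))[rownames(expr)]
  counts <- matrix(0L, nrow(expr), length(tissues), dimnames = dimnames(expr))
  files <- setNames(file.path(out_dir, sprintf("reads_%s.fastq.gz", tissues)),
                    tissues)
  withSeed(subSeed(config$seed, "reads"), {
    for (t in tissues) {
      w <- expr[, t] * L
      if (sum(w) > 0 && config$reads_per_sample > 0L) {
        counts[, t] <- as.integer(stats::rmultinom(1L, config$reads_per_sample,
                                                   w / sum(w)))
      }
      seqs <- character(0); rids <- character(0)
      for (g in rownames(expr)) {
        n <- counts[g, t]
        if (n == 0L) next
        tx <- as.character(cdnas[[g]])
        starts <- sample.int(L[g] - config$read_length + 1L, n, replace = TRUE)
        rd <- substring(tx, starts, starts + config$read_length - 1L)
        flip <- runif(n) < 0.5
        if (any(flip))
          rd[flip] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(rd[flip])))
        seqs <- c(seqs, rd)
      }
      if (length(seqs)) {
        seqs <- seqs[sample(length(seqs))]
        rids <- sprintf("%s_r%06d", t, seq_along(seqs))
      }
      reads <- Biostrings::DNAStringSet(seqs)
      names(reads) <- rids
      writeFastq(reads, files[[t]])
      logMsg("info", "simulateReads: %d reads -> %s", length(reads), files[[t]])
    }
  })
  list(counts = counts, files = files)
}

#' Write a complete synthetic dataset to disk
#'
#' Runs \code{\link{generateProteome}}, \code{\link{generateGenome}} and
#' \code{\link{simulateReads}} and writes genome.fasta, proteome.fasta,
#' queries.fasta, cdna.fasta, annotations.gff3, reads_<tissue>.fastq.gz,
#' expected_counts.tsv and truth.json.
#'
#' @param config generator configuration
#' @param out_dir output directory (created)
#' @return invisibly, a list with all in-memory stage outputs and file paths
#' @export
simulateDataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- generateProteome(config)
  gen <- generateGenome(prot$truth, prot$proteome, config)
  rds <- simulateReads(gen$cdnas, gen$truth, config, out_dir)
  paths <- list(
    proteome = file.path(out_dir, "proteome.fasta"),
    queries = file.path(out_dir, "queries.fasta"),
    genome = file.path(out_dir, "genome.fasta"),
    cdna = file.path(out_dir, "cdna.fasta"),
    annotations = file.path(out_dir, "annotations.gff3"),
    counts = file.path(out_dir, "expected_counts.tsv"),
    truth = file.path(out_dir, "truth.json"))
  writeFasta(prot$proteome, paths$proteome)
  writeFasta(prot$queries, paths$queries)
  writeFasta(gen$genome, paths$genome)
  writeFasta(gen$cdnas, paths$cdna)
  writeAnnotations(gen$annotations, paths$annotations)
  write.table(data.frame(gene_id = rownames(rds$counts), rds$counts),
              paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  writeTruthJson(gen$truth, paths$truth)
  invisible(c(gen, list(queries = prot$queries, reads = rds,
                        paths = c(paths, rds$files))))
}

#' Serialize a truth table to JSON
#'
#' @param truth a \code{FamilyTruth}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeTruthJson <- function(truth, path) {
  g <- truth@genes
  out <- list(
    genes = lapply(seq_len(nrow(g)), function(i) {
      x <- as.list(g[i, setdiff(names(g), c("exon_lengths", "intron_lengths"))])
      x$exon_lengths <- g$exon_lengths[[i]]
      x$intron_lengths <- if ("intron_lengths" %in% names(g))
        g$intron_lengths[[i]] else NULL
      x
    }),
    expression = as.data.frame(truth@expression),
    decoys = truth@decoys)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
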