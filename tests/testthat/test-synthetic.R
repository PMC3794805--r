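test_that("generator configs validate their invariants", {
  expect_error(generatorConfig(read_length = 19), ">= 20")
  expect_error(generatorConfig(partner_divergence = 0.3), "partner_divergence")
  expect_error(generatorConfig(ancestor_length = c(ZIK = 100, MEKK = 460, Raf = 550)),
               "too short")
})

test_that("the packaged paper profile pins the published family composition", {
  cfg <- paperProfileConfig()
  g <- cfg$genes
  expect_identical(nrow(g), 78L)
  tab <- table(g$subfamily)
  expect_identical(as.integer(tab[c("ZIK", "MEKK", "Raf")]), c(12L, 22L, 44L))
  expect_identical(sum(!g$expressed), 18L)
  expect_identical(range(g$exon_count), c(1L, 23L))
  expect_equal(sum(!is.na(g$partner)) / 2, 12)
  expect_equal(sum(g$tandem) / 2, 2)
  expect_identical(sum(g$chromosome == 6L), 11L)
  expect_identical(sum(g$chromosome == 10L), 3L)
  expect_identical(sum(g$contrast == "higher0"), 11L)
  expect_identical(sum(g$contrast == "higher3"), 8L)
  # partner symmetry
  p <- setNames(g$partner, g$gene_id)
  has <- !is.na(p)
  expect_identical(unname(p[p[has]]), names(p)[has])
})

test_that("same seed gives byte-identical synthetic data", {
  cfg <- smallConfig()
  a <- generateProteome(cfg)
  b <- generateProteome(cfg)
  expect_identical(as.character(a$proteome), as.character(b$proteome))
  expect_identical(as.character(a$queries), as.character(b$queries))
  expect_identical(a$truth@expression, b$truth@expression)
  ga <- generateGenome(a$truth, a$proteome, cfg)
  gb <- generateGenome(b$truth, b$proteome, cfg)
  expect_identical(as.character(ga$genome), as.character(gb$genome))
  da <- tempfile(); db <- tempfile()
  ra <- simulateReads(ga$cdnas, ga$truth, cfg, da)
  rb <- simulateReads(gb$cdnas, gb$truth, cfg, db)
  expect_identical(ra$counts, rb$counts)
  expect_identical(readLines(gzfile(ra$files[["leaf"]])),
                   readLines(gzfile(rb$files[["leaf"]])))
})

test_that("a single-ZIK config yields one protein carrying the ZIK literal", {
  cfg <- generatorConfig(seed = 3, n_zik = 1, n_mekk = 0, n_raf = 0,
                         n_decoys = 0, n_unexpressed = 0,
                         duplication_pairs = 0, n_tandem = 0,
                         raf_higher_0dpa = 0, raf_higher_3dpa = 0)
  pr <- generateProteome(cfg)
  expect_length(pr$proteome, 1L)
  expect_true(grepl("GTPEFMAPELY", as.character(pr$proteome[[1]]), fixed = TRUE))
})

test_that("planted motifs survive mutation and decoys never carry all hallmarks", {
  sd <- smallDataset()
  fam <- familyGenes(sd$truth)
  sigs <- subfamilySignatures()
  marks <- hallmarkPatterns()
  for (i in seq_len(nrow(fam))) {
    s <- as.character(sd$proteome[[fam$gene_id[i]]])
    expect_true(all(vapply(marks, prositeHits, logical(1), seqs = s)))
    expect_true(prositeHits(sigs[[fam$subfamily[i]]], s))
  }
  for (d in decoyIds(sd$truth)) {
    s <- as.character(sd$proteome[[d]])
    expect_false(all(vapply(marks, prositeHits, logical(1), seqs = s)))
  }
})

test_that("gene construction arithmetic: spans, GT..AG introns, exact cDNA", {
  sd <- smallDataset()
  fam <- familyGenes(sd$truth)
  tab <- annotationTable(sd$annotations)
  for (i in seq_len(nrow(fam))) {
    gid <- fam$gene_id[i]
    row <- tab[tab$gene_id == gid, ]
    exonW <- row$exon_ends[[1]] - row$exon_starts[[1]] + 1L
    introns <- if (length(exonW) > 1L)
      row$exon_starts[[1]][-1] - row$exon_ends[[1]][-length(exonW)] - 1L
    else integer(0)
    # genomic span = exons + introns; cDNA length = exon sum
    expect_identical(row$end - row$start + 1L, sum(exonW) + sum(introns))
    expect_identical(sum(exonW), Biostrings::width(sd$cdnas[gid]))
    # strand-adjusted exon concatenation spells the cDNA exactly
    chrom <- as.character(sd$genome[[row$chromosome]])
    pieces <- substring(chrom, row$exon_starts[[1]], row$exon_ends[[1]])
    spliced <- paste(pieces, collapse = "")
    if (row$strand == "-")
      spliced <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(spliced)))
    expect_identical(spliced, as.character(sd$cdnas[[gid]]))
    # introns begin GT and end AG in transcript orientation
    if (length(introns)) {
      for (k in seq_along(introns)) {
        iseq <- substring(chrom, row$exon_ends[[1]][k] + 1L,
                          row$exon_starts[[1]][k + 1L] - 1L)
        if (row$strand == "-")
          iseq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(iseq)))
        donors <- c(substr(iseq, 1, 2), substr(iseq, nchar(iseq) - 1, nchar(iseq)))
        expect_identical(donors, c("GT", "AG"))
      }
    }
  }
})

test_that("a zero-divergence duplication pair has identical cDNAs", {
  cfg <- generatorConfig(seed = 12, n_zik = 0, n_mekk = 0, n_raf = 4,
                         n_decoys = 0, n_unexpressed = 0,
                         duplication_pairs = 1, n_tandem = 0,
                         partner_divergence = 0, chromosome_count = 2,
                         chromosome_length = 80000,
                         raf_higher_0dpa = 0, raf_higher_3dpa = 0)
  pr <- generateProteome(cfg)
  gen <- generateGenome(pr$truth, pr$proteome, cfg)
  g <- familyGenes(gen$truth)
  pairRow <- g[!is.na(g$partner), ][1, ]
  expect_identical(as.character(gen$cdnas[[pairRow$gene_id]]),
                   as.character(gen$cdnas[[pairRow$partner]]))
})

test_that("read simulation respects the expression truth", {
  sd <- smallDataset()
  fam <- familyGenes(sd$truth)
  counts <- sd$reads$counts
  # conservation: per-sample realized counts sum to reads_per_sample
  expect_true(all(colSums(counts) == sd$cfg$reads_per_sample))
  # silent genes receive zero reads in every tissue
  silent <- fam$gene_id[!fam$expressed]
  expect_true(all(counts[silent, ] == 0L))
  expect_true(all(counts[fam$gene_id[fam$expressed], ] >= 0L))
})

test_that("expected counts scale with transcript length at equal RPKM", {
  cfg <- generatorConfig(seed = 5, n_zik = 1, n_mekk = 1, n_raf = 0,
                         n_decoys = 0, n_unexpressed = 0,
                         duplication_pairs = 0, n_tandem = 0,
                         chromosome_count = 1, chromosome_length = 60000,
                         reads_per_sample = 30000,
                         raf_higher_0dpa = 0, raf_higher_3dpa = 0)
  pr <- generateProteome(cfg)
  gen <- generateGenome(pr$truth, pr$proteome, cfg)
  # force equal RPKM truth; lengths are 3*380 vs 3*460
  tr <- gen$truth
  tr@expression[, ] <- 10
  rds <- simulateReads(gen$cdnas, tr, cfg, tempfile())
  L <- Biostrings::width(gen$cdnas)
  ratio <- (rds$counts[1, "leaf"] / rds$counts[2, "leaf"]) / (L[1] / L[2])
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
})
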