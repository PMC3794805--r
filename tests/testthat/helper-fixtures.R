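options(kinfamscan.verbose = 0)

# Shared fixtures, generated in code and cached for the duration of one
# test run. The small dataset exercises every stage quickly; the full
# paper-profile run backs the recovery checks and is computed once.
.fixtures <- new.env(parent = emptyenv())

smallConfig <- function() {
  generatorConfig(seed = 7L, n_zik = 2L, n_mekk = 3L, n_raf = 4L,
                  n_decoys = 10L, n_unexpressed = 2L,
                  duplication_pairs = 1L, n_tandem = 1L,
                  chromosome_count = 3L, chromosome_length = 100000L,
                  reads_per_sample = 5000L, exon_count_range = c(1L, 8L),
                  raf_higher_0dpa = 2L, raf_higher_3dpa = 1L)
}

smallDataset <- function() {
  if (is.null(.fixtures$small)) {
    old <- options(kinfamscan.verbose = 0)
    on.exit(options(old))
    cfg <- smallConfig()
    pr <- generateProteome(cfg)
    gen <- generateGenome(pr$truth, pr$proteome, cfg)
    dir <- tempfile("smallds_")
    rds <- simulateReads(gen$cdnas, gen$truth, cfg, dir)
    .fixtures$small <- list(cfg = cfg, proteome = pr$proteome,
                            queries = pr$queries, genome = gen$genome,
                            annotations = gen$annotations, cdnas = gen$cdnas,
                            truth = gen$truth, reads = rds)
  }
  .fixtures$small
}

paperRun <- function() {
  if (is.null(.fixtures$paper)) {
    old <- options(kinfamscan.verbose = 0)
    on.exit(options(old))
    cfg <- pipelineConfig(seed = 20131L, out_dir = tempfile("paper_run_"),
                          run_tree = FALSE)
    .fixtures$paper <- runPipeline(cfg)
  }
  .fixtures$paper
}
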