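#' Pipeline configuration
#'
#' Collects every stage setting of the end-to-end run. Defaults mirror the
#' survey conventions: 50\% identity screen, strict 0.8/0.8 duplication
#' thresholds, 1000 bootstrap replicates, 20-nt minimum read signatures.
#'
#' @param seed master seed; the generator and every stochastic stage derive
#'   their streams from it
#' @param out_dir directory receiving all stage outputs
#' @param generator a \code{\link{generatorConfig}}; defaults to the
#'   packaged paper profile at this seed
#' @param identity_threshold identity fraction for the screen
#' @param redundancy_identity,redundancy_coverage redundancy-removal
#'   thresholds
#' @param duplication_coverage,duplication_identity strict duplication
#'   thresholds
#' @param linkage_window tandem linkage distance (bp)
#' @param bootstrap_replicates bootstrap replicates for the tree stage
#' @param min_read_length minimum read signature length (nt)
#' @param min_reads unique-read threshold for the expressed call
#' @param run_tree set FALSE to skip the (slowest) phylogeny stage
#' @return a list of class "kinfam_pipeline_config"
#' @export
pipelineConfig <- function(seed = 1L, out_dir = tempfile("kinfam_run_"),
                           generator = NULL,
                           identity_threshold = 0.50,
                           redundancy_identity = 0.98,
                           redundancy_coverage = 0.98,
                           duplication_coverage = 0.8,
                           duplication_identity = 0.8,
                           linkage_window = 250000L,
                           bootstrap_replicates = 1000L,
                           min_read_length = 20L,
                           min_reads = 1L,
                           run_tree = TRUE) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 1,
            duplication_coverage > 0, duplication_coverage <= 1,
            duplication_identity > 0, duplication_identity <= 1,
            bootstrap_replicates >= 1L, min_read_length >= 1L)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 generator = generator %||% paperProfileConfig(seed = seed),
                 identity_threshold = identity_threshold,
                 redundancy_identity = redundancy_identity,
                 redundancy_coverage = redundancy_coverage,
                 duplication_coverage = duplication_coverage,
                 duplication_identity = duplication_identity,
                 linkage_window = as.integer(linkage_window),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 min_read_length = as.integer(min_read_length),
                 min_reads = as.integer(min_reads),
                 run_tree = isTRUE(run_tree)),
            class = "kinfam_pipeline_config")
}

#' Run the complete survey pipeline
#'
#' simulate -> identify -> classify -> protparam -> structure -> tree ->
#' duplication -> expression, with every stage output written under
#' \code{config$out_dir} (TSV/FASTA/GFF3/newick) so a run can be re-entered
#' at any stage, plus a JSON + text summary report. The run is
#' deterministic given the seed.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return invisibly, a list with the \code{summary} report, all in-memory
#'   stage results and the \code{truth} table
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "kinfam_pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  logMsg("info", "stage simulate")
  ds <- simulateDataset(config$generator, out)
  truth <- ds$truth

  logMsg("info", "stage identify")
  proteome <- readFasta(ds$paths$proteome, alphabet = "protein")
  queries <- readFasta(ds$paths$queries, alphabet = "protein")
  idf <- identifyFamily(proteome, queries,
                        threshold = config$identity_threshold,
                        redundancy_identity = config$redundancy_identity,
                        redundancy_coverage = config$redundancy_coverage)
  write.table(idf$report, file.path(out, "identify_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  logMsg("info", "stage classify")
  calls <- classifyProteins(idf$accepted)
  write.table(calls, file.path(out, "subfamily_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  subCounts <- summarizeSubfamilies(calls)

  logMsg("info", "stage protparam")
  params <- proteinParams(idf$accepted)
  write.table(params, file.path(out, "protein_params.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  logMsg("info", "stage structure")
  cdnas <- ds$cdnas
  structIds <- intersect(names(idf$accepted), names(cdnas))
  struct <- geneStructures(cdnas[structIds], ds$genome)
  write.table(struct$summary, file.path(out, "gene_structure.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeAnnotations(chainsToAnnotations(struct$chains),
                   file.path(out, "inferred_annotations.gff3"))
  sf <- setNames(truth@genes$subfamily, truth@genes$gene_id)
  chromDist <- chromosomeDistribution(struct$summary, sf)

  tree <- NULL
  if (config$run_tree && length(idf$accepted) >= 4L) {
    logMsg("info", "stage tree (%d bootstrap replicates)",
           config$bootstrap_replicates)
    msa <- progressiveMsa(idf$accepted)
    tree <- bootstrapSupport(msa, config$bootstrap_replicates,
                             seed = subSeed(config$seed, "bootstrap"))
    ape::write.tree(tree, file.path(out, "family_tree.nwk"))
  }

  logMsg("info", "stage duplication")
  dup <- callDuplications(cdnas[structIds], struct$summary,
                          cov = config$duplication_coverage,
                          ident = config$duplication_identity,
                          linkage_window = config$linkage_window)
  write.table(dup$pairs, file.path(out, "duplications.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  logMsg("info", "stage expression")
  exprTab <- quantifyExpression(cdnas, unlist(ds$paths[c("leaf", "ovule0", "ovule3")]),
                                min_length = config$min_read_length)
  write.table(exprTab, file.path(out, "expression_long.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  wide <- stats::reshape(exprTab[, c("transcript_id", "tissue", "rpkm")],
                         idvar = "transcript_id", timevar = "tissue",
                         direction = "wide")
  names(wide) <- sub("^rpkm\\.", "", names(wide))
  write.table(wide, file.path(out, "rpkm_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  exprCalls <- callExpression(exprTab, min_reads = config$min_reads)
  write.table(exprCalls, file.path(out, "expression_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = config$seed,
    funnel = list(candidates = length(proteome),
                  passed_identity = sum(idf$report$passed_identity),
                  non_redundant = sum(idf$report$passed_identity &
                                        is.na(idf$report$redundant_with)),
                  accepted = length(idf$accepted)),
    subfamilies = as.list(subCounts),
    chromosome_counts = as.list(chromDist$counts),
    duplication = list(pairs = nrow(dup$pairs), events = dup$n_events),
    expression = list(expressed = sum(exprCalls$expressed),
                      total = nrow(exprCalls),
                      higher_0DPA = sum(exprCalls$preference == "higher_0DPA" &
                                          exprCalls$expressed),
                      higher_3DPA = sum(exprCalls$preference == "higher_3DPA" &
                                          exprCalls$expressed)))
  result <- list(summary = summary, identify = idf, calls = calls,
                 params = params, structure = struct, tree = tree,
                 duplication = dup, expression = exprTab,
                 expression_calls = exprCalls, truth = truth,
                 dataset = ds, config = config)
  summary$recovery <- scoreAgainstTruth(result, truth)
  result$summary <- summary
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("candidates=%d passed=%d nonredundant=%d accepted=%d",
            summary$funnel$candidates, summary$funnel$passed_identity,
            summary$funnel$non_redundant, summary$funnel$accepted),
    sprintf("subfamilies ZIK=%d MEKK=%d Raf=%d unclassified=%d",
            subCounts[["ZIK"]], subCounts[["MEKK"]], subCounts[["Raf"]],
            subCounts[["unclassified"]]),
    sprintf("duplication pairs=%d events=%d", nrow(dup$pairs), dup$n_events),
    sprintf("expressed=%d/%d", summary$expression$expressed,
            summary$expression$total)),
    file.path(out, "summary.txt"))
  invisible(result)
}

#' Score pipeline outputs against the generator truth
#'
#' Per-stage precision/recall and exact-match rates: identification
#' (accepted vs planted family members), classification (called vs planted
#' subfamily), structure (exact recovery of the planted exon chain),
#' duplication (recovered vs planted partner pairs) and expression
#' (expressed-gene set vs truth).
#'
#' @param result a \code{\link{runPipeline}} result (or a compatible list)
#' @param truth the \code{FamilyTruth}
#' @return nested list of metrics
#' @export
scoreAgainstTruth <- function(result, truth) {
  g <- truth@genes
  if (nrow(g) == 0L) stop("empty truth table")
  planted <- g$gene_id
  accepted <- result$identify$report$protein_id[result$identify$report$accepted]
  known <- c(planted, truth@decoys)
  if (!all(accepted %in% known))
    stop("accepted ids not present in the truth table")
  tp <- sum(accepted %in% planted)
  ident <- list(precision = if (length(accepted)) tp / length(accepted) else NA,
                recall = tp / length(planted))

  calls <- result$calls
  m <- match(calls$protein_id, planted)
  classOk <- !is.na(m) & calls$subfamily == g$subfamily[m]
  classification <- list(exact = sum(classOk),
                         total = nrow(calls),
                         accuracy = if (nrow(calls)) mean(classOk) else NA)

  structure <- NULL
  if (!is.null(result$structure)) {
    chains <- result$structure$chains
    okv <- vapply(planted, function(gid) {
      ch <- chains[[gid]]
      if (is.null(ch) || ch$status != "ok") return(FALSE)
      i <- match(gid, planted)
      tExon <- g$exon_lengths[[i]]
      if (ch$exon_count != length(tExon)) return(FALSE)
      widths <- ch$exons[, 2L] - ch$exons[, 1L] + 1L
      if (ch$strand == "-") widths <- rev(widths)
      all(widths == tExon) &&
        identical(as.integer(if (ch$strand == "-") rev(ch$intron_lengths)
                             else ch$intron_lengths),
                  as.integer(g$intron_lengths[[i]])) &&
        ch$chromosome == sprintf("Chr%02d", g$chromosome[i]) &&
        ch$strand == g$strand[i] &&
        min(ch$exons[, 1L]) == g$locus_start[i] &&
        max(ch$exons[, 2L]) == g$locus_end[i]
    }, logical(1))
    structure <- list(exact = sum(okv), total = length(okv),
                      accuracy = mean(okv))
  }

  duplication <- NULL
  if (!is.null(result$duplication)) {
    truthPairs <- unique(t(apply(
      cbind(g$gene_id, g$partner)[!is.na(g$partner), , drop = FALSE],
      1L, sort)))
    called <- result$duplication$pairs
    calledKeys <- if (nrow(called))
      apply(cbind(called$gene_a, called$gene_b), 1L,
            function(x) paste(sort(x), collapse = "|")) else character(0)
    truthKeys <- if (nrow(truthPairs))
      apply(truthPairs, 1L, paste, collapse = "|") else character(0)
    tpd <- sum(calledKeys %in% truthKeys)
    duplication <- list(
      precision = if (length(calledKeys)) tpd / length(calledKeys) else NA,
      recall = if (length(truthKeys)) tpd / length(truthKeys) else NA)
  }

  expression <- NULL
  if (!is.null(result$expression_calls)) {
    ec <- result$expression_calls
    m <- match(ec$gene_id, planted)
    if (anyNA(m)) stop("expression call ids not in truth")
    expression <- list(
      accuracy = mean(ec$expressed == g$expressed[m]),
      expressed_called = sum(ec$expressed),
      expressed_truth = sum(g$expressed))
  }

  list(identification = ident, classification = classification,
       structure = structure, duplication = duplication,
       expression = expression)
}
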