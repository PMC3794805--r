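#' Identity screen against a query family set
#'
#' For every candidate protein, the best local-alignment identity against
#' any query is computed (BLASTP-hit semantics: identity over the local
#' alignment's columns, not over the full sequence length — the screen is
#' configurable through \code{scoring} and the caller can recompute identity
#' over full length from the returned coverage if preferred). Candidates at
#' or above \code{threshold} pass.
#'
#' @param candidates AAStringSet of candidate proteins
#' @param queries AAStringSet of query family proteins (>= 1)
#' @param threshold identity fraction required to pass (default 0.50)
#' @param min_aligned minimum local-alignment length (residue-vs-residue
#'   columns) for a hit to count. Optimal local alignments between unrelated
#'   proteins are occasionally only a handful of columns long with
#'   deceptively high identity; a heuristic search would never report such
#'   hits, so they are excluded here the same way
#' @param scoring protein scoring scheme
#' @return data.frame: protein_id, best_query_id, best_identity,
#'   best_aligned_length, passed_identity
#' @export
screenByIdentity <- function(candidates, queries, threshold = 0.50,
                             min_aligned = 50L,
                             scoring = alignScoring("protein")) {
  if (length(candidates) == 0L)
    return(data.frame(protein_id = character(0), best_query_id = character(0),
                      best_identity = numeric(0),
                      best_aligned_length = integer(0),
                      passed_identity = logical(0)))
  if (length(queries) == 0L) stop("at least one query sequence is required")
  best <- rep(0, length(candidates))
  bestLen <- rep(0L, length(candidates))
  bestQ <- rep(NA_character_, length(candidates))
  for (q in seq_along(queries)) {
    st <- alignManyStats(candidates, queries[[q]], scoring, "local")
    ident <- ifelse(st$alignedLength >= min_aligned, st$identity, 0)
    upd <- ident > best
    best[upd] <- ident[upd]
    bestLen[upd] <- st$alignedLength[upd]
    bestQ[upd] <- names(queries)[q]
  }
  out <- data.frame(protein_id = names(candidates), best_query_id = bestQ,
                    best_identity = best, best_aligned_length = bestLen,
                    passed_identity = best >= threshold,
                    row.names = NULL)
  logMsg("info", "screenByIdentity: %d/%d candidates pass at %.2f",
         sum(out$passed_identity), nrow(out), threshold)
  out
}

#' Redundancy removal by self-alignment
#'
#' Single-linkage clustering of near-identical entries: two sequences are
#' linked when their global-alignment identity is at least
#' \code{identity_min} and the coverage of each sequence is at least
#' \code{coverage_min}. Within each cluster the longest member is kept
#' (ties broken toward the lexicographically smallest id). The defaults
#' (0.98/0.98) collapse only near-identical database duplicates. Because
#' global identity can never exceed the ratio of the shorter to the longer
#' sequence length, pairs failing that bound are skipped without alignment.
#'
#' @param passed AAStringSet of sequences that passed the identity screen
#' @param coverage_min,identity_min linkage thresholds
#' @param scoring protein scoring scheme
#' @return list with \code{kept} (AAStringSet) and \code{redundant_with}
#'   (named character: dropped id -> keeper id)
#' @export
removeRedundancy <- function(passed, coverage_min = 0.98, identity_min = 0.98,
                             scoring = alignScoring("protein")) {
  n <- length(passed)
  if (n <= 1L)
    return(list(kept = passed, redundant_with = setNames(character(0), character(0))))
  ids <- names(passed)
  lens <- Biostrings::width(passed)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (j in 2:n) {
    cand <- which(pmin(lens[1:(j - 1L)], lens[j]) / pmax(lens[1:(j - 1L)], lens[j])
                  >= identity_min)
    if (!length(cand)) next
    st <- alignManyStats(passed[cand], passed[[j]], scoring, "global")
    link <- st$identity >= identity_min & st$coverageA >= coverage_min &
      st$coverageB >= coverage_min
    for (i in cand[link]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keepIdx <- vapply(split(seq_len(n), comp), function(members) {
    best <- members[lens[members] == max(lens[members])]
    best[order(ids[best])][1L]
  }, integer(1))
  keeperOf <- setNames(ids[keepIdx][match(comp, comp[keepIdx])], ids)
  dropped <- ids[ids != keeperOf]
  logMsg("info", "removeRedundancy: %d/%d kept", n - length(dropped), n)
  list(kept = passed[setdiff(ids, dropped)],
       redundant_with = keeperOf[dropped])
}

#' Kinase hallmark validation
#'
#' A protein is accepted when every required hallmark pattern matches at
#' least once.
#'
#' @param proteins AAStringSet
#' @param patterns named list of \code{PrositePattern}, e.g. from
#'   \code{\link{hallmarkPatterns}}
#' @return data.frame: protein_id, matched_hallmarks (comma-separated),
#'   all_hallmarks (logical)
#' @export
validateHallmarks <- function(proteins, patterns) {
  if (length(patterns) == 0L) stop("no hallmarks configured")
  hits <- vapply(patterns, prositeHits, logical(length(proteins)),
                 seqs = proteins)
  if (length(proteins) == 1L) hits <- matrix(hits, nrow = 1L,
                                             dimnames = list(NULL, names(patterns)))
  matched <- apply(hits, 1L, function(h) paste(names(patterns)[h], collapse = ","))
  out <- data.frame(protein_id = names(proteins), matched_hallmarks = matched,
                    all_hallmarks = rowSums(hits) == length(patterns),
                    row.names = NULL)
  logMsg("info", "validateHallmarks: %d/%d carry all %d hallmarks",
         sum(out$all_hallmarks), nrow(out), length(patterns))
  out
}

#' The full identification funnel
#'
#' Chains the identity screen, redundancy removal (among passing candidates)
#' and hallmark validation, mirroring the screen-then-check design of
#' genome-wide gene family surveys. The funnel is monotone: raising the
#' identity threshold can only shrink the accepted set.
#'
#' @inheritParams screenByIdentity
#' @param patterns hallmark patterns for \code{\link{validateHallmarks}}
#' @param redundancy_identity,redundancy_coverage thresholds for
#'   \code{\link{removeRedundancy}}
#' @return list with \code{report} (one row per candidate: protein_id,
#'   best_query_id, best_identity, passed_identity, redundant_with,
#'   matched_hallmarks, accepted) and \code{accepted} (AAStringSet)
#' @export
identifyFamily <- function(candidates, queries,
                           patterns = hallmarkPatterns(),
                           threshold = 0.50,
                           min_aligned = 50L,
                           redundancy_identity = 0.98,
                           redundancy_coverage = 0.98,
                           scoring = alignScoring("protein")) {
  screen <- screenByIdentity(candidates, queries, threshold,
                             min_aligned = min_aligned, scoring = scoring)
  passed <- candidates[screen$passed_identity]
  red <- removeRedundancy(passed, redundancy_coverage, redundancy_identity, scoring)
  hall <- if (length(red$kept))
    validateHallmarks(red$kept, patterns)
  else data.frame(protein_id = character(0), matched_hallmarks = character(0),
                  all_hallmarks = logical(0))
  report <- screen
  report$redundant_with <- NA_character_
  if (length(red$redundant_with))
    report$redundant_with[match(names(red$redundant_with), report$protein_id)] <-
      unname(red$redundant_with)
  report$matched_hallmarks <- hall$matched_hallmarks[
    match(report$protein_id, hall$protein_id)]
  report$accepted <- report$passed_identity & is.na(report$redundant_with) &
    !is.na(report$matched_hallmarks) &
    report$protein_id %in% hall$protein_id[hall$all_hallmarks]
  accepted <- candidates[report$protein_id[report$accepted]]
  logMsg("info", "identifyFamily: %d candidates -> %d passed -> %d kept -> %d accepted",
         length(candidates), length(passed), length(red$kept), length(accepted))
  list(report = report, accepted = accepted)
}
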