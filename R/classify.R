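#' Subfamily signature matchers
#'
#' The three diagnostic kinase-subdomain-VIII signatures: the ZIK literal
#' GTPEFMAPELY, the MEKK consensus G-[TS]-P-x-[WF]-M-A-P-E-V, and the less
#' conserved Raf consensus G-T-x-x-[WY]-M-A-P-E-[LV]. "x" means any of the
#' 20 standard residues. The ZIK literal structurally never satisfies the
#' MEKK pattern (which requires a terminal V) nor the Raf pattern (which
#' requires W/Y at position 5); the MEKK and Raf patterns do intersect,
#' which is why classification applies the precedence ZIK > MEKK > Raf and
#' flags multi-class matches as ambiguous.
#'
#' @return named list of \code{PrositePattern}: ZIK, MEKK, Raf
#' @export
subfamilySignatures <- function() {
  list(ZIK = parseProsite("G-T-P-E-F-M-A-P-E-L-Y", "ZIK"),
       MEKK = parseProsite("G-[TS]-P-x-[WF]-M-A-P-E-V", "MEKK"),
       Raf = parseProsite("G-T-x-x-[WY]-M-A-P-E-[LV]", "Raf"))
}

#' Kinase-domain span from hallmark matches
#'
#' The span runs from the leftmost ATP-binding-loop hit to the rightmost
#' active-site hit (the two hallmark anchors that bracket the catalytic
#' core in the scaffold).
#'
#' @param protein residue string or AAString
#' @param marks hallmark patterns (\code{\link{hallmarkPatterns}})
#' @return integer c(start, end), or NA values if either anchor is missing
#' @export
kinaseDomainSpan <- function(protein, marks = hallmarkPatterns()) {
  atp <- prositeMatch(marks$atp_binding, protein)
  act <- prositeMatch(marks$st_active_site, protein)
  if (nrow(atp) == 0L || nrow(act) == 0L) return(c(NA_integer_, NA_integer_))
  c(min(atp$start), max(act$end))
}

#' Classify one protein into ZIK / MEKK / Raf
#'
#' The signature patterns are evaluated in precedence order ZIK > MEKK >
#' Raf; the first matching class wins, and \code{ambiguous} is set when more
#' than one class matches. A protein matching no signature is
#' "unclassified". The kinase-domain position is reported as N-terminal
#' when the domain midpoint falls in the first third of the sequence,
#' C-terminal in the last third, central otherwise.
#'
#' @param protein residue string or AAString
#' @param kinase_domain_span integer c(start, end); computed from hallmark
#'   hits when NULL
#' @param sigs signature matchers from \code{\link{subfamilySignatures}}
#' @param marks hallmark patterns (used only when the span is computed here)
#' @return one-row data.frame: subfamily, signature_hit, signature_start,
#'   domain_position, ambiguous
#' @export
classifyProtein <- function(protein, kinase_domain_span = NULL,
                            sigs = subfamilySignatures(),
                            marks = hallmarkPatterns()) {
  s <- as.character(protein)
  hits <- lapply(sigs, prositeMatch, seq = s)
  matched <- names(sigs)[vapply(hits, nrow, integer(1)) > 0L]
  if (length(matched)) {
    subfamily <- matched[1L]  # precedence = list order ZIK > MEKK > Raf
    h <- hits[[subfamily]][1L, ]
    sigHit <- h$match; sigStart <- h$start
  } else {
    subfamily <- "unclassified"; sigHit <- NA_character_; sigStart <- NA_integer_
  }
  span <- kinase_domain_span %||% kinaseDomainSpan(s, marks)
  pos <- if (anyNA(span)) NA_character_ else {
    midpoint <- (span[1L] + span[2L]) / 2
    L <- nchar(s)
    if (midpoint <= L / 3) "N-terminal"
    else if (midpoint > 2 * L / 3) "C-terminal" else "central"
  }
  data.frame(subfamily = subfamily, signature_hit = sigHit,
             signature_start = sigStart, domain_position = pos,
             ambiguous = length(matched) >= 2L, row.names = NULL)
}

#' Classify a set of accepted proteins
#'
#' @param proteins AAStringSet (typically the accepted set from
#'   \code{\link{identifyFamily}})
#' @inheritParams classifyProtein
#' @return data.frame with one row per protein: protein_id plus the
#'   \code{\link{classifyProtein}} columns
#' @export
classifyProteins <- function(proteins, sigs = subfamilySignatures(),
                             marks = hallmarkPatterns()) {
  rows <- lapply(seq_along(proteins), function(i)
    cbind(protein_id = names(proteins)[i],
          classifyProtein(proteins[[i]], sigs = sigs, marks = marks)))
  out <- do.call(rbind, rows)
  logMsg("info", "classifyProteins: %s",
         paste(names(table(out$subfamily)), table(out$subfamily),
               sep = "=", collapse = " "))
  out
}

#' Subfamily counts
#'
#' @param calls data.frame from \code{\link{classifyProteins}}
#' @return named integer vector over ZIK, MEKK, Raf, unclassified; sums to
#'   the number of calls
#' @export
summarizeSubfamilies <- function(calls) {
  lv <- c("ZIK", "MEKK", "Raf", "unclassified")
  tab <- table(factor(calls$subfamily, levels = lv))
  setNames(as.integer(tab), lv)
}
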