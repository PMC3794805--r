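#' Packaged Bjellqvist pK table
#'
#' pK values for the ionizable groups used in the net-charge model: the
#' alpha-amino group (with residue-specific variants for the N-terminal
#' residue), the alpha-carboxyl group, and the side chains of C, D, E, H, K,
#' R and Y (with C-terminal-residue variants for D and E). The packaged file
#' carries the immobilized-pH-gradient calibration values used by the ExPASy
#' Compute pI/Mw tool; the code treats the table as opaque configuration.
#'
#' @param path TSV with columns group, residue, pk
#' @return list with components \code{nterm}, \code{cterm}, \code{side},
#'   \code{side_cterm}
#' @export
pkTable <- function(path = extdata("pk_bjellqvist.tsv")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(tab$pk > 0 & tab$pk < 14))
  pick <- function(g) setNames(tab$pk[tab$group == g], tab$residue[tab$group == g])
  list(nterm = pick("nterm"), cterm = unname(pick("cterm")["default"]),
       side = pick("sidechain"), side_cterm = pick("sidechain_cterm"))
}

#' Packaged average residue masses
#'
#' @param path TSV with columns residue, mass; the \code{water} row is the
#'   mass of one water molecule
#' @return list with \code{residues} (named vector, Da) and \code{water} (Da)
#' @export
massTable <- function(path = extdata("aa_masses.tsv")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(tab$mass > 0))
  m <- setNames(tab$mass, tab$residue)
  list(residues = m[setdiff(names(m), "water")], water = unname(m["water"]))
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch model: the N-terminus and the side chains of H, K
#' and R contribute \eqn{+1/(1+10^{pH-pK})}; the C-terminus and the side
#' chains of C, D, E and Y contribute \eqn{-1/(1+10^{pK-pH})}. The
#' N-terminal pK depends on the leading residue where the pK set provides a
#' variant; a C-terminal D or E uses its C-terminal side-chain pK.
#'
#' @param protein residue string (20-letter alphabet)
#' @param pH numeric vector of pH values
#' @param pk pK set from \code{\link{pkTable}}
#' @return numeric vector of net charges, one per pH
#' @export
netCharge <- function(protein, pH, pk = pkTable()) {
  res <- seqChars(protein)
  if (length(res) == 0L) stop("empty protein")
  bad <- setdiff(res, AA20)
  if (length(bad)) stop("residue outside the 20-letter alphabet: ", bad[1L])
  first <- res[1L]; last <- res[length(res)]
  ntermPk <- unname(if (first %in% names(pk$nterm)) pk$nterm[first]
                    else pk$nterm["default"])
  counts <- table(factor(res, levels = AA20))
  # C-terminal D/E side chain uses its own pK
  ctermSide <- NULL
  if (last %in% names(pk$side_cterm)) {
    counts[last] <- counts[last] - 1L
    ctermSide <- unname(pk$side_cterm[last])
  }
  pos <- function(pK, n) n / (1 + 10^(pH - pK))
  neg <- function(pK, n) -n / (1 + 10^(pK - pH))
  q <- pos(ntermPk, 1) + neg(pk$cterm, 1)
  for (r in c("H", "K", "R")) q <- q + pos(pk$side[r], counts[[r]])
  for (r in c("C", "D", "E", "Y")) q <- q + neg(pk$side[r], counts[[r]])
  if (!is.null(ctermSide)) q <- q + neg(ctermSide, 1)
  unname(q)
}

#' Theoretical isoelectric point
#'
#' Bisection on pH in [0, 14] for the root of \code{\link{netCharge}}, which
#' is strictly decreasing in pH, so the root is unique. Iteration stops when
#' the net charge magnitude or the bracketing interval falls below
#' \code{tol}.
#'
#' @inheritParams netCharge
#' @param tol convergence tolerance (pH units / charge units)
#' @return the pI, a single pH value
#' @export
isoelectricPoint <- function(protein, pk = pkTable(), tol = 1e-4) {
  lo <- 0; hi <- 14
  mid <- (lo + hi) / 2
  repeat {
    q <- netCharge(protein, mid, pk)
    if (abs(q) < tol || (hi - lo) < tol) break
    if (q > 0) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
  }
  mid
}

#' Average molecular weight
#'
#' Sum of the average isotopic residue masses plus the mass of one water
#' molecule, in Daltons.
#'
#' @inheritParams netCharge
#' @param masses mass set from \code{\link{massTable}}
#' @return molecular weight in Da
#' @export
molecularWeight <- function(protein, masses = massTable()) {
  res <- seqChars(protein)
  if (length(res) == 0L) stop("empty protein")
  bad <- setdiff(res, names(masses$residues))
  if (length(bad)) stop("unknown residue: ", bad[1L])
  sum(masses$residues[res]) + masses$water
}

#' Per-protein physicochemical parameter table
#'
#' The per-gene table of sequence length, theoretical pI and molecular
#' weight (reported in kDa, rounded to two decimals to match the
#' conventional report format).
#'
#' @param proteins AAStringSet
#' @param pk,masses parameter sets
#' @return data.frame with columns id, AA, pI, Mw_kDa
#' @export
proteinParams <- function(proteins, pk = pkTable(), masses = massTable()) {
  s <- as.character(proteins)
  data.frame(
    id = names(proteins) %||% seq_along(proteins),
    AA = nchar(s),
    pI = round(vapply(s, isoelectricPoint, numeric(1), pk = pk), 2),
    Mw_kDa = round(vapply(s, molecularWeight, numeric(1),
                          masses = masses) / 1000, 2),
    row.names = NULL)
}
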