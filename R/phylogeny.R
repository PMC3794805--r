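# ---- progressive multiple alignment ----------------------------------------

# Linear-gap profile-profile alignment. M is the column-score matrix
# (sum-of-pairs substitution score between profile columns, averaged over
# sequence pairs; gaps score 0). Returns the traceback path as a matrix of
# (iA, iB) column indices with 0 marking a gap column. Rows of the DP are
# vectorised with a running-maximum trick, ties break diagonal > up > left.
.profileDP <- function(M, gap) {
  nA <- nrow(M); nB <- ncol(M)
  H <- matrix(0, nA + 1L, nB + 1L)
  H[1L, ] <- -gap * (0:nB)
  H[, 1L] <- -gap * (0:nA)
  j <- seq_len(nB)
  for (i in seq_len(nA)) {
    V <- pmax(H[i, j] + M[i, ], H[i, j + 1L] - gap)
    W <- c(H[i + 1L, 1L], V + gap * j)
    H[i + 1L, j + 1L] <- cummax(W)[j + 1L] - gap * j
  }
  # traceback with fixed tie order
  path <- matrix(0L, 0L, 2L)
  i <- nA; jj <- nB
  eps <- 1e-9
  while (i > 0L || jj > 0L) {
    h <- H[i + 1L, jj + 1L]
    if (i > 0L && jj > 0L && abs(H[i, jj] + M[i, jj] - h) < eps) {
      path <- rbind(c(i, jj), path); i <- i - 1L; jj <- jj - 1L
    } else if (i > 0L && abs(H[i, jj + 1L] - gap - h) < eps) {
      path <- rbind(c(i, 0L), path); i <- i - 1L
    } else {
      path <- rbind(c(0L, jj), path); jj <- jj - 1L
    }
  }
  list(path = path, score = H[nA + 1L, nB + 1L])
}

# Residue-frequency matrix (20 x L) of a character-matrix profile.
.profileFreq <- function(prof) {
  L <- ncol(prof)
  F <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
  for (a in AA20) F[a, ] <- colSums(prof == a)
  F
}

.mergeProfiles <- function(profA, profB, S, gap) {
  FA <- .profileFreq(profA); FB <- .profileFreq(profB)
  M <- crossprod(FA, S[AA20, AA20] %*% FB) / (nrow(profA) * nrow(profB))
  dp <- .profileDP(M, gap)
  path <- dp$path
  out <- matrix("-", nrow(profA) + nrow(profB), nrow(path))
  selA <- path[, 1L] > 0L; selB <- path[, 2L] > 0L
  out[seq_len(nrow(profA)), selA] <- profA[, path[selA, 1L], drop = FALSE]
  out[nrow(profA) + seq_len(nrow(profB)), selB] <- profB[, path[selB, 2L], drop = FALSE]
  rownames(out) <- c(rownames(profA), rownames(profB))
  out
}

#' Progressive multiple sequence alignment
#'
#' ClustalW-style progressive alignment: pairwise global alignments give
#' p-distances (one minus identity), a neighbor-joining guide tree orders
#' the merges, and profiles are merged by profile-profile dynamic
#' programming with average sum-of-pairs substitution scores and a linear
#' gap penalty. Ungapping any output row recovers the corresponding input.
#'
#' @param seqs AAStringSet (>= 1 sequence)
#' @param scoring protein scoring scheme; its gap opening penalty is used
#'   as the linear profile gap cost
#' @return an \code{AAMultipleAlignment}
#' @export
progressiveMsa <- function(seqs, scoring = alignScoring("protein")) {
  n <- length(seqs)
  if (n == 0L) stop("no sequences")
  ids <- names(seqs) %||% as.character(seq_len(n))
  if (n == 1L) {
    out <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(
      setNames(as.character(seqs), ids)))
    return(out)
  }
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(seqChars(as.character(seqs[[i]])), nrow = 1L)
    rownames(m) <- ids[i]
    m
  })
  if (n == 2L) {
    hit <- globalAlign(as.character(seqs[[1L]]), as.character(seqs[[2L]]), scoring)
    aln <- rbind(seqChars(hit@alignedA), seqChars(hit@alignedB))
    rownames(aln) <- ids
    merged <- aln
  } else {
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (j in 2:n) {
      st <- alignManyStats(seqs[1:(j - 1L)], seqs[[j]], scoring, "global")
      d[1:(j - 1L), j] <- d[j, 1:(j - 1L)] <- 1 - st$identity
    }
    nj <- neighborJoining(d, keep_merges = TRUE)
    merged <- NULL
    live <- profiles
    names(live) <- ids
    for (m in nj$merges) {
      a <- live[[m[1L]]]; b <- live[[m[2L]]]
      live[[m[1L]]] <- NULL; live[[m[2L]]] <- NULL
      live[[m[3L]]] <- .mergeProfiles(a, b, scoring$matrix, scoring$gapOpening)
    }
    # the final NJ join can leave up to three live profiles; fold them in
    while (length(live) > 1L) {
      live[[1L]] <- .mergeProfiles(live[[1L]], live[[2L]], scoring$matrix,
                                   scoring$gapOpening)
      live[[2L]] <- NULL
    }
    merged <- live[[1L]]
  }
  merged <- merged[ids, , drop = FALSE]
  rows <- apply(merged, 1L, paste, collapse = "")
  Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(setNames(rows, ids)))
}

# ---- distances --------------------------------------------------------------

# Explicit MultipleAlignment/character-matrix conversion (avoids relying on
# as.matrix S4 dispatch from within the namespace).
.msaMatrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (methods::is(msa, "MultipleAlignment")) {
    rows <- as.character(Biostrings::unmasked(msa))
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    rownames(m) <- names(rows)
    return(m)
  }
  stop("expected an aligned character matrix or MultipleAlignment")
}

#' Pairwise p-distances from an alignment
#'
#' d(i, j) = mismatches / columns where both rows carry a residue
#' (pairwise deletion of gap columns). A pair with no comparable columns is
#' an error.
#'
#' @param msa an \code{AAMultipleAlignment}, or a character matrix of
#'   aligned rows
#' @return symmetric numeric matrix with zero diagonal
#' @export
pDistance <- function(msa) {
  m <- .msaMatrix(msa)
  n <- nrow(m)
  if (n < 2L) stop("need at least two rows")
  ids <- rownames(m)
  B <- (m != "-") * 1
  comp <- tcrossprod(B)
  matches <- matrix(0, n, n)
  for (a in setdiff(unique(as.vector(m)), "-"))
    matches <- matches + tcrossprod((m == a) * 1)
  off <- comp; diag(off) <- 1
  if (any(off == 0)) {
    bad <- which(off == 0, arr.ind = TRUE)[1L, ]
    stop("rows ", ids[bad[1L]], " and ", ids[bad[2L]], " share no columns")
  }
  d <- (comp - matches) / comp
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

# ---- neighbor joining -------------------------------------------------------

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimising
#' Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k) is joined (ties
#' resolved toward the lexicographically smallest pair of cluster labels,
#' each cluster labelled by its smallest member id), with rate-corrected
#' branch lengths. Negative branch-length estimates are clamped to zero
#' with a warning attribute. On additive distance matrices the generating
#' topology is recovered exactly.
#'
#' @param d symmetric distance matrix with ids as dimnames (n >= 2)
#' @param keep_merges also return the merge order (used by the progressive
#'   aligner's guide tree)
#' @return an unrooted \code{ape::phylo} tree; with \code{keep_merges} a
#'   list of \code{tree} and \code{merges}
#' @export
neighborJoining <- function(d, keep_merges = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa")
  ids <- rownames(d) %||% as.character(seq_len(n))
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0), all(d >= 0))
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  # cluster state: newick fragment + label (smallest member id)
  labs <- ids
  frags <- ids
  merges <- list()
  while (length(labs) > 2L) {
    m <- length(labs)
    rs <- rowSums(d)
    Q <- (m - 2) * d - outer(rs, rs, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    pairLab <- apply(best, 1L, function(ij) {
      p <- sort(c(labs[ij[1L]], labs[ij[2L]])); paste(p[1L], p[2L])
    })
    pick <- best[order(pairLab)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- bl(d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2)))
    lj <- bl(d[i, j] - (d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))))
    newFrag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], li, frags[j], lj)
    newLab <- min(labs[i], labs[j])
    merges[[length(merges) + 1L]] <- c(labs[i], labs[j], newLab)
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    labs <- c(labs[keep], newLab)
    frags <- c(frags[keep], newFrag)
    rownames(d) <- colnames(d) <- labs
  }
  # final join: a midpoint root that ape::unroot collapses, leaving one
  # bridge edge of the full remaining distance
  len <- bl(d[1L, 2L])
  nwk <- sprintf("(%s:%.10g,%s:%.10g);", frags[1L], len / 2, frags[2L], len / 2)
  merges[[length(merges) + 1L]] <- c(labs[1L], labs[2L], min(labs))
  tree <- ape::read.tree(text = nwk)
  if (length(tree$tip.label) > 2L) tree <- ape::unroot(tree)
  attr(tree, "clamped") <- clamped
  if (clamped) logMsg("debug", "neighborJoining: negative branch length clamped to 0")
  if (keep_merges) list(tree = tree, merges = merges) else tree
}

# ---- bootstrap --------------------------------------------------------------

#' Bipartitions of an unrooted tree
#'
#' Non-trivial bipartitions (internal edges) as canonical keys: the tip set
#' on the side not containing the alphabetically first tip, sorted and
#' joined with "|".
#'
#' @param tree an \code{ape::phylo}
#' @return character vector of bipartition keys, named by the internal node
#'   below each edge
#' @export
treeBipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  edge <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(edge)))
    sets[[edge[k, 1L]]] <- c(sets[[edge[k, 1L]]], sets[[edge[k, 2L]]])
  ref <- sort(tree$tip.label)[1L]
  keys <- character(0)
  for (k in seq_len(nrow(edge))) {
    child <- edge[k, 2L]
    if (child <= nt) next           # trivial split
    s <- sets[[child]]
    if (length(s) < 2L || length(s) > nt - 2L) next
    if (ref %in% s) s <- setdiff(tree$tip.label, s)
    keys[as.character(child)] <- paste(sort(s), collapse = "|")
  }
  keys
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; each replicate is
#' rebuilt with \code{\link{pDistance}} + \code{\link{neighborJoining}},
#' and each internal edge of the point tree receives the percentage of
#' replicate trees containing the same bipartition.
#'
#' @param msa an \code{AAMultipleAlignment} or aligned character matrix
#'   with at least 4 rows
#' @param replicates number of bootstrap replicates (surveys conventionally
#'   use 1000; smaller values are appropriate for quick runs)
#' @param seed RNG seed for the resampling
#' @return the point NJ tree (\code{ape::phylo}) with \code{node.label}
#'   holding percent support for internal edges ("" at the root node)
#' @export
bootstrapSupport <- function(msa, replicates = 1000L, seed = 1L) {
  m <- .msaMatrix(msa)
  if (nrow(m) < 4L) stop("bootstrap support needs at least 4 sequences")
  point <- neighborJoining(pDistance(m))
  pointKeys <- treeBipartitions(point)
  counts <- setNames(numeric(length(pointKeys)), pointKeys)
  done <- 0L
  withSeed(seed, {
    while (done < replicates) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep <- tryCatch(neighborJoining(pDistance(m[, cols, drop = FALSE])),
                      error = function(e) NULL)
      if (is.null(rep)) next     # a pair without comparable columns; redraw
      done <- done + 1L
      hit <- pointKeys %in% treeBipartitions(rep)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / replicates
  nt <- length(point$tip.label)
  labels <- rep("", point$Nnode)
  idx <- as.integer(names(pointKeys)) - nt
  labels[idx] <- sprintf("%g", round(support, 1))
  point$node.label <- labels
  attr(point, "support") <- support
  point
}
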