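# Independent alignment oracle: plain-R three-state affine-gap dynamic
# programme (Gotoh), written separately from the package's alignment engine.
# Gap convention matches the engine's: a gap of length k costs open + k*ext.
oracleAlignScore <- function(a, b, mat, open, ext, type = c("global", "local")) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)  # last column was a residue pair
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (b consumed)
  M[1L, 1L] <- 0
  if (type == "global") {
    for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + j * ext)
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1L, j + 1L] <- if (type == "local") max(prev, 0) + s else prev + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - (open + ext),
                               X[i, j + 1L] - ext,
                               Y[i, j + 1L] - (open + ext))
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - (open + ext),
                               Y[i + 1L, j] - ext,
                               X[i + 1L, j] - (open + ext))
      if (type == "local") best <- max(best, M[i + 1L, j + 1L])
    }
  }
  if (type == "local") best
  else max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Brute-force enumeration of every gapped alignment (tiny inputs only);
# validates the DP oracle itself. State: next indices and whether the last
# emitted column was a gap in a / in b (for affine accounting).
enumAlignScore <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1L, j + 1L, "m"))
    if (i <= length(av))
      best <- max(best, -(if (last == "x") ext else open + ext) +
                    rec(i + 1L, j, "x"))
    if (j <= length(bv))
      best <- max(best, -(if (last == "y") ext else open + ext) +
                    rec(i, j + 1L, "y"))
    best
  }
  rec(1L, 1L, "m")
}

randomSeq <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE),
                                         collapse = "")
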