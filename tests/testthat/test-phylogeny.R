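test_that("progressive alignment handles the base cases", {
  s <- Biostrings::AAStringSet(c(a = "MKWVTE", b = "MKWVTE"))
  msa <- progressiveMsa(s)
  m <- kinfamscan:::.msaMatrix(msa)
  expect_false(any(m == "-"))              # identical pair: gap-free
  expect_identical(ncol(m), 6L)

  msa1 <- progressiveMsa(Biostrings::AAStringSet(c(x = "MKWV")))
  expect_identical(as.character(kinfamscan:::.msaMatrix(msa1)[1, ]), c("M", "K", "W", "V"))
})

test_that("a deletion yields exactly one gap column (pairwise DP check)", {
  msa <- progressiveMsa(Biostrings::AAStringSet(c(a = "ACD", b = "AD")))
  m <- kinfamscan:::.msaMatrix(msa)
  expect_identical(ncol(m), 3L)
  expect_identical(sum(m == "-"), 1L)
  expect_identical(paste(m["a", ], collapse = ""), "ACD")
  # the pairwise oracle agrees this costs one gap column
  h <- globalAlign("ACD", "AD")
  expect_identical(nchar(h@alignedA), 3L)
})

test_that("alignment rows ungap to the inputs and columns cover the longest", {
  withr::local_seed(21)
  seqs <- vapply(1:6, function(i) randomSeq(sample(20:40, 1),
                                            Biostrings::AA_STANDARD), character(1))
  names(seqs) <- paste0("s", 1:6)
  msa <- progressiveMsa(Biostrings::AAStringSet(seqs))
  m <- kinfamscan:::.msaMatrix(msa)
  expect_gte(ncol(m), max(nchar(seqs)))
  for (id in names(seqs))
    expect_identical(paste(m[id, m[id, ] != "-"], collapse = ""), seqs[[id]])
})

test_that("p-distance follows its definition", {
  m <- rbind(a = c("A", "A", "A", "A"), b = c("A", "A", "A", "T"))
  d <- pDistance(m)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_true(isSymmetric(d))

  m2 <- rbind(a = c("A", "-"), b = c("-", "T"))
  expect_error(pDistance(m2), "share no columns")

  m3 <- rbind(a = c("A", "C", "-"), b = c("A", "T", "G"))
  expect_equal(pDistance(m3)["a", "b"], 0.5)  # pairwise deletion of the gap
})

test_that("neighbor joining: two-taxon edge and three-taxon closed form", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighborJoining(d2)
  expect_equal(sum(t2$edge.length), 1.0)

  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighborJoining(d3)
  # closed form: a = (dAB + dAC - dBC)/2 = 1, b = 1, c = 3
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["A"]], 1, tolerance = 1e-9)
  expect_equal(bl[["B"]], 1, tolerance = 1e-9)
  expect_equal(bl[["C"]], 3, tolerance = 1e-9)

  expect_error(neighborJoining(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least two")
})

test_that("the four-point split is recovered from an additive matrix", {
  # tree ((A,B),(C,D)) with unit branches -> AB|CD
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(d)
  expect_identical(unname(treeBipartitions(tr)), "C|D")
})

test_that("NJ recovers random additive topologies exactly (n <= 8)", {
  skip_if_not_installed("phangorn")
  withr::local_seed(61)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    ref$tip.label <- sprintf("t%02d", seq_len(n))
    d <- cophenetic(ref)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    est <- neighborJoining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(ref), est), 0)
  }
})

test_that("NJ topology agrees with the reference implementation", {
  skip_if_not_installed("phangorn")
  withr::local_seed(77)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    m <- matrix(runif(n * n, 0.05, 1), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("x", 1:n), paste0("x", 1:n))
    expect_equal(phangorn::RF.dist(neighborJoining(d), ape::nj(d)), 0)
  }
})

test_that("leaf permutation yields an isomorphic tree", {
  withr::local_seed(9)
  n <- 7
  m <- matrix(runif(n * n, 0.1, 1), n)
  d <- (m + t(m)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("x", 1:n), paste0("x", 1:n))
  p <- sample(n)
  t1 <- neighborJoining(d)
  t2 <- neighborJoining(d[p, p])
  expect_setequal(unname(treeBipartitions(t1)), unname(treeBipartitions(t2)))
})

test_that("negative branch estimates are clamped to zero", {
  d <- matrix(c(0, 1, 1, 10,
                1, 0, 1, 10,
                1, 1, 0, 1,
                10, 10, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(d)   # wildly non-additive
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap of a constant-signal alignment gives full support", {
  base <- rbind(A = c("A", "C"), B = c("A", "C"), C = c("W", "G"), D = c("W", "G"))
  m <- base[, rep(1:2, 50)]   # every column supports the same AB|CD split
  tr <- bootstrapSupport(m, replicates = 50, seed = 4)
  sup <- attr(tr, "support")
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup == 100))
})

test_that("subfamilies form monophyletic clades in the NJ tree", {
  sd <- smallDataset()
  fam <- familyGenes(sd$truth)
  msa <- progressiveMsa(sd$proteome[fam$gene_id])
  tr <- neighborJoining(pDistance(msa))
  bip <- treeBipartitions(tr)
  asSplit <- function(ids) {
    ref <- sort(fam$gene_id)[1]
    s <- sort(ids)
    if (ref %in% s) s <- sort(setdiff(fam$gene_id, s))
    paste(s, collapse = "|")
  }
  for (sf in c("ZIK", "MEKK", "Raf")) {
    ids <- fam$gene_id[fam$subfamily == sf]
    expect_true(asSplit(ids) %in% bip, label = paste(sf, "monophyly"))
  }
})
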