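test_that("the identity screen passes identical sequences and honours bounds", {
  withr::local_seed(19)
  q <- randomSeq(120, Biostrings::AA_STANDARD)
  cands <- Biostrings::AAStringSet(c(same = q,
                                     other = randomSeq(120, Biostrings::AA_STANDARD)))
  queries <- Biostrings::AAStringSet(c(q1 = q))
  scr <- screenByIdentity(cands, queries)
  expect_equal(scr$best_identity[scr$protein_id == "same"], 1)
  expect_true(scr$passed_identity[scr$protein_id == "same"])

  # threshold 0: everything passes
  scr0 <- screenByIdentity(cands, queries, threshold = 0)
  expect_true(all(scr0$passed_identity))

  expect_identical(nrow(screenByIdentity(Biostrings::AAStringSet(), queries)), 0L)
  expect_error(screenByIdentity(cands, Biostrings::AAStringSet()), "query")
})

test_that("unrelated random proteins do not reach 50% identity", {
  withr::local_seed(42)
  cands <- Biostrings::AAStringSet(setNames(
    replicate(30, randomSeq(300, Biostrings::AA_STANDARD)), sprintf("r%02d", 1:30)))
  queries <- Biostrings::AAStringSet(setNames(
    replicate(3, randomSeq(450, Biostrings::AA_STANDARD)), paste0("q", 1:3)))
  scr <- screenByIdentity(cands, queries)
  expect_identical(sum(scr$passed_identity), 0L)
})

test_that("redundancy removal collapses duplicates and keeps the longest", {
  a <- randomSeq(100, Biostrings::AA_STANDARD)
  x <- Biostrings::AAStringSet(c(p1 = a, p2 = a))
  red <- removeRedundancy(x)
  expect_identical(names(red$kept), "p1")   # tie broken to smallest id
  expect_identical(unname(red$redundant_with["p2"]), "p1")

  withr::local_seed(4)
  y <- Biostrings::AAStringSet(setNames(
    replicate(5, randomSeq(90, Biostrings::AA_STANDARD)), paste0("d", 1:5)))
  red <- removeRedundancy(y)
  expect_length(red$kept, 5L)
  expect_length(red$redundant_with, 0L)
})

test_that("single-linkage chains collapse to one keeper (brute-force check)", {
  withr::local_seed(8)
  base <- randomSeq(200, Biostrings::AA_STANDARD)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(length(v), k)
    v[at] <- vapply(v[at], function(r)
      sample(setdiff(Biostrings::AA_STANDARD, r), 1), character(1))
    paste(v, collapse = "")
  }
  b <- mutate(base, 3)   # ~98.5% to base
  c2 <- mutate(b, 3)     # ~98.5% to b, ~97% to base: chain a-b, b-c
  far <- randomSeq(200, Biostrings::AA_STANDARD)
  x <- Biostrings::AAStringSet(c(a = base, b = b, c = c2, z = far))
  red <- removeRedundancy(x, identity_min = 0.98, coverage_min = 0.98)
  # brute-force linkage oracle over all pairs
  ids <- names(x)
  link <- matrix(FALSE, 4, 4, dimnames = list(ids, ids))
  for (i in 1:3) for (j in (i + 1):4) {
    h <- globalAlign(as.character(x[[i]]), as.character(x[[j]]))
    link[i, j] <- link[j, i] <- h@identity >= 0.98 &&
      h@coverageA >= 0.98 && h@coverageB >= 0.98
  }
  expect_true(link["a", "b"] && link["b", "c"] && !link["a", "c"])
  expect_setequal(names(red$kept), c("a", "z"))
  expect_identical(unname(red$redundant_with[c("b", "c")]), c("a", "a"))
})

test_that("redundancy removal is independent of input order", {
  sd <- smallDataset()
  fam <- familyGenes(sd$truth)
  x <- sd$proteome[fam$gene_id]
  r1 <- removeRedundancy(x)
  r2 <- removeRedundancy(rev(x))
  expect_setequal(names(r1$kept), names(r2$kept))
})

test_that("hallmark validation accepts planted kinases and rejects the rest", {
  sd <- smallDataset()
  fam <- familyGenes(sd$truth)
  marks <- hallmarkPatterns()
  val <- validateHallmarks(sd$proteome[fam$gene_id], marks)
  expect_true(all(val$all_hallmarks))
  expect_false(any(validateHallmarks(
    Biostrings::AAStringSet(c(polyA = strrep("A", 200))), marks)$all_hallmarks))
  expect_error(validateHallmarks(sd$proteome[1], list()), "no hallmarks")
})

test_that("the funnel is monotone in the identity threshold", {
  sd <- smallDataset()
  accepted <- sapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    length(identifyFamily(sd$proteome, sd$queries, threshold = th)$accepted))
  expect_true(all(diff(accepted) <= 0))
})

test_that("on synthetic data the funnel accepts exactly the planted family", {
  sd <- smallDataset()
  idf <- identifyFamily(sd$proteome, sd$queries)
  expect_setequal(names(idf$accepted), familyGenes(sd$truth)$gene_id)
  # near-miss decoys pass the screen but fail hallmark validation
  rep <- idf$report
  dec <- rep[rep$protein_id %in% decoyIds(sd$truth), ]
  expect_false(any(dec$accepted))
})
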