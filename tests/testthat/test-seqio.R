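test_that("FASTA parsing preserves order, wraps lines and keeps descriptions", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), tf)
  x <- readFasta(tf)
  expect_length(x, 1L)
  expect_identical(names(x), "a")
  expect_identical(as.character(x[["a"]]), "ACGT")
  expect_identical(S4Vectors::mcols(x)$description, "")

  writeLines(c(">a", "AC", "GT", ">b x", "TT"), tf)
  x <- readFasta(tf)
  expect_identical(names(x), c("a", "b"))
  expect_identical(as.character(x[["a"]]), "ACGT")
  expect_identical(as.character(x[["b"]]), "TT")
  expect_identical(S4Vectors::mcols(x)$description, c("", "x"))
})

test_that("FASTA invariant violations are errors naming the offender", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TT"), tf)
  expect_error(readFasta(tf), "duplicate id a")
  writeLines(c(">a", "AC1T"), tf)
  expect_error(readFasta(tf), "outside both alphabets")
  writeLines(character(0), tf)
  expect_error(readFasta(tf), "empty|parse")
})

test_that("FASTA alphabet detection and forcing behave sensibly", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGTN"), tf)
  expect_s4_class(readFasta(tf), "DNAStringSet")
  expect_s4_class(readFasta(tf, alphabet = "protein"), "AAStringSet")
  writeLines(c(">a", "MKWLV"), tf)
  expect_s4_class(readFasta(tf), "AAStringSet")
  expect_error(readFasta(tf, alphabet = "dna"), "not a nucleotide")
})

test_that("FASTQ parsing handles records, vacuous input and malformed records", {
  tf <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGT", "+", "IIIIIIIIIIIIIIIIIIII"), tf)
  x <- readFastq(tf)
  expect_identical(names(x), "r1")
  expect_identical(as.character(x[[1]]), "ACGTACGTACGTACGTACGT")

  writeLines(character(0), tf)
  expect_length(readFastq(tf), 0L)

  writeLines(c("@r1", "ACGT", "+", "III"), tf)
  expect_error(readFastq(tf), "record 1.*lengths differ")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "AC"), tf)
  expect_error(readFastq(tf), "truncated FASTQ record 2")
})

test_that("FASTQ round-trips through the writer, including gzip", {
  reads <- Biostrings::DNAStringSet(c(r1 = "ACGTTGCA", r2 = "GGGGCCCC"))
  for (ext in c(".fq", ".fq.gz")) {
    tf <- withr::local_tempfile(fileext = ext)
    writeFastq(reads, tf)
    back <- readFastq(tf)
    expect_identical(as.character(back), as.character(reads))
  }
})

test_that("read/write FASTA is the identity on fuzzed valid records", {
  withr::local_seed(11)
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(Biostrings::AA_STANDARD, sample(5:80, 1), replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- sprintf("s%02d_%d", seq_len(n), rep)
    x <- Biostrings::AAStringSet(seqs)
    S4Vectors::mcols(x)$description <- sample(c("", "some words here"), n,
                                              replace = TRUE)
    tf <- withr::local_tempfile(fileext = ".fa")
    writeFasta(x, tf)
    back <- readFasta(tf, alphabet = "protein")
    expect_identical(as.character(back), as.character(x))
    expect_identical(S4Vectors::mcols(back)$description,
                     S4Vectors::mcols(x)$description)
  }
})

test_that("gene annotations validate their invariants", {
  expect_error(geneAnnotation("g1", "Chr01", 100, 50, "+",
                              rbind(c(100, 120))), "start")
  expect_error(geneAnnotation("g1", "Chr01", 1, 500, "+",
                              rbind(c(10, 100), c(90, 200))), "overlap")
  expect_error(geneAnnotation("g1", "Chr01", 1, 500, "+",
                              rbind(c(200, 300), c(10, 100))), "sorted")
  expect_error(geneAnnotation("g1", "Chr01", 50, 500, "+",
                              rbind(c(10, 100))), "outside")
})

test_that("annotations round-trip through GFF3, with 3 lines for 2 exons", {
  gr <- geneAnnotation("g1", "Chr02", 100, 450, "-",
                       rbind(c(100, 199), c(250, 450)))
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotations(gr, tf)
  body <- grep("^[^#]", readLines(tf), value = TRUE)
  expect_length(body, 3L)
  back <- readAnnotations(tf)
  a <- annotationTable(gr); b <- annotationTable(back)
  expect_identical(b$gene_id, a$gene_id)
  expect_identical(b$start, a$start)
  expect_identical(b$end, a$end)
  expect_identical(b$strand, a$strand)
  expect_identical(b$exon_starts, a$exon_starts)
  expect_identical(b$exon_ends, a$exon_ends)
})

test_that("an empty annotation set writes a header-only file", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotations(GenomicRanges::GRanges(), tf)
  expect_identical(readLines(tf)[1], "##gff-version 3")
  expect_length(readAnnotations(tf), 0L)
})
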