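test_that("FASTA records parse with ids, wrapping and case normalisation", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "ACGT",
               ">s2", "acgtac", "gtACGT"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2L)
  expect_identical(seqs[[1]]$id, "s1")
  expect_identical(seqs[[1]]$residues, "ACGT")
  expect_identical(seqs[[1]]$length, 4L)
  expect_identical(seqs[[2]]$residues, "ACGTACGTACGT")
})

test_that("strict policy rejects ambiguity codes naming record and character", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">bad", "ACGN"), f)
  expect_error(read_fasta(f, "strict"), "bad.*'N'")
})

test_that("skip_invalid drops offending records and reports the count", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "ACGN"), f)
  expect_message(seqs <- read_fasta(f, "skip_invalid"), "skipped 1")
  expect_length(seqs, 0L)
})

test_that("missing and empty inputs raise dedicated errors", {
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_error(read_fasta(f), "no sequences")
})

test_that("sequences shorter than 4 bp are rejected", {
  expect_error(nucleotide_sequence("s", "ACG"), "shorter than 4")
})

write_class_files <- function(dir, enh, non, strong = NULL, weak = NULL) {
  w <- function(name, recs) {
    if (is.null(recs)) return(NULL)
    p <- file.path(dir, name)
    writeLines(unlist(lapply(names(recs), function(id) c(paste0(">", id), recs[[id]]))), p)
    p
  }
  list(enh = w("enh.fa", enh), non = w("non.fa", non),
       strong = w("strong.fa", strong), weak = w("weak.fa", weak))
}

test_that("load_dataset assigns labels by file grouping and reports counts", {
  d <- withr::local_tempdir()
  p <- write_class_files(d,
    enh = list(e1 = "ACGTACGT", e2 = "AACGAACG"),
    non = list(n1 = "TTTTACGT", n2 = "GGGGACGT"))
  expect_message(ds <- load_dataset(p$enh, p$non), "2 enhancers")
  ct <- dataset_counts(ds)
  expect_identical(unname(ct[c("enhancer", "non_enhancer")]), c(2L, 2L))
  expect_true(all(ds$layer2[ds$layer1 == "enhancer"] == "unknown"))
})

test_that("strong/weak sources set layer-2 labels and keep class sums consistent", {
  d <- withr::local_tempdir()
  p <- write_class_files(d,
    enh = list(e1 = "ACGTACGT", e2 = "AACGAACG", e3 = "CCGGCCGG", e4 = "ACACACAC"),
    non = list(n1 = "TTTTACGT"),
    strong = list(e1 = "ACGTACGT", e2 = "AACGAACG"),
    weak = list(e3 = "CCGGCCGG", e4 = "ACACACAC"))
  ds <- suppressMessages(load_dataset(p$enh, p$non, p$strong, p$weak))
  ct <- dataset_counts(ds)
  expect_identical(unname(ct[["enhancer"]]), unname(ct[["strong"]] + ct[["weak"]]))
  expect_identical(unname(ct[c("strong", "weak")]), c(2L, 2L))
})

test_that("an id in both strong and weak sources is a label conflict", {
  d <- withr::local_tempdir()
  p <- write_class_files(d,
    enh = list(e1 = "ACGTACGT", e2 = "AACGAACG"),
    non = list(n1 = "TTTTACGT"),
    strong = list(e1 = "ACGTACGT"),
    weak = list(e1 = "ACGTACGT", e2 = "AACGAACG"))
  expect_error(suppressMessages(load_dataset(p$enh, p$non, p$strong, p$weak)),
               "label conflict")
})

test_that("duplicate ids across enhancer and non-enhancer files are rejected", {
  d <- withr::local_tempdir()
  p <- write_class_files(d,
    enh = list(s1 = "ACGTACGT"),
    non = list(s1 = "TTTTACGT"))
  expect_error(suppressMessages(load_dataset(p$enh, p$non)), "duplicate id")
})

test_that("datasets round-trip through per-class FASTA losslessly", {
  ds <- simulate_dataset(simulation_spec(n_enhancer = 6, n_non_enhancer = 4,
                                         length = 24, effect = 0.6, seed = 9))
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- suppressMessages(load_dataset(
    enhancer_source = NULL,
    non_enhancer_source = file.path(d, "non_enhancers.fasta"),
    strong_source = file.path(d, "strong.fasta"),
    weak_source = file.path(d, "weak.fasta")))
  ord <- match(ds$ids, back$ids)
  expect_false(anyNA(ord))
  expect_identical(vapply(back$sequences[ord], `[[`, "", "residues"),
                   vapply(ds$sequences, `[[`, "", "residues"))
  expect_identical(as.character(back$layer1[ord]), as.character(ds$layer1))
  expect_identical(as.character(back$layer2[ord]), as.character(ds$layer2))
})

test_that("a single FASTA plus TSV label map loads with both layers", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "all.fa")
  writeLines(c(">a", "ACGTACGT", ">b", "AACGAACG", ">c", "TTTTACGT"), fa)
  map <- file.path(d, "labels.tsv")
  writeLines(c("a\tstrong", "b\tweak", "c\tnon_enhancer"), map)
  ds <- load_dataset_map(fa, map)
  expect_identical(as.character(ds$layer1), c("enhancer", "enhancer", "non_enhancer"))
  expect_identical(as.character(ds$layer2)[1:2], c("strong", "weak"))
})

test_that("heterogeneous lengths trigger a warning but still load", {
  expect_warning(
    labeled_dataset(list(nucleotide_sequence("a", "ACGT"),
                         nucleotide_sequence("b", "ACGTACGT")),
                    layer1 = c("enhancer", "non_enhancer")),
    "heterogeneous")
})
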