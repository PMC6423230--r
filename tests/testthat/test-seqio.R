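test_that("FASTA reading validates and normalises input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTAA", ">c", "ACGT-CGTNA"), path)
  aln <- read_alignment(path, "nuclear")
  expect_s3_class(aln, "hyb_alignment")
  expect_equal(dim(aln), c(3L, 10L))
  expect_equal(rownames(aln), c("a", "b", "c"))

  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), path)
  expect_error(read_alignment(path, "nuclear"), "ragged")
  writeLines(character(0), path)
  expect_error(suppressWarnings(read_alignment(path, "nuclear")),
               "empty|unreadable")
})

test_that("unknown characters map to N with a warning", {
  expect_warning(
    aln <- alignment(matrix(c("A", "C", "R", "T"), 2, 2,
                            dimnames = list(c("a", "b"), NULL)), "L1"),
    "mapped to N")
  expect_equal(unname(unclass(aln)[1, 2]), "N")
})

test_that("write/read round trip is lossless", {
  aln <- aln_from_strings(c(x1 = "ACGTAC-TNA", x2 = "ACGTACGTAA", x3 = "AAGTACGTAA"),
                          locus = "rt")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path, "nuclear", locus_id = "rt")
  expect_identical(unclass(back), unclass(aln))
  expect_identical(attr(back, "locus_id"), "rt")
})

test_that("haplotype collapsing counts and members are exact", {
  a <- aln_from_strings(rep("ACGT", 5))
  h <- collapse_haplotypes(a)
  expect_equal(nrow(h$haplotypes), 1L)
  expect_equal(h$haplotypes$count, 5L)

  b <- aln_from_strings(c("AAAA", "AAAT", "AATT", "ATTT"))
  expect_equal(collapse_haplotypes(b)$haplotypes$count, rep(1L, 4))

  c3 <- aln_from_strings(c(s1 = "AAA", s2 = "AAT", s3 = "AAA"))
  h3 <- collapse_haplotypes(c3)
  expect_equal(h3$haplotypes$haplotype_id, c("H1", "H2"))
  expect_equal(h3$haplotypes$count, c(2L, 1L))
  expect_setequal(h3$members[["H1"]], c("s1", "s3"))
})

test_that("haplotype counts always sum to the row count", {
  set.seed(1)
  for (r in 1:20) {
    n <- sample(2:12, 1)
    m <- matrix(sample(c("A", "C"), n * 6, replace = TRUE), n, 6)
    rownames(m) <- paste0("s", seq_len(n))
    h <- collapse_haplotypes(alignment(m, "x"))
    expect_equal(sum(h$haplotypes$count), n)
    expect_lte(nrow(h$haplotypes), n)
  }
})

test_that("concatenation is additive, order-preserving, and N-fills", {
  mk <- function(id, len, keys) {
    m <- matrix("A", length(keys), len, dimnames = list(keys, NULL))
    alignment(m, id, "chloroplast")
  }
  keys <- c("i1", "i2")
  samples <- sample_table(data.frame(individual_id = keys, taxon = "t",
                                     population = "p"))
  ds <- multilocus_dataset(list(mk("a", 3, keys), mk("b", 4, keys)), samples)
  cc <- concatenate_loci(ds, "chloroplast")
  expect_equal(ncol(cc), 7L)
  expect_equal(rownames(cc), keys)

  one <- multilocus_dataset(list(mk("a", 5, keys)), samples)
  expect_equal(unclass(concatenate_loci(one, "chloroplast")),
               unclass(mk("a", 5, keys)), ignore_attr = TRUE)

  # missing individual at locus 2: N-fill occupies positions 5..10 (0-based
  # half-open) of the concatenated sequence
  keys3 <- c("i1", "i2", "i3")
  samples3 <- sample_table(data.frame(individual_id = keys3, taxon = "t",
                                      population = "p"))
  ds3 <- multilocus_dataset(
    list(mk("a", 5, keys3), mk("b", 6, keys3[1:2]), mk("c", 7, keys3)), samples3)
  expect_error(concatenate_loci(ds3, "chloroplast"), "missing from locus b")
  cc3 <- concatenate_loci(ds3, "chloroplast", fill_missing = TRUE)
  expect_equal(unname(unclass(cc3)["i3", 6:11]), rep("N", 6))
  expect_equal(unname(unclass(cc3)["i3", c(1:5, 12:18)]), rep("A", 12))
  expect_equal(unname(attr(cc3, "boundaries")["b", ]), c(5L, 11L))
})

test_that("simple indel coding follows the containment rule", {
  none <- aln_from_strings(c("ACGT", "ACGT", "ACCT"))
  expect_equal(ncol(code_indels(none)), 0L)

  # two of four sequences share a gap spanning columns 5-7 (1-based)
  shared <- aln_from_strings(c(a = "ACGT---ACG", b = "ACGT---ACG",
                               c = "ACGTAAAACG", d = "ACGTCAAACG"))
  ci <- code_indels(shared)
  expect_equal(ncol(ci), 1L)
  expect_equal(unname(ci[, 1]), c(1L, 1L, 0L, 0L))

  # a strictly containing gap scores missing for the shorter character
  contain <- aln_from_strings(c(a = "ACGT---ACG", b = "AC-------G",
                                c = "ACGTAAAACG"))
  ci2 <- code_indels(contain)
  expect_equal(ncol(ci2), 2L)
  short <- ci2[, "g5-7"]
  expect_equal(unname(short), c(1L, NA_integer_, 0L))
  expect_equal(unname(ci2[, "g3-9"]), c(0L, 1L, 0L))
})

test_that("indel coding is invariant to row order", {
  x <- c(a = "AC--TT", b = "ACGGTT", c = "A----T", d = "ACG-TT")
  c1 <- code_indels(aln_from_strings(x))
  c2 <- code_indels(aln_from_strings(x[c(3, 1, 4, 2)]))
  expect_identical(c1[rownames(c2), colnames(c2)], c2)
})

test_that("sample tables and datasets are validated", {
  df <- data.frame(individual_id = c("a", "a"), taxon = "t", population = "p")
  expect_error(sample_table(df), "duplicated")
  df2 <- data.frame(individual_id = "a", taxon = "t", population = "p",
                    role = "nonsense")
  expect_error(sample_table(df2), "unknown role")
  aln <- aln_from_strings(c(`a/1` = "ACGT", `a/2` = "ACGT", `b/1` = "ACGT"))
  samples <- sample_table(data.frame(individual_id = c("a", "b"),
                                     taxon = "t", population = "p"))
  expect_error(multilocus_dataset(list(aln), samples), "must have 2 row")
})
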