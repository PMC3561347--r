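test_that("property table has the published constants and centered columns", {
  kt <- kideraTable()
  expect_identical(dim(kt), c(20L, 9L))
  expect_identical(rownames(kt), aminoAcids())
  expect_equal(kt["A", "P1"], -1.44)
  expect_equal(kt["V", "P9"], -1.32)
  expect_equal(unname(kt["G", ]),
               c(-2.16, -1.02, -0.19, -0.03, -0.84, -0.99, -1.72, 1.43, 1.73))
  ## scales are centered over the 20 residues; P1 sums to zero exactly at
  ## the printed precision
  expect_lt(max(abs(colSums(kt))), 0.2)
  expect_equal(sum(kt[, "P1"]), 0, tolerance = 1e-12)
})

test_that("site profiles average canonical residues and skip gaps", {
  kt <- kideraTable()
  expect_equal(unname(siteProfile(c("G", "G", "G"))), unname(kt["G", ]))
  expect_equal(siteProfile(c("A", "V"))[["P1"]], (-1.44 + -0.34) / 2)
  expect_equal(unname(siteProfile(c("A", "-", "A"))), unname(kt["A", ]))
  expect_equal(unname(siteProfile(c("A", "X", "B", "A"))), unname(kt["A", ]))
  expect_error(siteProfile(c("-", "-")), "all-gap")
  expect_error(siteProfile(c("A", "*")), "stop symbol")
  expect_error(siteProfile(character(0)), "non-empty")
})

test_that("profile matrix has one mean row per column and validates input", {
  msa <- c(s1 = "ARNDC", s2 = "ARNDC", s3 = "AVND-")
  sp <- profileMatrix(msa)
  expect_identical(dim(profiles(sp)), c(5L, 9L))
  expect_identical(siteIds(sp), 1:5)
  expect_identical(sp@nSeqUsed, c(3L, 3L, 3L, 3L, 2L))
  ## column 1 is pure A
  expect_equal(unname(profiles(sp)[1, ]), unname(kideraTable()["A", ]))
  ## single-sequence alignment reproduces the residues' table rows
  one <- profileMatrix(c(x = "GWA"))
  expect_equal(unname(profiles(one)),
               unname(kideraTable()[c("G", "W", "A"), ]))
  expect_error(profileMatrix(c(a = "ARN", b = "AR")), "ragged")
  expect_error(profileMatrix(c(a = "A-N", b = "A-N")), "all-gap column")
})

test_that("profiles are permutation-invariant and inside the residue envelope", {
  set.seed(3)
  aa <- aminoAcids()
  m <- matrix(sample(c(aa, "-"), 20 * 30, replace = TRUE), 20, 30)
  rownames(m) <- paste0("t", 1:20)
  m[, colSums(matrix(m %in% aa, 20)) == 0] <- "A"  # no all-gap columns
  p1 <- profiles(profileMatrix(m))
  p2 <- profiles(profileMatrix(m[sample(20), ]))
  expect_equal(p1, p2)
  kt <- kideraTable()
  lo <- apply(kt, 2, min); hi <- apply(kt, 2, max)
  expect_true(all(sweep(p1, 2, lo, ">=") & sweep(p1, 2, hi, "<=")))
})

test_that("profile TSV round-trips to at least six decimals", {
  sp <- profileMatrix(c(a = "ARNDCQ", b = "GHILKM", c = "FPSTWY"))
  path <- tempfile(fileext = ".tsv")
  writeProfiles(sp, path)
  back <- readProfiles(path)
  expect_equal(profiles(back), profiles(sp), tolerance = 1e-7)
  expect_identical(siteIds(back), siteIds(sp))
})
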