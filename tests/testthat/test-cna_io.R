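test_that("write/read round-trips a CNA matrix in both file orientations", {
  set.seed(11)
  vals <- matrix(sample(-2:2, 24, replace = TRUE), 4, 6,
                 dimnames = list(sprintf("s%d", 1:4), sprintf("g%d", 1:6)))
  m <- cna_matrix(vals)
  for (orient in c("genes_as_rows", "samples_as_rows")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_cna_matrix(m, path, orientation = orient)
    back <- read_cna_matrix(path, orientation = orient)
    expect_identical(back$values, m$values)
  }
})

test_that("a genes-as-rows file and its transposed twin parse identically", {
  set.seed(12)
  vals <- matrix(sample(-2:2, 30, replace = TRUE), 5, 6,
                 dimnames = list(sprintf("s%d", 1:5), sprintf("g%d", 1:6)))
  m <- cna_matrix(vals)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_cna_matrix(m, p1, orientation = "genes_as_rows")
  write_cna_matrix(m, p2, orientation = "samples_as_rows")
  expect_identical(read_cna_matrix(p1, "genes_as_rows")$values,
                   read_cna_matrix(p2, "samples_as_rows")$values)
})

test_that("annotation columns are dropped and malformed files are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene Symbol\tLocus ID\tCytoband\tS1\tS2",
               "TP53\t7157\t17p13.1\t-1\t0",
               "MYC\t4609\t8q24.21\t2\t1",
               "EGFR\t1956\t7p11.2\t0\t-2"), path)
  m <- read_cna_matrix(path, "genes_as_rows")
  expect_equal(dim(m), c(2L, 3L))
  expect_setequal(colnames(m$values), c("TP53", "MYC", "EGFR"))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene Symbol\tS1", "TP53\t1", "TP53\t0"), dup)
  expect_error(read_cna_matrix(dup, "genes_as_rows"), "TP53")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene Symbol\tS1\tS2", "TP53\t1\tNAvalue"), bad)
  expect_error(read_cna_matrix(bad, "genes_as_rows"), "S2")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Gene Symbol\tS1", empty)
  expect_error(read_cna_matrix(empty, "genes_as_rows"), "empty")
})

test_that("cna_matrix enforces its invariants", {
  v <- matrix(0L, 2, 2, dimnames = list(c("a", "a"), c("g1", "g2")))
  expect_error(cna_matrix(v), "duplicate sample")
  v2 <- matrix(c(0, 0.5, 1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(cna_matrix(v2), "integer")
  v3 <- matrix(c(0L, 3L, -1L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_warning(cna_matrix(v3), "outside")
  v4 <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(cna_matrix(v4, labels = c(a = "x")), "missing")
})

test_that("read_labels handles headers, duplicates and conflicts", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tclass", "s1\tBRCA", "s2\tOV", "s3\tBRCA",
               "s4\tOV", "s5\tOV", "s6\tBRCA"), p)
  labs <- suppressMessages(read_labels(p))
  expect_length(labs, 6)
  expect_setequal(unique(labs), c("BRCA", "OV"))

  pd <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tBRCA", "s1\tBRCA", "s2\tOV"), pd)
  expect_warning(labs2 <- suppressMessages(read_labels(pd)), "deduplicated")
  expect_length(labs2, 2)

  pc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tBRCA", "s1\tOV"), pc)
  expect_error(suppressMessages(read_labels(pc)), "conflicting.*s1")
})

test_that("harmonize intersects genes, removes shared samples, and is idempotent", {
  mk <- function(samples, genes, seed) {
    set.seed(seed)
    cna_matrix(matrix(sample(-2:2, length(samples) * length(genes), TRUE),
                      length(samples), length(genes),
                      dimnames = list(samples, genes)))
  }
  train <- mk(c("t1", "t2", "t3"), c("A", "B", "C"), 1)
  test <- mk(c("t2", "u1", "u2"), c("B", "C", "D"), 2)
  h <- suppressMessages(harmonize(train, test))
  expect_identical(colnames(h$train$values), c("B", "C"))
  expect_identical(colnames(h$test$values), c("B", "C"))
  expect_false("t2" %in% rownames(h$test$values))

  h2 <- suppressMessages(harmonize(h$train, h$test))
  expect_identical(h2$train$values, h$train$values)
  expect_identical(h2$test$values, h$test$values)

  disjoint <- mk(c("x1", "x2"), c("E", "F"), 3)
  expect_error(suppressMessages(harmonize(train, disjoint)), "no genes shared")
})

test_that("max-abs scaling maps to [-1, 1] and is exactly reversible", {
  vals <- matrix(c(-2L, -1L, 0L, 1L, -2L, 2L), 2, 3,
                 dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  m <- cna_matrix(vals)
  s <- scale_cna(m)
  expect_equal(s$scale_divisor, 2)
  expect_equal(max(abs(s$values)), 1)
  expect_identical(s$values * s$scale_divisor, vals * 1.0)  # power-of-two exact

  # hand-derived: values {-2,-1,0,1} with |x|max = 2 scale to {-1,-0.5,0,0.5}
  m2 <- cna_matrix(matrix(c(-2L, -1L, 0L, 1L), 1, 4,
                          dimnames = list("s", sprintf("g%d", 1:4))))
  expect_equal(as.vector(scale_cna(m2)$values), c(-1, -0.5, 0, 0.5))

  zero <- cna_matrix(matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("g1", "g2"))))
  expect_error(scale_cna(zero), "zero")
  expect_equal(as.vector(scale_cna(zero, "fixed", divisor = 2)$values), rep(0, 4))

  # divisor fitted on train is reapplied unchanged to held-out data
  s3 <- apply_scaling(m2, s$scale_divisor)
  expect_equal(s3$scale_divisor, s$scale_divisor)
  expect_true(all(abs(s3$values) <= 1))
})
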