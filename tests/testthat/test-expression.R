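test_that("expression files are read back exactly and validated", {
  path <- write_tsv_fixture(c(
    "feature\tS1\tS2\tS3\tS4",
    "miR-a\t1\t2\t3\t4",
    "miR-b\t0.5\t-1.25\t2\t0",
    "miR-c\t-3\t0\t1\t7"))
  x <- read_expression(path, kind = "mirna")
  expect_equal(n_features(x), 3)
  expect_equal(n_samples(x), 4)
  expect_identical(feature_ids(x), c("miR-a", "miR-b", "miR-c"))
  expect_identical(unname(x$kind), rep("mirna", 3))
  expect_equal(x$values["miR-b", "S2"], -1.25)

  # write -> read round trip is exact for finite decimal inputs
  out <- tempfile(fileext = ".tsv")
  write_expression(x, out)
  expect_identical(read_expression(out, kind = "mirna")$values, x$values)
})

test_that("malformed expression files are rejected with informative errors", {
  dup <- write_tsv_fixture(c("feature\tS1\tS2\tS3",
                             "g1\t1\t2\t3", "g1\t4\t5\t6"))
  expect_error(read_expression(dup, "mrna"), "duplicate feature id")

  nonnum <- write_tsv_fixture(c("feature\tS1\tS2\tS3",
                                "g1\t1\tx\t3"))
  expect_error(read_expression(nonnum, "mrna"), "non-numeric.*g1.*S2")

  missing <- write_tsv_fixture(c("feature\tS1\tS2\tS3",
                                 "g1\t1\tNA\t3"))
  expect_error(read_expression(missing, "mrna"), "missing value.*g1.*S2")
  # mean imputation fills the gap when asked for
  x <- read_expression(missing, "mrna", impute = TRUE)
  expect_equal(unname(x$values["g1", "S2"]), 2)

  ragged <- write_tsv_fixture(c("feature\tS1\tS2\tS3",
                                "g1\t1\t2\t3", "g2\t1\t2"))
  expect_error(read_expression(ragged, "mrna"), "line 3")
})

test_that("integration aligns shared samples with miRNA rows first", {
  mir <- make_expr(matrix(1:8, 2, 4,
                          dimnames = list(c("miR-1", "miR-2"),
                                          c("S1", "S2", "S3", "S4"))),
                   kind = rep("mirna", 2))
  # mRNA samples deliberately shuffled
  mr_vals <- matrix(101:112, 3, 4,
                    dimnames = list(c("gA", "gB", "gC"),
                                    c("S4", "S3", "S2", "S1")))
  mr <- make_expr(mr_vals, kind = rep("mrna", 3))
  x <- integrate_expression(mir, mr)
  expect_equal(dim(x$values), c(5L, 4L))
  expect_identical(feature_ids(x), c("miR-1", "miR-2", "gA", "gB", "gC"))
  expect_identical(sample_ids(x), c("S1", "S2", "S3", "S4"))
  expect_equal(unname(x$values["gA", "S4"]), 101)  # column realigned
  expect_identical(unname(x$kind),
                   c("mirna", "mirna", "mrna", "mrna", "mrna"))

  # invariant to input column order
  mr2 <- make_expr(mr_vals[, c("S1", "S2", "S3", "S4")],
                   kind = rep("mrna", 3))
  expect_identical(integrate_expression(mir, mr2)$values, x$values)
})

test_that("integration rejects disjoint samples and id collisions", {
  a <- make_expr(matrix(1:4, 2, 2, dimnames = list(c("m1", "m2"),
                                                   c("S1", "S2"))),
                 kind = rep("mirna", 2))
  b <- make_expr(matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("T1", "T2"))),
                 kind = rep("mrna", 2))
  expect_error(integrate_expression(a, b), "share no sample")

  clash <- make_expr(matrix(1:4, 2, 2, dimnames = list(c("m1", "g9"),
                                                       c("S1", "S2"))),
                     kind = rep("mrna", 2))
  expect_error(integrate_expression(a, clash), "present in both.*m1")
})

test_that("standardization z-scores rows and is idempotent", {
  x <- make_expr(rbind(c(1, 2, 3), c(10, 30, 20)))
  z <- standardize_expression(x)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(z$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z$values, 1, sd)), c(1, 1), tolerance = 1e-12)
  z2 <- standardize_expression(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-9)

  const <- make_expr(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_error(standardize_expression(const), "constant feature.*f02")
})

test_that("ground-truth tables deduplicate and support lookups", {
  path <- write_tsv_fixture(c("miR-1\tGENE1", "miR-1\tGENE2",
                              "miR-1\tGENE1",  # duplicate pair
                              "miR-2\tGENE3", "miR-3\tGENE1"))
  gt <- read_ground_truth(path)
  expect_equal(attr(gt, "n_pairs"), 4L)
  expect_equal(attr(gt, "n_mirnas"), 3L)
  expect_setequal(targets_of(gt, "miR-1"), c("GENE1", "GENE2"))
  expect_identical(targets_of(gt, "miR-99"), character(0))

  empty <- write_tsv_fixture(character(0))
  expect_warning(gt0 <- read_ground_truth(empty), "empty")
  expect_equal(attr(gt0, "n_pairs"), 0L)

  bad <- write_tsv_fixture(c("miR-1\tGENE1\textra"))
  expect_error(read_ground_truth(bad), "line 1.*3 columns")

  # round trip through the writer
  out <- tempfile()
  write_ground_truth(gt, out)
  gt2 <- read_ground_truth(out)
  expect_equal(attr(gt2, "n_pairs"), 4L)
  expect_setequal(targets_of(gt2, "miR-1"), targets_of(gt, "miR-1"))
})
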