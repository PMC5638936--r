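test_that("construction validates invariants", {
  X <- matrix(1:6, 3, 2)
  expect_s3_class(survival_dataset(X, c(1, 2, 3), c(1, 0, 1)),
                  "survival_dataset")
  expect_error(survival_dataset(X, c(0, 2, 3), c(1, 0, 1)),
               class = "spaft_validation_error")
  expect_error(survival_dataset(X, c(1, 2, 3), c(1, 2, 1)),
               class = "spaft_validation_error")
  expect_error(survival_dataset(X, c(1, 2), c(1, 0)),
               class = "spaft_validation_error")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(survival_dataset(Xna, c(1, 2, 3), c(1, 0, 1)),
               class = "spaft_validation_error")
})

test_that("read_dataset parses a hand-written fixture, both separators", {
  for (sep in c("\t", ",")) {
    ef <- withr::local_tempfile(fileext = ".tsv")
    sf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(paste(c("sample_id", "gA", "gB"), collapse = sep),
                 paste(c("s1", "1.5", "2"), collapse = sep),
                 paste(c("s2", "0", "-1"), collapse = sep),
                 paste(c("s3", "3", "4.25"), collapse = sep)), ef)
    writeLines(c(paste(c("sample_id", "time", "status"), collapse = sep),
                 paste(c("s3", "5", "1"), collapse = sep),
                 paste(c("s1", "2", "0"), collapse = sep),
                 paste(c("s2", "1", "1"), collapse = sep)), sf)
    d <- read_dataset(ef, sf)
    expect_equal(dim(d), c(3L, 2L))
    # survival file order governs row order
    expect_equal(d$sample_ids, c("s3", "s1", "s2"))
    expect_equal(d$X["s1", "gA"], 1.5)
    expect_equal(d$time, c(5, 2, 1))
  }
})

test_that("read_dataset rejects bad inputs with named offenders", {
  ef <- withr::local_tempfile(); sf <- withr::local_tempfile()
  writeLines(c("sample_id\tgA", "s1\t1", "s2\t2"), ef)
  writeLines(c("sample_id\ttime\tstatus", "sX\t1\t1", "s2\t2\t0"), sf)
  expect_error(read_dataset(ef, sf), "sX",
               class = "spaft_validation_error")
  writeLines(c("sample_id\ttime\tstatus", "s1\t0\t1", "s2\t2\t0"), sf)
  expect_error(read_dataset(ef, sf), class = "spaft_validation_error")
  writeLines(c("sample_id\ttime\tstatus", "s1\t1\tcensored", "s2\t2\t0"), sf)
  expect_error(read_dataset(ef, sf), class = "spaft_validation_error")
  expect_error(read_dataset("/nonexistent/x.tsv", sf),
               class = "spaft_validation_error")
})

test_that("write/read round trip is exact on a random fixture", {
  set.seed(42)
  d <- make_toy_surv(n = 10, p = 20, seed = 42)
  ef <- withr::local_tempfile(); sf <- withr::local_tempfile()
  write_dataset(d, ef, sf)
  d2 <- read_dataset(ef, sf)
  expect_identical(unname(d2$X), unname(d$X))
  expect_identical(d2$time, d$time)
  expect_identical(d2$status, d$status)
})

test_that("genes-as-rows transposition works", {
  ef <- withr::local_tempfile(); sf <- withr::local_tempfile()
  writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gB\t3\t4"), ef)
  writeLines(c("sample_id\ttime\tstatus", "s1\t1\t1", "s2\t2\t0"), sf)
  d <- read_dataset(ef, sf, genes_as_rows = TRUE)
  expect_equal(unname(d$X), matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(d$gene_ids, c("gA", "gB"))
})

test_that("standardize centers/scales, is idempotent and invertible", {
  d <- survival_dataset(cbind(g1 = c(1, 2, 3), g2 = c(2, 4, 9)),
                        c(1, 2, 3), c(1, 1, 1))
  s <- standardize(d)
  expect_equal(unname(colMeans(s$data$X)), c(0, 0))
  expect_equal(unname(apply(s$data$X, 2, sd)), c(1, 1))
  s2 <- standardize(s$data)
  expect_lt(max(abs(s2$data$X - s$data$X)), 1e-12)

  set.seed(7)
  d <- make_toy_surv(n = 20, p = 50, seed = 7)
  s <- standardize(d)
  back <- unstandardize(s$data, s$record)
  expect_lt(max(abs(back$X - d$X)), 1e-10)
  # applying the record to new data matches the training transform
  expect_equal(apply_standardization(d$X, s$record), s$data$X)
})

test_that("zero-variance genes are dropped with warning; all-constant errors", {
  X <- cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  d <- survival_dataset(X, 1:3, c(1, 1, 1))
  expect_warning(s <- standardize(d), "zero-variance")
  expect_equal(s$data$gene_ids, "g1")
  dc <- survival_dataset(cbind(g1 = c(2, 2, 2)), 1:3, c(1, 1, 1))
  expect_error(suppressWarnings(standardize(dc)),
               class = "spaft_validation_error")
})

test_that("split_train_test partitions deterministically and exhaustively", {
  d <- make_toy_surv(n = 250, p = 2, seed = 1)
  sp <- split_train_test(d, 200, seed = 9)
  expect_equal(nrow(sp$train$X), 200)
  expect_equal(nrow(sp$test$X), 50)
  sp2 <- split_train_test(d, 200, seed = 9)
  expect_identical(sp$train$sample_ids, sp2$train$sample_ids)
  expect_error(split_train_test(d, 0, 1), class = "spaft_validation_error")
  expect_error(split_train_test(d, 250, 1), class = "spaft_validation_error")
  d2 <- make_toy_surv(n = 23, p = 2, seed = 2)
  for (s in 1:100) {
    sp <- split_train_test(d2, 11, seed = s)
    ids <- c(sp$train$sample_ids, sp$test$sample_ids)
    expect_setequal(ids, d2$sample_ids)
    expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  }
})
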