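printed_table2 <- data.frame(
  code = c("SOM", "ANX", "EMO", "CON", "GUI", "TEN", "MAN", "GRA", "DEP",
           "HOS", "SUS", "HAL", "MOT", "UNC", "THO", "BLU", "EXC", "DIS"),
  mean = c(1.8, 2.1, 2.5, 2.4, 1.5, 2.0, 1.5, 1.5, 1.8, 1.9, 2.4, 2.6, 1.7,
           1.9, 2.5, 2.3, 1.6, 1.4),
  sd = c(1.2, 1.2, 1.5, 1.5, 0.9, 1.1, 1.0, 1.0, 1.1, 1.3, 1.5, 1.6, 1.2,
         1.2, 1.6, 1.4, 1.2, 0.8)
)

test_that("CSV round trip preserves the response matrix", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(A = c(1L, 7L, 3L), B = c(2L, 5L, 6L))
  write.csv(df, f, row.names = FALSE)
  cat2 <- make_test_catalog(2, 1, codes = c("A", "B"))
  m <- load_responses(f, cat2)
  expect_identical(dim(m), c(3L, 2L))
  expect_equal(unname(unclass(m)), unname(as.matrix(df)),
               ignore_attr = TRUE)

  # column order in the file is irrelevant; catalog order wins
  write.csv(df[, c("B", "A")], f, row.names = FALSE)
  m2 <- load_responses(f, cat2)
  expect_identical(unclass(m2), unclass(m))
})

test_that("invalid cells are rejected or dropped per policy", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(A = c(1L, 8L, 3L), B = c(2L, 2L, 2L)), f,
            row.names = FALSE)
  cat2 <- make_test_catalog(2, 1, codes = c("A", "B"))
  expect_error(load_responses(f, cat2), "row 2, column A")
  expect_message(m <- load_responses(f, cat2, policy = "drop-row"),
                 "dropped 1")
  expect_identical(nrow(m), 2L)
  expect_identical(attr(m, "dropped_rows"), 1L)

  write.csv(data.frame(A = c(1, 2.5), B = c(2, 2), C = c(1, 1)), f,
            row.names = FALSE)
  expect_error(load_responses(f, cat2), "unknown column.*C")
  write.csv(data.frame(A = c(1, 2.5), B = c(2, 2)), f, row.names = FALSE)
  expect_error(load_responses(f, cat2), "non-integer cell at row 2, column A")
  write.csv(data.frame(A = 1:2), f, row.names = FALSE)
  expect_error(load_responses(f, cat2), "missing column.*B")
})

test_that("item summary reproduces the reference frequency table", {
  counts <- bprs_reference_counts()
  s <- summarize_items(counts)
  # counts sum to n for every item and percentages to ~100
  expect_true(all(rowSums(counts) == 1438L))
  pct <- as.matrix(s[, grep("^pct_", names(s))])
  expect_true(all(abs(rowSums(pct) - 100) <= 0.3))
  # every SD at 1 decimal; all means except the internally inconsistent
  # DIS row of the source table (its counts imply 1.3)
  expect_equal(round_half_up(s$sd, 1), printed_table2$sd)
  keep <- s$code != "DIS"
  expect_equal(round_half_up(s$mean[keep], 1), printed_table2$mean[keep])
  expect_equal(round_half_up(s$mean[s$code == "DIS"], 1), 1.3)
})

test_that("summary agrees between raw responses and tabulated counts", {
  set.seed(8)
  x <- ordinal_matrix(matrix(sample(1:7, 600, TRUE), 100, 6), K = 7)
  s_raw <- summarize_items(x)
  counts <- as.matrix(s_raw[, paste0("count_", 1:7)])
  rownames(counts) <- s_raw$code
  s_tab <- summarize_items(counts)
  expect_equal(s_raw$mean, s_tab$mean)
  expect_equal(s_raw$sd, s_tab$sd)
})

test_that("degenerate one-category item has mean 1 and SD 0", {
  s <- summarize_items(rbind(A = c(25, 0, 0, 0, 0, 0, 0),
                             B = c(10, 15, 0, 0, 0, 0, 0)))
  expect_equal(s$mean[1], 1)
  expect_equal(s$sd[1], 0)
})

test_that("summary write/reload round trip is idempotent", {
  s <- summarize_items(bprs_reference_counts())
  f <- tempfile(fileext = ".tsv")
  write_item_summary(s, f)
  back <- read_item_summary(f)
  expect_equal(back$mean, round_half_up(s$mean, 1))
  expect_equal(back$sd, round_half_up(s$sd, 1))
  expect_equal(as.matrix(back[, paste0("count_", 1:7)]),
               as.matrix(s[, paste0("count_", 1:7)]),
               ignore_attr = TRUE)
  f2 <- tempfile(fileext = ".tsv")
  counts <- as.matrix(back[, paste0("count_", 1:7)])
  rownames(counts) <- back$item
  write_item_summary(summarize_items(counts), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("high-dose flag applies inclusive thresholds on either criterion", {
  expect_true(flag_high_dose(1000, 0.5))
  expect_false(flag_high_dose(999, 1.49))
  expect_true(flag_high_dose(0, 1.5))
  expect_equal(flag_high_dose(c(1200, 10), c(0.1, 0.2)), c(TRUE, FALSE))
  expect_error(flag_high_dose(-1, 0.5), "nonnegative")
})

test_that("packaged catalog has the 8/10 group split and survives JSON", {
  cat <- bprs_catalog()
  expect_identical(nrow(cat), 18L)
  expect_identical(sum(cat$group == "DSM"), 8L)
  expect_identical(sum(cat$group == "non-DSM"), 10L)
  expect_setequal(cat$code[cat$group == "DSM"],
                  c("EMO", "CON", "MAN", "SUS", "HAL", "MOT", "THO", "BLU"))
  shipped <- read_item_catalog(system.file("extdata", "bprs_catalog.json",
                                           package = "bprsnet"))
  expect_equal(as.data.frame(shipped), as.data.frame(cat))
  f <- tempfile(fileext = ".json")
  write_item_catalog(cat, f)
  expect_equal(as.data.frame(read_item_catalog(f)), as.data.frame(cat))
})

test_that("a full-size generated cohort loads back with its shape intact", {
  ds <- sample_ordinal(make_truth_network(seed = 1), 1438, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_synthetic_csv(ds, f)
  m <- load_responses(f)
  expect_identical(dim(m), c(1438L, 18L))
  expect_equal(unclass(m), unclass(ds$data), ignore_attr = TRUE)
})
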