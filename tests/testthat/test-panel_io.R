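test_that("read_panel round-trips a complete long-format table", {
  p <- toy_panel(3, 52)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- read_panel(f, treated_id = "b1")
  expect_identical(dim(p2$sales), c(3L, 52L))
  expect_equal(p2$sales, p$sales)
  expect_identical(p2$treated_id, "b1")
  expect_length(p2$incomplete_brands, 0)
})

test_that("read_panel validates schema, duplicates, and values", {
  p <- toy_panel(3, 10)
  long <- toy_long(p)
  f <- withr::local_tempfile(fileext = ".csv")

  # custom column names via schema mapping
  renamed <- setNames(long, c("brand_desc", "wk", "eq_units"))
  write.csv(renamed, f, row.names = FALSE)
  p2 <- read_panel(f, treated_id = "b1",
                   schema = list(brand = "brand_desc", week = "wk",
                                 sales = "eq_units"))
  expect_equal(p2$sales, p$sales)
  expect_error(read_panel(f, treated_id = "b1"), "schema error")

  # duplicated (brand, week) cell
  write.csv(rbind(long, long[long$brand == "b1" & long$week == 7, ]),
            f, row.names = FALSE)
  expect_error(read_panel(f, treated_id = "b1"), "integrity error")

  # negative sales
  bad <- long; bad$sales[3] <- -5
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_panel(f, treated_id = "b1"), "value error")
})

test_that("missing weeks flag a brand incomplete; filter_brands drops it", {
  p <- toy_panel(4, 52)
  long <- toy_long(p)
  long <- long[!(long$brand == "b3" & long$week == 20), ]   # 51 of 52 weeks
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, f, row.names = FALSE)
  p2 <- read_panel(f, treated_id = "b1")
  expect_identical(p2$incomplete_brands, "b3")
  expect_true(anyNA(p2$sales["b3", ]))          # never imputed
  p3 <- suppressMessages(filter_brands(p2))
  expect_false("b3" %in% p3$brand_ids)
  expect_length(p3$incomplete_brands, 0)
})

test_that("aggregate_subbrands sums constituents and conserves totals", {
  m <- matrix(10, 5, 4,
              dimnames = list(c("s1", "s2", "s3", "s4", "other"), NULL))
  p <- sales_panel(m, treated_id = "s1")
  mapping <- c(s1 = "major", s2 = "major", s3 = "major", s4 = "major")
  agg <- aggregate_subbrands(p, mapping)
  expect_equal(unname(agg$sales["major", 1]), 40)
  expect_identical(agg$treated_id, "major")
  expect_equal(colSums(agg$sales), colSums(p$sales))  # weekly conservation

  # identity mapping leaves the panel unchanged
  id <- aggregate_subbrands(p, character())
  expect_equal(id$sales, p$sales)
  expect_identical(id$treated_id, "s1")
})

test_that("aggregate_subbrands rejects donor contamination of the treated unit", {
  # "major" is an existing stand-alone donor; mapping the treated sub-brand
  # onto that label would silently merge a pure donor into the treated unit
  m <- matrix(1, 3, 4, dimnames = list(c("esco_a", "esco_b", "major"), NULL))
  p <- sales_panel(m, treated_id = "esco_a")
  expect_error(
    aggregate_subbrands(p, c(esco_a = "major", esco_b = "major")),
    "configuration error")
})

test_that("filter_brands applies exclusions, logs shares, is idempotent", {
  set.seed(3)
  m <- matrix(runif(4 * 12, 1000, 2000), 4, 12,
              dimnames = list(c("b1", "b2", "b3", "acc"), NULL))
  m["acc", ] <- 0.04                     # accessory with negligible sales
  meta <- data.frame(brand = rownames(m),
                     product_type = c("e-cigarette", "e-cigarette",
                                      "e-cigarette", "accessory"))
  p <- sales_panel(m, treated_id = "b1", brand_meta = meta)
  expect_message(f1 <- filter_brands(p, exclusions = "accessory"),
                 "<0.1%")
  expect_false("acc" %in% f1$brand_ids)
  expect_silent(f2 <- filter_brands(f1, exclusions = "accessory"))
  expect_equal(f2$sales, f1$sales)       # idempotent

  # complete panel, no exclusions: unchanged
  expect_equal(filter_brands(p)$sales, p$sales)

  # removing the treated brand is fatal
  expect_error(filter_brands(p, exclusions = "e-cigarette"),
               "fatal configuration error")
})

test_that("write_results writes deterministic tables and refuses empties", {
  tabs <- list(gaps = data.frame(week = 1:3, gap = c(-0.1, -0.2, -0.3)),
               ranks = data.frame(brand = c("a", "b"), rank = 1:2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(tabs, d1, manifest = list(seed = 1))
  write_results(tabs, d2, manifest = list(seed = 1))
  for (f in c("gaps.csv", "ranks.csv", "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_error(write_results(list(), d1), "non-empty")
  expect_error(write_results(list(x = data.frame()), d1), "empty")
})
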