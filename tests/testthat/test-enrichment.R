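test_that("histogram pdfs are conserved and ratios behave", {
  reg <- region_from_mask(disk_mask(128, 50))
  obs <- sample_null(reg, 500, multiplier = 1, seed = 1)
  nul <- sample_null(reg, 500, multiplier = 20, seed = 2)
  pr <- enrichment(obs, nul, r0 = reg$r0, bins = 10)
  expect_equal(sum(pr$observed_pdf), 1, tolerance = 1e-12)
  expect_equal(sum(pr$null_pdf), 1, tolerance = 1e-12)
  expect_true(all(pr$relative_frequency >= 0, na.rm = TRUE))
  expect_equal(nrow(pr), 10)
})

test_that("self-consistency: null against itself is flat at 1", {
  reg <- region_from_mask(disk_mask(128, 50))
  obs <- sample_null(reg, 2000, multiplier = 1, seed = 3)
  nul <- sample_null(reg, 2000, multiplier = 10, seed = 4)
  pr <- enrichment(obs, nul, r0 = reg$r0, bins = 10)
  se <- with(pr, relative_frequency *
               sqrt((1 - observed_pdf) / (observed_pdf * 2000) +
                    (1 - null_pdf) / (null_pdf * 20000)))
  dev <- abs(pr$relative_frequency - 1)
  expect_true(all(dev < 3 * se + 0.05, na.rm = TRUE))
})

test_that("rim-concentrated observations give the analytic first-bin ratio", {
  ## all observed mass in r/r0 <= 0.1 on a disk: ratio ~ 1/0.19
  ## (large disk so pixelation bias is small)
  reg <- region_from_mask(disk_mask(256, 110))
  nul <- sample_null(reg, 2000, multiplier = 50, seed = 5)
  obs <- runif(5000, 0, 0.1 * reg$r0)
  pr <- enrichment(obs, nul, r0 = reg$r0, bins = 10)
  expect_equal(pr$relative_frequency[1], 1 / 0.19, tolerance = 0.06)
  expect_true(all(pr$relative_frequency[-1] == 0, na.rm = TRUE))
})

test_that("distances above r0 are clipped with a warning; empty null bins are NA", {
  expect_warning(pr <- enrichment(c(0.5, 1.2), c(0.1, 0.5, 0.9), r0 = 1),
                 "clipped")
  expect_equal(sum(pr$observed_pdf), 1)
  pr2 <- enrichment(runif(100, 0, 0.3), runif(100, 0, 0.3), r0 = 1, bins = 10)
  expect_true(all(is.na(pr2$relative_frequency[8:10])))
})

test_that("aggregation across structures gives per-bin mean and sd", {
  reg <- region_from_mask(disk_mask(96, 36))
  prs <- lapply(1:4, function(k) {
    obs <- sample_null(reg, 500, multiplier = 1, seed = 10 + k)
    nul <- sample_null(reg, 500, multiplier = 10, seed = 20 + k)
    enrichment(obs, nul, r0 = reg$r0, bins = 10)
  })
  agg <- aggregate_enrichment(prs)
  expect_equal(nrow(agg), 10)
  expect_true(all(agg$n_kdna == 4))
  expect_equal(agg$mean_rf[1],
               mean(vapply(prs, function(p) p$relative_frequency[1], 1.0)))
})
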