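marey_loci <- function(cm, mb, chr = "chr01") {
  data.frame(marker_id = sprintf("m%03d", seq_along(cm)), chromosome = chr,
             genetic_pos = cm, physical_pos = mb, stringsAsFactors = FALSE)
}

test_that("a monotone map loses nothing; unanchored loci are excluded", {
  loci <- marey_loci(c(0, 5, 10, 15), c(0, 10, 20, 30))
  m <- filter_marey_outliers(loci)
  expect_equal(nrow(m$points), 4)
  expect_equal(nrow(m$excluded), 0)

  loci$physical_pos[2] <- NA
  m <- filter_marey_outliers(loci)
  expect_equal(m$excluded$reason, "unanchored")
  expect_equal(m$excluded$marker_id, "m002")
})

test_that("a single swapped locus inside a monotone run is excluded", {
  cm <- c(0, 2, 4, 6, 8, 30, 12, 14, 16, 18)  # m006 out of order
  mb <- seq(0, 45, by = 5)
  m <- filter_marey_outliers(marey_loci(cm, mb))
  expect_equal(m$excluded$marker_id, "m006")
  expect_equal(m$excluded$reason, "non-monotone")
  expect_equal(nrow(m$points), 9)
})

test_that("outlier filter matches brute-force LNDS for n <= 12", {
  set.seed(4)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    cm <- sample(seq_len(20), n, replace = TRUE)
    m <- filter_marey_outliers(marey_loci(cm, seq_len(n)))
    expect_equal(nrow(m$points), brute_lnds_len(cm))
    expect_false(is.unsorted(m$points$genetic_pos))
  }
})

test_that("fewer than two anchored loci is an error", {
  expect_error(filter_marey_outliers(marey_loci(1, 1)), "fewer than 2")
})

test_that("two points give a linear interpolant with secant slope", {
  m <- filter_marey_outliers(marey_loci(c(0, 20), c(0, 40)))
  f <- fit_monotone_interpolant(m)
  expect_equal(f$fun(20), 10)
  expect_equal(f$deriv(c(5, 15, 35)), rep(0.5, 3))
})

test_that("parabolic truth is recovered within 0.5 cM and its derivative", {
  mb <- seq(0, 100, by = 5)
  m <- filter_marey_outliers(marey_loci(0.01 * mb^2, mb))
  f <- fit_monotone_interpolant(m)
  grid <- seq(0, 100, by = 0.1)
  expect_lt(max(abs(f$fun(grid) - 0.01 * grid^2)), 0.5)
  rp <- local_rates(f, grid_Mb = 50)
  expect_lt(abs(rp$rate - 1.0), 0.05)
})

test_that("interpolant is non-decreasing on a dense grid (simulated maps)", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(8:40, 1)
    mb <- sort(runif(n, 0, 70))
    mb <- mb[!duplicated(mb)]
    cm <- cumsum(c(0, rexp(length(mb) - 1, 1)))
    f <- fit_monotone_interpolant(
      filter_marey_outliers(marey_loci(cm, mb)))
    grid <- seq(min(mb), max(mb), length.out = 1000)
    expect_true(all(diff(f$fun(grid)) >= -1e-9))
    expect_true(all(local_rates(f, grid)$rate >= 0))
  }
})

test_that("duplicate physical positions collapse to the mean with warning", {
  loci <- marey_loci(c(0, 4, 6, 10), c(0, 5, 5, 10))
  m <- filter_marey_outliers(loci)
  expect_warning(f <- fit_monotone_interpolant(m), "collapsed")
  expect_equal(f$fun(5), 5)
})

test_that("a linear Marey map yields a constant local rate", {
  m <- filter_marey_outliers(marey_loci(seq(0, 60, by = 6),
                                        seq(0, 50, by = 5)))
  f <- fit_monotone_interpolant(m)
  rp <- local_rates(f)
  expect_true(all(abs(rp$rate - 1.2) < 1e-8))
  expect_equal(rp$chromosome_avg, 1.2)
})

test_that("telomere-enriched recombination shows up as higher end rates", {
  mb <- seq(0, 60, by = 2)
  ## U-shaped rate profile: integral of 0.3 + 4 (x - 1/2)^2 over x = Mb/60
  x <- mb / 60
  cm <- 60 * (0.3 * x + 4 * ((x - 0.5)^3 + 0.125) / 3)
  f <- fit_monotone_interpolant(filter_marey_outliers(marey_loci(cm, mb)))
  rp <- local_rates(f)
  ends <- rp$rate[rp$grid_Mb <= 10 | rp$grid_Mb >= 50]
  center <- rp$rate[rp$grid_Mb > 20 & rp$grid_Mb < 40]
  expect_gt(mean(ends), mean(center))
})

test_that("integrated local rate recovers the chromosome's cM span", {
  set.seed(9)
  mb <- sort(runif(25, 0, 65))
  cm <- cumsum(c(0, rexp(24, 0.8)))
  f <- fit_monotone_interpolant(filter_marey_outliers(marey_loci(cm, mb)))
  rp <- local_rates(f, grid_Mb = seq(min(mb), max(mb), length.out = 4001))
  integral <- sum(diff(rp$grid_Mb) *
                    (rp$rate[-1] + rp$rate[-length(rp$rate)]) / 2)
  span <- max(cm) - min(cm)
  expect_lt(abs(integral - span) / span, 0.01)
})

test_that("adding a point on the fitted curve changes nothing material", {
  mb <- seq(0, 50, by = 5)
  cm <- 0.02 * mb^1.5
  f <- fit_monotone_interpolant(filter_marey_outliers(marey_loci(cm, mb)))
  new_mb <- 12.5
  loci2 <- marey_loci(c(cm, f$fun(new_mb)), c(mb, new_mb))
  m2 <- filter_marey_outliers(loci2)
  expect_equal(nrow(m2$excluded), 0)   # the new point is not an outlier
  f2 <- fit_monotone_interpolant(m2)
  grid <- seq(0, 50, by = 0.5)
  expect_lt(max(abs(f2$fun(grid) - f$fun(grid))), 0.05)
})

test_that("average rates reproduce span arithmetic", {
  expect_equal(average_rates(data.frame(chromosome = "chr01",
                                        cM_span = 100, Mb_span = 100))$rate,
               c(1, 1))
  ## from mapped loci of a simulated design the ratio is exact
  sim <- small_sim(n = 20, n_chr = 2, length_cM = 60, markers = 13,
                   seed = 41)
  avg <- average_rates(sim$genotypes$loci)
  expect_equal(avg$rate[avg$chromosome == "chr01"], 60 / 48)
  expect_equal(avg$rate[avg$chromosome == "genome"], 120 / 96)
  expect_error(average_rates(data.frame(chromosome = "c", cM_span = 1,
                                        Mb_span = 0)), "zero")
})

test_that("rate-distortion regression handles exact, constant, tiny n", {
  mb <- seq(0, 50, by = 5)
  cm <- 0.01 * mb^2
  f <- fit_monotone_interpolant(filter_marey_outliers(marey_loci(cm, mb)))
  ## exact linear relation between rate and -log10 p -> r^2 = 1
  res <- fake_results("chr01", cm, rep(0.5, length(mb)),
                      physical_pos = mb)
  res$neg_log10_p <- 2 + 3 * pmax(0, f$deriv(mb))
  ## summary.lm warns about the (intended) essentially perfect fit
  fit <- suppressWarnings(rate_vs_distortion(f, res))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope_sign, 1L)

  ## constant predictor
  flin <- fit_monotone_interpolant(
    filter_marey_outliers(marey_loci(mb, mb)))
  fit2 <- rate_vs_distortion(flin, res)
  expect_equal(fit2$r_squared, 0)
  expect_match(fit2$note, "constant predictor")

  fit3 <- rate_vs_distortion(f, res[1:2, ])
  expect_true(is.na(fit3$r_squared))
})
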