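## a one-marker paternal population with chosen codes and phase
one_marker_pop <- function(codes, phase = 0L) {
  loci <- data.frame(marker_id = "m1", chromosome = "chr01",
                     genetic_pos = 0, physical_pos = 0,
                     seg_class = "paternal",
                     phase_maternal = NA_integer_,
                     phase_paternal = phase)
  genotype_matrix(loci, matrix(codes, ncol = 1,
                               dimnames = list(NULL, "m1")))
}

test_that("phase links the heterozygous code to the right homolog", {
  ## phase 0: the p allele rides on homolog 1 -> all-np means homolog 1
  g <- one_marker_pop(rep("np", 96), phase = 0L)
  prof <- transmission_profile(g, "paternal")
  expect_equal(prof$freq_homolog1, 1.0)

  ## phase 1 puts p on homolog 2: 5 np carriers -> freq_homolog2 = 5/96
  g <- one_marker_pop(c(rep("np", 5), rep("nn", 91)), phase = 1L)
  prof <- transmission_profile(g, "paternal")
  expect_equal(1 - prof$freq_homolog1, 5 / 96)
  expect_equal(prof$n_informative, 96L)

  ## the skewed-peak case: 91 np carriers, phase 1 -> homolog 2 at 91/96
  g <- one_marker_pop(c(rep("np", 91), rep("nn", 5)), phase = 1L)
  prof <- transmission_profile(g, "paternal")
  expect_equal(1 - prof$freq_homolog1, 91 / 96)
})

test_that("profile frequencies equal the simulator truth exactly", {
  sim <- small_sim(n = 40, n_chr = 2, markers = 21, seed = 31)
  prof <- transmission_profile(sim$genotypes, "paternal")
  for (chr in c("chr01", "chr02")) {
    truth_freq <- colMeans(sim$truth$paternal[[chr]]$indicator == 1L)
    expect_equal(prof$freq_homolog1[prof$chromosome == chr],
                 unname(truth_freq))
  }
})

test_that("profile chi-square reproduces test_distortion on the same loci", {
  sim <- small_sim(n = 50, n_chr = 1, markers = 15, seed = 32,
                   selections = sel_gametic("paternal", "chr01", 30, 0.8))
  prof <- transmission_profile(sim$genotypes, "paternal")
  res <- test_distortion(sim$genotypes)
  expect_equal(prof$chi2, res$chi2)
  expect_equal(prof$p_value, res$p_value)
})

test_that("combination profile is flat under independent transmission", {
  ## maternal and paternal markers interleaved 0.5 cM apart
  map <- chromosome_map("chr01", 10, 10, n_markers = 21)
  classes <- rep(c("maternal", "paternal"), length.out = 21)
  d <- cross_design(map, 8000, marker_classes = classes, seed = 33)
  sim <- simulate_population(d)
  cp <- combination_profile(sim$genotypes, window_cM = 1)
  expect_gt(nrow(cp), 0)
  frac <- as.matrix(cp[, c("n_M1P1", "n_M1P2", "n_M2P1", "n_M2P2")]) / cp$n
  expect_true(all(abs(frac - 0.25) < 3 * sqrt(0.25 * 0.75 / 8000)))
  expect_false(any(cp$significant))
})

test_that("a lethal homolog combination empties its cell", {
  ## maternal and paternal markers coincide at the selected position, so
  ## the profiled pair reads exactly the homologs selection acted on
  map <- chromosome_map("chr01", 10, 10, marker_cM = c(5, 5),
                        marker_Mb = c(5, 5))
  d <- cross_design(map, 300,
                    marker_classes = c("maternal", "paternal"),
                    selections = sel_zygotic("chr01", 5, c(M1P1 = 0),
                                             pos_paternal_cM = 5),
                    seed = 34)
  sim <- simulate_population(d)
  cp <- combination_profile(sim$genotypes, window_cM = 5)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$n_M1P1, 0L)
  expect_true(cp$significant)
})

test_that("one-sided gametic bias distorts only that parent's margin", {
  map <- chromosome_map("chr01", 10, 10, n_markers = 11)
  classes <- rep(c("maternal", "paternal"), length.out = 11)
  d <- cross_design(map, 6000, marker_classes = classes,
                    selections = sel_gametic("maternal", "chr01", 5, 0.8),
                    seed = 35)
  sim <- simulate_population(d)
  cp <- combination_profile(sim$genotypes, window_cM = 1)
  at <- which.min(abs(cp$maternal_cM - 5))
  m1 <- (cp$n_M1P1[at] + cp$n_M1P2[at]) / cp$n[at]
  p1 <- (cp$n_M1P1[at] + cp$n_M2P1[at]) / cp$n[at]
  se <- sqrt(0.25 / cp$n[at])
  expect_lt(abs(m1 - 0.8), 3 * sqrt(0.8 * 0.2 / cp$n[at]))
  expect_lt(abs(p1 - 0.5), 3 * se)
})

test_that("crossover counting follows indicator transitions exactly", {
  ## constant indicator -> 0; pattern 1,1,2,2,1 -> 2
  loci <- data.frame(marker_id = paste0("m", 1:5), chromosome = "chr01",
                     genetic_pos = 0:4, physical_pos = 0:4,
                     seg_class = "paternal",
                     phase_maternal = NA_integer_, phase_paternal = 0L)
  ## phase 0: np = homolog 1, nn = homolog 2
  codes <- rbind(rep("np", 5),
                 c("np", "np", "nn", "nn", "np"))
  colnames(codes) <- loci$marker_id
  g <- genotype_matrix(loci, codes)
  xo <- count_crossovers(g, "paternal")
  expect_equal(xo$n_crossovers, c(0L, 2L))
})

test_that("missing codes are skipped, not counted as transitions", {
  loci <- data.frame(marker_id = paste0("m", 1:4), chromosome = "chr01",
                     genetic_pos = 0:3, physical_pos = 0:3,
                     seg_class = "paternal",
                     phase_maternal = NA_integer_, phase_paternal = 0L)
  codes <- matrix(c("np", "--", "np", "nn"), nrow = 1,
                  dimnames = list("p1", loci$marker_id))
  g <- genotype_matrix(loci, codes)
  expect_equal(count_crossovers(g, "paternal")$n_crossovers, 1L)
})

test_that("detected crossovers equal truth minus within-gap double events", {
  map <- chromosome_map("chr01", 100, 90, n_markers = 101)  # 1 marker/cM
  sim <- simulate_population(cross_design(map, 400, seed = 36))
  detected <- count_crossovers(sim$genotypes, "paternal")
  true_counts <- lengths(sim$truth$paternal$chr01$crossovers)
  expect_true(all(detected$n_crossovers <= true_counts))
  loss <- sum(true_counts) - sum(detected$n_crossovers)
  ## per 1-cM gap, Poisson lambda = 0.01: expected invisible events
  ## lambda - P(odd) = lambda - exp(-lambda)*sinh(lambda) ~ lambda^2
  lam <- 0.01
  exp_loss_per_gamete <- 100 * (lam - exp(-lam) * sinh(lam))
  exp_loss <- 400 * exp_loss_per_gamete
  expect_lt(loss, exp_loss + 3 * sqrt(exp_loss) + 3)
})

test_that("mean detected crossovers per progeny approaches L_total/100", {
  maps <- list(chromosome_map("chr01", 80, 70, n_markers = 81),
               chromosome_map("chr02", 60, 50, n_markers = 61))
  sim <- simulate_population(cross_design(maps, 1500, seed = 37))
  xo <- count_crossovers(sim$genotypes, "paternal")
  s <- summarize_crossovers(xo)
  expect_equal(s$n_progeny, 1500)
  ## expected 1.4 per paternal meiosis; SE ~ sqrt(1.4/1500)
  expect_lt(abs(s$mean_per_progeny - 1.4), 3 * sqrt(1.4 / 1500) + 0.02)
})

test_that("min_run smoothing ignores single-locus flips", {
  loci <- data.frame(marker_id = paste0("m", 1:5), chromosome = "chr01",
                     genetic_pos = 0:4, physical_pos = 0:4,
                     seg_class = "paternal",
                     phase_maternal = NA_integer_, phase_paternal = 0L)
  codes <- matrix(c("np", "np", "nn", "np", "np"), nrow = 1,
                  dimnames = list("p1", loci$marker_id))
  g <- genotype_matrix(loci, codes)
  expect_equal(count_crossovers(g, "paternal")$n_crossovers, 2L)
  expect_equal(count_crossovers(g, "paternal", min_run = 2)$n_crossovers,
               0L)
})
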