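test_that("a well-formed pair of files round-trips through read_genotypes", {
  g <- tiny_matrix()
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, gp, mp)
  g2 <- read_genotypes(gp, mp)
  expect_equal(nrow(g2$loci), 3)
  expect_equal(length(g2$progeny_ids), 3)
  expect_equal(g2, g)
  ## markers sorted by (chromosome, genetic_pos)
  expect_equal(g2$loci$marker_id, c("mA", "mB", "mC"))
})

test_that("round-trip is the identity on simulator output", {
  sim <- small_sim(n = 25, classes = c("maternal", "paternal",
                                       "biparental")[
    1 + (seq_len(62) %% 3)])
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(sim$genotypes, gp, mp)
  expect_equal(read_genotypes(gp, mp), sim$genotypes)
})

test_that("illegal codes and malformed inputs are rejected with context", {
  loci <- tiny_loci()
  codes <- tiny_codes()
  codes[2, "mB"] <- "hk"   # hk on an <nnxnp> marker
  expect_error(genotype_matrix(loci, codes), "illegal code 'hk'.*mB")

  g <- tiny_matrix()
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, gp, mp)
  tab <- read.delim(gp, check.names = FALSE, colClasses = "character")
  tab$p2[tab$marker_id == "mB"] <- "hk"
  write.table(tab, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(gp, mp), "illegal code 'hk'.*mB.*p2")

  ## duplicate marker_id
  tab <- read.delim(gp, check.names = FALSE, colClasses = "character")
  tab$marker_id[2] <- tab$marker_id[1]
  write.table(tab, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(gp, mp), "duplicate marker_id")

  ## marker present in only one file
  write_genotypes(g, gp, mp)
  mtab <- read.delim(mp, stringsAsFactors = FALSE)
  write.table(mtab[-1, ], mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(gp, mp), "only one file")
})

test_that("missing-code markers are dropped by default and retainable", {
  g <- tiny_matrix()
  g$codes[1, "mB"] <- "--"
  g <- genotype_matrix(g$loci, g$codes)
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, gp, mp)
  expect_message(g2 <- read_genotypes(gp, mp), "dropping 1 marker")
  expect_false("mB" %in% g2$loci$marker_id)
  g3 <- read_genotypes(gp, mp, drop_missing = FALSE)
  expect_true("mB" %in% g3$loci$marker_id)
})

test_that("collapse_bins groups identical columns and is idempotent", {
  loci <- tiny_loci()[c(1, 2), ]
  codes <- tiny_codes()[, c(1, 2)]
  ## make mB a duplicate pattern of a new paternal marker mD
  loci <- rbind(loci, data.frame(marker_id = "mD", chromosome = "chr01",
                                 genetic_pos = 12, physical_pos = 13,
                                 seg_class = "paternal",
                                 phase_maternal = NA_integer_,
                                 phase_paternal = 1L))
  codes <- cbind(codes, mD = codes[, "mB"])
  g <- genotype_matrix(loci, codes)
  cb <- collapse_bins(g)
  expect_equal(nrow(cb$bins), 2)
  expect_equal(sort(cb$bins$n_members), c(1L, 2L))
  bin2 <- cb$bins[cb$bins$n_members == 2, ]
  expect_setequal(bin2$members[[1]], c("mB", "mD"))
  expect_equal(bin2$representative, "mB")  # smallest genetic_pos
  ## idempotence
  cb2 <- collapse_bins(cb$matrix)
  expect_equal(cb2$matrix, cb$matrix)
  expect_true(all(cb2$bins$n_members == 1))
})

test_that("all-distinct columns give one bin per marker", {
  g <- tiny_matrix()
  cb <- collapse_bins(g)
  expect_equal(nrow(cb$bins), nrow(g$loci))
})

test_that("simulator output with k duplicated columns loses exactly k bins", {
  sim <- small_sim(n = 40, n_chr = 1, markers = 15, seed = 11)
  g <- sim$genotypes
  base_excess <- nrow(g$loci) - nrow(collapse_bins(g)$bins)
  k <- 4
  dup_src <- sample(seq_len(n <- nrow(g$loci)), k)
  loci <- g$loci
  codes <- g$codes
  for (i in seq_len(k)) {
    loci <- rbind(loci, transform(loci[dup_src[i], ],
                                  marker_id = paste0("dup", i),
                                  genetic_pos = loci$genetic_pos[dup_src[i]]))
    codes <- cbind(codes, codes[, dup_src[i], drop = FALSE])
    colnames(codes)[ncol(codes)] <- paste0("dup", i)
  }
  g2 <- genotype_matrix(loci, codes)
  cb <- collapse_bins(g2)
  expect_equal(nrow(g2$loci) - nrow(cb$bins), base_excess + k)
})

test_that("compare_maps: identity, discordant chromosomes, adjacent swap", {
  a <- tiny_loci()
  expect_equal(compare_maps(a, a)$order_concordance, 1.0)
  expect_equal(compare_maps(a, a)$discordant_chromosome, 0L)

  b <- a
  b$chromosome[1] <- "chr09"
  cmp <- compare_maps(a, b)
  expect_equal(cmp$discordant_chromosome, 1L)
  expect_equal(cmp$n_shared, 3L)

  ## 5 markers, one adjacent swap -> 9/10 concordant pairs
  m5 <- data.frame(marker_id = paste0("s", 1:5), chromosome = "chr01",
                   genetic_pos = c(0, 5, 10, 15, 20))
  m5b <- m5
  m5b$genetic_pos <- c(0, 10, 5, 15, 20)
  cmp <- compare_maps(m5, m5b)
  expect_equal(cmp$order_concordance, 9 / 10)
  expect_equal(cmp$n_pairs, 10L)
})

test_that("compare_maps concordance equals a brute-force pair count", {
  set.seed(3)
  n <- 8
  a <- data.frame(marker_id = paste0("x", 1:n), chromosome = "chr01",
                  genetic_pos = sort(runif(n, 0, 50)))
  b <- a
  b$genetic_pos <- sample(b$genetic_pos)
  cmp <- compare_maps(a, b)
  conc <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (sign(a$genetic_pos[i] - a$genetic_pos[j]) ==
        sign(b$genetic_pos[i] - b$genetic_pos[j])) conc <- conc + 1
  }
  expect_equal(cmp$order_concordance, conc / tot)
  ## symmetry
  cmp_rev <- compare_maps(b, a)
  expect_equal(cmp_rev$order_concordance, cmp$order_concordance)
  expect_equal(cmp_rev$n_shared, cmp$n_shared)
})

test_that("empty marker intersection yields a defined result", {
  a <- tiny_loci()
  b <- tiny_loci()
  b$marker_id <- paste0("other_", b$marker_id)
  cmp <- compare_maps(a, b)
  expect_equal(cmp$n_shared, 0L)
  expect_true(is.na(cmp$order_concordance))
})
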