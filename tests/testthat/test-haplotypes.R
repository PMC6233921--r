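test_that("genotype tables parse row-for-row and reject malformed rows", {
  df <- tinyGenotypes(n_ind = 1, n_snps = 2)[1:4, ]
  path <- tempfile(fileext = ".tsv")
  writeGenotypeTable(df, path)
  back <- readGenotypeTable(path)
  expect_equal(nrow(back), 4L)
  expect_equal(back$call, df$call)
  expect_equal(back$snp_id, df$snp_id)

  bad <- df; bad$call[2] <- "X"
  writeGenotypeTable(bad, path)
  expect_error(readGenotypeTable(path), "unknown call code 'X'.*row 2")

  mism <- df; mism$region <- 2L
  expect_error(validateGenotypeTable(mism), "chromosome/region mismatch")

  tworeg <- rbind(df, transform(df, chromosome = "V", region = 3L,
                                snp_id = paste0("V_", 1:4)))
  expect_error(validateGenotypeTable(tworeg), "more than one region")

  expect_error(validateGenotypeTable(df[, -8]), "missing required column")
})

test_that("QC drops exactly the planted failures and reports them", {
  ## 10 individuals, 4 SNPs per chromosome; SNP I_2 missing in 40% of
  ## individuals (over threshold 0.30); individual ind1 missing at 3 of its
  ## remaining 7 SNPs (3/7 > 0.25)
  df <- tinyGenotypes(n_ind = 10, n_snps = 4)
  df$call[df$snp_id == "I_2" & df$individual %in% paste0("ind", 1:4)] <-
    "MISSING"
  df$call[df$individual == "ind1" &
          df$snp_id %in% c("II_1", "II_2", "II_3")] <- "MISSING"
  res <- applyQC(df)
  expect_equal(res$report$dropped_snps, "I_2")
  expect_equal(res$report$dropped_individuals, "ctrl.1/0/ind1")
  expect_false(any(res$calls$snp_id == "I_2"))
  expect_false(any(res$calls$individual == "ind1"))
})

test_that("QC leaves clean data untouched and is idempotent", {
  df <- tinyGenotypes(n_ind = 6, n_snps = 5)
  res <- applyQC(df)
  expect_equal(res$calls, df)
  expect_equal(res$report$n_dropped_snps, 0L)
  expect_equal(res$report$n_dropped_individuals, 0L)

  ## idempotence on data that does trigger drops
  df2 <- tinyGenotypes(n_ind = 10, n_snps = 4)
  df2$call[df2$snp_id == "I_3" & df2$individual %in% paste0("ind", 1:5)] <-
    "MISSING"
  once <- applyQC(df2)
  twice <- applyQC(once$calls)
  expect_equal(twice$calls, once$calls)
  expect_equal(twice$report$n_dropped_snps, 0L)

  expect_error(applyQC(df, snp_fail_threshold = 0), "thresholds")
  allmiss <- transform(df, call = "MISSING")
  expect_error(applyQC(allmiss), "removed all")
})

test_that("HET-heavy SNPs are dropped by the het threshold", {
  df <- tinyGenotypes(n_ind = 10, n_snps = 3)
  df$call[df$snp_id == "II_1" & df$individual %in% paste0("ind", 1:4)] <-
    "HET"
  res <- applyQC(df, het_threshold = 0.30)
  expect_true("II_1" %in% res$report$dropped_snps)
})

test_that("CWH construction is deterministic and ordered by position", {
  df <- tinyGenotypes(n_ind = 2, n_snps = 3)
  cwh <- callsToCwh(df)
  expect_equal(nrow(cwh), 4L)              # 2 individuals x 2 chromosomes
  expect_true(all(cwh$cwh == "000"))       # homozygous REF everywhere
  ## identical calls give identical CWH strings
  expect_equal(cwh$cwh[cwh$individual == "ind1"],
               cwh$cwh[cwh$individual == "ind2"])
  ## alleles follow position order, 0 = REF, 1 = ALT
  df2 <- tinyGenotypes(n_ind = 1, n_snps = 3)
  df2$call[df2$snp_id == "I_2"] <- "ALT"
  expect_equal(callsToCwh(df2)$cwh[1], "010")
})

test_that("residual HET and MISSING calls are handled per the rules", {
  df <- tinyGenotypes(n_ind = 3, n_snps = 3)
  df$call[df$individual == "ind1" & df$snp_id == "I_1"] <- "HET"
  expect_warning(cwh <- callsToCwh(df), "heterozygous")
  expect_false("ind1" %in% cwh$individual)

  ## a single MISSING per chromosome is imputed to the sample major allele
  df2 <- tinyGenotypes(n_ind = 4, n_snps = 3)
  df2$call[df2$snp_id == "I_2" & df2$individual != "ind1"] <- "ALT"
  df2$call[df2$snp_id == "I_2" & df2$individual == "ind1"] <- "MISSING"
  cwh2 <- callsToCwh(df2)
  expect_equal(cwh2$cwh[cwh2$individual == "ind1" &
                        cwh2$chromosome == "I"], "010")

  ## more than max_impute MISSING on one chromosome excludes the individual
  df3 <- tinyGenotypes(n_ind = 2, n_snps = 4)
  df3$call[df3$individual == "ind1" & df3$snp_id %in% c("I_1", "I_3")] <-
    "MISSING"
  expect_warning(cwh3 <- callsToCwh(df3), "too many failed")
  expect_false("ind1" %in% cwh3$individual)
})

test_that("RWH concatenation, exclusions and count bounds hold", {
  df <- tinyGenotypes(n_ind = 2, n_snps = 2)
  df$call[df$individual == "ind2" & df$chromosome == "II"] <- "ALT"
  rwh <- cwhToRwh(callsToCwh(df))
  expect_equal(nrow(rwh), 2L)
  expect_equal(rwh$rwh[rwh$individual == "ind1"], "0000")
  expect_equal(rwh$rwh[rwh$individual == "ind2"], "0011")
  expect_equal(rwh$rwh_id, rwhId(1, rwh$rwh))

  ## individual with a single chromosome is excluded
  half <- callsToCwh(df)
  half <- half[!(half$individual == "ind1" & half$chromosome == "II"), ]
  expect_warning(rwh2 <- cwhToRwh(half), "both chromosomes")
  expect_false("ind1" %in% rwh2$individual)

  ## 2 CWHs on chromosome I x 1 CWH on II under full linkage -> 2 RWHs
  df3 <- tinyGenotypes(n_ind = 4, n_snps = 2)
  df3$call[df3$individual %in% c("ind1", "ind2") &
           df3$chromosome == "I"] <- "ALT"
  rwh3 <- cwhToRwh(callsToCwh(df3))
  n_cwh_I <- length(unique(substr(rwh3$rwh, 1, 2)))
  n_cwh_II <- length(unique(substr(rwh3$rwh, 3, 4)))
  n_rwh <- length(unique(rwh3$rwh_id))
  expect_equal(n_rwh, 2L)
  expect_gte(n_rwh, max(n_cwh_I, n_cwh_II))
  expect_lte(n_rwh, n_cwh_I * n_cwh_II)
})

test_that("tally counts sum to sample sizes and parse regimes", {
  df <- tinyGenotypes(n_ind = 5, n_snps = 2, population = "sudden.3",
                      generation = 10L)
  counts <- tallyRwh(cwhToRwh(callsToCwh(df)))
  expect_equal(sum(counts$count), 5L)
  expect_equal(unique(counts$regime), "sudden")
  expect_equal(unique(counts$replicate), "3")
  expect_equal(counts$rwh_id[1], rwhId(1, "0000"))
  ## all individuals identical -> a single RWH carrying the whole sample
  expect_equal(nrow(counts), 1L)
})

test_that("minor-RWH grouping follows the ranking rule and conserves counts", {
  ## 5 RWHs with max observed frequencies .5/.3/.1/.06/.04 at one epoch
  counts <- data.frame(regime = "sudden", replicate = "1",
                       generation = 10L, region = 1L,
                       rwh_id = paste0("R1:h", 1:5),
                       count = c(25L, 15L, 5L, 3L, 2L))
  g <- groupMinor(counts, top_k = 3)
  bg <- g[g$designation == "background", ]
  expect_equal(nrow(bg), 1L)
  expect_equal(bg$rwh_id, "H0R1")
  expect_equal(bg$count, 5L)               # sum of the two minor RWHs
  expect_setequal(g$rwh_id[g$designation == "primary"],
                  paste0("R1:h", 1:3))
  expect_equal(sum(g$count), sum(counts$count))

  ## fewer RWHs than top_k: all primary, no background rows
  g2 <- groupMinor(counts[1:2, ], top_k = 3)
  expect_true(all(g2$designation == "primary"))
  expect_equal(sum(g2$count), 40L)
})

test_that("ranking uses the max frequency across epochs within a replicate", {
  ## h2 is rare at generation 10 but peaks at generation 35: its max
  ## frequency (0.6) outranks h1 (0.5)
  counts <- data.frame(regime = "gradual", replicate = "2",
                       generation = rep(c(10L, 35L), each = 3),
                       region = 1L,
                       rwh_id = rep(paste0("R1:h", 1:3), 2),
                       count = c(10L, 2L, 8L, 2L, 12L, 6L))
  g <- groupMinor(counts, top_k = 1)
  expect_setequal(g$rwh_id[g$designation == "primary"], "R1:h2")
})

test_that("regime pooling sums replicates and unions primaries", {
  counts <- data.frame(regime = "sudden",
                       replicate = rep(c("1", "2"), each = 2),
                       generation = 10L, region = 1L,
                       rwh_id = rep(c("R1:x", "R1:y"), 2),
                       count = c(3L, 9L, 5L, 7L),
                       designation = c("primary", "primary",
                                       "background", "primary"))
  p <- poolToRegime(counts)
  expect_equal(p$count[p$rwh_id == "R1:x"], 8L)
  expect_equal(p$count[p$rwh_id == "R1:y"], 16L)
  ## background in one replicate but primary in the other stays primary
  expect_equal(p$designation[p$rwh_id == "R1:x"], "primary")
  ## single replicate pools to itself
  one <- counts[counts$replicate == "1", ]
  p1 <- poolToRegime(one)
  expect_equal(p1$count, one$count[order(-one$count)])
})

test_that("generator output round-trips exactly through the pipeline", {
  sm <- smallExperiment(seed = 5, emit = "full",
                        regimes = c(sudden = 2L),
                        n_ancestral = 24L, n_evolved = 8L, snps = 8L)
  path <- tempfile(fileext = ".tsv")
  writeGenotypeTable(sm$exp$genotypes, path)
  back <- readGenotypeTable(path)
  expect_equal(nrow(back), nrow(sm$exp$genotypes))

  qc <- applyQC(back)
  expect_equal(qc$report$n_dropped_snps, 0L)
  tallied <- tallyRwh(cwhToRwh(callsToCwh(qc$calls)))
  truth <- truthCountsTable(sm$exp)
  key <- function(d) paste(d$regime, d$replicate, d$generation, d$region,
                           d$rwh_id)
  tallied <- tallied[order(key(tallied)), ]
  truth <- truth[order(key(truth)), ]
  expect_equal(key(tallied), key(truth))
  expect_equal(tallied$count, truth$count)

  ## pooling equals the sum of the planted per-replicate draws
  pooled <- poolToRegime(groupMinor(tallied, top_k = 3))
  expect_equal(sum(pooled$count), sum(truth$count))

  summ <- distinctRwhSummary(tallied)
  expect_equal(summ$product, prod(summ$distinct_per_region))
  expect_equal(length(summ$distinct_per_region), 3L)
})
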