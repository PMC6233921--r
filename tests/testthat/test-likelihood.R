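# Hand-built data objects around the two-lineage world: one sudden regime
# with counts at epoch 10, plus ancestral fitness rows.
suddenData <- function(counts10 = c(A = 3, B = 1),
                       fitness = NULL, epochs = c(0L, 10L)) {
  pooled <- data.frame(
    regime = c("ancestral", "ancestral", "sudden", "sudden"),
    generation = c(0L, 0L, 10L, 10L), region = 1L,
    rwh_id = c("A", "B", names(counts10)),
    count = c(50L, 50L, unname(counts10)),
    designation = "primary")
  if (is.null(fitness))
    fitness <- data.frame(regime = character(0), generation = integer(0),
                          env_mM = numeric(0), replicate = integer(0),
                          growth_rate = numeric(0))
  assembleInferenceData(pooled, fitness,
                        list(sudden = envSchedule("sudden", 10)),
                        epochs = epochs)
}

test_that("fitness likelihood is the squared natural log of the ratio", {
  w <- twoLineageWorld(s305 = 0, s25 = 0)      # both lineages neutral
  ## predicted ancestral mean fitness at any x is exp(b) of lineage A
  predicted <- meanFitness(c(0.5, 0.5), 305, w$lineages, w$norms)
  mk <- function(phi) suddenData(
    fitness = data.frame(regime = "ancestral", generation = 0L,
                         env_mM = 305, replicate = 1L, growth_rate = phi))
  ## perfect fit -> 0
  expect_equal(loglikFitness(w$norms, w$ancestral, mk(predicted)), 0)
  ## ratio e -> -1, and the kernel is symmetric in the ratio
  expect_equal(loglikFitness(w$norms, w$ancestral, mk(predicted * exp(1))),
               -1)
  expect_equal(loglikFitness(w$norms, w$ancestral,
                             mk(predicted / exp(1))), -1)
  expect_error(
    assembleInferenceData(
      data.frame(regime = "ancestral", generation = 0L, region = 1L,
                 rwh_id = "A", count = 1L),
      data.frame(regime = "ancestral", generation = 0L, env_mM = 25,
                 replicate = 1L, growth_rate = -2),
      list()) |> loglikFitness(norms = w$norms, ancestral = w$ancestral),
    "> 0")
})

test_that("genotype likelihood matches hand multinomial arithmetic", {
  ## equal-fitness lineages: predicted marginals stay (0.5, 0.5);
  ## counts (3, 1) -> 4 * ln(0.5)
  w <- twoLineageWorld(s305 = 0, s25 = 0)
  d <- suddenData(c(A = 3, B = 1))
  expect_equal(as.numeric(loglikGenotypes(w$norms, w$ancestral, d)),
               4 * log(0.5))
  ## zero counts contribute nothing
  d0 <- suddenData(c(A = 0, B = 0))
  expect_equal(as.numeric(loglikGenotypes(w$norms, w$ancestral, d0)), 0)
})

test_that("lineages sharing an RWH pool their marginal frequency", {
  ## two regions; lineages L1=(x,p), L2=(x,q), L3=(y,p); RWH x marginal is
  ## g1 + g2 = 0.3 + 0.2 = 0.5
  lin <- lineageSet(rbind(c("x", "p"), c("x", "q"), c("y", "p")))
  anc <- ancestralState(lin, c(0.3, 0.2, 0.5))
  ids <- c("x", "y", "p", "q")
  nm <- reactionNorms("linear",
    cbind(a = setNames(rep(0, 4), ids), b = rep(0, 4)))
  pooled <- data.frame(
    regime = c("ancestral", "sudden"), generation = c(0L, 10L),
    region = c(1L, 1L), rwh_id = c("x", "x"), count = c(10L, 1L),
    designation = "primary")
  d <- assembleInferenceData(pooled, data.frame(
    regime = character(0), generation = integer(0), env_mM = numeric(0),
    replicate = integer(0), growth_rate = numeric(0)),
    list(sudden = envSchedule("sudden", 10)), epochs = c(0L, 10L))
  expect_equal(as.numeric(loglikGenotypes(nm, anc, d)), log(0.5))
})

test_that("genotype likelihood equals brute-force enumeration", {
  ## oracle: enumerate marginals p_l = sum_k I(l in S_k) g_k^[h] with
  ## explicit loops, propagate epochs by repeated per-generation updates
  set.seed(81)
  for (rep in 1:12) {
    n_regions <- sample(1:3, 1)
    n_rwh <- sample(2:4, 1)
    w <- randomWorld(n_regions = n_regions, n_rwh = n_rwh)
    keep <- sort(sample(nLineages(w$lineages), min(5,
                                                   nLineages(w$lineages))))
    lin <- lineageSet(lineageRwh(w$lineages)[keep, , drop = FALSE])
    f <- runif(length(keep)); anc <- ancestralState(lin, f / sum(f))
    epochs <- c(0L, 10L, 35L)
    sched <- envSchedule("gradual", 35)
    ## observed counts: arbitrary small integers over the RWHs per region
    rows <- list()
    for (g in epochs[-1]) for (r in seq_len(n_regions)) {
      ids <- unique(lineageRwh(lin)[, r])
      rows[[length(rows) + 1L]] <- data.frame(
        regime = "gradual", generation = g, region = r, rwh_id = ids,
        count = sample(0:5, length(ids), replace = TRUE),
        designation = "primary")
    }
    anc_rows <- do.call(rbind, lapply(seq_len(n_regions), function(r)
      data.frame(regime = "ancestral", generation = 0L, region = r,
                 rwh_id = unique(lineageRwh(lin)[, r]), count = 5L,
                 designation = "primary")))
    pooled <- rbind(anc_rows, do.call(rbind, rows))
    d <- assembleInferenceData(pooled, data.frame(
      regime = character(0), generation = integer(0), env_mM = numeric(0),
      replicate = integer(0), growth_rate = numeric(0)),
      list(gradual = sched), epochs = epochs)
    got <- as.numeric(loglikGenotypes(w$norms, anc, d))
    ## oracle
    oracle <- 0
    gfreq <- anc@freq
    for (g in epochs[-1]) {
      prev <- if (g == 10) 0L else 10L
      gfreq <- if (g == 10) anc@freq else gfreq
      for (t in (prev + 1):g)
        gfreq <- selectionStep(gfreq, scheduleEnv(sched, t), lin, w$norms)
      for (r in seq_len(n_regions)) {
        drows <- pooled[pooled$generation == g & pooled$region == r, ]
        for (i in seq_len(nrow(drows))) {
          p_l <- 0
          for (k in seq_len(nLineages(lin)))
            if (lineageRwh(lin)[k, r] == drows$rwh_id[i])
              p_l <- p_l + gfreq[k]
          oracle <- oracle + drows$count[i] * log(max(p_l, 1e-12))
        }
      }
    }
    expect_equal(got, unname(oracle), tolerance = 1e-10)
  }
})

test_that("total log-likelihood is additive over components and regimes", {
  sm <- smallExperiment(seed = 9, regimes = c(sudden = 2L, gradual = 2L))
  d <- experimentData(sm)
  anc <- truthAncestral(sm$spec)
  nm <- sm$tn$norms
  ## truth RWH names -> pipeline ids for the norms and the ancestral state
  map <- sm$exp$truth$rwh_map
  cf <- normCoef(nm)[map$rwh_name, c("a", "b")]
  rownames(cf) <- map$rwh_id
  nm_p <- reactionNorms("linear", cf)
  rwh_p <- lineageRwh(ancestralLineages(anc))
  rwh_p[] <- map$rwh_id[match(rwh_p, map$rwh_name)]
  anc_p <- ancestralState(lineageSet(rwh_p), anc@freq)

  tot <- as.numeric(totalLoglik(nm_p, anc_p, d))
  lf <- loglikFitness(nm_p, anc_p, d)
  lg <- as.numeric(loglikGenotypes(nm_p, anc_p, d))
  expect_equal(tot, lf + lg)
  ## fitness weight scales only the fitness part
  expect_equal(as.numeric(totalLoglik(nm_p, anc_p, d,
                                      fitness_weight = 2)),
               2 * lf + lg)

  ## duplicating a regime doubles its genotype contribution
  counts <- truthCountsTable(sm$exp)
  dup <- counts[counts$regime == "sudden", ]
  dup$regime <- "sudden2"
  pooled2 <- poolToRegime(groupMinor(rbind(counts, dup), top_k = 3))
  d2 <- assembleInferenceData(pooled2, sm$exp$fitness,
                              c(sm$exp$schedules,
                                list(sudden2 = sm$exp$schedules$sudden)))
  lg2 <- as.numeric(loglikGenotypes(nm_p, anc_p, d2))
  ## recompute single-regime contributions for the exact decomposition
  only <- function(dd, cc) {
    keep <- dd
    keep$regimes <- keep$regimes[cc]
    keep
  }
  lg_sudden <- as.numeric(loglikGenotypes(nm_p, anc_p, only(d, "sudden")))
  expect_equal(lg2, lg + lg_sudden, tolerance = 1e-9)
})

test_that("likelihood is invariant to lineage relabeling and row order", {
  sm <- smallExperiment(seed = 10, regimes = c(sudden = 2L))
  d <- experimentData(sm)
  freqs <- estimateAncestralFreqs(d)
  set.seed(1)
  anc <- sampleAncestral(freqs, primary_ids = d$ancestral_primary,
                         n_secondary = 2)
  ids <- sort(unique(as.vector(lineageRwh(ancestralLineages(anc)))))
  nm <- reactionNorms("linear", cbind(
    a = setNames(runif(length(ids), -0.004, 0.004), ids),
    b = runif(length(ids), -0.5, 0.5)))
  base <- as.numeric(totalLoglik(nm, anc, d))
  ## permute lineages
  perm <- sample(nLineages(ancestralLineages(anc)))
  anc2 <- ancestralState(
    lineageSet(lineageRwh(ancestralLineages(anc))[perm, , drop = FALSE]),
    anc@freq[perm])
  expect_equal(as.numeric(totalLoglik(nm, anc2, d)), base)
})

test_that("intercept shifts between regions are a gauge freedom", {
  ## every lineage carries exactly one RWH per region, so adding +delta to
  ## all region-1 intercepts and -delta to all region-2 intercepts leaves
  ## every lineage norm — hence all predictions and the likelihood —
  ## unchanged; only lineage-level quantities are identifiable
  sm <- smallExperiment(seed = 11, regimes = c(sudden = 2L, gradual = 2L))
  d <- experimentData(sm)
  freqs <- estimateAncestralFreqs(d)
  set.seed(2)
  anc <- sampleAncestral(freqs, primary_ids = d$ancestral_primary,
                         n_secondary = 2)
  ids <- sort(unique(as.vector(lineageRwh(ancestralLineages(anc)))))
  nm <- reactionNorms("linear", cbind(
    a = setNames(runif(length(ids), -0.004, 0.004), ids),
    b = runif(length(ids), -0.5, 0.5)))
  cf <- normCoef(nm)[, c("a", "b")]
  delta <- 0.37
  r1 <- grepl("^(R1:|H0R1)", ids); r2 <- grepl("^(R2:|H0R2)", ids)
  cf2 <- cf; cf2[r1, "b"] <- cf2[r1, "b"] + delta
  cf2[r2, "b"] <- cf2[r2, "b"] - delta
  nm2 <- reactionNorms("linear", cf2)
  expect_equal(as.numeric(totalLoglik(nm2, anc, d)),
               as.numeric(totalLoglik(nm, anc, d)), tolerance = 1e-9)
})

test_that("unseen observed RWHs are floored, never -Inf", {
  w <- twoLineageWorld()
  ## an observed RWH "C" that no lineage carries and no background exists
  pooled <- data.frame(
    regime = c("ancestral", "ancestral", "sudden", "sudden"),
    generation = c(0L, 0L, 10L, 10L), region = 1L,
    rwh_id = c("A", "B", "A", "C"), count = c(50L, 50L, 3L, 1L),
    designation = "primary")
  d <- assembleInferenceData(pooled, data.frame(
    regime = character(0), generation = integer(0), env_mM = numeric(0),
    replicate = integer(0), growth_rate = numeric(0)),
    list(sudden = envSchedule("sudden", 10)), epochs = c(0L, 10L))
  ll <- loglikGenotypes(w$norms, w$ancestral, d)
  expect_true(is.finite(as.numeric(ll)))
})

test_that("analytic gradients match finite differences", {
  set.seed(82)
  sm <- smallExperiment(seed = 12, regimes = c(sudden = 2L, gradual = 2L))
  d <- experimentData(sm)
  freqs <- estimateAncestralFreqs(d)
  anc <- sampleAncestral(freqs, primary_ids = d$ancestral_primary,
                         n_secondary = 4)
  ctx <- normsel:::likelihoodContext(anc, d, "linear")
  for (trial in 1:3) {
    cf <- matrix(0, length(ctx$rwh_ids), 3,
                 dimnames = list(ctx$rwh_ids, c("a", "b", "c")))
    cf[, "a"] <- runif(nrow(cf), -0.004, 0.004)
    cf[, "b"] <- runif(nrow(cf), -0.5, 0.5)
    got <- normsel:::.loglikEngine(cf, ctx, grad = TRUE)$grad
    for (j in c("a", "b")) {
      for (i in sample(nrow(cf), 4)) {
        ## step sized per parameter: slopes cumulate over ~1e4
        ## mM-generations, so tiny steps hit likelihood roundoff
        h <- if (j == "a") 1e-8 else 1e-6
        cp <- cf; cp[i, j] <- cp[i, j] + h
        cm <- cf; cm[i, j] <- cm[i, j] - h
        fd <- (normsel:::.loglikEngine(cp, ctx)$loglik -
               normsel:::.loglikEngine(cm, ctx)$loglik) / (2 * h)
        expect_equal(got[i, j], fd,
                     tolerance = 1e-4 * max(1, abs(fd)))
      }
    }
  }
})
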