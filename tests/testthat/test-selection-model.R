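test_that("reaction-norm evaluation matches hand arithmetic", {
  nm <- reactionNorms("linear",
    cbind(a = c(flat = 0, lin = 0.01), b = c(log(2), 0)))
  expect_equal(unname(rwhLogFitness(123, nm)["flat"]), log(2))
  expect_equal(unname(rwhLogFitness(100, nm)["lin"]), 1.0)
  q <- reactionNorms("quadratic",
    cbind(a = c(sq = 1), b = c(sq = 0), c = c(sq = 0)))
  expect_equal(unname(rwhLogFitness(-2, q)["sq"]), 4)
  expect_error(rwhLogFitness(Inf, nm), "finite")
})

test_that("lineage log-fitness is additive over regions", {
  lin <- lineageSet(cbind(`1` = "x", `2` = "y", `3` = "z"))
  nm0 <- reactionNorms("linear",
    cbind(a = c(x = 0, y = 0, z = 0), b = c(0, 0, 0)))
  expect_equal(unname(lineageLogFitness(50, lin, nm0)), 0)
  nm <- reactionNorms("linear",
    cbind(a = c(x = 0, y = 0, z = 0), b = c(log(2), log(3), 0)))
  expect_equal(unname(exp(lineageLogFitness(50, lin, nm))), 6)
  ## single-region lineage reduces to the RWH norm
  l1 <- lineageSet(cbind(`1` = c("x", "y")))
  nm1 <- reactionNorms("linear", cbind(a = c(x = 0.002, y = -0.001),
                                       b = c(0.1, 0.9)))
  expect_equal(unname(lineageLogFitness(150, l1, nm1)),
               unname(rwhLogFitness(150, nm1)))
  expect_error(lineageLogFitness(50, lin, nm1), "no reaction-norm.*z")
})

test_that("the selection step normalizes by mean fitness", {
  w <- twoLineageWorld(s305 = log(2), s25 = log(2))
  expect_equal(unname(selectionStep(c(0.5, 0.5), 305, w$lineages,
                                    w$norms)),
               c(2 / 3, 1 / 3))
  ## neutral invariance
  expect_equal(unname(selectionStep(c(0.3, 0.7), 305,
                             w$lineages,
                             reactionNorms("linear",
                               cbind(a = c(A = 0, B = 0), b = c(1, 1))))),
               c(0.3, 0.7))
  ## boundary states are fixed points
  expect_equal(unname(selectionStep(c(1, 0), 305, w$lineages, w$norms)),
               c(1, 0))
  expect_error(selectionStep(c(0.5, 0.6), 305, w$lineages, w$norms),
               "sum to 1")
})

test_that("epoch propagation equals stepwise composition and closed form", {
  set.seed(71)
  w <- randomWorld(n_regions = 2, n_rwh = 3, a_max = 0.002)
  sched <- envSchedule("gradual", 50)
  g <- w$ancestral@freq
  ## product form vs sequential steps
  gp <- propagateEpoch(g, sched, 0, 35, w$lineages, w$norms)
  gs <- g
  for (t in 1:35)
    gs <- selectionStep(gs, scheduleEnv(sched, t), w$lineages, w$norms)
  expect_equal(gp, gs, tolerance = 1e-10)
  ## semigroup: split at an interior generation
  mid <- propagateEpoch(g, sched, 0, 17, w$lineages, w$norms)
  expect_equal(propagateEpoch(mid, sched, 17, 35, w$lineages, w$norms),
               gp, tolerance = 1e-10)
  ## single generation equals step
  expect_equal(propagateEpoch(g, sched, 4, 5, w$lineages, w$norms),
               selectionStep(g, scheduleEnv(sched, 5), w$lineages,
                             w$norms))
  expect_error(propagateEpoch(g, sched, 5, 5, w$lineages, w$norms),
               "from_gen")
  expect_error(propagateEpoch(g, sched, 49, 55, w$lineages, w$norms),
               "does not cover")
})

test_that("two-lineage constant-environment dynamics are logistic", {
  w <- twoLineageWorld(s305 = 0.12, s25 = -0.08, g0 = c(0.2, 0.8))
  sched <- envSchedule("sudden", 100)
  traj <- predictTrajectories(w$ancestral, sched, 100, w$norms)
  lgt <- function(p) log(p / (1 - p))
  xi <- lineageLogFitness(305, w$lineages, w$norms)
  dxi <- unname(xi[1] - xi[2])
  for (t in c(1, 10, 50, 100))
    expect_equal(unname(lgt(traj[t + 1, 1]) - lgt(traj[1, 1])),
                 t * dxi, tolerance = 1e-10)
})

test_that("trajectories stay on the simplex and respect neutrality", {
  set.seed(72)
  w <- randomWorld(n_regions = 3, n_rwh = 3)
  traj <- predictTrajectories(w$ancestral, envSchedule("gradual", 100),
                              100, w$norms)
  expect_true(all(abs(rowSums(traj) - 1) < 1e-12))
  expect_true(all(traj >= 0))
  ## neutral norms freeze the trajectory
  ids <- normIds(w$norms)
  nm0 <- reactionNorms("linear",
    cbind(a = setNames(rep(0, length(ids)), ids), b = rep(0.5, length(ids))))
  traj0 <- predictTrajectories(w$ancestral, envSchedule("sudden", 20), 20,
                               nm0)
  for (t in 1:21) expect_equal(unname(traj0[t, ]),
                               unname(w$ancestral@freq))
  ## a dominant lineage sweeps monotonically in a constant environment
  w2 <- twoLineageWorld(s305 = 0.2, s25 = 0.2, g0 = c(0.1, 0.9))
  tr2 <- predictTrajectories(w2$ancestral, envSchedule("sudden", 50), 50,
                             w2$norms)
  expect_true(all(diff(tr2[, 1]) > 0))
})

test_that("crossing norms give rise-then-fall dynamics under gradual change", {
  ## intermediate-optimal lineage: favored below the crossing, disfavored
  ## above it; under the gradual ramp its frequency rises then falls
  w <- twoLineageWorld(s305 = -0.15, s25 = 0.1, g0 = c(0.5, 0.5))
  traj <- predictTrajectories(w$ancestral, envSchedule("gradual", 50), 50,
                              w$norms)
  f <- traj[, 1]
  peak <- which.max(f)
  expect_gt(peak, 1)
  expect_lt(peak, 51)
  expect_gt(f[peak], f[1])
  expect_gt(f[peak], f[51])
})

test_that("fitness moments match hand arithmetic and Fisher monotonicity", {
  w <- twoLineageWorld(g0 = c(0.5, 0.5))
  nm <- reactionNorms("linear",
    cbind(a = c(A = 0, B = 0), b = c(log(2), log(4))))
  expect_equal(meanFitness(c(0.5, 0.5), 100, w$lineages, nm), 3)
  expect_equal(fitnessVariance(c(0.5, 0.5), 100, w$lineages, nm), 1)
  ## monomorphic population: mean = lambda, variance 0
  expect_equal(meanFitness(c(1, 0), 100, w$lineages, nm), 2)
  expect_equal(fitnessVariance(c(1, 0), 100, w$lineages, nm), 0)
  ## mean fitness is non-decreasing along deterministic trajectories in a
  ## constant environment, on randomized instances
  set.seed(73)
  for (i in 1:25) {
    w <- randomWorld(n_regions = 2, n_rwh = 3, a_max = 0.003, b_max = 1)
    x <- runif(1, 25, 305)
    sched <- envSchedule("const", 30, env = rep(x, 30))
    traj <- predictTrajectories(w$ancestral, sched, 30, w$norms)
    wbar <- apply(traj, 1, meanFitness, x = x, lineages = w$lineages,
                  norms = w$norms)
    expect_true(all(diff(wbar) >= -1e-12))
  }
})

test_that("crossing points agree with closed form and a bisection oracle", {
  ## slopes 0.02 vs 0 and intercept difference 5 favoring the flat norm
  lin <- lineageSet(cbind(`1` = c("P", "Q")))
  nm <- reactionNorms("linear",
    cbind(a = c(P = 0.02, Q = 0), b = c(P = 0, Q = 5)))
  expect_equal(crossingPoints("L1", "L2", lin, nm, c(0, 400)), 250)
  ## parallel distinct norms never cross
  nm2 <- reactionNorms("linear",
    cbind(a = c(P = 0.01, Q = 0.01), b = c(P = 0, Q = 1)))
  expect_length(crossingPoints("L1", "L2", lin, nm2, c(0, 400)), 0)
  ## identical norms: infinite crossing set
  nm3 <- reactionNorms("linear",
    cbind(a = c(P = 0.01, Q = 0.01), b = c(P = 1, Q = 1)))
  expect_error(crossingPoints("L1", "L2", lin, nm3), "coincide")
  ## negative-discriminant quadratic difference
  nmq <- reactionNorms("quadratic",
    cbind(a = c(P = 1, Q = 0), b = c(P = 0, Q = 0), c = c(P = 1, Q = 0)))
  expect_length(crossingPoints("L1", "L2", lin, nmq, c(-10, 10)), 0)

  ## bisection oracle on randomized multi-region instances
  set.seed(74)
  n_checked <- 0
  for (i in 1:20) {
    w <- randomWorld(n_regions = 3, n_rwh = 2)
    ids <- lineageIds(w$lineages)[1:2]
    xs <- tryCatch(crossingPoints(ids[1], ids[2], w$lineages, w$norms,
                                  c(0, 400)),
                   error = function(e) numeric(0))
    for (x0 in xs) {
      fdiff <- function(x)
        diff(-lineageLogFitness(x, w$lineages, w$norms)[1:2])
      lo <- max(0, x0 - 25); hi <- min(400, x0 + 25)
      if (sign(fdiff(lo)) != sign(fdiff(hi))) {
        root <- uniroot(fdiff, c(lo, hi), tol = 1e-9)$root
        expect_equal(x0, root, tolerance = 1e-6)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 3)
})
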