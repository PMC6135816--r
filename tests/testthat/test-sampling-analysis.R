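test_that("local profiles count overwritten residues per stage", {
  t <- tinyTarget()
  lib9 <- tinyLib9()
  ch <- makeExtendedChain(t$sequence, t$ssTrue)
  log <- basinfold:::newTrajectoryLog(ch)
  frag <- lib9@windows[[1]][[2]]
  ch2 <- insertFragment(ch, 1L, frag)
  basinfold:::logMove(log, "stage2", 1L, "regular", 1L, 9L, 2L, TRUE, -1, 2,
                      resChanged = 1:9, chainAfter = ch2)
  prof <- localProfile(log, lib9)
  expect_equal(unname(prof$counts[, "stage2"]), c(rep(1L, 9), 0L, 0L, 0L))
  expect_true(all(prof$counts[, c("stage1", "stage3", "stage4")] == 0L))
})

test_that("sampling every library fragment once gives triplet fractions of 1", {
  t <- tinyTarget()
  lib9 <- makeLibrary(t, 9L, depth = 3L, nativeEnrichment = 0, seed = 5)
  ch <- makeExtendedChain(t$sequence, t$ssTrue)
  log <- basinfold:::newTrajectoryLog(ch)
  for (w in seq_along(lib9@windows))
    for (r in seq_along(lib9@windows[[w]])) {
      ch2 <- insertFragment(ch, w, lib9@windows[[w]][[r]])
      basinfold:::logMove(log, "stage2", 1L, "regular", w, 9L, r, TRUE, 0, 2,
                          resChanged = w:(w + 8L), chainAfter = ch2)
    }
  prof <- localProfile(log, lib9)
  expect_equal(prof$tripletFraction, rep(1, 12))
})

test_that("Hamming dissimilarities count differing upper-triangle cells", {
  m <- buildCartesian(tinyTarget()$native)
  cm <- contactMap(m)
  expect_equal(hammingMatrix(list(cm, cm))[1, 2], 0)
  ## flip exactly 3 upper-triangle cells
  m2 <- contactMatrix(cm)
  flips <- rbind(c(1, 5), c(2, 9), c(3, 12))
  for (k in 1:3) {
    i <- flips[k, 1]; j <- flips[k, 2]
    m2[i, j] <- 1L - m2[i, j]
    m2[j, i] <- m2[i, j]
  }
  cm2 <- methods::new("ContactMap", map = m2, cutoff = 8, minSep = 3L)
  expect_equal(hammingMatrix(list(cm, cm2))[1, 2], 3)
  ## random maps: elementwise XOR-sum oracle
  set.seed(20)
  maps <- lapply(1:5, function(i)
    contactMap(buildCartesian(randomChain(14, i + 40))))
  h <- hammingMatrix(maps)
  for (a in 1:4) for (b in (a + 1):5) {
    xor <- sum(contactMatrix(maps[[a]])[upper.tri(diag(14))] !=
               contactMatrix(maps[[b]])[upper.tri(diag(14))])
    expect_equal(h[a, b], xor)
    expect_equal(h[b, a], xor)
  }
  expect_true(all(diag(h) == 0))
})

test_that("classical MDS recovers Euclidean configurations exactly", {
  ## collinear points
  x <- matrix(c(0, 1, 3, 7), 4, 1)
  d <- as.matrix(dist(cbind(x, 0)))
  y <- classicalMDS(d, k = 2)
  expect_equal(as.matrix(dist(y)), d, tolerance = 1e-8, ignore_attr = TRUE)
  ## collinear input has one positive eigenvalue: output is reduced to 1-D
  expect_equal(ncol(y), 1L)
  expect_true(attr(y, "reduced"))
  ## a genuine 2-D configuration, cross-checked against stats::cmdscale
  set.seed(8)
  pts <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(pts))
  y2 <- classicalMDS(d2, k = 2)
  expect_equal(as.matrix(dist(y2)), d2, tolerance = 1e-8, ignore_attr = TRUE)
  ref <- stats::cmdscale(d2, k = 2)
  expect_equal(abs(y2), abs(ref), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(classicalMDS(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("trajectory sampling follows the cadence in both modes", {
  t <- tinyTarget()
  ch <- t$native
  log <- basinfold:::newTrajectoryLog(ch)
  for (i in 1:250)
    basinfold:::logMove(log, "stage2", 1L, "regular", 1L, 9L, 1L, TRUE, 0, 2,
                        resChanged = 1:9, chainAfter = ch)
  expect_length(sampleTrajectory(log, "accepted-move", 100L), 2L)
  expect_length(sampleTrajectory(log, "accepted-move", 1L), 250L)
  for (i in 1:5) basinfold:::logLmin(log, ch, i)
  lm <- sampleTrajectory(log, "lmin", 2L)
  expect_length(lm, 2L)
  expect_error(sampleTrajectory(log, "bogus"), "arg")
  expect_error(sampleTrajectory(log, "lmin", 0L), "cadence")
})

test_that("PAM matches exhaustive search on small instances and beats random medoids", {
  set.seed(9)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(pts))
  for (k in 2:3) {
    r <- pamCluster(d, k)
    combs <- utils::combn(8, k)
    objs <- apply(combs, 2, function(m)
      sum(apply(d[, m, drop = FALSE], 1, min)))
    expect_equal(r$objective, min(objs), tolerance = 1e-12)
  }
  ## larger instance: never worse than 100 random medoid sets, and agrees
  ## with the cluster-package implementation
  set.seed(10)
  pts <- matrix(rnorm(60), 30, 2)
  d <- as.matrix(dist(pts))
  r <- pamCluster(d, 4L)
  set.seed(11)
  for (i in 1:100) {
    m <- sample(30, 4)
    expect_lte(r$objective,
               sum(apply(d[, m, drop = FALSE], 1, min)) + 1e-12)
  }
  ref <- cluster::pam(stats::as.dist(d), 4L)
  expect_equal(r$objective, ref$objective[["swap"]] * 30, tolerance = 1e-9)
})

test_that("the Markov-state entropy is 0 when confined and 1 when uniform", {
  expect_equal(labelSequenceEntropy(rep(3L, 50), 20L), 0)
  expect_true(is.na(labelSequenceEntropy(1L, 20L)))
  set.seed(12)
  lab <- sample.int(20L, 40000L, replace = TRUE)
  expect_gt(labelSequenceEntropy(lab, 20L), 0.98)
  expect_lte(labelSequenceEntropy(lab, 20L), 1)
  ## permutation invariance under cluster relabelling
  perm <- sample(20L)
  expect_equal(labelSequenceEntropy(perm[lab], 20L),
               labelSequenceEntropy(lab, 20L), tolerance = 1e-12)
  ## occupancy variant is also normalised
  expect_equal(labelSequenceEntropy(rep(1:20, 50), 20L, "occupancy"), 1)
})

test_that("entropyMeasure clusters pooled structures and scores runs", {
  t <- tinyTarget()
  set.seed(30)
  jitterChain <- function(seed) {
    set.seed(seed)
    tor <- torsions(t$native)
    TorsionChain(t$sequence, t$ssTrue,
                 wrapAngle(tor[, 1] + runif(12, -60, 60)),
                 wrapAngle(tor[, 2] + runif(12, -60, 60)), tor[, 3])
  }
  refs <- lapply(1:20, jitterChain)
  runs <- list(lapply(21:26, jitterChain), lapply(27:32, jitterChain),
               list(jitterChain(33)))  # third run: too short
  r <- entropyMeasure(runs, c(refs, list(t$native)), nClusters = 5L)
  expect_length(r$entropy, 3L)
  expect_true(all(r$entropy[1:2] >= 0 & r$entropy[1:2] <= 1))
  expect_true(is.na(r$entropy[3]))
  expect_length(r$labels[[1]], 6L)
})

test_that("Mack-Skillings: degenerate data, Friedman reduction, permutation oracle", {
  ## all observations equal: statistic 0, p = 1
  r0 <- mackSkillings(rep(5, 12), rep(1:3, 4), rep(1:4, each = 3),
                      posthoc = FALSE)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  ## one replicate per cell reduces to the Friedman statistic
  set.seed(13)
  v <- rnorm(15)
  g <- rep(1:3, 5)
  b <- rep(1:5, each = 3)
  r <- mackSkillings(v, g, b, posthoc = FALSE)
  fr <- stats::friedman.test(matrix(v, 5, 3, byrow = TRUE))
  expect_equal(r$statistic, unname(fr$statistic), tolerance = 1e-9)
  expect_equal(r$p.value, fr$p.value, tolerance = 1e-9)
  ## 3 blocks x 3 groups x 1 replicate: the Monte-Carlo critical value
  ## converges to the exact enumeration over all within-block permutations
  set.seed(14)
  v3 <- rnorm(9)
  g3 <- rep(1:3, 3)
  b3 <- rep(1:3, each = 3)
  r3 <- mackSkillings(v3, g3, b3, alpha = 0.2, mcIterations = 20000L,
                      seed = 5)
  perms <- as.matrix(expand.grid(1:6, 1:6, 1:6))
  allPerms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                     6, 3, byrow = TRUE)
  maxDiffs <- apply(perms, 1, function(p) {
    S <- numeric(3)
    for (blk in 1:3) S <- S + allPerms[p[blk], ]
    max(dist(S))
  })
  ## the critical value must be conservative at level alpha under the exact
  ## permutation distribution, and the next-smaller atom must not be
  exactTail <- function(c) mean(maxDiffs > c)
  expect_lte(exactTail(r3$critical), r3$alpha + 0.005)
  atoms <- sort(unique(maxDiffs))
  below <- atoms[atoms < r3$critical - 1e-9]
  if (length(below)) expect_gt(exactTail(max(below)), r3$alpha - 0.02)
  expect_error(mackSkillings(v3[-1], g3[-1], b3[-1], posthoc = FALSE),
               "empty cell")
})

test_that("the RMSD kernel density integrates to one and shows modes", {
  k <- rmsdKDE(c(2, 2.1, 1.9, 8, 8.2, 7.8), bandwidth = 0.7)
  area <- sum(diff(k$x) * (head(k$y, -1) + tail(k$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  ## two far-separated groups give two modes
  dens <- k$y
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  expect_gte(length(peaks), 2L)
  ## single value: Gaussian centred at the value with sd = bandwidth
  k1 <- rmsdKDE(4, bandwidth = 0.7)
  expect_equal(k1$x[which.max(k1$y)], 4, tolerance = 0.02)
  expect_equal(max(k1$y), stats::dnorm(0, sd = 0.7), tolerance = 1e-3)
  expect_error(rmsdKDE(c(1, 2), bandwidth = 0), "bandwidth")
})
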