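test_that("the Metropolis rule accepts downhill always and uphill by exp(-dE/kT)", {
  expect_true(metropolisAccept(-0.5, 2, 0.9999))
  expect_true(metropolisAccept(0, 2, 0.999))
  expect_false(metropolisAccept(2, 2, 0.99))
  expect_true(metropolisAccept(2, 2, 0.1))
  expect_error(metropolisAccept(1, 0, 0.5), "kT")
  expect_error(metropolisAccept(1, -2, 0.5), "kT")
})

test_that("the quench controller follows the 150-rejection / reset-on-accept rule", {
  ctrl <- newTemperatureController()
  expect_equal(ctrl$kT, 2)
  for (i in 1:149) ctrl <- updateTemperature(ctrl, FALSE)
  expect_equal(ctrl$kT, 2)
  ctrl <- updateTemperature(ctrl, FALSE)   # 150th consecutive rejection
  expect_equal(ctrl$kT, 3)
  ## continue to 450 consecutive rejections in total
  for (i in 1:300) ctrl <- updateTemperature(ctrl, FALSE)
  expect_equal(ctrl$kT, 5)
  ctrl <- updateTemperature(ctrl, TRUE)    # any acceptance resets
  expect_equal(ctrl$kT, 2)
  expect_equal(ctrl$counter, 0L)
  ## 149 rejections then an acceptance never raises the temperature
  c2 <- newTemperatureController()
  for (i in 1:149) c2 <- updateTemperature(c2, FALSE)
  c2 <- updateTemperature(c2, TRUE)
  expect_equal(c2$kT, 2)
})

test_that("the quench temperature trace is reproduced by a brute-force replay", {
  replayOracle <- function(acc, base = 2, threshold = 150L, step = 1) {
    kT <- numeric(length(acc))
    cur <- base
    rej <- 0L
    for (i in seq_along(acc)) {
      kT[i] <- cur          # temperature used for decision i
      if (acc[i]) {
        cur <- base
        rej <- 0L
      } else {
        rej <- rej + 1L
        if (rej >= threshold) {
          cur <- cur + step
          rej <- 0L
        }
      }
    }
    kT
  }
  for (seed in 1:3) {
    set.seed(seed)
    acc <- runif(2000) < 0.002    # rare acceptances so quenching kicks in
    ctrl <- newTemperatureController()
    kT <- numeric(length(acc))
    for (i in seq_along(acc)) {
      kT[i] <- ctrl$kT
      ctrl <- updateTemperature(ctrl, acc[i])
    }
    expect_identical(kT, replayOracle(acc))
    expect_gt(max(kT), 2)   # quenching fired at least once
  }
})

test_that("empirical acceptance frequency matches exp(-dE/kT) within 3 sigma", {
  set.seed(7)
  n <- 10000L
  u <- runif(n)
  rate <- mean(vapply(u, function(x) metropolisAccept(1.5, 2, x), TRUE))
  p <- exp(-1.5 / 2)
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("stage budgets follow the defaults and the increase_cycles multiplier", {
  b1 <- stageBudgets(baselineConfig())
  expect_equal(b1$stage1, 2000L)
  expect_equal(b1$stage2, 2000L)
  expect_equal(b1$stage3PerSubstage, 4000L)
  expect_equal(b1$stage4Regular, 4000L)
  expect_equal(b1$stage4Gunn, 8000L)
  b10 <- stageBudgets(baselineConfig(increaseCycles = 10))
  expect_equal(b10$stage1, 20000L)
  expect_equal(b10$stage4Gunn, 80000L)
  ## fractional multipliers floor with a minimum of 1
  bf <- stageBudgets(baselineConfig(increaseCycles = 0.0001))
  expect_equal(bf$stage1, 1L)
})

test_that("stage 1 stops once every residue has been altered, or on budget", {
  t <- tinyTarget()
  set.seed(21)
  r <- runStage1(makeExtendedChain(t$sequence, t$ssTrue), tinyLib9(),
                 baselineConfig(increaseCycles = 0.5))
  expect_equal(r$reason, "all residues altered")
  expect_lte(r$attempts, 1000L)
  set.seed(21)
  r1 <- runStage1(makeExtendedChain(t$sequence, t$ssTrue), tinyLib9(),
                  baselineConfig(increaseCycles = 0.0001))
  expect_equal(r1$attempts, 1L)
  expect_equal(r1$reason, "budget")
})

test_that("stage 3 runs 10 substages, converges early on static structures", {
  t <- tinyTarget()
  cfg <- baselineConfig(increaseCycles = 0.01, convergenceRmsd = NA)
  set.seed(4)
  r <- runStage3(t$native, tinyLib9(), cfg)
  expect_equal(r$attempts, rep(40L, 10L))   # convergence disabled: full budget
  expect_false(any(r$converged))
  ## a library whose only fragments equal the current torsions: every move is
  ## accepted (dE = 0) but nothing varies, so each substage converges right
  ## after the 100-accepted-move check
  nat <- t$native
  idx9 <- lapply(1:4, function(w) w:(w + 8))
  staticLib <- FragmentLibrary(lapply(idx9, function(ix)
    list(Fragment(torsions(nat)[ix, ]))), 9L)
  cfg2 <- baselineConfig(increaseCycles = 0.1)   # 400 per substage
  set.seed(4)
  r2 <- runStage3(nat, staticLib, cfg2)
  expect_true(all(r2$converged))
  expect_true(all(r2$attempts == 100L))
})

test_that("stage 4 runs its two phases at the configured lengths", {
  t <- tinyTarget()
  set.seed(9)
  r <- runStage4(t$native, tinyLib3(), baselineConfig(increaseCycles = 0.005))
  expect_equal(unname(r$attempts), c(20L, 40L))
  tab <- moveTable(r$log)
  expect_equal(sum(tab$phase == "regular"), 20L)
  expect_equal(sum(tab$phase == "gunn"), 40L)
  ## the basin-hopping protocols shorten stage 4 by a factor of 10
  b <- stageBudgets(baselineConfig(stage4LengthFactor = 0.1))
  expect_equal(b$stage4Regular, 400L)
  expect_equal(b$stage4Gunn, 800L)
})

test_that("baseline runs are reproducible and keep the evaluation ledger consistent", {
  t <- tinyTarget()
  a <- runBaseline(t$sequence, t$ssTrue, tinyLib9(), tinyLib3(),
                   increaseCycles = 0.01, seed = 17)
  b <- runBaseline(t$sequence, t$ssTrue, tinyLib9(), tinyLib3(),
                   increaseCycles = 0.01, seed = 17)
  expect_identical(moveTable(a$log), moveTable(b$log))
  expect_identical(torsions(a$decoy), torsions(b$decoy))
  ## one scoring call per attempted move
  expect_equal(ledgerTotal(a$ledger), nrow(moveTable(a$log)))
  ## budget conservation: stages 2-4 at their exact budgets, stage 1 may stop
  ## early
  tab <- moveTable(a$log)
  expect_equal(sum(tab$stage == "stage2"), 20L)
  expect_lte(sum(tab$stage == "stage1"), 20L)
  expect_equal(sum(tab$stage == "stage4"), 120L)   # 40 regular + 80 gunn
})

test_that("gunn-phase moves displace the rest of the chain less than regular moves", {
  t <- tinyTarget()
  lib3 <- tinyLib3()
  disp <- function(biased, seed) {
    set.seed(seed)
    mean(replicate(40, {
      if (biased) {
        mv <- gunnBiasedMove(t$native, lib3)
        mv$penalty
      } else {
        mv <- basinfold:::drawMove(lib3)
        cand <- insertFragment(t$native, mv$window, mv$frag)
        gunnPenalty(t$native, cand, mv$window, 3L)
      }
    }))
  }
  biased <- vapply(1:20, function(s) disp(TRUE, s), numeric(1))
  regular <- vapply(1:20, function(s) disp(FALSE, s), numeric(1))
  expect_true(all(biased < regular))
})
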