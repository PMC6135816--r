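## Basin-hopping search: alternating forced perturbation and greedy local
## search over fragment insertions, an archive of the lowest-scoring local
## minima, and a simulated-annealing Metropolis comparison of successive
## local minima. Two move rule sets: "bilevel" (perturbation alters loop
## residues, local search alters secondary-structure elements, terminal
## loops are never touched) and "ils" (both operators act anywhere).

#' Insert a candidate into a best-score archive
#'
#' Keeps the `capacity` lowest-scoring candidates seen so far, in ascending
#' score order. On a tie with the current worst retained score, the earlier
#' candidate is kept.
#'
#' @param archive an [Archive-class].
#' @param structure the candidate structure (stored as-is).
#' @param score finite candidate score.
#' @return list with `archive` (updated) and `retained` (logical).
#' @export
archiveInsert <- function(archive, structure, score) {
  if (!is.finite(score)) stop("score must be finite")
  k <- length(archive@scores)
  if (k == archive@capacity && score >= archive@scores[k])
    return(list(archive = archive, retained = FALSE))
  ## insert after any equal scores (earlier candidates rank first on ties)
  pos <- sum(archive@scores <= score) + 1L
  archive@scores <- append(archive@scores, score, after = pos - 1L)
  archive@members <- append(archive@members, list(structure), after = pos - 1L)
  if (length(archive@scores) > archive@capacity) {
    archive@scores <- archive@scores[seq_len(archive@capacity)]
    archive@members <- archive@members[seq_len(archive@capacity)]
  }
  list(archive = archive, retained = TRUE)
}

#' Partition residues into move roles
#'
#' Derives per-residue roles from the predicted secondary structure:
#' `element` for H/E residues, `terminal-loop` for the maximal runs of L
#' touching either terminus, `loop` for all other L residues. Under the
#' `bilevel` rule set perturbation may only alter `loop` residues and local
#' search only `element` residues (terminal loops are altered by neither);
#' under `ils` both operators alter full insertion windows.
#'
#' @param ss secondary-structure string or vector (H/E/L).
#' @param ruleSet `"bilevel"` or `"ils"`.
#' @return list with `roles` (character per residue) and `ruleSet`.
#' @export
movePartition <- function(ss, ruleSet = c("bilevel", "ils")) {
  ruleSet <- match.arg(ruleSet)
  if (length(ss) == 1L && nchar(ss) > 1L) ss <- strsplit(ss, "")[[1]]
  n <- length(ss)
  roles <- ifelse(ss == "L", "loop", "element")
  i <- 1L
  while (i <= n && ss[i] == "L") {
    roles[i] <- "terminal-loop"
    i <- i + 1L
  }
  i <- n
  while (i >= 1L && ss[i] == "L") {
    roles[i] <- "terminal-loop"
    i <- i - 1L
  }
  list(roles = roles, ruleSet = ruleSet)
}

## residues a bilevel operator may overwrite inside a window
bilevelTargets <- function(partition, window, L, what) {
  idx <- window:(window + L - 1L)
  idx[partition$roles[idx] == what]
}

## windows (of length L over n residues) containing >= 1 residue of a role
eligibleWindows <- function(partition, L, what) {
  n <- length(partition$roles)
  wins <- seq_len(windowCount(n, L))
  keep <- vapply(wins, function(w)
    any(partition$roles[w:(w + L - 1L)] == what), TRUE)
  wins[keep]
}

applyPartialInsertion <- function(chain, window, frag, targets) {
  off <- targets - window + 1L
  chain@phi[targets] <- frag@torsions[off, 1L]
  chain@psi[targets] <- frag@torsions[off, 2L]
  chain@omega[targets] <- frag@torsions[off, 3L]
  chain
}

#' Forced perturbation step
#'
#' Performs one fragment insertion that is accepted unconditionally (no
#' score evaluation). Under `bilevel`, the window is drawn uniformly from
#' 9-mer windows containing at least one non-terminal loop residue and only
#' those loop residues are overwritten; under `ils` any window may be drawn
#' and the full window is overwritten.
#'
#' @param chain current [TorsionChain-class].
#' @param lib9 9-mer [FragmentLibrary-class].
#' @param partition a [movePartition()].
#' @return list with `chain`, `window`, `rank`, `resChanged`.
#' @export
perturbation <- function(chain, lib9, partition) {
  L <- lib9@fragLength
  if (partition$ruleSet == "bilevel") {
    wins <- intersect(seq_along(lib9@windows),
                      eligibleWindows(partition, L, "loop"))
    if (!length(wins))
      stop("no legal perturbation: no non-terminal loop residues")
    w <- wins[sample.int(length(wins), 1L)]
    r <- sample.int(length(lib9@windows[[w]]), 1L)
    frag <- lib9@windows[[w]][[r]]
    targets <- bilevelTargets(partition, w, L, "loop")
    chain <- applyPartialInsertion(chain, w, frag, targets)
  } else {
    mv <- drawMove(lib9)
    w <- mv$window
    r <- mv$rank
    targets <- w:(w + L - 1L)
    chain <- insertFragment(chain, w, mv$frag)
  }
  list(chain = chain, window = w, rank = r, resChanged = targets)
}

#' Greedy local search
#'
#' Proposes fragment insertions and keeps one iff it strictly lowers the
#' score; stops after `budget` proposals, `maxFail` consecutive failures, or
#' when the global scoring-call budget is exhausted. Under `bilevel` only
#' element (H/E) residues inside the window are overwritten.
#'
#' @param chain starting [TorsionChain-class] (typically just perturbed).
#' @param lib a [FragmentLibrary-class].
#' @param partition a [movePartition()].
#' @param fn a [ScoreFunction-class].
#' @param budget maximum proposals (default 50).
#' @param maxFail consecutive-failure cutoff (default 20).
#' @param ledger evaluation ledger (counted: the initial state evaluation
#'   plus one call per proposal).
#' @param log optional [TrajectoryLog-class]; accepted moves are recorded.
#' @param globalBudget optional cap on `ledgerTotal(ledger)`: the search
#'   truncates when reached.
#' @param startScore optional known score of `chain` (skips the initial
#'   evaluation).
#' @return list with `chain` (the local minimum), `score`, `acceptedMoves`.
#' @export
localSearch <- function(chain, lib, partition, fn, budget = 50L,
                        maxFail = 20L, ledger = NULL, log = NULL,
                        globalBudget = Inf, startScore = NULL) {
  stopifnot(budget >= 1L)
  L <- lib@fragLength
  bilevel <- partition$ruleSet == "bilevel"
  wins <- seq_along(lib@windows)   # the library defines the window universe
  if (bilevel)
    wins <- intersect(wins, eligibleWindows(partition, L, "element"))
  if (!length(wins)) stop("no legal local-search window")
  if (is.null(startScore)) {
    if (!is.null(ledger) && ledger$total >= globalBudget)
      return(list(chain = chain, score = NA_real_, acceptedMoves = 0L))
    startScore <- scoreChain(chain, fn, ledger, "local_search")
  }
  cur <- chain
  curScore <- startScore
  fails <- 0L
  nAcc <- 0L
  for (i in seq_len(budget)) {
    if (!is.null(ledger) && ledger$total >= globalBudget) break
    w <- wins[sample.int(length(wins), 1L)]
    r <- sample.int(length(lib@windows[[w]]), 1L)
    frag <- lib@windows[[w]][[r]]
    targets <- if (bilevel) bilevelTargets(partition, w, L, "element")
               else w:(w + L - 1L)
    cand <- applyPartialInsertion(cur, w, frag, targets)
    candScore <- scoreChain(cand, fn, ledger, "local_search")
    if (candScore < curScore) {
      if (!is.null(log))
        logMove(log, "stage3", 1L, "local_search", w, L, r, TRUE,
                candScore - curScore, NA_real_, resChanged = targets,
                chainAfter = cand)
      cur <- cand
      curScore <- candScore
      fails <- 0L
      nAcc <- nAcc + 1L
    } else {
      if (!is.null(log))
        logMove(log, "stage3", 1L, "local_search", w, L, r, FALSE,
                candScore - curScore, NA_real_)
      fails <- fails + 1L
      if (fails >= maxFail) break
    }
  }
  list(chain = cur, score = curScore, acceptedMoves = nAcc)
}

#' Geometric annealing schedule for local-minimum comparisons
#'
#' Temperature cools geometrically from `tStart` to `tEnd` over `total`
#' comparisons, so more disruptive transitions between local minima are
#' accepted near the start of a run and conservative ones towards the end.
#'
#' @param tStart,tEnd start/end temperatures in score units (defaults 2.5,
#'   0.5; `tEnd` > 0).
#' @param total number of comparisons covered by the schedule.
#' @return an annealing schedule list.
#' @export
annealingSchedule <- function(tStart = 2.5, tEnd = 0.5, total = 100L) {
  stopifnot(tEnd > 0, tStart >= tEnd, total >= 1L)
  list(tStart = tStart, tEnd = tEnd, total = as.integer(total))
}

#' Temperature at a schedule step
#' @param schedule an [annealingSchedule()].
#' @param step 0-based comparison index, `0 <= step < total`.
#' @return temperature in score units.
#' @export
temperatureAt <- function(schedule, step) {
  if (step < 0L || step >= schedule$total) stop("step beyond schedule")
  if (schedule$total == 1L) return(schedule$tStart)
  schedule$tStart *
    (schedule$tEnd / schedule$tStart)^(step / (schedule$total - 1L))
}

#' Metropolis comparison of successive local minima
#'
#' @param prevScore,newScore scores of the previous and new local minimum.
#' @param schedule an [annealingSchedule()].
#' @param step 0-based comparison index.
#' @param u uniform deviate in \[0, 1).
#' @return logical: accept the new local minimum as the new incumbent.
#' @export
lminAcceptance <- function(prevScore, newScore, schedule, step, u) {
  metropolisAccept(newScore - prevScore, temperatureAt(schedule, step), u)
}

#' Basin-hopping configuration
#'
#' @param archiveSize archive capacity (default 10).
#' @param tStart,tEnd annealing temperatures (defaults 2.5, 0.5).
#' @param lsBudget local-search proposals per iteration (default 50).
#' @param lsMaxFail local-search consecutive-failure cutoff (default 20).
#' @param perturbCount fragment insertions per perturbation step (default 1).
#' @param scoreSet name of the weight set used throughout the basin-hopping
#'   segment (default "score3", the full set).
#' @return a config list.
#' @export
basinHoppingConfig <- function(archiveSize = 10L, tStart = 2.5, tEnd = 0.5,
                               lsBudget = 50L, lsMaxFail = 20L,
                               perturbCount = 1L, scoreSet = "score3") {
  list(archiveSize = as.integer(archiveSize), tStart = tStart, tEnd = tEnd,
       lsBudget = as.integer(lsBudget), lsMaxFail = as.integer(lsMaxFail),
       perturbCount = as.integer(perturbCount), scoreSet = scoreSet)
}

#' Run a basin-hopping protocol (bilevel or ILS)
#'
#' Stage 1 (randomisation) is identical to the baseline protocol. The stage
#' 2-3 region is replaced by alternating forced perturbation and greedy
#' local search; every local minimum is considered for the archive of the
#' `archiveSize` lowest-scoring minima, and successive minima are compared
#' with a Metropolis criterion under a geometric annealing schedule. The
#' segment ends when `budget` scoring calls have been consumed. Finally a
#' shortened stage 4 (regular + conservative 3-mer moves, budgets reduced by
#' `stage4LengthFactor = 1/10`) polishes each archived structure
#' independently; polished structures replace their pre-polish versions
#' one-to-one and the archive is re-sorted by polished score.
#'
#' @param sequence amino-acid string.
#' @param ss predicted secondary-structure string (H/E/L).
#' @param lib9,lib3 fragment libraries.
#' @param variant `"bilevel"` or `"ils"`.
#' @param budget total scoring-call budget for stage 1 + the basin-hopping
#'   segment (must exceed the stage-1 cost).
#' @param seed RNG seed.
#' @param config [baselineConfig()] for stage 1/4 (the stage-4 length factor
#'   defaults to 1/10 here).
#' @param bhConfig [basinHoppingConfig()].
#' @param recordAccepted store accepted-move snapshots.
#' @return list with `archive` ([Archive-class], polished), `log`, `ledger`,
#'   `comparisons` (number of local-minimum comparisons), `variant`.
#' @export
runBasinHopping <- function(sequence, ss, lib9, lib3,
                            variant = c("bilevel", "ils"), budget = 20000L,
                            seed = 1L, config = baselineConfig(
                              stage4LengthFactor = 0.1),
                            bhConfig = basinHoppingConfig(),
                            recordAccepted = TRUE) {
  variant <- match.arg(variant)
  ## force all arguments before seeding: lazily evaluated arguments may
  ## themselves draw from or reset the RNG
  force(sequence); force(ss); force(lib9); force(lib3); force(budget)
  force(config); force(bhConfig)
  set.seed(seed)
  chain <- makeExtendedChain(sequence, ss)
  partition <- movePartition(chainSS(chain), variant)
  log <- newTrajectoryLog(chain, seed, recordAccepted)
  ledger <- newLedger()
  s1 <- runStage1(chain, lib9, config, log, ledger)
  if (ledger$total >= budget)
    stop("budget must exceed the stage-1 scoring cost")
  fn <- config$sets[[bhConfig$scoreSet]]
  ## schedule length: expected number of LMin comparisons in the remaining
  ## budget, assuming full-length local searches
  remaining <- budget - ledger$total
  sched <- annealingSchedule(bhConfig$tStart, bhConfig$tEnd,
                             max(2L, ceiling(remaining /
                                             (bhConfig$lsBudget + 1L))))
  archive <- Archive(bhConfig$archiveSize)
  cur <- s1$chain
  curScore <- scoreChain(cur, fn, ledger, "basin_hopping")
  step <- 0L
  while (ledger$total < budget) {
    pchain <- cur
    for (p in seq_len(bhConfig$perturbCount)) {
      pt <- perturbation(pchain, lib9, partition)
      pchain <- pt$chain
      logMove(log, "stage2", 1L, "perturbation", pt$window,
              lib9@fragLength, pt$rank, TRUE, NA_real_, NA_real_,
              resChanged = pt$resChanged, chainAfter = pchain)
    }
    ls <- localSearch(pchain, lib9, partition, fn, bhConfig$lsBudget,
                      bhConfig$lsMaxFail, ledger, log, globalBudget = budget)
    if (is.na(ls$score)) break
    logLmin(log, ls$chain, ls$score)
    archive <- archiveInsert(archive, ls$chain, ls$score)$archive
    u <- stats::runif(1L)
    if (lminAcceptance(curScore, ls$score, sched,
                       min(step, sched$total - 1L), u)) {
      cur <- ls$chain
      curScore <- ls$score
    }
    step <- step + 1L
  }
  ## stage-4 polishing, applied independently to each archived structure
  polished <- archive
  if (length(archive@scores)) {
    newScores <- numeric(length(archive@scores))
    newMembers <- vector("list", length(archive@scores))
    for (i in seq_along(archive@members)) {
      s4 <- runStage4(archive@members[[i]], lib3, config, log, ledger)
      newMembers[[i]] <- s4$chain
      newScores[i] <- scoreChain(s4$chain, config$sets$score3)
    }
    ord <- order(newScores)
    polished <- new("Archive", capacity = archive@capacity,
                    scores = newScores[ord], members = newMembers[ord])
  }
  list(archive = polished, log = log, ledger = ledger, comparisons = step,
       variant = variant)
}
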