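## Metropolis acceptance, the quenching temperature controller, the
## trajectory log, and the four-stage baseline sampling protocol.

#' Metropolis acceptance rule
#'
#' Accepts a move iff its score change is non-positive, or with probability
#' `exp(-deltaE / kT)` otherwise (compared against the supplied uniform
#' deviate, so the decision is a pure function of its arguments).
#'
#' @param deltaE score change of the proposed move.
#' @param kT temperature parameter (> 0, score units).
#' @param u uniform random number in \[0, 1).
#' @return logical: accept the move.
#' @examples
#' metropolisAccept(-0.5, 2, 0.99)  # TRUE: downhill always accepted
#' @export
metropolisAccept <- function(deltaE, kT, u) {
  if (kT <= 0) stop("kT must be positive")
  deltaE <= 0 || u < exp(-deltaE / kT)
}

#' Quenching temperature controller
#'
#' The sampler runs at a mostly constant temperature (default 2 kT units).
#' Every `threshold` (default 150) consecutive rejected insertions raise the
#' temperature by `step` (default 1 kT unit); this can happen repeatedly. Any
#' acceptance resets the temperature to its base value, regardless of the
#' level reached, and zeroes the rejection counter.
#'
#' @param base base temperature in kT units (default 2).
#' @param threshold consecutive rejections triggering a raise (default 150).
#' @param step temperature increment in kT units (default 1).
#' @return a controller list with fields `kT`, `base`, `counter`,
#'   `threshold`, `step`.
#' @export
newTemperatureController <- function(base = 2, threshold = 150L, step = 1) {
  list(kT = base, base = base, counter = 0L, threshold = as.integer(threshold),
       step = step)
}

#' Update the quench controller after a move decision
#'
#' @param ctrl controller from [newTemperatureController()].
#' @param accepted logical: was the move accepted?
#' @return the updated controller.
#' @export
updateTemperature <- function(ctrl, accepted) {
  if (accepted) {
    ctrl$counter <- 0L
    ctrl$kT <- ctrl$base
  } else {
    ctrl$counter <- ctrl$counter + 1L
    if (ctrl$counter >= ctrl$threshold) {
      ctrl$kT <- ctrl$kT + ctrl$step
      ctrl$counter <- 0L
    }
  }
  ctrl
}

## Trajectory log -------------------------------------------------------------

LOG_CHUNK <- 4096L

#' Create a trajectory log
#'
#' @param chain the starting [TorsionChain-class] (template for snapshots).
#' @param seed the run seed, recorded for reproducibility.
#' @param recordAccepted store a torsion snapshot for every accepted move
#'   (enables accepted-move trajectory sampling; default TRUE).
#' @return a [TrajectoryLog-class].
#' @export
newTrajectoryLog <- function(chain, seed = NA_integer_, recordAccepted = TRUE) {
  e <- new.env(parent = emptyenv())
  e$seed <- seed
  e$template <- chain
  e$n <- 0L
  e$cap <- LOG_CHUNK
  e$stage <- character(LOG_CHUNK)
  e$substage <- integer(LOG_CHUNK)
  e$phase <- character(LOG_CHUNK)
  e$window <- integer(LOG_CHUNK)
  e$fragLen <- integer(LOG_CHUNK)
  e$rank <- integer(LOG_CHUNK)
  e$accepted <- logical(LOG_CHUNK)
  e$deltaE <- numeric(LOG_CHUNK)
  e$kT <- numeric(LOG_CHUNK)
  e$nAccepted <- 0L
  e$resChanged <- list()      # per accepted move: overwritten residue indices
  e$accSnaps <- list()        # per accepted move: torsion matrix snapshot
  e$recordAccepted <- isTRUE(recordAccepted)
  e$lminSnaps <- list()       # basin-hopping: one snapshot per local minimum
  e$lminScores <- numeric(0)
  new("TrajectoryLog", env = e)
}

logMove <- function(log, stage, substage, phase, window, fragLen, rank,
                    accepted, deltaE, kT, resChanged = NULL,
                    chainAfter = NULL) {
  e <- log@env
  if (e$n == e$cap) {
    grow <- function(v) c(v, vector(mode(v), LOG_CHUNK))
    for (f in c("stage", "phase")) assign(f, grow(get(f, e)), e)
    for (f in c("substage", "window", "fragLen", "rank"))
      assign(f, grow(get(f, e)), e)
    e$accepted <- c(e$accepted, logical(LOG_CHUNK))
    e$deltaE <- c(e$deltaE, numeric(LOG_CHUNK))
    e$kT <- c(e$kT, numeric(LOG_CHUNK))
    e$cap <- e$cap + LOG_CHUNK
  }
  i <- e$n + 1L
  e$n <- i
  e$stage[i] <- stage
  e$substage[i] <- substage
  e$phase[i] <- phase
  e$window[i] <- window
  e$fragLen[i] <- fragLen
  e$rank[i] <- rank
  e$accepted[i] <- accepted
  e$deltaE[i] <- deltaE
  e$kT[i] <- kT
  if (accepted) {
    k <- e$nAccepted + 1L
    e$nAccepted <- k
    e$resChanged[[k]] <- as.integer(resChanged)
    if (e$recordAccepted && !is.null(chainAfter))
      e$accSnaps[[k]] <- torsions(chainAfter)
  }
  invisible(log)
}

logLmin <- function(log, chain, score) {
  e <- log@env
  k <- length(e$lminScores) + 1L
  e$lminSnaps[[k]] <- torsions(chain)
  e$lminScores[k] <- score
  invisible(log)
}

#' Move table of a trajectory log
#' @param log a [TrajectoryLog-class].
#' @return data.frame with one row per attempted move (stage, substage,
#'   phase, window, fragLen, rank, accepted, deltaE, kT).
#' @export
moveTable <- function(log) {
  e <- log@env
  i <- seq_len(e$n)
  data.frame(stage = e$stage[i], substage = e$substage[i], phase = e$phase[i],
             window = e$window[i], fragLen = e$fragLen[i], rank = e$rank[i],
             accepted = e$accepted[i], deltaE = e$deltaE[i], kT = e$kT[i])
}

#' Accepted-move and local-minimum counts of a log
#' @param log a [TrajectoryLog-class].
#' @return integer count.
#' @export
acceptedCount <- function(log) log@env$nAccepted

#' @rdname acceptedCount
#' @export
lminCount <- function(log) length(log@env$lminScores)

chainFromSnapshot <- function(template, tors) {
  TorsionChain(template@sequence, template@ss, tors[, 1L], tors[, 2L],
               tors[, 3L])
}

#' Residues overwritten by each accepted move
#' @param log a [TrajectoryLog-class].
#' @return list of integer vectors, one per accepted move.
#' @export
acceptedResidues <- function(log) log@env$resChanged

setMethod("show", "TrajectoryLog", function(object) {
  e <- object@env
  cat(sprintf("TrajectoryLog: %d attempts, %d accepted, %d local minima\n",
              e$n, e$nAccepted, length(e$lminScores)))
})

## Stage machinery ------------------------------------------------------------

#' Baseline protocol configuration
#'
#' Default per-stage move budgets (2000; 2000; 10 x 4000; 4000 + 8000) and
#' the control parameters of the staged protocol. `increaseCycles`
#' multiplies every stage budget; `stage4LengthFactor` shrinks stage 4 (the
#' basin-hopping protocols use 1/10 so that polishing each archived decoy
#' costs a tenth of a standard stage 4). Budgets are rounded down with a
#' floor of 1, so fractional multipliers can be used for desk-scale runs.
#'
#' @param increaseCycles budget multiplier (default 1).
#' @param stage4LengthFactor stage-4 budget shrink factor (default 1).
#' @param kTBase,rejectionThreshold,kTStep quench controller settings
#'   (defaults 2, 150, 1).
#' @param convergenceRmsd stage-3 convergence threshold in Angstroms
#'   (default 3); set to `NA` to disable the convergence check.
#' @param convergenceEvery accepted-move cadence of the stage-3 convergence
#'   check (default 100).
#' @param gunnDraws candidate draws per conservative stage-4 move (default 10).
#' @param sets score weight sets (default [defaultWeightSets()]).
#' @return a config list.
#' @export
baselineConfig <- function(increaseCycles = 1, stage4LengthFactor = 1,
                           kTBase = 2, rejectionThreshold = 150L, kTStep = 1,
                           convergenceRmsd = 3, convergenceEvery = 100L,
                           gunnDraws = 10L, sets = defaultWeightSets()) {
  list(increaseCycles = increaseCycles,
       stage4LengthFactor = stage4LengthFactor,
       kTBase = kTBase, rejectionThreshold = as.integer(rejectionThreshold),
       kTStep = kTStep, convergenceRmsd = convergenceRmsd,
       convergenceEvery = as.integer(convergenceEvery),
       gunnDraws = as.integer(gunnDraws), sets = sets)
}

#' Per-stage move budgets
#' @param config a [baselineConfig()] list.
#' @return named list: stage1, stage2, stage3PerSubstage, stage4Regular,
#'   stage4Gunn (all after applying the multipliers, floored at 1).
#' @export
stageBudgets <- function(config) {
  mult <- config$increaseCycles
  f <- function(x) max(1L, as.integer(floor(x)))
  list(stage1 = f(2000 * mult), stage2 = f(2000 * mult),
       stage3PerSubstage = f(4000 * mult),
       stage4Regular = f(4000 * mult * config$stage4LengthFactor),
       stage4Gunn = f(8000 * mult * config$stage4LengthFactor))
}

## One standard Metropolis fragment-insertion attempt; returns updated state.
attemptMove <- function(state, lib, fn, stageLab, substage, phase, log,
                        ledger, config) {
  mv <- drawMove(lib)
  cand <- insertFragment(state$chain, mv$window, mv$frag)
  candScore <- scoreChain(cand, fn, ledger, stageLab)
  dE <- candScore - state$score
  u <- stats::runif(1L)
  acc <- metropolisAccept(dE, state$ctrl$kT, u)
  kTUsed <- state$ctrl$kT
  state$ctrl <- updateTemperature(state$ctrl, acc)
  L <- lib@fragLength
  logMove(log, stageLab, substage, phase, mv$window, L, mv$rank, acc, dE,
          kTUsed, resChanged = mv$window:(mv$window + L - 1L),
          chainAfter = if (acc) cand)
  if (acc) {
    state$chain <- cand
    state$score <- candScore
  }
  state
}

newSearchState <- function(chain, fn, config) {
  list(chain = chain,
       score = scoreChain(chain, fn),   # cached baseline, not ledger-counted
       ctrl = newTemperatureController(config$kTBase,
                                       config$rejectionThreshold,
                                       config$kTStep))
}

#' Stage 1: conformational randomisation
#'
#' 9-mer insertions under the clash-dominated score, starting from the
#' extended conformation, until every residue has been altered at least once
#' by an accepted move or the budget is exhausted.
#'
#' @param chain starting [TorsionChain-class] (normally extended).
#' @param lib9 9-mer [FragmentLibrary-class].
#' @param config a [baselineConfig()].
#' @param log a [newTrajectoryLog()] (created if NULL).
#' @param ledger an evaluation ledger (created if NULL).
#' @return list with `chain`, `log`, `ledger`, `attempts`, `reason`.
#' @export
runStage1 <- function(chain, lib9, config = baselineConfig(), log = NULL,
                      ledger = NULL) {
  if (is.null(log)) log <- newTrajectoryLog(chain)
  if (is.null(ledger)) ledger <- newLedger()
  fn <- stageScoreSchedule(1L, sets = config$sets)
  budget <- stageBudgets(config)$stage1
  state <- newSearchState(chain, fn, config)
  altered <- logical(length(chain))
  attempts <- 0L
  reason <- "budget"
  while (attempts < budget) {
    attempts <- attempts + 1L
    accBefore <- acceptedCount(log)
    state <- attemptMove(state, lib9, fn, "stage1", 1L, "regular", log,
                         ledger, config)
    if (acceptedCount(log) > accBefore) {
      mv <- log@env
      altered[mv$resChanged[[acceptedCount(log)]]] <- TRUE
      if (all(altered)) {
        reason <- "all residues altered"
        break
      }
    }
  }
  list(chain = state$chain, log = log, ledger = ledger, attempts = attempts,
       reason = reason)
}

#' Stage 2: 9-mer sampling under the score1 analogue
#' @inheritParams runStage1
#' @return list with `chain`, `log`, `ledger`, `attempts`.
#' @export
runStage2 <- function(chain, lib9, config = baselineConfig(), log = NULL,
                      ledger = NULL) {
  if (is.null(log)) log <- newTrajectoryLog(chain)
  if (is.null(ledger)) ledger <- newLedger()
  fn <- stageScoreSchedule(2L, sets = config$sets)
  budget <- stageBudgets(config)$stage2
  state <- newSearchState(chain, fn, config)
  for (i in seq_len(budget))
    state <- attemptMove(state, lib9, fn, "stage2", 1L, "regular", log,
                         ledger, config)
  list(chain = state$chain, log = log, ledger = ledger, attempts = budget)
}

#' Stage 3: ten substages with alternating scores and a convergence check
#'
#' Each substage runs up to its budget of 9-mer insertions under one of two
#' alternating weight sets. Every `convergenceEvery` accepted insertions the
#' current structure is compared (C-alpha RMSD) to a rolling reference; if
#' the structure has not varied by at least `convergenceRmsd` the substage
#' terminates early. The reference is updated at every check.
#'
#' @inheritParams runStage1
#' @return list with `chain`, `log`, `ledger`, `attempts` (per substage
#'   vector), `converged` (logical per substage).
#' @export
runStage3 <- function(chain, lib9, config = baselineConfig(), log = NULL,
                      ledger = NULL) {
  if (is.null(log)) log <- newTrajectoryLog(chain)
  if (is.null(ledger)) ledger <- newLedger()
  budget <- stageBudgets(config)$stage3PerSubstage
  attempts <- integer(10L)
  converged <- logical(10L)
  cur <- chain
  for (sub in 1:10) {
    fn <- stageScoreSchedule(3L, sub, sets = config$sets)
    state <- newSearchState(cur, fn, config)
    ref <- buildCartesian(state$chain)
    accSince <- 0L
    for (i in seq_len(budget)) {
      attempts[sub] <- attempts[sub] + 1L
      accBefore <- acceptedCount(log)
      state <- attemptMove(state, lib9, fn, "stage3", sub, "regular", log,
                           ledger, config)
      if (acceptedCount(log) > accBefore) accSince <- accSince + 1L
      if (!is.na(config$convergenceRmsd) &&
          accSince >= config$convergenceEvery) {
        curModel <- buildCartesian(state$chain)
        moved <- caRMSD(curModel, ref)
        ref <- curModel
        accSince <- 0L
        if (moved < config$convergenceRmsd) {
          converged[sub] <- TRUE
          break
        }
      }
    }
    cur <- state$chain
  }
  list(chain = cur, log = log, ledger = ledger, attempts = attempts,
       converged = converged)
}

#' Stage 4: 3-mer refinement with a conservative second phase
#'
#' First `stage4Regular` standard 3-mer insertion attempts, then
#' `stage4Gunn` attempts using the conservative insertion operator that
#' samples several candidates and proposes the one with minimal lever-arm
#' penalty ([gunnBiasedMove()]). No convergence check is applied.
#'
#' @inheritParams runStage1
#' @param lib3 3-mer [FragmentLibrary-class].
#' @return list with `chain`, `log`, `ledger`, `attempts` (named: regular,
#'   gunn).
#' @export
runStage4 <- function(chain, lib3, config = baselineConfig(), log = NULL,
                      ledger = NULL) {
  if (is.null(log)) log <- newTrajectoryLog(chain)
  if (is.null(ledger)) ledger <- newLedger()
  fn <- stageScoreSchedule(4L, sets = config$sets)
  b <- stageBudgets(config)
  state <- newSearchState(chain, fn, config)
  for (i in seq_len(b$stage4Regular))
    state <- attemptMove(state, lib3, fn, "stage4", 1L, "regular", log,
                         ledger, config)
  for (i in seq_len(b$stage4Gunn)) {
    mv <- gunnBiasedMove(state$chain, lib3, config$gunnDraws)
    cand <- insertFragment(state$chain, mv$window, mv$frag)
    candScore <- scoreChain(cand, fn, ledger, "stage4")
    dE <- candScore - state$score
    u <- stats::runif(1L)
    acc <- metropolisAccept(dE, state$ctrl$kT, u)
    kTUsed <- state$ctrl$kT
    state$ctrl <- updateTemperature(state$ctrl, acc)
    logMove(log, "stage4", 1L, "gunn", mv$window, lib3@fragLength, mv$rank,
            acc, dE, kTUsed,
            resChanged = mv$window:(mv$window + lib3@fragLength - 1L),
            chainAfter = if (acc) cand)
    if (acc) {
      state$chain <- cand
      state$score <- candScore
    }
  }
  list(chain = state$chain, log = log, ledger = ledger,
       attempts = c(regular = b$stage4Regular, gunn = b$stage4Gunn))
}

#' Run the staged baseline protocol
#'
#' Stages 1-4 in order from the extended conformation: randomisation, 9-mer
#' sampling, ten alternating-score substages with convergence checking, and
#' 3-mer refinement with a conservative second phase. All stochastic choices
#' are drawn from R's RNG seeded once at entry, so a fixed seed reproduces
#' the run exactly.
#'
#' @param sequence amino-acid string.
#' @param ss secondary-structure string (H/E/L).
#' @param lib9,lib3 9-mer and 3-mer fragment libraries.
#' @param increaseCycles budget multiplier (default 1).
#' @param seed RNG seed.
#' @param config optional [baselineConfig()]; `increaseCycles` overrides its
#'   multiplier.
#' @param recordAccepted store accepted-move snapshots in the log.
#' @return list with `decoy` (final [TorsionChain-class]), `score` (final
#'   score under the full weight set, not ledger-counted), `log`, `ledger`,
#'   `stages` (per-stage summaries).
#' @export
runBaseline <- function(sequence, ss, lib9, lib3, increaseCycles = 1,
                        seed = 1L, config = baselineConfig(),
                        recordAccepted = TRUE) {
  force(sequence); force(ss); force(lib9); force(lib3)   # see runBasinHopping
  config$increaseCycles <- increaseCycles
  set.seed(seed)
  chain <- makeExtendedChain(sequence, ss)
  log <- newTrajectoryLog(chain, seed, recordAccepted)
  ledger <- newLedger()
  s1 <- runStage1(chain, lib9, config, log, ledger)
  s2 <- runStage2(s1$chain, lib9, config, log, ledger)
  s3 <- runStage3(s2$chain, lib9, config, log, ledger)
  s4 <- runStage4(s3$chain, lib3, config, log, ledger)
  finalScore <- scoreChain(s4$chain, config$sets$score3)
  list(decoy = s4$chain, score = finalScore, log = log, ledger = ledger,
       stages = list(stage1 = s1[c("attempts", "reason")],
                     stage2 = s2["attempts"],
                     stage3 = s3[c("attempts", "converged")],
                     stage4 = s4["attempts"]))
}
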