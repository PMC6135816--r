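## Low-resolution scoring. A documented, simplified score family stands in
## for the staged knowledge-based weight sets of production fragment-assembly
## codes: five terms combined by stage-dependent non-negative weights, lower
## is better. Every call through scoreModel() increments an evaluation
## ledger, since protocol budgets are expressed in scoring-function calls.

#' Create an evaluation ledger
#'
#' Mutable counter of scoring-function calls, total and per stage label.
#' Samplers pass it to [scoreModel()]; protocol budgets are expressed in
#' these counts.
#'
#' @return an environment of class `EvaluationLedger`.
#' @export
newLedger <- function() {
  e <- new.env(parent = emptyenv())
  e$total <- 0L
  e$stages <- integer(0)
  class(e) <- "EvaluationLedger"
  e
}

#' @export
print.EvaluationLedger <- function(x, ...) {
  cat(sprintf("EvaluationLedger: %d calls\n", x$total))
  if (length(x$stages))
    for (s in names(x$stages)) cat(sprintf("  %s: %d\n", s, x$stages[[s]]))
  invisible(x)
}

#' Ledger accessors
#' @param ledger an [newLedger()] object.
#' @return total count / named per-stage counts.
#' @export
ledgerTotal <- function(ledger) ledger$total

#' @rdname ledgerTotal
#' @export
ledgerStages <- function(ledger) ledger$stages

bumpLedger <- function(ledger, stage) {
  if (is.null(ledger)) return(invisible(NULL))
  ledger$total <- ledger$total + 1L
  if (is.na(match(stage, names(ledger$stages)))) ledger$stages[[stage]] <- 0L
  ledger$stages[[stage]] <- ledger$stages[[stage]] + 1L
  invisible(NULL)
}

#' Default weight sets (score0..score5 analogues)
#'
#' Named stage-dependent combinations of the five score terms. score0 is
#' clash-dominated (used for the randomisation stage), score1 adds weak
#' compactness/contact guidance (stage 2), score2 and score5 are the two
#' alternating stage-3 sets, and score3 is the full-weight set used in
#' stage 4 and for final decoy scores.
#'
#' @return named list of [ScoreFunction-class] objects.
#' @export
defaultWeightSets <- function() {
  list(
    score0 = ScoreFunction("score0", c(clash = 1)),
    score1 = ScoreFunction("score1", c(clash = 1, compactness = 0.1,
                                       contact = 0.2, ss_pair = 0.2,
                                       hbond_proxy = 0.2)),
    score2 = ScoreFunction("score2", c(clash = 2, compactness = 0.25,
                                       contact = 0.5, ss_pair = 1,
                                       hbond_proxy = 1)),
    score3 = ScoreFunction("score3", c(clash = 2, compactness = 0.25,
                                       contact = 1, ss_pair = 1,
                                       hbond_proxy = 1)),
    score4 = ScoreFunction("score4", c(clash = 2, compactness = 0.25,
                                       contact = 2, ss_pair = 1,
                                       hbond_proxy = 1)),
    score5 = ScoreFunction("score5", c(clash = 2, compactness = 0.5,
                                       contact = 1, ss_pair = 2,
                                       hbond_proxy = 0.5))
  )
}

#' Load weight sets from a YAML config
#'
#' The file maps set names to `term: weight` maps, e.g.
#' `score3: {clash: 2, contact: 1}`. Unnamed terms default to 0.
#'
#' @param path YAML file.
#' @return named list of [ScoreFunction-class] objects.
#' @export
readWeightSets <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(setNames(names(raw), names(raw)), function(nm)
    ScoreFunction(nm, unlist(raw[[nm]])))
}

#' Stage-dependent score schedule
#'
#' Maps a protocol stage (and, for stage 3, the substage) to its weight set:
#' stage 1 uses the clash-dominated score0 analogue, stage 2 score1, stage 3
#' alternates score2 (odd substages) and score5 (even substages), and stage 4
#' uses the full score3 analogue.
#'
#' @param stage integer in 1..4.
#' @param substage substage index (stage 3 only; 1..10).
#' @param sets weight sets, by default [defaultWeightSets()].
#' @return a [ScoreFunction-class].
#' @export
stageScoreSchedule <- function(stage, substage = 1L,
                               sets = defaultWeightSets()) {
  if (!stage %in% 1:4) stop("stage must be in 1..4")
  switch(as.character(stage),
    "1" = sets$score0,
    "2" = sets$score1,
    "3" = if (substage %% 2L == 1L) sets$score2 else sets$score5,
    "4" = sets$score3)
}

#' Raw score terms of a model
#'
#' Term definitions (all translation/rotation invariant):
#' \describe{
#'   \item{clash}{sum of `max(0, d0 - d)^2` over all C-alpha and centroid
#'     atom pairs of residues with |i-j| >= 2, with onset `d0 = 3.6`
#'     Angstroms for C-alpha/C-alpha pairs (non-bonded backbone spacing)
#'     and 3.0 for pairs involving a centroid.}
#'   \item{compactness}{`(Rg - Rg_ideal)^2` with `Rg_ideal = 2.2 * N^0.38`.}
#'   \item{contact}{minus half the sum over residues of the contact degree
#'     (C-alpha contacts at 8 Angstroms, |i-j| >= 3) saturated at 8
#'     neighbours per residue. The saturation keeps over-collapsed globules
#'     from outscoring native-like packing.}
#'   \item{ss_pair}{minus the number of such contacts where both residues
#'     are predicted strand (E).}
#'   \item{hbond_proxy}{minus the number of predicted-helix (H) residues
#'     whose (phi, psi) lie in the helical region
#'     (phi in \[-100, -30\], psi in \[-75, -5\]).}
#' }
#'
#' @param model a [CartesianModel-class].
#' @param clashDist clash onset distance (default 3.0 Angstroms).
#' @param cutoff,minSep contact definition (defaults 8 Angstroms, 3).
#' @return named numeric of the five terms.
#' @export
scoreTerms <- function(model, clashDist = 3.0, caClashDist = 3.6, cutoff = 8,
                       minSep = 3L) {
  n <- length(model)
  res <- rep(seq_len(n), 2L)
  xyz <- rbind(model@caXYZ, model@cenXYZ)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(res, res, "-"))
  up <- upper.tri(d) & sep >= 2L
  isCa <- c(rep(TRUE, n), rep(FALSE, n))
  caPair <- outer(isCa, isCa, "&")
  onset <- ifelse(caPair[up], caClashDist, clashDist)
  viol <- pmax(0, onset - d[up])
  clash <- sum(viol^2)
  rg <- radiusOfGyration(model)
  rgIdeal <- 2.2 * n^0.38
  compact <- (rg - rgIdeal)^2
  dca <- d[seq_len(n), seq_len(n)]
  isContact <- dca < cutoff & abs(outer(seq_len(n), seq_len(n), "-")) >= minSep
  nContact <- sum(pmin(rowSums(isContact), 8)) / 2
  ee <- outer(model@ss == "E", model@ss == "E", "&")
  nEE <- sum((isContact & ee)[upper.tri(ee)])
  helical <- model@ss == "H" & model@phi >= -100 & model@phi <= -30 &
    model@psi >= -75 & model@psi <= -5
  c(clash = clash, compactness = compact, contact = -nContact,
    ss_pair = -nEE, hbond_proxy = -sum(helical))
}

#' Score a model
#'
#' Weighted combination of [scoreTerms()]; lower is better. If a ledger is
#' supplied the call is counted against it (exactly one increment per call).
#'
#' @param model a [CartesianModel-class].
#' @param fn a [ScoreFunction-class].
#' @param ledger optional [newLedger()] evaluation ledger.
#' @param stage stage label used in the ledger (default the score name).
#' @return finite numeric score.
#' @export
scoreModel <- function(model, fn, ledger = NULL, stage = fn@name) {
  bumpLedger(ledger, stage)
  sum(fn@weights * scoreTerms(model))
}

#' Score a torsion chain (builds coordinates first)
#' @inheritParams scoreModel
#' @param chain a [TorsionChain-class].
#' @return finite numeric score.
#' @export
scoreChain <- function(chain, fn, ledger = NULL, stage = fn@name)
  scoreModel(buildCartesian(chain), fn, ledger, stage)

#' Scale scores to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1. If all values
#' are equal the whole vector maps to 0 (documented convention).
#'
#' @param scores numeric vector.
#' @return numeric vector in \[0, 1\].
#' @export
scaleScores <- function(scores) {
  r <- range(scores)
  if (r[1L] == r[2L]) return(rep(0, length(scores)))
  (scores - r[1L]) / (r[2L] - r[1L])
}
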