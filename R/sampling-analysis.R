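## Local and global measures of sampling: per-residue accepted-move profiles,
## contact-map Hamming dissimilarities, classical MDS, PAM clustering, a
## Markov-state entropy measure, the Mack-Skillings rank test, and RMSD
## kernel densities.

tripletKey <- function(t) paste(sprintf("%.3f", t), collapse = "/")

#' Per-residue local sampling profile
#'
#' Counts, per residue and per stage, how many accepted moves (including
#' transiently accepted perturbation and hill-climbing moves) overwrote the
#' residue's torsions, and the fraction of the unique torsion triplets
#' available for that residue in the 9-mer library that were sampled at
#' least once.
#'
#' @param log a [TrajectoryLog-class].
#' @param lib9 the 9-mer [FragmentLibrary-class] the run used.
#' @return list with `counts` (residues x stages matrix) and
#'   `tripletFraction` (numeric per residue).
#' @export
localProfile <- function(log, lib9) {
  e <- log@env
  n <- length(e$template)
  mt <- moveTable(log)
  accRows <- which(mt$accepted)
  stages <- c("stage1", "stage2", "stage3", "stage4")
  counts <- matrix(0L, n, length(stages), dimnames = list(NULL, stages))
  L9 <- lib9@fragLength
  ## available unique triplets per residue
  avail <- vector("list", n)
  for (w in seq_along(lib9@windows))
    for (f in lib9@windows[[w]])
      for (p in seq_len(L9)) {
        res <- w + p - 1L
        avail[[res]] <- c(avail[[res]], tripletKey(f@torsions[p, ]))
      }
  avail <- lapply(avail, unique)
  sampled <- vector("list", n)
  for (k in seq_along(accRows)) {
    row <- accRows[k]
    res <- e$resChanged[[k]]
    st <- mt$stage[row]
    if (st %in% stages) counts[res, st] <- counts[res, st] + 1L
    if (mt$fragLen[row] == L9 && mt$rank[row] >= 1L) {
      frag <- lib9@windows[[mt$window[row]]][[mt$rank[row]]]
      for (r in res) {
        key <- tripletKey(frag@torsions[r - mt$window[row] + 1L, ])
        sampled[[r]] <- c(sampled[[r]], key)
      }
    }
  }
  frac <- vapply(seq_len(n), function(r) {
    if (!length(avail[[r]])) return(NA_real_)
    length(intersect(unique(sampled[[r]]), avail[[r]])) / length(avail[[r]])
  }, numeric(1L))
  list(counts = counts, tripletFraction = frac)
}

#' Hamming dissimilarity matrix between contact maps
#'
#' Entry (a, b) is the number of upper-triangle cells in which the two
#' binary contact maps differ.
#'
#' @param maps list of [ContactMap-class] objects of equal size.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
hammingMatrix <- function(maps) {
  sizes <- vapply(maps, function(m) nrow(m@map), 1L)
  if (length(unique(sizes)) != 1L) stop("contact maps differ in size")
  up <- upper.tri(maps[[1L]]@map)
  x <- t(vapply(maps, function(m) as.numeric(m@map[up]),
                numeric(sum(up))))
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  dimnames(d) <- NULL
  d
}

#' Classical multidimensional scaling
#'
#' Double-centres the squared dissimilarities, eigendecomposes, and builds
#' coordinates from the k largest positive eigenvalues (eigenvector times
#' square-root eigenvalue). If fewer than k positive eigenvalues remain, the
#' returned dimension is reduced and flagged via the `"reduced"` attribute.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k requested embedding dimension (default 2).
#' @return items-by-k coordinate matrix; attribute `"eig"` carries the
#'   eigenvalues.
#' @export
classicalMDS <- function(d, k = 2L) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values[1L], 0) * 1e-12 & eg$values > 0)
  kUse <- min(k, length(pos))
  coords <- eg$vectors[, pos[seq_len(kUse)], drop = FALSE] %*%
    diag(sqrt(eg$values[pos[seq_len(kUse)]]), kUse)
  attr(coords, "eig") <- eg$values
  attr(coords, "reduced") <- kUse < k
  coords
}

#' Sample structures from a trajectory log
#'
#' `"accepted-move"` mode returns the structure after every `cadence`-th
#' accepted move; `"lmin"` mode returns every `cadence`-th local minimum
#' (perturbed non-minimum states are never sampled in this mode, since they
#' would overstate useful exploration).
#'
#' @param log a [TrajectoryLog-class] recorded with snapshots.
#' @param mode `"accepted-move"` or `"lmin"`.
#' @param cadence sampling cadence (>= 1; default 100).
#' @return list of [TorsionChain-class] objects, in trajectory order.
#' @export
sampleTrajectory <- function(log, mode = c("accepted-move", "lmin"),
                             cadence = 100L) {
  mode <- match.arg(mode)
  if (cadence < 1L) stop("cadence must be >= 1")
  e <- log@env
  snaps <- if (mode == "accepted-move") e$accSnaps else e$lminSnaps
  idx <- seq_along(snaps)
  idx <- idx[idx %% cadence == 0L]
  lapply(snaps[idx], chainFromSnapshot, template = e$template)
}

## PAM (k-medoids), BUILD + SWAP, deterministic lowest-index tie-breaking ----

#' PAM clustering of a dissimilarity matrix
#'
#' Partitioning around medoids with the classic BUILD initialisation and
#' SWAP improvement passes. All ties (medoid choice, swap choice) are broken
#' towards the lowest index, so the result is deterministic.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k number of clusters.
#' @return list with `medoids` (indices), `labels` (cluster id per item),
#'   `objective` (total dissimilarity to assigned medoids).
#' @export
pamCluster <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n) stop("more clusters than items")
  ## BUILD
  medoids <- which.min(colSums(d))
  while (length(medoids) < k) {
    dmin <- if (length(medoids) == 1L) d[, medoids] else
      do.call(pmin, as.data.frame(d[, medoids, drop = FALSE]))
    gains <- vapply(seq_len(n), function(h) {
      if (h %in% medoids) return(-Inf)
      sum(pmax(0, dmin - d[, h]))
    }, numeric(1L))
    medoids <- c(medoids, which.max(gains))
  }
  ## SWAP
  repeat {
    dm <- d[, medoids, drop = FALSE]
    near <- apply(dm, 1L, which.min)
    first <- dm[cbind(seq_len(n), near)]
    second <- apply(dm, 1L, function(r) sort(r, partial = 2L)[2L])
    if (k == 1L) second <- rep(Inf, n)
    best <- list(delta = 0, m = NA, h = NA)
    nonMed <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      isNear <- near == mi
      for (h in nonMed) {
        dh <- d[, h]
        delta <- sum(pmin(dh[isNear], second[isNear]) - first[isNear]) +
          sum(pmin(0, dh[!isNear] - first[!isNear]))
        if (delta < best$delta - 1e-12) best <- list(delta = delta, m = mi,
                                                     h = h)
      }
    }
    if (is.na(best$m)) break
    medoids[best$m] <- best$h
  }
  medoids <- sort(medoids)
  dm <- d[, medoids, drop = FALSE]
  labels <- apply(dm, 1L, which.min)
  list(medoids = medoids, labels = as.integer(labels),
       objective = sum(dm[cbind(seq_len(n), labels)]))
}

#' Markov-state entropy of trajectory exploration
#'
#' Pools per-run trajectory samples with a reference decoy set (normally
#' including the native), clusters the pooled contact-map Hamming
#' dissimilarities with PAM into `nClusters` clusters, models each run's
#' movement through the clusters as a Markov chain, and reports for each run
#' the occupancy-weighted transition entropy
#' `-sum_i pi_i sum_j p_ij log p_ij / log(nClusters)`, in \[0, 1\]. A run
#' confined to one cluster scores 0; a run hopping uniformly over all
#' clusters approaches 1. `mode = "occupancy"` instead returns the plain
#' normalised entropy of each run's cluster-occupancy distribution.
#'
#' @param trajectories list of runs; each run is a list of
#'   [TorsionChain-class] samples in trajectory order.
#' @param references list of reference [TorsionChain-class] decoys (included
#'   in the clustering only).
#' @param nClusters number of PAM clusters (default 20).
#' @param cutoff,minSep contact-map parameters.
#' @param mode `"transition"` (default) or `"occupancy"`.
#' @return list with `entropy` (per run; NA for runs with < 2 samples),
#'   `labels` (per-run cluster label sequences), `clustering` (the
#'   [pamCluster()] result on the pooled set).
#' @export
entropyMeasure <- function(trajectories, references, nClusters = 20L,
                           cutoff = 8, minSep = 3L,
                           mode = c("transition", "occupancy")) {
  mode <- match.arg(mode)
  runs <- lengths(trajectories)
  pool <- c(unlist(trajectories, recursive = FALSE), references)
  if (length(pool) < nClusters) stop("fewer items than clusters")
  maps <- lapply(pool, function(ch)
    contactMap(buildCartesian(ch), cutoff, minSep))
  d <- hammingMatrix(maps)
  cl <- pamCluster(d, nClusters)
  offsets <- cumsum(c(0L, runs))
  labels <- lapply(seq_along(trajectories), function(i)
    cl$labels[(offsets[i] + 1L):offsets[i + 1L]])
  entropy <- vapply(labels, labelSequenceEntropy, numeric(1L),
                    nClusters = nClusters, mode = mode)
  list(entropy = entropy, labels = labels, clustering = cl)
}

#' Entropy of a cluster-label sequence
#' @param labels integer cluster labels along one trajectory.
#' @param nClusters number of clusters K (normalisation is log K).
#' @param mode `"transition"` or `"occupancy"`.
#' @return normalised entropy in \[0, 1\]; NA for fewer than 2 samples.
#' @export
labelSequenceEntropy <- function(labels, nClusters,
                                 mode = c("transition", "occupancy")) {
  mode <- match.arg(mode)
  if (length(labels) < 2L) return(NA_real_)
  if (mode == "occupancy") {
    p <- tabulate(labels, nClusters) / length(labels)
    p <- p[p > 0]
    return(-sum(p * log(p)) / log(nClusters))
  }
  from <- labels[-length(labels)]
  to <- labels[-1L]
  occ <- tabulate(labels, nClusters) / length(labels)
  h <- 0
  for (i in unique(from)) {
    pij <- tabulate(to[from == i], nClusters)
    pij <- pij / sum(pij)
    pij <- pij[pij > 0]
    h <- h + occ[i] * (-sum(pij * log(pij)))
  }
  h / log(nClusters)
}

## Mack-Skillings test --------------------------------------------------------

pseudoInverse <- function(v, tol = 1e-10) {
  eg <- eigen(v, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values)
  eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / eg$values[keep], sum(keep)) %*%
    t(eg$vectors[, keep, drop = FALSE])
}

msStatistic <- function(rankList, cellIndex, k) {
  ## rankList: per block, vector of within-block ranks; cellIndex: per block,
  ## integer group id per observation
  S <- numeric(k)
  ES <- numeric(k)
  V <- matrix(0, k, k)
  for (b in seq_along(rankList)) {
    r <- rankList[[b]]
    g <- cellIndex[[b]]
    ni <- length(r)
    cij <- tabulate(g, k)
    m <- vapply(seq_len(k), function(j) mean(r[g == j]), numeric(1L))
    S <- S + m
    ES <- ES + (ni + 1) / 2
    vb <- matrix(-(ni + 1) / 12, k, k)
    diag(vb) <- (ni + 1) * (ni - cij) / (12 * cij)
    V <- V + vb
  }
  dev <- S - ES
  list(S = S, stat = drop(t(dev) %*% pseudoInverse(V) %*% dev))
}

#' Mack-Skillings test for replicated two-way layouts
#'
#' Rank-based test for treatment (group) differences across blocks with
#' replication. Observations are ranked within each block; the statistic is
#' a quadratic form of the summed cell mean ranks against their null
#' covariance and is compared to a chi-square distribution with k - 1
#' degrees of freedom (with one replicate per cell this reduces to the
#' Friedman statistic). The conservative post-hoc procedure compares every
#' pairwise difference `|S_i - S_j|` of the summed cell mean ranks to a
#' critical value calibrated by Monte-Carlo permutation within blocks of the
#' maximum pairwise difference.
#'
#' @param values numeric observations.
#' @param groups treatment labels (the protocols being compared).
#' @param blocks block labels (the targets).
#' @param alpha experiment-wise error rate for the post-hoc critical value
#'   (default 0.05).
#' @param mcIterations Monte-Carlo iterations for the critical value
#'   (default 50000).
#' @param seed RNG seed for the Monte-Carlo calibration.
#' @param posthoc compute the Monte-Carlo post-hoc critical value (default
#'   TRUE; set FALSE to skip the simulation).
#' @return list with `statistic`, `df`, `p.value`, `S` (per group),
#'   `pairwise` (matrix of |S_i - S_j|), `critical`, `alpha`,
#'   `mcIterations`.
#' @export
mackSkillings <- function(values, groups, blocks, alpha = 0.05,
                          mcIterations = 50000L, seed = 1L, posthoc = TRUE) {
  groups <- factor(groups)
  blocks <- factor(blocks)
  k <- nlevels(groups)
  if (k < 2L || nlevels(blocks) < 2L)
    stop("need at least 2 groups and 2 blocks")
  cellCounts <- table(blocks, groups)
  if (any(cellCounts == 0L)) stop("empty cell in the two-way layout")
  rankList <- list()
  cellIndex <- list()
  for (b in levels(blocks)) {
    sel <- blocks == b
    rankList[[b]] <- rank(values[sel])
    cellIndex[[b]] <- as.integer(groups[sel])
  }
  obs <- msStatistic(rankList, cellIndex, k)
  stat <- obs$stat
  p <- stats::pchisq(stat, df = k - 1L, lower.tail = FALSE)
  pairwise <- abs(outer(obs$S, obs$S, "-"))
  dimnames(pairwise) <- list(levels(groups), levels(groups))
  critical <- NA_real_
  if (posthoc) {
    set.seed(seed)
    maxDiff <- numeric(mcIterations)
    for (it in seq_len(mcIterations)) {
      Sp <- numeric(k)
      for (b in seq_along(rankList)) {
        r <- sample(rankList[[b]])
        g <- cellIndex[[b]]
        Sp <- Sp + vapply(seq_len(k), function(j) mean(r[g == j]),
                          numeric(1L))
      }
      maxDiff[it] <- max(dist(Sp))
    }
    critical <- stats::quantile(maxDiff, 1 - alpha, names = FALSE)
  }
  list(statistic = stat, df = k - 1L, p.value = p, S = setNames(obs$S,
       levels(groups)), pairwise = pairwise, critical = critical,
       alpha = alpha, mcIterations = mcIterations)
}

#' Gaussian kernel density of RMSD values
#'
#' Fixed-bandwidth Gaussian KDE (the bandwidth is the kernel standard
#' deviation, default 0.7 Angstroms), evaluated on a regular 512-point grid
#' spanning the data range extended by 4 bandwidths on each side.
#'
#' @param rmsds numeric RMSD values (>= 1 value).
#' @param bandwidth kernel standard deviation in Angstroms (default 0.7).
#' @param n grid size (default 512).
#' @return list with `x`, `y`, `bandwidth`.
#' @export
rmsdKDE <- function(rmsds, bandwidth = 0.7, n = 512L) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (!length(rmsds)) stop("need at least one value")
  from <- min(rmsds) - 4 * bandwidth
  to <- max(rmsds) + 4 * bandwidth
  dd <- stats::density(rmsds, bw = bandwidth, kernel = "gaussian", n = n,
                       from = from, to = to)
  list(x = dd$x, y = dd$y, bandwidth = bandwidth)
}
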