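## Calibur-style clustering of decoy sets by pairwise C-alpha RMSD, with an
## exact triangle-inequality prefilter, automatic threshold selection, and
## top-1 / top-3 model reporting.

decoyCaCoords <- function(decoys) {
  lapply(decoys, function(d) {
    if (is(d, "TorsionChain")) d <- buildCartesian(d)
    if (is(d, "CartesianModel")) caCoords(d) else as.matrix(d)
  })
}

pairwiseRmsdMatrix <- function(coords, threshold = Inf, prefilter = FALSE) {
  n <- length(coords)
  centered <- lapply(coords, function(x) sweep(x, 2L, colMeans(x)))
  rg <- vapply(centered, function(x) sqrt(mean(rowSums(x^2))), numeric(1L))
  refD <- vapply(centered, function(x) rmsdCoords(centered[[1L]], x),
                 numeric(1L))
  d <- matrix(0, n, n)
  skipped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (prefilter) {
        ## exact lower bounds on superposed RMSD: radius-of-gyration gap and
        ## the triangle inequality anchored at decoy 1
        lb <- max(abs(rg[i] - rg[j]), abs(refD[i] - refD[j]))
        if (lb >= threshold) {
          d[i, j] <- d[j, i] <- lb
          skipped <- skipped + 1L
          next
        }
      }
      d[i, j] <- d[j, i] <- rmsdCoords(centered[[i]], centered[[j]])
    }
  }
  attr(d, "skipped") <- skipped
  d
}

greedyClusters <- function(d, threshold) {
  n <- nrow(d)
  unassigned <- rep(TRUE, n)
  centers <- integer(0)
  members <- list()
  while (any(unassigned)) {
    idx <- which(unassigned)
    neigh <- vapply(idx, function(i) sum(d[i, idx] < threshold), 1L)
    center <- idx[which.max(neigh)]   # ties: lowest index (which.max rule)
    mem <- idx[d[center, idx] < threshold]
    mem <- union(center, mem)
    centers <- c(centers, center)
    members <- c(members, list(sort(mem)))
    unassigned[mem] <- FALSE
  }
  sizes <- lengths(members)
  ord <- order(-sizes, centers)
  new("ClusterSolution", threshold = threshold,
      centers = as.integer(centers[ord]), members = members[ord],
      sizes = as.integer(sizes[ord]))
}

#' Cluster decoys by pairwise C-alpha RMSD
#'
#' Greedy largest-first clustering: the decoy with the most neighbours
#' within `threshold` among unassigned decoys becomes the next cluster
#' centre and claims its neighbours (exclusive membership); repeat until all
#' decoys are assigned. With `prefilter = TRUE`, exact lower bounds on the
#' superposed RMSD (the radius-of-gyration gap and a triangle-inequality
#' bound anchored at a reference decoy) skip full superpositions that cannot
#' fall below the threshold; the result is identical with the prefilter on
#' or off.
#'
#' @param decoys list of [TorsionChain-class] / [CartesianModel-class] (or
#'   C-alpha coordinate matrices) of equal length.
#' @param threshold clustering radius in Angstroms, or `"auto"` to use
#'   [autoThreshold()].
#' @param prefilter use the exact lower-bound prefilter (default TRUE).
#' @return a `ClusterSolution` (clusters ordered by size descending, ties by
#'   lower centre id).
#' @export
clusterDecoys <- function(decoys, threshold = "auto", prefilter = TRUE) {
  if (!length(decoys)) stop("empty decoy set")
  coords <- decoyCaCoords(decoys)
  if (identical(threshold, "auto"))
    threshold <- autoThreshold(decoys)
  d <- pairwiseRmsdMatrix(coords, threshold, prefilter)
  greedyClusters(d, threshold)
}

#' Automatic clustering-threshold selection
#'
#' Scans a grid of percentiles (default 5, 10, ..., 95) of the sampled
#' pairwise RMSD distribution and returns the smallest threshold at which
#' the most-neighboured decoy already has at least `minFraction` of the
#' decoy set within range. Scale-equivariant: scaling all coordinates scales
#' the chosen threshold by the same factor.
#'
#' @param decoys list of >= 10 decoys.
#' @param minFraction required neighbour fraction for the top decoy
#'   (default 1/10).
#' @param percentiles percentile grid of sampled pairwise RMSDs.
#' @param maxPairs maximum number of pairs sampled to build the percentile
#'   grid (evenly strided; default 2000).
#' @return threshold in Angstroms.
#' @export
autoThreshold <- function(decoys, minFraction = 0.1,
                          percentiles = seq(5, 95, by = 5),
                          maxPairs = 2000L) {
  if (length(decoys) < 10L)
    stop("need >= 10 decoys for automatic threshold selection; ",
         "pass an explicit threshold")
  coords <- decoyCaCoords(decoys)
  d <- pairwiseRmsdMatrix(coords)
  vals <- d[upper.tri(d)]
  if (length(vals) > maxPairs)
    vals <- vals[seq(1L, length(vals), length.out = maxPairs)]
  grid <- unique(stats::quantile(vals, percentiles / 100, names = FALSE))
  grid <- grid[grid > 1e-6]   # numerically-zero RMSDs are not thresholds
  ## degenerate case: all decoys (near-)identical; any tiny radius clusters
  ## everything
  if (!length(grid)) return(1e-6)
  n <- nrow(d)
  for (t in sort(grid)) {
    best <- max(vapply(seq_len(n), function(i) sum(d[i, ] < t), 1L))
    if (best >= minFraction * n) return(t)
  }
  max(grid)
}

#' Report top-1 / top-3 cluster-centre models
#'
#' @param solution a [clusterDecoys()] result.
#' @param decoys the decoy list the solution was computed on.
#' @param native optional native structure for RMSD reporting.
#' @return list with `top1` (centre decoy index), `top3` (up to three centre
#'   indices), `short` (TRUE if fewer than 3 clusters), `sizes`, and, with a
#'   native, `rmsdTop1`, `rmsdTop3`, `bestOfTop3`.
#' @export
selectModels <- function(solution, decoys, native = NULL) {
  centers <- solution@centers
  top3 <- centers[seq_len(min(3L, length(centers)))]
  out <- list(top1 = centers[1L], top3 = top3, short = length(centers) < 3L,
              sizes = solution@sizes)
  if (!is.null(native)) {
    coords <- decoyCaCoords(decoys)
    natCa <- decoyCaCoords(list(native))[[1L]]
    rms <- vapply(top3, function(i) rmsdCoords(coords[[i]], natCa),
                  numeric(1L))
    out$rmsdTop1 <- rms[1L]
    out$rmsdTop3 <- rms
    out$bestOfTop3 <- min(rms)
  }
  out
}

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution: %d clusters at threshold %.2f A; sizes: %s\n",
              length(object@centers), object@threshold,
              paste(utils::head(object@sizes, 10L), collapse = ", ")))
})

#' ClusterSolution accessors
#' @param x a ClusterSolution.
#' @return centre indices / member index lists / sizes / threshold.
#' @export
clusterCenters <- function(x) x@centers

#' @rdname clusterCenters
#' @export
clusterMembers <- function(x) x@members

#' @rdname clusterCenters
#' @export
clusterSizes <- function(x) x@sizes

#' @rdname clusterCenters
#' @export
clusterThreshold <- function(x) x@threshold
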