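#' @import methods
NULL

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
SS_CODES <- c("H", "E", "L")

## Ideal internal geometry (Engh-Huber-style idealisation), Angstroms / degrees.
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
CENTROID_DIST <- 2.5

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @examples
#' wrapAngle(c(200, -180, 540))
#' @export
wrapAngle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' TorsionChain: torsion-space backbone representation
#'
#' Per-residue backbone torsion angles (phi, psi, omega, degrees, in
#' (-180, 180]) together with the amino-acid sequence and a three-state
#' secondary-structure string (H/E/L). These torsions are the only decision
#' variables of the samplers; Cartesian coordinates are derived on demand
#' with [buildCartesian()].
#'
#' @slot sequence character vector of 1-letter residue codes.
#' @slot ss character vector of per-residue labels in H/E/L.
#' @slot phi,psi,omega numeric vectors of torsions in degrees.
#' @export
setClass("TorsionChain",
  representation(sequence = "character", ss = "character",
                 phi = "numeric", psi = "numeric", omega = "numeric"))

setValidity("TorsionChain", function(object) {
  n <- length(object@sequence)
  if (n == 0L) return("empty sequence")
  if (!all(object@sequence %in% AA_CODES))
    return("invalid residue code(s)")
  if (!all(object@ss %in% SS_CODES))
    return("secondary-structure labels must be in {H, E, L}")
  lens <- c(length(object@ss), length(object@phi), length(object@psi),
            length(object@omega))
  if (any(lens != n)) return("sequence, ss and torsion arrays differ in length")
  ang <- c(object@phi, object@psi, object@omega)
  if (any(!is.finite(ang))) return("non-finite torsion angle")
  if (any(ang <= -180 | ang > 180)) return("torsions must lie in (-180, 180]")
  TRUE
})

#' Construct a TorsionChain
#'
#' @param sequence amino-acid string (1-letter codes) or character vector.
#' @param ss secondary-structure string/vector over H/E/L (PSIPRED 'C' is not
#'   accepted here; see [readSs2()] which maps C to L).
#' @param phi,psi,omega numeric vectors of torsions in degrees; wrapped into
#'   (-180, 180].
#' @return a [TorsionChain-class] object.
#' @export
TorsionChain <- function(sequence, ss, phi, psi, omega) {
  if (length(sequence) == 1L && nchar(sequence) != 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(ss) == 1L && nchar(ss) != 1L) ss <- strsplit(ss, "")[[1]]
  new("TorsionChain", sequence = as.character(sequence), ss = as.character(ss),
      phi = wrapAngle(as.numeric(phi)), psi = wrapAngle(as.numeric(psi)),
      omega = wrapAngle(as.numeric(omega)))
}

#' CartesianModel: low-resolution Cartesian coordinates
#'
#' Backbone N, C-alpha, C atoms plus one sidechain centroid pseudoatom per
#' residue, as built by [buildCartesian()] in a canonical frame. Sequence,
#' secondary structure and the generating torsions are carried along so that
#' scoring terms that depend on them need no extra arguments.
#'
#' @slot nXYZ,caXYZ,cXYZ,cenXYZ n-by-3 coordinate matrices (Angstroms).
#' @slot sequence,ss per-residue annotations (see [TorsionChain-class]).
#' @slot phi,psi,omega the generating torsions (degrees).
#' @export
setClass("CartesianModel",
  representation(nXYZ = "matrix", caXYZ = "matrix", cXYZ = "matrix",
                 cenXYZ = "matrix", sequence = "character", ss = "character",
                 phi = "numeric", psi = "numeric", omega = "numeric"))

setValidity("CartesianModel", function(object) {
  n <- length(object@sequence)
  for (nm in c("nXYZ", "caXYZ", "cXYZ", "cenXYZ")) {
    m <- slot(object, nm)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L)
      return(sprintf("%s must be an n-by-3 matrix", nm))
    if (any(!is.finite(m))) return(sprintf("non-finite coordinates in %s", nm))
  }
  if (n > 1L) {
    d <- sqrt(rowSums((object@caXYZ[-1L, , drop = FALSE] -
                       object@caXYZ[-n, , drop = FALSE])^2))
    trans <- abs(wrapAngle(object@omega[-n])) > 170
    ideal <- idealCaCaDistance()
    if (any(trans & abs(d - ideal) > 0.1))
      return("consecutive CA-CA distance departs from the ideal trans value")
  }
  TRUE
})

#' ContactMap: binary residue-residue contact matrix
#'
#' Symmetric 0/1 matrix marking residue pairs whose C-alpha atoms lie within
#' a distance cutoff at sufficient sequence separation.
#'
#' @slot map integer matrix (0/1), symmetric, zero diagonal.
#' @slot cutoff distance cutoff in Angstroms.
#' @slot minSep minimum sequence separation |i-j|.
#' @export
setClass("ContactMap",
  representation(map = "matrix", cutoff = "numeric", minSep = "integer"))

setValidity("ContactMap", function(object) {
  m <- object@map
  if (nrow(m) != ncol(m)) return("map must be square")
  if (!all(m %in% c(0L, 1L))) return("map entries must be 0/1")
  if (!isTRUE(all.equal(m, t(m)))) return("map must be symmetric")
  if (any(diag(m) != 0L)) return("map diagonal must be zero")
  idx <- abs(row(m) - col(m)) < object@minSep
  if (any(m[idx] != 0L)) return("entries below minimum separation must be 0")
  TRUE
})

#' Fragment: a torsion-triplet backbone fragment
#'
#' @slot torsions L-by-3 matrix (phi, psi, omega in degrees, (-180, 180]).
#' @slot source free-text provenance tag.
#' @export
setClass("Fragment",
  representation(torsions = "matrix", source = "character"))

setValidity("Fragment", function(object) {
  t <- object@torsions
  if (!is.matrix(t) || ncol(t) != 3L) return("torsions must be an L-by-3 matrix")
  if (nrow(t) < 1L) return("empty fragment")
  if (any(!is.finite(t))) return("non-finite torsion")
  if (any(t <= -180 | t > 180)) return("torsions must lie in (-180, 180]")
  TRUE
})

#' Construct a Fragment
#' @param torsions L-by-3 matrix of (phi, psi, omega) in degrees.
#' @param source provenance tag.
#' @return a [Fragment-class] object.
#' @export
Fragment <- function(torsions, source = "synthetic") {
  torsions <- wrapAngle(as.matrix(torsions))
  dimnames(torsions) <- list(NULL, c("phi", "psi", "omega"))
  new("Fragment", torsions = torsions, source = as.character(source))
}

#' FragmentLibrary: per-window ranked lists of fragments
#'
#' One entry per insertion window (indexed by start residue, 1-based); each
#' entry is a ranked list of [Fragment-class] objects of a common length
#' (typically 9 or 3). File order defines rank: fragment pickers emit
#' highest-scoring fragments first and no re-scoring is done here.
#'
#' @slot fragLength fragment length (3 or 9 in standard use).
#' @slot windows list of lists of Fragment, windows in ascending start order.
#' @export
setClass("FragmentLibrary",
  representation(fragLength = "integer", windows = "list"))

setValidity("FragmentLibrary", function(object) {
  if (length(object@windows) < 1L) return("library has no windows")
  if (any(vapply(object@windows, length, 1L) < 1L))
    return("every window must hold at least one fragment")
  ok <- vapply(object@windows, function(w)
    all(vapply(w, function(f) is(f, "Fragment") &&
                 nrow(f@torsions) == object@fragLength, TRUE)), TRUE)
  if (!all(ok)) return("fragments must match the library fragment length")
  TRUE
})

#' Construct a FragmentLibrary
#' @param windows list (ascending window start) of lists of [Fragment-class].
#' @param fragLength common fragment length.
#' @return a [FragmentLibrary-class] object.
#' @export
FragmentLibrary <- function(windows, fragLength) {
  new("FragmentLibrary", fragLength = as.integer(fragLength), windows = windows)
}

#' ScoreFunction: a named weight set over low-resolution score terms
#'
#' Terms are clash, compactness, contact, ss_pair and hbond_proxy; see
#' [scoreModel()] for their definitions. Lower scores are better.
#'
#' @slot name stage label (score0..score5 analogue).
#' @slot weights named non-negative numeric over the five terms.
#' @export
setClass("ScoreFunction",
  representation(name = "character", weights = "numeric"))

SCORE_TERMS <- c("clash", "compactness", "contact", "ss_pair", "hbond_proxy")

setValidity("ScoreFunction", function(object) {
  w <- object@weights
  if (!identical(sort(names(w)), sort(SCORE_TERMS)))
    return("weights must be named over the five score terms")
  if (any(w < 0)) return("weights must be non-negative")
  if (!any(w > 0)) return("at least one weight must be positive")
  TRUE
})

#' Construct a ScoreFunction
#' @param name label, e.g. "score3".
#' @param weights named numeric over clash, compactness, contact, ss_pair,
#'   hbond_proxy; missing terms default to 0.
#' @return a [ScoreFunction-class] object.
#' @export
ScoreFunction <- function(name, weights) {
  w <- setNames(numeric(length(SCORE_TERMS)), SCORE_TERMS)
  w[names(weights)] <- as.numeric(weights)
  new("ScoreFunction", name = as.character(name), weights = w)
}

#' Archive: capacity-bounded store of the best local minima
#'
#' Keeps the `capacity` lowest-scoring structures seen so far, in ascending
#' score order; on score ties the earlier candidate is kept.
#'
#' @slot capacity maximum number of entries (default 10).
#' @slot scores numeric vector, non-decreasing.
#' @slot members list of stored structures (TorsionChain).
#' @export
setClass("Archive",
  representation(capacity = "integer", scores = "numeric", members = "list"))

setValidity("Archive", function(object) {
  if (object@capacity < 1L) return("capacity must be >= 1")
  if (length(object@scores) != length(object@members))
    return("scores and members differ in length")
  if (length(object@scores) > object@capacity) return("archive over capacity")
  if (is.unsorted(object@scores)) return("scores must be non-decreasing")
  TRUE
})

#' Construct an empty Archive
#' @param capacity maximum number of stored structures (default 10).
#' @return an empty [Archive-class].
#' @export
Archive <- function(capacity = 10L) {
  new("Archive", capacity = as.integer(capacity), scores = numeric(0),
      members = list())
}

#' TrajectoryLog: mutable per-run record of attempts and snapshots
#'
#' Environment-backed accumulator recording one row per attempted move
#' (stage, substage/phase, window, accepted flag, score delta, kT) plus
#' structure snapshots taken at a fixed cadence of accepted moves (and, for
#' basin-hopping runs, one snapshot per local minimum). Mutated in place by
#' the samplers; convert with [moveTable()] / [snapshotChains()].
#'
#' @slot env the backing environment.
#' @export
setClass("TrajectoryLog", representation(env = "environment"))

setClass("ClusterSolution",
  representation(threshold = "numeric", centers = "integer",
                 members = "list", sizes = "integer"))

#' @describeIn TorsionChain-class number of residues
#' @param x object
#' @export
setMethod("length", "TorsionChain", function(x) length(x@sequence))

#' @describeIn CartesianModel-class number of residues
#' @param x object
#' @export
setMethod("length", "CartesianModel", function(x) length(x@sequence))

setMethod("show", "TorsionChain", function(object) {
  cat(sprintf("TorsionChain of %d residues\n  seq: %s\n  ss : %s\n",
              length(object), paste(object@sequence, collapse = ""),
              paste(object@ss, collapse = "")))
})

setMethod("show", "CartesianModel", function(object) {
  cat(sprintf("CartesianModel: %d residues (N, CA, C + centroid)\n",
              length(object)))
})

setMethod("show", "FragmentLibrary", function(object) {
  d <- vapply(object@windows, length, 1L)
  cat(sprintf("FragmentLibrary: %d-mers, %d windows, depth %d-%d\n",
              object@fragLength, length(object@windows), min(d), max(d)))
})

setMethod("show", "Archive", function(object) {
  cat(sprintf("Archive: %d/%d entries", length(object@scores),
              object@capacity))
  if (length(object@scores))
    cat(sprintf("; scores [%.3f, %.3f]", min(object@scores),
                max(object@scores)))
  cat("\n")
})

setMethod("show", "ScoreFunction", function(object) {
  cat(sprintf("ScoreFunction '%s': %s\n", object@name,
              paste(sprintf("%s=%g", names(object@weights), object@weights),
                    collapse = ", ")))
})

## Accessors -----------------------------------------------------------------

#' Accessors for torsion-space objects
#'
#' @param x a TorsionChain or CartesianModel.
#' @return `chainSequence`/`chainSS` return per-residue character vectors;
#'   `torsions` returns an n-by-3 matrix (phi, psi, omega).
#' @export
chainSequence <- function(x) x@sequence

#' @rdname chainSequence
#' @export
chainSS <- function(x) x@ss

#' @rdname chainSequence
#' @export
torsions <- function(x)
  cbind(phi = x@phi, psi = x@psi, omega = x@omega)

#' Coordinate accessors
#' @param x a CartesianModel.
#' @return an n-by-3 matrix of coordinates (Angstroms).
#' @export
caCoords <- function(x) x@caXYZ

#' @rdname caCoords
#' @export
centroidCoords <- function(x) x@cenXYZ

#' @rdname caCoords
#' @export
nCoords <- function(x) x@nXYZ

#' @rdname caCoords
#' @export
cCoords <- function(x) x@cXYZ

#' Archive accessors
#' @param x an Archive.
#' @return `archiveScores` the sorted score vector; `archiveMembers` the
#'   stored structures.
#' @export
archiveScores <- function(x) x@scores

#' @rdname archiveScores
#' @export
archiveMembers <- function(x) x@members

#' Contact-map accessors
#' @param x a ContactMap.
#' @return the underlying 0/1 integer matrix.
#' @export
contactMatrix <- function(x) x@map
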