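## Torsion-space <-> Cartesian geometry. All bond lengths and angles are fixed
## at the ideal values declared in AllClasses.R; the backbone is grown with
## the standard internal-coordinate (NeRF) construction.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Place atom D given A-B-C, bond |CD|, angle B-C-D, torsion A-B-C-D.
placeAtom <- function(a, b, c, bond, angleDeg, torsionDeg) {
  th <- deg2rad(angleDeg)
  ph <- deg2rad(torsionDeg)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  c + as.vector(m %*% d2)
}

dihedralDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrapAngle(rad2deg(atan2(y, x)))
}

#' Ideal trans C-alpha virtual bond length
#'
#' The CA(i)-CA(i+1) distance implied by the fixed internal geometry when
#' omega = 180 degrees. It depends only on the ideal bond lengths/angles,
#' not on phi or psi.
#'
#' @return distance in Angstroms (about 3.80).
#' @export
idealCaCaDistance <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ## build a 2-residue chain directly from internal coordinates
    n1 <- c(0, 0, 0)
    ca1 <- c(BOND_N_CA, 0, 0)
    c1 <- ca1 + BOND_CA_C *
      c(-cos(deg2rad(ANGLE_N_CA_C)), sin(deg2rad(ANGLE_N_CA_C)), 0)
    n2 <- placeAtom(n1, ca1, c1, BOND_C_N, ANGLE_CA_C_N, 150)   # psi arbitrary
    ca2 <- placeAtom(ca1, c1, n2, BOND_N_CA, ANGLE_C_N_CA, 180) # omega trans
    cache <<- vnorm(ca2 - ca1)
    cache
  }
})

#' Build a fully extended chain
#'
#' Constructs the canonical extended starting conformation used by the
#' low-resolution protocol: every residue set to phi = -150, psi = 150,
#' omega = 180 degrees.
#'
#' @param sequence amino-acid string (1-letter codes).
#' @param ss secondary-structure string over H/E/L, same length.
#' @return a [TorsionChain-class].
#' @examples
#' makeExtendedChain("ACDEFG", "LLHHLL")
#' @export
makeExtendedChain <- function(sequence, ss) {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
  if (length(ss) == 1L && length(sequence) > 1L) ss <- strsplit(ss, "")[[1]]
  if (length(sequence) == 0L) stop("empty sequence")
  if (length(ss) != length(sequence))
    stop("sequence and ss differ in length")
  n <- length(sequence)
  TorsionChain(sequence, ss, phi = rep(-150, n), psi = rep(150, n),
               omega = rep(180, n))
}

#' Build Cartesian coordinates from backbone torsions
#'
#' Grows N, C-alpha, C atoms residue by residue from the chain's torsions
#' with fixed ideal bond lengths and angles, placing the first residue in a
#' canonical frame (N at the origin, CA on +x, C in the xy plane). A sidechain
#' centroid pseudoatom is added 2.5 Angstroms from CA along the local
#' pseudo-C-beta direction (glycine: centroid = CA). phi of the first residue
#' and psi/omega of the last do not affect coordinates.
#'
#' @param chain a [TorsionChain-class].
#' @return a [CartesianModel-class].
#' @export
buildCartesian <- function(chain) {
  stopifnot(is(chain, "TorsionChain"))
  n <- length(chain)
  N <- CA <- C <- matrix(0, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(BOND_N_CA, 0, 0)
  C[1L, ] <- CA[1L, ] + BOND_CA_C *
    c(-cos(deg2rad(ANGLE_N_CA_C)), sin(deg2rad(ANGLE_N_CA_C)), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      N[i + 1L, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], BOND_C_N,
                               ANGLE_CA_C_N, chain@psi[i])
      CA[i + 1L, ] <- placeAtom(CA[i, ], C[i, ], N[i + 1L, ], BOND_N_CA,
                                ANGLE_C_N_CA, chain@omega[i])
      C[i + 1L, ] <- placeAtom(C[i, ], N[i + 1L, ], CA[i + 1L, ], BOND_CA_C,
                               ANGLE_N_CA_C, chain@phi[i + 1L])
    }
  }
  CEN <- CA
  notGly <- chain@sequence != "G"
  ## pseudo-C-beta direction: combination of the N/C bisector at CA and the
  ## backbone-plane normal chosen so the centroid makes the ideal tetrahedral
  ## angles with the N-CA and C-CA bonds
  for (i in which(notGly)) {
    b1 <- unitv(CA[i, ] - N[i, ])
    b2 <- unitv(CA[i, ] - C[i, ])
    bis <- unitv(b1 + b2)
    nrm <- unitv(cross3(b1, b2))
    ## angle(N-CA-CEN) = angle(C-CA-CEN) = 110.5 deg (tetrahedral)
    target <- cos(deg2rad(180 - 110.5))
    alpha <- min(target / sum(b1 * bis), 1)
    dir <- alpha * bis + sqrt(max(0, 1 - alpha^2)) * nrm
    CEN[i, ] <- CA[i, ] + CENTROID_DIST * unitv(dir)
  }
  new("CartesianModel", nXYZ = N, caXYZ = CA, cXYZ = C, cenXYZ = CEN,
      sequence = chain@sequence, ss = chain@ss, phi = chain@phi,
      psi = chain@psi, omega = chain@omega)
}

## CA-only trace (no centroids, no S4 object); used by inner search loops
## where only C-alpha positions are needed.
caTraceOfChain <- function(chain) {
  n <- length(chain@phi)
  N <- CA <- C <- matrix(0, n, 3L)
  CA[1L, ] <- c(BOND_N_CA, 0, 0)
  C[1L, ] <- CA[1L, ] + BOND_CA_C *
    c(-cos(deg2rad(ANGLE_N_CA_C)), sin(deg2rad(ANGLE_N_CA_C)), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      N[i + 1L, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], BOND_C_N,
                               ANGLE_CA_C_N, chain@psi[i])
      CA[i + 1L, ] <- placeAtom(CA[i, ], C[i, ], N[i + 1L, ], BOND_N_CA,
                                ANGLE_C_N_CA, chain@omega[i])
      C[i + 1L, ] <- placeAtom(C[i, ], N[i + 1L, ], CA[i + 1L, ], BOND_CA_C,
                               ANGLE_N_CA_C, chain@phi[i + 1L])
    }
  }
  CA
}

#' Extract backbone torsions from a Cartesian model
#'
#' Recomputes phi/psi/omega dihedrals from the coordinates. Undefined
#' terminal torsions (phi of residue 1, psi/omega of residue n) are returned
#' as the values stored with the model so that the round trip
#' torsions -> coordinates -> torsions is the identity.
#'
#' @param model a [CartesianModel-class].
#' @return a [TorsionChain-class].
#' @export
extractTorsions <- function(model) {
  n <- length(model)
  phi <- model@phi
  psi <- model@psi
  omega <- model@omega
  if (n > 1L) {
    for (i in 2:n)
      phi[i] <- dihedralDeg(model@cXYZ[i - 1L, ], model@nXYZ[i, ],
                            model@caXYZ[i, ], model@cXYZ[i, ])
    for (i in seq_len(n - 1L)) {
      psi[i] <- dihedralDeg(model@nXYZ[i, ], model@caXYZ[i, ],
                            model@cXYZ[i, ], model@nXYZ[i + 1L, ])
      omega[i] <- dihedralDeg(model@caXYZ[i, ], model@cXYZ[i, ],
                              model@nXYZ[i + 1L, ], model@caXYZ[i + 1L, ])
    }
  }
  TorsionChain(model@sequence, model@ss, phi, psi, omega)
}

#' Compute a binary contact map
#'
#' Entry (i, j) is 1 iff the C-alpha distance is below `cutoff` and the
#' sequence separation |i - j| is at least `minSep`.
#'
#' @param model a [CartesianModel-class].
#' @param cutoff C-alpha distance cutoff in Angstroms (default 8).
#' @param minSep minimum sequence separation (default 3).
#' @return a [ContactMap-class].
#' @export
contactMap <- function(model, cutoff = 8, minSep = 3L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  minSep <- as.integer(minSep)
  n <- length(model)
  if (n < minSep + 1L) stop("model too short for the requested separation")
  d <- as.matrix(stats::dist(model@caXYZ))
  m <- (d < cutoff) * 1L
  m[abs(row(m) - col(m)) < minSep] <- 0L
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  new("ContactMap", map = m, cutoff = cutoff, minSep = minSep)
}

#' Radius of gyration of the C-alpha trace
#' @param model a [CartesianModel-class].
#' @return radius of gyration in Angstroms.
#' @export
radiusOfGyration <- function(model) {
  xyz <- model@caXYZ
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2L, ctr)^2)))
}

kabschRotation <- function(a, b) {
  ## rotation matrix mapping centred b onto centred a
  h <- crossprod(b, a)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

rmsdCoords <- function(a, b, superpose = TRUE) {
  if (!superpose) return(sqrt(mean(rowSums((a - b)^2))))
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  if (nrow(a) == 1L) return(0)
  r <- kabschRotation(ac, bc)
  sqrt(mean(rowSums((ac - bc %*% t(r))^2)))
}

#' C-alpha RMSD after optimal superposition
#'
#' Root-mean-square deviation between corresponding C-alpha atoms of two
#' models after optimal rigid-body superposition (Kabsch algorithm).
#'
#' @param a,b [CartesianModel-class] objects (or n-by-3 coordinate matrices)
#'   of equal length.
#' @return RMSD in Angstroms.
#' @export
caRMSD <- function(a, b) {
  xa <- if (is(a, "CartesianModel")) a@caXYZ else as.matrix(a)
  xb <- if (is(b, "CartesianModel")) b@caXYZ else as.matrix(b)
  if (nrow(xa) != nrow(xb)) stop("models differ in length")
  rmsdCoords(xa, xb)
}
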