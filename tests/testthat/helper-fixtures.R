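# Shared in-code fixtures. Everything is generated deterministically; no
# files are read.

tinyTarget <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeToyTarget(12, "helix-bundle", seed = 3)
    cache
  }
})

tinyLib9 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeLibrary(tinyTarget(), 9L, depth = 10L,
                            nativeEnrichment = 0.5, seed = 1)
    cache
  }
})

tinyLib3 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeLibrary(tinyTarget(), 3L, depth = 20L,
                            nativeEnrichment = 0.5, seed = 2)
    cache
  }
})

randomChain <- function(n, seed) {
  set.seed(seed)
  TorsionChain(paste(sample(strsplit("ACDEFHIKLMNPQRSTVWY", "")[[1]], n,
                            TRUE), collapse = ""),
               paste(sample(c("H", "E", "L"), n, TRUE), collapse = ""),
               runif(n, -179, 180), runif(n, -179, 180),
               runif(n, 160, 180))
}

rotationMatrix <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

rigidMoveModel <- function(model, r, tvec) {
  move <- function(x) sweep(x %*% t(r), 2L, tvec, "+")
  methods::new("CartesianModel", nXYZ = move(nCoords(model)),
               caXYZ = move(caCoords(model)), cXYZ = move(cCoords(model)),
               cenXYZ = move(centroidCoords(model)),
               sequence = chainSequence(model), ss = chainSS(model),
               phi = model@phi, psi = model@psi, omega = model@omega)
}

# numerical RMSD oracle: minimise over explicit rotations (no Kabsch)
rmsdOracle <- function(a, b) {
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  f <- function(par) {
    r <- rotationMatrix(par[1], par[2], par[3])
    sqrt(mean(rowSums((ac - bc %*% t(r))^2)))
  }
  best <- Inf
  for (s in 1:12) {
    set.seed(s)
    o <- optim(runif(3, -pi, pi), f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# tiny rosetta-dialect fragment file content (2 windows x 3 fragments of
# length 3); torsions in columns 6-8, one includes an out-of-range angle
rosettaFragText <- function() {
  frag <- function(phi, psi, om)
    sprintf(" 2gb1 A   %2d V H %9.3f %9.3f %9.3f  0.50", 10:12, phi, psi, om)
  c("position:            1 neighbors:          3", "",
    frag(c(-60, -65, -70), c(-40, -45, -50), c(180, 180, 180)), "",
    frag(c(-120, -118, -116), c(130, 132, 134), c(180, 180, 180)), "",
    frag(c(200, -75, -80), c(145, 150, 155), c(180, 180, 180)), "",
    "position:            2 neighbors:          3", "",
    frag(c(-58, -61, -64), c(-38, -41, -44), c(180, 180, 180)), "",
    frag(c(-122, -119, -117), c(128, 131, 133), c(180, 180, 180)), "",
    frag(c(-90, -85, -88), c(0, 5, -5), c(180, 180, 180)), "")
}
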