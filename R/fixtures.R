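## Synthetic test substrate: toy targets with known compact natives, fragment
## libraries with controlled native enrichment, and noisy secondary-structure
## predictions. Everything is deterministic given a seed.

## Ramachandran basin centres (phi, psi) and the jitter half-widths used when
## sampling decoy torsions; omega is drawn near trans (180 +/- 2 degrees).
RAMA_BASINS <- list(
  alpha = c(phi = -62, psi = -41, jphi = 12, jpsi = 12),
  beta = c(phi = -120, psi = 130, jphi = 20, jpsi = 20),
  ppii = c(phi = -75, psi = 145, jphi = 10, jpsi = 10)
)

## SS-conditional basin weights for decoy fragments (alpha, beta, ppii)
RAMA_WEIGHTS <- list(H = c(0.70, 0.15, 0.15),
                     E = c(0.15, 0.70, 0.15),
                     L = c(0.34, 0.33, 0.33))

drawBasinTorsions <- function(ss) {
  w <- RAMA_WEIGHTS[[ss]]
  b <- RAMA_BASINS[[sample.int(3L, 1L, prob = w)]]
  c(wrapAngle(b[["phi"]] + stats::runif(1L, -b[["jphi"]], b[["jphi"]])),
    wrapAngle(b[["psi"]] + stats::runif(1L, -b[["jpsi"]], b[["jpsi"]])),
    wrapAngle(180 + stats::runif(1L, -2, 2)))
}

## Loop torsion templates that fold the chain back on itself. The (phi, psi)
## values were calibrated numerically (Nelder-Mead on compactness + clash
## objectives over canonical 2- and 3-element layouts) and are frozen here;
## omega stays trans. Each motif has a cycle of 4-residue turn templates.
TURN_TEMPLATES <- list(
  "helix-bundle" = list(
    two = list(rbind(c(-57.2, -130.8), c(-47.0, 105.8), c(2.5, 149.7),
                     c(144.2, 72.6))),
    multi = list(rbind(c(-46.0, -91.3), c(-40.4, 117.9), c(33.3, 126.9),
                       c(114.8, 66.5)),
                 rbind(c(48.4, 51.2), c(-172.9, -32.5), c(-114.9, 84.0),
                       c(-78.6, 11.8)))),
  "hairpin-sheet" = list(
    two = list(rbind(c(36.4, 47.8), c(-153.6, -83.1), c(-78.7, 93.0),
                     c(-16.7, -24.3))),
    multi = list(rbind(c(47.5, -19.4), c(-15.3, 92.9), c(-73.0, -39.9),
                       c(-105.8, -93.8)),
                 rbind(c(44.1, 72.2), c(70.5, 31.1), c(-22.2, -41.2),
                       c(54.6, -34.1)))),
  "mixed" = list(
    two = list(rbind(c(-55.2, 20.4), c(112.6, 162.4), c(125.4, 134.7),
                     c(-38.6, -49.2))),
    multi = list(rbind(c(-55.2, 20.4), c(112.6, 162.4), c(125.4, 134.7),
                       c(-38.6, -49.2)),
                 rbind(c(8.2, -1.4), c(123.6, -132.5), c(117.7, -146.9),
                       c(-118.0, -8.9))))
)

splitLengths <- function(core, k) {
  lens <- rep(core %/% k, k)
  if (core %% k) lens[seq_len(core %% k)] <- lens[seq_len(core %% k)] + 1L
  lens
}

motifLayout <- function(n, motif) {
  loopLen <- 4L
  if (motif == "helix-bundle") {
    nEl <- max(2L, min(5L, round((n + loopLen) / 18)))
    labels <- rep("H", nEl)
  } else if (motif == "hairpin-sheet") {
    ## strands must stay short: long two-strand hairpins cannot reach the
    ## compactness target
    nEl <- max(2L, min(8L, round((n + loopLen) / 9)))
    labels <- rep("E", nEl)
  } else { # mixed: one helix block then short strands
    nStr <- max(1L, round(0.55 * n / 11))
    labels <- c("H", rep("E", nStr))
    nEl <- length(labels)
  }
  core <- n - (nEl - 1L) * loopLen
  if (core < 3L * nEl) { # very short chains: fall back to two elements
    nEl <- 2L
    labels <- labels[c(1L, length(labels))]
    core <- n - loopLen
  }
  lens <- if (motif == "mixed" && nEl > 1L) {
    h <- max(3L, round(0.45 * core))
    c(h, splitLengths(core - h, nEl - 1L))
  } else splitLengths(core, nEl)
  ss <- character(0)
  for (i in seq_len(nEl)) {
    ss <- c(ss, rep(labels[i], lens[i]))
    if (i < nEl) ss <- c(ss, rep("L", loopLen))
  }
  ss
}

nativeTorsionsFor <- function(ss, motif, jitter = 2) {
  n <- length(ss)
  phi <- psi <- numeric(n)
  omega <- rep(180, n)
  phi[ss == "H"] <- -62
  psi[ss == "H"] <- -41
  phi[ss == "E"] <- -120
  psi[ss == "E"] <- 130
  nTurns <- sum(rle(ss)$values == "L")
  tset <- if (nTurns <= 1L) TURN_TEMPLATES[[motif]]$two
          else TURN_TEMPLATES[[motif]]$multi
  runs <- rle(ss)
  pos <- 1L
  turnId <- 0L
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    if (runs$values[k] == "L") {
      turnId <- turnId + 1L
      tmpl <- tset[[(turnId - 1L) %% length(tset) + 1L]]
      for (j in seq_len(len)) {
        row <- tmpl[(j - 1L) %% nrow(tmpl) + 1L, ]
        phi[pos + j - 1L] <- row[1L]
        psi[pos + j - 1L] <- row[2L]
      }
    }
    pos <- pos + len
  }
  phi <- wrapAngle(phi + stats::runif(n, -jitter, jitter))
  psi <- wrapAngle(psi + stats::runif(n, -jitter, jitter))
  list(phi = phi, psi = psi, omega = omega)
}

#' Generate a toy target with a known compact native
#'
#' Builds a synthetic target: a random sequence, a true secondary-structure
#' string following the requested motif, and a native torsion chain whose
#' rebuilt model is compact (radius of gyration below 1.3 times the
#' `2.2 * N^0.38` ideal) and clash-free (no C-alpha pair under 3 Angstroms).
#' Element torsions sit at canonical helix/strand values and loops use
#' hand-tuned turn templates; small per-seed jitter makes each target unique.
#' Jitter draws are retried (deterministically) until the invariants hold.
#'
#' @param nResidues chain length, 10..150.
#' @param motif one of `"helix-bundle"`, `"hairpin-sheet"`, `"mixed"`.
#' @param seed RNG seed; targets are deterministic given (n, motif, seed).
#' @return list with `sequence`, `ssTrue`, `native` ([TorsionChain-class]),
#'   `nativeModel` ([CartesianModel-class]), `seed`.
#' @export
makeToyTarget <- function(nResidues,
                          motif = c("helix-bundle", "hairpin-sheet", "mixed"),
                          seed = 1L) {
  motif <- match.arg(motif)
  if (nResidues < 10L || nResidues > 150L)
    stop("nResidues must be in 10..150")
  set.seed(seed)
  ss <- motifLayout(as.integer(nResidues), motif)
  sequence <- sample(setdiff(AA_CODES, "G"), nResidues, replace = TRUE)
  sequence[ss == "L"] <- "G"   # glycine-rich turns, keeps turns clash-free
  rgMax <- 1.3 * 2.2 * nResidues^0.38
  rgTarget <- 2.2 * nResidues^0.38
  okNative <- function(model) {
    min(stats::dist(model@caXYZ)) >= 3.0 &&
      radiusOfGyration(model) <= rgMax
  }
  best <- NULL
  bestRg <- Inf
  for (try in 1:20) {
    tor <- nativeTorsionsFor(ss, motif, jitter = 2)
    chain <- TorsionChain(sequence, ss, tor$phi, tor$psi, tor$omega)
    model <- buildCartesian(chain)
    rg <- radiusOfGyration(model)
    if (min(stats::dist(model@caXYZ)) >= 3.0 && rg < bestRg) {
      best <- list(chain = chain, model = model)
      bestRg <- rg
    }
    if (!is.null(best) && bestRg <= rgMax) break
  }
  if (is.null(best) || bestRg > rgMax) {
    ## polish loop torsions numerically, one loop at a time along the chain
    ## (chain-growth): each 4-residue turn is optimised against the prefix
    ## ending at the following element, under a compactness + clash
    ## objective. Deterministic given the seed.
    runs <- rle(ss)
    bounds <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(bounds, -1L) + 1L)
    loopRuns <- which(runs$values == "L")
    tor <- nativeTorsionsFor(ss, motif, jitter = 2)
    for (attempt in 1:3) {
      for (lr in loopRuns) {
        idx <- starts[lr]:bounds[lr]
        prefixEnd <- if (lr < length(runs$lengths)) bounds[lr + 1L]
                     else bounds[lr]
        pre <- seq_len(prefixEnd)
        rgPre <- 2.2 * length(pre)^0.38
        objective <- function(par) {
          p <- tor$phi[pre]
          q <- tor$psi[pre]
          p[idx] <- wrapAngle(par[seq_along(idx)])
          q[idx] <- wrapAngle(par[length(idx) + seq_along(idx)])
          ca <- caTraceOfChain(TorsionChain(sequence[pre], ss[pre], p, q,
                                            tor$omega[pre]))
          d <- stats::dist(ca)
          rg <- sqrt(mean(rowSums(sweep(ca, 2L, colMeans(ca))^2)))
          max(0, rg - rgPre)^2 + 20 * sum(pmax(0, 3.5 - d[d < 3.5])^2)
        }
        bestPar <- c(tor$phi[idx], tor$psi[idx])
        bestVal <- objective(bestPar)
        for (s in 1:4) {
          start0 <- if (s == 1L) bestPar else
            wrapAngle(bestPar + stats::runif(length(bestPar), -40, 40))
          opt <- stats::optim(start0, objective, method = "Nelder-Mead",
                              control = list(maxit = 1200L))
          if (opt$value < bestVal) {
            bestVal <- opt$value
            bestPar <- opt$par
          }
          if (bestVal < 1e-4) break
        }
        tor$phi[idx] <- wrapAngle(bestPar[seq_along(idx)])
        tor$psi[idx] <- wrapAngle(bestPar[length(idx) + seq_along(idx)])
      }
      chain <- TorsionChain(sequence, ss, tor$phi, tor$psi, tor$omega)
      model <- buildCartesian(chain)
      if (okNative(model)) {
        best <- list(chain = chain, model = model)
        bestRg <- radiusOfGyration(model)
        break
      }
      tor <- nativeTorsionsFor(ss, motif, jitter = 8)
    }
  }
  if (is.null(best) || bestRg > rgMax)
    stop("could not generate a compact clash-free native for this size/motif")
  list(sequence = paste(sequence, collapse = ""),
       ssTrue = paste(ss, collapse = ""), native = best$chain,
       nativeModel = best$model, seed = seed)
}

#' Generate a synthetic fragment library for a toy target
#'
#' Each insertion window receives `depth` fragments. With probability
#' `nativeEnrichment` a window's list includes the exact native fragment
#' (the native torsions over that window) at a random rank; all remaining
#' fragments are decoys drawn from three Ramachandran basins (alpha, beta,
#' polyproline-II-like) with secondary-structure-conditional weights.
#'
#' @param target a [makeToyTarget()] result.
#' @param fragLength fragment length (9 or 3).
#' @param depth fragments per window (standard: 25 for 9-mers, 200 for
#'   3-mers).
#' @param nativeEnrichment per-window probability of containing the native
#'   fragment, in \[0, 1\].
#' @param seed RNG seed.
#' @return a [FragmentLibrary-class].
#' @export
makeLibrary <- function(target, fragLength = 9L, depth = 25L,
                        nativeEnrichment = 0.5, seed = 1L) {
  if (nativeEnrichment < 0 || nativeEnrichment > 1)
    stop("nativeEnrichment must be in [0, 1]")
  force(target)   # lazy target expressions may touch the RNG
  set.seed(seed)
  native <- target$native
  ssVec <- native@ss
  n <- length(native)
  fragLength <- as.integer(fragLength)
  nWin <- windowCount(n, fragLength)
  if (nWin < 1L) stop("fragment length exceeds chain length")
  windows <- vector("list", nWin)
  for (w in seq_len(nWin)) {
    idx <- w:(w + fragLength - 1L)
    frags <- vector("list", depth)
    nativeRank <- if (stats::runif(1L) < nativeEnrichment)
      sample.int(depth, 1L) else 0L
    for (r in seq_len(depth)) {
      if (r == nativeRank) {
        frags[[r]] <- Fragment(torsions(native)[idx, , drop = FALSE],
                               source = "native")
      } else {
        t <- t(vapply(ssVec[idx], drawBasinTorsions, numeric(3L)))
        frags[[r]] <- Fragment(t, source = "decoy")
      }
    }
    windows[[w]] <- frags
  }
  FragmentLibrary(windows, fragLength)
}

#' Generate a noisy secondary-structure prediction
#'
#' Keeps each residue's true label with probability `q3Accuracy`, otherwise
#' replaces it with one of the two other labels uniformly.
#'
#' @param ssTrue true secondary-structure string (H/E/L).
#' @param q3Accuracy per-residue retention probability in \[0, 1\].
#' @param seed RNG seed.
#' @return predicted ss string.
#' @export
makeSsPrediction <- function(ssTrue, q3Accuracy, seed = 1L) {
  if (q3Accuracy < 0 || q3Accuracy > 1) stop("q3Accuracy must be in [0, 1]")
  force(ssTrue)
  set.seed(seed)
  ss <- strsplit(ssTrue, "")[[1]]
  flip <- stats::runif(length(ss)) >= q3Accuracy
  for (i in which(flip))
    ss[i] <- sample(setdiff(SS_CODES, ss[i]), 1L)
  paste(ss, collapse = "")
}
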