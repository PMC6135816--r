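## Fragment libraries: readers/writers, truncation, the standard insertion
## operator, and the conservative (lever-arm-penalised) insertion used late
## in stage 4.

#' Number of insertion windows for a chain/library combination
#' @param chainLength number of residues.
#' @param fragLength fragment length.
#' @return chainLength - fragLength + 1.
#' @export
windowCount <- function(chainLength, fragLength) chainLength - fragLength + 1L

#' Read a fragment library
#'
#' Two dialects are supported. `"tsv"` is the package's native tabular
#' format with columns `window_start`, `rank`, `pos`, `phi`, `psi`, `omega`.
#' `"rosetta_frag"` parses the classic fragment-picker interchange format:
#' `position: P neighbors: K` header lines, then one row per fragment
#' residue whose backbone torsions sit in fixed whitespace-separated columns
#' (pdb id, chain, residue number, amino acid, secondary structure, phi,
#' psi, omega, ...); fragments are separated by blank lines and trailing
#' columns are tolerated. Only the torsions are consumed. File order defines
#' rank. All torsions are wrapped into (-180, 180].
#'
#' @param path file path.
#' @param dialect `"rosetta_frag"` or `"tsv"`.
#' @return a [FragmentLibrary-class].
#' @export
readFragments <- function(path, dialect = c("rosetta_frag", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") readFragmentsTsv(path) else readFragmentsRosetta(path)
}

readFragmentsTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("window_start", "rank", "pos", "phi", "psi", "omega")
  if (!all(need %in% names(tab)))
    stop("tsv fragment file must have columns: ", paste(need, collapse = ", "))
  starts <- sort(unique(tab$window_start))
  if (!identical(starts, seq(min(starts), max(starts))) || min(starts) != 1L)
    stop("window gap: window starts must cover 1..n without gaps")
  lens <- unique(tapply(tab$pos, paste(tab$window_start, tab$rank), length))
  if (length(lens) != 1L) stop("fragments of mixed length in file")
  windows <- lapply(starts, function(s) {
    sub <- tab[tab$window_start == s, , drop = FALSE]
    lapply(sort(unique(sub$rank)), function(r) {
      fr <- sub[sub$rank == r, , drop = FALSE]
      fr <- fr[order(fr$pos), , drop = FALSE]
      Fragment(cbind(fr$phi, fr$psi, fr$omega), source = "tsv")
    })
  })
  FragmentLibrary(windows, fragLength = as.integer(lens))
}

readFragmentsRosetta <- function(path) {
  lines <- readLines(path)
  windows <- list()
  curFrags <- list()
  curRows <- NULL
  pos <- NA_integer_
  fragLen <- NA_integer_
  flushFrag <- function() {
    if (!is.null(curRows)) {
      curFrags[[length(curFrags) + 1L]] <<- Fragment(curRows,
                                                     source = "rosetta_frag")
      if (is.na(fragLen)) fragLen <<- nrow(curRows)
      else if (nrow(curRows) != fragLen)
        stop("fragments of mixed length in file")
      curRows <<- NULL
    }
  }
  flushWindow <- function() {
    flushFrag()
    if (length(curFrags)) {
      if (!is.na(pos)) windows[[pos]] <<- curFrags
      curFrags <<- list()
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^position:", ln)) {
      flushWindow()
      m <- regmatches(ln, regexec("^position:\\s*(\\d+)", ln))[[1]]
      if (length(m) < 2L) stop("malformed position header at line ", i)
      pos <- as.integer(m[2L])
    } else if (ln == "") {
      flushFrag()
    } else {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 8L) stop("malformed fragment record at line ", i)
      tors <- suppressWarnings(as.numeric(f[6:8]))
      if (any(is.na(tors))) stop("malformed torsion columns at line ", i)
      curRows <- rbind(curRows, tors)
    }
  }
  flushWindow()
  if (length(windows) == 0L) stop("no fragments found in file")
  empties <- vapply(windows, is.null, TRUE)
  if (any(empties))
    stop("window gap: missing window(s) at start position(s) ",
         paste(which(empties), collapse = ", "))
  FragmentLibrary(windows, fragLength = fragLen)
}

#' Write a fragment library in the tsv dialect
#' @param lib a [FragmentLibrary-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFragments <- function(lib, path) {
  rows <- do.call(rbind, lapply(seq_along(lib@windows), function(s) {
    do.call(rbind, lapply(seq_along(lib@windows[[s]]), function(r) {
      t <- lib@windows[[s]][[r]]@torsions
      data.frame(window_start = s, rank = r, pos = seq_len(nrow(t)),
                 phi = round(t[, 1L], 3L), psi = round(t[, 2L], 3L),
                 omega = round(t[, 3L], 3L))
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncate a library to a fixed depth
#'
#' Keeps the first `min(depth, available)` fragments per window, preserving
#' order. Standard use keeps the 25 highest-scoring 9-mers and top 200
#' 3-mers per window.
#'
#' @param lib a [FragmentLibrary-class].
#' @param depth maximum fragments per window (>= 1).
#' @return a [FragmentLibrary-class].
#' @export
truncateLibrary <- function(lib, depth) {
  if (depth < 1) stop("depth must be >= 1")
  FragmentLibrary(lapply(lib@windows, function(w)
    w[seq_len(min(length(w), depth))]), lib@fragLength)
}

#' Insert a fragment into a chain
#'
#' Overwrites the torsions of residues `windowStart .. windowStart + L - 1`
#' with the fragment's; all other residues are unchanged. Later insertions
#' can partially or completely overwrite earlier ones.
#'
#' @param chain a [TorsionChain-class].
#' @param windowStart 1-based start residue of the insertion window.
#' @param frag a [Fragment-class].
#' @return the modified [TorsionChain-class].
#' @export
insertFragment <- function(chain, windowStart, frag) {
  L <- nrow(frag@torsions)
  if (windowStart < 1L || windowStart > length(chain) - L + 1L)
    stop("insertion window out of range")
  idx <- windowStart:(windowStart + L - 1L)
  chain@phi[idx] <- frag@torsions[, 1L]
  chain@psi[idx] <- frag@torsions[, 2L]
  chain@omega[idx] <- frag@torsions[, 3L]
  chain
}

#' Lever-arm penalty of a fragment insertion
#'
#' A conservative-move penalty in the spirit of the Gunn cost: it estimates
#' how much a proposed insertion displaces the rest of the chain. Both chains
#' are rebuilt in the canonical frame (which holds the segment preceding the
#' window fixed) and the penalty is the unsuperposed C-alpha RMSD over all
#' residues outside the insertion window. It is zero when the insertion
#' leaves all non-window residues unmoved, in particular for insertions at
#' the final window.
#'
#' @param chainBefore,chainAfter chains differing only inside the window.
#' @param windowStart window start residue (1-based).
#' @param L window length.
#' @return non-negative penalty (Angstroms).
#' @export
gunnPenalty <- function(chainBefore, chainAfter, windowStart, L) {
  n <- length(chainBefore)
  idx <- windowStart:(windowStart + L - 1L)
  out <- setdiff(seq_len(n), idx)
  tb <- torsions(chainBefore)
  ta <- torsions(chainAfter)
  if (length(out) && any(wrapAngle(tb[out, ] - ta[out, ]) != 0))
    stop("chains differ outside the insertion window")
  if (!length(out)) return(0)
  ca1 <- caTraceOfChain(chainBefore)
  ca2 <- caTraceOfChain(chainAfter)
  sqrt(mean(rowSums((ca1[out, , drop = FALSE] - ca2[out, , drop = FALSE])^2)))
}

#' Draw a uniform (window, fragment) proposal from a library
#' @param lib a [FragmentLibrary-class].
#' @return list with `window` and `frag`. Draws two uniforms from the RNG.
#' @keywords internal
drawMove <- function(lib) {
  w <- sample.int(length(lib@windows), 1L)
  f <- sample.int(length(lib@windows[[w]]), 1L)
  list(window = w, frag = lib@windows[[w]][[f]], rank = f)
}

#' Conservative (lever-arm-minimising) fragment move
#'
#' Samples `draws` candidate (window, fragment) pairs uniformly and returns
#' the candidate with the smallest [gunnPenalty()], i.e. the insertion whose
#' lever-arm effect on the rest of the chain is minimal. Used in the latter
#' part of stage 4.
#'
#' @param chain current [TorsionChain-class].
#' @param lib a [FragmentLibrary-class].
#' @param draws number of candidates to sample (default 10).
#' @return list with `window`, `frag`, `rank`, `penalty`.
#' @export
gunnBiasedMove <- function(chain, lib, draws = 10L) {
  caBefore <- caTraceOfChain(chain)
  n <- nrow(caBefore)
  L <- lib@fragLength
  best <- NULL
  for (i in seq_len(draws)) {
    mv <- drawMove(lib)
    cand <- insertFragment(chain, mv$window, mv$frag)
    out <- setdiff(seq_len(n), mv$window:(mv$window + L - 1L))
    pen <- if (!length(out)) 0 else {
      caAfter <- caTraceOfChain(cand)
      sqrt(mean(rowSums((caBefore[out, , drop = FALSE] -
                         caAfter[out, , drop = FALSE])^2)))
    }
    if (is.null(best) || pen < best$penalty) {
      best <- mv
      best$penalty <- pen
    }
  }
  best
}
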