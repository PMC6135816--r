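## Shared format readers/writers: PSIPRED .ss2, FASTA, PDB (backbone +
## centroid pseudoatom), decoy manifests, trajectory logs, run configs.

#' Read a PSIPRED .ss2 secondary-structure prediction
#'
#' Parses the standard vertical format: comment/blank lines, then one row
#' per residue with index, amino acid, predicted label and the three state
#' confidences (coil, helix, strand). Coil labels `C` are mapped to `L`.
#'
#' @param path .ss2 file.
#' @param sequence optional sequence; length consistency is checked.
#' @return list with `ss` (string over H/E/L), `aa` (string) and `conf`
#'   (n-by-3 matrix, columns L/H/E).
#' @export
readSs2 <- function(path, sequence = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  aa <- character(0)
  ss <- character(0)
  conf <- NULL
  for (i in rows) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6L) stop("malformed .ss2 record at line ", i)
    v <- suppressWarnings(as.numeric(f[4:6]))
    if (any(is.na(v)) || !f[3L] %in% c("H", "E", "C", "L"))
      stop("malformed .ss2 record at line ", i)
    aa <- c(aa, f[2L])
    ss <- c(ss, if (f[3L] == "C") "L" else f[3L])
    conf <- rbind(conf, v)
  }
  if (!length(ss)) stop("no residues found in ", path)
  dimnames(conf) <- list(NULL, c("L", "H", "E"))
  if (!is.null(sequence)) {
    n <- if (length(sequence) == 1L) nchar(sequence) else length(sequence)
    if (n != length(ss))
      stop("sequence length (", n, ") does not match .ss2 (", length(ss), ")")
  }
  list(ss = paste(ss, collapse = ""), aa = paste(aa, collapse = ""),
       conf = conf)
}

#' Write a PSIPRED-style .ss2 file
#' @param sequence amino-acid string.
#' @param ss secondary-structure string (H/E/L; L written as C).
#' @param path output file.
#' @param conf optional n-by-3 confidence matrix (columns L/H/E); defaults
#'   to full confidence in the given label.
#' @return `path`, invisibly.
#' @export
writeSs2 <- function(sequence, ss, path, conf = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  s <- strsplit(ss, "")[[1]]
  if (is.null(conf)) {
    conf <- matrix(0, length(s), 3L, dimnames = list(NULL, c("L", "H", "E")))
    conf[cbind(seq_along(s), match(s, c("L", "H", "E")))] <- 1
  }
  out <- c("# PSIPRED VFORMAT (synthetic)", "",
           sprintf("%4d %s %s  %6.3f %6.3f %6.3f", seq_along(s), aa,
                   ifelse(s == "L", "C", s), conf[, "L"], conf[, "H"],
                   conf[, "E"]))
  writeLines(out, path)
  invisible(path)
}

#' Read a single sequence from a FASTA file
#' @param path FASTA file.
#' @return amino-acid string (first record).
#' @export
readFastaSequence <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("readFastaSequence requires the Biostrings package")
  as.character(Biostrings::readAAStringSet(path)[[1L]])
}

#' Write a single-record FASTA file
#' @param sequence amino-acid string.
#' @param path output file.
#' @param name record name.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(sequence, path, name = "target") {
  writeLines(c(paste0(">", name), sequence), path)
  invisible(path)
}

#' Write a low-resolution model as PDB
#'
#' Emits ATOM records for N, CA, C and the sidechain centroid pseudoatom
#' (atom name `CEN`) of each residue.
#'
#' @param model a [CartesianModel-class] (or [TorsionChain-class], built
#'   first).
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(model, path) {
  if (is(model, "TorsionChain")) model <- buildCartesian(model)
  n <- length(model)
  resid3 <- vapply(model@sequence, bio3d::aa123, character(1L))
  xyz <- numeric(0)
  elety <- character(0)
  resno <- integer(0)
  resid <- character(0)
  for (i in seq_len(n)) {
    xyz <- c(xyz, model@nXYZ[i, ], model@caXYZ[i, ], model@cXYZ[i, ],
             model@cenXYZ[i, ])
    elety <- c(elety, c("N", "CA", "C", "CEN"))
    resno <- c(resno, rep(i, 4L))
    resid <- c(resid, rep(resid3[i], 4L))
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = "A")
  invisible(path)
}

#' Read a low-resolution model from PDB
#'
#' Expects the layout written by [writePDB()] (N, CA, C and optionally CEN
#' per residue). Torsions are recomputed from the coordinates; undefined
#' terminal torsions are set to the extended-chain values. Secondary
#' structure is not stored in PDB and defaults to all-L unless given.
#'
#' @param path PDB file.
#' @param ss optional secondary-structure string.
#' @return a [CartesianModel-class].
#' @export
readPDBModel <- function(path, ss = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  resnos <- sort(unique(at$resno))
  n <- length(resnos)
  pick <- function(name) {
    m <- matrix(NA_real_, n, 3L)
    sel <- at$elety == name
    m[match(at$resno[sel], resnos), ] <-
      cbind(at$x[sel], at$y[sel], at$z[sel])
    m
  }
  N <- pick("N")
  CA <- pick("CA")
  C <- pick("C")
  CEN <- pick("CEN")
  if (any(is.na(N)) || any(is.na(CA)) || any(is.na(C)))
    stop("PDB lacks complete N/CA/C backbone")
  if (any(is.na(CEN))) CEN <- CA
  seq1 <- vapply(at$resid[match(resnos, at$resno)], bio3d::aa321,
                 character(1L))
  if (is.null(ss)) ss <- rep("L", n)
  if (length(ss) == 1L && nchar(ss) > 1L) ss <- strsplit(ss, "")[[1]]
  phi <- rep(-150, n)
  psi <- rep(150, n)
  omega <- rep(180, n)
  if (n > 1L) {
    for (i in 2:n) phi[i] <- dihedralDeg(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    for (i in seq_len(n - 1L)) {
      psi[i] <- dihedralDeg(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
      omega[i] <- dihedralDeg(CA[i, ], C[i, ], N[i + 1L, ], CA[i + 1L, ])
    }
  }
  new("CartesianModel", nXYZ = N, caXYZ = CA, cXYZ = C, cenXYZ = CEN,
      sequence = seq1, ss = ss, phi = phi, psi = psi, omega = omega)
}

#' Write decoys and a score manifest
#'
#' One PDB per decoy plus a TSV manifest with columns id, file, score, seed.
#'
#' @param decoys an [Archive-class] or list of chains/models.
#' @param outDir output directory (created if needed).
#' @param scores per-decoy scores (taken from the archive if omitted).
#' @param seed run seed recorded in the manifest.
#' @return the manifest data.frame, invisibly.
#' @export
writeDecoys <- function(decoys, outDir, scores = NULL, seed = NA_integer_) {
  if (is(decoys, "Archive")) {
    scores <- decoys@scores
    decoys <- decoys@members
  }
  if (!length(decoys)) stop("empty decoy set")
  if (is.null(scores)) scores <- rep(NA_real_, length(decoys))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("decoy_%03d.pdb", seq_along(decoys))
  for (i in seq_along(decoys)) writePDB(decoys[[i]], file.path(outDir,
                                                               files[i]))
  manifest <- data.frame(id = seq_along(decoys), file = files,
                         score = scores, seed = seed)
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write a trajectory log as gzipped TSV
#' @param log a [TrajectoryLog-class].
#' @param path output path (e.g. `trajectory.tsv.gz`).
#' @return `path`, invisibly.
#' @export
writeTrajectoryLog <- function(log, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(moveTable(log), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a run configuration (YAML)
#'
#' A config snapshot together with the seed is sufficient to reproduce a run
#' bit-for-bit.
#'
#' @param config a named list (e.g. [baselineConfig()] plus run metadata);
#'   ScoreFunction entries are serialised as weight maps.
#' @param path YAML file.
#' @return `path` / the config list.
#' @export
writeRunConfig <- function(config, path) {
  ser <- config
  if (!is.null(ser$sets))
    ser$sets <- lapply(ser$sets, function(fn) as.list(fn@weights))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sets))
    cfg$sets <- lapply(setNames(names(cfg$sets), names(cfg$sets)),
                       function(nm) ScoreFunction(nm, unlist(cfg$sets[[nm]])))
  cfg
}
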