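#' Construct a trajectory ensemble
#'
#' Container for a residue-resolved coordinate trajectory: a
#' `frames x residues x 3` array of alpha-carbon positions with residue
#' metadata, optionally carrying all-atom coordinates for heavy-atom
#' contact analysis.
#'
#' @param coords Numeric array `frames x residues x 3`, Angstrom.
#' @param residues Tibble with one row per residue (`chain`, `resid`,
#'   `resname`); autogenerated when omitted.
#' @param atom_coords Optional all-atom array `frames x atoms x 3`.
#' @param atom_residue Optional integer vector mapping each atom to its
#'   residue index (required with `atom_coords`).
#' @param aligned Whether frames are already superposed.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(coords, residues = NULL, atom_coords = NULL,
                                atom_residue = NULL, aligned = FALSE) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 2) stop("need at least 2 frames", call. = FALSE)
  n_res <- dim(coords)[2]
  if (is.null(residues)) {
    residues <- tibble::tibble(chain = "A", resid = seq_len(n_res),
                               resname = "ALA")
  }
  stopifnot(nrow(residues) == n_res)
  if (!is.null(atom_coords)) {
    stopifnot(length(dim(atom_coords)) == 3,
              dim(atom_coords)[1] == dim(coords)[1],
              length(atom_residue) == dim(atom_coords)[2],
              all(atom_residue %in% seq_len(n_res)))
  }
  structure(
    list(coords = coords, residues = tibble::as_tibble(residues),
         atom_coords = atom_coords, atom_residue = atom_residue,
         aligned = aligned),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d frames x %d residues%s%s\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (!is.null(x$atom_coords))
                sprintf(" (+%d atoms/frame)", dim(x$atom_coords)[2]) else "",
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' Read a coordinate trajectory from a multi-model PDB or XYZ file
#'
#' Multi-model PDB files (MODEL/ENDMDL records) are parsed with
#' `bio3d::read.pdb`; alpha carbons become the residue nodes and all
#' non-hydrogen atoms are retained for heavy-atom contact analysis. XYZ
#' trajectories treat every atom as a node candidate. Frames with
#' inconsistent atom counts raise a format error naming the frame.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"xyz"`.
#' @return A [trajectory_ensemble()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such trajectory file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") read_trajectory_pdb(path) else read_trajectory_xyz(path)
}

read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  atom_lines <- grepl("^ATOM  |^HETATM", lines)
  if (length(model_starts) < 2) {
    stop("PDB trajectory needs at least 2 MODEL records", call. = FALSE)
  }
  # validate per-model atom counts before handing to the parser
  model_id <- cumsum(grepl("^MODEL", lines))
  counts <- tapply(atom_lines[model_id > 0], model_id[model_id > 0], sum)
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf(
      "inconsistent atom count in frame %d (%d atoms vs %d in frame 1)",
      bad, counts[bad], counts[1]), call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                          # frames x 3*natoms
  n_frames <- nrow(xyz)
  natoms <- ncol(xyz) / 3
  atom_arr <- array(NA_real_, c(n_frames, natoms, 3))
  atom_arr[, , 1] <- xyz[, seq(1, ncol(xyz), 3)]
  atom_arr[, , 2] <- xyz[, seq(2, ncol(xyz), 3)]
  atom_arr[, , 3] <- xyz[, seq(3, ncol(xyz), 3)]

  at <- pdb$atom
  res_key <- paste(at$chain, at$resno)
  res_index <- match(res_key, unique(res_key))
  ca <- which(at$elety == "CA")
  if (!length(ca)) stop("no alpha carbons (CA atoms) found", call. = FALSE)
  heavy <- which(!(at$elesy %in% c("H", "D")) & !grepl("^H", at$elety))

  residues <- tibble::tibble(
    chain = at$chain[ca], resid = at$resno[ca], resname = at$resid[ca]
  )
  # residue index of each CA, remapped to 1..n_nodes
  ca_res <- res_index[ca]
  keep <- heavy[res_index[heavy] %in% ca_res]
  atom_res <- match(res_index[keep], ca_res)

  trajectory_ensemble(
    coords = atom_arr[, ca, , drop = FALSE],
    residues = residues,
    atom_coords = atom_arr[, keep, , drop = FALSE],
    atom_residue = atom_res
  )
}

read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      stop(sprintf("malformed atom count at frame %d", frame), call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop(sprintf("truncated frame %d", frame), call. = FALSE)
    }
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4)) {
      stop(sprintf("malformed coordinate line in frame %d", frame),
           call. = FALSE)
    }
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(co))) {
      stop(sprintf("non-numeric coordinates in frame %d", frame),
           call. = FALSE)
    }
    frames[[frame]] <- co
    i <- i + 2L + nat
  }
  if (length(frames) < 2) stop("XYZ trajectory needs at least 2 frames",
                               call. = FALSE)
  nat <- vapply(frames, nrow, 1L)
  if (length(unique(nat)) > 1) {
    bad <- which(nat != nat[1])[1]
    stop(sprintf("inconsistent atom count in frame %d (%d vs %d in frame 1)",
                 bad, nat[bad], nat[1]), call. = FALSE)
  }
  coords <- array(NA_real_, c(length(frames), nat[1], 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory_ensemble(coords)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Alpha-carbon-only writer (one CA atom per residue per MODEL), the
#' reduced representation used by the synthetic trajectory generator.
#' Coordinates are written at standard PDB precision (1e-3 Angstrom).
#'
#' @param traj A [trajectory_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  co <- traj$coords
  res <- traj$residues
  n_frames <- dim(co)[1]; n_res <- dim(co)[2]
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n_res), substr(res$resname, 1, 3), substr(res$chain, 1, 1),
      res$resid, co[f, , 1], co[f, , 2], co[f, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Generate a synthetic trajectory with a prescribed correlation structure
#'
#' Draws per-frame residue displacements about a base geometry so that the
#' displacement correlation matrix converges to `target_correlation` as the
#' number of frames grows: each spatial axis receives an independent
#' multivariate-normal draw with covariance
#' `fluctuation_sd^2 * target_correlation`. A synthetic stand-in for a
#' steered-MD pulling trajectory.
#'
#' @param n_residues Number of residues.
#' @param target_correlation Symmetric positive-semidefinite matrix with
#'   unit diagonal; defaults to the identity (independent residues).
#' @param base_geometry `n_residues x 3` matrix of mean positions,
#'   Angstrom; defaults to a straight chain with 3.8 A spacing.
#' @param n_frames Number of frames.
#' @param fluctuation_sd Displacement SD per axis, Angstrom.
#' @param seed Integer seed (deterministic output).
#' @return A [trajectory_ensemble()] (already aligned by construction).
#' @export
generate_correlated_trajectory <- function(n_residues,
                                           target_correlation = NULL,
                                           base_geometry = NULL,
                                           n_frames = 1000,
                                           fluctuation_sd = 1,
                                           seed = 1L) {
  if (is.null(target_correlation)) target_correlation <- diag(n_residues)
  C <- as.matrix(target_correlation)
  stopifnot(nrow(C) == n_residues, ncol(C) == n_residues)
  if (max(abs(C - t(C))) > 1e-8 || max(abs(diag(C) - 1)) > 1e-8) {
    stop("`target_correlation` must be symmetric with unit diagonal",
         call. = FALSE)
  }
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    stop("`target_correlation` is not positive semi-definite", call. = FALSE)
  }
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n_residues)
  if (is.null(base_geometry)) {
    base_geometry <- cbind(3.8 * (seq_len(n_residues) - 1), 0, 0)
  }
  base_geometry <- as.matrix(base_geometry)
  stopifnot(nrow(base_geometry) == n_residues, ncol(base_geometry) == 3)

  coords <- withr::with_seed(as.integer(seed), {
    out <- array(NA_real_, c(n_frames, n_residues, 3))
    for (ax in 1:3) {
      z <- matrix(stats::rnorm(n_frames * n_residues), n_frames, n_residues)
      disp <- fluctuation_sd * z %*% t(L)
      out[, , ax] <- sweep(disp, 2, base_geometry[, ax], `+`)
    }
    out
  })
  trajectory_ensemble(coords, aligned = TRUE)
}
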