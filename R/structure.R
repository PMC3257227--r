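#' Read a PDB structure
#'
#' Minimal fixed-column parser for ATOM/HETATM/MODEL/ENDMDL records, which
#' is all the downstream analyses need (coordinates in angstrom, original
#' 1-based residue numbering preserved).  Multi-model NMR-style files are
#' supported: the first model is returned by default and the model count is
#' reported in the `"n_models"` attribute.  Insertion codes are rejected --
#' the residue-keyed joins downstream assume plain integer numbering.
#'
#' @param path PDB file path.
#' @param model 1-based model index to extract.
#' @param hetatm include HETATM records (waters etc.)?
#' @return object of class `"structure_model"`: a list with `atoms` (a
#'   data.frame with columns `atom_name`, `res_seq`, `res_code`, `chain`,
#'   `element`, `x`, `y`, `z`) and attribute `n_models`.
#' @export
read_structure <- function(path, model = 1L, hetatm = TRUE) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") |
    (hetatm & startsWith(lines, "HETATM"))
  n_models <- max(1L, sum(startsWith(lines, "MODEL")))
  if (!any(is_atom)) stop("no ATOM records in ", path)
  # assign model index to each line
  model_idx <- cumsum(startsWith(lines, "MODEL"))
  model_idx[model_idx == 0L] <- 1L
  keep <- is_atom & model_idx == model
  if (!any(keep)) stop("model ", model, " not present (file has ", n_models, ")")
  rec <- lines[keep]
  icode <- substr(rec, 27, 27)
  if (any(icode != " "))
    stop("insertion codes are not supported")
  atom_name <- trimws(substr(rec, 13, 16))
  res_code <- trimws(substr(rec, 18, 20))
  chain <- substr(rec, 22, 22)
  res_seq <- as.integer(substr(rec, 23, 26))
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  element <- trimws(substr(rec, 77, 78))
  # fall back to the first alphabetic character of the atom name
  noel <- !nzchar(element)
  element[noel] <- substr(gsub("[^A-Za-z]", "", atom_name[noel]), 1, 1)
  if (any(!is.finite(c(x, y, z)))) stop("non-finite coordinates in ", path)
  structure_model(data.frame(atom_name = atom_name, res_seq = res_seq,
                             res_code = res_code, chain = chain,
                             element = toupper(element),
                             x = x, y = y, z = z, stringsAsFactors = FALSE),
                  n_models = n_models)
}

#' Construct a structure model
#' @param atoms data.frame with columns `atom_name`, `res_seq`, `res_code`,
#'   `element`, `x`, `y`, `z` (optional `chain`).
#' @param n_models number of models in the source file.
#' @return object of class `"structure_model"`.
#' @export
structure_model <- function(atoms, n_models = 1L) {
  need <- c("atom_name", "res_seq", "res_code", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) stop("atoms lacks columns: ",
                                         paste(setdiff(need, names(atoms)), collapse = ", "))
  if (nrow(atoms) < 1L) stop("structure must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  if (is.null(atoms$chain)) atoms$chain <- "A"
  structure(list(atoms = atoms), n_models = n_models,
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues, %d model(s)\n",
              nrow(x$atoms), length(unique(x$atoms$res_seq)),
              attr(x, "n_models") %||% 1L))
  invisible(x)
}

# coordinate matrix (n_atoms x 3)
coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

.pdb_atom_line <- function(i, a, bfac = 0) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i, ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name),
                    a$atom_name),
          a$res_code, a$chain %||% "A", a$res_seq, a$x, a$y, a$z, 1.00, bfac,
          a$element)
}

#' Write a structure as PDB
#' @param model a [structure_model()].
#' @param path output path.
#' @param bfactor optional per-atom numeric vector written to the B-factor
#'   column (used by the report module to map per-residue scalars onto the
#'   structure).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, bfactor = NULL) {
  a <- model$atoms
  if (is.null(bfactor)) bfactor <- rep(0, nrow(a))
  stopifnot(length(bfactor) == nrow(a))
  lines <- vapply(seq_len(nrow(a)), function(i)
    .pdb_atom_line(i, a[i, ], bfactor[i]), character(1))
  writeLines(c(provenance_header(lines), lines, "END"), path)
  invisible(path)
}

#' Multi-frame coordinate trajectory
#'
#' @param topology a [structure_model()] giving atom identities.
#' @param frames numeric array `n_frames x n_atoms x 3` (angstrom).
#' @param frame_interval_ps time between stored frames in picoseconds.
#' @param box optional `n_frames x 3` orthorhombic box edges (angstrom).
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames, frame_interval_ps = 0.2, box = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  d <- dim(frames)
  if (length(d) != 3L || d[3] != 3L) stop("frames must be n_frames x n_atoms x 3")
  if (d[2] != nrow(topology$atoms))
    stop("frame atom count inconsistent with topology")
  structure(list(topology = topology, frames = frames,
                 frame_interval_ps = frame_interval_ps, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt=%g ps\n",
              dim(x$frames)[1], dim(x$frames)[2], x$frame_interval_ps))
  invisible(x)
}

#' Read a multi-model PDB as a trajectory
#' @param path PDB with one MODEL per frame.
#' @param frame_interval_ps frame spacing in ps.
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(path, frame_interval_ps = 0.2) {
  first <- read_structure(path, model = 1L)
  n <- attr(first, "n_models")
  na <- nrow(first$atoms)
  fr <- array(NA_real_, c(n, na, 3))
  fr[1, , ] <- coords(first)
  if (n > 1L) for (m in 2:n) fr[m, , ] <- coords(read_structure(path, model = m))
  trajectory(first, fr, frame_interval_ps)
}

#' Write a trajectory as a multi-model PDB
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  n <- dim(traj$frames)[1]
  out <- character(0)
  for (m in seq_len(n)) {
    am <- a
    am$x <- traj$frames[m, , 1]; am$y <- traj$frames[m, , 2]
    am$z <- traj$frames[m, , 3]
    out <- c(out, sprintf("MODEL     %4d", m),
             vapply(seq_len(nrow(am)), function(i)
               .pdb_atom_line(i, am[i, ]), character(1)),
             "ENDMDL")
  }
  writeLines(c(provenance_header(out), out, "END"), path)
  invisible(path)
}
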