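# Trajectory post-processing: least-squares superposition, RMSF,
# hydrogen-bond percentage lifetimes, hydration-site density grids (MDHS),
# and probe-sphere atom depth indexes.

#' Kabsch least-squares superposition
#'
#' Returns the rigid transform (rotation + translation) that superposes
#' `mobile[sel, ]` onto `ref[sel, ]`, and applies it to all rows of
#' `mobile`.  A degenerate (collinear or < 3 atom) selection is rejected
#' because it does not determine the rotation.
#'
#' @param mobile,ref n x 3 coordinate matrices.
#' @param sel integer atom indices used for the superposition (default
#'   all).
#' @return transformed copy of `mobile`.
#' @export
superpose <- function(mobile, ref, sel = seq_len(nrow(mobile))) {
  stopifnot(ncol(mobile) == 3, ncol(ref) == 3)
  if (length(sel) < 3L) stop("superposition selection needs >= 3 atoms")
  A <- mobile[sel, , drop = FALSE]; B <- ref[sel, , drop = FALSE]
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  sv <- svd(crossprod(A0, B0))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-30))
    stop("degenerate superposition selection (collinear atoms)")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$u %*% S %*% t(sv$v)
  sweep(sweep(mobile, 2, cA) %*% R, 2, cB, `+`)
}

#' Per-atom root-mean-square fluctuations
#'
#' Each frame is least-squares superposed on the reference over the
#' superposition selection (removing global translation and rotation),
#' then the RMSF of every atom about its mean position is computed:
#' `rmsf_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param selection atom indices used for superposition (default all).
#' @param reference n_atoms x 3 reference coordinates (default the
#'   topology coordinates).
#' @return data.frame `atom`, `residue_seq`, `atom_name`, `rmsf` (angstrom).
#' @export
rmsf <- function(traj, selection = NULL, reference = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$frames)[1]
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(selection)) selection <- seq_len(dim(traj$frames)[2])
  if (is.null(reference)) reference <- coords(traj$topology)
  fitted <- array(NA_real_, dim(traj$frames))
  for (f in seq_len(nf))
    fitted[f, , ] <- superpose(traj$frames[f, , ], reference, selection)
  mean_pos <- apply(fitted, c(2, 3), mean)
  dev2 <- sweep(fitted, c(2, 3), mean_pos)^2
  msf <- apply(dev2, 2, sum) / nf       # sums x,y,z and frames
  data.frame(atom = seq_along(msf),
             residue_seq = traj$topology$atoms$res_seq,
             atom_name = traj$topology$atoms$atom_name,
             rmsf = sqrt(msf))
}

#' Hydrogen-bond criteria
#'
#' Geometric acceptance for a donor-acceptor contact: donor-acceptor
#' distance cutoff (default 3.5 angstrom, i.e. 0.35 nm) and an angular
#' cutoff of 75 degrees interpreted as the maximum deviation of the
#' D-H...A angle from linearity (`angle(D-H-A) >= 105` degrees); the
#' alternative `"adh"` convention accepts when the H-D-A angle at the
#' donor is below the cutoff.
#'
#' @param distance_cut_A donor-acceptor heavy-atom distance cutoff.
#' @param angle_cut_deg angular cutoff in degrees.
#' @param convention `"dha_deviation"` or `"adh"`.
#' @return list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(distance_cut_A = 3.5, angle_cut_deg = 75,
                           convention = c("dha_deviation", "adh")) {
  structure(list(distance_cut = distance_cut_A, angle_cut = angle_cut_deg,
                 convention = match.arg(convention)),
            class = "hbond_criteria")
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# does donor (d, h) bond acceptor a in coordinate frame X?
.hbond_ok <- function(X, d, h, a, crit) {
  if (sqrt(sum((X[d, ] - X[a, ])^2)) > crit$distance_cut) return(FALSE)
  if (crit$convention == "dha_deviation") {
    theta <- .angle_deg(X[d, ] - X[h, ], X[a, ] - X[h, ])  # D-H-A at H
    180 - theta <= crit$angle_cut
  } else {
    .angle_deg(X[h, ] - X[d, ], X[a, ] - X[d, ]) <= crit$angle_cut
  }
}

#' Hydrogen-bond percentage lifetimes
#'
#' For each donor, the percentage of trajectory frames in which at least
#' one acceptor satisfies the distance and angle criteria -- the
#' "hydrogen bond percentage lifetime".  The complementary
#' `freedom = 1 - lifetime/100` (fractional freedom from intramolecular
#' hydrogen bonding) is returned alongside, ready for
#' [correlate_with_hbond_freedom()].
#'
#' @param traj a [trajectory()].
#' @param donors data.frame with columns `d` (heavy donor atom index) and
#'   `h` (attached hydrogen index; NA skips the donor with a warning) and
#'   optionally `residue_seq`.
#' @param acceptors integer vector of acceptor atom indices.
#' @param criteria an [hbond_criteria()].
#' @return data.frame `d`, `h`, `residue_seq`, `lifetime_pct`, `freedom`.
#' @export
hbond_lifetimes <- function(traj, donors, acceptors,
                            criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "trajectory"), inherits(criteria, "hbond_criteria"))
  no_h <- is.na(donors$h)
  if (any(no_h)) {
    warning(sum(no_h), " donor(s) without attached hydrogen skipped")
    donors <- donors[!no_h, , drop = FALSE]
  }
  nf <- dim(traj$frames)[1]
  hits <- integer(nrow(donors))
  for (f in seq_len(nf)) {
    X <- traj$frames[f, , ]
    for (i in seq_len(nrow(donors))) {
      d <- donors$d[i]; h <- donors$h[i]
      acc <- setdiff(acceptors, c(d, h))
      # distance prefilter, then the angle test
      dd <- sqrt(colSums((t(X[acc, , drop = FALSE]) - X[d, ])^2))
      for (a in acc[dd <= criteria$distance_cut]) {
        if (.hbond_ok(X, d, h, a, criteria)) { hits[i] <- hits[i] + 1L; break }
      }
    }
  }
  data.frame(d = donors$d, h = donors$h,
             residue_seq = donors$residue_seq %||%
               traj$topology$atoms$res_seq[donors$d],
             lifetime_pct = 100 * hits / nf,
             freedom = 1 - hits / nf)
}

# distance from each point (m x 3) to the protein surface:
# min over heavy atoms of (euclidean distance - vdW radius)
.surface_distance <- function(points, protein_xyz, protein_radii,
                              chunk = 20000L) {
  m <- nrow(points)
  out <- numeric(m)
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(m, start + chunk - 1L)
    P <- points[idx, , drop = FALSE]
    dmin <- rep(Inf, length(idx))
    for (j in seq_len(nrow(protein_xyz))) {
      dj <- sqrt((P[, 1] - protein_xyz[j, 1])^2 +
                   (P[, 2] - protein_xyz[j, 2])^2 +
                   (P[, 3] - protein_xyz[j, 3])^2) - protein_radii[j]
      dmin <- pmin(dmin, dj)
    }
    out[idx] <- dmin
  }
  out
}

#' Water-density grid and molecular-dynamics hydration sites
#'
#' Frames are superposed on the reference over the protein selection, then
#' water-oxygen positions within `shell2_max` of the protein surface
#' (distance to the nearest heavy atom minus its van der Waals radius) are
#' binned on a 3D grid (default spacing 0.5 angstrom, i.e. 0.05 nm)
#' anchored to the reference bounding box padded by `shell2_max`.  Voxel
#' densities are normalized by the mean count over the bulk shell
#' (`shell1_max` to `shell2_max` from the surface); hydration sites (MDHS)
#' are first-shell voxels that are 26-neighbourhood local maxima with
#' normalized density at or above `site_factor` times bulk.
#'
#' @param traj a [trajectory()].
#' @param water_oxygens integer indices of water oxygen atoms.
#' @param protein_atoms integer indices of protein heavy atoms (default:
#'   all non-water, non-hydrogen atoms).
#' @param spacing_A grid step.
#' @param shell1_max_A,shell2_max_A first-shell / bulk-shell outer radii.
#' @param site_factor MDHS threshold as a multiple of bulk density.
#' @param superpose_frames superpose each frame on the topology reference
#'   first?
#' @return list of class `"hydration_grid"`: `origin`, `spacing`, `counts`
#'   (3D array), `density` (normalized), `bulk_mean_count`, `mdhs`
#'   (data.frame x, y, z, density), `total_obs`.
#' @export
hydration_grid <- function(traj, water_oxygens, protein_atoms = NULL,
                           spacing_A = 0.5, shell1_max_A = 6,
                           shell2_max_A = 8, site_factor = 2,
                           superpose_frames = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology$atoms
  if (is.null(protein_atoms))
    protein_atoms <- which(!(seq_len(nrow(top)) %in% water_oxygens) &
                             top$element != "H")
  ref <- coords(traj$topology)
  pxyz <- ref[protein_atoms, , drop = FALSE]
  pr <- vdw_radius(top$element[protein_atoms])
  # origin snapped to an absolute lattice (multiples of the grid spacing):
  # makes voxel boundaries reproducible and the binning equivariant under
  # axis-aligned rigid motions by multiples of the spacing
  origin <- spacing_A * floor((apply(pxyz, 2, min) - shell2_max_A -
                                 spacing_A) / spacing_A)
  upper <- apply(pxyz, 2, max) + shell2_max_A + spacing_A
  dims <- ceiling((upper - origin) / spacing_A) + 1L
  counts <- array(0L, dims)
  nf <- dim(traj$frames)[1]
  total_obs <- 0L
  for (f in seq_len(nf)) {
    X <- traj$frames[f, , ]
    if (superpose_frames) X <- superpose(X, ref, protein_atoms)
    W <- X[water_oxygens, , drop = FALSE]
    sd_w <- .surface_distance(W, pxyz, pr)
    W <- W[sd_w <= shell2_max_A, , drop = FALSE]
    if (nrow(W) == 0L) next
    ijk <- floor(sweep(W, 2, origin) / spacing_A) + 1L
    inside <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
    ijk <- ijk[inside, , drop = FALSE]
    for (r in seq_len(nrow(ijk)))
      counts[ijk[r, 1], ijk[r, 2], ijk[r, 3]] <-
        counts[ijk[r, 1], ijk[r, 2], ijk[r, 3]] + 1L
    total_obs <- total_obs + nrow(ijk)
  }
  # voxel-centre shell classification
  centers_axis <- function(k) origin[k] + (seq_len(dims[k]) - 0.5) * spacing_A
  gx <- centers_axis(1); gy <- centers_axis(2); gz <- centers_axis(3)
  vox <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  vs <- .surface_distance(vox, pxyz, pr)
  shell <- array(0L, dims)                     # 0 outside, 1 first, 2 bulk
  shell[vs <= shell1_max_A & vs > -Inf] <- 1L
  shell[vs > shell1_max_A & vs <= shell2_max_A] <- 2L
  # normalization uses only bulk voxels fully inside the counted region
  # (water observations are truncated at shell2_max, so voxels straddling
  # that boundary undercount and would bias the bulk mean low)
  margin <- spacing_A * sqrt(3) / 2
  bulk_full <- vs > shell1_max_A & vs <= shell2_max_A - margin
  if (!any(bulk_full)) bulk_full <- shell == 2L
  bulk_mean <- mean(counts[bulk_full])
  if (!is.finite(bulk_mean) || bulk_mean <= 0)
    stop("normalization error: empty bulk shell")
  density <- counts / bulk_mean
  # MDHS: first-shell local maxima above site_factor
  mdhs <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                     density = numeric(0))
  cand <- which(shell == 1L & density >= site_factor, arr.ind = TRUE)
  if (nrow(cand)) {
    is_max <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
      ni <- max(1, i - 1):min(dims[1], i + 1)
      nj <- max(1, j - 1):min(dims[2], j + 1)
      nk <- max(1, k - 1):min(dims[3], k + 1)
      nb <- counts[ni, nj, nk]
      is_max[r] <- counts[i, j, k] == max(nb)
    }
    cand <- cand[is_max, , drop = FALSE]
    mdhs <- data.frame(x = gx[cand[, 1]], y = gy[cand[, 2]],
                       z = gz[cand[, 3]],
                       density = density[cand])
    mdhs <- mdhs[order(-mdhs$density), , drop = FALSE]
  }
  structure(list(origin = origin, spacing = spacing_A, counts = counts,
                 density = density, shell = shell,
                 shell1_max = shell1_max_A, shell2_max = shell2_max_A,
                 bulk_mean_count = bulk_mean, mdhs = mdhs,
                 total_obs = total_obs),
            class = "hydration_grid")
}

#' @export
print.hydration_grid <- function(x, ...) {
  cat(sprintf("<hydration_grid> %s voxels @ %.2f A, %d water obs, %d MDHS\n",
              paste(dim(x$counts), collapse = "x"), x$spacing, x$total_obs,
              nrow(x$mdhs)))
  invisible(x)
}

#' Probe-sphere atom depth index
#'
#' For each target atom, a probe sphere (default radius 8 angstrom) is
#' centred on the atom and its solvent-exposed volume estimated by
#' deterministic grid quadrature (voxels of `spacing_A`), excluding voxels
#' inside any protein atom's van der Waals sphere.  The depth index is
#' normalized so that an isolated atom scores exactly 2:
#' `D_i = 2 * V_exposed / V_exposed_isolated`.  Deeply buried atoms
#' approach 0; `D_i` is monotone non-increasing as neighbouring atoms are
#' added.
#'
#' @param model a [structure_model()].
#' @param probe_radius_A probe sphere radius; must exceed the largest van
#'   der Waals radius present.
#' @param targets integer atom indices to evaluate (default all).
#' @param spacing_A quadrature voxel edge.
#' @return data.frame `atom`, `residue_seq`, `atom_name`, `depth`.
#' @export
atom_depth <- function(model, probe_radius_A = 8, targets = NULL,
                       spacing_A = 0.5) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- coords(model)
  radii <- vdw_radius(model$atoms$element)
  if (probe_radius_A <= max(radii))
    stop("probe_radius must exceed the largest van der Waals radius")
  if (is.null(targets)) targets <- seq_len(nrow(xyz))
  # voxel offsets within the probe sphere
  g <- seq(-probe_radius_A, probe_radius_A, by = spacing_A)
  off <- as.matrix(expand.grid(x = g, y = g, z = g))
  off <- off[rowSums(off^2) <= probe_radius_A^2, , drop = FALSE]
  depth <- numeric(length(targets))
  for (t in seq_along(targets)) {
    i <- targets[t]
    pts <- sweep(off, 2, xyz[i, ], `+`)
    free <- rowSums(off^2) > radii[i]^2      # outside the target's own sphere
    n_iso <- sum(free)
    nb <- which(sqrt(colSums((t(xyz) - xyz[i, ])^2)) <
                  probe_radius_A + max(radii))
    for (j in setdiff(nb, i)) {
      if (!any(free)) break
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & dj2 > radii[j]^2
    }
    depth[t] <- 2 * sum(free) / n_iso
  }
  data.frame(atom = targets,
             residue_seq = model$atoms$res_seq[targets],
             atom_name = model$atoms$atom_name[targets],
             depth = depth)
}
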