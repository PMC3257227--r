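# Synthetic-data generators with known ground truth.  Defaults reproduce
# the measured regime of the mBS experiments: exchange rates spanning
# three decades (0.003-2.2 1/hr), an isotropic 7.9 ns tumbler with
# S2 = 0.90 +/- 0.07 and flexible-loop dips, two-state urea titrations
# with a 4.2 M midpoint, attenuation profiles spanning ~0.4-2.0 with
# planted hot spots, and toy solvated trajectories with known hydrogen-bond
# occupancies.  Every generator seeds the RNG explicitly and returns a
# machine-readable truth table.

.AA_NO_PRO <- setdiff(.AA3, "PRO")

#' Synthetic hydrogen-exchange decays
#'
#' Per-residue first-order decays with log-uniform rates over the
#' observed three-decade range, sampled on a realistic multi-day schedule,
#' with fractional Gaussian noise.
#'
#' @param n_residues number of residues.
#' @param k_range rate range in 1/hr (log-uniform).
#' @param timepoints_hr sampling schedule in hours.
#' @param noise fractional noise level (default 5%).
#' @param I0 reference intensity.
#' @param pH_read,temperature_K conditions used to tabulate the intrinsic
#'   rates of the generated sequence (for P and dG truth values).
#' @param seed RNG seed; identical seeds give identical output.
#' @return list with `series` (list of [peak_series()]), `sequence`
#'   (one-letter string with a leading residue so every generated residue
#'   has a left neighbour), and `truth` (data.frame with `k_true`, `k_rc`,
#'   `P`, `dG_op`).
#' @export
gen_hx <- function(n_residues = 47, k_range = c(0.003, 2.2),
                   timepoints_hr = c(0.25, 0.5, 1, 2, 4, 8, 16, 24, 48, 72),
                   noise = 0.05, I0 = 100, pH_read = 5.65,
                   temperature_K = 300, seed = 1) {
  set.seed(seed)
  codes <- sample(.AA_NO_PRO, n_residues + 1L, replace = TRUE)
  seq1 <- paste(aa_one(codes), collapse = "")
  k_true <- exp(stats::runif(n_residues, log(k_range[1]), log(k_range[2])))
  series <- vector("list", n_residues)
  truth <- data.frame(residue_seq = integer(n_residues),
                      residue_code = character(n_residues),
                      k_true = k_true, k_rc = NA_real_, P = NA_real_,
                      dG_op = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n_residues)) {
    seq_no <- i + 1L      # position 1 is the left-neighbour anchor
    y <- I0 * exp(-k_true[i] * timepoints_hr)
    if (noise > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise))
    series[[i]] <- peak_series(residue_id(seq_no, codes[seq_no]), "time_hr",
                               timepoints_hr, y)
    krc <- intrinsic_rate(codes[seq_no], codes[seq_no - 1L], pH_read,
                          temperature_K)
    truth$residue_seq[i] <- seq_no
    truth$residue_code[i] <- codes[seq_no]
    truth$k_rc[i] <- krc
    truth$P[i] <- krc / k_true[i]
    truth$dG_op[i] <- .RGAS * temperature_K * log(krc / k_true[i])
  }
  list(series = series, sequence = seq1, truth = truth)
}

# truncated-normal draw on (lo, hi]
.rtnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x > lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Synthetic 15N relaxation dataset
#'
#' Per-residue order parameters drawn from a truncated normal on (0, 1]
#' (defaults: mean 0.90, sd 0.07) around a global isotropic tumbler
#' (default 7.9 ns), with optional planted flexible residues (low S2,
#' emulating hinge-loop dips) and planted exchange contributions; rates
#' from [forward_rates()] with fractional Gaussian noise.
#'
#' @param n_residues number of residues.
#' @param tau_c_ns global correlation time (ns).
#' @param S2_mean,S2_sd order-parameter distribution.
#' @param tau_e_ps internal correlation time (ps), shared.
#' @param flexible_residues integer positions forced to `flexible_S2`.
#' @param flexible_S2 order parameter of the planted flexible residues.
#' @param rex_residues integer positions given `rex_value`.
#' @param rex_value exchange contribution (1/s).
#' @param noise fractional noise on R1, R2, NOE (0 = noiseless; declared
#'   errors are floored at 2% for fit weighting either way).
#' @param field_MHz spectrometer field.
#' @param seed RNG seed.
#' @return list with `records` ([relaxation_records()]) and `truth`.
#' @export
gen_relaxation <- function(n_residues = 100, tau_c_ns = 7.9, S2_mean = 0.90,
                           S2_sd = 0.07, tau_e_ps = 30,
                           flexible_residues = integer(0), flexible_S2 = 0.6,
                           rex_residues = integer(0), rex_value = 0,
                           noise = 0.02, field_MHz = 500.13, seed = 1) {
  set.seed(seed)
  S2 <- if (S2_sd > 0) .rtnorm(n_residues, S2_mean, S2_sd) else
    rep(S2_mean, n_residues)
  S2[flexible_residues] <- flexible_S2
  Rex <- numeric(n_residues)
  Rex[rex_residues] <- rex_value
  R1 <- R2 <- NOE <- exy <- ezz <- numeric(n_residues)
  for (i in seq_len(n_residues)) {
    fr <- forward_rates(S2[i], tau_e_ps * 1e-12, tau_c_ns * 1e-9, Rex[i],
                        field_MHz)
    R1[i] <- fr$R1; R2[i] <- fr$R2; NOE[i] <- fr$NOE
    exy[i] <- fr$eta_xy; ezz[i] <- fr$eta_zz
  }
  err <- pmax(noise, 0.02)
  if (noise > 0) {
    R1 <- R1 * (1 + stats::rnorm(n_residues, 0, noise))
    R2 <- R2 * (1 + stats::rnorm(n_residues, 0, noise))
    NOE <- NOE * (1 + stats::rnorm(n_residues, 0, noise))
    exy <- exy * (1 + stats::rnorm(n_residues, 0, noise))
    ezz <- ezz * (1 + stats::rnorm(n_residues, 0, noise))
  }
  rec <- relaxation_records(seq_len(n_residues), R1, R2, NOE, field_MHz,
                            R1_err = err * R1, R2_err = err * R2,
                            NOE_err = err * abs(NOE),
                            eta_xy = exy, eta_zz = ezz)
  list(records = rec,
       truth = data.frame(residue_seq = seq_len(n_residues), S2_true = S2,
                          tau_e_ps = tau_e_ps, tau_c_ns = tau_c_ns,
                          Rex_true = Rex))
}

#' Synthetic urea titration cohort
#'
#' Two-state native-fraction curves on a 0-7 M grid with per-residue
#' midpoint jitter and fractional intensity noise.
#'
#' @param n_residues cohort size (default 30).
#' @param C_half mean unfolding midpoint (M).
#' @param m_value kcal/(mol M).
#' @param conc_M concentration grid (must start at 0).
#' @param midpoint_jitter_M SD of the per-residue midpoint.
#' @param noise fractional intensity noise.
#' @param temperature_K temperature.
#' @param seed RNG seed.
#' @return list with `series` and `truth`.
#' @export
gen_urea <- function(n_residues = 30, C_half = 4.2, m_value = 1.2,
                     conc_M = 0:7, midpoint_jitter_M = 0.1, noise = 0.05,
                     temperature_K = 300, seed = 1) {
  set.seed(seed)
  RT <- .RGAS * temperature_K
  ch <- C_half + stats::rnorm(n_residues, 0, midpoint_jitter_M)
  codes <- sample(.AA_NO_PRO, n_residues, replace = TRUE)
  series <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    fN <- 1 / (1 + exp(-(m_value * (ch[i] - conc_M)) / RT))
    y <- fN
    if (noise > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise))
    series[[i]] <- peak_series(residue_id(i, codes[i]), "urea_M", conc_M, y)
  }
  list(series = series,
       truth = data.frame(residue_seq = seq_len(n_residues),
                          residue_code = codes, C_half_true = ch,
                          m_true = m_value,
                          dG_true = m_value * ch))
}

#' Synthetic diamagnetic/paramagnetic volume pairs
#'
#' Lognormal baseline volumes; the two spectra receive independent global
#' gains (which exercises autoscaling), non-hot-spot residues get a mild
#' lognormal attenuation spread and the planted hot spots an exact
#' attenuation factor.
#'
#' @param n_residues profile size (default 87 usable pairs).
#' @param hotspot_set residue positions planted as hot spots.
#' @param hotspot_factor true attenuation of the hot spots.
#' @param att_sdlog lognormal sd of the background attenuation.
#' @param noise fractional volume noise.
#' @param seed RNG seed.
#' @return list with `pairs` ([volume_pairs()]) and `truth`.
#' @export
gen_para <- function(n_residues = 87, hotspot_set = c(13, 15, 45, 65, 87),
                     hotspot_factor = 2.0, att_sdlog = 0.15, noise = 0.05,
                     seed = 1) {
  set.seed(seed)
  if (any(hotspot_set > n_residues))
    stop("hotspot_set outside 1..n_residues")
  base <- stats::rlnorm(n_residues, meanlog = log(100), sdlog = 0.4)
  att <- stats::rlnorm(n_residues, 0, att_sdlog)
  att[hotspot_set] <- hotspot_factor
  gain_d <- stats::runif(1, 0.5, 2)
  gain_p <- stats::runif(1, 0.5, 2)
  V_d <- gain_d * base * (1 + stats::rnorm(n_residues, 0, noise))
  V_p <- gain_p * base / att * (1 + stats::rnorm(n_residues, 0, noise))
  codes <- sample(.AA_NO_PRO, n_residues, replace = TRUE)
  list(pairs = volume_pairs(seq_len(n_residues), V_d, V_p, codes),
       truth = data.frame(residue_seq = seq_len(n_residues),
                          attenuation_true = att,
                          hotspot = seq_len(n_residues) %in% hotspot_set))
}

#' Idealised helical backbone for toy structures
#'
#' N, H, CA, C, O atoms per residue placed on an alpha-helical spiral
#' (1.5 angstrom rise, 100 degrees per residue).  Geometry is idealised,
#' not stereochemically refined; it provides a compact non-collinear 3D
#' scaffold for trajectory and depth tests.
#'
#' @param n_residues chain length.
#' @return a [structure_model()].
#' @export
make_synthetic_helix <- function(n_residues = 10) {
  rows <- list()
  for (i in seq_len(n_residues)) {
    phi <- (i - 1) * 100 * pi / 180
    z <- (i - 1) * 1.5
    ca <- c(2.3 * cos(phi), 2.3 * sin(phi), z)
    n <- ca + c(-0.9 * cos(phi + 0.5), -0.9 * sin(phi + 0.5), -0.9)
    h <- n + c(-0.8 * cos(phi + 0.5), -0.8 * sin(phi + 0.5), -0.6)
    cc <- ca + c(0.8 * cos(phi - 0.4), 0.8 * sin(phi - 0.4), 1.0)
    o <- cc + c(0.9 * cos(phi - 0.4), 0.9 * sin(phi - 0.4), 0.7)
    at <- rbind(
      data.frame(atom_name = "N", element = "N", x = n[1], y = n[2], z = n[3]),
      data.frame(atom_name = "H", element = "H", x = h[1], y = h[2], z = h[3]),
      data.frame(atom_name = "CA", element = "C", x = ca[1], y = ca[2], z = ca[3]),
      data.frame(atom_name = "C", element = "C", x = cc[1], y = cc[2], z = cc[3]),
      data.frame(atom_name = "O", element = "O", x = o[1], y = o[2], z = o[3]))
    at$res_seq <- i; at$res_code <- "ALA"
    rows[[i]] <- at
  }
  structure_model(do.call(rbind, rows))
}

#' Synthetic solvated toy trajectory
#'
#' Jitters a template protein with iid Gaussian displacements (so the
#' expected RMSF of an unconstrained atom is `jitter_sd * sqrt(3)`),
#' surrounds it with uniformly redrawn waters (plus, optionally, one water
#' pinned at a planted hydration site every frame), and holds specified
#' donor-acceptor pairs inside the hydrogen-bond criteria for an exact
#' fraction of frames (ideal 2.9 angstrom linear geometry when "on",
#' 5 angstrom when "off").  Atoms participating in planted bonds are not
#' jittered.
#'
#' @param template a [structure_model()]; default a 10-residue helix.
#' @param n_waters number of water oxygens.
#' @param n_frames number of frames.
#' @param jitter_sd per-coordinate Gaussian displacement SD (angstrom).
#' @param planted_hbonds data.frame with columns `d`, `h`, `a` (atom
#'   indices into the template) and `occupancy` in [0, 1].
#' @param planted_site numeric xyz of a pinned water, or NULL.
#' @param water_pad half-width margin of the uniform water box beyond the
#'   protein bounding box (angstrom).
#' @param frame_interval_ps frame spacing.
#' @param seed RNG seed.
#' @return list with `traj` (a [trajectory()]), `water_oxygens`,
#'   `protein_atoms`, and `truth` (expected rmsf, per-bond occupancy,
#'   planted site).
#' @export
gen_trajectory <- function(template = make_synthetic_helix(10),
                           n_waters = 40, n_frames = 100, jitter_sd = 0.3,
                           planted_hbonds = NULL, planted_site = NULL,
                           water_pad = 6, frame_interval_ps = 0.2, seed = 1) {
  set.seed(seed)
  pa <- template$atoms
  np <- nrow(pa)
  pinned <- !is.null(planted_site)
  n_total <- np + n_waters + as.integer(pinned)
  pxyz <- coords(template)
  lo <- apply(pxyz, 2, min) - water_pad
  hi <- apply(pxyz, 2, max) + water_pad
  fixed_atoms <- integer(0)
  if (!is.null(planted_hbonds))
    fixed_atoms <- unique(unlist(planted_hbonds[, c("d", "h", "a")]))
  on_frames <- list()
  if (!is.null(planted_hbonds))
    for (b in seq_len(nrow(planted_hbonds)))
      on_frames[[b]] <- seq_len(round(planted_hbonds$occupancy[b] * n_frames))
  frames <- array(NA_real_, c(n_frames, n_total, 3))
  for (f in seq_len(n_frames)) {
    X <- pxyz
    jit <- matrix(stats::rnorm(np * 3, 0, jitter_sd), np, 3)
    jit[fixed_atoms, ] <- 0
    X <- X + jit
    if (!is.null(planted_hbonds)) {
      for (b in seq_len(nrow(planted_hbonds))) {
        d <- planted_hbonds$d[b]; h <- planted_hbonds$h[b]
        a <- planted_hbonds$a[b]
        u <- X[h, ] - X[d, ]; u <- u / sqrt(sum(u^2))
        dist <- if (f %in% on_frames[[b]]) 2.9 else 5.0
        X[a, ] <- X[d, ] + u * dist     # linear D-H...A geometry
      }
    }
    W <- cbind(stats::runif(n_waters, lo[1], hi[1]),
               stats::runif(n_waters, lo[2], hi[2]),
               stats::runif(n_waters, lo[3], hi[3]))
    block <- rbind(X, W)
    if (pinned) block <- rbind(block, matrix(planted_site, 1))
    frames[f, , ] <- block
  }
  watoms <- data.frame(atom_name = "OW", res_seq = np + seq_len(n_waters + pinned),
                       res_code = "HOH", element = "O",
                       x = 0, y = 0, z = 0)
  top <- structure_model(rbind(pa[, c("atom_name", "res_seq", "res_code",
                                      "element", "x", "y", "z")],
                               watoms))
  # topology coordinates = template protein + first-frame waters
  top$atoms$x <- frames[1, , 1]; top$atoms$y <- frames[1, , 2]
  top$atoms$z <- frames[1, , 3]
  top$atoms$x[seq_len(np)] <- pxyz[, 1]
  top$atoms$y[seq_len(np)] <- pxyz[, 2]
  top$atoms$z[seq_len(np)] <- pxyz[, 3]
  truth <- list(rmsf_expected = jitter_sd * sqrt(3),
                hbond_occupancy = if (is.null(planted_hbonds)) NULL else
                  round(planted_hbonds$occupancy * n_frames) / n_frames,
                planted_site = planted_site)
  list(traj = trajectory(top, frames, frame_interval_ps),
       water_oxygens = np + seq_len(n_waters + pinned),
       protein_atoms = seq_len(np), truth = truth)
}
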