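make_frames <- function(base, n) {
  fr <- array(NA_real_, c(n, nrow(base), 3))
  for (f in seq_len(n)) fr[f, , ] <- base
  fr
}

five_atoms <- function() {
  structure_model(data.frame(
    atom_name = c("C1", "C2", "C3", "C4", "C5"), res_seq = 1:5,
    res_code = "ALA", element = "C",
    x = c(0, 3, 0, 1, 1.5), y = c(0, 0, 3, 1, 0.5), z = c(0, 0, 0, 2, 4)))
}

test_that("rmsf is zero for static frames and rigid-motion frames", {
  m <- five_atoms()
  base <- ribodyn:::coords(m)
  tr <- trajectory(m, make_frames(base, 5))
  expect_equal(rmsf(tr)$rmsf, rep(0, 5), tolerance = 1e-12)
  # frames differing only by a rigid rotation + translation
  th <- seq(0.3, 1.5, length.out = 4)
  fr <- array(NA_real_, c(4, 5, 3))
  for (f in 1:4) {
    R <- matrix(c(cos(th[f]), -sin(th[f]), 0,
                  sin(th[f]), cos(th[f]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    fr[f, , ] <- sweep(base %*% t(R), 2, c(f, -f, 2 * f), `+`)
  }
  expect_lt(max(rmsf(trajectory(m, fr))$rmsf), 1e-8)
})

test_that("a +/-1 A displaced atom has rmsf exactly 1", {
  m <- five_atoms()
  base <- ribodyn:::coords(m)
  fr <- make_frames(base, 2)
  fr[1, 5, 3] <- base[5, 3] + 1
  fr[2, 5, 3] <- base[5, 3] - 1
  out <- rmsf(trajectory(m, fr), selection = 1:4)
  expect_equal(out$rmsf[5], 1, tolerance = 1e-9)
  expect_lt(max(out$rmsf[1:4]), 1e-9)
})

test_that("degenerate superposition selections are rejected", {
  m <- five_atoms()
  tr <- trajectory(m, make_frames(ribodyn:::coords(m), 3))
  expect_error(rmsf(tr, selection = 1:2), ">= 3 atoms")
  lin <- structure_model(data.frame(atom_name = c("C1", "C2", "C3"),
                                    res_seq = 1:3, res_code = "ALA",
                                    element = "C", x = c(0, 1, 2),
                                    y = 0, z = 0))
  tr2 <- trajectory(lin, make_frames(ribodyn:::coords(lin), 3))
  expect_error(rmsf(tr2), "collinear")
})

test_that("static geometries respect the hydrogen-bond criteria", {
  # ideal linear N-H...O at 2.9 A donor-acceptor -> 100%
  at <- data.frame(atom_name = c("N", "H", "O", "C1", "C2"),
                   res_seq = c(1, 1, 2, 3, 3), res_code = "ALA",
                   element = c("N", "H", "O", "C", "C"),
                   x = c(0, 1, 2.9, 0, 3), y = c(0, 0, 0, 3, 3),
                   z = c(0, 0, 0, 0, 0.5))
  m <- structure_model(at)
  tr <- trajectory(m, make_frames(ribodyn:::coords(m), 4))
  don <- data.frame(d = 1, h = 2, residue_seq = 1)
  expect_equal(hbond_lifetimes(tr, don, 3)$lifetime_pct, 100)
  # same geometry stretched to 3.6 A -> 0%
  at2 <- at; at2$x[3] <- 3.6
  m2 <- structure_model(at2)
  tr2 <- trajectory(m2, make_frames(ribodyn:::coords(m2), 4))
  expect_equal(hbond_lifetimes(tr2, don, 3)$lifetime_pct, 0)
  # donors without hydrogens are skipped with a warning
  expect_warning(out <- hbond_lifetimes(tr, data.frame(d = c(1, 4),
                                                       h = c(2, NA),
                                                       residue_seq = c(1, 3)),
                                        3), "without attached hydrogen")
  expect_identical(nrow(out), 1L)
})

test_that("property: lifetimes equal the brute-force oracle on random toys", {
  for (s in 1:50) {
    set.seed(s)
    na <- 6; nf <- 10
    fr <- array(runif(nf * na * 3, 0, 6), c(nf, na, 3))
    top <- structure_model(data.frame(
      atom_name = c("N", "H", "O", "O", "O", "O"), res_seq = 1:6,
      res_code = "ALA", element = c("N", "H", "O", "O", "O", "O"),
      x = fr[1, , 1], y = fr[1, , 2], z = fr[1, , 3]))
    tr <- trajectory(top, fr)
    don <- data.frame(d = 1, h = 2, residue_seq = 1)
    expect_equal(hbond_lifetimes(tr, don, 3:6)$lifetime_pct,
                 oracle_hbond_lifetime(tr, don, 3:6))
  }
})

test_that("planted hydrogen-bond occupancies are recovered exactly", {
  hb <- data.frame(d = 1, h = 2, a = 10, occupancy = 0.6)
  g <- gen_trajectory(n_frames = 100, n_waters = 5, planted_hbonds = hb,
                      seed = 6)
  lt <- hbond_lifetimes(g$traj, data.frame(d = 1, h = 2, residue_seq = 1), 10)
  expect_equal(lt$lifetime_pct, 60)
  expect_equal(lt$freedom, 0.4)
})

test_that("jittered trajectories reproduce the closed-form rmsf", {
  g <- gen_trajectory(n_frames = 200, n_waters = 10, jitter_sd = 0.3,
                      seed = 5)
  r <- rmsf(g$traj, selection = g$protein_atoms)
  got <- mean(r$rmsf[g$protein_atoms])
  expect_lt(abs(got / g$truth$rmsf_expected - 1), 0.05)
})

test_that("hydration grid conserves counts and finds the planted site", {
  site <- c(4, 0, 8)
  g <- gen_trajectory(n_frames = 150, n_waters = 30, jitter_sd = 0.2,
                      planted_site = site, seed = 7)
  hg <- hydration_grid(g$traj, g$water_oxygens, g$protein_atoms)
  expect_identical(hg$total_obs, sum(hg$counts))
  expect_gt(nrow(hg$mdhs), 0L)
  top <- unlist(hg$mdhs[1, c("x", "y", "z")])
  expect_lt(sqrt(sum((top - site)^2)), hg$spacing)
  expect_true(all(hg$mdhs$density >= 2))
})

test_that("uniform waters give flat density and no hydration sites", {
  tmpl <- structure_model(data.frame(
    atom_name = c("C1", "C2", "C3", "C4"), res_seq = 1:4, res_code = "ALA",
    element = "C", x = c(0, 3, 0, 1.5), y = c(0, 0, 3, 1.5),
    z = c(0, 0, 0, 2)))
  g <- gen_trajectory(template = tmpl, n_frames = 2000, n_waters = 150,
                      jitter_sd = 0, water_pad = 9, seed = 11)
  hg <- hydration_grid(g$traj, g$water_oxygens, g$protein_atoms,
                       spacing_A = 1.0)
  d1 <- hg$density[hg$shell == 1L]
  expect_lt(abs(mean(d1) - 1), 0.05)
  expect_lt(max(d1), 2)
  expect_identical(nrow(hg$mdhs), 0L)
})

test_that("the grid is equivariant under axis-aligned rigid motion", {
  g <- gen_trajectory(n_frames = 40, n_waters = 25, jitter_sd = 0.2,
                      seed = 13)
  hg <- hydration_grid(g$traj, g$water_oxygens, g$protein_atoms)
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  shift <- c(5, -3, 2)
  rot <- function(M) sweep(M %*% t(R90), 2, shift, `+`)
  top2 <- g$traj$topology
  xyz2 <- rot(ribodyn:::coords(top2))
  top2$atoms$x <- xyz2[, 1]; top2$atoms$y <- xyz2[, 2]
  top2$atoms$z <- xyz2[, 3]
  fr2 <- g$traj$frames
  for (f in seq_len(dim(fr2)[1])) fr2[f, , ] <- rot(g$traj$frames[f, , ])
  hg2 <- hydration_grid(trajectory(top2, fr2), g$water_oxygens,
                        g$protein_atoms)
  expect_identical(hg$total_obs, hg2$total_obs)
  expect_equal(sort(as.vector(hg$counts[hg$counts > 0])),
               sort(as.vector(hg2$counts[hg2$counts > 0])))
})

test_that("atom depth normalizes, buries, and matches the MC oracle", {
  iso <- structure_model(data.frame(atom_name = "C", res_seq = 1,
                                    res_code = "ALA", element = "C",
                                    x = 0, y = 0, z = 0))
  expect_equal(atom_depth(iso)$depth, 2, tolerance = 1e-12)
  expect_error(atom_depth(iso, probe_radius_A = 1.5), "probe_radius")
  # dense cluster: central atom deeply buried
  gr <- expand.grid(x = seq(-10, 10, 2.5), y = seq(-10, 10, 2.5),
                    z = seq(-10, 10, 2.5))
  gr <- gr[gr$x^2 + gr$y^2 + gr$z^2 <= 100, ]
  clust <- structure_model(data.frame(atom_name = "C", res_seq = 1,
                                      res_code = "ALA", element = "C",
                                      x = gr$x, y = gr$y, z = gr$z))
  ctr <- which.min(gr$x^2 + gr$y^2 + gr$z^2)
  expect_lt(atom_depth(clust, targets = ctr)$depth, 0.3)
  # two-atom system vs Monte-Carlo volume oracle, within 1%
  for (sep in c(2, 4, 6)) {
    two <- structure_model(data.frame(atom_name = c("C1", "C2"),
                                      res_seq = 1:2, res_code = "ALA",
                                      element = "C", x = c(0, sep),
                                      y = 0, z = 0))
    dq <- atom_depth(two, targets = 1, spacing_A = 0.25)$depth
    dmc <- oracle_depth_mc(ribodyn:::coords(two), vdw_radius(c("C", "C")),
                           1, n = 2e5)
    expect_lt(abs(dq / dmc - 1), 0.01)
  }
})

test_that("atom depth is monotone non-increasing as neighbours are added", {
  tgt <- data.frame(atom_name = "C", res_seq = 1, res_code = "ALA",
                    element = "C", x = 0, y = 0, z = 0)
  set.seed(4)
  ring <- data.frame(atom_name = "C", res_seq = 2, res_code = "ALA",
                     element = "C", x = runif(30, -5, 5),
                     y = runif(30, -5, 5), z = runif(30, -5, 5))
  prev <- Inf
  for (n in c(0, 5, 15, 30)) {
    mm <- structure_model(rbind(tgt, ring[seq_len(n), ]))
    d <- atom_depth(mm, targets = 1)$depth
    expect_lte(d, prev + 1e-12)
    prev <- d
  }
})
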