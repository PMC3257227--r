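# Independent oracles, written directly from the textbook expressions and
# kept separate from the package implementation paths they check.

# spectral density evaluated with plain arithmetic
oracle_J <- function(S2, te, tc, w) {
  tau <- if (te > 0) 1 / (1 / tc + 1 / te) else 0
  (2 / 5) * (S2 * tc / (1 + (w * tc)^2) + (1 - S2) * tau / (1 + (w * tau)^2))
}

# dipolar/CSA constants from first principles (SI)
oracle_dc <- function(field_MHz) {
  gH <- 2.6752218744e8; gN <- -2.71261808e7
  mu0 <- 4 * pi * 1e-7; hbar <- 1.054571817e-34; rNH <- 1.02e-10
  wH <- 2 * pi * field_MHz * 1e6
  wN <- wH * gN / gH
  list(d = mu0 * hbar * gH * gN / (4 * pi * rNH^3),
       c = abs(wN) * (-160e-6) / sqrt(3),
       wH = wH, wN = wN, gH = gH, gN = gN)   # wN signed (gamma_N < 0)
}

# rates assembled independently of forward_rates()
oracle_rates <- function(S2, te, tc, field_MHz) {
  k <- oracle_dc(field_MHz)
  J <- function(w) oracle_J(S2, te, tc, abs(w))
  d2 <- k$d^2; c2 <- k$c^2
  R1 <- d2 / 4 * (J(k$wH - k$wN) + 3 * J(k$wN) + 6 * J(k$wH + k$wN)) +
    c2 * J(k$wN)
  R2 <- d2 / 8 * (4 * J(0) + J(k$wH - k$wN) + 3 * J(k$wN) + 6 * J(k$wH) +
                    6 * J(k$wH + k$wN)) + c2 / 6 * (4 * J(0) + 3 * J(k$wN))
  sig <- d2 / 4 * (6 * J(k$wH + k$wN) - J(k$wH - k$wN))
  list(R1 = R1, R2 = R2, NOE = 1 + (k$gH / k$gN) * sig / R1)
}

# brute-force hydrogen-bond lifetime: per-frame O(n^2) re-evaluation with
# its own geometry code
oracle_hbond_lifetime <- function(traj, donors, acceptors, dist_cut = 3.5,
                                  ang_cut = 75) {
  nf <- dim(traj$frames)[1]
  hits <- integer(nrow(donors))
  ang <- function(v1, v2) {
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  for (f in seq_len(nf)) {
    X <- traj$frames[f, , ]
    for (i in seq_len(nrow(donors))) {
      d <- donors$d[i]; h <- donors$h[i]
      found <- FALSE
      for (a in acceptors) {
        if (a == d || a == h) next
        if (sqrt(sum((X[d, ] - X[a, ])^2)) > dist_cut) next
        dha <- ang(X[d, ] - X[h, ], X[a, ] - X[h, ])
        if (180 - dha <= ang_cut) { found <- TRUE; break }
      }
      if (found) hits[i] <- hits[i] + 1L
    }
  }
  100 * hits / nf
}

# Monte-Carlo exposed-volume depth for a target atom among neighbours
oracle_depth_mc <- function(xyz, radii, target, probe = 8, n = 1e6,
                            seed = 99) {
  set.seed(seed)
  # uniform points in the probe sphere around the target
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- probe * runif(n)^(1 / 3)
  pts <- sweep(u * r, 2, xyz[target, ], `+`)
  free <- rowSums(sweep(pts, 2, xyz[target, ])^2) > radii[target]^2
  for (j in seq_len(nrow(xyz))) {
    if (j == target) next
    free <- free & (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
      (pts[, 3] - xyz[j, 3])^2 > radii[j]^2
  }
  iso <- rowSums(sweep(pts, 2, xyz[target, ])^2) > radii[target]^2
  2 * sum(free) / sum(iso)
}

# intrinsic-rate reference: hand evaluation of the Ala-Ala poly-DL-alanine
# rate in D2O (log10 reference rates 1.62 / 10.05 / -1.5 per minute,
# pKD 15.05, pD = pH + 0.4), frozen before the implementation was written
oracle_ala_ala_rate_hr <- function(pH, T = 293) {
  pD <- pH + 0.4
  arr <- function(Ea) exp(-Ea / 1.987 * (1 / T - 1 / 293))
  (10^1.62 * 10^(-pD) * arr(14000) +
     10^10.05 * 10^(pD - 15.05) * arr(17000) +
     10^(-1.5) * arr(19000)) * 60
}
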