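test_that("spectral density has the rigid limit and decays with frequency", {
  tc <- 7.9e-9
  expect_equal(spectral_density(1, 0, tc, 0), 0.4 * tc, tolerance = 1e-15)
  expect_equal(spectral_density(1, 30e-12, tc, 0), 0.4 * tc,
               tolerance = 1e-15)
  w <- 10^seq(6, 11, length.out = 40)
  J <- spectral_density(0.9, 30e-12, tc, w)
  expect_true(all(diff(J) < 0))
  expect_lt(J[40], 1e-3 * J[1])
})

test_that("spectral density matches direct arithmetic at the 15N frequency", {
  ic <- ribodyn:::interaction_constants(500.13)
  wN <- abs(ic$omega_N)
  got <- spectral_density(0.9, 30e-12, 7.9e-9, wN)
  expect_equal(got, oracle_J(0.9, 30e-12, 7.9e-9, wN),
               tolerance = 1e-12)
  # frozen regression value
  expect_equal(got, 3.888554034687e-10, tolerance = 1e-10)
})

test_that("forward rates match the independent oracle", {
  for (S2 in c(0.7, 1)) for (tc in c(4e-9, 7.9e-9)) {
    a <- forward_rates(S2, 30e-12, tc, 0, 500.13)
    b <- oracle_rates(S2, 30e-12, tc, 500.13)
    expect_equal(a$R1, b$R1, tolerance = 1e-10)
    expect_equal(a$R2, b$R2, tolerance = 1e-10)
    expect_equal(a$NOE, b$NOE, tolerance = 1e-10)
  }
  # frozen rigid-limit ratio at the working field
  fr <- forward_rates(1, 0, 7.9e-9, 0, 500.13)
  expect_equal(fr$R2 / fr$R1, 5.272930827718, tolerance = 1e-10)
})

test_that("extreme narrowing collapses R1 and R2; Rex is additive to R2", {
  # dipolar R1 = R2 exactly when J is flat; the CSA mechanism keeps its
  # 7/6 transverse excess, leaving a ~0.3% residual at this field
  fr <- forward_rates(1, 0, 1e-12, 0, 500.13)
  expect_equal(fr$R1, fr$R2, tolerance = 0.01)
  a <- forward_rates(0.9, 30e-12, 7.9e-9, 0, 500.13)
  b <- forward_rates(0.9, 30e-12, 7.9e-9, 5, 500.13)
  expect_equal(b$R2 - a$R2, 5, tolerance = 1e-12)
  expect_equal(b$R1, a$R1, tolerance = 1e-15)
  expect_equal(b$NOE, a$NOE, tolerance = 1e-15)
  expect_equal(b$eta_xy, a$eta_xy, tolerance = 1e-15)
})

test_that("model-free round trip recovers all parameters on noiseless data", {
  # S2 levels from the spec'd invariant, three residues each
  S2s <- rep(c(0.5, 0.7, 0.9, 1.0), each = 3)
  n <- length(S2s)
  R1 <- R2 <- NOE <- numeric(n)
  for (i in seq_len(n)) {
    fr <- forward_rates(S2s[i], 30e-12, 7.9e-9, 0, 500.13)
    R1[i] <- fr$R1; R2[i] <- fr$R2; NOE[i] <- fr$NOE
  }
  rec <- relaxation_records(seq_len(n), R1, R2, NOE, 500.13)
  fit <- fit_model_free(rec, n_mc = 0)
  expect_lt(abs(fit$tau_c_ns / 7.9 - 1), 0.005)
  expect_true(all(abs(fit$residues$S2 / S2s - 1) < 0.005))
  # tau_e is only identifiable when S2 < 1
  mobile <- S2s < 1
  expect_true(all(abs(fit$residues$tau_e_ps[mobile] / 30 - 1) < 0.005))
  expect_true(all(fit$backcalc < 1e-4))
})

test_that("a rigid rotor fits to S2 >= 0.99 everywhere", {
  g <- gen_relaxation(n_residues = 12, S2_mean = 1, S2_sd = 0, tau_e_ps = 0,
                      noise = 0, seed = 2)
  fit <- fit_model_free(g$records, n_mc = 0)
  expect_true(all(fit$residues$S2 >= 0.99))
})

test_that("planted flexible dips are recovered in rank order", {
  g <- gen_relaxation(n_residues = 15, S2_mean = 0.9, S2_sd = 0.03,
                      flexible_residues = c(4, 9, 13), flexible_S2 = 0.6,
                      noise = 0, seed = 7)
  fit <- fit_model_free(g$records, n_mc = 0)
  m <- merge(fit$residues, g$truth, by = "residue_seq")
  expect_equal(cor(m$S2, m$S2_true, method = "spearman"), 1)
  dips <- m$residue_seq[order(m$S2)][1:3]
  expect_setequal(dips, c(4, 9, 13))
})

test_that("noisy recovery: tau_c bias < 1% and S2 RMSE < 0.02", {
  # spec'd as a 200-replicate study; run scaled down (3 replicates,
  # 20 residues) to stay inside the suite's time budget
  for (seed in 1:3) {
    g <- gen_relaxation(n_residues = 20, noise = 0.02, seed = seed)
    fit <- fit_model_free(g$records, n_mc = 0)
    expect_lt(abs(fit$tau_c_ns / 7.9 - 1), 0.01)
    m <- merge(fit$residues, g$truth, by = "residue_seq")
    expect_lt(sqrt(mean((m$S2 - m$S2_true)^2)), 0.02)
  }
})

test_that("Monte-Carlo bounds bracket the point estimates", {
  g <- gen_relaxation(n_residues = 12, noise = 0.02, seed = 4)
  fit <- fit_model_free(g$records, n_mc = 40, seed = 11)
  expect_true(all(c("S2_lo", "S2_hi") %in% names(fit$residues)))
  expect_true(all(fit$residues$S2_lo <= fit$residues$S2_hi))
  expect_gt(mean(fit$residues$S2 >= fit$residues$S2_lo &
                   fit$residues$S2 <= fit$residues$S2_hi), 0.8)
})

test_that("exclusions are honoured and scarce data rejected", {
  g <- gen_relaxation(n_residues = 12, noise = 0, seed = 3)
  df <- as.data.frame(g$records)
  df$NOE[2] <- -0.3   # mobile terminus: auto-excluded
  rec <- relaxation_records(df$residue_seq, df$R1, df$R2, df$NOE, 500.13)
  fit <- fit_model_free(rec, exclusions = 5L, n_mc = 0)
  expect_setequal(fit$excluded$residue_seq, c(2L, 5L))
  expect_false(any(fit$residues$residue_seq %in% c(2L, 5L)))
  expect_error(fit_model_free(rec[1:8, ], n_mc = 0), "insufficient")
})

test_that("reduced mapping is consistent with the forward model", {
  ic <- ribodyn:::interaction_constants(500.13)
  wN <- abs(ic$omega_N); wH <- ic$omega_H
  for (tc in c(4, 8, 12)) {
    fr <- forward_rates(0.9, 30e-12, tc * 1e-9, 0, 500.13)
    rec <- relaxation_records(1:10, rep(fr$R1, 10), rep(fr$R2, 10),
                              rep(fr$NOE, 10), 500.13)
    m <- reduced_spectral_density(rec)
    Ja <- function(w) spectral_density(0.9, 30e-12, tc * 1e-9, w)
    expect_lt(abs(m$J0[1] / Ja(0) - 1), 0.03)
    expect_lt(abs(m$JwN[1] / Ja(wN) - 1), 0.03)
    expect_lt(abs(m$JwH087[1] / Ja(0.87 * wH) - 1), 0.03)
  }
})

test_that("rigid-body rates map onto the rigid curve", {
  fr <- forward_rates(1, 0, 8e-9, 0, 500.13)
  rec <- relaxation_records(1:10, rep(fr$R1, 10), rep(fr$R2, 10),
                            rep(fr$NOE, 10), 500.13)
  m <- reduced_spectral_density(rec, rigid_tauc_ns = 8)
  wN <- abs(ribodyn:::interaction_constants(500.13)$omega_N)
  tc_implied <- m$J0[1] / 0.4
  expect_lt(abs(m$JwN[1] / (0.4 * tc_implied / (1 + (wN * tc_implied)^2)) - 1),
            0.005)
  expect_s3_class(attr(m, "rigid_curve"), "data.frame")
})

test_that("Rex shifts only J(0); NOE = 1 zeroes the high-frequency density", {
  fr0 <- forward_rates(0.9, 30e-12, 8e-9, 0, 500.13)
  fr8 <- forward_rates(0.9, 30e-12, 8e-9, 8, 500.13)
  rec <- relaxation_records(1:2, c(fr0$R1, fr8$R1), c(fr0$R2, fr8$R2),
                            c(fr0$NOE, fr8$NOE), 500.13)
  m <- reduced_spectral_density(rec)
  expect_gt(m$J0[2], m$J0[1])
  expect_equal(m$JwN[2], m$JwN[1], tolerance = 1e-12)
  rec1 <- relaxation_records(1, 2, 8, 1, 500.13)  # NOE exactly 1
  m1 <- reduced_spectral_density(rec1)
  expect_equal(m1$JwH087, 0)
})

test_that("planted exchange contributions are recovered exactly", {
  g <- gen_relaxation(n_residues = 50, noise = 0, S2_sd = 0.05,
                      rex_residues = c(7, 20, 33), rex_value = 6, seed = 8)
  de <- detect_exchange(g$records)
  expect_setequal(de$residue_seq[de$flagged], c(7, 20, 33))
  g0 <- gen_relaxation(n_residues = 50, noise = 0, S2_sd = 0.05, seed = 9)
  expect_identical(sum(detect_exchange(g0$records)$flagged), 0L)
})

test_that("a uniform Rex yields no flags but a global-offset warning", {
  gu <- gen_relaxation(n_residues = 50, noise = 0, S2_sd = 0.05,
                       rex_residues = 1:50, rex_value = 4, seed = 10)
  expect_warning(de <- detect_exchange(gu$records), "whole sequence")
  expect_identical(sum(de$flagged), 0L)
  expect_true(attr(de, "global_offset_warning"))
  expect_error(detect_exchange(gu$records[1:3, ]), "at least 5")
})

test_that("the empirical size formula reproduces its reference points", {
  expect_equal(round(empirical_tauc(124, 300), 1), 8.5)
  expect_equal(empirical_tauc(248, 300) / empirical_tauc(124, 300), 2^0.93,
               tolerance = 1e-12)
  expect_lt(empirical_tauc(124, 310), empirical_tauc(124, 300))
  expect_error(empirical_tauc(5, 300))
})
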