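# One-site ITC model: concentrations, equilibrium, heats, fitting.

fylir_protocol <- function() itc_protocol() # 30 uM cell, 300 uM, 30 x 8 uL

test_that("effective concentrations: identity, asymptote, discrete oracle", {
  pr <- fylir_protocol()
  c1 <- effective_concentrations(pr, 1)
  dv1 <- pr$injection_volumes[1]
  expect_equal(c1$M, pr$cell_conc * exp(-dv1 / pr$cell_volume))
  # limits: no injection -> (M0, 0); infinite dilution -> (0, Xs)
  pr0 <- itc_protocol(injection_volumes = c(1e-12, 10))
  expect_equal(effective_concentrations(pr0, 1)$M, pr0$cell_conc,
               tolerance = 1e-6)
  expect_lt(effective_concentrations(pr0, 2)$M, 1e-9)
  expect_equal(effective_concentrations(pr0, 2)$X, pr0$syringe_conc,
               tolerance = 1e-3)
  # continuous vs discrete stepwise dilution within 0.5% (30 x 8 uL / 1.4 mL)
  cc <- effective_concentrations(pr)
  oo <- oracle_stepwise_conc(pr$cell_volume, pr$cell_conc, pr$syringe_conc,
                             pr$injection_volumes)
  expect_true(all(abs(cc$M / oo[, "M"] - 1) < 0.005))
  expect_true(all(abs(cc$X / oo[, "X"] - 1) < 0.005))
})

test_that("complex concentration: limits and fixed-point oracle", {
  expect_equal(bound_fraction(30e-6, 0, 1e-6), 0)
  # tight-binding limit: everything injected is bound while X < N*M
  expect_equal(bound_fraction(30e-6, 10e-6, 1e-15), 10e-6, tolerance = 1e-6)
  set.seed(71)
  for (k in 1:50) {
    M <- 10^runif(1, -6, -4); X <- 10^runif(1, -7, -3.5)
    Kd <- 10^runif(1, -7, -3); N <- runif(1, 0.5, 2)
    cc <- bound_fraction(M, X, Kd, N)
    expect_gte(cc, 0)
    expect_lte(cc, min(N * M, X) + 1e-15)
    expect_equal(cc, oracle_complex(M, X, Kd, N), tolerance = 1e-10)
  }
})

test_that("predicted heats: dH = 0 flatline, saturation conservation", {
  pr <- fylir_protocol()
  h0 <- predict_heats(pr, N = 1, K_D = 1e-5, dH = 0, q_dil = -0.11)
  expect_equal(h0$normalized_kcal_per_mol, rep(-0.11, 30))
  # saturating titration: total raw heat = N*M0*V0*dH within 2%
  prs <- itc_protocol(cell_conc = 10e-6, syringe_conc = 400e-6,
                      injection_volumes = rep(8e-6, 30))
  hs <- predict_heats(prs, N = 1, K_D = 5e-8, dH = -8, q_dil = 0)
  total <- sum(hs$heat_cal)
  expect_equal(total, 1 * 10e-6 * 1.4e-3 * (-8000), tolerance = 0.02)
})

test_that("negating dH negates all model heats (q_dil = 0)", {
  pr <- fylir_protocol()
  hp <- predict_heats(pr, 1, 8.86e-6, dH = 8, q_dil = 0)
  hm <- predict_heats(pr, 1, 8.86e-6, dH = -8, q_dil = 0)
  expect_equal(hp$normalized_kcal_per_mol, -hm$normalized_kcal_per_mol)
  expect_equal(hp$heat_cal, -hm$heat_cal)
})

test_that("model heats match an independent numeric implementation", {
  set.seed(72)
  for (k in 1:10) {
    pr <- itc_protocol(cell_volume = runif(1, 0.2e-3, 2e-3),
                       cell_conc = 10^runif(1, -5.5, -4),
                       syringe_conc = 10^runif(1, -4.5, -3),
                       injection_volumes = rep(10^runif(1, -6.2, -5), 25))
    N <- runif(1, 0.7, 1.5); Kd <- 10^runif(1, -7, -4.5)
    dH <- runif(1, -15, -2); qd <- runif(1, -0.2, 0.2)
    got <- predict_heats(pr, N, Kd, dH, qd)$normalized_kcal_per_mol
    want <- oracle_heats(pr, N, Kd, dH, qd)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("c ~ 3.4 isotherm has the Wiseman shape at its inflection", {
  # near-differential protocol (tiny injections, negligible dilution) so
  # per-injection heats approximate dQ/d(moles injected)
  pr <- itc_protocol(cell_volume = 1.4e-3, cell_conc = 30e-6,
                     syringe_conc = 5e-3,
                     injection_volumes = rep(0.35e-6, 50))
  h <- predict_heats(pr, N = 1, K_D = 8.86e-6, dH = -8, q_dil = 0)
  conc <- effective_concentrations(pr)
  ratio <- conc$X / conc$M
  expect_gt(max(ratio), 1.8)
  # finite-difference oracle of the cumulative heat content
  oracle_slope <- function(i) {
    cpl <- function(X) oracle_complex(conc$M[i], X, 8.86e-6, 1)
    dX <- 1e-9
    (cpl(conc$X[i] + dX) - cpl(conc$X[i] - dX)) / (2 * dX) * (-8)
  }
  mid <- which(ratio > 0.5 & ratio < 1.6)
  fd <- vapply(mid, oracle_slope, numeric(1))
  expect_equal(h$normalized_kcal_per_mol[mid], fd, tolerance = 0.03)
  # shallow sigmoid: heats decrease in magnitude, steepest near ratio 1
  mag <- abs(h$normalized_kcal_per_mol)
  expect_true(all(diff(mag) < 0))
  steep <- which.max(abs(diff(h$normalized_kcal_per_mol)))
  expect_gt(ratio[steep], 0.6)
  expect_lt(ratio[steep], 1.4)
})

test_that("titration simulation: noise-free equality, determinism, moments", {
  pr <- fylir_protocol()
  h0 <- simulate_titration(pr, 1, 8.86e-6, -8, -0.05, noise_sd = 0)
  expect_equal(h0$normalized_kcal_per_mol,
               predict_heats(pr, 1, 8.86e-6, -8, -0.05)$normalized_kcal_per_mol)
  ha <- simulate_titration(pr, 1, 8.86e-6, -8, -0.05, noise_sd = 0.1, seed = 73)
  hb <- simulate_titration(pr, 1, 8.86e-6, -8, -0.05, noise_sd = 0.1, seed = 73)
  expect_identical(ha, hb)
  # noise moments over many seeds: mean ~ 0, sd ~ noise_sd
  base <- predict_heats(pr, 1, 8.86e-6, -8, -0.05)$normalized_kcal_per_mol
  res <- unlist(lapply(1:300, function(s)
    simulate_titration(pr, 1, 8.86e-6, -8, -0.05, noise_sd = 0.1,
                       seed = 5000 + s)$normalized_kcal_per_mol - base))
  expect_lt(abs(mean(res)), 3 * 0.1 / sqrt(length(res)))
  expect_equal(sd(res), 0.1, tolerance = 0.03)
  expect_lt(abs(mean(res^3)) / 0.1^3, 0.1)  # no skew
})

test_that("noise-free self-consistency: all parameters within 0.1%", {
  pr <- fylir_protocol()
  truth <- c(N = 1, K_D = 8.86e-6, dH = -8, q_dil = -0.05)
  h <- simulate_titration(pr, truth[["N"]], truth[["K_D"]], truth[["dH"]],
                          truth[["q_dil"]], noise_sd = 0)
  fit <- fit_one_site(h)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-3)
  for (p in names(truth))
    expect_lt(abs(coef(fit)[[p]] / truth[[p]] - 1), 1e-3)
})

test_that("K_D recovery at 2% noise reproduces both reported affinities", {
  pr <- fylir_protocol()
  med_kd <- function(kd_true, off) {
    median(vapply(1:11, function(s) {
      h <- simulate_titration(pr, 1, kd_true, -8, -0.05, noise_frac = 0.02,
                              seed = off + s)
      coef(fit_one_site(h))[["K_D"]]
    }, numeric(1)))
  }
  kd1 <- med_kd(8.86e-6, 6000)
  expect_lt(abs(kd1 - 8.86e-6), 1.13e-6)  # within the stated uncertainty
  kd2 <- med_kd(6.92e-6, 7000)
  expect_lt(abs(kd2 - 6.92e-6), 2.25e-6)
})

test_that("reported standard errors are calibrated against the truth", {
  # the fitted K_D scatters with the breadth its own standard error claims:
  # ~68% of replicates within 1 SE of truth, ~95% within 2 SE (wide Monte
  # Carlo bands at 40 replicates); dH is recovered to ~its own precision
  pr <- fylir_protocol()
  res <- t(vapply(1:40, function(s) {
    h <- simulate_titration(pr, 1, 8.86e-6, -8, -0.05, noise_frac = 0.02,
                            seed = 8000 + s)
    f <- fit_one_site(h)
    c(kd = coef(f)[["K_D"]], se = f$se[["K_D"]], dh = coef(f)[["dH"]])
  }, numeric(3)))
  cov1 <- mean(abs(res[, "kd"] - 8.86e-6) < res[, "se"], na.rm = TRUE)
  cov2 <- mean(abs(res[, "kd"] - 8.86e-6) < 2 * res[, "se"], na.rm = TRUE)
  expect_gt(cov1, 0.5)
  expect_lt(cov1, 0.95)
  expect_gt(cov2, 0.8)
  expect_lt(median(abs(res[, "dh"] / -8 - 1)), 0.1)
})

test_that("flat heats flag an unidentifiable K_D", {
  pr <- fylir_protocol()
  h <- simulate_titration(pr, 1, 1e-5, dH = 0, q_dil = -0.05,
                          noise_sd = 0.01, seed = 74)
  fit <- suppressWarnings(fit_one_site(h, force_se = TRUE))
  expect_true(!fit$identifiable ||
                is.na(fit$se[["K_D"]]) ||
                fit$se[["K_D"]] > coef(fit)[["K_D"]])
})

test_that("c-value guard suppresses K_D errors outside [0.1, 1000]", {
  pr <- itc_protocol(cell_conc = 30e-6, syringe_conc = 3e-3,
                     injection_volumes = rep(8e-6, 30))
  h <- simulate_titration(pr, 1, 1e-3, -8, 0, noise_sd = 0.005, seed = 75)
  fit <- suppressWarnings(fit_one_site(h))
  if (fit$c_value < 0.1 || fit$c_value > 1000)
    expect_true(is.na(fit$se[["K_D"]]))
  fit2 <- suppressWarnings(fit_one_site(h, force_se = TRUE))
  expect_true(fit$c_value > 0)
})

test_that("heats CSV round-trips through the documented unit conversion", {
  pr <- fylir_protocol()
  h <- simulate_titration(pr, 1, 8.86e-6, -8, -0.05, noise_frac = 0.02,
                          seed = 76)
  tf <- tempfile(fileext = ".csv")
  write_injection_heats(h, tf)
  back <- read_injection_heats(tf, pr)
  expect_equal(back$normalized_kcal_per_mol, h$normalized_kcal_per_mol,
               tolerance = 1e-9)
  expect_equal(back$volume_l, h$volume_l, tolerance = 1e-12)
  fit <- fit_one_site(back)
  # CSV carries ~15 significant digits; the refit agrees to well beyond
  # any scientifically meaningful precision
  expect_equal(coef(fit)[["K_D"]],
               coef(fit_one_site(h))[["K_D"]], tolerance = 1e-6)
})

test_that("fit methods: coef, fitted, residuals, predict, simulate, plot", {
  pr <- fylir_protocol()
  h <- simulate_titration(pr, 1, 8.86e-6, -8, -0.05, noise_frac = 0.02,
                          seed = 77)
  fit <- fit_one_site(h)
  expect_named(coef(fit), c("N", "K_D", "dH", "q_dil"))
  expect_equal(fitted(fit) + residuals(fit), h$normalized_kcal_per_mol)
  expect_s3_class(predict(fit), "injection_heats")
  sims <- simulate(fit, nsim = 2, seed = 78)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "injection_heats")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
  expect_output(print(fit), "K_D")
  expect_output(print(summary(fit)), "c-value")
})

test_that("power-trace integration recovers per-injection heats", {
  # synthetic exponential-return-to-baseline peaks
  tt <- seq(0, 600, by = 0.5)
  bounds <- c(0, 200, 400)
  q_true <- c(12, 8, 5) # ucal
  pw <- numeric(length(tt))
  for (i in seq_along(bounds)) {
    tau <- 12
    sel <- tt >= bounds[i]
    pw[sel] <- pw[sel] + (q_true[i] / tau) * exp(-(tt[sel] - bounds[i]) / tau)
  }
  got <- integrate_power(tt, pw, bounds)
  expect_equal(got, q_true, tolerance = 0.01)
})
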