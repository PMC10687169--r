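# independent equilibrium oracle: solve mass action for bound complex by
# root-finding instead of the closed-form quadratic
oracle_heats <- function(n, kd, dh, protocol, baseline = 0) {
  V0 <- protocol$cell_volume
  dvc <- cumsum(protocol$injection_volumes)
  Mt <- protocol$cell_conc * (1 - dvc / (2 * V0)) / (1 + dvc / (2 * V0))
  Xt <- protocol$syringe_conc * (dvc / V0) / (1 + dvc / (2 * V0))
  Q <- numeric(length(Mt))
  for (i in seq_along(Mt)) {
    St <- n * Mt[i]  # total site concentration
    f <- function(b) (St - b) * (Xt[i] - b) - kd * b
    b <- stats::uniroot(f, c(0, min(St, Xt[i])), tol = 1e-15)$root
    Q[i] <- b * dh * V0
  }
  Qprev <- c(0, Q[-length(Q)])
  dv <- protocol$injection_volumes
  (Q - Qprev + (dv / V0) * (Q + Qprev) / 2) * 1e6 + baseline
}

std_protocol <- function() itc_protocol(0.05e-3, 1e-3)
hi_protocol <- function() itc_protocol(0.225e-3, 4.5e-3)

test_that("zero enthalpy gives baseline-only heats", {
  h <- itc_heats(1, 1e-5, 0, std_protocol(), baseline = 0.37)
  expect_equal(h, rep(0.37, 60))
})

test_that("heats scale linearly in the enthalpy", {
  p <- std_protocol()
  h1 <- itc_heats(1, 5e-5, -1500, p)
  h2 <- itc_heats(1, 5e-5, -3000, p)
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
})

test_that("the tight-binding limit is piecewise linear with a break at n", {
  p <- std_protocol()
  n <- 0.8
  h <- itc_heats(n, 1e-12, -4000, p)
  ratio <- degronstruct:::itc_concentrations(p)$ratio
  # before saturation every injected mole binds: heat per injection constant
  pre <- h[ratio < 0.9 * n][-1]
  expect_lt(diff(range(pre)) / abs(mean(pre)), 0.02)
  # after the break nothing binds
  post <- h[ratio > 1.1 * n]
  expect_lt(max(abs(post)) / abs(mean(pre)), 0.02)
})

test_that("the quadratic isotherm matches the root-finding oracle to 1e-6", {
  for (kd in c(1e-6, 1.83e-5, 3.85e-4, 1e-3)) {
    p <- if (kd > 1e-4) hi_protocol() else std_protocol()
    got <- itc_heats(0.97, kd, -4200, p, baseline = 0.1)
    want <- oracle_heats(0.97, kd, -4200, p, baseline = 0.1)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("non-physical binding parameters are rejected", {
  expect_error(itc_heats(1, -1e-6, -4000, std_protocol()), "positive")
  expect_error(itc_heats(0, 1e-6, -4000, std_protocol()), "positive")
})

test_that("fitting a noiseless titration recovers the parameters to 0.1%", {
  p <- std_protocol()
  truth <- list(n = 0.95, kd = 5e-5, dh = -3000, baseline = 0.2)
  h <- itc_heats(truth$n, truth$kd, truth$dh, p, truth$baseline)
  fit <- fit_itc(h, p)
  expect_true(fit$converged)
  expect_equal(fit$n, truth$n, tolerance = 1e-3)
  expect_equal(fit$kd, truth$kd, tolerance = 1e-3)
  expect_equal(fit$dh, truth$dh, tolerance = 1e-3)
})

test_that("self-fit recovery holds across the measured K_D range", {
  # the assay's two working protocols: standard for tight, concentrated for
  # weak binders; median of a few noisy replicates within 5% of truth
  cases <- list(list(kd = 1.89e-5, p = std_protocol(), fix_n = FALSE),
                list(kd = 4.36e-5, p = std_protocol(), fix_n = FALSE),
                list(kd = 1.24e-4, p = hi_protocol(), fix_n = TRUE),
                list(kd = 6.26e-4, p = hi_protocol(), fix_n = TRUE))
  for (cs in cases) {
    kds <- sapply(1:7, function(s) {
      ser <- simulate_itc(1, cs$kd, -4000, cs$p, noise_prop = 0.02, seed = s)
      suppressWarnings(fit_itc(ser$heats, cs$p, init = list(n = 1),
                               fix_n = cs$fix_n))$kd
    })
    expect_lt(abs(stats::median(kds) - cs$kd) / cs$kd, 0.05,
              label = sprintf("relative bias at K_D %.3g", cs$kd))
  }
})

test_that("flat heats are flagged unidentifiable, short series refused", {
  p <- std_protocol()
  fit <- fit_itc(rep(0, 60), p)
  expect_equal(fit$dh, 0)
  expect_false(fit$kd_identifiable)
  p4 <- itc_protocol(0.05e-3, 1e-3, n_injections = 4)
  expect_error(fit_itc(rep(1, 4), p4), "at least 8")
})

test_that("low c-value fits carry a low-confidence warning", {
  p <- itc_protocol(1e-6, 2e-5)  # c ~ 0.002
  h <- itc_heats(1, 5e-4, -4000, p)
  expect_warning(fit <- fit_itc(h, p, init = list(n = 1), fix_n = TRUE),
                 "low-confidence")
  expect_true(fit$low_confidence)
})

test_that("a noiseless sigmoid melt fits its Tm exactly", {
  mc <- simulate_melt(60, noise_sd = 0)
  fit <- fit_melt(mc$temperature, mc$signal)
  expect_equal(fit$tm, 60, tolerance = 1e-6)
  expect_equal(fit$tm_derivative, 60, tolerance = 0.2)
})

test_that("delta_tm is the fitted difference and is antisymmetric", {
  ref <- fit_melt(simulate_melt(50)$temperature, simulate_melt(50)$signal)
  smp <- fit_melt(simulate_melt(62)$temperature, simulate_melt(62)$signal)
  expect_equal(delta_tm(smp, ref), 12, tolerance = 1e-6)
  expect_equal(delta_tm(smp, ref), -delta_tm(ref, smp), tolerance = 1e-12)
})

test_that("Tm is recovered within 0.1 C under 1% noise on the 0.2 C grid", {
  errs <- sapply(1:30, function(s) {
    mc <- simulate_melt(58.3, noise_sd = 0.01, seed = s)
    fit_melt(mc$temperature, mc$signal)$tm - 58.3
  })
  expect_lt(mean(abs(errs)), 0.1)
})

test_that("curves without a resolvable transition error out", {
  expect_error(fit_melt(seq(25, 95, 0.2), rep(1, 351)), "flat")
  # transition far outside the scanned range
  mc <- simulate_melt(150, noise_sd = 0)
  expect_error(fit_melt(mc$temperature, mc$signal), "transition")
})
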