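test_that("uninduced reporter stays identically zero", {
  p <- reporter_params("x", alpha = 1, delta_m = 0.1, beta = 1, kappa = 1,
                       delta_p = 0.003)
  out <- simulate_reporter(p, perturbation_schedule(), seq(0, 1440, by = 30))
  expect_true(all(out$f == 0))
  expect_true(all(out$m == 0))
})

test_that("long-run induction reaches the closed-form steady state", {
  p <- reporter_params("x", alpha = 1, delta_m = 0.1, beta = 1, kappa = 1,
                       delta_p = 0.003)
  ss <- reporter_steady_state(p)
  expect_equal(unname(ss["m"]), 10)
  expect_equal(unname(ss["p"]), 1 * 10 / 1.003)
  expect_equal(unname(ss["f"]), 10 / 1.003 / 0.003)
  out <- simulate_reporter(p, perturbation_schedule(ligand_on(0, 1)),
                           c(2880, 5760))
  expect_lt(abs(out$f[2] - ss["f"]) / ss["f"], 0.01)
  # closed-form agreement is much tighter than the 1% the bound asks for
  expect_lt(abs(out$f[2] - ss["f"]) / ss["f"], 1e-6)
})

test_that("adaptive solution agrees with a fixed-step Euler oracle", {
  p <- reporter_params("x", alpha = 1, delta_m = 0.05, beta = 1,
                       kappa = 0.2, delta_p = 0.01)
  sch <- perturbation_schedule(ligand_on(0, 1), ligand_off(120),
                               ligand_on(200, 0.5))
  keep <- c(60, 119, 150, 240)
  out <- simulate_reporter(p, sch, keep)
  orc <- euler_reporter(
    p,
    S_fun = function(t) if (t < 120) 1 else if (t < 200) 0 else 0.5,
    beta_on_fun = function(t) TRUE, t_end = 240, h = 0.01, keep = keep)
  # Euler at h = 0.01 carries O(h) error itself; 1e-3 relative is its level
  expect_lt(max(abs(out$f - orc$f) / pmax(orc$f, 1e-8)), 1e-3)
  expect_lt(max(abs(out$m - orc$m) / pmax(orc$m, 1e-8)), 1e-3)
})

test_that("translation blockade leaves pure first-order decay", {
  p <- reporter_params("x", alpha = 1, delta_m = 0.1, beta = 1, kappa = 1,
                       delta_p = 0.003)
  ss <- reporter_steady_state(p)
  t_block <- 5760
  sch <- perturbation_schedule(ligand_on(0, 1), translation_block_on(t_block))
  lag <- 5 * log(2) / p$kappa
  probe <- t_block + c(lag, 120, 480, 960)
  out <- simulate_reporter(p, sch, probe)
  expected <- ss["f"] * exp(-p$delta_p * (probe - t_block))
  expect_true(all(abs(out$f - expected) / expected < 0.02))
})

test_that("kinase inhibition decays strictly slower than translation block", {
  p <- reporter_preset("dynGFP")
  t0 <- 2880
  probe <- t0 + seq(30, 720, by = 30)
  chx <- simulate_reporter(p, perturbation_schedule(
    ligand_on(0, 1), translation_block_on(t0)), c(t0, probe))
  sb <- simulate_reporter(p, perturbation_schedule(
    ligand_on(0, 1), kinase_inhibitor_on(t0)), c(t0, probe))
  frac_chx <- chx$f[-1] / chx$f[1]
  frac_sb <- sb$f[-1] / sb$f[1]
  expect_true(all(frac_sb > frac_chx))
})

test_that("preset orderings embody the destabilised-reporter design", {
  dg <- reporter_preset("dynGFP")
  gf <- reporter_preset("GFP")
  td <- reporter_preset("TdTomato")
  # stated invariants on the presets themselves
  hl <- function(p) log(2) / p$delta_p / 60
  expect_gt(hl(dg), 3); expect_lt(hl(dg), 5)
  expect_gt(hl(gf), 24); expect_gt(hl(td), 24)
  expect_lt(log(2) / dg$kappa, log(2) / gf$kappa)
  expect_lt(log(2) / gf$kappa, log(2) / td$kappa)

  # dynGFP reaches half of its own plateau strictly earlier
  t_grid <- seq(0, 2880, by = 3)
  rise_half <- function(p) {
    out <- simulate_reporter(p, perturbation_schedule(ligand_on(0, 1)),
                             t_grid)
    fstar <- reporter_steady_state(p)["f"]
    t_grid[which(out$f >= 0.5 * fstar)[1]]
  }
  expect_lt(rise_half(dg), rise_half(gf))

  # and falls below half of its pre-block level strictly earlier
  fall_half <- function(p) {
    t0 <- 8640
    probe <- t0 + seq(0, 2880, by = 3)
    out <- simulate_reporter(p, perturbation_schedule(
      ligand_on(0, 1), translation_block_on(t0)), probe)
    probe[which(out$f <= 0.5 * out$f[1])[1]] - t0
  }
  f_dg <- fall_half(dg)
  expect_lt(f_dg, fall_half(gf))
  expect_lt(f_dg, fall_half(td))
})

test_that("state variables stay non-negative across random schedules", {
  set.seed(42)
  for (rep in 1:12) {
    p <- reporter_params("r", alpha = runif(1, 0, 2),
                         delta_m = runif(1, 0.001, 0.5),
                         beta = runif(1, 0, 2),
                         kappa = runif(1, 0.001, 1),
                         delta_p = runif(1, 0.001, 0.1))
    ev <- sort(runif(3, 1, 1200))
    sch <- perturbation_schedule(ligand_on(ev[1], runif(1)),
                                 ligand_off(ev[2]),
                                 translation_block_on(ev[3]))
    out <- simulate_reporter(p, sch, seq(0, 1440, by = 20),
                             onset_delay = runif(1, 0, 100))
    expect_true(all(out$m >= 0 & out$p >= 0 & out$f >= 0))
  }
})

test_that("constant induction rises monotonically toward the plateau", {
  p <- reporter_preset("dynGFP")
  out <- simulate_reporter(p, perturbation_schedule(ligand_on(0, 1)),
                           seq(0, 4320, by = 10))
  expect_true(all(diff(out$f) >= -1e-9))
  expect_true(all(out$f <= reporter_steady_state(p)["f"] * (1 + 1e-9)))
})

test_that("simulate_reporter rejects malformed input", {
  p <- reporter_preset("dynGFP")
  sch <- perturbation_schedule(ligand_on(0, 1))
  expect_error(simulate_reporter(p, sch, c(10, 5)), "increasing")
  expect_error(simulate_reporter(p, sch, numeric(0)), "non-empty")
  expect_error(simulate_reporter(p, sch, c(0, 10), onset_delay = -1),
               "onset_delay")
  expect_error(reporter_params("bad", alpha = -1, delta_m = 0.1, beta = 1,
                               kappa = 1, delta_p = 0.01), "rates")
  expect_error(reporter_params("bad", alpha = 1, delta_m = 0, beta = 1,
                               kappa = 1, delta_p = 0.01), "delta_m")
  expect_error(perturbation_schedule(ligand_on(10), ligand_off(5)),
               "increasing")
  expect_error(ligand_on(0, level = 2), "level")
})

test_that("half-life estimation matches closed forms and printed chase data", {
  # single chase point: 48% remaining at 4 h
  expect_equal(estimate_half_life(4, 0.48), 4 * log(2) / log(1 / 0.48))
  expect_equal(round(estimate_half_life(4, 0.48)), 4)
  # exact halving per hour
  expect_equal(estimate_half_life(c(1, 2, 3), c(0.5, 0.25, 0.125)), 1.0)
  # machine-precision recovery on noiseless exponentials
  k <- 0.17
  t <- seq(0.5, 12, length.out = 15)
  expect_equal(estimate_half_life(t, exp(-k * t)), log(2) / k,
               tolerance = 1e-12)
})

test_that("half-life estimation handles degenerate and noisy input", {
  expect_error(estimate_half_life(numeric(0), numeric(0)), "invalid")
  expect_error(estimate_half_life(c(1, 2), c(1, 1)), "no decay")
  expect_error(estimate_half_life(c(1, 2), c(0.5)), "length")
  expect_warning(h <- estimate_half_life(c(1, 2, 3), c(1.05, 0.5, 0.25)),
                 "above 1")
  expect_gt(h, 0)
  # noisy exponential: within 10% of the generating constant
  set.seed(1)
  t <- seq(0.5, 10, length.out = 20)
  frac <- exp(-0.3 * t) * exp(rnorm(20, 0, 0.05))
  expect_lt(abs(estimate_half_life(t, frac) - log(2) / 0.3) / (log(2) / 0.3),
            0.1)
})

test_that("reporter parameters and schedules round-trip through JSON", {
  p <- reporter_preset("dynGFP")
  sch <- perturbation_schedule(ligand_on(0, 1), kinase_inhibitor_on(500))
  path <- tempfile(fileext = ".json")
  write_reporter_json(p, sch, path)
  back <- read_reporter_json(path)
  expect_equal(back$params, p)
  expect_equal(as.data.frame(back$schedule), as.data.frame(sch))
  # empty schedule survives too
  write_reporter_json(p, perturbation_schedule(), path)
  expect_equal(nrow(read_reporter_json(path)$schedule), 0)
  # simulated series CSV carries the documented columns
  out <- simulate_reporter(p, sch, c(0, 100, 200))
  csv <- tempfile(fileext = ".csv")
  write_kinetics_csv(out, csv)
  got <- read.csv(csv)
  expect_equal(names(got), c("t_min", "mRNA", "immature", "mature"))
  expect_equal(got$mature, out$f)
})
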