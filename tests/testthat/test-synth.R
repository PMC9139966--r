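small_pp <- function(n_cells = 8, n_frames = 40, ...) {
  population_params(n_cells = n_cells, field_width = 128,
                    field_height = 128, n_frames = n_frames, seed = 5, ...)
}

test_that("a degenerate mixture yields a single responder class", {
  pp <- small_pp(n_cells = 10, frac_early = 1, frac_late = 0, frac_non = 0)
  pop <- simulate_population(pp)
  expect_true(all(pop$cells$responder_class == "early"))
})

test_that("population generation is bit-exact under a fixed seed", {
  pp <- population_params(n_cells = 200, n_frames = 60, seed = 7)
  a <- simulate_population(pp)
  b <- simulate_population(pp)
  expect_identical(a$cells, b$cells)
  expect_identical(a$x, b$x)
  expect_identical(a$traces, b$traces)
  pp2 <- population_params(n_cells = 200, n_frames = 60, seed = 8)
  expect_false(identical(simulate_population(pp2)$cells$responder_class,
                         a$cells$responder_class))
})

test_that("onset delays centre on the class mean (CLT bound)", {
  pp <- population_params(n_cells = 500, n_frames = 40, seed = 11)
  pop <- simulate_population(pp)
  early <- pop$cells$onset_delay[pop$cells$responder_class == "early"]
  n_early <- length(early)
  expect_lt(abs(mean(early) - pp$onset_early_mean),
            3 * pp$onset_early_sd / sqrt(n_early))
  late <- pop$cells$onset_delay[pop$cells$responder_class == "late"]
  expect_lt(abs(mean(late) - pp$onset_late_mean),
            3 * pp$onset_late_sd / sqrt(length(late)))
  expect_true(all(is.na(
    pop$cells$onset_delay[pop$cells$responder_class == "non"])))
})

test_that("trajectories respect field bounds and excluded volume", {
  pp <- population_params(n_cells = 35, field_width = 192,
                          field_height = 192, n_frames = 50, seed = 2)
  pop <- simulate_population(pp)
  expect_true(all(pop$x >= 1 & pop$x <= 192))
  expect_true(all(pop$y >= 1 & pop$y <= 192))
  min_d <- min(sapply(seq_len(pp$n_frames), function(f) {
    d <- as.matrix(stats::dist(cbind(pop$x[f, ], pop$y[f, ])))
    min(d[upper.tri(d)])
  }))
  # soft collision resolution (a few sweeps per frame, boundaries
  # re-applied) keeps nuclei near or beyond the exclusion distance
  expect_gt(min_d, 0.6 * pp$exclusion_radius)
  # and without it, nuclei pass straight through each other
  pp0 <- population_params(n_cells = 35, field_width = 192,
                           field_height = 192, n_frames = 50, seed = 2,
                           exclusion_radius = 0)
  pop0 <- simulate_population(pp0)
  min_d0 <- min(sapply(seq_len(pp0$n_frames), function(f) {
    d <- as.matrix(stats::dist(cbind(pop0$x[f, ], pop0$y[f, ])))
    min(d[upper.tri(d)])
  }))
  expect_lt(min_d0, min_d)
})

test_that("generator rejects inconsistent parameters", {
  expect_error(population_params(frac_early = 0.5, frac_late = 0.5,
                                 frac_non = 0.2), "sum to 1")
  expect_error(population_params(n_cells = 0), "n_cells")
  expect_error(population_params(onset_early_sd = -1), "SD")
  pp <- small_pp()
  late_sched <- list(params = reporter_preset("dynGFP"),
                     schedule = perturbation_schedule(ligand_on(5000, 1)))
  expect_error(simulate_population(pp, list(early = late_sched,
                                            late = late_sched,
                                            non = late_sched)),
               "horizon")
})

test_that("noiseless rendering reproduces the analytic Gaussian field", {
  pp <- small_pp(n_cells = 1, nucleus_sigma_cv = 0, amplitude_cv = 0,
                 n_frames = 8)
  pop <- simulate_population(pp)
  # pin the cell to a known state
  pop$x[, 1] <- 50; pop$y[, 1] <- 30
  pop$cells$nucleus_sigma <- 3
  pop$cells$rfp_amplitude <- 500
  pop$traces[, 1] <- 0
  ip <- imaging_params(background = 100)
  st <- render_frames(pop, ip, noise = FALSE)
  rfp <- matrix(st[1, 1, , ], 128, 128)
  expect_equal(rfp[30, 50], 600)
  expect_equal(rfp[30, 53], 500 * exp(-0.5) + 100, tolerance = 1e-9)
  # reporter channel of a dark cell is pure background
  gfp <- matrix(st[1, 2, , ], 128, 128)
  expect_true(all(gfp == 100))
})

test_that("rendering is bit-identical under a fixed noise seed", {
  pp <- small_pp()
  pop <- simulate_population(pp)
  a <- render_frames(pop, imaging_params(), noise = TRUE, seed = 31)
  b <- render_frames(pop, imaging_params(), noise = TRUE, seed = 31)
  expect_identical(a, b)
  c <- render_frames(pop, imaging_params(), noise = TRUE, seed = 32)
  expect_false(identical(a, c))
  expect_true(is.integer(a))
  expect_true(min(a) >= 0 && max(a) <= 65535)
})

test_that("cytometry snapshots scale the true trace", {
  pp <- small_pp(n_cells = 3, frac_early = 0, frac_late = 0, frac_non = 1)
  pop <- simulate_population(pp)
  sn <- snapshot_cytometry(pop, 10, sigma = 0)
  expect_true(all(sn$intensity == 0))
  # pure scaling: trace value 10 at photons_per_unit 3 reads 30
  pop$traces[10, ] <- 10
  sn2 <- snapshot_cytometry(pop, 10, imaging_params(photons_per_unit = 3),
                            sigma = 0)
  expect_true(all(sn2$intensity == 30))
  expect_error(snapshot_cytometry(pop, 0), "frame_index")
  expect_error(snapshot_cytometry(pop, 41), "frame_index")
})

test_that("lognormal size noise preserves the median intensity", {
  pp <- population_params(n_cells = 1000, frac_early = 1, frac_late = 0,
                          frac_non = 0, n_frames = 480, seed = 3)
  pop <- simulate_population(pp)
  sn <- snapshot_cytometry(pop, 480, sigma = 0.25, seed = 3)
  noiseless <- imaging_params()$photons_per_unit * pop$traces[480, ]
  expect_lt(abs(median(sn$intensity) - median(noiseless)) /
              median(noiseless), 0.05)
  # heterogeneity: responder CV at 24 h at least the configured lognormal CV
  cv <- sd(sn$intensity) / mean(sn$intensity)
  expect_gte(cv, sqrt(exp(0.25^2) - 1) * 0.95)
})
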