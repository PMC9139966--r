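test_that("a blank frame yields no detections", {
  expect_equal(nrow(detect_nuclei(matrix(100, 60, 60), 50, 6)), 0)
  expect_error(detect_nuclei(array(1, c(2, 2, 2)), 50, 6), "2D")
  expect_error(detect_nuclei(matrix(100, 10, 10), min_amplitude = 0),
               "min_amplitude")
})

test_that("a single rendered Gaussian is recovered to sub-pixel accuracy", {
  img <- render_spots(80, 100, 50.4, 30.3, 3, 500)
  d <- detect_nuclei(img, 50, 6, init_sigma = 3)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 50.4), 0.05)
  expect_lt(abs(d$y - 30.3), 0.05)
  expect_lt(abs(d$sx - 3) / 3, 0.02)
  expect_lt(abs(d$sy - 3) / 3, 0.02)
  expect_lt(abs(d$amplitude - 500) / 500, 0.02)
})

test_that("separation controls whether close peaks merge or split", {
  # sigma 1.5 spots 4 px apart: bimodal profile (mixture split disabled to
  # isolate the suppression-radius behaviour)
  img <- render_spots(60, 60, c(28, 32), c(30, 30), 1.5, c(400, 400))
  merged <- detect_nuclei(img, 50, 6, init_sigma = 1.5,
                          split_factor = Inf)
  expect_equal(nrow(merged), 1)
  # the merged detection lies between the two true centers
  expect_gt(merged$x, 28)
  expect_lt(merged$x, 32)
  expect_lt(abs(merged$y - 30), 0.5)
  split <- detect_nuclei(img, 50, 3, init_sigma = 1.5)
  expect_equal(nrow(split), 2)
  expect_lt(min(split$x), 28.5)
  expect_gt(max(split$x), 31.5)
})

test_that("the mixture split pass resolves sub-resolution pairs", {
  # two sigma-3 nuclei 4.5 px apart render as one unimodal spot
  img <- render_spots(80, 80, c(38, 42.5), c(40, 40), 3, c(500, 430))
  d <- detect_nuclei(img, 50, 4, init_sigma = 3)
  expect_equal(nrow(d), 2)
  expect_lt(abs(min(d$x) - 38), 0.2)
  expect_lt(abs(max(d$x) - 42.5), 0.2)
  # a genuine single wide nucleus is not split
  img1 <- render_spots(80, 80, 40, 40, 3.4, 500)
  d1 <- detect_nuclei(img1, 50, 4, init_sigma = 3)
  expect_equal(nrow(d1), 1)
})

test_that("link costs follow the Gaussian transition priors", {
  pr <- link_priors(pos_sd = 2, logshape_sd = 0.2, logint_sd = 0.3,
                    gate = 9)
  d1 <- data.frame(frame = 1, x = 10, y = 10, sx = 3, sy = 3,
                   amplitude = 500, background = 100)
  d2 <- d1; d2$frame <- 2
  expect_equal(link_cost(d1, d2, pr), 0)
  d2b <- d2; d2b$x <- 10 + pr$pos_sd
  expect_equal(link_cost(d1, d2b, pr), 0.5)
  pr1 <- link_priors(pos_sd = 2, logshape_sd = 0.2, logint_sd = 1, gate = 9)
  d2c <- d2; d2c$amplitude <- exp(1) * 500
  expect_equal(link_cost(d1, d2c, pr1), 0.5)
  d3 <- d2; d3$frame <- 3
  expect_error(link_cost(d1, d3, pr), "consecutive")
  expect_error(link_priors(pos_sd = 0), "> 0")
})

test_that("frame assignment is optimal against exhaustive search", {
  pr <- link_priors()
  mk <- function(n, frame, seed) {
    set.seed(seed)
    data.frame(frame = rep(frame, n), x = runif(n, 0, 30),
               y = runif(n, 0, 30),
               sx = exp(rnorm(n, log(3), 0.1)),
               sy = exp(rnorm(n, log(3), 0.1)),
               amplitude = exp(rnorm(n, log(500), 0.2)),
               background = rep(100, n))
  }
  set.seed(99)
  for (rep in 1:40) {
    n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
    a <- mk(n1, 1, rep * 2)
    b <- mk(n2, 2, rep * 2 + 1)
    lf <- link_frames(a, b, pr)
    cost <- smadtrace:::link_cost_matrix(a, b, pr)
    bf <- brute_force_matching(cost, pr$gate)
    expect_equal(matching_total(lf, pr$gate), bf$total, tolerance = 1e-9)
  }
})

test_that("assignment handles identity, crossing and gating cases", {
  pr <- link_priors()
  a <- data.frame(frame = 1, x = c(10, 20), y = c(10, 10), sx = 3, sy = 3,
                  amplitude = 500, background = 100)
  b <- a; b$frame <- 2
  lf <- link_frames(a, b, pr)
  expect_equal(lf$pairs$i, c(1, 2))
  expect_equal(lf$pairs$j, c(1, 2))
  expect_equal(sum(lf$pairs$cost), 0)

  # crossing: the swapped pairing is constructed to be cheaper
  a2 <- data.frame(frame = 1, x = c(10, 13), y = c(10, 10), sx = 3, sy = 3,
                   amplitude = 500, background = 100)
  b2 <- data.frame(frame = 2, x = c(13.2, 9.8), y = c(10, 10), sx = 3,
                   sy = 3, amplitude = 500, background = 100)
  lf2 <- link_frames(a2, b2, pr)
  expect_equal(lf2$pairs$j[lf2$pairs$i == 1], 2)
  expect_equal(lf2$pairs$j[lf2$pairs$i == 2], 1)

  # gating: nothing within reach
  b3 <- data.frame(frame = 2, x = 100, y = 100, sx = 3, sy = 3,
                   amplitude = 500, background = 100)
  lf3 <- link_frames(a2[1, ], b3, pr)
  expect_equal(nrow(lf3$pairs), 0)
  expect_equal(lf3$unmatched_t, 1)
  expect_equal(lf3$unmatched_t1, 1)
  expect_error(link_frames(a2, transform(b3, frame = 3), pr), "consecutive")
})

test_that("a steady noiseless cell yields one complete track", {
  pp <- population_params(n_cells = 1, field_width = 64, field_height = 64,
                          n_frames = 50, motion_sd = 0.5, seed = 4,
                          nucleus_sigma_cv = 0, amplitude_cv = 0)
  pop <- simulate_population(pp)
  st <- render_frames(pop, imaging_params(), noise = FALSE)
  det <- detect_stack(st, channel = 1)
  ts <- build_tracks(det, link_priors())
  expect_equal(nrow(ts$summary), 1)
  expect_equal(ts$summary$completeness, 1.0)
  expect_equal(tracking_fraction(ts, pop), 1.0)
})

test_that("short invisibility is bridged as an in-track gap", {
  # detections for one cell over 50 frames, invisible for frames 20-21
  frames <- setdiff(1:50, 20:21)
  det <- data.frame(frame = frames, x = 30 + 0.1 * frames, y = 25,
                    sx = 3, sy = 3, amplitude = 500, background = 100)
  ts <- build_tracks(det, link_priors(), max_gap = 3)
  expect_equal(nrow(ts$summary), 1)
  expect_equal(ts$summary$n_detections, 48)
  expect_equal(ts$summary$start_frame, 1)
  expect_equal(ts$summary$end_frame, 50)
  expect_false(any(20:21 %in% ts$tracks$frame))
  # with max_gap 1 the track cannot be rejoined
  ts2 <- build_tracks(det, link_priors(), max_gap = 1,
                      min_completeness = 0)
  expect_equal(nrow(ts2$summary), 2)
})

test_that("two crossing cells keep two tracks with sane endpoints", {
  nT <- 40
  x1 <- seq(20, 60, length.out = nT); y1 <- rep(30, nT)
  x2 <- seq(60, 20, length.out = nT); y2 <- 30 + seq(-6, 6, length.out = nT)
  ip <- imaging_params()
  stack <- array(0, dim = c(nT, 2, 64, 80))
  for (f in 1:nT) {
    stack[f, 1, , ] <- render_spots(64, 80, c(x1[f], x2[f]),
                                    c(y1[f], y2[f]), 3, c(500, 560))
    stack[f, 2, , ] <- 100
  }
  det <- suppressWarnings(detect_stack(stack, channel = 1))
  ts <- build_tracks(det, link_priors(), stack = stack, channel = 1)
  expect_equal(nrow(ts$summary), 2)
  ends <- t(sapply(ts$summary$track_id, function(id) {
    tr <- ts$tracks[ts$tracks$track_id == id, ]
    unlist(tr[nrow(tr), c("x", "y")])
  }))
  true_ends <- rbind(c(x1[nT], y1[nT]), c(x2[nT], y2[nT]))
  # each track terminal lies within 2 px of one of the true endpoints
  for (k in 1:2) {
    d <- sqrt((true_ends[, 1] - ends[k, 1])^2 +
                (true_ends[, 2] - ends[k, 2])^2)
    expect_lt(min(d), 2)
  }
})

test_that("track building is invariant to detection order within frames", {
  pp <- population_params(n_cells = 12, field_width = 128,
                          field_height = 128, n_frames = 30, seed = 9)
  pop <- simulate_population(pp)
  st <- render_frames(pop, imaging_params(), noise = TRUE, seed = 17)
  det <- suppressWarnings(detect_stack(st, channel = 1))
  set.seed(123)
  perm <- do.call(rbind, lapply(split(det, det$frame),
                                function(d) d[sample(nrow(d)), ]))
  canon <- function(ts) {
    unname(lapply(
      split(ts$tracks[, c("frame", "x", "y")], ts$tracks$track_id),
      function(d) d[order(d$frame), ]))
  }
  t1 <- canon(build_tracks(det, link_priors()))
  t2 <- canon(build_tracks(perm, link_priors()))
  key <- function(l) sort(sapply(l, function(d) paste(round(d$x, 6),
                                                      collapse = ",")))
  expect_equal(key(t1), key(t2))
})

test_that("noiseless well-separated nuclei are recovered exactly", {
  pp <- population_params(n_cells = 5, field_width = 200,
                          field_height = 200, n_frames = 60,
                          motion_sd = 0.8, seed = 21,
                          frac_early = 1, frac_late = 0, frac_non = 0,
                          onset_early_mean = 60, onset_early_sd = 10,
                          exclusion_radius = 40)
  pop <- simulate_population(pp)
  st <- render_frames(pop, imaging_params(), noise = FALSE)
  det <- detect_stack(st, channel = 1)
  ts <- build_tracks(det, link_priors())
  expect_equal(tracking_fraction(ts, pop), 1.0)
  tr <- extract_traces(ts, st, gfp_channel = 2, frame_interval = 3)
  n_checked <- 0L
  for (i in seq_along(tr$cell_id)) {
    t1 <- ts$tracks[ts$tracks$track_id == tr$cell_id[i], ][1, ]
    cell <- which.min((pop$x[1, ] - t1$x)^2 + (pop$y[1, ] - t1$y)^2)
    margin <- min(pop$x[, cell], pop$y[, cell], 200 - pop$x[, cell],
                  200 - pop$y[, cell])
    if (margin < 8) next  # mask clips at the field border
    n_checked <- n_checked + 1L
    truth <- pop$traces[, cell]
    expect_gt(cor(tr$raw[i, ], truth), 0.999)
    sel <- truth > 0.2 * max(truth)
    ratio <- tr$raw[i, sel] / truth[sel]
    # grid-aligned masks make the photometry shift-invariant, so the
    # extracted trace is an exact affine image of the true trace
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  }
  expect_gte(n_checked, 3)
})

test_that("tracking fraction counts covered cells correctly", {
  pp <- population_params(n_cells = 10, field_width = 256,
                          field_height = 256, n_frames = 20, seed = 13)
  pop <- simulate_population(pp)
  # perfect tracks for cells 1..8, none for 9-10
  det <- do.call(rbind, lapply(1:20, function(f) {
    data.frame(frame = f, x = pop$x[f, 1:8], y = pop$y[f, 1:8],
               sx = 3, sy = 3, amplitude = 500, background = 100)
  }))
  ts <- build_tracks(det, link_priors())
  expect_equal(tracking_fraction(ts, pop), 0.8)
  expect_equal(tracking_fraction(
    structure(list(tracks = det[0, ], summary = ts$summary[0, ]),
              class = "track_set"), pop), 0)
  expect_error(tracking_fraction(ts, pop, match_radius = 0), "match_radius")
})

test_that("tracking degrades monotonically with density and motility", {
  frac_at <- function(n_cells, motion_sd, seed) {
    pp <- population_params(n_cells = n_cells, field_width = 128,
                            field_height = 128, n_frames = 40,
                            motion_sd = motion_sd, seed = seed,
                            exclusion_radius = 6)
    pop <- simulate_population(pp)
    st <- render_frames(pop, imaging_params(), noise = TRUE)
    det <- suppressWarnings(detect_stack(st, channel = 1))
    ts <- build_tracks(det, link_priors(), stack = st, channel = 1)
    tracking_fraction(ts, pop)
  }
  seeds <- 1:3
  dens <- sapply(c(6, 18, 38), function(n) {
    mean(sapply(seeds, function(s) frac_at(n, 1, s)))
  })
  expect_true(all(diff(dens) <= 1e-9))
  mot <- sapply(c(0.5, 2, 4), function(m) {
    mean(sapply(seeds, function(s) frac_at(14, m, s + 10)))
  })
  expect_true(all(diff(mot) <= 1e-9))
})
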