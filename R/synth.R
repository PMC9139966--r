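#' Population generator parameters
#'
#' Describes the simulated clonal cell population: mixture fractions of
#' early, late and non-responders, the onset-delay distributions of the two
#' responder classes, the imaging field, the motility model and the imaging
#' cadence.  Defaults describe a desk-scale field (512 x 512 px, 250 cells)
#' imaged for 24 h at 1 frame / 3 min, with responder onsets centred at
#' 300 min (early) and 700 min (late).
#'
#' @param n_cells Number of cells (>= 1).
#' @param frac_early,frac_late,frac_non Mixture fractions, must sum to 1.
#' @param onset_early_mean,onset_early_sd Early-responder onset-delay
#'   distribution (min); normal truncated at zero.
#' @param onset_late_mean,onset_late_sd Late-responder onset-delay
#'   distribution (min).
#' @param field_width,field_height Field size (px).
#' @param pixel_size Pixel size (um/px); metadata only.
#' @param motion_sd Random-walk displacement SD per axis per frame (px).
#' @param exclusion_radius Excluded-volume distance (px): after every
#'   step, pairs of nuclei closer than this are pushed apart symmetrically
#'   (nuclei are impenetrable; 0 disables the interaction).
#' @param frame_interval Imaging cadence (min/frame).
#' @param n_frames Number of frames.
#' @param nucleus_sigma Median nuclear Gaussian width (px).
#' @param nucleus_sigma_cv,amplitude_cv Lognormal cell-to-cell variation of
#'   nuclear width and nuclear-marker amplitude.
#' @param rfp_amplitude Median nuclear-marker peak amplitude (counts).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `population_params`.
#' @export
population_params <- function(n_cells = 250,
                              frac_early = 0.45, frac_late = 0.35,
                              frac_non = 0.20,
                              onset_early_mean = 300, onset_early_sd = 25,
                              onset_late_mean = 700, onset_late_sd = 40,
                              field_width = 512, field_height = 512,
                              pixel_size = 1.3,
                              motion_sd = 1,
                              exclusion_radius = 10,
                              frame_interval = 3, n_frames = 480,
                              nucleus_sigma = 3,
                              nucleus_sigma_cv = 0.05,
                              rfp_amplitude = 500,
                              amplitude_cv = 0.15,
                              seed = 7) {
  fr <- c(frac_early, frac_late, frac_non)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9) {
    stop("invalid input: mixture fractions must lie in [0,1] and sum to 1",
         call. = FALSE)
  }
  if (n_cells < 1) stop("invalid input: n_cells must be >= 1", call. = FALSE)
  if (onset_early_sd < 0 || onset_late_sd < 0) {
    stop("invalid input: onset SDs must be >= 0", call. = FALSE)
  }
  if (n_frames < 1 || frame_interval <= 0) {
    stop("invalid input: need n_frames >= 1 and frame_interval > 0",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "population_params")
}

#' Reporter model used by the population generator
#'
#' The single-cell trace model behind the synthetic movies: a dynGFP-type
#' fluorophore (fast maturation, protein half-life 227 min) driven by a
#' transcriptional burst.  Pathway activity jumps to 1 for
#' `burst_duration` minutes when a cell's response starts and then relaxes
#' to a sustained level `sustained_level`; reporter transcript turnover in
#' this context is fast (half-life `mrna_half_life` min) so that the
#' half-rise of the trace closely tracks the activation time, making the
#' generative onset identifiable from the measured trace.
#'
#' @param burst_duration Burst length (min).
#' @param sustained_level Pathway activity after the burst, in \[0, 1\].
#' @param mrna_half_life Reporter mRNA half-life (min).
#' @return List with elements `params` (a [reporter_params()]) and
#'   `schedule` (a [perturbation_schedule()]; empty for `responding =
#'   FALSE`).
#' @export
population_reporter <- function(burst_duration = 18, sustained_level = 0.03,
                                mrna_half_life = 4) {
  ln2 <- log(2)
  params <- reporter_params("dynGFP-population", alpha = 1,
                            delta_m = ln2 / mrna_half_life, beta = 1,
                            kappa = ln2 / 6, delta_p = ln2 / 227)
  schedule <- perturbation_schedule(ligand_on(0, 1),
                                    ligand_on(burst_duration,
                                              sustained_level))
  list(params = params, schedule = schedule)
}

#' Default responder-class map
#'
#' Maps each responder class to the reporter parameters and perturbation
#' schedule used for its true traces.  Early and late responders share the
#' same burst model and differ only in their onset-delay distribution;
#' non-responders never activate (empty schedule, so S(t) = 0).
#'
#' @param reporter Output of [population_reporter()] (or a compatible list).
#' @return Named list with entries `early`, `late`, `non`.
#' @export
default_responder_map <- function(reporter = population_reporter()) {
  none <- list(params = reporter$params,
               schedule = perturbation_schedule())
  list(early = reporter, late = reporter, non = none)
}

# inverse-CDF sampling of a normal truncated at zero; vectorised and
# deterministic under the current RNG state
rtruncnorm0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate a ground-truth cell population
#'
#' Draws responder classes from the mixture, class-specific onset delays
#' (normal truncated at zero), uniform initial positions and
#' reflecting-boundary Gaussian random-walk trajectories, and computes each
#' cell's true mature-fluorophore trace on the frame grid with
#' [simulate_reporter()].  Deterministic given `pp$seed`.
#'
#' @param pp A [population_params()] object.
#' @param rp_map A responder-class map, see [default_responder_map()].
#' @return An object of class `cell_population`: a list with elements
#'   `params`, `cells` (data frame: `cell_id`, `responder_class`,
#'   `onset_delay`, `nucleus_sigma`, `rfp_amplitude`), `x` and `y`
#'   (n_frames x n_cells position matrices, px), `traces` (n_frames x
#'   n_cells true-trace matrix) and `t` (frame times, min).
#' @export
simulate_population <- function(pp, rp_map = default_responder_map()) {
  stopifnot(inherits(pp, "population_params"))
  if (!all(c("early", "late", "non") %in% names(rp_map))) {
    stop("invalid input: rp_map needs entries early, late, non",
         call. = FALSE)
  }
  horizon <- (pp$n_frames - 1) * pp$frame_interval
  for (cls in c("early", "late", "non")) {
    sch <- rp_map[[cls]]$schedule
    if (nrow(sch) > 0 && max(sch$time) > horizon) {
      stop("invalid input: schedule events extend past the imaging horizon",
           call. = FALSE)
    }
  }

  set.seed(pp$seed)
  n <- pp$n_cells
  cls <- sample(c("early", "late", "non"), n, replace = TRUE,
                prob = c(pp$frac_early, pp$frac_late, pp$frac_non))
  # draw a delay for every cell (fixed RNG layout); only responders use it
  d_early <- rtruncnorm0(n, pp$onset_early_mean, pp$onset_early_sd)
  d_late <- rtruncnorm0(n, pp$onset_late_mean, pp$onset_late_sd)
  onset <- ifelse(cls == "early", d_early,
                  ifelse(cls == "late", d_late, NA_real_))

  x0 <- stats::runif(n, 1, pp$field_width)
  y0 <- stats::runif(n, 1, pp$field_height)
  steps_x <- matrix(stats::rnorm((pp$n_frames - 1) * n, 0, pp$motion_sd),
                    nrow = pp$n_frames - 1)
  steps_y <- matrix(stats::rnorm((pp$n_frames - 1) * n, 0, pp$motion_sd),
                    nrow = pp$n_frames - 1)
  x <- matrix(0, pp$n_frames, n)
  y <- matrix(0, pp$n_frames, n)
  cur <- resolve_collisions(x0, y0, pp$exclusion_radius)
  x[1, ] <- reflect_into(cur$x, 1, pp$field_width)
  y[1, ] <- reflect_into(cur$y, 1, pp$field_height)
  for (f in seq_len(pp$n_frames - 1)) {
    nx <- x[f, ] + steps_x[f, ]
    ny <- y[f, ] + steps_y[f, ]
    cur <- resolve_collisions(nx, ny, pp$exclusion_radius)
    x[f + 1, ] <- reflect_into(cur$x, 1, pp$field_width)
    y[f + 1, ] <- reflect_into(cur$y, 1, pp$field_height)
  }

  sig <- pp$nucleus_sigma * exp(stats::rnorm(n, 0, pp$nucleus_sigma_cv))
  amp <- pp$rfp_amplitude * exp(stats::rnorm(n, 0, pp$amplitude_cv))

  t_grid <- (seq_len(pp$n_frames) - 1) * pp$frame_interval
  traces <- matrix(0, nrow = pp$n_frames, ncol = n)
  for (i in seq_len(n)) {
    spec <- rp_map[[cls[i]]]
    if (nrow(spec$schedule) == 0L) next  # S(t) = 0, trace stays zero
    traces[, i] <- simulate_reporter(spec$params, spec$schedule, t_grid,
                                     onset_delay = onset[i])$f
  }

  structure(list(
    params = pp,
    cells = data.frame(cell_id = seq_len(n), responder_class = cls,
                       onset_delay = onset, nucleus_sigma = sig,
                       rfp_amplitude = amp),
    x = x, y = y, traces = traces, t = t_grid,
    rp_map = rp_map), class = "cell_population")
}

# soft excluded-volume interaction: nuclei closer than r_min are pushed
# apart symmetrically along their connecting line, a few sweeps per frame
resolve_collisions <- function(x, y, r_min, sweeps = 5) {
  if (r_min <= 0 || length(x) < 2) return(list(x = x, y = y))
  for (s in seq_len(sweeps)) {
    dx <- outer(x, x, "-")
    dy <- outer(y, y, "-")
    d <- sqrt(dx^2 + dy^2)
    close <- which(d < r_min & upper.tri(d), arr.ind = TRUE)
    if (nrow(close) == 0L) break
    for (k in seq_len(nrow(close))) {
      i <- close[k, 1]; j <- close[k, 2]
      dd <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (dd >= r_min) next
      if (dd < 1e-9) {  # coincident: separate along x
        ux <- 1; uy <- 0; dd <- 0
      } else {
        ux <- (x[i] - x[j]) / dd
        uy <- (y[i] - y[j]) / dd
      }
      push <- (r_min - dd) / 2
      x[i] <- x[i] + push * ux; y[i] <- y[i] + push * uy
      x[j] <- x[j] - push * ux; y[j] <- y[j] - push * uy
    }
  }
  list(x = x, y = y)
}

# fold values into [lo, hi] by repeated boundary reflection
reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  u <- (v - lo) %% (2 * span)
  lo + ifelse(u > span, 2 * span - u, u)
}

#' Imaging and rendering parameters
#'
#' @param background Uniform background level (counts).
#' @param photons_per_unit Expected counts per model fluorophore unit.
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param gfp_psf_sigma Width of the rendered reporter spot (px).
#' @param rfp_channel,gfp_channel Channel indices (1-based) of the nuclear
#'   marker and the reporter in rendered stacks.
#' @param bit_depth Stored bit depth; pixel values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(background = 100, photons_per_unit = 4,
                           read_noise_sd = 2, gfp_psf_sigma = 1,
                           rfp_channel = 1, gfp_channel = 2,
                           bit_depth = 16) {
  if (background < 0) stop("invalid input: background must be >= 0",
                           call. = FALSE)
  if (photons_per_unit <= 0) {
    stop("invalid input: photons_per_unit must be > 0", call. = FALSE)
  }
  if (read_noise_sd < 0) stop("invalid input: read_noise_sd must be >= 0",
                              call. = FALSE)
  structure(as.list(environment()), class = "imaging_params")
}

#' Render a population into a two-channel time-lapse stack
#'
#' The nuclear-marker channel is a sum over cells of isotropic 2D Gaussians
#' (width `nucleus_sigma`, amplitude `rfp_amplitude`) at each cell's
#' position plus background; the reporter channel is a Gaussian spot of
#' width `gfp_psf_sigma` at the same position with peak amplitude
#' `photons_per_unit * true_trace` plus background.  With `noise = TRUE`
#' every pixel's expected value lambda is replaced by
#' `Poisson(lambda) + Normal(0, read_noise_sd)`, clipped to the bit depth
#' and quantised to integers.  With `noise = FALSE` the expected values are
#' returned unquantised (continuous), so that noiseless renders can serve
#' as exact oracles for detection and trace extraction.
#'
#' @param pop A [simulate_population()] result.
#' @param ip An [imaging_params()] object.
#' @param noise Apply Poisson + read noise and quantise?
#' @param seed Seed for the noise stream; defaults to a render substream of
#'   the population seed.
#' @return Numeric (noiseless) or integer (noisy) array with dimensions
#'   `(frame, channel, y, x)`.
#' @export
render_frames <- function(pop, ip = imaging_params(), noise = TRUE,
                          seed = NULL) {
  stopifnot(inherits(pop, "cell_population"),
            inherits(ip, "imaging_params"))
  pp <- pop$params
  nT <- pp$n_frames
  h <- pp$field_height
  w <- pp$field_width
  if (nrow(pop$x) != nT || ncol(pop$traces) != nrow(pop$cells)) {
    stop("invalid input: population frame/cell dimensions are inconsistent",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- stage_seed(pp$seed, "render")
  vmax <- 2^ip$bit_depth - 1

  stack <- if (noise) {
    array(0L, dim = c(nT, 2, h, w))
  } else {
    array(0, dim = c(nT, 2, h, w))
  }
  set.seed(seed)
  sig <- pop$cells$nucleus_sigma
  amp <- pop$cells$rfp_amplitude
  psf <- rep(ip$gfp_psf_sigma, nrow(pop$cells))
  for (f in seq_len(nT)) {
    rfp <- render_gaussians_cpp(h, w, pop$x[f, ], pop$y[f, ], sig, sig,
                                amp) + ip$background
    gfp <- render_gaussians_cpp(h, w, pop$x[f, ], pop$y[f, ], psf, psf,
                                ip$photons_per_unit * pop$traces[f, ]) +
      ip$background
    if (noise) {
      rfp <- stats::rpois(length(rfp), rfp) +
        stats::rnorm(length(rfp), 0, ip$read_noise_sd)
      gfp <- stats::rpois(length(gfp), gfp) +
        stats::rnorm(length(gfp), 0, ip$read_noise_sd)
      rfp <- matrix(as.integer(pmin(pmax(round(rfp), 0), vmax)), h, w)
      gfp <- matrix(as.integer(pmin(pmax(round(gfp), 0), vmax)), h, w)
    }
    stack[f, ip$rfp_channel, , ] <- rfp
    stack[f, ip$gfp_channel, , ] <- gfp
  }
  stack
}

#' Cytometry-like intensity snapshot of a population
#'
#' Emulates a flow-cytometry readout at one frame: each cell's true trace
#' value scaled to photon counts, on top of an optional autofluorescence
#' baseline, with multiplicative lognormal cell-size noise
#' (`exp(N(0, sigma^2))`, median 1).
#'
#' @param pop A [simulate_population()] result.
#' @param frame_index Frame to sample (1-based).
#' @param ip An [imaging_params()] (only `photons_per_unit` is used).
#' @param sigma Lognormal cell-size noise parameter.
#' @param baseline Additive autofluorescence baseline (counts) applied
#'   before the multiplicative noise.
#' @param seed Seed for the noise stream; defaults to a snapshot substream
#'   of the population seed.
#' @return Data frame with columns `cell_id`, `intensity`.
#' @export
snapshot_cytometry <- function(pop, frame_index, ip = imaging_params(),
                               sigma = 0.25, baseline = 0, seed = NULL) {
  stopifnot(inherits(pop, "cell_population"))
  if (frame_index < 1 || frame_index > pop$params$n_frames) {
    stop("invalid input: frame_index out of range", call. = FALSE)
  }
  if (is.null(seed)) seed <- stage_seed(pop$params$seed, "snapshot")
  n <- nrow(pop$cells)
  set.seed(seed)
  fac <- if (sigma > 0) exp(stats::rnorm(n, 0, sigma)) else rep(1, n)
  data.frame(
    cell_id = pop$cells$cell_id,
    intensity = (baseline + ip$photons_per_unit *
                   pop$traces[frame_index, ]) * fac)
}

#' Simulate a well-level screening experiment
#'
#' Emulates a plate-based screen read at one time point: `n_wells`
#' replicate stimulated wells (default responder map) and `n_wells`
#' unstimulated control wells (no induction), each an independent
#' population.  The well readout is the confluency-corrected field
#' intensity — mean per-cell intensity including the imaging background —
#' multiplied by a lognormal well-to-well technical factor of coefficient
#' of variation `well_cv`.
#'
#' @param pp A [population_params()]; each well uses a seed derived from
#'   `pp$seed` and the well index.
#' @param ip An [imaging_params()]; its `background` is the per-cell
#'   autofluorescence baseline.
#' @param frame_index Frame at which wells are read (default: last frame,
#'   i.e. 24 h under the default cadence).
#' @param n_wells Replicate wells per condition.
#' @param well_cv Lognormal well-to-well technical variation.
#' @param sigma Per-cell lognormal size-noise parameter.
#' @param rp_map Responder map for stimulated wells.
#' @return Data frame with columns `well`, `condition`
#'   (`"stimulated"`/`"unstimulated"`), `value` (well mean intensity).
#' @export
simulate_screen <- function(pp, ip = imaging_params(), frame_index = NULL,
                            n_wells = 8, well_cv = 0.04, sigma = 0.25,
                            rp_map = default_responder_map()) {
  stopifnot(inherits(pp, "population_params"))
  if (is.null(frame_index)) frame_index <- pp$n_frames
  unstim_map <- rp_map
  unstim_map$early <- rp_map$non
  unstim_map$late <- rp_map$non
  out <- list()
  for (cond in c("stimulated", "unstimulated")) {
    m <- if (cond == "stimulated") rp_map else unstim_map
    for (wl in seq_len(n_wells)) {
      wseed <- stage_seed(pp$seed, "screen") +
        wl * 131L + (cond == "unstimulated") * 7919L
      pw <- pp
      pw$seed <- wseed %% .Machine$integer.max
      popw <- simulate_population(pw, m)
      snap <- snapshot_cytometry(popw, frame_index, ip, sigma = sigma,
                                 baseline = ip$background,
                                 seed = pw$seed + 1L)
      set.seed(pw$seed + 2L)
      wfac <- exp(stats::rnorm(1, 0, sqrt(log(1 + well_cv^2))))
      out[[length(out) + 1L]] <- data.frame(
        well = wl, condition = cond,
        value = mean(snap$intensity) * wfac)
    }
  }
  do.call(rbind, out)
}
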