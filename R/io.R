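#' Deterministic per-stage seed substreams
#'
#' All randomness in a run flows from one configuration seed through named
#' substreams, so any stage can be re-run reproducibly in isolation.
#'
#' @param seed Base integer seed.
#' @param stage Stage name.
#' @return Integer seed for the stage.
#' @export
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, render = 211L, track = 307L, traces = 401L,
            cluster = 503L, metrics = 601L, screen = 701L, snapshot = 809L)
  if (!stage %in% names(offs)) {
    stop("invalid input: unknown stage '", stage, "'", call. = FALSE)
  }
  as.integer((as.numeric(seed) * 31 + offs[[stage]]) %% 2147483647)
}

#' Read / write multi-page TIFF image stacks
#'
#' Stacks are stored as 16-bit multi-page TIFF with pages in frame-major,
#' channel-minor order; in R they are arrays with dimensions
#' `(frame, channel, y, x)`.  `read_stack(write_stack(x))` is bit-exact
#' for 16-bit integer data.  8-bit files are upcast to the 16-bit range
#' with a warning.
#'
#' @param stack Integer/numeric array `(frame, channel, y, x)` with values
#'   in `[0, 65535]`.
#' @param path File path.
#' @param channels Number of channels interleaved per frame in the file.
#' @return `read_stack`: an integer array `(frame, channel, y, x)`.
#'   `write_stack`: the path, invisibly.
#' @export
write_stack <- function(stack, path, channels = dim(stack)[2]) {
  if (length(dim(stack)) != 4L) {
    stop("format error: stack must be a 4D (frame, channel, y, x) array",
         call. = FALSE)
  }
  nT <- dim(stack)[1]
  nC <- dim(stack)[2]
  pages <- vector("list", nT * nC)
  k <- 1L
  for (f in seq_len(nT)) {
    for (ch in seq_len(nC)) {
      m <- matrix(as.numeric(stack[f, ch, , ]), dim(stack)[3],
                  dim(stack)[4])
      pages[[k]] <- pmin(pmax(m, 0), 65535) / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, channels = 2) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      stop("format error: cannot read TIFF stack: ",
           conditionMessage(e), call. = FALSE)
    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% channels != 0L) {
    stop("format error: page count is not a multiple of the channel count",
         call. = FALSE)
  }
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    stop("format error: expected single-sample (grayscale) pages",
         call. = FALSE)
  }
  mx <- max(vapply(pages, max, numeric(1)))
  if (mx <= 255) {
    warning("8-bit TIFF input; upcasting to the 16-bit range")
    pages <- lapply(pages, function(m) m * 257L)
  }
  nT <- length(pages) %/% channels
  h <- nrow(pages[[1]])
  w <- ncol(pages[[1]])
  stack <- array(0L, dim = c(nT, channels, h, w))
  k <- 1L
  for (f in seq_len(nT)) {
    for (ch in seq_len(channels)) {
      stack[f, ch, , ] <- as.integer(pages[[k]])
      k <- k + 1L
    }
  }
  stack
}

# configuration schema: known keys per section
config_schema <- function() {
  list(
    population = names(formals(population_params)),
    imaging = names(formals(imaging_params)),
    reporter = names(formals(population_reporter)),
    tracking = c("pos_sd", "logshape_sd", "logint_sd", "gate",
                 "min_amplitude", "min_separation", "init_sigma",
                 "max_gap", "min_completeness", "match_radius",
                 "write_masks"),
    analysis = c("k", "linkage_method", "onset_threshold", "sustain",
                 "noise_floor", "smooth_k"),
    metrics = c("n_wells", "well_cv", "snapshot_sigma",
                "positivity_quantile"),
    seed = NULL, output_dir = NULL)
}

#' Build and validate a run configuration
#'
#' A run configuration collects every tunable of the pipeline in one
#' JSON-serialisable list.  Unknown keys are rejected; omitted keys take
#' the package defaults.  Configurations round-trip losslessly through
#' [write_config()] / [read_config()].
#'
#' @param population,imaging,reporter,tracking,analysis,metrics Named
#'   lists overriding defaults of the respective stage.
#' @param seed Base seed for all stage substreams.
#' @param output_dir Directory for pipeline outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(population = list(), imaging = list(),
                       reporter = list(), tracking = list(),
                       analysis = list(), metrics = list(), seed = 7,
                       output_dir = tempfile("smadtrace_run_")) {
  cfg <- list(population = population, imaging = imaging,
              reporter = reporter, tracking = tracking,
              analysis = analysis, metrics = metrics, seed = seed,
              output_dir = output_dir)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  schema <- config_schema()
  extra <- setdiff(names(cfg), names(schema))
  if (length(extra) > 0) {
    stop("invalid config: unknown key(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(schema)) {
    if (is.null(schema[[sec]]) || is.null(cfg[[sec]])) next
    extra <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(extra) > 0) {
      stop("invalid config: unknown key(s) in ", sec, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (sec in c("population", "imaging", "reporter", "tracking",
                "analysis", "metrics")) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- list()
    cfg[[sec]] <- as.list(cfg[[sec]])
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

cfg_get <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (`simulate`, `render`, `track`,
#' `traces`, `cluster`, `metrics`); the stage list must be contiguous in
#' that order.  Every stage reads only the declared outputs of earlier
#' stages from `output_dir` (recomputing nothing upstream) and writes its
#' own files there; a missing upstream file raises a dependency error
#' naming the stage.  Identical configuration and seed produce
#' bit-identical outputs.
#'
#' @param cfg A [run_config()].
#' @param stages Character vector of stages to run.
#' @return Manifest data frame (`file`, `md5`) of every file produced.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "render", "track",
                                         "traces", "cluster", "metrics")) {
  validate_config(cfg)
  order_all <- c("simulate", "render", "track", "traces", "cluster",
                 "metrics")
  stages <- unique(stages)
  if (!all(stages %in% order_all)) {
    stop("invalid input: unknown stage(s)", call. = FALSE)
  }
  idx <- sort(match(stages, order_all))
  if (length(idx) == 0L || !all(diff(idx) == 1L)) {
    stop("invalid input: stages must form a contiguous run of ",
         paste(order_all, collapse = " -> "), call. = FALSE)
  }
  stages <- order_all[idx]
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  pop_over <- cfg$population[setdiff(names(cfg$population), "seed")]
  pp <- do.call(population_params,
                c(pop_over, list(seed = stage_seed(cfg$seed, "simulate"))))
  ip <- do.call(imaging_params, cfg$imaging)
  rp_map <- default_responder_map(do.call(population_reporter,
                                          cfg$reporter))
  produced <- character(0)
  log_stage <- function(stage, t0) {
    message(sprintf("[%s] stage=%s elapsed=%.1fs seed=%d",
                    format(Sys.time(), "%H:%M:%S"), stage,
                    proc.time()[3] - t0, cfg$seed))
  }
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("dependency error: stage '", stage, "' needs missing input ",
           basename(path), call. = FALSE)
    }
    path
  }

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    pop <- simulate_population(pp, rp_map)
    gt <- data.frame(
      cell_id = rep(pop$cells$cell_id, each = pp$n_frames),
      frame = rep(seq_len(pp$n_frames), nrow(pop$cells)),
      t_min = rep(pop$t, nrow(pop$cells)),
      x = as.vector(pop$x), y = as.vector(pop$y),
      responder_class = rep(pop$cells$responder_class,
                            each = pp$n_frames),
      onset_delay = rep(pop$cells$onset_delay, each = pp$n_frames),
      true_trace = as.vector(pop$traces))
    utils::write.csv(gt, file.path(out, "ground_truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(population = pp[setdiff(names(pp), "")],
           cells = pop$cells),
      file.path(out, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    produced <- c(produced, "ground_truth.csv", "ground_truth.json")
    log_stage("simulate", t0)
  }

  if ("render" %in% stages) {
    t0 <- proc.time()[3]
    if (!exists("pop", inherits = FALSE)) {
      need(file.path(out, "ground_truth.csv"), "render")
      pop <- simulate_population(pp, rp_map)  # deterministic re-derivation
    }
    stack <- render_frames(pop, ip, noise = TRUE,
                           seed = stage_seed(cfg$seed, "render"))
    write_stack(stack, file.path(out, "stack.tiff"))
    produced <- c(produced, "stack.tiff")
    log_stage("render", t0)
  }

  priors <- link_priors(
    pos_sd = cfg_get(cfg, "tracking", "pos_sd", 2),
    logshape_sd = cfg_get(cfg, "tracking", "logshape_sd", 0.2),
    logint_sd = cfg_get(cfg, "tracking", "logint_sd", 0.3),
    gate = cfg_get(cfg, "tracking", "gate", 9))

  if ("track" %in% stages) {
    t0 <- proc.time()[3]
    stack <- read_stack(need(file.path(out, "stack.tiff"), "track"),
                        channels = 2)
    det <- detect_stack(
      stack, channel = ip$rfp_channel,
      min_amplitude = cfg_get(cfg, "tracking", "min_amplitude", 50),
      min_separation = cfg_get(cfg, "tracking", "min_separation", 6),
      init_sigma = cfg_get(cfg, "tracking", "init_sigma", 3))
    ts <- build_tracks(
      det, priors,
      max_gap = cfg_get(cfg, "tracking", "max_gap", 10),
      min_completeness = cfg_get(cfg, "tracking", "min_completeness",
                                 0.8),
      stack = stack, channel = ip$rfp_channel,
      init_sigma = cfg_get(cfg, "tracking", "init_sigma", 3))
    utils::write.csv(det, file.path(out, "detections.csv"),
                     row.names = FALSE)
    utils::write.csv(ts$tracks, file.path(out, "tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(ts$summary, file.path(out, "track_summary.csv"),
                     row.names = FALSE)
    produced <- c(produced, "detections.csv", "tracks.csv",
                  "track_summary.csv")
    if (isTRUE(cfg_get(cfg, "tracking", "write_masks", FALSE))) {
      write_masks_rle(ts, dim(stack)[3], dim(stack)[4],
                      file.path(out, "masks.json"))
      produced <- c(produced, "masks.json")
    }
    log_stage("track", t0)
  }

  if ("traces" %in% stages) {
    t0 <- proc.time()[3]
    if (!exists("stack", inherits = FALSE)) {
      stack <- read_stack(need(file.path(out, "stack.tiff"), "traces"),
                          channels = 2)
    }
    trk <- utils::read.csv(need(file.path(out, "tracks.csv"), "traces"))
    tr <- extract_traces(trk, stack, gfp_channel = ip$gfp_channel,
                         frame_interval = pp$frame_interval)
    long <- data.frame(
      cell_id = rep(tr$cell_id, each = length(tr$t)),
      frame = rep(seq_along(tr$t), length(tr$cell_id)),
      t_min = rep(tr$t, length(tr$cell_id)),
      raw = as.vector(t(tr$raw)), norm = as.vector(t(tr$norm)))
    utils::write.csv(long, file.path(out, "traces.csv"),
                     row.names = FALSE)
    produced <- c(produced, "traces.csv")
    log_stage("traces", t0)
  }

  if ("cluster" %in% stages) {
    t0 <- proc.time()[3]
    if (!exists("tr", inherits = FALSE)) {
      long <- utils::read.csv(need(file.path(out, "traces.csv"),
                                   "cluster"))
      ids <- sort(unique(long$cell_id))
      nT <- max(long$frame)
      raw <- matrix(long$raw[order(match(long$cell_id, ids),
                                   long$frame)],
                    nrow = length(ids), byrow = TRUE)
      tr <- structure(list(t = sort(unique(long$t_min)), cell_id = ids,
                           raw = raw, norm = normalise_traces(raw)),
                      class = "trace_set")
    }
    cl <- cluster_traces(
      tr$norm, k = cfg_get(cfg, "analysis", "k", 3),
      linkage_method = cfg_get(cfg, "analysis", "linkage_method",
                               "average"))
    feats <- classify_responders(
      tr, cl,
      noise_floor = cfg_get(cfg, "analysis", "noise_floor", NULL),
      threshold = cfg_get(cfg, "analysis", "onset_threshold", 0.5),
      sustain = cfg_get(cfg, "analysis", "sustain", 2),
      smooth_k = cfg_get(cfg, "analysis", "smooth_k", 9))
    hm <- heatmap_matrix(tr, features = feats, sort_by = "onset")
    utils::write.csv(feats, file.path(out, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(cell_id = tr$cell_id,
                                cluster = cl$labels),
                     file.path(out, "clusters.csv"), row.names = FALSE)
    utils::write.csv(hm$matrix, file.path(out, "heatmap.csv"),
                     row.names = TRUE)
    produced <- c(produced, "features.csv", "clusters.csv",
                  "heatmap.csv")
    log_stage("cluster", t0)
  }

  if ("metrics" %in% stages) {
    t0 <- proc.time()[3]
    screen <- simulate_screen(
      pp, ip,
      n_wells = cfg_get(cfg, "metrics", "n_wells", 8),
      well_cv = cfg_get(cfg, "metrics", "well_cv", 0.04),
      sigma = cfg_get(cfg, "metrics", "snapshot_sigma", 0.25),
      rp_map = rp_map)
    zs <- z_prime(screen$value[screen$condition == "stimulated"],
                  screen$value[screen$condition == "unstimulated"])
    jsonlite::write_json(unclass(zs), file.path(out, "screen_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(screen, file.path(out, "screen_wells.csv"),
                     row.names = FALSE)
    produced <- c(produced, "screen_stats.json", "screen_wells.csv")
    log_stage("metrics", t0)
  }

  files <- file.path(out, produced)
  manifest <- data.frame(file = produced,
                         md5 = unname(tools::md5sum(files)))
  manifest
}

#' Write detection masks as run-length-encoded JSON
#'
#' @param track_set A [build_tracks()] result.
#' @param h,w Field dimensions (px).
#' @param path Output JSON path.
#' @param mask_scale Ellipse half-axes in units of sigma.
#' @return The path, invisibly.
#' @export
write_masks_rle <- function(track_set, h, w, path, mask_scale = 2) {
  trk <- track_set$tracks
  rle_one <- function(x, y, sx, sy) {
    cmin <- max(1L, floor(x - mask_scale * sx))
    cmax <- min(w, ceiling(x + mask_scale * sx))
    runs <- list()
    for (cc in cmin:cmax) {
      u <- (cc - x) / (mask_scale * sx)
      if (abs(u) > 1) next
      half <- mask_scale * sy * sqrt(1 - u^2)
      r0 <- max(1L, ceiling(y - half))
      r1 <- min(h, floor(y + half))
      if (r0 > r1) next
      runs[[length(runs) + 1L]] <- c(cc, r0, r1 - r0 + 1L)
    }
    runs
  }
  masks <- lapply(seq_len(nrow(trk)), function(i) {
    list(track_id = trk$track_id[i], frame = trk$frame[i],
         runs = rle_one(trk$x[i], trk$y[i], trk$sx[i], trk$sy[i]))
  })
  jsonlite::write_json(masks, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
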