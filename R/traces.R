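#' Extract per-cell reporter traces through nuclear masks
#'
#' For every track and frame, the reporter intensity is read through the
#' track's elliptical nuclear mask (half-axes `mask_scale * sigma`): the
#' mean pixel value over the mask minus the frame background (the median
#' of all pixels outside every mask).  The ellipse axes use each track's
#' median fitted sigma and the ellipse is centred on the pixel grid
#' (rounded center), so the mask pixel set has a constant shape along a
#' track and the photometry is free of sub-pixel discretisation wobble.
#' Frames inside a track's span without a detection (gap frames) are
#' filled by linear interpolation; frames outside the span carry the
#' nearest observed value.
#'
#' @param track_set A [build_tracks()] result (or a compatible long data
#'   frame with columns `track_id`, `frame`, `x`, `y`, `sx`, `sy`).
#' @param stack Image stack `(frame, channel, y, x)`.
#' @param gfp_channel Reporter channel index.
#' @param frame_interval Minutes per frame (for the time axis).
#' @param mask_scale Ellipse half-axes in units of sigma.
#' @param background Optional fixed background per frame; when `NULL`,
#'   estimated per frame from mask-free pixels.
#' @return An object of class `trace_set`: list with `t` (time, min),
#'   `cell_id` (track ids), `raw` and `norm` (traces x frames matrices).
#'   `norm` is the per-trace min-max normalisation; a constant trace
#'   normalises to all zeros.
#' @export
extract_traces <- function(track_set, stack, gfp_channel = 2,
                           frame_interval = 3, mask_scale = 2,
                           background = NULL) {
  trk <- if (inherits(track_set, "track_set")) track_set$tracks else
    track_set
  nT <- dim(stack)[1]
  h <- dim(stack)[3]
  w <- dim(stack)[4]
  if (nrow(trk) > 0 && max(trk$frame) > nT) {
    stop("invalid input: tracks reference frames beyond the stack",
         call. = FALSE)
  }
  ids <- sort(unique(trk$track_id))
  n <- length(ids)
  raw <- matrix(NA_real_, nrow = n, ncol = nT)
  if (n == 0L) {
    return(structure(list(t = (seq_len(nT) - 1) * frame_interval,
                          cell_id = integer(0), raw = raw[0, , drop = FALSE],
                          norm = raw[0, , drop = FALSE]),
                     class = "trace_set"))
  }
  med_sx <- vapply(split(trk$sx, trk$track_id), stats::median, numeric(1))
  med_sy <- vapply(split(trk$sy, trk$track_id), stats::median, numeric(1))
  row_of <- match(trk$track_id, ids)

  zero_masks <- 0L
  for (f in seq_len(nT)) {
    sel <- which(trk$frame == f)
    img <- matrix(as.numeric(stack[f, gfp_channel, , ]), h, w)
    if (length(sel) == 0L) next
    ph <- mask_photometry_cpp(img, round(trk$x[sel]), round(trk$y[sel]),
                              med_sx[row_of[sel]], med_sy[row_of[sel]],
                              scale = mask_scale)
    bg <- if (is.null(background)) {
      stats::median(img[!ph$mask])
    } else {
      background
    }
    zero_masks <- zero_masks + sum(ph$count == 0)
    val <- ph$sum / ph$count - bg
    val[ph$count == 0] <- NA_real_
    raw[cbind(row_of[sel], f)] <- val
  }
  if (zero_masks > 0L) {
    warning(sprintf("%d mask(s) had zero pixels inside the field; skipped",
                    zero_masks))
  }

  # fill gaps: linear interpolation inside the span, nearest value outside
  for (i in seq_len(n)) {
    v <- raw[i, ]
    obs <- which(!is.na(v))
    if (length(obs) == 0L) { raw[i, ] <- 0; next }
    if (length(obs) == 1L) { raw[i, ] <- v[obs]; next }
    if (anyNA(v)) {
      raw[i, ] <- stats::approx(obs, v[obs], xout = seq_len(nT),
                                rule = 2)$y
    }
  }
  structure(list(t = (seq_len(nT) - 1) * frame_interval,
                 cell_id = ids, raw = raw, norm = normalise_traces(raw)),
            class = "trace_set")
}

#' Min-max normalise trace rows to \[0, 1\]
#'
#' @param raw Traces x frames matrix.
#' @return Matrix of the same shape; constant rows map to all zeros
#'   (idempotent: normalising a normalised matrix changes nothing).
#' @export
normalise_traces <- function(raw) {
  rng <- apply(raw, 1, range)
  span <- rng[2, ] - rng[1, ]
  out <- (raw - rng[1, ]) / ifelse(span == 0, 1, span)
  out[span == 0, ] <- 0
  out
}

#' Hierarchical clustering of normalised traces
#'
#' Agglomerative clustering of whole normalised traces under Euclidean
#' distance; flat labels by cutting the tree at `k` clusters.
#' Deterministic: [stats::hclust()] breaks merge ties by lowest row index.
#'
#' @param norm_matrix Cells x frames matrix without missing values.
#' @param k Number of flat clusters (1 <= k <= number of cells).
#' @param linkage_method Linkage criterion (default `"average"`; `"ward.D2"`
#'   and `"complete"` are sensible alternatives).
#' @return An object of class `cluster_result`: list with `labels`
#'   (1..k per cell), `heights` (merge heights), `tree` (the `hclust`
#'   object), `k`.
#' @export
cluster_traces <- function(norm_matrix, k = 3,
                           linkage_method = "average") {
  if (anyNA(norm_matrix)) {
    stop("invalid input: traces contain missing values", call. = FALSE)
  }
  n <- nrow(norm_matrix)
  if (k < 1 || k > n) {
    stop("invalid input: need 1 <= k <= number of cells", call. = FALSE)
  }
  tree <- stats::hclust(stats::dist(norm_matrix, method = "euclidean"),
                        method = linkage_method)
  labels <- if (k == 1L) rep(1L, n) else unname(stats::cutree(tree, k = k))
  structure(list(labels = labels, heights = tree$height, tree = tree,
                 k = k), class = "cluster_result")
}

#' Onset time of a normalised trace
#'
#' The earliest time at which the normalised trace stays at or above
#' `threshold` for at least `sustain` consecutive frames; `NA` if it never
#' does.  The sustain requirement guards against single-frame noise
#' spikes.
#'
#' @param norm Normalised trace (vector in \[0, 1\]).
#' @param t Time vector (min), same length.
#' @param threshold Crossing threshold on the normalised scale.
#' @param sustain Required consecutive frames at or above threshold.
#' @return Onset time (min) or `NA`.
#' @export
onset_time <- function(norm, t, threshold = 0.5, sustain = 2) {
  above <- norm >= threshold
  if (sustain > 1) {
    run <- stats::filter(as.numeric(above), rep(1, sustain),
                         sides = 1)
    idx <- which(run == sustain)[1] - sustain + 1L
  } else {
    idx <- which(above)[1]
  }
  if (is.na(idx) || length(idx) == 0L) return(NA_real_)
  t[idx]
}

# centred running mean used for robust range and peak estimates
running_mean <- function(v, k = 9) {
  if (k <= 1 || length(v) < k) return(v)
  sm <- stats::filter(v, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # pad the filter's edge NAs with shrinking windows
  half <- (k - 1) %/% 2
  n <- length(v)
  for (i in seq_len(half)) {
    sm[i] <- mean(v[1:(i + half)])
    sm[n - i + 1] <- mean(v[(n - i + 1 - half):n])
  }
  sm
}

#' Classify traces into early, late and non-responders
#'
#' Non-responders are identified per cell from the signal range: a cell
#' whose dynamic range (max minus min of the 9-frame running mean of the
#' raw trace) does not exceed its noise floor — by default 3x the median
#' frame-to-frame absolute difference of its raw trace — or that never
#' sustains a half-range crossing, is a non-responder.  Remaining cells
#' inherit a class from their cluster: clusters are ranked by the median
#' onset of their responder members, and a cluster is `early` when its
#' median onset lies at or below the midpoint of the extreme clusters'
#' medians, `late` otherwise (for two responder clusters this is simply
#' smaller vs larger median onset).
#'
#' @param traces A [extract_traces()] result (or compatible `trace_set`).
#' @param cluster A [cluster_traces()] result over the same cells.
#' @param noise_floor Either a single value, a per-cell vector, or `NULL`
#'   for the default rule.
#' @param threshold,sustain Passed to [onset_time()].
#' @param smooth_k Running-mean window (frames) for range and peak.
#' @return Data frame with columns `cell_id`, `responder_class`,
#'   `onset_min` (`NA` for non-responders), `peak_min`, `dynamic_range`,
#'   `cluster`; the cluster-to-class map is attached as attribute
#'   `class_map`.
#' @export
classify_responders <- function(traces, cluster, noise_floor = NULL,
                                threshold = 0.5, sustain = 2,
                                smooth_k = 9) {
  raw <- traces$raw
  norm <- traces$norm
  t <- traces$t
  n <- nrow(raw)
  if (length(cluster$labels) != n) {
    stop("invalid input: cluster labels do not match the trace set",
         call. = FALSE)
  }
  smoothed <- t(apply(raw, 1, running_mean, k = smooth_k))
  if (n == 1L) smoothed <- matrix(smoothed, nrow = 1)
  rng <- apply(smoothed, 1, function(v) max(v) - min(v))
  if (is.null(noise_floor)) {
    noise_floor <- 3 * apply(raw, 1, function(v) {
      stats::median(abs(diff(v)))
    })
  }
  floor_vec <- rep_len(noise_floor, n)

  onset <- vapply(seq_len(n), function(i) {
    onset_time(norm[i, ], t, threshold, sustain)
  }, numeric(1))
  responder <- rng > floor_vec & !is.na(onset)

  cls <- rep("non", n)
  class_map <- rep(NA_character_, cluster$k)
  if (any(responder)) {
    med_onset <- vapply(seq_len(cluster$k), function(g) {
      sel <- responder & cluster$labels == g
      if (!any(sel)) return(NA_real_)
      stats::median(onset[sel])
    }, numeric(1))
    have <- which(!is.na(med_onset))
    if (length(have) == 1L) {
      class_map[have] <- "early"
    } else {
      mid <- (min(med_onset[have]) + max(med_onset[have])) / 2
      class_map[have] <- ifelse(med_onset[have] <= mid, "early", "late")
    }
    cls[responder] <- class_map[cluster$labels[responder]]
  } else {
    warning("all cells are non-responders; no responder classes assigned")
  }

  peak <- vapply(seq_len(n), function(i) {
    v <- smoothed[i, ]
    from <- if (!is.na(onset[i]) && responder[i]) {
      which(t >= onset[i])[1]
    } else 1L
    t[from - 1L + which.max(v[from:length(v)])]
  }, numeric(1))

  out <- data.frame(cell_id = traces$cell_id,
                    responder_class = cls,
                    onset_min = ifelse(cls == "non", NA_real_, onset),
                    peak_min = peak,
                    dynamic_range = rng,
                    cluster = cluster$labels)
  attr(out, "class_map") <- class_map
  out
}

#' Histogram of peak times per responder class
#'
#' @param features A [classify_responders()] result.
#' @param bin_width Bin width (min), > 0.
#' @return Data frame with columns `responder_class`, `bin_start`,
#'   `count` (only non-empty bins).
#' @export
peak_time_histogram <- function(features, bin_width = 60) {
  if (bin_width <= 0) {
    stop("invalid input: bin_width must be > 0", call. = FALSE)
  }
  if (nrow(features) == 0L) {
    return(data.frame(responder_class = character(0),
                      bin_start = numeric(0), count = integer(0)))
  }
  bin <- floor(features$peak_min / bin_width) * bin_width
  agg <- stats::aggregate(list(count = bin),
                          by = list(responder_class =
                                      features$responder_class,
                                    bin_start = bin), FUN = length)
  agg <- agg[order(agg$responder_class, agg$bin_start), ]
  rownames(agg) <- NULL
  agg
}

#' Heatmap matrix of normalised traces
#'
#' Rows are cells ordered by the chosen key (ascending onset with
#' non-responders last, or contiguous cluster blocks), columns are frames;
#' values are the already-normalised intensities (no re-scaling).
#'
#' @param traces A `trace_set`.
#' @param features A [classify_responders()] result (required for
#'   `sort_by = "onset"`).
#' @param cluster A [cluster_traces()] result (required for
#'   `sort_by = "cluster"`).
#' @param sort_by Row ordering key.
#' @return List with `matrix` (ordered normalised traces) and `order`
#'   (row order as indices into the trace set, for provenance).
#' @export
heatmap_matrix <- function(traces, features = NULL, cluster = NULL,
                           sort_by = c("onset", "cluster")) {
  sort_by <- match.arg(sort_by)
  ord <- if (sort_by == "onset") {
    stopifnot(!is.null(features))
    order(is.na(features$onset_min), features$onset_min)
  } else {
    stopifnot(!is.null(cluster))
    order(cluster$labels)
  }
  m <- traces$norm[ord, , drop = FALSE]
  rownames(m) <- traces$cell_id[ord]
  list(matrix = m, order = ord)
}

#' Export a cluster tree as Newick text
#'
#' @param cluster A [cluster_traces()] result.
#' @param labels Optional tip labels (defaults to cell ids 1..n).
#' @return A Newick string (also usable with [ape::read.tree()]).
#' @export
cluster_newick <- function(cluster, labels = NULL) {
  tree <- cluster$tree
  if (!is.null(labels)) tree$labels <- as.character(labels)
  ape::write.tree(ape::as.phylo(tree))
}

#' Suggest a cluster count by mean silhouette width
#'
#' Scores each candidate k by the average silhouette over all cells and
#' returns the best-scoring k.  Advisory only: the analysis defaults to
#' k = 3 (early, late, non) and never applies this suggestion
#' automatically.
#'
#' @param norm_matrix Cells x frames matrix of normalised traces.
#' @param k_range Candidate cluster counts.
#' @param linkage_method Passed to [cluster_traces()].
#' @return List with `k` (suggested count) and `scores` (mean silhouette
#'   per candidate).
#' @export
suggest_k <- function(norm_matrix, k_range = 2:6,
                      linkage_method = "average") {
  d <- as.matrix(stats::dist(norm_matrix))
  n <- nrow(d)
  k_range <- k_range[k_range >= 2 & k_range < n]
  scores <- vapply(k_range, function(k) {
    lab <- cluster_traces(norm_matrix, k = k,
                          linkage_method = linkage_method)$labels
    sil <- vapply(seq_len(n), function(i) {
      own <- lab == lab[i]
      a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]), function(g) {
        mean(d[i, lab == g])
      }, numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(sil)
  }, numeric(1))
  list(k = k_range[which.max(scores)],
       scores = stats::setNames(scores, k_range))
}
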