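#' Detect nuclei in a single frame as 2D Gaussians
#'
#' Candidate peaks are local maxima above the frame background (median
#' pixel value) plus `min_amplitude`, suppressed within `min_separation`
#' pixels.  Each candidate is refined by least squares against the model
#' `A * exp(-(dx^2/(2 sx^2) + dy^2/(2 sy^2))) + b` over a window of total
#' width ~6 initial sigma.  Candidates whose fit diverges (non-finite
#' parameters, non-positive amplitude, or center outside the window) are
#' dropped with a warning.  Two mixture refinements follow: a fitted
#' Gaussian whose width is inflated beyond `split_factor * init_sigma`
#' (the signature of two sub-resolution nuclei rendering as one unimodal
#' spot) is re-fitted as two components seeded along the local principal
#' axis, and the split is kept when it clearly reduces the residual; and
#' when the 2-sigma ellipses of two accepted detections intersect, the
#' pair is re-fitted jointly (shared background) to resolve overlap bias.
#'
#' @param img Numeric matrix (a single channel frame; rows = y, cols = x).
#' @param min_amplitude Minimum peak height above background (> 0).
#' @param min_separation Minimum peak separation (px, Chebyshev).
#' @param init_sigma Initial Gaussian width for the fit (px).
#' @param split_factor Width inflation (relative to `init_sigma`) above
#'   which a two-component split is attempted.
#' @param frame Frame index recorded in the output.
#' @return Data frame with columns `frame`, `x`, `y`, `sx`, `sy`,
#'   `amplitude`, `background`, sorted by `x` then `y`.
#' @export
detect_nuclei <- function(img, min_amplitude = 50, min_separation = 4,
                          init_sigma = 3, split_factor = 1.2,
                          frame = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("invalid input: img must be a numeric 2D matrix", call. = FALSE)
  }
  if (min_amplitude <= 0) {
    stop("invalid input: min_amplitude must be > 0", call. = FALSE)
  }
  bg <- stats::median(img)
  peaks <- local_maxima_cpp(img, as.integer(ceiling(min_separation)),
                            bg + min_amplitude)
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      sx = numeric(0), sy = numeric(0),
                      amplitude = numeric(0), background = numeric(0))
  if (nrow(peaks) == 0L) return(empty)

  halfwin <- as.integer(ceiling(3 * init_sigma))
  n_dropped <- 0L
  acc <- matrix(NA_real_, nrow(peaks), 7)  # x y sx sy amp bg rss
  for (i in seq_len(nrow(peaks))) {
    ry <- peaks[i, 1]; cx <- peaks[i, 2]
    fit <- fit_gaussians_cpp(img, ry, cx, halfwin, init_sigma,
                             img[ry, cx] - bg, bg)
    if (!all(is.finite(fit)) || fit[7] != 1 || fit[1] <= 0) {
      n_dropped <- n_dropped + 1L
      next
    }
    if (abs(fit[2] - cx) > halfwin + 1 || abs(fit[3] - ry) > halfwin + 1) {
      # converged onto a neighbour; keep a seed-based moment detection so
      # the nucleus is not lost
      acc[i, ] <- c(cx, ry, init_sigma, init_sigma, img[ry, cx] - bg,
                    bg, fit[8])
      next
    }
    acc[i, ] <- c(fit[2], fit[3], fit[4], fit[5], fit[1], fit[6], fit[8])
  }
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d candidate(s) with divergent Gaussian fits",
                    n_dropped))
  }
  acc <- acc[!is.na(acc[, 1]), , drop = FALSE]
  if (nrow(acc) == 0L) return(empty)
  det <- data.frame(frame = frame, x = acc[, 1], y = acc[, 2],
                    sx = acc[, 3], sy = acc[, 4], amplitude = acc[, 5],
                    background = acc[, 6], rss = acc[, 7])

  det <- split_merged(img, det, init_sigma, split_factor, min_amplitude,
                      frame)
  det$rss <- NULL
  det <- refine_overlaps(img, det, halfwin)
  det <- dedupe_detections(det, min_amplitude)
  det <- det[order(det$x, det$y), , drop = FALSE]
  rownames(det) <- NULL
  det
}

# final cleanup: drop sub-threshold amplitudes and, among detections
# closer than 2 px, keep only the brightest
dedupe_detections <- function(det, min_amplitude) {
  det <- det[det$amplitude >= 0.5 * min_amplitude, , drop = FALSE]
  n <- nrow(det)
  if (n < 2L) return(det)
  d2 <- outer(det$x, det$x, "-")^2 + outer(det$y, det$y, "-")^2
  close <- which(d2 < 4 & upper.tri(d2), arr.ind = TRUE)
  keep <- rep(TRUE, n)
  for (k in seq_len(nrow(close))) {
    i <- close[k, 1]; j <- close[k, 2]
    if (keep[i] && keep[j]) {
      keep[if (det$amplitude[i] >= det$amplitude[j]) j else i] <- FALSE
    }
  }
  det[keep, , drop = FALSE]
}

# Mixture split pass: an accepted Gaussian whose fitted width is inflated
# is re-fitted as two components seeded +- along the principal axis of the
# background-subtracted intensity moments; the split replaces the single
# detection when it clearly reduces the residual.
split_merged <- function(img, det, init_sigma, split_factor,
                         min_amplitude, frame) {
  h <- nrow(img); w <- ncol(img)
  hw <- ceiling(3 * init_sigma)
  cand <- which(pmax(det$sx, det$sy) > split_factor * init_sigma)
  out <- vector("list", length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    r0 <- max(1, round(det$y[i]) - hw); r1 <- min(h, round(det$y[i]) + hw)
    c0 <- max(1, round(det$x[i]) - hw); c1 <- min(w, round(det$x[i]) + hw)
    win <- img[r0:r1, c0:c1, drop = FALSE]
    ys <- row(win) + r0 - 1
    xs <- col(win) + c0 - 1
    wts <- pmax(win - det$background[i], 0)
    # restrict the moments to the detection's own ellipse so neighbouring
    # spots cannot steer the principal axis
    inside <- ((xs - det$x[i]) / (2.5 * det$sx[i]))^2 +
      ((ys - det$y[i]) / (2.5 * det$sy[i]))^2 <= 1
    wts[!inside] <- 0
    if (sum(wts) <= 0) next
    mx <- sum(wts * xs) / sum(wts)
    my <- sum(wts * ys) / sum(wts)
    cxx <- sum(wts * (xs - mx)^2) / sum(wts)
    cyy <- sum(wts * (ys - my)^2) / sum(wts)
    cxy <- sum(wts * (xs - mx) * (ys - my)) / sum(wts)
    eg <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
    off <- min(sqrt(max(eg$values[1] - init_sigma^2, 0.25)), 4)
    v <- eg$vectors[, 1]
    fit <- fit_gaussians_cpp(img,
                             c(my - off * v[2], my + off * v[2]),
                             c(mx - off * v[1], mx + off * v[1]),
                             hw, rep(init_sigma, 2),
                             rep(det$amplitude[i] / 2, 2),
                             det$background[i])
    sep <- sqrt((fit[2] - fit[7])^2 + (fit[3] - fit[8])^2)
    near <- max(abs(c(fit[2], fit[7]) - det$x[i]),
                abs(c(fit[3], fit[8]) - det$y[i]))
    ok <- all(is.finite(fit)) && fit[12] == 1 &&
      fit[13] < 0.6 * det$rss[i] &&
      fit[1] > 0.4 * min_amplitude && fit[6] > 0.4 * min_amplitude &&
      sep >= 1.5 && near <= 2.5 * max(det$sx[i], det$sy[i]) + 1 &&
      all(fit[c(4, 5, 9, 10)] >= 0.5 * init_sigma) &&
      all(fit[c(4, 5, 9, 10)] <= 1.8 * init_sigma)
    if (ok) {
      out[[k]] <- data.frame(
        frame = frame, x = fit[c(2, 7)], y = fit[c(3, 8)],
        sx = fit[c(4, 9)], sy = fit[c(5, 10)],
        amplitude = fit[c(1, 6)], background = fit[11],
        rss = fit[13], row.names = NULL)
    }
  }
  replaced <- cand[!vapply(out, is.null, logical(1))]
  if (length(replaced) > 0) {
    det <- rbind(det[-replaced, , drop = FALSE],
                 do.call(rbind, out[!vapply(out, is.null, logical(1))]))
  }
  det
}

# Joint two-component refit for detections whose 2-sigma ellipses
# intersect.  The refit replaces the pair only when it stays sane: both
# components converge near their seeds with comparable amplitude and
# width, otherwise the single fits are kept.
refine_overlaps <- function(img, det, halfwin) {
  n <- nrow(det)
  if (n < 2L) return(det)
  dx <- outer(det$x, det$x, "-")
  dy <- outer(det$y, det$y, "-")
  rsum <- outer(2 * pmax(det$sx, det$sy), 2 * pmax(det$sx, det$sy), "+")
  close <- which(sqrt(dx^2 + dy^2) < rsum & upper.tri(rsum), arr.ind = TRUE)
  for (k in seq_len(nrow(close))) {
    i <- close[k, 1]; j <- close[k, 2]
    fit <- fit_gaussians_cpp(img, c(det$y[i], det$y[j]),
                             c(det$x[i], det$x[j]), halfwin,
                             c(det$sx[i], det$sx[j]),
                             c(det$amplitude[i], det$amplitude[j]),
                             (det$background[i] + det$background[j]) / 2)
    ok <- all(is.finite(fit)) && fit[12] == 1 &&
      fit[1] > 0.3 * det$amplitude[i] && fit[6] > 0.3 * det$amplitude[j] &&
      abs(fit[2] - det$x[i]) <= 3 && abs(fit[3] - det$y[i]) <= 3 &&
      abs(fit[7] - det$x[j]) <= 3 && abs(fit[8] - det$y[j]) <= 3 &&
      all(fit[c(4, 5, 9, 10)] >= 0.5 * c(det$sx[i], det$sy[i],
                                         det$sx[j], det$sy[j])) &&
      all(fit[c(4, 5, 9, 10)] <= 2 * c(det$sx[i], det$sy[i],
                                       det$sx[j], det$sy[j]))
    if (ok) {
      det[i, c("amplitude", "x", "y", "sx", "sy")] <- fit[1:5]
      det[j, c("amplitude", "x", "y", "sx", "sy")] <- fit[6:10]
      det[c(i, j), "background"] <- fit[11]
    }
  }
  det
}

#' Continuity priors for frame-to-frame linking
#'
#' Gaussian transition priors expressing that a nucleus's position, shape
#' and overall intensity cannot change dramatically between consecutive
#' frames: independent normals on the displacement (SD `pos_sd` per axis),
#' on the log change of each sigma component (SD `logshape_sd`) and on the
#' log change of amplitude (SD `logint_sd`).  `gate` is the maximum
#' admissible link cost (negative log prior up to a constant); the default
#' 9 corresponds to a combined ~3-sigma excursion.
#'
#' @param pos_sd Expected displacement SD (px/frame), > 0.
#' @param logshape_sd SD of the per-frame log change in sigma, > 0.
#' @param logint_sd SD of the per-frame log change in amplitude, > 0.
#' @param gate Maximum link cost, > 0.
#' @return An object of class `link_priors`.
#' @export
link_priors <- function(pos_sd = 2, logshape_sd = 0.2, logint_sd = 0.3,
                        gate = 9) {
  if (pos_sd <= 0 || logshape_sd <= 0 || logint_sd <= 0 || gate <= 0) {
    stop("invalid input: all prior SDs and the gate must be > 0",
         call. = FALSE)
  }
  structure(list(pos_sd = pos_sd, logshape_sd = logshape_sd,
                 logint_sd = logint_sd, gate = gate),
            class = "link_priors")
}

#' Link cost between two detections in consecutive frames
#'
#' The negative log of the product of the transition priors (constant terms
#' dropped):
#' `||dcenter||^2/(2 pos_sd^2) + sum(log(s2/s1)^2)/(2 logshape_sd^2) +
#'  log(A2/A1)^2/(2 logint_sd^2)`.
#'
#' @param d1,d2 Single detections (one-row data frames as produced by
#'   [detect_nuclei()]); `d2` must be one frame after `d1`.
#' @param priors A [link_priors()] object.
#' @param gap_scale Multiplies `pos_sd` (used for gap closing, where the
#'   expected displacement grows with the square root of the frame gap).
#' @return Non-negative scalar cost.
#' @export
link_cost <- function(d1, d2, priors, gap_scale = 1) {
  if (d2$frame != d1$frame + 1) {
    stop("invalid input: detections must be in consecutive frames",
         call. = FALSE)
  }
  pos_sd <- priors$pos_sd * gap_scale
  ((d2$x - d1$x)^2 + (d2$y - d1$y)^2) / (2 * pos_sd^2) +
    (log(d2$sx / d1$sx)^2 + log(d2$sy / d1$sy)^2) /
      (2 * priors$logshape_sd^2) +
    log(d2$amplitude / d1$amplitude)^2 / (2 * priors$logint_sd^2)
}

# vectorised cost matrix between two detection tables; gap_scale may be a
# per-row vector (one value per row of a)
link_cost_matrix <- function(a, b, priors, gap_scale = 1) {
  pos_sd <- priors$pos_sd * gap_scale
  pos <- (outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2) /
    (2 * pos_sd^2)
  shp <- (outer(log(a$sx), log(b$sx), "-")^2 +
            outer(log(a$sy), log(b$sy), "-")^2) / (2 * priors$logshape_sd^2)
  int <- outer(log(a$amplitude), log(b$amplitude), "-")^2 /
    (2 * priors$logint_sd^2)
  pos + shp + int
}

# Hungarian algorithm (shortest augmenting path with potentials) for a
# square cost matrix of finite costs; returns the column assigned to each
# row.  O(n^3).
hungarian_square <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)[!used[seq_len(n) + 1]]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) {
          minv[j + 1] <- cur
          way[j + 1] <- j0
        }
        if (minv[j + 1] < delta) {
          delta <- minv[j + 1]
          j1 <- j + 1L
        }
      }
      for (j in 0:n) {
        jj <- j + 1L
        if (used[jj]) {
          u[p[jj] + 1] <- u[p[jj] + 1] + delta
          v[jj] <- v[jj] - delta
        } else {
          minv[jj] <- minv[jj] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) assign[p[j + 1]] <- j
  assign
}

# Gated rectangular assignment: minimise the sum of matched pair costs plus
# `gate` for every unmatched detection on either side.  Pairs with cost >
# gate are inadmissible.  Solved exactly via the standard dummy-augmented
# square LAP, decomposed over connected components of the gated bipartite
# graph.
solve_gated_assignment <- function(cost, gate) {
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  pairs <- matrix(integer(0), ncol = 2)
  if (n1 > 0 && n2 > 0) {
    adm <- which(cost <= gate, arr.ind = TRUE)
    if (nrow(adm) > 0) {
      # connected components over the admissible edges
      comp_r <- integer(n1)
      comp_c <- integer(n2)
      ncomp <- 0L
      for (s in seq_len(n1)) {
        if (comp_r[s] != 0L) next
        ncomp <- ncomp + 1L
        qr <- s
        qc <- integer(0)
        comp_r[s] <- ncomp
        while (length(qr) > 0 || length(qc) > 0) {
          if (length(qr) > 0) {
            r <- qr[1]; qr <- qr[-1]
            nb <- adm[adm[, 1] == r, 2]
            nb <- nb[comp_c[nb] == 0L]
            comp_c[nb] <- ncomp
            qc <- c(qc, nb)
          } else {
            cc <- qc[1]; qc <- qc[-1]
            nb <- adm[adm[, 2] == cc, 1]
            nb <- nb[comp_r[nb] == 0L]
            comp_r[nb] <- ncomp
            qr <- c(qr, nb)
          }
        }
      }
      for (k in seq_len(ncomp)) {
        ri <- which(comp_r == k)
        ci <- which(comp_c == k)
        if (length(ri) == 1L && length(ci) == 1L) {
          pairs <- rbind(pairs, c(ri, ci))
          next
        }
        sub <- cost[ri, ci, drop = FALSE]
        m1 <- length(ri); m2 <- length(ci)
        big <- sum(sub[sub <= gate]) + gate * (m1 + m2) + 1
        sq <- matrix(big, m1 + m2, m2 + m1)
        blk <- sub
        blk[blk > gate] <- big
        sq[seq_len(m1), seq_len(m2)] <- blk
        sq[cbind(seq_len(m1), m2 + seq_len(m1))] <- gate
        sq[cbind(m1 + seq_len(m2), seq_len(m2))] <- gate
        sq[m1 + seq_len(m2), m2 + seq_len(m1)] <- 0
        a <- hungarian_square(sq)
        for (r in seq_len(m1)) {
          if (a[r] <= m2 && sub[r, a[r]] <= gate) {
            pairs <- rbind(pairs, c(ri[r], ci[a[r]]))
          }
        }
      }
    }
  }
  list(pairs = pairs,
       unmatched_1 = setdiff(seq_len(n1), pairs[, 1]),
       unmatched_2 = setdiff(seq_len(n2), pairs[, 2]))
}

#' Optimal frame-to-frame assignment of detections
#'
#' Maximum-a-posteriori linking: the total objective is the sum of link
#' costs of matched pairs plus `gate` for every unmatched detection, the
#' standard gated linear-assignment formulation; pairs with cost above the
#' gate are inadmissible.  Solved exactly (Hungarian algorithm on the
#' dummy-augmented cost matrix), so for small frames it coincides with
#' exhaustive search over all gated matchings.
#'
#' @param dets_t,dets_t1 Detection tables from consecutive frames.
#' @param priors A [link_priors()].
#' @return List with `pairs` (data frame: `i`, `j`, `cost` — row indices
#'   into `dets_t` and `dets_t1`), `unmatched_t`, `unmatched_t1`.
#' @export
link_frames <- function(dets_t, dets_t1, priors) {
  if (nrow(dets_t) > 0 && nrow(dets_t1) > 0 &&
      any(dets_t1$frame != dets_t$frame[1] + 1)) {
    stop("invalid input: detections must come from consecutive frames",
         call. = FALSE)
  }
  cost <- link_cost_matrix(dets_t, dets_t1, priors)
  sol <- solve_gated_assignment(cost, priors$gate)
  pairs <- data.frame(i = sol$pairs[, 1], j = sol$pairs[, 2],
                      cost = cost[sol$pairs])
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched_t = sol$unmatched_1,
       unmatched_t1 = sol$unmatched_2)
}

#' Build tracks by chaining frame-to-frame assignments
#'
#' Frames are processed in order; open tracks compete for the detections of
#' each frame through the gated assignment of [link_frames()].  A track
#' whose last detection is `g` frames back (`g <= max_gap`) may still
#' claim a detection, with `pos_sd` scaled by `sqrt(g)`; unclaimed
#' detections found new tracks.  Tracks whose completeness — detections
#' per movie frame, where the movie spans the full frame range of the
#' input — falls below `min_completeness` are discarded; the default 0.8
#' is also what "successfully tracked" means in [tracking_fraction()].
#'
#' When the image stack is supplied, each Gaussian is additionally
#' forwarded from frame to frame: an open track left without a detection
#' re-fits its Gaussian on the new frame seeded at its last position, and
#' the guided fit is adopted as a recovered detection when it stays within
#' the link gate.  This keeps tracks alive through close encounters in
#' which two nuclei blend into a single unresolvable spot.
#'
#' @param detections Data frame of all detections (columns as produced by
#'   [detect_nuclei()], with `frame` filled in).
#' @param priors A [link_priors()].
#' @param max_gap Maximum admissible frame difference when re-joining a
#'   track (so up to `max_gap - 1` consecutive missing frames); the
#'   default bridges short sub-resolution encounters between nuclei.
#' @param min_completeness Minimum fraction of spanned frames with a
#'   detection.
#' @param stack Optional image stack `(frame, channel, y, x)` enabling
#'   guided Gaussian forwarding for unmatched tracks.
#' @param channel Nuclear-marker channel of `stack`.
#' @param init_sigma Seed width for guided re-fits (px).
#' @return An object of class `track_set`: list with `tracks` (long data
#'   frame: `track_id`, `frame`, `x`, `y`, `sx`, `sy`, `amplitude`,
#'   `background`, `recovered`) and `summary` (per track: `track_id`,
#'   `start_frame`, `end_frame`, `n_detections`, `completeness`).
#' @export
build_tracks <- function(detections, priors = link_priors(), max_gap = 10,
                         min_completeness = 0.8, stack = NULL,
                         channel = 1, init_sigma = 3) {
  empty <- structure(
    list(tracks = cbind(track_id = integer(0), detections[0, ],
                        recovered = logical(0)),
         summary = data.frame(track_id = integer(0),
                              start_frame = integer(0),
                              end_frame = integer(0),
                              n_detections = integer(0),
                              completeness = numeric(0))),
    class = "track_set")
  if (nrow(detections) == 0L) return(empty)
  det_frames <- sort(unique(detections$frame))
  frames <- if (is.null(stack)) det_frames else
    seq(det_frames[1], max(det_frames))
  by_frame <- split(detections, detections$frame)
  # guided re-fits use a tight window so neighbouring nuclei cannot
  # capture the fit
  hw <- as.integer(ceiling(2 * init_sigma))

  # Open-track state.  Positions always follow the latest fit; the
  # reference amplitude and shape are slow exponential averages over real
  # (non-recovered) detections only, so a track keeps its identity cues
  # while it sits on a blended two-nucleus spot.
  last_frame <- integer(0)
  last_x <- last_y <- last_sx <- last_sy <- last_amp <- last_bg <- numeric(0)
  ref_amp <- ref_sx <- ref_sy <- numeric(0)
  out <- list()
  add_rows <- function(ids, f, d, rec) {
    out[[length(out) + 1L]] <<- data.frame(
      track_id = ids, frame = f, x = d$x, y = d$y, sx = d$sx, sy = d$sy,
      amplitude = d$amplitude, background = d$background, recovered = rec)
  }
  register <- function(ids, f, d, rec = FALSE) {
    last_frame[ids] <<- f
    last_x[ids] <<- d$x; last_y[ids] <<- d$y
    last_sx[ids] <<- d$sx; last_sy[ids] <<- d$sy
    last_amp[ids] <<- d$amplitude; last_bg[ids] <<- d$background
    if (!rec) {
      new <- is.na(ref_amp[ids])
      ref_amp[ids] <<- ifelse(new, d$amplitude,
                              0.9 * ref_amp[ids] + 0.1 * d$amplitude)
      ref_sx[ids] <<- ifelse(new, d$sx, 0.9 * ref_sx[ids] + 0.1 * d$sx)
      ref_sy[ids] <<- ifelse(new, d$sy, 0.9 * ref_sy[ids] + 0.1 * d$sy)
    }
  }

  first <- by_frame[[as.character(frames[1])]]
  n_tracks <- nrow(first)
  ref_amp <- rep(NA_real_, n_tracks)
  ref_sx <- ref_sy <- rep(NA_real_, n_tracks)
  consec_rec <- rep(0L, n_tracks)
  register(seq_len(n_tracks), frames[1], first)
  add_rows(seq_len(n_tracks), frames[1], first, FALSE)

  for (f in frames[-1]) {
    b <- by_frame[[as.character(f)]]
    open <- which(f - last_frame <= max_gap & last_frame < f)
    matched <- integer(0)
    if (length(open) > 0 && !is.null(b) && nrow(b) > 0) {
      a <- data.frame(x = last_x[open], y = last_y[open],
                      sx = ref_sx[open], sy = ref_sy[open],
                      amplitude = ref_amp[open])
      g <- f - last_frame[open]
      cost <- link_cost_matrix(a, b, priors, gap_scale = sqrt(g))
      sol <- solve_gated_assignment(cost, priors$gate)
      if (nrow(sol$pairs) > 0) {
        matched <- open[sol$pairs[, 1]]
        d <- b[sol$pairs[, 2], , drop = FALSE]
        register(matched, f, d)
        add_rows(matched, f, d, FALSE)
        consec_rec[matched] <- 0L
      }
      new_det <- b[sol$unmatched_2, , drop = FALSE]
    } else {
      new_det <- b
    }
    if (!is.null(stack)) {
      # forward unmatched Gaussians by a guided re-fit at their last
      # position; a track may be carried this way for at most max_gap
      # consecutive frames before it must re-acquire a real detection
      lost <- setdiff(which(last_frame < f & f - last_frame <= max_gap &
                              consec_rec < max_gap),
                      matched)
      if (length(lost) > 0) {
        img <- matrix(as.numeric(stack[f, channel, , ]), dim(stack)[3],
                      dim(stack)[4])
        for (id in lost) {
          cy <- min(max(round(last_y[id]), 1L), nrow(img))
          cx <- min(max(round(last_x[id]), 1L), ncol(img))
          fit <- fit_gaussians_cpp(img, cy, cx, hw, init_sigma,
                                   last_amp[id], last_bg[id])
          if (!all(is.finite(fit)) || fit[7] != 1 || fit[1] <= 0) next
          g1 <- f - last_frame[id]
          sep <- sqrt((fit[2] - last_x[id])^2 + (fit[3] - last_y[id])^2)
          # accept only plausible continuations: bounded displacement and
          # a fit that is still nucleus-like (a blended two-nucleus spot
          # is fine, a runaway flat fit is not)
          if (sep > 3 * priors$pos_sd * sqrt(g1)) next
          if (max(fit[4], fit[5]) > 4 * init_sigma) next
          if (fit[1] < 0.25 * ref_amp[id]) next
          d <- data.frame(
            x = fit[2], y = fit[3], sx = ref_sx[id], sy = ref_sy[id],
            amplitude = min(max(fit[1], 0.5 * ref_amp[id]),
                            2.5 * ref_amp[id]),
            background = fit[6])
          register(id, f, d, rec = TRUE)
          add_rows(id, f, d, TRUE)
          consec_rec[id] <- consec_rec[id] + 1L
        }
      }
    }
    if (!is.null(new_det) && nrow(new_det) > 0) {
      ids <- n_tracks + seq_len(nrow(new_det))
      n_tracks <- n_tracks + nrow(new_det)
      ref_amp[ids] <- NA_real_
      ref_sx[ids] <- NA_real_
      ref_sy[ids] <- NA_real_
      consec_rec[ids] <- 0L
      register(ids, f, new_det)
      add_rows(ids, f, new_det, FALSE)
    }
  }

  tracks <- do.call(rbind, out)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  agg <- do.call(rbind, lapply(split(tracks$frame, tracks$track_id),
                               function(fr) {
                                 c(min(fr), max(fr), length(fr))
                               }))
  movie_span <- max(detections$frame) - min(detections$frame) + 1
  summary <- data.frame(track_id = as.integer(rownames(agg)),
                        start_frame = agg[, 1], end_frame = agg[, 2],
                        n_detections = agg[, 3])
  summary$completeness <- summary$n_detections / movie_span
  keep <- summary$track_id[summary$completeness >= min_completeness]
  tracks <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  summary <- summary[summary$track_id %in% keep, , drop = FALSE]
  # relabel 1..n in order of first appearance
  relab <- stats::setNames(seq_along(keep), sort(keep))
  tracks$track_id <- relab[as.character(tracks$track_id)]
  summary$track_id <- relab[as.character(summary$track_id)]
  rownames(tracks) <- rownames(summary) <- NULL
  structure(list(tracks = tracks, summary = summary), class = "track_set")
}

#' Fraction of ground-truth cells successfully tracked
#'
#' A simulated cell counts as tracked when a single track has a detection
#' within `match_radius` of the cell's true position in at least
#' `min_coverage` of the cell's frames.
#'
#' @param track_set A [build_tracks()] result.
#' @param pop The generating [simulate_population()] object.
#' @param match_radius Matching radius (px), > 0.
#' @param min_coverage Required fraction of covered frames.
#' @return Fraction in \[0, 1\].
#' @export
tracking_fraction <- function(track_set, pop, match_radius = 5,
                              min_coverage = 0.8) {
  if (match_radius <= 0) {
    stop("invalid input: match_radius must be > 0", call. = FALSE)
  }
  stopifnot(inherits(pop, "cell_population"))
  n_cells <- nrow(pop$cells)
  nT <- pop$params$n_frames
  if (nrow(track_set$tracks) == 0L) return(0)
  tracked <- rep(FALSE, n_cells)
  r2 <- match_radius^2
  for (id in track_set$summary$track_id) {
    tr <- track_set$tracks[track_set$tracks$track_id == id, , drop = FALSE]
    d2 <- (pop$x[tr$frame, , drop = FALSE] - tr$x)^2 +
      (pop$y[tr$frame, , drop = FALSE] - tr$y)^2
    cov <- colSums(d2 <= r2)
    tracked <- tracked | (cov >= min_coverage * nT)
  }
  mean(tracked)
}

#' Detect nuclei in every frame of a stack
#'
#' Convenience wrapper running [detect_nuclei()] on the nuclear-marker
#' channel of each frame of a `(frame, channel, y, x)` stack.
#'
#' @param stack Image stack array.
#' @param channel Nuclear-marker channel index.
#' @param ... Passed to [detect_nuclei()].
#' @return Data frame of detections across all frames.
#' @export
detect_stack <- function(stack, channel = 1, ...) {
  nT <- dim(stack)[1]
  out <- vector("list", nT)
  for (f in seq_len(nT)) {
    img <- matrix(as.numeric(stack[f, channel, , ]), dim(stack)[3],
                  dim(stack)[4])
    out[[f]] <- detect_nuclei(img, ..., frame = f)
  }
  do.call(rbind, out)
}
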