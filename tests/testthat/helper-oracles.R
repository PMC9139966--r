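# Independent oracles used across the suite.

# Fixed-step explicit Euler integration of the reporter model with
# piecewise-constant pathway activity S(t) and translation switch; an
# intentionally naive reference for the adaptive solver.
euler_reporter <- function(params, S_fun, beta_on_fun, t_end, h = 0.01,
                           keep = NULL) {
  n <- ceiling(t_end / h)
  m <- p <- f <- 0
  if (is.null(keep)) keep <- t_end
  keep_step <- round(keep / h)
  out <- matrix(NA_real_, length(keep), 4)
  for (i in seq_len(n)) {
    t <- (i - 1) * h
    S <- S_fun(t)
    be <- if (beta_on_fun(t)) params$beta else 0
    dm <- params$alpha * S - params$delta_m * m
    dp <- be * m - (params$kappa + params$delta_p) * p
    df <- params$kappa * p - params$delta_p * f
    m <- m + h * dm
    p <- p + h * dp
    f <- f + h * df
    hit <- which(keep_step == i)
    if (length(hit)) out[hit, ] <- rep(c(i * h, m, p, f), each = length(hit))
  }
  colnames(out) <- c("t", "m", "p", "f")
  as.data.frame(out)
}

# Exhaustive search over all gated matchings, minimising the sum of
# matched costs plus `gate` per unmatched detection on either side.
brute_force_matching <- function(cost, gate) {
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  best <- list(total = gate * (n1 + n2), pairs = matrix(integer(0), ncol = 2))
  rec <- function(i, used, pairs, tot) {
    if (i > n1) {
      total <- tot + gate * (n1 - nrow(pairs)) + gate * (n2 - nrow(pairs))
      if (total < best$total - 1e-12) {
        best <<- list(total = total, pairs = pairs)
      }
      return(invisible())
    }
    rec(i + 1L, used, pairs, tot)
    for (j in seq_len(n2)) {
      if (!used[j] && cost[i, j] <= gate) {
        rec(i + 1L, replace(used, j, TRUE), rbind(pairs, c(i, j)),
            tot + cost[i, j])
      }
    }
  }
  rec(1L, rep(FALSE, n2), matrix(integer(0), ncol = 2), 0)
  best
}

# total objective value achieved by a link_frames result
matching_total <- function(lf, gate) {
  sum(lf$pairs$cost) + gate * (length(lf$unmatched_t) +
                                 length(lf$unmatched_t1))
}

# render a single frame of Gaussian spots (thin wrapper over the package
# kernel, used as the analytic ground truth in detection tests)
render_spots <- function(h, w, x, y, sigma, amp, background = 100) {
  smadtrace:::render_gaussians_cpp(h, w, x, y, rep(sigma, length(x)),
                                   rep(sigma, length(x)), amp) + background
}
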