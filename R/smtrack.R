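#' Link localizations into trajectories
#'
#' Greedy nearest-neighbor frame-to-frame linking under a maximum step
#' length, with gap bridging up to `max_gap` missed frames. A simplified
#' stand-in for full multi-hypothesis trackers: adequate for simulated
#' localizations at the densities this package generates. Unlinkable points
#' start new (possibly single-frame) tracks.
#'
#' @param localizations data.frame with columns `frame`, `x`, `y`
#'   (one channel), sorted or sortable by frame.
#' @param max_step maximum link distance per frame interval (um); scaled by
#'   sqrt(gap + 1) when bridging gaps.
#' @param max_gap maximum bridged gap (frames, default 0).
#' @return list of trajectory data.frames (`frame`, `x`, `y`), each with
#'   strictly increasing frames.
#' @export
link_tracks <- function(localizations, max_step, max_gap = 0L) {
  stopifnot(all(c("frame", "x", "y") %in% names(localizations)))
  ord0 <- order(localizations$frame)
  loc <- localizations[ord0, ]
  n <- nrow(loc)
  track_of <- integer(n)        # track id per localization row
  n_tracks <- 0L
  act_id <- integer(0)          # active track ids
  act_xy <- matrix(numeric(0), 0, 2)
  act_frame <- integer(0)
  frame_rows <- split(seq_len(n), loc$frame)
  for (fr_chr in names(frame_rows)) {
    fr <- as.integer(fr_chr)
    rows <- frame_rows[[fr_chr]]
    live <- act_frame >= fr - 1L - max_gap
    act_id <- act_id[live]
    act_xy <- act_xy[live, , drop = FALSE]
    act_frame <- act_frame[live]
    assigned_cur <- logical(length(rows))
    assigned_act <- logical(length(act_id))
    if (length(act_id)) {
      cx <- loc$x[rows]; cy <- loc$y[rows]
      gap <- fr - act_frame
      dmat <- sqrt(outer(cx, act_xy[, 1], "-")^2 +
                     outer(cy, act_xy[, 2], "-")^2)
      lim <- matrix(rep(max_step * sqrt(gap), each = length(rows)),
                    nrow = length(rows))
      dmat[dmat > lim] <- Inf
      for (k in order(dmat)) {
        if (!is.finite(dmat[k])) break
        i <- (k - 1) %% nrow(dmat) + 1
        j <- (k - 1) %/% nrow(dmat) + 1
        if (assigned_cur[i] || assigned_act[j]) next
        track_of[rows[i]] <- act_id[j]
        act_xy[j, ] <- c(loc$x[rows[i]], loc$y[rows[i]])
        act_frame[j] <- fr
        assigned_cur[i] <- TRUE
        assigned_act[j] <- TRUE
      }
    }
    new_i <- which(!assigned_cur)
    if (length(new_i)) {
      new_ids <- n_tracks + seq_along(new_i)
      n_tracks <- n_tracks + length(new_i)
      track_of[rows[new_i]] <- new_ids
      act_id <- c(act_id, new_ids)
      act_xy <- rbind(act_xy, cbind(loc$x[rows[new_i]], loc$y[rows[new_i]]))
      act_frame <- c(act_frame, rep(fr, length(new_i)))
    }
  }
  out <- lapply(split(seq_len(n), track_of), function(i) {
    t <- loc[i, c("frame", "x", "y")]
    rownames(t) <- NULL
    t
  })
  names(out) <- NULL
  out
}

track_positional_sd <- function(track) {
  sqrt(stats::var(track$x) * (nrow(track) - 1) / nrow(track) +
         stats::var(track$y) * (nrow(track) - 1) / nrow(track))
}

#' Filter immobile emitters
#'
#' Removes trajectories whose overall positional standard deviation (radial
#' SD around the track centroid) falls below a multiple of the localization
#' precision — a simplified spatiotemporal-cluster criterion for stuck or
#' surface-adsorbed emitters.
#'
#' @param tracks list of trajectory data.frames.
#' @param precision localization precision (um).
#' @param multiple threshold multiple of the precision (default 2).
#' @return filtered list of trajectories (mobile ones).
#' @export
filter_immobile <- function(tracks, precision, multiple = 2) {
  keep <- vapply(tracks, function(t)
    nrow(t) >= 2 && track_positional_sd(t) >= multiple * precision,
    logical(1))
  tracks[keep]
}

#' Dual-color co-tracking analysis
#'
#' Frame-by-frame co-localization of channel A and B trajectories within a
#' cutoff radius (default 0.1 um = 100 nm), pairing greedily by increasing
#' distance within each frame. Runs of the same (A, B) track pair lasting
#' at least `min_frames` consecutive frames (default 10) form
#' co-trajectories. The co-tracked fraction is frame-based (relative level
#' of co-localization): the number of per-frame pairings belonging to
#' qualifying runs, normalized by the per-frame mean of the two channels'
#' particle counts, time-averaged. The frame-based form is robust against
#' track-identity swaps at crossings, which split a co-trajectory into two
#' runs without losing its frames.
#'
#' @param tracks_a,tracks_b trajectory lists for the two channels.
#' @param radius co-localization cutoff (um).
#' @param min_frames minimum co-diffusion length (frames).
#' @return `CoTrackingResult`: list(pairs (data.frame a, b, n_frames of the
#'   longest qualifying run), fraction, n_a, n_b, radius, min_frames).
#' @export
cotrack <- function(tracks_a, tracks_b, radius = 0.1, min_frames = 10L) {
  empty <- function() {
    out <- list(pairs = data.frame(a = integer(), b = integer(),
                                   n_frames = integer()),
                fraction = 0, n_a = length(tracks_a), n_b = length(tracks_b),
                radius = radius, min_frames = min_frames)
    class(out) <- "CoTrackingResult"
    out
  }
  if (!length(tracks_a) || !length(tracks_b)) return(empty())
  flat <- function(tracks) {
    do.call(rbind, lapply(seq_along(tracks), function(i)
      data.frame(id = i, frame = tracks[[i]]$frame,
                 x = tracks[[i]]$x, y = tracks[[i]]$y)))
  }
  fa <- flat(tracks_a); fb <- flat(tracks_b)
  frames <- sort(intersect(unique(fa$frame), unique(fb$frame)))
  fa_spl <- split(fa, factor(fa$frame, levels = frames))
  fb_spl <- split(fb, factor(fb$frame, levels = frames))
  pairings <- vector("list", length(frames))
  denom <- 0
  for (f in seq_along(frames)) {
    ca <- fa_spl[[f]]; cb <- fb_spl[[f]]
    denom <- denom + mean(c(nrow(ca), nrow(cb)))
    if (!nrow(ca) || !nrow(cb)) next
    dmat <- sqrt(outer(ca$x, cb$x, "-")^2 + outer(ca$y, cb$y, "-")^2)
    dmat[dmat > radius] <- Inf
    used_a <- logical(nrow(ca)); used_b <- logical(nrow(cb))
    rows <- list()
    for (k in order(dmat)) {
      if (!is.finite(dmat[k])) break
      i <- (k - 1) %% nrow(dmat) + 1
      j <- (k - 1) %/% nrow(dmat) + 1
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      rows[[length(rows) + 1L]] <- c(frames[f], ca$id[i], cb$id[j])
    }
    if (length(rows)) pairings[[f]] <- do.call(rbind, rows)
  }
  pairings <- do.call(rbind, pairings)
  if (is.null(pairings) || denom == 0) return(empty())
  p <- data.frame(frame = pairings[, 1], a = pairings[, 2], b = pairings[, 3])
  p <- p[order(p$a, p$b, p$frame), ]
  new_run <- c(TRUE, diff(p$frame) != 1 | diff(p$a) != 0 | diff(p$b) != 0)
  p$run <- cumsum(new_run)
  run_len <- table(p$run)
  good_runs <- as.integer(names(run_len)[run_len >= min_frames])
  q <- p[p$run %in% good_runs, ]
  if (!nrow(q)) return(empty())
  runs <- unique(q[, c("a", "b", "run")])
  runs$n_frames <- as.integer(run_len[as.character(runs$run)])
  pairs <- stats::aggregate(n_frames ~ a + b, runs, max)
  out <- list(pairs = pairs, fraction = min(nrow(q) / denom, 1),
              n_a = length(tracks_a), n_b = length(tracks_b),
              radius = radius, min_frames = min_frames)
  class(out) <- "CoTrackingResult"
  out
}

#' @export
print.CoTrackingResult <- function(x, ...) {
  cat(sprintf("Co-tracking: %d pairs / (%d, %d) tracks -> fraction %.3f\n",
              nrow(x$pairs), x$n_a, x$n_b, x$fraction))
  invisible(x)
}

#' Diffusion coefficient from pooled mean squared displacement
#'
#' Pools squared displacements over all trajectories with a lifetime
#' greater than `min_lifetime` frames, computes MSD(tau) for the first
#' `n_lags` lag times, and fits MSD = 4 D tau + b by linear regression
#' (2-D). The intercept absorbs the localization-noise floor.
#'
#' @param tracks list of trajectory data.frames.
#' @param dt frame interval (s).
#' @param n_lags number of lag times used (default 4).
#' @param min_lifetime minimum trajectory lifetime, exclusive (default 10
#'   frames: only tracks longer than this enter the pool).
#' @return `DiffusionEstimate`: list(D (um^2/s), intercept, n_lags, msd
#'   (data.frame lag_s, msd), n_tracks).
#' @export
msd_diffusion <- function(tracks, dt, n_lags = 4L, min_lifetime = 10L) {
  use <- tracks[vapply(tracks, nrow, 1L) > min_lifetime]
  if (!length(use))
    stop("insufficient data: no trajectory longer than ", min_lifetime,
         " frames")
  msd <- numeric(n_lags)
  for (lag in seq_len(n_lags)) {
    acc <- 0; cnt <- 0
    for (t in use) {
      # match on frame numbers to respect gaps
      j <- match(t$frame + lag, t$frame)
      ok <- which(!is.na(j))
      if (length(ok)) {
        acc <- acc + sum((t$x[j[ok]] - t$x[ok])^2 + (t$y[j[ok]] - t$y[ok])^2)
        cnt <- cnt + length(ok)
      }
    }
    if (cnt == 0) stop("no displacement pairs at lag ", lag)
    msd[lag] <- acc / cnt
  }
  tau <- seq_len(n_lags) * dt
  fit <- stats::lm(msd ~ tau)
  out <- list(D = unname(stats::coef(fit)[2]) / 4,
              intercept = unname(stats::coef(fit)[1]),
              n_lags = n_lags,
              msd = data.frame(lag_s = tau, msd = msd),
              n_tracks = length(use))
  class(out) <- "DiffusionEstimate"
  out
}

#' @export
print.DiffusionEstimate <- function(x, ...) {
  cat(sprintf("D = %.4g um^2/s (%d tracks, %d lags)\n",
              x$D, x$n_tracks, x$n_lags))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the sup-norm distance between the two empirical CDFs. The p-value
#' is exact (lattice-path enumeration over all orderings) when
#' min(n, m) <= 8 and the pooled sample has no ties; small tied samples
#' fall back to full enumeration, everything else to the asymptotic
#' Kolmogorov distribution.
#'
#' @param x,y numeric samples (non-empty).
#' @return list(statistic, p_value, method).
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  d_stat <- ks_d(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (min(n, m) <= 8 && !ties) {
    p <- ks_exact_p(n, m, d_stat)
    method <- "exact (lattice)"
  } else if (ties && choose(n + m, n) <= 20000) {
    p <- ks_enum_p(x, y, d_stat)
    method <- "exact (enumeration)"
  } else {
    ne <- n * m / (n + m)
    t <- sqrt(ne) * d_stat
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    p <- min(max(p, 0), 1)
    method <- "asymptotic"
  }
  list(statistic = d_stat, p_value = p, method = method)
}

ks_d <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(v) sum(x <= v), 1L) / n
  fy <- vapply(pooled, function(v) sum(y <= v), 1L) / m
  max(abs(fx - fy))
}

# exact P(D >= d) for untied samples: count monotone lattice paths from
# (0,0) to (n,m) with max |i*m - j*n| < d*n*m; p = 1 - count / choose(n+m,n)
ks_exact_p <- function(n, m, d) {
  c_int <- round(d * n * m)  # observed sup deviation on the integer lattice
  cnt <- matrix(0, n + 1, m + 1)
  cnt[1, 1] <- 1
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    if (abs(i * m - j * n) >= c_int) next  # blocked: reaches observed D
    acc <- 0
    if (i > 0) acc <- acc + cnt[i, j + 1]
    if (j > 0) acc <- acc + cnt[i + 1, j]
    cnt[i + 1, j + 1] <- acc
  }
  1 - cnt[n + 1, m + 1] / choose(n + m, n)
}

# brute-force enumeration over label assignments of the pooled values
ks_enum_p <- function(x, y, d) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  ge <- 0
  for (k in seq_len(ncol(idx))) {
    xi <- pooled[idx[, k]]
    yi <- pooled[-idx[, k]]
    if (ks_d(xi, yi) >= d - 1e-12) ge <- ge + 1
  }
  ge / ncol(idx)
}
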