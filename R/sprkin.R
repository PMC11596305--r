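#' 1:1 Langmuir kinetic parameters
#'
#' @param ka association rate (1/(M s), > 0).
#' @param kd dissociation rate (1/s, > 0).
#' @param rmax maximal response (RU, > 0).
#' @return `KineticParams` with derived `KD = kd/ka` (M).
#' @export
kinetic_params <- function(ka, kd, rmax) {
  if (ka <= 0 || kd <= 0 || rmax <= 0) stop("ka, kd and Rmax must be > 0")
  out <- list(ka = ka, kd = kd, KD = kd / ka, rmax = rmax)
  class(out) <- "KineticParams"
  out
}

#' @export
print.KineticParams <- function(x, ...) {
  cat(sprintf("ka %.3g 1/(M s), kd %.3g 1/s, KD %.3g M, Rmax %.3g RU\n",
              x$ka, x$kd, x$KD, x$rmax))
  invisible(x)
}

model_1to1 <- function(ka, kd, rmax, conc, time, t_assoc) {
  kobs <- ka * conc + kd
  req <- if (conc > 0) rmax * conc / (conc + kd / ka) else 0
  r <- numeric(length(time))
  a <- time <= t_assoc
  r[a] <- req * (1 - exp(-kobs * time[a]))
  r0 <- req * (1 - exp(-kobs * t_assoc))
  r[!a] <- r0 * exp(-kd * (time[!a] - t_assoc))
  r
}

#' Simulate a 1:1 binding sensogram
#'
#' Closed-form 1:1 Langmuir response: association
#' R(t) = Req (1 - exp(-(ka C + kd) t)) with Req = Rmax C / (C + KD),
#' dissociation R(t) = R0 exp(-kd (t - t0)). Optional additive Gaussian
#' noise and linear baseline drift. Defaults follow a 180 s injection and a
#' 600 s dissociation phase.
#'
#' @param params a [kinetic_params()].
#' @param conc analyte concentration (M, >= 0).
#' @param t_assoc association span (s).
#' @param t_dissoc dissociation span (s).
#' @param dt time step (s).
#' @param noise_sd additive Gaussian noise SD (RU, >= 0).
#' @param drift linear drift (RU/s) applied over the whole curve.
#' @param seed optional RNG seed for the noise.
#' @return `Sensogram`: list(time, response, conc, t_assoc).
#' @export
simulate_sensogram <- function(params, conc, t_assoc = 180, t_dissoc = 600,
                               dt = 1, noise_sd = 0, drift = 0,
                               seed = NULL) {
  stopifnot(inherits(params, "KineticParams"))
  if (conc < 0) stop("concentration must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  time <- seq(0, t_assoc + t_dissoc, by = dt)
  r <- model_1to1(params$ka, params$kd, params$rmax, conc, time, t_assoc)
  r <- r + drift * time
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    r <- r + stats::rnorm(length(r), 0, noise_sd)
  }
  out <- list(time = time, response = r, conc = conc, t_assoc = t_assoc)
  class(out) <- "Sensogram"
  out
}

#' Double referencing of a sensogram
#'
#' Subtracts the reference-surface response and the zero-concentration
#' sensogram from a sample curve. All three curves must share the time grid.
#'
#' @param sample,reference,zero `Sensogram` objects on one grid.
#' @return corrected `Sensogram`.
#' @export
double_reference <- function(sample, reference, zero) {
  grids_equal <- function(a, b)
    length(a$time) == length(b$time) && all(a$time == b$time)
  if (!grids_equal(sample, reference) || !grids_equal(sample, zero))
    stop("time grids are not aligned across the three channels")
  sample$response <- sample$response - reference$response - zero$response
  sample
}

#' Global 1:1 kinetic fit of a multi-concentration sensogram set
#'
#' Least-squares fit sharing (ka, kd, Rmax) across all concentrations
#' (global, multi-cycle style), minimized with Nelder-Mead on log
#' parameters from multiple log-spaced starts. Leave-one-out refits (one
#' concentration's curve omitted at a time) give the mean and sample SD of
#' ka, kd and KD.
#'
#' @param sensograms list of `Sensogram` objects at >= 2 concentrations
#'   spanning more than a 2-fold range.
#' @param n_starts number of log-spaced multi-starts on ka (default 8).
#' @param loo compute leave-one-out statistics (default TRUE).
#' @param per_curve if TRUE, additionally report independent per-curve fits.
#' @return `KineticFit`: list(estimate (KineticParams), sse, loo (data.frame
#'   of per-omission estimates), stats (mean/sd of ka, kd, KD), per_curve).
#' @export
fit_1to1 <- function(sensograms, n_starts = 8, loo = TRUE,
                     per_curve = FALSE) {
  if (length(sensograms) < 2) stop("need sensograms at >= 2 concentrations")
  concs <- vapply(sensograms, function(s) s$conc, 1.0)
  pos <- concs[concs > 0]
  if (!length(pos) || max(pos) / min(pos) <= 2)
    stop("concentrations must span more than a 2-fold range")
  rng <- max(vapply(sensograms, function(s) max(abs(s$response)), 1.0))
  if (rng < .Machine$double.eps * 100)
    stop("insufficient signal: responses are flat")
  sse <- function(lp) {
    ka <- exp(lp[1]); kd <- exp(lp[2]); rmax <- exp(lp[3])
    s <- 0
    for (sg in sensograms) {
      pred <- model_1to1(ka, kd, rmax, sg$conc, sg$time, sg$t_assoc)
      s <- s + sum((sg$response - pred)^2)
    }
    if (!is.finite(s)) return(1e300)
    s
  }
  # data-driven anchors: Rmax from the largest plateau, kd from the tails
  rmax0 <- max(vapply(sensograms, function(s) max(s$response), 1.0)) * 1.2
  kd0 <- estimate_kd_from_tails(sensograms)
  ka_grid <- 10^seq(3, 8, length.out = n_starts)
  best <- NULL
  for (ka0 in ka_grid) {
    fit <- stats::optim(log(c(ka0, kd0, rmax0)), sse, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("1:1 fit failed to converge from any start")
  est <- kinetic_params(exp(best$par[1]), exp(best$par[2]), exp(best$par[3]))
  out <- list(estimate = est, sse = best$value, loo = NULL, stats = NULL,
              per_curve = NULL)
  if (loo && length(sensograms) >= 3) {
    rows <- lapply(seq_along(sensograms), function(i) {
      sub <- sensograms[-i]
      f <- fit_1to1_point(sub, start = best$par)
      data.frame(omitted_conc = concs[i], ka = f$ka, kd = f$kd, KD = f$KD)
    })
    out$loo <- do.call(rbind, rows)
    out$stats <- data.frame(
      parameter = c("ka", "kd", "KD"),
      mean = c(mean(out$loo$ka), mean(out$loo$kd), mean(out$loo$KD)),
      sd = c(stats::sd(out$loo$ka), stats::sd(out$loo$kd),
             stats::sd(out$loo$KD)))
  }
  if (per_curve) {
    out$per_curve <- lapply(sensograms, function(sg)
      fit_1to1_point(list(sg, sg), start = best$par))
  }
  class(out) <- "KineticFit"
  out
}

# single-start refit used for LOO / per-curve passes
fit_1to1_point <- function(sensograms, start) {
  sse <- function(lp) {
    ka <- exp(lp[1]); kd <- exp(lp[2]); rmax <- exp(lp[3])
    s <- 0
    for (sg in sensograms) {
      pred <- model_1to1(ka, kd, rmax, sg$conc, sg$time, sg$t_assoc)
      s <- s + sum((sg$response - pred)^2)
    }
    if (!is.finite(s)) return(1e300)
    s
  }
  fit <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  kinetic_params(exp(fit$par[1]), exp(fit$par[2]), exp(fit$par[3]))
}

estimate_kd_from_tails <- function(sensograms) {
  kds <- c()
  for (sg in sensograms) {
    i <- sg$time > sg$t_assoc & sg$response > 0
    if (sum(i) > 5) {
      co <- stats::coef(stats::lm(log(sg$response[i]) ~ sg$time[i]))
      if (is.finite(co[2]) && co[2] < 0) kds <- c(kds, -co[2])
    }
  }
  if (!length(kds)) 1e-3 else stats::median(kds)
}

#' @export
print.KineticFit <- function(x, ...) {
  cat("Global 1:1 kinetic fit\n")
  print(x$estimate)
  if (!is.null(x$stats)) {
    cat("leave-one-out statistics:\n")
    print(x$stats, row.names = FALSE)
  }
  invisible(x)
}

#' Mean and sample standard deviation of leave-one-out estimates
#'
#' @param values numeric vector (length >= 2).
#' @return list(mean, sd) with the n-1 denominator SD.
#' @export
loo_stats <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  list(mean = mean(values), sd = stats::sd(values))
}

#' Read/write the sensogram CSV dialect
#'
#' Columns: time_s, response_ru, concentration_M, phase (assoc|dissoc).
#'
#' @param path CSV file.
#' @return list of `Sensogram` objects (one per concentration).
#' @export
read_sensogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "response_ru", "concentration_M", "phase")
  if (!all(need %in% names(d)))
    stop("sensogram CSV must have columns ", paste(need, collapse = ", "))
  lapply(split(d, d$concentration_M), function(g) {
    g <- g[order(g$time_s), ]
    t_assoc <- max(g$time_s[g$phase == "assoc"])
    out <- list(time = g$time_s, response = g$response_ru,
                conc = g$concentration_M[1], t_assoc = t_assoc)
    class(out) <- "Sensogram"
    out
  })
}

#' @rdname read_sensogram_csv
#' @param sensograms list of `Sensogram` objects.
#' @export
write_sensogram_csv <- function(sensograms, path) {
  rows <- lapply(sensograms, function(sg)
    data.frame(time_s = sg$time, response_ru = sg$response,
               concentration_M = sg$conc,
               phase = ifelse(sg$time <= sg$t_assoc, "assoc", "dissoc")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
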