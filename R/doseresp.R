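#' Four-parameter logistic parameters
#'
#' @param bottom,top asymptotic responses (top != bottom).
#' @param ec50 midpoint concentration (M, > 0).
#' @param hill slope; positive for increasing curves, negative for
#'   decreasing (inhibition) curves.
#' @return `FourPLParams`.
#' @export
fourpl_params <- function(bottom, top, ec50, hill) {
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (top == bottom) stop("top must differ from bottom")
  out <- list(bottom = bottom, top = top, ec50 = ec50, hill = hill)
  class(out) <- "FourPLParams"
  out
}

#' @export
print.FourPLParams <- function(x, ...) {
  cat(sprintf("4PL: bottom %.3g, top %.3g, ec50 %.3g M, hill %.3g\n",
              x$bottom, x$top, x$ec50, x$hill))
  invisible(x)
}

#' Evaluate a four-parameter logistic curve
#'
#' f(c) = bottom + (top - bottom) / (1 + (ec50/c)^hill). At c = 0 the
#' analytic limit is used: bottom for hill > 0, top for hill < 0.
#'
#' @param params list or `FourPLParams` (bottom, top, ec50, hill).
#' @param conc concentrations (M, >= 0); vectorized.
#' @return response values.
#' @export
fourpl_eval <- function(params, conc) {
  if (any(conc < 0)) stop("concentrations must be >= 0")
  b <- params$bottom; t <- params$top; e <- params$ec50; h <- params$hill
  out <- numeric(length(conc))
  z <- conc == 0
  out[z] <- if (h > 0) b else t
  out[!z] <- b + (t - b) / (1 + (e / conc[!z])^h)
  out
}

#' Min-max normalization against plate controls
#'
#' Maps raw readouts to a percent scale: 100 (x - mean(neg)) /
#' (mean(pos) - mean(neg)). Positive controls define 100% (e.g. cells with
#' the constant agonist dose), negative controls 0% (untreated).
#'
#' @param x raw responses.
#' @param pos_ctrl,neg_ctrl control readouts (non-empty).
#' @return percent-scale responses.
#' @export
normalize_to_controls <- function(x, pos_ctrl, neg_ctrl) {
  if (!length(pos_ctrl) || !length(neg_ctrl))
    stop("both control sets must be non-empty")
  span <- mean(pos_ctrl) - mean(neg_ctrl)
  if (span == 0) stop("degenerate controls: positive mean equals negative mean")
  100 * (x - mean(neg_ctrl)) / span
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit minimized with Nelder-Mead. Initializations are
#' data-driven (bottom = min, top = max, ec50 = geometric mid of the
#' nonzero doses) with both hill signs tried, plus seeded jittered
#' restarts; the best restart is returned. Zero concentrations enter
#' through the analytic c -> 0 limit.
#'
#' @param concentrations doses (M, >= 0; >= 4 distinct nonzero values).
#' @param responses observed responses, same length.
#' @param n_restarts extra jittered restarts per hill sign (default 3).
#' @param seed RNG seed for the restarts.
#' @return `FourPLParams` with attributes `sse` and `convergence`.
#' @export
fit_fourpl <- function(concentrations, responses, n_restarts = 3, seed = 1L) {
  if (length(concentrations) != length(responses))
    stop("concentrations and responses must have equal length")
  nz <- unique(concentrations[concentrations > 0])
  if (length(nz) < 4) stop("need >= 4 distinct nonzero concentrations")
  if (stats::sd(responses) == 0)
    stop("degenerate fit: responses are constant")
  obj <- function(p) {
    pr <- list(bottom = p[1], top = p[2], ec50 = exp(p[3]), hill = p[4])
    if (pr$hill == 0) return(1e300)
    s <- sum((responses - fourpl_eval(pr, concentrations))^2)
    if (!is.finite(s)) 1e300 else s
  }
  b0 <- min(responses); t0 <- max(responses)
  le0 <- mean(log(range(nz)))
  set.seed(seed)
  starts <- list(c(b0, t0, le0, 1), c(b0, t0, le0, -1))
  for (k in seq_len(n_restarts)) {
    starts <- c(starts,
                list(c(b0, t0, le0 + stats::rnorm(1, 0, 1),
                       sample(c(-1, 1), 1) * stats::runif(1, 0.5, 2))))
  }
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value))
    stop("4PL fit failed to converge (all restarts diverged)")
  out <- fourpl_params(best$par[1], best$par[2], exp(best$par[3]),
                       best$par[4])
  attr(out, "sse") <- best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Potency (EC50/IC50) estimate across replicates
#'
#' Fits a 4PL curve per replicate and summarizes the midpoint
#' concentration. With equal-sized replicates the summary is the plain mean
#' and sample SD of the per-replicate estimates; with unequal replicate
#' sizes (or `method = "loo"`) leave-one-replicate-out fits on the pooled
#' data are used instead, mirroring how unequal biological replicates are
#' handled.
#'
#' @param replicates list of data.frames with columns `concentration`,
#'   `response`.
#' @param kind `"EC50"` or `"IC50"` (labeling only; the hill sign is free).
#' @param method `"auto"` (default), `"replicate"` or `"loo"`.
#' @param seed passed to [fit_fourpl()].
#' @return `PotencyEstimate`: list(kind, values, mean, sd, fits).
#' @export
estimate_potency <- function(replicates, kind = c("EC50", "IC50"),
                             method = c("auto", "replicate", "loo"),
                             seed = 1L) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (!length(replicates)) stop("need at least one replicate")
  sizes <- vapply(replicates, nrow, 1L)
  if (method == "auto")
    method <- if (length(unique(sizes)) == 1L) "replicate" else "loo"
  if (method == "replicate") {
    fits <- lapply(replicates, function(d)
      fit_fourpl(d$concentration, d$response, seed = seed))
  } else {
    if (length(replicates) < 2)
      stop("leave-one-out requires >= 2 replicates")
    fits <- lapply(seq_along(replicates), function(i) {
      pooled <- do.call(rbind, replicates[-i])
      fit_fourpl(pooled$concentration, pooled$response, seed = seed)
    })
  }
  values <- vapply(fits, function(f) f$ec50, 1.0)
  out <- list(kind = kind, values = values, mean = mean(values),
              sd = if (length(values) > 1) stats::sd(values) else 0,
              method = method, fits = fits)
  class(out) <- "PotencyEstimate"
  out
}

#' @export
print.PotencyEstimate <- function(x, ...) {
  cat(sprintf("%s = %.3g +/- %.3g M (n = %d, %s)\n",
              x$kind, x$mean, x$sd, length(x$values), x$method))
  invisible(x)
}

#' Read the dose-response CSV dialect
#'
#' Columns: concentration_M, response, role (sample|pos_ctrl|neg_ctrl),
#' replicate_id.
#'
#' @param path CSV file.
#' @return list of replicate data.frames (normalized if controls present)
#'   plus attributes `pos_ctrl`/`neg_ctrl`.
#' @export
read_dose_response_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_M", "response", "role", "replicate_id")
  if (!all(need %in% names(d)))
    stop("dose-response CSV must have columns ", paste(need, collapse = ", "))
  pos <- d$response[d$role == "pos_ctrl"]
  neg <- d$response[d$role == "neg_ctrl"]
  smp <- d[d$role == "sample", ]
  reps <- lapply(split(smp, smp$replicate_id), function(g)
    data.frame(concentration = g$concentration_M, response = g$response))
  attr(reps, "pos_ctrl") <- pos
  attr(reps, "neg_ctrl") <- neg
  reps
}
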