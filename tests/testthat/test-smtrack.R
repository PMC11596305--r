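test_that("linking: single emitter, separated emitters, ground-truth identity", {
  # one emitter, no noise -> one trajectory with all frames
  one <- data.frame(frame = 0:49, x = cumsum(rnorm(50, 0, 0.05)),
                    y = cumsum(rnorm(50, 0, 0.05)))
  tr <- link_tracks(one, max_step = 1)
  expect_equal(length(tr), 1)
  expect_equal(nrow(tr[[1]]), 50)
  expect_true(all(diff(tr[[1]]$frame) > 0))
  # two emitters always far apart -> never merged
  two <- rbind(data.frame(frame = 0:49, x = 0, y = 0),
               data.frame(frame = 0:49, x = 10, y = 10))
  tr2 <- link_tracks(two, max_step = 1)
  expect_equal(length(tr2), 2)
  # 20 simulated emitters: >= 95% of links match ground truth
  cfg <- trajectory_sim_config(n_per_channel = 20, dimer_fraction = 0,
                               d_monomer = 0.05, precision = 0, seed = 77)
  fld <- simulate_two_channel_field(cfg)
  la <- fld$localizations[fld$localizations$channel == "A", ]
  max_step <- 5 * sqrt(4 * 0.05 * cfg$dt)
  tracks <- link_tracks(la, max_step)
  # a link is correct when consecutive positions share one true id
  key <- paste(la$frame, round(la$x, 9), round(la$y, 9))
  id_of <- la$true_id[match(unlist(lapply(tracks, function(t)
    paste(t$frame, round(t$x, 9), round(t$y, 9)))), key)]
  lens <- vapply(tracks, nrow, 1L)
  same <- unlist(mapply(function(n, off) {
    ids <- id_of[off + seq_len(n)]
    ids[-1] == ids[-n]
  }, lens, cumsum(c(0, lens[-length(lens)])), SIMPLIFY = FALSE))
  expect_gte(mean(same), 0.95)
})

test_that("immobile filtering separates fixed and mobile emitters", {
  set.seed(55)
  prec <- 0.02
  fixed <- data.frame(frame = 0:99, x = 5 + rnorm(100, 0, prec),
                      y = 5 + rnorm(100, 0, prec))
  cfg <- trajectory_sim_config(n_per_channel = 1, dimer_fraction = 0,
                               d_monomer = 0.1, precision = prec, seed = 56)
  mob <- simulate_two_channel_field(cfg)$localizations
  mob <- mob[mob$channel == "A", c("frame", "x", "y")]
  out <- filter_immobile(list(fixed, mob), prec)
  expect_equal(length(out), 1)
  expect_equal(out[[1]], mob, ignore_attr = TRUE)
  # mixture classification accuracy >= 95%
  n_fix <- 20; n_mob <- 20
  mk_fixed <- function(s) {
    set.seed(900 + s)
    data.frame(frame = 0:99, x = rnorm(100, 0, prec), y = rnorm(100, 0, prec))
  }
  cfgm <- trajectory_sim_config(n_per_channel = n_mob, dimer_fraction = 0,
                                d_monomer = 0.1, precision = prec, seed = 58)
  locm <- simulate_two_channel_field(cfgm)$localizations
  mobs <- lapply(split(locm[locm$channel == "A", ],
                       locm$true_id[locm$channel == "A"]),
                 function(d) d[, c("frame", "x", "y")])
  pool <- c(lapply(seq_len(n_fix), mk_fixed), mobs)
  truth <- c(rep(FALSE, n_fix), rep(TRUE, n_mob))
  kept <- filter_immobile(pool, prec)
  got <- vapply(pool, function(t)
    any(vapply(kept, function(k) identical(k, t), logical(1))), logical(1))
  expect_gte(mean(got == truth), 0.95)
})

test_that("cotrack: identical, disjoint and empty channels", {
  t1 <- list(data.frame(frame = 0:29, x = cumsum(rnorm(30, 0, 0.05)),
                        y = cumsum(rnorm(30, 0, 0.05))))
  ct <- cotrack(t1, t1)
  expect_equal(ct$fraction, 1)
  expect_equal(nrow(ct$pairs), 1)
  far <- list(data.frame(frame = 0:29, x = t1[[1]]$x + 5, y = t1[[1]]$y))
  expect_equal(cotrack(t1, far)$fraction, 0)
  expect_equal(cotrack(list(), t1)$fraction, 0)
  expect_equal(cotrack(t1, list())$fraction, 0)
})

test_that("cotrack estimates the dimer fraction within 5 points; zero control < 1%", {
  cfg <- trajectory_sim_config(n_per_channel = 100, dimer_fraction = 0.3,
                               seed = 3)
  fld <- simulate_two_channel_field(cfg)
  loc <- fld$localizations
  max_step <- 5 * sqrt(4 * cfg$d_monomer * cfg$dt)
  ta <- link_tracks(loc[loc$channel == "A", ], max_step)
  tb <- link_tracks(loc[loc$channel == "B", ], max_step)
  ct <- cotrack(ta, tb)
  expect_lt(abs(ct$fraction - 0.3), 0.05)
  # channel symmetry on the all-dimer field
  cfg1 <- trajectory_sim_config(n_per_channel = 40, dimer_fraction = 1,
                                seed = 13)
  f1 <- simulate_two_channel_field(cfg1)
  l1 <- f1$localizations
  ta1 <- link_tracks(l1[l1$channel == "A", ], max_step)
  tb1 <- link_tracks(l1[l1$channel == "B", ], max_step)
  expect_equal(cotrack(ta1, tb1)$fraction, cotrack(tb1, ta1)$fraction,
               tolerance = 1e-12)
  # no dimers -> fraction under 1%
  cfg0 <- trajectory_sim_config(n_per_channel = 100, dimer_fraction = 0,
                                seed = 5)
  f0 <- simulate_two_channel_field(cfg0)
  l0 <- f0$localizations
  ct0 <- cotrack(link_tracks(l0[l0$channel == "A", ], max_step),
                 link_tracks(l0[l0$channel == "B", ], max_step))
  expect_lt(ct0$fraction, 0.01)
})

test_that("cotrack fraction is monotone in radius and min_frames", {
  cfg <- trajectory_sim_config(n_per_channel = 60, dimer_fraction = 0.4,
                               seed = 21)
  fld <- simulate_two_channel_field(cfg)
  loc <- fld$localizations
  max_step <- 5 * sqrt(4 * cfg$d_monomer * cfg$dt)
  ta <- link_tracks(loc[loc$channel == "A", ], max_step)
  tb <- link_tracks(loc[loc$channel == "B", ], max_step)
  fr_radius <- vapply(c(0.05, 0.1, 0.2),
                      function(r) cotrack(ta, tb, radius = r)$fraction, 1.0)
  expect_true(all(diff(fr_radius) >= 0))
  fr_minf <- vapply(c(5L, 10L, 30L),
                    function(m) cotrack(ta, tb, min_frames = m)$fraction, 1.0)
  expect_true(all(diff(fr_minf) <= 0))
})

test_that("MSD diffusion: truth recovery, stationary floor, lifetime filter", {
  cfg <- trajectory_sim_config(n_per_channel = 250, dimer_fraction = 0,
                               d_monomer = 0.1, seed = 9)
  fld <- simulate_two_channel_field(cfg)  # 500 monomer tracks over channels
  loc <- fld$localizations
  tracks <- lapply(split(loc, loc$true_id),
                   function(d) d[order(d$frame), c("frame", "x", "y")])
  est <- msd_diffusion(tracks, cfg$dt)
  expect_equal(est$n_tracks, 500)
  expect_lt(abs(est$D - 0.1) / 0.1, 0.10)
  # localization noise shows up as a positive intercept ~ 4 sigma^2
  expect_gt(est$intercept, 0)
  expect_lt(abs(est$intercept - 4 * cfg$precision^2), 4 * cfg$precision^2)
  # stationary emitters -> D at the noise floor
  set.seed(14)
  still <- lapply(1:30, function(i)
    data.frame(frame = 0:59, x = rnorm(60, 0, 0.02), y = rnorm(60, 0, 0.02)))
  est0 <- msd_diffusion(still, 0.032)
  expect_lt(abs(est0$D), 0.005)
  # an exactly-10-frame trajectory is excluded ("greater than 10 frames")
  ten <- list(data.frame(frame = 0:9, x = rnorm(10), y = rnorm(10)))
  expect_error(msd_diffusion(ten, 0.032), "insufficient data")
  eleven <- list(data.frame(frame = 0:10, x = rnorm(11), y = rnorm(11)))
  expect_silent(msd_diffusion(eleven, 0.032))
})

test_that("MSD estimator is unbiased over repeated simulations", {
  ds <- vapply(1:10, function(s) {
    cfg <- trajectory_sim_config(n_per_channel = 60, dimer_fraction = 0,
                                 d_monomer = 0.1, seed = 1000 + s)
    loc <- simulate_two_channel_field(cfg)$localizations
    tracks <- lapply(split(loc, loc$true_id),
                     function(d) d[order(d$frame), c("frame", "x", "y")])
    msd_diffusion(tracks, cfg$dt)$D
  }, 1.0)
  expect_lt(abs(mean(ds) - 0.1) / 0.1, 0.03)
})

test_that("KS test: trivial cases and exact enumeration oracle", {
  same <- ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disj <- ks_two_sample(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disj$statistic, 1)
  set.seed(33)
  for (k in 1:6) {
    n <- sample(3:5, 1); m <- sample(3:5, 1)
    x <- rnorm(n); y <- rnorm(m, mean = sample(c(0, 1.5), 1))
    got <- ks_two_sample(x, y)
    orc <- ks_oracle(x, y)
    expect_equal(got$statistic, orc$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, orc$p_value, tolerance = 1e-12)
  }
  # asymptotic branch is a sane approximation at moderate n
  set.seed(34)
  x <- rnorm(60); y <- rnorm(80, 0.8)
  big <- ks_two_sample(x, y)
  expect_equal(big$method, "asymptotic")
  ref <- suppressWarnings(stats::ks.test(x, y))
  expect_equal(big$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(big$p_value - ref$p.value), 0.02)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})
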