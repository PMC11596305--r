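# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms than the package code.

# Horn's closed-form quaternion superposition (eigenvector of the 4x4
# key matrix) — independent of the SVD-based Kabsch path.
quaternion_superpose <- function(mobile, target) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(target, 2, colMeans(target))
  s <- crossprod(p, q)
  n4 <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],       -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],       -s[1,1]-s[2,2]+s[3,3]),
    4, 4, byrow = TRUE)
  eig <- eigen(n4, symmetric = TRUE)
  lam <- eig$values[1]
  qt <- eig$vectors[, 1]
  w <- qt[1]; x <- qt[2]; y <- qt[3]; z <- qt[4]
  rot <- matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
  msd <- (sum(p^2) + sum(q^2) - 2*lam) / nrow(p)
  list(rotation = t(rot), rmsd = sqrt(max(msd, 0)))
}

# quaternion -> rotation matrix, for constructing known rigid transforms
quat_to_rot <- function(w, x, y, z) {
  n <- sqrt(w^2+x^2+y^2+z^2); w <- w/n; x <- x/n; y <- y/n; z <- z/n
  matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
}

# fixed-step RK4 integration of dR/dt = ka*C*(Rmax - R) - kd*R, then
# dR/dt = -kd*R in the dissociation phase
rk4_sensogram <- function(ka, kd, rmax, conc, times, t_assoc, h = 0.01) {
  deriv_a <- function(r) ka * conc * (rmax - r) - kd * r
  deriv_d <- function(r) -kd * r
  out <- numeric(length(times))
  r <- 0; t <- 0
  for (i in seq_along(times)) {
    target <- times[i]
    while (t < target - 1e-12) {
      step <- min(h, target - t)
      f <- if (t < t_assoc) deriv_a else deriv_d
      k1 <- f(r); k2 <- f(r + step/2*k1); k3 <- f(r + step/2*k2)
      k4 <- f(r + step*k3)
      r <- r + step/6*(k1 + 2*k2 + 2*k3 + k4)
      t <- t + step
    }
    out[i] <- r
  }
  out
}

# brute-force two-sample KS: D statistic by direct ECDF comparison and
# p-value by full enumeration of label assignments of the pooled sample
ks_oracle <- function(x, y) {
  d_of <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(vapply(g, function(v) sum(a <= v)/length(a) -
                     sum(b <= v)/length(b), 1.0)))
  }
  d0 <- d_of(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  hits <- 0
  for (k in seq_len(ncol(idx))) {
    if (d_of(pooled[idx[, k]], pooled[-idx[, k]]) >= d0 - 1e-12)
      hits <- hits + 1
  }
  list(statistic = d0, p_value = hits / ncol(idx))
}

# independent exhaustive register scan (re-implements the argmin contract
# without reusing optimize_register internals)
register_scan_oracle <- function(bundle, annotation, site, orientation,
                                 half_width, reference_xyz = NULL) {
  ch <- annotation$chain[1]
  ref <- if (is.null(reference_xyz))
    bifacet:::gather_backbone(bundle, rep(ch, length(site$positions)),
                              site$positions, "CA", "o")
  else reference_xyz
  best <- NULL
  for (o in seq.int(-half_width, half_width)) {
    mp <- tryCatch(map_pseudosymmetric_positions(
      bundle, annotation, orientation, o, positions = site$positions),
      error = function(e) NULL)
    if (is.null(mp)) next
    dst <- bifacet:::gather_backbone(bundle, rep(ch, nrow(mp)), mp$dest,
                                     "CA", "o")
    r <- kabsch_superpose(ref, dst)$rmsd
    cand <- list(offset = o, rmsd = r)
    if (is.null(best) || r < best$rmsd - 1e-12 ||
        (abs(r - best$rmsd) <= 1e-12 &&
           (abs(o) < abs(best$offset) ||
              (abs(o) == abs(best$offset) && o < best$offset))))
      best <- cand
  }
  best
}

random_rigid <- function() {
  q <- stats::rnorm(4)
  list(rotation = quat_to_rot(q[1], q[2], q[3], q[4]),
       translation = stats::rnorm(3, 0, 20))
}

apply_rigid_structure <- function(s, rot, tr) {
  xy <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  xy <- sweep(xy, 2, tr, "+")
  s$atoms$x <- xy[, 1]; s$atoms$y <- xy[, 2]; s$atoms$z <- xy[, 3]
  s
}
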