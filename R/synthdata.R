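#' Ideal four-helix bundle generator
#'
#' Builds backbone (N, CA, C, O) coordinates of four straight ideal
#' alpha-helices on a square arrangement with up-down-up-down topology.
#' Helix phases are chosen so that the bundle carries an exact two-fold
#' pseudosymmetry relating the H2/H3 face to the H1/H4 face (a 180-degree
#' rotation about an in-plane axis maps H2 onto H1 and H3 onto H4), which
#' is the property binding-site grafting exploits.
#'
#' Geometry uses textbook ideal-helix parameters: 1.5 A axial rise per
#' residue, 3.6 residues per turn, 2.3 A C-alpha helical radius. N, C and O
#' are placed on auxiliary cylinders; only the C-alpha trace is exact.
#'
#' @param n_res residues per helix (default 24).
#' @param bundle_radius distance of each helix axis from the bundle axis
#'   (default 8 A, a typical four-helix-bundle packing distance).
#' @param rise axial rise per residue (A).
#' @param res_per_turn residues per helical turn.
#' @param ca_radius C-alpha helical radius (A).
#' @param chain chain identifier.
#' @return list with `structure` (a [structure_from_atoms()] `Structure`)
#'   and `annotation` (data.frame: helix, chain, start, end, direction).
#' @export
make_ideal_bundle <- function(n_res = 24L, bundle_radius = 8,
                              rise = 1.5, res_per_turn = 3.6,
                              ca_radius = 2.3, chain = "A") {
  stopifnot(n_res >= 6, bundle_radius > 0)
  omega <- 2 * pi / res_per_turn
  # per-helix axis positions on a square; phases give exact pseudosymmetry
  axis_angle <- c(45, 135, 225, 315) * pi / 180
  phase <- c(pi, 0, 0, pi)
  direction <- c("up", "down", "up", "down")
  gap <- 3L  # unmodeled loop residues between helices in the numbering
  # cylinder parameters per backbone atom: radius, phase offset, z offset
  atom_par <- list(N  = c(1.56, -0.49, -0.95),
                   CA = c(2.30,  0.00,  0.00),
                   C  = c(1.64,  0.45,  1.05),
                   O  = c(1.90,  0.77,  1.25))
  rows <- list()
  ann <- data.frame(helix = 1:4, chain = chain, start = NA_integer_,
                    end = NA_integer_, direction = direction,
                    stringsAsFactors = FALSE)
  resno <- 0L
  for (h in 1:4) {
    resno <- resno + if (h == 1) 1L else gap + 1L
    ann$start[h] <- resno
    cx <- bundle_radius * cos(axis_angle[h])
    cy <- bundle_radius * sin(axis_angle[h])
    for (j in seq_len(n_res)) {
      for (an in names(atom_par)) {
        p <- atom_par[[an]]
        alpha <- omega * j + phase[h] + p[2]
        lx <- p[1] * cos(alpha)
        ly <- p[1] * sin(alpha)
        lz <- rise * j + p[3]
        if (direction[h] == "down") { ly <- -ly; lz <- -lz }
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain, resno = resno, resname = "ALA", atom = an,
          x = cx + lx, y = cy + ly, z = lz, stringsAsFactors = FALSE)
      }
      if (j < n_res) resno <- resno + 1L
    }
    ann$end[h] <- resno
  }
  list(structure = structure_from_atoms(do.call(rbind, rows)),
       annotation = ann)
}

#' Toy ternary complex with a prescribed receptor anchor distance
#'
#' Builds a minimal complex: a ligand chain plus two receptor stub chains
#' placed so that the C-alpha atoms of their most C-terminal residues are a
#' requested distance apart. A fixture for the inter-TMD spacing metric.
#'
#' @param anchor_distance requested anchor C-alpha distance (A), > 0.
#' @param ligand optional `Structure` used as the ligand chain
#'   (re-labelled "L"); default is a short ideal helix.
#' @param receptor_chains ids for the two receptor chains.
#' @return a `Structure` with ligand and two receptor chains.
#' @export
make_toy_complex <- function(anchor_distance, ligand = NULL,
                             receptor_chains = c("R", "S")) {
  stopifnot(anchor_distance > 0, length(receptor_chains) == 2)
  if (is.null(ligand)) {
    lig <- make_ideal_bundle(n_res = 8)$structure
    lig$atoms <- lig$atoms[lig$atoms$resno <= 8, ]
  } else lig <- ligand
  lig$atoms$chain <- "L"
  stub <- function(chain, x0) {
    # 3-residue CA-only stub ending at (x0, 0, 0)
    data.frame(chain = chain, resno = 1:3, resname = "GLY", atom = "CA",
               x = x0 + c(-7.6, -3.8, 0), y = 0, z = 0,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(lig$atoms,
                 stub(receptor_chains[1], -anchor_distance / 2),
                 stub(receptor_chains[2], anchor_distance / 2))
  structure_from_atoms(atoms)
}

#' Configuration for the two-channel membrane trajectory simulator
#'
#' Defaults encode the imaging conditions of the co-tracking assay this
#' package analyzes: 32 ms frame interval and 150-frame stacks. Diffusion
#' coefficients default to typical cytokine-receptor mobility on live-cell
#' membranes (monomer 0.1 um^2/s; dimer 0.05 um^2/s).
#'
#' @param n_per_channel emitters per channel.
#' @param dimer_fraction fraction of particles per channel that are dimers
#'   (each dimer carries exactly one emitter per channel).
#' @param d_monomer,d_dimer diffusion coefficients (um^2/s).
#' @param dt frame interval (s).
#' @param frames frames per stack.
#' @param precision localization precision (um, 1 sigma per axis).
#' @param field side length of the square field (um); boundaries reflect.
#' @param seed integer RNG seed.
#' @return a `TrajectorySimConfig` list.
#' @export
trajectory_sim_config <- function(n_per_channel = 100L, dimer_fraction = 0.3,
                                  d_monomer = 0.1, d_dimer = 0.05,
                                  dt = 0.032, frames = 150L,
                                  precision = 0.02, field = 20,
                                  seed = 1L) {
  stopifnot(dimer_fraction >= 0, dimer_fraction <= 1,
            d_monomer >= 0, d_dimer >= 0, dt > 0, frames >= 2, field > 0)
  out <- list(n_per_channel = as.integer(n_per_channel),
              dimer_fraction = dimer_fraction, d_monomer = d_monomer,
              d_dimer = d_dimer, dt = dt, frames = as.integer(frames),
              precision = precision, field = field, seed = as.integer(seed))
  class(out) <- "TrajectorySimConfig"
  out
}

brownian_path <- function(frames, d, dt, field, start) {
  step_sd <- sqrt(2 * d * dt)
  xy <- matrix(0, frames, 2)
  xy[1, ] <- start
  if (frames > 1) {
    steps <- matrix(stats::rnorm(2 * (frames - 1), 0, step_sd), ncol = 2)
    xy[, 1] <- start[1] + c(0, cumsum(steps[, 1]))
    xy[, 2] <- start[2] + c(0, cumsum(steps[, 2]))
  }
  # reflecting boundaries on [0, field]
  reflect <- function(v) {
    v <- v %% (2 * field)
    ifelse(v > field, 2 * field - v, v)
  }
  cbind(reflect(xy[, 1]), reflect(xy[, 2]))
}

#' Simulate a dual-color single-molecule field
#'
#' Monomers diffuse independently per channel; each dimer carries one
#' emitter per channel moving on an identical Brownian path. Gaussian
#' localization noise of the configured precision is added per frame and
#' axis. Ground-truth identities and dimer pairings are returned.
#'
#' @param config a [trajectory_sim_config()].
#' @return list with `localizations` (data.frame: frame, x, y, channel,
#'   true_id) and `truth` (data.frame: true_id_a, true_id_b for dimers,
#'   plus counts in attributes).
#' @export
simulate_two_channel_field <- function(config) {
  stopifnot(inherits(config, "TrajectorySimConfig"))
  set.seed(config$seed)
  n <- config$n_per_channel
  n_dim <- round(config$dimer_fraction * n)
  n_mono <- n - n_dim
  loc <- list()
  emit <- function(path, channel, id) {
    noisy <- path + matrix(stats::rnorm(length(path), 0, config$precision),
                           ncol = 2)
    data.frame(frame = seq_len(config$frames) - 1L,
               x = noisy[, 1], y = noisy[, 2],
               channel = channel, true_id = id, stringsAsFactors = FALSE)
  }
  id <- 0L
  truth <- data.frame(true_id_a = integer(), true_id_b = integer())
  for (k in seq_len(n_dim)) {
    start <- stats::runif(2, 0, config$field)
    path <- brownian_path(config$frames, config$d_dimer, config$dt,
                          config$field, start)
    ida <- (id <- id + 1L); idb <- (id <- id + 1L)
    loc[[length(loc) + 1L]] <- emit(path, "A", ida)
    loc[[length(loc) + 1L]] <- emit(path, "B", idb)
    truth <- rbind(truth, data.frame(true_id_a = ida, true_id_b = idb))
  }
  for (ch in c("A", "B")) {
    for (k in seq_len(n_mono)) {
      start <- stats::runif(2, 0, config$field)
      path <- brownian_path(config$frames, config$d_monomer, config$dt,
                            config$field, start)
      loc[[length(loc) + 1L]] <- emit(path, ch, (id <- id + 1L))
    }
  }
  localizations <- do.call(rbind, loc)
  attr(truth, "n_dimers") <- n_dim
  attr(truth, "n_per_channel") <- n
  list(localizations = localizations, truth = truth)
}

#' Random sequence pool around a template
#'
#' Draws unique amino-acid variants differing from the template only at the
#' given mutable positions, sampling uniformly from the allowed alphabet.
#' Mirrors an in-silico combinatorial design output pool.
#'
#' @param template amino-acid string.
#' @param n number of unique variants requested (template included in the
#'   diversity bound but not automatically in the pool).
#' @param positions mutable positions (1-based).
#' @param alphabet allowed letters; default all proteinogenic amino acids
#'   except G, P and C (17 letters).
#' @param seed RNG seed.
#' @return character vector of `n` unique sequences.
#' @export
make_sequence_pool <- function(template, n, positions,
                               alphabet = setdiff(strsplit(
                                 "ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 c("G", "P", "C")),
                               seed = 1L) {
  stopifnot(n >= 1)
  tl <- strsplit(template, "")[[1]]
  if (length(positions) && max(positions) > length(tl))
    stop("mutable positions outside template length")
  diversity <- length(alphabet)^length(positions)
  if (n > diversity)
    stop("requested ", n, " variants exceeds diversity ", diversity)
  set.seed(seed)
  seen <- character(0)
  while (length(seen) < n) {
    v <- tl
    v[positions] <- sample(alphabet, length(positions), replace = TRUE)
    s <- paste(v, collapse = "")
    if (!s %in% seen) seen <- c(seen, s)
  }
  seen
}

#' Simulate dose-response plates from a known 4PL truth
#'
#' Generates replicate concentration-response series from a four-parameter
#' logistic curve with multiplicative-scale Gaussian noise, plus positive
#' and negative control wells, emulating a proliferation /
#' competitive-inhibition plate readout.
#'
#' @param params list or `FourPLParams` with bottom, top, ec50, hill.
#' @param concentrations dose grid (M; may include 0).
#' @param n_replicates number of replicate series.
#' @param noise_frac Gaussian noise SD as a fraction of the top-bottom span.
#' @param n_controls control wells per kind.
#' @param seed RNG seed.
#' @return list of replicate data.frames (concentration, response) with
#'   attributes `pos_ctrl` and `neg_ctrl` (numeric control readouts).
#' @export
simulate_dose_response <- function(params, concentrations, n_replicates = 3,
                                   noise_frac = 0.05, n_controls = 6,
                                   seed = 1L) {
  set.seed(seed)
  span <- abs(params$top - params$bottom)
  reps <- lapply(seq_len(n_replicates), function(r) {
    mu <- fourpl_eval(params, concentrations)
    data.frame(concentration = concentrations,
               response = mu + stats::rnorm(length(mu), 0, noise_frac * span))
  })
  hi <- max(params$top, params$bottom)
  lo <- min(params$top, params$bottom)
  attr(reps, "pos_ctrl") <- hi + stats::rnorm(n_controls, 0, noise_frac * span)
  attr(reps, "neg_ctrl") <- lo + stats::rnorm(n_controls, 0, noise_frac * span)
  reps
}
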