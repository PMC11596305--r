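#' Binding-site definition
#'
#' An ordered set of (position, target amino acid) entries defining a
#' receptor-binding site on the source face of the bundle, e.g. the
#' site-II-mimicking patch carried on helices 2/3.
#'
#' @param positions residue positions (template numbering).
#' @param aa one-letter target amino acids, same length.
#' @param role `"primary"` or `"secondary"`.
#' @param reference free-text label of the source site.
#' @return a `BindingSite`.
#' @export
binding_site <- function(positions, aa, role = c("primary", "secondary"),
                         reference = "") {
  role <- match.arg(role)
  if (length(positions) != length(aa))
    stop("positions and aa must have equal length")
  if (anyDuplicated(positions)) stop("binding-site positions must be unique")
  aa <- toupper(aa)
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    stop("amino acids must be one-letter codes from the 20-letter alphabet")
  out <- list(positions = as.integer(positions), aa = aa, role = role,
              reference = reference)
  class(out) <- "BindingSite"
  out
}

helix_of <- function(annotation, resno) {
  h <- which(annotation$start <= resno & annotation$end >= resno)
  if (length(h) != 1L) return(NA_integer_)
  h
}

#' Map positions between the pseudosymmetric faces of a four-helix bundle
#'
#' Maps residue positions on the H2/H3 (source) face onto the H1/H4
#' (destination) face. The source helix-pair C-alpha trace is best-fit
#' superposed onto the destination pair under the helix pairing selected by
#' `orientation` ("parallel": rotation about the bundle axis, H2->H4 and
#' H3->H1, axial sense of the site preserved; "antiparallel": two-fold
#' rotation about an in-plane axis, H2->H1 and H3->H4, axial sense
#' inverted; both traverse the destination helices co-directionally). Each
#' transformed source C-alpha is then matched to its nearest destination
#' C-alpha (greedy by distance, bijective, 3.5 A cutoff) and the matched
#' destination residue is shifted by `register_offset` along its helix.
#'
#' @param bundle a `Structure` (the helical bundle).
#' @param annotation helix annotation data.frame (helix, chain, start, end,
#'   direction), as from [make_ideal_bundle()].
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param register_offset integer residue shift along the destination helix.
#' @param positions source positions to map; default all residues of H2/H3.
#' @param max_ca_dist nearest-neighbor acceptance cutoff (A).
#' @return data.frame: `source`, `dest`, `dest_helix`, `dist` (A, before
#'   the register shift).
#' @export
map_pseudosymmetric_positions <- function(bundle, annotation,
                                          orientation = c("parallel",
                                                          "antiparallel"),
                                          register_offset = 0L,
                                          positions = NULL,
                                          max_ca_dist = 3.5) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(bundle, "Structure"), nrow(annotation) == 4)
  seg <- function(h) annotation$start[h]:annotation$end[h]
  # Two pseudosymmetries relate the faces of an up-down-up-down bundle:
  # a rotation about the bundle axis (axial sense of the site preserved,
  # "parallel"), pairing H2->H4 and H3->H1; and a two-fold rotation about
  # an in-plane axis (axial sense inverted, "antiparallel"), pairing
  # H2->H1 and H3->H4. Both traverse destination helices co-directionally.
  pair_src <- list(seg(2), seg(3))
  pair_dst <- if (orientation == "parallel") list(seg(4), seg(1))
              else list(seg(1), seg(4))
  src_res <- integer(0); dst_res <- integer(0)
  for (k in 1:2) {
    L <- min(length(pair_src[[k]]), length(pair_dst[[k]]))
    src_res <- c(src_res, pair_src[[k]][seq_len(L)])
    dst_res <- c(dst_res, pair_dst[[k]][seq_len(L)])
  }
  ch <- annotation$chain[1]
  ca <- function(res) gather_backbone(bundle, rep(ch, length(res)), res,
                                      "CA", "bundle")
  sp <- kabsch_superpose(ca(src_res), ca(dst_res))
  if (is.null(positions)) positions <- c(seg(2), seg(3))
  bad <- positions[!positions %in% c(seg(2), seg(3))]
  if (length(bad))
    stop("source positions not on helices 2/3: ", paste(bad, collapse = ", "))
  moved <- apply_superposition(sp, ca(positions))
  dest_all <- c(seg(1), seg(4))
  dest_xyz <- ca(dest_all)
  dmat <- sqrt(pmax(outer(rowSums(moved^2), rowSums(dest_xyz^2), "+") -
                      2 * moved %*% t(dest_xyz), 0))
  # greedy bijective assignment by increasing distance
  assign_src <- rep(NA_integer_, length(positions))
  assign_d <- rep(NA_real_, length(positions))
  ord <- order(dmat)
  taken_dst <- logical(length(dest_all))
  done_src <- logical(length(positions))
  for (k in ord) {
    i <- (k - 1) %% nrow(dmat) + 1
    j <- (k - 1) %/% nrow(dmat) + 1
    if (done_src[i] || taken_dst[j]) next
    if (dmat[i, j] > max_ca_dist) break
    assign_src[i] <- dest_all[j]
    assign_d[i] <- dmat[i, j]
    done_src[i] <- TRUE
    taken_dst[j] <- TRUE
  }
  if (any(!done_src))
    stop("unmatched source positions (no destination C-alpha within ",
         max_ca_dist, " A): ",
         paste(positions[!done_src], collapse = ", "))
  dest_helix <- vapply(assign_src, function(r) helix_of(annotation, r), 1L)
  dest <- assign_src + as.integer(register_offset)
  ok <- dest >= annotation$start[dest_helix] & dest <= annotation$end[dest_helix]
  if (any(!ok))
    stop("register offset ", register_offset,
         " pushes mapped positions outside destination helices: ",
         paste(positions[!ok], collapse = ", "))
  data.frame(source = positions, dest = dest, dest_helix = dest_helix,
             dist = assign_d)
}

#' Optimize the graft register
#'
#' Exhaustively scans integer register offsets in `[-half_width, half_width]`
#' and returns the offset minimizing the backbone RMSD (local best fit of
#' C-alphas) between the reference site geometry and the candidate
#' destination patch. The reference defaults to the site's own backbone on
#' the source face; supplying external reference coordinates (e.g. the
#' native receptor-binding site the graft must reproduce) anchors the
#' optimum independently of the site definition. Ties are broken toward
#' smaller absolute offset, then toward the negative offset.
#'
#' @param bundle,annotation,orientation as in
#'   [map_pseudosymmetric_positions()].
#' @param site a [binding_site()] whose positions lie on H2/H3.
#' @param half_width scan half-width in residues (default 4).
#' @param reference_xyz optional N x 3 matrix of reference site C-alpha
#'   coordinates (N = number of site positions).
#' @return list with `offset`, `rmsd`, and the full `scan` data.frame
#'   (offset, rmsd, feasible).
#' @export
optimize_register <- function(bundle, annotation, site,
                              orientation = c("parallel", "antiparallel"),
                              half_width = 4L, reference_xyz = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(site, "BindingSite"))
  offsets <- seq.int(-half_width, half_width)
  ch <- annotation$chain[1]
  src_xyz <- if (is.null(reference_xyz))
    gather_backbone(bundle, rep(ch, length(site$positions)),
                    site$positions, "CA", "bundle")
  else as.matrix(reference_xyz)
  if (nrow(src_xyz) != length(site$positions))
    stop("reference_xyz must have one row per site position")
  scan <- data.frame(offset = offsets, rmsd = NA_real_, feasible = FALSE)
  for (i in seq_along(offsets)) {
    mp <- tryCatch(
      map_pseudosymmetric_positions(bundle, annotation, orientation,
                                    offsets[i], positions = site$positions),
      error = function(e) NULL)
    if (is.null(mp)) next
    dst_xyz <- gather_backbone(bundle, rep(ch, nrow(mp)), mp$dest,
                               "CA", "bundle")
    scan$rmsd[i] <- kabsch_superpose(src_xyz, dst_xyz)$rmsd
    scan$feasible[i] <- TRUE
  }
  if (!any(scan$feasible))
    stop("no feasible register offset in the scanned window")
  feas <- scan[scan$feasible, ]
  # argmin; ties -> smaller |offset|, then negative
  ord <- order(feas$rmsd, abs(feas$offset), feas$offset)
  best <- feas[ord[1], ]
  list(offset = best$offset, rmsd = best$rmsd, scan = scan)
}

#' Apply a graft mutation set to a template sequence
#'
#' Substitutes the target amino acids at the mapped destination positions;
#' all other positions are untouched and length is preserved.
#'
#' @param template amino-acid string.
#' @param positions destination positions (1-based).
#' @param aa one-letter amino acids, same length as `positions`.
#' @return mutated sequence string.
#' @export
apply_graft <- function(template, positions, aa) {
  if (length(positions) != length(aa))
    stop("positions and aa must have equal length")
  if (!length(positions)) return(template)
  tl <- strsplit(template, "")[[1]]
  if (any(positions < 1 | positions > length(tl)))
    stop("destination positions outside sequence length")
  if (anyDuplicated(positions)) {
    dup <- unique(positions[duplicated(positions)])
    conflicting <- vapply(dup, function(p)
      length(unique(aa[positions == p])) > 1, logical(1))
    if (any(conflicting))
      stop("position collision: multiple sources map to destination ",
           paste(dup[conflicting], collapse = ", "))
  }
  tl[positions] <- aa
  paste(tl, collapse = "")
}

#' Graft a binding site onto the pseudosymmetric face
#'
#' Convenience wrapper: optimizes the register, maps the site positions,
#' and emits the mutated sequence.
#'
#' @inheritParams optimize_register
#' @param template template amino-acid sequence; position i of the sequence
#'   corresponds to residue number i of the bundle numbering.
#' @return a `GraftResult`: mutated_sequence, mapping (data.frame),
#'   register offset and site RMSD at the optimum.
#' @export
graft_site <- function(bundle, annotation, site, template,
                       orientation = c("parallel", "antiparallel"),
                       half_width = 4L) {
  orientation <- match.arg(orientation)
  opt <- optimize_register(bundle, annotation, site, orientation, half_width)
  mp <- map_pseudosymmetric_positions(bundle, annotation, orientation,
                                      opt$offset, positions = site$positions)
  seq_out <- apply_graft(template, mp$dest, site$aa)
  out <- list(mutated_sequence = seq_out, mapping = mp,
              register_offset = opt$offset, site_rmsd = opt$rmsd,
              orientation = orientation)
  class(out) <- "GraftResult"
  out
}

#' @export
print.GraftResult <- function(x, ...) {
  cat(sprintf("GraftResult: %s graft, offset %+d, site rmsd %.3f A, %d mutations\n",
              x$orientation, x$register_offset, x$site_rmsd, nrow(x$mapping)))
  invisible(x)
}

#' Assess primary and secondary site geometry of a model
#'
#' Backbone RMSD of the model's primary- and secondary-site residues
#' against the corresponding residues of a reference structure (e.g. the
#' native cytokine's receptor-binding site II).
#'
#' @param model,reference `Structure` objects.
#' @param primary_pairs,secondary_pairs paired-residue data.frames as in
#'   [backbone_rmsd()].
#' @param atoms backbone atom set (default C-alpha only).
#' @param fit local best-fit (TRUE, default) or current-frame RMSD.
#' @return list with `primary` and `secondary` RMSDs (A).
#' @export
assess_graft_sites <- function(model, reference, primary_pairs,
                               secondary_pairs, atoms = "CA", fit = TRUE) {
  list(primary = backbone_rmsd(model, reference, primary_pairs, atoms, fit),
       secondary = backbone_rmsd(model, reference, secondary_pairs, atoms, fit))
}

#' Inter-TMD spacing of ternary complex models
#'
#' For each model, measures the Euclidean distance between the two receptor
#' anchor atoms: by default the C-alpha of the most C-terminal resolved
#' residue of each receptor chain (the membrane-proximal end of the modeled
#' ectodomain). Reports per-model distances, ensemble mean and sample SD.
#'
#' @param models list of `Structure` ternary-complex models.
#' @param receptor_chains the two receptor chain ids.
#' @param anchor_residues optional named list (chain -> residue number)
#'   overriding the most-C-terminal default.
#' @return `SpacingEstimate`: list(distances, mean, sd).
#' @export
inter_tmd_spacing <- function(models, receptor_chains = c("R", "S"),
                              anchor_residues = NULL) {
  if (inherits(models, "Structure")) models <- list(models)
  if (!length(models)) stop("need at least one model")
  stopifnot(length(receptor_chains) == 2)
  anchor <- function(s, chain) {
    at <- s$atoms[s$atoms$chain == chain & s$atoms$atom == "CA", ]
    if (!nrow(at)) stop("receptor chain '", chain,
                        "' missing (or has no C-alpha atoms)")
    r <- if (!is.null(anchor_residues) && chain %in% names(anchor_residues))
      anchor_residues[[chain]] else max(at$resno)
    row <- at[at$resno == r, ]
    if (nrow(row) != 1L) stop("anchor residue ", r, " not resolvable in chain ",
                              chain)
    c(row$x, row$y, row$z)
  }
  d <- vapply(models, function(s)
    sqrt(sum((anchor(s, receptor_chains[1]) -
                anchor(s, receptor_chains[2]))^2)), 1.0)
  out <- list(distances = d, mean = mean(d),
              sd = if (length(d) > 1) stats::sd(d) else 0)
  class(out) <- "SpacingEstimate"
  out
}

#' @export
print.SpacingEstimate <- function(x, ...) {
  cat(sprintf("Inter-TMD spacing: %.1f +/- %.1f A (n = %d)\n",
              x$mean, x$sd, length(x$distances)))
  invisible(x)
}
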