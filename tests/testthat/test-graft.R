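bundle <- make_ideal_bundle(n_res = 24)
bs <- bundle$structure
ann <- bundle$annotation
site_pos <- c(ann$start[2] + c(2:7), ann$start[3] + c(2:7))

test_that("face mapping is bijective, tight on the ideal bundle, and matches an exhaustive oracle", {
  for (orient in c("parallel", "antiparallel")) {
    mp <- map_pseudosymmetric_positions(bs, ann, orient, 0)
    # bijection: no duplicated destinations, inverse recovers sources
    expect_false(anyDuplicated(mp$dest) > 0)
    expect_false(anyDuplicated(mp$source) > 0)
    # ideal bundle: every mapped C-alpha pair within 2 A after superposition
    expect_lt(max(mp$dist), 2.0)
    # exhaustive nearest-neighbor oracle: brute-force closest destination
    seg <- function(h) ann$start[h]:ann$end[h]
    src <- c(seg(2), seg(3)); dst <- c(seg(1), seg(4))
    # NB: keep request order (select_atoms returns file order)
    ca <- function(res) t(vapply(res, function(r)
      unlist(bs$atoms[bs$atoms$resno == r & bs$atoms$atom == "CA",
                      c("x", "y", "z")]), numeric(3)))
    pr_dst <- if (orient == "parallel") c(seg(4), seg(1)) else c(seg(1), seg(4))
    sp <- kabsch_superpose(ca(src), ca(pr_dst))
    moved <- apply_superposition(sp, ca(src))
    dxyz <- ca(dst)
    nearest <- vapply(seq_along(src), function(i) {
      d <- sqrt(rowSums(sweep(dxyz, 2, moved[i, ])^2))
      dst[which.min(d)]
    }, 1L)
    expect_equal(mp$dest[match(src, mp$source)], nearest)
  }
})

test_that("parallel and antiparallel mappings differ and offsets shift destinations", {
  mp <- map_pseudosymmetric_positions(bs, ann, "parallel", 0)
  mpa <- map_pseudosymmetric_positions(bs, ann, "antiparallel", 0)
  expect_false(identical(mp$dest[order(mp$source)],
                         mpa$dest[order(mpa$source)]))
  mp1 <- map_pseudosymmetric_positions(bs, ann, "parallel", 1,
                                       positions = site_pos)
  mp0 <- map_pseudosymmetric_positions(bs, ann, "parallel", 0,
                                       positions = site_pos)
  expect_equal(mp1$dest, mp0$dest + 1L)
  # offset pushing positions off the helix errors
  expect_error(
    map_pseudosymmetric_positions(bs, ann, "parallel", 30,
                                  positions = site_pos),
    "outside destination helices")
})

test_that("register optimizer: pre-aligned optimum, constructed inverse, exhaustive-scan oracle", {
  site <- binding_site(site_pos, rep("W", length(site_pos)))
  ref_xyz <- coords(select_atoms(bs, residues = site_pos, atoms = "CA"))
  for (orient in c("parallel", "antiparallel")) {
    opt <- optimize_register(bs, ann, site, orient)
    expect_equal(opt$offset, 0L)
    expect_lt(opt$rmsd, 1e-6)
    # rmsd at the optimum <= every other scanned offset
    feas <- opt$scan[opt$scan$feasible, ]
    expect_true(all(opt$rmsd <= feas$rmsd + 1e-12))
    # site definition shifted +2 along the source helices, reference fixed
    site2 <- binding_site(site_pos + 2L, rep("W", length(site_pos)))
    opt2 <- optimize_register(bs, ann, site2, orient,
                              reference_xyz = ref_xyz)
    expect_equal(opt2$offset, -2L)
    # independent exhaustive re-scan agrees
    oracle <- register_scan_oracle(bs, ann, site2, orient, 4, ref_xyz)
    expect_equal(opt2$offset, oracle$offset)
    expect_equal(opt2$rmsd, oracle$rmsd, tolerance = 1e-9)
  }
  # destination helices truncated: site near the source helix ends has no
  # destination coverage at any offset -> empty feasible window
  trunc <- bundle
  keep <- !(trunc$structure$atoms$resno %in%
              c((ann$end[1] - 9):ann$end[1], (ann$end[4] - 9):ann$end[4]))
  trunc$structure <- structure_from_atoms(trunc$structure$atoms[keep, ])
  trunc$annotation$end[c(1, 4)] <- trunc$annotation$end[c(1, 4)] - 10L
  far_site <- binding_site(c(ann$end[2] - 2:0, ann$end[3] - 2:0), rep("A", 6))
  expect_error(optimize_register(trunc$structure, trunc$annotation, far_site,
                                 "antiparallel", half_width = 2L),
               "no feasible")
})

test_that("apply_graft substitutes exactly, preserves length, and is idempotent", {
  set.seed(5)
  template <- paste(sample(LETTERS[1:20], 60, replace = TRUE), collapse = "")
  expect_identical(apply_graft(template, integer(0), character(0)), template)
  pos <- c(3L, 17L, 44L)
  aa <- c("W", "W", "W")
  mut <- apply_graft(template, pos, aa)
  expect_equal(nchar(mut), nchar(template))
  hamming <- sum(strsplit(mut, "")[[1]] != strsplit(template, "")[[1]])
  expect_equal(hamming, 3)
  expect_identical(apply_graft(mut, pos, aa), mut)  # idempotent
  changed <- which(strsplit(mut, "")[[1]] != strsplit(template, "")[[1]])
  expect_true(all(changed %in% pos))
  expect_error(apply_graft(template, c(2L, 2L), c("A", "C")), "collision")
  expect_error(apply_graft(template, 100L, "A"), "outside sequence")
})

test_that("graft_site emits a mutated sequence at the mapped destinations", {
  site <- binding_site(site_pos, rep("W", length(site_pos)))
  template <- paste(rep("A", max(ann$end)), collapse = "")
  gr <- graft_site(bs, ann, site, template, "antiparallel")
  expect_equal(nchar(gr$mutated_sequence), nchar(template))
  mutated_at <- which(strsplit(gr$mutated_sequence, "")[[1]] != "A")
  expect_setequal(mutated_at, gr$mapping$dest)
  expect_true(all(gr$mapping$dest >= ann$start[1]))
})

test_that("assess_graft_sites: self gives (0,0); noised matches direct computation", {
  prim <- data.frame(chain_a = "A", resno_a = site_pos, chain_b = "A",
                     resno_b = site_pos)
  sec_pos <- c(ann$start[1] + c(2:7), ann$start[4] + c(2:7))
  sec <- data.frame(chain_a = "A", resno_a = sec_pos, chain_b = "A",
                    resno_b = sec_pos)
  self <- assess_graft_sites(bs, bs, prim, sec)
  expect_equal(self$primary, 0, tolerance = 1e-12)
  expect_equal(self$secondary, 0, tolerance = 1e-12)
  set.seed(97)
  noisy <- bs
  noisy$atoms[, c("x", "y", "z")] <-
    noisy$atoms[, c("x", "y", "z")] + rnorm(3 * nrow(noisy$atoms), sd = 0.3)
  got <- assess_graft_sites(bs, noisy, prim, sec)
  direct <- function(pairs) {
    xa <- coords(select_atoms(bs, residues = pairs$resno_a, atoms = "CA"))
    xb <- coords(select_atoms(noisy, residues = pairs$resno_b, atoms = "CA"))
    sp <- kabsch_superpose(xa, xb)
    sqrt(mean(rowSums((apply_superposition(sp, xa) - xb)^2)))
  }
  expect_lt(abs(got$primary - direct(prim)), 1e-12)
  expect_lt(abs(got$secondary - direct(sec)), 1e-12)
})

test_that("inter-TMD spacing: constructed distances, hand stats, isometry", {
  one <- inter_tmd_spacing(make_toy_complex(100))
  expect_equal(one$mean, 100, tolerance = 1e-6)
  expect_equal(one$sd, 0)
  d <- c(80, 84, 84, 86, 86)
  models <- lapply(d, make_toy_complex)
  est <- inter_tmd_spacing(models)
  expect_equal(est$mean, 84, tolerance = 1e-6)
  expect_equal(est$sd, sd(d), tolerance = 1e-6)
  expect_equal(est$distances, d, tolerance = 1e-6)
  # invariant under a common rigid transform of every model
  set.seed(3)
  rg <- random_rigid()
  moved <- lapply(models, apply_rigid_structure, rot = rg$rotation,
                  tr = rg$translation)
  est2 <- inter_tmd_spacing(moved)
  expect_equal(est2$distances, est$distances, tolerance = 1e-9)
  broken <- make_toy_complex(50)
  broken$atoms <- broken$atoms[broken$atoms$chain != "S", ]
  expect_error(inter_tmd_spacing(broken), "chain 'S' missing")
})
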