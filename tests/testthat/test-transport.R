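test_that("ligand files load with the documented anchor rules", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "argon", "Ar 0.0 0.0 0.0"), xyz)
  lig <- load_ligand(xyz)
  expect_equal(nrow(lig$atoms), 1)
  expect_equal(lig$anchor_index, 1)

  # diatomic tie: lower index wins
  xyz2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "dioxygen", "O 0 0 0", "O 0 0 1.21"), xyz2)
  lig2 <- load_ligand(xyz2)
  expect_equal(lig2$anchor_index, 1)

  # 5-atom toy: anchor matches a brute-force nearest-to-centroid scan
  set.seed(3)
  m <- matrix(round(runif(15, -2, 2), 3), ncol = 3)
  xyz5 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "toy",
               sprintf("C %.3f %.3f %.3f", m[, 1], m[, 2], m[, 3])), xyz5)
  lig5 <- load_ligand(xyz5)
  cen <- colMeans(m)
  expect_equal(lig5$anchor_index,
               which.min(sqrt(colSums((t(m) - cen)^2))))
  expect_equal(load_ligand(xyz5, anchor = 4)$anchor_index, 4)
  expect_error(load_ligand(xyz5, anchor = 9), class = "tunnelr_input_error")

  # PDB ligands go through the structure reader
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O1  LIG A   1       1.200   0.000   0.000  1.00  0.00           O",
    "END"), pdb)
  ligp <- load_ligand(pdb)
  expect_equal(nrow(ligp$atoms), 2)
  expect_equal(ligp$atoms$vdw_radius, unname(bondi_radii()[c("C", "O")]))
})

test_that("discretization spaces discs by delta and always includes the end", {
  mk <- function(L) tunnelr:::new_tunnel_set(tibble::tibble(
    id = 1L, exit_vertex = NA_integer_, cost_search = NA_real_,
    centerline = list(tibble::tibble(l = seq(0, L, by = 0.1),
                                     x = seq(0, L, by = 0.1),
                                     y = 0, z = 0, r = 1.5))))
  t4 <- compute_properties(mk(4))
  d4 <- discretize(t4, delta = 1.0)
  expect_equal(nrow(d4), 5)
  expect_equal(d4$arc_length, 0:4)

  t42 <- compute_properties(mk(4.2))
  d42 <- discretize(t42, delta = 1.0)
  expect_equal(nrow(d42), 6)
  expect_equal(d42$arc_length[6], 4.2)

  # straight +x centerline: all normals along +x, radius = r + margin
  expect_equal(unique(round(d4$nx, 9)), 1)
  expect_equal(unique(d4$radius), 1.5 + 1.0)
  expect_error(discretize(t4, delta = 5), class = "tunnelr_input_error")
  # consecutive arc steps equal delta (last disc may be shorter)
  expect_true(all(abs(diff(d42$arc_length)[1:4] - 1.0) < 1e-9))
})

test_that("the steric score matches its closed form", {
  lig <- make_toy_ligand("sphere")  # C, vdw 1.7
  rec1 <- assign_radii(tibble::tibble(
    serial = 1L, element = "C", name = "C", resname = "UNK", chain = "A",
    resno = 1L, ins = "", x = 3.4, y = 0, z = 0, is_hetero = FALSE,
    considered = TRUE))
  pose <- list(quat = c(1, 0, 0, 0), anchor = c(0, 0, 0))
  # at d = s: the well minimum, -eps
  expect_equal(score_pose(lig, pose, rec1), -0.2, tolerance = 1e-12)
  # zero crossing at d = s * 2^(-1/6)
  rec0 <- dplyr::mutate(rec1, x = 3.4 * 2^(-1 / 6))
  expect_equal(score_pose(lig, pose, rec0), 0, tolerance = 1e-12)
  # beyond the 8 A cutoff: empty sum
  recf <- dplyr::mutate(rec1, x = 8.5)
  expect_equal(score_pose(lig, pose, recf), 0)
  # pair cap at +10
  recc <- dplyr::mutate(rec1, x = 0.3)
  expect_equal(score_pose(lig, pose, recc), 10)
})

test_that("on-disc optimization matches a dense in-plane grid for a point ligand", {
  h <- fix_constricted()
  discs <- discretize(h$rep1, delta = 0.3)
  lig <- make_toy_ligand("sphere")
  s <- h$fx$structure
  for (i in c(2L, nrow(discs) %/% 2L, nrow(discs) - 1L)) {
    disc <- discs[i, ]
    pose <- optimize_on_disc(lig, disc, s, n_starts = 24, seed = 5)
    # 0.2 A polar grid over the disc
    rr <- seq(0, disc$radius, by = 0.2)
    grid <- do.call(rbind, lapply(rr, function(r0) {
      nth <- max(1, ceiling(2 * pi * r0 / 0.2))
      th <- seq(0, 2 * pi, length.out = nth + 1)[-1]
      cbind(r0 * cos(th), r0 * sin(th))
    }))
    e1 <- c(disc$e1x, disc$e1y, disc$e1z)
    e2 <- c(disc$e2x, disc$e2y, disc$e2z)
    cenp <- c(disc$cx, disc$cy, disc$cz)
    es <- apply(grid, 1, function(uv) {
      score_pose(lig, list(quat = c(1, 0, 0, 0),
                           anchor = cenp + uv[1] * e1 + uv[2] * e2), s)
    })
    expect_lte(pose$energy, min(es) + 0.1)
  }
})

test_that("the optimizer dominates random feasible poses and is idle in vacuum", {
  h <- fix_constricted()
  discs <- discretize(h$rep1, delta = 0.3)
  lig <- make_toy_ligand("diatomic", 1.5)
  s <- h$fx$structure
  disc <- discs[nrow(discs) %/% 2L, ]
  pose <- optimize_on_disc(lig, disc, s, n_starts = 24, seed = 5)
  e1 <- c(disc$e1x, disc$e1y, disc$e1z)
  e2 <- c(disc$e2x, disc$e2y, disc$e2z)
  cenp <- c(disc$cx, disc$cy, disc$cz)
  rand <- withr::with_seed(99, {
    replicate(100, {
      r0 <- sqrt(runif(1)) * disc$radius
      th <- runif(1, 0, 2 * pi)
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- runif(1, 0, pi)
      q <- c(cos(ang / 2), sin(ang / 2) * ax)
      score_pose(lig, list(quat = q,
                           anchor = cenp + r0 * cos(th) * e1 +
                             r0 * sin(th) * e2), s)
    })
  })
  expect_lte(pose$energy, min(rand) + 1e-9)

  # disc far from any receptor atom: energy 0
  vac <- disc
  vac$cx <- 500; vac$cy <- 500; vac$cz <- 500
  pose0 <- optimize_on_disc(lig, vac, s, n_starts = 4, seed = 1)
  expect_equal(pose0$energy, 0)
})

test_that("profiles are seed-deterministic and direction-aware", {
  h <- fix_constricted()
  discs <- discretize(h$rep1, delta = 0.5)
  lig <- make_toy_ligand("sphere")
  s <- h$fx$structure
  a <- lower_bound_profile(lig, discs, s, direction = "in", seed = 3)
  b <- lower_bound_profile(lig, discs, s, direction = "in", seed = 3)
  expect_identical(a$entries, b$entries)
  # "in" runs mouth -> site: arc length decreasing
  expect_true(all(diff(a$entries$arc_length) < 0))
  o <- lower_bound_profile(lig, discs, s, direction = "out", seed = 3)
  expect_true(all(diff(o$entries$arc_length) > 0))
  # same discs, same seed: identical per-disc energies either way
  expect_equal(sort(o$entries$energy), sort(a$entries$energy))
})

test_that("upper-bound energies dominate the lower bound disc by disc", {
  h <- fix_channel()
  rep1 <- detect_rep1(h)
  discs <- discretize(rep1, delta = 0.3)
  s <- h$fx$structure
  for (lig in list(make_toy_ligand("sphere"), make_toy_ligand("diatomic", 1.5))) {
    up <- upper_bound_profile(lig, discs, s, direction = "in", seed = 7)
    # a failed continuous path is a legal outcome; the bound ordering must
    # hold on every disc the pass computed
    expect_true(up$status %in% c("done", "failed"))
    m <- nrow(up$entries)
    gap <- up$entries$energy - up$lower$entries$energy[seq_len(m)]
    expect_true(all(gap >= -1e-6))
  }
  # single-atom ligand: rotation is irrelevant, bounds coincide
  up1 <- upper_bound_profile(make_toy_ligand("sphere"), discs, s,
                             direction = "in", seed = 7)
  expect_lt(max(abs(up1$entries$energy - up1$lower$entries$energy)), 1e-6)
})

test_that("profile maxima track the constriction and respond to ligand size", {
  h <- fix_constricted()
  discs <- discretize(h$rep1, delta = 0.3)
  lo <- lower_bound_profile(make_toy_ligand("sphere"), discs,
                            h$fx$structure, direction = "in", seed = 7)
  ent <- lo$entries
  ax <- h$fx$truth$channel_axes[1, ]
  imax <- which.max(ent$energy)
  disc_max <- discs[discs$index == ent$disc_index[imax], ]
  z_max <- sum(c(disc_max$cx, disc_max$cy, disc_max$cz) * ax)
  expect_lte(abs(z_max - h$fx$truth$l_star), 0.3 + 0.1)

  # a fatter probe (Br vdw 1.85 vs C 1.70) never lowers the peak
  fat <- make_toy_ligand("sphere", element = "BR")
  lof <- lower_bound_profile(fat, discs, h$fx$structure, direction = "in",
                             seed = 7)
  expect_gte(max(lof$entries$energy), max(ent$energy))
})

test_that("an over-long rod either spikes above its lower bound or fails", {
  h <- fix_constricted()
  discs <- discretize(h$rep1, delta = 0.3)
  rod <- make_toy_ligand("rod3", 1.4)  # end-to-end 2.8 A > constriction diameter
  up <- upper_bound_profile(rod, discs, h$fx$structure, direction = "in",
                            seed = 7, max_rotation = 10)
  if (up$status == "done") {
    m <- nrow(up$entries)
    expect_gte(max(up$entries$energy), max(up$lower$entries$energy[seq_len(m)]))
  } else {
    expect_equal(up$status, "failed")
    expect_lt(nrow(up$entries), nrow(discs))
  }
})

test_that("barrier extraction follows the explicit and automatic rules", {
  # energies given in site -> mouth order (arc length ascending)
  mk_prof <- function(e, direction = "in") {
    n <- length(e)
    tunnelr:::new_profile(tibble::tibble(
      disc_index = seq_len(n), arc_length = seq(0, n - 1), energy = e,
      anchor_x = 0, anchor_y = 0, anchor_z = 0,
      quat_w = 1, quat_x = 0, quat_y = 0, quat_z = 0),
      direction, "lower_bound")
  }
  # energies in site -> mouth order: [-2, 0, 3, 1, -1]
  p <- mk_prof(c(-2, 0, 3, 1, -1))
  b <- barrier_analysis(p, i_B = 1, i_MAX = 3, i_S = 5)$barriers
  expect_equal(b$E_B, -2)
  expect_equal(b$E_MAX, 3)
  expect_equal(b$E_S, -1)
  expect_equal(b$Ea, 3 - (-1))
  expect_equal(b$dE_bind, -2 - (-1))

  # flat zero profile: all differences vanish
  z <- barrier_analysis(mk_prof(rep(0, 10)))$barriers
  expect_equal(z$Ea, 0)
  expect_equal(z$dE_bind, 0)

  # monotonically decreasing site -> mouth: E_MAX at the site end, Ea >= 0
  d <- barrier_analysis(mk_prof(seq(5, -5, length.out = 11)))$barriers
  expect_equal(d$i_MAX, d$i_B)
  expect_gte(d$Ea, 0)
  expect_gte(d$E_MAX, max(d$E_B, d$E_S))

  # auto rules agree with explicit indices at the auto argmin/argmax
  e <- c(-3, -1, 2, 6, 1, -0.5, -2)
  auto <- barrier_analysis(mk_prof(e))$barriers
  expl <- barrier_analysis(mk_prof(e), i_B = auto$i_B, i_MAX = auto$i_MAX,
                           i_S = auto$i_S)$barriers
  expect_equal(auto[c("E_B", "E_MAX", "E_S", "Ea", "dE_bind")],
               expl[c("E_B", "E_MAX", "E_S", "Ea", "dE_bind")])
  expect_error(barrier_analysis(mk_prof(e), i_B = 99),
               class = "tunnelr_input_error")

  # direction governs which minimum anchors the activation energy
  po <- barrier_analysis(mk_prof(c(-2, 0, 3, 1, -1), direction = "out"),
                         i_B = 1, i_MAX = 3, i_S = 5)$barriers
  expect_equal(po$Ea, 3 - (-2))
})

test_that("profile tidiers and plots expose the barrier annotations", {
  h <- fix_constricted()
  discs <- discretize(h$rep1, delta = 0.5)
  lo <- barrier_analysis(lower_bound_profile(
    make_toy_ligand("sphere"), discs, h$fx$structure, seed = 2))
  gl <- glance(lo)
  expect_equal(gl$status, "done")
  expect_false(any(is.na(unlist(gl[c("E_B", "E_MAX", "E_S", "Ea")]))))
  td <- tidy(lo)
  expect_equal(nrow(td), nrow(discs))
  expect_s3_class(autoplot(lo), "ggplot")
})
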