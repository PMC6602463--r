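mk_structure <- function(df) {
  n <- nrow(df)
  assign_radii(tibble::tibble(
    serial = seq_len(n),
    element = df$element,
    name = df$element,
    resname = col_or(df, "resname", "UNK"),
    chain = col_or(df, "chain", "A"),
    resno = df$resno,
    ins = "",
    x = df$x, y = df$y, z = df$z,
    is_hetero = col_or(df, "is_hetero", FALSE),
    considered = TRUE))
}

test_that("residue starting points are means of per-residue mass centres", {
  s <- mk_structure(tibble::tibble(
    element = "C", resno = 1L, x = 1, y = 2, z = 3))
  expect_equal(start_from_residues(s, "A:1")$raw_point, c(1, 2, 3))

  s2 <- mk_structure(tibble::tibble(
    element = "C", resno = 1:2, x = c(0, 2), y = 0, z = 0))
  expect_equal(start_from_residues(s2, c("A:1", "A:2"))$raw_point, c(1, 0, 0))

  # two-residue toy: residue 1 = {C, O}, residue 2 = {N}; oracle computed as
  # unweighted mean over residues of mass-weighted centres
  s3 <- mk_structure(tibble::tibble(
    element = c("C", "O", "N"), resno = c(1L, 1L, 2L),
    x = c(0, 1, 5), y = 0, z = 0))
  m <- atomic_masses()
  com1 <- (m[["C"]] * 0 + m[["O"]] * 1) / (m[["C"]] + m[["O"]])
  expect_equal(start_from_residues(s3, c("A:1", "A:2"))$raw_point,
               c((com1 + 5) / 2, 0, 0), tolerance = 1e-6)
  expect_error(start_from_residues(s3, "B:9"), class = "tunnelr_input_error")
})

test_that("ligand starting points are mass-weighted centres of the group", {
  s <- mk_structure(tibble::tibble(
    element = c("C", "C"), resno = 50L, resname = "LIG", is_hetero = TRUE,
    x = 0, y = 0, z = c(0, 2)))
  expect_equal(start_from_ligand(s, "LIG")$raw_point, c(0, 0, 1))

  co <- mk_structure(tibble::tibble(
    element = c("C", "O"), resno = 51L, resname = "CMO", is_hetero = TRUE,
    x = c(0, 1), y = 0, z = 0))
  m <- atomic_masses()
  expect_equal(start_from_ligand(co, "CMO")$raw_point[1],
               m[["O"]] / (m[["C"]] + m[["O"]]), tolerance = 1e-6)
  expect_error(start_from_ligand(co, "XYZ", 999), class = "tunnelr_input_error")
  expect_error(start_from_ligand(co, "HOH"), class = "tunnelr_input_error")
})

test_that("a hemispherical dent is recovered as the top-ranked pocket", {
  dent <- make_dented_shell(dent_centers = c(0, 0, 8), dent_radius = 4,
                            r_outer = 8, lattice_spacing = 1.0, seed = 3)
  pk <- detect_pockets(dent$structure)
  expect_gte(nrow(pk), 1)
  cen <- unlist(pk[1, c("centroid_x", "centroid_y", "centroid_z")])
  expect_lt(sqrt(sum((cen - c(0, 0, 8))^2)), 2)
  # every alpha sphere is collision-free (brute force)
  sp <- pk$spheres[[1]]
  expect_true(all(brute_clearance(as.matrix(sp[, c("x", "y", "z")]),
                                  dent$structure) >= 0))
  # determinism incl. the Monte-Carlo volume
  expect_identical(pk, detect_pockets(dent$structure))

  # the pocket starting point lands in the dent region and, once snapped
  # to a Voronoi vertex, has positive clearance
  st <- start_from_pocket(pk[1, ], dent$structure)
  expect_equal(st$mode, "pocket")
  expect_lt(sqrt(sum((st$raw_point - c(0, 0, 8))^2)), dent$truth$dent_radius + 1)
  net <- label_bulk(build_network(dent$structure), 6, 0)
  snapped <- quiet_snap(st, net, maximal_distance = 3, desired_radius = 1)
  expect_gt(brute_clearance(matrix(snapped$snapped_point, 1),
                            dent$structure), 0)
})

test_that("pocket counts follow the dents: two apart, none on a solid ball", {
  two <- make_dented_shell(dent_centers = rbind(c(0, 0, 8), c(0, 0, -8)),
                           dent_radius = 4, r_outer = 8,
                           lattice_spacing = 1.0, seed = 3)
  pk2 <- detect_pockets(two$structure)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$rank, 1:2)

  solid <- make_dented_shell(dent_centers = NULL, r_outer = 8,
                             lattice_spacing = 1.0, seed = 3)
  expect_equal(nrow(detect_pockets(solid$structure)), 0)
})

test_that("catalytic residue lists flag the containing pocket", {
  dent <- make_dented_shell(dent_centers = c(0, 0, 8), dent_radius = 4,
                            r_outer = 8, lattice_spacing = 1.0, seed = 3)
  pk <- detect_pockets(dent$structure)
  res <- pk$residues[[1]]
  id <- sprintf("%s:%d", res$chain[1], res$resno[1])
  pk_cat <- detect_pockets(dent$structure, catalytic_residues = id)
  expect_true(pk_cat$catalytic[1])
  pk_no <- detect_pockets(dent$structure, catalytic_residues = "A:999999")
  expect_false(any(pk_no$catalytic))
})

test_that("snapping respects the maximal distance and prefers the desired radius", {
  h <- fix_channel()
  net <- h$net
  v <- net$vertices
  # a point exactly on a non-bulk vertex with sufficient clearance snaps to
  # it with zero displacement
  iv <- which(v$label == "interior" & v$clearance > 0.5)[100]
  st <- snap_to_vertex(c(v$x[iv], v$y[iv], v$z[iv]), net,
                       maximal_distance = 1, desired_radius = 0.3)
  expect_equal(st$snapped_vertex, v$id[iv])
  expect_lt(sqrt(sum((st$raw_point - st$snapped_point)^2)), 1e-9)

  # far in bulk solvent: no candidate within range
  expect_error(snap_to_vertex(c(50, 50, 50), net, maximal_distance = 3),
               class = "tunnelr_geometry_error")

  # fallback picks the largest clearance in range, with a warning, and the
  # result matches an exhaustive scan over vertices
  p <- c(0, 0, 0)
  expect_warning(st2 <- snap_to_vertex(p, net, maximal_distance = 5,
                                       desired_radius = 5.0),
                 "largest-clearance")
  d <- sqrt((v$x - p[1])^2 + (v$y - p[2])^2 + (v$z - p[3])^2)
  cand <- which(d <= 5 & v$label != "bulk")
  expect_equal(v$clearance[st2$snapped_vertex], max(v$clearance[cand]))
  expect_lte(sqrt(sum((st2$raw_point - st2$snapped_point)^2)), 5)

  # when qualifying vertices exist, the nearest one is chosen (brute scan)
  st3 <- snap_to_vertex(p, net, maximal_distance = 5, desired_radius = 1.0)
  ok <- cand[v$clearance[cand] >= 1.0]
  expect_equal(st3$snapped_vertex, ok[which.min(d[ok])])
})
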