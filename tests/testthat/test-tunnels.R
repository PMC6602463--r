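# build a tunnel set directly from a centerline for closed-form checks
toy_tunnel <- function(cl) {
  tunnelr:::new_tunnel_set(tibble::tibble(
    id = 1L, exit_vertex = NA_integer_, cost_search = NA_real_,
    centerline = list(cl)))
}

test_that("tunnel properties reproduce closed forms", {
  # straight line, constant r = 1, L = 4: cost = L / r^2 = 4
  l <- seq(0, 4, by = 0.1)
  t1 <- compute_properties(toy_tunnel(tibble::tibble(
    l = l, x = l, y = 0, z = 0, r = 1)))
  expect_equal(t1$length, 4)
  expect_equal(t1$curvature, 1)
  expect_equal(t1$cost, 4, tolerance = 1e-12)
  expect_equal(t1$throughput, exp(-4), tolerance = 1e-12)

  # piecewise radius: 2 A over the first 1 A, 1 A over the next 1 A
  eps <- 1e-12
  l2 <- c(0, 0.5, 1, 1 + eps, 1.5, 2)
  t2 <- compute_properties(toy_tunnel(tibble::tibble(
    l = l2, x = l2, y = 0, z = 0, r = c(2, 2, 2, 1, 1, 1))))
  expect_equal(t2$bottleneck_radius, 1)
  expect_equal(t2$cost, 1.25, tolerance = 1e-9)
  expect_equal(t2$throughput, exp(-1.25), tolerance = 1e-9)

  # semicircular centerline: curvature = pi * rho / (2 rho) = pi / 2
  th <- seq(0, pi, length.out = 721)
  rho <- 5
  arc <- rho * th
  t3 <- compute_properties(toy_tunnel(tibble::tibble(
    l = arc, x = rho * cos(th), y = rho * sin(th), z = 0, r = 1)))
  expect_equal(t3$curvature, pi / 2, tolerance = 1e-4)

  # coincident endpoints: curvature undefined
  lc <- c(0, 1, 2)
  expect_error(compute_properties(toy_tunnel(tibble::tibble(
    l = lc, x = c(0, 1, 0), y = 0, z = 0, r = 1))),
    class = "tunnelr_geometry_error")
})

test_that("a drilled channel yields a tunnel exiting along the drill axis", {
  h <- fix_channel()
  rep1 <- detect_rep1(h, probe = 0.9)
  cl <- rep1$centerline[[1]]
  n <- nrow(cl)
  # exit within 2 A laterally of the +z axis
  expect_lt(sqrt(cl$x[n]^2 + cl$y[n]^2), 2)
  expect_gt(cl$z[n], h$fx$truth$r_outer - 1)
  # bottleneck within a lattice spacing of the drilled radius
  expect_lt(abs(rep1$bottleneck_radius - 1.5), h$fx$truth$lattice_spacing)
  expect_lte(rep1$curvature, 1.15)
  # probe filter: the centerline radius never drops below the probe
  # (sampling tolerance: the filter and the profile sample at ~0.5 A)
  expect_gte(min(cl$r), 0.9 - 0.05)
  # arc length is strictly increasing from 0 to L
  expect_equal(cl$l[1], 0)
  expect_true(all(diff(cl$l) > 0))
  expect_equal(cl$l[n], rep1$length)
})

test_that("the probe radius filters narrow channels and monotonically prunes", {
  h <- fix_two_channel()
  t09 <- cluster_tunnels(compute_properties(
    find_tunnels(h$net, h$start$snapped_vertex, 0.9)), 3.5)
  t15 <- cluster_tunnels(compute_properties(
    find_tunnels(h$net, h$start$snapped_vertex, 1.5)), 3.5)
  expect_equal(length(unique(t09$cluster_id)), 2)
  expect_equal(length(unique(t15$cluster_id)), 1)
  expect_lte(nrow(t15), nrow(t09))
  # the survivor is the wide +z channel
  r1 <- t15[t15$priority_rank == 1 & t15$is_representative, ][1, ]
  ex <- r1$centerline[[1]][nrow(r1$centerline[[1]]), ]
  expect_gt(ex$z, 6)
  expect_lt(sqrt(ex$x^2 + ex$y^2), 2)
  # and the wide channel also ranks first when both are present
  w1 <- t09[t09$priority_rank == 1 & t09$is_representative, ][1, ]
  exw <- w1$centerline[[1]][nrow(w1$centerline[[1]]), ]
  expect_gt(exw$z, 6)
})

test_that("shrinking atom radii never decreases tunnel throughput", {
  h <- fix_channel()
  rep1 <- detect_rep1(h, probe = 0.9)
  shrunk <- dplyr::mutate(h$fx$structure, vdw_radius = vdw_radius - 0.2)
  net2 <- label_bulk(build_network(shrunk), 3, 4)
  st2 <- quiet_snap(c(0, 0, 0), net2)
  tun2 <- cluster_tunnels(compute_properties(
    find_tunnels(net2, st2$snapped_vertex, 0.9)), 3.5)
  rep2 <- tun2[tun2$is_representative & tun2$priority_rank == 1, ][1, ]
  expect_gte(rep2$throughput, rep1$throughput)
})

test_that("tunnel clustering merges near-duplicates and separates channels", {
  h <- fix_channel()
  tun <- compute_properties(find_tunnels(h$net, h$start$snapped_vertex, 0.9))
  # duplicate of the first tunnel perturbed by 0.1 A per point
  base <- tun[1, ]
  pert <- base
  pert$centerline <- list(dplyr::mutate(base$centerline[[1]], x = x + 0.1))
  pert$id <- nrow(tun) + 1L
  both <- tunnelr:::new_tunnel_set(dplyr::bind_rows(base, pert))
  both <- compute_properties(both)
  cl <- cluster_tunnels(both, 3.5)
  expect_equal(length(unique(cl$cluster_id)), 1)

  # singleton: one cluster, rank 1, representative
  single <- cluster_tunnels(compute_properties(base), 3.5)
  expect_equal(single$priority_rank, 1L)
  expect_true(single$is_representative)

  # ranking: representative of rank 1 has the maximal throughput overall
  all_cl <- cluster_tunnels(tun, 3.5)
  r1 <- all_cl[all_cl$priority_rank == 1 & all_cl$is_representative, ]
  expect_equal(r1$throughput, max(all_cl$throughput))
})

test_that("lining residues obey the closed boundary convention", {
  # single-atom structure at exactly r + vdw + cutoff from the sphere centre
  cl <- tibble::tibble(l = c(0, 1), x = c(0, 1), y = 0, z = 0, r = 1)
  tun <- compute_properties(toy_tunnel(cl))
  mk <- function(xpos) {
    assign_radii(tibble::tibble(
      serial = 1:5, element = "C", name = "C", resname = "UNK", chain = "A",
      resno = 1:5, ins = "",
      x = c(xpos, 100, 101, 102, 103), y = c(0, 0, 1, 2, 3), z = 0,
      is_hetero = FALSE, considered = TRUE))
  }
  # atom surface exactly at r(l) + cutoff from the sphere surface at (1,0,0):
  # boundary is closed, so it is included
  at <- mk(1 + 1 + 1.7 + 3.0)
  res <- lining_residues(tun, at, contact_cutoff = 3.0)
  expect_true(1L %in% res$lining$resno)
  # just beyond: excluded
  out <- mk(1 + 1 + 1.7 + 3.0 + 1e-3)
  res2 <- lining_residues(tun, out, contact_cutoff = 3.0)
  expect_false(1L %in% res2$lining$resno)
  # far structure: empty lists
  far <- mk(200)
  res3 <- lining_residues(tun, far, contact_cutoff = 3.0)
  expect_equal(nrow(res3$lining), 0)
  expect_equal(nrow(res3$bottleneck_residues), 0)
})

test_that("bottleneck residues ring the fixture constriction", {
  h <- fix_constricted()
  res <- lining_residues(h$rep1, h$fx$structure, contact_cutoff = 3.0)
  expect_gt(nrow(res$lining), nrow(res$bottleneck_residues))
  expect_gt(nrow(res$bottleneck_residues), 0)
  # bottleneck residues are pseudo-atoms near the constriction plane
  bres <- res$bottleneck_residues
  atoms <- h$fx$structure[h$fx$structure$resno %in% bres$resno, ]
  bl <- h$rep1$centerline[[1]]
  bi <- h$rep1$bottleneck_index
  d <- sqrt((atoms$x - bl$x[bi])^2 + (atoms$y - bl$y[bi])^2 +
            (atoms$z - bl$z[bi])^2)
  expect_true(all(d < bl$r[bi] + 1.7 + 3.0 + 1e-9))
})

test_that("the radius profile is consistent with the computed properties", {
  h <- fix_constricted()
  prof <- tunnel_profile(h$rep1)
  expect_equal(min(prof$r), h$rep1$bottleneck_radius)
  expect_equal(max(prof$l), h$rep1$length)
  expect_equal(prof$l[which.min(prof$r)],
               h$rep1$centerline[[1]]$l[h$rep1$bottleneck_index])
  # constant-radius profile stays constant
  cl <- tibble::tibble(l = 0:5, x = 0:5, y = 0, z = 0, r = 2)
  t0 <- compute_properties(toy_tunnel(cl))
  expect_equal(unique(tunnel_profile(t0)$r), 2)
})

test_that("tidy/glance/autoplot provide the tabular views", {
  h <- fix_channel()
  tun <- detect_rep1(h)
  td <- tidy(tun)
  expect_true(all(c("id", "l", "r") %in% names(td)))
  gl <- glance(tun)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("bottleneck_radius", "throughput") %in% names(gl)))
  p <- autoplot(tun)
  expect_s3_class(p, "ggplot")
})
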