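new_ligand <- function(atoms, anchor = "centroid_nearest", name = "ligand",
                       radii_table = bondi_radii()) {
  if (nrow(atoms) == 0) stop_input("ligand has no atoms")
  el <- toupper(atoms$element)
  r <- unname(radii_table[el])
  r[is.na(r)] <- radii_table[["default"]]
  atoms$vdw_radius <- r
  anchor_index <- resolve_anchor(atoms, anchor)
  structure(list(atoms = atoms, anchor_index = anchor_index, name = name),
            class = "tunnelr_ligand")
}

resolve_anchor <- function(atoms, anchor) {
  if (is.numeric(anchor)) {
    anchor <- as.integer(anchor)
    if (anchor < 1 || anchor > nrow(atoms)) {
      stop_input("anchor index %d out of range (1..%d)", anchor, nrow(atoms))
    }
    return(anchor)
  }
  heavy <- which(toupper(atoms$element) != "H")
  if (length(heavy) == 0) heavy <- seq_len(nrow(atoms))
  if (identical(anchor, "first_heavy")) return(heavy[1])
  # centroid_nearest: heavy atom nearest the geometric centroid (ties: lower
  # index)
  cen <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
  d <- sqrt((atoms$x[heavy] - cen[1])^2 + (atoms$y[heavy] - cen[2])^2 +
            (atoms$z[heavy] - cen[3])^2)
  heavy[which.min(round(d, 9))]
}

#' @export
print.tunnelr_ligand <- function(x, ...) {
  cat(sprintf("<tunnelr_ligand '%s'> %d atom(s), anchor atom %d (%s)\n",
              x$name, nrow(x$atoms), x$anchor_index,
              x$atoms$element[x$anchor_index]))
  invisible(x)
}

#' Load a small-molecule ligand from a PDB or XYZ file
#'
#' The format is chosen by extension (`.xyz` else PDB). The anchor atom - the
#' atom constrained to the disc plane during restrained optimization - is by
#' default the heavy atom nearest the ligand's geometric centroid.
#'
#' @param path Ligand file.
#' @param anchor `"centroid_nearest"`, `"first_heavy"`, or an explicit atom
#'   index (1-based).
#' @param name Display name (defaults to the file basename).
#' @return A `tunnelr_ligand`: rigid atom set plus anchor index.
#' @export
load_ligand <- function(path, anchor = "centroid_nearest", name = NULL) {
  if (!file.exists(path)) stop_input("ligand file not found: %s", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    atoms <- read_xyz(path)
  } else {
    s <- read_structure(path, keep_hetero = TRUE)
    atoms <- s[, c("element", "x", "y", "z")]
  }
  new_ligand(atoms, anchor = anchor, name = name)
}

# minimal XYZ reader: count line, comment line, then "El x y z" rows
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop_input("XYZ file %s too short", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop_input("bad atom count in XYZ file %s", path)
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  bad <- lengths(rows) < 4
  if (any(bad)) stop_input("malformed XYZ coordinate line in %s", path)
  tibble::tibble(
    element = vapply(rows, `[`, "", 1),
    x = as.numeric(vapply(rows, `[`, "", 2)),
    y = as.numeric(vapply(rows, `[`, "", 3)),
    z = as.numeric(vapply(rows, `[`, "", 4)))
}

#' Cut a tunnel into discs
#'
#' Places disc centres along the centerline at arc lengths `0, delta,
#' 2*delta, ...` plus the tunnel end `L`; each disc's normal is the local
#' centerline tangent and its radius is the tunnel radius at that arc length
#' plus `disc_margin`.
#'
#' @param tunnel One row of a `tunnelr_tunnels` tibble (properties computed).
#' @param delta Distance between consecutive disc centres (angstroms).
#' @param disc_margin Margin added to `r(l)` for the in-plane anchor bound.
#' @return Tibble of discs: `index`, `arc_length`, centre `cx/cy/cz`, normal
#'   `nx/ny/nz`, in-plane basis `e1*/e2*`, `radius`.
#' @export
discretize <- function(tunnel, delta = 0.3, disc_margin = 1.0) {
  if (delta <= 0) stop_input("delta must be positive")
  cl <- tunnel$centerline[[1]]
  L <- cl$l[nrow(cl)]
  if (delta >= L) {
    stop_input("delta %.2f leaves fewer than 2 discs for a tunnel of length %.2f",
               delta, L)
  }
  lo <- seq(0, L, by = delta)
  if (L - lo[length(lo)] > 1e-9) lo <- c(lo, L)
  fx <- function(vals) approx(cl$l, vals, lo)$y
  cx <- fx(cl$x); cy <- fx(cl$y); cz <- fx(cl$z); r <- fx(cl$r)
  # tangent by central differences on the disc positions
  eps <- pmin(delta, L) / 2
  tx <- approx(cl$l, cl$x, pmin(lo + eps, L))$y - approx(cl$l, cl$x, pmax(lo - eps, 0))$y
  ty <- approx(cl$l, cl$y, pmin(lo + eps, L))$y - approx(cl$l, cl$y, pmax(lo - eps, 0))$y
  tz <- approx(cl$l, cl$z, pmin(lo + eps, L))$y - approx(cl$l, cl$z, pmax(lo - eps, 0))$y
  nrm <- sqrt(tx^2 + ty^2 + tz^2)
  nrm[nrm < 1e-12] <- 1
  n <- cbind(tx, ty, tz) / nrm
  basis <- purrr::map(seq_along(lo), function(i) plane_basis(n[i, ]))
  tibble::tibble(
    index = seq_along(lo),
    arc_length = lo,
    cx = cx, cy = cy, cz = cz,
    nx = n[, 1], ny = n[, 2], nz = n[, 3],
    e1x = purrr::map_dbl(basis, ~ .x$e1[1]),
    e1y = purrr::map_dbl(basis, ~ .x$e1[2]),
    e1z = purrr::map_dbl(basis, ~ .x$e1[3]),
    e2x = purrr::map_dbl(basis, ~ .x$e2[1]),
    e2y = purrr::map_dbl(basis, ~ .x$e2[2]),
    e2z = purrr::map_dbl(basis, ~ .x$e2[3]),
    radius = r + disc_margin)
}

# deterministic orthonormal in-plane basis for a unit normal
plane_basis <- function(n) {
  ref <- diag(3)[, which.min(abs(n))]
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

lig_local_coords <- function(ligand) {
  a <- ligand$anchor_index
  m <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  sweep(m, 2, m[a, ])
}

#' Score a rigid ligand pose against the considered receptor atoms
#'
#' The score is a capped 12-6 steric potential summed over ligand/receptor
#' atom pairs within `cutoff`:
#' `e = eps * ((s/d)^12 - 2 (s/d)^6)` with `s = r_i + r_j`, each pair capped
#' at `+cap`. Energies are in dimensionless score units (not comparable to
#' any force-field or docking scale); only profile shape and barrier
#' ordering are meaningful.
#'
#' @param ligand A `tunnelr_ligand`.
#' @param pose List with unit quaternion `quat` (w, x, y, z) and `anchor`
#'   (xyz of the anchor atom).
#' @param structure Atom table (considered atoms are the receptor).
#' @param cutoff,eps,cap Potential parameters.
#' @return Scalar score.
#' @export
score_pose <- function(ligand, pose, structure, cutoff = 8, eps = 0.2,
                       cap = 10) {
  rec <- considered_atoms(structure)
  posed <- .apply_pose(lig_local_coords(ligand), pose$quat, pose$anchor)
  .lj_score(posed, ligand$atoms$vdw_radius, coords_matrix(rec),
            rec$vdw_radius, cutoff, eps, cap)
}

# receptor subset relevant for poses anchored on one disc
receptor_subset <- function(structure, disc, ligand, cutoff = 8) {
  rec <- considered_atoms(structure)
  loc <- lig_local_coords(ligand)
  extent <- if (nrow(loc) > 1) max(sqrt(rowSums(loc^2))) else 0
  reach <- cutoff + disc$radius + extent + 0.5
  d2 <- (rec$x - disc$cx)^2 + (rec$y - disc$cy)^2 + (rec$z - disc$cz)^2
  rec[d2 <= reach^2, , drop = FALSE]
}

# per-disc deterministic RNG stream
disc_seed <- function(seed, index, attempt = 0L) {
  (as.integer(seed) + 7919L * as.integer(index) +
     104729L * as.integer(attempt)) %% 2147483562L
}

make_starts <- function(n_starts, disc_radius, include_base = TRUE) {
  u <- sqrt(runif(n_starts)) * disc_radius
  th <- runif(n_starts, 0, 2 * pi)
  ang <- runif(n_starts, 0, pi)
  ax <- matrix(stats::rnorm(3 * n_starts), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  starts <- cbind(u * cos(th), u * sin(th), ax * ang)
  if (include_base) starts <- rbind(0, starts)
  starts
}

#' Optimize a rigid ligand pose on one disc
#'
#' Minimizes [score_pose()] over the 5 free degrees of freedom (2 in-plane
#' anchor coordinates, 3 rotational) subject to the anchor lying on the disc
#' plane within the disc radius, and optionally to a maximal rotation away
#' from `init_pose`. Multi-start Nelder-Mead: `n_starts` random rotations and
#' in-plane positions from the seeded generator, plus the base pose
#' (`init_pose` when given).
#'
#' @param ligand A `tunnelr_ligand`.
#' @param disc One row of a [discretize()] result.
#' @param structure Atom table.
#' @param n_starts Number of random restarts.
#' @param seed Stream seed.
#' @param init_pose Optional starting pose (list `quat`, `anchor`).
#' @param max_rotation Optional maximal angular distance (degrees) from
#'   `init_pose`'s rotation.
#' @param maxit Local-refinement iteration budget per start.
#' @param receptor Optional precomputed receptor subset.
#' @return A pose list: `energy`, `anchor`, `quat`.
#' @export
optimize_on_disc <- function(ligand, disc, structure, n_starts = 24L,
                             seed = 1L, init_pose = NULL, max_rotation = NULL,
                             maxit = 150L, receptor = NULL) {
  rec <- receptor %||% receptor_subset(structure, disc, ligand)
  starts <- withr::with_seed(disc_seed(seed, disc$index),
                             make_starts(n_starts, disc$radius))
  # the rotation restraint is vacuous for a point ligand; dropping it keeps
  # the objective identical across modes so the bounds agree exactly
  if (nrow(ligand$atoms) == 1) max_rotation <- NULL
  q0 <- if (is.null(init_pose)) c(1, 0, 0, 0) else init_pose$quat
  res <- .optimize_disc(
    lig_local_coords(ligand), ligand$atoms$vdw_radius,
    coords_matrix(rec), rec$vdw_radius,
    c(disc$cx, disc$cy, disc$cz), c(disc$nx, disc$ny, disc$nz),
    c(disc$e1x, disc$e1y, disc$e1z), c(disc$e2x, disc$e2y, disc$e2z),
    disc$radius, starts, q0,
    if (is.null(max_rotation)) -1 else max_rotation,
    8, 0.2, 10, as.integer(maxit))
  list(energy = res$energy, anchor = res$anchor, quat = res$quat)
}

new_profile <- function(entries, direction, mode, status = "done",
                        params = list()) {
  structure(list(entries = entries, direction = direction, mode = mode,
                 status = status, params = params, barriers = NULL),
            class = "tunnelr_profile")
}

#' @export
print.tunnelr_profile <- function(x, ...) {
  cat(sprintf("<tunnelr_profile mode=%s direction=%s status=%s> %d disc(s)\n",
              x$mode, x$direction, x$status, nrow(x$entries)))
  if (!is.null(x$barriers)) {
    b <- x$barriers
    cat(sprintf("  E_B %.3f  E_MAX %.3f  E_S %.3f  Ea %.3f  dE_bind %.3f\n",
                b$E_B, b$E_MAX, b$E_S, b$Ea, b$dE_bind))
  }
  invisible(x)
}

profile_entry <- function(disc, pose) {
  tibble::tibble(
    disc_index = disc$index, arc_length = disc$arc_length,
    energy = pose$energy,
    anchor_x = pose$anchor[1], anchor_y = pose$anchor[2],
    anchor_z = pose$anchor[3],
    quat_w = pose$quat[1], quat_x = pose$quat[2], quat_y = pose$quat[3],
    quat_z = pose$quat[4])
}

order_discs <- function(discs, direction) {
  if (direction == "in") {
    discs[order(-discs$arc_length), , drop = FALSE]  # mouth -> active site
  } else {
    discs[order(discs$arc_length), , drop = FALSE]
  }
}

#' Lower-bound energy profile
#'
#' Optimizes the pose on every disc independently (spatial restraint only):
#' fast, but consecutive poses may flip, so barriers can be underestimated -
#' hence a lower bound.
#'
#' @param ligand A `tunnelr_ligand`.
#' @param discs A [discretize()] result.
#' @param structure Atom table.
#' @param direction `"in"` (bulk solvent to active site) or `"out"`.
#' @param n_starts,seed,maxit Passed to [optimize_on_disc()].
#' @return A `tunnelr_profile` with one entry per disc in trajectory order.
#' @export
lower_bound_profile <- function(ligand, discs, structure, direction = "in",
                                n_starts = 24L, seed = 1L, maxit = 150L) {
  direction <- match.arg(direction, c("in", "out"))
  if (nrow(discs) < 2) stop_input("need at least 2 discs")
  ord <- order_discs(discs, direction)
  entries <- purrr::map(seq_len(nrow(ord)), function(i) {
    disc <- ord[i, ]
    pose <- optimize_on_disc(ligand, disc, structure, n_starts = n_starts,
                             seed = seed, maxit = maxit)
    profile_entry(disc, pose)
  })
  new_profile(dplyr::bind_rows(entries), direction, "lower_bound",
              params = list(n_starts = n_starts, seed = seed))
}

#' Upper-bound energy profile
#'
#' Sequential pass in trajectory order: each disc is optimized starting from
#' the previous disc's pose with the rotation restricted to `max_rotation`
#' degrees, which enforces continuous ligand movement. When the best energy
#' found exceeds the lower-bound energy at the same disc by more than
#' `energy_slack`, the pass backtracks up to `backtrack_window` discs and
#' retries with fresh seeded restarts; on exhaustion the profile is marked
#' `status = "failed"` (a legal outcome: a continuous path may not exist for
#' a given rotation budget). Energies are never below the spatial-only
#' optimum, so the profile bounds the passage cost from above.
#'
#' @inheritParams lower_bound_profile
#' @param max_rotation Maximal per-step rotation (degrees).
#' @param backtrack_window Maximum number of discs to backtrack.
#' @param energy_slack Acceptance slack over the lower bound (score units).
#' @param lower Optional precomputed lower-bound profile (same seed); used
#'   for the backtracking acceptance threshold.
#' @return A `tunnelr_profile`; check `status`.
#' @export
upper_bound_profile <- function(ligand, discs, structure, direction = "in",
                                n_starts = 24L, seed = 1L, maxit = 150L,
                                max_rotation = 10, backtrack_window = 5L,
                                energy_slack = 2.0, lower = NULL) {
  direction <- match.arg(direction, c("in", "out"))
  if (nrow(discs) < 2) stop_input("need at least 2 discs")
  if (max_rotation <= 0) stop_input("max_rotation must be positive")
  lower <- lower %||% lower_bound_profile(ligand, discs, structure,
                                          direction = direction,
                                          n_starts = n_starts, seed = seed,
                                          maxit = maxit)
  ord <- order_discs(discs, direction)
  m <- nrow(ord)
  lower_e <- lower$entries$energy
  poses <- vector("list", m)
  status <- "done"

  single_atom <- nrow(ligand$atoms) == 1
  optimize_step <- function(i, init, attempt = 0L) {
    disc <- ord[i, ]
    starts <- withr::with_seed(disc_seed(seed, disc$index, attempt),
                               make_starts(n_starts, disc$radius))
    rec <- receptor_subset(structure, disc, ligand)
    res <- .optimize_disc(
      lig_local_coords(ligand), ligand$atoms$vdw_radius,
      coords_matrix(rec), rec$vdw_radius,
      c(disc$cx, disc$cy, disc$cz), c(disc$nx, disc$ny, disc$nz),
      c(disc$e1x, disc$e1y, disc$e1z), c(disc$e2x, disc$e2y, disc$e2z),
      disc$radius, starts,
      if (is.null(init)) c(1, 0, 0, 0) else init$quat,
      if (is.null(init) || single_atom) -1 else max_rotation,
      8, 0.2, 10, as.integer(maxit))
    list(energy = res$energy, anchor = res$anchor, quat = res$quat)
  }

  i <- 1L
  attempt_at <- integer(m)
  while (i <= m) {
    init <- if (i == 1L) NULL else poses[[i - 1L]]
    poses[[i]] <- optimize_step(i, init, attempt_at[i])
    # any pose found under the rotation restraint is feasible for the
    # unconstrained per-disc problem, so it can tighten the lower bound
    if (poses[[i]]$energy < lower_e[i]) {
      lower_e[i] <- poses[[i]]$energy
      lower$entries[i, c("energy", "anchor_x", "anchor_y", "anchor_z",
                         "quat_w", "quat_x", "quat_y", "quat_z")] <-
        as.list(c(poses[[i]]$energy, poses[[i]]$anchor, poses[[i]]$quat))
    }
    if (poses[[i]]$energy > lower_e[i] + energy_slack && i > 1L) {
      # backtrack: retry a window of previous discs with fresh starts
      done <- FALSE
      for (w in seq_len(min(backtrack_window, i - 1L))) {
        j0 <- i - w
        attempt_at[j0:i] <- attempt_at[i] + 1L
        for (j in j0:i) {
          init_j <- if (j == 1L) NULL else poses[[j - 1L]]
          poses[[j]] <- optimize_step(j, init_j, attempt_at[j])
          if (poses[[j]]$energy < lower_e[j]) {
            lower_e[j] <- poses[[j]]$energy
            lower$entries[j, c("energy", "anchor_x", "anchor_y", "anchor_z",
                               "quat_w", "quat_x", "quat_y", "quat_z")] <-
              as.list(c(poses[[j]]$energy, poses[[j]]$anchor, poses[[j]]$quat))
          }
        }
        if (poses[[i]]$energy <= lower_e[i] + energy_slack) {
          done <- TRUE
          break
        }
      }
      if (!done) {
        status <- "failed"
        m <- i
        break
      }
    }
    i <- i + 1L
  }
  entries <- dplyr::bind_rows(
    purrr::map(seq_len(m), function(k) profile_entry(ord[k, ], poses[[k]])))
  prof <- new_profile(entries, direction, "upper_bound", status = status,
                      params = list(n_starts = n_starts, seed = seed,
                                    max_rotation = max_rotation,
                                    backtrack_window = backtrack_window,
                                    energy_slack = energy_slack))
  prof$lower <- lower
  prof
}

#' Extract binding and activation energies from a profile
#'
#' With automatic selection, `E_B` is the minimum energy over the 20% of
#' discs nearest the active-site end (arc length 0), `E_S` the minimum over
#' the 20% nearest the tunnel mouth, and `E_MAX` the global maximum between
#' those two minima. The activation energy is `E_MAX - E_S` for direction
#' `"in"` and `E_MAX - E_B` for `"out"`; the binding energy difference is
#' `E_B - E_S`. Explicit indices (positions in site-to-mouth order) override
#' the automatic rules.
#'
#' @param profile A `tunnelr_profile`.
#' @param i_B,i_MAX,i_S `"auto"` or explicit 1-based positions in
#'   site-to-mouth order.
#' @return The profile with `barriers` filled (`E_B`, `E_MAX`, `E_S`, `Ea`,
#'   `dE_bind`, indices, status).
#' @export
barrier_analysis <- function(profile, i_B = "auto", i_MAX = "auto",
                             i_S = "auto") {
  ent <- dplyr::arrange(profile$entries, .data$arc_length)  # site -> mouth
  e <- ent$energy
  m <- length(e)
  pick <- function(i, default) {
    if (identical(i, "auto")) return(default)
    i <- as.integer(i)
    if (i < 1 || i > m) stop_input("explicit index %d out of range 1..%d", i, m)
    i
  }
  k <- max(1L, ceiling(0.2 * m))
  site_zone <- seq_len(k)
  mouth_zone <- seq(m - k + 1L, m)
  iB <- pick(i_B, site_zone[which.min(e[site_zone])])
  iS <- pick(i_S, mouth_zone[which.min(e[mouth_zone])])
  span <- seq(min(iB, iS), max(iB, iS))
  iM <- pick(i_MAX, span[which.max(e[span])])
  E_B <- e[iB]; E_S <- e[iS]; E_MAX <- e[iM]
  profile$barriers <- list(
    E_B = E_B, E_MAX = E_MAX, E_S = E_S,
    Ea = if (profile$direction == "in") E_MAX - E_S else E_MAX - E_B,
    dE_bind = E_B - E_S,
    i_B = iB, i_MAX = iM, i_S = iS,
    mode = profile$mode, direction = profile$direction,
    status = profile$status)
  profile
}
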