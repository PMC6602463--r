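new_starting_point <- function(raw_point, mode, snapped_vertex = NULL,
                               snapped_point = NULL) {
  structure(list(raw_point = as.numeric(raw_point), mode = mode,
                 snapped_vertex = snapped_vertex,
                 snapped_point = snapped_point),
            class = "tunnelr_start")
}

#' @export
print.tunnelr_start <- function(x, ...) {
  cat(sprintf("<tunnelr_start mode=%s> raw (%.2f, %.2f, %.2f)\n", x$mode,
              x$raw_point[1], x$raw_point[2], x$raw_point[3]))
  if (!is.null(x$snapped_vertex)) {
    cat(sprintf("  snapped to vertex %d at (%.2f, %.2f, %.2f), displacement %.2f\n",
                x$snapped_vertex, x$snapped_point[1], x$snapped_point[2],
                x$snapped_point[3],
                sqrt(sum((x$raw_point - x$snapped_point)^2))))
  }
  invisible(x)
}

# mass-weighted centre of mass of one atom subset
residue_com <- function(atoms) {
  m <- atomic_masses()
  w <- unname(m[toupper(atoms$element)])
  w[is.na(w)] <- m[["default"]]
  c(sum(w * atoms$x), sum(w * atoms$y), sum(w * atoms$z)) / sum(w)
}

# parse "CHAIN:RESNO" ids into a tibble
parse_residue_ids <- function(residue_ids) {
  if (is.data.frame(residue_ids)) return(residue_ids)
  parts <- strsplit(residue_ids, ":", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop_input("residue ids must be 'CHAIN:RESNO', got: %s",
               paste(residue_ids[bad], collapse = ", "))
  }
  tibble::tibble(chain = vapply(parts, `[`, "", 1),
                 resno = as.integer(vapply(parts, `[`, "", 2)))
}

#' Starting point from selected residues
#'
#' The raw point is the unweighted mean over residues of the per-residue
#' (mass-weighted) centres of mass.
#'
#' @param structure Atom table.
#' @param residue_ids Character vector of `"CHAIN:RESNO"` ids, or a data frame
#'   with `chain` and `resno` columns.
#' @return A `tunnelr_start` (unsnapped; see [snap_to_vertex()]).
#' @export
start_from_residues <- function(structure, residue_ids) {
  ids <- parse_residue_ids(residue_ids)
  coms <- purrr::pmap(ids, function(chain, resno, ...) {
    atoms <- dplyr::filter(structure, .data$chain == !!chain,
                           .data$resno == !!resno)
    if (nrow(atoms) == 0) {
      stop_input("residue %s:%d matches no atom", chain, resno)
    }
    residue_com(atoms)
  })
  new_starting_point(colMeans(do.call(rbind, coms)), "residues")
}

#' Starting point at the centre of mass of a bound ligand
#'
#' @param structure Atom table.
#' @param residue_name HETATM residue name of the ligand.
#' @param residue_number Optional residue number to disambiguate.
#' @return A `tunnelr_start`.
#' @export
start_from_ligand <- function(structure, residue_name, residue_number = NULL) {
  if (residue_name %in% c("HOH", "WAT")) {
    stop_input("water is not an acceptable starting ligand")
  }
  atoms <- dplyr::filter(structure, .data$is_hetero,
                         .data$resname == residue_name)
  if (!is.null(residue_number)) {
    atoms <- dplyr::filter(atoms, .data$resno == residue_number)
  }
  if (nrow(atoms) == 0) {
    stop_input("ligand %s %s not found", residue_name,
               residue_number %||% "")
  }
  new_starting_point(residue_com(atoms), "ligand")
}

#' Detect candidate pockets from alpha spheres of the Voronoi network
#'
#' Alpha spheres are Voronoi vertices whose sphere touching the nearest atoms
#' (radius measured to atom centres) falls inside the pocket-sized window
#' `[alpha_min, alpha_max]`, that do not collide with any atom, and that are
#' not part of the bulk solvent. Spheres are single-linkage clustered at
#' `cluster_dist`; clusters smaller than `min_spheres` are discarded as
#' packing noise. Pockets are ranked by a Monte-Carlo estimate of their
#' union-of-spheres volume (fixed internal seed, deterministic), with ties
#' broken by centroid lexicographic order.
#'
#' @param structure Atom table.
#' @param alpha_min,alpha_max Alpha-sphere radius window (angstroms, measured
#'   to atom centres).
#' @param cluster_dist Single-linkage clustering distance (angstroms).
#' @param catalytic_residues Optional `"CHAIN:RESNO"` ids; pockets containing
#'   at least one are flagged catalytic.
#' @param min_spheres Minimum alpha spheres per reported pocket.
#' @param network Optional prebuilt network (rebuilt otherwise).
#' @param mc_samples Monte-Carlo sample count for the volume estimate.
#' @return A `tunnelr_pockets` tibble: `rank`, `n_spheres`,
#'   `volume_estimate`, `centroid_x/y/z`, `catalytic`, plus list-columns
#'   `spheres` and `residues`.
#' @export
detect_pockets <- function(structure, alpha_min = 3.0, alpha_max = 6.0,
                           cluster_dist = 4.5, catalytic_residues = NULL,
                           min_spheres = 10L, network = NULL,
                           mc_samples = 20000L) {
  atoms <- considered_atoms(structure)
  if (is.null(network)) network <- build_network(structure)
  # pocket admission needs its own bulk scale: anything narrower than
  # alpha_max is a potential pocket, so only solvent regions wider than the
  # window cap count as bulk here (tunnel-detection labels are untouched)
  network <- label_bulk(network, shell_radius = alpha_max, shell_depth = 0)
  v <- network$vertices
  xyz <- coords_matrix(atoms)
  center_dist <- .clearance_query(as.matrix(v[, c("x", "y", "z")]), xyz,
                                  rep(0, nrow(xyz)))
  admit <- v$label != "bulk" & v$clearance > 0 &
    center_dist >= alpha_min & center_dist <= alpha_max
  if (any(admit)) {
    # burial check: a pocket sphere touches atoms on several sides, so the
    # unit directions to its contact atoms largely cancel; a sphere floating
    # in open solvent just beyond the surface sees all its contacts in a
    # narrow one-sided cone. Exclude candidates whose mean contact
    # direction is too long.
    cand <- which(admit)
    spread <- vapply(cand, function(i) {
      p <- c(v$x[i], v$y[i], v$z[i])
      dv <- sweep(xyz, 2, p, "-")
      dn <- sqrt(rowSums(dv^2))
      nb <- dn <= center_dist[i] + 1.0
      sqrt(sum(colMeans(dv[nb, , drop = FALSE] / dn[nb])^2))
    }, 0.0)
    admit[cand[spread > 0.7]] <- FALSE
  }
  empty <- tibble::tibble(
    rank = integer(), n_spheres = integer(), volume_estimate = numeric(),
    centroid_x = numeric(), centroid_y = numeric(), centroid_z = numeric(),
    catalytic = logical(), spheres = list(), residues = list())
  class(empty) <- c("tunnelr_pockets", class(empty))
  if (!any(admit)) return(empty)

  sph <- tibble::tibble(
    x = v$x[admit], y = v$y[admit], z = v$z[admit],
    radius = center_dist[admit], clearance = v$clearance[admit])
  cl <- if (nrow(sph) == 1) 1L else {
    cutree(hclust(dist(sph[, c("x", "y", "z")]), method = "single"),
           h = cluster_dist)
  }
  cat_ids <- if (is.null(catalytic_residues)) NULL else
    parse_residue_ids(catalytic_residues)

  pockets <- purrr::map(unique(cl), function(k) {
    sp <- sph[cl == k, , drop = FALSE]
    if (nrow(sp) < min_spheres) return(NULL)
    vol <- mc_sphere_union_volume(sp, mc_samples)
    # lining residues: any atom within 1 A of an alpha-sphere surface
    near <- rep(FALSE, nrow(atoms))
    for (i in seq_len(nrow(sp))) {
      d <- sqrt((atoms$x - sp$x[i])^2 + (atoms$y - sp$y[i])^2 +
                (atoms$z - sp$z[i])^2)
      near <- near | abs(d - sp$radius[i]) <= 1.0
    }
    res <- dplyr::distinct(atoms[near, c("chain", "resno", "resname")])
    res <- dplyr::arrange(res, .data$chain, .data$resno)
    catal <- !is.null(cat_ids) &&
      nrow(dplyr::inner_join(res, cat_ids, by = c("chain", "resno"))) > 0
    tibble::tibble(
      n_spheres = nrow(sp), volume_estimate = vol,
      centroid_x = mean(sp$x), centroid_y = mean(sp$y),
      centroid_z = mean(sp$z), catalytic = catal,
      spheres = list(sp), residues = list(res))
  })
  pockets <- dplyr::bind_rows(pockets)
  if (nrow(pockets) == 0) return(empty)
  pockets <- dplyr::arrange(pockets, dplyr::desc(.data$volume_estimate),
                            .data$centroid_x, .data$centroid_y,
                            .data$centroid_z)
  pockets <- dplyr::mutate(pockets, rank = dplyr::row_number(),
                           .before = 1)
  class(pockets) <- c("tunnelr_pockets", class(pockets))
  pockets
}

# Monte-Carlo union-of-spheres volume with a fixed seed (deterministic)
mc_sphere_union_volume <- function(sp, n = 20000L) {
  lo <- c(min(sp$x - sp$radius), min(sp$y - sp$radius), min(sp$z - sp$radius))
  hi <- c(max(sp$x + sp$radius), max(sp$y + sp$radius), max(sp$z + sp$radius))
  box <- prod(hi - lo)
  pts <- withr::with_seed(10007L, {
    matrix(runif(3 * n), ncol = 3)
  })
  pts <- sweep(sweep(pts, 2, hi - lo, "*"), 2, lo, "+")
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(sp))) {
    d2 <- (pts[, 1] - sp$x[i])^2 + (pts[, 2] - sp$y[i])^2 +
      (pts[, 3] - sp$z[i])^2
    inside <- inside | d2 <= sp$radius[i]^2
  }
  box * mean(inside)
}

#' Starting point from a detected pocket
#'
#' The raw point is the unweighted mean over the pocket's member residues of
#' their mass-weighted centres of mass.
#'
#' @param pocket One row of a [detect_pockets()] result.
#' @param structure Atom table the pocket was detected in.
#' @return A `tunnelr_start`.
#' @export
start_from_pocket <- function(pocket, structure) {
  res <- pocket$residues[[1]]
  if (is.null(res) || nrow(res) == 0) stop_input("pocket has no member residues")
  start <- start_from_residues(structure, res[, c("chain", "resno")])
  start$mode <- "pocket"
  start
}

#' Snap a point to an admissible Voronoi vertex
#'
#' Among non-bulk vertices within `maximal_distance` of the point, returns
#' the nearest vertex whose clearance is at least `desired_radius`. When no
#' vertex meets the desired radius, the largest-clearance vertex within range
#' is used instead (with a warning): the desired radius is a soft constraint,
#' the maximal distance a hard one.
#'
#' @param point Numeric xyz, or a `tunnelr_start` to snap in place.
#' @param network Labelled `tunnelr_network`.
#' @param maximal_distance Hard limit on the snap displacement (angstroms).
#' @param desired_radius Soft minimum clearance of the snapped vertex.
#' @return A `tunnelr_start` with `snapped_vertex` and `snapped_point` set.
#' @export
snap_to_vertex <- function(point, network, maximal_distance = 3.0,
                           desired_radius = 5.0) {
  start <- if (inherits(point, "tunnelr_start")) point else
    new_starting_point(point, "coordinates")
  p <- start$raw_point
  v <- network$vertices
  d <- sqrt((v$x - p[1])^2 + (v$y - p[2])^2 + (v$z - p[3])^2)
  cand <- which(d <= maximal_distance & v$label != "bulk")
  if (length(cand) == 0) {
    stop_geometry(
      "no non-bulk Voronoi vertex within %.2f angstrom of the starting point",
      maximal_distance)
  }
  good <- cand[v$clearance[cand] >= desired_radius]
  pick <- if (length(good) > 0) {
    good[order(d[good], good)][1]
  } else {
    warn(sprintf(paste0("no vertex within %.2f angstrom has clearance >= %.2f; ",
                        "using the largest-clearance vertex in range"),
                 maximal_distance, desired_radius))
    cand[order(-v$clearance[cand], cand)][1]
  }
  start$snapped_vertex <- v$id[pick]
  start$snapped_point <- c(v$x[pick], v$y[pick], v$z[pick])
  start
}
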