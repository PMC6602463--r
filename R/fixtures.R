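#' Synthetic pseudo-protein with analytically known channels
#'
#' Builds a hollow spherical shell of carbon pseudo-atoms on a jittered cubic
#' lattice and drills one or more straight cylindrical channels from the
#' central cavity to the outside. Because the drilled radius profile is known
#' by construction, the generated structure comes with a machine-readable
#' ground-truth record (axis clearance profile, bottleneck, analytic cost
#' integral) against which tunnel detection can be validated.
#'
#' Atoms are grouped into one-atom residues with sequential numbers so that
#' residue-annotation code paths are exercised. The lattice is jittered by
#' `0.05 * lattice_spacing` (seeded) to avoid the degenerate cospherical
#' point sets a perfect lattice would feed the tessellation.
#'
#' @param r_inner,r_outer Inner and outer shell radii (angstroms).
#' @param channel_radius Drilled radius of each channel; recycled over axes.
#'   A radius of 0 drills nothing (solid shell wall).
#' @param channel_axis Unit axis of each channel: a 3-vector or a matrix with
#'   one row per channel.
#' @param lattice_spacing Lattice constant h (angstroms, at most 1).
#' @param atom_element Element of the pseudo-atoms (sets the vdW radius).
#' @param constriction Optional `list(l_star=, r_star=, width=)`: the first
#'   channel narrows linearly to `r_star` at axial position `l_star` over the
#'   given half-width (default 2).
#' @param seed Jitter seed.
#' @return A list with `structure` (atom table, radii assigned, all atoms
#'   considered) and `truth` (ground-truth record incl. `axis_profile`,
#'   `bottleneck`, `l_star`, `cost_axis`).
#' @export
make_shell_channel <- function(r_inner = 6, r_outer = 12, channel_radius = 1.5,
                               channel_axis = c(0, 0, 1),
                               lattice_spacing = 0.8, atom_element = "C",
                               constriction = NULL, seed = 1L) {
  stopifnot(r_outer > r_inner, r_inner > 0, lattice_spacing <= 1.0)
  axes <- if (is.matrix(channel_axis)) channel_axis else
    matrix(channel_axis, nrow = 1)
  axes <- axes / sqrt(rowSums(axes^2))
  radii <- rep_len(channel_radius, nrow(axes))
  avdw <- unname(bondi_radii()[[toupper(atom_element)]] %||% 1.70)

  drill_radius <- function(k, t) {
    r <- rep(radii[k], length(t))
    if (k == 1 && !is.null(constriction)) {
      w <- constriction$width %||% 2
      dip <- pmax(0, 1 - abs(t - constriction$l_star) / w)
      r <- r - (radii[k] - constriction$r_star) * dip
    }
    r
  }

  s <- seq(-r_outer, r_outer, by = lattice_spacing)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  rad <- sqrt(rowSums(g^2))
  keep <- rad >= r_inner & rad <= r_outer
  g <- g[keep, , drop = FALSE]
  for (k in seq_len(nrow(axes))) {
    if (radii[k] <= 0) next
    t_ax <- g %*% axes[k, ]
    d_ax <- sqrt(pmax(0, rowSums(g^2) - t_ax^2))
    carve <- t_ax > 0 & d_ax < drill_radius(k, t_ax) + avdw
    g <- g[!carve, , drop = FALSE]
  }
  if (nrow(g) < 5) stop_geometry("fixture spec produced fewer than 5 atoms")
  g <- g + withr::with_seed(seed,
    matrix(runif(length(g), -0.05, 0.05) * lattice_spacing, ncol = 3))

  structure_tbl <- tibble::tibble(
    serial = seq_len(nrow(g)),
    element = atom_element,
    name = atom_element,
    resname = "PSD",
    chain = "A",
    resno = seq_len(nrow(g)),
    ins = "",
    x = g[, 1], y = g[, 2], z = g[, 3],
    is_hetero = FALSE,
    considered = TRUE
  )
  structure_tbl <- assign_radii(structure_tbl)

  # measured ground truth along the first channel axis (brute geometry)
  t_grid <- seq(0, r_outer + 3, by = 0.1)
  pts <- outer(t_grid, axes[1, ])
  prof <- .clearance_query(pts, g, rep(avdw, nrow(g)))
  in_wall <- t_grid >= r_inner & t_grid <= r_outer
  bottleneck <- if (any(in_wall)) min(prof[in_wall]) else NA_real_
  l_star <- if (any(in_wall)) t_grid[in_wall][which.min(prof[in_wall])] else NA_real_
  upto <- t_grid <= r_outer
  cost_axis <- if (all(prof[upto] > 0)) {
    trapz(t_grid[upto], 1 / prof[upto]^2)
  } else {
    Inf
  }
  truth <- list(
    kind = "shell_channel",
    r_inner = r_inner, r_outer = r_outer,
    channel_axes = axes, channel_radii = radii,
    lattice_spacing = lattice_spacing, atom_vdw = avdw, seed = seed,
    n_atoms = nrow(g),
    constriction = constriction,
    axis_profile = tibble::tibble(t = t_grid, clearance = prof),
    bottleneck = bottleneck,
    l_star = l_star,
    cost_axis = cost_axis
  )
  list(structure = structure_tbl, truth = truth)
}

#' Solid pseudo-protein ball with hemispherical surface dents
#'
#' Pocket-detection harness: a filled ball of carbon pseudo-atoms with
#' spherical voids of `dent_radius` carved at points on the outer surface
#' (the intersection with the ball is a hemispherical dent).
#'
#' @param dent_centers Matrix with one dent centre per row (each on the outer
#'   surface), or NULL for a dent-free ball.
#' @param dent_radius Dent radius (angstroms).
#' @param r_outer Ball radius.
#' @param lattice_spacing,seed As in [make_shell_channel()].
#' @return A list with `structure` and `truth` (dent centres and radius).
#' @export
make_dented_shell <- function(dent_centers = NULL, dent_radius = 4,
                              r_outer = 8, lattice_spacing = 1.0, seed = 1L) {
  s <- seq(-r_outer, r_outer, by = lattice_spacing)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  keep <- sqrt(rowSums(g^2)) <= r_outer
  g <- g[keep, , drop = FALSE]
  if (!is.null(dent_centers)) {
    dent_centers <- if (is.matrix(dent_centers)) dent_centers else
      matrix(dent_centers, nrow = 1)
    for (k in seq_len(nrow(dent_centers))) {
      d <- sqrt(colSums((t(g) - dent_centers[k, ])^2))
      g <- g[d > dent_radius, , drop = FALSE]
    }
  }
  if (nrow(g) < 5) stop_geometry("fixture spec produced fewer than 5 atoms")
  g <- g + withr::with_seed(seed,
    matrix(runif(length(g), -0.05, 0.05) * lattice_spacing, ncol = 3))
  structure_tbl <- tibble::tibble(
    serial = seq_len(nrow(g)),
    element = "C", name = "C", resname = "PSD", chain = "A",
    resno = seq_len(nrow(g)), ins = "",
    x = g[, 1], y = g[, 2], z = g[, 3],
    is_hetero = FALSE, considered = TRUE
  )
  list(structure = assign_radii(structure_tbl),
       truth = list(kind = "dented_shell", dent_centers = dent_centers,
                    dent_radius = dent_radius, r_outer = r_outer,
                    lattice_spacing = lattice_spacing, seed = seed,
                    n_atoms = nrow(g)))
}

#' Toy rigid ligands for transport tests
#'
#' @param kind `"sphere"` (one atom), `"diatomic"` (two atoms separated by
#'   `bond_length`) or `"rod3"` (three collinear atoms with consecutive
#'   spacing `bond_length`).
#' @param bond_length Interatomic distance (angstroms).
#' @param element Element of every atom.
#' @return A `tunnelr_ligand` object; see [load_ligand()].
#' @export
make_toy_ligand <- function(kind = c("sphere", "diatomic", "rod3"),
                            bond_length = 1.5, element = "C") {
  kind <- match.arg(kind)
  if (kind != "sphere" && bond_length <= 0) {
    stop_input("bond_length must be positive")
  }
  zs <- switch(kind,
    sphere = 0,
    diatomic = c(0, bond_length),
    rod3 = c(-bond_length, 0, bond_length))
  atoms <- tibble::tibble(
    element = element,
    x = 0, y = 0, z = zs
  )
  new_ligand(atoms, anchor = "centroid_nearest", name = kind)
}

#' Write a fixture with its ground-truth record
#'
#' Emits `<name>.pdb` (re-readable by [read_structure()]) and
#' `<name>.truth.json`.
#'
#' @param fixture List with `structure` and `truth` from a fixture generator.
#' @param dir Output directory.
#' @param name Basename for the two files.
#' @return Paths of the written files, invisibly.
#' @export
write_fixture <- function(fixture, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  js <- file.path(dir, paste0(name, ".truth.json"))
  write_structure(fixture$structure, pdb)
  tr <- fixture$truth
  tr$axis_profile <- NULL  # bulky; retained in-memory only
  jsonlite::write_json(tr, js, auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(c(pdb = pdb, truth = js))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
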