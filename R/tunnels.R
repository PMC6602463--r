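new_tunnel_set <- function(df) {
  class(df) <- c("tunnelr_tunnels", setdiff(class(df), "tunnelr_tunnels"))
  df
}

#' @export
print.tunnelr_tunnels <- function(x, ...) {
  cat(sprintf("<tunnelr_tunnels> %d tunnel(s)\n", nrow(x)))
  show <- intersect(c("id", "cluster_id", "priority_rank", "bottleneck_radius",
                      "length", "curvature", "cost", "throughput"), names(x))
  print(tibble::as_tibble(x)[, show])
  invisible(x)
}

# resample a centerline polyline (cols x,y,z,r) at <= `step` spacing
resample_centerline <- function(pts, step = 0.5) {
  seg <- sqrt(rowSums((pts[-1, c("x", "y", "z"), drop = FALSE] -
                       pts[-nrow(pts), c("x", "y", "z"), drop = FALSE])^2))
  l <- c(0, cumsum(seg))
  keep <- c(TRUE, diff(l) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  l <- l[keep]
  L <- l[length(l)]
  if (L <= 1e-9 || length(l) < 2) return(NULL)
  lo <- unique(sort(c(seq(0, L, by = step), L)))
  xo <- approx(l, pts$x, lo)$y
  yo <- approx(l, pts$y, lo)$y
  zo <- approx(l, pts$z, lo)$y
  ro <- approx(l, pts$r, lo)$y
  tibble::tibble(l = lo, x = xo, y = yo, z = zo, r = ro)
}

#' Find lowest-cost tunnels from a starting vertex
#'
#' Restricts the network to edges passable by a probe of `probe_radius`, runs
#' a single-source lowest-cost (Dijkstra) search from the starting vertex,
#' and returns one tunnel per goal vertex - a bulk-adjacent non-bulk vertex
#' that is a local cost minimum among its bulk-adjacent neighbours. Bulk
#' vertices themselves are excluded from the search graph, and each path is
#' truncated at its first bulk-adjacent vertex, so tunnel length runs from
#' the starting point to the protein surface. Centerlines are resampled at
#' 0.5 angstrom spacing with linear interpolation of the clearance radius.
#'
#' @param network Labelled `tunnelr_network`.
#' @param start_vertex Vertex id (e.g. `snapped_vertex` of a snapped
#'   [snap_to_vertex()] result).
#' @param probe_radius Minimum probe radius that must fit along the tunnel.
#' @return A `tunnelr_tunnels` tibble (possibly 0-row): `id`, `exit_vertex`,
#'   `cost_search` (Dijkstra cost of the untruncated path) and a `centerline`
#'   list-column of tibbles with `l`, `x`, `y`, `z`, `r`. Property columns
#'   are filled by [compute_properties()].
#' @export
find_tunnels <- function(network, start_vertex, probe_radius = 0.9) {
  v <- network$vertices
  if (is.null(network$shell)) {
    stop_geometry("network is unlabelled; run label_bulk() first")
  }
  if (v$label[start_vertex] == "bulk") {
    stop_geometry("starting vertex %d lies in the bulk solvent", start_vertex)
  }
  if (v$clearance[start_vertex] < probe_radius) {
    stop_geometry("starting vertex clearance %.2f is below the probe radius %.2f",
                  v$clearance[start_vertex], probe_radius)
  }
  pg <- passable_graph(network, probe_radius = probe_radius, drop_bulk = TRUE)
  dvec <- dijkstra_costs(nrow(v), pg$edges, start_vertex)

  # a tunnel mouth is a vertex from which the probe can actually step into
  # bulk solvent: bulk-adjacency is judged on probe-passable edges only
  # (unfiltered adjacency would let long sliver edges that cut through the
  # wall fake an exit deep inside the structure)
  bulk <- v$label == "bulk"
  e <- network$edges
  e <- e[is.finite(e$cost) & e$min_clearance >= probe_radius, , drop = FALSE]
  touches_bulk <- unique(c(e$from[bulk[e$to]], e$to[bulk[e$from]]))
  goal <- intersect(touches_bulk, which(!bulk & is.finite(dvec)))
  empty <- new_tunnel_set(tibble::tibble(
    id = integer(), exit_vertex = integer(), cost_search = numeric(),
    centerline = list()))
  if (length(goal) == 0) return(empty)

  # keep goals that are local cost minima among their goal-vertex neighbours
  goal_set <- logical(nrow(v))
  goal_set[goal] <- TRUE
  adj <- rbind(pg$edges[, c("from", "to")],
               setNames(pg$edges[, c("to", "from")], c("from", "to")))
  adj <- adj[goal_set[adj$from] & goal_set[adj$to], , drop = FALSE]
  is_min <- setNames(rep(TRUE, length(goal)), goal)
  if (nrow(adj) > 0) {
    worse <- dvec[adj$from] > dvec[adj$to] |
      (dvec[adj$from] == dvec[adj$to] & adj$from > adj$to)
    is_min[as.character(unique(adj$from[worse]))] <- FALSE
  }
  goal <- goal[is_min[as.character(goal)]]
  goal <- setdiff(goal, start_vertex)
  if (length(goal) == 0) return(empty)

  paths <- suppressWarnings(igraph::shortest_paths(
    pg$graph, from = start_vertex, to = goal,
    weights = igraph::E(pg$graph)$weight, output = "vpath"))$vpath

  shell_r <- network$shell$shell_radius
  tunnels <- purrr::map(seq_along(goal), function(k) {
    vp <- as.integer(paths[[k]])
    if (length(vp) < 2) return(NULL)
    # truncate at the first bulk-adjacent vertex on the path
    hit <- which(vp %in% touches_bulk)
    if (length(hit) > 0) vp <- vp[seq_len(hit[1])]
    if (length(vp) < 2) return(NULL)
    pts <- cbind(v$x[vp], v$y[vp], v$z[vp])
    # continue along the mouth vertex's passable exit edge towards bulk and
    # stop where the bulk probe first fits: the surface. This keeps any
    # narrow passage inside a long exit edge on the centerline.
    last <- vp[length(vp)]
    exit_e <- e[(e$from == last & bulk[e$to]) | (e$to == last & bulk[e$from]), ,
                drop = FALSE]
    if (nrow(exit_e) > 0) {
      exit_e <- exit_e[order(exit_e$cost), ][1, ]
      bvert <- if (exit_e$from == last) exit_e$to else exit_e$from
      a <- pts[nrow(pts), ]
      b <- c(v$x[bvert], v$y[bvert], v$z[bvert])
      tt <- seq(0, 1, length.out = max(2, ceiling(sqrt(sum((b - a)^2)) / 0.25)))
      seg <- outer(1 - tt, a) + outer(tt, b)
      segc <- .clearance_query(seg, network$atoms$xyz, network$atoms$radius)
      open_at <- which(segc >= shell_r)[1]
      keep <- if (is.na(open_at)) length(tt) - 1 else open_at - 1
      if (keep >= 2) pts <- rbind(pts, seg[2:keep, , drop = FALSE])
    }
    cl <- resample_centerline(tibble::tibble(
      x = pts[, 1], y = pts[, 2], z = pts[, 3], r = 0))
    if (is.null(cl)) return(NULL)
    # r(l) is the true local clearance at the resampled points
    cl$r <- .clearance_query(cbind(cl$x, cl$y, cl$z), network$atoms$xyz,
                             network$atoms$radius)
    tibble::tibble(exit_vertex = last,
                   cost_search = unname(dvec[last]),
                   centerline = list(cl))
  })
  out <- dplyr::bind_rows(tunnels)
  if (nrow(out) == 0) return(empty)
  out <- dplyr::distinct(out, .data$exit_vertex, .keep_all = TRUE)
  out <- dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
  new_tunnel_set(out)
}

#' Compute tunnel properties from the centerline
#'
#' Fills per-tunnel length `L` (sum of segment lengths), bottleneck radius
#' and index (minimum of `r(l)`), curvature (`L` over the straight start-end
#' distance), cost (trapezoidal integral of `r(l)^-2` over `l`) and
#' throughput (`exp(-cost)`).
#'
#' @param tunnels A `tunnelr_tunnels` tibble.
#' @return The tibble with property columns filled.
#' @export
compute_properties <- function(tunnels) {
  props <- purrr::map(tunnels$centerline, function(cl) {
    if (nrow(cl) < 2) stop_geometry("centerline needs at least 2 spheres")
    L <- cl$l[nrow(cl)]
    chord <- sqrt(sum((unlist(cl[nrow(cl), c("x", "y", "z")]) -
                       unlist(cl[1, c("x", "y", "z")]))^2))
    if (chord <= 1e-9) {
      stop_geometry("tunnel start and end coincide; curvature undefined")
    }
    cost <- trapz(cl$l, 1 / cl$r^2)
    tibble::tibble(
      length = L,
      bottleneck_radius = min(cl$r),
      bottleneck_index = which.min(cl$r),
      curvature = L / chord,
      cost = cost,
      throughput = exp(-cost))
  })
  out <- dplyr::bind_cols(
    dplyr::select(tunnels, -dplyr::any_of(c(
      "length", "bottleneck_radius", "bottleneck_index", "curvature",
      "cost", "throughput"))),
    dplyr::bind_rows(props))
  new_tunnel_set(out)
}

#' Cluster tunnels and rank clusters by cost
#'
#' The pairwise tunnel distance is the mean Euclidean distance between
#' centerlines resampled at 20 equal arc-length fractions. Tunnels are
#' average-linkage clustered and the dendrogram cut at
#' `clustering_threshold` (angstroms); each cluster's representative is its
#' lowest-cost member and clusters are ranked by ascending representative
#' cost, so priority rank 1 has the highest throughput.
#'
#' @param tunnels A `tunnelr_tunnels` tibble with properties computed.
#' @param clustering_threshold Dendrogram cut height (angstroms).
#' @return The tibble with `cluster_id`, `priority_rank` and
#'   `is_representative` columns, sorted by rank then cost.
#' @export
cluster_tunnels <- function(tunnels, clustering_threshold = 3.5) {
  if (nrow(tunnels) == 0) stop_input("no tunnels to cluster")
  frac <- (0:19) / 19
  prof <- purrr::map(tunnels$centerline, function(cl) {
    L <- cl$l[nrow(cl)]
    cbind(approx(cl$l, cl$x, frac * L)$y,
          approx(cl$l, cl$y, frac * L)$y,
          approx(cl$l, cl$z, frac * L)$y)
  })
  n <- nrow(tunnels)
  cl_id <- if (n == 1) 1L else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        D[i, j] <- D[j, i] <- mean(sqrt(rowSums((prof[[i]] - prof[[j]])^2)))
      }
    }
    cutree(hclust(stats::as.dist(D), method = "average"),
           h = clustering_threshold)
  }
  out <- dplyr::mutate(tunnels, cluster_id = cl_id)
  reps <- dplyr::summarise(
    dplyr::group_by(out, .data$cluster_id),
    rep_cost = min(.data$cost), .groups = "drop")
  reps <- dplyr::arrange(reps, .data$rep_cost)
  reps$priority_rank <- seq_len(nrow(reps))
  out <- dplyr::left_join(out, reps, by = "cluster_id")
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$cluster_id),
    is_representative = dplyr::row_number(.data$cost) == 1L)
  out <- dplyr::ungroup(out)
  out <- dplyr::select(out, -"rep_cost")
  out <- dplyr::arrange(out, .data$priority_rank, .data$cost, .data$id)
  new_tunnel_set(out)
}

#' Residues lining a tunnel and its bottleneck
#'
#' A residue lines the tunnel when any of its atoms' surfaces comes within
#' `contact_cutoff` of any centerline sphere's surface
#' (`dist(atom, centre) - vdw - r(l) <= contact_cutoff`, boundary included).
#' Bottleneck residues use only the bottleneck sphere.
#'
#' @param tunnel One row of a `tunnelr_tunnels` tibble (properties computed).
#' @param structure Atom table.
#' @param contact_cutoff Surface-to-surface cutoff (angstroms).
#' @return List with `lining` and `bottleneck_residues` tibbles, both sorted
#'   by chain then residue number.
#' @export
lining_residues <- function(tunnel, structure, contact_cutoff = 3.0) {
  cl <- tunnel$centerline[[1]]
  atoms <- considered_atoms(structure)
  bi <- tunnel$bottleneck_index
  near_any <- rep(FALSE, nrow(atoms))
  near_bottle <- rep(FALSE, nrow(atoms))
  axyz <- coords_matrix(atoms)
  for (i in seq_len(nrow(cl))) {
    d <- sqrt((axyz[, 1] - cl$x[i])^2 + (axyz[, 2] - cl$y[i])^2 +
              (axyz[, 3] - cl$z[i])^2) - atoms$vdw_radius - cl$r[i]
    hit <- d <= contact_cutoff
    near_any <- near_any | hit
    if (i == bi) near_bottle <- hit
  }
  pick <- function(mask) {
    res <- dplyr::distinct(atoms[mask, c("chain", "resno", "resname")])
    dplyr::arrange(res, .data$chain, .data$resno)
  }
  list(lining = pick(near_any), bottleneck_residues = pick(near_bottle))
}

#' Radius profile of a tunnel
#'
#' @param tunnel One row of a `tunnelr_tunnels` tibble.
#' @return Tibble with `l` (arc length from the starting point, angstroms)
#'   and `r` (tunnel radius, angstroms).
#' @export
tunnel_profile <- function(tunnel) {
  cl <- tunnel$centerline[[1]]
  tibble::tibble(l = cl$l, r = cl$r)
}
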