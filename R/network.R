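#' Build the clearance-annotated Voronoi network of a structure
#'
#' Computes the 3D Delaunay tessellation of the considered atom centres; the
#' Voronoi vertices are the circumcentres of the finite tetrahedra and the
#' Voronoi edges connect circumcentres of facet-adjacent tetrahedra. Every
#' vertex carries its clearance (distance to the nearest atom *surface*, i.e.
#' van der Waals aware), and every edge its length, minimum clearance and
#' integrated cost contribution `sum(seg_len / clearance_mid^2)` over
#' `edge_samples` interior sample points plus the endpoints. Segments whose
#' midpoint clearance is non-positive make the edge impassable (infinite
#' cost).
#'
#' @param structure Atom table with radii assigned and a `considered` mask.
#' @param edge_samples Number of interior sample points per edge.
#' @return A `tunnelr_network` object: a list with `vertices` (tibble `id`,
#'   `x`, `y`, `z`, `clearance`, `on_hull`, `label`) and `edges` (tibble
#'   `from`, `to`, `length`, `min_clearance`, `cost`). Labels are set by
#'   [label_bulk()]; until then every vertex is `"interior"`.
#' @export
build_network <- function(structure, edge_samples = 3L) {
  atoms <- considered_atoms(structure)
  if (nrow(atoms) < 5) {
    stop_geometry("tessellation needs at least 5 considered atoms, got %d",
                  nrow(atoms))
  }
  xyz <- coords_matrix(atoms)
  if (anyDuplicated(round(xyz, 6)) > 0) {
    stop_geometry("considered atoms contain duplicated coordinates")
  }
  rk <- qr(sweep(xyz, 2, colMeans(xyz)))$rank
  if (rk < 3) stop_geometry("considered atoms are degenerate (coplanar)")
  del <- .delaunay3d(xyz)
  if (nrow(del$vertices) == 0) {
    stop_geometry("tessellation produced no finite Voronoi vertices")
  }
  if (del$skipped > 0.001 * nrow(xyz)) {
    warn(sprintf("tessellation skipped %d near-degenerate atoms", del$skipped))
  }
  clearance <- .clearance_query(del$vertices, xyz, atoms$vdw_radius)
  ann <- .annotate_edges(del$vertices, del$edges, xyz, atoms$vdw_radius,
                         as.integer(edge_samples))
  structure(list(
    vertices = tibble::tibble(
      id = seq_len(nrow(del$vertices)),
      x = del$vertices[, 1], y = del$vertices[, 2], z = del$vertices[, 3],
      clearance = clearance,
      on_hull = del$on_hull,
      label = "interior"
    ),
    edges = tibble::tibble(
      from = del$edges[, 1], to = del$edges[, 2],
      length = ann$length, min_clearance = ann$min_clearance, cost = ann$cost
    ),
    n_atoms = nrow(atoms),
    atoms = list(xyz = xyz, radius = atoms$vdw_radius),
    edge_samples = as.integer(edge_samples),
    shell = NULL
  ), class = "tunnelr_network")
}

#' @export
print.tunnelr_network <- function(x, ...) {
  cat(sprintf("<tunnelr_network> %d vertices, %d edges (from %d atoms)\n",
              nrow(x$vertices), nrow(x$edges), x$n_atoms))
  if (!is.null(x$shell)) {
    cat(sprintf("  labels: %s (shell_radius %.2f, shell_depth %.2f)\n",
                paste(sprintf("%s=%d", names(table(x$vertices$label)),
                              table(x$vertices$label)), collapse = " "),
                x$shell$shell_radius, x$shell$shell_depth))
  }
  invisible(x)
}

#' Label bulk-solvent and shallow surface regions of the network
#'
#' A vertex is bulk when a probe of `shell_radius` fits there (clearance at
#' least `shell_radius`) *and* the vertex communicates with the unbounded
#' exterior through a chain of edges the same probe can pass (edge minimum
#' clearance at least `shell_radius`, seeded at the tessellation hull). Wide
#' but fully enclosed interior cavities therefore stay interior, which keeps
#' them usable as tunnel starting regions. Non-bulk vertices within
#' `shell_depth` (path length along edges) of any bulk vertex are labelled
#' surface; everything else is interior.
#'
#' @param network A `tunnelr_network`.
#' @param shell_radius Bulk-probe radius (angstroms).
#' @param shell_depth Depth of the shallow surface layer (angstroms).
#' @return The network with vertex labels set to bulk/surface/interior.
#' @export
label_bulk <- function(network, shell_radius = 3.0, shell_depth = 4.0) {
  v <- network$vertices
  e <- network$edges
  wide <- v$clearance >= shell_radius
  label <- rep("interior", nrow(v))
  if (any(wide)) {
    sub_e <- e[e$min_clearance >= shell_radius & wide[e$from] & wide[e$to], ,
               drop = FALSE]
    g <- igraph::make_empty_graph(n = nrow(v), directed = FALSE)
    if (nrow(sub_e) > 0) {
      g <- igraph::add_edges(g, rbind(sub_e$from, sub_e$to))
    }
    comp <- igraph::components(g)$membership
    seeds <- which(wide & v$on_hull)
    if (length(seeds) > 0) {
      bulk_comp <- unique(comp[seeds])
      label[wide & comp %in% bulk_comp] <- "bulk"
    }
  }
  if (shell_depth > 0 && any(label == "bulk")) {
    bulk_ids <- which(label == "bulk")
    g2 <- igraph::make_empty_graph(n = nrow(v) + 1, directed = FALSE)
    aux <- nrow(v) + 1L
    ee <- rbind(e$from, e$to)
    g2 <- igraph::add_edges(g2, ee)
    g2 <- igraph::add_edges(g2, rbind(rep(aux, length(bulk_ids)), bulk_ids))
    w <- c(e$length, rep(1e-9, length(bulk_ids)))
    d <- suppressWarnings(
      igraph::distances(g2, v = aux, weights = w)[1, seq_len(nrow(v))])
    label[label != "bulk" & d <= shell_depth] <- "surface"
  }
  network$vertices$label <- label
  network$shell <- list(shell_radius = shell_radius, shell_depth = shell_depth)
  network
}

#' Single-source lowest-cost distances over a weighted edge table
#'
#' The path-search primitive used by [find_tunnels()]: Dijkstra's algorithm
#' on an undirected graph given as an edge table with non-negative costs.
#'
#' @param n_vertices Number of vertices (ids 1..n).
#' @param edges Data frame with `from`, `to`, `cost`.
#' @param start Source vertex id.
#' @return Numeric vector of length `n_vertices`; `Inf` where unreachable.
#' @export
dijkstra_costs <- function(n_vertices, edges, start) {
  g <- igraph::make_empty_graph(n = n_vertices, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  unname(suppressWarnings(
    igraph::distances(g, v = start, weights = edges$cost))[1, ])
}

# igraph over passable edges (finite cost, optional probe filter), bulk
# vertices removed; returns list(graph, edge table used)
passable_graph <- function(network, probe_radius = 0, drop_bulk = TRUE) {
  v <- network$vertices
  e <- network$edges
  keep <- is.finite(e$cost) & e$min_clearance >= probe_radius
  if (drop_bulk) {
    bulk <- v$label == "bulk"
    keep <- keep & !bulk[e$from] & !bulk[e$to]
  }
  e <- e[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(v), directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, rbind(e$from, e$to))
  igraph::E(g)$weight <- e$cost
  igraph::E(g)$length <- e$length
  list(graph = g, edges = e)
}
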