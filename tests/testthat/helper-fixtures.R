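# Shared fixtures, built once per test run. All geometry is generated in
# code; the ground-truth records come from the generators themselves.

quiet_snap <- function(...) suppressWarnings(snap_to_vertex(...))

`%||%` <- function(x, y) if (is.null(x)) y else x

col_or <- function(df, nm, default) if (nm %in% names(df)) df[[nm]] else default

# small hollow shell with one 1.5 A channel along +z
fix_channel <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      fx <- make_shell_channel(r_inner = 4, r_outer = 8, channel_radius = 1.5,
                               lattice_spacing = 0.8, seed = 1)
      net <- label_bulk(build_network(fx$structure), 3, 4)
      st <- quiet_snap(c(0, 0, 0), net)
      val <<- list(fx = fx, net = net, start = st)
    }
    val
  }
})

# two channels: wide +z (2.0 A), narrow +x (1.2 A)
fix_two_channel <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      fx <- make_shell_channel(r_inner = 4, r_outer = 8,
                               channel_radius = c(2.0, 1.2),
                               channel_axis = rbind(c(0, 0, 1), c(1, 0, 0)),
                               lattice_spacing = 0.8, seed = 2)
      net <- label_bulk(build_network(fx$structure), 3, 4)
      st <- quiet_snap(c(0, 0, 0), net)
      val <<- list(fx = fx, net = net, start = st)
    }
    val
  }
})

# wide channel with a tight constriction near the mouth (transport harness);
# the constriction is narrower than the default probe, hence probe 0.7
fix_constricted <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      fx <- make_shell_channel(r_inner = 4, r_outer = 8, channel_radius = 2.0,
                               lattice_spacing = 0.8,
                               constriction = list(l_star = 7, r_star = 0.6,
                                                   width = 2.5),
                               seed = 11)
      net <- label_bulk(build_network(fx$structure), 3, 4)
      st <- quiet_snap(c(0, 0, 0), net)
      tun <- cluster_tunnels(compute_properties(
        find_tunnels(net, st$snapped_vertex, probe_radius = 0.7)), 3.5)
      rep1 <- tun[tun$is_representative & tun$priority_rank == 1, ][1, ]
      val <<- list(fx = fx, net = net, start = st, tunnels = tun, rep1 = rep1)
    }
    val
  }
})

detect_rep1 <- function(h, probe = 0.9) {
  tun <- cluster_tunnels(compute_properties(
    find_tunnels(h$net, h$start$snapped_vertex, probe_radius = probe)), 3.5)
  tun[tun$is_representative & tun$priority_rank == 1, ][1, ]
}

# brute-force clearance: distance to the nearest atom surface
brute_clearance <- function(points, structure) {
  atoms <- structure[structure$considered, ]
  apply(points, 1, function(p) {
    min(sqrt((atoms$x - p[1])^2 + (atoms$y - p[2])^2 + (atoms$z - p[3])^2) -
          atoms$vdw_radius)
  })
}

# exhaustive simple-path enumeration: independent oracle for Dijkstra
enum_shortest <- function(n, edges, start) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]; w <- edges$cost[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  best <- rep(Inf, n)
  best[start] <- 0
  visited <- rep(FALSE, n)
  recurse <- function(u, acc) {
    if (acc < best[u]) best[u] <<- acc
    visited[u] <<- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (!visited[v]) recurse(v, acc + nb[r, 2])
      }
    }
    visited[u] <<- FALSE
  }
  recurse(start, 0)
  best
}

random_graph <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(5:12, 1)
    m <- sample(n:(2 * n), 1)
    edges <- unique(t(replicate(m, sort(sample(n, 2)))))
    tibble::tibble(from = edges[, 1], to = edges[, 2],
                   cost = round(runif(nrow(edges), 0.1, 5), 3))
  })
}

# hand-written 2-model PDB for model selection tests
write_two_model_pdb <- function(path) {
  atom_line <- function(serial, name, res, resno, x, y, z, el) {
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, res, resno, x, y, z, el)
  }
  l <- c("MODEL        1",
         atom_line(1, "CA", "ALA", 1, 0, 0, 0, "C"),
         atom_line(2, "CB", "ALA", 1, 1.5, 0, 0, "C"),
         atom_line(3, "N", "ALA", 1, 0, 1.4, 0, "N"),
         "ENDMDL",
         "MODEL        2",
         atom_line(1, "CA", "ALA", 1, 10, 0, 0, "C"),
         atom_line(2, "CB", "ALA", 1, 11.5, 0, 0, "C"),
         atom_line(3, "N", "ALA", 1, 10, 1.4, 0, "N"),
         "ENDMDL",
         "END")
  writeLines(l, path)
  path
}
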