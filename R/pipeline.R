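#' Default parameters of the detection and transport pipeline
#'
#' All tunable parameters with their defaults; [run_config()] starts from
#' this list. Radii and distances are in angstroms, `max_rotation` in
#' degrees, energies in score units.
#'
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(
    probe_radius = 0.9,
    shell_radius = 3.0,
    shell_depth = 4.0,
    clustering_threshold = 3.5,
    maximal_distance = 3.0,
    desired_radius = 5.0,
    contact_cutoff = 3.0,
    edge_samples = 3L,
    exclude_water = TRUE,
    include_het_names = character(),
    delta = 0.3,
    disc_margin = 1.0,
    n_starts = 24L,
    max_rotation = 10,
    backtrack_window = 5L,
    energy_slack = 2.0,
    seed = 1L
  )
}

#' Assemble a run configuration
#'
#' @param structure_path Input PDB path.
#' @param output_dir Output directory for artifacts.
#' @param start Starting-point specification, exactly one mode:
#'   `list(coordinates = c(x, y, z))`, `list(residues = c("A:12", ...))`,
#'   `list(ligand = "LIG")` or `list(pocket = rank)`.
#' @param ... Parameter overrides (see [default_params()]); unknown names are
#'   rejected.
#' @return A `tunnelr_config` list.
#' @export
run_config <- function(structure_path, output_dir, start, ...) {
  over <- list(...)
  base <- default_params()
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    stop_input("unknown configuration key(s): %s",
               paste(unknown, collapse = ", "))
  }
  base[names(over)] <- over
  if (length(start) != 1 || !names(start) %in%
        c("coordinates", "residues", "ligand", "pocket")) {
    stop_input("exactly one starting-point mode must be given")
  }
  structure(c(list(structure_path = structure_path, output_dir = output_dir,
                   start = start), base),
            class = "tunnelr_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with `structure_path`, `output_dir`, `start` and any
#'   parameter overrides.
#' @return A `tunnelr_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  req <- c("structure_path", "output_dir", "start")
  if (!all(req %in% names(y))) {
    stop_input("config must define %s", paste(req, collapse = ", "))
  }
  extra <- y[setdiff(names(y), req)]
  do.call(run_config, c(y[req], extra))
}

log_line <- function(log, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  cat(msg, "\n", sep = "", file = log, append = TRUE)
  invisible(msg)
}

#' Run the tunnel-detection pipeline and write its artifacts
#'
#' Four phases: structure pre-treatment, starting-point detection, network
#' construction and tunnel search/clustering. Writes to the output
#' directory: `tunnels.json` (all properties, lining residues, centerlines
#' and the parameters actually used), `profile_<k>.csv` and `tunnel_<k>.pdb`
#' per cluster representative, `view.pml` (plain-text PyMOL commands),
#' `config.yaml` (echo) and `run.log`.
#'
#' @param config A `tunnelr_config`.
#' @return Exit status, invisibly: 0 on success (also with zero tunnels),
#'   2 on input errors, 3 on geometry errors.
#' @export
cmd_detect <- function(config) {
  status <- tryCatch({
    detect_run(config)
    0L
  }, tunnelr_input_error = function(e) {
    message("input error (detect): ", conditionMessage(e))
    2L
  }, tunnelr_geometry_error = function(e) {
    message("geometry error (detect): ", conditionMessage(e))
    3L
  })
  invisible(status)
}

detect_run <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$output_dir, "run.log")
  cat("", file = log)
  cfg_echo <- unclass(config)
  cfg_echo$include_het_names <- as.list(cfg_echo$include_het_names)
  yaml::write_yaml(cfg_echo, file.path(config$output_dir, "config.yaml"))
  log_line(log, "phase 1: reading %s", config$structure_path)
  s <- read_structure(config$structure_path)
  s <- assign_radii(s)
  s <- select_considered(s, exclude_water = config$exclude_water,
                         include_het_names = config$include_het_names)
  log_line(log, "  %d atoms, %d considered", nrow(s), sum(s$considered))

  log_line(log, "phase 2: network (%d considered atoms, edge_samples=%d)",
           sum(s$considered), config$edge_samples)
  net <- build_network(s, edge_samples = config$edge_samples)
  net <- label_bulk(net, shell_radius = config$shell_radius,
                    shell_depth = config$shell_depth)
  log_line(log, "  %d vertices (%d bulk), %d edges", nrow(net$vertices),
           sum(net$vertices$label == "bulk"), nrow(net$edges))

  log_line(log, "phase 3: starting point (%s mode)", names(config$start))
  raw <- switch(names(config$start),
    coordinates = new_starting_point(config$start$coordinates, "coordinates"),
    residues = start_from_residues(s, config$start$residues),
    ligand = start_from_ligand(s, config$start$ligand),
    pocket = {
      pockets <- detect_pockets(s, network = net)
      rk <- config$start$pocket
      if (nrow(pockets) < rk) stop_geometry("pocket rank %d not found", rk)
      start_from_pocket(pockets[rk, ], s)
    })
  start <- snap_to_vertex(raw, net,
                          maximal_distance = config$maximal_distance,
                          desired_radius = config$desired_radius)
  log_line(log, "  snapped to vertex %d (clearance %.2f)",
           start$snapped_vertex,
           net$vertices$clearance[start$snapped_vertex])

  log_line(log, "phase 4: tunnel search (probe %.2f)", config$probe_radius)
  tunnels <- find_tunnels(net, start$snapped_vertex,
                          probe_radius = config$probe_radius)
  if (nrow(tunnels) == 0) {
    warn("no tunnel found for the given probe radius")
    log_line(log, "  no tunnels found (legal empty result)")
    write_tunnels_json(new_tunnel_set(tibble::tibble()), list(), config, s,
                       file.path(config$output_dir, "tunnels.json"))
    return(invisible(0L))
  }
  tunnels <- compute_properties(tunnels)
  tunnels <- cluster_tunnels(tunnels,
                             clustering_threshold = config$clustering_threshold)
  reps <- tunnels[tunnels$is_representative, ]
  log_line(log, "  %d tunnels in %d clusters", nrow(tunnels), nrow(reps))

  residues <- purrr::map(seq_len(nrow(reps)), function(i) {
    lining_residues(reps[i, ], s, contact_cutoff = config$contact_cutoff)
  })
  write_tunnels_json(reps, residues, config, s,
                     file.path(config$output_dir, "tunnels.json"))
  for (i in seq_len(nrow(reps))) {
    k <- reps$priority_rank[i]
    prof <- tunnel_profile(reps[i, ])
    write.csv(data.frame(l_angstrom = prof$l, r_angstrom = prof$r),
              file.path(config$output_dir, sprintf("profile_%d.csv", k)),
              row.names = FALSE)
    cl <- reps$centerline[[i]]
    write_spheres_pdb(data.frame(x = cl$x, y = cl$y, z = cl$z, r = cl$r,
                                 radius = cl$r),
                      file.path(config$output_dir, sprintf("tunnel_%d.pdb", k)))
  }
  writeLines(c(
    sprintf("load %s, protein", normalizePath(config$structure_path)),
    "hide everything, protein",
    "show cartoon, protein",
    purrr::map_chr(reps$priority_rank, function(k) {
      paste0(sprintf("load tunnel_%d.pdb, tun%d\n", k, k),
             sprintf("alter tun%d, vdw=b\n", k),
             sprintf("show spheres, tun%d", k))
    }),
    "rebuild"), file.path(config$output_dir, "view.pml"))
  log_line(log, "done")
  invisible(0L)
}

write_tunnels_json <- function(reps, residues, config, structure, path) {
  tl <- purrr::map(seq_len(nrow(reps)), function(i) {
    cl <- reps$centerline[[i]]
    res <- residues[[i]]
    list(
      rank = reps$priority_rank[i],
      cluster_id = reps$cluster_id[i],
      bottleneck_radius = reps$bottleneck_radius[i],
      length = reps$length[i],
      curvature = reps$curvature[i],
      cost = reps$cost[i],
      throughput = reps$throughput[i],
      lining_residues = res$lining,
      bottleneck_residues = res$bottleneck_residues,
      centerline = as.list(cl))
  })
  cfg <- unclass(config)
  cfg$include_het_names <- as.list(cfg$include_het_names)
  jsonlite::write_json(
    list(parameters = cfg, n_tunnels = nrow(reps), tunnels = tl),
    path, auto_unbox = TRUE, digits = 8, pretty = TRUE)
}

read_tunnels_json <- function(path) {
  if (!file.exists(path)) stop_input("tunnels.json not found at %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (j$n_tunnels == 0) {
    return(new_tunnel_set(tibble::tibble()))
  }
  tn <- j$tunnels
  out <- tibble::tibble(
    id = seq_len(nrow(tn)),
    priority_rank = tn$rank,
    cluster_id = tn$cluster_id,
    bottleneck_radius = tn$bottleneck_radius,
    length = tn$length,
    curvature = tn$curvature,
    cost = tn$cost,
    throughput = tn$throughput,
    centerline = purrr::map(seq_len(nrow(tn)), function(i) {
      tibble::as_tibble(tn$centerline[i, ][, c("l", "x", "y", "z", "r")]) |>
        tidyr::unnest(c("l", "x", "y", "z", "r"))
    })
  )
  out$bottleneck_index <- purrr::map_int(out$centerline, ~ which.min(.x$r))
  new_tunnel_set(out)
}

#' Run a ligand-transport analysis against a detected tunnel
#'
#' Reads `tunnels.json` from a completed detection run, discretizes the
#' selected tunnel and computes the requested energy profile. Writes into
#' `<run_dir>/transport_<job>/`: `profile.csv`, `trajectory.pdb` (one MODEL
#' per disc pose) and `barriers.json`.
#'
#' @param config List/`tunnelr_config` with at least `structure_path`,
#'   `output_dir` (the detection run directory), `ligand_path`, `tunnel_rank`,
#'   `mode` (`"lower_bound"`/`"upper_bound"`), `direction`, and optionally
#'   the transport parameters of [default_params()] plus `job_id`.
#' @return Exit status invisibly: 0 on success (including an upper-bound
#'   "failed" path, reported in `barriers.json`), 2 on input errors.
#' @export
cmd_transport <- function(config) {
  status <- tryCatch({
    transport_run(config)
    0L
  }, tunnelr_input_error = function(e) {
    message("input error (transport): ", conditionMessage(e))
    2L
  }, tunnelr_geometry_error = function(e) {
    message("geometry error (transport): ", conditionMessage(e))
    3L
  })
  invisible(status)
}

transport_run <- function(config) {
  p <- default_params()
  p[intersect(names(config), names(p))] <-
    config[intersect(names(config), names(p))]
  tunnels <- read_tunnels_json(file.path(config$output_dir, "tunnels.json"))
  rk <- config$tunnel_rank %||% 1L
  if (nrow(tunnels) == 0 || !rk %in% tunnels$priority_rank) {
    stop_input("tunnel rank %s not present in %s", rk, config$output_dir)
  }
  tunnel <- tunnels[tunnels$priority_rank == rk, ][1, ]
  ligand <- load_ligand(config$ligand_path)
  s <- read_structure(config$structure_path)
  s <- assign_radii(s)
  s <- select_considered(s, exclude_water = p$exclude_water,
                         include_het_names = p$include_het_names)
  discs <- discretize(tunnel, delta = p$delta, disc_margin = p$disc_margin)
  mode <- match.arg(config$mode %||% "lower_bound",
                    c("lower_bound", "upper_bound"))
  direction <- match.arg(config$direction %||% "in", c("in", "out"))
  prof <- if (mode == "lower_bound") {
    lower_bound_profile(ligand, discs, s, direction = direction,
                        n_starts = p$n_starts, seed = p$seed)
  } else {
    upper_bound_profile(ligand, discs, s, direction = direction,
                        n_starts = p$n_starts, seed = p$seed,
                        max_rotation = p$max_rotation,
                        backtrack_window = p$backtrack_window,
                        energy_slack = p$energy_slack)
  }
  prof <- barrier_analysis(prof)
  job <- config$job_id %||% sprintf("%s_%s_%s", ligand$name, rk, mode)
  jdir <- file.path(config$output_dir, paste0("transport_", job))
  dir.create(jdir, showWarnings = FALSE, recursive = TRUE)
  ent <- tidy.tunnelr_profile(prof)
  write.csv(
    data.frame(disc_index = ent$disc_index,
               arc_length_angstrom = ent$arc_length, energy = ent$energy,
               anchor_x = ent$anchor_x, anchor_y = ent$anchor_y,
               anchor_z = ent$anchor_z, quat_w = ent$quat_w,
               quat_x = ent$quat_x, quat_y = ent$quat_y,
               quat_z = ent$quat_z),
    file.path(jdir, "profile.csv"), row.names = FALSE)
  write_trajectory_pdb(ligand, prof, file.path(jdir, "trajectory.pdb"))
  jsonlite::write_json(
    c(prof$barriers,
      list(ligand = ligand$name, tunnel_rank = rk, delta = p$delta,
           seed = p$seed)),
    file.path(jdir, "barriers.json"), auto_unbox = TRUE, digits = 8,
    pretty = TRUE)
  invisible(0L)
}

write_trajectory_pdb <- function(ligand, profile, path) {
  loc <- lig_local_coords(ligand)
  con <- file(path, "w")
  on.exit(close(con))
  ent <- profile$entries
  for (i in seq_len(nrow(ent))) {
    posed <- .apply_pose(loc, c(ent$quat_w[i], ent$quat_x[i], ent$quat_y[i],
                                ent$quat_z[i]),
                         c(ent$anchor_x[i], ent$anchor_y[i], ent$anchor_z[i]))
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "HETATM%5d %-4s LIG A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(posed)), substr(ligand$atoms$element, 1, 2), 1L,
      posed[, 1], posed[, 2], posed[, 3], 1, 0,
      toupper(substr(ligand$atoms$element, 1, 2))), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Summarize a completed run directory
#'
#' @param run_dir Directory written by [cmd_detect()] (and optionally
#'   [cmd_transport()] jobs).
#' @return A list of two tibbles, `tunnels` (rank, bottleneck, length,
#'   curvature, throughput) and `transport` (one row per job: ligand,
#'   tunnel, direction, mode, barrier energies, status), ordered by job id.
#' @export
cmd_report <- function(run_dir) {
  jf <- file.path(run_dir, "tunnels.json")
  if (!file.exists(jf)) stop_input("no tunnels.json in %s", run_dir)
  j <- jsonlite::read_json(jf, simplifyVector = TRUE)
  tunnels <- if (j$n_tunnels == 0) {
    tibble::tibble(rank = integer(), bottleneck_radius = numeric(),
                   length = numeric(), curvature = numeric(),
                   cost = numeric(), throughput = numeric())
  } else {
    tibble::as_tibble(j$tunnels[, c("rank", "bottleneck_radius", "length",
                                    "curvature", "cost", "throughput")])
  }
  jobs <- sort(list.dirs(run_dir, recursive = FALSE))
  jobs <- jobs[grepl("^transport_", basename(jobs))]
  transport <- purrr::map(jobs, function(d) {
    b <- jsonlite::read_json(file.path(d, "barriers.json"),
                             simplifyVector = TRUE)
    tibble::tibble(job = sub("^transport_", "", basename(d)),
                   ligand = b$ligand, tunnel_rank = b$tunnel_rank,
                   direction = b$direction, mode = b$mode,
                   E_B = b$E_B, E_MAX = b$E_MAX, E_S = b$E_S, Ea = b$Ea,
                   dE_bind = b$dE_bind, status = b$status)
  })
  list(tunnels = tunnels, transport = dplyr::bind_rows(transport))
}
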