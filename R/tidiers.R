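#' Tidy a tunnel set into long profile form
#'
#' @param x A `tunnelr_tunnels` tibble.
#' @param ... Unused.
#' @return Tibble with one row per centerline sphere: `id`, `cluster_id` and
#'   `priority_rank` when present, `l`, `x`, `y`, `z`, `r`.
#' @export
tidy.tunnelr_tunnels <- function(x, ...) {
  meta <- intersect(c("id", "cluster_id", "priority_rank"), names(x))
  tidyr::unnest(tibble::as_tibble(x)[, c(meta, "centerline")],
                "centerline")
}

#' One-row-per-tunnel property summary
#'
#' @param x A `tunnelr_tunnels` tibble with properties computed.
#' @param ... Unused.
#' @return Tibble of scalar tunnel properties.
#' @export
glance.tunnelr_tunnels <- function(x, ...) {
  cols <- intersect(c("id", "cluster_id", "priority_rank", "is_representative",
                      "bottleneck_radius", "length", "curvature", "cost",
                      "throughput", "exit_vertex"), names(x))
  tibble::as_tibble(x)[, cols]
}

#' Per-disc entries of an energy profile
#'
#' @param x A `tunnelr_profile`.
#' @param ... Unused.
#' @return The entry tibble in trajectory order, with `step` added.
#' @export
tidy.tunnelr_profile <- function(x, ...) {
  dplyr::mutate(x$entries, step = dplyr::row_number(), .before = 1)
}

#' One-row summary of an energy profile
#'
#' @param x A `tunnelr_profile` (run [barrier_analysis()] first to fill the
#'   barrier fields).
#' @param ... Unused.
#' @return One-row tibble: mode, direction, status, disc count and barrier
#'   energies (NA until extracted).
#' @export
glance.tunnelr_profile <- function(x, ...) {
  b <- x$barriers
  tibble::tibble(
    mode = x$mode, direction = x$direction, status = x$status,
    n_discs = nrow(x$entries),
    E_B = b$E_B %||% NA_real_, E_MAX = b$E_MAX %||% NA_real_,
    E_S = b$E_S %||% NA_real_, Ea = b$Ea %||% NA_real_,
    dE_bind = b$dE_bind %||% NA_real_)
}

#' Plot tunnel radius profiles
#'
#' @param object A `tunnelr_tunnels` tibble.
#' @param ... Unused.
#' @return A ggplot: radius over arc length, one line per tunnel.
#' @export
autoplot.tunnelr_tunnels <- function(object, ...) {
  df <- tidy.tunnelr_tunnels(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$l, .data$r,
                                   group = .data$id,
                                   colour = factor(.data$id))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length l [Å]", y = "tunnel radius r(l) [Å]",
                  colour = "tunnel") +
    ggplot2::theme_minimal()
}

#' Plot an energy profile over the tunnel arc length
#'
#' @param object A `tunnelr_profile`.
#' @param ... Unused.
#' @return A ggplot of per-disc energy; barrier points are marked when
#'   [barrier_analysis()] has been run.
#' @export
autoplot.tunnelr_profile <- function(object, ...) {
  df <- object$entries
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$arc_length, .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "arc length along tunnel [Å]",
                  y = "binding energy [score units]",
                  title = sprintf("%s profile (%s)", object$mode,
                                  object$direction)) +
    ggplot2::theme_minimal()
  if (!is.null(object$barriers)) {
    ent <- dplyr::arrange(df, .data$arc_length)
    b <- object$barriers
    marks <- ent[c(b$i_B, b$i_MAX, b$i_S), ]
    marks$label <- c("E_B", "E_MAX", "E_S")
    p <- p + ggplot2::geom_point(data = marks, colour = "red", size = 2) +
      ggplot2::geom_text(data = marks,
                         ggplot2::aes(label = .data$label),
                         vjust = -1, colour = "red", size = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
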