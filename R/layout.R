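#' Idealized 64-channel 10-20/10-10 electrode layout
#'
#' Flat polar projection of the extended 10-20 system: the vertex Cz at the
#' origin, the outer circumferential ring (Fpz...Oz) at radius 0.8, midline
#' electrodes at 0.2 steps along the y axis, and intermediate rows placed by
#' linear interpolation between their midline and outer-ring endpoints. This
#' is an idealized template layout (it carries the topology of a standard
#' 64-channel cap, not measured head coordinates); it serves to define channel
#' neighbourhoods for cluster formation and spatial weighting in the
#' simulator. Four EOG channels carry no scalp position.
#'
#' @return data.frame with columns `label`, `x`, `y`, `type`
#'   (`"scalp"`/`"eog"`).
#' @export
electrode_layout_1020 <- function() {
  ring <- function(deg) c(x = 0.8 * sin(deg * pi / 180), y = 0.8 * cos(deg * pi / 180))
  # outer circumferential ring, 18 degree (10%) steps; negative = left
  outer <- list(
    Fpz = ring(0), Fp2 = ring(18), AF8 = ring(36), F8 = ring(54),
    FT8 = ring(72), T8 = ring(90), TP8 = ring(108), P8 = ring(126),
    PO8 = ring(144), O2 = ring(162), Oz = ring(180), O1 = ring(-162),
    PO7 = ring(-144), P7 = ring(-126), TP7 = ring(-108), T7 = ring(-90),
    FT7 = ring(-72), F7 = ring(-54), AF7 = ring(-36), Fp1 = ring(-18))
  midline <- list(AFz = c(0, 0.6), Fz = c(0, 0.4), Cz = c(0, 0),
                  CPz = c(0, -0.2), Pz = c(0, -0.4), POz = c(0, -0.6))
  # intermediate rows: fractions along the segment midline endpoint -> outer
  # ring endpoint (1/4, 1/2, 3/4 for four-electrode rows; 1/2 for AF/PO)
  interp <- function(from, to, frac) from + frac * (to - from)
  rows <- list(
    list(c("AF3"), "AFz", "AF7", c(0.5)),
    list(c("F1", "F3", "F5"), "Fz", "F7", c(0.25, 0.5, 0.75)),
    list(c("FC1", "FC3", "FC5"), c(0, 0.2), "FT7", c(0.25, 0.5, 0.75)),
    list(c("C1", "C3", "C5"), "Cz", "T7", c(0.25, 0.5, 0.75)),
    list(c("CP1", "CP3", "CP5"), "CPz", "TP7", c(0.25, 0.5, 0.75)),
    list(c("P1", "P3", "P5"), "Pz", "P7", c(0.25, 0.5, 0.75)),
    list(c("PO3"), "POz", "PO7", c(0.5)),
    list(c("AF4"), "AFz", "AF8", c(0.5)),
    list(c("F2", "F4", "F6"), "Fz", "F8", c(0.25, 0.5, 0.75)),
    list(c("FC2", "FC4", "FC6"), c(0, 0.2), "FT8", c(0.25, 0.5, 0.75)),
    list(c("C2", "C4", "C6"), "Cz", "T8", c(0.25, 0.5, 0.75)),
    list(c("CP2", "CP4", "CP6"), "CPz", "TP8", c(0.25, 0.5, 0.75)),
    list(c("P2", "P4", "P6"), "Pz", "P8", c(0.25, 0.5, 0.75)),
    list(c("PO4"), "POz", "PO8", c(0.5)))
  pos <- c(outer, midline)
  for (r in rows) {
    from <- if (is.character(r[[2]])) pos[[r[[2]]]] else r[[2]]
    to <- pos[[r[[3]]]]
    for (i in seq_along(r[[1]])) pos[[r[[1]][i]]] <- interp(from, to, r[[4]][i])
  }
  scalp <- data.frame(label = names(pos),
                      x = vapply(pos, `[`, numeric(1), 1L),
                      y = vapply(pos, `[`, numeric(1), 2L),
                      type = "scalp", row.names = NULL)
  eog <- data.frame(label = c("HEOGL", "HEOGR", "VEOGU", "VEOGD"),
                    x = NA_real_, y = NA_real_, type = "eog")
  rbind(scalp, eog)
}

#' Channel neighbourhood graph from a sensor layout
#'
#' Two scalp channels are neighbours when their distance in the flat layout is
#' at most `max_dist` (default 0.28 covers nearest lateral and row-to-row
#' spacings of ~0.2 without bridging across a full row). EOG channels have no
#' neighbours. The relation is symmetric and irreflexive and, for the packaged
#' template, every scalp channel has at least one neighbour.
#'
#' @param layout data.frame as returned by [electrode_layout_1020()].
#' @param max_dist neighbourhood distance threshold in layout units.
#' @return object of class `neighbour_graph`: list with `labels` and the
#'   logical `adjacency` matrix.
#' @export
channel_neighbours <- function(layout = electrode_layout_1020(), max_dist = 0.28) {
  stopifnot(all(c("label", "x", "y") %in% names(layout)))
  n <- nrow(layout)
  d <- as.matrix(stats::dist(layout[, c("x", "y")]))
  adj <- d <= max_dist & !is.na(d)
  diag(adj) <- FALSE
  adj[is.na(layout$x), ] <- FALSE
  adj[, is.na(layout$x)] <- FALSE
  dimnames(adj) <- list(layout$label, layout$label)
  scalp <- layout$type == "scalp"
  if (any(scalp & rowSums(adj) == 0))
    warning("scalp channel(s) without neighbours: ",
            paste(layout$label[scalp & rowSums(adj) == 0], collapse = ", "))
  structure(list(labels = layout$label, adjacency = adj,
                 max_dist = max_dist), class = "neighbour_graph")
}

#' @export
print.neighbour_graph <- function(x, ...) {
  cat(sprintf("Channel neighbour graph: %d channels, mean degree %.1f (max_dist = %g)\n",
              length(x$labels), mean(rowSums(x$adjacency)), x$max_dist))
  invisible(x)
}
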