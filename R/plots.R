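# ggplot2 visualization helpers.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col coord_fixed
#'   facet_wrap labs theme_minimal ylim
#' @export
ggplot2::autoplot

#' Plot a pocket grid
#'
#' Axis-projected scatter of the retained grid points (and optionally the
#' pocket atoms) on the xy, xz and yz planes.
#'
#' @param object A `pocket_grid`.
#' @param atoms Optional atom tibble drawn underneath the grid points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pocket_grid <- function(object, atoms = NULL, ...) {
  pts <- as.data.frame(object$points)
  names(pts) <- c("x", "y", "z")
  proj <- function(df, what) {
    bind_rows(
      tibble(h = df$x, v = df$y, plane = "xy", what = what),
      tibble(h = df$x, v = df$z, plane = "xz", what = what),
      tibble(h = df$y, v = df$z, plane = "yz", what = what))
  }
  dat <- proj(pts, "grid point")
  if (!is.null(atoms) && nrow(atoms) > 0) {
    dat <- bind_rows(proj(as.data.frame(atoms[, c("x", "y", "z")]), "atom"),
                     dat)
  }
  ggplot(dat, aes(x = .data$h, y = .data$v, colour = .data$what)) +
    geom_point(size = 1) +
    facet_wrap(~plane, scales = "free") +
    coord_fixed() +
    labs(x = NULL, y = NULL, colour = NULL,
         title = sprintf("Pocket grid (%d points, %.2f Å spacing)",
                         nrow(pts), object$spacing)) +
    theme_minimal()
}

#' Plot benchmark metrics
#'
#' Bar chart of the pocket-level and residue-level metrics in a
#' `metrics_report` (or of the binary relevance-filter metrics).
#'
#' @param object A `metrics_report` or `relevance_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  dat <- tidy(object)
  dat <- dat[!is.na(dat$value), ]
  ggplot(dat, aes(x = .data$metric, y = .data$value)) +
    geom_col(fill = "steelblue") +
    ylim(0, 1) +
    labs(x = NULL, y = NULL, title = "Pocket extraction metrics") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.metrics_report
#' @export
autoplot.relevance_metrics <- function(object, ...) {
  dat <- tidy(object)
  ggplot(dat, aes(x = .data$metric, y = .data$value)) +
    geom_col(fill = "darkorange") +
    ylim(0, 1) +
    labs(x = NULL, y = NULL, title = "Relevance filter metrics") +
    theme_minimal()
}

#' Plot mapped pockets
#'
#' Residue-centroid scatter (xz projection) coloured by pocket, with
#' interface pockets marked by shape.
#'
#' @param object A `mapped_pockets` tibble.
#' @param structure The `protein_structure` the pockets were mapped onto.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mapped_pockets <- function(object, structure, ...) {
  rows <- lapply(seq_len(nrow(object)), function(i) {
    cent <- residue_centroids(structure, object$residues[[i]])
    mutate(cent,
           pocket = sprintf("%s [%s]", object$name[[i]],
                            paste(object$chains[[i]], collapse = "")),
           interface = object$interface[[i]])
  })
  dat <- bind_rows(rows)
  ggplot(dat, aes(x = .data$x, y = .data$z, colour = .data$pocket,
                  shape = .data$interface)) +
    geom_point(size = 2) +
    coord_fixed() +
    labs(x = "x (Å)", y = "z (Å)", colour = NULL,
         shape = "interface") +
    theme_minimal()
}
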