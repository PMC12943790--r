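#' @title Diagram plotting
#' @description Base-graphics renderings of binary sections and the
#'   triangular ternary diagram, following the field's visual conventions:
#'   circled phase markers, domain boundaries, eutectic points, an optional
#'   recommended mixing-ratio segment and a cross at the 1:1 test point.
#' @name plotting
NULL

#' @export
plot.binary_diagram <- function(x, n = 201, ...) {
  s <- sample_binary_diagram(x, n)
  plot(s$x, s$T_C, type = "n", xlab = x$x_axis,
       ylab = "temperature (°C)",
       main = paste("Binary section:", paste(x$section, collapse = " / ")), ...)
  for (ph in unique(s$phase)) {
    sel <- s$phase == ph
    graphics::lines(s$x[sel], s$T_C[sel], lwd = 2)
  }
  for (e in x$eutectics) {
    graphics::points(e$x_A, e$T_eu - 273.15, pch = 19)
    graphics::text(e$x_A, e$T_eu - 273.15,
                   sprintf("  x=%.3f, %.1f°C", e$x_A, e$T_eu - 273.15),
                   adj = c(0, 1), cex = 0.8)
  }
  invisible(x)
}

#' @param show_domains Colour the dominating-phase domains from a raster?
#' @param grid_density Raster density when `show_domains` is `TRUE`.
#' @param mixing_line Draw the racemate-agent mixing line?
#' @param test_point Mark the 1:1 test composition with a cross?
#' @rdname plotting
#' @export
plot.ternary_diagram <- function(x, show_domains = TRUE, grid_density = 101,
                                 mixing_line = TRUE, test_point = TRUE, ...) {
  ps <- x$phase_set
  corners <- .simplex_xy(diag(3))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.08, 1.08), ylim = c(-0.1, sqrt(3) / 2 + 0.08),
                        asp = 1)
  if (show_domains) {
    dm <- domain_map(x, grid_density)
    g <- dm$grid[!is.na(dm$grid$phase), ]
    if (nrow(g)) {
      xy <- .simplex_xy(as.matrix(g[, c("c1", "c2", "c3")]))
      phs <- sort(unique(g$phase))
      cols <- grDevices::hcl.colors(max(3L, length(phs)), "Set 3")[seq_along(phs)]
      graphics::points(xy[, 1], xy[, 2], pch = 15, cex = 0.45,
                       col = cols[match(g$phase, phs)])
    }
  }
  graphics::polygon(corners[, 1], corners[, 2], border = "black", lwd = 1.5)
  graphics::text(corners[c(1, 2), 1], corners[c(1, 2), 2] - 0.05,
                 ps$components[1:2], cex = 0.9)
  graphics::text(corners[3, 1], corners[3, 2] + 0.05, ps$components[3], cex = 0.9)

  for (s in x$subternaries) {
    xy <- .simplex_xy(s$coords)
    graphics::polygon(xy[, 1], xy[, 2], border = "grey35", lty = 3)
  }
  for (e in x$eutectics) {
    if (is.null(e)) next
    xy <- .simplex_xy(e$composition)
    graphics::points(xy[, 1], xy[, 2], pch = 8, cex = 0.9)
    graphics::text(xy[, 1], xy[, 2] - 0.03,
                   sprintf("%.0f°C", e$T_eu - 273.15), cex = 0.7)
  }
  coords <- t(vapply(ps$phases, `[[`, numeric(3), "coords"))
  xy <- .simplex_xy(coords)
  graphics::points(xy[, 1], xy[, 2], pch = 21, bg = "white", cex = 2.2)
  graphics::text(xy[, 1], xy[, 2], names(ps$phases), cex = 0.65)

  if (mixing_line) {
    sgrid <- seq(0, 1, length.out = 50)
    line_xy <- .simplex_xy(cbind((1 - sgrid) / 2, (1 - sgrid) / 2, sgrid))
    graphics::lines(line_xy[, 1], line_xy[, 2], lty = 2, col = "purple", lwd = 2)
  }
  if (test_point) {
    tp <- .simplex_xy(c(0.25, 0.25, 0.5))
    graphics::points(tp[, 1], tp[, 2], pch = 4, col = "red", cex = 1.6, lwd = 2)
  }
  graphics::title(main = sprintf("Ternary melting phase diagram (%s)",
                                 paste(ps$components, collapse = " / ")))
  invisible(x)
}

#' Write a ternary diagram plot to a PNG or SVG file
#'
#' @param diagram A [ternary_diagram()].
#' @param path Output path ending in `.png` or `.svg`.
#' @param width,height Device size in inches.
#' @param ... Passed to [plot.ternary_diagram()].
#' @return Invisibly, `path`.
#' @export
save_ternary_plot <- function(diagram, path, width = 7, height = 6.5, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") grDevices::png(path, width = width, height = height,
                                   units = "in", res = 150)
  else if (ext == "svg") grDevices::svg(path, width = width, height = height)
  else stop("unsupported plot format '.", ext, "' (use .png or .svg)",
            call. = FALSE)
  on.exit(grDevices::dev.off())
  plot(diagram, ...)
  invisible(path)
}
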