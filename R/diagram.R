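#' Polar-diagram layout
#'
#' Fixed drawing conventions for the radar diagram: parameters in registry
#' order, first axis at 12 o'clock, proceeding clockwise, radial scale 0-10
#' with the acceptability ring at 5.
#'
#' @param start_angle angle of the first axis in radians (default `pi/2`,
#'   i.e. straight up).
#' @param clockwise logical; direction of successive axes.
#' @return A list with the layout fields.
#' @export
diagram_layout <- function(start_angle = pi / 2, clockwise = TRUE) {
  list(start_angle = start_angle, clockwise = clockwise,
       r_max = 10, r_accept = 5)
}

#' Cartesian vertices of a radius polygon
#'
#' Vertex k sits at angle `start - k * 2*pi/n` (clockwise) with radial
#' distance equal to the clamped radius, so negative raw radii collapse to
#' the origin.
#'
#' @param profile a `radius_profile`.
#' @param layout a [diagram_layout()].
#' @return A data.frame with columns `id`, `x`, `y`; the polygon is closed
#'   implicitly (last vertex connects back to the first).
#' @export
polygon_coordinates <- function(profile, layout = diagram_layout()) {
  check_profile(profile)
  n <- nrow(profile$radii)
  k <- seq_len(n) - 1L
  step <- if (layout$clockwise) -2 * pi / n else 2 * pi / n
  theta <- layout$start_angle + k * step
  r <- profile$radii$clamped_r
  data.frame(id = profile$radii$id,
             x = r * cos(theta), y = r * sin(theta),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shaded-area ratio of a profile
#'
#' Area of the radius polygon (shoelace formula on the clamped radii) divided
#' by the area of the full-score circle of radius 10.  For a constant profile
#' of radius c over n axes this equals `(c/10)^2 * n * sin(2*pi/n) / (2*pi)`
#' — at c = 10 the polygon ratio is exactly the reliability factor formula.
#'
#' @param profile a `radius_profile`.
#' @return Ratio in `[0, 1]`.
#' @export
shaded_area_ratio <- function(profile) {
  pts <- polygon_coordinates(profile)
  x <- pts$x; y <- pts$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  area / (pi * 10^2)
}

#' Render a radar diagram as SVG
#'
#' Writes a deterministic, self-contained SVG: grid rings at 2.5-unit steps,
#' the acceptability ring at 5 emphasised, one labelled axis per parameter
#' and the filled radius polygon.  Byte output depends only on the profile.
#'
#' @param profile a `radius_profile`.
#' @param path output file path.
#' @param layout a [diagram_layout()].
#' @return Invisibly, the path written.
#' @export
render_svg <- function(profile, path, layout = diagram_layout()) {
  check_profile(profile)
  pts <- polygon_coordinates(profile, layout)
  n <- nrow(pts)
  size <- 520
  cx <- size / 2
  scale <- 20 # px per radius unit
  to_px <- function(x, y) c(cx + x * scale, cx - y * scale)

  fmt <- function(x) sprintf("%.2f", x)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size),
    sprintf('<title>SeDeM profile %s (%s)</title>', profile$batch_id,
            profile$system)
  )
  for (ring in c(2.5, 5, 7.5, 10)) {
    lines <- c(lines, sprintf(
      '<circle cx="%d" cy="%d" r="%s" fill="none" stroke="%s" stroke-width="%s"/>',
      cx, cx, fmt(ring * scale),
      if (ring == layout$r_accept) "#cc0000" else "#cccccc",
      if (ring == layout$r_accept) "1.5" else "0.8"))
  }
  step <- if (layout$clockwise) -2 * pi / n else 2 * pi / n
  for (k in seq_len(n)) {
    theta <- layout$start_angle + (k - 1L) * step
    tip <- to_px(10 * cos(theta), 10 * sin(theta))
    lab <- to_px(11.7 * cos(theta), 11.7 * sin(theta))
    lines <- c(lines,
      sprintf('<line x1="%d" y1="%d" x2="%s" y2="%s" stroke="#999999" stroke-width="0.8"/>',
              cx, cx, fmt(tip[1]), fmt(tip[2])),
      sprintf('<text x="%s" y="%s" font-size="11" text-anchor="middle" class="axis-label">%s</text>',
              fmt(lab[1]), fmt(lab[2]), profile$radii$id[k]))
  }
  poly <- apply(pts, 1, function(row) {
    p <- to_px(as.numeric(row[["x"]]), as.numeric(row[["y"]]))
    paste0(fmt(p[1]), ",", fmt(p[2]))
  })
  lines <- c(lines,
    sprintf('<polygon points="%s" fill="#4477aa" fill-opacity="0.45" stroke="#224466" stroke-width="1.5"/>',
            paste(poly, collapse = " ")),
    "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
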