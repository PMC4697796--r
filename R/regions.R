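# Planar regions representing a spread nucleus. All coordinates are in nm,
# image convention (x right, y down). A region is either a disc or a simple
# polygon; it defines the domain over which random foci are placed by the
# complete-spatial-randomness (CSR) null.

#' Disc-shaped nuclear region
#'
#' @param center_x_nm,center_y_nm disc centre, nm.
#' @param radius_nm disc radius, nm (> 0).
#' @return an object of class `region`.
#' @export
region_disc <- function(center_x_nm, center_y_nm, radius_nm) {
  if (!is.finite(radius_nm) || radius_nm <= 0) {
    stop_format("radius_nm must be a positive finite number, got %s", radius_nm)
  }
  structure(
    list(
      type = "disc",
      center_x_nm = center_x_nm, center_y_nm = center_y_nm,
      radius_nm = radius_nm
    ),
    class = "region"
  )
}

#' Polygonal nuclear region
#'
#' The polygon must be simple (non self-intersecting) and non-degenerate.
#' Vertices are given in order; the polygon is closed implicitly.
#'
#' @param x_nm,y_nm numeric vertex coordinates, nm, length >= 3.
#' @return an object of class `region`.
#' @export
region_polygon <- function(x_nm, y_nm) {
  if (length(x_nm) != length(y_nm) || length(x_nm) < 3) {
    stop_format("polygon needs >= 3 (x, y) vertex pairs")
  }
  if (!all(is.finite(x_nm)) || !all(is.finite(y_nm))) {
    stop_format("polygon vertices must be finite")
  }
  reg <- structure(
    list(type = "polygon", x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm)),
    class = "region"
  )
  if (region_area_nm2(reg) <= 0) {
    stop_format("polygon is degenerate (zero area)")
  }
  reg
}

#' Region area in nm^2
#' @param region a `region`.
#' @return area, nm^2.
#' @export
region_area_nm2 <- function(region) {
  switch(region$type,
    disc = pi * region$radius_nm^2,
    polygon = {
      x <- region$x_nm
      y <- region$y_nm
      n <- length(x)
      j <- c(n, seq_len(n - 1L))
      abs(sum(x[j] * y - x * y[j])) / 2
    },
    stop_format("unknown region type '%s'", region$type)
  )
}

#' Region area in um^2
#' @inheritParams region_area_nm2
#' @export
region_area_um2 <- function(region) region_area_nm2(region) / 1e6

#' Axis-aligned bounding box of a region
#' @inheritParams region_area_nm2
#' @return named numeric `c(xmin, xmax, ymin, ymax)`, nm.
#' @export
region_bbox <- function(region) {
  switch(region$type,
    disc = c(
      xmin = region$center_x_nm - region$radius_nm,
      xmax = region$center_x_nm + region$radius_nm,
      ymin = region$center_y_nm - region$radius_nm,
      ymax = region$center_y_nm + region$radius_nm
    ),
    polygon = c(
      xmin = min(region$x_nm), xmax = max(region$x_nm),
      ymin = min(region$y_nm), ymax = max(region$y_nm)
    )
  )
}

#' Point-in-region test
#' @inheritParams region_area_nm2
#' @param x_nm,y_nm point coordinates (vectorized), nm.
#' @return logical vector.
#' @export
region_contains <- function(region, x_nm, y_nm) {
  switch(region$type,
    disc = (x_nm - region$center_x_nm)^2 + (y_nm - region$center_y_nm)^2 <=
      region$radius_nm^2,
    polygon = point_in_polygon(x_nm, y_nm, region$x_nm, region$y_nm)
  )
}

# even-odd ray-casting rule; boundary points count as inside
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Uniform random points in a region
#'
#' Draws i.i.d. uniform points from the region (directly for a disc, by
#' bounding-box rejection for a polygon). Uses the current RNG stream.
#'
#' @inheritParams region_area_nm2
#' @param n number of points.
#' @return an `n` x 2 matrix with columns `x_nm`, `y_nm`.
#' @export
region_sample <- function(region, n) {
  n <- as.integer(n)
  if (n <= 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x_nm", "y_nm"))))
  }
  if (region$type == "disc") {
    r <- region$radius_nm * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    out <- cbind(
      x_nm = region$center_x_nm + r * cos(th),
      y_nm = region$center_y_nm + r * sin(th)
    )
    return(out)
  }
  bb <- region_bbox(region)
  xs <- numeric(0)
  ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 16L)
    cx <- stats::runif(m, bb["xmin"], bb["xmax"])
    cy <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- region_contains(region, cx, cy)
    xs <- c(xs, cx[keep])
    ys <- c(ys, cy[keep])
  }
  cbind(x_nm = xs[seq_len(n)], y_nm = ys[seq_len(n)])
}

#' @export
print.region <- function(x, ...) {
  if (x$type == "disc") {
    cat(sprintf(
      "<region: disc r = %.0f nm, area = %.2f um^2>\n",
      x$radius_nm, region_area_um2(x)
    ))
  } else {
    cat(sprintf(
      "<region: polygon, %d vertices, area = %.2f um^2>\n",
      length(x$x_nm), region_area_um2(x)
    ))
  }
  invisible(x)
}
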