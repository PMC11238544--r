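#' Rectilinear collective-variable grid
#'
#' Defines the discretization of the 1- or 2-dimensional CV space on which
#' densities, mean forces and free-energy surfaces are evaluated. Fields are
#' node-centered. On a periodic axis the domain is half-open, `[min, max)`:
#' the node at `max` is identified with the node at `min` and the spacing is
#' `(max - min) / nbins`; on an aperiodic axis nodes span the closed interval
#' and the spacing is `(max - min) / (nbins - 1)`.
#'
#' @param bounds numeric vector `c(min, max)` for 1D, or a list of two such
#'   vectors (one per axis) for 2D.
#' @param nbins integer number of nodes per axis (scalar or per-axis), >= 8.
#' @param periodic logical per axis.
#' @return an object of class `cv_grid` with elements `ndim`, `lower`,
#'   `upper`, `nbins`, `periodic`, `spacing`, and node coordinates `axes`
#'   (list of per-axis numeric vectors).
#' @examples
#' g <- make_grid(list(c(-3, 3), c(-3, 3)), nbins = 200)
#' g1 <- make_grid(c(-pi, pi), nbins = 100, periodic = TRUE)
#' @export
make_grid <- function(bounds, nbins, periodic = FALSE) {
  if (is.numeric(bounds)) bounds <- list(bounds)
  ndim <- length(bounds)
  if (!ndim %in% 1:2) stop("only 1- and 2-dimensional CV grids are supported")
  nbins <- rep_len(as.integer(nbins), ndim)
  periodic <- rep_len(as.logical(periodic), ndim)
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(upper <= lower)) stop("bounds must satisfy max > min on every axis")
  if (any(nbins < 8L)) stop("nbins must be >= 8 on every axis")
  spacing <- ifelse(periodic, (upper - lower) / nbins,
                    (upper - lower) / (nbins - 1L))
  axes <- lapply(seq_len(ndim), function(a)
    lower[a] + (seq_len(nbins[a]) - 1L) * spacing[a])
  structure(list(ndim = ndim, lower = lower, upper = upper, nbins = nbins,
                 periodic = periodic, spacing = spacing, axes = axes),
            class = "cv_grid")
}

#' @export
print.cv_grid <- function(x, ...) {
  cat(sprintf("cv_grid: %dD, %s nodes\n", x$ndim,
              paste(x$nbins, collapse = " x ")))
  for (a in seq_len(x$ndim))
    cat(sprintf("  axis %d: [%g, %g%s spacing %g%s\n", a, x$lower[a],
                x$upper[a], if (x$periodic[a]) ")" else "]", x$spacing[a],
                if (x$periodic[a]) ", periodic" else ""))
  invisible(x)
}

n_nodes <- function(grid) prod(grid$nbins)

grid_period <- function(grid) grid$upper - grid$lower

#' Node coordinates of a grid
#'
#' @param grid a `cv_grid`.
#' @return a matrix with one row per node (column-major over axes, first axis
#'   fastest) and one column per CV.
#' @export
grid_points <- function(grid) {
  if (grid$ndim == 1L) matrix(grid$axes[[1]], ncol = 1L)
  else as.matrix(expand.grid(s1 = grid$axes[[1]], s2 = grid$axes[[2]],
                             KEEP.OUT.ATTRS = FALSE))
}

same_grid <- function(a, b, tol = 1e-12) {
  a$ndim == b$ndim && all(a$nbins == b$nbins) &&
    all(abs(a$lower - b$lower) < tol) && all(abs(a$upper - b$upper) < tol) &&
    all(a$periodic == b$periodic)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("fields are defined on different grids")
}

#' Minimum-image displacement in CV space
#'
#' Computes `a - b` per axis, wrapping periodic axes to the minimum image so
#' that the result never exceeds half a period in magnitude. Aperiodic axes
#' use plain subtraction. Required for torsional CVs.
#'
#' @param a,b numeric vectors (or matrices with one row per point).
#' @param grid a `cv_grid` supplying periodicity and periods.
#' @return displacement(s) with the same shape as `a`.
#' @export
wrap_displacement <- function(a, b, grid) {
  d <- a - b
  per <- grid_period(grid)
  if (is.matrix(d)) {
    for (ax in which(grid$periodic))
      d[, ax] <- d[, ax] - per[ax] * round(d[, ax] / per[ax])
  } else {
    w <- grid$periodic
    d[w] <- d[w] - per[w] * round(d[w] / per[w])
  }
  d
}

# internal: shape a flat node vector as the canonical array (axis 1 = s1)
field_shape <- function(grid, values) {
  if (length(values) != n_nodes(grid))
    stop("value array shape does not match the grid node count")
  if (grid$ndim == 2L) matrix(values, grid$nbins[1], grid$nbins[2])
  else as.numeric(values)
}

#' Scalar field on a CV grid
#'
#' @param grid a `cv_grid`.
#' @param values numeric, one value per node; for 2D either a flat vector in
#'   column-major order (first CV fastest) or an `nbins[1] x nbins[2]` matrix.
#' @return a `scalar_field` with elements `grid` and `values`.
#' @export
scalar_field <- function(grid, values) {
  structure(list(grid = grid, values = field_shape(grid, values)),
            class = "scalar_field")
}

#' Vector field on a CV grid
#'
#' @param grid a `cv_grid`.
#' @param components list of per-axis value arrays (one per CV dimension).
#' @return a `vector_field` with elements `grid` and `components`.
#' @export
vector_field <- function(grid, components) {
  if (length(components) != grid$ndim)
    stop("need one component array per CV dimension")
  structure(list(grid = grid, components = lapply(components, field_shape,
                                                  grid = grid)),
            class = "vector_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("scalar_field on %dD grid (%s): range [%g, %g]\n", x$grid$ndim,
              paste(x$grid$nbins, collapse = " x "),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("vector_field on %dD grid (%s), %d components\n", x$grid$ndim,
              paste(x$grid$nbins, collapse = " x "), length(x$components)))
  invisible(x)
}

#' Time-ordered CV trajectory
#'
#' @param times strictly increasing numeric vector of sample times.
#' @param samples numeric matrix (one row per time, one column per CV) or a
#'   vector for a single CV.
#' @param stride time between stored samples (defaults to the median spacing
#'   of `times`).
#' @return a `cv_trajectory`.
#' @export
cv_trajectory <- function(times, samples, stride = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  if (length(times) != nrow(samples))
    stop("times and samples disagree in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (is.null(stride))
    stride <- if (length(times) > 1L) stats::median(diff(times)) else 0
  structure(list(times = as.numeric(times), samples = samples,
                 stride = stride), class = "cv_trajectory")
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat(sprintf("cv_trajectory: %d samples, %d CV(s), t in [%g, %g]\n",
              nrow(x$samples), ncol(x$samples), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Write a field to a plain-text grid file
#'
#' Header lines (prefixed `#!`) give the per-axis bounds, node counts and
#' periodicity; the body has one row per node: node coordinates followed by
#' the value(s). Numbers are written at full double precision, so
#' write/read round-trips are bit-exact.
#'
#' @param field a `scalar_field` or `vector_field`.
#' @param path output file.
#' @export
write_field <- function(field, path) {
  g <- field$grid
  hdr <- c(sprintf("#! GRID ndim %d", g$ndim),
           vapply(seq_len(g$ndim), function(a)
             sprintf("#! AXIS %d min %.17g max %.17g nbins %d periodic %d",
                     a, g$lower[a], g$upper[a], g$nbins[a],
                     as.integer(g$periodic[a])), character(1)))
  vals <- if (inherits(field, "scalar_field")) list(field$values)
          else field$components
  hdr <- c(hdr, sprintf("#! KIND %s NVALUES %d",
                        if (inherits(field, "scalar_field")) "scalar"
                        else "vector", length(vals)))
  pts <- grid_points(g)
  body <- cbind(pts, do.call(cbind, lapply(vals, as.vector)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(body, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a field written by [write_field()]
#'
#' @param path grid text file.
#' @return a `scalar_field` or `vector_field`, as written.
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#!")]
  ndim <- as.integer(sub(".*ndim ", "", hdr[grepl("GRID", hdr)]))
  ax <- hdr[grepl("AXIS", hdr)]
  get <- function(l, key) sub(paste0(".*", key, " ([^ ]+).*"), "\\1", l)
  bounds <- lapply(ax, function(l)
    c(as.numeric(get(l, "min")), as.numeric(get(l, "max"))))
  nbins <- vapply(ax, function(l) as.integer(get(l, "nbins")), integer(1))
  periodic <- vapply(ax, function(l) get(l, "periodic") == "1", logical(1))
  kindline <- hdr[grepl("KIND", hdr)]
  kind <- get(kindline, "KIND")
  nval <- as.integer(get(kindline, "NVALUES"))
  g <- make_grid(bounds, nbins, periodic)
  body <- utils::read.table(text = lines[!startsWith(lines, "#!")])
  if (nrow(body) != n_nodes(g)) stop("grid file body does not match header")
  vals <- lapply(seq_len(nval), function(k) body[[ndim + k]])
  if (kind == "scalar") scalar_field(g, vals[[1]])
  else vector_field(g, vals)
}
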