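#' Numerical integration of the mean force
#'
#' Turns the averaged mean force `<dF/ds>` into the free-energy surface
#' `F(s)` by cumulative trapezoid integration (1D), a Fourier least-squares
#' solve (2D, [integrate_2d_fft()]) or a sparse finite-difference
#' least-squares solve (2D, [integrate_2d_fd()]). Integration errors are
#' much smaller than the sampling errors of the force itself; the two 2D
#' methods agree closely on smooth fully explored fields.
#'
#' @name fes_integration
NULL

new_fes_result <- function(grid, fes, mask, method, residual,
                           segments = 1L) {
  fes[!mask] <- NA_real_
  if (any(mask)) fes <- fes - min(fes[mask])
  structure(list(fes = scalar_field(grid, fes), explored_mask = mask,
                 method = method, residual = residual, segments = segments),
            class = "fes_result")
}

#' @export
print.fes_result <- function(x, ...) {
  cat(sprintf(
    "fes_result (%s): %.1f%% explored, %d segment(s), residual %.3g\n",
    x$method, 100 * mean(x$explored_mask), x$segments, x$residual))
  invisible(x)
}

#' Integrate a 1D mean force
#'
#' Cumulative trapezoid of `<dF/ds>` along the grid, per contiguous explored
#' segment; each segment is independently gauged and the minimum over all
#' explored nodes is shifted to zero.
#'
#' @param force a `vector_field` on a 1D grid (`NA` = unexplored).
#' @param mask optional logical explored mask (default: finite force).
#' @return an `fes_result`.
#' @export
integrate_1d <- function(force, mask = NULL) {
  g <- force$grid
  stopifnot(g$ndim == 1L)
  f <- force$components[[1]]
  if (is.null(mask)) mask <- is.finite(f)
  n <- g$nbins[1]
  fes <- rep(NA_real_, n)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nseg <- 0L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    nseg <- nseg + 1L
    i <- starts[k]:ends[k]
    fi <- f[i]
    fes[i] <- c(0, cumsum((fi[-1] + fi[-length(fi)]) / 2 * g$spacing[1]))
    fes[i] <- fes[i] - min(fes[i])
  }
  grad <- rep(NA_real_, n)
  ok <- which(mask)
  if (length(ok) > 1L) grad[ok] <- fd_grad_1d(ifelse(mask, fes, NA),
                                              g$spacing[1])[ok]
  resid <- sqrt(mean((grad[mask] - f[mask])^2, na.rm = TRUE))
  new_fes_result(g, fes, mask, "fd", resid, segments = nseg)
}

# finite-difference stencils as (offset, coefficient/dx) pairs, tried in
# order: 4th-order central, 4th-order one-sided (boundaries), 2nd-order
# central, first-order one-sided (last resort on ragged masks)
fd_stencils <- list(
  central4 = list(off = c(-2L, -1L, 1L, 2L),
                  coef = c(1 / 12, -8 / 12, 8 / 12, -1 / 12)),
  central2 = list(off = c(-1L, 1L), coef = c(-1 / 2, 1 / 2)),
  onesided4f = list(off = 0:4,
                    coef = c(-25, 48, -36, 16, -3) / 12),
  onesided4b = list(off = -(0:4),
                    coef = -c(-25, 48, -36, 16, -3) / 12),
  fwd = list(off = c(0L, 1L), coef = c(-1, 1)),
  bwd = list(off = c(-1L, 0L), coef = c(-1, 1)))

# derivative along one axis of a 1D slice layout: v indexed 1..n
fd_deriv_line <- function(v, dx, periodic) {
  n <- length(v)
  idx <- function(i) if (periodic) ((i - 1L) %% n) + 1L else pmin(pmax(i, 1L), n)
  out <- rep(NA_real_, n)
  i <- seq_len(n)
  usable <- function(off) {
    j <- outer(i, off, `+`)
    if (periodic) matrix(TRUE, n, length(off))
    else j >= 1L & j <= n
  }
  done <- rep(FALSE, n)
  for (st in fd_stencils) {
    ok <- rowSums(!usable(st$off)) == 0L & !done
    if (!any(ok)) next
    acc <- rep(0, n)
    for (k in seq_along(st$off))
      acc <- acc + st$coef[k] * v[idx(i + st$off[k])]
    out[ok] <- acc[ok] / dx
    done <- done | ok
  }
  out
}

fd_grad_1d <- function(v, dx, periodic = FALSE) fd_deriv_line(v, dx, periodic)

#' Finite-difference gradient of a scalar field
#'
#' The discrete operator whose least-squares inverse [integrate_2d_fd()]
#' computes: 4th-order central differences where the stencil fits, 2nd-order
#' central one node from an aperiodic boundary, one-sided at the boundary
#' itself; periodic axes wrap. Useful for round-trip checks and residuals.
#'
#' @param field a `scalar_field`.
#' @return a `vector_field`.
#' @export
fd_gradient <- function(field) {
  g <- field$grid
  if (g$ndim == 1L)
    return(vector_field(g, list(fd_grad_1d(field$values, g$spacing[1],
                                           g$periodic[1]))))
  v <- field$values
  gx <- apply(v, 2L, fd_deriv_line, dx = g$spacing[1],
              periodic = g$periodic[1])
  gy <- t(apply(v, 1L, fd_deriv_line, dx = g$spacing[2],
                periodic = g$periodic[2]))
  vector_field(g, list(gx, gy))
}

# curl-consistent polynomial trend of a 2D force field: fits F as a dense
# polynomial of the given total degree to (gx, gy) over the mask and
# returns the trend surface and its analytic gradient on the grid
poly_trend_2d <- function(grid, gx, gy, mask, degree) {
  x <- grid$axes[[1]]; y <- grid$axes[[2]]
  # scale coordinates to [-1, 1] for conditioning
  sx <- 2 / (max(x) - min(x)); sy <- 2 / (max(y) - min(y))
  cx <- (max(x) + min(x)) / 2; cy <- (max(y) + min(y)) / 2
  X <- matrix((x - cx) * sx, length(x), length(y))
  Y <- matrix((y - cy) * sy, length(x), length(y), byrow = TRUE)
  pows <- subset(expand.grid(i = 0:degree, j = 0:degree),
                 i + j >= 1 & i + j <= degree)
  xs <- X[mask]; ys <- Y[mask]
  bx <- vapply(seq_len(nrow(pows)), function(k) {
    i <- pows$i[k]; j <- pows$j[k]
    if (i == 0) rep(0, length(xs)) else i * xs^(i - 1) * ys^j * sx
  }, numeric(length(xs)))
  by <- vapply(seq_len(nrow(pows)), function(k) {
    i <- pows$i[k]; j <- pows$j[k]
    if (j == 0) rep(0, length(xs)) else j * xs^i * ys^(j - 1) * sy
  }, numeric(length(xs)))
  coef <- qr.coef(qr(rbind(bx, by)), c(gx[mask], gy[mask]))
  coef[is.na(coef)] <- 0
  Fp <- 0; Gpx <- 0; Gpy <- 0
  for (k in seq_len(nrow(pows))) {
    i <- pows$i[k]; j <- pows$j[k]
    Fp <- Fp + coef[k] * X^i * Y^j
    Gpx <- Gpx + coef[k] * (if (i == 0) 0 else i * X^(i - 1) * Y^j * sx)
    Gpy <- Gpy + coef[k] * (if (j == 0) 0 else j * X^i * Y^(j - 1) * sy)
  }
  list(F = Fp, gx = Gpx, gy = Gpy)
}

# even (mirror) extension of a scalar component along one axis; sign = -1
# gives the odd extension used for the gradient component along that axis
mirror_extend <- function(m, axis, sign) {
  if (axis == 1L) rbind(m, sign * m[nrow(m):1, , drop = FALSE])
  else cbind(m, sign * m[, ncol(m):1, drop = FALSE])
}

fft_freq <- function(n, d) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n]
  2 * pi * k / (n * d)
}

#' Integrate a 2D mean force by Fourier transform
#'
#' Least-squares solution of `grad F = g` in Fourier space
#' (`F_hat = -i (kx gx_hat + ky gy_hat) / (kx^2 + ky^2)`). Aperiodic axes
#' are mirror-padded (even extension of F, odd/even extension of the
#' gradient components) to suppress wrap-around artifacts; periodic axes are
#' transformed directly. Unexplored nodes are filled with zero force for the
#' solve but masked in the output.
#'
#' @param force a `vector_field` on a 2D grid.
#' @param mask optional logical explored mask (default: finite force).
#' @param fill_iterations for partially explored inputs, number of
#'   inpainting sweeps: each sweep re-solves with the unexplored gradient
#'   replaced by the gradient of the current solution, so the unexplored
#'   region stops biasing the least-squares fit inside the mask.
#' @param detrend_degree on grids with an aperiodic axis, total degree of
#'   the polynomial trend removed before the transform (its analytic
#'   integral is added back). Detrending suppresses the ringing the mirror
#'   extension produces when the force is large at the boundary; 0 disables.
#' @return an `fes_result` with the spectral residual over the mask.
#' @export
integrate_2d_fft <- function(force, mask = NULL, fill_iterations = 30L,
                             detrend_degree = 4L) {
  g <- force$grid
  stopifnot(g$ndim == 2L)
  gx0 <- force$components[[1]]; gy0 <- force$components[[2]]
  if (is.null(mask)) mask <- is.finite(gx0) & is.finite(gy0)
  nx0 <- g$nbins[1]; ny0 <- g$nbins[2]
  trend <- NULL
  if (any(!g$periodic) && detrend_degree > 0L && sum(mask) > 30L) {
    trend <- poly_trend_2d(g, gx0, gy0, mask, detrend_degree)
    gx0 <- gx0 - trend$gx; gy0 <- gy0 - trend$gy
  }
  ext <- !g$periodic # mirror-extend aperiodic axes
  kx <- fft_freq(if (ext[1]) 2 * nx0 else nx0, g$spacing[1])
  ky <- fft_freq(if (ext[2]) 2 * ny0 else ny0, g$spacing[2])
  nx <- length(kx); ny <- length(ky)
  KX <- matrix(kx, nx, ny); KY <- matrix(ky, nx, ny, byrow = TRUE)
  k2 <- KX^2 + KY^2
  solve_once <- function(gx, gy) {
    if (ext[1]) { gx <- mirror_extend(gx, 1L, -1); gy <- mirror_extend(gy, 1L, 1) }
    if (ext[2]) { gx <- mirror_extend(gx, 2L, 1); gy <- mirror_extend(gy, 2L, -1) }
    Fh <- -1i * (KX * stats::fft(gx) + KY * stats::fft(gy)) /
      ifelse(k2 == 0, 1, k2)
    Fh[k2 == 0] <- 0
    list(F = Re(stats::fft(Fh, inverse = TRUE))[seq_len(nx0),
                                                seq_len(ny0)] / (nx * ny),
         gx = Re(stats::fft(1i * KX * Fh, inverse = TRUE))[seq_len(nx0),
                                                seq_len(ny0)] / (nx * ny),
         gy = Re(stats::fft(1i * KY * Fh, inverse = TRUE))[seq_len(nx0),
                                                seq_len(ny0)] / (nx * ny))
  }
  gx <- gx0; gy <- gy0
  gx[!mask] <- 0; gy[!mask] <- 0
  sol <- solve_once(gx, gy)
  if (any(!mask) && any(mask)) {
    for (it in seq_len(fill_iterations)) {
      gx[!mask] <- sol$gx[!mask]
      gy[!mask] <- sol$gy[!mask]
      sol <- solve_once(gx, gy)
    }
  }
  resid <- if (any(mask))
    sqrt(mean((sol$gx[mask] - gx0[mask])^2 +
              (sol$gy[mask] - gy0[mask])^2)) else 0
  Fv <- sol$F
  if (!is.null(trend)) Fv <- Fv + trend$F
  new_fes_result(g, Fv, mask, "fft", resid)
}

#' Integrate a 2D mean force by finite differences
#'
#' Sparse least-squares solve of the discrete central-difference gradient
#' system restricted to explored nodes. Disconnected explored components are
#' gauged independently and their count reported; a node with no usable
#' stencil gets FES 0.
#'
#' @inheritParams integrate_2d_fft
#' @return an `fes_result`.
#' @export
integrate_2d_fd <- function(force, mask = NULL) {
  g <- force$grid
  stopifnot(g$ndim == 2L)
  gx <- force$components[[1]]; gy <- force$components[[2]]
  if (is.null(mask)) mask <- is.finite(gx) & is.finite(gy)
  nx <- g$nbins[1]; ny <- g$nbins[2]
  node <- matrix(seq_len(nx * ny), nx, ny)
  dx <- g$spacing[1]; dy <- g$spacing[2]

  if (all(g$periodic) && all(mask)) {
    # fully periodic, fully explored: the least-squares problem for the
    # central-difference operator diagonalizes in Fourier space; solve it
    # there exactly (minimum-norm over the operator's parity null modes)
    Dsym <- function(n, d) { # symbol of the 4th-order central difference
      th <- 2 * pi * (seq_len(n) - 1) / n
      1i * (8 * sin(th) - sin(2 * th)) / (6 * d)
    }
    DX <- matrix(Dsym(nx, dx), nx, ny)
    DY <- matrix(Dsym(ny, dy), nx, ny, byrow = TRUE)
    den <- Mod(DX)^2 + Mod(DY)^2
    Fh <- (Conj(DX) * stats::fft(gx) + Conj(DY) * stats::fft(gy)) /
      ifelse(den == 0, 1, den)
    Fh[den == 0] <- 0
    fes <- Re(stats::fft(Fh, inverse = TRUE)) / (nx * ny)
    fes <- fes - min(fes)
    gr2 <- fd_gradient(scalar_field(g, fes))
    resid <- sqrt(mean((gr2$components[[1]] - gx)^2 +
                       (gr2$components[[2]] - gy)^2))
    return(new_fes_result(g, fes, mask, "fd", resid))
  }

  # node ids shifted along an axis (NA outside aperiodic bounds)
  shift_nodes <- function(axis, by) {
    n <- g$nbins[axis]
    idx <- seq_len(n) + by
    if (g$periodic[axis]) idx <- ((idx - 1L) %% n) + 1L
    else idx[idx < 1L | idx > n] <- NA_integer_
    if (axis == 1L) {
      out <- node[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
      out[is.na(idx), ] <- NA_integer_
    } else {
      out <- node[, ifelse(is.na(idx), 1L, idx), drop = FALSE]
      out[, is.na(idx)] <- NA_integer_
    }
    out
  }
  tri_i <- list(); tri_j <- list(); tri_x <- list(); rhs_list <- list()
  edge_a <- list(); edge_b <- list()
  eq <- 0L
  for (axis in 1:2) {
    dd <- if (axis == 1L) dx else dy
    gcomp <- if (axis == 1L) gx else gy
    shifts <- lapply(-4:4, function(by) shift_nodes(axis, by))
    names(shifts) <- as.character(-4:4)
    ok_at <- lapply(shifts, function(s) !is.na(s) &
                      mask[ifelse(is.na(s), 1L, s)])
    assigned <- !mask # never assign equations outside the mask
    for (st in fd_stencils) {
      use <- !assigned
      for (o in st$off) use <- use & ok_at[[as.character(o)]]
      if (!any(use)) next
      n_use <- sum(use)
      ids <- eq + seq_len(n_use)
      eq <- eq + n_use
      prev <- NULL
      for (k in seq_along(st$off)) {
        nd <- shifts[[as.character(st$off[k])]][use]
        tri_i <- c(tri_i, list(ids))
        tri_j <- c(tri_j, list(nd))
        tri_x <- c(tri_x, list(rep(st$coef[k] / dd, n_use)))
        if (!is.null(prev)) {
          edge_a <- c(edge_a, list(prev)); edge_b <- c(edge_b, list(nd))
        }
        prev <- nd
      }
      rhs_list <- c(rhs_list, list(gcomp[use]))
      assigned <- assigned | use
    }
  }
  rhs <- unlist(rhs_list)

  fes <- matrix(NA_real_, nx, ny)
  nseg <- 0L
  keep <- which(mask)
  if (eq > 0L) {
    # connected components of the equation-coupling graph
    ea <- match(unlist(edge_a), keep); eb <- match(unlist(edge_b), keep)
    gr <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
    gr <- igraph::add_edges(gr, rbind(ea, eb))
    comp <- igraph::components(gr)$membership
    nseg <- max(comp)
    A <- Matrix::sparseMatrix(i = unlist(tri_i),
                              j = match(unlist(tri_j), keep),
                              x = unlist(tri_x),
                              dims = c(eq, length(keep)))
    AtA <- Matrix::crossprod(A)
    Atb <- Matrix::crossprod(A, rhs)
    # pin one node per component to fix the gauge, then solve
    pins <- vapply(seq_len(nseg), function(k) which(comp == k)[1L],
                   integer(1))
    P <- Matrix::sparseMatrix(i = pins, j = pins, x = rep(1, nseg),
                              dims = dim(AtA))
    sol <- as.numeric(Matrix::solve(AtA + P, Atb))
    fes[keep] <- sol
    for (k in seq_len(nseg)) { # gauge each component: min 0
      sel <- keep[comp == k]
      fes[sel] <- fes[sel] - min(fes[sel])
    }
  } else if (length(keep)) {
    fes[keep] <- 0
    nseg <- length(keep)
  }
  gr2 <- fd_gradient(scalar_field(g, fes))
  rx <- gr2$components[[1]]; ry <- gr2$components[[2]]
  ok <- mask & is.finite(rx) & is.finite(ry)
  resid <- if (any(ok))
    sqrt(mean((rx[ok] - force$components[[1]][ok])^2 +
              (ry[ok] - force$components[[2]][ok])^2)) else 0
  new_fes_result(g, fes, mask, "fd", resid, segments = nseg)
}

#' Average absolute deviation between surfaces
#'
#' Mean of `|F - F_ref|` over the mask after aligning both fields to the
#' same gauge (each field's mask-mean is subtracted before differencing), so
#' the result is invariant to constant offsets.
#'
#' @param fes an `fes_result` or `scalar_field`.
#' @param reference a `scalar_field` (e.g. from [reference_fes()]).
#' @param mask optional logical mask (default: the explored mask of `fes`,
#'   or finite values).
#' @return the AAD (scalar).
#' @export
aad <- function(fes, reference, mask = NULL) {
  f <- if (inherits(fes, "fes_result")) fes$fes else fes
  if (is.null(mask))
    mask <- if (inherits(fes, "fes_result")) fes$explored_mask
            else is.finite(f$values)
  stopifnot_same_grid(f$grid, reference$grid)
  if (!any(mask)) stop("empty mask in aad()")
  a <- f$values[mask]; b <- reference$values[mask]
  mean(abs((a - mean(a)) - (b - mean(b))))
}
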