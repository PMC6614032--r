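# Interpolation of model fields from their native grids onto the standard
# analysis grid. Values are point samples at cell centers; bilinear
# interpolation among the four surrounding source centers is the default,
# with longitude wraparound and a nearest-row clamp poleward of the
# outermost source-center latitude.

# Bracketing indices and weight along the latitude axis, with polar clamp.
lat_bracket <- function(src_lat, target_lat) {
  n <- length(src_lat)
  i0 <- findInterval(target_lat, src_lat)
  i0 <- pmin(pmax(i0, 1L), n - 1L)
  w <- (target_lat - src_lat[i0]) / (src_lat[i0 + 1L] - src_lat[i0])
  w <- pmin(pmax(w, 0), 1)  # clamp beyond the outermost center rows
  list(i0 = i0, i1 = i0 + 1L, w = w)
}

# Bracketing indices and weight along longitude, wrapping modulo 360.
lon_bracket <- function(src_lon, target_lon) {
  ord <- order(src_lon)
  s <- src_lon[ord]
  n <- length(s)
  j0 <- integer(length(target_lon))
  w <- numeric(length(target_lon))
  # distance east from each source center to the target
  for (k in seq_along(target_lon)) {
    d <- (target_lon[k] - s) %% 360
    a <- which.min(d)
    b <- a %% n + 1L
    gap <- (s[b] - s[a]) %% 360
    if (gap == 0) gap <- 360
    j0[k] <- a
    w[k] <- d[a] / gap
  }
  list(j0 = ord[j0], j1 = ord[j0 %% n + 1L], w = w)
}

# Sparse interpolation operator mapping flattened source cells to flattened
# target cells (cell index = lat + (lon - 1) * n_lat).
regrid_weights <- function(source, target, method) {
  slat <- grid_lat_centers(source)
  slon <- grid_lon_centers(source)
  tlat <- grid_lat_centers(target)
  tlon <- grid_lon_centers(target)
  if (source$n_lat == 1L) {
    lb <- list(i0 = rep(1L, target$n_lat), i1 = rep(1L, target$n_lat),
               w = rep(0, target$n_lat))
  } else {
    lb <- lat_bracket(slat, tlat)
  }
  jb <- lon_bracket(slon, tlon)
  if (method == "nearest") {
    lb$w <- round(lb$w)
    jb$w <- round(jb$w)
  }
  n_tgt <- target$n_lat * target$n_lon
  # expand over the target lat x lon plane (lat varies fastest)
  i0 <- rep(lb$i0, times = target$n_lon)
  i1 <- rep(lb$i1, times = target$n_lon)
  wl <- rep(lb$w, times = target$n_lon)
  j0 <- rep(jb$j0, each = target$n_lat)
  j1 <- rep(jb$j1, each = target$n_lat)
  wj <- rep(jb$w, each = target$n_lat)
  tcell <- seq_len(n_tgt)
  src <- function(i, j) cell_flat_index(source, i, j)
  Matrix::sparseMatrix(
    i = c(src(i0, j0), src(i0, j1), src(i1, j0), src(i1, j1)),
    j = rep(tcell, 4L),
    x = c((1 - wl) * (1 - wj), (1 - wl) * wj, wl * (1 - wj), wl * wj),
    dims = c(source$n_lat * source$n_lon, n_tgt)
  )
}

#' Regrid a monthly field onto a target grid
#'
#' Interpolates every month of a gap-free (no missing cells) field to the
#' cell centers of `target`. Bilinear interpolation uses the four source cell
#' centers surrounding each target center, with longitude wraparound across
#' the dateline; target centers poleward of the outermost source-center
#' latitude use the nearest source row. `"nearest"` assigns the value of the
#' closest source center and exists chiefly as an oracle for testing.
#'
#' @param field a [monthly_field()] with no missing cells.
#' @param target a [regular_grid()].
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return a [monthly_field()] on `target` with the same time axis; the
#'   interpolation method is recorded in the output's `attrs`.
#' @export
regrid <- function(field, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "monthly_field"), inherits(target, "regular_grid"))
  if (any(field$missing_mask)) {
    stop("regrid requires a source field with no missing cells", call. = FALSE)
  }
  W <- regrid_weights(field$grid, target, method)
  out <- as.matrix(field_matrix(field) %*% W)
  dim(out) <- c(field$time$n_months, target$n_lat, target$n_lon)
  monthly_field(target, field$time, out,
                attrs = c(field$attrs, list(regrid_method = method)))
}
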