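# Internal helpers shared across modules.

#' Normalize longitudes to [-180, 180)
#'
#' Inputs on [0, 360) (or any real value) are wrapped into the package's single
#' internal longitude convention.
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return numeric vector in [-180, 180).
#' @export
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# Evaluate an expression with a temporary RNG state, restoring the caller's
# .Random.seed afterwards so seeded generators do not perturb the session.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage sub-seed derived from a root seed. Keeps every seed
# in [0, 2^31): stage-level reproducibility without collisions between stages
# or between models/scenarios within a stage.
derive_seed <- function(root, stage, index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(root) * 48271 + h * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# Great-circle (haversine) distance in kilometres between a point and vectors
# of coordinates. Mean Earth radius 6371.0088 km.
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
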