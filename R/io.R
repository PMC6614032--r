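# Plain-text serialization of the pipeline's containers. Gridded fields use
# a simple self-describing header + one-line-per-month layout; tables are
# CSV; configuration and truth parameters round-trip as YAML.

#' Write / read a monthly field as plain text
#'
#' Header lines (`key: value`) carry the grid, time axis and metadata,
#' followed by one whitespace-separated line of cell values per month (cells
#' in latitude-fastest order, `NA` for missing). Intended for small fields
#' and stage hand-off; values round-trip at full double precision.
#'
#' @param field a [monthly_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  g <- field$grid
  hdr <- c(
    "urbheat_field: 1",
    sprintf("lat_edge_south: %.17g", g$lat_edge_south),
    sprintf("lon_edge_west: %.17g", g$lon_edge_west),
    sprintf("lat_step: %.17g", g$lat_step),
    sprintf("lon_step: %.17g", g$lon_step),
    sprintf("n_lat: %d", g$n_lat),
    sprintf("n_lon: %d", g$n_lon),
    sprintf("start_year: %d", field$time$start_year),
    sprintf("start_month: %d", field$time$start_month),
    sprintf("n_months: %d", field$time$n_months),
    sprintf("units: degC")
  )
  for (k in names(field$attrs)) {
    v <- field$attrs[[k]]
    if (is.character(v) || is.numeric(v) || is.logical(v)) {
      hdr <- c(hdr, sprintf("attr_%s: %s", k, paste(v, collapse = ",")))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("data:", con)
  m <- field_matrix(field)
  for (t in seq_len(nrow(m))) {
    writeLines(paste(format(m[t, ], digits = 17, trim = TRUE, scientific = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  split_at <- which(lines == "data:")
  if (length(split_at) != 1) stop("not an urbheat field file", call. = FALSE)
  hdr <- lines[seq_len(split_at - 1)]
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  names(vals) <- keys
  g <- regular_grid(
    as.numeric(vals["lat_edge_south"]), as.numeric(vals["lon_edge_west"]),
    as.numeric(vals["lat_step"]), as.numeric(vals["lon_step"]),
    as.integer(vals["n_lat"]), as.integer(vals["n_lon"])
  )
  tm <- month_time(as.integer(vals["start_year"]),
                   as.integer(vals["start_month"]),
                   as.integer(vals["n_months"]))
  body <- lines[(split_at + 1):length(lines)]
  stopifnot(length(body) == tm$n_months)
  m <- t(vapply(strsplit(body, " ", fixed = TRUE), function(x) {
    x[x == "NA"] <- NA_character_
    as.numeric(x)
  }, numeric(g$n_lat * g$n_lon)))
  missing_mask <- matrix(is.na(m[1, ]), g$n_lat, g$n_lon)
  dim(m) <- c(tm$n_months, g$n_lat, g$n_lon)
  attrs <- as.list(vals[startsWith(keys, "attr_")])
  names(attrs) <- sub("^attr_", "", names(attrs))
  monthly_field(g, tm, m, missing_mask = missing_mask, attrs = attrs)
}

#' Write / read a land mask as plain text
#' @param mask a [land_mask()].
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  f <- monthly_field(mask$grid, month_time(2000L, 1L, 1L),
                     array(as.numeric(mask$is_land),
                           c(1L, mask$grid$n_lat, mask$grid$n_lon)),
                     attrs = list(kind = "land_mask"))
  write_field(f, path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  f <- read_field(path)
  land_mask(f$grid, f$values[1, , ] > 0.5)
}

#' Write / read a city table as CSV
#' @param cities a city table.
#' @param path file path.
#' @export
write_city_table <- function(cities, path) {
  utils::write.csv(cities, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_city_table
#' @export
read_city_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("city_id", "lat", "lon")
  if (!all(need %in% names(out))) {
    stop("city table needs at least city_id, lat, lon columns", call. = FALSE)
  }
  out$lon <- normalize_lon(out$lon)
  class(out) <- c("city_table", "data.frame")
  out
}

#' Round-trip synthetic truth parameters as YAML
#' @param truth a [synthetic_truth()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$model_biases <- as.list(x$model_biases)  # keep names in YAML mapping
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  x$model_biases <- unlist(x$model_biases)
  do.call(synthetic_truth, x)
}
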