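#' Read and write population maps
#'
#' A population map is a 3-column tab-separated file without header:
#' individual, population label, role (`ancestral`, `derived`,
#' `proxy_polyploid`).
#'
#' @param path file path.
#' @return [read_popmap()]: a [pop_map()].
#' @export
read_popmap <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE, fill = TRUE)
  if (ncol(dt) < 3L) stop("popmap needs 3 tab-separated columns")
  pop_map(dt[[1]], dt[[2]], dt[[3]])
}

#' @rdname read_popmap
#' @param pops a [pop_map()].
#' @export
write_popmap <- function(pops, path) {
  fwrite(as.data.table(pops)[, c("individual", "population", "role")],
         path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write individual coordinates
#'
#' CSV with header `individual,lat,lon`, decimal degrees WGS84. The
#' writer keeps 6 decimal places (about 0.1 m), enough for any
#' population-scale distance work.
#'
#' @param path file path.
#' @return a data.table `individual`, `lat`, `lon`.
#' @export
read_coords <- function(path) {
  dt <- fread(path, header = TRUE)
  need <- c("individual", "lat", "lon")
  if (!all(need %in% names(dt)))
    stop("coordinates file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dt$individual)) stop("duplicate individual in coordinates")
  check_latlon(dt$lat, dt$lon)
  dt[, c("individual", "lat", "lon")]
}

#' @rdname read_coords
#' @param coords data.frame `individual`, `lat`, `lon`.
#' @export
write_coords <- function(coords, path) {
  out <- data.table(
    individual = as.character(coords$individual),
    lat = formatC(coords$lat, format = "f", digits = 6),
    lon = formatC(coords$lon, format = "f", digits = 6)
  )
  fwrite(out, path, quote = FALSE)
  invisible(path)
}

check_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(abs(lat) > 90))
    stop("latitude outside [-90, 90]")
  if (any(!is.finite(lon)) || any(abs(lon) > 360))
    stop("longitude out of range")
  invisible(TRUE)
}

#' Read a contact borderline
#'
#' The sexual/apomict contact line as an ordered point list, either a
#' CSV with header `lat,lon` or a GeoJSON file containing a LineString
#' (possibly wrapped in a Feature / FeatureCollection). GeoJSON
#' coordinates are `[lon, lat]` and are swapped on read.
#'
#' @param path file path (`.geojson`/`.json` triggers GeoJSON parsing).
#' @return a data.table `lat`, `lon`, in file order.
#' @export
read_borderline <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    coords <- find_linestring(gj)
    if (is.null(coords)) stop("no LineString found in GeoJSON")
    pts <- data.table(
      lat = vapply(coords, function(p) as.numeric(p[[2]]), numeric(1)),
      lon = vapply(coords, function(p) as.numeric(p[[1]]), numeric(1))
    )
  } else {
    dt <- fread(path, header = TRUE)
    if (!all(c("lat", "lon") %in% names(dt)))
      stop("borderline CSV needs columns lat,lon")
    pts <- dt[, c("lat", "lon")]
  }
  if (nrow(pts) < 1L) stop("borderline needs >=1 point")
  check_latlon(pts$lat, pts$lon)
  pts
}

find_linestring <- function(x) {
  if (!is.list(x)) return(NULL)
  if (identical(x$type, "LineString")) return(x$coordinates)
  if (identical(x$type, "Feature")) return(find_linestring(x$geometry))
  if (identical(x$type, "FeatureCollection")) {
    for (f in x$features) {
      r <- find_linestring(f)
      if (!is.null(r)) return(r)
    }
  }
  NULL
}

#' @rdname read_borderline
#' @param border data.frame `lat`, `lon`.
#' @export
write_borderline <- function(border, path) {
  out <- data.table(
    lat = formatC(border$lat, format = "f", digits = 6),
    lon = formatC(border$lon, format = "f", digits = 6)
  )
  fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read and write trace matrices and diversity tables
#'
#' Plain TSV serializations of the tracing and diversity results, with a
#' header and one row per entity; round-trippable.
#'
#' @param x the object ([trace_private_alleles()] result or
#'   [population_diversity()] result).
#' @param path file path.
#' @name io_results
NULL

#' @rdname io_results
#' @export
write_trace_matrix <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname io_results
#' @export
read_trace_matrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  need <- c("individual", "ancestor", "raw_count", "n_variant_sites", "proportion")
  if (!all(need %in% names(dt)))
    stop("trace matrix file needs columns: ", paste(need, collapse = ", "))
  structure(dt, class = c("trace_matrix", class(dt)))
}

#' @rdname io_results
#' @export
write_diversity_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname io_results
#' @export
read_diversity_table <- function(path) {
  fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}
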