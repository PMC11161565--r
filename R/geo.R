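#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectors recycle).
#' @param radius_km Earth radius, default 6371 km.
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Distance from individuals to a contact borderline
#'
#' Distance of each individual to the sexual/apomict contact line,
#' by default as the minimum great-circle distance to the *vertices* of
#' the ordered point list (nearest-hub semantics, matching the
#' distance-to-nearest-hub GIS operation); `method = "segment"` instead
#' projects onto the line segments under a local equirectangular
#' approximation and is never larger than the hub distance.
#'
#' @param coords data.frame `individual`, `lat`, `lon` (decimal
#'   degrees).
#' @param border data.frame `lat`, `lon`, ordered points.
#' @param method `"hub"` (default) or `"segment"`.
#' @return a data.table `individual`, `distance_km`.
#' @export
distance_to_borderline <- function(coords, border, method = c("hub", "segment")) {
  method <- match.arg(method)
  if (nrow(border) < 1L) stop("borderline needs >=1 point")
  check_latlon(coords$lat, coords$lon)
  check_latlon(border$lat, border$lon)
  n <- nrow(coords)
  d <- numeric(n)
  for (i in seq_len(n)) {
    dv <- haversine_km(coords$lat[i], coords$lon[i], border$lat, border$lon)
    d[i] <- min(dv)
    if (method == "segment" && nrow(border) > 1L) {
      for (j in seq_len(nrow(border) - 1L)) {
        d[i] <- min(d[i], point_segment_km(
          coords$lat[i], coords$lon[i],
          border$lat[j], border$lon[j], border$lat[j + 1], border$lon[j + 1]))
      }
    }
  }
  data.table(individual = as.character(coords$individual), distance_km = d)
}

# local equirectangular projection around the segment, then planar
# point-to-segment distance
point_segment_km <- function(plat, plon, alat, alon, blat, blon) {
  lat0 <- (alat + blat) / 2 * pi / 180
  km_deg <- pi * 6371 / 180
  px <- (plon) * km_deg * cos(lat0); py <- plat * km_deg
  ax <- (alon) * km_deg * cos(lat0); ay <- alat * km_deg
  bx <- (blon) * km_deg * cos(lat0); by <- blat * km_deg
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Regression of individual heterozygosity on distance to the contact
#' line
#'
#' The contact-zone test of geographical parthenogenesis: does
#' individual expected heterozygosity of sexuals decline with distance
#' from the sexual/apomict borderline? Two estimators:
#' \itemize{
#' \item `naive`: ordinary least squares of `Hexp_ind` on distance.
#' \item `residual`: `Hexp_ind` is first regressed on the individual's
#'   recovered variant sites (a coverage proxy); the residuals are then
#'   regressed on distance. This removes the coverage-heterozygosity
#'   confound (low-coverage individuals lose heterozygous calls).
#' }
#' Individuals below `min_sites` recovered variant sites, or belonging
#' to excluded populations, are dropped before fitting.
#'
#' @param div output of [individual_hexp()].
#' @param distances output of [distance_to_borderline()].
#' @param mode `"naive"` or `"residual"`.
#' @param min_sites minimum recovered variant sites (default 6000).
#' @param exclude population labels to drop (requires `pops`).
#' @param pops optional [pop_map()] (needed when `exclude` is used).
#' @return an `hexp_regression` list: `slope` (per km), `intercept`,
#'   `r`, `p`, `n`, `mode`.
#' @export
hexp_distance_regression <- function(div, distances,
                                     mode = c("naive", "residual"),
                                     min_sites = 6000L,
                                     exclude = character(0),
                                     pops = NULL) {
  mode <- match.arg(mode)
  m <- merge(as.data.table(div), as.data.table(distances), by = "individual")
  n0 <- nrow(m)
  if (length(exclude)) {
    if (is.null(pops)) stop("excluding populations requires a popmap")
    keep_ind <- pops$individual[!pops$population %in% exclude]
    m <- m[m$individual %in% keep_ind]
  }
  n1 <- nrow(m)
  m <- m[!is.na(m$Hexp_ind) & m$n_variant_sites >= min_sites]
  if (nrow(m) < 3L)
    stop(sprintf(
      "need >= 3 individuals after filtering (matched %d, after exclusions %d, after min_sites %d)",
      n0, n1, nrow(m)))
  y <- if (mode == "residual")
    stats::resid(lm(Hexp_ind ~ n_variant_sites, data = m))
  else m$Hexp_ind
  fit <- lm(y ~ m$distance_km)
  sm <- summary(fit)
  r <- if (stats::sd(y) == 0) 0 else cor(y, m$distance_km)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r = unname(r), p = unname(sm$coefficients[2, 4]),
    n = nrow(m), mode = mode
  ), class = "hexp_regression")
}

#' @export
print.hexp_regression <- function(x, ...) {
  cat(sprintf(
    "Hexp ~ distance (%s mode): slope = %.3g per km, r = %.3f, p = %.3g, n = %d\n",
    x$mode, x$slope, x$r, x$p, x$n))
  invisible(x)
}
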