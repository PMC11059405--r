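# The raster pipeline: per-pixel climate-driven reproduction numbers, risk
# classification, annual aggregation, 95% confidence-interval layers and
# point-overlay validation.

RISK_CODES <- c(low = 1, moderate = 2, high = 3)

#' Per-pixel reproduction-number map
#'
#' Apply the climate-driven reproduction number to co-registered monthly
#' temperature and rainfall rasters. A cell is nodata in the output when
#' either input is nodata or the temperature-dependent mortality is
#' undefined there.
#'
#' @param temp Temperature raster (`irmap_raster`, degC).
#' @param rain Rainfall raster (`irmap_raster`, mm/month), co-registered
#'   with `temp`.
#' @param params A [model_parameters()] object.
#' @param lh A [life_history_parameters()] object.
#' @return An `irmap_raster` of reproduction numbers.
#' @export
r0_map <- function(temp, rain, params = model_parameters(),
                   lh = life_history_parameters()) {
  stopifnot(inherits(temp, "irmap_raster"), inherits(rain, "irmap_raster"))
  raster_compatible(temp, rain, "temperature and rainfall grids")
  vals <- r0_climate(as.vector(temp$values), as.vector(rain$values),
                     params, lh)
  out <- temp
  out$values <- matrix(vals, nrow = nrow(temp$values))
  out
}

#' Risk-class map
#'
#' Per-pixel [classify_risk()], coded 1 = low, 2 = moderate, 3 = high,
#' nodata where the reproduction number is nodata.
#'
#' @param r0map An `irmap_raster` of reproduction numbers.
#' @param thresholds Class boundaries, see [classify_risk()].
#' @return An `irmap_raster` of class codes.
#' @export
classify_map <- function(r0map, thresholds = c(1, 1.1)) {
  stopifnot(inherits(r0map, "irmap_raster"))
  cls <- classify_risk(as.vector(r0map$values), thresholds)
  out <- r0map
  out$values <- matrix(as.numeric(RISK_CODES[as.character(cls)]),
                       nrow = nrow(r0map$values))
  out
}

check_monthly <- function(monthly) {
  if (!is.list(monthly) || length(monthly) != 12 ||
      !all(vapply(monthly, inherits, logical(1), "irmap_raster"))) {
    abort("monthly must be a list of exactly 12 irmap_raster grids")
  }
  for (i in 2:12) raster_compatible(monthly[[1]], monthly[[i]],
                                    "monthly grids")
  invisible(TRUE)
}

monthly_array <- function(monthly) {
  nr <- nrow(monthly[[1]]$values); nc <- ncol(monthly[[1]]$values)
  array(unlist(lapply(monthly, function(g) g$values)), dim = c(nr, nc, 12))
}

#' Annual aggregate of monthly maps
#'
#' Pixel-wise mean (default) or median over the valid months of 12
#' co-registered monthly rasters; a pixel is nodata only when all 12
#' months are nodata there.
#'
#' @param monthly List of 12 co-registered `irmap_raster` grids.
#' @param method `"mean"` (default) or `"median"`.
#' @return An `irmap_raster` with the aggregation method recorded in the
#'   `"aggregation"` attribute.
#' @export
annual_aggregate <- function(monthly, method = c("mean", "median")) {
  method <- match.arg(method)
  check_monthly(monthly)
  arr <- monthly_array(monthly)
  f <- if (method == "mean") {
    function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  } else {
    function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  }
  out <- monthly[[1]]
  out$values <- apply(arr, c(1, 2), f)
  attr(out, "aggregation") <- method
  out
}

#' 95% confidence-interval layers across monthly maps
#'
#' Per-pixel mean and sample standard deviation (divisor n - 1) across the
#' 12 monthly rasters, and the normal-approximation bounds
#' `mean +/- 1.96 * sd`. Pixels with fewer than 2 valid months get nodata
#' standard deviation and bounds.
#'
#' @param monthly List of 12 co-registered `irmap_raster` grids.
#' @return An object of class `irmap_ci`: a list of `irmap_raster` layers
#'   `mean`, `sd`, `lower`, `upper`.
#' @export
ci_rasters <- function(monthly) {
  check_monthly(monthly)
  arr <- monthly_array(monthly)
  mean_v <- apply(arr, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  sd_v <- apply(arr, c(1, 2), function(v) {
    if (sum(!is.na(v)) < 2) NA_real_ else sd(v, na.rm = TRUE)
  })
  template <- monthly[[1]]
  wrap <- function(m) { g <- template; g$values <- m; g }
  structure(
    list(mean = wrap(mean_v), sd = wrap(sd_v),
         lower = wrap(mean_v - 1.96 * sd_v),
         upper = wrap(mean_v + 1.96 * sd_v)),
    class = "irmap_ci")
}

#' @export
print.irmap_ci <- function(x, ...) {
  cat("<irmap_ci> 95% confidence-interval layers (mean, sd, lower, upper)\n")
  print(x$mean)
  invisible(x)
}

#' @export
glance.irmap_ci <- function(x, ...) {
  w <- x$upper$values - x$lower$values
  tibble(
    width_min = min(w, na.rm = TRUE),
    width_max = max(w, na.rm = TRUE),
    mean_min = min(x$mean$values, na.rm = TRUE),
    mean_max = max(x$mean$values, na.rm = TRUE),
    n_valid = sum(!is.na(w))
  )
}

#' Overlay resistance observation points on a risk-class map
#'
#' Score the confirmed-resistant points against a classified map: the
#' accuracy is the fraction of scored points whose containing pixel carries
#' the target class. Points with status other than `"resistant"` are not
#' scored, and points falling off-grid or on nodata pixels are dropped
#' (and counted).
#'
#' @param points Data frame with columns `lon`, `lat`, `status` (and
#'   optionally `year`); status is `"resistant"` or `"susceptible"`.
#' @param classmap An `irmap_raster` of class codes from [classify_map()].
#' @param target_class Class code to score against (default 3 = high); the
#'   names `"low"`, `"moderate"`, `"high"` are also accepted.
#' @return A one-row tibble: `accuracy`, `n_scored`, `n_target`, `n_low`,
#'   `n_moderate`, `n_high`, `n_dropped`.
#' @export
overlay_accuracy <- function(points, classmap, target_class = 3) {
  stopifnot(inherits(classmap, "irmap_raster"))
  if (!is.data.frame(points) ||
      !all(c("lon", "lat", "status") %in% names(points))) {
    abort("points must have columns lon, lat, status")
  }
  if (is.character(target_class)) {
    target_class <- RISK_CODES[[match.arg(target_class,
                                          names(RISK_CODES))]]
  }
  scored <- dplyr::filter(tibble::as_tibble(points),
                          .data$status == "resistant")
  if (nrow(scored) == 0) abort("no resistant points to score")
  hit <- cell_lookup(classmap, scored$lon, scored$lat)
  dropped <- is.na(hit$value)
  cls <- hit$value[!dropped]
  if (length(cls) == 0) {
    abort("all resistant points fall off-grid or on nodata pixels")
  }
  tibble(
    accuracy = mean(cls == target_class),
    n_scored = length(cls),
    n_target = sum(cls == target_class),
    n_low = sum(cls == 1),
    n_moderate = sum(cls == 2),
    n_high = sum(cls == 3),
    n_dropped = sum(dropped)
  )
}

#' Read / write resistance observation points
#'
#' CSV with columns `lon`, `lat`, `year`, `status`
#' (status in `{"resistant", "susceptible"}`).
#'
#' @param path File path.
#' @return `read_points_csv()` returns a tibble; `write_points_csv()`
#'   returns `path` invisibly.
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such points file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "year", "status")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("points CSV missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(df$status), c("resistant", "susceptible"))
  if (length(bad)) {
    abort(paste0("unknown status value(s): ", paste(bad, collapse = ", ")))
  }
  if (any(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90)) {
    abort("point coordinates outside [-180, 180] x [-90, 90]")
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_points_csv
#' @param points Data frame with columns `lon`, `lat`, `year`, `status`.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points)[c("lon", "lat", "year", "status")],
                   path, row.names = FALSE)
  invisible(path)
}
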