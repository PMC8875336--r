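#' Assemble the eight-feature sample table for intensity modelling
#'
#' One row per retained segment, carrying the eight candidate predictors
#' of grazing intensity: segment duration `T` (s), walking distance `C`
#' (m), slope `P` (deg), elevation `E` (m), aspect `D` (deg), `NDVI`,
#' animal weight `S` (kg) and ambient temperature `Ftemp` (deg C), plus
#' the `target` intensity (g/m^2) of the grid cell containing the segment
#' midpoint. Terrain and NDVI are sampled at the midpoint; temperature is
#' interpolated at the midpoint time. Rows touching nodata in any feature
#' are dropped and counted (attribute `"dropped"`).
#'
#' @param segments segment data.frame from [segmentize()] (planar)
#' @param rasters list with elements `ndvi`, `dem`, `slope`, `aspect`
#'   (`grazint_raster`s covering the segment midpoints)
#' @param temperature a `grazint_temperature` data.frame (`hour`, `temp_c`)
#' @param weight animal body weight (kg)
#' @param intensity an `intensity_grid` supplying the target
#' @return a `feature_table` data.frame with columns
#'   `T,C,P,E,D,NDVI,S,Ftemp,target`
#' @export
extract_features <- function(segments, rasters, temperature, weight, intensity) {
  if (nrow(segments) == 0) stop("no segments to extract features from")
  need <- c("ndvi", "dem", "slope", "aspect")
  if (!all(need %in% names(rasters)))
    stop("rasters must contain: ", paste(need, collapse = ", "))
  mid <- cbind(segments$mid_x, segments$mid_y)
  ndvi <- sample_raster(rasters$ndvi, mid)
  elev <- sample_raster(rasters$dem, mid)
  slope <- sample_raster(rasters$slope, mid)
  aspect <- sample_raster(rasters$aspect, mid)
  hr <- as.POSIXlt(segments$midpoint_time, tz = "UTC")
  hr <- hr$hour + hr$min / 60 + hr$sec / 3600
  temp <- stats::approx(temperature$hour, temperature$temp_c, xout = hr,
                        rule = 2)$y
  rc <- cell_of(intensity$values, segments$mid_x, segments$mid_y)
  target <- rep(NA_real_, nrow(segments))
  ok <- !is.na(rc[, 1])
  target[ok] <- intensity$values$values[rc[ok, , drop = FALSE]]
  tab <- data.frame(T = segments$duration, C = segments$length,
                    P = slope, E = elev, D = aspect, NDVI = ndvi,
                    S = weight, Ftemp = temp, target = target)
  keep <- stats::complete.cases(tab)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Standardize feature columns to zero mean and unit variance
#'
#' Column-wise `(x - mean) / sd` with the sample standard deviation
#' (denominator n-1). The fitted means and deviations are returned so the
#' same transform can be applied to new data and inverted.
#'
#' @param table a `feature_table` (or any numeric data.frame)
#' @param columns columns to standardize; default all
#' @return list with `table` (standardized) and `params` (data.frame of
#'   `mean` and `sd` per column)
#' @export
standardize <- function(table, columns = names(table)) {
  if (nrow(table) < 2) stop("need at least 2 rows to standardize")
  mu <- vapply(table[columns], mean, numeric(1))
  sd <- vapply(table[columns], stats::sd, numeric(1))
  if (any(sd == 0))
    stop("constant column(s) cannot be standardized: ",
         paste(columns[sd == 0], collapse = ", "))
  out <- table
  for (j in seq_along(columns))
    out[[columns[j]]] <- (table[[columns[j]]] - mu[j]) / sd[j]
  list(table = out,
       params = data.frame(column = columns, mean = mu, sd = sd,
                           row.names = NULL))
}

#' Invert a standardization
#' @param table standardized table
#' @param params the `params` element returned by [standardize()]
#' @return table on the original scale
#' @export
destandardize <- function(table, params) {
  out <- table
  for (j in seq_len(nrow(params))) {
    cn <- params$column[j]
    if (cn %in% names(out))
      out[[cn]] <- out[[cn]] * params$sd[j] + params$mean[j]
  }
  out
}

#' The nine screened feature combinations
#'
#' Inclusion masks over the eight features, in the header order
#' NDVI, S (weight), T (duration), Ftemp (temperature), C (distance),
#' P (slope), D (aspect), E (elevation). `X1` includes all eight; `X7` is
#' the NDVI/weight/duration/temperature/distance subset.
#'
#' @return a 9 x 8 0/1 integer matrix with rownames `X1`..`X9`
#' @export
feature_combinations <- function() {
  m <- rbind(
    X1 = c(1, 1, 1, 1, 1, 1, 1, 1),
    X2 = c(1, 1, 1, 1, 0, 0, 0, 0),
    X3 = c(0, 0, 0, 0, 1, 1, 1, 1),
    X4 = c(1, 1, 0, 0, 1, 1, 1, 1),
    X5 = c(1, 0, 1, 0, 1, 1, 1, 1),
    X6 = c(0, 1, 1, 1, 0, 1, 1, 1),
    X7 = c(1, 1, 1, 1, 1, 0, 0, 0),
    X8 = c(1, 1, 1, 1, 1, 1, 0, 0),
    X9 = c(1, 1, 1, 1, 1, 1, 1, 0))
  colnames(m) <- c("NDVI", "S", "T", "Ftemp", "C", "P", "D", "E")
  storage.mode(m) <- "integer"
  m
}

#' Select the feature columns of one combination
#'
#' Filters columns per the combination mask (rows are never reordered;
#' column order follows the mask header order, target last). Aspect is
#' circular, so when selected it is encoded as two columns `D_sin`,
#' `D_cos` by default; `aspect = "raw"` keeps the flat degree value.
#'
#' @param table a `feature_table` with all eight features
#' @param combo a combination id `"X1"`..`"X9"`, or a named/unnamed 0/1
#'   mask of length 8 in the header order
#' @param aspect `"sincos"` or `"raw"`
#' @return data.frame of the selected feature columns plus `target`
#' @export
select_combination <- function(table, combo = "X1",
                               aspect = c("sincos", "raw")) {
  aspect <- match.arg(aspect)
  combos <- feature_combinations()
  if (is.character(combo)) {
    if (!combo %in% rownames(combos))
      stop("unknown combination '", combo, "'; valid ids: ",
           paste(rownames(combos), collapse = ", "))
    mask <- combos[combo, ]
  } else {
    if (length(combo) != 8) stop("a custom mask must have 8 entries")
    mask <- as.integer(combo)
    names(mask) <- colnames(combos)
  }
  keep <- colnames(combos)[mask == 1]
  out <- table[, keep, drop = FALSE]
  if ("D" %in% keep && aspect == "sincos") {
    rad <- out$D * pi / 180
    pos <- which(names(out) == "D")
    left <- out[, seq_len(pos - 1), drop = FALSE]
    right <- out[, -seq_len(pos), drop = FALSE]
    out <- cbind(left, D_sin = sin(rad), D_cos = cos(rad), right)
  }
  out$target <- table$target
  rownames(out) <- NULL
  out
}
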