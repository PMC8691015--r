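#' Dose grid
#'
#' A regular 3D scalar field of absorbed dose in Gy.
#'
#' @param grid a [grid_spec()].
#' @param dose numeric array matching `grid$shape`; finite and non-negative.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose) {
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  if (is.null(dim(dose)) || !all(dim(dose) == grid$shape))
    stop("dose shape does not match grid shape")
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and non-negative")
  structure(list(grid = grid, dose = dose), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d x %d voxels, dose range [%.2f, %.2f] Gy\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$dose), max(x$dose)))
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' Absolute structure volume receiving at least each dose level, evaluated at
#' every bin edge from 0 Gy upwards with the given bin width (default 10 cGy).
#' Dose is sampled at voxel centres; the mask and the dose grid must share
#' one [grid_spec()].
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [binary_mask()] on the same grid.
#' @param bin_width DVH bin width in Gy.
#' @param structure optional structure name carried into the result.
#' @return Object of class `cumulative_dvh` with fields `structure`,
#'   `bin_width`, `dose_gy` (bin edges) and `volume_cc` (non-increasing;
#'   equal to the total volume at 0 Gy and 0 beyond the maximum dose).
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.1, structure = NA) {
  if (!same_grid(dose$grid, mask$grid))
    stop("dose and mask are on different grids")
  if (bin_width <= 0) stop("bin_width must be > 0")
  d <- dose$dose[mask$values]
  if (length(d) == 0) stop("empty structure")
  vv <- prod(mask$grid$spacing) / 1000
  edges <- seq(0, (floor(max(d) / bin_width) + 1) * bin_width, by = bin_width)
  ds <- sort(d)
  # volume with dose >= edge; doses exactly at an edge count as at-or-above
  n_below <- findInterval(edges - bin_width * 1e-9, ds)
  vol <- (length(ds) - n_below) * vv
  structure(list(structure = structure, bin_width = bin_width,
                 dose_gy = edges, volume_cc = vol,
                 total_volume_cc = length(ds) * vv),
            class = "cumulative_dvh")
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("cumulative_dvh%s: %.2f cm^3, edges 0..%.1f Gy (bin %.2f Gy)\n",
              if (is.na(x$structure)) "" else paste0(" [", x$structure, "]"),
              x$total_volume_cc, max(x$dose_gy), x$bin_width))
  invisible(x)
}

#' Volume-weighted mean dose
#'
#' Arithmetic mean of the dose over the masked voxels (voxels have equal
#' volume, so this is the volume-weighted mean).
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [binary_mask()] on the same grid.
#' @return DMEAN in Gy.
#' @export
dmean <- function(dose, mask) {
  if (!same_grid(dose$grid, mask$grid))
    stop("dose and mask are on different grids")
  d <- dose$dose[mask$values]
  if (length(d) == 0) stop("empty structure")
  mean(d)
}

#' Dose to the maximally exposed 2 cm^3
#'
#' The dose level at which the cumulative DVH crosses `volume_cc` (default
#' 2 cm^3), by linear interpolation between bin edges (`interpolate = FALSE`
#' returns the bin floor instead). For structures smaller than `volume_cc`
#' the minimum structure dose is returned, flagged `"volume<2cc"`.
#'
#' @param dvh a [cumulative_dvh()].
#' @param volume_cc the exposed volume, cm^3.
#' @param interpolate interpolate linearly within the crossing bin.
#' @return D2CC in Gy, with attribute `flag` (`NA` or `"volume<2cc"`).
#' @export
d2cc <- function(dvh, volume_cc = 2, interpolate = TRUE) {
  v <- dvh$volume_cc
  e <- dvh$dose_gy
  if (dvh$total_volume_cc < volume_cc) {
    # minimum structure dose: last edge at which the whole volume remains
    dmin <- e[max(which(v >= dvh$total_volume_cc))]
    return(structure(dmin, flag = "volume<2cc"))
  }
  i <- max(which(v >= volume_cc))
  if (i == length(v)) return(structure(e[i], flag = NA_character_))
  out <- if (interpolate && v[i] > v[i + 1]) {
    e[i] + (v[i] - volume_cc) / (v[i] - v[i + 1]) * (e[i + 1] - e[i])
  } else {
    e[i]
  }
  structure(out, flag = NA_character_)
}

#' Relative volume receiving at least 5 Gy
#'
#' @param dvh a [cumulative_dvh()].
#' @param threshold_gy dose threshold, Gy (default 5).
#' @return Fraction in `[0, 1]`.
#' @export
v5gy <- function(dvh, threshold_gy = 5) {
  if (dvh$total_volume_cc <= 0) stop("empty structure")
  if (threshold_gy > max(dvh$dose_gy)) return(0)
  i <- max(which(dvh$dose_gy <= threshold_gy + 1e-12))
  dvh$volume_cc[i] / dvh$total_volume_cc
}

#' All three dose metrics for one structure
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [binary_mask()] on the same grid.
#' @param bin_width DVH bin width in Gy.
#' @return List with `dmean`, `d2cc`, `v5gy` and `flag` (from [d2cc()]).
#' @export
dose_metrics <- function(dose, mask, bin_width = 0.1) {
  dvh <- cumulative_dvh(dose, mask, bin_width = bin_width)
  d2 <- d2cc(dvh)
  list(dmean = dmean(dose, mask), d2cc = as.numeric(d2),
       v5gy = v5gy(dvh), flag = attr(d2, "flag"))
}

#' Write a cumulative DVH to CSV
#'
#' Columns `dose_gy` (bin edges at the DVH bin width) and `volume_cc`.
#' @param dvh a [cumulative_dvh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  write.csv(data.frame(dose_gy = dvh$dose_gy, volume_cc = dvh$volume_cc),
            path, row.names = FALSE)
  invisible(path)
}
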