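#' Radial averaged kymograph around a moving cell centre
#'
#' For every frame, averages the signal intensity over concentric rings of
#' `ring_width` pixels around the cell centre, producing a time-by-radius
#' intensity grid. If a junction-channel stack is supplied, the per-frame
#' contour radius is the centre of the ring with maximal junction intensity.
#'
#' @param signal A numeric 3D array `[row, col, frame]`, or a list of
#'   matrices (one per frame).
#' @param centre Either a length-2 vector (fixed centre, `c(x, y)` in pixel
#'   coordinates where x indexes columns) or a frames-by-2 matrix.
#' @param junction Optional junction-channel stack of the same shape.
#' @param ring_width Ring width in pixels (default 3).
#' @param max_radius Outermost radius in pixels (default: largest that fits
#'   in the image from the first centre).
#' @return An object of class `extr_kymo`: `$intensity` (frames x bins
#'   matrix), `$radius` (bin centres, px), `$contour_radius` (per frame, px;
#'   `NA` without a junction channel), `$npix` (pixels per bin per frame).
#'   Frames whose centre falls outside the image are skipped with a warning
#'   (rows of `NA`).
#' @export
radial_kymograph <- function(signal, centre, junction = NULL, ring_width = 3,
                             max_radius = NULL) {
  frames <- as_frame_list(signal)
  nt <- length(frames)
  dims <- dim(frames[[1]])
  if (is.null(dim(centre))) centre <- matrix(centre, nt, 2, byrow = TRUE)
  if (!is.null(junction)) junction <- as_frame_list(junction)
  if (is.null(max_radius)) {
    max_radius <- floor(min(centre[1, 1] - 1, dims[2] - centre[1, 1],
                            centre[1, 2] - 1, dims[1] - centre[1, 2]))
  }
  nbins <- max(1L, floor(max_radius / ring_width))
  radius <- (seq_len(nbins) - 0.5) * ring_width
  intensity <- matrix(NA_real_, nt, nbins)
  npix <- matrix(NA_real_, nt, nbins)
  contour <- rep(NA_real_, nt)
  col_x <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  row_y <- matrix(seq_len(dims[1]), dims[1], dims[2])
  for (f in seq_len(nt)) {
    cx <- centre[f, 1]; cy <- centre[f, 2]
    if (cx < 1 || cx > dims[2] || cy < 1 || cy > dims[1]) {
      warn(sprintf("frame %d skipped: centre outside image", f))
      next
    }
    d <- sqrt((col_x - cx)^2 + (row_y - cy)^2)
    bin <- floor(d / ring_width) + 1L
    inside <- bin <= nbins
    sums <- tapply(frames[[f]][inside], bin[inside], sum)
    cnts <- tapply(rep(1, sum(inside)), bin[inside], sum)
    idx <- as.integer(names(sums))
    intensity[f, idx] <- sums / cnts
    npix[f, idx] <- cnts
    if (!is.null(junction)) {
      jsums <- tapply(junction[[f]][inside], bin[inside], mean)
      contour[f] <- radius[idx[which.max(jsums)]]
    }
  }
  structure(list(intensity = intensity, radius = radius,
                 contour_radius = contour, npix = npix,
                 ring_width = ring_width),
            class = "extr_kymo")
}

as_frame_list <- function(x) {
  if (is.list(x)) return(x)
  if (length(dim(x)) == 2) return(list(x))
  lapply(seq_len(dim(x)[3]), function(f) x[, , f])
}

#' @export
print.extr_kymo <- function(x, ...) {
  cat(sprintf("<extr_kymo> %d frames x %d radial bins (%g px rings)\n",
              nrow(x$intensity), ncol(x$intensity), x$ring_width))
  invisible(x)
}

#' @export
tidy.extr_kymo <- function(x, ...) {
  tibble(frame = rep(seq_len(nrow(x$intensity)), ncol(x$intensity)),
         radius_px = rep(x$radius, each = nrow(x$intensity)),
         intensity = as.vector(x$intensity))
}

#' @export
autoplot.extr_kymo <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$frame, .data$radius_px,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frame", y = "distance from centre (px)")
}

#' Mean intensities of the medial, junctional and total cell regions
#'
#' Given a binary cell mask, measures the mean image intensity over the
#' mask eroded by `erode_px` (medio-apical signal), the mask dilated by
#' `dilate_px` (total signal), and a band of width `band_px` centred on the
#' cell contour (junctional signal). Optionally subtracts the mean of a
#' background region outside the tissue.
#'
#' @param mask Binary matrix (non-zero = inside the cell).
#' @param image Numeric matrix of the same size.
#' @param erode_px,dilate_px,band_px Pixel offsets (defaults 3, 3 and 6).
#' @param background Optional: either a scalar background level or a list
#'   `list(x, y, size)` describing a square ROI (default 20 px) whose mean
#'   is subtracted.
#' @return A one-row tibble: `medial`, `junctional`, `total`,
#'   `background`. An erosion that empties the mask flags `medial = NA`
#'   with a warning.
#' @export
region_intensities <- function(mask, image, erode_px = 3, dilate_px = 3,
                               band_px = 6, background = NULL) {
  mask <- (mask != 0) * 1
  if (sum(mask) == 0) {
    abort("empty mask", class = "extrudr_parameter_error")
  }
  bg <- 0
  if (!is.null(background)) {
    bg <- if (is.numeric(background) && length(background) == 1) background
    else {
      size <- background$size %||% 20
      xs <- background$x + seq_len(size) - 1
      ys <- background$y + seq_len(size) - 1
      mean(image[ys, xs])
    }
  }
  eroded <- EBImage::erode(mask, disc_brush(erode_px))
  dilated <- EBImage::dilate(mask, disc_brush(dilate_px))
  half <- band_px / 2
  band <- EBImage::dilate(mask, disc_brush(half)) -
    EBImage::erode(mask, disc_brush(half))
  medial <- if (sum(eroded) == 0) {
    warn("erosion emptied the mask: medial intensity undefined")
    NA_real_
  } else mean(image[eroded > 0]) - bg
  tibble(medial = medial,
         junctional = mean(image[band > 0]) - bg,
         total = mean(image[dilated > 0]) - bg,
         background = bg)
}

disc_brush <- function(px) {
  size <- 2 * ceiling(px) + 1
  EBImage::makeBrush(size, shape = "disc")
}

#' Apicobasal intensity profiles aligned to the junctional reference
#'
#' Each cell's per-plane mean intensities are shifted so that the
#' reference-channel maximum (the apical junctional plane) sits at relative
#' depth 0, then min-max normalised to [0, 1]. The ensemble mean and SEM
#' are computed per relative plane over the cells present there. A flat
#' reference profile is flagged and its tie broken towards the most apical
#' plane (lowest `z`).
#'
#' @param profiles Long tibble with columns `cell_id`, `z` (plane index,
#'   increasing from apical to basal), `reference`, `signal`.
#' @return A list: `$members` (per-cell `rel_z`, `signal_norm`), `$summary`
#'   (`rel_z`, `mean`, `sem`, `n`), `$flags` (cells with a flat reference).
#' @export
apicobasal_profile <- function(profiles) {
  flags <- character()
  members <- profiles |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$z)
      if (nrow(df) < 3) {
        abort("need at least 3 z planes per cell", class = "extrudr_parameter_error")
      }
      if (max(df$reference) == min(df$reference)) {
        flags <<- c(flags, as.character(key$cell_id))
      }
      zmax <- df$z[which.max(df$reference)]  # which.max ties -> most apical
      rng <- range(df$signal)
      sn <- if (diff(rng) == 0) rep(0, nrow(df)) else {
        (df$signal - rng[1]) / diff(rng)
      }
      tibble(rel_z = df$z - zmax, signal_norm = sn)
    }) |>
    dplyr::ungroup()
  summary <- members |>
    dplyr::group_by(.data$rel_z) |>
    dplyr::summarise(mean = mean(.data$signal_norm),
                     sem = sd(.data$signal_norm) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  list(members = members, summary = summary, flags = flags)
}
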