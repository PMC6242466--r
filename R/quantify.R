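#' Background intensity model of a plate image
#'
#' A pixel is classified as background iff its intensity is at most
#' `level + k * spread`. When a grid is supplied the level and robust spread
#' are estimated from pixels at inter-colony margins (the diagonal midpoints
#' between neighboring colony centers), which keeps bright colonies out of
#' the estimate.
#'
#' @param level Background intensity level.
#' @param spread Robust scale of the background.
#' @param k Multiplier for the background/foreground cut.
#' @return A list of class `background_model`.
#' @export
background_model <- function(level, spread = 0, k = 3) {
  if (spread < 0) stop("spread must be non-negative")
  if (k <= 0) stop("k must be positive")
  structure(list(level = level, spread = spread, k = k),
            class = "background_model")
}

#' @rdname background_model
#' @param image Numeric image matrix.
#' @param grid Optional [grid_spec()]; without it the whole image is used
#'   (valid when colonies cover a minority of pixels).
#' @export
estimate_background <- function(image, grid = NULL, k = 3) {
  if (is.null(grid)) {
    px <- as.numeric(image)
  } else {
    cen <- grid_centers(grid)
    mx <- round(cen$x + grid$pitch_x / 2)
    my <- round(cen$y + grid$pitch_y / 2)
    ok <- mx >= 1 & mx < ncol(image) - 1 & my >= 1 & my < nrow(image) - 1
    px <- unlist(lapply(which(ok), function(i) {
      image[(my[i]):(my[i] + 2), (mx[i]):(mx[i] + 2)]
    }))
  }
  background_model(level = stats::median(px),
                   spread = stats::mad(px), k = k)
}

is_background <- function(intensity, bg) {
  intensity <= bg$level + bg$k * bg$spread
}

px <- function(image, x, y) image[y + 1L, x + 1L]

#' Estimate the colony grid of a plate image
#'
#' Recovers the rotation of the colony rows relative to the image frame, the
#' center-to-center pitch, and the position of the top-left colony. The angle
#' maximizes the variance of the intensity profile of foreground pixels
#' projected onto the row axis; peaks of the row/column profiles give the
#' pitch (span between the outermost peak centroids over the peak count) and
#' the first peak gives the top-left center. A manual anchor overrides the
#' corresponding estimates.
#'
#' @param image Numeric image matrix.
#' @param format_hint Plate format, 384 or 1536.
#' @param anchor Optional list with any of `top_left` (`c(x, y)`), `angle`,
#'   `pitch` (`c(pitch_x, pitch_y)`); given parts are taken as-is.
#' @param angle_range,angle_step Search window for the angle, degrees.
#' @return A [grid_spec()].
#' @export
estimate_grid <- function(image, format_hint = 1536L, anchor = NULL,
                          angle_range = 5, angle_step = 0.25) {
  dims <- grid_dims(format_hint)
  bg <- estimate_background(image, k = 3)
  fg <- which(image > bg$level + bg$k * bg$spread + 1e-9)
  full_anchor <- !is.null(anchor) && !is.null(anchor$top_left) &&
    !is.null(anchor$angle) && !is.null(anchor$pitch)
  if (length(fg) < dims[1] * dims[2] && !full_anchor)
    stop("grid-detection error: no colony structure found and no full anchor")

  w <- image[fg] - bg$level
  yx <- arrayInd(fg, dim(image))
  y <- yx[, 1] - 1L
  x <- yx[, 2] - 1L

  if (!is.null(anchor) && !is.null(anchor$angle)) {
    theta <- anchor$angle * pi / 180
  } else {
    cand <- seq(-angle_range, angle_range, by = angle_step) * pi / 180
    score <- vapply(cand, function(th) {
      r <- round(-x * sin(th) + y * cos(th))
      stats::var(vapply(split(w, r), sum, 0))
    }, 0)
    theta <- cand[which.max(score)]
  }

  r <- -x * sin(theta) + y * cos(theta)   # row axis coordinate
  c_ <- x * cos(theta) + y * sin(theta)   # column axis coordinate
  row_pk <- profile_peaks(r, w)
  col_pk <- profile_peaks(c_, w)
  if ((length(row_pk) < 2 || length(col_pk) < 2) && !full_anchor)
    stop("grid-detection error: too few row/column peaks")

  if (!is.null(anchor) && !is.null(anchor$pitch)) {
    pitch_x <- anchor$pitch[1]; pitch_y <- anchor$pitch[2]
  } else {
    pitch_y <- (row_pk[length(row_pk)] - row_pk[1]) / (length(row_pk) - 1)
    pitch_x <- (col_pk[length(col_pk)] - col_pk[1]) / (length(col_pk) - 1)
  }
  if (!is.null(anchor) && !is.null(anchor$top_left)) {
    top_left <- as.numeric(anchor$top_left)
  } else {
    r0 <- row_pk[1]; c0 <- col_pk[1]
    top_left <- c(c0 * cos(theta) - r0 * sin(theta),
                  c0 * sin(theta) + r0 * cos(theta))
  }
  grid_spec(format = format_hint, top_left = top_left,
            angle = theta * 180 / pi, pitch_x = pitch_x, pitch_y = pitch_y)
}

# weighted 1-D intensity profile -> sub-pixel peak positions; min_frac is
# kept low so rows/columns of uniformly dim colonies still register
profile_peaks <- function(coord, weight, min_frac = 0.05) {
  b <- round(coord)
  prof <- vapply(split(weight, b), sum, 0)
  pos <- as.numeric(names(prof))
  ord <- order(pos)
  pos <- pos[ord]; prof <- prof[ord]
  # fill gaps so local-maximum detection sees a regular axis
  full <- seq(min(pos), max(pos))
  v <- numeric(length(full))
  v[match(pos, full)] <- prof
  sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  n <- length(sm)
  if (n < 3) return(numeric(0))
  is_max <- sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) &
    sm > min_frac * max(sm)
  peaks <- full[is_max]
  # sub-pixel refinement: intensity centroid within +/- 3 bins
  vapply(peaks, function(p) {
    win <- full >= p - 3 & full <= p + 3
    sum(full[win] * v[win]) / sum(v[win])
  }, 0)
}

walk_to_background <- function(image, x, y, bg, max_walk = 40) {
  w <- ncol(image); h <- nrow(image)
  step_dir <- function(dx, dy) {
    d <- 0L
    repeat {
      nx <- x + (d + 1L) * dx; ny <- y + (d + 1L) * dy
      if (nx < 0 || nx >= w || ny < 0 || ny >= h) return(c(d, 1L))
      if (is_background(px(image, nx, ny), bg)) return(c(d, 0L))
      d <- d + 1L
      if (d >= max_walk) return(c(d, 1L))
    }
  }
  left <- step_dir(-1L, 0L); right <- step_dir(1L, 0L)
  up <- step_dir(0L, -1L); down <- step_dir(0L, 1L)
  list(left = left[1], right = right[1], up = up[1], down = down[1],
       capped = any(c(left[2], right[2], up[2], down[2]) == 1L))
}

#' Measure one colony around an estimated center
#'
#' Implements the colony-measurement walk: (1) the intensity center of
#' gravity within a 17 x 17 window around the estimated center (background
#' level subtracted so flat background does not bias the centroid), rounded
#' to a pixel; (2) from that pixel, walks left/right/up/down to the pixel
#' before the first background pixel and re-centers at the midpoint of the
#' bounding box; (3) repeats the walk once from the new center, giving the
#' final central pixel and four border distances. The oval has semi-axes
#' `(left + right) / 2` and `(up + down) / 2`; the integrated density is the
#' mean intensity over pixels inside the oval times the oval area
#' `pi * a * b`.
#'
#' @param image Numeric image matrix.
#' @param est_center Estimated center `c(x, y)` (0-based pixel coordinates).
#' @param bg A [background_model()].
#' @param window Search window side (odd), default 17.
#' @param max_walk Walk cap in pixels; exceeding it flags the measurement.
#' @param subtract_background If `TRUE`, subtract `bg$level` from the mean
#'   density. Off by default; downstream normalization absorbs the offset.
#' @return One-row data frame: center_x, center_y, semi_x, semi_y, area,
#'   mean_density, integrated_density, missing, capped.
#' @export
measure_colony <- function(image, est_center, bg, window = 17L,
                           max_walk = 40L, subtract_background = FALSE) {
  h <- (window - 1L) %/% 2L
  cx0 <- min(max(round(est_center[1]), h), ncol(image) - 1L - h)
  cy0 <- min(max(round(est_center[2]), h), nrow(image) - 1L - h)
  xs <- (cx0 - h):(cx0 + h)
  ys <- (cy0 - h):(cy0 + h)
  win <- image[ys + 1L, xs + 1L]
  if (all(is_background(win, bg)))
    return(data.frame(center_x = NA_real_, center_y = NA_real_,
                      semi_x = 0, semi_y = 0, area = 0, mean_density = 0,
                      integrated_density = 0, missing = TRUE, capped = FALSE))
  wgt <- pmax(win - bg$level, 0)
  cx <- round(sum(t(wgt) * xs) / sum(wgt))
  cy <- round(sum(wgt * ys) / sum(wgt))

  wk <- walk_to_background(image, cx, cy, bg, max_walk)
  cx <- cx + round((wk$right - wk$left) / 2)
  cy <- cy + round((wk$down - wk$up) / 2)
  wk2 <- walk_to_background(image, cx, cy, bg, max_walk)
  fx <- cx + round((wk2$right - wk2$left) / 2)
  fy <- cy + round((wk2$down - wk2$up) / 2)
  a <- (wk2$left + wk2$right) / 2
  b <- (wk2$up + wk2$down) / 2

  if (a == 0 && b == 0)
    return(data.frame(center_x = fx, center_y = fy, semi_x = 0, semi_y = 0,
                      area = 0, mean_density = 0, integrated_density = 0,
                      missing = FALSE, capped = wk$capped || wk2$capped))
  ex <- max(1, ceiling(a)); ey <- max(1, ceiling(b))
  oxs <- pmax(0, fx - ex):pmin(ncol(image) - 1L, fx + ex)
  oys <- pmax(0, fy - ey):pmin(nrow(image) - 1L, fy + ey)
  d2 <- outer(((oys - fy) / max(b, 0.5))^2, ((oxs - fx) / max(a, 0.5))^2, "+")
  inside <- d2 <= 1
  vals <- image[oys + 1L, oxs + 1L][inside]
  mean_density <- mean(vals) - if (subtract_background) bg$level else 0
  area <- pi * a * b
  data.frame(center_x = fx, center_y = fy, semi_x = a, semi_y = b,
             area = area, mean_density = mean_density,
             integrated_density = mean_density * area,
             missing = FALSE, capped = wk$capped || wk2$capped)
}

#' Quantify every colony of a plate
#'
#' Runs [measure_colony()] at each predicted grid center and joins the
#' measurements to strain identities from the plate layout.
#'
#' @param image Numeric image matrix.
#' @param grid A [grid_spec()].
#' @param layout Data frame with columns row, col, strain_id (0-based grid
#'   indices); positions absent from the layout or with `NA` strain_id are
#'   treated as intentionally empty.
#' @param bg Optional [background_model()]; estimated from the image and
#'   grid when omitted.
#' @param ... Passed to [measure_colony()].
#' @return Data frame, one row per grid position: row, col, strain_id plus
#'   the [measure_colony()] fields.
#' @export
quantify_plate <- function(image, grid, layout, bg = NULL, ...) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!all(c("row", "col", "strain_id") %in% names(layout)))
    stop("layout needs columns row, col, strain_id")
  if (any(layout$row < 0 | layout$row >= grid$n_rows |
          layout$col < 0 | layout$col >= grid$n_cols))
    stop("layout/grid dimension mismatch")
  if (is.null(bg)) bg <- estimate_background(image, grid)
  cen <- grid_centers(grid)
  meas <- vector("list", nrow(cen))
  for (i in seq_len(nrow(cen)))
    meas[[i]] <- measure_colony(image, c(cen$x[i], cen$y[i]), bg, ...)
  out <- cbind(cen[, c("row", "col")], do.call(rbind, meas))
  out$strain_id <- layout$strain_id[match(paste(out$row, out$col),
                                          paste(layout$row, layout$col))]
  out[, c("row", "col", "strain_id", "center_x", "center_y", "semi_x",
          "semi_y", "area", "mean_density", "integrated_density",
          "missing", "capped")]
}
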