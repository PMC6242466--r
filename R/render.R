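#' Grid geometry of a pinned colony array
#'
#' @param format Colonies per plate, 384 (16 x 24) or 1536 (32 x 48).
#' @param top_left Pixel coordinate `c(x, y)` of the first (row 0, col 0)
#'   colony center; 0-based, x = column, y = row, origin at the top left.
#' @param angle Rotation of the colony rows relative to the image frame,
#'   degrees, in (-45, 45).
#' @param pitch_x,pitch_y Center-to-center spacing in pixels.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(format = 1536L, top_left = c(20, 20), angle = 0,
                      pitch_x = 20, pitch_y = 20) {
  dims <- grid_dims(format)
  if (pitch_x <= 0 || pitch_y <= 0) stop("pitch must be positive")
  if (angle <= -45 || angle >= 45) stop("angle must lie in (-45, 45) degrees")
  structure(list(n_rows = dims[1], n_cols = dims[2],
                 top_left = as.numeric(top_left), angle = angle,
                 pitch_x = pitch_x, pitch_y = pitch_y,
                 format = as.integer(format)),
            class = "grid_spec")
}

grid_dims <- function(format) {
  switch(as.character(format),
         "384" = c(16L, 24L),
         "1536" = c(32L, 48L),
         stop("plate format must be 384 or 1536"))
}

#' Predicted colony centers of a grid
#'
#' @param grid A [grid_spec()].
#' @return Data frame with 0-based grid indices `row`, `col` and pixel
#'   coordinates `x`, `y` (row-major order).
#' @export
grid_centers <- function(grid) {
  idx <- expand.grid(col = seq_len(grid$n_cols) - 1L,
                     row = seq_len(grid$n_rows) - 1L)
  th <- grid$angle * pi / 180
  u <- idx$col * grid$pitch_x
  v <- idx$row * grid$pitch_y
  data.frame(row = idx$row, col = idx$col,
             x = grid$top_left[1] + u * cos(th) - v * sin(th),
             y = grid$top_left[2] + u * sin(th) + v * cos(th))
}

#' Draw one colony into an image matrix
#'
#' The colony is a Gaussian-capped disc: intensity falls off as
#' `exp(-r^2 / (2 sigma^2))` and is truncated at radius `R = 3 sigma`, with
#' `R` proportional to the square root of the integrated density (wider
#' colonies are bigger, as on pinned arrays) and capped below half the grid
#' pitch so neighbors never overlap. The amplitude is rescaled so the
#' discrete pixel sum equals `density` exactly.
#'
#' @param image Numeric matrix (rows = y, cols = x), intensity units.
#' @param cx,cy Center pixel coordinate (0-based).
#' @param density Target integrated pixel sum above background.
#' @param r_ref,d_ref Radius scale: `R = r_ref * sqrt(density / d_ref)`.
#' @param r_max Radius cap in pixels.
#' @return The image with the colony added.
#' @keywords internal
draw_colony <- function(image, cx, cy, density, r_ref = 5, d_ref = 2048,
                        r_min = 3, r_max = 8.5) {
  if (density <= 0) return(image)
  # pinned colonies have a minimum footprint of a few pixels even when
  # nearly empty; sub-pixel discs are not physical
  R <- min(r_max, max(r_min, r_ref * sqrt(density / d_ref)))
  sigma <- R / 3
  h <- ceiling(R)
  xs <- (round(cx) - h):(round(cx) + h)
  ys <- (round(cy) - h):(round(cy) + h)
  xs <- xs[xs >= 0 & xs < ncol(image)]
  ys <- ys[ys >= 0 & ys < nrow(image)]
  r2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  prof <- exp(-r2 / (2 * sigma^2))
  prof[r2 > R^2] <- 0
  s <- sum(prof)
  if (s > 0)
    image[ys + 1L, xs + 1L] <- image[ys + 1L, xs + 1L] + density / s * prof
  image
}

#' Render plate images from a density table
#'
#' Inverse of the quantification stage: draws each colony of each physical
#' plate (one image per plate x imaging day) as a radially smooth disc whose
#' pixel sum above background equals its table density, on a flat background
#' with optional Gaussian pixel noise. Strains are laid out row-major in
#' plate order; positions beyond the last strain stay empty.
#'
#' @param table Raw-stage density table (see [simulate_screen()]).
#' @param grid A [grid_spec()]; its format fixes the positions per plate.
#' @param image_noise_sd SD of additive Gaussian pixel noise.
#' @param background Background intensity level.
#' @param margin Pixels of margin beyond the outermost centers.
#' @param seed Integer seed for the pixel noise.
#' @return List with `plates` (per plate x day: `image`, `plate_id`, `day`,
#'   `centers` with the true center and the drawn density of each position)
#'   and `layout` (plate_id, row, col, strain_id; strain_id `NA` for empty
#'   positions).
#' @export
render_plates <- function(table, grid, image_noise_sd = 0, background = 500,
                          margin = 20, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  set.seed(seed)
  strains <- unique(table$strain_id)
  per_plate <- grid$n_rows * grid$n_cols
  plate_ids <- sort(unique(table$plate_id))
  # strains are assigned row-major within each plate, in first-seen order
  layout_list <- list()
  plates <- list()
  cen <- grid_centers(grid)
  width <- ceiling(max(cen$x) + margin)
  height <- ceiling(max(cen$y) + margin)
  for (pid in plate_ids) {
    sub <- table[table$plate_id == pid, , drop = FALSE]
    pstrains <- unique(sub$strain_id)
    if (length(pstrains) > per_plate)
      stop("layout error: plate ", pid, " has ", length(pstrains),
           " strains for ", per_plate, " positions")
    lay <- data.frame(plate_id = pid, row = cen$row, col = cen$col,
                      strain_id = c(pstrains,
                                    rep(NA_character_,
                                        per_plate - length(pstrains))),
                      stringsAsFactors = FALSE)
    layout_list[[pid]] <- lay
    for (d in sort(unique(sub$day))) {
      dsub <- sub[sub$day == d, , drop = FALSE]
      dens <- dsub$density[match(lay$strain_id, dsub$strain_id)]
      dens[is.na(dens)] <- 0
      img <- matrix(background, nrow = height, ncol = width)
      for (i in seq_len(per_plate)) {
        if (dens[i] > 0)
          img <- draw_colony(img, cen$x[i], cen$y[i], dens[i],
                             r_max = 0.45 * min(grid$pitch_x, grid$pitch_y))
      }
      if (image_noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, image_noise_sd),
                            nrow = height)
      plates[[length(plates) + 1L]] <- list(
        image = img, plate_id = pid, day = d,
        centers = data.frame(row = cen$row, col = cen$col,
                             x = cen$x, y = cen$y, density = dens,
                             strain_id = lay$strain_id,
                             stringsAsFactors = FALSE))
    }
  }
  list(plates = plates, layout = do.call(rbind, layout_list))
}
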