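#' Generate a synthetic thorax geometry
#'
#' Places two ellipsoidal lung regions laterally and one heart region
#' ventrally/centrally inside an elliptical body outline on a square pixel
#' grid, mimicking the anatomy visible in a transverse EIT slice. Rows run
#' ventral (top) to dorsal (bottom), columns right to left lung. A small
#' seed-driven jitter of centres and radii makes subjects distinguishable
#' while keeping the three regions disjoint by construction.
#'
#' @param grid_size side length of the square grid in pixels (>= 16,
#'   default 32).
#' @param seed integer seed controlling the anatomical jitter.
#' @return an object of class `thorax_geometry`: list with `grid_size`,
#'   binary matrices `lung_mask`, `heart_mask`, `body_mask`,
#'   `background_mask` (body minus organs), and `left_lung_mask` /
#'   `right_lung_mask` components.
#' @export
make_geometry <- function(grid_size = 32L, seed = 0L) {
  if (grid_size < 16L)
    stop("`grid_size` must be at least 16 pixels to fit two lungs and a heart as disjoint regions")
  g <- as.integer(grid_size)
  restore <- save_rng(); on.exit(restore())
  set.seed(seed)
  jit <- function(x, frac = 0.02) x * (1 + runif(1, -frac, frac))

  rr <- matrix(seq_len(g), g, g)          # row index (ventral -> dorsal)
  cc <- matrix(seq_len(g), g, g, byrow = TRUE)
  ellipse <- function(r0, c0, a, b) ((rr - r0) / a)^2 + ((cc - c0) / b)^2 <= 1

  ctr <- (g + 1) / 2
  body <- ellipse(ctr, ctr, 0.46 * g, 0.48 * g)

  # lungs: dorsal-lateral ellipses; heart: ventral, slightly left of centre
  lung_r <- jit(0.54 * g); lung_a <- jit(0.22 * g); lung_b <- jit(0.135 * g)
  right_lung <- ellipse(lung_r, jit(0.28 * g), lung_a, lung_b)
  left_lung  <- ellipse(lung_r, jit(0.72 * g), lung_a, lung_b)
  heart <- ellipse(jit(0.33 * g), jit(0.54 * g), jit(0.105 * g), jit(0.12 * g))

  # enforce disjointness with a 1-pixel guard band around the heart
  guard <- mask_dilate(heart)
  right_lung <- right_lung & !guard
  left_lung <- left_lung & !guard
  lung <- (right_lung | left_lung) & body
  heart <- heart & body

  geom <- structure(list(
    grid_size = g,
    lung_mask = lung, heart_mask = heart,
    left_lung_mask = left_lung & body, right_lung_mask = right_lung & body,
    body_mask = body, background_mask = body & !lung & !heart,
    seed = as.integer(seed)
  ), class = "thorax_geometry")
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  with(geom, {
    if (any(lung_mask & heart_mask)) stop("lung and heart masks overlap")
    if (any((lung_mask | heart_mask) & !body_mask))
      stop("organ masks extend outside the body outline")
    for (m in list(left_lung_mask, right_lung_mask, heart_mask)) {
      if (sum(m) < 4L)
        stop("each anatomical region needs at least 4 pixels; increase grid_size")
      if (max(label_components4(m)) != 1L)
        stop("each anatomical region must be a single 4-connected component")
    }
  })
  invisible(geom)
}

#' @export
print.thorax_geometry <- function(x, ...) {
  cat(sprintf("<thorax_geometry> %dx%d grid: lung %d px (L %d / R %d), heart %d px\n",
              x$grid_size, x$grid_size, sum(x$lung_mask),
              sum(x$left_lung_mask), sum(x$right_lung_mask),
              sum(x$heart_mask)))
  invisible(x)
}

# Save the caller-visible RNG state; returns a function restoring it.
# Usage: restore <- save_rng(); on.exit(restore()); set.seed(seed)
save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }
  }
}
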