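#' Configuration of a synthetic stained-section scene
#'
#' Describes a grayscale immunohistochemistry field: dark (DAB-like)
#' stained structures on a bright noisy background. Vessels are capsules
#' (thick line segments); CD163-like cells are placed by an inhomogeneous
#' Poisson point process whose intensity decays exponentially with
#' distance d from the nearest vessel boundary,
#' \deqn{\lambda(d) = \lambda_{wall} e^{-d/\ell} + \lambda_{bg},}
#' Iba1-like (microglial) cells by a homogeneous Poisson process, and
#' amyloid plaques as diffuse blobs surrounded by a mixed periplaque cell
#' population.
#'
#' @param image_size_px Width x height in pixels (default 1879 x 872, a
#'   standard slide-scanner field).
#' @param pixels_per_micron Spatial calibration (default 0.585 px/um,
#'   i.e. a 200 um scale bar spanning 117 px).
#' @param n_vessels Number of vessels.
#' @param vessel_radius_um Range (min, max) of vessel capsule radii, um.
#' @param vessel_length_um Range of vessel segment lengths, um.
#' @param cd163_rate_at_wall Intensity of the CD163 process at the vessel
#'   wall, cells per mm^2.
#' @param cd163_decay_length_um Exponential decay length of the
#'   perivascular gradient, um.
#' @param cd163_background_rate Distance-independent CD163 intensity,
#'   cells per mm^2.
#' @param iba1_rate Homogeneous Iba1 cell intensity, cells per mm^2.
#' @param n_plaques Number of plaques.
#' @param plaque_radius_um Range of plaque radii, um.
#' @param periplaque_cells_mean Mean number of periplaque cells per plaque
#'   (Poisson).
#' @param periplaque_band_um Width of the band around the plaque boundary
#'   in which periplaque cells are placed, um.
#' @param phenotype_mixture Proportions over the periplaque phenotypes
#'   `microglia` (Iba1+/Trem2+/Tmem119+/DAPI+), `microglia_like` (all
#'   markers incl. Cd163) and `infiltrate` (Cd163+/DAPI+ only); must sum
#'   to 1 (default 0.60/0.25/0.15).
#' @param cell_radius_um Range of cell soma radii, um.
#' @param stain_intensity Named 8-bit mean intensities of the stained
#'   structures per channel (dark-on-bright: must be below
#'   `background_intensity`).
#' @param background_intensity 8-bit background mean (default 220).
#' @param noise_sd Additive Gaussian intensity noise SD (8-bit units).
#' @param seed Integer RNG seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_size_px = c(1879L, 872L),
                         pixels_per_micron = 0.585,
                         n_vessels = 8L,
                         vessel_radius_um = c(8, 20),
                         vessel_length_um = c(80, 250),
                         cd163_rate_at_wall = 120,
                         cd163_decay_length_um = 60,
                         cd163_background_rate = 15,
                         iba1_rate = 80,
                         n_plaques = 5L,
                         plaque_radius_um = c(15, 40),
                         periplaque_cells_mean = 8,
                         periplaque_band_um = 30,
                         phenotype_mixture = c(microglia = 0.60,
                                               microglia_like = 0.25,
                                               infiltrate = 0.15),
                         cell_radius_um = c(3, 6),
                         stain_intensity = c(Cd163 = 80, Iba1 = 80, OC = 120),
                         background_intensity = 220,
                         noise_sd = 8,
                         seed = 1L) {
  if (length(image_size_px) != 2 || any(image_size_px < 16))
    stop("`image_size_px` must be (width, height), each >= 16 px")
  if (pixels_per_micron <= 0) stop("`pixels_per_micron` must be > 0")
  if (cd163_decay_length_um <= 0) stop("decay length must be > 0")
  rates <- c(cd163_rate_at_wall, cd163_background_rate, iba1_rate)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (abs(sum(phenotype_mixture) - 1) > 1e-9)
    stop("phenotype mixture proportions must sum to 1")
  if (!all(c("microglia", "microglia_like", "infiltrate") %in%
             names(phenotype_mixture)))
    stop("phenotype_mixture must name microglia, microglia_like, infiltrate")
  if (any(stain_intensity >= background_intensity))
    stop("stain intensities must be below the background (dark-on-bright)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  w_um <- image_size_px[1] / pixels_per_micron
  h_um <- image_size_px[2] / pixels_per_micron
  if (n_vessels > 0 && 2 * max(vessel_radius_um) >= min(w_um, h_um))
    stop("vessels cannot fit in the image bounds")
  if (n_plaques > 0 && 2 * max(plaque_radius_um) >= min(w_um, h_um))
    stop("plaques cannot fit in the image bounds")
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixels_per_micron = pixels_per_micron,
         n_vessels = as.integer(n_vessels),
         vessel_radius_um = vessel_radius_um,
         vessel_length_um = vessel_length_um,
         cd163_rate_at_wall = cd163_rate_at_wall,
         cd163_decay_length_um = cd163_decay_length_um,
         cd163_background_rate = cd163_background_rate,
         iba1_rate = iba1_rate,
         n_plaques = as.integer(n_plaques),
         plaque_radius_um = plaque_radius_um,
         periplaque_cells_mean = periplaque_cells_mean,
         periplaque_band_um = periplaque_band_um,
         phenotype_mixture = phenotype_mixture,
         cell_radius_um = cell_radius_um,
         stain_intensity = stain_intensity,
         background_intensity = background_intensity,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# distance from points (px, py) to segment (x0,y0)-(x1,y1); all in um
dist_point_segment <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else
    pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

# signed distance to the nearest vessel boundary (negative inside the
# capsule) and the index of the nearest vessel, for point vectors in um
nearest_vessel_distance <- function(px, py, vessels) {
  best <- rep(Inf, length(px)); idx <- rep(NA_integer_, length(px))
  for (v in seq_len(nrow(vessels))) {
    d <- dist_point_segment(px, py, vessels$x0[v], vessels$y0[v],
                            vessels$x1[v], vessels$y1[v]) -
         vessels$radius_um[v]
    better <- d < best
    best[better] <- d[better]
    idx[better] <- v
  }
  list(dist = best, nearest = idx)
}

#' Per-pixel distance to the nearest vessel boundary
#'
#' Computes, from the vessel capsule geometry, the exact Euclidean
#' distance of every pixel center to the nearest vessel boundary, the
#' identity of that vessel, and the binary vessel mask. Used by the
#' perivascular halo analysis; overlap regions between neighbouring
#' vessels' halos are resolved by nearest-vessel assignment.
#'
#' @param vessels data.frame with columns `x0, y0, x1, y1, radius_um`
#'   (segment endpoints and capsule radius, um).
#' @param image_size_px Width x height in pixels.
#' @param pixels_per_micron Spatial calibration.
#' @return List with matrices (height x width) `dist_um` (0 inside
#'   vessels), `nearest` (vessel index) and logical `vessel_mask`.
#' @export
vessel_distance_field <- function(vessels, image_size_px,
                                  pixels_per_micron) {
  w <- image_size_px[1]; h <- image_size_px[2]
  xs <- ((seq_len(w)) - 0.5) / pixels_per_micron
  ys <- ((seq_len(h)) - 0.5) / pixels_per_micron
  px <- rep(xs, each = h)     # column-major over an h x w matrix
  py <- rep(ys, times = w)
  nv <- nearest_vessel_distance(px, py, vessels)
  dist <- matrix(pmax(0, nv$dist), h, w)
  list(dist_um = dist,
       nearest = matrix(nv$nearest, h, w),
       vessel_mask = matrix(nv$dist <= 0, h, w))
}

paint_disc <- function(mat, cx_px, cy_px, r_px, value) {
  h <- nrow(mat); w <- ncol(mat)
  rows <- max(1, floor(cy_px - r_px)):min(h, ceiling(cy_px + r_px))
  cols <- max(1, floor(cx_px - r_px)):min(w, ceiling(cx_px + r_px))
  if (!length(rows) || !length(cols)) return(mat)
  dd <- outer((rows - 0.5 - cy_px)^2, (cols - 0.5 - cx_px)^2, "+")
  sub <- mat[rows, cols, drop = FALSE]
  sub[dd <= r_px^2] <- value
  mat[rows, cols] <- sub
  mat
}

marker_sets <- list(
  microglia = c("Iba1", "Trem2", "Tmem119", "DAPI"),
  microglia_like = c("Iba1", "Trem2", "Tmem119", "DAPI", "Cd163"),
  infiltrate = c("Cd163", "DAPI")
)

#' Simulate a stained-section image with ground truth
#'
#' Generates per-channel 8-bit grayscale images (dark stain on a bright
#' noisy background) of a field containing vessels, a perivascular
#' gradient of CD163-like cells, uniformly placed Iba1-like microglia,
#' plaque blobs and periplaque cells of mixed phenotype, together with
#' exact ground truth (cell coordinates and marker sets, continuous
#' distance to the nearest vessel boundary, vessel mask, plaque regions,
#' and the exact painted pixel fraction per channel before noise).
#'
#' CD163-like cells are drawn by thinning a homogeneous Poisson process at
#' the maximal intensity; Iba1-like cells by a homogeneous process; both
#' are excluded from vessel lumina.
#'
#' @param config A [scene_config()].
#' @param channels Channels to render (subset of `"Cd163"`, `"Iba1"`,
#'   `"OC"`).
#' @return List with `image` (named list of integer matrices, plus the
#'   calibration as attribute `pixels_per_micron`), `vessels`, `plaques`,
#'   and `ground_truth` (list: `cells` data.frame with `x_um`, `y_um`,
#'   `radius_um`, `markers` (semicolon-joined), `dist_vessel_um`,
#'   `compartment`, `plaque`; `vessel_mask`; `painted_fraction`).
#' @export
simulate_staining_image <- function(config = scene_config(),
                                    channels = c("Cd163", "Iba1", "OC")) {
  stopifnot(inherits(config, "scene_config"))
  channels <- match.arg(channels, c("Cd163", "Iba1", "OC"),
                        several.ok = TRUE)
  set.seed(config$seed)
  ppm <- config$pixels_per_micron
  w_px <- config$image_size_px[1]; h_px <- config$image_size_px[2]
  w_um <- w_px / ppm; h_um <- h_px / ppm
  area_mm2 <- w_um * h_um / 1e6

  # --- vessels: random capsules fully inside the field
  nv <- config$n_vessels
  vessels <- if (nv > 0) {
    r <- stats::runif(nv, config$vessel_radius_um[1],
                      config$vessel_radius_um[2])
    len <- stats::runif(nv, config$vessel_length_um[1],
                        config$vessel_length_um[2])
    theta <- stats::runif(nv, 0, pi)
    margin <- r + 1
    cx <- stats::runif(nv, margin, w_um - margin)
    cy <- stats::runif(nv, margin, h_um - margin)
    clamp <- function(v, lo, hi) pmin(hi, pmax(lo, v))
    data.frame(
      vessel = seq_len(nv),
      x0 = clamp(cx - len / 2 * cos(theta), margin, w_um - margin),
      y0 = clamp(cy - len / 2 * sin(theta), margin, h_um - margin),
      x1 = clamp(cx + len / 2 * cos(theta), margin, w_um - margin),
      y1 = clamp(cy + len / 2 * sin(theta), margin, h_um - margin),
      radius_um = r
    )
  } else {
    data.frame(vessel = integer(), x0 = numeric(), y0 = numeric(),
               x1 = numeric(), y1 = numeric(), radius_um = numeric())
  }

  signed_dist <- function(px, py) {
    if (nrow(vessels) == 0)
      return(list(dist = rep(Inf, length(px)),
                  nearest = rep(NA_integer_, length(px))))
    nearest_vessel_distance(px, py, vessels)
  }

  # --- CD163-like cells: inhomogeneous Poisson via thinning
  lambda_max <- config$cd163_rate_at_wall + config$cd163_background_rate
  cd163 <- NULL
  if (lambda_max > 0) {
    n_cand <- stats::rpois(1, lambda_max * area_mm2)
    if (n_cand > 0) {
      px <- stats::runif(n_cand, 0, w_um)
      py <- stats::runif(n_cand, 0, h_um)
      sd0 <- signed_dist(px, py)
      d <- pmax(0, sd0$dist)
      lam <- config$cd163_rate_at_wall *
        exp(-d / config$cd163_decay_length_um) + config$cd163_background_rate
      keep <- stats::runif(n_cand) < lam / lambda_max & sd0$dist > 0
      cd163 <- data.frame(x_um = px[keep], y_um = py[keep])
    }
  }
  if (is.null(cd163)) cd163 <- data.frame(x_um = numeric(), y_um = numeric())

  # --- Iba1-like microglia: homogeneous Poisson
  n_iba <- stats::rpois(1, config$iba1_rate * area_mm2)
  iba1 <- if (n_iba > 0) {
    px <- stats::runif(n_iba, 0, w_um)
    py <- stats::runif(n_iba, 0, h_um)
    keep <- signed_dist(px, py)$dist > 0
    data.frame(x_um = px[keep], y_um = py[keep])
  } else data.frame(x_um = numeric(), y_um = numeric())

  # --- plaques and periplaque cells
  np <- config$n_plaques
  plaques <- if (np > 0) {
    pr <- stats::runif(np, config$plaque_radius_um[1],
                       config$plaque_radius_um[2])
    margin <- pr + config$periplaque_band_um
    data.frame(plaque = seq_len(np),
               x_um = stats::runif(np, margin, w_um - margin),
               y_um = stats::runif(np, margin, h_um - margin),
               radius_um = pr)
  } else {
    data.frame(plaque = integer(), x_um = numeric(), y_um = numeric(),
               radius_um = numeric())
  }
  peri <- list()
  for (p in seq_len(np)) {
    m <- stats::rpois(1, config$periplaque_cells_mean)
    if (m == 0) next
    ang <- stats::runif(m, 0, 2 * pi)
    rad <- plaques$radius_um[p] + stats::runif(m, 0, config$periplaque_band_um)
    phen <- sample(names(config$phenotype_mixture), m, replace = TRUE,
                   prob = config$phenotype_mixture)
    peri[[length(peri) + 1]] <- data.frame(
      x_um = pmin(w_um, pmax(0, plaques$x_um[p] + rad * cos(ang))),
      y_um = pmin(h_um, pmax(0, plaques$y_um[p] + rad * sin(ang))),
      phenotype = phen, plaque = p, stringsAsFactors = FALSE)
  }
  peri <- if (length(peri)) do.call(rbind, peri) else
    data.frame(x_um = numeric(), y_um = numeric(),
               phenotype = character(), plaque = integer())

  cells <- rbind(
    if (nrow(cd163)) data.frame(cd163, phenotype = "infiltrate",
                                plaque = NA_integer_,
                                compartment = "parenchyma") else NULL,
    if (nrow(iba1)) data.frame(iba1, phenotype = "microglia",
                               plaque = NA_integer_,
                               compartment = "parenchyma") else NULL,
    if (nrow(peri)) data.frame(peri[c("x_um", "y_um", "phenotype")],
                               plaque = peri$plaque,
                               compartment = "periplaque") else NULL
  )
  if (is.null(cells))
    cells <- data.frame(x_um = numeric(), y_um = numeric(),
                        phenotype = character(), plaque = integer(),
                        compartment = character())
  n_cells <- nrow(cells)
  cells$radius_um <- if (n_cells) stats::runif(n_cells,
                                               config$cell_radius_um[1],
                                               config$cell_radius_um[2])
                     else numeric()
  cells$markers <- vapply(cells$phenotype,
                          function(p) paste(marker_sets[[p]], collapse = ";"),
                          "")
  cells$dist_vessel_um <- if (n_cells && nrow(vessels))
    pmax(0, signed_dist(cells$x_um, cells$y_um)$dist) else
    rep(NA_real_, n_cells)

  # --- vessel mask on the pixel grid
  field <- if (nrow(vessels))
    vessel_distance_field(vessels, config$image_size_px, ppm) else
    list(dist_um = matrix(Inf, h_px, w_px),
         nearest = matrix(NA_integer_, h_px, w_px),
         vessel_mask = matrix(FALSE, h_px, w_px))

  # --- render channels: paint stain (exact), then add noise
  has_marker <- function(marker)
    vapply(strsplit(cells$markers, ";", fixed = TRUE),
           function(m) marker %in% m, TRUE)
  imgs <- list(); painted <- numeric()
  for (ch in channels) {
    img <- matrix(config$background_intensity, h_px, w_px)
    val <- config$stain_intensity[[ch]]
    if (ch == "OC") {
      for (p in seq_len(nrow(plaques)))
        img <- paint_disc(img, plaques$x_um[p] * ppm, plaques$y_um[p] * ppm,
                          plaques$radius_um[p] * ppm, val)
    } else {
      sel <- which(has_marker(ch))
      for (i in sel)
        img <- paint_disc(img, cells$x_um[i] * ppm, cells$y_um[i] * ppm,
                          cells$radius_um[i] * ppm, val)
    }
    painted[ch] <- mean(img != config$background_intensity)
    if (config$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, config$noise_sd)
    imgs[[ch]] <- matrix(as.integer(pmin(255, pmax(0, round(img)))),
                         h_px, w_px)
  }
  attr(imgs, "pixels_per_micron") <- ppm

  list(
    image = imgs,
    vessels = vessels,
    plaques = plaques,
    ground_truth = list(
      cells = cells,
      vessel_mask = field$vessel_mask,
      vessel_distance_um = field$dist_um,
      nearest_vessel = field$nearest,
      painted_fraction = painted
    )
  )
}
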