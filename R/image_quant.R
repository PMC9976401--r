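#' Spatial calibration from a scale bar
#'
#' @param span_microns Physical length of the scale bar, um (> 0).
#' @param span_pixels Pixel span of the same bar (> 0).
#' @return Object of class `image_calibration`: list with
#'   `pixels_per_micron`, converters `um_to_px()` / `px_to_um()`, and the
#'   `source` record. A 200 um bar spanning 117 px gives 0.585 px/um.
#' @export
calibrate <- function(span_microns, span_pixels) {
  if (span_microns <= 0 || span_pixels <= 0)
    stop("scale-bar spans must be > 0")
  f <- span_pixels / span_microns
  structure(
    list(pixels_per_micron = f,
         um_to_px = function(um) um * f,
         px_to_um = function(px) px / f,
         source = c(span_microns = span_microns, span_pixels = span_pixels)),
    class = "image_calibration"
  )
}

#' @export
print.image_calibration <- function(x, ...) {
  cat("image_calibration:", x$pixels_per_micron, "pixels/um (",
      x$source[["span_microns"]], "um =", x$source[["span_pixels"]], "px)\n")
  invisible(x)
}

#' Threshold specification for dark-on-bright staining
#'
#' DAB reaction product is dark, so stained pixels are those at or below
#' the intensity cut. Manual per-image threshold picking within a fixed
#' range is replaced by a deterministic cut, defaulting to the range
#' midpoint (175 for the usual 170--180 range; 155 for the 150--160 OC
#' range).
#'
#' @param channel Marker name.
#' @param range Length-2 intensity range (0..255, low <= high) within
#'   which the cut may sit.
#' @param cut Intensity cut; defaults to the range midpoint.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(channel = "Cd163", range = c(170, 180),
                           cut = mean(range)) {
  if (length(range) != 2 || range[1] > range[2] ||
      range[1] < 0 || range[2] > 255)
    stop("`range` must satisfy 0 <= low <= high <= 255")
  if (cut < range[1] || cut > range[2])
    stop("`cut` must lie within `range`")
  structure(list(channel = channel, range = range, cut = cut,
                 polarity = "stained_below"),
            class = "threshold_spec")
}

#' Binarize an 8-bit image
#'
#' Labels a pixel as stained iff its intensity is at or below the
#' threshold cut; pixels outside the reference mask are never labeled.
#'
#' @param image Numeric/integer matrix of 8-bit intensities.
#' @param spec A [threshold_spec()], or a numeric cut.
#' @param reference_mask Optional logical matrix restricting the analysis
#'   region (must be non-empty if supplied).
#' @return Logical matrix.
#' @export
binarize <- function(image, spec = threshold_spec(), reference_mask = NULL) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  cut <- if (inherits(spec, "threshold_spec")) spec$cut else as.numeric(spec)
  mask <- image <= cut
  if (!is.null(reference_mask)) {
    if (!identical(dim(reference_mask), dim(image)))
      stop("reference mask dimensions differ from image")
    if (!any(reference_mask)) stop("reference mask is empty")
    mask <- mask & reference_mask
  }
  mask
}

#' Percent-area loading
#'
#' Loading = 100 x (labeled pixels within the reference area) / (reference
#' area pixels), computed with exact integer counts.
#'
#' @param mask Logical matrix of labeled (stained) pixels.
#' @param reference_mask Logical matrix of the analysed region; defaults
#'   to the whole image.
#' @return Object of class `loading_result`: list with `labeled_area`,
#'   `reference_area` (pixel counts) and `loading` (percent).
#' @export
compute_loading <- function(mask, reference_mask = NULL) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mask <- mask > 0
  if (is.null(reference_mask)) {
    reference_mask <- matrix(TRUE, nrow(mask), ncol(mask))
  } else {
    if (!identical(dim(reference_mask), dim(mask)))
      stop("reference mask dimensions differ from mask")
    reference_mask <- reference_mask > 0
  }
  ref <- sum(reference_mask)
  if (ref == 0) stop("reference area is zero")
  lab <- sum(mask & reference_mask)
  structure(list(labeled_area = lab, reference_area = ref,
                 loading = 100 * lab / ref),
            class = "loading_result")
}

#' @export
print.loading_result <- function(x, ...) {
  cat(sprintf("loading: %.4f%% (%d / %d px)\n",
              x$loading, x$labeled_area, x$reference_area))
  invisible(x)
}

#' Aggregate loadings across images of one individual
#'
#' A single burden per individual is the ratio of summed labeled areas to
#' summed reference areas over all of that individual's images --- not the
#' mean of per-image percentages, which would weight small fields equally
#' with large ones.
#'
#' @param loadings List of `loading_result` objects.
#' @return A single `loading_result`.
#' @export
aggregate_loading <- function(loadings) {
  stopifnot(length(loadings) > 0,
            all(vapply(loadings, inherits, TRUE, "loading_result")))
  lab <- sum(vapply(loadings, `[[`, 0, "labeled_area"))
  ref <- sum(vapply(loadings, `[[`, 0, "reference_area"))
  structure(list(labeled_area = lab, reference_area = ref,
                 loading = 100 * lab / ref),
            class = "loading_result")
}

#' Concentric distance rings around a vessel mask
#'
#' Euclidean distance transform from the vessel mask; ring k collects the
#' pixels with (k-1) w < d <= k w um from the vessel boundary (w = ring
#' width, default 85 um, three rings reaching 255 um), clipped to the
#' image bounds, vessel pixels excluded. Rings are pairwise disjoint and
#' partition the d <= n w disk minus the vessel; pixels at an exact ring
#' radius belong to the inner ring.
#'
#' @param vessel_mask Logical matrix (non-empty).
#' @param cal An [calibrate()] object (or a pixels-per-micron scalar).
#' @param ring_width_um Ring width, um (default 85).
#' @param n_rings Number of rings (default 3).
#' @return List of `n_rings` logical matrices.
#' @export
vessel_distance_rings <- function(vessel_mask, cal, ring_width_um = 85,
                                  n_rings = 3L) {
  if (!is.matrix(vessel_mask)) stop("`vessel_mask` must be a matrix")
  vessel_mask <- vessel_mask > 0
  if (!any(vessel_mask)) stop("vessel mask is empty")
  ppm <- if (inherits(cal, "image_calibration")) cal$pixels_per_micron
         else as.numeric(cal)
  d_px <- EBImage::distmap(matrix(as.numeric(!vessel_mask),
                                  nrow(vessel_mask), ncol(vessel_mask)))
  d_um <- as.matrix(d_px) / ppm
  rings <- lapply(seq_len(n_rings), function(k) {
    d_um > (k - 1) * ring_width_um & d_um <= k * ring_width_um &
      !vessel_mask
  })
  if (all(!vapply(rings, any, TRUE)))
    stop("all rings are empty: vessel mask leaves no surrounding pixels")
  names(rings) <- paste0("ring", seq_len(n_rings))
  rings
}

#' Per-ring stain loadings around a vessel
#'
#' @param stain_mask Logical matrix of stained pixels.
#' @param rings Ring masks from [vessel_distance_rings()].
#' @return data.frame with one row per ring: `ring`, `labeled_px`,
#'   `ring_px`, `loading` (percent; `NA` for an empty ring).
#' @export
halo_loadings <- function(stain_mask, rings) {
  stopifnot(is.list(rings), length(rings) >= 1)
  out <- lapply(seq_along(rings), function(k) {
    r <- rings[[k]]
    n <- sum(r)
    data.frame(ring = k, labeled_px = sum(stain_mask & r), ring_px = n,
               loading = if (n == 0) NA_real_ else
                 100 * sum(stain_mask & r) / n)
  })
  do.call(rbind, out)
}

#' Per-vessel halo loading table
#'
#' Tabulates, for every vessel and every concentric ring, the stained and
#' total pixel counts and the percent loading, using a nearest-vessel
#' distance field so that overlapping halos from neighbouring vessels are
#' assigned to the closer vessel. The resulting vessel x ring matrix is
#' the matched-data input of the Friedman gradient test.
#'
#' @param stain_mask Logical matrix of stained pixels.
#' @param field A distance field from [vessel_distance_field()].
#' @param ring_width_um Ring width, um.
#' @param n_rings Number of rings.
#' @return List: `table` (data.frame vessel_id, ring, labeled_px, ring_px,
#'   loading_pct), `loading_matrix` (vessels x rings, NA for empty rings).
#' @export
halo_table <- function(stain_mask, field, ring_width_um = 85, n_rings = 3L) {
  d <- field$dist_um; nearest <- field$nearest
  if (!identical(dim(stain_mask), dim(d)))
    stop("stain mask dimensions differ from distance field")
  ring <- ceiling(d / ring_width_um)
  sel <- which(d > 0 & ring <= n_rings & !is.na(nearest))
  vid <- nearest[sel]; rid <- ring[sel]; st <- stain_mask[sel]
  vlev <- sort(unique(as.vector(nearest[!is.na(nearest)])))
  key <- factor(paste(vid, rid, sep = ":"),
                levels = as.vector(outer(vlev, seq_len(n_rings),
                                         paste, sep = ":")))
  tot <- table(key)
  lab <- table(key[st])
  tab <- data.frame(
    vessel_id = rep(vlev, times = n_rings),
    ring = rep(seq_len(n_rings), each = length(vlev)),
    labeled_px = as.integer(lab[levels(key)]),
    ring_px = as.integer(tot[levels(key)])
  )
  tab$labeled_px[is.na(tab$labeled_px)] <- 0L
  tab$ring_px[is.na(tab$ring_px)] <- 0L
  tab$loading_pct <- ifelse(tab$ring_px > 0,
                            100 * tab$labeled_px / tab$ring_px, NA_real_)
  m <- matrix(NA_real_, length(vlev), n_rings,
              dimnames = list(paste0("vessel", vlev),
                              paste0("ring", seq_len(n_rings))))
  m[cbind(match(tab$vessel_id, vlev), tab$ring)] <- tab$loading_pct
  list(table = tab, loading_matrix = m)
}

#' Vessel-proximal vs distal stain loading
#'
#' Splits the reference area into a vessel-proximal region and its
#' complement and computes the stain loading in each, the "vessel+" vs
#' "vessel-" comparison of perivascular enrichment.
#'
#' @param stain_mask Logical matrix of stained pixels.
#' @param vessel_proximal_mask Logical matrix of the vessel-proximal
#'   region (a strict, non-empty subset of the reference area).
#' @param reference_mask Optional reference area (default: whole image).
#' @return List with `loading_vessel_plus` and `loading_vessel_minus`
#'   (`loading_result` objects).
#' @export
vessel_enrichment <- function(stain_mask, vessel_proximal_mask,
                              reference_mask = NULL) {
  if (is.null(reference_mask))
    reference_mask <- matrix(TRUE, nrow(stain_mask), ncol(stain_mask))
  prox <- vessel_proximal_mask & reference_mask
  dist <- !vessel_proximal_mask & reference_mask
  if (!any(prox) || !any(dist))
    stop("degenerate partition: both regions must be non-empty")
  list(loading_vessel_plus = compute_loading(stain_mask, prox),
       loading_vessel_minus = compute_loading(stain_mask, dist))
}

#' Count periplaque myeloid phenotypes
#'
#' Tallies DAPI-positive cells lying within `radius_um` of a plaque
#' boundary (closed boundary: a cell exactly at the radius counts) into
#' the phenotype classes Iba1+/Trem2+/Cd163- ("microglia"),
#' Iba1+/Trem2+/Cd163+ ("microglia_like"), Cd163+/Iba1-/Trem2-
#' ("infiltrate"), and "other". A plaque is Cd163-infiltrated iff at
#' least one Cd163+ cell lies within the radius.
#'
#' @param cells data.frame with `x_um`, `y_um` and `markers`
#'   (semicolon-joined marker names including DAPI status), as produced
#'   by [simulate_staining_image()].
#' @param plaques data.frame with `plaque`, `x_um`, `y_um`, `radius_um`.
#' @param radius_um Counting radius from the plaque boundary (default 50).
#' @return List: `counts` (data.frame plaque x phenotype counts, totals,
#'   `cd163_infiltrated` flag), `proportions` (matrix, NA rows flagged for
#'   plaques with zero periplaque cells).
#' @export
count_periplaque_phenotypes <- function(cells, plaques, radius_um = 50) {
  cells <- as.data.frame(cells)
  plaques <- as.data.frame(plaques)
  classes <- c("microglia", "microglia_like", "infiltrate", "other")
  msets <- strsplit(cells$markers, ";", fixed = TRUE)
  has <- function(marker) vapply(msets, function(m) marker %in% m, TRUE)
  dapi <- has("DAPI"); iba <- has("Iba1"); trem <- has("Trem2")
  cd <- has("Cd163")
  phen <- ifelse(iba & trem & !cd, "microglia",
          ifelse(iba & trem & cd, "microglia_like",
          ifelse(cd & !iba & !trem, "infiltrate", "other")))

  counts <- matrix(0L, nrow(plaques), length(classes),
                   dimnames = list(plaques$plaque, classes))
  infiltrated <- logical(nrow(plaques))
  for (p in seq_len(nrow(plaques))) {
    d <- sqrt((cells$x_um - plaques$x_um[p])^2 +
              (cells$y_um - plaques$y_um[p])^2) - plaques$radius_um[p]
    near <- d <= radius_um & dapi
    if (any(near)) {
      t <- table(factor(phen[near], levels = classes))
      counts[p, ] <- as.integer(t)
    }
    infiltrated[p] <- any(d <= radius_um & cd)
  }
  totals <- rowSums(counts)
  props <- counts / ifelse(totals == 0, NA_real_, totals)
  if (any(totals == 0))
    message(sum(totals == 0),
            " plaque(s) with zero periplaque cells: proportions undefined")
  list(
    counts = data.frame(plaque = plaques$plaque, counts,
                        total = totals, cd163_infiltrated = infiltrated),
    proportions = props
  )
}
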