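test_that("calibration from a scale bar", {
  cal <- calibrate(200, 117)
  expect_identical(cal$pixels_per_micron, 0.585)
  expect_equal(calibrate(1, 1)$pixels_per_micron, 1)
  expect_equal(calibrate(100, 58.5)$pixels_per_micron, 0.585)
  expect_equal(cal$um_to_px(200), 117)
  expect_equal(cal$px_to_um(117), 200)
  expect_error(calibrate(0, 10), "> 0")
})

test_that("binarize labels dark pixels only, within the reference mask", {
  img <- matrix(255L, 10, 10)
  expect_false(any(binarize(img, threshold_spec())))
  expect_true(all(binarize(matrix(0L, 10, 10), threshold_spec())))
  img[3, 3] <- 100L
  ref <- matrix(TRUE, 10, 10); ref[3, 3] <- FALSE
  expect_false(any(binarize(img, threshold_spec(), ref)))
  expect_error(binarize(img, threshold_spec(), matrix(FALSE, 10, 10)),
               "empty")
  expect_error(threshold_spec(range = c(180, 170)), "low <= high")
  expect_error(threshold_spec(range = c(170, 180), cut = 200), "within")
})

test_that("loading is an exact pixel-count percentage", {
  mask <- matrix(FALSE, 100, 100)
  mask[seq_len(250)] <- TRUE
  l <- compute_loading(mask)
  expect_equal(l$loading, 2.5)
  expect_equal(l$labeled_area, 250L)
  full <- compute_loading(mask, mask)      # mask == reference -> 100%
  expect_equal(full$loading, 100)
  expect_error(compute_loading(mask, matrix(FALSE, 100, 100)), "zero")
})

test_that("aggregation across images follows the summed-counts formula", {
  # two fields of unequal area: 10/100 px and 90/900 px labeled
  l1 <- compute_loading(matrix(c(rep(TRUE, 10), rep(FALSE, 90)), 10, 10))
  m2 <- matrix(FALSE, 30, 30); m2[seq_len(90)] <- TRUE
  l2 <- compute_loading(m2)
  agg <- aggregate_loading(list(l1, l2))
  expect_equal(agg$loading, 100 * (10 + 90) / (100 + 900))  # 10%
  # mean of percentages would also be 10 here; make them differ
  m3 <- matrix(FALSE, 10, 10); m3[seq_len(50)] <- TRUE      # 50% of 100 px
  agg2 <- aggregate_loading(list(compute_loading(m3), l2))
  expect_equal(agg2$loading, 100 * (50 + 90) / (100 + 900))
  expect_false(isTRUE(all.equal(agg2$loading, mean(c(50, 10)))))
})

test_that("loading is invariant under translation and rotation", {
  set.seed(30)
  mask <- matrix(runif(400) < 0.2, 20, 20)
  ref <- matrix(runif(400) < 0.8, 20, 20)
  base <- compute_loading(mask, ref)$loading
  rot <- function(m) t(m)[, nrow(m):1]                    # 90 degrees
  expect_equal(compute_loading(rot(mask), rot(ref))$loading, base)
  big_m <- matrix(FALSE, 25, 25); big_m[3:22, 4:23] <- mask
  big_r <- matrix(FALSE, 25, 25); big_r[3:22, 4:23] <- ref
  expect_equal(compute_loading(big_m, big_r)$loading, base)
})

test_that("lowering the threshold cut never increases the loading", {
  set.seed(31)
  img <- matrix(sample.int(256, 2500, replace = TRUE) - 1L, 50, 50)
  cuts <- c(180, 175, 170, 150, 100)
  loads <- vapply(cuts, function(ct)
    compute_loading(binarize(img, ct))$loading, 0)
  expect_true(all(diff(loads) <= 0))
})

test_that("rings around a point vessel match analytic annulus areas", {
  vm <- matrix(FALSE, 701, 701); vm[351, 351] <- TRUE
  cal <- calibrate(1, 1)                                   # 1 px = 1 um
  rings <- vessel_distance_rings(vm, cal, ring_width_um = 85, n_rings = 3)
  for (k in 1:3) {
    analytic <- pi * ((85 * k)^2 - (85 * (k - 1))^2)
    expect_lt(abs(sum(rings[[k]]) - analytic) / analytic, 0.02)
  }
  # disjoint and collectively exhaustive of d <= 255 minus the vessel
  overlap <- rings[[1]] & rings[[2]] | rings[[1]] & rings[[3]] |
    rings[[2]] & rings[[3]]
  expect_false(any(overlap))
  d <- sqrt(outer((1:701 - 351)^2, (1:701 - 351)^2, "+"))
  inside <- d <= 255 & !vm
  expect_equal(sum(rings[[1]] | rings[[2]] | rings[[3]]), sum(inside))
})

test_that("ring partition accounts for every pixel exactly", {
  set.seed(33)
  vm <- matrix(FALSE, 120, 160); vm[40:50, 60:100] <- TRUE
  rings <- vessel_distance_rings(vm, calibrate(1, 1), ring_width_um = 20,
                                 n_rings = 3)
  counted <- Reduce(`+`, lapply(rings, sum)) + sum(vm)
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(!vm), 120, 160)))
  expect_equal(counted + sum(d > 60), 120 * 160)
})

test_that("vessel near the image edge yields clipped ring areas", {
  vm <- matrix(FALSE, 100, 100); vm[50, 3] <- TRUE
  rings <- vessel_distance_rings(vm, calibrate(1, 1), ring_width_um = 30,
                                 n_rings = 2)
  # clipping: ring 1 area is below the full annulus area
  expect_lt(sum(rings[[1]]), pi * 30^2)
  h <- halo_loadings(matrix(FALSE, 100, 100), rings)
  expect_equal(h$ring_px, unname(vapply(rings, sum, 0L)))
})

test_that("halo loadings localize stain to the correct ring", {
  vm <- matrix(FALSE, 301, 301); vm[151, 151] <- TRUE
  rings <- vessel_distance_rings(vm, calibrate(1, 1), ring_width_um = 40,
                                 n_rings = 3)
  stain <- matrix(FALSE, 301, 301)
  stain[rings[[1]]] <- TRUE                   # all stain inside ring 1
  h <- halo_loadings(stain, rings)
  expect_equal(h$loading, c(100, 0, 0))
  # empty ring -> missing loading
  h2 <- halo_loadings(stain, c(rings, list(matrix(FALSE, 301, 301))))
  expect_true(is.na(h2$loading[4]))
})

test_that("uniform random stain shows no ring trend", {
  set.seed(34)
  vm <- matrix(FALSE, 200, 200); vm[90:110, 95:105] <- TRUE
  rings <- vessel_distance_rings(vm, calibrate(1, 1), ring_width_um = 25,
                                 n_rings = 3)
  p <- 0.1
  loads <- replicate(30, {
    stain <- matrix(runif(4e4) < p, 200, 200)
    halo_loadings(stain, rings)$loading
  })
  expect_lt(max(abs(rowMeans(loads) - 100 * p)), 1.5)
})

test_that("vessel enrichment splits loadings by proximity", {
  stain <- matrix(FALSE, 50, 50); stain[1:10, 1:10] <- TRUE
  prox <- matrix(FALSE, 50, 50); prox[1:20, 1:20] <- TRUE
  enr <- vessel_enrichment(stain, prox)
  expect_equal(enr$loading_vessel_plus$loading, 100 * 100 / 400)
  expect_equal(enr$loading_vessel_minus$loading, 0)
  expect_error(vessel_enrichment(stain, matrix(TRUE, 50, 50)),
               "degenerate")
})

test_that("periplaque counting gates on DAPI and uses a closed boundary", {
  plaques <- data.frame(plaque = 1, x_um = 100, y_um = 100, radius_um = 20)
  cells <- data.frame(
    x_um = c(100, 100, 100, 100 + 20 + 50, 100 + 20 + 50.001),
    y_um = c(125, 130, 135, 100, 100),
    markers = c("Iba1;Trem2;Tmem119;DAPI",          # microglia
                "Iba1;Trem2;Tmem119;DAPI;Cd163",    # microglia-like
                "Cd163",                            # DAPI-negative
                "Cd163;DAPI",                       # exactly on boundary
                "Cd163;DAPI"))                      # just outside
  out <- count_periplaque_phenotypes(cells, plaques, radius_um = 50)
  counts <- out$counts
  expect_equal(counts$microglia, 1)
  expect_equal(counts$microglia_like, 1)
  expect_equal(counts$infiltrate, 1)       # the boundary cell counts
  expect_equal(counts$total, 3)            # DAPI-negative cell excluded
  expect_true(counts$cd163_infiltrated)
  # no DAPI-positive cells at all -> zero counts, undefined proportions
  nod <- cells[3, , drop = FALSE]
  out0 <- suppressMessages(
    count_periplaque_phenotypes(nod, plaques, radius_um = 50))
  expect_equal(out0$counts$total, 0)
  expect_true(all(is.na(out0$proportions)))
})

test_that("planted phenotype mixture is recovered across many plaques", {
  cfg <- scene_config(image_size_px = c(1500, 1200), n_vessels = 0,
                      cd163_rate_at_wall = 0, cd163_background_rate = 0,
                      iba1_rate = 0, n_plaques = 60,
                      periplaque_cells_mean = 10, noise_sd = 0, seed = 21)
  scn <- simulate_staining_image(cfg, channels = "OC")
  out <- count_periplaque_phenotypes(scn$ground_truth$cells, scn$plaques,
                                     radius_um = cfg$periplaque_band_um)
  tot <- colSums(out$counts[c("microglia", "microglia_like", "infiltrate",
                              "other")])
  props <- tot / sum(tot)
  expect_lt(abs(props[["microglia"]] - 0.60), 0.05)
  expect_lt(abs(props[["microglia_like"]] - 0.25), 0.05)
  expect_lt(abs(props[["infiltrate"]] - 0.15), 0.05)
})
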