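# build a minimal az_mask by hand for arithmetic tests
manual_az <- function(labels, pixel_nm = 10) {
  nlab <- max(labels)
  tab <- data.frame(az_id = seq_len(nlab),
                    area_px = tabulate(labels[labels > 0], nlab))
  tab$area_nm2 <- tab$area_px * pixel_nm^2
  tab$x_nm <- tab$y_nm <- NA_real_
  structure(list(labels = labels, table = tab, pixel_nm = pixel_nm),
            class = "az_mask")
}

disk_image <- function(n, centers, r_px, value = 100, bg = 0) {
  img <- matrix(bg, n, n)
  for (k in seq_len(nrow(centers))) {
    dx <- outer((seq_len(n) - 1) - centers[k, 1], rep(1, n))
    dy <- outer(rep(1, n), (seq_len(n) - 1) - centers[k, 2])
    img[dx^2 + dy^2 <= r_px^2] <- value
  }
  img
}

test_that("unsharp binarization finds well-separated disks exactly", {
  set.seed(1)
  centers <- as.matrix(expand.grid(c(50, 120, 190, 260, 330),
                                   c(60, 200))[1:10, ])
  img <- disk_image(384, centers, r_px = 8, value = 100, bg = 2)
  mask <- unsharp_binarize(img, sigma_px = 5, min_area_nm2 = 2000)
  lab <- azphys:::.label8(mask)
  expect_equal(max(lab), 10)
  # scale invariance of the mask
  mask2 <- unsharp_binarize(img * 7.3, sigma_px = 5, min_area_nm2 = 2000)
  expect_identical(mask2[, ], mask[, ])
})

test_that("constant images give an empty flagged mask", {
  m <- unsharp_binarize(matrix(0, 64, 64))
  expect_false(any(m))
  expect_true(attr(m, "flat"))
  m2 <- unsharp_binarize(matrix(7, 64, 64))
  expect_false(any(m2))
})

test_that("labeling merges diagonal neighbors (8-connectivity)", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE
  m[8, 8] <- TRUE
  lab <- azphys:::.label8(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
})

test_that("a rendered disk's mask area matches its geometric area", {
  img <- disk_image(256, matrix(c(128, 128), 1), r_px = 10,
                    value = 100, bg = 1)
  imgset <- sted_image_set(img, img, img, img, pixel_nm = 10)
  az <- make_az_masks(imgset, close_nm = 0, az_dilate_nm = 0)
  expect_equal(nrow(az$table), 1)
  # pi * 100^2 nm^2 within a one-pixel perimeter band
  perim <- 2 * pi * 100 * 10  # nm^2 per pixel ring
  expect_lt(abs(az$table$area_nm2 - pi * 100^2), perim)
})

test_that("AZ masks recover the number of rendered active zones", {
  fld <- shared_field()
  az <- make_az_masks(fld)
  expect_lt(abs(nrow(az$table) - nrow(fld$ground_truth$azs)), 3)
})

test_that("gating excludes small-terminal AZs and PSD-negative AZs", {
  fld <- shared_field()
  gt <- fld$ground_truth
  az <- gate_azs(make_az_masks(fld), fld)
  tab <- az$table
  # match detected AZs to ground truth by nearest center
  near_small <- vapply(seq_len(nrow(tab)), function(i) {
    d <- sqrt((gt$azs$x_nm - tab$x_nm[i])^2 + (gt$azs$y_nm - tab$y_nm[i])^2)
    gt$azs$small[which.min(d)]
  }, TRUE)
  expect_true(all(!tab$gated[near_small]))
  expect_true(all(tab$gated[!near_small]))
  # remove PSD-95 signal entirely -> nothing passes the PSD gate
  fld2 <- fld
  fld2$images$psd95 <- matrix(0, nrow(fld$images$psd95),
                              ncol(fld$images$psd95))
  az2 <- gate_azs(make_az_masks(fld2), fld2)
  expect_false(any(az2$table$psd95_pos))
  # gating is idempotent
  az3 <- gate_azs(az, fld)
  expect_identical(az3$table$gated, az$table$gated)
})

test_that("background is the median of the non-AZ area", {
  labels <- matrix(0L, 128, 128)
  labels[30:40, 30:40] <- 1L
  az <- manual_az(labels)
  img <- matrix(10, 128, 128)
  img[labels == 1] <- 500
  expect_equal(as.numeric(estimate_background(img, az)), 10)
  # all-AZ image errors
  az_all <- manual_az(matrix(1L, 32, 32))
  expect_error(estimate_background(matrix(1, 32, 32), az_all),
               "insufficient")
})

test_that("intensity integration subtracts background and clamps at zero", {
  labels <- matrix(0L, 64, 64)
  labels[11:20, 11:30] <- 1L  # 200 px
  labels[40:44, 40:44] <- 2L  # 25 px
  az <- manual_az(labels)
  img <- matrix(10, 64, 64)
  img[labels == 1] <- 100
  ints <- integrate_az_intensity(img, az, background = 10)
  expect_equal(unname(ints["1"]), (100 - 10) * 200)  # 18000
  expect_equal(unname(ints["2"]), 0)
  # AZ dimmer than background clamps to zero with a flag
  img[labels == 2] <- 5
  ints2 <- integrate_az_intensity(img, az, background = 10)
  expect_equal(unname(ints2["2"]), 0)
  expect_true(attr(ints2, "clamped")[2])
})

test_that("Richardson-Lucy conserves mass and restores resolution", {
  n <- 96
  img0 <- matrix(0, n, n)
  # two points 80 nm apart (8 px at 10 nm), blurred by sigma = 40 nm
  img0[44, 48] <- 1000
  img0[52, 48] <- 1000
  blur <- azphys:::.gauss_blur(img0, 4) + 1
  dec <- deconvolve_sted(blur, kernel_sigma_nm = 40, pixel_nm = 10,
                         iterations = 20)
  expect_lt(abs(sum(dec) - sum(blur)) / sum(blur), 0.01)
  # resolution restoration at the 2-sigma limit: the blurred pair is a
  # single blob for the cluster segmentation, but after deconvolution
  # (40 iterations to dig the saddle below the watershed tolerance)
  # the two spots separate
  az_all <- manual_az(matrix(1L, n, n))
  pre <- segment_clusters(blur, blur, az_all, min_area_nm2 = 500)
  expect_equal(nrow(pre), 1)
  dec40 <- deconvolve_sted(blur, 40, 10, iterations = 40)
  post <- segment_clusters(dec40, blur, az_all, min_area_nm2 = 500)
  expect_equal(nrow(post), 2)
  expect_error(deconvolve_sted(matrix(-1, 8, 8), 40, 10), "non-negative")
})

test_that("deconvolving the PSF itself concentrates its mass", {
  n <- 128
  delta <- matrix(0, n, n); delta[64, 64] <- 1e4
  psf_img <- azphys:::.gauss_blur(delta, 4) + 0.1
  dec <- deconvolve_sted(psf_img, kernel_sigma_nm = 40, pixel_nm = 10,
                         iterations = 20)
  # >= 90% of (signal) mass within 1 sigma (4 px) of the center
  dx <- outer(seq_len(n) - 64, rep(1, n))
  dy <- outer(rep(1, n), seq_len(n) - 64)
  core <- dx^2 + dy^2 <= 16
  expect_gt(sum(dec[core]) / 1e4, 0.9)
  # a delta-like input stays a single dominant peak at the same place
  dec2 <- deconvolve_sted(delta + 0.1, 40, 10, iterations = 5)
  expect_equal(which.max(dec2), which.max(delta))
})

test_that("two programmed clusters in a noise-free AZ are segmented as two", {
  scene <- small_scene(noise_model = "none")
  fld <- render_sted_field(scene, "WT", seed = 12)
  az <- make_az_masks(fld)
  dec <- deconvolve_sted(fld$images$cav + 1e-6, 40, 10, 20)
  cl <- segment_clusters(dec, fld$images$cav, az)
  gt <- fld$ground_truth
  # each segmented cluster is assigned to exactly one AZ id
  expect_true(all(table(cl$cluster_id) == 1))
  # pick ground-truth AZs with exactly 2 cav clusters >= 150 nm apart
  for (a in gt$azs$az_id) {
    cc <- gt$clusters[gt$clusters$az_id == a & gt$clusters$channel == "cav", ]
    if (nrow(cc) != 2) next
    if (sqrt(diff(cc$x_nm)^2 + diff(cc$y_nm)^2) < 150) next
    d <- sqrt((az$table$x_nm - gt$azs$x_nm[gt$azs$az_id == a])^2 +
                (az$table$y_nm - gt$azs$y_nm[gt$azs$az_id == a])^2)
    det_id <- az$table$az_id[which.min(d)]
    expect_equal(sum(cl$az_id == det_id), 2)
  }
})

test_that("cluster metrics are sane: ellipse axes ordered, centroids inside", {
  fld <- shared_field()
  az <- make_az_masks(fld)
  dec <- deconvolve_sted(fld$images$cav, 40, 10, 20)
  cl <- segment_clusters(dec, fld$images$cav, az)
  expect_true(all(cl$length_nm >= cl$width_nm))
  expect_true(all(cl$width_nm > 0))
  lim <- fld$pixel_nm * nrow(fld$images$cav)
  expect_true(all(cl$x_nm >= 0 & cl$x_nm <= lim))
})

test_that("nearest-neighbor distances follow plane geometry", {
  cav <- data.frame(cluster_id = 1, az_id = 1, x_nm = 0, y_nm = 0)
  munc <- data.frame(cluster_id = 1:2, az_id = 1,
                     x_nm = c(50, 120), y_nm = 0)
  nnd <- nearest_neighbor_distances(cav, munc)
  expect_equal(nnd$nnd_nm, 50)
  # coincident centroids give zero
  nnd0 <- nearest_neighbor_distances(cav,
    data.frame(cluster_id = 1, az_id = 1, x_nm = 0, y_nm = 0))
  expect_equal(nnd0$nnd_nm, 0)
  # AZs lacking a partner set are skipped and recorded
  cav2 <- rbind(cav, data.frame(cluster_id = 2, az_id = 2,
                                x_nm = 500, y_nm = 500))
  nnd2 <- nearest_neighbor_distances(cav2, munc)
  expect_equal(attr(nnd2, "skipped"), 2)
  # symmetric mode reports both directions
  nnds <- nearest_neighbor_distances(cav, munc, symmetric = TRUE)
  expect_setequal(unique(nnds$direction), c("cav_to_munc", "munc_to_cav"))
})

test_that("programmed cav-munc offset is recovered on sparse pair scenes", {
  nnds <- unlist(lapply(1:3, function(s) {
    scene <- image_scene_params(field_px = 512, n_terminals = 1,
                                n_small_terminals = 0,
                                az_per_terminal = 10,
                                cluster_mean_wt = 1.15)
    quantify_field(render_sted_field(scene, "WT", seed = s))$nnd$nnd_nm
  }))
  expect_gt(length(nnds), 20)
  expect_lt(abs(mean(nnds) - 61), 3)
})

test_that("per-animal aggregation averages correctly and builds a valid CDF", {
  rec <- data.frame(
    az_id = 1:6,
    animal_id = rep(c("a1", "a2"), each = 3),
    genotype = "WT",
    cav_intensity = c(10, 20, 30, 40, 50, 60),
    munc_intensity = 1:6,
    n_clusters = c(1, 2, 3, 2, 2, 2),
    mean_nnd_nm = c(50, 60, 70, 55, 65, 75),
    area_nm2 = rep(1000, 6))
  agg <- aggregate_per_animal(rec)
  pa <- agg$per_animal
  expect_equal(nrow(pa), 2)  # unit of analysis: animals, not AZs
  expect_equal(pa$cav_intensity[pa$animal_id == "a1"], 20)
  expect_equal(pa$cav_intensity[pa$animal_id == "a2"], 50)
  expect_equal(pa$n_az, c(3, 3))
  cdf <- agg$intensity_cdf
  expect_true(all(diff(cdf$cdf[cdf$genotype == "WT"]) >= 0))
  expect_equal(max(cdf$cdf), 1)
})

test_that("mask generation scales with pixel size in physical units", {
  img5 <- disk_image(256, matrix(c(128, 128), 1), r_px = 20,
                     value = 100, bg = 1)  # 100 nm disk at 5 nm/px
  imgset <- sted_image_set(img5, img5, img5, img5, pixel_nm = 5)
  az <- make_az_masks(imgset, close_nm = 0, az_dilate_nm = 0)
  expect_lt(abs(az$table$area_nm2 - pi * 100^2), 2 * pi * 100 * 5)
})
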