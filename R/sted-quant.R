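#' Four-channel registered image set
#'
#' Container for one imaging field: Munc13-1 (STED), Ca2+ channel
#' (STED; Cav2.1 or Cav2.2), VGLUT1 (confocal) and PSD-95 (confocal),
#' all sharing one pixel grid.
#'
#' @param munc13,cav,vglut1,psd95 Numeric matrices of equal dimensions.
#' @param pixel_nm Pixel size (nm), > 0.
#' @param field_id,animal_id,genotype Metadata strings.
#' @param cav_label Which channel the `cav` image holds
#'   (`"Cav2.1"` or `"Cav2.2"`).
#' @return An object of class `sted_image_set` (also usable wherever a
#'   rendered `sted_field` is accepted: both carry `$images` and
#'   `$pixel_nm`).
#' @export
sted_image_set <- function(munc13, cav, vglut1, psd95, pixel_nm,
                           field_id = "f1", animal_id = "a1",
                           genotype = "WT", cav_label = "Cav2.1") {
  dims <- lapply(list(munc13, cav, vglut1, psd95), dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all channels must have the same shape")
  if (pixel_nm <= 0) stop("pixel_nm must be > 0")
  structure(list(images = list(munc13 = munc13, cav = cav,
                               vglut1 = vglut1, psd95 = psd95),
                 pixel_nm = pixel_nm, field_id = field_id,
                 animal_id = animal_id, condition = genotype,
                 cav_label = cav_label),
            class = "sted_image_set")
}

# unsharp band-pass enhancement, min-max normalized to [0, 1]
.sharpen_norm <- function(img, sigma_px, amount, smooth_px) {
  base <- if (smooth_px > 0) .gauss_blur(img, smooth_px) else img
  sharp <- base + amount * (base - .gauss_blur(img, sigma_px))
  (sharp - min(sharp)) / diff(range(sharp))
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally via union-find over the label adjacency graph.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (p in seq_len(nrow(pairs))) {
    a <- find(pairs[p, 1]); b <- find(pairs[p, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, 0L)
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Unsharp-mask sharpening followed by Otsu binarization
#'
#' Sharpens the image as `base + amount * (base - gaussian(img, sigma))`
#' where `base` is the image smoothed with a small noise-suppression
#' Gaussian (`smooth_px`), i.e. a band-pass enhancement of blob-scale
#' structure. The sharpened image is thresholded with Otsu's method on
#' its min-max normalized intensities (hence invariant to positive
#' rescaling), guarded by a robust background floor
#' (`median + 4 * MAD`) so that sparse-foreground images cannot drive
#' the threshold into the background noise. Small gaps can be closed
#' morphologically and components below a minimum area are removed.
#'
#' @param img Numeric matrix (single channel).
#' @param sigma_px Gaussian sigma of the unsharp blur (pixels), > 0.
#' @param amount Unsharp gain (default 1).
#' @param min_area_nm2 Minimum component area kept (nm^2).
#' @param pixel_nm Pixel size (nm).
#' @param smooth_px Sigma of the noise-suppression smoothing (pixels);
#'   0 disables it.
#' @param close_nm Radius of a morphological closing applied to the
#'   binary mask before the size filter (nm); 0 (default) disables it.
#'   Used by AZ masking to bridge the punctate substructure of one AZ.
#' @return A logical matrix mask with attribute `flat` (TRUE for a
#'   constant image, in which case the mask is empty).
#' @export
unsharp_binarize <- function(img, sigma_px = 5, amount = 1,
                             min_area_nm2 = 2000, pixel_nm = 10,
                             smooth_px = 1.5, close_nm = 0) {
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  if (diff(range(img)) == 0) {
    m <- matrix(FALSE, nrow(img), ncol(img))
    attr(m, "flat") <- TRUE
    return(m)
  }
  norm <- .sharpen_norm(img, sigma_px, amount, smooth_px)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  thr <- max(thr, stats::median(norm) + 4 * stats::mad(norm))
  mask <- norm > thr
  if (close_nm > 0) {
    r_px <- max(1, round(close_nm / pixel_nm))
    brush <- EBImage::makeBrush(2 * r_px + 1, "disc")
    mask <- EBImage::closing(1 * mask, brush) > 0
  }
  min_px <- min_area_nm2 / pixel_nm^2
  if (min_px > 1) {
    lab <- .label8(mask)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0], max(lab))
      mask <- matrix(lab > 0 & areas[pmax(lab, 1)] >= min_px,
                     nrow(img), ncol(img))
    }
  }
  attr(mask, "flat") <- FALSE
  mask
}

#' Generate labeled active-zone masks from the Munc13-1 channel
#'
#' Runs [unsharp_binarize()] on the Munc13-1 STED image (with a
#' morphological closing so that the punctate Munc13-1 substructure of
#' one AZ becomes a single component), labels components with
#' 8-connectivity and reports per-label areas.
#'
#' @param imgset A `sted_image_set` or rendered `sted_field`.
#' @param sigma_px,amount,min_area_nm2 See [unsharp_binarize()].
#' @param close_nm Closing radius bridging intra-AZ puncta (nm).
#' @param az_dilate_nm Radius by which each labeled AZ is grown after
#'   labeling (nm); makes the mask cover the full AZ extent (PSF tails,
#'   channel clusters at the AZ edge) rather than only the brightest
#'   cores. Grown regions never overwrite another label.
#' @return A list of class `az_mask`: `labels` (integer matrix),
#'   `table` (data.frame `az_id`, `area_px`, `area_nm2`, `x_nm`, `y_nm`
#'   intensity-weighted centroids), `pixel_nm`.
#' @export
make_az_masks <- function(imgset, sigma_px = 5, amount = 1,
                          min_area_nm2 = 2000, close_nm = 60,
                          az_dilate_nm = 80) {
  px <- imgset$pixel_nm
  img <- imgset$images$munc13
  mask <- unsharp_binarize(img, sigma_px, amount, min_area_nm2, px,
                           close_nm = close_nm)
  labels <- .label8(mask)
  if (az_dilate_nm > 0 && max(labels) > 0) {
    r_px <- max(1, round(az_dilate_nm / px))
    brush <- EBImage::makeBrush(2 * r_px + 1, "disc")
    grown <- round(as.matrix(EBImage::dilate(labels, brush)))
    labels <- ifelse(labels > 0, labels, grown)
  }
  nlab <- max(labels)
  tab <- if (nlab > 0) {
    idx <- which(labels > 0)
    lab_v <- labels[idx]
    w <- img[idx]
    xs <- (row(labels)[idx] - 1) * px
    ys <- (col(labels)[idx] - 1) * px
    data.frame(
      az_id = seq_len(nlab),
      area_px = tabulate(lab_v, nlab),
      x_nm = as.numeric(tapply(w * xs, lab_v, sum) /
                          tapply(w, lab_v, sum)),
      y_nm = as.numeric(tapply(w * ys, lab_v, sum) /
                          tapply(w, lab_v, sum)))
  } else {
    data.frame(az_id = integer(), area_px = integer(),
               x_nm = numeric(), y_nm = numeric())
  }
  tab$area_nm2 <- tab$area_px * px^2
  structure(list(labels = labels, table = tab, pixel_nm = px),
            class = "az_mask")
}

#' Gate active zones by VGLUT1/PSD-95 colocalization and terminal size
#'
#' An AZ passes when (a) its centroid lies inside the VGLUT1-positive
#' mask dilated by `d_coloc_nm`, (b) a PSD-95-positive pixel lies within
#' `d_coloc_nm` of the AZ mask, and (c) the VGLUT1 component containing
#' it has area >= `terminal_min_area_um2` (this removes AZs of small
#' terminals, confining the analysis to large mossy-fiber boutons).
#' Boundary pixels belong to the masks (closed masks).
#'
#' @param az An [make_az_masks()] result.
#' @param imgset The image set it came from.
#' @param d_coloc_nm Colocalization tolerance (nm).
#' @param terminal_min_area_um2 Minimum VGLUT1 component area (um^2).
#' @param vglut_sigma_px,psd_sigma_px Unsharp sigmas for the confocal
#'   masks.
#' @return The `az_mask` with gating columns added to `table`:
#'   `vglut1_pos`, `psd95_pos`, `large_terminal`, `gated` (all three).
#' @export
gate_azs <- function(az, imgset, d_coloc_nm = 100,
                     terminal_min_area_um2 = 1.0,
                     vglut_sigma_px = 20, psd_sigma_px = 10) {
  px <- az$pixel_nm
  r_px <- max(1, round(d_coloc_nm / px))
  brush <- EBImage::makeBrush(2 * r_px + 1, "disc")
  vmask <- unsharp_binarize(imgset$images$vglut1, vglut_sigma_px,
                            min_area_nm2 = 1e4, pixel_nm = px)
  pmask <- unsharp_binarize(imgset$images$psd95, psd_sigma_px,
                            min_area_nm2 = 1e3, pixel_nm = px)
  vdil <- EBImage::dilate(1 * vmask, brush) > 0
  pdil <- EBImage::dilate(1 * pmask, brush) > 0
  # terminal components on the dilated mask; areas from the raw mask
  vlab <- .label8(vdil)
  varea <- if (max(vlab) > 0)
    vapply(seq_len(max(vlab)), function(l) sum(vmask[vlab == l]), 0)
  else numeric()
  tab <- az$table
  n <- nrow(tab)
  tab$vglut1_pos <- tab$psd95_pos <- tab$large_terminal <- FALSE
  for (a in seq_len(n)) {
    i <- pmin(pmax(round(tab$x_nm[a] / px) + 1, 1), nrow(vdil))
    j <- pmin(pmax(round(tab$y_nm[a] / px) + 1, 1), ncol(vdil))
    comp <- vlab[i, j]
    tab$vglut1_pos[a] <- comp > 0
    if (comp > 0)
      tab$large_terminal[a] <- varea[comp] * px^2 / 1e6 >=
        terminal_min_area_um2
    tab$psd95_pos[a] <- any(pdil[az$labels == tab$az_id[a]])
  }
  tab$gated <- tab$vglut1_pos & tab$psd95_pos & tab$large_terminal
  az$table <- tab
  az
}

#' Estimate per-pixel background from the non-AZ area
#'
#' Median intensity over pixels outside all AZ masks dilated by a guard
#' ring.
#'
#' @param img Channel image.
#' @param az An `az_mask`.
#' @param guard_nm Guard-ring dilation radius (nm).
#' @return Background (counts/pixel), with attribute `frac_outside`.
#' @export
estimate_background <- function(img, az, guard_nm = 100) {
  r_px <- max(1, round(guard_nm / az$pixel_nm))
  brush <- EBImage::makeBrush(2 * r_px + 1, "disc")
  outside <- !(EBImage::dilate(1 * (az$labels > 0), brush) > 0)
  frac <- mean(outside)
  if (frac < 0.1)
    stop("insufficient non-AZ area (", round(100 * frac), "% of field)")
  structure(stats::median(img[outside]), frac_outside = frac)
}

#' Background-subtracted intensity integral over an AZ mask
#'
#' `sum(pixel - background)` over the AZ mask; negative totals are
#' clamped to zero and flagged.
#'
#' @param img Channel image.
#' @param az An `az_mask`.
#' @param az_id AZ label(s); default all.
#' @param background Counts/pixel (from [estimate_background()]).
#' @return Named numeric vector of integrals (counts) with attribute
#'   `clamped` (logical vector).
#' @export
integrate_az_intensity <- function(img, az, az_id = NULL, background = 0) {
  if (is.null(az_id)) az_id <- az$table$az_id
  idx <- which(az$labels > 0)
  lab_v <- az$labels[idx]
  sums <- tapply(img[idx], lab_v, sum)
  npx <- tabulate(lab_v, max(az$labels))
  out <- vapply(az_id, function(l) {
    s <- sums[as.character(l)]
    if (is.na(s)) return(NA_real_)
    unname(s) - background * npx[l]
  }, 0)
  clamped <- !is.na(out) & out < 0
  out[clamped] <- 0
  names(out) <- az_id
  attr(out, "clamped") <- clamped
  out
}

#' Richardson-Lucy deconvolution with a Gaussian PSF
#'
#' Multiplicative RL iterations with a symmetric Gaussian kernel
#' (sigma = `kernel_sigma_nm`), FFT-based with circular boundary, which
#' keeps the output non-negative and conserves total intensity to well
#' under 1%.
#'
#' @param img Non-negative channel image with some signal.
#' @param kernel_sigma_nm Gaussian sigma (nm); the nominal "40 nm
#'   radius" convention of STED cluster analysis maps to sigma = 40 nm
#'   here (see the methods vignette for the alternative FWHM reading).
#' @param pixel_nm Pixel size (nm).
#' @param iterations RL iteration count (default 20).
#' @return Deconvolved image (same dimensions).
#' @export
deconvolve_sted <- function(img, kernel_sigma_nm = 40, pixel_nm = 10,
                            iterations = 20) {
  if (kernel_sigma_nm <= 0) stop("kernel_sigma_nm must be > 0")
  if (any(img < 0) || sum(img) <= 0)
    stop("image must be non-negative with positive total intensity")
  sigma_px <- kernel_sigma_nm / pixel_nm
  otf <- .gauss_otf(nrow(img), sigma_px)
  est <- img
  eps <- 1e-12
  for (it in seq_len(iterations)) {
    conv <- pmax(.fft_conv(est, otf), eps)
    est <- est * .fft_conv(img / conv, otf)  # symmetric kernel
    est[est < 0] <- 0
  }
  est
}

#' Segment Ca2+-channel (or Munc13-1) clusters and compute metrics
#'
#' Masks clusters on the (typically deconvolved) image by
#' [unsharp_binarize()], labels them with 8-connectivity, and measures
#' each cluster on the raw channel: intensity-weighted centroid,
#' integrated intensity, area, and equivalent-ellipse length/width from
#' second moments. A cluster belongs to an AZ iff its mask intersects
#' the AZ mask (ties broken by largest overlap; each cluster is counted
#' once).
#'
#' @param img Segmentation image (e.g. from [deconvolve_sted()]).
#' @param raw Photometry image (the original, non-deconvolved channel);
#'   defaults to `img`.
#' @param az An `az_mask` (gated or not).
#' @param sigma_px,amount Unsharp parameters (see [unsharp_binarize()]).
#' @param min_area_nm2 Minimum cluster area kept (nm^2).
#' @param smooth_px Noise-suppression smoothing for the cluster mask
#'   (pixels); default 0 because the deconvolved input is already
#'   regularized and extra blur merges close clusters.
#' @param thr_factor Multiplier on the Otsu threshold (default 0.4):
#'   the capture threshold is deliberately below the Otsu split so that
#'   dim clusters survive, with touching clusters separated afterwards
#'   by the watershed step. 1 with `ws_tolerance = 0` reproduces plain
#'   Otsu binarization + connected components.
#' @param ws_tolerance Watershed tolerance on the normalized (0-1)
#'   sharpened intensity used to split touching clusters; 0 disables
#'   splitting.
#' @return A data.frame of class `cluster_set`: `cluster_id`, `az_id`
#'   (0 when outside every AZ), `x_nm`, `y_nm`, `area_nm2`,
#'   `length_nm`, `width_nm`, `intensity`.
#' @export
segment_clusters <- function(img, raw = img, az, sigma_px = 3, amount = 1,
                             min_area_nm2 = 1500, smooth_px = 0,
                             thr_factor = 0.4, ws_tolerance = 0.05) {
  px <- az$pixel_nm
  if (diff(range(img)) == 0) {
    labels <- matrix(0L, nrow(img), ncol(img))
  } else {
    norm <- .sharpen_norm(img, sigma_px, amount, smooth_px)
    ot <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    thr <- max(thr_factor * ot,
               stats::median(norm) + 4 * stats::mad(norm))
    mask <- norm > thr
    labels <- if (ws_tolerance > 0) {
      h <- ifelse(mask, norm, 0)
      round(as.matrix(EBImage::watershed(EBImage::Image(h),
                                         tolerance = ws_tolerance,
                                         ext = 1)))
    } else {
      .label8(mask)
    }
    min_px <- min_area_nm2 / px^2
    areas <- tabulate(labels[labels > 0])
    drop <- which(areas < min_px)
    if (length(drop)) labels[labels %in% drop] <- 0L
    if (max(labels) > 0) {
      kept <- sort(unique(labels[labels > 0]))
      labels[labels > 0] <- match(labels[labels > 0], kept)
    }
  }
  nlab <- max(labels)
  if (nlab == 0) {
    out <- data.frame(cluster_id = integer(), az_id = integer(),
                      x_nm = numeric(), y_nm = numeric(),
                      area_nm2 = numeric(), length_nm = numeric(),
                      width_nm = numeric(), intensity = numeric())
    class(out) <- c("cluster_set", "data.frame")
    return(out)
  }
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  w <- pmax(raw[idx], 0)
  xs <- (row(labels)[idx] - 1) * px
  ys <- (col(labels)[idx] - 1) * px
  wsum <- tapply(w, lab_v, sum)
  cx <- tapply(w * xs, lab_v, sum) / wsum
  cy <- tapply(w * ys, lab_v, sum) / wsum
  # second central moments -> equivalent ellipse axes (full lengths)
  vx <- tapply(w * xs^2, lab_v, sum) / wsum - cx^2
  vy <- tapply(w * ys^2, lab_v, sum) / wsum - cy^2
  vxy <- tapply(w * xs * ys, lab_v, sum) / wsum - cx * cy
  tr <- vx + vy
  dt <- sqrt(pmax((vx - vy)^2 + 4 * vxy^2, 0))
  l1 <- pmax((tr + dt) / 2, 0)
  l2 <- pmax((tr - dt) / 2, 0)
  az_of <- vapply(seq_len(nlab), function(l) {
    ov <- az$labels[idx[lab_v == l]]
    ov <- ov[ov > 0]
    if (!length(ov)) return(0L)
    tt <- table(ov)
    as.integer(names(tt)[which.max(tt)])
  }, 0L)
  out <- data.frame(cluster_id = seq_len(nlab), az_id = az_of,
                    x_nm = as.numeric(cx), y_nm = as.numeric(cy),
                    area_nm2 = tabulate(lab_v, nlab) * px^2,
                    length_nm = as.numeric(4 * sqrt(l1)),
                    width_nm = as.numeric(4 * sqrt(l2)),
                    intensity = as.numeric(wsum))
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Nearest-neighbor distances between two cluster sets, per AZ
#'
#' For each Ca2+-channel cluster in an AZ, the Euclidean distance to
#' the nearest Munc13-1 cluster centroid of the same AZ. AZs lacking
#' clusters of either kind are skipped (recorded in the `skipped`
#' attribute). Set `symmetric = TRUE` to also compute the
#' Munc13-1-to-Cav direction.
#'
#' @param cav,munc `cluster_set` data.frames (see [segment_clusters()]).
#' @param symmetric Logical (default FALSE, Cav -> Munc13-1 only).
#' @return A data.frame `az_id`, `cluster_id`, `nnd_nm` (and
#'   `direction` when symmetric), with attribute `skipped`.
#' @export
nearest_neighbor_distances <- function(cav, munc, symmetric = FALSE) {
  one_way <- function(from, to) {
    shared <- intersect(unique(from$az_id[from$az_id > 0]),
                        unique(to$az_id[to$az_id > 0]))
    res <- lapply(shared, function(a) {
      f <- from[from$az_id == a, ]
      t2 <- to[to$az_id == a, ]
      d <- vapply(seq_len(nrow(f)), function(k)
        min(sqrt((t2$x_nm - f$x_nm[k])^2 + (t2$y_nm - f$y_nm[k])^2)), 0)
      data.frame(az_id = a, cluster_id = f$cluster_id, nnd_nm = d)
    })
    out <- if (length(res)) do.call(rbind, res) else
      data.frame(az_id = integer(), cluster_id = integer(),
                 nnd_nm = numeric())
    attr(out, "skipped") <- setdiff(unique(from$az_id[from$az_id > 0]),
                                    shared)
    out
  }
  fwd <- one_way(cav, munc)
  if (!symmetric) return(fwd)
  rev <- one_way(munc, cav)
  fwd$direction <- "cav_to_munc"
  if (nrow(rev)) rev$direction <- "munc_to_cav"
  out <- rbind(fwd, rev)
  attr(out, "skipped") <- attr(fwd, "skipped")
  out
}

#' Quantify one field end to end
#'
#' Convenience driver running the full pipeline on a rendered or loaded
#' field: AZ masks, gating, background estimation, background-subtracted
#' Cav and Munc13-1 intensity integrals, Richardson-Lucy deconvolution
#' and cluster segmentation of both STED channels, and nearest-neighbor
#' distances. Only gated AZs are reported.
#'
#' @param field A `sted_field` or `sted_image_set`.
#' @param params Optional named list overriding pipeline defaults:
#'   `az_sigma_px`, `az_close_nm`, `az_min_area_nm2`, `d_coloc_nm`,
#'   `terminal_min_area_um2`, `rl_iterations`, `rl_sigma_nm`,
#'   `cluster_sigma_px`, `cluster_min_area_nm2`, `guard_nm`.
#' @return A list of class `az_quant`: `records` (per-AZ data.frame:
#'   `az_id`, `animal_id`, `genotype`, `cav_intensity`,
#'   `munc_intensity`, `n_clusters`, `mean_nnd_nm`, `area_nm2`),
#'   `clusters_cav`, `clusters_munc`, `nnd`, `az` (the gated mask),
#'   `background` (per channel).
#' @export
quantify_field <- function(field, params = list()) {
  p <- utils::modifyList(list(
    az_sigma_px = 5, az_close_nm = 60, az_min_area_nm2 = 2000,
    az_dilate_nm = 80, d_coloc_nm = 100, terminal_min_area_um2 = 1.0,
    rl_iterations = 20, rl_sigma_nm = 40,
    cluster_sigma_px = 3, cluster_min_area_nm2 = 1500,
    cluster_thr_factor = 0.4, cluster_ws_tolerance = 0.05,
    guard_nm = 100), params)
  px <- field$pixel_nm
  az <- make_az_masks(field, sigma_px = p$az_sigma_px,
                      min_area_nm2 = p$az_min_area_nm2,
                      close_nm = p$az_close_nm,
                      az_dilate_nm = p$az_dilate_nm)
  az <- gate_azs(az, field, d_coloc_nm = p$d_coloc_nm,
                 terminal_min_area_um2 = p$terminal_min_area_um2)
  bg_cav <- estimate_background(field$images$cav, az, p$guard_nm)
  bg_munc <- estimate_background(field$images$munc13, az, p$guard_nm)
  cav_int <- integrate_az_intensity(field$images$cav, az,
                                    background = bg_cav)
  munc_int <- integrate_az_intensity(field$images$munc13, az,
                                     background = bg_munc)
  dec <- deconvolve_sted(field$images$cav, p$rl_sigma_nm, px,
                         p$rl_iterations)
  clus_cav <- segment_clusters(dec, field$images$cav, az,
                               sigma_px = p$cluster_sigma_px,
                               min_area_nm2 = p$cluster_min_area_nm2,
                               thr_factor = p$cluster_thr_factor,
                               ws_tolerance = p$cluster_ws_tolerance)
  dec_munc <- deconvolve_sted(field$images$munc13, p$rl_sigma_nm, px,
                              p$rl_iterations)
  clus_munc <- segment_clusters(dec_munc, field$images$munc13, az,
                                sigma_px = p$cluster_sigma_px,
                                min_area_nm2 = p$cluster_min_area_nm2,
                                thr_factor = p$cluster_thr_factor,
                                ws_tolerance = p$cluster_ws_tolerance)
  nnd <- nearest_neighbor_distances(clus_cav, clus_munc)
  tab <- az$table[az$table$gated, , drop = FALSE]
  rec <- data.frame(
    az_id = tab$az_id,
    animal_id = if (is.null(field$animal_id)) "a1" else field$animal_id,
    genotype = field$condition,
    cav_intensity = as.numeric(cav_int[as.character(tab$az_id)]),
    munc_intensity = as.numeric(munc_int[as.character(tab$az_id)]),
    n_clusters = vapply(tab$az_id, function(a)
      sum(clus_cav$az_id == a), 0L),
    mean_nnd_nm = vapply(tab$az_id, function(a) {
      d <- nnd$nnd_nm[nnd$az_id == a]
      if (length(d)) mean(d) else NA_real_
    }, 0),
    area_nm2 = tab$area_nm2)
  structure(list(records = rec, clusters_cav = clus_cav,
                 clusters_munc = clus_munc, nnd = nnd, az = az,
                 background = c(cav = as.numeric(bg_cav),
                                munc13 = as.numeric(bg_munc))),
            class = "az_quant")
}

#' Aggregate per-AZ records to per-animal summaries
#'
#' Averages each metric per animal (the unit of analysis for group
#' statistics, preventing pseudo-replication over hundreds of AZs), and
#' emits histogram/cumulative-distribution tables of the per-AZ Ca2+
#' channel intensity.
#'
#' @param records Per-AZ data.frame (rows from `quantify_field()$records`,
#'   possibly concatenated over fields), with `animal_id`, `genotype`,
#'   `cav_intensity`, `munc_intensity`, `n_clusters`, `mean_nnd_nm`,
#'   `area_nm2`.
#' @param breaks Histogram break count for the intensity tables.
#' @return A list of class `animal_summary`: `per_animal` (one row per
#'   animal: means of each metric plus `n_az`), `intensity_hist`
#'   (data.frame `genotype`, `mid`, `count`, `density`),
#'   `intensity_cdf` (data.frame `genotype`, `intensity`, `cdf`),
#'   `excluded_animals`.
#' @export
aggregate_per_animal <- function(records, breaks = 20) {
  stopifnot(all(c("animal_id", "genotype") %in% names(records)))
  split_by <- interaction(records$animal_id, records$genotype, drop = TRUE)
  rows <- lapply(split(records, split_by), function(df) {
    data.frame(animal_id = df$animal_id[1], genotype = df$genotype[1],
               n_az = nrow(df),
               cav_intensity = mean(df$cav_intensity, na.rm = TRUE),
               munc_intensity = mean(df$munc_intensity, na.rm = TRUE),
               n_clusters = mean(df$n_clusters, na.rm = TRUE),
               mean_nnd_nm = mean(df$mean_nnd_nm, na.rm = TRUE),
               area_nm2 = mean(df$area_nm2, na.rm = TRUE))
  })
  per_animal <- do.call(rbind, rows)
  rownames(per_animal) <- NULL
  excluded <- per_animal$animal_id[per_animal$n_az == 0]
  per_animal <- per_animal[per_animal$n_az > 0, , drop = FALSE]
  br <- pretty(range(records$cav_intensity, finite = TRUE), breaks)
  hist_tab <- do.call(rbind, lapply(split(records, records$genotype),
    function(df) {
      h <- graphics::hist(df$cav_intensity, breaks = br, plot = FALSE)
      data.frame(genotype = df$genotype[1], mid = h$mids,
                 count = h$counts, density = h$density)
    }))
  cdf_tab <- do.call(rbind, lapply(split(records, records$genotype),
    function(df) {
      x <- sort(df$cav_intensity)
      data.frame(genotype = df$genotype[1], intensity = x,
                 cdf = seq_along(x) / length(x))
    }))
  rownames(hist_tab) <- rownames(cdf_tab) <- NULL
  structure(list(per_animal = per_animal, intensity_hist = hist_tab,
                 intensity_cdf = cdf_tab,
                 excluded_animals = as.character(excluded)),
            class = "animal_summary")
}
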