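#' Scene parameters for synthetic STED-like fields
#'
#' Describes the statistical structure of a four-channel mossy-fiber
#' field: large VGLUT1-positive boutons (irregular unions of ellipses)
#' containing clustered active zones (AZs); Munc13-1 and Ca2+-channel
#' clusters inside each AZ, the channel clusters offset ~61 nm from
#' their Munc13-1 partners; PSD-95 apposed to each AZ; per-channel
#' Gaussian PSF blur, Poisson/Gaussian noise and 16-bit quantization.
#'
#' @param field_px Image side (pixels).
#' @param pixel_nm Pixel size (nm).
#' @param n_terminals Number of large terminals.
#' @param terminal_area_um2 Mean large-terminal area (um^2).
#' @param n_small_terminals Number of small terminals (below the
#'   large-terminal size filter; they carry one AZ each and should be
#'   excluded by gating).
#' @param small_terminal_area_um2 Mean small-terminal area (um^2).
#' @param az_per_terminal Mean AZ count per large terminal
#'   (zero-truncated Poisson).
#' @param az_min_sep_nm Minimum AZ center separation (nm).
#' @param az_area_um2 Median AZ area (um^2, log-normal with
#'   `az_area_sdlog`).
#' @param az_area_sdlog Log-SD of the AZ area distribution.
#' @param cluster_mean_wt,cluster_mean_ko Mean cluster count per AZ
#'   (zero-truncated Poisson) for the WT and KO conditions.
#' @param cluster_min_sep_nm Minimum separation between cluster
#'   centroids within an AZ (nm); keeps programmed counts resolvable at
#'   STED resolution.
#' @param cluster_radius_nm Radius of the uniform-disk cluster
#'   footprint (nm); protein clusters are extended objects, not point
#'   emitters.
#' @param cluster_intensity Mean integrated intensity per Ca2+-channel
#'   cluster (counts; gamma, shape 4).
#' @param munc_intensity Mean integrated intensity per Munc13-1 cluster.
#' @param ko_intensity_scale Programmed KO/WT ratio of the median
#'   per-AZ total Ca2+-channel intensity (0 < scale <= 1); the
#'   per-cluster multiplier is derived from it by calibrating against
#'   the exact medians of the compound count-intensity distribution.
#' @param cav_munc_distance_nm Programmed centroid offset between a
#'   channel cluster and its Munc13-1 partner (nm).
#' @param cav_munc_jitter_nm Isotropic SD of that offset (nm).
#' @param psf_fwhm_sted_nm,psf_fwhm_confocal_nm PSF FWHM for the STED
#'   (Munc13-1, Cav) and confocal (VGLUT1, PSD-95) channels; 0 disables
#'   blurring.
#' @param vglut_intensity,psd_intensity Per-pixel intensity of the
#'   VGLUT1 terminal fill and the PSD-95 disks (counts).
#' @param psd_radius_nm,psd_offset_nm PSD-95 disk radius and its offset
#'   from the AZ center (nm).
#' @param background Named numeric: per-pixel background counts for
#'   channels `munc13`, `cav`, `vglut1`, `psd95`.
#' @param noise_model `"poisson"`, `"gaussian"`, `"both"` or `"none"`.
#' @param read_noise_sd Gaussian read-noise SD (counts).
#' @return An object of class `image_scene_params`.
#' @export
image_scene_params <- function(field_px = 1024, pixel_nm = 10,
                               n_terminals = 2, terminal_area_um2 = 4,
                               n_small_terminals = 1,
                               small_terminal_area_um2 = 0.3,
                               az_per_terminal = 10, az_min_sep_nm = 450,
                               az_area_um2 = 0.04, az_area_sdlog = 0.3,
                               cluster_mean_wt = 2.5, cluster_mean_ko = 2.3,
                               cluster_min_sep_nm = 110,
                               cluster_radius_nm = 50,
                               cluster_intensity = 5000,
                               munc_intensity = 5000,
                               ko_intensity_scale = 0.78,
                               cav_munc_distance_nm = 61,
                               cav_munc_jitter_nm = 10,
                               psf_fwhm_sted_nm = 60,
                               psf_fwhm_confocal_nm = 250,
                               vglut_intensity = 30, psd_intensity = 50,
                               psd_radius_nm = 80, psd_offset_nm = 120,
                               background = c(munc13 = 3, cav = 3,
                                              vglut1 = 2, psd95 = 2),
                               noise_model = "both", read_noise_sd = 2) {
  if (pixel_nm <= 0) stop("invalid scene: pixel_nm must be > 0")
  if (ko_intensity_scale <= 0 || ko_intensity_scale > 1)
    stop("invalid scene: ko_intensity_scale must be in (0, 1]")
  if (n_terminals < 1) stop("invalid scene: need at least one terminal")
  if (any(background < 0)) stop("invalid scene: background must be >= 0")
  stopifnot(noise_model %in% c("poisson", "gaussian", "both", "none"))
  structure(as.list(environment()), class = "image_scene_params")
}

# zero-truncated Poisson: lambda with mean m, and sampler
.ztp_lambda <- function(m) {
  stopifnot(m > 1)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 c(1e-6, 5 * m))$root
}

.rztp <- function(n, lambda) {
  stats::qpois(stats::runif(n, exp(-lambda), 1), lambda)
}

# median of sum_{i=1..N} X_i with N ~ ZTP(lambda), X ~ gamma(shape 4,
# unit scale); the CDF is a ZTP mixture of gamma(4k) distributions
.ztp_gamma_median <- function(lambda, shape = 4, kmax = 40) {
  k <- seq_len(kmax)
  w <- stats::dpois(k, lambda) / (1 - exp(-lambda))
  w <- w / sum(w)
  cdf <- function(t) sum(w * stats::pgamma(t, shape * k))
  stats::uniroot(function(t) cdf(t) - 0.5, c(1e-3, shape * kmax))$root
}

# FFT convolution with circular boundary; kernel given as small matrix
.fft_conv <- function(img, otf) {
  Re(stats::fft(stats::fft(img) * otf, inverse = TRUE)) / length(img)
}

# optical transfer function of a centered gaussian kernel, field-sized
.gauss_otf <- function(n, sigma_px) {
  r <- ceiling(4 * sigma_px)
  ax <- c(0:r, (n - r):(n - 1))  # wrapped offsets
  d <- pmin(ax, n - ax)
  g <- exp(-d^2 / (2 * sigma_px^2))
  k <- matrix(0, n, n)
  k[ax + 1, ax + 1] <- outer(g, g)
  k <- k / sum(k)
  stats::fft(k)
}

.gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  .fft_conv(img, .gauss_otf(nrow(img), sigma_px))
}

# uniform-disk deposit: spread `val` equally over pixels whose centers
# lie within r_px of the continuous 0-based center; falls back to the
# bilinear point deposit for sub-pixel radii. Conserves the integral
# exactly in both branches.
.deposit_disk <- function(mat, x, y, val, r_px) {
  if (r_px < 1) return(.deposit(mat, x, y, val))
  n <- nrow(mat)
  for (k in seq_along(x)) {
    i <- max(0, floor(x[k] - r_px)):min(n - 1, ceiling(x[k] + r_px))
    j <- max(0, floor(y[k] - r_px)):min(n - 1, ceiling(y[k] + r_px))
    hit <- outer((i - x[k])^2, (j - y[k])^2, "+") <= r_px^2
    npx <- sum(hit)
    if (npx == 0) { mat <- .deposit(mat, x[k], y[k], val[k]); next }
    sub <- mat[i + 1, j + 1]
    sub[hit] <- sub[hit] + val[k] / npx
    mat[i + 1, j + 1] <- sub
  }
  mat
}

# bilinear sub-pixel deposit of `val` at continuous 0-based (x, y) px
.deposit <- function(mat, x, y, val) {
  i0 <- floor(x); j0 <- floor(y)
  fx <- x - i0; fy <- y - j0
  for (k in seq_along(x)) {
    ii <- i0[k] + 1; jj <- j0[k] + 1  # to 1-based
    mat[ii, jj] <- mat[ii, jj] + val[k] * (1 - fx[k]) * (1 - fy[k])
    mat[ii + 1, jj] <- mat[ii + 1, jj] + val[k] * fx[k] * (1 - fy[k])
    mat[ii, jj + 1] <- mat[ii, jj + 1] + val[k] * (1 - fx[k]) * fy[k]
    mat[ii + 1, jj + 1] <- mat[ii + 1, jj + 1] + val[k] * fx[k] * fy[k]
  }
  mat
}

# fill an ellipse into a logical matrix (0-based px center coordinates)
.fill_ellipse <- function(mask, cx, cy, a, b, theta) {
  n <- nrow(mask)
  r <- max(a, b)
  i <- max(0, floor(cx - r)):min(n - 1, ceiling(cx + r))
  j <- max(0, floor(cy - r)):min(n - 1, ceiling(cy + r))
  dx <- outer(i - cx, rep(1, length(j)))
  dy <- outer(rep(1, length(i)), j - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  hit <- (u / a)^2 + (v / b)^2 <= 1
  mask[i + 1, j + 1] <- mask[i + 1, j + 1] | hit
  mask
}

# dart-throwing with progressive relaxation of the separation constraint
.place_points <- function(n_pts, sampler, min_sep, max_tries = 2000) {
  pts <- matrix(NA_real_, 0, 2)
  sep <- min_sep
  tries <- 0
  while (nrow(pts) < n_pts) {
    cand <- sampler()
    ok <- !nrow(pts) ||
      min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= sep
    if (ok) pts <- rbind(pts, cand)
    tries <- tries + 1
    if (tries %% 200 == 0) sep <- sep * 0.9  # relax if crowded
    if (tries > max_tries)
      stop("generation error: could not place ", n_pts,
           " points at min separation ", round(min_sep), " nm")
  }
  pts
}

#' Render a synthetic four-channel STED-like field with ground truth
#'
#' Places terminals, AZs and clusters according to
#' [image_scene_params()], renders the four channels (Munc13-1 STED,
#' Cav STED, VGLUT1 confocal, PSD-95 confocal), applies PSF blur and
#' noise, and returns the images together with complete per-object
#' annotations. All randomness flows from one seeded generator; the same
#' `(scene, condition, seed)` reproduces bit-identical output.
#'
#' @param scene An [image_scene_params()] object.
#' @param condition `"WT"` or `"KO"`. KO multiplies per-cluster Cav
#'   intensity by `ko_intensity_scale` and draws cluster counts with
#'   mean `cluster_mean_ko`.
#' @param seed Integer seed.
#' @param animal_id,field_id Identifiers stored with the field.
#' @param apply_psf Logical; apply the Gaussian PSF blur (default TRUE).
#' @param quantize Logical; round/clip to 16-bit integers (default
#'   TRUE). Disable to check exact intensity conservation.
#' @return A list of class `sted_field`: `images` (named list of
#'   matrices `munc13`, `cav`, `vglut1`, `psd95`), `pixel_nm`,
#'   `condition`, `animal_id`, `field_id`, `saturated` (per-channel
#'   logical), and `ground_truth` (list of data.frames `terminals`,
#'   `azs`, `clusters`, plus `scene`, `condition`, `seed`).
#' @export
render_sted_field <- function(scene, condition = c("WT", "KO"), seed = 1,
                              animal_id = "a1", field_id = "f1",
                              apply_psf = TRUE, quantize = TRUE) {
  stopifnot(inherits(scene, "image_scene_params"))
  condition <- match.arg(condition)
  set.seed(seed)
  n <- scene$field_px
  px <- scene$pixel_nm
  field_nm <- n * px

  ## --- terminals -------------------------------------------------------
  n_lg <- scene$n_terminals
  n_sm <- scene$n_small_terminals
  areas_um2 <- c(rep(scene$terminal_area_um2, n_lg),
                 rep(scene$small_terminal_area_um2, n_sm))
  r_nm <- sqrt(areas_um2 * 1e6 / pi)
  margin <- 1.6 * max(r_nm)
  if (2 * margin >= field_nm)
    stop("generation error: field too small for requested terminal area")
  centers <- matrix(NA_real_, 0, 2)
  for (k in seq_along(r_nm)) {
    placed <- FALSE
    for (try in 1:500) {
      cand <- stats::runif(2, 1.45 * r_nm[k], field_nm - 1.45 * r_nm[k])
      if (!nrow(centers) ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >=
              1.25 * (r_nm[seq_len(nrow(centers))] + r_nm[k]))) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("generation error: could not place terminal ", k,
           " (constraint: non-overlapping terminals within the field)")
  }
  tmask <- matrix(0L, n, n)  # terminal label image
  for (k in seq_along(r_nm)) {
    m <- matrix(FALSE, n, n)
    r_px <- r_nm[k] / px
    cx <- centers[k, 1] / px; cy <- centers[k, 2] / px
    for (e in seq_len(sample(2:4, 1))) {
      off <- stats::runif(2, -0.3, 0.3) * r_px
      m <- .fill_ellipse(m, cx + off[1], cy + off[2],
                         r_px * stats::runif(1, 0.7, 1.05),
                         r_px * stats::runif(1, 0.55, 0.9),
                         stats::runif(1, 0, pi))
    }
    tmask[m] <- k
  }
  terminals <- data.frame(
    terminal_id = seq_along(r_nm),
    x_nm = centers[, 1], y_nm = centers[, 2],
    small = seq_along(r_nm) > n_lg,
    area_px = as.integer(tabulate(tmask[tmask > 0], length(r_nm))))
  terminals$area_um2 <- terminals$area_px * px^2 / 1e6

  ## --- active zones ----------------------------------------------------
  lam_az <- .ztp_lambda(scene$az_per_terminal)
  dmap <- as.matrix(EBImage::distmap(1 * (tmask > 0))) * px  # nm to edge
  az_list <- list()
  az_id <- 0
  for (k in seq_along(r_nm)) {
    n_az <- if (k <= n_lg) .rztp(1, lam_az) else 1L
    areas <- stats::rlnorm(n_az, log(scene$az_area_um2 * 1e6),
                           scene$az_area_sdlog)  # nm^2
    radii <- sqrt(areas / pi)
    # candidate pixels: inside this terminal, away from its edge
    elig <- which(tmask == k & dmap >= max(radii) + 100, arr.ind = TRUE)
    if (nrow(elig) < n_az)
      elig <- which(tmask == k & dmap >= stats::median(radii), arr.ind = TRUE)
    if (!nrow(elig))
      stop("generation error: terminal ", k,
           " too small to host an AZ (constraint: AZ inside terminal)")
    sampler <- function() {
      ij <- elig[sample.int(nrow(elig), 1), ]
      c((ij[1] - 1) * px, (ij[2] - 1) * px) + stats::runif(2, 0, px)
    }
    pts <- .place_points(n_az, sampler, scene$az_min_sep_nm)
    for (a in seq_len(n_az)) {
      az_id <- az_id + 1
      az_list[[az_id]] <- data.frame(
        az_id = az_id, terminal_id = k, small = k > n_lg,
        x_nm = pts[a, 1], y_nm = pts[a, 2], radius_nm = radii[a])
    }
  }
  azs <- do.call(rbind, az_list)

  ## --- clusters --------------------------------------------------------
  clu_mean <- if (condition == "KO") scene$cluster_mean_ko else
    scene$cluster_mean_wt
  lam_clu <- .ztp_lambda(clu_mean)
  # ko_intensity_scale is the programmed ratio of MEDIAN per-AZ total
  # Cav intensity (the pipeline's reported statistic). The per-AZ total
  # is a compound ZTP-of-gammas variable whose median depends on the
  # count distribution, so the per-cluster multiplier is calibrated
  # against the exact medians of both compounds (gamma scale cancels).
  cav_scale <- if (condition == "KO") {
    lam_wt <- .ztp_lambda(scene$cluster_mean_wt)
    scene$ko_intensity_scale *
      .ztp_gamma_median(lam_wt) / .ztp_gamma_median(lam_clu)
  } else 1
  clus <- list()
  azs$n_clusters <- 0L
  azs$cav_total <- 0
  azs$munc_total <- 0
  for (a in seq_len(nrow(azs))) {
    nc <- .rztp(1, lam_clu)
    R <- max(azs$radius_nm[a] * 0.9,
             scene$cluster_min_sep_nm * sqrt(nc) / 1.7)
    ctr <- c(azs$x_nm[a], azs$y_nm[a])
    sampler <- function() {
      rr <- R * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
      ctr + rr * c(cos(th), sin(th))
    }
    munc_xy <- .place_points(nc, sampler, scene$cluster_min_sep_nm)
    cav_xy <- matrix(NA_real_, nc, 2)
    for (cc in seq_len(nc)) {
      for (try in 1:60) {
        d <- stats::rnorm(1, scene$cav_munc_distance_nm,
                          scene$cav_munc_jitter_nm)
        th <- stats::runif(1, 0, 2 * pi)
        cand <- munc_xy[cc, ] + abs(d) * c(cos(th), sin(th))
        sep_ok <- cc == 1 ||
          min(sqrt(rowSums(sweep(cav_xy[seq_len(cc - 1), , drop = FALSE],
                                 2, cand)^2))) >= 100
        if (sep_ok && all(cand > 2 * px) && all(cand < field_nm - 2 * px)) break
      }
      cav_xy[cc, ] <- cand
    }
    munc_i <- stats::rgamma(nc, shape = 4, scale = scene$munc_intensity / 4)
    cav_i <- stats::rgamma(nc, shape = 4,
                           scale = scene$cluster_intensity / 4) * cav_scale
    azs$n_clusters[a] <- nc
    azs$cav_total[a] <- sum(cav_i)
    azs$munc_total[a] <- sum(munc_i)
    clus[[a]] <- data.frame(
      az_id = azs$az_id[a],
      channel = rep(c("munc13", "cav"), each = nc),
      x_nm = c(munc_xy[, 1], cav_xy[, 1]),
      y_nm = c(munc_xy[, 2], cav_xy[, 2]),
      intensity = c(munc_i, cav_i))
  }
  clusters <- do.call(rbind, clus)
  stopifnot(all(clusters$x_nm > 0 & clusters$x_nm < field_nm),
            all(clusters$y_nm > 0 & clusters$y_nm < field_nm))

  ## --- render channels -------------------------------------------------
  bg <- scene$background
  ch <- list(munc13 = matrix(bg[["munc13"]], n, n),
             cav = matrix(bg[["cav"]], n, n),
             vglut1 = matrix(bg[["vglut1"]], n, n),
             psd95 = matrix(bg[["psd95"]], n, n))
  mm <- clusters$channel == "munc13"
  r_clu <- scene$cluster_radius_nm / px
  ch$munc13 <- .deposit_disk(ch$munc13, clusters$x_nm[mm] / px,
                             clusters$y_nm[mm] / px,
                             clusters$intensity[mm], r_clu)
  ch$cav <- .deposit_disk(ch$cav, clusters$x_nm[!mm] / px,
                          clusters$y_nm[!mm] / px,
                          clusters$intensity[!mm], r_clu)
  ch$vglut1 <- ch$vglut1 + (tmask > 0) * scene$vglut_intensity
  psd <- matrix(FALSE, n, n)
  for (a in seq_len(nrow(azs))) {
    th <- stats::runif(1, 0, 2 * pi)
    cx <- (azs$x_nm[a] + scene$psd_offset_nm * cos(th)) / px
    cy <- (azs$y_nm[a] + scene$psd_offset_nm * sin(th)) / px
    r <- scene$psd_radius_nm / px
    psd <- .fill_ellipse(psd, cx, cy, r, r, 0)
  }
  ch$psd95 <- ch$psd95 + psd * scene$psd_intensity

  if (apply_psf) {
    s_sted <- scene$psf_fwhm_sted_nm / 2.3548 / px
    s_conf <- scene$psf_fwhm_confocal_nm / 2.3548 / px
    if (s_sted > 0) {
      otf <- .gauss_otf(n, s_sted)
      ch$munc13 <- .fft_conv(ch$munc13, otf)
      ch$cav <- .fft_conv(ch$cav, otf)
    }
    if (s_conf > 0) {
      otf <- .gauss_otf(n, s_conf)
      ch$vglut1 <- .fft_conv(ch$vglut1, otf)
      ch$psd95 <- .fft_conv(ch$psd95, otf)
    }
  }
  if (scene$noise_model %in% c("poisson", "both"))
    ch <- lapply(ch, function(m)
      matrix(stats::rpois(length(m), pmax(m, 0)), n, n))
  if (scene$noise_model %in% c("gaussian", "both"))
    ch <- lapply(ch, function(m)
      m + stats::rnorm(length(m), 0, scene$read_noise_sd))
  saturated <- c(munc13 = FALSE, cav = FALSE, vglut1 = FALSE, psd95 = FALSE)
  if (quantize) {
    for (nm in names(ch)) {
      m <- round(ch[[nm]])
      saturated[nm] <- any(m > 65535)
      ch[[nm]] <- pmin(pmax(m, 0), 65535)
    }
  }

  structure(list(images = ch, pixel_nm = px, condition = condition,
                 animal_id = animal_id, field_id = field_id,
                 saturated = saturated,
                 ground_truth = list(terminals = terminals, azs = azs,
                                     clusters = clusters, scene = scene,
                                     condition = condition, seed = seed)),
            class = "sted_field")
}

#' @export
print.sted_field <- function(x, ...) {
  cat(sprintf(
    "sted_field %s/%s (%s): %d px @ %g nm, %d AZs, %d clusters\n",
    x$animal_id, x$field_id, x$condition, nrow(x$images$munc13),
    x$pixel_nm, nrow(x$ground_truth$azs), nrow(x$ground_truth$clusters)))
  invisible(x)
}
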