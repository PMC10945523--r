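#' Default configuration for an end-to-end demonstration run
#'
#' Bundles every module's parameter block into one nested list:
#' `circuit`, `channel`, `release` (trace generators), `scene` (image
#' generator, reduced field count/size for a desk-scale run),
#' `pipeline` (image quantification), `ephys` (cells, durations, noise),
#' `epsc` (train settings), `imaging` (animals x fields) and `stats`
#' (significance level). Unknown keys in overrides are rejected.
#'
#' @param ... Named overrides, e.g. `ephys = list(n_cells = 4)`.
#' @return A validated config list of class `run_config`.
#' @export
demo_config <- function(...) {
  base <- list(
    circuit = list(Cm_baseline = 1000, Gm = 1, Gs = 20, noise_sd = 0),
    channel = list(g_max = 0.9, V_half = -5, k_slope = 7, E_rev = 65,
                   tau_act = 1.4, ko_scale = 0.7),
    release = list(rrp_size = 52, tau_release = 45, hill_K = 30,
                   hill_n = 3),
    scene = list(field_px = 512, n_terminals = 1, n_small_terminals = 1,
                 az_per_terminal = 8, ko_intensity_scale = 0.78,
                 cluster_mean_wt = 2.5, cluster_mean_ko = 2.3),
    pipeline = list(),
    ephys = list(n_cells = 5, durations = c(5, 10, 20, 50, 100),
                 dcm_noise_sd = 3, v_step = 10,
                 ca_scales = c(0.4, 0.6, 0.8, 1, 1.2)),
    epsc = list(n_stim = 25, freq_hz = 50, n_cells = 6, U = 0.02,
                noise_sd = 10, ko_amp_scale = 0.25),
    imaging = list(n_animals = 4, fields_per_animal = 1),
    stats = list(alpha = 0.05))
  over <- list(...)
  for (blk in names(over)) {
    if (!blk %in% names(base))
      stop("unknown config block: ", blk)
    bad <- setdiff(names(over[[blk]]), names(base[[blk]]))
    if (length(bad) && !blk %in% c("scene", "pipeline"))
      stop("unknown config key in ", blk, ": ", paste(bad, collapse = ", "))
    base[[blk]] <- utils::modifyList(base[[blk]], over[[blk]])
  }
  structure(base, class = "run_config")
}

# derived sub-seed, kept below 2^31
.subseed <- function(seed, k) (seed * 1009L + k) %% 2147483647L

#' Run a full synthesize-analyze-compare demonstration
#'
#' Deterministically generates synthetic WT and KO data with the
#' configured generators, runs every analysis stage (capacitance,
#' depletion and Hill fits, IV, EPSC trains, image quantification with
#' per-animal aggregation) and the group statistics, and optionally
#' writes tidy CSV tables, JSON stats reports and the resolved config
#' beside them.
#'
#' @param config A [demo_config()] list.
#' @param seed Integer master seed; every stage derives its own seed
#'   from it, so the same `(config, seed)` reproduces identical output.
#' @param out_dir Output directory; `NULL` (default) skips writing.
#' @return A list of class `demo_result`: `fits` (per-genotype
#'   depletion fits, Hill fit, IV fits), `duration_response`,
#'   `hill_points`, `epsc_summary`, `az_records`, `per_animal`,
#'   `stats` (named p-values: `cav_intensity`, `munc_intensity`,
#'   `n_clusters`, `nnd`, `peak_ica_t`, `epsc_first_t`),
#'   `seed`, `config`.
#' @export
run_demo <- function(config = demo_config(), seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  chan <- do.call(ca_channel_params, config$channel)
  rel <- do.call(release_params, config$release)

  ## --- duration-response + depletion fits per genotype ----------------
  ephys <- config$ephys
  dr <- list(); k <- 0
  for (gt in c("WT", "KO")) for (cell in seq_len(ephys$n_cells)) {
    k <- k + 1
    dr[[k]] <- simulate_depletion_dataset(
      rel, chan, ephys$durations, V_step = ephys$v_step,
      noise_sd = ephys$dcm_noise_sd, seed = .subseed(seed, k),
      condition = gt, cell_id = paste0(gt, "_c", cell),
      animal_id = paste0(gt, "_an", 1 + (cell - 1) %% 4))
  }
  duration_response <- do.call(rbind, dr)
  fit_by_gt <- lapply(split(duration_response, duration_response$condition),
    function(df) {
      agg <- stats::aggregate(dCm_fF ~ duration_ms, df, mean)
      fit_depletion(agg)
    })

  ## --- Hill relation over the Ca2+ titration --------------------------
  hp <- lapply(seq_along(ephys$ca_scales), function(i) {
    sc <- ephys$ca_scales[i]
    ch2 <- do.call(ca_channel_params,
                   utils::modifyList(config$channel,
                                     list(g_max = config$channel$g_max * sc)))
    simulate_depletion_dataset(rel, ch2, max(ephys$durations),
                               V_step = ephys$v_step, noise_sd = 0,
                               condition = "WT",
                               cell_id = paste0("titr", i))
  })
  hill_points <- do.call(rbind, hp)
  hill <- fit_hill(hill_points$peak_I_pA, hill_points$dCm_fF,
                   n = rel$hill_n)

  ## --- IV + peak-current group comparison -----------------------------
  levels <- seq(-80, 70, by = 10)
  iv_traces <- lapply(levels, function(v)
    simulate_ca_current(chan, v, 5, fs = 50))
  iv <- build_iv(iv_traces, levels, window = c(5, 10))
  # per-cell peak currents at +10 mV: cell-to-cell channel-density
  # scatter (lognormal, CV ~25%) plus recording noise, measured back
  # through peak_current()
  cell_peak <- function(gt, i) {
    set.seed(.subseed(seed, 500 + i + 100 * (gt == "KO")))
    ch2 <- do.call(ca_channel_params, utils::modifyList(
      config$channel,
      list(g_max = config$channel$g_max * exp(stats::rnorm(1, 0, 0.25)))))
    tr <- simulate_ca_current(ch2, 10, 20, fs = 20, noise_sd = 1,
                              seed = .subseed(seed, 900 + i),
                              condition = gt)
    peak_current(tr, c(5, 25))
  }
  peak_wt <- vapply(seq_len(ephys$n_cells), function(i)
    cell_peak("WT", i), 0)
  peak_ko <- vapply(seq_len(ephys$n_cells), function(i)
    cell_peak("KO", i), 0)
  t_ica <- two_sample_t(peak_wt, peak_ko)

  ## --- EPSC trains -----------------------------------------------------
  ep <- config$epsc
  amp_scales <- c(WT = 1, KO = ep$ko_amp_scale)
  trains <- lapply(seq_along(amp_scales), function(g) {
    lapply(seq_len(ep$n_cells), function(i) {
      st <- simulate_epsc_train(ep$n_stim, ep$freq_hz, fs = 20,
                                U = ep$U, noise_sd = ep$noise_sd,
                                A_max = 5000 * amp_scales[g],
                                seed = .subseed(seed, 700 + i + 50 * g))
      extract_epsc_amplitudes(st)
    })
  })
  names(trains) <- names(amp_scales)
  epsc_summary <- lapply(trains, summarize_train)
  t_epsc <- two_sample_t(
    vapply(trains$WT, function(tr) tr$amp_corr_pA[1], 0),
    vapply(trains$KO, function(tr) tr$amp_corr_pA[1], 0))

  ## --- imaging ---------------------------------------------------------
  im <- config$imaging
  recs <- list(); r <- 0
  for (gt in c("WT", "KO")) for (an in seq_len(im$n_animals))
    for (f in seq_len(im$fields_per_animal)) {
      r <- r + 1
      scene <- do.call(image_scene_params, config$scene)
      fld <- render_sted_field(scene, gt, seed = .subseed(seed, 1000 + r),
                               animal_id = paste0(gt, "_an", an),
                               field_id = paste0("f", f))
      q <- quantify_field(fld, config$pipeline)
      recs[[r]] <- q$records
    }
  az_records <- do.call(rbind, recs)
  agg <- aggregate_per_animal(az_records)
  pa <- agg$per_animal
  mw <- function(metric) {
    exact_mann_whitney(pa[[metric]][pa$genotype == "WT"],
                       pa[[metric]][pa$genotype == "KO"],
                       unit = "animal")$p
  }
  stats_out <- list(cav_intensity = mw("cav_intensity"),
                    munc_intensity = mw("munc_intensity"),
                    n_clusters = mw("n_clusters"),
                    nnd = mw("mean_nnd_nm"),
                    peak_ica_t = t_ica$p,
                    epsc_first_t = t_epsc$p)

  res <- structure(list(
    fits = list(depletion = fit_by_gt, hill = hill, iv = iv),
    duration_response = duration_response,
    hill_points = hill_points, epsc_summary = epsc_summary,
    az_records = az_records, per_animal = pa, stats = stats_out,
    seed = seed, config = config), class = "demo_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(duration_response,
                     file.path(out_dir, "duration_response.csv"),
                     row.names = FALSE)
    utils::write.csv(hill_points, file.path(out_dir, "hill_points.csv"),
                     row.names = FALSE)
    utils::write.csv(az_records, file.path(out_dir, "az_records.csv"),
                     row.names = FALSE)
    utils::write.csv(pa, file.path(out_dir, "per_animal.csv"),
                     row.names = FALSE)
    utils::write.csv(iv$table, file.path(out_dir, "iv_curve.csv"),
                     row.names = FALSE)
    fits_json <- list(
      depletion = lapply(fit_by_gt, function(f)
        list(C_inf_fF = f$C_inf_fF, tau_ms = f$tau_ms,
             residual_rms_fF = f$residual_rms_fF)),
      hill = list(C_max_fF = hill$C_max_fF, K_pA = hill$K_pA, n = hill$n),
      iv = as.list(iv$fit_params))
    jsonlite::write_json(fits_json, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(c(unclass(config), list(seed = seed)),
                     file.path(out_dir, "resolved_config.yaml"))
    writeLines(c(paste("azphys", as.character(utils::packageVersion("azphys"))),
                 paste("R", getRversion()), paste("seed", seed),
                 paste("time", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
               file.path(out_dir, "run_log.txt"))
  }
  res
}

#' @export
print.demo_result <- function(x, ...) {
  cat("demo run (seed", x$seed, ")\n")
  for (gt in names(x$fits$depletion)) {
    f <- x$fits$depletion[[gt]]
    cat(sprintf("  %s depletion: C_inf = %.1f fF, tau = %.1f ms\n",
                gt, f$C_inf_fF, f$tau_ms))
  }
  cat(sprintf("  Hill (n = %g): C_max = %.1f fF, K = %.1f pA\n",
              x$fits$hill$n, x$fits$hill$C_max_fF, x$fits$hill$K_pA))
  cat("  p-values:",
      paste(names(x$stats), signif(unlist(x$stats), 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
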