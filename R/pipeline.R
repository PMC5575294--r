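scenario_defaults <- function() {
  list(
    protocol = list(flow_rate = 25, total_volume = 500, mode = "continuous",
                    needle_tip = c(1334, 2000), frame_interval = 60),
    tissue = list(epsilon = 1.0, anisotropy = 1.0, crack_width = 800,
                  youngs_modulus = 1.01, fracture_threshold = 4100,
                  lag_volume = 100, mu_abs = 1.0),
    detector = list(gain_mean = 30000, gain_pattern_sd = 0.02,
                    offset_mean = 1000, offset_pattern_sd = 0.05,
                    read_noise_sd = 50, poisson = TRUE, n_gain_frames = 10,
                    texture_sd = 0, texture_scale_px = 8, quantize = TRUE),
    geometry = list(dims = c(2667, 4000), pixel_size = 9),
    frames = NULL, drift = NULL, front_rim_mm = 0,
    dr_relax_h = 0, dr_relax_v = 0, seed = NULL
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a scenario configuration from a YAML file
#'
#' Plain-text structured scenario file with full defaulting: any omitted
#' key takes the package default (echoed into the run log by
#' [run_simulate()]). Keys mirror [scenario_config()]; the frame schedule
#' may be given as `frames: {start, end, interval}` or an explicit
#' `frames: {times: [...]}`.
#'
#' @param path path to the YAML file.
#' @param seed optional seed overriding the file's `seed` entry.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(scenario_defaults(), user)
  if (!is.null(seed)) cfg$seed <- seed
  frame_times <- NULL
  if (!is.null(cfg$frames)) {
    fr <- cfg$frames
    frame_times <- if (!is.null(fr$times)) as.numeric(fr$times)
      else seq(fr$start, fr$end, by = fr$interval)
  }
  drift <- cfg$drift
  if (!is.null(drift)) {
    drift <- as.data.frame(lapply(drift, as.numeric))
    stopifnot(all(c("time", "dr", "dc") %in% names(drift)))
  }
  scenario_config(
    protocol = do.call(injection_protocol, cfg$protocol),
    tissue = do.call(tissue_parameters, cfg$tissue),
    detector = do.call(detector_model, cfg$detector),
    dims = cfg$geometry$dims, pixel_size = cfg$geometry$pixel_size,
    frame_times = frame_times, drift = drift,
    front_rim_mm = cfg$front_rim_mm, dr_relax_h = cfg$dr_relax_h,
    dr_relax_v = cfg$dr_relax_v, seed = cfg$seed
  )
}

config_provenance <- function(config) {
  list(
    seed = config$seed,
    protocol = config$protocol[c("flow_rate", "total_volume", "mode",
                                 "needle_tip", "frame_interval",
                                 "duration")],
    tissue = unclass(config$tissue),
    detector = unclass(config$detector),
    geometry = list(dims = config$dims, pixel_size = config$pixel_size),
    n_frames = length(config$frame_times),
    front_rim_mm = config$front_rim_mm,
    dr_relax_h = config$dr_relax_h, dr_relax_v = config$dr_relax_v
  )
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate a scenario and write the stack, flats and ground truth
#'
#' Runs [generate_stack()] and writes everything an analysis needs to a
#' directory: the radiograph stack (`stack/`), gain and offset calibration
#' stacks (`gain/`, `offset/`), the injection protocol (`protocol.yml`),
#' the ground-truth manifest (`truth.yml` + `depot_truth.tsv`) and a run
#' log echoing every parameter, defaults included.
#'
#' @param config a [scenario_config()] or path to a scenario YAML.
#' @param out_dir output directory (created).
#' @param seed optional override of the scenario seed.
#' @return the [generate_stack()] result, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_scenario_config(config, seed)
  else if (!is.null(seed)) config$seed <- as.integer(seed)
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_stack(config)
  write_stack(sim$stack, file.path(out_dir, "stack"))
  nglist <- sim$flats$gain_frames
  write_stack(image_stack(nglist, seq_along(nglist) - 1,
                          pixel_size = config$pixel_size),
              file.path(out_dir, "gain"))
  nolist <- sim$flats$offset_frames
  write_stack(image_stack(nolist, seq_along(nolist) - 1,
                          pixel_size = config$pixel_size),
              file.path(out_dir, "offset"))
  pr <- config$protocol
  yaml::write_yaml(list(flow_rate = pr$flow_rate,
                        total_volume = pr$total_volume, mode = pr$mode,
                        needle_tip = pr$needle_tip,
                        frame_interval = pr$frame_interval),
                   file.path(out_dir, "protocol.yml"))
  truth <- sim$truth
  truth$drift <- NULL
  yaml::write_yaml(lapply(truth, function(x) if (is.numeric(x)) as.numeric(x) else x),
                   file.path(out_dir, "truth.yml"))
  write_tsv(cbind(sim$depot, as.data.frame(sim$truth$drift)),
            file.path(out_dir, "depot_truth.tsv"))
  prov <- config_provenance(config)
  yaml::write_yaml(prov, file.path(out_dir, "run_log.yml"))
  invisible(sim)
}

#' Analyse a radiograph stack end to end and write report tables
#'
#' Full measurement pipeline on a stack directory as written by
#' [run_simulate()] (or assembled from real data in the same layout):
#' flat-field correction, optional drift registration, RCS maps against a
#' pre-onset baseline, wetting-front tracking, aspect ratios, cube-root
#' growth fit, onset and quasi-saturation times, RCS profiles and their
#' temporal variation, ROI coefficient-of-variation series and the Darcy
#' permeability estimate. All tables are tab-delimited; every analysis
#' parameter (defaults included) is recorded in `run_metadata.yml`.
#'
#' @param input_dir directory containing `stack/`, `gain/`, `offset/` and
#'   `protocol.yml`.
#' @param out_dir directory for the report tables (created).
#' @param tissue a [tissue_parameters()] for the analysis (mu_abs etc.).
#' @param options list of analysis options; recognised (with defaults):
#'   `baseline_index` (1), `register` (FALSE), `noise_floor` (0),
#'   `roi_size_mm` (0.9), `window_mm` (0.9), `qs_window` (60),
#'   `qs_rel_tol` (0.01), `onset_baseline` (3 pre-onset frames),
#'   `tissue_label` ("tissue").
#' @return list of all computed results, invisibly.
#' @export
run_analysis <- function(input_dir, out_dir,
                         tissue = tissue_parameters(), options = list()) {
  opt <- merge_config(list(baseline_index = 1, register = FALSE,
                           noise_floor = NULL, roi_size_mm = 0.9,
                           window_mm = 0.9, qs_window = 60,
                           qs_rel_tol = 0.01, onset_baseline = 3,
                           tissue_label = "tissue"),
                      options)
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  proto_file <- file.path(input_dir, "protocol.yml")
  if (!file.exists(proto_file)) stop("protocol.yml not found in ", input_dir)
  p <- yaml::read_yaml(proto_file)
  protocol <- injection_protocol(p$flow_rate, p$total_volume,
                                 mode = p$mode,
                                 needle_tip = as.numeric(p$needle_tip),
                                 frame_interval = p$frame_interval)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  raw <- read_stack(file.path(input_dir, "stack"))
  gain <- read_stack(file.path(input_dir, "gain"))
  offset <- read_stack(file.path(input_dir, "offset"))
  flat <- flat_field_set(gain$frames, offset$frames)

  trans <- image_stack(lapply(raw$frames, flat_field_correct, flat = flat),
                       raw$timestamps, pixel_size = raw$pixel_size,
                       exposure = raw$exposure)
  shifts <- NULL
  if (isTRUE(opt$register) && length(trans) >= 2) {
    reg <- register_drift(trans, reference_index = opt$baseline_index)
    trans <- reg$corrected
    shifts <- reg$shifts
  }

  baseline <- trans$frames[[opt$baseline_index]]
  maps <- lapply(trans$frames, rcs_map, baseline = baseline,
                 mu_abs = tissue$mu_abs)

  trace <- track_wf(trans, protocol, tissue,
                    baseline_index = opt$baseline_index,
                    noise_floor = opt$noise_floor)
  write_tsv(as.data.frame(trace), file.path(out_dir, "wf_trace.tsv"))

  cen <- central_rcs(maps, protocol$needle_tip)
  onset <- tryCatch(onset_time(trans$timestamps, cen,
                               baseline_window = opt$onset_baseline),
                    error = function(e) NA_real_)
  write_tsv(data.frame(onset_time = onset),
            file.path(out_dir, "onset.tsv"))

  qs <- tryCatch(quasi_saturation_time(trace, rel_tol = opt$qs_rel_tol,
                                       window = opt$qs_window),
                 error = function(e) NA_real_)
  write_tsv(data.frame(qs_time = qs), file.path(out_dir, "qs.tsv"))

  ar <- lapply(c(IR = "IR", DR = "DR"), function(rg) {
    tryCatch(suppressWarnings(aspect_ratio(trace, rg)),
             error = function(e) list(mean = NA_real_, sd = NA_real_,
                                      n = 0L, region = rg))
  })
  write_tsv(data.frame(region = names(ar),
                       mean = vapply(ar, `[[`, 0, "mean"),
                       sd = vapply(ar, `[[`, 0, "sd"),
                       n = vapply(ar, function(a) as.numeric(a$n), 0)),
            file.path(out_dir, "aspect_ratio.tsv"))

  fits <- lapply(c(horizontal = "horizontal", vertical = "vertical"),
                 function(dir) {
    tryCatch(suppressWarnings(
      fit_normalized_wf(trace, protocol, direction = dir)),
      error = function(e) NULL)
  })
  fit_tbl <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(direction = nm,
               wf_max = if (is.null(f)) NA_real_ else f$wf_max,
               r_squared = if (is.null(f)) NA_real_ else f$r_squared)
  }))
  write_tsv(fit_tbl, file.path(out_dir, "fit.tsv"))

  perm <- tryCatch(estimate_permeability(trace, protocol,
                                         tissue_label = opt$tissue_label),
                   error = function(e) NULL)
  perm_tbl <- if (is.null(perm)) {
    data.frame(tissue = opt$tissue_label, flow_rate = protocol$flow_rate,
               k_horizontal = NA_real_, k_vertical = NA_real_)
  } else as.data.frame(perm)
  write_tsv(perm_tbl, file.path(out_dir, "permeability.tsv"))

  profs <- do.call(rbind, lapply(c("horizontal", "vertical"), function(dir) {
    cbind(direction = dir,
          rcs_profile_series(maps, trans$timestamps, protocol$needle_tip,
                             direction = dir,
                             pixel_size = trans$pixel_size,
                             window_mm = opt$window_mm))
  }))
  write_tsv(profs, file.path(out_dir, "rcs_profiles.tsv"))

  vari <- do.call(rbind, lapply(c("horizontal", "vertical"), function(dir) {
    pd <- profs[profs$direction == dir, ]
    ts <- unique(pd$time)
    if (length(ts) < 2) return(NULL)
    do.call(rbind, lapply(seq_len(length(ts) - 1), function(i) {
      p1 <- pd[pd$time == ts[i], c("distance", "rcs")]
      p2 <- pd[pd$time == ts[i + 1], c("distance", "rcs")]
      v <- rcs_temporal_variation(p1, p2, ts[i], ts[i + 1])
      cbind(direction = dir, t1 = ts[i], t2 = ts[i + 1], v)
    }))
  }))
  if (!is.null(vari)) write_tsv(vari, file.path(out_dir, "rcs_variation.tsv"))

  cv_tbl <- tryCatch({
    rois <- suppressWarnings(
      define_rois(protocol$needle_tip, trace, dim(baseline),
                  pixel_size = trans$pixel_size,
                  size_mm = opt$roi_size_mm))
    roi_cv(trans, rois)
  }, error = function(e) NULL)
  if (!is.null(cv_tbl)) write_tsv(cv_tbl, file.path(out_dir, "roi_cv.tsv"))

  meta <- list(input_dir = input_dir,
               protocol = p,
               tissue = unclass(tissue),
               options = opt,
               registered = isTRUE(opt$register),
               n_frames = length(trans))
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yml"))

  invisible(list(protocol = protocol, trace = trace, onset = onset,
                 qs = qs, aspect = ar, fits = fits, permeability = perm,
                 profiles = profs, variation = vari, roi_cv = cv_tbl,
                 shifts = shifts))
}

#' Compare analysis estimates against simulator ground truth
#'
#' Runs [run_analysis()] on a simulated dataset and compares the recovered
#' quantities (final semi-axes, depot anisotropy, onset time and the
#' Darcy permeability equivalent) with the generator's truth manifest,
#' reporting per-quantity errors and pass/fail against tolerances.
#'
#' @param input_dir a [run_simulate()] output directory (must contain
#'   `truth.yml`).
#' @param out_dir directory for the comparison table and the nested
#'   analysis output.
#' @param tissue,options passed to [run_analysis()].
#' @param tolerances list with `semi_axis_mm`, `anisotropy_abs`,
#'   `onset_s` (defaults: 2 pixels, 0.05, one frame interval) and `k_rel`
#'   (0.1).
#' @return data frame with columns `quantity`, `truth`, `estimate`,
#'   `error`, `tol`, `pass`; attribute `ok` is `TRUE` when all pass.
#' @export
run_recover <- function(input_dir, out_dir, tissue = NULL,
                        options = list(), tolerances = list()) {
  truth_file <- file.path(input_dir, "truth.yml")
  if (!file.exists(truth_file)) stop("truth manifest not found in ",
                                     input_dir)
  truth <- yaml::read_yaml(truth_file)
  need <- c("final_a_h", "final_a_v", "anisotropy", "onset_time",
            "flow_rate", "pixel_size")
  if (!all(need %in% names(truth)) ||
      any(!vapply(truth[need], function(x) length(x) == 1 && is.finite(as.numeric(x)), TRUE))) {
    stop("truth manifest corrupted or incomplete")
  }
  if (is.null(tissue)) {
    tissue <- tissue_parameters(epsilon = truth$epsilon,
                                lag_volume = truth$lag_volume,
                                mu_abs = truth$mu_abs)
  }
  px_mm <- truth$pixel_size / 1000
  frame_int <- yaml::read_yaml(file.path(input_dir,
                                         "protocol.yml"))$frame_interval
  tol <- merge_config(list(semi_axis_mm = 2 * px_mm, anisotropy_abs = 0.05,
                           onset_s = frame_int, k_rel = 0.1), tolerances)

  res <- run_analysis(input_dir, file.path(out_dir, "analysis"),
                      tissue = tissue, options = options)
  trace <- res$trace
  ir <- trace[trace$region == "IR" & is.finite(trace$wf_h) &
              is.finite(trace$wf_v), , drop = FALSE]
  if (nrow(ir) == 0) stop("no usable injection-region samples recovered")
  last <- ir[nrow(ir), ]
  ar_ir <- res$aspect$IR$mean

  p <- injection_pressure(truth$flow_rate, "uL/min")
  k_true <- permeability_darcy(truth$flow_rate, truth$final_a_h / 1000, p)
  k_est <- if (is.null(res$permeability)) NA_real_ else
    res$permeability$k_horizontal

  rows <- list(
    list("final_a_h_mm", truth$final_a_h, last$wf_h,
         abs(last$wf_h - truth$final_a_h), tol$semi_axis_mm),
    list("final_a_v_mm", truth$final_a_v, last$wf_v,
         abs(last$wf_v - truth$final_a_v), tol$semi_axis_mm),
    list("anisotropy", truth$anisotropy, ar_ir,
         abs(ar_ir - truth$anisotropy), tol$anisotropy_abs),
    list("onset_s", truth$onset_time, res$onset,
         abs(res$onset - truth$onset_time), tol$onset_s),
    list("k_equivalent", k_true, k_est,
         abs(k_est - k_true) / k_true, tol$k_rel)
  )
  cmp <- do.call(rbind, lapply(rows, function(r) {
    data.frame(quantity = r[[1]], truth = r[[2]], estimate = r[[3]],
               error = r[[4]], tol = r[[5]],
               pass = is.finite(r[[4]]) && r[[4]] <= r[[5]])
  }))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cmp, file.path(out_dir, "recover.tsv"))
  attr(cmp, "ok") <- all(cmp$pass)
  cmp
}

#' Command-line entry point
#'
#' Implements the `simulate`, `analyze` and `recover` verbs used by the
#' `inst/cli/depotr.R` wrapper script. Flags: `--config` (scenario YAML,
#' simulate only), `--input`, `--out`, `--seed`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 on success, 1 on usage errors, 2 on
#'   data/processing errors.
#' @export
cli_main <- function(args) {
  usage <- function() {
    cat("usage: depotr <simulate|analyze|recover> [--config F] [--input D]",
        "[--out D] [--seed N]\n")
    1L
  }
  if (length(args) < 1) return(usage())
  verb <- args[1]
  if (!verb %in% c("simulate", "analyze", "recover")) return(usage())
  flags <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- rest[i]
    if (!startsWith(key, "--") || i == length(rest)) return(usage())
    flags[[substring(key, 3)]] <- rest[i + 1]
    i <- i + 2
  }
  if (is.null(flags$out)) return(usage())
  status <- tryCatch({
    if (verb == "simulate") {
      if (is.null(flags$config)) return(usage())
      run_simulate(flags$config, flags$out,
                   seed = if (!is.null(flags$seed))
                     as.integer(flags$seed) else NULL)
    } else if (verb == "analyze") {
      if (is.null(flags$input)) return(usage())
      run_analysis(flags$input, flags$out)
    } else {
      if (is.null(flags$input)) return(usage())
      cmp <- run_recover(flags$input, flags$out)
      if (!isTRUE(attr(cmp, "ok"))) {
        message("recovery FAILED for: ",
                paste(cmp$quantity[!cmp$pass], collapse = ", "))
        return(2L)
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  status
}
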