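# The descriptor pipeline: analyze_frames() turns a trajectory into the
# per-frame descriptor table (the package's central object), and the
# run_generate / run_analyze / run_report stages orchestrate a reproducible
# generate -> analyze -> report workflow from a single configuration.

#' Analyze a helix-dimer trajectory into per-frame descriptors
#'
#' For every frame: the signed crossing angle (negative = left-handed
#' packing), lateral separation L, the N/C-termini distance difference
#' delta-d, the unwrapped helix rotations dtheta_A / dtheta_B relative to
#' frame 0, and the dimerization state classified from L.
#'
#' @param frames a `dimer_frames` trajectory (>= 2 frames for rotation
#'   series; a single frame yields NA rotations).
#' @param L_mode lateral separation mode, `"center"` (default) or
#'   `"min_pair"`.
#' @param residues internal residue indices averaged for the helix
#'   rotations (default 1:25, the TMD core).
#' @param strict require 28 beads per helix for the segmented axes.
#' @param fallback_threshold |Omega| in degrees below which the midpoint
#'   rotation reference is used.
#' @return object of class `dimer_descriptors` (a data.frame) with columns
#'   time, omega_deg, L_nm, delta_d_nm, dtheta_A_deg, dtheta_B_deg, state,
#'   and attribute `conventions` recording every convention in force.
#' @examples
#' wp <- data.frame(time = c(0, 10), crossing = c(-25, -25),
#'                  spinB = c(0, 90))
#' tr <- generate_trajectory(trajectory_script(wp, seed = 1), dt = 1)
#' d <- analyze_frames(tr)
#' summary(d)
#' @export
analyze_frames <- function(frames, L_mode = c("center", "min_pair"),
                           residues = 1:25, strict = TRUE,
                           fallback_threshold = 14.4) {
  L_mode <- match.arg(L_mode)
  if (!inherits(frames, "dimer_frames"))
    stop("'frames' must be a dimer_frames object", call. = FALSE)
  nf <- length(frames)
  geo <- lapply(seq_len(nf), function(s)
    frame_geometry(frames[[s]], L_mode = L_mode))
  if (nf >= 2L) {
    rot <- rotation_timeseries(frames, residues = residues, strict = strict,
                               fallback_threshold = fallback_threshold)
    dA <- rot$dtheta_A; dB <- rot$dtheta_B
  } else {
    dA <- dB <- NA_real_
  }
  L <- vapply(geo, `[[`, numeric(1L), "L")
  out <- data.frame(
    time = vapply(seq_len(nf), function(s) frames[[s]]$time, numeric(1L)),
    omega_deg = vapply(geo, `[[`, numeric(1L), "omega"),
    L_nm = L,
    delta_d_nm = vapply(geo, `[[`, numeric(1L), "delta_d"),
    dtheta_A_deg = dA,
    dtheta_B_deg = dB,
    state = as.character(classify_state(L)),
    stringsAsFactors = FALSE)
  structure(out,
            conventions = c(
              L_mode = L_mode,
              omega_sign = "negative = left-handed packing",
              rotation_sign = "CCW positive viewed from the C-terminal side",
              rotation_residues = paste(range(residues), collapse = ".."),
              fallback_threshold_deg = as.character(fallback_threshold),
              state_thresholds_nm = "1.5, 3.0"),
            class = c("dimer_descriptors", "data.frame"))
}

#' @export
print.dimer_descriptors <- function(x, ...) {
  cat(sprintf("dimer_descriptors: %d frames, time %g..%g\n",
              nrow(x), x$time[1L], x$time[nrow(x)]))
  tab <- table(x$state)
  cat("  states:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  omega: %.1f..%.1f deg; L: %.2f..%.2f nm\n",
              min(x$omega_deg), max(x$omega_deg), min(x$L_nm), max(x$L_nm)))
  invisible(x)
}

#' @export
summary.dimer_descriptors <- function(object, ...) {
  num <- object[, c("omega_deg", "L_nm", "delta_d_nm",
                    "dtheta_A_deg", "dtheta_B_deg")]
  out <- list(n_frames = nrow(object),
              descriptor_summary = do.call(rbind, lapply(num, summary)),
              state_fractions = prop.table(table(object$state)),
              conventions = attr(object, "conventions"))
  class(out) <- "summary.dimer_descriptors"
  out
}

#' @export
print.summary.dimer_descriptors <- function(x, ...) {
  cat(sprintf("Helix-dimer trajectory descriptors (%d frames)\n\n",
              x$n_frames))
  print(round(x$descriptor_summary, 3))
  cat("\nState fractions:\n")
  print(round(x$state_fractions, 3))
  cat("\nConventions:\n")
  for (nm in names(x$conventions))
    cat(sprintf("  %s: %s\n", nm, x$conventions[[nm]]))
  invisible(x)
}

#' @export
plot.dimer_descriptors <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$omega_deg, type = "l", xlab = "time",
                 ylab = expression(Omega ~ "(deg)"))
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$time, x$L_nm, type = "l", xlab = "time",
                 ylab = "L (nm)")
  graphics::abline(h = c(1.5, 3), lty = 3)
  graphics::plot(x$time, x$delta_d_nm, type = "l", xlab = "time",
                 ylab = expression(Delta * d ~ "(nm)"))
  graphics::matplot(x$time, cbind(x$dtheta_A_deg, x$dtheta_B_deg),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "time", ylab = expression(Delta * theta ~ "(deg)"))
  invisible(x)
}

#' Run configuration for the generate/analyze/report pipeline
#'
#' @param output_dir directory for all stage outputs.
#' @param script a [trajectory_script()] (for [run_generate()]).
#' @param dt frame interval.
#' @param input trajectory file analyzed by [run_analyze()] (defaults to
#'   the file written by [run_generate()]).
#' @param format input format for [read_frames()].
#' @param selection a [selection_spec()].
#' @param L_mode,fallback_threshold analysis conventions
#'   (see [analyze_frames()]).
#' @param pivot_threshold,flip_dead_band event-detection settings (degrees).
#' @param fes_T,fes_bin_width,fes_convention,fes_support free-energy grid
#'   settings (see [fes_2d()]).
#' @param regions optional named list of [region_window()]s summarized in
#'   the report.
#' @param reference_pairs optional `pair_list` for contact concordance.
#' @param contact_params kernel parameters from [rrcs_params()].
#' @param seed integer seed recorded and used by the generator.
#' @return object of class `run_config`.
#' @export
run_config <- function(output_dir, script = NULL, dt = 1, input = NULL,
                       format = "auto", selection = selection_spec(),
                       L_mode = "center", fallback_threshold = 14.4,
                       pivot_threshold = 45, flip_dead_band = 5,
                       fes_T = 323, fes_bin_width = 5,
                       fes_convention = "per_bin",
                       fes_support = c(-180, 360),
                       regions = NULL, reference_pairs = NULL,
                       contact_params = rrcs_params("cg"), seed = 1L) {
  stopifnot_scalar(pivot_threshold, "pivot_threshold", positive = TRUE)
  stopifnot_scalar(flip_dead_band, "flip_dead_band", nonneg = TRUE)
  structure(list(output_dir = output_dir, script = script, dt = dt,
                 input = input, format = format, selection = selection,
                 L_mode = L_mode, fallback_threshold = fallback_threshold,
                 pivot_threshold = pivot_threshold,
                 flip_dead_band = flip_dead_band, fes_T = fes_T,
                 fes_bin_width = fes_bin_width,
                 fes_convention = fes_convention, fes_support = fes_support,
                 regions = regions, reference_pairs = reference_pairs,
                 contact_params = contact_params, seed = as.integer(seed)),
            class = "run_config")
}

cfg_path <- function(config, name) file.path(config$output_dir, name)

ensure_outdir <- function(config) {
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  invisible(config$output_dir)
}

#' Generate stage: write a scripted trajectory and its ground truth
#'
#' Writes the scripted trajectory as a multi-model PDB (`trajectory.pdb`)
#' and a machine-readable ground-truth sidecar (`ground_truth.json`)
#' echoing the waypoint poses, noise settings and seed verbatim.
#'
#' @param config a [run_config()] with a `script`.
#' @return list with `trajectory` and `sidecar` paths, invisibly.
#' @export
run_generate <- function(config) {
  if (!inherits(config, "run_config"))
    stop("'config' must be a run_config", call. = FALSE)
  if (!inherits(config$script, "trajectory_script"))
    stop("config$script must be a trajectory_script", call. = FALSE)
  ensure_outdir(config)
  frames <- generate_trajectory(config$script, dt = config$dt)
  traj <- cfg_path(config, "trajectory.pdb")
  write_frames_pdb(frames, traj)
  sidecar <- cfg_path(config, "ground_truth.json")
  jsonlite::write_json(list(
    waypoints = config$script$waypoints,
    noise_sd = config$script$noise_sd,
    bend_amplitude = config$script$bend_amplitude,
    seed = config$script$seed, dt = config$dt,
    n_frames = length(frames)),
    sidecar, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(trajectory = traj, sidecar = sidecar))
}

#' Analyze stage: descriptor CSV from a trajectory file
#'
#' Reads the configured input (default: the file written by
#' [run_generate()]), computes the per-frame descriptors and writes
#' `descriptors.csv`. Every convention and threshold in force is recorded
#' once in the CSV header and in `run_log.txt`.
#'
#' @param config a [run_config()].
#' @return the `dimer_descriptors` table, invisibly.
#' @export
run_analyze <- function(config) {
  if (!inherits(config, "run_config"))
    stop("'config' must be a run_config", call. = FALSE)
  ensure_outdir(config)
  input <- if (is.null(config$input)) cfg_path(config, "trajectory.pdb")
           else config$input
  if (!file.exists(input))
    stop(sprintf("input trajectory '%s' does not exist", input),
         call. = FALSE)
  frames <- read_frames(input, format = config$format,
                        selection = config$selection, dt = config$dt)
  desc <- analyze_frames(frames, L_mode = config$L_mode,
                         fallback_threshold = config$fallback_threshold)
  conv <- c(attr(desc, "conventions"),
            pivot_threshold_deg = as.character(config$pivot_threshold),
            flip_dead_band_deg = as.character(config$flip_dead_band),
            fes_T_K = as.character(config$fes_T),
            fes_bin_width_deg = as.character(config$fes_bin_width),
            fes_convention = config$fes_convention)
  write_descriptors(desc, cfg_path(config, "descriptors.csv"),
                    conventions = conv)
  writeLines(c(sprintf("[%s] helixdimer %s analyze: %s (%d frames)",
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       as.character(utils::packageVersion("helixdimer")),
                       input, nrow(desc)),
               paste0(names(conv), " = ", conv)),
             cfg_path(config, "run_log.txt"))
  invisible(desc)
}

#' Report stage: aggregate descriptors, landscape, events and contacts
#'
#' Reads `descriptors.csv`, filters to dimer-scale frames, builds the
#' free-energy grid (written as `fes.csv` plus `fes_meta.json`), detects
#' pivots and handedness flips (written as `events.json` / `events.csv`),
#' summarizes any configured rotation-plane regions, and writes
#' `report.json` with state fractions, event counts, region summaries, the
#' package version and a configuration fingerprint.
#'
#' @param config a [run_config()].
#' @return the report as a list, invisibly.
#' @export
run_report <- function(config) {
  if (!inherits(config, "run_config"))
    stop("'config' must be a run_config", call. = FALSE)
  desc_path <- cfg_path(config, "descriptors.csv")
  if (!file.exists(desc_path))
    stop("missing upstream stage: run_analyze has not written descriptors.csv",
         call. = FALSE)
  desc <- read_descriptors(desc_path)
  retained <- filter_dimeric(desc, L_max = 3.0)
  fes <- if (nrow(retained)) {
    fes_2d(retained$dtheta_A_deg, retained$dtheta_B_deg, T = config$fes_T,
           bin_width = config$fes_bin_width, support = config$fes_support,
           convention = config$fes_convention)
  } else NULL
  if (!is.null(fes)) {
    utils::write.csv(fes$U, cfg_path(config, "fes.csv"), row.names = FALSE)
    jsonlite::write_json(list(edges_A = fes$edges_A, edges_B = fes$edges_B,
                              T = fes$T, convention = fes$convention),
                         cfg_path(config, "fes_meta.json"), digits = NA,
                         auto_unbox = TRUE)
  }
  pivots <- detect_pivots(desc$omega_deg, time = desc$time,
                          threshold = config$pivot_threshold)
  flips <- detect_handedness_flips(desc$omega_deg, time = desc$time,
                                   dead_band = config$flip_dead_band)
  events <- rbind(pivots, flips)
  if (nrow(desc) >= 2L) {
    series <- structure(list(time = desc$time, dtheta_A = desc$dtheta_A_deg,
                             dtheta_B = desc$dtheta_B_deg),
                        class = "rotation_series")
    events <- associate_rotations(events, series)
  }
  write_events(events, json_path = cfg_path(config, "events.json"),
               csv_path = cfg_path(config, "events.csv"))
  regions <- lapply(config$regions, function(w) region_summary(desc, w))
  state_fractions <- as.list(prop.table(table(
    factor(desc$state, levels = c("dimeric", "pre_dimeric", "monomeric")))))
  report <- list(
    package_version = as.character(utils::packageVersion("helixdimer")),
    config_hash = config_hash(paste(deparse(config[setdiff(names(config),
                                                           "script")]),
                                    collapse = "")),
    n_frames = nrow(desc),
    n_retained_dimeric = attr(retained, "n_retained"),
    state_fractions = state_fractions,
    n_pivots = nrow(pivots),
    n_handedness_flips = nrow(flips),
    events = events,
    region_summaries = regions,
    fes_file = if (!is.null(fes)) "fes.csv" else NULL)
  jsonlite::write_json(report, cfg_path(config, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
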