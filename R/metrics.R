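# Virtual thermometry, ablation-extent measurement, and the delta-T /
# percent-difference / replicate-summary statistics used to compare
# simulation against experiment.

#' Thermometry sensor log
#'
#' One channel's (time, temperature) series with its nominal probe
#' position and provenance.
#'
#' @param channel Channel label (`"T1"`, `"T2"`, ...).
#' @param nominal_position Probe position (m), length 3.
#' @param times Times (s), strictly increasing, starting at 0.
#' @param temperatures Temperatures (degC), same length as `times`.
#' @param provenance One of `"simulated"`, `"synthetic"`, `"measured"`.
#' @param nominal_distance Optional nominal radial distance from the
#'   shaft axis (m).
#' @param condition Optional condition tag (free text, e.g.
#'   `"80W_3.5min_20C"`), used by [summarize_replicates()].
#' @return An object of class `sensor_log`.
#' @export
sensor_log <- function(channel, nominal_position, times, temperatures,
                       provenance = c("simulated", "synthetic", "measured"),
                       nominal_distance = NA_real_, condition = NA_character_) {
  provenance <- match.arg(provenance)
  stopifnot(length(times) == length(temperatures), length(times) >= 1L,
            times[1] == 0, !is.unsorted(times, strictly = TRUE))
  structure(list(channel = channel, nominal_position = nominal_position,
                 times = times, temperatures = temperatures,
                 provenance = provenance,
                 nominal_distance = nominal_distance, condition = condition),
            class = "sensor_log")
}

#' Sample a temperature field at a probe
#'
#' Trilinear interpolation of every stored snapshot at the probe position.
#'
#' @param field A `temperature_field`.
#' @param probe A [probe_spec()].
#' @return A [sensor_log()] with provenance `"simulated"`.
#' @export
sample_probe <- function(field, probe) {
  grid <- field$grid
  u <- (probe$position - grid$origin) / grid$spacing
  if (any(u < 0) || any(u > grid$dim))
    stop(sprintf("probe '%s' outside grid domain", probe$name))
  st <- .trilinear_stencil(grid, probe$position)
  temps <- vapply(field$values, function(v) sum(v[st$idx] * st$w), numeric(1))
  sensor_log(channel = probe$name, nominal_position = probe$position,
             times = field$times, temperatures = temps,
             provenance = "simulated",
             nominal_distance = probe$nominal_distance)
}

#' Initial, final and change in temperature of a log
#'
#' @param log A [sensor_log()].
#' @return List with `T_initial` (first sample), `T_final` (last sample)
#'   and `delta` (`T_final - T_initial`), all degC.
#' @export
delta_T <- function(log) {
  stopifnot(inherits(log, "sensor_log"), length(log$temperatures) >= 1L)
  ti <- log$temperatures[1]
  tf <- log$temperatures[length(log$temperatures)]
  list(T_initial = ti, T_final = tf, delta = tf - ti)
}

#' Signed integer percent difference, simulation vs experiment
#'
#' `100 * (simulation_dT - experiment_dT) / experiment_dT`, rounded half
#' away from zero to an integer percent: a simulation below the experiment
#' yields a negative value.
#'
#' @param experiment_dT Experimental temperature change (degC), nonzero.
#' @param simulation_dT Simulated temperature change (degC).
#' @return Signed integer percent.
#' @export
percent_diff <- function(experiment_dT, simulation_dT) {
  if (any(experiment_dT == 0)) stop("experiment_dT must be nonzero")
  x <- 100 * (simulation_dT - experiment_dT) / experiment_dT
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Ablation extent from an isothermal contour
#'
#' Measures, on the final stored snapshot, the radial depth D of the
#' region at or above `iso_temperature` — the maximum distance from the
#' shaft axis along the radiation direction in the central cross-sectional
#' plane (through the active-zone center) — and the length L of the
#' iso-region along the shaft axis. Both use sub-voxel linear
#' interpolation across the crossing interval of a densely sampled
#' trilinear profile. An empty region yields zeros.
#'
#' @param field A `temperature_field`.
#' @param iso_temperature Isotherm (degC), e.g. 55 or 60.
#' @param pose The [applicator_pose()].
#' @return List with `depth_D` (m), `length_L` (m), `iso_temperature`.
#' @export
ablation_extent <- function(field, iso_temperature, pose) {
  grid <- field$grid
  vfinal <- field$values[[length(field$values)]]
  ac <- active_zone_center(pose)
  rd <- pose$radiation_direction
  ax <- pose$axis_direction
  step <- grid$spacing / 10

  sample_at <- function(pts) {
    apply(pts, 1, function(p) {
      u <- (p - grid$origin) / grid$spacing
      if (any(u < 0) || any(u > grid$dim)) return(NA_real_)
      st <- .trilinear_stencil(grid, p)
      sum(vfinal[st$idx] * st$w)
    })
  }
  last_crossing <- function(svals, rvals) {
    hot <- which(!is.na(svals) & svals >= iso_temperature)
    if (length(hot) == 0L) return(0)
    k <- max(hot)
    if (k == length(svals) || is.na(svals[k + 1])) return(rvals[k])
    # linear interpolation across the crossing interval
    f <- (svals[k] - iso_temperature) / (svals[k] - svals[k + 1])
    rvals[k] + f * (rvals[k + 1] - rvals[k])
  }

  # radial depth along +radiation_direction from the axis
  rmax <- sum(abs(grid$dim * grid$spacing))  # generous; clipped by domain
  rr <- seq(0, rmax, by = step)
  pts <- t(vapply(rr, function(r) ac + r * rd, numeric(3)))
  sv <- sample_at(pts)
  depth <- last_crossing(sv, rr)

  # axial extent: scan lines parallel to the axis at the hottest radial
  # offsets in the forward plane; the iso-region length is the union extent
  smax <- grid$dim[1] * grid$spacing
  ss <- seq(-smax / 2, smax / 2, by = step)
  offs <- seq(0, max(depth, grid$spacing), by = grid$spacing / 2)
  lo <- Inf; hi <- -Inf
  for (ro in offs) {
    base <- ac + ro * rd
    pts <- t(vapply(ss, function(s) base + s * ax, numeric(3)))
    sv <- sample_at(pts)
    hot <- which(!is.na(sv) & sv >= iso_temperature)
    if (length(hot) == 0L) next
    k1 <- min(hot); k2 <- max(hot)
    s_lo <- if (k1 == 1L || is.na(sv[k1 - 1])) ss[k1] else {
      f <- (sv[k1] - iso_temperature) / (sv[k1] - sv[k1 - 1])
      ss[k1] + f * (ss[k1 - 1] - ss[k1])
    }
    s_hi <- if (k2 == length(ss) || is.na(sv[k2 + 1])) ss[k2] else {
      f <- (sv[k2] - iso_temperature) / (sv[k2] - sv[k2 + 1])
      ss[k2] + f * (ss[k2 + 1] - ss[k2])
    }
    lo <- min(lo, s_lo); hi <- max(hi, s_hi)
  }
  len <- if (is.finite(lo) && is.finite(hi)) hi - lo else 0

  list(depth_D = depth, length_L = len, iso_temperature = iso_temperature)
}

#' Summarize replicate logs and extents per condition
#'
#' Computes mean and sample standard deviation (n-1 denominator) of the
#' initial temperature, final temperature, temperature change and nominal
#' placement distance per (condition, channel), plus the visible-extent
#' D/L summaries per condition when extents are supplied. With a single
#' replicate the mean is reported and the standard deviation is `NA`
#' (flagged unavailable).
#'
#' @param logs List of [sensor_log()]s carrying `condition` tags.
#' @param extents Optional list of extents (each a list with `depth_D`,
#'   `length_L` and a `condition` element).
#' @return A `data.frame` with one row per (condition, channel) and, if
#'   extents are given, attribute `"extents"` holding the per-condition
#'   D/L summary.
#' @export
summarize_replicates <- function(logs, extents = NULL) {
  stopifnot(length(logs) >= 1L)
  rows <- do.call(rbind, lapply(logs, function(lg) {
    d <- delta_T(lg)
    data.frame(condition = lg$condition, channel = lg$channel,
               T_initial = d$T_initial, T_final = d$T_final,
               delta = d$delta, distance = lg$nominal_distance,
               stringsAsFactors = FALSE)
  }))
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = if (length(x) >= 2L) stats::sd(x) else NA_real_)
  }
  grp <- split(rows, list(rows$condition, rows$channel), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(condition = g$condition[1], channel = g$channel[1], n = nrow(g),
               T_initial_mean = msd(g$T_initial)["mean"],
               T_initial_sd = msd(g$T_initial)["sd"],
               T_final_mean = msd(g$T_final)["mean"],
               T_final_sd = msd(g$T_final)["sd"],
               delta_mean = msd(g$delta)["mean"],
               delta_sd = msd(g$delta)["sd"],
               distance_mean = msd(g$distance)["mean"],
               distance_sd = msd(g$distance)["sd"],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(extents)) {
    erows <- do.call(rbind, lapply(extents, function(e) {
      data.frame(condition = if (!is.null(e$condition)) e$condition else NA,
                 depth_D = e$depth_D, length_L = e$length_L,
                 stringsAsFactors = FALSE)
    }))
    egrp <- split(erows, erows$condition, drop = TRUE)
    esum <- do.call(rbind, lapply(egrp, function(g) {
      data.frame(condition = g$condition[1], n = nrow(g),
                 D_mean = msd(g$depth_D)["mean"], D_sd = msd(g$depth_D)["sd"],
                 L_mean = msd(g$length_L)["mean"], L_sd = msd(g$length_L)["sd"],
                 stringsAsFactors = FALSE)
    }))
    rownames(esum) <- NULL
    attr(out, "extents") <- esum
  }
  out
}

#' Build the experiment-vs-simulation comparison table
#'
#' Joins experimental and simulated temperature changes by condition and
#' channel and computes the signed integer percent difference for each
#' row. Unmatched conditions are reported (message) and skipped.
#'
#' @param experiment `data.frame` with columns `condition`, `channel`,
#'   `delta` (degC).
#' @param simulation `data.frame` with the same columns.
#' @return `data.frame` with columns `condition`, `channel`,
#'   `experiment_dT`, `simulation_dT`, `percent_diff`.
#' @export
build_comparison_table <- function(experiment, simulation) {
  key <- function(d) paste(d$condition, d$channel, sep = "|")
  ek <- key(experiment); sk <- key(simulation)
  common <- intersect(ek, sk)
  dropped <- setdiff(union(ek, sk), common)
  if (length(dropped) > 0L)
    message("unmatched condition/channel pairs skipped: ",
            paste(dropped, collapse = ", "))
  idx_e <- match(common, ek); idx_s <- match(common, sk)
  out <- data.frame(condition = experiment$condition[idx_e],
                    channel = experiment$channel[idx_e],
                    experiment_dT = experiment$delta[idx_e],
                    simulation_dT = simulation$delta[idx_s],
                    stringsAsFactors = FALSE)
  out$percent_diff <- percent_diff(out$experiment_dT, out$simulation_dT)
  out
}

#' Write sensor logs to CSV
#'
#' Long format with columns `time_s`, `channel`, `temperature_C`.
#'
#' @param logs List of [sensor_log()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_logs <- function(logs, path) {
  d <- do.call(rbind, lapply(logs, function(lg) {
    data.frame(time_s = lg$times, channel = lg$channel,
               temperature_C = lg$temperatures, stringsAsFactors = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read sensor logs from CSV
#'
#' Inverse of [write_sensor_logs()]; positions and distances are not
#' stored in the CSV and come back as `NA`.
#'
#' @param path CSV with columns `time_s`, `channel`, `temperature_C`.
#' @param provenance Provenance tag for the logs, default `"measured"`.
#' @return Named list of [sensor_log()]s, one per channel.
#' @export
read_sensor_logs <- function(path, provenance = "measured") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$channel), function(g) {
    g <- g[order(g$time_s), ]
    sensor_log(channel = g$channel[1], nominal_position = rep(NA_real_, 3),
               times = g$time_s, temperatures = g$temperature_C,
               provenance = provenance)
  })
}
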