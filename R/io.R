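# File formats: tab-delimited motion-storage tables (STO/MOT dialect) for
# trajectories, YAML for run configuration, CSV/JSON for results.
#
# Internally the package is strictly SI (m, rad, N, Nm, s). Degrees exist
# only at the motion-file boundary, governed by the inDegrees header flag.

#' Motion-storage table
#'
#' A time-stamped numeric table in the tab-delimited motion-storage dialect
#' (STO/MOT-style): a small key-value header (`name`, `nRows`, `nColumns`,
#' `inDegrees`), an `endheader` line, one line of column labels (first
#' column `time`), then the numeric matrix.
#'
#' @param data data.frame whose first column is `time` (s), strictly
#'   increasing; remaining columns numeric.
#' @param name table name written to the header.
#' @param in_degrees logical; if `TRUE`, angular columns are in degrees on
#'   disk (they are converted to radians by [read_motion()]).
#' @return An object of class `motion_table`.
#' @export
motion_table <- function(data, name = "motion", in_degrees = FALSE) {
  if (!is.data.frame(data) || ncol(data) < 1L)
    stopf("data must be a data.frame with a time column")
  if (names(data)[1L] != "time") stopf("first column must be 'time'")
  tm <- data$time
  if (any(!is.finite(tm)) || any(diff(tm) <= 0))
    stopf("time column must be finite and strictly increasing")
  structure(list(data = data, name = name, in_degrees = in_degrees),
            class = "motion_table")
}

#' Write a motion-storage table
#'
#' @param table a [motion_table()].
#' @param path output file path.
#' @param digits significant digits written (declared precision of the
#'   round-trip).
#' @return `path`, invisibly.
#' @export
write_motion <- function(table, path, digits = 10) {
  stopifnot(inherits(table, "motion_table"))
  d <- table$data
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(table$name,
               sprintf("nRows=%d", nrow(d)),
               sprintf("nColumns=%d", ncol(d)),
               sprintf("inDegrees=%s", if (table$in_degrees) "yes" else "no"),
               "endheader",
               paste(names(d), collapse = "\t")), con)
  m <- vapply(d, function(col) formatC(col, digits = digits, format = "g"),
              character(nrow(d)))
  if (nrow(d) == 1L) m <- matrix(m, nrow = 1L)
  writeLines(apply(m, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a motion-storage table
#'
#' Angular columns (any label not matching ground reaction, center of
#' pressure or time) are converted from degrees to radians when the header
#' declares `inDegrees=yes`; the returned table is always in SI units.
#'
#' @param path file path.
#' @return A [motion_table()] (with `in_degrees = FALSE`, since values are
#'   converted on read).
#' @export
read_motion <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", trimws(lines))
  if (is.na(end)) stopf("malformed header in %s: no endheader line", path)
  header <- lines[seq_len(end - 1L)]
  kv <- grep("=", header, value = TRUE)
  keys <- sub("=.*", "", kv); vals <- sub(".*=", "", kv)
  name <- if (end >= 2L && !grepl("=", lines[1L])) trimws(lines[1L]) else "motion"
  in_deg <- tolower(trimws(vals[match("inDegrees", keys)])) %in% c("yes", "true")
  in_deg <- isTRUE(in_deg)
  labels <- strsplit(trimws(lines[end + 1L]), "[\t ]+")[[1L]]
  body <- lines[seq.int(end + 2L, length(lines))]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "[\t ]+")
  nc <- lengths(rows)
  if (any(nc != length(labels))) {
    bad <- which(nc != length(labels))[1L]
    stopf("ragged row at line %d of %s: %d fields, expected %d",
          end + 1L + bad, path, nc[bad], length(labels))
  }
  m <- matrix(as.numeric(unlist(rows)), ncol = length(labels), byrow = TRUE)
  if (any(!is.finite(m))) stopf("non-numeric value in %s", path)
  d <- as.data.frame(m)
  names(d) <- labels
  if (names(d)[1L] != "time") stopf("first column of %s must be 'time'", path)
  if (any(diff(d$time) <= 0)) stopf("non-monotone time column in %s", path)
  if (in_deg) {
    ang <- setdiff(names(d), "time")
    ang <- ang[!grepl("^(grf|cop|force|moment)", ang)]
    for (a in ang) d[[a]] <- d[[a]] * pi / 180
  }
  declared <- suppressWarnings(as.integer(vals[match("nRows", keys)]))
  if (!is.na(declared) && declared != nrow(d))
    stopf("header of %s declares %d rows but %d found", path, declared, nrow(d))
  motion_table(d, name = name, in_degrees = FALSE)
}

# ---------------------------------------------------------------------------
# Run configuration

# canonical units for validated blocks; configuration files may restate them
# but may not contradict them
.afosim_units <- list(
  k_trans = "N/m", k_rot = "Nm/rad",
  c_trans = "N/(m/s)", c_rot = "Nm/(rad/s)",
  mass = "kg", length = "m", torque = "Nm", time = "s")

#' Default run configuration
#'
#' Complete configuration with every default filled in: interface element
#' parameters per region, segment and shell properties, the auxiliary-body
#' mass (1e-05 kg), controller gains and task weights (knee and ankle
#' weighted 10, all other coordinates 1), the misalignment magnitude
#' (0.02 m), the number of bootstrap interpolation steps (10), the
#' experiment grid, synthetic-gait parameters and residual thresholds.
#'
#' @return A nested list of class `afo_config`.
#' @export
default_config <- function() {
  cfg <- list(
    model = list(
      body_mass = 72, body_height = 1.76,
      thigh_length = 0.431, shank_length = 0.433, ankle_height = 0.08,
      segments = list(
        foot = list(mass = 1.05, inertia = 0.0050,
                    com = c(0.05, -0.04, 0)),
        foot_shell = list(mass = 0.15, inertia = 0.0020,
                          com = c(0.06, -0.05, 0)),
        calf_shell = list(mass = 0.25, inertia = 0.0040,
                          com = c(-0.03, 0.22, 0)),
        aux_body = list(mass = 1e-05)),
      interface = list(
        tibia = list(k_trans = c(100, 10000, 100),
                     k_rot = c(200, 500, 200),
                     c_trans = c(5, 5, 5), c_rot = c(5, 5, 5),
                     units = list(k_trans = "N/m", k_rot = "Nm/rad",
                                  c_trans = "N/(m/s)", c_rot = "Nm/(rad/s)")),
        foot = list(k_trans = c(10000, 500, 500),
                    k_rot = c(500, 200, 200),
                    c_trans = c(5, 5, 5), c_rot = c(5, 5, 5),
                    units = list(k_trans = "N/m", k_rot = "Nm/rad",
                                 c_trans = "N/(m/s)", c_rot = "Nm/(rad/s)"))),
      anchors = list(
        foot_instep = c(0.09, -0.02, 0), foot_heel = c(-0.05, -0.05, 0),
        shank_strap = c(0.03, 0.25, 0), shank_rim = c(-0.04, 0.30, 0)),
      markers = list(
        foot = c(0.10, -0.02, 0), shank = c(-0.04, 0.28, 0)),
      muscles = list(
        plantarflexors = list(f_max_iso = 4000, moment_arm = 0.05,
                              tau_act = 0.015, tau_deact = 0.05),
        dorsiflexors = list(f_max_iso = 1200, moment_arm = 0.04,
                            tau_act = 0.015, tau_deact = 0.05)),
      misalignment = c(0, 0, 0)),
    controller = list(
      k_p = 2500, k_v = 100, dt = 0.001, record_dt = 0.01,
      task_weights = list(ankle = 10, knee = 10, other = 1),
      reserve_scale = 2, reserve_penalty = 1,
      n_bootstrap_steps = 10, settle_time = 1.2, settle_tol = 1e-3,
      gravity = 9.81),
    gait = list(
      cycle_duration = list(slow = 1.25, medium = 1.05, fast = 0.90),
      stride_speed = list(slow = 1.00, medium = 1.25, fast = 1.50),
      stance_fraction = list(slow = 0.62, medium = 0.60, fast = 0.58),
      grf_peak_bw = list(slow = 1.04, medium = 1.08, fast = 1.12),
      amplitude_scale = list(slow = 0.95, medium = 1.00, fast = 1.08),
      jitter_angle_deg = 0.8, jitter_grf_frac = 0.02,
      support_smooth_frac = 0.05),
    experiment = list(
      levels = c("PF25", "PF50", "PF75", "PF100"),
      speeds = c("slow", "medium", "fast"),
      directions = c("zero", "front", "back", "up", "down",
                     "inside", "outside"),
      misalignment_magnitude = 0.02,
      n_subjects = 1),
    thresholds = list(
      residual_force_frac = 0.05, residual_moment = 25))
  structure(cfg, class = "afo_config", user_keys = character())
}

#' @noRd
validate_config <- function(cfg) {
  for (site in c("tibia", "foot")) {
    blk <- cfg$model$interface[[site]]
    for (nm in c("k_trans", "k_rot", "c_trans", "c_rot")) {
      v <- blk[[nm]]
      if (length(v) != 3L || !all(is.finite(v)))
        stopf("model.interface.%s.%s must be 3 finite numbers", site, nm)
      if (any(v < 0))
        stopf("model.interface.%s.%s: negative coefficient", site, nm)
      u <- blk$units[[nm]]
      if (!is.null(u) && !identical(u, .afosim_units[[nm]]))
        stopf("unit mismatch for model.interface.%s.%s: '%s' (expected '%s')",
              site, nm, u, .afosim_units[[nm]])
    }
  }
  for (seg in names(cfg$model$segments)) {
    m <- cfg$model$segments[[seg]]$mass
    if (!is.finite(m) || m <= 0)
      stopf("model.segments.%s.mass must be positive", seg)
  }
  with(cfg$controller, {
    if (dt <= 0 || record_dt < dt) stopf("controller.dt/record_dt invalid")
    if (k_p <= 0 || k_v <= 0) stopf("controller gains must be positive")
  })
  for (w in cfg$controller$task_weights)
    if (!is.finite(w) || w <= 0) stopf("task weights must be positive")
  if (cfg$experiment$misalignment_magnitude < 0)
    stopf("experiment.misalignment_magnitude must be >= 0")
  if (cfg$thresholds$residual_force_frac <= 0 ||
      cfg$thresholds$residual_moment <= 0)
    stopf("thresholds must be positive")
  invisible(cfg)
}

#' @noRd
flatten_keys <- function(x, path = "") {
  if (!is.list(x)) return(path)
  unlist(lapply(names(x), function(nm)
    flatten_keys(x[[nm]], if (nzchar(path)) paste0(path, ".", nm) else nm)))
}

#' Load a run configuration
#'
#' Reads a YAML configuration document, merges it over [default_config()]
#' (unknown keys are rejected, naming the offending field), validates units
#' and value ranges, and records which fields were user-supplied.
#'
#' @param path YAML file path, or `NULL` for the pure default configuration.
#' @return A validated `afo_config`; `attr(, "user_keys")` lists the fields
#'   that came from the file rather than from the defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  user <- character()
  if (!is.null(path)) {
    doc <- yaml::read_yaml(path)
    if (!is.null(doc)) {
      # yaml reads numeric vectors as lists of scalars; normalise leaves
      doc <- rapply(doc, function(x) x, how = "replace")
      doc <- simplify_numeric(doc)
      cfg2 <- merge_config(unclass(cfg), doc)
      user <- flatten_keys(doc)
      cfg <- structure(cfg2, class = "afo_config")
    }
  }
  attr(cfg, "user_keys") <- user
  validate_config(cfg)
  cfg
}

# collapse YAML lists of scalars back into numeric vectors
#' @noRd
simplify_numeric <- function(x) {
  if (!is.list(x)) return(x)
  if (length(x) > 0L && is.null(names(x)) &&
      all(vapply(x, function(e) is.numeric(e) && length(e) == 1L, logical(1))))
    return(as.numeric(x))
  lapply(x, simplify_numeric)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical serialized configuration; written into every
#' result artifact so that runs are traceable and reproducibility checks
#' (identical hash + seed implies identical results) are possible.
#'
#' @param cfg an `afo_config`.
#' @return Character MD5 hex digest.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(unclass(cfg), control = "all"), tf)
  unname(tools::md5sum(tf))
}
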