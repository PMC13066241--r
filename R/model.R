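# Coupled sagittal-plane human-leg + AFO multibody model.
#
# Frame convention (used everywhere in the package): x anterior, y vertical
# (up), z the ankle flexion axis (mediolateral), right-handed. Dorsiflexion
# is a positive rotation about z, plantarflexion negative.
#
# Topology: a massless-in-practice auxiliary body (1e-05 kg) is attached to
# the ankle joint center (plus any misalignment offset) by a joint that is
# free in the three translations and locked in rotation; the foot shell and
# calf shell are each pinned to the auxiliary body about z at the device
# center of rotation; four viscoelastic interface elements (two per region)
# couple the shells to the foot and tibia at strap/landmark anchor points.
# With zero offset the device rotation axis coincides with the ankle axis.
#
# Free coordinates: ankle rz (tracked), auxiliary tx, ty, tz, foot-shell rz,
# calf-shell rz. The knee and hip are prescribed base coordinates.

#' Assemble the coupled leg + orthosis model
#'
#' Builds the sagittal-plane model of foot, shank (prescribed base), device
#' shells, auxiliary body and the four interface elements from a run
#' configuration. Anchor points and markers come from the configuration;
#' shell-side anchors are placed so that segment and shell frames coincide
#' in the neutral pose (interface elements are unloaded at build time).
#'
#' @param config an `afo_config` (see [default_config()]), or `NULL` for
#'   defaults.
#' @return An object of class `afo_model`.
#' @export
build_model <- function(config = NULL) {
  if (is.null(config)) config <- default_config()
  stopifnot(inherits(config, "afo_config"))
  mc <- config$model
  for (f in c("body_mass", "thigh_length", "shank_length"))
    if (is.null(mc[[f]])) stopf("missing model field: %s", f)
  segs <- mc$segments
  for (s in c("foot", "foot_shell", "calf_shell", "aux_body"))
    if (is.null(segs[[s]])) stopf("missing segment parameters: %s", s)

  bushing_of <- function(site) {
    blk <- mc$interface[[site]]
    bushing_params(blk$k_trans, blk$k_rot, blk$c_trans, blk$c_rot)
  }
  # two elements per region, at the strap/landmark anchor points
  elements <- list(
    list(name = "foot_instep", site = "foot", segment = "foot",
         shell = "foot_shell", params = bushing_of("foot"),
         r_seg = mc$anchors$foot_instep),
    list(name = "foot_heel", site = "foot", segment = "foot",
         shell = "foot_shell", params = bushing_of("foot"),
         r_seg = mc$anchors$foot_heel),
    list(name = "shank_strap", site = "tibia", segment = "tibia",
         shell = "calf_shell", params = bushing_of("tibia"),
         r_seg = mc$anchors$shank_strap),
    list(name = "shank_rim", site = "tibia", segment = "tibia",
         shell = "calf_shell", params = bushing_of("tibia"),
         r_seg = mc$anchors$shank_rim))

  muscles <- list(
    plantarflexors = list(
      f_max_iso = mc$muscles$plantarflexors$f_max_iso,
      moment_arm = mc$muscles$plantarflexors$moment_arm,
      sign = -1, w = 1,
      tau_act = mc$muscles$plantarflexors$tau_act,
      tau_deact = mc$muscles$plantarflexors$tau_deact),
    dorsiflexors = list(
      f_max_iso = mc$muscles$dorsiflexors$f_max_iso,
      moment_arm = mc$muscles$dorsiflexors$moment_arm,
      sign = +1, w = 1,
      tau_act = mc$muscles$dorsiflexors$tau_act,
      tau_deact = mc$muscles$dorsiflexors$tau_deact))

  joints <- list(
    ankle = list(parent = "shank", child = "foot", free = "rz"),
    aux_joint = list(parent = "shank", child = "aux_body",
                     free = c("tx", "ty", "tz"), locked = c("rx", "ry", "rz")),
    foot_shell_pin = list(parent = "aux_body", child = "foot_shell",
                          free = "rz"),
    calf_shell_pin = list(parent = "aux_body", child = "calf_shell",
                          free = "rz"))

  model <- structure(list(
    config = config,
    body_mass = mc$body_mass,
    thigh_length = mc$thigh_length, shank_length = mc$shank_length,
    ankle_height = mc$ankle_height,
    segments = segs, joints = joints, muscles = muscles,
    elements = elements,
    markers = mc$markers,
    misalignment = as.numeric(mc$misalignment),
    weakening_level = "healthy",
    gravity = config$controller$gravity),
    class = "afo_model")
  model
}

#' @export
print.afo_model <- function(x, ...) {
  cat(sprintf(
    "<afo_model> %s | %d interface elements | misalignment (%g, %g, %g) m\n",
    x$weakening_level, length(x$elements),
    x$misalignment[1], x$misalignment[2], x$misalignment[3]))
  cat(sprintf("  plantarflexors w = %.2f, dorsiflexors w = %.2f\n",
              x$muscles$plantarflexors$w, x$muscles$dorsiflexors$w))
  invisible(x)
}

#' Apply a foot-drop weakening level
#'
#' Patient variants paralyze the dorsiflexors (0% maximum isometric force)
#' and retain 25/50/75/100% of plantarflexor maximum isometric force for
#' PF25/PF50/PF75/PF100. Only the weakening factors change; mass
#' properties, geometry and interface parameters are untouched. The
#' operation is idempotent.
#'
#' @param model an `afo_model`.
#' @param level one of `"PF25"`, `"PF50"`, `"PF75"`, `"PF100"`.
#' @return The modified model.
#' @export
apply_weakening <- function(model, level) {
  stopifnot(inherits(model, "afo_model"))
  levels <- c(PF25 = 0.25, PF50 = 0.50, PF75 = 0.75, PF100 = 1.00)
  if (!is.character(level) || length(level) != 1L || !(level %in% names(levels)))
    stopf("unknown weakening level '%s'; valid levels: %s",
          as.character(level)[1L], paste(names(levels), collapse = ", "))
  model$muscles$plantarflexors$w <- unname(levels[[level]])
  model$muscles$dorsiflexors$w <- 0
  model$weakening_level <- level
  model
}

#' Shift the device axis relative to the ankle axis
#'
#' Misalignment is realized, as in the modeling concept, by shifting the
#' auxiliary body (which carries the device center of rotation) relative to
#' the ankle joint axis: front/back are +/- x (anterior/posterior), up/down
#' +/- y (proximal/distal), inside/outside -/+ z (medial/lateral). The
#' shells keep their anchor points on the leg, so the interface elements
#' remain unloaded in the neutral pose; only the pivot moves. Nothing else
#' in the model changes.
#'
#' @param model an `afo_model`.
#' @param direction one of `"zero"`, `"front"`, `"back"`, `"up"`, `"down"`,
#'   `"inside"`, `"outside"`.
#' @param magnitude offset magnitude in meters (default 0.02).
#' @return The modified model.
#' @export
apply_misalignment <- function(model, direction, magnitude = 0.02) {
  stopifnot(inherits(model, "afo_model"))
  dirs <- list(zero = c(0, 0, 0), front = c(1, 0, 0), back = c(-1, 0, 0),
               up = c(0, 1, 0), down = c(0, -1, 0),
               inside = c(0, 0, -1), outside = c(0, 0, 1))
  if (!is.character(direction) || length(direction) != 1L ||
      !(direction %in% names(dirs)))
    stopf("unknown misalignment direction '%s'; valid: %s",
          as.character(direction)[1L], paste(names(dirs), collapse = ", "))
  if (!is.finite(magnitude) || magnitude < 0)
    stopf("misalignment magnitude must be >= 0")
  off <- if (direction == "zero") c(0, 0, 0) else dirs[[direction]] * magnitude
  model$misalignment <- off
  model$misalignment_direction <- direction
  model
}

#' Marker pairs for relative-movement readout
#'
#' One marker is defined at the origin of each shell and a twin marker at
#' the same location on the corresponding body segment (foot region on the
#' toe/foot body, shank region on the tibia), so both markers of a pair
#' coincide in the model's initial state. Relative movement is the
#' displacement of the shell marker from its segment twin, expressed in the
#' segment frame.
#'
#' @param model an `afo_model`.
#' @return A list of two pairs, each with the segment, the shell, and the
#'   marker location (segment frame, m).
#' @export
marker_pairs <- function(model) {
  stopifnot(inherits(model, "afo_model"))
  list(
    foot = list(segment = "foot", shell = "foot_shell",
                r_seg = as.numeric(model$markers$foot)),
    shank = list(segment = "tibia", shell = "calf_shell",
                 r_seg = as.numeric(model$markers$shank)))
}

#' Create the four foot-drop patient variants
#'
#' Derives the PF25, PF50, PF75 and PF100 patient models (dorsiflexors
#' paralyzed in all of them) from a base model, which is left untouched.
#'
#' @param base_model an `afo_model`.
#' @return Named list of four `afo_model`s (PF25, PF50, PF75, PF100).
#' @export
patient_variants <- function(base_model) {
  stopifnot(inherits(base_model, "afo_model"))
  levels <- c("PF25", "PF50", "PF75", "PF100")
  stats::setNames(lapply(levels, function(l) apply_weakening(base_model, l)),
                  levels)
}
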