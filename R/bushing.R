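# Viscoelastic 6-DOF interface elements ("bushings").
#
# Each element couples a device shell to a body segment through three
# translational and three rotational spring-damper pairs acting per axis.
# The element penalizes the pose deviation of the shell-side frame from the
# segment-side frame; rotations use a fixed-order small-angle (x, y, z)
# convention so the per-axis law is well defined.

#' Interface element parameters
#'
#' Bundles the twelve coefficients of one viscoelastic interface element:
#' per-axis translational stiffness (N/m), rotational stiffness (Nm/rad),
#' translational damping (N/(m/s)) and rotational damping (Nm/(rad/s)).
#'
#' @param k_trans numeric length-3, translational stiffness per axis, N/m.
#' @param k_rot numeric length-3, rotational stiffness per axis, Nm/rad.
#' @param c_trans numeric length-3, translational damping per axis, N/(m/s).
#' @param c_rot numeric length-3, rotational damping per axis, Nm/(rad/s).
#' @return An object of class `bushing_params`.
#' @seealso [default_interface_params()] for the body-region defaults.
#' @export
bushing_params <- function(k_trans, k_rot, c_trans, c_rot) {
  p <- list(k_trans = as.numeric(k_trans), k_rot = as.numeric(k_rot),
            c_trans = as.numeric(c_trans), c_rot = as.numeric(c_rot))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 3L) stopf("%s must have length 3 (x, y, z)", nm)
    if (!all(is.finite(v))) stopf("%s contains non-finite values", nm)
    if (any(v < 0)) stopf("%s contains negative coefficients", nm)
  }
  structure(p, class = "bushing_params")
}

#' @export
print.bushing_params <- function(x, ...) {
  cat("<bushing_params>\n")
  m <- rbind(`k_trans [N/m]` = x$k_trans, `k_rot [Nm/rad]` = x$k_rot,
             `c_trans [N/(m/s)]` = x$c_trans, `c_rot [Nm/(rad/s)]` = x$c_rot)
  colnames(m) <- c("x", "y", "z")
  print(m)
  invisible(x)
}

#' Default interface parameters per body region
#'
#' Returns the reference parameter set of the interface element for the two
#' attachment regions of the orthosis. The stiffest translational direction
#' (10,000 N/m) is the one held by straps and fasteners: vertically (y) on
#' the tibia, fore-aft (x) on the foot. Directions with more compressible
#' soft tissue in series are softer (100 N/m on the tibia, 500 N/m on the
#' foot). Rotations resisted by the straps get 500 Nm/rad, all remaining
#' rotational directions 200 Nm/rad. Damping is 5 in the native unit of
#' every axis.
#'
#' @param site `"tibia"` or `"foot"`.
#' @return A [bushing_params()] object.
#' @export
default_interface_params <- function(site = c("tibia", "foot")) {
  if (!is.character(site) || length(site) != 1L ||
      !(site %in% c("tibia", "foot")))
    stopf("unknown interface site '%s'; valid sites: tibia, foot",
          as.character(site)[1L])
  damp <- c(5, 5, 5)
  switch(site,
    tibia = bushing_params(k_trans = c(100, 10000, 100),
                           k_rot   = c(200, 500, 200),
                           c_trans = damp, c_rot = damp),
    foot  = bushing_params(k_trans = c(10000, 500, 500),
                           k_rot   = c(500, 200, 200),
                           c_trans = damp, c_rot = damp))
}

#' Relative frame pose
#'
#' Small container for a relative pose (or pose rate): a 3-vector of
#' translations (m) and a 3-vector of fixed-order small-angle rotation
#' components about x, y, z (rad). Used to express the deviation of the
#' shell-side frame of an interface element from its segment-side frame.
#'
#' @param position numeric length-3, m (or m/s for a rate).
#' @param rotation numeric length-3, rad (or rad/s for a rate).
#' @param frame name of the frame of expression.
#' @return An object of class `frame_pose`.
#' @export
frame_pose <- function(position = c(0, 0, 0), rotation = c(0, 0, 0),
                       frame = "element") {
  position <- as.numeric(position); rotation <- as.numeric(rotation)
  if (length(position) != 3L || length(rotation) != 3L)
    stopf("position and rotation must have length 3")
  structure(list(position = position, rotation = rotation, frame = frame),
            class = "frame_pose")
}

#' Force-moment pair (wrench)
#'
#' @param force numeric length-3, N.
#' @param moment numeric length-3, Nm.
#' @param frame name of the frame of expression.
#' @return An object of class `wrench`.
#' @export
wrench <- function(force = c(0, 0, 0), moment = c(0, 0, 0),
                   frame = "element") {
  force <- as.numeric(force); moment <- as.numeric(moment)
  if (length(force) != 3L || length(moment) != 3L)
    stopf("force and moment must have length 3")
  structure(list(force = force, moment = moment, frame = frame),
            class = "wrench")
}

#' Wrench of a viscoelastic interface element
#'
#' Per-axis spring-damper law of the interface element. For each axis i the
#' restoring force is `-(k_trans_i * dx_i + c_trans_i * dxdot_i)` and the
#' restoring moment `-(k_rot_i * dtheta_i + c_rot_i * dthetadot_i)`. The
#' returned wrench acts on the displaced (shell-side) body; the reaction on
#' the segment-side body is its negation, so the pair always sums to zero.
#'
#' @param params a [bushing_params()] object.
#' @param rel_pose [frame_pose()]: pose of the shell-side frame relative to
#'   the segment-side frame, expressed in the element (segment-side) frame.
#' @param rel_vel [frame_pose()]: rate of `rel_pose`, same frame.
#' @return A [wrench()] acting on the shell-side body, expressed in the
#'   element frame.
#' @export
bushing_wrench <- function(params, rel_pose, rel_vel = frame_pose()) {
  stopifnot(inherits(params, "bushing_params"))
  if (!identical(rel_pose$frame, rel_vel$frame))
    stopf("rel_pose frame '%s' does not match rel_vel frame '%s'",
          rel_pose$frame, rel_vel$frame)
  check_finite(rel_pose$position, "rel_pose$position")
  check_finite(rel_pose$rotation, "rel_pose$rotation")
  check_finite(rel_vel$position, "rel_vel$position")
  check_finite(rel_vel$rotation, "rel_vel$rotation")
  wrench(
    force  = -(params$k_trans * rel_pose$position +
               params$c_trans * rel_vel$position),
    moment = -(params$k_rot * rel_pose$rotation +
               params$c_rot * rel_vel$rotation),
    frame  = rel_pose$frame)
}

#' Instantaneous interface power
#'
#' Power delivered by an interface wrench through a relative velocity,
#' split into the recoverable (spring) and dissipated (damper) parts.
#' The damper part is non-negative for any motion (passivity).
#'
#' @param w a [wrench()] acting on the shell-side body.
#' @param rel_vel [frame_pose()] rate, same frame as `w`.
#' @param params the [bushing_params()] of the element (needed to attribute
#'   the split); if `NULL` only the total is returned.
#' @return A list with `total`, `spring` and `dissipated` power in W
#'   (`dissipated` is the power absorbed by the dampers, >= 0).
#' @export
interface_power <- function(w, rel_vel, params = NULL) {
  stopifnot(inherits(w, "wrench"), inherits(rel_vel, "frame_pose"))
  if (!identical(w$frame, rel_vel$frame))
    stopf("wrench frame '%s' does not match rel_vel frame '%s'",
          w$frame, rel_vel$frame)
  total <- sum(w$force * rel_vel$position) + sum(w$moment * rel_vel$rotation)
  if (is.null(params))
    return(list(total = total, spring = NA_real_, dissipated = NA_real_))
  dissipated <- sum(params$c_trans * rel_vel$position^2) +
    sum(params$c_rot * rel_vel$rotation^2)
  list(total = total, spring = total + dissipated, dissipated = dissipated)
}
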