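#' Fully compensating hand aim offset under a cursor rotation
#'
#' Solves for the hand-space aim rotation that places the rotated cursor
#' exactly on the target, by root-finding the cursor's signed angular
#' error over candidate aim offsets. The result is reported in the same
#' clockwise-positive sense as the applied rotation, so a 45 degree
#' clockwise cursor rotation requires a -45 degree (i.e. 45 degree
#' counterclockwise) change of the hand's movement direction.
#'
#' @param rotation_deg_cw Applied cursor rotation, degrees clockwise.
#' @param target_deg Target direction, degrees.
#' @param distance Reach distance, m.
#' @return Aim offset in degrees, clockwise-positive (negative when the
#'   hand must rotate counterclockwise).
#' @export
compensation_aim_offset <- function(rotation_deg_cw, target_deg = 90,
                                    distance = 0.10) {
  target <- distance * dir_vec(target_deg)
  err <- function(delta_ccw) {
    hand <- distance * dir_vec(target_deg + delta_ccw)
    cursor <- apply_rotation(hand, rotation_deg_cw)
    signed_angular_error(cursor, c(0, 0), target)
  }
  sol <- stats::uniroot(err, interval = rotation_deg_cw + c(-89, 89),
                        tol = 1e-10)
  -sol$root # clockwise-positive convention of the rotation itself
}
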