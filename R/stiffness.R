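# 2D rotation of a symmetric 2x2 matrix given as components (a11, a12, a22):
# R(psi) S R(psi)^T, vectorized over psi and components
.rot_sym2 <- function(a11, a12, a22, psi) {
  c_ <- cos(psi); s_ <- sin(psi)
  list(a11 = a11 * c_^2 - 2 * a12 * c_ * s_ + a22 * s_^2,
       a12 = (a11 - a22) * s_ * c_ + a12 * (c_^2 - s_^2),
       a22 = a11 * s_^2 + 2 * a12 * s_ * c_ + a22 * c_^2)
}

# per-step tilt/roll covariance mapped to tangent-deflection coordinates.
# In the (normal, binormal) plane a (tilt, roll) fluctuation deflects the
# tangent by (tilt, -roll), so the off-diagonal covariance changes sign.
.deflection_cov <- function(P, steps) {
  list(a11 = P$var_tilt[steps], a12 = -P$cov[steps], a22 = P$var_roll[steps])
}

#' Accumulated tilt/roll covariance over a loop
#'
#' Sums the per-step tilt/roll covariance matrices over the `loop_size` steps
#' of a candidate loop centered at `center`, each co-rotated by the twist
#' accumulated between that step and the loop center, and expressed in the
#' tangent-deflection coordinates of the material frame at the center (x =
#' normal, y = binormal). This is the angular covariance of the loop's
#' end-to-end tangent deflection, and shares its angular origin with the
#' `phi_b` reported by [curvature_profile()].
#'
#' @param seq DNA string.
#' @param center Loop center, 1-based bp.
#' @param loop_size Loop size N, bp (the N steps from
#'   `center - floor(N/2)` onward are summed).
#' @param params A [dinuc_params()] set.
#' @param circular Logical; wrap windows?
#' @param ambiguity Non-ACGT handling, as in [ground_state_path()].
#' @return A symmetric 2x2 matrix, radians^2.
#' @export
summed_covariance <- function(seq, center, loop_size, params = dinuc_params(),
                              circular = FALSE,
                              ambiguity = c("error", "substitute")) {
  seq_int <- .seq_to_int(seq, ambiguity)
  L <- length(seq_int)
  pad <- 0L
  if (circular) {
    pad <- .SUPPORT_MARGIN + 1L
    reps <- ceiling(pad / L)
    seq_int <- c(utils::tail(rep(seq_int, reps), pad), seq_int,
                 utils::head(rep(seq_int, reps), pad))
  }
  P <- .param_tables(params)
  steps <- .step_codes(seq_int)
  tc <- c(0, cumsum(P$twist[steps]))
  i <- center + pad
  s <- i - loop_size %/% 2L
  if (s < 1L || s + loop_size - 1L > length(steps)) {
    abort(paste0("loop of ", loop_size, " bp centered at ", center,
                 " is not supported on this ", L, " bp sequence"))
  }
  k <- seq.int(s, s + loop_size - 1L)
  S <- .deflection_cov(P, steps[k])
  rot <- .rot_sym2(S$a11, S$a12, S$a22, tc[k] - tc[i])
  matrix(c(sum(rot$a11), sum(rot$a12), sum(rot$a12), sum(rot$a22)), 2, 2)
}

# ceiling for the directional persistence length when the directional
# variance (nearly) vanishes
.A_CAP <- 1000

#' Direction-dependent local persistence length
#'
#' Converts the accumulated angular covariance of a loop into a local
#' worm-like-chain persistence length for bending in direction `phi`:
#' the mean-square tangent deflection in a bending plane over contour length
#' L is L/A, so `A(phi) = rise * N / (u' sigma u)` with `u = (cos phi,
#' sin phi)`. A is periodic in `phi` with period pi (a bending plane, not a
#' signed direction) and is capped at `max_A` when the directional variance
#' underflows (with a warning).
#'
#' @param sigma Symmetric 2x2 accumulated covariance, radians^2 (e.g. from
#'   [summed_covariance()]).
#' @param loop_size Loop size N, bp.
#' @param phi Bend direction(s), radians; vectorized.
#' @param rise Base-pair rise, nm.
#' @param max_A Ceiling, nm.
#' @return Persistence length(s), nm.
#' @export
directional_persistence_length <- function(sigma, loop_size, phi, rise = 0.334,
                                           max_A = .A_CAP) {
  u1 <- cos(phi); u2 <- sin(phi)
  v <- sigma[1, 1] * u1^2 + 2 * sigma[1, 2] * u1 * u2 + sigma[2, 2] * u2^2
  A <- rise * loop_size / v
  capped <- !is.finite(A) | A > max_A
  if (any(capped)) {
    warn(paste0("directional variance underflow for ", sum(capped),
                " direction(s); persistence length capped at ", max_A, " nm"))
    A[capped] <- max_A
  }
  A
}
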