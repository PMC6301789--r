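# The model's work coefficient pins kBT via C = F / 12.16 (F in pN), i.e.
# kBT = 0.334 nm * 12.16 pN ~= 4.06 pN nm. Kept exactly as the model defines
# it so that the closed-form loop sizes (109 bp at 360 deg, 73 bp at 240 deg,
# both at 3 pN) come out on the printed integers.
.C_DENOM <- 12.16

#' Model constants for tip-loop energetics
#'
#' Bundles the closed-form constants of the tip-loop energy
#' `E_total(N) = C*N + B/N` (units of kBT): the per-bp work coefficient
#' `C = F/12.16` (F in pN), the full-circle bending constant
#' `B360 = 2*pi^2*A/rise` (~2955 for A = 50 nm, rise = 0.334 nm), and its
#' partial-loop scaling `B_angle = B360 * (angle/360)^2`. A 240 degree arc is
#' the tip bend that matches the DNA angle in the plectoneme stem.
#'
#' @param tension Tension F across the molecule, pN.
#' @param bend_angle Loop bend angle, degrees (240 for a plectoneme tip).
#' @param rise Base-pair rise, nm.
#' @param bulk_persistence_length Bulk persistence length A, nm.
#' @return A one-row tibble: `tension`, `bend_angle`, `C`, `B360`, `B_angle`.
#' @export
loop_energetics <- function(tension = 3, bend_angle = 240, rise = 0.334,
                            bulk_persistence_length = 50) {
  if (tension < 0) abort("`tension` must be non-negative (pN)")
  B360 <- 2 * pi^2 * bulk_persistence_length / rise
  tibble(tension = tension, bend_angle = bend_angle,
         C = tension / .C_DENOM, B360 = B360,
         B_angle = B360 * (bend_angle / 360)^2)
}

#' Optimal tip-loop size under tension
#'
#' Minimizing `E_total(N) = C*N + B_angle/N` over the loop size N gives
#' `N* = sqrt(B_angle / C)`. At 3 pN this yields 109 bp for a full 360 degree
#' loop and 73 bp for the 240 degree plectoneme tip.
#'
#' @inheritParams loop_energetics
#' @return A one-row tibble: `tension`, `bend_angle`, `loop_bp` (nearest
#'   integer) and `loop_exact` (unrounded).
#' @examples
#' optimal_loop_size(3, 360)$loop_bp  # 109
#' optimal_loop_size(3, 240)$loop_bp  # 73
#' @export
optimal_loop_size <- function(tension = 3, bend_angle = 360, rise = 0.334,
                              bulk_persistence_length = 50) {
  if (tension <= 0) abort("`tension` must be positive (pN)")
  if (bend_angle <= 0 || bend_angle > 360) {
    abort("`bend_angle` must be in (0, 360] degrees")
  }
  k <- loop_energetics(tension, bend_angle, rise, bulk_persistence_length)
  n_exact <- sqrt(k$B_angle / k$C)
  tibble(tension = tension, bend_angle = bend_angle,
         loop_bp = as.integer(round(n_exact)), loop_exact = n_exact)
}

#' Bending energy of a tip loop with intrinsic curvature
#'
#' Energy (kBT) to close a loop of `loop_size` bp into a `bend_angle` arc when
#' the segment carries intrinsic curvature `theta` pointing in direction
#' `phi_b` and the loop is bent in direction `phi`. The intrinsic bend
#' subtracts from the imposed bend by the law of cosines:
#'
#' `E = (angle/360)^2 * 2*pi^2 * A / (rise * N) *
#'   (1 + (theta/angle)^2 - 2*(theta/angle)*cos(phi - phi_b))`
#'
#' For the 240 degree tip the prefactor is the (2/3)^2 = (240/360)^2 scaling
#' of the full-circle energy. With `phi = phi_b` this reduces to
#' `(2/3)^2 * 2*pi^2 * A/(rise*N) * (1 - theta/240)^2`: ~18 kBT for a straight
#' (theta = 0) 73 bp segment at A = 50 nm, falling to zero for a segment
#' pre-bent to the full 240 degrees.
#'
#' @param loop_size Loop size N, bp.
#' @param persistence_length Local persistence length A, nm.
#' @param theta Intrinsic curvature of the segment, degrees.
#' @param phi Bend direction, radians; defaults to `phi_b` (preferred
#'   direction).
#' @param phi_b Preferred bend direction, radians.
#' @param bend_angle Loop bend angle, degrees.
#' @param rise Base-pair rise, nm.
#' @return Bending energy, kBT. Vectorized over all numeric arguments.
#' @export
bend_energy <- function(loop_size, persistence_length = 50, theta = 0,
                        phi = phi_b, phi_b = 0, bend_angle = 240,
                        rise = 0.334) {
  if (any(loop_size < 1)) abort("`loop_size` must be >= 1 bp")
  if (any(persistence_length <= 0)) abort("`persistence_length` must be > 0 nm")
  u <- theta / bend_angle
  (bend_angle / 360)^2 * 2 * pi^2 * persistence_length / (rise * loop_size) *
    (1 + u^2 - 2 * u * cos(phi - phi_b))
}

#' Total tip-loop energy: work plus bending
#'
#' `E_total = (F/12.16)*N + E_bend`, in kBT: the work of pulling `loop_size`
#' bp of contour against tension F plus the [bend_energy()] of closing the
#' loop.
#'
#' @inheritParams bend_energy
#' @param tension Tension F, pN.
#' @return Total energy, kBT. Vectorized.
#' @export
total_energy <- function(loop_size, tension = 3, persistence_length = 50,
                         theta = 0, phi = phi_b, phi_b = 0, bend_angle = 240,
                         rise = 0.334) {
  if (any(tension < 0)) abort("`tension` must be non-negative (pN)")
  tension / .C_DENOM * loop_size +
    bend_energy(loop_size, persistence_length, theta, phi, phi_b, bend_angle,
                rise)
}
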