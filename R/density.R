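# loop-size grid spanning the isotropic optimum (73 bp at 3 pN): 40..120 bp
# in 8 bp increments, 8 bend directions every 45 degrees starting at phi_B
.LOOP_SIZES <- seq(40L, 120L, by = 8L)
.N_DIRECTIONS <- 8L

# Boltzmann-weight engine. Works on the padded arrays of a helix_path.
# For every supported center i and every (loop size N, bend direction k) cell:
# theta/phi_B from windowed tangent chords, the accumulated tilt/roll
# covariance (twist-co-rotated into the center frame) from prefix sums, the
# directional persistence length, and the total energy C*N + E_bend. Returns
# per-center W_tot; optionally the full 11x8 grid at one center.
.wtot_engine <- function(path, params, tension, loop_sizes = .LOOP_SIZES,
                         n_directions = .N_DIRECTIONS, tangent_window = 11L,
                         grid_center = NULL) {
  P <- .param_tables(params)
  rise <- P$rise
  h <- (tangent_window - 1L) %/% 2L
  n <- nrow(path$positions)
  Tn <- .all_tangents(path, tangent_window)
  steps <- path$step_codes
  tc <- path$twist_cum
  S <- .deflection_cov(P, steps)
  Srot <- .rot_sym2(S$a11, S$a12, S$a22, tc[seq_along(steps)])
  pA11 <- c(0, cumsum(Srot$a11))
  pA12 <- c(0, cumsum(Srot$a12))
  pA22 <- c(0, cumsum(Srot$a22))

  n_max <- max(loop_sizes)
  lo <- h + 1L + n_max %/% 2L
  hi <- n - h - (n_max - n_max %/% 2L)
  if (!is.null(grid_center)) {
    idx <- grid_center + path$pad
    if (idx < lo || idx > hi) {
      abort(paste0("center ", grid_center, " lacks full support for a ",
                   n_max, " bp loop"))
    }
    centers <- idx
  } else {
    centers <- seq.int(lo, hi)
    orig <- centers - path$pad
    keep <- orig >= 1L & orig <= path$length
    centers <- centers[keep]
  }
  if (length(centers) == 0) {
    abort(paste0("sequence too short: no center supports a ", n_max,
                 " bp loop (minimum length ", .MIN_LENGTH, " bp)"))
  }

  phis <- (seq_len(n_directions) - 1L) * 2 * pi / n_directions
  w_tot <- numeric(length(centers))
  grid <- if (is.null(grid_center)) NULL else vector("list", length(loop_sizes))

  Tm <- Tn[centers, , drop = FALSE]
  Nm <- path$normal[centers, , drop = FALSE]
  Bm <- path$binormal[centers, , drop = FALSE]
  tci <- tc[centers]

  for (jn in seq_along(loop_sizes)) {
    N <- loop_sizes[jn]
    half <- N %/% 2L
    s <- centers - half
    e <- s + N
    Ts <- Tn[s, , drop = FALSE]
    Te <- Tn[e, , drop = FALSE]
    theta <- acos(pmin(1, pmax(-1, rowSums(Ts * Te)))) * 180 / pi
    v <- Te - Ts
    v <- v - rowSums(v * Tm) * Tm
    phi_b <- atan2(rowSums(v * Bm), rowSums(v * Nm))
    phi_b[sqrt(rowSums(v^2)) < 1e-12] <- 0
    # covariance over steps s .. e-1, co-rotated into the center frame
    cw <- .rot_sym2(pA11[e] - pA11[s], pA12[e] - pA12[s], pA22[e] - pA22[s],
                    -tci)
    u <- theta / 240
    work <- tension / .C_DENOM * N
    pref <- (2 / 3)^2 * 2 * pi^2 / (rise * N)
    for (k in seq_len(n_directions)) {
      phi <- phi_b + phis[k]
      varphi <- cw$a11 * cos(phi)^2 + 2 * cw$a12 * cos(phi) * sin(phi) +
        cw$a22 * sin(phi)^2
      A <- rise * N / varphi
      A[!is.finite(A) | A > .A_CAP] <- .A_CAP
      e_bend <- pref * A * (1 + u^2 - 2 * u * cos(phis[k]))
      e_tot <- work + e_bend
      w_tot <- w_tot + exp(-e_tot)
      if (!is.null(grid)) {
        grid[[jn]][[k]] <- tibble(
          loop_size = N, direction = k - 1L, phi = phi, theta = theta,
          phi_b = phi_b, persistence_length = A, e_bend = e_bend,
          e_total = e_tot, w = exp(-e_tot))
      }
    }
  }
  out <- list(positions = centers - path$pad, w_tot = w_tot)
  if (!is.null(grid)) {
    out$grid <- dplyr::bind_rows(lapply(grid, dplyr::bind_rows))
  }
  out
}

#' Energy and Boltzmann-weight grid at one position
#'
#' Evaluates the full tip-loop conformation grid for a plectoneme tip centered
#' at `center`: loop sizes 40-120 bp in 8 bp increments by eight bend
#' directions at every 45 degrees starting from the preferred direction
#' `phi_b` (11 x 8 = 88 cells). Each cell carries the intrinsic curvature,
#' the directional persistence length, the bending and total energies (kBT)
#' and the Boltzmann weight `w = exp(-e_total)`.
#'
#' @param seq DNA string.
#' @param center Center position, 1-based bp.
#' @param tension Tension, pN.
#' @param params A [dinuc_params()] set.
#' @param circular Logical; wrap windows?
#' @param ambiguity Non-ACGT handling, as in [ground_state_path()].
#' @return A tibble with 88 rows: `loop_size`, `direction` (0..7), `phi`,
#'   `theta`, `phi_b`, `persistence_length`, `e_bend`, `e_total`, `w`.
#' @export
energy_grid <- function(seq, center, tension = 3, params = dinuc_params(),
                        circular = FALSE,
                        ambiguity = c("error", "substitute")) {
  path <- ground_state_path(seq, params, circular, ambiguity)
  res <- .wtot_engine(path, params, tension, grid_center = center)
  res$grid
}

#' Predicted plectoneme density along a molecule
#'
#' The core prediction: for every base i with full support, sums Boltzmann
#' weights `exp(-E_total(N, i, phi))` over the tip-loop grid (loop sizes
#' 40-120 bp step 8, eight bend directions anchored at the preferred direction
#' phi_B) into a total weight `W_tot(i)`. The predicted plectoneme density is
#' `W_tot` normalized to mean 1 over the molecule -- the same convention used
#' for experimental density profiles -- and `-ln W_tot` is the corresponding
#' free-energy landscape in kBT.
#'
#' On a linear molecule the leading and trailing 65 bp lack full support and
#' are reported as `NA` (never zero); on a circular molecule every position is
#' defined.
#'
#' @param seq DNA string (character scalar or Biostrings object), length >=
#'   131 bp.
#' @param tension Tension across the molecule, pN (default 3, characteristic
#'   of a stretched single molecule).
#' @param params A [dinuc_params()] set.
#' @param circular Logical; treat the molecule as circular?
#' @param loop_sizes Candidate tip-loop sizes, bp.
#' @param n_directions Number of bend directions (every 360/n degrees from
#'   phi_B).
#' @param ambiguity Non-ACGT handling, as in [ground_state_path()].
#' @return A tibble of class `plectoneme_profile` with one row per base:
#'   `position`, `w_tot`, `density` (mean 1 over defined positions),
#'   `free_energy` (kBT), `defined`. Attributes record tension, parameter-set
#'   name and circularity. Use [gaussian_smooth()] for resolution-matched
#'   smoothing, and `tidy()`/`glance()`/`autoplot()` to work with the result.
#' @examples
#' seq <- make_fixture("flat_random", length = 500, seed = 1)
#' prof <- plectoneme_density(seq)
#' glance(prof)
#' @export
plectoneme_density <- function(seq, tension = 3, params = dinuc_params(),
                               circular = FALSE, loop_sizes = .LOOP_SIZES,
                               n_directions = .N_DIRECTIONS,
                               ambiguity = c("error", "substitute")) {
  path <- ground_state_path(seq, params, circular, ambiguity)
  if (path$length < .MIN_LENGTH) {
    abort(paste0("sequence is ", path$length, " bp; the model needs at least ",
                 .MIN_LENGTH,
                 " bp (120 bp maximal loop plus 11 bp tangent windows)"))
  }
  res <- .wtot_engine(path, params, tension, loop_sizes, n_directions)
  L <- path$length
  w <- rep(NA_real_, L)
  w[res$positions] <- res$w_tot
  defined <- !is.na(w)
  density <- w / mean(w[defined])
  out <- tibble(position = seq_len(L), w_tot = w, density = density,
                free_energy = -log(w), defined = defined)
  .new_profile(out, tension = tension, params_name = params$name,
               circular = circular)
}

.new_profile <- function(df, tension, params_name, circular, fwhm = NULL) {
  structure(df, class = c("plectoneme_profile", class(tibble())),
            tension = tension, params_name = params_name, circular = circular,
            fwhm = fwhm)
}

#' @export
print.plectoneme_profile <- function(x, ...) {
  cat("<plectoneme_profile> ", nrow(x), " bp (",
      if (isTRUE(attr(x, "circular"))) "circular" else "linear",
      "), tension ", attr(x, "tension"), " pN, parameter set '",
      attr(x, "params_name"), "'\n", sep = "")
  NextMethod()
}

# FFT "same"-size convolution of x with an odd-length kernel, zero-padded
.conv_same <- function(x, kern) {
  half <- (length(kern) - 1L) %/% 2L
  n <- length(x)
  m <- n + 2L * half
  xp <- c(x, rep(0, 2L * half))
  kp <- rep(0, m)
  # wrap the kernel so its center sits at lag 0: lags 0..half at the front,
  # lags -1..-half folded onto the back
  kp[seq_len(half + 1L)] <- kern[(half + 1L):(2L * half + 1L)]
  kp[m - seq_len(half) + 1L] <- kern[half:1L]
  re <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / m
  re[seq_len(n)]
}

# Gaussian smoothing of a numeric vector with NA-masked positions.
# linear: truncated-kernel renormalization at the edges, then an exact
# restore of the mean over defined positions; circular: wrapped (aliased)
# kernel via circular FFT convolution, which preserves the mean exactly.
.gauss_smooth_vec <- function(x, fwhm, circular = FALSE) {
  sigma <- fwhm / sqrt(8 * log(2))
  n <- length(x)
  mask <- as.numeric(!is.na(x))
  x0 <- ifelse(is.na(x), 0, x)
  if (circular) {
    # aliased (wrapped) Gaussian kernel at lags 0..n-1, summing every image
    # of the tail that winds around a short molecule
    j <- seq_len(n) - 1L
    wraps <- ceiling(4 * sigma / n) + 1L
    kern <- rep(0, n)
    for (m in (-wraps):wraps) {
      kern <- kern + exp(-(j + m * n)^2 / (2 * sigma^2))
    }
    kern <- kern / sum(kern)
    num <- Re(stats::fft(stats::fft(x0) * stats::fft(kern), inverse = TRUE)) / n
    den <- Re(stats::fft(stats::fft(mask) * stats::fft(kern), inverse = TRUE)) / n
  } else {
    half <- min(ceiling(4 * sigma), 10L * n)
    kk <- (-half):half
    kern <- exp(-kk^2 / (2 * sigma^2))
    kern <- kern / sum(kern)
    num <- .conv_same(x0, kern)
    den <- .conv_same(mask, kern)
  }
  y <- rep(NA_real_, n)
  ok <- mask > 0 & den > 1e-12
  y[ok] <- num[ok] / den[ok]
  mx <- mean(x[ok])
  my <- mean(y[ok])
  if (is.finite(my) && abs(my) > 0) y[ok] <- y[ok] * (mx / my)
  y
}

#' Resolution-matched Gaussian smoothing of a density profile
#'
#' Convolves the predicted density with a Gaussian kernel of the given full
#' width at half maximum (default 1600 bp, sigma = FWHM/sqrt(8 ln 2) ~ 679
#' bp), matching the optical resolution of single-molecule plectoneme
#' imaging. Edges of a linear molecule are handled by renormalizing the
#' truncated kernel and the profile mean over defined positions is preserved;
#' windows of a circular molecule wrap.
#'
#' @param x A `plectoneme_profile` (adds/replaces the `smoothed_density`
#'   column) or a plain numeric vector (returns the smoothed vector).
#' @param fwhm Full width at half maximum of the kernel, bp.
#' @param ... Passed between methods; the numeric method accepts `circular`.
#' @return Same shape as the input.
#' @export
gaussian_smooth <- function(x, fwhm = 1600, ...) UseMethod("gaussian_smooth")

#' @rdname gaussian_smooth
#' @export
gaussian_smooth.plectoneme_profile <- function(x, fwhm = 1600, ...) {
  if (fwhm <= 0) abort("`fwhm` must be positive")
  sm <- .gauss_smooth_vec(x$density, fwhm, isTRUE(attr(x, "circular")))
  x$smoothed_density <- sm
  attr(x, "fwhm") <- fwhm
  x
}

#' @rdname gaussian_smooth
#' @param circular Logical; wrap the kernel (numeric method)?
#' @export
gaussian_smooth.numeric <- function(x, fwhm = 1600, circular = FALSE, ...) {
  if (fwhm <= 0) abort("`fwhm` must be positive")
  .gauss_smooth_vec(x, fwhm, circular)
}
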