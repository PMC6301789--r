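# elementary rotations about the local frame axes; the frame matrix has
# columns (t, n, b) so t = e1, n = e2, b = e3 in local coordinates
.rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}
.rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
.rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# map between IUPAC ambiguity codes and a fixed representative base (first
# base of the code's set, alphabetically); used only under ambiguity = "substitute"
.IUPAC_REP <- c(R = "A", Y = "C", S = "C", W = "A", K = "G", M = "A",
                B = "C", D = "A", H = "A", V = "A", N = "A", U = "T")

# encode a DNA string as integers 1..4 (A,C,G,T)
.seq_to_int <- function(seq, ambiguity = c("error", "substitute")) {
  ambiguity <- match.arg(ambiguity)
  if (methods::is(seq, "XString") || methods::is(seq, "XStringSet")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1) {
    abort("`seq` must be a single DNA string (character or Biostrings object)")
  }
  ch <- strsplit(toupper(seq), "")[[1]]
  code <- match(ch, c("A", "C", "G", "T"))
  if (anyNA(code)) {
    bad <- which(is.na(code))
    if (ambiguity == "error") {
      abort(paste0("non-ACGT base '", ch[bad[1]], "' at position ", bad[1],
                   " (", length(bad), " such positions); use ambiguity = ",
                   "\"substitute\" to map IUPAC codes to representative bases"))
    }
    rep_ <- .IUPAC_REP[ch[bad]]
    if (anyNA(rep_)) {
      abort(paste0("character '", ch[bad[which(is.na(rep_))[1]]],
                   "' is not a IUPAC nucleotide code"))
    }
    warn(paste0("substituted ", length(bad),
                " IUPAC ambiguity code(s) with representative bases"))
    code[bad] <- match(rep_, c("A", "C", "G", "T"))
  }
  code
}

# per-step dinucleotide codes 1..16 for a sequence of base codes
.step_codes <- function(seq_int) {
  n <- length(seq_int)
  4L * (seq_int[-n] - 1L) + seq_int[-1L]
}

# margin (bp) of centers without full support on a linear molecule:
# max loop half-size + tangent half-window
.SUPPORT_MARGIN <- 65L
.MIN_LENGTH <- 131L  # 2*margin + 1: at least one supported center

#' Intrinsic ground-state path of a DNA sequence
#'
#' Reconstructs the zero-temperature 3D trace of the double helix by composing
#' the per-dinucleotide wedge rotations along the sequence. Starting from an
#' arbitrary global frame, each step advances the position by `rise` nm along
#' the current tangent and then updates the material frame (t, n, b) by a
#' twist rotation about t, a roll rotation about n, and a tilt rotation about
#' b, in that fixed order.
#'
#' For circular molecules every downstream window (tangents, curvature,
#' covariance sums) wraps around the origin; internally the sequence is padded
#' with its own ends so that all positions have full support.
#'
#' @param seq A DNA string (character scalar, or a Biostrings `DNAString`).
#' @param params A [dinuc_params()] set.
#' @param circular Logical; treat the molecule as circular (all windows wrap)?
#' @param ambiguity `"error"` (default) rejects non-ACGT bases with the
#'   offending offset; `"substitute"` maps IUPAC codes to a fixed
#'   representative base with a warning.
#' @return An object of class `helix_path` (see Details), usable with
#'   [windowed_tangent()], [curvature_profile()] and [path_positions()].
#' @details The object holds per-base positions (nm) and orthonormal material
#'   frames, the accumulated twist, and per-step total rotation angles.
#'   Consecutive positions are exactly `rise` nm apart by construction.
#' @examples
#' path <- ground_state_path(strrep("ACGT", 30), dinuc_params())
#' path_positions(path)
#' @export
ground_state_path <- function(seq, params = dinuc_params(), circular = FALSE,
                              ambiguity = c("error", "substitute")) {
  seq_int <- .seq_to_int(seq, ambiguity)
  L <- length(seq_int)
  if (L < 2) abort("`seq` must have length >= 2")
  pad <- 0L
  if (circular) {
    pad <- .SUPPORT_MARGIN + 1L
    reps <- ceiling(pad / L)
    left <- utils::tail(rep(seq_int, reps), pad)
    right <- utils::head(rep(seq_int, reps), pad)
    seq_int <- c(left, seq_int, right)
  }
  P <- .param_tables(params)
  steps <- .step_codes(seq_int)
  n <- length(seq_int)
  pos <- matrix(0, n, 3)
  Tm <- matrix(0, n, 3); Nm <- matrix(0, n, 3); Bm <- matrix(0, n, 3)
  M <- diag(3)
  Tm[1, ] <- M[, 1]; Nm[1, ] <- M[, 2]; Bm[1, ] <- M[, 3]
  rot <- P$rot
  rise <- P$rise
  for (k in seq_len(n - 1L)) {
    pos[k + 1L, ] <- pos[k, ] + rise * M[, 1]
    M <- M %*% rot[[steps[k]]]
    Tm[k + 1L, ] <- M[, 1]; Nm[k + 1L, ] <- M[, 2]; Bm[k + 1L, ] <- M[, 3]
  }
  # twist accumulated at base j over steps strictly before j
  twist_cum <- c(0, cumsum(P$twist[steps]))
  structure(list(positions = pos, tangent = Tm, normal = Nm, binormal = Bm,
                 twist_cum = twist_cum, step_codes = steps,
                 step_angle = P$step_angle[steps],
                 pad = pad, length = L, circular = circular,
                 rise = rise, params_name = P$name),
            class = "helix_path")
}

#' @export
print.helix_path <- function(x, ...) {
  cat("<helix_path> ", x$length, " bp (", if (x$circular) "circular" else "linear",
      "), parameter set '", x$params_name, "', rise ", x$rise, " nm\n", sep = "")
  invisible(x)
}

#' Positions of a ground-state path as a tibble
#'
#' @param path A `helix_path`.
#' @return A tibble with columns `position` (1-based bp) and `x`, `y`, `z` (nm).
#' @export
path_positions <- function(path) {
  idx <- path$pad + seq_len(path$length)
  tibble(position = seq_len(path$length),
         x = path$positions[idx, 1], y = path$positions[idx, 2],
         z = path$positions[idx, 3])
}

# all windowed tangents on the padded arrays; rows outside support are NA
.all_tangents <- function(path, window = 11L) {
  h <- (window - 1L) %/% 2L
  n <- nrow(path$positions)
  Tn <- matrix(NA_real_, n, 3)
  if (n >= window) {
    rng <- (h + 1L):(n - h)
    d <- path$positions[rng + h, , drop = FALSE] -
      path$positions[rng - h, , drop = FALSE]
    d <- d / sqrt(rowSums(d^2))
    Tn[rng, ] <- d
  }
  Tn
}

#' Windowed tangent vector at one position
#'
#' The tangent is the unit chord of the ground-state path across a window of
#' `window` bp (default 11 bp, one helical turn, ~3.7 nm): the chord over a
#' full turn cancels the intra-turn wobble of the helical axis.
#'
#' @param path A `helix_path`.
#' @param i Center position, 1-based bp.
#' @param window Odd window width in bp.
#' @return A unit 3-vector.
#' @export
windowed_tangent <- function(path, i, window = 11L) {
  if (window %% 2L == 0L) abort("`window` must be odd")
  h <- (window - 1L) %/% 2L
  idx <- path$pad + i
  if (idx - h < 1L || idx + h > nrow(path$positions)) {
    abort(paste0("position ", i, " has no full ", window,
                 " bp tangent support on this linear path"))
  }
  d <- path$positions[idx + h, ] - path$positions[idx - h, ]
  d / sqrt(sum(d^2))
}

#' Intrinsic curvature and preferred bend direction along a path
#'
#' For a candidate loop of `loop_size` bp centered at position i, the
#' intrinsic curvature `theta` is the angle between the windowed tangents at
#' the two ends of the stretch (i - floor(N/2) and i - floor(N/2) + N), and
#' the preferred bend direction `phi_b` is the azimuth, in the (normal,
#' binormal) plane of the material frame at i, of the component of the
#' end-to-end tangent change perpendicular to the mid tangent. `phi_b` is set
#' to 0 by convention where the curvature vanishes.
#'
#' Both quantities are invariant under rigid rotation/translation of the path.
#'
#' @param path A `helix_path`.
#' @param loop_size Loop (stretch) size N in bp.
#' @param tangent_window Tangent chord window, bp (default 11).
#' @return A tibble with one row per supported center: `position`,
#'   `loop_size`, `theta` (degrees, in `[0, 180]`), `phi_b` (radians).
#' @export
curvature_profile <- function(path, loop_size, tangent_window = 11L) {
  if (loop_size < tangent_window) {
    abort("`loop_size` must be at least the tangent window")
  }
  Tn <- .all_tangents(path, tangent_window)
  h <- (tangent_window - 1L) %/% 2L
  n <- nrow(path$positions)
  half <- loop_size %/% 2L
  # centers (padded index) with full support for both end tangents
  lo <- h + 1L + half
  hi <- n - h - (loop_size - half)
  centers_p <- seq.int(lo, hi)
  # restrict to original coordinates
  orig <- centers_p - path$pad
  keep <- orig >= 1L & orig <= path$length
  centers_p <- centers_p[keep]
  orig <- orig[keep]
  if (length(centers_p) == 0) {
    abort(paste0("no center has full support for loop_size ", loop_size,
                 " on this ", path$length, " bp path"))
  }
  s <- centers_p - half
  e <- s + loop_size
  Ts <- Tn[s, , drop = FALSE]
  Te <- Tn[e, , drop = FALSE]
  dotp <- pmin(1, pmax(-1, rowSums(Ts * Te)))
  theta <- acos(dotp) * 180 / pi
  v <- Te - Ts
  Tm <- Tn[centers_p, , drop = FALSE]
  v <- v - rowSums(v * Tm) * Tm
  phi_b <- atan2(rowSums(v * path$binormal[centers_p, , drop = FALSE]),
                 rowSums(v * path$normal[centers_p, , drop = FALSE]))
  phi_b[sqrt(rowSums(v^2)) < 1e-12] <- 0
  tibble(position = orig, loop_size = loop_size, theta = theta, phi_b = phi_b)
}
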