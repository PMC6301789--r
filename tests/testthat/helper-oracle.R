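# Independent slow re-implementations used as oracles. Deliberately share no
# code with the package: rotations are composed with the Rodrigues axis-angle
# formula about world axes instead of local frame-matrix products, and every
# model quantity is accumulated with plain nested loops.

oracle_rodrigues <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma::cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

# ground-state path: world-axis rotations of the frame vectors, twist about
# t, then roll about n, then tilt about b
oracle_path <- function(seq, params) {
  g <- params$geometry
  st <- params$stiffness
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  deg <- pi / 180
  t_ <- c(1, 0, 0); n_ <- c(0, 1, 0); b_ <- c(0, 0, 1)
  pos <- matrix(0, L, 3)
  Tm <- Nm <- Bm <- matrix(0, L, 3)
  Tm[1, ] <- t_; Nm[1, ] <- n_; Bm[1, ] <- b_
  tc <- numeric(L)
  for (k in 1:(L - 1)) {
    pos[k + 1, ] <- pos[k, ] + params$rise * t_
    stp <- paste0(ch[k], ch[k + 1])
    row <- which(g$step == stp)
    tw <- g$twist[row] * deg; ro <- g$roll[row] * deg; ti <- g$tilt[row] * deg
    n_ <- oracle_rodrigues(n_, t_, tw); b_ <- oracle_rodrigues(b_, t_, tw)
    t_ <- oracle_rodrigues(t_, n_, ro); b_ <- oracle_rodrigues(b_, n_, ro)
    t_ <- oracle_rodrigues(t_, b_, ti); n_ <- oracle_rodrigues(n_, b_, ti)
    Tm[k + 1, ] <- t_; Nm[k + 1, ] <- n_; Bm[k + 1, ] <- b_
    tc[k + 1] <- tc[k] + tw
  }
  list(pos = pos, Tm = Tm, Nm = Nm, Bm = Bm, tc = tc, ch = ch)
}

oracle_tangent <- function(op, i, window = 11) {
  h <- (window - 1) / 2
  d <- op$pos[i + h, ] - op$pos[i - h, ]
  d / sqrt(sum(d^2))
}

# direct nested-loop W_tot over defined centers of a linear sequence
oracle_wtot <- function(seq, tension, params, loop_sizes = seq(40, 120, 8),
                        n_dir = 8, a_cap = 1000) {
  op <- oracle_path(seq, params)
  g <- params$geometry
  st <- params$stiffness
  L <- length(op$ch)
  h <- 5
  centers <- 66:(L - 65)
  w_tot <- numeric(length(centers))
  for (ci in seq_along(centers)) {
    i <- centers[ci]
    acc <- 0
    for (N in loop_sizes) {
      s <- i - floor(N / 2)
      e <- s + N
      Ts <- oracle_tangent(op, s)
      Te <- oracle_tangent(op, e)
      theta <- acos(min(1, max(-1, sum(Ts * Te)))) * 180 / pi
      Tm <- oracle_tangent(op, i)
      v <- Te - Ts
      v <- v - sum(v * Tm) * Tm
      phi_b <- if (sqrt(sum(v^2)) < 1e-12) 0 else {
        atan2(sum(v * op$Bm[i, ]), sum(v * op$Nm[i, ]))
      }
      Sig <- matrix(0, 2, 2)
      for (k in s:(e - 1)) {
        stp <- paste0(op$ch[k], op$ch[k + 1])
        row <- which(st$step == stp)
        S <- matrix(c(st$var_tilt[row], -st$cov_tilt_roll[row],
                      -st$cov_tilt_roll[row], st$var_roll[row]), 2, 2)
        psi <- op$tc[k] - op$tc[i]
        R <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2)
        Sig <- Sig + R %*% S %*% t(R)
      }
      for (k in 0:(n_dir - 1)) {
        dphi <- k * 2 * pi / n_dir
        phi <- phi_b + dphi
        u <- c(cos(phi), sin(phi))
        varphi <- drop(t(u) %*% Sig %*% u)
        A <- params$rise * N / varphi
        if (!is.finite(A) || A > a_cap) A <- a_cap
        ub <- theta / 240
        eb <- (2 / 3)^2 * 2 * pi^2 * A / (params$rise * N) *
          (1 + ub^2 - 2 * ub * cos(dphi))
        acc <- acc + exp(-(tension / 12.16 * N + eb))
      }
    }
    w_tot[ci] <- acc
  }
  list(positions = centers, w_tot = w_tot)
}

# synthetic planar circular-arc helix_path: bend `rate` degrees per step in
# the (x, y) plane, frames carried along (n points to the arc center)
arc_path <- function(n_bp, rate_deg, rise = 0.334) {
  a <- (seq_len(n_bp) - 1) * rate_deg * pi / 180
  Tm <- cbind(cos(a), sin(a), 0)
  Nm <- cbind(-sin(a), cos(a), 0)
  Bm <- cbind(0, 0, rep(1, n_bp))
  pos <- apply(Tm * rise, 2, function(col) cumsum(c(0, col[-n_bp])))
  structure(list(positions = pos, tangent = Tm, normal = Nm, binormal = Bm,
                 twist_cum = rep(0, n_bp), step_codes = integer(0),
                 step_angle = rep(rate_deg * pi / 180, n_bp - 1),
                 pad = 0L, length = n_bp, circular = FALSE, rise = rise,
                 params_name = "arc"),
            class = "helix_path")
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
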