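#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# the 16 dinucleotide steps, in fixed alphabetical order; this order is the
# internal index used by every lookup table (code 4*(first-1) + second)
DINUC_STEPS <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                      rep(c("A", "C", "G", "T"), times = 4))

#' Load a dinucleotide geometry + stiffness parameter set
#'
#' A parameter set holds, for each of the 16 dinucleotide steps, the intrinsic
#' wedge geometry (tilt, roll, twist; degrees) and the thermal stiffness (the
#' symmetric 2x2 covariance of tilt and roll fluctuations; radians^2), plus
#' the base-pair rise (nm) and the bulk persistence length (nm). Two sets ship
#' with the package:
#'
#' * `"default"` (alias `"wedge_synthetic"`) -- a composite wedge-style set
#'   calibrated against classical macroscopic benchmarks of sequence-dependent
#'   DNA shape (phased A-tract curvature, ~10.6 bp helical repeat). See the
#'   header of `inst/extdata/params/wedge_synthetic.params` for provenance and
#'   axis conventions.
#' * `"smooth_synthetic"` -- the same set with wedge magnitudes halved, to
#'   expose the sensitivity of predictions to the geometry set.
#'
#' User files use a flat whitespace-separated format, one record per step
#' (`step tilt roll twist var_tilt var_roll cov_tilt_roll`), optional
#' `name`/`rise`/`bulk_persistence_length` key-value lines, and `#` comments.
#' Angles are degrees in files and reports; conversion to radians happens
#' exactly once, inside the numerical engine.
#'
#' @param source Name of a shipped set (`"default"`, `"wedge_synthetic"`,
#'   `"smooth_synthetic"`) or the path of a parameter file.
#' @return An object of class `dinuc_params`: a list with elements `name`,
#'   `geometry` (tibble: step, tilt, roll, twist), `stiffness` (tibble: step,
#'   var_tilt, var_roll, cov_tilt_roll), `rise`, `bulk_persistence_length`.
#' @examples
#' p <- dinuc_params()
#' p$geometry
#' @export
dinuc_params <- function(source = "default") {
  shipped <- c(default = "wedge_synthetic", wedge_synthetic = "wedge_synthetic",
               smooth_synthetic = "smooth_synthetic")
  path <- if (source %in% names(shipped)) {
    system.file("extdata", "params", paste0(shipped[[source]], ".params"),
                package = "plectoneme", mustWork = TRUE)
  } else {
    if (!file.exists(source)) {
      abort(paste0("`source` is neither a shipped parameter set (",
                   paste(unique(shipped), collapse = ", "),
                   ") nor an existing file: ", source))
    }
    source
  }
  x <- read_dinuc_params(path)
  report <- validate_dinuc_params(x)
  if (nrow(report) > 0) {
    abort(paste0("invalid parameter set '", x$name, "':\n",
                 paste0("- ", report$message, collapse = "\n")))
  }
  x
}

#' List the parameter sets shipped with the package
#'
#' @return A tibble with columns `name` and `path`.
#' @export
dinuc_param_sets <- function() {
  dir <- system.file("extdata", "params", package = "plectoneme", mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.params$", full.names = TRUE)
  tibble(name = sub("\\.params$", "", basename(files)), path = files)
}

# parse the flat key-value parameter format; no validation here
read_dinuc_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- sub("\\.params$", "", basename(path))
  rise <- 0.334
  bulk <- 50
  rec <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- toupper(tok[1])
    if (key %in% DINUC_STEPS) {
      if (length(tok) != 7) {
        abort(paste0("malformed record for step ", key, " in ", path,
                     ": expected 7 fields, got ", length(tok)))
      }
      vals <- suppressWarnings(as.numeric(tok[-1]))
      if (anyNA(vals)) {
        abort(paste0("non-numeric value in record for step ", key, " in ", path))
      }
      rec[[key]] <- vals
    } else if (tolower(tok[1]) == "name") {
      name <- tok[2]
    } else if (tolower(tok[1]) == "rise") {
      rise <- as.numeric(tok[2])
    } else if (tolower(tok[1]) == "bulk_persistence_length") {
      bulk <- as.numeric(tok[2])
    } else {
      abort(paste0("unrecognized line in ", path, ": '", ln, "'"))
    }
  }
  steps <- names(rec)
  m <- unname(do.call(rbind, rec))
  geometry <- tibble(step = steps, tilt = m[, 1], roll = m[, 2], twist = m[, 3])
  stiffness <- tibble(step = steps, var_tilt = m[, 4], var_roll = m[, 5],
                      cov_tilt_roll = m[, 6])
  new_dinuc_params(name, geometry, stiffness, rise, bulk)
}

new_dinuc_params <- function(name, geometry, stiffness, rise = 0.334,
                             bulk_persistence_length = 50) {
  structure(list(name = name,
                 geometry = as_tibble(geometry),
                 stiffness = as_tibble(stiffness),
                 rise = rise,
                 bulk_persistence_length = bulk_persistence_length),
            class = "dinuc_params")
}

#' Validate a dinucleotide parameter set
#'
#' Checks every invariant of the parameter-set contract and reports all
#' violations (it never throws): the 16-step completeness of both tables,
#' positive semi-definiteness of each tilt/roll covariance, the twist sanity
#' range of (20, 45) degrees (one helical turn is ~10-11 bp), and positive
#' rise and bulk persistence length.
#'
#' @param params A `dinuc_params` object (possibly invalid).
#' @return A tibble with columns `check`, `step`, `message`; zero rows iff the
#'   set is valid.
#' @export
validate_dinuc_params <- function(params) {
  bad <- list()
  note <- function(check, step, message) {
    bad[[length(bad) + 1]] <<- tibble(check = check, step = step, message = message)
  }
  for (tab in c("geometry", "stiffness")) {
    steps <- params[[tab]]$step
    for (s in setdiff(DINUC_STEPS, steps)) {
      note("missing_step", s, paste0(tab, " table is missing step ", s))
    }
    for (s in setdiff(steps, DINUC_STEPS)) {
      note("unknown_step", s, paste0(tab, " table has unknown step ", s))
    }
    if (anyDuplicated(steps)) {
      note("duplicate_step", steps[duplicated(steps)][1],
           paste0(tab, " table has duplicated steps"))
    }
    m <- as.matrix(params[[tab]][-1])
    if (!all(is.finite(m))) note("nonfinite", NA_character_,
                                 paste0(tab, " table has non-finite values"))
  }
  g <- params$geometry
  for (k in seq_len(nrow(g))) {
    if (is.finite(g$twist[k]) && (g$twist[k] <= 20 || g$twist[k] >= 45)) {
      note("twist_range", g$step[k],
           paste0("twist for step ", g$step[k], " (", g$twist[k],
                  " deg) outside the sanity range (20, 45)"))
    }
  }
  st <- params$stiffness
  for (k in seq_len(nrow(st))) {
    vt <- st$var_tilt[k]; vr <- st$var_roll[k]; cv <- st$cov_tilt_roll[k]
    if (!all(is.finite(c(vt, vr, cv)))) next
    # symmetric 2x2 PSD <=> nonneg diagonal and nonneg determinant
    if (vt < 0 || vr < 0 || vt * vr - cv^2 < -1e-12) {
      note("not_psd", st$step[k],
           paste0("tilt/roll covariance for step ", st$step[k],
                  " is not positive semi-definite"))
    }
  }
  if (!is.finite(params$rise) || params$rise <= 0) {
    note("rise", NA_character_, "rise must be a positive number of nm")
  }
  if (!is.finite(params$bulk_persistence_length) ||
      params$bulk_persistence_length <= 0) {
    note("bulk_A", NA_character_, "bulk_persistence_length must be positive")
  }
  if (length(bad) == 0) {
    tibble(check = character(), step = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Write a parameter set to the flat file format
#'
#' Values are written at full double precision, so a write/read round trip
#' reproduces the set bit-exactly.
#'
#' @param params A `dinuc_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dinuc_params <- function(params, path) {
  g <- params$geometry[match(DINUC_STEPS, params$geometry$step), ]
  s <- params$stiffness[match(DINUC_STEPS, params$stiffness$step), ]
  num <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c(
    "# dinucleotide parameter set (degrees for angles, rad^2 for variances)",
    "# columns: step tilt roll twist var_tilt var_roll cov_tilt_roll",
    paste("name", params$name),
    paste("rise", num(params$rise)),
    paste("bulk_persistence_length", num(params$bulk_persistence_length)),
    paste(g$step, num(g$tilt), num(g$roll), num(g$twist),
          num(s$var_tilt), num(s$var_roll), num(s$cov_tilt_roll))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct the null-geometry control set
#'
#' Zero tilt and roll for every step, a uniform twist, and an isotropic
#' stiffness. Under this set the ground-state path of any sequence is a
#' straight line, the intrinsic curvature is identically zero, and the
#' predicted plectoneme density is uniform -- the analytic control used
#' throughout the test suite.
#'
#' @param twist Uniform twist, degrees per step.
#' @param variance Per-plane per-step angular variance, radians^2. The default
#'   `rise/bulk_persistence_length` makes the directional persistence length
#'   exactly the bulk value.
#' @param rise,bulk_persistence_length Rise (nm/step) and bulk persistence
#'   length (nm).
#' @return A valid `dinuc_params` object named `"null"`.
#' @export
null_dinuc_params <- function(twist = 34.3, variance = rise / bulk_persistence_length,
                              rise = 0.334, bulk_persistence_length = 50) {
  new_dinuc_params(
    "null",
    tibble(step = DINUC_STEPS, tilt = 0, roll = 0, twist = twist),
    tibble(step = DINUC_STEPS, var_tilt = variance, var_roll = variance,
           cov_tilt_roll = 0),
    rise, bulk_persistence_length
  )
}

#' @export
print.dinuc_params <- function(x, ...) {
  cat("<dinuc_params> set '", x$name, "': rise ", x$rise, " nm, bulk A ",
      x$bulk_persistence_length, " nm\n", sep = "")
  cat("mean twist ", round(mean(x$geometry$twist), 2), " deg (helical repeat ~",
      round(360 / mean(x$geometry$twist), 2), " bp)\n", sep = "")
  print(dplyr::left_join(x$geometry, x$stiffness, by = "step"), n = 16)
  invisible(x)
}

# internal lookup tables, radians, indexed by step code 1..16 in DINUC_STEPS
# order; also the per-step frame rotation matrices and total rotation angles
.param_tables <- function(params) {
  g <- params$geometry[match(DINUC_STEPS, params$geometry$step), ]
  s <- params$stiffness[match(DINUC_STEPS, params$stiffness$step), ]
  deg <- pi / 180
  tilt <- g$tilt * deg
  roll <- g$roll * deg
  twist <- g$twist * deg
  rot <- vector("list", 16)
  angle <- numeric(16)
  for (k in 1:16) {
    R <- .rot_x(twist[k]) %*% .rot_y(roll[k]) %*% .rot_z(tilt[k])
    rot[[k]] <- R
    angle[k] <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
  }
  list(tilt = tilt, roll = roll, twist = twist,
       var_tilt = s$var_tilt, var_roll = s$var_roll, cov = s$cov_tilt_roll,
       rot = rot, step_angle = angle,
       rise = params$rise, bulk_A = params$bulk_persistence_length,
       name = params$name)
}
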