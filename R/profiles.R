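#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
#' @importFrom generics tidy glance
#' @import Rcpp
#' @useDynLib cardioresp, .registration = TRUE
NULL

# Parameter names grouped by the physical quantity they represent; used both by
# the validator and by tidy().  Names mirror the tabulated symbols.
.param_groups <- list(
  resistance = c("rli", "rri", "rlo", "rro", "raa", "rabd", "ruba_set",
                 "rubv_set", "rkida_set", "rkidv_set", "rspa_set", "rspv_set",
                 "rlla_set", "rrla_set", "rllv_set", "rrlv_set", "rsup",
                 "rinfext", "rinfint", "rcp", "rap", "rvp", "r_airways"),
  compliance = c("cla", "cra", "caa", "cabd", "cub", "ckid", "csp", "cll",
                 "crl", "csup", "cinfext", "cinfint", "cap", "cvp"),
  inertance = c("laa", "labd", "lap"),
  volume = c("vlv0", "vrv0", "vub0_set", "vkid0_set", "vsp0_set", "vll0_set",
             "vrl0_set", "vap0", "vvp0", "vla0", "vra0"),
  time_constant = c("tau_p", "t_met", "t_elmax", "t_ermax", "t_ris", "t_tcs",
                    "t_tcv", "t_vis"),
  positive = c("hr_set", "elmax", "ermax", "e_lung", "weight", "ka", "kes",
               "kev", "fes0", "fes_inf", "paa_set0", "blood_per_kg", "v_eexp",
               "k_met", "delta", "peak_vo2")
)

.read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    abort(sprintf("malformed line in %s: %s", path, lines[bad][1]))
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  out <- as.list(vals)
  names(out) <- keys
  num <- suppressWarnings(lapply(out, as.numeric))
  for (k in keys) if (!is.na(num[[k]])) out[[k]] <- num[[k]]
  out
}

.profile_fixture <- function(condition) {
  system.file("extdata", paste0(condition, ".params"),
              package = "cardioresp", mustWork = TRUE)
}

.required_params <- function() {
  # the healthy fixture defines the complete parameter set
  names(.read_params(.profile_fixture("healthy")))
}

#' Load a condition profile
#'
#' Assembles the complete parameter vector for one simulated subject: the
#' `healthy` set (resting cardiovascular network, ventilation, baroreflex,
#' metabolic control and exercise metabolic drive) or the `hf` set, in which
#' the chronic heart-failure overrides (reduced left-ventricular systolic
#' elastance, stiffer diastolic filling, systemic and pulmonary hypertension,
#' blunted inotropic gain, larger dead-space fraction, stiffer lungs, steeper
#' metabolic drive) replace the corresponding healthy entries.
#'
#' @param condition `"healthy"` or `"hf"`.
#' @param overrides optional named list of parameter values replacing entries
#'   of the loaded set; unknown names are an error.
#' @return an object of class `cardioresp_profile`: a named list of parameters
#'   (units as tabulated: mmHg, cm3, s, l/min, ml gas/dl blood).
#' @examples
#' p <- load_profile("healthy")
#' p$elmax            # peak left-ventricular elastance, mmHg/cm3
#' tidy(p)
#' @export
load_profile <- function(condition = c("healthy", "hf"), overrides = NULL) {
  condition <- match.arg(condition)
  prof <- .read_params(.profile_fixture(condition))
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abort("`overrides` must be a fully named list")
    }
    unknown <- setdiff(names(overrides), names(prof))
    if (length(unknown) > 0) {
      abort(paste0("unknown parameter(s) in `overrides`: ",
                   paste(unknown, collapse = ", ")))
    }
    prof[names(overrides)] <- overrides
  }
  missing <- setdiff(.required_params(), names(prof))
  if (length(missing) > 0) {
    abort(paste0("profile is missing required parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  class(prof) <- "cardioresp_profile"
  prof
}

#' Validate a condition profile
#'
#' Checks the structural invariants of a parameter set: resistances,
#' compliances, inertances, volumes and time constants must be positive, the
#' basal-resistance ratio `s0` must lie in \[0, 1\], the effective tidal-volume
#' fraction `k_dv` in (0, 1\], and the condition label must name a shipped set.
#' Violations are reported, never raised.
#'
#' @param profile a `cardioresp_profile` (or plain named list).
#' @return a tibble with columns `parameter`, `value`, `rule`; zero rows when
#'   every invariant holds.
#' @export
validate_profile <- function(profile) {
  viol <- list()
  flag <- function(parameter, value, rule) {
    viol[[length(viol) + 1L]] <<- tibble(
      parameter = parameter,
      value = if (is.numeric(value)) value else NA_real_,
      rule = rule
    )
  }
  positive_groups <- c("resistance", "compliance", "inertance",
                       "time_constant", "positive")
  for (grp in positive_groups) {
    for (nm in .param_groups[[grp]]) {
      v <- profile[[nm]]
      if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
        flag(nm, NA_real_, "must be a finite number")
      } else if (v <= 0) {
        flag(nm, v, "must be > 0")
      }
    }
  }
  for (nm in .param_groups$volume) {
    v <- profile[[nm]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
      flag(nm, NA_real_, "must be a finite number")
    } else if (v < 0) {
      flag(nm, v, "must be >= 0")
    }
  }
  s0 <- profile[["s0"]]
  if (!is.numeric(s0) || !is.finite(s0) || s0 < 0 || s0 > 1) {
    flag("s0", s0, "must lie in [0, 1]")
  }
  kdv <- profile[["k_dv"]]
  if (!is.numeric(kdv) || !is.finite(kdv) || kdv <= 0 || kdv > 1) {
    flag("k_dv", kdv, "must lie in (0, 1]")
  }
  if (!identical(profile[["condition"]], "healthy") &&
      !identical(profile[["condition"]], "hf")) {
    flag("condition", NA_real_, "must be 'healthy' or 'hf'")
  }
  if (length(viol) == 0) {
    tibble(parameter = character(), value = double(), rule = character())
  } else {
    do.call(rbind, viol)
  }
}

#' Serialize a profile to the key-value configuration format
#'
#' Numeric values are written with full double precision so that writing and
#' re-loading reproduces every parameter bit-exactly.
#'
#' @param profile a `cardioresp_profile`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  fmt <- vapply(names(profile), function(nm) {
    v <- profile[[nm]]
    if (is.numeric(v)) sprintf("%s = %.17g", nm, v) else sprintf("%s = %s", nm, v)
  }, "")
  writeLines(fmt, path)
  invisible(path)
}

#' Re-load a profile written by [write_profile()]
#' @param path file written by [write_profile()].
#' @return a `cardioresp_profile`.
#' @export
read_profile <- function(path) {
  prof <- .read_params(path)
  missing <- setdiff(.required_params(), names(prof))
  if (length(missing) > 0) {
    abort(paste0("profile file is missing parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  class(prof) <- "cardioresp_profile"
  prof
}

#' @export
print.cardioresp_profile <- function(x, ...) {
  cat("<cardioresp_profile> condition:", x$condition,
      "-", length(x) - 1L, "parameters\n")
  cat(sprintf("  HR_set %g bpm, Elmax %g mmHg/cm3, Paa_set0 %g mmHg, K_DV %g\n",
              x$hr_set, x$elmax, x$paa_set0, x$k_dv))
  invisible(x)
}

#' Tidy a condition profile into a parameter table
#'
#' @param x a `cardioresp_profile`.
#' @param ... unused.
#' @return a tibble with columns `parameter`, `value`, `group`.
#' @export
tidy.cardioresp_profile <- function(x, ...) {
  nm <- setdiff(names(x), "condition")
  grp <- vapply(nm, function(p) {
    hit <- names(.param_groups)[vapply(.param_groups, function(g) p %in% g, TRUE)]
    if (length(hit) > 0) hit[1] else "other"
  }, "")
  tibble(parameter = nm,
         value = unname(vapply(nm, function(p) as.numeric(x[[p]]), 0)),
         group = unname(grp))
}

# flatten a profile into the named numeric vector consumed by the C++ engine
.profile_numeric <- function(profile) {
  nm <- setdiff(names(profile), "condition")
  v <- vapply(nm, function(p) as.numeric(profile[[p]]), 0)
  names(v) <- nm
  v
}
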