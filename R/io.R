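#' Tumor-study tables: read, validate, write
#'
#' The on-disk format is strict comma-delimited text with a header and
#' columns `animal_id`, `arm_id`, `dose_mg_per_kg`, `time_day`,
#' `tumor_volume_mm3`. Extra columns are preserved as the `metadata`
#' attribute. Readers refuse silent coercion: non-numeric values (for
#' example volumes with thousands separators) are reported with row and
#' column.
#'
#' @param path File path.
#' @return `read_tumor_study()` returns a validated `tumor_study` data
#'   frame; `write_tumor_study()` returns `path` invisibly.
#' @export
read_tumor_study <- function(path) {
  if (!file.exists(path)) stop_invalid("read_tumor_study: no such file: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("animal_id", "arm_id", "dose_mg_per_kg", "time_day",
                "tumor_volume_mm3")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_invalid("read_tumor_study: missing required column(s): ",
                 paste(missing, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop_invalid("read_tumor_study: non-numeric value '",
                   raw[[col]][bad[1]], "' in column '", col, "', row ",
                   bad[1], " (thousands separators and units are not ",
                   "accepted)")
    }
    v
  }
  out <- data.frame(animal_id = raw$animal_id, arm_id = raw$arm_id,
                    dose_mg_per_kg = num("dose_mg_per_kg"),
                    time_day = num("time_day"),
                    tumor_volume_mm3 = num("tumor_volume_mm3"))
  extra <- setdiff(names(raw), required)
  study <- as_tumor_study(out)
  if (length(extra)) attr(study, "metadata") <- raw[extra]
  study
}

# Validate a tumor-study data frame and stamp the class.
as_tumor_study <- function(df) {
  required <- c("animal_id", "arm_id", "dose_mg_per_kg", "time_day",
                "tumor_volume_mm3")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid("tumor study: missing required column(s): ",
                 paste(missing, collapse = ", "))
  }
  if (any(df$time_day < 0)) {
    stop_invalid("tumor study: negative time_day in row ",
                 which(df$time_day < 0)[1])
  }
  if (any(df$tumor_volume_mm3 <= 0)) {
    stop_invalid("tumor study: non-positive tumor volume in row ",
                 which(df$tumor_volume_mm3 <= 0)[1])
  }
  has_day0 <- tapply(df$time_day, df$animal_id, function(t) any(t == 0))
  if (any(!has_day0)) {
    stop_invalid("tumor study: animal(s) without a day-0 measurement: ",
                 paste(names(has_day0)[!has_day0], collapse = ", "))
  }
  if (!inherits(df, "tumor_study")) {
    class(df) <- c("tumor_study", class(df))
  }
  df
}

#' @param study A `tumor_study` data frame.
#' @rdname read_tumor_study
#' @export
write_tumor_study <- function(study, path) {
  cols <- c("animal_id", "arm_id", "dose_mg_per_kg", "time_day",
            "tumor_volume_mm3")
  write.csv(as.data.frame(study)[cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a concentration table into profiles
#'
#' Strict reader for the delimited concentration format (columns
#' `subject_id`, `time_day`, `conc`, `unit`, `analyte`). Units must be
#' `ug/mL` or `nM` and uniform within a subject; the analyte must be
#' `free` or `total`.
#'
#' @param path File path.
#' @return A named list of [concentration_profile()] objects, one per
#'   subject.
#' @export
read_concentration_table <- function(path) {
  if (!file.exists(path)) {
    stop_invalid("read_concentration_table: no such file: ", path)
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("subject_id", "time_day", "conc", "unit", "analyte")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_invalid("read_concentration_table: missing required column(s): ",
                 paste(missing, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop_invalid("read_concentration_table: non-numeric value '",
                   raw[[col]][bad[1]], "' in column '", col, "', row ",
                   bad[1])
    }
    v
  }
  time_day <- num("time_day")
  conc <- num("conc")
  supported <- c("ug/mL", "nM")
  bad_unit <- !raw$unit %in% supported
  if (any(bad_unit)) {
    stop_invalid("read_concentration_table: unsupported unit '",
                 raw$unit[bad_unit][1], "' (supported: ",
                 paste(supported, collapse = ", "), ")")
  }
  if (any(!raw$analyte %in% c("free", "total"))) {
    stop_invalid("read_concentration_table: analyte must be 'free' or ",
                 "'total'")
  }
  n_skipped <- 0L
  profiles <- list()
  for (sid in unique(raw$subject_id)) {
    sel <- raw$subject_id == sid & !is.na(conc)
    if (!any(sel)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (length(unique(raw$unit[sel])) > 1) {
      stop_invalid("read_concentration_table: mixed units within subject '",
                   sid, "'")
    }
    ord <- order(time_day[sel])
    profiles[[sid]] <- concentration_profile(
      time_day[sel][ord], conc[sel][ord], unit = raw$unit[sel][1],
      analyte = raw$analyte[sel][1], subject_id = sid)
  }
  if (n_skipped > 0) {
    warning("read_concentration_table: skipped ", n_skipped,
            " subject group(s) with no usable rows", call. = FALSE)
  }
  profiles
}

#' Read and validate a run configuration
#'
#' YAML configuration with the recognized top-level blocks `pk`, `tgi`,
#' `tmdd`, `regimen`, `solver`, `bootstrap`, `translation` and `units`.
#' Unknown keys are rejected, every block is validated against its type's
#' invariants, and all violations are reported together rather than one
#' at a time.
#'
#' @param path YAML file path.
#' @return A named list with parsed and validated blocks (constructed
#'   package objects where applicable).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("read_run_config: no such file: ", path)
  cfg <- fix_yaml_keys(yaml::read_yaml(path))
  known <- c("pk", "tgi", "tmdd", "regimen", "solver", "bootstrap",
             "translation", "units")
  problems <- character(0)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown top-level key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  out <- list()
  grab <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      problems <<- c(problems, paste0(label, ": ", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(cfg$pk)) {
    out$pk <- grab("pk", do.call(two_cpt_params,
                                 cfg$pk[c("Vc", "CL", "Vp", "Q")]))
  }
  if (!is.null(cfg$tgi)) {
    out$tgi <- grab("tgi", do.call(tgi_params, cfg$tgi))
  }
  if (!is.null(cfg$tmdd)) {
    out$tmdd <- grab("tmdd", {
      lin <- do.call(two_cpt_params, cfg$tmdd$pk[c("Vc", "CL", "Vp", "Q")])
      args <- cfg$tmdd[setdiff(names(cfg$tmdd), "pk")]
      do.call(tmdd_params, c(list(linear = lin), args))
    })
  }
  if (!is.null(cfg$regimen)) {
    out$regimen <- grab("regimen", parse_regimen_config(cfg$regimen))
  }
  if (!is.null(cfg$solver)) {
    out$solver <- grab("solver", {
      s <- cfg$solver
      stopifnot(is.numeric(s$rtol), s$rtol > 0,
                is.numeric(s$atol), s$atol > 0)
      s[c("rtol", "atol")]
    })
  }
  if (!is.null(cfg$bootstrap)) {
    out$bootstrap <- grab("bootstrap", {
      b <- modifyList(list(n_boot = 10000, seed = 1, level = 0.8),
                      cfg$bootstrap)
      stopifnot(b$n_boot >= 1, b$level > 0, b$level < 1)
      b
    })
  }
  if (!is.null(cfg$translation)) {
    out$translation <- grab("translation", {
      tr <- modifyList(list(regression = 0.8, regrowth = 1.2,
                            horizon_after_last_dose = 21),
                       cfg$translation)
      stopifnot(tr$regression <= tr$regrowth,
                tr$horizon_after_last_dose >= 0)
      tr
    })
  }
  if (!is.null(cfg$units)) {
    u <- cfg$units
    conv <- unit_conventions()
    if ((!is.null(u$MW_ADC) && u$MW_ADC != conv$MW_ADC) ||
        (!is.null(u$MW_ECD) && u$MW_ECD != conv$MW_ECD)) {
      problems <- c(problems, paste0(
        "units: MW_ADC and MW_ECD are fixed conventions (",
        conv$MW_ADC, " and ", conv$MW_ECD, " kDa) and cannot be overridden"))
    }
    out$units <- conv
  }
  if (length(problems)) {
    stop_invalid("invalid configuration '", path, "':\n  - ",
                 paste(problems, collapse = "\n  - "))
  }
  out
}

# YAML 1.1 parses the bare scalars y/n/yes/no as booleans, including when
# they are mapping keys - so a Hill-coefficient key `n:` arrives named
# "FALSE". Restore such keys recursively.
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "FALSE"] <- "n"
    nm[nm == "TRUE"] <- "y"
    names(x) <- nm
  }
  lapply(x, fix_yaml_keys)
}

# Regimen block: either an explicit schedule or the Q-shorthand.
parse_regimen_config <- function(r) {
  if (!is.null(r$schedule)) {
    tt <- vapply(r$schedule, `[[`, numeric(1), "time_day")
    dd <- vapply(r$schedule, `[[`, numeric(1), "dose_mg_per_kg")
    ih <- vapply(r$schedule, function(e) {
      if (is.null(e$infusion_h)) 0 else e$infusion_h
    }, numeric(1))
    dosing_regimen(tt, dd, ih / 24)
  } else {
    need <- c("dose", "interval_day", "n_doses")
    if (!all(need %in% names(r))) {
      stop("regimen shorthand needs keys: ", paste(need, collapse = ", "))
    }
    dosing_regimen_q(r$dose, r$interval_day, r$n_doses,
                     infusion_h = if (is.null(r$infusion_h)) 0
                                  else r$infusion_h,
                     start_day = if (is.null(r$start_day)) 0
                                 else r$start_day)
  }
}
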