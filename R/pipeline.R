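# Read -> fit -> select -> derive -> report, as one pipeline.

#' Read a residual-activity table
#'
#' Reads a delimited text table (comma or tab separated; the delimiter is
#' sniffed from the header line) with columns `temperature_C`, `time_min`,
#' `replicate`, `activity`. If a temperature group's activities exceed 1.5
#' the input is taken to be in absolute units (e.g. U mL^-1) and is
#' normalized to the replicate mean at the earliest sampling time of that
#' group (reported via a message); fractional input is left untouched.
#'
#' @param path Path to the delimited file.
#' @param already_normalized Disable the absolute-unit heuristic and treat
#'   the input as activity fractions as-is.
#' @return A tibble with the four columns above, activities as fractions.
#' @export
read_activity_table <- function(path, already_normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (length(header) == 0) stop("empty input file: ", path, call. = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("temperature_C", "time_min", "replicate", "activity")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("input is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tbl) == 0) stop("input has no data rows", call. = FALSE)
  for (col in c("temperature_C", "time_min", "activity")) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    if (any(is.na(v))) {
      stop("non-numeric values in column '", col, "'", call. = FALSE)
    }
    tbl[[col]] <- v
  }
  dup <- duplicated(tbl[c("temperature_C", "time_min", "replicate")])
  if (any(dup)) {
    d <- tbl[which(dup)[1], ]
    stop(sprintf(
      "duplicated (temperature, time, replicate) key: (%g, %g, %s)",
      d$temperature_C, d$time_min, as.character(d$replicate)), call. = FALSE)
  }
  tbl <- dplyr::select(tbl, dplyr::all_of(required))
  if (!already_normalized) {
    tbl <- tbl |>
      dplyr::group_by(.data$temperature_C) |>
      dplyr::group_modify(function(g, key) {
        if (max(g$activity) > 1.5) {
          a0 <- mean(g$activity[g$time_min == min(g$time_min)])
          message(sprintf(
            "normalizing %g degC activities to t = %g min replicate mean (%.3g)",
            key$temperature_C, min(g$time_min), a0))
          g$activity <- g$activity / a0
        }
        g
      }) |>
      dplyr::ungroup()
  }
  tbl
}

#' Run the full inactivation analysis pipeline
#'
#' Fits all eight models at every temperature, selects the admissible
#' model by the physical and statistical criteria, and derives the
#' kinetic and activation-thermodynamic summaries appropriate to the
#' accepted model: half-life, D-value, z-value and a true-rate Arrhenius/
#' Eyring analysis for first-order; reliable life, z'-value, the
#' log-logistic b(T) model and an apparent (alpha^-1) Arrhenius/Eyring
#' analysis for Weibull.
#'
#' @param data A long activity table (tibble with `temperature_C`,
#'   `time_min`, `replicate`, `activity`) or a path accepted by
#'   [read_activity_table()].
#' @param label Dataset label recorded in the report.
#' @param zprime_base Log base for the z' regression (`"log10"` default,
#'   `"ln"` for the natural-log convention).
#' @param eyring_units `"si"` (rates converted to s^-1; default) or
#'   `"paper-compat"` (see [eyring_thermodynamics()]).
#' @param n_starts Multi-start restarts per fit (default 10).
#' @return An object of class `inactivation_report`: a list with
#'   `digest`, `fits`, `verdicts`, `accepted_model`, `kinetics`,
#'   `thermo`, and `options`.
#' @examples
#' \donttest{
#' report <- simulate_inactivation(paper_presets("lipase_ps", seed = 1)) |>
#'   run_pipeline(label = "lipase_ps synthetic")
#' report$accepted_model
#' }
#' @export
run_pipeline <- function(data, label = "dataset",
                         zprime_base = c("log10", "ln"),
                         eyring_units = c("si", "paper-compat"),
                         n_starts = 10) {
  zprime_base <- match.arg(zprime_base)
  eyring_units <- match.arg(eyring_units)
  if (is.character(data)) data <- read_activity_table(data)
  stopifnot(is.data.frame(data))
  if (!all(c("temperature_C", "time_min", "activity") %in% names(data))) {
    stop("data must have columns temperature_C, time_min, activity", call. = FALSE)
  }

  fits <- fit_models(data, n_starts = n_starts)
  verdicts <- select_model(fits)
  accepted <- verdicts$model_id[verdicts$status == "accepted"]

  kinetics <- NULL
  thermo <- NULL
  if (length(accepted) == 1) {
    acc_fits <- dplyr::filter(fits, .data$model_id == accepted)
    kinetics <- kinetic_summary(acc_fits, zprime_base = zprime_base)
    per <- kinetics$per_temperature
    if (accepted == "weibull") {
      thermo <- thermo_summary(per$temperature_C, 1 / per$alpha,
                               apparent = TRUE, units = eyring_units,
                               arrhenius_rate_unit = "per_h")
    } else {
      rate_col <- if ("k" %in% names(per)) "k" else NULL
      if (!is.null(rate_col)) {
        thermo <- thermo_summary(per$temperature_C, per[[rate_col]],
                                 apparent = accepted != "first_order",
                                 units = eyring_units,
                                 arrhenius_rate_unit = "per_min")
      }
    }
  } else {
    warning("no model was accepted; kinetic and thermodynamic summaries omitted",
            call. = FALSE)
  }

  digest <- data |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(m = dplyr::n(), .groups = "drop")

  structure(
    list(
      label = label,
      digest = digest,
      fits = fits,
      verdicts = verdicts,
      accepted_model = if (length(accepted) == 1) accepted else NA_character_,
      kinetics = kinetics,
      thermo = thermo,
      options = list(zprime_base = zprime_base, eyring_units = eyring_units,
                     n_starts = n_starts,
                     package_version = as.character(utils::packageVersion("thermokin")))
    ),
    class = "inactivation_report"
  )
}

#' @export
print.inactivation_report <- function(x, ...) {
  cat("Inactivation analysis:", x$label, "\n")
  cat("Curves:", nrow(x$digest), "temperature(s);",
      paste0(x$digest$temperature_C, collapse = "/"), "degC\n")
  cat("Accepted model:", x$accepted_model, "\n\n")
  if (!is.null(x$kinetics)) print(x$kinetics)
  if (!is.null(x$thermo)) {
    cat("\n")
    print(x$thermo)
  }
  invisible(x)
}

#' Flatten a fit table to one row per parameter
#'
#' @param fits Output of [fit_models()].
#' @return A tibble: `temperature_C`, `model_id`, `term`, `estimate`,
#'   `std_error`, plus the per-fit statistics.
#' @export
tidy_fits <- function(fits) {
  purrr::pmap_dfr(fits, function(temperature_C, model_id, converged,
                                 estimates, std_errors, r2, chi2, sem, m, p, ...) {
    tibble::tibble(
      temperature_C = temperature_C, model_id = model_id,
      term = names(estimates), estimate = unname(estimates),
      std_error = unname(std_errors),
      r2 = r2, chi2 = chi2, sem = sem, converged = converged
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_pipeline
#' @param x An `inactivation_report`.
#' @param ... Unused.
#' @export
tidy.inactivation_report <- function(x, ...) {
  tidy_fits(x$fits)
}

#' @rdname run_pipeline
#' @export
glance.inactivation_report <- function(x, ...) {
  out <- tibble::tibble(
    label = x$label,
    accepted_model = x$accepted_model,
    n_curves = nrow(x$digest),
    Ea = if (!is.null(x$thermo)) x$thermo$Ea else NA_real_,
    arrhenius_r2 = if (!is.null(x$thermo)) x$thermo$arrhenius$r2 else NA_real_
  )
  if (!is.null(x$kinetics)) {
    if (!is.null(x$kinetics[["z"]])) out$z <- x$kinetics[["z"]]$z
    if (!is.null(x$kinetics[["z_prime"]])) out$z_prime <- x$kinetics[["z_prime"]]$z_prime
  }
  out
}

#' @rdname kinetic_summary
#' @param x A `kinetic_summary`.
#' @param ... Unused.
#' @export
tidy.kinetic_summary <- function(x, ...) x$per_temperature

#' @rdname kinetic_summary
#' @export
glance.kinetic_summary <- function(x, ...) {
  out <- tibble::tibble(model_id = x$model_id)
  if (!is.null(x[["z"]])) {
    out$z <- x[["z"]]$z
    out$z_r2 <- x[["z"]]$r2
  }
  if (!is.null(x$z_prime)) {
    out$z_prime <- x$z_prime$z_prime
    out$z_prime_r2 <- x$z_prime$r2
    out$z_prime_log_base <- x$z_prime$log_base
  }
  if (!is.null(x$log_logistic)) {
    out$k_prime <- x$log_logistic$k_prime
    out$T_c <- x$log_logistic$T_c
    out$log_logistic_r2 <- x$log_logistic$r2
  }
  out
}

#' @rdname thermo_summary
#' @param x A `thermo_summary`.
#' @param ... Unused.
#' @export
tidy.thermo_summary <- function(x, ...) x$per_temperature

#' @rdname thermo_summary
#' @export
glance.thermo_summary <- function(x, ...) {
  tibble::tibble(
    Ea = x$Ea, arrhenius_intercept = x$arrhenius$intercept,
    arrhenius_r2 = x$arrhenius$r2, apparent = x$apparent, units = x$units
  )
}

#' Write an analysis report to disk
#'
#' Serializes an [run_pipeline()] report as a JSON file plus delimited
#' tables (fit table, verdict table, per-temperature kinetic and
#' thermodynamic summaries). Output is deterministic for identical inputs
#' and options: stable row ordering and fixed numeric formatting.
#'
#' @param report An `inactivation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "inactivation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  fit_tbl <- tidy_fits(report$fits)
  p <- file.path(dir, "fits.csv")
  readr::write_csv(fit_tbl, p)
  paths <- c(paths, p)

  p <- file.path(dir, "verdicts.csv")
  readr::write_csv(report$verdicts, p)
  paths <- c(paths, p)

  json <- list(
    label = report$label,
    accepted_model = report$accepted_model,
    options = report$options,
    digest = report$digest,
    fits = fit_tbl,
    verdicts = report$verdicts
  )
  if (!is.null(report$kinetics)) {
    json$kinetics <- c(
      list(per_temperature = report$kinetics$per_temperature),
      report$kinetics[setdiff(names(report$kinetics), c("per_temperature", "model_id"))]
    )
    p <- file.path(dir, "kinetics.csv")
    readr::write_csv(report$kinetics$per_temperature, p)
    paths <- c(paths, p)
  }
  if (!is.null(report$thermo)) {
    json$thermo <- list(
      Ea = report$thermo$Ea, arrhenius = report$thermo$arrhenius,
      apparent = report$thermo$apparent, units = report$thermo$units,
      per_temperature = report$thermo$per_temperature
    )
    p <- file.path(dir, "thermo.csv")
    readr::write_csv(report$thermo$per_temperature, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
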