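#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files are two columns (`wavenumber_cm-1`, `absorbance`) with an
#' optional header, comma-separated, '.' decimal. JCAMP-DX files must carry
#' `##FIRSTX`, `##LASTX`, `##NPOINTS` and a fixed-form AFFN
#' `##XYDATA=(X++(Y..Y))` block; descending instrument order is converted
#' to the canonical ascending grid.
#'
#' @param path file path.
#' @param format `"auto"` (by extension/content), `"csv"` or `"jcamp"`.
#' @return an `ir_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^##", first) ||
                  grepl("\\.(jdx|dx|jcm)$", path, ignore.case = TRUE))
      "jcamp" else "csv"
  }
  if (format == "csv") read_spectrum_csv(path) else read_spectrum_jcamp(path)
}

read_spectrum_csv <- function(path) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  df <- utils::read.csv(path, header = has_header, check.names = FALSE)
  if (ncol(df) < 2) stop("spectrum CSV needs two columns")
  o <- order(df[[1]])
  ir_spectrum(df[[1]][o], df[[2]][o])
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path)
  grab <- function(field) {
    i <- grep(paste0("^##", field, "="), lines)
    if (length(i) == 0)
      stop("malformed JCAMP-DX file: missing ##", field, "= header")
    sub(paste0("^##", field, "="), "", lines[i[1]])
  }
  firstx <- as.numeric(grab("FIRSTX"))
  lastx <- as.numeric(grab("LASTX"))
  npoints <- as.integer(grab("NPOINTS"))
  xfac <- as.numeric(grab("XFACTOR"))
  yfac <- as.numeric(grab("YFACTOR"))
  i0 <- grep("^##XYDATA=", lines)
  if (length(i0) == 0) stop("malformed JCAMP-DX file: missing ##XYDATA= header")
  iend <- grep("^##END=", lines)
  iend <- if (length(iend)) iend[iend > i0][1] else length(lines) + 1
  body <- lines[(i0 + 1):(iend - 1)]
  x <- numeric(0); y <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    if (length(vals) < 2 || anyNA(vals)) stop("malformed JCAMP-DX XYDATA line: ", ln)
    x <- c(x, vals[1])
    y <- c(y, vals[-1])
  }
  if (length(y) != npoints)
    stop("JCAMP-DX NPOINTS (", npoints, ") does not match data (", length(y), ")")
  dx <- (lastx - firstx) / (npoints - 1)
  grid <- (firstx + dx * (seq_len(npoints) - 1)) * xfac
  o <- order(grid)
  ir_spectrum(grid[o], (y * yfac)[o])
}

#' Write a spectrum to CSV or JCAMP-DX
#'
#' CSV is written in canonical ascending order with full double precision,
#' so that [read_spectrum()] round-trips bit-identically. JCAMP-DX is
#' written in descending instrument order with explicit
#' `##FIRSTX`/`##LASTX` and fixed-form AFFN XYDATA.
#'
#' @param spec an `ir_spectrum`.
#' @param path output path.
#' @param format `"csv"` or `"jcamp"`.
#' @param title JCAMP `##TITLE=` value.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, format = c("csv", "jcamp"),
                           title = "azeoblend spectrum") {
  format <- match.arg(format)
  stopifnot(inherits(spec, "ir_spectrum"))
  if (format == "csv") {
    write_atomic(path, function(p) {
      con <- file(p, "w")
      on.exit(close(con))
      writeLines("wavenumber_cm-1,absorbance", con)
      writeLines(paste(sprintf("%.17g", spec$wavenumbers),
                       sprintf("%.17g", spec$absorbance), sep = ","), con)
    })
  } else {
    n <- length(spec$wavenumbers)
    wn <- rev(spec$wavenumbers)   # descending, instrument convention
    ab <- rev(spec$absorbance)
    write_atomic(path, function(p) {
      con <- file(p, "w")
      on.exit(close(con))
      writeLines(c(
        paste0("##TITLE=", title),
        "##JCAMP-DX=4.24",
        "##DATA TYPE=INFRARED SPECTRUM",
        "##XUNITS=1/CM",
        "##YUNITS=ABSORBANCE",
        "##XFACTOR=1",
        "##YFACTOR=1",
        sprintf("##FIRSTX=%.10g", wn[1]),
        sprintf("##LASTX=%.10g", wn[n]),
        sprintf("##NPOINTS=%d", n),
        sprintf("##DELTAX=%.10g", (wn[n] - wn[1]) / (n - 1)),
        "##XYDATA=(X++(Y..Y))"), con)
      for (i in seq(1, n, by = 6)) {
        j <- min(i + 5, n)
        writeLines(paste(sprintf("%.10g", wn[i]),
                         paste(sprintf("%.8e", ab[i:j]), collapse = " ")), con)
      }
      writeLines("##END=", con)
    })
  }
  invisible(path)
}

config_schema <- list(
  temperature_K = c(200, 500),
  component_a = NA, component_b = NA,
  activity_coefficients = c(-50, 50),
  generator = NA, fit = NA, assay = NA)

#' Read and validate a run configuration
#'
#' YAML with top-level keys `temperature_K`, `component_a`, `component_b`,
#' `activity_coefficients`, and optional `generator`, `fit` and `assay`
#' sections. Unknown keys are rejected; numeric fields are range-checked
#' at load.
#'
#' @param path YAML file path.
#' @return a validated list of class `azeo_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("temperature_K", "component_a", "component_b",
                "activity_coefficients")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  }
  rng <- config_schema$temperature_K
  if (cfg$temperature_K < rng[1] || cfg$temperature_K > rng[2])
    stop("temperature_K out of range [", rng[1], ", ", rng[2], "]")
  rng <- config_schema$activity_coefficients
  if (any(cfg$activity_coefficients < rng[1] | cfg$activity_coefficients > rng[2]))
    stop("activity_coefficients out of range")
  for (side in c("component_a", "component_b")) {
    comp <- cfg[[side]]
    need <- c("name", "molar_mass_g_mol", "antoine")
    miss <- setdiff(need, names(comp))
    if (length(miss))
      stop(side, " is missing field(s): ", paste(miss, collapse = ", "))
    if (comp$molar_mass_g_mol <= 0) stop(side, ": molar mass must be positive")
    if (length(comp$antoine) != 3) stop(side, ": antoine needs 3 coefficients")
  }
  structure(cfg, class = "azeo_config")
}

#' Build a binary VLE system from a run configuration
#'
#' @param config an `azeo_config` (or a path to one).
#' @return an [binary_vle()] object.
#' @export
vle_from_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  mk <- function(c) component(c$name, c$molar_mass_g_mol,
                              unlist(c$antoine),
                              t_range = unlist(c$t_range_K %||% c(273.15, 400)),
                              molar_volume = c$molar_volume_mL_mol %||% NA_real_)
  binary_vle(mk(config$component_a), mk(config$component_b),
             activity_model(unlist(config$activity_coefficients)),
             config$temperature_K)
}

#' Run the full synthetic-analysis pipeline
#'
#' Orchestrates the whole chain on synthetic data: azeotrope location on
#' the configured system, the oven-evaporation experiment, the Avrami
#' drift fit with bootstrap CI, PLS calibration with LOO direction
#' selection, and (unless disabled) the repellence assays with sigmoid
#' fits and protection durations. Writes `report.json` (machine-readable,
#' atomic) and `summary.txt` to `out_dir`; identical config and seed give
#' byte-identical reports.
#'
#' @param config an `azeo_config` or path; `NULL` uses the shipped
#'   reference system.
#' @param out_dir output directory.
#' @param seed integer seed governing every stochastic stage.
#' @param bootstrap_replicates bootstrap size for the azeotrope CI.
#' @param assay logical: run the repellence stage?
#' @param threshold protection-duration threshold.
#' @param quiet suppress stage banners.
#' @return the report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir = ".", seed = 42,
                         bootstrap_replicates = 200, assay = TRUE,
                         threshold = 0.8, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[azeoblend] ", ...)
  vle <- if (is.null(config)) make_reference_vle() else vle_from_config(config)
  gen <- generator_config(seed = seed)

  say("stage 1/5: azeotrope location (T = ", vle$temperature, " K)")
  az <- find_azeotropes(vle)

  say("stage 2/5: oven-evaporation experiment (", gen$n_oven, " dishes, seed ",
      seed, ")")
  oven <- gen_oven_experiment(gen, vle, spectra = FALSE)

  say("stage 3/5: Avrami drift fit + bootstrap (B = ", bootstrap_replicates, ")")
  fit <- fit_avrami(oven$drift)
  boot <- bootstrap_azeotrope(fit, n_replicates = bootstrap_replicates,
                              seed = seed)

  say("stage 4/5: PLS calibration (", gen$n_calibration, " mixtures)")
  calset <- gen_calibration_set(gen)
  cv <- loo_cv_select(calset$cal, max_components = 15)

  assay_report <- NULL
  if (assay) {
    say("stage 5/5: repellence assays (", gen$n_subjects, " subjects)")
    truths <- list(
      blend = list(p_max = 0.99, t50 = 5.5, s = 0.4),
      ir3535 = list(p_max = 0.95, t50 = 4.2, s = 0.6),
      deet = list(p_max = 0.98, t50 = 3.2, s = 0.25))
    assay_report <- lapply(names(truths), function(tr) {
      counts <- gen_assay_counts(truths[[tr]], gen,
                                 seed = seed + match(tr, names(truths)),
                                 treatment = tr)
      curve <- protection_curve(counts)
      sf <- fit_protection_curve(curve)
      dur <- if (!sf$degenerate && threshold < sf$p_max)
        protection_duration(sf, threshold) else NA_real_
      list(treatment = tr, p_max = sf$p_max, t50_h = sf$t50_h, s_h = sf$s_h,
           duration_h_at_threshold = dur, threshold = threshold)
    })
    names(assay_report) <- names(truths)
  } else say("stage 5/5: repellence stage skipped (no assay section)")

  report <- list(
    seed = seed,
    temperature_K = vle$temperature,
    azeotropes = az,
    azeotrope_fit = list(estimate_molpct = boot$estimate_molpct,
                         ci_low_molpct = boot$ci_low_molpct,
                         ci_high_molpct = boot$ci_high_molpct,
                         n_replicates = boot$n_replicates,
                         n_trajectories = length(fit$ids)),
    pls = list(chosen_components = cv$chosen,
               mean_abs_error_molpct = cv$table$mean_abs_error_molpct[cv$chosen],
               max_abs_error_molpct = cv$table$max_abs_error_molpct[cv$chosen],
               cv_table = cv$table),
    repellence = if (is.null(assay_report)) "skipped" else assay_report)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_atomic(file.path(out_dir, "report.json"), function(p)
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE))
  write_atomic(file.path(out_dir, "summary.txt"), function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(c(
      sprintf("azeoblend pipeline report (seed %d)", seed),
      sprintf("azeotropes: %s",
              paste(sprintf("%.1f mol%% (%s, %s)", az$x_a_molpct, az$sign,
                            az$stability), collapse = "; ")),
      sprintf("drift-fit azeotrope estimate: %.1f mol%% (%.1f, %.1f)",
              boot$estimate_molpct, boot$ci_low_molpct, boot$ci_high_molpct),
      sprintf("PLS directions chosen by LOO: %d (mean |err| %.2f mol%%, max %.2f mol%%)",
              cv$chosen, cv$table$mean_abs_error_molpct[cv$chosen],
              cv$table$max_abs_error_molpct[cv$chosen]),
      if (is.null(assay_report)) "repellence: skipped" else
        sprintf("protection duration at P > %.2f: %s", threshold,
                paste(vapply(assay_report, function(a)
                  sprintf("%s %.1f h", a$treatment,
                          a$duration_h_at_threshold), character(1)),
                  collapse = ", "))), con)
  })
  invisible(report)
}
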