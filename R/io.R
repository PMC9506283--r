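#' Read a measurement curve from a headered TSV file
#'
#' All curve kinds share one interchange dialect: tab-separated numeric
#' columns preceded by `# key: value` metadata lines. Column layouts:
#' isotherm `(area, pressure)`; transient `(time, delta_pi[, flag])`
#' with a required `rel_area_change` key; reflectivity `(qz, R[, dR])`;
#' gixd `(qxy, intensity)`. Malformed rows are rejected with their line
#' numbers.
#'
#' @param path File path.
#' @param kind One of `"isotherm"`, `"transient"`, `"reflectivity"`,
#'   `"gixd"`.
#' @return The corresponding typed curve tibble with metadata
#'   attributes (see [curve_meta()]).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_curve(gen_isotherm("ideal_gas"), f)
#' iso <- read_curve(f, "isotherm")
#' curve_meta(iso, "temperature")
#' @export
read_curve <- function(path, kind = c("isotherm", "transient", "reflectivity", "gixd")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste("file not found:", path))
  lines <- readLines(path)
  if (!length(lines)) abort("empty file")
  header <- grep("^#", lines, value = TRUE)
  body_idx <- grep("^[^#]", lines)
  if (!length(body_idx)) abort("file has no data rows")
  meta <- parse_header(header)

  spec <- curve_spec(kind)
  fields <- lapply(strsplit(lines[body_idx], "\t", fixed = TRUE), trimws)
  ncols <- lengths(fields)
  ok_cols <- ncols %in% c(length(spec$cols), length(spec$cols) + length(spec$opt_cols))
  if (!all(ok_cols)) {
    abort(sprintf(
      "wrong column count for %s on line(s) %s (expected %d%s columns)",
      kind, paste(head(body_idx[!ok_cols], 5), collapse = ", "),
      length(spec$cols),
      if (length(spec$opt_cols)) paste0(" or ", length(spec$cols) + length(spec$opt_cols)) else ""
    ))
  }
  n_use <- min(ncols)
  vals <- suppressWarnings(
    vapply(seq_len(n_use), function(j) {
      as.numeric(vapply(fields, `[[`, character(1), j))
    }, numeric(length(fields)))
  )
  if (length(fields) == 1L) vals <- matrix(vals, nrow = 1)
  bad <- which(apply(vals, 1, function(r) any(is.na(r))))
  if (length(bad)) {
    abort(paste(
      "non-numeric payload on line(s)",
      paste(head(body_idx[bad], 5), collapse = ", ")
    ))
  }
  df <- as_tibble(setNames(
    as.data.frame(vals),
    c(spec$cols, spec$opt_cols)[seq_len(n_use)]
  ))
  for (key in spec$required_meta) {
    if (is.null(meta[[key]])) {
      abort(sprintf("missing required header key `%s` for a %s file", key, kind))
    }
  }
  build_curve(kind, df, meta)
}

curve_spec <- function(kind) {
  switch(kind,
    isotherm = list(cols = c("area", "pressure"), opt_cols = character(0),
                    required_meta = character(0)),
    transient = list(cols = c("time", "delta_pi"), opt_cols = "flag",
                     required_meta = "rel_area_change"),
    reflectivity = list(cols = c("qz", "R"), opt_cols = "dR",
                        required_meta = character(0)),
    gixd = list(cols = c("qxy", "intensity"), opt_cols = character(0),
                required_meta = character(0))
  )
}

parse_header <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
  meta <- list()
  for (m in kv) {
    if (length(m) == 3L) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

build_curve <- function(kind, df, meta) {
  switch(kind,
    isotherm = new_ml_curve(df,
      class = "ml_isotherm",
      temperature = meta$temperature_K %||% meta$temperature %||% NA_real_,
      composition = meta$composition %||% "unknown",
      subphase = meta$subphase %||% "unknown", seed = meta$seed
    ),
    transient = new_ml_curve(df,
      class = "ml_transient",
      rel_area_change = meta$rel_area_change,
      target_pressure = meta$pi0 %||% meta$target_pressure %||% NA_real_,
      seed = meta$seed
    ),
    reflectivity = {
      out <- df
      if (!is.null(meta$subphase_rho_e)) {
        out$RF <- fresnel(df$qz, meta$subphase_rho_e)
        out$RRF <- out$R / out$RF
      }
      new_ml_curve(out,
        class = "ml_reflectivity",
        subphase_rho_e = meta$subphase_rho_e %||% .water_rho_e,
        wavelength = meta$wavelength %||% 1.55, seed = meta$seed
      )
    },
    gixd = new_ml_curve(df,
      class = "ml_gixd",
      wavelength = meta$wavelength %||% 1.55, seed = meta$seed
    )
  )
}

#' Write a curve to a headered TSV file
#'
#' The inverse of [read_curve()]: metadata attributes become `# key:
#' value` lines and the payload is written as tab-separated columns at
#' full precision, so a write/read round trip is lossless.
#'
#' @param x A curve tibble (isotherm, transient, reflectivity or gixd).
#' @param path Output path.
#' @param extra_meta Named list of additional header keys (for example
#'   the generating seed).
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path, extra_meta = list()) {
  kind_cols <- list(
    ml_isotherm = c("area", "pressure"),
    ml_transient = c("time", "delta_pi"),
    ml_reflectivity = c("qz", "R"),
    ml_gixd = c("qxy", "intensity")
  )
  kind <- intersect(class(x), names(kind_cols))
  if (!length(kind)) abort("not a writable curve object")
  cols <- kind_cols[[kind[1]]]

  meta_keys <- list(
    ml_isotherm = c(temperature_K = "temperature", composition = "composition",
                    subphase = "subphase"),
    ml_transient = c(rel_area_change = "rel_area_change", pi0 = "target_pressure"),
    ml_reflectivity = c(subphase_rho_e = "subphase_rho_e", wavelength = "wavelength"),
    ml_gixd = c(wavelength = "wavelength")
  )[[kind[1]]]
  meta <- list()
  for (k in names(meta_keys)) {
    v <- curve_meta(x, meta_keys[[k]])
    if (!is.null(v) && !all(is.na(v))) meta[[k]] <- v
  }
  meta <- modifyList(meta, extra_meta)

  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 15)), con)
  }
  mat <- vapply(cols, function(cn) format(x[[cn]], digits = 17, trim = TRUE,
                                          scientific = FALSE), character(nrow(x)))
  writeLines(apply(matrix(mat, ncol = length(cols)), 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Run an analysis pipeline
#'
#' Executes a sequence of named stages, reading and writing the
#' package's interchange files in `out_dir` and emitting one
#' machine-readable JSON manifest per stage (inputs, parameters, seed,
#' package version, outputs), so every output can be regenerated from
#' its manifest. Available stages:
#'
#' * `synth` - generate the default synthetic inputs (isotherm,
#'   transient, reflectivity, diffraction pattern);
#' * `isotherm` - compression modulus, lift-off and gradient segments;
#' * `rheology` - relaxation fit, viscoelastic spectrum, plateau;
#' * `xrr` - slab-model fit and electron density profile;
#' * `gixd` - Bragg-peak fit, d-spacing and coherence length.
#'
#' @param stages Character vector of stage names, run in order.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing all randomness in the run.
#' @param params Named list of per-stage parameter lists, e.g.
#'   `list(rheology = list(max_modes = 2))`.
#' @param inputs Named list of per-stage input paths; stages default to
#'   the files the `synth` stage writes into `out_dir`.
#' @return Named list of per-stage result objects, invisibly.
#' @examples
#' \donttest{
#' run_pipeline(c("synth", "isotherm", "rheology"), out_dir = tempfile())
#' }
#' @export
run_pipeline <- function(stages, out_dir, seed = 1L, params = list(),
                         inputs = list()) {
  valid <- c("synth", "isotherm", "rheology", "xrr", "gixd")
  bad <- setdiff(stages, valid)
  if (length(bad)) {
    abort(sprintf(
      "unknown stage `%s`; valid stages: %s", bad[1], paste(valid, collapse = ", ")
    ))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (stage in stages) {
    p <- params[[stage]] %||% list()
    input <- inputs[[stage]]
    res <- tryCatch(
      run_stage(stage, out_dir, seed, p, input),
      error = function(e) {
        abort(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)))
      }
    )
    manifest <- list(
      stage = stage,
      inputs = res$inputs,
      parameters = if (length(p)) p else NULL,
      seed = seed,
      package_version = as.character(utils::packageVersion("leafletlab")),
      outputs = res$outputs
    )
    jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    results[[stage]] <- res$value
  }
  invisible(results)
}

run_stage <- function(stage, out_dir, seed, p, input) {
  path <- function(f) file.path(out_dir, f)
  switch(stage,
    synth = {
      iso <- gen_isotherm("piecewise_linear",
        coefficients = list(liftoff_area = p$liftoff_area %||% 64,
                            slopes = p$slopes %||% c(3, 9),
                            break_pressures = p$break_pressures %||% 22),
        area = seq(70, 30, length.out = 400),
        noise_sd = p$isotherm_noise_sd %||% 0.05, seed = seed
      )
      tr <- gen_relaxation(
        delta_pi_inf = p$delta_pi_inf %||% 1.0,
        amplitudes = p$amplitudes %||% 0.5,
        taus = p$taus %||% 100,
        time = seq(0, 900, by = 0.5),
        noise_sd = p$transient_noise_sd %||% 0.01, seed = seed + 1L
      )
      refl <- gen_reflectivity(
        slab_model(p$thickness %||% c(17.3, 9.0), p$rho_e %||% c(0.30, 0.45),
                   sigma = p$sigma %||% 3),
        noise_rel = p$reflectivity_noise_rel %||% 0.02, seed = seed + 2L
      )
      pat <- gen_gixd_peak(p$q0 %||% 1.5036, p$fwhm %||% 0.0318,
        amplitude = p$amplitude %||% 400,
        noise_sd = p$gixd_noise_sd %||% 2, seed = seed + 3L
      )
      write_curve(iso, path("isotherm.tsv"), extra_meta = list(seed = seed))
      write_curve(tr, path("transient.tsv"), extra_meta = list(seed = seed + 1L))
      write_curve(refl, path("reflectivity.tsv"), extra_meta = list(seed = seed + 2L))
      write_curve(pat, path("gixd.tsv"), extra_meta = list(seed = seed + 3L))
      list(
        inputs = NULL, value = NULL,
        outputs = c("isotherm.tsv", "transient.tsv", "reflectivity.tsv", "gixd.tsv")
      )
    },
    isotherm = {
      input <- input %||% path("isotherm.tsv")
      iso <- read_curve(input, "isotherm")
      cm <- compression_modulus(iso, window = p$window %||% 11L,
                                polyorder = p$polyorder %||% 2L)
      seg <- segment_gradients(iso, n_segments = p$n_segments %||% 2L)
      report <- list(
        liftoff_area = liftoff_area(iso, threshold = p$threshold %||% 0.5,
                                    window = p$liftoff_window %||% 5L),
        segments = tidy(seg), seed = curve_meta(iso, "seed")
      )
      readr::write_tsv(cm, path("compression_modulus.tsv"))
      jsonlite::write_json(report, path("isotherm_report.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(inputs = input, value = report,
           outputs = c("compression_modulus.tsv", "isotherm_report.json"))
    },
    rheology = {
      input <- input %||% path("transient.tsv")
      tr <- read_curve(input, "transient")
      fit <- fit_relaxation(tr, max_modes = p$max_modes %||% 2L)
      nu <- 10^seq(log10(p$nu_min %||% 1e-4), log10(p$nu_max %||% 1),
        length.out = p$nu_points %||% 241
      )
      sp <- spectrum_from_fit(fit, nu = nu)
      readr::write_tsv(sp, path("spectrum.tsv"))
      report <- list(
        fit = tidy(fit), n_modes = fit$n_modes,
        plateau = plateau_modulus(sp), seed = curve_meta(tr, "seed")
      )
      jsonlite::write_json(report, path("rheology_report.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(inputs = input, value = report,
           outputs = c("spectrum.tsv", "rheology_report.json"))
    },
    xrr = {
      input <- input %||% path("reflectivity.tsv")
      curve <- read_curve(input, "reflectivity")
      init <- slab_model(p$init_thickness %||% c(15, 10),
                         p$init_rho_e %||% c(0.32, 0.42),
                         sigma = p$init_sigma %||% 3)
      fit <- fit_reflectivity(curve, init, fixed = p$fixed %||% character(0))
      prof <- density_profile(fit$model)
      readr::write_tsv(prof, path("density_profile.tsv"))
      report <- list(
        parameters = tidy(fit), d_tot = fit$d_tot,
        first_minimum = first_minimum(slab_reflectivity(
          fit$model, seq(0.03, 0.45, 5e-4)
        )),
        seed = curve_meta(curve, "seed")
      )
      jsonlite::write_json(report, path("xrr_report.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(inputs = input, value = report,
           outputs = c("density_profile.tsv", "xrr_report.json"))
    },
    gixd = {
      input <- input %||% path("gixd.tsv")
      pat <- read_curve(input, "gixd")
      pk <- fit_peak(pat, shape = p$shape %||% "lorentzian",
                     q_window = p$q_window)
      report <- list(
        peak = tidy(pk),
        packing = classify_packing(pk),
        seed = curve_meta(pat, "seed")
      )
      jsonlite::write_json(report, path("gixd_report.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(inputs = input, value = report, outputs = "gixd_report.json")
    }
  )
}
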