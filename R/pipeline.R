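# End-to-end orchestration: generate (or load) measurement sets, run the
# impedance / window / transient analyses, fit the excitation model and
# emit the safety map plus a reproducibility manifest.

default_run_config <- function() {
  list(
    generator = NULL,          # list(material, diameters_m, separation_factor,
                               #      medium, currents_a, pulse_widths_s)
    input_dir = NULL,
    reactance_freq_hz = 1e4,
    scan_rate_v_per_s = 0.2,
    detector = list(baseline_band = 0.4, onset_ratio = 3),
    shannon_k = 1.8,
    out_dir = "stimsafe-run",
    seed = 1L
  )
}

#' Parse and validate a pipeline configuration file
#'
#' JSON configuration mirroring the arguments of [run_pipeline()].
#' Defaults are applied (reactance frequency 10 kHz, scan rate 0.2 V/s,
#' baseline band 0.4, onset ratio 3); unknown keys are rejected by name.
#' Exactly one of `generator` or `input_dir` must be present.
#'
#' @param path Path to a JSON file.
#' @return A validated config list of class `"run_config"`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(user)
}

#' @rdname parse_config
#' @param cfg A named list of configuration values.
#' @export
validate_config <- function(cfg) {
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  # keep absent optional keys present-as-NULL so configs round-trip
  for (nm in names(defaults)) {
    if (!nm %in% names(out)) out[nm] <- list(NULL)
  }
  out <- out[names(defaults)]
  has_gen <- !is.null(out$generator)
  has_in <- !is.null(out$input_dir)
  if (has_gen == has_in)
    stop("exactly one of 'generator' or 'input_dir' must be given")
  if (has_gen) {
    need <- c("material", "diameters_m")
    miss <- setdiff(need, names(out$generator))
    if (length(miss))
      stop("generator spec missing keys: ", paste(miss, collapse = ", "))
    gdef <- list(separation_factor = 1.5, medium = "benchtop_saline",
                 currents_a = c(20, 63, 200, 630, 2000) * 1e-6,
                 pulse_widths_s = c(100, 180, 320, 560, 1000) * 1e-6)
    out$generator <- utils::modifyList(gdef, out$generator)
  }
  stopifnot(out$reactance_freq_hz > 0, out$scan_rate_v_per_s > 0)
  out$seed <- as.integer(out$seed)
  structure(out, class = "run_config")
}

#' Run the full safety-limit pipeline
#'
#' Executes generate/load, interface delineation, impedance-diameter
#' scaling, electrolysis-window detection, cathodal-excitation
#' extraction, full-model fitting, current-limit inversion and the
#' Shannon comparison; writes every artifact under `cfg$out_dir` along
#' with a manifest JSON (config, seed, package version, file hashes).
#'
#' @param cfg A config list from [parse_config()] / [validate_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  if (is.null(cfg$generator))
    stop("loading measured input directories is supported record-by-record ",
         "through the read_*_csv functions; run_pipeline currently ",
         "orchestrates generated studies (cfg$generator)")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- cfg$generator
  preset <- material_preset(g$material)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  emit <- function(obj, fname, writer) {
    p <- file.path(cfg$out_dir, fname)
    writer(obj, p)
    files <<- c(files, p, sidecar_path(p)[file.exists(sidecar_path(p))])
    p
  }

  # EIS per diameter: delineate interface, reactance at the principal f
  eis_rows <- stage("eis_analysis", {
    rows <- lapply(seq_along(g$diameters_m), function(j) {
      d <- g$diameters_m[j]
      spec <- electrode_spec(g$material, d, g$separation_factor, g$medium)
      ds <- generate_eis_dataset(
        spec, preset, configs = c("three_contact", "four_contact"),
        noise = noise_spec(seed = cfg$seed + j))
      emit(ds$three_contact, sprintf("eis_3c_D%.0fum.csv", d * 1e6),
           write_eis_csv)
      emit(ds$four_contact, sprintf("eis_4c_D%.0fum.csv", d * 1e6),
           write_eis_csv)
      iface <- delineate_interface(ds$three_contact, ds$four_contact)
      data.frame(diameter_m = d,
                 z_imag_ohm = reactance_at(iface, cfg$reactance_freq_hz))
    })
    do.call(rbind, rows)
  })
  scaling <- stage("impedance_scaling",
                   fit_impedance_scaling(eis_rows$diameter_m,
                                         eis_rows$z_imag_ohm))

  # electrolysis window from the stimulation configuration (two-contact)
  d_ref <- g$diameters_m[which.min(abs(g$diameters_m -
                                         stats::median(g$diameters_m)))]
  spec_ref <- electrode_spec(g$material, d_ref, g$separation_factor,
                             g$medium)
  window <- stage("cv_analysis", {
    cv <- generate_cv(spec_ref, preset,
                      scan_rate = cfg$scan_rate_v_per_s,
                      noise = noise_spec(seed = cfg$seed),
                      config = "two_contact")
    emit(cv, sprintf("cv_2c_D%.0fum.csv", d_ref * 1e6), write_cv_csv)
    detect_electrolysis_window(cv,
                               baseline_band = cfg$detector$baseline_band,
                               onset_ratio = cfg$detector$onset_ratio)
  })

  # transients over the current x pulse-width x diameter design
  records <- stage("transient_analysis", {
    rows <- lapply(seq_along(g$diameters_m), function(j) {
      d <- g$diameters_m[j]
      spec <- electrode_spec(g$material, d, g$separation_factor, g$medium)
      vts <- generate_transient_dataset(spec, preset, g$currents_a,
                                        g$pulse_widths_s,
                                        noise = noise_spec(seed = cfg$seed + j))
      z <- attr(vts, "z_imag_10k")
      do.call(rbind, lapply(vts, function(vt) {
        feat <- extract_cathodal_excitation(vt)
        data.frame(i_inj = vt$pulse$i_inj, t_pw = vt$pulse$t_pw,
                   z_imag = z, v_access = feat$v_access,
                   v_elec = feat$v_elec, diameter_m = d)
      }))
    })
    do.call(rbind, rows)
  })
  p <- file.path(cfg$out_dir, "transient_features.csv")
  utils::write.csv(records[c("i_inj", "t_pw", "v_access", "v_elec")],
                   p, row.names = FALSE)
  files <- c(files, p)

  params <- stage("safety_model", fit_full_model(records))

  # safety map: model limit vs Shannon limit over the design space
  safety_map <- stage("safety_map", {
    grid <- expand.grid(diameter_m = g$diameters_m,
                        t_pw_s = g$pulse_widths_s,
                        KEEP.OUT.ATTRS = FALSE)
    grid$i_limit_model_a <- ilimit_vs_diameter(
      params, scaling, abs(window$e_mc), grid$t_pw_s, grid$diameter_m)
    grid$i_limit_shannon_a <- vapply(seq_len(nrow(grid)), function(j)
      shannon_limit(grid$diameter_m[j], grid$t_pw_s[j],
                    cfg$shannon_k)$i_limit_a, 0)
    grid
  })
  p <- file.path(cfg$out_dir, "safety_map.csv")
  utils::write.csv(safety_map, p, row.names = FALSE)
  files <- c(files, p)

  results <- list(
    scaling = unclass(scaling),
    window = list(e_mc = window$e_mc, e_ma = window$e_ma,
                  detector = window$method_meta[c("baseline_band",
                                                  "onset_ratio")]),
    safety_params = unclass(params)[c("a", "b", "k2", "k4", "k6",
                                      "adj_r2")],
    unit_convention = params$unit_convention
  )
  p <- file.path(cfg$out_dir, "results.json")
  jsonlite::write_json(results, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p)

  manifest <- list(
    package = "stimsafe",
    version = as.character(utils::packageVersion("stimsafe")),
    seed = cfg$seed,
    config = unclass(cfg),
    results = results,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f)))
  )
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
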