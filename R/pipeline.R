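#' Configuration for the full interaction pipeline
#'
#' Collects the per-assay inputs and every tunable threshold of the
#' workflow. Inputs may be in-memory objects ([titration_series()],
#' [melting_curve()]) or file paths readable by [read_titration_table()] /
#' [read_melting_table()].
#'
#' @param inputs Named list of assay inputs, any subset of:
#'   * `quench`: named list (names = temperature in K) of emission
#'     titrations;
#'   * `sync15`, `sync60`: synchronous titrations;
#'   * `ans`: ANS titration;
#'   * `melting`: named list of melting curves (e.g. `native`, `complex`);
#'   * `cd`: data frame with columns `theta208`, `protein_conc_M`,
#'     `n_residues`, `path_length_cm` (one row per condition), or a list of
#'     far-UV [spectrum()] objects plus those scan conditions;
#'   * `zeta`: named numeric vector of zeta potentials in mV.
#' @param tau0 Fluorophore lifetime in s (default 6 ns).
#' @param breakpoint Stern-Volmer breakpoint policy: a concentration in
#'   molar (default 15e-6) or `"auto"`.
#' @param static_factor,f_threshold Passed to [classify_quenching()].
#' @param shift_threshold nm, passed to [shift_series()].
#' @param plateau_rel_tol Passed to [detect_plateau()].
#' @param force_epsilon J/mol, passed to [classify_forces()].
#' @param window Optional wavelength window for peak extraction.
#' @param reference_thermo Optional list(dH, dS) of externally reported
#'   thermodynamic parameters; when present the thermo stage emits the
#'   [vant_hoff_consistency()] diagnostic against them.
#' @param seed Optional integer consumed by any stochastic stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(inputs = list(), tau0 = 6e-9, breakpoint = 15e-6,
                            static_factor = 100, f_threshold = 10,
                            shift_threshold = 1, plateau_rel_tol = 0.05,
                            force_epsilon = 100, window = NULL,
                            reference_thermo = NULL, seed = NULL) {
  thresholds <- c(tau0 = tau0, static_factor = static_factor,
                  f_threshold = f_threshold, shift_threshold = shift_threshold,
                  plateau_rel_tol = plateau_rel_tol,
                  force_epsilon = force_epsilon)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    abort("all pipeline thresholds must be positive and finite.")
  }
  structure(
    list(inputs = inputs, tau0 = tau0, breakpoint = breakpoint,
         static_factor = static_factor, f_threshold = f_threshold,
         shift_threshold = shift_threshold,
         plateau_rel_tol = plateau_rel_tol, force_epsilon = force_epsilon,
         window = window, reference_thermo = reference_thermo, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full spectroscopic interaction workflow
#'
#' Executes every analysis stage whose input is present in the
#' configuration -- Stern-Volmer quenching (per temperature) with mechanism
#' classification, double-log binding fits, van't Hoff thermodynamics with
#' force classification (and, when references are supplied, the
#' consistency diagnostic), synchronous shift analysis, ANS normalisation
#' with plateau detection, first-derivative melting temperatures with the
#' Tm change, CD records, and colloidal-stability classes -- and assembles
#' a structured report. A failing stage is recorded under `errors` without
#' aborting the others.
#'
#' @param config A [pipeline_config()] with at least one assay input.
#' @return An object of class `"interaction_report"`: list with the echoed
#'   `config` (thresholds), per-stage results (each carrying an `operation`
#'   provenance field), `conclusions` (quench mechanism, force class,
#'   spontaneity, shift verdicts, plateau onset, delta-Tm) and `errors`.
#'   Serialise with [report_json()]; print for a human summary.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  inputs <- config$inputs
  if (length(inputs) == 0 || all(purrr::map_lgl(inputs, is.null))) {
    abort("no assay inputs present in the configuration.")
  }
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  as_series <- function(x) if (is.character(x)) read_titration_table(x) else x
  as_curve <- function(x) if (is.character(x)) read_melting_table(x) else x

  report <- list(config = .echo_config(config))

  # --- quenching + binding per temperature -----------------------------------
  if (!is.null(inputs$quench)) {
    report$quench <- stage("quench", {
      fits <- purrr::imap(inputs$quench, function(series, nm) {
        series <- as_series(series)
        pts <- stern_volmer_points(series, window = config$window)
        fit <- fit_two_regime_sv(pts, breakpoint = config$breakpoint,
                                 tau0 = config$tau0)
        cls <- classify_quenching(fit, static_factor = config$static_factor,
                                  f_threshold = config$f_threshold)
        list(temperature_K = attr(series, "temperature_K"),
             points = pts, fit = fit, classification = cls)
      })
      list(operation = "stern_volmer_points + fit_two_regime_sv + classify_quenching",
           by_temperature = fits)
    })
    report$binding <- stage("binding", {
      fits <- purrr::map(inputs$quench, function(series) {
        series <- as_series(series)
        pts <- stern_volmer_points(series, window = config$window)
        fit_double_log(pts)
      })
      list(operation = "fit_double_log",
           by_temperature = fits,
           kb_table = purrr::map_dfr(fits, ~ tibble(
             temperature_K = .x$temperature_K, Kb = .x$Kb, n_sites = .x$n_sites)))
    })
  }

  # --- thermodynamics --------------------------------------------------------
  kb_tbl <- report$binding$kb_table
  if (!is.null(kb_tbl) && nrow(kb_tbl) >= 2) {
    report$thermo <- stage("thermo", {
      prof <- thermo_profile(kb_tbl[, c("temperature_K", "Kb")],
                             epsilon = config$force_epsilon)
      consistency <- NULL
      if (!is.null(config$reference_thermo)) {
        consistency <- withCallingHandlers(
          vant_hoff_consistency(prof$vant_hoff,
                                config$reference_thermo$dH,
                                config$reference_thermo$dS),
          warning = function(w) invokeRestart("muffleWarning")
        )
      }
      list(operation = "vant_hoff_fit + gibbs_free_energy + classify_forces",
           profile = prof, consistency = consistency)
    })
  }

  # --- conformational probes -------------------------------------------------
  for (nm in c("sync15", "sync60")) {
    if (!is.null(inputs[[nm]])) {
      report[[nm]] <- stage(nm, {
        sh <- shift_series(as_series(inputs[[nm]]),
                           threshold = config$shift_threshold,
                           window = config$window)
        list(operation = "shift_series", shifts = sh,
             verdict = attr(sh, "verdict"))
      })
    }
  }
  if (!is.null(inputs$ans)) {
    report$ans <- stage("ans", {
      norm <- normalize_ans(as_series(inputs$ans), window = config$window)
      list(operation = "normalize_ans + detect_plateau",
           normalized = norm,
           plateau_onset_M = detect_plateau(norm, rel_tol = config$plateau_rel_tol))
    })
  }
  if (!is.null(inputs$melting)) {
    report$melting <- stage("melting", {
      tms <- purrr::map(inputs$melting, ~ melting_tm(as_curve(.x)))
      tm_tbl <- tibble(condition = names(tms),
                       Tm_C = purrr::map_dbl(tms, "Tm_C"))
      d_tm <- if (all(c("native", "complex") %in% tm_tbl$condition)) {
        tm_tbl$Tm_C[tm_tbl$condition == "complex"] -
          tm_tbl$Tm_C[tm_tbl$condition == "native"]
      } else NA_real_
      list(operation = "melting_tm", results = tms, table = tm_tbl,
           delta_Tm_C = d_tm)
    })
  }
  if (!is.null(inputs$cd)) {
    report$cd <- stage("cd", {
      cd_in <- inputs$cd
      rec <- purrr::pmap_dfr(as_tibble(cd_in), cd_record)
      list(operation = "mean_residue_ellipticity + helix_fraction",
           records = rec)
    })
  }
  if (!is.null(inputs$zeta)) {
    report$zeta <- stage("zeta", {
      z <- inputs$zeta
      list(operation = "classify_colloidal_stability",
           table = tibble(system = names(z) %||% as.character(seq_along(z)),
                          zeta_mV = unname(z),
                          stability = classify_colloidal_stability(unname(z))))
    })
  }

  report$conclusions <- .pipeline_conclusions(report)
  report$errors <- errors
  structure(report, class = "interaction_report")
}

.echo_config <- function(config) {
  list(tau0 = config$tau0, breakpoint = config$breakpoint,
       static_factor = config$static_factor,
       f_threshold = config$f_threshold,
       shift_threshold = config$shift_threshold,
       plateau_rel_tol = config$plateau_rel_tol,
       force_epsilon = config$force_epsilon,
       window = config$window, reference_thermo = config$reference_thermo,
       seed = config$seed)
}

.pipeline_conclusions <- function(report) {
  con <- list()
  if (!is.null(report$quench)) {
    first <- report$quench$by_temperature[[1]]
    con$quench_mechanism <- first$classification$mechanism
    con$sv_linear <- first$classification$linear
  }
  if (!is.null(report$thermo)) {
    con$force_class <- report$thermo$profile$force_class
    con$spontaneous <- all(report$thermo$profile$dG_by_T$spontaneous)
    if (!is.null(report$thermo$consistency)) {
      con$thermo_consistent_with_reference <-
        isTRUE(attr(report$thermo$consistency, "consistent"))
    }
  }
  for (nm in c("sync15", "sync60")) {
    if (!is.null(report[[nm]])) con[[paste0(nm, "_verdict")]] <- report[[nm]]$verdict
  }
  if (!is.null(report$ans)) con$ans_plateau_onset_M <- report$ans$plateau_onset_M
  if (!is.null(report$melting)) {
    con$delta_Tm_C <- report$melting$delta_Tm_C
    con$destabilised <- isTRUE(report$melting$delta_Tm_C < 0)
  }
  con
}

#' Serialise an interaction report to JSON
#'
#' Canonical machine-readable form of a [run_pipeline()] report: tibbles
#' become arrays of records, fit objects are reduced to their tidy
#' summaries, and all numbers are written at full precision.
#'
#' @param report An `"interaction_report"`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_json <- function(report, path = NULL) {
  if (!inherits(report, "interaction_report")) {
    abort("`report` must be an interaction_report.")
  }
  simplify <- function(x) {
    if (inherits(x, "sv_fit") || inherits(x, "binding_fit") ||
        inherits(x, "vant_hoff_fit")) {
      return(list(tidy = as.data.frame(generics::tidy(x)),
                  glance = as.data.frame(generics::glance(x))))
    }
    if (inherits(x, "quench_class")) {
      return(list(kq = as.data.frame(x$kq), mechanism = x$mechanism,
                  linear = x$linear, rationale = x$rationale))
    }
    if (inherits(x, "tm_result")) {
      return(list(Tm_C = x$Tm_C))
    }
    if (inherits(x, "thermo_result")) {
      return(list(dH = x$dH, dS = x$dS,
                  dG_by_T = as.data.frame(x$dG_by_T),
                  force_class = x$force_class, r2 = x$r2))
    }
    if (is.data.frame(x)) return(as.data.frame(x))
    if (is.list(x)) return(purrr::map(x, simplify))
    x
  }
  json <- jsonlite::toJSON(simplify(unclass(report)), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @export
print.interaction_report <- function(x, ...) {
  cat("Spectroscopic interaction report\n")
  cat("================================\n")
  con <- x$conclusions
  if (!is.null(x$quench)) {
    for (q in x$quench$by_temperature) {
      cat(sprintf("SV fit at %g K: K_SV = %s 1/M (breakpoint %s M)\n",
                  q$temperature_K,
                  paste(sprintf("%.4g", q$fit$regimes$K_SV), collapse = ", "),
                  format(q$fit$breakpoint)))
    }
    cat(sprintf("Quenching mechanism: %s (SV plot %s)\n",
                con$quench_mechanism,
                if (isTRUE(con$sv_linear)) "linear" else "non-linear"))
  }
  if (!is.null(x$binding)) {
    tb <- x$binding$kb_table
    for (i in seq_len(nrow(tb))) {
      cat(sprintf("Binding at %g K: Kb = %.4g 1/M, n = %.2f\n",
                  tb$temperature_K[i], tb$Kb[i], tb$n_sites[i]))
    }
  }
  if (!is.null(x$thermo)) {
    p <- x$thermo$profile
    cat(sprintf("Thermodynamics: dH = %.4g kJ/mol, dS = %.4g J/(mol K) -> %s, %s\n",
                p$dH / 1e3, p$dS, p$force_class,
                if (isTRUE(con$spontaneous)) "spontaneous" else "non-spontaneous"))
    if (isTRUE(con$thermo_consistent_with_reference == FALSE)) {
      cat("  NOTE: OLS van't Hoff estimates disagree with the supplied reference dH/dS.\n")
    }
  }
  for (nm in c("sync15", "sync60")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("Synchronous %s nm shift verdict: %s\n",
                  sub("sync", "", nm), x[[nm]]$verdict))
    }
  }
  if (!is.null(x$ans)) {
    cat(sprintf("ANS plateau onset: %s M\n", format(x$ans$plateau_onset_M)))
  }
  if (!is.null(x$melting)) {
    tb <- x$melting$table
    for (i in seq_len(nrow(tb))) {
      cat(sprintf("Tm (%s): %.2f C\n", tb$condition[i], tb$Tm_C[i]))
    }
    if (is.finite(x$melting$delta_Tm_C)) {
      cat(sprintf("delta Tm: %.2f C\n", x$melting$delta_Tm_C))
    }
  }
  if (!is.null(x$cd)) {
    cat(sprintf("CD: helix %% = %s\n",
                paste(sprintf("%.1f", x$cd$records$helix_pct), collapse = ", ")))
  }
  if (!is.null(x$zeta)) {
    z <- x$zeta$table
    cat(sprintf("Zeta: %s\n",
                paste(sprintf("%s %.4g mV (%s)", z$system, z$zeta_mV,
                              z$stability), collapse = "; ")))
  }
  if (length(x$errors) > 0) {
    cat("Stage errors:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

# ---- melting-curve text I/O -------------------------------------------------

#' Write a melting curve to a delimited text file
#'
#' Same dialect as [write_titration_table()]: `#` key:value header, then
#' `temperature_C,intensity` rows at full precision.
#'
#' @param curve A [melting_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_melting_table <- function(curve, path) {
  if (!inherits(curve, "melting_curve")) abort("`curve` must be a melting_curve.")
  rows <- paste(sprintf("%.17g", curve$temperature_C),
                sprintf("%.17g", curve$intensity), sep = ",")
  writeLines(c("# specbind melting v1", "temperature_C,intensity", rows), path)
  invisible(path)
}

#' Read a melting curve written by [write_melting_table()]
#' @param path Input file path.
#' @return A [melting_curve()].
#' @export
read_melting_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  melting_curve(df$temperature_C, df$intensity)
}
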