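#' Assemble a titration series from wide-format CSV files
#'
#' Reads an emission table (and optionally a matching absorbance table)
#' whose column headers are ligand concentrations in micromolar, and builds
#' a validated [titration_series].
#'
#' @param emission_path CSV path for the emission titration.
#' @param temperature Temperature in K.
#' @param protein_conc Total protein concentration in mol/L.
#' @param absorbance_path Optional CSV path for matching absorbance spectra.
#' @param excitation_wavelength nm (default 280).
#' @return A [titration_series].
#' @export
read_titration <- function(emission_path, temperature, protein_conc,
                           absorbance_path = NULL,
                           excitation_wavelength = 280) {
  emission <- read_spectrum_table(emission_path, kind = "emission")
  concs <- attr(emission, "concentrations_M")
  if (anyNA(concs)) {
    stop("format error: emission column headers must be ligand concentrations in uM",
         call. = FALSE)
  }
  absorbance <- NULL
  if (!is.null(absorbance_path)) {
    absorbance <- read_spectrum_table(absorbance_path, kind = "absorbance")
  }
  titration_series(temperature = temperature, protein_conc = protein_conc,
                   ligand_concs = concs, emission_spectra = emission,
                   excitation_wavelength = excitation_wavelength,
                   absorbance_spectra = absorbance)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read YAML configs", call. = FALSE)
      }
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

as_series <- function(x, defaults) {
  if (inherits(x, "titration_series")) return(x)
  stopifnot(is.list(x))
  read_titration(
    emission_path = x$emission,
    temperature = x$temperature,
    protein_conc = x$protein_conc %||% defaults$protein_conc,
    absorbance_path = x$absorbance,
    excitation_wavelength = x$excitation_wavelength %||%
      defaults$excitation_wavelength %||% 280)
}

as_spectra_list <- function(x, kind) {
  if (is.character(x)) return(read_spectrum_table(x, kind = kind))
  stopifnot(is.list(x))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full binding-characterization pipeline
#'
#' Orchestrates, as the supplied inputs permit: inner-filter correction,
#' Stern-Volmer fits per temperature, quenching-mechanism classification,
#' double-log binding fits, Van't Hoff thermodynamics with Gibbs energies
#' and force classification, CD helix estimation, EEM peak tables with
#' Rayleigh masking, synchronous-fluorescence shift/quench tables, DPV peak
#' metrics and site-marker comparison. Stage failures are recorded and
#' independent stages continue.
#'
#' @param config A named list, or a path to a JSON (or YAML) file. Any
#'   subset of the following entries is honoured:
#' \describe{
#'   \item{titrations}{List of [titration_series] objects, or of lists with
#'     `emission`/`absorbance` CSV paths plus `temperature` and
#'     `protein_conc`.}
#'   \item{ka, temperatures}{Association constants (M^-1) and temperatures
#'     (K) for a thermodynamics-only run (used when no titrations given).}
#'   \item{tau0}{Unquenched lifetime in s (default 1e-8).}
#'   \item{protein_conc, excitation_wavelength}{Defaults for titrations.}
#'   \item{read_wavelength}{Fixed emission wavelength for intensity
#'     readout; NULL (default) reads per-spectrum maxima.}
#'   \item{smooth_halfwidth}{Boxcar half-width in nm for the intensity
#'     readout (default 0), see [titration_intensities()].}
#'   \item{cd}{List: `spectrum` (a [spectrum] in mdeg) or `theta` (CSV
#'     path), `conc` (mg/mL), `path_length` (cm), `mrw`.}
#'   \item{eem}{An [eem] or a matrix-CSV path; plus optional
#'     `rayleigh_halfwidth` (nm).}
#'   \item{synchronous}{List of lists: `delta` (nm), `spectra` (list of
#'     [spectrum] or CSV path).}
#'   \item{dpv}{List of voltammogram [spectrum] objects or a CSV path.}
#'   \item{markers}{List: `plain`, `A`, `B` (series or CSV specs),
#'     `wavelength` (default 347), `site_A`, `site_B`.}
#'   \item{near_zero_tol}{J/mol, for force classification (default 4000).}
#'   \item{output_dir}{If set, report.json / report.md / CSV tables are
#'     written there.}
#' }
#' @return An object of class `quench_report`: per-stage status, fitted
#'   results, a per-temperature summary table (`table1`: T, K_SV, k_q,
#'   K_a, dS, dH, dG) and an EEM peak table (`table2`) when computed.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  tau0 <- config$tau0 %||% 1e-8
  near_zero_tol <- config$near_zero_tol %||% 4000
  report <- list(stages = list(), config_echo = list(
    tau0_s = tau0, near_zero_tol_J_mol = near_zero_tol,
    units = list(concentration = "mol/L", temperature = "K",
                 wavelength = "nm", potential = "V",
                 dH = "J/mol", dS = "J/(mol K)", dG = "J/mol")))

  run_stage <- function(name, expr) {
    res <- tryCatch(list(status = "ok", value = expr),
                    error = function(e) list(status = "failed",
                                             value = NULL,
                                             message = conditionMessage(e)))
    report$stages[[name]] <<- res[c("status", "message")]
    res$value
  }

  # -- titration-driven stages ------------------------------------------
  sv_fits <- list()
  bind_fits <- list()
  if (!is.null(config$titrations)) {
    series_list <- run_stage("load_titrations", {
      lapply(config$titrations, as_series, defaults = config)
    })
    if (!is.null(series_list)) {
      corrected <- run_stage("inner_filter_correction", {
        lapply(series_list, correct_titration)
      })
      if (is.null(corrected)) corrected <- series_list
      for (series in corrected) {
        tlab <- sprintf("%g", series$temperature)
        f <- titration_intensities(series,
                                   wavelength = config$read_wavelength,
                                   smooth_halfwidth =
                                     config$smooth_halfwidth %||% 0)
        sv <- run_stage(paste0("stern_volmer_T", tlab), {
          stern_volmer_fit(f[1], f[-1], series$ligand_concs[-1],
                           tau0 = tau0, temperature = series$temperature)
        })
        if (!is.null(sv)) sv_fits[[tlab]] <- sv
        bf <- run_stage(paste0("double_log_T", tlab), {
          double_log_fit(f[1], f[-1], series$ligand_concs[-1],
                         series$protein_conc)
        })
        if (!is.null(bf)) bind_fits[[tlab]] <- bf
      }
      report$quenching <- sv_fits
      report$binding <- bind_fits
      if (length(sv_fits) >= 2) {
        report$mechanism <- run_stage("mechanism_classification",
                                      classify_mechanism(sv_fits))
      }
    }
  }

  # -- thermodynamics ----------------------------------------------------
  ka <- NULL
  temps <- NULL
  if (length(bind_fits) >= 2) {
    ka <- vapply(bind_fits, function(b) b$K_a, numeric(1))
    temps <- as.numeric(names(bind_fits))
  }
  if (is.null(ka) && !is.null(config$ka)) {
    ka <- as.numeric(config$ka)
    temps <- as.numeric(config$temperatures)
  }
  if (!is.null(ka)) {
    report$thermo <- run_stage("vant_hoff",
                               vant_hoff_fit(ka, temps,
                                             near_zero_tol = near_zero_tol))
  }

  # -- per-temperature summary block (Table-1 style) ---------------------
  if (!is.null(ka) || length(sv_fits)) {
    tt <- sort(unique(c(temps,
                        as.numeric(names(sv_fits)))))
    tab <- data.frame(temperature = tt)
    tab$K_SV <- vapply(as.character(tt), function(k) {
      if (!is.null(sv_fits[[k]])) sv_fits[[k]]$K_SV else NA_real_
    }, numeric(1))
    tab$k_q <- vapply(as.character(tt), function(k) {
      if (!is.null(sv_fits[[k]])) sv_fits[[k]]$k_q else NA_real_
    }, numeric(1))
    tab$K_a <- if (!is.null(ka)) ka[match(tt, temps)] else NA_real_
    if (!is.null(report$thermo)) {
      tab$dS <- report$thermo$dS
      tab$dH <- report$thermo$dH
      tab$dG <- gibbs(report$thermo$dH, report$thermo$dS, tt)
      report$force_class <- report$thermo$force_class
    }
    report$table1 <- tab
  }

  # -- CD ----------------------------------------------------------------
  if (!is.null(config$cd)) {
    report$cd <- run_stage("cd_helix", {
      cd <- config$cd
      sp <- cd$spectrum
      if (is.null(sp)) {
        sp <- read_spectrum_table(cd$theta, kind = "emission")[[1]]
      }
      cd_analysis(sp, conc = cd$conc, path_length = cd$path_length,
                  mrw = cd$mrw %||% 110)
    })
  }

  # -- EEM ---------------------------------------------------------------
  if (!is.null(config$eem)) {
    report$table2 <- run_stage("eem_peaks", {
      x <- config$eem
      if (is.character(x)) x <- read_eem(x)
      eem_peak_table(x, rayleigh_halfwidth = config$rayleigh_halfwidth %||% 15)
    })
  }

  # -- synchronous fluorescence -----------------------------------------
  if (!is.null(config$synchronous)) {
    report$synchronous <- list()
    for (blk in config$synchronous) {
      nm <- paste0("synchronous_delta", blk$delta)
      tabk <- run_stage(nm, {
        shift_and_quench_table(as_spectra_list(blk$spectra, "synchronous"))
      })
      if (!is.null(tabk)) report$synchronous[[as.character(blk$delta)]] <- tabk
    }
  }

  # -- DPV ---------------------------------------------------------------
  if (!is.null(config$dpv)) {
    report$dpv <- run_stage("dpv_metrics", {
      dpv_series_metrics(as_spectra_list(config$dpv, "voltammogram"))
    })
  }

  # -- site markers ------------------------------------------------------
  if (!is.null(config$markers)) {
    report$markers <- run_stage("site_markers", {
      mk <- config$markers
      site_marker_comparison(
        as_series(mk$plain, config), as_series(mk$A, config),
        as_series(mk$B, config),
        wavelength = mk$wavelength %||% 347,
        site_A = mk$site_A %||% "I", site_B = mk$site_B %||% "II")
    })
  }

  report$failed_stages <- names(Filter(function(s) s$status == "failed",
                                       report$stages))
  class(report) <- "quench_report"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(report, file.path(config$output_dir, "report.json"))
    if (!is.null(report$table1)) {
      utils::write.csv(report$table1,
                       file.path(config$output_dir, "table1.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$table2)) {
      utils::write.csv(as.data.frame(report$table2),
                       file.path(config$output_dir, "table2_eem_peaks.csv"),
                       row.names = FALSE)
    }
    writeLines(utils::capture.output(print(report)),
               file.path(config$output_dir, "report.md"))
  }
  report
}

#' @export
print.quench_report <- function(x, ...) {
  cat("== binding characterization report ==\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  [%s] %s%s\n",
                if (s$status == "ok") "ok" else "FAILED", nm,
                if (!is.null(s$message)) paste0(": ", s$message) else ""))
  }
  if (!is.null(x$mechanism)) {
    cat(sprintf("mechanism: %s quenching\n", x$mechanism$verdict))
  }
  if (!is.null(x$table1)) {
    cat("per-temperature summary (SI units):\n")
    print(format(x$table1, digits = 4))
  }
  if (!is.null(x$force_class)) {
    cat(sprintf("dominant force: %s\n", x$force_class))
  }
  if (!is.null(x$cd)) {
    cat(sprintf("alpha-helix: %.1f%% (MRE_208 = %.0f)\n",
                x$cd$helix_pct, x$cd$mre_208))
  }
  if (!is.null(x$table2)) {
    cat("EEM fluorophore peaks (Rayleigh-masked):\n")
    print(format(as.data.frame(x$table2), digits = 4))
  }
  if (!is.null(x$dpv)) {
    cat(sprintf("DPV: delta E_p = %+.3g V, delta I_p = %+.3g\n",
                x$dpv$delta_E_p, x$dpv$delta_I_p))
  }
  if (!is.null(x$markers)) {
    cat(sprintf("site assignment: %s\n", x$markers$assigned_site))
  }
  invisible(x)
}
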