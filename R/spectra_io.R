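#' Construct a spectrum
#'
#' A spectrum is the basic measured curve used throughout the package: an
#' ordered abscissa (wavelength in nm for optical data, potential in V for
#' voltammetry) paired with a signal vector (fluorescence a.u., absorbance,
#' mdeg, or current in uA).
#'
#' @param abscissa Numeric vector, strictly increasing, length >= 3.
#' @param signal Numeric vector of the same length as `abscissa`.
#' @param label Free-text label (e.g. the ligand concentration the trace
#'   was recorded at).
#' @return An object of class `spectrum`: a list with elements `abscissa`,
#'   `signal` and `label`.
#' @examples
#' sp <- spectrum(300:450, dnorm(300:450, 347, 25), label = "0 uM")
#' peak <- find_peak(sp)
#' @export
spectrum <- function(abscissa, signal, label = "") {
  abscissa <- as.numeric(abscissa)
  signal <- as.numeric(signal)
  if (length(abscissa) != length(signal)) {
    stop("abscissa and signal must have equal length", call. = FALSE)
  }
  if (length(abscissa) < 3) {
    stop("a spectrum needs at least 3 points", call. = FALSE)
  }
  if (anyNA(abscissa) || any(!is.finite(abscissa))) {
    stop("abscissa must be finite", call. = FALSE)
  }
  d <- diff(abscissa)
  if (any(d <= 0)) {
    row <- which(d <= 0)[1] + 1L
    stop(sprintf("abscissa must be strictly increasing (violated at row %d, value %g)",
                 row, abscissa[row]), call. = FALSE)
  }
  structure(list(abscissa = abscissa, signal = signal,
                 label = as.character(label)[1]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, abscissa %g..%g%s\n",
              length(x$abscissa), min(x$abscissa), max(x$abscissa),
              if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' Construct a fluorescence titration series
#'
#' Bundles one emission spectrum per ligand concentration, recorded at a
#' single temperature, together with the protein concentration and
#' (optionally) the matching absorbance spectra needed for inner-filter
#' correction. The first rung of the ladder must be 0 (the unquenched F0
#' spectrum).
#'
#' @param temperature Temperature in K.
#' @param protein_conc Total protein concentration in mol/L.
#' @param ligand_concs Ligand concentration ladder in mol/L; non-negative,
#'   strictly increasing, starting at 0.
#' @param emission_spectra List of [spectrum] objects, one per rung.
#' @param excitation_wavelength Excitation wavelength in nm (default 280,
#'   the tryptophan/tyrosine band of serum albumins).
#' @param absorbance_spectra Optional list of absorbance [spectrum] objects,
#'   one per rung, used for inner-filter correction.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(temperature, protein_conc, ligand_concs,
                             emission_spectra, excitation_wavelength = 280,
                             absorbance_spectra = NULL) {
  ligand_concs <- as.numeric(ligand_concs)
  if (length(ligand_concs) < 2) {
    stop("a titration needs at least 2 ligand concentrations", call. = FALSE)
  }
  if (ligand_concs[1] != 0) {
    stop("ligand ladder must start at 0 (the F0 spectrum)", call. = FALSE)
  }
  if (any(ligand_concs < 0) || any(diff(ligand_concs) <= 0)) {
    stop("ligand ladder must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (length(emission_spectra) != length(ligand_concs)) {
    stop("need one emission spectrum per ligand concentration", call. = FALSE)
  }
  if (!all(vapply(emission_spectra, inherits, logical(1), "spectrum"))) {
    stop("emission_spectra must be a list of spectrum objects", call. = FALSE)
  }
  if (!is.null(absorbance_spectra)) {
    if (length(absorbance_spectra) != length(ligand_concs)) {
      stop("need one absorbance spectrum per ligand concentration",
           call. = FALSE)
    }
    if (!all(vapply(absorbance_spectra, inherits, logical(1), "spectrum"))) {
      stop("absorbance_spectra must be a list of spectrum objects",
           call. = FALSE)
    }
  }
  temperature <- as.numeric(temperature)[1]
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  protein_conc <- as.numeric(protein_conc)[1]
  if (!is.finite(protein_conc) || protein_conc < 0) {
    stop("protein_conc must be non-negative (mol/L)", call. = FALSE)
  }
  structure(list(temperature = temperature,
                 protein_conc = protein_conc,
                 ligand_concs = ligand_concs,
                 emission_spectra = emission_spectra,
                 excitation_wavelength = as.numeric(excitation_wavelength)[1],
                 absorbance_spectra = absorbance_spectra),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> T = %g K, [P] = %g M, %d rungs (0..%g M)%s\n",
              x$temperature, x$protein_conc, length(x$ligand_concs),
              max(x$ligand_concs),
              if (is.null(x$absorbance_spectra)) "" else ", with absorbance"))
  invisible(x)
}

#' Construct an excitation-emission matrix (EEM)
#'
#' @param excitation Excitation wavelength grid in nm, strictly increasing,
#'   length >= 2.
#' @param emission Emission wavelength grid in nm, strictly increasing.
#' @param intensity Matrix of intensities, `length(excitation)` rows by
#'   `length(emission)` columns.
#' @return An object of class `eem`.
#' @export
eem <- function(excitation, emission, intensity) {
  excitation <- as.numeric(excitation)
  emission <- as.numeric(emission)
  intensity <- as.matrix(intensity)
  if (length(excitation) < 2) {
    stop("EEM needs at least 2 excitation rows", call. = FALSE)
  }
  if (length(emission) < 2) {
    stop("EEM needs at least 2 emission columns", call. = FALSE)
  }
  if (any(diff(excitation) <= 0) || any(diff(emission) <= 0)) {
    stop("EEM grids must be strictly increasing", call. = FALSE)
  }
  if (nrow(intensity) != length(excitation) ||
      ncol(intensity) != length(emission)) {
    stop("intensity matrix dimensions must match the grids", call. = FALSE)
  }
  structure(list(excitation = excitation, emission = emission,
                 intensity = intensity),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d x %d (ex %g..%g nm, em %g..%g nm)\n",
              length(x$excitation), length(x$emission),
              min(x$excitation), max(x$excitation),
              min(x$emission), max(x$emission)))
  invisible(x)
}

abscissa_column_name <- function(kind) {
  if (identical(kind, "voltammogram")) "potential_V" else "wavelength_nm"
}

#' Read a wide-format spectral table
#'
#' Reads a CSV whose first column is the abscissa (`wavelength_nm` for
#' optical data, `potential_V` for voltammograms) and whose remaining
#' columns each hold one measured series. Column headers are kept as labels;
#' headers that parse as numbers are interpreted as ligand concentrations in
#' micromolar and converted to mol/L in the `concentrations_M` attribute
#' (equations downstream need molar units).
#'
#' @param path Path to a UTF-8 CSV file with a mandatory header row,
#'   comma separator and "." decimal mark.
#' @param kind One of `"emission"`, `"absorbance"`, `"synchronous"`,
#'   `"voltammogram"`; fixes the expected abscissa column name.
#' @return A list of [spectrum] objects (order preserved), with attribute
#'   `concentrations_M` (NA where a header is not numeric).
#' @export
read_spectrum_table <- function(path,
                                kind = c("emission", "absorbance",
                                         "synchronous", "voltammogram")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  hdr <- names(df)
  if (ncol(df) < 2) {
    stop("format error: table needs an abscissa column and at least one series",
         call. = FALSE)
  }
  if (any(is.na(hdr)) || any(!nzchar(hdr))) {
    stop("format error: missing column header", call. = FALSE)
  }
  if (anyDuplicated(hdr)) {
    stop("format error: duplicate column header: ",
         hdr[duplicated(hdr)][1], call. = FALSE)
  }
  expected <- abscissa_column_name(kind)
  if (hdr[1] != expected) {
    stop(sprintf("format error: first column must be '%s', found '%s'",
                 expected, hdr[1]), call. = FALSE)
  }
  x <- df[[1]]
  bad <- which(diff(x) <= 0)
  if (length(bad)) {
    # report the file line (header row included) for easy lookup
    stop(sprintf("validation error: abscissa not strictly increasing at row %d (%g after %g)",
                 bad[1] + 2L, x[bad[1] + 1L], x[bad[1]]), call. = FALSE)
  }
  spectra <- lapply(2:ncol(df), function(j) spectrum(x, df[[j]], hdr[j]))
  conc_um <- suppressWarnings(as.numeric(hdr[-1]))
  attr(spectra, "concentrations_M") <- conc_um * 1e-6
  spectra
}

#' Write spectra as a wide-format spectral table
#'
#' Inverse of [read_spectrum_table()]: all spectra must share one abscissa.
#'
#' @param spectra List of [spectrum] objects on a common abscissa.
#' @param path Output CSV path.
#' @param kind Same choices as in [read_spectrum_table()]; fixes the
#'   abscissa column name.
#' @return Invisibly, `path`.
#' @export
write_spectrum_table <- function(spectra, path,
                                 kind = c("emission", "absorbance",
                                          "synchronous", "voltammogram")) {
  kind <- match.arg(kind)
  stopifnot(length(spectra) >= 1)
  x <- spectra[[1]]$abscissa
  for (sp in spectra) {
    if (!isTRUE(all.equal(sp$abscissa, x, tolerance = 0))) {
      stop("all spectra must share the same abscissa to be tabled",
           call. = FALSE)
    }
  }
  df <- data.frame(x, check.names = FALSE)
  names(df) <- abscissa_column_name(kind)
  for (sp in spectra) df[[sp$label]] <- sp$signal
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an excitation-emission matrix CSV
#'
#' Expects a matrix layout: the first row carries the emission grid (its
#' first cell is ignored), the first column the excitation grid, and the
#' body the intensities.
#'
#' @param path Path to the matrix CSV.
#' @return An [eem] object.
#' @export
read_eem <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) {
    stop("validation error: EEM needs at least 2 excitation rows", call. = FALSE)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1) {
    stop(sprintf("format error: ragged rows (row %d has %d fields, expected %d)",
                 which(widths != widths[1])[1], widths[widths != widths[1]][1],
                 widths[1]), call. = FALSE)
  }
  em <- as.numeric(parts[[1]][-1])
  body <- parts[-1]
  ex <- as.numeric(vapply(body, `[`, character(1), 1))
  mat <- t(vapply(body, function(p) as.numeric(p[-1]), numeric(length(em))))
  if (anyNA(em) || anyNA(ex) || anyNA(mat)) {
    stop("format error: non-numeric cell in EEM table", call. = FALSE)
  }
  eem(ex, em, mat)
}

#' Write an excitation-emission matrix CSV
#'
#' @param x An [eem] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eem <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  header <- paste(c("ex_nm\\em_nm", format(x$emission, digits = 15,
                                           trim = TRUE)), collapse = ",")
  rows <- vapply(seq_along(x$excitation), function(i) {
    paste(c(format(x$excitation[i], digits = 15, trim = TRUE),
            format(x$intensity[i, ], digits = 15, trim = TRUE,
                   scientific = FALSE)), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# Flatten a result record into a data frame for the CSV side-car, if it has
# a natural tabular part; NULL otherwise.
result_table <- function(results) {
  if (inherits(results, "thermo_result")) return(results$dG_by_T)
  if (inherits(results, "quenching_fit")) return(results$points)
  if (inherits(results, "binding_fit")) return(results$points)
  if (inherits(results, "eem_peaks")) return(as.data.frame(results))
  if (inherits(results, "dpv_metrics")) return(results$steps)
  if (is.data.frame(results)) return(results)
  NULL
}

#' Write an analysis result to JSON (and CSV for tabular parts)
#'
#' Serializes any of the package's result records (quenching fits, binding
#' fits, thermodynamic results, peak tables, pipeline reports) to
#' machine-readable JSON at full double precision. When the record has a
#' natural tabular part (e.g. the per-temperature Gibbs energies), a flat
#' CSV with the same basename is written next to the JSON.
#'
#' @param results A non-empty result record or list.
#' @param path Output path for the JSON file.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || (is.list(results) && length(results) == 0)) {
    stop("validation error: empty result record", call. = FALSE)
  }
  tab <- result_table(results)
  payload <- unclass(results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  if (!is.null(tab)) {
    csv_path <- sub("\\.json$", ".csv", path)
    if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
    utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = TRUE),
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
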