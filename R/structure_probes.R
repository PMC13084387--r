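#' Mean residue ellipticity from observed ellipticity
#'
#' Converts circular-dichroism ellipticity in millidegrees to mean residue
#' ellipticity (MRE, deg cm^2 dmol^-1) using the mass-concentration form
#' \deqn{[\theta]_{MRE} = \frac{\theta_{obs} \cdot MRW}{10 \, c \, l}}
#' with c in mg/mL, l in cm and MRW the mean residue weight in Da
#' (about 110 for serum albumins). An equivalent molar form
#' (`conc` in mol/L times `n_residues` in place of c/MRW) is selectable via
#' `form = "molar"`.
#'
#' @param theta_obs Observed ellipticity in mdeg; vectorized.
#' @param conc Protein concentration: mg/mL (`form = "mass"`) or mol/L
#'   (`form = "molar"`); > 0.
#' @param path_length Path length in cm, > 0.
#' @param mrw Mean residue weight in Da (mass form), > 0. Default 110.
#' @param n_residues Residue count (molar form).
#' @param form `"mass"` (default) or `"molar"`.
#' @return MRE in deg cm^2 dmol^-1.
#' @examples
#' mre_from_ellipticity(-36.56, conc = 0.1995, path_length = 0.1)
#' @export
mre_from_ellipticity <- function(theta_obs, conc, path_length, mrw = 110,
                                 n_residues = NULL,
                                 form = c("mass", "molar")) {
  form <- match.arg(form)
  if (!is.finite(conc) || conc <= 0) {
    stop("validation error: conc must be positive", call. = FALSE)
  }
  if (!is.finite(path_length) || path_length <= 0) {
    stop("validation error: path_length must be positive", call. = FALSE)
  }
  if (form == "mass") {
    if (!is.finite(mrw) || mrw <= 0) {
      stop("validation error: mrw must be positive", call. = FALSE)
    }
    theta_obs * mrw / (10 * conc * path_length)
  } else {
    if (is.null(n_residues) || !is.finite(n_residues) || n_residues <= 0) {
      stop("validation error: n_residues must be positive for molar form",
           call. = FALSE)
    }
    # equivalent to the mass form with c = C_molar * M and MRW = M / n
    theta_obs / (10 * conc * n_residues * path_length)
  }
}

# Bowman reference ellipticities at 208 nm (deg cm^2 dmol^-1):
# -33,000 for a fully alpha-helical chain, -4,000 for random coil.
HELIX_MRE_208 <- -33000
COIL_MRE_208 <- -4000

#' Alpha-helix fraction from MRE at 208 nm (Bowman's equation)
#'
#' \deqn{\alpha\mbox{-helix}(\%) = 100 \cdot
#'   \frac{-[\theta]_{208} - 4000}{33000 - 4000}}
#' The returned percentage is clamped to \[0, 100\] (the formula itself is
#' unbounded); the unclamped value is kept in the `"raw"` attribute.
#'
#' @param mre_208 Mean residue ellipticity at 208 nm, deg cm^2 dmol^-1;
#'   vectorized.
#' @return Helix content in percent, with attribute `raw`.
#' @examples
#' helix_fraction(-33000) # 100
#' helix_fraction(-4000)  # 0
#' @export
helix_fraction <- function(mre_208) {
  if (any(!is.finite(mre_208))) {
    stop("validation error: mre_208 must be finite", call. = FALSE)
  }
  raw <- 100 * (-mre_208 - (-COIL_MRE_208)) / (-HELIX_MRE_208 - (-COIL_MRE_208))
  out <- pmin(100, pmax(0, raw))
  attr(out, "raw") <- raw
  out
}

#' Full CD secondary-structure record from an mdeg spectrum
#'
#' Converts an observed far-UV CD spectrum (mdeg) to MRE, reads the MRE at
#' 208 nm by interpolation and estimates the alpha-helix content.
#'
#' @param cd_spectrum A [spectrum] with wavelengths in nm covering 208 nm
#'   and signal in mdeg.
#' @inheritParams mre_from_ellipticity
#' @return An object of class `cd_record` with the MRE spectrum, `mre_208`,
#'   `helix_pct` (clamped) and `helix_pct_raw`.
#' @export
cd_analysis <- function(cd_spectrum, conc, path_length, mrw = 110) {
  stopifnot(inherits(cd_spectrum, "spectrum"))
  mre <- mre_from_ellipticity(cd_spectrum$signal, conc, path_length, mrw)
  mre_sp <- spectrum(cd_spectrum$abscissa, mre, cd_spectrum$label)
  mre_208 <- absorbance_at(mre_sp, 208)
  h <- helix_fraction(mre_208)
  structure(list(theta_obs = cd_spectrum, mre = mre_sp, mre_208 = mre_208,
                 conc = conc, path_length = path_length,
                 mean_residue_weight = mrw,
                 helix_pct = as.numeric(h),
                 helix_pct_raw = attr(h, "raw")),
            class = "cd_record")
}

#' @export
print.cd_record <- function(x, ...) {
  cat(sprintf("<cd_record> MRE(208) = %.0f deg cm^2 dmol^-1, alpha-helix = %.1f%%\n",
              x$mre_208, x$helix_pct))
  invisible(x)
}

#' Locate a peak in a spectrum
#'
#' Finds the grid maximum within a window; ties are broken to the smallest
#' abscissa. With `refine = TRUE` and an interior maximum, a parabola
#' through the maximum and its two neighbours refines the position and
#' height (useful for broad voltammetric peaks sampled coarsely).
#'
#' @param spectrum A [spectrum].
#' @param window Length-2 numeric interval on the abscissa; default the
#'   full range.
#' @param refine Parabolic refinement flag (default off).
#' @return A list of class `peak_info`: `position`, `height`, `method`.
#' @export
find_peak <- function(spectrum, window = NULL, refine = FALSE) {
  stopifnot(inherits(spectrum, "spectrum"))
  x <- spectrum$abscissa
  y <- spectrum$signal
  if (is.null(window)) window <- range(x)
  keep <- which(x >= min(window) & x <= max(window))
  if (length(keep) == 0) {
    stop("range error: window does not overlap the abscissa", call. = FALSE)
  }
  if (length(keep) < 3) {
    stop("range error: need at least 3 points in the window", call. = FALSE)
  }
  xs <- x[keep]
  ys <- y[keep]
  i <- which.max(ys)            # first max = smallest abscissa on ties
  pos <- xs[i]
  height <- ys[i]
  method <- "grid_max"
  if (refine && i > 1 && i < length(xs)) {
    x3 <- xs[(i - 1):(i + 1)]
    y3 <- ys[(i - 1):(i + 1)]
    # quadratic through the three points; vertex of y = a x^2 + b x + c
    co <- as.numeric(solve(cbind(1, x3, x3^2), y3))
    if (is.finite(co[3]) && co[3] < 0) {
      v <- -co[2] / (2 * co[3])
      if (v >= x3[1] && v <= x3[3]) {
        pos <- v
        height <- co[1] + co[2] * v + co[3] * v^2
        method <- "parabolic"
      }
    }
  }
  structure(list(position = pos, height = height, method = method),
            class = "peak_info")
}

#' @export
print.peak_info <- function(x, ...) {
  cat(sprintf("<peak_info> position %.4g, height %.4g (%s)\n",
              x$position, x$height, x$method))
  invisible(x)
}

#' Peak shift and quench table across a titration
#'
#' For each step of a series of spectra (e.g. synchronous fluorescence at
#' fixed delta-lambda, or the emission titration itself), locates the peak
#' and tabulates its position, height, signed shift versus step 0
#' (negative = blue shift) and signed percent height change versus step 0.
#'
#' @param x A [titration_series] or a list of [spectrum] objects (>= 2).
#' @param window Optional abscissa window passed to [find_peak()].
#' @param refine Parabolic refinement flag.
#' @return A data frame with columns `step`, `label`, `position`, `height`,
#'   `shift`, `percent_change`.
#' @export
shift_and_quench_table <- function(x, window = NULL, refine = FALSE) {
  if (inherits(x, "titration_series")) {
    spectra <- x$emission_spectra
    labels <- as.character(x$ligand_concs)
  } else {
    spectra <- x
    labels <- vapply(spectra, function(sp) sp$label, character(1))
  }
  if (length(spectra) < 2) {
    stop("validation error: need at least 2 steps", call. = FALSE)
  }
  peaks <- lapply(spectra, find_peak, window = window, refine = refine)
  pos <- vapply(peaks, function(p) p$position, numeric(1))
  h <- vapply(peaks, function(p) p$height, numeric(1))
  data.frame(step = seq_along(spectra) - 1L, label = labels,
             position = pos, height = h,
             shift = pos - pos[1],
             percent_change = 100 * (h - h[1]) / h[1])
}

#' EEM fluorophore peak table with Rayleigh masking
#'
#' First- and second-order Rayleigh scattering produce ridges along
#' \eqn{\lambda_{em} = \lambda_{ex}} and \eqn{\lambda_{em} = 2\lambda_{ex}}
#' that must be excluded before reading fluorophore peaks off an
#' excitation-emission matrix. Cells within `rayleigh_halfwidth` nm of
#' either ridge are masked; remaining local maxima (8-neighbour rule)
#' above `min_height` are reported ordered by decreasing intensity. Cells
#' bordering the mask are not eligible as peaks — the flank of a clipped
#' ridge would otherwise surface as a spurious maximum at the mask edge.
#' Ties are broken to the first cell in row-major (excitation, then
#' emission) order.
#'
#' @param x An [eem].
#' @param rayleigh_halfwidth Mask half-width in nm (>= 0), default 15.
#' @param min_height Minimum reported intensity (default 0: strictly
#'   positive maxima only).
#' @return A data frame of class `eem_peaks` with columns `excitation`,
#'   `emission`, `intensity`.
#' @export
eem_peak_table <- function(x, rayleigh_halfwidth = 15, min_height = 0) {
  stopifnot(inherits(x, "eem"))
  if (!is.finite(rayleigh_halfwidth) || rayleigh_halfwidth < 0) {
    stop("validation error: rayleigh_halfwidth must be >= 0", call. = FALSE)
  }
  ex <- x$excitation
  em <- x$emission
  m <- x$intensity
  exm <- matrix(ex, nrow = length(ex), ncol = length(em))
  emm <- matrix(em, nrow = length(ex), ncol = length(em), byrow = TRUE)
  masked <- abs(emm - exm) <= rayleigh_halfwidth |
    abs(emm - 2 * exm) <= rayleigh_halfwidth
  if (all(masked)) {
    stop("analysis error: Rayleigh mask covers the whole matrix",
         call. = FALSE)
  }
  work <- m
  work[masked] <- -Inf
  nr <- nrow(work)
  nc <- ncol(work)
  # dilate the mask by one cell: ridge flanks next to the mask edge are
  # not eligible as peaks
  near_mask <- masked
  for (di in -1:1) {
    for (dj in -1:1) {
      src_i <- pmin(pmax(seq_len(nr) + di, 1), nr)
      src_j <- pmin(pmax(seq_len(nc) + dj, 1), nc)
      near_mask <- near_mask | masked[src_i, src_j, drop = FALSE]
    }
  }
  if (all(near_mask)) {
    stop("analysis error: Rayleigh mask covers the whole matrix",
         call. = FALSE)
  }
  hits <- which(!near_mask & work > min_height, arr.ind = TRUE)
  is_max <- logical(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1]
    j <- hits[k, 2]
    v <- work[i, j]
    nb <- work[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    is_max[k] <- v >= max(nb)
  }
  hits <- hits[is_max, , drop = FALSE]
  out <- data.frame(excitation = ex[hits[, 1]], emission = em[hits[, 2]],
                    intensity = m[cbind(hits[, 1], hits[, 2])])
  # row-major order for deterministic tie-breaks, then sort by intensity
  out <- out[order(out$excitation, out$emission), , drop = FALSE]
  out <- out[order(-out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_masked") <- sum(masked)
  class(out) <- c("eem_peaks", "data.frame")
  out
}

#' Differential pulse voltammetry series metrics
#'
#' Extracts the peak potential \eqn{E_p} and peak current \eqn{I_p} of each
#' voltammogram in a series (e.g. a fixed ligand concentration titrated
#' with protein) and the overall shifts \eqn{\Delta E_p} and
#' \eqn{\Delta I_p} (last minus first). A strictly falling peak current
#' across the series signals progressive sequestration of the
#' electroactive ligand into a non-electroactive complex.
#'
#' @param voltammograms List of >= 2 [spectrum] objects (potential in V,
#'   current in uA).
#' @param window Optional potential window passed to [find_peak()].
#' @param refine Parabolic refinement (default TRUE: DPV peaks are broad
#'   relative to the sampling pitch).
#' @return An object of class `dpv_metrics` with fields `steps` (data frame
#'   of E_p, I_p), `delta_E_p`, `delta_I_p`, `I_p_strictly_decreasing`.
#' @export
dpv_series_metrics <- function(voltammograms, window = NULL, refine = TRUE) {
  if (length(voltammograms) < 2) {
    stop("validation error: need at least 2 voltammograms", call. = FALSE)
  }
  peaks <- lapply(voltammograms, find_peak, window = window, refine = refine)
  ep <- vapply(peaks, function(p) p$position, numeric(1))
  ip <- vapply(peaks, function(p) p$height, numeric(1))
  structure(list(
    steps = data.frame(step = seq_along(voltammograms) - 1L,
                       E_p = ep, I_p = ip),
    delta_E_p = ep[length(ep)] - ep[1],
    delta_I_p = ip[length(ip)] - ip[1],
    I_p_strictly_decreasing = all(diff(ip) < 0)),
    class = "dpv_metrics")
}

#' @export
print.dpv_metrics <- function(x, ...) {
  cat(sprintf("<dpv_metrics> %d steps, delta E_p = %+.3g V, delta I_p = %+.3g%s\n",
              nrow(x$steps), x$delta_E_p, x$delta_I_p,
              if (x$I_p_strictly_decreasing) ", I_p strictly decreasing" else ""))
  invisible(x)
}
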