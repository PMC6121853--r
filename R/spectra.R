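#' Spectral data model
#'
#' A `spectrum` is a wavelength-indexed curve: patch reflectance R(lambda),
#' ambient irradiance I(lambda), receptor sensitivity S(lambda), or media
#' transmission T(lambda). Wavelengths are in nanometres and must be strictly
#' ascending; values must be finite and non-negative. Reflectance, sensitivity
#' and transmission are proportions in [0, 1]; irradiance is in arbitrary
#' photon units.
#'
#' @param wavelength_nm numeric vector of wavelengths (nm), strictly
#'   ascending. Integration needs at least 2 points; single-point spectra
#'   arise only as pointwise resampling results.
#' @param value numeric vector of the same length.
#' @param kind one of `"reflectance"`, `"irradiance"`, `"sensitivity"`,
#'   `"transmission"`.
#' @return An object of class `spectrum`: a data frame with columns
#'   `wavelength_nm` and `value` and attribute `kind`.
#' @examples
#' s <- spectrum(400:700, rep(0.5, 301), "reflectance")
#' print(s)
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("reflectance", "irradiance", "sensitivity",
                              "transmission")) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value))
    stop("wavelength_nm and value must have equal length", call. = FALSE)
  if (length(wavelength_nm) < 1)
    stop("a spectrum needs at least 1 point", call. = FALSE)
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(value)))
    stop("wavelengths and values must be finite", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly ascending", call. = FALSE)
  if (any(value < 0))
    stop("spectral values must be non-negative", call. = FALSE)
  if (kind %in% c("reflectance", "sensitivity", "transmission") &&
      any(value > 1 + 1e-9))
    stop(kind, " values must lie in [0, 1]", call. = FALSE)
  out <- data.frame(wavelength_nm = wavelength_nm, value = pmin(value, 1e300))
  class(out) <- c("spectrum", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> kind=%s, %d points, %.0f-%.0f nm, value range [%.4g, %.4g]\n",
              attr(x, "kind"), nrow(x), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$value), max(x$value)))
  invisible(x)
}

#' Default working wavelength grid
#'
#' 300-750 nm in 1 nm steps, covering the fish-visible range. All model
#' inputs are resampled onto a single common grid so that integrals never
#' silently misalign.
#'
#' @return numeric vector of wavelengths (nm).
#' @export
default_grid <- function() seq(300, 750, by = 1)

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation of the spectral curve onto `grid`. The grid must lie
#' within the wavelength range of `s`; extrapolation is refused.
#'
#' @param s a [spectrum].
#' @param grid strictly ascending numeric vector of target wavelengths (nm).
#' @return a [spectrum] of the same kind on `grid`.
#' @export
resample <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly ascending", call. = FALSE)
  if (min(grid) < min(s$wavelength_nm) || max(grid) > max(s$wavelength_nm))
    stop(sprintf("grid [%g, %g] outside source range [%g, %g]",
                 min(grid), max(grid), min(s$wavelength_nm),
                 max(s$wavelength_nm)), call. = FALSE)
  v <- stats::approx(s$wavelength_nm, s$value, xout = grid, method = "linear")$y
  spectrum(grid, v, attr(s, "kind"))
}

# Floor applied to spectra before any log transform downstream: black patches
# approach zero reflectance and logs must stay finite.
SPECTRUM_FLOOR <- 1e-6

#' Visual pigment absorbance template
#'
#' Synthesises a photoreceptor spectral sensitivity from its wavelength of
#' maximum absorbance using the standard A1 visual-pigment nomogram
#' (alpha band plus beta band, summed and peak-normalized). Used as the
#' surrogate when measured sensitivities are unavailable.
#'
#' The alpha band is
#' \deqn{S_\alpha(\lambda) = 1/(e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda}, A = 69.7, B = 28, C = -14.9,
#' D = 0.674, b = 0.922, c = 1.104 and
#' \eqn{a = 0.8795 + 0.0459\, e^{-(\lambda_{max}-300)^2/11940}}. The beta band
#' is a Gaussian \eqn{A_\beta e^{-((\lambda-\lambda_{m\beta})/b_\beta)^2}}
#' with \eqn{A_\beta = 0.26}, \eqn{\lambda_{m\beta} = 189 + 0.315\lambda_{max}}
#' and \eqn{b_\beta = -40.5 + 0.195\lambda_{max}}.
#'
#' @param lambda_max wavelength of peak absorbance (nm), in [330, 600].
#' @param grid target wavelength grid (nm); default [default_grid()].
#' @param beta_band include the beta (short-wavelength) band? Default TRUE.
#' @return a sensitivity [spectrum] with maximum value 1 on `grid`.
#' @export
pigment_template <- function(lambda_max, grid = default_grid(),
                             beta_band = TRUE) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      lambda_max < 330 || lambda_max > 600)
    stop("lambda_max must be a single value in [330, 600] nm", call. = FALSE)
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  s <- alpha
  if (beta_band) {
    lmb <- 189 + 0.315 * lambda_max
    bb <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((grid - lmb) / bb)^2)
  }
  spectrum(grid, s / max(s), "sensitivity")
}

#' Underwater light environment
#'
#' Bundles a surface irradiance spectrum with a diffuse attenuation
#' coefficient K(lambda) (per metre) and a depth, from which the ambient
#' irradiance at depth follows by Beer-Lambert attenuation.
#'
#' @param surface_irradiance irradiance [spectrum] just below the surface.
#' @param attenuation [spectrum] holding K(lambda) in 1/m (kind
#'   `"transmission"` semantics but unbounded above; pass values via an
#'   irradiance-kind spectrum if they exceed 1).
#' @param depth_m non-negative depth in metres.
#' @return object of class `light_environment`.
#' @export
light_environment <- function(surface_irradiance, attenuation, depth_m) {
  stopifnot(inherits(surface_irradiance, "spectrum"),
            inherits(attenuation, "spectrum"))
  if (attr(surface_irradiance, "kind") != "irradiance")
    stop("surface_irradiance must have kind 'irradiance'", call. = FALSE)
  if (!is.numeric(depth_m) || length(depth_m) != 1 || depth_m < 0)
    stop("depth_m must be a single non-negative number", call. = FALSE)
  if (any(attenuation$value < 0))
    stop("attenuation coefficients must be >= 0", call. = FALSE)
  structure(list(surface_irradiance = surface_irradiance,
                 attenuation = attenuation, depth_m = depth_m),
            class = "light_environment")
}

#' @export
print.light_environment <- function(x, ...) {
  cat(sprintf("<light_environment> depth %.1f m, surface grid %.0f-%.0f nm\n",
              x$depth_m, min(x$surface_irradiance$wavelength_nm),
              max(x$surface_irradiance$wavelength_nm)))
  invisible(x)
}

#' Ambient irradiance at depth
#'
#' Beer-Lambert depth attenuation of the surface irradiance:
#' \deqn{I_d(\lambda) = I_0(\lambda)\, e^{-K(\lambda) d}.}
#' Surface irradiance and attenuation must already share a common wavelength
#' grid (use [resample()]).
#'
#' @param env a [light_environment].
#' @return irradiance [spectrum] at `env$depth_m`.
#' @export
ambient_irradiance <- function(env) {
  stopifnot(inherits(env, "light_environment"))
  i0 <- env$surface_irradiance
  k <- env$attenuation
  if (nrow(i0) != nrow(k) || any(i0$wavelength_nm != k$wavelength_nm))
    stop("surface irradiance and attenuation are on different grids; resample first",
         call. = FALSE)
  spectrum(i0$wavelength_nm, i0$value * exp(-k$value * env$depth_m),
           "irradiance")
}

#' Read and write spectra as CSV
#'
#' Long format with columns `spectrum_id`, `kind`, `wavelength_nm`, `value`
#' (UTF-8, '.' decimal), matching common spectrometer exports. `read_spectra`
#' returns a named list of [spectrum] objects; `write_spectra` accepts such a
#' list.
#'
#' @param path file path.
#' @param spectra named list of [spectrum] objects.
#' @return `read_spectra`: named list of spectra. `write_spectra`: `path`,
#'   invisibly.
#' @export
read_spectra <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "kind", "wavelength_nm", "value")
  if (!all(need %in% names(d)))
    stop("spectra CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(d, d$spectrum_id), function(g) {
    g <- g[order(g$wavelength_nm), ]
    spectrum(g$wavelength_nm, g$value, unique(g$kind)[1])
  })
  out
}

#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(is.list(spectra), !is.null(names(spectra)))
  rows <- lapply(names(spectra), function(id) {
    s <- spectra[[id]]
    data.frame(spectrum_id = id, kind = attr(s, "kind"),
               wavelength_nm = s$wavelength_nm, value = s$value)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
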