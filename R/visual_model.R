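#' Receptor class
#'
#' One photoreceptor channel: its spectral sensitivity, relative density
#' eta, and (optionally) an explicit Weber fraction omega. When omega is not
#' given it is derived from the system-level noise parameter as
#' \eqn{\omega_i = \nu / \sqrt{\eta_i}}.
#'
#' @param name channel label.
#' @param sensitivity a sensitivity [spectrum].
#' @param relative_density relative receptor density eta > 0.
#' @param weber_fraction optional explicit Weber fraction in (0, 1).
#' @return object of class `receptor_class`.
#' @export
receptor_class <- function(name, sensitivity, relative_density = 1,
                           weber_fraction = NULL) {
  stopifnot(inherits(sensitivity, "spectrum"))
  if (attr(sensitivity, "kind") != "sensitivity")
    stop("sensitivity spectrum must have kind 'sensitivity'", call. = FALSE)
  if (relative_density <= 0) stop("relative_density must be > 0", call. = FALSE)
  if (!is.null(weber_fraction) &&
      (weber_fraction <= 0 || weber_fraction >= 1))
    stop("weber_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(name = name, sensitivity = sensitivity,
                 relative_density = relative_density,
                 weber_fraction = weber_fraction),
            class = "receptor_class")
}

#' Visual system
#'
#' A set of chromatic receptor channels plus a luminance (double-cone)
#' channel, with per-channel Weber fractions derived from a noise parameter
#' nu as \eqn{\omega_i = \nu/\sqrt{\eta_i}} unless given explicitly.
#'
#' If `luminance_receptor` is NULL the luminance sensitivity defaults to the
#' sum of the two longest-wavelength chromatic sensitivities (the double-cone
#' convention common for fish achromatic vision), peak-normalized, with Weber
#' fraction `luminance_weber`.
#'
#' @param chromatic_receptors list of >= 2 [receptor_class] objects, ordered
#'   short to long wavelength.
#' @param luminance_receptor optional explicit [receptor_class] for the
#'   achromatic channel.
#' @param noise_parameter system noise nu > 0 used to derive Weber fractions.
#' @param luminance_weber Weber fraction of the luminance channel.
#' @param ocular_transmission optional transmission [spectrum] applied to all
#'   channels.
#' @return object of class `visual_system` with elements `chromatic_receptors`
#'   (each with a filled-in `weber_fraction`), `luminance_receptor`,
#'   `ocular_transmission`, `noise_parameter`.
#' @export
visual_system <- function(chromatic_receptors, luminance_receptor = NULL,
                          noise_parameter = 0.05 * sqrt(2),
                          luminance_weber = 0.05,
                          ocular_transmission = NULL) {
  stopifnot(is.list(chromatic_receptors), length(chromatic_receptors) >= 2)
  if (noise_parameter <= 0) stop("noise_parameter must be > 0", call. = FALSE)
  nm <- vapply(chromatic_receptors, function(r) r$name, character(1))
  if (anyDuplicated(nm)) stop("receptor names must be unique", call. = FALSE)
  grid <- chromatic_receptors[[1]]$sensitivity$wavelength_nm
  for (r in chromatic_receptors)
    if (!identical(r$sensitivity$wavelength_nm, grid))
      stop("all sensitivities must share a common wavelength grid", call. = FALSE)
  chromatic_receptors <- lapply(chromatic_receptors, function(r) {
    if (is.null(r$weber_fraction))
      r$weber_fraction <- noise_parameter / sqrt(r$relative_density)
    if (r$weber_fraction <= 0 || r$weber_fraction >= 1)
      stop("derived Weber fraction for '", r$name, "' outside (0, 1)",
           call. = FALSE)
    r
  })
  if (is.null(luminance_receptor)) {
    n <- length(chromatic_receptors)
    dc <- chromatic_receptors[[n - 1]]$sensitivity$value +
      chromatic_receptors[[n]]$sensitivity$value
    luminance_receptor <- receptor_class(
      "luminance", spectrum(grid, dc / max(dc), "sensitivity"),
      relative_density = 1, weber_fraction = luminance_weber)
  } else if (is.null(luminance_receptor$weber_fraction)) {
    luminance_receptor$weber_fraction <- luminance_weber
  }
  if (!is.null(ocular_transmission)) {
    stopifnot(inherits(ocular_transmission, "spectrum"))
    if (!identical(ocular_transmission$wavelength_nm, grid))
      stop("ocular transmission must be on the receptor grid", call. = FALSE)
  }
  structure(list(chromatic_receptors = chromatic_receptors,
                 luminance_receptor = luminance_receptor,
                 ocular_transmission = ocular_transmission,
                 noise_parameter = noise_parameter),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  nm <- vapply(x$chromatic_receptors, function(r) r$name, character(1))
  om <- vapply(x$chromatic_receptors, function(r) r$weber_fraction, numeric(1))
  cat(sprintf("<visual_system> %d chromatic channels (%s) + luminance\n",
              length(nm), paste(nm, collapse = ", ")))
  cat(sprintf("  Weber fractions: %s; luminance %.3g\n",
              paste(sprintf("%s=%.3g", nm, om), collapse = ", "),
              x$luminance_receptor$weber_fraction))
  invisible(x)
}

#' Weber fractions of a visual system
#' @param system a [visual_system].
#' @return named numeric vector of chromatic Weber fractions.
#' @export
weber_fractions <- function(system) {
  stopifnot(inherits(system, "visual_system"))
  vapply(system$chromatic_receptors,
         function(r) stats::setNames(r$weber_fraction, r$name), numeric(1))
}

# trapezoidal integral over an arbitrary (ascending) grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Receptor quantum catch
#'
#' The photon catch of one receptor class viewing a reflecting patch:
#' \deqn{Q = \int R(\lambda) I(\lambda) S(\lambda) T(\lambda)\, d\lambda}
#' evaluated by the trapezoid rule on the common grid (T, the ocular
#' transmission, is taken as 1 when absent).
#'
#' @param reflectance reflectance [spectrum].
#' @param illuminant irradiance [spectrum] on the same grid.
#' @param receptor a [receptor_class].
#' @param ocular optional transmission [spectrum].
#' @return scalar catch Q >= 0.
#' @export
quantum_catch <- function(reflectance, illuminant, receptor, ocular = NULL) {
  stopifnot(inherits(reflectance, "spectrum"), inherits(illuminant, "spectrum"),
            inherits(receptor, "receptor_class"))
  if (attr(illuminant, "kind") != "irradiance")
    stop("illuminant must have kind 'irradiance'", call. = FALSE)
  grid <- receptor$sensitivity$wavelength_nm
  if (!identical(reflectance$wavelength_nm, grid) ||
      !identical(illuminant$wavelength_nm, grid))
    stop("reflectance, illuminant and sensitivity are on different grids",
         call. = FALSE)
  if (all(illuminant$value == 0))
    stop("illuminant is identically zero", call. = FALSE)
  y <- reflectance$value * illuminant$value * receptor$sensitivity$value
  if (!is.null(ocular)) {
    if (!identical(ocular$wavelength_nm, grid))
      stop("ocular transmission on a different grid", call. = FALSE)
    y <- y * ocular$value
  }
  trapz(grid, y)
}

# Catches clamped here before logs: numerical safety for near-black patches.
CATCH_FLOOR <- 1e-9

#' von Kries-adapted quantum catch vector
#'
#' Computes the quantum catch of every channel of `system` for a patch and
#' normalizes each by the channel's catch for an ideal white (R = 1)
#' under the same illuminant. A perfect white therefore maps to all-ones,
#' and scaling the illuminant by any constant leaves the adapted catches
#' unchanged (illuminant-intensity invariance).
#'
#' @param reflectance reflectance [spectrum].
#' @param illuminant irradiance [spectrum] on the same grid.
#' @param system a [visual_system].
#' @param illuminant_id optional label stored with the result.
#' @return object of class `quantum_catch_vector`: list with
#'   `adapted_catches` (named, one per chromatic channel), `luminance_catch`,
#'   `illuminant_id`.
#' @export
adapt <- function(reflectance, illuminant, system, illuminant_id = "ambient") {
  stopifnot(inherits(system, "visual_system"))
  grid <- reflectance$wavelength_nm
  white <- spectrum(grid, rep(1, length(grid)), "reflectance")
  oc <- system$ocular_transmission
  q <- vapply(system$chromatic_receptors, function(r) {
    qw <- quantum_catch(white, illuminant, r, oc)
    if (qw <= 0) stop("zero white catch for channel '", r$name, "'",
                      call. = FALSE)
    quantum_catch(reflectance, illuminant, r, oc) / qw
  }, numeric(1))
  names(q) <- vapply(system$chromatic_receptors, function(r) r$name,
                     character(1))
  qlw <- quantum_catch(white, illuminant, system$luminance_receptor, oc)
  if (qlw <= 0) stop("zero white catch for luminance channel", call. = FALSE)
  ql <- quantum_catch(reflectance, illuminant, system$luminance_receptor, oc) / qlw
  structure(list(adapted_catches = pmax(q, CATCH_FLOOR),
                 luminance_catch = max(ql, CATCH_FLOOR),
                 illuminant_id = illuminant_id),
            class = "quantum_catch_vector")
}

#' @export
print.quantum_catch_vector <- function(x, ...) {
  cat("<quantum_catch_vector>",
      paste(sprintf("%s=%.4g", names(x$adapted_catches), x$adapted_catches),
            collapse = ", "),
      sprintf("| luminance=%.4g (%s)\n", x$luminance_catch, x$illuminant_id))
  invisible(x)
}

check_catches <- function(a, b) {
  stopifnot(inherits(a, "quantum_catch_vector"),
            inherits(b, "quantum_catch_vector"))
  if (length(a$adapted_catches) != length(b$adapted_catches))
    stop("catch vectors have different numbers of channels", call. = FALSE)
  if (any(c(a$adapted_catches, b$adapted_catches,
            a$luminance_catch, b$luminance_catch) <= 0))
    stop("all quantum catches must be strictly positive", call. = FALSE)
}

#' Receptor-noise-limited chromatic contrast
#'
#' Perceptual chromatic distance Delta-S (in just-noticeable differences,
#' JND) between two adapted catch vectors, with log receptor signals
#' \eqn{\Delta f_i = \ln(q_i^a / q_i^b)} and channel noise given by the Weber
#' fractions. For a dichromat
#' \deqn{\Delta S = |\Delta f_1 - \Delta f_2| / \sqrt{\omega_1^2 + \omega_2^2};}
#' for a trichromat the standard three-channel form is used; for more
#' channels the generic quadratic form (noise-weighted distance in the
#' chromatic subspace orthogonal to the achromatic direction) applies.
#' Contrasts above 1 JND are conventionally taken as discriminable.
#'
#' @param a,b [adapt()]ed quantum catch vectors under the same system.
#' @param system the [visual_system].
#' @return scalar Delta-S >= 0, symmetric in (a, b).
#' @export
chromatic_contrast <- function(a, b, system) {
  check_catches(a, b)
  w <- weber_fractions(system)
  df <- unname(log(a$adapted_catches) - log(b$adapted_catches))
  w <- unname(w)
  n <- length(w)
  if (n == 2) {
    abs(df[1] - df[2]) / sqrt(w[1]^2 + w[2]^2)
  } else if (n == 3) {
    num <- w[1]^2 * (df[2] - df[3])^2 + w[2]^2 * (df[1] - df[3])^2 +
      w[3]^2 * (df[1] - df[2])^2
    den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
    sqrt(num / den)
  } else {
    sqrt(rnl_quadratic_form(df, w))
  }
}

# Generic receptor-noise-limited squared distance: Mahalanobis distance of the
# log-signal difference in the subspace orthogonal to the achromatic
# (all-ones) direction, with diagonal channel noise.
# dS^2 = df' [W - W 1 (1' W 1)^-1 1' W] df,  W = diag(1/omega^2)
rnl_quadratic_form <- function(df, w) {
  Winv <- diag(1 / w^2, length(w))
  ones <- rep(1, length(w))
  P <- Winv - (Winv %*% ones %*% t(ones) %*% Winv) /
    as.numeric(t(ones) %*% Winv %*% ones)
  as.numeric(t(df) %*% P %*% df)
}

#' Achromatic (luminance) contrast
#'
#' \deqn{\Delta L = |\ln(q_L^a / q_L^b)| / \omega_L} in JND, using the
#' luminance (double-cone) channel.
#'
#' @inheritParams chromatic_contrast
#' @return scalar Delta-L >= 0, symmetric in (a, b).
#' @export
achromatic_contrast <- function(a, b, system) {
  check_catches(a, b)
  abs(log(a$luminance_catch) - log(b$luminance_catch)) /
    system$luminance_receptor$weber_fraction
}

#' Maxwell triangle coordinates
#'
#' Projects a trichromatic catch vector onto a unit-side equilateral triangle
#' centered at the origin: catches are normalized to sum 1 and used as
#' barycentric weights of the three vertices (vertex order = receptor order,
#' counter-clockwise starting at the top).
#'
#' @param a a [adapt()]ed quantum catch vector with exactly 3 chromatic
#'   channels.
#' @return numeric length-2 vector (x, y); equal catches map to (0, 0).
#' @export
maxwell_coordinates <- function(a) {
  stopifnot(inherits(a, "quantum_catch_vector"))
  q <- a$adapted_catches
  if (length(q) != 3)
    stop("Maxwell triangle requires a trichromatic catch vector", call. = FALSE)
  wts <- q / sum(q)
  # unit side length, centroid at origin
  v <- rbind(c(0, 1 / sqrt(3)),
             c(-1 / 2, -1 / (2 * sqrt(3))),
             c(1 / 2, -1 / (2 * sqrt(3))))
  as.numeric(wts %*% v)
}
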