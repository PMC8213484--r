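#' Subject anthropometrics for the inverted-pendulum model
#'
#' Holds the constants of the single-link sagittal-plane pendulum: body mass
#' `m` (excluding the feet, kg), COM height above the ankle joint `h` (m),
#' moment of inertia about the ankle `I_a` (kg m^2) and gravitational
#' acceleration `g` (m/s^2). When `inertia_kgm2` is not supplied it defaults
#' to the point-mass value `m * h^2`, the conventional first approximation.
#' Only the ratio `I_a / (m^2 g h)` enters the COM reconstruction, and the
#' validity-index correlation is invariant to rescaling `I_a`, so this default
#' affects the scale of the reconstructed COP error but not the index itself.
#'
#' Two derived coefficients are stored: `c1 = I_a / (m g h)` (s^2; multiplies
#' COM acceleration in the pendulum identity) and `c2 = I_a / (m^2 g h)`
#' (m/N; multiplies the AP ground-reaction force in the double integration).
#'
#' @param mass_kg Body mass excluding feet (kg).
#' @param com_height_m COM height above the ankle joint (m).
#' @param inertia_kgm2 Moment of inertia about the ankle (kg m^2); default
#'   `mass_kg * com_height_m^2`.
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @return An object of class `anthro_model` with fields `m`, `h`, `I_a`,
#'   `g`, `c1`, `c2`.
#' @examples
#' anthro_model(70, 0.9)
#' @export
anthro_model <- function(mass_kg, com_height_m, inertia_kgm2 = NULL, g = 9.81) {
  m <- as.numeric(mass_kg); h <- as.numeric(com_height_m)
  I_a <- if (is.null(inertia_kgm2)) m * h^2 else as.numeric(inertia_kgm2)
  g <- as.numeric(g)
  if (!all(is.finite(c(m, h, I_a, g))) || any(c(m, h, I_a, g) <= 0))
    stop("mass, COM height, inertia and g must all be positive and finite")
  structure(list(m = m, h = h, I_a = I_a, g = g,
                 c1 = I_a / (m * g * h), c2 = I_a / (m^2 * g * h)),
            class = "anthro_model")
}

#' @export
print.anthro_model <- function(x, ...) {
  cat(sprintf("<anthro_model> m = %.2f kg, h = %.3f m, I_a = %.2f kg m^2, g = %.3f m/s^2\n",
              x$m, x$h, x$I_a, x$g))
  cat(sprintf("  c1 = I_a/(m g h) = %.4g s^2, c2 = I_a/(m^2 g h) = %.4g m/N\n",
              x$c1, x$c2))
  invisible(x)
}
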