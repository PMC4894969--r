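#' Sneddon force for a conical indenter
#'
#' Contact force of a rigid cone indenting an elastic half-space:
#' `F = (2/pi) tan(alpha) E / (1 - nu^2) * delta^2`, with `alpha` the tip
#' half-opening angle, `E` Young's modulus and `nu` the Poisson ratio. The
#' force is zero at zero indentation, strictly increasing and convex for
#' `E > 0`.
#'
#' @param delta_um Indentation depth(s), micrometres (>= 0).
#' @param E_pa Young's modulus, Pa.
#' @param poisson_ratio Poisson ratio (default 0.5, incompressible).
#' @param half_angle_deg Tip half-angle, degrees (default 18).
#' @return Force in nanonewtons.
#' @examples
#' sneddon_force(1, 1000) # ~0.276 nN
#' @export
sneddon_force <- function(delta_um, E_pa, poisson_ratio = 0.5,
                          half_angle_deg = 18) {
  if (any(delta_um < 0)) stop("indentation depth must be >= 0")
  sneddon_coef(E_pa, poisson_ratio, half_angle_deg) * delta_um^2
}

# Sneddon prefactor in nN per um^2: (2/pi) tan(alpha) E/(1-nu^2) [Pa = N/m^2]
# times (1e-6 m)^2 per um^2 times 1e9 nN per N = E-term * 1e-3.
sneddon_coef <- function(E_pa, poisson_ratio, half_angle_deg) {
  2 / pi * tan(half_angle_deg * pi / 180) * E_pa / (1 - poisson_ratio^2) * 1e-3
}

#' Locate the contact point of an approach force curve
#'
#' Scans candidate contact points over the sample grid; for each candidate
#' `z0` the curve is modelled as a zero baseline before contact and the
#' Sneddon quadratic after contact (with the cantilever-bending correction
#' `delta = (z - z0) - F/k` when enabled), and the candidate minimizing the
#' total squared residual wins; the winner is then refined continuously
#' between its neighbouring grid points by golden-section search, so the
#' estimate is not limited to the sampling grid. Requires a rising
#' post-contact region; a flat curve raises an error.
#'
#' @param curve A [force_curve].
#' @param bending_correction Subtract the cantilever deflection `F/k` from
#'   the piezo travel when computing indentation (default `TRUE`).
#' @return A list: `z0_um`, `rss`, `index` (grid index of the contact
#'   point).
#' @export
find_contact_point <- function(curve, bending_correction = TRUE) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z_um; F <- curve$force_nN
  n <- length(z)
  rng <- max(F) - min(F)
  if (rng <= 0 || max(F) <= 0) stop("no contact detected: no rising force region")
  b_um_per_nN <- if (bending_correction) 1e-3 / curve$spring_constant else 0
  joint_rss <- function(z0) {
    pre <- F[z < z0]
    delta <- (z - z0) - F * b_um_per_nN
    post <- which(z >= z0 & delta > 0)
    if (length(post) < 10L) return(list(rss = Inf, coef = 0))
    x <- delta[post]^2; y <- F[post]
    cc <- max(0, sum(x * y) / sum(x * x))
    list(rss = sum(pre^2) + sum((y - cc * x)^2), coef = cc)
  }
  best <- NULL
  for (i in seq_len(n - 9L)) { # keep >= 10 post-contact samples
    r <- joint_rss(z[i])
    if (is.finite(r$rss) && (is.null(best) || r$rss < best$rss))
      best <- list(z0_um = z[i], rss = r$rss, index = i, coef = r$coef)
  }
  if (is.null(best) || best$coef <= 0)
    stop("no contact detected: no rising force region")
  # continuous refinement between the neighbouring grid points
  lo <- z[max(best$index - 1L, 1L)]
  hi <- z[min(best$index + 1L, n)]
  if (hi > lo) {
    opt <- stats::optimize(function(z0) joint_rss(z0)$rss, c(lo, hi))
    if (is.finite(opt$objective) && opt$objective <= best$rss) {
      best$z0_um <- opt$minimum
      best$rss <- opt$objective
    }
  }
  best[c("z0_um", "rss", "index")]
}

#' Fit Young's modulus to an approach force curve (Sneddon model)
#'
#' After optional baseline subtraction (median force over the leading 20% of
#' samples) and contact-point detection, the indentation is computed as
#' `delta = (z - z0) - F/k` (piezo travel minus cantilever bending; the
#' correction can be disabled to match analyses that fit the raw
#' separation) and Young's modulus is obtained by no-intercept linear
#' regression of `F` on `delta^2` — exact for the Sneddon form and fully
#' deterministic. The fit domain runs from contact to the trigger force.
#' The fit is flagged poor when the residual RMS exceeds
#' `3 * max(baseline noise SD, 0.5% of the trigger force)`, e.g. when the
#' curve follows a different contact geometry.
#'
#' @param curve A [force_curve].
#' @param trigger_nN Upper force bound of the fit domain; defaults to the
#'   curve's trigger (1.5 nN in the reference analysis, with 0.6-3.0 nN
#'   meaningful).
#' @param bending_correction See [find_contact_point()].
#' @param baseline_subtract Subtract the pre-approach force offset.
#' @return A list of class `sneddon_fit`: `E_pa`, `z0_um`, `residual_rms_nN`,
#'   `delta_range_um`, `n_fit`, `poor_fit`.
#' @export
fit_young_modulus <- function(curve, trigger_nN = NULL,
                              bending_correction = TRUE,
                              baseline_subtract = TRUE) {
  stopifnot(inherits(curve, "force_curve"))
  trigger_nN <- trigger_nN %||% curve$trigger_nN
  z <- curve$z_um; F <- curve$force_nN
  if (baseline_subtract) {
    lead <- seq_len(max(3L, floor(0.2 * length(F))))
    F <- F - median(F[lead])
  }
  cal <- force_curve(z, F, spring_constant = curve$spring_constant,
                     half_angle_deg = curve$half_angle_deg,
                     poisson_ratio = curve$poisson_ratio,
                     trigger_nN = trigger_nN)
  cp <- find_contact_point(cal, bending_correction = bending_correction)
  b_um_per_nN <- if (bending_correction) 1e-3 / curve$spring_constant else 0
  delta <- (cal$z_um - cp$z0_um) - cal$force_nN * b_um_per_nN
  sel <- which(cal$z_um >= cp$z0_um & delta > 0 &
                 cal$force_nN <= trigger_nN)
  if (length(sel) < 10L) stop("fewer than 10 post-contact samples below trigger")
  x <- delta[sel]^2; y <- cal$force_nN[sel]
  cc <- sum(x * y) / sum(x * x)
  if (cc <= 0) stop("non-physical fit: negative force-indentation slope")
  E <- cc / sneddon_coef(1, curve$poisson_ratio, curve$half_angle_deg)
  rms <- sqrt(mean((y - cc * x)^2))
  pre <- cal$force_nN[cal$z_um < cp$z0_um]
  noise <- if (length(pre) >= 3L) sd(pre) else 0
  structure(list(E_pa = E, z0_um = cp$z0_um, residual_rms_nN = rms,
                 delta_range_um = range(delta[sel]), n_fit = length(sel),
                 poor_fit = rms > 3 * max(noise, 0.005 * trigger_nN)),
            class = "sneddon_fit")
}

#' @export
print.sneddon_fit <- function(x, ...) {
  cat(sprintf(
    "Sneddon fit: E = %.4g Pa, z0 = %.3g um, rms %.3g nN over %d samples%s\n",
    x$E_pa, x$z0_um, x$residual_rms_nN, x$n_fit,
    if (x$poor_fit) " [poor fit]" else ""))
  invisible(x)
}
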