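# Kinetic parameter set shared by every compiled model.

#' Kinetic parameters for compiled FFL models
#'
#' One parameter set is applied to every layer of every model so that
#' topologies, not rate constants, drive the differences between networks.
#'
#' @param k1,k2,k3 basal (constitutive) activation rate constants (1/time)
#'   at the X, Y and Z layers.
#' @param kp regulated catalytic rate constant (1/time per unit of
#'   normalised regulator activity); the only step in one-step models and
#'   the first step in two-step models.
#' @param kpp catalytic rate constant of the second modification step in
#'   two-step models (1/time per unit of normalised regulator activity).
#' @param ka constitutive inactivation rate constant (1/time), identical
#'   at every layer.
#' @param total conserved number of molecules per node (active + inactive
#'   (+ intermediate) forms), in arbitrary units.
#' @param s_ref normalisation scale for the input S when it acts as a
#'   regulator (counts); regulated rates scale with `S / s_ref`.  The
#'   default is three times the top staircase plateau, so the worst-case
#'   joint drive on a multiply-regulated node stays at or below the
#'   constitutive inactivation rate and no network saturates (see the
#'   vignette).
#' @param p_ref normalisation scale for protein regulators (counts);
#'   regulated rates scale with `active copies / p_ref`.  Default: three
#'   times the conserved total, matching the `s_ref` convention.
#' @param and_factor attenuation applied per extra regulator in an AND
#'   gate, `and_factor^(m-1) * kp * prod(activities)`; the default 0.5
#'   halves the joint effect.  `NULL` requests per-model calibration so
#'   that the AND variant matches its all-OR twin's mean output at input
#'   mean 1 (see the vignette for why this is not the default).
#' @return An object of class `ffl_params`.
#' @examples
#' p <- ffl_params()
#' p$kp
#' @export
ffl_params <- function(k1 = 1, k2 = 1, k3 = 1, kp = 10, kpp = 40, ka = 5,
                       total = 60, s_ref = 18, p_ref = 3 * total,
                       and_factor = 0.5) {
  rates <- c(k1 = k1, k2 = k2, k3 = k3, kp = kp, kpp = kpp, ka = ka,
             total = total, s_ref = s_ref, p_ref = p_ref)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all kinetic parameters must be positive and finite")
  if (!is.null(and_factor) && (!is.numeric(and_factor) || and_factor <= 0))
    stop("and_factor must be NULL (auto-calibrate) or a positive number")
  structure(list(k1 = k1, k2 = k2, k3 = k3, kp = kp, kpp = kpp, ka = ka,
                 total = total, s_ref = s_ref, p_ref = p_ref,
                 and_factor = and_factor),
            class = "ffl_params")
}

#' @export
print.ffl_params <- function(x, ...) {
  cat("<ffl_params> k1=", x$k1, " k2=", x$k2, " k3=", x$k3,
      " kp=", x$kp, " kpp=", x$kpp, " ka=", x$ka,
      " total=", x$total, " s_ref=", x$s_ref, " p_ref=", x$p_ref,
      " and_factor=", if (is.null(x$and_factor)) "auto" else x$and_factor,
      "\n", sep = "")
  invisible(x)
}
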