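#' 1:1 binding model P + A <-> PA
#'
#' Holds the thermodynamic and kinetic constants of a reversible 1:1
#' probe-analyte reaction. Supply any two of `K_d`, `k_on`, `k_off`;
#' the third is completed via `K_d = k_off / k_on`. If all three are
#' given they must be mutually consistent. `k_on` has no default:
#' association rates vary by orders of magnitude between probes and a
#' silent default would silently set the dissociation timescale.
#'
#' @param K_d dissociation constant, molar.
#' @param k_on association rate constant, 1/(M s).
#' @param k_off dissociation rate constant, 1/s.
#' @return object of class `binding_model` with all three fields set.
#' @export
binding_model <- function(K_d = NULL, k_on = NULL, k_off = NULL) {
  n_given <- sum(!vapply(list(K_d, k_on, k_off), is.null, TRUE))
  if (n_given < 2)
    stop("supply at least two of K_d, k_on, k_off")
  if (is.null(K_d)) K_d <- k_off / k_on
  if (is.null(k_off)) k_off <- K_d * k_on
  if (is.null(k_on)) k_on <- k_off / K_d
  if (any(c(K_d, k_on, k_off) <= 0))
    stop("all rate/equilibrium constants must be > 0")
  if (abs(K_d - k_off / k_on) > 1e-12 * K_d)
    stop("inconsistent constants: K_d != k_off / k_on")
  structure(list(K_d = K_d, k_on = k_on, k_off = k_off),
            class = "binding_model")
}

#' Equilibrium speciation of a 1:1 binding reaction
#'
#' Solves mass action `K_d * PA = P_free * A_free` under conservation
#' `P_free + PA = P_total`, `A_free + PA = A_total`. The complex
#' concentration is the physical root of the quadratic
#' `PA^2 - (P + A + K_d) PA + P A = 0`, computed in the
#' cancellation-free product form `PA = 2 P A / (b + sqrt(b^2 - 4 P A))`
#' with `b = P + A + K_d`, which stays accurate in the
#' quantitative-capture limit (K_d far below the concentrations). The
#' free species are not formed by subtraction (which would cancel
#' catastrophically in that same limit) but from their own stable
#' quadratics, e.g. `P_free = 2 K_d P / (c + sqrt(c^2 + 4 K_d P))` with
#' `c = A - P + K_d`, so conservation and mass action both close to
#' near machine precision across all regimes. All arguments are
#' vectorised.
#'
#' @param P_total,A_total total probe and analyte concentrations,
#'   molar (>= 0).
#' @param K_d dissociation constant, molar (> 0).
#' @return list of vectors `P_free`, `A_free`, `PA` (molar).
#' @export
solve_equilibrium <- function(P_total, A_total, K_d) {
  if (any(P_total < 0) || any(A_total < 0))
    stop("total concentrations must be >= 0")
  if (any(K_d <= 0)) stop("`K_d` must be > 0")
  b <- P_total + A_total + K_d
  disc <- b * b - 4 * P_total * A_total
  sq <- sqrt(pmax(disc, 0))
  PA <- ifelse(b + sq > 0, 2 * P_total * A_total / (b + sq), 0)
  free_root <- function(tot, other) {
    # positive root of x^2 + c x - K_d tot = 0, branch chosen by sign(c)
    cc <- other - tot + K_d
    sq <- sqrt(cc * cc + 4 * K_d * tot)
    ifelse(cc >= 0, 2 * K_d * tot / (cc + sq), (sq - cc) / 2)
  }
  list(P_free = free_root(P_total, A_total),
       A_free = free_root(A_total, P_total), PA = PA)
}

#' Fraction of analyte bound under excess probe
#'
#' Limit of [solve_equilibrium()] for vanishing analyte:
#' `f = c_probe / (c_probe + K_d)`.
#'
#' @param c_probe probe concentration, molar (>= 0).
#' @param K_d dissociation constant, molar.
#' @return bound fraction in \[0, 1\].
#' @export
fraction_bound_excess_probe <- function(c_probe, K_d) {
  if (any(c_probe < 0)) stop("`c_probe` must be >= 0")
  c_probe / (c_probe + K_d)
}

#' Speciation curve over a probe-concentration grid
#'
#' @param c_probe_grid probe concentrations, molar.
#' @param K_d dissociation constant, molar.
#' @return data frame with `c_probe` and `fraction_bound`.
#' @export
speciation_curve <- function(c_probe_grid, K_d) {
  data.frame(c_probe = c_probe_grid,
             fraction_bound = fraction_bound_excess_probe(c_probe_grid, K_d))
}

#' Surviving complex fraction after washout
#'
#' After instantaneous removal of the free reagents (irreversible
#' washout: no rebinding), the complex decays as `exp(-k_off * t)`.
#'
#' @param t time since washout, seconds (>= 0).
#' @param model a [binding_model()].
#' @return surviving fraction in \[0, 1\].
#' @export
dissociation_survival <- function(t, model) {
  stopifnot(inherits(model, "binding_model"))
  if (any(t < 0)) stop("`t` must be >= 0")
  exp(-model$k_off * t)
}

#' Export a speciation or survival curve as CSV
#' @param df data frame (e.g. from [speciation_curve()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
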