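#' Parameters of the anharmonic pair potential
#'
#' Cells interact through a short-range anharmonic potential with three
#' regimes: strong repulsion below the rest separation `r0` (resistance to
#' compression), weak attraction between `r0` and the cutoff `rc` (adhesion),
#' and no interaction at or beyond `rc`. The force (positive = repulsive,
#' along the separation axis) is
#'
#' \deqn{F(d) = k_{rep}\,((r_0 - d)/r_0)^{p_{rep}} \quad (d < r_0)}
#' \deqn{F(d) = -k_{adh}\,\bigl[(d - r_0)(r_c - d)/h^2\bigr]^{p_{adh}}
#'   \quad (r_0 \le d < r_c),\ h = (r_c - r_0)/2}
#' \deqn{F(d) = 0 \quad (d \ge r_c)}
#'
#' so the attraction vanishes continuously at both ends of its window and the
#' force is continuous on \eqn{(0, \infty)}.
#'
#' @param r0 Rest length (simulation length units): pair equilibrium
#'   separation. Must satisfy `0 < r0 < rc`.
#' @param rc Cutoff (length units): interaction range; force is exactly zero
#'   at and beyond `rc`.
#' @param k_rep Repulsion strength (force units); `> 0`.
#' @param k_adh Adhesion strength (force units); `>= 0`.
#' @param p_rep Repulsion exponent (dimensionless, `> 1` so the short-range
#'   branch is anharmonic).
#' @param p_adh Adhesion exponent (dimensionless, `> 0`); `1` gives the
#'   default quadratic adhesion bump.
#'
#' @return An object of class `potential_params` (a named list).
#' @examples
#' pp <- potential_params()
#' pair_force(c(0.8, 1, 1.3, 1.6, 2), pp)
#' @export
potential_params <- function(r0 = 1, rc = 1.6, k_rep = 10, k_adh = 1,
                             p_rep = 2, p_adh = 1) {
  if (!is.numeric(r0) || r0 <= 0 || r0 >= rc) {
    abort("`r0` must satisfy 0 < r0 < rc.", class = "blastopack_config_error")
  }
  if (k_rep <= 0) abort("`k_rep` must be > 0.", class = "blastopack_config_error")
  if (k_adh < 0) abort("`k_adh` must be >= 0.", class = "blastopack_config_error")
  if (p_rep <= 1) abort("`p_rep` must be > 1 (anharmonic short-range branch).",
                        class = "blastopack_config_error")
  if (p_adh <= 0) abort("`p_adh` must be > 0.", class = "blastopack_config_error")
  structure(
    list(r0 = r0, rc = rc, k_rep = k_rep, k_adh = k_adh,
         p_rep = p_rep, p_adh = p_adh),
    class = "potential_params"
  )
}

stop_degenerate_pair <- function(which = NULL) {
  msg <- "Degenerate pair: coincident particles (separation <= 0)."
  if (!is.null(which)) {
    msg <- paste0(msg, " Offending pair indices: ",
                  paste(which, collapse = ", "), ".")
  }
  abort(msg, class = "blastopack_degenerate_pair")
}

#' Signed pair force at given separations
#'
#' Scalar force along the separation axis between two cells; positive values
#' are repulsive (push the pair apart), negative attractive. Vectorised over
#' `d`.
#'
#' @param d Separation distance(s); all must be `> 0`.
#' @param params A [potential_params()] object.
#' @param rest_override Optional replacement for the rest length setting the
#'   *range* of the repulsive branch; used for the cavity particle, whose
#'   rest size grows over the simulation. The overlap is still normalised by
#'   the cell rest length `params$r0`, so a large cavity is as stiff per
#'   unit of penetration as a cell (its stiffness does not dilute with its
#'   size).
#' @param repulsive_only If `TRUE`, only the repulsive branch is evaluated
#'   (zero at and beyond the rest length); this is the cavity interaction.
#' @return Numeric vector of signed force magnitudes, same length as `d`.
#' @seealso [pair_potential()] for the potential whose negative gradient this
#'   force is; [cavity_force()].
#' @export
pair_force <- function(d, params, rest_override = NULL,
                       repulsive_only = FALSE) {
  if (any(!is.finite(d)) || any(d <= 0)) stop_degenerate_pair()
  r0 <- rest_override %||% params$r0
  f <- numeric(length(d))
  rep_idx <- d < r0
  if (any(rep_idx)) {
    f[rep_idx] <- params$k_rep *
      ((r0 - d[rep_idx]) / params$r0)^params$p_rep
  }
  if (!repulsive_only && params$k_adh > 0) {
    rc <- params$rc
    att_idx <- d >= r0 & d < rc
    if (any(att_idx)) {
      h2 <- ((rc - r0) / 2)^2
      g <- (d[att_idx] - r0) * (rc - d[att_idx]) / h2
      f[att_idx] <- -params$k_adh * g^params$p_adh
    }
  }
  f
}

#' Pair potential energy at given separations
#'
#' The potential \eqn{U(d)} whose negative derivative is [pair_force()], with
#' \eqn{U \equiv 0} at and beyond the cutoff. Closed form for the default
#' adhesion exponent `p_adh = 1`; other exponents fall back to adaptive
#' quadrature (intended for diagnostics, not inner loops).
#'
#' @inheritParams pair_force
#' @return Numeric vector of energies.
#' @export
pair_potential <- function(d, params, rest_override = NULL,
                           repulsive_only = FALSE) {
  if (any(!is.finite(d)) || any(d <= 0)) stop_degenerate_pair()
  r0 <- rest_override %||% params$r0
  rc <- params$rc
  u <- numeric(length(d))
  rep_idx <- d < r0
  if (any(rep_idx)) {
    pe <- params$p_rep + 1
    u[rep_idx] <- params$k_rep * params$r0 / pe *
      ((r0 - d[rep_idx]) / params$r0)^pe
  }
  if (repulsive_only || params$k_adh == 0) return(u)

  if (params$p_adh == 1) {
    # antiderivative of (s - r0)(rc - s): P(s) = -s^3/3 + (r0+rc)s^2/2 - r0*rc*s
    h2 <- ((rc - r0) / 2)^2
    P <- function(s) -s^3 / 3 + (r0 + rc) * s^2 / 2 - r0 * rc * s
    u_att <- function(x) -params$k_adh / h2 * (P(rc) - P(x))
    att_idx <- d >= r0 & d < rc
    u[att_idx] <- u_att(d[att_idx])
    u[rep_idx] <- u[rep_idx] + u_att(r0)
  } else {
    att_depth <- function(x) {
      integrate(function(s) pair_force(s, params, rest_override = r0),
                lower = x, upper = rc, rel.tol = 1e-10)$value
    }
    att_idx <- d >= r0 & d < rc
    u[att_idx] <- vapply(d[att_idx], att_depth, numeric(1))
    if (any(rep_idx)) u[rep_idx] <- u[rep_idx] + att_depth(r0)
  }
  u
}

#' Repulsive force exerted by the cavity on one cell
#'
#' The cavity is modelled as a single large particle at a fixed centre that
#' only repels: the repulsive branch of [pair_force()] with the cavity's
#' current rest size substituted for `r0`, directed radially away from the
#' cavity centre. Zero at separations at or beyond the cavity rest size.
#'
#' @param position Length-2 numeric: the cell's coordinates.
#' @param state A [tissue_state] (uses `cavity_center` and `cavity_rest`).
#' @param params A [potential_params()] object.
#' @return Length-2 numeric force vector.
#' @export
cavity_force <- function(position, state, params) {
  dvec <- position - state$cavity_center
  d <- sqrt(sum(dvec^2))
  if (d <= 0) stop_degenerate_pair()
  if (d >= state$cavity_rest) return(c(0, 0))
  f <- pair_force(d, params, rest_override = state$cavity_rest,
                  repulsive_only = TRUE)
  f * dvec / d
}
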