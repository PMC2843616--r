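#' Model parameters for a solubility screen
#'
#' Container for the three linked probabilities of the yield model and the
#' fragment counts behind them. Any subset may be supplied; missing members
#' are derived where possible (`p_D = p_S / p_S_given_D`,
#' `p_S_given_D = f/F`). Supplied members are cross-checked:
#' \eqn{p_S \le p_{S|D}}, \eqn{p_D\, p_{S|D} = p_S} and
#' \eqn{p_{S|D} = f/F} within `tol`, and \eqn{1 \le f \le F}.
#'
#' `tol` defaults to 0.015 so that a consistent triple rounded to two
#' decimals (the precision screens are typically reported at) still
#' validates: rounding each factor by up to 0.005 can move the product by
#' about three times that.
#'
#' @param p_S marginal fragment solubility probability.
#' @param p_S_given_D conditional solubility probability for fragments of
#'   soluble domains (boundary-prediction success rate).
#' @param p_D domain-existence prediction success rate.
#' @param f,F soluble / testable fragment counts per (soluble) domain;
#'   per-domain averages (non-integers) are allowed but restrict use to the
#'   multiple-copy model.
#' @param se named list of standard errors (`p_S`, `p_S_given_D`, `p_D`),
#'   each in \eqn{[0, 0.5]}.
#' @param tol consistency tolerance for the cross-checks.
#' @return an object of class `model_parameters`.
#' @examples
#' model_parameters(p_S = 111 / 215, p_S_given_D = 111 / 175)
#' @export
model_parameters <- function(p_S = NULL, p_S_given_D = NULL, p_D = NULL,
                             f = NULL, F = NULL, se = list(), tol = 0.015) {
  chk_prob <- function(x, name) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1 || !is_prob(x)))
      stop(sprintf("%s must be a single probability in [0, 1]", name))
  }
  chk_prob(p_S, "p_S"); chk_prob(p_S_given_D, "p_S_given_D"); chk_prob(p_D, "p_D")
  if (!is.null(f) || !is.null(F)) {
    if (is.null(f) || is.null(F)) stop("supply f and F together")
    if (!is.numeric(f) || !is.numeric(F) || f < 1 || f > F)
      stop("need 1 <= f <= F")
  }
  if (is.null(p_S_given_D) && !is.null(f)) p_S_given_D <- f / F
  if (!is.null(p_S) && !is.null(p_S_given_D)) {
    if (p_S > p_S_given_D + 1e-12)
      stop("inconsistent: p_S exceeds p_S_given_D")
    if (is.null(p_D)) p_D <- p_D_from_conditionals(p_S, p_S_given_D)
  }
  if (!is.null(p_D) && !is.null(p_S) && !is.null(p_S_given_D) &&
      abs(p_D * p_S_given_D - p_S) > tol)
    stop(sprintf("inconsistent: p_D * p_S_given_D = %.4f but p_S = %.4f (tol %.3f)",
                 p_D * p_S_given_D, p_S, tol))
  # integer f carries up to 0.5/F rounding against a ratio-valued p_S_given_D
  if (!is.null(p_S_given_D) && !is.null(f) &&
      abs(f / F - p_S_given_D) > max(tol, 0.5 / F))
    stop("inconsistent: f/F and p_S_given_D disagree")
  for (nm in names(se)) {
    if (!is.numeric(se[[nm]]) || se[[nm]] < 0 || se[[nm]] > 0.5)
      stop("standard errors must lie in [0, 0.5]")
  }
  structure(list(p_S = p_S, p_S_given_D = p_S_given_D, p_D = p_D,
                 f = f, F = F, se = se),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, digits = 3, ...) {
  fmt <- function(p, s) {
    if (is.null(p)) return("   --")
    if (!is.null(s)) sprintf("%.*f +/- %.*f", digits, p, digits, s)
    else sprintf("%.*f", digits, p)
  }
  cat("Solubility-screen model parameters\n")
  cat("  p(S)   fragment soluble:            ", fmt(x$p_S, x$se$p_S), "\n")
  cat("  p(S|D) boundary prediction success: ", fmt(x$p_S_given_D, x$se$p_S_given_D), "\n")
  cat("  p(D)   domain prediction success:   ", fmt(x$p_D, x$se$p_D), "\n")
  if (!is.null(x$f))
    cat(sprintf("  f / F  soluble / testable fragments: %g / %g\n", x$f, x$F))
  invisible(x)
}

#' Screen design point
#'
#' One experimental plan: `M` predicted domains, `N` fragments tested per
#' domain, set-up cost ratio `r`, and the fragment-sampling model
#' (`"multiple"` = designs may repeat, `"single"` = N distinct designs).
#'
#' @param M number of domains examined (positive integer).
#' @param N fragments tested per domain (positive integer).
#' @param r set-up cost ratio (non-negative).
#' @param copy_mode `"multiple"` or `"single"`.
#' @return an object of class `design_point`.
#' @export
design_point <- function(M, N, r = 0, copy_mode = c("multiple", "single")) {
  copy_mode <- match.arg(copy_mode)
  if (!is_count(M) || length(M) != 1) stop("M must be a positive integer")
  if (!is_count(N) || length(N) != 1) stop("N must be a positive integer")
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0)
    stop("r must be a single non-negative number")
  structure(list(M = as.integer(M), N = as.integer(N), r = r, copy_mode = copy_mode),
            class = "design_point")
}
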