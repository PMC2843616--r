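#' Domain-prediction probability from fragment-level probabilities
#'
#' The fragment-level solubility probability decomposes as
#' \eqn{p(S) = p(D)\, p(S|D)}: a fragment is soluble only if its domain was
#' correctly predicted to exist (and be producible in soluble form) and its
#' boundaries were correctly chosen. Inverting gives the domain-existence
#' prediction success rate \eqn{p(D) = p(S)/p(S|D)}.
#'
#' @param p_S probability (in \eqn{[0,1]}) that a tested fragment is soluble.
#' @param p_S_given_D conditional probability that a fragment of a soluble
#'   domain is soluble; must be positive and at least `p_S`.
#' @return `p_S / p_S_given_D`, guaranteed in \eqn{[0,1]}.
#' @examples
#' p_D_from_conditionals(111 / 215, 111 / 175) # pilot screen: 0.81
#' @export
p_D_from_conditionals <- function(p_S, p_S_given_D) {
  if (!is_prob(p_S) || !is.numeric(p_S_given_D) || any(!is.finite(p_S_given_D)))
    stop("p_S and p_S_given_D must be probabilities in [0, 1]")
  if (any(p_S_given_D <= 0))
    stop("p_S_given_D = 0: p(D) is undefined when no fragment of a soluble domain can be soluble")
  if (any(p_S_given_D > 1))
    stop("p_S_given_D must be a probability in (0, 1]")
  if (any(p_S > p_S_given_D + 1e-12))
    stop("inconsistent inputs: p_S > p_S_given_D would imply p(D) > 1")
  clip01(p_S / p_S_given_D)
}

resolve_q <- function(f, F, q, allow_average = TRUE) {
  if (!is.null(q)) {
    if (!is_prob(q)) stop("q = f/F must be a probability in [0, 1]")
    return(q)
  }
  if (is.null(f) || is.null(F))
    stop("supply either q or both f and F")
  if (!is.numeric(f) || !is.numeric(F) || any(!is.finite(f)) || any(!is.finite(F)))
    stop("f and F must be finite numbers")
  if (any(F <= 0) || any(f <= 0)) stop("f and F must be positive (f = 0 means no soluble fragment exists)")
  if (any(f > F)) stop("f must not exceed F")
  if (!allow_average && (!is_count(f) || !is_count(F)))
    stop("single-copy sampling requires integer f and F (hypergeometric undefined otherwise)")
  f / F
}

#' Probability of at least one soluble fragment: multiple-copy model
#'
#' With-replacement sampling of fragment designs: each of the `N` tested
#' fragments of a soluble domain is independently soluble with probability
#' \eqn{q = f/F}, so \eqn{P_N = 1 - (1-q)^N}. Appropriate when the same
#' boundary choice may be drawn more than once, or as the binomial
#' approximation to without-replacement testing when \eqn{N \ll F}.
#'
#' Averaged, non-integer `f` and `F` are accepted here (only the ratio
#' matters); [P_N_single()] requires true integers.
#'
#' @param f number (or per-domain average) of soluble fragments of a
#'   soluble domain.
#' @param F number (or average) of testable fragments per domain, e.g. 900
#'   for a 30 x 30 termini window.
#' @param N number of fragments tested per domain; may be a vector.
#' @param q alternative to `(f, F)`: the ratio \eqn{f/F} directly.
#' @return \eqn{P_N}, vectorized over `N`.
#' @examples
#' P_N_multiple(q = 0.63, N = 9) # pilot conditions: 0.99987
#' @export
P_N_multiple <- function(f = NULL, F = NULL, N, q = NULL) {
  q <- resolve_q(f, F, q)
  if (!is_count(N)) stop("N must be a positive integer")
  clip01(1 - (1 - q)^N)
}

#' Probability of at least one soluble fragment: single-copy model
#'
#' Without-replacement sampling: `N` distinct fragments are drawn from the
#' `F` testable designs, of which `f` are soluble. The no-success
#' probability is hypergeometric, \eqn{P_N^C = C(F-f, N) / C(F, N)}, and
#' \eqn{P_N = 1 - P_N^C}. Evaluated as the iterated ratio
#' \eqn{\prod_{i=0}^{N-1} (F-f-i)/(F-i)} -- no factorials are formed, so
#' large windows (\eqn{F \ge 10^4}) neither overflow nor lose precision
#' to cancellation. Exactly 1 when \eqn{N > F - f}: the insoluble
#' designs alone cannot fill the draw.
#'
#' @inheritParams P_N_multiple
#' @param N number of distinct fragments tested, \eqn{1 \le N \le F};
#'   may be a vector.
#' @return \eqn{P_N}, vectorized over `N`.
#' @examples
#' P_N_single(f = 2, F = 5, N = 2) # 1 - C(3,2)/C(5,2) = 0.7
#' @export
P_N_single <- function(f, F, N) {
  if (!is_count(f) || !is_count(F))
    stop("single-copy sampling requires integer f >= 1 and F >= 1 (hypergeometric undefined otherwise)")
  if (f > F) stop("f must not exceed F")
  if (!is_count(N)) stop("N must be a positive integer")
  if (any(N > F)) stop("N must not exceed F: cannot draw more distinct fragments than exist")
  i <- seq_len(max(N)) - 1
  p_none_all <- cumprod(pmax(F - f - i, 0) / (F - i))
  clip01(1 - p_none_all[N])
}

P_N_for_mode <- function(params, N, copy_mode) {
  copy_mode <- match.arg(copy_mode, c("multiple", "single"))
  if (copy_mode == "multiple") {
    q <- if (!is.null(params$p_S_given_D)) params$p_S_given_D else
      resolve_q(params$f, params$F, NULL)
    P_N_multiple(q = q, N = N)
  } else {
    if (is.null(params$f) || is.null(params$F))
      stop("single-copy mode needs integer f and F in the model parameters")
    P_N_single(params$f, params$F, N)
  }
}

#' Expected number of soluble domains for a screen design
#'
#' For a design testing `N` fragments in each of `M` predicted domains,
#' the expected soluble-domain count is
#' \eqn{E_{domain} = M\, p(D)\, P_N}, and its cost-normalized counterpart
#' under the fixed budget \eqn{M(N + r) = const} is
#' \eqn{e_{domain} = P_N / (N + r)}.
#'
#' @param params a [model_parameters()] object; `p_D` is taken directly or
#'   derived from `p_S` and `p_S_given_D`.
#' @param design a [design_point()] (`M`, `N`, `r`, `copy_mode`).
#' @return an object of class `yield_value`: a list with `P_N`,
#'   `P_N_complement`, `E_domain`, `e_domain`, plus the design.
#' @examples
#' par <- model_parameters(p_D = 0.81, p_S_given_D = 0.63)
#' expected_domains(par, design_point(M = 1, N = 9))
#' @export
expected_domains <- function(params, design) {
  stopifnot(inherits(params, "model_parameters"), inherits(design, "design_point"))
  p_D <- params$p_D
  if (is.null(p_D)) {
    if (is.null(params$p_S) || is.null(params$p_S_given_D))
      stop("p_D is not set and cannot be derived: need p_S and p_S_given_D")
    p_D <- p_D_from_conditionals(params$p_S, params$p_S_given_D)
  }
  P <- P_N_for_mode(params, design$N, design$copy_mode)
  out <- list(
    P_N = P,
    P_N_complement = 1 - P,
    E_domain = design$M * p_D * P,
    e_domain = P / (design$N + design$r),
    M = design$M, N = design$N, r = design$r, copy_mode = design$copy_mode,
    p_D = p_D
  )
  class(out) <- "yield_value"
  out
}

#' @export
print.yield_value <- function(x, digits = 4, ...) {
  cat(sprintf("Screen yield (%s-copy model): M = %d, N = %d, r = %g\n",
              x$copy_mode, x$M, x$N, x$r))
  cat(sprintf("  P_N       = %.*f   (P_N^C = %.*f)\n", digits, x$P_N, digits, x$P_N_complement))
  cat(sprintf("  E_domain  = %.*f   (E_domain/M = %.*f)\n",
              digits, x$E_domain, digits, x$E_domain / x$M))
  cat(sprintf("  e_domain  = %.*g   (per unit cost)\n", digits, x$e_domain))
  invisible(x)
}

#' Cost-normalized expected yield per domain slot
#'
#' Evaluates \eqn{e_{domain} = P_N / (N + r)} directly from the sampling
#' parameters, without requiring \eqn{p(D)} (which only rescales the curve
#' and does not move its maximum).
#'
#' @inheritParams P_N_multiple
#' @param r set-up cost ratio: supplemental cost of starting a new domain
#'   relative to testing one more fragment. Non-negative.
#' @param copy_mode `"multiple"` (with replacement) or `"single"` (without).
#' @return \eqn{e_{domain}}, vectorized over `N`.
#' @examples
#' e_domain(q = 0.63, N = 1:5, r = 0) # monotone decreasing when r = 0
#' @export
e_domain <- function(q = NULL, f = NULL, F = NULL, N, r = 0,
                     copy_mode = c("multiple", "single")) {
  copy_mode <- match.arg(copy_mode)
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0)
    stop("r must be a single non-negative number")
  P <- if (copy_mode == "multiple") P_N_multiple(f, F, N, q = q)
       else {
         if (is.null(f) || is.null(F)) stop("single-copy mode requires integer f and F")
         P_N_single(f, F, N)
       }
  P / (N + r)
}

#' Expected soluble domains with per-domain (f, F) heterogeneity
#'
#' When soluble domains differ in how many of their testable fragments are
#' soluble, the expected count is the sum of per-domain success
#' probabilities, \eqn{\sum_i P_N(f_i, F_i)}, rather than
#' \eqn{M\,p(D)\,P_N} at averaged values. Domains with \eqn{f_i = 0}
#' (failed predictions) contribute zero.
#'
#' @param per_domain a data frame (or 2-column matrix) with columns `f`
#'   and `F`, one row per domain.
#' @param N fragments tested per domain (scalar).
#' @param copy_mode `"multiple"` or `"single"`; single mode requires
#'   `N <= min(F_i)`.
#' @return the expected number of soluble domains (non-negative real).
#' @examples
#' expected_domains_heterogeneous(data.frame(f = c(3, 0), F = c(10, 10)), N = 1)
#' @export
expected_domains_heterogeneous <- function(per_domain, N,
                                           copy_mode = c("multiple", "single")) {
  copy_mode <- match.arg(copy_mode)
  per_domain <- as.data.frame(per_domain)
  if (!all(c("f", "F") %in% names(per_domain)))
    stop("per_domain needs columns 'f' and 'F'")
  f <- per_domain$f; Ftot <- per_domain$F
  if (any(!is.finite(f)) || any(!is.finite(Ftot)) || any(f < 0) || any(Ftot < 1) || any(f > Ftot))
    stop("each row must satisfy 0 <= f <= F, F >= 1")
  if (copy_mode == "single" && N > min(Ftot))
    stop("single-copy mode: N exceeds the smallest F among the domains")
  contrib <- vapply(seq_along(f), function(i) {
    if (f[i] == 0) return(0)
    if (copy_mode == "multiple") P_N_multiple(f = f[i], F = Ftot[i], N = N)
    else P_N_single(f[i], Ftot[i], N)
  }, numeric(1))
  sum(contrib)
}
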