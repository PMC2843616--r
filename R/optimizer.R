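#' Locate the cost-optimal number of fragments per domain
#'
#' Tabulates \eqn{P_N} and \eqn{e_{domain} = P_N/(N+r)} over
#' \eqn{N = 1, \dots, N_{max}} and returns the integer maximizer of
#' \eqn{e_{domain}} (ties broken to the smallest N, i.e. the cheaper
#' design). The scan is exhaustive — the integer domain is small — and a
#' boundary maximum is never returned silently:
#' \itemize{
#'   \item if the curve is flat to machine precision (the single-copy
#'     `f = 1`, `r = 0` case, where \eqn{e_{domain} = 1/F} for every N),
#'     `N_optimum = 1` is reported with `flat = TRUE`;
#'   \item in single-copy mode the domain genuinely ends at `N = F`, so a
#'     maximum there is reported with `boundary = TRUE`;
#'   \item otherwise a maximum at `N_max` raises an error asking for a
#'     larger `N_max` (the default heuristic,
#'     \eqn{\lceil 10(r+1)+100 \rceil} in multiple mode, exceeds the
#'     continuous optimum in practice).
#' }
#'
#' @inheritParams e_domain
#' @param N_max upper end of the scan; defaults to `ceiling(10 * (r + 1) +
#'   100)` in multiple mode and to `F` in single mode (values above `F`
#'   are clamped with a warning).
#' @return an object of class `yield_curve`: the tabulated `curve`
#'   (`N`, `P_N`, `e_domain`), `N_optimum`, `e_at_optimum`, logical flags
#'   `flat` and `boundary`, and the parameters used.
#' @examples
#' find_N_optimum(q = 0.63, r = 1000)$N_optimum # 7
#' find_N_optimum(q = 0.63, r = 0)$N_optimum    # 1: no set-up cost
#' @export
find_N_optimum <- function(q = NULL, f = NULL, F = NULL, r = 0,
                           copy_mode = c("multiple", "single"),
                           N_max = NULL) {
  copy_mode <- match.arg(copy_mode)
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0)
    stop("r must be a single non-negative number")
  if (copy_mode == "multiple") {
    q <- resolve_q(f, F, q)
    if (is.null(N_max)) N_max <- ceiling(10 * (r + 1) + 100)
  } else {
    if (is.null(f) || is.null(F))
      stop("single-copy mode requires integer f and F")
    if (!is_count(f) || !is_count(F) || f > F)
      stop("single-copy mode requires integers 1 <= f <= F")
    q <- f / F
    if (is.null(N_max)) N_max <- F
    if (N_max > F) {
      warning("N_max clamped to F = ", F, " in single-copy mode")
      N_max <- F
    }
  }
  if (!is_count(N_max) || length(N_max) != 1) stop("N_max must be a positive integer")
  N <- seq_len(N_max)
  P <- if (copy_mode == "multiple") P_N_multiple(q = q, N = N)
       else P_N_single(f, F, N)
  e <- P / (N + r)
  flat <- (max(e) - min(e)) <= 1e-12 * max(e, .Machine$double.xmin)
  i <- which.max(e) # first maximum = smallest N on ties
  boundary <- FALSE
  if (flat) {
    i <- 1L
  } else if (i == N_max) {
    if (copy_mode == "single" && N_max == F) {
      boundary <- TRUE
    } else {
      stop("e_domain still increasing at N_max = ", N_max,
           "; search inconclusive, increase N_max")
    }
  }
  structure(list(
    curve = data.frame(N = N, P_N = P, e_domain = e),
    N_optimum = as.integer(i), e_at_optimum = e[i],
    flat = flat, boundary = boundary,
    copy_mode = copy_mode, r = r, q = q, f = f, F = F, N_max = as.integer(N_max)
  ), class = "yield_curve")
}

#' @export
print.yield_curve <- function(x, ...) {
  par_txt <- if (x$copy_mode == "single")
    sprintf("f = %g, F = %g", x$f, x$F) else sprintf("q = p(S|D) = %g", x$q)
  cat(sprintf("Yield curve (%s-copy model, %s, r = %g, N scanned 1..%d)\n",
              x$copy_mode, par_txt, x$r, x$N_max))
  cat(sprintf("  N_optimum = %d, e_domain(N_optimum) = %.6g%s%s\n",
              x$N_optimum, x$e_at_optimum,
              if (x$flat) "  [flat curve]" else "",
              if (x$boundary) "  [maximum at the N = F boundary]" else ""))
  invisible(x)
}

#' Serialize a yield curve as TSV plus a JSON sidecar
#'
#' @param yc a `yield_curve` from [find_N_optimum()].
#' @param tsv_path path for the tabulated curve (`N`, `P_N`, `e_domain`).
#' @param json_path path for the sidecar holding `N_optimum`, flags and
#'   parameters; defaults to `tsv_path` with a `.json` extension.
#' @return `tsv_path`, invisibly.
#' @export
write_yield_curve <- function(yc, tsv_path, json_path = NULL) {
  stopifnot(inherits(yc, "yield_curve"))
  if (is.null(json_path)) json_path <- paste0(sub("\\.tsv$", "", tsv_path), ".json")
  write.table(yc$curve, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  side <- list(N_optimum = yc$N_optimum, e_at_optimum = yc$e_at_optimum,
               flat = yc$flat, boundary = yc$boundary,
               copy_mode = yc$copy_mode, r = yc$r, q = yc$q,
               f = yc$f, F = yc$F, N_max = yc$N_max)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))], json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tsv_path)
}

#' Continuous stationary point of the normalized yield
#'
#' Treating N as continuous in the multiple-copy model, the maximizer of
#' \eqn{e_{domain} = (1-(1-q)^N)/(N+r)} satisfies the transcendental
#' stationarity condition
#' \deqn{-(N+r)\,(1-q)^N \ln(1-q) = 1 - (1-q)^N,}
#' which has a unique positive root when `r > 0`. The root is found by
#' bracketing and bisection to \eqn{10^{-9}}; the integer optimum from
#' [find_N_optimum()] lies in its floor/ceiling whenever the continuous
#' optimum is at least 1. For `r = 0` the derivative is negative for all
#' `N > 0` (the curve decreases monotonically) and a boundary indicator is
#' returned with the optimum at `N = 1`.
#'
#' @param q probability \eqn{f/F}, strictly inside (0, 1).
#' @param r set-up cost ratio.
#' @return a list with `N` (the continuous root, or 1) and `boundary`
#'   (`TRUE` when the optimum sits on the `N = 1` boundary).
#' @export
solve_continuous_optimum <- function(q, r) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1)
    stop("q must lie strictly inside (0, 1)")
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0)
    stop("r must be a single non-negative number")
  L <- log(1 - q)
  g <- function(N) {
    u <- (1 - q)^N
    -(N + r) * u * L - (1 - u)
  }
  if (r == 0) return(list(N = 1, boundary = TRUE))
  lo <- 1e-12
  if (g(lo) <= 0) return(list(N = 1, boundary = TRUE))
  hi <- 1
  while (g(hi) > 0) hi <- hi * 2
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  list(N = (lo + hi) / 2, boundary = FALSE)
}

#' Map of N_optimum over a grid of p(S|D) and set-up cost values
#'
#' Runs [find_N_optimum()] on every (q, r) pair and checks the expected
#' monotone structure: within a cost level `r`, N_optimum does not increase
#' with q (better boundary prediction needs fewer tries); within a q,
#' N_optimum does not decrease with r (a higher set-up cost favors testing
#' more fragments before moving on).
#'
#' @param q_grid probabilities \eqn{f/F} to scan.
#' @param r_grid set-up cost ratios to scan.
#' @param copy_mode `"multiple"` or `"single"`.
#' @param F window size, required in single mode (`f = round(q * F)`).
#' @param N_max optional scan bound passed through to [find_N_optimum()].
#' @return a data frame with one row per (q, r): `q`, `r`, `N_optimum`,
#'   `flat`, `boundary`.
#' @examples
#' m <- n_optimum_map(seq(0.2, 1, 0.2), c(1, 10))
#' @export
n_optimum_map <- function(q_grid, r_grid, copy_mode = c("multiple", "single"),
                          F = NULL, N_max = NULL) {
  copy_mode <- match.arg(copy_mode)
  if (!length(q_grid) || !length(r_grid)) stop("grids must be non-empty")
  if (copy_mode == "single" && is.null(F))
    stop("single-copy mode requires F (f is taken as round(q * F))")
  grid <- expand.grid(q = q_grid, r = r_grid, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    qi <- grid$q[i]; ri <- grid$r[i]
    yc <- if (copy_mode == "multiple")
      find_N_optimum(q = qi, r = ri, copy_mode = "multiple", N_max = N_max)
    else
      find_N_optimum(f = max(1L, as.integer(round(qi * F))), F = F,
                     r = ri, copy_mode = "single", N_max = N_max)
    data.frame(q = qi, r = ri, N_optimum = yc$N_optimum,
               flat = yc$flat, boundary = yc$boundary)
  })
  out <- do.call(rbind, res)
  for (ri in unique(out$r)) {
    sub <- out[out$r == ri, ]
    sub <- sub[order(sub$q), ]
    if (any(diff(sub$N_optimum) > 0))
      stop("internal check failed: N_optimum increased with q at r = ", ri)
  }
  for (qi in unique(out$q)) {
    sub <- out[out$q == qi, ]
    sub <- sub[order(sub$r), ]
    if (any(diff(sub$N_optimum) < 0))
      stop("internal check failed: N_optimum decreased with r at q = ", qi)
  }
  out[order(out$r, out$q), , drop = FALSE]
}
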