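# Free-end (free-free beam) bending eigenmodes used for the fluctuation
# analysis. Mode k has wavenumber q = alpha_k / L. Three conventions for
# alpha_k are supported:
#   "exact"           roots of the free-end eigenvalue condition
#                     tan(a/2) + tanh(a/2) = 0 (k odd, symmetric modes)
#                     tan(a/2) - tanh(a/2) = 0 (k even, antisymmetric modes);
#                     the only choice under which the mode set is orthonormal,
#                     and therefore the default,
#   "half_integer_pi" alpha_k = (k + 1/2) * pi, the large-k asymptote,
#   "printed"         alpha_k = k + 1/2 (no pi), kept for comparison with
#                     sources that quote the wavenumber in that form.

.alpha_cache <- new.env(parent = emptyenv())

#' Eigenvalues of the free-end bending modes
#'
#' @param k integer vector of mode numbers (1-based).
#' @param convention one of `"exact"`, `"half_integer_pi"`, `"printed"`.
#' @return numeric vector alpha_k; the wavenumber of mode k on a filament of
#'   length L is `q = alpha_k / L`.
#' @export
mode_alpha <- function(k, convention = c("exact", "half_integer_pi", "printed")) {
  convention <- match.arg(convention)
  stopifnot(all(k >= 1), all(k == round(k)))
  switch(convention,
    printed = k + 0.5,
    half_integer_pi = (k + 0.5) * pi,
    exact = vapply(k, function(kk) {
      key <- as.character(kk)
      if (!is.null(.alpha_cache[[key]])) return(.alpha_cache[[key]])
      f <- if (kk %% 2 == 1) function(a) tan(a / 2) + tanh(a / 2)
           else function(a) tan(a / 2) - tanh(a / 2)
      ctr <- (kk + 0.5) * pi
      root <- uniroot(f, c(ctr - 0.5, ctr + 0.5), tol = 1e-13)$root
      .alpha_cache[[key]] <- root
      root
    }, numeric(1))
  )
}

#' Free-end bending eigenfunctions and their antiderivatives
#'
#' Evaluates the k-th free-end eigenfunction `y_q(s)` (units 1/sqrt(um), so
#' that `integral y_q^2 ds = 1`) and its antiderivative `ytilde_q(s)` on a
#' grid of arclength positions. Odd modes are symmetric about the filament
#' midpoint (cosh/cos form), even modes antisymmetric (sinh/sin form); the
#' antiderivative satisfies `d ytilde/ds = y_q`, which is what turns the
#' deflection projection into a tangent-angle projection by integration by
#' parts.
#'
#' @param k mode number, 1..10.
#' @param L contour length in um.
#' @param s numeric vector of arclength positions in `[0, L]` (um).
#' @param convention eigenvalue convention, see [mode_alpha()].
#' @return list with `k`, `alpha`, `q` (1/um), `y`, `ytilde` and the
#'   derivative `yprime` evaluated at `s`.
#' @export
eigenfunctions <- function(k, L, s,
                           convention = c("exact", "half_integer_pi", "printed")) {
  convention <- match.arg(convention)
  stopifnot(length(k) == 1L, k >= 1, k <= 10, L > 0,
            all(s >= -1e-9), all(s <= L + 1e-9))
  alpha <- mode_alpha(k, convention)
  q <- alpha / L
  u <- s - L / 2
  if (abs(cos(alpha / 2)) < 1e-8 || abs(sin(alpha / 2)) < 1e-8)
    stop("degenerate eigenvalue: cos(alpha/2) or sin(alpha/2) ~ 0 for k = ", k,
         call. = FALSE)
  if (k %% 2 == 1) {
    y <- (1 / sqrt(L)) * (cosh(q * u) / cosh(alpha / 2) +
                            cos(q * u) / cos(alpha / 2))
    yt <- (sqrt(L) / alpha) * (sinh(q * u) / cosh(alpha / 2) +
                                 sin(q * u) / cos(alpha / 2))
    yp <- (q / sqrt(L)) * (sinh(q * u) / cosh(alpha / 2) -
                             sin(q * u) / cos(alpha / 2))
  } else {
    y <- (1 / sqrt(L)) * (sinh(q * u) / sinh(alpha / 2) +
                            sin(q * u) / sin(alpha / 2))
    yp <- (q / sqrt(L)) * (cosh(q * u) / sinh(alpha / 2) +
                             cos(q * u) / sin(alpha / 2))
    # antiderivative of the sinh/sin form: the cos term enters with a minus
    # sign (d/ds cos = -sin); at the exact eigenvalues ytilde then vanishes
    # at both ends, which is what makes the tangent-angle projection exact.
    yt <- (sqrt(L) / alpha) * (cosh(q * u) / sinh(alpha / 2) -
                                 cos(q * u) / sin(alpha / 2))
  }
  list(k = k, alpha = alpha, q = q, y = y, ytilde = yt, yprime = yp)
}
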