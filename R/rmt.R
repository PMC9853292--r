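# Random-matrix-theory threshold selection.
#
# As the correlation threshold rises, the thresholded matrix loses its dense
# random (noise) component and the nearest-neighbour spacing distribution
# (NNSD) of its unfolded eigenvalues transitions from Gaussian orthogonal
# ensemble statistics (Wigner surmise, level repulsion) to Poisson statistics
# (uncorrelated levels), signalling nonrandom modular structure. The selected
# threshold is the smallest scanned value whose NNSD is compatible with
# Poisson.

# Unfold a spectrum: map eigenvalues through a smooth estimate of the
# cumulative spectral function so spacings have unit mean. The estimate is a
# cubic smoothing spline (few effective df, so only the global density is
# captured) of rank against eigenvalue, projected to be non-decreasing.
# Degenerate eigenvalues are collapsed first. Returns NULL when the spectrum
# is too small to unfold.
unfold_spacings <- function(eigenvalues, df_unfold = 10, min_eigen = 20) {
  ev <- sort(eigenvalues)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]
  n <- length(ev)
  if (n < min_eigen) return(NULL)
  fit <- smooth.spline(ev, seq_len(n), df = min(df_unfold, n - 2))
  u <- cummax(predict(fit, ev)$y)
  d <- diff(u)
  list(n_eigen = n, spacings = d, spacing_mean = mean(d))
}

# Chi-square goodness of fit of unit-mean spacings against a reference
# spacing law, on bins of width `bw` over [0, dmax] (overflow mass folded
# into the last bin), pooling adjacent bins until each expects >= min_exp
# counts. Returns c(statistic, p).
nnsd_chisq <- function(spacings, ref_cdf, bw = 0.1, dmax = 3, min_exp = 5) {
  d <- spacings / mean(spacings)
  brk <- seq(0, dmax, by = bw)
  obs <- tabulate(findInterval(pmin(d, dmax - 1e-12), brk,
                               rightmost.closed = TRUE),
                  nbins = length(brk) - 1)
  pe <- diff(ref_cdf(brk))
  pe[length(pe)] <- pe[length(pe)] + (1 - ref_cdf(dmax))
  e <- pe * length(d)
  O <- numeric(0); E <- numeric(0); co <- 0; ce <- 0
  for (i in seq_along(e)) {
    co <- co + obs[i]; ce <- ce + e[i]
    if (ce >= min_exp) { O <- c(O, co); E <- c(E, ce); co <- 0; ce <- 0 }
  }
  if (ce > 0 && length(E) > 0) {
    O[length(O)] <- O[length(O)] + co
    E[length(E)] <- E[length(E)] + ce
  }
  if (length(E) < 2) return(c(NA_real_, NA_real_))
  stat <- sum((O - E)^2 / E)
  c(stat, pchisq(stat, df = length(E) - 1, lower.tail = FALSE))
}

poisson_spacing_cdf <- function(x) 1 - exp(-x)
goe_spacing_cdf <- function(x) 1 - exp(-pi * x^2 / 4)

#' Select a correlation threshold by random matrix theory
#'
#' Scans candidate thresholds `s` in ascending order. For each `s` the
#' correlation matrix is thresholded (entries with `|rho| < s` zeroed, signed
#' values kept elsewhere, unit diagonal), isolated rows are dropped, the
#' eigenvalues are unfolded, and the NNSD is tested by chi-square against the
#' Poisson law `P(d) = exp(-d)` and the GOE Wigner surmise
#' `P(d) = (pi d / 2) exp(-pi d^2 / 4)`. The selected threshold is the
#' smallest `s` whose Poisson fit is not rejected at level `alpha`.
#'
#' Scans are skipped (with a diagnostic note) when the thresholded matrix has
#' fewer than `min_eigen` distinct eigenvalues or when the unfolded spacing
#' mean deviates from 1 by more than 0.05 (a failed unfolding).
#'
#' Note the scan range must extend below the noise-correlation scale
#' (roughly `2/sqrt(n_samples)`) for the GOE phase to be observable at all;
#' the 0.30 default suits the 20-30-sample regime typical of these studies.
#'
#' @param corr A `men_corr` object.
#' @param s_min,s_max,step Scan range and increment.
#' @param alpha Rejection level for the Poisson chi-square test.
#' @return An object of class `rmt_scan`: list with `scan` (tibble:
#'   `threshold`, `n_eigen`, `spacing_mean`, `chisq_poisson`, `p_poisson`,
#'   `chisq_goe`, `p_goe`, `valid`, `note`), `selected`, `alpha`, and the
#'   unfolding settings. Errors if no scanned threshold is compatible with
#'   Poisson.
#' @export
rmt_select_threshold <- function(corr, s_min = 0.30, s_max = 0.99,
                                 step = 0.01, alpha = 0.05) {
  stopifnot(inherits(corr, "men_corr"))
  if (length(corr$ids) < 30) {
    stop("need >= 30 OTUs for a meaningful spectrum", call. = FALSE)
  }
  rho <- corr$rho
  rows <- purrr::map_dfr(seq(s_min, s_max, by = step), function(s) {
    empty <- tibble::tibble(threshold = s, n_eigen = NA_integer_,
                            spacing_mean = NA_real_,
                            chisq_poisson = NA_real_, p_poisson = NA_real_,
                            chisq_goe = NA_real_, p_goe = NA_real_,
                            valid = FALSE, note = "")
    a <- rho
    a[abs(a) < s] <- 0
    diag(a) <- 1
    keep <- rowSums(a != 0) > 1  # diagonal always non-zero
    if (sum(keep) < 20) {
      empty$note <- "fewer than 20 connected rows"
      return(empty)
    }
    ev <- eigen(a[keep, keep, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    uf <- unfold_spacings(ev)
    if (is.null(uf)) {
      empty$note <- "degenerate spectrum (too few distinct eigenvalues)"
      return(empty)
    }
    if (all(uf$spacings < 1e-10)) {
      empty$note <- "degenerate spectrum (all spacings zero)"
      return(empty)
    }
    cp <- nnsd_chisq(uf$spacings, poisson_spacing_cdf)
    cg <- nnsd_chisq(uf$spacings, goe_spacing_cdf)
    ok <- abs(uf$spacing_mean - 1) <= 0.05 && !is.na(cp[2])
    tibble::tibble(threshold = s, n_eigen = uf$n_eigen,
                   spacing_mean = uf$spacing_mean,
                   chisq_poisson = cp[1], p_poisson = cp[2],
                   chisq_goe = cg[1], p_goe = cg[2],
                   valid = ok,
                   note = if (ok) "" else "unfolding failed spacing-mean check")
  })
  sel <- rows$threshold[rows$valid & rows$p_poisson > alpha]
  if (length(sel) == 0) {
    stop("no GOE-to-Poisson transition found in [", s_min, ", ", s_max,
         "]; widen the scan range (it must reach below the noise-correlation",
         " scale ~2/sqrt(n_samples))", call. = FALSE)
  }
  structure(list(scan = rows, selected = sel[1], alpha = alpha,
                 n_samples = corr$n_samples),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat("RMT threshold scan:", sum(!is.na(x$scan$p_poisson)), "of",
      nrow(x$scan), "thresholds evaluated\n")
  cat("selected threshold:", x$selected,
      sprintf("(smallest with Poisson p > %g)\n", x$alpha))
  invisible(x)
}
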