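# Vectorised per-spectrum chi2 / effective-d.f. machinery.
#
# All statistics live in square-root residual space: delta_i = sqrt(H_i) -
# sqrt(M_i) over the populated bins (H_i > 0), each with variance budget
# 1/4 + sigma2_M,i (Poisson sampling after the square-root transform plus
# optional per-bin model-training variance). Fitting the N quantities
# removes variance from the residuals; the removal in bin i is estimated by
# error propagation through d(delta_i)/dQ_k = P(i|k) / (2 sqrt(M_i)) and the
# quantity covariance C, and the effective d.f. is the expected chi2:
#   neff = sum_i clip(1 - sigma2_dfc,i / (1/4 + sigma2_M,i), 0, 1).
.spectrum_stats <- function(h, P, q, C, sigma2M, eps) {
  m <- drop(P %*% q)
  pop <- h > 0
  n <- sum(pop)
  if (n == 0L)
    return(list(chi2 = 0, neff = NA_real_, n_populated = 0L,
                delta = numeric(0L), sigma2_dfc = numeric(0L)))
  mf <- pmax(m[pop], eps)
  delta <- sqrt(h[pop]) - sqrt(m[pop])
  denom <- 0.25 + sigma2M[pop]
  chi2 <- sum(delta^2 / denom)
  A <- P[pop, , drop = FALSE] / (2 * sqrt(mf))
  A[m[pop] == 0, ] <- 0                     # populated bin, zero model support
  s2 <- rowSums((A %*% C) * A)
  terms <- pmin(pmax(1 - s2 / denom, 0), 1)
  neff <- min(max(sum(terms), n - ncol(P)), n)
  list(chi2 = chi2, neff = neff, n_populated = n, delta = delta,
       sigma2_dfc = s2)
}

.all_stats <- function(H, P, Q, covs, sigma2M, eps) {
  S <- nrow(H)
  if (is.null(sigma2M)) sigma2M <- rep(0, ncol(H))
  chi2 <- numeric(S); neff <- numeric(S); np <- integer(S)
  for (s in seq_len(S)) {
    r <- .spectrum_stats(H[s, ], P, Q[s, ], covs[, , s], sigma2M, eps)
    chi2[s] <- r$chi2; neff[s] <- r$neff; np[s] <- r$n_populated
  }
  list(chi2 = chi2, neff = neff, n_populated = np)
}

#' Local chi-squared of a single spectrum
#'
#' Square-root-space goodness-of-fit of one spectrum against its model
#' prediction: `chi2 = sum_i (sqrt(H_i) - sqrt(M_i))^2 / (1/4 + sigma2_M,i)`
#' over the populated bins (`H_i > 0`). The 1/4 term is the Poisson sampling
#' variance after the square-root transform; `sigma2_M` carries optional
#' per-bin model-training variance (default 0, appropriate for PMFs learned
#' from a large cohort).
#'
#' @param spectrum non-negative count vector of length I.
#' @param model an [lpm_components()] object.
#' @param quantities fitted quantity vector for this spectrum.
#' @param model_variance optional per-bin variance added to 1/4; defaults to
#'   the model's own `model_variance`, else 0.
#' @param epsilon floor for model values.
#' @return a list: `chi2`, `n_populated`, and per-populated-bin `delta`
#'   residuals.
#' @export
local_chi2 <- function(spectrum, model, quantities, model_variance = NULL,
                       epsilon = 1e-12) {
  model <- as_lpm_components(model)
  if (is.null(model_variance)) model_variance <- model$model_variance
  if (is.null(model_variance)) model_variance <- rep(0, nrow(model$pmfs))
  C0 <- matrix(0, model$order, model$order)
  r <- .spectrum_stats(as.numeric(spectrum), model$pmfs,
                       as.numeric(quantities), C0, model_variance, epsilon)
  list(chi2 = r$chi2, n_populated = r$n_populated, delta = r$delta)
}

#' Effective degrees-of-freedom of a single spectrum
#'
#' The expected local chi-squared after accounting for the variance removed
#' from the residuals by fitting the quantities, computed by error
#' propagation from the quantity covariance:
#' `sigma2_dfc,i = d_i' C d_i` with `d_i = P(i|.)/(2 sqrt(M_i))`, and
#' `neff = sum_i clip(1 - sigma2_dfc,i / (1/4 + sigma2_M,i), 0, 1)` over
#' populated bins. `neff` is generally non-integer; for an N-component model
#' it lies between `n_populated - N` and `n_populated` (a single
#' well-populated component gives exactly `n - 1`).
#'
#' @inheritParams local_chi2
#' @param covariance N x N quantity covariance from [mvb_covariance()].
#' @return a list: `neff`, `n_populated`, per-populated-bin `sigma2_dfc`.
#' @export
effective_dof <- function(spectrum, model, quantities, covariance,
                          model_variance = NULL, epsilon = 1e-12) {
  model <- as_lpm_components(model)
  if (is.null(model_variance)) model_variance <- model$model_variance
  if (is.null(model_variance)) model_variance <- rep(0, nrow(model$pmfs))
  r <- .spectrum_stats(as.numeric(spectrum), model$pmfs,
                       as.numeric(quantities), covariance, model_variance,
                       epsilon)
  list(neff = r$neff, n_populated = r$n_populated, sigma2_dfc = r$sigma2_dfc)
}

#' Chi-squared survival P-value with fractional degrees-of-freedom
#'
#' `P = Q(neff/2, chi2/2)`, the regularized upper incomplete gamma function,
#' i.e. the chi-squared survival function, valid for non-integer d.f.
#'
#' @param chi2 non-negative statistic (vectorized).
#' @param neff positive, possibly fractional, degrees-of-freedom.
#' @return P-values in `[0, 1]`.
#' @export
chi2_pvalue <- function(chi2, neff) {
  if (any(chi2 < 0, na.rm = TRUE)) stop("chi2 must be >= 0")
  if (any(neff <= 0, na.rm = TRUE)) stop("neff must be > 0")
  stats::pchisq(chi2, df = neff, lower.tail = FALSE)
}

#' Null-component significance test
#'
#' Tests, spectrum by spectrum, whether the named components are needed to
#' describe the data. Quantities are fitted once with the full model and once
#' with the null components removed (a genuine refit, not a zeroing), and a
#' local chi-squared with effective d.f. and P-value is computed for both.
#' Under the null hypothesis (the component really is absent) `pvalue_null`
#' is uniform on `[0, 1]`; where the component is present the null refit
#' cannot absorb its signal and `pvalue_null` collapses towards zero.
#' The null-reduced P-values are the headline test output.
#'
#' No multiple-comparison correction is applied: at threshold `alpha` a
#' fraction `alpha` of truly-null spectra is expected to be flagged.
#'
#' @param cohort an [lpm_cohort()] or counts matrix.
#' @param model an [lpm_components()] object or fitted [lpm()] model whose
#'   PMFs define the full model.
#' @param null_components component names or indices to remove (a nonempty
#'   strict subset).
#' @param ... further arguments passed to the quantity fits (see [lpm()]).
#' @return an object of class `"lpm_test"`: per-spectrum `chi2_full`,
#'   `chi2_null`, `neff_full`, `neff_null`, `pvalue_full`, `pvalue_null`,
#'   `n_populated`, the excluded `null_components`, and the two fits.
#' @export
test_null_component <- function(cohort, model, null_components, ...) {
  cohort <- as_lpm_cohort(cohort)
  comps <- as_lpm_components(model)
  if (is.character(null_components))
    null_idx <- match(null_components, comps$component_names)
  else null_idx <- as.integer(null_components)
  if (anyNA(null_idx) || length(null_idx) == 0L ||
      any(null_idx < 1L | null_idx > comps$order))
    stop("null_components must name existing components")
  null_idx <- unique(null_idx)
  if (length(null_idx) >= comps$order)
    stop("cannot remove all components")

  reduced <- lpm_components(comps$pmfs[, -null_idx, drop = FALSE],
                            component_names = comps$component_names[-null_idx],
                            model_variance = comps$model_variance)
  fit_full <- lpm(cohort, components = comps, ...)
  fit_null <- lpm(cohort, components = reduced, ...)

  s2M <- comps$model_variance
  eps <- fit_full$epsilon
  full <- .all_stats(cohort$counts, comps$pmfs, fit_full$quantities,
                     fit_full$covariances, s2M, eps)
  null <- .all_stats(cohort$counts, reduced$pmfs, fit_null$quantities,
                     fit_null$covariances, s2M, eps)
  pv <- function(x) ifelse(is.na(x$neff) | x$neff <= 0, NA_real_,
                           stats::pchisq(x$chi2, df = x$neff,
                                         lower.tail = FALSE))
  structure(list(chi2_full = full$chi2, chi2_null = null$chi2,
                 neff_full = full$neff, neff_null = null$neff,
                 pvalue_full = pv(full), pvalue_null = pv(null),
                 n_populated = full$n_populated,
                 null_components = comps$component_names[null_idx],
                 fit_full = fit_full, fit_null = fit_null,
                 coords = cohort$coords),
            class = "lpm_test")
}

#' @export
print.lpm_test <- function(x, ...) {
  S <- length(x$chi2_full)
  cat(sprintf("Null-component test: %d spectra, null = {%s}\n",
              S, paste(x$null_components, collapse = ", ")))
  cat(sprintf("  mean chi2 full %.3f (mean neff %.3f), null %.3f (mean neff %.3f)\n",
              mean(x$chi2_full), mean(x$neff_full, na.rm = TRUE),
              mean(x$chi2_null), mean(x$neff_null, na.rm = TRUE)))
  cat(sprintf("  mean null P-value %.4f; %d/%d spectra with P < 0.01\n",
              mean(x$pvalue_null, na.rm = TRUE),
              sum(x$pvalue_null < 0.01, na.rm = TRUE), S))
  invisible(x)
}

#' @export
as.data.frame.lpm_test <- function(x, ...) {
  out <- data.frame(chi2_full = x$chi2_full, chi2_null = x$chi2_null,
                    neff_full = x$neff_full, neff_null = x$neff_null,
                    pvalue_full = x$pvalue_full, pvalue_null = x$pvalue_null,
                    n_populated = x$n_populated)
  if (!is.null(x$coords)) out <- cbind(as.data.frame(x$coords), out)
  out
}

#' Significance mask at a confidence threshold
#'
#' Marks the spectra whose null-reduced P-value falls below `alpha`; when
#' pixel coordinates are available the mask is also laid out as an image
#' matrix (attribute `"image"`).
#'
#' @param result an [test_null_component()] result.
#' @param alpha significance threshold in (0, 1].
#' @param coords optional S x 2 integer coordinates overriding those carried
#'   by the test.
#' @return logical vector, one entry per spectrum (`NA` P-values are
#'   `FALSE`); attribute `"image"` holds the pixel map when coordinates are
#'   present.
#' @export
significance_mask <- function(result, alpha = 0.01, coords = NULL) {
  stopifnot(inherits(result, "lpm_test"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  mask <- !is.na(result$pvalue_null) & result$pvalue_null < alpha
  if (is.null(coords)) coords <- result$coords
  if (!is.null(coords)) {
    img <- matrix(NA, max(coords[, 2L]) - min(coords[, 2L]) + 1L,
                  max(coords[, 1L]) - min(coords[, 1L]) + 1L)
    img[cbind(coords[, 2L] - min(coords[, 2L]) + 1L,
              coords[, 1L] - min(coords[, 1L]) + 1L)] <- mask
    attr(mask, "image") <- img
  }
  mask
}
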