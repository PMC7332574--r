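# Square-root-space global chi-squared. Residuals sqrt(H) - sqrt(M) have
# sampling variance ~ 1/4 under Poisson noise, so each populated bin
# contributes 4 * residual^2. Populated = H > 0; empty bins are excluded
# from D (they still penalize the likelihood through the -M term).
.global_chi2 <- function(H, M, n_params) {
  resid <- sqrt(H) - sqrt(M)
  populated <- sum(H > 0)
  D <- populated - n_params
  if (D <= 0) stop("model over-parameterized for data: ", populated,
                   " populated bins <= ", n_params, " parameters")
  chi2 <- 4 * sum(resid[H > 0]^2)
  structure(list(chi2_per_dof = chi2 / D, dof = as.integer(D),
                 populated_bins = as.integer(populated),
                 parameter_count = as.integer(n_params),
                 residual_matrix = resid),
            class = "lpm_gof")
}

#' Global goodness-of-fit of a linear Poisson model
#'
#' Computes the image-wide chi-squared per degree-of-freedom in square-root
#' residual space: `chi2_D = (1/D) sum_si (sqrt(H) - sqrt(M))^2 / (1/4)`
#' over populated bins (`H > 0`). The square-root transform turns Poisson
#' counts into approximately Gaussian variables with variance 1/4, so a
#' correct model at native count scaling gives `chi2_D ~ 1`. `D` is the
#' number of populated bins minus the number of estimated parameters
#' (`S*N` quantities, plus `N*(I-1)` free PMF entries when the PMFs were
#' learned from the same data).
#'
#' @param fit a fitted [lpm()] object.
#' @return an object of class `"lpm_gof"`: `chi2_per_dof`, `dof`,
#'   `populated_bins`, `parameter_count` and the square-root-space
#'   `residual_matrix`.
#' @export
global_chi2 <- function(fit) {
  stopifnot(inherits(fit, "lpm"))
  if (is.null(fit$gof))
    stop("model over-parameterized for data: no global chi2 report")
  fit$gof
}

#' @export
print.lpm_gof <- function(x, ...) {
  cat(sprintf("Global chi2/dof = %.4f  (%d populated bins - %d parameters = %d d.f.)\n",
              x$chi2_per_dof, x$populated_bins, x$parameter_count, x$dof))
  invisible(x)
}

#' Bland-Altman noise diagnostic
#'
#' Verifies the Poisson noise assumption by stratifying the raw residuals
#' `H - M` into equal-occupancy intensity strata by model value `M` and
#' fitting a power law `sd(residual) = a * M^b` across strata (least squares
#' on the log-log stratum means). Poisson counts give `b ~ 0.5` (noise grows
#' with the square root of the signal); additive constant-variance noise
#' gives `b ~ 0`.
#'
#' @param fit a fitted [lpm()] object.
#' @param strata number of equal-occupancy intensity strata (>= 20 populated
#'   strata are required).
#' @return a list of class `"lpm_bland_altman"`: `amplitude` (a),
#'   `exponent` (b) and the per-stratum diagnostic `table`
#'   (mean model intensity, residual sd, count).
#' @export
bland_altman <- function(fit, strata = 20L) {
  stopifnot(inherits(fit, "lpm"))
  H <- fit$cohort$counts
  M <- fitted(fit)
  keep <- M > 0 & H > 0
  m <- M[keep]; r <- (H - M)[keep]
  if (all(r == 0))                  # perfect fit: no noise to characterise
    return(structure(list(amplitude = 0, exponent = 0,
                          table = data.frame(mean_intensity = numeric(0L),
                                             residual_sd = numeric(0L),
                                             n = integer(0L))),
                     class = "lpm_bland_altman"))
  if (length(unique(m)) < strata)
    stop("too few distinct populated intensities for ", strata, " strata")
  br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = strata + 1L)))
  g <- cut(m, breaks = br, include.lowest = TRUE)
  tab <- data.frame(mean_intensity = tapply(m, g, mean),
                    residual_sd = tapply(r, g, stats::sd),
                    n = as.integer(table(g)))
  tab <- tab[is.finite(tab$residual_sd) & tab$residual_sd > 0 & tab$n >= 2L, ]
  if (nrow(tab) < 20L) stop("too few populated strata: ", nrow(tab))
  fitlm <- stats::lm(log(residual_sd) ~ log(mean_intensity), data = tab)
  structure(list(amplitude = unname(exp(stats::coef(fitlm)[1L])),
                 exponent = unname(stats::coef(fitlm)[2L]),
                 table = tab),
            class = "lpm_bland_altman")
}

#' @export
print.lpm_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman power law: sd(residual) = %.4g * M^%.4f over %d strata\n",
              x$amplitude, x$exponent, nrow(x$table)))
  cat("  (Poisson noise: exponent ~ 0.5; additive noise: exponent ~ 0)\n")
  invisible(x)
}

#' @export
plot.lpm_bland_altman <- function(x, ...) {
  graphics::plot(x$table$mean_intensity, x$table$residual_sd, log = "xy",
                 xlab = "model intensity M", ylab = "residual SD",
                 main = "Bland-Altman noise diagnostic", ...)
  graphics::curve(x$amplitude * t^x$exponent, xname = "t", add = TRUE, lty = 2)
  invisible(x)
}
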