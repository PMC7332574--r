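# Per-spectrum minimum-variance-bound machinery.
#
# The negative Hessian of the per-spectrum extended log-likelihood wrt the
# quantities is [C^-1]_ab = sum_i H_i P(i|a) P(i|b) / M_i^2 (observed
# information; the expected form replaces H with M, giving
# sum_i P(i|a)P(i|b)/M_i). Inverting gives the quantity error covariance;
# rank-deficient information matrices get a Moore-Penrose pseudo-inverse and
# a degeneracy flag instead of an error.
.mvb_one <- function(h, P, q, eps, information) {
  m <- drop(P %*% q)
  mf <- pmax(m, eps)
  w <- if (information == "observed") sqrt(h) / mf else 1 / sqrt(mf)
  A <- P * w                       # row-scaled: crossprod gives information
  info <- crossprod(A)
  cov <- tryCatch({
    ch <- chol(info)
    if (min(diag(ch)) < sqrt(eps)) stop("near-singular")
    list(C = chol2inv(ch), degenerate = FALSE)
  }, error = function(e) list(C = MASS::ginv(info), degenerate = TRUE))
  cov
}

.mvb_all <- function(H, P, Q, eps, information) {
  S <- nrow(Q); N <- ncol(Q)
  covs <- array(0, dim = c(N, N, S))
  degen <- logical(S)
  for (s in seq_len(S)) {
    r <- .mvb_one(H[s, ], P, Q[s, ], eps, information)
    covs[, , s] <- (r$C + t(r$C)) / 2
    degen[s] <- r$degenerate
  }
  list(covariances = covs, degenerate = degen)
}

#' Minimum-variance-bound covariance of fitted quantities
#'
#' Error covariance of one spectrum's quantity estimates from the inverse of
#' the negative Hessian of the per-spectrum extended Poisson log-likelihood,
#' evaluated at the fit: `[C^-1]_ab = sum_i H_i P(i|a) P(i|b) / M_i^2`.
#' The square roots of the diagonal are the +/-1 SD error bars. A singular
#' information matrix (e.g. duplicated components, empty spectrum) yields a
#' Moore-Penrose pseudo-inverse with the `degenerate` attribute set rather
#' than an error.
#'
#' For a single component the bound reduces to `var(Q) = Q = total counts`,
#' the familiar Poisson counting error.
#'
#' @param spectrum non-negative count vector of length I.
#' @param model an [lpm_components()] object.
#' @param quantities fitted quantity vector of length N for this spectrum.
#' @param epsilon floor for model values in divisions.
#' @param information `"observed"` (counts-weighted, default) or
#'   `"expected"` (model-weighted) Fisher information.
#' @return an N x N symmetric covariance matrix with logical attribute
#'   `degenerate`.
#' @export
mvb_covariance <- function(spectrum, model, quantities, epsilon = 1e-12,
                           information = c("observed", "expected")) {
  model <- as_lpm_components(model)
  information <- match.arg(information)
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != nrow(model$pmfs)) stop("spectrum length must equal bins")
  if (length(quantities) != model$order) stop("quantities length must equal order")
  r <- .mvb_one(spectrum, model$pmfs, as.numeric(quantities), epsilon, information)
  C <- (r$C + t(r$C)) / 2
  dimnames(C) <- list(model$component_names, model$component_names)
  attr(C, "degenerate") <- r$degenerate
  C
}

#' Pull distribution of fitted quantities against simulation truth
#'
#' For every spectrum and component the pull is
#' `(Q_hat - Q_true) / sigma` with `sigma` the minimum-variance-bound error
#' bar. Honest error estimates give pulls with mean 0 (no bias) and standard
#' deviation 1 (predicted spread equals observed spread). Because quantities
#' cannot be fitted below zero, pulls are truncated where the true quantity
#' is within a few error bars of zero; statistics are therefore reported both
#' raw and with near-zero-truth spectra excluded (`Q_true >= min_truth_sd *
#' sigma`).
#'
#' @param fit a fitted [lpm()] object (typically a projection onto the true
#'   PMFs of a simulation).
#' @param truth an [truth_maps()] result, or an S x N matrix of true
#'   quantities aligned with the fit.
#' @param min_truth_sd exclusion threshold, in error-bar units, below which
#'   a true quantity counts as "near zero".
#' @param exclude `"spectrum"` (default): keep only spectra in which *every*
#'   component's truth clears the threshold — truncation at zero couples
#'   across components through their covariance, so a near-zero component
#'   contaminates its partners; `"component"`: each component keeps the
#'   spectra where its own truth clears the threshold.
#' @return a data frame of class `"lpm_pulls"`, one row per component:
#'   raw and filtered pull mean/sd, numbers used and excluded. The full pull
#'   matrix is in attribute `"pulls"`.
#' @export
pull_distribution <- function(fit, truth, min_truth_sd = 3,
                              exclude = c("spectrum", "component")) {
  exclude <- match.arg(exclude)
  stopifnot(inherits(fit, "lpm"))
  Qt <- if (inherits(truth, "lpm_truth")) truth$true_quantities else as.matrix(truth)
  Q <- fit$quantities
  if (!all(dim(Qt) == dim(Q))) stop("truth and fit dimensions differ")
  N <- ncol(Q)
  sig <- sqrt(t(apply(fit$covariances, 3L, diag)))
  if (N == 1L) sig <- matrix(sig, ncol = 1L)
  ok <- sig > 0
  pulls <- matrix(NA_real_, nrow(Q), N)
  pulls[ok] <- (Q[ok] - Qt[ok]) / sig[ok]
  zero_sigma_bad <- sum(!ok & abs(Q - Qt) > 0)
  far <- ok & (Qt >= min_truth_sd * sig)
  if (exclude == "spectrum") {
    keep <- rowSums(far) == N
    far <- far & keep
  }
  stat <- function(v) if (sum(!is.na(v)) > 1L)
    c(mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE)) else c(NA_real_, NA_real_)
  raw <- apply(pulls, 2L, stat)
  filt <- vapply(seq_len(N), function(k) stat(ifelse(far[, k], pulls[, k], NA)),
                 numeric(2L))
  out <- data.frame(component = fit$components$component_names,
                    mean = filt[1L, ], sd = filt[2L, ],
                    n = colSums(far, na.rm = TRUE),
                    raw_mean = raw[1L, ], raw_sd = raw[2L, ],
                    n_excluded = colSums(!far))
  attr(out, "pulls") <- pulls
  attr(out, "zero_sigma_excluded") <- zero_sigma_bad
  class(out) <- c("lpm_pulls", "data.frame")
  out
}

#' @export
print.lpm_pulls <- function(x, ...) {
  cat("Pull distribution (Q_hat - Q_true)/sigma per component\n")
  cat("  [mean/sd exclude near-zero-truth spectra; raw_* include all]\n")
  print.data.frame(x, row.names = FALSE, digits = 4L)
  invisible(x)
}
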