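#' Predicted histogram under a linear Poisson model
#'
#' Expected counts for one or more spectra: `M[s, i] = sum_k Q[s, k] P(i|k)`.
#' Because every component PMF sums to one, the predicted total of each
#' spectrum equals the sum of its quantities.
#'
#' @param model an [lpm_components()] object (or a fitted [lpm()] model).
#' @param quantities non-negative quantity vector (one spectrum) or S x N
#'   matrix.
#' @return a vector of I expected counts, or an S x I matrix.
#' @export
model_prediction <- function(model, quantities) {
  model <- as_lpm_components(model)
  if (is.null(dim(quantities))) {
    if (length(quantities) != model$order) stop("quantity length must equal model order")
    drop(model$pmfs %*% quantities)
  } else {
    if (ncol(quantities) != model$order) stop("quantities must have N columns")
    quantities %*% t(model$pmfs)
  }
}

#' Extended Poisson log-likelihood of a cohort under a model
#'
#' `sum_si H log(M) - sum_si M`: the Poisson log-likelihood (up to the
#' H-dependent `-log H!` constant) in which the total event count is itself
#' Poisson with expectation equal to the summed model mass. Model values are
#' floored at `epsilon` inside the logarithm; bins with observed counts but
#' zero model support therefore contribute a large penalty rather than
#' `-Inf`.
#'
#' @param cohort an [lpm_cohort()] or counts matrix.
#' @param model an [lpm_components()] object.
#' @param quantities S x N non-negative matrix (or N-vector for S = 1).
#' @param epsilon floor applied to model values inside the logarithm.
#' @return a single number.
#' @export
extended_log_likelihood <- function(cohort, model, quantities, epsilon = 1e-12) {
  H <- as_lpm_cohort(cohort)$counts
  model <- as_lpm_components(model)
  if (is.null(dim(quantities))) quantities <- matrix(quantities, nrow = 1L)
  if (any(quantities < 0)) stop("quantities must be non-negative")
  M <- quantities %*% t(model$pmfs)
  .ell(H, M, epsilon)
}

.ell <- function(H, M, eps) {
  pos <- H > 0
  sum(H[pos] * log(pmax(M[pos], eps))) - sum(M)
}

# One EM pass machinery shared by the joint and fixed-PMF fits.
#
# E-step responsibilities r_is(k) = Q_sk P_ik / M_si are never materialised:
# with R = H/M the M-step contractions reduce to
#   Q <- Q * (R %*% P)          (counts assigned to each component)
#   P <- colnorm(P * (t(R) %*% Q))
# which is the classic pLSA/KL-NNMF multiplicative scheme; both parameter
# blocks are updated from the same E-step, so the extended log-likelihood is
# non-decreasing at every iteration.
.em_loop <- function(H, P, Q, fixed_pmfs, max_iter, tol, eps) {
  covered <- rowSums(P) > 0              # bins inside model support
  Huse <- H
  if (!all(covered)) Huse[, !covered] <- 0
  if (fixed_pmfs)
    return(.em_project(H, Huse, P, Q, max_iter, tol, eps))
  trace <- numeric(0L)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- Q %*% t(P)
    R <- Huse / pmax(M, eps)
    R[Huse == 0] <- 0
    Qn <- Q * (R %*% P)
    Pn <- P * crossprod(R, Q)
    cs <- colSums(Pn)
    if (any(cs <= 0)) {
      return(list(P = P, Q = Qn, trace = trace, converged = FALSE,
                  degenerate = TRUE, iterations = it))
    }
    P <- sweep(Pn, 2L, cs, "/")
    Q <- Qn
    M <- Q %*% t(P)
    ll <- .ell(H, M, eps)
    trace <- c(trace, ll)
    if (is.finite(ll) && is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(P = P, Q = Q, trace = trace, converged = converged,
       degenerate = FALSE, iterations = length(trace))
}

# Fixed-PMF projection: the per-spectrum problems are independent, so each
# spectrum is frozen once its own extended log-likelihood changes by less
# than its share of the tolerance; the remaining active set shrinks and the
# total log-likelihood trace stays non-decreasing.
.em_project <- function(H, Huse, P, Q, max_iter, tol, eps) {
  S <- nrow(H)
  tol_s <- tol / max(S, 1L)
  ll_s <- rep(-Inf, S)
  active <- rep(TRUE, S)
  trace <- numeric(0L)
  it <- 0L
  while (it < max_iter && any(active)) {
    it <- it + 1L
    Ha <- Huse[active, , drop = FALSE]
    Qa <- Q[active, , drop = FALSE]
    M <- Qa %*% t(P)
    R <- Ha / pmax(M, eps)
    R[Ha == 0] <- 0
    Qa <- Qa * (R %*% P)
    Q[active, ] <- Qa
    M <- Qa %*% t(P)
    Hfull <- H[active, , drop = FALSE]
    ll_new <- rowSums(ifelse(Hfull > 0, Hfull * log(pmax(M, eps)), 0)) -
      rowSums(M)
    settled <- is.finite(ll_s[active]) & abs(ll_new - ll_s[active]) < tol_s
    ll_s[active] <- ll_new
    active[active] <- !settled
    trace <- c(trace, sum(ll_s))
  }
  list(P = P, Q = Q, trace = trace, converged = !any(active),
       degenerate = FALSE, iterations = it)
}

.init_pmfs <- function(I, N) {
  # flat Dirichlet columns
  P <- matrix(stats::rgamma(I * N, shape = 1), I, N)
  sweep(P, 2L, colSums(P), "/")
}

.finalize_fit <- function(cohort, P, Q, fixed_pmfs, trace, converged, iterations,
                          eps, information, component_names, model_variance,
                          call) {
  H <- cohort$counts
  comps <- lpm_components(P, component_names = component_names,
                          model_variance = model_variance, tol = 1e-6)
  M <- Q %*% t(comps$pmfs)
  loglik <- rowSums(ifelse(H > 0, H * log(pmax(M, eps)), 0)) - rowSums(M)
  n_params <- nrow(H) * ncol(Q) + if (fixed_pmfs) 0L else ncol(Q) * (nrow(P) - 1L)
  # tiny exact problems can have D <= 0; the fit is still valid, only the
  # global chi2 report is unavailable
  gof <- tryCatch(.global_chi2(H, M, n_params), error = function(e) NULL)
  cv <- .mvb_all(H, comps$pmfs, Q, eps = eps, information = information)
  colnames(Q) <- comps$component_names
  structure(list(components = comps, quantities = Q,
                 covariances = cv$covariances, degenerate = cv$degenerate,
                 loglik = loglik, total = sum(Q),
                 fixed_pmfs = fixed_pmfs, gof = gof,
                 trace = trace, converged = converged, iterations = iterations,
                 epsilon = eps, information = information,
                 cohort = cohort, call = call),
            class = "lpm")
}

#' Fit a linear Poisson model to a cohort of count histograms
#'
#' Describes every spectrum `s` as a non-negative mixture of component PMFs,
#' `H[s, i] ~ Poisson(sum_k Q[s, k] P(i|k))`, fitted by
#' expectation-maximization under the extended Poisson likelihood. Two modes:
#'
#' * **joint** (`order` given): both the PMFs and the quantities are learned.
#'   `restarts` models are fitted from random Dirichlet starting PMFs and the
#'   one with the lowest global chi-squared per degree-of-freedom is kept
#'   (ties broken by restart index); restarts in which a component collapses
#'   to zero mass are discarded.
#' * **projection** (`components` given): the PMFs are held fixed and only the
#'   per-spectrum quantities are estimated.
#'
#' Initial quantities are `total counts / N` for every component; convergence
#' is declared when the total extended log-likelihood changes by less than
#' `tol` (default `1e-6 * S`) between iterations. The returned object carries
#' the per-spectrum minimum-variance-bound covariances of the quantities (see
#' [mvb_covariance()]) and the global goodness-of-fit report (see
#' [global_chi2()]).
#'
#' @param x an [lpm_cohort()] object or a non-negative counts matrix
#'   (spectra as rows).
#' @param order number of components to learn (joint mode).
#' @param components an [lpm_components()] object of fixed PMFs
#'   (projection mode). Exactly one of `order`/`components` must be given.
#' @param restarts number of random restarts in joint mode.
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute convergence tolerance on the total extended
#'   log-likelihood; default `1e-6 * nrow(x)`.
#' @param seed optional integer seed controlling the random restarts.
#' @param epsilon floor for model values inside logarithms and divisions.
#' @param information `"observed"` (default) or `"expected"` Fisher
#'   information in the quantity covariances.
#' @param max_sep logical: apply the MAX SEP separation post-process
#'   (see [max_sep()]) after the joint fit.
#' @return an object of class `"lpm"` with components, quantities (S x N),
#'   per-spectrum covariances (N x N x S array), per-spectrum log-likelihoods
#'   and a `gof` global fit report. Methods: `print`, `summary`, `coef`,
#'   `vcov`, `fitted`, `residuals`, `logLik`, `predict`, `simulate`, `plot`.
#' @examples
#' truth <- truth_maps(16, 16, demo_shapes(16, 16), total_mean = 500,
#'                     total_sd = 50, seed = 1)
#' comps <- source_pmfs(list("ramp-up", "ramp-down",
#'                           list("top-hat", start = 3, width = 6),
#'                           "dirichlet"), bins = 24, seed = 2)
#' coh <- draw_cohort(truth, comps, seed = 3)
#' fit <- lpm(coh, components = comps)   # projection onto known PMFs
#' head(coef(fit))
#' @export
lpm <- function(x, order = NULL, components = NULL, restarts = 5L,
                max_iter = 2000L, tol = NULL, seed = NULL, epsilon = 1e-12,
                information = c("observed", "expected"), max_sep = FALSE) {
  cohort <- as_lpm_cohort(x)
  information <- match.arg(information)
  H <- cohort$counts
  S <- nrow(H); I <- ncol(H)
  if (is.null(tol)) tol <- 1e-6 * S
  stopifnot(tol > 0, max_iter >= 1L, epsilon > 0, epsilon <= 1e-9)
  if (!is.null(seed)) set.seed(seed)
  cl <- match.call()

  if (!is.null(components)) {
    comps <- as_lpm_components(components)
    if (nrow(comps$pmfs) != I) stop("model has ", nrow(comps$pmfs),
                                    " bins but cohort has ", I)
    uncovered <- rowSums(H[, rowSums(comps$pmfs) == 0, drop = FALSE])
    if (any(uncovered > 0 & rowSums(H) == uncovered))
      warning("some spectra have all counts outside the model support; ",
              "their quantities are zero")
    Q0 <- matrix(rowSums(H) / comps$order, S, comps$order)
    res <- .em_loop(H, comps$pmfs, Q0, fixed_pmfs = TRUE,
                    max_iter = max_iter, tol = tol, eps = epsilon)
    return(.finalize_fit(cohort, comps$pmfs, res$Q, TRUE, res$trace,
                         res$converged, res$iterations, epsilon, information,
                         comps$component_names, comps$model_variance, cl))
  }

  if (is.null(order)) stop("give either `order` or `components`")
  N <- as.integer(order)
  if (N < 1L) stop("order must be >= 1")
  if (sum(rowSums(H) > 0) < N)
    stop("cohort needs at least `order` spectra with nonzero totals")

  best <- NULL
  best_chi2 <- Inf
  n_params <- S * N + N * (I - 1L)
  for (r in seq_len(restarts)) {
    P0 <- .init_pmfs(I, N)
    Q0 <- matrix(rowSums(H) / N, S, N)
    res <- .em_loop(H, P0, Q0, fixed_pmfs = FALSE,
                    max_iter = max_iter, tol = tol, eps = epsilon)
    if (res$degenerate || any(colSums(res$Q) <= 0)) {
      message("restart ", r, ": component collapsed to zero mass, discarded")
      next
    }
    gof_r <- tryCatch(.global_chi2(H, res$Q %*% t(res$P), n_params),
                      error = function(e) NULL)
    # restart score: global chi2/dof where defined, else -loglik
    score <- if (is.null(gof_r)) -utils::tail(res$trace, 1L) else gof_r$chi2_per_dof
    if (score < best_chi2) {       # ties keep the earlier restart
      best_chi2 <- score
      best <- res
    }
  }
  if (is.null(best)) stop("all restarts degenerate")
  fit <- .finalize_fit(cohort, best$P, best$Q, FALSE, best$trace,
                       best$converged, best$iterations, epsilon, information,
                       paste0("C", seq_len(N)), NULL, cl)
  if (isTRUE(max_sep)) fit <- max_sep(fit, max_iter = max_iter, tol = tol)
  fit
}

#' Fit quantities for fixed component PMFs
#'
#' Convenience wrapper around [lpm()] in projection mode: the component PMFs
#' are held fixed and only the per-spectrum quantities are estimated.
#'
#' @param cohort an [lpm_cohort()] or counts matrix.
#' @param model an [lpm_components()] object.
#' @param ... further arguments passed to [lpm()].
#' @return a fitted `"lpm"` object.
#' @export
fit_quantities <- function(cohort, model, ...) {
  lpm(cohort, components = model, ...)
}

#' @export
print.lpm <- function(x, ...) {
  cat(sprintf("Linear Poisson model: %d spectra x %d bins, order %d (%s)\n",
              nrow(x$quantities), nrow(x$components$pmfs), x$components$order,
              if (x$fixed_pmfs) "fixed PMFs" else "jointly learned PMFs"))
  cat(sprintf("  extended log-likelihood %.6g, total quantity %.6g\n",
              sum(x$loglik), x$total))
  if (!is.null(x$gof))
    cat(sprintf("  global chi2/dof %.4f on %d d.f.%s\n",
                x$gof$chi2_per_dof, x$gof$dof,
                if (x$converged) "" else "  [NOT converged]"))
  else if (!x$converged) cat("  [NOT converged]\n")
  invisible(x)
}

#' @export
summary.lpm <- function(object, ...) {
  q <- object$quantities
  se <- sqrt(t(apply(object$covariances, 3L, diag)))
  if (object$components$order == 1L) se <- matrix(se, ncol = 1L)
  tab <- data.frame(component = object$components$component_names,
                    mean_quantity = colMeans(q),
                    total_quantity = colSums(q),
                    mean_se = colMeans(se),
                    zero_bins = colSums(object$components$pmfs == 0))
  out <- list(fit = object, table = tab)
  class(out) <- "summary.lpm"
  out
}

#' @export
print.summary.lpm <- function(x, ...) {
  print(x$fit)
  cat("\nPer-component summary:\n")
  print(x$table, row.names = FALSE, digits = 4L)
  cat(sprintf("\nDegenerate (rank-deficient) covariance in %d/%d spectra\n",
              sum(x$fit$degenerate), length(x$fit$degenerate)))
  invisible(x)
}

#' @export
coef.lpm <- function(object, ...) object$quantities

#' @export
logLik.lpm <- function(object, ...) {
  val <- sum(object$loglik)
  attr(val, "df") <- length(object$quantities) +
    if (object$fixed_pmfs) 0L else
      object$components$order * (nrow(object$components$pmfs) - 1L)
  class(val) <- "logLik"
  val
}

#' @export
fitted.lpm <- function(object, ...) {
  model_prediction(object$components, object$quantities)
}

#' Residuals of a fitted linear Poisson model
#'
#' @param object a fitted [lpm()] object.
#' @param type `"sqrt"` (default): `sqrt(H) - sqrt(M)`, the
#'   variance-stabilized residual with sampling variance ~ 1/4 used by all
#'   chi-squared statistics; `"response"`: `H - M`; `"pearson"`:
#'   `(H - M)/sqrt(M)`.
#' @param ... unused.
#' @return an S x I residual matrix.
#' @export
residuals.lpm <- function(object, type = c("sqrt", "response", "pearson"), ...) {
  type <- match.arg(type)
  H <- object$cohort$counts
  M <- fitted(object)
  switch(type,
         sqrt = sqrt(H) - sqrt(M),
         response = H - M,
         pearson = (H - M) / sqrt(pmax(M, object$epsilon)))
}

#' Per-spectrum quantity covariances of a fitted model
#'
#' @param object a fitted [lpm()] object.
#' @param spectrum optional spectrum index; if given, that spectrum's N x N
#'   covariance matrix is returned, otherwise the full N x N x S array.
#' @param ... unused.
#' @export
vcov.lpm <- function(object, spectrum = NULL, ...) {
  if (is.null(spectrum)) object$covariances
  else object$covariances[, , spectrum]
}

#' Project a fitted model onto new spectra
#'
#' Refits per-spectrum quantities for `newdata` with the learned PMFs held
#' fixed.
#'
#' @param object a fitted [lpm()] object.
#' @param newdata an [lpm_cohort()] or counts matrix; defaults to the
#'   training cohort.
#' @param ... further arguments passed to [lpm()].
#' @return a fitted `"lpm"` object (projection mode).
#' @export
predict.lpm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$cohort
  lpm(newdata, components = object$components, ...)
}

#' Simulate cohorts from a fitted model
#'
#' Draws independent Poisson counts around the fitted expectations — the
#' parametric bootstrap used by the null-calibration checks.
#'
#' @param object a fitted [lpm()] object.
#' @param nsim number of replicate cohorts.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` [lpm_cohort()] objects.
#' @export
simulate.lpm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- fitted(object)
  lapply(seq_len(nsim), function(j) {
    lpm_cohort(matrix(stats::rpois(length(M), M), nrow(M), ncol(M)),
               bin_labels = object$cohort$bin_labels,
               coords = object$cohort$coords)
  })
}

#' @export
plot.lpm <- function(x, ...) {
  P <- x$components$pmfs
  graphics::matplot(seq_len(nrow(P)), P, type = "l", lty = 1,
                    xlab = "bin", ylab = "P(i|k)",
                    main = "Component PMFs", ...)
  graphics::legend("topright", legend = x$components$component_names,
                   col = seq_len(ncol(P)), lty = 1, cex = 0.8)
  invisible(x)
}
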