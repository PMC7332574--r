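# MAX SEP: reduce the linear degeneracy of a learned component set by
# subtracting the largest multiple of each component from every other that
# keeps all probabilities non-negative, then renormalizing and letting EM
# re-converge. Components gain zero bins ("simple structure") while the
# model keeps describing the data.

#' Maximal non-negative pairwise subtraction
#'
#' Computes the largest `alpha` such that `pk - alpha * pl` stays
#' non-negative — `alpha = min over bins with pl > 0 of pk/pl` — and returns
#' the subtracted, renormalized component. When the subtraction would leave
#' less than `mass_floor` of the component's mass (near-identical
#' components), it is skipped entirely: `alpha = 0`, `pk` unchanged, and the
#' `capped` attribute is set.
#'
#' @param pk,pl normalized PMF vectors of equal length.
#' @param mass_floor minimum fraction of `pk`'s mass that must survive.
#' @return a list: `alpha` and the renormalized `pmf`; logical attribute
#'   `capped` on `alpha`.
#' @examples
#' max_sep_pair(c(0.5, 0.5), c(1, 0))       # alpha 0.5 -> c(0, 1)
#' max_sep_pair(c(0.2, 0.8), c(0.5, 0.5))   # alpha 0.4 -> c(0, 1)
#' @export
max_sep_pair <- function(pk, pl, mass_floor = 0.05) {
  stopifnot(length(pk) == length(pl), all(pk >= 0), all(pl >= 0))
  if (all(pl == 0)) {
    alpha <- 0
    attr(alpha, "capped") <- FALSE
    return(list(alpha = alpha, pmf = pk))
  }
  pos <- pl > 0
  alpha_raw <- min(pk[pos] / pl[pos])
  # both PMFs sum to one, so the surviving mass is 1 - alpha
  if (alpha_raw > 1 - mass_floor) {
    alpha <- 0
    attr(alpha, "capped") <- TRUE
    return(list(alpha = alpha, pmf = pk))
  }
  p <- pk - alpha_raw * pl
  p[p <= 1e-12] <- 0                 # snap rounding dust to exact zeros
  alpha <- alpha_raw
  attr(alpha, "capped") <- FALSE
  list(alpha = alpha, pmf = p / sum(p))
}

# one full sweep over ordered pairs (k != l); returns the separated PMFs and
# the largest alpha applied
.max_sep_sweep <- function(P, mass_floor) {
  N <- ncol(P)
  amax <- 0
  capped_any <- FALSE
  for (k in seq_len(N)) for (l in seq_len(N)) {
    if (k == l) next
    r <- max_sep_pair(P[, k], P[, l], mass_floor)
    if (isTRUE(attr(r$alpha, "capped"))) capped_any <- TRUE
    if (r$alpha > 0) {
      P[, k] <- r$pmf
      amax <- max(amax, r$alpha)
    }
  }
  list(P = P, alpha_max = amax, capped = capped_any)
}

#' Separate the components of a fitted model (MAX SEP)
#'
#' Alternates full pairwise-subtraction sweeps with EM re-convergence: each
#' sweep subtracts the maximal non-negativity-preserving multiple of every
#' component from every other (in fixed index order, for determinism), then
#' the joint EM is run to convergence from the separated PMFs. Rounds repeat
#' until no subtraction exceeds `alpha_min`, the PMFs stop changing, or
#' `max_rounds` is reached. If the re-fitted model's global chi-squared per
#' d.f. ends up more than `gof_tol` (relative) above the input model's, the
#' separation is rejected and the input fit returned with a warning.
#'
#' @param fit a fitted [lpm()] object (joint fit, with its cohort).
#' @param alpha_min smallest subtraction worth applying; a sweep whose
#'   largest alpha is below this ends the alternation.
#' @param mass_floor see [max_sep_pair()].
#' @param max_rounds maximum number of (sweep + EM) rounds.
#' @param gof_tol maximum tolerated relative increase of the global
#'   chi-squared per d.f.
#' @param max_iter,tol EM controls for the re-convergence, defaulting to the
#'   original fit's.
#' @return a fitted `"lpm"` object with separated components (or the input
#'   fit when separation is rejected).
#' @export
max_sep <- function(fit, alpha_min = 1e-6, mass_floor = 0.05,
                    max_rounds = 10L, gof_tol = 0.05,
                    max_iter = 2000L, tol = NULL) {
  stopifnot(inherits(fit, "lpm"))
  cohort <- fit$cohort
  H <- cohort$counts
  if (is.null(tol)) tol <- 1e-6 * nrow(H)
  P <- fit$components$pmfs
  Q <- fit$quantities
  n_params <- length(Q) + ncol(Q) * (nrow(P) - 1L)
  # baseline with the same (joint) parameter count as the re-fit below
  chi2_old <- .global_chi2(H, Q %*% t(P), n_params)$chi2_per_dof
  changed <- FALSE
  for (round in seq_len(max_rounds)) {
    sw <- .max_sep_sweep(P, mass_floor)
    if (sw$capped)
      warning("near-identical components: some subtractions capped by mass_floor")
    if (sw$alpha_max <= alpha_min) break
    changed <- TRUE
    res <- .em_loop(H, sw$P, Q, fixed_pmfs = FALSE,
                    max_iter = max_iter, tol = tol, eps = fit$epsilon)
    if (res$degenerate) {
      warning("EM re-fit degenerate after separation; keeping previous PMFs")
      break
    }
    delta <- sum(abs(res$P - P))
    P <- res$P
    Q <- res$Q
    if (delta < 1e-8) break
  }
  if (!changed) return(fit)
  chi2_new <- .global_chi2(H, Q %*% t(P), n_params)$chi2_per_dof
  if (chi2_new > chi2_old * (1 + gof_tol)) {
    warning(sprintf(
      "separation rejected: chi2/dof %.4f exceeds input %.4f by more than %g%%",
      chi2_new, chi2_old, 100 * gof_tol))
    return(fit)
  }
  .finalize_fit(cohort, P, Q, fixed_pmfs = FALSE,
                trace = fit$trace, converged = TRUE,
                iterations = fit$iterations, eps = fit$epsilon,
                information = fit$information,
                component_names = fit$components$component_names,
                model_variance = fit$components$model_variance,
                call = fit$call)
}
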