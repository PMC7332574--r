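# Monte Carlo generator of mixed-tissue histogram images: source PMFs mixed
# by geometric ground-truth quantity maps, then independent per-bin Poisson
# draws. This is the oracle behind every calibration check in the package.

#' Build source component PMFs from recipes
#'
#' Recipes mirror the kinds of spectra used to exercise a spectral-unmixing
#' model: linear ramps (heavily overlapping bins), top-hats (unique bins),
#' random Dirichlet draws (everything in between) and user-supplied tables.
#'
#' @param recipes a list; each element one of the strings `"ramp-up"`,
#'   `"ramp-down"`, `"dirichlet"`, a list `list("top-hat", start =, width =)`
#'   (1-based start bin), or a numeric vector of I non-negative weights.
#' @param bins number of histogram bins I.
#' @param seed optional integer seed (used by `"dirichlet"` recipes).
#' @param concentration Dirichlet concentration parameter for random PMFs;
#'   values above 1 avoid near-empty bins.
#' @return an [lpm_components()] object with one component per recipe.
#' @examples
#' source_pmfs(list("ramp-up", list("top-hat", start = 1, width = 4)), bins = 4)
#' @export
source_pmfs <- function(recipes, bins, seed = NULL, concentration = 5) {
  if (!is.null(seed)) set.seed(seed)
  I <- as.integer(bins)
  one <- function(rc) {
    if (is.numeric(rc)) {
      if (length(rc) != I || any(rc < 0) || sum(rc) <= 0)
        stop("user PMF must be I non-negative weights with positive sum")
      return(rc / sum(rc))
    }
    if (is.list(rc) && identical(rc[[1L]], "top-hat")) {
      start <- as.integer(rc$start); width <- as.integer(rc$width)
      if (is.na(start) || is.na(width) || start < 1L || width < 1L ||
          start + width - 1L > I)
        stop("top-hat window [", start, ", ", start + width - 1L,
             "] outside bins 1..", I)
      p <- numeric(I); p[start:(start + width - 1L)] <- 1 / width
      return(p)
    }
    switch(as.character(rc),
           "ramp-up"   = { w <- seq_len(I); w / sum(w) },
           "ramp-down" = { w <- rev(seq_len(I)); w / sum(w) },
           "dirichlet" = { w <- stats::rgamma(I, shape = concentration); w / sum(w) },
           stop("unknown recipe: ", rc))
  }
  P <- vapply(recipes, one, numeric(I))
  nm <- vapply(seq_along(recipes), function(j) {
    rc <- recipes[[j]]
    if (is.numeric(rc)) paste0("user", j)
    else if (is.list(rc)) paste0("tophat", j)
    else paste0(gsub("-", "_", rc), j)
  }, character(1L))
  lpm_components(P, component_names = nm)
}

#' Ground-truth quantity maps from overlapping geometric shapes
#'
#' Lays out per-pixel true component quantities on a `width x height` image:
#' each shape (rectangle, disc or full-field) deposits weight for one
#' component, overlapping shapes sum, and a shape may carry a linear gradient
#' along x or y instead of a constant weight. The per-pixel totals are then
#' rescaled so that each pixel's expected total ion quantity is an
#' independent draw from a Gaussian (`total_mean`, `total_sd`) truncated at
#' zero — emulating pixel-to-pixel signal variation — while the per-pixel
#' component *fractions* set by the shapes are preserved.
#'
#' @param width,height image size in pixels.
#' @param shapes list of shape descriptors, each a list with elements
#'   `geometry` (`"rectangle"`, `"disc"` or `"full-field"`), `component`
#'   (integer index), `weight` (positive scalar) and, optionally for the
#'   gradient case, `gradient = c(from, to)` with `along = "x"` or `"y"`;
#'   rectangles take `x0, y0, x1, y1` (inclusive pixel ranges), discs take
#'   `cx, cy, r`.
#' @param total_mean,total_sd Gaussian parameters of the per-pixel expected
#'   total quantity (counts).
#' @param n_components number of components; defaults to the largest index
#'   used by the shapes.
#' @param seed optional integer seed for the per-pixel total draws.
#' @return an object of class `"lpm_truth"`: `true_quantities` (S x N, pixel
#'   order is row-major over y then x), `coords`, `width`, `height`,
#'   `expected_total_mean`, `expected_total_sd`, `seed`.
#' @export
truth_maps <- function(width, height, shapes, total_mean, total_sd,
                       n_components = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (total_mean < 0 || total_sd < 0) stop("total_mean/total_sd must be >= 0")
  px <- expand.grid(x = seq_len(width), y = seq_len(height))
  S <- nrow(px)
  kmax <- max(vapply(shapes, function(s) as.integer(s$component), integer(1L)))
  N <- if (is.null(n_components)) kmax else as.integer(n_components)
  if (kmax > N) stop("shape references component beyond n_components")
  Q <- matrix(0, S, N)
  for (s in shapes) {
    w <- s$weight
    if (!is.null(s$gradient)) {
      if (length(s$gradient) != 2L || any(s$gradient < 0))
        stop("gradient must be two non-negative values")
    } else if (is.null(w) || w < 0) stop("shape weight must be >= 0")
    inside <- switch(s$geometry,
      "rectangle"  = px$x >= s$x0 & px$x <= s$x1 & px$y >= s$y0 & px$y <= s$y1,
      "disc"       = (px$x - s$cx)^2 + (px$y - s$cy)^2 <= s$r^2,
      "full-field" = rep(TRUE, S),
      stop("unknown geometry: ", s$geometry))
    if (!is.null(s$gradient)) {
      along <- if (is.null(s$along)) "x" else s$along
      v <- if (along == "x") px$x else px$y
      rng <- range(v[inside])
      frac <- if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L]) else 0
      w <- s$gradient[1L] + (s$gradient[2L] - s$gradient[1L]) * frac
    }
    Q[inside, s$component] <- Q[inside, s$component] +
      if (length(w) > 1L) w[inside] else w
  }
  tot <- rowSums(Q)
  target <- pmax(stats::rnorm(S, total_mean, total_sd), 0)
  nz <- tot > 0
  Q[nz, ] <- Q[nz, , drop = FALSE] * (target[nz] / tot[nz])
  structure(list(true_quantities = Q, coords = as.matrix(px),
                 width = as.integer(width), height = as.integer(height),
                 expected_total_mean = total_mean,
                 expected_total_sd = total_sd, seed = seed),
            class = "lpm_truth")
}

#' @export
print.lpm_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d x %d pixels, %d components\n",
              x$width, x$height, ncol(x$true_quantities)))
  cat(sprintf("  per-pixel expected total ~ N(%.4g, %.4g) truncated at 0\n",
              x$expected_total_mean, x$expected_total_sd))
  invisible(x)
}

#' Shapes of the default demonstration image
#'
#' Three overlapping tissue layers (a full-field background, a large
#' rectangle and a large central disc) plus a "pathology" rectangle whose
#' weight ramps linearly along x from 0 to the local tissue weight, i.e.
#' from 0 to ~33% of the pixel signal at its right-hand edge. The shapes
#' overlap over a substantial central region so that pull statistics
#' restricted to pixels where every component is well away from zero retain
#' a few thousand pixels.
#'
#' @param width,height image size the shapes are laid out on.
#' @return a shape list for [truth_maps()].
#' @export
demo_shapes <- function(width = 128, height = 128) {
  list(
    list(geometry = "full-field", component = 1L, weight = 1),
    list(geometry = "rectangle", component = 2L, weight = 1,
         x0 = round(width * 0.10), y0 = round(height * 0.10),
         x1 = round(width * 0.90), y1 = round(height * 0.90)),
    list(geometry = "disc", component = 3L, weight = 1,
         cx = round(width * 0.50), cy = round(height * 0.50),
         r = round(min(width, height) * 0.35)),
    list(geometry = "rectangle", component = 4L, gradient = c(0, 1),
         along = "x",
         x0 = round(width * 0.15), y0 = round(height * 0.30),
         x1 = round(width * 0.85), y1 = round(height * 0.70))
  )
}

#' Draw a Poisson cohort from simulation truth
#'
#' Per pixel `s` and bin `i`, counts are independent
#' `Poisson(sum_k Q_true[s, k] P(i|k))` draws.
#'
#' @param truth an [truth_maps()] result (or S x N matrix of true
#'   quantities).
#' @param model an [lpm_components()] object of source PMFs.
#' @param seed optional integer seed.
#' @return an [lpm_cohort()]; pixel coordinates are carried over when
#'   `truth` provides them.
#' @export
draw_cohort <- function(truth, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- as_lpm_components(model)
  Qt <- if (inherits(truth, "lpm_truth")) truth$true_quantities else as.matrix(truth)
  if (ncol(Qt) != model$order) stop("truth has ", ncol(Qt),
                                    " components but model has ", model$order)
  M <- Qt %*% t(model$pmfs)
  counts <- matrix(stats::rpois(length(M), M), nrow(M), ncol(M))
  coords <- if (inherits(truth, "lpm_truth")) truth$coords else NULL
  lpm_cohort(counts, coords = coords)
}

#' Draw i.i.d. null spectra from a fixed mixture
#'
#' Generates `n` independent spectra whose expectations all follow the same
#' stated mixture of the model's components — the generator behind the
#' null-hypothesis calibration checks, where the quantities of the component
#' under test are zero (or the component is omitted).
#'
#' @param model an [lpm_components()] object.
#' @param quantities either an N-vector used for every spectrum or an
#'   `n x N` matrix of per-spectrum quantities.
#' @param n number of spectra (ignored when `quantities` is a matrix).
#' @param seed optional integer seed.
#' @return an [lpm_cohort()].
#' @export
null_cohort <- function(model, quantities, n = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- as_lpm_components(model)
  if (is.null(dim(quantities))) {
    if (is.null(n)) stop("give n when quantities is a single vector")
    if (n == 0L) return(lpm_cohort(matrix(0, 0L, nrow(model$pmfs))))
    quantities <- matrix(quantities, n, model$order, byrow = TRUE)
  }
  if (nrow(quantities) == 0L)
    return(lpm_cohort(matrix(0, 0L, nrow(model$pmfs))))
  M <- quantities %*% t(model$pmfs)
  lpm_cohort(matrix(stats::rpois(length(M), M), nrow(M), ncol(M)))
}
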