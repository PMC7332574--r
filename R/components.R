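#' Construct a component model
#'
#' A component model is a set of probability mass functions (PMFs), one per
#' component ("tissue spectrum"), stored as the columns of an I bins x N
#' components matrix. Each column must sum to one; columns that have drifted
#' by no more than `tol` are silently renormalized, larger deviations are an
#' error. An optional per-bin model variance (in square-root residual space)
#' carries training error into the local chi-squared statistics.
#'
#' @param pmfs non-negative numeric matrix, I bins x N components.
#' @param component_names optional character vector of N names.
#' @param model_variance optional non-negative I-vector of per-bin model
#'   variance added to the 1/4 sampling variance in square-root space.
#' @param tol maximum tolerated deviation of a column sum from one.
#' @return an object of class `"lpm_components"`.
#' @export
lpm_components <- function(pmfs, component_names = NULL, model_variance = NULL,
                           tol = 1e-9) {
  pmfs <- as.matrix(pmfs)
  storage.mode(pmfs) <- "double"
  if (anyNA(pmfs) || any(pmfs < 0)) stop("pmfs must be non-negative and finite")
  cs <- colSums(pmfs)
  if (any(abs(cs - 1) > tol))
    stop(sprintf("component %d sums to %.12g (deviation > %g)",
                 which.max(abs(cs - 1)), cs[which.max(abs(cs - 1))], tol))
  pmfs <- sweep(pmfs, 2L, cs, "/")
  N <- ncol(pmfs)
  if (is.null(component_names)) {
    component_names <- colnames(pmfs)
    if (is.null(component_names)) component_names <- paste0("C", seq_len(N))
  }
  if (length(component_names) != N) stop("component_names length must equal N")
  colnames(pmfs) <- component_names
  if (!is.null(model_variance)) {
    model_variance <- as.numeric(model_variance)
    if (length(model_variance) != nrow(pmfs) || any(model_variance < 0))
      stop("model_variance must be a non-negative I-vector")
  }
  structure(list(pmfs = pmfs, component_names = component_names,
                 model_variance = model_variance, order = N),
            class = "lpm_components")
}

#' @export
print.lpm_components <- function(x, ...) {
  cat(sprintf("Component model: %d bins x %d components (%s)\n",
              nrow(x$pmfs), x$order,
              paste(utils::head(x$component_names, 6L), collapse = ", ")))
  zeros <- colSums(x$pmfs == 0)
  cat(sprintf("  zero bins per component: %s\n", paste(zeros, collapse = " ")))
  invisible(x)
}

#' @export
dim.lpm_components <- function(x) dim(x$pmfs)

as_lpm_components <- function(x) {
  if (inherits(x, "lpm_components")) return(x)
  if (inherits(x, "lpm")) return(x$components)
  lpm_components(x)
}

#' Read / write a component model
#'
#' Models are stored as tab-separated text: rows are bins, columns are
#' components, the header row carries the component names, and an optional
#' leading `bin` column carries bin labels. Columns are renormalized on read
#' when their sums deviate from one by at most 1e-9; larger drift is a
#' validation error.
#'
#' @param path file path.
#' @return `read_components` returns an [lpm_components()] object;
#'   `write_components` returns `path` invisibly.
#' @export
read_components <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (names(tab)[1L] == "bin") tab <- tab[, -1L, drop = FALSE]
  lpm_components(as.matrix(tab))
}

#' @rdname read_components
#' @param model an [lpm_components()] object (or a fitted [lpm()] model).
#' @export
write_components <- function(model, path) {
  model <- as_lpm_components(model)
  out <- as.data.frame(model$pmfs)
  # 17 significant digits keep the round-trip below 1e-12 absolute
  out[] <- lapply(out, function(v) formatC(v, digits = 17, format = "g"))
  utils::write.table(cbind(bin = seq_len(nrow(model$pmfs)), out), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
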