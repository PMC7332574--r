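#' Construct a histogram cohort
#'
#' A cohort holds the observed counts for a set of spectra (one row per
#' spectrum, one column per histogram bin), optionally with per-spectrum
#' integer pixel coordinates for image layout and a count-scaling factor.
#' All statistics in the package are per-spectrum; coordinates are carried
#' only so that results can be rendered as maps.
#'
#' @param counts numeric matrix, S spectra x I bins, all entries >= 0.
#' @param bin_labels optional vector of I bin labels (e.g. m/z centres).
#'   Numeric labels must be strictly increasing.
#' @param coords optional S x 2 integer matrix (or data.frame) of pixel
#'   coordinates; rows must be unique.
#' @param scale positive scalar: counts-per-raw-unit conversion already
#'   applied to `counts` (1 = native counts).
#' @return an object of class `"lpm_cohort"`.
#' @seealso [read_cohort()], [write_cohort()], [draw_cohort()]
#' @export
lpm_cohort <- function(counts, bin_labels = NULL, coords = NULL, scale = 1) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  dimnames(counts) <- NULL
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at spectrum %d, bin %d", bad[1L], bad[2L]))
  }
  I <- ncol(counts)
  if (is.null(bin_labels)) bin_labels <- seq_len(I)
  if (length(bin_labels) != I) stop("bin_labels length must equal number of bins")
  if (is.numeric(bin_labels) && I > 1L && any(diff(bin_labels) <= 0))
    stop("numeric bin_labels must be strictly increasing")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(counts) || ncol(coords) != 2L)
      stop("coords must be an S x 2 matrix")
    storage.mode(coords) <- "integer"
    if (anyDuplicated(coords)) stop("coords must be unique per spectrum")
    colnames(coords) <- c("x", "y")
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive scalar")
  structure(list(counts = counts, bin_labels = bin_labels,
                 coords = coords, scale = scale),
            class = "lpm_cohort")
}

#' @export
print.lpm_cohort <- function(x, ...) {
  cat(sprintf("Histogram cohort: %d spectra x %d bins\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total counts %.6g, median spectrum total %.6g\n",
              sum(x$counts), stats::median(rowSums(x$counts))))
  if (!is.null(x$coords)) cat("  pixel coordinates present\n")
  if (x$scale != 1) cat(sprintf("  count scale %.6g applied\n", x$scale))
  invisible(x)
}

#' @export
dim.lpm_cohort <- function(x) dim(x$counts)

# coerce matrices/data.frames transparently where a cohort is expected
as_lpm_cohort <- function(x) {
  if (inherits(x, "lpm_cohort")) return(x)
  lpm_cohort(x)
}

#' Read a histogram cohort from a delimited text file
#'
#' The on-disk format is tab-separated: a header row of bin labels, one row
#' per spectrum. Optional leading `x` and `y` columns carry integer pixel
#' coordinates.
#'
#' @param path file path.
#' @return an [lpm_cohort()] object.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  nm <- names(tab)
  coords <- NULL
  if (length(nm) >= 2L && identical(nm[1:2], c("x", "y"))) {
    coords <- as.matrix(tab[, 1:2])
    tab <- tab[, -(1:2), drop = FALSE]
    nm <- nm[-(1:2)]
  }
  counts <- as.matrix(tab)
  if (!is.numeric(counts)) {
    bad <- which(!vapply(tab, is.numeric, logical(1L)))[1L]
    stop(sprintf("non-numeric entries in column %d ('%s') of %s", bad, nm[bad], path))
  }
  labs <- suppressWarnings(as.numeric(nm))
  if (!anyNA(labs)) nm <- labs
  lpm_cohort(counts, bin_labels = nm, coords = coords)
}

#' Write a histogram cohort to a delimited text file
#'
#' @param cohort an [lpm_cohort()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_lpm_cohort(cohort)
  out <- as.data.frame(cohort$counts)
  names(out) <- as.character(cohort$bin_labels)
  if (!is.null(cohort$coords)) out <- cbind(as.data.frame(cohort$coords), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
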