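#' Construct a spectra matrix
#'
#' The central container for binned spectral data: a samples x bins intensity
#' matrix with a ppm axis. Intensities are non-negative arbitrary units; the
#' ppm axis is stored in descending order (NMR convention) but every
#' operation in the package is order-agnostic. A one-way scaling state
#' (raw -> normalized -> centered/pareto) guards against accidentally
#' normalizing or scaling twice.
#'
#' @param intensities Numeric matrix, samples in rows, bins in columns.
#' @param ppm_centers Numeric vector of bin centers (ppm), strictly monotone,
#'   one per column.
#' @param bin_width Bin width in ppm.
#' @param sample_ids Character vector of unique sample ids, one per row.
#' @param scaling_state One of `"raw"`, `"normalized"`, `"centered"`,
#'   `"pareto"`, `"centered_pareto"`.
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(intensities, ppm_centers, bin_width,
                           sample_ids = rownames(intensities),
                           scaling_state = "raw") {
  intensities <- as.matrix(intensities)
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%03d", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  scaling_state <- match.arg(scaling_state,
    c("raw", "normalized", "centered", "pareto", "centered_pareto"))
  if (length(ppm_centers) != ncol(intensities))
    stop("ppm_centers length must equal the number of columns")
  if (length(sample_ids) != nrow(intensities))
    stop("sample_ids length must equal the number of rows")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(intensities)))
    stop("intensities contain non-finite values")
  d <- diff(ppm_centers)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("ppm_centers must be strictly monotone")
  rownames(intensities) <- sample_ids
  colnames(intensities) <- format(ppm_centers, trim = TRUE)
  structure(
    list(intensities = intensities, ppm_centers = as.numeric(ppm_centers),
         bin_width = as.numeric(bin_width), sample_ids = sample_ids,
         scaling_state = scaling_state),
    class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d bins, ppm [%.3f, %.3f], state: %s\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$ppm_centers), max(x$ppm_centers), x$scaling_state))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$intensities)

#' Bin raw ppm-intensity traces onto a common axis
#'
#' Sums the intensities of all trace points falling in each half-open bin
#' `[left, right)`, over the ppm range shared by all traces. Bins that
#' intersect an exclusion interval (e.g. the residual water resonance) are
#' dropped entirely.
#'
#' @param traces Named list of per-sample traces, each a data frame or list
#'   with numeric `ppm` and `intensity` components.
#' @param bin_width Bin width in ppm (default 0.01).
#' @param exclusions List of length-2 numeric vectors giving ppm intervals to
#'   exclude; defaults to the water region (4.5-5.0 ppm) and the TMSP
#'   reference region (-0.05-0.05 ppm).
#' @return A [spectra_matrix()] in `raw` state, ppm axis descending.
#' @export
bin_spectra <- function(traces, bin_width = 0.01,
                        exclusions = list(c(4.5, 5.0), c(-0.05, 0.05))) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!length(traces)) stop("no traces supplied")
  if (is.null(names(traces)))
    names(traces) <- sprintf("s%03d", seq_along(traces))
  for (tr in traces)
    if (any(!is.finite(tr$ppm)) || any(!is.finite(tr$intensity)))
      stop("traces contain non-finite values")
  lo <- max(vapply(traces, function(tr) min(tr$ppm), numeric(1)))
  hi <- min(vapply(traces, function(tr) max(tr$ppm), numeric(1)))
  if (hi <= lo) stop("traces share no overlapping ppm range")
  # bin edges anchored at multiples of bin_width so edges are reproducible
  first_edge <- floor(lo / bin_width) * bin_width
  edges <- seq(first_edge, hi + bin_width, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  keep <- rep(TRUE, length(centers))
  for (ex in exclusions) {
    ex <- sort(as.numeric(ex))
    # drop a bin if [left, right) intersects the closed exclusion interval
    keep <- keep & !(edges[-length(edges)] <= ex[2] & edges[-1] > ex[1])
  }
  mat <- t(vapply(traces, function(tr) {
    idx <- findInterval(tr$ppm, edges, left.open = FALSE, rightmost.closed = FALSE)
    inside <- idx >= 1 & idx <= length(centers)
    as.numeric(tapply(tr$intensity[inside],
                      factor(idx[inside], levels = seq_along(centers)),
                      sum, default = 0))
  }, numeric(length(centers))))
  ord <- order(centers[keep], decreasing = TRUE)
  spectra_matrix(mat[, keep, drop = FALSE][, ord, drop = FALSE],
                 ppm_centers = centers[keep][ord], bin_width = bin_width,
                 sample_ids = names(traces))
}

#' Total-area normalization
#'
#' Divides each spectrum by its summed intensity so that every row sums to 1,
#' removing sample-size (cell number, dilution) differences while preserving
#' relative bin proportions within each sample.
#'
#' @param m A [spectra_matrix()] in `raw` or `normalized` state.
#' @return The normalized `spectra_matrix` (state `normalized`). Idempotent.
#' @export
normalize_total_area <- function(m) {
  stopifnot(inherits(m, "spectra_matrix"))
  if (!m$scaling_state %in% c("raw", "normalized"))
    stop("cannot normalize data in state '", m$scaling_state, "'")
  sums <- rowSums(m$intensities)
  if (any(sums <= 0))
    stop("zero or negative total area for sample(s): ",
         paste(m$sample_ids[sums <= 0], collapse = ", "))
  m$intensities <- m$intensities / sums
  m$scaling_state <- "normalized"
  m
}

#' Column scaling for multivariate modeling
#'
#' Mean-centering and/or Pareto scaling of the bin columns. Pareto scaling
#' divides each column by the square root of its standard deviation
#' (denominator n-1), damping -- but not flattening -- the dynamic range
#' between strong and weak spectral regions. Columns with zero standard
#' deviation are left unscaled and reported in the `constant_bins` attribute.
#'
#' @param m A [spectra_matrix()] not yet centered or scaled.
#' @param method `"center"`, `"pareto"`, or `"center_pareto"`.
#' @return The scaled `spectra_matrix`; attribute `constant_bins` lists the
#'   indices of zero-variance columns.
#' @export
scale_spectra <- function(m, method = c("center_pareto", "center", "pareto")) {
  stopifnot(inherits(m, "spectra_matrix"))
  method <- match.arg(method)
  if (!m$scaling_state %in% c("raw", "normalized"))
    stop("data already scaled (state '", m$scaling_state, "')")
  if (nrow(m$intensities) < 2) stop("scaling requires n_samples >= 2")
  x <- m$intensities
  if (method %in% c("center", "center_pareto"))
    x <- sweep(x, 2, colMeans(x), "-")
  if (method %in% c("pareto", "center_pareto")) {
    sds <- apply(m$intensities, 2, stats::sd)
    constant <- unname(which(sds == 0))
    fac <- sqrt(sds)
    fac[fac == 0] <- 1
    x <- sweep(x, 2, fac, "/")
  } else {
    constant <- unname(which(apply(m$intensities, 2, stats::sd) == 0))
  }
  m$intensities <- x
  m$scaling_state <- switch(method, center = "centered", pareto = "pareto",
                            center_pareto = "centered_pareto")
  attr(m, "constant_bins") <- constant
  m
}

#' Write / read a spectra matrix as TSV
#'
#' Plain-text interchange format: first column `sample_id`, remaining columns
#' headed by their bin ppm centers.
#'
#' @param m A [spectra_matrix()].
#' @param path Output file path.
#' @export
write_spectra_tsv <- function(m, path) {
  stopifnot(inherits(m, "spectra_matrix"))
  df <- data.frame(sample_id = m$sample_ids, m$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", format(m$ppm_centers, trim = TRUE, digits = 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_tsv
#' @param bin_width Bin width to record on the read object (not stored in the
#'   TSV; inferred from the axis when `NULL`).
#' @export
read_spectra_tsv <- function(path, bin_width = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ppm <- as.numeric(colnames(df)[-1])
  if (is.null(bin_width))
    bin_width <- if (length(ppm) > 1) stats::median(abs(diff(ppm))) else 0.01
  spectra_matrix(as.matrix(df[, -1, drop = FALSE]), ppm_centers = ppm,
                 bin_width = bin_width, sample_ids = df$sample_id)
}

#' Write / read a sample design as TSV
#'
#' Three columns: `sample_id`, `compound`, `dose_label`.
#'
#' @param design A [sample_design()].
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design[, c("sample_id", "compound", "dose_label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sample_design(df$sample_id, df$compound, df$dose_label)
}
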