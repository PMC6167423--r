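## Metabolic fingerprints: discriminant-bin selection, chemical-shift
## annotation, and table aggregation across comparisons.

#' Read a chemical-shift table
#'
#' Reads a TSV with one row per metabolite: a `metabolite` column, a
#' `shifts` column of semicolon-separated `ppm(multiplicity)` entries, and
#' any number of additional per-comparison flag columns (`x` = discriminant).
#' Three such tables are shipped with the package, transcribing the
#' published assignments for a BPA dose series, an E2 dose series, and the
#' joint two-compound comparison.
#'
#' @param path Path to a shift-table TSV, or one of the shorthand names
#'   `"bpa"`, `"e2"`, `"combined"` for the packaged tables.
#' @return Object of class `shift_table`: `metabolites` (data frame with
#'   flag columns), `shifts` (long data frame: metabolite, ppm,
#'   multiplicity).
#' @export
read_shift_table <- function(path) {
  if (path %in% c("bpa", "e2", "combined"))
    path <- system.file("extdata", paste0("shift_table_", path, ".tsv"),
                        package = "fingernet")
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", fill = TRUE)
  stopifnot(all(c("metabolite", "shifts") %in% names(df)))
  if (anyDuplicated(df$metabolite))
    stop("duplicate metabolite names in shift table")
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    parts <- trimws(strsplit(df$shifts[i], ";")[[1]])
    ppm <- as.numeric(sub("^([0-9.]+).*$", "\\1", parts))
    mult <- ifelse(grepl("\\(", parts),
                   sub("^[0-9.]+\\(([^,)]+).*$", "\\1", parts), "")
    data.frame(metabolite = df$metabolite[i], ppm = ppm, multiplicity = mult,
               stringsAsFactors = FALSE)
  }))
  if (any(!is.finite(long$ppm)) || any(long$ppm < -0.5) || any(long$ppm > 10))
    stop("shift table contains ppm values outside [-0.5, 10]")
  structure(list(metabolites = df, shifts = long), class = "shift_table")
}

#' Select discriminant bins
#'
#' The two-criterion rule for calling a spectral variable discriminant: its
#' VIP score must exceed `vip_threshold` (influence on the class separation)
#' and its Kruskal-Wallis p-value across the comparison's groups must fall
#' below `alpha` (univariate confirmation). Both statistics are recorded for
#' every selected bin.
#'
#' @param vip A [vip_scores()] result fitted on the same columns as `X`.
#' @param X The [spectra_matrix()] (or matrix) the model was fitted on.
#' @param design A [sample_design()] restricted to the comparison's groups.
#' @param vip_threshold VIP cut-off (default 1.5).
#' @param alpha Kruskal-Wallis significance level (default 0.05, raw).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()]
#'   (e.g. `"BH"`) applied to the Kruskal-Wallis p-values before
#'   thresholding.
#' @return Data frame with one row per *selected* bin: `bin` (column
#'   index), `ppm` (when available), `vip`, `p_kw`; attributes
#'   `vip_threshold` and `alpha` record the thresholds used.
#' @export
select_discriminant_bins <- function(vip, X, design, vip_threshold = 1.5,
                                     alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(vip, "vip_result"))
  ppm <- if (inherits(X, "spectra_matrix")) X$ppm_centers else NULL
  Xm <- as_X(X)
  if (length(vip$vip) != ncol(Xm))
    stop("VIP length (", length(vip$vip), ") does not match number of bins (",
         ncol(Xm), ")")
  if (nrow(Xm) != nrow(design)) stop("X rows and design rows differ")
  p_kw <- apply(Xm, 2, function(v) kruskal_wallis(v, design)$p)
  p_use <- stats::p.adjust(p_kw, method = p_adjust)
  sel <- which(vip$vip > vip_threshold & p_use < alpha)
  out <- data.frame(bin = sel,
                    ppm = if (is.null(ppm)) NA_real_ else ppm[sel],
                    vip = vip$vip[sel], p_kw = p_kw[sel])
  attr(out, "vip_threshold") <- vip_threshold
  attr(out, "alpha") <- alpha
  out
}

#' Annotate selected bins with metabolite assignments
#'
#' Assigns each discriminant bin the metabolite owning the nearest tabulated
#' chemical shift within `tol_ppm`. Ties are broken by smallest absolute ppm
#' distance, then alphabetically by metabolite name. Bins with no tabulated
#' shift nearby are retained as `"unassigned"`. A pure function of its
#' inputs.
#'
#' @param bins Data frame from [select_discriminant_bins()] (needs `ppm`,
#'   `vip`, `p_kw`).
#' @param table A [read_shift_table()] object.
#' @param tol_ppm Maximum assignment distance in ppm (default 0.02).
#' @param comparison_id Label for the comparison (e.g.
#'   `"BPA_1e-6M_vs_control"`).
#' @return Object of class `fingerprint`: `comparison_id` and `entries`
#'   (data frame bin_ppm, metabolite, vip, p_kw).
#' @export
annotate_bins <- function(bins, table, tol_ppm = 0.02,
                          comparison_id = "comparison") {
  stopifnot(inherits(table, "shift_table"))
  if (!nrow(table$shifts)) stop("empty shift table")
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  assign_one <- function(p) {
    d <- abs(table$shifts$ppm - p)
    ok <- which(d <= tol_ppm)
    if (!length(ok)) return("unassigned")
    ok <- ok[order(d[ok], table$shifts$metabolite[ok])]
    table$shifts$metabolite[ok[1]]
  }
  entries <- data.frame(
    bin_ppm = bins$ppm,
    metabolite = vapply(bins$ppm, assign_one, character(1)),
    vip = bins$vip, p_kw = bins$p_kw, stringsAsFactors = FALSE)
  structure(list(comparison_id = comparison_id, entries = entries,
                 vip_threshold = attr(bins, "vip_threshold"),
                 alpha = attr(bins, "alpha")),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s: %d bins, %d assigned metabolites\n",
              x$comparison_id, nrow(x$entries),
              length(setdiff(unique(x$entries$metabolite), "unassigned"))))
  invisible(x)
}

#' Metabolite names of a fingerprint
#'
#' @param fp A `fingerprint`.
#' @return Sorted character vector of assigned metabolite names (the
#'   `"unassigned"` placeholder excluded).
#' @export
fingerprint_metabolites <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  sort(setdiff(unique(fp$entries$metabolite), "unassigned"))
}

#' Aggregate fingerprints into a metabolite x comparison table
#'
#' The union of assigned metabolites forms the rows; each comparison
#' contributes a logical flag column. This is the layout of published
#' discriminant-metabolite tables, and the unique-metabolite count is the
#' headline number of such a table.
#'
#' @param fps List of `fingerprint` objects.
#' @return Object of class `fingerprint_table`: `flags` (logical data frame,
#'   metabolite rows x comparison columns) and `n_metabolites`.
#' @export
aggregate_fingerprints <- function(fps) {
  if (!length(fps)) stop("need >= 1 fingerprint")
  stopifnot(all(vapply(fps, inherits, logical(1), "fingerprint")))
  mets <- sort(unique(unlist(lapply(fps, fingerprint_metabolites))))
  flags <- vapply(fps, function(fp) mets %in% fingerprint_metabolites(fp),
                  logical(length(mets)))
  flags <- as.data.frame(matrix(flags, nrow = length(mets)),
                         row.names = mets)
  colnames(flags) <- vapply(fps, `[[`, character(1), "comparison_id")
  structure(list(flags = flags, n_metabolites = length(mets)),
            class = "fingerprint_table")
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat(sprintf("<fingerprint_table> %d metabolites x %d comparisons\n",
              x$n_metabolites, ncol(x$flags)))
  invisible(x)
}

#' Build fingerprints from a shift table's flag columns
#'
#' Turns the per-comparison flag columns of a packaged shift table directly
#' into `fingerprint` objects (one per flag column), bypassing the
#' statistical selection -- useful to work with published
#' discriminant-metabolite tables as data.
#'
#' @param table A [read_shift_table()] whose `metabolites` data frame has
#'   flag columns besides `metabolite` and `shifts` (`x` = discriminant).
#' @return List of `fingerprint` objects named by flag column.
#' @export
fingerprints_from_flags <- function(table) {
  stopifnot(inherits(table, "shift_table"))
  flag_cols <- setdiff(names(table$metabolites), c("metabolite", "shifts"))
  if (!length(flag_cols)) stop("shift table has no flag columns")
  out <- lapply(flag_cols, function(cn) {
    col <- table$metabolites[[cn]]
    mets <- table$metabolites$metabolite[!is.na(col) & trimws(col) == "x"]
    first_ppm <- vapply(mets, function(m)
      table$shifts$ppm[table$shifts$metabolite == m][1], numeric(1))
    structure(list(comparison_id = cn,
                   entries = data.frame(bin_ppm = first_ppm, metabolite = mets,
                                        vip = NA_real_, p_kw = NA_real_,
                                        stringsAsFactors = FALSE),
                   vip_threshold = NA_real_, alpha = NA_real_),
              class = "fingerprint")
  })
  names(out) <- flag_cols
  out
}

#' Export a fingerprint table as TSV
#'
#' @param ft A `fingerprint_table`.
#' @param path Output path.
#' @export
write_fingerprint_table <- function(ft, path) {
  stopifnot(inherits(ft, "fingerprint_table"))
  df <- data.frame(metabolite = rownames(ft$flags),
                   ifelse(as.matrix(ft$flags), "x", ""),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
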