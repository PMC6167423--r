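#' Build a sample design table
#'
#' A sample design describes the group structure of a spectral data set: one
#' row per sample, each sample belonging to exactly one treatment group
#' (compound x dose), with exactly one group flagged as the vehicle control.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param compound Character vector, the compound each sample was exposed to
#'   (the control group typically carries the vehicle name, e.g. `"DMSO"`).
#' @param dose_label Character vector of dose labels; the control group must
#'   use `"control"`.
#' @return A `data.frame` of class `sample_design` with columns `sample_id`,
#'   `compound`, `dose_label`, `group` (compound and dose pasted together;
#'   `"control"` for the control group) and `group_index` (control first).
#' @examples
#' d <- sample_design(
#'   sample_id  = sprintf("s%02d", 1:6),
#'   compound   = rep(c("DMSO", "BPA"), each = 3),
#'   dose_label = rep(c("control", "1e-6M"), each = 3)
#' )
#' table(d$group)
#' @export
sample_design <- function(sample_id, compound, dose_label) {
  sample_id <- as.character(sample_id)
  compound <- as.character(compound)
  dose_label <- as.character(dose_label)
  n <- length(sample_id)
  if (length(compound) != n || length(dose_label) != n)
    stop("sample_id, compound and dose_label must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  group <- ifelse(dose_label == "control", "control",
                  paste(compound, dose_label, sep = "_"))
  if (!any(group == "control"))
    stop("no control group: exactly one group must have dose_label 'control'")
  sizes <- table(group)
  if (any(sizes < 2))
    stop("group sizes must be >= 2; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  levels <- c("control", sort(setdiff(unique(group), "control")))
  out <- data.frame(
    sample_id = sample_id,
    compound = compound,
    dose_label = dose_label,
    group = group,
    group_index = match(group, levels),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_design", "data.frame")
  out
}

#' Default multi-dose exposure design
#'
#' One vehicle control group of 17 samples plus three dose groups of 12
#' samples each for a single compound, mirroring a typical dose-range
#' in-vitro exposure study design.
#'
#' @param compound Compound name for the dose groups.
#' @param doses Character vector of three dose labels, high to low.
#' @param n_control,n_dose Group sizes.
#' @param control_compound Name of the vehicle used for controls.
#' @return A [sample_design()] table.
#' @export
default_design <- function(compound = "BPA",
                           doses = c("1e-6M", "1e-9M", "1e-12M"),
                           n_control = 17, n_dose = 12,
                           control_compound = "DMSO") {
  compound_col <- c(rep(control_compound, n_control),
                    rep(compound, n_dose * length(doses)))
  dose_col <- c(rep("control", n_control), rep(doses, each = n_dose))
  sample_design(
    sample_id = sprintf("%s_%03d", tolower(compound), seq_along(compound_col)),
    compound = compound_col,
    dose_label = dose_col
  )
}

#' Two-compound exposure design
#'
#' A shared control group plus three dose groups per compound, the layout of
#' a joint multi-compound comparison model.
#'
#' @param compounds Character vector of two compound names.
#' @param doses_list List of dose-label vectors, one per compound.
#' @inheritParams default_design
#' @return A [sample_design()] table with `1 + 3 * length(compounds)` groups.
#' @export
two_compound_design <- function(compounds = c("BPA", "E2"),
                                doses_list = list(
                                  c("1e-6M", "1e-9M", "1e-12M"),
                                  c("1e-9M", "1e-12M", "1e-15M")),
                                n_control = 17, n_dose = 12,
                                control_compound = "DMSO") {
  stopifnot(length(compounds) == length(doses_list))
  compound_col <- rep(control_compound, n_control)
  dose_col <- rep("control", n_control)
  for (i in seq_along(compounds)) {
    compound_col <- c(compound_col, rep(compounds[i], n_dose * length(doses_list[[i]])))
    dose_col <- c(dose_col, rep(doses_list[[i]], each = n_dose))
  }
  sample_design(
    sample_id = sprintf("smp_%03d", seq_along(compound_col)),
    compound = compound_col,
    dose_label = dose_col
  )
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
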