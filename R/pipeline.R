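## End-to-end orchestration: config -> spectra -> chemometrics ->
## fingerprints -> sub-networks, with fixed seeds throughout.

#' Build planted signatures from a shift table
#'
#' Turns the flag columns of a shift table into [signature_spec()] objects:
#' each flagged metabolite gets its tabulated chemical shifts as signal bins
#' and the given effect size in every group whose flag column marks it.
#' Effect direction alternates by metabolite order -- published tables
#' report which metabolites discriminate, not the sign, so the simulation
#' assigns directions arbitrarily and nothing downstream may assert them.
#'
#' @param table A [read_shift_table()] with flag columns named after groups.
#' @param effect Effect size in units of the noise SD (default 1.5).
#' @return List of [signature_spec()] objects.
#' @export
signatures_from_shift_table <- function(table, effect = 1.5) {
  stopifnot(inherits(table, "shift_table"))
  flag_cols <- setdiff(names(table$metabolites), c("metabolite", "shifts"))
  mets <- table$metabolites$metabolite
  lapply(seq_along(mets), function(i) {
    flags <- vapply(flag_cols, function(cn) {
      v <- table$metabolites[[cn]][i]
      !is.na(v) && trimws(v) == "x"
    }, logical(1))
    eff <- stats::setNames(ifelse(flags, effect, 0), flag_cols)
    signature_spec(mets[i],
                   bin_ppms = table$shifts$ppm[table$shifts$metabolite == mets[i]],
                   effect_by_group = c(eff, control = 0),
                   direction = if (i %% 2) 1 else -1)
  })
}

#' Read and validate a pipeline configuration
#'
#' The configuration is one YAML file. All validation errors are collected
#' and reported together, not one at a time.
#'
#' @param path Path to a YAML config (or an already-parsed list).
#' @return The validated config list (invisibly errors otherwise).
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  errs <- character(0)
  want <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)

  ch <- cfg$chemometrics
  if (is.null(ch)) ch <- list()
  folds <- ch$folds %||% 7
  n_perm <- ch$n_perm %||% 200
  vip_threshold <- ch$vip_threshold %||% 1.5
  alpha <- ch$alpha %||% 0.05
  n_osc <- ch$n_osc %||% 1
  want(is.numeric(folds) && folds >= 2, "chemometrics.folds must be >= 2")
  want(is.numeric(n_perm) && n_perm >= 1, "chemometrics.n_perm must be >= 1")
  want(is.numeric(vip_threshold) && vip_threshold > 0,
       "chemometrics.vip_threshold must be > 0")
  want(is.numeric(alpha) && alpha > 0 && alpha < 1,
       "chemometrics.alpha must be in (0, 1)")
  want(is.numeric(n_osc) && n_osc >= 1, "chemometrics.n_osc must be >= 1")

  has_synth <- !is.null(cfg$synth)
  has_files <- !is.null(cfg$inputs$spectra_tsv) && !is.null(cfg$inputs$design_tsv)
  want(has_synth || has_files,
       "either a synth block or inputs.spectra_tsv + inputs.design_tsv is required")

  groups <- NULL
  if (has_synth) {
    want(!is.null(cfg$synth$shift_table),
         "synth.shift_table is required (path or bpa/e2/combined)")
    if (!is.null(cfg$synth$shift_table)) {
      tbl <- tryCatch(read_shift_table(cfg$synth$shift_table),
                      error = function(e) NULL)
      if (is.null(tbl)) want(FALSE, "synth.shift_table cannot be read")
      else groups <- c("control",
                       setdiff(names(tbl$metabolites), c("metabolite", "shifts")))
    }
  } else if (has_files && file.exists(cfg$inputs$design_tsv %||% "")) {
    groups <- unique(read_design_tsv(cfg$inputs$design_tsv)$group)
  }
  for (cmp in cfg$comparisons) {
    want(!is.null(cmp$name), "every comparison needs a name")
    want(length(cmp$groups) >= 2, "every comparison needs >= 2 groups")
    if (!is.null(groups)) {
      bad <- setdiff(cmp$groups, groups)
      want(length(bad) == 0,
           paste0("comparison '", cmp$name %||% "?",
                  "' references unknown group(s): ", paste(bad, collapse = ", ")))
    }
  }
  if (length(errs))
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$chemometrics <- list(folds = folds, n_perm = n_perm,
                           vip_threshold = vip_threshold, alpha = alpha,
                           n_osc = n_osc)
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' From a validated config: (1) obtain spectra -- simulated from a shift
#' table's planted signatures or read from TSV; (2) total-area normalize,
#' mean-center and Pareto scale; (3) PCA screening for outliers; (4) per
#' comparison: OSC filtering, PLS-DA with cross-validation-chosen component
#' count, permutation validation, VIP, discriminant-bin selection and
#' chemical-shift annotation into a fingerprint; (5) map fingerprints onto
#' the (compartment-collapsed) metabolic network and extract lightest-path
#' sub-networks; (6) set algebra on configured sub-network pairs. All
#' randomness is derived from the single `seed`, so identical config + seed
#' reproduces identical numbers.
#'
#' @param config Path to a YAML config or a config list (validated either
#'   way).
#' @param out_dir Output directory (created); `NULL` skips file output.
#' @param seed Master seed.
#' @return A run report list: `design`, `models` (per comparison: A, r2y,
#'   q2, permutation p, fingerprint), `subnetworks`, `pair_subnetworks`,
#'   `pca`, `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1) {
  cfg <- validate_config(config)
  ch <- cfg$chemometrics
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  ## -- stage 1: data ---------------------------------------------------------
  if (!is.null(cfg$synth)) {
    s <- cfg$synth
    tbl <- read_shift_table(s$shift_table)
    flag_cols <- setdiff(names(tbl$metabolites), c("metabolite", "shifts"))
    # derive compound/dose structure from the flag column names
    parts <- strsplit(flag_cols, "_")
    compounds <- vapply(parts, `[[`, character(1), 1)
    doses <- vapply(parts, function(p) paste(p[-1], collapse = "_"), character(1))
    design <- sample_design(
      sample_id = sprintf("smp_%03d",
                          seq_len((s$n_control %||% 17) +
                                    (s$n_dose %||% 12) * length(flag_cols))),
      compound = c(rep("DMSO", s$n_control %||% 17),
                   rep(compounds, each = s$n_dose %||% 12)),
      dose_label = c(rep("control", s$n_control %||% 17),
                     rep(doses, each = s$n_dose %||% 12)))
    sigs <- signatures_from_shift_table(tbl, effect = s$effect %||% 1.5)
    spectra <- simulate_spectra(design, sigs,
                                n_bins = s$n_bins %||% 200,
                                ppm_range = c(0.4, 9.6),
                                noise_sd = s$noise_sd %||% 1,
                                confounder_sd = s$confounder_sd %||% 0,
                                seed = seed + 101)
  } else {
    spectra <- read_spectra_tsv(cfg$inputs$spectra_tsv)
    design <- read_design_tsv(cfg$inputs$design_tsv)
    tbl <- read_shift_table(cfg$inputs$shift_table %||% "combined")
  }

  ## -- stage 2: preprocessing ------------------------------------------------
  spectra <- normalize_total_area(spectra)
  scaled <- scale_spectra(spectra, "center_pareto")

  ## -- stage 3: PCA screening ------------------------------------------------
  pca <- pca_screen(scaled, n_components = 2,
                    alpha = cfg$preprocess$pca_alpha %||% 0.05)

  ## -- stage 4: per-comparison chemometrics ----------------------------------
  comparisons <- cfg$comparisons
  if (is.null(comparisons))
    comparisons <- list(list(name = "all_groups",
                             groups = sort(unique(design$group))))
  models <- list()
  fingerprints <- list()
  for (cmp in comparisons) {
    rows <- design$group %in% cmp$groups
    sub_design <- design[rows, , drop = FALSE]
    x <- as_X(scaled)[rows, , drop = FALSE]
    x <- sweep(x, 2, colMeans(x))
    osc <- osc_filter(x, sub_design, n_osc = ch$n_osc)
    xf <- osc$filtered_X
    sel <- select_components(xf, sub_design, folds = ch$folds,
                             seed = seed + 211,
                             max_A = cfg$chemometrics$max_A %||% 10)
    fit <- fit_plsda(xf, sub_design, A = sel$A)
    perm <- permutation_test(xf, sub_design, A = sel$A, folds = ch$folds,
                             n_perm = ch$n_perm, seed = seed + 307)
    vip <- vip_scores(fit)
    # univariate confirmation runs on the *unfiltered* (pre-OSC) data: OSC
    # removes within-group variance only, which would inflate rank-test
    # significance across the board
    spectra_sub <- scaled
    spectra_sub$intensities <- x
    spectra_sub$sample_ids <- sub_design$sample_id
    bins <- select_discriminant_bins(vip, spectra_sub, sub_design,
                                     vip_threshold = ch$vip_threshold,
                                     alpha = ch$alpha)
    fp <- annotate_bins(bins, tbl, tol_ppm = cfg$fingerprint$tol_ppm %||% 0.02,
                        comparison_id = cmp$name)
    models[[cmp$name]] <- list(A = sel$A, r2y = fit$r2y,
                               q2 = sel$q2_per_component[sel$A],
                               permutation_p = perm$empirical_p_q2,
                               variance_removed_osc = osc$variance_removed,
                               n_selected_bins = nrow(bins),
                               fit = fit)
    fingerprints[[cmp$name]] <- fp
  }

  ## -- stage 5: network ------------------------------------------------------
  subnetworks <- list()
  pair_subnetworks <- list()
  graph <- NULL
  if (!is.null(cfg$network)) {
    nc <- cfg$network
    net <- if (!is.null(nc$sbml)) read_sbml(nc$sbml)
    else generate_toy_network(nc$toy_n_metabolites %||% 30,
                              nc$toy_n_reactions %||% 45,
                              n_compartments = nc$toy_n_compartments %||% 2,
                              hub_degree = nc$toy_hub_degree %||% 10,
                              seed = seed + 401)
    net1 <- merge_compartments(net)
    side <- if (!is.null(nc$side_compounds_tsv))
      utils::read.table(nc$side_compounds_tsv, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)$id
    else character(0)
    graph <- build_compound_graph(net1, side_compounds = side,
                                  weight_scheme = nc$weight_scheme %||%
                                    "degree_squared")
    mapping <- if (!is.null(nc$mapping_tsv))
      utils::read.table(nc$mapping_tsv, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    else {
      # deterministic synthetic mapping: table metabolites, alphabetically,
      # onto network metabolites
      graph_mets <- sort(igraph::V(graph)$name[
        igraph::V(graph)$type == "metabolite"])
      tbl_mets <- sort(tbl$metabolites$metabolite)
      data.frame(name = tbl_mets,
                 network_id = graph_mets[
                   (seq_along(tbl_mets) - 1) %% length(graph_mets) + 1],
                 stringsAsFactors = FALSE)
    }
    for (nm in names(fingerprints)) {
      mapped <- map_fingerprint_to_network(
        fingerprint_metabolites(fingerprints[[nm]]), mapping)
      subnetworks[[nm]] <- if (length(mapped$seed_ids) >= 2)
        extract_subnetwork(graph, mapped$seed_ids)
      else structure(list(metabolites = character(0), reactions = character(0),
                          seeds = mapped$seed_ids,
                          unmapped_seeds = mapped$unmapped,
                          provenance = list(), unreachable_pairs = list(),
                          parent_id = igraph::graph_attr(graph, "parent_id")),
                     class = "subnetwork")
    }
    for (pair in cfg$network$pairs) {
      a <- subnetworks[[pair$a]]; b <- subnetworks[[pair$b]]
      if (is.null(a) || is.null(b)) next
      nm <- paste(pair$a, pair$b, sep = "_vs_")
      pair_subnetworks[[paste0("common_", nm)]] <-
        subnetwork_algebra(a, b, "intersect")
      pair_subnetworks[[paste0("specific_", nm)]] <-
        subnetwork_algebra(a, b, "difference")
    }
  }

  report <- list(design = design, pca = pca, models = models,
                 fingerprints = fingerprints, subnetworks = subnetworks,
                 pair_subnetworks = pair_subnetworks, seed = seed)

  ## -- stage 6: outputs ------------------------------------------------------
  if (!is.null(out_dir)) {
    summaries <- lapply(models, function(m)
      m[c("A", "r2y", "q2", "permutation_p", "n_selected_bins")])
    jsonlite::write_json(list(seed = seed, models = summaries),
                         file.path(out_dir, "model_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(models)) {
      utils::write.table(
        data.frame(sample_id = models[[nm]]$fit$design$sample_id,
                   group = models[[nm]]$fit$design$group,
                   models[[nm]]$fit$T),
        file.path(out_dir, paste0("scores_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        fingerprints[[nm]]$entries,
        file.path(out_dir, paste0("fingerprint_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(fingerprints))
      write_fingerprint_table(aggregate_fingerprints(unname(fingerprints)),
                              file.path(out_dir, "fingerprint_table.tsv"))
    for (nm in names(subnetworks))
      if (length(subnetworks[[nm]]$metabolites))
        export_subnetwork(subnetworks[[nm]], graph,
                          file.path(out_dir, paste0("subnetwork_", nm, ".sif")),
                          format = "sif")
    for (nm in names(pair_subnetworks))
      if (length(pair_subnetworks[[nm]]$metabolites))
        export_subnetwork(pair_subnetworks[[nm]], graph,
                          file.path(out_dir, paste0(nm, ".sif")),
                          format = "sif")
  }
  report
}

#' Path to the packaged demo configuration
#'
#' A small synthetic two-compound study (shared control, three doses per
#' compound, planted signatures from the combined shift table, a structured
#' confounder) analysed against a toy two-compartment network.
#'
#' @return File path of the YAML config.
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "fingernet")
}
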