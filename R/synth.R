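#' Define a planted metabolite signature
#'
#' A signature places a metabolite's multi-bin pattern on the simulated ppm
#' axis and states, per exposure group, how strongly the metabolite responds
#' (in units of the additive noise SD). The control group always has effect
#' zero. Effect direction (increase vs decrease) is a free choice of the
#' simulation: real exposure studies report which metabolites discriminate,
#' not necessarily the sign, so no downstream code may rely on direction.
#'
#' @param metabolite Metabolite name.
#' @param bin_ppms Numeric vector of ppm centers carrying the signal.
#' @param effect_by_group Named numeric vector mapping group labels to signed
#'   effect sizes in units of the noise SD; the control group, if present,
#'   must map to 0.
#' @param direction Sign (+1/-1) per bin; recycled. Defaults to +1.
#' @return An object of class `signature_spec`.
#' @export
signature_spec <- function(metabolite, bin_ppms, effect_by_group,
                           direction = 1) {
  if (is.null(names(effect_by_group)))
    stop("effect_by_group must be a named vector (group -> effect)")
  if ("control" %in% names(effect_by_group) &&
      effect_by_group[["control"]] != 0)
    stop("control group effect must be 0")
  direction <- rep_len(sign(direction), length(bin_ppms))
  if (any(direction == 0)) stop("direction must be +1 or -1")
  structure(list(metabolite = metabolite, bin_ppms = as.numeric(bin_ppms),
                 effect_by_group = effect_by_group, direction = direction),
            class = "signature_spec")
}

#' Simulate binned NMR spectra with planted structure
#'
#' Generates a samples x bins intensity matrix with the statistical structure
#' the downstream analysis assumes: a smooth positive baseline, additive
#' Gaussian noise, per-group effects planted on the signature bins (scaled in
#' units of the noise SD), a multiplicative per-sample size factor
#' (lognormal, sd 0.05 on the log scale) that motivates total-area
#' normalization, and one structured rank-one confounder whose sample scores
#' are drawn independently of group labels -- exactly the kind of variation
#' orthogonal signal correction is designed to remove.
#'
#' The assembled matrix is shifted by a single global offset when needed so
#' all intensities are non-negative; a common offset leaves group contrasts
#' untouched.
#'
#' @param design A [sample_design()].
#' @param signatures List of [signature_spec()] objects (may be empty).
#' @param n_bins Number of bins on the simulated axis.
#' @param ppm_range Length-2 numeric, ppm span of the axis.
#' @param noise_sd Additive noise standard deviation (intensity units).
#' @param confounder_sd Standard deviation of the confounder scores
#'   (intensity units; the loading vector has unit norm). 0 disables it.
#' @param size_factor_sd SD (log scale) of the per-sample multiplicative
#'   size factor applied to the baseline (default 0.05). 0 disables it,
#'   leaving the pure additive-noise model.
#' @param seed Integer seed; the same call with the same seed returns a
#'   bitwise-identical matrix.
#' @return A [spectra_matrix()] in `raw` state. Attribute `planted` records
#'   the truth: signature bin indices per metabolite, the confounder scores
#'   and loading, and the confounder's share of centered total variance.
#' @export
simulate_spectra <- function(design, signatures = list(), n_bins = 200,
                             ppm_range = c(0.5, 9.5), noise_sd = 1,
                             confounder_sd = 0, size_factor_sd = 0.05,
                             seed = 1) {
  stopifnot(inherits(design, "sample_design"))
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  all_ppms <- unlist(lapply(signatures, `[[`, "bin_ppms"))
  if (n_bins < length(unique(all_ppms)))
    stop("n_bins must be >= number of distinct signature bins")
  if (length(all_ppms) &&
      (min(all_ppms) < min(ppm_range) || max(all_ppms) > max(ppm_range)))
    stop("signature ppm outside the simulated axis [",
         min(ppm_range), ", ", max(ppm_range), "]")
  n <- nrow(design)
  ppm <- seq(max(ppm_range), min(ppm_range), length.out = n_bins)
  bin_width <- if (n_bins > 1) abs(ppm[1] - ppm[2]) else diff(range(ppm_range))

  with_local_seed(seed, {
    baseline <- noise_sd * stats::runif(n_bins, 5, 15)
    size_factor <- if (size_factor_sd > 0) stats::rlnorm(n, 0, size_factor_sd)
    else rep(1, n)
    x <- outer(size_factor, baseline)

    sig_bins <- list()
    for (sg in signatures) {
      idx <- vapply(sg$bin_ppms, function(p) which.min(abs(ppm - p)), integer(1))
      sig_bins[[sg$metabolite]] <- sort(unique(c(sig_bins[[sg$metabolite]], idx)))
      for (g in names(sg$effect_by_group)) {
        rows <- which(design$group == g)
        if (!length(rows)) next
        shift <- sg$effect_by_group[[g]] * noise_sd * sg$direction
        x[rows, idx] <- x[rows, idx] +
          matrix(shift, nrow = length(rows), ncol = length(idx), byrow = TRUE)
      }
    }

    conf_scores <- rep(0, n)
    conf_loading <- rep(0, n_bins)
    if (confounder_sd > 0) {
      conf_loading <- stats::rnorm(n_bins)
      conf_loading <- conf_loading / sqrt(sum(conf_loading^2))
      conf_scores <- stats::rnorm(n, 0, confounder_sd)
      x <- x + conf_scores %o% conf_loading
    }
    x <- x + matrix(stats::rnorm(n * n_bins, 0, noise_sd), n, n_bins)
    if (min(x) < 0) x <- x - min(x)

    xc <- sweep(x, 2, colMeans(x))
    conf_share <- if (confounder_sd > 0)
      sum((scale(conf_scores, scale = FALSE) %o% conf_loading)^2) / sum(xc^2)
    else 0

    out <- spectra_matrix(x, ppm_centers = ppm, bin_width = bin_width,
                          sample_ids = design$sample_id)
    attr(out, "planted") <- list(signature_bins = sig_bins,
                                 confounder_scores = conf_scores,
                                 confounder_loading = conf_loading,
                                 confounder_variance_share = conf_share)
    out
  })
}

#' Generate a toy metabolic network
#'
#' Builds a small connected bipartite metabolite-reaction network as a test
#' double for a genome-scale reconstruction. With more than one compartment,
#' every metabolite is replicated per compartment and consecutive replicas
#' are linked by reversible transport reactions, so that compartment
#' collapsing has real work to do. An optional hub metabolite (the first one)
#' is wired into enough reactions to reach `hub_degree`, while all other
#' metabolites are kept strictly below it -- mimicking cofactor-like hubs
#' that lightest-path weighting must avoid.
#'
#' @param n_metabolites Number of distinct metabolites (>= 2).
#' @param n_reactions Number of non-transport reactions (>= 1).
#' @param n_compartments Number of compartments (>= 1).
#' @param hub_degree Target minimum degree for the single hub (0 = no hub).
#' @param seed Integer seed.
#' @return A [metabolic_network()].
#' @export
generate_toy_network <- function(n_metabolites, n_reactions,
                                 n_compartments = 1, hub_degree = 0,
                                 seed = 1) {
  if (n_metabolites < 2) stop("n_metabolites must be >= 2")
  if (n_reactions < 1) stop("n_reactions must be >= 1")
  if (n_compartments < 1) stop("n_compartments must be >= 1")
  if (hub_degree > n_reactions * 2)
    stop("infeasible hub_degree ", hub_degree, " with ", n_reactions,
         " reactions")
  mets <- sprintf("m%02d", seq_len(n_metabolites))
  hub <- if (hub_degree > 0) mets[1] else NA_character_

  with_local_seed(seed, {
    # cap per-metabolite reaction participation below hub_degree for non-hubs
    cap <- if (hub_degree > 0) hub_degree - 1L else Inf
    degree <- stats::setNames(integer(n_metabolites), mets)
    pick <- function(pool, k) {
      pool <- pool[degree[pool] < cap | pool == hub]
      if (length(pool) < k) stop("infeasible degree demands: not enough ",
                                 "metabolites below the hub-degree cap")
      if (length(pool) == 1) pool else sample(pool, k)
    }
    connected <- mets[1]
    remaining <- mets[-1]
    subs <- vector("list", n_reactions)
    prods <- vector("list", n_reactions)
    for (j in seq_len(n_reactions)) {
      s <- pick(connected, 1)
      if (length(remaining)) {
        k <- ceiling(length(remaining) / (n_reactions - j + 1))
        p <- remaining[seq_len(k)]
        remaining <- remaining[-seq_len(k)]
        connected <- c(connected, p)
      } else {
        p <- pick(setdiff(connected, s), 1)
      }
      subs[[j]] <- s
      prods[[j]] <- p
      degree[c(s, p)] <- degree[c(s, p)] + 1L
    }
    if (length(remaining))
      stop("infeasible degree demands: could not place all metabolites")
    if (hub_degree > 0) {
      j <- 1
      while (degree[hub] < hub_degree && j <= n_reactions) {
        if (!hub %in% c(subs[[j]], prods[[j]])) {
          subs[[j]] <- c(subs[[j]], hub)
          degree[hub] <- degree[hub] + 1L
        }
        j <- j + 1
      }
      if (degree[hub] < hub_degree)
        stop("infeasible degree demands: hub degree unreachable")
    }
    rev_flags <- stats::runif(n_reactions) < 0.3

    comps <- sprintf("c%d", seq_len(n_compartments))
    met_tbl <- expand.grid(base = mets, compartment = comps,
                           stringsAsFactors = FALSE)
    met_tbl <- data.frame(
      id = paste(met_tbl$base, met_tbl$compartment, sep = "_"),
      name = met_tbl$base, compartment = met_tbl$compartment,
      stringsAsFactors = FALSE)

    rx_id <- sprintf("r%02d", seq_len(n_reactions))
    reactions <- data.frame(id = rx_id, name = rx_id, reversible = rev_flags,
                            stringsAsFactors = FALSE)
    stoich <- do.call(rbind, lapply(seq_len(n_reactions), function(j) {
      rbind(
        data.frame(reaction_id = rx_id[j],
                   metabolite_id = paste(subs[[j]], comps[1], sep = "_"),
                   role = "substrate", coef = 1, stringsAsFactors = FALSE),
        data.frame(reaction_id = rx_id[j],
                   metabolite_id = paste(prods[[j]], comps[1], sep = "_"),
                   role = "product", coef = 1, stringsAsFactors = FALSE))
    }))
    if (n_compartments > 1) {
      for (ci in seq_len(n_compartments - 1)) {
        tid <- sprintf("t_%s_%s_%s", mets, comps[ci], comps[ci + 1])
        reactions <- rbind(reactions,
          data.frame(id = tid, name = tid, reversible = TRUE,
                     stringsAsFactors = FALSE))
        stoich <- rbind(stoich,
          data.frame(reaction_id = rep(tid, 2),
                     metabolite_id = c(paste(mets, comps[ci], sep = "_"),
                                       paste(mets, comps[ci + 1], sep = "_")),
                     role = rep(c("substrate", "product"), each = n_metabolites),
                     coef = 1, stringsAsFactors = FALSE))
      }
    }
    metabolic_network(met_tbl, reactions, stoich)
  })
}
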