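# Shared fixture builders; everything is generated in code.

# Chain A-r1-B-r2-C plus a detour A-r3-H-r4-C through a hub H that is wired
# into extra reactions until its degree reaches 8.
chain_hub_network <- function() {
  mets <- data.frame(
    id = c("A", "B", "C", "H", sprintf("X%d", 1:6)),
    name = c("A", "B", "C", "H", sprintf("X%d", 1:6)),
    compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("r1", "r2", "r3", "r4", sprintf("r%d", 5:10)),
    name = c("r1", "r2", "r3", "r4", sprintf("r%d", 5:10)),
    reversible = FALSE, stringsAsFactors = FALSE)
  st <- rbind(
    data.frame(reaction_id = "r1", metabolite_id = c("A", "B"),
               role = c("substrate", "product"), coef = 1),
    data.frame(reaction_id = "r2", metabolite_id = c("B", "C"),
               role = c("substrate", "product"), coef = 1),
    data.frame(reaction_id = "r3", metabolite_id = c("A", "H"),
               role = c("substrate", "product"), coef = 1),
    data.frame(reaction_id = "r4", metabolite_id = c("H", "C"),
               role = c("substrate", "product"), coef = 1),
    do.call(rbind, lapply(1:6, function(i)
      data.frame(reaction_id = sprintf("r%d", i + 4),
                 metabolite_id = c("H", sprintf("X%d", i)),
                 role = c("substrate", "product"), coef = 1))))
  metabolic_network(mets, rx, st)
}

# Minimum node-weight path cost by exhaustive simple-path enumeration.
enumerate_lightest_cost <- function(g, src, dst) {
  paths <- igraph::all_simple_paths(g, from = src, to = dst)
  if (!length(paths)) return(Inf)
  w <- stats::setNames(igraph::V(g)$weight, igraph::V(g)$name)
  min(vapply(paths, function(p) sum(w[igraph::V(g)$name[as.integer(p)]]),
             numeric(1)))
}

# Mean silhouette of a 2-level grouping on a 1-d score vector.
silhouette_1d <- function(score, is_control) {
  d <- abs(outer(score, score, "-"))
  n <- length(score)
  s <- vapply(seq_len(n), function(i) {
    same <- is_control == is_control[i]; same[i] <- FALSE
    a <- mean(d[i, same]); b <- mean(d[i, !same])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Ten single-bin signatures with a common effect size in every dose group.
ten_bin_signatures <- function(effect = 1.5,
                               groups = c("BPA_1e-6M", "BPA_1e-9M",
                                          "BPA_1e-12M")) {
  lapply(1:10, function(i) {
    eff <- stats::setNames(rep(effect, length(groups)), groups)
    signature_spec(paste0("Met", i), 0.5 + i * 0.8,
                   effect_by_group = c(eff, control = 0),
                   direction = if (i %% 2) 1 else -1)
  })
}

# Ten signatures with dose-specific response patterns (some bins respond at
# every dose, others only at particular doses), the structure of published
# fingerprint tables.
dose_pattern_signatures <- function(effect = 3,
                                    groups = c("BPA_1e-6M", "BPA_1e-9M",
                                               "BPA_1e-12M")) {
  pattern <- list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),
                  c(1, 0, 0), c(1, 0, 0), c(1, 1, 0),
                  c(0, 1, 1), c(0, 0, 1), c(0, 0, 1))
  lapply(1:10, function(i) {
    eff <- stats::setNames(effect * pattern[[i]], groups)
    signature_spec(paste0("Met", i), 0.5 + i * 0.8,
                   effect_by_group = c(eff, control = 0),
                   direction = if (i %% 2) 1 else -1)
  })
}

# Seeded null draw (no group structure).
with_seed_values <- function(seed, n = 48) {
  set.seed(seed)
  stats::rnorm(n)
}

# One full recovery run: simulate, preprocess, OSC, PLS-DA (CV-chosen A),
# VIP + rank-test selection; returns recovered / false-positive counts.
recovery_run <- function(seed, effect = 1.5, confounder_sd = 0,
                         n_bins = 200) {
  d <- default_design()
  sp <- simulate_spectra(d, ten_bin_signatures(effect), n_bins = n_bins,
                         noise_sd = 1, confounder_sd = confounder_sd,
                         seed = seed)
  planted <- sort(unlist(attr(sp, "planted")$signature_bins))
  scaled <- scale_spectra(normalize_total_area(sp), "center_pareto")
  x0 <- scaled$intensities
  x <- osc_filter(x0, d, n_osc = 1)$filtered_X
  A <- select_components(x, d, seed = seed + 7, max_A = 4)$A
  fit <- fit_plsda(x, d, A = A)
  bins <- select_discriminant_bins(vip_scores(fit), x0, d)
  c(recovered = sum(planted %in% bins$bin),
    false_pos = sum(!bins$bin %in% planted))
}
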