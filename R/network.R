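#' Construct a metabolic network
#'
#' A genome-scale metabolic network reduced to what sub-network extraction
#' needs: metabolites with compartment tags, reactions with reversibility,
#' and a long-format stoichiometry table linking the two.
#'
#' @param metabolites Data frame with columns `id`, `name`, `compartment`.
#' @param reactions Data frame with columns `id`, `name`, `reversible`.
#' @param stoichiometry Data frame with columns `reaction_id`,
#'   `metabolite_id`, `role` (`"substrate"`/`"product"`) and `coef` (> 0).
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoichiometry <- as.data.frame(stoichiometry, stringsAsFactors = FALSE)
  rownames(metabolites) <- rownames(reactions) <- rownames(stoichiometry) <- NULL
  stopifnot(all(c("id", "name", "compartment") %in% names(metabolites)),
            all(c("id", "name", "reversible") %in% names(reactions)),
            all(c("reaction_id", "metabolite_id", "role", "coef") %in%
                  names(stoichiometry)))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids")
  if (!all(stoichiometry$metabolite_id %in% metabolites$id))
    stop("stoichiometry references unknown metabolite(s): ",
         paste(utils::head(setdiff(stoichiometry$metabolite_id,
                                   metabolites$id)), collapse = ", "))
  if (!all(stoichiometry$reaction_id %in% reactions$id))
    stop("stoichiometry references unknown reaction(s)")
  if (!all(stoichiometry$role %in% c("substrate", "product")))
    stop("role must be 'substrate' or 'product'")
  if (any(stoichiometry$coef <= 0))
    stop("stoichiometric coefficients must be strictly positive")
  structure(list(metabolites = metabolites, reactions = reactions,
                 stoichiometry = stoichiometry),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites, %d reactions, %d compartments\n",
              nrow(x$metabolites), nrow(x$reactions),
              length(unique(x$metabolites$compartment))))
  invisible(x)
}

# stable fingerprint of a network, used to check that two sub-networks
# derive from the same parent
network_id <- function(net) {
  key <- paste(c(sort(net$metabolites$id), "|", sort(net$reactions$id)),
               collapse = ";")
  # cheap rolling hash; only equality matters
  sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)) %% 2147483647
}

## ---- SBML I/O --------------------------------------------------------------

#' Read a metabolic network from SBML
#'
#' Parses SBML Level 2 or Level 3 core: compartments, species (with their
#' compartment attribute), and reactions with `listOfReactants`,
#' `listOfProducts` and reversibility. Either the whole file parses or an
#' error is raised; no partial network is ever returned.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_network()].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing"))
    stop("no <model> element in '", path, "'")
  level <- xml2::xml_attr(doc, "level")

  sp <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (!length(sp)) stop("SBML model contains no species")
  met <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]
  if (any(is.na(met$compartment)))
    stop("species without compartment attribute: ",
         paste(utils::head(met$id[is.na(met$compartment)]), collapse = ", "))

  rx <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (!length(rx)) stop("SBML model contains no reactions")
  rev_attr <- xml2::xml_attr(rx, "reversible")
  # SBML L2 default is reversible="true"; L3 requires the attribute
  rev_default <- !identical(level, "3")
  reversible <- ifelse(is.na(rev_attr), rev_default, rev_attr == "true")
  rx_id <- xml2::xml_attr(rx, "id")
  rx_name <- xml2::xml_attr(rx, "name")
  rx_name[is.na(rx_name)] <- rx_id[is.na(rx_name)]

  stoich <- do.call(rbind, lapply(seq_along(rx), function(i) {
    refs <- function(xpath, role) {
      nodes <- xml2::xml_find_all(rx[[i]], xpath)
      if (!length(nodes)) return(NULL)
      st <- xml2::xml_attr(nodes, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      data.frame(reaction_id = rx_id[i],
                 metabolite_id = xml2::xml_attr(nodes, "species"),
                 role = role, coef = st, stringsAsFactors = FALSE)
    }
    rbind(refs("./listOfReactants/speciesReference", "substrate"),
          refs("./listOfProducts/speciesReference", "product"))
  }))
  metabolic_network(met,
                    data.frame(id = rx_id, name = rx_name,
                               reversible = reversible,
                               stringsAsFactors = FALSE),
                    stoich)
}

#' Write a metabolic network as SBML Level 3
#'
#' @param net A [metabolic_network()].
#' @param path Output path.
#' @export
write_sbml <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">')
  w('  <model id="model">')
  w('    <listOfCompartments>')
  for (cp in unique(net$metabolites$compartment))
    w('      <compartment id="', esc(cp), '" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(net$metabolites)))
    w('      <species id="', esc(net$metabolites$id[i]),
      '" name="', esc(net$metabolites$name[i]),
      '" compartment="', esc(net$metabolites$compartment[i]),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>')
  w('    </listOfSpecies>')
  w('    <listOfReactions>')
  for (i in seq_len(nrow(net$reactions))) {
    rid <- net$reactions$id[i]
    st <- net$stoichiometry[net$stoichiometry$reaction_id == rid, , drop = FALSE]
    w('      <reaction id="', esc(rid), '" name="', esc(net$reactions$name[i]),
      '" reversible="', tolower(as.character(net$reactions$reversible[i])),
      '" fast="false">')
    for (role in c("substrate", "product")) {
      part <- st[st$role == role, , drop = FALSE]
      if (!nrow(part)) next
      tag <- if (role == "substrate") "listOfReactants" else "listOfProducts"
      w('        <', tag, '>')
      for (j in seq_len(nrow(part)))
        w('          <speciesReference species="', esc(part$metabolite_id[j]),
          '" stoichiometry="', format(part$coef[j]), '" constant="true"/>')
      w('        </', tag, '>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}

## ---- compartment collapsing ------------------------------------------------

#' Collapse a multi-compartment network to one compartment
#'
#' Treats any metabolite present in several compartments as a single
#' metabolite, mirroring the information content of untargeted metabolomics,
#' which cannot localize metabolites within the cell. After substituting the
#' collapsed metabolite ids: (a) reactions whose substrate multiset equals
#' their product multiset (pure transport) are removed; (b) reactions with
#' identical substrate/product multisets and reversibility are deduplicated,
#' keeping the lexicographically smallest reaction id; reactions left with no
#' participants at all are dropped. The operation is idempotent.
#'
#' @param net A [metabolic_network()].
#' @param suffix_regex Regular expression matching the compartment suffix of
#'   metabolite ids (default: trailing underscore + alphanumerics, e.g.
#'   `"_c"`, `"_m"`).
#' @return A one-compartment [metabolic_network()] with attributes
#'   `id_mapping` (data frame old id -> new id) and `removed_reactions`.
#' @export
merge_compartments <- function(net, suffix_regex = "_[A-Za-z0-9]+$") {
  stopifnot(inherits(net, "metabolic_network"))
  base_id <- sub(suffix_regex, "", net$metabolites$id)
  mapping <- data.frame(old_id = net$metabolites$id, new_id = base_id,
                        stringsAsFactors = FALSE)
  first <- !duplicated(base_id)
  mets <- data.frame(id = base_id[first],
                     name = sub(suffix_regex, "", net$metabolites$name[first]),
                     compartment = "cell", stringsAsFactors = FALSE)

  st <- net$stoichiometry
  st$metabolite_id <- mapping$new_id[match(st$metabolite_id, mapping$old_id)]
  # merge duplicate participants within one reaction side
  st <- stats::aggregate(coef ~ reaction_id + metabolite_id + role, data = st,
                         FUN = sum)

  side_key <- function(rid, role) {
    part <- st[st$reaction_id == rid & st$role == role, , drop = FALSE]
    part <- part[order(part$metabolite_id), , drop = FALSE]
    paste(part$metabolite_id, part$coef, sep = ":", collapse = ",")
  }
  rx <- net$reactions
  subs_key <- vapply(rx$id, side_key, character(1), role = "substrate")
  prod_key <- vapply(rx$id, side_key, character(1), role = "product")

  removed <- character(0)
  # (a) pure transport: substrate multiset equals product multiset
  transport <- subs_key == prod_key & subs_key != ""
  # empty reactions (no participants survived)
  empty <- subs_key == "" & prod_key == ""
  removed <- rx$id[transport | empty]

  keep <- !(transport | empty)
  rx <- rx[keep, , drop = FALSE]
  subs_key <- subs_key[keep]
  prod_key <- prod_key[keep]

  # (b) deduplicate identical reactions, keep lexicographically smallest id
  dup_key <- paste(subs_key, prod_key, rx$reversible, sep = "|")
  ord <- order(dup_key, rx$id)
  rx <- rx[ord, , drop = FALSE]
  dup_key <- dup_key[ord]
  dup <- duplicated(dup_key)
  removed <- c(removed, rx$id[dup])
  rx <- rx[!dup, , drop = FALSE]
  rx <- rx[order(rx$id), , drop = FALSE]

  st <- st[st$reaction_id %in% rx$id, , drop = FALSE]
  # metabolites left without reactions are kept: they may still be seeds
  mets <- mets[order(mets$id), , drop = FALSE]
  out <- metabolic_network(mets, rx, st)
  attr(out, "id_mapping") <- mapping
  attr(out, "removed_reactions") <- removed
  out
}

## ---- compound graph and lightest paths -------------------------------------

#' Default side-compound list
#'
#' Ubiquitous cofactor-like metabolites (water, protons, adenosine
#' phosphates, nicotinamide cofactors, CO2, phosphate, O2) that create
#' biologically meaningless shortcuts and are excluded from path-finding.
#' Shipped as a plain TSV so users can edit it.
#'
#' @return Character vector of side-compound names/ids (lower case).
#' @export
default_side_compounds <- function() {
  path <- system.file("extdata", "side_compounds.tsv", package = "fingernet")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)$id
}

#' Build the compound graph of a network
#'
#' The bipartite graph with one node per (non-side) metabolite and one node
#' per reaction, and an undirected edge linking each reaction to each of its
#' substrates and products. Reactions that lose all substrates or all
#' products to side-compound filtering are dropped. Metabolite node weights
#' are computed from the node degree *in this graph*: squared degree
#' (default, the established hub-avoidance choice), raw degree, or unit.
#' Reaction nodes always have weight 1.
#'
#' @param net A [metabolic_network()].
#' @param side_compounds Character vector of metabolite ids to exclude;
#'   unknown ids produce a warning, not an error.
#' @param weight_scheme `"degree_squared"`, `"degree"`, or `"unit"`.
#' @return An [igraph::graph] with vertex attributes `type` (`"metabolite"`/
#'   `"reaction"`) and `weight`, and graph attribute `parent_id`.
#' @export
build_compound_graph <- function(net, side_compounds = character(0),
                                 weight_scheme = c("degree_squared", "degree",
                                                   "unit")) {
  stopifnot(inherits(net, "metabolic_network"))
  weight_scheme <- match.arg(weight_scheme)
  unknown <- setdiff(side_compounds, net$metabolites$id)
  if (length(unknown))
    warning("side compounds not in network (ignored): ",
            paste(utils::head(unknown), collapse = ", "))
  st <- net$stoichiometry
  st <- st[!st$metabolite_id %in% side_compounds, , drop = FALSE]
  has_sub <- unique(st$reaction_id[st$role == "substrate"])
  has_prod <- unique(st$reaction_id[st$role == "product"])
  keep_rx <- intersect(has_sub, has_prod)
  st <- st[st$reaction_id %in% keep_rx, , drop = FALSE]
  if (!nrow(st)) stop("empty compound graph after side-compound filtering")

  edges <- unique(st[, c("reaction_id", "metabolite_id")])
  mets <- sort(unique(edges$metabolite_id))
  rxs <- sort(unique(edges$reaction_id))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(mets, rxs),
                          type = rep(c("metabolite", "reaction"),
                                     c(length(mets), length(rxs))),
                          stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  w <- ifelse(igraph::V(g)$type == "reaction", 1,
              switch(weight_scheme,
                     degree_squared = deg^2,
                     degree = deg,
                     unit = 1))
  igraph::V(g)$weight <- pmax(w, 1)
  g <- igraph::set_graph_attr(g, "parent_id", network_id(net))
  g
}

# Edge weights such that a path's edge-weight sum equals its node-weight sum
# minus half the endpoint weights (a constant for fixed src/dst): each edge
# gets the mean of its endpoints' node weights.
node_to_edge_weights <- function(g) {
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  (igraph::V(g)$weight[ends[, 1]] + igraph::V(g)$weight[ends[, 2]]) / 2
}

#' Lightest path between two metabolites
#'
#' The path minimizing the sum of node weights over all its nodes (endpoints
#' included). With squared-degree weights this steers paths away from hub
#' metabolites. Ties are broken deterministically in favour of the
#' lexicographically smallest node-name sequence.
#'
#' @param g A compound graph from [build_compound_graph()].
#' @param src,dst Metabolite ids (must differ and be present in `g`).
#' @return A list with `nodes` (character vector of the node sequence, empty
#'   when unreachable), `cost` (node-weight sum, `Inf` when unreachable) and
#'   `found` (logical).
#' @export
lightest_path <- function(g, src, dst) {
  if (identical(src, dst)) stop("src and dst must differ")
  vn <- igraph::V(g)$name
  missing <- setdiff(c(src, dst), vn)
  if (length(missing))
    stop("node(s) not in graph: ", paste(missing, collapse = ", "))
  ew <- node_to_edge_weights(g)
  paths <- suppressWarnings(
    igraph::all_shortest_paths(g, from = src, to = dst, weights = ew))$res
  if (!length(paths))
    return(list(nodes = character(0), cost = Inf, found = FALSE))
  seqs <- lapply(paths, function(p) igraph::V(g)$name[as.integer(p)])
  # deterministic tie-break: lexicographically smallest node sequence
  keys <- vapply(seqs, paste, character(1), collapse = "\r")
  best <- seqs[[order(keys)[1]]]
  wts <- stats::setNames(igraph::V(g)$weight, vn)
  list(nodes = best, cost = sum(wts[best]), found = TRUE)
}

#' Extract the sub-network spanned by a metabolite fingerprint
#'
#' Computes the lightest path for every unordered pair of seed metabolites
#' and returns the union of all paths: the part of the network most likely
#' related to the fingerprint. Unreachable pairs are recorded, never silently
#' dropped.
#'
#' @param g A compound graph from [build_compound_graph()].
#' @param seeds Character vector of metabolite ids (>= 2 must be present in
#'   the graph).
#' @return An object of class `subnetwork`: metabolite and reaction id sets,
#'   the seeds, per-pair path provenance, and unreachable pairs.
#' @export
extract_subnetwork <- function(g, seeds) {
  seeds <- unique(as.character(seeds))
  vn <- igraph::V(g)$name
  mapped <- seeds[seeds %in% vn]
  unmapped <- setdiff(seeds, mapped)
  if (length(mapped) < 2)
    stop("need >= 2 seeds present in the graph; unmapped: ",
         paste(unmapped, collapse = ", "))
  type <- stats::setNames(igraph::V(g)$type, vn)
  provenance <- list()
  unreachable <- list()
  nodes <- character(0)
  mapped <- sort(mapped)
  for (i in seq_len(length(mapped) - 1)) {
    for (j in seq(i + 1, length(mapped))) {
      p <- lightest_path(g, mapped[i], mapped[j])
      key <- paste(mapped[i], mapped[j], sep = "~")
      if (p$found) {
        provenance[[key]] <- p$nodes
        nodes <- union(nodes, p$nodes)
      } else {
        unreachable[[length(unreachable) + 1]] <- c(mapped[i], mapped[j])
      }
    }
  }
  structure(list(
    metabolites = sort(nodes[type[nodes] == "metabolite"]),
    reactions = sort(nodes[type[nodes] == "reaction"]),
    seeds = mapped, unmapped_seeds = unmapped,
    provenance = provenance, unreachable_pairs = unreachable,
    parent_id = igraph::graph_attr(g, "parent_id")),
    class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d metabolites, %d reactions, %d seeds, %d unreachable pairs\n",
              length(x$metabolites), length(x$reactions), length(x$seeds),
              length(x$unreachable_pairs)))
  invisible(x)
}

#' Set algebra on sub-networks
#'
#' Applies a set operation independently to the metabolite and reaction id
#' sets of two sub-networks derived from the same parent network: the
#' intersection gives the effects shared by two exposures, the difference
#' the exposure-specific part.
#'
#' @param a,b `subnetwork` objects from the same compound graph.
#' @param op `"intersect"`, `"difference"` (a minus b), or `"union"`.
#' @return A `subnetwork`; seeds receive the same set operation, and path
#'   provenance is restricted to paths whose nodes all survive.
#' @export
subnetwork_algebra <- function(a, b, op = c("intersect", "difference", "union")) {
  stopifnot(inherits(a, "subnetwork"), inherits(b, "subnetwork"))
  op <- match.arg(op)
  if (!identical(a$parent_id, b$parent_id))
    stop("sub-networks derive from different parent networks")
  f <- switch(op, intersect = intersect, difference = setdiff, union = union)
  mets <- sort(f(a$metabolites, b$metabolites))
  rxs <- sort(f(a$reactions, b$reactions))
  seeds <- sort(f(a$seeds, b$seeds))
  prov <- c(a$provenance, if (op == "union") b$provenance)
  keep_nodes <- c(mets, rxs)
  prov <- prov[vapply(prov, function(p) all(p %in% keep_nodes), logical(1))]
  prov <- prov[!duplicated(names(prov))]
  structure(list(metabolites = mets, reactions = rxs, seeds = seeds,
                 unmapped_seeds = union(a$unmapped_seeds, b$unmapped_seeds),
                 provenance = prov,
                 unreachable_pairs = if (op == "union")
                   unique(c(a$unreachable_pairs, b$unreachable_pairs))
                 else list(),
                 parent_id = a$parent_id),
            class = "subnetwork")
}

#' Map fingerprint metabolite names to network ids
#'
#' Case-insensitive exact matching of fingerprint metabolite names against a
#' curated synonym table. Names without a match are returned, never silently
#' dropped. A synonym mapping to two different network ids is an error.
#'
#' @param metabolite_names Character vector of fingerprint metabolite names.
#' @param mapping Data frame with columns `name` and `network_id`.
#' @return List with `seed_ids` (character) and `unmapped` (character).
#' @export
map_fingerprint_to_network <- function(metabolite_names, mapping) {
  if (is.null(mapping) || !nrow(mapping)) stop("empty mapping table")
  stopifnot(all(c("name", "network_id") %in% names(mapping)))
  key <- tolower(trimws(mapping$name))
  amb <- tapply(mapping$network_id, key, function(v) length(unique(v)))
  if (any(amb > 1))
    stop("ambiguous mapping for: ",
         paste(names(amb)[amb > 1], collapse = ", "))
  idx <- match(tolower(trimws(metabolite_names)), key)
  list(seed_ids = unique(mapping$network_id[idx[!is.na(idx)]]),
       unmapped = unique(metabolite_names[is.na(idx)]))
}

#' Export a sub-network
#'
#' SIF (one `reaction_id interacts metabolite_id` row per bipartite edge
#' present in the sub-network), GraphML (node `type` and `seed` attributes;
#' round-trips through [igraph::read_graph()]), or a two-file TSV (nodes +
#' edges).
#'
#' @param s A `subnetwork`.
#' @param g The compound graph it was extracted from (supplies the edges).
#' @param path Output path (for `tsv`, the basename; `_nodes.tsv` and
#'   `_edges.tsv` are appended).
#' @param format `"sif"`, `"graphml"`, or `"tsv"`.
#' @return The path(s) written, invisibly.
#' @export
export_subnetwork <- function(s, g, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(s, "subnetwork"))
  format <- match.arg(format)
  nodes <- c(s$metabolites, s$reactions)
  if (!length(nodes)) stop("cannot export an empty subnetwork")
  sg <- igraph::induced_subgraph(g, nodes)
  igraph::V(sg)$seed <- igraph::V(sg)$name %in% s$seeds
  ends <- igraph::ends(sg, igraph::E(sg))
  # orient every edge reaction -> metabolite
  is_rx1 <- ends[, 1] %in% s$reactions
  rx_col <- ifelse(is_rx1, ends[, 1], ends[, 2])
  met_col <- ifelse(is_rx1, ends[, 2], ends[, 1])
  switch(format,
    sif = {
      writeLines(paste(rx_col, "interacts", met_col, sep = "\t"), path)
      invisible(path)
    },
    graphml = {
      igraph::write_graph(sg, path, format = "graphml")
      invisible(path)
    },
    tsv = {
      np <- paste0(path, "_nodes.tsv")
      ep <- paste0(path, "_edges.tsv")
      utils::write.table(
        data.frame(id = igraph::V(sg)$name, type = igraph::V(sg)$type,
                   seed = igraph::V(sg)$seed, stringsAsFactors = FALSE),
        np, sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(reaction_id = rx_col, metabolite_id = met_col,
                   stringsAsFactors = FALSE),
        ep, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(c(np, ep))
    })
}
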