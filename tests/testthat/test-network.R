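minimal_sbml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="mini">',
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="a_c" name="A" compartment="c"/>',
    '      <species id="b_c" name="B" compartment="c"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="r1" reversible="false">',
    '        <listOfReactants><speciesReference species="a_c" stoichiometry="1"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="b_c" stoichiometry="2"/></listOfProducts>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  path
}

test_that("SBML reading recovers species, reactions and reversibility", {
  f <- minimal_sbml(tempfile(fileext = ".xml"))
  net <- read_sbml(f)
  expect_equal(nrow(net$metabolites), 2)
  expect_equal(nrow(net$reactions), 1)
  expect_false(net$reactions$reversible[1])
  expect_equal(net$stoichiometry$coef[net$stoichiometry$role == "product"], 2)
})

test_that("SBML round-trip preserves the network", {
  net <- generate_toy_network(8, 11, n_compartments = 2, seed = 6)
  f <- tempfile(fileext = ".xml")
  write_sbml(net, f)
  back <- read_sbml(f)
  expect_equal(sort(back$metabolites$id), sort(net$metabolites$id))
  expect_equal(sort(back$reactions$id), sort(net$reactions$id))
  o1 <- net$reactions[order(net$reactions$id), ]
  o2 <- back$reactions[order(back$reactions$id), ]
  expect_equal(o2$reversible, o1$reversible)
  s1 <- net$stoichiometry[order(net$stoichiometry$reaction_id,
                                net$stoichiometry$metabolite_id,
                                net$stoichiometry$role), ]
  s2 <- back$stoichiometry[order(back$stoichiometry$reaction_id,
                                 back$stoichiometry$metabolite_id,
                                 back$stoichiometry$role), ]
  expect_equal(s2$coef, s1$coef)
})

test_that("unparseable or incomplete SBML raises an error, never a partial network", {
  bad <- tempfile(fileext = ".xml")
  writeLines(substr(paste(readLines(minimal_sbml(tempfile())), collapse = "\n"),
                    1, 200), bad)
  expect_error(read_sbml(bad))
  nocomp <- tempfile(fileext = ".xml")
  txt <- readLines(minimal_sbml(tempfile()))
  writeLines(sub(' compartment="c"', "", txt), nocomp)
  expect_error(read_sbml(nocomp), "compartment")
})

test_that("compartment collapse removes pure transport and duplicates", {
  mets <- data.frame(id = c("glc_c", "glc_m"), name = c("glc", "glc"),
                     compartment = c("c", "m"), stringsAsFactors = FALSE)
  rx <- data.frame(id = "t1", name = "transport", reversible = TRUE,
                   stringsAsFactors = FALSE)
  st <- data.frame(reaction_id = "t1", metabolite_id = c("glc_c", "glc_m"),
                   role = c("substrate", "product"), coef = 1,
                   stringsAsFactors = FALSE)
  merged <- merge_compartments(metabolic_network(mets, rx, st))
  expect_equal(nrow(merged$metabolites), 1)
  expect_equal(nrow(merged$reactions), 0)
  expect_equal(attr(merged, "removed_reactions"), "t1")

  # hexokinase duplicated in two compartments -> one survives, smallest id
  mets2 <- data.frame(id = c("glc_c", "g6p_c", "glc_m", "g6p_m"),
                      name = c("glc", "g6p", "glc", "g6p"),
                      compartment = rep(c("c", "m"), each = 2),
                      stringsAsFactors = FALSE)
  rx2 <- data.frame(id = c("hex_m", "hex_c"), name = "hexokinase",
                    reversible = FALSE, stringsAsFactors = FALSE)
  st2 <- rbind(
    data.frame(reaction_id = "hex_c", metabolite_id = c("glc_c", "g6p_c"),
               role = c("substrate", "product"), coef = 1),
    data.frame(reaction_id = "hex_m", metabolite_id = c("glc_m", "g6p_m"),
               role = c("substrate", "product"), coef = 1))
  merged2 <- merge_compartments(metabolic_network(mets2, rx2, st2))
  expect_equal(merged2$reactions$id, "hex_c")
  expect_equal(nrow(merged2$metabolites), 2)
  mapping <- attr(merged2, "id_mapping")
  expect_equal(mapping$new_id[mapping$old_id == "glc_m"], "glc")
})

test_that("compartment collapse is idempotent and shrinks counts", {
  net <- generate_toy_network(12, 16, n_compartments = 3, seed = 8)
  m1 <- merge_compartments(net)
  m2 <- merge_compartments(m1)
  expect_equal(m2$metabolites$id, m1$metabolites$id)
  expect_equal(m2$reactions$id, m1$reactions$id)
  expect_lt(nrow(m1$metabolites), nrow(net$metabolites))
  expect_lte(nrow(m1$reactions), nrow(net$reactions))
})

test_that("compound graph is bipartite with scheme-dependent weights", {
  mets <- data.frame(id = c("A", "B", "C", "h2o"),
                     name = c("A", "B", "C", "water"), compartment = "c",
                     stringsAsFactors = FALSE)
  rx <- data.frame(id = c("r1", "r2"), name = c("r1", "r2"),
                   reversible = FALSE, stringsAsFactors = FALSE)
  st <- rbind(
    data.frame(reaction_id = "r1", metabolite_id = c("A", "B", "h2o"),
               role = c("substrate", "product", "product"), coef = 1),
    data.frame(reaction_id = "r2", metabolite_id = c("B", "C"),
               role = c("substrate", "product"), coef = 1))
  net <- metabolic_network(mets, rx, st)
  g <- build_compound_graph(net, side_compounds = "h2o")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  expect_false("h2o" %in% igraph::V(g)$name)
  ends <- igraph::ends(g, igraph::E(g))
  types <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_true(all(types[ends[, 1]] != types[ends[, 2]]))

  gu <- build_compound_graph(net, weight_scheme = "unit")
  expect_true(all(igraph::V(gu)$weight == 1))
  gd <- build_compound_graph(net, weight_scheme = "degree")
  wB <- igraph::V(gd)$weight[igraph::V(gd)$name == "B"]
  expect_equal(wB, 2)
  expect_warning(build_compound_graph(net, side_compounds = "nope"),
                 "not in network")
})

test_that("side-compound filtering can drop one-sided reactions", {
  mets <- data.frame(id = c("A", "h2o"), name = c("A", "water"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(id = "r1", name = "r1", reversible = FALSE,
                   stringsAsFactors = FALSE)
  st <- data.frame(reaction_id = "r1", metabolite_id = c("A", "h2o"),
                   role = c("substrate", "product"), coef = 1,
                   stringsAsFactors = FALSE)
  net <- metabolic_network(mets, rx, st)
  expect_error(build_compound_graph(net, side_compounds = "h2o"), "empty")
})

test_that("lightest path avoids hubs under squared-degree weights", {
  g <- build_compound_graph(chain_hub_network())
  expect_equal(igraph::V(g)$weight[igraph::V(g)$name == "H"], 64)
  p <- lightest_path(g, "A", "C")
  expect_equal(p$nodes, c("A", "r1", "B", "r2", "C"))
  expect_equal(p$cost, 14)
  # with unit weights both routes tie at 5 nodes; lexicographic tie-break
  gu <- build_compound_graph(chain_hub_network(), weight_scheme = "unit")
  pu <- lightest_path(gu, "A", "C")
  expect_equal(pu$nodes, c("A", "r1", "B", "r2", "C"))
  expect_error(lightest_path(g, "A", "A"), "differ")
  expect_error(lightest_path(g, "A", "missing"), "not in graph")
})

test_that("unit-weight lightest paths equal breadth-first shortest paths", {
  for (seed in 1:10) {
    net <- generate_toy_network(5, 6, seed = seed)
    g <- build_compound_graph(net, weight_scheme = "unit")
    mets <- igraph::V(g)$name[igraph::V(g)$type == "metabolite"]
    pair <- sort(mets)[1:2]
    p <- lightest_path(g, pair[1], pair[2])
    bfs_len <- igraph::distances(g, pair[1], pair[2], weights = NA)[1, 1]
    expect_equal(length(p$nodes) - 1, unname(bfs_len))
  }
})

test_that("unreachable pairs are flagged, not fabricated", {
  mets <- data.frame(id = c("A", "B", "C", "D"), name = c("A", "B", "C", "D"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(id = c("r1", "r2"), name = c("r1", "r2"),
                   reversible = FALSE, stringsAsFactors = FALSE)
  st <- rbind(
    data.frame(reaction_id = "r1", metabolite_id = c("A", "B"),
               role = c("substrate", "product"), coef = 1),
    data.frame(reaction_id = "r2", metabolite_id = c("C", "D"),
               role = c("substrate", "product"), coef = 1))
  g <- build_compound_graph(metabolic_network(mets, rx, st))
  p <- lightest_path(g, "A", "C")
  expect_false(p$found)
  expect_equal(p$nodes, character(0))
  sn <- extract_subnetwork(g, c("A", "B", "C"))
  expect_equal(length(sn$unreachable_pairs), 2)
})

test_that("subnetwork extraction unions lightest paths over seed pairs", {
  g <- build_compound_graph(chain_hub_network())
  sn <- extract_subnetwork(g, c("A", "C"))
  expect_equal(sn$metabolites, c("A", "B", "C"))
  expect_equal(sn$reactions, c("r1", "r2"))
  # adjacent seeds: exactly the connecting reaction
  sn2 <- extract_subnetwork(g, c("A", "B"))
  expect_equal(sn2$metabolites, c("A", "B"))
  expect_equal(sn2$reactions, "r1")
  expect_error(extract_subnetwork(g, c("A", "nope")), "nope")
})

test_that("adding a seed never removes nodes (monotonicity)", {
  for (seed in 1:5) {
    net <- generate_toy_network(8, 11, seed = seed)
    g <- build_compound_graph(net)
    mets <- sort(igraph::V(g)$name[igraph::V(g)$type == "metabolite"])
    s1 <- extract_subnetwork(g, mets[1:2])
    s2 <- extract_subnetwork(g, mets[1:3])
    expect_true(all(s1$metabolites %in% s2$metabolites))
    expect_true(all(s1$reactions %in% s2$reactions))
  }
})

test_that("subnetwork set algebra follows set semantics", {
  g <- build_compound_graph(chain_hub_network())
  a <- extract_subnetwork(g, c("A", "C"))
  b <- extract_subnetwork(g, c("A", "B"))
  expect_equal(subnetwork_algebra(a, a, "difference")$metabolites,
               character(0))
  d <- subnetwork_algebra(a, b, "difference")
  expect_equal(d$metabolites, "C")
  expect_equal(d$reactions, "r2")
  i <- subnetwork_algebra(a, b, "intersect")
  expect_true(all(i$metabolites %in% a$metabolites) &&
                all(i$metabolites %in% b$metabolites))
  u <- subnetwork_algebra(a, b, "union")
  expect_equal(u$metabolites, c("A", "B", "C"))

  g2 <- build_compound_graph(generate_toy_network(5, 6, seed = 1))
  mets2 <- sort(igraph::V(g2)$name[igraph::V(g2)$type == "metabolite"])
  other <- extract_subnetwork(g2, mets2[1:2])
  expect_error(subnetwork_algebra(a, other), "different parent")
})

test_that("fingerprint names map case-insensitively with explicit misses", {
  mapping <- data.frame(name = c("Succinate", "Glycine"),
                        network_id = c("succ", "gly"),
                        stringsAsFactors = FALSE)
  res <- map_fingerprint_to_network(c("succinate", "Isopropanol"), mapping)
  expect_equal(res$seed_ids, "succ")
  expect_equal(res$unmapped, "Isopropanol")
  dup <- rbind(mapping,
               data.frame(name = "SUCCINATE", network_id = "succ2"))
  expect_error(map_fingerprint_to_network("Succinate", dup), "ambiguous")
  expect_error(map_fingerprint_to_network("x", mapping[0, ]), "empty")
})

test_that("subnetwork export round-trips and rejects bad requests", {
  g <- build_compound_graph(chain_hub_network())
  sn <- extract_subnetwork(g, c("A", "B"))
  sif <- tempfile(fileext = ".sif")
  export_subnetwork(sn, g, sif, "sif")
  rows <- readLines(sif)
  expect_length(rows, 2)
  expect_true(all(grepl("^r1\tinteracts\t[AB]$", rows)))

  gml <- tempfile(fileext = ".graphml")
  export_subnetwork(sn, g, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("A", "B", "r1"))
  expect_equal(igraph::ecount(back), 2)

  empty <- subnetwork_algebra(sn, sn, "difference")
  expect_error(export_subnetwork(empty, g, tempfile(), "sif"), "empty")
  expect_error(export_subnetwork(sn, g, tempfile(), "sbml"))
})
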