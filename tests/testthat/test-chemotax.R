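lib <- skeleton_library()

toy_taxonomy <- function() {
  g <- data.frame(taxon_id = 1001:1003,
                  canonical_name = c("Salvia", "Ajuga", "Pogostemon"),
                  rank = "genus", parent_genus_id = NA_integer_,
                  stringsAsFactors = FALSE)
  s <- data.frame(taxon_id = 2001:2004,
                  canonical_name = c("Salvia officinalis", "Salvia miltiorrhiza",
                                     "Ajuga reptans", "Pogostemon cablin"),
                  rank = "species",
                  parent_genus_id = c(1001L, 1001L, 1002L, 1003L),
                  stringsAsFactors = FALSE)
  rbind(g, s)
}

test_that("merge_occurrences unions sources, deduplicates, and excludes unresolved", {
  tx <- toy_taxonomy(); cm <- read_clade_map()
  src <- list(
    dnp = data.frame(compound_id = c("c1", "c1", "c2", "c3"),
                     taxon_id = c(2001L, 2001L, 2003L, NA)),
    sistemat = data.frame(compound_id = "c1", taxon_id = 2001L))
  expect_message(occ <- merge_occurrences(src, tx, cm), "excluded 1")
  # shared (compound, species) stays as 2 rows with distinct source tags
  expect_equal(sum(occ$compound_id == "c1" & occ$taxon_id == 2001L), 2)
  expect_equal(nrow(occ), 3)
  expect_equal(attr(occ, "n_unresolved"), 1L)
  expect_equal(occ$clade[occ$compound_id == "c2"], "Ajugoideae")

  empty <- merge_occurrences(list(dnp = data.frame(compound_id = character(),
                                                   taxon_id = integer())),
                             tx, cm)
  expect_equal(nrow(empty), 0)
})

test_that("merged row count equals a brute-force set union over three sources", {
  tx <- toy_taxonomy(); cm <- read_clade_map()
  set.seed(21)
  mk <- function() data.frame(
    compound_id = sample(sprintf("c%d", 1:6), 15, replace = TRUE),
    taxon_id = sample(c(2001L, 2002L, 2003L, 2004L), 15, replace = TRUE))
  src <- list(a = mk(), b = mk(), c = mk())
  occ <- merge_occurrences(src, tx, cm)
  brute <- unique(do.call(rbind, lapply(names(src), function(s)
    cbind(src[[s]], source_db = s))))
  expect_equal(nrow(occ), nrow(brute))
})

test_that("skeleton_distribution computes genus/clade/compound marginals", {
  tx <- toy_taxonomy(); cm <- read_clade_map()
  # one compound in 3 genera across 2 clades (Salvia+Ajuga: Nepetoideae,
  # Ajugoideae; Pogostemon: Lamioideae => 3 genera, 3 clades for c1)
  src <- list(dnp = data.frame(compound_id = "c1",
                               taxon_id = c(2001L, 2003L, 2004L)))
  occ <- merge_occurrences(src, tx, cm)
  asg <- data.frame(compound_id = "c1", skeleton_id = "SK_A")
  ds <- skeleton_distribution(occ, asg)
  expect_equal(ds$per_skeleton$n_compounds, 1)
  expect_equal(ds$per_skeleton$n_genera, 3)
  expect_equal(ds$per_skeleton$n_clades, 3)

  # two genera, two clades
  src <- list(dnp = data.frame(compound_id = "c1", taxon_id = c(2001L, 2002L, 2003L)))
  occ <- merge_occurrences(src, tx, cm)
  ds <- skeleton_distribution(occ, asg)
  expect_equal(ds$per_skeleton$n_genera, 2)
  expect_equal(ds$per_skeleton$n_clades, 2)

  # missing assignment errors with the offending id
  expect_error(skeleton_distribution(occ, data.frame(compound_id = "zz",
                                                     skeleton_id = "S")),
               "c1")
})

test_that("counting consistency and monotonicity hold on generated data", {
  cfg <- generator_config(seed = 31, n_compounds = 40)
  cp <- generate_compounds(cfg, lib)
  tx <- generate_taxonomy(cfg)
  oc <- generate_occurrence(cfg, cp, tx)
  src <- split(oc$occurrence[c("compound_id", "taxon_id")],
               oc$occurrence$source_db)
  occ <- merge_occurrences(src, tx$taxonomy, tx$clade_map)
  asg <- lapply(cp$compounds, extract_skeleton, library = lib)
  ds <- skeleton_distribution(occ, asg)
  # sum of per-skeleton compound counts == number of assigned compounds seen
  expect_equal(sum(ds$per_skeleton$n_compounds),
               length(unique(occ$compound_id)))
  # generator marginals match exactly
  m <- oc$marginals[order(oc$marginals$skeleton_id), ]
  p <- ds$per_skeleton[order(ds$per_skeleton$skeleton_id), ]
  expect_equal(p$n_compounds, m$n_compounds)
  expect_equal(p$n_genera, m$n_genera)
  expect_equal(p$n_clades, m$n_clades)
  # adding rows never decreases a genus/clade cell
  extra_sp <- tx$taxonomy$taxon_id[tx$taxonomy$rank == "species"][1]
  occ2 <- merge_occurrences(list(extra = data.frame(
    compound_id = unique(occ$compound_id),
    taxon_id = extra_sp)), tx$taxonomy, tx$clade_map)
  occb <- rbind(occ, occ2)
  ds2 <- skeleton_distribution(occb, asg)
  j <- match(ds$per_skeleton$skeleton_id, ds2$per_skeleton$skeleton_id)
  expect_true(all(ds2$per_skeleton$n_genera[j] >= ds$per_skeleton$n_genera))
  expect_true(all(ds2$per_skeleton$n_clades[j] >= ds$per_skeleton$n_clades))
})

test_that("unknown_route_skeletons is the set difference against known products", {
  ids <- vapply(lib$entries, `[[`, "", "canonical_id")
  dist <- data.frame(skeleton_id = unname(ids))
  known <- data.frame(product_skeleton = c("Sk4 labdane", "Sk2 clerodane",
                                           "Sk4 labdane", "Sk1 kaurane"))
  unk <- unknown_route_skeletons(dist, known, lib)
  expect_equal(length(unk), 3)   # abietane, pimarane, atisane remain
  expect_false(ids[["Sk4 labdane"]] %in% unk)
  # disjoint known set returns everything observed
  unk2 <- unknown_route_skeletons(data.frame(skeleton_id = c("X", "Y")),
                                  known, lib)
  expect_equal(sort(unk2), c("X", "Y"))
})

test_that("database_overlap counts per-source and pairwise intersections", {
  tx <- toy_taxonomy(); cm <- read_clade_map()
  same <- data.frame(compound_id = c("c1", "c2"), taxon_id = 2001L)
  occ <- merge_occurrences(list(a = same, b = same), tx, cm)
  ov <- database_overlap(occ)
  expect_equal(ov$shared_a_b, ov$n_a)
  disj <- merge_occurrences(list(
    a = data.frame(compound_id = "c1", taxon_id = 2001L),
    b = data.frame(compound_id = "c2", taxon_id = 2001L)), tx, cm)
  expect_equal(database_overlap(disj)$shared_a_b, 0)
  expect_error(database_overlap(merge_occurrences(
    list(a = same), tx, cm)), "two sources")
  # brute-force pairwise intersections on a random fixture
  set.seed(12)
  mk <- function() data.frame(
    compound_id = sample(sprintf("c%d", 1:8), 12, replace = TRUE),
    taxon_id = sample(2001:2004, 12, replace = TRUE))
  src <- list(a = mk(), b = mk(), c = mk())
  occ <- merge_occurrences(src, tx, cm)
  ov <- database_overlap(occ)
  for (g in ov$genus) {
    d <- occ[occ$genus == g, ]
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      expect_equal(
        ov[[paste0("shared_", pair[1], "_", pair[2])]][ov$genus == g],
        length(intersect(unique(d$compound_id[d$source_db == pair[1]]),
                         unique(d$compound_id[d$source_db == pair[2]]))))
    }
  }
})

test_that("positional pattern counts use existential mapping semantics", {
  queries <- default_pattern_queries()
  lab <- lib$entries[["Sk4 labdane"]]
  # labdane with a 7,8 double bond: matches Delta7(8), not Delta8(9)
  cpd <- make_reference_compound("lab78", lab, double_bonds = list(c(7, 8)),
                                 hydroxyls = c(13))
  asg <- list(extract_skeleton(cpd, lib))
  r <- positional_pattern_count(list(cpd), asg, lib, queries$labdane_delta7)
  expect_equal(r$n_matching, 1)
  r <- positional_pattern_count(list(cpd), asg, lib, queries$labdane_delta8.9)
  expect_equal(r$n_matching, 0)
  # fully saturated skeleton-only compound never matches a solid double bond
  sat <- make_reference_compound("sat", lab)
  asg2 <- list(extract_skeleton(sat, lib))
  r <- positional_pattern_count(list(sat), asg2, lib, queries$labdane_delta7)
  expect_equal(r$n_matching, 0)
  # clerodane 4(18) epoxide
  cle <- lib$entries[["Sk2 clerodane"]]
  ep <- make_reference_compound("cle-epoxy", cle, epoxides = list(c(4, 18)))
  asg3 <- list(extract_skeleton(ep, lib))
  r <- positional_pattern_count(list(ep), asg3, lib, queries$clerodane_epoxy4.18)
  expect_equal(r$n_matching, 1)
  r <- positional_pattern_count(list(ep), asg3, lib, queries$clerodane_delta4.18)
  expect_equal(r$n_matching, 0)
  # a compound with several satisfying automorphisms still counts once
  expect_error(positional_pattern_count(
    list(cpd), asg, lib,
    pattern_query("bad", "Sk4 labdane",
                  data.frame(kind = "double_bond", p = 7, q = 99,
                             solid = TRUE))),
    "positions")
})

test_that("pattern queries load from YAML and JSON config files", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("- name: labdane Delta7(8)",
               "  scope: Sk4 labdane",
               "  constraints:",
               "    - {kind: double_bond, p: 7, q: 8, solid: true}",
               "    - {kind: any, p: 3, q: 4, solid: false}"), yml)
  q <- read_pattern_queries(yml)[[1]]
  expect_s3_class(q, "pattern_query")
  expect_equal(q$skeleton_scope, "Sk4 labdane")
  expect_equal(nrow(q$constraints), 2)
  lab <- lib$entries[["Sk4 labdane"]]
  cpd <- make_reference_compound("lab78y", lab, double_bonds = list(c(7, 8)))
  asg <- list(extract_skeleton(cpd, lib))
  expect_equal(positional_pattern_count(list(cpd), asg, lib, q)$n_matching, 1)
})

test_that("pattern matching equals the brute-force all-mappings oracle", {
  queries <- default_pattern_queries()
  set.seed(41)
  fixtures <- list()
  for (k in 1:20) {
    scope <- sample(c("Sk4 labdane", "Sk2 clerodane"), 1)
    entry <- lib$entries[[scope]]
    nb <- nrow(entry$skeleton$bonds)
    dbs <- if (runif(1) < 0.7)
      lapply(sample(nb, sample(1:2, 1)), function(b)
        c(entry$skeleton$bonds$i[b], entry$skeleton$bonds$j[b])) else NULL
    eps <- if (runif(1) < 0.3) {
      b <- sample(nb, 1)
      list(c(entry$skeleton$bonds$i[b], entry$skeleton$bonds$j[b]))
    } else NULL
    fixtures[[k]] <- make_reference_compound(sprintf("fx%02d", k), entry,
                                             double_bonds = dbs,
                                             hydroxyls = sample(10, 2),
                                             epoxides = eps)
  }
  asg <- lapply(fixtures, extract_skeleton, library = lib)
  names(asg) <- NULL
  for (q in queries) {
    got <- positional_pattern_count(fixtures, asg, lib, q)$matching_ids
    entry <- lib$entries[[q$skeleton_scope]]
    want <- character(0)
    for (i in seq_along(fixtures)) {
      if (asg[[i]]$skeleton_id != entry$canonical_id) next
      if (oracle_pattern_match(fixtures[[i]]$graph, asg[[i]]$skeleton,
                               entry, q$constraints))
        want <- c(want, fixtures[[i]]$compound_id)
    }
    expect_equal(sort(got), sort(want), info = q$name)
  }
})
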