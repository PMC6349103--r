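#' Synthetic labeled data generation
#'
#' Generates compound libraries with known ground truth by decorating
#' reference skeleton graphs (hydroxylation, carbonyls, desaturation,
#' demethylation, esterification, glycosylation), randomized occurrence
#' tables over a synthetic genus/clade taxonomy, randomized homology hit
#' tables with an exhaustively computed retained set, and peptide sets with
#' planted near-identical clones. Decorations operate directly on the
#' graph with valence bookkeeping, so every generated structure is
#' chemically valid by construction. One seed fixes every byte of output;
#' the sub-generators draw their streams from fixed offsets of the
#' configured seed so they are individually reproducible.
#'
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' @param seed integer seed fixing all randomness end-to-end.
#' @param n_compounds number of compounds to generate.
#' @param templates reference skeleton names to decorate (must exist in
#'   the library; default: all shipped skeletons).
#' @param decorations named list of per-compound application
#'   probabilities: `hydroxylation` (per-site, up to 3 sites), `carbonyl`,
#'   `desaturation`, `demethylation`, `esterification`, `glycosylation`,
#'   all in `[0, 1]`. Demethylation removes a skeleton methyl and so
#'   changes the core (nor-skeletons); it defaults to 0 so the template is
#'   the expected skeleton.
#' @param max_acyl_carbons longest acyl chain attached by esterification
#'   (kept below the core size so no fragment can tie with the skeleton).
#' @param n_genera,n_clades,species_per_genus shape of the synthetic
#'   taxonomy (`n_clades` at most 12; clades are assigned round-robin so
#'   clade marginals are exact by construction).
#' @param occurrence_density probability a compound is reported from a
#'   given species.
#' @param sources source-database tags for occurrence rows.
#' @param n_subjects,n_queries shape of the synthetic hit table.
#' @param hit_boundary_fraction fraction of subjects whose best hit sits
#'   exactly at the identity/coverage thresholds (exercises the inclusive
#'   boundary).
#' @param n_peptides,n_clones peptide set shape for clustering tests.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed, n_compounds = 200, templates = NULL,
                             decorations = list(), max_acyl_carbons = 6,
                             n_genera = 24, n_clades = 12,
                             species_per_genus = 3,
                             occurrence_density = 0.05,
                             sources = c("DNP-like", "SISTEMAT-like"),
                             n_subjects = 60, n_queries = 8,
                             hit_boundary_fraction = 0.1,
                             n_peptides = 12, n_clones = 8) {
  dec <- list(hydroxylation = 0.6, carbonyl = 0.3, desaturation = 0.5,
              demethylation = 0, esterification = 0.3, glycosylation = 0.1)
  dec[names(decorations)] <- decorations
  stopifnot(all(unlist(dec) >= 0), all(unlist(dec) <= 1),
            n_clades <= 12, n_clades >= 1, max_acyl_carbons >= 1,
            occurrence_density >= 0, occurrence_density <= 1)
  structure(list(seed = as.integer(seed), n_compounds = n_compounds,
                 templates = templates, decorations = dec,
                 max_acyl_carbons = max_acyl_carbons, n_genera = n_genera,
                 n_clades = n_clades, species_per_genus = species_per_genus,
                 occurrence_density = occurrence_density, sources = sources,
                 n_subjects = n_subjects, n_queries = n_queries,
                 hit_boundary_fraction = hit_boundary_fraction,
                 n_peptides = n_peptides, n_clones = n_clones),
            class = "generator_config")
}

# ---- graph decoration helpers --------------------------------------------

# Free valence per atom (C: 4, O: 2, others treated as saturated).
mg_free_valence <- function(g) {
  cap <- ifelse(g$atoms$element == "C", 4,
                ifelse(g$atoms$element == "O", 2, 0))
  pmax(cap - mg_valence(g), 0)
}

# Append one atom bonded to `attach`; returns the new graph (no validation
# beyond valence, which callers ensure).
mg_add_atom <- function(g, element, attach, order = 1) {
  atoms <- rbind(g$atoms, data.frame(element = element, charge = 0L))
  bonds <- rbind(g$bonds, data.frame(i = attach, j = nrow(atoms),
                                     order = order))
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

mg_remove_atom <- function(g, idx) {
  keep <- setdiff(seq_len(n_atoms(g)), idx)
  mg_induced(g, keep)
}

# Apply one named decoration in place; returns list(graph, applied).
apply_decoration <- function(g, kind, max_acyl_carbons = 6) {
  free <- mg_free_valence(g)
  carbons <- which(g$atoms$element == "C")
  pick <- function(cand) if (length(cand)) cand[sample.int(length(cand), 1)] else NULL
  switch(kind,
    hydroxylation = {
      at <- pick(carbons[free[carbons] >= 1])
      if (is.null(at)) return(list(graph = g, applied = FALSE))
      list(graph = mg_add_atom(g, "O", at, 1), applied = TRUE)
    },
    carbonyl = {
      at <- pick(carbons[free[carbons] >= 2])
      if (is.null(at)) return(list(graph = g, applied = FALSE))
      list(graph = mg_add_atom(g, "O", at, 2), applied = TRUE)
    },
    desaturation = {
      cc <- which(g$atoms$element[g$bonds$i] == "C" &
                    g$atoms$element[g$bonds$j] == "C" &
                    g$bonds$order == 1 &
                    free[g$bonds$i] >= 1 & free[g$bonds$j] >= 1)
      bk <- pick(cc)
      if (is.null(bk)) return(list(graph = g, applied = FALSE))
      g$bonds$order[bk] <- 2
      list(graph = g, applied = TRUE)
    },
    demethylation = {
      deg1 <- carbons[vapply(carbons, function(a)
        length(mg_neighbors(g, a)), integer(1)) == 1]
      at <- pick(deg1)
      if (is.null(at)) return(list(graph = g, applied = FALSE))
      list(graph = mg_remove_atom(g, at), applied = TRUE)
    },
    esterification = {
      at <- pick(carbons[free[carbons] >= 1])
      if (is.null(at)) return(list(graph = g, applied = FALSE))
      len <- sample.int(max_acyl_carbons, 1)   # acyl carbons incl. carbonyl C
      g <- mg_add_atom(g, "O", at, 1)          # ester oxygen
      o_idx <- n_atoms(g)
      g <- mg_add_atom(g, "C", o_idx, 1)       # carbonyl carbon
      c_idx <- n_atoms(g)
      g <- mg_add_atom(g, "O", c_idx, 2)       # carbonyl oxygen
      prev <- c_idx
      for (k in seq_len(len - 1)) {
        g <- mg_add_atom(g, "C", prev, 1)
        prev <- n_atoms(g)
      }
      list(graph = g, applied = TRUE, acyl_carbons = len)
    },
    glycosylation = {
      at <- pick(carbons[free[carbons] >= 1])
      if (is.null(at)) return(list(graph = g, applied = FALSE))
      g <- mg_add_atom(g, "O", at, 1)          # glycosidic oxygen
      o_link <- n_atoms(g)
      # pyranose: C1..C5 + ring O + C6 on C5; hydroxyls on C2, C3, C4, C6
      g <- mg_add_atom(g, "C", o_link, 1); c1 <- n_atoms(g)
      prev <- c1; ring_c <- c1
      for (k in 2:5) { g <- mg_add_atom(g, "C", prev, 1); prev <- n_atoms(g)
                       ring_c <- c(ring_c, prev) }
      g <- mg_add_atom(g, "O", prev, 1)        # ring oxygen on C5
      ring_o <- n_atoms(g)
      g$bonds <- rbind(g$bonds, data.frame(i = c1, j = ring_o, order = 1))
      g <- structure(g, class = "molgraph")
      g <- mg_add_atom(g, "C", ring_c[5], 1)   # C6
      c6 <- n_atoms(g)
      for (at2 in c(ring_c[2:4], c6)) g <- mg_add_atom(g, "O", at2, 1)
      list(graph = g, applied = TRUE)
    },
    stop("unknown decoration: ", kind))
}

#' Generate a labeled synthetic compound library
#'
#' Each compound starts from a sampled template skeleton and receives
#' random decorations per the configured probabilities. The ground truth
#' records, per compound, the template, the decorations applied, and the
#' expected skeleton ID — the canonical ID of the decorated carbon core
#' (identical to the template's unless demethylation ran).
#'
#' @param config a [generator_config()].
#' @param library a [skeleton_library()] containing the templates.
#' @return list with `compounds` (list of compound records, structure text
#'   as canonical SMILES) and `ground_truth` (data.frame `compound_id`,
#'   `template`, `expected_skeleton_id`, `template_intact`, `decorations`).
#' @export
generate_compounds <- function(config, library = skeleton_library()) {
  stopifnot(inherits(config, "generator_config"))
  templates <- config$templates
  if (is.null(templates)) templates <- names(library$entries)
  stopifnot(all(templates %in% names(library$entries)))
  set.seed(config$seed)
  dec_order <- c("demethylation", "desaturation", "carbonyl",
                 "esterification", "glycosylation")
  compounds <- vector("list", config$n_compounds)
  gt <- vector("list", config$n_compounds)
  for (i in seq_len(config$n_compounds)) {
    tpl <- templates[sample.int(length(templates), 1)]
    g <- library$entries[[tpl]]$skeleton
    applied <- character(0)
    for (kind in dec_order) {
      if (stats::runif(1) < config$decorations[[kind]]) {
        r <- apply_decoration(g, kind, config$max_acyl_carbons)
        if (r$applied) { g <- r$graph; applied <- c(applied, kind) }
      }
    }
    n_oh <- stats::rbinom(1, 3, config$decorations$hydroxylation)
    for (k in seq_len(n_oh)) {
      r <- apply_decoration(g, "hydroxylation")
      if (r$applied) { g <- r$graph; applied <- c(applied, "hydroxylation") }
    }
    g <- standardize(g)
    id <- sprintf("SYN%04d", i)
    # expected skeleton: the fragment holding the template core. Template
    # atoms keep the lowest indices (decorations only append or drop), so
    # the core is the fragment containing atom 1.
    core_frags <- saturate_and_fragment(g)
    core <- core_frags[[which(vapply(core_frags, function(f)
      1L %in% attr(f, "orig_atoms"), logical(1)))[1]]]
    smi <- molgraph_to_smiles(g)
    compounds[[i]] <- list(compound_id = id, name = id,
                           structure_text = smi, graph = g,
                           parse_error = NA_character_,
                           source_db = "synthetic", taxa = character(0))
    gt[[i]] <- data.frame(compound_id = id, template = tpl,
                          expected_skeleton_id = canonical_skeleton_id(core),
                          template_intact = !("demethylation" %in% applied),
                          decorations = paste(applied, collapse = ";"),
                          stringsAsFactors = FALSE)
  }
  list(compounds = compounds, ground_truth = do.call(rbind, gt))
}

#' Generate a synthetic taxonomy and clade map
#'
#' Genera are partitioned into clades round-robin (clade marginals exact
#' by construction), then species are attached to genera.
#'
#' @param config a [generator_config()].
#' @return list with `taxonomy` (taxon-record data.frame) and `clade_map`.
#' @export
generate_taxonomy <- function(config) {
  clade_names <- unique(read_clade_map()$clade)[seq_len(config$n_clades)]
  genera <- sprintf("Genus%03d", seq_len(config$n_genera))
  clade_map <- data.frame(genus = genera,
                          clade = clade_names[(seq_len(config$n_genera) - 1) %%
                                                config$n_clades + 1],
                          stringsAsFactors = FALSE)
  gen_df <- data.frame(taxon_id = 1000L + seq_along(genera),
                       canonical_name = genera, rank = "genus",
                       parent_genus_id = NA_integer_,
                       stringsAsFactors = FALSE)
  sp <- expand.grid(g = seq_along(genera),
                    s = seq_len(config$species_per_genus))
  sp_df <- data.frame(taxon_id = 10000L + seq_len(nrow(sp)),
                      canonical_name = sprintf("%s species%02d",
                                               genera[sp$g], sp$s),
                      rank = "species",
                      parent_genus_id = 1000L + sp$g,
                      stringsAsFactors = FALSE)
  list(taxonomy = rbind(gen_df, sp_df), clade_map = clade_map)
}

#' Generate a synthetic occurrence table with true marginals
#'
#' Each (compound, species) pair is reported with probability
#' `occurrence_density`; each reported pair appears in a non-empty random
#' subset of the configured sources. True per-skeleton marginals (distinct
#' compounds, genera, clades) are computed exhaustively from the sampled
#' rows and the ground-truth skeleton labels.
#'
#' @param config a [generator_config()].
#' @param compounds output of [generate_compounds()].
#' @param taxa output of [generate_taxonomy()].
#' @return list with `occurrence` (data.frame `compound_id`, `taxon_id`,
#'   `source_db`) and `marginals` (data.frame `skeleton_id`,
#'   `n_compounds`, `n_genera`, `n_clades`).
#' @export
generate_occurrence <- function(config, compounds, taxa) {
  set.seed(config$seed + 1L)
  species <- taxa$taxonomy[taxa$taxonomy$rank == "species", ]
  ids <- vapply(compounds$compounds, `[[`, "", "compound_id")
  rows <- list()
  for (cid in ids) {
    hit <- which(stats::runif(nrow(species)) < config$occurrence_density)
    for (s in hit) {
      srcs <- config$sources[stats::runif(length(config$sources)) < 0.7]
      if (length(srcs) == 0)
        srcs <- config$sources[sample.int(length(config$sources), 1)]
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = cid, taxon_id = species$taxon_id[s], source_db = srcs,
        stringsAsFactors = FALSE)
    }
  }
  occurrence <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_id = character(), taxon_id = integer(),
               source_db = character())
  # exhaustive true marginals from the sampled rows
  sk <- stats::setNames(compounds$ground_truth$expected_skeleton_id,
                        compounds$ground_truth$compound_id)
  gmap <- stats::setNames(
    taxa$taxonomy$canonical_name[match(species$parent_genus_id,
                                       taxa$taxonomy$taxon_id)],
    species$taxon_id)
  cmap <- stats::setNames(taxa$clade_map$clade, taxa$clade_map$genus)
  marg <- list()
  for (skel in sort(unique(unname(sk[occurrence$compound_id])))) {
    sub <- occurrence[sk[occurrence$compound_id] == skel, , drop = FALSE]
    genera <- unique(unname(gmap[as.character(sub$taxon_id)]))
    marg[[length(marg) + 1]] <- data.frame(
      skeleton_id = skel, n_compounds = length(unique(sub$compound_id)),
      n_genera = length(genera),
      n_clades = length(unique(unname(cmap[genera]))),
      stringsAsFactors = FALSE)
  }
  marginals <- if (length(marg)) do.call(rbind, marg) else
    data.frame(skeleton_id = character(), n_compounds = integer(),
               n_genera = integer(), n_clades = integer())
  list(occurrence = occurrence, marginals = marginals)
}

#' Generate a synthetic homology hit table with ground truth
#'
#' Identities and coverages are drawn uniformly with a configured fraction
#' of subjects planted exactly at the filtering boundary (identity 35.0,
#' coverage 70). The ground-truth retained set is computed by exhaustive
#' application of the filtering rule, independent of
#' [filter_candidates()].
#'
#' @param config a [generator_config()].
#' @param filter a [filter_config()] defining the ground-truth rule.
#' @return list with `hits` (parsed-schema data.frame), `query_lengths`
#'   (named vector), `retained_truth` (character vector of subject ids).
#' @export
generate_hits <- function(config, filter = filter_config()) {
  set.seed(config$seed + 2L)
  qids <- sprintf("Q%02d", seq_len(config$n_queries))
  qlen <- stats::setNames(sample(300:800, config$n_queries, replace = TRUE),
                          qids)
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%03d", s)
    n_hit <- sample.int(3, 1)
    at_boundary <- stats::runif(1) < config$hit_boundary_fraction
    for (h in seq_len(n_hit)) {
      q <- qids[sample.int(length(qids), 1)]
      L <- qlen[[q]]
      if (at_boundary && h == 1) {
        ident <- filter$min_identity
        span <- ceiling(L * filter$min_coverage / 100)
      } else {
        ident <- round(stats::runif(1, 15, 99), 1)
        span <- sample.int(L, 1)
      }
      qs <- sample.int(L - span + 1, 1)
      bits <- round(stats::runif(1, 50, 800), 1)
      if (at_boundary && h == 1) bits <- 1000  # boundary hit is the best hit
      rows[[length(rows) + 1]] <- data.frame(
        query_id = q, subject_id = sid, percent_identity = ident,
        alignment_length = span, mismatches = round(span * (1 - ident / 100)),
        gap_opens = 0L, q_start = qs, q_end = qs + span - 1L,
        s_start = 1L, s_end = span, evalue = 10^-stats::runif(1, 5, 50),
        bitscore = bits, query_length = as.numeric(L),
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  # exhaustive ground truth, written as a direct transcription of the rule
  retained <- character(0)
  for (sid in unique(hits$subject_id)) {
    d <- hits[hits$subject_id == sid, ]
    best <- NULL
    for (k in seq_len(nrow(d))) {
      if (is.null(best) || d$bitscore[k] > best$bitscore ||
          (d$bitscore[k] == best$bitscore &&
             d$percent_identity[k] > best$percent_identity) ||
          (d$bitscore[k] == best$bitscore &&
             d$percent_identity[k] == best$percent_identity &&
             d$query_id[k] < best$query_id))
        best <- d[k, ]
    }
    cov <- 100 * (best$q_end - best$q_start + 1) / best$query_length
    if (!(best$percent_identity < filter$min_identity ||
            cov < filter$min_coverage))
      retained <- c(retained, sid)
  }
  list(hits = hits, query_lengths = qlen, retained_truth = sort(retained))
}

#' Generate synthetic peptides with planted clusters
#'
#' Random base peptides plus clones mutated at a few percent of positions,
#' so clusters at a high identity threshold are known by construction.
#'
#' @param config a [generator_config()].
#' @param mutation_rate per-position substitution probability for clones.
#' @return list with `seqs` (named character vector) and `clone_of`
#'   (named character: clone id -> base id).
#' @export
generate_peptides <- function(config, mutation_rate = 0.02) {
  set.seed(config$seed + 3L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- stats::setNames(vapply(seq_len(config$n_peptides), function(i)
    paste(sample(aa, sample(80:120, 1), replace = TRUE), collapse = ""),
    character(1)), sprintf("P%03d", seq_len(config$n_peptides)))
  clones <- character(0); clone_of <- character(0)
  for (k in seq_len(config$n_clones)) {
    src <- sample(names(base), 1)
    s <- strsplit(base[[src]], "")[[1]]
    mut <- stats::runif(length(s)) < mutation_rate
    s[mut] <- sample(aa, sum(mut), replace = TRUE)
    nm <- sprintf("P%03dc%d", match(src, names(base)), k)
    clones[nm] <- paste(s, collapse = "")
    clone_of[nm] <- src
  }
  list(seqs = c(base, clones), clone_of = clone_of)
}

#' Generate and write a full synthetic data set
#'
#' Writes the SMILES list, ground-truth CSV, taxonomy CSV, clade CSV,
#' occurrence CSV, 12-column hit table, and peptide FASTA that exercise
#' every analysis stage. All output is plain text and reproducible
#' byte-for-byte from the seed.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @param library a [skeleton_library()].
#' @return invisibly, a named list of the file paths written.
#' @export
generate_dataset <- function(config, out_dir, library = skeleton_library()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  cp <- generate_compounds(config, library)
  writeLines(vapply(cp$compounds, function(r)
    paste(r$structure_text, r$compound_id, sep = "\t"), character(1)),
    p("compounds.smi"))
  utils::write.csv(cp$ground_truth, p("ground_truth.csv"), row.names = FALSE)
  tx <- generate_taxonomy(config)
  utils::write.csv(tx$taxonomy, p("taxonomy.csv"), row.names = FALSE)
  utils::write.csv(tx$clade_map, p("clades.csv"), row.names = FALSE)
  oc <- generate_occurrence(config, cp, tx)
  utils::write.csv(oc$occurrence, p("occurrence.csv"), row.names = FALSE)
  ht <- generate_hits(config)
  hit_cols <- c("query_id", "subject_id", "percent_identity",
                "alignment_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")
  utils::write.table(ht$hits[hit_cols], p("hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  set.seed(config$seed + 4L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  queries <- vapply(ht$query_lengths, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(queries),
                              p("queries.fasta"))
  pp <- generate_peptides(config)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(pp$seqs),
                              p("peptides.fasta"))
  invisible(list(compounds = p("compounds.smi"), queries = p("queries.fasta"),
                 ground_truth = p("ground_truth.csv"),
                 taxonomy = p("taxonomy.csv"), clades = p("clades.csv"),
                 occurrence = p("occurrence.csv"), hits = p("hits.tsv"),
                 peptides = p("peptides.fasta")))
}
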