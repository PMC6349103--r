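#' Chemotaxonomic distribution statistics
#'
#' Merges compound occurrence data across source databases, computes
#' per-skeleton and per-genus distribution summaries (how many genera and
#' how many of the 12 primary clades each skeleton has been reported in,
#' how many compounds each skeleton accounts for), the set of skeletons
#' with no known biosynthetic route, database overlap comparisons, and
#' counts of compounds matching positional structural patterns on numbered
#' reference skeletons.
#'
#' @name chemotax
NULL

#' Merge per-source occurrence tables
#'
#' @param sources named list of data.frames, each with columns
#'   `compound_id` and `taxon_id` (taxa already resolved; unresolved rows
#'   carry `NA` and are excluded with a logged count). The list names
#'   become the `source_db` tags.
#' @param taxonomy taxonomy data.frame from [read_taxonomy()].
#' @param clade_map data.frame from [read_clade_map()].
#' @return data.frame (`compound_id`, `taxon_id`, `genus`, `clade`,
#'   `source_db`), deduplicated on (`compound_id`, `taxon_id`,
#'   `source_db`); the number of excluded unresolved rows is attached as
#'   attribute `n_unresolved`.
#' @export
merge_occurrences <- function(sources, taxonomy, clade_map) {
  stopifnot(is.list(sources), !is.null(names(sources)))
  rows <- lapply(names(sources), function(src) {
    df <- sources[[src]]
    if (is.null(df) || nrow(df) == 0) return(NULL)
    data.frame(compound_id = as.character(df$compound_id),
               taxon_id = df$taxon_id, source_db = src,
               stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, rows)
  if (is.null(occ) || nrow(occ) == 0) {
    out <- data.frame(compound_id = character(), taxon_id = integer(),
                      genus = character(), clade = character(),
                      source_db = character())
    attr(out, "n_unresolved") <- 0L
    return(out)
  }
  unresolved <- is.na(occ$taxon_id)
  if (any(unresolved))
    message(sprintf("excluded %d occurrence row(s) with unresolved taxa",
                    sum(unresolved)))
  occ <- occ[!unresolved, , drop = FALSE]
  occ <- occ[!duplicated(occ[c("compound_id", "taxon_id", "source_db")]), ,
             drop = FALSE]
  ti <- match(occ$taxon_id, taxonomy$taxon_id)
  if (anyNA(ti)) stop("occurrence taxon_id absent from taxonomy: ",
                      paste(unique(occ$taxon_id[is.na(ti)]), collapse = ", "))
  # genus of a species record is its parent; of a genus record, itself
  gid <- ifelse(taxonomy$rank[ti] == "species",
                taxonomy$parent_genus_id[ti], taxonomy$taxon_id[ti])
  gname <- taxonomy$canonical_name[match(gid, taxonomy$taxon_id)]
  occ$genus <- vapply(strsplit(gname, "\\s+"), `[`, "", 1)
  occ$clade <- assign_clade(occ$genus, clade_map)
  occ <- occ[order(occ$compound_id, occ$taxon_id, occ$source_db),
             c("compound_id", "taxon_id", "genus", "clade", "source_db")]
  rownames(occ) <- NULL
  attr(occ, "n_unresolved") <- sum(unresolved)
  occ
}

#' Skeleton and genus distribution summaries
#'
#' For each skeleton: the number of distinct compounds bearing it, distinct
#' genera and distinct primary clades it has been reported in (a compound
#' counts once per skeleton; `unassigned` clades are not counted against
#' the 12). For each genus: distinct compounds, distinct skeletons, and
#' per-source compound counts.
#'
#' @param occ occurrence data.frame from [merge_occurrences()].
#' @param assignments list of skeleton assignments from
#'   [extract_skeleton()] (or a data.frame with `compound_id`,
#'   `skeleton_id`); every compound in `occ` must be assigned.
#' @return object of class `distribution_summary`: list with data.frames
#'   `per_skeleton` (`skeleton_id`, `n_compounds`, `n_genera`, `n_clades`)
#'   and `per_genus` (`genus`, `n_compounds`, `n_skeletons`, one
#'   `n_<source>` column per source).
#' @export
skeleton_distribution <- function(occ, assignments) {
  amap <- assignment_map(assignments)
  missing <- setdiff(unique(occ$compound_id), names(amap))
  if (length(missing))
    stop("no skeleton assignment for compound(s): ",
         paste(missing, collapse = ", "))
  occ$skeleton_id <- unname(amap[occ$compound_id])
  per_skeleton <- if (nrow(occ)) {
    sk <- split(occ, occ$skeleton_id)
    do.call(rbind, lapply(sk, function(d) data.frame(
      skeleton_id = d$skeleton_id[1],
      n_compounds = length(unique(d$compound_id)),
      n_genera = length(unique(d$genus)),
      n_clades = length(unique(d$clade[d$clade != "unassigned"])),
      stringsAsFactors = FALSE)))
  } else {
    data.frame(skeleton_id = character(), n_compounds = integer(),
               n_genera = integer(), n_clades = integer())
  }
  per_genus <- if (nrow(occ)) {
    srcs <- sort(unique(occ$source_db))
    gn <- split(occ, occ$genus)
    do.call(rbind, lapply(gn, function(d) {
      row <- data.frame(genus = d$genus[1],
                        n_compounds = length(unique(d$compound_id)),
                        n_skeletons = length(unique(d$skeleton_id)),
                        stringsAsFactors = FALSE)
      for (s in srcs)
        row[[paste0("n_", gsub("[^A-Za-z0-9]", "_", s))]] <-
          length(unique(d$compound_id[d$source_db == s]))
      row
    }))
  } else {
    data.frame(genus = character(), n_compounds = integer(),
               n_skeletons = integer())
  }
  rownames(per_skeleton) <- rownames(per_genus) <- NULL
  structure(list(per_skeleton = per_skeleton, per_genus = per_genus),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary> %d skeleton(s), %d genus(era)\n",
              nrow(x$per_skeleton), nrow(x$per_genus)))
  invisible(x)
}

# compound_id -> skeleton_id lookup from a list of assignments or a df.
assignment_map <- function(assignments) {
  if (is.data.frame(assignments)) {
    stats::setNames(as.character(assignments$skeleton_id),
                    assignments$compound_id)
  } else {
    stats::setNames(vapply(assignments, `[[`, "", "skeleton_id"),
                    vapply(assignments, `[[`, "", "compound_id"))
  }
}

#' Skeletons with no known biosynthetic route
#'
#' Set difference between the observed skeletons and the skeletons of
#' known enzyme products.
#'
#' @param distribution a `distribution_summary` (or data.frame with a
#'   `skeleton_id` column).
#' @param known_enzyme_products data.frame with a `product_skeleton` column
#'   holding reference skeleton names (enzyme reference table schema).
#' @param library [skeleton_library()] used to map reference names to
#'   canonical skeleton IDs.
#' @return character vector of skeleton IDs lacking a known route.
#' @export
unknown_route_skeletons <- function(distribution, known_enzyme_products,
                                    library) {
  per_sk <- if (inherits(distribution, "distribution_summary"))
    distribution$per_skeleton else distribution
  observed <- unique(as.character(per_sk$skeleton_id))
  refs <- unique(known_enzyme_products$product_skeleton)
  refs <- refs[!is.na(refs) & nzchar(refs)]
  known_ids <- vapply(refs, function(r)
    library_entry(library, r)$canonical_id, character(1))
  sort(setdiff(observed, known_ids))
}

#' Per-genus comparison between source databases
#'
#' For each genus, the number of distinct compounds per source and, for
#' every source pair, the size of the compound-id intersection.
#'
#' @param occ occurrence data.frame with at least two distinct `source_db`
#'   values.
#' @return data.frame with one row per genus: `genus`, one `n_<source>`
#'   count per source, one `shared_<a>_<b>` intersection count per source
#'   pair.
#' @export
database_overlap <- function(occ) {
  srcs <- sort(unique(occ$source_db))
  if (length(srcs) < 2) stop("database_overlap needs at least two sources")
  safe <- function(s) gsub("[^A-Za-z0-9]", "_", s)
  gn <- split(occ, occ$genus)
  out <- do.call(rbind, lapply(gn, function(d) {
    row <- data.frame(genus = d$genus[1], stringsAsFactors = FALSE)
    sets <- lapply(srcs, function(s) unique(d$compound_id[d$source_db == s]))
    names(sets) <- srcs
    for (s in srcs) row[[paste0("n_", safe(s))]] <- length(sets[[s]])
    for (a in seq_along(srcs)) for (b in seq_along(srcs)) if (a < b)
      row[[paste0("shared_", safe(srcs[a]), "_", safe(srcs[b]))]] <-
        length(intersect(sets[[a]], sets[[b]]))
    row
  }))
  rownames(out) <- NULL
  out
}

# --- positional pattern queries -------------------------------------------

#' Define a positional pattern query
#'
#' A query is scoped to one reference skeleton and lists constraints at
#' numbered positions. Solid constraints must hold in the original
#' (pre-saturation) structure under at least one isomorphism of the
#' compound's skeleton onto the reference; dashed positions are wildcards
#' (any bond or substituent) and thus carry no computational constraint —
#' they may be listed for documentation and are validated but ignored.
#'
#' Constraint kinds: `double_bond` (order-2 bond between the atoms at the
#' two positions; an aromatic bond also satisfies it), `epoxide_bridge`
#' (the two atoms are bonded and share one oxygen neighbor, forming a
#' three-membered C-O-C ring), `any` (explicit wildcard).
#'
#' @param name query label.
#' @param skeleton_scope reference skeleton name (e.g. `"Sk4 labdane"`).
#' @param constraints data.frame with columns `kind`, `p`, `q` (skeleton
#'   position numbers) and logical `solid`.
#' @return object of class `pattern_query`.
#' @export
pattern_query <- function(name, skeleton_scope, constraints) {
  stopifnot(is.data.frame(constraints),
            all(c("kind", "p", "q", "solid") %in% names(constraints)),
            all(constraints$kind %in% c("double_bond", "epoxide_bridge",
                                        "any")))
  structure(list(name = name, skeleton_scope = skeleton_scope,
                 constraints = constraints), class = "pattern_query")
}

#' Shipped positional pattern queries
#'
#' The queries behind the clade-distribution pattern counts for labdanes
#' and clerodanes: desaturation at 7(8) and 8(9) on the labdane skeleton,
#' desaturation at 3(4) and 4(18) and the 4(18)-epoxide on the clerodane
#' skeleton. All positions other than the constrained pair are wildcards.
#'
#' @return named list of [pattern_query()] objects.
#' @export
default_pattern_queries <- function() {
  q <- function(name, scope, kind, p, qq)
    pattern_query(name, scope, data.frame(kind = kind, p = p, q = qq,
                                          solid = TRUE))
  list(
    labdane_delta7   = q("labdane Delta7(8)",  "Sk4 labdane", "double_bond", 7, 8),
    labdane_delta8.9 = q("labdane Delta8(9)",  "Sk4 labdane", "double_bond", 8, 9),
    clerodane_delta3 = q("clerodane Delta3(4)", "Sk2 clerodane", "double_bond", 3, 4),
    clerodane_delta4.18 = q("clerodane Delta4(18)", "Sk2 clerodane",
                            "double_bond", 4, 18),
    clerodane_epoxy4.18 = q("clerodane 4(18)-epoxy", "Sk2 clerodane",
                            "epoxide_bridge", 4, 18))
}

#' Read pattern queries from a configuration file
#'
#' YAML or JSON: a list of entries with `name`, `scope` (reference skeleton
#' name), and `constraints`, each with `kind`, `p`, `q`, and `solid`
#' (default true; dashed/wildcard positions may be listed with
#' `solid: false`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list of [pattern_query()] objects.
#' @export
read_pattern_queries <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(spec, function(s) {
    cons <- do.call(rbind, lapply(s$constraints, function(co)
      data.frame(kind = co$kind, p = as.integer(co$p), q = as.integer(co$q),
                 solid = if (is.null(co$solid)) TRUE else isTRUE(co$solid))))
    pattern_query(s$name, s$scope, cons)
  })
  stats::setNames(out, vapply(spec, `[[`, "", "name"))
}

#' Count compounds matching a positional pattern
#'
#' A compound matches when its extracted skeleton is isomorphic to the
#' query's reference skeleton and at least one isomorphism mapping of the
#' reference onto the skeleton satisfies every solid constraint in the
#' original structure (existential semantics over automorphisms: a
#' compound never counts twice).
#'
#' @param compounds list of compound records (graphs needed).
#' @param assignments matching list of skeleton assignments from
#'   [extract_skeleton()] (must retain the `skeleton` fragment).
#' @param library [skeleton_library()].
#' @param query a [pattern_query()].
#' @param occ optional occurrence data.frame; when given, a per-clade
#'   breakdown of matching compounds is returned.
#' @return list with `n_matching`, `matching_ids`, and (when `occ` given)
#'   `per_clade` (data.frame `clade`, `n_compounds`).
#' @export
positional_pattern_count <- function(compounds, assignments, library, query,
                                     occ = NULL) {
  stopifnot(inherits(query, "pattern_query"))
  entry <- library_entry(library, query$skeleton_scope)
  npos <- n_atoms(entry$skeleton)
  cons <- query$constraints
  bad <- !(cons$p %in% seq_len(npos)) | !(cons$q %in% seq_len(npos))
  if (any(bad)) stop("query positions outside the scoped skeleton numbering")
  cons <- cons[cons$solid & cons$kind != "any", , drop = FALSE]
  amap <- stats::setNames(assignments,
                          vapply(assignments, `[[`, "", "compound_id"))
  matching <- character(0)
  for (cpd in compounds) {
    a <- amap[[cpd$compound_id]]
    if (is.null(a) || a$skeleton_id != entry$canonical_id) next
    if (pattern_matches(cpd$graph, a$skeleton, entry, cons))
      matching <- c(matching, cpd$compound_id)
  }
  out <- list(n_matching = length(matching), matching_ids = matching)
  if (!is.null(occ)) {
    hit <- occ[occ$compound_id %in% matching, , drop = FALSE]
    per_clade <- if (nrow(hit)) {
      cl <- split(hit, hit$clade)
      do.call(rbind, lapply(cl, function(d) data.frame(
        clade = d$clade[1], n_compounds = length(unique(d$compound_id)),
        stringsAsFactors = FALSE)))
    } else data.frame(clade = character(), n_compounds = integer())
    rownames(per_clade) <- NULL
    out$per_clade <- per_clade
  }
  out
}

# Does any isomorphism reference -> skeleton fragment satisfy all solid
# constraints in the original structure? `skeleton` carries orig_atoms.
pattern_matches <- function(graph, skeleton, entry, cons) {
  if (nrow(cons) == 0) return(TRUE)
  maps <- igraph::isomorphisms(mg_to_igraph(entry$skeleton),
                               mg_to_igraph(skeleton))
  orig <- attr(skeleton, "orig_atoms")
  for (mp in maps) {
    to_frag <- as.integer(mp)        # reference position -> fragment atom
    ok <- TRUE
    for (k in seq_len(nrow(cons))) {
      a <- orig[to_frag[entry$positions[[as.character(cons$p[k])]]]]
      b <- orig[to_frag[entry$positions[[as.character(cons$q[k])]]]]
      ok <- switch(cons$kind[k],
        double_bond = {
          o <- mg_bond_order(graph, a, b)
          !is.na(o) && (o == 2 || o == 1.5)
        },
        epoxide_bridge = {
          o <- mg_bond_order(graph, a, b)
          if (is.na(o)) FALSE else {
            shared <- intersect(mg_neighbors(graph, a), mg_neighbors(graph, b))
            any(graph$atoms$element[shared] == "O")
          }
        })
      if (!ok) break
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Read an enzyme reference table
#'
#' Schema of the curated enzyme reference set: columns `enzyme`, `class`,
#' `substrate`, `product`, `product_skeleton` (reference skeleton name).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_enzyme_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "class", "substrate", "product", "product_skeleton")
  if (!all(need %in% names(df)))
    stop("enzyme reference needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a skeleton-occurrence table
#'
#' Schema of a curated skeleton-distribution tabulation: one row per
#' (skeleton, genus) with columns `skeleton_id` (or `skeleton`), `genus`,
#' and optionally `clade`, `n_compounds`, `source_db`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_skeleton_occurrence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("skeleton" %in% names(df) && !"skeleton_id" %in% names(df))
    names(df)[names(df) == "skeleton"] <- "skeleton_id"
  if (!all(c("skeleton_id", "genus") %in% names(df)))
    stop("skeleton occurrence table needs columns skeleton_id (or skeleton) and genus")
  df
}
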