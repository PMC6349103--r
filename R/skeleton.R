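#' Carbon-skeleton extraction
#'
#' The skeleton of a compound is its core alkane: all bonds are converted to
#' single bonds, every bond involving at least one non-carbon atom is
#' broken, and among the resulting all-carbon fragments the one with a
#' carbon count closest to a target (20 for diterpenes) is retained. The
#' retained fragment is canonicalized so that identical skeletons from
#' different compounds deduplicate by string equality.
#'
#' @name skeleton
NULL

#' Saturate a structure and fragment it at heteroatoms
#'
#' All bond orders are set to 1, bonds touching a non-carbon atom are
#' broken, non-carbon atoms are discarded, and the remaining carbon graph
#' is split into connected components. The union of fragments covers
#' exactly the carbon atoms of the input (asserted).
#'
#' @param graph a standardized [molgraph] with at least one carbon atom.
#' @return list of connected all-carbon, all-single-bond `molgraph`
#'   fragments; each carries the original atom indices in attribute
#'   `orig_atoms`.
#' @export
saturate_and_fragment <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  carbons <- which(graph$atoms$element == "C")
  if (length(carbons) == 0) stop("no carbon skeleton")
  core <- mg_induced(graph, carbons)
  core$bonds$order <- rep(1, nrow(core$bonds))  # saturation
  orig <- attr(core, "orig_atoms")
  comp <- mg_components(core)
  frags <- lapply(sort(unique(comp)), function(cc) {
    idx <- which(comp == cc)
    f <- mg_induced(core, idx)
    attr(f, "orig_atoms") <- orig[attr(f, "orig_atoms")]
    f
  })
  total <- sum(vapply(frags, n_atoms, integer(1)))
  stopifnot(total == length(carbons))  # carbon conservation
  frags
}

#' Canonical identifier for a carbon skeleton fragment
#'
#' Two fragments receive the same ID iff their unlabeled graphs are
#' isomorphic. The ID is built from a canonical labeling (BLISS, via
#' igraph) of the saturated hydrocarbon: atom count plus the sorted edge
#' list under canonical labels.
#'
#' @param fragment connected all-carbon single-bond `molgraph`.
#' @return a deterministic string identifier.
#' @export
canonical_skeleton_id <- function(fragment) {
  stopifnot(inherits(fragment, "molgraph"))
  n <- n_atoms(fragment)
  if (n == 0) stop("empty fragment")
  if (length(unique(mg_components(fragment))) != 1)
    stop("fragment is disconnected")
  if (nrow(fragment$bonds) == 0) return(sprintf("C%d:", n))
  ig <- mg_to_igraph(fragment)
  perm <- igraph::canonical_permutation(ig)$labeling
  cg <- igraph::permute(ig, perm)
  e <- igraph::as_edgelist(cg, names = FALSE)
  e <- t(apply(e, 1, sort))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  sprintf("C%d:%s", n, paste(e[, 1], e[, 2], sep = "-", collapse = ";"))
}

#' Choose the skeleton fragment
#'
#' Retains the fragment whose carbon count is closest to `target`. Ties
#' within `margin` are broken deterministically: more rings, then more
#' carbons, then smaller canonical ID; when a runner-up sits within
#' `margin` of the best distance the assignment is flagged ambiguous for
#' review. A per-compound override (canonical skeleton ID) replaces the
#' automatic choice, mirroring manual curation of wrong-fragment cases.
#'
#' @param fragments non-empty list of carbon fragments from
#'   [saturate_and_fragment()].
#' @param target carbon count the skeleton should be closest to
#'   (20 for diterpenes).
#' @param margin distance slack within which a runner-up marks the choice
#'   ambiguous (0 = exact ties only).
#' @param overrides optional named character vector or list mapping
#'   `compound_id` to a chosen fragment canonical ID.
#' @param compound_id id used to look up `overrides`.
#' @return list with `fragment` (the chosen `molgraph`), `ambiguous`,
#'   `override_applied`.
#' @export
select_skeleton_fragment <- function(fragments, target = 20, margin = 0,
                                     overrides = NULL, compound_id = NULL) {
  if (length(fragments) == 0) stop("empty fragment list")
  nc <- vapply(fragments, n_atoms, integer(1))
  dist <- abs(nc - target)
  rings <- vapply(fragments, ring_count, integer(1))
  ids <- vapply(fragments, canonical_skeleton_id, character(1))
  ord <- order(dist, -rings, -nc, ids)
  best <- ord[1]
  ambiguous <- length(fragments) > 1 && (dist[ord[2]] - dist[best]) <= margin
  override_applied <- FALSE
  if (!is.null(overrides) && !is.null(compound_id) &&
      compound_id %in% names(overrides)) {
    want <- overrides[[compound_id]]
    hit <- which(ids == want)
    if (length(hit)) {
      best <- hit[1]
      override_applied <- TRUE
      ambiguous <- FALSE
    } else {
      warning(sprintf("override for %s names no fragment of this compound",
                      compound_id))
    }
  }
  list(fragment = fragments[[best]], ambiguous = ambiguous,
       override_applied = override_applied)
}

#' Extract and classify the skeleton of one compound
#'
#' Composes saturation/fragmentation, fragment selection, and canonical
#' identification, then matches the skeleton against a reference library by
#' graph isomorphism (canonical-ID equality). Idempotent on pure skeletons:
#' extracting from a bare skeleton returns the identical ID.
#'
#' @param compound a compound record (needs `compound_id` and `graph`).
#' @param library a [skeleton_library()]; `NULL` to skip reference naming.
#' @param target,margin,overrides passed to [select_skeleton_fragment()].
#' @return a skeleton assignment: list with `compound_id`, `skeleton_id`,
#'   `carbon_count`, `ring_count`, `reference_name`,
#'   `fragment_carbon_counts` (sorted), `ambiguous`, `override_applied`,
#'   and `skeleton` (the fragment `molgraph`, original atom indices in
#'   attribute `orig_atoms`).
#' @export
extract_skeleton <- function(compound, library = NULL, target = 20,
                             margin = 0, overrides = NULL) {
  if (is.null(compound$graph)) stop("compound has no parsed structure: ",
                                    compound$compound_id)
  frags <- saturate_and_fragment(compound$graph)
  sel <- select_skeleton_fragment(frags, target = target, margin = margin,
                                  overrides = overrides,
                                  compound_id = compound$compound_id)
  frag <- sel$fragment
  id <- canonical_skeleton_id(frag)
  fcc <- sort(vapply(frags, n_atoms, integer(1)))
  stopifnot(sum(fcc) == n_carbons(compound$graph),
            n_atoms(frag) %in% fcc)
  ref <- NA_character_
  if (!is.null(library)) {
    hit <- match(id, vapply(library$entries, `[[`, "", "canonical_id"))
    if (!is.na(hit)) ref <- library$entries[[hit]]$reference_name
  }
  list(compound_id = compound$compound_id, skeleton_id = id,
       carbon_count = n_atoms(frag), ring_count = ring_count(frag),
       reference_name = ref, fragment_carbon_counts = fcc,
       ambiguous = sel$ambiguous, override_applied = sel$override_applied,
       skeleton = frag)
}

#' Deduplicate skeleton assignments
#'
#' @param assignments list of assignments from [extract_skeleton()].
#' @return data.frame with one row per distinct `skeleton_id`
#'   (`skeleton_id`, `carbon_count`, `reference_name`, `n_compounds`),
#'   ordered by decreasing `n_compounds` then ID; `n_compounds` sums to the
#'   number of assignments.
#' @export
dedup_skeletons <- function(assignments) {
  if (length(assignments) == 0)
    return(data.frame(skeleton_id = character(), carbon_count = integer(),
                      reference_name = character(), n_compounds = integer()))
  df <- data.frame(
    skeleton_id = vapply(assignments, `[[`, "", "skeleton_id"),
    carbon_count = vapply(assignments, `[[`, 0L, "carbon_count"),
    reference_name = vapply(assignments, `[[`, "", "reference_name"),
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n_compounds = df$skeleton_id),
                          by = df[c("skeleton_id", "carbon_count",
                                    "reference_name")], FUN = length)
  agg <- agg[order(-agg$n_compounds, agg$skeleton_id), ]
  rownames(agg) <- NULL
  agg
}

#' Flatten skeleton assignments to a data.frame
#'
#' One row per assignment, with `fragment_carbon_counts` collapsed by `;`
#' — the layout written by the `extract` command line.
#'
#' @param assignments list of assignments from [extract_skeleton()].
#' @return data.frame.
#' @export
assignments_table <- function(assignments) {
  do.call(rbind, lapply(assignments, function(a) {
    data.frame(compound_id = a$compound_id, skeleton_id = a$skeleton_id,
               carbon_count = a$carbon_count,
               reference_name = a$reference_name, ambiguous = a$ambiguous,
               override_applied = a$override_applied,
               fragment_carbon_counts = paste(a$fragment_carbon_counts,
                                              collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
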