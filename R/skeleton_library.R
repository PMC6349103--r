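#' Reference skeleton library
#'
#' Loads a library of named reference skeletons with position numbering.
#' The shipped library covers the diterpene skeletons most widely
#' distributed in the Lamiaceae — kaurane (Sk1), clerodane (Sk2), abietane
#' (Sk3), labdane (Sk4), pimarane (Sk6), and atisane (Sk14) — built from
#' the standard diterpene numbering (decalin positions 1-10, side chain and
#' C/D-ring carbons 11-16, methyl carbons 17-20). Atom `k` of each entry's
#' graph is skeleton position `k`, so the numbering map is the identity.
#'
#' @param path JSON file describing the skeletons; default is the shipped
#'   library.
#' @return object of class `skeleton_library`: list with `entries`, each a
#'   list of `reference_name`, `skeleton` ([molgraph]), `positions` (named
#'   integer map position -> atom index), `canonical_id`.
#' @export
skeleton_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "skeleton_library.json",
                        package = "skeletax", mustWork = TRUE)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  entries <- lapply(spec$skeletons, function(s) {
    edges <- do.call(rbind, lapply(s$edges, as.integer))
    g <- graph_from_edges(s$carbons, edges)
    if (length(unique(mg_components(g))) != 1)
      stop("library skeleton not connected: ", s$reference_name)
    pos <- stats::setNames(seq_len(s$carbons), as.character(seq_len(s$carbons)))
    list(reference_name = s$reference_name, skeleton = g, positions = pos,
         canonical_id = canonical_skeleton_id(g))
  })
  nm <- vapply(entries, `[[`, "", "reference_name")
  if (anyDuplicated(nm)) stop("duplicate reference names in library")
  ids <- vapply(entries, `[[`, "", "canonical_id")
  if (anyDuplicated(ids)) stop("library contains isomorphic duplicate skeletons")
  structure(list(entries = stats::setNames(entries, nm)), class = "skeleton_library")
}

#' @export
print.skeleton_library <- function(x, ...) {
  cat(sprintf("<skeleton_library> %d entries: %s\n", length(x$entries),
              paste(names(x$entries), collapse = ", ")))
  invisible(x)
}

# Fetch one entry by reference name (exact match).
library_entry <- function(library, reference_name) {
  e <- library$entries[[reference_name]]
  if (is.null(e)) stop("unknown reference skeleton: ", reference_name)
  e
}
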