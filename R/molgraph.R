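#' Molecular graph objects
#'
#' A `molgraph` is an element-labeled, bond-order-labeled undirected graph
#' describing one compound record (possibly with several connected
#' components, e.g. salts). Hydrogens are always implicit: explicit hydrogen
#' atoms are collapsed on construction. Atom indices are 1-based and
#' contiguous; bonds are stored once per atom pair with `i < j`.
#'
#' Bond orders are numeric: 1, 2, 3, or 1.5 for aromatic bonds that were not
#' kekulized by the source format.
#'
#' @param atoms data.frame with columns `element` (chemical symbol) and
#'   `charge` (integer formal charge).
#' @param bonds data.frame with columns `i`, `j` (atom indices) and `order`.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds) {
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      stringsAsFactors = FALSE)
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.numeric(bonds$order))
  }
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint outside atom range")
    if (any(bonds$i == bonds$j)) stop("self-loop bond")
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    key <- paste(bonds$i, bonds$j)
    if (anyDuplicated(key)) stop("duplicate bond between an atom pair")
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  g <- structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
  collapse_hydrogens(g)
}

collapse_hydrogens <- function(g) {
  is_h <- g$atoms$element %in% c("H", "D", "T")
  if (!any(is_h)) return(g)
  keep <- which(!is_h)
  remap <- integer(nrow(g$atoms)); remap[keep] <- seq_along(keep)
  b <- g$bonds
  b <- b[!(is_h[b$i] | is_h[b$j]), , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  structure(list(atoms = g$atoms[keep, , drop = FALSE], bonds = b),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  comp <- mg_components(x)
  cat(sprintf("<molgraph> %d atoms, %d bonds, %d component(s)\n",
              n_atoms(x), nrow(x$bonds), length(unique(comp))))
  invisible(x)
}

#' Number of atoms in a molecular graph
#' @param g a `molgraph`.
#' @return integer atom count (hydrogens are implicit and never counted).
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' Count carbon atoms
#' @param g a `molgraph`.
#' @return integer number of carbon atoms.
#' @export
n_carbons <- function(g) sum(g$atoms$element == "C")

# Sum of bond orders incident to each atom (aromatic counted as 1.5).
mg_valence <- function(g) {
  v <- numeric(n_atoms(g))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      v[g$bonds$i[k]] <- v[g$bonds$i[k]] + g$bonds$order[k]
      v[g$bonds$j[k]] <- v[g$bonds$j[k]] + g$bonds$order[k]
    }
  }
  v
}

# igraph view of a molgraph (undirected, unlabeled edges).
mg_to_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds)) g$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g))))
}

# Connected-component membership for every atom.
mg_components <- function(g) {
  if (n_atoms(g) == 0) return(integer())
  ig <- mg_to_igraph(g)
  as.integer(igraph::components(ig)$membership)
}

# Induced subgraph on a set of atom indices; records original indices in
# attr "orig_atoms" (needed to look bonds up in the parent structure).
mg_induced <- function(g, idx) {
  idx <- sort(unique(as.integer(idx)))
  remap <- integer(n_atoms(g)); remap[idx] <- seq_along(idx)
  b <- g$bonds
  b <- b[b$i %in% idx & b$j %in% idx, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  out <- structure(list(atoms = g$atoms[idx, , drop = FALSE], bonds = b),
                   class = "molgraph")
  rownames(out$atoms) <- NULL
  attr(out, "orig_atoms") <- idx
  out
}

# Adjacency lookup: order of the bond between atoms a and b, or NA.
mg_bond_order <- function(g, a, b) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  hit <- which(g$bonds$i == a & g$bonds$j == b)
  if (length(hit)) g$bonds$order[hit[1]] else NA_real_
}

# Neighbors of atom a.
mg_neighbors <- function(g, a) {
  c(g$bonds$j[g$bonds$i == a], g$bonds$i[g$bonds$j == a])
}

#' Build a molecular graph from an edge list
#'
#' Convenience constructor for all-carbon, all-single-bond graphs such as
#' reference skeletons: atoms are numbered 1..n and every listed edge gets
#' bond order 1.
#'
#' @param n number of atoms.
#' @param edges two-column matrix or data.frame of atom index pairs.
#' @param element chemical symbol for every atom (default carbon).
#' @return a `molgraph`.
#' @export
graph_from_edges <- function(n, edges, element = "C") {
  edges <- as.data.frame(edges)
  names(edges)[1:2] <- c("i", "j")
  molgraph(data.frame(element = rep(element, n), charge = 0L),
           data.frame(i = edges$i, j = edges$j, order = 1))
}

#' Cycle rank (number of independent rings) of a molecular graph
#' @param g a `molgraph`.
#' @return integer cycle rank, `bonds - atoms + components`.
#' @export
ring_count <- function(g) {
  if (n_atoms(g) == 0) return(0L)
  ncomp <- length(unique(mg_components(g)))
  as.integer(nrow(g$bonds) - n_atoms(g) + ncomp)
}

#' Test two molecular graphs for isomorphism
#'
#' Element labels and bond orders are compared via graph coloring for atoms;
#' bond orders are only compared when both graphs carry them. For the
#' all-carbon single-bond graphs used in skeleton work this reduces to plain
#' graph isomorphism (VF2).
#'
#' @param g1,g2 `molgraph` objects.
#' @return logical.
#' @export
mg_isomorphic <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2) || nrow(g1$bonds) != nrow(g2$bonds))
    return(FALSE)
  if (n_atoms(g1) == 0) return(TRUE)
  pal <- sort(unique(c(g1$atoms$element, g2$atoms$element)))
  c1 <- match(g1$atoms$element, pal); c2 <- match(g2$atoms$element, pal)
  igraph::isomorphic(mg_to_igraph(g1), mg_to_igraph(g2), method = "vf2",
                     vertex.color1 = c1, vertex.color2 = c2)
}
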