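# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written without reusing the package's
# algorithmic path: selection by explicit pairwise comparison, isomorphism
# by backtracking search, alignment by enumerating optimal DP tracebacks.

# ---- fixture builders -----------------------------------------------------

# Random chemically-plausible molecular graph: random tree over C/O/N plus
# a few extra edges, some double bonds. Always at least one carbon.
random_molecule <- function(n_max = 30, n_min = 2) {
  n <- sample(n_min:n_max, 1)
  el <- c("C", sample(c("C", "O", "N"), n - 1, replace = TRUE,
                      prob = c(0.7, 0.2, 0.1)))
  bonds <- NULL
  if (n > 1) {
    parent <- vapply(2:n, function(k) sample.int(k - 1, 1), integer(1))
    bonds <- data.frame(i = parent, j = 2:n, order = 1)
    extra <- sample(0:2, 1)
    for (e in seq_len(extra)) {
      pair <- sort(sample.int(n, 2))
      if (!any(bonds$i == pair[1] & bonds$j == pair[2]))
        bonds <- rbind(bonds, data.frame(i = pair[1], j = pair[2], order = 1))
    }
    dbl <- runif(nrow(bonds)) < 0.2
    bonds$order[dbl] <- 2
  }
  molgraph(data.frame(element = el, charge = 0L), bonds)
}

# Random connected all-carbon single-bond graph (a skeleton-like fragment).
random_carbon_graph <- function(n_max = 16, n_min = 2, extra_max = 3) {
  n <- sample(n_min:n_max, 1)
  parent <- vapply(2:n, function(k) sample.int(k - 1, 1), integer(1))
  bonds <- data.frame(i = parent, j = 2:n, order = 1)
  for (e in seq_len(sample(0:extra_max, 1))) {
    pair <- sort(sample.int(n, 2))
    if (pair[1] != pair[2] &&
        !any(bonds$i == pair[1] & bonds$j == pair[2]))
      bonds <- rbind(bonds, data.frame(i = pair[1], j = pair[2], order = 1))
  }
  graph_from_edges(n, bonds[c("i", "j")])
}

# Relabel the atoms of a molgraph by a random permutation.
mg_permute_random <- function(g) {
  n <- n_atoms(g)
  perm <- sample.int(n)          # perm[old] = new index
  atoms <- g$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  b <- g$bonds
  molgraph(atoms, data.frame(i = perm[b$i], j = perm[b$j], order = b$order))
}

# A labdane-skeleton compound decorated in code: optional double bonds
# (position pairs), hydroxyls (positions), epoxide bridges (position pairs).
make_reference_compound <- function(id, entry, double_bonds = NULL,
                                    hydroxyls = NULL, epoxides = NULL) {
  g <- entry$skeleton
  for (db in double_bonds) {
    i <- min(db); j <- max(db)
    hit <- which(g$bonds$i == i & g$bonds$j == j)
    stopifnot(length(hit) == 1)
    g$bonds$order[hit] <- 2
  }
  for (h in hydroxyls) g <- skeletax:::mg_add_atom(g, "O", h, 1)
  for (ep in epoxides) {
    g <- skeletax:::mg_add_atom(g, "O", ep[1], 1)
    o <- n_atoms(g)
    g$bonds <- rbind(g$bonds, data.frame(i = min(ep[2], o), j = max(ep[2], o),
                                         order = 1))
    class(g) <- "molgraph"
  }
  g <- standardize(g)
  list(compound_id = id, name = id, structure_text = NA_character_,
       graph = g, parse_error = NA_character_, source_db = "synthetic",
       taxa = character(0))
}

# ---- fragment-selection oracle -------------------------------------------

# Exhaustive argmin over |carbons - target| with the documented tie rule,
# decided by explicit pairwise comparison (no sorting machinery).
oracle_select_fragment <- function(fragments, target = 20) {
  better <- function(a, b) {           # is fragment a strictly better than b?
    ka <- c(abs(n_atoms(a) - target), -ring_count(a), -n_atoms(a))
    kb <- c(abs(n_atoms(b) - target), -ring_count(b), -n_atoms(b))
    for (k in 1:3) {
      if (ka[k] < kb[k]) return(TRUE)
      if (ka[k] > kb[k]) return(FALSE)
    }
    canonical_skeleton_id(a) < canonical_skeleton_id(b)
  }
  best <- fragments[[1]]
  for (f in fragments[-1]) if (better(f, best)) best <- f
  best
}

# ---- brute-force isomorphism ---------------------------------------------

# All isomorphisms g1 -> g2 (unlabeled graphs, same size) by backtracking
# with degree pruning. Returns list of integer vectors m with m[v1] = v2,
# or logical via brute_isomorphic().
brute_all_isomorphisms <- function(g1, g2, max_maps = Inf) {
  n <- n_atoms(g1)
  if (n != n_atoms(g2) || nrow(g1$bonds) != nrow(g2$bonds)) return(list())
  adj <- function(g) {
    A <- matrix(FALSE, n_atoms(g), n_atoms(g))
    for (k in seq_len(nrow(g$bonds))) {
      A[g$bonds$i[k], g$bonds$j[k]] <- TRUE
      A[g$bonds$j[k], g$bonds$i[k]] <- TRUE
    }
    A
  }
  A1 <- adj(g1); A2 <- adj(g2)
  d1 <- rowSums(A1); d2 <- rowSums(A2)
  if (!identical(sort(d1), sort(d2))) return(list())
  maps <- list()
  map <- integer(n); used <- logical(n)
  recurse <- function(v) {
    if (length(maps) >= max_maps) return()
    if (v > n) { maps[[length(maps) + 1]] <<- map; return() }
    for (w in which(!used & d2 == d1[v])) {
      ok <- TRUE
      for (u in seq_len(v - 1))
        if (A1[u, v] != A2[map[u], w]) { ok <- FALSE; break }
      if (ok) {
        map[v] <<- w; used[w] <<- TRUE
        recurse(v + 1)
        used[w] <<- FALSE
      }
    }
  }
  recurse(1)
  maps
}

brute_isomorphic <- function(g1, g2) {
  length(brute_all_isomorphisms(g1, g2, max_maps = 1)) > 0
}

# Pattern-query oracle: does any brute-force isomorphism of the reference
# skeleton onto the compound's skeleton fragment satisfy all solid
# constraints in the original structure?
oracle_pattern_match <- function(graph, skeleton, entry, constraints) {
  maps <- brute_all_isomorphisms(entry$skeleton, skeleton)
  orig <- attr(skeleton, "orig_atoms")
  cons <- constraints[constraints$solid & constraints$kind != "any", ,
                      drop = FALSE]
  if (nrow(cons) == 0) return(length(maps) > 0)
  for (mp in maps) {
    ok <- TRUE
    for (k in seq_len(nrow(cons))) {
      a <- orig[mp[entry$positions[[as.character(cons$p[k])]]]]
      b <- orig[mp[entry$positions[[as.character(cons$q[k])]]]]
      o <- skeletax:::mg_bond_order(graph, a, b)
      if (cons$kind[k] == "double_bond") {
        ok <- !is.na(o) && o >= 1.5
      } else {
        shared <- intersect(skeletax:::mg_neighbors(graph, a),
                            skeletax:::mg_neighbors(graph, b))
        ok <- !is.na(o) && any(graph$atoms$element[shared] == "O")
      }
      if (!ok) break
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# ---- alignment oracle -----------------------------------------------------

# Gotoh affine-gap global alignment: returns the optimal score and the set
# of identity values over all optimal alignments (enumerated by traceback,
# capped). Gap of length L costs open + L * extend.
oracle_global_align <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 5, gap_extend = 1,
                                max_paths = 2000) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in y (consumes x)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in x (consumes y)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # enumerate identity counts over all optimal tracebacks; the origin is
  # (1, 1) in state M (the empty prefix); the X/Y border columns follow the
  # same recurrence as the interior so traceback passes through them.
  idents <- integer(0); n_paths <- 0
  val_of <- function(state, i, j)
    switch(state, M = M[i, j], X = X[i, j], Y = Y[i, j])
  tb <- function(i, j, state, nid) {
    if (n_paths >= max_paths) return()
    if (i == 1 && j == 1) {
      if (state == "M") { idents <<- c(idents, nid); n_paths <<- n_paths + 1 }
      return()
    }
    if (state == "M" && i > 1 && j > 1) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      add <- as.integer(x[i - 1] == y[j - 1])
      for (prev in c("M", "X", "Y")) {
        val <- val_of(prev, i - 1, j - 1)
        if (val > NEG / 2 && val + s == M[i, j])
          tb(i - 1, j - 1, prev, nid + add)
      }
    } else if (state == "X" && i > 1) {
      if (M[i - 1, j] > NEG / 2 &&
          M[i - 1, j] - gap_open - gap_extend == X[i, j])
        tb(i - 1, j, "M", nid)
      if (X[i - 1, j] > NEG / 2 && X[i - 1, j] - gap_extend == X[i, j])
        tb(i - 1, j, "X", nid)
    } else if (state == "Y" && j > 1) {
      if (M[i, j - 1] > NEG / 2 &&
          M[i, j - 1] - gap_open - gap_extend == Y[i, j])
        tb(i, j - 1, "M", nid)
      if (Y[i, j - 1] > NEG / 2 && Y[i, j - 1] - gap_extend == Y[i, j])
        tb(i, j - 1, "Y", nid)
    }
  }
  for (st in c("M", "X", "Y")) {
    val <- switch(st, M = M[n + 1, m + 1], X = X[n + 1, m + 1],
                  Y = Y[n + 1, m + 1])
    if (val == best) tb(n + 1, m + 1, st, 0L)
  }
  list(score = best,
       identities = unique(100 * idents / min(n, m)),
       capped = n_paths >= max_paths)
}
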