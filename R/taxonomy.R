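#' Taxon-name resolution and clade assignment
#'
#' Occurrence databases report taxa as free-text names with authorities,
#' synonym markers, hybrids, and typos. This module normalizes those
#' strings, resolves them against a reference taxonomy (NCBI-TaxID-like)
#' by exact, then normalized, then fuzzy comparison, and assigns genera to
#' one of the 12 primary monophyletic Lamiaceae clades.
#'
#' @name taxonomy
NULL

# Marker tokens never part of a binomial name.
.name_markers <- c("syn", "syn.", "cf", "cf.", "var", "var.", "aff", "aff.",
                   "subsp", "subsp.", "ssp", "ssp.", "sp", "sp.", "x")

#' Normalize a raw taxon-name string
#'
#' Lowercases, strips parenthesized annotations, collapses whitespace,
#' removes hybrid signs and `syn.`/`cf.`/`var.` style markers, and keeps the
#' first two remaining tokens (genus + species epithet); authority strings
#' after the epithet fall away with the truncation.
#'
#' @param raw character vector of raw names.
#' @return character vector of normalized names; `""` when nothing remains
#'   (unmatched).
#' @export
normalize_name <- function(raw) {
  vapply(raw, function(x) {
    if (is.na(x)) return("")
    x <- tolower(x)
    x <- gsub("\\([^)]*\\)", " ", x)      # parenthesized synonyms etc.
    x <- gsub("×", " ", x)           # hybrid sign
    x <- gsub("[^a-z.-]", " ", x)
    toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ")[[1]]
    toks <- toks[!(toks %in% .name_markers) & nzchar(toks)]
    toks <- gsub("\\.$", "", toks)
    toks <- toks[nzchar(toks)]
    paste(utils::head(toks, 2), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a reference taxonomy table
#'
#' CSV with columns `taxon_id`, `canonical_name`, `rank`
#' (`genus`/`species`), `parent_genus_id` (empty for genera).
#'
#' @param path CSV file.
#' @return data.frame of taxon records.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "canonical_name", "rank")
  if (!all(need %in% names(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in taxonomy")
  if (!"parent_genus_id" %in% names(df)) df$parent_genus_id <- NA_integer_
  sp <- df$rank == "species"
  if (any(sp & is.na(df$parent_genus_id)))
    stop("species records must carry parent_genus_id")
  df
}

#' Resolve one raw taxon name against a reference taxonomy
#'
#' Tries byte-exact match on `canonical_name`, then match on normalized
#' names, then fuzzy match (similarity `1 - edit_distance / max_length` on
#' normalized names, at or above `fuzzy_threshold`). Fuzzy matches are
#' flagged for review. When the species fails to match but the genus token
#' matches a genus-rank record, the genus-level record is accepted (method
#' `normalized` at genus precision). The genus reported is the first token
#' of the matched canonical name, or of the normalized raw name when
#' unmatched.
#'
#' @param raw one raw name string.
#' @param reference taxonomy data.frame from [read_taxonomy()].
#' @param fuzzy_threshold minimum normalized similarity for a fuzzy match.
#' @return one-row data.frame: `raw_name`, `taxon_id`, `method`
#'   (`exact`/`normalized`/`fuzzy`/`unmatched`), `matched_name`, `genus`,
#'   `flagged`.
#' @export
resolve_taxon <- function(raw, reference, fuzzy_threshold = 0.9) {
  stopifnot(nrow(reference) > 0)
  res <- function(id, method, matched, flagged = FALSE) {
    genus <- if (!is.na(matched) && nzchar(matched))
      strsplit(normalize_name(matched), " ")[[1]][1]
    else {
      nt <- strsplit(normalize_name(raw), " ")[[1]]
      if (length(nt) && nzchar(nt[1])) nt[1] else NA_character_
    }
    data.frame(raw_name = raw, taxon_id = id, method = method,
               matched_name = matched, genus = genus, flagged = flagged,
               stringsAsFactors = FALSE)
  }
  hit <- which(reference$canonical_name == raw)
  if (length(hit))
    return(res(reference$taxon_id[hit[1]], "exact",
               reference$canonical_name[hit[1]]))
  norm <- normalize_name(raw)
  if (!nzchar(norm)) return(res(NA_integer_, "unmatched", NA_character_))
  ref_norm <- normalize_name(reference$canonical_name)
  hit <- which(ref_norm == norm)
  if (length(hit))
    return(res(reference$taxon_id[hit[1]], "normalized",
               reference$canonical_name[hit[1]]))
  # genus-level fallback before fuzzy: species epithet unknown but genus known
  genus_tok <- strsplit(norm, " ")[[1]][1]
  if (length(strsplit(norm, " ")[[1]]) > 1) {
    ghit <- which(reference$rank == "genus" & ref_norm == genus_tok)
    if (length(ghit))
      return(res(reference$taxon_id[ghit[1]], "normalized",
                 reference$canonical_name[ghit[1]]))
  }
  d <- vapply(ref_norm, osa_distance, integer(1), a = norm, USE.NAMES = FALSE)
  sim <- 1 - d / pmax(nchar(norm), nchar(ref_norm))
  ord <- order(-sim, reference$canonical_name)
  if (sim[ord[1]] >= fuzzy_threshold)
    return(res(reference$taxon_id[ord[1]], "fuzzy",
               reference$canonical_name[ord[1]], flagged = TRUE))
  res(NA_integer_, "unmatched", NA_character_)
}

#' Resolve a vector of raw names
#'
#' @param raw character vector.
#' @inheritParams resolve_taxon
#' @return data.frame, one row per input name, as in [resolve_taxon()].
#' @export
resolve_taxa <- function(raw, reference, fuzzy_threshold = 0.9) {
  do.call(rbind, lapply(raw, resolve_taxon, reference = reference,
                        fuzzy_threshold = fuzzy_threshold))
}

#' Optimal-string-alignment (restricted Damerau-Levenshtein) distance
#'
#' Edit distance counting insertions, deletions, substitutions, and
#' transpositions of adjacent characters each as one operation. A
#' transposed genus name ("Salvai" for "Salvia") is one edit away, which
#' keeps common typos above usual similarity thresholds.
#'
#' @param a,b character strings.
#' @return integer distance.
#' @export
osa_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0) return(m)
  if (m == 0) return(n)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
      if (i > 1 && j > 1 && x[i] == y[j - 1] && x[i - 1] == y[j])
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
    }
  }
  d[n + 1, m + 1]
}

#' Read a genus-to-clade map
#'
#' CSV with columns `genus`, `clade`. At most 12 distinct clades and one
#' clade per genus are enforced.
#'
#' @param path CSV file; `NULL` loads the shipped Lamiaceae map covering
#'   the genera discussed in the source chemotaxonomic literature.
#' @return data.frame with `genus`, `clade`.
#' @export
read_clade_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lamiaceae_clades.csv",
                        package = "skeletax", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("genus", "clade") %in% names(df)))
  if (anyDuplicated(tolower(df$genus))) stop("a genus maps to several clades")
  if (length(unique(df$clade)) > 12)
    stop("clade map has more than 12 distinct clades")
  df
}

#' Assign a genus to its clade
#'
#' Case-insensitive lookup on the normalized genus; unknown genera return
#' `"unassigned"`.
#'
#' @param genus character vector of genus names.
#' @param clade_map data.frame from [read_clade_map()].
#' @return character vector of clade names.
#' @export
assign_clade <- function(genus, clade_map) {
  idx <- match(tolower(trimws(genus)), tolower(clade_map$genus))
  out <- clade_map$clade[idx]
  out[is.na(out)] <- "unassigned"
  out
}
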