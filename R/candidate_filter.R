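#' Homology-hit filtering and identity-based peptide merging
#'
#' Re-implements the candidate-selection computations natively: parsing
#' tabular (12-column, outfmt-6 style) homology search output, computing
#' query coverage, retaining subjects whose hit to the most similar query
#' reaches both an identity and a coverage threshold, and merging peptides
#' at a pairwise-identity threshold by deterministic greedy clustering.
#'
#' @name candidate_filter
NULL

.hit_cols <- c("query_id", "subject_id", "percent_identity",
               "alignment_length", "mismatches", "gap_opens",
               "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")

#' Parse a tabular homology hit table
#'
#' Standard 12-column tab-separated layout (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score). Query lengths are joined from a
#' named vector or from a FASTA file of the query peptides.
#'
#' @param path hit table file.
#' @param query_lengths named numeric vector (query_id -> length) or path
#'   to the query FASTA.
#' @return data.frame of validated hits with a `query_length` column.
#' @export
parse_hit_table <- function(path, query_lengths) {
  if (is.character(query_lengths) && length(query_lengths) == 1 &&
      file.exists(query_lengths)) {
    aa <- Biostrings::readAAStringSet(query_lengths)
    query_lengths <- stats::setNames(Biostrings::width(aa),
                                     sub("\\s.*", "", names(aa)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(.hit_cols)))
    names(out) <- .hit_cols
    out$query_length <- numeric(0)
    return(out)
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < 12))
    stop(sprintf("malformed hit table row (line %d): expected 12 columns, got %d",
                 which(nf < 12)[1], nf[which(nf < 12)[1]]))
  m <- do.call(rbind, lapply(rows, `[`, 1:12))
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   percent_identity = as.numeric(m[, 3]),
                   alignment_length = as.integer(m[, 4]),
                   mismatches = as.integer(m[, 5]),
                   gap_opens = as.integer(m[, 6]),
                   q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
                   s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
                   evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$percent_identity) | is.na(df$q_start) |
                 is.na(df$q_end) | is.na(df$bitscore))
  if (length(bad))
    stop(sprintf("malformed hit table row (line %d): non-numeric field", bad[1]))
  bad <- which(df$q_start < 1 | df$q_end < df$q_start)
  if (length(bad))
    stop(sprintf("invalid query coordinates (line %d): q_start %d, q_end %d",
                 bad[1], df$q_start[bad[1]], df$q_end[bad[1]]))
  if (any(df$percent_identity < 0 | df$percent_identity > 100))
    stop("percent_identity outside [0, 100]")
  ql <- query_lengths[df$query_id]
  if (anyNA(ql))
    stop("missing query length for: ",
         paste(unique(df$query_id[is.na(ql)]), collapse = ", "))
  df$query_length <- as.numeric(ql)
  if (any(df$q_end > df$query_length))
    stop("q_end exceeds query_length for ",
         df$query_id[which(df$q_end > df$query_length)[1]])
  df
}

#' Query coverage of a hit or hit group
#'
#' `best_hsp` basis: the span of a single HSP over the query length.
#' `merged_hsps` basis: the length of the union of all `[q_start, q_end]`
#' intervals in `hits` over the query length (all rows must share one
#' query).
#'
#' @param hits one or more rows of a parsed hit table.
#' @param basis `"best_hsp"` (per-row spans) or `"merged_hsps"` (one
#'   merged value).
#' @return percent coverage: a vector (per row) for `best_hsp`, a single
#'   value for `merged_hsps`.
#' @export
query_coverage <- function(hits, basis = c("best_hsp", "merged_hsps")) {
  basis <- match.arg(basis)
  stopifnot(all(hits$query_length > 0))
  if (basis == "best_hsp")
    return(100 * (hits$q_end - hits$q_start + 1) / hits$query_length)
  stopifnot(length(unique(hits$query_id)) <= 1)
  if (nrow(hits) == 0) return(numeric(0))
  100 * interval_union_length(hits$q_start, hits$q_end) / hits$query_length[1]
}

# Total length covered by the union of integer intervals [starts, ends].
interval_union_length <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= cur_e + 1L) {
      cur_e <- max(cur_e, ends[k])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- starts[k]; cur_e <- ends[k]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Filtering configuration
#'
#' Thresholds follow the rule "remove subjects with less than
#' `min_coverage`% coverage or `min_identity`% identity to the most
#' similar query": values at exactly the threshold are retained.
#'
#' @param min_identity minimum percent identity (default 35).
#' @param min_coverage minimum percent query coverage (default 70).
#' @param coverage_basis `"best_hsp"` (default; coverage of the single
#'   best HSP) or `"merged_hsps"` (union of all HSP spans between the
#'   subject and its best query).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_identity = 35, min_coverage = 70,
                          coverage_basis = c("best_hsp", "merged_hsps")) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 coverage_basis = match.arg(coverage_basis)),
            class = "filter_config")
}

#' Filter candidate subjects by identity and coverage to their best query
#'
#' For each subject, the most similar query is the hit with the highest bit
#' score (ties: higher identity, then lexicographically smaller query id).
#' The subject is retained iff that hit's identity and coverage both reach
#' the thresholds (boundary inclusive).
#'
#' @param hits parsed hit table from [parse_hit_table()].
#' @param config a [filter_config()].
#' @return data.frame with one row per subject: `subject_id`,
#'   `best_query`, `identity`, `coverage`, `retained`; sorted by subject.
#' @export
filter_candidates <- function(hits, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(hits) == 0)
    return(data.frame(subject_id = character(), best_query = character(),
                      identity = numeric(), coverage = numeric(),
                      retained = logical()))
  out <- do.call(rbind, lapply(split(hits, hits$subject_id), function(d) {
    o <- order(-d$bitscore, -d$percent_identity, d$query_id)
    best <- d[o[1], ]
    cov <- if (config$coverage_basis == "best_hsp") {
      query_coverage(best, "best_hsp")
    } else {
      query_coverage(d[d$query_id == best$query_id, ], "merged_hsps")
    }
    data.frame(subject_id = best$subject_id, best_query = best$query_id,
               identity = best$percent_identity, coverage = cov,
               retained = best$percent_identity >= config$min_identity &&
                 cov >= config$min_coverage,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$subject_id), ]
  rownames(out) <- NULL
  out
}

# --- pairwise identity and greedy clustering ------------------------------

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO*", "")[[1]]

#' Percent identity between two peptides by global alignment
#'
#' Needleman-Wunsch global alignment (via Biostrings) with configurable
#' scores; a gap of length L costs `gap_open + L * gap_extend`. Identity is
#' the number of identical aligned columns over the length of the shorter
#' sequence — the convention of identity-threshold clustering tools.
#'
#' @param a,b peptide strings (amino-acid alphabet).
#' @param match,mismatch,gap_open,gap_extend alignment scores (defaults
#'   +1, -1, 5, 1; gap penalties are magnitudes).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 5, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  chars <- unique(strsplit(paste0(a, b), "")[[1]])
  bad <- setdiff(chars, .aa_alphabet)
  if (length(bad))
    stop("invalid amino-acid character(s): ", paste(bad, collapse = ""))
  sub <- matrix(mismatch, length(.aa_alphabet), length(.aa_alphabet),
                dimnames = list(.aa_alphabet, .aa_alphabet))
  diag(sub) <- match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sub, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  100 * Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

#' Greedy identity clustering of peptides
#'
#' Sequences are sorted by length descending (ties: lexicographic id) and
#' each joins the first existing cluster whose representative it matches
#' at or above the identity threshold, else founds a new cluster — the
#' deterministic longest-first greedy scheme of identity-merging tools.
#'
#' @param seqs named character vector of peptides (unique ids).
#' @param threshold percent identity required to join a cluster
#'   (default 95).
#' @param ... alignment scores passed to [pairwise_identity()].
#' @return list of clusters, each `list(representative_id, member_ids)`
#'   (members include the representative).
#' @export
greedy_cluster <- function(seqs, threshold = 95, ...) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  clusters <- list()
  for (id in names(seqs)) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_id <- clusters[[k]]$representative_id
      if (pairwise_identity(seqs[[id]], seqs[[rep_id]], ...) >= threshold) {
        clusters[[k]]$member_ids <- c(clusters[[k]]$member_ids, id)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1]] <-
        list(representative_id = id, member_ids = id)
  }
  clusters
}

#' Write clusters as a two-column TSV
#'
#' @param clusters list from [greedy_cluster()].
#' @param path output file (columns `representative`, `member`).
#' @return invisibly, the data.frame written.
#' @export
write_clusters <- function(clusters, path) {
  df <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(representative = cl$representative_id,
               member = cl$member_ids, stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(representative = character(),
                                    member = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
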