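write_hits <- function(rows, path) {
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), character(1)),
             path)
}

test_that("hit tables parse, validate coordinates, and join query lengths", {
  tf <- tempfile()
  write_hits(list(
    c("Q1", "S1", "87.5", "100", "12", "1", "1", "100", "5", "104",
      "1e-50", "350.1")), tf)
  h <- parse_hit_table(tf, c(Q1 = 120))
  expect_equal(nrow(h), 1)
  expect_equal(h$percent_identity, 87.5)
  expect_equal(h$query_length, 120)

  write_hits(list(c("Q1", "S1", "87.5", "100", "12", "1", "100", "1", "5",
                    "104", "1e-50", "350.1")), tf)
  expect_error(parse_hit_table(tf, c(Q1 = 120)), "line 1")

  writeLines(character(0), tf)
  expect_equal(nrow(parse_hit_table(tf, c(Q1 = 120))), 0)

  write_hits(list(c("Q9", "S1", "80", "10", "1", "0", "1", "10", "1", "10",
                    "1e-5", "30")), tf)
  expect_error(parse_hit_table(tf, c(Q1 = 120)), "missing query length")

  # lengths can come from the query FASTA
  fa <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(Q1 = "MKLVINTT")), fa)
  write_hits(list(c("Q1", "S1", "80", "6", "1", "0", "1", "6", "1", "6",
                    "1e-5", "30")), tf)
  expect_equal(parse_hit_table(tf, fa)$query_length, 8)
})

test_that("query coverage: best HSP span vs merged interval union", {
  h <- data.frame(query_id = "Q", q_start = c(1L, 41L), q_end = c(50L, 100L),
                  query_length = 100)
  expect_equal(query_coverage(h[1, ], "best_hsp"), 50)
  expect_equal(query_coverage(h, "merged_hsps"), 100)   # union covers 1..100
  # best single HSP spans 60
  expect_equal(max(query_coverage(h, "best_hsp")), 60)
  h1 <- data.frame(query_id = "Q", q_start = 1L, q_end = 70L,
                   query_length = 100)
  expect_equal(query_coverage(h1, "best_hsp"), 70)
  # disjoint intervals
  h2 <- data.frame(query_id = "Q", q_start = c(1L, 61L), q_end = c(20L, 80L),
                   query_length = 100)
  expect_equal(query_coverage(h2, "merged_hsps"), 40)
})

test_that("filtering keeps boundary values and matches exhaustive rule application", {
  mk <- function(q, s, id, qs, qe, bits, qlen = 100)
    data.frame(query_id = q, subject_id = s, percent_identity = id,
               alignment_length = qe - qs + 1, mismatches = 0L,
               gap_opens = 0L, q_start = qs, q_end = qe, s_start = qs,
               s_end = qe, evalue = 1e-10, bitscore = bits,
               query_length = qlen, stringsAsFactors = FALSE)
  hits <- rbind(
    mk("Q1", "keep_boundary", 35.0, 1, 70, 200),    # exactly 35% / 70%
    mk("Q1", "drop_identity", 34.9, 1, 90, 200),
    mk("Q1", "drop_coverage", 80.0, 1, 69, 200),
    mk("Q1", "keep_high", 90.0, 1, 95, 200),
    mk("Q1", "best_query_rule", 80.0, 1, 95, 100),  # lower bitscore, passes
    mk("Q2", "best_query_rule", 20.0, 1, 95, 500))  # higher bitscore, fails
  out <- filter_candidates(hits)
  expect_true(out$retained[out$subject_id == "keep_boundary"])
  expect_false(out$retained[out$subject_id == "drop_identity"])
  expect_false(out$retained[out$subject_id == "drop_coverage"])
  expect_true(out$retained[out$subject_id == "keep_high"])
  # the most similar query is by bitscore, and ONLY that hit is judged
  expect_equal(out$best_query[out$subject_id == "best_query_rule"], "Q2")
  expect_false(out$retained[out$subject_id == "best_query_rule"])

  # exhaustive rule application over a toy table of 6 subjects
  retained_brute <- character(0)
  for (s in unique(hits$subject_id)) {
    d <- hits[hits$subject_id == s, ]
    d <- d[order(-d$bitscore, -d$percent_identity, d$query_id), ]
    cov <- 100 * (d$q_end[1] - d$q_start[1] + 1) / d$query_length[1]
    if (!(d$percent_identity[1] < 35 || cov < 70))
      retained_brute <- c(retained_brute, s)
  }
  expect_equal(sort(out$subject_id[out$retained]), sort(retained_brute))
})

test_that("merged-HSP coverage never falls below best-HSP coverage", {
  set.seed(17)
  for (k in 1:30) {
    n <- sample(1:4, 1)
    qs <- sample(1:80, n); qe <- pmin(qs + sample(5:40, n, replace = TRUE), 100)
    h <- data.frame(query_id = "Q", q_start = qs, q_end = qe,
                    query_length = 100)
    expect_gte(query_coverage(h, "merged_hsps"),
               max(query_coverage(h, "best_hsp")))
  }
})

test_that("pairwise identity matches the exhaustive alignment oracle", {
  expect_equal(pairwise_identity("MKLV", "MKLV"), 100)
  expect_equal(pairwise_identity("AAAA", "AATA"), 75)
  expect_error(pairwise_identity("MK1V", "MKLV"), "invalid amino-acid")
  set.seed(23)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:40) {
    a <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    b <- if (runif(1) < 0.5) {
      s <- strsplit(a, "")[[1]]
      mut <- runif(length(s)) < 0.2
      s[mut] <- sample(aa, sum(mut), replace = TRUE)
      paste(s, collapse = "")
    } else paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    orc <- oracle_global_align(a, b)
    got <- pairwise_identity(a, b)
    expect_true(got %in% orc$identities || orc$capped,
                info = sprintf("%s vs %s: got %.2f, oracle {%s}", a, b, got,
                               paste(round(orc$identities, 2), collapse = ",")))
  }
})

test_that("greedy clustering is deterministic and sound", {
  seqs <- c(a = "MKLVINTTTT", b = "MKLVINTTTT", c = "AAAAAAAAAA")
  cl <- greedy_cluster(seqs, 95)
  expect_equal(length(cl), 2)
  reps <- vapply(cl, `[[`, "", "representative_id")
  expect_true(all(c("a", "c") %in% reps))    # length ties broken by id
  expect_equal(sort(cl[[which(reps == "a")]]$member_ids), c("a", "b"))

  # two sequences at ~50% identity stay separate
  cl <- greedy_cluster(c(x = "MKLVMKLVMK", y = "MALVMALVMA"), 95)
  expect_equal(length(cl), 2)

  # 10-sequence set equals an independent greedy replay on the identity matrix
  set.seed(29)
  pp <- generate_peptides(generator_config(seed = 29, n_peptides = 6,
                                           n_clones = 4))
  cl <- greedy_cluster(pp$seqs, 95)
  ord <- names(pp$seqs)[order(-nchar(pp$seqs), names(pp$seqs))]
  reps_replay <- character(0); memb <- list()
  for (id in ord) {
    placed <- FALSE
    for (r in reps_replay) {
      if (pairwise_identity(pp$seqs[[id]], pp$seqs[[r]]) >= 95) {
        memb[[r]] <- c(memb[[r]], id); placed <- TRUE; break
      }
    }
    if (!placed) { reps_replay <- c(reps_replay, id); memb[[id]] <- id }
  }
  expect_equal(vapply(cl, `[[`, "", "representative_id"), reps_replay)
  # soundness: every member is >= 95% identical to its representative
  for (c1 in cl)
    for (m in c1$member_ids)
      expect_gte(pairwise_identity(pp$seqs[[m]],
                                   pp$seqs[[c1$representative_id]]), 95)
})

test_that("raising thresholds never grows the retained set", {
  ht <- generate_hits(generator_config(seed = 37, n_subjects = 40))
  prev <- NULL
  for (mi in c(20, 35, 50, 80)) {
    out <- filter_candidates(ht$hits, filter_config(min_identity = mi))
    kept <- out$subject_id[out$retained]
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  prev <- NULL
  for (mc in c(40, 70, 90)) {
    out <- filter_candidates(ht$hits, filter_config(min_coverage = mc))
    kept <- out$subject_id[out$retained]
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})
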