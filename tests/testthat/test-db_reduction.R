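make_seqs <- function(...) {
  s <- c(...)
  stats::setNames(s, paste0("q", seq_along(s)))
}

test_that("merge_dedupe removes exact duplicates with stable order", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGT", ">b", "TTTTCCCC"), f1)
  writeLines(c(">c", "acgtacgt"), f2)  # same sequence as a, lower case
  merged <- merge_dedupe(c(f1, f2))
  expect_equal(length(merged), 2L)
  expect_equal(unname(merged), c("ACGTACGT", "TTTTCCCC"))

  expect_equal(length(merge_dedupe(character())), 0L)

  # 5 sequences with 2 exact duplicates -> 3, matching set semantics
  seqs <- make_seqs("AAAA", "CCCC", "AAAA", "GGGG", "CCCC")
  out <- merge_dedupe(list(seqs))
  expect_equal(sort(unname(out)), sort(unique(unname(seqs))))
  expect_equal(unname(out), c("AAAA", "CCCC", "GGGG"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("no header", "ACGT"), bad)
  expect_error(merge_dedupe(bad), "malformed FASTA")
})

test_that("align_16s equals the quadratic DP oracle", {
  # identical 250-nt pair scores 250 * match = 500
  q <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  hits <- align_16s(c(q1 = q), c(r1 = q))
  expect_equal(hits$score, 500)

  # zero-similarity pair yields no hit
  none <- align_16s(c(q1 = strrep("A", 30)), c(r1 = strrep("C", 30)))
  expect_equal(nrow(none), 0L)

  expect_error(align_16s(c(q1 = "ACGU"), c(r1 = "ACGT")), "non-nucleotide")

  set.seed(77)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T", "N"), sample(20:60, 1),
                      TRUE, prob = c(rep(0.24, 4), 0.04)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), TRUE),
               collapse = "")
    h <- align_16s(stats::setNames(a, "q"), stats::setNames(b, "r"))
    expected <- oracle_sw(a, b)
    got <- if (nrow(h)) h$score else 0
    expect_equal(got, expected)
  }
})

test_that("filter_hits applies strict score cutoff and strict top-k", {
  p <- reduction_params(min_score = 450, top_k = 200)
  h1 <- data.frame(query_id = "q", subject_id = "s", score = 450)
  expect_false(any(filter_hits(h1, p)$retained))   # strict >
  h2 <- data.frame(query_id = "q", subject_id = sprintf("s%03d", 1:300),
                   score = 500)
  expect_equal(sum(filter_hits(h2, p)$retained), 200L)
  # ties at the cap break by subject_id lexicographic order
  expect_equal(sort(h2$subject_id[filter_hits(h2, p)$retained]),
               sprintf("s%03d", 1:200))

  set.seed(9)
  h3 <- data.frame(query_id = sample(c("q1", "q2"), 60, TRUE),
                   subject_id = sprintf("s%02d", 1:60),
                   score = sample(300:600, 60))
  p3 <- reduction_params(min_score = 450, top_k = 5)
  got <- filter_hits(h3, p3)
  for (qid in c("q1", "q2")) {
    sub <- h3[h3$query_id == qid & h3$score > 450, ]
    expected <- head(sub$subject_id[order(-sub$score, sub$subject_id)], 5)
    expect_setequal(got$subject_id[got$retained & got$query_id == qid], expected)
  }
})

test_that("build_reduced_db takes the union of retained taxa's proteins", {
  tr <- tiny_tree()
  bundle <- list(
    ref16s = data.frame(seq_id = c("r1", "r2", "r3"),
                        taxon_id = c("s1a", "s2a", "s3a"),
                        sequence = NA, stringsAsFactors = FALSE),
    proteins = data.frame(
      protein_id = c(paste0("P1_", 1:3), paste0("P2_", 1:2), paste0("P3_", 1:4)),
      taxon_id = c(rep("s1a", 3), rep("s2a", 2), rep("s3a", 4)),
      sequence = "MKV", stringsAsFactors = FALSE))

  none <- data.frame(query_id = character(), subject_id = character(),
                     score = numeric(), retained = logical())
  expect_equal(nrow(build_reduced_db(none, bundle)$proteins), 0L)

  hits <- data.frame(query_id = c("q1", "q1", "q2"),
                     subject_id = c("r1", "r2", "r1"),
                     score = c(500, 480, 470), retained = TRUE)
  db <- build_reduced_db(hits, bundle)
  expect_equal(nrow(db$proteins), 5L)  # 3 + 2
  expect_true(all(db$proteins$protein_id %in% bundle$proteins$protein_id))
  expect_equal(db$provenance$n_queries[db$provenance$taxon_id == "s1a"][1], 2L)

  bad <- transform(hits, subject_id = c("r1", "rX", "r1"))
  expect_error(build_reduced_db(bad, bundle), "rX")
})

test_that("reduction is monotone in min_score/top_k and idempotent", {
  cfg <- tiny_config(seed = 55)
  tr <- make_taxonomy(cfg)
  bundle <- make_reference_bundle(tr, 4, seed = 55)
  refs <- stats::setNames(bundle$ref16s$sequence, bundle$ref16s$seq_id)
  # queries: noisy copies of a few references
  set.seed(55)
  queries <- vapply(refs[1:4], function(s) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), 12)
    for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }, character(1))
  names(queries) <- paste0("q", 1:4)
  hits <- align_16s(queries, refs)

  prot_set <- function(min_score, top_k) {
    p <- reduction_params(min_score = min_score, top_k = top_k)
    sort(build_reduced_db(filter_hits(hits, p), bundle)$proteins$protein_id)
  }
  base <- prot_set(300, 10)
  expect_true(all(prot_set(400, 10) %in% base))   # raising min_score shrinks
  expect_true(all(prot_set(300, 2) %in% base))    # lowering top_k shrinks

  # idempotence: reducing the already-reduced bundle returns the same DB
  p <- reduction_params(min_score = 300, top_k = 10)
  db1 <- build_reduced_db(filter_hits(hits, p), bundle)
  bundle2 <- bundle
  bundle2$proteins <- db1$proteins
  db2 <- build_reduced_db(filter_hits(hits, p), bundle2)
  expect_equal(sort(db2$proteins$protein_id), sort(db1$proteins$protein_id))
})

test_that("tabular hit adapter reads outfmt-6-like TSVs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "r1", "98.5", "250", "3", "0", "1", "250", "1",
                     "250", "1e-100", "471"), collapse = "\t"), f)
  h <- read_tabular_hits(f)
  expect_equal(h$score, 471)
  expect_equal(h$query_id, "q1")
})
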