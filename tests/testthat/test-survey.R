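test_that("search keeps at most max_targets hits, ordered by bitscore", {
  withr::local_seed(7)
  ref <- example_reference_set()
  phac1 <- ref[ref$class_label == "PhaC1", ]
  # six planted homologs of descending identity in one species
  homs <- do.call(rbind, lapply(seq(95, 45, by = -10), function(t) {
    m <- mutate_to_identity(phac1, t, seed = t)
    m$id <- sprintf("HOM%02d", t)
    m$organism <- "Species una"
    m
  }))
  hits <- search_homologs(phac1, homs, survey_config(max_targets = 4))
  expect_identical(nrow(hits), 4L)
  expect_true(all(diff(hits$bitscore) <= 0))
  # the four highest-identity homologs win
  expect_setequal(hits$sacc, c("HOM95", "HOM85", "HOM75", "HOM65"))

  two <- search_homologs(phac1, homs[1:2, ], survey_config(max_targets = 4))
  expect_identical(nrow(two), 2L)
  expect_true(all(diff(two$bitscore) <= 0))
})

test_that("search over unalignable subjects returns an empty hit list", {
  query <- protein_records("Q", strrep("W", 50))
  subjects <- protein_records(c("S1", "S2"),
                              c(strrep("P", 80), strrep("G", 120)))
  hits <- search_homologs(query, subjects)
  expect_identical(nrow(hits), 0L)
  expect_error(search_homologs(query, subjects[0, ]), "non-empty proteome")
})

test_that("deduplication collapses identical statistics and is idempotent", {
  withr::local_seed(3)
  hits <- random_hit_frame(6L)
  dup <- rbind(hits, hits[2, ])
  out <- deduplicate_hits(dup)
  expect_identical(nrow(out), 6L)

  # same subject, different pident: both kept
  pair <- rbind(hits[1, ], hits[1, ])
  pair$pident[2] <- pair$pident[2] - 1
  expect_identical(nrow(deduplicate_hits(pair)), 2L)

  for (i in 1:20) {
    x <- random_hit_frame(sample(1:12, 1))
    x <- rbind(x, x[sample(nrow(x), 3, replace = TRUE), ])
    once <- deduplicate_hits(x)
    expect_identical(deduplicate_hits(once), once)     # idempotent
    expect_true(all(once$sacc %in% x$sacc))            # output subset
  }
})

test_that("classification picks the highest-identity class and applies the
           strong/weak threshold with strict inequality below", {
  mk <- function(pident, bitscore = 500, sacc = "S1") {
    h <- random_hit_frame(1L)
    h$pident <- pident; h$bitscore <- bitscore; h$sacc <- sacc
    h
  }
  call <- classify_organism(list(PhaC_Hme = mk(55), PhaC1 = mk(80)), "org")
  expect_identical(call$best_class, "PhaC1")
  expect_identical(call$strength, "strong")

  weak <- classify_organism(list(PhaC1 = mk(64.9)), "org")
  expect_identical(weak$strength, "weak")
  exact <- classify_organism(list(PhaC1 = mk(65.0)), "org")
  expect_identical(exact$strength, "strong")

  # equal pident: the class with the higher bitscore wins
  tie <- classify_organism(list(PhaC1 = mk(70, bitscore = 110),
                                PhaC3 = mk(70, bitscore = 120)), "org")
  expect_identical(tie$best_class, "PhaC3")

  # within a class, bitscore then pident then accession pick the hit
  multi <- classify_organism(list(PhaC1 = rbind(mk(70, 300, "B"),
                                                mk(75, 300, "A"),
                                                mk(90, 200, "C"))), "org")
  expect_identical(multi$per_class$sacc, "A")

  expect_error(classify_organism(list(), "org"), "no hits")
})

test_that("raising the weak threshold never converts weak to strong", {
  withr::local_seed(11)
  for (i in 1:30) {
    p <- stats::runif(1, 30, 95)
    h <- random_hit_frame(1L); h$pident <- p
    lo <- classify_organism(list(PhaC1 = h), "o",
                            survey_config(weak_threshold = 55))
    hi <- classify_organism(list(PhaC1 = h), "o",
                            survey_config(weak_threshold = 75))
    if (lo$strength == "weak") expect_identical(hi$strength, "weak")
  }
})

test_that("query coverage is alignment length over reference length", {
  ref <- protein_records("R1", random_aa_string(500))
  hit <- random_hit_frame(1L)
  hit$qacc <- "R1"; hit$length <- 250L
  expect_equal(query_coverage(hit, ref), 50)
  self <- local_align(ref, ref)
  expect_equal(query_coverage(self, ref), 100)
  hit$qacc <- "R2"
  expect_error(query_coverage(hit, ref), "does not match")
})

test_that("planted truncation shows up as reduced query coverage", {
  fx <- survey_fixture()
  ct <- fx$res$calls_table
  row <- ct[ct$organism == "Halobacterium truncatum" &
              ct$class == "PhaC_Hme", ]
  expect_true(row$query_coverage >= 60 && row$query_coverage <= 65)
})

test_that("profiles tally strong classes and histogram paralog counts", {
  calls <- list(fake_call("A", "PhaC1"),
                fake_call("B", c("PhaC1", "PhaC3")),
                fake_call("C", c("PhaC_Hme", "PhaC1", "PhaC2", "PhaC3")))
  tal <- tally_profiles(calls)
  expect_identical(unname(tal$summary$histogram),
                   c(0L, 1L, 1L, 0L, 1L))
  expect_identical(tal$summary$most_prevalent, 1L)  # tie resolves smallest
  expect_identical(unname(tal$summary$class_counts["PhaC1"]), 3L)

  allweak <- tally_profiles(list(fake_call("A", character(), "PhaC1"),
                                 fake_call("B", character(), "PhaC2")))
  expect_true(all(allweak$profiles$n_paralogs == 0L))
  expect_identical(unname(allweak$summary$histogram["0"]), 2L)

  duo <- tally_profiles(list(fake_call("A", c("PhaC1", "PhaC3"))))
  expect_identical(duo$profiles$n_paralogs, 2L)
  expect_identical(unname(duo$summary$class_counts),
                   c(0L, 1L, 0L, 1L))
})

test_that("full survey recovers every planted class and strength", {
  fx <- survey_fixture()
  ct <- fx$res$calls_table
  for (tr in fx$truths) {
    for (j in seq_len(nrow(tr$hits))) {
      row <- ct[ct$organism == tr$species & ct$class == tr$hits$class[j], ]
      expect_identical(nrow(row), 1L)
      expect_identical(row$sacc,
                       sprintf("%s_%s", gsub(" ", "_", tr$species),
                               tr$hits$class[j]))
      expect_lt(abs(row$pident - tr$hits$identity[j]), 3.05)
      expect_identical(row$strong, tr$hits$identity[j] >= 65)
    }
  }
  # the two-paralog species classifies to its highest-identity class
  best <- fx$res$calls[["Haloferax duplexa"]]
  expect_identical(best$best_class, "PhaC1")
  expect_identical(best$strength, "strong")
  # histogram reflects planted paralog counts: one species with 2 strong
  # classes, one with 1, one weak-only
  expect_identical(unname(fx$res$summary$histogram),
                   c(1L, 1L, 1L, 0L, 0L))
})

test_that("survey orchestration errors and reruns deterministically", {
  expect_error(run_survey(example_reference_set(), character()),
               "no proteomes found")
  fx <- survey_fixture()
  res2 <- run_survey(fx$refs, fx$ds$proteome_paths, fx$ds$loci_path)
  expect_equal(res2$calls_table, fx$res$calls_table)
  expect_equal(res2$summary, fx$res$summary)
  # written artifacts round-trip through the seqio dialects
  hits_back <- read_hit_table(file.path(fx$dir, "out", "hits.tsv"))
  expect_identical(nrow(hits_back), nrow(fx$res$hits))
})
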