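# a small deterministic scenario: one drug, four indications, hand-set
# probabilities; criteria built directly so q matches the worked example
toy_suggestion_setup <- function() {
  pm <- build_phenome_matrix(tibble::tribble(
    ~drug_id, ~term_id, ~term_class,
    "dX", "i1", "indication",
    "dX", "i4", "indication",
    "dX", "s1", "side_effect",
    "dY", "i2", "indication",
    "dY", "i3", "indication"
  ))
  pid <- matrix(c(0.5, 0.3, 0.004, 0.196), 1, 4,
                dimnames = list("dX", c("i1", "i2", "i3", "i4")))
  crit <- structure(
    list(q = 0.005, n_known_pairs = 3L,
         per_drug_is = c(dX = 2L, dY = 1L), default_is = 13L),
    class = "decision_criteria"
  )
  list(pm = pm, pid = pid, crit = crit)
}

test_that("suggestions pass both criteria and never include known pairs", {
  tv <- toy_suggestion_setup()
  sug <- suggest_indications(tv$pm, tv$pid, tv$crit)
  # i1 (known, rank 1) consumes one IS slot; i2 (novel, 0.3, rank 2) is the
  # single suggestion; i3 fails the chance test; i4 is known
  expect_equal(nrow(sug), 1L)
  expect_equal(sug$term_id, "i2")
  expect_equal(sug$rank, 2L)
  expect_true(all(sug$novel))
})

test_that("suggestions satisfy both criteria by independent re-checking", {
  sp <- generate_lda_phenome(
    n_drugs = 100, n_side_effects = 150, n_indications = 100,
    n_topics = 6, alpha = 0.5, beta = 0.05, tokens_per_drug = 20, seed = 5
  )
  pm <- sp$matrix
  crit <- decision_criteria(pm)
  m <- fit_lda(as_phenome_corpus(pm),
               lda_config(6, alpha = 0.5, beta = 0.05, seed = 9))
  pid <- indication_probabilities(phenotype_probabilities(m), pm)
  sug <- suggest_indications(pm, pid, crit)
  expect_gt(nrow(sug), 0)

  # independent verifier pass over every emitted suggestion
  ind <- pm$mat[, indication_ids(pm), drop = FALSE]
  expect_true(all(ind[cbind(sug$drug_id, sug$term_id)] == 0)) # novelty
  expect_true(all(sug$probability > crit$q))                  # chance rule
  expect_true(all(sug$rank <= sug$is))                        # IS rule
  # ranks are consistent with pid: no novel term with higher probability
  # than a suggested one was skipped below the IS cutoff
  for (i in head(seq_len(nrow(sug)), 10)) {
    p <- pid[sug$drug_id[i], ]
    expect_equal(sum(p > p[sug$term_id[i]]) + 1L, sug$rank[i])
  }

  # drugs with zero known indications never appear
  expect_true(all(known_indication_counts(pm)[unique(sug$drug_id)] > 0))
})

test_that("suggestion output is invariant to input record order", {
  sp <- generate_lda_phenome(
    n_drugs = 40, n_side_effects = 30, n_indications = 25,
    n_topics = 3, alpha = 0.3, beta = 0.05, tokens_per_drug = 15, seed = 8
  )
  recs <- tidy(sp$matrix)
  set.seed(1)
  shuffled <- recs[sample.int(nrow(recs)), ]
  run <- function(r) {
    pm <- build_phenome_matrix(r)
    m <- fit_lda(as_phenome_corpus(pm),
                 lda_config(3, alpha = 0.3, beta = 0.05,
                            n_iterations = 300, burn_in = 100, seed = 4))
    pid <- indication_probabilities(phenotype_probabilities(m), pm)
    suggest_indications(pm, pid, decision_criteria(pm))
  }
  expect_identical(run(recs), run(shuffled))
})

test_that("retrieval serves only drugs without indications, thresholded", {
  tv <- toy_suggestion_setup()
  expect_error(retrieve_indications(tv$pm, tv$pid, tv$crit, "dX"),
               "suggest_indications")

  # all probabilities at or below chance: empty retrieval
  pid0 <- matrix(rep(0.25, 4), 1, 4,
                 dimnames = list("dZ", c("i1", "i2", "i3", "i4")))
  crit0 <- structure(
    list(q = 0.25, n_known_pairs = 1L, per_drug_is = c(dZ = 0L),
         default_is = 13L),
    class = "decision_criteria"
  )
  pm0 <- build_phenome_matrix(tibble::tribble(
    ~drug_id, ~term_id, ~term_class,
    "dZ", "s1", "side_effect",
    "dW", "i1", "indication",
    "dW", "i2", "indication",
    "dW", "i3", "indication",
    "dW", "i4", "indication"
  ))
  expect_equal(nrow(retrieve_indications(pm0, pid0, crit0, "dZ")), 0L)
})

test_that("retrieval recovers a stripped drug's own-block indications", {
  fx <- make_block_fixture(5, 10, 20, 0.15, 0.02, seed = 2)
  recs <- tidy(fx$matrix)
  stripped <- dplyr::filter(
    recs, !(drug_id == "d001" & term_class == "indication")
  )
  pm <- build_phenome_matrix(stripped)
  expect_equal(known_indication_counts(pm)[["d001"]], 0L)
  crit <- decision_criteria(pm)
  m <- fit_lda(as_phenome_corpus(pm), lda_config(5, alpha = 0.1, seed = 3))
  pid <- indication_probabilities(phenotype_probabilities(m), pm)
  ret <- retrieve_indications(pm, pid, crit, "d001")
  expect_gt(nrow(ret), 0)
  expect_lte(nrow(ret), crit$default_is)
  expect_gt(sum(grepl("^b01_", ret$term_id)), 0) # block 1 is drug d001's
  expect_true(all(ret$probability > crit$q))
})

test_that("drug queries rank by score with k from the column sum", {
  pm <- build_phenome_matrix(tibble::tribble(
    ~drug_id, ~term_id, ~term_class,
    "d1", "iq", "indication",
    "d2", "iq", "indication",
    "d1", "io", "indication",
    "d3", "s1", "side_effect"
  ))
  pid <- matrix(c(0.2, 0.8, 0.5, 0.5, 0.9, 0.1), 3, 2, byrow = TRUE,
                dimnames = list(c("d1", "d2", "d3"), c("iq", "io")))
  qd <- query_drugs(pm, pid, "iq")
  expect_equal(qd$drug_id, c("d3", "d2", "d1"))
  expect_equal(attr(qd, "k"), 2L)
  # candidates: top-k minus known holders; d3 is new in the top 2
  expect_equal(qd$drug_id[qd$candidate], "d3")
  expect_error(query_drugs(pm, pid, "nope"), "unknown indication")

  # single-drug indication whose holder is top-ranked: no candidates
  qd2 <- query_drugs(pm, pid, "io")
  expect_equal(attr(qd2, "k"), 1L)
  expect_equal(qd2$drug_id[1], "d1") # the sole holder tops its own query
  expect_equal(sum(qd2$candidate), 0L)
  # the query scores are exactly the pid column
  expect_equal(setNames(qd2$score, qd2$drug_id),
               sort(pid[, "io"], decreasing = TRUE))
})
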