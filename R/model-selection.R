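#' Deterministic train/held-out token split
#'
#' Holds out every `every`-th token of each document, counting along the
#' document's canonical token order, so the split is reproducible without a
#' separate RNG stream. Documents with fewer than `every` tokens contribute
#' no held-out tokens.
#'
#' @param corpus a `phenome_corpus`.
#' @param every hold out token positions `every, 2*every, ...` (default 10,
#'   i.e. a 90/10 split).
#' @return list with `train` and `test` corpora sharing the vocabulary.
#' @export
heldout_split <- function(corpus, every = 10L) {
  stopifnot(inherits(corpus, "phenome_corpus"), every >= 2L)
  split_one <- function(doc) {
    idx <- seq_along(doc)
    held <- idx %% every == 0L
    list(train = doc[!held], test = doc[held])
  }
  parts <- lapply(corpus$documents, split_one)
  mk <- function(which) {
    structure(
      list(
        documents = lapply(parts, `[[`, which),
        vocabulary = corpus$vocabulary
      ),
      class = "phenome_corpus"
    )
  }
  list(train = mk("train"), test = mk("test"))
}

#' Choose the number of topics over a candidate grid
#'
#' For each candidate K the corpus is split 90/10 by [heldout_split()],
#' `replicates` models are fitted on the training tokens with derived seeds,
#' and the criterion is evaluated on the held-out tokens; the K with the
#' smallest mean score wins, ties going to the smaller K. The default
#' criterion is held-out perplexity; any other information-loss style
#' objective can be registered as `criterion = "plugin"` with a
#' `plugin_fn(model, test_corpus)` returning a scalar to minimize.
#'
#' @param corpus a `phenome_corpus`.
#' @param grid positive integer candidates for K.
#' @param criterion `"heldout_perplexity"` (default) or `"plugin"`.
#' @param replicates fits per K (scores are averaged).
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param plugin_fn required when `criterion = "plugin"`.
#' @param config_fn optional function `K -> lda_config` to override sampler
#'   settings; the derived seed is applied afterwards.
#' @return a `topic_selection`: `chosen_k`, per-fit `scores` tibble, and a
#'   per-K `summary` tibble.
#' @export
select_topics <- function(corpus, grid,
                          criterion = c("heldout_perplexity", "plugin"),
                          replicates = 3L, seed = 0L,
                          plugin_fn = NULL, config_fn = NULL) {
  stopifnot(inherits(corpus, "phenome_corpus"), length(grid) >= 1L,
            all(grid >= 1L), replicates >= 1L)
  criterion <- arg_match(criterion)
  if (criterion == "plugin" && !is.function(plugin_fn)) {
    abort("criterion = 'plugin' requires a plugin_fn(model, test_corpus)")
  }
  score_fn <- if (criterion == "plugin") plugin_fn else heldout_perplexity
  split <- heldout_split(corpus)
  if (n_corpus_tokens(split$test) == 0L) {
    abort("corpus too small for a 90/10 held-out split")
  }

  grid <- as.integer(grid)
  scores <- purrr::map_dfr(seq_along(grid), function(gi) {
    k <- grid[gi]
    purrr::map_dfr(seq_len(replicates), function(r) {
      fit_seed <- as.integer(seed) + 7919L * gi + r
      cfg <- if (is.null(config_fn)) lda_config(k) else config_fn(k)
      cfg$seed <- fit_seed
      model <- fit_lda(split$train, cfg)
      tibble(k = k, replicate_id = r, seed = fit_seed,
             score = score_fn(model, split$test))
    })
  })
  summary <- scores |>
    group_by(k) |>
    summarise(mean_score = mean(score), sd_score = stats::sd(score),
              .groups = "drop") |>
    arrange(k)
  if (!all(is.finite(summary$mean_score))) {
    abort("non-finite criterion score encountered")
  }
  chosen <- summary$k[which.min(summary$mean_score)]  # which.min: first min
  structure(
    list(chosen_k = chosen, scores = scores, summary = summary,
         criterion = criterion, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "topic_selection"
  )
}

#' @export
print.topic_selection <- function(x, ...) {
  cat("<topic_selection> chosen K = ", x$chosen_k, " by ", x$criterion,
      " over grid {", paste(x$summary$k, collapse = ", "), "}, ",
      x$replicates, " replicate(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.topic_selection <- function(x, ...) x$scores

#' @export
glance.topic_selection <- function(x, ...) {
  tibble(
    chosen_k = x$chosen_k, criterion = x$criterion,
    replicates = x$replicates, seed = x$seed,
    best_score = min(x$summary$mean_score)
  )
}
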