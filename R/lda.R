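#' Configuration for the collapsed Gibbs LDA fit
#'
#' Hyperparameters and sampler schedule for [fit_lda()]. Defaults follow the
#' common Gibbs-LDA conventions: symmetric document prior `alpha = 50/K`,
#' symmetric topic-word prior `beta = 0.01`, 2,000 sweeps with a 500-sweep
#' burn-in and posterior-mean samples taken every 10 sweeps thereafter.
#'
#' @param n_topics number of topics K (>= 1).
#' @param alpha,beta positive symmetric Dirichlet concentrations for the
#'   per-drug topic mixtures and per-topic phenotype distributions.
#' @param n_iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging; must be < `n_iterations`.
#' @param sample_lag sweeps between retained posterior samples.
#' @param seed integer seed; identical seed + config + corpus gives a
#'   bit-identical model.
#' @return an `lda_config` list.
#' @export
lda_config <- function(n_topics,
                       alpha = 50 / n_topics,
                       beta = 0.01,
                       n_iterations = 2000L,
                       burn_in = 500L,
                       sample_lag = 10L,
                       seed = 1L) {
  stopifnot(
    length(n_topics) == 1L, n_topics >= 1L,
    alpha > 0, beta > 0,
    n_iterations >= 1L, burn_in >= 0L, burn_in < n_iterations,
    sample_lag >= 1L
  )
  structure(
    list(
      n_topics = as.integer(n_topics), alpha = alpha, beta = beta,
      n_iterations = as.integer(n_iterations), burn_in = as.integer(burn_in),
      sample_lag = as.integer(sample_lag), seed = as.integer(seed)
    ),
    class = "lda_config"
  )
}

#' Fit latent Dirichlet allocation to a phenome corpus
#'
#' Runs a collapsed Gibbs sampler over the token-level topic assignments and
#' returns posterior-mean estimates of the per-drug topic mixtures
#' `theta` (\eqn{M \times K}, rows are \eqn{p(t|d)}) and the per-topic
#' phenotype distributions `phi` (\eqn{K \times N}, rows are \eqn{p(ph|t)}),
#' averaged over post-burn-in states at the configured lag. Every row of both
#' matrices sums to 1; all randomness goes through R's RNG, so fits are
#' reproducible from `config$seed`.
#'
#' @param corpus a `phenome_corpus` from [as_phenome_corpus()].
#' @param config an [lda_config()].
#' @return an `lda_model` with elements `theta`, `phi`, `config`,
#'   `n_samples`.
#' @export
fit_lda <- function(corpus, config) {
  stopifnot(inherits(corpus, "phenome_corpus"), inherits(config, "lda_config"))
  n_tokens <- n_corpus_tokens(corpus)
  if (length(corpus$documents) == 0L || n_tokens == 0L) {
    abort("cannot fit LDA to an empty corpus")
  }
  if (config$n_topics > n_tokens) {
    warn("more topics than tokens; surplus topics will stay near the prior")
  }
  docs0 <- lapply(corpus$documents, function(d) as.integer(d) - 1L)
  set.seed(config$seed)
  fit <- cpp_lda_gibbs(
    docs0, length(corpus$vocabulary), config$n_topics,
    config$alpha, config$beta,
    config$n_iterations, config$burn_in, config$sample_lag
  )
  theta <- fit$theta
  phi <- fit$phi
  dimnames(theta) <- list(names(corpus$documents),
                          paste0("topic", seq_len(config$n_topics)))
  dimnames(phi) <- list(paste0("topic", seq_len(config$n_topics)),
                        corpus$vocabulary)
  structure(
    list(theta = theta, phi = phi, config = config,
         n_samples = fit$n_samples),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> K = ", x$config$n_topics, ", ", nrow(x$theta),
      " drugs, ", ncol(x$phi), " phenotypes, posterior mean over ",
      x$n_samples, " Gibbs samples (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Tidy LDA estimates
#'
#' @param x an `lda_model`.
#' @param matrix `"theta"` for per-drug topic mixtures (columns `drug_id`,
#'   `topic`, `probability`) or `"phi"` for per-topic phenotype
#'   distributions (columns `topic`, `term_id`, `probability`).
#' @param ... unused.
#' @export
tidy.lda_model <- function(x, matrix = c("theta", "phi"), ...) {
  matrix <- arg_match(matrix)
  if (matrix == "theta") {
    as_tibble(x$theta, rownames = "drug_id") |>
      tidyr::pivot_longer(-drug_id, names_to = "topic",
                          values_to = "probability")
  } else {
    as_tibble(x$phi, rownames = "topic") |>
      tidyr::pivot_longer(-topic, names_to = "term_id",
                          values_to = "probability")
  }
}

#' @export
glance.lda_model <- function(x, ...) {
  tibble(
    n_topics = x$config$n_topics, alpha = x$config$alpha,
    beta = x$config$beta, n_iterations = x$config$n_iterations,
    burn_in = x$config$burn_in, sample_lag = x$config$sample_lag,
    seed = x$config$seed, n_drugs = nrow(x$theta), n_terms = ncol(x$phi),
    n_samples = x$n_samples
  )
}

#' Held-out perplexity of a corpus under a fitted model
#'
#' Computes `exp(-sum(log p(ph|d)) / n_tokens)` where \eqn{p(ph|d)} is the
#' path probability \eqn{\sum_t p(t|d) p(ph|t)}. Lower is better; a model
#' that assigns the held-out tokens probability 1 has perplexity 1, and a
#' uniform phenotype distribution over a vocabulary of V terms has
#' perplexity V.
#'
#' @param model an `lda_model`.
#' @param corpus a `phenome_corpus`; documents are matched to model drugs by
#'   name and every token must exist in the model vocabulary.
#' @return a positive scalar.
#' @export
heldout_perplexity <- function(model, corpus) {
  stopifnot(inherits(model, "lda_model"), inherits(corpus, "phenome_corpus"))
  vocab_map <- match(corpus$vocabulary, colnames(model$phi))
  if (anyNA(vocab_map)) {
    abort("corpus contains tokens outside the model vocabulary")
  }
  docs <- corpus$documents[lengths(corpus$documents) > 0L]
  if (length(docs) == 0L) abort("no held-out tokens to score")
  drug_rows <- match(names(docs), rownames(model$theta))
  if (anyNA(drug_rows)) abort("corpus contains drugs unknown to the model")
  pphd <- phenotype_probabilities(model)
  loglik <- 0
  n_tok <- 0L
  for (i in seq_along(docs)) {
    p <- pphd[drug_rows[i], vocab_map[docs[[i]]]]
    loglik <- loglik + sum(log(p))
    n_tok <- n_tok + length(docs[[i]])
  }
  exp(-loglik / n_tok)
}

#' Serialize and restore a fitted model
#'
#' `theta` and `phi` are written as TSV matrices with drug/term headers at
#' full binary precision (17 significant digits), plus a config sidecar;
#' reloading restores bit-identical matrices.
#'
#' @param model an `lda_model`.
#' @param stem path prefix; creates `<stem>_theta.tsv`, `<stem>_phi.tsv`,
#'   `<stem>_config.tsv`.
#' @export
write_lda_model <- function(model, stem) {
  paths <- paste0(stem, c("_theta.tsv", "_phi.tsv", "_config.tsv"))
  write_num_matrix(model$theta, paths[1], "drug_id")
  write_num_matrix(model$phi, paths[2], "topic")
  cfg <- model$config
  readr::write_tsv(
    tibble(
      key = c(names(cfg), "n_samples"),
      value = c(
        vapply(cfg, function(v) formatC(v, digits = 17, format = "g"),
               character(1)),
        as.character(model$n_samples)
      )
    ),
    paths[3]
  )
  invisible(paths)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(stem) {
  theta <- read_num_matrix(paste0(stem, "_theta.tsv"))
  phi <- read_num_matrix(paste0(stem, "_phi.tsv"))
  cfg_tbl <- readr::read_tsv(
    paste0(stem, "_config.tsv"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  cfg <- setNames(as.list(as.numeric(cfg_tbl$value)), cfg_tbl$key)
  config <- lda_config(
    n_topics = cfg$n_topics, alpha = cfg$alpha, beta = cfg$beta,
    n_iterations = cfg$n_iterations, burn_in = cfg$burn_in,
    sample_lag = cfg$sample_lag, seed = cfg$seed
  )
  structure(
    list(theta = theta, phi = phi, config = config,
         n_samples = as.integer(cfg$n_samples)),
    class = "lda_model"
  )
}

write_num_matrix <- function(m, path, rowname_col) {
  header <- paste(c(rowname_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            formatC(m[i, ], digits = 17, format = "g")), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

read_num_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
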