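#' Enumerate maskable known drug-indication pairs
#'
#' Lists every 1-cell in the indication columns. A pair is eligible for
#' masking only when its indication is held by at least two drugs: masking
#' the sole holder would remove the indication from the data set entirely
#' rather than hide one link. Order is deterministic (canonical column order,
#' then drug id).
#'
#' @param x a [phenome_matrix].
#' @return tibble with `drug_id`, `term_id`, `eligible`.
#' @export
enumerate_maskable_pairs <- function(x) {
  stopifnot(inherits(x, "phenome_matrix"))
  ind_cols <- which(x$classes == "indication")
  sub <- x$mat[, ind_cols, drop = FALSE]
  col_sums <- Matrix::colSums(sub)
  trip <- Matrix::mat2triplet(sub)
  tibble(
    drug_id = rownames(sub)[trip$i],
    term_id = colnames(sub)[trip$j],
    eligible = col_sums[trip$j] >= 2
  ) |>
    arrange(match(term_id, colnames(sub)), drug_id)
}

# score the masked indication for one drug under a fitted model
score_masked <- function(theta_row, phi, x, criteria, drug, term) {
  row <- cpp_path_probabilities(theta_row, phi)
  dimnames(row) <- list(drug, colnames(phi))
  pid <- suppressWarnings(indication_probabilities(row, x))
  ranked <- rank_and_decide(pid, criteria, drug)
  ranked[ranked$term_id == term, ]
}

#' Leave-one-out masked-indication recovery experiment
#'
#' For each eligible known drug-indication pair, one at a time: the cell is
#' switched from 1 to 0, the model is re-estimated on the perturbed data, the
#' masked indication's renormalized probability `p(i|d)` and its rank among
#' all indications are computed, and both decision criteria are applied. The
#' drug's indication space (IS) is always taken from the unperturbed matrix,
#' so the masked link itself still counts toward IS. The input matrix is
#' never modified.
#'
#' Two re-estimation policies are available. `mode = "refit"` (default)
#' refits the full model on the perturbed matrix with a per-pair derived
#' seed. `mode = "foldin"` fits one model on the unperturbed matrix and, per
#' pair, re-samples only the perturbed drug's topic assignments against the
#' fixed topic-phenotype distributions - much cheaper for large matrices, at
#' the cost of phi still having seen the masked cell.
#'
#' @param x a [phenome_matrix].
#' @param config an [lda_config()]; its seed is combined with the pair index
#'   so every pair gets an independent, reproducible fit.
#' @param pairs optional tibble with `drug_id`, `term_id` selecting a subset
#'   of the eligible pairs (e.g. a random sample for large matrices);
#'   defaults to all eligible pairs. Requesting an ineligible pair is an
#'   error naming it.
#' @param criteria a [decision_criteria()]; defaults to criteria computed
#'   from `x`.
#' @param mode `"refit"` or `"foldin"`.
#' @return a `recovery_report`: per-pair `results` tibble (`drug_id`,
#'   `term_id`, `probability`, `rank`, `above_chance`, `within_is`, `is`)
#'   plus the mode, criteria and config used.
#' @export
run_recovery <- function(x, config, pairs = NULL,
                         criteria = decision_criteria(x),
                         mode = c("refit", "foldin")) {
  stopifnot(inherits(x, "phenome_matrix"), inherits(config, "lda_config"))
  mode <- arg_match(mode)
  eligible <- enumerate_maskable_pairs(x) |> filter(eligible)
  if (is.null(pairs)) {
    pairs <- eligible
  } else {
    pairs <- as_tibble(pairs)[, c("drug_id", "term_id")]
    key <- paste(pairs$drug_id, pairs$term_id, sep = "\r")
    ok <- key %in% paste(eligible$drug_id, eligible$term_id, sep = "\r")
    if (!all(ok)) {
      abort(paste0(
        "ineligible pair(s) requested: ",
        paste(paste(pairs$drug_id[!ok], pairs$term_id[!ok]), collapse = "; ")
      ))
    }
  }
  if (nrow(pairs) == 0L) abort("no maskable pairs to test")

  base_model <- NULL
  base_corpus <- NULL
  if (mode == "foldin") {
    base_corpus <- as_phenome_corpus(x)
    base_model <- fit_lda(base_corpus, config)
  }
  col_index <- match(pairs$term_id, colnames(x$mat))

  results <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    drug <- pairs$drug_id[i]
    term <- pairs$term_id[i]
    pair_seed <- config$seed + i
    if (mode == "refit") {
      masked <- set_cell(x, drug, term, 0)
      cfg <- config
      cfg$seed <- pair_seed
      model <- fit_lda(as_phenome_corpus(masked), cfg)
      theta_row <- model$theta[drug, , drop = FALSE]
      phi <- model$phi
    } else {
      doc <- base_corpus$documents[[drug]]
      doc <- doc[doc != col_index[i]]
      set.seed(pair_seed)
      theta_vec <- cpp_lda_foldin(
        as.integer(doc) - 1L, base_model$phi, config$alpha,
        config$n_iterations, config$burn_in, config$sample_lag
      )
      theta_row <- matrix(theta_vec, nrow = 1,
                          dimnames = list(drug, colnames(base_model$theta)))
      phi <- base_model$phi
    }
    score_masked(theta_row, phi, x, criteria, drug, term)
  })
  results$is <- vapply(results$drug_id, function(d) is_for_drug(criteria, d),
                       integer(1), USE.NAMES = FALSE)
  structure(
    list(results = results, mode = mode, criteria = criteria,
         config = config),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  g <- generics::glance(x)
  cat("<recovery_report> ", g$n_tested, " masked pairs (", x$mode,
      " mode): ", g$n_above_chance, " above chance, ", g$n_recovered,
      " recovered; success rate s = ",
      ifelse(is.na(g$success_rate), "undefined",
             paste0(round(100 * g$success_rate), "%")),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.recovery_report <- function(x, ...) x$results

#' @export
glance.recovery_report <- function(x, ...) {
  r <- x$results
  n_above <- sum(r$above_chance)
  n_rec <- sum(r$above_chance & r$within_is)
  tibble(
    n_tested = nrow(r),
    n_above_chance = n_above,
    n_recovered = n_rec,
    n_within_is = sum(r$within_is),
    success_rate = if (n_above == 0) NA_real_ else n_rec / n_above,
    mode = x$mode,
    q = x$criteria$q
  )
}

#' Recovery success rate
#'
#' Among masked pairs whose recovered probability beats random chance, the
#' fraction also ranked within the drug's indication space:
#' `s = n_recovered / n_above_chance`. Undefined (`NA`) when nothing is above
#' chance - an empty denominator is not a 0% success rate.
#'
#' @param n_recovered,n_above_chance counts with
#'   `n_recovered <= n_above_chance`.
#' @return proportion in `[0, 1]`, or `NA_real_` when
#'   `n_above_chance == 0`.
#' @examples
#' success_rate(3844, 5516) # ~0.70
#' @export
success_rate <- function(n_recovered, n_above_chance) {
  stopifnot(n_recovered >= 0, n_above_chance >= 0,
            n_recovered <= n_above_chance)
  if (n_above_chance == 0) {
    warn("no pairs above chance; success rate is undefined")
    return(NA_real_)
  }
  n_recovered / n_above_chance
}

#' Summarize a recovery experiment
#'
#' Produces the aggregate success rate, a histogram of recovered `p(i|d)`
#' values (bin width aligned to the chance threshold by default), and the
#' success rate stratified by the drug's indication space: for each IS
#' cutoff, the rate recomputed after dropping all drugs with IS below the
#' cutoff, which exposes the dependence of recoverability on how much
#' indication information a drug carries.
#'
#' @param report a `recovery_report`, or its per-pair results tibble.
#' @param bin_width histogram bin width (default 0.005).
#' @return list of tibbles: `summary`, `histogram` (`bin_lower`,
#'   `bin_upper`, `n`, `n_above_chance`), `by_is_cutoff` (`min_is`,
#'   `n_tested`, `n_above_chance`, `n_recovered`, `success_rate`).
#' @export
summarize_recovery <- function(report, bin_width = 0.005) {
  stopifnot(bin_width > 0)
  if (inherits(report, "recovery_report")) {
    r <- report$results
    q <- report$criteria$q
  } else {
    r <- as_tibble(report)
    q <- attr(report, "q") %||% NA_real_
  }
  if (nrow(r) == 0L) abort("empty recovery report")
  n_above <- sum(r$above_chance)
  n_rec <- sum(r$above_chance & r$within_is)
  summary <- tibble(
    n_tested = nrow(r), n_above_chance = n_above, n_recovered = n_rec,
    success_rate = success_rate(n_rec, n_above), q = q,
    bin_width = bin_width
  )
  bins <- floor(r$probability / bin_width)
  histogram <- tibble(bin = bins, above_chance = r$above_chance) |>
    group_by(bin) |>
    summarise(n = n(), n_above_chance = sum(above_chance),
              .groups = "drop") |>
    mutate(bin_lower = bin * bin_width, bin_upper = (bin + 1) * bin_width) |>
    select(bin_lower, bin_upper, n, n_above_chance)
  cutoffs <- sort(unique(r$is))
  by_is <- purrr::map_dfr(cutoffs, function(v) {
    sub <- r[r$is >= v, ]
    na <- sum(sub$above_chance)
    nr <- sum(sub$above_chance & sub$within_is)
    tibble(
      min_is = v, n_tested = nrow(sub), n_above_chance = na,
      n_recovered = nr,
      success_rate = if (na == 0) NA_real_ else nr / na
    )
  })
  list(summary = summary, histogram = histogram, by_is_cutoff = by_is)
}

#' Write a recovery report as TSV files
#'
#' @param report a `recovery_report`.
#' @param stem path prefix; writes `<stem>_pairs.tsv` and
#'   `<stem>_summary.tsv`.
#' @export
write_recovery_report <- function(report, stem) {
  paths <- paste0(stem, c("_pairs.tsv", "_summary.tsv"))
  readr::write_tsv(report$results, paths[1])
  readr::write_tsv(generics::glance(report), paths[2])
  invisible(paths)
}
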