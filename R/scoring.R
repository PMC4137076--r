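#' Drug-to-phenotype path probabilities
#'
#' Combines the fitted conditionals into
#' \eqn{p(ph|d) = \sum_t p(t|d)\, p(ph|t)}, i.e. the matrix product
#' `theta %*% phi`, computed with an explicit fixed-order accumulation over
#' topics so results are reproducible to the bit. Every drug row sums to 1.
#'
#' @param model an `lda_model`.
#' @return numeric matrix (drugs x phenotypes) with dimnames.
#' @export
phenotype_probabilities <- function(model) {
  stopifnot(inherits(model, "lda_model"))
  if (ncol(model$theta) != nrow(model$phi)) {
    abort("theta and phi disagree on the number of topics")
  }
  out <- cpp_path_probabilities(model$theta, model$phi)
  dimnames(out) <- list(rownames(model$theta), colnames(model$phi))
  out
}

#' Indication-restricted, per-drug renormalized probabilities
#'
#' Restricts the phenotype probabilities to indication columns and
#' renormalizes each drug row to sum to 1 (the paper-style `p(i|d)` used for
#' ranking). Renormalization is a positive per-row rescaling, so the order of
#' indications within a drug is unchanged. Rows with zero indication mass
#' (possible only for degenerate models) are set to `NA`, flagged in the
#' `"excluded_drugs"` attribute, and warned about.
#'
#' @param pphd matrix from [phenotype_probabilities()].
#' @param x the [phenome_matrix] the model was fitted to (supplies the
#'   indication column set).
#' @return numeric matrix (drugs x indications), rows summing to 1.
#' @export
indication_probabilities <- function(pphd, x) {
  stopifnot(inherits(x, "phenome_matrix"))
  ind <- indication_ids(x)
  if (length(ind) == 0L) abort("matrix has no indication columns")
  if (!all(ind %in% colnames(pphd))) {
    abort("phenotype probabilities lack some indication columns")
  }
  sub <- pphd[, ind, drop = FALSE]
  mass <- rowSums(sub)
  zero <- mass <= 0 | !is.finite(mass)
  if (any(zero)) {
    warn(paste0(
      sum(zero), " drug(s) have zero indication mass and are excluded ",
      "from ranking"
    ))
    sub[zero, ] <- NA_real_
    mass[zero] <- 1
  }
  out <- sub / mass
  attr(out, "excluded_drugs") <- rownames(sub)[zero]
  out
}

#' Random-chance probability of a known drug-indication pair
#'
#' The probability of drawing one of the `n_known_pairs` known
#' drug-indication links uniformly from the full `n_drugs x n_indications`
#' grid: `q = n_known_pairs / (n_drugs * n_indications)`. Predicted
#' probabilities at or below `q` are treated as indistinguishable from
#' chance.
#'
#' @param n_known_pairs,n_drugs,n_indications positive counts, with
#'   `n_known_pairs <= n_drugs * n_indications`.
#' @return the probability `q`.
#' @examples
#' random_chance(12066, 996, 2276) # ~0.005
#' @export
random_chance <- function(n_known_pairs, n_drugs, n_indications) {
  stopifnot(n_known_pairs > 0, n_drugs > 0, n_indications > 0)
  if (n_known_pairs > n_drugs * n_indications) {
    abort("more known pairs than grid cells")
  }
  n_known_pairs / (n_drugs * n_indications)
}

#' Decision criteria: random chance and indication space
#'
#' Bundles the two acceptance rules for a predicted drug-indication link:
#' its renormalized probability must strictly exceed the random-chance
#' threshold `q`, and its rank among all indications for the drug must fall
#' within the drug's indication space (IS), the count of its known
#' indications. Drugs with no known indications fall back to `default_is`
#' (13, the average indication count in the SIDER release the method was
#' developed on).
#'
#' @param x a [phenome_matrix].
#' @param default_is fallback IS for drugs with zero known indications.
#' @param n_known_pairs count used in `q`; defaults to all known
#'   drug-indication pairs in `x`.
#' @return a `decision_criteria` list: `q`, `n_known_pairs`, `per_drug_is`
#'   (named integer vector), `default_is`.
#' @export
decision_criteria <- function(x, default_is = 13L, n_known_pairs = NULL) {
  stopifnot(inherits(x, "phenome_matrix"), default_is >= 1L)
  g <- generics::glance(x)
  n_known <- as.integer(n_known_pairs %||% g$n_known_pairs)
  structure(
    list(
      q = random_chance(n_known, g$n_drugs, g$n_indications),
      n_known_pairs = n_known,
      per_drug_is = known_indication_counts(x),
      default_is = as.integer(default_is)
    ),
    class = "decision_criteria"
  )
}

#' @export
print.decision_criteria <- function(x, ...) {
  cat("<decision_criteria> q = ", signif(x$q, 4), " (", x$n_known_pairs,
      " known pairs), IS for ", length(x$per_drug_is),
      " drugs, default IS = ", x$default_is, "\n", sep = "")
  invisible(x)
}

is_for_drug <- function(criteria, drug) {
  k <- criteria$per_drug_is[[drug]]
  if (is.null(k) || is.na(k) || k == 0L) criteria$default_is else k
}

#' Rank all indications for one drug and apply both criteria
#'
#' Orders all indications by descending `p(i|d)` (ties broken by the
#' canonical column order, so ranking is stable and deterministic) and flags
#' each against the two decision rules.
#'
#' @param pid matrix from [indication_probabilities()].
#' @param criteria a [decision_criteria()].
#' @param drug a drug id present in `pid`.
#' @return tibble with one row per indication: `drug_id`, `term_id`,
#'   `probability`, `rank` (1 = most probable), `above_chance`
#'   (`probability > q`, strictly), `within_is` (`rank <= IS(drug)`).
#' @export
rank_and_decide <- function(pid, criteria, drug) {
  stopifnot(inherits(criteria, "decision_criteria"))
  if (!drug %in% rownames(pid)) abort(paste0("unknown drug: ", drug))
  p <- pid[drug, ]
  if (anyNA(p)) abort(paste0("drug ", drug, " was excluded (zero indication mass)"))
  ord <- order(-p, seq_along(p))
  rnk <- integer(length(p))
  rnk[ord] <- seq_along(p)
  k <- is_for_drug(criteria, drug)
  tibble(
    drug_id = drug,
    term_id = colnames(pid),
    probability = unname(p),
    rank = rnk,
    above_chance = unname(p) > criteria$q,
    within_is = rnk <= k
  ) |>
    arrange(rank)
}

#' Write ranked predictions as TSV
#'
#' @param predictions a tibble of ranked predictions or suggestions.
#' @param path output file.
#' @export
write_scores <- function(predictions, path) {
  readr::write_tsv(predictions, path)
  invisible(path)
}
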