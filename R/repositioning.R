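#' Suggest novel indications for drugs with known indications
#'
#' Applies the two decision criteria to the unperturbed model: for every drug
#' with at least one known indication, all indications are ranked by the
#' renormalized `p(i|d)` and the unobserved ones (cell = 0) that both beat
#' random chance and fall within the drug's indication space are emitted.
#' Known indications participate in the ranking (they typically occupy the
#' top positions, so they consume part of the IS budget) but are never
#' suggested. Drugs without any known indication are handled by
#' [retrieve_indications()] instead.
#'
#' @param x a [phenome_matrix].
#' @param pid matrix from [indication_probabilities()].
#' @param criteria a [decision_criteria()].
#' @return tibble of suggestions sorted by drug then rank: `drug_id`,
#'   `term_id`, `probability`, `rank`, `is`, `novel` (always `TRUE`).
#' @export
suggest_indications <- function(x, pid, criteria) {
  stopifnot(inherits(x, "phenome_matrix"),
            inherits(criteria, "decision_criteria"))
  with_known <- names(which(criteria$per_drug_is > 0L))
  with_known <- intersect(sort(with_known), rownames(pid))
  excluded <- attr(pid, "excluded_drugs") %||% character(0)
  with_known <- setdiff(with_known, excluded)
  ind_mat <- x$mat[, indication_ids(x), drop = FALSE]
  out <- purrr::map_dfr(with_known, function(d) {
    ranked <- rank_and_decide(pid, criteria, d)
    known <- ind_mat[d, ranked$term_id] > 0
    ranked |>
      mutate(novel = !known, is = is_for_drug(criteria, d)) |>
      filter(novel, above_chance, within_is) |>
      select(drug_id, term_id, probability, rank, is, novel)
  })
  arrange(out, drug_id, rank)
}

#' Retrieve indications for a drug recorded without any
#'
#' For a drug whose indication row is empty (as for the 39 SIDER drugs
#' lacking indication records), returns the top `default_is` indications
#' whose probabilities strictly exceed random chance, in rank order. The IS
#' criterion cannot be drug-specific here, so the data-set average
#' (`criteria$default_is`, 13 by default) stands in.
#'
#' @inheritParams suggest_indications
#' @param drug a drug id with zero known indications; a drug that has known
#'   indications is an error directing to [suggest_indications()].
#' @return tibble like [suggest_indications()], at most `default_is` rows.
#' @export
retrieve_indications <- function(x, pid, criteria, drug) {
  stopifnot(inherits(x, "phenome_matrix"),
            inherits(criteria, "decision_criteria"))
  if (!drug %in% rownames(pid)) abort(paste0("unknown drug: ", drug))
  if (isTRUE(criteria$per_drug_is[[drug]] > 0L)) {
    abort(paste0(
      drug, " has known indications; use suggest_indications() for it"
    ))
  }
  rank_and_decide(pid, criteria, drug) |>
    filter(rank <= criteria$default_is, above_chance) |>
    mutate(is = criteria$default_is, novel = TRUE) |>
    select(drug_id, term_id, probability, rank, is, novel)
}

#' Rank drugs for a queried indication
#'
#' The reverse query `p(drug|indication)`: drugs are ordered by their score
#' for the queried indication, computed from the per-drug renormalized
#' `p(i|d)` under a uniform prior over drugs, so the ordering is that of
#' `p(i|d)` read down the indication's column. With `k` set to the number of
#' drugs already known to hold the indication, the drugs in the top `k`
#' positions that are not yet associated with it are the repositioning
#' candidates.
#'
#' @param x a [phenome_matrix].
#' @param pid matrix from [indication_probabilities()].
#' @param indication an indication term id present in the matrix.
#' @return a `drug_query`: tibble with `drug_id`, `score`, `rank`, `known`,
#'   `candidate`, carrying the queried `indication` and `k` as attributes.
#' @export
query_drugs <- function(x, pid, indication) {
  stopifnot(inherits(x, "phenome_matrix"))
  if (!indication %in% indication_ids(x)) {
    abort(paste0("unknown indication: ", indication))
  }
  scores <- pid[, indication]
  keep <- !is.na(scores)
  scores <- scores[keep]
  ord <- order(-scores, seq_along(scores))
  holders <- rownames(x$mat)[x$mat[, indication] > 0]
  k <- max(1L, length(holders))
  res <- tibble(
    drug_id = names(scores)[ord],
    score = unname(scores)[ord],
    rank = seq_along(ord)
  ) |>
    mutate(
      known = drug_id %in% holders,
      candidate = rank <= k & !known
    )
  structure(res, indication = indication, k = k,
            class = c("drug_query", class(res)))
}

#' @export
print.drug_query <- function(x, ...) {
  cat("<drug_query> indication ", attr(x, "indication"), ", k = ",
      attr(x, "k"), " known holder(s), ", sum(x$candidate),
      " candidate drug(s)\n", sep = "")
  NextMethod()
}
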