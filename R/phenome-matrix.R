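#' The binary drug-phenome incidence matrix
#'
#' A `phenome_matrix` holds a sparse 0/1 matrix with drugs as rows and
#' phenotype terms as columns, together with a class label
#' (`"side_effect"` or `"indication"`) for every column. Columns are stored
#' in canonical order: all side-effect columns first, then all indication
#' columns, each block sorted lexicographically by term id, so every
#' downstream index, rank, and tie-break is reproducible.
#'
#' @name phenome_matrix
#' @seealso [build_phenome_matrix()], [as_phenome_corpus()]
NULL

PHENOTYPE_CLASSES <- c("side_effect", "indication")

# Internal constructor. `mat` is a base or Matrix 0/1 matrix with complete
# dimnames; `classes` labels each column. Columns are reordered canonically.
new_phenome_matrix <- function(mat, classes) {
  mat <- Matrix::Matrix(mat, sparse = TRUE)
  mat <- methods::as(methods::as(mat, "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("phenome matrix needs drug row names and term column names")
  }
  if (anyDuplicated(rownames(mat))) abort("duplicate drug identifiers")
  if (anyDuplicated(colnames(mat))) abort("duplicate phenotype identifiers")
  if (length(classes) != ncol(mat)) {
    abort("one class label per phenotype column is required")
  }
  if (!all(classes %in% PHENOTYPE_CLASSES)) {
    abort("phenotype classes must be 'side_effect' or 'indication'")
  }
  x <- mat@x
  if (length(x) && !all(x %in% c(0, 1))) {
    abort("phenome matrix cells must all be 0 or 1")
  }
  mat <- Matrix::drop0(mat)
  ord <- order(match(classes, PHENOTYPE_CLASSES), colnames(mat))
  structure(
    list(mat = mat[, ord, drop = FALSE], classes = classes[ord]),
    class = "phenome_matrix"
  )
}

#' @export
print.phenome_matrix <- function(x, ...) {
  g <- generics::glance(x)
  cat("<phenome_matrix> ", g$n_drugs, " drugs x ", g$n_phenotypes,
      " phenotypes (", g$n_side_effects, " side effects, ",
      g$n_indications, " indications), ", g$n_known_pairs,
      " known drug-indication pairs\n", sep = "")
  invisible(x)
}

#' @export
dim.phenome_matrix <- function(x) dim(x$mat)

#' Drug and phenotype accessors
#'
#' @param x a [phenome_matrix].
#' @return Character vectors of identifiers, or a named integer vector of
#'   per-drug known-indication counts for [known_indication_counts()].
#' @export
drug_ids <- function(x) rownames(x$mat)

#' @rdname drug_ids
#' @export
phenotype_ids <- function(x) colnames(x$mat)

#' @rdname drug_ids
#' @export
indication_ids <- function(x) colnames(x$mat)[x$classes == "indication"]

#' @rdname drug_ids
#' @export
side_effect_ids <- function(x) colnames(x$mat)[x$classes == "side_effect"]

#' @rdname drug_ids
#' @export
known_indication_counts <- function(x) {
  sub <- x$mat[, x$classes == "indication", drop = FALSE]
  counts <- Matrix::rowSums(sub)
  setNames(as.integer(counts), rownames(sub))
}

#' Summarize a phenome matrix
#'
#' `glance()` returns the one-row accounting of a phenome matrix: drug,
#' side-effect and indication counts, the number of known drug-indication
#' pairs (1-cells in indication columns), and the complementary number of
#' unknown pairs that repositioning can draw from.
#'
#' @param x a [phenome_matrix].
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.phenome_matrix <- function(x, ...) {
  n_ind <- sum(x$classes == "indication")
  ind <- x$mat[, x$classes == "indication", drop = FALSE]
  n_known <- as.integer(sum(ind))
  tibble(
    n_drugs = nrow(x$mat),
    n_phenotypes = ncol(x$mat),
    n_side_effects = sum(x$classes == "side_effect"),
    n_indications = n_ind,
    n_known_pairs = n_known,
    n_unknown_pairs = nrow(x$mat) * n_ind - n_known
  )
}

#' @describeIn glance.phenome_matrix long tibble of all 1-cells
#'   (`drug_id`, `term_id`, `term_class`), in canonical column order.
#' @export
tidy.phenome_matrix <- function(x, ...) {
  trip <- Matrix::mat2triplet(x$mat)
  tibble(
    drug_id = rownames(x$mat)[trip$i],
    term_id = colnames(x$mat)[trip$j],
    term_class = x$classes[trip$j]
  ) |>
    arrange(match(term_class, PHENOTYPE_CLASSES), term_id, drug_id)
}

#' Drug-indication pair accounting from declared counts
#'
#' Computes, from bare counts, the size of the full drug-by-indication grid,
#' the known portion, and the unknown remainder available to repositioning.
#' This is the same accounting [glance.phenome_matrix()] performs on a
#' concrete matrix, exposed for declared totals (e.g. the published SIDER
#' release sizes).
#'
#' @param n_drugs,n_indications,n_known_pairs non-negative counts;
#'   `n_known_pairs` must not exceed the grid size.
#' @return a one-row tibble with `n_possible`, `n_known`, `n_unknown`.
#' @examples
#' pair_accounting(996, 2276, 12066)
#' @export
pair_accounting <- function(n_drugs, n_indications, n_known_pairs) {
  stopifnot(n_drugs >= 0, n_indications >= 0, n_known_pairs >= 0)
  n_possible <- n_drugs * n_indications
  if (n_known_pairs > n_possible) {
    abort("more known pairs than cells in the drug-indication grid")
  }
  tibble(
    n_possible = n_possible,
    n_known = n_known_pairs,
    n_unknown = n_possible - n_known_pairs
  )
}

# set one cell; used by the masking harness. Returns a new object.
set_cell <- function(x, drug, term, value) {
  m <- x$mat
  m[drug, term] <- value
  new_phenome_matrix(Matrix::drop0(m), x$classes)
}
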