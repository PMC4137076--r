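#' Column mapping for SIDER-style association tables
#'
#' Describes how the columns of a long-format drug-phenotype table map onto
#' the fields phenorepo needs. Columns may be named (matched against the file
#' header) or given as 1-based positions (the file is then read without a
#' header). `class_values` maps each canonical class to the labels that
#' denote it in the file; matching is case-insensitive.
#'
#' @param drug_column,term_id_column,term_name_column,class_column column
#'   names or 1-based positions. `term_name_column` may be `NULL`, in which
#'   case term ids double as display names.
#' @param class_values named list with elements `side_effect` and
#'   `indication`, each a character vector of accepted labels.
#' @return a `phenome_dialect` list.
#' @export
phenome_dialect <- function(drug_column = "drug_id",
                            term_id_column = "term_id",
                            term_name_column = "term_name",
                            class_column = "term_class",
                            class_values = list(
                              side_effect = c("side_effect", "side effect", "se", "adverse"),
                              indication = c("indication", "ind")
                            )) {
  stopifnot(
    is.list(class_values),
    all(c("side_effect", "indication") %in% names(class_values))
  )
  structure(
    list(
      drug_column = drug_column,
      term_id_column = term_id_column,
      term_name_column = term_name_column,
      class_column = class_column,
      class_values = class_values
    ),
    class = "phenome_dialect"
  )
}

#' Read a long-format drug-phenotype association table
#'
#' Reads a tab-separated table with one drug/term association per row and
#' returns one record per data row as a tibble with columns `drug_id`,
#' `term_id`, `term_name`, `term_class`. Duplicated associations are kept at
#' this stage (deduplication happens in [build_phenome_matrix()]). Rows whose
#' class label cannot be mapped, or with an empty drug or term id, are
#' dropped with a warning and attached to the result as the `"rejected"`
#' attribute so nothing is silently discarded.
#'
#' @param path path to a UTF-8 TSV file.
#' @param dialect a [phenome_dialect()] describing the column layout.
#' @return tibble of phenome records; zero rows (with a warning) for a table
#'   that has a header but no data.
#' @export
read_phenome_table <- function(path, dialect = phenome_dialect()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cols <- list(
    drug_id = dialect$drug_column,
    term_id = dialect$term_id_column,
    term_name = dialect$term_name_column,
    class = dialect$class_column
  )
  positional <- all(vapply(purrr::compact(cols), is.numeric, logical(1)))
  raw <- readr::read_tsv(
    path,
    col_names = !positional,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  pick <- function(spec) {
    if (is.null(spec)) return(NULL)
    if (is.numeric(spec)) {
      if (spec > ncol(raw)) abort("positional column beyond table width")
      return(raw[[spec]])
    }
    if (!spec %in% names(raw)) {
      abort(paste0("column '", spec, "' not found in header"))
    }
    raw[[spec]]
  }
  records <- tibble(
    drug_id = pick(cols$drug_id),
    term_id = pick(cols$term_id),
    term_name = pick(cols$term_name) %||% pick(cols$term_id),
    term_class_raw = pick(cols$class)
  )
  if (nrow(records) == 0L) {
    warn("association table contains no data rows")
    out <- tibble(
      drug_id = character(), term_id = character(),
      term_name = character(), term_class = character()
    )
    return(structure(out, rejected = records[0, ]))
  }

  lut <- c(
    setNames(
      rep("side_effect", length(dialect$class_values$side_effect)),
      tolower(dialect$class_values$side_effect)
    ),
    setNames(
      rep("indication", length(dialect$class_values$indication)),
      tolower(dialect$class_values$indication)
    )
  )
  records$term_class <- unname(lut[tolower(trimws(records$term_class_raw))])
  bad <- is.na(records$term_class) | is.na(records$drug_id) |
    is.na(records$term_id) | records$drug_id == "" | records$term_id == ""
  rejected <- records[bad, ]
  if (nrow(rejected) > 0) {
    warn(paste0(
      nrow(rejected), " row(s) could not be mapped (unrecognized class ",
      "label or empty identifier); see attr(x, 'rejected')"
    ))
  }
  out <- records[!bad, c("drug_id", "term_id", "term_name", "term_class")]
  structure(as_tibble(out), rejected = rejected)
}

#' Build the binary drug-phenome matrix from association records
#'
#' Deduplicates (drug, term) pairs and assembles the 0/1 incidence matrix,
#' with side-effect columns first and indication columns second, each sorted
#' by term id, and drugs sorted by drug id. The result is therefore invariant
#' to the order of the input records. Drugs that appear only with side
#' effects (no indications) are retained.
#'
#' @param records data frame with columns `drug_id`, `term_id`, `term_class`
#'   (as produced by [read_phenome_table()]); a `term_name` column is
#'   tolerated and ignored for matrix construction.
#' @return a [phenome_matrix].
#' @export
build_phenome_matrix <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("cannot build a phenome matrix from zero records")
  stopifnot(all(c("drug_id", "term_id", "term_class") %in% names(records)))
  if (!all(records$term_class %in% PHENOTYPE_CLASSES)) {
    abort("term_class must be 'side_effect' or 'indication'")
  }

  class_per_term <- distinct(records, term_id, term_class)
  clash <- class_per_term |> count(term_id) |> filter(n > 1L)
  if (nrow(clash) > 0) {
    abort(paste0(
      "term(s) labelled with both classes: ",
      paste(clash$term_id, collapse = ", ")
    ))
  }

  pairs <- distinct(records, drug_id, term_id)
  class_per_term <- arrange(
    class_per_term, match(term_class, PHENOTYPE_CLASSES), term_id
  )
  drugs <- sort(unique(records$drug_id))
  mat <- Matrix::sparseMatrix(
    i = match(pairs$drug_id, drugs),
    j = match(pairs$term_id, class_per_term$term_id),
    x = 1,
    dims = c(length(drugs), nrow(class_per_term)),
    dimnames = list(drugs, class_per_term$term_id)
  )
  new_phenome_matrix(mat, class_per_term$term_class)
}

#' Convert a phenome matrix to an LDA corpus
#'
#' Each drug becomes one document; each 1-cell contributes exactly one token
#' (the phenotype's column index), so a document's length equals its row sum.
#' Tokens within a document follow the canonical column order.
#'
#' @param x a [phenome_matrix].
#' @return a `phenome_corpus`: list with `documents` (named list of 1-based
#'   integer token vectors) and `vocabulary` (the column order). Drugs with
#'   all-zero rows yield empty documents, with a warning.
#' @export
as_phenome_corpus <- function(x) {
  stopifnot(inherits(x, "phenome_matrix"))
  tm <- Matrix::t(x$mat)  # CsparseMatrix: column-per-drug slices are ordered
  docs <- lapply(seq_len(ncol(tm)), function(d) {
    tm@i[(tm@p[d] + 1L):tm@p[d + 1L]] + 1L
  })
  lens <- diff(tm@p)
  docs[lens == 0L] <- list(integer(0))
  names(docs) <- rownames(x$mat)
  if (any(lens == 0L)) {
    warn(paste0(sum(lens == 0L), " drug(s) have no phenotypes (empty documents)"))
  }
  structure(
    list(documents = docs, vocabulary = colnames(x$mat)),
    class = "phenome_corpus"
  )
}

#' @export
print.phenome_corpus <- function(x, ...) {
  cat("<phenome_corpus> ", length(x$documents), " documents, ",
      sum(lengths(x$documents)), " tokens, vocabulary of ",
      length(x$vocabulary), "\n", sep = "")
  invisible(x)
}

n_corpus_tokens <- function(corpus) sum(lengths(corpus$documents))

#' Serialize and restore a phenome matrix
#'
#' Writes three plain-text files next to `stem`: `<stem>_dense.tsv` (the 0/1
#' matrix with drug rows and term columns), `<stem>_triplets.tsv` (sparse
#' `drug_id`, `term_id`, `value` rows) and `<stem>_terms.tsv` (term order and
#' class labels). `read_phenome_matrix()` restores an identical object from
#' the triplet + term files.
#'
#' @param x a [phenome_matrix].
#' @param stem path prefix for the output files.
#' @return `write_phenome_matrix()` returns the three paths invisibly.
#' @export
write_phenome_matrix <- function(x, stem) {
  dense <- as.matrix(x$mat)
  dense_df <- as_tibble(dense, rownames = "drug_id")
  paths <- paste0(stem, c("_dense.tsv", "_triplets.tsv", "_terms.tsv"))
  readr::write_tsv(dense_df, paths[1])
  trip <- tidy(x) |> mutate(value = 1L) |> select(drug_id, term_id, value)
  readr::write_tsv(trip, paths[2])
  readr::write_tsv(
    tibble(term_id = colnames(x$mat), term_class = x$classes,
           column = seq_along(x$classes)),
    paths[3]
  )
  invisible(paths)
}

#' @rdname write_phenome_matrix
#' @export
read_phenome_matrix <- function(stem) {
  trip <- readr::read_tsv(
    paste0(stem, "_triplets.tsv"),
    col_types = readr::cols(
      drug_id = readr::col_character(),
      term_id = readr::col_character(),
      value = readr::col_integer()
    ),
    progress = FALSE
  )
  terms <- readr::read_tsv(
    paste0(stem, "_terms.tsv"),
    col_types = readr::cols(
      term_id = readr::col_character(),
      term_class = readr::col_character(),
      column = readr::col_integer()
    ),
    progress = FALSE
  )
  drugs <- sort(unique(trip$drug_id))
  mat <- Matrix::sparseMatrix(
    i = match(trip$drug_id, drugs),
    j = match(trip$term_id, terms$term_id),
    x = as.numeric(trip$value),
    dims = c(length(drugs), nrow(terms)),
    dimnames = list(drugs, terms$term_id)
  )
  new_phenome_matrix(mat, terms$term_class)
}
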