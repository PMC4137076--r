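test_that("association tables are read with named and positional mappings", {
  path <- write_toy_tsv(toy_records())
  recs <- read_phenome_table(path)
  expect_equal(nrow(recs), 7L)
  expect_equal(recs$term_class[recs$term_id == "in1"],
               rep("indication", 2))
  expect_equal(sum(recs$term_class == "side_effect"), 4L)

  # positional mapping reads a headerless file
  raw <- toy_records()
  hp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(raw, hp, col_names = FALSE)
  recs_pos <- read_phenome_table(
    hp, phenome_dialect(drug_column = 1, term_id_column = 2,
                        term_name_column = 3, class_column = 4)
  )
  expect_equal(recs_pos, recs)
})

test_that("class labels map case-insensitively and bad rows are reported", {
  recs <- toy_records()
  recs$term_class[3] <- "Indication"
  recs$term_class[7] <- "Side Effect"
  path <- write_toy_tsv(recs)
  parsed <- read_phenome_table(path)
  expect_equal(nrow(parsed), 7L)
  expect_equal(parsed$term_class[3], "indication")

  recs$term_class[1] <- "mystery"
  path2 <- write_toy_tsv(recs)
  expect_warning(parsed2 <- read_phenome_table(path2), "could not be mapped")
  expect_equal(nrow(parsed2), 6L)
  expect_equal(nrow(attr(parsed2, "rejected")), 1L)
  expect_equal(attr(parsed2, "rejected")$term_id, "se1")
})

test_that("header-only tables give an empty record list with a warning", {
  path <- write_toy_tsv(toy_records()[0, ])
  expect_warning(recs <- read_phenome_table(path), "no data rows")
  expect_equal(nrow(recs), 0L)
})

test_that("missing files and absent columns are errors", {
  expect_error(read_phenome_table("no/such/file.tsv"), "no such file")
  path <- write_toy_tsv(toy_records())
  expect_error(
    read_phenome_table(path, phenome_dialect(drug_column = "compound")),
    "not found in header"
  )
})

test_that("build_phenome_matrix dedups, orders columns, and counts pairs", {
  pm <- build_phenome_matrix(toy_records())
  expect_equal(dim(pm), c(3L, 4L))
  # side effects first, then indications, each lexicographic
  expect_equal(phenotype_ids(pm), c("se1", "se2", "in1", "in2"))
  expect_equal(indication_ids(pm), c("in1", "in2"))
  g <- glance(pm)
  expect_equal(g$n_known_pairs, 3L)
  expect_equal(g$n_side_effects + g$n_indications, g$n_phenotypes)
  expect_equal(sum(pm$mat), 7)

  # repeating the same pair three times still yields a single 1-cell
  tripled <- dplyr::bind_rows(toy_records(),
                              toy_records()[c(1, 1), ])
  pm3 <- build_phenome_matrix(tripled)
  expect_equal(as.matrix(pm3$mat), as.matrix(pm$mat))

  # drugs with no indications are retained
  expect_true("dC" %in% drug_ids(pm))
  expect_equal(known_indication_counts(pm)[["dC"]], 0L)
})

test_that("build_phenome_matrix is invariant to record order", {
  recs <- toy_records()
  set.seed(42)
  shuffled <- recs[sample.int(nrow(recs)), ]
  a <- build_phenome_matrix(recs)
  b <- build_phenome_matrix(shuffled)
  expect_identical(as.matrix(a$mat), as.matrix(b$mat))
  expect_identical(a$classes, b$classes)
})

test_that("a term carrying both class labels is an error naming the term", {
  recs <- toy_records()
  recs$term_class[1] <- "indication" # se1 now both classes
  expect_error(build_phenome_matrix(recs), "se1")
  expect_error(build_phenome_matrix(toy_records()[0, ]), "zero records")
})

test_that("corpus conversion follows the binary-to-token rule", {
  pm <- build_phenome_matrix(toy_records())
  corp <- as_phenome_corpus(pm)
  expect_s3_class(corp, "phenome_corpus")
  # document lengths equal row sums; total tokens = distinct pairs
  expect_equal(unname(lengths(corp$documents)),
               unname(Matrix::rowSums(pm$mat)), ignore_attr = TRUE)
  expect_equal(sum(lengths(corp$documents)), 7L)
  # tokens are distinct column indices (count 1 each)
  expect_true(all(vapply(corp$documents, anyDuplicated, integer(1)) == 0L))

  # round trip: rebuilding the incidence from documents reproduces the matrix
  rebuilt <- matrix(0, length(corp$documents), length(corp$vocabulary),
                    dimnames = list(names(corp$documents), corp$vocabulary))
  for (d in names(corp$documents)) rebuilt[d, corp$documents[[d]]] <- 1
  expect_equal(rebuilt, as.matrix(pm$mat), ignore_attr = TRUE)

  # 2x3 all-ones matrix gives two documents of length 3
  allone <- build_phenome_matrix(tidyr::expand_grid(
    drug_id = c("x", "y"), term_id = c("p1", "p2", "p3")
  ) |> dplyr::mutate(term_class = "side_effect"))
  corp2 <- as_phenome_corpus(allone)
  expect_equal(lengths(corp2$documents), c(x = 3L, y = 3L))
})

test_that("an all-zero drug row yields an empty document with a warning", {
  pm <- build_phenome_matrix(toy_records())
  pm0 <- phenorepo:::set_cell(pm, "dC", "se2", 0)
  expect_warning(corp <- as_phenome_corpus(pm0), "empty documents")
  expect_equal(corp$documents$dC, integer(0))
})

test_that("matrix serialization round-trips through triplet TSV", {
  pm <- build_phenome_matrix(toy_records())
  stem <- file.path(withr::local_tempdir(), "toy")
  paths <- write_phenome_matrix(pm, stem)
  expect_true(all(file.exists(paths)))
  back <- read_phenome_matrix(stem)
  expect_identical(as.matrix(back$mat), as.matrix(pm$mat))
  expect_identical(back$classes, pm$classes)

  # dense TSV carries the same 0/1 content
  dense <- readr::read_tsv(paths[1], show_col_types = FALSE)
  expect_equal(unname(as.matrix(dense[, -1])), unname(as.matrix(pm$mat)))
})
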