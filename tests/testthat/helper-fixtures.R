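# Shared small fixtures, built in code.

# 3 drugs x 4 terms, 7 associations (2 indication terms, 2 side effects).
toy_records <- function() {
  tibble::tribble(
    ~drug_id, ~term_id, ~term_name,      ~term_class,
    "dA",     "se1",    "headache",      "side_effect",
    "dA",     "se2",    "nausea",        "side_effect",
    "dA",     "in1",    "hypertension",  "indication",
    "dB",     "se1",    "headache",      "side_effect",
    "dB",     "in1",    "hypertension",  "indication",
    "dB",     "in2",    "migraine",      "indication",
    "dC",     "se2",    "nausea",        "side_effect"
  )
}

write_toy_tsv <- function(records, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  readr::write_tsv(records, path)
  path
}

# Small block fixture shared by several LDA-level tests.
small_blocks <- function(seed = 1) {
  phenorepo::make_block_fixture(
    n_blocks = 3, drugs_per_block = 8, phenos_per_block = 12,
    indication_fraction = 0.25, noise_rate = 0.05, seed = seed
  )
}
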