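test_that("mutation specs parse in order and reject bad tokens", {
  spec <- parse_mutation_spec("A5G")
  expect_equal(spec$wt, "A")
  expect_equal(spec$pos, 5L)
  expect_equal(spec$mut, "G")

  spec <- parse_mutation_spec("D123A/R456K")
  expect_equal(spec$wt, c("D", "R"))
  expect_equal(spec$pos, c(123L, 456L))
  expect_equal(spec$mut, c("A", "K"))
  expect_equal(format_mutation_spec(spec), "D123A/R456K")

  expect_error(parse_mutation_spec("A5A"), "silent.*A5A")
  expect_error(parse_mutation_spec("A5G/G5C"), "duplicate.*G5C")
  expect_error(parse_mutation_spec("X5G"), "malformed.*X5G")
  expect_error(parse_mutation_spec("A5"), "malformed")
  expect_error(parse_mutation_spec(""), "non-empty")
})

test_that("mutations are applied exactly at the stated positions", {
  expect_equal(apply_mutations("MKVA", parse_mutation_spec("V3L")), "MKLA")
  empty <- parse_mutation_spec("A5G")[0, ]
  expect_equal(apply_mutations("MKVA", empty), "MKVA")
  expect_error(apply_mutations("MKVA", parse_mutation_spec("A3L")),
               "mismatch at position 3.*has 'V'")
  expect_error(apply_mutations("MKVA", parse_mutation_spec("A9L")),
               "beyond sequence length")
  # multiple substitutions, length preserved, only stated sites change
  out <- apply_mutations("MKVAW", parse_mutation_spec("M1A/W5F"))
  expect_equal(out, "AKVAF")
  expect_equal(nchar(out), 5L)
})

test_that("SMILES canonicalization collapses synonyms and is idempotent", {
  forms <- canonicalize_smiles(c("OCC", "CCO"))
  expect_equal(forms[1], forms[2])
  benzene <- canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_equal(benzene[1], benzene[2])
  expect_equal(canonicalize_smiles(forms[1]), forms[1])  # idempotent
  expect_true(is.na(canonicalize_smiles("notasmiles")))
  expect_error(canonicalize_smiles("notasmiles", strict = TRUE),
               "unparseable")
})

test_that("max-K_M deduplication keeps the per-key maximum", {
  rec <- data.frame(sequence = c("MKVA", "MKVA", "MSTA"),
                    canonical_smiles = c("CCO", "CCO", "CCO"),
                    km_value = c(2, 5, 1), stringsAsFactors = FALSE)
  out <- deduplicate_max_km(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$km_value[out$sequence == "MKVA"], 5)
  # distinct keys all survive
  rec2 <- data.frame(sequence = c("A", "C", "D"),
                     canonical_smiles = "CCO", km_value = 1:3)
  expect_equal(nrow(deduplicate_max_km(rec2)), 3L)
  expect_equal(nrow(deduplicate_max_km(rec2[0, ])), 0L)
  # ties keep the first-seen record
  rec3 <- data.frame(sequence = "A", canonical_smiles = "CCO",
                     km_value = c(2, 2), id = c("first", "second"))
  expect_equal(deduplicate_max_km(rec3)$id, "first")
})

test_that("deduplication matches a brute-force group-by-max oracle", {
  set.seed(101)
  for (rep in 1:3) {
    n <- 1000
    keys <- sample(paste0("K", 1:300), n, replace = TRUE)
    rec <- data.frame(sequence = keys,
                      canonical_smiles = sample(c("CCO", "CC", "O"),
                                                n, TRUE),
                      km_value = round(stats::rexp(n), 6),
                      stringsAsFactors = FALSE)
    out <- deduplicate_max_km(rec)
    oracle <- tapply(rec$km_value,
                     paste(rec$sequence, rec$canonical_smiles), max)
    got <- stats::setNames(out$km_value,
                           paste(out$sequence, out$canonical_smiles))
    expect_setequal(names(got), names(oracle))
    expect_equal(unname(got[names(oracle)]), unname(as.vector(oracle)))
  }
  # 10 records with 3 planted keys
  set.seed(7)
  rec <- data.frame(sequence = sample(c("S1", "S2", "S3"), 10, TRUE),
                    canonical_smiles = "CCO",
                    km_value = stats::runif(10))
  out <- deduplicate_max_km(rec)
  expect_equal(nrow(out), length(unique(rec$sequence)))
  for (k in unique(rec$sequence))
    expect_equal(out$km_value[out$sequence == k],
                 max(rec$km_value[rec$sequence == k]))
})

test_that("length filter removes >= 1000 residues and keeps 999", {
  rec <- data.frame(sequence = c(strrep("A", 999), strrep("A", 1000),
                                 strrep("A", 1500)))
  out <- filter_by_length(rec)
  expect_equal(nchar(out$sequence), 999L)
  expect_equal(nrow(filter_by_length(rec[0, , drop = FALSE])), 0L)
})

test_that("log10 transform sets log10_km and rejects non-positive K_M", {
  rec <- data.frame(km_value = c(1, 100, 0.01))
  out <- log10_transform(rec)
  expect_equal(out$log10_km, c(0, 2, -2))
  expect_equal(out$km_value, rec$km_value)
  expect_error(log10_transform(data.frame(km_value = c(1, 0))),
               "non-positive K_M.*record 2")
})

test_that("train/test split is sized, disjoint and reproducible", {
  sp <- split_train_test(10, 0.8, seed = 3)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(sp, split_train_test(10, 0.8, seed = 3))
  expect_false(identical(sp, split_train_test(10, 0.8, seed = 4)))
  # the published cleaned-dataset size splits 80/20 into 15,803 / 3,951
  sp_big <- split_train_test(19754, 0.8, seed = 1)
  expect_length(sp_big$train, 9051 + 6752)
  expect_length(sp_big$test, 2263 + 1688)
  expect_error(split_train_test(1), "at least 2")
})

test_that("overlap detection finds exactly the shared keys", {
  a <- data.frame(sequence = c("S1", "S2"), canonical_smiles = c("CCO", "CC"))
  b <- data.frame(sequence = c("S3", "S4"), canonical_smiles = c("CCO", "CC"))
  expect_equal(nrow(find_overlap(a, b)), 0L)
  b2 <- rbind(b, data.frame(sequence = "S1", canonical_smiles = "CCO"))
  ov <- find_overlap(a, b2)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$sequence, "S1")

  # 100 random records with 7 planted collisions vs brute-force comparison
  set.seed(11)
  q <- data.frame(sequence = paste0("Q", 1:100),
                  canonical_smiles = sample(c("CCO", "CC"), 100, TRUE))
  r <- data.frame(sequence = paste0("R", 1:100),
                  canonical_smiles = sample(c("CCO", "CC"), 100, TRUE))
  planted <- sample(100, 7)
  r[1:7, ] <- q[planted, ]
  ov <- find_overlap(q, r)
  expect_equal(nrow(ov), 7L)
  brute <- 0L
  qk <- paste(q$sequence, q$canonical_smiles)
  rk <- paste(r$sequence, r$canonical_smiles)
  for (x in unique(qk)) if (any(rk == x)) brute <- brute + 1L
  expect_equal(nrow(ov), brute)
})

test_that("full curation chain is idempotent and leaves no violations", {
  raw <- make_fixture("curation")
  cur <- curate_records(raw)
  clean <- cur$clean
  # invariants: no long sequences, no duplicate keys, mutants materialized
  expect_true(all(nchar(clean$sequence) < 1000))
  expect_false(any(duplicated(paste(clean$sequence,
                                    clean$canonical_smiles))))
  expect_equal(clean$log10_km, log10(clean$km_value))
  # idempotence: curating the curated table changes nothing observable
  again <- curate_records(clean)
  expect_equal(nrow(again$rejects), 0L)
  expect_equal(again$clean$sequence, clean$sequence)
  expect_equal(again$clean$km_value, clean$km_value)
  expect_equal(again$clean$canonical_smiles, clean$canonical_smiles)
})

test_that("record tables round-trip through TSV and JSON-lines", {
  raw <- make_fixture("curation")[c(1, 9), ]
  tsv <- tempfile(fileext = ".tsv")
  jsonl <- tempfile(fileext = ".jsonl")
  write_kinetic_records(raw, tsv)
  write_kinetic_records(raw, jsonl)
  back_tsv <- read_kinetic_records(tsv)
  back_jsonl <- read_kinetic_records(jsonl)
  for (col in c("smiles", "sequence", "mutation_spec", "km_value")) {
    expect_equal(back_tsv[[col]], raw[[col]])
    expect_equal(back_jsonl[[col]], raw[[col]])
  }
  expect_error(read_kinetic_records(
    {f <- tempfile(); writeLines("a\tb", f); f}), "lacks column")
})

test_that("FASTA sequences are read with headers as names", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">seq1 some description", "MKVA", "WTTA",
               ">seq2", "mnli"), f)
  seqs <- read_fasta_sequences(f)
  expect_equal(seqs, c(seq1 = "MKVAWTTA", seq2 = "MNLI"))
})
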