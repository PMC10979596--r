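AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

RECORD_COLUMNS <- c("substrate_name", "smiles", "ec_number", "organism",
                    "uniprot_id", "sequence", "enzyme_type", "mutation_spec",
                    "km_value")

#' Validate an amino-acid sequence
#'
#' @param sequence character vector of protein sequences.
#' @return logical vector: `TRUE` where the sequence is a non-empty string of
#'   the 20 standard one-letter residue codes (uppercase).
#' @export
is_valid_sequence <- function(sequence) {
  !is.na(sequence) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
}

#' Parse a point-mutation specification
#'
#' Mutation strings follow the common kinetic-database convention
#' `<WT><POS><MUT>` with multiple substitutions joined by `/`, e.g.
#' `"D123A/R456K"`. Positions are 1-based.
#'
#' @param text a single mutation string.
#' @return An object of class `mutation_spec`: a data frame with columns
#'   `wt` (wildtype residue), `pos` (1-based position) and `mut` (mutant
#'   residue), one row per substitution, in the order written.
#' @examples
#' parse_mutation_spec("A5G")
#' parse_mutation_spec("D123A/R456K")
#' @export
parse_mutation_spec <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("mutation spec must be a single non-empty string")
  tokens <- strsplit(text, "/", fixed = TRUE)[[1]]
  pat <- "^([ACDEFGHIKLMNPQRSTVWY])([0-9]+)([ACDEFGHIKLMNPQRSTVWY])$"
  bad <- tokens[!grepl(pat, tokens)]
  if (length(bad))
    stop("malformed mutation token: '", bad[1], "'")
  wt  <- sub(pat, "\\1", tokens)
  pos <- as.integer(sub(pat, "\\2", tokens))
  mut <- sub(pat, "\\3", tokens)
  if (any(pos < 1L))
    stop("mutation position must be >= 1 in token '",
         tokens[which(pos < 1L)[1]], "'")
  if (anyDuplicated(pos))
    stop("duplicate mutation position in token '",
         tokens[which(duplicated(pos))[1]], "'")
  silent <- wt == mut
  if (any(silent))
    stop("silent substitution (wildtype equals mutant) in token '",
         tokens[which(silent)[1]], "'")
  structure(data.frame(wt = wt, pos = pos, mut = mut,
                       stringsAsFactors = FALSE),
            class = c("mutation_spec", "data.frame"))
}

#' Format a mutation spec back to its string form
#' @param spec a `mutation_spec`.
#' @return the `<WT><POS><MUT>/...` string.
#' @export
format_mutation_spec <- function(spec) {
  paste(paste0(spec$wt, spec$pos, spec$mut), collapse = "/")
}

#' Apply point substitutions to a wildtype sequence
#'
#' Each substitution is checked against the sequence: the residue at the
#' stated position must equal the spec's wildtype residue (a mismatch signals
#' stale numbering in the source record).
#'
#' @param wildtype_sequence amino-acid string.
#' @param spec a `mutation_spec` (or a mutation string, parsed on the fly).
#' @return the mutated sequence; same length as the input.
#' @examples
#' apply_mutations("MKVA", parse_mutation_spec("V3L"))
#' @export
apply_mutations <- function(wildtype_sequence, spec) {
  if (is.character(spec)) spec <- parse_mutation_spec(spec)
  if (nrow(spec) == 0L) return(wildtype_sequence)
  chars <- strsplit(wildtype_sequence, "")[[1]]
  if (any(spec$pos > length(chars)))
    stop("mutation position ", spec$pos[which(spec$pos > length(chars))[1]],
         " beyond sequence length ", length(chars))
  have <- chars[spec$pos]
  bad <- have != spec$wt
  if (any(bad)) {
    i <- which(bad)[1]
    stop("wildtype residue mismatch at position ", spec$pos[i],
         ": sequence has '", have[i], "', spec expects '", spec$wt[i], "'")
  }
  chars[spec$pos] <- spec$mut
  paste(chars, collapse = "")
}

# Memoised per-session canonical-SMILES cache.
.smiles_cache <- new.env(parent = emptyenv())

.canonicalize_one <- function(s) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
    error = function(e) "")
  can <- sub("[\t ].*$", "", sub("\n$", "", out))
  if (!nzchar(can)) NA_character_ else can
}

#' Canonicalize SMILES strings
#'
#' Maps every valid writing of a molecule to one canonical SMILES string
#' (Open Babel canonicalization via ChemmineOB), so records of the same
#' substrate under synonymous encodings collide on the same key. The function
#' is idempotent. Unparseable SMILES yield `NA` so callers can quarantine the
#' record rather than drop it silently; use `strict = TRUE` to raise an error
#' instead.
#'
#' @param smiles character vector of SMILES strings.
#' @param strict error on unparseable input instead of returning `NA`.
#' @return character vector of canonical SMILES (`NA` where unparseable).
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))   # same molecule, one canonical form
#' @export
canonicalize_smiles <- function(smiles, strict = FALSE) {
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) {
      out[i] <- NA_character_
      next
    }
    key <- paste0("s:", s)
    hit <- .smiles_cache[[key]]
    if (is.null(hit)) {
      hit <- .canonicalize_one(s)
      assign(key, hit, envir = .smiles_cache)
    }
    out[i] <- hit
  }
  if (strict && anyNA(out))
    stop("unparseable SMILES: '", smiles[which(is.na(out))[1]], "'")
  out
}

#' Keep the maximum-K_M record per (sequence, canonical SMILES) key
#'
#' Kinetic databases report several K_M values for one enzyme-substrate pair
#' (different assay conditions); curation keeps the entry with the largest
#' K_M. Ties keep the first-seen record. Output order is the order of first
#' appearance of each key.
#'
#' @param records data frame with columns `sequence`, `canonical_smiles`,
#'   `km_value`.
#' @return the deduplicated data frame.
#' @export
deduplicate_max_km <- function(records) {
  stopifnot(all(c("sequence", "canonical_smiles", "km_value") %in%
                  names(records)))
  if (nrow(records) == 0L) return(records)
  key <- paste(records$sequence, records$canonical_smiles, sep = "\r")
  first <- !duplicated(key)
  keep <- integer(sum(first))
  names(keep) <- key[first]
  for (i in seq_len(nrow(records))) {
    k <- key[i]
    j <- keep[[k]]
    if (j == 0L || records$km_value[i] > records$km_value[j])
      keep[[k]] <- i
  }
  records[sort(unname(keep)), , drop = FALSE]
}

#' Remove records whose protein sequence is too long
#'
#' Enzymes of 1,000 or more residues are treated as fusion proteins and
#' removed; every surviving sequence is strictly shorter than `max_len`.
#'
#' @param records data frame with a `sequence` column.
#' @param max_len removal threshold (default 1000; a length-999 sequence is
#'   kept, a length-1000 sequence is removed).
#' @return the filtered data frame.
#' @export
filter_by_length <- function(records, max_len = 1000L) {
  records[nchar(records$sequence) < max_len, , drop = FALSE]
}

#' Attach log10-transformed K_M values
#'
#' @param records data frame with a positive `km_value` column.
#' @return the data frame with a `log10_km` column set; `km_value` unchanged.
#' @export
log10_transform <- function(records) {
  bad <- !is.finite(records$km_value) | records$km_value <= 0
  if (any(bad))
    stop("non-positive K_M value in record ", which(bad)[1])
  records$log10_km <- log10(records$km_value)
  records
}

#' Split records into training and test sets
#'
#' Uniform random split, reproducible under `seed`; the training set has
#' `round(train_fraction * n)` records.
#'
#' @param n number of records (or a data frame, whose rows are counted).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test` (disjoint, covering
#'   `1:n`).
#' @export
split_train_test <- function(n, train_fraction = 0.8, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 2L) stop("need at least 2 records to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(train_fraction * n)
  perm <- with_local_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[seq.int(n_train + 1L, n)]))
}

#' Find (sequence, canonical SMILES) keys shared by two record sets
#'
#' Used to remove leakage between an independent evaluation set and the
#' training data: an entry with the same substrate and amino-acid sequence as
#' a training entry is a duplicate.
#'
#' @param query,reference data frames with `sequence` and `canonical_smiles`.
#' @return data frame of the shared keys (columns `sequence`,
#'   `canonical_smiles`), empty when the sets are disjoint.
#' @export
find_overlap <- function(query, reference) {
  qk <- unique(paste(query$sequence, query$canonical_smiles, sep = "\r"))
  rk <- unique(paste(reference$sequence, reference$canonical_smiles,
                     sep = "\r"))
  shared <- intersect(qk, rk)
  parts <- strsplit(shared, "\r", fixed = TRUE)
  data.frame(sequence = vapply(parts, `[`, "", 1),
             canonical_smiles = vapply(parts, function(p) p[2], ""),
             stringsAsFactors = FALSE)
}

#' Curate raw kinetic records
#'
#' Runs the full cleaning chain: field validation, mutation application
#' (mutant sequences are materialized from the wildtype sequence plus the
#' mutation spec), SMILES canonicalization, removal of non-positive K_M and
#' invalid sequences, sequence-length filtering, maximum-K_M deduplication
#' and log10 transformation. Records failing a rule are quarantined with a
#' reason code, never silently dropped. The chain is idempotent: curating an
#' already-curated table changes nothing.
#'
#' @param records data frame in the record dialect (see
#'   [read_kinetic_records()]); extra columns are carried through.
#' @param max_len sequence-length removal threshold (default 1000).
#' @return list with `clean` (curated records, including `canonical_smiles`
#'   and `log10_km`) and `rejects` (quarantined records with a `reason`
#'   column; reasons: `bad_smiles`, `bad_sequence`, `bad_mutation`,
#'   `nonpositive_km`, `sequence_too_long`).
#' @export
curate_records <- function(records, max_len = 1000L) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(c("smiles", "sequence", "enzyme_type", "km_value"),
                  names(records))
  if (length(miss))
    stop("records table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(records$mutation_spec)) records$mutation_spec <- NA_character_
  records$mutation_spec[!is.na(records$mutation_spec) &
                          !nzchar(records$mutation_spec)] <- NA_character_
  records$km_value <- as.numeric(records$km_value)

  reason <- rep(NA_character_, nrow(records))

  # mutant sequences materialized from wildtype + spec; a sequence already
  # carrying the substitutions is left unchanged (idempotent curation)
  is_mut <- !is.na(records$mutation_spec)
  for (i in which(is_mut)) {
    spec <- tryCatch(parse_mutation_spec(records$mutation_spec[i]),
                     error = function(e) e)
    if (inherits(spec, "error")) {
      reason[i] <- "bad_mutation"
      next
    }
    chars <- strsplit(records$sequence[i], "")[[1]]
    if (max(spec$pos) <= length(chars) &&
        all(chars[spec$pos] == spec$mut)) {
      records$enzyme_type[i] <- "mutant"   # already materialized
      next
    }
    seq_i <- tryCatch(apply_mutations(records$sequence[i], spec),
                      error = function(e) e)
    if (inherits(seq_i, "error")) {
      reason[i] <- "bad_mutation"
    } else {
      records$sequence[i] <- seq_i
      records$enzyme_type[i] <- "mutant"
    }
  }

  ok <- is.na(reason)
  bad_seq <- ok & !is_valid_sequence(records$sequence)
  reason[bad_seq] <- "bad_sequence"

  records$canonical_smiles <- canonicalize_smiles(records$smiles)
  reason[is.na(reason) & is.na(records$canonical_smiles)] <- "bad_smiles"

  bad_km <- is.na(reason) &
    (!is.finite(records$km_value) | records$km_value <= 0)
  reason[bad_km] <- "nonpositive_km"

  too_long <- is.na(reason) & nchar(records$sequence) >= max_len
  reason[too_long] <- "sequence_too_long"

  rejects <- records[!is.na(reason), , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- reason[!is.na(reason)]
  clean <- records[is.na(reason), , drop = FALSE]
  clean <- deduplicate_max_km(clean)
  clean <- log10_transform(clean)
  rownames(clean) <- NULL
  rownames(rejects) <- NULL
  list(clean = clean, rejects = rejects)
}

#' Read and write kinetic-record tables
#'
#' The tabular dialect is a tab-separated file with header columns
#' `substrate_name, smiles, ec_number, organism, uniprot_id, sequence,
#' enzyme_type, mutation_spec, km_value`. The JSON-lines dialect holds one
#' record object per line with the same fields. The format is chosen from the
#' file extension (`.jsonl`/`.ndjson` vs anything else = TSV) unless `format`
#' is given.
#'
#' @param path file path.
#' @param format `"tsv"` or `"jsonl"`; default guesses from the extension.
#' @return `read_kinetic_records`: a data frame in the record dialect.
#' @export
read_kinetic_records <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "tsv")
  if (format == "jsonl") {
    rec <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""), quote = "")
  }
  # optional columns may be dropped by JSON writers when entirely missing
  for (opt in c("uniprot_id", "mutation_spec"))
    if (is.null(rec[[opt]])) rec[[opt]] <- rep(NA_character_, nrow(rec))
  miss <- setdiff(RECORD_COLUMNS, names(rec))
  if (length(miss))
    stop("record file lacks column(s): ", paste(miss, collapse = ", "))
  rec$km_value <- as.numeric(rec$km_value)
  rec[c(RECORD_COLUMNS, setdiff(names(rec), RECORD_COLUMNS))]
}

#' @rdname read_kinetic_records
#' @param records data frame to write.
#' @export
write_kinetic_records <- function(records, path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "tsv")
  if (format == "jsonl") {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(records, con, verbose = FALSE)
  } else {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (names = FASTA headers up to
#'   the first whitespace).
#' @export
read_fasta_sequences <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  names_out <- sub("^>(\\S*).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  stats::setNames(unname(seqs), names_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
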