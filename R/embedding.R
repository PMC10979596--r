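#' Construct a protein embedder
#'
#' A protein embedder is the pluggable contract used everywhere a fixed-length
#' protein representation is needed: a pure function of the sequence returning
#' a finite numeric vector of constant dimension `dim`. The bundled
#' [mock_embedder()] (amino-acid composition plus hashed 3-mer frequencies) is
#' the download-free default; a wrapper around a protein language model such
#' as ESM-2 650M (hidden size 1,280, mean-pooled over residue states) plugs in
#' through the same constructor.
#'
#' @param fun function taking one amino-acid sequence string and returning a
#'   numeric vector of length `dim`.
#' @param dim embedding dimension.
#' @param name short identifier stored in manifests (e.g. `"esm2_650m"`,
#'   `"mock"`).
#' @return an object of class `protein_embedder`.
#' @export
protein_embedder <- function(fun, dim, name) {
  stopifnot(is.function(fun), dim >= 1)
  structure(list(fun = fun, dim = as.integer(dim), name = name,
                 cache = new.env(parent = emptyenv())),
            class = "protein_embedder")
}

#' @export
print.protein_embedder <- function(x, ...) {
  cat("<protein_embedder> ", x$name, ", d_prot = ", x$dim, "\n", sep = "")
  invisible(x)
}

#' Mock protein embedding
#'
#' Deterministic, download-free stand-in for a language-model embedding. The
#' first 20 entries are the amino-acid composition fractions (alphabetical
#' one-letter order, summing to 1); the remaining `d - 20` entries are hashed
#' 3-mer frequency features, so sequences differing by a single substitution
#' produce different vectors while permutations of a sequence keep the
#' composition block unchanged.
#'
#' @param sequence amino-acid string.
#' @param d embedding dimension, at least 20 (default 1280, matching the
#'   hidden size of the ESM-2 650M language model so the combined feature
#'   vector has its standard 1,408 length).
#' @return numeric vector of length `d`.
#' @export
mock_embed <- function(sequence, d = 1280L) {
  if (d < 20L) stop("mock embedding dimension must be >= 20")
  if (!is_valid_sequence(sequence))
    stop("invalid amino-acid sequence: '",
         substr(sequence, 1, 30), if (nchar(sequence) > 30) "..." else "",
         "'")
  codes <- match(strsplit(sequence, "")[[1]], AA_ALPHABET)
  n <- length(codes)
  comp <- tabulate(codes, nbins = 20L) / n
  rest <- numeric(d - 20L)
  if (n >= 3L && d > 20L) {
    i <- seq_len(n - 2L)
    # polynomial rolling hash of each 3-mer into the remaining slots
    h <- (codes[i] * 961L + codes[i + 1L] * 31L + codes[i + 2L]) %%
      (d - 20L) + 1L
    rest <- tabulate(h, nbins = d - 20L) / (n - 2L)
  }
  c(comp, rest)
}

#' Bundled mock embedder
#'
#' @param d embedding dimension (default 1280).
#' @return a [protein_embedder()] wrapping [mock_embed()], named `"mock"`.
#' @export
mock_embedder <- function(d = 1280L) {
  force(d)
  protein_embedder(function(sequence) mock_embed(sequence, d), d, "mock")
}

#' Embed protein sequences
#'
#' Applies the embedder to each sequence, memoising results per embedder so
#' repeated sequences (the common case in kinetic datasets) are computed
#' once. Batched and one-at-a-time calls agree elementwise because the
#' embedder contract is a pure per-sequence function.
#'
#' @param sequences character vector of amino-acid sequences.
#' @param embedder a [protein_embedder()].
#' @return numeric matrix, `length(sequences)` x `embedder$dim`, rows in
#'   input order.
#' @export
embed_sequences <- function(sequences, embedder) {
  stopifnot(inherits(embedder, "protein_embedder"))
  out <- matrix(NA_real_, length(sequences), embedder$dim)
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    v <- embedder$cache[[s]]
    if (is.null(v)) {
      v <- embedder$fun(s)
      if (length(v) != embedder$dim || !all(is.finite(v)))
        stop("embedder '", embedder$name, "' violated its contract on a ",
             "sequence of length ", nchar(s))
      assign(s, v, envir = embedder$cache)
    }
    out[i, ] <- v
  }
  out
}

#' @rdname embed_sequences
#' @param sequence a single sequence.
#' @return `embed_sequence`: numeric vector of length `embedder$dim`.
#' @export
embed_sequence <- function(sequence, embedder) {
  drop(embed_sequences(sequence, embedder))
}

#' Write / read an embedding archive
#'
#' Plain-text archive (TSV) mapping each sequence to its embedding vector,
#' with a manifest header line naming the embedder and dimension so results
#' are reproducible under any embedder choice.
#'
#' @param sequences character vector of sequences.
#' @param embeddings matrix from [embed_sequences()].
#' @param path output file.
#' @param embedder the embedder used (for the manifest line).
#' @export
write_embedding_archive <- function(sequences, embeddings, path, embedder) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("# embedder=%s d_prot=%d", embedder$name, embedder$dim),
             con)
  utils::write.table(
    data.frame(sequence = sequences, embeddings),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_archive
#' @return `read_embedding_archive`: list with `sequences`, `embeddings`,
#'   `embedder_name`, `d_prot`.
#' @export
read_embedding_archive <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("embedder=(\\S+) d_prot=(\\d+)", hdr))[[1]]
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  list(sequences = tab$sequence,
       embeddings = as.matrix(tab[, -1, drop = FALSE]),
       embedder_name = m[2], d_prot = as.integer(m[3]))
}
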