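HYDROPHOBIC_AA <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Metabolite-like SMILES vocabulary
#'
#' Around fifty common small metabolites and substrate-like molecules
#' (sugars, organic acids, amino acids, phenols, nucleobases), plus
#' programmatic alkyl and aromatic variants, giving the synthetic generator a
#' realistic spread of molecule sizes (1 to ~20 heavy atoms) and aromatic
#' ring counts (0-2).
#'
#' @param n_alkyl number of programmatic linear-alkyl alcohol/acid variants.
#' @param n_aromatic number of programmatic substituted-benzene variants.
#' @return character vector of SMILES strings.
#' @export
smiles_vocabulary <- function(n_alkyl = 6L, n_aromatic = 6L) {
  base <- c(
    "OCC1OC(O)C(O)C(O)C1O",      # glucopyranose (no stereo)
    "OCC1OC(O)C(O)C1O",          # ribofuranose
    "CC(=O)C(=O)O",              # pyruvate
    "CC(O)C(=O)O",               # lactate
    "CCO",                       # ethanol
    "CC(=O)O",                   # acetate
    "OC(=O)CC(O)(CC(=O)O)C(=O)O",# citrate
    "OC(=O)CCC(=O)O",            # succinate
    "OC(=O)C=CC(=O)O",           # fumarate/maleate skeleton
    "OC(C(=O)O)CC(=O)O",         # malate
    "OC(=O)C(=O)O",              # oxalate
    "O=CC(O)C(O)C(O)C(O)CO",     # open-chain hexose
    "NCC(=O)O",                  # glycine
    "CC(N)C(=O)O",               # alanine
    "OCC(N)C(=O)O",              # serine
    "NC(CS)C(=O)O",              # cysteine
    "CSCCC(N)C(=O)O",            # methionine
    "NC(CCC(=O)O)C(=O)O",        # glutamate
    "NC(CC(=O)O)C(=O)O",         # aspartate
    "NC(CCC(N)=O)C(=O)O",        # glutamine
    "NC(Cc1ccccc1)C(=O)O",       # phenylalanine
    "NC(Cc1ccc(O)cc1)C(=O)O",    # tyrosine
    "NC(Cc1c[nH]c2ccccc12)C(=O)O", # tryptophan
    "NCCCC(=O)O",                # GABA
    "NCCCCN",                    # putrescine
    "NC(N)=O",                   # urea
    "OCC(O)CO",                  # glycerol
    "OCC(O)C(O)C(O)CO",          # pentitol
    "CC=O",                      # acetaldehyde
    "OC=O",                      # formate
    "O=Cc1ccccc1",               # benzaldehyde
    "OC(=O)c1ccccc1",            # benzoate
    "OC(=O)c1ccccc1O",           # salicylate
    "Oc1ccccc1",                 # phenol
    "Oc1ccccc1O",                # catechol
    "Nc1ccccc1",                 # aniline
    "Cc1ccccc1",                 # toluene
    "Oc1ccc(cc1)[N+](=O)[O-]",   # p-nitrophenol
    "Oc1ccc2ccccc2c1",           # 2-naphthol
    "c1ccc2[nH]ccc2c1",          # indole
    "Nc1ncnc2[nH]cnc12",         # adenine
    "O=c1[nH]cnc2[nH]cnc12",     # hypoxanthine
    "NC(=O)c1cccnc1",            # nicotinamide
    "OCC[N+](C)(C)C",            # choline
    "CC(C)CC(N)C(=O)O",          # leucine
    "CC(C)C(N)C(=O)O",           # valine
    "NC(Cc1cnc[nH]1)C(=O)O",     # histidine
    "OC(=O)CCC(=O)C(=O)O",       # 2-oxoglutarate
    "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", # caffeine
    "CC(=O)NC1C(O)OC(CO)C(O)C1O" # N-acetylglucosamine
  )
  alkyl <- vapply(seq_len(n_alkyl), function(k)
    paste0(strrep("C", k + 1), "O"), "")
  aromatic <- vapply(seq_len(n_aromatic), function(k)
    paste0(strrep("C", k), "c1ccccc1"), "")
  unique(c(base, alkyl, aromatic))
}

#' Synthetic dataset configuration
#'
#' The generator plants a known functional dependence of log10 K_M on
#' substrate-graph descriptors and sequence composition:
#' `log10_km = beta0 + beta1 * heavy_atom_count + beta2 *
#' aromatic_ring_count + beta3 * hydrophobic_fraction(sequence) + (sum of
#' per-substitution mutation effects ~ N(0, tau^2)) + N(0, sigma^2)`.
#' All three descriptors are recoverable from the molecular-graph features
#' and the mock embedder's composition block, so the planted signal is
#' expressible by the model family.
#'
#' @param n_records number of records.
#' @param wildtype_fraction fraction of wildtype records (default 0.5).
#' @param n_base_enzymes number of distinct wildtype enzymes (default 25).
#' @param mutants_per_enzyme size of the characterized-mutant pool per base
#'   enzyme (default 8); mutant records draw from this pool, so one mutant is
#'   observed with several substrates, as in real kinetic databases.
#' @param seq_len_range wildtype sequence length range (default 100-500).
#' @param vocabulary substrate SMILES vocabulary
#'   (default [smiles_vocabulary()]).
#' @param beta coefficients `c(beta0, beta1, beta2, beta3)`: intercept -1.0
#'   (K_M around 0.1 mM), 0.08 per heavy atom, 0.3 per aromatic ring, 2.0 on
#'   the hydrophobic fraction.
#' @param tau per-substitution mutation-effect scale (default 0.3).
#' @param sigma Gaussian measurement-noise scale on log10 K_M (default 0.3).
#' @param seed integer seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 2000L, wildtype_fraction = 0.5,
                             n_base_enzymes = 25L, mutants_per_enzyme = 8L,
                             seq_len_range = c(100L, 500L),
                             vocabulary = smiles_vocabulary(),
                             beta = c(-1.0, 0.08, 0.3, 2.0),
                             tau = 0.3, sigma = 0.3, seed = 1L) {
  stopifnot(n_records >= 1L, sigma >= 0, tau >= 0,
            wildtype_fraction >= 0, wildtype_fraction <= 1,
            length(beta) == 4, length(vocabulary) >= 1)
  structure(list(n_records = as.integer(n_records),
                 wildtype_fraction = wildtype_fraction,
                 n_base_enzymes = as.integer(n_base_enzymes),
                 mutants_per_enzyme = as.integer(mutants_per_enzyme),
                 seq_len_range = as.integer(seq_len_range),
                 vocabulary = vocabulary, beta = beta, tau = tau,
                 sigma = sigma, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Hydrophobic residue fraction of a sequence
#'
#' Fraction of residues in \{A, C, F, I, L, M, V, W\} — a sum over entries of
#' the composition block of [mock_embed()].
#'
#' @param sequence amino-acid string.
#' @return value in `[0, 1]`.
#' @export
hydrophobic_fraction <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  mean(chars %in% HYDROPHOBIC_AA)
}

#' Generate a synthetic kinetic-record dataset
#'
#' Emulates a curated enzyme-kinetics table (same columns as the record
#' dialect) with the planted label model of [synthetic_config()]. Fully
#' reproducible under the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (data frame in the record dialect, including
#'   the K_M unit tag `km_unit = "mM"`) and `truth` (ground-truth manifest:
#'   per-record descriptors, signal and noise-free label, the coefficient
#'   vector, the mutation-effect registry and the seed).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  voc <- config$vocabulary
  # descriptor table for the vocabulary (computed once, outside the RNG)
  graphs <- lapply(voc, smiles_to_graph)
  heavy <- vapply(graphs, function(g) g$n_atoms, 0L)
  rings <- vapply(graphs, aromatic_ring_count, 0L)

  with_local_seed(config$seed, {
    nb <- config$n_base_enzymes
    base_seqs <- vapply(seq_len(nb), function(i) {
      len <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]), 1)
      paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
    }, "")
    base_ec <- paste(rep_len(1:6, nb),
                     sample(1:9, nb, TRUE), sample(1:30, nb, TRUE),
                     sample(1:90, nb, TRUE), sep = ".")
    base_org <- paste("Synthetica", paste0("exempli", seq_len(nb)))

    # characterized-mutant pool with per-substitution effects ~ N(0, tau^2)
    effects <- list()
    pool <- list()
    for (e in seq_len(nb)) {
      wt <- base_seqs[e]
      chars <- strsplit(wt, "")[[1]]
      for (v in seq_len(config$mutants_per_enzyme)) {
        k <- sample(1:3, 1)
        pos <- sort(sample(length(chars), k))
        muts <- vapply(pos, function(p)
          sample(setdiff(AA_ALPHABET, chars[p]), 1), "")
        eff <- 0
        for (j in seq_len(k)) {
          key <- paste(e, pos[j], muts[j], sep = ":")
          if (is.null(effects[[key]]))
            effects[[key]] <- stats::rnorm(1, 0, config$tau)
          eff <- eff + effects[[key]]
        }
        spec <- paste(paste0(chars[pos], pos, muts), collapse = "/")
        pool[[length(pool) + 1L]] <- list(
          enzyme = e, spec = spec, effect = eff,
          sequence = apply_mutations(wt, parse_mutation_spec(spec)))
      }
    }

    n <- config$n_records
    sub_i <- sample(length(voc), n, replace = TRUE)
    is_wt <- stats::runif(n) < config$wildtype_fraction
    enz_i <- sample(nb, n, replace = TRUE)
    mut_i <- sample(length(pool), n, replace = TRUE)

    # the record table carries the wildtype sequence plus the mutation spec
    # (curation materializes the mutant sequence); the label model uses the
    # materialized sequence, which is the actual enzyme
    sequence <- character(n)      # as written in the record
    true_seq <- character(n)      # materialized enzyme sequence
    mutation_spec <- rep(NA_character_, n)
    mut_effect <- numeric(n)
    for (i in seq_len(n)) {
      if (is_wt[i]) {
        sequence[i] <- base_seqs[enz_i[i]]
        true_seq[i] <- sequence[i]
      } else {
        m <- pool[[mut_i[i]]]
        enz_i[i] <- m$enzyme
        sequence[i] <- base_seqs[m$enzyme]
        true_seq[i] <- m$sequence
        mutation_spec[i] <- m$spec
        mut_effect[i] <- m$effect
      }
    }

    hfrac <- vapply(true_seq, hydrophobic_fraction, 0, USE.NAMES = FALSE)
    b <- config$beta
    signal <- b[1] + b[2] * heavy[sub_i] + b[3] * rings[sub_i] +
      b[4] * hfrac + mut_effect
    noise <- stats::rnorm(n, 0, config$sigma)
    log10_km <- signal + noise

    records <- data.frame(
      substrate_name = paste0("compound_", sub_i),
      smiles = voc[sub_i],
      ec_number = base_ec[enz_i],
      organism = base_org[enz_i],
      uniprot_id = NA_character_,
      sequence = sequence,
      enzyme_type = ifelse(is_wt, "wildtype", "mutant"),
      mutation_spec = mutation_spec,
      km_value = 10^log10_km,
      km_unit = "mM",
      stringsAsFactors = FALSE)

    truth <- list(
      beta = b, tau = config$tau, sigma = config$sigma, seed = config$seed,
      descriptors = data.frame(heavy_atoms = heavy[sub_i],
                               aromatic_rings = rings[sub_i],
                               hydrophobic_fraction = hfrac,
                               mutation_effect = mut_effect,
                               sequence = true_seq,
                               signal = signal, noise = noise,
                               log10_km = log10_km,
                               stringsAsFactors = FALSE),
      mutation_effects = unlist(effects))
    list(records = records, truth = truth)
  })
}

#' Bundled deterministic test fixtures
#'
#' `"curation"`: 12 raw records exercising every cleaning rule — two
#' duplicate pairs (one via SMILES synonyms, resolved to the maximum K_M), a
#' length-1000 sequence (removed), a non-positive K_M and a malformed SMILES
#' (both quarantined) — leaving exactly 7 survivors whose EC labels cover
#' classes 1-6 and include both wildtype and mutant enzymes.
#'
#' @param name fixture name.
#' @return data frame of raw records.
#' @export
make_fixture <- function(name = "curation") {
  if (!identical(name, "curation"))
    stop("unknown fixture: '", name, "'")
  s <- c(
    s1 = "MKTAYIAKQRQISFVKSHFSRQLE",
    s2 = "MNIFEMLRIDEGLRLKIYKDTEGY",
    s3 = "MADEEKLPPGWEKRMSRSSGRVYY",
    s4 = "MTEYKLVVVGAGGVGKSALTIQLI",
    s5 = "MKVLWAALLVTFLAGCQAKVEQAV",
    s6 = "MGLSAEQKAIVRETWALVKPDLPA",  # A at position 5
    s7 = "MVLSPADKTNVKAAWGKVGAHAGE",
    s8 = "MPKIIEAIYENGVFKPLQKVDLKE",  # K at position 3
    s9 = "MSTNPKPQRKTKRNTNRRPQDVKF")
  data.frame(
    substrate_name = c("ethanol", "ethanol", "acetate", "acetate",
                       "ethanol", "ethanol", "mystery", "benzene",
                       "lactate", "glycine", "pyruvate", "phenol"),
    smiles = c("OCC", "CCO", "CC(=O)O", "CC(=O)O", "CCO", "CCO",
               "notasmiles", "c1ccccc1", "CC(O)C(=O)O", "NCC(=O)O",
               "CC(=O)C(=O)O", "Oc1ccccc1"),
    ec_number = c("1.1.1.1", "1.1.1.1", "2.7.1.1", "2.7.1.1", "3.1.1.1",
                  "1.1.1.2", "2.1.1.1", "3.2.1.1", "4.1.1.1", "5.3.1.1",
                  "6.3.1.1", "2.3.1.1"),
    organism = "Synthetica exempli",
    uniprot_id = NA_character_,
    sequence = unname(c(s["s1"], s["s1"], s["s2"], s["s2"],
                        strrep("A", 1000), s["s3"], s["s4"], s["s5"],
                        s["s6"], s["s7"], s["s8"], s["s9"])),
    enzyme_type = c("wildtype", "wildtype", "wildtype", "wildtype",
                    "wildtype", "wildtype", "wildtype", "wildtype",
                    "mutant", "wildtype", "mutant", "wildtype"),
    mutation_spec = c(NA, NA, NA, NA, NA, NA, NA, NA,
                      "A5G", NA, "K3R", NA),
    km_value = c(2.0, 5.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.8,
                 1.2, 0.9, 3.5, 0.25),
    stringsAsFactors = FALSE, row.names = NULL)
}
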