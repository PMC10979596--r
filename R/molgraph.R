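ELEMENT_TABLE <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")
HYBRID_TABLE  <- c("sp", "sp2", "sp3", "other")

#' Atom feature dimension
#'
#' Length of the per-atom feature vector: one-hot element over
#' \{C,N,O,S,P,F,Cl,Br,I,other\} (10), one-hot heavy-atom degree 0-5 (6),
#' one-hot formal charge -2..+2 (5), one-hot hybridization
#' \{sp,sp2,sp3,other\} (4), aromatic flag (1), one-hot attached-hydrogen
#' count 0-4 (5).
#' @return integer, 31.
#' @export
atom_feature_dim <- function() 31L

one_hot <- function(value, table) {
  v <- numeric(length(table))
  i <- match(value, table)
  if (is.na(i)) i <- length(table)  # "other" slot is last
  v[i] <- 1
  v
}

#' Featurize one atom
#'
#' @param element element symbol (outside the supported table maps to the
#'   "other" slot).
#' @param degree heavy-atom degree (clipped to 0-5).
#' @param formal_charge integer formal charge (clipped to -2..+2).
#' @param hybridization one of `"sp"`, `"sp2"`, `"sp3"` (anything else maps
#'   to "other").
#' @param aromatic logical aromaticity flag.
#' @param n_h attached-hydrogen count (clipped to 0-4).
#' @return numeric vector of length [atom_feature_dim()], entries in
#'   \{0, 1\}.
#' @export
atom_feature_vector <- function(element, degree, formal_charge,
                                hybridization, aromatic, n_h) {
  c(one_hot(element, ELEMENT_TABLE),
    one_hot(min(max(degree, 0L), 5L), 0:5),
    one_hot(min(max(formal_charge, -2L), 2L), -2:2),
    one_hot(hybridization, HYBRID_TABLE),
    as.numeric(aromatic),
    one_hot(min(max(n_h, 0L), 4L), 0:4))
}

.mol2_hybrid <- function(sybyl) {
  suffix <- ifelse(grepl(".", sybyl, fixed = TRUE),
                   sub("^[^.]*\\.", "", sybyl), "")
  out <- rep("other", length(sybyl))
  out[suffix == "1"] <- "sp"
  out[suffix %in% c("2", "ar", "am", "pl3", "co2", "cat")] <- "sp2"
  out[suffix == "3"] <- "sp3"
  out
}

# Lines of the section starting at `start` (a @<TRIPOS> header index),
# up to the next section header; character(0) for an empty section.
.mol2_section <- function(lines, start) {
  if (is.na(start)) return(character(0))
  ends <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  stop_at <- min(ends[ends > start]) - 1L
  if (stop_at < start + 1L) return(character(0))
  out <- lines[seq.int(start + 1L, stop_at)]
  out[nzchar(trimws(out))]
}

# Formal charges from the MOL2 UNITY_ATOM_ATTR section: blocks of
# "<atom_id> <n_attrs>" followed by n_attrs "name value" lines.
.charges_from_mol2 <- function(lines, n_atoms) {
  charges <- integer(n_atoms)
  attr_lines <- .mol2_section(lines,
                              which(lines == "@<TRIPOS>UNITY_ATOM_ATTR")[1])
  i <- 1L
  while (i <= length(attr_lines)) {
    hdr <- as.integer(strsplit(trimws(attr_lines[i]), "\\s+")[[1]])
    atom_id <- hdr[1]; n_attr <- hdr[2]
    for (j in seq_len(n_attr)) {
      f <- strsplit(trimws(attr_lines[i + j]), "\\s+")[[1]]
      if (f[1] == "charge" && atom_id <= n_atoms)
        charges[atom_id] <- as.integer(f[2])
    }
    i <- i + 1L + n_attr
  }
  charges
}

.graph_cache <- new.env(parent = emptyenv())

#' Convert a SMILES string to a molecular graph
#'
#' Nodes are heavy atoms (hydrogens are implicit, entering only through the
#' attached-H count feature); each chemical bond is stored as two directed
#' edges. Node order is the toolkit's canonical atom order, so equal
#' canonical SMILES give bit-identical graphs. Structure perception
#' (aromaticity, hybridization, formal charge) comes from Open Babel via
#' ChemmineOB.
#'
#' @param smiles a single SMILES string (canonical input recommended).
#' @return an object of class `molgraph`: list with `n_atoms`,
#'   `node_features` (n_atoms x [atom_feature_dim()] matrix), `edges`
#'   (directed 2-column integer matrix, both directions per bond), `element`,
#'   `aromatic`, `degree`, `n_h`, `formal_charge`, `hybridization`, `smiles`.
#' @examples
#' \donttest{
#' g <- smiles_to_graph("CCO")   # ethanol: 3 nodes, 4 directed edges
#' }
#' @export
smiles_to_graph <- function(smiles) {
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("smiles must be a single non-empty string")
  key <- paste0("g:", smiles)
  hit <- .graph_cache[[key]]
  if (!is.null(hit)) return(hit)

  mol2 <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, "\n"),
                              options = data.frame(names = "h", args = "")),
    error = function(e) "")
  if (!nzchar(mol2)) stop("unparseable SMILES: '", smiles, "'")
  lines <- strsplit(mol2, "\n")[[1]]
  atom_lines <- .mol2_section(lines, which(lines == "@<TRIPOS>ATOM")[1])
  if (!length(atom_lines)) stop("zero-atom molecule: '", smiles, "'")
  af <- strsplit(trimws(atom_lines), "\\s+")
  sybyl <- vapply(af, `[`, "", 6)
  element_all <- sub("\\..*$", "", sybyl)
  # MOL2 atom names keep element case ("NA"/"CL"); SYBYL types are cased
  element_all[element_all == "NA"] <- "Na"

  bonds <- matrix(integer(0), 0, 2)
  bond_ar <- logical(0)
  bond_lines <- .mol2_section(lines, which(lines == "@<TRIPOS>BOND")[1])
  if (length(bond_lines)) {
    bf <- strsplit(trimws(bond_lines), "\\s+")
    bonds <- cbind(vapply(bf, function(x) as.integer(x[2]), 0L),
                   vapply(bf, function(x) as.integer(x[3]), 0L))
    bond_ar <- vapply(bf, `[`, "", 4) == "ar"
  }

  heavy <- element_all != "H"
  n <- sum(heavy)
  if (n == 0L) stop("zero-atom molecule: '", smiles, "'")
  idx_map <- integer(length(heavy))
  idx_map[heavy] <- seq_len(n)

  both_heavy <- heavy[bonds[, 1]] & heavy[bonds[, 2]]
  hb <- bonds[both_heavy, , drop = FALSE]
  hb <- cbind(idx_map[hb[, 1]], idx_map[hb[, 2]])
  hb_ar <- bond_ar[both_heavy]

  # attached hydrogens per heavy atom
  n_h <- integer(n)
  h_edge <- xor(heavy[bonds[, 1]], heavy[bonds[, 2]])
  for (i in which(h_edge)) {
    hv <- if (heavy[bonds[i, 1]]) bonds[i, 1] else bonds[i, 2]
    n_h[idx_map[hv]] <- n_h[idx_map[hv]] + 1L
  }

  degree <- tabulate(c(hb[, 1], hb[, 2]), nbins = n)
  aromatic <- grepl("\\.ar$", sybyl[heavy])
  # atoms on aromatic bonds are aromatic even if typed otherwise
  if (any(hb_ar)) {
    ar_atoms <- unique(c(hb[hb_ar, 1], hb[hb_ar, 2]))
    aromatic[ar_atoms] <- TRUE
  }
  hybrid <- .mol2_hybrid(sybyl[heavy])
  charge <- .charges_from_mol2(lines, length(heavy))[heavy]
  element <- element_all[heavy]

  feat <- matrix(0, n, atom_feature_dim())
  for (i in seq_len(n))
    feat[i, ] <- atom_feature_vector(element[i], degree[i], charge[i],
                                     hybrid[i], aromatic[i], n_h[i])

  edges <- rbind(hb, hb[, 2:1, drop = FALSE])
  if (nrow(edges)) edges <- edges[order(edges[, 1], edges[, 2]), ,
                                  drop = FALSE]
  storage.mode(edges) <- "integer"

  g <- structure(
    list(n_atoms = n, node_features = feat, edges = edges,
         element = element, aromatic = aromatic, degree = degree,
         n_h = n_h, formal_charge = charge, hybridization = hybrid,
         smiles = smiles),
    class = "molgraph")
  assign(key, g, envir = .graph_cache)
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, ": ", x$n_atoms, " heavy atoms, ",
      nrow(x$edges) / 2, " bonds, ", sum(x$aromatic), " aromatic atoms\n",
      sep = "")
  invisible(x)
}

#' Count aromatic rings in a molecular graph
#'
#' Circuit rank of the aromatic subgraph: aromatic bonds - aromatic atoms +
#' connected aromatic components (1 for benzene, 2 for naphthalene).
#'
#' @param graph a `molgraph`.
#' @return nonnegative integer.
#' @export
aromatic_ring_count <- function(graph) {
  ar <- which(graph$aromatic)
  if (!length(ar)) return(0L)
  e <- graph$edges
  e <- e[e[, 1] < e[, 2], , drop = FALSE]             # undirected
  e <- e[e[, 1] %in% ar & e[, 2] %in% ar, , drop = FALSE]
  # connected components of the aromatic subgraph
  comp <- stats::setNames(seq_along(ar), ar)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(e))) {
      a <- as.character(e[i, 1]); b <- as.character(e[i, 2])
      if (comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  as.integer(nrow(e) - length(ar) + length(unique(comp)))
}
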