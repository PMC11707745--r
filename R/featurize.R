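# Molecular featurization: three representations per molecule.
#   1. circular (extended-connectivity) fingerprint, default radius 3 hashed
#      and folded to 1024 bits, plus a named physicochemical descriptor panel;
#   2. an attributed molecular graph (9 node features, 4 edge features);
#   3. a 3D conformer embedded and MMFF-minimized with a fixed random seed.
# Representations 1 feed the gradient-boosting models; 2 and 3 serve the
# pluggable graph/conformer regressor interface.

# ---------------------------------------------------------------------------
# fingerprints

#' Extended-connectivity fingerprint
#'
#' Computes a hashed circular-substructure fingerprint. Substructures up to
#' the given radius are enumerated around every atom, hashed into a 4096-bit
#' vector by the chemistry backend, and folded (bitwise OR of aligned blocks)
#' to `n_bits`. The fingerprint is a deterministic function of the molecule:
#' any SMILES of the same structure yields the same bits.
#'
#' @param smiles character vector of SMILES.
#' @param radius circular neighborhood radius (default 3, i.e. ECFP6).
#' @param n_bits folded fingerprint length (default 1024); must divide 4096.
#' @param strict if `TRUE`, unparsable SMILES raise a featurization error;
#'   otherwise their rows are `NA`.
#' @return for a single SMILES an integer 0/1 vector of length `n_bits`;
#'   otherwise an integer matrix (molecules x bits).
#' @export
compute_ecfp <- function(smiles, radius = 3, n_bits = 1024, strict = TRUE) {
  if (!radius %in% 0:5) {
    stop_bcstools("radius must be an integer in 0..5", "bcstools_featurization_error")
  }
  if (n_bits < 1 || 4096 %% n_bits != 0) {
    stop_bcstools("n_bits must divide 4096", "bcstools_featurization_error")
  }
  fpname <- paste0("ECFP", 2L * radius)
  ids <- paste0("bcstools_id_", seq_along(smiles))
  lines <- run_obabel(smiles, ids, c("-ofpt", "-xf", fpname, "-xh"))
  raw <- parse_fpt_hex(lines, ids)
  mat <- matrix(NA_integer_, nrow = length(smiles), ncol = n_bits)
  rownames(mat) <- if (!is.null(names(smiles))) names(smiles) else ids
  for (i in seq_along(smiles)) {
    bits <- raw[[i]]
    if (!is.null(bits)) mat[i, ] <- fold_bits(bits, n_bits)
  }
  failed <- apply(mat, 1L, anyNA)
  if (strict && any(failed)) {
    stop_bcstools(
      sprintf("fingerprint generation failed for %d molecule(s)", sum(failed)),
      "bcstools_featurization_error"
    )
  }
  if (length(smiles) == 1L) return(mat[1L, ])
  mat
}

# Parse `obabel -ofpt -xh` output: one ">id  ..." header per molecule followed
# by lines of 8-hex-digit words (32 bits each, most significant digit first).
parse_fpt_hex <- function(lines, ids) {
  out <- vector("list", length(ids))
  names(out) <- ids
  cur <- NULL
  words <- character(0)
  flush <- function() {
    if (!is.null(cur) && cur %in% ids && length(words)) {
      out[[cur]] <<- hex_words_to_bits(words)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur <- strsplit(trimws(sub("^>", "", ln)), "\\s+")[[1L]][1L]
      words <- character(0)
    } else if (!is.null(cur)) {
      words <- c(words, strsplit(trimws(ln), "\\s+")[[1L]])
    }
  }
  flush()
  out
}

hex_digit_bits <- local({
  tab <- sapply(0:15, function(v) as.integer(intToBits(v)[4:1]))
  dimnames(tab) <- list(NULL, c(0:9, letters[1:6]))
  tab
})

# 8-hex-digit words -> 0/1 vector; word w occupies bits (w-1)*32 + 1..32 with
# the word's least-significant bit first.
hex_words_to_bits <- function(words) {
  words <- words[nzchar(words)]
  digs <- strsplit(tolower(paste(words, collapse = "")), "")[[1L]]
  bits <- as.vector(hex_digit_bits[, digs])          # MSB-first within word
  per_word <- split(bits, rep(seq_along(words), each = 32L))
  unlist(lapply(per_word, rev), use.names = FALSE)   # LSB-first indexing
}

# Fold a bit vector to length n by OR of aligned blocks.
fold_bits <- function(bits, n) {
  stopifnot(length(bits) %% n == 0L)
  as.integer(rowSums(matrix(bits, nrow = n)) > 0L)
}

# ---------------------------------------------------------------------------
# descriptors

element_table <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S", "Cl",
             "K", "Ca", "Fe", "Zn", "Se", "Br", "I", "Li"),
  number = c(1, 5, 6, 7, 8, 9, 11, 12, 14, 15, 16, 17, 19, 20, 26, 30, 34, 35, 53, 3),
  mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 22.99, 24.305, 28.086,
           30.974, 32.06, 35.45, 39.098, 40.078, 55.845, 65.38, 78.971, 79.904,
           126.904, 6.94),
  valence = c(1, 3, 4, 3, 2, 1, 1, 2, 4, 3, 2, 1, 1, 2, 0, 0, 2, 1, 1, 1),
  stringsAsFactors = FALSE
)

#' Physicochemical descriptor panel
#'
#' Computes the package's standard 2D descriptor panel: OpenBabel bulk
#' properties (molecular weight, octanol-water log P estimate, topological
#' polar surface area, hydrogen-bond donor/acceptor counts, molar
#' refractivity) plus structural counts derived from the connection table
#' (heavy atoms, bonds, ring bonds, rotatable bonds, element counts, aromatic
#' fraction, formal charges, multiple-bond counts, cyclomatic ring count).
#' Descriptor values are deterministic and invariant under SMILES atom-order
#' permutation. Non-finite values are imputed to 0; the affected cells are
#' recorded in the `"imputed"` attribute.
#'
#' @param smiles character vector of SMILES.
#' @param descriptor_set optional character vector naming a subset of the
#'   panel to return (default: full panel).
#' @return numeric matrix (molecules x descriptors) with named columns; a
#'   named vector for a single SMILES.
#' @export
compute_descriptors <- function(smiles, descriptor_set = NULL) {
  n <- length(smiles)
  ob <- ob_properties(smiles)
  can <- canonicalize_smiles(smiles, strict = FALSE)
  blocks <- ob_convert(smiles, "sdf")
  struct <- t(vapply(seq_len(n), function(i) {
    if (is.null(blocks[[i]])) return(rep(NA_real_, 18L))
    structural_counts(parse_molblock(blocks[[i]]), can[i])
  }, numeric(18)))
  colnames(struct) <- descriptor_names()[8:25]
  mat <- cbind(ob, struct)
  rownames(mat) <- if (!is.null(names(smiles))) names(smiles) else paste0("cmp", seq_len(n))

  imputed <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(imputed)) mat[!is.finite(mat)] <- 0
  if (!is.null(descriptor_set)) {
    missing <- setdiff(descriptor_set, colnames(mat))
    if (length(missing)) {
      stop_bcstools(paste("unknown descriptors:", paste(missing, collapse = ", ")),
                    "bcstools_featurization_error")
    }
    mat <- mat[, descriptor_set, drop = FALSE]
  }
  attr(mat, "imputed") <- imputed
  if (n == 1L) {
    v <- mat[1L, ]
    attr(v, "imputed") <- imputed
    return(v)
  }
  mat
}

#' Names of the standard descriptor panel
#'
#' @return character vector of the descriptor columns produced by
#'   [compute_descriptors()].
#' @export
descriptor_names <- function() {
  c("MW", "LogP", "TPSA", "HBA1", "HBA2", "HBD", "MR",
    "NumHeavyAtoms", "NumBonds", "NumRingBonds", "NumRotatableBonds",
    "NumC", "NumN", "NumO", "NumS", "NumF", "NumHalogen", "NumAromaticAtoms",
    "FracAromatic", "NetCharge", "NumPosAtoms", "NumNegAtoms",
    "NumDoubleBonds", "NumTripleBonds", "NumRings")
}

# OpenBabel bulk properties, batch-computed for a SMILES vector.
ob_properties <- function(smiles) {
  props <- c("MW", "logP", "TPSA", "HBA1", "HBA2", "HBD", "MR")
  ids <- paste0("bcstools_id_", seq_along(smiles))
  lines <- run_obabel(smiles, ids,
                      c("-otxt", "--append", shQuote(paste(props, collapse = " "))))
  out <- matrix(NA_real_, length(smiles), length(props))
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    idx <- match(f[1L], ids)
    if (!is.na(idx) && length(f) >= length(props) + 1L) {
      out[idx, ] <- suppressWarnings(as.numeric(f[1L + seq_along(props)]))
    }
  }
  colnames(out) <- c("MW", "LogP", "TPSA", "HBA1", "HBA2", "HBD", "MR")
  out
}

# Connection-table derived counts for one molecule (parsed molblock + its
# canonical SMILES for aromatic-atom counting).
structural_counts <- function(mol, cansmi) {
  n_atoms <- nrow(mol$atoms)
  elements <- mol$atoms$symbol
  charges <- mol$atoms$charge
  edges <- mol$bonds
  ring_edge <- ring_bonds(edges, n_atoms)
  deg <- tabulate(c(edges$a, edges$b), nbins = n_atoms)
  arom_atoms <- aromatic_atom_count(cansmi)
  rotatable <- sum(edges$order == 1 & !ring_edge &
                     deg[edges$a] > 1L & deg[edges$b] > 1L)
  c(
    NumHeavyAtoms = n_atoms,
    NumBonds = nrow(edges),
    NumRingBonds = sum(ring_edge),
    NumRotatableBonds = rotatable,
    NumC = sum(elements == "C"),
    NumN = sum(elements == "N"),
    NumO = sum(elements == "O"),
    NumS = sum(elements == "S"),
    NumF = sum(elements == "F"),
    NumHalogen = sum(elements %in% c("F", "Cl", "Br", "I")),
    NumAromaticAtoms = arom_atoms,
    FracAromatic = if (n_atoms > 0) arom_atoms / n_atoms else 0,
    NetCharge = sum(charges),
    NumPosAtoms = sum(charges > 0),
    NumNegAtoms = sum(charges < 0),
    NumDoubleBonds = sum(edges$order == 2),
    NumTripleBonds = sum(edges$order == 3),
    NumRings = cyclomatic_rings(edges, n_atoms)
  )
}

# 1 = sp, 2 = sp2 (incl. aromatic), 3 = sp3/other, from SYBYL atom types.
sybyl_hybridization <- function(types) {
  suffix <- sub("^[^.]*\\.?", "", types)
  ifelse(suffix == "1", 1,
         ifelse(suffix %in% c("2", "ar", "am", "pl3", "cat"), 2, 3))
}

# Aromatic atoms counted from the aromatic (lowercase) notation of an
# already-canonical SMILES string.
aromatic_atom_count <- function(can) {
  if (is.na(can) || !nzchar(can)) return(0L)
  brackets <- regmatches(can, gregexpr("\\[[^]]*\\]", can))[[1L]]
  nb <- 0L
  for (b in brackets) {
    sym <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", b)
    if (sym %in% c("c", "n", "o", "s", "p", "se", "as")) nb <- nb + 1L
  }
  bare <- gsub("\\[[^]]*\\]", "", can)
  # lowercase aromatic organic-subset atoms outside brackets
  nb + sum(strsplit(bare, "")[[1L]] %in% c("c", "n", "o", "s", "p"))
}

# Ring bonds = edges that are not bridges (lie on at least one cycle).
# Iterative DFS bridge finding; molecule graphs are small.
ring_bonds <- function(edges, n_atoms) {
  m <- nrow(edges)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n_atoms)
  for (k in seq_len(m)) {
    adj[[edges$a[k]]] <- c(adj[[edges$a[k]]], k)
    adj[[edges$b[k]]] <- c(adj[[edges$b[k]]], k)
  }
  other <- function(k, v) if (edges$a[k] == v) edges$b[k] else edges$a[k]
  disc <- integer(n_atoms); low <- integer(n_atoms)
  timer <- 0L
  is_bridge <- logical(m)
  for (root in seq_len(n_atoms)) {
    if (disc[root] != 0L) next
    # stack of (vertex, incoming edge, next adjacency index)
    stack <- list(list(v = root, pe = 0L, i = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      if (fr$i <= length(adj[[fr$v]])) {
        k <- adj[[fr$v]][fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (k == fr$pe) next
        w <- other(k, fr$v)
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pe = k, i = 1L)
        } else {
          low[fr$v] <- min(low[fr$v], disc[w])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$v
          low[p] <- min(low[p], low[fr$v])
          if (low[fr$v] > disc[p]) is_bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

cyclomatic_rings <- function(edges, n_atoms) {
  if (n_atoms == 0L) return(0L)
  comp <- seq_len(n_atoms)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$a[k]); rb <- find(edges$b[k])
    if (ra != rb) comp[ra] <- rb
  }
  ncomp <- length(unique(vapply(seq_len(n_atoms), find, 1L)))
  nrow(edges) - n_atoms + ncomp
}

# ---------------------------------------------------------------------------
# molecular graph

#' Attributed molecular graph
#'
#' Builds the heavy-atom graph of a molecule: one node per heavy atom, one
#' undirected edge per bond, with 9 node features (atomic number, degree,
#' formal charge, implied hydrogen count, hybridization, aromaticity, ring
#' membership, atomic mass, heteroatom flag) and 4 edge features (bond order,
#' conjugation, ring membership, stereo flag). Feature encodings follow the
#' conventions of attention-based molecular graph featurizers; the exact
#' columns are fixed constants of this package.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `bcs_molgraph` with elements `node_features`
#'   (n x 9 matrix), `edge_features` (m x 4 matrix), `edges` (m x 2 atom index
#'   pairs), and `adjacency` (n x n symmetric logical, no self loops).
#' @export
build_graph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  can <- canonicalize_smiles(smiles)
  block <- ob_convert(can, "sdf")[[1L]]
  m2block <- ob_convert(can, "mol2")[[1L]]
  if (is.null(block) || is.null(m2block)) {
    stop_bcstools("structure conversion failed", "bcstools_featurization_error")
  }
  mol <- parse_molblock(block)
  m2 <- parse_mol2(m2block)
  n <- nrow(mol$atoms)
  if (n < 1L) stop_bcstools("molecule has no heavy atoms", "bcstools_featurization_error")
  elements <- mol$atoms$symbol
  charges <- mol$atoms$charge
  edges <- mol$bonds
  m <- nrow(edges)
  deg <- tabulate(c(edges$a, edges$b), nbins = n)
  ring_edge <- ring_bonds(edges, n)
  in_ring <- rep(FALSE, n)
  if (m) in_ring[unique(c(edges$a[ring_edge], edges$b[ring_edge]))] <- TRUE
  # SYBYL atom types from the MOL2 form carry aromaticity and hybridization
  arom_atom <- grepl("\\.ar$", m2$atom_type[seq_len(n)])
  hybrid <- sybyl_hybridization(m2$atom_type[seq_len(n)])
  arom_bond <- if (m) m2$bond_type[seq_len(m)] == "ar" else logical(0)

  ei <- match(elements, element_table$symbol)
  atomic_number <- ifelse(is.na(ei), 0, element_table$number[ei])
  mass <- ifelse(is.na(ei), 0, element_table$mass[ei])
  valence <- ifelse(is.na(ei), 0, element_table$valence[ei])
  order_sum <- rep(0, n)
  if (m) {
    # aromatic SDF rings are kekulized; bond orders 1/2/3 as written
    for (k in seq_len(m)) {
      order_sum[edges$a[k]] <- order_sum[edges$a[k]] + edges$order[k]
      order_sum[edges$b[k]] <- order_sum[edges$b[k]] + edges$order[k]
    }
  }
  n_h <- pmax(0, valence + charges - order_sum)

  node <- cbind(
    atomic_number = atomic_number,
    degree = deg,
    formal_charge = as.numeric(charges),
    num_hydrogens = n_h,
    hybridization = hybrid,
    aromatic = as.numeric(arom_atom),
    in_ring = as.numeric(in_ring),
    mass = mass,
    heteroatom = as.numeric(!elements %in% c("C", "H"))
  )
  rownames(node) <- paste0(elements, "_", seq_len(n))

  # a bond is conjugated when aromatic or when both ends are sp/sp2 centers
  conj <- if (m) arom_bond | (hybrid[edges$a] <= 2 & hybrid[edges$b] <= 2)
          else logical(0)
  edge <- cbind(
    bond_order = edges$order,
    conjugated = as.numeric(conj),
    in_ring = as.numeric(ring_edge),
    stereo = edges$stereo
  )

  adjacency <- matrix(FALSE, n, n)
  if (m) {
    adjacency[cbind(edges$a, edges$b)] <- TRUE
    adjacency[cbind(edges$b, edges$a)] <- TRUE
  }
  structure(
    list(node_features = node, edge_features = edge,
         edges = cbind(a = edges$a, b = edges$b), adjacency = adjacency,
         smiles = can),
    class = "bcs_molgraph"
  )
}

#' @export
print.bcs_molgraph <- function(x, ...) {
  cat(sprintf("Molecular graph of %s: %d nodes, %d edges\n",
              x$smiles, nrow(x$node_features), nrow(x$edge_features)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# 3D conformers

#' Embed and minimize a 3D conformer
#'
#' Generates a distance-geometry 3D embedding refined by MMFF94 minimization.
#' The embedding is performed by the RDKit toolkit through a bundled Python
#' bridge because it offers a seedable, fully reproducible embedding: the same
#' molecule and seed always give identical coordinates. Conformers are
#' generated in vacuum, one per molecule.
#'
#' @param smiles a single SMILES string.
#' @param seed integer random seed for the embedding.
#' @return an object of class `bcs_conformer`: `positions` (n_atoms x 3
#'   matrix, Angstrom, hydrogens included, element symbols as rownames),
#'   `energy` (MMFF94 energy, kcal/mol) and `seed`.
#' @export
embed_conformer <- function(smiles, seed = 42L) {
  stopifnot(length(smiles) == 1L)
  res <- embed_conformers(smiles, seed = seed)[[1L]]
  if (is.null(res)) {
    stop_bcstools(sprintf("no conformer could be generated for '%s'", smiles),
                  "bcstools_embedding_error")
  }
  res
}

#' Batch conformer embedding
#'
#' @param smiles character vector of SMILES.
#' @param seed integer seed shared by all embeddings.
#' @return list of `bcs_conformer` objects (`NULL` where embedding failed).
#' @export
embed_conformers <- function(smiles, seed = 42L) {
  python <- Sys.getenv("BCSTOOLS_PYTHON", unname(Sys.which("python")))
  if (!nzchar(python)) {
    stop_bcstools("no python interpreter found for the RDKit conformer bridge",
                  "bcstools_embedding_error")
  }
  script <- system.file("python", "embed_conformers.py", package = "bcstools")
  payload <- jsonlite::toJSON(list(smiles = as.list(unname(smiles)),
                                   seed = as.integer(seed)), auto_unbox = TRUE)
  out <- suppressWarnings(system2(python, shQuote(script), stdout = TRUE,
                                  stderr = FALSE, input = as.character(payload)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop_bcstools("the RDKit conformer bridge failed (is rdkit installed for python?)",
                  "bcstools_embedding_error")
  }
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  lapply(parsed, function(p) {
    if (!isTRUE(p$ok)) return(NULL)
    pos <- matrix(unlist(p$positions), ncol = 3L, byrow = TRUE)
    rownames(pos) <- unlist(p$symbols)
    structure(list(positions = pos, energy = as.numeric(p$energy),
                   seed = as.integer(seed)),
              class = "bcs_conformer")
  })
}

#' @export
print.bcs_conformer <- function(x, ...) {
  cat(sprintf("3D conformer: %d atoms, MMFF94 energy %.3f kcal/mol (seed %d)\n",
              nrow(x$positions), x$energy, x$seed))
  invisible(x)
}

#' Write conformers to an SDF file
#'
#' @param conformers list of `bcs_conformer` objects (as from
#'   [embed_conformers()]).
#' @param smiles the SMILES the conformers were embedded from (used for
#'   connectivity).
#' @param path output SDF path.
#' @return invisibly, `path`.
#' @export
write_conformer_sdf <- function(conformers, smiles, path) {
  stopifnot(length(conformers) == length(smiles))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(conformers)) {
    cf <- conformers[[i]]
    if (is.null(cf)) next
    pos <- cf$positions
    lines <- c(
      sprintf("conformer_%d", i), "  bcstools", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(pos), 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              pos[, 1L], pos[, 2L], pos[, 3L], rownames(pos)),
      "M  END",
      "> <smiles>", smiles[i], "",
      "> <mmff94_energy>", sprintf("%.6f", cf$energy), "",
      "$$$$"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# bundles

#' Featurize one molecule into all representations
#'
#' @param smiles a single SMILES string.
#' @param radius,n_bits fingerprint parameters (see [compute_ecfp()]).
#' @param conformer also embed a 3D conformer (slower; off by default).
#' @param seed seed for conformer embedding.
#' @return `bcs_feature_bundle`: `fingerprint`, `descriptors`, `graph`,
#'   `conformer` (or `NULL`).
#' @export
featurize_molecule <- function(smiles, radius = 3, n_bits = 1024,
                               conformer = FALSE, seed = 42L) {
  stopifnot(length(smiles) == 1L)
  structure(
    list(
      fingerprint = compute_ecfp(smiles, radius = radius, n_bits = n_bits),
      descriptors = compute_descriptors(smiles),
      graph = build_graph(smiles),
      conformer = if (conformer) embed_conformer(smiles, seed = seed) else NULL
    ),
    class = "bcs_feature_bundle"
  )
}

#' @export
print.bcs_feature_bundle <- function(x, ...) {
  cat(sprintf("Feature bundle: %d fingerprint bits (%d set), %d descriptors, graph %dx%d%s\n",
              length(x$fingerprint), sum(x$fingerprint), length(x$descriptors),
              nrow(x$graph$node_features), nrow(x$graph$edge_features),
              if (is.null(x$conformer)) "" else ", 3D conformer"))
  invisible(x)
}

# Non-failing batch featurization used by curation step 4.
try_featurize <- function(smiles, radius = 3, n_bits = 1024) {
  fp <- tryCatch(
    compute_ecfp(smiles, radius = radius, n_bits = n_bits, strict = FALSE),
    error = function(e) matrix(NA_integer_, length(smiles), n_bits)
  )
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
  desc <- tryCatch(compute_descriptors(smiles), error = function(e) NULL)
  if (is.null(desc)) {
    # batch failure: retry molecule-by-molecule so one bad record cannot sink
    # the whole dataset
    desc <- matrix(NA_real_, length(smiles), length(descriptor_names()),
                   dimnames = list(NULL, descriptor_names()))
    for (i in seq_along(smiles)) {
      d <- tryCatch(compute_descriptors(smiles[i]), error = function(e) NULL)
      if (!is.null(d)) desc[i, names(d)] <- d
    }
  }
  if (is.null(dim(desc))) desc <- matrix(desc, nrow = 1L, dimnames = list(NULL, names(desc)))
  ok <- !apply(fp, 1L, anyNA) & !apply(desc, 1L, anyNA)
  list(ok = ok, fingerprint = fp, descriptors = desc)
}

#' Attach feature matrices to a property dataset
#'
#' Computes the fingerprint and descriptor matrices for every record. All
#' records must featurize; run [clean_dataset()] first to drop molecules that
#' cannot (curation step 4).
#'
#' @param dataset a [property_dataset()].
#' @param radius,n_bits fingerprint parameters.
#' @return the dataset with `$features` populated.
#' @export
featurize_dataset <- function(dataset, radius = 3, n_bits = 1024) {
  stopifnot(inherits(dataset, "bcs_property_dataset"))
  smiles <- dataset$records$canonical_smiles
  fz <- try_featurize(smiles, radius = radius, n_bits = n_bits)
  if (!all(fz$ok)) {
    stop_bcstools(
      sprintf("featurization failed for %d record(s); clean the dataset first",
              sum(!fz$ok)),
      "bcstools_featurization_error"
    )
  }
  dataset$features <- list(fingerprint = fz$fingerprint, descriptors = fz$descriptors)
  dataset
}
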