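# OpenBabel bridge. All structure perception (parsing, canonical SMILES,
# fingerprints, properties, connection tables) goes through the obabel
# command-line tool in batch mode: one subprocess per call regardless of input
# size, which keeps large datasets cheap and handles degenerate molecules
# (single heavy atom, no bonds) uniformly. Every input line carries a
# positional identifier because obabel silently skips unparsable entries;
# callers join results back on the id.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop_bcstools("obabel executable not found on PATH", "bcstools_featurization_error")
  }
  unname(p)
}

run_obabel <- function(smiles, ids, args) {
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, ids), infile)
  # -e: skip unparsable entries instead of aborting the batch
  suppressWarnings(system2(obabel_path(), c(infile, "-e", args),
                           stdout = TRUE, stderr = FALSE))
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to a canonical form such that any two valid notations of
#' the same molecule (atom-order permutations, Kekulé vs. aromatic forms) map
#' to the same string. Stereochemistry is preserved, so distinct stereoisomers
#' remain distinct. Canonicalization is idempotent.
#'
#' @param raw character vector of SMILES strings.
#' @param strict if `TRUE` (default), unparsable input raises a parse error;
#'   if `FALSE`, unparsable entries become `NA` (used internally by
#'   [clean_dataset()], which counts rather than fails on bad records).
#' @param keep_largest_fragment for multi-fragment input (salts, mixtures),
#'   keep only the largest organic fragment before canonicalization. Set to
#'   `FALSE` to canonicalize the full multi-fragment structure.
#' @return character vector of canonical SMILES (with `NA` for failures when
#'   `strict = FALSE`).
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO"))          # identical output
#' canonicalize_smiles("C1=CC=CC=C1")            # same as "c1ccccc1"
#' }
#' @export
canonicalize_smiles <- function(raw, strict = TRUE, keep_largest_fragment = FALSE) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw)) {
    stop_bcstools("SMILES input must be a character vector", "bcstools_parse_error")
  }
  out <- rep(NA_character_, length(raw))
  ok <- !is.na(raw) & nzchar(trimws(raw))
  smi <- trimws(raw[ok])
  if (keep_largest_fragment) smi <- vapply(smi, largest_organic_fragment, "", USE.NAMES = FALSE)
  if (length(smi)) {
    ids <- paste0("bcstools_id_", seq_along(smi))
    lines <- run_obabel(smi, ids, "-ocan")
    res <- rep(NA_character_, length(smi))
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      for (p in parts) {
        if (length(p) >= 2L) {
          idx <- match(trimws(p[2L]), ids)
          if (!is.na(idx)) res[idx] <- p[1L]
        }
      }
    }
    res[!is.na(res) & !nzchar(res)] <- NA_character_
    out[ok] <- res
  }
  if (strict && anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    stop_bcstools(
      sprintf("unparsable SMILES: %s", paste(utils::head(bad, 5L), collapse = ", ")),
      "bcstools_parse_error"
    )
  }
  out
}

# Pick the fragment of a multi-fragment SMILES with the most carbon atoms
# (ties broken by a heavy-atom proxy: string length). Single-fragment input is
# returned unchanged.
largest_organic_fragment <- function(smiles) {
  if (!grepl(".", smiles, fixed = TRUE)) return(smiles)
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1L]]
  frags <- frags[nzchar(frags)]
  if (length(frags) <= 1L) return(smiles)
  ncarb <- vapply(frags, count_carbons, 0L)
  score <- ncarb * 1000L + nchar(frags)
  frags[[which.max(score)]]
}

# Count carbon atoms in a SMILES string without full parsing. Bracket atoms
# are inspected by their element symbol (so [Co], [Cl-], [Sc] do not count);
# outside brackets only the SMILES organic subset occurs, where "C" not
# followed by "l" and aromatic "c" are carbon.
count_carbons <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1L]]
  nc <- 0L
  for (b in brackets) {
    sym <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", b)
    if (sym %in% c("C", "c")) nc <- nc + 1L
  }
  bare <- gsub("\\[[^]]*\\]", "", smiles)
  nc <- nc + length(gregexpr("C(?!l)", bare, perl = TRUE)[[1L]] |> (\(x) x[x > 0])())
  nc <- nc + length(gregexpr("c", bare, fixed = TRUE)[[1L]] |> (\(x) x[x > 0])())
  nc
}

#' Test whether a molecule is organic
#'
#' A molecule is treated as organic iff it contains at least one carbon atom;
#' carbon-free molecules (water, simple salts) are flagged for removal during
#' dataset curation.
#'
#' @param smiles character vector of SMILES (canonical or raw).
#' @return logical vector.
#' @examples
#' \dontrun{
#' is_organic(c("O", "CCO", "[Na+].[Cl-]"))  # FALSE TRUE FALSE
#' }
#' @export
is_organic <- function(smiles) {
  vapply(smiles, function(s) !is.na(s) && count_carbons(s) > 0L, TRUE,
         USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# batch conversion to connection-table formats

# Convert SMILES to SDF (V2000 molblock) or MOL2 text; returns a list aligned
# with the input (NULL where conversion failed), each element the lines of one
# molecule's block.
ob_convert <- function(smiles, format = c("sdf", "mol2")) {
  format <- match.arg(format)
  ids <- paste0("bcstools_id_", seq_along(smiles))
  lines <- run_obabel(smiles, ids, paste0("-o", format))
  out <- vector("list", length(smiles))
  if (format == "sdf") {
    ends <- which(lines == "$$$$")
    start <- 1L
    for (e in ends) {
      block <- lines[start:(e - 1L)]
      idx <- match(trimws(block[1L]), ids)
      if (!is.na(idx)) out[[idx]] <- block
      start <- e + 1L
    }
  } else {
    heads <- which(lines == "@<TRIPOS>MOLECULE")
    bounds <- c(heads, length(lines) + 1L)
    for (i in seq_along(heads)) {
      block <- lines[heads[i]:(bounds[i + 1L] - 1L)]
      idx <- match(trimws(block[2L]), ids)
      if (!is.na(idx)) out[[idx]] <- block
    }
  }
  out
}

int3 <- function(line, from, to) {
  v <- suppressWarnings(as.integer(substr(line, from, to)))
  ifelse(is.na(v), 0L, v)
}

# Parse one V2000 molblock (lines) into atoms (symbol, charge) and bonds
# (a, b, order, stereo). Field positions follow the fixed-width MDL layout.
parse_molblock <- function(block) {
  counts <- block[4L]
  n_atoms <- int3(counts, 1L, 3L)
  n_bonds <- int3(counts, 4L, 6L)
  atoms <- data.frame(symbol = character(0), charge = integer(0))
  bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0),
                      stereo = integer(0))
  if (n_atoms > 0L) {
    al <- block[4L + seq_len(n_atoms)]
    atoms <- data.frame(
      symbol = trimws(substr(al, 31L, 34L)),
      charge = unname(mdl_charge(int3(al, 37L, 39L))),
      stringsAsFactors = FALSE
    )
  }
  if (n_bonds > 0L) {
    bl <- block[4L + n_atoms + seq_len(n_bonds)]
    bonds <- data.frame(
      a = int3(bl, 1L, 3L), b = int3(bl, 4L, 6L),
      order = int3(bl, 7L, 9L), stereo = int3(bl, 10L, 12L)
    )
  }
  # explicit "M  CHG" property lines override the atom-block charge column
  chg <- grep("^M  CHG", block, value = TRUE)
  for (ln in chg) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]])
    k <- f[1L]
    for (j in seq_len(k)) {
      atoms$charge[f[2L * j]] <- f[2L * j + 1L]
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# Decode the MDL old-style charge column.
mdl_charge <- function(code) {
  v <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)[code + 1L]
  ifelse(is.na(v), 0L, v)
}

# Parse one MOL2 block into SYBYL atom types and bond types. Gives per-atom
# aromaticity (type suffix ".ar") and hybridization, which the MDL molblock
# (always Kekulé) cannot express.
parse_mol2 <- function(block) {
  sec <- function(tag) {
    i <- which(block == tag)
    if (!length(i)) return(character(0))
    j <- i + 1L
    ends <- which(startsWith(block, "@<TRIPOS>"))
    stop_at <- ends[ends > i]
    k <- if (length(stop_at)) min(stop_at) - 1L else length(block)
    if (j > k) return(character(0))
    block[j:k]
  }
  atom_lines <- sec("@<TRIPOS>ATOM")
  bond_lines <- sec("@<TRIPOS>BOND")
  atom_type <- vapply(strsplit(trimws(atom_lines), "\\s+"),
                      function(f) f[6L], "")
  bond_type <- vapply(strsplit(trimws(bond_lines), "\\s+"),
                      function(f) f[4L], "")
  list(atom_type = atom_type, bond_type = bond_type)
}
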