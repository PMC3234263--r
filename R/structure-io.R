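# Residue-level structure model built on top of bio3d's PDB reader.

# Standard amino acids plus common modified residues mapped to their parent
# type. Residues without a mapping are classified "other" and ignored
# downstream.
.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.aa_parent <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                HYP = "PRO", CSO = "CYS", PCA = "GLU")

# DNA residue names: modern two-letter codes and the legacy one-letter
# dialect used by older PDB files; RNA names are also treated as nucleic.
.nuc_names <- c("DA", "DC", "DG", "DT", "DI", "DU",
                "A", "C", "G", "T", "U", "I")

.classify_residue <- function(resname) {
  resname <- toupper(resname)
  cls <- rep("other", length(resname))
  cls[resname %in% names(.aa3) | resname %in% names(.aa_parent)] <- "protein"
  cls[resname %in% .nuc_names] <- "nucleic"
  cls[resname %in% c("HOH", "WAT", "DOD")] <- "other"
  cls
}

.parent_resname <- function(resname) {
  resname <- toupper(resname)
  mapped <- unname(.aa_parent[resname])
  ifelse(is.na(mapped), resname, mapped)
}

.residue_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, insert)
}

.element_from_name <- function(elety) {
  # PDB atom names start with the element; two-letter elements relevant to
  # proteins/DNA are rare beyond these.
  up <- toupper(trimws(elety))
  el <- substr(up, 1, 1)
  el[substr(up, 1, 2) %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE")] <-
    substr(up, 1, 2)[substr(up, 1, 2) %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE")]
  # Digit-leading hydrogen names such as 1HB
  el[grepl("^[0-9]", up)] <- substr(sub("^[0-9]+", "", up), 1, 1)
  el
}

#' Read a PDB-format structure
#'
#' Parses a PDB file (or in-memory PDB text) into a residue/atom model.
#' Only the first MODEL of multi-model files is used, the first alternate
#' location is kept per atom, hydrogens are retained but flagged non-heavy,
#' and residues are classified as protein, nucleic or other from their
#' residue name (modified amino acids with a standard parent, e.g. MSE, are
#' mapped to the parent type).
#'
#' @param x path to a PDB file, or a character vector of PDB-format lines.
#' @param id identifier stored on the returned structure; defaults to the
#'   file base name.
#' @return An object of class `dbp_structure`: a list with `id`, an `atoms`
#'   data frame (one row per atom: chain, resno, insert, resname, atom name,
#'   element, x/y/z, `is_heavy`) and a `residues` data frame (one row per
#'   residue: `key`, chain, resno, insert, resname, one-letter `aa`,
#'   `molecule_class`, `has_ca`).
#' @examples
#' pdb <- c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
#'   "END")
#' s <- read_structure(pdb, id = "toy")
#' s$residues
#' @export
read_structure <- function(x, id = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    path <- x
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(id)) id <- "structure"
  }
  raw <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", raw)
  if (!any(rec)) {
    first <- if (length(raw)) raw[[1]] else "<empty input>"
    stop("no ATOM/HETATM records found; first line was: ", first)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB input: ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  element <- trimws(at$elesy)
  bad <- is.na(element) | element == ""
  element[bad] <- .element_from_name(at$elety[bad])
  coord_ok <- is.finite(at$x) & is.finite(at$y) & is.finite(at$z)
  if (any(!coord_ok)) {
    stop("non-finite coordinates for atom serial ",
         at$eleno[which(!coord_ok)[1]])
  }
  chain <- ifelse(is.na(at$chain), "", at$chain)
  insert <- ifelse(is.na(at$insert), "", at$insert)
  atoms <- data.frame(
    chain = chain,
    resno = at$resno,
    insert = insert,
    resname = .parent_resname(at$resid),
    name = trimws(at$elety),
    element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  atoms$is_heavy <- atoms$element != "H" & atoms$element != "D"
  atoms$key <- .residue_key(atoms$chain, atoms$resno, atoms$insert)
  structure_from_atoms(atoms, id = id)
}

#' Build a structure object from an atom table
#'
#' Low-level constructor used by [read_structure()] and the synthetic
#' fixture generator. Residue classification and keys are derived from the
#' atom table; atom order within the table is preserved.
#'
#' @param atoms data frame with columns chain, resno, insert, resname, name,
#'   element, x, y, z (and optionally is_heavy, key).
#' @param id structure identifier.
#' @return A `dbp_structure` object.
#' @export
structure_from_atoms <- function(atoms, id = "structure") {
  stopifnot(all(c("chain", "resno", "resname", "name", "element",
                  "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$is_heavy))
    atoms$is_heavy <- !(toupper(atoms$element) %in% c("H", "D"))
  if (is.null(atoms$key))
    atoms$key <- .residue_key(atoms$chain, atoms$resno, atoms$insert)
  if (nrow(atoms) == 0) stop("atom table is empty")

  first <- !duplicated(atoms$key)
  res <- atoms[first, c("key", "chain", "resno", "insert", "resname")]
  rownames(res) <- NULL
  res$molecule_class <- .classify_residue(res$resname)
  res$aa <- unname(.aa3[res$resname])
  ca <- atoms$key[atoms$name == "CA" & atoms$element == "C"]
  res$has_ca <- res$key %in% ca
  # residue keys must be unique within a chain: guaranteed by construction
  # (key includes chain), but duplicated keys separated by other residues
  # indicate a malformed file.
  runs <- rle(atoms$key)$values
  if (anyDuplicated(runs))
    stop("residue key appears in two disjoint blocks: ",
         runs[duplicated(runs)][1])
  out <- list(id = id, atoms = atoms, residues = res)
  class(out) <- "dbp_structure"
  out
}

#' @export
print.dbp_structure <- function(x, ...) {
  cat("Structure", x$id, "\n")
  tab <- table(x$residues$chain, x$residues$molecule_class)
  for (ch in rownames(tab)) {
    cat(sprintf("  chain %-2s %s\n", ch,
                paste(sprintf("%s:%d", colnames(tab), tab[ch, ]),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Select one chain of a structure
#'
#' @param structure a `dbp_structure`.
#' @param chain_id chain identifier.
#' @return The residue table of that chain, in author (file) order.
#' @export
select_chain <- function(structure, chain_id) {
  stopifnot(inherits(structure, "dbp_structure"))
  avail <- unique(structure$residues$chain)
  if (!chain_id %in% avail) {
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(sort(avail), collapse = ", "))
  }
  res <- structure$residues[structure$residues$chain == chain_id, ]
  rownames(res) <- NULL
  res
}

# Atom table for a set of residue keys, optionally heavy atoms only.
.chain_atoms <- function(structure, keys, heavy_only = TRUE) {
  a <- structure$atoms[structure$atoms$key %in% keys, ]
  if (heavy_only) a <- a[a$is_heavy, ]
  a
}

# Named matrix of C-alpha coordinates for the protein residues of a chain.
.ca_coords <- function(structure, chain_id) {
  res <- select_chain(structure, chain_id)
  res <- res[res$molecule_class == "protein", ]
  a <- structure$atoms
  ca <- a[a$key %in% res$key & a$name == "CA" & a$element == "C", ]
  ca <- ca[!duplicated(ca$key), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$key
  # preserve author order
  m[res$key[res$key %in% rownames(m)], , drop = FALSE]
}

#' Write a structure as PDB-format text
#'
#' Emits ATOM records (fixed-column PDB dialect) for all atoms of the
#' structure, with TER records between chains. Coordinates are written at
#' 3 decimals, the PDB precision.
#'
#' @param structure a `dbp_structure`.
#' @param path optional output file; if `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the character vector
#'   of PDB lines.
#' @export
write_structure <- function(structure, path = NULL) {
  a <- structure$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, ]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      nm <- sub$name[i]
      # atom-name column convention: 1-letter elements start in column 14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, "", sub$resname[i], ch, sub$resno[i],
        ifelse(sub$insert[i] == "", " ", sub$insert[i]),
        sub$x[i], sub$y[i], sub$z[i], 1.00, 0.00, sub$element[i]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
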