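# PSI-BLAST ASCII PSSM input/output and logistic scaling.

# Column order of the log-odds block in PSI-BLAST -out_ascii_pssm output.
.pssm_cols <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the text matrix written by PSI-BLAST's `-out_ascii_pssm` option
#' and keeps the first block of 20 log-odds columns per residue.
#'
#' @param path path to the PSSM file, or a character vector of its lines.
#' @return Object of class `pssm`: a numeric matrix (residues x 20 amino
#'   acid types, PSI-BLAST column order) with the query sequence as a
#'   `sequence` attribute and `scaled = FALSE`.
#' @export
read_pssm <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D\\s+C", lines)
  if (!length(hdr)) stop("not a PSI-BLAST ASCII PSSM: header row not found")
  body <- lines[(hdr[1] + 1):length(lines)]
  rows <- grep("^\\s*\\d+\\s+[A-Z]\\s", body, value = TRUE)
  if (!length(rows)) stop("not a PSI-BLAST ASCII PSSM: no residue rows")
  parts <- strsplit(trimws(rows), "\\s+")
  seq_letters <- vapply(parts, `[`, character(1), 2)
  scores <- t(vapply(parts, function(p) {
    if (length(p) < 22)
      stop("malformed PSSM row (fewer than 20 score columns): ",
           paste(p, collapse = " "))
    as.numeric(p[3:22])
  }, numeric(20)))
  colnames(scores) <- .pssm_cols
  new_pssm(scores, seq_letters, scaled = FALSE)
}

#' Construct a PSSM object from a score matrix
#'
#' @param scores numeric matrix, residues x 20 (PSI-BLAST column order).
#' @param sequence one-letter codes, one per row.
#' @param scaled whether the scores are already logistic-scaled.
#' @return A `pssm` object.
#' @export
new_pssm <- function(scores, sequence, scaled = FALSE) {
  stopifnot(ncol(scores) == 20, nrow(scores) == length(sequence))
  colnames(scores) <- .pssm_cols
  structure(scores, sequence = sequence, scaled = scaled, class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM profile:", nrow(x), "residues x 20 columns",
      if (attr(x, "scaled")) "(logistic-scaled)" else "(raw log-odds)", "\n")
  invisible(x)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Emits the 20-column log-odds block in the `-out_ascii_pssm` dialect
#' (scores rounded to integers, as PSI-BLAST prints them).
#'
#' @param pssm a raw `pssm` object.
#' @param path output file.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"), !attr(pssm, "scaled"))
  seq_letters <- attr(pssm, "sequence")
  lines <- c("", "Last position-specific scoring matrix computed",
             paste0("            ", paste(sprintf("%3s", .pssm_cols),
                                          collapse = " ")))
  for (i in seq_len(nrow(pssm))) {
    lines <- c(lines, paste0(
      sprintf("%5d %s  ", i, seq_letters[i]),
      paste(sprintf("%3d", round(pssm[i, ])), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Logistic scaling of PSSM log-odds
#'
#' Maps every element through the standard logistic function
#' `1 / (1 + exp(-x))`, bringing the profile into (0, 1).
#'
#' @param pssm a `pssm` object (or plain matrix).
#' @return The scaled profile (class preserved, `scaled = TRUE`).
#' @export
scale_pssm <- function(pssm) {
  scaled <- 1 / (1 + exp(-unclass(pssm)))
  if (inherits(pssm, "pssm"))
    return(new_pssm(scaled, attr(pssm, "sequence"), scaled = TRUE))
  scaled
}

#' Align a PSSM to a chain's residues
#'
#' Checks that the profile covers the chain residue-for-residue (same
#' length, same one-letter amino-acid codes) and returns the score matrix
#' with residue keys as row names so that downstream feature code can look
#' rows up by residue.
#'
#' @param pssm a `pssm` object.
#' @param structure a `dbp_structure`.
#' @param chain_id protein chain the profile belongs to.
#' @return The score matrix with residue keys as row names (attributes
#'   preserved).
#' @export
align_pssm <- function(pssm, structure, chain_id) {
  res <- select_chain(structure, chain_id)
  res <- res[res$molecule_class == "protein", ]
  if (nrow(pssm) != nrow(res))
    stop("PSSM has ", nrow(pssm), " rows but chain ", chain_id,
         " has ", nrow(res), " protein residues")
  mism <- which(attr(pssm, "sequence") != res$aa)
  if (length(mism))
    stop("PSSM sequence disagrees with chain at position ", mism[1],
         ": profile ", attr(pssm, "sequence")[mism[1]],
         " vs residue ", res$resname[mism[1]], " (", res$key[mism[1]], ")")
  rownames(pssm) <- res$key
  pssm
}
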