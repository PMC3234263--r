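# Shrake-Rupley numerical accessible surface area.
#
# Open re-implementation of the NACCESS calculation: each heavy atom is
# covered with a deterministic quasi-uniform point lattice on its solvent-
# expanded sphere (radius + probe); points inside any neighboring expanded
# sphere are occluded; ASA = exposed fraction x expanded-sphere area.

# NACCESS-compatible van der Waals radii (Angstrom); atoms of elements not
# listed fall back to `default`.
.vdw_radii <- c(C = 1.76, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                SE = 1.90, default = 1.80)

.atom_radius <- function(element) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- .vdw_radii[["default"]]
  unname(r)
}

# Deterministic quasi-uniform unit-sphere lattice (golden-section spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Per-atom accessible area for a coordinate matrix (n x 3) with expanded
# radii `re` (vdW + probe). Returns a numeric vector of areas.
.shrake_rupley <- function(xyz, re, n_points) {
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  full <- 4 * pi * re^2
  if (n == 1) return(full)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    occ <- which(d2 < (re + re[i])^2 & seq_len(n) != i)
    if (length(occ) == 0) {
      area[i] <- full[i]
      next
    }
    sp <- pts * re[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    oc <- xyz[occ, , drop = FALSE]
    # squared distances: n_points x n_occ
    dd <- outer(rowSums(sp^2), rep(1, length(occ))) +
      outer(rep(1, n_points), rowSums(oc^2)) - 2 * (sp %*% t(oc))
    exposed <- rowSums(dd < outer(rep(1, n_points), re[occ]^2)) == 0
    area[i] <- full[i] * mean(exposed)
  }
  area
}

# Main-chain atom names; CA is deliberately counted with the side chain
# (side-chain areas here include the alpha carbon), and also with the main
# chain, so aa = mc + sc - asa(CA).
.mc_names <- c("N", "CA", "C", "O", "OXT")
.sc_excluded <- c("N", "C", "O", "OXT")

#' Residue accessible surface area (Shrake-Rupley)
#'
#' Computes numerical solvent-accessible surface area for the heavy atoms of
#' the protein residues of one chain, and aggregates per residue into five
#' components: all atoms (`aa_asa`), main chain (`mc_asa`; N, CA, C, O,
#' OXT), side chain (`sc_asa`; all other atoms plus the alpha carbon),
#' polar side chain (`ap_asa`; side-chain N and O atoms) and non-polar side
#' chain (`np_asa`; the rest of the side chain, alpha carbon included).
#' Because CA is counted in both the main-chain and side-chain components,
#' `aa_asa = mc_asa + sc_asa - ASA(CA)`, while `ap_asa + np_asa = sc_asa`
#' exactly.
#'
#' Only atoms of the selected chain occlude each other, so the chain is
#' annotated in isolation (bound and unbound forms of a protein get
#' identical surface annotation regardless of partners in the file).
#'
#' @param structure a `dbp_structure`.
#' @param chain_id chain to annotate.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points sphere points per atom; the default 960 keeps the
#'   numerical error well under 1 percent.
#' @param radii named vector of van der Waals radii by element; must contain
#'   a `default` entry.
#' @return Data frame with one row per protein residue: key, resno, insert,
#'   resname and the five ASA components in Angstrom squared. Residues with
#'   no heavy atoms are dropped with a warning.
#' @export
compute_asa <- function(structure, chain_id, probe_radius = 1.4,
                        n_points = 960, radii = .vdw_radii) {
  res <- select_chain(structure, chain_id)
  res <- res[res$molecule_class == "protein", ]
  if (nrow(res) == 0) stop("chain ", chain_id, " has no protein residues")
  atoms <- .chain_atoms(structure, res$key, heavy_only = TRUE)
  empty <- setdiff(res$key, unique(atoms$key))
  if (length(empty)) {
    warning("residues with no heavy atoms excluded: ",
            paste(empty, collapse = ", "))
    res <- res[!res$key %in% empty, ]
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- radii[atoms$element]
  r[is.na(r)] <- radii[["default"]]
  area <- .shrake_rupley(xyz, unname(r) + probe_radius, n_points)

  is_mc <- atoms$name %in% .mc_names
  is_sc <- !(atoms$name %in% .sc_excluded)
  is_polar <- atoms$element %in% c("N", "O")
  agg <- function(w) {
    v <- vapply(res$key, function(k)
      sum(area[atoms$key == k & w]), numeric(1))
    unname(v)
  }
  out <- data.frame(
    key = res$key, chain = res$chain, resno = res$resno,
    insert = res$insert, resname = res$resname,
    aa_asa = agg(rep(TRUE, nrow(atoms))),
    mc_asa = agg(is_mc),
    sc_asa = agg(is_sc),
    ap_asa = agg(is_sc & is_polar),
    np_asa = agg(is_sc & !is_polar),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# All-atom maximum ASA in an extended ALA-X-ALA tripeptide
# (Hubbard & Thornton reference values, as used by NACCESS).
.max_asa_aa <- c(
  ALA = 107.95, ARG = 238.76, ASN = 143.94, ASP = 140.39, CYS = 134.28,
  GLN = 178.50, GLU = 172.25, GLY = 80.10, HIS = 182.88, ILE = 175.12,
  LEU = 178.63, LYS = 200.81, MET = 194.15, PHE = 199.48, PRO = 136.13,
  SER = 116.50, THR = 139.27, TRP = 249.36, TYR = 212.76, VAL = 151.44)

#' Reference maximum accessible surface areas
#'
#' All-atom maximum ASA of each residue type in an extended ALA-X-ALA
#' tripeptide (Hubbard-Thornton reference values), used to convert absolute
#' ASA into relative solvent accessibility.
#'
#' @return Named numeric vector (Angstrom squared) over the 20 standard
#'   residue types.
#' @export
max_asa_reference <- function() .max_asa_aa

#' Relative solvent accessibility
#'
#' Divides each residue's all-atom ASA by its reference maximum in an
#' extended ALA-X-ALA tripeptide. Values may exceed 1 for distorted
#' conformations. Residue types absent from the reference table are skipped
#' with a warning (RSA set to `NA`).
#'
#' @param asa data frame from [compute_asa()].
#' @param max_asa_table named vector of per-type maxima; defaults to the
#'   bundled Hubbard-Thornton table.
#' @return The input with an `rsa` column appended.
#' @export
compute_rsa <- function(asa, max_asa_table = max_asa_reference()) {
  mx <- max_asa_table[asa$resname]
  if (anyNA(mx)) {
    warning("no reference maximum ASA for residue type(s): ",
            paste(unique(asa$resname[is.na(mx)]), collapse = ", "),
            "; RSA set to NA")
  }
  asa$rsa <- unname(asa$aa_asa / mx)
  asa
}

#' Flag surface residues
#'
#' A residue is a surface residue when its all-atom relative solvent
#' accessibility is at least `threshold` (default 10 percent, inclusive).
#'
#' @param annotation data frame with an `rsa` column.
#' @param threshold RSA threshold (fraction).
#' @return The input with a logical `is_surface` column appended; residues
#'   with `NA` RSA are not surface.
#' @export
annotate_surface <- function(annotation, threshold = 0.10) {
  annotation$is_surface <- !is.na(annotation$rsa) &
    annotation$rsa >= threshold
  annotation
}

#' Label DNA-binding residues of a protein-DNA complex
#'
#' A surface residue is labelled `binding` when any of its heavy atoms lies
#' within `cutoff` (default 4.5 Angstrom, inclusive) of any heavy atom of a
#' nucleic-acid residue in the structure; all other surface residues are
#' `nonbinding`, and buried residues are `not_surface`.
#'
#' @param structure the `dbp_structure` holding both protein and DNA.
#' @param chain_id protein chain being annotated.
#' @param annotation surface-flagged annotation for that chain
#'   (from [annotate_surface()]).
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return The annotation with a `binding_label` column
#'   (binding/nonbinding/not_surface).
#' @export
label_binding_residues <- function(structure, chain_id, annotation,
                                   cutoff = 4.5) {
  nuc_keys <- structure$residues$key[
    structure$residues$molecule_class == "nucleic"]
  annotation$binding_label <- ifelse(annotation$is_surface,
                                     "nonbinding", "not_surface")
  if (length(nuc_keys) == 0) {
    warning("no nucleic-acid residues in structure ", structure$id,
            "; all surface residues labelled nonbinding")
    return(annotation)
  }
  dna <- .chain_atoms(structure, nuc_keys, heavy_only = TRUE)
  dxyz <- as.matrix(dna[, c("x", "y", "z")])
  prot <- .chain_atoms(structure, annotation$key, heavy_only = TRUE)
  cut2 <- cutoff^2
  for (i in which(annotation$is_surface)) {
    p <- prot[prot$key == annotation$key[i], c("x", "y", "z")]
    p <- as.matrix(p)
    d2 <- outer(rowSums(p^2), rep(1, nrow(dxyz))) +
      outer(rep(1, nrow(p)), rowSums(dxyz^2)) - 2 * (p %*% t(dxyz))
    if (min(d2) <= cut2) annotation$binding_label[i] <- "binding"
  }
  annotation
}

#' Full surface annotation of one protein chain
#'
#' Convenience wrapper chaining [compute_asa()], [compute_rsa()],
#' [annotate_surface()] and [label_binding_residues()]. ASA is always
#' computed on the isolated protein chain; the binding labels use whatever
#' nucleic-acid residues the structure contains (none: all surface residues
#' nonbinding, with a warning unless `expect_dna = FALSE`).
#'
#' @param structure a `dbp_structure`.
#' @param chain_id protein chain to annotate.
#' @param rsa_threshold surface RSA threshold.
#' @param binding_cutoff heavy-atom binding cutoff in Angstrom.
#' @param expect_dna set `FALSE` to silence the missing-DNA warning when
#'   annotating an unbound structure.
#' @inheritParams compute_asa
#' @return Annotation data frame: residue identity, five ASA components,
#'   `rsa`, `is_surface`, `binding_label`.
#' @export
annotate_structure <- function(structure, chain_id, rsa_threshold = 0.10,
                               binding_cutoff = 4.5, probe_radius = 1.4,
                               n_points = 960, expect_dna = TRUE) {
  ann <- compute_asa(structure, chain_id, probe_radius = probe_radius,
                     n_points = n_points)
  ann <- compute_rsa(ann)
  ann <- annotate_surface(ann, threshold = rsa_threshold)
  has_dna <- any(structure$residues$molecule_class == "nucleic")
  if (!has_dna && !expect_dna) {
    ann$binding_label <- ifelse(ann$is_surface, "nonbinding", "not_surface")
    return(ann)
  }
  label_binding_residues(structure, chain_id, ann, cutoff = binding_cutoff)
}

#' Write an annotation table as TSV
#'
#' @param annotation annotation data frame.
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
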