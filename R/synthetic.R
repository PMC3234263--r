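# Synthetic protein-DNA fixtures: idealized helical chains with side-chain
# pseudo-atoms, DNA pseudo-residues planted at a controlled offset from a
# designated binding site, and synthetic PSSM profiles with a planted
# evolutionary signal at binding positions.

# side-chain reach (Angstrom from CA to the outermost pseudo-atom) by type;
# used both for geometry and for picking the DNA anchor atom.
.sc_reach <- c(GLY = 0, ALA = 1.5, SER = 2.5, CYS = 2.5, THR = 2.5,
               VAL = 2.5, PRO = 2.5, ASP = 3.5, ASN = 3.5, LEU = 3.5,
               ILE = 3.5, GLU = 4.5, GLN = 4.5, MET = 4.5, HIS = 4.5,
               PHE = 4.5, LYS = 5.5, ARG = 6.0, TYR = 5.5, TRP = 5.5)

.polar_tip <- c(SER = "OG", THR = "OG1", ASP = "OD1", ASN = "OD1",
                GLU = "OE1", GLN = "OE1", LYS = "NZ", ARG = "NH1",
                HIS = "ND1", TYR = "OH")

#' Specification of a synthetic protein-DNA fixture
#'
#' Collects the knobs of the generator: chain count and length, helix
#' geometry, binding-site size and placement, the offset of the DNA
#' pseudo-atoms from the binding residues (offsets below the 4.5 Angstrom
#' rule make the planted residues binding by construction), the effect size
#' of the planted PSSM signal, and the compositional bias of binding sites
#' toward basic residues.
#'
#' @param n_chains number of protein-DNA complexes in a dataset.
#' @param n_residues residues per protein chain.
#' @param binding_size number of planted binding residues per chain.
#' @param dna_offset distance (Angstrom) from a binding residue's outermost
#'   side-chain atom to its DNA pseudo-atom.
#' @param effect_size shift (in SD units) added to the signal PSSM columns
#'   at binding positions.
#' @param binding_bias probability that a planted binding residue is ARG or
#'   LYS (the remainder is drawn from the background composition).
#' @param rise,twist,radius helix geometry: rise per residue (Angstrom),
#'   twist per residue (degrees), C-alpha radius (Angstrom). Defaults are
#'   ideal alpha-helix values, giving realistic contact density at the
#'   8 Angstrom cutoff.
#' @param seed base seed; every derived random draw is a deterministic
#'   function of it.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chains = 20, n_residues = 60, binding_size = 8,
                         dna_offset = 3.0, effect_size = 1.5,
                         binding_bias = 0.6, rise = 1.5, twist = 100,
                         radius = 2.3, seed = 1) {
  stopifnot(n_chains >= 1, n_residues >= 10, binding_size >= 1,
            dna_offset > 0, binding_bias >= 0, binding_bias <= 1)
  out <- list(n_chains = n_chains, n_residues = n_residues,
              binding_size = binding_size, dna_offset = dna_offset,
              effect_size = effect_size, binding_bias = binding_bias,
              rise = rise, twist = twist, radius = radius, seed = seed)
  class(out) <- "fixture_spec"
  out
}

# binding positions on one helix face: alternate +3/+4 steps (period 3.5,
# close to the 3.6-residue helical repeat) starting near the chain middle.
.binding_positions <- function(n_residues, binding_size) {
  start <- max(3, floor(n_residues / 2) - 2 * binding_size)
  steps <- rep(c(3, 4), length.out = binding_size - 1)
  pos <- cumsum(c(start, steps))
  if (any(pos > n_residues - 2))
    stop("binding site does not fit on the chain; reduce binding_size")
  pos
}

#' Generate one synthetic protein-DNA complex
#'
#' Builds an idealized helical protein chain (chain A) with backbone atoms
#' N/CA/C/O and radially pointing side-chain pseudo-atoms (CB, CG, and a
#' polar tip atom for polar types), plus a DNA pseudo-chain (chain B) whose
#' residues carry two heavy pseudo-atoms (P, C1') placed `dna_offset`
#' Angstrom outside the outermost side-chain atom of each designated
#' binding residue. By construction, with `dna_offset < 4.5` exactly the
#' designated residues satisfy the heavy-atom binding rule; the generator
#' verifies this and errors if the geometry cannot honor it.
#'
#' @param spec a `fixture_spec`.
#' @param chain_index index of the chain within a dataset (shifts the
#'   derived seed so chains differ).
#' @return List with `structure` (a `dbp_structure`), `truth` (keys of the
#'   planted binding residues), `binding_positions` and `sequence`.
#' @export
generate_complex <- function(spec, chain_index = 1) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((spec$seed * 1009 + chain_index * 7919) %% .Machine$integer.max)

  n <- spec$n_residues
  bpos <- .binding_positions(n, spec$binding_size)
  types <- names(.aa3)
  seq3 <- sample(types, n, replace = TRUE)
  # planted binding residues carry side chains long enough (reach >= 2.5)
  # that their DNA pseudo-atoms clear the neighbors' backbones; a
  # binding_bias fraction are basic (ARG/LYS), as at real interfaces
  long_types <- names(.sc_reach)[.sc_reach >= 2.5]
  basic <- stats::runif(length(bpos)) < spec$binding_bias
  seq3[bpos] <- sample(long_types, length(bpos), replace = TRUE)
  seq3[bpos][basic] <- sample(c("ARG", "LYS"), sum(basic), replace = TRUE)

  theta <- (seq_len(n) - 1) * spec$twist * pi / 180
  z <- (seq_len(n) - 1) * spec$rise
  u <- cbind(cos(theta), sin(theta), 0)          # outward radial direction
  ca <- cbind(spec$radius * cos(theta), spec$radius * sin(theta), z)

  ch_v <- character(0); rn_v <- integer(0); rs_v <- character(0)
  nm_v <- character(0); el_v <- character(0)
  xyz_v <- vector("list", 0)
  add <- function(chain, resno, resname, name, element, xyz) {
    ch_v[[length(ch_v) + 1]] <<- chain
    rn_v[[length(rn_v) + 1]] <<- resno
    rs_v[[length(rs_v) + 1]] <<- resname
    nm_v[[length(nm_v) + 1]] <<- name
    el_v[[length(el_v) + 1]] <<- element
    xyz_v[[length(xyz_v) + 1]] <<- xyz
  }
  tangent <- function(i) {
    t <- c(-sin(theta[i]) * spec$radius * spec$twist * pi / 180,
           cos(theta[i]) * spec$radius * spec$twist * pi / 180, spec$rise)
    t / sqrt(sum(t^2))
  }
  for (i in seq_len(n)) {
    tg <- tangent(i)
    add("A", i, seq3[i], "N", "N", ca[i, ] - 1.2 * tg - 0.4 * u[i, ])
    add("A", i, seq3[i], "CA", "C", ca[i, ])
    add("A", i, seq3[i], "C", "C", ca[i, ] + 1.2 * tg - 0.4 * u[i, ])
    add("A", i, seq3[i], "O", "O", ca[i, ] + 1.4 * tg - 1.5 * u[i, ])
    reach <- .sc_reach[[seq3[i]]]
    tip <- .polar_tip[seq3[i]]
    if (reach >= 1.5) add("A", i, seq3[i], "CB", "C", ca[i, ] + 1.5 * u[i, ])
    if (reach >= 4.5) add("A", i, seq3[i], "CG", "C",
                          ca[i, ] + (1.5 + reach) / 2 * u[i, ])
    if (reach >= 2.5) {
      nm <- if (!is.na(tip)) tip else "CD"
      add("A", i, seq3[i], nm, substr(nm, 1, 1), ca[i, ] + reach * u[i, ])
    }
  }
  # DNA pseudo-residues, one per binding position
  dna_res <- c("DA", "DT")
  for (j in seq_along(bpos)) {
    i <- bpos[j]
    reach <- .sc_reach[[seq3[i]]]
    anchor <- ca[i, ] + reach * u[i, ]
    p <- anchor + spec$dna_offset * u[i, ]
    add("B", j, dna_res[(j %% 2) + 1], "P", "P", p)
    add("B", j, dna_res[(j %% 2) + 1], "C1'", "C", p + c(0, 0, 1.4))
  }
  xyz <- do.call(rbind, xyz_v)
  at <- data.frame(chain = ch_v, resno = rn_v, insert = "", resname = rs_v,
                   name = nm_v, element = el_v,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
  s <- structure_from_atoms(at, id = sprintf("synthetic_%03d", chain_index))

  # construction guarantees: no atom clashes, and the distance rule
  # recovers exactly the planted set
  prot <- at[at$chain == "A", c("x", "y", "z")]
  dmin <- min(stats::dist(as.matrix(prot)))
  if (dmin < 0.8) stop("geometrically impossible spec: atom clash (",
                       round(dmin, 2), " Angstrom)")
  truth_keys <- .residue_key("A", bpos, "")
  labelled <- .rule_binding_keys(s, cutoff = 4.5)
  if (spec$dna_offset < 4.5 && !setequal(labelled, truth_keys))
    stop("geometrically impossible spec: distance rule labels ",
         length(labelled), " residues, planted ", length(truth_keys),
         " (extra: ", paste(setdiff(labelled, truth_keys), collapse = ","),
         "; missing: ",
         paste(setdiff(truth_keys, labelled), collapse = ","), ")")
  list(structure = s, truth = truth_keys, binding_positions = bpos,
       sequence = unname(.aa3[seq3]))
}

# keys of protein residues with any heavy atom within cutoff of any
# nucleic heavy atom (label oracle used by the generator's self-check).
.rule_binding_keys <- function(structure, cutoff = 4.5) {
  res <- structure$residues
  dna <- .chain_atoms(structure, res$key[res$molecule_class == "nucleic"])
  if (!nrow(dna)) return(character(0))
  dxyz <- as.matrix(dna[, c("x", "y", "z")])
  prot_keys <- res$key[res$molecule_class == "protein"]
  hits <- vapply(prot_keys, function(k) {
    p <- as.matrix(.chain_atoms(structure, k)[, c("x", "y", "z")])
    d2 <- outer(rowSums(p^2), rep(1, nrow(dxyz))) +
      outer(rep(1, nrow(p)), rowSums(dxyz^2)) - 2 * (p %*% t(dxyz))
    min(d2) <= cutoff^2
  }, logical(1))
  prot_keys[hits]
}

#' Generate a synthetic PSSM with a planted signal
#'
#' Background log-odds are i.i.d. Normal(0, 1); at the designated signal
#' positions the chosen columns are shifted upward by `effect_size`
#' standard deviations.
#'
#' @param sequence one-letter residue codes of the chain.
#' @param signal_positions residue positions carrying the signal.
#' @param effect_size shift in SD units.
#' @param signal_cols PSSM columns receiving the shift (default the basic
#'   residues R and K, mimicking interface conservation of basic types).
#' @param seed seed.
#' @return A raw `pssm` object.
#' @export
generate_pssm <- function(sequence, signal_positions = integer(0),
                          effect_size = 1.5, signal_cols = c("R", "K"),
                          seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(sequence)
  m <- matrix(stats::rnorm(n * 20), n, 20,
              dimnames = list(NULL, .pssm_cols))
  m[signal_positions, signal_cols] <-
    m[signal_positions, signal_cols] + effect_size
  new_pssm(m, sequence, scaled = FALSE)
}

#' Generate and prepare a synthetic dataset
#'
#' Produces `n_chains` synthetic complexes with planted binding sites and
#' matching signal-bearing PSSMs, and runs [prepare_chain()] on each so the
#' result can go straight into [dbp_cv()].
#'
#' @param spec a `fixture_spec`.
#' @param L patch size used for preparation.
#' @param n_points Shrake-Rupley point density (the default is reduced
#'   relative to production annotation; the fixtures' surfaces are simple).
#' @param ... further arguments to [prepare_chain()].
#' @return Object of class `dbp_dataset`: list with `chains` (prepared
#'   `dbp_chain` objects) and `truth` (planted binding keys per chain).
#' @export
synthetic_dataset <- function(spec, L = 25, n_points = 240, ...) {
  stopifnot(inherits(spec, "fixture_spec"))
  chains <- vector("list", spec$n_chains)
  truth <- vector("list", spec$n_chains)
  for (i in seq_len(spec$n_chains)) {
    cx <- generate_complex(spec, chain_index = i)
    pssm <- generate_pssm(cx$sequence, cx$binding_positions,
                          effect_size = spec$effect_size,
                          seed = (spec$seed * 131 + i) %% .Machine$integer.max)
    chains[[i]] <- prepare_chain(cx$structure, "A", pssm, L = L,
                                 n_points = n_points, ...)
    truth[[i]] <- cx$truth
  }
  names(truth) <- vapply(chains, `[[`, character(1), "id")
  out <- list(chains = chains, truth = truth, spec = spec)
  class(out) <- "dbp_dataset"
  out
}

#' @export
print.dbp_dataset <- function(x, ...) {
  n_surf <- sum(vapply(x$chains, function(ch)
    sum(ch$annotation$is_surface), numeric(1)))
  n_bind <- sum(vapply(x$chains, function(ch)
    sum(ch$annotation$binding_label == "binding"), numeric(1)))
  cat(sprintf("Synthetic dataset: %d chains, %d surface residues (%d binding)\n",
              length(x$chains), n_surf, n_bind))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits the complex as PDB text, the profile in PSI-BLAST ASCII layout and
#' the ground-truth binding keys as TSV.
#'
#' @param complex result of [generate_complex()].
#' @param pssm matching raw `pssm`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(complex, pssm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- complex$structure$id
  paths <- c(pdb = file.path(dir, paste0(id, ".pdb")),
             pssm = file.path(dir, paste0(id, ".pssm")),
             truth = file.path(dir, paste0(id, "_truth.tsv")))
  write_structure(complex$structure, paths[["pdb"]])
  write_pssm(pssm, paths[["pssm"]])
  utils::write.table(data.frame(key = complex$truth),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
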