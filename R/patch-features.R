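# Surface patches, distance-dependent weighting, and the reduced weighted
# feature encodings (RW-PSSM, WIP, WBC, ScASA; C-PSSM for comparison).

#' Distance-dependent weighting factor
#'
#' Weight of a patch residue as a function of its C-alpha distance to the
#' central residue. Every scheme satisfies w(0) = 1 and decreases strictly
#' with distance:
#' \describe{
#'   \item{reciprocal}{`1 / (1 + d)` (default)}
#'   \item{exponential}{`exp(-d / sigma)`}
#'   \item{linear}{`max(1 - d / d_max, floor)` with a small positive floor
#'     so weights stay in (0, 1]}
#' }
#'
#' @param d distance(s) in Angstrom, non-negative.
#' @param scheme weighting function id.
#' @param sigma decay length of the exponential scheme (Angstrom).
#' @param d_max zero-crossing of the linear scheme (Angstrom).
#' @return Weights in (0, 1].
#' @export
weighting_factor <- function(d, scheme = c("reciprocal", "exponential",
                                           "linear"),
                             sigma = 5, d_max = 50) {
  scheme <- match.arg(scheme)
  if (any(d < 0)) stop("distances must be non-negative")
  switch(scheme,
         reciprocal = 1 / (1 + d),
         exponential = exp(-d / sigma),
         linear = pmax(1 - d / d_max, 1e-9))
}

#' Build a surface patch
#'
#' The patch of a central surface residue is the residue itself plus its
#' L-1 spatially nearest surface residues of the same chain, by C-alpha
#' distance (ascending; ties broken by ascending position in the chain).
#' When fewer than L surface residues exist, all of them are used.
#'
#' @param central residue key of the central residue; must be a surface
#'   residue.
#' @param surface_keys keys of all surface residues of the chain, in chain
#'   order.
#' @param ca_coords C-alpha coordinate matrix with residue keys as row
#'   names (must cover all surface residues).
#' @param L patch size (default 25).
#' @param scheme,sigma,d_max passed to [weighting_factor()].
#' @return Object of class `surface_patch`: `members` (keys, central
#'   first), `d` (distances, Angstrom) and `w` (weights).
#' @export
surface_patch <- function(central, surface_keys, ca_coords, L = 25,
                          scheme = "reciprocal", sigma = 5, d_max = 50) {
  if (!central %in% surface_keys)
    stop("central residue ", central, " is not a surface residue")
  stopifnot(all(surface_keys %in% rownames(ca_coords)), L >= 1)
  xyz <- ca_coords[surface_keys, , drop = FALSE]
  dc <- sqrt(rowSums((xyz - matrix(ca_coords[central, ], nrow(xyz), 3,
                                   byrow = TRUE))^2))
  ord <- order(dc, seq_along(surface_keys))
  take <- ord[seq_len(min(L, length(surface_keys)))]
  members <- surface_keys[take]
  d <- unname(dc[take])
  out <- list(central = central, members = members, d = d,
              w = weighting_factor(d, scheme, sigma = sigma, d_max = d_max))
  class(out) <- "surface_patch"
  out
}

#' Build patches for all surface residues of a chain
#'
#' @inheritParams surface_patch
#' @return Named list of `surface_patch` objects, one per surface residue.
#' @export
build_patches <- function(surface_keys, ca_coords, L = 25,
                          scheme = "reciprocal", sigma = 5, d_max = 50) {
  stats::setNames(lapply(surface_keys, surface_patch,
                         surface_keys = surface_keys, ca_coords = ca_coords,
                         L = L, scheme = scheme, sigma = sigma,
                         d_max = d_max),
                  surface_keys)
}

.patch_rows <- function(patch, profile) {
  missing <- setdiff(patch$members, rownames(profile))
  if (length(missing))
    stop("no PSSM row for patch residue(s): ",
         paste(missing, collapse = ", "))
  profile[patch$members, , drop = FALSE]
}

#' Reduced weighted PSSM encoding (40 values)
#'
#' First 20 values: the central residue's logistic-scaled PSSM row. Last 20:
#' for each amino-acid type, the weighted average of that PSSM column over
#' the patch's neighboring residues (central excluded; weights from the
#' patch's weighting factors, normalized by their sum). A patch with no
#' neighbors yields zeros in the second block, so the encoding length is
#' always 40 whatever the patch size.
#'
#' @param patch a `surface_patch`.
#' @param profile scaled PSSM matrix with residue keys as row names.
#' @return Named numeric vector of length 40 (`pssm_c_*` then `pssm_w_*`).
#' @export
rw_pssm <- function(patch, profile) {
  rows <- .patch_rows(patch, profile)
  central <- rows[1, ]
  if (nrow(rows) > 1) {
    w <- patch$w[-1]
    f <- colSums(rows[-1, , drop = FALSE] * w) / sum(w)
  } else {
    f <- stats::setNames(numeric(20), colnames(rows))
  }
  stats::setNames(c(central, f),
                  c(paste0("pssm_c_", colnames(rows)),
                    paste0("pssm_w_", colnames(rows))))
}

#' Concatenated PSSM encoding (L x 20 values)
#'
#' Scaled PSSM rows of all patch members concatenated in patch order
#' (central first, then neighbors by ascending distance); patches smaller
#' than `L` are zero-padded to length `L * 20`.
#'
#' @inheritParams rw_pssm
#' @param L nominal patch size defining the padded length.
#' @return Named numeric vector of length `L * 20`.
#' @export
c_pssm <- function(patch, profile, L = 25) {
  rows <- .patch_rows(patch, profile)
  v <- as.numeric(t(rows))
  out <- numeric(L * 20)
  out[seq_along(v)] <- v
  names(out) <- paste0("pssm_p", rep(seq_len(L), each = 20), "_",
                       rep(colnames(rows), L))
  out
}

#' Interface propensity table
#'
#' Log2 odds-ratio enrichment of each amino-acid type among DNA-binding vs
#' nonbinding surface residues, with a symmetric pseudocount:
#' `IP_a = log2( ((N_Ba + psi) / (N_B + 20 psi)) /
#'               ((N_NBa + psi) / (N_NB + 20 psi)) )`.
#' Positive values mark interface-enriched types; a type with equal binding
#' and nonbinding frequencies scores 0.
#'
#' @param resnames 3-letter residue names of labelled surface residues.
#' @param labels matching labels, `"binding"` or `"nonbinding"`.
#' @param pseudocount psi (default 1).
#' @return Object of class `propensity_table`: list with `ip` (named
#'   20-vector over residue types) and the underlying counts.
#' @export
interface_propensity <- function(resnames, labels, pseudocount = 1) {
  stopifnot(length(resnames) == length(labels))
  types <- names(.aa3)
  nb <- labels == "binding"
  nn <- labels == "nonbinding"
  if (!any(nb) || !any(nn))
    stop("need at least one binding and one nonbinding residue")
  n_ba <- vapply(types, function(t) sum(resnames == t & nb), numeric(1))
  n_nba <- vapply(types, function(t) sum(resnames == t & nn), numeric(1))
  n_b <- sum(nb); n_nb <- sum(nn)
  ip <- log2(((n_ba + pseudocount) / (n_b + 20 * pseudocount)) /
               ((n_nba + pseudocount) / (n_nb + 20 * pseudocount)))
  out <- list(ip = stats::setNames(ip, types),
              n_ba = n_ba, n_b = n_b, n_nba = n_nba, n_nb = n_nb,
              pseudocount = pseudocount)
  class(out) <- "propensity_table"
  out
}

#' @export
print.propensity_table <- function(x, ...) {
  cat("Interface propensity over", x$n_b, "binding /", x$n_nb,
      "nonbinding surface residues\n")
  print(round(sort(x$ip, decreasing = TRUE), 3))
  invisible(x)
}

#' Distance-weighted patch average of a per-residue scalar
#'
#' `sum(w_i x_i) / sum(w_i)` over all patch members, central residue
#' included. This single operation realizes the weighted average
#' betweenness centrality (WBC), weighted interface propensity (WIP) and
#' weighted side-chain ASA (WScASA), depending on which scalar is supplied.
#'
#' @param patch a `surface_patch`.
#' @param values named numeric vector covering all patch members.
#' @return The weighted average.
#' @export
patch_average <- function(patch, values) {
  missing <- setdiff(patch$members, names(values))
  if (length(missing))
    stop("no value for patch residue(s): ", paste(missing, collapse = ", "))
  x <- values[patch$members]
  sum(patch$w * x) / sum(patch$w)
}

#' Assemble per-residue feature vectors for one chain
#'
#' Builds the full reduced feature encoding for every surface residue of a
#' prepared chain: 40 RW-PSSM values, the weighted interface propensity
#' (WIP), the weighted betweenness centrality (WBC) and the central
#' residue's raw side-chain ASA (ScASA) — 43 values in total. The
#' `feature_set` argument drops blocks for ablation experiments, and
#' `encoding = "c"` swaps the 40-value RW-PSSM block for the concatenated
#' `L * 20` C-PSSM block.
#'
#' @param chain a `dbp_chain` from [prepare_chain()].
#' @param ip_table a `propensity_table` (required when `"wip"` is in the
#'   feature set).
#' @param encoding `"rw"` (reduced weighted) or `"c"` (concatenated).
#' @param feature_set subset of `c("pssm", "wip", "wbc", "scasa")`.
#' @return Numeric matrix, one row per surface residue (row names are
#'   residue keys).
#' @export
assemble_features <- function(chain, ip_table = NULL, encoding = c("rw", "c"),
                              feature_set = c("pssm", "wip", "wbc",
                                              "scasa")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(chain, "dbp_chain"))
  unknown <- setdiff(feature_set, c("pssm", "wip", "wbc", "scasa"))
  if (length(unknown)) stop("unknown feature block(s): ",
                            paste(unknown, collapse = ", "))
  surf <- chain$annotation[chain$annotation$is_surface, ]
  blocks <- list()
  if ("pssm" %in% feature_set) {
    enc_fun <- if (encoding == "rw") {
      function(p) rw_pssm(p, chain$pssm)
    } else {
      function(p) c_pssm(p, chain$pssm, L = chain$L)
    }
    blocks$pssm <- t(vapply(chain$patches[surf$key], enc_fun,
                            enc_fun(chain$patches[[surf$key[1]]])))
  }
  if ("wip" %in% feature_set) {
    if (is.null(ip_table)) stop("feature set includes WIP but no ",
                                "propensity table was supplied")
    ipv <- stats::setNames(ip_table$ip[surf$resname], surf$key)
    blocks$wip <- cbind(wip = vapply(chain$patches[surf$key],
                                     patch_average, numeric(1),
                                     values = ipv))
  }
  if ("wbc" %in% feature_set) {
    blocks$wbc <- cbind(wbc = vapply(chain$patches[surf$key],
                                     patch_average, numeric(1),
                                     values = chain$bc))
  }
  if ("scasa" %in% feature_set) {
    blocks$scasa <- cbind(sc_asa = surf$sc_asa)
  }
  m <- do.call(cbind, blocks)
  rownames(m) <- surf$key
  m
}

#' Prepare one chain for feature extraction
#'
#' Runs the label-independent part of the pipeline for a protein chain:
#' surface annotation (ASA, RSA, surface flag, binding label when DNA is
#' present), C-alpha contact graph and betweenness centrality over the
#' whole chain, logistic scaling and alignment of the PSSM, and surface
#' patches of size `L`. The result carries everything the per-fold feature
#' assembly needs; only the interface-propensity table (label-dependent) is
#' computed later.
#'
#' @param structure a `dbp_structure`.
#' @param chain_id protein chain to prepare.
#' @param pssm raw `pssm` for that chain.
#' @param L patch size.
#' @param scheme,sigma,d_max weighting scheme parameters.
#' @param contact_cutoff C-alpha contact cutoff (Angstrom).
#' @param rsa_threshold surface threshold.
#' @param binding_cutoff heavy-atom binding cutoff (Angstrom).
#' @param n_points Shrake-Rupley point density.
#' @param expect_dna passed to [annotate_structure()].
#' @return Object of class `dbp_chain` holding the annotation, scaled
#'   aligned PSSM, betweenness scores, patches and configuration.
#' @export
prepare_chain <- function(structure, chain_id, pssm, L = 25,
                          scheme = "reciprocal", sigma = 5, d_max = 50,
                          contact_cutoff = 8.0, rsa_threshold = 0.10,
                          binding_cutoff = 4.5, n_points = 960,
                          expect_dna = TRUE) {
  ann <- annotate_structure(structure, chain_id,
                            rsa_threshold = rsa_threshold,
                            binding_cutoff = binding_cutoff,
                            n_points = n_points, expect_dna = expect_dna)
  ca <- .ca_coords(structure, chain_id)
  graph <- contact_graph(ca, cutoff = contact_cutoff)
  bc <- betweenness_centrality(graph)
  sp <- align_pssm(scale_pssm(pssm), structure, chain_id)
  surf_keys <- ann$key[ann$is_surface]
  patches <- build_patches(surf_keys, ca, L = L, scheme = scheme,
                           sigma = sigma, d_max = d_max)
  out <- list(id = paste0(structure$id, "_", chain_id),
              chain_id = chain_id, annotation = ann, pssm = sp, bc = bc,
              ca = ca, graph = graph, patches = patches, L = L,
              scheme = scheme, sigma = sigma, d_max = d_max)
  class(out) <- "dbp_chain"
  out
}

#' Rebuild the surface patches of a prepared chain at a new size
#'
#' Cheap re-derivation used by the patch-size sweep: annotation, contact
#' graph and PSSM are reused; only the patches (and stored L) change.
#'
#' @param chain a `dbp_chain`.
#' @param L new patch size.
#' @return The chain with patches of size `L`.
#' @export
rebuild_patches <- function(chain, L) {
  stopifnot(inherits(chain, "dbp_chain"))
  surf_keys <- chain$annotation$key[chain$annotation$is_surface]
  chain$patches <- build_patches(surf_keys, chain$ca, L = L,
                                 scheme = chain$scheme, sigma = chain$sigma,
                                 d_max = chain$d_max)
  chain$L <- L
  chain
}

#' Write a feature matrix as TSV
#'
#' @param features matrix from [assemble_features()].
#' @param path output file; residue keys in the first column.
#' @export
write_features <- function(features, path) {
  df <- data.frame(key = rownames(features), features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
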