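# Surface patches, weighting factors, PSSM encodings, interface propensity
# and the assembled feature vector.

patch_coords <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * 3, 0, 25), n, 3)
  rownames(m) <- paste0("A:", seq_len(n))
  m
}

test_that("every weighting scheme is 1 at zero and strictly decreasing", {
  for (sch in c("reciprocal", "exponential", "linear")) {
    expect_equal(weighting_factor(0, sch), 1)
    d <- seq(0, 30, by = 0.5)
    w <- weighting_factor(d, sch)
    expect_true(all(diff(w) < 0))
    expect_true(all(w > 0 & w <= 1))
    expect_gt(weighting_factor(2, sch), weighting_factor(5, sch))
  }
  expect_equal(weighting_factor(3.8), 1 / 4.8)
  expect_error(weighting_factor(-1), "non-negative")
})

test_that("patches take the L nearest surface residues, ties by chain order", {
  xyz <- patch_coords(12, seed = 3)
  keys <- rownames(xyz)
  p <- surface_patch(keys[4], keys, xyz, L = 5)
  # brute-force: sort all distances to the central residue
  d <- sqrt(colSums((t(xyz) - xyz[4, ])^2))
  expect_equal(p$members, keys[order(d, seq_along(keys))][1:5])
  expect_equal(p$members[1], keys[4])
  expect_equal(p$d[1], 0)
  expect_equal(p$w[1], 1)
  expect_true(all(diff(p$d) >= 0))
  expect_true(all(diff(p$w) <= 0))

  # fewer surface residues than L: truncate
  small <- surface_patch(keys[1], keys[1:5], xyz[1:5, ], L = 25)
  expect_equal(length(small$members), 5)
  # L = 1: the central residue alone
  solo <- surface_patch(keys[1], keys, xyz, L = 1)
  expect_equal(solo$members, keys[1])
  expect_equal(solo$d, 0)
  expect_equal(solo$w, 1)

  # exact distance ties resolve by ascending position
  tie <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(-3, 0, 0))
  rownames(tie) <- paste0("A:", 1:4)
  pt <- surface_patch("A:1", rownames(tie), tie, L = 3)
  expect_equal(pt$members, c("A:1", "A:2", "A:3"))

  expect_error(surface_patch("A:99", keys, xyz), "not a surface residue")
})

test_that("logistic scaling maps log-odds into (0,1) symmetrically", {
  m <- matrix(c(0, 10, -3, 3), 2, 2)
  p <- new_pssm(cbind(m, matrix(0, 2, 18)), c("A", "R"))
  sp <- scale_pssm(p)
  expect_equal(unname(sp[1, 1]), 0.5)
  expect_gt(sp[2, 1], 0.9999)
  expect_equal(unname(sp[1, 2] + sp[2, 2]), 1.0)  # logistic(-3)+logistic(3)
  expect_true(all(sp > 0 & sp < 1))
  expect_true(attr(sp, "scaled"))
})

test_that("PSI-BLAST ASCII profiles round-trip through the writer", {
  set.seed(8)
  m <- matrix(sample(-8:10, 5 * 20, replace = TRUE), 5, 20)
  p <- new_pssm(m, c("M", "K", "R", "A", "Y"))
  path <- tempfile(fileext = ".pssm")
  write_pssm(p, path)
  p2 <- read_pssm(path)
  expect_equal(unclass(p2), unclass(p), ignore_attr = TRUE)
  expect_equal(attr(p2, "sequence"), attr(p, "sequence"))
})

test_that("PSSM alignment enforces sequence agreement with the chain", {
  s <- read_structure(poly_ala_pdb(3))
  good <- new_pssm(matrix(0, 3, 20), c("A", "A", "A"))
  aligned <- align_pssm(good, s, "A")
  expect_equal(rownames(aligned), paste0("A:", 1:3))
  bad <- new_pssm(matrix(0, 3, 20), c("A", "K", "A"))
  expect_error(align_pssm(bad, s, "A"), "position 2")
  short <- new_pssm(matrix(0, 2, 20), c("A", "A"))
  expect_error(align_pssm(short, s, "A"), "2 rows")
})

test_that("the reduced weighted PSSM has 40 values whatever the patch size", {
  xyz <- patch_coords(40, seed = 9)
  keys <- rownames(xyz)
  profile <- matrix(runif(40 * 20), 40, 20,
                    dimnames = list(keys, pdnabind:::.pssm_cols))
  for (L in c(1, 5, 25, 35)) {
    p <- surface_patch(keys[2], keys, xyz, L = L)
    v <- rw_pssm(p, profile)
    expect_length(v, 40)
  }
  # no neighbors: weighted block is all zero
  v1 <- rw_pssm(surface_patch(keys[2], keys, xyz, L = 1), profile)
  expect_equal(unname(v1[21:40]), rep(0, 20))
  expect_equal(unname(v1[1:20]), unname(profile[keys[2], ]))
})

test_that("the weighted PSSM average is a true weighted mean over neighbors", {
  # constant profile: every weighted average equals the constant
  xyz <- patch_coords(10, seed = 12)
  keys <- rownames(xyz)
  const <- matrix(0.5, 10, 20, dimnames = list(keys, pdnabind:::.pssm_cols))
  p <- surface_patch(keys[1], keys, xyz, L = 6)
  expect_equal(unname(rw_pssm(p, const)[21:40]), rep(0.5, 20))

  # five-residue patch with a hand-made profile: explicit arithmetic check
  hand <- matrix(seq(0.01, 1, length.out = 5 * 20), 5, 20,
                 dimnames = list(keys[1:5], pdnabind:::.pssm_cols))
  p5 <- surface_patch(keys[1], keys[1:5], xyz[1:5, ], L = 5)
  v <- rw_pssm(p5, hand)
  w <- p5$w[-1]
  rows <- hand[p5$members[-1], ]
  manual <- apply(rows, 2, function(col) sum(w * col) / sum(w))
  expect_equal(unname(v[21:40]), unname(manual))
  # weighted averages stay inside the value range
  expect_true(all(v[21:40] >= apply(rows, 2, min) - 1e-12))
  expect_true(all(v[21:40] <= apply(rows, 2, max) + 1e-12))
})

test_that("the concatenated PSSM is L x 20 in distance order with zero padding", {
  xyz <- patch_coords(30, seed = 4)
  keys <- rownames(xyz)
  profile <- matrix(runif(30 * 20), 30, 20,
                    dimnames = list(keys, pdnabind:::.pssm_cols))
  p <- surface_patch(keys[1], keys, xyz, L = 25)
  expect_length(c_pssm(p, profile, L = 25), 500)
  p1 <- surface_patch(keys[1], keys, xyz, L = 1)
  expect_equal(unname(c_pssm(p1, profile, L = 1)),
               unname(profile[keys[1], ]))
  p5 <- surface_patch(keys[3], keys, xyz, L = 5)
  v <- c_pssm(p5, profile, L = 5)
  expect_equal(unname(v), as.numeric(t(profile[p5$members, ])))
  # truncated patch zero-pads
  ptr <- surface_patch(keys[1], keys[1:3], xyz[1:3, ], L = 5)
  vtr <- c_pssm(ptr, profile, L = 5)
  expect_length(vtr, 100)
  expect_equal(unname(vtr[61:100]), rep(0, 40))
})

test_that("rw_pssm errors when a patch member lacks a profile row", {
  xyz <- patch_coords(5, seed = 2)
  keys <- rownames(xyz)
  profile <- matrix(0.5, 4, 20, dimnames = list(keys[1:4],
                                                pdnabind:::.pssm_cols))
  p <- surface_patch(keys[1], keys, xyz, L = 5)
  expect_error(rw_pssm(p, profile), "A:5")
})

test_that("interface propensity is a centered log2 enrichment", {
  # equal frequencies in both classes: IP 0 for that type
  resnames <- c(rep("ALA", 40), rep("ARG", 40))
  labels <- rep(c("binding", "nonbinding"), 40)
  ip <- interface_propensity(resnames, labels)
  expect_equal(unname(ip$ip[c("ALA", "ARG")]), c(0, 0))

  # a type twice as frequent among binding residues: IP close to 1
  resnames2 <- c(rep("ARG", 4000), rep("ALA", 6000),
                 rep("ARG", 2000), rep("ALA", 8000))
  labels2 <- c(rep("binding", 10000), rep("nonbinding", 10000))
  ip2 <- interface_propensity(resnames2, labels2)
  expect_equal(unname(ip2$ip["ARG"]), 1, tolerance = 0.01)
  expect_gt(ip2$ip["ARG"], 0)
  expect_lt(ip2$ip["ALA"], 0)

  # swapping the labels negates every propensity (symmetric pseudocount)
  swapped <- ifelse(labels2 == "binding", "nonbinding", "binding")
  ip_sw <- interface_propensity(resnames2, swapped)
  expect_equal(unname(ip_sw$ip), unname(-ip2$ip), tolerance = 1e-12)

  expect_error(interface_propensity("ALA", "binding"), "nonbinding")
})

test_that("the weighted patch average interpolates its inputs", {
  xyz <- patch_coords(8, seed = 21)
  keys <- rownames(xyz)
  p <- surface_patch(keys[2], keys, xyz, L = 5)
  const <- setNames(rep(3.3, 8), keys)
  expect_equal(patch_average(p, const), 3.3)

  vals <- setNames(runif(8), keys)
  manual <- sum(p$w * vals[p$members]) / sum(p$w)
  expect_equal(patch_average(p, vals), manual)
  expect_gte(patch_average(p, vals), min(vals[p$members]))
  expect_lte(patch_average(p, vals), max(vals[p$members]))

  solo <- surface_patch(keys[1], keys, xyz, L = 1)
  expect_equal(patch_average(solo, vals), unname(vals[keys[1]]))

  # constant weights reduce to the arithmetic mean
  p_eq <- p; p_eq$w <- rep(1, length(p$w))
  expect_equal(patch_average(p_eq, vals), mean(vals[p$members]))

  dropped <- p$members[2]
  expect_error(patch_average(p, vals[names(vals) != dropped]), dropped,
               fixed = TRUE)
})

test_that("the assembled feature vector is 43-dimensional with named blocks", {
  ds <- small_dataset(n_chains = 2, seed = 31)
  ch <- ds$chains[[1]]
  surf <- ch$annotation[ch$annotation$is_surface, ]
  ip <- interface_propensity(surf$resname, surf$binding_label)
  full <- assemble_features(ch, ip)
  expect_equal(ncol(full), 43)
  expect_equal(colnames(full)[41:43], c("wip", "wbc", "sc_asa"))

  # leave-one-out block arithmetic
  expect_equal(ncol(assemble_features(ch, ip,
                                      feature_set = c("wip", "wbc", "scasa"))), 3)
  expect_equal(ncol(assemble_features(ch, ip,
                                      feature_set = c("pssm", "wbc", "scasa"))), 42)
  expect_equal(ncol(assemble_features(ch, ip,
                                      feature_set = c("pssm", "wip", "scasa"))), 42)
  expect_equal(ncol(assemble_features(ch, ip,
                                      feature_set = c("pssm", "wip", "wbc"))), 42)
  # C-PSSM encoding: 20 L + 3
  expect_equal(ncol(assemble_features(ch, ip, encoding = "c")),
               20 * ch$L + 3)
  # determinism
  expect_identical(full, assemble_features(ch, ip))
  expect_error(assemble_features(ch, NULL), "propensity")
})
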