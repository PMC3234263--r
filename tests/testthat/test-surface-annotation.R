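# Shrake-Rupley ASA, relative accessibility, surface flags, binding labels.

single_atom_structure <- function() {
  # one GLY represented by a single carbon: nothing occludes it
  read_structure(c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
                   "END"))
}

test_that("an unoccluded atom gets its full expanded-sphere area", {
  s <- single_atom_structure()
  asa <- compute_asa(s, "A")
  expect_equal(asa$aa_asa, 4 * pi * (1.76 + 1.4)^2, tolerance = 1e-12)
})

test_that("numerical ASA matches a dense brute-force reference within 1%", {
  s <- read_structure(poly_ala_pdb(2))
  atoms <- s$atoms[s$atoms$is_heavy, ]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- c(C = 1.76, N = 1.65, O = 1.40)[atoms$element]
  ref <- brute_force_asa(xyz, unname(radii), n_points = 4800)
  asa <- compute_asa(s, "A", n_points = 960)
  per_res <- vapply(unique(atoms$key), function(k)
    sum(ref[atoms$key == k]), numeric(1))
  expect_equal(asa$aa_asa, unname(per_res[asa$key]), tolerance = 0.01)
})

test_that("residues far apart do not occlude each other", {
  one <- poly_ala_pdb(1)
  far <- pdb_atom_line(10, "CA", "GLY", "A", 2, 100, 0, 0, "C")
  s_pair <- read_structure(c(one[one != "END"], far, "END"))
  s_one <- read_structure(one)
  a_pair <- compute_asa(s_pair, "A")
  a_one <- compute_asa(s_one, "A")
  expect_equal(a_pair$aa_asa[1], a_one$aa_asa[1], tolerance = 1e-6)
})

test_that("a residue buried in a dense cage has zero ASA", {
  lines <- pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C")
  pts <- 300
  i <- seq_len(pts) - 0.5
  phi <- acos(1 - 2 * i / pts); th <- pi * (1 + sqrt(5)) * i
  cage <- vapply(seq_len(pts), function(j)
    pdb_atom_line(j + 1, "CA", "GLY", "A", j + 1,
                  5 * sin(phi[j]) * cos(th[j]), 5 * sin(phi[j]) * sin(th[j]),
                  5 * cos(phi[j]), "C"), character(1))
  s <- read_structure(c(lines, cage, "END"))
  asa <- compute_asa(s, "A", n_points = 960)
  expect_equal(asa$aa_asa[asa$resno == 1], 0)
})

test_that("ASA converges in point density and occlusion is monotone", {
  spec <- fixture_spec(n_chains = 1, n_residues = 15, binding_size = 2,
                       seed = 5)
  s <- generate_complex(spec)$structure
  a1 <- compute_asa(s, "A", n_points = 960)
  a2 <- compute_asa(s, "A", n_points = 1920)
  expect_lt(max(abs(a1$aa_asa - a2$aa_asa) / pmax(a2$aa_asa, 1)), 0.01)

  # adding atoms to the chain never increases an existing residue's ASA
  extra <- s$atoms[1, ]
  extra$resno <- 999L; extra$name <- "CA"; extra$element <- "C"
  extra$resname <- "GLY"
  extra$x <- s$atoms$x[1] + 2.5
  extra$key <- "A:999"
  s_more <- structure_from_atoms(rbind(s$atoms, extra), id = "more")
  a3 <- compute_asa(s_more, "A", n_points = 960)
  a3 <- a3[match(a1$key, a3$key), ]
  expect_true(all(a3$aa_asa <= a1$aa_asa + 1e-9))
})

test_that("ASA components are consistent", {
  spec <- fixture_spec(n_chains = 1, n_residues = 15, binding_size = 2,
                       seed = 6)
  s <- generate_complex(spec)$structure
  asa <- compute_asa(s, "A", n_points = 240)
  expect_true(all(asa[, c("aa_asa", "mc_asa", "sc_asa", "ap_asa",
                          "np_asa")] >= 0))
  # polar + nonpolar side chain partition the side chain exactly
  expect_equal(asa$ap_asa + asa$np_asa, asa$sc_asa, tolerance = 1e-6)
  # CA is counted in both mc and sc: aa <= mc + sc, with equality only if
  # the alpha carbon is fully buried
  expect_true(all(asa$aa_asa <= asa$mc_asa + asa$sc_asa + 1e-9))
})

test_that("RSA is ASA over the tabulated tripeptide maximum", {
  asa <- data.frame(key = "A:1", resname = "GLY", aa_asa = 40.05)
  r <- compute_rsa(asa)
  expect_equal(r$rsa, 40.05 / max_asa_reference()[["GLY"]])
  asa2 <- data.frame(key = "A:1", resname = "ALA", aa_asa = 0)
  expect_equal(compute_rsa(asa2)$rsa, 0)
  asa3 <- data.frame(key = "A:1", resname = "XYZ", aa_asa = 10)
  expect_warning(r3 <- compute_rsa(asa3), "XYZ")
  expect_true(is.na(r3$rsa))
})

test_that("the 10% surface threshold is inclusive", {
  ann <- data.frame(rsa = c(0.10, 0.0999, 0, 0.5))
  ann <- annotate_surface(ann)
  expect_equal(ann$is_surface, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("the 4.5 Angstrom heavy-atom rule is inclusive and partitions the surface", {
  # one surface residue with a DNA pseudo-atom at a controlled distance
  mk <- function(d) {
    lines <- c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
               pdb_atom_line(2, "P", "DA", "B", 1, d, 0, 0, "P"),
               "END")
    read_structure(lines)
  }
  ann <- data.frame(key = "A:1", resname = "GLY", rsa = 0.9,
                    is_surface = TRUE)
  lab_in <- label_binding_residues(mk(4.4), "A", ann)
  lab_out <- label_binding_residues(mk(4.6), "A", ann)
  expect_equal(lab_in$binding_label, "binding")
  expect_equal(lab_out$binding_label, "nonbinding")

  # full annotation: binding + nonbinding = surface, disjoint by construction
  spec <- fixture_spec(n_chains = 1, n_residues = 25, binding_size = 4,
                       seed = 2)
  cx <- generate_complex(spec)
  full <- annotate_structure(cx$structure, "A", n_points = 240)
  expect_equal(sum(full$binding_label %in% c("binding", "nonbinding")),
               sum(full$is_surface))
  expect_true(all(full$binding_label[!full$is_surface] == "not_surface"))
})

test_that("a structure without DNA yields all-nonbinding surface with a warning", {
  s <- read_structure(poly_ala_pdb(3))
  ann <- compute_rsa(compute_asa(s, "A", n_points = 240))
  ann <- annotate_surface(ann)
  expect_warning(lab <- label_binding_residues(s, "A", ann), "nucleic")
  expect_true(all(lab$binding_label[lab$is_surface] == "nonbinding"))
})
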