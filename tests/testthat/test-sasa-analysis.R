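iso_atoms <- function(elements, coords) {
  at <- data.frame(name = elements, resname = "ALA", chain = "A",
                   resno = seq_along(elements), ins = " ", occ = 1, bfactor = 0,
                   element = elements, vdw = helixptm:::vdw_radius_of(elements),
                   stringsAsFactors = FALSE)
  helixptm:::new_structure("iso", at, list(coords))
}

test_that("isolated spheres reproduce the closed form for every element", {
  for (el in c("C", "N", "O", "S", "P")) {
    s <- iso_atoms(el, matrix(0, 1, 3))
    r <- helixptm:::vdw_radius_of(el) + 1.4
    expect_equal(sasa(s)$total, 4 * pi * r^2, tolerance = 0.005)
  }
  # two atoms beyond occlusion range are both fully exposed
  s2 <- iso_atoms(c("C", "C"), rbind(c(0, 0, 0), c(10, 0, 0)))
  rep2 <- sasa(s2)
  expect_equal(rep2$per_atom, rep(4 * pi * 3.1^2, 2), tolerance = 0.005)
  # coincident atoms are rejected
  s0 <- iso_atoms(c("C", "C"), matrix(0, 2, 3))
  expect_error(sasa(s0), "overlapping")
})

test_that("additivity and burial monotonicity hold", {
  tp <- toy_protein("hlh_contact")
  rep <- sasa(tp)
  expect_equal(sum(rep$per_residue$area), rep$total, tolerance = 1e-9)
  expect_equal(sum(rep$per_atom, na.rm = TRUE), rep$total, tolerance = 1e-9)
  expect_true(all(rep$per_atom >= 0, na.rm = TRUE))

  # adding a neighbour never increases another atom's area
  set.seed(9)
  base <- matrix(rnorm(30, sd = 2.5), 10, 3)
  s1 <- iso_atoms(rep("C", 10), base)
  s2 <- iso_atoms(rep("C", 11), rbind(base, base[1, ] + c(2.2, 0, 0)))
  a1 <- sasa(s1)$per_atom
  a2 <- sasa(s2)$per_atom[1:10]
  expect_true(all(a2 <= a1 + 1e-9))
})

test_that("960-point SASA agrees with a dense-sampling oracle on clusters", {
  set.seed(31)
  for (k in 1:3) {
    n <- 20
    coords <- matrix(rnorm(3 * n, sd = 3), n, 3)
    # enforce minimum separation to avoid coincident centres
    ok <- !any(dist(coords) < 0.5)
    while (!ok) {
      coords <- matrix(rnorm(3 * n, sd = 3), n, 3)
      ok <- !any(dist(coords) < 0.5)
    }
    els <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
    s <- iso_atoms(els, coords)
    fast <- sasa(s, n_points = 960)$total
    dense <- sasa(s, n_points = 1e5)$total
    expect_equal(fast, dense, tolerance = 0.01)
  }
})

test_that("active environment excludes the target and respects epsilon", {
  # single free residue: no other residues, empty membership
  p <- build_peptide("AASAA")
  single <- helixptm:::new_structure("ser", p$atoms[helixptm:::residue_atom_rows(p, "A", 2), ],
                                     list(model_xyz(p)[helixptm:::residue_atom_rows(p, "A", 2), ]))
  mod <- apply_ptm(single, "A", 0, "PHOSPHO_S")
  ae <- active_environment(single, mod, "A", 0)
  expect_equal(nrow(ae), 0)

  # unchanged structure: empty membership
  tp <- toy_protein("hlh_contact")
  ae0 <- active_environment(tp, tp, "A", 7)
  expect_equal(nrow(ae0), 0)

  # packed interface: non-empty, target excluded, all deltas above epsilon
  seq32 <- paste0(strrep("A", 7), "K", strrep("A", 24))
  tpk <- toy_protein("hlh_contact", sequence = seq32)
  modk <- apply_ptm(tpk, "A", 7, "ACETYL_K")
  ae <- active_environment(tpk, modk, "A", 7)
  expect_gt(nrow(ae), 0)
  expect_false(any(ae$resno == 8))  # the PTM residue itself (author number 8)
  expect_true(all(abs(ae$delta) > attr(ae, "epsilon")))

  # topology mismatch beyond the moiety is an error
  other <- apply_ptm(tpk, "A", 2, "NTERM_ACETYL")
  expect_error(active_environment(tpk, apply_ptm(other, "A", 7, "ACETYL_K"), "A", 7),
               "beyond the modification")
})

test_that("survey averages occurrences and structures correctly", {
  seq32 <- paste0(strrep("A", 7), "K", strrep("A", 24))
  tpk <- toy_protein("hlh_contact", sequence = seq32)
  ann <- "AAAAAAA-AC(K)-AAAA"
  one <- survey(list(tpk), ann, gene = "TOY")
  expect_equal(one$n_prot, 1)
  three <- survey(list(tpk, tpk, tpk), ann, gene = "TOY")
  expect_equal(three$n_prot, 3)
  for (k in c("VN", "VM", "UN", "UM")) {
    expect_equal(three[[k]], one[[k]], tolerance = 1e-9)
  }
  expect_gt(one$VM, one$VN)
  expect_equal(one$loc, "K8")
  expect_error(survey(list(tpk), "WWW-AC(K)-WWW"), "not found")
})
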