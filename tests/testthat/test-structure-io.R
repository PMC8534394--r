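test_that("PDB write/read round trip preserves topology and coordinates", {
  tp <- toy_protein("hlh_contact")
  txt <- write_pdb(tp)
  tp2 <- read_pdb(paste(txt, collapse = "\n"), id = tp$id)
  expect_equal(nrow(tp2$atoms), nrow(tp$atoms))
  expect_equal(tp2$atoms$name, tp$atoms$name)
  expect_lt(max(abs(model_xyz(tp2) - model_xyz(tp))), 1e-3)

  # multi-model round trip keeps all frames
  tr <- perturb_trajectory(build_ideal_helix(8), n_frames = 3, sigma = 0.1)
  txt <- write_pdb(tr)
  expect_equal(sum(grepl("^MODEL", txt)), 3)
  tr2 <- read_pdb(paste(txt, collapse = "\n"))
  expect_equal(n_models(tr2), 3)
  for (m in 1:3) expect_lt(max(abs(model_xyz(tr2, m) - model_xyz(tr, m))), 1e-3)
})

test_that("parser matches an independent PDB reader on a real structure", {
  skip_if_not_installed("bio3d")
  f <- system.file("examples", "1hel.pdb", package = "bio3d")
  s <- read_pdb(f)
  p <- bio3d::read.pdb(f, verbose = FALSE)
  ca1 <- model_xyz(s)[s$atoms$name == "CA", ]
  idx <- which(p$atom$elety == "CA" & p$atom$type == "ATOM")
  ca2 <- cbind(p$atom$x[idx], p$atom$y[idx], p$atom$z[idx])
  expect_equal(nrow(ca1), nrow(ca2))
  expect_lt(max(abs(ca1 - ca2)), 1e-9)
})

test_that("parse errors are informative and empty structures rejected", {
  bad <- c("ATOM      1  N   ALA A   1      abc.000   0.000   0.000  1.00  0.00           N")
  expect_error(read_pdb(paste(bad, collapse = "\n")), "line 1")
  expect_error(read_pdb("REMARK nothing here\nEND"), "empty structure")
  s <- toy_protein("single_helix")
  s$xyz <- list()
  expect_error(write_pdb(s), "empty model")
})

test_that("altloc conformers collapse to highest occupancy", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- read_pdb(paste(lines, collapse = "\n"))
  expect_equal(sum(s$atoms$name == "CA"), 1)
  expect_equal(model_xyz(s)[s$atoms$name == "CA", 1], 2.0)  # occupancy 0.60 wins
})

test_that("chain_sequence maps residues and handles MSE", {
  s <- build_peptide("AGK")
  expect_equal(chain_sequence(s, "A"), "AGK")
  expect_error(chain_sequence(s, "Z"), "no such chain")
  s$atoms$resname[s$atoms$resno == 2] <- "MSE"
  expect_equal(chain_sequence(s, "A"), "AMK")
  expect_equal(chain_sequence(s, "A", mse_as_met = FALSE), "AXK")
})

test_that("find_peptide locates exact occurrences and maps back to the query", {
  s <- build_peptide("AGK")
  hit <- find_peptide(s, "AGK")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 3L)
  expect_equal(nrow(find_peptide(s, "WWW")), 0)
  expect_error(find_peptide(s, "AG"), "at least 3")

  seq32 <- paste0(strrep("A", 4), "KYKYK", strrep("A", 23))
  tp <- toy_protein("hlh_contact", sequence = seq32)
  for (q in c("KYKYK", "AKY", "YKA")) {
    for (h in seq_len(nrow(find_peptide(tp, q)))) {
      hit <- find_peptide(tp, q)[h, ]
      sub <- substr(chain_sequence(tp, hit$chain), hit$start + 1, hit$end)
      expect_equal(sub, q)
    }
  }
})

test_that("hydrogens and waters are discarded on input", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  HA  ALA A   1       1.500   1.000   0.000  1.00  0.00           H",
    "ATOM      4  C   ALA A   1       2.500   1.000   0.000  1.00  0.00           C",
    "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END")
  s <- read_pdb(paste(lines, collapse = "\n"))
  expect_equal(nrow(s$atoms), 3)
  expect_false(any(s$atoms$element == "H"))
  expect_false(any(s$atoms$resname == "HOH"))
})
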