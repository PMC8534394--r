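test_that("amide hydrogens are placed at 1.0 A on non-proline residues", {
  h <- build_ideal_helix(12)
  hp <- place_amide_hydrogens(h)
  rt <- residue_table(hp)
  xyz <- model_xyz(hp)
  for (i in seq_len(nrow(rt))) {
    idx <- seq.int(rt$first[i], rt$last[i])
    nh <- idx[hp$atoms$name[idx] == "H"]
    if (i == 1) {
      expect_length(nh, 0)
    } else {
      expect_length(nh, 1)
      nn <- idx[hp$atoms$name[idx] == "N"]
      expect_equal(sqrt(sum((xyz[nh, ] - xyz[nn, ])^2)), 1.0, tolerance = 1e-9)
    }
  }
  # prolines get no H
  p <- build_peptide("AAPAA")
  pp <- place_amide_hydrogens(p)
  rt <- residue_table(pp)
  pro <- which(rt$resname == "PRO")
  idx <- seq.int(rt$first[pro], rt$last[pro])
  expect_false(any(pp$atoms$name[idx] == "H"))
})

test_that("Kabsch-Sander energy is symmetric and guards clashes", {
  # C and O on the N-H perpendicular bisector plane: r_ON = r_OH and
  # r_CH = r_CN, so the electrostatic term vanishes
  donor <- list(N = c(0, 0, 0), H = c(1, 0, 0))
  acceptor <- list(C = c(0.5, 3, 0), O = c(0.5, 4, 0))
  expect_equal(hbond_energy(donor, acceptor), 0, tolerance = 1e-12)
  # canonical i -> i+4 geometry in an ideal helix is an accepted bond
  h <- place_amide_hydrogens(build_ideal_helix(12))
  rt <- residue_table(h)
  xyz <- model_xyz(h)
  grab <- function(i, nm) {
    idx <- seq.int(rt$first[i], rt$last[i])
    xyz[idx[h$atoms$name[idx] == nm][1], ]
  }
  e <- hbond_energy(list(N = grab(6, "N"), H = grab(6, "H")),
                    list(C = grab(2, "C"), O = grab(2, "O")))
  expect_lt(e, -0.5)
  # clash guard: any distance < 0.5 A means no bond
  expect_true(is.na(hbond_energy(list(N = c(0, 0, 0), H = c(0.1, 0, 0)),
                                 list(C = c(0.2, 0, 0), O = c(3, 0, 0)))))
  expect_true(is.na(hbond_energy(list(N = c(0, 0, 0)), list(C = c(3, 0, 0)))))
})

test_that("ideal helices are assigned H in the core, extended chains are not", {
  h <- build_ideal_helix(18)
  ss <- strsplit(ss_string(assign_ss(h), "A"), "")[[1]]
  core <- ss[3:16]
  expect_gte(mean(core == "H"), 0.9)
  expect_true(all(ss %in% c("H", "G", "E", "C")))

  ext <- build_peptide(strrep("A", 12), phi = -139, psi = 135)
  expect_false(any(strsplit(ss_string(assign_ss(ext), "A"), "")[[1]] == "H"))

  short <- build_peptide("AAAA")
  expect_equal(ss_string(assign_ss(short), "A"), "CCCC")
})

test_that("assignment is invariant to atom order within residues", {
  h <- build_ideal_helix(14)
  ss1 <- ss_string(assign_ss(h), "A")
  # reverse atom order inside every residue
  rt <- residue_table(h)
  perm <- unlist(lapply(seq_len(nrow(rt)), function(i) rev(seq.int(rt$first[i], rt$last[i]))))
  h2 <- h
  h2$atoms <- h$atoms[perm, ]
  rownames(h2$atoms) <- NULL
  h2$xyz[[1]] <- h$xyz[[1]][perm, , drop = FALSE]
  expect_equal(ss_string(assign_ss(h2), "A"), ss1)
})

test_that("helix run assignments respect minimum lengths", {
  asg <- data.frame(chain = "A", resno = 1:11, ins = " ",
                    resname = "ALA",
                    ss = strsplit("CCHHHHHHHCC", "")[[1]],
                    stringsAsFactors = FALSE)
  class(asg) <- c("ss_assignment", "data.frame")
  seg <- helix_segments(asg, min_len = 5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length, 7)
  expect_equal(seg$start, 2L)
  expect_equal(seg$end, 9L)

  asg$ss <- strsplit("HHHHCHHHHHH", "")[[1]]
  seg <- helix_segments(asg, min_len = 5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length, 6)

  # G states join runs only when requested
  asg$ss <- strsplit("HHHHGGHHHHH", "")[[1]]
  expect_equal(nrow(helix_segments(asg, min_len = 8)), 0)
  expect_equal(nrow(helix_segments(asg, min_len = 8, include_310 = TRUE)), 1)
})

test_that("known lysozyme helices are recovered from a real structure", {
  skip_if_not_installed("bio3d")
  s <- read_pdb(system.file("examples", "1hel.pdb", package = "bio3d"))
  seg <- helix_segments(assign_ss(s))
  # hen lysozyme's canonical alpha-helices (author numbering)
  covers <- function(a, b) any(seg$resno_start <= a + 2 & seg$resno_end >= b - 2)
  expect_true(covers(5, 14))
  expect_true(covers(25, 36))
  expect_true(covers(90, 99))
})
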