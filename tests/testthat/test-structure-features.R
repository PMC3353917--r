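atom_line <- function(serial, name, resname, resno, x, y, z, chain = "A",
                      record = "ATOM", alt = " ", occ = 1.00) {
  sprintf("%-6s%5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           %s",
          record, serial, name, alt, resname, chain, resno, x, y, z, occ,
          substr(name, 1, 1))
}

test_that("PDB parsing handles minimal input, models, chains and altLocs", {
  txt <- c(atom_line(1, "N", "GLY", 1, 0, 0, 0),
           atom_line(2, "CA", "GLY", 1, 1.46, 0, 0), "END")
  m <- parse_structure(txt)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$residues), 1L)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$sequence, "G")

  nmr <- c("MODEL     1",
           atom_line(1, "N", "ALA", 1, 0, 0, 0),
           atom_line(2, "CA", "ALA", 1, 1.46, 0, 0),
           "ENDMDL", "MODEL     2",
           atom_line(3, "N", "ALA", 1, 50, 50, 50),
           atom_line(4, "CA", "ALA", 1, 51.46, 50, 50),
           "ENDMDL", "END")
  m1 <- parse_structure(nmr)
  expect_equal(nrow(m1$atoms), 2L)
  expect_equal(m1$atoms$x[1], 0)

  het <- c(sub("^ATOM  ", "HETATM", atom_line(1, "O", "HOH", 1, 0, 0, 0)), "END")
  expect_error(parse_structure(het), "ATOM")

  two <- c(atom_line(1, "CA", "GLY", 1, 0, 0, 0, chain = "A"),
           atom_line(2, "CA", "GLY", 1, 9, 0, 0, chain = "B"), "END")
  expect_equal(parse_structure(two)$chain, "A")
  expect_equal(parse_structure(two, chain = "B")$atoms$x, 9)
  expect_error(parse_structure(two, chain = "Z"), "A, B")

  alt <- c(atom_line(1, "CA", "SER", 1, 0, 0, 0, alt = "A", occ = 0.3),
           atom_line(2, "CA", "SER", 1, 5, 0, 0, alt = "B", occ = 0.7), "END")
  ma <- parse_structure(alt)
  expect_equal(nrow(ma$atoms), 1L)
  expect_equal(ma$atoms$x, 5)  # highest occupancy wins
})

test_that("net charge follows the K/R positive, D/E negative convention", {
  expect_equal(compute_net_charge("DEKKR"), 1)
  expect_equal(compute_net_charge("GGGGG"), 0)
  expect_equal(compute_net_charge("HHHH"), 0)
  expect_equal(compute_net_charge("KRKR"), 4)
  expect_error(compute_net_charge("ACDB"), "non-standard")
  expect_error(compute_net_charge(""), "non-empty")
})

test_that("chain volume is the additive sum over the packaged residue table", {
  expect_equal(compute_volume("GGGGG"), 5 * residue_volumes[["G"]])
  s1 <- "ACDEF"; s2 <- "WYKLM"
  expect_equal(compute_volume(paste0(s1, s2)),
               compute_volume(s1) + compute_volume(s2))
  ten <- "MKVLAWYTDE"
  expect_equal(compute_volume(ten),
               sum(residue_volumes[strsplit(ten, "")[[1]]]))
})

test_that("isolated-sphere SASA matches the closed form within 1%", {
  one <- structure(list(
    atoms = data.frame(name = "SG", element = "S", residue = 1L, resid = "CYS",
                       x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    residues = data.frame(serial = 1L, resno = 1L, insert = "", resid = "CYS",
                          aa = "C", stringsAsFactors = FALSE),
    chain = "A", sequence = "C"), class = "structure_model")
  got <- compute_sasa(one, probe_radius = 1.4)
  expect_equal(got$total, 4 * pi * (1.8 + 1.4)^2, tolerance = 0.01)
  expect_error(compute_sasa(one, probe_radius = -1), "positive")

  # far-apart atoms do not occlude each other
  two <- one
  two$atoms <- rbind(one$atoms, transform(one$atoms, x = 100))
  got2 <- compute_sasa(two)
  expect_equal(got2$total, 2 * got$total, tolerance = 1e-6)
})

test_that("SASA agrees with a Monte-Carlo point oracle on atom clusters", {
  # two overlapping spheres, d = 2 A
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0))
  radii <- c(1.7, 1.7)
  oracle <- brute_sasa(xyz, radii, probe = 1.4, n_mc = 40000, seed = 11)
  m <- structure(list(
    atoms = data.frame(name = "C", element = "C", residue = 1L, resid = "ALA",
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
    residues = data.frame(serial = 1L, resno = 1L, insert = "", resid = "ALA",
                          aa = "A", stringsAsFactors = FALSE),
    chain = "A", sequence = "A"), class = "structure_model")
  got <- compute_sasa(m, n_points = 2000)
  expect_equal(got$total, sum(oracle), tolerance = 0.02)

  # random 5-atom clusters
  for (s in 1:3) {
    set.seed(100 + s)
    xyz <- matrix(rnorm(15, sd = 1.6), 5, 3)
    radii <- sample(c(1.52, 1.55, 1.7, 1.8), 5, replace = TRUE)
    m$atoms <- data.frame(name = "C", element = "C", residue = 1L,
                          resid = "ALA", x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], stringsAsFactors = FALSE)
    # bypass element lookup by injecting radii through element codes
    m$atoms$element <- c(C = "C")[1]
    got <- sasa_points_total(xyz, radii)
    oracle <- sum(brute_sasa(xyz, radii, n_mc = 40000, seed = s))
    expect_equal(got, oracle, tolerance = 0.02)
  }
})

test_that("adding an atom never increases another atom's exposed area", {
  set.seed(3)
  xyz <- matrix(rnorm(12, sd = 2), 4, 3)
  radii <- rep(1.7, 4)
  before <- sasa_points_per_atom(xyz, radii)
  after <- sasa_points_per_atom(rbind(xyz, c(0.5, 0.5, 0.5)), c(radii, 1.7))
  expect_true(all(after[1:4] <= before + 1e-9))
})

test_that("surface hydrophobicity is the hydrophobic fraction of total area", {
  leu <- build_peptide(6, -57, -47, aa = "LEU")
  m_leu <- model_from_peptide(leu)
  expect_equal(surface_hydrophobicity(m_leu), 1.0)

  asp <- build_peptide(6, -57, -47, aa = "ASP")
  m_asp <- model_from_peptide(asp)
  expect_equal(surface_hydrophobicity(m_asp), 0.0)

  mixed <- build_peptide(6, -57, -47, aa = "ALA")
  mixed$resid <- c("ALA", "ASP", "ALA", "ASP", "ALA", "ASP")
  m_mix <- model_from_peptide(mixed)
  sasa <- compute_sasa(m_mix)
  manual <- sum(sasa$per_residue[c("1", "3", "5")]) / sasa$total
  expect_equal(surface_hydrophobicity(m_mix, sasa), manual)
  expect_true(surface_hydrophobicity(m_mix) >= 0 &&
                surface_hydrophobicity(m_mix) <= 1)
})

test_that("an ideal poly-Ala helix is assigned >= 80% H", {
  hel <- build_peptide(20, -57, -47)
  ss <- assign_secondary_structure(model_from_peptide(hel))
  expect_length(ss, 20)
  expect_gte(mean(ss == "H"), 0.8)
  expect_equal(sum(ss == "E"), 0)
})

test_that("paired antiparallel strands are sheet, an isolated strand is not", {
  sheet <- build_antiparallel_sheet()
  ss <- assign_secondary_structure(
    parse_structure(peptide_pdb_text(sheet$s1, sheet$s2)))
  expect_gte(mean(ss == "E"), 0.6)

  lone <- build_peptide(8, -139, 135)
  ss1 <- assign_secondary_structure(model_from_peptide(lone))
  expect_equal(sum(ss1 %in% c("H", "E")), 0)
})

test_that("secondary structure requires enough complete backbones", {
  short <- build_peptide(4, -57, -47)
  expect_error(assign_secondary_structure(model_from_peptide(short)),
               "5 residues")
})

test_that("feature extraction populates all 11 variables consistently", {
  hel <- build_peptide(20, -57, -47)
  txt <- peptide_pdb_text(hel)
  fv <- extract_features(parse_structure(txt), id = "helix", label = "unknown")
  expect_setequal(setdiff(names(fv), c("id", "label")),
                  names(feature_variables()))
  ss <- assign_secondary_structure(parse_structure(txt))
  expect_equal(fv$pct_alpha, 100 * sum(ss == "H") / 20)
  expect_equal(fv$pct_beta, 0)
  expect_identical(fv$pct_secondary, fv$pct_alpha + fv$pct_beta)
  expect_lte(fv$alpha + fv$beta + fv$coil, 20)
  expect_true(fv$surface_hydrophobicity >= 0 && fv$surface_hydrophobicity <= 1)

  # determinism: identical text -> identical features
  fv2 <- extract_features(parse_structure(txt), id = "helix")
  expect_identical(fv[names(feature_variables())],
                   fv2[names(feature_variables())])
})

test_that("feature tables round-trip through CSV with display names", {
  tab <- suppressMessages(simulate_feature_table(
    n_per_class = c(natural = 5, random = 5), seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  header <- readLines(path, n = 1)
  expect_true(grepl("Net charge", header, fixed = TRUE))
  expect_true(grepl("% Secondary structure", header, fixed = TRUE))
  back <- read_feature_table(path)
  expect_equal(back, tab, ignore_attr = TRUE, tolerance = 1e-12)

  broken <- tab; broken$label <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_feature_table(broken, path2), "label")
})
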