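test_that("fixtures round-trip through mmCIF and PDB", {
  fx <- make_fixture("Oph5Ow")
  for (fmt in c("mmcif", "pdb")) {
    path <- withr::local_tempfile(
      fileext = if (fmt == "mmcif") ".cif" else ".pdb")
    write_structure(fx$atoms, path, fmt)
    back <- read_structure(path)
    expect_equal(nrow(back), nrow(fx$atoms))
    expect_identical(back$name, fx$atoms$name)
    expect_identical(back$residue_name, fx$atoms$residue_name)
    expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                        as.matrix(fx$atoms[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("both dialects give identical downstream labels", {
  fx <- make_fixture("cis_clamp")
  labels <- purrr::map_chr(c("mmcif", "pdb"), function(fmt) {
    path <- withr::local_tempfile(
      fileext = if (fmt == "mmcif") ".cif" else ".pdb")
    write_structure(fx$atoms, path, fmt)
    run_diagnosis(path)$ions$label
  })
  expect_identical(labels[1], labels[2])
  expect_identical(labels[1], "cis-2Oph.4Ow")
})

test_that("a minimal mmCIF parses into the expected typed table", {
  fx <- make_fixture("ideal_6Ow")
  path <- withr::local_tempfile(fileext = ".cif")
  write_structure(fx$atoms, path)
  st <- assign_roles(read_structure(path))
  expect_equal(nrow(st), 7L)
  expect_equal(sum(st$role == "metal"), 1L)
  expect_equal(sum(st$role == "Ow"), 6L)
})

test_that("alternate locations other than blank/A are dropped", {
  # hand-written four-atom PDB: altloc A at 0.6, B at 0.4, plus two plain
  lines <- c(
    "ATOM      1  OP1AG   A   1       0.000   0.000   0.000  0.60 10.00           O",
    "ATOM      2  OP1BG   A   1       0.500   0.000   0.000  0.40 10.00           O",
    "ATOM      3  OP2 G   A   1       2.000   0.000   0.000  1.00 10.00           O",
    "ATOM      4  P   G   A   1       1.000   1.000   0.000  1.00 10.00           P",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  st <- read_structure(path)
  expect_equal(nrow(st), 3L)
  expect_setequal(st$altloc, c("A", ""))
  expect_equal(sum(st$name == "OP1"), 1L)
  expect_equal(st$occupancy[st$name == "OP1"], 0.6)
})

test_that("unreadable inputs raise informative errors", {
  expect_error(read_structure(withr::local_tempfile()), "no such file")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty))
  junk <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site.id", "1 2 3"), junk)
  expect_error(read_structure(junk), "atom_site")
})

test_that("role assignment covers the nomenclature and is total", {
  fx <- make_fixture("Nb5Ow")
  st <- assign_roles(fx$atoms)
  g <- st[st$residue_name == "G", ]
  expect_equal(g$role[g$name == "O6"], "Ob")
  expect_equal(g$role[g$name == "N7"], "Nb")
  expect_equal(g$role[g$name == "N1"], "other")  # protonated in G
  expect_equal(g$role[g$name == "N2"], "other")  # amino nitrogen
  expect_equal(g$role[g$name == "N9"], "other")  # glycosidic
  expect_equal(g$role[g$name == "N3"], "Nb")
  # totality
  expect_false(anyNA(st$role))
  expect_equal(nrow(st), nrow(fx$atoms))

  # protein categories on a hand-built residue set
  prot <- tibble::tibble(
    atom_id = 1:6, record = "ATOM",
    name = c("OD1", "OD2", "ND1", "NE2", "O", "OG"),
    altloc = "", residue_name = c("ASP", "ASP", "HIS", "HIS", "GLY", "SER"),
    chain_id = "P", residue_number = 1:6, icode = "",
    x = 0, y = 0, z = as.numeric(1:6), occupancy = 1, b_factor = 10,
    element = c("O", "O", "N", "N", "O", "O"))
  roles <- assign_roles(prot)$role
  expect_identical(roles, c("Ocoo", "Ocoo", "NHis", "NHis", "Obb", "OHprot"))
})

test_that("modified nucleotides map onto parent-base templates", {
  psu <- tibble::tibble(
    atom_id = 1:2, record = "ATOM", name = c("O2", "O4"), altloc = "",
    residue_name = "PSU", chain_id = "A", residue_number = 1, icode = "",
    x = c(0, 1), y = 0, z = 0, occupancy = 1, b_factor = 10, element = "O")
  expect_identical(assign_roles(psu)$role, c("Ob", "Ob"))
  unknown <- dplyr::mutate(psu, residue_name = "XYZ")
  expect_warning(out <- assign_roles(unknown), "unknown")
  expect_identical(out$role, c("other", "other"))
})

test_that("neighbor search matches brute force on random clouds", {
  for (seed in 1:100) {
    cloud <- random_cloud(60, box = 12, seed = seed)
    set.seed(seed + 5000)
    probe <- runif(3, 0, 12)
    radius <- runif(1, 0.5, 5)
    got <- neighbors(cloud, probe, radius)
    expect_identical(got$atom_id, bf_neighbors(cloud, probe, radius))
    expect_true(!is.unsorted(got$distance))
  }
})

test_that("neighbor search edge cases behave", {
  st <- make_fixture("ideal_6Ow")$atoms
  waters <- st[st$residue_name == "HOH", ]
  hits <- neighbors(waters, c(0, 0, 0), 2.3)
  expect_equal(nrow(hits), 6L)
  expect_equal(hits$distance, rep(2.07, 6), tolerance = 1e-6)
  expect_equal(nrow(neighbors(st, c(0, 0, 0), 0)), 0L)
})
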