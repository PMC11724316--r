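test_that("a planted bidentate clamp is found and annotated", {
  st <- fixture_structure("cis_clamp")
  cc <- scan_clamps(st)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$stabilizer, "direct_bidentate")
  expect_false(is.na(cc$ion_id))
  expect_equal(cc$distance, sqrt(2) * 2.07, tolerance = 1e-2)
  expect_equal(cc$op_combo, "OP1-OP2")
})

test_that("the B-factor filter discards poorly modelled pairs", {
  st <- fixture_structure("cis_clamp", b_override = c(`OP2/1` = 65))
  expect_equal(nrow(scan_clamps(st)), 0L)
  # exactly at the cutoff is retained
  st60 <- fixture_structure("cis_clamp", b_override = c(`OP2/1` = 60))
  expect_equal(nrow(scan_clamps(st60)), 1L)
})

test_that("intra-residue OP1-OP2 contacts never flood the scan", {
  # a single phosphate group has d(OP1...OP2) ~ 2.5 A but is one group
  st <- fixture_structure("Oph5Ow")
  expect_equal(nrow(scan_clamps(st)), 0L)
})

test_that("clamp scan equals brute-force all-pairs filtering", {
  p <- geometry_params()
  for (motif in c("cis_clamp", "fac_3Oph", "Trans_4Oph", "helix_negative")) {
    st <- fixture_structure(motif)
    got <- scan_clamps(st)
    oph <- st[st$role == "Oph", ]
    brute <- 0L
    if (nrow(oph) >= 2) {
      for (i in seq_len(nrow(oph) - 1)) for (j in (i + 1):nrow(oph)) {
        d <- sqrt(sum((as.numeric(oph[i, c("x", "y", "z")]) -
                         as.numeric(oph[j, c("x", "y", "z")]))^2))
        same_group <- oph$chain_id[i] == oph$chain_id[j] &&
          oph$residue_number[i] == oph$residue_number[j]
        if (d < p$clamp_dmax && !same_group &&
            oph$b_factor[i] <= p$clamp_bmax && oph$b_factor[j] <= p$clamp_bmax) {
          brute <- brute + 1L
        }
      }
    }
    expect_equal(nrow(got), brute)
  }
})

test_that("every direct bidentate clamp ion carries >= 2 Oph in its label", {
  for (motif in c("cis_clamp", "fac_3Oph", "Cis_4Oph")) {
    st <- fixture_structure(motif)
    sh <- label_sites(build_shells(st))
    cc <- scan_clamps(st, shells = sh)
    direct <- cc[cc$stabilizer == "direct_bidentate", ]
    for (ion in unique(direct$ion_id)) {
      lab <- sh$label[sh$ion_id == ion]
      n_oph <- as.integer(stringr::str_match(lab, "(\\d)Oph")[, 2])
      expect_gte(n_oph, 2L)
    }
  }
})

test_that("water-mediated clamp stabilisation is recognised", {
  st <- make_fixture("Oph5Ow")$atoms
  # second phosphate: its OP1 within clamp range of the bound OP2 and at
  # hydrogen-bond distance of exactly one first-shell water
  op1 <- c(2.6, 3.0, 0)       # 3.05 A from the bound OP2; 2.76 A from
  p <- c(3.01, 4.39, 0.28)    # exactly one first-shell water
  op2 <- c(4.32, 4.65, 0.93)
  st2 <- dplyr::bind_rows(st, mgion:::phosphate_from_points(
    p, op1, op2, resno = 7L))
  st2$atom_id <- seq_len(nrow(st2))
  st2 <- assign_roles(mgion:::new_mg_structure(st2))
  cc <- scan_clamps(st2)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$stabilizer, "water_mediated")
})

test_that("carboxylate clamps are reported only behind the flag", {
  asp <- function(resno, shift) tibble::tibble(
    atom_id = NA_integer_, record = "ATOM",
    name = c("OD1", "OD2"), altloc = "", residue_name = "ASP",
    chain_id = "P", residue_number = resno, icode = "",
    x = shift + c(0, 0.8), y = c(0, 1.0), z = 0,
    occupancy = 1, b_factor = 20, element = "O")
  st <- dplyr::bind_rows(asp(1L, 0), asp(2L, 2.6))
  st$atom_id <- seq_len(nrow(st))
  st <- assign_roles(mgion:::new_mg_structure(st))
  expect_equal(nrow(scan_clamps(st)), 0L)
  withflag <- scan_clamps(st, include_carboxyl = TRUE)
  expect_gte(nrow(withflag), 1L)
  expect_true(all(withflag$op_combo == "carboxyl"))
})

test_that("trans candidates are window-bound and marked as candidates", {
  st <- fixture_structure("trans_2Oph")
  tc <- scan_trans_candidates(st)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$status, "candidate")
  expect_false(is.na(tc$ion_id))
  expect_equal(tc$distance, 2 * 2.07, tolerance = 1e-2)

  # without the ion the pair is still reported, with an empty ion id
  no_ion <- st[!(st$chain_id %in% c("M", "S")), ]
  tc2 <- scan_trans_candidates(mgion:::new_mg_structure(no_ion))
  expect_equal(nrow(tc2), 1L)
  expect_true(is.na(tc2$ion_id))

  # window edges: 3.85 excluded, 4.0 included
  two_op <- function(d) {
    t1 <- mgion:::phosphate_at(c(d / 2, 0, 0), resno = 1L, op_name = "OP1")
    t2 <- mgion:::phosphate_at(c(-d / 2, 0, 0), resno = 2L, op_name = "OP1")
    st <- dplyr::bind_rows(t1, t2)
    st$atom_id <- seq_len(nrow(st))
    assign_roles(mgion:::new_mg_structure(st))
  }
  expect_equal(nrow(scan_trans_candidates(two_op(3.85))), 0L)
  expect_equal(nrow(scan_trans_candidates(two_op(4.0))), 1L)
})

test_that("head-to-tail purine seats are detected; normal stacks are not", {
  st <- fixture_structure("purine_seat")
  ps <- scan_purine_seats(st)
  expect_equal(nrow(ps), 1L)
  expect_false(is.na(ps$ion_id))
  sh <- label_sites(build_shells(st))
  expect_identical(sh$label[sh$ion_id == ps$ion_id], "cis-2Nb.4Ow")

  # push the second guanine away until d(N7...N7) = 3.9: no hit
  n7 <- st[st$name == "N7", ]
  gap <- as.numeric(n7[2, c("x", "y", "z")]) -
    as.numeric(n7[1, c("x", "y", "z")])
  d0 <- sqrt(sum(gap^2))
  shift <- (3.9 / d0 - 1) * gap
  res2 <- st$chain_id == "A" & st$residue_number == 2
  st2 <- st
  st2$x[res2] <- st2$x[res2] + shift[1]
  st2$y[res2] <- st2$y[res2] + shift[2]
  st2$z[res2] <- st2$z[res2] + shift[3]
  expect_equal(nrow(scan_purine_seats(st2)), 0L)

  # empty structure
  empty <- st[0, ]
  expect_equal(nrow(scan_purine_seats(mgion:::new_mg_structure(empty))), 0L)
})

test_that("O2'(n)...OP(n+1) motifs are found with their ion", {
  st <- fixture_structure("o2p_motif")
  hits <- scan_o2p_motifs(st)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 3.0, tolerance = 1e-3)
  expect_false(is.na(hits$ion_id))
  expect_equal(hits$op_name, "OP1")

  # same geometry without the ion: candidate with empty ion id
  no_ion <- st[st$role != "metal", ]
  hits2 <- scan_o2p_motifs(mgion:::new_mg_structure(no_ion))
  expect_equal(nrow(hits2), 1L)
  expect_true(is.na(hits2$ion_id))
})

test_that("the helical negative control is clean for every scan", {
  st <- fixture_structure("helix_negative")
  expect_equal(nrow(scan_clamps(st)), 0L)
  expect_equal(nrow(scan_purine_seats(st)), 0L)
  expect_equal(nrow(scan_o2p_motifs(st)), 0L)
})

test_that("planted motifs are recovered under mild coordinate jitter", {
  recovered <- vapply(1:40, function(seed) {
    st <- fixture_structure("cis_clamp", jitter_sd = 0.05, seed = seed)
    nrow(scan_clamps(st)) == 1L
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})
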