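# Deterministic synthetic-structure generator.  Every motif is built from
# internal-coordinate templates (P-OP 1.48 A, OP-P-OP 119 degrees,
# idealized planar guanine, octahedral Mg(H2O)6 at 2.07 A / 2.19 A for N
# ligands) so that the target distances and angles hold exactly before
# jitter, and ships its ground truth alongside.

P_OP <- 1.48
OP_P_OP <- 119
P_OBRIDGE <- 1.60
MG_O <- 2.07
MG_N <- 2.19
K_O <- 2.80

# Idealized planar guanine (standard base reference frame, z = 0).
GUANINE_TEMPLATE <- local({
  m <- rbind(
    N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962), N7 = c(0.870, 3.969),
    C5 = c(0.071, 2.833), C6 = c(0.424, 1.460), O6 = c(1.554, 0.955),
    N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087), N2 = c(-2.949, 0.139),
    N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177)
  )
  cbind(m, 0)
})

atom_rows <- function(names, resname, chain, resno, xyz, elements,
                      record = "ATOM", occ = 1, b = 20) {
  xyz <- matrix(xyz, ncol = 3)
  tibble::tibble(
    atom_id = NA_integer_, record = record, name = names, altloc = "",
    residue_name = resname, chain_id = chain, residue_number = as.integer(resno),
    icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ, b_factor = b,
    element = elements
  )
}

ion_atom <- function(element = "MG", xyz = c(0, 0, 0), resno = 901,
                     chain = "M", b = 15, occ = 1) {
  atom_rows(toupper(element), toupper(element), chain, resno, xyz,
            toupper(element), record = "HETATM", occ = occ, b = b)
}

water_atom <- function(xyz, resno, chain = "S", b = 25) {
  atom_rows("O", "HOH", chain, resno, xyz, "O", record = "HETATM", b = b)
}

rotate_in_plane <- function(u, n, theta_deg) {
  # Rodrigues rotation of u about unit normal n.
  th <- theta_deg * pi / 180
  u * cos(th) + cross3(n, u) * sin(th) + n * sum(n * u) * (1 - cos(th))
}

perp_axis <- function(vhat, ref = c(0.283, 0.579, 0.764)) {
  w <- cross3(vhat, ref)
  if (sqrt(sum(w^2)) < 1e-6) w <- cross3(vhat, c(1, 0, 0))
  unit(w)
}

# Phosphate fragment whose named OP atom sits at `v` (ion at origin), with
# angle(P-OP...ion) = p_op_angle and the ion lying exactly in the
# OP1-P-OP2 plane spanned by (vhat, w).
phosphate_at <- function(v, resno, chain = "A", op_name = "OP2",
                         resname = "G", p_op_angle = 148, w = NULL,
                         b = 20) {
  vhat <- unit(v)
  if (is.null(w)) w <- perp_axis(vhat)
  n <- unit(cross3(vhat, w))
  u <- rotate_in_plane(-vhat, n, p_op_angle)      # OP -> P direction
  p <- v + P_OP * u
  p1 <- unit(v - p)                               # P -> coordinated OP
  cand_a <- rotate_in_plane(p1, n, OP_P_OP)
  cand_b <- rotate_in_plane(p1, n, -OP_P_OP)
  # free OP points away from the ion
  other_dir <- if (sum((p + P_OP * cand_a)^2) >= sum((p + P_OP * cand_b)^2)) {
    cand_a
  } else cand_b
  op_other <- p + P_OP * other_dir
  e <- unit(-(p1 + other_dir))
  o5 <- p + P_OBRIDGE * unit(e + n)
  o3 <- p + P_OBRIDGE * unit(e - n)
  other_name <- if (op_name == "OP1") "OP2" else "OP1"
  atom_rows(c("P", op_name, other_name, "O5'", "O3'"),
            resname, chain, resno,
            rbind(p, v, op_other, o5, o3),
            c("P", "O", "O", "O", "O"), b = b)
}

# Explicit phosphate from P/OP1/OP2 positions (bridging oxygens added).
phosphate_from_points <- function(p, op1, op2, resno, chain = "A",
                                  resname = "G", b = 20) {
  p1 <- unit(op1 - p); p2 <- unit(op2 - p)
  n <- unit(cross3(p1, p2))
  e <- unit(-(p1 + p2))
  o5 <- p + P_OBRIDGE * unit(e + n)
  o3 <- p + P_OBRIDGE * unit(e - n)
  atom_rows(c("P", "OP1", "OP2", "O5'", "O3'"), resname, chain, resno,
            rbind(p, op1, op2, o5, o3), c("P", "O", "O", "O", "O"), b = b)
}

# Rigid placement of the planar guanine so that `ligand` ("O6" or "N7")
# sits at v with the ion (origin) in the base plane.  For O6 the
# C6=O6...ion angle is `ob_angle`; for N7 the ring lone pair points at
# the ion.
guanine_at <- function(v, ligand = c("N7", "O6"), resno, chain = "A",
                       ob_angle = 144, w = NULL, b = 20) {
  ligand <- match.arg(ligand)
  tpl <- GUANINE_TEMPLATE
  lig_xyz <- tpl[ligand, ]
  ez <- c(0, 0, 1)
  if (ligand == "N7") {
    u1 <- unit(tpl["C5", ] - lig_xyz)
    u2 <- unit(tpl["C8", ] - lig_xyz)
    dir_ion <- unit(-(u1 + u2))
  } else {
    co <- unit(tpl["C6", ] - lig_xyz)
    cand_a <- rotate_in_plane(co, ez, ob_angle)
    cand_b <- rotate_in_plane(co, ez, -ob_angle)
    centroid <- colMeans(tpl)
    away <- unit(lig_xyz - centroid)
    dir_ion <- if (sum(cand_a * away) >= sum(cand_b * away)) cand_a else cand_b
  }
  vhat <- unit(v)
  if (is.null(w)) w <- perp_axis(vhat)
  n_g <- unit(cross3(vhat, w))
  a_frame <- cbind(dir_ion, cross3(ez, dir_ion), ez)
  b1 <- -vhat
  b_frame <- cbind(b1, cross3(n_g, b1), n_g)
  rot <- b_frame %*% t(a_frame)
  placed <- t(rot %*% t(sweep(tpl, 2, lig_xyz))) + rep(v, each = nrow(tpl))
  elements <- substr(rownames(tpl), 1, 1)
  atom_rows(rownames(tpl), "G", chain, resno, placed, elements, b = b)
}

# Bare ribose 2'-hydroxyl fragment (O2' ligand plus its carbon).
o2prime_at <- function(v, resno, chain = "A", resname = "G", b = 20) {
  vhat <- unit(v)
  w <- perp_axis(vhat)
  c2 <- v + 1.42 * unit(0.6 * vhat + w)
  atom_rows(c("O2'", "C2'"), resname, chain, resno, rbind(v, c2),
            c("O", "C"), b = b)
}

OCT_DIRS <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

# Evenly spread unit vectors (golden spiral) for non-octahedral shells.
spread_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * 2.399963229728653
  cbind(r * cos(phi), r * sin(phi), z)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

finalize_fixture <- function(parts, motif, jitter_sd, seed, truth) {
  atoms <- dplyr::bind_rows(parts)
  if (jitter_sd > 0) {
    with_local_seed(seed, {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter_sd)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter_sd)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter_sd)
    })
  }
  atoms$x <- round(atoms$x, 3); atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)
  atoms$atom_id <- seq_len(nrow(atoms))
  st <- new_mg_structure(atoms,
                         provenance = list(source = paste0("fixture:", motif),
                                           format = "memory",
                                           jitter_sd = jitter_sd,
                                           seed = seed))
  list(atoms = st, truth = truth)
}

SITE_MOTIFS <- c(
  ideal_6Ow = "6Ow", Oph5Ow = "Oph.5Ow", Ob5Ow = "Ob.5Ow", Nb5Ow = "Nb.5Ow",
  cis_clamp = "cis-2Oph.4Ow", trans_2Oph = "trans-2Oph.4Ow",
  fac_3Oph = "fac-3Oph.3Ow", mer_3Oph = "mer-3Oph.3Ow",
  Cis_4Oph = "Cis-4Oph.2Ow", Trans_4Oph = "Trans-4Oph.2Ow",
  purine_seat = "cis-2Nb.4Ow",
  Cis_3Oph_Or = "Cis-3Oph.Or.2Ow", fac_2Oph_Or = "fac-2Oph.Or.3Ow"
)

#' Generate a synthetic structure with a planted, labelled motif
#'
#' Deterministic generator of small chemically plausible fragments used to
#' exercise every stage of the pipeline without downloading structures.
#' Atoms are placed from internal-coordinate templates so the motif's
#' target distances and angles hold exactly, then optional Gaussian jitter
#' (seeded) perturbs all coordinates.  Ground truth (expected site labels,
#' scan hits, pair classes) is returned alongside.
#'
#' Motifs: `ideal_6Ow`, `Oph5Ow`, `Ob5Ow`, `Nb5Ow`, `cis_clamp`
#' (= cis-2Oph.4Ow bidentate clamp), `trans_2Oph`, `fac_3Oph`,
#' `mer_3Oph`, `Cis_4Oph`, `Trans_4Oph`, `purine_seat` (cis-2Nb.4Ow on
#' head-to-tail guanines), `Cis_3Oph_Or`, `fac_2Oph_Or`, `o2p_motif`,
#' `K_site`, `mgA_pair` .. `mgD_pair`, `mgK_pair`, `helix_negative`
#' (ion-free helical fragment, a no-hit control for every scan).
#'
#' @param motif motif name (see above) or any site label from the
#'   nomenclature (e.g. `"mer-Oph.2Ob.3Ow"`), which is built generically.
#' @param jitter_sd Gaussian coordinate noise, A (0 = exact geometry).
#' @param seed integer seed for the jitter.
#' @param ... motif-specific overrides: `d` (ligand distance for the
#'   clamp/trans Oph...Oph construction is implied by the cis/trans
#'   angles), `oo_distance` (cis_clamp Oph...Oph target, default 2.93 A),
#'   `b_override` (named B-factor tweaks, see details in the source),
#'   `ion` (element for `K_site`, default "K").
#' @return list with `atoms` (an `mg_structure`) and `truth` (list:
#'   `labels` tibble, expected scan counts, expected `pair_class`).
#' @examples
#' fx <- make_fixture("cis_clamp")
#' fx$truth$labels
#' @export
make_fixture <- function(motif, jitter_sd = 0, seed = 1L, ...) {
  opts <- list(...)
  if (jitter_sd < 0) rlang::abort("jitter_sd must be >= 0")
  if (motif %in% names(SITE_MOTIFS)) {
    return(site_fixture(SITE_MOTIFS[[motif]], motif, jitter_sd, seed, opts))
  }
  if (grepl("O|N", motif) && grepl("\\d|Ow", motif)) {
    known <- c("o2p_motif", "K_site", "mgA_pair", "mgB_pair", "mgC_pair",
               "mgD_pair", "mgK_pair", "helix_negative")
    if (!motif %in% known) {
      return(site_fixture(motif, motif, jitter_sd, seed, opts))
    }
  }
  switch(motif,
    o2p_motif = o2p_fixture(jitter_sd, seed, opts),
    K_site = k_site_fixture(jitter_sd, seed, opts),
    mgA_pair = mg_pair_fixture("A", jitter_sd, seed, opts),
    mgB_pair = mg_pair_fixture("B", jitter_sd, seed, opts),
    mgC_pair = mg_pair_fixture("C", jitter_sd, seed, opts),
    mgD_pair = mg_pair_fixture("D", jitter_sd, seed, opts),
    mgK_pair = mgk_pair_fixture(jitter_sd, seed, opts),
    helix_negative = helix_fixture(jitter_sd, seed, opts),
    rlang::abort(paste0("unknown fixture motif: ", motif))
  )
}

parse_label <- function(label) {
  m <- stringr::str_match(label,
    "^((?:cis|trans|fac|mer|Cis|Trans)-)?((?:\\d?[A-Za-z']+\\.?)+)$")
  if (is.na(m[1, 1])) rlang::abort(paste0("cannot parse site label: ", label))
  prefix <- ifelse(is.na(m[1, 2]), "", m[1, 2])
  tokens <- stringr::str_split_1(m[1, 3], "\\.")
  counts <- integer(0)
  for (tok in tokens) {
    tm <- stringr::str_match(tok, "^(\\d*)([A-Za-z']+)$")
    cat <- tm[1, 3]
    if (!cat %in% LABEL_ORDER) {
      rlang::abort(paste0("unknown ligand category '", cat, "' in ", label))
    }
    counts[cat] <- as.integer(ifelse(nzchar(tm[1, 2]), tm[1, 2], "1"))
  }
  list(prefix = prefix, counts = counts)
}

ligand_distance <- function(category) {
  ifelse(category %in% c("Nb", "NHis"), MG_N, MG_O)
}

# Vertex slots (rows of OCT_DIRS) for the non-water ligands and waters
# implied by a prefix.
vertex_plan <- function(n_nonwater, prefix, label) {
  all_slots <- 1:6
  nw <- switch(as.character(n_nonwater),
    "0" = integer(0),
    "1" = 1L,
    "2" = if (prefix == "trans-") c(1L, 2L) else c(1L, 3L),
    "3" = if (prefix == "fac-") c(1L, 3L, 5L) else c(1L, 2L, 3L),
    "4" = if (prefix == "Trans-") c(1L, 2L, 3L, 4L) else c(1L, 2L, 4L, 6L),
    "5" = c(1L, 2L, 3L, 4L, 5L),
    "6" = all_slots
  )
  if (n_nonwater %in% 2:4 && !nzchar(prefix)) {
    rlang::abort(paste0("label ", label,
                        " needs an isomer prefix for ", n_nonwater,
                        " non-water ligands"))
  }
  list(nonwater = nw, water = setdiff(all_slots, nw))
}

site_fixture <- function(label, motif, jitter_sd, seed, opts) {
  parsed <- parse_label(label)
  counts <- parsed$counts
  n_w <- if ("Ow" %in% names(counts)) counts[["Ow"]] else 0L
  nonwater_cats <- rep(setdiff(names(counts), "Ow"),
                       counts[setdiff(names(counts), "Ow")])
  if (n_w + length(nonwater_cats) != 6L) {
    rlang::abort(paste0("label ", label, " is not hexacoordinated"))
  }
  plan <- vertex_plan(length(nonwater_cats), parsed$prefix, label)
  parts <- list(ion_atom("MG"))
  resno <- 0L
  supported <- c("Oph", "Or", "Ob", "Nb")
  if (!all(nonwater_cats %in% supported)) {
    rlang::abort(paste0("no fragment builder for categories: ",
      paste(setdiff(nonwater_cats, supported), collapse = ", ")))
  }
  oo <- opts$oo_distance
  if (!is.null(oo) && identical(motif, "cis_clamp") && oo >= 3.4) {
    rlang::abort(paste0("inconsistent fixture spec: cis_clamp with ",
                        "Oph...Oph = ", oo, " A is not a clamp (>= 3.4 A)"))
  }
  for (k in seq_along(nonwater_cats)) {
    cat_k <- nonwater_cats[k]
    v <- OCT_DIRS[plan$nonwater[k], ] * ligand_distance(cat_k)
    resno <- resno + 1L
    parts[[length(parts) + 1L]] <- switch(cat_k,
      Oph = phosphate_at(v, resno = resno,
                         op_name = if (k %% 2) "OP2" else "OP1"),
      Or = o2prime_at(v, resno = resno),
      Ob = guanine_at(v, "O6", resno = resno),
      Nb = guanine_at(v, "N7", resno = resno)
    )
  }
  # optional non-right cis angle for the two-Oph clamp (sets the
  # Oph...Oph distance without changing the Mg-O distances)
  if (!is.null(oo) && identical(motif, "cis_clamp")) {
    theta <- 2 * asin(oo / (2 * MG_O)) * 180 / pi
    second <- parts[[3L]]
    axis <- c(0, 0, 1)
    xyz <- as.matrix(second[, c("x", "y", "z")])
    rot_by <- theta - 90
    xyz <- t(apply(xyz, 1, rotate_in_plane, n = axis, theta_deg = rot_by))
    second$x <- xyz[, 1]; second$y <- xyz[, 2]; second$z <- xyz[, 3]
    parts[[3L]] <- second
  }
  for (k in seq_along(plan$water)) {
    parts[[length(parts) + 1L]] <-
      water_atom(OCT_DIRS[plan$water[k], ] * MG_O, resno = 100L + k)
  }
  if (!is.null(opts$b_override)) {
    parts <- apply_b_override(parts, opts$b_override)
  }
  n_oph <- sum(nonwater_cats == "Oph")
  n_cis_oph <- expected_cis_oph_pairs(parsed$prefix, n_oph)
  truth <- list(
    labels = tibble::tibble(ion_chain = "M", ion_resno = 901L, label = label),
    clamps = n_cis_oph,
    purine_seats = if (label == "cis-2Nb.4Ow") 1L else 0L,
    o2p_hits = 0L,
    pair_class = NA_character_
  )
  finalize_fixture(parts, motif, jitter_sd, seed, truth)
}

# Number of cis Oph-Oph pairs (each is a bidentate clamp hit) implied by
# the vertex plan.
expected_cis_oph_pairs <- function(prefix, n_oph) {
  if (n_oph < 2) return(0L)
  slots <- vertex_plan(n_oph, prefix, "internal")$nonwater
  dirs <- OCT_DIRS[slots, , drop = FALSE]
  cnt <- 0L
  for (i in seq_len(nrow(dirs) - 1)) for (j in (i + 1):nrow(dirs)) {
    if (sum(dirs[i, ] * dirs[j, ]) > -0.5) cnt <- cnt + 1L  # not antipodal
  }
  cnt
}

apply_b_override <- function(parts, b_override) {
  # b_override: named numeric, names like "OP2/1" (atom name / residue no)
  for (key in names(b_override)) {
    bits <- stringr::str_split_1(key, "/")
    parts <- purrr::map(parts, function(p) {
      hit <- p$name == bits[1] & p$residue_number == as.integer(bits[2])
      p$b_factor[hit] <- b_override[[key]]
      p
    })
  }
  parts
}

o2p_fixture <- function(jitter_sd, seed, opts) {
  d_o2_op <- opts$d_o2_op %||% 3.0
  v <- c(MG_O, 0, 0)
  parts <- list(
    ion_atom("MG"),
    o2prime_at(v, resno = 1L)
  )
  # next-residue phosphate: its OP1 sits d_o2_op beyond the O2', well
  # outside the ion's windows
  op1 <- v + c(d_o2_op, 0, 0)
  p <- op1 + P_OP * unit(c(0.55, 0.84, 0))
  p2dir <- rotate_in_plane(unit(op1 - p), c(0, 0, 1), OP_P_OP)
  op2 <- p + P_OP * p2dir
  parts[[length(parts) + 1L]] <-
    phosphate_from_points(p, op1, op2, resno = 2L)
  for (k in 1:5) {
    parts[[length(parts) + 1L]] <-
      water_atom(OCT_DIRS[k + 1, ] * MG_O, resno = 100L + k)
  }
  truth <- list(
    labels = tibble::tibble(ion_chain = "M", ion_resno = 901L,
                            label = "Or.5Ow"),
    clamps = 0L, purine_seats = 0L, o2p_hits = 1L,
    pair_class = NA_character_
  )
  finalize_fixture(parts, "o2p_motif", jitter_sd, seed, truth)
}

k_site_fixture <- function(jitter_sd, seed, opts) {
  ion <- toupper(opts$ion %||% "K")
  n_lig <- opts$n_ligands %||% 7L
  d <- opts$d %||% K_O
  parts <- list(ion_atom(ion))
  dirs <- spread_dirs(n_lig)
  for (k in seq_len(n_lig)) {
    parts[[length(parts) + 1L]] <- water_atom(dirs[k, ] * d, resno = 100L + k)
  }
  truth <- list(
    labels = tibble::tibble(ion_chain = "M", ion_resno = 901L,
                            label = NA_character_),   # not hexacoordinated
    clamps = 0L, purine_seats = 0L, o2p_hits = 0L,
    pair_class = NA_character_
  )
  finalize_fixture(parts, "K_site", jitter_sd, seed, truth)
}

# Complete an ion's octahedron with waters, given the unit directions of
# ligands already in place.
complete_waters <- function(centre, dirs, n_add, resno_start,
                            chain = "S", d = MG_O) {
  dirs <- matrix(dirs, ncol = 3)
  e1 <- unit(dirs[1, ])
  if (nrow(dirs) >= 2) {
    e2 <- dirs[2, ] - sum(dirs[2, ] * e1) * e1
    e2 <- unit(e2)
  } else {
    e2 <- perp_axis(e1)
  }
  e3 <- cross3(e1, e2)
  slots <- rbind(-e1, -e2, e3, -e3, e2)
  # drop slots too close to an existing ligand direction
  ok <- apply(slots, 1, function(s) {
    all(apply(dirs, 1, function(u) vec_angle(s, u)) > 45)
  })
  slots <- slots[ok, , drop = FALSE]
  stopifnot(nrow(slots) >= n_add)
  purrr::map(seq_len(n_add), function(k) {
    water_atom(centre + slots[k, ] * d, resno = resno_start + k,
               chain = chain)
  })
}

mg_pair_fixture <- function(type, jitter_sd, seed, opts) {
  parts <- list()
  if (type == "A") {
    d_mm <- opts$d %||% 4.8
    a <- c(-d_mm / 2, 0, 0); b <- c(d_mm / 2, 0, 0)
    half_sep <- P_OP * sin(OP_P_OP / 2 * pi / 180)   # half OP...OP width
    dx <- d_mm / 2 - half_sep
    y0 <- sqrt(MG_O^2 - dx^2)
    p_off <- sqrt(P_OP^2 - half_sep^2)
    for (s in c(1, -1)) {                            # two bridging groups
      op1 <- c(-half_sep, s * y0, 0)
      op2 <- c(half_sep, s * y0, 0)
      p <- c(0, s * (y0 + p_off), 0)
      parts[[length(parts) + 1L]] <-
        phosphate_from_points(p, op1, op2, resno = if (s > 0) 1L else 2L)
    }
    dirs_a <- rbind(unit(c(-half_sep, y0, 0) - a),
                    unit(c(-half_sep, -y0, 0) - a))
    dirs_b <- rbind(unit(c(half_sep, y0, 0) - b),
                    unit(c(half_sep, -y0, 0) - b))
    parts <- c(parts, list(ion_atom("MG", a, resno = 901L),
                           ion_atom("MG", b, resno = 902L)))
    parts <- c(parts, complete_waters(a, dirs_a, 4L, 100L),
               complete_waters(b, dirs_b, 4L, 110L))
    truth_class <- "MgA_uc2"
    labels <- c("cis-2Oph.4Ow", "cis-2Oph.4Ow")
  } else {
    spec <- switch(type,
      B = list(d = 3.8, n_bridge_w = 1L, bridge_op = FALSE),
      C = list(d = 2.8, n_bridge_w = 2L, bridge_op = TRUE),
      D = list(d = 2.38, n_bridge_w = 3L, bridge_op = FALSE)
    )
    d_mm <- opts$d %||% spec$d
    a <- c(-d_mm / 2, 0, 0); b <- c(d_mm / 2, 0, 0)
    ring_r <- sqrt(MG_O^2 - (d_mm / 2)^2)
    n_bridge <- spec$n_bridge_w + as.integer(spec$bridge_op)
    phis <- seq(0, by = 2 * pi / max(n_bridge, 2), length.out = n_bridge)
    bridge_xyz <- cbind(0, ring_r * cos(phis), ring_r * sin(phis))
    k_w <- 0L
    dirs_a <- NULL; dirs_b <- NULL
    for (i in seq_len(n_bridge)) {
      pos <- bridge_xyz[i, ]
      dirs_a <- rbind(dirs_a, unit(pos - a))
      dirs_b <- rbind(dirs_b, unit(pos - b))
      if (spec$bridge_op && i == 1L) {
        # bridging OP1: build its phosphate pointing away from both ions
        p <- pos + P_OP * unit(c(0, pos[2], pos[3]))
        p2dir <- rotate_in_plane(unit(pos - p), unit(c(1, 0, 0)), OP_P_OP)
        op2 <- p + P_OP * p2dir
        parts[[length(parts) + 1L]] <-
          phosphate_from_points(p, pos, op2, resno = 1L)
      } else {
        k_w <- k_w + 1L
        parts[[length(parts) + 1L]] <- water_atom(pos, resno = 100L + k_w,
                                                  chain = "T")
      }
    }
    parts <- c(parts, list(ion_atom("MG", a, resno = 901L),
                           ion_atom("MG", b, resno = 902L)))
    n_own <- 6L - n_bridge
    parts <- c(parts, complete_waters(a, dirs_a, n_own, 120L),
               complete_waters(b, dirs_b, n_own, 140L))
    truth_class <- paste0("Mg", type, "_uc", n_bridge)
    labels <- if (spec$bridge_op) c("Oph.5Ow", "Oph.5Ow") else c("6Ow", "6Ow")
  }
  truth <- list(
    labels = tibble::tibble(ion_chain = "M", ion_resno = c(901L, 902L),
                            label = labels),
    clamps = 0L, purine_seats = 0L, o2p_hits = 0L,
    pair_class = truth_class
  )
  finalize_fixture(parts, paste0("mg", type, "_pair"), jitter_sd, seed, truth)
}

mgk_pair_fixture <- function(jitter_sd, seed, opts) {
  d_mm <- opts$d %||% 4.0
  d_wk <- 2.9
  mg <- c(0, 0, 0); k <- c(d_mm, 0, 0)
  xw <- (MG_O^2 + d_mm^2 - d_wk^2) / (2 * d_mm)
  yw <- sqrt(MG_O^2 - xw^2)
  w1 <- c(xw, yw, 0); w2 <- c(xw, -yw, 0)
  parts <- list(ion_atom("MG", mg, resno = 901L),
                ion_atom("K", k, resno = 902L),
                water_atom(w1, resno = 101L, chain = "T"),
                water_atom(w2, resno = 102L, chain = "T"))
  dirs_mg <- rbind(unit(w1 - mg), unit(w2 - mg))
  parts <- c(parts, complete_waters(mg, dirs_mg, 4L, 120L))
  # fill the K+ shell to 7 with its own waters at 2.8 A, away from Mg
  k_dirs <- spread_dirs(9)
  k_dirs <- k_dirs[k_dirs[, 1] > -0.2, , drop = FALSE]
  kept <- 0L
  for (i in seq_len(nrow(k_dirs))) {
    if (kept >= 5L) break
    pos <- k + K_O * k_dirs[i, ]
    if (min(sqrt(sum((pos - w1)^2)), sqrt(sum((pos - w2)^2))) < 2.4) next
    if (sqrt(sum((pos - mg)^2)) < 3.4) next
    kept <- kept + 1L
    parts[[length(parts) + 1L]] <- water_atom(pos, resno = 140L + kept)
  }
  truth <- list(
    labels = tibble::tibble(ion_chain = "M", ion_resno = c(901L, 902L),
                            label = c("6Ow", NA_character_)),
    clamps = 0L, purine_seats = 0L, o2p_hits = 0L,
    pair_class = "MgK_uc2"
  )
  finalize_fixture(parts, "mgK_pair", jitter_sd, seed, truth)
}

helix_fixture <- function(jitter_sd, seed, opts) {
  n_res <- opts$n_res %||% 8L
  twist <- 32.7 * pi / 180
  rise <- 2.81
  parts <- list()
  for (i in seq_len(n_res)) {
    th <- i * twist; z <- i * rise
    radial <- c(cos(th), sin(th), 0)
    tangential <- c(-sin(th), cos(th), 0)
    p <- 9.4 * radial + c(0, 0, z)
    op1 <- p + 1.3 * radial + c(0, 0, 0.7)
    op2 <- p + 1.3 * radial - c(0, 0, 0.7)
    o5 <- p + 1.6 * unit(tangential + c(0, 0, 0.5))
    o3 <- p - 1.6 * unit(tangential - c(0, 0, 0.5))
    o2p <- 6.8 * c(cos(th + 0.17), sin(th + 0.17), 0) + c(0, 0, z + 1.2)
    n7 <- 4.5 * c(cos(th + 0.35), sin(th + 0.35), 0) + c(0, 0, z + 0.5)
    parts[[length(parts) + 1L]] <- atom_rows(
      c("P", "OP1", "OP2", "O5'", "O3'", "O2'", "N7"),
      "G", "A", i, rbind(p, op1, op2, o5, o3, o2p, n7),
      c("P", "O", "O", "O", "O", "O", "N"))
  }
  truth <- list(
    labels = tibble::tibble(ion_chain = character(), ion_resno = integer(),
                            label = character()),
    clamps = 0L, purine_seats = 0L, o2p_hits = 0L,
    pair_class = NA_character_
  )
  finalize_fixture(parts, "helix_negative", jitter_sd, seed, truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
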