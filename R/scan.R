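residue_key <- function(a) paste(a$chain_id, a$residue_number, a$icode,
                                 sep = "|")

# shells may be NULL; build lazily once.
ensure_shells <- function(atoms, shells, params) {
  if (is.null(shells)) build_shells(atoms, params) else shells
}

# Map atom_id -> ids of ions holding it inner-shell.
inner_shell_index <- function(shells) {
  if (nrow(shells) == 0L) {
    return(tibble::tibble(atom_id = integer(), ion_id = integer(),
                          ion_element = character()))
  }
  purrr::map_dfr(seq_len(nrow(shells)), function(i) {
    lig <- shells$ligands[[i]]
    if (!nrow(lig)) return(NULL)
    tibble::tibble(atom_id = lig$atom_id, ion_id = shells$ion_id[i],
                   ion_element = shells$ion_element[i])
  })
}

#' Scan for bidentate phosphate clamps
#'
#' Screens all pairs of anionic phosphate oxygens from distinct phosphate
#' groups with d(Oph...Oph) below 3.4 A, discarding poorly modelled pairs
#' in which either atom has a B-factor above 60 A^2.  Each surviving pair
#' is annotated with its stabiliser: `direct_bidentate` when one Mg is
#' inner-shell to both oxygens (the classic Mg2+ clamp / 10-membered
#' ring), `water_mediated` when a Mg binds one oxygen directly and
#' reaches the other through exactly one of its first-shell waters within
#' the hydrogen-bond window, else `none_found` (a candidate site for an
#' unmodelled ion).  Optionally the same screen runs over Asp/Glu
#' carboxylate oxygen pairs.
#'
#' @param atoms an `mg_structure` with roles.
#' @param params a [geometry_params()] object.
#' @param shells optional precomputed [build_shells()] result.
#' @param include_carboxyl also report Ocoo...Ocoo pairs (distinct
#'   residues) under `op_combo = "carboxyl"`.
#' @return `mg_clamps` tibble: atom ids/names/residues of both oxygens,
#'   `distance`, `op_combo` (`OP1-OP1`, `OP2-OP2`, `OP1-OP2`,
#'   `carboxyl`), `sequence_separation` (|delta residue| within a chain,
#'   NA across chains), `stabilizer`, `ion_id` (NA when none).
#' @examples
#' st <- assign_roles(make_fixture("cis_clamp")$atoms)
#' scan_clamps(st)
#' @export
scan_clamps <- function(atoms, params = geometry_params(), shells = NULL,
                        include_carboxyl = FALSE) {
  require_roles(atoms)
  roles <- "Oph"
  if (include_carboxyl) roles <- c(roles, "Ocoo")
  cand <- atoms[atoms$role %in% roles, ]
  empty <- tibble::tibble(
    atom_a = integer(), atom_b = integer(), name_a = character(),
    name_b = character(), residue_a = character(), residue_b = character(),
    distance = double(), op_combo = character(),
    sequence_separation = integer(), stabilizer = character(),
    ion_id = integer()
  )
  if (nrow(cand) < 2L) return(as_mg_scan(empty, "mg_clamps"))
  hits <- pairs_within(as.matrix(cand[, c("x", "y", "z")]), params$clamp_dmax)
  hits <- hits[hits$distance < params$clamp_dmax, ]
  a <- cand[hits$i, ]; b <- cand[hits$j, ]
  keep <- residue_key(a) != residue_key(b) &          # distinct groups
    a$b_factor <= params$clamp_bmax & b$b_factor <= params$clamp_bmax &
    a$role == b$role                                  # no mixed Oph/Ocoo
  a <- a[keep, ]; b <- b[keep, ]
  d <- hits$distance[keep]
  if (!nrow(a)) return(as_mg_scan(empty, "mg_clamps"))

  shells <- ensure_shells(atoms, shells, params)
  out <- purrr::map_dfr(seq_len(nrow(a)), function(k) {
    stab <- clamp_stabilizer(a$atom_id[k], b$atom_id[k], atoms, shells,
                             params)
    combo <- if (a$role[k] == "Ocoo") {
      "carboxyl"
    } else {
      paste(sort(c(a$name[k], b$name[k])), collapse = "-")
    }
    tibble::tibble(
      atom_a = a$atom_id[k], atom_b = b$atom_id[k],
      name_a = a$name[k], name_b = b$name[k],
      residue_a = paste0(a$residue_name[k], "/", a$chain_id[k], "/",
                         a$residue_number[k]),
      residue_b = paste0(b$residue_name[k], "/", b$chain_id[k], "/",
                         b$residue_number[k]),
      distance = d[k],
      op_combo = combo,
      sequence_separation = if (a$chain_id[k] == b$chain_id[k]) {
        abs(a$residue_number[k] - b$residue_number[k])
      } else NA_integer_,
      stabilizer = stab$mode,
      ion_id = stab$ion_id
    )
  })
  as_mg_scan(dplyr::arrange(out, .data$distance), "mg_clamps")
}

clamp_stabilizer <- function(id_a, id_b, atoms, shells, params) {
  none <- list(mode = "none_found", ion_id = NA_integer_)
  if (nrow(shells) == 0L) return(none)
  mg <- shells[shells$ion_element %in% c("MG", "ZN"), ]
  if (nrow(mg) == 0L) return(none)
  holds <- function(i, id) id %in% mg$ligands[[i]]$atom_id
  for (i in seq_len(nrow(mg))) {
    if (holds(i, id_a) && holds(i, id_b)) {
      return(list(mode = "direct_bidentate", ion_id = mg$ion_id[i]))
    }
  }
  for (i in seq_len(nrow(mg))) {
    has_a <- holds(i, id_a); has_b <- holds(i, id_b)
    if (xor(has_a, has_b)) {
      free_id <- if (has_a) id_b else id_a
      free <- atoms[atoms$atom_id == free_id, ]
      waters <- mg$ligands[[i]][mg$ligands[[i]]$role == "Ow", ]
      if (!nrow(waters)) next
      wd <- sqrt((waters$x - free$x)^2 + (waters$y - free$y)^2 +
                   (waters$z - free$z)^2)
      n_bridge <- sum(wd >= params$outer_window[1] &
                        wd <= params$outer_window[2])
      if (n_bridge == 1L) {
        return(list(mode = "water_mediated", ion_id = mg$ion_id[i]))
      }
    }
  }
  none
}

as_mg_scan <- function(x, cls) {
  structure(tibble::as_tibble(x), class = c(cls, "mg_scan",
                                            class(tibble::tibble())))
}

#' Scan for trans-2Oph candidate sites
#'
#' Phosphate-oxygen pairs from distinct groups separated by roughly the
#' trans O...O distance (default window 3.9-4.4 A around the 4.13 A
#' mean).  These are candidates only: the trans separation overlaps with
#' common ion-free Oph...Oph distances, so every hit is marked
#' `candidate` and annotated with a Mg inner-shell to both atoms when one
#' exists.
#'
#' @inheritParams scan_clamps
#' @return tibble like [scan_clamps()] with `status = "candidate"` and
#'   `ion_id` (NA when no shared ion).
#' @export
scan_trans_candidates <- function(atoms, params = geometry_params(),
                                  shells = NULL) {
  require_roles(atoms)
  cand <- atoms[atoms$role == "Oph", ]
  empty <- tibble::tibble(
    atom_a = integer(), atom_b = integer(), residue_a = character(),
    residue_b = character(), distance = double(), status = character(),
    ion_id = integer()
  )
  if (nrow(cand) < 2L) return(as_mg_scan(empty, "mg_trans_candidates"))
  w <- params$trans_candidate_window
  hits <- pairs_within(as.matrix(cand[, c("x", "y", "z")]), w[2])
  hits <- hits[hits$distance >= w[1], ]
  a <- cand[hits$i, ]; b <- cand[hits$j, ]
  keep <- residue_key(a) != residue_key(b)
  a <- a[keep, ]; b <- b[keep, ]; d <- hits$distance[keep]
  if (!nrow(a)) return(as_mg_scan(empty, "mg_trans_candidates"))
  shells <- ensure_shells(atoms, shells, params)
  inner <- inner_shell_index(shells[shells$ion_element %in% c("MG", "ZN"), ])
  shared_ion <- function(id_a, id_b) {
    ions <- intersect(inner$ion_id[inner$atom_id == id_a],
                      inner$ion_id[inner$atom_id == id_b])
    if (length(ions)) ions[1] else NA_integer_
  }
  out <- tibble::tibble(
    atom_a = a$atom_id, atom_b = b$atom_id,
    residue_a = paste0(a$residue_name, "/", a$chain_id, "/",
                       a$residue_number),
    residue_b = paste0(b$residue_name, "/", b$chain_id, "/",
                       b$residue_number),
    distance = d,
    status = "candidate",
    ion_id = purrr::map2_int(a$atom_id, b$atom_id, shared_ion)
  )
  as_mg_scan(dplyr::arrange(out, .data$distance), "mg_trans_candidates")
}

#' Scan for head-to-tail stacked purine N7 seats
#'
#' The only nucleobase arrangement that brings two purine N7 atoms within
#' 3.4 A of each other is the head-to-tail stack that seats a
#' cis-2Nb.4Ow ion; ordinarily stacked purines keep their N7 atoms
#' beyond about 3.8 A.  Reports all inter-residue purine N7 pairs below
#' the cutoff, annotated with any metal inner-shell to both nitrogens.
#'
#' @inheritParams scan_clamps
#' @return tibble: atom ids, residues, `distance`, `ion_id`.
#' @export
scan_purine_seats <- function(atoms, params = geometry_params(),
                              shells = NULL) {
  require_roles(atoms)
  aliases <- base_aliases()
  resname <- toupper(atoms$residue_name)
  parent <- aliases$parent[match(resname, toupper(aliases$residue_name))]
  base <- dplyr::coalesce(parent, resname)
  cand <- atoms[atoms$name == "N7" & base %in% c("A", "G"), ]
  empty <- tibble::tibble(
    atom_a = integer(), atom_b = integer(), residue_a = character(),
    residue_b = character(), distance = double(), ion_id = integer()
  )
  if (nrow(cand) < 2L) return(as_mg_scan(empty, "mg_purine_seats"))
  hits <- pairs_within(as.matrix(cand[, c("x", "y", "z")]),
                       params$clamp_dmax)
  hits <- hits[hits$distance < params$clamp_dmax, ]
  a <- cand[hits$i, ]; b <- cand[hits$j, ]
  keep <- residue_key(a) != residue_key(b)
  a <- a[keep, ]; b <- b[keep, ]; d <- hits$distance[keep]
  if (!nrow(a)) return(as_mg_scan(empty, "mg_purine_seats"))
  shells <- ensure_shells(atoms, shells, params)
  inner <- inner_shell_index(shells)
  shared_ion <- function(id_a, id_b) {
    ions <- intersect(inner$ion_id[inner$atom_id == id_a],
                      inner$ion_id[inner$atom_id == id_b])
    if (length(ions)) ions[1] else NA_integer_
  }
  out <- tibble::tibble(
    atom_a = a$atom_id, atom_b = b$atom_id,
    residue_a = paste0(a$residue_name, "/", a$chain_id, "/",
                       a$residue_number),
    residue_b = paste0(b$residue_name, "/", b$chain_id, "/",
                       b$residue_number),
    distance = d,
    ion_id = purrr::map2_int(a$atom_id, b$atom_id, shared_ion)
  )
  as_mg_scan(dplyr::arrange(out, .data$distance), "mg_purine_seats")
}

#' Scan for O2'(n)...OP(n+1) proximity motifs
#'
#' Finds ribose O2' atoms of residue n within 3.4 A of an OP1/OP2 atom of
#' the next residue (n+1) of the same chain -- the rare backbone turn
#' that, when a Mg coordinates the O2', produces the
#' Cis-3Oph.Or.2Ow / fac-2Oph.Or.3Ow six-membered-ring motifs (typical
#' observed separations are near 3.0 A, versus > 3.4 A in canonical
#' helices).  Hits without a coordinated Mg are candidate sites.
#'
#' @inheritParams scan_clamps
#' @return tibble: `o2_id`, `op_id`, `op_name`, residues, `distance`,
#'   `ion_id` (Mg inner-shell to the O2', NA when none).
#' @export
scan_o2p_motifs <- function(atoms, params = geometry_params(),
                            shells = NULL) {
  require_roles(atoms)
  o2 <- atoms[atoms$name == "O2'" & atoms$role == "Or", ]
  op <- atoms[atoms$role == "Oph", ]
  empty <- tibble::tibble(
    o2_id = integer(), op_id = integer(), op_name = character(),
    residue_o2 = character(), residue_op = character(),
    distance = double(), ion_id = integer()
  )
  if (!nrow(o2) || !nrow(op)) return(as_mg_scan(empty, "mg_o2p_motifs"))
  cand <- dplyr::inner_join(
    dplyr::mutate(o2, .next = .data$residue_number + 1L),
    op,
    by = c("chain_id", ".next" = "residue_number"),
    suffix = c("_o2", "_op"), relationship = "many-to-many"
  )
  if (!nrow(cand)) return(as_mg_scan(empty, "mg_o2p_motifs"))
  d <- sqrt((cand$x_o2 - cand$x_op)^2 + (cand$y_o2 - cand$y_op)^2 +
              (cand$z_o2 - cand$z_op)^2)
  cand <- cand[d <= params$clamp_dmax, ]
  d <- d[d <= params$clamp_dmax]
  if (!nrow(cand)) return(as_mg_scan(empty, "mg_o2p_motifs"))
  shells <- ensure_shells(atoms, shells, params)
  inner <- inner_shell_index(shells[shells$ion_element %in% c("MG", "ZN"), ])
  ion_of <- function(id) {
    ions <- inner$ion_id[inner$atom_id == id]
    if (length(ions)) ions[1] else NA_integer_
  }
  out <- tibble::tibble(
    o2_id = cand$atom_id_o2, op_id = cand$atom_id_op,
    op_name = cand$name_op,
    residue_o2 = paste0(cand$residue_name_o2, "/", cand$chain_id, "/",
                        cand$residue_number),
    residue_op = paste0(cand$residue_name_op, "/", cand$chain_id, "/",
                        cand$.next),
    distance = d,
    ion_id = purrr::map_int(cand$atom_id_o2, ion_of)
  )
  as_mg_scan(dplyr::arrange(out, .data$distance), "mg_o2p_motifs")
}
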