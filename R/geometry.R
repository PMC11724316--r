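#' Build first coordination shells around every metal
#'
#' For each metal ion, collects O/N ligand atoms whose role is one of the
#' coordinating categories and whose distance falls in the
#' element-appropriate acceptance window (Mg: 1.9-2.3 A, K: 2.6-3.2 A).
#' Carbon, phosphorus and other metals are never ligands; neither are
#' hydrogens nor atoms below the occupancy cutoff.  For Mg the O/N atoms
#' in the (2.3, 3.4] exclusion zone are inventoried separately: a
#' correctly modelled Mg site has none.  All ligand-ion-ligand angles are
#' computed, each pair is tagged cis/trans (cut at 135 degrees), and
#' hexacoordinated shells receive an octahedral-distortion score and
#' category (`correct` < 5, `slightly_distorted` 5-10,
#' `highly_distorted` > 10 degrees; other coordination numbers are
#' `not_octahedral`).
#'
#' @param atoms an `mg_structure` with roles assigned.
#' @param params a [geometry_params()] object.
#' @return an `mg_shells` tibble, one row per metal: ion identity columns
#'   (`ion_id`, `ion_element`, `ion_chain`, `ion_resno`, `ion_label`),
#'   `coordination_number`, `n_exclusion`, `distortion` (mean absolute
#'   angular deviation, degrees), `distortion_sum` (the same deviation
#'   summed over the 15 angle slots), `distortion_category`, and
#'   list-columns `ligands`, `exclusion`, `angles`.
#' @examples
#' st <- assign_roles(make_fixture("ideal_6Ow")$atoms)
#' build_shells(st)
#' @export
build_shells <- function(atoms, params = geometry_params()) {
  require_roles(atoms)
  ions <- dplyr::filter(atoms, .data$role == "metal")
  shells <- purrr::map(seq_len(nrow(ions)),
                       function(i) build_shell(atoms, ions[i, ], params))
  out <- dplyr::bind_rows(shells)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      ion_id = integer(), ion_element = character(), ion_chain = character(),
      ion_resno = integer(), ion_label = character(), ion_occupancy = double(),
      coordination_number = integer(), n_exclusion = integer(),
      distortion = double(), distortion_sum = double(),
      distortion_category = character(),
      ligands = list(), exclusion = list(), angles = list()
    )
  }
  structure(out, class = c("mg_shells", class(tibble::tibble())),
            params = params)
}

#' Build the coordination shell of a single ion
#'
#' @param atoms an `mg_structure` with roles assigned.
#' @param ion a single-row tibble (one metal atom) or an `atom_id`.
#' @param params a [geometry_params()] object.
#' @return one-row `mg_shells`-shaped tibble (see [build_shells()]).
#' @export
build_shell <- function(atoms, ion, params = geometry_params()) {
  require_roles(atoms)
  if (!is.data.frame(ion)) ion <- atoms[atoms$atom_id == ion, ]
  stopifnot(nrow(ion) == 1L)
  if (ion$role != "metal") rlang::abort("build_shell: atom is not a metal")
  centre <- c(ion$x, ion$y, ion$z)
  window <- element_window(ion$element, params)
  probe_r <- max(window[2], params$mg_exclusion[2])
  near <- neighbors(atoms, centre, probe_r)
  near <- dplyr::filter(near, .data$atom_id != ion$atom_id)

  on_mask <- toupper(near$element) %in% c("O", "N")
  lig <- near[on_mask &
                near$role %in% LIGAND_ROLES &
                near$occupancy >= params$min_occupancy &
                near$distance >= window[1] & near$distance <= window[2], ]
  is_mg <- toupper(ion$element) %in% c("MG", "ZN")
  if (is_mg) {
    excl <- near[on_mask &
                   near$distance > params$mg_exclusion[1] &
                   near$distance <= params$mg_exclusion[2], ]
  } else {
    excl <- near[0, ]
  }

  n_lig <- nrow(lig)
  ang <- shell_angles(centre, lig, params)
  dist_info <- octahedral_distortion(
    centre, as.matrix(lig[, c("x", "y", "z")]), params)

  tibble::tibble(
    ion_id = ion$atom_id,
    ion_element = toupper(ion$element),
    ion_chain = ion$chain_id,
    ion_resno = ion$residue_number,
    ion_label = paste0(ion$residue_name, "/", ion$chain_id, "/",
                       ion$residue_number),
    ion_occupancy = ion$occupancy,
    coordination_number = n_lig,
    n_exclusion = nrow(excl),
    distortion = dist_info$mean_dev,
    distortion_sum = dist_info$sum_dev,
    distortion_category = dist_info$category,
    ligands = list(tibble::as_tibble(lig)),
    exclusion = list(tibble::as_tibble(excl)),
    angles = list(ang)
  )
}

shell_angles <- function(centre, lig, params) {
  n <- nrow(lig)
  if (n < 2L) {
    return(tibble::tibble(i = integer(), j = integer(),
                          atom_i = integer(), atom_j = integer(),
                          angle = double(), geometry = character()))
  }
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  pairs <- utils::combn(n, 2)
  angle <- apply(pairs, 2, function(p) {
    point_angle(xyz[p[1], ], centre, xyz[p[2], ])
  })
  tibble::tibble(
    i = pairs[1, ], j = pairs[2, ],
    atom_i = lig$atom_id[pairs[1, ]], atom_j = lig$atom_id[pairs[2, ]],
    angle = angle,
    geometry = ifelse(angle <= params$cis_trans_cut, "cis", "trans")
  )
}

#' Octahedral distortion of a six-ligand shell
#'
#' Assigns the six ligands to ideal octahedron vertices by exact
#' minimisation (equivalently: the best of the 15 pairings of ligands
#' into three trans pairs) and reports the mean absolute deviation of the
#' 12 cis angles from 90 degrees and the 3 trans angles from 180 degrees.
#' The summed deviation over the 15 angle slots is reported alongside.
#' Categories: `correct` (< 5 degrees), `slightly_distorted` (5-10),
#' `highly_distorted` (> 10); any coordination number other than six is
#' `not_octahedral` with an undefined value.
#'
#' @param centre numeric xyz of the ion.
#' @param ligand_xyz numeric matrix, one ligand per row.
#' @param params a [geometry_params()] object (category thresholds).
#' @return list with `mean_dev`, `sum_dev` (degrees), `category`, and
#'   `trans_pairs` (3 x 2 matrix of ligand row indices, or NULL).
#' @examples
#' oct <- 2.07 * rbind(diag(3), -diag(3))
#' octahedral_distortion(c(0, 0, 0), oct)$mean_dev
#' @export
octahedral_distortion <- function(centre, ligand_xyz,
                                  params = geometry_params()) {
  if (is.null(dim(ligand_xyz))) ligand_xyz <- matrix(ligand_xyz, ncol = 3)
  n <- nrow(ligand_xyz)
  if (n != 6L) {
    return(list(mean_dev = NA_real_, sum_dev = NA_real_,
                category = "not_octahedral", trans_pairs = NULL))
  }
  ang <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6) {
    ang[i, j] <- ang[j, i] <-
      point_angle(ligand_xyz[i, ], centre, ligand_xyz[j, ])
  }
  matchings <- trans_matchings()
  best <- Inf; best_m <- NULL
  for (m in matchings) {
    trans_dev <- sum(abs(ang[m] - 180))
    cis_dev <- sum(abs(ang[upper.tri(ang)] - 90)) -
      sum(abs(ang[m] - 90))
    total <- trans_dev + cis_dev
    if (total < best) { best <- total; best_m <- m }
  }
  mean_dev <- best / 15
  category <- if (mean_dev < params$distortion_correct_max) {
    "correct"
  } else if (mean_dev <= params$distortion_slight_max) {
    "slightly_distorted"
  } else "highly_distorted"
  list(mean_dev = mean_dev, sum_dev = best, category = category,
       trans_pairs = best_m)
}

# The 15 perfect matchings of {1..6} into three unordered pairs, each as a
# 3 x 2 index matrix usable for matrix indexing into the angle matrix.
trans_matchings <- function() {
  res <- list()
  others <- 2:6
  for (a in others) {
    rest <- setdiff(others, a)
    first <- rest[1]
    for (b in setdiff(rest, first)) {
      last <- setdiff(rest, c(first, b))
      res[[length(res) + 1L]] <-
        rbind(c(1L, a), c(first, b), last)
    }
  }
  res
}

#' cis/trans geometry of a ligand pair
#'
#' A ligand-ion-ligand angle at or below 135 degrees (midpoint between the
#' modal cis 90 and trans 177 values) is `cis`, otherwise `trans`.
#'
#' @param shell one row of an [build_shells()] result.
#' @param ligand_a,ligand_b `atom_id`s of two ligands in the shell.
#' @param params a [geometry_params()] object.
#' @return `"cis"` or `"trans"`.
#' @export
cis_trans <- function(shell, ligand_a, ligand_b, params = geometry_params()) {
  ang <- shell$angles[[1]]
  hit <- ang[(ang$atom_i == ligand_a & ang$atom_j == ligand_b) |
               (ang$atom_i == ligand_b & ang$atom_j == ligand_a), ]
  if (nrow(hit) != 1L) rlang::abort("ligand pair not found in shell")
  ifelse(hit$angle <= params$cis_trans_cut, "cis", "trans")
}

#' Phosphate-group geometry of Oph ligands
#'
#' For every phosphate-oxygen ligand of a shell, reports the P-OP...ion
#' angle at the coordinated OP atom and the unsigned distance from the ion
#' to the plane through P, OP1 and OP2 of the parent phosphate group.  In
#' well-formed monodentate sites the angle clusters near 148 +/- 10
#' degrees with the ion close to the OP1-P-OP2 plane (mean deviation
#' about 0.7 A).
#'
#' @param atoms the `mg_structure` the shell was built from.
#' @param shell one row of a [build_shells()] result.
#' @return tibble with one row per Oph ligand: `atom_id`, `op_name`,
#'   `residue`, `p_op_ion_angle` (degrees), `plane_distance` (A),
#'   `available` (FALSE when the parent P/OP sibling is missing).
#' @export
phosphate_geometry <- function(atoms, shell) {
  lig <- shell$ligands[[1]]
  oph <- lig[lig$role == "Oph", ]
  centre <- ion_xyz(atoms, shell)
  if (nrow(oph) == 0L) {
    return(tibble::tibble(atom_id = integer(), op_name = character(),
                          residue = character(), p_op_ion_angle = double(),
                          plane_distance = double(), available = logical()))
  }
  purrr::map_dfr(seq_len(nrow(oph)), function(k) {
    o <- oph[k, ]
    sib <- atoms[atoms$chain_id == o$chain_id &
                   atoms$residue_number == o$residue_number &
                   atoms$icode == o$icode &
                   atoms$name %in% c("P", "OP1", "OP2"), ]
    out <- tibble::tibble(
      atom_id = o$atom_id, op_name = o$name,
      residue = paste0(o$residue_name, "/", o$chain_id, "/",
                       o$residue_number),
      p_op_ion_angle = NA_real_, plane_distance = NA_real_,
      available = FALSE
    )
    p <- sib[sib$name == "P", ]
    if (nrow(p) != 1L || nrow(sib) != 3L) return(out)
    op1 <- sib[sib$name == "OP1", ]; op2 <- sib[sib$name == "OP2", ]
    out$p_op_ion_angle <- point_angle(
      c(p$x, p$y, p$z), c(o$x, o$y, o$z), centre)
    nrm <- cross3(c(op1$x, op1$y, op1$z) - c(p$x, p$y, p$z),
                  c(op2$x, op2$y, op2$z) - c(p$x, p$y, p$z))
    nrm <- nrm / sqrt(sum(nrm^2))
    out$plane_distance <- abs(sum((centre - c(p$x, p$y, p$z)) * nrm))
    out$available <- TRUE
    out
  })
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

ion_xyz <- function(atoms, shell) {
  ion <- atoms[atoms$atom_id == shell$ion_id, ]
  c(ion$x, ion$y, ion$z)
}

# Ring atom names per parent base (purine/pyrimidine cores).
RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"),
  `T` = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# Bonded ring carbon of each exocyclic carbonyl oxygen.
OB_PARENT_C <- c(O2 = "C2", O4 = "C4", O6 = "C6")

#' Nucleobase geometry of Ob/Nb ligands
#'
#' For carbonyl-oxygen (Ob) ligands: the C=O...ion angle at the oxygen and
#' the unsigned distance of the ion from the least-squares base plane
#' (well-formed sites cluster near 144 degrees with the ion in-plane).
#' For ring-nitrogen (Nb) ligands: the angle between the in-plane lone
#' pair direction (exterior bisector of the two ring bonds at N) and the
#' N...ion vector (0 degrees = perfectly aligned), plus the same
#' plane distance.
#'
#' @inheritParams phosphate_geometry
#' @return tibble, one row per Ob/Nb ligand: `atom_id`, `name`, `role`,
#'   `residue`, `angle` (degrees; C=O...ion for Ob, lone-pair deviation
#'   for Nb), `plane_distance` (A), `available`.
#' @export
base_geometry <- function(atoms, shell) {
  lig <- shell$ligands[[1]]
  tgt <- lig[lig$role %in% c("Ob", "Nb"), ]
  centre <- ion_xyz(atoms, shell)
  if (nrow(tgt) == 0L) {
    return(tibble::tibble(atom_id = integer(), name = character(),
                          role = character(), residue = character(),
                          angle = double(), plane_distance = double(),
                          available = logical()))
  }
  aliases <- base_aliases()
  purrr::map_dfr(seq_len(nrow(tgt)), function(k) {
    o <- tgt[k, ]
    out <- tibble::tibble(
      atom_id = o$atom_id, name = o$name, role = o$role,
      residue = paste0(o$residue_name, "/", o$chain_id, "/",
                       o$residue_number),
      angle = NA_real_, plane_distance = NA_real_, available = FALSE
    )
    resname <- toupper(o$residue_name)
    parent <- aliases$parent[match(resname, toupper(aliases$residue_name))]
    base <- if (!is.na(parent)) parent else resname
    ring_names <- RING_ATOMS[[base]]
    if (is.null(ring_names)) return(out)
    res <- atoms[atoms$chain_id == o$chain_id &
                   atoms$residue_number == o$residue_number &
                   atoms$icode == o$icode, ]
    ring <- res[match(ring_names, res$name), ]
    if (anyNA(ring$atom_id)) return(out)
    ring_xyz <- as.matrix(ring[, c("x", "y", "z")])
    fit <- lsq_plane(ring_xyz)
    out$plane_distance <- abs(sum((centre - fit$centroid) * fit$normal))
    if (o$role == "Ob") {
      cname <- OB_PARENT_C[[o$name]]
      cat_row <- res[res$name == cname, ]
      if (nrow(cat_row) == 1L) {
        out$angle <- point_angle(c(cat_row$x, cat_row$y, cat_row$z),
                                 c(o$x, o$y, o$z), centre)
        out$available <- TRUE
      }
    } else {
      nbrs <- ring_neighbors(o$name, base)
      nb_rows <- res[match(nbrs, res$name), ]
      if (!anyNA(nb_rows$atom_id)) {
        npos <- c(o$x, o$y, o$z)
        u1 <- unit(c(nb_rows$x[1], nb_rows$y[1], nb_rows$z[1]) - npos)
        u2 <- unit(c(nb_rows$x[2], nb_rows$y[2], nb_rows$z[2]) - npos)
        lp <- unit(-(u1 + u2))
        out$angle <- vec_angle(lp, centre - npos)
        out$available <- TRUE
      }
    }
    out
  })
}

unit <- function(v) v / sqrt(sum(v^2))

# Ring bond partners of each coordinating nitrogen.
ring_neighbors <- function(name, base) {
  purine <- base %in% c("A", "G")
  switch(name,
    N7 = c("C5", "C8"),
    N1 = if (purine) c("C2", "C6") else c("C2", "C6"),
    N3 = if (purine) c("C2", "C4") else c("C2", "C4"),
    rlang::abort(paste0("no ring template for nitrogen ", name))
  )
}

# Least-squares plane: centroid + unit normal (smallest principal axis).
lsq_plane <- function(xyz) {
  centroid <- colMeans(xyz)
  centred <- sweep(xyz, 2, centroid)
  sv <- svd(centred)
  list(centroid = centroid, normal = sv$v[, 3])
}

#' Water-mediated (outer-shell) contacts of a shell
#'
#' For each first-shell water of the ion, finds all non-water O/N atoms in
#' the hydrogen-bond window (default 2.6-3.2 A), excluding atoms that are
#' already inner-shell to the same ion.  Each (water, acceptor) pair is
#' counted once.
#'
#' @inheritParams phosphate_geometry
#' @param params a [geometry_params()] object.
#' @return tibble: `water_id`, `acceptor_id`, `acceptor_name`,
#'   `acceptor_role`, `acceptor_residue`, `distance`.
#' @export
outer_shell_contacts <- function(atoms, shell, params = geometry_params()) {
  lig <- shell$ligands[[1]]
  waters <- lig[lig$role == "Ow", ]
  inner_ids <- c(lig$atom_id, shell$ion_id)
  purrr::map_dfr(seq_len(nrow(waters)), function(k) {
    w <- waters[k, ]
    near <- neighbors(atoms, c(w$x, w$y, w$z), params$outer_window[2])
    near <- near[toupper(near$element) %in% c("O", "N") &
                   near$role != "Ow" &
                   !(near$atom_id %in% inner_ids) &
                   near$distance >= params$outer_window[1], ]
    if (!nrow(near)) return(NULL)
    tibble::tibble(
      water_id = w$atom_id,
      acceptor_id = near$atom_id,
      acceptor_name = near$name,
      acceptor_role = near$role,
      acceptor_residue = paste0(near$residue_name, "/", near$chain_id, "/",
                                near$residue_number),
      distance = near$distance
    )
  })
}
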