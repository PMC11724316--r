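#' Detect bridged metal-metal pairs
#'
#' An ion pair is two metals within `dmax` (default 5.5 A) that share at
#' least one (and up to three) bridging first-shell ligand -- water or
#' O/N atom -- or a bridging phosphate group (a residue contributing an
#' OP atom inner-shell to each ion, possibly different OP atoms of the
#' same group).  Sharing is evaluated under each metal's own acceptance
#' window.
#'
#' @param atoms an `mg_structure` with roles.
#' @param shells a [build_shells()] result (built if omitted).
#' @param params a [geometry_params()] object.
#' @param dmax maximum inter-metal distance, A.
#' @return `mg_pairs` tibble: ion ids/elements/labels, `distance`,
#'   `shared_waters`, `shared_nonwater`, `shared_phosphate_groups`,
#'   `class_label`, `suffix`, `note`.
#' @examples
#' fx <- make_fixture("mgC_pair")
#' st <- assign_roles(fx$atoms)
#' find_ion_pairs(st)
#' @export
find_ion_pairs <- function(atoms, shells = NULL, params = geometry_params(),
                           dmax = params$pair_dmax) {
  require_roles(atoms)
  shells <- ensure_shells(atoms, shells, params)
  empty <- tibble::tibble(
    ion_a = integer(), ion_b = integer(), element_a = character(),
    element_b = character(), label_a = character(), label_b = character(),
    distance = double(), shared_waters = integer(),
    shared_nonwater = integer(), shared_phosphate_groups = integer(),
    class_label = character(), suffix = integer(), note = character()
  )
  if (nrow(shells) < 2L) return(as_mg_scan(empty, "mg_pairs"))
  ions <- atoms[match(shells$ion_id, atoms$atom_id), ]
  hits <- pairs_within(as.matrix(ions[, c("x", "y", "z")]), dmax)
  if (!nrow(hits)) return(as_mg_scan(empty, "mg_pairs"))
  out <- purrr::map_dfr(seq_len(nrow(hits)), function(k) {
    i <- hits$i[k]; j <- hits$j[k]
    lig_i <- shells$ligands[[i]]; lig_j <- shells$ligands[[j]]
    shared_ids <- intersect(lig_i$atom_id, lig_j$atom_id)
    shared <- lig_i[lig_i$atom_id %in% shared_ids, ]
    ph_i <- unique(residue_key(lig_i[lig_i$role == "Oph", ]))
    ph_j <- unique(residue_key(lig_j[lig_j$role == "Oph", ]))
    shared_ph <- length(intersect(ph_i, ph_j))
    n_w <- sum(shared$role == "Ow")
    n_nw <- sum(shared$role != "Ow")
    if (n_w + n_nw == 0L && shared_ph == 0L) return(NULL)
    pair <- tibble::tibble(
      ion_a = shells$ion_id[i], ion_b = shells$ion_id[j],
      element_a = shells$ion_element[i], element_b = shells$ion_element[j],
      label_a = shells$ion_label[i], label_b = shells$ion_label[j],
      distance = hits$distance[k],
      shared_waters = n_w, shared_nonwater = n_nw,
      shared_phosphate_groups = shared_ph
    )
    cls <- classify_pair(pair, params)
    pair$class_label <- cls$class_label
    pair$suffix <- cls$suffix
    pair$note <- cls$note
    pair
  })
  if (is.null(out) || nrow(out) == 0L) return(as_mg_scan(empty, "mg_pairs"))
  as_mg_scan(dplyr::arrange(out, .data$distance), "mg_pairs")
}

#' Classify a metal-metal pair into the micro-cluster taxonomy
#'
#' Mg...Mg pairs, by inter-metal distance d:
#' \itemize{
#'   \item `MgA_uc<k>`: d in 4.2-5.5 A bridged by k >= 1 phosphate
#'     group(s) (typical observed separations 4.5-5.3 A);
#'   \item `MgB_uc<k>`: d in 3.2-4.2 A (upper edge open) (exemplar 3.8 A);
#'   \item `MgC_uc<k>`: d in 2.6-3.2 A (both edges open) (exemplar 2.7-2.8 A);
#'   \item `MgD_uc<k>`: d <= 2.6 A (exemplar 2.38 A); always carries the
#'     note `requires independent confirmation`.
#' }
#' For MgB/C/D the suffix k is the number of shared ligands (waters plus
#' O/N atoms, 1-3); for MgA it is the number of shared phosphate groups.
#' Mg...K pairs with d in 3.5-4.4 A sharing 2 or 3 ligands are
#' `MgK_uc2`/`MgK_uc3`.  Everything else is `unclassified` with a
#' machine-readable reason.  The classification is symmetric in the two
#' ions.
#'
#' @param pair one row of a [find_ion_pairs()] result (the shared-ligand
#'   inventory must be present).
#' @param params a [geometry_params()] object.
#' @return list with `class_label`, `suffix`, `note`.
#' @export
classify_pair <- function(pair, params = geometry_params()) {
  d <- pair$distance
  els <- sort(c(pair$element_a, pair$element_b))
  n_shared <- pair$shared_waters + pair$shared_nonwater
  both_mg <- all(els == "MG")
  mg_k <- identical(els, c("K", "MG"))
  un <- function(reason) list(class_label = "unclassified", suffix = NA_integer_,
                              note = reason)
  if (both_mg) {
    if (d <= params$mgd_max) {
      if (n_shared < 1L) return(un("no shared ligand"))
      return(list(class_label = paste0("MgD_uc", min(n_shared, 3L)),
                  suffix = min(n_shared, 3L),
                  note = "requires independent confirmation"))
    }
    if (d < params$mgc_max) {
      if (n_shared < 1L) return(un("no shared ligand"))
      return(list(class_label = paste0("MgC_uc", min(n_shared, 3L)),
                  suffix = min(n_shared, 3L), note = ""))
    }
    if (d < params$mgb_max) {
      if (n_shared < 1L) return(un("no shared ligand"))
      return(list(class_label = paste0("MgB_uc", min(n_shared, 3L)),
                  suffix = min(n_shared, 3L), note = ""))
    }
    if (d <= params$pair_dmax) {
      if (pair$shared_phosphate_groups >= 1L) {
        k <- min(pair$shared_phosphate_groups, 3L)
        return(list(class_label = paste0("MgA_uc", k), suffix = k,
                    note = ""))
      }
      return(un("no bridging phosphate group in the MgA distance range"))
    }
    return(un("beyond pair distance cutoff"))
  }
  if (mg_k) {
    if (d >= params$mgk_window[1] && d <= params$mgk_window[2] &&
        n_shared %in% c(2L, 3L)) {
      return(list(class_label = paste0("MgK_uc", n_shared),
                  suffix = n_shared, note = ""))
    }
    return(un("Mg-K pair outside the MgK distance/sharing definition"))
  }
  un(paste0("element combination ", paste(els, collapse = "-"),
            " outside the Mg-Mg / Mg-K taxonomy"))
}

#' Assemble ion pairs into multi-ion chains
#'
#' Treats classified pairs as edges of a graph over ions and returns its
#' connected components -- the extended ion chains built from
#' micro-clusters sharing members.
#'
#' @param pairs a [find_ion_pairs()] result.
#' @return tibble: `component`, `n_ions`, `members` (list of ion ids),
#'   `labels` (list of ion labels), `edge_classes` (list of the pair
#'   classes inside the component).
#' @export
assemble_chains <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(component = integer(), n_ions = integer(),
                          members = list(), labels = list(),
                          edge_classes = list()))
  }
  verts <- unique(c(pairs$ion_a, pairs$ion_b))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs$ion_a),
               to = as.character(pairs$ion_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(verts))
  )
  comp <- igraph::components(g)
  membership <- comp$membership
  label_of <- stats::setNames(c(pairs$label_a, pairs$label_b),
                              c(pairs$ion_a, pairs$ion_b))
  purrr::map_dfr(seq_len(comp$no), function(ci) {
    ids <- as.integer(names(membership)[membership == ci])
    edge_sel <- pairs$ion_a %in% ids | pairs$ion_b %in% ids
    tibble::tibble(
      component = ci,
      n_ions = length(ids),
      members = list(sort(ids)),
      labels = list(unname(label_of[as.character(sort(ids))])),
      edge_classes = list(pairs$class_label[edge_sel])
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$n_ions), .data$component)
}
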