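#' Canonical nomenclature label of a hexacoordinated shell
#'
#' Assembles the binding-site name from the multiset of ligand categories
#' in canonical order (Oph > Or > Ob > Nb > Ocoo > Obb > Ocno > OHprot >
#' Ow > NHis) with multiplicity digits ("1" omitted), e.g. `2Oph.4Ow` for
#' an ion bound to two phosphate oxygens and four waters.  Isomer prefix
#' rules, by number of non-water ligands:
#' \itemize{
#'   \item 2: `cis-`/`trans-` by the mutual ligand-ion-ligand angle;
#'   \item 3: `fac-` when the three are mutually cis, else `mer-`;
#'   \item 4: `Cis-`/`Trans-` (capitalised) by the mutual angle of the two
#'     remaining waters;
#'   \item 0, 1, 5 or 6: no prefix.
#' }
#' Shells that are not hexacoordinated receive no label (`NA`); they are
#' reported through [diagnose_ions()] instead.
#'
#' @param shell one row of a [build_shells()] result.
#' @param params a [geometry_params()] object.
#' @return list with `text` (e.g. `"cis-2Oph.4Ow"`), `prefix`, and
#'   `counts` (named integer vector over categories).
#' @examples
#' st <- assign_roles(make_fixture("cis_clamp")$atoms)
#' label_site(build_shells(st)[1, ])$text
#' @export
label_site <- function(shell, params = geometry_params()) {
  lig <- shell$ligands[[1]]
  counts <- table(factor(lig$role, levels = LABEL_ORDER))
  counts <- counts[counts > 0]
  if (shell$coordination_number != 6L) {
    return(list(text = NA_character_, prefix = NA_character_,
                counts = counts))
  }
  ang <- shell$angles[[1]]
  nonwater <- which(lig$role != "Ow")
  water <- which(lig$role == "Ow")
  pair_geom <- function(i, j) {
    hit <- ang[(ang$i == i & ang$j == j) | (ang$i == j & ang$j == i), ]
    hit$geometry
  }
  n_nw <- length(nonwater)
  prefix <- ""
  if (n_nw == 2L) {
    prefix <- if (pair_geom(nonwater[1], nonwater[2]) == "cis") {
      "cis-"
    } else "trans-"
  } else if (n_nw == 3L) {
    geoms <- c(pair_geom(nonwater[1], nonwater[2]),
               pair_geom(nonwater[1], nonwater[3]),
               pair_geom(nonwater[2], nonwater[3]))
    prefix <- if (all(geoms == "cis")) "fac-" else "mer-"
  } else if (n_nw == 4L) {
    prefix <- if (pair_geom(water[1], water[2]) == "cis") "Cis-" else "Trans-"
  }
  body <- paste0(ifelse(counts > 1, counts, ""), names(counts),
                 collapse = ".")
  list(text = paste0(prefix, body), prefix = prefix, counts = counts)
}

#' Label every shell in a shell table
#'
#' @param shells a [build_shells()] result.
#' @param params a [geometry_params()] object.
#' @return the input with `label` and `prefix` columns appended.
#' @export
label_sites <- function(shells, params = geometry_params()) {
  labs <- purrr::map(seq_len(nrow(shells)),
                     function(i) label_site(shells[i, ], params))
  shells$label <- purrr::map_chr(labs, "text")
  shells$prefix <- purrr::map_chr(labs, "prefix")
  shells
}

DIAG_FLAGS <- c("incomplete_shell", "exclusion_zone_contact",
                "likely_K_as_Mg", "likely_Mg_as_K", "likely_water",
                "not_octahedral", "low_density", "low_occupancy")

#' Diagnose possible ion-assignment problems
#'
#' Screens every metal for the classic modelling flaws: coordination
#' distances beyond the Mg 2.3 A limit, incomplete shells, and
#' misassigned ions.  Flags (per ion):
#' \itemize{
#'   \item `incomplete_shell`: Mg with fewer than six ligands;
#'   \item `exclusion_zone_contact`: O/N atoms in the Mg (2.3, 3.4] zone;
#'   \item `likely_K_as_Mg`: a Mg-labelled ion with >= 6 O/N in the K
#'     window (2.6-3.2 A) and < 4 in the Mg window -- the heptahedral
#'     d(Mg...O) = 2.8 A signature of a K+ modelled as Mg2+;
#'   \item `likely_Mg_as_K`: a K-labelled ion with >= 5 O/N in 1.9-2.3 A;
#'   \item `likely_water`: at most 2 O/N contacts in 2.3-3.4 A and none
#'     in the Mg window;
#'   \item `not_octahedral`: coordination number differs from six;
#'   \item `low_density`: density sidecar value below 4.0 sigma;
#'   \item `low_occupancy`: ion occupancy below the cutoff.
#' }
#' An ion is `well_defined` iff it is hexacoordinated, its distortion
#' category is `correct` or `slightly_distorted`, and its density peak
#' (when provided) is at least the 4.0 sigma minimum.
#'
#' @param atoms the `mg_structure` with roles.
#' @param shells a [build_shells()] result.
#' @param density optional sidecar: tibble with columns `ion_id`, `sigma`,
#'   or a path to a TSV with those columns.
#' @param params a [geometry_params()] object.
#' @return tibble, one row per ion: identity columns, `flags` (list-column
#'   of flag names), `well_defined`, and evidence counts
#'   (`n_mg_window`, `n_k_window`, `n_exclusion`, `sigma`).
#' @export
diagnose_ions <- function(atoms, shells, density = NULL,
                          params = geometry_params()) {
  require_roles(atoms)
  if (is.character(density)) {
    density <- readr::read_tsv(density, show_col_types = FALSE)
  }
  if (nrow(shells) == 0L) {
    return(tibble::tibble(
      ion_id = integer(), ion_element = character(), ion_label = character(),
      coordination_number = integer(), distortion = double(),
      distortion_category = character(), n_mg_window = integer(),
      n_k_window = integer(), n_exclusion = integer(), sigma = double(),
      flags = list(), well_defined = logical()
    ))
  }
  purrr::map_dfr(seq_len(nrow(shells)), function(i) {
    sh <- shells[i, ]
    ion <- atoms[atoms$atom_id == sh$ion_id, ]
    near <- neighbors(atoms, c(ion$x, ion$y, ion$z), params$mg_exclusion[2])
    near <- near[near$atom_id != ion$atom_id &
                   toupper(near$element) %in% c("O", "N"), ]
    n_mg <- sum(near$distance >= params$mg_window[1] &
                  near$distance <= params$mg_window[2])
    n_k <- sum(near$distance >= params$k_window[1] &
                 near$distance <= params$k_window[2])
    n_excl <- sum(near$distance > params$mg_exclusion[1] &
                    near$distance <= params$mg_exclusion[2])
    sigma <- NA_real_
    if (!is.null(density)) {
      hit <- density$sigma[match(sh$ion_id, density$ion_id)]
      if (length(hit)) sigma <- hit
    }
    is_mg <- sh$ion_element %in% c("MG", "ZN")
    is_k <- sh$ion_element == "K"
    flags <- character()
    if (is_mg && sh$coordination_number < 6L) {
      flags <- c(flags, "incomplete_shell")
    }
    if (is_mg && sh$n_exclusion > 0L) {
      flags <- c(flags, "exclusion_zone_contact")
    }
    if (is_mg && n_k >= 6L && n_mg < 4L) flags <- c(flags, "likely_K_as_Mg")
    if (is_k && n_mg >= 5L) flags <- c(flags, "likely_Mg_as_K")
    if (is_mg && n_excl <= 2L && n_mg == 0L) {
      flags <- c(flags, "likely_water")
    }
    if (sh$distortion_category == "not_octahedral") {
      flags <- c(flags, "not_octahedral")
    }
    if (!is.na(sigma) && sigma < params$density_min) {
      flags <- c(flags, "low_density")
    }
    if (ion$occupancy < params$min_occupancy) {
      flags <- c(flags, "low_occupancy")
    }
    well <- sh$coordination_number == 6L &&
      sh$distortion_category %in% c("correct", "slightly_distorted") &&
      (is.na(sigma) || sigma >= params$density_min)
    tibble::tibble(
      ion_id = sh$ion_id, ion_element = sh$ion_element,
      ion_label = sh$ion_label,
      coordination_number = sh$coordination_number,
      distortion = sh$distortion,
      distortion_category = sh$distortion_category,
      n_mg_window = n_mg, n_k_window = n_k, n_exclusion = n_excl,
      sigma = sigma,
      flags = list(flags),
      well_defined = well
    )
  })
}

#' Frequency table of binding-site labels
#'
#' @param ions a tibble with `label` and `well_defined` columns (e.g. a
#'   [label_sites()] result joined with [diagnose_ions()], or the `ions`
#'   table of a [run_diagnosis()] report).
#' @return tibble: `label`, `n`, `n_well_defined`, sorted by frequency.
#' @export
summarize_sites <- function(ions) {
  if (nrow(ions) == 0L) {
    return(tibble::tibble(label = character(), n = integer(),
                          n_well_defined = integer()))
  }
  if (!"well_defined" %in% names(ions)) ions$well_defined <- NA
  ions |>
    dplyr::mutate(label = dplyr::coalesce(.data$label, "<unlabelled>")) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     n_well_defined = sum(.data$well_defined %in% TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label)
}
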