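#' Geometry parameter set for ion-site validation
#'
#' Bundles every distance, angle and threshold used by the shell builder,
#' the classifiers and the motif scans.  Defaults are the consensus values
#' for hexacoordinated Mg2+ derived from small-molecule crystallography
#' (first-shell d(Mg...O) = 2.07 +/- 0.04 A, d(Mg...N) = 2.19 +/- 0.08 A,
#' cis/trans coordination angles 90 +/- 3 / 177 +/- 4 degrees) together
#' with the acceptance window (1.9-2.3 A), the O/N exclusion zone
#' (2.3-3.4 A), the K+ window (2.6-3.2 A), the bidentate-clamp screen
#' (d(Oph...Oph) < 3.4 A with B-factors <= 60 A^2) and the ion-pair
#' distance bins.
#'
#' @param ... named overrides for any default listed below.  Unknown keys
#'   are an error; lengths must match the default (windows are length-2
#'   `c(lo, hi)` vectors in Angstrom).
#'
#' @details Defaults:
#' \describe{
#'   \item{mg_o_mean, mg_o_sd}{2.07, 0.04 A; first-shell Mg-O distance.}
#'   \item{mg_n_mean, mg_n_sd}{2.19, 0.08 A; first-shell Mg-N distance.}
#'   \item{mg_window}{c(1.9, 2.3) A; Mg ligand acceptance window.}
#'   \item{mg_exclusion}{c(2.3, 3.4) A; no O/N atom should occur in this
#'     open-closed band around a correctly modelled Mg.}
#'   \item{k_window}{c(2.6, 3.2) A; K+ ligand window.}
#'   \item{k_coord_range}{c(6, 9); plausible K+ coordination numbers.}
#'   \item{cis_angle, cis_tol}{90, 3 degrees.}
#'   \item{trans_angle, trans_tol}{177, 4 degrees.}
#'   \item{cis_oo, cis_oo_sd}{2.93, 0.09 A; O...O across a cis pair.}
#'   \item{trans_oo, trans_oo_sd}{4.13, 0.07 A; O...O across a trans pair.}
#'   \item{cis_trans_cut}{135 degrees; ligand pairs at or below are cis.}
#'   \item{outer_window}{c(2.6, 3.2) A; hydrogen-bond window used for
#'     water-mediated (outer-shell) contacts.}
#'   \item{clamp_dmax, clamp_bmax}{3.4 A, 60 A^2; bidentate-clamp screen.}
#'   \item{trans_candidate_window}{c(3.9, 4.4) A; Oph...Oph window for
#'     trans-2Oph candidates.}
#'   \item{distortion_correct_max, distortion_slight_max}{5, 10 degrees.}
#'   \item{density_min}{4.0 sigma; minimum density peak for a
#'     "well-defined" site when a density sidecar is supplied.}
#'   \item{pair_dmax}{5.5 A; maximum inter-metal distance for ion pairs.}
#'   \item{mgd_max, mgc_max, mgb_max}{2.6, 3.2, 4.2 A; Mg...Mg class bin
#'     edges (<=2.6 MgD; (2.6,3.2) MgC; [3.2,4.2) MgB; [4.2, pair_dmax]
#'     plus a bridging phosphate group MgA).}
#'   \item{mgk_window}{c(3.5, 4.4) A; Mg...K pair distance window.}
#'   \item{min_occupancy}{0.5; atoms below are kept in the table but are
#'     not ligand candidates.}
#' }
#'
#' @return an object of class `mg_params` (a validated named list).
#' @examples
#' p <- geometry_params()
#' p$mg_window
#' geometry_params(clamp_dmax = 3.2)$clamp_dmax
#' @export
geometry_params <- function(...) {
  defaults <- list(
    mg_o_mean = 2.07, mg_o_sd = 0.04,
    mg_n_mean = 2.19, mg_n_sd = 0.08,
    mg_window = c(1.9, 2.3),
    mg_exclusion = c(2.3, 3.4),
    k_window = c(2.6, 3.2),
    k_coord_range = c(6, 9),
    cis_angle = 90, cis_tol = 3,
    trans_angle = 177, trans_tol = 4,
    cis_oo = 2.93, cis_oo_sd = 0.09,
    trans_oo = 4.13, trans_oo_sd = 0.07,
    cis_trans_cut = 135,
    outer_window = c(2.6, 3.2),
    clamp_dmax = 3.4, clamp_bmax = 60,
    trans_candidate_window = c(3.9, 4.4),
    distortion_correct_max = 5, distortion_slight_max = 10,
    density_min = 4.0,
    pair_dmax = 5.5,
    mgd_max = 2.6, mgc_max = 3.2, mgb_max = 4.2,
    mgk_window = c(3.5, 4.4),
    na_window = c(2.2, 2.7),
    min_occupancy = 0.5
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      inherits(overrides[[1L]], "mg_params")) {
    return(overrides[[1L]])
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    rlang::abort(paste0("unknown geometry parameter(s): ",
                        paste(bad, collapse = ", ")))
  }
  for (key in names(overrides)) {
    value <- as.numeric(overrides[[key]])
    if (length(value) != length(defaults[[key]]) || anyNA(value)) {
      rlang::abort(paste0("parameter '", key, "' must be numeric of length ",
                          length(defaults[[key]])))
    }
    defaults[[key]] <- value
  }
  validate_params(structure(defaults, class = "mg_params"))
}

validate_params <- function(p) {
  stopifnot(
    p$mg_window[1] < p$mg_window[2],
    p$mg_exclusion[1] < p$mg_exclusion[2],
    p$mg_window[2] == p$mg_exclusion[1],  # 2.3 closes one, opens the other
    p$k_window[1] < p$k_window[2],
    p$outer_window[1] < p$outer_window[2],
    p$distortion_correct_max < p$distortion_slight_max,
    p$mgd_max < p$mgc_max, p$mgc_max < p$mgb_max, p$mgb_max < p$pair_dmax
  )
  p
}

#' Read geometry parameter overrides from a config file
#'
#' Plain-text `key = value` format, one per line; `#` starts a comment.
#' Windows take two comma-separated numbers (`mg_window = 1.9, 2.3`).
#' Units are Angstrom for distances and degrees for angles, matching
#' [geometry_params()].
#'
#' @param path file path.
#' @return an `mg_params` object.
#' @export
read_geometry_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (line in lines) {
    parts <- stringr::str_split_fixed(line, "=", 2)
    if (!nzchar(parts[2])) {
      rlang::abort(paste0("cannot parse parameter line: '", line, "'"))
    }
    key <- stringr::str_trim(parts[1])
    value <- as.numeric(stringr::str_trim(stringr::str_split_1(parts[2], ",")))
    overrides[[key]] <- value
  }
  do.call(geometry_params, overrides)
}

#' @export
print.mg_params <- function(x, ...) {
  cat("<mg_params> ion-site geometry parameters\n")
  for (key in names(x)) {
    cat(sprintf("  %-24s %s\n", key, paste(format(x[[key]]), collapse = ", ")))
  }
  invisible(x)
}

# Per-element first-shell acceptance window, in Angstrom.  Zn2+ shares the
# Mg window (comparable ionic radius); Na+ gets its own intermediate one.
element_window <- function(element, params) {
  element <- toupper(element)
  if (element == "K") return(params$k_window)
  if (element == "NA") return(params$na_window)
  params$mg_window
}
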