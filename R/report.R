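#' Run the full ion-diagnosis pipeline on a structure
#'
#' Executes read -> role assignment -> coordination shells -> site labels
#' and diagnoses -> motif scans (bidentate clamps, trans candidates,
#' purine N7 seats, O2'-phosphate motifs) -> ion pairs -> chains ->
#' summary tables.  Deterministic for a fixed input and configuration.
#'
#' @param input a file path (mmCIF/PDB) or an `mg_structure` already in
#'   memory (e.g. from [make_fixture()]).
#' @param format file format for paths: `"auto"`, `"mmcif"` or `"pdb"`.
#' @param params a [geometry_params()] object.
#' @param density optional per-ion density-peak sidecar: TSV path or
#'   tibble with columns `ion_id`, `sigma`.
#' @param include_carboxyl also scan carboxylate clamp pairs.
#' @return an `mg_report` object: a list of tibbles `atoms`, `shells`,
#'   `ions` (label + diagnosis per metal), `clamps`, `trans_candidates`,
#'   `purine_seats`, `o2p_motifs`, `pairs`, `chains`, `summary`, plus
#'   `params` and a `provenance` block.
#' @examples
#' rep <- run_diagnosis(make_fixture("cis_clamp")$atoms)
#' rep$ions$label
#' @export
run_diagnosis <- function(input, format = c("auto", "mmcif", "pdb"),
                          params = geometry_params(), density = NULL,
                          include_carboxyl = FALSE) {
  atoms <- if (is.character(input)) {
    read_structure(input, match.arg(format))
  } else {
    input
  }
  if (!"role" %in% names(atoms)) atoms <- assign_roles(atoms)
  shells <- build_shells(atoms, params)
  shells <- label_sites(shells, params)
  diagnoses <- diagnose_ions(atoms, shells, density, params)
  ions <- dplyr::left_join(
    diagnoses,
    dplyr::select(tibble::as_tibble(shells), "ion_id", "label", "prefix"),
    by = "ion_id"
  )
  clamps <- scan_clamps(atoms, params, shells,
                        include_carboxyl = include_carboxyl)
  trans_candidates <- scan_trans_candidates(atoms, params, shells)
  purine_seats <- scan_purine_seats(atoms, params, shells)
  o2p_motifs <- scan_o2p_motifs(atoms, params, shells)
  pairs <- find_ion_pairs(atoms, shells, params)
  chains <- assemble_chains(pairs)
  summary <- summarize_sites(ions)
  flag_counts <- tibble::tibble(
    flag = unlist(ions$flags) %||% character()) |>
    dplyr::count(.data$flag, name = "n")
  op_combos <- if (nrow(clamps)) {
    dplyr::count(tibble::as_tibble(clamps), .data$op_combo, name = "n")
  } else {
    tibble::tibble(op_combo = character(), n = integer())
  }
  prov <- attr(atoms, "provenance") %||% list()
  structure(
    list(
      atoms = atoms, shells = shells, ions = ions,
      clamps = clamps, trans_candidates = trans_candidates,
      purine_seats = purine_seats, o2p_motifs = o2p_motifs,
      pairs = pairs, chains = chains,
      summary = summary, flag_counts = flag_counts, op_combos = op_combos,
      params = params,
      provenance = list(source = prov$source, format = prov$format,
                        package_version =
                          as.character(utils::packageVersion("mgion")))
    ),
    class = "mg_report"
  )
}

#' @export
print.mg_report <- function(x, ...) {
  cat("<mg_report> ", x$provenance$source %||% "in-memory structure", "\n",
      sep = "")
  cat("  atoms: ", nrow(x$atoms), "; metal ions: ", nrow(x$ions), "\n",
      sep = "")
  if (nrow(x$ions)) {
    cat("  well-defined ions: ", sum(x$ions$well_defined), " of ",
        nrow(x$ions), "\n", sep = "")
  }
  cat("  clamp pairs: ", nrow(x$clamps),
      "; trans candidates: ", nrow(x$trans_candidates),
      "; purine seats: ", nrow(x$purine_seats),
      "; O2'-OP motifs: ", nrow(x$o2p_motifs), "\n", sep = "")
  cat("  ion pairs: ", nrow(x$pairs), " in ", nrow(x$chains),
      " chain(s)\n", sep = "")
  if (nrow(x$summary)) {
    cat("  site inventory:\n")
    inv <- utils::head(x$summary, 10)
    for (i in seq_len(nrow(inv))) {
      cat(sprintf("    %-22s %3d (%d well-defined)\n", inv$label[i],
                  inv$n[i], inv$n_well_defined[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-ion tidy view of a diagnosis report
#'
#' @param x an `mg_report`.
#' @param ... unused.
#' @return tibble with one row per metal: identity, label, coordination
#'   number, distortion, flags (comma-separated), `well_defined`.
#' @method tidy mg_report
#' @export
tidy.mg_report <- function(x, ...) {
  dplyr::mutate(x$ions,
                flags = purrr::map_chr(.data$flags, paste, collapse = ","))
}

#' One-row summary of a diagnosis report
#'
#' @param x an `mg_report`.
#' @param ... unused.
#' @return one-row tibble: atom/ion counts, well-defined count, scan hit
#'   counts, pair and chain counts.
#' @method glance mg_report
#' @export
glance.mg_report <- function(x, ...) {
  tibble::tibble(
    n_atoms = nrow(x$atoms),
    n_ions = nrow(x$ions),
    n_mg = sum(x$ions$ion_element == "MG"),
    n_k = sum(x$ions$ion_element == "K"),
    n_well_defined = sum(x$ions$well_defined),
    n_hexacoordinated = sum(x$ions$coordination_number == 6L),
    n_clamps = nrow(x$clamps),
    n_trans_candidates = nrow(x$trans_candidates),
    n_purine_seats = nrow(x$purine_seats),
    n_o2p_motifs = nrow(x$o2p_motifs),
    n_pairs = nrow(x$pairs),
    n_chains = nrow(x$chains)
  )
}

#' Bar chart of the binding-site inventory
#'
#' @param object an `mg_report`.
#' @param ... unused.
#' @return a ggplot: label frequencies split by well-definedness.
#' @method autoplot mg_report
#' @export
autoplot.mg_report <- function(object, ...) {
  ions <- tidy(object)
  ions$label <- dplyr::coalesce(ions$label, "<unlabelled>")
  ions$status <- ifelse(ions$well_defined, "well-defined", "flagged")
  ggplot2::ggplot(ions, ggplot2::aes(
    y = stats::reorder(.data$label, .data$label, FUN = length),
    fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "ions", y = NULL, fill = NULL,
                  title = "Metal binding-site inventory") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of first-shell ligand distances
#'
#' @param shells a [build_shells()] result.
#' @param params a [geometry_params()] object (window guides).
#' @return a ggplot with the Mg window and exclusion zone marked.
#' @export
plot_shell_distances <- function(shells, params = geometry_params()) {
  lig <- dplyr::bind_rows(shells$ligands)
  ggplot2::ggplot(lig, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = 0.02, fill = "grey40") +
    ggplot2::geom_vline(xintercept = params$mg_window, linetype = 2,
                        colour = "darkgreen") +
    ggplot2::geom_vline(xintercept = params$mg_exclusion[2], linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "ligand distance (\u00c5)", y = "count",
                  title = "First-shell coordination distances") +
    ggplot2::theme_minimal()
}

#' Write a diagnosis report to disk
#'
#' Emits a versioned JSON document (machine-readable, stable key order,
#' no timestamps so identical runs are byte-identical) and/or flat TSV
#' tables `ions.tsv`, `clamps.tsv`, `pairs.tsv`, `summary.tsv`.
#'
#' @param report an `mg_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("json", "tsv")`.
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "tsv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ions_flat <- tidy(report)
  if ("json" %in% formats) {
    doc <- list(
      schema = "mgion-report/1",
      provenance = report$provenance,
      params = unclass(report$params),
      ions = ions_flat,
      clamps = tibble::as_tibble(report$clamps),
      trans_candidates = tibble::as_tibble(report$trans_candidates),
      purine_seats = tibble::as_tibble(report$purine_seats),
      o2p_motifs = tibble::as_tibble(report$o2p_motifs),
      pairs = tibble::as_tibble(report$pairs),
      summary = report$summary,
      flag_counts = report$flag_counts,
      op_combos = report$op_combos
    )
    jsonlite::write_json(doc, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if ("tsv" %in% formats) {
    readr::write_tsv(ions_flat, file.path(dir, "ions.tsv"))
    readr::write_tsv(tibble::as_tibble(report$clamps),
                     file.path(dir, "clamps.tsv"))
    readr::write_tsv(tibble::as_tibble(report$pairs),
                     file.path(dir, "pairs.tsv"))
    readr::write_tsv(report$summary, file.path(dir, "summary.tsv"))
  }
  invisible(dir)
}
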