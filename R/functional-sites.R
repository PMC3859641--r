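# Functional-site association: interface delta-ASA classes, ligand and
# catalytic-site distances, folding hotspots.

#' Interface profile from monomer and complex states
#'
#' Per-residue loss of solvent accessibility upon complex formation:
#' `delta_asa = ASA(monomer alone) - ASA(same chain inside the complex)`.
#' Small negative values (numerical noise) are clamped to zero; a negative
#' value beyond `tol` raises a warning before clamping. Interface classes:
#' `none` (delta <= 5), `rim` (5 < delta < 25), `intermediate`
#' (25 <= delta <= 85) and `core` (delta > 85 Angstrom squared).
#'
#' @param monomer A [structure_model()] of the free chain(s).
#' @param complex A [structure_model()] containing the same chains plus
#'   their partners (e.g. from [apply_assembly()]).
#' @param probe_radius,n_points,radii See [compute_atom_sasa()].
#' @param tol Numeric tolerance for negative delta-ASA.
#' @return Tibble `chain_id`, `res_number`, `aa`, `asa_monomer`,
#'   `asa_complex`, `delta_asa`, `iface_class`.
#' @export
interface_profile <- function(monomer, complex, probe_radius = 1.4,
                              n_points = 960, radii = vdw_radii(),
                              tol = 1e-3) {
  mono_res <- model_residues(monomer)
  cplx <- complex[!complex$het, ]
  shared <- intersect(unique(mono_res$chain_id), unique(cplx$chain_id))
  if (length(shared) == 0) abort("monomer chains not found in the complex")
  cplx_res <- model_residues(cplx[cplx$chain_id %in% shared, ])
  mism <- dplyr::symdiff(
    select(filter(mono_res, .data$chain_id %in% shared),
           "chain_id", "res_number", "aa"),
    select(cplx_res, "chain_id", "res_number", "aa")
  )
  if (nrow(mism) > 0) {
    abort(paste0("monomer/complex residue mismatch at: ",
                 paste(mism$chain_id, mism$res_number, collapse = ", ")))
  }
  res_asa <- function(m) {
    compute_atom_sasa(m[!m$het, ], probe_radius, n_points, radii) |>
      group_by(.data$chain_id, .data$res_number) |>
      summarise(aa = first(.data$aa), asa = sum(.data$asa), .groups = "drop")
  }
  a_mono <- res_asa(monomer[monomer$chain_id %in% shared, ])
  a_cplx <- compute_atom_sasa(cplx, probe_radius, n_points, radii) |>
    filter(.data$chain_id %in% shared) |>
    group_by(.data$chain_id, .data$res_number) |>
    summarise(asa = sum(.data$asa), .groups = "drop")
  out <- inner_join(rename(a_mono, asa_monomer = "asa"),
                    rename(a_cplx, asa_complex = "asa"),
                    by = c("chain_id", "res_number")) |>
    mutate(delta_asa = .data$asa_monomer - .data$asa_complex)
  if (any(out$delta_asa < -tol)) {
    warn(sprintf("%d residue(s) with delta ASA below -%g; clamped to 0",
                 sum(out$delta_asa < -tol), tol))
  }
  out |>
    mutate(
      delta_asa = pmax(0, .data$delta_asa),
      iface_class = classify_interface(.data$delta_asa)
    )
}

#' Classify delta-ASA values into interface classes
#'
#' @param delta_asa Numeric vector (Angstrom squared).
#' @param none_max,rim_max,core_min Class thresholds.
#' @return Character vector in `{none, rim, intermediate, core}`.
#' @export
classify_interface <- function(delta_asa, none_max = 5, rim_max = 25,
                               core_min = 85) {
  dplyr::case_when(
    delta_asa <= none_max ~ "none",
    delta_asa < rim_max ~ "rim",
    delta_asa > core_min ~ "core",
    TRUE ~ "intermediate"
  )
}

#' Site-to-ligand association by class
#'
#' For each site and ligand class, the minimum Euclidean distance from any
#' heavy atom of the site residue to any atom of a ligand in that class.
#' `direct` flags distances strictly below `cutoff` (11.5 Angstrom, about
#' the radius of ubiquitin). Classes without a ligand in the structure give
#' `NA` distances (reported missing, not zero).
#'
#' @param model A [structure_model()] retaining its hetero atoms.
#' @param sites Tibble with `chain_id`, `res_number`.
#' @param class_map Named list of hetero residue codes ([ligand_classes()]).
#' @param cutoff Direct-association cutoff in Angstrom.
#' @return Tibble `site_id`, `ligand_class`, `min_dist`, `direct`.
#' @export
ligand_association <- function(model, sites, class_map = ligand_classes(),
                               cutoff = 11.5) {
  het <- model[model$het, ]
  sites <- as_tibble(sites)
  out <- pmap(list(sites$chain_id, sites$res_number), function(ch, rn) {
    satoms <- model[!model$het & model$chain_id == ch &
                      model$res_number == rn, ]
    if (nrow(satoms) == 0) abort(paste0("site ", ch, ":", rn, " not in model"))
    imap(class_map, function(codes, cls) {
      lat <- het[toupper(het$resid3) %in% codes, ]
      md <- if (nrow(lat) == 0) NA_real_ else
        min(cross_dist(coords(satoms), coords(lat)))
      tibble(site_id = paste0(ch, ":", rn), ligand_class = cls,
             min_dist = md, direct = !is.na(md) & md < cutoff)
    }) |> list_rbind()
  }) |> list_rbind()
  out
}

#' Site-to-catalytic-site association
#'
#' Minimum C-beta distance (C-alpha for glycine) from each site to any
#' catalytic residue; `direct` at strictly below `cutoff`.
#'
#' @param model A [structure_model()].
#' @param sites Tibble with `chain_id`, `res_number`.
#' @param catalytic Tibble with `chain_id`, `res_number` of catalytic
#'   residues; an empty table gives `NA` distances.
#' @param cutoff Direct-association cutoff in Angstrom.
#' @return Tibble `site_id`, `min_cbeta_dist`, `direct`.
#' @export
catalytic_association <- function(model, sites, catalytic, cutoff = 11.5) {
  cb <- cbeta_atoms(model, warn = FALSE)
  key <- paste0(cb$chain_id, ":", cb$res_number)
  catalytic <- as_tibble(catalytic)
  cat_idx <- if (nrow(catalytic) == 0) integer(0) else {
    match(paste0(catalytic$chain_id, ":", catalytic$res_number), key)
  }
  if (length(cat_idx) > 0 && anyNA(cat_idx)) {
    abort("catalytic residues absent from the structure")
  }
  sites <- as_tibble(sites)
  sidx <- match(paste0(sites$chain_id, ":", sites$res_number), key)
  if (anyNA(sidx)) abort("site residues absent from the structure")
  xyz <- cbind(cb$x, cb$y, cb$z)
  md <- if (length(cat_idx) == 0) rep(NA_real_, length(sidx)) else {
    apply(cross_dist(xyz[sidx, , drop = FALSE],
                     xyz[cat_idx, , drop = FALSE]), 1, min)
  }
  tibble(site_id = paste0(sites$chain_id, ":", sites$res_number),
         min_cbeta_dist = md, direct = !is.na(md) & md < cutoff)
}

#' Flag folding hotspots from an alanine-scan table
#'
#' Consumes externally computed alanine-scan folding energies and flags
#' residues whose mutation destabilises the fold by more than `threshold`
#' (default 2 kcal/mol) as folding hotspots.
#'
#' @param ddg_table Tibble with columns `res_number` (optionally `chain_id`)
#'   and `ddg` (kcal/mol).
#' @param threshold Hotspot threshold, strict inequality.
#' @return The table with an added logical `hotspot` column (`NA` for
#'   missing energies).
#' @export
flag_hotspots <- function(ddg_table, threshold = 2) {
  ddg_table <- as_tibble(ddg_table)
  if (nrow(ddg_table) == 0) return(mutate(ddg_table, hotspot = logical(0)))
  if (!is.numeric(ddg_table$ddg)) abort("ddg values must be numeric")
  mutate(ddg_table, hotspot = ifelse(is.na(.data$ddg), NA, .data$ddg > threshold))
}

#' Read an alanine-scan energy table
#'
#' Tab-separated with columns `res_number` and `ddg` (optionally
#' `chain_id`), as written by computational alanine-scan tools.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_ddg_table <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              comment.char = "#")) |>
    mutate(res_number = as.integer(.data$res_number),
           ddg = as.numeric(.data$ddg))
}
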