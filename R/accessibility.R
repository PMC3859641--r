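# Accessibility descriptors: solvent accessible surface area (Shrake-Rupley),
# relative accessibility RSA, protrusion index CX and depth index DPX.

# Deterministic golden-spiral point set on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(model, radii, unknown_element) {
  r <- radii[toupper(model$element)]
  if (anyNA(r)) {
    unknown <- unique(model$element[is.na(r)])
    if (unknown_element == "fail") {
      abort(paste0("no van der Waals radius for element(s): ",
                   paste(unknown, collapse = ", "),
                   "; extend the radii table or use unknown_element = \"carbon\""))
    }
    r[is.na(r)] <- radii[["C"]]
  }
  unname(r)
}

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley SASA: each atom's solvent-extended sphere (van der Waals
#' radius plus probe) is sampled with a deterministic golden-spiral point
#' set; a point is accessible when it lies outside every neighbour's
#' extended sphere. ASA is the accessible fraction of the sphere area.
#'
#' @param model A [structure_model()] (all rows are used; subset beforehand
#'   to exclude hetero atoms if desired).
#' @param probe_radius Solvent probe radius in Angstrom.
#' @param n_points Sphere sample points per atom.
#' @param radii Named van der Waals radius table, see [vdw_radii()].
#' @param unknown_element `"fail"` (default) or `"carbon"` fallback.
#' @return `model` with an added per-atom `asa` column (Angstrom squared).
#' @export
compute_atom_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                              radii = vdw_radii(),
                              unknown_element = c("fail", "carbon")) {
  unknown_element <- match.arg(unknown_element)
  if (nrow(model) == 0) abort("model has no atoms")
  if (probe_radius <= 0) abort("probe_radius must be positive")
  r <- atom_radii(model, radii, unknown_element) + probe_radius
  xyz <- coords(model)
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  d <- cross_dist(xyz, xyz)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
    if (length(nb) == 0) {
      asa[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i] + rep(xyz[i, ], each = n_points)
    pd <- cross_dist(p, xyz[nb, , drop = FALSE])
    exposed <- rowSums(pd < rep(r[nb], each = n_points)) == 0
    asa[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  model$asa <- asa
  model
}

#' Per-residue relative solvent accessibility
#'
#' RSA = 100 x residue ASA / reference maximum ASA, capped at 100.
#'
#' @param model_asa A model with an `asa` column ([compute_atom_sasa()]).
#' @param reference Named per-residue maximum ASA table ([rsa_reference()]).
#' @return Tibble `chain_id`, `res_number`, `aa`, `asa`, `rsa`.
#' @export
compute_residue_rsa <- function(model_asa, reference = rsa_reference()) {
  poly <- model_asa[!model_asa$het, ]
  res <- poly |>
    group_by(.data$chain_id, .data$res_number) |>
    summarise(aa = first(.data$aa), asa = sum(.data$asa), .groups = "drop")
  ref <- reference[res$aa]
  if (anyNA(ref)) {
    bad <- unique(res$aa[is.na(ref)])
    abort(paste0("no RSA reference for residue type(s): ",
                 paste(bad, collapse = ", ")))
  }
  mutate(res, rsa = pmin(100, 100 * .data$asa / unname(ref)))
}

#' Per-atom protrusion index CX
#'
#' For each heavy atom, the sphere of radius `sphere_radius` is split into
#' occupied volume `V_int` (number of heavy-atom centres inside, self
#' included, times the mean atom volume) and empty volume
#' `V_ext = V_sphere - V_int`; `CX = V_ext / V_int`, floored at 0. High
#' values mark protruding atoms.
#'
#' @param model A [structure_model()].
#' @param sphere_radius Sphere radius in Angstrom.
#' @param atom_volume Mean heavy-atom volume in cubic Angstrom.
#' @return `model` with an added per-atom `cx` column.
#' @export
compute_cx <- function(model, sphere_radius = 10, atom_volume = 20.1) {
  if (nrow(model) == 0) abort("model has no atoms")
  if (sphere_radius <= 0 || atom_volume <= 0) {
    abort("sphere_radius and atom_volume must be positive")
  }
  xyz <- coords(model)
  d <- cross_dist(xyz, xyz)
  inside <- rowSums(d <= sphere_radius) # self included (d[i,i] = 0)
  v_int <- inside * atom_volume
  v_sphere <- 4 / 3 * pi * sphere_radius^3
  model$cx <- pmax(0, (v_sphere - v_int) / v_int)
  model
}

#' Per-atom depth index DPX
#'
#' DPX is 0 for solvent-exposed atoms (ASA above `asa_threshold`) and the
#' Euclidean distance to the nearest exposed atom otherwise.
#'
#' @param model_asa A model with an `asa` column ([compute_atom_sasa()]).
#' @param asa_threshold Exposure threshold on ASA (default: strictly
#'   positive ASA counts as exposed).
#' @return The model with an added per-atom `dpx` column (Angstrom).
#' @export
compute_dpx <- function(model_asa, asa_threshold = 0) {
  if (!"asa" %in% names(model_asa)) abort("run compute_atom_sasa() first")
  exposed <- model_asa$asa > asa_threshold
  if (!any(exposed)) abort("structure has no solvent-exposed atom")
  dpx <- numeric(nrow(model_asa))
  if (any(!exposed)) {
    d <- cross_dist(coords(model_asa[!exposed, ]), coords(model_asa[exposed, ]))
    dpx[!exposed] <- apply(d, 1, min)
  }
  model_asa$dpx <- dpx
  model_asa
}

#' Residue-level accessibility profile
#'
#' Computes SASA, RSA, CX and DPX on the polymer atoms of a structure and
#' aggregates them per residue: `rsa`, `cx_max`, `cx_mean`, `dpx_mean`,
#' `dpx_max`. The maximum CX and mean DPX are the residue-level protrusion
#' and depth descriptors used by the discrimination layer.
#'
#' @param model A [structure_model()].
#' @param probe_radius,n_points,radii,unknown_element See [compute_atom_sasa()].
#' @param cx_radius,cx_atom_volume See [compute_cx()].
#' @param dpx_asa_threshold See [compute_dpx()].
#' @param reference See [compute_residue_rsa()].
#' @return Tibble with one row per residue.
#' @export
accessibility_profile <- function(model, probe_radius = 1.4, n_points = 960,
                                  radii = vdw_radii(),
                                  unknown_element = c("fail", "carbon"),
                                  cx_radius = 10, cx_atom_volume = 20.1,
                                  dpx_asa_threshold = 0,
                                  reference = rsa_reference()) {
  poly <- model[!model$het, ]
  poly <- compute_atom_sasa(poly, probe_radius, n_points, radii,
                            match.arg(unknown_element))
  poly <- compute_cx(poly, cx_radius, cx_atom_volume)
  poly <- compute_dpx(poly, dpx_asa_threshold)
  rsa <- compute_residue_rsa(poly, reference)
  per_res <- poly |>
    group_by(.data$chain_id, .data$res_number) |>
    summarise(
      cx_max = max(.data$cx), cx_mean = mean(.data$cx),
      dpx_mean = mean(.data$dpx), dpx_max = max(.data$dpx),
      .groups = "drop"
    )
  rsa |>
    select("chain_id", "res_number", "aa", "rsa") |>
    inner_join(per_res, by = c("chain_id", "res_number"))
}
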