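# End-to-end analysis: descriptors -> Ub vs NonUb statistics -> indicator
# scoring -> ROC/AUC with DeLong comparisons.

#' Per-residue structural descriptors for a set of models
#'
#' Computes the descriptor panel on every chain: protrusion (`cx_max`,
#' `cx_mean`), contact-network `degree` and `closeness`, distances to the
#' geometric center, and kappa/alpha structural-alphabet states. The
#' `"full"` panel adds the SASA-derived descriptors `rsa`, `dpx_mean` and
#' `dpx_max` (the costlier computation).
#'
#' @param models Named list of [structure_model()]s (distinct chain ids).
#' @param panel `"core"` or `"full"`.
#' @param contact_mode See [build_rcn()].
#' @param n_points Sphere points for SASA (full panel).
#' @param alphabet Structural-alphabet map ([sa_alphabet()]).
#' @return Tibble with one row per residue.
#' @export
residue_descriptors <- function(models, panel = c("full", "core"),
                                contact_mode = "cbeta_7.5", n_points = 960,
                                alphabet = sa_alphabet()) {
  panel <- match.arg(panel)
  map(models, function(m) {
    poly <- m[!m$het, ]
    cx <- compute_cx(poly) |>
      group_by(.data$chain_id, .data$res_number) |>
      summarise(aa = first(.data$aa), cx_max = max(.data$cx),
                cx_mean = mean(.data$cx), .groups = "drop")
    cen <- network_centralities(build_rcn(m, mode = contact_mode)) |>
      tidyr::separate_wider_delim("node", ":",
                                  names = c("chain_id", "res_number")) |>
      mutate(res_number = as.integer(.data$res_number))
    cdist <- center_distances(m)
    conf <- compute_kappa_alpha(m) |> assign_structural_alphabet(alphabet)
    out <- cx |>
      inner_join(cen, by = c("chain_id", "res_number")) |>
      inner_join(cdist, by = c("chain_id", "res_number")) |>
      left_join(conf, by = c("chain_id", "res_number"))
    if (panel == "full") {
      acc <- accessibility_profile(m, n_points = n_points)
      out <- left_join(out,
                       select(acc, "chain_id", "res_number", "rsa",
                              "dpx_mean", "dpx_max"),
                       by = c("chain_id", "res_number"))
    }
    out
  }) |> list_rbind()
}

DESCRIPTOR_PANEL <- c("rsa", "cx_max", "dpx_mean", "degree", "closeness",
                      "center_dist", "center_dist_corrected")

#' Compare descriptors between Ub and NonUb sites
#'
#' One Wilcoxon rank-sum comparison (with effect size `r`) per descriptor;
#' negative `r` means the Ub sites are shifted higher.
#'
#' @param site_descriptors Tibble of per-site descriptor values with a
#'   `label` column.
#' @param descriptors Descriptor columns to compare (defaults to those
#'   present from the standard panel).
#' @return Tibble `descriptor`, `p_value`, `effect_r`, `n_ub`, `n_nonub`.
#' @export
compare_descriptors <- function(site_descriptors,
                                descriptors = intersect(DESCRIPTOR_PANEL,
                                                        names(site_descriptors))) {
  ub <- site_descriptors$label == "Ub"
  map(descriptors, function(dcol) {
    v <- site_descriptors[[dcol]]
    res <- wilcoxon_effect(v[ub], v[!ub])
    tibble(descriptor = dcol, p_value = res$p_value, effect_r = res$effect_r,
           n_ub = res$n1, n_nonub = res$n2)
  }) |> list_rbind()
}

#' Run the full site-discrimination analysis
#'
#' The complete pipeline on a set of structures with labelled lysines:
#' per-residue descriptors, Ub-vs-NonUb descriptor comparisons, the six
#' site indicators (scaled CX, closeness, sequence-context and
#' conformation-context naive Bayes scores, first- and second-shell
#' microenvironment scores), per-indicator ROC/AUC, the cross-validated
#' weighted combination, and DeLong comparisons against the
#' sequence-pattern indicator.
#'
#' @param models Named list of [structure_model()]s.
#' @param sites Site tibble (`chain_id`, `res_number`, `label`), e.g. from
#'   [annotate_sites()] or [generate_benchmark_set()].
#' @param panel Descriptor panel, see [residue_descriptors()].
#' @param k Context half-width (residues).
#' @param folds,seed Cross-validation parameters.
#' @param weights Fixed combination weights, or `NULL` for the seeded
#'   per-fold grid search.
#' @param combine Compute the weighted combination (set `FALSE` to report
#'   single indicators only, e.g. for null calibrations).
#' @param grid_step Grid step of the weight search.
#' @param shells Microenvironment shell boundaries (Angstrom).
#' @param contact_mode,n_points Passed to [residue_descriptors()].
#' @return A `ubi_analysis` object (list of tibbles; see Details) with
#'   `tidy()`/`glance()`/`autoplot()` methods.
#' @export
analyze_sites <- function(models, sites, panel = c("core", "full"), k = 6,
                          folds = 5, seed = 1, weights = NULL,
                          grid_step = 0.25, shells = c(0, 7.5, 11.5, 15.5),
                          contact_mode = "cbeta_7.5", n_points = 960,
                          combine = TRUE) {
  panel <- match.arg(panel)
  sites <- as_tibble(sites) |>
    mutate(site_id = paste0(.data$chain_id, ":", .data$res_number)) |>
    filter(.data$label %in% c("Ub", "NonUb"))
  if (length(unique(sites$label)) < 2) {
    abort("need both Ub and NonUb sites")
  }
  desc <- residue_descriptors(models, panel = panel,
                              contact_mode = contact_mode,
                              n_points = n_points)
  site_desc <- sites |>
    left_join(select(desc, -"aa"), by = c("chain_id", "res_number"))
  comparisons <- compare_descriptors(site_desc)

  labels <- select(site_desc, "site_id", "label")
  seq_track <- select(desc, "chain_id", "res_number", symbol = "aa")
  conf_track <- select(desc, "chain_id", "res_number", symbol = "sa_state")
  seq_w <- context_windows(seq_track, sites, k, require_center = "K")
  conf_w <- context_windows(conf_track, sites, k)
  seq_nb <- nb_positional_likelihood(seq_w, labels, folds, seed)
  conf_nb <- nb_positional_likelihood(conf_w, labels, folds, seed + 1L)
  shp <- map(models, function(m) {
    s <- filter(sites, .data$chain_id %in% unique(m$chain_id))
    if (nrow(s) == 0) return(NULL)
    shell_propensities(m, semi_join_sites(s), shells = shells)
  }) |> list_rbind()
  shell_score <- function(s, off) {
    comp <- shp |>
      filter(.data$shell == s) |>
      select("site_id", symbol = "aa", "count")
    nb_composition_likelihood(comp, labels, folds, seed + off)
  }
  sh1 <- shell_score(1, 2L)
  sh2 <- shell_score(2, 3L)

  indicators <- site_desc |>
    select("site_id", "label", cx = "cx_max", "closeness") |>
    left_join(select(seq_nb, "site_id", seq_nb = "score"), by = "site_id") |>
    left_join(select(conf_nb, "site_id", conf_nb = "score"), by = "site_id") |>
    left_join(select(sh1, "site_id", shell1 = "score"), by = "site_id") |>
    left_join(select(sh2, "site_id", shell2 = "score"), by = "site_id")

  ind_cols <- c("cx", "closeness", "seq_nb", "conf_nb", "shell1", "shell2")
  rocs <- lapply(setNames(ind_cols, ind_cols), function(cc) {
    roc_auc(scale_unit_interval(indicators[[cc]]), indicators$label)
  })
  combined <- NULL
  if (combine) {
    combined <- combine_indicators(indicators, weights = weights,
                                   folds = folds, seed = seed + 4L,
                                   grid_step = grid_step)
    rocs$combined <- roc_auc(combined$combined, combined$label)
  }

  base <- indicators$seq_nb
  delong <- map(setdiff(names(rocs), "seq_nb"), function(nm) {
    if (nm == "combined") {
      keep <- match(combined$site_id, indicators$site_id)
      dl <- delong_test(combined$combined, base[keep], combined$label)
      return(mutate(dl, indicator = nm, .before = 1))
    }
    sc <- indicators[[nm]]
    dl <- delong_test(sc, base, indicators$label)
    mutate(dl, indicator = nm, .before = 1)
  }) |> list_rbind()

  aucs <- tibble(indicator = names(rocs),
                 auc = map_dbl(rocs, function(r) r$auc)) |>
    left_join(select(delong, "indicator", delong_p_vs_seq = "p_value"),
              by = "indicator")

  structure(list(
    sites = sites, descriptors = desc, site_descriptors = site_desc,
    comparisons = comparisons, indicators = indicators,
    combined = combined, rocs = rocs, aucs = aucs, delong = delong,
    config = list(panel = panel, k = k, folds = folds, seed = seed,
                  grid_step = grid_step, shells = shells,
                  contact_mode = contact_mode, n_points = n_points)
  ), class = "ubi_analysis")
}

# sites columns needed by shell_propensities
semi_join_sites <- function(sites) select(sites, "chain_id", "res_number")

#' @export
print.ubi_analysis <- function(x, ...) {
  cat(sprintf("<ubi_analysis: %d sites (%d Ub / %d NonUb), %d descriptors>\n",
              nrow(x$sites), sum(x$sites$label == "Ub"),
              sum(x$sites$label == "NonUb"), nrow(x$comparisons)))
  cat("Descriptor comparisons (Wilcoxon p, effect r):\n")
  print(as.data.frame(x$comparisons), digits = 3)
  cat("Indicator AUCs:\n")
  print(as.data.frame(x$aucs), digits = 3)
  invisible(x)
}

#' @rdname analyze_sites
#' @param x A `ubi_analysis` object.
#' @param ... Unused.
#' @method tidy ubi_analysis
#' @export
tidy.ubi_analysis <- function(x, ...) x$comparisons

#' @rdname analyze_sites
#' @method glance ubi_analysis
#' @export
glance.ubi_analysis <- function(x, ...) {
  wide <- tidyr::pivot_wider(select(x$aucs, "indicator", "auc"),
                             names_from = "indicator", values_from = "auc",
                             names_prefix = "auc_")
  dplyr::bind_cols(
    tibble(n_sites = nrow(x$sites), n_ub = sum(x$sites$label == "Ub")),
    wide,
    tibble(delong_p_combined_vs_seq =
             x$aucs$delong_p_vs_seq[x$aucs$indicator == "combined"])
  )
}

# --- config-driven run ------------------------------------------------------

ANALYSIS_CONFIG_KEYS <- c(
  "structures", "sites", "output_dir", "seed", "panel", "k", "folds",
  "grid_step", "shells", "contact_mode", "n_points", "max_identity",
  "filter", "restore_modified", "ddg", "catalytic", "ligand_classes",
  "synthetic"
)

#' Run the analysis from a configuration
#'
#' Config-driven orchestration: reads structures and a site table (or
#' generates the synthetic benchmark when a `synthetic` block is given),
#' optionally applies the dataset filters, runs [analyze_sites()], attaches
#' the optional functional-site sections (alanine-scan hotspots,
#' catalytic-site association, ligand association) when their inputs are
#' configured, and writes all result tables plus a machine-readable JSON
#' summary into `output_dir`. Outputs are a pure function of config and
#' seed. Unknown config keys are rejected; the config is serialised into
#' the summary.
#'
#' @param config Path to a YAML file or an equivalent named list. Keys:
#'   `structures` (directory or vector of PDB paths), `sites` (TSV path),
#'   or `synthetic` (list of [synthetic_spec()] arguments); optional `ddg`,
#'   `catalytic` (TSV paths), `ligand_classes` (YAML path); `output_dir`;
#'   and the [analyze_sites()] parameters.
#' @return The `ubi_analysis` object, invisibly, with attribute
#'   `"summary"` (the list written as JSON).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), ANALYSIS_CONFIG_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  seed <- as.integer(config$seed %||% 1L)

  if (!is.null(config$synthetic)) {
    spec <- do.call(synthetic_spec,
                    utils::modifyList(config$synthetic, list(seed = seed)))
    bench <- generate_benchmark_set(spec)
    models <- bench$models
    sites <- bench$sites
  } else {
    paths <- config$structures
    if (length(paths) == 1 && dir.exists(paths)) {
      paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
    }
    models <- lapply(paths, parse_structure,
                     restore_modified = isTRUE(config$restore_modified))
    names(models) <- vapply(models, function(m) attr(m, "source_id"), "")
    ann <- read_site_table(config$sites)
    sites <- map(models, annotate_sites, annotations = ann) |> list_rbind()
  }

  if (isTRUE(config$filter)) {
    coll <- tibble(
      chain = names(models),
      model = unname(models),
      sites = lapply(names(models), function(nm) {
        filter(sites, .data$chain_id %in% unique(models[[nm]]$chain_id))
      })
    )
    coll <- filter_dataset(coll, max_identity = config$max_identity %||% 0.5)
    models <- setNames(coll$model, coll$chain)
    sites <- list_rbind(coll$sites)
  }

  an <- analyze_sites(
    models, sites,
    panel = config$panel %||% "core",
    k = config$k %||% 6, folds = config$folds %||% 5, seed = seed,
    grid_step = config$grid_step %||% 0.25,
    shells = config$shells %||% c(0, 7.5, 11.5, 15.5),
    contact_mode = config$contact_mode %||% "cbeta_7.5",
    n_points = config$n_points %||% 960
  )

  sections <- list()
  sections$hotspots <- if (!is.null(config$ddg)) {
    flag_hotspots(read_ddg_table(config$ddg))
  } else "skipped: no input"
  sections$catalytic <- if (!is.null(config$catalytic)) {
    cat_tbl <- read_site_table(config$catalytic)
    map(models, function(m) {
      s <- filter(an$sites, .data$chain_id %in% unique(m$chain_id))
      ct <- filter(cat_tbl, .data$chain_id %in% unique(m$chain_id))
      if (nrow(s) == 0 || nrow(ct) == 0) return(NULL)
      catalytic_association(m, s, ct)
    }) |> list_rbind()
  } else "skipped: no input"
  sections$ligands <- {
    cls <- ligand_classes(config$ligand_classes)
    has_het <- any(map_lgl(models, function(m) any(m$het)))
    if (has_het) {
      map(models, function(m) {
        if (!any(m$het)) return(NULL)
        s <- filter(an$sites, .data$chain_id %in% unique(m$chain_id))
        if (nrow(s) == 0) return(NULL)
        ligand_association(m, s, cls)
      }) |> list_rbind()
    } else "skipped: no input"
  }

  summary <- list(
    config = config[order(names(config))],
    n_chains = length(models),
    n_sites = nrow(an$sites), n_ub = sum(an$sites$label == "Ub"),
    comparisons = an$comparisons,
    aucs = an$aucs,
    sections = map(sections, function(s) if (is.character(s)) s else "computed")
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(tbl, nm) {
      if (is.data.frame(tbl)) {
        utils::write.table(tbl, file.path(config$output_dir, nm), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    wr(an$descriptors, "descriptors.tsv")
    wr(an$comparisons, "comparisons.tsv")
    wr(an$indicators, "indicators.tsv")
    wr(an$aucs, "aucs.tsv")
    for (nm in names(sections)) {
      if (is.data.frame(sections[[nm]])) wr(sections[[nm]], paste0(nm, ".tsv"))
    }
    jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
  }
  an$sections <- sections
  attr(an, "summary") <- summary
  invisible(an)
}
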