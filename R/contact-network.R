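# Residue contact networks: construction, degree and closeness centrality,
# and distances to the protein geometric center.

#' Build a residue contact network
#'
#' Nodes are polymer residues; an undirected edge connects two residues
#' whose representative atoms fall strictly below the distance cutoff. Two
#' contact definitions are supported: `cbeta_7.5` (C-beta to C-beta
#' distance, C-alpha for glycine, cutoff 7.5 Angstrom) and `anyatom_4.0`
#' (minimum over all heavy-atom pairs, cutoff 4.0 Angstrom). Sequence
#' adjacency plays no role: the criterion is purely spatial.
#'
#' @param model A [structure_model()] with at least two residues.
#' @param mode Contact definition.
#' @param cbeta_cutoff,anyatom_cutoff Distance cutoffs in Angstrom.
#' @return An `igraph` graph whose vertex names are `"<chain>:<res_number>"`,
#'   with graph attribute `mode`.
#' @export
build_rcn <- function(model, mode = c("cbeta_7.5", "anyatom_4.0"),
                      cbeta_cutoff = 7.5, anyatom_cutoff = 4.0) {
  mode <- match.arg(mode)
  res <- model_residues(model)
  if (nrow(res) < 2) abort("a contact network needs at least two residues")
  ids <- paste0(res$chain_id, ":", res$res_number)
  if (mode == "cbeta_7.5") {
    cb <- cbeta_atoms(model)
    stopifnot(nrow(cb) == nrow(res))
    d <- cross_dist(cbind(cb$x, cb$y, cb$z), cbind(cb$x, cb$y, cb$z))
    adj <- d < cbeta_cutoff
  } else {
    poly <- model[!model$het, ]
    ridx <- match(paste0(poly$chain_id, ":", poly$res_number), ids)
    d <- cross_dist(coords(poly), coords(poly))
    close <- d < anyatom_cutoff
    n <- length(ids)
    adj <- matrix(FALSE, n, n)
    pair <- which(close, arr.ind = TRUE)
    adj[cbind(ridx[pair[, 1]], ridx[pair[, 2]])] <- TRUE
  }
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- ids
  g <- igraph::set_graph_attr(g, "mode", mode)
  g
}

#' Degree and closeness centrality of a contact network
#'
#' Closeness follows the reachable-set (Wasserman-Faust) convention so that
#' disconnected graphs stay comparable:
#' `closeness(v) = (r_v / sum of d(v, u) over reachable u) * (r_v / (n - 1))`
#' where `r_v` is the number of nodes reachable from `v` (excluding `v`) and
#' `n` the node count. The value is 1 for a node adjacent to every other
#' node, and 0 for an isolated node.
#'
#' @param net Graph from [build_rcn()] (any igraph graph works).
#' @return Tibble `node`, `degree`, `closeness`.
#' @export
network_centralities <- function(net) {
  n <- igraph::vcount(net)
  d <- igraph::distances(net)
  deg <- igraph::degree(net)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / sum(di[reach])) * (r / (n - 1))
  }, numeric(1))
  tibble(node = igraph::V(net)$name %||% as.character(seq_len(n)),
         degree = as.integer(deg), closeness = clo)
}

#' Distances to the protein geometric center
#'
#' The geometric center is the unweighted mean of the heavy-atom
#' coordinates (or of the C-alpha atoms with `center_atoms = "calpha"`).
#' Each residue's distance is measured from its C-beta atom (C-alpha for
#' glycine). The size-corrected distance divides by the radius of gyration
#' (unweighted, over the same atom set), making the measure comparable
#' across proteins of different size.
#'
#' @param model A [structure_model()].
#' @param center_atoms Atom set defining center and radius of gyration.
#' @return Tibble `chain_id`, `res_number`, `center_dist`,
#'   `center_dist_corrected`, with attribute `"rg"` (radius of gyration).
#' @export
center_distances <- function(model, center_atoms = c("heavy", "calpha")) {
  center_atoms <- match.arg(center_atoms)
  poly <- model[!model$het, ]
  if (nrow(poly) == 0) abort("model has no polymer atoms")
  ref <- if (center_atoms == "calpha") poly[poly$atom_name == "CA", ] else poly
  xyz <- coords(ref)
  ctr <- colMeans(xyz)
  rg <- sqrt(mean(rowSums((xyz - rep(ctr, each = nrow(xyz)))^2)))
  cb <- cbeta_atoms(model, warn = FALSE)
  dist <- sqrt(rowSums((cbind(cb$x, cb$y, cb$z) -
                          rep(ctr, each = nrow(cb)))^2))
  out <- tibble(chain_id = cb$chain_id, res_number = cb$res_number,
                center_dist = dist,
                center_dist_corrected = if (rg > 0) dist / rg else NA_real_)
  attr(out, "rg") <- rg
  out
}
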