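# Fixture builders and independent oracles, shared across test files.

# Format a PDB ATOM/HETATM record (standard fixed columns).
pdb_atom_line <- function(eleno, name, resid, chain, resno, x, y, z,
                          type = "ATOM", alt = " ", occ = 1, b = 0,
                          element = substr(gsub("[0-9]", "", name), 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, paste0(" ", name), alt, resid, chain, resno,
          x, y, z, occ, b, element)
}

# A minimal structure_model built directly from vectors of Ca (and
# optionally Cb) coordinates.
toy_model <- function(ca, aa = NULL, cb = NULL, chain = "A",
                      source_id = "toy") {
  n <- nrow(ca)
  aa <- aa %||% rep("A", n)
  rows <- tibble::tibble(
    chain_id = chain, res_number = seq_len(n), aa = aa,
    resid3 = ubistruct::aa123(aa), atom_name = "CA", element = "C",
    x = ca[, 1], y = ca[, 2], z = ca[, 3], het = FALSE
  )
  if (!is.null(cb)) {
    keep <- aa != "G"
    aa_cb <- aa[keep]
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      chain_id = chain, res_number = which(keep), aa = aa_cb,
      resid3 = ubistruct::aa123(aa_cb), atom_name = "CB", element = "C",
      x = cb[keep, 1], y = cb[keep, 2], z = cb[keep, 3], het = FALSE
    ))
  }
  ubistruct::structure_model(rows, source_id = source_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic alpha-helical Ca trace: 2.3 A radius, 1.5 A rise, 100 deg/residue
# (right-handed).
ideal_helix_ca <- function(n, radius = 2.3, rise = 1.5, turn = 100) {
  i <- 0:(n - 1)
  th <- i * turn * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

# Independent BFS shortest paths on an adjacency matrix.
bfs_dist_oracle <- function(adj, v) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[v] <- 0
  frontier <- v
  while (length(frontier) > 0) {
    nxt <- integer()
    for (u in frontier) {
      nb <- which(adj[u, ] & is.infinite(d))
      d[nb] <- d[u] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

# Reachable-set closeness from the BFS oracle.
closeness_oracle <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    d <- bfs_dist_oracle(adj, v)[-v]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / sum(d[is.finite(d)])) * (r / (n - 1))
  }, numeric(1))
}

# Exhaustive two-sided rank-sum p-value by bitmask enumeration of all
# assignments of the pooled sample to group 1.
wilcoxon_p_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  rk <- rank(pooled)
  mu <- n1 * (n + 1) / 2
  obs <- sum(rk[seq_len(n1)])
  ws <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) == n1) ws <- c(ws, sum(rk[bits == 1]))
  }
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

# Monte-Carlo single-atom-pair SASA oracle: random points on the extended
# sphere, kept when outside the neighbour's extended sphere.
sasa_pair_oracle <- function(p1, p2, r1, r2, probe, n = 200000, seed = 99) {
  set.seed(seed)
  R1 <- r1 + probe; R2 <- r2 + probe
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * R1 + rep(p1, each = n)
  keep <- sqrt(rowSums((pts - rep(p2, each = n))^2)) > R2
  4 * pi * R1^2 * mean(keep)
}

# Independent dihedral via the atan2(|b2| b1 . (b2 x b3), (b1 x b2).(b2 x b3))
# formulation.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  atan2(sqrt(sum(b2^2)) * sum(b1 * cr(b2, b3)),
        sum(cr(b1, b2) * cr(b2, b3))) * 180 / pi
}

# Trapezoidal area under a ubi_roc curve.
trapezoid_auc <- function(roc) {
  cv <- roc$curve
  sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
}

# Small labelled benchmark reused by several files (cached per session).
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- ubistruct::generate_benchmark_set(
        ubistruct::synthetic_spec(n_chains = 8, chain_length = c(60, 120),
                                  seed = 2024)
      )
    }
    cache
  }
})
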