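# Parsing, assembly construction, site labelling, dataset filters.

make_pdb_text <- function(lines) paste(c(lines, "END"), collapse = "\n")

test_that("parsing keeps the first model, first altLoc, and drops hydrogens", {
  txt <- make_pdb_text(c(
    "MODEL        1",
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0, element = "C"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 2.0, 1.4, 0, alt = "A", element = "C"),
    pdb_atom_line(4, "CB", "ALA", "A", 1, 9.9, 9.9, 0, alt = "B", element = "C"),
    pdb_atom_line(5, "H", "ALA", "A", 1, 0.5, 0.9, 0, element = "H"),
    pdb_atom_line(6, "CA", "GLY", "A", 2, 3.8, 0, 0, element = "C"),
    pdb_atom_line(7, "CA", "LYS", "A", 3, 7.6, 0, 0, element = "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 50, 50, 50, element = "C"),
    "ENDMDL"
  ))
  m <- parse_structure(txt, source_id = "fix")
  expect_equal(nrow(model_residues(m)), 3)
  expect_false(any(m$element == "H"))
  # first altLoc kept, occupancy ignored
  cb <- m[m$atom_name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(c(cb$x, cb$y), c(2.0, 1.4))
  # model 2 coordinates absent
  expect_false(any(m$x == 50))
  # one atom per (residue, atom_name)
  expect_equal(anyDuplicated(paste(m$chain_id, m$res_number, m$atom_name)), 0)
})

test_that("MODRES-annotated hetero residues are restored on request", {
  txt <- make_pdb_text(c(
    "MODRES 1ABC MLZ A    3  LYS  N-METHYL-LYSINE",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0, element = "C"),
    pdb_atom_line(3, "CA", "MLZ", "A", 3, 7.6, 0, 0, type = "HETATM",
                  element = "C")
  ))
  plain <- parse_structure(txt)
  expect_equal(nrow(model_residues(plain)), 2)
  expect_true(any(plain$het))
  restored <- parse_structure(txt, restore_modified = TRUE)
  res <- model_residues(restored)
  expect_equal(nrow(res), 3)
  expect_equal(res$aa[res$res_number == 3], "K")
})

test_that("parse failures and insertion codes are structured errors", {
  expect_error(parse_structure("JUNK RECORD\nEND", source_id = "bad"),
               "ATOM")
  txt <- make_pdb_text(
    pdb_atom_line(1, "CA", "ALA", "B", 1, 0, 0, 0, element = "C")
  )
  expect_error(parse_structure(txt, chain = "Z"), "chain")
})

test_that("round-trip through PDB format preserves residues and coordinates", {
  m <- small_benchmark()$models[[1]]
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, tf)
  back <- parse_structure(tf)
  expect_equal(nrow(back), nrow(m))
  expect_equal(model_residues(back)$aa, model_residues(m)$aa)
  ord <- order(back$res_number, back$atom_name)
  ord0 <- order(m$res_number, m$atom_name)
  expect_lt(max(abs(back$x[ord] - m$x[ord0])), 1e-3)
  expect_lt(max(abs(back$z[ord] - m$z[ord0])), 1e-3)
})

test_that("assembly transforms validate rotations and preserve geometry", {
  ca <- rbind(c(1, 0, 0), c(4.8, 0, 0), c(8.6, 0, 0))
  m <- toy_model(ca)
  ident <- tibble::tibble(
    biomolecule = 1L, transform = 1L, target_chains = list("A"),
    rotation = list(diag(3)), translation = list(c(0, 0, 0))
  )
  a1 <- apply_assembly(m, ident)
  expect_equal(unique(a1$chain_id), "A")
  expect_equal(a1$x, m$x)

  shift <- tibble::tibble(
    biomolecule = 1L, transform = 2L, target_chains = list("A"),
    rotation = list(diag(3)), translation = list(c(10, 0, 0))
  )
  dimer <- apply_assembly(m, dplyr::bind_rows(ident, shift))
  expect_setequal(unique(dimer$chain_id), c("A", "A.2"))
  c1 <- colMeans(as.matrix(dimer[dimer$chain_id == "A", c("x", "y", "z")]))
  c2 <- colMeans(as.matrix(dimer[dimer$chain_id == "A.2", c("x", "y", "z")]))
  expect_equal(sqrt(sum((c1 - c2)^2)), 10)
  # rigid transform: intra-copy distances preserved
  d0 <- dist(as.matrix(m[, c("x", "y", "z")]))
  d2 <- dist(as.matrix(dimer[dimer$chain_id == "A.2", c("x", "y", "z")]))
  expect_lt(max(abs(d0 - d2)), 1e-6)

  # 180 deg rotation about z maps (1,0,0) to (-1,0,0)
  rot <- tibble::tibble(
    biomolecule = 1L, transform = 2L, target_chains = list("A"),
    rotation = list(diag(c(-1, -1, 1))), translation = list(c(0, 0, 0))
  )
  flipped <- apply_assembly(m, rot)
  expect_equal(flipped$x[1], -1)
  expect_equal(flipped$y[1], 0)

  bad <- tibble::tibble(
    biomolecule = 1L, transform = 1L, target_chains = list("A"),
    rotation = list(matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 1), 3)),
    translation = list(c(0, 0, 0))
  )
  expect_error(apply_assembly(m, bad), "orthonormal")
  absent <- dplyr::mutate(ident, target_chains = list("Q"))
  expect_error(apply_assembly(m, absent), "absent")
})

test_that("REMARK 350 BIOMT records parse into transform tables", {
  lines <- c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A, B",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000       10.00000",
    "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        5.00000"
  )
  tr <- assembly_transforms(lines)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$target_chains[[1]], c("A", "B"))
  expect_equal(tr$rotation[[2]][1, 1], -1)
  expect_equal(tr$translation[[2]], c(10, 0, 5))
})

test_that("site annotation labels every lysine and reports rejects", {
  aa <- c("K", "A", "K", "G", "K")
  ca <- cbind(seq_along(aa) * 3.8, 0, 0)
  m <- toy_model(ca, aa = aa)
  ann <- tibble::tibble(chain_id = "A", res_number = c(1L, 4L, 99L),
                        label = c("Ub", "Ub", "Ace"))
  sites <- annotate_sites(m, ann)
  expect_equal(nrow(sites), 3) # one row per lysine
  expect_equal(sites$label[sites$res_number == 1], "Ub")
  expect_equal(sites$label[sites$res_number == 3], "NonUb")
  skipped <- attr(sites, "skipped")
  expect_equal(nrow(skipped), 2)
  expect_true(any(grepl("not lysine", skipped$reason)))
  expect_true(any(grepl("absent", skipped$reason)))

  empty <- annotate_sites(m, NULL)
  expect_true(all(empty$label == "NonUb"))
})

test_that("dataset filter drops redundant, single-class and flagged chains", {
  mk <- function(aa, chain) {
    toy_model(cbind(seq_along(aa) * 3.8, 0, 0), aa = aa, chain = chain)
  }
  seq1 <- c("K", "A", "L", "K", "V", "E", "K", "T", "Y", "W")
  seq2 <- seq1                      # identical -> redundant
  seq3 <- c("K", "P", "D", "K", "H", "C", "M", "F", "R", "N") # dissimilar
  m1 <- mk(seq1, "A"); m2 <- mk(seq2, "B"); m3 <- mk(seq3, "C")
  s <- function(m, ub_at) {
    annotate_sites(m, tibble::tibble(chain_id = unique(m$chain_id),
                                     res_number = ub_at, label = "Ub"))
  }
  coll <- tibble::tibble(
    chain = c("A", "B", "C"),
    model = list(m1, m2, m3),
    sites = list(s(m1, 1L), s(m2, 1L), s(m3, 1L))
  )
  out <- filter_dataset(coll)
  expect_equal(nrow(out), 2) # one of the identical pair dropped
  expect_true("C" %in% out$chain)
  # idempotence
  expect_identical(filter_dataset(out)$chain, out$chain)

  # chain with Ub only is removed
  all_ub <- s(m3, 1L)
  all_ub$label <- "Ub"
  coll2 <- tibble::tibble(chain = "C", model = list(m3), sites = list(all_ub))
  expect_equal(nrow(filter_dataset(coll2)), 0)
  # low resolution flag removes the chain
  coll3 <- dplyr::mutate(coll, resolution_ok = c(TRUE, TRUE, FALSE))
  expect_false("C" %in% filter_dataset(coll3)$chain)
  # empty input is fine
  expect_equal(nrow(filter_dataset(coll[0, ])), 0)
})

test_that("global-alignment identity behaves like a fraction of matches", {
  expect_equal(seq_identity("KALKV", "KALKV"), 1)
  expect_lt(seq_identity("KALKVEKTYW", "KPDKHCMFRN"), 0.5)
  expect_equal(seq_identity("", "KAL"), 0)
})
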