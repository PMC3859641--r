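# Kappa/alpha angles, structural alphabet assignment, DSSP reading.

test_that("kappa is 180 on a collinear trace and alpha 0 on a planar cis one", {
  line <- cbind(seq(0, 8) * 3.8, 0, 0)
  ka <- compute_kappa_alpha(toy_model(line))
  expect_true(all(abs(ka$kappa[!is.na(ka$kappa)] - 180) < 1e-6))

  # planar "cis" zigzag: p1 and p4 on the same side -> alpha = 0
  cis <- rbind(c(0, 1, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0), c(4, 0, 0))
  ka2 <- compute_kappa_alpha(toy_model(cis), chain_break_cutoff = 10)
  expect_equal(ka2$alpha[2], 0, tolerance = 1e-9)
})

test_that("an ideal right-handed helix gives kappa ~89 and alpha ~+50", {
  hx <- ideal_helix_ca(12)
  ka <- compute_kappa_alpha(toy_model(hx))
  mid <- !is.na(ka$kappa) & !is.na(ka$alpha)
  expect_true(all(abs(ka$kappa[mid] - 89) < 2))
  expect_true(all(abs(ka$alpha[mid] - 50) < 2))
  # independent vector-algebra oracle at one position
  i <- 5
  expect_equal(ka$alpha[i],
               dihedral_oracle(hx[i - 1, ], hx[i, ], hx[i + 1, ], hx[i + 2, ]),
               tolerance = 1e-9)
})

test_that("angles are undefined at chain ends and across breaks", {
  hx <- ideal_helix_ca(10)
  broken <- hx
  broken[6:10, 3] <- broken[6:10, 3] + 50 # > 4.5 A jump between 5 and 6
  ka <- compute_kappa_alpha(toy_model(broken))
  expect_true(is.na(ka$kappa[1]))
  expect_true(is.na(ka$alpha[nrow(ka)]))
  expect_true(is.na(ka$kappa[5]) && is.na(ka$kappa[6]))

  # mirror reflection flips alpha, keeps kappa
  mir <- hx; mir[, 1] <- -mir[, 1]
  ka0 <- compute_kappa_alpha(toy_model(hx))
  kam <- compute_kappa_alpha(toy_model(mir))
  ok <- !is.na(ka0$alpha)
  expect_equal(kam$alpha[ok], -ka0$alpha[ok], tolerance = 1e-9)
  expect_equal(kam$kappa[!is.na(ka0$kappa)], ka0$kappa[!is.na(ka0$kappa)],
               tolerance = 1e-9)

  # rigid motion leaves both angles unchanged
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  kar <- compute_kappa_alpha(toy_model(hx %*% rot + 3))
  expect_equal(kar$kappa[ok], ka0$kappa[ok], tolerance = 1e-6)
  expect_equal(kar$alpha[ok], ka0$alpha[ok], tolerance = 1e-6)
})

test_that("alphabet assignment is nearest-centroid with Y merged into A", {
  map <- sa_alphabet()
  expect_equal(nrow(map), 23) # 22 states plus the merged Y entry
  expect_equal(map$merge_into[map$state == "Y"], "A")

  # a centroid's own angles assign to that state
  e <- map[map$state == "E", ]
  got <- assign_structural_alphabet(tibble::tibble(kappa = e$kappa,
                                                   alpha = e$alpha))
  expect_equal(got$sa_state, "E")
  expect_equal(got$sa_group, "strand")

  # Y's centroid relabels to A, group helix
  y <- map[map$state == "Y", ]
  gy <- assign_structural_alphabet(tibble::tibble(kappa = y$kappa,
                                                  alpha = y$alpha))
  expect_equal(gy$sa_state, "A")
  expect_equal(gy$sa_group, "helix")

  # helix-ideal angles land in the helix group
  gh <- assign_structural_alphabet(tibble::tibble(kappa = 89, alpha = 50))
  expect_true(gh$sa_group == "helix")

  # undefined angles give undefined states, not errors
  gna <- assign_structural_alphabet(tibble::tibble(kappa = NA_real_,
                                                   alpha = 20))
  expect_true(is.na(gna$sa_state))
})

test_that("assignment equals a brute-force scan with alpha wrap-around", {
  map <- sa_alphabet()
  set.seed(5)
  kk <- runif(400, 0, 180)
  aa <- runif(400, -180, 180)
  got <- assign_structural_alphabet(tibble::tibble(kappa = kk, alpha = aa))
  wrap <- function(x) { x <- (x + 180) %% 360 - 180; ifelse(x == -180, 180, x) }
  want <- vapply(seq_along(kk), function(i) {
    d <- sqrt((kk[i] - map$kappa)^2 + wrap(aa[i] - map$alpha)^2)
    cand <- map$state[d == min(d)]
    st <- sort(cand)[1]
    if (!is.na(map$merge_into[map$state == st])) map$merge_into[map$state == st] else st
  }, "")
  expect_equal(got$sa_state, want)
})

test_that("ideal helices and strands map to their conformational groups", {
  hx <- assign_structural_alphabet(compute_kappa_alpha(toy_model(ideal_helix_ca(20))))
  def <- hx[!is.na(hx$sa_state), ]
  expect_gte(mean(def$sa_group == "helix"), 0.95)

  # pleated strand trace (3.3 A axial step, 1.9 A alternating displacement)
  i <- 0:14
  strand <- cbind(i * 3.3, 1.9 * (i %% 2), 0)
  st <- assign_structural_alphabet(compute_kappa_alpha(toy_model(strand)))
  def2 <- st[!is.na(st$sa_state), ]
  expect_gte(mean(def2$sa_group == "strand"), 0.95)
})

test_that("DSSP files parse with blank codes mapped to L", {
  dssp <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  H  >0   0    0",
    "    2    2 A K  G  X0   0    0",
    "    3    3 A V     X0   0    0",
    "    4      A !              0",
    "    5    5 A L  E  <0   0    0"
  )
  ss <- read_dssp(paste(dssp, collapse = "\n"))
  expect_equal(nrow(ss), 4) # break row skipped
  expect_equal(ss$ss_type, c("H", "G", "L", "E"))
  expect_equal(ss$res_number, c(1L, 2L, 3L, 5L))
  expect_error(read_dssp("no header here"), "header")
})

test_that("DSSP-structure mismatches are reported with residue lists", {
  aa <- c("M", "K", "V")
  m <- toy_model(cbind(0:2 * 3.8, 0, 0), aa = aa)
  ok <- tibble::tibble(chain_id = "A", res_number = 1:3, aa = aa,
                       ss_type = c("H", "H", "L"))
  joined <- match_secondary_structure(m, ok)
  expect_equal(joined$ss_type, c("H", "H", "L"))
  extra <- dplyr::bind_rows(ok, tibble::tibble(chain_id = "A", res_number = 9L,
                                               aa = "W", ss_type = "T"))
  expect_error(match_secondary_structure(m, extra), "9")
  expect_error(match_secondary_structure(m, ok[-2, ]), "2")
})

test_that("state grouping follows the packaged table and rejects unknowns", {
  expect_equal(group_alphabet_states(c("E", "V", "Z", "A")),
               c("strand", "highly-curved-coil", "flat-coil", "helix"))
  expect_error(group_alphabet_states("J"), "unknown")
})
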