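test_that("known molecules get the expected descriptor vectors", {
  d <- compute_descriptors(c("O=C1CCCCCCCCCCCCO1",  # oxacyclotetradecan-2-one
                             "C1CCCCCCCCCCC1"))     # cyclododecane
  expect_equal(d$MW[1], 212.33, tolerance = 0.01)
  expect_equal(d$heteroatoms[1], 2L)
  expect_equal(d$heavyatoms[1], 15L)
  expect_equal(d$HBD[1], 0L)
  expect_equal(d$HBA[1], 2L)
  expect_equal(d$TPSA[1], 26.3)
  expect_equal(d$NRB[1], 0L)

  expect_equal(d$heteroatoms[2], 0L)
  expect_equal(d$HBA[2], 0L)
  expect_equal(d$HBD[2], 0L)
  expect_equal(d$NRB[2], 0L)

  # determinism
  expect_identical(compute_descriptors("O=C1CCCCCCCCCCCCO1"),
                   compute_descriptors("O=C1CCCCCCCCCCCCO1"))
})

test_that("rotatable bonds follow the acyclic non-terminal convention", {
  d <- compute_descriptors(c("CCCC", "CC(C)C", "CCOC", "c1ccccc1C=O"))
  expect_equal(d$NRB, c(1L, 0L, 1L, 1L))
})

test_that("composition determines the additive descriptors regardless of arrangement", {
  reg <- load_motifs()
  comp <- rep(c("SM001", "SM002", "SM004", "SM005", "SM006", "SM013"),
              c(3, 4, 1, 1, 1, 2))
  smis <- withr::with_seed(12, vapply(1:50, function(i)
    assemble_macrocycle(sample(comp), reg), character(1)))
  d <- compute_descriptors(smis)
  for (cn in c("heavyatoms", "heteroatoms", "HBD", "HBA"))
    expect_length(unique(d[[cn]]), 1L)
  for (cn in c("MW", "TPSA"))  # additive; identical up to float summation order
    expect_lt(diff(range(d[[cn]])), 1e-9)
})

test_that("drug-likeness flags use the Lipinski/Veber thresholds with inclusive bounds", {
  desc <- tibble::tibble(
    MW = c(456.6, 500.1, 500), SlogP = c(3.3, 5.57, 5),
    HBD = c(2L, 6L, 5L), HBA = c(7L, 11L, 10L),
    TPSA = c(110, 153.47, 140), NRB = c(4L, 11L, 10L))
  f <- flag_druglikeness(desc)
  expect_true(all(unlist(f[1, ])))
  expect_false(any(unlist(f[2, ])))
  expect_true(all(unlist(f[3, c("lipinski_mw", "lipinski_slogp", "lipinski_hbd",
                                "lipinski_hba", "veber_tpsa", "veber_nrb")])))
  # monotone in MW: raising MW can only flip pass -> fail
  lo <- flag_druglikeness(tibble::tibble(MW = 499, SlogP = 1, HBD = 0, HBA = 0, TPSA = 0, NRB = 0))
  hi <- flag_druglikeness(tibble::tibble(MW = 501, SlogP = 1, HBD = 0, HBA = 0, TPSA = 0, NRB = 0))
  expect_true(lo$lipinski_mw)
  expect_false(hi$lipinski_mw)
})

test_that("library summaries report the configured sample statistics", {
  one <- tibble::tibble(MW = 400, SlogP = 2, TPSA = 90, HBA = 5L, HBD = 1L,
                        NRB = 3L, heteroatoms = 5L, heavyatoms = 28L,
                        sequence = "A-B")
  s1 <- summarize_library(one)
  mw <- s1$stats[s1$stats$descriptor == "MW", ]
  expect_equal(mw$min, 400); expect_equal(mw$max, 400)
  expect_equal(mw$mean, 400); expect_equal(mw$sd, 0)

  two <- rbind(one, one)
  two$MW <- c(400, 440)
  s2 <- summarize_library(two)
  mw2 <- s2$stats[s2$stats$descriptor == "MW", ]
  expect_equal(mw2$mean, 420)
  expect_equal(mw2$sd, sqrt((20^2 + 20^2) / 1))  # sample SD, 28.28
  expect_error(summarize_library(one[0, ]), class = "macrolib_domain_error")

  expect_equal(s2$motif_usage$scaffolds_containing, c(2, 2))
  expect_equal(s2$motif_usage$total_occurrences, c(2, 2))
})

test_that("correlations agree with a direct two-pass Pearson to 1e-12", {
  set.seed(42)
  tbl <- tibble::tibble(MW = rnorm(200, 400, 20))
  tbl$heavyatoms <- tbl$MW / 14 + rnorm(200, 0, 0.5)
  tbl$TPSA <- runif(200, 50, 130)
  tbl$HBA <- rpois(200, 6)
  r <- correlation_matrix(tbl, vars = c("MW", "heavyatoms", "TPSA", "HBA"))
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  for (pair in list(c("MW", "heavyatoms"), c("MW", "TPSA"), c("TPSA", "HBA"))) {
    expect_equal(r[pair[1], pair[2]],
                 oracle_pearson(tbl[[pair[1]]], tbl[[pair[2]]]),
                 tolerance = 1e-12)
  }
  # perfectly linear pair
  lin <- tibble::tibble(MW = 1:10, heavyatoms = 2 * (1:10) + 3)
  expect_equal(correlation_matrix(lin, c("MW", "heavyatoms"))["MW", "heavyatoms"], 1)
  # constant column is undefined, not zero
  const <- tibble::tibble(MW = rnorm(5), HBD = rep(2L, 5))
  rc <- correlation_matrix(const, c("MW", "HBD"))
  expect_true(is.na(rc["MW", "HBD"]))
})

test_that("acceptors equal heteroatoms across any common-motif library", {
  reg <- load_motifs(categories = "common")
  pool <- rep(reg$motifs$motif_id, reg$motifs$default_repeat_cap)
  smis <- withr::with_seed(5, vapply(1:60, function(i)
    assemble_macrocycle(sample(pool, 8), reg), character(1)))
  d <- compute_descriptors(smis)
  expect_identical(d$HBA, d$heteroatoms)
  r <- correlation_matrix(d, c("HBA", "heteroatoms"))
  expect_equal(r["HBA", "heteroatoms"], 1)
})
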