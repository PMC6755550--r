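test_that("tanimoto follows set arithmetic, symmetry and bounds", {
  a <- rep(0L, 10); a[c(1, 2, 3)] <- 1L
  b <- rep(0L, 10); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(rep(0L, 10), rep(0L, 10)), 0)
  d <- rep(0L, 10); d[8:10] <- 1L
  expect_equal(tanimoto(a, d), 0)
  expect_error(tanimoto(a, rep(0L, 9)), class = "macrolib_domain_error")

  set.seed(9)
  for (i in 1:25) {
    x <- rbinom(64, 1, 0.3); y <- rbinom(64, 1, 0.3)
    t1 <- tanimoto(x, y)
    expect_equal(t1, tanimoto(y, x))
    expect_gte(t1, 0); expect_lte(t1, 1)
    if (sum(x)) expect_equal(tanimoto(x, x), 1)
  }
})

test_that("MACCS keys are deterministic, 2D and chirality-blind", {
  s <- "CC1CC(C)C(O)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1"
  fp1 <- maccs_fingerprint(s)
  fp2 <- maccs_fingerprint(s)
  expect_identical(fp1, fp2)
  expect_true(all(fp1 %in% c(0, 1)))
  # stereoisomers share a fingerprint
  iso <- maccs_fingerprint(c("C[C@H](O)CC(=O)OC1CCCCCCCCCCC1",
                             "C[C@@H](O)CC(=O)OC1CCCCCCCCCCC1"))
  expect_identical(iso[1, ], iso[2, ])
  # degenerate input: tiny molecule, sparse vector, no error
  tiny <- maccs_fingerprint("C")
  expect_lt(sum(tiny), 5)
})

test_that("maximum aggregation picks the argmax probe, first-wins on ties", {
  recs <- c("O=C1CCCCCCCCCCCCO1",
            "CC1CC(C)C(O)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1",
            "CCC1CC(=O)CC(C)C(O)CC(OC)CC(C)C(=O)O1")
  probes <- c(pA = "O=C1CCCCCCCCCCCCO1",
              pB = "CC1CC(C)C(O)CC(=O)CC(C)CC(C)CC(C)C(=O)O1")
  res <- best_probe_similarity(recs, probes)
  # exhaustive pairwise oracle
  fr <- maccs_fingerprint(recs); fpb <- maccs_fingerprint(probes)
  for (i in seq_along(recs)) {
    scores <- vapply(1:2, function(j) tanimoto(fr[i, ], fpb[j, ]), numeric(1))
    expect_equal(res$scores$best_score[i], max(scores))
    expect_equal(res$scores$best_probe[i], names(probes)[which.max(scores)])
  }
  expect_equal(res$scores$best_score[1], 1)  # record equals probe pA
  expect_equal(res$scores$best_probe[1], "pA")

  # duplicated probe fingerprints give identical scores; tie goes to the first
  twin <- c(first = probes[[2]], second = probes[[2]])
  res2 <- best_probe_similarity(recs, twin)
  expect_true(all(res2$scores$best_probe == "first"))
  expect_error(best_probe_similarity(recs, character(0)),
               class = "macrolib_domain_error")
})

test_that("probe simplification removes sugars and truncates esters and amines", {
  core <- "CC1CC(C)C(O)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1"
  # O-linked tetrahydropyran (sugar-like) -> hydroxyl at the attachment O
  sugar <- "CC1CC(C)C(OC2CCCCO2)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1"
  expect_identical(simplify_probe(sugar), standardize(core))
  # exocyclic acetate -> hydroxyl
  acetate <- "CC1CC(C)C(OC(C)=O)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1"
  expect_identical(simplify_probe(acetate), standardize(core))
  # substituted amine -> primary amine
  amine <- "CC1CC(C)C(N(C)C)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1"
  amine_core <- "CC1CC(C)C(N)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1"
  expect_identical(simplify_probe(amine), standardize(amine_core))
  # bare scaffold is a fixed point; the transform is idempotent
  expect_identical(simplify_probe(core), standardize(core))
  for (s in c(sugar, acetate, amine)) {
    once <- simplify_probe(s)
    expect_identical(simplify_probe(once), once)
  }
  # plain ethers and hydroxyls survive untouched
  ether <- "CC1CC(C)C(OC)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1"
  expect_identical(simplify_probe(ether), standardize(ether))
  expect_error(simplify_probe("C1CCCCC1"), class = "macrolib_domain_error")
})

test_that("the shipped synthetic probe file loads and behaves", {
  path <- system.file("extdata", "probes_synthetic.smi", package = "macrolib")
  expect_true(nzchar(path))
  lines <- readLines(path)
  parts <- strsplit(lines, " ", fixed = TRUE)
  probes <- stats::setNames(vapply(parts, `[`, character(1), 1),
                            vapply(parts, `[`, character(1), 2))
  expect_gte(length(probes), 5L)
  simplified <- vapply(probes, simplify_probe, character(1))
  # glycoside and acetate collapse onto the bare scaffold
  expect_identical(simplified[["synthetic_glycoside_02"]],
                   simplified[["synthetic_macrolactone_01"]])
  expect_identical(simplified[["synthetic_acetate_03"]],
                   simplified[["synthetic_macrolactone_01"]])
})
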