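test_that("length pairs honour ranges, ring-size precedence and priority order", {
  reg <- load_motifs()
  v1m <- v1m_rules()
  lp <- generate_length_pairs(v1m, 12)
  expect_equal(nrow(lp), 1L)
  expect_equal(lp$L_C, 12L)
  expect_equal(lp$L_R, 0L)

  r <- building_rules(csm_min = 1, csm_max = 2, rsm_min = 1, rsm_max = 2,
                      total_min = 3, total_max = 5, priority = "common")
  lp3 <- generate_length_pairs(r, 3)
  expect_equal(lp3$L_C, c(2L, 1L))
  expect_equal(lp3$L_R, c(1L, 2L))
  expect_equal(nrow(generate_length_pairs(r, 5)), 0L)

  rr <- building_rules(csm_min = 1, csm_max = 2, rsm_min = 1, rsm_max = 2,
                       total_min = 3, total_max = 3, priority = "rare")
  lpr <- generate_length_pairs(rr, 3)
  expect_equal(lpr$L_C, c(1L, 2L))
})

test_that("combinations are duplicate-free, cap-respecting and complete", {
  combos <- generate_combinations(c("A", "A", "B"), 2)
  keys <- sort(vapply(combos, function(x) paste(rep(names(x), x), collapse = ""), character(1)))
  expect_identical(keys, c("AA", "AB"))
  expect_identical(generate_combinations(c("A", "B"), 0), list(integer(0)))
  expect_identical(generate_combinations(c("A", "B"), 3), list())

  # benchmark pool: generating-function count of size-12 sub-multisets
  pool <- rep(c("SM001","SM002","SM003","SM004","SM005","SM006","SM008","SM009","SM013"),
              c(3, 4, 1, 1, 1, 2, 1, 1, 2))
  combos12 <- generate_combinations(pool, 12)
  expect_equal(length(combos12), 261L)
  keys12 <- vapply(combos12, function(x)
    paste(sort(rep(names(x), x)), collapse = "|"), character(1))
  expect_false(anyDuplicated(keys12) > 0)
  for (cc in combos12) {
    expect_equal(sum(cc), 12)
    expect_true(all(cc <= c(SM001 = 3, SM002 = 4, SM003 = 1, SM004 = 1, SM005 = 1,
                            SM006 = 2, SM008 = 1, SM009 = 1, SM013 = 2)[names(cc)]))
  }
})

test_that("templates are emitted once, across repeated arrivals", {
  store <- new.env(parent = emptyenv())
  t1 <- make_templates(list(c(A = 1L, B = 1L)), list(integer(0)), store)
  expect_length(t1, 1L)
  t2 <- make_templates(list(c(A = 2L), c(A = 1L, B = 1L)), list(c(C = 1L)), store)
  keys <- vapply(t2, attr, character(1), "key")
  expect_length(t2, 2L)
  expect_setequal(keys, c("A:2|C:1", "A:1|B:1|C:1"))
  # duplicate arriving again is suppressed
  t3 <- make_templates(list(c(A = 2L)), list(c(C = 1L)), store)
  expect_length(t3, 0L)
})

test_that("assembly produces the expected lactone and carbocycle", {
  reg <- load_motifs()
  lact <- assemble_macrocycle(rep("SM001", 12), reg, add_ester = TRUE)
  expect_identical(lact, standardize("O=C1CCCCCCCCCCCCO1"))
  d <- compute_descriptors(lact)
  expect_equal(d$MW, 212.33, tolerance = 0.01)
  expect_equal(d$heteroatoms, 2L)
  expect_equal(d$heavyatoms, 15L)
  expect_equal(d$HBD, 0L)

  carb <- assemble_macrocycle(rep("SM001", 12), reg, add_ester = FALSE)
  expect_identical(carb, standardize("C1CCCCCCCCCCC1"))
  dc <- compute_descriptors(carb)
  expect_equal(dc$MW, 168.32, tolerance = 0.01)
  expect_equal(dc$heteroatoms, 0L)
})

test_that("a sequence and its reversal close to the same ring", {
  reg <- load_motifs()
  seqs <- list(c("SM001", "SM002", "SM005", "SM001"),
               c("SM004", "SM001", "SM006", "SM002", "SM001"))
  for (s in seqs) {
    expect_identical(assemble_macrocycle(s, reg, add_ester = FALSE),
                     assemble_macrocycle(rev(s), reg, add_ester = FALSE))
  }
})

test_that("standardization is idempotent on random assemblies", {
  reg <- load_motifs(categories = "common")
  pool <- rep(reg$motifs$motif_id, reg$motifs$default_repeat_cap)
  raw <- withr::with_seed(99, replicate(40, {
    s <- sample(pool, 8)
    assemble_macrocycle(s, reg, add_ester = sample(c(TRUE, FALSE), 1),
                        canonical = FALSE)
  }))
  once <- standardize(raw)
  expect_identical(standardize(once), once)
  # explicit hydrogens collapse to the same heavy-atom graph
  expect_identical(standardize("C([H])([H])C([H])([H])O[H]"), standardize("CCO"))
})

test_that("skip-0 traversal of a template stream yields the raw permutations", {
  units <- c("A", "B")
  tmpl <- list(structure(c(A = 1L, B = 1L), key = "A:1|B:1"))
  out <- permute_with_skip(units, tmpl, skip = 0, n = 10)
  expect_length(out$sequences, 2L)
  expect_setequal(vapply(out$sequences, paste, character(1), collapse = ""),
                  c("AB", "BA"))
  expect_true(out$exhausted)
})

test_that("duplicated units triple-count the raw stream but collapse on dedupe", {
  tab <- two_motif_table  # A cap 2, B cap 1
  reg <- toy_registry(tab)
  units <- expand_units(reg)
  tmpl <- list(structure(c(A = 2L, B = 1L), key = "A:2|B:1"))
  out <- permute_with_skip(units, tmpl, skip = 0, n = 100)
  expect_length(out$sequences, 6L)  # 3! instance permutations
  smis <- vapply(out$sequences, function(s)
    assemble_macrocycle(s, reg, add_ester = TRUE, canonical = FALSE), character(1))
  expect_length(unique(standardize(smis)), 3L)
})

test_that("stream arithmetic: candidates appear at multiples of the stride", {
  tab <- two_motif_table
  tab$default_repeat_cap <- c(3L, 2L)
  reg <- toy_registry(tab)
  units <- expand_units(reg)
  tmpls <- generate_combinations(units, 3)
  tmpls <- lapply(tmpls, function(x) { attr(x, "key") <- "k"; x })
  for (skip in c(7, 25)) {
    out <- permute_with_skip(units, tmpls, skip = skip, n = 5)
    expect_equal(out$positions, skip * (seq_along(out$positions) - 1))
  }
})

test_that("exhaustive enumeration equals the brute-force oracle", {
  cases <- list(
    list(motifs = tibble::tibble(
      motif_id = c("A", "B"), category = "common",
      fragment = c("[*:1]C[*:2]", "[*:1]C(C)[*:2]"),
      default_repeat_cap = c(2L, 1L)), ring = 3L, ester = FALSE),
    list(motifs = tibble::tibble(
      motif_id = c("A", "B", "C"), category = "common",
      fragment = c("[*:1]C[*:2]", "[*:1]C(O)[*:2]", "[*:1]C(=O)[*:2]"),
      default_repeat_cap = c(2L, 1L, 1L)), ring = 4L, ester = TRUE),
    list(motifs = tibble::tibble(
      motif_id = c("A", "B", "C"), category = c("common", "common", "rare"),
      fragment = c("[*:1]C[*:2]", "[*:1]C(C)(O)[*:2]", "[*:1]C(=C)[*:2]"),
      default_repeat_cap = c(3L, 2L, 1L)), ring = 5L, ester = TRUE)
  )
  for (cs in cases) {
    reg <- toy_registry(cs$motifs, seed = 21L)
    caps <- stats::setNames(cs$motifs$default_repeat_cap, cs$motifs$motif_id)
    rules <- building_rules(csm_min = 0, csm_max = cs$ring, rsm_min = 0,
                            rsm_max = cs$ring, total_min = cs$ring,
                            total_max = cs$ring, skip = 0, library_size = 1e6,
                            add_ester = cs$ester)
    res <- suppressWarnings(run_enumeration(rules, reg, compute_descriptors = FALSE))
    expected <- oracle_library(reg, caps, cs$ring, add_ester = cs$ester)
    expect_setequal(res$records$smiles, expected)
    expect_false(anyDuplicated(res$records$smiles) > 0)
  }
})

test_that("emitted records satisfy every constraint of the rules", {
  reg <- load_motifs()
  rules <- v1m_rules(library_size = 300, skip = 2.9e9)
  res <- run_enumeration(rules, reg, compute_descriptors = FALSE)
  expect_equal(nrow(res$records), 300L)
  caps <- c(SM001 = 3, SM002 = 4, SM003 = 1, SM004 = 1, SM005 = 1,
            SM006 = 2, SM008 = 1, SM009 = 1, SM013 = 2)
  for (s in strsplit(res$records$sequence, "-", fixed = TRUE)) {
    expect_length(s, 12L)
    tb <- table(s)
    expect_true(all(tb <= caps[names(tb)]))
  }
  expect_false(anyDuplicated(res$records$smiles) > 0)
  # every scaffold is a lactone: exactly one in-ring ester
  expect_true(all(grepl("O", res$records$smiles, fixed = TRUE)))
})

test_that("runs are deterministic and exhaust gracefully", {
  fix <- make_toy_fixture(2, 3, seed = 7)
  r1 <- suppressWarnings(run_enumeration(fix$rules, fix$registry, compute_descriptors = FALSE))
  r2 <- suppressWarnings(run_enumeration(fix$rules, fix$registry, compute_descriptors = FALSE))
  expect_identical(r1$records, r2$records)

  small <- fix$rules
  small$library_size <- 1e6
  expect_warning(run_enumeration(small, fix$registry, compute_descriptors = FALSE),
                 "exhausted")
})
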