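#' Length pairs for one ring size
#'
#' All splits of a ring size into a common-unit count and a rare-unit count
#' allowed by the per-category ranges. With priority `"common"` the pairs are
#' sorted by ascending rare count (common-only first), and symmetrically for
#' `"rare"` priority, so the traversal exhausts the prioritized category
#' before admitting the other.
#'
#' @param rules a `building_rules` object.
#' @param ring_size total motif units in the macrocycle.
#' @param pool_common,pool_rare optional pool sizes used to cap the counts at
#'   what the repeat caps can actually supply.
#' @return tibble with columns `L_C`, `L_R` (possibly zero rows).
#' @export
generate_length_pairs <- function(rules, ring_size, pool_common = Inf, pool_rare = Inf) {
  lr_lo <- max(rules$rsm_min, ring_size - min(rules$csm_max, pool_common))
  lr_hi <- min(rules$rsm_max, pool_rare, ring_size - rules$csm_min)
  if (lr_lo > lr_hi)
    return(tibble::tibble(L_C = integer(0), L_R = integer(0)))
  lr <- seq(lr_lo, lr_hi)
  lp <- tibble::tibble(L_C = as.integer(ring_size - lr), L_R = as.integer(lr))
  if (rules$priority == "common") lp[order(lp$L_R), ] else lp[order(lp$L_C), ]
}

#' All distinct motif multisets of a given size from a capped unit pool
#'
#' Enumerates, without duplicates, every way to draw `length` units from the
#' pool respecting per-motif repeat caps. Motifs are visited in their
#' first-occurrence order in the (shuffled) pool and counts are allocated
#' largest-first, which fixes a deterministic generation order.
#'
#' @param units character vector of motif ids, one entry per unit.
#' @param length multiset size (0 gives the single empty multiset).
#' @return list of named integer count vectors (zero counts dropped).
#' @export
generate_combinations <- function(units, length) {
  stopifnot(length >= 0)
  if (length == 0L) return(list(integer(0)))
  ids <- unique(units)
  caps <- as.integer(table(factor(units, levels = ids)))
  if (length > sum(caps)) return(list())
  out <- list()
  rec <- function(i, remaining, acc) {
    if (remaining == 0L) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    if (i > length(ids)) return(invisible())
    tail_cap <- if (i < length(ids)) sum(caps[(i + 1L):length(ids)]) else 0L
    hi <- min(caps[i], remaining)
    lo <- max(0L, remaining - tail_cap)
    if (hi < lo) return(invisible())
    for (k in seq(hi, lo)) {
      acc2 <- acc
      if (k > 0L) acc2 <- c(acc2, stats::setNames(k, ids[i]))
      rec(i + 1L, remaining - k, acc2)
    }
  }
  rec(1L, as.integer(length), stats::setNames(integer(0), character(0)))
  out
}

#' Combine category halves into deduplicated composition templates
#'
#' Forms the cartesian product of common-category and rare-category
#' multisets and keeps each combined multiset once; templates already
#' present in `store` (the per-ring-size template storage) are suppressed,
#' which is what guarantees that no composition is enumerated twice.
#'
#' @param common_halves,rare_halves lists of named count vectors from
#'   [generate_combinations()].
#' @param store an environment used as the seen-template set (keys are the
#'   sorted multiset strings); a fresh one is created when `NULL`.
#' @return list of named integer count vectors, with attribute `key`.
#' @export
make_templates <- function(common_halves, rare_halves, store = NULL) {
  if (is.null(store)) store <- new.env(parent = emptyenv())
  out <- list()
  for (ch in common_halves) {
    for (rh in rare_halves) {
      counts <- c(ch, rh)
      ids <- sort(names(counts))
      key <- paste(sprintf("%s:%d", ids, counts[ids]), collapse = "|")
      if (!is.null(store[[key]])) next
      store[[key]] <- TRUE
      attr(counts, "key") <- key
      out[[length(out) + 1L]] <- counts
    }
  }
  out
}

#' All admissible composition templates for a rules/registry pair
#'
#' Enumerates every distinct motif multiset reachable under the rules (all
#' ring sizes, length pairs, caps). Useful for composition-level analyses:
#' descriptors that depend only on which motifs are present (molecular
#' weight, atom counts, H-bond counts, TPSA) can be computed once per
#' composition instead of once per arrangement.
#'
#' @param rules a `building_rules` object.
#' @param registry a `motif_registry`.
#' @return tibble with `ring_size`, `key`, `counts` (list column), and a
#'   representative assembled `smiles` per composition.
#' @export
enumerate_compositions <- function(rules, registry) {
  rules <- validate_rules(rules, registry)
  caps <- effective_caps(rules, registry)
  common_units <- expand_units(registry, caps[registry$motifs$motif_id[registry$motifs$category == "common"]],
                               categories = "common")
  rare_units <- expand_units(registry, caps[registry$motifs$motif_id[registry$motifs$category == "rare"]],
                             categories = "rare")
  rows <- list()
  for (ring_size in seq(rules$total_min, rules$total_max)) {
    store <- new.env(parent = emptyenv())
    lp <- generate_length_pairs(rules, ring_size,
                                pool_common = length(common_units),
                                pool_rare = length(rare_units))
    for (j in seq_len(nrow(lp))) {
      ch <- generate_combinations(common_units, lp$L_C[j])
      rh <- generate_combinations(rare_units, lp$L_R[j])
      for (tmpl in make_templates(ch, rh, store)) {
        seq_ids <- rep(names(tmpl), times = tmpl)
        smi <- assemble_macrocycle(seq_ids, registry, add_ester = rules$add_ester)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          ring_size = ring_size, key = attr(tmpl, "key"),
          counts = list(tmpl), smiles = smi)
      }
    }
  }
  do.call(rbind, rows)
}

# --- exact unranking of the instance-level stream --------------------------

# lexicographic unranking of the idx-th (0-based) k-combination of 1..n
unrank_combination <- function(n, k, idx) {
  out <- integer(k)
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      c_skip <- choose(n - x, k - i)
      if (idx < c_skip) break
      idx <- idx - c_skip
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

# Lehmer (factorial-base) unranking of the idx-th (0-based) permutation
unrank_permutation <- function(vec, idx) {
  n <- length(vec)
  out <- vector(mode = mode(vec), length = n)
  pool <- vec
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    d <- floor(idx / f)
    idx <- idx - d * f
    out[i] <- pool[d + 1L]
    pool <- pool[-(d + 1L)]
  }
  out
}

# stream-block bookkeeping for one template over a given unit pool
template_block <- function(tmpl, unit_pool) {
  ids <- names(tmpl)
  caps <- vapply(ids, function(id) sum(unit_pool == id), integer(1))
  subset_sizes <- choose(caps, as.integer(tmpl))
  L <- sum(tmpl)
  list(L = L, ids = ids, k = as.integer(tmpl), caps = caps,
       subset_sizes = subset_sizes, fL = factorial(L),
       len = factorial(L) * prod(subset_sizes))
}

# decode local stream position (0-based) of a template into a motif sequence
decode_position <- function(block, unit_pool, local) {
  subset_idx <- floor(local / block$fL)
  perm_idx <- local - subset_idx * block$fL
  chosen <- integer(0)
  # mixed-radix digits over motifs, last motif least significant
  for (i in rev(seq_along(block$ids))) {
    s <- block$subset_sizes[i]
    d <- subset_idx %% s
    subset_idx <- floor(subset_idx / s)
    slots <- which(unit_pool == block$ids[i])
    chosen <- c(chosen, slots[unrank_combination(block$caps[i], block$k[i], d)])
  }
  base <- unit_pool[sort(chosen)]
  unrank_permutation(base, perm_idx)
}

#' Skip-sampled traversal of the template permutation stream
#'
#' Treats every allowed repeat of a motif as a distinct stream element, so a
#' template using k_i of the cap_i available units of motif i occupies an
#' L! * prod(choose(cap_i, k_i)) block of the stream. Candidates are taken at
#' positions `start_pos, start_pos + stride, ...` where the stride is
#' `max(skip, 1)`; traversal stops after `n` candidates or at stream
#' exhaustion.
#'
#' @param units shuffled unit pool (character vector of motif ids).
#' @param templates list of named count vectors in generation order.
#' @param skip stream positions advanced per candidate (0 = exhaustive).
#' @param n maximum number of candidates to return.
#' @param start_pos 0-based stream position of the first candidate.
#' @return list with `sequences` (list of motif-id vectors), `positions`,
#'   `end_pos` (position after the last candidate) and `exhausted`.
#' @export
permute_with_skip <- function(units, templates, skip, n, start_pos = 0) {
  stopifnot(skip >= 0, n >= 0)
  stride <- max(skip, 1)
  blocks <- lapply(templates, template_block, unit_pool = units)
  total <- sum(vapply(blocks, `[[`, numeric(1), "len"))
  if (total > 2^53)
    stop(errorCondition(
      "arrangement stream exceeds 2^53 positions; exact traversal arithmetic would lose precision (use census() for accounting)",
      class = c("macrolib_domain_error", "error", "condition")))
  seqs <- list(); poss <- numeric(0)
  pos <- start_pos
  bs <- 0
  for (b in blocks) {
    be <- bs + b$len
    while (pos < be && length(seqs) < n) {
      seqs[[length(seqs) + 1L]] <- decode_position(b, units, pos - bs)
      poss[length(seqs)] <- pos
      pos <- pos + stride
    }
    bs <- be
    if (length(seqs) >= n) break
  }
  list(sequences = seqs, positions = poss, end_pos = pos,
       exhausted = pos >= total)
}

# --- assembly and standardization ------------------------------------------

#' Assemble a macrocycle from an ordered motif sequence
#'
#' Bonds attachment point R2 of each unit to R1 of the next, then closes the
#' ring: either through an ester bridge whose carbonyl carbon bonds to the
#' last unit's R2 and whose bridging oxygen bonds to the first unit's R1 (a
#' lactone, the "macrolide scaffold" closure), or by a direct single bond.
#'
#' @param sequence character vector of motif ids in building order.
#' @param registry a `motif_registry` supplying the fragments.
#' @param add_ester close through an ester bridge (`TRUE`) or directly.
#' @param canonical return the standardized canonical SMILES (default) or
#'   the raw assembled SMILES.
#' @return a SMILES string.
#' @examples
#' reg <- load_motifs()
#' assemble_macrocycle(rep("SM001", 12), reg)  # oxacyclotetradecan-2-one
#' @export
assemble_macrocycle <- function(sequence, registry, add_ester = TRUE,
                                canonical = TRUE) {
  cores <- stats::setNames(vapply(registry$motifs$fragment, fragment_core, character(1)),
                           registry$motifs$motif_id)
  unknown <- setdiff(sequence, names(cores))
  if (length(unknown))
    stop(errorCondition(paste("unknown motif id:", paste(unique(unknown), collapse = ", ")),
                        class = c("macrolib_reference_error", "error", "condition")))
  parts <- unname(cores[sequence])
  parts[1] <- smiles_insert_after_atom(parts[1], "%99", "first")
  if (add_ester) {
    raw <- paste0(paste(parts, collapse = ""), "C(=O)O%99")
  } else {
    parts[length(parts)] <- smiles_insert_after_atom(parts[length(parts)], "%99", "last")
    raw <- paste(parts, collapse = "")
  }
  if (!canonical) return(raw)
  out <- tryCatch(standardize(raw), error = function(e) {
    stop(errorCondition(
      sprintf("assembly produced invalid chemistry for sequence %s: %s",
              paste(sequence, collapse = "-"), conditionMessage(e)),
      class = c("macrolib_chemistry_error", "error", "condition")))
  })
  out
}

#' Standardize structures
#'
#' Normalizes a structure the way library builders do before deduplication
#' and descriptor work: explicit hydrogens are dropped, the molecule is
#' sanitized (valence/aromaticity perception), metal fragments are
#' disconnected, functional-group representations are normalized, protonation
#' is reionized to the neutral form, and whatever stereochemistry is present
#' is assigned; the result is the canonical SMILES. Idempotent. Delegated to
#' the OpenBabel backend.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES.
#' @export
standardize <- function(smiles) {
  ob_canonical(smiles)
}

# --- the orchestrated run ---------------------------------------------------

#' Run a constrained macrocycle enumeration
#'
#' Orchestrates the full generation pipeline: ring sizes, length pairs,
#' per-category combinations, deduplicated composition templates, the
#' skip-sampled instance-permutation stream, ring assembly, standardization,
#' canonical-structure deduplication, and descriptor computation. Emits
#' exactly `library_size` scaffolds unless the stream is exhausted first (in
#' which case a warning reports the shortfall).
#'
#' @param rules a `building_rules` object.
#' @param registry a `motif_registry`.
#' @param compute_descriptors attach the descriptor vector to each record.
#' @param chunk_size internal batch size for canonicalization.
#' @param verbose print progress.
#' @return list with `records` (tibble: ordinal, ring_size, position,
#'   sequence, smiles, descriptors) and `report` (parameters, motif pools,
#'   seed, per-ring-size counts, census, elapsed seconds).
#' @export
run_enumeration <- function(rules, registry, compute_descriptors = TRUE,
                            chunk_size = 1024L, verbose = FALSE) {
  t0 <- Sys.time()
  rules <- validate_rules(rules, registry)
  caps <- effective_caps(rules, registry)
  common_ids <- registry$motifs$motif_id[registry$motifs$category == "common"]
  rare_ids <- registry$motifs$motif_id[registry$motifs$category == "rare"]
  common_units <- expand_units(registry, caps[common_ids], categories = "common")
  rare_units <- expand_units(registry, caps[rare_ids], categories = "rare")
  pool <- c(common_units, rare_units)

  seen <- new.env(parent = emptyenv())
  recs <- list()
  per_ring <- integer(0)
  emitted <- 0
  exhausted_all <- TRUE

  for (ring_size in seq(rules$total_min, rules$total_max)) {
    store <- new.env(parent = emptyenv())
    templates <- list()
    lp <- generate_length_pairs(rules, ring_size,
                                pool_common = length(common_units),
                                pool_rare = length(rare_units))
    for (j in seq_len(nrow(lp))) {
      ch <- generate_combinations(common_units, lp$L_C[j])
      rh <- generate_combinations(rare_units, lp$L_R[j])
      templates <- c(templates, make_templates(ch, rh, store))
    }
    if (!length(templates)) { per_ring[as.character(ring_size)] <- 0L; next }
    if (verbose)
      message(sprintf("ring size %d: %d templates", ring_size, length(templates)))

    cursor <- 0
    ring_count <- 0L
    repeat {
      need <- rules$library_size - emitted
      if (need <= 0) { exhausted_all <- FALSE; break }
      batch <- permute_with_skip(pool, templates, rules$skip,
                                 n = min(need, chunk_size), start_pos = cursor)
      cursor <- batch$end_pos
      if (!length(batch$sequences)) break
      smis <- vapply(batch$sequences, function(s)
        assemble_macrocycle(s, registry, add_ester = rules$add_ester,
                            canonical = FALSE), character(1))
      can <- standardize(smis)
      for (i in seq_along(can)) {
        if (!is.null(seen[[can[i]]])) next
        seen[[can[i]]] <- TRUE
        emitted <- emitted + 1
        ring_count <- ring_count + 1L
        recs[[length(recs) + 1L]] <- list(
          ordinal = emitted, ring_size = ring_size,
          position = batch$positions[i],
          sequence = paste(batch$sequences[[i]], collapse = "-"),
          smiles = can[i])
      }
      if (verbose && emitted %% 2000 < chunk_size)
        message(sprintf("  emitted %d", emitted))
      if (batch$exhausted) break
    }
    per_ring[as.character(ring_size)] <- ring_count
  }

  if (emitted < rules$library_size)
    warning(sprintf("permutation stream exhausted after %d of %.0f requested scaffolds",
                    emitted, rules$library_size))

  records <- if (length(recs)) {
    tibble::as_tibble(do.call(rbind, lapply(recs, function(r)
      data.frame(r, stringsAsFactors = FALSE))))
  } else {
    tibble::tibble(ordinal = integer(0), ring_size = integer(0),
                   position = numeric(0), sequence = character(0),
                   smiles = character(0))
  }
  if (compute_descriptors && nrow(records)) {
    desc <- compute_descriptors(records$smiles)
    records <- tibble::as_tibble(cbind(records, desc[, setdiff(names(desc), "smiles")]))
  }

  report <- list(
    parameters = rules,
    repeat_caps = caps,
    common_motifs = common_ids, rare_motifs = rare_ids,
    shuffle_seed = registry$shuffle_seed,
    counts_per_ring_size = per_ring,
    emitted = emitted,
    exhausted = exhausted_all && emitted < rules$library_size,
    census = census(rules, registry),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  list(records = records, report = report)
}
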