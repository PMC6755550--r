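#' Exact size of the instance-level arrangement stream
#'
#' The enumeration engine treats every allowed repeat of a motif as a
#' distinct unit in the selection pool, so the raw permutation stream over a
#' pool of `unit_count` units taken `length` at a time has
#' `unit_count!/(unit_count - length)!` entries (a falling factorial). This
#' is the headline space size the coverage arithmetic is based on; identical
#' units make some of those arrangements collapse onto the same molecule,
#' which [count_distinct_sequences()] accounts for.
#'
#' @param unit_count size of the unit pool (sum of repeat caps).
#' @param length number of units per scaffold (ring size in motif units).
#' @return a `bigint` with the exact arrangement count.
#' @examples
#' count_total_arrangements(16, 12)  # 871,782,912,000
#' @export
count_total_arrangements <- function(unit_count, length) {
  stopifnot(unit_count >= 0, length >= 0)
  if (length > unit_count)
    stop(errorCondition("length exceeds unit count", class = c("macrolib_domain_error", "error", "condition")))
  acc <- as_bigint(1)
  if (length == 0) return(acc)
  for (k in seq(unit_count, unit_count - length + 1L)) acc <- bi_mul_small(acc, k)
  acc
}

#' Exact count of distinct motif sequences under repeat caps
#'
#' Number of distinct ordered sequences of `length` motifs drawable from a
#' capped multiset (motif i available at most `caps[i]` times). Computed by
#' exact dynamic programming over motifs: incorporating a motif with cap c
#' maps dp[j] -> sum_k C(j+k, k)-weighted combinations, i.e. the coefficient
#' recurrence of the product of truncated exponential series, all in exact
#' integer arithmetic.
#'
#' @param caps named or unnamed vector of non-negative repeat caps.
#' @param length sequence length.
#' @return a `bigint`.
#' @examples
#' count_distinct_sequences(c(A = 2, B = 1), 2)  # 3: AA AB BA
#' @export
count_distinct_sequences <- function(caps, length) {
  caps <- as.integer(caps)
  stopifnot(all(caps >= 0), length >= 0)
  if (length > sum(caps)) return(as_bigint(0))
  # dp[[j+1]] = number of distinct sequences of length j from motifs so far
  dp <- vector("list", length + 1L)
  dp[[1L]] <- as_bigint(1)
  for (j in seq_len(length)) dp[[j + 1L]] <- as_bigint(0)
  for (cap in caps) {
    new <- vector("list", length + 1L)
    for (j in 0:length) {
      acc <- as_bigint(0)
      for (k in 0:min(cap, j)) {
        # place k copies of this motif into j slots: C(j, k) interleavings
        acc <- bi_add(acc, bi_mul_small(dp[[j - k + 1L]], choose(j, k)))
      }
      new[[j + 1L]] <- acc
    }
    dp <- new
  }
  dp[[length + 1L]]
}

#' Number of distinct compositions (unordered motif multisets)
#'
#' @param caps vector of repeat caps.
#' @param length multiset size.
#' @return integer count of distinct multisets.
#' @export
count_compositions <- function(caps, length) {
  caps <- as.integer(caps)
  stopifnot(all(caps >= 0), length >= 0)
  # polynomial product of (1 + x + ... + x^cap) coefficients
  poly <- 1
  for (cap in caps) {
    poly <- stats::convolve(c(poly, rep(0, cap)), rev(rep(1, cap + 1L)), type = "open")
    poly <- round(poly[seq_len(min(length(poly), length + 1L))])
  }
  if (length + 1L > length(poly)) 0L else as.integer(poly[length + 1L])
}

#' Coverage fraction of a skip-sampled run
#'
#' A run that emits `library_size` scaffolds advancing `skip` stream
#' positions per emission traverses `library_size * skip` positions of the
#' arrangement stream; the coverage fraction is that count over the total
#' stream size.
#'
#' @param library_size number of emitted scaffolds.
#' @param skip stream stride per emission.
#' @param total total arrangement count (`bigint` or number).
#' @return coverage fraction in `[0, 1]`.
#' @examples
#' coverage_fraction(1e6, 1e5, count_total_arrangements(16, 12))  # 0.1147
#' @export
coverage_fraction <- function(library_size, skip, total) {
  tot <- if (inherits(total, "bigint")) as.numeric.bigint(total) else as.numeric(total)
  if (tot <= 0)
    stop(errorCondition("total must be positive", class = c("macrolib_domain_error", "error", "condition")))
  stopifnot(library_size >= 0, skip >= 0)
  frac <- (library_size * skip) / tot
  min(frac, 1)
}

#' Census of an enumeration configuration
#'
#' Exact accounting of the arrangement space implied by a rules/registry
#' pair: instance-level stream size, distinct (multiset-aware) sequence
#' count, number of composition templates, positions traversed by the
#' configured run, and the resulting coverage fraction.
#'
#' @param rules a [building_rules()] object.
#' @param registry a motif registry from [load_motifs()].
#' @return a list of class `census_result`.
#' @export
census <- function(rules, registry) {
  rules <- validate_rules(rules, registry)
  ccaps <- category_caps(rules, registry, "common")
  rcaps <- category_caps(rules, registry, "rare")
  nc <- sum(ccaps); nr <- sum(rcaps)
  total <- as_bigint(0)
  distinct <- as_bigint(0)
  ncomp <- 0L
  for (ring_size in seq(rules$total_min, rules$total_max)) {
    lp <- generate_length_pairs(rules, ring_size, pool_common = nc, pool_rare = nr)
    for (j in seq_len(nrow(lp))) {
      lc <- lp$L_C[j]; lr <- lp$L_R[j]
      # per length pair: ring_size! * C(nc, lc) * C(nr, lr) instance
      # arrangements (every capped repeat counted as a distinct unit)
      blk <- bi_mul(bigint_factorial(ring_size),
                    bi_mul(as_bigint(choose(nc, lc)), as_bigint(choose(nr, lr))))
      total <- bi_add(total, blk)
      # distinct sequences: category-internal distinct sequences interleaved
      # over the C(ring_size, lc) common-position choices
      dseq <- bi_mul(count_distinct_sequences(ccaps, lc),
                     count_distinct_sequences(rcaps, lr))
      distinct <- bi_add(distinct, bi_mul(dseq, as_bigint(choose(ring_size, lc))))
      ncomp <- ncomp + count_compositions(ccaps, lc) * count_compositions(rcaps, lr)
    }
  }
  traversed <- min(rules$library_size * max(rules$skip, 1), as.numeric(total))
  res <- list(
    total_arrangements = total,
    distinct_sequences = distinct,
    composition_count = ncomp,
    traversed = traversed,
    coverage = coverage_fraction(rules$library_size, rules$skip, total)
  )
  class(res) <- "census_result"
  res
}

#' @export
print.census_result <- function(x, ...) {
  cat("Enumeration-space census\n")
  cat("  arrangement stream (instance-level):", format(x$total_arrangements), "\n")
  cat("  distinct motif sequences:           ", format(x$distinct_sequences), "\n")
  cat("  composition templates:              ", x$composition_count, "\n")
  cat(sprintf("  positions traversed by this run:     %.0f\n", x$traversed))
  cat(sprintf("  coverage: %.2f%%\n", 100 * x$coverage))
  invisible(x)
}
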