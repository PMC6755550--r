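# Independent oracles used across the suite. These deliberately avoid the
# engine's unranking/skip machinery: sequences are generated by plain
# recursion and deduplicated after canonicalization.

# all distinct motif-id sequences of a given length from a capped multiset
oracle_sequences <- function(caps, length) {
  ids <- names(caps)
  out <- list()
  rec <- function(remaining, left, acc) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (id in ids) {
      if (remaining[[id]] > 0L) {
        r2 <- remaining
        r2[[id]] <- r2[[id]] - 1L
        rec(r2, left - 1L, c(acc, id))
      }
    }
  }
  rec(as.list(caps), as.integer(length), character(0))
  out
}

# brute-force set of distinct canonical macrocycles from a registry
oracle_library <- function(registry, caps, ring_size, add_ester = FALSE) {
  seqs <- oracle_sequences(caps, ring_size)
  raw <- vapply(seqs, function(s)
    assemble_macrocycle(s, registry, add_ester = add_ester, canonical = FALSE),
    character(1))
  unique(standardize(raw))
}

# two-pass Pearson correlation, no shortcuts
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

toy_registry <- function(motifs, seed = 11L) {
  load_motifs(motifs, shuffle_seed = seed)
}

two_motif_table <- tibble::tibble(
  motif_id = c("A", "B"),
  category = "common",
  fragment = c("[*:1]C[*:2]", "[*:1]C(C)[*:2]"),
  default_repeat_cap = c(2L, 1L)
)
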