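#' MACCS structural-key fingerprints
#'
#' The standard 166-key MACCS substructure fingerprint (computed by the
#' OpenBabel backend, bit-compatible with the common toolkit
#' implementations), returned as a 0/1 matrix whose 256 columns are the
#' fingerprint's storage block; only the MACCS key positions are ever set.
#' MACCS keys are 2D: stereoisomers receive identical fingerprints.
#'
#' @param smiles character vector of SMILES.
#' @return 0/1 matrix, one row per structure.
#' @export
maccs_fingerprint <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  fp <- ob_maccs(smiles)
  if (nrow(fp) != length(smiles))
    stop(errorCondition("structure failed to parse during fingerprinting",
                        class = c("macrolib_chemistry_error", "error", "condition")))
  fp
}

#' Tanimoto coefficient of two binary key vectors
#'
#' `|a AND b| / |a OR b|`, the standard similarity measure for structural
#' keys; 0 when both vectors are empty (by convention).
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop(errorCondition("fingerprint length mismatch",
                        class = c("macrolib_domain_error", "error", "condition")))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Best-probe Tanimoto similarity (maximum aggregation)
#'
#' Scores every library scaffold against every probe molecule with
#' MACCS/Tanimoto and reports, per scaffold, only the highest score and the
#' probe achieving it (ties resolved to the first probe in input order).
#' The summary gives per-probe assignment counts, the score distribution
#' quartiles, and the number of scaffolds at or above the similarity cutoff.
#'
#' @param smiles character vector of library SMILES.
#' @param probes named character vector of probe SMILES (names label the
#'   probes; unnamed probes get `probe1`, `probe2`, ...).
#' @param cutoff similarity threshold for the "good similarity" count.
#' @return list with `scores` (tibble: smiles, best_probe, best_score) and
#'   `summary` (per-probe counts, quartiles, above-cutoff count); the full
#'   score matrix is attached as attribute `all_scores`.
#' @export
best_probe_similarity <- function(smiles, probes, cutoff = 0.75) {
  if (!length(probes))
    stop(errorCondition("empty probe set",
                        class = c("macrolib_domain_error", "error", "condition")))
  if (is.null(names(probes)))
    names(probes) <- paste0("probe", seq_along(probes))
  fl <- maccs_fingerprint(smiles)
  fpb <- maccs_fingerprint(probes)
  inter <- fl %*% t(fpb)
  nl <- rowSums(fl); nb <- rowSums(fpb)
  uni <- outer(nl, nb, `+`) - inter
  scores <- ifelse(uni == 0, 0, inter / uni)
  colnames(scores) <- names(probes)
  best_idx <- apply(scores, 1, which.max)  # first max on ties
  res <- tibble::tibble(
    smiles = smiles,
    best_probe = names(probes)[best_idx],
    best_score = scores[cbind(seq_along(best_idx), best_idx)]
  )
  qs <- stats::quantile(res$best_score, c(0, .25, .5, .75, 1))
  summary <- list(
    per_probe_counts = table(factor(res$best_probe, levels = names(probes))),
    score_quartiles = qs,
    mean_score = mean(res$best_score),
    above_cutoff = sum(res$best_score >= cutoff),
    cutoff = cutoff
  )
  structure(list(scores = res, summary = summary), all_scores = scores)
}

#' Simplify a macrolide to its comparable core scaffold
#'
#' Rule-based preprocessing that makes glycosylated, decorated macrolides
#' comparable to bare enumerated scaffolds: (i) sugar blocks - exocyclic
#' saturated 5/6-membered oxygen heterocycles attached through a glycosidic
#' oxygen - are excised and the attachment oxygen capped as a hydroxyl;
#' (ii) exocyclic ester substituents (O-acyl chains) are truncated to a
#' hydroxyl; (iii) substituted exocyclic amino groups are truncated to a
#' primary amine. The macrocyclic ring framework itself is untouched.
#' Idempotent on its own outputs.
#'
#' @param smiles a single SMILES containing a macrocyclic ring (>= 12 ring
#'   atoms).
#' @return the simplified canonical SMILES.
#' @export
simplify_probe <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  g <- mol_graph(smiles)
  bridges <- graph_bridges(g$n, g$edges)
  ring_comp <- graph_components(g$n, g$edges, keep = !bridges)
  ring_atom <- rep(FALSE, g$n)
  if (nrow(g$edges)) {
    for (i in which(!bridges)) ring_atom[g$edges[i, ]] <- TRUE
  }
  sizes <- table(ring_comp[ring_atom])
  macro_comp <- as.integer(names(sizes)[sizes >= 12])
  if (!length(macro_comp))
    stop(errorCondition("no macrocycle (ring of >= 12 atoms) found",
                        class = c("macrolib_domain_error", "error", "condition")))
  macro <- which(ring_comp %in% macro_comp & ring_atom)

  is_sugar_atom <- function(v) {
    if (!ring_atom[v]) return(FALSE)
    comp_atoms <- which(ring_comp == ring_comp[v] & ring_atom)
    length(comp_atoms) %in% c(5L, 6L) && any(g$elem[comp_atoms] == "O")
  }
  carbonyl_carbon <- function(v) {
    if (g$elem[v] != "C") return(FALSE)
    any(g$edges[, 1] == v & g$order == 2L & g$elem[g$edges[, 2]] == "O") ||
      any(g$edges[, 2] == v & g$order == 2L & g$elem[g$edges[, 1]] == "O")
  }

  drop <- logical(g$n)
  for (a in macro) {
    nb <- c(g$edges[g$edges[, 1] == a, 2], g$edges[g$edges[, 2] == a, 1])
    for (v in unique(nb)) {
      if (v %in% macro || drop[v]) next
      sub <- reachable_without(g$n, g$edges, v, a)
      if (any(sub %in% macro)) next  # fused/bridging, leave alone
      if (g$elem[v] == "O") {
        rest <- setdiff(sub, v)
        if (!length(rest)) next  # already a hydroxyl
        roots <- intersect(rest, c(g$edges[g$edges[, 1] == v, 2],
                                   g$edges[g$edges[, 2] == v, 1]))
        if (any(vapply(roots, is_sugar_atom, logical(1))) ||
            any(vapply(roots, carbonyl_carbon, logical(1)))) {
          drop[rest] <- TRUE  # glycoside or O-acyl ester: cap O as hydroxyl
        }
      } else if (g$elem[v] == "N") {
        rest <- setdiff(sub, v)
        if (length(rest)) drop[rest] <- TRUE  # substituted amine -> NH2
      }
    }
  }
  if (!any(drop)) return(ob_canonical(smiles))
  keep <- which(!drop)
  remap <- match(seq_len(g$n), keep)
  ekeep <- !drop[g$edges[, 1]] & !drop[g$edges[, 2]]
  edges <- cbind(remap[g$edges[ekeep, 1]], remap[g$edges[ekeep, 2]])
  molblock_to_smiles(graph_to_molblock(g$elem[keep], edges, g$order[ekeep]))
}
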