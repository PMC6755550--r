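#' Molecular descriptor vectors
#'
#' Computes, for each structure, the descriptor set used to profile scaffold
#' libraries: molecular weight (average atomic masses), Wildman-Crippen
#' fragment-based octanol/water partition estimate (SlogP), Ertl topological
#' polar surface area, hydrogen-bond acceptors and donors, rotatable bonds,
#' and heteroatom/heavy-atom counts. SlogP, TPSA, molecular weight and donor
#' counts come from the OpenBabel backend; acceptors follow the Lipinski
#' convention (count of N and O atoms), under which acceptor count equals
#' heteroatom count for oxygen-only chemistries. Rotatable bonds are acyclic
#' single bonds between two non-terminal heavy atoms.
#'
#' @param smiles character vector of SMILES (standardized or not).
#' @return tibble with columns `smiles`, `MW`, `SlogP`, `TPSA`, `HBA`,
#'   `HBD`, `NRB`, `heteroatoms`, `heavyatoms`.
#' @examples
#' \donttest{compute_descriptors("O=C1CCCCCCCCCCCCO1")}
#' @export
compute_descriptors <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  p <- ob_props(smiles)
  counts <- lapply(p$formula, parse_formula)
  n_el <- function(el) vapply(counts, function(x) as.integer(x[[el]] %||% 0L), integer(1))
  nC <- n_el("C"); nH <- n_el("H"); nN <- n_el("N"); nO <- n_el("O")
  heavy <- vapply(counts, function(x)
    sum(unlist(x[setdiff(names(x), "H")])), integer(1))
  het <- heavy - nC
  tibble::tibble(
    smiles = smiles,
    MW = p$MW,
    SlogP = p$logP,
    TPSA = p$TPSA,
    HBA = nN + nO,
    HBD = as.integer(p$HBD),
    NRB = ob_rotatable_bonds(smiles),
    heteroatoms = as.integer(het),
    heavyatoms = as.integer(heavy)
  )
}

#' Lipinski and Veber drug-likeness flags
#'
#' Lipinski's rule of five: MW <= 500, SlogP <= 5, HBD <= 5, HBA <= 10.
#' Veber's rules: TPSA <= 140 A^2 and rotatable bonds <= 10. Boundary values
#' pass.
#'
#' @param desc a descriptor tibble from [compute_descriptors()] (or any data
#'   frame with the needed columns).
#' @return tibble of logical flags, one row per structure.
#' @export
flag_druglikeness <- function(desc) {
  tibble::tibble(
    lipinski_mw = desc$MW <= 500,
    lipinski_slogp = desc$SlogP <= 5,
    lipinski_hbd = desc$HBD <= 5,
    lipinski_hba = desc$HBA <= 10,
    veber_tpsa = desc$TPSA <= 140,
    veber_nrb = desc$NRB <= 10
  )
}

DESCRIPTOR_COLS <- c("MW", "SlogP", "TPSA", "HBA", "HBD", "NRB",
                     "heteroatoms", "heavyatoms")

#' Library-level descriptor and motif summaries
#'
#' Per-descriptor minimum, maximum, mean and sample standard deviation,
#' binned histograms, and motif-usage statistics (how many scaffolds contain
#' each motif, total occurrences, and the per-scaffold repeat distribution).
#'
#' @param records scaffold tibble from [run_enumeration()] (needs the
#'   descriptor columns; motif statistics need the `sequence` column).
#' @param breaks number of histogram bins per descriptor.
#' @return list with `stats`, `histograms`, and (when sequences are present)
#'   `motif_usage`.
#' @export
summarize_library <- function(records, breaks = 20L) {
  if (!nrow(records))
    stop(errorCondition("empty library", class = c("macrolib_domain_error", "error", "condition")))
  cols <- intersect(DESCRIPTOR_COLS, names(records))
  stats_tbl <- do.call(rbind, lapply(cols, function(cn) {
    x <- records[[cn]]
    tibble::tibble(descriptor = cn, min = min(x), max = max(x),
                   mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  }))
  hists <- lapply(stats::setNames(cols, cols), function(cn)
    graphics::hist(records[[cn]], breaks = breaks, plot = FALSE))
  out <- list(stats = stats_tbl, histograms = hists)
  if ("sequence" %in% names(records)) {
    seqs <- strsplit(records$sequence, "-", fixed = TRUE)
    ids <- sort(unique(unlist(seqs)))
    per <- vapply(seqs, function(s) table(factor(s, levels = ids)),
                  integer(length(ids)))
    per <- if (is.null(dim(per))) matrix(per, nrow = 1, dimnames = list(ids, NULL)) else per
    max_rep <- max(per)
    rep_dist <- t(apply(per, 1, function(r) tabulate(r + 1L, nbins = max_rep + 1L)))
    colnames(rep_dist) <- paste0("n_rep", 0:max_rep)
    out$motif_usage <- tibble::as_tibble(cbind(
      tibble::tibble(motif_id = ids,
                     scaffolds_containing = rowSums(per > 0),
                     total_occurrences = rowSums(per)),
      tibble::as_tibble(rep_dist)))
  }
  out
}

#' Pearson correlation matrix of the descriptor columns
#'
#' @param records scaffold tibble with descriptor columns.
#' @param vars descriptor columns to correlate.
#' @return symmetric matrix of Pearson coefficients with unit diagonal;
#'   entries involving a constant column are `NA` (undefined, not zero).
#' @export
correlation_matrix <- function(records, vars = c("MW", "SlogP", "TPSA", "HBA",
                                                 "HBD", "heteroatoms", "heavyatoms")) {
  vars <- intersect(vars, names(records))
  if (nrow(records) < 2L)
    stop(errorCondition("need at least two records",
                        class = c("macrolib_domain_error", "error", "condition")))
  x <- as.matrix(records[, vars])
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r)[!constant] <- 1
  r
}
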