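#' Built-in structural-motif registry
#'
#' Backbone building blocks for macrolide/macrocycle assembly. Each motif is
#' a small fragment with two attachment points written `[*:1]` (incoming
#' bond) and `[*:2]` (outgoing bond); concatenating motifs R2->R1 and closing
#' the ring (optionally through an ester bridge) yields the macrocycle.
#'
#' The nine common motifs are the polyketide backbone units recurrent in
#' well-known bioactive macrolides: methylene, methyl-, ethyl-substituted
#' carbons, a ring ketone, hydroxyl- and methoxy-substituted carbons, a
#' carbon carrying both methyl and hydroxyl, a formyl (carboxaldehyde)
#' carbon, and an alkene unit (modelled with an exocyclic methylene so that
#' every unit contributes exactly one ring-backbone atom; twelve units plus
#' the ester bridge then close a 14-membered lactone, the erythromycin ring
#' size). Each common motif carries at most one oxygen and no other
#' heteroatom. The exact common-motif structures were fixed by calibrating
#' assembled-library descriptor extremes (molecular weight, TPSA,
#' heteroatom/heavy-atom and H-bond-donor counts) against reference
#' macrolide-scaffold libraries; see the package vignette.
#'
#' The seven rare motifs are synthetic placeholder entries (plausible
#' polyketide units carrying amine, carboxyl, longer alkyl, in-chain ester,
#' ether and gem-dimethyl functionality); users studying rare chemistry are
#' expected to supply their own definitions via [load_motifs()].
#'
#' @return a tibble with columns `motif_id`, `name`, `category`, `fragment`,
#'   `default_repeat_cap`, `ring_atom_count`.
#' @examples
#' default_motifs()
#' @export
default_motifs <- function() {
  tibble::tribble(
    ~motif_id, ~name,                 ~category, ~fragment,            ~default_repeat_cap, ~ring_atom_count,
    "SM001",   "methylene",           "common",  "[*:1]C[*:2]",        3L, 1L,
    "SM002",   "methyl",              "common",  "[*:1]C(C)[*:2]",     4L, 1L,
    "SM003",   "ethyl",               "common",  "[*:1]C(CC)[*:2]",    1L, 1L,
    "SM004",   "keto",                "common",  "[*:1]C(=O)[*:2]",    1L, 1L,
    "SM005",   "hydroxyl",            "common",  "[*:1]C(O)[*:2]",     1L, 1L,
    "SM006",   "hydroxyl-methyl",     "common",  "[*:1]C(C)(O)[*:2]",  2L, 1L,
    "SM008",   "carboxaldehyde",      "common",  "[*:1]C(C=O)[*:2]",   1L, 1L,
    "SM009",   "methoxy",             "common",  "[*:1]C(OC)[*:2]",    1L, 1L,
    "SM013",   "alkene",              "common",  "[*:1]C(=C)[*:2]",    2L, 1L,
    "SM007",   "amino (synthetic)",   "rare",    "[*:1]C(N)[*:2]",     1L, 1L,
    "SM010",   "carboxyl (synthetic)","rare",    "[*:1]C(C(=O)O)[*:2]",1L, 1L,
    "SM011",   "propyl (synthetic)",  "rare",    "[*:1]C(CCC)[*:2]",   1L, 1L,
    "SM012",   "ester (synthetic)",   "rare",    "[*:1]C(=O)O[*:2]",   1L, 2L,
    "SM014",   "ethoxy (synthetic)",  "rare",    "[*:1]C(OCC)[*:2]",   1L, 1L,
    "SM015",   "N-methylamino (synthetic)", "rare", "[*:1]C(NC)[*:2]", 1L, 1L,
    "SM016",   "gem-dimethyl (synthetic)",  "rare", "[*:1]C(C)(C)[*:2]", 1L, 1L
  )
}

#' Load and validate a structural-motif registry
#'
#' @param config `NULL` for the built-in motifs, a data frame with columns
#'   `motif_id`, `category`, `fragment`, `repeat_cap` (or
#'   `default_repeat_cap`), or the path of a CSV/TSV file with those columns.
#' @param categories restrict to these categories (e.g. `"common"`).
#' @param shuffle_seed integer seed used to shuffle the expanded unit pool so
#'   that repeated motifs do not cluster; recorded in run reports.
#' @return a `motif_registry` object.
#' @export
load_motifs <- function(config = NULL, categories = c("common", "rare"),
                        shuffle_seed = 7421L) {
  if (is.null(config)) {
    motifs <- default_motifs()
  } else if (is.character(config) && length(config) == 1L) {
    sep <- if (grepl("\\.tsv$", config)) "\t" else ","
    motifs <- tibble::as_tibble(utils::read.csv(config, sep = sep, stringsAsFactors = FALSE))
  } else {
    motifs <- tibble::as_tibble(config)
  }
  if (!nrow(motifs)) {
    reg <- structure(list(motifs = motifs, shuffle_seed = as.integer(shuffle_seed)),
                     class = "motif_registry")
    return(reg)
  }
  if ("repeat_cap" %in% names(motifs) && !"default_repeat_cap" %in% names(motifs))
    names(motifs)[names(motifs) == "repeat_cap"] <- "default_repeat_cap"
  needed <- c("motif_id", "category", "fragment", "default_repeat_cap")
  missing <- setdiff(needed, names(motifs))
  if (length(missing))
    stop("motif config lacks columns: ", paste(missing, collapse = ", "))
  if (!"name" %in% names(motifs)) motifs$name <- motifs$motif_id
  if (anyDuplicated(motifs$motif_id))
    stop(errorCondition(
      paste("duplicate motif_id:", paste(unique(motifs$motif_id[duplicated(motifs$motif_id)]), collapse = ", ")),
      class = c("macrolib_conflict_error", "error", "condition")))
  if (any(motifs$default_repeat_cap < 0))
    stop(errorCondition("negative repeat cap", class = c("macrolib_validation_error", "error", "condition")))
  motifs <- motifs[motifs$category %in% categories, , drop = FALSE]
  # validate every fragment
  rac <- integer(nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    rac[i] <- validate_fragment(motifs$fragment[i], motifs$motif_id[i])
  }
  if ("ring_atom_count" %in% names(motifs)) {
    bad <- which(!is.na(motifs$ring_atom_count) & motifs$ring_atom_count != rac)
    if (length(bad))
      stop(errorCondition(
        paste0("declared ring_atom_count disagrees with fragment backbone for: ",
               paste(motifs$motif_id[bad], collapse = ", ")),
        class = c("macrolib_validation_error", "error", "condition")))
  }
  motifs$ring_atom_count <- rac
  structure(list(motifs = motifs, shuffle_seed = as.integer(shuffle_seed)),
            class = "motif_registry")
}

# checks attachment-point syntax and chemistry; returns backbone atom count
validate_fragment <- function(fragment, motif_id) {
  pts <- gregexpr("\\[\\*:[0-9]+\\]", fragment)[[1]]
  n_pts <- if (pts[1] == -1L) 0L else length(pts)
  if (n_pts != 2L)
    stop(errorCondition(
      sprintf("motif %s: fragment must contain exactly two attachment points, found %d", motif_id, n_pts),
      class = c("macrolib_validity_error", "error", "condition")))
  if (!grepl("^\\[\\*:1\\]", fragment) || !grepl("\\[\\*:2\\]$", fragment))
    stop(errorCondition(
      sprintf("motif %s: fragment must start with [*:1] and end with [*:2]", motif_id),
      class = c("macrolib_validity_error", "error", "condition")))
  core <- fragment_core(fragment)
  ok <- tryCatch(nzchar(ob_canonical(core)), error = function(e) FALSE)
  if (!isTRUE(ok))
    stop(errorCondition(
      sprintf("motif %s: fragment does not parse: %s", motif_id, fragment),
      class = c("macrolib_format_error", "error", "condition")))
  length(smiles_top_atoms(core))
}

fragment_core <- function(fragment) {
  sub("\\[\\*:2\\]$", "", sub("^\\[\\*:1\\]", "", fragment))
}

#' Expand a registry into its shuffled unit pool
#'
#' A motif with repeat cap k contributes k interchangeable units to the
#' selection pool. The pool is shuffled with the registry seed so repeats of
#' one motif do not cluster in the deterministic traversal order; the same
#' seed always yields the same order.
#'
#' @param registry a `motif_registry`.
#' @param caps optional named vector overriding the per-motif repeat caps.
#' @param categories categories to include.
#' @return character vector of motif ids, one entry per unit.
#' @export
expand_units <- function(registry, caps = NULL, categories = c("common", "rare")) {
  m <- registry$motifs
  m <- m[m$category %in% categories, , drop = FALSE]
  use_caps <- m$default_repeat_cap
  names(use_caps) <- m$motif_id
  if (!is.null(caps)) {
    unknown <- setdiff(names(caps), registry$motifs$motif_id)
    if (length(unknown))
      stop(errorCondition(paste("unknown motif_id in caps:", paste(unknown, collapse = ", ")),
                          class = c("macrolib_reference_error", "error", "condition")))
    use_caps[intersect(names(caps), names(use_caps))] <-
      caps[intersect(names(caps), names(use_caps))]
  }
  if (any(use_caps < 0))
    stop(errorCondition("negative repeat cap", class = c("macrolib_validation_error", "error", "condition")))
  units <- rep(names(use_caps), times = use_caps)
  if (length(units) < 2L) return(units)
  withr::with_seed(registry$shuffle_seed, sample(units))
}

#' Oxygen and heteroatom content of each motif fragment
#'
#' @param registry a `motif_registry`.
#' @return tibble with per-motif oxygen, nitrogen and total heteroatom counts.
#' @export
motif_oxygen_counts <- function(registry) {
  m <- registry$motifs
  f <- vapply(m$fragment, fragment_core, character(1))
  counts <- lapply(f, function(core) {
    fm <- ob_props(core)$formula
    el <- parse_formula(fm)
    c(O = el[["O"]] %||% 0L, N = el[["N"]] %||% 0L,
      het = sum(unlist(el[setdiff(names(el), c("C", "H"))])))
  })
  out <- do.call(rbind, counts)
  tibble::tibble(motif_id = m$motif_id, oxygens = out[, "O"],
                 nitrogens = out[, "N"], heteroatoms = out[, "het"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.motif_registry <- function(x, ...) {
  cat("Motif registry:", nrow(x$motifs), "motifs (",
      sum(x$motifs$category == "common"), "common,",
      sum(x$motifs$category == "rare"), "rare ), shuffle seed", x$shuffle_seed, "\n")
  print(x$motifs, n = Inf)
  invisible(x)
}
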