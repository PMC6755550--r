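#' Write a library run to disk
#'
#' One SDF and one CSV per ring size, named `RS_<n>.sdf` / `RS_<n>.csv`,
#' plus `library_info.txt` (every build parameter, the selected motifs, the
#' shuffle seed, per-ring-size counts, space census and elapsed time - enough
#' to reproduce the run exactly) and `SM_info.csv` (per-motif usage totals
#' and per-scaffold repeat distributions). SDF records carry the descriptor
#' values as data fields.
#'
#' @param result list from [run_enumeration()].
#' @param out_dir output directory (created if needed).
#' @param coords3d placeholder flag mirroring the optional 3D output of the
#'   original workflow; 2D depiction coordinates are always generated.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, out_dir, coords3d = FALSE) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  records <- result$records
  report <- result$report
  flags <- if (nrow(records)) flag_druglikeness(records) else NULL
  paths <- character(0)

  ring_sizes <- if (nrow(records)) sort(unique(records$ring_size)) else integer(0)
  for (rs in ring_sizes) {
    sel <- records[records$ring_size == rs, ]
    fsel <- flags[records$ring_size == rs, ]
    csv_path <- file.path(out_dir, sprintf("RS_%d.csv", rs))
    utils::write.csv(cbind(sel[, setdiff(names(sel), "smiles")],
                           structure = sel$smiles, fsel),
                     csv_path, row.names = FALSE)
    sdf_path <- file.path(out_dir, sprintf("RS_%d.sdf", rs))
    blocks <- ob_sdf_text(sel$smiles, gen2d = TRUE)
    desc_cols <- intersect(DESCRIPTOR_COLS, names(sel))
    con <- file(sdf_path, "w")
    for (i in seq_len(nrow(sel))) {
      blk <- sub("^[^\n]*", as.character(sel$ordinal[i]), blocks[i])
      blk <- sub("\n+$", "\n", blk)
      items <- paste0(">  <", c("sequence", desc_cols), ">\n",
                      c(sel$sequence[i],
                        vapply(desc_cols, function(cn) format(sel[[cn]][i]), character(1))),
                      "\n\n", collapse = "")
      cat(blk, items, "$$$$\n", sep = "", file = con)
    }
    close(con)
    paths <- c(paths, csv_path, sdf_path)
  }
  if (!length(ring_sizes)) {
    csv_path <- file.path(out_dir, sprintf("RS_%d.csv", report$parameters$total_min))
    utils::write.csv(records, csv_path, row.names = FALSE)
    paths <- c(paths, csv_path)
  }

  info_path <- file.path(out_dir, "library_info.txt")
  p <- report$parameters
  info <- c(
    "macrolib enumeration report",
    sprintf("generated: %s", format(Sys.time())),
    "",
    "parameters:",
    sprintf("  1 csm_min: %d", p$csm_min),
    sprintf("  2 csm_max: %d", p$csm_max),
    sprintf("  3 rsm_min: %d", p$rsm_min),
    sprintf("  4 rsm_max: %d", p$rsm_max),
    sprintf("  5 total_min: %d", p$total_min),
    sprintf("  6 total_max: %d", p$total_max),
    sprintf("  7 priority: %s", p$priority),
    sprintf("  8 skip: %.0f", p$skip),
    sprintf("  9 library_size: %.0f", p$library_size),
    sprintf(" 10 add_ester: %s", p$add_ester),
    sprintf(" 11 repeat_caps: %s",
            paste(sprintf("%s=%d", names(report$repeat_caps), report$repeat_caps),
                  collapse = ", ")),
    "",
    sprintf("common motifs: %s", paste(report$common_motifs, collapse = ", ")),
    sprintf("rare motifs: %s", paste(report$rare_motifs, collapse = ", ")),
    sprintf("shuffle seed: %d", report$shuffle_seed),
    sprintf("emitted: %d", report$emitted),
    sprintf("counts per ring size: %s",
            paste(sprintf("RS_%s=%d", names(report$counts_per_ring_size),
                          report$counts_per_ring_size), collapse = ", ")),
    sprintf("arrangement space: %s", format(report$census$total_arrangements)),
    sprintf("coverage: %.4f%%", 100 * report$census$coverage),
    sprintf("elapsed seconds: %.1f", report$elapsed)
  )
  writeLines(info, info_path)
  paths <- c(paths, info_path)

  if (nrow(records)) {
    usage <- summarize_library(records)$motif_usage
    sm_path <- file.path(out_dir, "SM_info.csv")
    utils::write.csv(usage, sm_path, row.names = FALSE)
    paths <- c(paths, sm_path)
  }
  invisible(paths)
}

#' Read a per-ring-size scaffold CSV back into a tibble
#'
#' @param path a `RS_<n>.csv` written by [write_outputs()].
#' @return tibble with the canonical structures in column `smiles`.
#' @export
read_scaffolds <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  names(d)[names(d) == "structure"] <- "smiles"
  d
}

#' Deterministic toy motif/rules fixtures
#'
#' Builds a small, self-consistent motif table (simple carbon/oxygen
#' fragments) and a feasible exhaustive-enumeration rule set, for tests and
#' worked examples. Deterministic per seed. If the requested ring size
#' exceeds what the generated caps supply, caps are raised with a warning.
#'
#' @param n_motifs number of motifs (1-6).
#' @param ring_size scaffold size in motif units.
#' @param seed integer seed.
#' @param add_ester close rings through an ester bridge.
#' @return list with `registry` (a `motif_registry`) and `rules`.
#' @export
make_toy_fixture <- function(n_motifs, ring_size, seed, add_ester = FALSE) {
  stopifnot(n_motifs >= 1)
  pool <- tibble::tribble(
    ~name, ~fragment,
    "methylene", "[*:1]C[*:2]",
    "methyl",    "[*:1]C(C)[*:2]",
    "hydroxyl",  "[*:1]C(O)[*:2]",
    "keto",      "[*:1]C(=O)[*:2]",
    "ethyl",     "[*:1]C(CC)[*:2]",
    "alkene",    "[*:1]C(=C)[*:2]"
  )
  n_motifs <- min(n_motifs, nrow(pool))
  sel <- withr::with_seed(seed, pool[sample(nrow(pool), n_motifs), ])
  caps <- withr::with_seed(seed + 1L, sample(1:2, n_motifs, replace = TRUE))
  if (sum(caps) < ring_size) {
    warning("ring size exceeds generated caps; raising caps to make the fixture feasible")
    while (sum(caps) < ring_size) caps[which.min(caps)] <- caps[which.min(caps)] + 1L
  }
  motifs <- tibble::tibble(
    motif_id = sprintf("TM%03d", seq_len(n_motifs)),
    name = sel$name, category = "common", fragment = sel$fragment,
    default_repeat_cap = as.integer(caps))
  registry <- load_motifs(motifs, shuffle_seed = seed)
  rules <- building_rules(csm_min = ring_size, csm_max = ring_size,
                          total_min = ring_size, total_max = ring_size,
                          priority = "common", skip = 0,
                          library_size = 1e6, add_ester = add_ester)
  list(registry = registry, rules = rules)
}
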