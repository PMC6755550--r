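#' Building rules for an enumeration run
#'
#' The eleven user parameters governing a library build: per-category unit
#' ranges, total ring size (in motif units), category priority, the
#' skip-sampling stride, target library size, ester closure, and per-motif
#' repeat caps.
#'
#' @param csm_min,csm_max allowed range of common motifs per macrocycle.
#' @param rsm_min,rsm_max allowed range of rare motifs per macrocycle.
#' @param total_min,total_max ring-size range in motif units; ring size takes
#'   precedence: category ranges are clamped so the counts always sum to the
#'   ring size.
#' @param priority `"common"` or `"rare"`; which category the traversal
#'   exhausts first.
#' @param skip number of permutation-stream positions advanced per emitted
#'   scaffold (0 = exhaustive).
#' @param library_size maximum number of scaffolds to emit.
#' @param add_ester if `TRUE` close the ring through an ester bridge
#'   (lactone, "macrolide scaffold"); if `FALSE` close with a direct bond
#'   ("macrocycle scaffold").
#' @param repeat_caps named integer vector of per-motif repeat caps; motifs
#'   not named keep their registry default.
#' @return a `building_rules` object.
#' @export
building_rules <- function(csm_min = 0L, csm_max = 0L,
                           rsm_min = 0L, rsm_max = 0L,
                           total_min = 1L, total_max = total_min,
                           priority = c("common", "rare"),
                           skip = 0L, library_size = 1000L,
                           add_ester = TRUE, repeat_caps = NULL) {
  priority <- match.arg(priority)
  rules <- list(csm_min = as.integer(csm_min), csm_max = as.integer(csm_max),
                rsm_min = as.integer(rsm_min), rsm_max = as.integer(rsm_max),
                total_min = as.integer(total_min), total_max = as.integer(total_max),
                priority = priority, skip = as.numeric(skip),
                library_size = as.numeric(library_size),
                add_ester = isTRUE(add_ester), repeat_caps = repeat_caps)
  class(rules) <- "building_rules"
  rules
}

#' The benchmark 1-million-macrolide configuration
#'
#' Twelve common units per scaffold (14-membered lactone ring), no rare
#' units, skip 100,000, library size 1,000,000, ester closure, and repeat
#' caps 3/4/2/2 for the methylene, methyl, hydroxyl-methyl and alkene motifs
#' (one for every other motif), giving a 16-unit selection pool.
#'
#' @param library_size,skip overrides for scaled-down runs.
#' @return a `building_rules` object.
#' @export
v1m_rules <- function(library_size = 1e6, skip = 1e5) {
  building_rules(csm_min = 12, csm_max = 16, rsm_min = 0, rsm_max = 0,
                 total_min = 12, total_max = 12, priority = "common",
                 skip = skip, library_size = library_size, add_ester = TRUE,
                 repeat_caps = c(SM001 = 3L, SM002 = 4L, SM006 = 2L, SM013 = 2L))
}

# per-motif caps actually in force for a rules/registry pair (common+rare)
effective_caps <- function(rules, registry) {
  caps <- registry$motifs$default_repeat_cap
  names(caps) <- registry$motifs$motif_id
  if (!is.null(rules$repeat_caps)) {
    known <- intersect(names(rules$repeat_caps), names(caps))
    caps[known] <- rules$repeat_caps[known]
  }
  caps
}

category_caps <- function(rules, registry, category) {
  caps <- effective_caps(rules, registry)
  ids <- registry$motifs$motif_id[registry$motifs$category == category]
  caps[ids]
}

#' Validate building rules against a registry
#'
#' Checks range coherence, the ring-size feasibility rule (the run is
#' rejected when the minimum ring size exceeds the combined category maxima),
#' that the capped unit pools can actually supply some feasible length pair,
#' and that all referenced motif ids exist. Returns the rules unchanged
#' (validation is idempotent).
#'
#' @param rules a `building_rules` object.
#' @param registry a `motif_registry`.
#' @return the validated rules.
#' @export
validate_rules <- function(rules, registry) {
  stopifnot(inherits(rules, "building_rules"), inherits(registry, "motif_registry"))
  with(rules, {
    if (csm_min < 0 || csm_min > csm_max || rsm_min < 0 || rsm_min > rsm_max)
      stop(errorCondition("category ranges must satisfy 0 <= min <= max",
                          class = c("macrolib_validation_error", "error", "condition")))
    if (total_min <= 0 || total_min > total_max)
      stop(errorCondition("ring-size range must satisfy 0 < min <= max",
                          class = c("macrolib_validation_error", "error", "condition")))
  })
  if (rules$library_size <= 0)
    stop(errorCondition("library_size must be positive",
                        class = c("macrolib_validation_error", "error", "condition")))
  if (rules$skip < 0)
    stop(errorCondition("skip must be non-negative",
                        class = c("macrolib_validation_error", "error", "condition")))
  if (!is.null(rules$repeat_caps)) {
    unknown <- setdiff(names(rules$repeat_caps), registry$motifs$motif_id)
    if (length(unknown))
      stop(errorCondition(paste("unknown motif_id in repeat_caps:", paste(unknown, collapse = ", ")),
                          class = c("macrolib_reference_error", "error", "condition")))
  }
  if (rules$total_min > rules$csm_max + rules$rsm_max)
    stop(errorCondition(
      "infeasible: minimum ring size exceeds the combined maximum of common and rare units",
      class = c("macrolib_infeasible_error", "error", "condition")))
  # the capped pools must supply at least one length pair at some ring size
  ccaps <- sum(category_caps(rules, registry, "common"))
  rcaps <- sum(category_caps(rules, registry, "rare"))
  feasible <- FALSE
  for (rs in seq(rules$total_min, rules$total_max)) {
    lp <- generate_length_pairs(rules, rs, pool_common = ccaps, pool_rare = rcaps)
    if (nrow(lp)) { feasible <- TRUE; break }
  }
  if (!feasible)
    stop(errorCondition(
      "infeasible: repeat caps cannot supply any allowed ring size",
      class = c("macrolib_infeasible_error", "error", "condition")))
  rules
}

#' @export
print.building_rules <- function(x, ...) {
  cat("Building rules\n")
  cat(sprintf("  common units per macrocycle: %d..%d\n", x$csm_min, x$csm_max))
  cat(sprintf("  rare units per macrocycle:   %d..%d\n", x$rsm_min, x$rsm_max))
  cat(sprintf("  ring size (motif units):     %d..%d\n", x$total_min, x$total_max))
  cat(sprintf("  priority: %s | skip: %.0f | library size: %.0f | ester: %s\n",
              x$priority, x$skip, x$library_size, x$add_ester))
  if (!is.null(x$repeat_caps))
    cat("  repeat caps:", paste(sprintf("%s=%d", names(x$repeat_caps), x$repeat_caps), collapse = ", "), "\n")
  invisible(x)
}
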