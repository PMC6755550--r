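# Thin wrappers around the OpenBabel backend (ChemmineOB) plus small graph
# utilities shared by the descriptor and similarity modules. All heavy
# chemistry (parsing, canonicalization, Wildman-Crippen logP, Ertl TPSA,
# MACCS keys) is delegated to OpenBabel; this file only adapts formats.

ob_mol_refs <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

# canonical SMILES; vectorized; errors when any input fails to parse
ob_canonical <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste(smiles, collapse = "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("\t.*$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(smiles))
    stop(errorCondition(
      sprintf("structure failed to parse/sanitize (%d of %d converted)",
              length(lines), length(smiles)),
      class = c("macrolib_chemistry_error", "error", "condition")))
  lines
}

ob_props <- function(smiles) {
  p <- ChemmineOB::prop_OB(ob_mol_refs(smiles))
  if (nrow(p) != length(smiles))
    stop(errorCondition("structure failed to parse during property calculation",
                        class = c("macrolib_chemistry_error", "error", "condition")))
  p
}

# rotatable bonds: acyclic single bonds between two non-terminal heavy atoms
# (standard descriptor SMARTS, evaluated by OpenBabel; each bond matches in
# both directions, hence the halving)
ob_rotatable_bonds <- function(smiles) {
  n <- ChemmineOB::smartsSearch_OB(ob_mol_refs(smiles),
                                   "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]",
                                   uniqueMatches = FALSE)
  as.integer(n / 2L)
}

ob_maccs <- function(smiles) {
  fp <- ChemmineOB::fingerprint_OB(ob_mol_refs(smiles), "MACCS")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
  rownames(fp) <- names(smiles)
  fp
}

# SMILES -> V2000 molblocks (one string per molecule)
ob_sdf_text <- function(smiles, gen2d = FALSE) {
  src <- paste(smiles, collapse = "\n")
  txt <- if (gen2d) {
    ChemmineOB::convertFormat("SMI", "SDF", src,
                              options = data.frame(names = "gen2D", args = ""))
  } else {
    ChemmineOB::convertFormat("SMI", "SDF", src)
  }
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n")[[1]]
  blocks <- blocks[nzchar(gsub("[[:space:]]", "", blocks))]
  if (length(blocks) != length(smiles))
    stop(errorCondition("structure failed SDF conversion",
                        class = c("macrolib_chemistry_error", "error", "condition")))
  blocks
}

parse_formula <- function(formula) {
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]] # "C24" "H40" "O8"
  el <- sub("[0-9]+$", "", toks)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  cnt[is.na(cnt)] <- 1L
  out <- tapply(cnt, el, sum)
  as.list(out)
}

# --- molecular graphs ------------------------------------------------------

# molecule graph from a SMILES: list(elem, edges = 2-col matrix, order)
mol_graph <- function(smiles) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(paste0(ob_sdf_text(smiles), "$$$$"), tmp)
  sdf <- ChemmineR::read.SDFset(tmp)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elem <- sub("_[0-9]+$", "", rownames(ab))
  edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  list(elem = elem, edges = edges, order = as.integer(bb[, 3]),
       n = length(elem))
}

# bridge (cut) edges via iterative DFS with discovery/low times
graph_bridges <- function(n, edges) {
  if (!nrow(edges)) return(logical(0))
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, i))
    adj[[b]] <- rbind(adj[[b]], c(a, i))
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(nrow(edges))
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, pe = 0L, i = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$i == 1L) {
        timer <- timer + 1L
        disc[v] <- low[v] <- timer
      }
      nb <- adj[[v]]
      if (is.null(nb) || fr$i > nrow(nb)) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pf <- stack[[length(stack)]]
          u <- pf$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[fr$pe] <- TRUE
        }
        next
      }
      stack[[length(stack)]]$i <- fr$i + 1L
      w <- nb[fr$i, 1]; ei <- nb[fr$i, 2]
      if (ei == fr$pe) next
      if (disc[w] != 0L) {
        low[v] <- min(low[v], disc[w])
      } else {
        stack[[length(stack) + 1L]] <- list(v = w, pe = ei, i = 1L)
      }
    }
  }
  is_bridge
}

# connected components of a subgraph given by kept edges
graph_components <- function(n, edges, keep = rep(TRUE, nrow(edges))) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  if (nrow(edges)) {
    for (i in which(keep)) {
      a <- find(edges[i, 1]); b <- find(edges[i, 2])
      if (a != b) comp[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# atoms reachable from `start` without crossing atom `blocked`
reachable_without <- function(n, edges, start, blocked) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); seen[blocked] <- TRUE
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[blocked] <- FALSE
  which(seen)
}

# minimal V2000 writer for an edited graph (zero coordinates; OpenBabel
# re-perceives everything downstream)
graph_to_molblock <- function(elem, edges, order) {
  n <- length(elem); m <- nrow(edges)
  header <- c("edited", "  macrolib", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, elem)
  bonds <- if (m) sprintf("%3d%3d%3d  0  0  0  0", edges[, 1], edges[, 2], order) else character(0)
  paste(c(header, atoms, bonds, "M  END"), collapse = "\n")
}

molblock_to_smiles <- function(molblock) {
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(molblock, "\n$$$$\n"))
  s <- sub("\t.*$", "", strsplit(out, "\n")[[1]][1])
  if (!nzchar(s))
    stop(errorCondition("edited structure failed to convert",
                        class = c("macrolib_chemistry_error", "error", "condition")))
  s
}

# --- SMILES token helpers (assembly only; not a parser) --------------------

# positions (start, end) of atom tokens at branch depth 0 of a fragment core
smiles_top_atoms <- function(core) {
  chars <- strsplit(core, "")[[1]]
  i <- 1L; depth <- 0L
  out <- list()
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") { depth <- depth + 1L; i <- i + 1L; next }
    if (ch == ")") { depth <- depth - 1L; i <- i + 1L; next }
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      if (depth == 0L) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L; next
    }
    if (grepl("[A-Z]", ch)) {
      j <- i
      if (i < length(chars) && ch %in% c("C", "B") && chars[i + 1L] %in% c("l", "r"))
        j <- i + 1L
      if (depth == 0L) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L; next
    }
    i <- i + 1L
  }
  out
}

# insert text immediately after the first or last top-level atom of a core
smiles_insert_after_atom <- function(core, text, which = c("first", "last")) {
  which <- match.arg(which)
  atoms <- smiles_top_atoms(core)
  if (!length(atoms))
    stop(errorCondition("fragment core has no backbone atom",
                        class = c("macrolib_validity_error", "error", "condition")))
  pos <- if (which == "first") atoms[[1]][2] else atoms[[length(atoms)]][2]
  paste0(substr(core, 1, pos), text,
         substr(core, pos + 1L, nchar(core)))
}
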