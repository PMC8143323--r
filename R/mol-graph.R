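# Molecular graph construction from SMILES.
#
# SMILES text is parsed by Open Babel (through ChemmineOB) into a hydrogen-
# explicit, kekulized connection table; ring perception and aromaticity are
# then applied here so that a single, documented aromaticity convention
# underlies every descriptor (see perceive_aromaticity).

#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES string to a hydrogen-explicit molecular graph with
#' perceived rings and aromaticity. Open Babel performs the SMILES reading;
#' ring finding and the aromaticity model are applied by this package so that
#' descriptor values follow one fixed convention.
#'
#' @param smiles SMILES string for a single (possibly multi-fragment) molecule.
#' @param name optional molecule label carried through to outputs.
#' @param oxo_ring_aromatic logical; the aromaticity convention switch. When
#'   `TRUE` (default, set globally via `options(fqchelate.oxo_ring_aromatic=)`)
#'   a ring atom bearing an exocyclic double bond to O/N/S contributes zero
#'   pi electrons and the ring may still be aromatic, so the 4-oxo-quinoline
#'   core of the fluoroquinolones is perceived as a fully aromatic bicycle.
#'   When `FALSE` such rings are left non-aromatic (enaminone perception).
#' @return An object of class `mol_graph`: a list with `atoms` (data frame:
#'   `element`, `charge`, `aromatic`, `n_h`, `degree`, `in_ring`, `in_ring3`),
#'   `bonds` (data frame: `a1`, `a2`, `order`, `aromatic`, `in_ring`),
#'   `rings` (list of atom index vectors), `smiles` and `name`.
#' @examples
#' \donttest{
#' g <- parse_smiles("c1ccccc1", name = "benzene")
#' sum(g$atoms$aromatic)
#' }
#' @export
parse_smiles <- function(smiles, name = NULL,
                         oxo_ring_aromatic = getOption("fqchelate.oxo_ring_aromatic", TRUE)) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  validate_smiles_syntax(smiles)
  sdf <- sdf_from_smiles(smiles)
  g <- parse_sdf_v2000(sdf)
  g$smiles <- smiles
  g$name <- if (is.null(name)) NA_character_ else name
  g$rings <- find_rings(g$atoms, g$bonds, max_size = 8L)
  g <- perceive_aromaticity(g, oxo_ring_aromatic = oxo_ring_aromatic)
  class(g) <- "mol_graph"
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  heavy <- x$atoms$element != "H"
  cat(sprintf("<mol_graph %s: %d atoms (%d heavy), %d bonds, %d rings, %d aromatic atoms>\n",
              if (is.na(x$name)) "" else x$name,
              nrow(x$atoms), sum(heavy), nrow(x$bonds),
              length(x$rings), sum(x$atoms$aromatic)))
  invisible(x)
}

# Cheap syntactic screen so malformed SMILES fail with a character position
# before reaching the converter.
validate_smiles_syntax <- function(smiles) {
  if (!nzchar(smiles)) stop("empty SMILES string", call. = FALSE)
  chars <- strsplit(smiles, "")[[1]]
  paren <- 0L; bracket <- 0L
  ring_open <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") paren <- paren + 1L
    if (ch == ")") {
      paren <- paren - 1L
      if (paren < 0L) stop(sprintf("SMILES parse error at position %d: unmatched ')'", i), call. = FALSE)
    }
    if (ch == "[") {
      if (bracket > 0L) stop(sprintf("SMILES parse error at position %d: nested '['", i), call. = FALSE)
      bracket <- bracket + 1L
    }
    if (ch == "]") {
      bracket <- bracket - 1L
      if (bracket < 0L) stop(sprintf("SMILES parse error at position %d: unmatched ']'", i), call. = FALSE)
    }
    if (bracket == 0L && grepl("[0-9]", ch)) {
      d <- as.integer(ch)
      if (d %in% ring_open) ring_open <- setdiff(ring_open, d) else ring_open <- c(ring_open, d)
    }
  }
  if (paren > 0L) stop(sprintf("SMILES parse error at position %d: unclosed '('", nchar(smiles)), call. = FALSE)
  if (bracket > 0L) stop(sprintf("SMILES parse error at position %d: unclosed '['", nchar(smiles)), call. = FALSE)
  if (length(ring_open) > 0L)
    stop(sprintf("SMILES parse error: unclosed ring bond number(s) %s",
                 paste(ring_open, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

sdf_from_smiles <- function(smiles) {
  # explicit hydrogens; 2D coordinates are generated only so the writer has
  # a coordinate block (the graph uses connectivity alone)
  out <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(smiles, "\tmol\n"),
    options = data.frame(names = c("h", "gen2D"), args = c("", ""),
                         stringsAsFactors = FALSE)
  )
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE))
    stop(sprintf("SMILES parse error: Open Babel could not read '%s'", smiles), call. = FALSE)
  out
}

parse_sdf_v2000 <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1L) stop("SMILES parse error: empty molecule", call. = FALSE)
  atom_lines <- lines[5:(4 + n_atoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  xyz <- cbind(
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30))
  )
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (n_bonds > 0L) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  }
  charge <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- flds[1]
    for (k in seq_len(n)) charge[flds[2 * k]] <- flds[2 * k + 1]
  }
  unknown <- setdiff(unique(element), names(.monoisotopic_mass))
  unknown <- setdiff(unknown, "H")
  if (length(unknown) > 0L)
    stop(sprintf("unknown element(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  n_h <- integer(n_atoms)
  degree <- integer(n_atoms)
  if (n_bonds > 0L) {
    for (i in seq_len(n_bonds)) {
      a1 <- bonds$a1[i]; a2 <- bonds$a2[i]
      degree[a1] <- degree[a1] + 1L; degree[a2] <- degree[a2] + 1L
      if (element[a2] == "H") n_h[a1] <- n_h[a1] + 1L
      if (element[a1] == "H") n_h[a2] <- n_h[a2] + 1L
    }
  }
  atoms <- data.frame(
    element = element, charge = charge, aromatic = FALSE,
    n_h = n_h, degree = degree, in_ring = FALSE, in_ring3 = FALSE,
    stringsAsFactors = FALSE
  )
  bonds$aromatic <- rep(FALSE, nrow(bonds))
  bonds$in_ring <- rep(FALSE, nrow(bonds))
  list(atoms = atoms, bonds = bonds, xyz = xyz)
}

# Enumerate simple cycles of the heavy-atom graph up to max_size atoms.
# Molecules handled here are small, so a bounded depth-first search with the
# smallest-index-first canonicalisation is adequate and deterministic.
find_rings <- function(atoms, bonds, max_size = 8L) {
  n <- nrow(atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[i]; a2 <- bonds$a2[i]
    if (atoms$element[a1] == "H" || atoms$element[a2] == "H") next
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  rings <- list(); seen <- character(0)
  path <- integer(max_size)
  dfs <- function(start, v, depth, onpath) {
    for (w in adj[[v]]) {
      if (w == start && depth >= 3L) {
        key <- paste(sort(path[seq_len(depth)]), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path[seq_len(depth)]
        }
      } else if (w > start && !onpath[w] && depth < max_size) {
        path[depth + 1L] <<- w
        onpath[w] <- TRUE
        dfs(start, w, depth + 1L, onpath)
        onpath[w] <- FALSE
      }
    }
  }
  onpath <- logical(n)
  for (s in seq_len(n)) {
    if (atoms$element[s] == "H" || length(adj[[s]]) < 2L) next
    path[1L] <- s; onpath[s] <- TRUE
    dfs(s, s, 1L, onpath)
    onpath[s] <- FALSE
  }
  # keep only rings that are not the union of two smaller ones (drop envelope
  # cycles of fused systems): a cycle is redundant if every edge lies in some
  # strictly smaller cycle
  if (length(rings) > 1L) {
    edge_key <- function(a, b) paste(min(a, b), max(a, b))
    ring_edges <- lapply(rings, function(r) {
      m <- length(r)
      vapply(seq_len(m), function(i) edge_key(r[i], r[i %% m + 1L]), character(1))
    })
    sizes <- lengths(rings)
    keep <- vapply(seq_along(rings), function(i) {
      smaller <- unlist(ring_edges[sizes < sizes[i]])
      !all(ring_edges[[i]] %in% smaller)
    }, logical(1))
    rings <- rings[keep]
  }
  rings
}

# Aromaticity perception: Hueckel 4n+2 counting on each 5-7 membered ring of
# C/N/O/S atoms. Per-atom pi-electron contributions:
#   * atom with a double bond to another ring atom (this ring or a fused one): 1
#   * carbon with an exocyclic double bond to O/N/S: 0 when the oxo-aromatic
#     convention is on, otherwise the ring is rejected
#   * N with <= 3 sigma bonds and no double bond (pyrrole-type): 2
#   * divalent O or S (furan/thiophene-type): 2
#   * anything else rejects the ring.
perceive_aromaticity <- function(g, oxo_ring_aromatic = TRUE) {
  atoms <- g$atoms; bonds <- g$bonds
  ring_member <- rep(FALSE, nrow(atoms))
  for (r in g$rings) {
    ring_member[r] <- TRUE
    atoms$in_ring[r] <- TRUE
    if (length(r) == 3L) atoms$in_ring3[r] <- TRUE
  }
  bond_in_ring <- function(a1, a2, ring) (a1 %in% ring) && (a2 %in% ring) &&
    any(vapply(seq_along(ring), function(i) {
      j <- ring[i]; k <- ring[i %% length(ring) + 1L]
      (j == a1 && k == a2) || (j == a2 && k == a1)
    }, logical(1)))
  dbl_partners <- lapply(seq_len(nrow(atoms)), function(i) {
    sel <- (bonds$a1 == i | bonds$a2 == i) & bonds$order == 2L
    setdiff(c(bonds$a1[sel], bonds$a2[sel]), i)
  })
  total_sigma <- atoms$degree  # explicit-H graph: degree counts all neighbours
  aromatic_rings <- list()
  for (r in g$rings) {
    sz <- length(r)
    if (sz < 5L || sz > 7L) next
    ok <- TRUE; electrons <- 0L
    for (a in r) {
      elt <- atoms$element[a]
      if (!(elt %in% c("C", "N", "O", "S"))) { ok <- FALSE; break }
      dp <- dbl_partners[[a]]
      if (length(dp) > 0L && any(dp %in% r)) {
        electrons <- electrons + 1L
      } else if (length(dp) > 0L && any(ring_member[dp])) {
        electrons <- electrons + 1L  # kekule double bond into a fused ring
      } else if (length(dp) > 0L) {
        exo <- atoms$element[dp]
        if (elt == "C" && any(exo %in% c("O", "N", "S")) && oxo_ring_aromatic) {
          electrons <- electrons + 0L
        } else { ok <- FALSE; break }
      } else if (elt == "N" && total_sigma[a] <= 3L) {
        electrons <- electrons + 2L
      } else if (elt %in% c("O", "S") && total_sigma[a] == 2L) {
        electrons <- electrons + 2L
      } else { ok <- FALSE; break }
    }
    if (ok && electrons %% 4L == 2L) aromatic_rings[[length(aromatic_rings) + 1L]] <- r
  }
  for (r in aromatic_rings) {
    atoms$aromatic[r] <- TRUE
    for (i in seq_len(nrow(bonds))) {
      if (bonds$in_ring[i] && bonds$aromatic[i]) next
      if (bond_in_ring(bonds$a1[i], bonds$a2[i], r)) bonds$aromatic[i] <- TRUE
    }
  }
  for (i in seq_len(nrow(bonds))) {
    for (r in g$rings) {
      if (bond_in_ring(bonds$a1[i], bonds$a2[i], r)) { bonds$in_ring[i] <- TRUE; break }
    }
  }
  g$atoms <- atoms; g$bonds <- bonds
  g
}

# Neighbour indices of atom i (all atoms, including hydrogens).
mg_neighbors <- function(g, i) {
  sel <- g$bonds$a1 == i | g$bonds$a2 == i
  setdiff(c(g$bonds$a1[sel], g$bonds$a2[sel]), i)
}

# Bond orders of bonds incident to atom i, aligned with mg_neighbors order.
mg_bond_to <- function(g, i, j) {
  sel <- (g$bonds$a1 == i & g$bonds$a2 == j) | (g$bonds$a1 == j & g$bonds$a2 == i)
  g$bonds[sel, , drop = FALSE]
}

# Molecular formula (Hill order) of the graph.
mg_formula <- function(g) {
  counts <- table(g$atoms$element)
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    n <- counts[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

# Number of connected components of the heavy+H graph.
mg_n_components <- function(g) {
  n <- nrow(g$atoms)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, setdiff(mg_neighbors(g, v), which(comp > 0L)))
    }
  }
  cur
}
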