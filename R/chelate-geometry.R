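# Construction of 1:1 bidentate FQ-metal chelate starting geometries: the
# metal binds the 3-carboxyl carbonyl oxygen and the 4-keto oxygen of the
# N-protonated FQ cation and completes an octahedron with four waters (two
# of the original six hydration waters are displaced by the chelate bite).

.covalent_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                      F = 0.57, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
                      P = 1.07, S = 1.05, Cl = 1.02, K = 2.03, Ca = 1.76,
                      Fe = 1.32, Cu = 1.32, Zn = 1.22, Br = 1.20, I = 1.39)

#' Read / write XYZ geometry files
#'
#' Plain XYZ: atom count, comment line, then `element x y z` in Angstrom.
#'
#' @param path file path.
#' @return data frame with columns `element, x, y, z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  data.frame(
    element = vapply(rows, `[`, character(1), 1),
    x = as.numeric(vapply(rows, `[`, character(1), 2)),
    y = as.numeric(vapply(rows, `[`, character(1), 3)),
    z = as.numeric(vapply(rows, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_xyz
#' @param geometry data frame `element, x, y, z`.
#' @param comment comment line content.
#' @export
write_xyz <- function(geometry, path, comment = "") {
  lines <- c(nrow(geometry), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f",
                     geometry$element, geometry$x, geometry$y, geometry$z))
  writeLines(lines, path)
  invisible(path)
}

geom_dist <- function(geometry, i, j) {
  sqrt((geometry$x[i] - geometry$x[j])^2 +
       (geometry$y[i] - geometry$y[j])^2 +
       (geometry$z[i] - geometry$z[j])^2)
}

# Bond inference from interatomic distances: bonded if within 1.25x the sum
# of covalent radii.
infer_bonds <- function(geometry, scale = 1.25) {
  n <- nrow(geometry)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rsum <- .covalent_radius[[geometry$element[i]]] + .covalent_radius[[geometry$element[j]]]
    if (geom_dist(geometry, i, j) <= scale * rsum)
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out) == 0L) return(data.frame(a1 = integer(0), a2 = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a1 = m[, 1], a2 = m[, 2])
}

# Identify the chelating donor oxygens of an FQ geometry: the carbonyl
# oxygen of the 3-carboxyl group (the carboxyl oxygen without hydrogen) and
# the 4-keto oxygen (terminal O on a ring carbon that is not the carboxyl
# carbon), constrained to lie in one chelation pocket (O...O within
# 2.0-4.2 A). Ties are broken by the shortest O-O separation.
find_donor_oxygens <- function(geometry) {
  bonds <- infer_bonds(geometry)
  nbrs <- function(i) {
    sel1 <- bonds$a1 == i; sel2 <- bonds$a2 == i
    c(bonds$a2[sel1], bonds$a1[sel2])
  }
  elt <- geometry$element
  o_idx <- which(elt == "O")
  carboxyl_o <- integer(0); keto_o <- integer(0)
  for (i in o_idx) {
    nb <- nbrs(i)
    heavy <- nb[elt[nb] != "H"]
    has_h <- any(elt[nb] == "H")
    if (length(heavy) != 1L || elt[heavy] != "C") next
    cnb <- nbrs(heavy)
    c_o_count <- sum(elt[cnb] == "O")
    if (c_o_count == 2L && !has_h) carboxyl_o <- c(carboxyl_o, i)
    if (c_o_count == 1L && !has_h && length(nb) == 1L) keto_o <- c(keto_o, i)
  }
  if (length(carboxyl_o) == 0L || length(keto_o) == 0L)
    stop("substructure error: could not identify the 3-carboxyl and 4-keto donor oxygens",
         call. = FALSE)
  best <- NULL; best_d <- Inf
  for (i in carboxyl_o) for (j in keto_o) {
    d <- geom_dist(geometry, i, j)
    if (d >= 2.0 && d <= 4.2 && d < best_d) { best <- c(i, j); best_d <- d }
  }
  if (is.null(best))
    stop("substructure error: no carboxyl/keto oxygen pair within the chelation pocket range",
         call. = FALSE)
  c(carboxyl = best[1], keto = best[2])
}

unit_vec <- function(v) v / sqrt(sum(v^2))

# Rotate the carboxyl group into the chelation pocket when the input
# conformer has the carbonyl oxygen anti to the keto oxygen: flip the
# ring-C / carboxyl-C torsion by 180 degrees if that shortens the donor
# O...O separation.
orient_carboxyl_for_chelation <- function(geometry, donors) {
  bonds <- infer_bonds(geometry)
  nbrs <- function(i) {
    sel1 <- bonds$a1 == i; sel2 <- bonds$a2 == i
    c(bonds$a2[sel1], bonds$a1[sel2])
  }
  o_cx <- donors[["carboxyl"]]
  c_cx <- nbrs(o_cx)[geometry$element[nbrs(o_cx)] == "C"][1]
  ring_c <- setdiff(nbrs(c_cx)[geometry$element[nbrs(c_cx)] == "C"], c_cx)[1]
  if (is.na(ring_c)) return(geometry)
  flipped <- rotate_torsion(geometry, ring_c, c_cx, 180, bonds = bonds)
  if (geom_dist(flipped, donors[["carboxyl"]], donors[["keto"]]) <
      geom_dist(geometry, donors[["carboxyl"]], donors[["keto"]])) flipped else geometry
}

#' Build a 1:1 bidentate FQ-metal chelate starting geometry
#'
#' Places the metal at the element-dependent starting distance from the two
#' donor oxygens (Al 1.9, Mg 2.1, Ca 2.4 Angstrom) and completes the
#' octahedral coordination sphere with four water molecules; the reaction
#' partner hexahydrate loses two waters to the chelate bite.
#'
#' @param fq_geometry data frame `element, x, y, z` of the N-protonated FQ
#'   cation (charge +1).
#' @param metal `"Mg"`, `"Ca"` or `"Al"`.
#' @param fq_label label for the resulting species.
#' @return a [species()] with role `chelate_complex`, charge
#'   `+1 + metal charge`, and the assembled starting geometry.
#' @export
build_chelate_geometry <- function(fq_geometry, metal = c("Al", "Mg", "Ca"),
                                   fq_label = "fq") {
  metal <- match.arg(metal)
  donors <- find_donor_oxygens(fq_geometry)
  fq_geometry <- orient_carboxyl_for_chelation(fq_geometry, donors)
  d_mo <- .metal_o_distance[[metal]]
  o1 <- as.numeric(fq_geometry[donors["carboxyl"], c("x", "y", "z")])
  o2 <- as.numeric(fq_geometry[donors["keto"], c("x", "y", "z")])
  mid <- (o1 + o2) / 2
  half <- sqrt(sum((o2 - o1)^2)) / 2
  if (d_mo <= half)
    stop(sprintf("geometry error: donor oxygens too far apart (%.2f A) for %s-O = %.2f A",
                 2 * half, metal, d_mo), call. = FALSE)
  # direction away from the FQ: from the donor carbons' centroid through mid
  bonds <- infer_bonds(fq_geometry)
  nbrs <- function(i) {
    sel1 <- bonds$a1 == i; sel2 <- bonds$a2 == i
    c(bonds$a2[sel1], bonds$a1[sel2])
  }
  cdon <- unique(unlist(lapply(donors, function(i)
    nbrs(i)[fq_geometry$element[nbrs(i)] == "C"])))
  cmid <- c(mean(fq_geometry$x[cdon]), mean(fq_geometry$y[cdon]), mean(fq_geometry$z[cdon]))
  out_dir <- unit_vec(mid - cmid)
  h <- sqrt(d_mo^2 - half^2)
  m_pos <- mid + out_dir * h
  # octahedral axes: e1, e2 toward the donors; fill remaining four vertices
  e1 <- unit_vec(o1 - m_pos)
  e2r <- o2 - m_pos
  e2 <- unit_vec(e2r - sum(e2r * e1) * e1)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  water_dirs <- list(-e1, -e2, e3, -e3)
  water_atoms <- list()
  for (wd in water_dirs) {
    ow <- m_pos + wd * d_mo
    # hydrogens: 0.96 A bonds opening away from the metal
    perp <- if (abs(sum(wd * e3)) < 0.9) unit_vec(pracma_cross(wd, e3)) else unit_vec(pracma_cross(wd, e1))
    h1 <- ow + unit_vec(wd * 0.55 + perp * 0.83) * 0.96
    h2 <- ow + unit_vec(wd * 0.55 - perp * 0.83) * 0.96
    water_atoms[[length(water_atoms) + 1L]] <-
      data.frame(element = c("O", "H", "H"),
                 x = c(ow[1], h1[1], h2[1]),
                 y = c(ow[2], h1[2], h2[2]),
                 z = c(ow[3], h1[3], h2[3]), stringsAsFactors = FALSE)
  }
  geo <- rbind(
    fq_geometry,
    data.frame(element = metal, x = m_pos[1], y = m_pos[2], z = m_pos[3],
               stringsAsFactors = FALSE),
    do.call(rbind, water_atoms)
  )
  rownames(geo) <- NULL
  # steric screen: no non-bonded pair closer than 0.7 A
  n <- nrow(geo)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (geom_dist(geo, i, j) < 0.7)
      stop(sprintf("geometry error: steric clash between atoms %d and %d", i, j),
           call. = FALSE)
  }
  species(label = sprintf("%s_%s_chelate", fq_label, metal),
          role = "chelate_complex", charge = 1L + .metal_charge[[metal]],
          geometry = geo, metal = metal)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Octahedral metal hexahydrate starting geometry
#'
#' @param metal `"Mg"`, `"Ca"` or `"Al"`.
#' @return a [species()] with role `metal_hexahydrate`.
#' @export
metal_hexahydrate_geometry <- function(metal = c("Al", "Mg", "Ca")) {
  metal <- match.arg(metal)
  d <- .metal_o_distance[[metal]]
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  rows <- list(data.frame(element = metal, x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  for (k in seq_len(6)) {
    wd <- dirs[k, ]
    ow <- wd * d
    perp <- if (abs(wd[3]) < 0.9) unit_vec(pracma_cross(wd, c(0, 0, 1))) else c(1, 0, 0)
    h1 <- ow + unit_vec(wd * 0.55 + perp * 0.83) * 0.96
    h2 <- ow + unit_vec(wd * 0.55 - perp * 0.83) * 0.96
    rows[[k + 1L]] <- data.frame(element = c("O", "H", "H"),
                                 x = c(ow[1], h1[1], h2[1]),
                                 y = c(ow[2], h1[2], h2[2]),
                                 z = c(ow[3], h1[3], h2[3]), stringsAsFactors = FALSE)
  }
  species(label = sprintf("%s_hexahydrate", metal), role = "metal_hexahydrate",
          charge = .metal_charge[[metal]], geometry = do.call(rbind, rows),
          metal = metal)
}

#' Donor oxygen-metal bond lengths of a chelate complex
#'
#' Euclidean C3-carboxyl-O...M and C4-keto-O...M distances, reported to one
#' decimal (the precision at which such coordination distances are usually
#' discussed).
#'
#' @param complex a [species()] with role `chelate_complex` and geometry.
#' @return named numeric vector `c(carboxyl = ..., keto = ...)` in Angstrom.
#' @export
donor_bond_lengths <- function(complex) {
  stopifnot(inherits(complex, "qm_species"))
  if (is.null(complex$geometry)) stop("complex has no geometry", call. = FALSE)
  geo <- complex$geometry
  m_idx <- which(geo$element %in% names(.metal_charge))
  if (length(m_idx) != 1L)
    stop("substructure error: complex must contain exactly one metal atom", call. = FALSE)
  donors <- find_donor_oxygens_near_metal(geo, m_idx)
  d <- c(carboxyl = geom_dist(geo, donors["carboxyl"], m_idx),
         keto = geom_dist(geo, donors["keto"], m_idx))
  round(d, 1)
}

find_donor_oxygens_near_metal <- function(geo, m_idx) {
  elt <- geo$element
  bonds <- infer_bonds(geo[, c("element", "x", "y", "z")])
  # drop bonds involving the metal so the organic substructure rule applies
  bonds <- bonds[bonds$a1 != m_idx & bonds$a2 != m_idx, , drop = FALSE]
  nbrs <- function(i) {
    sel1 <- bonds$a1 == i; sel2 <- bonds$a2 == i
    c(bonds$a2[sel1], bonds$a1[sel2])
  }
  o_idx <- which(elt == "O")
  carboxyl_o <- integer(0); keto_o <- integer(0)
  for (i in o_idx) {
    nb <- nbrs(i)
    heavy <- nb[elt[nb] != "H"]
    has_h <- any(elt[nb] == "H")
    if (length(heavy) != 1L || elt[heavy] != "C") next
    cnb <- nbrs(heavy)
    if (sum(elt[cnb] == "O") == 2L && !has_h) carboxyl_o <- c(carboxyl_o, i)
    if (sum(elt[cnb] == "O") == 1L && !has_h && length(nb) == 1L) keto_o <- c(keto_o, i)
  }
  if (length(carboxyl_o) == 0L || length(keto_o) == 0L)
    stop("substructure error: donor oxygens not identifiable in complex", call. = FALSE)
  # of the candidates, take those closest to the metal
  pick <- function(cand) cand[which.min(vapply(cand, function(i) geom_dist(geo, i, m_idx), numeric(1)))]
  c(carboxyl = pick(carboxyl_o), keto = pick(keto_o))
}

# ---------------------------------------------------------------------------
# Conformer start enumeration ------------------------------------------------

# Rotate the subtree on the k-side of bond j-k around the j->k axis.
rotate_torsion <- function(geometry, j, k, angle_deg, bonds = infer_bonds(geometry)) {
  n <- nrow(geometry)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$a1[r]]] <- c(adj[[bonds$a1[r]]], bonds$a2[r])
    adj[[bonds$a2[r]]] <- c(adj[[bonds$a2[r]]], bonds$a1[r])
  }
  # atoms reachable from k without passing through j
  seen <- logical(n); seen[j] <- TRUE
  stack <- k
  while (length(stack) > 0L) {
    v <- stack[[1]]; stack <- stack[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  moving <- setdiff(which(seen), c(j, k))
  if (length(moving) == 0L) return(geometry)
  axis <- unit_vec(as.numeric(geometry[k, c("x", "y", "z")]) -
                   as.numeric(geometry[j, c("x", "y", "z")]))
  origin <- as.numeric(geometry[k, c("x", "y", "z")])
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  for (i in moving) {
    v <- as.numeric(geometry[i, c("x", "y", "z")]) - origin
    vr <- v * ct + pracma_cross(axis, v) * st + axis * sum(axis * v) * (1 - ct)
    geometry[i, c("x", "y", "z")] <- origin + vr
  }
  geometry
}

kabsch_rmsd <- function(g1, g2) {
  p <- as.matrix(g1[, c("x", "y", "z")])
  q <- as.matrix(g2[, c("x", "y", "z")])
  p <- sweep(p, 2, colMeans(p)); q <- sweep(q, 2, colMeans(q))
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((q - p %*% t(rot))^2)))
}

#' Enumerate torsional conformer starting geometries
#'
#' Deterministically enumerates combinations of the named torsions on fixed
#' angle grids, removes duplicates (superposition RMSD < 0.05 Angstrom) and,
#' when a force-field adapter is supplied, returns the starts ranked by
#' adapter energy (ascending); otherwise in enumeration order.
#'
#' @param sp a [species()] with geometry.
#' @param torsion_rules list of `list(bond = c(j, k), angles = degrees)`;
#'   each rotates the subtree on the `k` side about the `j-k` bond.
#' @param adapter optional function(geometry) -> numeric energy (e.g. a
#'   force-field scoring hook); failures are propagated with the offending
#'   geometry serialized to a temp XYZ file named in the error.
#' @return list of [species()] records (one per unique start).
#' @export
enumerate_conformer_starts <- function(sp, torsion_rules, adapter = NULL) {
  stopifnot(inherits(sp, "qm_species"))
  if (is.null(sp$geometry)) stop("species has no geometry", call. = FALSE)
  bonds <- infer_bonds(sp$geometry)
  grids <- lapply(torsion_rules, function(tr) tr$angles)
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  geoms <- list()
  for (r in seq_len(nrow(combos))) {
    g <- sp$geometry
    for (ti in seq_along(torsion_rules)) {
      tr <- torsion_rules[[ti]]
      g <- rotate_torsion(g, tr$bond[1], tr$bond[2], combos[r, ti], bonds = bonds)
    }
    dup <- any(vapply(geoms, function(g0) kabsch_rmsd(g0, g) < 0.05, logical(1)))
    if (!dup) geoms[[length(geoms) + 1L]] <- g
  }
  if (!is.null(adapter)) {
    energies <- vapply(seq_along(geoms), function(i) {
      tryCatch(adapter(geoms[[i]]), error = function(e) {
        f <- tempfile(fileext = ".xyz")
        write_xyz(geoms[[i]], f, comment = "adapter failure")
        stop(sprintf("conformer adapter failed on start %d (geometry written to %s): %s",
                     i, f, conditionMessage(e)), call. = FALSE)
      })
    }, numeric(1))
    geoms <- geoms[order(energies)]
  }
  lapply(seq_along(geoms), function(i) {
    s <- sp
    s$label <- sprintf("%s_conf%02d", sp$label, i)
    s$geometry <- geoms[[i]]
    s
  })
}
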