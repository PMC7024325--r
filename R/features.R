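#' Pharmacophore feature vocabulary
#'
#' The six feature types used throughout the package: hydrogen-bond donor
#' and acceptor, aromatic ring, hydrophobic group, and negatively /
#' positively ionisable centre.
#'
#' @return Character vector of the six feature type labels.
#' @export
feature_types <- function() {
  c("HBD", "HBA", "aromatic", "hydrophobic", "anion", "cation")
}

#' Default feature perception rules
#'
#' The perception rule table maps named structural rules onto feature
#' types.  It is data, not code: rows can be dropped (or `enabled` set to
#' `FALSE`) to mimic the definitions of an external matcher.  The shipped
#' rules follow widely used pharmacophore conventions:
#'
#' * `aromatic_ring` — one `aromatic` point at the centroid of every
#'   aromatic ring;
#' * `donor` — one `HBD` point on every O or N carrying at least one
#'   hydrogen (explicit or implicit);
#' * `acceptor` — one `HBA` point on every O or N with non-positive formal
#'   charge, excluding pyrrole-type aromatic nitrogens;
#' * `anion_carboxylate` — one `anion` point at the centroid of a
#'   deprotonated carboxylate group (C plus both oxygens);
#' * `anion_charged` — one `anion` point on any other negatively charged
#'   atom;
#' * `cation_charged` — one `cation` point on every positively charged
#'   atom;
#' * `hydrophobic_group` — one `hydrophobic` point at the centroid of each
#'   connected set of three or more non-aromatic carbons having no
#'   heteroatom neighbours.
#'
#' @return A data.frame with columns `rule`, `feature_type` and `enabled`.
#' @export
feature_rules <- function() {
  data.frame(
    rule = c("aromatic_ring", "donor", "acceptor", "anion_carboxylate",
             "anion_charged", "cation_charged", "hydrophobic_group"),
    feature_type = c("aromatic", "HBD", "HBA", "anion", "anion", "cation",
                     "hydrophobic"),
    enabled = TRUE,
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Molecule container: a light internal representation extracted from an SDF
# record (parsed by ChemmineR), carrying exactly what feature perception
# needs -- elements, 3D coordinates, formal charges, bonds and aromatic
# rings.

new_pharm_mol <- function(title, elem, xyz, charge, bonds, rings_idx, aromatic_rings) {
  structure(
    list(title = title, elem = elem, xyz = xyz, charge = charge,
         bonds = bonds, rings = rings_idx, aromatic_rings = aromatic_rings),
    class = "pharm_mol"
  )
}

#' @export
print.pharm_mol <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, %d bonds, %d ring(s)>\n",
              x$title, length(x$elem), nrow(x$bonds), length(x$rings)))
  invisible(x)
}

# Standard valences used for implicit hydrogen counting.
.ps_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                 I = 1, B = 3, Si = 4)

.ps_implicit_h <- function(elem, charge, bond_order_sum) {
  val <- .ps_valence[elem]
  if (is.na(val)) return(0L)
  val <- if (elem == "C") val - abs(charge) else val + charge
  max(0, round(val - bond_order_sum))
}

.ps_parse_charges <- function(lines, n_atoms) {
  charge <- numeric(n_atoms)
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg) {
    flds <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    npairs <- flds[1]
    for (k in seq_len(npairs)) {
      charge[flds[2 * k]] <- flds[2 * k + 1]
    }
  }
  charge
}

.ps_mol_from_sdf <- function(sdf, lines) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  xyz <- unname(ab[, c("C1", "C2", "C3"), drop = FALSE])
  storage.mode(xyz) <- "double"
  n <- length(elem)
  if (n > 1L && all(xyz == 0))
    stop_validation(paste0("molecule '", ChemmineR::sdfid(sdf),
                           "' has no 3D coordinates (all atoms at the origin); ",
                           "embed conformers before feature perception"))
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  rng <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                  error = function(e) list(RINGS = NULL, AROMATIC = logical(0)))
  ring_idx <- lapply(rng$RINGS, function(r) as.integer(sub("^.*_", "", r)))
  arom <- which(as.logical(rng$AROMATIC))
  new_pharm_mol(
    title = ChemmineR::sdfid(sdf),
    elem = elem,
    xyz = xyz,
    charge = .ps_parse_charges(lines, n),
    bonds = bonds,
    rings_idx = ring_idx,
    aromatic_rings = if (length(ring_idx)) ring_idx[arom] else list()
  )
}

#' Read molecules from an SDF file
#'
#' Parses a (possibly multi-record) V2000 SDF file into lightweight
#' molecule objects suitable for [perceive_features()].  Formal charges
#' are taken from `M CHG` property lines.  Each record must carry explicit
#' 3D coordinates; records whose atoms all sit at the origin (the usual
#' signature of coordinate-free input) are rejected.
#'
#' @param path Path to an SDF file.
#' @return A list of molecule objects, named by their title lines.
#' @export
read_sdf_molecules <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  sdfstr <- tryCatch(ChemmineR::read.SDFstr(path),
                     error = function(e) stop_validation(
                       paste0("cannot parse SDF '", path, "': ", conditionMessage(e))))
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(sdfstr)),
                     error = function(e) stop_validation(
                       paste0("cannot parse SDF '", path, "': ", conditionMessage(e))))
  mols <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    mols[[i]] <- .ps_mol_from_sdf(sdfset[[i]], as.character(sdfstr[[i]]))
  }
  names(mols) <- vapply(mols, function(m) m$title, character(1))
  mols
}

# ---------------------------------------------------------------------------
# Perception rules.  Each returns a coordinate matrix (possibly 0-row).

.ps_centroid <- function(xyz, idx) colMeans(xyz[idx, , drop = FALSE])

.ps_neighbours <- function(mol) {
  n <- length(mol$elem)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

.ps_h_counts <- function(mol, nb) {
  n <- length(mol$elem)
  bsum <- numeric(n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    o <- if (o == 4) 1.5 else o        # aromatic bonds count 1.5
    bsum[mol$bonds$a1[k]] <- bsum[mol$bonds$a1[k]] + o
    bsum[mol$bonds$a2[k]] <- bsum[mol$bonds$a2[k]] + o
  }
  vapply(seq_len(n), function(i) {
    expl <- sum(mol$elem[nb[[i]]] == "H")
    expl + .ps_implicit_h(mol$elem[i], mol$charge[i], bsum[i])
  }, numeric(1))
}

.ps_aromatic_atoms <- function(mol) unique(unlist(mol$aromatic_rings))

.ps_find_carboxylates <- function(mol, nb) {
  # carbons bonded to exactly two terminal oxygens, the group carrying a
  # negative charge -> list of atom index triples (C, O, O)
  heavy_deg <- vapply(nb, function(v) sum(mol$elem[v] != "H"), numeric(1))
  out <- list()
  for (c_i in which(mol$elem == "C")) {
    os <- nb[[c_i]][mol$elem[nb[[c_i]]] == "O"]
    os <- os[heavy_deg[os] == 1]
    if (length(os) == 2 && any(mol$charge[c(c_i, os)] < 0))
      out[[length(out) + 1L]] <- c(c_i, os)
  }
  out
}

#' Perceive pharmacophore features of a molecule
#'
#' Applies the perception rule table to a 3D molecule and returns its
#' typed feature points.  Group features (aromatic rings, hydrophobic
#' clusters, carboxylates) are placed at the centroid of the matched atom
#' set; atom features sit on the atom itself.  Deterministic for a fixed
#' molecule and rule table.
#'
#' @param mol A molecule object from [read_sdf_molecules()].
#' @param rules A rule table as returned by [feature_rules()]; rows with
#'   `enabled = FALSE` are skipped.
#' @return A data.frame of feature points with columns `type`, `x`, `y`,
#'   `z` (zero rows when nothing matches).
#' @export
perceive_features <- function(mol, rules = feature_rules()) {
  if (!inherits(mol, "pharm_mol"))
    stop_argument("'mol' must be a molecule object from read_sdf_molecules()")
  nb <- .ps_neighbours(mol)
  hc <- .ps_h_counts(mol, nb)
  arom <- .ps_aromatic_atoms(mol)
  carbox <- .ps_find_carboxylates(mol, nb)
  carbox_o <- unlist(lapply(carbox, function(g) g[-1]))

  pts <- list()
  add <- function(type, mat) {
    if (is.null(mat) || NROW(mat) == 0) return()
    mat <- matrix(mat, ncol = 3)
    pts[[length(pts) + 1L]] <<- data.frame(type = type, x = mat[, 1],
                                           y = mat[, 2], z = mat[, 3])
  }
  active_rules <- rules[rules$enabled, , drop = FALSE]
  for (k in seq_len(nrow(active_rules))) {
    rule <- active_rules$rule[k]
    type <- active_rules$feature_type[k]
    mat <- switch(rule,
      aromatic_ring = if (length(mol$aromatic_rings))
        t(vapply(mol$aromatic_rings, function(r) .ps_centroid(mol$xyz, r),
                 numeric(3))),
      donor = {
        idx <- which(mol$elem %in% c("O", "N") & hc >= 1)
        mol$xyz[idx, , drop = FALSE]
      },
      acceptor = {
        idx <- which(mol$elem %in% c("O", "N") & mol$charge <= 0)
        # pyrrole-type aromatic N (three connections or bearing H) has no
        # available lone pair in the ring plane
        drop <- idx[mol$elem[idx] == "N" & idx %in% arom &
                      (vapply(nb[idx], length, numeric(1)) >= 3 | hc[idx] >= 1)]
        mol$xyz[setdiff(idx, drop), , drop = FALSE]
      },
      anion_carboxylate = if (length(carbox))
        t(vapply(carbox, function(g) .ps_centroid(mol$xyz, g), numeric(3))),
      anion_charged = {
        idx <- setdiff(which(mol$charge < 0), carbox_o)
        idx <- setdiff(idx, unlist(lapply(carbox, `[`, 1)))
        mol$xyz[idx, , drop = FALSE]
      },
      cation_charged = mol$xyz[mol$charge > 0, , drop = FALSE],
      hydrophobic_group = {
        cand <- which(vapply(seq_along(mol$elem), function(i) {
          mol$elem[i] == "C" && !(i %in% arom) &&
            all(mol$elem[nb[[i]]] %in% c("C", "H"))
        }, logical(1)))
        comps <- .ps_components(cand, nb)
        comps <- comps[vapply(comps, length, numeric(1)) >= 3]
        if (length(comps))
          t(vapply(comps, function(g) .ps_centroid(mol$xyz, g), numeric(3)))
      },
      stop_argument(paste0("unknown perception rule: ", rule))
    )
    add(type, mat)
  }
  if (!length(pts))
    return(data.frame(type = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  out
}

# Connected components of an induced subgraph (atom indices in `cand`).
.ps_components <- function(cand, nb) {
  comps <- list()
  seen <- logical(max(c(cand, 0L)) + 1L)
  for (s in cand) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nxt <- intersect(nb[[v]], cand)
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Read a compound library with perceived features
#'
#' Reads a multi-record SDF file, perceives pharmacophore features for
#' every record, and groups records into compounds.  Records sharing a
#' compound identifier are pooled as conformers of one compound, matching
#' the convention that enumerated stereoisomers (and their conformers)
#' count as a single compound.
#'
#' @param path SDF file path.
#' @param id_from How to obtain the compound identifier: `"title"` uses
#'   the record title line (default), or the name of an SDF data field.
#' @param rules Perception rule table, see [feature_rules()].
#' @return A named list of [conformer_set()] objects.
#' @export
read_compound_library <- function(path, id_from = "title", rules = feature_rules()) {
  mols <- read_sdf_molecules(path)
  ids <- if (identical(id_from, "title")) {
    vapply(mols, function(m) m$title, character(1))
  } else {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    vapply(seq_along(sdfset), function(i) {
      db <- ChemmineR::datablock(sdfset[[i]])
      val <- db[[id_from]]
      if (is.null(val)) stop_validation(
        paste0("record ", i, " lacks SDF field '", id_from, "'"))
      as.character(val)
    }, character(1))
  }
  feats <- lapply(mols, perceive_features, rules = rules)
  out <- lapply(split(feats, factor(ids, levels = unique(ids))), function(fs) {
    conformer_set(compound_id = "", conformers = unname(fs))
  })
  for (id in names(out)) out[[id]]$compound_id <- id
  out
}
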