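# Structure input/output: parse PDB files into the internal conformation
# model, place missing backbone amide hydrogens, and write ensembles back
# out as multi-model PDB. Parsing is delegated to bio3d; this module only
# normalizes records (altlocs, hetero groups, numbering) into a
# per-residue representation suited to amide-centric distance counting.

# Non-standard residues mapped to their parent amino acid.
NONSTD_MAP <- c(MSE = "MET", SEC = "CYS", HYP = "PRO", MLY = "LYS",
                CSO = "CYS", PTR = "TYR", SEP = "SER", TPO = "THR")

STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

map_resname <- function(resid) {
  out <- ifelse(resid %in% STD_AA, resid, NONSTD_MAP[resid])
  unname(out)
}

infer_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy) && !is.na(elesy) && nzchar(trimws(elesy))) {
    return(toupper(trimws(elesy)))
  }
  nm <- gsub("[0-9']", "", toupper(elety))
  if (nchar(nm) == 0) return("X")
  # Two-letter elements occurring in protein/PDB context; backbone and
  # side-chain carbons like "CD" are carbon, not cadmium.
  if (nm %in% c("SE", "FE", "ZN", "MG", "MN", "CU", "NA", "CL")) return(nm)
  substr(nm, 1, 1)
}

#' Construct a conformation from an atom table
#'
#' Builds the internal single-model representation used throughout pfkit
#' from a per-atom data frame. Residues are renumbered 1..n in order of
#' appearance; the original (author) numbering is retained for joining
#' against experimental tables.
#'
#' @param atoms data frame with columns `resno` (author numbering),
#'   `resid` (3-letter code), `elety` (atom name), `x`, `y`, `z` and
#'   optionally `elesy` (element symbol).
#' @param label free-text identifier for the conformation.
#' @return An object of class `"conformation"` with elements `atoms`
#'   (normalized atom table keyed by internal `resno`), `sequence`
#'   (3-letter codes), `author_resno`, `amide_h` (n x 3 matrix, `NA` rows
#'   where no amide hydrogen is assigned) and `label`.
#' @export
new_conformation <- function(atoms, label = "") {
  stopifnot(all(c("resno", "resid", "elety", "x", "y", "z") %in% names(atoms)))
  key <- paste(atoms$resno, atoms$resid)
  ures <- unique(key)
  internal <- match(key, ures)
  elesy <- if ("elesy" %in% names(atoms)) atoms$elesy else rep(NA, nrow(atoms))
  element <- vapply(seq_len(nrow(atoms)),
                    function(k) infer_element(atoms$elety[k], elesy[k]),
                    character(1))
  at <- data.frame(
    resno = internal,
    elety = trimws(atoms$elety),
    element = element,
    x = atoms$x, y = atoms$y, z = atoms$z,
    is_heavy = !(element %in% c("H", "D")),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  first_idx <- match(seq_along(ures), internal)
  conf <- structure(list(
    atoms = at,
    sequence = atoms$resid[first_idx],
    author_resno = atoms$resno[first_idx],
    amide_h = matrix(NA_real_, nrow = length(ures), ncol = 3),
    incomplete = logical(length(ures)),
    label = label
  ), class = "conformation")
  # carry over experimentally determined amide H positions, if any
  hsel <- at$elety %in% c("H", "HN", "D", "DN") & !at$is_heavy
  for (k in which(hsel)) {
    conf$amide_h[at$resno[k], ] <- c(at$x[k], at$y[k], at$z[k])
  }
  conf$amide_h[1, ] <- NA_real_
  conf$amide_h[conf$sequence == "PRO", ] <- NA_real_
  conf
}

n_residues <- function(conf) length(conf$sequence)

#' One-letter sequence of a conformation
#' @param conf a `"conformation"` object.
#' @return Character scalar of one-letter residue codes.
#' @export
sequence1 <- function(conf) {
  paste(bio3d::aa321(conf$sequence), collapse = "")
}

# Coordinates of a named atom in residue i, or NULL if absent.
atom_coord <- function(conf, i, elety) {
  sel <- which(conf$atoms$resno == i & conf$atoms$elety == elety)
  if (length(sel) == 0) return(NULL)
  as.numeric(conf$atoms[sel[1], c("x", "y", "z")])
}

# Matrix of heavy-atom coordinates with their residue indices.
heavy_coords <- function(conf) {
  sel <- conf$atoms$is_heavy
  list(xyz = as.matrix(conf$atoms[sel, c("x", "y", "z")]),
       resno = conf$atoms$resno[sel],
       elety = conf$atoms$elety[sel])
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %s: %d residues, %d atoms, %d amide H placed\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              n_residues(x), nrow(x$atoms),
              sum(stats::complete.cases(x$amide_h))))
  invisible(x)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d conformation(s) from %s\n",
              length(x$conformations),
              if (nzchar(x$source)) x$source else "(unknown)"))
  invisible(x)
}

#' Construct an ensemble from a list of conformations
#'
#' All members must share the same sequence.
#'
#' @param conformations non-empty list of `"conformation"` objects.
#' @param source free-text provenance label.
#' @return An object of class `"ensemble"`.
#' @export
new_ensemble <- function(conformations, source = "") {
  if (length(conformations) < 1) stop("ensemble must contain >= 1 conformation")
  seqs <- vapply(conformations, function(cf) paste(cf$sequence, collapse = " "),
                 character(1))
  if (length(unique(seqs)) != 1) {
    stop("sequence mismatch across conformations in ensemble")
  }
  structure(list(conformations = conformations, source = source),
            class = "ensemble")
}

#' Read protein conformations from a PDB file
#'
#' Parses a single- or multi-model PDB file into an ensemble. Water and
#' unmappable hetero groups are dropped, alternate locations are resolved
#' to the highest-occupancy copy (ties broken toward altloc "A"), and
#' residues are renumbered 1..n while the author numbering is retained.
#' Only the first protein chain is kept; additional chains are dropped
#' with a warning.
#'
#' @param path path to a PDB-format file.
#' @param model_selector `"all"` (default) to keep every MODEL, `"first"`
#'   to keep only the first.
#' @return An object of class `"ensemble"`.
#' @export
read_conformations <- function(path, model_selector = c("all", "first")) {
  model_selector <- match.arg(model_selector)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at$resid <- toupper(trimws(at$resid))
  mapped <- map_resname(at$resid)
  keep <- !is.na(mapped)
  rejected <- setdiff(unique(at$resid[!keep]),
                      c("HOH", "DOD", "WAT", "SO4", "GOL", "EDO", "CL",
                        "NA", "MG", "ZN", "CA", "PO4", "ACT"))
  if (length(rejected) > 0 && any(at$type[at$resid %in% rejected] == "ATOM")) {
    stop("unmapped non-standard residue(s): ", paste(rejected, collapse = ", "))
  }
  at$resid <- mapped
  at$row <- seq_len(nrow(at))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no protein residues found in ", path)

  chains <- unique(at$chain)
  if (length(chains) > 1) {
    warning("multiple chains found; keeping first chain '", chains[1], "'")
    at <- at[at$chain %in% chains[1], , drop = FALSE]
  }

  # altloc resolution: within each (residue, atom name) group keep the
  # highest occupancy; ties go to altloc "A", then alphabetical.
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(nzchar(alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(paste(at$resno, at$insert, at$elety), -occ, alt != "A", alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
    at <- at[order(at$row), , drop = FALSE]
  }

  nmodel <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (model_selector == "first") nmodel <- 1
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)

  confs <- lapply(seq_len(nmodel), function(m) {
    mx <- xyz[m, ]
    df <- data.frame(
      resno = at$resno, resid = at$resid, elety = at$elety,
      x = mx[3 * (at$row - 1) + 1],
      y = mx[3 * (at$row - 1) + 2],
      z = mx[3 * (at$row - 1) + 3],
      elesy = if ("elesy" %in% names(at)) at$elesy else NA,
      stringsAsFactors = FALSE
    )
    new_conformation(df, label = paste0("model", m))
  })
  new_ensemble(confs, source = path)
}

#' Place backbone amide hydrogens by ideal geometry
#'
#' For every non-proline residue after the first, sets the amide hydrogen
#' 1.01 Angstrom from the backbone nitrogen, in the peptide plane defined
#' by C(i-1), N(i), CA(i), anti-parallel (trans) to the preceding carbonyl
#' C=O direction. Experimentally determined hydrogen positions already
#' present in the input are preserved.
#'
#' @param conf a `"conformation"` object.
#' @return The conformation with its `amide_h` matrix filled in; residues
#'   with missing backbone atoms are flagged in `$incomplete` and left
#'   without a hydrogen (with a warning).
#' @export
place_amide_hydrogens <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  n <- n_residues(conf)
  for (i in seq_len(n)) {
    if (i == 1 || conf$sequence[i] == "PRO") {
      conf$amide_h[i, ] <- NA_real_
      next
    }
    if (all(is.finite(conf$amide_h[i, ]))) next  # experimental H preserved
    N <- atom_coord(conf, i, "N")
    CA <- atom_coord(conf, i, "CA")
    Cp <- atom_coord(conf, i - 1, "C")
    Op <- atom_coord(conf, i - 1, "O")
    if (is.null(N) || is.null(CA) || is.null(Cp) || is.null(Op)) {
      conf$incomplete[i] <- TRUE
      warning("residue ", i, ": missing backbone atoms, amide H not placed")
      next
    }
    nrm <- unit_vec(cross3(Cp - N, CA - N))
    d <- Cp - Op                      # anti-parallel to C=O
    d_ip <- d - sum(d * nrm) * nrm    # projected into the peptide plane
    conf$amide_h[i, ] <- N + IDEAL_GEOM$b_n_h * unit_vec(d_ip)
  }
  conf
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' Heavy atoms and any assigned amide hydrogens are written with author
#' residue numbering; ensembles with more than one member produce
#' MODEL/ENDMDL blocks. Coordinates round-trip through
#' [read_conformations()] to PDB precision (1e-3 Angstrom).
#'
#' @param ens an `"ensemble"` object.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  ref <- ens$conformations[[1]]
  # build shared atom layout: heavy atoms in stored order, amide H after N
  rows <- list()
  for (i in seq_len(n_residues(ref))) {
    idx <- which(ref$atoms$resno == i & ref$atoms$is_heavy)
    nm <- ref$atoms$elety[idx]
    has_h <- all(is.finite(ref$amide_h[i, ]))
    npos <- which(nm == "N")
    ord <- if (length(npos) == 1) c(idx[seq_len(npos)], NA, idx[-seq_len(npos)]) else c(idx, NA)
    if (!has_h) ord <- ord[!is.na(ord)]
    rows[[i]] <- data.frame(resno = i, atom_idx = ord)
  }
  layout <- do.call(rbind, rows)
  natom <- nrow(layout)

  coords_of <- function(conf) {
    xyz <- numeric(3 * natom)
    for (k in seq_len(natom)) {
      ai <- layout$atom_idx[k]
      p <- if (is.na(ai)) conf$amide_h[layout$resno[k], ]
           else as.numeric(conf$atoms[ai, c("x", "y", "z")])
      xyz[(3 * k - 2):(3 * k)] <- p
    }
    xyz
  }
  xyz <- t(vapply(ens$conformations, coords_of, numeric(3 * natom)))
  if (nrow(xyz) == 1) xyz <- as.vector(xyz)

  elety <- ifelse(is.na(layout$atom_idx), "H", ref$atoms$elety[layout$atom_idx])
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = ref$author_resno[layout$resno],
    resid = ref$sequence[layout$resno],
    elety = elety,
    chain = "A"
  )
  invisible(path)
}
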