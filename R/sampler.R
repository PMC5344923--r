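# Coarse-grained conformational sampling in backbone (phi, psi) space.
#
# Conformations are perturbed in internal coordinates: bond lengths and
# bond angles are held fixed, peptide bonds stay trans (omega = 180), and
# moves add Gaussian noise to the (phi, psi) angles of a randomly chosen
# fragment. A dihedral change is applied as a rigid rotation of all atoms
# downstream of the rotated bond, so unperturbed geometry is preserved
# exactly. Generated conformations are filtered by a soft-sphere clash
# score, and an iterative loop re-weights fragment selection toward
# regions of large disagreement with the experimental HDX data.

#' Extract backbone dihedral angles
#'
#' Standard torsions: `phi = C(i-1)-N-CA-C`, `psi = N-CA-C-N(i+1)`.
#' `phi` of the first residue and `psi` of the last are undefined and
#' reported as `NA`, so an (N+1)-residue chain carries 2N degrees of
#' freedom.
#'
#' @param conf a `"conformation"` with complete backbone.
#' @return A `"dihedral_vector"`: list with numeric `phi` and `psi` in
#'   degrees (range (-180, 180]).
#' @export
extract_dihedrals <- function(conf) {
  n <- n_residues(conf)
  bb <- lapply(seq_len(n), function(i) {
    atoms <- list(N = atom_coord(conf, i, "N"),
                  CA = atom_coord(conf, i, "CA"),
                  C = atom_coord(conf, i, "C"))
    if (any(vapply(atoms, is.null, logical(1)))) {
      stop("residue ", i, ": missing backbone atom, cannot extract dihedrals")
    }
    atoms
  })
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- dihedral_angle(bb[[i - 1]]$C, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
    }
    if (i < n) {
      psi[i] <- dihedral_angle(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, bb[[i + 1]]$N)
    }
  }
  structure(list(phi = phi, psi = psi), class = "dihedral_vector")
}

#' Rebuild a conformation from backbone dihedrals
#'
#' Reconstructs the backbone with ideal bond lengths and angles, trans
#' peptide bonds (omega = 180), seeded from the template's first-residue
#' N/CA/C positions. Side chains are carried rigidly in each residue's
#' local backbone frame; amide hydrogens are re-placed.
#'
#' @param dv a `"dihedral_vector"` whose length matches the template.
#' @param template a `"conformation"` providing sequence, side-chain
#'   geometry and the starting frame.
#' @return A new `"conformation"`.
#' @export
rebuild_conformation <- function(dv, template) {
  n <- n_residues(template)
  if (length(dv$phi) != n) stop("dihedral vector length does not match template")
  g <- IDEAL_GEOM
  bb <- vector("list", n)
  bb[[1]] <- list(N = atom_coord(template, 1, "N"),
                  CA = atom_coord(template, 1, "CA"),
                  C = atom_coord(template, 1, "C"))
  if (any(vapply(bb[[1]], is.null, logical(1)))) {
    stop("template residue 1 lacks backbone atoms")
  }
  for (i in seq_len(n - 1)) {
    psi <- if (is.na(dv$psi[i])) 180 else dv$psi[i]
    Nn <- place_atom(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C,
                     g$b_c_n, g$a_ca_c_n, psi)
    CAn <- place_atom(bb[[i]]$CA, bb[[i]]$C, Nn,
                      g$b_n_ca, g$a_c_n_ca, 180)        # omega
    Cn <- place_atom(bb[[i]]$C, Nn, CAn,
                     g$b_ca_c, g$a_n_ca_c, dv$phi[i + 1])
    bb[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  # carbonyl O: in the psi plane, trans to the next amide nitrogen
  O <- lapply(seq_len(n), function(i) {
    psi <- if (is.na(dv$psi[i])) 180 else dv$psi[i]
    place_atom(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, g$b_c_o, g$a_ca_c_o,
               psi + 180)
  })

  out <- template
  for (i in seq_len(n)) {
    Ft <- tryCatch(residue_frame(atom_coord(template, i, "N"),
                                 atom_coord(template, i, "CA"),
                                 atom_coord(template, i, "C")),
                   error = function(e) NULL)
    Fr <- residue_frame(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
    ca_t <- atom_coord(template, i, "CA")
    rows <- which(out$atoms$resno == i)
    for (k in rows) {
      nm <- out$atoms$elety[k]
      p <- switch(nm,
                  N = bb[[i]]$N, CA = bb[[i]]$CA, C = bb[[i]]$C, O = O[[i]],
                  {
                    if (is.null(Ft)) next
                    local <- t(Ft) %*% (as.numeric(out$atoms[k, c("x", "y", "z")]) - ca_t)
                    bb[[i]]$CA + as.vector(Fr %*% local)
                  })
      out$atoms[k, c("x", "y", "z")] <- p
    }
  }
  out$amide_h[] <- NA_real_
  place_amide_hydrogens(out)
}

#' Soft-sphere clash score
#'
#' Sum over heavy-atom pairs separated by at least two residues in
#' sequence of `max(0, d_clash - d)^2` with `d_clash` = 3.0 Angstrom.
#' Zero for clash-free structures.
#'
#' @param conf a `"conformation"`.
#' @param d_clash clash distance, Angstrom.
#' @return Non-negative numeric score.
#' @export
clash_score <- function(conf, d_clash = 3.0) {
  hv <- heavy_coords(conf)
  n <- nrow(hv$xyz)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(hv$xyz))
  sep <- abs(outer(hv$resno, hv$resno, "-"))
  pen <- matrix(pmax(0, d_clash - d)^2, nrow = n)  # pmax drops dim
  pen[sep < 2] <- 0
  sum(pen[upper.tri(pen)])
}

#' Define a sampling fragment
#'
#' @param id free-text identifier.
#' @param residues integer vector of residue indices (not necessarily
#'   contiguous).
#' @param weight non-negative sampling weight.
#' @return A `"fragment"` list.
#' @export
fragment <- function(id, residues, weight = 1) {
  stopifnot(length(residues) >= 1, weight >= 0)
  structure(list(id = as.character(id), residues = sort(unique(as.integer(residues))),
                 weight = weight), class = "fragment")
}

#' Contiguous-block fragment decomposition
#'
#' Splits a chain of `n` residues into contiguous fragments of roughly
#' `block` residues with uniform weight, a convenient default when no
#' expert decomposition is supplied.
#'
#' @param n chain length.
#' @param block target fragment size in residues.
#' @return List of `"fragment"` objects.
#' @export
default_fragments <- function(n, block = 5) {
  starts <- seq(1, n, by = block)
  lapply(seq_along(starts), function(k) {
    fragment(id = paste0("F", k),
             residues = starts[k]:min(starts[k] + block - 1, n))
  })
}

#' Sampler configuration
#'
#' @param n_conformations target number of accepted conformations.
#' @param perturbation_sigma Gaussian step size for (phi, psi), degrees.
#' @param energy_threshold clash-score acceptance bound; `NULL` means
#'   "auto": 1.1 times the starting conformation's clash score.
#' @param fragments list of [fragment()] objects; at least one must have
#'   positive weight.
#' @param seed integer RNG seed; the whole exploration is deterministic
#'   given the seed.
#' @param max_attempts_per_accept attempt budget per requested
#'   conformation before the exploration gives up.
#' @return A `"sampler_config"` list.
#' @export
sampler_config <- function(n_conformations = 100, perturbation_sigma = 5,
                           energy_threshold = NULL, fragments,
                           seed = 1L, max_attempts_per_accept = 50L) {
  stopifnot(n_conformations >= 1, perturbation_sigma > 0,
            max_attempts_per_accept >= 1, length(fragments) >= 1)
  structure(list(n_conformations = as.integer(n_conformations),
                 perturbation_sigma = perturbation_sigma,
                 energy_threshold = energy_threshold,
                 fragments = fragments,
                 seed = as.integer(seed),
                 max_attempts_per_accept = as.integer(max_attempts_per_accept)),
            class = "sampler_config")
}

# Draw a fragment index with probability proportional to weight.
draw_fragment <- function(fragments) {
  w <- vapply(fragments, function(f) f$weight, numeric(1))
  if (all(w <= 0)) stop("all fragment weights are zero")
  if (length(fragments) == 1) return(1L)
  sample.int(length(fragments), 1, prob = w)
}

# Apply a rotation of `delta` degrees to dihedral `which` ("phi"/"psi")
# of residue i: rotates all atoms downstream of the bond.
apply_dihedral_delta <- function(conf, i, which, delta) {
  n <- n_residues(conf)
  at <- conf$atoms
  if (which == "phi") {
    if (i == 1) return(conf)                      # phi_1 undefined
    p0 <- atom_coord(conf, i, "N")
    p1 <- atom_coord(conf, i, "CA")
    move <- (at$resno == i & !(at$elety %in% c("N", "H", "HN", "D", "DN"))) |
      at$resno > i
    move_h <- seq_len(n) > i
  } else {
    if (i == n) return(conf)                      # psi_n undefined
    p0 <- atom_coord(conf, i, "CA")
    p1 <- atom_coord(conf, i, "C")
    move <- (at$resno == i & at$elety == "O") | at$resno > i
    move_h <- seq_len(n) > i
  }
  pts <- as.matrix(at[move, c("x", "y", "z")])
  conf$atoms[move, c("x", "y", "z")] <- rotate_about_axis(pts, p0, p1 - p0, delta)
  hsel <- move_h & apply(is.finite(conf$amide_h), 1, all)
  if (any(hsel)) {
    conf$amide_h[hsel, ] <- rotate_about_axis(conf$amide_h[hsel, , drop = FALSE],
                                              p0, p1 - p0, delta)
  }
  conf
}

#' Propose a perturbed conformation
#'
#' Selects a fragment with probability proportional to its weight and
#' adds independent Gaussian noise (sd = `perturbation_sigma`) to the
#' (phi, psi) angles of its residues, applied as rigid rotations about
#' the corresponding backbone bonds. Uses (and advances) the current RNG
#' state.
#'
#' @param conf a `"conformation"`.
#' @param config a [sampler_config()].
#' @return The perturbed `"conformation"`, with the chosen fragment id in
#'   attribute `"fragment"`.
#' @export
propose_move <- function(conf, config) {
  fi <- draw_fragment(config$fragments)
  frag <- config$fragments[[fi]]
  for (i in frag$residues) {
    deltas <- stats::rnorm(2, 0, config$perturbation_sigma)
    conf <- apply_dihedral_delta(conf, i, "phi", deltas[1])
    conf <- apply_dihedral_delta(conf, i, "psi", deltas[2])
  }
  conf$label <- paste0(conf$label, "+", frag$id)
  attr(conf, "fragment") <- frag$id
  conf
}

#' Explore conformational space from a starting structure
#'
#' Repeatedly picks a random member of the growing collection (starting
#' from `start`), applies [propose_move()], and accepts the proposal iff
#' its [clash_score()] does not exceed the energy threshold. Stops after
#' `n_conformations` acceptances or when the attempt budget is
#' exhausted. Fully deterministic given `config$seed`.
#'
#' @param start a `"conformation"` (amide hydrogens need not be placed).
#' @param config a [sampler_config()].
#' @return An `"ensemble"` of accepted conformations, with the realized
#'   threshold in attribute `"energy_threshold"`.
#' @export
explore <- function(start, config) {
  stopifnot(inherits(start, "conformation"), inherits(config, "sampler_config"))
  set.seed(config$seed)
  threshold <- config$energy_threshold
  if (is.null(threshold)) threshold <- 1.1 * clash_score(start)
  pool <- list(start)
  accepted <- list()
  budget <- config$max_attempts_per_accept * config$n_conformations
  attempts <- 0
  while (length(accepted) < config$n_conformations && attempts < budget) {
    attempts <- attempts + 1
    base <- pool[[sample.int(length(pool), 1)]]
    cand <- propose_move(base, config)
    if (clash_score(cand) <= threshold) {
      cand$label <- paste0("s", length(accepted) + 1)
      accepted[[length(accepted) + 1]] <- cand
      pool[[length(pool) + 1]] <- cand
    }
  }
  if (length(accepted) == 0) {
    stop("no conformation accepted within the attempt budget; ",
         "increase energy_threshold or reduce perturbation_sigma")
  }
  ens <- new_ensemble(accepted, source = "explore")
  attr(ens, "energy_threshold") <- threshold
  ens
}

# Per-residue error map from a fit report. MS reports need the peptide
# table to spread each peptide's error over its residues.
residue_error_map <- function(report, peptides = NULL) {
  if (inherits(report, "nmr_fit_report")) {
    return(report$per_residue_error)
  }
  if (inherits(report, "ms_fit_report")) {
    if (is.null(peptides)) {
      stop("MS fit reports need the peptide table to map errors to residues")
    }
    acc <- list()
    for (k in seq_len(nrow(peptides))) {
      id <- peptides$id[k]
      if (!id %in% names(report$per_peptide_error)) next
      for (i in peptides$start[k]:peptides$end[k]) {
        key <- as.character(i)
        acc[[key]] <- c(acc[[key]], report$per_peptide_error[[id]])
      }
    }
    return(vapply(acc, mean, numeric(1)))
  }
  stop("unsupported report type")
}

#' Re-weight fragments toward regions of large data discrepancy
#'
#' Each fragment's discrepancy is the mean per-residue fit error over its
#' residues; fragments in the top quartile of discrepancy have their
#' weight multiplied by `boost`, and all weights are renormalized to sum
#' to one. Fragments with no scored residue keep the base weight.
#'
#' @param report an `"nmr_fit_report"` or `"ms_fit_report"`.
#' @param fragments list of [fragment()] objects.
#' @param boost multiplicative weight boost for high-discrepancy
#'   fragments.
#' @param peptides peptide table (`id`, `start`, `end`), required for MS
#'   reports.
#' @return The fragment list with updated, normalized weights.
#' @export
discrepancy_weights <- function(report, fragments, boost = 4, peptides = NULL) {
  err <- residue_error_map(report, peptides)
  disc <- vapply(fragments, function(f) {
    v <- err[as.character(f$residues)]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (all(is.na(disc))) stop("no overlap between fit report and fragments")
  q75 <- stats::quantile(disc, 0.75, na.rm = TRUE, names = FALSE)
  w <- vapply(fragments, function(f) f$weight, numeric(1))
  w <- ifelse(!is.na(disc) & disc >= q75, w * boost, w)
  w <- w / sum(w)
  for (k in seq_along(fragments)) fragments[[k]]$weight <- w[k]
  fragments
}

# Fit report (not just the score) of one conformation vs experimental data.
conformation_report <- function(conf, experimental, params = model_params()) {
  pf <- protection_factors(place_amide_hydrogens(conf), params)
  if (is.numeric(experimental) || inherits(experimental, "pf_set")) {
    return(nmr_fit(pf, experimental))
  }
  der <- derive_peptide_curves(pf, experimental$peptides,
                               experimental$rates, experimental$times)
  ms_fit(der, experimental$curves)
}

#' Iterative discrepancy-guided refinement
#'
#' Round 1 explores from the start with uniform fragment weights; each
#' later round re-weights the fragments by the current best
#' conformation's per-residue fit errors ([discrepancy_weights()]) and
#' explores again, seeded from the current best. Returns the best-scoring
#' conformation overall and a per-round trace. Stops early once the best
#' score reaches `stop_score`.
#'
#' @param start a `"conformation"`.
#' @param experimental observed data as in [select_best()].
#' @param config a [sampler_config()]; round r uses `config$seed + r - 1`.
#' @param n_rounds maximum number of exploration rounds.
#' @param stop_score early-stopping bound on the aggregate fit error.
#' @param boost weight multiplier passed to [discrepancy_weights()].
#' @param params a [model_params()].
#' @return A `"refine_result"`: list with `best` (conformation),
#'   `best_score`, `start_score` and `trace` (data frame with one row per
#'   executed round: `round`, `best_score` so-far, `best_label`, and a
#'   compact `weights` string of the weights used that round).
#' @export
iterate_refine <- function(start, experimental, config, n_rounds = 5,
                           stop_score = 0, boost = 4, params = model_params()) {
  stopifnot(n_rounds >= 1)
  peptides <- if (is.list(experimental) && !is.null(experimental$peptides)) {
    experimental$peptides
  } else NULL
  best_conf <- start
  best_score <- conformation_score(start, experimental, params)
  start_score <- best_score
  base_frags <- config$fragments
  for (k in seq_along(base_frags)) base_frags[[k]]$weight <- 1
  frags <- base_frags
  trace <- data.frame(round = integer(0), best_score = numeric(0),
                      best_label = character(0), weights = character(0))
  for (r in seq_len(n_rounds)) {
    cfg <- config
    cfg$fragments <- frags
    cfg$seed <- config$seed + r - 1L
    ens <- explore(best_conf, cfg)
    sel <- select_best(ens, experimental, params)
    if (sel$best_score < best_score) {
      best_score <- sel$best_score
      best_conf <- sel$best
    }
    trace <- rbind(trace, data.frame(
      round = r, best_score = best_score, best_label = best_conf$label,
      weights = paste(sprintf("%.3g", vapply(frags, function(f) f$weight,
                                             numeric(1))), collapse = ","),
      stringsAsFactors = FALSE))
    if (best_score <= stop_score) break
    if (r < n_rounds) {
      rep_best <- conformation_report(best_conf, experimental, params)
      frags <- discrepancy_weights(rep_best, base_frags, boost, peptides)
    }
  }
  structure(list(best = best_conf, best_score = best_score,
                 start_score = start_score, trace = trace),
            class = "refine_result")
}
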