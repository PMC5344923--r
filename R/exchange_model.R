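# Phenomenological protection-factor model: protection from exchange is
# attributed to hydrogen bonds formed by the amide hydrogen and to the
# packing density (heavy-atom contacts) around it,
#
#   ln P_i(C) = beta_h * N_i^h(C) + beta_c * N_i^c(C)
#
# with ensemble averages taken over ln P. Both counters measure distances
# from the amide hydrogen of residue i and ignore residues i-2..i+2, since
# the hydrogen bonds that maintain secondary structure involve residues at
# least three positions apart in sequence.

#' Model parameters for the protection-factor expression
#'
#' @param beta_h weight per amide hydrogen bond (dimensionless).
#' @param beta_c weight per heavy-atom contact (dimensionless).
#' @param hbond_cutoff H...O acceptor distance cutoff, Angstrom.
#' @param contact_cutoff H...heavy-atom contact cutoff, Angstrom.
#' @param exclusion_window half-width of the excluded sequence
#'   neighborhood: residues `i - w .. i + w` never contribute to the
#'   counts of residue `i`.
#' @return A list of class `"model_params"`.
#' @export
model_params <- function(beta_h = 2, beta_c = 0.35, hbond_cutoff = 2.4,
                         contact_cutoff = 6.5, exclusion_window = 2L) {
  stopifnot(hbond_cutoff > 0, contact_cutoff > 0, exclusion_window >= 0)
  structure(list(beta_h = beta_h, beta_c = beta_c,
                 hbond_cutoff = hbond_cutoff,
                 contact_cutoff = contact_cutoff,
                 exclusion_window = as.integer(exclusion_window)),
            class = "model_params")
}

amide_h_or_stop <- function(conf, i) {
  h <- conf$amide_h[i, ]
  if (!all(is.finite(h))) {
    stop("residue ", i, " has no amide hydrogen (proline, N-terminus, or ",
         "incomplete backbone)")
  }
  h
}

#' Count hydrogen bonds formed by an amide hydrogen
#'
#' Counts main-chain carbonyl oxygens (atom name "O"; terminal OXT is not
#' a main-chain oxygen) within `hbond_cutoff` of the amide hydrogen of
#' residue `i`, excluding acceptors from residues `i - w .. i + w`.
#'
#' @param conf a `"conformation"` with amide hydrogens placed.
#' @param i residue index (internal numbering).
#' @param params a [model_params()] object.
#' @return Non-negative integer count.
#' @export
count_amide_hbonds <- function(conf, i, params = model_params()) {
  h <- amide_h_or_stop(conf, i)
  sel <- conf$atoms$elety == "O" &
    abs(conf$atoms$resno - i) > params$exclusion_window
  if (!any(sel)) return(0L)
  xyz <- as.matrix(conf$atoms[sel, c("x", "y", "z")])
  d2 <- colSums((t(xyz) - h)^2)
  sum(d2 <= params$hbond_cutoff^2)
}

#' Count heavy-atom contacts around an amide hydrogen
#'
#' Counts all heavy atoms (main-chain and side-chain, any residue outside
#' the excluded window `i - w .. i + w`) within `contact_cutoff` of the
#' amide hydrogen of residue `i`.
#'
#' @inheritParams count_amide_hbonds
#' @return Non-negative integer count.
#' @export
count_heavy_contacts <- function(conf, i, params = model_params()) {
  h <- amide_h_or_stop(conf, i)
  sel <- conf$atoms$is_heavy &
    abs(conf$atoms$resno - i) > params$exclusion_window
  if (!any(sel)) return(0L)
  xyz <- as.matrix(conf$atoms[sel, c("x", "y", "z")])
  d2 <- colSums((t(xyz) - h)^2)
  sum(d2 <= params$contact_cutoff^2)
}

#' Protection factor from hydrogen-bond and contact counts
#'
#' Evaluates `ln P = beta_h * n_h + beta_c * n_c`. With the default
#' parameters a single hydrogen bond contributes 2 and a single contact
#' 0.35 to the natural-log protection factor.
#'
#' @param n_h number of amide hydrogen bonds.
#' @param n_c number of heavy-atom contacts.
#' @param params a [model_params()] object.
#' @return `ln P` (natural log, dimensionless).
#' @export
lnp_from_counts <- function(n_h, n_c, params = model_params()) {
  stopifnot(all(n_h >= 0), all(n_c >= 0))
  params$beta_h * n_h + params$beta_c * n_c
}

#' Per-residue protection factors of a conformation
#'
#' @param conf a `"conformation"` with amide hydrogens placed.
#' @param params a [model_params()] object.
#' @return An object of class `"pf_set"`: list with `lnP` (named numeric,
#'   names are internal residue indices; prolines, the N-terminus and
#'   incomplete residues are absent) and `counts` (data frame with
#'   `resno`, `n_hbonds`, `n_contacts`, `lnP`).
#' @export
protection_factors <- function(conf, params = model_params()) {
  stopifnot(inherits(conf, "conformation"))
  idx <- which(apply(is.finite(conf$amide_h), 1, all))
  n_h <- vapply(idx, function(i) as.integer(count_amide_hbonds(conf, i, params)),
                integer(1))
  n_c <- vapply(idx, function(i) as.integer(count_heavy_contacts(conf, i, params)),
                integer(1))
  lnp <- lnp_from_counts(n_h, n_c, params)
  names(lnp) <- idx
  structure(list(
    lnP = lnp,
    counts = data.frame(resno = idx, n_hbonds = n_h, n_contacts = n_c,
                        lnP = lnp, row.names = NULL)
  ), class = "pf_set")
}

#' Ensemble-averaged protection factors
#'
#' Averages the natural-log protection factor over all conformations:
#' `ln P_i(S) = mean over C in S of ln P_i(C)`. The average is taken on
#' the log scale, not over `P` itself.
#'
#' @param ens an `"ensemble"` whose members have amide hydrogens placed.
#' @param params a [model_params()] object.
#' @return A `"pf_set"`; `counts` holds the mean counts across members.
#' @export
ensemble_protection_factors <- function(ens, params = model_params()) {
  stopifnot(inherits(ens, "ensemble"))
  per <- lapply(ens$conformations, protection_factors, params = params)
  common <- Reduce(intersect, lapply(per, function(p) names(p$lnP)))
  if (length(common) == 0) stop("no residue with amide H in every member")
  colmat <- function(f) do.call(cbind, lapply(per, f))
  lnp <- rowMeans(colmat(function(p) p$lnP[common]))
  nh <- rowMeans(colmat(function(p) {
    v <- p$counts$n_hbonds; names(v) <- p$counts$resno; v[common]
  }))
  nc <- rowMeans(colmat(function(p) {
    v <- p$counts$n_contacts; names(v) <- p$counts$resno; v[common]
  }))
  names(lnp) <- common
  structure(list(
    lnP = lnp,
    counts = data.frame(resno = as.integer(common), n_hbonds = nh,
                        n_contacts = nc, lnP = lnp, row.names = NULL)
  ), class = "pf_set")
}

#' @export
print.pf_set <- function(x, ...) {
  cat(sprintf("<pf_set> ln P for %d residues (mean %.2f, range %.2f-%.2f)\n",
              length(x$lnP), mean(x$lnP), min(x$lnP), max(x$lnP)))
  invisible(x)
}
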