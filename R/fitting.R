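# Goodness-of-fit between structurally-derived and experimental HDX data,
# and best-conformation selection from an ensemble.
#
# HDX-NMR comparisons work on per-residue natural-log protection factors:
# per-residue error |lnP_der - lnP_obs|, its mean, and the squared Pearson
# correlation between the two series. HDX-MS comparisons work on peptide
# uptake curves: per-peptide error sum_t |D_der(t) - D_obs(t)| and its
# mean over peptides.

as_lnp_vector <- function(x) {
  if (inherits(x, "pf_set")) return(x$lnP)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a pf_set or a named numeric vector of ln P values")
}

#' Compare derived and observed protection factors (HDX-NMR)
#'
#' Computes, over residues present in both series, the absolute error
#' `|lnP_der - lnP_obs|` per residue, its mean, and the squared Pearson
#' correlation between the series. Residues present in only one series
#' are dropped (their count is reported, not an error). Both inputs must
#' be in natural log; use [convert_log10_lnp()] for log10-reported data.
#'
#' @param derived,observed `"pf_set"` objects or named numeric vectors of
#'   ln P keyed by residue index.
#' @return An `"nmr_fit_report"`: list with `per_residue_error` (named),
#'   `mean_abs_error`, `r_squared` (NA, flagged, when either series has
#'   zero variance or fewer than 2 common residues), `r_sign` (sign of
#'   the Pearson correlation), `n`, and `n_dropped`.
#' @export
nmr_fit <- function(derived, observed) {
  d <- as_lnp_vector(derived)
  o <- as_lnp_vector(observed)
  common <- intersect(names(d), names(o))
  if (length(common) == 0) stop("no residue in common between the two series")
  err <- abs(d[common] - o[common])
  r2 <- NA_real_
  rs <- NA_real_
  if (length(common) >= 2 &&
      stats::sd(d[common]) > 0 && stats::sd(o[common]) > 0) {
    r <- stats::cor(d[common], o[common])
    r2 <- r^2
    rs <- sign(r)
  }
  structure(list(
    per_residue_error = err,
    mean_abs_error = mean(err),
    r_squared = r2,
    r_sign = rs,
    n = length(common),
    n_dropped = length(d) + length(o) - 2 * length(common)
  ), class = "nmr_fit_report")
}

#' Convert log10 protection factors to natural log
#'
#' Some HDX-NMR datasets report protection factors as log10 P rather than
#' ln P; everything internal to pfkit is natural log.
#'
#' @param x numeric vector of log10 P values.
#' @return `x * log(10)`.
#' @export
convert_log10_lnp <- function(x) x * log(10)

#' Compare derived and observed peptide uptake curves (HDX-MS)
#'
#' For every peptide present in both sets, computes the error
#' `sum over t of |D_der(t) - D_obs(t)|` on the shared experimental time
#' grid, and aggregates into an unweighted mean over peptides.
#'
#' @param derived,observed named lists of `"uptake_curve"` objects keyed
#'   by peptide id.
#' @return An `"ms_fit_report"`: list with `per_peptide_error` (named),
#'   `mean_error`, `n_peptides`, `n_dropped` and `times`.
#' @export
ms_fit <- function(derived, observed) {
  common <- intersect(names(derived), names(observed))
  if (length(common) == 0) stop("no peptide in common between the two sets")
  err <- vapply(common, function(id) {
    a <- derived[[id]]
    b <- observed[[id]]
    if (length(a$times) != length(b$times) ||
        any(abs(a$times - b$times) > 1e-9)) {
      stop("time-grid mismatch for peptide '", id, "'")
    }
    sum(abs(a$values - b$values))
  }, numeric(1))
  structure(list(
    per_peptide_error = err,
    mean_error = mean(err),
    n_peptides = length(common),
    n_dropped = length(derived) + length(observed) - 2 * length(common),
    times = derived[[common[1]]]$times
  ), class = "ms_fit_report")
}

# Aggregate fit score of one conformation against experimental data.
# NMR observations: named ln P vector / pf_set -> mean absolute error.
# MS observations: list(peptides = data.frame(id, start, end, sequence),
# curves = named list of uptake curves, rates = intrinsic_rates,
# times = shared grid) -> mean summed curve error.
conformation_score <- function(conf, experimental, params = model_params()) {
  pf <- protection_factors(place_amide_hydrogens(conf), params)
  if (is.numeric(experimental) || inherits(experimental, "pf_set")) {
    return(nmr_fit(pf, experimental)$mean_abs_error)
  }
  if (is.list(experimental) && !is.null(experimental$curves)) {
    der <- derive_peptide_curves(pf, experimental$peptides,
                                 experimental$rates, experimental$times)
    return(ms_fit(der, experimental$curves)$mean_error)
  }
  stop("unsupported experimental data type")
}

#' Derive peptide uptake curves from protection factors
#'
#' Runs the kinetics stage of the forward pipeline: residue uptake from
#' ln P and intrinsic rates, averaged into peptide curves.
#'
#' @param pf a `"pf_set"`.
#' @param peptides data frame with columns `id`, `start`, `end`,
#'   `sequence` (internal numbering).
#' @param rates an [intrinsic_rates()] vector (or any named numeric of
#'   1/min rates keyed by residue index).
#' @param times shared time grid, minutes.
#' @return Named list of `"uptake_curve"` objects keyed by peptide id.
#' @export
derive_peptide_curves <- function(pf, peptides, rates, times) {
  lnp <- as_lnp_vector(pf)
  res_idx <- intersect(names(lnp), names(rates))
  curves <- lapply(res_idx, function(i) {
    residue_uptake(lnp[[i]], rates[[i]], times)
  })
  names(curves) <- res_idx
  out <- lapply(seq_len(nrow(peptides)), function(k) {
    peptide_uptake(peptides$start[k], peptides$end[k], peptides$sequence[k],
                   curves)
  })
  names(out) <- peptides$id
  out
}

#' Select the conformation best fitting experimental HDX data
#'
#' Scores every member of an ensemble through the full forward pipeline
#' (protection factors, and for MS data the uptake kinetics) against the
#' experimental observations, and returns the minimizer. Ties are broken
#' toward the lowest index.
#'
#' @param ens an `"ensemble"`.
#' @param experimental named ln P vector / `"pf_set"` for HDX-NMR data,
#'   or a list with `peptides`, `curves`, `rates`, `times` for HDX-MS
#'   data (see [conformation_score()] internals via
#'   [derive_peptide_curves()]).
#' @param params a [model_params()] object.
#' @return A `"selection_result"`: list with `best_index`, `best_score`,
#'   `scores` (per-conformation) and `best` (the winning conformation).
#' @export
select_best <- function(ens, experimental, params = model_params()) {
  stopifnot(inherits(ens, "ensemble"))
  scores <- vapply(ens$conformations, conformation_score,
                   numeric(1), experimental = experimental, params = params)
  best <- which.min(scores)  # which.min returns the first minimum
  structure(list(
    best_index = best,
    best_score = scores[best],
    scores = scores,
    best = ens$conformations[[best]]
  ), class = "selection_result")
}

#' Read observed protection factors from CSV
#'
#' Expected columns: `residue` (author numbering), `value`, and
#' optionally `log_base` (`"ln"` or `"log10"`, default `"ln"`). Values
#' are converted to natural log and re-keyed to a conformation's internal
#' numbering when `conf` is given.
#'
#' @param path CSV file path.
#' @param conf optional `"conformation"` used to map author numbering to
#'   internal residue indices; unmatched residues are dropped with a
#'   warning.
#' @return Named numeric vector of ln P.
#' @export
read_observed_pf <- function(path, conf = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "value") %in% names(df)))
  v <- df$value
  if ("log_base" %in% names(df)) {
    is10 <- df$log_base == "log10"
    v[is10] <- convert_log10_lnp(v[is10])
  }
  names(v) <- df$residue
  if (!is.null(conf)) {
    idx <- match(as.integer(names(v)), conf$author_resno)
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " observed residue(s) not present in structure;",
              " dropped")
    }
    v <- v[!is.na(idx)]
    names(v) <- idx[!is.na(idx)]
  }
  v
}
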