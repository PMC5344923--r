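# Intrinsic amide exchange rates and deuterium-uptake kinetics.
#
# Intrinsic (unstructured-chain) rates follow the reference-parameter
# method of Bai, Milne, Mayne & Englander (1993, Proteins 17:75-86) with
# the poly-DL-alanine reference rates and nearest-neighbor inductive
# corrections: for the amide of residue i,
#
#   k_int = k_A * 10^(A_L(i) + A_R(i-1)) * 10^(-pD)
#         + k_B * 10^(B_L(i) + B_R(i-1)) * 10^(pD - pK_D)
#         + k_W * 10^(B_L(i) + B_R(i-1))
#
# with Arrhenius temperature scaling of the acid, base and water terms.
# Protonation of Asp/Glu/His side chains is treated as a step switch at
# the residue pKa (no titration-curve interpolation). Uptake then follows
# pseudo-first-order kinetics: d_i(t) = 1 - exp(-(k_int / P_i) * t).

# Nearest-neighbor inductive corrections, log10 units, D2O reference.
# Columns: acid left (residue's own amide), acid right (effect on the
# following residue's amide), base left, base right. Asp/Glu rows are the
# charged carboxylate forms; *_H rows the protonated forms; HIS_H is the
# protonated imidazolium form.
BAI_TABLE <- local({
  m <- rbind(
    A     = c( 0.00,  0.00,  0.00,  0.00),
    R     = c(-0.59, -0.32,  0.08,  0.22),
    N     = c(-0.58, -0.13,  0.49,  0.32),
    D     = c( 0.90,  0.58, -0.30, -0.18),
    D_H   = c(-0.90, -0.12,  0.69,  0.60),
    C     = c(-0.54, -0.46,  0.62,  0.55),
    Q     = c(-0.47, -0.27,  0.06,  0.20),
    E     = c(-0.90,  0.31, -0.51, -0.15),
    E_H   = c(-0.60, -0.27,  0.24,  0.39),
    G     = c(-0.22,  0.22,  0.27,  0.17),
    H     = c( 0.00,  0.00, -0.10,  0.14),
    H_H   = c(-0.80, -0.51,  0.80,  0.83),
    I     = c(-0.91, -0.59, -0.73, -0.23),
    L     = c(-0.57, -0.13, -0.58, -0.21),
    K     = c(-0.56, -0.29, -0.04,  0.12),
    M     = c(-0.64, -0.28, -0.01,  0.11),
    F     = c(-0.52, -0.43, -0.24,  0.06),
    P     = c( 0.00, -0.19,  0.00, -0.24),
    S     = c(-0.44, -0.39,  0.37,  0.30),
    T     = c(-0.79, -0.47, -0.07,  0.20),
    W     = c(-0.40, -0.44, -0.41, -0.11),
    Y     = c(-0.41, -0.37, -0.27,  0.05),
    V     = c(-0.74, -0.30, -0.70, -0.14),
    NTERM = c( 0.00, -1.32,  0.00,  1.62),
    CTERM = c( 0.96,  0.00, -1.80,  0.00)
  )
  colnames(m) <- c("AL", "AR", "BL", "BR")
  m
})

# Reference rates (poly-DL-alanine, D2O, 293 K): log10 of k_A (1/M/min),
# k_B (1/M/min), k_W (1/min); pK of D2O; activation energies kcal/mol.
BAI_REF <- list(lg_ka = 1.62, lg_kb = 10.05, lg_kw = -1.5, pKD = 15.05,
                Ea_acid = 14, Ea_base = 17, Ea_water = 19,
                Tref = 293, R = 1.9872e-3)

# Side-chain pKa switch points (D2O-adjusted) for charged-form selection.
SIDECHAIN_PKA <- c(D = 4.0, E = 4.9, H = 7.0)

bai_row <- function(aa, pH) {
  key <- aa
  if (aa %in% names(SIDECHAIN_PKA)) {
    protonated <- pH < SIDECHAIN_PKA[aa]
    if (aa == "H") key <- if (protonated) "H_H" else "H"
    else key <- if (protonated) paste0(aa, "_H") else aa
  }
  BAI_TABLE[key, ]
}

#' Intrinsic (unstructured-chain) amide exchange rates
#'
#' Predicts per-residue intrinsic exchange rates from sequence using the
#' poly-DL-alanine reference rates with nearest-neighbor inductive
#' corrections and Arrhenius temperature scaling. The N-terminal residue
#' and prolines carry no amide N-H and are omitted; the second residue
#' receives the N-terminal ammonium correction and the last residue the
#' carboxy-terminal correction.
#'
#' @param sequence one-letter amino-acid string.
#' @param pH solution pH (read as pD for D2O work); must lie in 0..14.
#' @param temperature temperature in Kelvin.
#' @return A named numeric vector of class `"intrinsic_rates"`: rates in
#'   1/min keyed by residue position, with `pH` and `temperature`
#'   attributes.
#' @export
intrinsic_rates <- function(sequence, pH = 7, temperature = 293) {
  stopifnot(nchar(sequence) >= 2, pH >= 0, pH <= 14,
            temperature > 250, temperature < 350)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% rownames(BAI_TABLE))
  if (length(bad) > 0) {
    stop("unknown residue letter '", aa[bad[1]], "' at position ", bad[1])
  }
  n <- length(aa)
  arr <- function(Ea) exp(-(Ea / BAI_REF$R) * (1 / temperature - 1 / BAI_REF$Tref))
  ka <- 10^BAI_REF$lg_ka * arr(BAI_REF$Ea_acid)
  kb <- 10^BAI_REF$lg_kb * arr(BAI_REF$Ea_base)
  kw <- 10^BAI_REF$lg_kw * arr(BAI_REF$Ea_water)

  out <- numeric(0)
  for (i in 2:n) {
    if (aa[i] == "P") next
    own <- bai_row(aa[i], pH)
    prev <- bai_row(aa[i - 1], pH)
    AL <- own["AL"] + prev["AR"]
    BL <- own["BL"] + prev["BR"]
    if (i == 2) {           # left neighbor is the N-terminal ammonium
      AL <- AL + BAI_TABLE["NTERM", "AR"]
      BL <- BL + BAI_TABLE["NTERM", "BR"]
    }
    if (i == n) {           # own residue carries the terminal carboxylate
      AL <- AL + BAI_TABLE["CTERM", "AL"]
      BL <- BL + BAI_TABLE["CTERM", "BL"]
    }
    k <- ka * 10^(AL - pH) +
      kb * 10^(BL + pH - BAI_REF$pKD) +
      kw * 10^BL
    out[as.character(i)] <- unname(k)
  }
  structure(out, class = "intrinsic_rates", pH = pH, temperature = temperature)
}

#' Residue-level deuterium uptake curve
#'
#' Pseudo-first-order exchange: `d(t) = 1 - exp(-(k_int / P) * t)` with
#' `P = exp(lnP)`.
#'
#' @param lnP natural-log protection factor.
#' @param k_int intrinsic exchange rate, 1/min.
#' @param times time points in minutes (non-negative, increasing).
#' @return An `"uptake_curve"`: list with `times` and `values` in `[0, 1]`.
#' @export
residue_uptake <- function(lnP, k_int, times) {
  if (!is.finite(lnP)) stop("lnP must be finite")
  if (!is.finite(k_int) || k_int <= 0) stop("k_int must be positive")
  stopifnot(all(times >= 0), !is.unsorted(times, strictly = FALSE))
  values <- 1 - exp(-(k_int / exp(lnP)) * times)
  structure(list(times = times, values = values), class = "uptake_curve")
}

#' Exchangeable positions of a proteolytic peptide
#'
#' Excludes the peptide's first residue (it becomes a free amine after
#' digestion), its second residue (rapid back-exchange), and every
#' proline (no amide N-H). The number of returned positions is the
#' normalizer n_j of the peptide-uptake average.
#'
#' @param start,end inclusive residue bounds (internal numbering).
#' @param sequence one-letter sequence of the peptide (`end - start + 1`
#'   characters).
#' @return Integer vector of residue indices; empty (with a warning) when
#'   no position survives the exclusions.
#' @export
exchangeable_positions <- function(start, end, sequence) {
  stopifnot(start >= 1, end >= start,
            nchar(sequence) == end - start + 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  pos <- seq(start, end)
  keep <- seq_along(pos) > 2 & aa != "P"
  out <- pos[keep]
  if (length(out) == 0) {
    warning("peptide ", start, "-", end,
            " has no exchangeable position; uptake undefined")
  }
  out
}

#' Peptide-level deuterium uptake curve
#'
#' Averages residue uptake over the peptide's exchangeable positions:
#' `D_j(t) = (1/n_j) * sum d_i(t)`.
#'
#' @param start,end,sequence peptide definition as in
#'   [exchangeable_positions()].
#' @param residue_curves named list of `"uptake_curve"` objects keyed by
#'   residue index, on a shared time grid.
#' @return An `"uptake_curve"` for the peptide.
#' @export
peptide_uptake <- function(start, end, sequence, residue_curves) {
  pos <- exchangeable_positions(start, end, sequence)
  if (length(pos) == 0) stop("peptide uptake undefined: no exchangeable position")
  missing <- setdiff(as.character(pos), names(residue_curves))
  if (length(missing) > 0) {
    stop("missing residue uptake curve(s) for position(s): ",
         paste(missing, collapse = ", "))
  }
  curves <- residue_curves[as.character(pos)]
  times <- curves[[1]]$times
  for (cv in curves) {
    if (length(cv$times) != length(times) || any(cv$times != times)) {
      stop("residue curves are not on a shared time grid")
    }
  }
  vals <- rowMeans(do.call(cbind, lapply(curves, function(cv) cv$values)))
  structure(list(times = times, values = vals), class = "uptake_curve")
}
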