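# Packaged experimental protection-factor tables (CI2, Im7) and synthetic
# structure/data generators. The generators build poly-alanine chains
# with ideal bond geometry directly in internal coordinates, so every
# pipeline stage can be exercised without external structure downloads.

DATASET_MD5 <- c(
  ci2 = "0df9df3e93401558fe692a151306bef8",
  im7 = "1dbcdb72ff7c57ab5d230eedd563c420"
)

#' Load a packaged HDX-NMR protection-factor table
#'
#' Two residue-level ln P tables ship with the package: `"ci2"` (14
#' residues of truncated chymotrypsin inhibitor 2, native state;
#' exchange rates from Itzhaki et al. 1995) and `"im7"` (26 residues of
#' the bacterial immunity protein Im7, folding-intermediate study;
#' exchange rates from Gorski et al. 2001). Values are stored verbatim in
#' author residue numbering and verified against a packaged checksum on
#' every load.
#'
#' @param name `"ci2"` or `"im7"` (case-insensitive).
#' @return A `"packaged_dataset"`: list with `name`, `residues` (data
#'   frame `residue`, `resname`, `value`, `log_base`), `note` (numbering
#'   metadata) and `provenance`.
#' @export
load_dataset <- function(name) {
  key <- tolower(name)
  if (!key %in% names(DATASET_MD5)) {
    stop("unknown dataset '", name, "'; packaged datasets: ",
         paste(names(DATASET_MD5), collapse = ", "))
  }
  path <- system.file("extdata", paste0(key, "_lnp.csv"), package = "pfkit",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (md5 != DATASET_MD5[[key]]) {
    stop("packaged dataset '", key, "' failed its checksum; installation ",
         "is corrupt")
  }
  lines <- readLines(path)
  note <- sub("^# *", "", grep("^#", lines, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(name = key, residues = df,
                 note = paste(note, collapse = " "),
                 provenance = if (key == "ci2") {
                   "Itzhaki, Neira & Fersht exchange-rate measurements"
                 } else {
                   "Gorski et al. folding-intermediate HDX-NMR study"
                 }),
            class = "packaged_dataset")
}

#' @export
print.packaged_dataset <- function(x, ...) {
  cat(sprintf("<packaged_dataset> %s: %d residues (%s)\n",
              x$name, nrow(x$residues), x$note))
  invisible(x)
}

# Poly-alanine chain built with ideal internal coordinates; CB placed by
# the standard tetrahedral construction from the backbone frame.
build_chain <- function(phi, psi, resnames, label) {
  n <- length(resnames)
  g <- IDEAL_GEOM
  a <- deg2rad(g$a_n_ca_c)
  bb <- vector("list", n)
  bb[[1]] <- list(N = c(0, 0, 0),
                  CA = c(g$b_n_ca, 0, 0),
                  C = c(g$b_n_ca, 0, 0) + g$b_ca_c * c(-cos(a), sin(a), 0))
  for (i in seq_len(n - 1)) {
    ps <- if (is.na(psi[i])) 180 else psi[i]
    Nn <- place_atom(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, g$b_c_n, g$a_ca_c_n, ps)
    CAn <- place_atom(bb[[i]]$CA, bb[[i]]$C, Nn, g$b_n_ca, g$a_c_n_ca, 180)
    Cn <- place_atom(bb[[i]]$C, Nn, CAn, g$b_ca_c, g$a_n_ca_c, phi[i + 1])
    bb[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  rows <- list()
  for (i in seq_len(n)) {
    ps <- if (is.na(psi[i])) 180 else psi[i]
    O <- place_atom(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, g$b_c_o, g$a_ca_c_o,
                    ps + 180)
    ats <- rbind(N = bb[[i]]$N, CA = bb[[i]]$CA, C = bb[[i]]$C, O = O)
    if (resnames[i] != "GLY") {
      b <- bb[[i]]$CA - bb[[i]]$N
      cc <- bb[[i]]$C - bb[[i]]$CA
      ax <- cross3(b, cc)
      CB <- bb[[i]]$CA - 0.58273431 * ax + 0.56802827 * b - 0.54067466 * cc
      ats <- rbind(ats, CB = CB)
    }
    rows[[i]] <- data.frame(resno = i, resid = resnames[i],
                            elety = rownames(ats),
                            x = ats[, 1], y = ats[, 2], z = ats[, 3],
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  place_amide_hydrogens(new_conformation(df, label = label))
}

#' Ideal alpha-helix test structure
#'
#' Poly-alanine with (phi, psi) = (-57, -47), ideal bond geometry and
#' amide hydrogens placed.
#'
#' @param n residue count (>= 4).
#' @return A `"conformation"`.
#' @export
make_ideal_helix <- function(n) {
  stopifnot(n >= 4)
  build_chain(phi = c(NA, rep(-57, n - 1)), psi = c(rep(-47, n - 1), NA),
              resnames = rep("ALA", n), label = sprintf("helix%d", n))
}

#' Fully extended poly-alanine test structure
#'
#' (phi, psi) = (180, 180): no acceptor oxygen approaches any amide
#' hydrogen, so all hydrogen-bond counts are zero by construction.
#'
#' @param n residue count (>= 4).
#' @return A `"conformation"`.
#' @export
make_extended_chain <- function(n) {
  stopifnot(n >= 4)
  build_chain(phi = c(NA, rep(180, n - 1)), psi = c(rep(180, n - 1), NA),
              resnames = rep("ALA", n), label = sprintf("extended%d", n))
}

# Random-coil poly-alanine: uniform phi in (-180, -30), psi in (-90, 180),
# loosely mimicking allowed coil space; used by oracle-equivalence tests.
random_coil <- function(n, label = "coil") {
  phi <- c(NA, stats::runif(n - 1, -180, -30))
  psi <- c(stats::runif(n - 1, -90, 180), NA)
  build_chain(phi, psi, rep("ALA", n), label)
}

#' Synthesize observed-style HDX data from a known conformation
#'
#' Runs the forward pipeline on `conf` and adds Gaussian noise, producing
#' data in the same shape as real experimental input. Used for
#' closed-loop and parameter-recovery testing: with `noise_sigma = 0`
#' the generating conformation scores exactly zero against its own
#' synthesized data.
#'
#' @param conf a `"conformation"` (amide hydrogens are placed if absent).
#' @param mode `"nmr"` (per-residue ln P) or `"ms"` (peptide uptake
#'   curves).
#' @param noise_sigma Gaussian noise sd (ln P units for NMR, uptake
#'   fraction for MS; MS values are clipped back to `[0, 1]`).
#' @param seed RNG seed; the output is deterministic given the seed.
#' @param params a [model_params()].
#' @param peptides,rates,times MS mode only: peptide table (`id`,
#'   `start`, `end`, `sequence`), intrinsic rates, and time grid
#'   (minutes).
#' @param path optional CSV output path (observed-data schema, author
#'   numbering for NMR).
#' @return For NMR, a named ln P vector keyed by internal residue index;
#'   for MS, a named list of `"uptake_curve"` objects keyed by peptide
#'   id.
#' @export
synthesize_observation <- function(conf, mode = c("nmr", "ms"),
                                   noise_sigma = 0, seed = 1,
                                   params = model_params(),
                                   peptides = NULL, rates = NULL,
                                   times = NULL, path = NULL) {
  mode <- match.arg(mode)
  stopifnot(noise_sigma >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  pf <- protection_factors(place_amide_hydrogens(conf), params)
  if (mode == "nmr") {
    obs <- pf$lnP + stats::rnorm(length(pf$lnP), 0, noise_sigma)
    if (!is.null(path)) {
      idx <- as.integer(names(obs))
      utils::write.csv(data.frame(residue = conf$author_resno[idx],
                                  value = signif(obs, 6), log_base = "ln"),
                       path, row.names = FALSE)
    }
    return(obs)
  }
  stopifnot(!is.null(peptides), !is.null(rates), !is.null(times))
  curves <- derive_peptide_curves(pf, peptides, rates, times)
  curves <- lapply(curves, function(cv) {
    cv$values <- pmin(1, pmax(0, cv$values +
                                stats::rnorm(length(cv$values), 0, noise_sigma)))
    cv
  })
  if (!is.null(path)) {
    df <- do.call(rbind, lapply(names(curves), function(id) {
      k <- match(id, peptides$id)
      data.frame(peptide_id = id, start = peptides$start[k],
                 end = peptides$end[k], sequence = peptides$sequence[k],
                 time_min = curves[[id]]$times,
                 uptake_frac = signif(curves[[id]]$values, 6))
    }))
    utils::write.csv(df, path, row.names = FALSE)
  }
  curves
}
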