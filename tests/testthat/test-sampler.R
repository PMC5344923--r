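test_that("dihedral extraction reads back the construction angles", {
  h <- make_ideal_helix(10)
  dv <- extract_dihedrals(h)
  expect_true(all(abs(dv$phi[2:10] + 57) < 1))
  expect_true(all(abs(dv$psi[1:9] + 47) < 1))
  expect_true(is.na(dv$phi[1]))
  expect_true(is.na(dv$psi[10]))

  ext <- make_extended_chain(8)
  dve <- extract_dihedrals(ext)
  expect_true(all(abs(abs(dve$phi[-1]) - 180) < 1))
  expect_true(all(abs(abs(dve$psi[-8]) - 180) < 1))
})

test_that("extract/rebuild round-trips ideal-geometry fixtures", {
  for (conf in list(make_ideal_helix(12), make_extended_chain(9))) {
    dv <- extract_dihedrals(conf)
    back <- rebuild_conformation(dv, conf)
    dev <- max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                     as.matrix(conf$atoms[, c("x", "y", "z")])))
    expect_lt(dev, 1e-3)
  }
  dv <- extract_dihedrals(make_ideal_helix(12))
  expect_error(rebuild_conformation(dv, make_ideal_helix(11)), "length")
})

test_that("rebuilding an all-helical dihedral vector yields helical rise", {
  ext <- make_extended_chain(15)
  dv <- extract_dihedrals(ext)
  dv$phi[-1] <- -57
  dv$psi[-15] <- -47
  helixed <- rebuild_conformation(dv, ext)
  ca <- t(vapply(1:15, function(i) pfkit:::atom_coord(helixed, i, "CA"),
                 numeric(3)))
  axis <- prcomp(ca)$rotation[, 1]
  rise <- abs(mean(diff(ca %*% axis)))
  expect_gt(rise, 1.4)
  expect_lt(rise, 1.6)
})

test_that("dihedral perturbations are strictly downstream", {
  h <- make_ideal_helix(10)
  mod <- pfkit:::apply_dihedral_delta(h, 5, "psi", 180)
  dev <- abs(as.matrix(mod$atoms[, c("x", "y", "z")]) -
               as.matrix(h$atoms[, c("x", "y", "z")]))
  per_res <- tapply(rowSums(dev), mod$atoms$resno, max)
  expect_true(all(per_res[as.character(1:4)] == 0))
  # residue 5: only its carbonyl O moves under a psi rotation
  r5 <- which(h$atoms$resno == 5)
  moved5 <- rowSums(dev[r5, , drop = FALSE]) > 1e-12
  expect_equal(h$atoms$elety[r5][moved5], "O")
  expect_true(all(per_res[as.character(6:10)] > 0.1))

  cfg1 <- sampler_config(n_conformations = 1, perturbation_sigma = 8,
                         fragments = list(fragment("f5", 5)), seed = 1)
  set.seed(2)
  m <- propose_move(h, cfg1)
  dev2 <- abs(as.matrix(m$atoms[, c("x", "y", "z")]) -
                as.matrix(h$atoms[, c("x", "y", "z")]))
  expect_true(all(dev2[m$atoms$resno < 5, ] == 0))
  expect_equal(attr(m, "fragment"), "f5")

  # continuity: a vanishing step size leaves the structure unchanged
  cfg0 <- sampler_config(n_conformations = 1, perturbation_sigma = 1e-9,
                         fragments = list(fragment("all", 1:10)), seed = 1)
  set.seed(3)
  m0 <- propose_move(h, cfg0)
  expect_lt(max(abs(as.matrix(m0$atoms[, c("x", "y", "z")]) -
                      as.matrix(h$atoms[, c("x", "y", "z")]))), 1e-6)
})

test_that("clash score penalizes soft-sphere overlap quadratically", {
  expect_equal(clash_score(make_ideal_helix(12)), 0)
  # two heavy atoms at 2.0 A, three residues apart: (3 - 2)^2 = 1
  conf <- sparse_conformation(3, NULL)
  conf$atoms$x <- c(0, 500, 2)   # N atoms of residues 1, 2, 3
  expect_equal(clash_score(conf), 1)
  # adjacent-residue pairs are not penalized
  conf2 <- sparse_conformation(2, NULL)
  conf2$atoms$x <- c(0, 1)
  expect_equal(clash_score(conf2), 0)

  # brute-force oracle on a compact decoy
  set.seed(14)
  decoy <- pfkit:::random_coil(20)
  hv <- pfkit:::heavy_coords(decoy)
  acc <- 0
  for (a in seq_len(nrow(hv$xyz) - 1)) {
    for (b in (a + 1):nrow(hv$xyz)) {
      if (abs(hv$resno[a] - hv$resno[b]) < 2) next
      d <- sqrt(sum((hv$xyz[a, ] - hv$xyz[b, ])^2))
      if (d < 3) acc <- acc + (3 - d)^2
    }
  }
  expect_equal(clash_score(decoy), acc)
})

test_that("fragment selection follows the configured weights", {
  frags <- list(fragment("A", 1:3, weight = 3), fragment("B", 4:6, weight = 1))
  set.seed(101)
  draws <- replicate(10000, pfkit:::draw_fragment(frags))
  expect_lt(abs(mean(draws == 1) - 0.75), 0.02)

  # chi-square goodness of fit for a 4-fragment weight vector
  frags4 <- list(fragment("a", 1, weight = 1), fragment("b", 2, weight = 2),
                 fragment("c", 3, weight = 3), fragment("d", 4, weight = 4))
  set.seed(102)
  draws4 <- replicate(10000, pfkit:::draw_fragment(frags4))
  tab <- tabulate(draws4, 4)
  pval <- stats::chisq.test(tab, p = (1:4) / 10)$p.value
  expect_gt(pval, 0.01)

  expect_error(pfkit:::draw_fragment(list(fragment("z", 1, weight = 0))),
               "zero")
})

test_that("exploration is threshold-respecting and seed-deterministic", {
  start <- make_ideal_helix(10)
  frags <- default_fragments(10)
  cfg <- sampler_config(n_conformations = 5, perturbation_sigma = 6,
                        energy_threshold = Inf, fragments = frags, seed = 42)
  ens <- explore(start, cfg)
  expect_length(ens$conformations, 5)

  cfg_fin <- sampler_config(n_conformations = 8, perturbation_sigma = 6,
                            energy_threshold = 0.5, fragments = frags,
                            seed = 42)
  ens_fin <- explore(start, cfg_fin)
  expect_true(all(vapply(ens_fin$conformations, clash_score,
                         numeric(1)) <= 0.5))

  same <- explore(start, cfg)
  for (k in 1:5) {
    expect_identical(same$conformations[[k]]$atoms,
                     ens$conformations[[k]]$atoms)
  }
  cfg2 <- cfg
  cfg2$seed <- 43L
  other <- explore(start, cfg2)
  expect_gt(max(abs(as.matrix(other$conformations[[1]]$atoms[, c("x", "y", "z")]) -
                      as.matrix(ens$conformations[[1]]$atoms[, c("x", "y", "z")]))),
            1e-6)

  # a tiny step size from a clash-free start stays near the start
  cfg_tiny <- sampler_config(n_conformations = 3, perturbation_sigma = 0.01,
                             energy_threshold = 0, fragments = frags,
                             seed = 7)
  near <- explore(start, cfg_tiny)
  for (cf in near$conformations) {
    rmsd <- sqrt(mean((backbone_xyz(cf) - backbone_xyz(start))^2))
    expect_lt(rmsd, 0.1)
  }

  # an impossible acceptance bound errors out with advice
  cfg_bad <- sampler_config(n_conformations = 2, perturbation_sigma = 6,
                            energy_threshold = -1, fragments = frags,
                            seed = 1, max_attempts_per_accept = 3)
  expect_error(explore(start, cfg_bad), "no conformation accepted")
})

test_that("discrepancy weighting boosts the most discordant fragments", {
  frags <- lapply(1:4, function(k) fragment(paste0("F", k), ((k - 1) * 5 + 1):(k * 5)))
  mk_report <- function(err) {
    structure(list(per_residue_error = err), class = "nmr_fit_report")
  }
  # uniform errors: every fragment is boosted, weights renormalize equal
  uni <- discrepancy_weights(mk_report(setNames(rep(1, 20), 1:20)), frags)
  expect_equal(vapply(uni, function(f) f$weight, numeric(1)), rep(0.25, 4))

  # all error in fragment 2: its weight becomes boost / (boost + k - 1)
  err <- setNames(rep(0, 20), 1:20)
  err[6:10] <- 2
  one <- discrepancy_weights(mk_report(err), frags, boost = 4)
  w <- vapply(one, function(f) f$weight, numeric(1))
  expect_equal(w[2], 4 / (4 + 3))
  expect_equal(w[-2], rep(1 / 7, 3))

  # the boosted set matches an independent sort of fragment discrepancies
  set.seed(66)
  err2 <- setNames(runif(20), 1:20)
  out <- discrepancy_weights(mk_report(err2), frags, boost = 4)
  disc <- vapply(frags, function(f) mean(err2[as.character(f$residues)]),
                 numeric(1))
  top <- which(disc >= sort(disc, decreasing = TRUE)[1])  # 4 frags: top quartile = max
  w2 <- vapply(out, function(f) f$weight, numeric(1))
  expect_equal(which(w2 == max(w2)), top)
  expect_equal(sum(w2), 1)

  expect_error(discrepancy_weights(mk_report(c(`99` = 1)), frags),
               "no overlap")
})

test_that("refinement stops at a planted optimum and never backtracks", {
  start <- make_ideal_helix(12)
  frags <- default_fragments(12)
  obs_self <- synthesize_observation(start, "nmr", noise_sigma = 0)
  cfg <- sampler_config(n_conformations = 5, perturbation_sigma = 6,
                        energy_threshold = Inf, fragments = frags, seed = 5)
  res <- iterate_refine(start, obs_self, cfg, n_rounds = 4)
  expect_equal(res$best_score, 0)
  expect_equal(nrow(res$trace), 1)   # early stop after round 1

  obs_noisy <- synthesize_observation(start, "nmr", noise_sigma = 1, seed = 2)
  res2 <- iterate_refine(start, obs_noisy, cfg, n_rounds = 3, stop_score = -1)
  expect_equal(nrow(res2$trace), 3)
  expect_true(all(diff(res2$trace$best_score) <= 0))
  expect_lte(res2$best_score, res2$start_score)
})
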