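test_that("hydrogen-bond counting honors cutoff and sequence exclusion", {
  p <- model_params()
  h4 <- c(0, 0, 0)
  # acceptor O in residue 1 (separation 3) at 2.0 A -> counted
  conf <- sparse_conformation(
    7, data.frame(resno = 1, elety = "O", x = 2, y = 0, z = 0),
    amide_h = list("4" = h4))
  expect_equal(count_amide_hbonds(conf, 4, p), 1)
  expect_equal(count_heavy_contacts(conf, 4, p), 1)  # the O is also a contact

  # same geometry but the O belongs to residue i+2 -> excluded
  conf2 <- sparse_conformation(
    7, data.frame(resno = 6, elety = "O", x = 2, y = 0, z = 0),
    amide_h = list("4" = h4))
  expect_equal(count_amide_hbonds(conf2, 4, p), 0)
  expect_equal(count_heavy_contacts(conf2, 4, p), 0)

  # O beyond the 2.4 A cutoff -> no bond (but still a 6.5 A contact)
  conf3 <- sparse_conformation(
    7, data.frame(resno = 1, elety = "O", x = 2.5, y = 0, z = 0),
    amide_h = list("4" = h4))
  expect_equal(count_amide_hbonds(conf3, 4, p), 0)
  expect_equal(count_heavy_contacts(conf3, 4, p), 1)

  # boundary convention: distances exactly at the cutoff count
  conf4 <- sparse_conformation(
    7, data.frame(resno = 1, elety = "O", x = 2.4, y = 0, z = 0),
    amide_h = list("4" = h4))
  expect_equal(count_amide_hbonds(conf4, 4, p), 1)

  # side-chain oxygens are not acceptors; OXT is not a main-chain O
  conf5 <- sparse_conformation(
    7, data.frame(resno = c(1, 1), elety = c("OD1", "OXT"),
                  x = c(2, 2), y = c(0, 0.1), z = 0),
    amide_h = list("4" = h4))
  expect_equal(count_amide_hbonds(conf5, 4, p), 0)
  expect_equal(count_heavy_contacts(conf5, 4, p), 2)

  # residues without an amide hydrogen raise an error
  expect_error(count_amide_hbonds(conf, 1, p), "no amide hydrogen")
})

test_that("contact counting matches a constructed count", {
  h4 <- c(0, 0, 0)
  ring <- data.frame(resno = 9, elety = paste0("C", 1:10),
                     x = 3 * cos(seq_len(10)), y = 3 * sin(seq_len(10)),
                     z = 0)
  far <- data.frame(resno = 9, elety = "CZ", x = 50, y = 0, z = 0)
  conf <- sparse_conformation(12, rbind(ring, far),
                              amide_h = list("4" = h4))
  # base N atoms of residues outside the window sit at x = 1000*i: far away
  expect_equal(count_heavy_contacts(conf, 4, model_params()), 10)
})

test_that("both counters agree with a brute-force all-pairs oracle", {
  p <- model_params()
  set.seed(202)
  for (k in 1:15) {
    conf <- pfkit:::random_coil(30, label = paste0("coil", k))
    for (i in which(stats::complete.cases(conf$amide_h))) {
      oracle <- brute_force_counts(conf, i)
      expect_identical(as.integer(count_amide_hbonds(conf, i, p)),
                       as.integer(oracle["nh"]))
      expect_identical(as.integer(count_heavy_contacts(conf, i, p)),
                       as.integer(oracle["nc"]))
    }
  }
})

test_that("counts are invariant under rigid motion and atom order", {
  p <- model_params()
  set.seed(7)
  conf <- pfkit:::random_coil(20)
  idx <- which(stats::complete.cases(conf$amide_h))
  base_h <- vapply(idx, count_amide_hbonds, numeric(1), conf = conf, params = p)
  base_c <- vapply(idx, count_heavy_contacts, numeric(1), conf = conf, params = p)

  moved <- random_rigid_transform(conf, seed = 5)
  expect_equal(vapply(idx, count_amide_hbonds, numeric(1), conf = moved,
                      params = p), base_h)
  expect_equal(vapply(idx, count_heavy_contacts, numeric(1), conf = moved,
                      params = p), base_c)

  perm <- conf
  set.seed(8)
  perm$atoms <- perm$atoms[sample.int(nrow(perm$atoms)), ]
  expect_equal(vapply(idx, count_amide_hbonds, numeric(1), conf = perm,
                      params = p), base_h)
  expect_equal(vapply(idx, count_heavy_contacts, numeric(1), conf = perm,
                      params = p), base_c)
})

test_that("counts grow monotonically with their cutoffs", {
  set.seed(31)
  conf <- pfkit:::random_coil(25)
  idx <- which(stats::complete.cases(conf$amide_h))
  cuts <- c(2, 4, 6.5, 9)
  for (i in idx) {
    nh <- vapply(cuts, function(cc) {
      count_amide_hbonds(conf, i, model_params(hbond_cutoff = cc))
    }, numeric(1))
    nc <- vapply(cuts, function(cc) {
      count_heavy_contacts(conf, i, model_params(contact_cutoff = cc))
    }, numeric(1))
    expect_true(all(diff(nh) >= 0))
    expect_true(all(diff(nc) >= 0))
  }
})

test_that("the protection-factor expression is linear in the counts", {
  p <- model_params()
  expect_equal(lnp_from_counts(1, 0, p), 2)
  expect_equal(lnp_from_counts(0, 1, p), 0.35)
  expect_equal(lnp_from_counts(1, 10, p), 5.5)
  expect_equal(lnp_from_counts(3, 4, p) - lnp_from_counts(2, 4, p), p$beta_h)
  expect_equal(lnp_from_counts(2, 5, p) - lnp_from_counts(2, 4, p), p$beta_c)
  expect_error(lnp_from_counts(-1, 0, p))

  pf <- protection_factors(make_ideal_helix(12))
  expect_equal(unname(pf$lnP),
               2 * pf$counts$n_hbonds + 0.35 * pf$counts$n_contacts)
  expect_true(all(pf$lnP >= 0))
  expect_false("1" %in% names(pf$lnP))  # N-terminus absent
})

test_that("ensemble averaging equals the member-wise mean of ln P", {
  set.seed(77)
  members <- lapply(1:5, function(k) pfkit:::random_coil(15, paste0("m", k)))
  ens <- new_ensemble(members, source = "random")
  avg <- ensemble_protection_factors(ens)
  per <- lapply(members, protection_factors)
  manual <- rowMeans(do.call(cbind, lapply(per, function(p) p$lnP)))
  expect_equal(avg$lnP, manual[names(avg$lnP)])

  # an ensemble of identical members reduces to the single-model result
  same <- new_ensemble(list(members[[1]], members[[1]], members[[1]]))
  expect_equal(ensemble_protection_factors(same)$lnP,
               protection_factors(members[[1]])$lnP)

  # two-member arithmetic mean
  two <- new_ensemble(members[1:2])
  expect_equal(ensemble_protection_factors(two)$lnP,
               (per[[1]]$lnP + per[[2]]$lnP) / 2)
})
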