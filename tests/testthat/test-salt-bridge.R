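test_that("mode rules agree with the brute-force oracle over all 64 contact patterns", {
  combos <- expand.grid(NE_O1 = c(FALSE, TRUE), NE_O2 = c(FALSE, TRUE),
                        NH1_O1 = c(FALSE, TRUE), NH1_O2 = c(FALSE, TRUE),
                        NH2_O1 = c(FALSE, TRUE), NH2_O2 = c(FALSE, TRUE))
  got <- absalt:::.mode_from_contacts(combos$NE_O1, combos$NE_O2,
                                      combos$NH1_O1, combos$NH1_O2,
                                      combos$NH2_O1, combos$NH2_O2)
  want <- vapply(seq_len(nrow(combos)), function(i) {
    oracle_mode(as.list(combos[i, ]))
  }, character(1))
  expect_identical(got, want)
})

test_that("forced geometries classify as expected", {
  gdm <- make_gdm()
  # NH1-O1 and NH2-O2 at 2.8 A, NE far: side-on
  nh1 <- c(1.33 * cos(pi / 3), 1.33 * sin(pi / 3), 0)
  nh2 <- c(1.33 * cos(pi / 3), -1.33 * sin(pi / 3), 0)
  side <- classify_mode(gdm, make_carb(nh1 + c(2.8, 0, 0), nh2 + c(2.8, 0, 0)))
  expect_identical(side$mode, "side_on")
  expect_gte(nrow(side$contacts), 2)
  expect_identical(sort(unique(side$contacts$acceptor_atom)), c("O1", "O2"))

  # only NH1-O1 = 3.0 A within cutoff: backside (monodentate)
  back <- classify_mode(gdm, make_carb(nh1 + c(0, 3.0, 0), nh1 + c(0, 5.2, 0)))
  expect_identical(back$mode, "backside")

  # NE and NH1 on distinct oxygens: end-on
  ne <- c(-1.33, 0, 0)
  endon <- classify_mode(gdm, make_carb(ne + c(0, 0, 2.9), nh1 + c(0, 0, 2.9)))
  expect_identical(endon$mode, "end_on")

  # all N...O beyond cutoff: none
  none <- classify_mode(gdm, make_carb(c(10, 0, 0), c(12, 0, 0)))
  expect_identical(none$mode, "none")
  expect_identical(nrow(none$contacts), 0L)

  # two nitrogens sharing one oxygen is monodentate toward that oxygen
  shared <- classify_mode(gdm, make_carb(c(1.33 * cos(pi / 3) + 2, 0, 0),
                                         c(1.33 * cos(pi / 3) + 10, 0, 0)))
  expect_identical(shared$mode, "backside")

  expect_error(classify_mode(gdm, make_carb(c(3, 0, 0), c(5, 0, 0)),
                             cutoff = 0), "positive")
})

test_that("classification is invariant under rigid motion and oxygen label swap", {
  set.seed(11)
  gdm <- make_gdm()
  carbs <- list(
    side = make_carb(c(3.56, 1.10, 0), c(3.56, -1.10, 0)),
    back = make_carb(c(-4.2, 0, 0), c(-6.3, 0.5, 0)),
    none = make_carb(c(8, 8, 8), c(9, 9, 9))
  )
  for (carb in carbs) {
    ref <- classify_mode(gdm, carb)$mode
    for (i in 1:10) {
      R <- random_rotation_matrix()
      t <- rnorm(3, 0, 20)
      expect_identical(classify_mode(apply_rigid(gdm, R, t),
                                     apply_rigid(carb, R, t))$mode, ref)
    }
    swapped <- carb
    swapped[, c("O1_x", "O1_y", "O1_z", "O2_x", "O2_y", "O2_z")] <-
      carb[, c("O2_x", "O2_y", "O2_z", "O1_x", "O1_y", "O1_z")]
    expect_identical(classify_mode(gdm, swapped)$mode, ref)
  }
})

test_that("enlarging the cutoff never turns a mode into none", {
  set.seed(23)
  gdm <- make_gdm()
  for (i in 1:50) {
    carb <- make_carb(rnorm(3, 0, 3), rnorm(3, 0, 3) + c(2.2, 0, 0))
    m1 <- classify_mode(gdm, carb, cutoff = 3.0)$mode
    m2 <- classify_mode(gdm, carb, cutoff = 4.0)$mode
    if (m1 != "none") expect_true(m2 != "none")
  }
})

test_that("group extraction finds the amyloid-beta guanidinium and carboxylates", {
  ens <- gen_ensemble(1, seed = 5)
  groups <- extract_groups(ens[ens$conformer_id == 1, ])
  expect_identical(groups$guanidinium$residue_index, 5L)
  expect_identical(groups$carboxylate$residue_index,
                   c(1L, 3L, 7L, 11L, 22L, 23L))
  expect_identical(
    groups$carboxylate$residue_name[groups$carboxylate$residue_index %in% c(1, 7, 23)],
    rep("ASP", 3)
  )

  # no Arg -> empty guanidinium list
  no_arg <- ens[ens$conformer_id == 1 & ens$residue_name != "ARG", ]
  expect_identical(nrow(extract_groups(no_arg)$guanidinium), 0L)

  # Arg missing NH2 is skipped with a warning
  broken <- ens[!(ens$conformer_id == 1 & ens$atom_name == "NH2"), ]
  expect_warning(g <- extract_groups(broken[broken$conformer_id == 1, ]),
                 "ARG")
  expect_identical(nrow(g$guanidinium), 0L)
})

test_that("ensemble scan counts planted bridges exactly on a tiny ensemble", {
  ens <- make_tiny_ensemble(10, bridged = c(2, 5, 9))
  scan <- scan_ensemble(ens)
  occ <- bridge_occupancy(scan)
  row <- occ[occ$acceptor == 7, ]
  expect_equal(row$occupancy, 0.3)
  expect_equal(row$f_side_on, 0.3)
  expect_equal(row$f_end_on + row$f_backside, 0)

  # no qualifying contacts anywhere
  empty <- scan_ensemble(make_tiny_ensemble(5))
  expect_true(all(bridge_occupancy(empty)$occupancy == 0))

  expect_error(scan_ensemble(ens[0, ]), "empty ensemble")
})

test_that("mode fractions decompose occupancy into bidentate and monodentate parts", {
  ens <- gen_ensemble(300, seed = 9,
                      bridges = tibble::tibble(
                        acceptor = c(7L, 3L), mode = c("side_on", "backside"),
                        occupancy = c(0.3, 0.2)),
                      double_bridge = NULL)
  occ <- bridge_occupancy(scan_ensemble(ens))
  expect_equal(occ$occupancy, occ$f_side_on + occ$f_end_on + occ$f_backside,
               tolerance = 1e-12)
  bidentate <- occ$f_side_on + occ$f_end_on
  expect_true(all(occ$f_backside + bidentate == occ$occupancy))
  # backside-planted pair shows only monodentate fractions
  expect_equal(occ$f_side_on[occ$acceptor == 3], 0)
  expect_gt(occ$f_backside[occ$acceptor == 3], 0)
})

test_that("simultaneous bridging counts conformers bridging every acceptor", {
  ens <- make_tiny_ensemble(10, bridged = c(1, 4))
  scan <- scan_ensemble(ens)
  # single acceptor pair in this fixture; ask for an unknown acceptor
  expect_error(simultaneous_bridging(scan, 5, c(7, 9)), "not scanned")
  expect_error(simultaneous_bridging(scan, 5, 7), "at least 2")

  ens2 <- gen_ensemble(200, seed = 31,
                       bridges = tibble::tibble(
                         acceptor = c(7L, 3L), mode = "side_on",
                         occupancy = c(0.3, 0.3)),
                       double_bridge = list(acceptors = c(3, 7),
                                            fraction = 0.005,
                                            modes = c("backside", "side_on")))
  scan2 <- scan_ensemble(ens2)
  tr <- attr(ens2, "truth")$bridges
  truth_both <- tr |>
    dplyr::filter(acceptor %in% c(3, 7)) |>
    dplyr::count(conformer_id) |>
    dplyr::filter(n == 2) |>
    nrow()
  got <- simultaneous_bridging(scan2, 5, c(3, 7))
  expect_equal(got$n_bridging, truth_both)
  # set inclusion: joint fraction cannot exceed either marginal
  occ2 <- bridge_occupancy(scan2)
  expect_lte(got$fraction, min(occ2$occupancy[occ2$acceptor %in% c(3, 7)]))
})

test_that("conditional C-alpha distances split the ensemble by bridge presence", {
  # degenerate ensemble: all conformers identical -> sd 0 on the non-empty side
  ens <- make_tiny_ensemble(4, bridged = 1:4)
  scan <- scan_ensemble(ens)
  cd <- conditional_ca_distance(ens, scan,
                                data.frame(donor = 5, acceptor = 7), c(3, 8))
  expect_equal(cd$n_with, 4L)
  expect_equal(cd$sd_with, 0)
  expect_identical(cd$n_without, 0L)
  expect_true(is.na(cd$mean_without))
  expect_equal(cd$mean_with, 5 * 3.8 / 10, tolerance = 1e-9)

  # partition equals an independent per-conformer reclassification
  ens2 <- gen_ensemble(150, seed = 13)
  scan2 <- scan_ensemble(ens2)
  spec <- data.frame(donor = 5, acceptor = c(3, 7))
  cd2 <- conditional_ca_distance(ens2, scan2, spec, c(3, 8))
  manual_bridged <- vapply(sort(unique(ens2$conformer_id)), function(cf) {
    g <- extract_groups(ens2[ens2$conformer_id == cf, ])
    any(vapply(c(3L, 7L), function(a) {
      carb <- g$carboxylate[g$carboxylate$residue_index == a, ]
      classify_mode(g$guanidinium, carb)$mode != "none"
    }, logical(1)))
  }, logical(1))
  expect_identical(cd2$n_with, sum(manual_bridged))
  expect_identical(cd2$n_without, sum(!manual_bridged))
})

test_that("occupancy estimates converge to the planted rate with ensemble size", {
  for (n in c(500, 5000)) {
    ens <- gen_ensemble(n, seed = 100 + n)
    occ <- bridge_occupancy(scan_ensemble(ens))
    p <- occ$occupancy[occ$acceptor == 7]
    expect_lt(abs(p - 0.14), 2 * sqrt(0.14 * 0.86 / n) + 1e-12)
  }
})
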