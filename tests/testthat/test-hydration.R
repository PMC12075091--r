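test_that("RDF localizes an isolated pair and honours periodic images", {
  # two fixed atoms at distance d: g is zero except the bin containing d
  atoms <- data.frame(id = 1:2, element = c("S", "O"),
                      role = c("sulfur", "water_oxygen"), mol = 1:2)
  top <- topology(atoms, data.frame(atom1 = integer(), atom2 = integer()))
  box <- c(20, 20, 20)
  co <- array(0, c(2, 3, 1))
  co[1, , 1] <- c(10, 10, 10); co[2, , 1] <- c(13.25, 10, 10)
  r <- compute_rdf(trajectory(co, box, top), bin_width = 0.5)
  expect_true(all(r$g[r$r != 3.25] == 0))
  expect_gt(r$g[r$r == 3.25], 0)

  # atoms straddling the boundary: minimum image distance 3, not box - 3
  co2 <- array(0, c(2, 3, 1))
  co2[1, , 1] <- c(1, 10, 10); co2[2, , 1] <- c(18, 10, 10)
  r2 <- compute_rdf(trajectory(co2, box, top), bin_width = 0.5)
  expect_gt(r2$g[r2$r == 2.75], 0)  # bin (2.5, 3]
  expect_true(all(r2$g[r2$r > 3.5] == 0))

  expect_error(compute_rdf(trajectory(co, box, top), r_max = 11),
               "half the smallest box edge")
  expect_error(compute_rdf(trajectory(co, box, top),
                           reference_role = "other"), "no atoms")
})

test_that("ideal-gas RDF is flat at unity", {
  ig <- ideal_gas_frames(400L, c(30, 30, 30), 600L, seed = 3L)
  r <- compute_rdf(ig, bin_width = 0.1)
  expect_lt(mean(abs(r$g[r$r >= 3] - 1)), 0.05)
  # and its coordination number is the analytic sphere count
  expect_equal(coordination_number(r, 6),
               400 / 27000 * 4 / 3 * pi * 216, tolerance = 0.05)
})

test_that("first_peak finds constructed shells and rejects flat profiles", {
  mk_profile <- function(g, bw = 0.1) {
    structure(list(r = bw * (seq_along(g) - 0.5), g = g, bin_width = bw,
                   r_max = bw * length(g), rho = 0.01, n_frames = 1L,
                   reference = "sulfur", target = "water_oxygen",
                   n_ref = 1L, n_target = 1L),
              class = "rdf_profile")
  }
  r <- seq(0.05, 10, 0.1)
  bump <- 1 + 1.5 * exp(-0.5 * ((r - 3.8) / 0.3)^2)
  pk <- first_peak(mk_profile(bump))
  expect_equal(pk$r_peak, 3.8, tolerance = 0.1 + 1e-9)
  mono <- rev(seq(0.1, 3, length.out = length(r)))
  expect_error(first_peak(mk_profile(mono)), "no local maximum")

  # a generated thiol run has its shell where the schedule puts it
  gen <- generate_solvation_trajectory("thiol", n_waters = 60L,
                                       n_frames = 400L, seed = 21L)
  rt <- compute_rdf(gen$trajectory, bin_width = 0.1)
  pk2 <- first_peak(rt)
  expect_gte(pk2$r_peak, 3.0)
  expect_lte(pk2$r_peak, 3.8)
})

test_that("coordination number integrates to the direct count", {
  # k waters held fixed inside r_cut every frame
  k <- 4L
  pos <- list(c(3.2, 0, 0), c(0, 3.4, 0), c(0, 0, 3.1), c(-3.3, 0, 0))
  traj <- fixed_water_trajectory(pos, donate = FALSE, n_frames = 5L)
  r <- compute_rdf(traj, bin_width = 0.05)
  expect_equal(coordination_number(r, 4), k, tolerance = 0.1)
  expect_error(coordination_number(r, 99), "exceeds")

  # stochastic fixture: integral vs direct per-frame average within 2%
  gen <- generate_solvation_trajectory("thiol", n_waters = 80L,
                                       n_frames = 500L, seed = 23L)
  rt <- compute_rdf(gen$trajectory, bin_width = 0.05)
  r_cut <- 4.5
  o_ids <- gen$trajectory$topology$atoms$id[
    gen$trajectory$topology$atoms$role == "water_oxygen"]
  direct <- mean(vapply(seq_len(500L), function(fr) {
    d <- sqrt(colSums((t(gen$trajectory$coords[o_ids, , fr]) -
                         gen$trajectory$coords[1L, , fr])^2))
    sum(d <= r_cut)
  }, 0))
  expect_equal(coordination_number(rt, r_cut), direct, tolerance = 0.02)
})

test_that("hydrogen-bond detection applies distance and angle criteria", {
  box <- c(30, 30, 30)
  crit <- hbond_criteria()
  # donating water at 3.2 A, aligned: one OH-S bond
  t1 <- fixed_water_trajectory(list(c(0, 3.2, 0)), donate = TRUE)
  hb <- detect_hbonds(t1$coords[, , 1], t1$topology, crit, box)
  expect_identical(hb$direction, "OH-S")
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$distance, 3.2, tolerance = 1e-6)
  expect_gt(hb$angle, 150)
  # same oxygen position, hydrogens pointing away: nothing
  t2 <- fixed_water_trajectory(list(c(0, 3.2, 0)), donate = FALSE)
  hb2 <- detect_hbonds(t2$coords[, , 1], t2$topology, crit, box)
  expect_identical(nrow(hb2), 0L)
  # beyond the O...S cutoff: nothing even when aligned
  t3 <- fixed_water_trajectory(list(c(0, 4.5, 0)), donate = TRUE)
  expect_identical(nrow(detect_hbonds(t3$coords[, , 1], t3$topology,
                                      crit, box)), 0L)
  # disulfide: only OH-S / OH-O can ever appear
  gen <- generate_solvation_trajectory("disulfide", n_waters = 20L,
                                       n_frames = 5L, seed = 31L)
  for (fr in 1:5) {
    hb4 <- detect_hbonds(gen$trajectory$coords[, , fr],
                         gen$trajectory$topology, crit,
                         gen$trajectory$box)
    expect_false(any(hb4$direction == "SH-O"))
  }
})

test_that("raising cutoffs never loses bonds (monotone criteria)", {
  gen <- generate_solvation_trajectory("thiol", n_waters = 30L,
                                       n_frames = 10L, seed = 41L)
  loose <- hbond_criteria(dist_OO = 4.0, dist_OS = 4.5, angle_dev = 40)
  for (fr in c(1L, 5L, 10L)) {
    n_tight <- nrow(detect_hbonds(gen$trajectory$coords[, , fr],
                                  gen$trajectory$topology,
                                  hbond_criteria(), gen$trajectory$box))
    n_loose <- nrow(detect_hbonds(gen$trajectory$coords[, , fr],
                                  gen$trajectory$topology, loose,
                                  gen$trajectory$box))
    expect_gte(n_loose, n_tight)
  }
})

test_that("bond intervals are maximal runs within the window", {
  # hand-built occupancy pattern: bonded frames {3,4,5, 9}
  pos_on <- c(0, 3.2, 0)
  traj_on <- fixed_water_trajectory(list(pos_on), donate = TRUE,
                                    n_frames = 10L)
  traj_off <- fixed_water_trajectory(list(c(0, 12, 0)), donate = TRUE,
                                     n_frames = 1L)
  co <- traj_on$coords
  for (fr in c(1, 2, 6, 7, 8, 10)) co[, , fr] <- traj_off$coords[, , 1]
  traj <- trajectory(co, traj_on$box, traj_on$topology)
  iv <- bond_intervals(traj)
  ohs <- iv[iv$direction == "OH-S", ]
  expect_identical(ohs$start_frame, c(3L, 9L))
  expect_identical(ohs$length, c(3L, 1L))
  # window restriction
  iv2 <- bond_intervals(traj, window = c(4, 10))
  expect_identical(iv2$start_frame[iv2$direction == "OH-S"], c(4L, 9L))
  expect_error(bond_intervals(traj, window = c(8, 2)), "window")
  expect_error(bond_intervals(traj, window = c(0, 5)), "window")
  # a never-bonded pair does not appear
  expect_false(any(iv$donor_id == 6L))
})

test_that("interaction scores weight residence as documented", {
  iv <- data.frame(donor_id = c(3L, 3L), acceptor_id = 1L,
                   direction = "OH-S", start_frame = c(1L, 10L),
                   end_frame = c(3L, 14L), length = c(3L, 5L))
  expect_equal(interaction_score(iv, "OH-S")$score, 8)
  expect_equal(interaction_score(iv, "OH-S", min_persistence = 4)$score, 5)
  expect_equal(interaction_score(iv, "OH-S", weight_exponent = 1)$score,
               9 + 25)
  expect_equal(interaction_score(iv, "SH-O")$score, 0)
  # monotone in the persistence filter
  for (mp in 1:6) {
    expect_gte(interaction_score(iv, "OH-S", min_persistence = mp)$score,
               interaction_score(iv, "OH-S",
                                 min_persistence = mp + 1L)$score)
  }
})

test_that("scores are invariant to water relabelling", {
  pos <- list(c(0, 3.2, 0), c(0, -3.3, 0), c(3.1, 3.1, 3.1))
  t1 <- fixed_water_trajectory(pos, donate = TRUE, n_frames = 4L)
  t2 <- fixed_water_trajectory(rev(pos), donate = TRUE, n_frames = 4L)
  s1 <- interaction_score(bond_intervals(t1), "OH-S")$score
  s2 <- interaction_score(bond_intervals(t2), "OH-S")$score
  expect_equal(s1, s2)
})

test_that("per-sulfur summary normalizes and combines directions", {
  a <- structure(list(direction = "OH-S", score = 10, n_intervals = 2L,
                      min_persistence = 1L, weight_exponent = 0,
                      window = c(1L, 10L)), class = "interaction_score")
  b <- structure(list(direction = "SH-O", score = 0, n_intervals = 0L,
                      min_persistence = 1L, weight_exponent = 0,
                      window = c(1L, 10L)), class = "interaction_score")
  s <- per_sulfur_summary(list(a, b), n_sulfur = 2L)
  expect_equal(s$per_sulfur[s$direction == "OH-S"], 5)
  expect_equal(s$total[s$direction == "combined"], 10)
  expect_equal(s$per_sulfur[s$direction == "combined"], 5)
  expect_error(per_sulfur_summary(list(a), 0L), "n_sulfur")
})

test_that("thiol shows ~2x the per-sulfur interaction of a disulfide", {
  # matched occupancy per direction stream; the thiol's extra donor
  # direction doubles its combined per-sulfur tally
  th <- generate_solvation_trajectory("thiol", n_waters = 80L,
                                      n_frames = 800L, seed = 51L)
  ds <- generate_solvation_trajectory("disulfide", n_waters = 80L,
                                      n_frames = 800L, seed = 52L)
  iv_t <- bond_intervals(th$trajectory)
  iv_d <- bond_intervals(ds$trajectory)
  comb <- function(iv, ns) {
    s <- per_sulfur_summary(list(interaction_score(iv, "OH-S"),
                                 interaction_score(iv, "SH-O")), ns)
    s$per_sulfur[s$direction == "combined"]
  }
  ratio <- comb(iv_t, 1L) / comb(iv_d, 2L)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  # the disulfide structural zero
  expect_equal(interaction_score(iv_d, "SH-O")$score, 0)
})
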