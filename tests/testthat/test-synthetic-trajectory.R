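test_that("a scheduled interval is realized in exactly its frames", {
  sched <- data.frame(donor_id = 3L, acceptor_id = 1L, direction = "OH-S",
                      start_frame = 10L, end_frame = 19L)
  gen <- generate_solvation_trajectory("thiol", n_waters = 10L,
                                       n_frames = 30L, schedule = sched,
                                       seed = 4L)
  iv <- bond_intervals(gen$trajectory)
  ohs <- iv[iv$direction == "OH-S", ]
  expect_identical(nrow(ohs), 1L)
  expect_identical(ohs$donor_id, 3L)
  expect_identical(c(ohs$start_frame, ohs$end_frame), c(10L, 19L))
})

test_that("disulfide solutes never schedule or realize SH-O bonds", {
  gen <- generate_solvation_trajectory("disulfide", n_waters = 30L,
                                       n_frames = 200L, seed = 6L)
  expect_false(any(gen$schedule$direction == "SH-O"))
  sched <- data.frame(donor_id = 1L, acceptor_id = 9L, direction = "SH-O",
                      start_frame = 1L, end_frame = 5L)
  expect_error(
    generate_solvation_trajectory("disulfide", n_waters = 10L,
                                  n_frames = 10L, schedule = sched),
    "no sulfur-bonded hydrogen")
})

test_that("unscheduled waters live in bulk, far from the sulfur", {
  gen <- generate_solvation_trajectory("thiol", n_waters = 25L,
                                       n_frames = 1L,
                                       schedule = data.frame(
                                         donor_id = integer(),
                                         acceptor_id = integer(),
                                         direction = character(),
                                         start_frame = integer(),
                                         end_frame = integer()),
                                       seed = 8L)
  traj <- gen$trajectory
  o_ids <- traj$topology$atoms$id[traj$topology$atoms$role == "water_oxygen"]
  s_pos <- traj$coords[1L, , 1L]
  d <- sqrt(colSums((t(traj$coords[o_ids, , 1L]) - s_pos)^2))
  expect_true(all(d >= 6 - 1e-9))
})

test_that("scheduled geometry sits inside the criteria with margin", {
  gen <- generate_solvation_trajectory("thiol", n_waters = 40L,
                                       n_frames = 300L, seed = 12L)
  traj <- gen$trajectory
  sched <- gen$schedule
  crit <- hbond_criteria()
  for (k in seq_len(min(5L, nrow(sched)))) {
    fr <- sched$start_frame[k]
    w_id <- if (sched$direction[k] == "OH-S") sched$donor_id[k] else
      sched$acceptor_id[k]
    s_id <- if (sched$direction[k] == "OH-S") sched$acceptor_id[k] else
      sched$donor_id[k]
    d <- sqrt(sum((traj$coords[w_id, , fr] - traj$coords[s_id, , fr])^2))
    expect_lte(d, 3.6 + 1e-6)
    expect_gte(d, 3.0 - 1e-6)
    # off-interval frames violate the distance criterion by >= 1 A
    off <- sched$end_frame[k] + 1L
    if (off <= dim(traj$coords)[3] &&
        !any(sched$start_frame <= off & sched$end_frame >= off &
               (sched$donor_id == w_id | sched$acceptor_id == w_id))) {
      d_off <- sqrt(sum(vapply(1:3, function(i) {
        (traj$coords[w_id, i, off] - traj$coords[s_id, i, off])
      }, 0)^2))
      expect_gte(d_off, crit$dist_OS + 1)
    }
  }
})

test_that("generation is deterministic under its seed", {
  g1 <- generate_solvation_trajectory("thiol", n_waters = 15L,
                                      n_frames = 40L, seed = 9L)
  g2 <- generate_solvation_trajectory("thiol", n_waters = 15L,
                                      n_frames = 40L, seed = 9L)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$schedule, g2$schedule)
  g3 <- generate_solvation_trajectory("thiol", n_waters = 15L,
                                      n_frames = 40L, seed = 10L)
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("ideal-gas frames follow Poisson neighbour statistics", {
  ig <- ideal_gas_frames(300L, c(30, 30, 30), 400L, seed = 14L)
  expect_identical(ig$coords, ideal_gas_frames(300L, c(30, 30, 30), 400L,
                                               seed = 14L)$coords)
  r <- 5
  expected <- 300 / 27000 * 4 / 3 * pi * r^3
  cnt <- vapply(seq_len(400L), function(fr) {
    d <- sqrt(colSums((t(ig$coords[-1L, , fr]) - ig$box / 2)^2))
    sum(d <= r)
  }, 0)
  expect_equal(mean(cnt), expected, tolerance = 0.1)
  expect_error(ideal_gas_frames(1L), ">= 2")
})

test_that("XYZ + topology round trip preserves the trajectory", {
  gen <- generate_solvation_trajectory("thiol", n_waters = 5L,
                                       n_frames = 3L, seed = 2L)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  topo <- withr::local_tempfile(fileext = ".json")
  write_xyz(gen$trajectory, xyz)
  write_topology(gen$trajectory$topology, topo, box = gen$trajectory$box)
  back <- read_trajectory(xyz, topo)
  expect_equal(back$coords, gen$trajectory$coords, tolerance = 1e-5)
  expect_identical(back$topology$atoms$role,
                   gen$trajectory$topology$atoms$role)
  expect_equal(back$box, gen$trajectory$box)
  # truncated file: wrong atom count in a frame
  lines <- readLines(xyz)
  writeLines(lines[-length(lines)], xyz)
  expect_error(read_trajectory(xyz, topo), "frame")
})

test_that("topology validation catches malformed waters and thiols", {
  atoms <- data.frame(id = 1:2, element = c("O", "H"),
                      role = c("water_oxygen", "water_hydrogen"),
                      mol = 1L)
  expect_error(topology(atoms, data.frame(atom1 = 1L, atom2 = 2L)),
               "exactly 2 bonded water hydrogens")
  atoms2 <- data.frame(id = 1:2, element = c("S", "H"),
                       role = c("sulfur", "sulfur_hydrogen"), mol = 1L)
  expect_error(topology(atoms2, data.frame(atom1 = integer(),
                                           atom2 = integer())),
               "exactly one sulfur")
  expect_error(topology(data.frame(id = 1, element = "X", role = "oops",
                                   mol = 1),
                        data.frame(atom1 = integer(), atom2 = integer())),
               "unknown role")
})

test_that("schedule statistics are stable across seeds", {
  res <- vapply(1:3, function(s) {
    sch <- generate_solvation_trajectory("thiol", n_waters = 60L,
                                         n_frames = 1500L,
                                         seed = s)$schedule
    mean(sch$end_frame - sch$start_frame + 1L)
  }, 0)
  expect_lt(max(res) / min(res), 1.5)
})
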