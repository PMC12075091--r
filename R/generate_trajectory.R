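# Synthetic solvation trajectories with a known hydrogen-bond schedule.
#
# There is no integrator here: waters are re-placed every frame so that the
# scheduled donor/acceptor pairs satisfy the geometric hydrogen-bond
# criteria (with margin) exactly during their intervals and violate the
# distance criterion by >= 2 A outside them.  The generator tests
# bookkeeping (detection, intervals, scores), not physics.

# n random unit vectors (rows)
rand_unit <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# a unit vector orthogonal to u (3-vector)
rand_perp <- function(u) {
  repeat {
    v <- stats::rnorm(3)
    v <- v - u * sum(v * u)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

deg2rad <- function(x) x * pi / 180

# Place a water donating an O-H...A hydrogen bond to acceptor at `acc`:
# O at distance r_da from the acceptor along `dir`, one H on the O->acceptor
# axis such that the D-H...A angle is `theta` degrees, the other H pointing
# away from the acceptor (~104.5 deg H-O-H).
place_donating_water <- function(acc, dir, r_da, theta, r_oh = 0.96) {
  o <- acc + r_da * dir
  u <- -dir                      # O -> acceptor
  # deviation alpha of the O-H bond from the O->acceptor axis giving the
  # requested D-H...A angle (one fixed-point refinement of the triangle)
  alpha <- (180 - theta) * (r_da - r_oh) / r_da
  for (i in 1:3) {
    a_r <- deg2rad(alpha)
    d_ha <- sqrt(r_oh^2 + r_da^2 - 2 * r_oh * r_da * cos(a_r))
    beta <- asin(pmin(1, r_oh * sin(a_r) / d_ha)) * 180 / pi
    alpha <- (180 - theta) - beta
  }
  v <- rand_perp(u)
  h1dir <- cos(deg2rad(alpha)) * u + sin(deg2rad(alpha)) * v
  h1 <- o + r_oh * h1dir
  # second H at ~104.5 deg from the first, biased away from the acceptor
  w <- -u - h1dir * sum(-u * h1dir)
  nw <- sqrt(sum(w^2))
  w <- if (nw > 1e-8) w / nw else rand_perp(h1dir)
  h2dir <- cos(deg2rad(104.5)) * h1dir + sin(deg2rad(104.5)) * w
  h2 <- o + r_oh * h2dir
  rbind(o, h1, h2)
}

# Place a water accepting an S-H...O bond from donor sulfur `s` whose
# hydrogen sits at `h` (S-H along unit vector `sh_dir`): O at donor-acceptor
# distance r_da from S with the S-H...O angle equal to `theta` degrees;
# both water hydrogens point away from the sulfur.
place_accepting_water <- function(s, h, sh_dir, r_da, theta, r_oh = 0.96) {
  phi <- deg2rad(180 - theta)
  w <- rand_perp(sh_dir)
  dir <- cos(phi) * sh_dir + sin(phi) * w   # from H toward O
  d_sh <- sqrt(sum((h - s)^2))
  # |O - s| = r_da with O = h + L*dir
  disc <- (2 * d_sh * cos(phi))^2 - 4 * (d_sh^2 - r_da^2)
  L <- (-2 * d_sh * cos(phi) + sqrt(disc)) / 2
  o <- h + L * dir
  u <- (o - s); u <- u / sqrt(sum(u^2))     # away from sulfur
  v <- rand_perp(u)
  h1 <- o + r_oh * (cos(deg2rad(55)) * u + sin(deg2rad(55)) * v)
  h2 <- o + r_oh * (cos(deg2rad(55)) * u - sin(deg2rad(55)) * v)
  rbind(o, h1, h2)
}

#' Automatically generated hydrogen-bond schedule
#'
#' Builds, per direction stream, alternating bonded intervals (lengths
#' `1 + Poisson(mean_residence - 1)`) and gaps tuned so the long-run mean
#' number of concurrent bonds per stream equals `occupancy`; each interval
#' is assigned to a water that is free over its whole span.
#'
#' @param streams data.frame with columns `direction` (`"OH-S"` or
#'   `"SH-O"`), `sulfur_id`, `occupancy` (mean bonds per frame for the
#'   stream).
#' @param water_ids ids of the water oxygens available for scheduling.
#' @param n_frames trajectory length.
#' @param mean_residence mean bonded-interval length in frames.
#' @param seed RNG seed.
#' @return schedule data.frame: `donor_id`, `acceptor_id`, `direction`,
#'   `start_frame`, `end_frame` (1-based, inclusive).
#' @export
auto_bond_schedule <- function(streams, water_ids, n_frames,
                               mean_residence = 20, seed = 1L) {
  stopifnot(n_frames >= 1L, mean_residence >= 1)
  busy <- matrix(FALSE, length(water_ids), n_frames)
  rownames(busy) <- as.character(water_ids)
  rows <- list()
  with_seed(seed, {
    for (si in seq_len(nrow(streams))) {
      dir_lab <- streams$direction[si]
      s_id <- streams$sulfur_id[si]
      occ <- streams$occupancy[si]
      n_slots <- max(1L, ceiling(occ))
      occ_slot <- occ / n_slots
      mean_gap <- max(1, mean_residence * (1 - occ_slot) / occ_slot)
      for (slot in seq_len(n_slots)) {
        pos <- 1L + stats::rgeom(1L, 1 / (1 + mean_gap))
        while (pos <= n_frames) {
          len <- 1L + stats::rpois(1L, max(0, mean_residence - 1))
          end <- min(pos + len - 1L, n_frames)
          free <- which(!apply(busy[, pos:end, drop = FALSE], 1L, any))
          if (length(free)) {
            w <- if (length(free) == 1L) free else sample(free, 1L)
            busy[w, pos:end] <- TRUE
            wid <- water_ids[w]
            rows[[length(rows) + 1L]] <- data.frame(
              donor_id = if (dir_lab == "OH-S") wid else s_id,
              acceptor_id = if (dir_lab == "OH-S") s_id else wid,
              direction = dir_lab,
              start_frame = pos, end_frame = end,
              stringsAsFactors = FALSE
            )
          }
          pos <- end + 1L + 1L + stats::rgeom(1L, 1 / mean_gap)
        }
      }
    }
  })
  if (!length(rows)) {
    return(data.frame(donor_id = integer(), acceptor_id = integer(),
                      direction = character(), start_frame = integer(),
                      end_frame = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Generate a synthetic solvation trajectory
#'
#' A thiol (one S with a bonded H) or disulfide (two S, no S-bonded H)
#' solute is fixed at the box centre; scheduled waters are placed so their
#' hydrogen bonds satisfy the default geometric criteria during their
#' intervals (donor-acceptor distance U(3.0, 3.6) A for O...S, D-H...A
#' angle U(160, 180) deg) and sit in bulk (>= 6 A from every sulfur)
#' otherwise; unscheduled waters are uniform in bulk, re-randomized every
#' frame.
#'
#' @param solute `"thiol"` or `"disulfide"`.
#' @param n_waters number of water molecules (default 200).
#' @param n_frames number of frames (default 2000).
#' @param box orthorhombic box lengths in Angstroms (default 30^3).
#' @param schedule optional bond-schedule data.frame (see
#'   [auto_bond_schedule()]); when `NULL` one is generated from
#'   `occupancy`/`mean_residence`.
#' @param occupancy target mean bonds per frame per direction stream
#'   (default 0.6, one stream per direction per sulfur).
#' @param mean_residence mean bonded-interval length in frames.
#' @param seed RNG seed.
#' @return list with `trajectory` (an `md_trajectory`) and `schedule`.
#' @export
generate_solvation_trajectory <- function(solute = c("thiol", "disulfide"),
                                          n_waters = 200L,
                                          n_frames = 2000L,
                                          box = c(30, 30, 30),
                                          schedule = NULL,
                                          occupancy = 0.6,
                                          mean_residence = 20,
                                          seed = 1L) {
  solute <- match.arg(solute)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (n_waters < 1L) stop("need at least one water")
  centre <- box / 2

  # --- topology ---------------------------------------------------------
  if (solute == "thiol") {
    s_ids <- 1L
    solute_atoms <- data.frame(
      id = 1:2, element = c("S", "H"),
      role = c("sulfur", "sulfur_hydrogen"), mol = 1L,
      stringsAsFactors = FALSE)
    solute_bonds <- data.frame(atom1 = 1L, atom2 = 2L)
    n_solute <- 2L
  } else {
    s_ids <- 1:2
    solute_atoms <- data.frame(
      id = 1:2, element = c("S", "S"),
      role = c("sulfur", "sulfur"), mol = 1L,
      stringsAsFactors = FALSE)
    solute_bonds <- data.frame(atom1 = 1L, atom2 = 2L)
    n_solute <- 2L
  }
  w_o_ids <- n_solute + 3L * (seq_len(n_waters) - 1L) + 1L
  water_atoms <- data.frame(
    id = rep(w_o_ids, each = 3L) + rep(0:2, n_waters),
    element = rep(c("O", "H", "H"), n_waters),
    role = rep(c("water_oxygen", "water_hydrogen", "water_hydrogen"),
               n_waters),
    mol = rep(seq_len(n_waters) + 1L, each = 3L),
    stringsAsFactors = FALSE)
  water_bonds <- data.frame(
    atom1 = rep(w_o_ids, each = 2L),
    atom2 = rep(w_o_ids, each = 2L) + rep(1:2, n_waters))
  top <- topology(rbind(solute_atoms, water_atoms),
                  rbind(solute_bonds, water_bonds))
  n_at <- nrow(top$atoms)

  # --- solute geometry (fixed in all frames) ----------------------------
  solute_xyz <- matrix(0, n_solute, 3L)
  if (solute == "thiol") {
    solute_xyz[1L, ] <- centre
    solute_xyz[2L, ] <- centre + c(1.34, 0, 0)   # S-H along +x
    sh_dir <- c(1, 0, 0)
  } else {
    solute_xyz[1L, ] <- centre - c(1.02, 0, 0)   # S-S bond 2.04 A
    solute_xyz[2L, ] <- centre + c(1.02, 0, 0)
    sh_dir <- NULL
  }

  # --- schedule ---------------------------------------------------------
  if (is.null(schedule)) {
    streams <- do.call(rbind, lapply(s_ids, function(sid) {
      d <- data.frame(direction = "OH-S", sulfur_id = sid,
                      occupancy = occupancy, stringsAsFactors = FALSE)
      if (solute == "thiol") {
        d <- rbind(d, data.frame(direction = "SH-O", sulfur_id = sid,
                                 occupancy = occupancy,
                                 stringsAsFactors = FALSE))
      }
      d
    }))
    schedule <- auto_bond_schedule(streams, w_o_ids, n_frames,
                                   mean_residence, seed = seed + 1L)
  } else {
    schedule <- as.data.frame(schedule)
    if (solute == "disulfide" && any(schedule$direction == "SH-O")) {
      stop("schedule requests SH-O bonds but a disulfide solute has no ",
           "sulfur-bonded hydrogen")
    }
    if (any(schedule$start_frame < 1L | schedule$end_frame > n_frames |
              schedule$start_frame > schedule$end_frame)) {
      stop("schedule intervals must lie within 1..n_frames")
    }
  }
  sched_water <- ifelse(schedule$direction == "OH-S",
                        schedule$donor_id, schedule$acceptor_id)
  sched_sulfur <- ifelse(schedule$direction == "OH-S",
                         schedule$acceptor_id, schedule$donor_id)

  # --- frames -----------------------------------------------------------
  coords <- array(NA_real_, c(n_at, 3L, n_frames))
  min_s_dist <- 6.0
  with_seed(seed, {
    for (fr in seq_len(n_frames)) {
      frame <- matrix(NA_real_, n_at, 3L)
      frame[seq_len(n_solute), ] <- solute_xyz
      active <- which(schedule$start_frame <= fr & schedule$end_frame >= fr)
      shell_o <- matrix(numeric(0), 0L, 3L)
      placed_waters <- integer(0)
      for (k in active) {
        s_id <- sched_sulfur[k]
        s_pos <- frame[s_id, ]
        r_da <- stats::runif(1L, 3.0, 3.6)
        theta <- stats::runif(1L, 160, 180)
        for (try in 1:60) {
          if (schedule$direction[k] == "OH-S") {
            dir <- drop(rand_unit(1L))
            if (solute == "thiol") {
              # keep clear of the S-H cone so no spurious S-H...O bond
              if (sum(dir * sh_dir) > cos(deg2rad(45))) next
            } else {
              other <- frame[setdiff(s_ids, s_id)[1L], ]
              to_other <- (other - s_pos) / sqrt(sum((other - s_pos)^2))
              # hemisphere well away from the second sulfur
              if (sum(dir * to_other) > -0.5) next
            }
            w_xyz <- place_donating_water(s_pos, dir, r_da, theta)
          } else {
            h_pos <- frame[2L, ]
            w_xyz <- place_accepting_water(s_pos, h_pos, sh_dir, r_da, theta)
          }
          ok <- !nrow(shell_o) ||
            all(sqrt(rowSums((shell_o - matrix(w_xyz[1L, ], nrow(shell_o),
                                               3L, byrow = TRUE))^2)) >= 2.4)
          if (ok) break
        }
        o_id <- sched_water[k]
        frame[o_id + 0:2, ] <- w_xyz
        shell_o <- rbind(shell_o, w_xyz[1L, , drop = FALSE])
        placed_waters <- c(placed_waters, o_id)
      }
      # bulk waters: uniform, >= 6 A (minimum image) from every sulfur
      bulk_ids <- setdiff(w_o_ids, placed_waters)
      need <- length(bulk_ids)
      if (need) {
        pos <- matrix(NA_real_, 0L, 3L)
        while (nrow(pos) < need) {
          cand <- cbind(stats::runif(2L * need, 0, box[1]),
                        stats::runif(2L * need, 0, box[2]),
                        stats::runif(2L * need, 0, box[3]))
          ok <- rep(TRUE, nrow(cand))
          for (sid in s_ids) {
            d <- sqrt(min_image(cand[, 1] - frame[sid, 1], box[1])^2 +
                        min_image(cand[, 2] - frame[sid, 2], box[2])^2 +
                        min_image(cand[, 3] - frame[sid, 3], box[3])^2)
            ok <- ok & d >= min_s_dist
          }
          pos <- rbind(pos, cand[ok, , drop = FALSE])
        }
        pos <- pos[seq_len(need), , drop = FALSE]
        hd1 <- rand_unit(need)
        perp <- rand_unit(need)
        perp <- perp - hd1 * rowSums(perp * hd1)
        perp <- perp / sqrt(rowSums(perp^2))
        hd2 <- cos(deg2rad(104.5)) * hd1 + sin(deg2rad(104.5)) * perp
        frame[bulk_ids, ] <- pos
        frame[bulk_ids + 1L, ] <- pos + 0.96 * hd1
        frame[bulk_ids + 2L, ] <- pos + 0.96 * hd2
      }
      coords[, , fr] <- frame
    }
  })
  list(trajectory = trajectory(coords, box, top), schedule = schedule)
}

#' Ideal-gas reference trajectory
#'
#' Uniformly distributed points in the box, re-drawn every frame, plus one
#' fixed reference atom at the box centre; the analytic oracle for the RDF
#' (g(r) = 1) and for Poisson neighbour counts.
#'
#' @param n_points number of gas points (role `water_oxygen`).
#' @param box orthorhombic box lengths (Angstroms).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return An `md_trajectory` whose atom 1 is the reference (role
#'   `sulfur`).
#' @export
ideal_gas_frames <- function(n_points = 500L, box = c(30, 30, 30),
                             n_frames = 2000L, seed = 1L) {
  if (n_points < 2L) stop("n_points must be >= 2")
  atoms <- data.frame(
    id = seq_len(n_points + 1L),
    element = c("S", rep("O", n_points)),
    role = c("sulfur", rep("water_oxygen", n_points)),
    mol = seq_len(n_points + 1L),
    stringsAsFactors = FALSE)
  top <- topology(atoms, data.frame(atom1 = integer(), atom2 = integer()))
  coords <- array(NA_real_, c(n_points + 1L, 3L, n_frames))
  with_seed(seed, {
    for (fr in seq_len(n_frames)) {
      coords[1L, , fr] <- box / 2
      coords[-1L, , fr] <- cbind(stats::runif(n_points, 0, box[1]),
                                 stats::runif(n_points, 0, box[2]),
                                 stats::runif(n_points, 0, box[3]))
    }
  })
  trajectory(coords, box, top)
}
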