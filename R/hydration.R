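#' Geometric hydrogen-bond criteria
#'
#' A directed bond D-H...A exists when the donor-acceptor minimum-image
#' distance is below the element-pair cutoff and the D-H...A angle is
#' within `angle_dev` degrees of linear.  Cutoffs default to 3.5 A for
#' O...O and 4.0 A for O...S (motivated by the ~3.8 A first peak of the
#' sulfur-water RDF).
#'
#' @param dist_OO O...O donor-acceptor cutoff (Angstroms).
#' @param dist_OS O...S donor-acceptor cutoff (Angstroms).
#' @param angle_dev maximum deviation of the D-H...A angle from 180 deg.
#' @return An `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_OO = 3.5, dist_OS = 4.0, angle_dev = 30) {
  if (dist_OO <= 0 || dist_OS <= 0) stop("distance cutoffs must be positive")
  if (angle_dev <= 0 || angle_dev >= 90) {
    stop("angle_dev must lie in (0, 90) degrees")
  }
  structure(list(dist_OO = dist_OO, dist_OS = dist_OS,
                 angle_dev = angle_dev),
            class = "hbond_criteria")
}

# minimum-image distance between one point and a matrix of points
mi_dist <- function(p, pts, box) {
  sqrt(min_image(pts[, 1] - p[1], box[1])^2 +
         min_image(pts[, 2] - p[2], box[2])^2 +
         min_image(pts[, 3] - p[3], box[3])^2)
}

# D-H...A angle (degrees) at the hydrogen, minimum-image vectors
dha_angle <- function(d_pos, h_pos, a_pos, box) {
  v1 <- vapply(1:3, function(i) min_image(d_pos[i] - h_pos[i], box[i]), 0)
  v2 <- vapply(1:3, function(i) min_image(a_pos[i] - h_pos[i], box[i]), 0)
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Radial distribution function under periodic boundaries
#'
#' `g(r) = <pair count in shell> / (N_ref * rho_target * V_shell)` averaged
#' over frames, with minimum-image distances in the orthorhombic box,
#' `V_shell = (4/3) pi (r2^3 - r1^3)` and the bulk target density
#' `rho = N_target / V_box`.
#'
#' @param traj an `md_trajectory`.
#' @param reference_role role of the reference atoms (default `"sulfur"`).
#' @param target_role role of the distributed atoms (default
#'   `"water_oxygen"`).
#' @param bin_width histogram bin width in Angstroms (default 0.1).
#' @param r_max maximum radius; must not exceed half the smallest box
#'   edge (default: exactly that).
#' @return An `rdf_profile`: bin centres `r`, `g`, raw `counts`, the bulk
#'   density and selection labels.
#' @export
compute_rdf <- function(traj, reference_role = "sulfur",
                        target_role = "water_oxygen", bin_width = 0.1,
                        r_max = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  half <- min(traj$box) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) {
    stop("r_max must not exceed half the smallest box edge (", half, " A)")
  }
  refs <- role_ids(traj$topology, reference_role)
  targets <- role_ids(traj$topology, target_role)
  if (!length(refs)) stop("no atoms with role '", reference_role, "'")
  if (!length(targets)) stop("no atoms with role '", target_role, "'")
  nb <- ceiling(r_max / bin_width)
  counts <- numeric(nb)
  nf <- n_frames(traj)
  for (fr in seq_len(nf)) {
    pts <- traj$coords[targets, , drop = FALSE, fr]
    dim(pts) <- c(length(targets), 3L)
    for (ref in refs) {
      d <- mi_dist(traj$coords[ref, , fr], pts, traj$box)
      d <- d[d > 1e-9 & d < nb * bin_width]
      if (length(d)) {
        counts <- counts + tabulate(ceiling(d / bin_width), nbins = nb)
      }
    }
  }
  rho <- length(targets) / prod(traj$box)
  edges <- bin_width * (0:nb)
  v_shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  g <- counts / (nf * length(refs) * rho * v_shell)
  structure(
    list(r = bin_width * (seq_len(nb) - 0.5), g = g, counts = counts,
         bin_width = bin_width, r_max = nb * bin_width, rho = rho,
         n_frames = nf, reference = reference_role, target = target_role,
         n_ref = length(refs), n_target = length(targets)),
    class = "rdf_profile"
  )
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat("<rdf_profile> ", x$reference, " -> ", x$target, ", ",
      length(x$r), " bins of ", x$bin_width, " A over ", x$n_frames,
      " frames\n", sep = "")
  invisible(x)
}

#' @export
plot.rdf_profile <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (Angstrom)",
                 ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' First peak of an RDF profile
#'
#' First local maximum of g(r) inside the search range that rises above
#' `min_height`.  The profile is lightly smoothed (3-bin moving average)
#' before peak finding: small-radius shells hold very few pairs, so raw
#' bins are noisy, and bulk is g = 1 -- a genuine first solvation shell
#' must clear the threshold, while density noise around the bulk level
#' must not.  The reported height is the raw g at the peak bin.
#'
#' @param profile an `rdf_profile`.
#' @param search_range `c(lo, hi)` in Angstroms (default 2-5 A).
#' @param min_height minimum (smoothed) g at the peak (default 1.3).
#' @return list with `r_peak` and `g_peak`.
#' @export
first_peak <- function(profile, search_range = c(2, 5), min_height = 1.3) {
  stopifnot(inherits(profile, "rdf_profile"))
  idx <- which(profile$r >= search_range[1] & profile$r <= search_range[2])
  if (length(idx) < 3L) stop("search range covers fewer than 3 bins")
  g <- profile$g
  n <- length(g)
  gs <- (g + c(g[1], g[-n]) + c(g[-1], g[n])) / 3
  for (i in idx[-c(1L, length(idx))]) {
    if (gs[i] > gs[i - 1L] && gs[i] >= gs[i + 1L] && gs[i] >= min_height) {
      return(list(r_peak = profile$r[i], g_peak = g[i]))
    }
  }
  stop("no local maximum above g = ", min_height, " in ",
       search_range[1], "-", search_range[2], " A")
}

#' Coordination number from an RDF profile
#'
#' `N(r_cut) = 4 pi rho \\int_0^{r_cut} g(r) r^2 dr`, evaluated by the
#' midpoint rule over the histogram bins (consistent with the binned g, so
#' it reproduces direct shell counts to rounding error).
#'
#' @param profile an `rdf_profile`.
#' @param r_cut integration limit in Angstroms (snapped to the nearest bin
#'   edge).
#' @return expected number of target atoms within `r_cut`.
#' @export
coordination_number <- function(profile, r_cut) {
  stopifnot(inherits(profile, "rdf_profile"))
  if (r_cut > profile$r_max + 1e-9) {
    stop("r_cut exceeds the profile range (", profile$r_max, " A)")
  }
  keep <- profile$r <= r_cut
  4 * pi * profile$rho *
    sum(profile$g[keep] * profile$r[keep]^2 * profile$bin_width)
}

# Directed sulfur-water hydrogen bonds in one frame, vectorized over
# waters.  Returns a data.frame (possibly empty).
hbonds_sulfur_frame <- function(frame, top, criteria, box) {
  atoms <- top$atoms
  s_ids <- atoms$id[atoms$role == "sulfur"]
  o_ids <- atoms$id[atoms$role == "water_oxygen"]
  out <- list()
  if (!length(s_ids) || !length(o_ids)) return(NULL)
  o_pos <- frame[o_ids, , drop = FALSE]
  for (s in s_ids) {
    s_pos <- frame[s, ]
    d <- mi_dist(s_pos, o_pos, box)
    cand <- which(d <= criteria$dist_OS)
    # OH-S: water oxygen donates one of its hydrogens to the sulfur
    for (ci in cand) {
      o <- o_ids[ci]
      for (h in bonded_hydrogens(top, o)) {
        ang <- dha_angle(frame[o, ], frame[h, ], s_pos, box)
        if (ang >= 180 - criteria$angle_dev) {
          out[[length(out) + 1L]] <- data.frame(
            donor = o, hydrogen = h, acceptor = s, direction = "OH-S",
            distance = d[ci], angle = ang, stringsAsFactors = FALSE)
        }
      }
    }
    # SH-O: the thiol hydrogen donates to a water oxygen
    for (h in bonded_hydrogens(top, s)) {
      for (ci in cand) {
        o <- o_ids[ci]
        ang <- dha_angle(s_pos, frame[h, ], frame[o, ], box)
        if (ang >= 180 - criteria$angle_dev) {
          out[[length(out) + 1L]] <- data.frame(
            donor = s, hydrogen = h, acceptor = o, direction = "SH-O",
            distance = d[ci], angle = ang, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

#' Detect hydrogen bonds in a single frame
#'
#' Directed geometric detection: `OH-S` (water donates to sulfur), `SH-O`
#' (a sulfur-bonded hydrogen donates to a water oxygen) and `OH-O`
#' (water-water).  A bond exists iff the donor-acceptor minimum-image
#' distance is within the element-pair cutoff and the D-H...A angle is
#' within `angle_dev` of linear.
#'
#' @param frame atoms x 3 coordinate matrix (one trajectory frame).
#' @param top an `md_topology`.
#' @param criteria an [hbond_criteria()].
#' @param box orthorhombic box lengths.
#' @param directions subset of `c("OH-S", "SH-O", "OH-O")` to report.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `direction`, `distance`, `angle` (possibly 0 rows).
#' @export
detect_hbonds <- function(frame, top, criteria = hbond_criteria(),
                          box, directions = c("OH-S", "SH-O", "OH-O")) {
  stopifnot(inherits(top, "md_topology"))
  frame <- as.matrix(frame)
  out <- list()
  if (any(c("OH-S", "SH-O") %in% directions)) {
    sb <- hbonds_sulfur_frame(frame, top, criteria, box)
    if (!is.null(sb)) out[[length(out) + 1L]] <- sb
  }
  if ("OH-O" %in% directions) {
    o_ids <- role_ids(top, "water_oxygen")
    if (length(o_ids) >= 2L) {
      o_pos <- frame[o_ids, , drop = FALSE]
      for (i in seq_along(o_ids)) {
        d <- mi_dist(o_pos[i, ], o_pos, box)
        cand <- which(d <= criteria$dist_OO & d > 1e-9)
        hs <- bonded_hydrogens(top, o_ids[i])
        for (ci in cand) {
          for (h in hs) {
            ang <- dha_angle(o_pos[i, ], frame[h, ], o_pos[ci, ], box)
            if (ang >= 180 - criteria$angle_dev) {
              out[[length(out) + 1L]] <- data.frame(
                donor = o_ids[i], hydrogen = h, acceptor = o_ids[ci],
                direction = "OH-O", distance = d[ci], angle = ang,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), direction = character(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[res$direction %in% directions, , drop = FALSE]
}

#' Maximal bonded-frame intervals per directed pair
#'
#' Scans the analysis window frame by frame and records, for every
#' (donor, acceptor, direction) pair, the maximal runs of consecutive
#' bonded frames.  By default only the sulfur-water directions are
#' tracked; add `"OH-O"` for (quadratic-cost) water-water bookkeeping.
#'
#' @param traj an `md_trajectory`.
#' @param criteria an [hbond_criteria()].
#' @param window `c(first, last)` frame (1-based, inclusive); `NULL` means
#'   the full trajectory.
#' @param directions directions to track.
#' @return A `bond_intervals` data.frame: `donor_id`, `acceptor_id`,
#'   `direction`, `start_frame`, `end_frame`, `length`; attributes carry
#'   the window and criteria.
#' @export
bond_intervals <- function(traj, criteria = hbond_criteria(),
                           window = NULL, directions = c("OH-S", "SH-O")) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (is.null(window)) window <- c(1L, nf)
  window <- as.integer(window)
  if (window[1] < 1L || window[2] > nf || window[1] > window[2]) {
    stop("empty or out-of-range analysis window")
  }
  frames <- window[1]:window[2]
  top <- traj$topology
  atoms <- top$atoms
  s_ids <- atoms$id[atoms$role == "sulfur"]
  o_ids <- atoms$id[atoms$role == "water_oxygen"]
  want_oho <- "OH-O" %in% directions
  # one logical row per directed pair (donor, acceptor)
  keys <- character(0)
  pair_tab <- list()
  bonded <- NULL
  grow <- function(key, donor, acceptor, dir_lab) {
    if (is.null(pair_tab[[key]])) {
      pair_tab[[key]] <<- list(donor = donor, acceptor = acceptor,
                               direction = dir_lab)
      bonded[[key]] <<- logical(length(frames))
    }
  }
  bonded <- list()
  for (j in seq_along(frames)) {
    fr <- frames[j]
    frame <- traj$coords[, , fr]
    hb <- detect_hbonds(frame, top, criteria, traj$box,
                        directions = directions)
    if (nrow(hb)) {
      # one bonded flag per directed heavy-atom pair per frame
      hb_key <- paste(hb$direction, hb$donor, hb$acceptor, sep = "|")
      for (i in which(!duplicated(hb_key))) {
        key <- hb_key[i]
        grow(key, hb$donor[i], hb$acceptor[i], hb$direction[i])
        bonded[[key]][j] <- TRUE
      }
    }
  }
  rows <- list()
  for (key in names(bonded)) {
    info <- pair_tab[[key]]
    r <- rle(bonded[[key]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    for (i in on) {
      rows[[length(rows) + 1L]] <- data.frame(
        donor_id = info$donor, acceptor_id = info$acceptor,
        direction = info$direction,
        start_frame = frames[starts[i]], end_frame = frames[ends[i]],
        length = r$lengths[i], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_id = integer(), acceptor_id = integer(),
               direction = character(), start_frame = integer(),
               end_frame = integer(), length = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$direction, out$donor_id, out$acceptor_id,
                   out$start_frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "criteria") <- criteria
  class(out) <- c("bond_intervals", "data.frame")
  out
}

#' Residence-weighted hydrogen-bond interaction score
#'
#' Sums, over the maximal bonded intervals of one direction, the interval
#' length raised to `1 + weight_exponent`, keeping only intervals of at
#' least `min_persistence` frames.  With the defaults (persistence 1,
#' exponent 0) the score is the total number of bonded frames: every
#' hydrogen bond counts once per frame it survives, i.e. a tally weighted
#' by residence time.
#'
#' @param intervals a [bond_intervals()] result.
#' @param direction `"OH-S"` or `"SH-O"`.
#' @param min_persistence minimum interval length in frames (default 1).
#' @param weight_exponent extra residence-time exponent (default 0).
#' @return An `interaction_score` with the score value (frames), the
#'   interval count, and the parameters used.
#' @export
interaction_score <- function(intervals, direction = c("OH-S", "SH-O"),
                              min_persistence = 1L, weight_exponent = 0) {
  direction <- match.arg(direction)
  lens <- intervals$length[intervals$direction == direction]
  lens <- lens[lens >= min_persistence]
  score <- sum(as.numeric(lens)^(1 + weight_exponent))
  structure(
    list(direction = direction, score = score, n_intervals = length(lens),
         min_persistence = min_persistence,
         weight_exponent = weight_exponent,
         window = attr(intervals, "window")),
    class = "interaction_score"
  )
}

#' @export
print.interaction_score <- function(x, ...) {
  cat("<interaction_score> ", x$direction, ": ", format(x$score),
      " (", x$n_intervals, " interval(s), persistence >= ",
      x$min_persistence, ", exponent ", x$weight_exponent, ")\n", sep = "")
  invisible(x)
}

#' Per-sulfur interaction-score summary
#'
#' Totals the directional scores, normalizes by the number of sulfur
#' atoms, and reports the combined (OH-S + SH-O) tally -- the quantity on
#' which a thiol shows roughly twice the per-sulfur interaction of a
#' disulfide.
#'
#' @param scores list of `interaction_score` objects (one per direction).
#' @param n_sulfur number of sulfur atoms (>= 1).
#' @return data.frame with one row per direction plus a `combined` row;
#'   columns `direction`, `total`, `per_sulfur`.
#' @export
per_sulfur_summary <- function(scores, n_sulfur) {
  if (n_sulfur < 1L) stop("n_sulfur must be >= 1")
  if (inherits(scores, "interaction_score")) scores <- list(scores)
  dirs <- vapply(scores, `[[`, "", "direction")
  tot <- vapply(scores, `[[`, 0, "score")
  out <- data.frame(direction = c(dirs, "combined"),
                    total = c(tot, sum(tot)),
                    stringsAsFactors = FALSE)
  out$per_sulfur <- out$total / n_sulfur
  out
}
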