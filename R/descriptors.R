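unit <- function(v) v / sqrt(sum(v^2))

vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Signed dihedral over four points, degrees in (-180, 180].
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  ang <- atan2(sum(vcross(n1, n2) * unit(b2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

atom_xyz <- function(model, chain, resno, atom, model_index = 1) {
  sel <- model$atoms$chain == chain & model$atoms$resno == resno &
    model$atoms$atom == atom
  if (sum(sel) != 1) {
    return(NULL)
  }
  model$coords[[model_index]][sel, ]
}

residue_xyz <- function(model, chain, resno, atoms = NULL, model_index = 1) {
  sel <- model$atoms$chain == chain & model$atoms$resno == resno
  if (!is.null(atoms)) sel <- sel & model$atoms$atom %in% atoms
  model$coords[[model_index]][sel, , drop = FALSE]
}

glycosidic_nitrogen <- function(base) if (base %in% c("A", "G")) "N9" else "N1"

#' Base-pair reference frames
#'
#' One orthonormal frame per base pair: the origin is the midpoint of the
#' two C1' atoms; y points along the C1'(top) to C1'(bottom) vector; z is
#' the consecutive-origin direction orthogonalized against y (approximating
#' the local helical axis); x = y x z. This simplified C1'-based frame is
#' shared with [build_duplex()], so twist and bend measured here recover
#' the builder's parameters exactly.
#'
#' @param model A `structure_model` with a pairing map.
#' @param model_index Which coordinate model of an ensemble to use.
#' @return A list with one element per pair: `origin`, `x`, `y`, `z`.
#' @export
basepair_frames <- function(model, model_index = 1) {
  pairing <- model$pairing
  n <- nrow(pairing)
  if (n < 2) stop("at least two base pairs are needed for frames", call. = FALSE)
  missing <- character(0)
  c1_top <- matrix(NA_real_, n, 3)
  c1_bot <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    a <- atom_xyz(model, "W", pairing$top_resno[i], "C1'", model_index)
    b <- atom_xyz(model, "Y", pairing$bottom_resno[i], "C1'", model_index)
    if (is.null(a)) missing <- c(missing, sprintf("W%d:C1'", pairing$top_resno[i]))
    if (is.null(b)) missing <- c(missing, sprintf("Y%d:C1'", pairing$bottom_resno[i]))
    if (!is.null(a)) c1_top[i, ] <- a
    if (!is.null(b)) c1_bot[i, ] <- b
  }
  if (length(missing) > 0) {
    stop(
      "missing atoms for base-pair frames: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  origins <- (c1_top + c1_bot) / 2
  purrr::map(seq_len(n), function(i) {
    y <- unit(c1_bot[i, ] - c1_top[i, ])
    lo <- max(1, i - 1)
    hi <- min(n, i + 1)
    d <- origins[hi, ] - origins[lo, ]
    z <- d - sum(d * y) * y
    if (sqrt(sum(z^2)) < 1e-9) {
      stop("degenerate helical direction at pair ", i, call. = FALSE)
    }
    z <- unit(z)
    list(origin = origins[i, ], x = vcross(y, z), y = y, z = z)
  })
}

#' Helical twist at one base-pair step
#'
#' The signed angle between the y axes of consecutive base-pair frames,
#' measured about their mean z axis, in (-180, 180]. Step k is between
#' pairs k and k+1.
#'
#' @param frames Output of [basepair_frames()].
#' @param step_index Step number (1 to length(frames) - 1).
#' @return Twist in degrees.
#' @export
step_twist <- function(frames, step_index) {
  n <- length(frames)
  if (step_index < 1 || step_index > n - 1) {
    stop("step index outside the duplex", call. = FALSE)
  }
  f1 <- frames[[step_index]]
  f2 <- frames[[step_index + 1]]
  zm <- unit(f1$z + f2$z)
  proj <- function(v) unit(v - sum(v * zm) * zm)
  y1 <- proj(f1$y)
  y2 <- proj(f2$y)
  atan2(sum(vcross(y1, y2) * zm), sum(y1 * y2)) * 180 / pi
}

#' Cumulative twist over a span of base-pair steps
#'
#' Sum of [step_twist()] over steps `from_pair` to `to_pair - 1`; e.g. a
#' span from pair 14 to pair 19 covers five steps.
#'
#' @inheritParams step_twist
#' @param from_pair,to_pair First and last base pair of the span.
#' @return Cumulative twist in degrees.
#' @export
cumulative_twist <- function(frames, from_pair, to_pair) {
  stopifnot(from_pair >= 1, to_pair > from_pair, to_pair <= length(frames))
  sum(vapply(
    from_pair:(to_pair - 1),
    function(k) step_twist(frames, k), numeric(1)
  ))
}

#' Per-model cumulative twist of an ensemble
#'
#' @param model A multi-model `structure_model`.
#' @param from_pair,to_pair Span of base pairs, as in [cumulative_twist()].
#' @return Numeric vector, one cumulative twist (degrees) per model.
#' @export
twist_series <- function(model, from_pair, to_pair) {
  vapply(
    seq_along(model$coords),
    function(m) cumulative_twist(basepair_frames(model, m), from_pair, to_pair),
    numeric(1)
  )
}

#' Untwist angle relative to a reference ensemble
#'
#' `Untwist = Twist_initial - Twist` for each model: positive values mean
#' further untwisting relative to the reference, negative values further
#' twisting. The reference twist is caller-supplied, either as a number or
#' as a vector of reference-ensemble twists to average (e.g. the early
#' segment of a trajectory, before the event of interest).
#'
#' @param twists Numeric vector of per-model cumulative twists (degrees),
#'   e.g. from [twist_series()].
#' @param twist_initial A single reference twist in degrees, or a numeric
#'   vector of reference twists whose mean is used.
#' @param n_blocks Blocks for the block-averaged uncertainty.
#' @return A `descriptor_series` tibble (columns `model`, `value`) with
#'   block-averaged mean and SD in attributes; see [block_average()].
#' @examples
#' untwist_angle(c(165, 170), twist_initial = 180)
#' @export
untwist_angle <- function(twists, twist_initial, n_blocks = 5) {
  if (length(twist_initial) == 0) {
    stop("empty reference ensemble for twist_initial", call. = FALSE)
  }
  ref <- mean(twist_initial)
  descriptor_series("untwist", ref - twists,
    units = "degrees",
    n_blocks = n_blocks, reference = ref
  )
}

arm_axis <- function(origins, forward) {
  centered <- sweep(origins, 2, colMeans(origins))
  ax <- svd(centered)$v[, 1]
  if (sum(ax * forward) < 0) ax <- -ax
  unit(ax)
}

#' DNA bend angle at a hinge
#'
#' The angle between the principal axes of the base-pair origins of the 5'
#' arm (pairs hinge - arm_length .. hinge - 1) and the 3' arm (pairs
#' hinge + 1 .. hinge + arm_length), each axis oriented 5' to 3'. A
#' straight helix reads 0.
#'
#' @param model A `structure_model`.
#' @param hinge_pair Index of the hinge base pair.
#' @param arm_length Number of pairs in each arm (>= 2).
#' @param model_index Coordinate model to use.
#' @return Bend angle in degrees.
#' @export
bend_angle <- function(model, hinge_pair, arm_length, model_index = 1) {
  frames <- basepair_frames(model, model_index)
  n <- length(frames)
  if (arm_length < 2 || hinge_pair - arm_length < 1 || hinge_pair + arm_length > n) {
    stop("insufficient arm pairs on one side of the hinge", call. = FALSE)
  }
  ori <- t(vapply(frames, function(f) f$origin, numeric(3)))
  i5 <- (hinge_pair - arm_length):(hinge_pair - 1)
  i3 <- (hinge_pair + 1):(hinge_pair + arm_length)
  a5 <- arm_axis(ori[i5, , drop = FALSE], ori[max(i5), ] - ori[min(i5), ])
  a3 <- arm_axis(ori[i3, , drop = FALSE], ori[max(i3), ] - ori[min(i3), ])
  acos(pmin(pmax(sum(a5 * a3), -1), 1)) * 180 / pi
}

#' Bend-direction pseudo-dihedral
#'
#' A signed dihedral over four points - a groove-flank reference at the
#' hinge (the top-strand C1' atom of the hinge pair), the distal
#' base-pair centroid of the 5' arm, the hinge base-pair origin, and the
#' distal base-pair centroid of the 3' arm - indicating whether the
#' duplex bends toward the minor or the major groove. The central bond of
#' the dihedral runs along the 5' arm axis, so the value is the azimuth
#' of the bend displacement about the helix axis, measured from the
#' backbone flank; a reference point placed in the minor-major mirror
#' plane itself cannot separate the two grooves by sign, which is why the
#' backbone flank is used. The sign is calibrated on builder fixtures:
#' bending toward the minor groove is negative, toward the major groove
#' positive, matching the field's reporting convention. Below `min_bend`
#' degrees of bend the direction is undefined and `NA` is returned.
#'
#' @inheritParams bend_angle
#' @param min_bend Bend angle below which the direction is undefined.
#' @return Dihedral in degrees in (-180, 180], or `NA` when undefined.
#' @export
bend_direction_dihedral <- function(model, hinge_pair, arm_length,
                                    model_index = 1, min_bend = 2) {
  bend <- bend_angle(model, hinge_pair, arm_length, model_index)
  if (bend < min_bend) {
    return(NA_real_)
  }
  frames <- basepair_frames(model, model_index)
  pair_centroid <- function(i) {
    colMeans(rbind(
      residue_xyz(model, "W", model$pairing$top_resno[i], model_index = model_index),
      residue_xyz(model, "Y", model$pairing$bottom_resno[i], model_index = model_index)
    ))
  }
  fh <- frames[[hinge_pair]]
  p_ref <- atom_xyz(
    model, "W", model$pairing$top_resno[hinge_pair], "C1'", model_index
  )
  if (is.null(p_ref)) {
    stop("missing atoms for bend direction: W", model$pairing$top_resno[hinge_pair],
      ":C1'",
      call. = FALSE
    )
  }
  p1 <- pair_centroid(hinge_pair - arm_length)
  p2 <- fh$origin
  p4 <- pair_centroid(hinge_pair + arm_length)
  # sign fixed so that minor-groove-directed bending is negative
  dihedral4(p_ref, p1, p2, p4)
}

#' Base-extrusion pseudo-dihedral
#'
#' Tracks rotation of a base out of the helical stack via the dihedral
#' over four centroids: the base pair 3' of the flip site, the 3'-neighbor
#' sugar ring, the flipping nucleotide's sugar ring, and the flipping
#' base's ring atoms. Reported in (-180, 180]; compare against the
#' stacked ideal-duplex baseline to quantify extrusion.
#'
#' @param model A `structure_model`.
#' @param nucleotide Top-strand residue number of the flipping base.
#' @param model_index Coordinate model to use.
#' @return Dihedral in degrees.
#' @export
base_extrusion_dihedral <- function(model, nucleotide, model_index = 1) {
  n <- nrow(model$pairing)
  if (nucleotide < 1 || nucleotide + 1 > n) {
    stop("nucleotide must have a 3' neighbor within the duplex", call. = FALSE)
  }
  base_of <- function(resno) {
    model$atoms$base[model$atoms$chain == "W" & model$atoms$resno == resno][1]
  }
  need <- function(xyz, what) {
    if (nrow(xyz) == 0) stop("missing ring atoms for ", what, call. = FALSE)
    colMeans(xyz)
  }
  p1 <- need(rbind(
    residue_xyz(model, "W", nucleotide + 1, model_index = model_index),
    residue_xyz(model, "Y", model$pairing$bottom_resno[
      match(nucleotide + 1, model$pairing$top_resno)
    ], model_index = model_index)
  ), "the 3' base pair")
  p2 <- need(
    residue_xyz(model, "W", nucleotide + 1, sugar_ring_atoms(), model_index),
    "the 3'-neighbor sugar ring"
  )
  p3 <- need(
    residue_xyz(model, "W", nucleotide, sugar_ring_atoms(), model_index),
    "the flipping nucleotide's sugar ring"
  )
  p4 <- need(
    residue_xyz(
      model, "W", nucleotide,
      base_ring_atoms(base_of(nucleotide)), model_index
    ),
    "the flipping base ring"
  )
  dihedral4(p1, p2, p3, p4)
}

default_hbond_table <- function() {
  list(
    donors = tibble::tibble(
      base = c("C", "G", "G", "A", "T"),
      atom = c("N4", "N1", "N2", "N6", "N3")
    ),
    acceptors = tibble::tibble(
      base = c("G", "C", "C", "A", "T", "T"),
      atom = c("O6", "N3", "O2", "N1", "O4", "O2")
    )
  )
}

#' Detect hydrogen bonds by donor-acceptor geometry
#'
#' Heavy-atom criterion: a donor and an acceptor from the supplied table,
#' on different residues, within `d_max` Angstrom. When explicit hydrogens
#' are present (within 1.2 A of the donor) the D-H...A angle must also be
#' at least `angle_min` degrees; models without hydrogens use the distance
#' criterion alone.
#'
#' @param model A `structure_model`.
#' @param table List with `donors` and `acceptors` tibbles (columns `base`,
#'   `atom`); the default covers Watson-Crick DNA edges.
#' @param d_max Maximum donor-acceptor distance in Angstrom.
#' @param angle_min Minimum D-H...A angle in degrees (used only when
#'   hydrogens exist).
#' @param model_index Coordinate model to use.
#' @return Tibble of bonds: donor/acceptor chain, residue, atom, distance,
#'   and angle (`NA` without hydrogens). Empty when none found.
#' @export
hydrogen_bonds <- function(model, table = default_hbond_table(),
                           d_max = 3.5, angle_min = 120, model_index = 1) {
  atoms <- model$atoms
  xyz <- model$coords[[model_index]]
  pick <- function(spec) {
    idx <- integer(0)
    for (r in seq_len(nrow(spec))) {
      sel <- atoms$atom == spec$atom[r] &
        (is.na(spec$base[r]) | atoms$base == spec$base[r])
      idx <- c(idx, which(sel))
    }
    unique(idx)
  }
  di <- pick(table$donors)
  ai <- pick(table$acceptors)
  out <- list()
  for (d in di) {
    for (a in ai) {
      if (atoms$chain[d] == atoms$chain[a] && atoms$resno[d] == atoms$resno[a]) next
      dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dist > d_max) next
      ang <- NA_real_
      hyd <- which(atoms$element == "H" &
        sqrt(rowSums(sweep(xyz, 2, xyz[d, ])^2)) < 1.2)
      if (length(hyd) > 0) {
        angs <- vapply(hyd, function(h) {
          v1 <- unit(xyz[d, ] - xyz[h, ])
          v2 <- unit(xyz[a, ] - xyz[h, ])
          acos(pmin(pmax(sum(v1 * v2), -1), 1)) * 180 / pi
        }, numeric(1))
        ang <- max(angs)
        if (ang < angle_min) next
      }
      out[[length(out) + 1]] <- tibble::tibble(
        donor_chain = atoms$chain[d], donor_resno = atoms$resno[d],
        donor_atom = atoms$atom[d],
        acceptor_chain = atoms$chain[a], acceptor_resno = atoms$resno[a],
        acceptor_atom = atoms$atom[a],
        distance = dist, angle = ang
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      donor_chain = character(0), donor_resno = integer(0),
      donor_atom = character(0), acceptor_chain = character(0),
      acceptor_resno = integer(0), acceptor_atom = character(0),
      distance = numeric(0), angle = numeric(0)
    ))
  }
  dplyr::bind_rows(out)
}
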