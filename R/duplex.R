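# Idealized planar base templates in the base-pair frame. Coordinates are a
# simplified cylindrical fiber model, not crystallographic geometry: what
# matters is that (i) the two C1' atoms sit symmetrically on the pair long
# axis (the frame y-axis, top strand at negative y), (ii) Watson-Crick
# donor/acceptor partners face each other at 2.9 A across the pair, and
# (iii) the same frame conventions are shared with the descriptor code so
# generator/analyzer round trips are exact by construction.
sugar_template <- function() {
  tibble::tibble(
    atom = c("C1'", "C2'", "C3'", "C4'", "O4'"),
    x = c(0.0, -1.0, -2.2, -2.2, -1.0),
    y = c(-5.2, -4.5, -4.6, -5.4, -5.8),
    z = c(0.0, -0.9, -0.9, 0.2, 0.6)
  )
}

base_template <- function(base) {
  switch(base,
    G = tibble::tibble(
      atom = c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2", "O6", "N2"),
      x = c(0.8, 0.1, 0.7, 1.9, 1.95, 3.0, 2.8, 1.7, 4.8, 0.8),
      y = c(-4.0, -3.15, -2.3, -2.75, -3.8, -2.25, -1.45, -2.1, -1.45, -1.45),
      z = 0
    ),
    A = tibble::tibble(
      atom = c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2", "N6"),
      x = c(0.8, 0.1, 0.7, 1.9, 1.95, 3.0, 2.8, 1.7, 4.8),
      y = c(-4.0, -3.15, -2.3, -2.75, -3.8, -2.25, -1.45, -2.1, -1.45),
      z = 0
    ),
    C = tibble::tibble(
      atom = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
      x = c(0.8, 1.0, 0.8, 2.8, 3.3, 4.8, 2.9, 1.7),
      y = c(-4.0, -2.7, -1.45, -1.45, -2.4, -1.45, -3.5, -4.1),
      z = 0
    ),
    T = tibble::tibble(
      atom = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6", "C7"),
      x = c(0.8, 1.0, 0.8, 2.8, 3.3, 4.8, 2.9, 1.7, 3.6),
      y = c(-4.0, -2.7, -1.45, -1.45, -2.4, -1.45, -3.5, -4.1, -4.3),
      z = 0
    ),
    stop("unknown base: ", base, call. = FALSE)
  )
}

complement_base <- function(base) c(A = "T", T = "A", C = "G", G = "C")[base]

base_ring_atoms <- function(base) {
  if (base %in% c("A", "G")) {
    c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2")
  } else {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  }
}

sugar_ring_atoms <- function() c("C1'", "C2'", "C3'", "C4'", "O4'")

nucleotide_template <- function(base, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  tpl <- dplyr::bind_rows(sugar_template(), base_template(base))
  if (strand == "bottom") tpl$y <- -tpl$y
  tpl$base <- base
  tpl
}

#' Specification of an idealized DNA duplex fixture
#'
#' Describes a straight double helix with uniform per-step rise and twist,
#' plus optional site perturbations applied as rigid rotations: extra
#' untwist at a base-pair step, a hinge bend of given magnitude and
#' direction, and rotation of a base about its backbone pivot (base
#' extrusion). The perturbations are constructed so that the corresponding
#' geometry descriptors recover them exactly, making the builder the
#' ground-truth source for descriptor tests.
#'
#' @param sequence Top-strand base string (A/C/G/T only), 5' to 3'.
#' @param rise Rise per base-pair step in Angstrom.
#' @param twist Helical twist per step in degrees.
#' @param untwist Optional data frame with columns `step`, `degrees`:
#'   extra untwist (subtracted from `twist`) at the given steps. Step k is
#'   between pairs k and k+1.
#' @param bend Optional data frame with columns `hinge`, `degrees`,
#'   `direction`: bend all pairs 3' of the hinge pair by `degrees`, tipping
#'   the 3' arm toward the in-plane direction `direction` (degrees;
#'   0 = toward the minor groove, 180 = toward the major groove).
#' @param extrude Optional data frame with columns `nucleotide`, `degrees`:
#'   rotate the base of the given top-strand nucleotide about the axis
#'   through its own and its 3'-neighbor's sugar centroids.
#' @return A `duplex_spec` list.
#' @examples
#' duplex_spec(strrep("AT", 12), bend = data.frame(
#'   hinge = 12, degrees = 20, direction = 0
#' ))
#' @export
duplex_spec <- function(sequence, rise = 3.4, twist = 36,
                        untwist = NULL, bend = NULL, extrude = NULL) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 1 || !all(bases %in% c("A", "C", "G", "T"))) {
    stop("sequence must be a non-empty A/C/G/T string", call. = FALSE)
  }
  n <- length(bases)
  stopifnot(rise > 0)
  if (!is.null(untwist)) {
    stopifnot(all(c("step", "degrees") %in% names(untwist)))
    if (any(untwist$step < 1 | untwist$step > n - 1)) {
      stop("untwist step index outside the duplex", call. = FALSE)
    }
  }
  if (!is.null(bend)) {
    stopifnot(all(c("hinge", "degrees", "direction") %in% names(bend)))
    if (any(bend$hinge < 2 | bend$hinge > n - 1)) {
      stop("bend hinge index outside the duplex", call. = FALSE)
    }
  }
  if (!is.null(extrude)) {
    stopifnot(all(c("nucleotide", "degrees") %in% names(extrude)))
    if (any(extrude$nucleotide < 1 | extrude$nucleotide > n - 1)) {
      stop("extrusion nucleotide must have a 3' neighbor in the duplex", call. = FALSE)
    }
  }
  structure(
    list(
      bases = bases, rise = rise, twist = twist,
      untwist = untwist, bend = bend, extrude = extrude
    ),
    class = "duplex_spec"
  )
}

rotate_about <- function(xyz, axis, angle_deg, origin) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  p <- sweep(xyz, 2, origin)
  # Rodrigues rotation
  cross_u <- function(v) cbind(
    u[2] * v[, 3] - u[3] * v[, 2],
    u[3] * v[, 1] - u[1] * v[, 3],
    u[1] * v[, 2] - u[2] * v[, 1]
  )
  rot <- p * cos(th) + cross_u(p) * sin(th) +
    outer(as.numeric(p %*% u), u) * (1 - cos(th))
  sweep(rot, 2, origin, `+`)
}

#' Build an idealized DNA duplex with known geometry
#'
#' Constructs atomic coordinates for the duplex described by a
#' [duplex_spec()]: base pairs are planar templates stacked along the
#' global z axis with the specified rise, rotated by the cumulative
#' per-step twist, with the complementary bottom strand generated and the
#' pairing map populated. Perturbations (extra untwist, hinge bend, base
#' extrusion) are applied as rigid rotations, in that order.
#'
#' @param spec A [duplex_spec()].
#' @return A `structure_model` (see [read_structure()]) with one model.
#' @examples
#' dx <- build_duplex(duplex_spec(strrep("GC", 6)))
#' dx
#' @export
build_duplex <- function(spec) {
  stopifnot(inherits(spec, "duplex_spec"))
  bases <- spec$bases
  n <- length(bases)
  step_twists <- rep(spec$twist, max(n - 1, 0))
  if (!is.null(spec$untwist)) {
    for (r in seq_len(nrow(spec$untwist))) {
      step_twists[spec$untwist$step[r]] <-
        step_twists[spec$untwist$step[r]] - spec$untwist$degrees[r]
    }
  }
  phi <- c(0, cumsum(step_twists)) * pi / 180
  origins <- cbind(0, 0, (seq_len(n) - 1) * spec$rise)

  place <- function(tpl, i) {
    cphi <- cos(phi[i])
    sphi <- sin(phi[i])
    gx <- tpl$x * cphi - tpl$y * sphi
    gy <- tpl$x * sphi + tpl$y * cphi
    cbind(gx, gy, tpl$z) + matrix(origins[i, ], nrow(tpl), 3, byrow = TRUE)
  }

  rows <- list()
  coords <- list()
  for (i in seq_len(n)) {
    top <- nucleotide_template(bases[i], "top")
    bot <- nucleotide_template(complement_base(bases[i]), "bottom")
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom = top$atom, base = top$base, chain = "W", resno = i
    )
    coords[[length(coords) + 1]] <- place(top, i)
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom = bot$atom, base = bot$base, chain = "Y", resno = i
    )
    coords[[length(coords) + 1]] <- place(bot, i)
  }
  atoms <- dplyr::bind_rows(rows)
  xyz <- do.call(rbind, coords)

  if (!is.null(spec$bend)) {
    for (r in seq_len(nrow(spec$bend))) {
      h <- spec$bend$hinge[r]
      beta <- spec$bend$degrees[r]
      delta <- spec$bend$direction[r] * pi / 180
      xh <- c(cos(phi[h]), sin(phi[h]), 0)
      yh <- c(-sin(phi[h]), cos(phi[h]), 0)
      zh <- c(0, 0, 1)
      dir_vec <- -cos(delta) * xh + sin(delta) * yh
      axis <- c(
        zh[2] * dir_vec[3] - zh[3] * dir_vec[2],
        zh[3] * dir_vec[1] - zh[1] * dir_vec[3],
        zh[1] * dir_vec[2] - zh[2] * dir_vec[1]
      )
      sel <- atoms$resno > h
      xyz[sel, ] <- rotate_about(xyz[sel, , drop = FALSE], axis, beta, origins[h, ])
    }
  }

  if (!is.null(spec$extrude)) {
    for (r in seq_len(nrow(spec$extrude))) {
      nt <- spec$extrude$nucleotide[r]
      rho <- spec$extrude$degrees[r]
      s_self <- colMeans(xyz[atoms$chain == "W" & atoms$resno == nt &
        atoms$atom %in% sugar_ring_atoms(), , drop = FALSE])
      s_next <- colMeans(xyz[atoms$chain == "W" & atoms$resno == nt + 1 &
        atoms$atom %in% sugar_ring_atoms(), , drop = FALSE])
      sel <- atoms$chain == "W" & atoms$resno == nt &
        !(atoms$atom %in% sugar_ring_atoms())
      xyz[sel, ] <- rotate_about(
        xyz[sel, , drop = FALSE],
        s_self - s_next, rho, s_next
      )
    }
  }

  new_structure_model(
    atoms = atoms,
    coords = list(xyz),
    pairing = tibble::tibble(top_resno = seq_len(n), bottom_resno = seq_len(n)),
    source = spec
  )
}

#' Combine single-model duplexes into an ensemble
#'
#' Stacks structurally identical models (same atoms in the same order)
#' into one multi-model `structure_model`, e.g. a synthetic trajectory of
#' duplexes built at drifting twist.
#'
#' @param models List of `structure_model` objects sharing one atom table.
#' @return A `structure_model` whose `coords` holds one matrix per model.
#' @export
structure_ensemble <- function(models) {
  stopifnot(length(models) >= 1)
  ref <- models[[1]]
  for (m in models[-1]) {
    if (!identical(ref$atoms, m$atoms)) {
      stop("all models must share an identical atom table", call. = FALSE)
    }
  }
  new_structure_model(
    atoms = ref$atoms,
    coords = purrr::flatten(purrr::map(models, "coords")),
    pairing = ref$pairing,
    source = ref$source
  )
}

new_structure_model <- function(atoms, coords, pairing, source = NULL) {
  atoms$element <- substr(atoms$atom, 1, 1)
  structure(
    list(atoms = atoms, coords = coords, pairing = pairing, source = source),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %d atoms, %d base pair(s), %d model(s)\n",
    nrow(x$atoms), nrow(x$pairing), length(x$coords)
  ))
  invisible(x)
}

#' Apply a rigid transform to every model of a structure
#'
#' @param model A `structure_model`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector in Angstrom.
#' @return The transformed `structure_model`.
#' @export
transform_structure <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  model$coords <- purrr::map(model$coords, function(m) {
    sweep(m %*% t(rotation), 2, translation, `+`)
  })
  model
}
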