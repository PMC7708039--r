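#' Write a decay trace as two-column delimited text
#'
#' Writes `time_ns` and `counts` with a '#'-prefixed metadata header
#' recording the acquisition settings, so the file round-trips through
#' [read_decay()].
#'
#' @param trace A `decay_trace`.
#' @param path Output file path.
#' @param delimiter Column delimiter (default tab).
#' @param extra_header Named character vector of extra `# key: value`
#'   header lines (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_decay <- function(trace, path, delimiter = "\t", extra_header = NULL) {
  acq <- attr(trace, "acq")
  hdr <- c(
    "# fretscape decay trace",
    if (!is.null(acq)) {
      sprintf(
        "# window: %.10g\n# n_channels: %d\n# peak_counts: %.10g\n# irf_fwhm: %.10g\n# background_rate: %.10g\n# seed: %d",
        acq$window, acq$n_channels, acq$peak_counts, acq$irf_fwhm,
        acq$background_rate, acq$seed
      )
    },
    if (!is.null(extra_header)) sprintf("# %s: %s", names(extra_header), extra_header),
    "# columns: time_ns, counts"
  )
  body <- paste(
    format(trace$time_ns, digits = 15, trim = TRUE, scientific = FALSE),
    format(trace$counts, digits = 15, trim = TRUE, scientific = FALSE),
    sep = delimiter
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a decay trace from two-column delimited text
#'
#' Expects optional '#'-prefixed header lines followed by rows of
#' `time_ns<delim>counts`. Acquisition metadata written by [write_decay()]
#' is restored. Parse problems (ragged rows, non-numeric cells, negative
#' counts, a non-monotone or unequally spaced time axis) raise errors that
#' name the offending line.
#'
#' @param path Input file path.
#' @param delimiter Column delimiter (default tab; use "," for CSV).
#' @return A `decay_trace` tibble.
#' @export
read_decay <- function(path, delimiter = "\t") {
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  hdr <- lines[is_hdr]
  data_lines <- which(!is_hdr)
  if (length(data_lines) < 2) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(lines[data_lines], delimiter, fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop(sprintf(
      "line %d: expected 2 columns, found %d",
      data_lines[bad[1]], lengths(parts)[bad[1]]
    ), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  nonnum <- which(rowSums(is.na(m)) > 0)
  if (length(nonnum) > 0) {
    stop(sprintf("line %d: non-numeric cell", data_lines[nonnum[1]]), call. = FALSE)
  }
  neg <- which(m[, 2] < 0)
  if (length(neg) > 0) {
    stop(sprintf("line %d: negative count", data_lines[neg[1]]), call. = FALSE)
  }
  dts <- diff(m[, 1])
  if (any(dts <= 0)) {
    stop(sprintf(
      "line %d: time axis not strictly increasing",
      data_lines[which(dts <= 0)[1] + 1]
    ), call. = FALSE)
  }
  if (max(dts) - min(dts) > 1e-6 * mean(dts)) {
    stop("time axis is not equally spaced", call. = FALSE)
  }
  get_meta <- function(key) {
    ln <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (length(ln) == 0) {
      return(NULL)
    }
    as.numeric(sub(sprintf("^#\\s*%s:\\s*", key), "", ln[1]))
  }
  acq <- NULL
  if (!is.null(get_meta("window"))) {
    acq <- acquisition(
      window = get_meta("window"), n_channels = get_meta("n_channels"),
      peak_counts = get_meta("peak_counts"), irf_fwhm = get_meta("irf_fwhm"),
      background_rate = get_meta("background_rate"),
      seed = as.integer(get_meta("seed"))
    )
  }
  out <- new_decay_trace(
    tibble::tibble(time_ns = m[, 1], counts = m[, 2]),
    acq = acq
  )
  attr(out, "header") <- hdr
  out
}

#' Write a lifetime distribution with a JSON diagnostics sidecar
#'
#' The distribution goes to `path` as `tau_ns<TAB>amplitude`; the fit
#' diagnostics go to `paste0(path, ".json")`.
#'
#' @param dist A `lifetime_distribution`.
#' @param path Output path for the delimited table.
#' @param extra Named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path, extra = NULL) {
  writeLines(
    c(
      "# fretscape lifetime distribution",
      "# columns: tau_ns, amplitude",
      paste(
        format(dist$tau_ns, digits = 15, trim = TRUE),
        format(dist$amplitude, digits = 15, trim = TRUE),
        sep = "\t"
      )
    ),
    path
  )
  diag <- attr(dist, "diagnostics")
  jsonlite::write_json(
    c(diag, extra),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a lifetime distribution written by [write_distribution()]
#'
#' @param path Path to the delimited table (the `.json` sidecar is read
#'   when present).
#' @return A `lifetime_distribution`.
#' @export
read_distribution <- function(path) {
  lines <- readLines(path)
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  diag <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) diag <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  new_lifetime_distribution(
    tibble::tibble(tau_ns = m[, 1], amplitude = m[, 2]),
    grid = m[, 1], diagnostics = diag
  )
}

pdb_resid <- function(base) paste0("D", base)

#' Write a structure model as standard PDB
#'
#' Multi-model ensembles are written as MODEL/ENDMDL records. Writing goes
#' through bio3d.
#'
#' @param model A `structure_model`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  atoms <- model$atoms
  xyz_rows <- do.call(rbind, purrr::map(model$coords, function(m) as.numeric(t(m))))
  pdb <- list(
    atom = data.frame(
      type = "ATOM",
      eleno = seq_len(nrow(atoms)),
      elety = atoms$atom,
      alt = NA,
      resid = pdb_resid(atoms$base),
      chain = atoms$chain,
      resno = atoms$resno,
      insert = NA,
      x = model$coords[[1]][, 1],
      y = model$coords[[1]][, 2],
      z = model$coords[[1]][, 3],
      o = 1, b = 0, segid = NA, elesy = atoms$element, charge = NA,
      stringsAsFactors = FALSE
    ),
    xyz = xyz_rows,
    calpha = rep(FALSE, nrow(atoms))
  )
  class(pdb) <- c("pdb")
  bio3d::write.pdb(pdb, file = path, xyz = xyz_rows)
  invisible(path)
}

#' Read a structure model from PDB
#'
#' Parses ATOM/HETATM records (through bio3d), keeping DNA residues
#' (resid A/C/G/T or DA/DC/DG/DT). Multi-MODEL files become coordinate
#' ensembles. The base-pairing map is taken from `pairing` when given, or
#' inferred by a C1'-C1' distance heuristic across the two chains.
#'
#' @param path PDB file path.
#' @param pairing Optional data frame with columns `top_resno`,
#'   `bottom_resno`; inferred when `NULL`.
#' @param chains Length-2 character: top and bottom strand chain ids
#'   (default W and Y).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, pairing = NULL, chains = c("W", "Y")) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  is_dna <- at$resid %in% c("DA", "DC", "DG", "DT", "A", "C", "G", "T")
  if (!any(is_dna)) stop("no DNA residues found in ", path, call. = FALSE)
  keep <- which(is_dna)
  atoms <- tibble::tibble(
    atom = at$elety[keep],
    base = sub("^D", "", at$resid[keep]),
    chain = at$chain[keep],
    resno = at$resno[keep]
  )
  n_models <- nrow(pdb$xyz)
  coords <- purrr::map(seq_len(n_models), function(m) {
    full <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    full[keep, , drop = FALSE]
  })
  model <- new_structure_model(atoms, coords, pairing = tibble::tibble(
    top_resno = integer(0), bottom_resno = integer(0)
  ))
  model$pairing <- if (!is.null(pairing)) {
    tibble::tibble(
      top_resno = as.integer(pairing$top_resno),
      bottom_resno = as.integer(pairing$bottom_resno)
    )
  } else {
    infer_pairing(model, chains)
  }
  model
}

# Pair residues across the two chains by base-edge contact: candidates
# have C1'-C1' distance < 12 A, and among candidates the pair with the
# closest base-base atom contact wins (Watson-Crick partners touch at
# hydrogen-bond range, ~3 A, while neighbors are well separated). Matching
# is globally greedy and one-to-one.
infer_pairing <- function(model, chains = c("W", "Y")) {
  atoms <- model$atoms
  xyz <- model$coords[[1]]
  sugar <- sugar_ring_atoms()
  top_res <- sort(unique(atoms$resno[atoms$chain == chains[1]]))
  bot_res <- sort(unique(atoms$resno[atoms$chain == chains[2]]))
  c1 <- function(chain, resno) {
    sel <- atoms$chain == chain & atoms$resno == resno & atoms$atom == "C1'"
    if (!any(sel)) {
      return(NULL)
    }
    xyz[which(sel)[1], ]
  }
  base_idx <- function(chain, resno) {
    which(atoms$chain == chain & atoms$resno == resno & !(atoms$atom %in% sugar))
  }
  D <- matrix(Inf, length(top_res), length(bot_res))
  for (i in seq_along(top_res)) {
    a <- c1(chains[1], top_res[i])
    bi <- base_idx(chains[1], top_res[i])
    if (is.null(a) || length(bi) == 0) next
    for (j in seq_along(bot_res)) {
      b <- c1(chains[2], bot_res[j])
      bj <- base_idx(chains[2], bot_res[j])
      if (is.null(b) || length(bj) == 0) next
      if (sqrt(sum((a - b)^2)) >= 12) next
      d2 <- outer(rowSums(xyz[bi, , drop = FALSE]^2),
        rowSums(xyz[bj, , drop = FALSE]^2), `+`
      ) - 2 * tcrossprod(xyz[bi, , drop = FALSE], xyz[bj, , drop = FALSE])
      D[i, j] <- sqrt(max(min(d2), 0))
    }
  }
  out <- list()
  while (any(is.finite(D)) && min(D) < 5) {
    ij <- arrayInd(which.min(D), dim(D))
    out[[length(out) + 1]] <- tibble::tibble(
      top_resno = top_res[ij[1]], bottom_resno = bot_res[ij[2]]
    )
    D[ij[1], ] <- Inf
    D[, ij[2]] <- Inf
  }
  if (length(out) == 0) {
    stop("could not infer any base pairs from C1' distances", call. = FALSE)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$top_resno)
}
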