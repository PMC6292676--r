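# Per-frame geometric observables: pair distances, side-chain COM salt
# bridges, residue-nucleic-acid contacts.

SIDECHAIN_ACID_O <- list(
  ASP = c("OD1", "OD2"), ASH = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"), GLH = c("OE1", "OE2")
)
SIDECHAIN_BASE_N <- list(
  LYS = "NZ", LYN = "NZ",
  ARG = c("NH1", "NH2", "NE"),
  HIS = c("ND1", "NE2"), HID = c("ND1", "NE2"),
  HIE = c("ND1", "NE2"), HIP = c("ND1", "NE2")
)

# Default salt-bridge strength bins (Angstrom, COM-COM upper bounds).
#' Salt-bridge strength bins
#'
#' Upper COM-COM distance bounds (Angstrom) for the strong/medium/weak
#' classes; anything beyond the last bound is classed `"none"`. These are
#' exposed defaults, not fixed constants.
#' @export
salt_bridge_bins <- c(strong = 3.5, medium = 4.5, weak = 6.0)

classify_salt_bridge <- function(d, bins = salt_bridge_bins) {
  cls <- cut(
    d,
    breaks = c(-Inf, bins, Inf),
    labels = c(names(bins), "none"),
    right = TRUE
  )
  factor(as.character(cls), levels = c(names(bins), "none"))
}

# centroid (unweighted) of a selection, per frame -> F x 3
selection_centroid <- function(traj, sel, weights = NULL) {
  if (length(sel) == 0) abort("empty selection")
  if (is.null(weights)) weights <- rep(1, length(sel))
  w <- weights / sum(weights)
  out <- matrix(0, n_frames(traj), 3)
  for (i in seq_along(sel)) {
    out <- out + w[i] * atom_coords(traj, sel[i])
  }
  out
}

#' Distance between two selections over a trajectory
#'
#' Euclidean distance per frame between the centroids of two atom
#' selections (single atoms give plain atom-atom distances). No periodic
#' imaging is applied: trajectories are assumed pre-imaged with the solute
#' whole.
#'
#' @param traj An `mdtrajectory`.
#' @param a,b Atom index vectors (see [select_atoms()]); multi-atom
#'   selections use their (unweighted) centroid.
#' @param id Monitor label stored with the series.
#' @return A tibble of class `distance_series` with columns `frame`,
#'   `time_ns`, `distance` (Angstrom).
#' @export
pair_distance_series <- function(traj, a, b, id = "distance") {
  ca <- selection_centroid(traj, a)
  cb <- selection_centroid(traj, b)
  d <- sqrt(rowSums((ca - cb)^2))
  out <- tibble::tibble(
    frame = seq_len(n_frames(traj)),
    time_ns = traj$times,
    distance = d
  )
  attr(out, "monitor") <- list(id = id, a = a, b = b)
  class(out) <- c("distance_series", class(out))
  out
}

sidechain_group <- function(x, chain, resno, role) {
  x <- as_structure(x)
  sel0 <- select_atoms(x, chain = chain, resno = resno)
  if (length(sel0) == 0) {
    abort(sprintf("residue %s:%s not found", chain, resno))
  }
  resid <- x$atoms$resid[sel0[1]]
  groups <- if (role == "acidic") SIDECHAIN_ACID_O else SIDECHAIN_BASE_N
  names_ok <- groups[[resid]]
  if (is.null(names_ok)) {
    abort(sprintf(
      "residue %s %s:%s is not a valid %s residue",
      resid, chain, resno, role
    ))
  }
  sel <- sel0[x$atoms$elety[sel0] %in% names_ok]
  if (length(sel) < length(names_ok)) {
    abort(sprintf(
      "residue %s %s:%s is missing side-chain atoms (%s)",
      resid, chain, resno,
      paste(setdiff(names_ok, x$atoms$elety[sel]), collapse = ", ")
    ))
  }
  sel
}

#' Salt-bridge distance series for an acidic/basic residue pair
#'
#' The salt-bridge coordinate is the distance between the mass-weighted
#' centre of mass of the carboxylate oxygens of the acidic side chain
#' (Asp OD1/OD2, Glu OE1/OE2) and the centre of mass of the nitrogen group
#' of the basic side chain (Lys NZ; Arg NH1/NH2/NE; His ND1/NE2). A strength
#' class is assigned per frame from the distance bins in `bins`.
#'
#' @param traj An `mdtrajectory`.
#' @param acidic,basic `list(chain = , resno = )` residue identifiers.
#' @param bins Named increasing distance bounds, see [salt_bridge_bins].
#' @return A tibble of class `salt_bridge_series` with columns `frame`,
#'   `time_ns`, `distance`, `strength`.
#' @export
salt_bridge_series <- function(traj, acidic, basic, bins = salt_bridge_bins) {
  sa <- sidechain_group(traj, acidic$chain, acidic$resno, "acidic")
  sb <- sidechain_group(traj, basic$chain, basic$resno, "basic")
  top <- traj$topology
  ca <- selection_centroid(traj, sa, weights = atom_masses(top, sa))
  cb <- selection_centroid(traj, sb, weights = atom_masses(top, sb))
  d <- sqrt(rowSums((ca - cb)^2))
  out <- tibble::tibble(
    frame = seq_len(n_frames(traj)),
    time_ns = traj$times,
    distance = d,
    strength = classify_salt_bridge(d, bins)
  )
  attr(out, "monitor") <- list(acidic = acidic, basic = basic, bins = bins)
  class(out) <- c("salt_bridge_series", class(out))
  out
}

#' Scan for salt bridges between two domains
#'
#' Enumerates every acidic x basic residue pair across two domains and keeps
#' the pairs whose COM-COM distance is within `form_cutoff` in at least
#' `min_occupancy` of the frames. Pairs with missing side-chain atoms are
#' reported and skipped.
#'
#' @param traj An `mdtrajectory`.
#' @param domains A `domain_assignment` (see [resolve_domains()]).
#' @param domain_a,domain_b Domain names to scan between.
#' @param form_cutoff Formation cutoff in Angstrom (default 4.5).
#' @param min_occupancy Minimum fraction of frames within cutoff (default 0.5).
#' @param bins Strength bins, see [salt_bridge_bins].
#' @return A tibble with one row per retained pair (`acidic_resno`,
#'   `basic_resno`, residue names, `occupancy`, `mean_distance`,
#'   `min_distance`, and a `series` list-column), sorted by decreasing
#'   occupancy; ties broken by residue numbers.
#' @export
scan_salt_bridges <- function(traj, domains, domain_a, domain_b,
                              form_cutoff = 4.5, min_occupancy = 0.5,
                              bins = salt_bridge_bins) {
  stopifnot(form_cutoff > 0)
  for (d in c(domain_a, domain_b)) {
    if (!d %in% names(domains)) abort(paste0("unknown domain: ", d))
  }
  top <- traj$topology
  residues_of <- function(d) {
    tibble::tibble(
      chain = domains[[d]]$chain, resno = domains[[d]]$resno,
      resid = top$atoms$resid[domains[[d]]$atoms]
    )
  }
  ra <- residues_of(domain_a)
  rb <- residues_of(domain_b)
  acid_names <- names(SIDECHAIN_ACID_O)
  base_names <- names(SIDECHAIN_BASE_N)
  # acidic in A vs basic in B, plus basic in A vs acidic in B
  pairs <- dplyr::bind_rows(
    tidyr::crossing(
      a = which(ra$resid %in% acid_names), b = which(rb$resid %in% base_names)
    ) |>
      dplyr::mutate(
        acid_chain = ra$chain[.data$a], acid_resno = ra$resno[.data$a],
        base_chain = rb$chain[.data$b], base_resno = rb$resno[.data$b]
      ),
    tidyr::crossing(
      a = which(rb$resid %in% acid_names), b = which(ra$resid %in% base_names)
    ) |>
      dplyr::mutate(
        acid_chain = rb$chain[.data$a], acid_resno = rb$resno[.data$a],
        base_chain = ra$chain[.data$b], base_resno = ra$resno[.data$b]
      )
  )
  if (nrow(pairs) == 0) {
    return(empty_salt_bridge_table())
  }
  rows <- purrr::pmap(pairs, function(a, b, acid_chain, acid_resno,
                                      base_chain, base_resno) {
    ser <- tryCatch(
      salt_bridge_series(
        traj,
        acidic = list(chain = acid_chain, resno = acid_resno),
        basic = list(chain = base_chain, resno = base_resno),
        bins = bins
      ),
      error = function(e) {
        inform(paste0("skipping pair ", acid_resno, "-", base_resno, ": ",
                      conditionMessage(e)))
        NULL
      }
    )
    if (is.null(ser)) {
      return(NULL)
    }
    occ <- mean(ser$distance <= form_cutoff)
    tibble::tibble(
      acidic_resno = acid_resno, basic_resno = base_resno,
      acidic_chain = acid_chain, basic_chain = base_chain,
      occupancy = occ,
      mean_distance = mean(ser$distance),
      min_distance = min(ser$distance),
      series = list(ser)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(empty_salt_bridge_table())
  }
  out <- dplyr::filter(out, .data$occupancy >= min_occupancy)
  dplyr::arrange(
    out, dplyr::desc(.data$occupancy), .data$acidic_resno, .data$basic_resno
  )
}

empty_salt_bridge_table <- function() {
  tibble::tibble(
    acidic_resno = integer(0), basic_resno = integer(0),
    acidic_chain = character(0), basic_chain = character(0),
    occupancy = numeric(0), mean_distance = numeric(0),
    min_distance = numeric(0), series = list()
  )
}

#' Nearest-partner contact series for one residue
#'
#' Per frame, the minimum heavy-atom distance between one residue's side
#' chain (plus Cα) and a partner selection (typically a nucleic-acid
#' chain), together with the partner residue achieving the minimum. Ties are
#' broken toward the lowest partner residue number. A residue monitored
#' against its own atoms legitimately reports 0.
#'
#' @param traj An `mdtrajectory`.
#' @param residue `list(chain = , resno = )` residue identifier.
#' @param partner Atom index vector for the partner (e.g. a DNA chain).
#' @return A tibble of class `contact_series` with columns `frame`,
#'   `time_ns`, `min_distance`, `partner_resno`, `partner_chain`.
#' @export
contact_series <- function(traj, residue, partner) {
  if (length(partner) == 0) abort("empty partner selection")
  top <- traj$topology
  sel <- select_atoms(top, chain = residue$chain, resno = residue$resno)
  sel <- sel[top$atoms$elem[sel] != "H"]
  if (length(sel) == 0) {
    abort(sprintf("residue %s:%s has no heavy atoms",
                  residue$chain, residue$resno))
  }
  partner <- partner[top$atoms$elem[partner] != "H"]
  p_resno <- top$atoms$resno[partner]
  p_chain <- top$atoms$chain[partner]
  f <- n_frames(traj)
  min_d <- numeric(f)
  arg_res <- integer(f)
  arg_ch <- character(f)
  # order partner atoms by residue number so which.min tie-breaks low resno
  ord <- order(p_resno, p_chain)
  partner <- partner[ord]
  p_resno <- p_resno[ord]
  p_chain <- p_chain[ord]
  pcols <- xyz_cols(partner)
  scols <- xyz_cols(sel)
  for (fr in seq_len(f)) {
    pm <- matrix(traj$xyz[fr, pcols], ncol = 3, byrow = TRUE)
    sm <- matrix(traj$xyz[fr, scols], ncol = 3, byrow = TRUE)
    # pairwise distances residue atoms x partner atoms
    d2 <- outer(rowSums(sm^2), rowSums(pm^2), "+") - 2 * sm %*% t(pm)
    dmin_per_partner <- sqrt(pmax(apply(d2, 2, min), 0))
    j <- which.min(dmin_per_partner)
    min_d[fr] <- dmin_per_partner[j]
    arg_res[fr] <- p_resno[j]
    arg_ch[fr] <- p_chain[j]
  }
  out <- tibble::tibble(
    frame = seq_len(f), time_ns = traj$times,
    min_distance = min_d, partner_resno = arg_res, partner_chain = arg_ch
  )
  attr(out, "monitor") <- list(residue = residue)
  class(out) <- c("contact_series", class(out))
  out
}

#' Smooth a monitor series with a centered moving average
#'
#' Adds a `smoothed` column; endpoints use truncated windows so the series
#' keeps its length and the raw values stay untouched.
#'
#' @param series A series tibble with a `distance` (or `min_distance`)
#'   column.
#' @param window Odd window width in frames, `1 <= window <= F`.
#' @return The input tibble with a `smoothed` column added.
#' @export
smooth_series <- function(series, window) {
  value_col <- if ("distance" %in% names(series)) "distance" else "min_distance"
  v <- series[[value_col]]
  f <- length(v)
  if (window < 1 || window > f || window %% 2 == 0) {
    abort("window must be odd and within 1..F")
  }
  half <- (window - 1) / 2
  sm <- vapply(seq_len(f), function(i) {
    mean(v[max(1, i - half):min(f, i + half)])
  }, numeric(1))
  series$smoothed <- sm
  series
}

#' Write a monitor series to CSV
#'
#' @param series A monitor series tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
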