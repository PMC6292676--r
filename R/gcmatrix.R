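# Generalized-correlation matrices and coupling scores.

#' Generalized correlation matrix of Cα motions
#'
#' For every pair of selected residues, estimates the mutual information
#' between their 3-D Cα displacement vectors (coordinates minus their time
#' mean, after superposition) with the Kraskov k-NN estimator, and maps it
#' to the generalized correlation coefficient
#' `r_MI = sqrt(1 - exp(-2 I / 3))`. Unlike a Pearson cross-correlation
#' map, `r_MI` captures non-linear and orthogonal correlated motions, and
#' lives on an absolute `[0, 1]` scale.
#'
#' The trajectory must be superposed first ([superpose()]); a residual drift
#' of the selection centroid beyond `drift_tol` triggers a warning, since
#' global motion masquerades as correlation.
#'
#' @param traj An `mdtrajectory`.
#' @param sel Atom indices (one per residue); defaults to all protein Cα.
#' @param k Neighbour count of the MI estimator (default 6).
#' @param stride Keep every `stride`-th frame (default 1).
#' @param jitter_seed Seed of the deterministic tie-breaking jitter.
#' @param drift_tol Centroid drift tolerance in Angstrom (default 1).
#' @return An object of class `gc_matrix`: `gc` (symmetric N x N matrix in
#'   `[0, 1]`, unit diagonal), `resno`, `chain`, and estimator metadata
#'   (`k`, `stride`, `n_frames`, `jitter_seed`).
#' @export
gc_matrix <- function(traj, sel = NULL, k = 6, stride = 1,
                      jitter_seed = 42, drift_tol = 1.0) {
  stopifnot(inherits(traj, "mdtrajectory"))
  sel <- sel %||% protein_ca_indices(traj$topology)
  if (length(sel) < 2) abort("need at least 2 residues")
  keep <- seq(1, n_frames(traj), by = stride)
  if (length(keep) < k + 2) abort("too few frames after striding (need k + 2)")
  cols <- xyz_cols(sel)
  x <- traj$xyz[keep, cols, drop = FALSE]

  # net drift of the selection centroid flags unremoved global motion
  # (skipped when the trajectory is marked superposed, e.g. by superpose()
  # or by a generator that draws displacements in a fixed frame)
  if (!isTRUE(attr(traj, "superposed"))) {
    com <- sapply(1:3, function(ax) {
      rowMeans(x[, seq(ax, ncol(x), by = 3), drop = FALSE])
    })
    drift <- max(sqrt(rowSums(sweep(com, 2, colMeans(com))^2)))
    if (drift > drift_tol) {
      warn(sprintf(
        "selection centroid drifts %.2f A across frames; superpose() first?",
        drift
      ))
    }
  }

  d <- sweep(x, 2, colMeans(x))
  if (any(apply(d, 2, sd) == 0)) {
    abort("degenerate input: a coordinate has zero variance across frames")
  }
  d <- add_tie_jitter(standardize_columns(d), jitter_seed)
  mi <- .ksg_mi_allpairs_cpp(d, length(sel), as.integer(k))
  mi[mi < 0] <- 0
  gc <- gc_coefficient(mi, d = 3)
  diag(gc) <- 1
  resno <- traj$topology$atoms$resno[sel]
  dimnames(gc) <- list(resno, resno)
  structure(
    list(
      gc = gc,
      resno = resno,
      chain = traj$topology$atoms$chain[sel],
      k = k, stride = stride, n_frames = length(keep),
      jitter_seed = jitter_seed
    ),
    class = "gc_matrix"
  )
}

#' Wrap a plain coefficient matrix as a `gc_matrix`
#'
#' Useful for hand-built matrices in tests and small worked examples.
#'
#' @param m Symmetric numeric matrix with entries in `[0, 1]`.
#' @param resno Residue numbers (default `1:N`).
#' @param chain Chain ids (default `"A"`).
#' @return A `gc_matrix`.
#' @export
as_gc_matrix <- function(m, resno = seq_len(nrow(m)), chain = "A") {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), max(abs(m - t(m))) < 1e-12,
            all(m >= 0 & m <= 1))
  diag(m) <- 1
  dimnames(m) <- list(resno, resno)
  structure(
    list(
      gc = m, resno = as.integer(resno),
      chain = rep_len(chain, nrow(m)),
      k = NA_integer_, stride = NA_integer_, n_frames = NA_integer_,
      jitter_seed = NA_integer_
    ),
    class = "gc_matrix"
  )
}

#' @export
print.gc_matrix <- function(x, ...) {
  off <- x$gc[upper.tri(x$gc)]
  cat(
    "<gc_matrix> ", nrow(x$gc), " residues",
    if (!is.na(x$n_frames)) paste0(", ", x$n_frames, " frames, k = ", x$k),
    "; off-diagonal GC: median ", sprintf("%.3f", stats::median(off)),
    ", max ", sprintf("%.3f", max(off)), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn gc_matrix Long-format tibble of the unique residue pairs.
#' @param x An object.
#' @param ... Unused.
#' @method tidy gc_matrix
#' @export
tidy.gc_matrix <- function(x, ...) {
  n <- nrow(x$gc)
  idx <- which(upper.tri(x$gc), arr.ind = TRUE)
  tibble::tibble(
    resno_i = x$resno[idx[, 1]],
    resno_j = x$resno[idx[, 2]],
    gc = x$gc[idx]
  )
}

#' @describeIn gc_matrix Heatmap of the coefficient matrix.
#' @param object A `gc_matrix`.
#' @method autoplot gc_matrix
#' @export
autoplot.gc_matrix <- function(object, ...) {
  df <- expand.grid(i = object$resno, j = object$resno)
  df$gc <- as.vector(object$gc)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$gc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "residue", y = "residue", fill = expression(r[MI]),
      title = "Generalized correlation matrix"
    ) +
    ggplot2::theme_minimal()
}

#' Per-residue generalized correlation score
#'
#' Sums, for each residue i, the coefficients `GC_ij` over all partners
#' `j != i` whose coefficient passes the threshold — a measure of both the
#' number and the intensity of a residue's strong couplings. The default
#' threshold 0.60 filters out the noise floor of weakly correlated motion.
#' The score is bounded by `N - 1` and is monotone non-increasing in the
#' threshold.
#'
#' @param gcm A `gc_matrix` (or plain symmetric matrix).
#' @param threshold Minimum coefficient to count (default 0.6).
#' @return A tibble with columns `resno`, `gcs`, `n_partners` and the
#'   threshold recorded in `attr(, "threshold")`.
#' @export
per_residue_gcs <- function(gcm, threshold = 0.6) {
  if (!inherits(gcm, "gc_matrix")) gcm <- as_gc_matrix(gcm)
  stopifnot(threshold >= 0, threshold <= 1)
  m <- gcm$gc
  diag(m) <- NA
  pass <- !is.na(m) & m >= threshold
  out <- tibble::tibble(
    resno = gcm$resno,
    gcs = unname(rowSums(m * pass, na.rm = TRUE)),
    n_partners = unname(rowSums(pass))
  )
  attr(out, "threshold") <- threshold
  out
}

#' Inter-domain coupling scores
#'
#' Aggregates a generalized-correlation matrix over a domain map: for each
#' pair of domains, the coefficients of the cross-domain residue pairs that
#' pass the threshold are accumulated and normalized, giving a score from 0
#' (uncorrelated domains) to 1 (fully correlated). With
#' `normalization = "pairs"` (the default) the sum is divided by the number
#' of qualifying residue pairs, which keeps the score in `[0, 1]` and below
#' the largest qualifying coefficient; `"residues"` divides by the number of
#' distinct residues participating in qualifying pairs instead. Diagonal
#' cells aggregate intra-domain pairs (`i != j`) when `include_intra` is
#' `TRUE`.
#'
#' @param gcm A `gc_matrix` (or plain symmetric matrix).
#' @param domains A `domain_assignment` (see [resolve_domains()]) or a named
#'   list of residue-number vectors.
#' @param threshold Minimum coefficient (default 0.6).
#' @param normalization `"pairs"` or `"residues"` (see above).
#' @param include_intra Fill diagonal cells from intra-domain pairs
#'   (default `TRUE`).
#' @return An object of class `domain_scores`: `scores` (symmetric D x D
#'   matrix), `n_pairs` (qualifying-pair counts), `threshold`,
#'   `normalization`, and the domain map hash in `map_hash`.
#' @export
domain_coupling_scores <- function(gcm, domains, threshold = 0.6,
                                   normalization = c("pairs", "residues"),
                                   include_intra = TRUE) {
  if (!inherits(gcm, "gc_matrix")) gcm <- as_gc_matrix(gcm)
  normalization <- match.arg(normalization)
  idx <- domain_gc_indices(gcm, domains)
  nd <- length(idx)
  scores <- matrix(0, nd, nd, dimnames = list(names(idx), names(idx)))
  npairs <- matrix(0L, nd, nd, dimnames = dimnames(scores))
  m <- gcm$gc
  for (a in seq_len(nd)) {
    for (b in seq_len(a)) {
      if (a == b && !include_intra) next
      sub <- m[idx[[a]], idx[[b]], drop = FALSE]
      if (a == b) {
        vals <- sub[upper.tri(sub)]
        ij <- which(upper.tri(sub), arr.ind = TRUE)
      } else {
        vals <- as.vector(sub)
        ij <- which(!is.na(sub), arr.ind = TRUE)
      }
      q <- vals >= threshold
      npairs[a, b] <- npairs[b, a] <- sum(q)
      if (any(q)) {
        denom <- if (normalization == "pairs") {
          sum(q)
        } else {
          length(unique(c(idx[[a]][ij[q, 1]], idx[[b]][ij[q, 2]])))
        }
        scores[a, b] <- scores[b, a] <- sum(vals[q]) / denom
      }
    }
  }
  structure(
    list(
      scores = scores, n_pairs = npairs,
      threshold = threshold, normalization = normalization,
      map_hash = rlang::hash(lapply(idx, function(i) gcm$resno[i]))
    ),
    class = "domain_scores"
  )
}

# Map domains to row indices of the GC matrix.
domain_gc_indices <- function(gcm, domains) {
  key <- paste(gcm$chain, gcm$resno)
  if (inherits(domains, "domain_assignment")) {
    idx <- lapply(domains, function(d) {
      which(key %in% paste(d$chain, d$resno))
    })
  } else {
    stopifnot(!is.null(names(domains)))
    idx <- lapply(domains, function(r) which(gcm$resno %in% r))
  }
  empty <- names(idx)[lengths(idx) == 0]
  if (length(empty) > 0) {
    abort(paste0(
      "domain(s) with no residues in the GC matrix: ",
      paste(empty, collapse = ", ")
    ))
  }
  idx
}

#' @export
print.domain_scores <- function(x, ...) {
  cat("<domain_scores> threshold ", x$threshold, ", normalization ",
      x$normalization, "\n", sep = "")
  print(round(x$scores, 3))
  invisible(x)
}

#' @describeIn domain_coupling_scores Long-format tibble (unique domain
#'   pairs, including diagonal cells).
#' @param x An object.
#' @param ... Unused.
#' @method tidy domain_scores
#' @export
tidy.domain_scores <- function(x, ...) {
  nd <- nrow(x$scores)
  idx <- which(upper.tri(x$scores, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    domain_a = rownames(x$scores)[idx[, 1]],
    domain_b = colnames(x$scores)[idx[, 2]],
    score = x$scores[idx],
    n_pairs = x$n_pairs[idx]
  )
}

#' @describeIn domain_coupling_scores Tile plot of the score matrix.
#' @param object A `domain_scores`.
#' @method autoplot domain_scores
#' @export
autoplot.domain_scores <- function(object, ...) {
  df <- expand.grid(
    domain_a = rownames(object$scores), domain_b = colnames(object$scores)
  )
  df$score <- as.vector(object$scores)
  ggplot2::ggplot(df, ggplot2::aes(.data$domain_a, .data$domain_b,
                                   fill = .data$score)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$score)
    ), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "GCs",
                  title = "Inter-domain coupling scores") +
    ggplot2::theme_minimal()
}
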