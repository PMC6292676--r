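# Domain maps: named residue ranges resolved against a topology.

#' Build a domain map
#'
#' A domain map names protein regions (e.g. REC1-3, HNH, RuvC, PI) as lists
#' of 1-based inclusive residue ranges on a chain. Author numbering from the
#' PDB file is used as-is; no renumbering ever happens. Domains must be
#' pairwise disjoint.
#'
#' @param entries Either a named list — `list(HNH = list(chain = "A",
#'   ranges = list(c(775, 908))), ...)` — or a data frame with columns
#'   `domain`, `chain`, `start`, `end` (one row per range).
#' @return A tibble of class `domain_map` with columns `domain`, `chain`,
#'   `start`, `end`.
#' @seealso [resolve_domains()], [spycas9_domain_map()]
#' @export
domain_map <- function(entries) {
  if (is.data.frame(entries)) {
    tab <- tibble::as_tibble(entries)[, c("domain", "chain", "start", "end")]
  } else {
    stopifnot(length(entries) >= 1, !is.null(names(entries)))
    tab <- purrr::map_dfr(names(entries), function(nm) {
      e <- entries[[nm]]
      ranges <- e$ranges
      if (is.numeric(ranges)) ranges <- list(ranges)
      stopifnot(length(ranges) >= 1)
      purrr::map_dfr(ranges, function(r) {
        r <- unlist(r)
        tibble::tibble(
          domain = nm, chain = e$chain %||% "A",
          start = as.integer(r[1]), end = as.integer(r[2])
        )
      })
    })
  }
  if (any(tab$end < tab$start)) abort("domain range with end < start")
  check_domain_overlap(tab)
  class(tab) <- c("domain_map", class(tab))
  tab
}

check_domain_overlap <- function(tab) {
  for (ch in unique(tab$chain)) {
    sub <- tab[tab$chain == ch, ]
    covered <- integer(0)
    owner <- character(0)
    for (i in seq_len(nrow(sub))) {
      r <- seq(sub$start[i], sub$end[i])
      hit <- r %in% covered
      if (any(hit)) {
        other <- unique(owner[match(r[hit], covered)])
        other <- setdiff(other, sub$domain[i])
        if (length(other) > 0) {
          abort(sprintf(
            "domains %s and %s overlap on chain %s",
            sub$domain[i], other[1], ch
          ))
        }
      }
      covered <- c(covered, r)
      owner <- c(owner, rep(sub$domain[i], length(r)))
    }
  }
  invisible(tab)
}

#' Default domain map for S. pyogenes Cas9
#'
#' Residue intervals follow the domain annotations commonly used for the
#' DNA-bound SpyCas9 complex (author numbering of the 5F9R deposition):
#' REC1 94-179 and 308-496, REC2 180-307, REC3 497-713, HNH 775-908,
#' RuvC 1-59 / 718-774 / 909-1098 (three discontinuous segments), the
#' PAM-interacting region 1099-1368, and the bridge helix (BH, 60-93) kept
#' as its own entry rather than pooled with RuvC. The boundaries are a
#' documented default, not a fact of the algorithm: every score records the
#' map that produced it, and any user map can be supplied instead.
#'
#' @param chain Protein chain id (default `"A"`).
#' @param include_bh Keep the bridge helix as a separate `BH` domain
#'   (default `TRUE`); with `FALSE` it is pooled into RuvC.
#' @return A `domain_map`.
#' @export
spycas9_domain_map <- function(chain = "A", include_bh = TRUE) {
  ruvc <- list(c(1, 59), c(718, 774), c(909, 1098))
  if (!include_bh) ruvc <- c(ruvc[1], list(c(60, 93)), ruvc[2:3])
  entries <- list(
    REC1 = list(chain = chain, ranges = list(c(94, 179), c(308, 496))),
    REC2 = list(chain = chain, ranges = list(c(180, 307))),
    REC3 = list(chain = chain, ranges = list(c(497, 713))),
    HNH = list(chain = chain, ranges = list(c(775, 908))),
    RuvC = list(chain = chain, ranges = ruvc),
    PI = list(chain = chain, ranges = list(c(1099, 1368)))
  )
  if (include_bh) {
    entries$BH <- list(chain = chain, ranges = list(c(60, 93)))
  }
  domain_map(entries)
}

#' Read a domain map from a YAML config
#'
#' Accepts either a top-level `domains:` mapping or a bare mapping of
#' `name: {chain: ..., ranges: [[a, b], ...]}` entries.
#'
#' @param path YAML file path.
#' @return A `domain_map`.
#' @export
read_domain_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  domain_map(cfg$domains %||% cfg)
}

#' Resolve a domain map against a topology
#'
#' Maps every domain to the indices of its protein Cα atoms, failing loudly
#' on overlapping domains or ranges that contain no Cα atom.
#'
#' @param map A `domain_map` (or anything [domain_map()] accepts).
#' @param x An `mdstruct` or `mdtrajectory`.
#' @return A named list (class `domain_assignment`); each element holds
#'   `atoms` (Cα atom indices), `resno` and `chain`.
#' @export
resolve_domains <- function(map, x) {
  if (!inherits(map, "domain_map")) map <- domain_map(map)
  x <- as_structure(x)
  out <- lapply(split(map, map$domain), function(sub) {
    atoms <- integer(0)
    for (i in seq_len(nrow(sub))) {
      idx <- select_atoms(
        x, chain = sub$chain[i],
        resno = seq(sub$start[i], sub$end[i]), elety = "CA", het = FALSE
      )
      if (length(idx) == 0) {
        abort(sprintf(
          "domain %s: range %d-%d (chain %s) matches no C-alpha atom",
          sub$domain[1], sub$start[i], sub$end[i], sub$chain[i]
        ))
      }
      atoms <- c(atoms, idx)
    }
    atoms <- sort(unique(atoms))
    list(
      atoms = atoms,
      resno = x$atoms$resno[atoms],
      chain = x$atoms$chain[atoms]
    )
  })
  out <- out[unique(map$domain)]
  structure(out, class = "domain_assignment", map = map)
}
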