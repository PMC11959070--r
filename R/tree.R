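#' Build a validated arterial tree
#'
#' Assembles the simulated physical system: tapered elastic segments in a
#' rooted branching topology, each leaf closed by a three-element Windkessel
#' terminal, plus named measurement sites (e.g. `aortic_root`,
#' `left_brachial`, `carotid`, `femoral`) located along segments.
#'
#' Segment wall mechanics follow a distensible tube law anchored at a
#' reference pressure: with `nonlinearity = 0` the cross-sectional area is
#' linear in pressure, `A(P) = A_ref (1 + D (P - P_ref))`, where `D` is the
#' distensibility in 1e-3/mmHg; a positive `nonlinearity` switches to an
#' exponentially stiffening law with the same slope at `P_ref`.
#'
#' @param config a list with elements `segments` (data frame: `id`, `parent`
#'   (`NA` for the root), `length_cm`, `din_cm`, `dout_cm`, `distensibility`
#'   in 1e-3/mmHg, optional `nonlinearity`), `terminals` (data frame:
#'   `segment`, `r1`, `r2` in mmHg s/mL, `c` in mL/mmHg, `pout` in mmHg),
#'   `sites` (data frame: `site`, `segment`, `position` in \[0, 1\]) and
#'   `reference` (list: `pressure_mmhg`, `aortic_distensibility`,
#'   `height_cm`).
#' @param dx_cm target spatial grid spacing (cm); each segment gets at least
#'   3 grid points.
#' @return an object of class `arterial_tree`.
#' @export
arterial_tree <- function(config, dx_cm = 1.5) {
  segs <- as_tibble(config$segments)
  needed <- c("id", "parent", "length_cm", "din_cm", "dout_cm", "distensibility")
  miss <- setdiff(needed, names(segs))
  if (length(miss) > 0) {
    abort(paste0("segment table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"nonlinearity" %in% names(segs)) segs$nonlinearity <- 0
  segs$nonlinearity[is.na(segs$nonlinearity)] <- 0
  if (anyDuplicated(segs$id)) abort("duplicate segment ids")

  for (col in c("length_cm", "din_cm", "dout_cm", "distensibility")) {
    bad <- which(!is.finite(segs[[col]]) | segs[[col]] <= 0)
    if (length(bad) > 0) {
      abort(paste0(
        "segment '", segs$id[bad[1]], "': non-positive ", col,
        " (", segs[[col]][bad[1]], ")"
      ))
    }
  }

  root <- segs$id[is.na(segs$parent)]
  if (length(root) != 1) {
    abort(paste0("topology must have exactly one root, found ", length(root)))
  }
  known <- segs$parent[!is.na(segs$parent)]
  bad_parent <- setdiff(known, segs$id)
  if (length(bad_parent) > 0) {
    abort(paste0("unknown parent segment(s): ", paste(bad_parent, collapse = ", ")))
  }

  # cycle / reachability check: walk up from every segment
  for (i in seq_len(nrow(segs))) {
    seen <- character(0)
    cur <- segs$id[i]
    while (!is.na(cur)) {
      if (cur %in% seen) abort(paste0("cycle in topology at segment '", cur, "'"))
      seen <- c(seen, cur)
      cur <- segs$parent[match(cur, segs$id)]
    }
  }

  term <- as_tibble(config$terminals)
  leaves <- setdiff(segs$id, known)
  no_term <- setdiff(leaves, term$segment)
  if (length(no_term) > 0) {
    abort(paste0("leaf segment(s) without terminal: ", paste(no_term, collapse = ", ")))
  }
  stray <- setdiff(term$segment, leaves)
  if (length(stray) > 0) {
    abort(paste0("terminal attached to non-leaf segment(s): ",
                 paste(stray, collapse = ", ")))
  }
  if (any(term$r1 < 0) || any(term$r2 <= 0)) {
    abort("terminal resistances must satisfy r1 >= 0, r2 > 0")
  }
  if (any(term$c <= 0)) abort("terminal compliances must be > 0")
  if (any(term$pout < 0)) abort("terminal outflow pressure must be >= 0")

  sites <- as_tibble(config$sites)
  bad_site <- setdiff(sites$segment, segs$id)
  if (length(bad_site) > 0) {
    abort(paste0("site(s) on unknown segment: ", paste(bad_site, collapse = ", ")))
  }
  if (any(sites$position < 0 | sites$position > 1)) {
    abort("site positions must lie in [0, 1]")
  }

  ref <- config$reference
  if (is.null(ref)) ref <- list()
  ref$pressure_mmhg <- ref$pressure_mmhg %||% 90
  ref$aortic_distensibility <- ref$aortic_distensibility %||%
    segs$distensibility[segs$id == root]
  ref$height_cm <- ref$height_cm %||% 180

  segs$n_grid <- pmax(3L, as.integer(ceiling(segs$length_cm / dx_cm)) + 1L)

  structure(
    list(segments = segs, terminals = term, sites = sites,
         reference = ref, root = root, dx_cm = dx_cm),
    class = "arterial_tree"
  )
}

#' Read an arterial tree from a YAML config file
#'
#' @param path path to a YAML document with `segments`, `terminals`, `sites`
#'   and `reference` blocks (see the packaged default,
#'   `system.file("extdata", "arterial_tree_default.yaml", package = "svpulse")`).
#' @param dx_cm target grid spacing (cm).
#' @return an `arterial_tree`.
#' @export
read_arterial_tree <- function(path, dx_cm = 1.5) {
  if (!file.exists(path)) abort(paste0("tree config not found: ", path))
  y <- yaml::read_yaml(path)
  to_df <- function(x) dplyr::bind_rows(lapply(x, function(row) {
    row[vapply(row, is.null, logical(1))] <- NA
    as_tibble(row)
  }))
  config <- list(
    segments = to_df(y$segments),
    terminals = to_df(y$terminals),
    sites = to_df(y$sites),
    reference = y$reference
  )
  arterial_tree(config, dx_cm = dx_cm)
}

#' The packaged reduced systemic arterial tree
#'
#' A nine-segment reduction of the systemic arterial tree covering the
#' aortic root to femoral path plus carotid and brachial branches. Geometry,
#' distensibilities and Windkessel terminal values are package defaults
#' chosen so that the reference state (cardiac output 5.5 L/min, heart rate
#' 75 bpm) produces physiological brachial pressures; the parallel
#' combination of the terminal resistances is 1.0 mmHg s/mL.
#'
#' @param dx_cm target grid spacing (cm).
#' @return an `arterial_tree`.
#' @export
default_arterial_tree <- function(dx_cm = 1.5) {
  path <- system.file("extdata", "arterial_tree_default.yaml", package = "svpulse")
  read_arterial_tree(path, dx_cm = dx_cm)
}

#' @export
print.arterial_tree <- function(x, ...) {
  cat("<arterial_tree>", nrow(x$segments), "segments,",
      nrow(x$terminals), "terminals, root:", x$root, "\n")
  cat("  sites:", paste(x$sites$site, collapse = ", "), "\n")
  cat("  total peripheral resistance:", signif(tree_tpr(x), 4), "mmHg s/mL\n")
  invisible(x)
}

#' Total peripheral resistance of a tree
#'
#' Parallel combination of all terminal resistances `r1 + r2`.
#'
#' @param tree an `arterial_tree`.
#' @return TPR in mmHg s/mL.
#' @export
tree_tpr <- function(tree) {
  1 / sum(1 / (tree$terminals$r1 + tree$terminals$r2))
}

# segment ids from root down to `id` (inclusive)
ancestor_chain <- function(tree, id) {
  chain <- character(0)
  cur <- id
  while (!is.na(cur)) {
    chain <- c(cur, chain)
    cur <- tree$segments$parent[match(cur, tree$segments$id)]
  }
  chain
}

# distance (cm) from the root inlet to a (segment, position) point
root_distance_cm <- function(tree, segment, position) {
  chain <- ancestor_chain(tree, segment)
  lens <- tree$segments$length_cm[match(chain, tree$segments$id)]
  sum(head(lens, -1)) + position * tail(lens, 1)
}

#' Anatomical path length between two named sites
#'
#' Walks the tree between two measurement sites and sums the traversed
#' segment lengths (the along-tree distance, not a straight line). Used as
#' the transit path for synthetic carotid-femoral pulse wave velocity.
#'
#' @param tree an `arterial_tree`.
#' @param from,to site names present in `tree$sites`.
#' @param units `"m"` (default) or `"cm"`.
#' @return path length, scalar.
#' @export
tree_path_length <- function(tree, from, to, units = c("m", "cm")) {
  units <- match.arg(units)
  s <- tree$sites
  for (nm in c(from, to)) {
    if (!nm %in% s$site) abort(paste0("unknown site: ", nm))
  }
  a <- s[s$site == from, ]
  b <- s[s$site == to, ]
  chain_a <- ancestor_chain(tree, a$segment)
  chain_b <- ancestor_chain(tree, b$segment)
  common <- 0
  while (common < min(length(chain_a), length(chain_b)) &&
         chain_a[common + 1] == chain_b[common + 1]) {
    common <- common + 1
  }
  da <- root_distance_cm(tree, a$segment, a$position)
  db <- root_distance_cm(tree, b$segment, b$position)
  if (identical(chain_a[seq_len(common)], chain_a) ||
      identical(chain_b[seq_len(common)], chain_b)) {
    # one site lies on the other's root path
    d <- abs(da - db)
  } else {
    lens <- tree$segments$length_cm[match(chain_a[seq_len(common)], tree$segments$id)]
    d_junction <- sum(lens)
    d <- (da - d_junction) + (db - d_junction)
  }
  if (units == "m") d / 100 else d
}

#' Scale an arterial tree to a sampled subject
#'
#' Applies the per-subject geometric and mechanical scalings used for
#' synthetic cohort generation: every segment length is multiplied by
#' `length_scale`, every inlet/outlet diameter by `diameter_scale`, every
#' segment distensibility and terminal compliance by the ratio of the
#' subject's aortic distensibility to the tree's reference value, and all
#' terminal resistances by a common factor chosen so their parallel
#' combination equals the subject's total peripheral resistance exactly.
#' Within each terminal the proximal/distal split is then re-balanced so the
#' proximal element tracks the stiffened bed's characteristic impedance
#' (scaling as `1/sqrt(distensibility scale)`, capped at half the terminal
#' total), which keeps terminal wave reflections consistent across stiffness
#' levels without altering the total resistance. The input tree is not
#' modified.
#'
#' @param tree an `arterial_tree`.
#' @param profile a one-row subject profile (see [sample_profiles()]) or a
#'   list with fields `length_scale`, `diameter_scale`, `distensibility`
#'   and `tpr`.
#' @return a new, rescaled `arterial_tree`.
#' @export
scale_tree <- function(tree, profile) {
  ls <- profile$length_scale %||% 1
  ds <- profile$diameter_scale %||% 1
  cs <- if (!is.null(profile$distensibility)) {
    profile$distensibility / tree$reference$aortic_distensibility
  } else {
    profile$distensibility_scale %||% 1
  }
  if (!is.finite(cs) || cs <= 0) abort("distensibility scale must be > 0")
  out <- tree
  out$segments <- tree$segments |>
    mutate(
      length_cm = .data$length_cm * ls,
      din_cm = .data$din_cm * ds,
      dout_cm = .data$dout_cm * ds,
      distensibility = .data$distensibility * cs
    )
  out$segments$n_grid <- pmax(3L, as.integer(ceiling(out$segments$length_cm / tree$dx_cm)) + 1L)
  rt <- NULL
  if (!is.null(profile$tpr)) {
    if (!is.finite(profile$tpr) || profile$tpr <= 0) {
      abort("target total peripheral resistance must be > 0")
    }
    rt <- profile$tpr / tree_tpr(tree)
  }
  out$terminals <- tree$terminals |>
    mutate(c = .data$c * cs)
  if (!is.null(rt)) {
    out$terminals <- out$terminals |>
      mutate(r1 = .data$r1 * rt, r2 = .data$r2 * rt)
  }
  # keep the proximal element matched to the stiffened bed's characteristic
  # impedance (Z ~ rho c / A ~ 1/sqrt(distensibility)); the total terminal
  # resistance is unchanged, only the R1/R2 split moves
  out$terminals <- out$terminals |>
    mutate(
      rt_total = .data$r1 + .data$r2,
      r1 = pmin(.data$r1 / sqrt(cs), 0.5 * .data$rt_total),
      r2 = .data$rt_total - .data$r1
    ) |>
    select(-"rt_total")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
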