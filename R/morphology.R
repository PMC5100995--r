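## Morphology: SWC input/output, tree representation, surface areas,
## spatial discretization and the global spine-area correction.

SWC_KIND_MAP <- c("1" = "soma", "2" = "axon", "3" = "basal", "4" = "apical",
                  "5" = "spine_neck", "6" = "spine_head")
DENDRITE_KINDS <- c("basal", "apical")

#' Create a neurite section
#'
#' A section is an unbranched stretch of neurite described by an ordered
#' chain of 3D sample points with per-point diameters (all in micrometres).
#' A single-point section is treated as a sphere of the stated diameter
#' (used for the soma and for spine heads).
#'
#' @param id integer section identifier, unique within a morphology.
#' @param kind one of `"soma"`, `"basal"`, `"apical"`, `"axon"`,
#'   `"spine_neck"`, `"spine_head"`.
#' @param points numeric matrix with columns `x`, `y`, `z`, `diam` (um).
#' @param parent id of the parent section, or `NA` for the root.
#' @param parent_pos arc-position (0-1) on the parent where this section
#'   attaches; children attach at the distal end (1) by default.
#' @return an object of class `cable_section`.
#' @export
section <- function(id, kind, points, parent = NA_integer_, parent_pos = 1) {
  points <- as.matrix(points)
  if (ncol(points) != 4L) stop("section points must have 4 columns (x,y,z,diam)")
  colnames(points) <- c("x", "y", "z", "diam")
  if (nrow(points) < 1L) stop("section needs at least one point")
  if (any(points[, "diam"] <= 0)) stop("non-positive diameter in section ", id)
  if (!kind %in% unname(SWC_KIND_MAP)) stop("unknown section kind: ", kind)
  structure(list(id = as.integer(id), kind = kind, points = points,
                 parent = as.integer(parent), parent_pos = parent_pos),
            class = "cable_section")
}

#' Assemble a morphology from sections
#'
#' @param sections list of [section()] objects. Exactly one section must be
#'   the root (parent `NA`); parent links must form a tree.
#' @param metadata optional free-text provenance string.
#' @return an object of class `cable_morphology`.
#' @export
morphology <- function(sections, metadata = "") {
  ids <- vapply(sections, function(s) s$id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate section ids")
  names(sections) <- as.character(ids)
  roots <- which(vapply(sections, function(s) is.na(s$parent), logical(1)))
  if (length(roots) != 1L) stop("morphology must have exactly one root section")
  for (s in sections) {
    if (!is.na(s$parent) && !as.character(s$parent) %in% names(sections))
      stop("section ", s$id, " references missing parent ", s$parent)
  }
  ## cycle check: walk to root from every section
  for (s in sections) {
    seen <- integer(0); cur <- s
    while (!is.na(cur$parent)) {
      if (cur$id %in% seen) stop("parent links contain a cycle")
      seen <- c(seen, cur$id)
      cur <- sections[[as.character(cur$parent)]]
    }
  }
  structure(list(sections = sections, soma_id = sections[[roots]]$id,
                 metadata = metadata),
            class = "cable_morphology")
}

#' @export
print.cable_morphology <- function(x, ...) {
  kinds <- vapply(x$sections, function(s) s$kind, character(1))
  cat("cable_morphology:", length(x$sections), "sections\n")
  print(table(kinds))
  cat(sprintf("total membrane area: %.1f um^2\n", total_area(x)))
  cat(sprintf("max path distance: %.1f um\n", max_path_distance(x)))
  invisible(x)
}

#' Read an SWC morphology file
#'
#' Reads the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments). Sample points are grouped into unbranched sections; type
#' codes are mapped 1 = soma, 2 = axon, 3 = basal, 4 = apical (5/6 are
#' accepted as spine neck/head). For a section branching off a non-soma
#' parent, the parent sample is prepended to the child's point chain so
#' that frustum geometry spans the branch point, per usual SWC semantics;
#' sections off the soma sphere start at their own first sample.
#'
#' @param path path to an SWC file.
#' @return a [morphology()] object.
#' @export
load_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  if (nrow(raw) == 0L) stop("empty SWC file")
  if (any(raw$r <= 0)) stop("SWC format error: non-positive radius")
  if (anyDuplicated(raw$id)) stop("SWC format error: duplicate sample ids")
  idx <- match(raw$parent, raw$id)
  if (any(is.na(idx) & raw$parent != -1))
    stop("SWC format error: sample references missing parent ",
         raw$parent[which(is.na(idx) & raw$parent != -1)[1]])
  if (sum(raw$parent == -1) != 1L) stop("SWC format error: need exactly one root sample")
  if (!all(as.character(raw$type) %in% names(SWC_KIND_MAP)))
    stop("SWC format error: unsupported type code")

  n <- nrow(raw)
  pidx <- ifelse(raw$parent == -1, NA_integer_, idx)
  nchild <- tabulate(pidx[!is.na(pidx)], nbins = n)
  is_soma <- raw$type == 1
  root_i <- which(raw$parent == -1)

  ## section starts: root; any sample whose parent is soma while it is not;
  ## any sample whose parent is a branch point; any type change
  starts <- root_i
  for (i in seq_len(n)) {
    p <- pidx[i]
    if (is.na(p)) next
    if ((is_soma[p] && !is_soma[i]) || nchild[p] >= 2L || raw$type[p] != raw$type[i])
      starts <- c(starts, i)
  }
  starts <- sort(unique(starts))
  sec_of <- integer(n)  # section index per sample
  sections <- list()
  sample_sec <- integer(n)
  for (k in seq_along(starts)) {
    chain <- starts[k]
    cur <- starts[k]
    repeat {
      kids <- which(pidx == cur)
      kids <- kids[!(kids %in% starts)]
      if (length(kids) != 1L) break
      cur <- kids
      chain <- c(chain, cur)
    }
    sample_sec[chain] <- k
    sections[[k]] <- chain
  }
  ## build section objects
  out <- vector("list", length(sections))
  for (k in seq_along(sections)) {
    chain <- sections[[k]]
    first <- chain[1]
    p <- pidx[first]
    pts <- cbind(raw$x[chain], raw$y[chain], raw$z[chain], 2 * raw$r[chain])
    parent_sec <- NA_integer_
    if (!is.na(p)) {
      parent_sec <- sample_sec[p]
      gap <- sqrt((raw$x[p] - raw$x[first])^2 + (raw$y[p] - raw$y[first])^2 +
                    (raw$z[p] - raw$z[first])^2)
      if (!is_soma[p] && gap > 1e-9) {
        ## prepend the parent sample so geometry spans the branch point
        pts <- rbind(c(raw$x[p], raw$y[p], raw$z[p], 2 * raw$r[p]), pts)
      }
    }
    out[[k]] <- section(k, unname(SWC_KIND_MAP[as.character(raw$type[first])]),
                        pts, parent = parent_sec)
  }
  morphology(out, metadata = paste("loaded from", basename(path)))
}

#' Write a morphology to an SWC file
#'
#' Inverse of [load_swc()]: a load/write/load round trip preserves point
#' coordinates and topology exactly (sample ids are renumbered).
#'
#' @param morph a [morphology()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  type_of <- stats::setNames(as.integer(names(SWC_KIND_MAP)), unname(SWC_KIND_MAP))
  lines <- character(0)
  next_id <- 1L
  last_id <- list()  # section id -> swc id of its last sample
  ## topological order: parents before children
  done <- character(0)
  pend <- morph$sections
  while (length(pend) > 0) {
    for (s in pend) {
      if (!is.na(s$parent) && !as.character(s$parent) %in% done) next
      pts <- s$points
      ## drop the first point only when it duplicates the parent's distal
      ## sample exactly (it was prepended at load time)
      skip_first <- FALSE
      if (!is.na(s$parent)) {
        psec <- morph$sections[[as.character(s$parent)]]
        ppt <- psec$points[nrow(psec$points), ]
        if (psec$kind != "soma" && nrow(pts) >= 2 &&
            all(abs(pts[1, ] - ppt) < 1e-9)) skip_first <- TRUE
      }
      prev <- if (is.na(s$parent)) -1L else last_id[[as.character(s$parent)]]
      rows <- seq_len(nrow(pts))
      if (skip_first) rows <- rows[-1]
      for (i in rows) {
        lines <- c(lines, sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                                  next_id, type_of[[s$kind]],
                                  pts[i, 1], pts[i, 2], pts[i, 3],
                                  pts[i, 4] / 2, prev))
        prev <- next_id
        next_id <- next_id + 1L
      }
      last_id[[as.character(s$id)]] <- prev
      done <- c(done, as.character(s$id))
    }
    pend <- Filter(function(s) !as.character(s$id) %in% done, pend)
  }
  writeLines(c("# SWC written by cablefit", lines), path)
  invisible(path)
}

#' Membrane surface area of a section
#'
#' Lateral areas of the conical frusta between consecutive sample points;
#' a single-point section counts as a sphere of the stated diameter.
#'
#' @param sec a [section()] object.
#' @return area in um^2.
#' @export
surface_area <- function(sec) {
  pts <- sec$points
  if (nrow(pts) == 1L) return(unname(pi * pts[1, "diam"]^2))
  r <- pts[, "diam"] / 2
  seg <- sqrt(rowSums((pts[-1, 1:3, drop = FALSE] - pts[-nrow(pts), 1:3, drop = FALSE])^2))
  r1 <- r[-length(r)]; r2 <- r[-1]
  sum(pi * (r1 + r2) * sqrt(seg^2 + (r2 - r1)^2))
}

section_length <- function(sec) {
  pts <- sec$points
  if (nrow(pts) == 1L) return(0)
  sum(sqrt(rowSums((pts[-1, 1:3, drop = FALSE] - pts[-nrow(pts), 1:3, drop = FALSE])^2)))
}

#' Total membrane area of a morphology
#' @param morph a [morphology()] object.
#' @param kinds restrict to these section kinds (default all).
#' @return area in um^2.
#' @export
total_area <- function(morph, kinds = NULL) {
  secs <- morph$sections
  if (!is.null(kinds)) secs <- Filter(function(s) s$kind %in% kinds, secs)
  sum(vapply(secs, surface_area, numeric(1)))
}

#' Maximal dendritic path distance from the soma
#' @param morph a [morphology()] object.
#' @return distance in um.
#' @export
max_path_distance <- function(morph) {
  comps <- discretize(morph, dx_rule(fixed_um = 25))
  max(comps$path_um[comps$kind %in% DENDRITE_KINDS], 0)
}

#' Discretization rule
#'
#' Either a fixed maximal segment length in um, or a fraction of the AC
#' space constant lambda at `freq_hz` (the d-lambda heuristic), evaluated
#' with nominal `ra` (Ohm cm) and `cm` (uF/cm^2). The number of segments
#' per section is always forced odd so every section has a centred node.
#'
#' @param fixed_um fixed maximal segment length (um); overrides the
#'   lambda rule when given.
#' @param lambda_frac fraction of lambda_f per segment (default 0.1).
#' @param freq_hz frequency for the space constant (default 100).
#' @param ra,cm nominal axial resistivity and capacitance used only to
#'   evaluate lambda for the grid (the simulated values are set later).
#' @return a rule object for [discretize()].
#' @export
dx_rule <- function(fixed_um = NULL, lambda_frac = 0.1, freq_hz = 100,
                    ra = 200, cm = 1) {
  structure(list(fixed_um = fixed_um, lambda_frac = lambda_frac,
                 freq_hz = freq_hz, ra = ra, cm = cm), class = "dx_rule")
}

lambda_f_um <- function(diam_um, freq_hz, ra, cm) {
  1e5 * sqrt(diam_um / (4 * pi * freq_hz * ra * cm))
}

#' Discretize a morphology into compartments
#'
#' Splits every section into an odd number of equal-arclength segments with
#' centred nodes. Areas are exact frustum areas per segment (diameter
#' linearly interpolated along the arc); the axial resistance between
#' neighbouring nodes integrates `Ra / (pi r(s)^2)` in closed form over the
#' two half-segments it spans. The result is returned at unit axial
#' resistivity (`ra_unit_Mohm`, MOhm per Ohm cm) so fitted `Ra` values can
#' be applied by scaling.
#'
#' @param morph a [morphology()] object.
#' @param rule a [dx_rule()].
#' @return data frame of compartments ordered parent-before-child, with
#'   columns `comp`, `section_id`, `kind`, `pos`, `length_um`, `area_um2`,
#'   `ra_unit_Mohm`, `path_um`, `parent`, `spine_factor`.
#' @export
discretize <- function(morph, rule = dx_rule()) {
  stopifnot(inherits(rule, "dx_rule"))
  secs <- morph$sections
  ## topological order
  order_ids <- character(0)
  pend <- secs
  while (length(pend) > 0) {
    for (s in pend)
      if (is.na(s$parent) || as.character(s$parent) %in% order_ids)
        order_ids <- c(order_ids, as.character(s$id))
    pend <- Filter(function(s) !as.character(s$id) %in% order_ids, pend)
  }

  ## accumulate columns as vectors (row-wise frames are too slow for
  ## spine-studded morphologies)
  c_sec <- integer(0); c_kind <- character(0); c_pos <- numeric(0)
  c_len <- numeric(0); c_area <- numeric(0); c_ra <- numeric(0)
  c_path <- numeric(0); c_parent <- integer(0); c_dhalf <- numeric(0)
  comp_counter <- 0L
  ## per-section bookkeeping for attachments at arbitrary parent_pos
  sec_comps <- list(); sec_dist_half <- list(); sec_pos <- list()
  sec_path0 <- list(); sec_len <- list()

  for (sid in order_ids) {
    s <- secs[[sid]]
    pts <- s$points
    single <- nrow(pts) == 1L

    if (is.na(s$parent)) {
      parent_comp <- 0L; path0 <- 0; pd_half <- 0
    } else {
      psid <- as.character(s$parent)
      pc <- sec_comps[[psid]]
      j <- which.min(abs(sec_pos[[psid]] - s$parent_pos))
      parent_comp <- pc[j]
      pd_half <- sec_dist_half[[psid]][j]
      path0 <- sec_path0[[psid]] + s$parent_pos * sec_len[[psid]]
    }

    if (single) {
      comp_counter <- comp_counter + 1L
      c_sec <- c(c_sec, s$id); c_kind <- c(c_kind, s$kind)
      c_pos <- c(c_pos, 0.5); c_len <- c(c_len, 0)
      c_area <- c(c_area, pi * pts[1, "diam"]^2)
      c_ra <- c(c_ra, pd_half); c_path <- c(c_path, path0)
      c_parent <- c(c_parent, parent_comp); c_dhalf <- c(c_dhalf, 0)
      sec_comps[[sid]] <- comp_counter
      sec_dist_half[[sid]] <- 0  # sphere: no internal axial resistance
      sec_pos[[sid]] <- 0.5
      sec_path0[[sid]] <- path0; sec_len[[sid]] <- 0
      next
    }

    seg <- sqrt(rowSums((pts[-1, 1:3, drop = FALSE] -
                           pts[-nrow(pts), 1:3, drop = FALSE])^2))
    if (any(seg == 0)) {
      ## collapse coincident samples (diameter steps at joined branch
      ## points): keep the distal diameter
      pts <- pts[c(seg > 0, TRUE), , drop = FALSE]
      seg <- seg[seg > 0]
    }
    L <- sum(seg)
    if (L <= 0) stop("degenerate zero-length section ", s$id)
    arc <- c(0, cumsum(seg))
    dmid <- stats::approx(arc, pts[, "diam"], xout = L / 2, rule = 2)$y

    target <- if (!is.null(rule$fixed_um)) rule$fixed_um else
      rule$lambda_frac * lambda_f_um(dmid, rule$freq_hz, rule$ra, rule$cm)
    nseg <- max(1L, ceiling(L / target))
    if (nseg %% 2L == 0L) nseg <- nseg + 1L

    bounds <- seq(0, L, length.out = nseg + 1L)
    ids <- comp_counter + seq_len(nseg)
    prox_half <- dist_half <- area <- numeric(nseg)
    for (j in seq_len(nseg)) {
      a <- bounds[j]; b <- bounds[j + 1L]; mid <- (a + b) / 2
      area[j] <- frustum_area_between(arc, pts[, "diam"], a, b)
      prox_half[j] <- axial_unit_between(arc, pts[, "diam"], a, mid)
      dist_half[j] <- axial_unit_between(arc, pts[, "diam"], mid, b)
    }
    mids <- (bounds[-1] + bounds[-(nseg + 1L)]) / 2
    ra_unit <- prox_half + c(pd_half, dist_half[-nseg])
    c_sec <- c(c_sec, rep(s$id, nseg)); c_kind <- c(c_kind, rep(s$kind, nseg))
    c_pos <- c(c_pos, mids / L); c_len <- c(c_len, diff(bounds))
    c_area <- c(c_area, area); c_ra <- c(c_ra, ra_unit)
    c_path <- c(c_path, path0 + mids)
    c_parent <- c(c_parent, c(parent_comp, ids[-nseg]))
    c_dhalf <- c(c_dhalf, dist_half)
    comp_counter <- comp_counter + nseg
    sec_comps[[sid]] <- ids
    sec_dist_half[[sid]] <- dist_half
    sec_pos[[sid]] <- mids / L
    sec_path0[[sid]] <- path0; sec_len[[sid]] <- L
  }
  data.frame(comp = seq_len(comp_counter), section_id = c_sec, kind = c_kind,
             pos = c_pos, length_um = c_len, area_um2 = c_area,
             ra_unit_Mohm = c_ra, path_um = c_path, parent = c_parent,
             spine_factor = rep(1, comp_counter),
             dist_half_unit_Mohm = c_dhalf)
}

#' Attach explicit spines directly to a compartment table
#'
#' Fast path for protocols placing many spines: appends a neck and head
#' compartment per attachment row without re-discretizing the tree. The
#' neck connects through the parent compartment's distal half-resistance,
#' matching what full rediscretization would produce for a distal
#' attachment.
#'
#' @param comps compartment table from [discretize()].
#' @param at_comps integer vector of compartment indices carrying spines
#'   (one spine per entry; repeats allowed).
#' @param spine a [spine_model()].
#' @return list `comps` (extended table) and `head_comps` (indices of the
#'   spine-head compartments).
#' @export
attach_spines <- function(comps, at_comps, spine = spine_model()) {
  n <- length(at_comps)
  if (n == 0L) return(list(comps = comps, head_comps = integer(0)))
  neck_unit <- 1e-2 * spine$neck_length_um /
    (pi * (spine$neck_diam_um / 2)^2)   # MOhm per Ohm cm
  neck_area <- pi * spine$neck_diam_um * spine$neck_length_um
  base <- nrow(comps)
  sec0 <- max(comps$section_id)
  neck_idx <- base + 2 * seq_len(n) - 1L
  head_idx <- base + 2 * seq_len(n)
  new <- data.frame(
    comp = rep(0L, 2 * n), section_id = 0L, kind = "", pos = 0.5,
    length_um = 0, area_um2 = 0, ra_unit_Mohm = 0, path_um = 0,
    parent = 0L, spine_factor = 1, dist_half_unit_Mohm = 0)
  new$comp <- as.integer(base + seq_len(2 * n))
  new$section_id[seq(1, 2 * n, 2)] <- sec0 + 2 * seq_len(n) - 1L
  new$section_id[seq(2, 2 * n, 2)] <- sec0 + 2 * seq_len(n)
  new$kind[seq(1, 2 * n, 2)] <- "spine_neck"
  new$kind[seq(2, 2 * n, 2)] <- "spine_head"
  new$length_um[seq(1, 2 * n, 2)] <- spine$neck_length_um
  new$area_um2[seq(1, 2 * n, 2)] <- neck_area
  new$area_um2[seq(2, 2 * n, 2)] <- spine$head_area_um2
  new$ra_unit_Mohm[seq(1, 2 * n, 2)] <-
    neck_unit / 2 + comps$dist_half_unit_Mohm[at_comps]
  new$ra_unit_Mohm[seq(2, 2 * n, 2)] <- neck_unit / 2
  new$path_um[seq(1, 2 * n, 2)] <- comps$path_um[at_comps]
  new$path_um[seq(2, 2 * n, 2)] <- comps$path_um[at_comps]
  new$parent[seq(1, 2 * n, 2)] <- as.integer(at_comps)
  new$parent[seq(2, 2 * n, 2)] <- neck_idx
  new$dist_half_unit_Mohm[seq(1, 2 * n, 2)] <- neck_unit / 2
  list(comps = rbind(comps, new), head_comps = head_idx)
}

## frustum lateral area of the piece of a section between arclengths a and b
frustum_area_between <- function(arc, diam, a, b) {
  knots <- sort(unique(c(a, b, arc[arc > a & arc < b])))
  d <- stats::approx(arc, diam, xout = knots, rule = 2)$y
  r <- d / 2
  ds <- diff(knots)
  r1 <- r[-length(r)]; r2 <- r[-1]
  sum(pi * (r1 + r2) * sqrt(ds^2 + (r2 - r1)^2))
}

## axial resistance integral at Ra = 1 Ohm cm, in MOhm:
## R = 1e-2 * integral ds / (pi r(s)^2); closed form L/(pi r1 r2) per
## linear-taper piece
axial_unit_between <- function(arc, diam, a, b) {
  if (b <= a) return(0)
  knots <- sort(unique(c(a, b, arc[arc > a & arc < b])))
  r <- stats::approx(arc, diam, xout = knots, rule = 2)$y / 2
  ds <- diff(knots)
  r1 <- r[-length(r)]; r2 <- r[-1]
  1e-2 * sum(ds / (pi * r1 * r2))
}

#' Apply the global spine membrane-area correction
#'
#' Dendritic spines are folded into the cable globally through the factor
#' `F = (shaft area + spine area) / shaft area`: compartments whose path
#' distance from the soma is at least `start_distance_um` get
#' `spine_factor = F`, which the solver applies as `Cm * F` and `Rm / F`.
#' The correction targets dendrites only (basal and apical); axon, soma and
#' explicitly modelled spines are left untouched. Use
#' `start_distance_um = 0` to spread the factor over the whole tree (the
#' convention used for mouse cells).
#'
#' @param comps compartment table from [discretize()].
#' @param F spine area factor (>= 1), default 1.9.
#' @param start_distance_um proximal cutoff (default 60 um: proximal
#'   dendrites carry very few spines).
#' @return the compartment table with `spine_factor` filled in.
#' @export
apply_spine_correction <- function(comps, F = 1.9, start_distance_um = 60) {
  if (F < 1) stop("spine factor F must be >= 1")
  if (start_distance_um < 0) stop("start_distance_um must be >= 0")
  sel <- comps$kind %in% DENDRITE_KINDS & comps$path_um >= start_distance_um
  comps$spine_factor <- ifelse(sel, F, 1)
  comps
}

#' Summarise a morphology
#'
#' @param morph a [morphology()] object.
#' @param F,start_distance_um spine correction used for the effective area.
#' @return list with section counts, raw and spine-corrected membrane area
#'   (um^2) and maximal dendritic path distance (um).
#' @export
morph_summary <- function(morph, F = 1.9, start_distance_um = 60) {
  comps <- apply_spine_correction(discretize(morph, dx_rule(fixed_um = 25)),
                                  F, start_distance_um)
  kinds <- vapply(morph$sections, function(s) s$kind, character(1))
  list(n_sections = length(morph$sections),
       sections_by_kind = table(kinds),
       area_raw_um2 = sum(comps$area_um2),
       area_spine_corrected_um2 = sum(comps$area_um2 * comps$spine_factor),
       max_path_distance_um = max(comps$path_um))
}

#' Attach an explicit two-compartment spine
#'
#' Adds a spine (cylindrical neck plus isopotential head) at the given
#' location. Default geometry: neck 1.35 um long, 0.25 um diameter; head
#' carrying 2.8 um^2 of membrane (modelled as the sphere of that area).
#'
#' @param morph a [morphology()] object.
#' @param at_section section id carrying the spine.
#' @param at_pos arc-position on that section (only the distal end, 1, is
#'   currently honoured by the discretizer for attachments).
#' @param spine a [spine_model()].
#' @return list `morph` (the extended morphology), `head_id` and `neck_id`.
#' @export
add_spine <- function(morph, at_section, at_pos = 1, spine = spine_model()) {
  sec <- morph$sections[[as.character(at_section)]]
  if (is.null(sec)) stop("no section with id ", at_section)
  base <- sec$points[nrow(sec$points), 1:3]
  ids <- vapply(morph$sections, function(s) s$id, integer(1))
  neck_id <- max(ids) + 1L
  head_id <- neck_id + 1L
  dirv <- c(0, 0, 1)
  neck_pts <- rbind(c(base, spine$neck_diam_um),
                    c(base + dirv * spine$neck_length_um, spine$neck_diam_um))
  head_diam <- sqrt(spine$head_area_um2 / pi)
  head_pts <- matrix(c(base + dirv * spine$neck_length_um, head_diam), nrow = 1)
  neck <- section(neck_id, "spine_neck", neck_pts, parent = at_section,
                  parent_pos = at_pos)
  head <- section(head_id, "spine_head", head_pts, parent = neck_id)
  secs <- c(morph$sections, list(neck, head))
  list(morph = morphology(unname(secs), metadata = morph$metadata),
       neck_id = neck_id, head_id = head_id)
}
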