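#' Passive membrane parameters
#'
#' Container for the passive cable properties shared by all compartments of a
#' morphology. Defaults are generic pyramidal-cell values; they are
#' user-overridable because measured passive properties vary widely across
#' preparations.
#'
#' @param axial_resistivity Cytoplasmic resistivity (Ohm cm). Default 150.
#' @param specific_capacitance Membrane capacitance per area (uF/cm^2).
#'   Default 1.
#' @param specific_leak_conductance Leak conductance per area (S/cm^2).
#'   Default 5e-5 (i.e. a membrane resistivity of 20 kOhm cm^2).
#' @param leak_reversal Leak reversal potential (mV relative to rest).
#'   Default 0, so the resting state is V = 0 everywhere.
#' @return An object of class `passive_params`.
#' @examples
#' passive_params()
#' passive_params(specific_leak_conductance = 2e-4)  # leakier membrane
#' @export
passive_params <- function(axial_resistivity = 150,
                           specific_capacitance = 1,
                           specific_leak_conductance = 5e-5,
                           leak_reversal = 0) {
  if (axial_resistivity <= 0 || specific_capacitance <= 0 ||
      specific_leak_conductance <= 0) {
    stop("axial_resistivity, specific_capacitance and ",
         "specific_leak_conductance must all be positive", call. = FALSE)
  }
  if (!is.finite(leak_reversal)) stop("leak_reversal must be finite", call. = FALSE)
  structure(
    list(axial_resistivity = axial_resistivity,
         specific_capacitance = specific_capacitance,
         specific_leak_conductance = specific_leak_conductance,
         leak_reversal = leak_reversal),
    class = "passive_params"
  )
}

#' @export
print.passive_params <- function(x, ...) {
  cat("Passive membrane parameters\n")
  cat(sprintf("  axial resistivity : %g Ohm cm\n", x$axial_resistivity))
  cat(sprintf("  capacitance       : %g uF/cm^2\n", x$specific_capacitance))
  cat(sprintf("  leak conductance  : %g S/cm^2 (Rm = %g kOhm cm^2)\n",
              x$specific_leak_conductance,
              1 / x$specific_leak_conductance / 1000))
  cat(sprintf("  leak reversal     : %g mV (rel. rest)\n", x$leak_reversal))
  invisible(x)
}

# internal constructor; nodes must already be in topological order
new_morphology <- function(nodes, passive) {
  stopifnot(is.data.frame(nodes))
  structure(list(nodes = nodes, passive = passive), class = "morphology")
}

validate_morphology <- function(m) {
  nd <- m$nodes
  roots <- which(nd$parent == 0L)
  if (length(roots) != 1L) {
    stop("morphology must have exactly one root, found ", length(roots),
         call. = FALSE)
  }
  if (any(nd$radius <= 0)) stop("all radii must be positive", call. = FALSE)
  if (any(nd$parent >= seq_len(nrow(nd)))) {
    stop("parent must precede child in topological order", call. = FALSE)
  }
  if (!any(nd$region == "soma")) stop("soma region is empty", call. = FALSE)
  m
}

#' Number of nodes in a morphology
#' @param m A `morphology`.
#' @return Integer node count.
#' @export
n_nodes <- function(m) nrow(m$nodes)

#' @export
print.morphology <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("Morphology: %d nodes (%d soma, %d dendrite), %d tip(s)\n",
              nrow(nd), sum(nd$region == "soma"), sum(nd$region == "dendrite"),
              sum(!seq_len(nrow(nd)) %in% nd$parent)))
  cat(sprintf("  max path distance from root: %.1f um\n",
              max(node_root_depths(x))))
  invisible(x)
}

#' Read a neuron morphology from an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; '#' comments).
#' Type 1 is soma; all other types are treated as dendrite. Node ids are
#' remapped to contiguous topological order (parents before children); the
#' original ids are kept in the `label` column.
#'
#' @param path Path to an SWC file.
#' @param passive A [passive_params()] object attached to the morphology.
#' @return A `morphology` object.
#' @seealso [write_swc()]
#' @export
read_swc <- function(path, passive = passive_params()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("SWC file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop("SWC parse error at line ", lineno[bad[1]],
         ": expected 7 fields, got ", length(fields[[bad[1]]]), call. = FALSE)
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (anyNA(mat)) {
    bad <- which(apply(mat, 1, anyNA))[1]
    stop("SWC parse error at line ", lineno[bad], ": non-numeric field",
         call. = FALSE)
  }
  ids <- as.integer(mat[, 1]); parents <- as.integer(mat[, 7])
  if (anyDuplicated(ids)) stop("duplicate SWC node ids", call. = FALSE)
  roots <- which(parents == -1L)
  if (length(roots) != 1L) {
    stop("SWC structural error: expected one root (parent = -1), found ",
         length(roots), call. = FALSE)
  }
  pidx <- match(parents, ids)            # row index of each node's parent
  pidx[roots] <- 0L
  if (anyNA(pidx)) stop("SWC structural error: unknown parent id", call. = FALSE)

  # keep the file's row order when it is already topological (so writing and
  # re-reading is an exact identity); otherwise reorder by BFS from the root
  n <- nrow(mat)
  if (all(pidx < seq_len(n))) {
    order <- seq_len(n)
  } else {
    children <- split(seq_len(n), factor(pidx, levels = 0:n))
    order <- integer(n); order[1] <- roots; got <- 1L; head <- 1L
    while (head <= got) {
      kids <- children[[as.character(order[head])]]
      if (length(kids)) {
        order[(got + 1):(got + length(kids))] <- kids
        got <- got + length(kids)
      }
      head <- head + 1L
    }
    if (got != n) {
      stop("SWC structural error: cycle or disconnected nodes", call. = FALSE)
    }
  }
  rank <- integer(n); rank[order] <- seq_len(n)
  par_old <- pidx[order]
  parent_new <- integer(n)
  parent_new[par_old != 0L] <- rank[par_old[par_old != 0L]]
  nd <- data.frame(
    id = seq_len(n),
    parent = parent_new,
    x = mat[order, 3], y = mat[order, 4], z = mat[order, 5],
    radius = mat[order, 6],
    region = ifelse(mat[order, 2] == 1, "soma", "dendrite"),
    label = ids[order],
    stringsAsFactors = FALSE
  )
  validate_morphology(new_morphology(nd, passive))
}

#' Write a morphology to an SWC file
#'
#' @param m A `morphology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  nd <- m$nodes
  type <- ifelse(nd$region == "soma", 1L, 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by synclamp", con)
  writeLines(sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                     nd$id, type, nd$x, nd$y, nd$z, nd$radius,
                     ifelse(nd$parent == 0L, -1L, nd$parent)), con)
  invisible(path)
}

#' Build a ball-and-stick morphology
#'
#' One spherical soma attached to an unbranched cylindrical dendrite: the
#' minimal morphology exhibiting the space clamp effect.
#'
#' @param soma_diameter Soma diameter (um).
#' @param stick_length Dendrite length (um); 0 gives a soma-only cell.
#' @param stick_diameter Dendrite diameter (um).
#' @param passive A [passive_params()] object.
#' @param step Spacing of dendrite points along the stick (um).
#' @return A `morphology` with the dendrite laid out along the x axis.
#' @examples
#' m <- build_ball_and_stick(20, 400, 2)
#' path_distance(m, 1, n_nodes(m))  # 400
#' @export
build_ball_and_stick <- function(soma_diameter = 20, stick_length = 400,
                                 stick_diameter = 2,
                                 passive = passive_params(), step = 10) {
  if (soma_diameter <= 0 || stick_diameter <= 0 || stick_length < 0 ||
      step <= 0) {
    stop("geometry must be positive (stick_length may be zero)", call. = FALSE)
  }
  soma <- data.frame(id = 1L, parent = 0L, x = 0, y = 0, z = 0,
                     radius = soma_diameter / 2, region = "soma",
                     label = 1L, stringsAsFactors = FALSE)
  if (stick_length == 0) return(validate_morphology(new_morphology(soma, passive)))
  npts <- max(1L, ceiling(stick_length / step))
  xs <- seq_len(npts) / npts * stick_length
  dend <- data.frame(id = 1L + seq_len(npts), parent = seq_len(npts),
                     x = xs, y = 0, z = 0, radius = stick_diameter / 2,
                     region = "dendrite", label = 1L + seq_len(npts),
                     stringsAsFactors = FALSE)
  validate_morphology(new_morphology(rbind(soma, dend), passive))
}

#' Build a random branched morphology
#'
#' Grows a binary tree from the soma: at each level every open branch tip
#' either bifurcates (probability `branch_prob`) or continues unbranched.
#' Branch sections are straight segments with random 3D direction jitter, so
#' path distance exceeds straight-line distance (zig-zag geometry).
#' Reproducible for a fixed seed.
#'
#' @param depth Number of branching levels (>= 1).
#' @param branch_prob Bifurcation probability per tip per level.
#' @param seed Integer seed for the branch/geometry draws.
#' @param passive A [passive_params()] object.
#' @param section_length Length of each branch section (um).
#' @param soma_diameter Soma diameter (um).
#' @param diameter Dendrite diameter at the root section (um); tapers by
#'   `taper` per level.
#' @param taper Multiplicative diameter taper per level.
#' @param points_per_section Sample points per branch section.
#' @return A `morphology`.
#' @examples
#' m <- build_random_tree(4, 0.5, seed = 1)
#' @export
build_random_tree <- function(depth, branch_prob, seed,
                              passive = passive_params(),
                              section_length = 100, soma_diameter = 20,
                              diameter = 2, taper = 0.8,
                              points_per_section = 5) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (branch_prob < 0 || branch_prob > 1) {
    stop("branch_prob must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list(data.frame(id = 1L, parent = 0L, x = 0, y = 0, z = 0,
                            radius = soma_diameter / 2, region = "soma",
                            label = 1L, stringsAsFactors = FALSE))
    nid <- 1L
    # open tips: node id, growth direction, current diameter
    tips <- list(list(at = 1L, dir = c(1, 0, 0), diam = diameter))
    for (lev in seq_len(depth)) {
      new_tips <- list()
      for (tp in tips) {
        ndir <- if (stats::runif(1) < branch_prob) 2L else 1L
        for (br in seq_len(ndir)) {
          dir <- tp$dir + stats::rnorm(3, sd = 0.6)
          dir <- dir / sqrt(sum(dir^2))
          parent <- tp$at
          base <- as.numeric(rows[[parent]][1, c("x", "y", "z")])
          step_len <- section_length / points_per_section
          for (p in seq_len(points_per_section)) {
            nid <- nid + 1L
            pos <- base + dir * step_len * p
            rows[[nid]] <- data.frame(
              id = nid, parent = parent, x = pos[1], y = pos[2], z = pos[3],
              radius = tp$diam / 2, region = "dendrite", label = nid,
              stringsAsFactors = FALSE)
            parent <- nid
          }
          new_tips[[length(new_tips) + 1L]] <-
            list(at = nid, dir = dir, diam = tp$diam * taper)
        }
      }
      tips <- new_tips
    }
    nd <- do.call(rbind, rows)
    validate_morphology(new_morphology(nd, passive))
  })
}

#' Path distance between two nodes
#'
#' Sum of 3D segment lengths along the unique tree path between nodes `a` and
#' `b`, i.e. the distance measured along the zig-zag geometry of the dendrite
#' rather than the straight-line distance.
#'
#' @param m A `morphology`.
#' @param a,b Node ids.
#' @return Distance in um; symmetric in `(a, b)`.
#' @export
path_distance <- function(m, a, b) {
  nd <- m$nodes
  if (!a %in% nd$id || !b %in% nd$id) {
    stop("unknown node id: ", if (!a %in% nd$id) a else b, call. = FALSE)
  }
  d_root <- node_root_depths(m)
  anc <- function(i) {             # path to root as a vector of ids
    out <- i
    while (nd$parent[i] != 0L) { i <- nd$parent[i]; out <- c(out, i) }
    out
  }
  pa <- anc(a); pb <- anc(b)
  common <- intersect(pa, pb)[1]   # deepest common ancestor (paths are
                                   # root-ward ordered)
  d_root[a] + d_root[b] - 2 * d_root[common]
}

# cumulative path length from root to each node (um)
node_root_depths <- function(m) {
  nd <- m$nodes
  seg <- numeric(nrow(nd))
  has_par <- nd$parent != 0L
  p <- nd$parent[has_par]
  seg[has_par] <- sqrt((nd$x[has_par] - nd$x[p])^2 +
                       (nd$y[has_par] - nd$y[p])^2 +
                       (nd$z[has_par] - nd$z[p])^2)
  d <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))) {
    d[i] <- if (nd$parent[i] == 0L) 0 else d[nd$parent[i]] + seg[i]
  }
  d
}

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
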