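# Chromosome geometry and the coordinate conventions used throughout.
#
# Positions are arm-local, 0-based, in the orientation of the genome assembly
# (dm6 stores 2L telomere->centromere and 2R centromere->telomere). Each arm
# carries an orientation flag that normalizes both onto a shared "chromosome
# axis" running from the left telomere, across the (unassembled) centromeric
# gap, to the right telomere. All distal/proximal logic is phrased in terms of
# distance from the telomere so that no sign conventions leak out of this file.

ARM_ORIENTATIONS <- c("telomere_to_centromere", "centromere_to_telomere")

#' Define one chromosome arm
#'
#' @param name Arm label, e.g. `"2L"`.
#' @param length Arm length in base pairs.
#' @param orientation Either `"telomere_to_centromere"` (assembly coordinate 0
#'   is the telomere, as for dm6 2L) or `"centromere_to_telomere"` (coordinate
#'   0 is the centromere-proximal end, as for dm6 2R).
#' @param het_boundary Position of the euchromatin/pericentric-heterochromatin
#'   boundary, expressed as a distance in bp from the telomeric end of the arm
#'   (so the euchromatin is `[0, het_boundary)` and the pericentric
#'   heterochromatin is `[het_boundary, length]` on the telomere-distance
#'   axis). Must satisfy `0 < het_boundary <= length`.
#' @return An object of class `arm_def`.
#' @export
arm_def <- function(name, length, orientation, het_boundary) {
  orientation <- match.arg(orientation, ARM_ORIENTATIONS)
  stopifnot(is.character(name), nzchar(name), length > 0)
  if (!(het_boundary > 0 && het_boundary <= length)) {
    stop("het_boundary must lie in (0, length] (given as distance from the telomere)")
  }
  structure(
    list(name = name, length = as.numeric(length), orientation = orientation,
         het_boundary = as.numeric(het_boundary)),
    class = "arm_def"
  )
}

#' Build a chromosome map
#'
#' A `chromosome_map` fixes the geometry every other module works against:
#' the arms in axis order, their orientations and heterochromatin boundaries,
#' and the unassembled centromeric satellite gap separating the two arm
#' assemblies of a metacentric chromosome.
#'
#' @param arms List of [arm_def()] objects: two for a metacentric chromosome
#'   (left arm first along the axis), one for a telocentric.
#' @param shape `"metacentric"` or `"telocentric"`.
#' @param gap_length Length in bp of the unassembled centromeric gap between
#'   the two arm assemblies (metacentric only). No SNPs and no crossovers are
#'   placed inside the gap.
#' @param name Chromosome label, e.g. `"2"`.
#' @return An object of class `chromosome_map`.
#' @examples
#' m <- chromosome_map(
#'   arms = list(
#'     arm_def("2L", 23e6, "telomere_to_centromere", 21e6),
#'     arm_def("2R", 25e6, "centromere_to_telomere", 19e6)
#'   ),
#'   shape = "metacentric", gap_length = 4e6, name = "2"
#' )
#' @export
chromosome_map <- function(arms, shape = c("metacentric", "telocentric"),
                           gap_length = 0, name = "chr") {
  shape <- match.arg(shape)
  stopifnot(is.list(arms), all(vapply(arms, inherits, TRUE, "arm_def")))
  n_expected <- if (shape == "metacentric") 2L else 1L
  if (length(arms) != n_expected) {
    stop(sprintf("a %s map needs exactly %d arm(s)", shape, n_expected))
  }
  if (shape == "telocentric" && gap_length != 0) {
    stop("telocentric maps have no centromeric gap")
  }
  names(arms) <- vapply(arms, `[[`, "", "name")
  structure(
    list(name = name, shape = shape, arms = arms,
         gap_length = as.numeric(gap_length)),
    class = "chromosome_map"
  )
}

#' @export
print.chromosome_map <- function(x, ...) {
  cat(sprintf("<chromosome_map '%s'> %s, %d arm(s), gap %.3g bp\n",
              x$name, x$shape, length(x$arms), x$gap_length))
  for (a in x$arms) {
    cat(sprintf("  %s: %.4g bp, %s, het boundary %.4g bp from telomere\n",
                a$name, a$length, a$orientation, a$het_boundary))
  }
  invisible(x)
}

arm_names <- function(map) names(map$arms)

get_arm <- function(map, arm) {
  a <- map$arms[[arm]]
  if (is.null(a)) stop(sprintf("unknown arm '%s' (have: %s)", arm,
                               paste(arm_names(map), collapse = ", ")))
  a
}

check_pos <- function(a, pos) {
  if (any(pos < 0 | pos > a$length)) {
    stop(sprintf("position out of range for arm %s [0, %.0f]", a$name, a$length))
  }
  invisible(TRUE)
}

# --- chromosome axis -------------------------------------------------------
# Axis coordinate: 0 at the left telomere (arm 1), increasing across the gap
# to the right telomere. For telocentric maps the axis equals distance from
# the telomere and the centromere sits at the far end.

#' Total length of the chromosome axis (arms plus gap), in bp
#' @param map A [chromosome_map()].
#' @export
axis_length <- function(map) {
  sum(vapply(map$arms, `[[`, 0, "length")) + map$gap_length
}

#' Interval of the chromosome axis occupied by the centromeric gap
#'
#' For a telocentric map this is the zero-width interval at the centromeric
#' end of the axis.
#' @param map A [chromosome_map()].
#' @return Numeric length-2 vector `c(start, end)` in axis bp.
#' @export
centromere_interval <- function(map) {
  if (map$shape == "metacentric") {
    l1 <- map$arms[[1]]$length
    c(l1, l1 + map$gap_length)
  } else {
    len <- map$arms[[1]]$length
    c(len, len)
  }
}

#' Centromere position on the chromosome axis (midpoint of the gap)
#' @param map A [chromosome_map()].
#' @export
centromere_axis <- function(map) mean(centromere_interval(map))

#' Distance of a position from its arm's telomere
#'
#' @param map A [chromosome_map()].
#' @param arm Arm name.
#' @param pos Arm-local position(s) in assembly orientation, bp.
#' @return Distance(s) from the telomeric end of the arm, bp.
#' @export
dist_from_telomere <- function(map, arm, pos) {
  a <- get_arm(map, arm)
  check_pos(a, pos)
  if (a$orientation == "telomere_to_centromere") pos else a$length - pos
}

#' Convert an arm-local position to the chromosome axis
#' @inheritParams dist_from_telomere
#' @return Axis coordinate(s), bp.
#' @export
arm_to_axis <- function(map, arm, pos) {
  a <- get_arm(map, arm)
  check_pos(a, pos)
  idx <- match(arm, arm_names(map))
  if (map$shape == "telocentric" || idx == 1L) {
    # left/only arm: axis runs telomere -> centromere
    if (a$orientation == "telomere_to_centromere") pos else a$length - pos
  } else {
    offset <- map$arms[[1]]$length + map$gap_length
    offset + if (a$orientation == "centromere_to_telomere") pos else a$length - pos
  }
}

#' Convert chromosome-axis coordinates back to (arm, position)
#' @param map A [chromosome_map()].
#' @param axis_pos Axis coordinate(s), bp. Positions inside the centromeric
#'   gap map to arm `NA`.
#' @return A data.frame with columns `arm` and `pos` (arm-local, assembly
#'   orientation).
#' @export
axis_to_arm <- function(map, axis_pos) {
  gap <- centromere_interval(map)
  if (map$shape == "telocentric") {
    a <- map$arms[[1]]
    pos <- if (a$orientation == "telomere_to_centromere") axis_pos else a$length - axis_pos
    return(data.frame(arm = a$name, pos = pos))
  }
  a1 <- map$arms[[1]]; a2 <- map$arms[[2]]
  # junction coordinates belong to the arms; only the gap interior is NA
  arm <- ifelse(axis_pos <= gap[1], a1$name, ifelse(axis_pos >= gap[2], a2$name, NA))
  pos <- numeric(length(axis_pos))
  left <- !is.na(arm) & arm == a1$name
  right <- !is.na(arm) & arm == a2$name
  pos[left] <- if (a1$orientation == "telomere_to_centromere") axis_pos[left] else a1$length - axis_pos[left]
  p2 <- axis_pos[right] - gap[2]
  pos[right] <- if (a2$orientation == "centromere_to_telomere") p2 else a2$length - p2
  pos[is.na(arm)] <- NA
  data.frame(arm = arm, pos = pos)
}

axis_dist_from_telomere <- function(map, axis_pos) {
  loc <- axis_to_arm(map, axis_pos)
  out <- rep(NA_real_, length(axis_pos))
  for (nm in arm_names(map)) {
    i <- !is.na(loc$arm) & loc$arm == nm
    if (any(i)) out[i] <- dist_from_telomere(map, nm, loc$pos[i])
  }
  out
}

# --- zone predicates -------------------------------------------------------

#' Fraction of the arm (or chromosome) lying between a position and its telomere
#'
#' Measures how distal a position is: 0 at the telomere, approaching 1 at the
#' centromere-proximal end. A crossover is "distal" (in the sense used for NDJ
#' cause categories) when this fraction is at most the configured cutoff
#' (default 0.24; see [categorizer_config()]).
#'
#' @inheritParams dist_from_telomere
#' @param scope For metacentric maps, `"per_arm"` (default) normalizes by the
#'   arm length; `"per_chromosome"` normalizes by the total assembled
#'   chromosome length. Telocentric maps always normalize by the chromosome
#'   (single-arm) length.
#' @return Fraction in `[0, 1]`.
#' @examples
#' m <- chromosome_map(list(arm_def("L", 23e6, "telomere_to_centromere", 21e6),
#'                          arm_def("R", 23e6, "centromere_to_telomere", 17e6)),
#'                     "metacentric", gap_length = 2e6)
#' chromosome_fraction_from_telomere(m, "L", 5.52e6)  # 0.24
#' @export
chromosome_fraction_from_telomere <- function(map, arm, pos,
                                              scope = c("per_arm", "per_chromosome")) {
  scope <- match.arg(scope)
  a <- get_arm(map, arm)
  d <- dist_from_telomere(map, arm, pos)
  denom <- if (map$shape == "telocentric" || scope == "per_chromosome") {
    sum(vapply(map$arms, `[[`, 0, "length"))
  } else {
    a$length
  }
  d / denom
}

#' Is a position pericentric?
#'
#' TRUE when the position lies within the pericentric heterochromatin
#' (centromere-proximal to the arm's `het_boundary`, boundary included), or
#' within the most centromere-proximal `eu_fraction` of that arm's euchromatin
#' adjacent to the boundary.
#'
#' @inheritParams dist_from_telomere
#' @param eu_fraction Fraction of the arm's euchromatin length adjoining the
#'   heterochromatin that still counts as pericentric (default 0.15).
#' @return Logical.
#' @export
is_pericentric <- function(map, arm, pos, eu_fraction = 0.15) {
  stopifnot(eu_fraction >= 0, eu_fraction < 1)
  a <- get_arm(map, arm)
  d <- dist_from_telomere(map, arm, pos)
  d >= a$het_boundary * (1 - eu_fraction)
}

# --- genetic map -----------------------------------------------------------

#' Construct a genetic-map table
#'
#' @param anchors A data.frame with columns `arm`, `bp` (arm-local assembly
#'   position) and `cM`. Within each arm, `cM` must be non-decreasing in `bp`;
#'   interpolation between anchors is piecewise linear and clamped at the
#'   outermost anchors.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.data.frame(anchors), all(c("arm", "bp", "cM") %in% names(anchors)))
  if (nrow(anchors) == 0) stop("empty genetic-map table")
  anchors <- anchors[order(anchors$arm, anchors$bp), , drop = FALSE]
  for (nm in unique(anchors$arm)) {
    sub <- anchors[anchors$arm == nm, ]
    if (nrow(sub) < 2) stop(sprintf("arm %s needs at least two anchors", nm))
    if (is.unsorted(sub$cM)) stop(sprintf("cM must be non-decreasing in bp on arm %s", nm))
  }
  structure(anchors, class = c("genetic_map", "data.frame"))
}

#' Read a genetic-map table from TSV
#' @param path TSV file with columns `arm`, `bp`, `cM`.
#' @export
read_genetic_map <- function(path) {
  genetic_map(read.delim(path, stringsAsFactors = FALSE))
}

#' Interpolate centimorgan position for arm-local bp coordinates
#'
#' @param gmap A [genetic_map()].
#' @param arm Arm name.
#' @param pos Arm-local position(s), bp.
#' @return Centimorgan value(s); piecewise-linear between anchors and clamped
#'   beyond the outermost anchors.
#' @export
bp_to_cM <- function(gmap, arm, pos) {
  stopifnot(inherits(gmap, "genetic_map"))
  sub <- gmap[gmap$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0) stop(sprintf("genetic map has no anchors for arm '%s'", arm))
  approx(sub$bp, sub$cM, xout = pos, rule = 2, ties = "ordered")$y
}

# --- configuration I/O -----------------------------------------------------

#' Read a chromosome map from a YAML config
#'
#' Expected structure: top-level keys `name`, `shape`, `gap_length`, and
#' `arms`, a list of records with `name`, `length`, `orientation` and
#' `het_boundary` (distance from the telomere, bp).
#'
#' @param path YAML file path.
#' @return A [chromosome_map()].
#' @export
read_chromosome_map <- function(path) {
  y <- yaml::read_yaml(path)
  chromosome_map_from_list(y)
}

chromosome_map_from_list <- function(y) {
  arms <- lapply(y$arms, function(a) {
    arm_def(a$name, a$length, a$orientation, a$het_boundary)
  })
  chromosome_map(arms, shape = y$shape,
                 gap_length = if (is.null(y$gap_length)) 0 else y$gap_length,
                 name = as.character(y$name))
}

#' Packaged D. melanogaster chromosome maps
#'
#' Chromosome geometries mirroring the dm6 assembly, with pericentric
#' heterochromatin boundaries matching the H3K9me3 domains used to shade
#' recombination-landscape figures. These are configuration constants, not
#' inferred quantities.
#'
#' @return `ndj_fly_maps()` returns a named list of [chromosome_map()]s for
#'   chromosomes `"2"`, `"3"` and `"X"`; `ndj_chr2_map()` returns the
#'   chromosome 2 map alone.
#' @export
ndj_fly_maps <- function() {
  path <- system.file("extdata", "fly_maps.yaml", package = "ndjmap", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  out <- lapply(y$chromosomes, chromosome_map_from_list)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @rdname ndj_fly_maps
#' @export
ndj_chr2_map <- function() ndj_fly_maps()[["2"]]

#' Packaged approximate chromosome 2 genetic map
#'
#' A coarse bp-to-cM anchor table for chromosome 2 based on classic
#' phenotypic-marker map positions placed on dm6 coordinates; adequate for
#' reporting double-crossover distances in centimorgans.
#' @return A [genetic_map()].
#' @export
ndj_chr2_genetic_map <- function() {
  read_genetic_map(system.file("extdata", "chr2_genetic_map.tsv",
                               package = "ndjmap", mustWork = TRUE))
}
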