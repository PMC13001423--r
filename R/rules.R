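#' Interaction types recognised by the annotator
#'
#' The six non-covalent interaction classes, in canonical order. This order
#' is used everywhere an indexed set of per-type maps or attention heads
#' appears.
#'
#' @return Character vector of length 6.
#' @export
interaction_types <- function() {
  c("hbond", "salt_bridge", "vdw", "hydrophobic", "pipi", "cation_pi")
}

# van der Waals radii (Angstrom) for heavy elements seen in complexes;
# unknown elements fall back to carbon.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92
)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Default geometric rule configuration
#'
#' Distance windows (Angstrom) and optional angular filters for the six
#' interaction types, plus the strength floor used by the piecewise-linear
#' decay. Exact published cutoffs for the reference annotation pipeline are
#' not available, so these defaults follow standard interaction-profiler
#' practice and every constant is configurable; the resolved configuration
#' is logged alongside every annotation output.
#'
#' Windows:
#' \itemize{
#'   \item hbond: donor--acceptor 2.5--3.5, D-H...A angle >= 120 degrees
#'     (angle filter skipped when no hydrogens are present);
#'   \item salt_bridge: charged-group centroid to charged atom 3.0--5.5;
#'   \item vdw: per-pair window sum of vdW radii +/- 0.5;
#'   \item hydrophobic: carbon--carbon 3.3--4.0;
#'   \item pipi: ring-centroid to ring-centroid 3.5--5.5 with interplanar
#'     angle <= 30 (parallel) or 60--90 (T-shaped);
#'   \item cation_pi: cation to ring centroid 3.5--6.0.
#' }
#'
#' @param ... Named overrides, e.g. `hbond = list(d_min = 2.4, d_cut = 3.6)`.
#'   Per-type entries are merged field-by-field into the defaults.
#' @return An object of class `rule_config`.
#' @export
default_rules <- function(...) {
  rules <- list(
    hbond       = list(d_min = 2.5, d_cut = 3.5, angle_min = 120),
    salt_bridge = list(d_min = 3.0, d_cut = 5.5),
    vdw         = list(slack = 0.5),
    hydrophobic = list(d_min = 3.3, d_cut = 4.0),
    pipi        = list(d_min = 3.5, d_cut = 5.5,
                       parallel_max = 30, tshape_min = 60, tshape_max = 90),
    cation_pi   = list(d_min = 3.5, d_cut = 6.0),
    floor = 1e-6,
    aggregation = "max",
    bond_cutoff = 1.75,   # heavy-atom covalent bond detection
    h_bond_len = 1.25     # X-H covalent attachment detection
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(rules[[nm]])) {
      for (f in names(over[[nm]])) rules[[nm]][[f]] <- over[[nm]][[f]]
    } else {
      rules[[nm]] <- over[[nm]]
    }
  }
  for (t in c("hbond", "salt_bridge", "hydrophobic", "pipi", "cation_pi")) {
    if (!(rules[[t]]$d_min < rules[[t]]$d_cut)) {
      stop("rule_config: d_min must be < d_cut for type ", t)
    }
  }
  structure(rules, class = "rule_config")
}

#' Type-specific distance window
#'
#' Returns the `(d_min, d_cut)` window for a type. For `vdw` the window
#' depends on the element pair, so the two elements must be supplied.
#'
#' @param rules A `rule_config`.
#' @param type One of [interaction_types()].
#' @param elem_a,elem_b Element symbols (only used for `vdw`).
#' @return Numeric vector `c(d_min, d_cut)`.
#' @export
rule_window <- function(rules, type, elem_a = NULL, elem_b = NULL) {
  if (!type %in% interaction_types()) stop("unknown interaction type: ", type)
  if (type == "vdw") {
    if (is.null(elem_a) || is.null(elem_b)) {
      stop("vdw window requires the element pair")
    }
    s <- vdw_radius(elem_a) + vdw_radius(elem_b)
    c(s - rules$vdw$slack, s + rules$vdw$slack)
  } else {
    c(rules[[type]]$d_min, rules[[type]]$d_cut)
  }
}

#' Piecewise-linear interaction strength decay
#'
#' Maps a geometric distance to a strength in `[floor, 1]`: 1 at or below
#' `d_min`, descending linearly to `floor` (default 1e-6) at `d_cut`, and 0
#' (no contact) beyond `d_cut`. Closer contacts are stronger; zero is
#' reserved for "no contact", so every detected contact carries a strictly
#' positive strength.
#'
#' @param d Distance(s), Angstrom. Must be non-negative.
#' @param d_min Plateau distance: strengths saturate at 1 at or below it.
#' @param d_cut Cutoff: strength reaches `floor` exactly at `d_cut`.
#' @param floor Minimum strength of a contact at the cutoff.
#' @return Numeric vector of strengths, same length as `d`.
#' @examples
#' decay_strength(3.0, 2.5, 3.5)
#' decay_strength(c(2.5, 3.5, 3.6), 2.5, 3.5)  # 1, 1e-6, 0
#' @export
decay_strength <- function(d, d_min, d_cut, floor = 1e-6) {
  if (any(d < 0)) stop("distance must be non-negative")
  if (any(d_min >= d_cut)) stop("d_min must be < d_cut")
  s <- 1 + (d - d_min) / (d_cut - d_min) * (floor - 1)
  s[d <= d_min] <- 1
  s[d > d_cut] <- 0
  s
}
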