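# Arterial tree: 71-segment network definition, stiffness law, terminal
# scaling, serialization.

MMHG <- 1333.223874  # dyn/cm^2 per mmHg

#' Olufsen-type arterial wall stiffness law
#'
#' Computes the wall stiffness ratio `Eh/r0` for a vessel of unstressed
#' radius `r0` as `k1 * exp(k2 * r0) + k3`.  Large arteries (large `r0`)
#' are dominated by the additive constant `k3`, which is the tunable
#' large-artery stiffness parameter of the personalization step.
#'
#' @param r0 Unstressed vessel radius in cm (vectorized, all > 0).
#' @param law List with elements `k1`, `k3` (dyn/cm^2) and `k2` (1/cm).
#' @return `Eh/r0` in dyn/cm^2.
#' @export
wall_stiffness <- function(r0, law) {
  if (any(!is.finite(r0)) || any(r0 <= 0)) stop("r0 must be positive")
  law$k1 * exp(law$k2 * r0) + law$k3
}

default_tree_path <- function() {
  system.file("extdata", "arterial_tree_71.json", package = "pulsedose",
              mustWork = TRUE)
}

#' Read an arterial tree from its JSON description
#'
#' @param path Path to a tree JSON document (defaults to the packaged
#'   71-segment adult tree).
#' @return An object of class `pwp_tree`.
#' @export
read_tree <- function(path = default_tree_path()) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- doc$segments
  term <- seg$terminal
  tree <- structure(list(
    version = doc$version,
    reference_height_cm = doc$reference_height_cm,
    height_cm = doc$reference_height_cm,
    blood = doc$blood,
    stiffness = doc$stiffness[c("k1", "k2", "k3")],
    cuff_sites = doc$cuff_sites,
    pwv_path = doc$pwv_path,
    segments = data.frame(
      id = seg$id,
      name = seg$name,
      side = seg$side,
      full_name = trimws(paste(seg$name, seg$side)),
      length_cm = seg$length_cm,
      radius_prox_cm = seg$radius_prox_cm,
      radius_dist_cm = seg$radius_dist_cm,
      parent = seg$parent,
      R1 = term$R1_mmHg_s_ml,
      R2 = term$R2_mmHg_s_ml,
      C = term$C_ml_mmHg,
      R1_baseline = term$R1_mmHg_s_ml,
      R2_baseline = term$R2_mmHg_s_ml,
      stringsAsFactors = FALSE
    ),
    SR = 1
  ), class = "pwp_tree")
  validate_tree(tree)
  tree
}

#' Validate arterial tree invariants
#'
#' Checks that the network is a single-rooted tree with 0-2 children per
#' segment, positive geometry, Windkessel terminals on every leaf, all four
#' cuff sites resolvable and a connected root-to-femoral path.
#'
#' @param tree A `pwp_tree`.
#' @return The tree, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  s <- tree$segments
  if (sum(s$parent == 0) != 1) stop("tree must have exactly one root")
  if (any(s$length_cm <= 0) || any(s$radius_prox_cm <= 0) ||
      any(s$radius_dist_cm <= 0))
    stop("lengths and radii must be positive")
  nch <- tabulate(s$parent[s$parent > 0], nbins = nrow(s))
  if (any(nch > 2)) stop("segments may have at most 2 children")
  leaf <- nch == 0
  if (any(leaf & !is.finite(s$R1))) stop("every leaf needs a terminal")
  if (any(!leaf & is.finite(s$R1))) stop("terminals allowed on leaves only")
  # C = 0 with R2 = 0 denotes a purely resistive terminal (R1 only)
  if (any(is.finite(s$R1) & (s$R1 <= 0 | s$R2 < 0 | s$C < 0), na.rm = TRUE))
    stop("terminal R1 must be positive; R2 and C non-negative")
  # acyclicity / connectivity by walking to root
  root <- which(s$parent == 0)
  for (i in seq_len(nrow(s))) {
    j <- i; n <- 0
    while (s$parent[j] != 0) {
      j <- s$parent[j]; n <- n + 1
      if (n > nrow(s)) stop("cycle detected in parent references")
    }
    if (j != root) stop("disconnected segment: ", s$full_name[i])
  }
  for (site in unlist(tree$cuff_sites))
    if (sum(s$full_name == site) != 1)
      stop("cuff site not uniquely resolvable: ", site)
  for (nm in c(tree$pwv_path$from, tree$pwv_path$to))
    if (sum(s$full_name == nm) != 1)
      stop("pwv path endpoint not resolvable: ", nm)
  invisible(tree)
}

#' Build the default 71-segment arterial tree for a given patient height
#'
#' Returns the packaged reference topology with segment lengths scaled by
#' `height_cm / 175` (175 cm is the reference height).  Radii, stiffness
#' and terminal Windkessel values are not height-scaled.
#'
#' @param height_cm Patient height in cm.
#' @return A `pwp_tree` with 71 segments.
#' @export
build_default_tree <- function(height_cm = 175) {
  if (!is.finite(height_cm) || height_cm <= 0)
    stop("height must be positive")
  if (height_cm < 100 || height_cm > 230)
    warning("height ", height_cm, " cm outside the usual adult range")
  tree <- read_tree()
  tree$segments$length_cm <-
    tree$segments$length_cm * height_cm / tree$reference_height_cm
  tree$height_cm <- height_cm
  tree
}

#' Scale terminal Windkessel resistances
#'
#' Multiplies every terminal's `R1` and `R2` by `SR` relative to their
#' baseline (unscaled) values; compliances are unchanged.  Scaling is
#' always applied from baseline, so the operation is idempotent in `SR`.
#'
#' @param tree A `pwp_tree`.
#' @param SR Positive resistance scaling factor.
#' @return The scaled tree.
#' @export
scale_terminals <- function(tree, SR) {
  if (!is.finite(SR) || SR <= 0) stop("SR must be positive")
  tree$segments$R1 <- tree$segments$R1_baseline * SR
  tree$segments$R2 <- tree$segments$R2_baseline * SR
  tree$SR <- SR
  tree
}

#' Total peripheral resistance of the terminal Windkessels
#'
#' Series-parallel reduction of the terminal elements: each leaf
#' contributes `R1 + R2` in series, all leaves combine in parallel.
#'
#' @param tree A `pwp_tree`.
#' @return Resistance in mmHg s/ml.
#' @export
total_terminal_resistance <- function(tree) {
  s <- tree$segments
  leaf <- is.finite(s$R1)
  1 / sum(1 / (s$R1[leaf] + s$R2[leaf]))
}

#' Write an arterial tree to JSON
#'
#' @param tree A `pwp_tree`.
#' @param path Output file path.
#' @export
write_tree <- function(tree, path) {
  s <- tree$segments
  segs <- lapply(seq_len(nrow(s)), function(i) {
    t <- if (is.finite(s$R1[i]))
      list(R1_mmHg_s_ml = s$R1[i], R2_mmHg_s_ml = s$R2[i],
           C_ml_mmHg = s$C[i]) else NULL
    list(id = s$id[i], name = s$name[i], side = s$side[i],
         length_cm = s$length_cm[i], radius_prox_cm = s$radius_prox_cm[i],
         radius_dist_cm = s$radius_dist_cm[i], parent = s$parent[i],
         terminal = t)
  })
  doc <- list(version = tree$version,
              reference_height_cm = tree$reference_height_cm,
              height_scaled_fields = list("length_cm"),
              blood = tree$blood, stiffness = tree$stiffness,
              cuff_sites = tree$cuff_sites, pwv_path = tree$pwv_path,
              segments = segs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @method print pwp_tree
#' @export
print.pwp_tree <- function(x, ...) {
  s <- x$segments
  nch <- tabulate(s$parent[s$parent > 0], nbins = nrow(s))
  cat("Arterial tree:", nrow(s), "segments,", sum(nch == 0),
      "terminal Windkessels\n")
  cat("  height:", x$height_cm, "cm (reference",
      x$reference_height_cm, "cm), SR =", x$SR, "\n")
  cat("  stiffness k1/k2/k3:", format(x$stiffness$k1, digits = 4),
      format(x$stiffness$k2, digits = 4),
      format(x$stiffness$k3, digits = 4), "\n")
  cat("  cuff sites:", paste(unlist(x$cuff_sites), collapse = ", "), "\n")
  invisible(x)
}

seg_index <- function(tree, name) {
  i <- which(tree$segments$full_name == name)
  if (length(i) != 1) stop("unknown segment: ", name)
  i
}

# ids along the path root -> segment `to` (inclusive)
tree_path <- function(tree, to) {
  s <- tree$segments
  j <- seg_index(tree, to)
  path <- j
  while (s$parent[j] != 0) {
    j <- s$parent[j]
    path <- c(j, path)
  }
  path
}
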