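## Sequence simulation along phylograms and node-age calibrations.

#' Simulate a nucleotide alignment along a phylogram
#'
#' Sites evolve independently under a general time-reversible model with
#' discrete-gamma among-site rate variation (no invariant-site class).
#' Each site is assigned one of the gamma categories uniformly at random;
#' the root sequence is drawn from the stationary base frequencies.
#' Branch lengths of `phy` are expected substitutions per site.
#'
#' @param phy a rooted binary `phylo`/`phylogram` with non-negative finite
#'   branch lengths in substitutions/site.
#' @param model a [subst_model()].
#' @return A character matrix (tips x sites) of bases `A`, `C`, `G`, `T`,
#'   with `rownames` equal to `phy$tip.label`.
#' @export
simulate_alignment <- function(phy, model = subst_model()) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length) || any(!is.finite(phy$edge.length)) ||
      any(phy$edge.length < 0))
    stop("phylogram must have finite non-negative branch lengths")
  if (!ape::is.binary(phy)) stop("phylogram must be binary")
  L <- model$length
  k <- model$n_categories
  cat_rates <- if (k == 1L) 1 else
    phangorn::discrete.gamma(model$gamma_shape, k)
  site_cat <- sample.int(k, L, replace = TRUE)
  aln <- matrix(NA_character_, length(phy$tip.label), L,
                dimnames = list(phy$tip.label, NULL))
  for (ci in seq_len(k)) {
    idx <- which(site_cat == ci)
    if (length(idx) == 0L) next
    sim <- phangorn::simSeq(phy, l = length(idx),
                            Q = unname(model$rates),
                            bf = unname(model$base_freq),
                            rate = cat_rates[ci], type = "DNA")
    m <- toupper(as.character(sim))
    aln[rownames(m), idx] <- m
  }
  aln
}

#' Choose the two calibrated nodes of a tree
#'
#' Every tree receives exactly two calibrations: one at the root and one
#' at a randomly chosen non-root internal node.  The second node is drawn
#' by first picking a level uniformly between 1 and the largest number of
#' internal nodes along any root-to-tip path (the root is level 1), then
#' picking uniformly among the internal nodes at that level; draws that
#' return the root are rejected and redrawn.
#'
#' @param tree a rooted `phylo` with at least two internal nodes.
#' @return A list with `root` and `node` (ape node numbers) and the
#'   drawn `level` of the second calibration.
#' @export
choose_calibration_nodes <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (tree$Nnode < 2L)
    stop("tree must have at least two internal nodes for two calibrations")
  root <- ntip + 1L
  level <- integer(ntip + tree$Nnode)
  level[root] <- 1L
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    level[ch] <- level[p] + 1L
  }
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  max_level <- max(level[internal])
  repeat {
    lv <- sample.int(max_level, 1L)
    cand <- internal[level[internal] == lv]
    node <- if (length(cand) == 1L) cand else sample(cand, 1L)
    if (node != root)
      return(list(root = root, node = node, level = lv))
  }
}

#' Hard uniform calibration bounds at the true age +/- 15%
#'
#' @param true_age true node age (> 0), in My.
#' @return An object of class `calibration` with `age`, `lower`
#'   (`0.85 * age`), `upper` (`1.15 * age`) and `type = "hard-uniform"`.
#' @export
calibration_bounds <- function(true_age) {
  if (!is.numeric(true_age) || true_age <= 0)
    stop("true_age must be positive")
  structure(list(age = true_age, lower = 0.85 * true_age,
                 upper = 1.15 * true_age, type = "hard-uniform"),
            class = "calibration")
}

#' Build the calibration table of a simulated tree
#'
#' Selects the calibrated nodes with [choose_calibration_nodes()] and
#' derives hard uniform bounds with [calibration_bounds()].  Clades are
#' identified by their tip sets so the table is robust to node rotation.
#'
#' @param tree a `time_tree` (or ultrametric `phylo` with ages).
#' @return A data frame with one row per calibration: `clade`
#'   (comma-joined sorted tip labels), `age`, `lower`, `upper`.
#' @export
calibrations_for <- function(tree) {
  picks <- choose_calibration_nodes(tree)
  ages <- node_ages(tree)
  rows <- lapply(c(picks$root, picks$node), function(nd) {
    b <- calibration_bounds(ages[nd])
    data.frame(clade = clade_key(tree, nd), age = b$age,
               lower = b$lower, upper = b$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## canonical clade identifier: sorted tip labels, comma-joined
clade_key <- function(tree, node) {
  ntip <- length(tree$tip.label)
  tips <- if (node <= ntip) node else
    phangorn::Descendants(tree, node, "tips")[[1L]]
  paste(sort(tree$tip.label[tips]), collapse = ",")
}
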