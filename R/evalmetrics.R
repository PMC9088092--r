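## Error, topological accuracy, uncertainty and age-distribution bias of
## reconstructed trees against simulated truth.
##
## All comparisons use the rooted-clade convention: a "bipartition" is the
## tip set of an internal node, so the denominator for an n-tip binary
## tree is n - 1 clades (the root clade included).

tree_phylo <- function(x) if (inherits(x, "dated_tree")) x$phy else x
tree_ages <- function(x) {
  if (inherits(x, "dated_tree")) x$ages else node_ages(x)
}

## clade keys of every internal node, named by node number
internal_clades <- function(phy) {
  ntip <- length(phy$tip.label)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  stats::setNames(vapply(nodes, function(nd) clade_key(phy, nd), ""),
                  nodes)
}

check_same_tips <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different tip sets")
}

#' Clades present in both trees
#'
#' @param true_tree,est_tree rooted trees (`phylo` or `dated_tree`) on
#'   the same tip set.
#' @return Character vector of shared clade keys (sorted tip labels,
#'   comma-joined).
#' @export
shared_clades <- function(true_tree, est_tree) {
  ta <- tree_phylo(true_tree); tb <- tree_phylo(est_tree)
  check_same_tips(ta, tb)
  intersect(internal_clades(ta), internal_clades(tb))
}

#' Median absolute percentage error of node ages
#'
#' For every clade present in both trees, the absolute percentage error
#' `|est - true| / true * 100` of its age; the tree-level score is the
#' median over shared clades (robust to the occasional wild estimate at a
#' shallow node).  Tips (age 0) are not nodes here.
#'
#' @param true_tree a tree with true ages (`time_tree` or ultrametric
#'   `phylo`).
#' @param est_tree the estimate (`dated_tree` or ultrametric `phylo`).
#' @param exclude optional character vector of clade keys to leave out
#'   (e.g. calibrated nodes).
#' @return MAPE in percent.
#' @export
mape_node_ages <- function(true_tree, est_tree, exclude = NULL) {
  ta <- tree_phylo(true_tree); tb <- tree_phylo(est_tree)
  check_same_tips(ta, tb)
  ca <- internal_clades(ta); cb <- internal_clades(tb)
  shared <- intersect(ca, cb)
  shared <- setdiff(shared, exclude)
  if (length(shared) == 0L) stop("no shared clades to score")
  age_a <- tree_ages(true_tree)[as.integer(names(ca)[match(shared, ca)])]
  age_b <- tree_ages(est_tree)[as.integer(names(cb)[match(shared, cb)])]
  keep <- age_a > 0
  stats::median(abs(age_b[keep] - age_a[keep]) / age_a[keep]) * 100
}

#' Topological error: true clades missing from the estimate
#'
#' One-sided count of true-tree clades absent from the estimated tree
#' ("number of true bipartitions not reconstructed").
#'
#' @inheritParams shared_clades
#' @return Non-negative integer count.
#' @export
topological_error <- function(true_tree, est_tree) {
  ta <- tree_phylo(true_tree); tb <- tree_phylo(est_tree)
  check_same_tips(ta, tb)
  length(setdiff(internal_clades(ta), internal_clades(tb)))
}

#' Robinson-Foulds distance (rooted-clade version)
#'
#' Symmetric-difference count of the two trees' clade sets.  For two
#' binary trees on the same tips this is twice [topological_error()].
#'
#' @inheritParams shared_clades
#' @return Non-negative integer count.
#' @export
rf_distance <- function(true_tree, est_tree) {
  ta <- tree_phylo(true_tree); tb <- tree_phylo(est_tree)
  check_same_tips(ta, tb)
  ca <- internal_clades(ta); cb <- internal_clades(tb)
  length(setdiff(ca, cb)) + length(setdiff(cb, ca))
}

#' Branch score (Kuhner-Felsenstein) distance
#'
#' Square root of the sum of squared branch length differences over the
#' union of clades of the two trees, tips included; a branch present in
#' only one tree is treated as having length zero in the other.
#'
#' @inheritParams shared_clades
#' @return Non-negative distance in branch-length units.
#' @export
branch_score <- function(true_tree, est_tree) {
  ta <- tree_phylo(true_tree); tb <- tree_phylo(est_tree)
  check_same_tips(ta, tb)
  if (is.null(ta$edge.length) || is.null(tb$edge.length))
    stop("both trees need branch lengths")
  blen <- function(phy) {
    ntip <- length(phy$tip.label)
    keys <- vapply(phy$edge[, 2L], function(nd) clade_key(phy, nd), "")
    stats::setNames(phy$edge.length, keys)
  }
  la <- blen(ta); lb <- blen(tb)
  keys <- union(names(la), names(lb))
  da <- ifelse(keys %in% names(la), la[keys], 0)
  db <- ifelse(keys %in% names(lb), lb[keys], 0)
  sqrt(sum((da - db)^2))
}

#' Mean 95% HPD interval width as a percentage of node age
#'
#' Averages `(upper - lower) / point age * 100` over the internal nodes
#' carrying an HPD interval and a positive point age.
#'
#' @param est_tree a `dated_tree` with HPD annotations.
#' @return Mean width in percent.
#' @export
hpd_width_pct <- function(est_tree) {
  stopifnot(inherits(est_tree, "dated_tree"))
  ages <- est_tree$ages
  hpd <- est_tree$hpd
  ok <- !is.na(hpd[, 1L]) & !is.na(hpd[, 2L]) & ages > 0
  if (!any(ok)) stop("no nodes carry an HPD interval")
  mean((hpd[ok, 2L] - hpd[ok, 1L]) / ages[ok]) * 100
}

#' Gamma statistic of an ultrametric tree
#'
#' Standardized summary of the distribution of internode intervals
#' (Pybus-Harvey).  With `g_k` the duration during which exactly `k`
#' lineages exist and `T = sum(k * g_k)`, the statistic is
#' `[(1/(n-2)) * sum_{i=2}^{n-1} sum_{k=2}^{i} k g_k - T/2] /
#'  (T * sqrt(1 / (12 (n-2))))`.
#' It follows a standard normal distribution for trees generated by a
#' constant-rate pure-birth process; larger values indicate relatively
#' more length near the root.
#'
#' @param tree an ultrametric tree (`phylo`, `time_tree` or
#'   `dated_tree`) with at least 3 tips.
#' @param tol relative ultrametricity tolerance on tip ages.
#' @return The gamma value.
#' @export
gamma_statistic <- function(tree, tol = 1e-6) {
  ages <- tree_ages(tree)
  phy <- tree_phylo(tree)
  ntip <- length(phy$tip.label)
  if (ntip < 3L) stop("gamma requires at least 3 tips")
  if (any(abs(ages[seq_len(ntip)]) > tol * max(ages)))
    stop("tree is not ultrametric within tolerance")
  node_age <- sort(ages[(ntip + 1L):(ntip + phy$Nnode)], decreasing = TRUE)
  ## g[k] = interval during which exactly k lineages exist, k = 2..n
  bounds <- c(node_age, 0)
  g <- bounds[seq_len(ntip - 1L)] - bounds[-1L]
  k <- 2:ntip
  kg <- k * g
  Tt <- sum(kg)
  inner <- sum(cumsum(kg)[seq_len(ntip - 2L)]) / (ntip - 2L)
  (inner - Tt / 2) / (Tt * sqrt(1 / (12 * (ntip - 2L))))
}

#' Difference in gamma between estimate and truth
#'
#' `gamma(est) - gamma(true)`.  A negative difference means the
#' reconstructed node ages are pushed rootward (older) relative to the
#' truth; positive means tipward.
#'
#' @param est_tree,true_tree ultrametric trees with the same tip number.
#' @param tol passed to [gamma_statistic()].
#' @return The signed difference.
#' @export
gamma_difference <- function(est_tree, true_tree, tol = 1e-6) {
  ea <- tree_phylo(est_tree); tr <- tree_phylo(true_tree)
  if (length(ea$tip.label) != length(tr$tip.label))
    stop("trees must have the same number of tips")
  gamma_statistic(est_tree, tol) - gamma_statistic(true_tree, tol)
}

#' Per-replicate evaluation report
#'
#' Bundles all error metrics of one reconstructed tree against its truth.
#'
#' @param true_tree the simulated `time_tree` (or ultrametric `phylo`).
#' @param est_tree the estimate (`dated_tree` for HPD metrics).
#' @param true_phylogram optional true branch lengths in subs/site for the
#'   branch score (defaults to comparing the time trees' lengths).
#' @return A one-row data frame: `mape`, `topo_error`, `rf`,
#'   `branch_score`, `hpd_width`, `gamma_true`, `gamma_est`,
#'   `gamma_diff`.
#' @export
metrics_report <- function(true_tree, est_tree, true_phylogram = NULL) {
  bs_true <- if (is.null(true_phylogram)) true_tree else true_phylogram
  hw <- if (inherits(est_tree, "dated_tree") &&
            any(!is.na(est_tree$hpd[, 1L])))
    hpd_width_pct(est_tree) else NA_real_
  gt <- gamma_statistic(true_tree)
  ge <- gamma_statistic(est_tree)
  data.frame(
    mape = mape_node_ages(true_tree, est_tree),
    topo_error = topological_error(true_tree, est_tree),
    rf = rf_distance(true_tree, est_tree),
    branch_score = branch_score(bs_true, est_tree),
    hpd_width = hw,
    gamma_true = gt, gamma_est = ge, gamma_diff = ge - gt)
}
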