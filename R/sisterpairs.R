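## Root-split sister-pair datasets and the contrast regression used to
## probe for a rate-diversification correlation, plus the selection
## filter for the Continuous model's replicate sets.

#' Build the sister-pair dataset of a set of trees
#'
#' Each tree contributes one pair: the two clades that split at the root.
#' Both clades are subsampled to the size of the smaller clade (uniformly
#' at random) -- the even-sampling device used to curb the node-density
#' effect -- and a per-clade branch-length summary is computed on the
#' sampled tips.  Clade sizes reported (and used in contrasts) are the
#' full, unsubsampled sizes.
#'
#' Two summaries are available.  The default, `"root_to_tip"`, is the
#' median over sampled tips of the path length from the root split to the
#' tip (the clade's stem branch included): both clades then span exactly
#' the same time depth, so under unlinked rate evolution the summary
#' carries no clade-size signal, while rate-size coupling (continuous
#' covariance or node-associated bursts, hidden events included)
#' lengthens the larger clade's paths.  The alternative,
#' `"branch_median"`, is the median over all branches of the subsampled
#' clade subtree, stem excluded; note that branch merging in a sparsely
#' subsampled large clade, and the older crown of a larger clade, make
#' summaries computed below the root split increase with clade size even
#' for unlinked rates (pure tree-shape artifacts), so this variant is
#' kept only for comparison.
#'
#' @param trees list of rooted binary `phylo` objects whose branch
#'   lengths are in substitutions/site (true phylograms or estimates).
#' @param summary per-clade branch-length summary, see Details.
#' @return A list of `sister_pair` objects: `tips_a`, `tips_b`,
#'   `size_a`, `size_b`, `median_a`, `median_b`.  A single-tip clade has
#'   a defined root-to-tip summary (its stem) but an undefined (NA)
#'   stem-excluded branch median.
#' @export
build_pairs <- function(trees,
                        summary = c("root_to_tip", "branch_median")) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  summary <- match.arg(summary)
  lapply(seq_along(trees), function(i) {
    phy <- trees[[i]]
    ntip <- length(phy$tip.label)
    root <- ntip + 1L
    kids <- phy$edge[phy$edge[, 1L] == root, 2L]
    if (length(kids) != 2L)
      stop("tree ", i, " does not have a two-child root")
    tipset <- lapply(kids, function(nd) {
      tp <- if (nd <= ntip) nd else
        phangorn::Descendants(phy, nd, "tips")[[1L]]
      phy$tip.label[tp]
    })
    if (any(lengths(tipset) == 0L)) stop("root child with zero tips")
    k <- min(lengths(tipset))
    med <- vapply(seq_len(2L), function(j) {
      samp <- if (lengths(tipset)[j] == k) tipset[[j]] else
        sample(tipset[[j]], k)
      clade_length_summary(phy, kids[j], samp, summary)
    }, numeric(1L))
    structure(list(replicate = i,
                   tips_a = tipset[[1L]], tips_b = tipset[[2L]],
                   size_a = length(tipset[[1L]]),
                   size_b = length(tipset[[2L]]),
                   median_a = med[1L], median_b = med[2L]),
              class = "sister_pair")
  })
}

## branch-length summary of a root-child clade over the sampled tips
clade_length_summary <- function(phy, clade_root, tips, summary) {
  ntip <- length(phy$tip.label)
  stem <- phy$edge.length[phy$edge[, 2L] == clade_root]
  if (summary == "branch_median") {
    if (clade_root <= ntip || length(tips) < 2L) return(NA_real_)
    sub2 <- ape::keep.tip(ape::extract.clade(phy, clade_root), tips)
    return(stats::median(sub2$edge.length))
  }
  ## root_to_tip: stem + depth below the clade root, so both clades of a
  ## pair span the same time depth
  if (clade_root <= ntip) return(stem)       # single-tip clade
  sub <- ape::extract.clade(phy, clade_root)
  depth <- ape::node.depth.edgelength(sub)
  stem + stats::median(depth[match(tips, sub$tip.label)])
}

#' Contrasts of a sister pair
#'
#' `(log size_a - log size_b, log median_a - log median_b)` under a fixed
#' arbitrary labelling; the downstream regression is through the origin,
#' so the sign of the labelling is immaterial.  Pairs with a zero or
#' missing median yield `NA` contrasts (dropped, with a warning, by
#' [regress_contrasts()]).
#'
#' @param pair a `sister_pair` from [build_pairs()].
#' @return Named numeric vector `c(d_log_size, d_log_median)`.
#' @export
pair_contrast <- function(pair) {
  stopifnot(inherits(pair, "sister_pair"))
  bad <- is.na(pair$median_a) || is.na(pair$median_b) ||
    pair$median_a <= 0 || pair$median_b <= 0
  c(d_log_size = log(pair$size_a) - log(pair$size_b),
    d_log_median = if (bad) NA_real_ else
      log(pair$median_a) - log(pair$median_b))
}

#' Contrast dataset of a set of sister pairs
#'
#' @param pairs list of `sister_pair` objects.
#' @return Data frame with one row per pair: `replicate`, `d_log_size`,
#'   `d_log_median`.
#' @export
contrast_dataset <- function(pairs) {
  rows <- t(vapply(pairs, pair_contrast, numeric(2L)))
  data.frame(replicate = vapply(pairs, `[[`, 0L, "replicate"),
             d_log_size = rows[, 1L], d_log_median = rows[, 2L])
}

#' Through-origin regression of size contrasts on length contrasts
#'
#' Least-squares regression through the origin of the log clade size
#' contrasts on the log median branch length contrasts, with a two-sided
#' t-test on the slope (df = n - 1).  Pairs with missing contrasts are
#' dropped with a warning.
#'
#' @param dataset data frame from [contrast_dataset()] (columns
#'   `d_log_size`, `d_log_median`).
#' @return List with `slope`, `p`, `sign` (+1/-1/0), `n`.
#' @export
regress_contrasts <- function(dataset) {
  ok <- stats::complete.cases(dataset[c("d_log_size", "d_log_median")])
  if (any(!ok))
    warning(sum(!ok), " pair(s) dropped (zero or undefined median)")
  x <- dataset$d_log_median[ok]
  y <- dataset$d_log_size[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 usable pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("all length contrasts are zero: regression undefined")
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  se <- sqrt(rss / (n - 1L) / sxx)
  tval <- if (se == 0) Inf * sign(slope) else slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 1L)
  list(slope = slope, p = p, sign = sign(slope), n = n)
}

#' Select a Continuous-model replicate set that shows the empirical
#' rate-diversification correlation
#'
#' Simulated Continuous sets are screened with the sister-pair regression
#' on their true branch lengths; the first candidate whose regression has
#' a positive slope significant at `alpha` is accepted, mirroring the
#' selection of a set that reproduces the empirically observed positive
#' correlation between clade size and branch length.
#'
#' @param candidates list of candidate sets, each a list of phylograms
#'   (true branch lengths).
#' @param alpha significance level of the selection filter.
#' @return List with `set` (the accepted candidate), `index`, `tried`,
#'   and the accepted `fit`.
#' @export
select_continuous_replicates <- function(candidates, alpha = 0.05) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  for (i in seq_along(candidates)) {
    fit <- regress_contrasts(contrast_dataset(build_pairs(candidates[[i]])))
    if (fit$sign > 0 && fit$p < alpha)
      return(list(set = candidates[[i]], index = i, tried = i, fit = fit))
  }
  stop("no candidate set passed the selection filter within the budget (",
       length(candidates), " sets tried)")
}
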