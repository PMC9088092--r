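## Punctuated model: bursts of substitutions at speciation events.
##
## Every lineage in a conditioned run is the daughter of some speciation
## event (the two crown lineages are daughters of the root divergence), so
## burst bookkeeping is per lineage: each lineage carries the burst granted
## at its birth.  Bursts at events whose daughters left no extant
## descendants are lost with those lineages; bursts on surviving lineages
## are absorbed into the pruned branch containing the lineage, which makes
## hidden speciation events contribute to surviving branch lengths.

#' Draw the per-tree burst fraction of total tree length
#'
#' The fraction of total tree length (substitutions/site, summed over all
#' branches) contributed by node-associated bursts is drawn per tree from
#' `Normal(mean_fraction, sd_fraction)` truncated to (0, 1) by redrawing.
#'
#' @param config a [burst_config()].
#' @return A single fraction in (0, 1).
#' @export
draw_tree_burst_fraction <- function(config) {
  stopifnot(inherits(config, "burst_config"))
  if (config$sd_fraction == 0) return(config$mean_fraction)
  repeat {
    f <- stats::rnorm(1L, config$mean_fraction, config$sd_fraction)
    if (f > 0 && f < 1) return(f)
  }
}

#' Assign burst magnitudes to every speciation event of a run
#'
#' Draws an i.i.d. raw burst for each (speciation event, daughter lineage)
#' pair -- including the root divergence and events whose descendants all
#' went extinct -- then rescales all bursts by the common factor that makes
#' the burst share of the pruned extant tree equal the target fraction
#' exactly: the rescaled bursts landing on surviving branches sum to
#' `fraction / (1 - fraction)` times the gradual substitution total.
#'
#' @param run a conditioned `full_tree` (extinct lineages retained).
#' @param fraction per-tree target burst fraction, typically from
#'   [draw_tree_burst_fraction()]; `0` is allowed and zeroes all bursts.
#' @param config a [burst_config()] giving the raw magnitude family.
#' @param pruned optionally, the result of `prune_extinct(run)` if already
#'   computed (avoids recomputation).
#' @return An object of class `burst_assignment`: per-lineage scaled burst
#'   lengths (`burst`), the raw draws (`raw`), the common `scale`, the
#'   target `fraction`, and the `run_id` tying it to `run`.
#' @export
assign_bursts <- function(run, fraction, config = burst_config(),
                          pruned = NULL) {
  stopifnot(inherits(run, "full_tree"), inherits(config, "burst_config"))
  if (is.null(run$present))
    stop("run must be conditioned (gsa_condition) before assigning bursts")
  nlin <- length(run$parent)
  if (nlin < 2L) stop("tree has no speciation events")
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  raw <- switch(config$family,
                exponential = stats::rexp(nlin, config$rate),
                fixed = rep(1 / config$rate, nlin))
  if (is.null(pruned)) pruned <- prune_extinct(run)
  if (pruned$run_id != run$run_id)
    stop("pruned tree does not belong to this run")
  surv_ids <- unlist(pruned$edge_chains)
  gradual_total <- sum(pruned$edge_subs)
  raw_surv <- sum(raw[surv_ids])
  scale <- if (fraction == 0) 0 else
    (fraction / (1 - fraction)) * gradual_total / raw_surv
  structure(list(burst = raw * scale, raw = raw, scale = scale,
                 fraction = fraction, run_id = run$run_id),
            class = "burst_assignment")
}

#' Add assigned bursts to a pruned time tree, giving the phylogram
#'
#' Each surviving branch receives the bursts of all lineages merged into
#' it: the burst granted at its top node (visible speciation or root) plus
#' one burst per hidden speciation event absorbed during pruning.  Branch
#' lengths of the result are gradual + burst substitutions/site, and the
#' burst share of total tree length equals the assignment's target
#' fraction exactly.
#'
#' @param tree a `time_tree` from [prune_extinct()].
#' @param assignment a `burst_assignment` produced on the same run.
#' @return An object of class `c("phylogram", "phylo")` with fields
#'   `edge_gradual`, `edge_burst` and `burst_fraction`.
#' @export
punctuate_phylogram <- function(tree, assignment) {
  stopifnot(inherits(tree, "time_tree"),
            inherits(assignment, "burst_assignment"))
  if (tree$run_id != assignment$run_id)
    stop("assignment was generated on a different run than this tree")
  eb <- vapply(tree$edge_chains,
               function(ch) sum(assignment$burst[ch]), numeric(1L))
  pg <- tree
  pg$edge.length <- tree$edge_subs + eb
  pg$edge_gradual <- tree$edge_subs
  pg$edge_burst <- eb
  pg$burst_fraction <- assignment$fraction
  class(pg) <- c("phylogram", "phylo")
  pg
}

#' Tabulate a burst assignment over the surviving tree
#'
#' One row per surviving lineage (= per visible or hidden speciation
#' event feeding an extant branch): the event time, the pruned-tree edge
#' the burst lands on, and the burst length.
#'
#' @param tree a `time_tree`; `assignment` the matching
#'   `burst_assignment`; `run` the conditioned `full_tree`.
#' @param assignment,run see above.
#' @return A data frame with columns `edge`, `lineage`, `event_time`,
#'   `burst`.
#' @export
burst_table <- function(tree, assignment, run) {
  stopifnot(tree$run_id == assignment$run_id,
            tree$run_id == run$run_id)
  rows <- lapply(seq_along(tree$edge_chains), function(i) {
    ch <- tree$edge_chains[[i]]
    data.frame(edge = i, lineage = ch, event_time = run$birth[ch],
               burst = assignment$burst[ch])
  })
  do.call(rbind, rows)
}
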