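# Independent brute-force oracles and small tree constructors.  These
# deliberately avoid the package's own clade/age machinery: clades are
# enumerated by walking the edge matrix directly.

# set of rooted clades (sorted, comma-joined tip labels) by edge walking
bf_clades <- function(phy, include_tips = FALSE) {
  ntip <- length(phy$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  nodes <- (ntip + 1):(ntip + phy$Nnode)
  if (include_tips) nodes <- c(seq_len(ntip), nodes)
  vapply(nodes, function(nd)
    paste(sort(tips_below(nd)), collapse = ","), "")
}

bf_rf <- function(a, b) {
  ca <- bf_clades(a); cb <- bf_clades(b)
  sum(!(ca %in% cb)) + sum(!(cb %in% ca))
}

bf_topo <- function(a, b) {
  ca <- bf_clades(a); cb <- bf_clades(b)
  sum(!(ca %in% cb))
}

bf_branch_score <- function(a, b) {
  key_len <- function(phy) {
    ntip <- length(phy$tip.label)
    tips_below <- function(node) {
      if (node <= ntip) return(phy$tip.label[node])
      kids <- phy$edge[phy$edge[, 1] == node, 2]
      unlist(lapply(kids, tips_below))
    }
    out <- list()
    for (i in seq_len(nrow(phy$edge))) {
      k <- paste(sort(tips_below(phy$edge[i, 2])), collapse = ",")
      out[[k]] <- phy$edge.length[i]
    }
    out
  }
  la <- key_len(a); lb <- key_len(b)
  total <- 0
  for (k in union(names(la), names(lb))) {
    da <- if (!is.null(la[[k]])) la[[k]] else 0
    db <- if (!is.null(lb[[k]])) lb[[k]] else 0
    total <- total + (da - db)^2
  }
  sqrt(total)
}

# independently coded Pybus-Harvey gamma via explicit double loop
bf_gamma <- function(phy) {
  bt <- sort(unname(ape::branching.times(phy)), decreasing = TRUE)
  n <- length(phy$tip.label)
  g <- numeric(n)  # g[k] for k = 2..n
  bounds <- c(bt, 0)
  for (k in 2:n) g[k] <- bounds[k - 1] - bounds[k]
  Tt <- 0
  for (k in 2:n) Tt <- Tt + k * g[k]
  acc <- 0
  for (i in 2:(n - 1)) {
    s <- 0
    for (k in 2:i) s <- s + k * g[k]
    acc <- acc + s
  }
  (acc / (n - 2) - Tt / 2) / (Tt * sqrt(1 / (12 * (n - 2))))
}

# two random rooted binary trees on the same labelled tips
random_tree_pair <- function(n = 8) {
  a <- ape::rtree(n)
  b <- ape::rtree(n)
  b$tip.label <- sample(a$tip.label)
  list(a = a, b = b)
}

# rebuild an ultrametric tree with transformed internal ages (same topology)
retime_tree <- function(phy, f) {
  ages <- max(ape::node.depth.edgelength(phy)) -
    ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  ages[seq_len(ntip)] <- 0
  new_ages <- ages
  idx <- (ntip + 1):(ntip + phy$Nnode)
  new_ages[idx] <- f(ages[idx])
  out <- phy
  out$edge.length <- new_ages[phy$edge[, 1]] - new_ages[phy$edge[, 2]]
  out
}

# hand-built conditioned run with two candidate n=3 intervals of
# durations 3 ([1,4)) and 1 ([5,6)); see test-simcore
two_interval_run <- function() {
  params <- sim_params(lambda0 = 0.1, r0 = 0.01, mu = 0.05, q = 1,
                       sigma2_lambda = 0, sigma2_r = 0, n_tips = 3)
  structure(list(
    parent = c(0L, 0L, 2L, 2L, 4L, 4L),
    birth = c(0, 0, 1, 1, 5, 5),
    death = c(NA, 1, 4, 5, NA, NA),
    u_lam = rep(log(0.1), 6), u_r = rep(log(0.01), 6),
    lastj0 = c(0, 0, 1, 1, 5, 5),
    jumps = list(lineage = integer(0), time = numeric(0),
                 u_lam = numeric(0), u_r = numeric(0)),
    events = list(time = c(1, 4, 5), delta = c(1L, -1L, 1L)),
    t_end = 6, present = NULL, params = params,
    run_id = "fixture-two-intervals", failed = FALSE, fail_reason = NULL),
    class = "full_tree")
}

# quick simulated replicate at reduced size for property tests
small_replicate <- function(n_tips = 10, punctuated = FALSE, q = 10) {
  p <- sim_params(n_tips = n_tips, q = q)
  simulate_time_tree(p, punctuated = punctuated)
}
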