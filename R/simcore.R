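## Forward-time birth-death simulation with jointly evolving speciation and
## substitution rates, conditioned on tip number by the Generalised
## Sampling Approach (GSA).
##
## A "full_tree" records every lineage ever born:
##   parent, birth, death (NA while alive), transformed rate state at birth
##   (log rates under the default log-scale Brownian motion), the inherited
##   time of the last rate jump, and a global time-ordered log of rate
##   jumps.  The speciation/extinction event log supports GSA conditioning.

new_run_id <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    sprintf("run-%d-%d", Sys.getpid(), counter)
  }
})

## transform between natural rates and the internal evolution scale
.to_state <- function(rate, params) {
  if (params$rate_scale == "log") log(rate) else rate
}
.to_rate <- function(u, params) {
  if (params$rate_scale == "log") exp(u) else pmax(u, params$rate_floor)
}

#' Draw the waiting time to the next simulation event
#'
#' Given the current speciation rates of all live lineages, draws the time
#' to the next event from an exponential distribution with rate equal to
#' the sum of the rates of all events (speciation, extinction, rate jump)
#' in all lineages, then picks the event type with probability
#' proportional to its total rate and the affected lineage proportionally
#' to its own contribution.
#'
#' @param lambda numeric vector of current speciation rates, one per live
#'   lineage.
#' @param mu extinction rate (per lineage).
#' @param q rate-jump event rate (per lineage).
#' @return A list with elements `dt` (waiting time), `event` (one of
#'   `"speciation"`, `"extinction"`, `"rate_jump"`), and `lineage` (index
#'   into `lambda`).
#' @export
draw_waiting_time <- function(lambda, mu, q) {
  n <- length(lambda)
  if (n == 0L) stop("no live lineages: the simulation state is empty")
  stopifnot(all(lambda >= 0), mu >= 0, q >= 0)
  S <- sum(lambda)
  total <- S + n * (mu + q)
  if (total <= 0) stop("total event rate is zero")
  dt <- stats::rexp(1L, total)
  u <- stats::runif(1L) * total
  if (u < n * q) {
    list(dt = dt, event = "rate_jump", lineage = sample.int(n, 1L))
  } else if (u < n * q + S) {
    k <- if (n == 1L) 1L else sample.int(n, 1L, prob = lambda)
    list(dt = dt, event = "speciation", lineage = k)
  } else {
    list(dt = dt, event = "extinction", lineage = sample.int(n, 1L))
  }
}

#' Draw bivariate rate increments
#'
#' Increments of the (log-scale, by default) speciation/substitution rate
#' pair are bivariate normal with mean zero and covariance `Sigma * dt`,
#' where `Sigma` is the instantaneous variance-covariance matrix of
#' [sigma_matrix()] and `dt` the time elapsed since the lineage's last
#' jump.
#'
#' @param params a [sim_params()] object.
#' @param dt elapsed time since the last jump (>= 0).
#' @param n number of increment pairs to draw.
#' @return An `n` x 2 matrix with columns `lambda` and `r`.
#' @export
draw_rate_increments <- function(params, dt, n = 1L) {
  if (dt < 0) stop("dt must be non-negative")
  Sig <- sigma_matrix(params)
  if (all(Sig == 0) || dt == 0)
    return(matrix(0, n, 2L, dimnames = list(NULL, c("lambda", "r"))))
  L <- chol_sigma(Sig)
  z <- matrix(stats::rnorm(2L * n), n, 2L)
  inc <- sqrt(dt) * (z %*% t(L))
  dimnames(inc) <- list(NULL, c("lambda", "r"))
  inc
}

## lower-triangular factor, tolerating singular Sigma (rho = +-1 or a
## zero variance)
chol_sigma <- function(Sig) {
  a <- sqrt(Sig[1L, 1L])
  b <- if (a > 0) Sig[2L, 1L] / a else 0
  c2 <- Sig[2L, 2L] - b^2
  matrix(c(a, b, 0, sqrt(max(c2, 0))), 2L, 2L)
}

#' Apply a rate-jump event to a lineage state
#'
#' Adds a bivariate-normal increment with covariance `Sigma * dt` to the
#' lineage's rate pair (on the evolution scale of `params`).  Under the
#' default log-scale evolution the rates stay strictly positive; under
#' natural-scale evolution they are reflected at `params$rate_floor`.
#'
#' @param state list with elements `lambda` and `r`, the lineage's current
#'   rates on the natural scale.
#' @param params a [sim_params()] object.
#' @param dt_since_last_jump elapsed time since this lineage's last jump.
#' @return The updated state list.
#' @export
apply_rate_jump <- function(state, params, dt_since_last_jump) {
  if (dt_since_last_jump < 0) stop("dt_since_last_jump must be non-negative")
  inc <- unname(draw_rate_increments(params, dt_since_last_jump, 1L))
  if (all(inc == 0)) return(state)     # degenerate (zero-variance) jump
  u <- c(.to_state(state$lambda, params) + inc[1L, 1L],
         .to_state(state$r, params) + inc[1L, 2L])
  if (params$rate_scale == "natural") {
    fl <- params$rate_floor
    u <- fl + abs(u - fl)        # reflect at the positive floor
  }
  state$lambda <- .to_rate(u[1L], params)
  state$r <- .to_rate(u[2L], params)
  state
}

#' Simulate the complete birth-death history, extinct lineages included
#'
#' Runs the forward-time process from two crown lineages at time 0 (the
#' root node is the first divergence), both initialized at
#' `(lambda0, r0)`.  At each step the waiting time to the next event is
#' exponential with rate equal to the summed event rates over all live
#' lineages; the event is a speciation (daughters inherit the parental
#' rates and last-jump time), an extinction, or a rate jump.  The run
#' stops when the number of live lineages first reaches `stop_tips` or at
#' `max_time`, whichever comes first.
#'
#' @param params a [sim_params()] object.
#' @param stop_tips stop when this many lineages are simultaneously alive.
#' @param max_time stop at this time if `stop_tips` was not reached.
#' @return An object of class `full_tree`.  If all lineages died before
#'   the stop condition the run is flagged with `$failed = TRUE` and the
#'   caller is expected to retry.
#' @export
simulate_full_tree <- function(params,
                               stop_tips = ceiling(1.5 * params$n_tips),
                               max_time = 500) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(stop_tips) && !is.finite(max_time))
    stop("either stop_tips or a finite max_time is required")
  if (is.null(stop_tips)) stop_tips <- Inf
  mu <- params$mu; q <- params$q
  Sig <- sigma_matrix(params)
  Lc <- chol_sigma(Sig)
  zero_sigma <- all(Sig == 0)
  logscale <- params$rate_scale == "log"
  fl <- params$rate_floor

  cap <- 1024L
  parent <- integer(cap); birth <- numeric(cap)
  death <- rep(NA_real_, cap)
  u_lam <- numeric(cap); u_r <- numeric(cap)   # state at birth
  lastj <- numeric(cap)
  u0 <- c(.to_state(params$lambda0, params), .to_state(params$r0, params))
  nlin <- 2L
  parent[1:2] <- 0L; birth[1:2] <- 0
  u_lam[1:2] <- u0[1L]; u_r[1:2] <- u0[2L]; lastj[1:2] <- 0

  ## current (possibly jumped) state per lineage
  cur_ul <- u_lam; cur_ur <- u_r

  jcap <- 4096L
  j_lin <- integer(jcap); j_t <- numeric(jcap)
  j_ul <- numeric(jcap); j_ur <- numeric(jcap); nj <- 0L

  ecap <- 1024L
  ev_t <- numeric(ecap); ev_d <- integer(ecap); nev <- 0L

  alive <- c(1L, 2L)
  lam_a <- rep(.to_rate(u0[1L], params), 2L)
  t <- 0

  finish <- function(failed, reason = NULL) {
    structure(list(
      parent = parent[seq_len(nlin)], birth = birth[seq_len(nlin)],
      death = death[seq_len(nlin)],
      u_lam = u_lam[seq_len(nlin)], u_r = u_r[seq_len(nlin)],
      lastj0 = lastj[seq_len(nlin)],
      jumps = list(lineage = j_lin[seq_len(nj)], time = j_t[seq_len(nj)],
                   u_lam = j_ul[seq_len(nj)], u_r = j_ur[seq_len(nj)]),
      events = list(time = ev_t[seq_len(nev)], delta = ev_d[seq_len(nev)]),
      t_end = t, present = NULL, params = params,
      run_id = new_run_id(), failed = failed, fail_reason = reason),
      class = "full_tree")
  }

  repeat {
    n <- length(alive)
    if (n == 0L) return(finish(TRUE, "all lineages went extinct"))
    if (n >= stop_tips) break
    S <- sum(lam_a)
    total <- S + n * (mu + q)
    dt <- stats::rexp(1L, total)
    if (t + dt > max_time) { t <- max_time; break }
    t <- t + dt
    u <- stats::runif(1L) * total
    if (u < n * q) {
      ## rate jump
      k <- sample.int(n, 1L)
      id <- alive[k]
      if (!zero_sigma) {
        dtj <- t - lastj[id]
        z <- Lc %*% stats::rnorm(2L) * sqrt(dtj)
        ul <- cur_ul[id] + z[1L]; ur <- cur_ur[id] + z[2L]
        if (!logscale) { ul <- fl + abs(ul - fl); ur <- fl + abs(ur - fl) }
        cur_ul[id] <- ul; cur_ur[id] <- ur
        lam_a[k] <- .to_rate(ul, params)
      }
      lastj[id] <- t
      nj <- nj + 1L
      if (nj > jcap) {
        jcap <- jcap * 2L
        length(j_lin) <- jcap; length(j_t) <- jcap
        length(j_ul) <- jcap; length(j_ur) <- jcap
      }
      j_lin[nj] <- id; j_t[nj] <- t
      j_ul[nj] <- cur_ul[id]; j_ur[nj] <- cur_ur[id]
    } else if (u < n * q + S) {
      ## speciation: both daughters retain the parental rates and
      ## inherit the parental last-jump time
      k <- if (n == 1L) 1L else sample.int(n, 1L, prob = lam_a)
      id <- alive[k]
      if (nlin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(birth) <- cap
        death <- c(death, rep(NA_real_, cap - length(death)))
        length(u_lam) <- cap; length(u_r) <- cap; length(lastj) <- cap
        length(cur_ul) <- cap; length(cur_ur) <- cap
      }
      d1 <- nlin + 1L; d2 <- nlin + 2L; nlin <- nlin + 2L
      parent[c(d1, d2)] <- id; birth[c(d1, d2)] <- t
      u_lam[c(d1, d2)] <- cur_ul[id]; u_r[c(d1, d2)] <- cur_ur[id]
      cur_ul[c(d1, d2)] <- cur_ul[id]; cur_ur[c(d1, d2)] <- cur_ur[id]
      lastj[c(d1, d2)] <- lastj[id]
      death[id] <- t
      alive <- c(alive[-k], d1, d2)
      lam_a <- c(lam_a[-k], rep(.to_rate(cur_ul[id], params), 2L))
      nev <- nev + 1L
      if (nev > ecap) {
        ecap <- ecap * 2L
        length(ev_t) <- ecap; length(ev_d) <- ecap
      }
      ev_t[nev] <- t; ev_d[nev] <- 1L
    } else {
      ## extinction
      k <- sample.int(n, 1L)
      id <- alive[k]
      death[id] <- t
      alive <- alive[-k]; lam_a <- lam_a[-k]
      nev <- nev + 1L
      if (nev > ecap) {
        ecap <- ecap * 2L
        length(ev_t) <- ecap; length(ev_d) <- ecap
      }
      ev_t[nev] <- t; ev_d[nev] <- -1L
    }
  }
  finish(FALSE)
}

#' @export
print.full_tree <- function(x, ...) {
  cat(sprintf("Complete birth-death history: %d lineages, t_end = %.3f%s\n",
              length(x$parent), x$t_end,
              if (isTRUE(x$failed)) " [FAILED RUN]" else ""))
  if (!is.null(x$present))
    cat(sprintf("  conditioned present = %.3f, %d extant lineages\n",
                x$present, sum(extant_lineages(x))))
  invisible(x)
}

## logical vector: alive at the (conditioned) present
extant_lineages <- function(run) {
  pr <- if (is.null(run$present)) run$t_end else run$present
  run$birth < pr & (is.na(run$death) | run$death > pr)
}

#' Condition a run on a fixed tip number (Generalised Sampling Approach)
#'
#' Scans the run's event log for the maximal time intervals during which
#' exactly `n_tips` lineages are extant, samples one interval with
#' probability proportional to its duration and a present time uniformly
#' within it, and truncates the run at that time.  Lineages alive at the
#' sampled present become the extant tips; births, deaths and rate jumps
#' after it are discarded.
#'
#' @param run a `full_tree` from [simulate_full_tree()], simulated with a
#'   stop condition exceeding `n_tips`.
#' @param n_tips required number of extant lineages.
#' @return The truncated `full_tree` with `$present` set.  If the run
#'   never holds exactly `n_tips` lineages it is returned flagged with
#'   `$failed = TRUE`.
#' @export
gsa_condition <- function(run, n_tips = run$params$n_tips) {
  stopifnot(inherits(run, "full_tree"))
  if (isTRUE(run$failed)) return(run)
  tt <- run$events$time
  N <- c(2L, 2L + cumsum(run$events$delta))
  starts <- c(0, tt)
  ends <- c(tt, run$t_end)
  ok <- which(N == n_tips & ends > starts)
  if (length(ok) == 0L) {
    run$failed <- TRUE
    run$fail_reason <- sprintf("run never holds exactly %d extant lineages",
                               n_tips)
    return(run)
  }
  dur <- ends[ok] - starts[ok]
  i <- ok[if (length(ok) == 1L) 1L else
            sample.int(length(ok), 1L, prob = dur)]
  present <- stats::runif(1L, starts[i], ends[i])
  truncate_run(run, present)
}

## cut a run at an absolute time, which becomes the present; lineages are
## stored in birth order, so the kept lineages form a prefix
truncate_run <- function(run, present) {
  keep <- run$birth < present
  nkeep <- sum(keep)
  stopifnot(all(which(keep) == seq_len(nkeep)))  # birth-ordered invariant
  run$parent <- run$parent[seq_len(nkeep)]
  run$birth <- run$birth[seq_len(nkeep)]
  dth <- run$death[seq_len(nkeep)]
  dth[!is.na(dth) & dth >= present] <- NA_real_
  run$death <- dth
  run$u_lam <- run$u_lam[seq_len(nkeep)]
  run$u_r <- run$u_r[seq_len(nkeep)]
  run$lastj0 <- run$lastj0[seq_len(nkeep)]
  jk <- run$jumps$lineage <= nkeep & run$jumps$time <= present
  run$jumps <- lapply(run$jumps, `[`, jk)
  ek <- run$events$time <= present
  run$events <- lapply(run$events, `[`, ek)
  run$t_end <- present
  run$present <- present
  run
}

#' Expected substitutions along a piecewise-constant rate trajectory
#'
#' @param durations segment durations (non-negative).
#' @param rates segment substitution rates (positive), same length.
#' @return `sum(rates * durations)`, the expected substitutions/site.
#' @export
integrate_branch_substitutions <- function(durations, rates) {
  if (length(durations) == 0L) return(0)
  stopifnot(length(durations) == length(rates),
            all(durations >= 0), all(rates > 0))
  sum(rates * durations)
}

## per-lineage trajectory within a truncated run: returns for lineage id a
## list(times, u_lam, u_r) of segment start times/states, plus the end time
lineage_trajectory <- function(run, id) {
  ji <- which(run$jumps$lineage == id)
  end <- if (is.na(run$death[id])) run$present else run$death[id]
  list(times = c(run$birth[id], run$jumps$time[ji]),
       u_lam = c(run$u_lam[id], run$jumps$u_lam[ji]),
       u_r = c(run$u_r[id], run$jumps$u_r[ji]),
       end = end)
}

#' Prune extinct lineages from a conditioned run
#'
#' Reduces the complete history to the binary tree spanned by the extant
#' tips.  Chains of lineages separated by speciation events whose other
#' daughter left no extant descendant are merged into single branches;
#' each merged branch records the summed gradual substitution expectation
#' of its segments, the count of hidden (pruned) speciation events
#' absorbed into it, and the identities of the merged lineages (used to
#' attribute punctuated bursts).  The returned tree is ultrametric over
#' the extant tips, with node ages in My before the present.
#'
#' @param run a conditioned `full_tree` (see [gsa_condition()]).
#' @return An object of class `c("time_tree", "phylo")` with extra fields
#'   `edge_subs`, `edge_hidden`, `edge_chains`, `ages`, `tip_lambda`,
#'   `tip_r`, `root_age`, `n_hidden`, `run_id`.
#' @export
prune_extinct <- function(run) {
  stopifnot(inherits(run, "full_tree"))
  if (isTRUE(run$failed)) stop("cannot prune a failed run")
  if (is.null(run$present))
    stop("run must be conditioned (gsa_condition) before pruning")
  present <- run$present
  nlin <- length(run$parent)
  extant <- extant_lineages(run)
  if (sum(extant) < 2L) stop("fewer than 2 extant lineages")

  children <- vector("list", nlin)
  for (i in seq_len(nlin)) {
    p <- run$parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  surv <- extant
  for (i in rev(seq_len(nlin)))            # ids are in birth order
    if (!surv[i] && length(children[[i]]))
      surv[i] <- any(surv[children[[i]]])

  ## gradual substitution expectation and final rates per lineage
  lin_subs <- numeric(nlin); lin_lam <- numeric(nlin); lin_r <- numeric(nlin)
  for (i in which(surv)) {
    tr <- lineage_trajectory(run, i)
    dur <- diff(c(tr$times, tr$end))
    r <- .to_rate(tr$u_r, run$params)
    lin_subs[i] <- sum(r * dur)
    k <- length(tr$u_lam)
    lin_lam[i] <- .to_rate(tr$u_lam[k], run$params)
    lin_r[i] <- r[k]
  }

  surviving_children <- function(i) {
    ch <- children[[i]]
    ch[surv[ch]]
  }

  ## locate the crown root of the extant tree: deepest lineage/time whose
  ## speciation has two surviving daughters (or time 0 if both initial
  ## lineages survive)
  roots <- which(run$parent == 0L)
  sroots <- roots[surv[roots]]
  if (length(sroots) == 2L) {
    root_time <- 0
    root_daughters <- sroots
  } else {
    cur <- sroots
    repeat {
      sc <- surviving_children(cur)
      if (length(sc) == 2L) { root_time <- run$death[cur]; break }
      if (length(sc) == 0L) stop("degenerate run: a single extant tip")
      cur <- sc
    }
    root_daughters <- sc
  }

  ## walk each root daughter, merging single-survivor chains
  tip_ids <- integer(0)
  edges <- list()        # list of (parent_key, child_key, ...) rows
  node_time <- c(root = root_time)
  node_count <- 0L
  descend <- function(d, parent_key) {
    chain <- d
    while (!extant[d]) {
      sc <- surviving_children(d)
      if (length(sc) == 1L) { d <- sc; chain <- c(chain, d) } else break
    }
    if (extant[d]) {
      key <- paste0("t", d)
      tip_ids <<- c(tip_ids, d)
      tm <- present
    } else {
      node_count <<- node_count + 1L
      key <- paste0("n", node_count)
      tm <- run$death[d]
    }
    node_time[key] <<- tm
    edges[[length(edges) + 1L]] <<- list(
      parent = parent_key, child = key, chain = chain,
      subs = sum(lin_subs[chain]), hidden = length(chain) - 1L,
      len = tm - node_time[[parent_key]])
    if (!extant[d])
      for (sc in surviving_children(d)) descend(sc, key)
    invisible(NULL)
  }
  for (d in root_daughters) descend(d, "root")

  ## assemble the ape phylo: tips 1..n, root n+1, internals follow
  ntip <- length(tip_ids)
  tip_keys <- paste0("t", tip_ids)
  int_keys <- c("root", if (node_count > 0L) paste0("n", seq_len(node_count)))
  num <- c(seq_len(ntip), ntip + seq_along(int_keys))
  names(num) <- c(tip_keys, int_keys)
  edge <- matrix(0L, length(edges), 2L)
  edge_len <- numeric(length(edges))
  edge_subs <- numeric(length(edges))
  edge_hidden <- integer(length(edges))
  edge_chains <- vector("list", length(edges))
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    edge[i, ] <- c(num[[e$parent]], num[[e$child]])
    edge_len[i] <- e$len
    edge_subs[i] <- e$subs
    edge_hidden[i] <- e$hidden
    edge_chains[[i]] <- e$chain
  }
  ages <- present - unlist(node_time)[c(tip_keys, int_keys)]
  names(ages) <- NULL
  ages[seq_len(ntip)] <- 0       # extant tips sit exactly at the present

  phy <- structure(list(
    edge = edge, edge.length = edge_len, Nnode = length(int_keys),
    tip.label = tip_keys,
    edge_subs = edge_subs, edge_hidden = edge_hidden,
    edge_chains = edge_chains,
    ages = ages,
    tip_lambda = stats::setNames(lin_lam[tip_ids], tip_keys),
    tip_r = stats::setNames(lin_r[tip_ids], tip_keys),
    root_age = present - root_time,
    n_hidden = sum(edge_hidden),
    run_id = run$run_id),
    class = c("time_tree", "phylo"), order = "cladewise")
  phy
}

#' Node ages of a tree
#'
#' Ages in time units before the present for every node (tips first, then
#' internal nodes, in ape numbering).  For a `time_tree` the stored exact
#' ages are returned; for a plain ultrametric `phylo` ages are computed
#' from the branch lengths.
#'
#' @param tree a `phylo` (ultrametric) or `time_tree`.
#' @return Numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  if (!is.null(tree$ages)) return(tree$ages)
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Convert a time tree to a phylogram of gradual substitution lengths
#'
#' Branch lengths become the per-branch expected substitutions/site
#' accumulated by the gradually evolving substitution rate (no bursts).
#'
#' @param tree a `time_tree` from [prune_extinct()].
#' @return An object of class `c("phylogram", "phylo")` with fields
#'   `edge_gradual` and `edge_burst` (zero here).
#' @export
as_phylogram <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  pg <- tree
  pg$edge.length <- tree$edge_subs
  pg$edge_gradual <- tree$edge_subs
  pg$edge_burst <- numeric(length(tree$edge_subs))
  class(pg) <- c("phylogram", "phylo")
  pg
}

#' Simulate one conditioned replicate (time tree + phylogram)
#'
#' High-level wrapper: simulates complete histories until one passes GSA
#' conditioning on `params$n_tips` extant tips, prunes extinct lineages,
#' and (for the punctuated model) adds speciation-associated substitution
#' bursts.  Failed runs (total extinction, or the target tip count never
#' attained) are discarded and redrawn; the retry count is reported.
#'
#' @param params a [sim_params()] object.
#' @param punctuated logical; add node-associated bursts?
#' @param burst a [burst_config()] (used when `punctuated = TRUE`).
#' @param max_tries maximum number of simulation attempts.
#' @param stop_tips,max_time outer stop condition passed to
#'   [simulate_full_tree()].
#' @return A list with components `time_tree`, `phylogram`,
#'   `burst_fraction` (NA unless punctuated), `tries`, and `run` (the
#'   conditioned `full_tree`).
#' @export
simulate_time_tree <- function(params, punctuated = FALSE,
                               burst = burst_config(), max_tries = 100L,
                               stop_tips = ceiling(1.5 * params$n_tips),
                               max_time = 500) {
  for (try in seq_len(max_tries)) {
    run <- simulate_full_tree(params, stop_tips = stop_tips,
                              max_time = max_time)
    if (isTRUE(run$failed)) next
    run <- gsa_condition(run, params$n_tips)
    if (isTRUE(run$failed)) next
    tt <- prune_extinct(run)
    if (punctuated) {
      f <- draw_tree_burst_fraction(burst)
      asg <- assign_bursts(run, f, burst, pruned = tt)
      pg <- punctuate_phylogram(tt, asg)
    } else {
      f <- NA_real_
      asg <- NULL
      pg <- as_phylogram(tt)
    }
    return(list(time_tree = tt, phylogram = pg, burst_fraction = f,
                assignment = asg, tries = try, run = run))
  }
  stop("no successful replicate in ", max_tries, " attempts")
}
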