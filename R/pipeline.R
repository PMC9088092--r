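## Orchestration: replicate suites (50 trees per model), file export,
## validation summaries, and deterministic fixtures for tests.

#' Derive a per-replicate seed from a master seed
#'
#' A small multiplicative-congruential mix of the master seed, a model
#' index and the replicate index; deterministic, collision-free in
#' practice, and always a positive 31-bit integer so any replicate can be
#' reproduced in isolation.
#'
#' @param master master seed (integer).
#' @param model model name or index.
#' @param rep replicate index.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, model, rep) {
  model_id <- if (is.character(model))
    match(model, c("unlinked", "continuous", "punctuated"), nomatch = 4L)
  else as.integer(model)
  m <- 2147483647
  s <- (as.numeric(master) %% m) + 1
  s <- (s * 48271) %% m
  s <- ((s + model_id) * 48271) %% m
  s <- ((s + as.numeric(rep)) * 48271) %% m
  as.integer(s) + 1L
}

#' Run a full simulation suite
#'
#' For each requested model, simulates `reps` conditioned replicates and
#' writes, per replicate: the time tree (Newick + NEXUS + branch sidecar),
#' the phylogram (Newick), the alignment (FASTA + relaxed PHYLIP), the
#' calibration table, the burst event table (punctuated model), and the
#' input bundles for the two external dating programs.  Fully reproducible
#' from `(config, seed)`: every replicate runs under its own derived seed.
#'
#' @param models character subset of
#'   `c("unlinked", "continuous", "punctuated")`.
#' @param reps replicates per model.
#' @param seed master seed.
#' @param out_dir output directory; created if needed.
#' @param params a [sim_params()] (the covariance is overridden per model
#'   preset); `burst`, `subst` configure the punctuated bursts and the
#'   sequence simulation.
#' @param burst,subst see above.
#' @param write_exports also write mcmctree/BEAST input bundles (slower).
#' @return Invisibly, a `run_manifest`: data frame of files with
#'   checksums plus per-replicate seeds, retry counts and summary
#'   statistics (root age, tip rate ranges, burst fraction).
#' @export
run_suite <- function(models = c("unlinked", "continuous", "punctuated"),
                      reps = 50L, seed = 1L, out_dir,
                      params = sim_params(), burst = burst_config(),
                      subst = subst_model(), write_exports = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(); stats_rows <- list()
  for (model in models) {
    mdir <- file.path(out_dir, model)
    dir.create(mdir, showWarnings = FALSE)
    pm <- sim_params(lambda0 = params$lambda0, r0 = params$r0,
                     mu = params$mu, q = params$q,
                     sigma2_lambda = params$sigma2_lambda,
                     sigma2_r = params$sigma2_r,
                     cov_lr = if (model == "continuous") 0.0044 else 0,
                     n_tips = params$n_tips,
                     rate_scale = params$rate_scale,
                     rate_floor = params$rate_floor)
    for (rep in seq_len(reps)) {
      rs <- derive_seed(seed, model, rep)
      set.seed(rs)
      sim <- simulate_time_tree(pm, punctuated = model == "punctuated",
                                burst = burst)
      stem <- file.path(mdir, sprintf("rep%03d", rep))
      files <- write_time_tree(sim$time_tree, stem)
      pg_file <- paste0(stem, "_phylogram.nwk")
      writeLines(write_newick(sim$phylogram), pg_file)
      files <- c(files, pg_file)
      aln <- simulate_alignment(sim$phylogram, subst)
      files <- c(files,
                 write_fasta(aln, paste0(stem, ".fasta")),
                 write_phylip(aln, paste0(stem, ".phy")))
      cal <- calibrations_for(sim$time_tree)
      cal_file <- paste0(stem, "_calibrations.tsv")
      utils::write.table(cal, cal_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, cal_file)
      if (model == "punctuated") {
        bt <- burst_table(sim$time_tree, sim$assignment, sim$run)
        bt_file <- paste0(stem, "_bursts.tsv")
        utils::write.table(bt, bt_file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, bt_file)
      }
      if (write_exports) {
        files <- c(files,
                   export_mcmctree_inputs(sim$time_tree, aln, cal,
                                          paste0(stem, "_mcmctree")),
                   export_beast_inputs(aln, cal,
                                       paste0(stem, "_beast.xml")))
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        model = model, rep = rep, seed = rs, file = unname(files),
        md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        model = model, rep = rep, seed = rs, tries = sim$tries,
        root_age = sim$time_tree$root_age,
        tip_loglambda_range = diff(range(log(sim$time_tree$tip_lambda))),
        tip_logr_range = diff(range(log(sim$time_tree$tip_r))),
        burst_fraction = sim$burst_fraction)
    }
  }
  out <- structure(list(files = do.call(rbind, manifest),
                        stats = do.call(rbind, stats_rows),
                        models = models, reps = reps, seed = seed,
                        params = params),
                   class = "run_manifest")
  utils::write.table(out$files, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$stats, file.path(out_dir, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Validation summary of a simulation suite
#'
#' Aggregates the realized tree characteristics that anchor the
#' simulation to its empirical target: mean crown (root) age, mean
#' within-tree range of log speciation rates at the tips, and (for the
#' punctuated model) the mean and SD of realized burst fractions.
#'
#' @param manifest a `run_manifest` from [run_suite()], or its `stats`
#'   data frame.
#' @return A data frame with one row per model plus an `all` row.
#' @export
summarize_validation <- function(manifest) {
  st <- if (inherits(manifest, "run_manifest")) manifest$stats else manifest
  if (is.null(st) || nrow(st) == 0L) stop("empty manifest")
  summarize <- function(d, label) {
    data.frame(
      model = label, n = nrow(d),
      mean_root_age = mean(d$root_age),
      mean_tip_loglambda_range = mean(d$tip_loglambda_range),
      mean_tip_logr_range = mean(d$tip_logr_range),
      mean_burst_fraction = mean(d$burst_fraction, na.rm = TRUE),
      sd_burst_fraction = stats::sd(d$burst_fraction, na.rm = TRUE))
  }
  rows <- lapply(split(st, st$model), function(d)
    summarize(d, d$model[1L]))
  out <- do.call(rbind, c(rows, list(summarize(st, "all"))))
  rownames(out) <- NULL
  out
}

#' Deterministic miniature fixtures for tests and examples
#'
#' Hand-checkable assets: a 3-tip tree whose gamma statistic is known in
#' closed form, a pair of 3-tip trees with a known MAPE, an annotated
#' NEXUS string with known HPD intervals, a hand-built 3-lineage history
#' in which one daughter of a cherry went extinct (one hidden speciation
#' event), and a toy 4-tip alignment.
#'
#' @param seed seed for the toy alignment.
#' @param dir optional directory; if given, the text fixtures are also
#'   written there.
#' @return A named list of fixtures.
#' @export
make_fixtures <- function(seed = 1L, dir = NULL) {
  set.seed(seed)
  gamma_tree <- parse_newick("((A:1,B:1):1,C:2);")   # g2 = g3 = 1
  mape_true <- parse_newick("((A:4,B:4):6,C:10);")   # ages 10, 4
  mape_est <- parse_newick("((A:5,B:5):6,C:11);")    # ages 11, 5
  hpd_nexus <- c(
    "#NEXUS", "begin trees;",
    "\ttranslate", "\t\t1 A,", "\t\t2 B,", "\t\t3 C", "\t\t;",
    paste0("tree SUMMARY = [&R] ((1:5,2:5)",
           "[&age_95%_HPD={4,6}]:5,3:10)[&age_95%_HPD={8,12}];"),
    "end;")
  extinct_cherry <- synthetic_history()
  toy_tree <- ape::rcoal(4L)
  toy_tree$edge.length <- toy_tree$edge.length * 0.1
  toy_aln <- simulate_alignment(toy_tree, subst_model(length = 40L))
  fx <- list(gamma_tree = gamma_tree, gamma_expected = -sqrt(3) / 5,
             mape_true = mape_true, mape_est = mape_est,
             mape_expected = 17.5,
             hpd_nexus = hpd_nexus, hpd_expected = 40,
             extinct_cherry = extinct_cherry,
             toy_aln = toy_aln)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(write_newick(gamma_tree), file.path(dir, "gamma_tree.nwk"))
    writeLines(hpd_nexus, file.path(dir, "hpd_tree.nex"))
    write_fasta(toy_aln, file.path(dir, "toy.fasta"))
  }
  fx
}

## a hand-built conditioned history: root splits at t=0 into lineages 1, 2;
## lineage 2 splits at t=1 into 3 (extinct at t=2) and 4 (extant); present
## at t=3.  Constant rates lambda=0.1, r=0.01.  Pruning must merge lineage
## 2 and 4 into one branch with one hidden event.
synthetic_history <- function() {
  params <- sim_params(lambda0 = 0.1, r0 = 0.01, mu = 0.05, q = 1,
                       sigma2_lambda = 0, sigma2_r = 0, n_tips = 2L)
  structure(list(
    parent = c(0L, 0L, 2L, 2L),
    birth = c(0, 0, 1, 1),
    death = c(NA, 1, 2, NA),
    u_lam = rep(log(0.1), 4L), u_r = rep(log(0.01), 4L),
    lastj0 = c(0, 0, 1, 1),
    jumps = list(lineage = integer(0), time = numeric(0),
                 u_lam = numeric(0), u_r = numeric(0)),
    events = list(time = c(1, 2), delta = c(1L, -1L)),
    t_end = 3, present = 3, params = params,
    run_id = "fixture-extinct-cherry", failed = FALSE,
    fail_reason = NULL),
    class = "full_tree")
}
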