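test_that("newick parse/write round-trips topology, labels and lengths", {
  phy <- parse_newick("((A:1,B:1):1,C:2);")
  expect_identical(length(phy$tip.label), 3L)
  txt <- write_newick(phy)
  phy2 <- parse_newick(txt)
  expect_identical(write_newick(phy2), txt)
  expect_setequal(phy2$tip.label, c("A", "B", "C"))

  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "unclosed")
  expect_error(parse_newick("(A:1,B:1)):1;"), "position")

  # 75-tip round trip preserves node ages
  set.seed(801)
  big <- ape::rcoal(75)
  big2 <- parse_newick(write_newick(big))
  a1 <- sort(ape::branching.times(big))
  a2 <- sort(ape::branching.times(big2))
  expect_equal(unname(a2), unname(a1), tolerance = 1e-12)
})

test_that("annotated NEXUS extracts point ages and HPD intervals", {
  fx <- make_fixtures(1)
  dt <- read_annotated_nexus(fx$hpd_nexus)
  expect_s3_class(dt, "dated_tree")
  ntip <- length(dt$phy$tip.label)
  expect_identical(ntip, 3L)
  expect_equal(sort(dt$ages[dt$ages > 0]), c(5, 10))
  root <- ntip + 1L
  expect_equal(unname(dt$hpd[root, ]), c(8, 12))
  expect_true(all(is.na(dt$hpd[seq_len(ntip), ])))

  # a tree with no comments: ages from branch lengths, no intervals
  plain <- c("#NEXUS", "begin trees;",
             "tree T = ((A:1,B:1):1,C:2);", "end;")
  dt2 <- read_annotated_nexus(plain)
  expect_equal(sort(dt2$ages[dt2$ages > 0]), c(1, 2))
  expect_true(all(is.na(dt2$hpd)))

  expect_error(read_annotated_nexus(c("#NEXUS", "begin taxa;", "end;")),
               "trees block")
})

test_that("a full-sized annotated fixture round-trips all internal nodes", {
  set.seed(802)
  big <- ape::rcoal(75)
  ages <- max(ape::node.depth.edgelength(big)) -
    ape::node.depth.edgelength(big)
  hpd <- cbind(ages * 0.9, ages * 1.1)
  hpd[seq_len(75), ] <- NA
  f <- tempfile(fileext = ".nex")
  write_annotated_nexus(big, f, hpd = hpd)
  dt <- read_annotated_nexus(f)
  expect_identical(sum(!is.na(dt$hpd[, 1])), 74L)
  expect_equal(sort(dt$ages[-seq_len(75)]), sort(ages[-seq_len(75)]),
               tolerance = 1e-9)
  # widths come back as written
  ok <- !is.na(dt$hpd[, 1])
  expect_equal(dt$hpd[ok, 2] - dt$hpd[ok, 1], 0.2 * dt$ages[ok],
               tolerance = 1e-6)
})

test_that("mcmctree export carries the calibrations and fixed topology", {
  set.seed(803)
  sim <- small_replicate(n_tips = 6)
  tt <- sim$time_tree
  aln <- simulate_alignment(sim$phylogram, subst_model(length = 60))
  cal <- calibrations_for(tt)
  dir <- tempfile()
  files <- export_mcmctree_inputs(tt, aln, cal, dir, rate_prior = "acln")
  tree_txt <- readLines(files["tree"])
  expect_identical(lengths(regmatches(tree_txt[2],
                                      gregexpr("B(", tree_txt[2],
                                               fixed = TRUE))), 2L)
  expect_match(tree_txt[2],
               sprintf("B\\(%.10g, %.10g\\)", cal$lower[1], cal$upper[1]))
  # re-parsing the exported tree recovers the topology
  bare <- gsub("'B\\([^)]*\\)'", "", tree_txt[2])
  reparsed <- parse_newick(bare)
  expect_identical(rf_distance(tt, reparsed), 0L)
  # control file requests the autocorrelated clock
  ctl <- readLines(files["ctl"])
  expect_true(any(grepl("clock\\s*= 3", ctl)))
  ctl2 <- readLines(export_mcmctree_inputs(tt, aln, cal, dir,
                                           rate_prior = "ucln")["ctl"])
  expect_true(any(grepl("clock\\s*= 2", ctl2)))
  # alignment dimensions in the PHYLIP header
  expect_match(readLines(files["seq"])[1], "^6 60$")

  bad <- cal; bad$clade[2] <- "tX,tY"
  expect_error(export_mcmctree_inputs(tt, aln, bad, dir), "unknown tips")
})

test_that("BEAST export is well-formed XML with uniform MRCA priors", {
  skip_if_not_installed("xml2")
  set.seed(804)
  sim <- small_replicate(n_tips = 5)
  aln <- simulate_alignment(sim$phylogram, subst_model(length = 2000))
  cal <- calibrations_for(sim$time_tree)
  f <- tempfile(fileext = ".xml")
  export_beast_inputs(aln, cal, f)
  doc <- xml2::read_xml(f)
  seqs <- xml2::xml_find_all(doc, ".//sequence")
  expect_identical(length(seqs), 5L)
  expect_identical(unique(nchar(xml2::xml_attr(seqs, "value"))), 2000L)
  pri <- xml2::xml_find_all(doc, ".//distribution[@monophyletic='true']")
  expect_identical(length(pri), 2L)
  unif <- xml2::xml_find_all(doc, ".//Uniform")
  expect_equal(sort(as.numeric(xml2::xml_attr(unif, "lower"))),
               sort(cal$lower))
})

test_that("writers are deterministic", {
  set.seed(805)
  sim <- small_replicate(n_tips = 6)
  f1 <- tempfile(); f2 <- tempfile()
  write_annotated_nexus(sim$time_tree, f1)
  write_annotated_nexus(sim$time_tree, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(write_newick(sim$time_tree), write_newick(sim$time_tree))
})
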