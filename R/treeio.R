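## Readers and writers: Newick, NEXUS (plain and annotated), FASTA,
## relaxed PHYLIP, tab-delimited sidecar tables, and input bundles for the
## two external Bayesian dating programs.
##
## Conventions: node ages are heights above the present (tips = 0); Newick
## branch lengths are durations; clades are identified by tip sets, never
## by internal node numbers.

#' Parse a Newick string
#'
#' @param text a single Newick string (with branch lengths).
#' @return A `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at end of input")
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy)) stop("malformed newick: could not be parsed")
  phy
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo`.
#' @param digits significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 15L) {
  ape::write.tree(tree, digits = digits)
}

#' Write a time tree with its per-branch sidecar table
#'
#' Emits Newick (branch lengths in My), a NEXUS copy with a translate
#' block, and a tab-delimited sidecar carrying the per-branch gradual
#' substitution expectation and hidden-speciation-event count.
#'
#' @param tree a `time_tree`.
#' @param stem output path stem; writes `<stem>.nwk`, `<stem>.nex`,
#'   `<stem>_branches.tsv`.
#' @return Invisibly, the vector of files written.
#' @export
write_time_tree <- function(tree, stem) {
  stopifnot(inherits(tree, "time_tree"))
  files <- paste0(stem, c(".nwk", ".nex", "_branches.tsv"))
  writeLines(write_newick(tree), files[1L])
  write_annotated_nexus(tree, files[2L])   # translate block, no timestamp
  tab <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                    length_my = tree$edge.length,
                    subs_per_site = tree$edge_subs,
                    hidden_events = tree$edge_hidden)
  utils::write.table(tab, files[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(files)
}

## ---- annotated NEXUS ----------------------------------------------------

## recursive-descent parser for newick with [&key=value] node comments
parse_annotated_newick <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos <= n) chars[pos] else ""
  read_comment <- function() {
    if (peek() != "[") return(NULL)
    start <- pos
    while (pos <= n && chars[pos] != "]") pos <<- pos + 1L
    if (pos > n) stop("unterminated [comment] starting at position ", start)
    out <- paste(chars[(start + 1L):(pos - 1L)], collapse = "")
    pos <<- pos + 1L
    out
  }
  read_token <- function() {
    start <- pos
    while (pos <= n && !(chars[pos] %in% c("(", ")", ",", ":", ";", "[")))
      pos <<- pos + 1L
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  parse_node <- function() {
    node <- list(children = list(), label = "", length = NA_real_,
                 comment = NULL)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        node$children[[length(node$children) + 1L]] <- parse_node()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed annotated newick near position ", pos)
      }
      if (!(peek() %in% c("(", ")", ",", ":", ";", "[")))
        node$label <- read_token()
    } else {
      node$label <- read_token()
    }
    cm <- read_comment()
    if (!is.null(cm)) node$comment <- cm
    if (peek() == ":") {
      pos <<- pos + 1L
      cm2 <- read_comment()             # BEAST puts rate comments here
      if (!is.null(cm2) && is.null(node$comment)) node$comment <- cm2
      node$length <- as.numeric(read_token())
    }
    node
  }
  root <- parse_node()
  if (peek() != ";") stop("annotated newick must end with ';'")
  root
}

## pull an HPD interval {lo,hi} out of a comment string, if present
comment_hpd <- function(comment) {
  if (is.null(comment)) return(c(NA_real_, NA_real_))
  m <- regmatches(comment,
                  regexpr("[A-Za-z0-9_.%]*95%?_?[Hh][Pp][Dd][A-Za-z0-9_.%]*=\\{[^}]*\\}",
                          comment))
  if (length(m) == 0L) return(c(NA_real_, NA_real_))
  vals <- regmatches(m, regexpr("\\{[^}]*\\}", m))
  as.numeric(strsplit(gsub("[{}]", "", vals), ",")[[1L]])
}

#' Read a NEXUS summary tree with per-node HPD annotations
#'
#' Consumes the annotated-NEXUS dialect written by Bayesian dating
#' software: a `trees` block (optionally with a `translate` table) whose
#' tree string carries bracketed `[&key=value]` node comments, with 95%
#' HPD age intervals encoded as `...95%_HPD={lower,upper}`.  Point node
#' ages are taken from the branch lengths (heights above the present,
#' tips at 0); nodes lacking an interval carry a point estimate only.
#' Unknown annotation keys are ignored.
#'
#' @param x path to a NEXUS file, or its contents as a character vector.
#' @return An object of class `dated_tree`: a list with `phy` (the
#'   `phylo`), `ages` (length `Ntip + Nnode`, tips 0), and `hpd`
#'   (`(Ntip + Nnode) x 2` matrix, `NA` where absent).
#' @export
read_annotated_nexus <- function(x) {
  txt <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else x
  one <- paste(txt, collapse = "\n")
  block <- regmatches(one, regexpr("(?is)begin\\s+trees\\s*;.*?end\\s*;",
                                   one, perl = TRUE))
  if (length(block) == 0L)
    stop("no trees block found: not an annotated NEXUS file")
  translate <- NULL
  tr <- regmatches(block, regexpr("(?is)translate\\s+.*?;", block,
                                  perl = TRUE))
  if (length(tr) == 1L) {
    body <- sub("(?is)^translate\\s+", "", sub(";$", "", tr), perl = TRUE)
    entries <- strsplit(body, ",")[[1L]]
    pieces <- lapply(entries, function(e) {
      e <- trimws(e)
      sp <- regmatches(e, regexpr("^\\S+", e))
      c(sp, trimws(sub("^\\S+\\s+", "", e)))
    })
    translate <- stats::setNames(vapply(pieces, `[`, "", 2L),
                                 vapply(pieces, `[`, "", 1L))
  }
  tl <- regmatches(block,
                   regexpr("(?i)\\btree\\s+[^=]+=[^(]*\\(", block,
                           perl = TRUE))
  if (length(tl) == 0L) stop("trees block contains no tree statement")
  start <- regexpr("(?i)\\btree\\s+[^=]+=", block, perl = TRUE)
  rest <- substr(block, start + attr(start, "match.length"),
                 nchar(block))
  open <- regexpr("(", rest, fixed = TRUE)
  semi <- regexpr(";", substr(rest, open, nchar(rest)), fixed = TRUE)
  nwk <- substr(rest, open, open + semi - 1L)

  root <- parse_annotated_newick(nwk)
  ## flatten to phylo + annotations
  tips <- list(); internals <- list()
  collect <- function(node) {
    if (length(node$children) == 0L) {
      tips[[length(tips) + 1L]] <<- node
    } else {
      internals[[length(internals) + 1L]] <<- node
      lapply(node$children, collect)
    }
    invisible(NULL)
  }
  collect(root)
  ntip <- length(tips); nnode <- length(internals)
  num_env <- new.env()
  tip_i <- 0L; int_i <- 0L
  edge <- matrix(0L, 0L, 2L); elen <- numeric(0)
  labels <- character(ntip)
  comments <- vector("list", ntip + nnode)
  assign_nums <- function(node) {
    if (length(node$children) == 0L) {
      tip_i <<- tip_i + 1L
      labels[tip_i] <<- node$label
      if (!is.null(node$comment)) comments[[tip_i]] <<- node$comment
      tip_i
    } else {
      int_i <<- int_i + 1L
      me <- ntip + int_i
      if (!is.null(node$comment)) comments[[me]] <<- node$comment
      for (ch in node$children) {
        chn <- assign_nums(ch)
        edge <<- rbind(edge, c(me, chn))
        elen <<- c(elen, if (is.na(ch$length)) 0 else ch$length)
      }
      me
    }
  }
  assign_nums(root)
  if (!is.null(translate)) {
    mapped <- unname(translate[labels])
    labels <- ifelse(is.na(mapped), labels, mapped)
  }
  phy <- structure(list(edge = edge, edge.length = elen, Nnode = nnode,
                        tip.label = gsub("^'|'$", "", labels)),
                   class = "phylo", order = "cladewise")
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth) - depth
  ages[seq_len(ntip)] <- 0          # symmetrize tips to the present
  hpd <- t(vapply(comments, comment_hpd, numeric(2L)))
  colnames(hpd) <- c("lower", "upper")
  structure(list(phy = phy, ages = ages, hpd = hpd),
            class = "dated_tree")
}

#' Write a dated tree as annotated NEXUS
#'
#' Inverse of [read_annotated_nexus()] for the fields the package uses:
#' a translate block and a tree string with `[&age_95%_HPD={lo,hi}]`
#' node comments where intervals are present.
#'
#' @param x a `dated_tree`, or an ultrametric `phylo`/`time_tree` (then
#'   `hpd` may supply intervals for internal nodes).
#' @param file output path.
#' @param hpd optional `(Ntip + Nnode) x 2` matrix of intervals.
#' @return Invisibly, `file`.
#' @export
write_annotated_nexus <- function(x, file, hpd = NULL) {
  if (inherits(x, "dated_tree")) {
    phy <- x$phy; ages <- x$ages
    if (is.null(hpd)) hpd <- x$hpd
  } else {
    phy <- x; ages <- node_ages(x)
  }
  ntip <- length(phy$tip.label)
  if (is.null(hpd)) hpd <- matrix(NA_real_, ntip + phy$Nnode, 2L)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  build <- function(node, parent_age) {
    cm <- if (!is.na(hpd[node, 1L]))
      sprintf("[&age_95%%_HPD={%.12g,%.12g}]", hpd[node, 1L], hpd[node, 2L])
    else ""
    blen <- sprintf(":%.12g", parent_age - ages[node])
    if (node <= ntip)
      return(paste0(node, cm, blen))
    kids <- phy$edge[children[[as.character(node)]], 2L]
    inner <- paste(vapply(kids, build, "", parent_age = ages[node]),
                   collapse = ",")
    paste0("(", inner, ")", cm, blen)
  }
  root <- ntip + 1L
  kids <- phy$edge[children[[as.character(root)]], 2L]
  cm <- if (!is.na(hpd[root, 1L]))
    sprintf("[&age_95%%_HPD={%.12g,%.12g}]", hpd[root, 1L], hpd[root, 2L])
  else ""
  nwk <- paste0("(",
                paste(vapply(kids, build, "", parent_age = ages[root]),
                      collapse = ","),
                ")", cm, ";")
  lines <- c("#NEXUS", "begin trees;", "\ttranslate",
             paste0("\t\t", seq_len(ntip), " ", phy$tip.label,
                    c(rep(",", ntip - 1L), "")),
             "\t\t;",
             paste0("tree SUMMARY = [&R] ", nwk),
             "end;")
  writeLines(lines, file)
  invisible(file)
}

## ---- exporters for external dating software -----------------------------

## match calibration clades (tip-set keys) to nodes; error if absent
calibration_nodes <- function(tree, calibrations) {
  vapply(calibrations$clade, function(cl) {
    tips <- strsplit(cl, ",")[[1L]]
    if (!all(tips %in% tree$tip.label))
      stop("calibration clade contains unknown tips: ", cl)
    nd <- if (length(tips) == 1L) match(tips, tree$tip.label) else
      ape::getMRCA(tree, tips)
    if (clade_key(tree, nd) != paste(sort(tips), collapse = ","))
      stop("calibration clade is not monophyletic in this tree: ", cl)
    nd
  }, integer(1L))
}

## relaxed PHYLIP, one line per sequence
write_phylip <- function(aln, file) {
  writeLines(c(sprintf("%d %d", nrow(aln), ncol(aln)),
               paste(rownames(aln), "  ",
                     apply(aln, 1L, paste, collapse = ""))),
             file)
  invisible(file)
}

## FASTA
write_fasta <- function(aln, file) {
  lines <- as.vector(rbind(paste0(">", rownames(aln)),
                           apply(aln, 1L, paste, collapse = "")))
  writeLines(lines, file)
  invisible(file)
}

#' Export an input bundle for PAML's mcmctree
#'
#' Writes the fixed rooted topology with calibration annotations, the
#' alignment in relaxed PHYLIP, and a control file for the requested rate
#' prior (autocorrelated or uncorrelated lognormal, via `clock = 3` or
#' `clock = 2`).  Hard uniform calibrations are encoded verbatim as
#' `'B(lower, upper)'` node annotations.
#'
#' @param tree the fixed (true) topology, a rooted binary `phylo`.
#' @param aln character alignment matrix from [simulate_alignment()].
#' @param calibrations calibration table from [calibrations_for()].
#' @param dir output directory (created if needed).
#' @param rate_prior `"acln"` (autocorrelated) or `"ucln"` (uncorrelated).
#' @param settings named list of control-file overrides (e.g. `burnin`).
#' @return Invisibly, named paths of `ctl`, `tree` and `seq` files.
#' @export
export_mcmctree_inputs <- function(tree, aln, calibrations, dir,
                                   rate_prior = c("acln", "ucln"),
                                   settings = list()) {
  rate_prior <- match.arg(rate_prior)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- calibration_nodes(tree, calibrations)

  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  annot <- rep("", ntip + tree$Nnode)
  annot[nodes] <- sprintf("'B(%.10g, %.10g)'",
                          calibrations$lower, calibrations$upper)
  build <- function(node) {
    if (node <= ntip) return(paste0(tree$tip.label[node], annot[node]))
    kids <- tree$edge[children[[as.character(node)]], 2L]
    paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")",
           annot[node])
  }
  tree_file <- file.path(dir, "mcmctree.trees")
  writeLines(c(sprintf("%d 1", ntip),
               paste0(build(ntip + 1L), ";")), tree_file)

  seq_file <- file.path(dir, "mcmctree.phy")
  write_phylip(aln, seq_file)

  ctl <- list(seqfile = basename(seq_file), treefile = basename(tree_file),
              outfile = "mcmctree_out.txt", ndata = 1, seqtype = 0,
              usedata = 3, clock = if (rate_prior == "acln") 3 else 2,
              model = 7, alpha = 0.3, ncatG = 4, cleandata = 0,
              BDparas = "1 1 0.1", rgene_gamma = "2 20",
              sigma2_gamma = "1 10", finetune = "1: .1 .1 .1 .1 .1 .1",
              print = 1, burnin = 20000, sampfreq = 100, nsample = 10000)
  ctl[names(settings)] <- settings
  ctl_file <- file.path(dir, "mcmctree.ctl")
  writeLines(sprintf("%s = %s", format(names(ctl)),
                     vapply(ctl, as.character, "")), ctl_file)
  invisible(c(ctl = ctl_file, tree = tree_file, seq = seq_file))
}

#' Export a BEAST 2 analysis configuration
#'
#' Emits a single XML document with the embedded alignment, a GTR+Gamma
#' site model, an uncorrelated lognormal relaxed clock, a birth-death
#' tree prior, and one hard-bounded uniform MRCA age prior per
#' calibration (monophyly enforced; topology is not fixed).
#'
#' @param aln character alignment matrix.
#' @param calibrations calibration table from [calibrations_for()].
#' @param file output path of the XML document.
#' @param chain_length MCMC chain length.
#' @param log_every sampling interval.
#' @return Invisibly, `file`.
#' @export
export_beast_inputs <- function(aln, calibrations, file,
                                chain_length = 1e7, log_every = 1000) {
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  taxa <- xml_escape(rownames(aln))
  seqs <- apply(aln, 1L, paste, collapse = "")
  seq_xml <- sprintf(
    '        <sequence id="seq_%s" taxon="%s" totalcount="4" value="%s"/>',
    taxa, taxa, seqs)
  cal_xml <- unlist(lapply(seq_len(nrow(calibrations)), function(i) {
    tips <- xml_escape(strsplit(calibrations$clade[i], ",")[[1L]])
    c(sprintf('        <distribution id="cal%d.prior" spec="beast.math.distributions.MRCAPrior" monophyletic="true" tree="@Tree.t:aln">', i),
      sprintf('          <taxonset id="cal%d.set" spec="TaxonSet">', i),
      sprintf('            <taxon id="%s.cal%d" spec="Taxon"/>', tips, i),
      '          </taxonset>',
      sprintf('          <Uniform id="cal%d.unif" name="distr" lower="%.10g" upper="%.10g"/>',
              i, calibrations$lower[i], calibrations$upper[i]),
      '        </distribution>')
  }))
  doc <- c(
    '<?xml version="1.0" encoding="UTF-8" standalone="no"?>',
    '<beast version="2.6" namespace="beast.core:beast.evolution.alignment:beast.evolution.tree:beast.math.distributions">',
    '  <data id="aln" spec="Alignment" dataType="nucleotide">',
    seq_xml,
    '  </data>',
    sprintf('  <run id="mcmc" spec="MCMC" chainLength="%d">',
            as.integer(chain_length)),
    '    <state id="state">',
    '      <tree id="Tree.t:aln" spec="beast.evolution.tree.Tree" name="stateNode">',
    '        <taxonset id="TaxonSet.aln" spec="TaxonSet" alignment="@aln"/>',
    '      </tree>',
    '    </state>',
    '    <distribution id="posterior" spec="util.CompoundDistribution">',
    '      <distribution id="prior" spec="util.CompoundDistribution">',
    cal_xml,
    '      </distribution>',
    '      <distribution id="likelihood" spec="util.CompoundDistribution">',
    '        <distribution id="treeLikelihood" spec="beast.evolution.likelihood.TreeLikelihood" data="@aln" tree="@Tree.t:aln">',
    '          <siteModel id="SiteModel" spec="beast.evolution.sitemodel.SiteModel" gammaCategoryCount="4" shape="0.3">',
    '            <substModel id="gtr" spec="beast.evolution.substitutionmodel.GTR"/>',
    '          </siteModel>',
    '          <branchRateModel id="ucln" spec="beast.evolution.branchratemodel.UCRelaxedClockModel" tree="@Tree.t:aln">',
    '            <LogNormal id="ucln.dist" name="distr" M="1.0" S="0.5" meanInRealSpace="true"/>',
    '          </branchRateModel>',
    '        </distribution>',
    '      </distribution>',
    '    </distribution>',
    sprintf('    <logger id="tracelog" fileName="beast.log" logEvery="%d"/>',
            as.integer(log_every)),
    '  </run>',
    '</beast>')
  writeLines(doc, file)
  invisible(file)
}
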