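## End-to-end orchestration: configuration with validated defaults, bundled
## synthetic scenarios, and the full simulate -> copy number -> annotate ->
## consensus -> recombination -> trees -> HTT-flag pipeline.

.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483629)
}

#' Default pipeline configuration
#'
#' All tunable thresholds of every stage with their default values.
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    scenario = "htt_plus_recombinant",
    simulate = list(
      n_strains = 8, n_lineages = 4, depth_scale = 0.05, within_scale = 0.15,
      ltr_len = 300, internal_len = 3000, subfamily_divergence = 0.12,
      root_copies = 2, kappa = 2, sub_rate = 1,
      transposition_rate = 0.25, solo_ltr_rate = 0.15,
      truncation_rate = 0.08, loss_rate = 0.03,
      background_length = 60000, n_contigs = 2, tsd_len = 5,
      fold_coverage = 30, read_len = 100, err = 0.01, frag_prob = 0.3,
      # chimera breakpoints (query coordinates): one 5' breakpoint after
      # gag plus part of pol, and a two-breakpoint middle swap
      breakpoint_5p = 1550, breakpoint_mid = c(1100, 2400)
    ),
    coverage = list(ltr_threshold = 1, int_threshold = 0.5, cap = 100,
                    min_depth = 1),
    annotate = list(max_gap = 250, min_full_frac = 0.9, ltr_only_frac = 0.8,
                    max_solo_internal = 0.05),
    consensus = list(min_depth = 1, depth_min = 0.75, breadth_min = 0.9),
    recomb = list(window = 50, step = 10, min_seg = 3),
    phylo = list(bootstrap = 100, min_support = 70, sim_ratio = 0.5,
                 variant = "bionj", min_absent_inside = 2)
  )
}

.checkRange <- function(errors, cfg, section, key, lo, hi) {
  v <- cfg[[section]][[key]]
  if (!is.numeric(v) || any(is.na(v)) || any(v < lo) || any(v > hi))
    c(errors, sprintf("%s.%s must lie in [%g, %g]", section, key, lo, hi))
  else errors
}

#' Validate and normalize a pipeline configuration
#'
#' Fills unset entries with defaults, reports every violation with its key
#' path (aggregated, never partial), and warns on unknown keys.
#'
#' @param config partial configuration list (possibly empty).
#' @return normalized configuration.
#' @export
validateConfig <- function(config = list()) {
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), names(def))) {
    if (is.list(def[[sec]])) {
      u2 <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(u2))
        warning("unknown config key(s) ignored: ",
                paste(paste0(sec, ".", u2), collapse = ", "))
    }
  }
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])
  errors <- character(0)
  if (!cfg$scenario %in% c("vertical_only", "htt_single",
                           "htt_plus_recombinant", "recombinant_only"))
    errors <- c(errors, paste("scenario must be one of vertical_only,",
                              "htt_single, htt_plus_recombinant,",
                              "recombinant_only"))
  errors <- .checkRange(errors, cfg, "coverage", "ltr_threshold", 0, Inf)
  errors <- .checkRange(errors, cfg, "coverage", "int_threshold", 0, Inf)
  errors <- .checkRange(errors, cfg, "coverage", "cap", 1e-9, Inf)
  errors <- .checkRange(errors, cfg, "annotate", "min_full_frac", 0, 1)
  errors <- .checkRange(errors, cfg, "annotate", "ltr_only_frac", 0, 1)
  errors <- .checkRange(errors, cfg, "annotate", "max_solo_internal", 0, 1)
  errors <- .checkRange(errors, cfg, "annotate", "max_gap", 0, Inf)
  errors <- .checkRange(errors, cfg, "consensus", "depth_min", 0, Inf)
  errors <- .checkRange(errors, cfg, "consensus", "breadth_min", 0, 1)
  errors <- .checkRange(errors, cfg, "recomb", "window", 1, Inf)
  errors <- .checkRange(errors, cfg, "recomb", "step", 1, Inf)
  errors <- .checkRange(errors, cfg, "recomb", "min_seg", 1, Inf)
  errors <- .checkRange(errors, cfg, "phylo", "bootstrap", 1, Inf)
  errors <- .checkRange(errors, cfg, "phylo", "min_support", 0, 100)
  errors <- .checkRange(errors, cfg, "phylo", "sim_ratio", 0, 1)
  errors <- .checkRange(errors, cfg, "simulate", "n_strains", 2, Inf)
  errors <- .checkRange(errors, cfg, "simulate", "err", 0, 0.499)
  errors <- .checkRange(errors, cfg, "simulate", "frag_prob", 0, 1)
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  cfg
}

#' Read a YAML configuration file
#' @param path YAML file path.
#' @return validated configuration.
#' @export
readConfig <- function(path) {
  validateConfig(yaml::read_yaml(path))
}

#' Build a diverged subfamily query pair from a common ancestor
#'
#' Two subfamily references (default ids \code{TyA}, \code{TyB}) derived
#' from one random ancestral element by evolving each copy half the target
#' divergence, with canonical \code{TG...CA} LTR termini restored.
#'
#' @param seed integer seed.
#' @param ltr_len,internal_len region lengths (defaults 300, 3000).
#' @param divergence target pairwise divergence between the two queries
#'   (default 0.12).
#' @param ids two query identifiers.
#' @return named list of two \linkS4class{TEQueryModel}.
#' @export
makeQueryPair <- function(seed = 1, ltr_len = 300, internal_len = 3000,
                          divergence = 0.12, ids = c("TyA", "TyB")) {
  withr_seed(seed, {
    anc <- randomQuery("anc", ltr_len, internal_len,
                       seed = .subseed(seed, 1))
    fix <- function(seqint, L) {
      qlen <- length(seqint)
      seqint[c(1, 2)] <- c(4L, 3L)
      seqint[c(L - 1L, L)] <- c(2L, 1L)
      seqint[c(qlen - L + 1L, qlen - L + 2L)] <- c(4L, 3L)
      seqint[c(qlen - 1L, qlen)] <- c(2L, 1L)
      seqint
    }
    mk <- function(id) {
      s <- .evolveInt(.seq2int(querySequence(anc)), divergence / 2, 2)
      newQuery(id, .int2seq(fix(s, ltr_len)), ltr_len)
    }
    setNames(list(mk(ids[1]), mk(ids[2])), ids)
  })
}

## resolve symbolic branch references ("stem:L3" or a literal branch label)
.resolveBranch <- function(tree, lineages, ref) {
  if (!startsWith(ref, "stem:")) return(ref)
  lin <- sub("^stem:", "", ref)
  strains <- names(lineages)[lineages == lin]
  if (!length(strains)) stop("no strains in lineage ", lin)
  if (length(strains) == 1L) return(strains)
  node <- ape::getMRCA(tree, strains)
  tree$node.label[node - length(tree$tip.label)]
}

## scheduled events for each bundled scenario, in symbolic branch references
.scenarioEvents <- function(scenario, cfg) {
  ev <- list(htt_events = list(), extinction_events = list(),
             recomb_events = list())
  if (scenario == "vertical_only") return(ev)
  if (scenario == "recombinant_only") {
    ## both subfamilies vertical everywhere; chimeras arise in lineage 4
    ev$recomb_events <- list(
      list(branch = "tip1:L4", time = 0.6, parentA = "TyA", parentB = "TyB",
           breakpoints = cfg$simulate$breakpoint_5p, name = "chimera5p"),
      list(branch = "tip2:L4", time = 0.6, parentA = "TyA", parentB = "TyB",
           breakpoints = cfg$simulate$breakpoint_mid, name = "chimeraMid"))
    return(ev)
  }
  ## subfamily TyB goes extinct early on the stems of lineages 3 and 4, then
  ## is horizontally re-introduced into lineage 4 from lineage 1
  ev$extinction_events <- list(
    list(branch = "stem:L3", time = 0.05, subfamily = "TyB"),
    list(branch = "stem:L4", time = 0.05, subfamily = "TyB"))
  ev$htt_events <- list(
    list(donor = "stem:L1", recipient = "stem:L4", time = 0.5,
         subfamily = "TyB"))
  if (scenario == "htt_plus_recombinant") {
    ev$recomb_events <- list(
      list(branch = "tip1:L4", time = 0.6, parentA = "TyA", parentB = "TyB",
           breakpoints = cfg$simulate$breakpoint_5p, name = "chimera5p"),
      list(branch = "tip2:L4", time = 0.6, parentA = "TyA", parentB = "TyB",
           breakpoints = cfg$simulate$breakpoint_mid, name = "chimeraMid"))
  }
  ev
}

## resolve "tipK:L" references to the K-th strain of lineage L
.resolveTipRef <- function(ref, lineages) {
  m <- regmatches(ref, regexec("^tip([0-9]+):(.+)$", ref))[[1]]
  if (!length(m)) return(ref)
  strains <- sort(names(lineages)[lineages == m[3]])
  k <- min(as.integer(m[2]), length(strains))
  strains[k]
}

#' Run a bundled synthetic scenario end to end
#'
#' Executes the full inference chain on one of the bundled scenarios:
#' \code{vertical_only} (both subfamilies inherited vertically everywhere),
#' \code{htt_single} (subfamily TyB extinct in two lineages, horizontally
#' re-introduced into one of them), and \code{htt_plus_recombinant}
#' (additionally two inter-subfamily chimeras with known breakpoints).
#' Stages: family simulation, genome emission, read-evidence simulation and
#' copy-number/presence estimation, hit-table annotation and classification,
#' strain consensus with QC, sliding-window breakpoint inference on
#' chimeras, bootstrapped element trees, partitioned trees around called
#' breakpoints, and HTT flagging.
#'
#' @param config configuration (see \code{\link{validateConfig}}); a partial
#'   list is completed with defaults.
#' @param outdir optional run directory; when given, all stage outputs are
#'   written there with a manifest.
#' @return run report list (see Details) with elements \code{config},
#'   \code{sim}, \code{cn_table}, \code{presence_agreement},
#'   \code{class_counts}, \code{class_accuracy}, \code{consensus},
#'   \code{breakpoints}, \code{te_tree}, \code{flags},
#'   \code{partition_support}, \code{fingerprint}.
#' @export
runEndToEnd <- function(config = list(), outdir = NULL) {
  cfg <- validateConfig(config)
  s <- cfg$seed
  sc <- cfg$simulate
  queries <- makeQueryPair(.subseed(s, 1), sc$ltr_len, sc$internal_len,
                           sc$subfamily_divergence)
  tree <- simulateHostTree(sc$n_strains, sc$depth_scale, .subseed(s, 2),
                           n_lineages = sc$n_lineages,
                           within_scale = sc$within_scale)
  lineages <- hostLineages(tree)
  ev <- .scenarioEvents(cfg$scenario, cfg)
  ev$htt_events <- lapply(ev$htt_events, function(e) {
    e$donor <- .resolveBranch(tree, lineages, e$donor)
    e$recipient <- .resolveBranch(tree, lineages, e$recipient)
    e
  })
  ev$extinction_events <- lapply(ev$extinction_events, function(e) {
    e$branch <- .resolveBranch(tree, lineages, e$branch)
    e
  })
  ev$recomb_events <- lapply(ev$recomb_events, function(e) {
    e$branch <- .resolveTipRef(e$branch, lineages)
    e
  })
  params <- list(kappa = sc$kappa, sub_rate = sc$sub_rate,
                 transposition_rate = sc$transposition_rate,
                 solo_ltr_rate = sc$solo_ltr_rate,
                 truncation_rate = sc$truncation_rate,
                 loss_rate = sc$loss_rate,
                 htt_events = ev$htt_events,
                 extinction_events = ev$extinction_events,
                 recomb_events = ev$recomb_events,
                 seed = .subseed(s, 3))
  sim <- simulateFamilyHistory(tree, params, unname(queries),
                               root_copies = sc$root_copies)
  run <- emitGenomes(sim, sc$background_length, .subseed(s, 4),
                     n_contigs = sc$n_contigs, tsd_len = sc$tsd_len)

  ## --- copy number & presence --------------------------------------------
  strains <- tree$tip.label
  cn_rows <- list()
  pileups <- list()
  k <- 0L
  for (st in strains) {
    for (qid in names(queries)) {
      k <- k + 1L
      evd <- simulateReadEvidence(run, sim, st, queries[[qid]],
                                  fold_coverage = sc$fold_coverage,
                                  read_len = sc$read_len, err = sc$err,
                                  seed = .subseed(s, 100 + k))
      prof <- downsampleDepth(evd$depth, cap = cfg$coverage$cap,
                              seed = .subseed(s, 300 + k))
      cn_rows[[k]] <- copyNumberEstimate(
        prof, queries[[qid]], strain_id = st,
        ltr_threshold = cfg$coverage$ltr_threshold,
        int_threshold = cfg$coverage$int_threshold,
        min_depth = cfg$coverage$min_depth)
      if (qid == "TyB") pileups[[st]] <- evd$pileup
    }
  }
  cn_table <- do.call(rbind, cn_rows)
  cn_table$true_cn_ltr <- mapply(function(st, q)
    trueCopyNumber(sim, st, q, "ltr"), cn_table$strain, cn_table$query_id)
  cn_table$true_cn_internal <- mapply(function(st, q)
    trueCopyNumber(sim, st, q, "internal"), cn_table$strain,
    cn_table$query_id)
  # inventory-derived presence: apply the same thresholds to the true copy
  # numbers the element inventory implies
  cn_table$true_present <- cn_table$true_cn_ltr > cfg$coverage$ltr_threshold |
    cn_table$true_cn_internal > cfg$coverage$int_threshold
  cn_table$called_present <- cn_table$presence_ltr |
    cn_table$presence_internal
  presence_agreement <- mean(cn_table$true_present == cn_table$called_present)

  ## --- annotation ---------------------------------------------------------
  hits <- emitHitTable(run, sim, queries, frag_prob = sc$frag_prob,
                       seed = .subseed(s, 5))
  elements <- annotateElements(
    hits, queries, max_gap = cfg$annotate$max_gap,
    min_full_frac = cfg$annotate$min_full_frac,
    ltr_only_frac = cfg$annotate$ltr_only_frac,
    max_solo_internal = cfg$annotate$max_solo_internal)
  truth_el <- simElements(sim)
  acc <- .classAccuracy(elements, truth_el, run$bed)
  class_counts <- table(factor(elements$class,
                               levels = c("FLE", "truncated", "solo_LTR")))

  ## --- consensus ----------------------------------------------------------
  cons_rows <- list()
  for (st in strains) {
    row <- cn_table[cn_table$strain == st & cn_table$query_id == "TyB", ]
    pass <- qcStrain(row$cn_internal, row$breadth_internal,
                     cfg$consensus$depth_min, cfg$consensus$breadth_min)
    if (isTRUE(pass)) {
      cons_rows[[st]] <- data.frame(
        strain = st, subfamily = "TyB",
        sequence = majorityConsensus(pileups[[st]],
                                     min_depth = cfg$consensus$min_depth),
        cn_internal = row$cn_internal, breadth = row$breadth_internal,
        stringsAsFactors = FALSE)
    }
  }
  consensus_table <- if (length(cons_rows)) do.call(rbind, cons_rows) else
    data.frame(strain = character(0), subfamily = character(0),
               sequence = character(0), cn_internal = numeric(0),
               breadth = numeric(0), stringsAsFactors = FALSE)

  ## --- recombination ------------------------------------------------------
  regs <- queryRegions(queries[[1]])
  ltr_len <- regs$ltr5[2]
  rec_el <- truth_el[truth_el$ancestry == "recombinant", , drop = FALSE]
  rec_el <- rec_el[!duplicated(rec_el$element_id), , drop = FALSE]
  pureA <- truth_el[truth_el$subfamily == "TyA" & truth_el$class == "FLE" &
                    truth_el$ancestry != "recombinant", , drop = FALSE]
  pureB <- truth_el[truth_el$subfamily == "TyB" & truth_el$class == "FLE" &
                    truth_el$ancestry != "recombinant", , drop = FALSE]
  bp_rows <- list()
  profiles <- list()
  for (i in seq_len(nrow(rec_el))) {
    if (!nrow(pureA) || !nrow(pureB)) break
    cand <- substr(rec_el$sequence[i], regs$internal[1] + 1, regs$internal[2])
    # parent representatives: the nearest pure FLE of each subfamily
    intSub <- function(x) substr(x, regs$internal[1] + 1, regs$internal[2])
    dA <- vapply(pureA$sequence, function(x)
      k2p(cand, intSub(x))$d, numeric(1))
    dB <- vapply(pureB$sequence, function(x)
      k2p(cand, intSub(x))$d, numeric(1))
    pA <- intSub(pureA$sequence[which.min(dA)])
    pB <- intSub(pureB$sequence[which.min(dB)])
    prof <- slidingWindowDivergence(cand, c(TyA = pA, TyB = pB),
                                    w = cfg$recomb$window,
                                    s = cfg$recomb$step)
    call <- inferBreakpoints(prof, min_seg = cfg$recomb$min_seg)
    truth_bp <- as.numeric(strsplit(rec_el$breakpoints[i], ",")[[1]]) -
      ltr_len
    bp_rows[[i]] <- data.frame(
      element_id = rec_el$element_id[i], strain = rec_el$strain[i],
      name = rec_el$subfamily[i],
      n_called = length(call$breakpoints),
      called = paste(round(call$breakpoints), collapse = ","),
      truth = paste(truth_bp, collapse = ","),
      segment_parents = paste(call$segments$parent, collapse = ","),
      stringsAsFactors = FALSE)
    profiles[[rec_el$element_id[i]]] <- list(profile = prof, call = call)
  }
  breakpoints <- if (length(bp_rows)) do.call(rbind, bp_rows) else
    data.frame(element_id = character(0), strain = character(0),
               name = character(0), n_called = integer(0),
               called = character(0), truth = character(0),
               segment_parents = character(0), stringsAsFactors = FALSE)

  ## --- element tree and HTT flags -----------------------------------------
  aln <- truthAlignment(sim, include_recombinant = FALSE)
  te_tree <- NULL; flags <- NULL; te_dm <- NULL
  if (length(aln) >= 4) {
    bt <- bootstrapSupport(aln, n = cfg$phylo$bootstrap,
                           seed = .subseed(s, 6),
                           variant = cfg$phylo$variant)
    te_tree <- midpointRoot(bt)
    te_dm <- distanceMatrix(aln)
    species_of <- setNames(lineages[sub("\\|.*$", "", names(aln))],
                           names(aln))
    presence_table <- data.frame(strain = cn_table$strain,
                                 subfamily = cn_table$query_id,
                                 present = cn_table$called_present,
                                 stringsAsFactors = FALSE)
    flags <- httFlag(te_tree, tree, species_of, lineages,
                     te_dm = te_dm, presence_table = presence_table,
                     min_support = cfg$phylo$min_support,
                     sim_ratio = cfg$phylo$sim_ratio,
                     rate_scale = sc$sub_rate,
                     min_absent_inside = cfg$phylo$min_absent_inside)
  }

  ## --- partitioned trees around the 5' chimera breakpoint ------------------
  partition_support <- NULL
  chim5 <- truth_el[truth_el$subfamily == "chimera5p" &
                    truth_el$element_id %in% names(profiles), , drop = FALSE]
  if (nrow(chim5)) {
    eid <- chim5$element_id[1]
    call <- profiles[[eid]]$call
    if (!is.null(call) && length(call$breakpoints) >= 1) {
      bp <- round(call$breakpoints[1])
      aln_all <- truthAlignment(sim, include_recombinant = TRUE)
      chim_tip <- paste(chim5$strain[1], eid, sep = "|")
      el_ids <- sub("^.*\\|", "", names(aln_all))
      el_sub <- truth_el$subfamily[match(el_ids, truth_el$element_id)]
      keep <- el_sub %in% c("TyA", "TyB") | names(aln_all) == chim_tip
      aln_part <- aln_all[keep]
      if (length(aln_part) >= 5 && chim_tip %in% names(aln_part)) {
        L <- nchar(aln_part[[1]])
        parts <- partitionAlignment(aln_part,
                                    list(five_prime = c(1, bp),
                                         three_prime = c(bp + 1, L)))
        sub_of <- el_sub[keep]
        tipsA <- names(aln_part)[sub_of == "TyA" & names(aln_part) != chim_tip]
        tipsB <- names(aln_part)[sub_of == "TyB" & names(aln_part) != chim_tip]
        bt5 <- bootstrapSupport(parts$five_prime, n = cfg$phylo$bootstrap,
                                seed = .subseed(s, 7),
                                variant = cfg$phylo$variant)
        bt3 <- bootstrapSupport(parts$three_prime, n = cfg$phylo$bootstrap,
                                seed = .subseed(s, 8),
                                variant = cfg$phylo$variant)
        partition_support <- data.frame(
          element_id = eid, breakpoint = bp,
          support_5p_with_parentA = cladeSupport(bt5, c(chim_tip, tipsA)),
          support_3p_with_parentB = cladeSupport(bt3, c(chim_tip, tipsB)),
          stringsAsFactors = FALSE)
      }
    }
  }

  report <- list(config = cfg, sim = sim, cn_table = cn_table,
                 presence_agreement = presence_agreement,
                 class_counts = as.list(class_counts),
                 class_accuracy = acc, consensus = consensus_table,
                 breakpoints = breakpoints, te_tree = te_tree,
                 te_dm = te_dm, flags = flags,
                 partition_support = partition_support)
  report$fingerprint <- .reportFingerprint(report)
  if (!is.null(outdir)) writeRunReport(report, run, outdir)
  report
}

## match annotated elements to truth via locus overlap and score class calls
.classAccuracy <- function(elements, truth_el, bed) {
  if (!nrow(elements) || !nrow(bed)) return(NA_real_)
  ok <- logical(0)
  for (i in seq_len(nrow(bed))) {
    b <- bed[i, ]
    cand <- which(elements$target_seq == b$seqname &
                  elements$start < b$end & elements$end > b$start)
    if (!length(cand)) { ok <- c(ok, FALSE); next }
    # best overlap
    ovl <- pmin(elements$end[cand], b$end) - pmax(elements$start[cand], b$start)
    j <- cand[which.max(ovl)]
    truth_class <- truth_el$class[truth_el$element_id == b$name &
                                  truth_el$strain == b$strain][1]
    ok <- c(ok, identical(elements$class[j], truth_class))
  }
  mean(ok)
}

## stable fingerprint of a run report (deterministic across reruns)
.reportFingerprint <- function(report) {
  keep <- report[c("cn_table", "presence_agreement", "class_counts",
                   "class_accuracy", "breakpoints",
                   "partition_support")]
  keep$consensus <- report$consensus$sequence
  keep$flags <- if (!is.null(report$flags)) report$flags$evidence
  keep$tree <- if (!is.null(report$te_tree))
    ape::write.tree(report$te_tree)
  js <- jsonlite::toJSON(keep, digits = 10, auto_unbox = TRUE, force = TRUE)
  tf <- tempfile()
  writeLines(js, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Write a run report and its intermediates to a run directory
#'
#' @param report output of \code{\link{runEndToEnd}}.
#' @param run the emitted genome run (from the report's simulation); may be
#'   NULL to skip FASTA/BED output.
#' @param outdir directory (created if needed).
#' @export
writeRunReport <- function(report, run = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$cn_table, file.path(outdir, "copy_number.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$breakpoints, file.path(outdir, "breakpoints.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$consensus))
    writeFastaFile(setNames(report$consensus$sequence,
                            paste(report$consensus$strain,
                                  report$consensus$subfamily, sep = "|")),
                   file.path(outdir, "consensus.fasta"))
  if (!is.null(report$te_tree))
    ape::write.tree(report$te_tree, file.path(outdir, "te_tree.nwk"))
  if (!is.null(report$flags))
    jsonlite::write_json(report$flags, file.path(outdir, "htt_flags.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  summary <- list(scenario = report$config$scenario,
                  seed = report$config$seed,
                  presence_agreement = report$presence_agreement,
                  class_counts = report$class_counts,
                  class_accuracy = report$class_accuracy,
                  n_flags = if (is.null(report$flags)) 0L
                            else nrow(report$flags),
                  fingerprint = report$fingerprint)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(run)) {
    writeFastaFile(run$fasta, file.path(outdir, "genomes.fasta"))
    writeBED(run$bed, file.path(outdir, "truth_elements.bed"))
  }
  writeManifest(outdir)
  invisible(outdir)
}
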