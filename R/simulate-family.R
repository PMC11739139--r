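## Forward simulation of TE family evolution along a host strain tree.
## Elements evolve by K2P substitution; stochastic per-element processes
## (transposition, solo-LTR formation, truncation, loss) are drawn as a
## Gillespie walk along each branch; horizontal transfers, subfamily
## extinctions and recombination events are scheduled at fixed branch
## positions. No indels are simulated, so the true homology alignment of
## internal regions is gap-free.

.defaultEvolutionParams <- function() {
  list(
    kappa = 2,
    sub_rate = 1,
    transposition_rate = 0.25,  # per FLE per unit branch length
    solo_ltr_rate = 0.15,
    truncation_rate = 0.08,
    loss_rate = 0.05,
    htt_events = list(),
    extinction_events = list(),
    recomb_events = list(),
    seed = 1
  )
}

## branch id = label of the child node of the edge
.branchIds <- function(tree) {
  labs <- c(tree$tip.label, tree$node.label)
  labs[tree$edge[, 2]]
}

.elem <- function(id, subfamily, class, q_start, q_end, seq_int,
                  ancestry = "vertical", origin = "root",
                  breakpoints = "", parents = "") {
  list(id = id, subfamily = subfamily, class = class,
       q_start = q_start, q_end = q_end, seq = seq_int,
       ancestry = ancestry, origin = origin,
       breakpoints = breakpoints, parents = parents)
}

#' Forward-simulate TE family evolution along a host tree
#'
#' Starting from one full-length element per root query, elements evolve by
#' K2P substitution along every branch while per-element Poisson processes
#' generate transpositions (duplications), solo-LTR formation (intra-element
#' LTR recombination excising the internal region), 5'/3' truncations and
#' full deletions.  Scheduled events model subfamily extinction on a branch,
#' horizontal transfer of one element state from a donor branch to a
#' recipient branch at stated times, and inter-subfamily recombination
#' creating chimeric elements with known breakpoints.  The result carries the
#' complete truth: per-strain element inventories with true class, subfamily
#' and sequence, plus a replayable event log.
#'
#' @param tree host tree from \code{\link{simulateHostTree}} (or any rooted
#'   \code{phylo} with branch lengths; node labels are added if missing).
#' @param params list of evolution parameters; unset entries take defaults:
#'   \code{kappa} (2), \code{sub_rate} (1), \code{transposition_rate} (0.25),
#'   \code{solo_ltr_rate} (0.15), \code{truncation_rate} (0.08),
#'   \code{loss_rate} (0.05), \code{seed} (1), and the scheduled event lists
#'   \code{htt_events} (each \code{list(donor=, recipient=, time=,
#'   subfamily=)}, time as fraction of the recipient branch),
#'   \code{extinction_events} (\code{list(branch=, time=, subfamily=)}) and
#'   \code{recomb_events} (\code{list(branch=, time=, parentA=, parentB=,
#'   breakpoints=, name=)}, breakpoints in query coordinates strictly inside
#'   the internal region).  Branches are referred to by the label of the
#'   child node of the edge (a tip label or \code{n<k>}).
#' @param root_elements list of \linkS4class{TEQueryModel}, one per
#'   subfamily present at the root; all must share the same region geometry.
#' @param root_copies number of root copies per subfamily (default 2).
#' @return a \linkS4class{TySimulation}.
#' @export
simulateFamilyHistory <- function(tree, params = list(), root_elements,
                                  root_copies = 2) {
  if (!length(root_elements)) stop("root_elements must be non-empty")
  p <- utils::modifyList(.defaultEvolutionParams(), params)
  # modifyList drops unnamed nested lists: restore event lists verbatim
  for (k in c("htt_events", "extinction_events", "recomb_events"))
    if (!is.null(params[[k]])) p[[k]] <- params[[k]]
  stopifnot(p$kappa > 0, p$sub_rate >= 0,
            p$transposition_rate >= 0, p$solo_ltr_rate >= 0,
            p$truncation_rate >= 0, p$loss_rate >= 0)
  if (is.null(tree$node.label)) tree <- ape::makeNodeLabel(tree, prefix = "n")
  qgeo <- lapply(root_elements, queryRegions)
  if (length(unique(vapply(qgeo, function(r)
    paste(unlist(r), collapse = ","), character(1)))) != 1L)
    stop("all root queries must share the same region geometry")
  regions <- qgeo[[1]]
  qlen <- regions$ltr3[2]
  ltr_len <- regions$ltr5[2]
  queries <- setNames(root_elements,
                      vapply(root_elements, queryId, character(1)))
  bids <- .branchIds(tree)
  all_branch_refs <- c(
    vapply(p$htt_events, function(e) c(e$donor, e$recipient), character(2)),
    vapply(p$extinction_events, function(e) e$branch, character(1)),
    vapply(p$recomb_events, function(e) e$branch, character(1)))
  bad <- setdiff(unlist(all_branch_refs), bids)
  if (length(bad))
    stop("invalid config: event references nonexistent branch(es): ",
         paste(bad, collapse = ", "))
  for (e in p$recomb_events) {
    b <- sort(e$breakpoints)
    if (!length(b) || any(b <= regions$internal[1]) ||
        any(b >= regions$internal[2]) || any(duplicated(b)))
      stop("invalid config: recombination breakpoints must be strictly ",
           "increasing and inside the internal region")
  }

  withr_seed(p$seed, {
    counter <- new.env()
    counter$n <- 0L
    newId <- function() {
      counter$n <- counter$n + 1L
      sprintf("e%04d", counter$n)
    }
    log_env <- new.env()
    log_env$rows <- list()
    logEvent <- function(event, branch, time, element_id, detail = "") {
      log_env$rows[[length(log_env$rows) + 1L]] <-
        data.frame(event = event, branch = branch, time = time,
                   element_id = element_id, detail = detail,
                   stringsAsFactors = FALSE)
    }

    ## scheduled events indexed by branch
    sched_by_branch <- list()
    addSched <- function(branch, time_frac, kind, payload) {
      sched_by_branch[[branch]] <<- c(sched_by_branch[[branch]],
        list(list(time_frac = time_frac, kind = kind, payload = payload)))
    }
    snapshots <- new.env()
    for (i in seq_along(p$htt_events)) {
      e <- p$htt_events[[i]]
      tfrac <- if (is.null(e$time)) 0.5 else e$time
      if (tfrac < 0 || tfrac > 1)
        stop("invalid config: htt time must lie within the branch interval")
      addSched(e$donor, tfrac, "htt_donate", list(idx = i, ev = e))
      addSched(e$recipient, tfrac, "htt_insert", list(idx = i, ev = e))
    }
    for (e in p$extinction_events)
      addSched(e$branch, if (is.null(e$time)) 0.1 else e$time,
               "extinction", list(ev = e))
    for (e in p$recomb_events)
      addSched(e$branch, if (is.null(e$time)) 0.5 else e$time,
               "recomb", list(ev = e))

    ## root inventory
    root_state <- list()
    for (q in root_elements) {
      qi <- .seq2int(querySequence(q))
      for (k in seq_len(root_copies))
        root_state[[length(root_state) + 1L]] <-
          .elem(newId(), queryId(q), "FLE", 0L, qlen, qi)
    }

    Ntip <- length(tree$tip.label)
    root_node <- Ntip + 1L
    node_state <- new.env()
    assign(as.character(root_node), root_state, envir = node_state)
    edge_in_progress <- new.env()

    node_label <- function(node) {
      if (node <= Ntip) tree$tip.label[node]
      else tree$node.label[node - Ntip]
    }
    edge_of_child_label <- function(lab) which(bids == lab)

    evolveAll <- function(S, d) {
      if (d <= 0 || !length(S)) return(S)
      lapply(S, function(el) {
        el$seq <- .evolveInt(el$seq, d, p$kappa)
        el
      })
    }

    applyStochastic <- function(S, which_kind, branch, at) {
      fle_idx <- which(vapply(S, function(e) e$class == "FLE", logical(1)))
      if (which_kind == "loss") {
        i <- sample.int(length(S), 1L)
        logEvent("loss", branch, at, S[[i]]$id)
        return(S[-i])
      }
      if (!length(fle_idx)) return(S)
      i <- fle_idx[sample.int(length(fle_idx), 1L)]
      el <- S[[i]]
      if (which_kind == "transposition") {
        daughter <- el
        daughter$id <- newId()
        daughter$origin <- paste0("transposition:", el$id)
        logEvent("transposition", branch, at, daughter$id,
                 paste0("source=", el$id))
        S[[length(S) + 1L]] <- daughter
      } else if (which_kind == "solo_ltr") {
        el$class <- "solo_LTR"
        el$seq <- el$seq[seq_len(ltr_len)]
        el$q_start <- 0L
        el$q_end <- ltr_len
        logEvent("solo_ltr", branch, at, el$id)
        S[[i]] <- el
      } else if (which_kind == "truncation") {
        len <- el$q_end - el$q_start
        cut <- round(runif(1, 0.25, 0.8) * len)
        if (runif(1) < 0.5) {  # cut from 5' end
          el$seq <- el$seq[(cut + 1L):len]
          el$q_start <- el$q_start + cut
        } else {               # cut from 3' end
          el$seq <- el$seq[seq_len(len - cut)]
          el$q_end <- el$q_end - cut
        }
        el$class <- "truncated"
        logEvent("truncation", branch, at, el$id, paste0("cut=", cut))
        S[[i]] <- el
      }
      S
    }

    applyScheduled <- function(S, ev, branch, at) {
      if (ev$kind == "extinction") {
        sf <- ev$payload$ev$subfamily
        gone <- vapply(S, function(e) e$subfamily == sf, logical(1))
        for (e in S[gone]) logEvent("loss", branch, at, e$id,
                                    paste0("extinction:", sf))
        logEvent("extinction", branch, at, "", sf)
        return(S[!gone])
      }
      if (ev$kind == "htt_donate") {
        sf <- ev$payload$ev$subfamily
        cand <- which(vapply(S, function(e)
          e$class == "FLE" && (is.null(sf) || e$subfamily == sf), logical(1)))
        if (!length(cand))
          stop("invalid config: no eligible donor element for htt event on ",
               "branch ", branch)
        el <- S[[cand[sample.int(length(cand), 1L)]]]
        assign(paste0("htt", ev$payload$idx), el, envir = snapshots)
        logEvent("htt_donate", branch, at, el$id)
        return(S)
      }
      if (ev$kind == "htt_insert") {
        key <- paste0("htt", ev$payload$idx)
        if (!exists(key, envir = snapshots))
          stop("internal error: donor snapshot missing for htt event")
        el <- get(key, envir = snapshots)
        el$id <- newId()
        el$ancestry <- "htt"
        el$origin <- paste0("htt_from:", ev$payload$ev$donor)
        logEvent("htt", branch, at, el$id,
                 paste0("donor=", ev$payload$ev$donor))
        S[[length(S) + 1L]] <- el
        return(S)
      }
      if (ev$kind == "recomb") {
        e <- ev$payload$ev
        ia <- which(vapply(S, function(x)
          x$class == "FLE" && x$subfamily == e$parentA, logical(1)))
        ib <- which(vapply(S, function(x)
          x$class == "FLE" && x$subfamily == e$parentB, logical(1)))
        if (!length(ia) || !length(ib))
          stop("invalid config: recombination on branch ", branch,
               " requires FLEs of both parent subfamilies")
        A <- S[[ia[sample.int(length(ia), 1L)]]]
        B <- S[[ib[sample.int(length(ib), 1L)]]]
        b <- sort(e$breakpoints)
        seqc <- A$seq
        bounds <- c(0L, b, qlen)
        for (k in seq_len(length(bounds) - 1L)) {
          if (k %% 2 == 0)   # even segments come from parent B
            seqc[(bounds[k] + 1L):bounds[k + 1L]] <-
              B$seq[(bounds[k] + 1L):bounds[k + 1L]]
        }
        nm <- if (is.null(e$name)) paste0("rec_", e$parentA, "_", e$parentB)
              else e$name
        chim <- .elem(newId(), nm, "FLE", 0L, qlen, seqc,
                      ancestry = "recombinant", origin = branch,
                      breakpoints = paste(b, collapse = ","),
                      parents = paste(e$parentA, e$parentB, sep = ","))
        logEvent("recombination", branch, at, chim$id,
                 paste0("parents=", chim$parents, ";breakpoints=",
                        chim$breakpoints))
        S[[length(S) + 1L]] <- chim
        return(S)
      }
      S
    }

    computeNode <- function(node) {
      key <- as.character(node)
      if (exists(key, envir = node_state)) return(get(key, envir = node_state))
      ei <- which(tree$edge[, 2] == node)
      parent <- tree$edge[ei, 1]
      blab <- bids[ei]
      if (exists(blab, envir = edge_in_progress))
        stop("invalid config: circular htt dependency involving branch ", blab)
      assign(blab, TRUE, envir = edge_in_progress)
      ## donor dependencies: any htt_insert on this branch requires its donor
      ## branch to be computed first
      for (ev in sched_by_branch[[blab]]) {
        if (ev$kind == "htt_insert") {
          dlab <- ev$payload$ev$donor
          dnode <- tree$edge[edge_of_child_label(dlab), 2]
          computeNode(dnode)
        }
      }
      S <- computeNode(parent)
      len <- tree$edge.length[ei]
      sched <- sched_by_branch[[blab]]
      times <- if (length(sched))
        vapply(sched, function(x) x$time_frac, numeric(1)) * len else numeric(0)
      ord <- order(times)
      sched <- sched[ord]; times <- times[ord]
      cur <- 0
      i_sched <- 1L
      rates <- c(transposition = p$transposition_rate,
                 solo_ltr = p$solo_ltr_rate,
                 truncation = p$truncation_rate)
      repeat {
        t_next_sched <- if (i_sched <= length(times)) times[i_sched] else len
        n_fle <- sum(vapply(S, function(e) e$class == "FLE", logical(1)))
        lam <- n_fle * sum(rates) + length(S) * p$loss_rate
        dt <- if (lam > 0) stats::rexp(1, lam) else Inf
        if (cur + dt < t_next_sched) {
          S <- evolveAll(S, dt * p$sub_rate)
          cur <- cur + dt
          ## choose event kind weighted by total rates
          w <- c(n_fle * rates, loss = length(S) * p$loss_rate)
          kind <- sample(names(w), 1L, prob = w)
          S <- applyStochastic(S, kind, blab, cur)
        } else {
          S <- evolveAll(S, (t_next_sched - cur) * p$sub_rate)
          cur <- t_next_sched
          if (i_sched <= length(sched)) {
            S <- applyScheduled(S, sched[[i_sched]], blab, cur)
            i_sched <- i_sched + 1L
          } else break
        }
      }
      assign(key, S, envir = node_state)
      rm(list = blab, envir = edge_in_progress)
      S
    }

    ## compute all tips in label order (deterministic)
    tip_states <- lapply(seq_len(Ntip), computeNode)
    names(tip_states) <- tree$tip.label

    rows <- list()
    for (s in tree$tip.label) {
      for (el in tip_states[[s]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = el$id, strain = s, subfamily = el$subfamily,
          class = el$class, q_start = el$q_start, q_end = el$q_end,
          sequence = .int2seq(el$seq), ancestry = el$ancestry,
          origin = el$origin, breakpoints = el$breakpoints,
          parents = el$parents, stringsAsFactors = FALSE)
      }
    }
    elements <- if (length(rows)) do.call(rbind, rows) else
      data.frame(element_id = character(0), strain = character(0),
                 subfamily = character(0), class = character(0),
                 q_start = integer(0), q_end = integer(0),
                 sequence = character(0), ancestry = character(0),
                 origin = character(0), breakpoints = character(0),
                 parents = character(0), stringsAsFactors = FALSE)
    events <- if (length(log_env$rows)) do.call(rbind, log_env$rows) else
      data.frame(event = character(0), branch = character(0),
                 time = numeric(0), element_id = character(0),
                 detail = character(0), stringsAsFactors = FALSE)
    new("TySimulation", tree = tree, lineages = hostLineages(tree),
        elements = elements, events = events, queries = queries,
        params = p)
  })
}

#' True region copy number of a strain from the simulation inventory
#'
#' Copy number of a query region as implied by the true element inventory:
#' the summed fraction of the region covered by each element's retained query
#' interval (a full-length element contributes 1 to the internal region and 2
#' across the two LTRs).
#'
#' @param sim a \linkS4class{TySimulation}.
#' @param strain strain id.
#' @param subfamily subfamily (query) id.
#' @param region one of \code{"internal"}, \code{"ltr"} (LTR copies: a
#'   full-length element counts 2, a solo LTR 1), \code{"ltr5"},
#'   \code{"ltr3"}.
#' @return numeric copy number.
#' @export
trueCopyNumber <- function(sim, strain, subfamily, region = "internal") {
  el <- simElements(sim)
  el <- el[el$strain == strain & el$subfamily == subfamily, , drop = FALSE]
  regs <- queryRegions(simQueries(sim)[[subfamily]])
  ivs <- switch(region,
                internal = list(regs$internal),
                ltr = list(regs$ltr5, regs$ltr3),
                ltr5 = list(regs$ltr5),
                ltr3 = list(regs$ltr3),
                stop("unknown region: ", region))
  if (!nrow(el)) return(0)
  total <- 0
  # per-LTR length as denominator for "ltr": counts LTR copies, not pairs
  rlen <- if (region == "ltr") regs$ltr5[2] - regs$ltr5[1] else
    sum(vapply(ivs, function(r) r[2] - r[1], numeric(1)))
  for (i in seq_len(nrow(el))) {
    cov <- sum(vapply(ivs, function(r)
      max(0, min(el$q_end[i], r[2]) - max(el$q_start[i], r[1])), numeric(1)))
    total <- total + cov
  }
  total / rlen
}

#' Gap-free truth alignment of element sequences over a query region
#'
#' Because no indels are simulated, element sequences retain exact positional
#' homology with the query: extracting a query region from every element that
#' fully covers it yields a gap-free alignment.
#'
#' @param sim a \linkS4class{TySimulation}.
#' @param region \code{"internal"} (default) or \code{"full"}.
#' @param classes element classes to include (default \code{"FLE"}).
#' @param subfamilies optional subfamily filter.
#' @param include_recombinant include chimeric elements (default TRUE).
#' @return named character vector, names \code{strain|element_id}.
#' @export
truthAlignment <- function(sim, region = "internal", classes = "FLE",
                           subfamilies = NULL, include_recombinant = TRUE) {
  el <- simElements(sim)
  regs <- queryRegions(simQueries(sim)[[1]])
  iv <- if (region == "full") c(0, regs$ltr3[2]) else regs[[region]]
  keep <- el$class %in% classes & el$q_start <= iv[1] & el$q_end >= iv[2]
  if (!is.null(subfamilies)) keep <- keep & el$subfamily %in% subfamilies
  if (!include_recombinant) keep <- keep & el$ancestry != "recombinant"
  el <- el[keep, , drop = FALSE]
  if (!nrow(el)) return(setNames(character(0), character(0)))
  out <- vapply(seq_len(nrow(el)), function(i) {
    # element sequence spans [q_start, q_end); extract [iv1, iv2)
    substr(el$sequence[i], iv[1] - el$q_start[i] + 1L,
           iv[2] - el$q_start[i])
  }, character(1))
  setNames(out, paste(el$strain, el$element_id, sep = "|"))
}
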