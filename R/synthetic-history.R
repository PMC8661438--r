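# Simulated species trees and gene-family birth-death histories with known
# ground truth, used to validate reconciliation and rate estimation.

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree conditioned on the number of tips, rescaled so the
#' root-to-tip depth equals `crown_age` (the stand-in for a published
#' time-calibrated chronogram).
#'
#' @param n_taxa number of tips (>= 2).
#' @param crown_age root depth in Myr (> 0).
#' @param seed integer seed.
#' @return an `ape::phylo` tree, rooted, binary, ultrametric; tips are
#'   labelled `sp01, sp02, ...`.
#' @export
simulate_species_tree <- function(n_taxa, crown_age, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be at least 2")
  if (crown_age <= 0) stop("crown_age must be positive")
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * crown_age / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tr
}

#' Simulate a gene-family history on a species tree
#'
#' Gillespie birth-death simulation of gene copies along every species
#' branch. Each duplication adds a copy (a gain on that branch), each death
#' removes one (a loss), so the ledger `n_desc = n_anc + G - L` holds on
#' every branch by construction. The true gene tree of extant copies is
#' returned in Newick, with tips `species|gene<id>`.
#'
#' @param tree species tree (`phylo`, branch lengths in Myr).
#' @param n_root gene copies at the species root.
#' @param birth,death rates per gene per Myr (>= 0).
#' @param seed integer seed (NULL to use the current RNG state).
#' @return list with class `fishor_history`: `species_tree`, `events`
#'   (data.frame: branch = child node label/id, t, n_anc, G, L, n_desc),
#'   `tips` (named list of gene ids per species), `gene_tree` (Newick string
#'   or NA if the family went extinct), `loss_ages` (per terminal branch, the
#'   ages in Myr before present of each loss event).
#' @export
simulate_gene_history <- function(tree, n_root, birth, death, seed = NULL) {
  if (birth < 0 || death < 0) stop("rates must be non-negative")
  if (n_root < 0) stop("n_root must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  env <- new.env()
  env$counter <- 0L
  node_key <- function(node) {
    if (node <= ntip) tree$tip.label[node] else paste0("node_", node)
  }
  branches <- vapply(seq_len(max(tree$edge)), node_key, character(1))
  env$G <- setNames(as.list(rep(0L, length(branches))), branches)
  env$L <- setNames(as.list(rep(0L, length(branches))), branches)
  env$loss_ages <- setNames(vector("list", length(branches)), branches)
  env$tips <- setNames(vector("list", ntip), tree$tip.label)
  n_at <- integer(max(tree$edge))
  children_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  edge_len <- function(child) tree$edge.length[match(child, tree$edge[, 2])]

  # recursive descent: returns newick fragment for one gene lineage entering
  # `node`'s subtree from above (already at the top of the branch to `node`),
  # or NULL if no extant descendants
  descend <- function(node) {
    if (node <= ntip) {
      env$counter <- env$counter + 1L
      gid <- paste0("g", env$counter)
      sp <- tree$tip.label[node]
      env$tips[[sp]] <- c(env$tips[[sp]], gid)
      return(paste0(sp, "|", gid))
    }
    kids <- children_of(node)
    parts <- list()
    for (k in kids) {
      frag <- lineage_on_branch(k)
      if (!is.null(frag)) parts[[length(parts) + 1L]] <- frag
    }
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L) return(parts[[1]])
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  # one lineage traversing the branch that ends at `child`
  lineage_on_branch <- function(child) {
    key <- node_key(child)
    t <- edge_len(child)
    survivors <- branch_bd(child, key, t)
    if (!length(survivors)) return(NULL)
    if (length(survivors) == 1L) return(survivors[[1]])
    paste0("(", paste(unlist(survivors), collapse = ","), ")")
  }
  # birth-death of a single lineage over remaining time t on branch `key`;
  # returns list of newick fragments for surviving sub-lineages
  branch_bd <- function(child, key, t_remain) {
    rate <- birth + death
    wait <- if (rate > 0) rexp(1, rate) else Inf
    if (wait >= t_remain) {
      frag <- descend(child)
      return(if (is.null(frag)) list() else list(frag))
    }
    t_remain <- t_remain - wait
    if (runif(1) < birth / max(rate, .Machine$double.eps)) {
      env$G[[key]] <- env$G[[key]] + 1L
      c(branch_bd(child, key, t_remain), branch_bd(child, key, t_remain))
    } else {
      env$L[[key]] <- env$L[[key]] + 1L
      if (child <= ntip)
        env$loss_ages[[key]] <- c(env$loss_ages[[key]], t_remain)
      list()
    }
  }

  frags <- list()
  for (i in seq_len(n_root)) {
    f <- descend(root)
    if (!is.null(f)) frags[[length(frags) + 1L]] <- f
  }
  gene_tree <- if (!length(frags)) NA_character_
  else if (length(frags) == 1L) paste0(unlist(frags), ";")
  else paste0("(", paste(unlist(frags), collapse = ","), ");")

  # per-branch ledger by preorder accumulation
  n_at[root] <- n_root
  ord <- rev(ape::postorder(tree))
  events <- list()
  for (ei in ord) {
    par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    key <- node_key(ch)
    n_anc <- n_at[par]
    G <- env$G[[key]]; L <- env$L[[key]]
    n_at[ch] <- n_anc + G - L
    events[[length(events) + 1L]] <- data.frame(
      branch = key, t = edge_len(ch), n_anc = n_anc, G = G, L = L,
      n_desc = n_at[ch], stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, events)
  structure(list(species_tree = tree, events = events,
                 tips = lapply(env$tips, function(x) if (is.null(x)) character(0) else x),
                 gene_tree = gene_tree,
                 loss_ages = env$loss_ages[tree$tip.label]),
            class = "fishor_history")
}

#' Observed pseudogene counts under age-dependent erasure
#'
#' Builds the terminal-branch table consumed by [loss_pseudo_sweep()] from a
#' simulated history: each loss event on a terminal branch leaves a
#' detectable pseudogene with probability `2^(-age / half_life)` (age in Myr
#' before present), emulating sequence decay and deletion of old
#' pseudogenes. Edge-gene counts are independent noise (assembly artifacts).
#'
#' @param history [simulate_gene_history()] output (or a list of them; loss
#'   events are pooled per terminal branch).
#' @param half_life detectability half-life in Myr.
#' @param edge_rate Poisson mean of the uncorrelated edge-gene count.
#' @param seed integer seed (NULL = current RNG state).
#' @return data.frame: branch, t, L, n_pseudo, n_truncated, n_edge.
#' @export
erode_pseudogene_record <- function(history, half_life = 30, edge_rate = 0.5,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hl <- if (inherits(history, "fishor_history")) list(history) else history
  tree <- hl[[1]]$species_tree
  tips <- tree$tip.label
  # terminal branch lengths keyed by tip
  t_of <- setNames(tree$edge.length[match(seq_along(tips), tree$edge[, 2])], tips)
  out <- lapply(tips, function(sp) {
    ages <- unlist(lapply(hl, function(h) h$loss_ages[[sp]]))
    L <- length(ages)
    n_obs <- if (L) sum(runif(L) < 2^(-ages / half_life)) else 0L
    data.frame(branch = sp, t = t_of[[sp]], L = L, n_pseudo = n_obs,
               n_truncated = 0L, n_edge = rpois(1, edge_rate),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
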