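# Gene-tree/species-tree reconciliation: LCA-mapping duplication-loss
# parsimony with DL-minimizing rooting, per-branch gain/loss counts,
# ancestral copy numbers, and birth/death rates.

#' Collapse low-support edges into polytomies
#'
#' Internal edges whose child node carries a support value below `threshold`
#' are contracted (the child's children are re-attached to its parent).
#' Nodes without a support label are kept. Tip set unchanged.
#'
#' @param tree `phylo` with numeric support values in `node.label` (0-100).
#' @param threshold support threshold (default 90; strictly-below collapses).
#' @return `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 90) {
  if (is.null(tree$node.label)) return(tree)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  if (any(!is.na(tree$node.label) & nzchar(tree$node.label) & is.na(supp)))
    stop("malformed support values in node labels")
  if (any(supp < 0 | supp > 100, na.rm = TRUE))
    stop("support values must lie in [0, 100]")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  drop_nodes <- which(!is.na(supp) & supp < threshold) + ntip
  drop_nodes <- setdiff(drop_nodes, root)
  if (!length(drop_nodes)) return(tree)
  edge <- tree$edge
  parent_of <- function(v) edge[edge[, 2] == v, 1]
  # contract bottom-up: reassign children of each dropped node to its parent
  for (v in drop_nodes) {
    p <- parent_of(v)
    while (p %in% drop_nodes) p <- parent_of(p)   # chains of contractions
    edge[edge[, 1] == v, 1] <- p
  }
  keep_edge <- !(edge[, 2] %in% drop_nodes)
  edge <- edge[keep_edge, , drop = FALSE]
  len <- tree$edge.length
  if (!is.null(len)) len <- len[keep_edge]
  # renumber internal nodes
  kept_nodes <- sort(unique(c(root, edge[edge[, 1] > ntip, 1], edge[edge[, 2] > ntip, 2])))
  map <- integer(max(tree$edge))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[kept_nodes] <- ntip + seq_along(kept_nodes)
  out <- list(edge = cbind(map[edge[, 1]], map[edge[, 2]]),
              tip.label = tree$tip.label,
              Nnode = length(kept_nodes))
  if (!is.null(len)) out$edge.length <- len
  nl <- tree$node.label[kept_nodes - ntip]
  out$node.label <- nl
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

# ---- internal tree helpers on ape phylo ------------------------------------

tree_children <- function(tree) {
  n <- max(tree$edge)
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

tree_parent <- function(tree) {
  n <- max(tree$edge)
  p <- integer(n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# preorder depth and ancestor matrix for LCA queries (small trees)
species_index <- function(stree) {
  ntip <- length(stree$tip.label)
  n <- max(stree$edge)
  par <- tree_parent(stree)
  root <- ntip + 1L
  depth <- integer(n)
  ord <- rev(ape::postorder(stree))
  nodes <- c(root, stree$edge[ord, 2])
  for (e in ord) depth[stree$edge[e, 2]] <- depth[stree$edge[e, 1]] + 1L
  anc <- vector("list", n)
  for (v in seq_len(n)) {
    path <- v
    u <- v
    while (u != root) { u <- par[u]; path <- c(path, u) }
    anc[[v]] <- path
  }
  list(ntip = ntip, root = root, parent = par, depth = depth, anc = anc,
       children = tree_children(stree))
}

species_lca <- function(idx, a, b) {
  if (a == b) return(a)
  pa <- idx$anc[[a]]
  pb <- idx$anc[[b]]
  inter <- pa[pa %in% pb]
  inter[1]
}

# map gene tip label -> species via "species|gene" convention or a named map
gene_species_map <- function(tips, map = NULL) {
  if (is.null(map)) {
    sp <- sub("\\|.*$", "", tips)
  } else {
    sp <- unname(map[tips])
  }
  if (anyNA(sp)) stop("unmapped gene-tree tips: ",
                      paste(tips[is.na(sp)], collapse = ", "))
  setNames(sp, tips)
}

# LCA mapping of every gene-tree node onto the species tree (rooted trees)
lca_mapping <- function(gtree, sidx, sp_of_tip, stip_index) {
  ntip_g <- length(gtree$tip.label)
  n <- max(gtree$edge)
  M <- integer(n)
  for (i in seq_len(ntip_g)) M[i] <- stip_index[[sp_of_tip[[gtree$tip.label[i]]]]]
  ord <- ape::postorder(gtree)
  ch <- tree_children(gtree)
  for (e in ord) {
    v <- gtree$edge[e, 1]
    if (M[v] == 0L) {
      kids <- ch[[v]]
      m <- M[kids[1]]
      for (k in kids[-1]) m <- species_lca(sidx, m, M[k])
      M[v] <- m
    }
  }
  M
}

# rooted duplication-loss reconciliation by path-walking; returns per-species
# branch G and L (keyed by species child node id), copy number n at each
# species node, and total duplications/losses
reconcile_rooted <- function(gtree, stree, sidx, sp_of_tip, stip_index) {
  M <- lca_mapping(gtree, sidx, sp_of_tip, stip_index)
  gch <- tree_children(gtree)
  ntip_g <- length(gtree$tip.label)
  groot <- ntip_g + 1L
  nS <- max(stree$edge)
  G <- integer(nS); L <- integer(nS); n_at <- integer(nS)
  is_dup <- rep(FALSE, max(gtree$edge))
  # v is a duplication iff M[v] equals the mapping of at least one child
  for (v in (ntip_g + 1L):max(gtree$edge)) {
    kids <- gch[[v]]
    if (is.null(kids)) next
    is_dup[v] <- any(M[kids] == M[v])
  }
  # duplications: count on the species branch entering M[v] (virtual stem
  # branch when M[v] is the species root)
  for (v in which(is_dup)) G[M[v]] <- G[M[v]] + 1L
  # walk each gene edge (u, v): start species node depends on u's event type
  path_down <- function(from, to) {
    # species nodes from `from` down to `to` inclusive (from is an ancestor)
    path <- sidx$anc[[to]]
    i <- match(from, path)
    rev(path[seq_len(i)])
  }
  alive_add <- function(node) n_at[node] <<- n_at[node] + 1L
  for (e in seq_len(nrow(gtree$edge))) {
    u <- gtree$edge[e, 1]; v <- gtree$edge[e, 2]
    start <- if (is_dup[u]) M[u] else {
      # child of M[u] on the path toward M[v]
      p <- sidx$anc[[M[v]]]
      p[match(M[u], p) - 1L]
    }
    path <- path_down(start, M[v])
    for (k in seq_along(path)) {
      w <- path[k]
      # a duplication node splits just above its species node, so its
      # incoming lineage is not counted there (the children lineages are)
      if (k < length(path) || !is_dup[v]) alive_add(w)
      if (k < length(path)) {
        nxt <- path[k + 1L]
        for (cc in sidx$children[[w]])
          if (cc != nxt) L[cc] <- L[cc] + 1L
      }
    }
  }
  # the gene root lineage itself (one copy at M[root]), unless it is a
  # duplication (its children's edges already cover that point)
  if (!is_dup[groot]) alive_add(M[groot])
  # the family's origination is one gain on the branch entering its origin
  # node (kept on the virtual root stem when the origin is the species
  # root), so that n_desc = n_anc + G - L holds on the origin branch too
  G[M[groot]] <- G[M[groot]] + 1L
  list(M = M, is_dup = is_dup, G = G, L = L, n_at = n_at,
       duplications = sum(is_dup), losses = sum(L), origin = M[groot])
}

# resolve polytomies guided by the species tree (duplication-minimizing):
# children of a polytomy are grouped by the species-tree structure of their
# mappings; same-mapping children are joined last (as duplications)
resolve_polytomies <- function(gtree, stree, sp_of_tip, stip_index) {
  if (ape::is.binary.phylo(gtree)) return(gtree)
  sidx <- species_index(stree)
  nwk <- resolve_node_newick(gtree, length(gtree$tip.label) + 1L,
                             sidx, sp_of_tip, stip_index, tree_children(gtree))
  ape::read.tree(text = paste0(nwk, ";"))
}

resolve_node_newick <- function(gtree, v, sidx, sp_of_tip, stip_index, gch) {
  ntip <- length(gtree$tip.label)
  if (v <= ntip) return(gtree$tip.label[v])
  parts <- vapply(gch[[v]], function(k)
    resolve_node_newick(gtree, k, sidx, sp_of_tip, stip_index, gch), character(1))
  maps <- vapply(gch[[v]], function(k)
    subtree_map(gtree, k, sidx, sp_of_tip, stip_index, gch), integer(1))
  join <- function(a, b) paste0("(", a, ",", b, ")")
  # iteratively merge the pair whose species LCA is deepest
  while (length(parts) > 2L) {
    best <- NULL; bestd <- -1L
    for (i in seq_along(parts)[-length(parts)]) for (j in (i + 1L):length(parts)) {
      l <- species_lca(sidx, maps[i], maps[j])
      d <- sidx$depth[l]
      if (d > bestd) { bestd <- d; best <- c(i, j, l) }
    }
    i <- best[1]; j <- best[2]
    parts[i] <- join(parts[i], parts[j]); maps[i] <- best[3]
    parts <- parts[-j]; maps <- maps[-j]
  }
  if (length(parts) == 2L) join(parts[1], parts[2]) else parts[1]
}

subtree_map <- function(gtree, v, sidx, sp_of_tip, stip_index, gch) {
  ntip <- length(gtree$tip.label)
  if (v <= ntip) return(stip_index[[sp_of_tip[[gtree$tip.label[v]]]]])
  maps <- vapply(gch[[v]], function(k)
    subtree_map(gtree, k, sidx, sp_of_tip, stip_index, gch), integer(1))
  m <- maps[1]
  for (k in maps[-1]) m <- species_lca(sidx, m, k)
  m
}

#' Reconcile a gene tree with a species tree
#'
#' LCA-mapping duplication-loss parsimony. The gene tree may be unrooted or
#' arbitrarily rooted: every branch is tried as the root and the rooting
#' minimizing duplications + losses is kept (ties broken toward the
#' midpoint-most rooting). Polytomies are resolved before mapping with a
#' species-tree-guided, duplication-minimizing heuristic. Gene tips map to
#' species either through the `species|gene` naming convention or an explicit
#' map.
#'
#' @param gene_tree `phylo` or Newick string.
#' @param species_tree rooted `phylo` (tips = species).
#' @param map optional named character vector: gene tip -> species.
#' @param rooted treat `gene_tree` as already rooted and skip the rooting
#'   search (used e.g. for simulated histories whose true root is known).
#' @param max_root_candidates with unrooted input, the exhaustive per-edge
#'   rooting search is only attempted up to this many edges; larger trees
#'   fall back to midpoint rooting (with a warning).
#' @return list with class `fishor_reconciliation`: `events` (data.frame per
#'   species branch: branch, t, n_anc, G, L, n_desc), `n_at_node` (copy number
#'   at each species node, named), `duplications`, `losses`, `origin`
#'   (species node where the family originates; its appearance there is
#'   booked as one gain on the branch entering that node, so the per-branch
#'   ledger balances), `root_G` (gains on the virtual stem above the species
#'   root), `rooted_gene_tree`.
#' @export
reconcile <- function(gene_tree, species_tree, map = NULL, rooted = FALSE,
                      max_root_candidates = 80L) {
  if (is.character(gene_tree)) gene_tree <- ape::read.tree(text = gene_tree)
  stree <- species_tree
  sp_of_tip <- gene_species_map(gene_tree$tip.label, map)
  bad <- setdiff(unique(sp_of_tip), stree$tip.label)
  if (length(bad)) stop("gene-tree tips map to unknown species: ",
                        paste(bad, collapse = ", "))
  stip_index <- setNames(seq_along(stree$tip.label), stree$tip.label)
  sidx <- species_index(stree)
  ntip_g <- length(gene_tree$tip.label)
  if (rooted || ntip_g <= 2L) {
    candidates <- list(gene_tree)
  } else {
    ug <- ape::unroot(gene_tree)
    if (nrow(ug$edge) > max_root_candidates) {
      warning("gene tree too large for exhaustive rooting search; ",
              "using midpoint rooting")
      mp <- tryCatch(phangorn::midpoint(ug), error = function(err) NULL)
      candidates <- list(if (is.null(mp)) gene_tree else mp)
    } else {
      # root on each edge in turn
      candidates <- lapply(seq_len(nrow(ug$edge)), function(e) {
        child <- ug$edge[e, 2]
        if (child <= length(ug$tip.label)) {
          tryCatch(ape::root(ug, outgroup = ug$tip.label[child],
                             resolve.root = TRUE), error = function(err) NULL)
        } else {
          tips_below <- ape::extract.clade(ug, child)$tip.label
          tryCatch(ape::root(ug, outgroup = tips_below, resolve.root = TRUE),
                   error = function(err) NULL)
        }
      })
      candidates <- Filter(Negate(is.null), candidates)
      if (!length(candidates)) candidates <- list(gene_tree)
    }
  }
  best <- NULL
  for (cand in candidates) {
    cand2 <- resolve_polytomies(cand, stree, sp_of_tip, stip_index)
    rec <- reconcile_rooted(cand2, stree, sidx, sp_of_tip, stip_index)
    cost <- rec$duplications + rec$losses
    bal <- tree_height_imbalance(cand2)
    if (is.null(best) || cost < best$cost ||
        (cost == best$cost && bal < best$bal)) {
      best <- list(tree = cand2, rec = rec, cost = cost, bal = bal)
    }
  }
  rec <- best$rec
  node_key <- function(node) {
    if (node <= sidx$ntip) stree$tip.label[node] else paste0("node_", node)
  }
  edge_rows <- lapply(seq_len(nrow(stree$edge)), function(e) {
    ch <- stree$edge[e, 2]; par <- stree$edge[e, 1]
    data.frame(branch = node_key(ch),
               t = if (is.null(stree$edge.length)) NA_real_ else stree$edge.length[e],
               n_anc = rec$n_at[par], G = rec$G[ch], L = rec$L[ch],
               n_desc = rec$n_at[ch], stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, edge_rows)
  n_at <- setNames(rec$n_at, vapply(seq_len(max(stree$edge)), node_key, character(1)))
  structure(list(events = events, n_at_node = n_at,
                 duplications = rec$duplications, losses = rec$losses,
                 origin = node_key(rec$origin),
                 root_G = rec$G[sidx$root],
                 rooted_gene_tree = best$tree),
            class = "fishor_reconciliation")
}

# max root-to-tip minus min root-to-tip path length (midpoint-ness criterion
# for rooting ties); unit branch lengths when absent
tree_height_imbalance <- function(tree) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  max(d) - min(d)
}

#' Per-branch birth and death rates
#'
#' `b = G / (n_anc * t)` and `d = L / (n_anc * t)`, per gene per Myr, with
#' the ancestral copy number anchored at the parent node. Rates are
#' undefined (NA) when `n_anc` is 0.
#'
#' @param G,L gains and losses on the branch.
#' @param n_anc ancestral copy number (parent node).
#' @param t branch length in Myr (> 0).
#' @return list: `b`, `d` (NA when undefined).
#' @export
branch_rates <- function(G, L, n_anc, t) {
  if (any(t <= 0)) stop("branch length must be positive")
  if (any(n_anc < 0)) stop("n_anc must be non-negative")
  b <- ifelse(n_anc > 0, G / (n_anc * t), NA_real_)
  d <- ifelse(n_anc > 0, L / (n_anc * t), NA_real_)
  list(b = b, d = d)
}

#' Aggregate several reconciliations over one species tree
#'
#' Sums per-branch gains, losses and copy numbers across gene families (one
#' reconciliation per family) and derives per-branch rates.
#'
#' @param recs list of [reconcile()] results on the same species tree.
#' @return data.frame: branch, t, n_anc, G, L, n_desc, b, d.
#' @export
aggregate_reconciliations <- function(recs) {
  stopifnot(length(recs) >= 1L)
  ev <- recs[[1]]$events
  agg <- ev[c("branch", "t")]
  agg$n_anc <- 0L; agg$G <- 0L; agg$L <- 0L; agg$n_desc <- 0L
  for (r in recs) {
    e <- r$events
    i <- match(agg$branch, e$branch)
    agg$n_anc <- agg$n_anc + e$n_anc[i]
    agg$G <- agg$G + e$G[i]
    agg$L <- agg$L + e$L[i]
    agg$n_desc <- agg$n_desc + e$n_desc[i]
  }
  r <- branch_rates(agg$G, agg$L, agg$n_anc, agg$t)
  agg$b <- r$b; agg$d <- r$d
  agg
}

#' Summarize per-branch rates
#'
#' Mean birth and death rates over branches with `t >= min_branch_Myr` and
#' defined rates; flags the extreme branches.
#'
#' @param branch_table data.frame with columns branch, t, b, d (e.g.
#'   [aggregate_reconciliations()] output).
#' @param min_branch_Myr branches shorter than this are excluded (default 2).
#' @return list with class `fishor_rate_summary`: `mean_birth`, `mean_death`,
#'   `n_branches`, `excluded` (branch ids), `max_birth_branch`,
#'   `max_death_branch`, `table` (eligible branches).
#' @export
summarize_rates <- function(branch_table, min_branch_Myr = 2.0) {
  eligible <- branch_table$t >= min_branch_Myr &
    !is.na(branch_table$b) & !is.na(branch_table$d)
  tab <- branch_table[eligible, , drop = FALSE]
  excluded <- branch_table$branch[!eligible]
  if (!nrow(tab)) {
    return(structure(list(mean_birth = NA_real_, mean_death = NA_real_,
                          n_branches = 0L, excluded = excluded,
                          max_birth_branch = NA_character_,
                          max_death_branch = NA_character_,
                          table = tab, empty = TRUE),
                     class = "fishor_rate_summary"))
  }
  structure(list(mean_birth = mean(tab$b), mean_death = mean(tab$d),
                 n_branches = nrow(tab), excluded = excluded,
                 max_birth_branch = tab$branch[which.max(tab$b)],
                 max_death_branch = tab$branch[which.max(tab$d)],
                 table = tab, empty = FALSE),
            class = "fishor_rate_summary")
}

#' Loss-versus-pseudogene correlation sweep over branch-length thresholds
#'
#' For each maximum terminal-branch-length threshold, the Pearson correlation
#' between inferred losses `L` and observed non-functional gene counts over
#' terminal branches with `t <= threshold`.
#'
#' @param terminal_table data.frame with columns `t`, `L`, `n_pseudo`,
#'   `n_truncated`, `n_edge` (one row per terminal branch).
#' @param thresholds Myr thresholds (default 2..200).
#' @param variant which observed count to correlate: `pseudo_truncated`
#'   (default, pseudogenes + truncated), `pseudo`, `truncated`, or `edge`.
#' @return data.frame: threshold, n_branches, r (NA with fewer than 3
#'   branches or degenerate variance).
#' @export
loss_pseudo_sweep <- function(terminal_table,
                              thresholds = seq(2, 200, by = 2),
                              variant = c("pseudo_truncated", "pseudo",
                                          "truncated", "edge")) {
  variant <- match.arg(variant)
  if (nrow(terminal_table) < 3L) stop("need at least 3 terminal branches")
  y <- switch(variant,
              pseudo_truncated = terminal_table$n_pseudo + terminal_table$n_truncated,
              pseudo = terminal_table$n_pseudo,
              truncated = terminal_table$n_truncated,
              edge = terminal_table$n_edge)
  out <- lapply(thresholds, function(tau) {
    sel <- terminal_table$t <= tau
    n <- sum(sel)
    r <- NA_real_
    if (n >= 3L) {
      ls <- terminal_table$L[sel]; ys <- y[sel]
      if (sd(ls) > 0 && sd(ys) > 0) r <- cor(ls, ys)
    }
    data.frame(threshold = tau, n_branches = n, r = r)
  })
  do.call(rbind, out)
}
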