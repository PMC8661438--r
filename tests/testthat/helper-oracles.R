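# Independent oracles used to freeze expected values. These deliberately
# re-derive results with different code paths (plain R dynamic programming,
# exhaustive enumeration, ape utilities) from the implementations they check.

# plain-R affine-gap Smith-Waterman (three-matrix formulation)
oracle_sw <- function(q, s, mat, gap_open = 11, gap_ext = 1) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  m <- length(qv); n <- length(sv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, E[i - 1, j] - gap_ext)
    F[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, F[i, j - 1] - gap_ext)
    d <- H[i - 1, j - 1] + mat[qv[i - 1], sv[j - 1]]
    H[i, j] <- max(0, d, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# exhaustive minimum duplication-loss reconciliation: try every rooting of
# the (unrooted) gene tree; for a rooted binary gene tree the LCA mapping is
# provably optimal, with dups where a child shares the node's mapping and
# losses from the standard depth formula
oracle_min_dl <- function(gene_tree, species_tree) {
  if (is.character(gene_tree)) gene_tree <- ape::read.tree(text = gene_tree)
  rootings <- list()
  if (length(gene_tree$tip.label) <= 2) {
    rootings <- list(gene_tree)
  } else {
    ug <- ape::unroot(gene_tree)
    for (e in seq_len(nrow(ug$edge))) {
      child <- ug$edge[e, 2]
      tt <- if (child <= length(ug$tip.label)) ug$tip.label[child]
      else ape::extract.clade(ug, child)$tip.label
      rt <- tryCatch(ape::root(ug, outgroup = tt, resolve.root = TRUE),
                     error = function(err) NULL)
      if (!is.null(rt)) rootings[[length(rootings) + 1]] <- rt
    }
  }
  best <- Inf
  for (rt in rootings) {
    cost <- oracle_dl_rooted(rt, species_tree)
    if (cost < best) best <- cost
  }
  best
}

oracle_dl_rooted <- function(gt, st) {
  ntip <- length(gt$tip.label)
  sp <- sub("\\|.*$", "", gt$tip.label)
  stip <- setNames(seq_along(st$tip.label), st$tip.label)
  # node depths in species tree
  ns <- max(st$edge)
  depth <- integer(ns); depth[length(st$tip.label) + 1] <- 0
  for (e in seq_len(nrow(st$edge)))
    depth[st$edge[, 2]] <- 0  # fill below properly
  ord <- rev(ape::postorder(st))
  for (e in ord) depth[st$edge[e, 2]] <- depth[st$edge[e, 1]] + 1
  # LCA mapping via ape::mrca
  MR <- ape::mrca(st)
  lca2 <- function(a, b) {
    if (a == b) return(a)
    if (a <= length(st$tip.label) && b <= length(st$tip.label)) return(MR[a, b])
    # general: climb ancestors
    anc <- function(v) {
      out <- v
      while (v != length(st$tip.label) + 1) {
        v <- st$edge[st$edge[, 2] == v, 1]; out <- c(out, v)
      }
      out
    }
    ia <- anc(a); ib <- anc(b)
    ia[ia %in% ib][1]
  }
  ng <- max(gt$edge)
  M <- integer(ng)
  for (i in seq_len(ntip)) M[i] <- stip[[sp[i]]]
  for (e in ape::postorder(gt)) {
    v <- gt$edge[e, 1]
    if (M[v] == 0) {
      kids <- gt$edge[gt$edge[, 1] == v, 2]
      m <- M[kids[1]]
      for (k in kids[-1]) m <- lca2(m, M[k])
      M[v] <- m
    }
  }
  isdup <- rep(FALSE, ng)
  for (v in (ntip + 1):ng) {
    kids <- gt$edge[gt$edge[, 1] == v, 2]
    if (length(kids)) isdup[v] <- any(M[kids] == M[v])
  }
  losses <- 0
  for (e in seq_len(nrow(gt$edge))) {
    u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
    dd <- depth[M[v]] - depth[M[u]]
    losses <- losses + dd - 1 + as.integer(isdup[u])
  }
  sum(isdup) + losses
}

# exhaustive binary-character parsimony: minimum changes over all internal
# labelings of a rooted tree
oracle_fitch_min <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  internal <- (ntip + 1):nn
  s <- states[tree$tip.label]
  best <- Inf
  grid <- expand.grid(rep(list(0:1), length(internal)))
  for (g in seq_len(nrow(grid))) {
    lab <- numeric(nn)
    lab[seq_len(ntip)] <- s
    lab[internal] <- as.numeric(grid[g, ])
    ok <- TRUE
    ch <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- lab[tree$edge[e, 1]]; b <- lab[tree$edge[e, 2]]
      if (is.na(b)) next   # missing tip: free choice, handled by min below
      ch <- ch + as.integer(a != b)
    }
    # missing tips contribute 0 (choose parent's state)
    if (ok && ch < best) best <- ch
  }
  best
}

# brute-force marginal posteriors for the binary F81-type model: enumerate
# all internal labelings
oracle_ml_posteriors <- function(tree, states, rate, pi1) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  internal <- (ntip + 1):nn
  s <- states[tree$tip.label]
  P <- function(t) {
    e <- exp(-rate * t); p0 <- 1 - pi1
    matrix(c(p0 + pi1 * e, p0 - p0 * e, pi1 - pi1 * e, pi1 + p0 * e), 2, 2)
  }
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  grid <- expand.grid(rep(list(0:1), length(internal)))
  tot <- 0
  marg <- matrix(0, nn, 2)
  for (g in seq_len(nrow(grid))) {
    lab <- numeric(nn)
    lab[seq_len(ntip)] <- s
    lab[internal] <- as.numeric(grid[g, ])
    pr <- c(1 - pi1, pi1)[lab[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      a <- lab[tree$edge[e, 1]]; b <- lab[tree$edge[e, 2]]
      v <- tree$edge[e, 2]
      if (is.na(b)) next
      pr <- pr * P(elen[[as.character(v)]])[a + 1, b + 1]
    }
    tot <- tot + pr
    for (v in internal) marg[v, lab[v] + 1] <- marg[v, lab[v] + 1] + pr
  }
  list(posteriors = marg[internal, , drop = FALSE] / tot, loglik = log(tot))
}

# small shared fixtures
tiny_refs <- function(seed = 3) {
  make_reference_set(n_per_family = 2,
                     families = c("beta", "delta", "eta"), seed = seed)
}

tiny_plan <- function() {
  implant_plan(n_functional = 4, n_pseudo = 2, n_truncated = 1, n_edge = 1,
               scaffold_sizes = rep(9000L, 4))
}

random_gene_species_pair <- function(seed) {
  set.seed(seed)
  n_sp <- sample(2:4, 1)
  st <- ape::rtree(n_sp, tip.label = paste0("S", seq_len(n_sp)))
  n_g <- sample(3:6, 1)
  gt <- ape::rtree(n_g)
  gt$tip.label <- paste0(sample(st$tip.label, n_g, replace = TRUE),
                         "|g", seq_len(n_g))
  list(gene = gt, species = st)
}
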