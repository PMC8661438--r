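# Ancestral reconstruction of a binary character (multilamellar olfactory
# rosette presence) by parsimony (DOWNPASS / ACCTRAN / DELTRAN) and by
# maximum likelihood under a two-state CTMC with unequal stationary
# frequencies (binary F81-type model), with MAP and MPPA state selection.

#' Binarize a lamella count
#'
#' Three or more primary olfactory lamellae define a multilamellar rosette
#' (state 1); zero to two lamellae mean absence (state 0).
#'
#' @param lamella_count non-negative integer (NA = unknown).
#' @return 1, 0 or NA.
#' @export
binarize_lamellae <- function(lamella_count) {
  if (length(lamella_count) > 1L)
    return(vapply(lamella_count, binarize_lamellae, numeric(1)))
  if (is.na(lamella_count)) return(NA_real_)
  if (lamella_count < 0) stop("lamella count must be non-negative")
  as.numeric(lamella_count >= 3)
}

check_states <- function(tree, states) {
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips))
    stop("no state for tips: ", paste(missing_tips, collapse = ", "))
  s <- states[tree$tip.label]
  if (!all(s %in% c(0, 1) | is.na(s)))
    stop("states must be 0, 1 or NA (unknown)")
  s
}

#' Parsimony ancestral reconstruction of a binary trait
#'
#' Fitch/Sankoff optimization. `DOWNPASS` reports the full most-parsimonious
#' state set per node (possibly ambiguous); `ACCTRAN` resolves ambiguity by
#' placing changes as close to the root as possible, `DELTRAN` as close to
#' the tips as possible. The number of changes equals the Fitch minimum for
#' every method. Unknown tip states (NA) are treated as missing (either
#' state allowed).
#'
#' @param tree rooted `phylo` (binary or multifurcating).
#' @param states named vector of tip states (0/1/NA).
#' @param method `"DOWNPASS"`, `"ACCTRAN"` or `"DELTRAN"`.
#' @return list with class `fishor_reconstruction`: `method`, `changes`
#'   (minimum change count), `node_states` (data.frame: node, state set as
#'   `"0"`, `"1"` or `"0/1"`), `branch_changes` (data.frame of edges whose
#'   endpoints differ; empty for DOWNPASS where ambiguity remains).
#' @export
parsimony_reconstruct <- function(tree, states,
                                  method = c("DOWNPASS", "ACCTRAN", "DELTRAN")) {
  method <- match.arg(method)
  s <- check_states(tree, states)
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  root <- ntip + 1L
  ch <- tree_children(tree)
  # Sankoff costs: cost[v, k] = min changes in subtree of v given state k
  cost <- matrix(0, nn, 2)
  for (i in seq_len(ntip)) {
    if (is.na(s[i])) next
    cost[i, ] <- ifelse(c(0, 1) == s[i], 0, Inf)
  }
  ord <- ape::postorder(tree)
  done <- rep(FALSE, nn)
  for (e in ord) {
    v <- tree$edge[e, 1]
    if (done[v]) next
    done[v] <- TRUE
    for (k in 1:2) {
      tot <- 0
      for (w in ch[[v]])
        tot <- tot + min(cost[w, k], cost[w, 3 - k] + 1)
      cost[v, k] <- tot
    }
  }
  minchanges <- min(cost[root, ])
  # DOWNPASS: most-parsimonious state sets via per-node re-rooting cost
  # (state k is in the MPR set of v iff some MPR assigns k to v)
  # computed with up-costs: ucost[v, k] = min changes outside subtree of v
  par <- tree_parent(tree)
  ucost <- matrix(0, nn, 2)
  ordl <- rev(ord)
  for (e in ordl) {
    v <- tree$edge[e, 2]
    p <- tree$edge[e, 1]
    for (k in 1:2) {
      sib_tot <- 0
      for (w in ch[[p]]) if (w != v)
        sib_tot <- sib_tot + min(cost[w, 1] + (1 != k), cost[w, 2] + (2 != k))
      # parent takes state k (cost of switching at the edge handled here):
      # min over parent state kp of ucost[p,kp] + I(kp != k) + sibling costs
      best <- Inf
      for (kp in 1:2) {
        sib <- 0
        for (w in ch[[p]]) if (w != v)
          sib <- sib + min(cost[w, kp], cost[w, 3 - kp] + 1)
        val <- ucost[p, kp] + (kp != k) + sib
        if (val < best) best <- val
      }
      ucost[v, k] <- best
    }
  }
  mpr <- matrix(FALSE, nn, 2)
  for (v in seq_len(nn))
    for (k in 1:2)
      mpr[v, k] <- (cost[v, k] + ucost[v, k]) == minchanges
  setstr <- function(m) if (all(m)) "0/1" else if (m[1]) "0" else "1"
  if (method == "DOWNPASS") {
    ns <- data.frame(node = seq_len(nn),
                     state = vapply(seq_len(nn), function(v) setstr(mpr[v, ]),
                                    character(1)),
                     stringsAsFactors = FALSE)
    return(structure(list(method = method, changes = minchanges,
                          node_states = ns,
                          branch_changes = data.frame(parent = integer(),
                                                      child = integer())),
                     class = "fishor_reconstruction"))
  }
  # ACCTRAN / DELTRAN: preorder selection among change-minimal choices
  assign <- integer(nn)
  rs <- which(cost[root, ] == minchanges)
  assign[root] <- if (length(rs) == 1L) rs else {
    # ambiguous root: deterministic tie-break toward state 0
    1L
  }
  nodes_pre <- c(root, tree$edge[rev(ord), 2])
  nodes_pre <- nodes_pre[!duplicated(nodes_pre)]
  for (v in nodes_pre) {
    if (v == root) next
    p <- assign[par[v]]
    tot <- vapply(1:2, function(k) cost[v, k] + (k != p), numeric(1))
    opts <- which(tot == min(tot))
    assign[v] <- if (length(opts) == 1L) opts
    else if (method == "DELTRAN") p        # delay: keep parent state
    else opts[opts != p][1]                # accelerate: change now
  }
  st <- assign - 1L
  ns <- data.frame(node = seq_len(nn), state = as.character(st),
                   stringsAsFactors = FALSE)
  bc <- tree$edge[st[tree$edge[, 1]] != st[tree$edge[, 2]], , drop = FALSE]
  structure(list(method = method, changes = minchanges, node_states = ns,
                 branch_changes = data.frame(parent = bc[, 1], child = bc[, 2])),
            class = "fishor_reconstruction")
}

# transition probability matrix of the binary F81-type chain
p_matrix_binary <- function(rate, pi1, t) {
  e <- exp(-rate * t)
  p0 <- 1 - pi1
  matrix(c(p0 + pi1 * e, p0 - p0 * e,
           pi1 - pi1 * e, pi1 + p0 * e),
         2, 2, byrow = FALSE,
         dimnames = list(c("0", "1"), c("0", "1")))
  # [i, j] = P(j at time t | i at 0): column j
}

# log-likelihood by pruning; returns also per-node partial likelihoods
binary_pruning <- function(tree, s, rate, pi1) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  root <- ntip + 1L
  ch <- tree_children(tree)
  elen <- tree$edge.length
  emap <- integer(nn); emap[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  down <- matrix(1, nn, 2)  # P(data below v | state at v)
  for (i in seq_len(ntip)) if (!is.na(s[i])) down[i, ] <- as.numeric(c(0, 1) == s[i])
  ord <- ape::postorder(tree)
  done <- rep(FALSE, nn)
  for (e in ord) {
    v <- tree$edge[e, 1]
    if (done[v]) next
    done[v] <- TRUE
    for (w in ch[[v]]) {
      P <- p_matrix_binary(rate, pi1, elen[emap[w]])
      down[v, ] <- down[v, ] * as.vector(P %*% down[w, ])
    }
  }
  rootp <- c(1 - pi1, pi1)
  ll <- log(sum(rootp * down[root, ]))
  list(loglik = ll, down = down, root = root, children = ch,
       elen = elen, emap = emap)
}

#' Maximum-likelihood ancestral reconstruction of a binary trait
#'
#' Two-state continuous-time Markov chain with stationary frequencies
#' `(1-pi1, pi1)` and rate scaling `rate` (the binary analogue of the F81
#' model: the chain jumps at rate `rate` to a state drawn from the
#' stationary distribution). Both parameters are estimated by bounded ML
#' (multiple starts). Marginal posterior state probabilities are computed
#' for every internal node; states are selected by MAP, or by MPPA (all
#' states with posterior above `1/(K+1)`, K = 2 states, so both states are
#' kept when the posterior is close to even).
#'
#' @param tree rooted `phylo` with positive branch lengths (zero-length
#'   terminal branches are replaced by `epsilon` with a warning).
#' @param states named vector of tip states (0/1/NA for missing).
#' @param method `"ML-MAP"` or `"ML-MPPA"` (selection rule only; posteriors
#'   are identical).
#' @param rate,pi1 optional fixed parameter values (NULL = estimate).
#' @param epsilon replacement for non-positive branch lengths.
#' @return list with class `fishor_reconstruction`: `method`, `rate`, `pi1`,
#'   `loglik`, `posteriors` (matrix node x 2), `node_states` (data.frame:
#'   node, state, p0, p1).
#' @export
ml_reconstruct <- function(tree, states, method = c("ML-MAP", "ML-MPPA"),
                           rate = NULL, pi1 = NULL, epsilon = 1e-6) {
  method <- match.arg(method)
  s <- check_states(tree, states)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length <= 0)) {
    warning("non-positive branch lengths replaced by epsilon")
    tree$edge.length[tree$edge.length <= 0] <- epsilon
  }
  obj <- function(par) {
    r <- exp(par[1]); p <- 1 / (1 + exp(-par[2]))
    -binary_pruning(tree, s, r, p)$loglik
  }
  if (is.null(rate) || is.null(pi1)) {
    th <- sum(tree$edge.length)
    starts <- list(c(log(1 / th * 10), 0), c(log(1 / th), 1), c(log(1 / th * 50), -1),
                   c(log(1 / th * 200), 0), c(log(1 / th * 2), 2))
    best <- NULL
    for (st in starts) {
      o <- tryCatch(optim(st, obj, method = "Nelder-Mead",
                          control = list(maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    rate <- exp(best$par[1]); pi1 <- 1 / (1 + exp(-best$par[2]))
  }
  pr <- binary_pruning(tree, s, rate, pi1)
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  root <- pr$root
  par_of <- tree_parent(tree)
  # up[v, ]: P(data outside subtree of v | state at v) via preorder
  up <- matrix(1, nn, 2)
  rootp <- c(1 - pi1, pi1)
  up[root, ] <- rootp
  ord_pre <- rev(ape::postorder(tree))
  for (e in ord_pre) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    sibprod <- c(1, 1)
    for (w in pr$children[[p]]) if (w != v) {
      P <- p_matrix_binary(rate, pi1, pr$elen[pr$emap[w]])
      sibprod <- sibprod * as.vector(P %*% pr$down[w, ])
    }
    msg <- up[p, ] * sibprod
    P <- p_matrix_binary(rate, pi1, pr$elen[pr$emap[v]])
    up[v, ] <- as.vector(t(P) %*% msg)
  }
  post <- up * pr$down
  post <- post / rowSums(post)
  sel <- function(p) {
    if (method == "ML-MAP") as.character(which.max(p) - 1L)
    else {
      keep <- which(p >= 1 / 3) - 1L
      paste(keep, collapse = "/")
    }
  }
  ns <- data.frame(node = seq_len(nn),
                   state = apply(post, 1, sel),
                   p0 = post[, 1], p1 = post[, 2],
                   stringsAsFactors = FALSE)
  structure(list(method = method, rate = rate, pi1 = pi1,
                 loglik = pr$loglik, posteriors = post, node_states = ns),
            class = "fishor_reconstruction")
}

#' Copy a congeneric species' state to species lacking data
#'
#' The preprocessing helper for genus-level state transfer: species without a
#' recorded state receive the state of a designated congeneric donor.
#'
#' @param states named vector (0/1/NA).
#' @param donors named character vector: recipient species -> donor species.
#' @return updated states vector.
#' @export
transfer_congeneric_state <- function(states, donors) {
  for (sp in names(donors)) {
    if (!is.na(states[sp]) || !donors[[sp]] %in% names(states)) next
    states[sp] <- states[[donors[[sp]]]]
  }
  states
}
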