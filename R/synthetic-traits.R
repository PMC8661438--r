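# Trait simulation on a phylogeny: Brownian motion, Ornstein-Uhlenbeck,
# Pagel's lambda transform, and a binary Markov (Mk) chain.

#' Simulate tip traits under a phylogenetic model
#'
#' Continuous models draw tips from the multivariate normal distribution
#' implied by the model on the tree: `BM` with covariance `sigma2 * C`
#' (`C` = shared path lengths), `lambda` with off-diagonals of `C` scaled,
#' and `OU` with fixed-root covariance
#' `sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_ij))`.
#' The binary `Mk` model is simulated as a two-state continuous-time Markov
#' chain along branches with rates `q01`, `q10`.
#'
#' @param tree `phylo` with branch lengths.
#' @param model `"BM"`, `"OU"`, `"lambda"` or `"Mk"`.
#' @param params model parameters: `sigma2` (>0 for continuous; 0 allowed for
#'   the degenerate no-noise case), `root` (ancestral value/state), `alpha`
#'   (OU, >= 0), `lambda` (in `[0,1]`), `q01`/`q10` (Mk, >= 0).
#' @param seed integer seed (NULL to use the current RNG state).
#' @return named vector of tip values (numeric, or integer 0/1 for Mk).
#' @export
simulate_traits <- function(tree, model = c("BM", "OU", "lambda", "Mk"),
                            params = list(), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  tips <- tree$tip.label
  n <- length(tips)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  if (model == "Mk") {
    q01 <- p("q01", 0.1); q10 <- p("q10", 0.1)
    if (q01 < 0 || q10 < 0) stop("Mk rates must be non-negative")
    root <- p("root", NA)
    if (is.na(root)) {
      pi1 <- if (q01 + q10 > 0) q01 / (q01 + q10) else 0.5
      root <- rbinom(1, 1, pi1)
    }
    state <- integer(max(tree$edge))
    state[n + 1L] <- as.integer(root)
    ord <- rev(ape::postorder(tree))
    for (ei in ord) {
      par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
      t <- tree$edge.length[ei]
      s <- state[par]
      # exact 2-state transition probability
      tot <- q01 + q10
      if (tot == 0) { state[ch] <- s; next }
      pi1 <- q01 / tot
      e <- exp(-tot * t)
      p1 <- pi1 + (s - pi1) * e     # P(state 1 at child)
      state[ch] <- rbinom(1, 1, p1)
    }
    return(setNames(state[seq_len(n)], tips))
  }
  sigma2 <- p("sigma2", 1)
  root <- p("root", 0)
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  C <- ape::vcv(tree)
  C <- C[tips, tips]
  if (model == "lambda") {
    lam <- p("lambda", 1)
    if (lam < 0 || lam > 1) stop("lambda must be in [0, 1]")
    d <- diag(C)
    C <- lam * C
    diag(C) <- d
  } else if (model == "OU") {
    alpha <- p("alpha", 1)
    if (alpha < 0) stop("OU alpha must be non-negative")
    if (alpha > 0) {
      D <- ape::cophenetic.phylo(tree)[tips, tips]
      Tt <- C   # shared path lengths t_ij
      C <- exp(-alpha * D) * (1 - exp(-2 * alpha * Tt)) / (2 * alpha)
    }
  }
  V <- sigma2 * C
  if (sigma2 == 0) return(setNames(rep(root, n), tips))
  ch <- chol(V + diag(1e-12, n))
  setNames(root + as.vector(t(ch) %*% rnorm(n)), tips)
}
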