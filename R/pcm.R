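# Phylogenetic comparative statistics: Pagel's lambda, PGLS under BM / OU /
# lambda covariance, phylogenetic logistic regression, and plain group
# comparison.

# model-implied covariance (unit sigma2)
pcm_vcv <- function(tree, model, par) {
  C <- ape::vcv(tree)
  if (model == "BM") return(C)
  if (model == "lambda") {
    d <- diag(C)
    C <- par * C
    diag(C) <- d
    return(C)
  }
  if (model == "OU") {
    if (par <= 0) return(C)
    D <- ape::cophenetic.phylo(tree)
    D <- D[rownames(C), colnames(C)]
    return(exp(-par * D) * (1 - exp(-2 * par * C)) / (2 * par))
  }
  stop("unknown model: ", model)
}

# profiled Gaussian log-likelihood of y ~ X b with covariance s2 * V
gls_profile <- function(y, X, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Li <- backsolve(ch, diag(n), transpose = TRUE)   # t(L)^-1 rows
  yt <- Li %*% y
  Xt <- Li %*% X
  fit <- tryCatch(qr(Xt), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(X)) return(NULL)
  beta <- qr.coef(fit, yt)
  r <- yt - Xt %*% beta
  s2 <- sum(r^2) / n
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  XtX_inv <- chol2inv(qr.R(fit))
  list(beta = as.vector(beta), s2 = s2, loglik = ll,
       cov_unscaled = XtX_inv, Xt = Xt, yt = yt)
}

#' Pagel's lambda phylogenetic signal of a continuous trait
#'
#' ML over `lambda` in `[0, 1]` with mean and variance profiled out;
#' likelihood-ratio test against `lambda = 0` with a chi-squared(1)
#' reference.
#'
#' @param tree `phylo`.
#' @param trait named numeric vector (tips).
#' @return list with class `fishor_lambda`: `lambda`, `loglik`, `loglik0`,
#'   `p_value`, `undefined` (TRUE on star trees or zero-variance traits).
#' @export
pagel_lambda <- function(tree, trait) {
  y <- trait[tree$tip.label]
  if (anyNA(y)) {
    keep <- names(y)[!is.na(y)]
    tree <- ape::keep.tip(tree, keep)
    y <- y[tree$tip.label]
  }
  if (length(y) < 4) stop("need at least 4 tips with data")
  if (sd(y) == 0)
    return(structure(list(lambda = NA_real_, loglik = NA_real_,
                          loglik0 = NA_real_, p_value = NA_real_,
                          undefined = TRUE), class = "fishor_lambda"))
  C <- ape::vcv(tree)
  off <- C; diag(off) <- 0
  if (max(abs(off)) < 1e-12)
    return(structure(list(lambda = NA_real_, loglik = NA_real_,
                          loglik0 = NA_real_, p_value = NA_real_,
                          undefined = TRUE), class = "fishor_lambda"))
  X <- matrix(1, length(y), 1)
  ll_of <- function(lam) {
    f <- gls_profile(y, X, pcm_vcv(tree, "lambda", lam))
    if (is.null(f)) -Inf else f$loglik
  }
  opt <- optimize(ll_of, c(0, 1), maximum = TRUE, tol = 1e-8)
  # check the boundaries too
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll_of(0)), c(1, ll_of(1)))
  best <- cand[which.max(cand[, 2]), ]
  lrt <- 2 * (best[2] - cand[2, 2])
  structure(list(lambda = best[1], loglik = best[2], loglik0 = cand[2, 2],
                 p_value = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
                 undefined = FALSE), class = "fishor_lambda")
}

#' Phylogenetic generalized least squares regression
#'
#' GLS with residual covariance implied by Brownian motion (`BM`), an
#' Ornstein-Uhlenbeck process with fixed root (`OU`, parameter `alpha`), or
#' Pagel's `lambda` transform; the structure parameter is estimated by ML
#' jointly with the coefficients. Reports per-coefficient t-tests, the
#' sign-carrying correlation-scale effect size
#' (for the first predictor) r = sign(t) sqrt(t^2 / (t^2 + df)), and
#' `AIC = 2k - 2logL` counting coefficients, the residual variance and the
#' structure parameter.
#'
#' @param tree `phylo`.
#' @param formula model formula over columns of `data`.
#' @param data data.frame with row names (or a `species` column) matching
#'   tip labels.
#' @param model `"BM"`, `"OU"` or `"lambda"`.
#' @param fixed_par optional fixed structure parameter (lambda or alpha).
#' @return list with class `fishor_pgls`: `model`, coefficient table,
#'   `par` (lambda-hat or alpha-hat), `sigma2`, `loglik`, `AIC`, `r`,
#'   `p_value` (first predictor), `n`.
#' @export
pgls <- function(tree, formula, data, model = c("BM", "OU", "lambda"),
                 fixed_par = NULL) {
  model <- match.arg(model)
  if (!is.null(data$species)) rownames(data) <- data$species
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  keep <- rownames(mf)
  if (length(keep) < ncol(mf) + 2) stop("too few complete cases")
  tr <- ape::keep.tip(tree, keep)
  mf <- mf[tr$tip.label, , drop = FALSE]
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("singular design matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n <- length(y); k <- ncol(X)
  fit_for <- function(par) gls_profile(y, X, pcm_vcv(tr, model, par))
  if (model == "BM") {
    par_hat <- NA_real_
    fit <- fit_for(0)
    n_par <- k + 1
  } else if (!is.null(fixed_par)) {
    par_hat <- fixed_par
    fit <- fit_for(fixed_par)
    n_par <- k + 1
  } else if (model == "lambda") {
    ll <- function(lam) { f <- fit_for(lam); if (is.null(f)) -Inf else f$loglik }
    opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- rbind(c(opt$maximum, opt$objective), c(0, ll(0)), c(1, ll(1)))
    par_hat <- cand[which.max(cand[, 2]), 1]
    fit <- fit_for(par_hat)
    n_par <- k + 2
  } else {  # OU alpha on log scale, multiple starts
    th <- max(ape::vcv(tr))
    ll <- function(la) { f <- fit_for(exp(la)); if (is.null(f)) -Inf else f$loglik }
    best <- NULL
    for (st in log(c(0.1, 1, 10) / th)) {
      o <- optimize(ll, c(st - 6, st + 6), maximum = TRUE, tol = 1e-8)
      if (is.null(best) || o$objective > best$objective) best <- o
    }
    par_hat <- exp(best$maximum)
    fit <- fit_for(par_hat)
    n_par <- k + 2
  }
  if (is.null(fit)) stop("singular covariance; cannot fit")
  df <- n - k
  se <- sqrt(diag(fit$cov_unscaled) * fit$s2 * n / df)
  tval <- fit$beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  coefs <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                      t = tval, p = pval, stringsAsFactors = FALSE)
  slot <- if (k >= 2) 2L else 1L
  t1 <- tval[slot]
  r <- sign(t1) * sqrt(t1^2 / (t1^2 + df))
  structure(list(model = model, coefficients = coefs, par = par_hat,
                 sigma2 = fit$s2, loglik = fit$loglik,
                 AIC = 2 * n_par - 2 * fit$loglik,
                 r = r, p_value = pval[slot], n = n),
            class = "fishor_pgls")
}

#' @export
print.fishor_pgls <- function(x, ...) {
  cat(sprintf("PGLS (%s model), n = %d, logL = %.3f, AIC = %.2f\n",
              x$model, x$n, x$loglik, x$AIC))
  if (!is.na(x$par)) cat("structure parameter:", signif(x$par, 4), "\n")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("effect size r = %.3f\n", x$r))
  invisible(x)
}

#' Phylogenetic logistic regression for a binary trait
#'
#' Logistic regression whose residual dependence follows the phylogeny
#' (evolving-threshold flavour): quasi-likelihood estimating equations with
#' working correlation `R(s) = s * C + (1 - s) * I`, where `C` is the
#' tree correlation matrix and `s` in `[0, 1]` is the phylogenetic-signal
#' parameter, estimated by Gaussian pseudo-likelihood of the Pearson
#' residuals. At `s = 0` the estimates equal ordinary logistic regression
#' exactly.
#'
#' @param tree `phylo`.
#' @param formula model formula (binary response).
#' @param data data.frame (row names or `species` column = tips).
#' @param fixed_signal optional fixed `s`.
#' @param max_iter,tol outer-iteration control.
#' @return list with class `fishor_phyloglm`: coefficient table (estimate,
#'   se, z, p), `signal` (s-hat), `separation` flag, `n`, `iterations`.
#' @export
phylo_logistic <- function(tree, formula, data, fixed_signal = NULL,
                           max_iter = 25L, tol = 1e-8) {
  if (!is.null(data$species)) rownames(data) <- data$species
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  keep <- rownames(mf)
  tr <- ape::keep.tip(tree, keep)
  mf <- mf[tr$tip.label, , drop = FALSE]
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2) stop("both response classes must be present")
  X <- model.matrix(formula, mf)
  n <- length(y)
  const_cols <- apply(X[, -1, drop = FALSE], 2, function(col) sd(col) == 0)
  if (any(const_cols)) {
    # degenerate predictors: intercept-only fit, slope undefined
    g <- glm(y ~ 1, family = binomial())
    co <- data.frame(term = c("(Intercept)", names(const_cols)[const_cols]),
                     estimate = c(coef(g)[1], NA), se = c(sqrt(vcov(g)[1, 1]), NA),
                     z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(coefficients = co, signal = NA_real_,
                          separation = FALSE, n = n, iterations = 0L),
                     class = "fishor_phyloglm"))
  }
  C <- ape::vcv(tr)
  C <- C / max(diag(C))   # correlation-scale
  fit_beta <- function(s, beta) {
    R <- s * C + (1 - s) * diag(n)
    Rch <- chol(R + diag(1e-10, n))
    sep <- FALSE
    for (it in seq_len(50L)) {
      eta <- as.vector(X %*% beta)
      mu <- 1 / (1 + exp(-eta))
      w <- mu * (1 - mu)
      if (any(w < 1e-10)) { sep <- TRUE; w <- pmax(w, 1e-10) }
      A <- sqrt(w)
      # V = A R A ; estimating equation X' D V^-1 (y - mu) = 0, D = diag(w)
      Vi_r <- backsolve(Rch, backsolve(Rch, (y - mu) / A, transpose = TRUE))
      Vi_X <- backsolve(Rch, backsolve(Rch, X * A, transpose = TRUE))
      U <- crossprod(X * A, Vi_r)            # X' D V^-1 (y-mu)
      Iw <- crossprod(X * A, Vi_X)           # X' D V^-1 D X
      step <- tryCatch(solve(Iw, U), error = function(e) NULL)
      if (is.null(step)) { sep <- TRUE; break }
      beta_new <- beta + as.vector(step)
      if (max(abs(beta_new)) > 30) { sep <- TRUE }
      if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
      beta <- beta_new
    }
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    A <- sqrt(w)
    Vi_X <- backsolve(Rch, backsolve(Rch, X * A, transpose = TRUE))
    Iw <- crossprod(X * A, Vi_X)
    rp <- (y - mu) / A
    Vi_rp <- backsolve(Rch, backsolve(Rch, rp, transpose = TRUE))
    phi <- sum(rp * Vi_rp) / n
    pll <- -0.5 * (n * log(max(phi, 1e-12)) + 2 * sum(log(diag(Rch))))
    list(beta = beta, cov = tryCatch(solve(Iw) * max(phi, 1), error = function(e) NULL),
         pseudo_ll = pll, separation = sep)
  }
  beta0 <- coef(glm(y ~ X - 1, family = binomial()))
  if (any(!is.finite(beta0))) beta0 <- rep(0, ncol(X))
  if (!is.null(fixed_signal)) {
    s_hat <- fixed_signal
    fit <- fit_beta(s_hat, beta0)
  } else {
    obj <- function(s) fit_beta(s, beta0)$pseudo_ll
    opt <- optimize(obj, c(0, 0.99), maximum = TRUE, tol = 1e-4)
    cand <- rbind(c(opt$maximum, opt$objective), c(0, obj(0)))
    s_hat <- cand[which.max(cand[, 2]), 1]
    fit <- fit_beta(s_hat, beta0)
  }
  separation <- fit$separation
  if (separation) {
    # penalized fallback: shrink with a ridge on the working update
    fit$beta <- pmin(pmax(fit$beta, -30), 30)
  }
  se <- if (!is.null(fit$cov)) sqrt(pmax(diag(fit$cov), 0)) else rep(NA_real_, ncol(X))
  z <- fit$beta / se
  co <- data.frame(term = colnames(X), estimate = fit$beta, se = se, z = z,
                   p = 2 * pnorm(abs(z), lower.tail = FALSE),
                   stringsAsFactors = FALSE)
  structure(list(coefficients = co, signal = s_hat, separation = separation,
                 n = n, iterations = NA_integer_),
            class = "fishor_phyloglm")
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact p-value for combined n at most 20 without ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list: `statistic` (U for the first group), `p_value`, `exact`.
#' @export
group_compare <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
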