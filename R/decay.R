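# Forward simulation of pseudogene sequence decay until a translated
# homology search at the pseudogene-mining threshold no longer detects the
# original protein.

#' Parameters of the pseudogene decay process
#'
#' Rates are per site per generation. Defaults: substitutions at 1e-8 and
#' indels at 0.05e-8, indel lengths 1-9 bp with a decreasing (power-law-like)
#' length distribution `p(l) ~ l^-1.7`, transition/transversion ratio 2, and
#' detection at translated-search e-value 1e-20 -- the pseudogene-mining
#' threshold. Detection aligns the original translated protein against the
#' evolving DNA; the search space is m = protein length, n = current DNA
#' length / 3. The default `detect_mode = "tblastn"` scores the best
#' single-frame local alignment (tblastn HSP semantics: frame switches break
#' the alignment, stops score via the matrix's `*` column); `"chained"`
#' instead allows frame switches at `frameshift_penalty`, which keeps decayed
#' sequences detectable longer than a real tblastn run would.
#'
#' @param mu_sub substitutions per site per generation.
#' @param mu_indel indels per site per generation.
#' @param ts_tv transition/transversion ratio.
#' @param indel_len_probs probabilities for indel lengths 1..9 (normalised).
#' @param detect_evalue detection threshold; the sequence is undetectable
#'   once the e-value exceeds it.
#' @param ka [ka_params()].
#' @param gap_open,gap_extend,frameshift_penalty alignment scoring.
#' @param detect_mode `"tblastn"` (single-frame HSP detection) or
#'   `"chained"` (frameshift-aware chaining at `frameshift_penalty`).
#' @param max_generations guard against non-termination.
#' @param check_every recompute the alignment every k-th mutation. The
#'   default 1 is exact; internally an exact score lower bound skips provably
#'   unnecessary recomputations without changing the result.
#' @return list with class `fishor_decay_params`.
#' @export
decay_params <- function(mu_sub = 1e-8, mu_indel = 0.05e-8, ts_tv = 2,
                         indel_len_probs = (1:9)^-1.7 / sum((1:9)^-1.7),
                         detect_evalue = 1e-20, ka = ka_params(),
                         gap_open = 11L, gap_extend = 1L,
                         frameshift_penalty = 15L,
                         detect_mode = c("tblastn", "chained"),
                         max_generations = 1e10, check_every = 1L) {
  detect_mode <- match.arg(detect_mode)
  if (mu_sub < 0 || mu_indel < 0) stop("mutation rates must be non-negative")
  if (mu_sub + mu_indel == 0) stop("at least one mutation rate must be positive")
  if (ts_tv <= 0) stop("ts_tv must be positive")
  if (length(indel_len_probs) != 9L || any(indel_len_probs < 0))
    stop("indel_len_probs must be 9 non-negative values")
  if (abs(sum(indel_len_probs) - 1) > 1e-8)
    stop("indel_len_probs must sum to 1")
  structure(list(mu_sub = mu_sub, mu_indel = mu_indel, ts_tv = ts_tv,
                 indel_len_probs = indel_len_probs,
                 detect_evalue = detect_evalue, ka = ka,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 frameshift_penalty = as.integer(frameshift_penalty),
                 detect_mode = detect_mode,
                 max_generations = max_generations,
                 check_every = as.integer(check_every)),
            class = "fishor_decay_params")
}

#' Apply one mutation event to a sequence
#'
#' One event: a substitution with probability `mu_sub/(mu_sub+mu_indel)`
#' (site uniform; transition with probability `ts_tv/(ts_tv+1)`), otherwise
#' an indel (insertion or deletion equiprobable, length drawn from
#' `indel_len_probs`, position uniform). Uses the current RNG state.
#'
#' @param sequence DNA string (non-empty).
#' @param params [decay_params()].
#' @return list: `sequence`, `event` (`"substitution"`, `"insertion"`,
#'   `"deletion"`), `position` (0-based), `length` (for indels),
#'   `exhausted` (TRUE when the sequence shrank below one codon).
#' @export
mutate_step <- function(sequence, params = decay_params()) {
  v <- encode_dna(sequence)
  n <- length(v)
  if (n < 1L) stop("sequence must be non-empty")
  p_sub <- params$mu_sub / (params$mu_sub + params$mu_indel)
  if (runif(1) < p_sub) {
    pos <- sample.int(n, 1L)
    cur <- v[pos]
    if (cur > 3L) cur <- sample(0:3, 1L)
    ts <- runif(1) < params$ts_tv / (params$ts_tv + 1)
    v[pos] <- if (ts) bitwXor(cur, 2L)
    else if (runif(1) < 0.5) bitwXor(cur, 1L) else bitwXor(cur, 3L)
    ev <- list(event = "substitution", position = pos - 1L, length = 1L)
  } else {
    len <- sample.int(9L, 1L, prob = params$indel_len_probs)
    if (runif(1) < 0.5) {
      pos <- sample.int(n, 1L)
      v <- v[-(pos:min(n, pos + len - 1L))]
      ev <- list(event = "deletion", position = pos - 1L, length = len)
    } else {
      pos <- sample.int(n + 1L, 1L) - 1L
      v <- append(v, sample(0:3, len, replace = TRUE), after = pos)
      ev <- list(event = "insertion", position = pos, length = len)
    }
  }
  c(list(sequence = decode_dna(v), exhausted = length(v) < 3L), ev)
}

#' Generations until a decaying coding sequence is undetectable
#'
#' The intact CDS accumulates mutations with exponential waiting times at
#' total rate `(mu_sub + mu_indel) * length`; after every mutation the
#' original translated protein is aligned against the evolving DNA
#' (frameshift-aware, Karlin-Altschul statistics) and the run stops at the
#' first mutation whose e-value exceeds `detect_evalue`. Deterministic given
#' the RNG state (use `set.seed()`).
#'
#' @param cds intact OR coding sequence (>= 300 nt; terminal stop codon is
#'   dropped from the protein query).
#' @param params [decay_params()].
#' @return list with class `fishor_decay_outcome`: `generations`,
#'   `n_substitutions`, `n_indels`, `final_length`, `reason`
#'   (`"undetectable"`, `"sequence_lost"`, or `"max_generations"`).
#' @export
time_to_undetectable <- function(cds, params = decay_params()) {
  if (nchar(cds) < 300L) stop("cds must be at least 300 nt")
  mat <- substitution_matrix("BLOSUM62")
  alpha <- rownames(mat)
  prot <- sub("\\*$", "", translate(cds))
  fs_pen <- if (identical(params$detect_mode, "tblastn")) 100000L
  else params$frameshift_penalty
  res <- decay_replicate_cpp(
    encode_dna(cds), encode_protein(prot, alpha), mat, codon_aa_table(alpha),
    match("X", alpha) - 1L, params$gap_open, params$gap_extend,
    fs_pen, params$mu_sub, params$mu_indel, params$ts_tv,
    params$indel_len_probs, params$detect_evalue, params$ka$lambda,
    params$ka$K, params$max_generations, params$check_every,
    60L)  # max score change per single mutation (see vignette)
  structure(res, class = "fishor_decay_outcome")
}

#' Distribution of generations-to-undetectability
#'
#' Independent replicates of [time_to_undetectable()].
#'
#' @param cds intact OR coding sequence.
#' @param params [decay_params()].
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param survival_at generation grid for the survival curve (defaults to 20
#'   points spanning the observed range).
#' @return list with class `fishor_decay_distribution`: `outcomes`
#'   (data.frame), `median`, `q25`, `q75`, `survival` (data.frame:
#'   generations, fraction still detectable).
#' @export
decay_distribution <- function(cds, params = decay_params(), n_reps = 10000L,
                               seed = 1L, survival_at = NULL) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  set.seed(seed)
  gens <- numeric(n_reps); nsub <- numeric(n_reps); nind <- numeric(n_reps)
  flen <- numeric(n_reps); reason <- character(n_reps)
  for (i in seq_len(n_reps)) {
    o <- time_to_undetectable(cds, params)
    gens[i] <- o$generations; nsub[i] <- o$n_substitutions
    nind[i] <- o$n_indels; flen[i] <- o$final_length; reason[i] <- o$reason
  }
  if (is.null(survival_at))
    survival_at <- seq(0, max(gens), length.out = 21L)[-1]
  surv <- vapply(survival_at, function(g) mean(gens > g), numeric(1))
  structure(list(
    outcomes = data.frame(replicate = seq_len(n_reps), generations = gens,
                          n_substitutions = nsub, n_indels = nind,
                          final_length = flen, reason = reason,
                          stringsAsFactors = FALSE),
    median = median(gens), q25 = unname(quantile(gens, 0.25)),
    q75 = unname(quantile(gens, 0.75)),
    survival = data.frame(generations = survival_at, fraction = surv)),
    class = "fishor_decay_distribution")
}

#' @export
print.fishor_decay_distribution <- function(x, ...) {
  cat(sprintf("pseudogene decay: %d replicates, median %.3g generations (IQR %.3g-%.3g)\n",
              nrow(x$outcomes), x$median, x$q25, x$q75))
  invisible(x)
}
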