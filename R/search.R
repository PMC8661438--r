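# Translated local homology search with Karlin-Altschul statistics.
#
# This is the engine behind OR gene mining and the decay simulator: exact
# Smith-Waterman on six-frame translations, with e-values computed as
# E = K * m * n * exp(-lambda * S).  No BLAST heuristics (seeding, X-drop)
# are used; inputs are desk-scale.

#' Karlin-Altschul parameters
#'
#' Defaults are the published gapped BLOSUM62 (gap open 11 / extend 1)
#' values, reproducing tblastn-scale e-values.
#'
#' @param lambda scale parameter (per raw-score unit).
#' @param K search-space constant.
#' @return list with class `fishor_ka`.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K), class = "fishor_ka")
}

#' Translate DNA in a given frame
#'
#' Standard genetic code; codons containing `N` translate to `X`, stop codons
#' to `*`. Trailing partial codons are dropped.
#'
#' @param dna string over `A,C,G,T,N`.
#' @param frame 0, 1 or 2 (nucleotides skipped at the 5' end).
#' @param code genetic code id; only `"standard"` is supported.
#' @return protein string.
#' @export
translate <- function(dna, frame = 0L, code = "standard") {
  if (!identical(code, "standard")) stop("unsupported genetic code: ", code)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  v <- encode_dna(dna)
  if (frame > 0L) v <- v[-seq_len(frame)]
  translate_int(v)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman under an affine gap model: a gap of length k costs
#' `gap_open + k * gap_extend` (BLAST convention).
#'
#' @param query,subject protein strings.
#' @param matrix substitution matrix id (see [substitution_matrix()]).
#' @param gap_open,gap_extend gap penalties (positive).
#' @return list: `score`, query/subject spans (1-based inclusive), `nident`,
#'   `length` (alignment columns).
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11L, gap_extend = 1L) {
  mat <- substitution_matrix(matrix)
  q <- encode_protein(query, rownames(mat))
  s <- encode_protein(subject, rownames(mat))
  sw_align_cpp(q, s, mat, as.integer(gap_open), as.integer(gap_extend), TRUE)
}

#' Karlin-Altschul e-value of a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param raw_score non-negative raw score.
#' @param m query length (aa).
#' @param n database length (aa equivalents).
#' @param params [ka_params()].
#' @return e-value (numeric).
#' @export
evalue <- function(raw_score, m, n, params = ka_params()) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  if (any(raw_score < 0)) stop("raw_score must be non-negative")
  params$K * m * n * exp(-params$lambda * raw_score)
}

#' Bit score from a raw score
#' @inheritParams evalue
#' @return bit score.
#' @export
bit_score <- function(raw_score, params = ka_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

# minimum raw score with evalue <= emax
score_cutoff <- function(emax, m, n, params = ka_params()) {
  (log(params$K * m * n) - log(emax)) / params$lambda
}

# normalise genome-ish inputs to a named character vector of scaffolds
genome_scaffolds <- function(genome) {
  if (inherits(genome, "fishor_genome")) {
    s <- genome$scaffolds
  } else if (methods::is(genome, "DNAStringSet")) {
    s <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    s <- as.character(Biostrings::readDNAStringSet(genome))
    names(s) <- sub("\\s.*$", "", names(s))
  } else if (is.character(genome)) {
    s <- genome
  } else stop("unsupported genome input")
  if (length(s) && is.null(names(s))) names(s) <- paste0("scaffold_", seq_along(s))
  s
}

# queries -> named character vector of proteins
as_protein_set <- function(queries) {
  if (methods::is(queries, "AAStringSet")) queries <- as.character(queries)
  if (is.list(queries)) queries <- unlist(queries)
  if (!is.character(queries)) stop("queries must be protein strings")
  if (is.null(names(queries))) names(queries) <- paste0("query_", seq_along(queries))
  queries
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), strand = character(),
             frame = integer(), raw = integer(), bitscore = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' Six-frame translated search of a genome
#'
#' For every query protein, every scaffold is scanned on both strands in all
#' three frames with exact Smith-Waterman; locally optimal alignments with
#' e-value at or below `evalue_max` are reported. Subject coordinates are
#' 0-based half-open on the forward strand regardless of hit strand.
#' The database size for e-values is the total genome length / 3 (aa
#' equivalents), with no edge-length correction.
#'
#' @param queries protein strings (named) or an `AAStringSet`.
#' @param genome a [implant_genome()] result, `DNAStringSet`, named character
#'   vector of scaffolds, or FASTA path.
#' @param evalue_max e-value threshold (> 0).
#' @param params [ka_params()].
#' @param matrix,gap_open,gap_extend alignment scoring.
#' @param max_hsps_per_window cap on locally optimal alignments extracted per
#'   candidate window.
#' @param scan_queries indices (or names) of the queries used for window
#'   discovery; defaults to all queries. A reduced scan set (e.g. one
#'   representative per gene family, see [pick_scan_reps()]) speeds up the
#'   scan without changing reported hits as long as every target region is
#'   homologous to some representative.
#' @param best_query_only report, per candidate window, only the hits of the
#'   best-scoring query (what best-hit region extraction consumes); other
#'   queries are still scored to determine the winner.
#' @return data.frame of hits sorted by (scaffold, start); columns mirror
#'   BLAST outfmt-6 plus `strand`, `frame`, `raw`.
#' @export
search_translated <- function(queries, genome, evalue_max = 1e-10,
                              params = ka_params(), matrix = "BLOSUM62",
                              gap_open = 11L, gap_extend = 1L,
                              max_hsps_per_window = 25L, scan_queries = NULL,
                              best_query_only = FALSE) {
  if (evalue_max <= 0) stop("evalue_max must be positive")
  scaffolds <- genome_scaffolds(genome)
  queries <- as_protein_set(queries)
  if (!length(scaffolds) || !length(queries)) return(empty_hits())
  mat <- substitution_matrix(matrix)
  alpha <- rownames(mat)
  mask_code <- match("*", alpha) - 1L
  n_db <- max(1, sum(nchar(scaffolds)) / 3)
  out <- vector("list", 64L); oi <- 0L
  qenc <- lapply(queries, encode_protein, alphabet = alpha)
  if (is.null(scan_queries)) scan_queries <- seq_along(queries)
  if (is.character(scan_queries)) scan_queries <- match(scan_queries, names(queries))
  m_max <- max(lengths(qenc))
  for (sc in names(scaffolds)) {
    L <- nchar(scaffolds[[sc]])
    if (L < 3L) next
    fwd <- encode_dna(scaffolds[[sc]])
    for (strand in c("+", "-")) {
      v <- if (strand == "+") fwd else revcomp_int(fwd)
      for (frame in 0:2) {
        w <- if (frame > 0L) v[-seq_len(frame)] else v
        if (length(w) < 3L) next
        pstr <- translate_int(w)
        senc <- as.integer(match(strsplit(pstr, "")[[1]], alpha) - 1L)
        n_aa <- length(senc)
        # window discovery: gapless pre-filter over the scan queries with a
        # 50% margin; every query is then confirmed against each window with
        # full gapped Smith-Waterman
        js <- integer(0)
        for (qi in scan_queries) {
          m <- length(qenc[[qi]])
          cutoff <- max(1, score_cutoff(evalue_max, m, n_db, params))
          colbest <- sw_gapless_colmax_cpp(qenc[[qi]], senc, mat)
          js <- c(js, which(colbest >= 0.5 * cutoff))
        }
        js <- sort(unique(js))
        if (!length(js)) next
        brk <- which(diff(js) > m_max)
        wins_s <- c(js[1], js[brk + 1]); wins_e <- c(js[brk], js[length(js)])
        for (ci in seq_along(wins_s)) {
          w0 <- max(1L, wins_s[ci] - m_max - 10L)
          w1 <- min(n_aa, wins_e[ci] + 10L)
          emit_hit <- function(qi, al) {
            m <- length(qenc[[qi]])
            aas <- w0 + al$sstart - 1L; aae <- w0 + al$send - 1L
            nt_s <- frame + 3L * (aas - 1L)        # 0-based on strand seq
            nt_e <- frame + 3L * aae
            if (strand == "+") { fs <- nt_s; fe <- nt_e }
            else { fs <- L - nt_e; fe <- L - nt_s }
            oi <<- oi + 1L
            if (oi > length(out)) out <<- c(out, vector("list", length(out)))
            out[[oi]] <<- data.frame(
              qseqid = names(queries)[qi], sseqid = sc,
              pident = round(100 * al$nident / max(1L, al$length), 2),
              length = al$length, qstart = al$qstart, qend = al$qend,
              sstart = fs, send = fe, strand = strand, frame = frame,
              raw = al$score, bitscore = bit_score(al$score, params),
              evalue = evalue(al$score, m, n_db, params),
              stringsAsFactors = FALSE)
          }
          if (best_query_only && length(queries) > 1L) {
            # a window may span several loci; repeatedly pick the strongest
            # query on the not-yet-masked window, extract its alignments
            # (masking them), and continue until nothing passes the cutoff
            sub <- senc[w0:w1]
            for (round in seq_len(max_hsps_per_window)) {
              qscore <- vapply(seq_along(queries), function(k)
                max(sw_gapless_colmax_cpp(qenc[[k]], sub, mat)), integer(1))
              qi <- which.max(qscore)
              q <- qenc[[qi]]
              cutoff <- max(1, score_cutoff(evalue_max, length(q), n_db, params))
              emitted <- FALSE
              for (rep in seq_len(max_hsps_per_window)) {
                al <- sw_align_cpp(q, sub, mat, gap_open, gap_extend, TRUE)
                if (al$score < cutoff) break
                emit_hit(qi, al)
                sub[al$sstart:al$send] <- mask_code
                emitted <- TRUE
              }
              if (!emitted) break
            }
          } else {
            for (qi in seq_along(queries)) {
              q <- qenc[[qi]]
              cutoff <- max(1, score_cutoff(evalue_max, length(q), n_db, params))
              sub <- senc[w0:w1]
              for (rep in seq_len(max_hsps_per_window)) {
                al <- sw_align_cpp(q, sub, mat, gap_open, gap_extend, TRUE)
                if (al$score < cutoff) break
                emit_hit(qi, al)
                sub[al$sstart:al$send] <- mask_code
              }
            }
          }
        }
      }
    }
  }
  if (oi == 0L) return(empty_hits())
  hits <- do.call(rbind, out[seq_len(oi)])
  hits <- hits[order(hits$sseqid, hits$sstart, hits$send, -hits$raw), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# score-only protein-protein local alignment (no traceback)
local_align_score <- function(query, subject, matrix = "BLOSUM62",
                              gap_open = 11L, gap_extend = 1L) {
  mat <- substitution_matrix(matrix)
  sw_score_cpp(encode_protein(query, rownames(mat)),
               encode_protein(subject, rownames(mat)),
               mat, as.integer(gap_open), as.integer(gap_extend))
}

# score-only frameshift-aware alignment
frameshift_align_score <- function(reference, region, frameshift_penalty = 15L,
                                   matrix = "BLOSUM62", gap_open = 11L,
                                   gap_extend = 1L) {
  mat <- substitution_matrix(matrix)
  alpha <- rownames(mat)
  fs_score_cpp(encode_protein(reference, alpha), encode_dna(region), mat,
               codon_aa_table(alpha), match("X", alpha) - 1L,
               as.integer(gap_open), as.integer(gap_extend),
               as.integer(frameshift_penalty))
}

#' Pick scan representatives from a protein set
#'
#' Greedy cover: a query joins the representative set unless it already
#' aligns to a chosen representative with at least `min_frac` of its
#' self-score. Used to reduce window-discovery work in [search_translated()].
#'
#' @param proteins named protein strings.
#' @param min_frac coverage fraction (default 0.6).
#' @return integer indices of representatives.
#' @export
pick_scan_reps <- function(proteins, min_frac = 0.6) {
  proteins <- as_protein_set(proteins)
  reps <- integer(0)
  for (i in seq_along(proteins)) {
    covered <- FALSE
    selfs <- local_align(proteins[[i]], proteins[[i]])$score
    for (r in reps) {
      if (local_align(proteins[[i]], proteins[[r]])$score >= min_frac * selfs) {
        covered <- TRUE; break
      }
    }
    if (!covered) reps <- c(reps, i)
  }
  reps
}

#' Frameshift-aware alignment of a protein to a DNA region
#'
#' Best-scoring chained local alignment in which the reading frame may switch
#' at a fixed penalty; reports all in-frame stop codons and frame switches
#' inside the aligned region. This is the evidence engine used to classify
#' pseudogenes (at least one stop or frameshift) versus truncated genes.
#'
#' @param reference protein string.
#' @param region DNA string (>= 30 nt).
#' @param frameshift_penalty raw-score cost per frame switch (positive).
#' @param stop_handling `"matrix"` scores residues against stop codons via the
#'   matrix's `*` column; `"forbid"` makes stops unalignable, breaking
#'   alignments at every stop.
#' @param matrix,gap_open,gap_extend alignment scoring.
#' @return list with class `fishor_codon_alignment`: `score`, `qstart`/`qend`
#'   (aa, 1-based), `sstart`/`send` (nt, 0-based half-open in the region),
#'   `stops` (0-based nt starts of aligned in-frame stop codons),
#'   `frameshifts` (0-based nt positions of frame switches), and
#'   `stop_support`/`fs_support` (cumulative path score at each event, so
#'   left-flank support = value and right-flank support = score - value).
#' @export
frameshift_align <- function(reference, region, frameshift_penalty = 15L,
                             stop_handling = c("matrix", "forbid"),
                             matrix = "BLOSUM62", gap_open = 11L, gap_extend = 1L) {
  stop_handling <- match.arg(stop_handling)
  if (nchar(region) < 30L) stop("region must be at least 30 nt long")
  mat <- substitution_matrix(matrix)
  alpha <- rownames(mat)
  stop_row <- match("*", alpha) - 1L
  if (stop_handling == "forbid") {
    mat <- mat
    mat[, stop_row + 1L] <- -10000L
    mat[stop_row + 1L, ] <- -10000L
  }
  p <- encode_protein(reference, alpha)
  d <- encode_dna(region)
  res <- fs_align_cpp(p, d, mat, codon_aa_table(alpha), match("X", alpha) - 1L,
                      stop_row, as.integer(gap_open), as.integer(gap_extend),
                      as.integer(frameshift_penalty), TRUE)
  structure(res, class = "fishor_codon_alignment")
}
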