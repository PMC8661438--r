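# Two-pass OR gene mining and classification.
#
# Pass 1 searches the genome with an external OR reference set at e <= 1e-10,
# extends non-overlapping best-hit regions by 1 kb on both sides, extracts
# ORFs > 750 bp, validates them against OR references versus non-OR decoys,
# and removes exact duplicates: the functional repertoire.  Pass 2 re-searches
# the genome with the species' own functional set at e <= 1e-20; best hits not
# overlapping a functional locus are classified edge (< 30 bp from a scaffold
# end), pseudogene (>= 1 in-frame stop or frameshift) or truncated.

#' Genome QC record
#'
#' Size congruence compares the assembly to the expectation
#' `C-value x 0.978e9` bp; completeness applies a BUSCO-style threshold.
#'
#' @param assembly_size assembly length in bp.
#' @param c_value haploid genome size in pg (NA allowed: size flag unknown).
#' @param busco_complete fraction of complete core genes, in `[0,1]`.
#' @param size_ratio_max maximum tolerated obs/exp (or exp/obs) size ratio.
#' @param completeness_min completeness threshold (default 0.90).
#' @param species species id.
#' @return list with class `fishor_qc`: inputs plus `expected_size`,
#'   `size_congruent` (NA when `c_value` missing), `completeness_ok`, `pass`.
#' @export
qc_genome <- function(assembly_size, c_value, busco_complete,
                      size_ratio_max = 1.5, completeness_min = 0.90,
                      species = "unknown") {
  if (assembly_size <= 0) stop("assembly_size must be positive")
  if (busco_complete < 0 || busco_complete > 1) stop("busco_complete must be in [0,1]")
  if (!is.na(c_value) && c_value <= 0) stop("c_value must be positive")
  expected <- if (is.na(c_value)) NA_real_ else c_value * 0.978e9
  size_ok <- if (is.na(expected)) NA
  else max(assembly_size / expected, expected / assembly_size) <= size_ratio_max
  comp_ok <- busco_complete >= completeness_min
  structure(list(species = species, assembly_size = assembly_size,
                 c_value = c_value, expected_size = expected,
                 busco_complete = busco_complete,
                 size_congruent = size_ok, completeness_ok = comp_ok,
                 pass = isTRUE(size_ok) && comp_ok),
            class = "fishor_qc")
}

# merge intervals; `gap` > 0 additionally bridges near-adjacent intervals
# (e.g. HSPs split at a frameshift point)
merge_intervals <- function(start, end, gap = 0L) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] < me + gap) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Find candidate OR regions (pass 1)
#'
#' Overlapping hits are clustered per scaffold; within each cluster the
#' best-scoring query's HSP intervals are merged into the best-hit region
#' (strand-aware). Regions are then extended by `extension` bp on both sides
#' and clipped at scaffold bounds.
#'
#' @param genome genome input (see [search_translated()]).
#' @param or_refs reference proteins (named character / `AAStringSet` /
#'   [make_reference_set()] output).
#' @param evalue_max pass-1 e-value threshold.
#' @param extension bp added on both sides of each best-hit region.
#' @param ... passed to [search_translated()].
#' @return data.frame: scaffold, start, end (0-based half-open, extended),
#'   core_start, core_end (pre-extension), strand, best_query, score.
#' @export
find_candidate_regions <- function(genome, or_refs, evalue_max = 1e-10,
                                   extension = 1000L, ...) {
  scaffolds <- genome_scaffolds(genome)
  queries <- ref_proteins(or_refs)
  hits <- search_translated(queries, scaffolds, evalue_max = evalue_max,
                            scan_queries = pick_scan_reps(queries),
                            best_query_only = TRUE, ...)
  if (!nrow(hits)) return(empty_regions())
  out <- list()
  for (sc in unique(hits$sseqid)) {
    h <- hits[hits$sseqid == sc, , drop = FALSE]
    cl <- merge_intervals(h$sstart, h$send, gap = 90L)
    for (ri in seq_len(nrow(cl))) {
      inr <- h$sstart < cl[ri, "end"] & h$send > cl[ri, "start"]
      hh <- h[inr, , drop = FALSE]
      bq <- hh$qseqid[which.max(hh$raw)]
      bstrand <- hh$strand[which.max(hh$raw)]
      hb <- hh[hh$qseqid == bq & hh$strand == bstrand, , drop = FALSE]
      m <- merge_intervals(hb$sstart, hb$send, gap = 90L)
      L <- nchar(scaffolds[[sc]])
      for (mi in seq_len(nrow(m))) {
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc,
          start = max(0L, m[mi, "start"] - extension),
          end = min(L, m[mi, "end"] + extension),
          core_start = m[mi, "start"], core_end = m[mi, "end"],
          strand = bstrand, best_query = bq, score = max(hb$raw),
          stringsAsFactors = FALSE)
      }
    }
  }
  regions <- do.call(rbind, out)
  regions[order(regions$scaffold, regions$start), , drop = FALSE]
}

empty_regions <- function() {
  data.frame(scaffold = character(), start = integer(), end = integer(),
             core_start = integer(), core_end = integer(), strand = character(),
             best_query = character(), score = integer(), stringsAsFactors = FALSE)
}

ref_proteins <- function(refs) {
  if (inherits(refs, "fishor_refs")) return(refs$protein)
  as_protein_set(refs)
}

#' Extract ORFs from a region
#'
#' All maximal start-to-stop open reading frames strictly longer than
#' `min_len` nucleotides (stop codon included), on both strands and all three
#' frames. "Maximal" means the first in-frame ATG after the previous stop.
#'
#' @param region DNA string.
#' @param min_len minimum ORF length in nt (exclusive; default 750).
#' @return data.frame: start, end (0-based half-open, region coordinates on
#'   the forward strand), strand, frame, seq (coding strand sequence).
#' @export
extract_orfs <- function(region, min_len = 750L) {
  L <- nchar(region)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") region else revcomp(region)
    v <- encode_dna(s)
    for (frame in 0:2) {
      w <- if (frame > 0) v[-seq_len(frame)] else v
      prot <- translate_int(w)
      # segments between stops; ORF = first M .. stop inclusive
      stops <- gregexpr("\\*", prot)[[1]]
      if (stops[1] == -1) next
      seg_start <- 1L
      for (st in stops) {
        seg <- substr(prot, seg_start, st - 1L)
        mpos <- regexpr("M", seg)
        if (mpos > 0) {
          aa_start <- seg_start + as.integer(mpos) - 1L   # 1-based aa
          nt_start <- frame + 3L * (aa_start - 1L)        # 0-based, strand coords
          nt_end <- frame + 3L * st                       # includes stop codon
          if (nt_end - nt_start > min_len) {
            fs <- if (strand == "+") nt_start else L - nt_end
            fe <- if (strand == "+") nt_end else L - nt_start
            out[[length(out) + 1L]] <- data.frame(
              start = fs, end = fe, strand = strand, frame = frame,
              seq = substr(s, nt_start + 1L, nt_end),
              stringsAsFactors = FALSE)
          }
        }
        seg_start <- st + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), seq = character(), stringsAsFactors = FALSE))
  o <- do.call(rbind, out)
  o[order(o$start, o$end), , drop = FALSE]
}

#' Validate a candidate ORF as an olfactory receptor
#'
#' Accepts the ORF iff its best local alignment score against the OR
#' references strictly exceeds its best score against the non-OR decoy
#' receptors (ties are rejected, conservatively). This is the deterministic
#' surrogate for the tree-clustering inspection gate.
#'
#' @param orf ORF nucleotide sequence (or protein if `is_protein = TRUE`).
#' @param or_refs,decoy_refs protein sets (named) or a `fishor_refs` object
#'   for `or_refs`.
#' @param is_protein whether `orf` is already a protein.
#' @return list: `accepted`, `family` (best OR reference family, if
#'   resolvable), `best_or`, `best_decoy`, `best_ref`.
#' @export
validate_or <- function(orf, or_refs, decoy_refs = NULL, is_protein = FALSE) {
  if (!nzchar(orf)) stop("empty ORF")
  if (inherits(or_refs, "fishor_refs") && is.null(decoy_refs))
    decoy_refs <- or_refs$decoy_protein
  fam <- if (inherits(or_refs, "fishor_refs")) or_refs$family else NULL
  ors <- ref_proteins(or_refs)
  decoys <- as_protein_set(decoy_refs)
  if (!length(ors) || !length(decoys)) stop("reference sets must be non-empty")
  prot <- if (is_protein) orf else sub("\\*$", "", translate(orf))
  s_or <- vapply(ors, function(r) local_align_score(prot, r), integer(1))
  s_dec <- vapply(decoys, function(r) local_align_score(prot, r), integer(1))
  best_ref <- names(ors)[which.max(s_or)]
  list(accepted = max(s_or) > max(s_dec),
       family = if (!is.null(fam)) unname(fam[best_ref]) else NA_character_,
       best_or = max(s_or), best_decoy = max(s_dec), best_ref = best_ref)
}

#' Remove exact nucleotide duplicates
#'
#' One representative per identical sequence string; the representative is
#' the first record in (scaffold, start) order.
#'
#' @param records data.frame with columns `seq`, `scaffold`, `start`.
#' @return the deduplicated data.frame, with attribute `n_removed`.
#' @export
dedup_identical <- function(records) {
  if (!nrow(records)) return(records)
  o <- order(records$scaffold, records$start)
  r <- records[o, , drop = FALSE]
  keep <- !duplicated(r$seq)
  out <- r[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Classify a non-functional OR hit
#'
#' Precedence: (1) `edge` if the hit lies within `edge_distance` bp of a
#' scaffold end; else (2) `pseudogene` if the frameshift-aware alignment of
#' the best-matching protein against the hit region reports at least one
#' in-frame stop or frame switch; else (3) `truncated`.
#'
#' @param start,end hit interval (0-based half-open).
#' @param scaffold_len scaffold length.
#' @param region_seq hit region sequence (coding strand).
#' @param query_protein best-matching protein.
#' @param functional_intervals optional matrix/data.frame with start/end of
#'   functional loci on the same scaffold; overlap is a contract violation.
#' @param edge_distance bp threshold for the edge rule (default 30).
#' @param frameshift_penalty passed to [frameshift_align()].
#' @param core optional `c(start, end)` interval (0-based, region
#'   coordinates): only stops/frameshifts inside it count as evidence. Used
#'   when `region_seq` carries flanking padding whose chance alignment
#'   overhang must not produce false loss-of-function calls.
#' @param boundary_trim stops/frameshifts within this many nt of the aligned
#'   span's ends are ignored (default 15): terminal alignment excursions into
#'   non-coding flank mimic the X-drop trimming of heuristic search tools and
#'   otherwise cause false loss-of-function calls at fragment boundaries.
#' @param min_flank_score an event only counts if the aligned path carries at
#'   least this much raw score on each side of it (default 60, ~12 aligned
#'   residues): a credible lesion must be flanked by homology on both sides,
#'   otherwise a chance extension past a fragment boundary can place a "stop"
#'   in non-coding flank.
#' @return list: `class`, `n_stops`, `n_frameshifts`, `alignment`.
#' @export
classify_nonfunctional <- function(start, end, scaffold_len, region_seq,
                                   query_protein,
                                   functional_intervals = NULL,
                                   edge_distance = 30L,
                                   frameshift_penalty = 15L,
                                   core = NULL, boundary_trim = 15L,
                                   min_flank_score = 60L) {
  if (!is.null(functional_intervals) && nrow(functional_intervals)) {
    if (any(functional_intervals$start < end & functional_intervals$end > start))
      stop("hit overlaps a functional OR interval; discard it upstream")
  }
  if (min(start, scaffold_len - end) < edge_distance)
    return(list(class = "edge", n_stops = NA_integer_,
                n_frameshifts = NA_integer_, alignment = NULL))
  al <- frameshift_align(query_protein, region_seq,
                         frameshift_penalty = frameshift_penalty)
  stops <- al$stops; shifts <- al$frameshifts
  ssup <- al$stop_support; fsup <- al$fs_support
  keep_s <- pmin(ssup, al$score - ssup) >= min_flank_score
  keep_f <- pmin(fsup, al$score - fsup) >= min_flank_score
  stops <- stops[keep_s]; shifts <- shifts[keep_f]
  if (!is.null(core)) {
    stops <- stops[stops >= core[1] & stops < core[2]]
    shifts <- shifts[shifts >= core[1] & shifts < core[2]]
  }
  lo <- al$sstart + boundary_trim; hi <- al$send - boundary_trim
  stops <- stops[stops >= lo & stops < hi]
  shifts <- shifts[shifts >= lo & shifts < hi]
  ns <- length(stops); nf <- length(shifts)
  cls <- if (ns + nf >= 1L) "pseudogene" else "truncated"
  list(class = cls, n_stops = ns, n_frameshifts = nf, alignment = al)
}

#' Assign an OR family label
#'
#' The label of the best-scoring labeled reference: protein-level
#' Smith-Waterman for intact sequences, frameshift-aware translated scoring
#' for pseudogenes. Ties break by percent identity, then reference order.
#'
#' @param seq nucleotide sequence of the record.
#' @param refs `fishor_refs` (or named proteins plus `family` vector).
#' @param family optional named family vector when `refs` is a protein set.
#' @param pseudo use the frameshift-aware route.
#' @return family label, or `"unclassified"` if nothing scores above 0.
#' @export
assign_family <- function(seq, refs, family = NULL, pseudo = FALSE) {
  if (inherits(refs, "fishor_refs")) { family <- refs$family; prots <- refs$protein }
  else prots <- as_protein_set(refs)
  if (is.null(family)) stop("labeled references required")
  score <- numeric(length(prots)); pid <- numeric(length(prots))
  if (pseudo) {
    for (i in seq_along(prots)) {
      score[i] <- frameshift_align_score(prots[[i]], seq)
      pid[i] <- score[i] / max(1, nchar(prots[[i]]))
    }
  } else {
    prot <- sub("\\*$", "", translate(seq))
    for (i in seq_along(prots)) {
      al <- local_align(prot, prots[[i]])
      score[i] <- al$score
      pid[i] <- al$nident / max(1, al$length)
    }
  }
  if (max(score) <= 0) return("unclassified")
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[order(-pid[best], best)][1]
  unname(family[names(prots)[best]])
}

#' Annotate a genome: full two-pass OR repertoire
#'
#' @param genome genome input (see [search_translated()]).
#' @param refs [make_reference_set()] output (supplies OR and decoy sets).
#' @param evalue1 pass-1 threshold (external references; default 1e-10).
#' @param evalue2 pass-2 threshold (own functional set; default 1e-20).
#' @param min_orf minimum ORF length, exclusive (default 750).
#' @param extension region extension in bp (default 1000).
#' @param edge_distance edge rule distance (default 30).
#' @param min_hit_len minimum reportable pass-2 hit length in nt (default 60).
#' @param species species id for the repertoire.
#' @return list with class `fishor_repertoire`: `species`, `records`
#'   (data.frame: locus_id, scaffold, start, end, strand, class, family,
#'   seq, evidence columns), `class_counts`, `family_counts` (functional
#'   genes only).
#' @export
annotate_genome <- function(genome, refs, evalue1 = 1e-10, evalue2 = 1e-20,
                            min_orf = 750L, extension = 1000L,
                            edge_distance = 30L, min_hit_len = 60L,
                            species = "synthetic") {
  scaffolds <- genome_scaffolds(genome)
  # ---- pass 1: functional genes
  regions <- find_candidate_regions(scaffolds, refs, evalue_max = evalue1,
                                    extension = extension)
  fun <- list()
  if (nrow(regions)) for (ri in seq_len(nrow(regions))) {
    rs <- substr(scaffolds[[regions$scaffold[ri]]], regions$start[ri] + 1L,
                 regions$end[ri])
    orfs <- extract_orfs(rs, min_len = min_orf)
    if (!nrow(orfs)) next
    for (oi in seq_len(nrow(orfs))) {
      val <- validate_or(orfs$seq[oi], refs)
      if (!val$accepted) next
      fun[[length(fun) + 1L]] <- data.frame(
        scaffold = regions$scaffold[ri],
        start = regions$start[ri] + orfs$start[oi],
        end = regions$start[ri] + orfs$end[oi],
        strand = orfs$strand[oi], class = "functional",
        family = val$family, seq = orfs$seq[oi],
        score = val$best_or, n_stops = 0L, n_frameshifts = 0L,
        stringsAsFactors = FALSE)
    }
  }
  functional <- if (length(fun)) do.call(rbind, fun) else NULL
  if (!is.null(functional)) {
    functional <- functional[!duplicated(functional[c("scaffold", "start", "end", "strand")]), , drop = FALSE]
    functional <- dedup_identical(functional)
    # same-strand overlaps: keep best score
    keep <- rep(TRUE, nrow(functional))
    for (i in seq_len(nrow(functional))) for (j in seq_len(nrow(functional))) {
      if (i == j || !keep[i] || !keep[j]) next
      same <- functional$scaffold[i] == functional$scaffold[j] &&
        functional$strand[i] == functional$strand[j]
      if (same && functional$start[i] < functional$end[j] &&
          functional$end[i] > functional$start[j]) {
        drop <- if (functional$score[i] >= functional$score[j]) j else i
        keep[drop] <- FALSE
      }
    }
    functional <- functional[keep, , drop = FALSE]
  }
  # ---- pass 2: non-functional classes, queried with the species' own genes
  nonfun <- NULL
  if (!is.null(functional) && nrow(functional)) {
    queries <- setNames(
      vapply(functional$seq, function(s) sub("\\*$", "", translate(s)), character(1)),
      sprintf("self_%03d", seq_len(nrow(functional))))
    hits2 <- search_translated(queries, scaffolds, evalue_max = evalue2,
                               scan_queries = pick_scan_reps(queries),
                               best_query_only = TRUE)
    if (nrow(hits2)) {
      # drop hits overlapping any functional locus
      ov <- logical(nrow(hits2))
      for (i in seq_len(nrow(hits2))) {
        f <- functional[functional$scaffold == hits2$sseqid[i], , drop = FALSE]
        ov[i] <- any(f$start < hits2$send[i] & f$end > hits2$sstart[i])
      }
      hits2 <- hits2[!ov, , drop = FALSE]
    }
    nf <- list()
    if (nrow(hits2)) for (sc in unique(hits2$sseqid)) {
      h <- hits2[hits2$sseqid == sc, , drop = FALSE]
      cl <- merge_intervals(h$sstart, h$send, gap = 90L)
      L <- nchar(scaffolds[[sc]])
      for (ri in seq_len(nrow(cl))) {
        inr <- h$sstart < cl[ri, "end"] & h$send > cl[ri, "start"]
        hh <- h[inr, , drop = FALSE]
        b <- hh[which.max(hh$bitscore), , drop = FALSE]   # best tblastn match
        if (b$send - b$sstart < min_hit_len) next
        # classify on the merged-region span (padded) so LoF evidence beyond
        # the best HSP is visible
        pad <- 90L
        w0 <- max(0L, cl[ri, "start"] - pad); w1 <- min(L, cl[ri, "end"] + pad)
        seq_fwd <- substr(scaffolds[[sc]], w0 + 1L, w1)
        region_seq <- if (b$strand == "+") seq_fwd else revcomp(seq_fwd)
        qp <- queries[[b$qseqid]]
        core <- if (b$strand == "+") c(cl[ri, "start"] - w0, cl[ri, "end"] - w0)
        else c(w1 - cl[ri, "end"], w1 - cl[ri, "start"])
        res <- classify_nonfunctional(b$sstart, b$send, L, region_seq, qp,
                                      edge_distance = edge_distance,
                                      core = core)
        hseq_fwd <- substr(scaffolds[[sc]], cl[ri, "start"] + 1L, cl[ri, "end"])
        hseq <- if (b$strand == "+") hseq_fwd else revcomp(hseq_fwd)
        famlab <- assign_family(hseq, refs, pseudo = TRUE)
        nf[[length(nf) + 1L]] <- data.frame(
          scaffold = sc, start = cl[ri, "start"], end = cl[ri, "end"],
          strand = b$strand, class = res$class, family = famlab, seq = hseq,
          score = b$raw,
          n_stops = if (is.na(res$n_stops)) 0L else res$n_stops,
          n_frameshifts = if (is.na(res$n_frameshifts)) 0L else res$n_frameshifts,
          stringsAsFactors = FALSE)
      }
    }
    nonfun <- if (length(nf)) do.call(rbind, nf) else NULL
  }
  records <- rbind(functional, nonfun)
  if (is.null(records))
    records <- data.frame(scaffold = character(), start = integer(),
                          end = integer(), strand = character(),
                          class = character(), family = character(),
                          seq = character(), score = numeric(),
                          n_stops = integer(), n_frameshifts = integer(),
                          stringsAsFactors = FALSE)
  records <- records[order(records$scaffold, records$start), , drop = FALSE]
  if (nrow(records))
    records$locus_id <- sprintf("%s_OR_%03d", species, seq_len(nrow(records)))
  else records$locus_id <- character(0)
  rownames(records) <- NULL
  cls <- c("functional", "pseudogene", "truncated", "edge")
  class_counts <- setNames(vapply(cls, function(k) sum(records$class == k), integer(1)), cls)
  famf <- records$family[records$class == "functional"]
  family_counts <- if (length(famf)) table(famf) else table(character(0))
  structure(list(species = species, records = records,
                 class_counts = class_counts,
                 family_counts = family_counts),
            class = "fishor_repertoire")
}

#' @export
print.fishor_repertoire <- function(x, ...) {
  cat("OR repertoire for", x$species, "\n")
  print(x$class_counts)
  invisible(x)
}

#' Compare an annotated repertoire against a truth table
#'
#' A predicted record matches a truth locus if their intervals share at least
#' half of the shorter interval and the classes agree.
#'
#' @param repertoire [annotate_genome()] output.
#' @param truth truth table (from [implant_genome()]).
#' @return list: per-class `precision`, `recall`, and the match table.
#' @export
repertoire_eval <- function(repertoire, truth) {
  rec <- repertoire$records
  cls <- c("functional", "pseudogene", "truncated", "edge")
  precision <- recall <- setNames(rep(NA_real_, length(cls)), cls)
  used <- rep(FALSE, nrow(rec))
  match_cls <- rep(NA_character_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- which(!used & rec$scaffold == truth$scaffold[i] &
                    rec$start < truth$end[i] & rec$end > truth$start[i])
    if (!length(cand)) next
    ovl <- pmin(rec$end[cand], truth$end[i]) - pmax(rec$start[cand], truth$start[i])
    minlen <- pmin(rec$end[cand] - rec$start[cand], truth$end[i] - truth$start[i])
    cand <- cand[ovl >= 0.5 * minlen]
    if (!length(cand)) next
    j <- cand[which.max(ovl[seq_along(cand)])]
    used[j] <- TRUE
    match_cls[i] <- rec$class[j]
  }
  for (k in cls) {
    tp <- sum(match_cls == k & truth$class == k, na.rm = TRUE)
    npred <- sum(rec$class == k)
    ntrue <- sum(truth$class == k)
    precision[k] <- if (npred > 0) tp / npred else NA_real_
    recall[k] <- if (ntrue > 0) tp / ntrue else NA_real_
  }
  list(precision = precision, recall = recall,
       matches = data.frame(truth_class = truth$class, matched_as = match_cls,
                            stringsAsFactors = FALSE))
}
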