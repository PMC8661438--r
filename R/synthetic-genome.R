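# Synthetic OR reference sets and genomes with implanted loci.
#
# The generator states the world the annotation pipeline is validated
# against: intact OR coding sequences (~310 aa, start..stop, no internal
# stops), pseudogenes carrying introduced premature stops and/or frameshifts,
# truncated remnants, and scaffold-edge fragments, embedded in i.i.d.
# intergenic sequence at configurable GC.

or_families <- function() c("beta", "gamma", "delta", "epsilon", "zeta", "eta", "alpha")

random_cds_int <- function(n_aa) {
  # random codons excluding stops; ATG start, TAA stop appended
  stops <- c(48L, 50L, 56L)  # TAA, TAG, TGA as 16a+4b+c
  body <- integer(0)
  while (length(body) < (n_aa - 1L)) {
    cand <- sample.int(64L, n_aa, replace = TRUE) - 1L
    cand <- cand[!(cand %in% stops)]
    body <- c(body, cand)
  }
  body <- body[seq_len(n_aa - 1L)]
  c(0L, 3L, 2L, as.integer(rbind(body %/% 16L, (body %/% 4L) %% 4L, body %% 4L)),
    3L, 0L, 0L)
}

# Jukes-Cantor-style mutation of an encoded CDS at `divergence` expected
# substitutions per site, preserving the start codon, the terminal stop, and
# never introducing an internal stop (mutations creating one are redrawn).
mutate_cds_int <- function(cds, divergence) {
  n <- length(cds)
  p <- 0.75 * (1 - exp(-4 * divergence / 3))
  sites <- which(runif(n) < p)
  sites <- sites[sites > 3L & sites <= (n - 3L)]
  for (s in sites) {
    old <- cds[s]
    cand <- setdiff(0:3, old)
    new <- cand[sample.int(3L, 1L)]
    cds[s] <- new
    cod0 <- s - ((s - 1L) %% 3L)
    codon <- 16L * cds[cod0] + 4L * cds[cod0 + 1L] + cds[cod0 + 2L]
    if (codon %in% c(48L, 50L, 56L)) cds[s] <- old
  }
  cds
}

#' Generate a labeled synthetic OR reference set with decoys
#'
#' One random ancestral CDS per family; family members are derived from the
#' ancestor by Jukes-Cantor-style mutation at `divergence` substitutions per
#' site. Families descend from a common ancestor mutated at
#' `between_divergence`, so within-family identity exceeds between-family
#' identity. A disjoint set of unrelated receptor-like decoy CDS emulates the
#' non-OR outgroup references used to reject false OR calls.
#'
#' @param families character vector drawn from
#'   `beta, gamma, delta, epsilon, zeta, eta, alpha`.
#' @param n_per_family members per family.
#' @param protein_length protein length in aa (CDS is `3*(length+1)` nt with
#'   the stop codon).
#' @param divergence within-family divergence (subs/site).
#' @param between_divergence divergence separating family ancestors.
#' @param n_decoys number of decoy receptors.
#' @param seed integer seed.
#' @return list with class `fishor_refs`: `cds`, `protein` (named character
#'   vectors), `family` (named factor-like character), `decoy_cds`,
#'   `decoy_protein`.
#' @export
make_reference_set <- function(families = c("beta", "gamma", "delta",
                                            "epsilon", "zeta", "eta"),
                               n_per_family = 3L, protein_length = 310L,
                               divergence = 0.05, between_divergence = 0.4,
                               n_decoys = 7L, seed = 1L) {
  if (!length(families)) stop("family list must be non-empty")
  bad <- setdiff(families, or_families())
  if (length(bad)) stop("unknown OR families: ", paste(bad, collapse = ", "))
  if (divergence >= between_divergence)
    stop("within-family divergence must be smaller than between-family divergence")
  set.seed(seed)
  root <- random_cds_int(protein_length)
  cds <- character(0); fam <- character(0)
  for (f in families) {
    anc <- mutate_cds_int(root, between_divergence / 2)
    for (i in seq_len(n_per_family)) {
      m <- mutate_cds_int(anc, divergence)
      nm <- sprintf("or_%s_%d", f, i)
      cds[nm] <- decode_dna(m)
      fam[nm] <- f
    }
  }
  decoy_cds <- character(0)
  for (i in seq_len(n_decoys)) {
    decoy_cds[sprintf("decoy_%d", i)] <- decode_dna(random_cds_int(protein_length))
  }
  prot <- vapply(cds, function(s) sub("\\*$", "", translate(s)), character(1))
  dprot <- vapply(decoy_cds, function(s) sub("\\*$", "", translate(s)), character(1))
  structure(list(cds = cds, protein = prot, family = fam,
                 decoy_cds = decoy_cds, decoy_protein = dprot),
            class = "fishor_refs")
}

#' Plan for genome implantation
#'
#' @param n_functional,n_pseudo,n_truncated,n_edge locus counts per class.
#' @param scaffold_sizes integer vector of scaffold lengths (bp).
#' @param gc intergenic GC content.
#' @param divergence divergence of each implanted copy from its source
#'   reference (subs/site).
#' @param min_spacing minimum bp between implanted loci on a scaffold.
#' @param edge_distance implanted edge loci end within this many bp of a
#'   scaffold end (must be < 30 to satisfy the downstream edge rule).
#' @return list with class `fishor_plan`.
#' @export
implant_plan <- function(n_functional = 20L, n_pseudo = 5L, n_truncated = 3L,
                         n_edge = 2L, scaffold_sizes = rep(12000L, 8L),
                         gc = 0.42, divergence = 0.05, min_spacing = 1200L,
                         edge_distance = 10L) {
  counts <- c(n_functional, n_pseudo, n_truncated, n_edge)
  if (any(counts < 0)) stop("plan counts must be non-negative")
  if (any(scaffold_sizes < 100)) stop("scaffolds must be at least 100 bp")
  structure(list(n_functional = n_functional, n_pseudo = n_pseudo,
                 n_truncated = n_truncated, n_edge = n_edge,
                 scaffold_sizes = as.integer(scaffold_sizes), gc = gc,
                 divergence = divergence, min_spacing = as.integer(min_spacing),
                 edge_distance = as.integer(edge_distance)),
            class = "fishor_plan")
}

random_intergenic <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p) - 1L
}

# introduce a premature stop: mutate a codon in the middle 80% to TAA
add_premature_stop <- function(v) {
  n_cod <- length(v) %/% 3L
  lo <- max(2L, ceiling(0.1 * n_cod)); hi <- min(n_cod - 1L, floor(0.9 * n_cod))
  cod <- sample(seq(lo, hi), 1L)
  i <- 3L * (cod - 1L) + 1L
  v[i:(i + 2L)] <- c(3L, 0L, 0L)
  v
}

# single indel of length 1 or 2 at a uniform position in the middle 80%
add_frameshift <- function(v) {
  n <- length(v)
  pos <- sample(seq(max(4L, ceiling(0.1 * n)), floor(0.9 * n)), 1L)
  len <- sample(1:2, 1L)
  if (runif(1) < 0.5) {
    v <- v[-(pos:min(n, pos + len - 1L))]
  } else {
    v <- append(v, sample(0:3, len, replace = TRUE), after = pos)
  }
  v
}

# apply the LoF model, rejecting placements that leave an intact ORF longer
# than 750 nt within the isolated locus
pseudogenize <- function(v, lof) {
  v0 <- v
  for (try in 1:60) {
    v <- v0
    for (i in seq_len(lof$n_stops)) v <- add_premature_stop(v)
    for (i in seq_len(lof$n_frameshifts)) v <- add_frameshift(v)
    if (nrow(extract_orfs(decode_dna(v), min_len = 750L)) == 0L) break
  }
  v
}

#' Loss-of-function model for implanted pseudogenes
#' @param n_stops premature stop codons introduced per pseudogene.
#' @param n_frameshifts frameshifting indels (length 1-2) per pseudogene.
#' @return list with class `fishor_lof`.
#' @export
lof_model <- function(n_stops = 1L, n_frameshifts = 1L) {
  if (n_stops < 0 || n_frameshifts < 0) stop("LoF counts must be non-negative")
  if (n_stops + n_frameshifts < 1L) stop("a pseudogene needs at least one LoF mutation")
  structure(list(n_stops = as.integer(n_stops),
                 n_frameshifts = as.integer(n_frameshifts)), class = "fishor_lof")
}

#' Implant OR loci into a synthetic genome
#'
#' Builds scaffolds of i.i.d. intergenic sequence and implants mutated copies
#' of the reference CDS in four classes: `functional` (intact), `pseudogene`
#' (carrying introduced premature stops and/or frameshifts), `truncated`
#' (5'- or 3'-clipped, no LoF, mid-scaffold) and `edge` (clipped fragment
#' ending within `edge_distance` bp of a scaffold end). Strands are random.
#' The truth table records every placement with 0-based half-open
#' coordinates.
#'
#' @param refs [make_reference_set()] output.
#' @param plan [implant_plan()].
#' @param lof [lof_model()].
#' @param seed integer seed.
#' @return list with class `fishor_genome`: `scaffolds` (named character) and
#'   `truth` (data.frame: scaffold, start, end, strand, class, family,
#'   source, locus_id).
#' @export
implant_genome <- function(refs, plan = implant_plan(), lof = lof_model(),
                           seed = 1L) {
  stopifnot(inherits(refs, "fishor_refs"), inherits(plan, "fishor_plan"))
  set.seed(seed)
  n_total <- plan$n_functional + plan$n_pseudo + plan$n_truncated + plan$n_edge
  classes <- rep(c("functional", "pseudogene", "truncated", "edge"),
                 c(plan$n_functional, plan$n_pseudo, plan$n_truncated, plan$n_edge))
  scaffolds <- lapply(plan$scaffold_sizes, random_intergenic, gc = plan$gc)
  names(scaffolds) <- sprintf("scaffold_%02d", seq_along(scaffolds))
  # capacity: edge loci need a free scaffold end; interior loci need slots
  max_locus <- 3L * 320L
  slot <- plan$min_spacing + max_locus
  interior_cap <- sum(pmax(0L, (plan$scaffold_sizes - 2L * plan$min_spacing) %/% slot))
  edge_cap <- 2L * length(scaffolds)
  if (plan$n_edge > edge_cap || (n_total - plan$n_edge) > interior_cap)
    stop("implantation plan exceeds genome capacity")
  if (n_total == 0L)
    return(structure(list(scaffolds = vapply(scaffolds, decode_dna, character(1)),
                          truth = empty_truth()), class = "fishor_genome"))
  # interior slots: (scaffold, offset) pairs, spaced
  slots <- list()
  for (sc in names(scaffolds)) {
    L <- length(scaffolds[[sc]])
    starts <- seq(plan$min_spacing, L - plan$min_spacing - max_locus, by = slot)
    for (st in starts) slots[[length(slots) + 1L]] <- list(sc = sc, start = st)
  }
  ends <- list()
  for (sc in names(scaffolds)) {
    ends[[length(ends) + 1L]] <- list(sc = sc, side = "left")
    ends[[length(ends) + 1L]] <- list(sc = sc, side = "right")
  }
  slots <- slots[sample.int(length(slots))]
  ends <- ends[sample.int(length(ends))]
  truth <- vector("list", n_total)
  si <- 0L; ei <- 0L
  src_names <- names(refs$cds)
  fun_sources <- character(0)
  for (k in seq_len(n_total)) {
    cls <- classes[k]
    # non-functional loci are decayed copies of the genome's own repertoire:
    # draw their source among the genes implanted as functional (when any),
    # as pseudogenes arise from duplicates of genes present in that genome
    pool <- if (cls != "functional" && length(fun_sources)) fun_sources else src_names
    src <- pool[sample.int(length(pool), 1L)]
    if (cls == "functional") fun_sources <- unique(c(fun_sources, src))
    v <- mutate_cds_int(encode_dna(refs$cds[[src]]), plan$divergence)
    if (cls == "pseudogene") {
      v <- pseudogenize(v, lof)
    } else if (cls == "truncated") {
      keep <- runif(1, 0.35, 0.6)
      nk <- floor(keep * length(v))
      v <- if (runif(1) < 0.5) v[seq_len(nk)] else v[seq(length(v) - nk + 1L, length(v))]
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (cls == "edge") {
      keep <- runif(1, 0.35, 0.6)
      nk <- floor(keep * length(v))
      ei <- ei + 1L
      e <- ends[[ei]]
      L <- length(scaffolds[[e$sc]])
      if (e$side == "left") {
        # fragment starts edge_distance from the left end; keep the locus
        # oriented so the clipped side faces the scaffold end
        v <- v[seq(length(v) - nk + 1L, length(v))]
        start <- plan$edge_distance
        frag <- if (strand == "+") v else revcomp_int(v)
        scaffolds[[e$sc]][(start + 1L):(start + nk)] <- frag
        truth[[k]] <- data.frame(scaffold = e$sc, start = start, end = start + nk,
                                 strand = strand, class = cls,
                                 family = refs$family[[src]], source = src,
                                 stringsAsFactors = FALSE)
      } else {
        v <- v[seq_len(nk)]
        start <- L - plan$edge_distance - nk
        frag <- if (strand == "+") v else revcomp_int(v)
        scaffolds[[e$sc]][(start + 1L):(start + nk)] <- frag
        truth[[k]] <- data.frame(scaffold = e$sc, start = start, end = start + nk,
                                 strand = strand, class = cls,
                                 family = refs$family[[src]], source = src,
                                 stringsAsFactors = FALSE)
      }
    } else {
      si <- si + 1L
      if (si > length(slots)) stop("implantation plan exceeds genome capacity")
      s <- slots[[si]]
      start <- s$start + sample.int(200L, 1L)
      if (cls == "pseudogene") {
        # in-context check: the implanted locus together with its random
        # flanks must not host an ORF > 750 nt (flanks can extend an open
        # frame beyond the locus), else the locus would be annotated
        # functional; redraw the LoF placement if needed
        v_src <- mutate_cds_int(encode_dna(refs$cds[[src]]), plan$divergence)
        for (try in 1:60) {
          nk <- length(v)
          frag <- if (strand == "+") v else revcomp_int(v)
          ctx <- scaffolds[[s$sc]]
          ctx[(start + 1L):(start + nk)] <- frag
          w0 <- max(1L, start - 900L); w1 <- min(length(ctx), start + nk + 900L)
          orfs <- extract_orfs(decode_dna(ctx[w0:w1]), min_len = 750L)
          ok <- !nrow(orfs) ||
            !any(orfs$start + w0 - 1L < start + nk & orfs$end + w0 - 1L > start)
          if (ok) break
          v <- pseudogenize(v_src, lof)
        }
      }
      nk <- length(v)
      frag <- if (strand == "+") v else revcomp_int(v)
      scaffolds[[s$sc]][(start + 1L):(start + nk)] <- frag
      truth[[k]] <- data.frame(scaffold = s$sc, start = start, end = start + nk,
                               strand = strand, class = cls,
                               family = refs$family[[src]], source = src,
                               stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  truth$locus_id <- sprintf("locus_%03d", seq_len(nrow(truth)))
  truth <- truth[order(truth$scaffold, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(scaffolds = vapply(scaffolds, decode_dna, character(1)),
                 truth = truth), class = "fishor_genome")
}

empty_truth <- function() {
  data.frame(scaffold = character(), start = integer(), end = integer(),
             strand = character(), class = character(), family = character(),
             source = character(), locus_id = character(),
             stringsAsFactors = FALSE)
}

#' Write a synthetic genome to FASTA (80-column wrap) and its truth table to TSV
#' @param genome [implant_genome()] output.
#' @param fasta,truth_tsv output paths (NULL to skip either).
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, fasta = NULL, truth_tsv = NULL) {
  stopifnot(inherits(genome, "fishor_genome"))
  if (!is.null(fasta)) {
    con <- file(fasta, "w")
    on.exit(close(con), add = TRUE)
    for (nm in names(genome$scaffolds)) {
      writeLines(paste0(">", nm), con)
      s <- genome$scaffolds[[nm]]
      writeLines(substring(s, seq(1, nchar(s), 80), pmin(nchar(s), seq(80, nchar(s) + 79, 80))), con)
    }
  }
  if (!is.null(truth_tsv))
    write.table(genome$truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(genome)
}
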