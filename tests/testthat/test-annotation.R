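# OR mining and classification pipeline.

test_that("qc_genome applies the size and completeness rules", {
  q <- qc_genome(0.978e9, 1.0, 0.95, size_ratio_max = 1.5)
  expect_equal(q$expected_size, 0.978e9)
  expect_true(q$size_congruent); expect_true(q$completeness_ok); expect_true(q$pass)
  expect_false(qc_genome(1e9, 1.0, 0.89, 1.5)$completeness_ok)
  q3 <- qc_genome(3e9, 1.0, 0.99, 1.5)
  expect_false(q3$size_congruent); expect_false(q3$pass)
  qna <- qc_genome(1e9, NA, 0.95)
  expect_true(is.na(qna$size_congruent)); expect_true(qna$completeness_ok)
  expect_error(qc_genome(-1, 1, 0.5), "positive")
})

test_that("find_candidate_regions extends and clips best-hit regions", {
  refs <- tiny_refs()
  g <- implant_genome(refs, implant_plan(2, 0, 0, 0, scaffold_sizes = c(9000, 9000)),
                      seed = 12)
  reg <- find_candidate_regions(g, refs, extension = 1000)
  expect_gte(nrow(reg), 2)
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    cover <- reg$scaffold == tr$scaffold & reg$start <= max(0, tr$start - 950) &
      reg$end >= tr$end
    expect_true(any(cover))
  }
  expect_true(all(reg$start >= 0))
  expect_true(all(reg$end <= nchar(g$scaffolds[reg$scaffold])))
  # pre-extension core regions do not overlap
  for (sc in unique(reg$scaffold)) {
    rs <- reg[reg$scaffold == sc, ]
    if (nrow(rs) > 1) {
      rs <- rs[order(rs$core_start), ]
      expect_true(all(rs$core_start[-1] >= head(rs$core_end, -1)))
    }
  }
})

test_that("extract_orfs keeps maximal ORFs strictly above the threshold", {
  refs <- tiny_refs()
  cds <- refs$cds[[1]]
  pad5 <- strrep("C", 101); pad3 <- strrep("G", 100)
  region <- paste0(pad5, cds, pad3)
  orfs <- extract_orfs(region)
  hit <- orfs[orfs$start == 101 & orfs$end == 101 + 933, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$seq, cds)
  # reverse-complement: same ORF with strand flipped, mirrored coordinates
  orfs_rc <- extract_orfs(fishor:::revcomp(region))
  L <- nchar(region)
  hit_rc <- orfs_rc[orfs_rc$strand == "-" & orfs_rc$end == L - 101, ]
  expect_equal(nrow(hit_rc), 1L)
  expect_equal(hit_rc$seq, cds)
  # strictly larger than min_len: a 750-nt ORF is rejected, a 753-nt kept
  mk_orf <- function(n_aa) {
    paste0("ATG", strrep("GCT", n_aa - 1), "TAA")  # (n_aa+1)*3 nt with stop
  }
  exact750 <- mk_orf(249)   # 750 nt
  expect_equal(nrow(extract_orfs(paste0(strrep("C", 60), exact750,
                                        strrep("C", 60)))), 0L)
  just_over <- mk_orf(250)  # 753 nt
  expect_equal(nrow(extract_orfs(paste0(strrep("C", 60), just_over,
                                        strrep("C", 60)))), 1L)
})

test_that("validate_or accepts true ORs, rejects decoys and ties", {
  refs <- tiny_refs()
  v <- validate_or(refs$cds[[2]], refs)
  expect_true(v$accepted)
  expect_equal(v$family, unname(refs$family[names(refs$cds)[2]]))
  d <- validate_or(refs$decoy_cds[[1]], refs)
  expect_false(d$accepted)
  # tie: same sequence in both sets -> rejected (conservative)
  orp <- setNames(refs$protein[1], "x")
  tie <- validate_or(refs$protein[[1]], orp, orp, is_protein = TRUE)
  expect_false(tie$accepted)
  expect_error(validate_or("", refs), "empty")
})

test_that("dedup_identical removes exact duplicates only, keeping first", {
  rec <- data.frame(scaffold = c("s2", "s1", "s1"), start = c(5L, 10L, 99L),
                    seq = c("AAA", "AAA", "AAC"), stringsAsFactors = FALSE)
  out <- dedup_identical(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(out$scaffold[out$seq == "AAA"], "s1")  # first by (scaffold, start)
  one_off <- data.frame(scaffold = c("s1", "s1"), start = c(1L, 2L),
                        seq = c("AAA", "AAT"), stringsAsFactors = FALSE)
  expect_equal(nrow(dedup_identical(one_off)), 2L)
  expect_equal(nrow(dedup_identical(rec[0, ])), 0L)
})

test_that("classify_nonfunctional applies edge > pseudogene > truncated", {
  refs <- tiny_refs()
  prot <- refs$protein[[1]]
  cds <- refs$cds[[1]]
  # within 30 bp of the scaffold end -> edge, before any alignment evidence
  expect_equal(classify_nonfunctional(9660, 9990, 10000, cds, prot)$class, "edge")
  # mid-scaffold with an internal stop -> pseudogene with evidence
  v <- fishor:::encode_dna(cds); v[301:303] <- c(3L, 0L, 0L)
  res <- classify_nonfunctional(4000, 4933, 10000, fishor:::decode_dna(v), prot)
  expect_equal(res$class, "pseudogene")
  expect_equal(res$n_stops, 1L)
  # clipped intact fragment mid-scaffold -> truncated
  frag <- substr(cds, 101, 500)
  expect_equal(classify_nonfunctional(4000, 4400, 10000, frag, prot)$class,
               "truncated")
  fi <- data.frame(start = 4100L, end = 4500L)
  expect_error(classify_nonfunctional(4000, 4400, 10000, frag, prot,
                                      functional_intervals = fi),
               "overlaps a functional")
})

test_that("assign_family labels by best reference, frameshift-aware for pseudogenes", {
  refs <- tiny_refs()
  nm <- names(refs$cds)
  expect_equal(assign_family(refs$cds[[nm[3]]], refs),
               unname(refs$family[nm[3]]))
  # pseudogenized copy (1-bp deletion) still labelled with its family
  v <- fishor:::encode_dna(refs$cds[[nm[3]]])[-400]
  expect_equal(assign_family(fishor:::decode_dna(v), refs, pseudo = TRUE),
               unname(refs$family[nm[3]]))
  # nothing scores above zero -> unclassified (tiny custom reference set:
  # poly-proline query against a poly-tryptophan reference cannot reach a
  # positive local score)
  expect_equal(assign_family(strrep("CCA", 10),
                             setNames("WWWWWWWWWW", "r1"),
                             family = c(r1 = "beta")),
               "unclassified")
})

test_that("annotate_genome recovers a small implant exactly and is scaffold-order invariant", {
  refs <- tiny_refs()
  g <- implant_genome(refs, tiny_plan(), seed = 14)
  rep <- annotate_genome(g, refs)
  expect_equal(unname(rep$class_counts),
               unname(c(functional = 4L, pseudogene = 2L, truncated = 1L, edge = 1L)))
  ev <- repertoire_eval(rep, g$truth)
  expect_true(all(ev$precision == 1, na.rm = TRUE))
  expect_true(all(ev$recall == 1, na.rm = TRUE))
  # family labels of functional records match the implanted sources
  fun <- rep$records[rep$records$class == "functional", ]
  expect_true(all(fun$family %in% unique(refs$family)))
  # no same-strand overlap among functional records
  for (sc in unique(fun$scaffold)) {
    for (std in c("+", "-")) {
      f <- fun[fun$scaffold == sc & fun$strand == std, ]
      if (nrow(f) > 1) {
        f <- f[order(f$start), ]
        expect_true(all(f$start[-1] >= head(f$end, -1)))
      }
    }
  }
  # permuting scaffold order leaves tallies unchanged
  g2 <- g
  g2$scaffolds <- g2$scaffolds[rev(seq_along(g2$scaffolds))]
  rep2 <- annotate_genome(g2, refs)
  expect_equal(rep$class_counts, rep2$class_counts)
  # empty genome
  g0 <- implant_genome(refs, implant_plan(0, 0, 0, 0, scaffold_sizes = c(4000)),
                       seed = 2)
  expect_true(all(annotate_genome(g0, refs)$class_counts == 0))
})

test_that("round trip at divergence 0 recovers the truth table", {
  refs <- tiny_refs()
  plan <- tiny_plan(); plan$divergence <- 0
  g <- implant_genome(refs, plan, seed = 17)
  rep <- annotate_genome(g, refs)
  expect_equal(unname(rep$class_counts), c(4L, 2L, 1L, 1L))
  # functional coordinates recovered exactly
  fun <- rep$records[rep$records$class == "functional", ]
  tf <- g$truth[g$truth$class == "functional", ]
  key <- function(d) paste(d$scaffold, d$start, d$end, d$strand)
  expect_setequal(key(fun), key(tf))
})

test_that("pass-2 pseudogene recall depends on pass-1 queries (ablation)", {
  refs <- tiny_refs()
  g <- implant_genome(refs, tiny_plan(), seed = 25)
  # full pipeline finds the pseudogenes
  rep <- annotate_genome(g, refs)
  expect_gte(rep$class_counts[["pseudogene"]], 1)
  # ablation: a pass-2-style search against an unrelated query set at the
  # stringent threshold finds nothing where the pseudogenes lie
  unrelated <- setNames(refs$decoy_protein[1:3], c("d1", "d2", "d3"))
  h <- search_translated(unrelated, g, evalue_max = 1e-20)
  ps <- g$truth[g$truth$class == "pseudogene", ]
  hit_pseudo <- FALSE
  if (nrow(h)) for (i in seq_len(nrow(ps)))
    hit_pseudo <- hit_pseudo || any(h$sseqid == ps$scaffold[i] &
                                      h$sstart < ps$end[i] & h$send > ps$start[i])
  expect_false(hit_pseudo)
})

test_that("write_repertoire emits GFF3 with 1-based coordinates", {
  refs <- tiny_refs()
  g <- implant_genome(refs, implant_plan(1, 1, 0, 0, scaffold_sizes = c(9000, 9000)),
                      seed = 5)
  rep <- annotate_genome(g, refs)
  out <- tempfile()
  write_repertoire(rep, out)
  gff <- readLines(file.path(out, "or_loci.gff3"))
  expect_equal(gff[1], "##gff-version 3")
  body <- read.table(text = gff[-1], sep = "\t", stringsAsFactors = FALSE)
  expect_equal(body$V4, rep$records$start + 1L)
  expect_equal(body$V5, rep$records$end)
  expect_true(file.exists(file.path(out, "summary.tsv")))
})
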