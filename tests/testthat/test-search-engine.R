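# Translated search engine: translation, Smith-Waterman, Karlin-Altschul
# statistics, six-frame search, frameshift-aware alignment.

test_that("translate follows the standard code, frames, and N/stop rules", {
  expect_equal(translate("ATGAAATAA", 0), "MK*")
  expect_equal(translate("ATGAAATAA", 1), "*N")
  expect_equal(translate("ATGNNN", 0), "MX")
  expect_error(translate("ATGQ", 0), "invalid characters")
  expect_error(translate("ATG", 3), "frame")
})

test_that("local_align matches a plain-R DP oracle and is symmetric", {
  mat <- substitution_matrix("BLOSUM62")
  # self-alignment equals the sum of diagonal entries
  q <- "MKWVTFISLLFLFSSAYSRG"
  self <- sum(diag(mat)[match(strsplit(q, "")[[1]], rownames(mat))])
  expect_equal(local_align(q, q)$score, self)
  set.seed(7)
  aas <- setdiff(rownames(mat), c("B", "Z", "X", "*"))
  for (i in 1:12) {
    a <- paste(sample(aas, sample(6:14, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(6:14, 1), replace = TRUE), collapse = "")
    expect_equal(local_align(a, b)$score, oracle_sw(a, b, mat))
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
  expect_error(local_align("MK", "MK", matrix = "NOPE"), "unknown substitution")
})

test_that("evalue follows the closed form and its monotonicity laws", {
  p <- ka_params()
  s_one <- log(p$K * 310 * 1e6) / p$lambda
  expect_equal(evalue(s_one, 310, 1e6), 1.0, tolerance = 1e-12)
  expect_equal(evalue(100, 310, 2e6), 2 * evalue(100, 310, 1e6))
  expect_equal(evalue(100, 310, 1e6, p), 0.041 * 310 * 1e6 * exp(-26.7))
  expect_lt(evalue(101, 310, 1e6), evalue(100, 310, 1e6))
  expect_error(evalue(10, 0, 1), "positive")
  # bit score relation is exact
  expect_equal(bit_score(100), (0.267 * 100 - log(0.041)) / log(2))
})

test_that("search_translated finds implanted loci and respects strand flips", {
  refs <- tiny_refs()
  g <- implant_genome(refs, tiny_plan(), seed = 21)
  fun <- g$truth[g$truth$class == "functional", ][1, ]
  q <- setNames(refs$protein[fun$source], "q1")
  hits <- search_translated(q, g, evalue_max = 1e-10)
  cover <- hits$sseqid == fun$scaffold & hits$sstart <= fun$start + 30 &
    hits$send >= fun$end - 30
  expect_true(any(cover))
  hit <- hits[which(cover)[1], ]
  expect_equal(hit$strand, fun$strand)
  # reverse-complement the scaffold: strand flips, coordinates map x -> L - x
  g2 <- g
  L <- nchar(g2$scaffolds[[fun$scaffold]])
  g2$scaffolds[[fun$scaffold]] <- fishor:::revcomp(g2$scaffolds[[fun$scaffold]])
  hits2 <- search_translated(q, g2$scaffolds[fun$scaffold], evalue_max = 1e-10)
  h2 <- hits2[which.max(hits2$raw), ]
  h1 <- hits[hits$sseqid == fun$scaffold, ][which.max(hits[hits$sseqid == fun$scaffold, ]$raw), ]
  expect_equal(h2$sstart, L - h1$send)
  expect_equal(h2$send, L - h1$sstart)
  expect_true(h2$strand != h1$strand)
  # empty genome: empty result, not an error
  expect_equal(nrow(search_translated(q, character(0))), 0L)
})

test_that("search e-values are calibrated: random genomes give no hits", {
  refs <- tiny_refs()
  q <- refs$protein[1:2]
  n_hit <- 0L
  for (s in 1:10) {
    set.seed(1000 + s)
    genome <- c(sc1 = fishor:::decode_dna(fishor:::random_intergenic(1e5, 0.42)))
    h <- search_translated(q, genome, evalue_max = 1e-10)
    n_hit <- n_hit + as.integer(nrow(h) > 0)
  }
  expect_lte(n_hit, 1L)   # >= 99% of seeds hit-free at desk scale
})

test_that("frameshift_align reports stops and frame switches faithfully", {
  refs <- tiny_refs()
  cds <- refs$cds[[1]]
  prot <- refs$protein[[1]]
  id <- frameshift_align(prot, cds)
  expect_equal(length(id$stops), 0L)       # terminal stop is outside m residues
  expect_equal(length(id$frameshifts), 0L)
  # one internal codon -> TAA
  v <- fishor:::encode_dna(cds)
  v[301:303] <- c(3L, 0L, 0L)
  wstop <- frameshift_align(prot, fishor:::decode_dna(v))
  expect_equal(length(wstop$stops), 1L)
  expect_equal(wstop$stops[1], 300)
  expect_equal(length(wstop$frameshifts), 0L)
  # 1-bp deletion mid-sequence -> exactly one switch within +-3 codons
  v2 <- fishor:::encode_dna(cds)[-450]
  wdel <- frameshift_align(prot, fishor:::decode_dna(v2))
  expect_equal(length(wdel$frameshifts), 1L)
  expect_lt(abs(wdel$frameshifts[1] - 450), 10)
  expect_error(frameshift_align(prot, "ATGAAA"), "at least 30")
})

test_that("pick_scan_reps covers every query", {
  refs <- tiny_refs()
  reps <- pick_scan_reps(refs$protein)
  expect_true(length(reps) >= 1 && length(reps) <= length(refs$protein))
  for (i in seq_along(refs$protein)) {
    selfs <- local_align(refs$protein[[i]], refs$protein[[i]])$score
    covered <- any(vapply(reps, function(r)
      local_align(refs$protein[[i]], refs$protein[[r]])$score >= 0.6 * selfs,
      logical(1)))
    expect_true(covered)
  }
})
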