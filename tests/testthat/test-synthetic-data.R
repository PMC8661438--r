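# Synthetic-data generators: species trees, gene histories, reference sets,
# genome implantation, trait simulation.

test_that("simulate_species_tree is ultrametric, scaled and deterministic", {
  t2 <- simulate_species_tree(2, 100, seed = 1)
  expect_equal(sort(unname(t2$edge.length)), c(100, 100))
  t8 <- simulate_species_tree(8, 250, seed = 7)
  depths <- ape::node.depth.edgelength(t8)[1:8]
  expect_true(all(abs(depths - 250) < 1e-9))
  expect_identical(ape::write.tree(simulate_species_tree(6, 50, seed = 42)),
                   ape::write.tree(simulate_species_tree(6, 50, seed = 42)))
  expect_error(simulate_species_tree(1, 100), "at least 2")
  expect_error(simulate_species_tree(4, -1), "positive")
})

test_that("simulate_gene_history keeps the ledger and honours degenerate rates", {
  tr <- simulate_species_tree(6, 120, seed = 3)
  h0 <- simulate_gene_history(tr, 10, 0, 0, seed = 5)
  expect_true(all(vapply(h0$tips, length, integer(1)) == 10))
  expect_true(all(h0$events$G == 0) && all(h0$events$L == 0))
  # pure death: all tips empty with probability ~ 1 for deep trees
  hd <- simulate_gene_history(tr, 5, 0, 10, seed = 6)
  expect_true(all(vapply(hd$tips, length, integer(1)) == 0))
  expect_true(is.na(hd$gene_tree))
  # conservation on every branch, several seeds
  for (s in 1:5) {
    h <- simulate_gene_history(tr, 8, 0.01, 0.01, seed = s)
    expect_true(all(h$events$n_desc == h$events$n_anc + h$events$G - h$events$L))
    expect_true(all(h$events$n_desc >= 0))
    # gene-tree tips match the inventory
    if (!is.na(h$gene_tree)) {
      gt <- ape::read.tree(text = h$gene_tree)
      expect_equal(length(gt$tip.label), sum(vapply(h$tips, length, integer(1))))
    }
  }
})

test_that("expected copy number is conserved when birth equals death", {
  # Monte-Carlo oracle: E[n(t)] = n0 for a linear birth-death process with
  # birth == death; two-tip tree, t = 100, rates 0.007
  tr <- simulate_species_tree(2, 100, seed = 1)
  set.seed(11)
  means <- replicate(200, {
    h <- simulate_gene_history(tr, 100, 0.007, 0.007)
    mean(vapply(h$tips, length, integer(1)))
  })
  expect_lt(abs(mean(means) - 100) / 100, 0.10)
})

test_that("make_reference_set builds valid labeled CDS with separated families", {
  refs <- make_reference_set(families = "delta", n_per_family = 3, seed = 2)
  expect_equal(unname(nchar(refs$cds)), rep(933L, 3))
  expect_true(all(!grepl("\\*", refs$protein)))       # no internal stops
  expect_true(all(substr(refs$cds, 1, 3) == "ATG"))
  expect_error(make_reference_set(families = character(0)), "non-empty")
  expect_error(make_reference_set(families = "sigma"), "unknown OR families")
  # within-family identity > between-family identity (alignment oracle)
  refs2 <- tiny_refs()
  pid <- function(a, b) {
    al <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                        Biostrings::AAString(b),
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5,
                                        type = "local")
    Biostrings::pid(al)
  }
  fam <- refs2$family
  win <- c(); btw <- c()
  nm <- names(refs2$protein)
  for (i in seq_along(nm)[-1]) for (j in seq_len(i - 1)) {
    p <- pid(refs2$protein[[i]], refs2$protein[[j]])
    if (fam[[nm[i]]] == fam[[nm[j]]]) win <- c(win, p) else btw <- c(btw, p)
  }
  expect_gt(mean(win), mean(btw))
  # decoys score below every true OR against the OR reference set
  best_or <- min(vapply(nm, function(a) max(vapply(setdiff(nm, a), function(b)
    local_align(refs2$protein[[a]], refs2$protein[[b]])$score, numeric(1))),
    numeric(1)))
  worst_decoy <- max(vapply(refs2$decoy_protein, function(d)
    max(vapply(refs2$protein, function(r) local_align(d, r)$score, numeric(1))),
    numeric(1)))
  expect_gt(best_or, worst_decoy)
})

test_that("implant_genome places classes as planned, within bounds", {
  refs <- tiny_refs()
  g0 <- implant_genome(refs, implant_plan(0, 0, 0, 0, scaffold_sizes = c(5000)),
                       seed = 1)
  expect_equal(nrow(g0$truth), 0L)
  g <- implant_genome(refs, implant_plan(1, 1, 1, 1, scaffold_sizes = rep(8000, 3)),
                      lof_model(n_stops = 1, n_frameshifts = 0), seed = 4)
  expect_equal(sort(g$truth$class),
               c("edge", "functional", "pseudogene", "truncated"))
  for (i in seq_len(nrow(g$truth))) {
    L <- nchar(g$scaffolds[[g$truth$scaffold[i]]])
    expect_gte(g$truth$start[i], 0)
    expect_lte(g$truth$end[i], L)
  }
  e <- g$truth[g$truth$class == "edge", ]
  L <- nchar(g$scaffolds[[e$scaffold]])
  expect_lt(min(e$start, L - e$end), 30)
  # every pseudogene shows LoF under the frameshift-aware aligner
  gp <- implant_genome(refs, tiny_plan(), seed = 9)
  ps <- gp$truth[gp$truth$class == "pseudogene", ]
  for (i in seq_len(nrow(ps))) {
    seq_fwd <- substr(gp$scaffolds[[ps$scaffold[i]]], ps$start[i] + 1, ps$end[i])
    seq_cod <- if (ps$strand[i] == "+") seq_fwd else fishor:::revcomp(seq_fwd)
    al <- frameshift_align(refs$protein[[ps$source[i]]], seq_cod)
    expect_gte(length(al$stops) + length(al$frameshifts), 1)
  }
  # intact implants show no LoF
  fn <- gp$truth[gp$truth$class == "functional", ]
  for (i in seq_len(nrow(fn))) {
    seq_fwd <- substr(gp$scaffolds[[fn$scaffold[i]]], fn$start[i] + 1, fn$end[i])
    seq_cod <- if (fn$strand[i] == "+") seq_fwd else fishor:::revcomp(seq_fwd)
    al <- frameshift_align(refs$protein[[fn$source[i]]], seq_cod)
    expect_equal(length(al$stops) + length(al$frameshifts), 0L)
  }
  expect_error(implant_genome(refs, implant_plan(500, 0, 0, 0,
                                                 scaffold_sizes = c(5000))),
               "capacity")
})

test_that("generator outputs are byte-identical under a fixed seed", {
  refs <- tiny_refs()
  g1 <- implant_genome(refs, tiny_plan(), seed = 33)
  g2 <- implant_genome(refs, tiny_plan(), seed = 33)
  expect_identical(g1$scaffolds, g2$scaffolds)
  expect_identical(g1$truth, g2$truth)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome(g1, fasta = f1); write_genome(g2, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulate_traits honours degenerate parameters and BM covariance", {
  tr <- simulate_species_tree(6, 80, seed = 2)
  z <- simulate_traits(tr, "BM", list(sigma2 = 0, root = 3.5), seed = 1)
  expect_true(all(z == 3.5))
  m0 <- simulate_traits(tr, "Mk", list(q01 = 0, q10 = 0, root = 1), seed = 1)
  expect_true(all(m0 == 1))
  expect_error(simulate_traits(tr, "lambda", list(lambda = 1.2)), "lambda")
  expect_error(simulate_traits(tr, "Mk", list(q01 = -1)), "non-negative")
  # empirical tip covariance matches sigma2 * shared path length
  tr4 <- simulate_species_tree(4, 50, seed = 5)
  V <- ape::vcv(tr4)
  set.seed(8)
  X <- replicate(2000, simulate_traits(tr4, "BM", list(sigma2 = 2)))
  emp <- cov(t(X))
  expect_lt(max(abs(emp - 2 * V[rownames(emp), colnames(emp)])) / max(2 * V), 0.15)
})
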