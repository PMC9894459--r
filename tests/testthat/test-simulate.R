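test_that("base abundance vectors are valid compositions", {
  b <- base_abundance_vectors()
  expect_equal(dim(b), c(3L, 5L))
  expect_equal(unname(rowSums(b)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(b > 0))
})

test_that("convergent vectors shrink dominant species and approach uniformity", {
  cv <- convergent_vectors()
  expect_equal(nrow(cv), 30L)
  expect_equal(unname(rowSums(cv)), rep(1, 30), tolerance = 1e-9)
  expect_true(all(cv >= 0))

  b <- base_abundance_vectors()
  # step 1 of G1: the 0.507 component decreases, the 0.022 component increases
  expect_lt(cv["G1-1", 2], b["G1", 2])
  expect_gt(cv["G1-1", 5], b["G1", 5])

  # L1 distance to the uniform vector strictly decreases with step
  unif <- rep(1 / 5, 5)
  for (g in 1:3) {
    l1 <- vapply(1:10, function(k)
      sum(abs(cv[sprintf("G%d-%d", g, k), ] - unif)), 0)
    expect_true(all(diff(l1) < 0))
  }

  # non-cumulative variant stays valid and moves the same way
  sv <- convergent_vectors(cumulative = FALSE, steps = 4)
  expect_equal(unname(rowSums(sv)), rep(1, 12), tolerance = 1e-9)
  expect_lt(sv["G1-1", 2], b["G1", 2])
})

test_that("gaussian vectors are valid, reproducible, and component-scaled", {
  gv <- gaussian_vectors(seed = 9)
  expect_equal(nrow(gv), 30L)
  expect_equal(unname(rowSums(gv)), rep(1, 30), tolerance = 1e-9)
  expect_true(all(gv >= 0))
  expect_identical(gv, gaussian_vectors(seed = 9))
  expect_false(identical(gv, gaussian_vectors(seed = 10)))

  # the half-normal perturbation: E|N(0, c)|/5 = c * sqrt(2/pi) / 5
  set.seed(61)
  c0 <- 0.4
  mc <- mean(abs(rnorm(1e5, 0, c0)) / 5)
  expect_equal(mc, c0 * sqrt(2 / pi) / 5, tolerance = 0.02)
  # consequence in the generator: perturbation spread scales with the
  # component, so large components vary more across replicates
  gv2 <- gaussian_vectors(reps = 200, seed = 12)
  g1 <- gv2[attr(gv2, "group") == 1, ]
  expect_gt(sd(g1[, 2]), sd(g1[, 5]))  # base 0.507 vs 0.022
})

test_that("synthetic genomes are reproducible with clean embedded ORFs", {
  gs <- make_genomes(n_species = 3, n_genes = 12, genome_len = 10000,
                     protein_len_range = c(100, 130), seed = 4)
  gs2 <- make_genomes(n_species = 3, n_genes = 12, genome_len = 10000,
                      protein_len_range = c(100, 130), seed = 4)
  expect_identical(gs$genomes, gs2$genomes)
  expect_equal(unname(nchar(gs$genomes)), rep(10000, 3))

  # every embedded ORF translates to its recorded protein plus the stop
  for (i in seq_len(nrow(gs$genes))) {
    g <- gs$genes[i, ]
    orf <- substr(gs$genomes[[g$species]], g$start, g$end)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
    expect_identical(aa, paste0(g$protein, "*"))
    expect_false(grepl("\\*", g$protein))
  }
  expect_error(make_genomes(n_genes = 50, genome_len = 3000), "10x")
  expect_error(make_genomes(n_genes = 50, genome_len = 5000,
                            protein_len_range = c(100, 160)), "infeasible")
})

test_that("species divergence drives proteome dissimilarity monotonically", {
  T_at <- function(div) {
    gs <- make_genomes(n_species = 2, n_genes = 10, genome_len = 9000,
                       protein_len_range = c(100, 120), divergence = div,
                       seed = 8)
    g <- gs$genes
    pa <- proteome("A", g$gene_id[g$species == "sp1"],
                   g$protein[g$species == "sp1"])
    pb <- proteome("B", g$gene_id[g$species == "sp2"],
                   g$protein[g$species == "sp2"])
    ab <- best_hits(pa, pb, engine = "exact")
    ba <- best_hits(pb, pa, engine = "exact")
    as.numeric(normalized_avg_dissimilarity(ab, ba))
  }
  t5 <- T_at(0.05)
  t20 <- T_at(0.20)
  expect_gt(t20, t5)
})

test_that("read sampling respects abundances, strands, and error rates", {
  gs <- make_genomes(n_species = 3, n_genes = 10, genome_len = 9000,
                     protein_len_range = c(100, 120), seed = 5)
  only1 <- synthetic_community(gs, c(1, 0, 0), id = "mono")
  rs <- sample_reads(only1, 500, read_len = 100, seed = 3)
  expect_true(all(startsWith(rs$id, "sp1_")))
  expect_identical(rs$seq, sample_reads(only1, 500, read_len = 100, seed = 3)$seq)

  # error-free reads are exact substrings of the genome or its reverse
  # complement
  both <- paste(gs$genomes[1],
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(gs$genomes[1]))))
  expect_true(all(vapply(rs$seq[1:50], grepl, TRUE, x = both, fixed = TRUE)))

  # equal genome lengths, abundance (0.5, 0.5, 0): binomial read split
  half <- synthetic_community(gs, c(0.5, 0.5, 0), id = "half")
  rh <- sample_reads(half, 10000, read_len = 100, seed = 6)
  n1 <- sum(startsWith(rh$id, "sp1_"))
  expect_lt(abs(n1 - 5000), 3 * sqrt(10000 * 0.25))
  expect_equal(sum(startsWith(rh$id, "sp3_")), 0L)

  # substitution errors break exact-substring identity
  re <- sample_reads(only1, 50, read_len = 100, error_rate = 0.05, seed = 3)
  expect_false(all(vapply(re$seq, grepl, TRUE, x = both, fixed = TRUE)))
})

test_that("community proteomes reflect abundance through coverage and gene recovery", {
  gs <- make_genomes(n_species = 3, n_genes = 20, genome_len = 14000,
                     protein_len_range = c(100, 120), seed = 6)
  ab <- c(0.6, 0.38, 0.02)
  comm <- synthetic_community(gs, ab, id = "c1")
  p <- community_proteome(comm)
  expect_true(all(p$records$has_start & p$records$has_stop))
  # rescaled abundance vectors renormalize to the same composition
  p2 <- community_proteome(synthetic_community(gs, ab * 2, id = "c1"))
  expect_equal(p$records, p2$records)
  # rare species lose part of their gene complement, dominant ones do not
  n_by_sp <- table(sub("_g.*", "", p$records$id))
  expect_lt(n_by_sp[["sp3"]], 20L)
  expect_gt(n_by_sp[["sp1"]], n_by_sp[["sp3"]])
  # zero-abundance species contribute nothing
  p0 <- community_proteome(synthetic_community(gs, c(0.5, 0.5, 0), id = "c0"))
  expect_false(any(startsWith(p0$records$id, "sp3")))
  # detection off: the full gene complement, regardless of abundance
  pf <- community_proteome(comm, detect = FALSE)
  expect_equal(length(pf), 60L)

  # different compositions give strictly positive dissimilarity
  q <- community_proteome(synthetic_community(gs, c(0.1, 0.3, 0.6), id = "c2"))
  abq <- best_hits(p, q, engine = "exact")
  qba <- best_hits(q, p, engine = "exact")
  T_pq <- normalized_avg_dissimilarity(
    abq, qba, setNames(p$records$coverage, p$records$id),
    setNames(q$records$coverage, q$records$id))
  expect_gt(as.numeric(T_pq), 0)
})

test_that("a reduced convergent simulation separates groups and orders steps", {
  # two groups, six steps each: groups stay monophyletic, and within a group
  # the dissimilarity to the step-1 sample grows monotonically with step
  cv <- convergent_vectors(base_abundance_vectors()[1:2, , drop = FALSE],
                           steps = 6)
  pr <- simulate_proteomes(cv, seed = 13)
  fit <- mpass(pr, engine = "auto")
  pat <- cophenetic(fit$tree)
  for (g in 1:2) {
    members <- grep(sprintf("^G%d-", g), rownames(cv), value = TRUE)
    expect_true(is_clade(fit$tree, members))
    steps <- sprintf("G%d-%d", g, 1:6)
    T_from_first <- fit$dist$T[steps[1], steps[-1]]
    expect_true(all(diff(T_from_first) > 0))
    # the most-converged sample branches deeper than the low-step cluster
    low <- steps[1:3]
    expect_gt(mean(pat[steps[6], low]), max(pat[low, low]))
  }
})
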