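scfg <- scoring_params()

test_that("local alignment scores match the substitution-matrix diagonal on identity", {
  seqs <- "ACDEFGHIKL"
  res <- strsplit(seqs, "")[[1]]
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  diag_sum <- sum(e$BLOSUM62[cbind(res, res)])
  a <- align_score(seqs, seqs, scfg)
  expect_equal(a$raw, diag_sum)
  expect_equal(a$score, (scfg$lambda * diag_sum - log(scfg$K)) / log(2))
})

test_that("self-alignment dominates a mutated copy and e-values fall with score", {
  set.seed(21)
  x <- random_protein(80)
  y <- mutate_protein(x, 0.5)
  expect_gt(align_score(x, x, scfg)$raw, align_score(x, y, scfg)$raw)

  # e-value strictly decreasing in bit score at fixed lengths
  bits <- c(20, 30, 40)
  ev <- vapply(bits, mpass:::.evalue, 0, m = 100, n = 100)
  expect_true(all(diff(ev) < 0))

  expect_error(align_score("MK!L", "MKL", scfg), "illegal")
})

test_that("best hits against self are the identity mapping", {
  set.seed(22)
  p <- random_proteome("p", n = 6, len = 60)
  ht <- best_hits(p, p, scfg, engine = "exact")
  expect_equal(ht$target_id, ht$query_id)
  expect_equal(ht$best_score, ht$self_score)
  expect_s3_class(ht, "hit_table")
})

test_that("best hits agree with exhaustive all-pairs scoring on a toy pair", {
  set.seed(23)
  a <- random_proteome("a", n = 5, len = 50)
  # target: mutated copies of a's proteins plus an unrelated one
  tseqs <- c(vapply(a$records$sequence[1:4], mutate_protein, "", rate = 0.2),
             random_protein(50))
  b <- proteome("b", paste0("b_g", 1:5), unname(tseqs))
  ht <- best_hits(a, b, scfg, engine = "exact")

  # brute-force oracle: score every query x target pair with align_score
  for (i in seq_len(5)) {
    raws <- vapply(b$records$sequence, function(t)
      align_score(a$records$sequence[i], t, scfg)$raw, 0)
    best <- which.max(raws)
    bits <- (scfg$lambda * raws[best] - log(scfg$K)) / log(2)
    ev <- nchar(a$records$sequence[i]) * sum(b$records$length) * 2^(-bits)
    if (ev <= scfg$max_evalue) {
      expect_equal(ht$target_id[i], b$records$id[best])
      expect_equal(ht$best_score[i], unname(bits))
    } else {
      expect_true(is.na(ht$target_id[i]))
    }
  }
})

test_that("unrelated queries yield no-hit entries", {
  set.seed(24)
  a <- random_proteome("a", n = 3, len = 40)
  b <- random_proteome("b", n = 3, len = 40)
  # random 40-mers share only spurious low-scoring local alignments, which a
  # stringent reporting threshold removes entirely
  strict <- scoring_params(max_evalue = 1e-6)
  ht <- best_hits(a, b, strict, engine = "exact")
  expect_true(all(is.na(ht$best_score)))
  expect_true(all(is.na(ht$target_id)))
  expect_error(best_hits(proteome("e", character(0), character(0)), a),
               "non-empty")
})

test_that("T has the hand-computed value on a weighted toy case", {
  # two genes with dissimilarities (0, 1) and coverages (3, 1):
  # weighted mean = (3*0 + 1*1) / 4 = 0.25 in both directions
  ht <- structure(
    data.frame(query_id = c("g1", "g2"),
               target_id = c("g1", NA),
               best_score = c(50, NA),
               evalue = c(1e-20, NA),
               self_score = c(50, 60)),
    class = c("hit_table", "data.frame"))
  covs <- c(g1 = 3, g2 = 1)
  T_val <- normalized_avg_dissimilarity(ht, ht, covs, covs)
  expect_equal(as.numeric(T_val), 0.25)
  # coverage-scale invariance: weights normalize within each sample
  expect_equal(as.numeric(normalized_avg_dissimilarity(ht, ht, covs * 7, covs)),
               0.25)
  expect_error(normalized_avg_dissimilarity(ht, ht, covs * 0, covs), "zero")
})

test_that("identical proteomes give T = 0 and disjoint proteomes give T = 1", {
  set.seed(25)
  p <- random_proteome("p", n = 4, len = 60, coverage = c(5, 1, 2, 8))
  q <- p; q$sample_id <- "q"
  ab <- best_hits(p, q, scfg, engine = "exact")
  T0 <- normalized_avg_dissimilarity(ab, ab,
                                     setNames(p$records$coverage, p$records$id),
                                     setNames(q$records$coverage, q$records$id))
  expect_equal(as.numeric(T0), 0)

  # unrelated proteomes: every gene is a no-hit under a stringent threshold,
  # so both directional aggregates are 1
  r <- random_proteome("r", n = 4, len = 60)
  strict <- scoring_params(max_evalue = 1e-6)
  ar <- best_hits(p, r, strict, engine = "exact")
  ra <- best_hits(r, p, strict, engine = "exact")
  expect_equal(as.numeric(normalized_avg_dissimilarity(ar, ra)), 1)
})

test_that("the exponential distance transform matches its closed form", {
  expect_equal(distance_from_T(0), 4.142)
  expect_equal(distance_from_T(1), 4.142 * exp(2.824))
  ts <- seq(0, 1, by = 0.05)
  expect_true(all(diff(distance_from_T(ts)) > 0))
  expect_error(distance_from_T(-0.01), "\\[0, 1\\]")
  expect_error(distance_from_T(1.01), "\\[0, 1\\]")
  # degenerate constants flatten the transform
  expect_equal(distance_from_T(c(0, 0.5, 1), distance_params(1, 0)),
               c(1, 1, 1))
})

test_that("Poisson-corrected substitution rates match closed forms", {
  expect_equal(poisson_corrected_rate(100, 100, 0), 0, ignore_attr = TRUE)
  expect_equal(poisson_corrected_rate(50, 100, 0), 100 * log(2),
               ignore_attr = TRUE)
  r <- poisson_corrected_rate(90, 110, 10)
  expect_equal(attr(r, "S1prime"), 0.1)
  expect_equal(as.numeric(r), -log(0.9) * 100)
  expect_error(poisson_corrected_rate(0, 100, 100), "aln_len > gapped")
  expect_error(poisson_corrected_rate(0, 100, 0), "undefined")
})

test_that("constants are recovered from calibration points", {
  tt <- seq(0.05, 0.95, length.out = 90)
  s2 <- 4.142 * exp(2.824 * tt)
  fit <- estimate_constants(tt, s2)
  expect_equal(fit$const1, 4.142, tolerance = 1e-6)
  expect_equal(fit$const2, 2.824, tolerance = 1e-6)

  set.seed(26)
  noisy <- s2 * exp(rnorm(90, 0, 0.05))
  fitn <- estimate_constants(tt, noisy, method = "nls")
  expect_equal(fitn$const1, 4.142, tolerance = 0.1)
  expect_equal(fitn$const2, 2.824, tolerance = 0.1)

  expect_error(estimate_constants(c(0.1, 0.2), c(5, 6)), "3 usable")
  expect_error(estimate_constants(c(0.3, 0.3, 0.3), c(5, 6, 7)), "all equal")
  expect_warning(estimate_constants(c(tt, 0.5), c(s2, -1)), "excluded")
})

test_that("T is symmetric, in range, and monotone under progressive mutation", {
  set.seed(27)
  base <- random_proteome("base", n = 6, len = 60, coverage = runif(6, 0.5, 5))
  rates <- c(0.05, 0.15, 0.3, 0.5)
  fam <- lapply(seq_along(rates), function(k) {
    proteome(paste0("m", k), paste0("m", k, "_g", 1:6),
             vapply(base$records$sequence, mutate_protein, "",
                    rate = rates[k], USE.NAMES = FALSE),
             coverage = base$records$coverage)
  })
  covb <- setNames(base$records$coverage, base$records$id)
  Ts <- vapply(fam, function(p) {
    ab <- best_hits(base, p, scfg, engine = "exact")
    ba <- best_hits(p, base, scfg, engine = "exact")
    covp <- setNames(p$records$coverage, p$records$id)
    T1 <- normalized_avg_dissimilarity(ab, ba, covb, covp)
    T2 <- normalized_avg_dissimilarity(ba, ab, covp, covb)
    expect_equal(as.numeric(T1), as.numeric(T2))  # symmetry
    as.numeric(T1)
  }, 0)
  expect_true(all(Ts >= 0 & Ts <= 1))
  expect_true(all(diff(Ts) >= -1e-12))  # non-decreasing in mutation load
  expect_gt(Ts[4], Ts[1])
})

test_that("the distance matrix is symmetric with zero diagonal and logs provenance", {
  set.seed(28)
  p1 <- random_proteome("s1", n = 5, len = 60)
  p2 <- proteome("s2", paste0("s2_g", 1:5),
                 vapply(p1$records$sequence, mutate_protein, "", rate = 0.1,
                        USE.NAMES = FALSE))
  p3 <- proteome("s3", paste0("s3_g", 1:5),
                 vapply(p1$records$sequence, mutate_protein, "", rate = 0.3,
                        USE.NAMES = FALSE))
  d <- build_distance_matrix(list(p1, p2, p3), scfg, engine = "exact")
  expect_equal(d$S, t(d$S))
  expect_equal(unname(diag(d$S)), rep(0, 3))
  expect_equal(nrow(d$pairs), 3L)
  expect_true(all(d$pairs$S >= 4.142))
  # three identical proteomes -> all off-diagonal S equal S(T = 0)
  q2 <- p1; q2$sample_id <- "t2"; q2$records$id <- paste0("t2_g", 1:5)
  q3 <- p1; q3$sample_id <- "t3"; q3$records$id <- paste0("t3_g", 1:5)
  di <- build_distance_matrix(list(p1, q2, q3), scfg, engine = "exact")
  expect_equal(unname(di$S[upper.tri(di$S)]), rep(4.142, 3))
  expect_error(build_distance_matrix(list(p1, p1, p2)), "duplicate")
})
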