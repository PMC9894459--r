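#' Distance-transform constants
#'
#' Parameters of the exponential map from the normalized average proteome
#' dissimilarity T to the metagenomic distance S = const1 * exp(const2 * T).
#' The defaults (4.142, 2.824) were calibrated against percent
#' Poisson-corrected 16S rRNA substitution rates across a balanced panel of
#' prokaryote, eukaryote, and archaeal genomes, so S is expressed on a percent
#' substitution-rate-equivalent scale.
#'
#' @param const1,const2 finite reals, `const1 > 0`, `const2 >= 0` (`const2 =
#'   0` degenerates to a constant transform, occasionally useful for
#'   diagnostics).
#' @return a `distance_params` list.
#' @export
distance_params <- function(const1 = 4.142, const2 = 2.824) {
  stopifnot(is.finite(const1), is.finite(const2), const1 > 0, const2 >= 0)
  structure(list(const1 = const1, const2 = const2), class = "distance_params")
}

#' Normalized average proteome dissimilarity T
#'
#' Aggregates two best-hit tables (A vs B and B vs A) into the
#' coverage-weighted normalized average dissimilarity T in `[0, 1]`. Per gene,
#' similarity is `best_score / self_score` (0 for a no-hit, so genes present in
#' only one metagenome still inform the distance), dissimilarity is its
#' complement, and each direction is the coverage-weighted mean over the query
#' sample's retained genes with weights `coverage / sum(coverage)`. T is the
#' arithmetic mean of the two directions, which symmetrizes it.
#'
#' Weight normalization makes T invariant to rescaling all of one sample's
#' coverages by a positive constant.
#'
#' @param ab,ba `hit_table`s from [best_hits()] in the two directions, computed
#'   under one scoring scheme.
#' @param cov_a,cov_b named coverage vectors (names = protein ids); defaults to
#'   equal weights when `NULL`.
#' @return T, a number in `[0, 1]`; attributes `similarity` (1 - T) and
#'   `directional` (the two one-way aggregates).
#' @export
normalized_avg_dissimilarity <- function(ab, ba, cov_a = NULL, cov_b = NULL) {
  one_way <- function(ht, cov) {
    s <- clamp01(ht$best_score / ht$self_score)
    s[is.na(ht$best_score)] <- 0
    w <- if (is.null(cov)) rep(1, nrow(ht)) else unname(cov[ht$query_id])
    if (anyNA(w)) stop("coverage map is missing ids: ",
                       paste(head(ht$query_id[is.na(w)], 5L), collapse = ", "))
    if (any(w < 0)) stop("negative coverage weights")
    tw <- sum(w)
    if (tw <= 0) stop("total coverage weight is zero; cannot normalize")
    sum(w * (1 - s)) / tw
  }
  ta <- one_way(ab, cov_a)
  tb <- one_way(ba, cov_b)
  structure((ta + tb) / 2, similarity = 1 - (ta + tb) / 2,
            directional = c(ta, tb))
}

#' Metagenomic distance S from dissimilarity T
#'
#' The exponential transform `S = const1 * exp(const2 * T)`, strictly
#' increasing in T, mapping the proteome dissimilarity onto a percent
#' 16S-substitution-rate-equivalent scale.
#'
#' @param T_value dissimilarity in `[0, 1]` (vectorized).
#' @param params a [distance_params()].
#' @return S (same length as `T_value`).
#' @export
distance_from_T <- function(T_value, params = distance_params()) {
  stopifnot(is.numeric(T_value))
  if (any(!is.finite(T_value)) || any(T_value < 0 | T_value > 1))
    stop("T must lie in [0, 1]")
  params$const1 * exp(params$const2 * T_value)
}

#' Percent Poisson-corrected substitution rate
#'
#' From an alignment summary, the observed substitution proportion is
#' `S1' = 1 - matched / (aln_len - gapped)` and the Poisson correction for
#' multiple hits at a site gives the percent rate `S2' = -ln(1 - S1') * 100`.
#'
#' @param matched count of matched (identical) loci.
#' @param aln_len alignment length.
#' @param gapped count of gapped loci (default 0).
#' @return S2' in percent (vectorized); attribute `S1prime` carries the
#'   uncorrected proportion.
#' @export
poisson_corrected_rate <- function(matched, aln_len, gapped = 0) {
  stopifnot(is.numeric(matched), is.numeric(aln_len), is.numeric(gapped))
  n <- max(length(matched), length(aln_len), length(gapped))
  matched <- rep_len(matched, n); aln_len <- rep_len(aln_len, n)
  gapped <- rep_len(gapped, n)
  if (any(gapped < 0) || any(aln_len <= gapped))
    stop("require aln_len > gapped >= 0")
  denom <- aln_len - gapped
  if (any(matched < 0 | matched > denom))
    stop("require 0 <= matched <= aln_len - gapped")
  s1 <- 1 - matched / denom
  if (any(s1 >= 1))
    stop("no matched loci: substitution rate undefined (S1' = 1)")
  structure(-log(1 - s1) * 100, S1prime = s1)
}

#' Re-estimate the distance-transform constants
#'
#' Least-squares fit of `S2' ~ c1 * exp(c2 * T)` to calibration points pairing
#' proteome dissimilarities T with percent Poisson-corrected 16S substitution
#' rates. The default is log-linear regression (`lm(log(S2') ~ T)`), optionally
#' refined by nonlinear least squares on the original scale.
#'
#' @param T_values,S2_values numeric vectors of equal length (>= 3 points).
#'   Non-positive `S2_values` are excluded with a warning (their log is
#'   undefined).
#' @param method `"log-linear"` or `"nls"` (log-linear start, `nls` refinement).
#' @return a [distance_params()] with attribute `fit` (the regression object).
#' @export
estimate_constants <- function(T_values, S2_values,
                               method = c("log-linear", "nls")) {
  method <- match.arg(method)
  stopifnot(length(T_values) == length(S2_values))
  ok <- is.finite(T_values) & is.finite(S2_values)
  pos <- ok & S2_values > 0
  if (any(ok & !pos))
    warning(sum(ok & !pos), " non-positive S2' value(s) excluded from the fit")
  x <- T_values[pos]; y <- S2_values[pos]
  if (length(x) < 3L) stop("need at least 3 usable calibration points")
  if (var(x) == 0) stop("T values are all equal; constants not identifiable")
  fit <- lm(log(y) ~ x)
  c1 <- exp(unname(coef(fit)[1L])); c2 <- unname(coef(fit)[2L])
  if (method == "nls") {
    fit <- nls(y ~ c1 * exp(c2 * x), start = list(c1 = c1, c2 = c2))
    c1 <- unname(coef(fit)["c1"]); c2 <- unname(coef(fit)["c2"])
  }
  structure(distance_params(const1 = c1, const2 = c2), fit = fit)
}

#' Build the sample-by-sample MPASS distance matrix
#'
#' All unordered pairs of proteomes are compared by coverage-weighted best-hit
#' similarity; each pair's T ([normalized_avg_dissimilarity()]) is transformed
#' to S ([distance_from_T()]). Identical sequences across all samples are
#' dereplicated first, so the alignment cost scales with the number of unique
#' proteins, not records. The diagonal is stored as 0 (tree methods require a
#' zero self-distance); note that the transform itself maps T = 0 to
#' `const1`, an offset property of the calibration that is logged per pair,
#' not subtracted.
#'
#' @param proteomes list of filtered [proteome()] objects with unique sample
#'   ids (>= 3 for downstream tree building).
#' @param scoring a [scoring_params()].
#' @param params a [distance_params()].
#' @param engine see [best_hits()].
#' @return an `mpass_dist` object: list with `S` (symmetric matrix, zero
#'   diagonal), `T` (symmetric matrix of dissimilarities), `pairs` (per-pair
#'   provenance data frame), `params`, `engine`.
#' @export
build_distance_matrix <- function(proteomes, scoring = scoring_params(),
                                  params = distance_params(),
                                  engine = c("auto", "exact", "blast")) {
  engine <- match.arg(engine)
  stopifnot(is.list(proteomes), length(proteomes) >= 3L)
  lapply(proteomes, function(p) stopifnot(inherits(p, "proteome")))
  labs <- unname(vapply(proteomes, function(p) p$sample_id, ""))
  if (anyDuplicated(labs))
    stop("duplicate sample labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  empty <- vapply(proteomes, function(p) nrow(p$records) == 0L, TRUE)
  if (any(empty))
    stop("empty proteome(s): ", paste(labs[empty], collapse = ", "))
  names(proteomes) <- labs
  uni <- .universe_of(proteomes)
  hu <- .hits_universe(uni$seqs, scoring, engine)
  n <- length(proteomes)
  Tm <- matrix(0, n, n, dimnames = list(labs, labs))
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    ab <- .pair_hits(uni, hu$hits, hu$self, i, j, proteomes, scoring)
    ba <- .pair_hits(uni, hu$hits, hu$self, j, i, proteomes, scoring)
    Tij <- normalized_avg_dissimilarity(
      ab, ba,
      setNames(proteomes[[i]]$records$coverage, proteomes[[i]]$records$id),
      setNames(proteomes[[j]]$records$coverage, proteomes[[j]]$records$id))
    Tm[i, j] <- Tm[j, i] <- as.numeric(Tij)
    pairs[[length(pairs) + 1L]] <- data.frame(
      a = labs[i], b = labs[j], T = as.numeric(Tij),
      S = distance_from_T(as.numeric(Tij), params),
      stringsAsFactors = FALSE)
  }
  S <- distance_from_T(Tm, params)
  diag(S) <- 0
  structure(list(S = S, T = Tm, pairs = do.call(rbind, pairs),
                 params = params, engine = hu$engine),
            class = "mpass_dist")
}

#' @export
print.mpass_dist <- function(x, ...) {
  cat("<mpass_dist>", nrow(x$S), "samples;", nrow(x$pairs), "pairs; engine:",
      x$engine, "\n")
  cat("  T range:", signif(min(x$pairs$T), 4), "-", signif(max(x$pairs$T), 4),
      "; S range:", signif(min(x$pairs$S), 4), "-", signif(max(x$pairs$S), 4),
      "\n")
  invisible(x)
}

#' @export
as.dist.mpass_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$S, diag = diag, upper = upper)
}

#' Write a distance matrix in lower-triangle PHYLIP format
#'
#' @param d an `mpass_dist`, matrix, or `dist`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  m <- if (inherits(d, "mpass_dist")) d$S else as.matrix(d)
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("S", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    vals <- if (i > 1) paste(sprintf("%.6f", m[i, seq_len(i - 1L)]),
                             collapse = "  ") else ""
    writeLines(trimws(sprintf("%-12s  %s", labs[i], vals), "right"), con)
  }
  invisible(path)
}
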