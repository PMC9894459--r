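#' Select the highest-coverage proteins of a sample
#'
#' Restricting the per-gene conservation analysis to the top-coverage genes
#' avoids unreliable low-depth predictions.
#'
#' @param p a [proteome()].
#' @param top_n number to keep (default 1000); ties broken by id. If the
#'   proteome is smaller, all records are returned with a warning.
#' @return the subset [proteome()].
#' @export
select_top_coverage <- function(p, top_n = 1000) {
  stopifnot(inherits(p, "proteome"), top_n >= 1)
  r <- p$records
  if (nrow(r) < top_n)
    warning("proteome has only ", nrow(r), " records (< top_n = ", top_n, ")")
  ord <- order(-r$coverage, r$id)
  out <- p
  out$records <- r[head(ord, top_n), , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

.dg_from_hit <- function(best_score, self_score, evalue, mode) {
  if (mode == "score") {
    d <- 1 - clamp01(best_score / self_score)
    d[is.na(best_score)] <- 1
  } else {
    # non-normative e-value mode: -log10(e) clipped to [0, 200], rescaled by
    # the self-hit's value; the self e-value at matched search space is
    # recovered from the self bit score
    nl <- function(e) pmin(200, pmax(0, -log10(pmax(e, 1e-300))))
    d <- 1 - clamp01(nl(evalue) / nl(2^(-self_score)))
    d[is.na(evalue)] <- 1
  }
  d
}

#' Distance of a single gene to a target proteome
#'
#' The per-gene analogue of the sample distance: the gene's best-hit
#' dissimilarity against the target proteome, passed through the same
#' exponential transform as the whole-proteome distance (without averaging
#' over genes). Mode `"score"` (default, normative) uses
#' `d = 1 - best_score / self_score`; mode `"evalue"` maps the best hit's
#' e-value monotonically onto `[0, 1]` and is provided for fidelity
#' experiments only. A no-hit gene gets the maximal distance
#' `distance_from_T(1)`.
#'
#' @param gene a single-row [proteome()] record (data frame row with `id`,
#'   `sequence`) or a one-record proteome.
#' @param target a [proteome()].
#' @param scoring a [scoring_params()].
#' @param params a [distance_params()].
#' @param mode `"score"` or `"evalue"`.
#' @param engine see [best_hits()].
#' @return the per-gene distance S_g.
#' @export
per_gene_distance <- function(gene, target, scoring = scoring_params(),
                              params = distance_params(),
                              mode = c("score", "evalue"),
                              engine = c("auto", "exact", "blast")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (inherits(gene, "proteome")) {
    stopifnot(nrow(gene$records) == 1L)
    g <- gene
  } else {
    g <- proteome("query", gene$id, gene$sequence)
  }
  ht <- best_hits(g, target, scoring = scoring, engine = engine)
  d <- .dg_from_hit(ht$best_score, ht$self_score, ht$evalue, mode)
  distance_from_T(d, params)
}

#' Trace gene conservation across samples and correlate with the tree
#'
#' For each selected high-coverage gene of the focal sample, computes its
#' per-gene distance S_g to every other sample and the Pearson correlation r
#' between that distance profile and the patristic (path-length) distance
#' from the focal leaf to each other leaf of the metagenomic tree. Genes with
#' `r > r_cutoff` are flagged tree-concordant: their presence/divergence
#' pattern follows the community phylogeny. Genes whose distance profile has
#' zero variance are excluded with a warning (r is undefined).
#'
#' @param focal the focal sample's [proteome()].
#' @param others named list of the other samples' proteomes.
#' @param tree `phylo` whose leaves include the focal and all other samples.
#' @param scoring a [scoring_params()].
#' @param params a [distance_params()].
#' @param top_n genes to trace (default 1000), by descending coverage.
#' @param r_cutoff concordance threshold (default 0.7).
#' @param mode,engine see [per_gene_distance()].
#' @return a `gene_trace`: list with `matrix` (genes x samples S_g, rows
#'   sorted by descending r), `r` (named correlations), `selected` (ids with
#'   `r > r_cutoff`), `focal`, `r_cutoff`.
#' @export
trace_genes <- function(focal, others, tree, scoring = scoring_params(),
                        params = distance_params(), top_n = 1000,
                        r_cutoff = 0.7, mode = c("score", "evalue"),
                        engine = c("auto", "exact", "blast")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  stopifnot(inherits(focal, "proteome"), is.list(others),
            inherits(tree, "phylo"))
  labs <- vapply(others, function(p) p$sample_id, "")
  need <- c(focal$sample_id, labs)
  if (!all(need %in% tree$tip.label))
    stop("samples missing from tree: ",
         paste(setdiff(need, tree$tip.label), collapse = ", "))
  sel <- suppressWarnings(select_top_coverage(focal, top_n))
  prots <- c(list(sel), others)
  uni <- .universe_of(prots)
  hu <- .hits_universe(uni$seqs, scoring, engine)
  Sg <- matrix(NA_real_, nrow(sel$records), length(others),
               dimnames = list(sel$records$id, labs))
  for (j in seq_along(others)) {
    ht <- .pair_hits(uni, hu$hits, hu$self, 1L, j + 1L, prots, scoring)
    d <- .dg_from_hit(ht$best_score, ht$self_score, ht$evalue, mode)
    Sg[, j] <- distance_from_T(d, params)
  }
  pat <- cophenetic(tree)[focal$sample_id, labs]
  sds <- apply(Sg, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " gene(s) excluded: constant distance profile ",
            "(undefined correlation)")
    keep <- rownames(Sg)[sds > 0]
    Sg <- Sg[sds > 0, , drop = FALSE]
    rownames(Sg) <- keep
  }
  r <- if (nrow(Sg)) apply(Sg, 1L, cor, y = pat)
       else setNames(numeric(0), character(0))
  ord <- order(-r)
  Sg <- Sg[ord, , drop = FALSE]
  r <- r[ord]
  structure(list(matrix = Sg, r = r,
                 selected = names(r)[r > r_cutoff],
                 focal = focal$sample_id, r_cutoff = r_cutoff),
            class = "gene_trace")
}

#' @export
print.gene_trace <- function(x, ...) {
  cat("<gene_trace> focal:", x$focal, "-", nrow(x$matrix), "genes x",
      ncol(x$matrix), "samples\n")
  cat("  tree-concordant (r >", x$r_cutoff, "):", length(x$selected), "of",
      length(x$r), sprintf("(%.1f%%)\n", 100 * length(x$selected) /
                             max(1L, length(x$r))))
  invisible(x)
}

#' Export a gene-trace matrix as TSV (heatmap input)
#'
#' Writes the genes-by-samples distance matrix with the per-gene correlation
#' as the first data column, rows sorted by descending r, ready for external
#' heatmap tools.
#'
#' @param x a `gene_trace` from [trace_genes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_trace <- function(x, path) {
  stopifnot(inherits(x, "gene_trace"))
  genes <- rownames(x$matrix)
  if (is.null(genes)) genes <- character(0)
  df <- data.frame(gene = genes, r = unname(x$r), x$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
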