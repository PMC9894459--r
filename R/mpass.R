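#' Fit a metagenomic tree by whole-proteome average similarity
#'
#' The central entry point: takes one proteome per sample, applies the
#' standard preprocessing (removal of partial and short proteins), computes
#' the coverage-weighted normalized average dissimilarity T and the
#' calibrated exponential distance S for every sample pair, and builds the
#' neighbor-joining metagenomic tree from the distance matrix.
#'
#' @param proteomes a named list of [proteome()] objects, or a character
#'   vector of protein FASTA paths (read via [read_proteome()]).
#' @param min_len,require_complete protein filters, see [filter_proteome()];
#'   set `filter = FALSE` to skip filtering (e.g. pre-filtered input).
#' @param filter apply [filter_proteome()] first (default `TRUE`).
#' @param scoring a [scoring_params()].
#' @param params a [distance_params()].
#' @param engine alignment engine, see [best_hits()].
#' @param dialect,strict header parsing options for FASTA input.
#' @return an object of class `mpass`: list with `dist` (`mpass_dist`),
#'   `tree` (`phylo`), `filtered` (per-sample record counts and removal
#'   reasons), `params`, `scoring`, `call`.
#' @seealso [rank_env_parameters()] to compare the tree against environmental
#'   gradients, [trace_genes()] for per-gene conservation.
#' @export
mpass <- function(proteomes, min_len = 100, require_complete = TRUE,
                  filter = TRUE, scoring = scoring_params(),
                  params = distance_params(),
                  engine = c("auto", "exact", "blast"),
                  dialect = "native", strict = FALSE) {
  engine <- match.arg(engine)
  cl <- match.call()
  if (is.character(proteomes)) {
    proteomes <- lapply(proteomes, read_proteome, dialect = dialect,
                        strict = strict)
  }
  stopifnot(is.list(proteomes), length(proteomes) >= 3L)
  labs <- unname(vapply(proteomes, function(p) p$sample_id, ""))
  names(proteomes) <- labs
  flt <- data.frame(sample = labs, input = NA_integer_,
                    retained = NA_integer_, short = 0L, partial = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(proteomes)) {
    flt$input[i] <- nrow(proteomes[[i]]$records)
    if (filter) {
      proteomes[[i]] <- filter_proteome(proteomes[[i]], min_len = min_len,
                                        require_complete = require_complete)
      rm_ <- attr(proteomes[[i]], "removed")
      flt$short[i] <- rm_[["short"]]
      flt$partial[i] <- rm_[["partial"]]
    }
    flt$retained[i] <- nrow(proteomes[[i]]$records)
  }
  if (any(flt$retained == 0L))
    stop("no proteins retained after filtering in sample(s): ",
         paste(flt$sample[flt$retained == 0L], collapse = ", "))
  d <- build_distance_matrix(proteomes, scoring = scoring, params = params,
                             engine = engine)
  tree <- nj_tree(d)
  structure(list(dist = d, tree = tree, filtered = flt, params = params,
                 scoring = scoring, call = cl),
            class = "mpass")
}

#' @export
print.mpass <- function(x, ...) {
  cat("Metagenomic tree by whole-proteome average similarity\n\n")
  cat("Samples:", nrow(x$dist$S), "  engine:", x$dist$engine, "\n")
  cat("Distance transform: S =", x$params$const1, "* exp(", x$params$const2,
      "* T )\n")
  cat("Pairwise T:", signif(min(x$dist$pairs$T), 4), "-",
      signif(max(x$dist$pairs$T), 4), "  S:",
      signif(min(x$dist$pairs$S), 4), "-", signif(max(x$dist$pairs$S), 4),
      "\n")
  cat("Tree:", length(x$tree$tip.label), "leaves,", x$tree$Nnode,
      "internal nodes (unrooted)\n")
  invisible(x)
}

#' @export
summary.mpass <- function(object, ...) {
  structure(list(filtered = object$filtered, pairs = object$dist$pairs,
                 params = object$params, tree = object$tree),
            class = "summary.mpass")
}

#' @export
print.summary.mpass <- function(x, ...) {
  cat("Per-sample filtering:\n")
  print(x$filtered, row.names = FALSE)
  cat("\nPairwise distances (T = weighted dissimilarity, S = distance):\n")
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mpass <- function(object, ...) {
  c(const1 = object$params$const1, const2 = object$params$const2)
}

#' @export
plot.mpass <- function(x, type = "unrooted", ...) {
  ape::plot.phylo(x$tree, type = type, ...)
  invisible(x)
}

#' @export
as.dist.mpass <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$dist$S, diag = diag, upper = upper)
}

#' Run the full pipeline with optional reports and file outputs
#'
#' Orchestrates the stages end to end: optional read trimming and
#' down-sampling to the smallest library (when raw reads and external
#' assembly/gene-calling hooks are configured), protein filtering, distance
#' matrix, neighbor-joining tree, and the optional environmental-parameter
#' ranking and gene-trace reports. With direct proteome input (the fully
#' self-contained path), the read stages are skipped.
#'
#' @param proteomes as in [mpass()].
#' @param reads optional named list of [read_set()]s; requires `assemble_hook`.
#' @param assemble_hook optional `function(read_set) -> proteome` standing in
#'   for external assembly + gene calling; without it, read input is an error.
#' @param trim_len optional read-trim length applied before down-sampling.
#' @param downsample_seed seed for down-sampling to the minimum library size.
#' @param env optional environmental table (data frame, see
#'   [read_env_table()]) to rank against the tree.
#' @param trace_focal optional sample id for a [trace_genes()] report.
#' @param out_dir optional directory; when given, writes `dist.phy`,
#'   `dist.tsv`, `tree.nwk`, and (if computed) `envrank.tsv`,
#'   `gene_trace.tsv`.
#' @param ... passed to [mpass()].
#' @return the `mpass` object, with components `env_rank` and `trace` added
#'   when requested.
#' @export
run_pipeline <- function(proteomes = NULL, reads = NULL, assemble_hook = NULL,
                         trim_len = NULL, downsample_seed = 1L, env = NULL,
                         trace_focal = NULL, out_dir = NULL, ...) {
  if (is.null(proteomes)) {
    if (is.null(reads))
      stop("stage 'input': provide proteomes or reads")
    if (is.null(assemble_hook))
      stop("stage 'assembly': read input requires an assemble_hook ",
           "(external assembler/gene-caller); supply proteomes directly ",
           "for the self-contained path")
    if (!is.null(trim_len))
      reads <- lapply(reads, trim_reads, max_len = trim_len)
    n_min <- min(vapply(reads, length, 0L))
    reads <- lapply(reads, downsample_reads, n = n_min,
                    seed = downsample_seed)
    proteomes <- lapply(reads, assemble_hook)
  }
  fit <- mpass(proteomes, ...)
  if (!is.null(env)) {
    fit$env_rank <- rank_env_parameters(fit$tree, env)
  }
  if (!is.null(trace_focal)) {
    labs <- rownames(fit$dist$S)
    if (!trace_focal %in% labs)
      stop("stage 'genetrace': unknown focal sample ", trace_focal)
    prots <- if (is.character(proteomes))
      lapply(proteomes, read_proteome) else proteomes
    names(prots) <- vapply(prots, function(p) p$sample_id, "")
    fit$trace <- trace_genes(prots[[trace_focal]],
                             prots[setdiff(labs, trace_focal)], fit$tree,
                             scoring = fit$scoring, params = fit$params)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phylip(fit$dist, file.path(out_dir, "dist.phy"))
    write.table(fit$dist$S, file.path(out_dir, "dist.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    write_newick(fit$tree, file.path(out_dir, "tree.nwk"))
    if (!is.null(fit$env_rank))
      write.table(fit$env_rank, file.path(out_dir, "envrank.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fit$trace))
      write_gene_trace(fit$trace, file.path(out_dir, "gene_trace.tsv"))
  }
  fit
}
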