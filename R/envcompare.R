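#' Read a sample-by-parameter environmental table
#'
#' TSV or CSV with a header row; the first column holds the sample labels
#' (matching the tree leaves), the remaining columns one environmental
#' parameter each (pH, temperature, ion concentrations, organic carbon and
#' nitrogen fractions, ...).
#'
#' @param path file; delimiter inferred from the extension (`.csv` vs tab).
#' @return data frame with sample labels as row names.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample labels in first column of ", path)
  rownames(df) <- as.character(df[[1L]])
  df[-1L]
}

#' Dendrogram of samples under a single environmental parameter
#'
#' Agglomerative clustering of samples on the absolute pairwise differences of
#' one measured variable, returned as a `phylo` dendrogram over the sample
#' labels. Exact ties in merge heights are collapsed into multifurcations so
#' the topology is not inflated by arbitrary binary resolutions; the topology
#' is invariant under positive affine transforms of the values.
#'
#' @param values numeric vector, named by sample (or use `labels`). Samples
#'   with missing values are dropped with a warning.
#' @param labels sample labels if `values` is unnamed.
#' @param linkage `"average"` (UPGMA, default), `"single"`, or `"complete"`.
#' @return a `phylo`; when all values are equal, a star tree with a warning.
#' @export
env_dendrogram <- function(values, labels = names(values),
                           linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (is.null(labels)) stop("sample labels required (names of 'values')")
  stopifnot(length(values) == length(labels))
  keep <- is.finite(values)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) dropped for missing values: ",
            paste(labels[!keep], collapse = ", "))
    values <- values[keep]; labels <- labels[keep]
  }
  if (length(values) < 4L)
    stop("need at least 4 samples with values to build a dendrogram")
  if (length(unique(values)) == 1L) {
    warning("all values equal; returning a star dendrogram")
    return(.star_tree(labels))
  }
  d <- dist(setNames(values, labels))
  hc <- hclust(d, method = linkage)
  tr <- ape::as.phylo(hc)
  # nested merges at identical heights leave zero-length internal edges;
  # collapse them (tolerance relative to tree depth, so affine-invariant)
  ape::di2multi(tr, tol = 1e-8 * max(hc$height))
}

.star_tree <- function(labels) {
  n <- length(labels)
  tr <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
             tip.label = labels, Nnode = 1L,
             edge.length = rep(0, n))
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Rank environmental parameters by topological similarity to a tree
#'
#' For each numeric column of the environmental table a single-parameter
#' dendrogram is built ([env_dendrogram()]) and compared to the metagenomic
#' tree by the Robinson-Foulds symmetric difference ([rf_distance()]). A low
#' symmetric difference marks a parameter whose gradient mirrors the
#' community tree, i.e. a candidate environmental driver.
#'
#' @param tree a `phylo` (e.g. from [nj_tree()]).
#' @param env data frame of parameters with sample row names (see
#'   [read_env_table()]); rows must match the tree leaves.
#' @param linkage passed to [env_dendrogram()].
#' @return data frame (`parameter`, `symmetric_difference`) sorted ascending,
#'   ties alphabetical.
#' @export
rank_env_parameters <- function(tree, env,
                                linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(tree, "phylo"), is.data.frame(env))
  samples <- rownames(env)
  if (!setequal(samples, tree$tip.label)) {
    stop("env samples and tree leaves differ; only in env: {",
         paste(setdiff(samples, tree$tip.label), collapse = ", "),
         "}; only in tree: {",
         paste(setdiff(tree$tip.label, samples), collapse = ", "), "}")
  }
  num <- vapply(env, is.numeric, TRUE)
  if (!all(num))
    warning("skipping non-numeric column(s): ",
            paste(names(env)[!num], collapse = ", "))
  cols <- names(env)[num]
  sd_vals <- vapply(cols, function(cn) {
    dg <- env_dendrogram(setNames(env[[cn]], samples), linkage = linkage)
    if (length(dg$tip.label) != length(samples)) {
      # missing values dropped a sample: topology not comparable
      return(NA_real_)
    }
    rf_distance(tree, dg)
  }, 0)
  out <- data.frame(parameter = cols, symmetric_difference = sd_vals,
                    stringsAsFactors = FALSE)
  out <- out[order(out$symmetric_difference, out$parameter), ]
  rownames(out) <- NULL
  out
}
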