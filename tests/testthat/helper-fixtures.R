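# fixtures shared across test files; everything is generated in code

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

# substitute a fraction of residues (never the leading M)
mutate_protein <- function(p, rate) {
  res <- strsplit(p, "")[[1]]
  hit <- which(runif(length(res)) < rate)
  hit <- hit[hit > 1L]
  if (length(hit))
    res[hit] <- vapply(res[hit], function(old) sample(setdiff(AA20, old), 1L), "")
  paste(res, collapse = "")
}

random_proteome <- function(sample_id, n = 5, len = 60, coverage = NULL) {
  seqs <- vapply(rep(len, n), random_protein, "")
  proteome(sample_id, sprintf("%s_g%d", sample_id, seq_len(n)), seqs,
           coverage = if (is.null(coverage)) 1 else coverage)
}

# caterpillar (ladder) tree over the given labels, unit branch lengths
caterpillar <- function(labels) {
  n <- length(labels)
  s <- sprintf("(%s:1,%s:1)", labels[1], labels[2])
  for (i in 3:n) s <- sprintf("(%s:1,%s:1)", s, labels[i])
  read_newick(paste0(s, ";"))
}

# a ladder tree over a focal sample and `n_other` increasingly distant
# samples, plus proteomes whose genes evolve cumulatively along the ladder:
# each sample's genes are a further-mutated copy of the previous sample's,
# so divergence from the focal sample grows with patristic distance
tree_consistent_fixture <- function(n_genes = 20, n_other = 5, len = 150,
                                    step_rate = 0.06, seed = 71) {
  set.seed(seed)
  others <- paste0("s", seq_len(n_other))
  tree <- caterpillar(c("focal", others))
  genes <- vapply(rep(len, n_genes), random_protein, "")
  focal <- proteome("focal", paste0("g", seq_len(n_genes)), genes,
                    coverage = runif(n_genes, 1, 10))
  cur <- genes
  prots <- list()
  for (j in seq_len(n_other)) {
    cur <- vapply(cur, mutate_protein, "", rate = step_rate,
                  USE.NAMES = FALSE)
    prots[[j]] <- proteome(others[j], paste0(others[j], "_g",
                                             seq_len(n_genes)), cur)
  }
  names(prots) <- others
  list(tree = tree, focal = focal, others = prots)
}

tiny_read_set <- function(n = 10, len = 50, sample_id = "s1") {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
  read_set(sample_id, paste0("r", seq_len(n)), seqs)
}
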