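#' The three base species-abundance vectors
#'
#' Relative abundances of the five community members used as starting points
#' by both simulated-metagenome schemes.
#'
#' @return a 3 x 5 matrix (rows `G1`-`G3`, columns `sp1`-`sp5`), each row
#'   summing to 1.
#' @export
base_abundance_vectors <- function() {
  m <- rbind(
    G1 = c(0.297, 0.507, 0.116, 0.058, 0.022),
    G2 = c(0.345, 0.244, 0.281, 0.088, 0.042),
    G3 = c(0.526, 0.320, 0.042, 0.066, 0.046))
  colnames(m) <- paste0("sp", 1:5)
  m
}

.check_abundance <- function(a) {
  if (any(a < 0) || abs(sum(a) - 1) > 1e-9)
    stop("abundance vector must be non-negative and sum to 1")
  invisible(a)
}

#' Convergent abundance-vector series
#'
#' From each base vector, generates `steps` vectors in which components above
#' the vector mean are decreased and components below it are increased, by
#' `rate` per step (compounded), then renormalized; the composition of each
#' group thereby converges towards the uniform vector with increasing step,
#' so the highest-step samples have lost most of their group-specific
#' signature. With `cumulative = FALSE` a single +/-`rate` perturbation at
#' step-scaled magnitude is applied instead of compounding.
#'
#' @param base matrix of base vectors (rows), default
#'   [base_abundance_vectors()].
#' @param steps vectors per group (default 10).
#' @param rate per-step fractional change (default 0.05).
#' @param cumulative compound the change over steps (default `TRUE`).
#' @return matrix of `nrow(base) * steps` abundance vectors, rows named
#'   `G{g}-{k}`; attributes `group` and `step`.
#' @export
convergent_vectors <- function(base = base_abundance_vectors(), steps = 10,
                               rate = 0.05, cumulative = TRUE) {
  stopifnot(is.matrix(base), steps >= 1, rate > 0, rate < 1)
  apply(base, 1L, .check_abundance)
  out <- matrix(NA_real_, nrow(base) * steps, ncol(base))
  colnames(out) <- colnames(base)
  grp <- integer(0); stp <- integer(0); labs <- character(0)
  row <- 0L
  for (g in seq_len(nrow(base))) {
    v0 <- base[g, ]
    hi <- v0 > mean(v0)   # classification fixed at the base vector
    for (k in seq_len(steps)) {
      f <- if (cumulative) {
        ifelse(hi, (1 - rate)^k, (1 + rate)^k)
      } else {
        ifelse(hi, 1 - rate * k, 1 + rate * k)
      }
      v <- v0 * f
      v <- v / sum(v)
      row <- row + 1L
      out[row, ] <- v
      grp <- c(grp, g); stp <- c(stp, k)
      labs <- c(labs, sprintf("G%d-%d", g, k))
    }
  }
  rownames(out) <- labs
  structure(out, group = grp, step = stp, scheme = "convergent")
}

#' Gaussian-noise abundance vectors
#'
#' From each base vector, generates `reps` randomized vectors by adding to
#' each component the absolute value of one-fifth Gaussian noise with mean
#' zero and standard deviation equal to that component
#' (`c + |N(0, c)| / 5`), then renormalizing.
#'
#' @inheritParams convergent_vectors
#' @param reps randomized vectors per base (default 10).
#' @param seed integer seed.
#' @return matrix of `nrow(base) * reps` abundance vectors, rows `G{g}-{k}`;
#'   attributes `group` and `step`.
#' @export
gaussian_vectors <- function(base = base_abundance_vectors(), reps = 10,
                             seed = 1L) {
  stopifnot(is.matrix(base), reps >= 1)
  apply(base, 1L, .check_abundance)
  with_seed(seed, {
    out <- matrix(NA_real_, nrow(base) * reps, ncol(base))
    colnames(out) <- colnames(base)
    grp <- integer(0); stp <- integer(0); labs <- character(0)
    row <- 0L
    for (g in seq_len(nrow(base))) {
      v0 <- base[g, ]
      for (k in seq_len(reps)) {
        v <- v0 + abs(rnorm(length(v0), 0, v0)) / 5
        v <- v / sum(v)
        row <- row + 1L
        out[row, ] <- v
        grp <- c(grp, g); stp <- c(stp, k)
        labs <- c(labs, sprintf("G%d-%d", g, k))
      }
    }
    rownames(out) <- labs
    structure(out, group = grp, step = stp, scheme = "gaussian")
  })
}

#' Generate divergent synthetic genomes with embedded protein-coding genes
#'
#' Builds `n_species` nucleotide genomes from a common ancestral gene set:
#' each gene is a random protein (starting with M) reverse-translated through
#' random synonymous codons, mutated per species at `divergence` per residue,
#' embedded as an ORF (ATG ... stop) in the genome, and separated by random
#' intergenic sequence; gene order is shuffled per species. Species thereby
#' share homologous but divergent gene content, emulating related community
#' members.
#'
#' @param n_species number of genomes (default 5).
#' @param n_genes genes per genome (default 100).
#' @param genome_len genome length in nt (default 50000).
#' @param protein_len_range min/max protein length in residues
#'   (default `c(100, 160)`, so every ORF is >= 300 nt).
#' @param divergence per-residue substitution probability applied
#'   independently per species (default 0.3, keeping cross-species best hits
#'   rare).
#' @param seed integer seed.
#' @return a `genome_set`: list with `genomes` (named nt strings), `genes`
#'   (data frame: `species`, `gene_id`, `family`, `start`, `end`, `protein`),
#'   `params`, `seed`.
#' @export
make_genomes <- function(n_species = 5, n_genes = 100, genome_len = 50000,
                         protein_len_range = c(100, 160), divergence = 0.3,
                         seed = 1L) {
  stopifnot(n_species >= 2, n_genes >= 1, length(protein_len_range) == 2L,
            protein_len_range[1L] >= 2, divergence >= 0, divergence <= 1)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]
  codons_of <- split(names(gc)[gc != "*"], gc[gc != "*"])
  max_gene_nt <- 3 * (protein_len_range[2L] + 2)
  if (genome_len < 10 * max_gene_nt)
    stop("genome_len must be at least 10x the maximum gene length (",
         10 * max_gene_nt, " nt)")
  with_seed(seed, {
    lens <- sample(seq(protein_len_range[1L], protein_len_range[2L]),
                   n_genes, replace = TRUE)
    ancestral <- vapply(lens, function(L)
      paste0("M", paste(sample(aa20, L - 1L, replace = TRUE), collapse = "")),
      "")
    coding_nt <- sum(3 * (lens + 1))  # codons incl. the M start, plus stop
    if (coding_nt > 0.95 * genome_len)
      stop("infeasible packing: ", coding_nt, " coding nt into ",
           genome_len, " nt genome")
    genomes <- character(n_species)
    gene_rows <- list()
    for (s in seq_len(n_species)) {
      ordg <- sample.int(n_genes)
      prots <- vapply(ancestral[ordg], function(p) {
        res <- strsplit(p, "")[[1]]
        mut <- which(runif(length(res)) < divergence)
        mut <- mut[mut > 1L]  # keep the start residue
        if (length(mut)) {
          res[mut] <- vapply(res[mut], function(old)
            sample(setdiff(aa20, old), 1L), "")
        }
        paste(res, collapse = "")
      }, "", USE.NAMES = FALSE)
      orfs <- vapply(prots, function(p) {
        res <- strsplit(p, "")[[1]]
        paste0(paste(vapply(res, function(a)
          sample(codons_of[[a]], 1L), ""), collapse = ""),
          sample(stops, 1L))
      }, "", USE.NAMES = FALSE)
      orf_nt <- nchar(orfs)
      spare <- genome_len - sum(orf_nt)
      if (spare < n_genes)
        stop("infeasible packing: ", sum(orf_nt), " coding nt leave too ",
             "little intergenic room in a ", genome_len, " nt genome")
      cuts <- sort(sample.int(spare, n_genes))
      gaps <- diff(c(0L, cuts))
      tail_gap <- spare - sum(gaps)
      pieces <- character(2L * n_genes + 1L)
      pos <- 0L
      starts <- integer(n_genes)
      rand_nt <- function(k) {
        if (k <= 0L) return("")
        paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
      }
      for (i in seq_len(n_genes)) {
        pieces[2L * i - 1L] <- rand_nt(gaps[i])
        pos <- pos + gaps[i]
        starts[i] <- pos + 1L
        pieces[2L * i] <- orfs[i]
        pos <- pos + orf_nt[i]
      }
      pieces[2L * n_genes + 1L] <- rand_nt(tail_gap)
      genomes[s] <- paste(pieces, collapse = "")
      gene_rows[[s]] <- data.frame(
        species = sprintf("sp%d", s),
        gene_id = sprintf("sp%d_g%03d", s, seq_len(n_genes)),
        family = ordg,
        start = starts,
        end = starts + orf_nt - 1L,
        protein = prots,
        stringsAsFactors = FALSE)
    }
    names(genomes) <- sprintf("sp%d", seq_len(n_species))
    structure(list(genomes = genomes, genes = do.call(rbind, gene_rows),
                   params = list(n_species = n_species, n_genes = n_genes,
                                 genome_len = genome_len,
                                 protein_len_range = protein_len_range,
                                 divergence = divergence),
                   seed = seed),
              class = "genome_set")
  })
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set>", length(x$genomes), "genomes of",
      x$params$genome_len, "nt,", x$params$n_genes, "genes each; divergence",
      x$params$divergence, "; seed", x$seed, "\n")
  invisible(x)
}

#' Bind genomes and an abundance vector into a synthetic community
#'
#' @param genomes a `genome_set` from [make_genomes()].
#' @param abundance non-negative proportions, one per genome (renormalized to
#'   sum 1; names, if any, must match the genome labels).
#' @param id community/sample label.
#' @return a `synthetic_community`.
#' @export
synthetic_community <- function(genomes, abundance, id = "community") {
  stopifnot(inherits(genomes, "genome_set"),
            length(abundance) == length(genomes$genomes))
  if (!is.null(names(abundance)) &&
      !identical(names(abundance), names(genomes$genomes)))
    stop("abundance labels do not match genome labels")
  if (any(abundance < 0) || sum(abundance) <= 0)
    stop("abundance must be non-negative with positive sum")
  abundance <- abundance / sum(abundance)
  names(abundance) <- names(genomes$genomes)
  structure(list(id = id, genomes = genomes, abundance = abundance),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community>", x$id, "-", length(x$abundance), "species\n")
  print(round(x$abundance, 4))
  invisible(x)
}

#' Sample shotgun reads from a synthetic community
#'
#' Reads are drawn from the member genomes with multinomial counts
#' proportional to abundance times genome length, uniform start positions,
#' random strand, and independent per-base substitution errors.
#'
#' @param comm a [synthetic_community()].
#' @param n_reads total reads.
#' @param read_len read length in nt (default 200).
#' @param error_rate per-base substitution probability (default 0).
#' @param seed integer seed.
#' @return a [read_set()].
#' @export
sample_reads <- function(comm, n_reads, read_len = 200, error_rate = 0,
                         seed = 1L) {
  stopifnot(inherits(comm, "synthetic_community"), n_reads >= 1,
            error_rate >= 0, error_rate < 1)
  glen <- nchar(comm$genomes$genomes)
  if (read_len > min(glen)) stop("read_len exceeds the shortest genome")
  w <- comm$abundance * glen
  w <- w / sum(w)
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n_reads, w))
    seqs <- character(n_reads)
    ids <- character(n_reads)
    pos <- 0L
    for (s in seq_along(glen)) {
      k <- counts[s]
      if (k == 0L) next
      starts <- sample.int(glen[s] - read_len + 1L, k, replace = TRUE)
      frag <- substring(comm$genomes$genomes[s], starts, starts + read_len - 1L)
      rc <- runif(k) < 0.5
      if (any(rc))
        frag[rc] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(frag[rc])))
      seqs[pos + seq_len(k)] <- frag
      ids[pos + seq_len(k)] <- sprintf("%s_r%06d",
                                       names(comm$abundance)[s], seq_len(k))
      pos <- pos + k
    }
    if (error_rate > 0) {
      m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = read_len)
      hit <- which(matrix(runif(length(m)) < error_rate, nrow = read_len))
      if (length(hit)) {
        nts <- c("A", "C", "G", "T")
        m[hit] <- vapply(m[hit], function(old)
          sample(setdiff(nts, old), 1L), "")
        seqs <- apply(m, 2L, paste, collapse = "")
      }
    }
    read_set(comm$id, ids, seqs)
  })
}

#' Proteome of a synthetic community (assembly-free shortcut)
#'
#' Translates the embedded genes of each member genome directly into a
#' [proteome()], bypassing read sampling, assembly, and gene calling so the
#' similarity stage can be exercised on its own. Each species' per-gene
#' k-tuple coverage is `n_species * mean_coverage * abundance` (i.e.
#' `mean_coverage` at uniform composition), and, mirroring assembly of a
#' finite read set, only a fraction `1 - exp(-coverage)` of a species' genes
#' is recovered (the Poisson probability that a locus is covered at all):
#' low-abundance members lose part of their gene complement, which is how
#' abundance shifts translate into proteome differences. Recovery is
#' deterministic - the first `round(fraction * n_genes)` genes in the
#' species' fixed gene order - so equal abundances always yield equal
#' proteomes. Set `detect = FALSE` to translate every gene regardless of
#' coverage.
#'
#' @param comm a [synthetic_community()].
#' @param mean_coverage per-species k-tuple coverage at uniform abundance
#'   (default 2).
#' @param detect emulate coverage-dependent gene recovery (default `TRUE`).
#' @return a [proteome()] with all-complete flags and abundance-proportional
#'   coverages.
#' @export
community_proteome <- function(comm, mean_coverage = 2, detect = TRUE) {
  stopifnot(inherits(comm, "synthetic_community"), mean_coverage > 0)
  genes <- comm$genomes$genes
  n_sp <- length(comm$abundance)
  ids <- character(0); seqs <- character(0); covs <- numeric(0)
  for (s in seq_len(n_sp)) {
    sp <- names(comm$abundance)[s]
    ab <- comm$abundance[[s]]
    if (ab <= 0) next
    g <- genes[genes$species == sp, , drop = FALSE]
    cov <- n_sp * mean_coverage * ab
    k <- if (detect) round(nrow(g) * (1 - exp(-cov))) else nrow(g)
    if (k == 0L) next
    g <- g[seq_len(k), , drop = FALSE]
    ids <- c(ids, g$gene_id)
    seqs <- c(seqs, g$protein)
    covs <- c(covs, rep(cov, k))
  }
  proteome(comm$id, ids, seqs, coverage = covs,
           has_start = TRUE, has_stop = TRUE)
}

#' Generate a full set of simulated community proteomes
#'
#' Convenience wrapper: one shared [make_genomes()] genome set, one
#' [synthetic_community()] per abundance vector, translated by
#' [community_proteome()].
#'
#' @param vectors abundance-vector matrix (rows = samples), e.g. from
#'   [convergent_vectors()] or [gaussian_vectors()].
#' @param genomes optional `genome_set`; by default built from `seed`.
#' @param mean_coverage,detect passed to [community_proteome()].
#' @param seed integer seed for the default genome set.
#' @return named list of [proteome()] objects.
#' @export
simulate_proteomes <- function(vectors, genomes = NULL, mean_coverage = 2,
                               detect = TRUE, seed = 1L) {
  stopifnot(is.matrix(vectors))
  if (is.null(genomes))
    genomes <- make_genomes(n_species = ncol(vectors), seed = seed)
  out <- lapply(rownames(vectors), function(lab) {
    comm <- synthetic_community(genomes, vectors[lab, ], id = lab)
    community_proteome(comm, mean_coverage = mean_coverage, detect = detect)
  })
  names(out) <- rownames(vectors)
  out
}
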