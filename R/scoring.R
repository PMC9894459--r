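#' Alignment scoring parameters
#'
#' Scoring configuration for local protein alignment and e-value reporting:
#' substitution matrix, affine gap penalties, and Karlin-Altschul parameters
#' used to convert raw Smith-Waterman scores to bit scores. Defaults match the
#' standard BLASTP configuration (BLOSUM62, gap existence 11, extension 1,
#' gapped lambda 0.267 and K 0.041, reporting threshold e-value 10).
#'
#' @param matrix substitution matrix name (a matrix shipped with Biostrings,
#'   e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul parameters for the chosen scheme.
#' @param max_evalue hits with e-value above this are treated as absent.
#' @return a `scoring_params` list.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, max_evalue = 10) {
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0, max_evalue > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, max_evalue = max_evalue),
            class = "scoring_params")
}

.substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

.bits <- function(raw, scoring) {
  (scoring$lambda * raw - log(scoring$K)) / log(2)
}

# e-value from a bit score: E = m * n * 2^(-bits); m = query length,
# n = effective target search space in residues
.evalue <- function(bits, m, n) m * n * 2^(-bits)

#' Score a local protein alignment
#'
#' Smith-Waterman local alignment of two amino-acid sequences under the
#' configured substitution matrix and affine gap penalties, reported as a raw
#' score, a bit score, and an e-value for a search space of
#' `nchar(a) * nchar(b)` residues.
#'
#' @param a,b amino-acid sequences (single strings).
#' @param scoring a [scoring_params()].
#' @return list with `raw`, `score` (bits), `evalue`.
#' @export
align_score <- function(a, b, scoring = scoring_params()) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(a)) ||
      grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(b)))
    stop("sequences contain illegal amino-acid characters")
  mat <- .substitution_matrix(scoring$matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  raw <- Biostrings::score(pa)
  bits <- .bits(raw, scoring)
  list(raw = raw, score = bits, evalue = .evalue(bits, nchar(a), nchar(b)))
}

# all-vs-all bit scores over a set of unique sequences ----------------------

# returns list(hits = data.frame(q, s, bits), self = numeric bit scores)
.hits_exact <- function(seqs, scoring) {
  n <- length(seqs)
  mat <- .substitution_matrix(scoring$matrix)
  pat <- Biostrings::AAStringSet(seqs)
  qs <- integer(0); ss <- integer(0); bb <- numeric(0)
  for (j in seq_len(n)) {
    raw <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(seqs[j]), type = "local",
      substitutionMatrix = mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
    qs <- c(qs, seq_len(n)); ss <- c(ss, rep.int(j, n)); bb <- c(bb, raw)
  }
  bits <- .bits(bb, scoring)
  self <- bits[qs == ss][order(qs[qs == ss])]
  list(hits = data.frame(q = qs, s = ss, bits = bits), self = self)
}

.hits_blast <- function(seqs, scoring) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "")
    stop("blastp/makeblastdb not found on PATH; use engine = \"exact\"")
  td <- tempfile("mpassblast"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "u.faa")
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- paste0("u", seq_along(seqs))
  Biostrings::writeXStringSet(x, fa)
  db <- file.path(td, "db")
  out <- file.path(td, "hits.tsv")
  st <- system2("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed (exit ", st, ")")
  st <- system2("blastp",
                c("-query", fa, "-db", db, "-out", out,
                  "-outfmt", shQuote("6 qseqid sseqid bitscore"),
                  "-evalue", format(scoring$max_evalue),
                  "-matrix", scoring$matrix,
                  "-gapopen", scoring$gap_open, "-gapextend", scoring$gap_extend,
                  "-max_target_seqs", "1000000", "-num_threads", "1"),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastp failed (exit ", st, ")")
  tab <- read.table(out, sep = "\t", header = FALSE,
                    col.names = c("q", "s", "bits"),
                    colClasses = c("character", "character", "numeric"))
  q <- as.integer(sub("^u", "", tab$q))
  s <- as.integer(sub("^u", "", tab$s))
  # several HSPs per pair are possible; keep the best
  key <- paste(q, s)
  best <- tapply(tab$bits, key, max)
  kq <- as.integer(sub(" .*", "", names(best)))
  ks <- as.integer(sub(".* ", "", names(best)))
  hits <- data.frame(q = kq, s = ks, bits = as.numeric(best))
  self <- rep(NA_real_, length(seqs))
  sh <- hits[hits$q == hits$s, ]
  self[sh$q] <- sh$bits
  if (anyNA(self)) {
    # exact self-hits are always significant; recover any that blast dropped
    miss <- which(is.na(self))
    mat <- .substitution_matrix(scoring$matrix)
    for (i in miss) {
      res <- strsplit(seqs[i], "")[[1]]
      self[i] <- .bits(sum(mat[cbind(res, res)]), scoring)
    }
  }
  list(hits = hits, self = self)
}

.choose_engine <- function(engine, n_unique) {
  if (engine != "auto") return(engine)
  if (n_unique > 60 && Sys.which("blastp") != "") "blast" else "exact"
}

.hits_universe <- function(seqs, scoring, engine = "auto") {
  engine <- .choose_engine(engine, length(seqs))
  res <- switch(engine,
                exact = .hits_exact(seqs, scoring),
                blast = .hits_blast(seqs, scoring),
                stop("unknown engine: ", engine))
  res$engine <- engine
  res
}

# map each proteome's records onto the unique-sequence universe
.universe_of <- function(proteomes) {
  seqs <- unique(unlist(lapply(proteomes, function(p) p$records$sequence),
                        use.names = FALSE))
  maps <- lapply(proteomes, function(p) match(p$records$sequence, seqs))
  list(seqs = seqs, maps = maps)
}

# best-hit table of one proteome against another from a precomputed universe
.pair_hits <- function(uni, hits, self, iq, it, proteomes, scoring) {
  pq <- proteomes[[iq]]; pt <- proteomes[[it]]
  mq <- uni$maps[[iq]]; mt <- uni$maps[[it]]
  tset <- unique(mt)
  sub <- hits[hits$s %in% tset, , drop = FALSE]
  best_bits <- rep(NA_real_, length(uni$seqs))
  best_s <- rep(NA_integer_, length(uni$seqs))
  if (nrow(sub)) {
    o <- order(sub$q, -sub$bits)
    sub <- sub[o, , drop = FALSE]
    first <- !duplicated(sub$q)
    best_bits[sub$q[first]] <- sub$bits[first]
    best_s[sub$q[first]] <- sub$s[first]
  }
  n_space <- sum(pt$records$length)
  bb <- best_bits[mq]
  ev <- .evalue(bb, pq$records$length, n_space)
  nohit <- is.na(bb) | ev > scoring$max_evalue
  tid <- pt$records$id[match(best_s[mq], mt)]
  tid[nohit] <- NA_character_
  out <- data.frame(
    query_id = pq$records$id,
    target_id = tid,
    best_score = ifelse(nohit, NA_real_, bb),
    evalue = ifelse(nohit, NA_real_, ev),
    self_score = self[mq],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("hit_table", "data.frame"),
            query_sample = pq$sample_id, target_sample = pt$sample_id)
}

#' Best-hit search of one proteome against another
#'
#' For every retained query protein, the maximal-bit-score local alignment
#' against the target proteome (or a no-hit entry when no alignment attains
#' e-value `<= scoring$max_evalue`), together with the query's self-score under
#' the same scoring scheme. E-values use a search space of query length times
#' total target residues.
#'
#' Identical sequences are dereplicated before alignment, so repeated
#' comparisons across many samples that share sequences cost one alignment per
#' unique pair.
#'
#' @param query,target [proteome()] objects (already filtered).
#' @param scoring a [scoring_params()].
#' @param engine `"exact"` (Smith-Waterman in R, exhaustive), `"blast"`
#'   (NCBI blastp on the PATH), or `"auto"` (blast for large problems when
#'   available, exact otherwise).
#' @return a `hit_table` data frame with columns `query_id`, `target_id`,
#'   `best_score` (bits), `evalue`, `self_score`; attributes `query_sample`
#'   and `target_sample`.
#' @export
best_hits <- function(query, target, scoring = scoring_params(),
                      engine = c("auto", "exact", "blast")) {
  engine <- match.arg(engine)
  stopifnot(inherits(query, "proteome"), inherits(target, "proteome"))
  if (nrow(query$records) == 0L || nrow(target$records) == 0L)
    stop("best_hits requires non-empty proteomes")
  prots <- list(query, target)
  uni <- .universe_of(prots)
  hu <- .hits_universe(uni$seqs, scoring, engine)
  .pair_hits(uni, hu$hits, hu$self, 1L, 2L, prots, scoring)
}
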