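#' Construct a proteome
#'
#' A proteome is one sample's set of predicted protein sequences together with
#' the per-gene metadata the distance computation needs: the k-tuple coverage of
#' the encoding contig/gene (a sequencing-depth proxy used as the gene weight)
#' and completeness flags (whether the encoding nucleotide sequence carried a
#' start and a stop codon).
#'
#' @param sample_id sample label.
#' @param id character vector of unique protein ids.
#' @param sequence character vector of amino-acid sequences (20-letter alphabet
#'   plus `X`).
#' @param coverage non-negative numeric vector, recycled; defaults to 1.
#' @param has_start,has_stop logical vectors, recycled; default `TRUE`.
#' @return An object of class `proteome`: a list with `sample_id` and a
#'   `records` data frame (`id`, `sequence`, `length`, `coverage`, `has_start`,
#'   `has_stop`).
#' @export
proteome <- function(sample_id, id, sequence, coverage = 1,
                     has_start = TRUE, has_stop = TRUE) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id))
    stop("duplicate protein ids in sample '", sample_id, "': ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(sequence) != length(id))
    stop("'id' and 'sequence' lengths differ")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad))
    stop("illegal amino-acid characters in records: ",
         paste(head(id[bad], 5L), collapse = ", "))
  n <- length(id)
  rec <- data.frame(
    id = id,
    sequence = sequence,
    length = nchar(sequence),
    coverage = rep_len(as.numeric(coverage), n),
    has_start = rep_len(as.logical(has_start), n),
    has_stop = rep_len(as.logical(has_stop), n),
    stringsAsFactors = FALSE
  )
  if (any(rec$coverage < 0 | !is.finite(rec$coverage)))
    stop("coverage must be finite and >= 0")
  structure(list(sample_id = sample_id, records = rec), class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("<proteome> sample:", x$sample_id, "-", nrow(x$records), "proteins\n")
  if (nrow(x$records)) {
    cat("  length:", min(x$records$length), "-", max(x$records$length),
        "aa; coverage:", signif(min(x$records$coverage), 4), "-",
        signif(max(x$records$coverage), 4), "\n")
    cat("  complete (start & stop):",
        sum(x$records$has_start & x$records$has_stop), "\n")
  }
  invisible(x)
}

#' @export
length.proteome <- function(x) nrow(x$records)

#' Construct a read set
#'
#' A read set is a sample's collection of short nucleotide reads, optionally
#' with per-base quality strings.
#'
#' @param sample_id sample label.
#' @param id read ids.
#' @param seq nucleotide sequences (alphabet A, C, G, T, N).
#' @param qual optional quality strings (same lengths as `seq`) or `NULL`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(sample_id, id, seq, qual = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("'id' and 'seq' lengths differ")
  if (any(nchar(seq) == 0L)) stop("empty read sequences are not allowed")
  if (any(grepl("[^ACGTN]", seq)))
    stop("reads contain characters outside {A,C,G,T,N}")
  if (!is.null(qual)) {
    qual <- as.character(qual)
    if (length(qual) != length(seq) || any(nchar(qual) != nchar(seq)))
      stop("quality strings must match read lengths")
  }
  structure(list(sample_id = sample_id, id = id, seq = seq, qual = qual),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$seq)

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> sample:", x$sample_id, "-", length(x$seq), "reads",
      if (!is.null(x$qual)) "(with qualities)" else "", "\n")
  invisible(x)
}

#' Parse coverage and completeness metadata from a FASTA header
#'
#' Assemblers and gene callers encode per-gene depth and completeness in their
#' deflines. Three dialects are recognized:
#' \describe{
#'   \item{`"assembler"`}{contig-style names carrying a `_cov_` token, e.g.
#'     `NODE_12_length_3400_cov_8.31`; completeness flags default to `TRUE`.}
#'   \item{`"genecaller"`}{gene-caller style `partial=XY` flags (Prodigal
#'     convention: `0` = that end intact, first digit is the start), plus an
#'     optional `cov=` field.}
#'   \item{`"native"`}{explicit `key=value` fields as written by
#'     [write_proteome()]: `id|cov=12.5|complete` or `id|cov=1|partial=01`.}
#' }
#'
#' @param header defline (without the leading `>`).
#' @param dialect one of `"native"`, `"assembler"`, `"genecaller"`.
#' @param strict if `TRUE`, an unrecognized header is an error; otherwise it
#'   yields coverage 1 and complete flags, with a warning.
#' @return list with `coverage`, `has_start`, `has_stop`.
#' @export
parse_coverage_header <- function(header,
                                  dialect = c("native", "assembler", "genecaller"),
                                  strict = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(header), length(header) == 1L)
  cov <- NA_real_
  hs <- NA
  he <- NA
  if (dialect == "assembler") {
    m <- regmatches(header, regexec("_cov_([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)", header))[[1]]
    if (length(m) >= 2L) {
      cov <- as.numeric(m[2L])
      hs <- he <- TRUE
    }
  } else {
    mc <- regmatches(header, regexec("cov=([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)", header))[[1]]
    if (length(mc) >= 2L) cov <- as.numeric(mc[2L])
    if (grepl("(\\||;|\\s)complete(\\s|$|\\|)", paste0("|", header, "|"))) {
      hs <- he <- TRUE
    } else {
      mp <- regmatches(header, regexec("partial=([01])([01])", header))[[1]]
      if (length(mp) == 3L) {
        hs <- mp[2L] == "0"
        he <- mp[3L] == "0"
      }
    }
    if (dialect == "native" && !is.na(cov) && is.na(hs)) {
      # cov= present but no completeness field: treat as complete
      hs <- he <- TRUE
    }
  }
  if (is.na(cov) && is.na(hs)) {
    if (strict)
      stop("header not recognized under dialect '", dialect, "': ", header)
    warning("header not recognized (dialect '", dialect,
            "'); defaulting to coverage 1, complete: ", header)
    return(list(coverage = 1, has_start = TRUE, has_stop = TRUE))
  }
  if (is.na(cov)) cov <- 1
  if (is.na(hs)) hs <- TRUE
  if (is.na(he)) he <- TRUE
  list(coverage = cov, has_start = hs, has_stop = he)
}

#' Read a protein FASTA file into a proteome
#'
#' Header metadata (coverage, completeness) is parsed per
#' [parse_coverage_header()]. The record id is the first `|`- or
#' whitespace-delimited token of the defline.
#'
#' @param path FASTA file.
#' @param sample_id sample label; default the file base name without extension.
#' @inheritParams parse_coverage_header
#' @return a [proteome()].
#' @export
read_proteome <- function(path, sample_id = NULL,
                          dialect = c("native", "assembler", "genecaller"),
                          strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(proteome(sample_id, character(), character()))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA (no header line) at line ", nonblank[1L], " of ", path)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "[|[:space:]]"), `[`, "", 1L)
  meta <- lapply(headers, parse_coverage_header, dialect = dialect, strict = strict)
  proteome(sample_id,
           id = ids,
           sequence = as.character(aa),
           coverage = vapply(meta, `[[`, 0, "coverage"),
           has_start = vapply(meta, `[[`, TRUE, "has_start"),
           has_stop = vapply(meta, `[[`, TRUE, "has_stop"))
}

#' Write a proteome as FASTA in the native header dialect
#'
#' Deflines are `id|cov={coverage}|complete` or `id|cov={coverage}|partial=XY`
#' (digit 1 marks a missing start/stop respectively), so that
#' [read_proteome()] round-trips all metadata.
#'
#' @param p a [proteome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(p, path) {
  stopifnot(inherits(p, "proteome"))
  r <- p$records
  flag <- ifelse(r$has_start & r$has_stop, "complete",
                 paste0("partial=", as.integer(!r$has_start),
                        as.integer(!r$has_stop)))
  aa <- Biostrings::AAStringSet(r$sequence)
  names(aa) <- sprintf("%s|cov=%s|%s", r$id, format(r$coverage, trim = TRUE,
                                                    scientific = FALSE), flag)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file.
#' @param sample_id sample label; default the file base name.
#' @return a [read_set()] with qualities.
#' @export
read_reads <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # cosmetic upstream notice about dropped metadata columns
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  read_set(sample_id,
           id = vapply(strsplit(names(x), "[[:space:]]"), `[`, "", 1L),
           seq = as.character(x),
           qual = as.character(Biostrings::quality(x)))
}

#' Write a read set as FASTQ
#'
#' @param rs a [read_set()]; reads without qualities get flat `I` (Q40).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  x <- Biostrings::DNAStringSet(rs$seq)
  names(x) <- rs$id
  qual <- if (is.null(rs$qual)) strrep("I", nchar(rs$seq)) else rs$qual
  x <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(Biostrings::BStringSet(qual)))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Trim reads to a maximum length
#'
#' Keeps the 5' prefix of each read (FASTX-Toolkit convention); reads already
#' at or below `max_len` are unchanged and order is preserved.
#'
#' @param rs a [read_set()].
#' @param max_len maximum retained length (>= 1).
#' @return the trimmed [read_set()].
#' @export
trim_reads <- function(rs, max_len) {
  stopifnot(inherits(rs, "read_set"), max_len >= 1)
  seq <- substr(rs$seq, 1L, max_len)
  qual <- if (is.null(rs$qual)) NULL else substr(rs$qual, 1L, max_len)
  read_set(rs$sample_id, rs$id, seq, qual)
}

#' Down-sample reads without replacement
#'
#' Uniform sampling without replacement to exactly `n` reads, reproducible by
#' `seed`; relative read order is preserved. Used to equalize sequencing effort
#' across samples before comparison (down-sample every sample to the smallest
#' library).
#'
#' @param rs a [read_set()].
#' @param n number of reads to keep (`n <= length(rs)`).
#' @param seed integer seed.
#' @return the down-sampled [read_set()].
#' @export
downsample_reads <- function(rs, n, seed = 1L) {
  stopifnot(inherits(rs, "read_set"))
  total <- length(rs$seq)
  if (n > total)
    stop("cannot sample ", n, " reads: only ", total, " available")
  keep <- sort(with_seed(seed, sample.int(total, n)))
  read_set(rs$sample_id, rs$id[keep], rs$seq[keep],
           if (is.null(rs$qual)) NULL else rs$qual[keep])
}

#' Remove partial and short predicted proteins
#'
#' Predicted proteins whose encoding sequences lack a start or a stop codon
#' (partial genes at contig edges) and proteins shorter than `min_len` residues
#' are removed before proteome comparison; very short predictions are enriched
#' for assembly artifacts. The length cut is strict: a protein of exactly
#' `min_len` residues is retained.
#'
#' @param p a [proteome()].
#' @param min_len minimum retained length in residues (default 100).
#' @param require_complete drop records lacking a start or stop flag
#'   (default `TRUE`).
#' @return the filtered [proteome()]; attribute `"removed"` holds counts by
#'   reason (`short`, `partial`).
#' @export
filter_proteome <- function(p, min_len = 100, require_complete = TRUE) {
  stopifnot(inherits(p, "proteome"))
  r <- p$records
  short <- r$length < min_len
  partial <- if (require_complete) !(r$has_start & r$has_stop) else rep(FALSE, nrow(r))
  keep <- !short & !partial
  out <- p
  out$records <- r[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "removed") <- c(short = sum(short), partial = sum(partial & !short))
  out
}
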