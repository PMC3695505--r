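#' @import data.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib duprec, .registration = TRUE
NULL

#' Construct genomic intervals
#'
#' Internal coordinates are 0-based, half-open throughout the package; SAM
#' and BED conversions happen exclusively in the readers and writers.
#'
#' @param chrom Sequence names.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param strand `"+"`, `"-"` or `"*"` (unknown).
#' @param genome Optional named character vector of sequences used to
#'   validate interval bounds.
#' @return A `data.table` with columns chrom, start, end, strand.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*", genome = NULL) {
  gi <- data.table(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = strand)
  if (any(gi$start < 0L) || any(gi$start >= gi$end))
    stop("invalid interval: need 0 <= start < end")
  if (!is.null(genome)) {
    len <- nchar(genome)[gi$chrom]
    if (anyNA(len)) stop("interval on unknown sequence")
    if (any(gi$end > len)) stop("interval exceeds sequence length")
  }
  gi[]
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; IUPAC ambiguity codes are preserved.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA in ", path, ": ",
                                          conditionMessage(e)))
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Write paired reads to a pair of FASTQ files
#'
#' @param reads `data.table` with columns qname, seq1, qual1, seq2, qual2
#'   (as produced by [simulate_reads()]).
#' @param prefix Output prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @param seed Seed recorded in a leading comment of each file.
#' @export
write_fastq <- function(reads, prefix, seed = NA_integer_) {
  for (mate in 1:2) {
    path <- sprintf("%s_%d.fastq", prefix, mate)
    sq <- if (mate == 1L) reads$seq1 else reads$seq2
    ql <- if (mate == 1L) reads$qual1 else reads$qual2
    lines <- as.vector(rbind(paste0("@", reads$qname, "/", mate), sq, "+", ql))
    writeLines(lines, path)
  }
  invisible(prefix)
}

#' Read candidate regions from a BED-like file
#'
#' Tab-separated, at least three columns; header and `#` comment lines are
#' skipped; rows with `start >= end` are rejected with a message.
#'
#' @param path BED file.
#' @param genome Optional genome (named character vector) for bounds checks.
#' @return `data.table` of intervals (see [genomic_interval()]).
#' @export
read_regions <- function(path, genome = NULL) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !grepl("^(#|track|browser)", ln)]
  if (!length(ln))
    return(genomic_interval(character(0), integer(0), integer(0))[0])
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("BED row with fewer than 3 columns in ", path)
  dt <- data.table(chrom = vapply(parts, `[`, "", 1L),
                   start = as.integer(vapply(parts, `[`, "", 2L)),
                   end = as.integer(vapply(parts, `[`, "", 3L)))
  drop <- is.na(dt$start) | is.na(dt$end) | dt$start >= dt$end | dt$start < 0L
  if (any(drop)) {
    message(sum(drop), " region(s) rejected (start >= end or malformed)")
    dt <- dt[!drop]
  }
  genomic_interval(dt$chrom, dt$start, dt$end, genome = genome)
}

#' Write intervals as BED
#' @param regions Interval `data.table`.
#' @param path Output file.
#' @export
write_regions <- function(regions, path) {
  fwrite(regions[, .(chrom, start, end)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

# ---- SAM -------------------------------------------------------------------

# Alignment tables carry one row per read end, SAM conventions (sequence
# stored reference-oriented when mapped to the minus strand), but 0-based
# positions.  Columns: qname, mate, mapped, chrom, pos, strand, mapq, ed,
# alen, seq, qual, proper.

#' Read paired-end alignments from a SAM file
#'
#' Primary alignments only.  MAPQ, sequence and qualities are preserved;
#' 1-based SAM positions are converted to the internal 0-based convention.
#'
#' @param path SAM file (text).
#' @param region Optional interval; only pairs with at least one end
#'   overlapping the interval are returned (the mate is kept regardless of
#'   where it maps).
#' @return Alignment `data.table`, one row per read end.
#' @export
read_alignments <- function(path, region = NULL) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln)) return(empty_alignments())
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- vapply(f, length, 1L)
  if (any(nf < 11L)) stop("truncated SAM record in ", path)
  flag <- as.integer(vapply(f, `[`, "", 2L))
  keep <- bitwAnd(flag, 0x900L) == 0L   # drop secondary/supplementary
  f <- f[keep]; flag <- flag[keep]
  ed <- vapply(f, function(x) {
    nm <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(nm)) as.integer(sub("^NM:i:", "", nm[1])) else NA_integer_
  }, 1L)
  aln <- data.table(
    qname = vapply(f, `[`, "", 1L),
    mate = ifelse(bitwAnd(flag, 0x40L) > 0L, 1L,
                  ifelse(bitwAnd(flag, 0x80L) > 0L, 2L, 1L)),
    mapped = bitwAnd(flag, 0x4L) == 0L,
    chrom = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+"),
    mapq = as.integer(vapply(f, `[`, "", 5L)),
    ed = ed,
    seq = vapply(f, `[`, "", 10L),
    qual = vapply(f, `[`, "", 11L),
    proper = bitwAnd(flag, 0x2L) > 0L)
  aln[mapped == FALSE, `:=`(chrom = NA_character_, pos = NA_integer_,
                            strand = NA_character_, ed = NA_integer_)]
  aln[, alen := nchar(seq)]
  unpaired <- bitwAnd(flag, 0x1L) == 0L
  if (any(unpaired)) {
    warning(sum(unpaired), " unpaired record(s) skipped")
    aln <- aln[!unpaired]
  }
  # drop names that do not form a pair (both mates present exactly once)
  cnt <- aln[, .(n = .N, m = uniqueN(mate)), by = qname]
  bad <- cnt[n != 2L | m != 2L, qname]
  if (length(bad)) {
    warning(length(bad), " read name(s) without a resolvable mate skipped")
    aln <- aln[!qname %in% bad]
  }
  if (!is.null(region)) {
    hit <- aln[mapped == TRUE & chrom == region$chrom[1] &
                 pos < region$end[1] & pos + alen > region$start[1], qname]
    aln <- aln[qname %in% unique(hit)]
  }
  setkey(aln, qname, mate)
  aln[]
}

empty_alignments <- function() {
  data.table(qname = character(0), mate = integer(0), mapped = logical(0),
             chrom = character(0), pos = integer(0), strand = character(0),
             mapq = integer(0), ed = integer(0), seq = character(0),
             qual = character(0), proper = logical(0), alen = integer(0))
}

#' Write an alignment table to SAM
#'
#' @param aln Alignment `data.table`.
#' @param genome Named character vector (for `@SQ` headers).
#' @param path Output file.
#' @param seed Seed recorded in an `@CO` header line.
#' @export
write_sam <- function(aln, genome, path, seed = NA_integer_) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)),
           sprintf("@CO\tduprec seed=%s", seed))
  a <- copy(aln)
  setorder(a, qname, mate)
  idx1 <- seq(1L, nrow(a), by = 2L)
  idx2 <- idx1 + 1L
  flag <- integer(nrow(a))
  for (k in 1:2) {
    self <- if (k == 1) idx1 else idx2
    other <- if (k == 1) idx2 else idx1
    fl <- 0x1L + (if (k == 1) 0x40L else 0x80L)
    fl <- fl + ifelse(a$mapped[self], 0L, 0x4L) +
      ifelse(a$mapped[other], 0L, 0x8L) +
      ifelse(a$mapped[self] & a$strand[self] == "-", 0x10L, 0L) +
      ifelse(a$mapped[other] & a$strand[other] == "-", 0x20L, 0L) +
      ifelse(a$proper[self] & a$mapped[self], 0x2L, 0L)
    flag[self] <- fl
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s%s",
                 a$qname, flag,
                 ifelse(a$mapped, a$chrom, "*"),
                 ifelse(a$mapped, a$pos + 1L, 0L),
                 ifelse(a$mapped, a$mapq, 0L),
                 ifelse(a$mapped, paste0(nchar(a$seq), "M"), "*"),
                 "=", 0L,
                 a$seq, a$qual,
                 ifelse(a$mapped & !is.na(a$ed), sprintf("\tNM:i:%d", a$ed), ""))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# ---- breakpoint calls ------------------------------------------------------

#' Write breakpoint calls to TSV
#'
#' Columns: chrom, pos, score, n_support, n_conflict, zygosity,
#' source_region, homolog_ids.  A `#` header records the seed.
#'
#' @param calls Breakpoint call `data.table`.
#' @param path Output file.
#' @param seed Seed recorded in the header.
#' @export
write_breakpoints <- function(calls, path, seed = NA_integer_) {
  cols <- c("chrom", "pos", "score", "n_support", "n_conflict", "zygosity",
            "source_region", "homolog_ids")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#duprec breakpoints seed=%s", seed), con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(calls)) {
    out <- calls[, cols, with = FALSE]
    writeLines(do.call(sprintf, c(list("%s\t%d\t%.17g\t%d\t%d\t%s\t%s\t%s"),
                                  as.list(out))), con)
  }
  invisible(path)
}

#' Read breakpoint calls written by [write_breakpoints()]
#' @param path TSV file.
#' @return `data.table` of calls.
#' @export
read_breakpoints <- function(path) {
  dt <- fread(path, sep = "\t", skip = 1L, header = TRUE,
              colClasses = list(character = c("chrom", "zygosity",
                                              "source_region", "homolog_ids")))
  dt[, `:=`(pos = as.integer(pos), score = as.numeric(score),
            n_support = as.integer(n_support),
            n_conflict = as.integer(n_conflict))]
  dt[]
}

#' Write reconstructed duplicons to FASTA with provenance headers
#'
#' @param recon List of duplicon reconstructions (see [reconstruct_duplicons()])
#'   or a named character vector of sequences.
#' @param path Output file.
#' @export
write_duplicons <- function(recon, path) {
  if (is.character(recon)) {
    write_fasta(recon, path)
    return(invisible(path))
  }
  seqs <- vapply(recon, function(r) r$consensus, "")
  names(seqs) <- vapply(recon, function(r) {
    sprintf("%s template=%s:%d-%d len=%d", r$id, r$template_chrom,
            r$template_start, r$template_end, nchar(r$consensus))
  }, "")
  write_fasta(seqs, path)
  invisible(path)
}
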