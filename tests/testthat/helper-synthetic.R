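# Shared fixture builders: everything is generated in code at test time.

library(data.table)

rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_r <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# one alignment-table row (SAM conventions, 0-based pos)
aln_row <- function(qname, mate, chrom = NA, pos = NA, strand = NA,
                    seq = strrep("A", 100), qual = strrep("I", nchar(seq)),
                    mapped = !is.na(chrom), mapq = 60L, ed = 0L) {
  data.table(qname = qname, mate = as.integer(mate), mapped = mapped,
             chrom = as.character(chrom), pos = as.integer(pos),
             strand = as.character(strand), mapq = as.integer(mapq),
             ed = as.integer(ed), seq = seq, qual = qual, proper = FALSE,
             alen = nchar(seq))
}

# a pair of rows with sensible defaults
aln_pair <- function(qname, chrom1, pos1, strand1, chrom2, pos2, strand2,
                     genome = NULL, L = 100L) {
  seqof <- function(ch, p, st) {
    if (is.na(ch)) return(rdna(L))
    s <- substr(genome[[ch]], p + 1L, p + L)
    s
  }
  rbind(aln_row(qname, 1L, chrom1, pos1, strand1,
                seq = if (is.null(genome)) strrep("A", L) else
                  seqof(chrom1, pos1, strand1)),
        aln_row(qname, 2L, chrom2, pos2, strand2,
                seq = if (is.null(genome)) strrep("C", L) else
                  seqof(chrom2, pos2, strand2)))
}

# genome with a single clean candidate region (no repeats)
clean_genome <- function(len = 20000L, seed = 11L) {
  set.seed(seed)
  g <- c(chrA = rdna(len))
  g
}

# cache expensive acceptance replicate sets across test files
.duprec_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .duprec_cache))
    assign(key, expr, envir = .duprec_cache)
  get(key, envir = .duprec_cache)
}
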