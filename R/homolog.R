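# Homolog recruitment: find all reference regions highly similar to a
# candidate copy-number-gain region and gather the read pairs anchored to
# any of them.

#' Find homologs of a candidate region
#'
#' The candidate sequence is probed against the genome with fixed-stride
#' subsequences routed through the k-mer mapper; clustered hit diagonals
#' are verified by banded end-gap-free alignment.  A hit is recruited when
#' alignment identity exceeds `config$min_identity` (matches over aligned
#' columns) and the aligned block length is within `config$max_block_diff`
#' of the candidate length.  Reciprocally overlapping hits (>= 50%) are
#' merged.  Only forward-strand homologs are recruited; an inverted copy
#' must be supplied as an explicit template downstream.
#'
#' @param candidate Single interval (see [genomic_interval()]).
#' @param genome Named character vector.
#' @param config A [run_config()].
#' @param index Optional prebuilt genome index.
#' @return Object of class `homology_set`: list with `members` (interval
#'   table, candidate first, with identity and block length), `sequences`,
#'   `flanks` and the candidate sequence `a_h`.
#' @export
find_homologs <- function(candidate, genome, config = run_config(),
                          index = NULL) {
  stopifnot(nrow(candidate) == 1L)
  clen <- candidate$end - candidate$start
  if (clen < 2L * config$kmer) stop("candidate shorter than two seeds")
  a_h <- substr(genome[[candidate$chrom]], candidate$start + 1L, candidate$end)
  if (mean(strsplit(a_h, "")[[1]] == "N") > 0.5)
    stop("candidate overlaps an assembly gap (>50% N); trim the region")
  if (is.null(index)) index <- build_genome_index(genome, config$kmer)

  probe_len <- 48L
  stride <- 24L
  offs <- unique(c(seq(0L, max(0L, clen - probe_len), by = stride),
                   clen - probe_len))
  probes <- substring(a_h, offs + 1L, offs + probe_len)
  hits <- as.data.table(cpp_map_reads(index, probes, 4L, 1L))
  members <- data.table(chrom = candidate$chrom, start = candidate$start,
                        end = candidate$end, strand = "+",
                        identity = 1, block = as.integer(clen))
  if (nrow(hits)) {
    hits <- hits[strand == 0L]
    hits[, diag := pos - offs[read]]
    setorder(hits, refid, diag)
    tol <- max(64L, as.integer(0.15 * clen))
    hits[, grp := cumsum(c(1L, (diff(diag) > tol) | (diff(refid) != 0L)))]
    cand_grp <- hits[, .(refid = refid[1], dlo = min(diag), dhi = max(diag),
                         n = uniqueN(read)), by = grp]
    # a recruitable homolog (identity > 0.95 over ~the whole candidate)
    # must be hit by a large fraction of the probes; partial block hits
    # (e.g. a shared repeat element) cannot pass the block-size bound, so
    # skip them before the expensive alignment
    min_probes <- max(2L, as.integer(0.4 * length(offs)))
    for (g in seq_len(nrow(cand_grp))) {
      if (cand_grp$n[g] < min_probes) next
      band <- max(64L, cand_grp$dhi[g] - cand_grp$dlo[g] + 128L)
      chrom_g <- names(genome)[cand_grp$refid[g]]
      reflen <- nchar(genome[[chrom_g]])
      wstart <- max(0L, cand_grp$dlo[g] - band)
      wend <- min(reflen, cand_grp$dhi[g] + clen + band)
      # self hit: skip, candidate is already member 1
      if (chrom_g == candidate$chrom &&
          wstart < candidate$end && wend > candidate$start &&
          abs(cand_grp$dlo[g] - candidate$start) < tol) next
      tseq <- substr(genome[[chrom_g]], wstart + 1L, wend)
      al <- cpp_align_endfree(a_h, tseq, config$sw_match, config$sw_mismatch,
                              config$sw_gap_open, config$sw_gap_extend,
                              dlo = -band + (cand_grp$dlo[g] - wstart),
                              dhi = band + (cand_grp$dhi[g] - wstart))
      if (is.na(al$score[1])) next
      if (al$cols == 0L) next
      ident <- al$matches / al$cols
      if (ident <= config$min_identity) next
      if (abs(al$cols - clen) / clen >= config$max_block_diff) next
      members <- rbind(members, data.table(
        chrom = chrom_g, start = wstart + al$tstart, end = wstart + al$tend,
        strand = "+", identity = ident, block = al$cols))
    }
  }
  # merge reciprocal >= 50% overlaps (duplicated windows of the same hit)
  if (nrow(members) > 1L) {
    keep <- rep(TRUE, nrow(members))
    for (i in 2:nrow(members)) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j] || members$chrom[i] != members$chrom[j]) next
        ov <- min(members$end[i], members$end[j]) -
          max(members$start[i], members$start[j])
        li <- members$end[i] - members$start[i]
        lj <- members$end[j] - members$start[j]
        if (ov >= 0.5 * li && ov >= 0.5 * lj) { keep[i] <- FALSE; break }
      }
    }
    members <- members[keep]
  }
  if (nrow(members) > 1L) {
    rest <- members[-1][order(chrom, start)]
    members <- rbind(members[1], rest)
  }
  members[, id := paste0("H", seq_len(.N))]
  lens <- nchar(genome)[members$chrom]
  flanks <- members[, .(id, chrom,
                        left_start = pmax(0L, start - config$flank_width),
                        left_end = start,
                        right_start = end,
                        right_end = pmin(as.integer(lens), end + config$flank_width))]
  sequences <- substring(genome[members$chrom], members$start + 1L,
                         members$end)
  names(sequences) <- members$id
  structure(list(members = members[], sequences = sequences, flanks = flanks,
                 a_h = a_h, candidate = candidate),
            class = "homology_set")
}

#' @export
print.homology_set <- function(x, ...) {
  cat(sprintf("homology set: %d member(s)\n", nrow(x$members)))
  print(x$members[, .(id, chrom, start, end, identity, block)])
  invisible(x)
}

#' Collect mate pairs anchored to a homology set
#'
#' Returns every pair with at least one mapped end overlapping a member or
#' its flank, each pair exactly once.
#'
#' @param hset A `homology_set`.
#' @param aln Alignment table (one row per end).
#' @return Subset of `aln` (both ends of every retained pair).
#' @export
collect_pairs <- function(hset, aln) {
  f <- hset$flanks
  hitnames <- character(0)
  m <- aln[mapped == TRUE]
  for (i in seq_len(nrow(f))) {
    sel <- m[chrom == f$chrom[i] & pos < f$right_end[i] &
               pos + alen > f$left_start[i], qname]
    hitnames <- c(hitnames, sel)
  }
  aln[qname %in% unique(hitnames)]
}

# which member (row index) does a mapped end overlap? 0 = none
member_of <- function(hset, chrom, pos, alen) {
  mb <- hset$members
  out <- integer(length(chrom))
  for (i in seq_len(nrow(mb))) {
    hit <- !is.na(chrom) & chrom == mb$chrom[i] & pos < mb$end[i] &
      (pos + alen) > mb$start[i]
    out[hit & out == 0L] <- i
  }
  out
}

# 0 = none, else member row index whose flank (left or right) is overlapped
flank_of <- function(hset, chrom, pos, alen) {
  f <- hset$flanks
  out <- integer(length(chrom))
  for (i in seq_len(nrow(f))) {
    hit <- !is.na(chrom) & chrom == f$chrom[i] &
      ((pos < f$left_end[i] & pos + alen > f$left_start[i]) |
         (pos < f$right_end[i] & pos + alen > f$right_start[i]))
    out[hit & out == 0L] <- i
  }
  out
}
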