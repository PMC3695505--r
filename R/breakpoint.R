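# Breakpoint detection from discordant one-end reads: genome-wide match
# sets, concordance-preferred discordant pair sets, per-read specificity,
# external-end clustering, orientation composition and zygosity.

#' Enumerate the match set of a read
#'
#' All genomic placements of the read (both strands) with edit distance at
#' most `max_edit`, sorted by (edit distance, position).
#'
#' @param seq Read sequence.
#' @param index Genome index from [build_genome_index()].
#' @param genome Named character vector (for chromosome names).
#' @param max_edit Maximum edit distance.
#' @return `data.table` with chrom, pos, alen, strand, ed.
#' @export
match_set <- function(seq, index, genome, max_edit = 6L) {
  h <- as.data.table(cpp_map_reads(index, seq, as.integer(max_edit), 1L))
  if (!nrow(h))
    return(data.table(chrom = character(0), pos = integer(0),
                      alen = integer(0), strand = character(0),
                      ed = integer(0)))
  out <- h[, .(chrom = names(genome)[refid], pos = pos, alen = alen,
               strand = ifelse(strand == 1L, "-", "+"), ed = ed)]
  setorder(out, ed, chrom, pos)
  out[]
}

#' Preferred discordant paired match set
#'
#' Forms the Cartesian product of two match sets, finds the best concordant
#' paired match c* (lowest summed edit distance; +Inf when none exists) and
#' returns every discordant paired match with summed edit distance strictly
#' below e(c*): a known concordant placement is always preferred unless a
#' discordant one aligns strictly better.
#'
#' @param m1,m2 Match sets from [match_set()].
#' @param config A [run_config()].
#' @return List: `D` (`data.table` of discordant paired matches with
#'   columns of both ends and `e`), `e_cstar`.
#' @export
preferred_discordant_set <- function(m1, m2, config = run_config()) {
  empty <- data.table(chrom1 = character(0), pos1 = integer(0),
                      alen1 = integer(0), strand1 = character(0),
                      ed1 = integer(0), chrom2 = character(0),
                      pos2 = integer(0), alen2 = integer(0),
                      strand2 = character(0), ed2 = integer(0),
                      e = integer(0))
  if (!nrow(m1) || !nrow(m2)) return(list(D = empty, e_cstar = Inf))
  a <- copy(m1); b <- copy(m2)
  setnames(a, paste0(names(a), "1")); setnames(b, paste0(names(b), "2"))
  a[, k := 1L]; b[, k := 1L]
  M <- merge(a, b, by = "k", allow.cartesian = TRUE)[, k := NULL]
  M[, e := ed1 + ed2]
  M[, conc := pair_concordant(chrom1, pos1, alen1, strand1,
                              chrom2, pos2, alen2, strand2, config)]
  e_cstar <- if (any(M$conc)) min(M[conc == TRUE, e]) else Inf
  D <- M[conc == FALSE & e < e_cstar][, conc := NULL]
  list(D = D, e_cstar = e_cstar)
}

#' Specificity score of a preferred discordant paired match
#'
#' `s(d) = 2^-(e(d) - e_min(D)) / n_e(d)` where `n_x` counts elements of D
#' at edit distance x.  The score is 1 exactly when d is the unique
#' minimum-edit-distance element and decays geometrically with excess edit
#' distance and multiplicity.
#'
#' @param e Edit distance of the paired match (may be a vector).
#' @param D The preferred discordant set (its `e` column is used).
#' @return Scores in (0, 1].
#' @export
specificity_score <- function(e, D) {
  if (!nrow(D)) return(numeric(length(e)))
  emin <- min(D$e)
  tab <- table(D$e)
  n_e <- as.integer(tab[as.character(e)])
  n_e[is.na(n_e)] <- 1L
  2^(-(e - emin)) / n_e
}

#' Cluster external ends of discordant one-end reads
#'
#' Single-linkage clustering of external-end positions per chromosome with
#' gap threshold `config$insert_size`.  (With gap threshold equal to the
#' distal threshold, inter-cluster distances always exceed it, so no
#' cluster is dropped as non-distal.)
#'
#' @param ends `data.table` with chrom, pos, alen, strand (one row per
#'   supporting external end).
#' @param config A [run_config()].
#' @return `ends` with a `cluster` integer column.
#' @export
cluster_ends <- function(ends, config = run_config()) {
  if (!nrow(ends)) { ends[, cluster := integer(0)]; return(ends) }
  setorder(ends, chrom, pos)
  gap <- config$insert_size
  newc <- c(TRUE, diff(ends$pos) > gap | ends$chrom[-1] != ends$chrom[-nrow(ends)])
  ends[, cluster := cumsum(newc)]
  ends[]
}

#' Orientation class of an external end relative to a breakpoint
#'
#' Forward reads upstream and reverse reads downstream support an
#' insertion at `b`; the two other combinations are counter-evidence
#' (conflicting reads).  A tolerance of `tol` bp absorbs reads whose
#' alignment was stretched a few bases across the junction.
#'
#' @param pos,alen,strand External end placement (vectors).
#' @param b Breakpoint coordinate.
#' @param tol Junction tolerance in bp.
#' @return Character vector in FWD_UP, REV_UP, FWD_DOWN, REV_DOWN.
#' @export
orientation_class <- function(pos, alen, strand, b, tol = 6L) {
  ifelse(strand == "+",
         ifelse(pos + alen <= b + tol, "FWD_UP", "FWD_DOWN"),
         ifelse(pos >= b - tol, "REV_DOWN", "REV_UP"))
}

#' Score one cluster and emit a breakpoint call
#'
#' The breakpoint `b` is the midpoint between the rightmost forward-
#' upstream end and the leftmost reverse-downstream start; with only one
#' orientation present it falls back to the innermost end offset by
#' `I - L`.  The score adds the specificity of every supporting read and
#' subtracts that of every conflicting read; calls below
#' `config$bp_score_threshold` are suppressed (NULL).
#'
#' @param cl `data.table` of external ends of one cluster (columns chrom,
#'   pos, alen, strand, s).
#' @param config A [run_config()].
#' @return One-row `data.table`, or `NULL` below threshold.
#' @export
call_breakpoint <- function(cl, config = run_config()) {
  if (!nrow(cl)) return(NULL)
  I <- config$insert_size; L <- config$read_length
  fwd_end <- cl[strand == "+", pos + alen]
  rev_start <- cl[strand == "-", pos]
  if (length(fwd_end) && length(rev_start)) {
    b <- as.integer(floor((max(fwd_end) + min(rev_start)) / 2))
  } else if (length(fwd_end)) {
    b <- as.integer(max(fwd_end) + (I - L))
  } else {
    b <- as.integer(min(rev_start) - (I - L))
  }
  score_at <- function(bb) {
    oc <- orientation_class(cl$pos, cl$alen, cl$strand, bb,
                            tol = config$max_edit)
    support <- oc %in% c("FWD_UP", "REV_DOWN")
    list(score = sum(cl$s[support]) - sum(cl$s[!support]),
         support = support, oc = oc)
  }
  sc <- score_at(b)
  if (any(!sc$support)) {
    # mixed composition: the extreme-end midpoint is contaminated by the
    # conflicting reads; place b at the boundary maximising
    # support - conflict (ties -> leftmost)
    cand <- sort(unique(c(fwd_end, rev_start)))
    scs <- vapply(cand, function(bb) score_at(bb)$score, 0)
    b2 <- cand[which.max(scs)]
    if (max(scs) > sc$score) { b <- as.integer(b2); sc <- score_at(b) }
  }
  score <- sc$score
  n_conflict <- sum(!sc$support)
  if (score < config$bp_score_threshold) return(NULL)
  # a cluster backed exclusively by multi-mapped reads must show the full
  # two-sided composition: deterministic placement of ambiguous reads
  # piles co-optimal placements onto one repeat copy, and those shadows
  # are one-sided -- the ambiguous-mapping signature the composition test
  # exists to catch
  if (all(cl$s < 1) &&
      !(any(sc$oc == "FWD_UP") && any(sc$oc == "REV_DOWN")))
    return(NULL)
  if (config$strict_composition && n_conflict > 0L) return(NULL)
  span <- max(cl$pos + cl$alen) - min(cl$pos)
  data.table(chrom = cl$chrom[1], pos = b, score = score,
             n_support = sum(sc$support), n_conflict = n_conflict,
             perfect_composition = n_conflict == 0L,
             span = span, expected_span = 2L * (I - L),
             high_conf = score >= config$bp_high_threshold &
               n_conflict == 0L)
}

# Shadow arbitration across a region's calls: a call supported by no
# uniquely placed read, whose reads mostly have a co-optimal alternative
# external placement inside another call that does have unique support,
# is that call's mapping shadow and is dropped.
drop_shadow_calls <- function(calls, supports, config) {
  if (is.null(calls) || nrow(calls) < 2L) return(calls)
  uniq_sup <- vapply(seq_len(nrow(calls)), function(k)
    any(supports[cluster == calls$cluster[k], s] >= 1), TRUE)
  if (all(uniq_sup) || !any(uniq_sup)) return(calls)
  spans <- lapply(which(uniq_sup), function(k) {
    cl <- supports[cluster == calls$cluster[k]]
    list(chrom = calls$chrom[k], lo = min(cl$pos) - config$insert_size,
         hi = max(cl$pos + cl$alen) + config$insert_size)
  })
  keep <- rep(TRUE, nrow(calls))
  for (k in which(!uniq_sup)) {
    cl <- supports[cluster == calls$cluster[k]]
    alts <- strsplit(cl$alt_ext[!is.na(cl$alt_ext)], ",", fixed = TRUE)
    if (!length(alts)) next
    inother <- vapply(alts, function(a) {
      p <- strsplit(a, ":", fixed = TRUE)
      any(vapply(p, function(x) {
        pos <- as.integer(x[2])
        any(vapply(spans, function(sp)
          sp$chrom == x[1] && pos >= sp$lo && pos <= sp$hi, TRUE))
      }, TRUE))
    }, TRUE)
    if (mean(inother) >= 0.5 && length(inother) >= 0.5 * nrow(cl))
      keep[k] <- FALSE
  }
  calls[keep]
}

#' Zygosity of an insertion from breakpoint-spanning coverage
#'
#' Counts concordant pairs whose outer span covers `b` and compares with
#' the rate at flanking control positions under a Poisson model with rates
#' lambda (no insertion), lambda/2 (heterozygous) and ~0 (homozygous).
#'
#' @param aln Full alignment table.
#' @param chrom,b Breakpoint position.
#' @param config A [run_config()].
#' @return List: `zygosity` ("HET"/"HOM"/"UNKNOWN"), `suspect` (TRUE when
#'   spanning coverage is consistent with no insertion at all), `n`,
#'   `lambda`.
#' @export
estimate_zygosity <- function(aln, chrom, b, config = run_config()) {
  chr_target <- chrom
  span_count <- function(at) {
    w <- aln[mapped == TRUE & chrom == chr_target &
               pos >= at - 2L * config$insert_hi &
               pos <= at + 2L * config$insert_hi]
    if (!nrow(w)) return(0L)
    ww <- dcast(w, qname ~ mate, value.var = c("mapped", "chrom", "pos",
                                               "strand", "alen"))
    ww <- ww[!is.na(mapped_1) & !is.na(mapped_2) & mapped_1 & mapped_2]
    if (!nrow(ww)) return(0L)
    ww <- ww[pair_concordant(chrom_1, pos_1, alen_1, strand_1,
                             chrom_2, pos_2, alen_2, strand_2, config)]
    sum(pmin(ww$pos_1, ww$pos_2) < at &
          pmax(ww$pos_1 + ww$alen_1, ww$pos_2 + ww$alen_2) > at)
  }
  n <- span_count(b)
  lambda <- mean(vapply(c(-3000L, -2000L, 2000L, 3000L),
                        function(d) span_count(b + d), 0L))
  if (lambda < 5) return(list(zygosity = "UNKNOWN", suspect = FALSE,
                              n = n, lambda = lambda))
  rates <- c(none = 1, HET = 0.5, HOM = 0.02) * lambda
  ll <- stats::dpois(n, rates, log = TRUE)
  win <- names(rates)[which.max(ll)]
  if (sum(ll == max(ll)) > 1L)
    return(list(zygosity = "UNKNOWN", suspect = FALSE, n = n,
                lambda = lambda))
  list(zygosity = if (win == "none") "UNKNOWN" else win,
       suspect = win == "none", n = n, lambda = lambda)
}

#' Detect insertion breakpoints for candidate regions
#'
#' Full detection pipeline per candidate region: homolog recruitment, pair
#' collection, triage with orphan rescue, genome-wide match sets for every
#' discordant one-end pair, concordance-preferred specificity scoring,
#' external-end clustering, composition scoring and zygosity estimation.
#'
#' @param genome Named character vector.
#' @param aln Alignment table (one row per end).
#' @param regions Candidate interval table.
#' @param config A [run_config()].
#' @param index Optional prebuilt genome index.
#' @param zygosity Estimate zygosity per call (costs a little time).
#' @return List: `calls` (one row per accepted breakpoint) and `contexts`
#'   (per-region homology set, triaged pairs and scored supports, consumed
#'   by [reconstruct_duplicons()]).
#' @export
find_breakpoints <- function(genome, aln, regions, config = run_config(),
                             index = NULL, zygosity = TRUE) {
  if (is.null(index)) index <- build_genome_index(genome, config$kmer)
  all_calls <- list(); contexts <- list()
  for (ri in seq_len(nrow(regions))) {
    region <- regions[ri]
    hset <- find_homologs(region, genome, config, index)
    sub <- collect_pairs(hset, aln)
    tri <- triage(sub, hset, genome, config, index)
    p <- tri$pairs
    disc <- p[class == "DISCORDANT_ONE_END" & (mem_1 > 0L | mem_2 > 0L)]
    region_str <- sprintf("%s:%d-%d", region$chrom, region$start, region$end)
    hids <- paste(hset$members$id, collapse = ",")
    calls <- NULL
    supports <- NULL
    if (nrow(disc)) {
      disc[, internal := ifelse(mem_1 > 0L, 1L, 2L)]
      # match sets are queried with the as-sequenced read so that hit
      # strands follow SAM conventions (stored sequences are
      # reference-oriented for minus-strand placements)
      disc[, asq_1 := ifelse(mapped_1 & strand_1 == "-",
                             as.character(cpp_revcomp(seq_1)), seq_1)]
      disc[, asq_2 := ifelse(mapped_2 & strand_2 == "-",
                             as.character(cpp_revcomp(seq_2)), seq_2)]
      seqs <- unique(c(disc$asq_1, disc$asq_2))
      mh <- cpp_map_reads(index, seqs, config$max_edit, 1L)
      mlist <- split(data.frame(chrom = names(genome)[mh$refid],
                                pos = mh$pos, alen = mh$alen,
                                strand = ifelse(mh$strand == 1L, "-", "+"),
                                ed = mh$ed, stringsAsFactors = FALSE),
                     factor(mh$read, levels = seq_along(seqs)))
      i1 <- match(disc$asq_1, seqs); i2 <- match(disc$asq_2, seqs)
      svec <- numeric(nrow(disc))
      altvec <- rep(NA_character_, nrow(disc))
      for (i in seq_len(nrow(disc))) {
        int <- disc$internal[i]
        m_int <- mlist[[if (int == 1L) i1[i] else i2[i]]]
        m_ext <- mlist[[if (int == 1L) i2[i] else i1[i]]]
        n1 <- nrow(m_int); n2 <- nrow(m_ext)
        if (!n1 || !n2) next
        ii <- rep.int(seq_len(n1), rep.int(n2, n1))
        jj <- rep.int(seq_len(n2), n1)
        e <- m_int$ed[ii] + m_ext$ed[jj]
        conc <- pair_concordant(m_int$chrom[ii], m_int$pos[ii],
                                m_int$alen[ii], m_int$strand[ii],
                                m_ext$chrom[jj], m_ext$pos[jj],
                                m_ext$alen[jj], m_ext$strand[jj], config)
        e_cstar <- if (any(conc)) min(e[conc]) else Inf
        inD <- !conc & e < e_cstar
        if (!any(inD)) next
        extpos <- if (int == 1L) disc$pos_2[i] else disc$pos_1[i]
        extchr <- if (int == 1L) disc$chrom_2[i] else disc$chrom_1[i]
        extstr <- if (int == 1L) disc$strand_2[i] else disc$strand_1[i]
        intpos <- if (int == 1L) disc$pos_1[i] else disc$pos_2[i]
        intchr <- if (int == 1L) disc$chrom_1[i] else disc$chrom_2[i]
        cur <- inD & m_ext$chrom[jj] == extchr & m_ext$strand[jj] == extstr &
          abs(m_ext$pos[jj] - extpos) <= config$max_edit &
          m_int$chrom[ii] == intchr &
          abs(m_int$pos[ii] - intpos) <= config$max_edit
        if (!any(cur)) next
        eD <- e[inD]
        ecur <- min(e[cur])
        svec[i] <- 2^(-(ecur - min(eD))) / sum(eD == ecur)
        # record co-optimal alternative external placements (shadow
        # arbitration below)
        alt <- inD & e == ecur & !cur
        if (any(alt))
          altvec[i] <- paste(sprintf("%s:%d", m_ext$chrom[jj][alt],
                                     m_ext$pos[jj][alt]), collapse = ",")
      }
      supports <- data.table(
        qname = disc$qname, s = svec, alt_ext = altvec,
        internal = disc$internal,
        chrom = ifelse(disc$internal == 1L, disc$chrom_2, disc$chrom_1),
        pos = ifelse(disc$internal == 1L, disc$pos_2, disc$pos_1),
        alen = ifelse(disc$internal == 1L, disc$alen_2, disc$alen_1),
        strand = ifelse(disc$internal == 1L, disc$strand_2, disc$strand_1))
      supports <- supports[s > 0]
      if (nrow(supports)) {
        supports <- cluster_ends(supports, config)
        for (cid in unique(supports$cluster)) {
          cl <- supports[cluster == cid]
          bc <- call_breakpoint(cl, config)
          if (is.null(bc)) next
          bc[, `:=`(source_region = region_str, homolog_ids = hids,
                    region_idx = ri, cluster = cid)]
          calls <- rbind(calls, bc, fill = TRUE)
        }
        calls <- drop_shadow_calls(calls, supports, config)
        if (!is.null(calls) && nrow(calls) && zygosity) {
          for (k in seq_len(nrow(calls))) {
            zg <- estimate_zygosity(aln, calls$chrom[k], calls$pos[k], config)
            calls[k, `:=`(zygosity = zg$zygosity, suspect = zg$suspect)]
          }
        } else if (!is.null(calls) && nrow(calls)) {
          calls[, `:=`(zygosity = "UNKNOWN", suspect = FALSE)]
        }
      }
    }
    all_calls[[ri]] <- calls
    contexts[[ri]] <- list(region = region, hset = hset, triage = tri,
                           supports = supports)
  }
  calls <- rbindlist(all_calls, fill = TRUE)
  if (nrow(calls)) setorder(calls, chrom, pos)
  list(calls = calls, contexts = contexts)
}
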