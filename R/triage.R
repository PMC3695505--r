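# Mate-pair classification, quality filtering, and orphan rescue by local
# realignment against the homology set.

#' Widen an alignment table to one row per pair
#' @param aln Alignment table (one row per end).
#' @return `data.table`, one row per qname with `_1`/`_2` suffixed fields.
#' @export
pairs_wide <- function(aln) {
  dcast(aln, qname ~ mate,
        value.var = c("mapped", "chrom", "pos", "strand", "mapq", "ed",
                      "alen", "seq", "qual"))
}

#' Classify mate pairs into the five read classes
#'
#' Classes: `TWO_END` (both ends within the homology set), `CONCORDANT_ONE_END`
#' / `DISCORDANT_ONE_END` (one end internal, the mapped mate outside with
#' valid / invalid geometry), `ORPHAN_ONE_END` (one end unmapped) and
#' `ORPHAN` (both unmapped).  Concordance means same chromosome,
#' forward-reverse orientation, and outer span within the configured insert
#' bounds.  Cross-member pairs count as two-end reads: both ends lie on
#' reference copies, so they carry no insertion signal.
#'
#' @param pairs Wide pair table from [pairs_wide()].
#' @param hset A `homology_set`.
#' @param config A [run_config()].
#' @return `pairs` with columns `class`, `mem_1`, `mem_2` added.
#' @export
classify_pairs <- function(pairs, hset, config = run_config()) {
  p <- pairs
  p[, mem_1 := member_of(hset, chrom_1, pos_1, alen_1)]
  p[, mem_2 := member_of(hset, chrom_2, pos_2, alen_2)]
  p[, conc := pair_concordant(chrom_1, pos_1, alen_1, strand_1,
                              chrom_2, pos_2, alen_2, strand_2, config)]
  p[, class := ifelse(!mapped_1 & !mapped_2, "ORPHAN",
               ifelse(!mapped_1 | !mapped_2, "ORPHAN_ONE_END",
               ifelse(mem_1 > 0L & mem_2 > 0L, "TWO_END",
               ifelse(conc, "CONCORDANT_ONE_END", "DISCORDANT_ONE_END"))))]
  p[, conc := NULL]
  p[]
}

# geometry test: same chrom, FR orientation, outer span within bounds
pair_concordant <- function(chrom1, pos1, alen1, strand1,
                            chrom2, pos2, alen2, strand2, config) {
  span <- pmax(pos1 + alen1, pos2 + alen2) - pmin(pos1, pos2)
  fr <- (pos1 <= pos2 & strand1 == "+" & strand2 == "-") |
    (pos2 <= pos1 & strand2 == "+" & strand1 == "-")
  ok <- !is.na(chrom1) & !is.na(chrom2) & chrom1 == chrom2 & fr &
    span >= config$insert_lo & span <= config$insert_hi
  ok & !is.na(ok)
}

#' Base-quality filter
#'
#' A read fails when at least `max_low_qual_bases` of its bases are below
#' Phred `q_threshold` (default: >= 10 nt under Q20).
#'
#' @param quals Character vector of Phred+33 quality strings.
#' @param config A [run_config()].
#' @return Logical vector, `TRUE` = read passes.
#' @export
quality_pass <- function(quals, config = run_config()) {
  vapply(quals, function(q) {
    if (is.na(q) || !nzchar(q) || q == "*") {
      warning("missing qualities treated as all-pass")
      return(TRUE)
    }
    sum(utf8ToInt(q) - 33L < config$q_threshold) < config$max_low_qual_bases
  }, TRUE, USE.NAMES = FALSE)
}

#' Rescue an unmapped read by Smith-Waterman against the homology set
#'
#' The read (both orientations) is aligned against every member extended
#' by its flanks.  The alignment is accepted when identity (matches over
#' alignment columns, gaps included) exceeds `config$min_similarity` and
#' the score exceeds `config$min_score_fraction` of the perfect-match
#' score; ties break by higher score, then leftmost genomic coordinate.
#'
#' @param seq Read sequence (as sequenced).
#' @param hset A `homology_set`.
#' @param genome Named character vector.
#' @param config A [run_config()].
#' @param index Optional genome index: candidate placements are then
#'   seeded through the k-mer index (relaxed edit bound) and verified by
#'   windowed Smith-Waterman, instead of exhaustive SW over every region.
#'   Results agree with the exhaustive route whenever the read retains one
#'   clean seed, which a rescuable read (similarity > 0.92) essentially
#'   always does.
#' @return List: `accepted`, and on success `chrom`, `start`, `end`,
#'   `strand`, `score`, `similarity`; on failure `reason`
#'   (`"NO_ALIGNMENT"`).
#' @export
rescue_read <- function(seq, hset, genome, config = run_config(),
                        index = NULL) {
  f <- hset$flanks
  perfect <- config$sw_match * nchar(seq)
  best <- NULL
  consider <- function(cand) {
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score &&
         (cand$chrom < best$chrom ||
          (cand$chrom == best$chrom && cand$start < best$start))))
      best <<- cand
  }
  if (is.null(index)) {
    for (i in seq_len(nrow(f))) {
      tstart <- f$left_start[i]
      tseq <- substr(genome[[f$chrom[i]]], tstart + 1L, f$right_end[i])
      for (strand in c("+", "-")) {
        q <- if (strand == "+") seq else as.character(cpp_revcomp(seq))
        al <- cpp_sw(q, tseq, config$sw_match, config$sw_mismatch,
                     config$sw_gap_open, config$sw_gap_extend)
        if (al$cols == 0L) next
        consider(list(chrom = f$chrom[i], start = tstart + al$tstart,
                      end = tstart + al$tend, strand = strand,
                      score = al$score, similarity = al$matches / al$cols))
      }
    }
  } else {
    hits <- as.data.table(cpp_map_reads(index, seq, 20L, 1L))
    if (nrow(hits)) {
      hits[, chrom := names(genome)[refid]]
      keep <- logical(nrow(hits))
      for (i in seq_len(nrow(f)))
        keep <- keep | (hits$chrom == f$chrom[i] &
                          hits$pos < f$right_end[i] &
                          hits$pos + hits$alen > f$left_start[i])
      hits <- hits[keep]
      pad <- 25L
      for (i in seq_len(nrow(hits))) {
        wstart <- max(0L, hits$pos[i] - pad)
        wend <- min(nchar(genome[[hits$chrom[i]]]),
                    hits$pos[i] + hits$alen[i] + pad)
        tseq <- substr(genome[[hits$chrom[i]]], wstart + 1L, wend)
        strand <- if (hits$strand[i] == 1L) "-" else "+"
        q <- if (strand == "+") seq else as.character(cpp_revcomp(seq))
        al <- cpp_sw(q, tseq, config$sw_match, config$sw_mismatch,
                     config$sw_gap_open, config$sw_gap_extend)
        if (al$cols == 0L) next
        consider(list(chrom = hits$chrom[i], start = wstart + al$tstart,
                      end = wstart + al$tend, strand = strand,
                      score = al$score, similarity = al$matches / al$cols))
      }
    }
  }
  if (is.null(best) || best$similarity <= config$min_similarity ||
      best$score <= config$min_score_fraction * perfect)
    return(list(accepted = FALSE, reason = "NO_ALIGNMENT"))
  c(list(accepted = TRUE), best)
}

#' Reclassify a pair after rescue
#'
#' Promotion rules: an orphan-one-end read whose rescued end lands (i)
#' within any member becomes a two-end read, (ii) in a flank of the member
#' holding its mate becomes concordant-one-end, (iii) in a flank of a
#' different member becomes discordant-one-end.  A discordant-one-end pair
#' whose external end is comparatively alignable to the mate's member
#' (identity within `config$comparative_tol` of its identity on the
#' original template) becomes two-end.  Rescue never demotes.
#'
#' @param class Current classification.
#' @param rescue Result of [rescue_read()] (or `NULL`).
#' @param hset A `homology_set`.
#' @param mate_member Member index (row in `hset$members`) of the mapped
#'   mate, 0 if none.
#' @return New classification string.
#' @export
reclassify <- function(class, rescue, hset, mate_member = 0L) {
  if (is.null(rescue) || !isTRUE(rescue$accepted)) return(class)
  if (class == "ORPHAN_ONE_END") {
    alen <- rescue$end - rescue$start
    m <- member_of(hset, rescue$chrom, rescue$start, alen)
    if (m > 0L) return("TWO_END")
    fl <- flank_of(hset, rescue$chrom, rescue$start, alen)
    if (fl > 0L && fl == mate_member) return("CONCORDANT_ONE_END")
    if (fl > 0L) return("DISCORDANT_ONE_END")
  }
  class
}

# rule 4: external read of a discordant pair comparatively alignable to the
# mate's member -> two-end (false discordance from multi-mapping).  Local
# identity is meaningless for short spurious hits, so comparability is
# judged on the Smith-Waterman score: within `comparative_tol` of the
# perfect-match score difference.
comparatively_alignable <- function(seq, own_member, mate_member, hset,
                                    genome, config = run_config()) {
  score_on <- function(i) {
    tseq <- hset$sequences[[i]]
    best <- 0
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else as.character(cpp_revcomp(seq))
      al <- cpp_sw(q, tseq, config$sw_match, config$sw_mismatch,
                   config$sw_gap_open, config$sw_gap_extend)
      best <- max(best, al$score)
    }
    best
  }
  perfect <- config$sw_match * nchar(seq)
  score_on(mate_member) >= score_on(own_member) -
    config$comparative_tol * perfect
}

#' Run the full triage on a collected pair set
#'
#' Classifies every pair, applies the base-quality filter to unmapped ends
#' of orphan-one-end pairs, attempts Smith-Waterman rescue, applies the
#' promotion rules, and fills rescued coordinates back into the pair table.
#'
#' @param aln Alignment subset from [collect_pairs()].
#' @param hset A `homology_set`.
#' @param genome Named character vector.
#' @param config A [run_config()].
#' @return List: `pairs` (wide, classified, with `rescued_1/_2` flags),
#'   `rescue` (per-attempt table), `counts` (class tally).
#' @export
triage <- function(aln, hset, genome, config = run_config(),
                   index = NULL) {
  p <- classify_pairs(pairs_wide(aln), hset, config)
  p[, `:=`(rescued_1 = FALSE, rescued_2 = FALSE)]
  resc <- list()
  cand <- which(p$class == "ORPHAN_ONE_END")
  for (i in cand) {
    unm <- if (!p$mapped_1[i]) 1L else 2L
    sq <- if (unm == 1L) p$seq_1[i] else p$seq_2[i]
    ql <- if (unm == 1L) p$qual_1[i] else p$qual_2[i]
    if (!quality_pass(ql, config)) {
      resc[[length(resc) + 1L]] <- data.table(qname = p$qname[i], end = unm,
                                              accepted = FALSE,
                                              reason = "LOW_QUALITY")
      next
    }
    rr <- rescue_read(sq, hset, genome, config, index)
    mate_mem <- if (unm == 1L) p$mem_2[i] else p$mem_1[i]
    newclass <- reclassify("ORPHAN_ONE_END", rr, hset, mate_mem)
    if (isTRUE(rr$accepted)) {
      resc[[length(resc) + 1L]] <- data.table(
        qname = p$qname[i], end = unm, accepted = TRUE, reason = NA_character_,
        chrom = rr$chrom, start = rr$start, endpos = rr$end,
        strand = rr$strand, score = rr$score, similarity = rr$similarity,
        new_class = newclass)
      # fill the rescued coordinates into the pair table
      if (unm == 1L) {
        p[i, `:=`(mapped_1 = TRUE, chrom_1 = rr$chrom, pos_1 = rr$start,
                  alen_1 = rr$end - rr$start, strand_1 = rr$strand,
                  mapq_1 = 0L, ed_1 = NA_integer_, rescued_1 = TRUE,
                  class = newclass)]
        if (rr$strand == "-") p[i, seq_1 := as.character(cpp_revcomp(seq_1))]
        p[i, mem_1 := member_of(hset, chrom_1, pos_1, alen_1)]
      } else {
        p[i, `:=`(mapped_2 = TRUE, chrom_2 = rr$chrom, pos_2 = rr$start,
                  alen_2 = rr$end - rr$start, strand_2 = rr$strand,
                  mapq_2 = 0L, ed_2 = NA_integer_, rescued_2 = TRUE,
                  class = newclass)]
        if (rr$strand == "-") p[i, seq_2 := as.character(cpp_revcomp(seq_2))]
        p[i, mem_2 := member_of(hset, chrom_2, pos_2, alen_2)]
      }
    } else {
      resc[[length(resc) + 1L]] <- data.table(qname = p$qname[i], end = unm,
                                              accepted = FALSE,
                                              reason = rr$reason)
    }
  }
  rescue_dt <- if (length(resc)) rbindlist(resc, fill = TRUE) else
    data.table(qname = character(0), end = integer(0), accepted = logical(0),
               reason = character(0))
  counts <- p[, .N, by = class]
  list(pairs = p[], rescue = rescue_dt, counts = counts)
}
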