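# Simulation of reference genomes, donor genomes with planted duplicons,
# paired-end reads and their mapping.  All randomness flows through R's RNG
# so a single set.seed() makes a whole dataset reproducible.

random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substitute, then indel; returns list(seq, n_sub, n_ins, n_del)
mutate_seq <- function(seq, sub_rate = 0, indel_rate = 0, max_indel = 5L) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  nsub <- 0L
  if (sub_rate > 0 && n > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    for (i in hit) {
      alt <- setdiff(c("A", "C", "G", "T"), s[i])
      s[i] <- sample(alt, 1L)
    }
    nsub <- length(hit)
  }
  nins <- 0L; ndel <- 0L
  if (indel_rate > 0 && n > 0) {
    nev <- stats::rbinom(1L, n, indel_rate)
    if (nev > 0) {
      at <- sort(sample.int(length(s), nev))
      for (i in rev(at)) { # right-to-left keeps earlier positions valid
        len <- sample.int(max_indel, 1L)
        if (stats::runif(1) < 0.5) { # insertion
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          s <- append(s, ins, after = i)
          nins <- nins + 1L
        } else {
          s <- s[-(i:min(length(s), i + len - 1L))]
          ndel <- ndel + 1L
        }
      }
    }
  }
  list(seq = paste(s, collapse = ""), n_sub = nsub, n_ins = nins, n_del = ndel)
}

# Plant copies of a family consensus, each independently diverged, at
# non-overlapping uniform positions (overwriting the background so the
# chromosome length is unchanged).
plant_repeats <- function(chroms, consensus, n_copies, divergence) {
  if (n_copies <= 0) return(chroms)
  rlen <- nchar(consensus)
  lens <- nchar(chroms)
  for (i in seq_len(n_copies)) {
    ch <- sample(seq_along(chroms), 1L, prob = lens)
    pos <- sample.int(lens[ch] - rlen, 1L)
    copy <- mutate_seq(consensus, sub_rate = divergence)$seq
    substr(chroms[ch], pos, pos + rlen - 1L) <- copy
  }
  chroms
}

#' Generate an artificial reference genome
#'
#' Default geometry is five 50 kb chromosomes.  In `random` mode the
#' background is i.i.d. sequence at the given GC content onto which three
#' interspersed repeat families are planted (a young and an old 300 bp
#' SINE-like family and a young 4 kb LINE-like family), emulating the
#' repeat structure of real genomic sequence that makes read placement
#' ambiguous.  In `fasta` mode chromosomes are sliced from a user genome at
#' seeded offsets.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length (>= 5000 bp).
#' @param source `"random"` or a path to / named vector of sequences.
#' @param gc GC content of the random background.
#' @param repeat_config List with per-family `len`, `divergence` and
#'   genome-wide coverage fraction `frac`; `NULL` disables repeats.
#' @param seed Integer seed.
#' @return Named character vector of chromosome sequences, with the seed in
#'   `attr(, "seed")`.
#' @export
make_reference <- function(n_chrom = 5L, chrom_len = 50000L,
                           source = "random", gc = 0.41,
                           repeat_config = default_repeats(), seed = 1L) {
  stopifnot(chrom_len >= 5000L)
  set.seed(seed)
  if (identical(source, "random")) {
    chroms <- vapply(seq_len(n_chrom), function(i) random_dna(chrom_len, gc), "")
    total <- n_chrom * chrom_len
    for (fam in repeat_config) {
      cons <- random_dna(fam$len, gc)
      n <- round(fam$frac * total / fam$len)
      chroms <- plant_repeats(chroms, cons, n, fam$divergence)
    }
  } else {
    src <- if (is.character(source) && length(source) == 1L && file.exists(source))
      read_fasta(source) else source
    pool <- paste(src, collapse = "")
    if (nchar(pool) < chrom_len)
      stop("source FASTA shorter than requested chromosome length")
    chroms <- vapply(seq_len(n_chrom), function(i) {
      off <- sample.int(nchar(pool) - chrom_len + 1L, 1L)
      toupper(substr(pool, off, off + chrom_len - 1L))
    }, "")
  }
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  attr(chroms, "seed") <- seed
  chroms
}

#' Default interspersed-repeat families of the random reference
#'
#' Coverage fractions and divergences approximate the young/old SINE and
#' young LINE content of human genomic sequence: low-divergence copies are
#' the ones short reads cannot place uniquely.
#' @return List of family descriptors.
#' @export
default_repeats <- function() {
  list(sine_young = list(len = 300L, divergence = 0.015, frac = 0.04),
       sine_old = list(len = 300L, divergence = 0.12, frac = 0.05),
       line_young = list(len = 4000L, divergence = 0.01, frac = 0.03))
}

#' Plant duplicon copies into a reference to create a donor genome
#'
#' A single 1--3 kb source segment is chosen uniformly; `n_copies`
#' independently mutated copies of it (substitutions, short indels,
#' optional terminal truncation) are inserted at uniform non-tandem
#' positions at least `min_spacing` from the source and from each other.
#'
#' @param genome Reference genome (named character vector).
#' @param n_copies Number of inserted copies (1--4 in the accuracy
#'   experiment).
#' @param dup_len_range Source segment length range in bp.
#' @param sub_rate Per-base substitution rate applied to every copy.
#' @param indel_rate Per-base rate of 1--`max_indel` bp indel events.
#' @param max_indel Maximum indel length.
#' @param trunc_prob Probability that a copy is truncated at one end.
#' @param max_trunc Maximum truncated fraction.
#' @param min_spacing Minimum distance between insertion points and the
#'   source region.
#' @param edge_margin Insertion points keep this distance from chromosome
#'   ends.
#' @param seed Integer seed.
#' @return List with `donor` (named character vector) and `truth`, a
#'   `data.table` with one row per planted copy: source interval, target
#'   chromosome, reference insertion coordinate `ref_pos` (0-based, the
#'   base before which the copy sits), donor coordinate `donor_pos`, the
#'   true inserted sequence `seq`, and the applied divergence tallies.
#' @export
plant_duplications <- function(genome, n_copies = 1L,
                               dup_len_range = c(1000L, 3000L),
                               sub_rate = 0.03, indel_rate = 5e-4,
                               max_indel = 5L, trunc_prob = 0.1,
                               max_trunc = 0.2, min_spacing = 5000L,
                               edge_margin = 2500L, seed = 1L) {
  set.seed(seed)
  stopifnot(n_copies >= 1L, n_copies <= 10L)
  lens <- nchar(genome)
  dup_len <- sample(dup_len_range[1]:dup_len_range[2], 1L)
  src_ch <- sample(seq_along(genome), 1L, prob = lens)
  src_start <- sample.int(lens[src_ch] - dup_len - 2L * edge_margin, 1L) +
    edge_margin
  src_seq <- substr(genome[[src_ch]], src_start + 1L, src_start + dup_len)

  # insertion sites, rejection-sampled for spacing
  sites <- data.table(ch = integer(0), pos = integer(0))
  tries <- 0L
  while (nrow(sites) < n_copies) {
    tries <- tries + 1L
    if (tries > 10000L) stop("genome too small for spacing constraints")
    ch <- sample(seq_along(genome), 1L, prob = lens)
    pos <- sample.int(lens[ch] - 2L * edge_margin, 1L) + edge_margin
    ok <- TRUE
    if (ch == src_ch && pos >= src_start - min_spacing &&
        pos <= src_start + dup_len + min_spacing) ok <- FALSE
    if (nrow(sites) && any(sites$ch == ch & abs(sites$pos - pos) < min_spacing))
      ok <- FALSE
    if (ok) sites <- rbind(sites, data.table(ch = ch, pos = pos))
  }

  truth <- vector("list", n_copies)
  for (i in seq_len(n_copies)) {
    s <- src_seq
    trunc <- 0L
    if (stats::runif(1) < trunc_prob) {
      trunc <- as.integer(round(stats::runif(1, 0, max_trunc) * dup_len))
      if (trunc > 0L) {
        if (stats::runif(1) < 0.5) s <- substr(s, trunc + 1L, nchar(s))
        else s <- substr(s, 1L, nchar(s) - trunc)
      }
    }
    mut <- mutate_seq(s, sub_rate, indel_rate, max_indel)
    truth[[i]] <- data.table(
      id = sprintf("dup%02d", i),
      src_chrom = names(genome)[src_ch], src_start = src_start,
      src_end = src_start + dup_len,
      tgt_chrom = names(genome)[sites$ch[i]], ref_pos = sites$pos[i],
      strand = "+", seq = mut$seq, n_sub = mut$n_sub, n_ins = mut$n_ins,
      n_del = mut$n_del, trunc = trunc)
  }
  truth <- rbindlist(truth)

  donor <- genome
  truth[, donor_pos := NA_integer_]
  for (ch in unique(truth$tgt_chrom)) {
    rows <- which(truth$tgt_chrom == ch)
    ord <- rows[order(truth$ref_pos[rows])]
    shift <- 0L
    for (r in ord) {
      truth$donor_pos[r] <- truth$ref_pos[r] + shift
      shift <- shift + nchar(truth$seq[r])
    }
    for (r in rev(ord)) { # insert right-to-left so earlier coords stay valid
      p <- truth$ref_pos[r]
      donor[[ch]] <- paste0(substr(donor[[ch]], 1L, p), truth$seq[r],
                            substr(donor[[ch]], p + 1L, nchar(donor[[ch]])))
    }
  }
  attr(donor, "seed") <- seed
  list(donor = donor, truth = truth[])
}

#' Simulate paired-end reads from a donor genome
#'
#' Fragments are uniform over the genome with normally distributed length;
#' reads are taken FR from the fragment ends with i.i.d. substitution
#' errors.  Qualities are constant at the Phred equivalent of `error_rate`,
#' except that a seeded 5% of reads get a Q2 tail of
#' `low_qual_tail` bases (error rate 10%) so the base-quality filter is
#' exercised.
#'
#' @param donor Donor genome (named character vector).
#' @param coverage Haploid coverage; the pair count is
#'   `coverage * genome_length / (2 * read_length)`.  The default matches
#'   the 40x, 100 x 2, 500 bp-insert library the defaults emulate.
#' @param read_length Read length L.
#' @param insert_mu,insert_sd Fragment length distribution.
#' @param error_rate Per-base substitution error rate.
#' @param low_qual_frac Fraction of reads receiving a low-quality tail.
#' @param low_qual_tail Length of that tail in bases.
#' @param seed Integer seed.
#' @return `data.table` with qname, chrom, fragment start/len (donor
#'   coordinates, for debugging), seq1/qual1 (forward) and seq2/qual2
#'   (reverse-complemented, as sequenced).
#' @export
simulate_reads <- function(donor, coverage = 40, read_length = 100L,
                           insert_mu = 500, insert_sd = 30,
                           error_rate = 0.005, low_qual_frac = 0.05,
                           low_qual_tail = 12L, seed = 1L) {
  set.seed(seed)
  lens <- nchar(donor)
  total <- sum(lens)
  n_pairs <- as.integer(round(coverage * total / (2 * read_length)))
  ch <- sample(seq_along(donor), n_pairs, replace = TRUE, prob = lens)
  frag <- pmax(2L * read_length,
               as.integer(round(stats::rnorm(n_pairs, insert_mu, insert_sd))))
  maxstart <- lens[ch] - frag
  skip <- maxstart < 0L
  if (any(skip)) {
    message(sum(skip), " fragment(s) skipped (insert longer than chromosome)")
    ch <- ch[!skip]; frag <- frag[!skip]; maxstart <- maxstart[!skip]
    n_pairs <- length(ch)
  }
  start <- as.integer(floor(stats::runif(n_pairs) * (maxstart + 1L)))
  seq1 <- substring(donor[ch], start + 1L, start + read_length)
  end2 <- substring(donor[ch], start + frag - read_length + 1L, start + frag)
  seq2 <- as.character(cpp_revcomp(end2))

  # vectorised error injection on the concatenated byte representation
  add_errors <- function(sq, rate) {
    n <- length(sq)
    if (n == 0L) return(sq)
    raw <- charToRaw(paste(sq, collapse = ""))
    total <- length(raw)
    nerr <- stats::rbinom(1L, total, rate)
    if (nerr > 0L) {
      at <- sample.int(total, nerr)
      bases <- charToRaw("ACGT")
      shift <- sample.int(3L, nerr, replace = TRUE)
      cur <- match(raw[at], bases)
      cur[is.na(cur)] <- 1L
      raw[at] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    starts <- seq.int(1L, total, by = read_length)
    substring(rawToChar(raw), starts, starts + read_length - 1L)
  }
  qbase <- as.integer(round(-10 * log10(max(error_rate, 1e-4))))
  qchar <- rawToChar(as.raw(qbase + 33L))
  q1 <- strrep(qchar, read_length)
  qual1 <- rep(q1, n_pairs)
  qual2 <- rep(q1, n_pairs)
  seq1 <- add_errors(seq1, error_rate)
  seq2 <- add_errors(seq2, error_rate)
  # low-quality tails: last `low_qual_tail` sequenced bases at Q2, 10% error
  lowq <- strrep(rawToChar(as.raw(2L + 33L)), low_qual_tail)
  a <- read_length - low_qual_tail + 1L
  mark <- function(sq, ql, rate = 0.1) {
    sel <- which(stats::runif(length(sq)) < low_qual_frac)
    if (length(sel)) {
      substr(ql[sel], a, read_length) <- lowq
      tails <- substr(sq[sel], a, read_length)
      raw <- charToRaw(paste(tails, collapse = ""))
      nerr <- stats::rbinom(1L, length(raw), rate)
      if (nerr > 0L) {
        at <- sample.int(length(raw), nerr)
        bases <- charToRaw("ACGT")
        shift <- sample.int(3L, nerr, replace = TRUE)
        cur <- match(raw[at], bases); cur[is.na(cur)] <- 1L
        raw[at] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      }
      starts <- seq.int(1L, length(raw), by = low_qual_tail)
      tails <- substring(rawToChar(raw), starts, starts + low_qual_tail - 1L)
      substr(sq[sel], a, read_length) <- tails
    }
    list(sq = sq, ql = ql)
  }
  r1 <- mark(seq1, qual1); seq1 <- r1$sq; qual1 <- r1$ql
  r2 <- mark(seq2, qual2); seq2 <- r2$sq; qual2 <- r2$ql
  data.table(qname = sprintf("r%07d", seq_len(n_pairs)),
             chrom = names(donor)[ch], frag_start = start, frag_len = frag,
             seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2)
}

#' Map simulated reads against a reference with the built-in mapper
#'
#' Seed-and-extend k-mer mapping with banded edit-distance verification;
#' best-scoring hit per end, unmapped when the best edit distance exceeds
#' `config$max_edit`.  Among co-optimal hits the lowest coordinate is
#' chosen deterministically and MAPQ is set to 0; otherwise MAPQ scales
#' with the gap to the second-best hit.  Proper-pair flags follow the
#' configured insert bounds.
#'
#' @param reads Read table from [simulate_reads()].
#' @param reference Reference genome (named character vector).
#' @param config A [run_config()] object.
#' @param index Optional prebuilt index from [build_genome_index()].
#' @return Alignment `data.table` (one row per end, SAM conventions).
#' @export
simple_map <- function(reads, reference, config = run_config(), index = NULL) {
  if (is.null(index)) index <- build_genome_index(reference, config$kmer)
  n <- nrow(reads)
  out <- vector("list", 2L)
  for (mate in 1:2) {
    sq <- if (mate == 1L) reads$seq1 else reads$seq2
    ql <- if (mate == 1L) reads$qual1 else reads$qual2
    h <- cpp_map_reads(index, sq, config$max_edit, 0L)
    mapq <- ifelse(h$n_best >= 2L, 0L,
                   ifelse(is.na(h$second_ed), 60L,
                          pmin(60L, 10L * (h$second_ed - h$ed))))
    strand <- ifelse(h$strand == 1L, "-", "+")
    # store reference-oriented sequence (SAM convention)
    seq_out <- sq
    rev <- which(h$mapped & h$strand == 1L)
    if (length(rev)) {
      seq_out[rev] <- as.character(cpp_revcomp(sq[rev]))
      ql[rev] <- as.character(cpp_revstr(ql[rev]))
    }
    out[[mate]] <- data.table(
      qname = reads$qname, mate = mate, mapped = h$mapped,
      chrom = ifelse(h$mapped, names(reference)[h$refid], NA_character_),
      pos = h$pos, strand = ifelse(h$mapped, strand, NA_character_),
      mapq = ifelse(h$mapped, mapq, 0L), ed = h$ed,
      seq = seq_out, qual = ql, alen = h$alen)
  }
  aln <- rbindlist(out)
  aln[, proper := FALSE]
  wide <- dcast(aln, qname ~ mate, value.var = c("mapped", "chrom", "pos",
                                                 "strand", "alen"))
  conc <- wide[mapped_1 & mapped_2 & chrom_1 == chrom_2 & strand_1 != strand_2]
  if (nrow(conc)) {
    conc[, `:=`(lo = pmin(pos_1, pos_2),
                hi = pmax(pos_1 + alen_1, pos_2 + alen_2))]
    conc[, fr := (pos_1 <= pos_2 & strand_1 == "+") |
           (pos_2 <= pos_1 & strand_2 == "+")]
    ok <- conc[fr == TRUE & hi - lo >= config$insert_lo &
                 hi - lo <= config$insert_hi, qname]
    aln[qname %in% ok, proper := TRUE]
  }
  setkey(aln, qname, mate)
  aln[]
}

#' Build a reusable k-mer index over a genome
#' @param genome Named character vector.
#' @param k Seed size.
#' @return External pointer consumed by the mapping routines.
#' @export
build_genome_index <- function(genome, k = 14L) {
  cpp_build_index(genome, as.integer(k))
}

#' Simulate a complete dataset in memory
#'
#' Convenience wrapper chaining [make_reference()], [plant_duplications()],
#' [simulate_reads()] and [simple_map()]; this is one replicate of the
#' accuracy experiment.
#'
#' @param seed Integer seed driving every stage.
#' @param n_copies Planted copy count (`NULL`: uniform on 1--4).
#' @param config A [run_config()].
#' @param coverage Sequencing depth.
#' @param ... Passed to [plant_duplications()].
#' @return List: reference, donor, truth, reads, aln, index, candidate
#'   region (the true source interval, standing in for an external CNV
#'   call), config.
#' @export
simulate_dataset <- function(seed = 1L, n_copies = NULL,
                             config = run_config(), coverage = 40, ...) {
  set.seed(seed)
  if (is.null(n_copies)) n_copies <- sample(1:4, 1L)
  reference <- make_reference(seed = seed)
  pd <- plant_duplications(reference, n_copies = n_copies,
                           seed = seed + 1L, ...)
  reads <- simulate_reads(pd$donor, coverage = coverage,
                          read_length = config$read_length,
                          insert_mu = config$insert_size,
                          error_rate = config$error_rate, seed = seed + 2L)
  index <- build_genome_index(reference, config$kmer)
  aln <- simple_map(reads, reference, config, index = index)
  region <- genomic_interval(pd$truth$src_chrom[1], pd$truth$src_start[1],
                             pd$truth$src_end[1])
  list(reference = reference, donor = pd$donor, truth = pd$truth,
       reads = reads, aln = aln, index = index, region = region,
       config = config, seed = seed)
}
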