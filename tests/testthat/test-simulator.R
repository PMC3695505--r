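test_that("make_reference geometry and determinism", {
  g1 <- make_reference(n_chrom = 2L, chrom_len = 5000L, seed = 7L,
                       repeat_config = list())
  expect_equal(unname(nchar(g1)), c(5000L, 5000L))
  g2 <- make_reference(n_chrom = 2L, chrom_len = 5000L, seed = 7L,
                       repeat_config = list())
  expect_identical(g1, g2)
  g3 <- make_reference(n_chrom = 2L, chrom_len = 5000L, seed = 8L,
                       repeat_config = list())
  expect_false(identical(g1, g3))
  # default experiment geometry: five 50 kb chromosomes
  g <- make_reference(seed = 1L)
  expect_equal(unname(nchar(g)), rep(50000L, 5L))
  expect_error(make_reference(chrom_len = 1000L))
})

test_that("plant_duplications records a consistent truth table", {
  g <- make_reference(n_chrom = 3L, chrom_len = 30000L, seed = 3L,
                      repeat_config = list())
  pd <- plant_duplications(g, n_copies = 4L, seed = 9L)
  expect_equal(nrow(pd$truth), 4L)
  # donor grows by the planted sequence lengths
  expect_equal(sum(nchar(pd$donor)) - sum(nchar(g)),
               sum(nchar(pd$truth$seq)))
  # extracting the donor at the recorded coordinate yields the true
  # sequence exactly
  for (i in 1:4) {
    tr <- pd$truth[i]
    got <- substr(pd$donor[[tr$tgt_chrom]], tr$donor_pos + 1L,
                  tr$donor_pos + nchar(tr$seq))
    expect_identical(got, tr$seq)
  }
  # source extracted from the reference is the shared template
  a_h <- substr(g[[pd$truth$src_chrom[1]]], pd$truth$src_start[1] + 1L,
                pd$truth$src_end[1])
  expect_equal(nchar(a_h), pd$truth$src_end[1] - pd$truth$src_start[1])
  # pairwise spacing of same-chromosome insertions
  same <- pd$truth[, .N, by = tgt_chrom][N > 1L, tgt_chrom]
  for (ch in same) {
    p <- sort(pd$truth[tgt_chrom == ch, ref_pos])
    expect_true(all(diff(p) >= 5000L))
  }
})

test_that("planted substitution count is binomially plausible", {
  g <- make_reference(n_chrom = 1L, chrom_len = 30000L, seed = 5L,
                      repeat_config = list())
  pd <- plant_duplications(g, n_copies = 1L, dup_len_range = c(2000L, 2000L),
                           sub_rate = 0.03, indel_rate = 0, trunc_prob = 0,
                           seed = 13L)
  ci <- qbinom(c(0.005, 0.995), 2000L, 0.03)
  expect_gte(pd$truth$n_sub, ci[1])
  expect_lte(pd$truth$n_sub, ci[2])
})

test_that("simulate_reads: count arithmetic, purity at zero error, determinism", {
  g <- c(chrA = rdna(20000, seed = 2))
  rd <- simulate_reads(g, coverage = 10, read_length = 100L, error_rate = 0,
                       low_qual_frac = 0, seed = 4L)
  expect_equal(nrow(rd), round(10 * 20000 / 200))
  # zero error: every read is an exact substring of the donor
  idx <- sample(nrow(rd), 20)
  for (i in idx) {
    frag <- substr(g[[rd$chrom[i]]], rd$frag_start[i] + 1L,
                   rd$frag_start[i] + rd$frag_len[i])
    expect_identical(rd$seq1[i], substr(frag, 1L, 100L))
    expect_identical(rd$seq2[i],
                     revcomp_r(substr(frag, rd$frag_len[i] - 99L,
                                      rd$frag_len[i])))
  }
  rd2 <- simulate_reads(g, coverage = 10, read_length = 100L, error_rate = 0,
                        low_qual_frac = 0, seed = 4L)
  expect_identical(rd, rd2)
})

test_that("simple_map places reads correctly and flags multimappers", {
  set.seed(31)
  core <- rdna(6000)
  dup <- substr(core, 2001, 3000)
  g <- c(chrA = paste0(core, strrep("T", 30), dup)) # exact duplicate block
  cfg <- run_config()
  idx <- build_genome_index(g, cfg$kmer)
  reads <- data.table(
    qname = c("u1", "m1", "j1"),
    seq1 = c(substr(core, 101, 200),     # unique exact
             substr(core, 2101, 2200),   # inside the duplicated block
             paste0(substr(core, 5951, 6000), rdna(50))), # novel junction
    qual1 = strrep("I", 100),
    seq2 = c(revcomp_r(substr(core, 501, 600)),
             revcomp_r(substr(core, 2501, 2600)),
             revcomp_r(substr(core, 5501, 5600))),
    qual2 = strrep("I", 100))
  aln <- simple_map(reads, g, cfg, index = idx)
  u <- aln[qname == "u1" & mate == 1]
  expect_true(u$mapped); expect_equal(u$pos, 100L); expect_equal(u$ed, 0L)
  expect_gt(u$mapq, 0L)
  m <- aln[qname == "m1" & mate == 1]
  expect_true(m$mapped)
  expect_equal(m$mapq, 0L)          # two co-optimal placements
  expect_equal(m$pos, 2100L)        # deterministic lowest coordinate
  j <- aln[qname == "j1" & mate == 1]
  expect_false(j$mapped)            # junction read has no reference witness
})

test_that("mapper best hit matches an exhaustive alignment oracle", {
  # oracle: minimum semi-global edit distance by sliding adist over all
  # offsets and window lengths, both strands
  oracle_ed <- function(read, ref, max_edit) {
    m <- nchar(read)
    best <- Inf
    for (s in c(read, revcomp_r(read))) {
      for (w in (m - max_edit):(m + max_edit)) {
        if (w < 1) next
        starts <- 1:(nchar(ref) - w + 1)
        subs <- substring(ref, starts, starts + w - 1L)
        d <- utils::adist(s, subs)
        best <- min(best, min(d))
      }
    }
    best
  }
  set.seed(77)
  g <- c(chrA = rdna(2000))
  idx <- build_genome_index(g, 14L)
  for (rep in 1:6) {
    pos <- sample(1800, 1)
    read <- substr(g[["chrA"]], pos, pos + 59L)
    nmut <- sample(0:4, 1)
    if (nmut > 0) {
      at <- sample(60, nmut)
      for (p in at) substr(read, p, p) <- sample(setdiff(c("A","C","G","T"),
                                                 substr(read, p, p)), 1)
    }
    if (rep %% 2 == 0) read <- revcomp_r(read)
    h <- duprec:::cpp_map_reads(idx, read, 6L, 0L)
    expect_true(h$mapped)
    expect_equal(h$ed, oracle_ed(read, g[["chrA"]], 6L))
  }
})

test_that("low-quality tails are planted so the Q20 filter has work", {
  g <- c(chrA = rdna(20000, seed = 6))
  rd <- simulate_reads(g, coverage = 10, read_length = 100L,
                       error_rate = 0.005, low_qual_frac = 0.05, seed = 8L)
  cfg <- run_config()
  frac_fail <- mean(!quality_pass(rd$qual1, cfg))
  expect_gt(frac_fail, 0.01)
  expect_lt(frac_fail, 0.12)
})
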