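test_that("match_set enumerates all placements on desk-scale genomes", {
  set.seed(71)
  core <- rdna(1500)
  block <- substr(core, 501, 800)
  g <- c(chrA = paste0(core, strrep("G", 20), block)) # exact duplicate block
  idx <- build_genome_index(g, 14L)
  # unique exact read
  r1 <- substr(core, 101, 160)
  m1 <- match_set(r1, idx, g, 6L)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$ed, 0L)
  expect_equal(m1$pos, 100L)
  # read inside the duplicated block: two exact placements
  r2 <- substr(core, 551, 610)
  m2 <- match_set(r2, idx, g, 6L)
  expect_equal(nrow(m2), 2L)
  expect_true(all(m2$ed == 0L))
  expect_equal(sort(m2$pos), c(550L, 1570L))
  # one mismatch, max_edit 0 -> empty
  r3 <- r1
  substr(r3, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(r3, 30, 30))[1]
  expect_equal(nrow(match_set(r3, idx, g, 0L)), 0L)
  # reverse-complement placements carry the minus strand
  m4 <- match_set(revcomp_r(r1), idx, g, 6L)
  expect_equal(m4$strand, "-")
  expect_equal(m4$pos, 100L)
})

test_that("preferred discordant set obeys the concordance preference", {
  cfg <- run_config()
  mk <- function(pos, strand, ed, chrom = "c1")
    data.table(chrom = chrom, pos = as.integer(pos), alen = 100L,
               strand = strand, ed = as.integer(ed))
  # concordant placement exists at e=2; discordant pair at e=0 beats it
  m1 <- mk(1000, "+", 0)
  m2 <- rbind(mk(1400, "-", 2), mk(9000, "-", 0))
  pd <- preferred_discordant_set(m1, m2, cfg)
  expect_equal(pd$e_cstar, 2)
  expect_equal(nrow(pd$D), 1L)
  expect_equal(pd$D$pos2, 9000L)
  # discordant e=1 vs concordant e=0 -> D empty
  m2b <- rbind(mk(1400, "-", 0), mk(9000, "-", 1))
  expect_equal(nrow(preferred_discordant_set(m1, m2b, cfg)$D), 0L)
  # no concordant pairing possible -> all three discordant pairs kept
  m2c <- rbind(mk(9000, "-", 3), mk(12000, "+", 1), mk(5000, "-", 2, "c2"))
  pd3 <- preferred_discordant_set(m1, m2c, cfg)
  expect_equal(pd3$e_cstar, Inf)
  expect_equal(nrow(pd3$D), 3L)
})

test_that("specificity score satisfies its defining properties", {
  # exhaustive over enumerated small D sets
  set.seed(72)
  for (trial in 1:50) {
    es <- sample(0:6, sample(1:6, 1), replace = TRUE)
    D <- data.table(e = es)
    s <- specificity_score(es, D)
    expect_true(all(s > 0 & s <= 1))
    # s == 1 iff unique minimum edit distance element
    is_unique_min <- es == min(es) & sum(es == min(es)) == 1L
    expect_equal(s == 1, is_unique_min)
    # strictly decreasing in e at fixed multiplicity
    ord <- order(es)
    mult <- table(es)
    if (length(mult) > 1 && all(mult == mult[1])) {
      su <- s[ord][!duplicated(es[ord])]
      expect_true(all(diff(su) < 0))
    }
  }
  # worked examples: two pairs at the minimum share 0.5; a unique pair two
  # edits above a vanished minimum scores 2^-2
  expect_equal(specificity_score(c(1, 1), data.table(e = c(1, 1))),
               c(0.5, 0.5))
  expect_equal(specificity_score(2, data.table(e = c(0, 2))), 0.25)
  expect_equal(specificity_score(0, data.table(e = 0)), 1)
})

test_that("cluster_ends is single-linkage with gap threshold I", {
  cfg <- run_config() # I = 500
  ends <- data.table(chrom = "c1",
                     pos = c(1000L, 1050L, 1120L, 1180L, 1200L,
                             3300L, 3400L, 9000L),
                     alen = 100L, strand = "+", s = 1)
  cl <- cluster_ends(copy(ends), cfg)
  expect_equal(cl[order(pos), cluster], c(1, 1, 1, 1, 1, 2, 2, 3))
  # oracle: single linkage via hclust on 1-d positions
  d <- hclust(dist(ends$pos), method = "single")
  oracle <- cutree(d, h = cfg$insert_size)
  expect_equal(length(unique(cl$cluster)), length(unique(oracle)))
  # chromosome boundaries split clusters
  ends2 <- data.table(chrom = c("c1", "c2"), pos = c(100L, 150L),
                      alen = 100L, strand = "+", s = 1)
  expect_equal(length(unique(cluster_ends(ends2, cfg)$cluster)), 2L)
})

test_that("orientation classes follow strand and side", {
  b <- 10000L
  expect_equal(orientation_class(9600L, 100L, "+", b), "FWD_UP")
  expect_equal(orientation_class(9600L, 100L, "-", b), "REV_UP")
  expect_equal(orientation_class(10200L, 100L, "+", b), "FWD_DOWN")
  expect_equal(orientation_class(10200L, 100L, "-", b), "REV_DOWN")
})

test_that("call_breakpoint scores, thresholds and positions correctly", {
  cfg <- run_config()
  sup <- function(n_fwd, n_rev, s = 1, b = 5000L) {
    rbind(
      if (n_fwd) data.table(chrom = "c1",
                            pos = b - 100L - seq_len(n_fwd) * 10L,
                            alen = 100L, strand = "+", s = s),
      if (n_rev) data.table(chrom = "c1", pos = b + seq_len(n_rev) * 10L,
                            alen = 100L, strand = "-", s = s))
  }
  # two unique supporting reads reach exactly the 2.0 threshold
  bc <- call_breakpoint(sup(1, 1), cfg)
  expect_false(is.null(bc))
  expect_equal(bc$score, 2)
  expect_true(bc$perfect_composition)
  expect_lt(abs(bc$pos - 5000L), 12L)
  # 3 supporting + 2 conflicting unique reads -> score 1, rejected
  # (reverse reads upstream of every candidate boundary are pure conflict)
  cl <- rbind(sup(3, 0), data.table(chrom = "c1", pos = c(4200L, 4250L),
                                    alen = 100L, strand = "-", s = 1))
  expect_null(call_breakpoint(cl, cfg))
  # 5 supporting + 2 conflicting -> score 3, emitted with the conflicts
  cl5 <- rbind(sup(5, 0), data.table(chrom = "c1", pos = c(4200L, 4250L),
                                     alen = 100L, strand = "-", s = 1))
  bc5 <- call_breakpoint(cl5, cfg)
  expect_equal(bc5$score, 3)
  expect_equal(bc5$n_conflict, 2L)
  # single read below threshold
  expect_null(call_breakpoint(sup(1, 0), cfg))
  # strict composition drops any call with conflicts
  cfg2 <- run_config(strict_composition = TRUE)
  cl2 <- rbind(sup(4, 4), data.table(chrom = "c1", pos = 4200L, alen = 100L,
                                     strand = "-", s = 0.5))
  expect_false(is.null(call_breakpoint(cl2, cfg)))
  expect_null(call_breakpoint(cl2, cfg2))
})

test_that("one-sided clusters use the I - L fallback position", {
  cfg <- run_config()
  cl <- data.table(chrom = "c1", pos = c(4500L, 4550L, 4600L), alen = 100L,
                   strand = "+", s = 1)
  bc <- call_breakpoint(cl, cfg)
  expect_false(is.null(bc))
  expect_equal(bc$pos, 4700L + (cfg$insert_size - cfg$read_length))
})

test_that("zygosity follows the binomial/Poisson coverage model", {
  cfg <- run_config()
  set.seed(73)
  # concordant pairs tiled along a chromosome, fragment length 500
  mkaln <- function(drop_at = NA, drop_frac = 0) {
    starts <- seq(0L, 12000L, by = 20L)
    keep <- rep(TRUE, length(starts))
    if (!is.na(drop_at)) {
      spans <- starts < drop_at & starts + 500L > drop_at
      keep[spans] <- runif(sum(spans)) >= drop_frac
    }
    starts <- starts[keep]
    rbindlist(lapply(seq_along(starts), function(i)
      aln_pair(sprintf("p%04d", i), "c1", starts[i], "+",
               "c1", starts[i] + 400L, "-")))
  }
  b <- 6000L
  hom <- estimate_zygosity(mkaln(b, 1), "c1", b, cfg)
  expect_identical(hom$zygosity, "HOM")
  het <- estimate_zygosity(mkaln(b, 0.5), "c1", b, cfg)
  expect_identical(het$zygosity, "HET")
  none <- estimate_zygosity(mkaln(), "c1", b, cfg)
  expect_true(none$suspect)
  # oracle: brute-force Poisson likelihood comparison for the HET case
  lam <- het$lambda; nobs <- het$n
  ll <- dpois(nobs, c(lam, lam / 2, 0.02 * lam), log = TRUE)
  expect_equal(which.max(ll), 2L)
  # sparse coverage -> UNKNOWN
  thin <- mkaln()[1:8]
  expect_identical(estimate_zygosity(thin, "c1", b, cfg)$zygosity, "UNKNOWN")
})

test_that("zero-divergence single duplicon is recovered within 15 bp", {
  # property version of the accuracy figure at desk scale
  hits <- vapply(1:4, function(i) {
    r <- run_replicate(seed = 8100 + i, n_copies = 1,
                       config = run_config(), coverage = 40,
                       sub_rate = 0, indel_rate = 0, trunc_prob = 0)
    length(r$errors) == 1L && abs(r$errors) <= 15L
  }, TRUE)
  expect_true(all(hits))
})
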