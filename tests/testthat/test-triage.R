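# Fixture: one genome with H at [4000, 5500) and an exact homolog copy at
# [11500, 13000), plus the triage config.
triage_fixture <- function() {
  cached("triage_fixture", {
    set.seed(61)
    left <- rdna(4000); mid <- rdna(6000); right <- rdna(4000)
    src <- rdna(1500)
    g <- c(chrA = paste0(left, src, mid, src, right))
    cfg <- run_config()
    hs <- find_homologs(genomic_interval("chrA", 4000L, 5500L), g, cfg)
    list(g = g, cfg = cfg, hs = hs)
  })
}

test_that("classification covers the five classes and matches geometry", {
  fx <- triage_fixture()
  aln <- rbind(
    # both ends within H1, FR, span 500 -> TWO_END
    aln_pair("te", "chrA", 4100L, "+", "chrA", 4500L, "-", genome = fx$g),
    # cross-member pair -> TWO_END (both on reference copies)
    aln_pair("xm", "chrA", 4100L, "+", "chrA", 11600L, "-", genome = fx$g),
    # internal + concordant mate just outside -> CONCORDANT_ONE_END
    aln_pair("co", "chrA", 5450L, "+", "chrA", 5800L, "-", genome = fx$g),
    # internal + mate 5 kb away -> DISCORDANT_ONE_END
    aln_pair("di", "chrA", 4200L, "+", "chrA", 9200L, "-", genome = fx$g),
    # internal + mate same position but FF orientation -> discordant
    aln_pair("ff", "chrA", 5450L, "+", "chrA", 5800L, "+", genome = fx$g),
    # one end unmapped -> ORPHAN_ONE_END
    rbind(aln_row("or", 1L, "chrA", 4300L, "+",
                  seq = substr(fx$g[["chrA"]], 4301L, 4400L)),
          aln_row("or", 2L)),
    # both unmapped -> ORPHAN
    rbind(aln_row("oo", 1L), aln_row("oo", 2L)))
  p <- classify_pairs(pairs_wide(aln), fx$hs, fx$cfg)
  cls <- setNames(p$class, p$qname)
  expect_identical(cls[["te"]], "TWO_END")
  expect_identical(cls[["xm"]], "TWO_END")
  expect_identical(cls[["co"]], "CONCORDANT_ONE_END")
  expect_identical(cls[["di"]], "DISCORDANT_ONE_END")
  expect_identical(cls[["ff"]], "DISCORDANT_ONE_END")
  expect_identical(cls[["or"]], "ORPHAN_ONE_END")
  expect_identical(cls[["oo"]], "ORPHAN")
})

test_that("quality filter boundary: >= 10 bases under Q20 fails", {
  cfg <- run_config()
  q30 <- strrep("?", 100) # Phred 30
  low <- "+"              # Phred 10
  mk <- function(nlow) paste0(strrep(low, nlow), substr(q30, nlow + 1, 100))
  expect_true(quality_pass(mk(9), cfg))
  expect_false(quality_pass(mk(10), cfg))
  expect_false(quality_pass(strrep("#", 100), cfg)) # all Q2
  expect_warning(ok <- quality_pass("*", cfg), "missing")
  expect_true(ok)
})

test_that("rescue accepts near-perfect reads and rejects diverged/random ones", {
  fx <- triage_fixture()
  h1 <- fx$hs$sequences[["H1"]]
  exact <- substr(h1, 301, 400)
  rr <- rescue_read(exact, fx$hs, fx$g, fx$cfg)
  expect_true(rr$accepted)
  expect_equal(rr$similarity, 1.0)
  expect_equal(rr$score, fx$cfg$sw_match * 100L) # perfect-match score
  expect_equal(rr$start, 4300L)

  # reverse-complement reads are found on the minus strand
  rc <- rescue_read(revcomp_r(exact), fx$hs, fx$g, fx$cfg)
  expect_true(rc$accepted)
  expect_identical(rc$strand, "-")
  expect_equal(rc$start, 4300L)

  # 10% substitutions: brute-force identity is below the 0.92 bound
  set.seed(62)
  div <- exact
  for (p in sample(100, 10)) substr(div, p, p) <-
      sample(setdiff(c("A", "C", "G", "T"), substr(div, p, p)), 1)
  pa <- Biostrings::pairwiseAlignment(div, exact, type = "global")
  expect_lt(Biostrings::pid(pa) / 100, 0.92)
  rd <- rescue_read(div, fx$hs, fx$g, fx$cfg)
  expect_false(rd$accepted)

  # random sequence: nothing alignable
  rnd <- rescue_read(rdna(100, seed = 63), fx$hs, fx$g, fx$cfg)
  expect_false(rnd$accepted)
  expect_identical(rnd$reason, "NO_ALIGNMENT")
})

test_that("seeded rescue equals the exhaustive Smith-Waterman route", {
  fx <- triage_fixture()
  idx <- build_genome_index(fx$g, fx$cfg$kmer)
  h1 <- fx$hs$sequences[["H1"]]
  set.seed(64)
  for (i in 1:6) {
    read <- substr(h1, 100 * i + 1, 100 * i + 100)
    nmut <- sample(0:6, 1)
    for (p in sample(100, nmut)) substr(read, p, p) <-
        sample(setdiff(c("A", "C", "G", "T"), substr(read, p, p)), 1)
    if (i %% 2 == 0) read <- revcomp_r(read)
    a <- rescue_read(read, fx$hs, fx$g, fx$cfg)            # exhaustive
    b <- rescue_read(read, fx$hs, fx$g, fx$cfg, index = idx) # seeded
    expect_equal(a$accepted, b$accepted, info = i)
    if (isTRUE(a$accepted)) {
      expect_equal(a$score, b$score, info = i)
      expect_equal(a$start, b$start, info = i)
    }
  }
})

test_that("reclassification applies the promotion rules and never demotes", {
  fx <- triage_fixture()
  inside <- list(accepted = TRUE, chrom = "chrA", start = 4400L, end = 4500L,
                 strand = "+", score = 200, similarity = 1)
  flank1 <- list(accepted = TRUE, chrom = "chrA", start = 3500L, end = 3600L,
                 strand = "+", score = 200, similarity = 1)
  flank2 <- list(accepted = TRUE, chrom = "chrA", start = 13200L, end = 13300L,
                 strand = "+", score = 200, similarity = 1)
  expect_identical(reclassify("ORPHAN_ONE_END", inside, fx$hs, 1L), "TWO_END")
  expect_identical(reclassify("ORPHAN_ONE_END", flank1, fx$hs, 1L),
                   "CONCORDANT_ONE_END")
  expect_identical(reclassify("ORPHAN_ONE_END", flank2, fx$hs, 1L),
                   "DISCORDANT_ONE_END")
  expect_identical(reclassify("ORPHAN_ONE_END", list(accepted = FALSE),
                              fx$hs, 1L), "ORPHAN_ONE_END")
  expect_identical(reclassify("TWO_END", inside, fx$hs, 1L), "TWO_END")
})

test_that("comparative alignability detects cross-template equivalence", {
  fx <- triage_fixture()
  cfg <- fx$cfg
  # members are exact copies: any internal read is comparatively alignable
  read <- substr(fx$hs$sequences[["H2"]], 201, 300)
  expect_true(comparatively_alignable(read, 2L, 1L, fx$hs, fx$g, cfg))
  # with genuinely different member sequences, a read private to its own
  # member is not comparable on the other
  set.seed(67)
  fake <- fx$hs
  fake$sequences <- c(H1 = rdna(1500), H2 = rdna(1500))
  priv <- substr(fake$sequences[["H2"]], 201, 300)
  expect_false(comparatively_alignable(priv, 2L, 1L, fake, fx$g, cfg))
})

test_that("triage yields a partition with class counts summing to total", {
  fx <- triage_fixture()
  set.seed(65)
  reads <- simulate_reads(fx$g, coverage = 4, read_length = 100L,
                          error_rate = 0.005, seed = 66L)
  aln <- simple_map(reads, fx$g, fx$cfg)
  sub <- collect_pairs(fx$hs, aln)
  tri <- triage(sub, fx$hs, fx$g, fx$cfg)
  expect_equal(sum(tri$counts$N), nrow(tri$pairs))
  expect_true(all(tri$pairs$class %in%
                    c("TWO_END", "CONCORDANT_ONE_END", "DISCORDANT_ONE_END",
                      "ORPHAN_ONE_END", "ORPHAN")))
  expect_equal(nrow(tri$pairs), length(unique(sub$qname)))
})
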