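test_that("create_phmm yields valid, template-dominated distributions", {
  cfg <- run_config()
  m <- create_phmm("ACGTT", cfg)
  expect_equal(m$K, 5L)
  expect_equal(rowSums(m$Em), rep(1, 5), tolerance = 1e-9)
  # template base has the highest emission in every column
  expect_equal(apply(m$Em, 1, which.max), c(1L, 2L, 3L, 4L, 4L))
  expect_true(all(m$Em >= cfg$mu / 3 - 1e-12))
  expect_true(all(m$Em <= 1 - cfg$mu + 1e-12))
  # all three transition families are distributions
  expect_equal(rowSums(m$trans[, 1:3]), rep(1, 6), tolerance = 1e-9)
  expect_equal(rowSums(m$trans[, 4:5]), rep(1, 6), tolerance = 1e-9)
  expect_equal(rowSums(m$trans[, 6:7]), rep(1, 6), tolerance = 1e-9)
  expect_error(create_phmm("", cfg))
})

test_that("emission update: prior preservation, saturation, clamping", {
  bg <- rep(0.1, 4)
  # no observations -> normalised background exactly
  e0 <- update_emission(rep(0, 4), bg, mu = 0.01, rho = 0.1)
  expect_equal(as.numeric(e0), rep(0.25, 4))
  # overwhelming observation of one symbol saturates at the cap
  e1 <- update_emission(c(1000, 0, 0, 0), bg, mu = 0.01, rho = 0.1)
  expect_equal(e1[1, 1], 0.99)
  expect_true(all(e1[1, 2:4] >= 0.01 / 3 - 1e-12))
  expect_equal(sum(e1), 1, tolerance = 1e-9)
  # proportionality before clamping: 3:1 observations at moderate depth
  e2 <- update_emission(c(30, 10, 0, 0), bg, mu = 0.01, rho = 0.1)
  expect_gt(e2[1, 1], e2[1, 2])
  expect_gt(e2[1, 2], e2[1, 3])
})

test_that("update rules stay sound under arbitrary update sequences", {
  cfg <- run_config()
  set.seed(81)
  for (trial in 1:100) {
    counts <- matrix(rpois(4 * 6, lambda = sample(c(0, 1, 5, 200), 1)), 6, 4)
    E <- update_emission(counts, rep(0.1, 4), cfg$mu, cfg$rho)
    expect_equal(rowSums(E), rep(1, 6), tolerance = 1e-9)
    expect_true(all(E >= cfg$mu / 3 - 1e-12 & E <= 1 - cfg$mu + 1e-12))
    tc <- matrix(rpois(7 * 5, lambda = sample(c(0, 2, 50), 1)), 5, 7)
    Tr <- update_transition(tc, cfg)
    for (grp in list(1:3, 4:5, 6:7))
      expect_equal(rowSums(Tr[, grp, drop = FALSE]), rep(1, 5),
                   tolerance = 1e-9)
  }
})

# exhaustive path enumeration oracle over the exact model topology:
# entry at M_j / I_j for j in [anchor-window, anchor+window], free exit
# after the last emission, delete states silent.
enumerate_viterbi <- function(m, s, anchor, window) {
  K <- m$K
  lEm <- log(m$Em); lTr <- log(m$trans); lIns <- log(0.25)
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  n <- length(codes)
  emit <- function(j, i) if (is.na(codes[i])) log(0.25) else lEm[j, codes[i]]
  best <- -Inf
  # state encoding: type M/I/D, column j, emitted i
  recurse <- function(type, j, i, lp) {
    if (lp <= best - 1e-12 && FALSE) return()
    if (i == n && type != "D") { best <<- max(best, lp); }
    if (i == n) return()
    if (type == "M" || type == "D") {
      row <- j + 1 # from-column j
      off <- if (type == "M") 0L else 5L
      if (j + 1 <= K)
        recurse("M", j + 1, i + 1,
                lp + lTr[row, if (type == "M") 1 else 6] + emit(j + 1, i + 1))
      if (type == "M")
        recurse("I", j, i + 1, lp + lTr[row, 2] + lIns)
      if (j + 1 <= K)
        recurse("D", j + 1, i,
                lp + lTr[row, if (type == "M") 3 else 7])
    } else { # I_j
      row <- j + 1
      if (j + 1 <= K)
        recurse("M", j + 1, i + 1, lp + lTr[row, 4] + emit(j + 1, i + 1))
      recurse("I", j, i + 1, lp + lTr[row, 5] + lIns)
    }
  }
  elo <- max(1, anchor - window); ehi <- min(K, anchor + window)
  for (j in elo:ehi) {
    recurse("M", j, 1, emit(j, 1))
    recurse("I", j, 1, lIns)
  }
  if (elo - 1 >= 0) recurse("I", elo - 1, 1, lIns)
  best
}

test_that("anchored Viterbi equals exhaustive path enumeration", {
  cfg <- run_config()
  m <- create_phmm("ACGTAC", cfg)
  reads <- c("ACGTAC",  # exact
             "ACTTAC",  # substitution
             "ACGAC",   # 1-base deletion vs template
             "ACGTTAC", # 1-base insertion
             "GTAC",    # offset start
             "ACNTAC")  # ambiguity code
  for (s in reads) {
    v <- anchored_viterbi(m, s, anchor = 1L, window = 6L)
    o <- enumerate_viterbi(m, s, anchor = 1L, window = 6L)
    expect_equal(v$logp, o, tolerance = 1e-9, info = s)
  }
  # a trained model keeps the equivalence
  recs <- data.table(qname = sprintf("r%d", 1:4), seq = rep("ACGTAC", 4),
                     anchor = 1L)
  m2 <- duprec:::retrain_phmm(m, recs, cfg)
  for (s in c("ACGTAC", "AGGTAC")) {
    v <- anchored_viterbi(m2, s, 1L, 6L)
    expect_equal(v$logp, enumerate_viterbi(m2, s, 1L, 6L), tolerance = 1e-9,
                 info = paste("trained", s))
  }
})

test_that("Viterbi path and likelihood behave canonically", {
  cfg <- run_config()
  tmpl <- "ACGTACGTACGTACGT"
  m <- create_phmm(tmpl, cfg)
  # exact substring at its anchor: pure match path, hand-computed logp
  s <- substr(tmpl, 5, 12)
  v <- anchored_viterbi(m, s, anchor = 5L, window = 2L)
  expect_true(all(v$path[, "state"] == 0L))
  expect_equal(v$path[, "col"], 5:12)
  hand <- sum(log(m$Em[cbind(5:12, match(strsplit(s, "")[[1]], BASES))])) +
    sum(log(m$trans[5:11 + 1, "MM"]))
  expect_equal(v$logp, hand, tolerance = 1e-9)
  # one substitution scores strictly lower
  s2 <- s; substr(s2, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                       substr(s2, 4, 4))[1]
  expect_lt(anchored_viterbi(m, s2, 5L, 2L)$logp, v$logp)
  # anchor outside the template errors
  expect_error(anchored_viterbi(m, s, 40L, 2L), "anchor")
})

test_that("consensus reflects argmax emissions, deletions and fallbacks", {
  cfg <- run_config()
  tmpl <- rdna(40, seed = 82) # random: indels are not self-similar
  m <- create_phmm(tmpl, cfg)
  # untrained model emits the template
  expect_identical(phmm_consensus(m), tmpl)
  # unanimous substitution at one column flips the consensus base
  mut <- tmpl
  substr(mut, 21, 21) <- setdiff(c("A", "C", "G", "T"),
                                 substr(tmpl, 21, 21))[1]
  recs <- data.table(qname = sprintf("r%d", 1:30), seq = rep(mut, 30),
                     anchor = 1L)
  m2 <- duprec:::retrain_phmm(m, recs, cfg)
  cons <- phmm_consensus(m2)
  expect_identical(substr(cons, 21, 21), substr(mut, 21, 21))
  expect_identical(nchar(cons), 40L)
  # a 4-bp deletion supported by every read shortens the consensus
  del <- paste0(substr(tmpl, 1, 16), substr(tmpl, 21, 40))
  recs3 <- data.table(qname = sprintf("d%d", 1:30), seq = rep(del, 30),
                      anchor = 1L)
  m3 <- duprec:::retrain_phmm(m, recs3, cfg)
  expect_identical(phmm_consensus(m3), del)
  # an insertion supported by every read appears in the consensus
  ins <- paste0(substr(tmpl, 1, 20), "TTA", substr(tmpl, 21, 40))
  recs4 <- data.table(qname = sprintf("i%d", 1:30), seq = rep(ins, 30),
                      anchor = 1L)
  m4 <- duprec:::retrain_phmm(m, recs4, cfg)
  expect_identical(phmm_consensus(m4), ins)
})

test_that("select_template spans the support projections padded by L", {
  cfg <- run_config()
  g <- c(chrA = rdna(12000, seed = 83))
  hs <- find_homologs(genomic_interval("chrA", 4000L, 7000L), g, cfg)
  sup <- data.table(int_member = 1L,
                    int_pos = c(4100L, 4300L, 6500L),
                    int_alen = 100L)
  tm <- select_template(data.table(chrom = "chrB", pos = 1L), hs, sup, cfg)
  expect_equal(tm$member, 1L)
  expect_equal(tm$tstart, 0L)             # 100 - L clipped at 0
  expect_equal(tm$end - tm$start, 2700L)  # 0 .. 2600+100 within the member
  expect_identical(tm$seq, substr(hs$sequences[["H1"]], 1L, 2700L))
  # empty projections fall back to the whole homolog with a warning
  expect_warning(tm0 <- select_template(data.table(chrom = "chrB", pos = 1L),
                                        hs, sup[0], cfg), "full longest")
  expect_equal(nchar(tm0$seq), 3000L)
})

test_that("training terminates, conserves reads and separates duplicons", {
  cfg <- run_config()
  r <- cached("train_small", {
    sim <- simulate_dataset(seed = 8207, n_copies = 2, coverage = 40)
    brk <- find_breakpoints(sim$reference, sim$aln, sim$region, cfg,
                            index = sim$index, zygosity = FALSE)
    list(sim = sim, brk = brk,
         rec = reconstruct_duplicons(brk, sim$aln, cfg)[[1]])
  })
  rec <- r$rec
  # unassigned pool is non-increasing and the loop terminated
  expect_true(all(diff(rec$log$unassigned) <= 0))
  expect_lte(nrow(rec$log), 31L)
  # read conservation: every pool pair is assigned or deferred
  if (!is.null(rec$pool)) {
    n_assigned <- sum(!is.na(rec$pool$assigned_to))
    n_deferred <- sum(is.na(rec$pool$assigned_to))
    expect_equal(n_assigned + n_deferred, nrow(rec$pool))
  }
  # each accepted breakpoint produced a consensus close to its truth
  acc <- breakpoint_accuracy(r$sim$truth, r$brk$calls)
  skip_if(nrow(acc$matches) == 0L)
  for (i in seq_len(nrow(acc$matches))) {
    rr <- rec$reconstructions[[sprintf("bp%d", acc$matches$call[i])]]
    truth_seq <- r$sim$truth[id == acc$matches$id[i], seq]
    sa <- sequence_accuracy(rr$consensus, truth_seq, "", cfg)
    expect_lt(sa$mismatch_pct_inferred, 1.0)
  }
})
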