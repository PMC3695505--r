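# Scoring pipeline output against the simulator's truth table and
# aggregating the accuracy experiment.

#' Match called breakpoints against planted truth
#'
#' Greedy nearest one-to-one pairing within `radius` bp on the same
#' chromosome.  Signed error is called minus true (positive = downstream).
#'
#' @param truth Truth table from [plant_duplications()].
#' @param calls Call table from [find_breakpoints()].
#' @param radius Maximum pairing distance in bp.
#' @return List: `matches` (truth id, call row, signed error), `n_miss`,
#'   `n_fp`, `exact_count` (TRUE when #calls == #truth), `all_found`.
#' @export
breakpoint_accuracy <- function(truth, calls, radius = 100L) {
  n_truth <- nrow(truth)
  n_calls <- if (is.null(calls)) 0L else nrow(calls)
  matches <- data.table(id = character(0), call = integer(0),
                        error = integer(0))
  if (n_calls && n_truth) {
    cand <- CJ(t = seq_len(n_truth), c = seq_len(n_calls))
    cand[, same := truth$tgt_chrom[t] == calls$chrom[c]]
    cand[, err := calls$pos[c] - truth$ref_pos[t]]
    cand <- cand[same == TRUE & abs(err) <= radius]
    cand <- cand[order(abs(err))]
    used_t <- logical(n_truth); used_c <- logical(n_calls)
    for (i in seq_len(nrow(cand))) {
      t <- cand$t[i]; c <- cand$c[i]
      if (used_t[t] || used_c[c]) next
      used_t[t] <- TRUE; used_c[c] <- TRUE
      matches <- rbind(matches, data.table(id = truth$id[t], call = c,
                                           error = cand$err[i]))
    }
  }
  list(matches = matches,
       n_miss = n_truth - nrow(matches),
       n_fp = n_calls - nrow(matches),
       exact_count = n_calls == n_truth,
       all_found = nrow(matches) == n_truth)
}

#' Sequence accuracy of a reconstruction
#'
#' End-gap-free global alignment of the inferred sequence against the true
#' duplicon, and of the reference template against the true duplicon (the
#' no-reconstruction baseline).  Mismatch percent counts mismatching and
#' internal gap columns over aligned columns.
#'
#' @param inferred Reconstructed sequence I.
#' @param true_seq True planted sequence A.
#' @param template Reference template sequence A_H.
#' @param config A [run_config()] (alignment scoring).
#' @return List: `mismatch_pct_inferred`, `mismatch_pct_template`,
#'   `pct_identity`, `aligned_len`.
#' @export
sequence_accuracy <- function(inferred, true_seq, template,
                              config = run_config()) {
  mp <- function(q, t) {
    if (!nzchar(q) || !nzchar(t)) return(list(pct = 100, id = 0, len = 0L))
    band <- max(64L, as.integer(0.3 * max(nchar(q), nchar(t))))
    al <- cpp_align_endfree(q, t, config$sw_match, config$sw_mismatch,
                            config$sw_gap_open, config$sw_gap_extend,
                            dlo = -band, dhi = band)
    if (is.na(al$score[1]) || al$cols == 0L || al$score <= 0)
      return(list(pct = 100, id = 0, len = 0L))
    list(pct = 100 * (al$mismatches + al$gapcols) / al$cols,
         id = 100 * al$matches / al$cols, len = al$cols)
  }
  a <- mp(inferred, true_seq)
  b <- mp(template, true_seq)
  list(mismatch_pct_inferred = a$pct, mismatch_pct_template = b$pct,
       pct_identity = a$id, aligned_len = a$len)
}

#' Run one replicate of the accuracy experiment
#'
#' Simulates a dataset, runs breakpoint detection against the true source
#' region, scores against the truth and (optionally) reconstructs every
#' accepted duplicon.
#'
#' @param seed Integer seed.
#' @param n_copies Planted copies (`NULL`: uniform 1--4).
#' @param config A [run_config()].
#' @param do_seq Run the profile-HMM reconstruction as well.
#' @param radius Truth/call pairing radius in bp.
#' @param ... Passed to [simulate_dataset()].
#' @return List of per-replicate records (see source).
#' @export
run_replicate <- function(seed, n_copies = NULL, config = run_config(),
                          do_seq = FALSE, radius = 100L, ...) {
  sim <- simulate_dataset(seed = seed, n_copies = n_copies, config = config,
                          ...)
  brk <- find_breakpoints(sim$reference, sim$aln, sim$region, config,
                          index = sim$index, zygosity = FALSE)
  acc <- breakpoint_accuracy(sim$truth, brk$calls, radius)
  recon <- data.table(id = character(0), mismatch_pct_inferred = numeric(0),
                      mismatch_pct_template = numeric(0))
  if (do_seq && nrow(acc$matches)) {
    rec <- reconstruct_duplicons(brk, sim$aln, config)[[1]]
    a_h <- sim$region[, substr(sim$reference[[chrom]], start + 1L, end)]
    for (i in seq_len(nrow(acc$matches))) {
      ci <- acc$matches$call[i]
      rid <- sprintf("bp%d", ci)
      rr <- rec$reconstructions[[rid]]
      if (is.null(rr)) next
      truth_seq <- sim$truth[id == acc$matches$id[i], seq]
      sa <- sequence_accuracy(rr$consensus, truth_seq, a_h, config)
      recon <- rbind(recon, data.table(
        id = acc$matches$id[i],
        mismatch_pct_inferred = sa$mismatch_pct_inferred,
        mismatch_pct_template = sa$mismatch_pct_template))
    }
  }
  list(seed = seed, n_true = nrow(sim$truth),
       n_calls = if (is.null(brk$calls)) 0L else nrow(brk$calls),
       exact_count = acc$exact_count, all_found = acc$all_found,
       errors = acc$matches$error, n_miss = acc$n_miss, n_fp = acc$n_fp,
       recon = recon)
}

#' Aggregate replicate records into the experiment summary
#'
#' @param reps List of records from [run_replicate()].
#' @return List of the summary statistics: `frac_exact_count`,
#'   `frac_all_found`, `mean_abs_error`, `frac_within_15bp`,
#'   `mean_mismatch_inferred`, `mean_mismatch_template`,
#'   `discrepancy_resolved_pct`, `n_replicates`, `n_breakpoints`.
#' @export
summarize_replicates <- function(reps) {
  errors <- unlist(lapply(reps, `[[`, "errors"))
  recon <- rbindlist(lapply(reps, `[[`, "recon"))
  mi <- if (nrow(recon)) mean(recon$mismatch_pct_inferred) else NA_real_
  mt <- if (nrow(recon)) mean(recon$mismatch_pct_template) else NA_real_
  list(frac_exact_count = mean(vapply(reps, `[[`, TRUE, "exact_count")),
       frac_all_found = mean(vapply(reps, `[[`, TRUE, "all_found")),
       mean_abs_error = if (length(errors)) mean(abs(errors)) else NA_real_,
       frac_within_15bp = if (length(errors)) mean(abs(errors) <= 15)
       else NA_real_,
       mean_mismatch_inferred = mi,
       mean_mismatch_template = mt,
       discrepancy_resolved_pct =
         if (!is.na(mi) && !is.na(mt) && mt > 0) 100 * (1 - mi / mt)
       else NA_real_,
       n_replicates = length(reps),
       n_breakpoints = length(errors))
}
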