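#' Run configuration
#'
#' Central container for every tunable parameter of the pipeline.  Values
#' not supplied fall back to defaults matching a 100 x 2 bp, 500 bp-insert
#' paired-end library.
#'
#' @param insert_size Expected insert (outer fragment) size I in bp.
#' @param insert_lo,insert_hi Concordance bounds on the outer span of a
#'   mate pair.  Defaults are `0.6 * I` and `1.6 * I`, which reproduce the
#'   conventional 300--800 bp window for a 500 bp insert.
#' @param read_length Read length L in bp.
#' @param flank_width Width of the flanking windows around every homolog
#'   member used for pair retrieval and orphan rescue (bp).
#' @param min_similarity,min_score_fraction Rescue acceptance thresholds: a
#'   Smith-Waterman realignment is accepted when identity exceeds
#'   `min_similarity` and its score exceeds `min_score_fraction` times the
#'   perfect-match score.
#' @param q_threshold,max_low_qual_bases Quality filter: a read fails when
#'   at least `max_low_qual_bases` bases are below Phred `q_threshold`.
#' @param bp_score_threshold Minimum breakpoint score for an emitted call
#'   (2 corresponds to two unique, unambiguous discordant one-end reads).
#' @param bp_high_threshold Score above which a call is flagged highly
#'   confident.
#' @param mu Assumed per-base sequencing error rate; bounds every trained
#'   emission/transition probability inside `[mu/3, 1 - mu]`.
#' @param rho Training rate: the weight of the background prior decays as
#'   `exp(-rho * n_observations)`.
#' @param w0 Initial background weight in the emission update.
#' @param max_edit Maximum edit distance allowed by the mapper and by match
#'   set enumeration.
#' @param kmer Seed size of the k-mer index.
#' @param min_identity,max_block_diff Homolog recruitment thresholds:
#'   identity > `min_identity` over the aligned block and block length
#'   within `max_block_diff` of the candidate length.
#' @param sw_match,sw_mismatch,sw_gap_open,sw_gap_extend Smith-Waterman
#'   scoring parameters (short-read conventions).
#' @param comparative_tol Maximum identity difference under which an
#'   external discordant read counts as comparatively alignable to its
#'   mate's member (discordant -> two-end promotion).
#' @param min_depth Distinct-read depth required before a profile-HMM
#'   column counts as trained.
#' @param recruit_threshold Minimum natural-log odds versus a uniform
#'   background for a recruited two-end pair.
#' @param recruit_margin Minimum natural-log likelihood margin of the best
#'   model over the runner-up; pairs inside the margin are deferred (they
#'   cover no discriminating site, so assigning them would only inject the
#'   competing duplicon's alleles into the model).
#' @param anchor_window Half-width (columns) of the anchored-Viterbi entry
#'   window; defaults to `2 * max_edit`.
#' @param strict_composition Drop any call with at least one conflicting
#'   read instead of merely penalising it.
#' @param error_rate Simulator per-base sequencing error rate.
#' @param seed Integer seed recorded in every output header.
#' @return An object of class `duprec_config` (a validated list).
#' @export
run_config <- function(insert_size = 500L,
                       insert_lo = NULL, insert_hi = NULL,
                       read_length = 100L,
                       flank_width = 1000L,
                       min_similarity = 0.92,
                       min_score_fraction = 0.80,
                       q_threshold = 20L,
                       max_low_qual_bases = 10L,
                       bp_score_threshold = 2.0,
                       bp_high_threshold = 20.0,
                       mu = 0.01,
                       rho = 0.1,
                       w0 = 1.0,
                       max_edit = 6L,
                       kmer = 14L,
                       min_identity = 0.95,
                       max_block_diff = 0.20,
                       sw_match = 2L, sw_mismatch = -3L,
                       sw_gap_open = -5L, sw_gap_extend = -2L,
                       comparative_tol = 0.02,
                       min_depth = 2L,
                       recruit_threshold = 2.0,
                       recruit_margin = 2.0,
                       anchor_window = NULL,
                       strict_composition = FALSE,
                       error_rate = 0.005,
                       seed = 1L) {
  if (is.null(insert_lo)) insert_lo <- as.integer(round(0.6 * insert_size))
  if (is.null(insert_hi)) insert_hi <- as.integer(round(1.6 * insert_size))
  if (is.null(anchor_window)) anchor_window <- 2L * as.integer(max_edit)
  cfg <- list(insert_size = as.integer(insert_size),
              insert_lo = as.integer(insert_lo),
              insert_hi = as.integer(insert_hi),
              read_length = as.integer(read_length),
              flank_width = as.integer(flank_width),
              min_similarity = min_similarity,
              min_score_fraction = min_score_fraction,
              q_threshold = as.integer(q_threshold),
              max_low_qual_bases = as.integer(max_low_qual_bases),
              bp_score_threshold = bp_score_threshold,
              bp_high_threshold = bp_high_threshold,
              mu = mu, rho = rho, w0 = w0,
              max_edit = as.integer(max_edit),
              kmer = as.integer(kmer),
              min_identity = min_identity,
              max_block_diff = max_block_diff,
              sw_match = as.integer(sw_match),
              sw_mismatch = as.integer(sw_mismatch),
              sw_gap_open = as.integer(sw_gap_open),
              sw_gap_extend = as.integer(sw_gap_extend),
              comparative_tol = comparative_tol,
              min_depth = as.integer(min_depth),
              recruit_threshold = recruit_threshold,
              recruit_margin = recruit_margin,
              anchor_window = as.integer(anchor_window),
              strict_composition = strict_composition,
              error_rate = error_rate,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "duprec_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$insert_lo < cfg$insert_size,
            cfg$insert_size < cfg$insert_hi,
            cfg$mu > 0, cfg$mu < 1,
            cfg$rho > 0, cfg$rho < 1,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$min_similarity > 0, cfg$min_similarity < 1,
            cfg$min_score_fraction > 0, cfg$min_score_fraction <= 1,
            cfg$read_length > cfg$kmer,
            cfg$max_edit >= 0)
  invisible(cfg)
}

#' @export
print.duprec_config <- function(x, ...) {
  cat("duprec run configuration\n")
  cat(sprintf("  insert %d bp [%d, %d], reads %d bp, flank %d bp\n",
              x$insert_size, x$insert_lo, x$insert_hi, x$read_length,
              x$flank_width))
  cat(sprintf("  mu = %g, rho = %g, max_edit = %d, seed = %d\n",
              x$mu, x$rho, x$max_edit, x$seed))
  invisible(x)
}
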