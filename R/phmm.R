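# Template-driven assembly with profile HMMs: one model per duplicon
# (existing homologs and newly inserted copies), trained boundary-in from
# anchored reads under error-rate-constrained updates, with two-end reads
# recruited by anchored Viterbi decoding until convergence.

BASES <- c("A", "C", "G", "T")
TR_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

base_codes <- function(seq) {
  x <- match(strsplit(seq, "")[[1]], BASES)
  x[is.na(x)] <- 0L # ambiguity -> 0, handled as N
  x
}

#' Constrained probability update (emission rule)
#'
#' `E(v) = (O_v + w * c_v) / (O + w * sum(c))` with background weight
#' `w = w0 * exp(-rho * O)`, clamped to `[mu/(n-1), 1 - mu]` and
#' renormalised so each row sums to one.  With no observations the row
#' equals the normalised background; as observations accumulate the prior
#' decays at rate `rho` and probabilities approach the observed
#' frequencies, but never reach 0 or 1: the floor/cap encode the residual
#' sequencing-error probability `mu`.
#'
#' @param counts Observation count matrix (rows = states, columns =
#'   symbols) or a single row vector.
#' @param background Background pseudo-count vector `c_v`.
#' @param mu Sequencing error rate (sets floor `mu/(n-1)` and cap `1-mu`).
#' @param rho Training rate.
#' @param w0 Initial background weight.
#' @return Probability matrix of the same shape, rows summing to 1.
#' @export
update_emission <- function(counts, background, mu = 0.01, rho = 0.1,
                            w0 = 1.0) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  n <- ncol(counts)
  O <- rowSums(counts)
  w <- w0 * exp(-rho * O)
  raw <- (counts + outer(w, background)) / (O + w * sum(background))
  clamp_renorm(raw, mu / (n - 1), 1 - mu)
}

# exact bounded renormalisation: distribute the deficit proportionally to
# the remaining headroom so values stay inside [lo, hi]
clamp_renorm <- function(P, lo, hi) {
  P <- pmin(pmax(P, lo), hi)
  for (it in 1:25) {
    s <- rowSums(P)
    if (all(abs(s - 1) < 1e-12)) break
    excess <- 1 - s              # per-row deficit (may be negative)
    up <- excess > 0             # length-nrow vectors recycle column-wise
    room <- (hi - P) * up + (P - lo) * !up
    rs <- rowSums(room)
    adj <- room * (excess / pmax(rs, 1e-300))
    P <- pmin(pmax(P + adj, lo), hi)
  }
  P
}

#' Constrained transition update
#'
#' Applies the same clamp-and-renormalise rule as [update_emission()] to
#' each family of outgoing transitions (match, insert and delete states
#' separately).
#'
#' @param counts `(K+1) x 7` transition count matrix with columns
#'   MM, MI, MD, IM, II, DM, DD (row j+1 = from-column j).
#' @param config A [run_config()] (for `mu`, `rho`, `w0`).
#' @return Probability matrix of the same shape; each of the three
#'   families sums to 1 per row.
#' @export
update_transition <- function(counts, config = run_config()) {
  bg_m <- c(0.90, 0.05, 0.05) * 0.4
  bg_i <- c(0.70, 0.30) * 0.4
  bg_d <- c(0.70, 0.30) * 0.4
  out <- matrix(0, nrow(counts), 7L,
                dimnames = list(NULL, TR_NAMES))
  out[, 1:3] <- update_emission(counts[, 1:3, drop = FALSE], bg_m,
                                config$mu, config$rho, config$w0)
  out[, 4:5] <- update_emission(counts[, 4:5, drop = FALSE], bg_i,
                                config$mu, config$rho, config$w0)
  out[, 6:7] <- update_emission(counts[, 6:7, drop = FALSE], bg_d,
                                config$mu, config$rho, config$w0)
  out
}

#' Create a profile HMM from a template sequence
#'
#' One match column per template base.  Emission and transition counts are
#' initialised with a single observation of the template, so the initial
#' probabilities are the update rule applied once over the uniform
#' background; untrained columns therefore emit the template base in the
#' consensus.
#'
#' @param template Template sequence (ACGT; other codes get a flat prior).
#' @param config A [run_config()].
#' @param id Model identifier.
#' @return Object of class `phmm`.
#' @export
create_phmm <- function(template, config = run_config(), id = "phmm") {
  K <- nchar(template)
  stopifnot(K >= 1L)
  codes <- base_codes(template)
  counts_em <- matrix(0, K, 4L, dimnames = list(NULL, BASES))
  ok <- which(codes > 0L)
  counts_em[cbind(ok, codes[ok])] <- 1
  counts_tr <- matrix(0, K + 1L, 7L, dimnames = list(NULL, TR_NAMES))
  counts_tr[1:K, "MM"] <- 1
  m <- list(id = id, K = K, template = template,
            counts_em = counts_em, counts_tr = counts_tr,
            bg_em = rep(0.1, 4L),
            mu = config$mu, rho = config$rho, w0 = config$w0,
            trained = rep(FALSE, K), depth = integer(K))
  m$Em <- update_emission(m$counts_em, m$bg_em, m$mu, m$rho, m$w0)
  m$trans <- update_transition(m$counts_tr, config)
  class(m) <- "phmm"
  m
}

#' @export
print.phmm <- function(x, ...) {
  cat(sprintf("phmm '%s': %d columns, %d trained, frontier [%d, %d]\n",
              x$id, x$K, sum(x$trained), frontier(x)[1], frontier(x)[2]))
  invisible(x)
}

# (left, right) frontier markers: columns 1..left and right..K are trained
frontier <- function(m) {
  tr <- which(m$trained)
  if (!length(tr)) return(c(0L, m$K + 1L))
  left <- if (tr[1] == 1L) max(which(cumsum(!m$trained) == 0L)) else 0L
  right <- if (tr[length(tr)] == m$K)
    min(which(rev(cumsum(rev(!m$trained))) == 0L)) else m$K + 1L
  c(left, right)
}

#' Anchored Viterbi decoding
#'
#' Standard profile-HMM Viterbi in log space, with entry restricted to
#' match/insert states within `window` columns of `anchor` (the read's
#' mapped offset on the template).  Entry and exit are free, so scores are
#' comparable across models.  With a window covering the whole model this
#' equals unrestricted decoding.
#'
#' @param m A `phmm`.
#' @param seq Read sequence (reference orientation).
#' @param anchor Template column (1-based) where the read is expected to
#'   start.
#' @param window Entry window half-width in columns.
#' @return List: `logp`, `path` (matrix with columns state/col/readpos;
#'   state 0 = match, 1 = insert, 2 = delete).
#' @export
anchored_viterbi <- function(m, seq, anchor, window = 12L) {
  if (anchor < 1L || anchor > m$K) stop("anchor outside template")
  cpp_viterbi(seq, log(m$Em), log(m$trans), log(0.25),
              as.integer(anchor), as.integer(window))
}

# Align a set of anchored reads and accumulate observation counts.
# recs: data.table(qname, seq, anchor).  Returns count structures.
align_reads <- function(m, recs, window) {
  K <- m$K
  anchors <- as.integer(pmin(pmax(recs$anchor, 1L), K))
  acc <- cpp_phmm_train(recs$seq, log(m$Em), log(m$trans), log(0.25),
                        anchors, as.integer(window))
  ins <- if (length(acc$ins_col))
    mapply(function(j, s) c(j, s), acc$ins_col, acc$ins_str,
           SIMPLIFY = FALSE) else list()
  list(counts_em = acc$counts_em, counts_tr = acc$counts_tr,
       depth = acc$depth, matchc = acc$matchc, delc = acc$delc,
       junction = acc$junction, ins = ins, logps = acc$logps)
}

# Fold newly assigned reads into a model's counts without realigning the
# existing ones (incremental retrain step).
absorb_counts <- function(m, recs, config) {
  if (!nrow(recs)) return(m)
  acc <- align_reads(m, recs, config$anchor_window)
  m$counts_em <- m$counts_em + acc$counts_em
  m$counts_tr <- m$counts_tr + acc$counts_tr
  m$depth <- m$depth + acc$depth
  m$matchc <- m$matchc + acc$matchc
  m$delc <- m$delc + acc$delc
  m$junction <- m$junction + acc$junction
  m$ins <- c(m$ins, acc$ins)
  m$Em <- update_emission(m$counts_em, m$bg_em, m$mu, m$rho, m$w0)
  m$trans <- update_transition(m$counts_tr, config)
  m$trained <- m$depth >= config$min_depth
  m
}

# Retrain a model from its assigned reads (full realignment).
retrain_phmm <- function(m, recs, config) {
  K <- m$K
  init_em <- matrix(0, K, 4L); init_tr <- matrix(0, K + 1L, 7L)
  codes <- base_codes(m$template)
  ok <- which(codes > 0L)
  init_em[cbind(ok, codes[ok])] <- 1
  init_tr[1:K, 1L] <- 1
  if (nrow(recs)) {
    acc <- align_reads(m, recs, config$anchor_window)
    m$counts_em <- init_em + acc$counts_em
    m$counts_tr <- init_tr + acc$counts_tr
    m$depth <- acc$depth
    m$matchc <- acc$matchc; m$delc <- acc$delc
    m$junction <- acc$junction; m$ins <- acc$ins
  } else {
    m$counts_em <- init_em; m$counts_tr <- init_tr
    m$depth <- integer(K)
    m$matchc <- integer(K); m$delc <- integer(K)
    m$junction <- integer(K + 1L); m$ins <- list()
  }
  m$Em <- update_emission(m$counts_em, m$bg_em, m$mu, m$rho, m$w0)
  m$trans <- update_transition(m$counts_tr, config)
  m$trained <- m$depth >= config$min_depth
  m
}

#' Maximum-likelihood consensus of a trained profile HMM
#'
#' Per-column argmax emission over match states; columns whose delete
#' usage outvotes match usage are dropped; insert positions used by more
#' than half of the spanning reads emit the majority inserted string.
#' Untrained columns fall back to the template base.
#'
#' @param m A trained `phmm`.
#' @return Consensus sequence (character scalar).
#' @export
phmm_consensus <- function(m) {
  K <- m$K
  tmpl <- strsplit(m$template, "")[[1]]
  parts <- character(0)
  ins_by_col <- list()
  if (length(m$ins)) {
    for (x in m$ins) {
      j <- as.character(x[1])
      ins_by_col[[j]] <- c(ins_by_col[[j]], x[2])
    }
  }
  for (j in seq_len(K)) {
    emit <- TRUE
    if (isTRUE(m$trained[j]) && !is.null(m$delc) &&
        m$delc[j] > m$matchc[j]) emit <- FALSE
    if (emit) {
      if (isTRUE(m$trained[j])) {
        e <- m$Em[j, ]
        best <- which(e == max(e))
        base <- if (length(best) > 1L && tmpl[j] %in% BASES[best])
          tmpl[j] else BASES[best[1]]
        parts[length(parts) + 1L] <- base
      } else {
        parts[length(parts) + 1L] <- tmpl[j]
      }
    }
    jn <- if (!is.null(m$junction)) m$junction[j + 1L] else 0L
    istr <- ins_by_col[[as.character(j)]]
    if (!is.null(istr) && jn > 0L && length(istr) > 0.5 * jn) {
      tab <- sort(table(istr), decreasing = TRUE)
      parts[length(parts) + 1L] <- names(tab)[1]
    }
  }
  paste(parts, collapse = "")
}

#' Select the initial template for a breakpoint duplicon
#'
#' A subsequence of the longest homolog spanning the projection of the
#' supporting reads' internal-mate positions, padded by one read length on
#' each side and clipped to the homolog.
#'
#' @param bp One breakpoint call row.
#' @param hset The `homology_set`.
#' @param supports Support table for the call's cluster, with
#'   `int_member` (member index) and `int_pos` (internal mate position).
#' @param config A [run_config()].
#' @return List: `seq`, `member` (index of the longest homolog), `tstart`
#'   (0-based offset within that member), `chrom`, `start`, `end`.
#' @export
select_template <- function(bp, hset, supports, config = run_config()) {
  mb <- hset$members
  longest <- which.max(mb$end - mb$start)
  mlen <- mb$end[longest] - mb$start[longest]
  if (nrow(supports)) {
    # project member offsets of the internal mates onto the longest member
    off <- supports$int_pos - mb$start[supports$int_member]
    lo <- max(0L, min(off) - config$read_length)
    hi <- min(mlen, max(off) + supports$int_alen[which.max(off)][1] +
                config$read_length)
  } else {
    warning("no support projections; using the full longest homolog")
    lo <- 0L; hi <- mlen
  }
  gstart <- mb$start[longest] + lo
  gend <- mb$start[longest] + hi
  seq <- substr(hset$sequences[[longest]], lo + 1L, hi)
  list(seq = seq, member = longest, tstart = lo,
       chrom = mb$chrom[longest], start = gstart, end = gend)
}

#' Initial read partition for training
#'
#' Concordant one-end pairs are assigned to their member's model (the
#' internal end, anchored by its mapped offset); each discordant one-end
#' support is assigned to its breakpoint's model via the internal mate.
#' Two-end pairs stay unassigned for iterative recruiting.
#'
#' @param pairs Triaged wide pair table.
#' @param hset The `homology_set`.
#' @param calls Calls for this region (with `cluster` ids).
#' @param supports Scored support table (with `cluster` ids).
#' @param config A [run_config()].
#' @return List: `assigned` (model id -> data.table(qname, seq, anchor)),
#'   `twoend` (unassigned pool with per-end member offsets).
#' @export
initial_partition <- function(pairs, hset, calls, supports,
                              config = run_config()) {
  mb <- hset$members
  assigned <- list()
  for (i in seq_len(nrow(mb))) assigned[[mb$id[i]]] <-
    data.table(qname = character(0), seq = character(0), anchor = integer(0))
  conc <- pairs[class == "CONCORDANT_ONE_END"]
  for (i in seq_len(nrow(conc))) {
    int <- if (conc$mem_1[i] > 0L) 1L else 2L
    mem <- if (int == 1L) conc$mem_1[i] else conc$mem_2[i]
    if (mem == 0L) next
    pos <- if (int == 1L) conc$pos_1[i] else conc$pos_2[i]
    sq <- if (int == 1L) conc$seq_1[i] else conc$seq_2[i]
    anchor <- pos - mb$start[mem] + 1L
    assigned[[mb$id[mem]]] <- rbind(assigned[[mb$id[mem]]],
                                    data.table(qname = conc$qname[i],
                                               seq = sq, anchor = anchor))
  }
  if (!is.null(calls) && nrow(calls)) {
    for (ci in seq_len(nrow(calls))) {
      bid <- sprintf("bp%d", ci)
      sup <- supports[cluster == calls$cluster[ci]]
      recs <- data.table(qname = sup$qname, seq = sup$int_seq,
                         anchor = sup$int_anchor)
      assigned[[bid]] <- recs[!is.na(anchor)]
    }
  }
  twoend <- pairs[class == "TWO_END"]
  list(assigned = assigned, twoend = twoend)
}

# augment breakpoint models with orphan mates anchored at the insertion
# site: pairs with one end mapped within I of b (pointing at the junction)
# and the other unmapped are rescued against the breakpoint template.
# The mapped mate's side and orientation determine which template end and
# which strand the orphan can come from, so only a one-insert-wide window
# of the template needs aligning.
rescue_breakpoint_orphans <- function(aln, call, template, config) {
  b <- call$pos; chr <- call$chrom
  w <- aln[qname %in% aln[mapped == TRUE & chrom == chr &
                            pos >= b - config$insert_hi &
                            pos <= b + config$insert_hi, qname]]
  ww <- pairs_wide(w)
  ww <- ww[xor(mapped_1, mapped_2)]
  out <- data.table(qname = character(0), seq = character(0),
                    anchor = integer(0))
  if (!nrow(ww)) return(out)
  perfect <- config$sw_match * config$read_length
  K <- nchar(template)
  wlen <- min(K, config$insert_hi)
  tmpl_left <- substr(template, 1L, wlen)
  tmpl_right <- substr(template, K - wlen + 1L, K)
  for (i in seq_len(nrow(ww))) {
    unm <- if (!ww$mapped_1[i]) 1L else 2L
    sq <- if (unm == 1L) ww$seq_1[i] else ww$seq_2[i]
    ql <- if (unm == 1L) ww$qual_1[i] else ww$qual_2[i]
    mpos <- if (unm == 1L) ww$pos_2[i] else ww$pos_1[i]
    mstr <- if (unm == 1L) ww$strand_2[i] else ww$strand_1[i]
    if (!quality_pass(ql, config)) next
    # FR library: an upstream forward mate pairs with a reverse-oriented
    # orphan from the insert's left end; downstream reverse mate with a
    # forward orphan from the right end
    if (mpos < b && mstr == "+") {
      tseq <- tmpl_left; toff <- 0L
      q <- as.character(cpp_revcomp(sq))
    } else if (mpos >= b && mstr == "-") {
      tseq <- tmpl_right; toff <- K - wlen
      q <- sq
    } else next
    al <- cpp_sw(q, tseq, config$sw_match, config$sw_mismatch,
                 config$sw_gap_open, config$sw_gap_extend)
    if (al$cols == 0L) next
    sim <- al$matches / al$cols
    if (sim <= config$min_similarity ||
        al$score <= config$min_score_fraction * perfect) next
    out <- rbind(out, data.table(qname = ww$qname[i], seq = q,
                                 anchor = toff + al$tstart + 1L))
  }
  out
}

#' Train duplicon models and reconstruct consensus sequences
#'
#' The full iterative procedure for one candidate region: build one model
#' per homolog and per accepted breakpoint, partition one-end reads by
#' their anchors, rescue breakpoint-flank orphans into the breakpoint
#' models, then alternate retraining (with frontier extension) and
#' recruiting of two-end reads by joint anchored-Viterbi likelihood until
#' no read is newly assigned or all are assigned.
#'
#' @param context One region context from [find_breakpoints()].
#' @param calls Calls belonging to this region.
#' @param aln Full alignment table (for orphan rescue around breakpoints).
#' @param config A [run_config()].
#' @param max_iter Safety bound on training rounds.
#' @return List of `duprec_reconstruction` objects (one per duplicon)
#'   plus bookkeeping (`log`).
#' @export
train_duplicons <- function(context, calls, aln, config = run_config(),
                            max_iter = 30L) {
  hset <- context$hset
  mb <- hset$members
  pairs <- context$triage$pairs
  supports <- copy(context$supports)
  if (is.null(supports)) supports <- data.table()
  # attach internal-mate info to supports
  if (nrow(supports)) {
    sp <- merge(supports, pairs[, .(qname, seq_1, seq_2, pos_1, pos_2,
                                    alen_1, alen_2, mem_1, mem_2)],
                by = "qname", sort = FALSE)
    sp[, int_seq := ifelse(internal == 1L, seq_1, seq_2)]
    sp[, int_pos := ifelse(internal == 1L, pos_1, pos_2)]
    sp[, int_alen := ifelse(internal == 1L, alen_1, alen_2)]
    sp[, int_member := ifelse(internal == 1L, mem_1, mem_2)]
    supports <- sp
  }
  models <- list(); meta <- list()
  for (i in seq_len(nrow(mb))) {
    id <- mb$id[i]
    models[[id]] <- create_phmm(hset$sequences[[i]], config, id = id)
    meta[[id]] <- list(member = i, tstart = 0L, chrom = mb$chrom[i],
                       start = mb$start[i], end = mb$end[i])
  }
  has_calls <- !is.null(calls) && nrow(calls) > 0L
  templates <- list()
  if (has_calls) {
    for (ci in seq_len(nrow(calls))) {
      id <- sprintf("bp%d", ci)
      sup <- supports[cluster == calls$cluster[ci] & int_member > 0L]
      tm <- select_template(calls[ci], hset, sup, config)
      models[[id]] <- create_phmm(tm$seq, config, id = id)
      meta[[id]] <- list(member = tm$member, tstart = tm$tstart,
                         chrom = tm$chrom, start = tm$start, end = tm$end,
                         breakpoint = sprintf("%s:%d", calls$chrom[ci],
                                              calls$pos[ci]))
      templates[[id]] <- tm
    }
  }
  if (nrow(supports)) {
    supports[, int_anchor := NA_integer_]
    for (ci in seq_len(nrow(calls))) {
      id <- sprintf("bp%d", ci)
      tm <- templates[[id]]
      sel <- supports$cluster == calls$cluster[ci] & supports$int_member > 0L
      supports[sel, int_anchor :=
                 int_pos - mb$start[int_member] - tm$tstart + 1L]
    }
  }
  part <- initial_partition(pairs, hset, calls, supports, config)
  assigned <- part$assigned
  if (has_calls) {
    for (ci in seq_len(nrow(calls))) {
      id <- sprintf("bp%d", ci)
      extra <- rescue_breakpoint_orphans(aln, calls[ci],
                                         models[[id]]$template, config)
      if (nrow(extra)) assigned[[id]] <- rbind(assigned[[id]], extra)
    }
  }
  # two-end pool with per-end anchors (member offsets)
  te <- part$twoend
  pool <- NULL
  if (nrow(te)) {
    pool <- te[, .(qname, seq_1, seq_2,
                   off_1 = pos_1 - mb$start[mem_1],
                   off_2 = pos_2 - mb$start[mem_2])]
    pool[, assigned_to := NA_character_]
  }
  null_ll <- function(s1, s2) (nchar(s1) + nchar(s2)) * log(0.25)
  n_unassigned <- if (is.null(pool)) 0L else nrow(pool)
  log <- data.table(iter = integer(0), unassigned = integer(0),
                    newly = integer(0))
  # initial training from the anchored one-end reads
  for (id in names(models))
    models[[id]] <- retrain_phmm(models[[id]], assigned[[id]], config)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (is.null(pool) || !nrow(pool[is.na(assigned_to)]) || iter > max_iter) {
      log <- rbind(log, data.table(iter = iter, unassigned = n_unassigned,
                                   newly = 0L))
      break
    }
    newly <- 0L
    idx <- which(is.na(pool$assigned_to))
    win <- config$anchor_window
    smat <- matrix(-Inf, length(idx), length(models),
                   dimnames = list(NULL, names(models)))
    ncand <- integer(length(idx))   # models whose template hosts the pair
    nready <- integer(length(idx))  # of those, models trained near the pair
    for (id in names(models)) {
      mt <- meta[[id]]; mdl <- models[[id]]
      a1 <- pool$off_1[idx] - mt$tstart + 1L
      a2 <- pool$off_2[idx] - mt$tstart + 1L
      inrange <- !is.na(a1) & !is.na(a2) & a1 >= 1L & a1 <= mdl$K &
        a2 >= 1L & a2 <= mdl$K
      ncand <- ncand + inrange
      # eligible: at least one end near a trained column
      cumtr <- cumsum(mdl$trained)
      near_trained <- function(a) {
        lo <- pmax(1L, a - win); hi <- pmin(mdl$K, a + win)
        (cumtr[hi] - c(0L, cumtr)[lo]) > 0L
      }
      ok <- inrange
      ok[ok] <- near_trained(a1[ok]) | near_trained(a2[ok])
      nready <- nready + ok
      if (!any(ok)) next
      lEm <- log(mdl$Em); lTr <- log(mdl$trans)
      lp1 <- cpp_phmm_score(pool$seq_1[idx][ok], lEm, lTr, log(0.25),
                            as.integer(a1[ok]), win)
      lp2 <- cpp_phmm_score(pool$seq_2[idx][ok], lEm, lTr, log(0.25),
                            as.integer(a2[ok]), win)
      smat[ok, id] <- lp1 + lp2
    }
    best <- if (nrow(smat)) apply(smat, 1L, max) else numeric(0)
    nullv <- (nchar(pool$seq_1[idx]) + nchar(pool$seq_2[idx])) * log(0.25)
    nwin <- rowSums(smat >= best - config$recruit_margin)
    winner <- colnames(smat)[max.col(smat, ties.method = "first")]
    # a pair is assigned only when every hosting model could be scored:
    # premature one-model assignment (before a competitor's frontier
    # arrives) would bypass the maximum-likelihood comparison
    sel <- which(is.finite(best) &
                   best - nullv >= config$recruit_threshold &
                   nwin == 1L & nready == ncand) # margin ties -> defer
    if (length(sel)) {
      for (id in unique(winner[sel])) {
        rows <- idx[sel[winner[sel] == id]]
        add <- data.table(
          qname = rep(pool$qname[rows], 2L),
          seq = c(pool$seq_1[rows], pool$seq_2[rows]),
          anchor = c(pool$off_1[rows] - meta[[id]]$tstart + 1L,
                     pool$off_2[rows] - meta[[id]]$tstart + 1L))
        assigned[[id]] <- rbind(assigned[[id]], add)
        # incremental retrain: align only the newly assigned reads and
        # fold their counts in; a full realignment happens at convergence
        models[[id]] <- absorb_counts(models[[id]], add, config)
      }
      pool$assigned_to[idx[sel]] <- winner[sel]
      newly <- length(sel)
    }
    n_unassigned <- nrow(pool[is.na(assigned_to)])
    log <- rbind(log, data.table(iter = iter, unassigned = n_unassigned,
                                 newly = newly))
    if (newly == 0L) break
  }
  # final full retrain for clean counts and consensus
  for (id in names(models))
    models[[id]] <- retrain_phmm(models[[id]], assigned[[id]], config)
  recon <- list()
  for (id in names(models)) {
    m <- models[[id]]; mt <- meta[[id]]
    tr <- which(m$trained)
    core <- NULL
    if (length(tr) >= 2L) {
      inner <- setdiff(seq(min(tr), max(tr)), tr)
      if (length(inner)) core <- c(min(inner), max(inner))
    }
    recon[[id]] <- structure(list(
      id = id, consensus = phmm_consensus(m),
      template = m$template, template_chrom = mt$chrom,
      template_start = mt$start, template_end = mt$end,
      breakpoint = mt$breakpoint, n_reads = nrow(assigned[[id]]),
      depth = m$depth, trained = m$trained, unresolved_core = core,
      model = m), class = "duprec_reconstruction")
  }
  list(reconstructions = recon, log = log, pool = pool,
       assigned_counts = vapply(assigned, nrow, 1L))
}

#' @export
print.duprec_reconstruction <- function(x, ...) {
  cat(sprintf("duplicon %s: %d bp consensus (%d reads, %d/%d columns trained)\n",
              x$id, nchar(x$consensus), x$n_reads, sum(x$trained),
              length(x$trained)))
  if (!is.null(x$unresolved_core))
    cat(sprintf("  unresolved core: columns %d-%d\n", x$unresolved_core[1],
                x$unresolved_core[2]))
  invisible(x)
}

#' Reconstruct duplicon sequences for every region
#'
#' Runs [train_duplicons()] for each region context produced by
#' [find_breakpoints()].
#'
#' @param brk Result of [find_breakpoints()].
#' @param aln Full alignment table.
#' @param config A [run_config()].
#' @return List of per-region results (reconstructions + training log).
#' @export
reconstruct_duplicons <- function(brk, aln, config = run_config()) {
  out <- list()
  for (ri in seq_along(brk$contexts)) {
    ctx <- brk$contexts[[ri]]
    calls <- if (nrow(brk$calls)) brk$calls[region_idx == ri] else brk$calls
    out[[ri]] <- train_duplicons(ctx, calls, aln, config)
  }
  out
}
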