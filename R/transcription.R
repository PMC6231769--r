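# Per-site transcription evidence: elongation (jump and incr tests on
# long-cap 5'-end windows) and initiation (short-cap reproducibility and
# representative mode).

# strand-relative half-open window [a, b) around a summit, as genomic
# 0-based [from, to): for '+' it is [summit + a, summit + b); for '-' it is
# mirrored about the summit.
#' @noRd
rel_window <- function(summit, strand, a, b) {
  if (strand == "+") c(summit + a, summit + b)
  else c(summit - b + 1L, summit - a + 1L)
}

#' @noRd
cum_track <- function(track) c(0, cumsum(as.numeric(track)))

# sum of track over 0-based half-open [from, to), clipped to bounds
#' @noRd
window_sum_cum <- function(csum, from, to) {
  L <- length(csum) - 1L
  from <- max(0L, from); to <- min(L, to)
  if (from >= to) return(0)
  csum[to + 1L] - csum[from + 1L]
}

#' Count long-cap 5' ends in the jump-test windows
#'
#' Upstream window -250:-75 and downstream window +75:+250 relative to peak
#' accessibility, rendered half-open (`[summit-250, summit-75)` and
#' `[summit+75, summit+250)` on the plus strand, each 175 bp) and mirrored
#' about the summit on the minus strand.
#'
#' @param tracks list of per-replicate 5'-end count vectors (one strand).
#' @param summit 0-based summit position(s).
#' @param strand `"+"` or `"-"`.
#' @param up,down strand-relative window bounds (defaults -250:-75, 75:250).
#' @return List of matrices `upstream`, `downstream` (sites x replicates).
#' @export
window_counts <- function(tracks, summit, strand, up = c(-250L, -75L),
                          down = c(75L, 250L)) {
  stopifnot_strand(strand)
  cs <- lapply(tracks, cum_track)
  count1 <- function(win) vapply(cs, function(cc)
    vapply(seq_along(summit), function(i) {
      w <- rel_window(summit[i], strand, win[1], win[2])
      window_sum_cum(cc, w[1], w[2])
    }, numeric(1)), numeric(length(summit)))
  upm <- count1(up); dnm <- count1(down)
  if (length(summit) == 1L) { upm <- matrix(upm, 1L); dnm <- matrix(dnm, 1L) }
  list(upstream = upm, downstream = dnm)
}

#' Jump test for elongating transcription
#'
#' One-sided NB Wald test of downstream versus upstream long-cap 5'-end
#' counts across all sites of one stage/strand, with Benjamini-Hochberg
#' adjustment across sites.  A site passes at `lfc > 1.5` and `padj < 0.1`.
#'
#' @param upstream,downstream sites x replicates count matrices from
#'   [window_counts()].
#' @param lfc_threshold,padj_threshold pass thresholds.
#' @return data.table: `up_total`, `down_total`, `lfc`, `p`, `padj`,
#'   `passed`.
#' @export
jump_test <- function(upstream, downstream, lfc_threshold = 1.5,
                      padj_threshold = 0.1) {
  res <- nb_two_group_test(upstream, downstream, alternative = "greater")
  padj <- stats::p.adjust(res$p, method = "BH")
  data.table::data.table(
    up_total = rowSums(upstream), down_total = rowSums(downstream),
    lfc = res$lfc, p = res$p, padj = padj,
    passed = res$lfc > lfc_threshold & padj < padj_threshold)
}

#' incr test for weak elongation signal
#'
#' Deterministic rule: zero reads upstream, at least one read downstream in
#' every biological replicate, and at least `min_total` reads downstream
#' summed across replicates.
#'
#' @param upstream,downstream sites x replicates count matrices.
#' @param min_total minimum summed downstream count (default 3).
#' @return data.table: `up_total`, `down_total`, `passed`.
#' @export
incr_test <- function(upstream, downstream, min_total = 3) {
  up_tot <- rowSums(upstream)
  dn_tot <- rowSums(downstream)
  all_pos <- rowSums(downstream >= 1) == ncol(downstream)
  data.table::data.table(up_total = up_tot, down_total = dn_tot,
                         passed = up_tot == 0 & all_pos & dn_tot >= min_total)
}

#' Pool short-cap replicates and build the reproducibility mask
#'
#' Pooled signal is the sum across replicates; a base pair is reproducible
#' when at least two replicates have nonzero initiation there.  Pooled
#' signal outside the mask is zeroed for downstream use.
#'
#' @param rep_tracks list of per-replicate 5'-end count vectors.
#' @return List: `pooled` (masked pooled counts), `mask` (logical vector).
#' @export
pool_shortcap <- function(rep_tracks) {
  stopifnot(length(rep_tracks) >= 2L)
  pooled <- Reduce(`+`, lapply(rep_tracks, as.numeric))
  nz <- Reduce(`+`, lapply(rep_tracks, function(v) as.integer(v > 0)))
  mask <- nz >= 2L
  pooled[!mask] <- 0
  list(pooled = pooled, mask = mask)
}

#' Representative transcription initiation call
#'
#' A site has transcription initiation when any reproducible base pair lies
#' within `window` bp of peak accessibility (inclusive on both ends).  The
#' mode is the reproducible position with maximal pooled signal (ties:
#' closest to the summit, then strand-relative downstream); sites without
#' reproducible signal get a best-guess mode `offset` bp strand-relative
#' downstream of the summit.
#'
#' @param pooled,mask from [pool_shortcap()].
#' @param summit 0-based summit position.
#' @param strand `"+"` or `"-"`.
#' @param window search half-width in bp (default 125).
#' @param offset best-guess offset in bp (default 60).
#' @return List: `passed`, `mode` (0-based bp), `provenance` (`"observed"`
#'   or `"best_guess"`).
#' @export
initiation_call <- function(pooled, mask, summit, strand, window = 125L,
                            offset = 60L) {
  stopifnot_strand(strand)
  L <- length(pooled)
  lo <- max(0L, summit - window); hi <- min(L - 1L, summit + window)
  idx <- (lo:hi)[mask[(lo:hi) + 1L]]
  if (length(idx) == 0L) {
    mode <- if (strand == "+") summit + offset else summit - offset
    return(list(passed = FALSE, mode = as.integer(mode),
                provenance = "best_guess"))
  }
  val <- pooled[idx + 1L]
  best <- idx[val == max(val)]
  d <- abs(best - summit)
  best <- best[d == min(d)]
  if (length(best) > 1L)   # equidistant up/down: prefer strand-relative downstream
    best <- if (strand == "+") max(best) else min(best)
  list(passed = TRUE, mode = as.integer(best), provenance = "observed")
}

#' Compute the full evidence set for called sites
#'
#' Runs the jump and incr tests per stage and strand (BH adjustment across
#' sites within each stage/strand) and the initiation call per strand from
#' the pooled short-cap tracks.
#'
#' @param sites called-sites data.table (`chrom`, `summit`).
#' @param signal a [simulate_signal()] bundle.
#' @param config pipeline configuration.
#' @return List of class `wormcis_evidence`: `jump[[stage]][[strand]]` and
#'   `incr[[stage]][[strand]]` data.tables (rows = sites), `init[[strand]]`
#'   data.table (`passed`, `mode`, `provenance`), `max_jump_lfc[[strand]]`
#'   numeric vector (max over stages), and `stages`.
#' @export
transcription_evidence <- function(sites, signal, config = default_config()) {
  stages <- signal$stages
  strands <- c("+", "-")
  n <- nrow(sites)
  chroms <- unique(sites$chrom)
  ev <- list(stages = stages, jump = list(), incr = list(), init = list(),
             max_jump_lfc = list())
  for (strand in strands) {
    jl <- list(); il <- list()
    for (st in stages) {
      upm <- matrix(0, n, signal$n_reps); dnm <- matrix(0, n, signal$n_reps)
      for (cn in chroms) {
        ii <- which(sites$chrom == cn)
        tracks <- lapply(seq_len(signal$n_reps), function(r)
          signal$lcap5[[st]][[r]][[strand]][[cn]])
        wc <- window_counts(tracks, sites$summit[ii], strand,
                            config$jump_up, config$jump_down)
        upm[ii, ] <- wc$upstream; dnm[ii, ] <- wc$downstream
      }
      jl[[st]] <- jump_test(upm, dnm, config$jump_lfc, config$jump_padj)
      il[[st]] <- incr_test(upm, dnm, config$incr_min_total)
    }
    ev$jump[[strand]] <- jl
    ev$incr[[strand]] <- il
    ev$max_jump_lfc[[strand]] <-
      do.call(pmax, lapply(jl, function(x) x$lfc))
    # initiation from pooled short-cap
    init <- vector("list", n)
    for (cn in chroms) {
      reps <- lapply(seq_along(signal$scap5), function(r)
        signal$scap5[[r]][[strand]][[cn]])
      ps <- pool_shortcap(reps)
      for (i in which(sites$chrom == cn))
        init[[i]] <- initiation_call(ps$pooled, ps$mask, sites$summit[i],
                                     strand, config$init_window,
                                     config$best_guess_offset)
    }
    ev$init[[strand]] <- data.table::data.table(
      passed = vapply(init, `[[`, logical(1), "passed"),
      mode = vapply(init, `[[`, integer(1), "mode"),
      provenance = vapply(init, `[[`, character(1), "provenance"))
  }
  class(ev) <- c("wormcis_evidence", "list")
  ev
}
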