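# Accessible-site identification: concavity detection on smoothed ATAC
# coverage, per-sample second-derivative scoring, IDR filtering, boundary
# setting and multi-source merging.

#' @noRd
d2_gauss_kernel <- function(bandwidth) {
  h <- as.integer(ceiling(4 * bandwidth))
  t <- -h:h
  k <- stats::dnorm(t, 0, bandwidth) * (t^2 - bandwidth^2) / bandwidth^4
  k - mean(k)   # exact zero response to constant tracks
}

#' Smoothed second derivative of a coverage track
#'
#' Convolution with the second derivative of a Gaussian kernel of standard
#' deviation `bandwidth`; linear in the input and exactly zero on constant
#' tracks.  Edges are padded with the boundary value (replicate padding), so
#' a constant track maps to zero everywhere rather than producing artificial
#' boundary steps.
#'
#' @param coverage numeric per-bp track.
#' @param bandwidth smoothing scale in bp (> 0).
#' @return Numeric track of the same length.
#' @export
smoothed_second_derivative <- function(coverage, bandwidth = 50) {
  stopifnot(bandwidth > 0)
  n <- length(coverage)
  if (n == 0L) stop("empty track", call. = FALSE)
  k <- d2_gauss_kernel(bandwidth)
  h <- (length(k) - 1L) / 2L
  x <- as.numeric(coverage)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  out <- stats::convolve(xp, rev(k), type = "open")
  out[(2L * h + 1L):(2L * h + n)]
}

# kernel dot-product at selected positions only (cheap per-sample scoring)
#' @noRd
d2_at_positions <- function(coverage, positions, bandwidth = 50) {
  k <- d2_gauss_kernel(bandwidth)
  h <- (length(k) - 1L) / 2L
  x <- as.numeric(coverage)
  padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
  vapply(positions, function(p) {
    # p is 0-based; padded index of p is p + h + 1
    sum(padded[(p + 1L):(p + 1L + 2L * h)] * k)
  }, numeric(1))
}

#' Find concave regions of a second-derivative track
#'
#' Maximal runs of strictly negative smoothed second derivative, each with a
#' summit at the position of maximum mean coverage within the run (leftmost
#' on ties).  Runs shorter than `min_width` bp are discarded.
#'
#' @param d2_track second-derivative track from
#'   [smoothed_second_derivative()] on the cross-stage mean coverage.
#' @param mean_coverage the mean coverage track itself (summit localization).
#' @param min_width minimum region width in bp.
#' @param chrom chromosome name attached to the output.
#' @param tol absolute tolerance below which the second derivative is
#'   treated as zero (absorbs FFT round-off on flat tracks).
#' @return data.table: `chrom`, `start`, `end` (0-based half-open), `summit`.
#' @export
find_concave_regions <- function(d2_track, mean_coverage, min_width = 20,
                                 chrom = "chrI", tol = 1e-8) {
  stopifnot(length(d2_track) == length(mean_coverage))
  r <- rle(d2_track < -tol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  if (!any(keep))
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), summit = integer(0)))
  s <- starts[keep]; e <- ends[keep]
  summit <- vapply(seq_along(s), function(i) {
    s[i] + which.max(mean_coverage[s[i]:e[i]]) - 1L
  }, integer(1))
  data.table::data.table(chrom = chrom, start = s - 1L, end = e,
                         summit = summit - 1L)
}

#' Score candidate peaks in each sample
#'
#' The per-sample score of a candidate is the magnitude of that sample's
#' smoothed second derivative at the candidate summit, floored at zero:
#' `max(0, -d2_sample(summit))`.  Linear in the sample coverage.
#'
#' @param candidates data.table from [find_concave_regions()].
#' @param sample_coverage numeric track of one sample.
#' @param bandwidth smoothing scale in bp.
#' @return Numeric score vector (one per candidate).
#' @export
score_candidates <- function(candidates, sample_coverage, bandwidth = 50) {
  if (nrow(candidates) == 0L) return(numeric(0))
  pmax(0, -d2_at_positions(sample_coverage, candidates$summit, bandwidth))
}

#' Call reproducible accessible sites
#'
#' A candidate is retained if its rank-cumulative IDR is at or below
#' `idr_cutoff` in at least one stage's replicate pair.  Site boundaries are
#' peak accessibility (the summit) extended by `flank` bp on both sides,
#' i.e. the half-open interval `[summit - flank, summit + flank + 1)` of
#' width `2 * flank + 1`.
#'
#' @param candidates data.table from [find_concave_regions()].
#' @param stage_scores named list: stage -> list of per-replicate score
#'   vectors (the first two replicates are paired for IDR).
#' @param idr_cutoff IDR retention threshold (default 0.001).
#' @param flank boundary flank in bp (default 75, giving 151-bp sites).
#' @return data.table: `chrom`, `start`, `end`, `summit`, `idr` (minimum
#'   across stages), one `idr_<stage>` column per stage.
#' @export
call_peaks <- function(candidates, stage_scores, idr_cutoff = 0.001,
                       flank = 75L) {
  stopifnot(idr_cutoff > 0, idr_cutoff < 1)
  n <- nrow(candidates)
  idr_mat <- matrix(NA_real_, n, length(stage_scores),
                    dimnames = list(NULL, names(stage_scores)))
  for (st in names(stage_scores)) {
    reps <- stage_scores[[st]]
    stopifnot(length(reps) >= 2L)
    fit <- fit_idr(reps[[1]], reps[[2]])
    idr_mat[, st] <- fit$IDR
  }
  min_idr <- apply(idr_mat, 1L, min)
  keep <- min_idr <= idr_cutoff
  out <- candidates[keep, c("chrom", "summit")]
  out[, `:=`(start = summit - as.integer(flank),
             end = summit + as.integer(flank) + 1L,
             idr = min_idr[keep])]
  for (st in colnames(idr_mat))
    data.table::set(out, j = paste0("idr_", st), value = idr_mat[keep, st])
  data.table::setcolorder(out, c("chrom", "start", "end", "summit", "idr"))
  out[]
}

#' Per-stage accessibility heights of called sites
#'
#' Height = maximum depth-normalized replicate-mean ATAC coverage within the
#' site boundary.  Each replicate track is scaled to reads-per-million
#' equivalents (1e6 / total track signal) before averaging.
#'
#' @param sites data.table with `chrom`, `start`, `end`.
#' @param atac `atac[[stage]][[rep]][[chrom]]` track lists (a
#'   [simulate_signal()] bundle component).
#' @param stages stage names to compute.
#' @return The sites table with `atac_<stage>_height` columns added.
#' @export
site_heights <- function(sites, atac, stages = names(atac)) {
  for (st in stages) {
    reps <- atac[[st]]
    norm <- lapply(reps, function(tr) {
      tot <- sum(vapply(tr, function(v) sum(as.numeric(v)), numeric(1)))
      lapply(tr, function(v) as.numeric(v) * 1e6 / tot)
    })
    h <- vapply(seq_len(nrow(sites)), function(i) {
      cn <- sites$chrom[i]
      idx <- (sites$start[i] + 1L):(sites$end[i])
      idx <- idx[idx >= 1L & idx <= length(norm[[1]][[cn]])]
      m <- Reduce(`+`, lapply(norm, function(r) r[[cn]][idx])) / length(norm)
      max(m)
    }, numeric(1))
    data.table::set(sites, j = paste0("atac_", st, "_height"), value = h)
  }
  sites
}

#' Merge peak sets with earlier-set precedence
#'
#' Keeps all primary sites, then secondary sites that do not overlap (share
#' at least one bp with) any kept site, then tertiary sites likewise.  Each
#' output site is tagged with its source.
#'
#' @param primary,secondary,tertiary site data.tables (`chrom`, `start`,
#'   `end`, ...); `secondary`/`tertiary` may be `NULL` or empty.
#' @param sources length-3 character vector of source tags.
#' @return Combined data.table with an `atac_source` column, sorted by
#'   position.
#' @export
merge_peak_sets <- function(primary, secondary = NULL, tertiary = NULL,
                            sources = c("atac_wt_pe", "atac_wt_se",
                                        "atac_glp1_se")) {
  as_gr <- function(x) GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  sets <- list(primary, secondary, tertiary)
  acc <- NULL
  out <- list()
  for (i in 1:3) {
    s <- sets[[i]]
    if (is.null(s) || nrow(s) == 0L) next
    s <- data.table::copy(s)
    if (!is.null(acc)) {
      ov <- IRanges::overlapsAny(as_gr(s), acc)
      s <- s[!ov]
    }
    if (nrow(s) == 0L) next
    s[, atac_source := sources[i]]
    acc <- if (is.null(acc)) as_gr(s) else c(acc, as_gr(s))
    out[[length(out) + 1L]] <- s
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), atac_source = character(0)))
  res <- data.table::rbindlist(out, fill = TRUE)
  data.table::setorder(res, chrom, start)
  res[]
}

#' Identify accessible sites from a signal bundle
#'
#' Driver composing the peak-calling steps for one replicate-set of stages:
#' cross-stage mean coverage, smoothed second derivative, concave regions,
#' per-sample scoring and IDR filtering.
#'
#' @param signal a [simulate_signal()] bundle (or equivalent structure).
#' @param stages stages to use (default all in the bundle).
#' @param config pipeline configuration ([default_config()]).
#' @return Called sites data.table (no heights; see [site_heights()]).
#' @export
find_accessible_sites <- function(signal, stages = signal$stages,
                                  config = default_config()) {
  chroms <- signal$chromosomes
  all_sites <- list()
  for (ci in seq_len(nrow(chroms))) {
    cn <- chroms$name[ci]
    tracks <- list()
    for (st in stages)
      for (r in seq_along(signal$atac[[st]]))
        tracks[[paste(st, r)]] <- as.numeric(signal$atac[[st]][[r]][[cn]])
    mean_cov <- Reduce(`+`, tracks) / length(tracks)
    d2 <- smoothed_second_derivative(mean_cov, config$d2_bandwidth)
    cand <- find_concave_regions(d2, mean_cov, config$min_concave_width, cn)
    if (nrow(cand) == 0L) next
    stage_scores <- lapply(stages, function(st)
      lapply(seq_along(signal$atac[[st]]), function(r)
        score_candidates(cand, as.numeric(signal$atac[[st]][[r]][[cn]]),
                         config$d2_bandwidth)))
    names(stage_scores) <- stages
    all_sites[[cn]] <- call_peaks(cand, stage_scores, config$idr_cutoff,
                                  config$boundary_flank)
  }
  if (!length(all_sites))
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), summit = integer(0),
                                  idr = numeric(0)))
  data.table::rbindlist(all_sites, fill = TRUE)
}
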