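# Signal simulation: per-stage/replicate ATAC coverage, stranded long-cap
# 5'-end and coverage tracks, and pooled-design short-cap 5'-end tracks.
# Tracks are named lists (one integer/numeric vector per chromosome).

#' @noRd
add_into <- function(vec, from, to, values) {
  # clip [from, to] (0-based inclusive) to track bounds and add
  L <- length(vec)
  lo <- max(0L, from); hi <- min(L - 1L, to)
  if (lo > hi) return(vec)
  off <- lo - from
  vec[(lo + 1L):(hi + 1L)] <- vec[(lo + 1L):(hi + 1L)] +
    values[(1L + off):(1L + off + (hi - lo))]
  vec
}

#' Simulate signal tracks for a genome with planted elements
#'
#' Emulates the statistical structure the downstream analysis assumes:
#' * ATAC coverage: a Gaussian bump (sd `atac_sd`) at each active element,
#'   amplitude `depth` times the element's stage multiplier, over a uniform
#'   Poisson background; per-replicate counts are negative binomial with the
#'   shared mean and dispersion `dispersion`.
#' * Long-cap 5' ends: promoter elements gain reads at `lcap5_rate` times the
#'   stage multiplier per bp over 400 bp strand-relative downstream of the
#'   element center; enhancers gain none (initiation without elongation).
#' * Long-cap coverage: a deterministic plateau of `ceiling(2 x multiplier)`
#'   from promoter center through the outron to the end of the first exon,
#'   plus Poisson background, so nascent transcription is continuous from
#'   distal promoters to their gene.
#' * Short-cap 5' ends (per replicate and strand, pooled design): active
#'   elements receive a reproducible initiation mode, with a divergent
#'   upstream antisense mode at promoters.
#'
#' @param genome,elements from [simulate_genome()] and [plant_elements()].
#' @param depth accessibility amplitude scale (reads per element); 0 disables
#'   all element-derived signal.
#' @param dispersion negative-binomial dispersion of replicate counts.
#' @param seed integer seed (bit-identical output for identical seeds).
#' @param stages stage names; `n_reps` ATAC/long-cap replicates per stage;
#'   `n_scap_reps` short-cap replicates.
#' @param bg_5p,bg_cov background Poisson rates per bp for 5'-end and
#'   coverage tracks.
#' @param atac_sd Gaussian sd of the accessibility bump in bp.
#' @param lcap5_rate downstream long-cap 5'-end rate per bp per unit
#'   multiplier; `scap_mean` expected initiation reads per replicate at an
#'   active element.
#' @return List of class `wormcis_signal`: `atac[[stage]][[rep]]`,
#'   `lcap5[[stage]][[rep]][[strand]]`, `lcapcov[[stage]][[rep]][[strand]]`,
#'   `scap5[[rep]][[strand]]`, each a per-chromosome list of integer vectors,
#'   plus `stages`, `n_reps` and `chromosomes`.
#' @export
simulate_signal <- function(genome, elements, depth = 50, dispersion = 0.05,
                            seed = 1L, stages = stage_names(), n_reps = 2L,
                            n_scap_reps = 4L, bg_5p = 0.01, bg_cov = 1.0,
                            atac_sd = 75, lcap5_rate = 0.08, scap_mean = 6) {
  stopifnot(depth >= 0, dispersion >= 0, n_reps >= 2L)
  chroms <- genome$chromosomes
  prof <- as.matrix(elements[, paste0("prof_", stages), with = FALSE])
  fe <- genome$exons[genome$exons$is_first, ]
  fe <- fe[match(elements$target_gene_id, fe$gene_id), ]
  is_prom <- elements$true_class %in% c("coding_promoter", "pseudogene_promoter")
  draw_nb <- function(mu) {
    n <- length(mu)
    if (dispersion > 0) as.integer(stats::rnbinom(n, size = 1 / dispersion, mu = mu))
    else as.integer(stats::rpois(n, mu))
  }
  # Gaussian bump shape, cached
  half <- as.integer(ceiling(4 * atac_sd))
  shape <- exp(-((-half:half)^2) / (2 * atac_sd^2))

  with_seed(seed, {
    per_rep <- function(inner) stats::setNames(
      lapply(stages, function(s) lapply(seq_len(n_reps), function(r) inner())),
      stages)
    stranded <- function() list(`+` = list(), `-` = list())
    out <- list(stages = stages, n_reps = n_reps, chromosomes = chroms,
                atac = per_rep(function() list()),
                lcap5 = per_rep(stranded),
                lcapcov = per_rep(stranded),
                scap5 = lapply(seq_len(n_scap_reps), function(r) stranded()))
    for (ci in seq_len(nrow(chroms))) {
      cname <- chroms$name[ci]; L <- chroms$length[ci]
      on_chrom <- which(elements$chrom == cname)
      for (si in seq_along(stages)) {
        st <- stages[si]
        mu <- rep(bg_cov, L)
        for (e in on_chrom) {
          amp <- depth * prof[e, si]
          if (amp <= 0) next
          c0 <- elements$center[e]
          mu <- add_into(mu, c0 - half, c0 + half, amp * shape)
        }
        for (r in seq_len(n_reps))
          out$atac[[st]][[r]][[cname]] <- draw_nb(mu)
        for (strand in c("+", "-")) {
          # long-cap 5' ends
          rate <- rep(bg_5p, L)
          cov_extra <- integer(L)
          for (e in on_chrom) {
            if (!is_prom[e] || elements$strand[e] != strand) next
            m <- prof[e, si]
            if (m <= 0 || depth == 0) next
            c0 <- elements$center[e]
            win <- if (strand == "+") c(c0, c0 + 400L) else c(c0 - 400L, c0)
            rate <- add_into(rate, win[1], win[2],
                             rep(lcap5_rate * m, win[2] - win[1] + 1L))
            # coverage plateau: center through outron to first-exon end
            fend <- if (strand == "+") fe$end[e] - 1L else fe$start[e]
            span <- sort(c(c0, fend))
            pl <- as.integer(ceiling(2 * m))
            idx <- (max(0L, span[1]) + 1L):(min(L - 1L, span[2]) + 1L)
            cov_extra[idx] <- pmax(cov_extra[idx], pl)
          }
          for (r in seq_len(n_reps)) {
            out$lcap5[[st]][[r]][[strand]][[cname]] <- draw_nb(rate)
            out$lcapcov[[st]][[r]][[strand]][[cname]] <-
              as.integer(stats::rpois(L, bg_cov)) + cov_extra
          }
        }
      }
      # short-cap: per replicate x strand, one pooled design
      active <- depth > 0 & apply(prof, 1, max) > 0
      modes <- list(`+` = list(), `-` = list())
      for (e in on_chrom) {
        if (!active[e]) next
        c0 <- elements$center[e]; cls <- elements$true_class[e]
        s0 <- elements$strand[e]
        if (cls %in% c("coding_promoter", "pseudogene_promoter", "ncRNA_site")) {
          modes[[s0]][[length(modes[[s0]]) + 1L]] <- c(c0, 1.0)
          anti <- other_strand(s0)
          am <- if (s0 == "+") c0 - 60L else c0 + 60L
          modes[[anti]][[length(modes[[anti]]) + 1L]] <- c(am, 0.4)
        } else if (cls == "enhancer") {
          modes[["+"]][[length(modes[["+"]]) + 1L]] <- c(c0 + 10L, 1.0)
          modes[["-"]][[length(modes[["-"]]) + 1L]] <- c(c0 - 10L, 1.0)
        }
      }
      tri <- (16 - abs(-15:15)) / sum(16 - abs(-15:15))  # spread component
      for (strand in c("+", "-")) {
        rate <- rep(bg_5p, L)
        for (mw in modes[[strand]]) {
          m <- as.integer(mw[1]); w <- scap_mean * mw[2]
          rate <- add_into(rate, m, m, 0.5 * w)
          rate <- add_into(rate, m - 15L, m + 15L, 0.5 * w * tri)
        }
        for (r in seq_len(n_scap_reps))
          out$scap5[[r]][[strand]][[cname]] <- as.integer(stats::rpois(L, rate))
      }
    }
    class(out) <- c("wormcis_signal", "list")
    out
  })
}

#' Simulate TF peak sets and a gene-by-tissue TPM table
#'
#' Designated enriched TFs bind elements of one target cluster at elevated
#' odds (`enrich_or` on the binding odds scale); a designated HOT subset of
#' elements receives summit-exact peaks from `hot_threshold` TFs.  Target
#' genes of each cluster get a dominant tissue with at least three-fold
#' expression over the runner-up; TF expression rows (named by factor) are
#' appended so relative TF expression can be computed from the same table.
#'
#' @param elements planted elements (rows with non-`NA` `true_cluster` form
#'   the binding universe).
#' @param clusters integer cluster label per element row; defaults to
#'   `elements$true_cluster`.
#' @param n_tfs,n_tissues number of factors and tissues (max 7 tissue names).
#' @param seed integer seed.
#' @param n_enriched number of planted enriched factors (first factors, one
#'   target cluster each, round-robin).
#' @param enrich_or planted odds ratio of enriched binding.
#' @param bg_rate background per-element binding probability.
#' @param hot_n number of HOT elements (requires `n_tfs >= hot_threshold`).
#' @param hot_threshold factor count defining HOT.
#' @param n_random_peaks extra off-element peaks per factor.
#' @return List: `tf_peaks` (data.table chrom/start/end/name/score/strand/
#'   summit), `tpm` (matrix genes+factors x tissues), `tpm_counts` (matrix,
#'   two NB replicate columns per tissue), `enriched` (factor, target
#'   cluster), `hot_elements` (element ids).
#' @export
simulate_tf_and_expression <- function(elements, clusters = elements$true_cluster,
                                       n_tfs = 30L, n_tissues = 7L, seed = 1L,
                                       n_enriched = 5L, enrich_or = 4,
                                       bg_rate = 0.08, hot_n = 0L,
                                       hot_threshold = 19L,
                                       n_random_peaks = 20L) {
  if (n_tfs < n_enriched)
    stop("n_tfs smaller than the number of enriched TFs", call. = FALSE)
  if (hot_n > 0L && n_tfs < hot_threshold)
    stop("HOT elements need at least hot_threshold TFs", call. = FALSE)
  tissues <- c("Gonad", "Hypodermis", "Intestine", "Muscle", "Neurons",
               "Glia", "Pharynx")[seq_len(n_tissues)]
  univ <- which(!is.na(clusters))
  mid <- elements$center[univ]
  cl <- clusters[univ]
  ks <- sort(unique(cl))
  chrom <- elements$chrom[1]
  chrom_max <- max(elements$center) + 5000L
  tf_names <- sprintf("tf_%03d", seq_len(n_tfs))
  enriched <- if (n_enriched > 0L)
    data.table::data.table(tf = tf_names[seq_len(n_enriched)],
                           target_cluster = ks[((seq_len(n_enriched) - 1L) %% length(ks)) + 1L])
  else data.table::data.table(tf = character(0), target_cluster = integer(0))

  with_seed(seed, {
    peaks <- list()
    emit <- function(tf, summit) {
      peaks[[length(peaks) + 1L]] <<- data.table::data.table(
        chrom = chrom, start = summit - 75L, end = summit + 76L,
        name = tf, score = 0L, strand = ".", summit = as.integer(summit))
    }
    for (ti in seq_len(n_tfs)) {
      tf <- tf_names[ti]
      p <- rep(bg_rate, length(univ))
      hit <- match(tf, enriched$tf)
      if (!is.na(hit)) {
        tc <- enriched$target_cluster[hit]
        p1 <- enrich_or * bg_rate / (1 - bg_rate + enrich_or * bg_rate)
        p[cl == tc] <- p1
      }
      bound <- stats::runif(length(univ)) < p
      for (i in which(bound))
        emit(tf, mid[i] + sample.int(301L, 1L) - 151L)
      if (n_random_peaks > 0L)
        for (s in sample.int(chrom_max - 2000L, n_random_peaks) + 1000L)
          emit(tf, s)
    }
    hot_elements <- character(0)
    if (hot_n > 0L) {
      hidx <- sample(univ, min(hot_n, length(univ)))
      hot_elements <- elements$element_id[hidx]
      for (i in hidx)
        for (tf in sample(tf_names, hot_threshold))
          emit(tf, elements$center[i])
    }
    tf_peaks <- data.table::rbindlist(peaks)

    # gene x tissue TPMs: cluster targets get a dominant tissue (fold >= 3)
    genes <- unique(stats::na.omit(elements$target_gene_id))
    gene_cl <- clusters[match(genes, elements$target_gene_id)]
    all_rows <- c(genes, tf_names)
    tpm <- matrix(0, nrow = length(all_rows), ncol = n_tissues,
                  dimnames = list(all_rows, tissues))
    dom_tissue <- function(k) ((k - 1L) %% n_tissues) + 1L
    for (gi in seq_along(genes)) {
      base <- 6 * exp(stats::rnorm(n_tissues, 0, 0.25))
      k <- gene_cl[gi]
      if (!is.na(k)) {
        # dominant tissue guaranteed >= 3-fold over the runner-up
        # (pseudo-value 0.1 included, matching the downstream bias call)
        base[dom_tissue(k)] <- (max(base[-dom_tissue(k)]) + 0.1) *
          stats::runif(1, 3.5, 6) - 0.1
      }
      tpm[gi, ] <- base
    }
    for (ti in seq_len(n_tfs)) {
      base <- 5 * exp(stats::rnorm(n_tissues, 0, 0.3))
      hit <- match(tf_names[ti], enriched$tf)
      if (!is.na(hit)) base[dom_tissue(enriched$target_cluster[hit])] <-
          25 * exp(stats::rnorm(1, 0, 0.15))
      tpm[length(genes) + ti, ] <- base
    }
    counts <- matrix(0L, nrow = nrow(tpm), ncol = 2L * n_tissues,
                     dimnames = list(all_rows,
                                     paste0(rep(tissues, each = 2L), "_rep", 1:2)))
    for (j in seq_len(n_tissues))
      for (r in 1:2)
        counts[, 2L * (j - 1L) + r] <-
          as.integer(stats::rnbinom(nrow(tpm), size = 20, mu = tpm[, j] * 20))
    list(tf_peaks = tf_peaks, tpm = tpm, tpm_counts = counts,
         enriched = enriched, hot_elements = hot_elements)
  })
}

#' Simulate relative-accessibility profiles from planted archetypes
#'
#' Draws `n` promoters from `k` temporal archetypes with multiplicative
#' log-normal noise; used to validate cluster recovery.
#'
#' @param n number of profiles; `k` archetypes; `noise_sd` log-scale sd;
#'   `seed` integer seed; `course` which time course.
#' @return List: `counts` (n x t matrix of accessibility values), `labels`
#'   (true archetype per row).
#' @export
simulate_profile_matrix <- function(n = 400L, k = 4L, noise_sd = 0.2,
                                    seed = 1L,
                                    course = c("development", "ageing")) {
  course <- match.arg(course)
  stages <- stage_names(course)
  arch <- archetype_profiles(stages, k)
  with_seed(seed, {
    labels <- sample.int(k, n, replace = TRUE)
    counts <- 100 * arch[labels, , drop = FALSE] *
      matrix(exp(stats::rnorm(n * length(stages), 0, noise_sd)), n)
    dimnames(counts) <- list(sprintf("prom_%04d", seq_len(n)), stages)
    list(counts = counts, labels = labels)
  })
}
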