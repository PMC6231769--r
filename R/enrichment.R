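# Tissue-bias calls, HOT masking, TF-binding enrichment per promoter
# cluster, relative TF expression, and element sequence features
# (consensus-motif scan, CpG density).

#' Assign TF peaks to elements by summit overlap
#'
#' A peak is assigned to an element when its summit falls in the 400-bp
#' half-open window centered at the element midpoint
#' (`[mid - 200, mid + 200)`).  Elements are classed HOT (>= `hot_threshold`
#' factors), cold (1 to `hot_threshold - 1`) or none (0).
#'
#' @param elements data.table with `chrom`, `start`, `end` (or `midpoint`)
#'   and ids in `element_id` (or rownames).
#' @param tf_peaks data.table with `chrom`, `name` (factor) and `summit`.
#' @param window window width in bp (default 400).
#' @param hot_threshold factor count defining HOT (default 19).
#' @return List of class `wormcis_tfmatrix`: `bound` (elements x factors
#'   logical matrix), `factor_count`, `hotness`, `peaks_per_factor`
#'   (number of peaks whose summit hits any element).
#' @export
assign_tf_peaks <- function(elements, tf_peaks, window = 400L,
                            hot_threshold = 19L) {
  ids <- if ("element_id" %in% names(elements)) elements$element_id
         else sprintf("elem_%04d", seq_len(nrow(elements)))
  mid <- if ("midpoint" %in% names(elements)) elements$midpoint
         else (elements$start + elements$end) %/% 2L
  half <- as.integer(window %/% 2L)
  el_gr <- GenomicRanges::GRanges(elements$chrom,
                                  IRanges::IRanges(mid - half + 1L, mid + half))
  pk_gr <- GenomicRanges::GRanges(tf_peaks$chrom,
                                  IRanges::IRanges(tf_peaks$summit + 1L,
                                                   tf_peaks$summit + 1L))
  ov <- GenomicRanges::findOverlaps(pk_gr, el_gr)
  factors <- sort(unique(tf_peaks$name))
  bound <- matrix(FALSE, length(ids), length(factors),
                  dimnames = list(ids, factors))
  if (length(ov)) {
    hit_f <- tf_peaks$name[S4Vectors::queryHits(ov)]
    hit_e <- S4Vectors::subjectHits(ov)
    bound[cbind(hit_e, match(hit_f, factors))] <- TRUE
  }
  fc <- rowSums(bound)
  hotness <- ifelse(fc >= hot_threshold, "HOT", ifelse(fc >= 1L, "cold", "none"))
  count_hits <- function(keep_el) {
    qh <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) %in% keep_el]
    tab <- table(factor(tf_peaks$name[unique(qh)], levels = factors))
    stats::setNames(as.integer(tab), factors)
  }
  structure(list(bound = bound, factor_count = fc, hotness = hotness,
                 peaks_per_factor = count_hits(seq_along(ids)),
                 peaks_nonhot_per_factor = count_hits(which(hotness != "HOT")),
                 factors = factors),
            class = "wormcis_tfmatrix")
}

#' Tissue-biased gene expression calls
#'
#' A gene is biased toward its top tissue when the fold change between the
#' highest and second-highest tissue TPMs (both with the 0.1 pseudo-value)
#' is at least `fold_threshold` and the BH-adjusted p of an NB two-group
#' test of the top versus second tissue's replicate counts is below
#' `padj_threshold`.
#'
#' @param tpm genes x tissues TPM matrix.
#' @param counts genes x (tissue x replicate) count matrix; replicate
#'   columns of tissue T must be named `T_rep1`, `T_rep2`, ...
#' @param fold_threshold,padj_threshold,pseudo thresholds (defaults 3,
#'   0.01, 0.1).
#' @return data.table: `gene`, `top_tissue`, `fold`, `padj`, `biased`.
#' @export
tissue_bias <- function(tpm, counts, fold_threshold = 3, padj_threshold = 0.01,
                        pseudo = 0.1) {
  tissues <- colnames(tpm)
  ord <- t(apply(tpm, 1L, order, decreasing = TRUE))
  top <- tissues[ord[, 1L]]; second <- tissues[ord[, 2L]]
  tp <- tpm[cbind(seq_len(nrow(tpm)), ord[, 1L])]
  sp <- tpm[cbind(seq_len(nrow(tpm)), ord[, 2L])]
  fold <- (tp + pseudo) / (sp + pseudo)
  rep_cols <- function(t) grep(paste0("^", t, "_rep"), colnames(counts))
  # NB test per top/second pairing; group by pairing so BH spans all genes
  p <- rep(NA_real_, nrow(tpm))
  for (pair in unique(paste(top, second))) {
    idx <- which(paste(top, second) == pair)
    t1 <- top[idx[1]]; t2 <- second[idx[1]]
    res <- nb_two_group_test(counts[idx, rep_cols(t2), drop = FALSE],
                             counts[idx, rep_cols(t1), drop = FALSE],
                             alternative = "greater")
    p[idx] <- res$p
  }
  padj <- stats::p.adjust(p, method = "BH")
  data.table::data.table(gene = rownames(tpm), top_tissue = top, fold = fold,
                         padj = padj,
                         biased = fold >= fold_threshold & padj < padj_threshold)
}

#' Per-cluster tissue composition
#'
#' Percentage of genes with biased expression in each tissue relative to
#' the total number of genes in the cluster.
#'
#' @param clusters data.table with `cluster` and `gene` columns (one row
#'   per promoter with its gene).
#' @param bias [tissue_bias()] output.
#' @return data.table: `cluster`, `tissue`, `percent`.
#' @export
cluster_tissue_composition <- function(clusters, bias) {
  biased <- bias[bias$biased, c("gene", "top_tissue")]
  tissues <- sort(unique(bias$top_tissue))
  out <- list()
  for (cl in sort(unique(clusters$cluster))) {
    g <- unique(clusters$gene[clusters$cluster == cl])
    g <- g[!is.na(g)]
    hit <- biased[biased$gene %in% g, ]
    for (t in tissues) {
      out[[length(out) + 1L]] <- data.table::data.table(
        cluster = cl, tissue = t,
        percent = if (length(g)) 100 * sum(hit$top_tissue == t) / length(g) else 0)
    }
  }
  data.table::rbindlist(out)
}

#' TF-binding enrichment per promoter cluster
#'
#' HOT elements are removed first.  For each factor with more than
#' `min_peaks` peaks overlapping non-HOT elements, a 2x2 table
#' (bound/unbound x in-cluster/other non-HOT clustered promoters) gives an
#' odds ratio (Haldane 0.5 correction only when a zero cell occurs) and a
#' two-sided Fisher exact p.  A factor is kept when some cluster reaches
#' `p < p_threshold` and its maximum odds ratio exceeds `min_or`.
#'
#' @param clusters data.table with `id` (element id) and `cluster`.
#' @param tfmat [assign_tf_peaks()] result over the same element universe.
#' @param min_peaks,p_threshold,min_or filters (defaults 200, 0.01, 2).
#' @return List: `table` (data.table factor, cluster, odds_ratio, p,
#'   n_bound_in), `kept` (character vector of kept factors),
#'   `n_universe` (non-HOT clustered elements).
#' @export
tf_enrichment <- function(clusters, tfmat, min_peaks = 200L,
                          p_threshold = 0.01, min_or = 2) {
  non_hot <- rownames(tfmat$bound)[tfmat$hotness != "HOT"]
  univ <- intersect(clusters$id, non_hot)
  cl <- clusters$cluster[match(univ, clusters$id)]
  bound <- tfmat$bound[univ, , drop = FALSE]
  # factor filter: peaks overlapping non-HOT elements
  eligible <- tfmat$factors[tfmat$peaks_nonhot_per_factor > min_peaks]
  rows <- list()
  for (f in eligible) {
    b <- bound[, f]
    for (k in sort(unique(cl))) {
      inc <- cl == k
      a11 <- sum(b & inc); a12 <- sum(!b & inc)
      a21 <- sum(b & !inc); a22 <- sum(!b & !inc)
      orv <- if (any(c(a11, a12, a21, a22) == 0))
        ((a11 + 0.5) * (a22 + 0.5)) / ((a12 + 0.5) * (a21 + 0.5))
      else (a11 * a22) / (a12 * a21)
      p <- stats::fisher.test(matrix(c(a11, a12, a21, a22), 2L, byrow = TRUE))$p.value
      rows[[length(rows) + 1L]] <- data.table::data.table(
        factor = f, cluster = k, odds_ratio = orv, p = p, n_bound_in = a11)
    }
  }
  tab <- if (length(rows)) data.table::rbindlist(rows)
         else data.table::data.table(factor = character(0), cluster = character(0),
                                     odds_ratio = numeric(0), p = numeric(0),
                                     n_bound_in = integer(0))
  kept <- character(0)
  if (nrow(tab)) {
    agg <- tab[, .(sig = any(p < p_threshold), max_or = max(odds_ratio)),
               by = factor]
    kept <- agg$factor[agg$sig & agg$max_or > min_or]
  }
  list(table = tab, kept = kept, n_universe = length(univ))
}

#' Relative TF expression across tissues, with deciles
#'
#' `log2((TPM + 0.1) / mean across tissues of (TPM + 0.1))` per factor and
#' tissue.  Deciles are calibrated per tissue on entries with `TPM >= 1`
#' only; smaller entries get decile `NA`.
#'
#' @param tpm factors x tissues TPM matrix.
#' @param pseudo pseudo-value added to all TPMs (default 0.1).
#' @return List: `log_ratio` (matrix), `decile` (integer matrix, 1-10 or
#'   `NA`).
#' @export
relative_tf_expression <- function(tpm, pseudo = 0.1) {
  shifted <- tpm + pseudo
  log_ratio <- log2(shifted / rowMeans(shifted))
  decile <- matrix(NA_integer_, nrow(tpm), ncol(tpm), dimnames = dimnames(tpm))
  for (j in seq_len(ncol(tpm))) {
    use <- tpm[, j] >= 1
    if (!any(use)) next
    br <- stats::quantile(tpm[use, j], probs = seq(0, 1, 0.1), names = FALSE)
    br[1] <- -Inf; br[length(br)] <- Inf
    decile[use, j] <- as.integer(cut(tpm[use, j], breaks = unique(br),
                                     labels = FALSE))
    # with duplicated breaks, rescale to 1..10 span
    dmax <- max(decile[use, j], na.rm = TRUE)
    if (dmax < 10L)
      decile[use, j] <- as.integer(round(decile[use, j] * 10 / dmax))
  }
  list(log_ratio = log_ratio, decile = decile)
}

#' Scan a sequence for an IUPAC consensus, both strands
#'
#' Zero-mismatch matching with IUPAC ambiguity codes expanded.
#'
#' @param sequence character scalar or `Biostrings::DNAString`.
#' @param iupac_pattern consensus pattern (IUPAC codes allowed).
#' @return data.table: `start` (0-based), `strand`.
#' @export
scan_consensus <- function(sequence, iupac_pattern) {
  seq <- Biostrings::DNAString(as.character(sequence))
  if (length(seq) == 0L)
    return(data.table::data.table(start = integer(0), strand = character(0)))
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") iupac_pattern
           else as.character(Biostrings::reverseComplement(
             Biostrings::DNAString(iupac_pattern)))
    m <- Biostrings::matchPattern(pat, seq, fixed = FALSE)
    if (length(m))
      hits[[strand]] <- data.table::data.table(
        start = BiocGenerics::start(m) - 1L, strand = strand)
  }
  if (!length(hits))
    return(data.table::data.table(start = integer(0), strand = character(0)))
  out <- data.table::rbindlist(hits)
  data.table::setorder(out, start, strand)
  out[]
}

#' CpG density profile
#'
#' Count of CG dinucleotide starts within the centered window, divided by
#' the window length; a stand-in definition (declared, not asserted to
#' match any published variant).
#'
#' @param sequence character scalar or DNAString.
#' @param window window size in bp.
#' @return Numeric per-bp density vector (same length as the sequence).
#' @export
cpg_density <- function(sequence, window = 200L) {
  s <- as.character(sequence)
  n <- nchar(s)
  if (n == 0L) return(numeric(0))
  chars <- strsplit(toupper(s), "")[[1]]
  is_cg <- c(chars[-n] == "C" & chars[-1] == "G", FALSE)
  half <- window %/% 2L
  cs <- c(0, cumsum(as.integer(is_cg)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (window - half) - 1L, n)
  (cs[hi + 1L] - cs[lo]) / window
}
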