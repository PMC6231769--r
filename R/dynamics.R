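# Accessibility dynamics: regulated-site calls across a time course,
# relative-accessibility profiles, PAM k-medoids clustering and
# accessibility-expression correlation.

#' Relative accessibility of a profile
#'
#' `log2(c_t + 1) - log2(mean(c) + 1)` with the mean taken within the
#' course; a flat profile maps to the zero vector and the transform is
#' exactly invertible given the mean.
#'
#' @param x nonnegative coverage vector over time points.
#' @return Numeric vector of the same length.
#' @export
relative_accessibility <- function(x) {
  log2(x + 1) - log2(mean(x) + 1)
}

#' Per-site ATAC count matrix
#'
#' Total coverage within each site interval per stage and replicate; the
#' unit consumed by the differential-accessibility tests.
#'
#' @param sites sites table; `signal` a signal bundle.
#' @return List per stage: sites x replicates integer matrix.
#' @export
site_stage_counts <- function(sites, signal) {
  out <- list()
  for (st in signal$stages) {
    m <- matrix(0, nrow(sites), signal$n_reps)
    for (cn in unique(sites$chrom)) {
      ii <- which(sites$chrom == cn)
      for (r in seq_len(signal$n_reps)) {
        cc <- cum_track(signal$atac[[st]][[r]][[cn]])
        m[ii, r] <- vapply(ii, function(i)
          window_sum_cum(cc, sites$start[i], sites$end[i]), numeric(1))
      }
    }
    out[[st]] <- round(m)
  }
  out
}

#' Regulated-accessibility calls over a time course
#'
#' Two-sided NB Wald tests between every unordered pair of time points
#' within the course, BH-adjusted across sites within each pair.  A site is
#' regulated when some pair reaches at least two-fold absolute change
#' (`|lfc| >= 1`) with `padj < 0.01`.
#'
#' @param counts list per stage of sites x replicates count matrices
#'   ([site_stage_counts()]).
#' @param course `"development"` or `"ageing"` (selects the stages).
#' @param config pipeline configuration.
#' @return data.table: `regulated`, `max_abs_lfc`, `min_padj`, with the
#'   per-pair results in `attr(, "pairs")`.
#' @export
differential_accessibility <- function(counts, course = c("development", "ageing"),
                                       config = default_config()) {
  course <- match.arg(course)
  stages <- intersect(stage_names(course), names(counts))
  stopifnot(length(stages) >= 2L)
  n <- nrow(counts[[stages[1]]])
  regulated <- rep(FALSE, n)
  max_lfc <- rep(0, n); min_padj <- rep(1, n)
  pairs <- list()
  for (a in seq_along(stages)[-length(stages)]) for (b in (a + 1L):length(stages)) {
    res <- nb_two_group_test(counts[[stages[a]]], counts[[stages[b]]],
                             alternative = "two.sided")
    padj <- stats::p.adjust(res$p, method = "BH")
    hit <- abs(res$lfc) >= config$regulated_lfc & padj < config$regulated_padj
    regulated <- regulated | hit
    max_lfc <- pmax(max_lfc, abs(res$lfc))
    min_padj <- pmin(min_padj, padj)
    pairs[[paste(stages[a], stages[b], sep = ":")]] <-
      data.table::data.table(lfc = res$lfc, padj = padj)
  }
  out <- data.table::data.table(regulated = regulated, max_abs_lfc = max_lfc,
                                min_padj = min_padj)
  data.table::setattr(out, "pairs", pairs)
  out
}

#' PAM k-medoids clustering
#'
#' Partitioning around medoids with the classic BUILD (greedy seeding) and
#' SWAP (steepest-descent medoid/non-medoid exchange, repeated to a local
#' optimum) phases on Euclidean distances.  Deterministic: ties are broken
#' by lowest index throughout.
#'
#' @param x n x t numeric matrix (rows are clustered) or a `dist`.
#' @param k number of medoids (`1 <= k <= n`).
#' @return List: `medoids` (row indices), `clustering` (medoid index per
#'   row, in `1..k`), `objective` (total within-cluster distance).
#' @export
pam_kmedoids <- function(x, k) {
  D <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  n <- nrow(D)
  if (n == 0L) stop("empty input", call. = FALSE)
  stopifnot(k >= 1L, k <= n)
  # BUILD
  med <- which.min(colSums(D))
  dmin <- D[, med]
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    costs <- vapply(cand, function(j) sum(pmin(dmin, D[, j])), numeric(1))
    j <- cand[which.min(costs)]
    med <- c(med, j)
    dmin <- pmin(dmin, D[, j])
  }
  # SWAP (steepest descent)
  objective <- function(med) sum(apply(D[, med, drop = FALSE], 1L, min))
  cur <- objective(med)
  repeat {
    # nearest and second-nearest medoid distances per point
    Dm <- D[, med, drop = FALSE]
    ord1 <- apply(Dm, 1L, which.min)
    d1 <- Dm[cbind(seq_len(n), ord1)]
    d2 <- if (length(med) > 1L) apply(Dm, 1L, function(r) sort(r)[2L]) else rep(Inf, n)
    best <- list(cost = cur, m = NA, h = NA)
    for (mi in seq_along(med)) {
      base <- ifelse(ord1 == mi, d2, d1)
      for (h in setdiff(seq_len(n), med)) {
        newcost <- sum(pmin(base, D[, h]))
        if (newcost < best$cost - 1e-12) best <- list(cost = newcost, m = mi, h = h)
      }
    }
    if (is.na(best$m)) break
    med[best$m] <- best$h
    cur <- best$cost
  }
  med <- unname(med[order(med)])
  Dm <- D[, med, drop = FALSE]
  clustering <- unname(apply(Dm, 1L, which.min))
  list(medoids = med, clustering = clustering, objective = objective(med))
}

#' Cluster promoter accessibility over a course
#'
#' Relative-accessibility transform of each promoter's depth-normalized
#' coverage profile, then PAM with the course default k (16 development, 10
#' ageing).  An optional merge map collapses named cluster pairs post hoc,
#' mirroring the published manual merge of two ageing clusters.
#'
#' @param mat promoters x time-points matrix of depth-normalized coverage
#'   (rownames are promoter ids).
#' @param course `"development"` or `"ageing"`.
#' @param k number of clusters (default from the course).
#' @param merge named character vector, e.g. `c(A = "AB", B = "AB")`,
#'   relabelling clusters after the fit.
#' @param config pipeline configuration.
#' @return data.table: `id`, `cluster` (letter labels), `is_medoid`, plus
#'   the relative profiles in `attr(, "profiles")` and medoid row indices
#'   in `attr(, "medoids")`.
#' @export
cluster_course <- function(mat, course = c("development", "ageing"), k = NULL,
                           merge = NULL, config = default_config()) {
  course <- match.arg(course)
  if (is.null(k)) k <- if (course == "development") config$k_dev else config$k_age
  if (nrow(mat) == 0L) {
    warning("no regulated promoters to cluster")
    return(data.table::data.table(id = character(0), cluster = character(0),
                                  is_medoid = logical(0)))
  }
  k <- min(k, nrow(mat))
  rel <- t(apply(mat, 1L, relative_accessibility))
  fit <- pam_kmedoids(rel, k)
  labels <- make.unique(c(LETTERS, paste0("Z", seq_len(max(0, k - 26)))))[seq_len(k)]
  cl <- labels[fit$clustering]
  if (!is.null(merge)) {
    hit <- cl %in% names(merge)
    cl[hit] <- unname(merge[cl[hit]])
  }
  out <- data.table::data.table(
    id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    cluster = cl,
    is_medoid = seq_len(nrow(mat)) %in% fit$medoids)
  data.table::setattr(out, "profiles", rel)
  data.table::setattr(out, "medoids", fit$medoids)
  out
}

#' Correlation of promoter accessibility with gene expression
#'
#' Pearson correlation per promoter between its relative accessibility and
#' the relative expression of its gene (same transform applied to
#' replicate-averaged FPM values), averaged per cluster.  Members with
#' zero-variance profiles on either side are excluded and tallied.
#'
#' @param clusters data.table from [cluster_course()] (needs the
#'   `profiles` attribute).
#' @param expression genes x time-points matrix of FPM-like values.
#' @param gene_map named character vector promoter id -> gene id.
#' @return List: `per_cluster` (data.table cluster, mean_r, n), `mean_r`,
#'   `sd_r` (across clusters), `n_dropped`.
#' @export
cluster_expression_correlation <- function(clusters, expression, gene_map) {
  prof <- attr(clusters, "profiles")
  stopifnot(!is.null(prof), nrow(prof) == nrow(clusters))
  rel_expr <- t(apply(expression, 1L, relative_accessibility))
  r <- rep(NA_real_, nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    g <- gene_map[clusters$id[i]]
    if (is.na(g) || !(g %in% rownames(rel_expr))) next
    a <- prof[i, ]; e <- rel_expr[g, ]
    if (stats::sd(a) == 0 || stats::sd(e) == 0) next
    r[i] <- stats::cor(a, e)
  }
  keep <- !is.na(r)
  per <- data.table::data.table(cluster = clusters$cluster[keep], r = r[keep])
  per_cluster <- per[, .(mean_r = mean(r), n = .N), by = cluster]
  data.table::setorder(per_cluster, cluster)
  list(per_cluster = per_cluster[],
       mean_r = mean(per_cluster$mean_r),
       sd_r = stats::sd(per_cluster$mean_r),
       n_dropped = sum(!keep))
}
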