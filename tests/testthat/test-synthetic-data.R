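# Generator contracts: placement geometry, determinism, planted signal
# structure.

test_that("simulate_genome respects bounds, determinism and outron fraction", {
  g1 <- simulate_genome(1, 10000, seed = 1)
  expect_equal(nrow(g1$genes), 1L)
  expect_true(all(g1$genes$start >= 0 & g1$genes$end <= 10000))
  expect_true(all(g1$exons$start >= 0 & g1$exons$end <= 10000))

  g2 <- simulate_genome(50, 5e5, seed = 7)
  g3 <- simulate_genome(50, 5e5, seed = 7)
  expect_identical(g2, g3)

  g <- simulate_genome(200, 2e6, seed = 7, outron_frac = 0.7)
  pc <- g$genes[g$genes$biotype == "protein_coding", ]
  frac <- mean(!is.na(pc$outron_start))
  # binomial error band: 0.7 +- 4 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(frac - 0.7), 4 * sqrt(0.7 * 0.3 / nrow(pc)))
  # at least one gene of each non-coding biotype
  expect_true(all(c("tRNA", "snRNA", "snoRNA", "rRNA", "miRNA", "pseudogene")
                  %in% g$genes$biotype))
  # outron strictly upstream of the first exon, strand-relative
  oo <- g$genes[!is.na(g$genes$outron_start), ]
  fe <- g$exons[g$exons$is_first, ]
  f5 <- fe$fivep[match(oo$gene_id, fe$gene_id)]
  expect_true(all(ifelse(oo$strand == "+", oo$outron_start < f5,
                         oo$outron_start > f5)))
  d <- abs(oo$outron_start - f5)
  expect_true(all(d >= 200 & d <= 1500))

  expect_error(simulate_genome(100, 1e4), "non-overlapping")
})

test_that("plant_elements produces the requested classes with constraints", {
  g <- simulate_genome(60, 6e5, seed = 2)
  el <- plant_elements(g, c(inactive = 5), seed = 1)
  expect_equal(nrow(el), 5L)
  expect_true(all(is.na(el$target_gene_id)))

  el <- plant_elements(g, c(coding_promoter = 30, enhancer = 15,
                            inactive = 5), seed = 3)
  expect_equal(as.integer(table(el$true_class)[c("coding_promoter", "enhancer",
                                                 "inactive")]),
               c(30L, 15L, 5L))
  enh <- el[el$true_class == "enhancer", ]
  for (pos in enh$center)
    expect_gt(min(abs(g$exons$fivep - pos)), 250)
  # coding promoters carry a target gene and sit at outron/first-exon geometry
  pr <- el[el$true_class == "coding_promoter", ]
  expect_false(anyNA(pr$target_gene_id))
  # same seed, same elements
  expect_identical(el, plant_elements(g, c(coding_promoter = 30, enhancer = 15,
                                           inactive = 5), seed = 3))
})

test_that("simulate_signal plants the assumed signal structure", {
  g <- simulate_genome(12, 1.2e5, seed = 5)
  el <- plant_elements(g, c(coding_promoter = 6, enhancer = 3, inactive = 3),
                       seed = 5)
  sig <- simulate_signal(g, el, seed = 9)
  expect_identical(sig, simulate_signal(g, el, seed = 9))

  cn <- g$chromosomes$name[1]
  # inactive elements: 5'-end counts near center at background rate
  bg_window <- function(track, c0) sum(track[(c0 - 250):(c0 + 250) + 1L])
  inact <- el[el$true_class == "inactive", ]
  obs <- unlist(lapply(seq_len(nrow(inact)), function(i)
    vapply(sig$stages, function(st)
      bg_window(sig$lcap5[[st]][[1]][["+"]][[cn]], inact$center[i]),
      numeric(1))))
  # 501 bp x rate 0.01 = ~5 expected; Poisson mean check over many windows
  expect_lt(abs(mean(obs) - 5.01), 1.5)

  # promoters: downstream long-cap 5' mean over upstream mean >= 8
  pr <- el[el$true_class == "coding_promoter", ]
  ratios <- vapply(seq_len(nrow(pr)), function(i) {
    c0 <- pr$center[i]; sd0 <- pr$strand[i]
    st <- sig$stages[which.max(as.matrix(
      pr[i, paste0("prof_", sig$stages), with = FALSE]))]
    tr <- lapply(1:2, function(r) sig$lcap5[[st]][[r]][[sd0]][[cn]])
    wc <- window_counts(tr, c0, sd0)
    (sum(wc$downstream) + 0.1) / (sum(wc$upstream) + 0.1)
  }, numeric(1))
  expect_gte(mean(ratios >= 8), 0.8)

  # depth = 0: element signal absent, background only
  sig0 <- simulate_signal(g, el, depth = 0, seed = 9)
  tot <- sum(vapply(sig0$stages, function(st)
    sum(as.numeric(sig0$atac[[st]][[1]][[cn]])), numeric(1)))
  L <- g$chromosomes$length[1]
  expect_lt(abs(tot / (length(sig0$stages) * L) - 1), 0.05) # bg_cov = 1
})

test_that("simulate_tf_and_expression plants enrichment, HOT and tissue bias", {
  g <- simulate_genome(40, 4e5, seed = 4)
  el <- plant_elements(g, c(coding_promoter = 30), seed = 4)
  # HOT construction with zero background rate
  tf <- simulate_tf_and_expression(el, n_tfs = 20, seed = 1, n_enriched = 0,
                                   bg_rate = 0, hot_n = 6, hot_threshold = 19)
  m <- assign_tf_peaks(el[, .(element_id, chrom, start = center - 75L,
                              end = center + 76L)], tf$tf_peaks)
  expect_equal(sum(m$factor_count >= 19), 6L)
  expect_setequal(names(which(m$factor_count >= 19)), tf$hot_elements)

  # planted enrichment: OR recomputed from overlaps pooled over 50
  # simulations lies in [3, 5] (planted odds-ratio parameter 4)
  g_big <- simulate_genome(220, 2.2e6, seed = 12)
  el_big <- plant_elements(g_big, c(coding_promoter = 180), seed = 12)
  tab <- c(a = 0, b = 0, c = 0, d = 0)
  for (s in 1:50) {
    tf <- simulate_tf_and_expression(el_big, n_tfs = 1, seed = s,
                                     n_enriched = 1, enrich_or = 4,
                                     bg_rate = 0.15, n_random_peaks = 0)
    m <- assign_tf_peaks(el_big[, .(element_id, chrom, start = center - 75L,
                                    end = center + 76L)], tf$tf_peaks)
    b <- m$bound[, tf$enriched$tf]
    inc <- el_big$true_cluster == tf$enriched$target_cluster
    tab <- tab + c(sum(b & inc), sum(!b & inc), sum(b & !inc), sum(!b & !inc))
  }
  or_emp <- (tab["a"] * tab["d"]) / (tab["b"] * tab["c"])
  expect_gt(or_emp, 3); expect_lt(or_emp, 5)

  # tissue dominance: cluster target genes have >= 3-fold top tissue
  tf2 <- simulate_tf_and_expression(el, n_tfs = 20, seed = 2)
  genes <- setdiff(rownames(tf2$tpm), sprintf("tf_%03d", 1:20))
  tg <- tf2$tpm[genes[!is.na(el$true_cluster[match(genes, el$target_gene_id)])], ,
                drop = FALSE]
  folds <- apply(tg, 1, function(x) { s <- sort(x, decreasing = TRUE)
    (s[1] + 0.1) / (s[2] + 0.1) })
  expect_true(all(folds >= 3))   # guaranteed by construction
  expect_error(simulate_tf_and_expression(el, n_tfs = 2, n_enriched = 5),
               "enriched")
})
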