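# TF assignment, HOT masking, tissue bias, enrichment, sequence features.

test_that("assign_tf_peaks: half-open 400-bp window and hotness classes", {
  el <- data.table::data.table(element_id = c("e1", "e2", "e3"),
                               chrom = "chr",
                               start = c(1000L, 3000L, 5000L),
                               end = c(1151L, 3151L, 5151L))
  mid <- (el$start + el$end) %/% 2L
  pk <- data.table::data.table(
    chrom = "chr",
    name = c("tfA", "tfA", "tfB"),
    summit = c(mid[1] + 199L, mid[2] + 200L, mid[1] - 200L))
  m <- assign_tf_peaks(el, pk, window = 400L)
  expect_true(m$bound["e1", "tfA"])     # +199 inside
  expect_false(m$bound["e2", "tfA"])    # +200 outside (half-open)
  expect_true(m$bound["e1", "tfB"])     # -200 inside
  expect_equal(unname(m$factor_count), c(2, 0, 0))
  expect_equal(unname(m$hotness), c("cold", "none", "none"))

  # 19 distinct factors -> HOT; 18 -> cold
  pk19 <- data.table::data.table(chrom = "chr", name = sprintf("f%02d", 1:19),
                                 summit = mid[1])
  expect_equal(unname(assign_tf_peaks(el, pk19)$hotness[1]), "HOT")
  expect_equal(unname(assign_tf_peaks(el, pk19[1:18])$hotness[1]), "cold")
})

test_that("tissue bias: fold arithmetic and thresholds", {
  tpm <- rbind(g1 = c(30, 9, 1, 1), g2 = c(30, 15, 1, 1), g3 = c(5, 5, 5, 5))
  colnames(tpm) <- c("Gonad", "Muscle", "Glia", "Pharynx")
  set.seed(7)
  counts <- matrix(rnbinom(3 * 8, size = 50, mu = rep(tpm, each = 2) * 30),
                   nrow = 3, byrow = FALSE)
  counts <- do.call(cbind, lapply(1:4, function(j)
    matrix(rnbinom(6, size = 50, mu = tpm[, j] * 30), 3)))
  colnames(counts) <- paste0(rep(colnames(tpm), each = 2), "_rep", 1:2)
  rownames(counts) <- rownames(tpm)
  tb <- tissue_bias(tpm, counts)
  expect_equal(tb$fold[1], 30.1 / 9.1)
  expect_gte(tb$fold[1], 3)
  expect_lt(tb$fold[2], 3)
  expect_false(tb$biased[2])     # fold < 3 regardless of padj
  expect_equal(tb$fold[3], 1)
  expect_false(tb$biased[3])
})

test_that("cluster tissue composition percentages", {
  bias <- data.table::data.table(
    gene = sprintf("g%02d", 1:10),
    top_tissue = rep(c("Gonad", "Muscle"), 5),
    fold = 5, padj = 0.001,
    biased = c(rep(TRUE, 4), rep(FALSE, 6)))
  cl <- data.table::data.table(cluster = "A", gene = sprintf("g%02d", 1:10))
  comp <- cluster_tissue_composition(cl, bias)
  expect_equal(comp$percent[comp$tissue == "Gonad"], 20)   # g01, g03
  expect_equal(comp$percent[comp$tissue == "Muscle"], 20)  # g02, g04
  expect_true(all(comp$percent >= 0 & comp$percent <= 100))
  # no biased genes -> zeros
  bias0 <- data.table::copy(bias)[, biased := FALSE]
  expect_true(all(cluster_tissue_composition(cl, bias0)$percent == 0))
})

test_that("tf_enrichment: OR arithmetic, HOT removal, peak filter", {
  # deterministic 2x2: (20,80,100,800) -> OR exactly 2
  or <- (20 * 800) / (80 * 100)
  expect_equal(or, 2)
  # construct a universe reproducing that table for one factor
  n_in <- 100; n_out <- 900
  ids <- sprintf("e%04d", seq_len(n_in + n_out))
  bound <- matrix(FALSE, n_in + n_out, 1, dimnames = list(ids, "tfX"))
  bound[c(1:20, n_in + 1:100), 1] <- TRUE
  tfmat <- structure(list(bound = bound, factor_count = rowSums(bound),
                          hotness = rep("cold", n_in + n_out),
                          peaks_per_factor = c(tfX = 120L),
                          peaks_nonhot_per_factor = c(tfX = 120L),
                          factors = "tfX"), class = "wormcis_tfmatrix")
  cl <- data.table::data.table(id = ids,
                               cluster = rep(c("A", "B"), c(n_in, n_out)))
  enr <- tf_enrichment(cl, tfmat, min_peaks = 100)
  rowA <- enr$table[enr$table$cluster == "A", ]
  expect_equal(rowA$odds_ratio, 2)
  expect_equal(rowA$p,
               stats::fisher.test(matrix(c(20, 80, 100, 800), 2,
                                         byrow = TRUE))$p.value)
  # a factor below the min-peak filter is excluded before testing
  enr2 <- tf_enrichment(cl, tfmat, min_peaks = 200)
  expect_equal(nrow(enr2$table), 0L)
  # HOT elements never contribute
  tfmat$hotness[1:20] <- "HOT"
  enr3 <- tf_enrichment(cl, tfmat, min_peaks = 100)
  expect_equal(enr3$n_universe, n_in + n_out - 20)
  expect_equal(enr3$table$n_bound_in[enr3$table$cluster == "A"], 0L)
})

test_that("Fisher p matches the hypergeometric enumeration oracle", {
  # independent oracle: sum of hypergeometric probabilities <= p(obs),
  # the standard two-sided definition
  fisher_oracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n, k)
    sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(9)
  for (i in 1:100) {
    tot <- sample(4:200, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    p_impl <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    expect_lt(abs(p_impl - fisher_oracle(a, b, c, d)), 1e-10)
  }
})

test_that("relative TF expression and deciles", {
  tpm <- rbind(f1 = c(4, 4, 4), f2 = c(10, 0, 0))
  colnames(tpm) <- c("Gonad", "Muscle", "Glia")
  r <- relative_tf_expression(tpm)
  expect_equal(unname(r$log_ratio[1, ]), c(0, 0, 0))
  expect_equal(r$log_ratio["f2", "Gonad"],
               log2(10.1 / mean(c(10.1, 0.1, 0.1))))
  # decile calibration ignores TPM < 1
  tpm2 <- matrix(c(seq(0, 0.9, 0.1), seq(1, 100, length.out = 30)), ncol = 1,
                 dimnames = list(NULL, "Gonad"))
  d <- relative_tf_expression(tpm2)$decile
  expect_true(all(is.na(d[1:10, 1])))
  expect_true(all(d[11:40, 1] %in% 1:10))
  expect_equal(min(d[11:40, 1]), 1L)
  expect_equal(max(d[11:40, 1]), 10L)
})

test_that("consensus scanning and CpG density", {
  m <- scan_consensus("GGTATAAAAGG", "TATAWAW")
  expect_true(any(m$start == 2 & m$strand == "+"))
  # N matches every position on both strands
  mN <- scan_consensus("ACGT", "N")
  expect_equal(sum(mN$strand == "+"), 4L)
  expect_equal(nrow(scan_consensus("", "TATA")), 0L)
  # reverse-strand hit
  mr <- scan_consensus("CCTTTATACC", "TATAAA")
  expect_true(any(mr$strand == "-"))

  d <- cpg_density("CGCGCG", window = 6)
  expect_equal(d[4], 3 / 6)
  expect_true(all(cpg_density("AATTAA", 4) == 0))
  expect_true(all(cpg_density(strrep("N", 10), 4) == 0))
})
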