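#' Default pipeline configuration
#'
#' All numeric thresholds of the analysis with their published defaults, plus
#' the synthetic-data generator settings.  Every field can be overridden via
#' `...`; unknown names are rejected.
#'
#' Analysis thresholds: `idr_cutoff` (0.001), `boundary_flank` (75 bp, giving
#' 151-bp sites), `min_concave_width` (20 bp), `d2_bandwidth` (50 bp,
#' smoothing scale of the second-derivative filter), jump-test windows
#' (-250:-75 upstream, +75:+250 downstream of peak accessibility),
#' `jump_lfc` (1.5) and `jump_padj` (0.1), `incr_min_total` (3),
#' `init_window` (125 bp), `best_guess_offset` (60 bp), `exon_dist` (250 bp),
#' `rescue_lfc` (1), `regulated_lfc` (1, i.e. two-fold) and `regulated_padj`
#' (0.01), `k_dev` (16) and `k_age` (10) medoid counts, `tissue_fold` (3) and
#' `tissue_padj` (0.01), `tpm_pseudo` (0.1), `hot_threshold` (19 factors),
#' `tf_min_peaks` (200), `tf_p` (0.01), `tf_min_or` (2), `tf_window` (400 bp).
#'
#' @param ... name = value overrides.
#' @return Named list of class `wormcis_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # peak calling
    d2_bandwidth = 50,
    min_concave_width = 20,
    idr_cutoff = 0.001,
    boundary_flank = 75,
    # elongation / initiation evidence
    jump_up = c(-250, -75),
    jump_down = c(75, 250),
    jump_lfc = 1.5,
    jump_padj = 0.1,
    incr_min_total = 3,
    init_window = 125,
    best_guess_offset = 60,
    # classification geometry
    exon_dist = 250,
    rescue_lfc = 1,
    continuity_min_cov = 1,
    # dynamics
    regulated_lfc = 1,
    regulated_padj = 0.01,
    k_dev = 16,
    k_age = 10,
    # tissue / TF enrichment
    tissue_fold = 3,
    tissue_padj = 0.01,
    tpm_pseudo = 0.1,
    hot_threshold = 19,
    tf_min_peaks = 200,
    tf_p = 0.01,
    tf_min_or = 2,
    tf_window = 400,
    # synthetic data generator (the stated world; see the methods vignette)
    sim_n_genes = 200,
    sim_chrom_length = 2e6,
    sim_n_promoters = 150,
    sim_n_enhancers = 100,
    sim_n_inactive = 50,
    sim_outron_frac = 0.7,
    sim_utr_frac = 0.6,
    sim_depth = 50,
    sim_dispersion = 0.05,
    sim_bg_5p = 0.01,
    sim_bg_cov = 1.0,
    sim_atac_sd = 75,
    sim_n_reps = 2,
    sim_n_scap_reps = 4,
    sim_n_clusters = 4,
    sim_n_tfs = 30,
    sim_hot_n = 20
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- c("wormcis_config", "list")
  validate_config(cfg)
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  pos <- c("d2_bandwidth", "min_concave_width", "idr_cutoff", "boundary_flank",
           "jump_lfc", "jump_padj", "incr_min_total", "init_window",
           "best_guess_offset", "exon_dist", "rescue_lfc", "continuity_min_cov",
           "regulated_lfc", "regulated_padj", "k_dev", "k_age", "tissue_fold",
           "tissue_padj", "tpm_pseudo", "hot_threshold", "tf_min_peaks",
           "tf_p", "tf_min_or", "tf_window")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar", call. = FALSE)
  if (cfg$idr_cutoff >= 1) stop("idr_cutoff must be in (0,1)", call. = FALSE)
  stopifnot(length(cfg$jump_up) == 2L, length(cfg$jump_down) == 2L,
            cfg$jump_up[1] < cfg$jump_up[2], cfg$jump_down[1] < cfg$jump_down[2])
  invisible(cfg)
}

#' Serialize / read a configuration
#'
#' Round-trips through a flat `key: value` YAML-style file.
#'
#' @param cfg a configuration from [default_config()].
#' @param path file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  write_flat_yaml(unclass(cfg), path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- read_flat_yaml(path)
  do.call(default_config, raw)
}

#' Configuration fingerprint
#'
#' Stable 32-bit FNV-1a hash of the serialized configuration; stamped into
#' every output table header so outputs are traceable to their parameters.
#'
#' @param cfg a configuration.
#' @return Eight-character hex string.
#' @export
config_hash <- function(cfg) {
  txt <- paste(vapply(seq_along(cfg), function(i) {
    paste0(names(cfg)[i], "=", paste(format(cfg[[i]], digits = 15), collapse = ","))
  }, character(1)), collapse = ";")
  fnv1a_hash(txt)
}
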