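#' Stage names of the two time courses
#'
#' The eleven fixed time points: six wild-type developmental stages (embryo,
#' four larval stages, young adult) followed by five sterile-adult ageing
#' time points (days 1, 2, 6, 9 and 13).
#'
#' @param course `"all"`, `"development"` or `"ageing"`.
#' @return Character vector of stage identifiers.
#' @export
stage_names <- function(course = c("all", "development", "ageing")) {
  course <- match.arg(course)
  dev <- c("wt_emb", "wt_l1", "wt_l2", "wt_l3", "wt_l4", "wt_ya")
  age <- c("glp1_d1", "glp1_d2", "glp1_d6", "glp1_d9", "glp1_d13")
  switch(course, all = c(dev, age), development = dev, ageing = age)
}

#' @noRd
other_strand <- function(strand) ifelse(strand == "+", "-", "+")

#' @noRd
stopifnot_strand <- function(strand) {
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
}

#' 32-bit FNV-1a hash of a character scalar
#'
#' Used to stamp output tables with a configuration fingerprint.
#'
#' @param x character scalar.
#' @return Eight-character lower-case hex string.
#' @export
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 0x811c9dc5
  # 32-bit arithmetic on doubles; multiply 16-bit halves to stay exact
  # (prime 0x01000193 = 256 * 2^16 + 403)
  p_hi <- 256; p_lo <- 403
  two32 <- 2^32
  for (b in bytes) {
    h <- bitwXor2_32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    mid <- (hi * p_lo + lo * p_hi) %% 65536
    h <- (lo * p_lo + mid * 65536) %% two32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# xor of two nonnegative doubles < 2^32
#' @noRd
bitwXor2_32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return Scalar ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Flat YAML-subset serialization: scalars and unnested numeric/character
# vectors only ("key: value" / "key: [a, b]").  Sufficient for PipelineConfig.
#' @noRd
write_flat_yaml <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  fmt1 <- function(v) {
    if (is.character(v)) v else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    if (length(v) == 1L) paste0(k, ": ", fmt1(v))
    else paste0(k, ": [", paste(fmt1(v), collapse = ", "), "]")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @noRd
read_flat_yaml <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (grepl("^\\[.*\\]$", val)) {
      parts <- trimws(strsplit(substr(val, 2, nchar(val) - 1L), ",")[[1]])
    } else parts <- val
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}
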