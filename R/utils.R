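`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_format(...)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}

# per-gene z-score across samples (denominator n-1); zero-variance rows -> NA
zscore_rows <- function(mat) {
  mu <- rowMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  out <- sweep(sweep(mat, 1L, mu, "-"), 1L, sdv, "/")
  out[sdv == 0 | is.na(sdv), ] <- NA_real_
  out
}

log2p1 <- function(x) log2(x + 1)

AUTOSOMES <- paste0("chr", 1:22)

is_autosome <- function(chrom) {
  chrom %in% AUTOSOMES | chrom %in% as.character(1:22)
}
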