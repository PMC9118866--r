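# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derived from a master seed and a stage label, so a
# single pipeline seed fans out to independent per-stage RNG streams.
# Result always fits a 32-bit signed integer.
subseed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Element-wise division with zero denominators flagged as undefined (NA),
# never Inf/NaN sentinels; NA inputs propagate.
safe_div <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

# Separable box blur with an odd window, edge-padded by replication.
# Used to make spatially clumped (not i.i.d.) canopy patterns.
box_blur <- function(m, window) {
  window <- as.integer(window)
  if (window <= 1L) return(m)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  blur1 <- function(x) {
    n <- length(x)
    padded <- c(rep(x[1L], half), x, rep(x[n], half))
    cs <- cumsum(padded)
    (cs[(window):(n + window - 1L)] - c(0, cs[seq_len(n - 1L)])) / window
  }
  m <- apply(m, 2L, blur1)
  t(apply(m, 1L, blur1))
}

stop_if_not_matrix_pair <- function(a, b, what_a, what_b) {
  if (!is.matrix(a) || !is.matrix(b) || !identical(dim(a), dim(b))) {
    stop(sprintf("%s and %s must be matrices of identical dimensions",
                 what_a, what_b), call. = FALSE)
  }
}
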