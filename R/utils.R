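# Internal helpers shared across modules.

# log(exp(a) + exp(b)) without overflow, vectorised over pairs
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

clamp01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# reverse complement of a plain character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming mismatches between equal-length strings a and b; 'N' in b (the
# reference side) matches anything, mirroring a near-zero N penalty.
# Vectorised by flattening each length group into one raw comparison.
count_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  la <- nchar(a)
  out <- rep(NA_integer_, length(a))
  ok <- la == nchar(b)
  rawN <- charToRaw("N")[1]
  for (len in unique(la[ok])) {
    idx <- which(ok & la == len)
    ra <- charToRaw(paste(a[idx], collapse = ""))
    rb <- charToRaw(paste(b[idx], collapse = ""))
    d <- ra != rb & rb != rawN
    out[idx] <- as.integer(.colSums(d, len, length(idx)))
  }
  out
}

# Wilson score interval (default) or Clopper-Pearson for a binomial proportion
binom_ci <- function(x, n, level = 0.95, method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(n > 0, x >= 0, x <= n)
  if (method == "wilson") {
    ci <- suppressWarnings(prop.test(x, n, conf.level = level, correct = FALSE)$conf.int)
  } else {
    ci <- binom.test(x, n, conf.level = level)$conf.int
  }
  c(lower = ci[1], upper = ci[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
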