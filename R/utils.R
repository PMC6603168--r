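#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stringr str_sub str_length str_detect
NULL

# internal: round half away from zero (printed-table convention)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# internal: Hamming distance between two equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# internal: character matrix (rows = sequences) from equal-length strings
seq_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1)
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = length(x),
         ncol = nchar(x[1]), byrow = TRUE)
}

# internal: full pairwise Hamming distance matrix for equal-length strings
pairwise_hamming <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(0, 1, 1))
  m <- seq_matrix(x)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    di <- colSums(t(m[(i + 1):n, , drop = FALSE]) != m[i, ])
    d[i, (i + 1):n] <- di
    d[(i + 1):n, i] <- di
  }
  d
}

# internal: draw a random DNA string vector, lengths possibly varying
random_dna <- function(lengths) {
  total <- sum(lengths)
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1
  vapply(seq_along(lengths),
         function(i) paste(bases[starts[i]:ends[i]], collapse = ""), "")
}

# internal: derive a child RNG seed (< 2^31) from a base seed and a tag;
# arithmetic in doubles (exact below 2^53) to avoid integer overflow
derive_seed <- function(seed, tag) {
  tc <- utf8ToInt(as.character(tag))
  h <- sum(tc * seq_along(tc)) %% 100003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483561) + 1L
}

# internal: stop unless condition, with sprintf-style message
assert_that <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}
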