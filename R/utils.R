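# Internal helpers: error classes, deterministic sorting, hashing, bit algebra.

abort_validation <- function(fmt, ...) {
  stop(structure(
    class = c("tandemr_validation_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

abort_numerical <- function(fmt, ...) {
  stop(structure(
    class = c("tandemr_numerical_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

# Locale-independent string sort; all user-visible orderings go through this
# so repeated runs give byte-identical output.
sort_radix <- function(x) {
  if (length(x) == 0L) return(x)
  x[order(x, method = "radix")]
}

order_radix <- function(x) order(x, method = "radix")

# Small rolling hash for provenance metadata (model/flux fingerprints).
# Not cryptographic; stable across platforms.
text_hash <- function(x) {
  s <- paste(as.character(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  p <- 2147483647  # 2^31 - 1
  for (b in bytes) h <- (h * 131 + b) %% p
  sprintf("%08x", as.integer(h %% 4294967087))
}

# Matrix of bit patterns: 2^n rows, n columns; row r is the isotopomer whose
# binary string (atom 1 leftmost = most significant) has index r.
bit_matrix <- function(n_atoms) {
  stopifnot(n_atoms >= 0L)
  if (n_atoms == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  r <- 0:(2^n_atoms - 1L)
  m <- vapply(seq_len(n_atoms),
              function(a) as.integer((r %/% 2^(n_atoms - a)) %% 2),
              integer(2^n_atoms))
  matrix(as.integer(m), nrow = 2^n_atoms, ncol = n_atoms)
}

# Binary label strings for all isotopomers of an n-atom metabolite,
# in index order (atom 1 leftmost).
iso_labels <- function(n_atoms) {
  if (n_atoms == 0L) return("")
  apply(bit_matrix(n_atoms), 1L, paste, collapse = "")
}

# "1,2,3" -> sorted integer vector; "" -> integer(0)
parse_atom_set <- function(s) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s)) return(integer(0))
  v <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
  if (anyNA(v)) abort_validation("cannot parse atom set '%s'", s)
  sort(unique(v))
}

format_atom_set <- function(v) paste(v, collapse = ",")

`%||%` <- function(a, b) if (is.null(a)) b else a
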