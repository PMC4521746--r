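# Shared helpers: tiny in-code networks, temp CSV writers, an independent
# direct-binning MID oracle, and the frozen isotopomer -> tandemer assignment
# of a 4-carbon metabolite under the fragment pair N = {2,3,4}, K = {2,3}.

tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# linear chain A (media) -> B -> C with identity maps and efflux
chain_network <- function() {
  parse_model(text = c(
    "#media A",
    "c1: A (ab) -> B (ab)",
    "c2: B (ab) -> C (ab)",
    "c3: C (ab) ->"))
}

chain_fluxes <- function(net) {
  structure(c(c1 = 1, c2 = 1, c3 = 1), class = "flux_vector")[
    c("c1", "c2", "c3")]
}

# Independent oracle: mass-isotopomer distribution of an atom subset by
# direct binning over the isotopomer distribution (no tandemer code path).
direct_fragment_mid <- function(dist, atoms) {
  n <- as.integer(round(log2(length(dist))))
  counts <- integer(length(dist))
  for (r in seq_along(dist)) {
    bits <- as.integer(intToBits(r - 1L))[seq_len(n)]
    # intToBits is little-endian over 2^0..; our convention: atom 1 is the
    # most significant bit, i.e. atom a has value 2^(n - a)
    lab <- rev(bits[seq_len(n)])
    counts[r] <- sum(lab[atoms])
  }
  mid <- numeric(length(atoms) + 1L)
  for (r in seq_along(dist)) mid[counts[r] + 1L] <- mid[counts[r] + 1L] + dist[r]
  mid
}

# random normalized tandemer matrix with the feasibility pattern of (p, k)
random_tandemer <- function(p, k) {
  mask <- outer(0:p, 0:k, function(i, j) (j <= i) & (j >= i - (p - k)))
  m <- matrix(0, p + 1, k + 1)
  m[mask] <- stats::runif(sum(mask))
  m <- m / sum(m)
  tandemer_matrix(m)
}

# Frozen expected assignment (published worked example): every isotopomer of
# a 4-carbon metabolite mapped to its tandemer (i, j) under N={2,3,4}, K={2,3}.
TABLE1_ASSIGNMENT <- data.frame(
  pattern = c("0000", "0001", "0010", "0011", "0100", "0101", "0110", "0111",
              "1000", "1001", "1010", "1011", "1100", "1101", "1110", "1111"),
  i = c(0, 1, 1, 2, 1, 2, 2, 3, 0, 1, 1, 2, 1, 2, 2, 3),
  j = c(0, 0, 1, 1, 1, 1, 2, 2, 0, 0, 1, 1, 1, 1, 2, 2),
  stringsAsFactors = FALSE)

# random MFP targets on the internal metabolites of a network
random_targets <- function(network, n_targets = 3L) {
  mets <- network$metabolites
  internal <- mets[!mets$is_media & mets$n_atoms > 0L, , drop = FALSE]
  out <- list()
  for (t in seq_len(n_targets)) {
    r <- if (nrow(internal) == 1L) 1L else sample(nrow(internal), 1L)
    n <- internal$n_atoms[r]
    np <- sample.int(n, 1L)
    N <- sort(sample.int(n, np))
    K <- sort(N[sample.int(np, sample(0:np, 1L))])
    out[[t]] <- mfp(internal$id[r], N, K)
  }
  # dedupe canonically
  out[!duplicated(vapply(out, mfp_id, ""))]
}
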