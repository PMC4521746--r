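# Tandemer algebra: metabolite fragment pairs (MFPs), tandemer distribution
# matrices, feasibility, marginalization from isotopomer distributions,
# Cauchy products and marginal mass-isotopomer distributions.

#' Construct a metabolite fragment pair (MFP)
#'
#' An MFP pairs a parent fragment `N` (the atoms retained in the MS1 parent
#' ion) with a product fragment `K`, `K` a subset of `N` (the atoms retained in
#' the MS2 product ion), for a named metabolite.  Atom indices are 1-based.
#'
#' @param metabolite Metabolite id (string).
#' @param parent Integer vector of 1-based atom indices of the parent fragment.
#' @param product Integer vector of 1-based atom indices of the product
#'   fragment; must be a subset of `parent`.  May be empty.
#' @return An object of class `"mfp"` with fields `metabolite`, `parent`,
#'   `product` (both sorted and deduplicated).
#' @examples
#' mfp("A", c(2, 3, 4), c(2, 3))
#' @export
mfp <- function(metabolite, parent, product = integer(0)) {
  if (!is.character(metabolite) || length(metabolite) != 1L || !nzchar(metabolite))
    abort_validation("metabolite id must be a non-empty string")
  parent <- sort(unique(as.integer(parent)))
  product <- sort(unique(as.integer(product)))
  if (length(parent) && any(parent < 1L))
    abort_validation("parent atom indices must be >= 1 (1-based)")
  if (!all(product %in% parent))
    abort_validation("product fragment must be a subset of the parent fragment (%s: {%s} not within {%s})",
                     metabolite, format_atom_set(product), format_atom_set(parent))
  structure(list(metabolite = metabolite, parent = parent, product = product),
            class = "mfp")
}

#' Canonical MFP identifier
#'
#' @param x An `"mfp"` object.
#' @return A string of the form `met^{N}_{K}`, e.g. `"A^{2,3,4}_{2,3}"`;
#'   canonical identity of an MFP for naming, deduplication and ordering.
#' @export
mfp_id <- function(x) {
  sprintf("%s^{%s}_{%s}", x$metabolite,
          format_atom_set(x$parent), format_atom_set(x$product))
}

#' @export
print.mfp <- function(x, ...) {
  cat("<mfp> ", mfp_id(x), "\n", sep = "")
  invisible(x)
}

#' Tandemer feasibility
#'
#' A tandemer `[M+i] > [m+j]` of an MFP with parent size `n_parent` and
#' product size `n_product` is feasible iff it denotes a non-empty set of
#' isotopomers: `j` can be at most `i` (the product fragment is enclosed in
#' the parent) and at least `i - (n_parent - n_product)` (when every parent
#' atom outside the product fragment is labeled).
#'
#' @param i Number of labeled atoms in the parent fragment (0-based count).
#' @param j Number of labeled atoms in the product fragment.
#' @param n_parent Parent fragment size `|N|`.
#' @param n_product Product fragment size `|K|`.
#' @return Logical (vectorized over `i`, `j`).
#' @examples
#' is_feasible(1, 0, 3, 2)  # TRUE
#' is_feasible(3, 0, 3, 2)  # FALSE
#' @export
is_feasible <- function(i, j, n_parent, n_product) {
  n_parent <- as.integer(n_parent); n_product <- as.integer(n_product)
  if (n_product > n_parent || n_product < 0L)
    abort_validation("need 0 <= n_product <= n_parent (got %d, %d)", n_parent, n_product)
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 0L | i > n_parent)) abort_validation("i out of range [0, %d]", n_parent)
  if (any(j < 0L | j > n_product)) abort_validation("j out of range [0, %d]", n_product)
  (j <= i) & (j >= i - (n_parent - n_product))
}

#' Number of feasible tandemers
#'
#' Closed form `(n_parent - n_product + 1) * (n_product + 1)`.
#'
#' @inheritParams is_feasible
#' @return Integer count of feasible `(i, j)` pairs.
#' @examples
#' n_feasible(3, 2)  # 6
#' @export
n_feasible <- function(n_parent, n_product) {
  n_parent <- as.integer(n_parent); n_product <- as.integer(n_product)
  if (n_product > n_parent || n_product < 0L)
    abort_validation("need 0 <= n_product <= n_parent (got %d, %d)", n_parent, n_product)
  (n_parent - n_product + 1L) * (n_product + 1L)
}

# Logical mask of feasible entries of a (p+1) x (k+1) tandemer matrix.
feasible_mask <- function(n_parent, n_product) {
  outer(0:n_parent, 0:n_product,
        function(i, j) (j <= i) & (j >= i - (n_parent - n_product)))
}

# Clamp tiny float negatives to zero; anything more negative signals an
# inconsistent model or a near-singular system and is a hard error.
clamp_values <- function(values, what = "tandemer matrix") {
  neg <- values < 0
  if (any(neg)) {
    worst <- min(values)
    if (worst < -1e-12)
      abort_numerical("%s has negative entry %.3e (inconsistent model or singular system)",
                      what, worst)
    values[neg] <- 0
  }
  values
}

#' Construct a tandemer distribution matrix
#'
#' The `(|N|+1) x (|K|+1)` probability matrix over parent/product label-count
#' transitions `[M+i] > [m+j]`; entry `(i, j)` is stored at `values[i+1, j+1]`.
#'
#' @param values Numeric matrix of size `(|N|+1) x (|K|+1)`.
#' @param fragment The `"mfp"` the matrix belongs to, or `NULL` for anonymous
#'   matrices (e.g. Cauchy products).
#' @param check Validate normalization (sum 1 within 1e-9), non-negativity
#'   (tiny negatives clamped) and zeroing of infeasible entries.
#' @return Object of class `"tandemer"` with fields `mfp` and `values`.
#' @export
tandemer_matrix <- function(values, fragment = NULL, check = TRUE) {
  values <- as.matrix(values)
  p <- nrow(values) - 1L; k <- ncol(values) - 1L
  if (k > p) abort_validation("tandemer matrix cannot have more columns than rows")
  if (!is.null(fragment)) {
    if (!inherits(fragment, "mfp")) abort_validation("fragment must be an 'mfp'")
    if (length(fragment$parent) != p || length(fragment$product) != k)
      abort_validation("matrix shape (%d x %d) does not match fragment %s",
                       p + 1L, k + 1L, mfp_id(fragment))
  }
  if (check) {
    values <- clamp_values(values)
    mask <- feasible_mask(p, k)
    if (any(values[!mask] != 0))
      abort_validation("infeasible tandemer entries must be exactly zero")
    s <- sum(values)
    if (abs(s - 1) > 1e-9)
      abort_numerical("tandemer matrix sums to %.12f, expected 1", s)
  }
  dimnames(values) <- list(paste0("M+", 0:p), paste0("m+", 0:k))
  structure(list(mfp = fragment, values = values), class = "tandemer")
}

#' @export
print.tandemer <- function(x, digits = 6, ...) {
  hdr <- if (is.null(x$mfp)) "<tandemer>" else paste0("<tandemer> ", mfp_id(x$mfp))
  cat(hdr, "\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Construct an isotopomer distribution
#'
#' A probability vector over all `2^n` positional labeling patterns of an
#' `n`-atom metabolite.  Patterns are binary strings read left to right as
#' atom `1..n` (`"1001"` = atoms 1 and 4 labeled).
#'
#' @param metabolite Metabolite id.
#' @param n_atoms Number of tracked atoms.
#' @param fractions Named numeric vector of abundances keyed by binary label
#'   string; unnamed full-length vectors (in index order) are also accepted.
#'   Unspecified isotopomers get abundance 0.
#' @return Named numeric vector of length `2^n` (class
#'   `"isotopomer_distribution"`), names the binary label strings, attributes
#'   `metabolite` and `n_atoms`.
#' @examples
#' isotopomer_distribution("A", 4, c("1001" = 0.6, "0101" = 0.3, "1011" = 0.1))
#' @export
isotopomer_distribution <- function(metabolite, n_atoms, fractions) {
  n_atoms <- as.integer(n_atoms)
  labs <- iso_labels(n_atoms)
  vals <- numeric(2^n_atoms)
  names(vals) <- labs
  if (is.null(names(fractions))) {
    if (length(fractions) != 2^n_atoms)
      abort_validation("unnamed fractions must have length 2^n = %d", 2^n_atoms)
    vals[] <- as.numeric(fractions)
  } else {
    bad <- setdiff(names(fractions), labs)
    if (length(bad))
      abort_validation("isotopomer label '%s' invalid for %d-atom metabolite %s",
                       bad[1L], n_atoms, metabolite)
    vals[names(fractions)] <- as.numeric(fractions)
  }
  if (any(vals < 0)) abort_validation("isotopomer abundances must be >= 0")
  s <- sum(vals)
  if (abs(s - 1) > 1e-6)
    abort_validation("isotopomer distribution of %s sums to %.8f, expected 1",
                     metabolite, s)
  vals <- vals / s
  structure(vals, metabolite = metabolite, n_atoms = n_atoms,
            class = "isotopomer_distribution")
}

#' Marginalize an isotopomer distribution onto an MFP
#'
#' Entry `(i, j)` of the resulting tandemer distribution matrix is the summed
#' abundance of all isotopomers having `i` labeled atoms inside the parent
#' fragment and `j` inside the product fragment.
#'
#' @param dist An [isotopomer_distribution()] (or plain numeric vector of
#'   length `2^n` in index order).
#' @param fragment The `"mfp"` to marginalize onto; atom indices must lie
#'   within `1..n`.
#' @return A [tandemer_matrix()] for `fragment`.
#' @examples
#' d <- isotopomer_distribution("A", 4,
#'   c("1001" = 0.6, "0101" = 0.3, "1011" = 0.1))
#' tandemer_from_isotopomers(d, mfp("A", c(2, 3, 4), c(2, 3)))
#' @export
tandemer_from_isotopomers <- function(dist, fragment) {
  vals <- as.numeric(dist)
  n <- as.integer(round(log2(length(vals))))
  if (2^n != length(vals))
    abort_validation("distribution length %d is not a power of two", length(vals))
  if (length(fragment$parent) && max(fragment$parent) > n)
    abort_validation("fragment %s references atom %d but metabolite has %d atoms",
                     mfp_id(fragment), max(fragment$parent), n)
  p <- length(fragment$parent); k <- length(fragment$product)
  bm <- bit_matrix(n)
  i <- if (p) as.integer(rowSums(bm[, fragment$parent, drop = FALSE])) else
    integer(length(vals))
  j <- if (k) as.integer(rowSums(bm[, fragment$product, drop = FALSE])) else
    integer(length(vals))
  m <- matrix(0, nrow = p + 1L, ncol = k + 1L)
  # column-major linear index into m
  li <- j * (p + 1L) + i + 1L
  acc <- rowsum(vals, li)
  m[as.integer(rownames(acc))] <- acc[, 1L]
  tandemer_matrix(m, fragment = fragment)
}

#' Cauchy product of two tandemer distribution matrices
#'
#' The 2-D convolution combining the tandemer distributions of two substrate
#' fragments into that of their condensation product:
#' `C(i,j) = sum over i1+i2=i, j1+j2=j of A(i1,j1) * B(i2,j2)`.
#'
#' @param a,b `"tandemer"` objects (or plain matrices) of sizes
#'   `(p1+1) x (k1+1)` and `(p2+1) x (k2+1)`.
#' @param fragment Optional `"mfp"` to attach to the result.
#' @return A `"tandemer"` of size `(p1+p2+1) x (k1+k2+1)`.  Infeasible entries
#'   of the result are zero automatically; normalization is preserved.
#' @export
cauchy_product <- function(a, b, fragment = NULL) {
  va <- if (inherits(a, "tandemer")) a$values else as.matrix(a)
  vb <- if (inherits(b, "tandemer")) b$values else as.matrix(b)
  for (nm in c("a", "b")) {
    v <- if (nm == "a") va else vb
    s <- sum(v)
    if (abs(s - 1) > 1e-6)
      warning(sprintf("cauchy_product: input '%s' sums to %.8f (not normalized); bilinearity still holds",
                      nm, s))
  }
  ra <- nrow(va); ca <- ncol(va); rb <- nrow(vb); cb <- ncol(vb)
  out <- matrix(0, nrow = ra + rb - 1L, ncol = ca + cb - 1L)
  for (i1 in seq_len(ra)) {
    for (j1 in seq_len(ca)) {
      x <- va[i1, j1]
      if (x == 0) next
      rows <- i1:(i1 + rb - 1L)
      cols <- j1:(j1 + cb - 1L)
      out[rows, cols] <- out[rows, cols] + x * vb
    }
  }
  out <- clamp_values(out)
  tandemer_matrix(out, fragment = fragment, check = FALSE)
}

#' Marginal mass-isotopomer distributions of a tandemer matrix
#'
#' `parent_mid()` returns the row sums (the MID of the parent fragment,
#' length `|N|+1`); `product_mid()` the column sums (MID of the product
#' fragment, length `|K|+1`).
#'
#' @param x A `"tandemer"` object.
#' @return Named numeric vector summing to 1.
#' @export
parent_mid <- function(x) {
  v <- if (inherits(x, "tandemer")) x$values else as.matrix(x)
  rowSums(v)
}

#' @rdname parent_mid
#' @export
product_mid <- function(x) {
  v <- if (inherits(x, "tandemer")) x$values else as.matrix(x)
  colSums(v)
}

# Ordered feasible cells of a (p, k) tandemer matrix: i ascending, then j.
feasible_cells <- function(n_parent, n_product) {
  i <- integer(0); j <- integer(0)
  for (ii in 0:n_parent) {
    jj <- max(0L, ii - (n_parent - n_product)):min(ii, n_product)
    i <- c(i, rep.int(ii, length(jj)))
    j <- c(j, jj)
  }
  cbind(i = i, j = j)
}

#' Vectorize / devectorize a tandemer matrix
#'
#' `vectorize_tandemer()` flattens the feasible entries of a tandemer matrix
#' into a row vector of length [n_feasible()], ordered by `i` ascending then
#' `j` ascending (the row layout of the cluster balance systems).
#' `devectorize_tandemer()` restores the full matrix, reinstating the
#' infeasible zeros.
#'
#' @param x A `"tandemer"` object (or plain matrix).
#' @return For `vectorize_tandemer()`, a numeric vector.
#' @export
vectorize_tandemer <- function(x) {
  v <- if (inherits(x, "tandemer")) x$values else as.matrix(x)
  p <- nrow(v) - 1L; k <- ncol(v) - 1L
  cells <- feasible_cells(p, k)
  v[cbind(cells[, "i"] + 1L, cells[, "j"] + 1L)]
}

#' @rdname vectorize_tandemer
#' @param row Numeric vector of length `n_feasible(n_parent, n_product)`.
#' @param fragment The `"mfp"` giving the target shape (or `NULL` with
#'   explicit `n_parent`, `n_product`).
#' @param n_parent,n_product Explicit fragment sizes when `fragment` is NULL.
#' @param check Passed to [tandemer_matrix()].
#' @export
devectorize_tandemer <- function(row, fragment = NULL, n_parent = NULL,
                                 n_product = NULL, check = TRUE) {
  if (!is.null(fragment)) {
    n_parent <- length(fragment$parent); n_product <- length(fragment$product)
  }
  if (length(row) != n_feasible(n_parent, n_product))
    abort_validation("row length %d does not match n_feasible(%d, %d) = %d",
                     length(row), n_parent, n_product,
                     n_feasible(n_parent, n_product))
  m <- matrix(0, nrow = n_parent + 1L, ncol = n_product + 1L)
  cells <- feasible_cells(n_parent, n_product)
  m[cbind(cells[, "i"] + 1L, cells[, "j"] + 1L)] <- row
  tandemer_matrix(m, fragment = fragment, check = check)
}
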