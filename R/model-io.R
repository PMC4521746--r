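# Model I/O: the atom-transition model format, flux/tracer/target CSVs,
# steady-state checking and result serialization.
#
# Model format (one reaction per line, UTF-8 text):
#   #media A B            -- declares media metabolites (labeling supplied)
#   v1: A (abcd) -> B (abcd)
#   v4: C (ab) <-> D (ab)          -- reversible, expanded to v4_f / v4_b
#   v6: B (abcd) + C (ef) -> E (cdef)
#   v7: D (ab) ->                  -- efflux to an untracked sink
#   v9: S (ab) -> P (ab) | S (ab) -> P (ba)   -- symmetric alternatives
# One lowercase letter per tracked atom; letters are unique within each side;
# every product letter must occur on the substrate side (a substrate letter
# absent from the products leaves to an untracked sink).  Metabolites with no
# tracked atoms (cofactors) appear without a parenthesized label string.

TERM_RE <- "^([A-Za-z0-9_.-]+)\\s*(\\(([a-z]+)\\))?$"

parse_side <- function(side, line_no) {
  side <- trimws(side)
  if (!nzchar(side)) return(list())
  parts <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
  lapply(parts, function(p) {
    m <- regmatches(p, regexec(TERM_RE, p))[[1L]]
    if (length(m) == 0L)
      abort_validation("line %d: cannot parse term '%s'", line_no, p)
    letters <- if (nzchar(m[4L])) strsplit(m[4L], "")[[1L]] else character(0)
    list(met = m[2L], atoms = letters)
  })
}

validate_mapping <- function(subs, prods, line_no, id, allow_nary = FALSE) {
  sub_letters <- unlist(lapply(subs, `[[`, "atoms"))
  prod_letters <- unlist(lapply(prods, `[[`, "atoms"))
  if (anyDuplicated(sub_letters))
    abort_validation("line %d (%s): duplicate atom letter on substrate side", line_no, id)
  if (anyDuplicated(prod_letters))
    abort_validation("line %d (%s): duplicate atom letter on product side", line_no, id)
  orphan <- setdiff(prod_letters, sub_letters)
  if (length(orphan))
    abort_validation("line %d (%s): product atom letter '%s' has no substrate source",
                     line_no, id, orphan[1L])
  n_tracked <- sum(vapply(subs, function(t) length(t$atoms) > 0L, logical(1)))
  if (n_tracked > 2L && !allow_nary)
    abort_validation("line %d (%s): more than 2 substrates carry tracked atoms (use split_nary = TRUE)",
                     line_no, id)
  invisible(TRUE)
}

split_nary_record <- function(rec) {
  # Rewrite an n-substrate condensation into a cascade of binary
  # condensations through auto-generated intermediate species.
  if (length(rec$alts) != 1L)
    abort_validation("reaction %s: split_nary does not support mapping alternatives", rec$id)
  if (rec$reversible)
    abort_validation("reaction %s: split_nary does not support reversible reactions", rec$id)
  alt <- rec$alts[[1L]]
  tracked <- Filter(function(t) length(t$atoms) > 0L, alt$lhs)
  others <- Filter(function(t) length(t$atoms) == 0L, alt$lhs)
  out <- list()
  k <- 0L
  while (length(tracked) > 2L) {
    k <- k + 1L
    imet <- sprintf("%s.nry%d", rec$id, k)
    merged <- list(met = imet, atoms = c(tracked[[1L]]$atoms, tracked[[2L]]$atoms))
    out[[length(out) + 1L]] <- list(
      id = sprintf("%s__nry%d", rec$id, k), flux_id = rec$id, reversible = FALSE,
      alts = list(list(lhs = tracked[1:2], rhs = list(merged))))
    tracked <- c(list(merged), tracked[-(1:2)])
  }
  out[[length(out) + 1L]] <- list(
    id = rec$id, flux_id = rec$id, reversible = FALSE,
    alts = list(list(lhs = c(tracked, others), rhs = alt$rhs)))
  out
}

#' Parse an atom-mapped metabolic network model
#'
#' Reads the plain-text reaction format documented in the package vignette:
#' one reaction per line `id: S1 (letters) [+ S2 (letters)] -> P1 (letters)
#' [+ P2 ...]`, with `<->` marking reversible reactions (expanded to `_f`/`_b`
#' irreversible pairs), `#media` lines declaring media metabolites, and `|`
#' separating equally weighted alternative atom mappings (molecular symmetry).
#'
#' @param path Path to the model file (ignored when `text` is given).
#' @param text Model file contents as a character vector or single string.
#' @param split_nary Rewrite reactions with more than two tracked-atom
#'   substrates into a cascade of binary condensations through auto-generated
#'   intermediates (default: such reactions are an error).
#' @return A `"tandemer_network"`: list with `metabolites` (data.frame `id`,
#'   `n_atoms`, `is_media`), `reactions` (expanded unidirectional mapping
#'   entries), `media`, and the parsed `spec` used by [serialize_model()].
#' @export
parse_model <- function(path = NULL, text = NULL, split_nary = FALSE) {
  if (is.null(text)) {
    if (is.null(path)) abort_validation("either path or text must be given")
    text <- readLines(path, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  media <- character(0)
  records <- list()
  seen_ids <- character(0)

  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw)) next
    if (startsWith(raw, "#")) {
      m <- regmatches(raw, regexec("^#media\\s+(.+)$", raw))[[1L]]
      if (length(m)) media <- c(media, strsplit(trimws(m[2L]), "\\s+")[[1L]])
      next
    }
    m <- regmatches(raw, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", raw))[[1L]]
    if (length(m) == 0L)
      abort_validation("line %d: cannot parse reaction line '%s'", ln, raw)
    id <- m[2L]; body <- m[3L]
    if (id %in% seen_ids) abort_validation("line %d: duplicate reaction id '%s'", ln, id)
    seen_ids <- c(seen_ids, id)

    alt_bodies <- trimws(strsplit(body, "|", fixed = TRUE)[[1L]])
    reversible <- NA
    alts <- lapply(alt_bodies, function(ab) {
      rev_here <- grepl("<->", ab, fixed = TRUE)
      sides <- strsplit(ab, if (rev_here) "<->" else "->", fixed = TRUE)[[1L]]
      if (length(sides) == 1L) sides <- c(sides, "")
      if (length(sides) != 2L)
        abort_validation("line %d (%s): expected exactly one arrow", ln, id)
      if (is.na(reversible)) reversible <<- rev_here
      else if (reversible != rev_here)
        abort_validation("line %d (%s): alternatives disagree on reversibility", ln, id)
      list(lhs = parse_side(sides[1L], ln), rhs = parse_side(sides[2L], ln))
    })
    # alternatives must involve the same species in the same order
    sig <- vapply(alts, function(a) paste(
      paste(vapply(a$lhs, `[[`, "", "met"), collapse = "+"), "->",
      paste(vapply(a$rhs, `[[`, "", "met"), collapse = "+")), "")
    if (length(unique(sig)) != 1L)
      abort_validation("line %d (%s): mapping alternatives must use the same metabolites", ln, id)
    for (a in alts) {
      validate_mapping(a$lhs, a$rhs, ln, id, allow_nary = split_nary)
      if (reversible) {
        sl <- sort(unlist(lapply(a$lhs, `[[`, "atoms")))
        pl <- sort(unlist(lapply(a$rhs, `[[`, "atoms")))
        if (!identical(sl, pl))
          abort_validation("line %d (%s): reversible reactions must conserve all tracked atoms",
                           ln, id)
        validate_mapping(a$rhs, a$lhs, ln, id)
      }
    }
    records[[length(records) + 1L]] <-
      list(id = id, flux_id = id, reversible = reversible, alts = alts)
  }

  # n-ary rewriting; the rewritten records must pass the binary check
  if (split_nary) {
    records <- do.call(c, lapply(records, function(rec) {
      n_tracked <- max(vapply(rec$alts, function(a)
        sum(vapply(a$lhs, function(t) length(t$atoms) > 0L, logical(1))), 0L))
      if (n_tracked > 2L) split_nary_record(rec) else list(rec)
    }))
    for (rec in records) for (a in rec$alts)
      validate_mapping(a$lhs, a$rhs, 0L, rec$id)
  }

  # metabolite table
  counts <- list()
  for (rec in records) for (a in rec$alts) for (t in c(a$lhs, a$rhs)) {
    n <- length(t$atoms)
    prev <- counts[[t$met]]
    if (is.null(prev)) counts[[t$met]] <- n
    else if (prev != n)
      abort_validation("metabolite '%s' appears with inconsistent atom counts (%d vs %d)",
                       t$met, prev, n)
  }
  ids <- sort_radix(names(counts))
  media <- sort_radix(unique(media))
  unknown_media <- setdiff(media, ids)
  if (length(unknown_media))
    abort_validation("#media references unknown metabolite '%s'", unknown_media[1L])
  metabolites <- data.frame(
    id = ids,
    n_atoms = as.integer(unlist(counts[ids])),
    is_media = ids %in% media,
    stringsAsFactors = FALSE, row.names = NULL)

  # expand: reversible -> _f/_b; one entry per mapping alternative
  entries <- list()
  for (rec in records) {
    w <- 1 / length(rec$alts)
    dirs <- if (rec$reversible) {
      list(list(id = paste0(rec$id, "_f"), swap = FALSE),
           list(id = paste0(rec$id, "_b"), swap = TRUE))
    } else list(list(id = rec$id, swap = FALSE))
    for (d in dirs) for (a in rec$alts) {
      lhs <- if (d$swap) a$rhs else a$lhs
      rhs <- if (d$swap) a$lhs else a$rhs
      entries[[length(entries) + 1L]] <- list(
        id = d$id,
        flux_id = if (rec$reversible) d$id else rec$flux_id,
        base_id = rec$id, weight = w,
        substrates = lhs, products = rhs)
    }
  }

  structure(list(metabolites = metabolites, reactions = entries,
                 media = media, spec = records),
            class = "tandemer_network")
}

#' @export
print.tandemer_network <- function(x, ...) {
  cat(sprintf("<tandemer_network> %d metabolites (%d media), %d mapping entries (%d reactions)\n",
              nrow(x$metabolites), sum(x$metabolites$is_media),
              length(x$reactions),
              length(unique(vapply(x$reactions, `[[`, "", "id")))))
  invisible(x)
}

n_atoms_of <- function(network, met) {
  i <- match(met, network$metabolites$id)
  if (is.na(i)) abort_validation("unknown metabolite '%s'", met)
  network$metabolites$n_atoms[i]
}

is_media_met <- function(network, met) {
  met %in% network$media
}

#' Serialize a network back to the model text format
#'
#' Inverse of [parse_model()]: `parse_model(text = serialize_model(net))`
#' yields an identical network (canonical form).
#'
#' @param network A `"tandemer_network"`.
#' @return Character vector of model-file lines.
#' @export
serialize_model <- function(network) {
  fmt_term <- function(t)
    if (length(t$atoms)) sprintf("%s (%s)", t$met, paste(t$atoms, collapse = ""))
    else t$met
  fmt_side <- function(side) paste(vapply(side, fmt_term, ""), collapse = " + ")
  out <- character(0)
  if (length(network$media))
    out <- c(out, paste("#media", paste(network$media, collapse = " ")))
  for (rec in network$spec) {
    arrow <- if (rec$reversible) "<->" else "->"
    eqs <- vapply(rec$alts, function(a)
      trimws(paste(fmt_side(a$lhs), arrow, fmt_side(a$rhs))), "")
    out <- c(out, sprintf("%s: %s", rec$id, paste(eqs, collapse = " | ")))
  }
  out
}

# ids whose fluxes must be supplied (after reversible expansion / n-ary split)
required_flux_ids <- function(network) {
  sort_radix(unique(vapply(network$reactions, `[[`, "", "flux_id")))
}

#' Parse a flux vector CSV
#'
#' Columns `reaction,flux`.  Reversible reactions require their expanded
#' `_f`/`_b` ids; fluxes must be non-negative and cover every reaction.
#'
#' @param path CSV path.
#' @param network The parsed network the fluxes belong to.
#' @return Named numeric vector keyed by reaction id, class `"flux_vector"`.
#' @export
parse_fluxes <- function(path, network) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric"))
  if (!all(c("reaction", "flux") %in% names(df)))
    abort_validation("flux CSV must have columns reaction,flux")
  if (anyDuplicated(df$reaction))
    abort_validation("duplicate reaction id in flux file: '%s'",
                     df$reaction[duplicated(df$reaction)][1L])
  req <- required_flux_ids(network)
  unknown <- setdiff(df$reaction, req)
  if (length(unknown))
    abort_validation("flux file references unknown reaction '%s'", unknown[1L])
  missing <- setdiff(req, df$reaction)
  if (length(missing))
    abort_validation("flux file is missing reaction '%s'", missing[1L])
  if (any(!is.finite(df$flux)) || any(df$flux < 0))
    abort_validation("fluxes must be finite and non-negative (reaction '%s')",
                     df$reaction[which(!is.finite(df$flux) | df$flux < 0)[1L]])
  v <- df$flux
  names(v) <- df$reaction
  structure(v[req], class = "flux_vector")
}

#' Parse a tracer specification CSV
#'
#' Columns `metabolite,isotopomer,fraction`; one row per isotopomer with
#' non-zero abundance, binary label strings with atom 1 leftmost.  Fractions
#' must sum to 1 per metabolite (tolerance 1e-6); only media metabolites may
#' be listed.
#'
#' @inheritParams parse_fluxes
#' @return Named list of [isotopomer_distribution()]s keyed by metabolite id.
#' @export
parse_tracers <- function(path, network) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  if (!all(c("metabolite", "isotopomer", "fraction") %in% names(df)))
    abort_validation("tracer CSV must have columns metabolite,isotopomer,fraction")
  out <- list()
  for (met in unique(df$metabolite)) {
    if (!met %in% network$metabolites$id)
      abort_validation("tracer references unknown metabolite '%s'", met)
    if (!is_media_met(network, met))
      abort_validation("tracer given for non-media metabolite '%s'", met)
    sub <- df[df$metabolite == met, ]
    n <- n_atoms_of(network, met)
    if (any(nchar(sub$isotopomer) != n))
      abort_validation("isotopomer label for %s must have %d characters", met, n)
    fr <- sub$fraction
    names(fr) <- sub$isotopomer
    out[[met]] <- isotopomer_distribution(met, n, fr)
  }
  out
}

#' Parse a target MFP list CSV
#'
#' Columns `metabolite,parent_atoms,product_atoms`; atom sets are
#' comma-separated 1-based indices (quoted in the CSV).  Targets are
#' deduplicated canonically.
#'
#' @inheritParams parse_fluxes
#' @return List of [mfp()] objects.
#' @export
parse_targets <- function(path, network) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  if (!all(c("metabolite", "parent_atoms", "product_atoms") %in% names(df)))
    abort_validation("target CSV must have columns metabolite,parent_atoms,product_atoms")
  out <- list()
  seen <- character(0)
  for (r in seq_len(nrow(df))) {
    met <- df$metabolite[r]
    n <- n_atoms_of(network, met)
    f <- mfp(met, parse_atom_set(df$parent_atoms[r]),
             parse_atom_set(df$product_atoms[r]))
    if (length(f$parent) && max(f$parent) > n)
      abort_validation("target %s exceeds the %d atoms of %s", mfp_id(f), n, met)
    id <- mfp_id(f)
    if (!id %in% seen) { seen <- c(seen, id); out[[length(out) + 1L]] <- f }
  }
  out
}

#' Check isotopic-steady-state flux balance
#'
#' Reports, per non-media metabolite with tracked atoms, total production,
#' total consumption and their difference.  The check passes when every
#' residual satisfies `|production - consumption| <= tol * max(1, production)`.
#'
#' @param network A `"tandemer_network"`.
#' @param fluxes A flux vector from [parse_fluxes()] (or named numeric).
#' @param tol Relative tolerance (default 1e-6).
#' @return data.frame `metabolite, production, consumption, residual, ok`
#'   with attribute `"ok"` (overall pass/fail).
#' @export
check_steady_state <- function(network, fluxes, tol = 1e-6) {
  mets <- network$metabolites
  keep <- !mets$is_media & mets$n_atoms > 0L
  prod <- stats::setNames(numeric(sum(keep)), mets$id[keep])
  cons <- prod
  for (e in network$reactions) {
    v <- unname(fluxes[e$flux_id]) * e$weight
    if (is.na(v)) abort_validation("no flux given for reaction '%s'", e$flux_id)
    for (t in e$products) if (t$met %in% names(prod))
      prod[t$met] <- prod[t$met] + v
    for (t in e$substrates) if (t$met %in% names(cons))
      cons[t$met] <- cons[t$met] + v
  }
  res <- prod - cons
  ok <- abs(res) <= tol * pmax(1, prod)
  out <- data.frame(metabolite = names(prod), production = unname(prod),
                    consumption = unname(cons), residual = unname(res),
                    ok = unname(ok), stringsAsFactors = FALSE)
  attr(out, "ok") <- all(ok)
  out
}

#' Write simulation results to CSV (and optionally JSON)
#'
#' The CSV is long-format `metabolite,parent_atoms,product_atoms,i,j,abundance`
#' listing only feasible tandemers.  The JSON companion stores the full
#' matrices plus metadata and round-trips bit-exactly via
#' [read_results_json()].
#'
#' @param results Named list of `"tandemer"` objects keyed by MFP id (e.g.
#'   the `results` field of [simulate_tandemers()]).
#' @param csv_path Output CSV path.
#' @param json_path Optional output JSON path.
#' @param meta Named list of provenance metadata stored in the JSON.
#' @return Invisibly, the CSV data.frame.
#' @export
write_results <- function(results, csv_path, json_path = NULL, meta = list()) {
  ids <- sort_radix(names(results))
  rows <- lapply(ids, function(id) {
    t <- results[[id]]
    f <- t$mfp
    cells <- feasible_cells(length(f$parent), length(f$product))
    data.frame(metabolite = f$metabolite,
               parent_atoms = format_atom_set(f$parent),
               product_atoms = format_atom_set(f$product),
               i = cells[, "i"], j = cells[, "j"],
               abundance = t$values[cbind(cells[, "i"] + 1L, cells[, "j"] + 1L)],
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(0), parent_atoms = character(0),
               product_atoms = character(0), i = integer(0), j = integer(0),
               abundance = numeric(0))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = TRUE)
  if (!is.null(json_path)) {
    payload <- list(
      metadata = c(list(package = "tandemr",
                        version = as.character(utils::packageVersion("tandemr"))),
                   meta),
      results = stats::setNames(lapply(ids, function(id) {
        t <- results[[id]]
        f <- t$mfp
        list(metabolite = f$metabolite, parent_atoms = f$parent,
             product_atoms = f$product,
             values = unclass(t$values))
      }), ids))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(df)
}

#' Read simulation results back from JSON
#'
#' @param path JSON path written by [write_results()].
#' @return List with `metadata` and `results` (named list of `"tandemer"`).
#' @export
read_results_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- lapply(raw$results, function(r) {
    f <- mfp(r$metabolite, r$parent_atoms, r$product_atoms)
    tandemer_matrix(r$values, fragment = f, check = FALSE)
  })
  list(metadata = raw$metadata, results = res)
}
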