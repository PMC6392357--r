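# Multi-marker diet identification against a local plant reference
# library, and marker-resolution scoring at family/genus/species levels.

#' Resolve one gut marker sequence against the reference library
#'
#' The candidate set is every reference taxon achieving the maximal
#' identity fraction for that marker. Candidates below the identity
#' floor leave the result unidentified; congeners with identical
#' reference sequences yield multi-member candidate sets (species
#' complexes).
#'
#' @param query aligned gut sequence (QC-passed).
#' @param ref_seqs named character vector of reference sequences for the
#'   marker (names = taxon ids).
#' @param marker marker name.
#' @param min_identity identity floor below which the marker result is
#'   unidentified.
#' @return List with `marker`, `outcome` (`"sequence"` or
#'   `"unidentified"`), `candidates` (taxon ids at maximal identity) and
#'   `identity`.
#' @export
resolve_marker <- function(query, ref_seqs, marker = NA_character_,
                           min_identity = 0.95) {
  if (!length(ref_seqs)) stopf("empty reference library")
  ident <- identity_fractions(query, ref_seqs)
  best <- max(ident)
  if (best < min_identity) {
    return(list(marker = marker, outcome = "unidentified",
                candidates = character(), identity = best))
  }
  cand <- sort(names(ident)[ident >= best - 1e-12])
  list(marker = marker, outcome = "sequence", candidates = cand,
       identity = best)
}

item_level <- function(taxa, reflib) {
  rows <- reflib[match(taxa, reflib$taxon_id), , drop = FALSE]
  if (length(taxa) == 1) "species"
  else if (length(unique(rows$genus)) == 1) "genus"
  else if (length(unique(rows$family)) == 1) "family"
  else "order"
}

item_nontree <- function(taxa, reflib) {
  all(reflib$growth_form[match(taxa, reflib$taxon_id)] == "nontree")
}

#' Combine per-marker results into a diet call
#'
#' Markers whose candidate sets intersect are merged into a single diet
#' item resolved to the intersection (extra markers can only sharpen a
#' call); disjoint candidate sets are kept as separate diet items,
#' interpreted as multiple true food plants rather than as errors. Each
#' item's resolved level is species for a singleton, genus when all
#' members are congeneric, family when confamilial.
#'
#' @param results list of [resolve_marker()] results for one larva.
#' @param reflib reference-library taxon table.
#' @return List of class `diet_call` with `items`, each item a list
#'   (`taxa`, `level`, `nontree`, `markers`); zero items when every
#'   marker failed (larva excluded from the molecular web).
#' @export
combine_markers <- function(results, reflib) {
  results <- Filter(function(r) identical(r$outcome, "sequence"), results)
  items <- list()
  for (r in results) {
    merged <- FALSE
    for (k in seq_along(items)) {
      common <- intersect(items[[k]]$taxa, r$candidates)
      if (length(common)) {
        items[[k]]$taxa <- common
        items[[k]]$markers <- union(items[[k]]$markers, r$marker)
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      items[[length(items) + 1]] <- list(taxa = sort(r$candidates),
                                         markers = r$marker)
    }
  }
  items <- lapply(items, function(it) {
    it$taxa <- sort(it$taxa)
    it$level <- item_level(it$taxa, reflib)
    it$nontree <- item_nontree(it$taxa, reflib)
    it
  })
  structure(list(items = items), class = "diet_call")
}

#' Score the taxonomic resolution of one diet item
#'
#' 1 when the item is unambiguous at the level within the local library,
#' 0 when ambiguous; nontree taxa lacking local (plot) references but
#' distinguishable from all local sequences are conservatively scored
#' 0.5 at species level.
#'
#' @param item one element of a [combine_markers()] call's `items`.
#' @param reflib reference-library taxon table.
#' @param level `"species"`, `"genus"` or `"family"`.
#' @return Score in \{0, 0.5, 1\}.
#' @export
score_resolution <- function(item, reflib,
                             level = c("species", "genus", "family")) {
  level <- match.arg(level)
  if (item$nontree && level == "species") return(0.5)
  rows <- reflib[match(item$taxa, reflib$taxon_id), , drop = FALSE]
  key <- switch(level,
    species = rows$taxon_id,
    genus = rows$genus,
    family = rows$family
  )
  if (length(unique(key)) == 1) 1 else 0
}

#' Resolve all larvae against the reference library
#'
#' Applies QC, per-marker resolution and marker combination to every
#' larva in a synthetic (or imported) dataset.
#'
#' @param larvae larva table with `marker_<m>` outcome columns.
#' @param gut list of per-marker named gut sequence vectors.
#' @param ref list of per-marker named reference sequence vectors.
#' @param reflib reference-library taxon table.
#' @param min_identity identity floor passed to [resolve_marker()].
#' @return Named list (by larva id) with per-larva `marker_results` and
#'   `call`.
#' @export
resolve_diets <- function(larvae, gut, ref, reflib, min_identity = 0.95) {
  spec <- marker_spec()
  # precompute per-marker reference character matrices once; identity
  # search is then a single vectorized comparison per query
  refidx <- lapply(ref, function(s) {
    m <- matrix(unlist(strsplit(toupper(s), "", fixed = TRUE)),
                nrow = nchar(s[[1]]), ncol = length(s))
    list(chars = m, valid = m != "-" & m != "N", ids = names(s))
  })
  out <- vector("list", nrow(larvae))
  names(out) <- larvae$larva_id
  for (i in seq_len(nrow(larvae))) {
    id <- larvae$larva_id[i]
    mres <- list()
    for (m in names(gut)) {
      if (!id %in% names(gut[[m]])) next
      q <- gut[[m]][[id]]
      if (!qc_filter(q, m, spec)) {
        mres[[m]] <- list(marker = m, outcome = "discarded_low_quality",
                          candidates = character(), identity = NA_real_)
      } else {
        mres[[m]] <- resolve_marker_indexed(q, refidx[[m]], m, min_identity)
      }
    }
    out[[id]] <- list(marker_results = mres,
                      call = combine_markers(mres, reflib))
  }
  out
}

# vectorized resolve_marker against a precomputed reference index
resolve_marker_indexed <- function(query, idx, marker, min_identity) {
  qc <- seq_to_chars(query)
  if (length(qc) != nrow(idx$chars)) {
    stopf("query length %d does not match reference length %d",
          length(qc), nrow(idx$chars))
  }
  ok <- idx$valid & !(qc %in% c("-", "N"))
  comp <- colSums(ok)
  if (any(comp == 0)) stopf("no comparable sites for some references")
  mism <- (idx$chars != qc) & ok
  ident <- stats::setNames(1 - colSums(mism) / comp, idx$ids)
  best <- max(ident)
  if (best < min_identity) {
    return(list(marker = marker, outcome = "unidentified",
                candidates = character(), identity = best))
  }
  list(marker = marker, outcome = "sequence",
       candidates = sort(idx$ids[ident >= best - 1e-12]), identity = best)
}

#' Per-marker and combined diet-identification resolution summary
#'
#' Mean resolution at family, genus and species levels, averaged over
#' diet individuals (a species eaten by ten larvae counts ten times),
#' for each marker alone and for the marker combination, plus sequence
#' counts — the shape of a marker-resolution table.
#'
#' @param resolved output of [resolve_diets()].
#' @param reflib reference-library taxon table.
#' @return data.frame with one row per marker plus a combined row;
#'   percentage columns `family_pct`, `genus_pct`, `species_pct` and
#'   `n_sequences`.
#' @export
resolution_summary <- function(resolved, reflib) {
  markers <- plant_markers()
  levels <- c("family", "genus", "species")
  score_item_set <- function(items) {
    if (!length(items)) return(NULL)
    sapply(levels, function(lv) {
      mean(vapply(items, score_resolution, numeric(1),
                  reflib = reflib, level = lv))
    })
  }
  rows <- list()
  for (m in markers) {
    per <- list()
    for (r in resolved) {
      mr <- r$marker_results[[m]]
      if (is.null(mr) || !identical(mr$outcome, "sequence")) next
      it <- list(taxa = mr$candidates,
                 level = item_level(mr$candidates, reflib),
                 nontree = item_nontree(mr$candidates, reflib))
      per[[length(per) + 1]] <- score_item_set(list(it))
    }
    rows[[m]] <- c(if (length(per)) colMeans(do.call(rbind, per)) * 100
                   else rep(NA_real_, 3),
                   n = length(per))
  }
  comb <- list()
  for (r in resolved) {
    s <- score_item_set(r$call$items)
    if (!is.null(s)) comb[[length(comb) + 1]] <- s
  }
  rows[["combined"]] <- c(if (length(comb)) colMeans(do.call(rbind, comb)) * 100
                          else rep(NA_real_, 3),
                          n = length(comb))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("family_pct", "genus_pct", "species_pct", "n_sequences")
  out <- round_half_up(out, 1)
  out$n_sequences <- as.integer(out$n_sequences)
  cbind(marker = rownames(out), out, row.names = NULL)
}

#' Overall diet recovery rate
#'
#' Percentage of larvae whose gut contents were identified by at least
#' one marker, reported to one decimal.
#'
#' @param n_identified larvae with an identified diet.
#' @param n_total all larvae.
#' @return Percentage (half-up, 1 dp).
#' @export
diet_recovery <- function(n_identified, n_total) {
  if (n_total <= 0) stopf("n_total must be positive")
  round_half_up(100 * n_identified / n_total, 1)
}

#' Write diet calls to a TSV file
#'
#' @param resolved output of [resolve_diets()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_diet_calls <- function(resolved, path) {
  rows <- list()
  for (id in names(resolved)) {
    items <- resolved[[id]]$call$items
    for (k in seq_along(items)) {
      it <- items[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        larva_id = id, item_index = k,
        taxa = paste(it$taxa, collapse = "+"),
        level = it$level, nontree = it$nontree,
        markers = paste(it$markers, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(larva_id = character(), item_index = integer(),
               taxa = character(), level = character(),
               nontree = logical(), markers = character())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
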