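# Per-larva agreement between the fogged host and the molecular diet,
# with spatial attribution of mismatches to observation or molecular
# bias, and observation-accuracy tallies by taxonomic level.

MISMATCH_CATEGORIES <- c("match", "near_neighbor", "far_neighbor",
                         "nontree", "low_resolution")

# does a diet item unambiguously resolve to the collection taxon at the
# given level?
item_matches_host <- function(item, host_taxon, reflib, level) {
  rows <- reflib[match(item$taxa, reflib$taxon_id), , drop = FALSE]
  host <- reflib[match(host_taxon, reflib$taxon_id), , drop = FALSE]
  key <- switch(level,
    species = rows$taxon_id,
    genus = rows$genus,
    family = rows$family
  )
  hkey <- switch(level,
    species = host$taxon_id,
    genus = host$genus,
    family = host$family
  )
  length(unique(key)) == 1 && unique(key) == hkey
}

# minimum distance from a point to any stem of the given taxa (Inf when
# none are mapped)
min_stem_distance <- function(x, y, taxa, stems) {
  sub <- stems[stems$taxon_id %in% taxa, , drop = FALSE]
  if (!nrow(sub)) return(Inf)
  min(sqrt((sub$x_m - x)^2 + (sub$y_m - y)^2))
}

classify_item <- function(item, larva, reflib, stems, radius) {
  host <- larva$collection_taxon
  if (item_matches_host(item, host, reflib, "species")) {
    return(list(category = "match", distance_m = 0))
  }
  if (item$nontree) {
    return(list(category = "nontree", distance_m = NA_real_))
  }
  mapped <- item$taxa[item$taxa %in% stems$taxon_id]
  if (!length(mapped)) {
    return(list(category = NA_character_, distance_m = NA_real_))
  }
  d <- min_stem_distance(larva$x_m, larva$y_m, mapped, stems)
  if (length(item$taxa) > 1) {
    # ambiguous at species level: a member within the near radius makes
    # the mismatch an observation-method (near-neighbour) bias,
    # otherwise it is a molecular resolution bias
    if (d <= radius) list(category = "near_neighbor", distance_m = d)
    else list(category = "low_resolution", distance_m = d)
  } else {
    if (d <= radius) list(category = "near_neighbor", distance_m = d)
    else list(category = "far_neighbor", distance_m = d)
  }
}

#' Classify one larva's diet against its fogged host
#'
#' Decision order per diet item: unambiguous agreement with the
#' collection species is a match; a nontree diet is an observation-method
#' sampling bias; an item ambiguous at species level is a near-neighbour
#' (observation) bias when any member has a stem within the near radius
#' of the collection stem and otherwise a molecular low-resolution bias;
#' an unambiguous non-matching species is a near or far neighbour by the
#' same radius. Multi-item larvae take the most favourable category in
#' the order match > near > far > nontree > low_resolution.
#'
#' @param larva one row of a larva table (with coordinates).
#' @param call a [combine_markers()] diet call.
#' @param reflib reference-library taxon table.
#' @param stems mapped stem table.
#' @param radius near/far radius in metres (inclusive near boundary).
#' @return List with `category` and `distance_m` (nearest relevant
#'   stem; `NA` when the category is not distance-based).
#' @export
classify_larva <- function(larva, call, reflib, stems, radius = 2) {
  if (!length(call$items)) {
    return(list(category = NA_character_, distance_m = NA_real_))
  }
  results <- lapply(call$items, classify_item, larva = larva,
                    reflib = reflib, stems = stems, radius = radius)
  cats <- vapply(results, function(r) r$category %||% NA_character_,
                 character(1))
  ok <- which(!is.na(cats))
  if (!length(ok)) {
    return(list(category = NA_character_, distance_m = NA_real_))
  }
  best <- ok[which.min(match(cats[ok], MISMATCH_CATEGORIES))]
  results[[best]]
}

#' Classify every larva with a non-empty diet call
#'
#' @param larvae larva table.
#' @param resolved output of [resolve_diets()].
#' @param reflib,stems community tables.
#' @param radius near/far radius in metres.
#' @return data.frame (larva_id, category, distance_m, diet_item);
#'   larvae whose diet taxa are unmapped non-nontree species are logged
#'   and excluded, larvae with no diet call are omitted.
#' @export
classify_diets <- function(larvae, resolved, reflib, stems, radius = 2) {
  rows <- list()
  n_err <- 0L
  for (i in seq_len(nrow(larvae))) {
    id <- larvae$larva_id[i]
    r <- resolved[[id]]
    if (is.null(r) || !length(r$call$items)) next
    cl <- classify_larva(larvae[i, ], r$call, reflib, stems, radius)
    if (is.na(cl$category)) {
      n_err <- n_err + 1L
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      larva_id = id, category = cl$category, distance_m = cl$distance_m,
      diet_item = paste(vapply(r$call$items, function(it) {
        paste(it$taxa, collapse = "+")
      }, character(1)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  if (n_err) {
    message(sprintf("%d larvae with unmapped non-nontree diet taxa excluded",
                    n_err))
  }
  if (!length(rows)) {
    return(data.frame(larva_id = character(), category = character(),
                      distance_m = numeric(), diet_item = character()))
  }
  do.call(rbind, rows)
}

#' Summarize diet mismatch categories and method contributions
#'
#' Per-category percentages over all classified larvae, and the
#' contribution of each method to mismatch over mismatched larvae only:
#' near + far + nontree is observation-method bias, low-resolution is
#' molecular-method bias.
#'
#' @param x either a character vector/factor of per-larva categories, a
#'   named count vector, or a [classify_diets()] table.
#' @return List with `counts`, `percentages` (1 dp, over all classified
#'   larvae), `contrib_observation_pct` and `contrib_molecular_pct`
#'   (over mismatched larvae; `NA` when nothing mismatches) and
#'   `n_classified`.
#' @export
summarize_mismatch <- function(x) {
  if (is.data.frame(x)) x <- x$category
  if (is.numeric(x)) {
    if (is.null(names(x)) || !all(names(x) %in% MISMATCH_CATEGORIES)) {
      stopf("count vectors must be named by mismatch category")
    }
    counts <- stats::setNames(rep(0, length(MISMATCH_CATEGORIES)),
                              MISMATCH_CATEGORIES)
    counts[names(x)] <- x
  } else {
    x <- factor(as.character(x), levels = MISMATCH_CATEGORIES)
    if (anyNA(x)) stopf("unknown mismatch category")
    counts <- table(x)
  }
  counts <- stats::setNames(as.numeric(counts), MISMATCH_CATEGORIES)
  total <- sum(counts)
  if (total == 0) stopf("no classified larvae")
  pct <- round_half_up(100 * counts / total, 1)
  mismatched <- total - counts[["match"]]
  obs_bias <- counts[["near_neighbor"]] + counts[["far_neighbor"]] +
    counts[["nontree"]]
  contrib_obs <- if (mismatched > 0) {
    round_half_up(100 * obs_bias / mismatched, 1)
  } else NA_real_
  contrib_mol <- if (mismatched > 0) {
    round_half_up(100 * counts[["low_resolution"]] / mismatched, 1)
  } else NA_real_
  list(counts = counts, percentages = pct,
       contrib_observation_pct = contrib_obs,
       contrib_molecular_pct = contrib_mol,
       n_classified = total, n_mismatched = mismatched)
}

#' Count larvae whose fogged host is confirmed by the molecular diet
#'
#' A larva is confirmed at a level when some diet item unambiguously
#' resolves to its collection taxon at that level; counts are therefore
#' non-increasing from family to species. With `marker` set, only that
#' marker's candidate sets are used and only larvae with a sequence for
#' that marker enter the denominator.
#'
#' @param larvae larva table.
#' @param resolved output of [resolve_diets()].
#' @param reflib reference-library taxon table.
#' @param marker optional single marker name.
#' @return List with `counts` (family/genus/species confirmations) and
#'   `n` (larvae considered).
#' @export
accuracy_by_level <- function(larvae, resolved, reflib, marker = NULL) {
  levels <- c("family", "genus", "species")
  counts <- stats::setNames(c(0L, 0L, 0L), levels)
  n <- 0L
  for (i in seq_len(nrow(larvae))) {
    id <- larvae$larva_id[i]
    r <- resolved[[id]]
    if (is.null(r)) next
    items <- if (is.null(marker)) {
      r$call$items
    } else {
      mr <- r$marker_results[[marker]]
      if (is.null(mr) || !identical(mr$outcome, "sequence")) list()
      else list(list(taxa = mr$candidates,
                     nontree = item_nontree(mr$candidates, reflib)))
    }
    if (!length(items)) next
    n <- n + 1L
    for (lv in levels) {
      hit <- any(vapply(items, item_matches_host, logical(1),
                        host_taxon = larvae$collection_taxon[i],
                        reflib = reflib, level = lv))
      if (hit) counts[[lv]] <- counts[[lv]] + 1L
    }
  }
  list(counts = counts, n = n)
}

#' Write a mismatch summary shaped like a category table
#'
#' @param summary a [summarize_mismatch()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mismatch_summary <- function(summary, path) {
  df <- data.frame(
    category = MISMATCH_CATEGORIES,
    n_larvae = as.numeric(summary$counts),
    pct_larvae = as.numeric(summary$percentages),
    method = c("", rep("observation", 3), "molecular"),
    stringsAsFactors = FALSE
  )
  df$contribution_pct <- c(NA, summary$contrib_observation_pct, NA, NA,
                           summary$contrib_molecular_pct)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
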