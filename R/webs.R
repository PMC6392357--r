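# Bipartite web construction (observation vs molecular) and node/link
# overlap tables.

# canonical column label for a set of member taxa (species complex when
# more than one member)
complex_label <- function(taxa, reflib, level = "species") {
  if (level == "genus") {
    g <- sort(unique(reflib$genus[match(taxa, reflib$taxon_id)]))
    return(paste(g, collapse = "+"))
  }
  nm <- sort(reflib$taxon_name[match(taxa, reflib$taxon_id)])
  paste(nm, collapse = "+")
}

make_web <- function(insect, plant, level) {
  if (!length(insect)) {
    w <- matrix(0L, 0, 0)
    attr(w, "level") <- level
    class(w) <- c("bipartite_web", class(w))
    return(w)
  }
  tab <- table(insect = insect, plant = plant)
  w <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  w <- w[rowSums(w) > 0, colSums(w) > 0, drop = FALSE]
  attr(w, "level") <- level
  class(w) <- c("bipartite_web", class(w))
  w
}

#' Build the observation web (field co-occurrence)
#'
#' Cell (i, p) counts the larvae of insect i collected from plant p; at
#' genus level, host columns are aggregated by genus.
#'
#' @param larvae larva table with `collection_taxon` and an insect label
#'   column.
#' @param reflib reference-library taxon table.
#' @param level `"species"` or `"genus"`.
#' @param insect_col column of `larvae` holding the insect label.
#' @return An integer count matrix of class `bipartite_web` (insects x
#'   plants) with a `level` attribute.
#' @export
build_observation_web <- function(larvae, reflib,
                                  level = c("species", "genus"),
                                  insect_col = "insect") {
  level <- match.arg(level)
  if (!insect_col %in% names(larvae)) {
    stopf("larvae must carry an '%s' column with accepted insect labels",
          insect_col)
  }
  keep <- !is.na(larvae[[insect_col]])
  n_skipped <- sum(!keep)
  if (n_skipped) {
    message(sprintf("%d larvae without accepted insect labels skipped",
                    n_skipped))
  }
  larvae <- larvae[keep, , drop = FALSE]
  rows <- reflib[match(larvae$collection_taxon, reflib$taxon_id), ]
  plant <- if (level == "genus") rows$genus else rows$taxon_name
  make_web(larvae[[insect_col]], plant, level)
}

#' Build the molecular web (gut-content diet calls)
#'
#' Each diet item of each larva adds one count to (insect, diet taxon);
#' species complexes form single columns labelled by their sorted member
#' names, merging into their genus at genus level.
#'
#' @param larvae larva table (restricted internally to larvae with a
#'   non-empty diet call — the "matched" set).
#' @param resolved output of [resolve_diets()].
#' @param reflib reference-library taxon table.
#' @param level `"species"` or `"genus"`.
#' @param insect_col column of `larvae` holding the insect label.
#' @return A `bipartite_web` matrix with a `complex_members` attribute
#'   mapping column labels to member taxon names.
#' @export
build_molecular_web <- function(larvae, resolved, reflib,
                                level = c("species", "genus"),
                                insect_col = "insect") {
  level <- match.arg(level)
  ins <- character()
  pl <- character()
  members <- list()
  for (i in seq_len(nrow(larvae))) {
    id <- larvae$larva_id[i]
    lab <- larvae[[insect_col]][i]
    if (is.na(lab)) next
    r <- resolved[[id]]
    if (is.null(r) || !length(r$call$items)) next
    for (it in r$call$items) {
      col <- complex_label(it$taxa, reflib, level)
      ins <- c(ins, lab)
      pl <- c(pl, col)
      mem <- if (level == "genus") {
        reflib$genus[match(it$taxa, reflib$taxon_id)]
      } else {
        reflib$taxon_name[match(it$taxa, reflib$taxon_id)]
      }
      members[[col]] <- sort(unique(c(members[[col]], mem)))
    }
  }
  w <- make_web(ins, pl, level)
  attr(w, "complex_members") <- members[colnames(w)]
  w
}

# member species names behind each plant column of a web
web_col_members <- function(web, reflib) {
  cm <- attr(web, "complex_members")
  out <- lapply(colnames(web), function(cl) {
    if (!is.null(cm) && !is.null(cm[[cl]])) cm[[cl]] else cl
  })
  names(out) <- colnames(web)
  out
}

overlap_row <- function(shared, obs_only, mol_only, scope, level) {
  total <- shared + obs_only + mol_only
  pct <- function(x) if (total > 0) round_half_up(100 * x / total, 1) else NA_real_
  data.frame(scope = scope, level = level,
             both = shared, obs_only = obs_only, mol_only = mol_only,
             total = total,
             both_pct = pct(shared), obs_only_pct = pct(obs_only),
             mol_only_pct = pct(mol_only),
             stringsAsFactors = FALSE)
}

#' Node and link overlap between observation and molecular webs
#'
#' Computes, at the webs' taxonomic level, the counts and percentages of
#' plant nodes and of links found by both methods (T+M+), only by
#' observation (T+M-), and only by the molecular method (T-M+), in three
#' scopes: plant nodes; links restricted to plant nodes present in both
#' webs; and links over all nodes. A species complex matches an
#' observation species when that species is one of its members.
#'
#' @param obs,mol `bipartite_web` matrices at the same level built from
#'   the same matched larvae.
#' @return data.frame with one row per scope (counts, totals and
#'   percentages to one decimal).
#' @param reflib reference-library taxon table.
#' @export
overlap_tables <- function(obs, mol, reflib) {
  if (!identical(attr(obs, "level"), attr(mol, "level"))) {
    stopf("webs must be built at the same taxonomic level")
  }
  level <- attr(obs, "level")
  mol_members <- web_col_members(mol, reflib)

  # --- plant nodes ---
  obs_nodes <- colnames(obs)
  covered_obs <- obs_nodes[vapply(obs_nodes, function(p) {
    any(vapply(mol_members, function(m) p %in% m, logical(1)))
  }, logical(1))]
  mol_unique <- names(mol_members)[!vapply(mol_members, function(m) {
    any(m %in% obs_nodes)
  }, logical(1))]
  nodes <- overlap_row(length(covered_obs),
                       length(obs_nodes) - length(covered_obs),
                       length(mol_unique), "nodes", level)

  links_of <- function(w) {
    idx <- which(w > 0, arr.ind = TRUE)
    data.frame(insect = rownames(w)[idx[, 1]], plant = colnames(w)[idx[, 2]],
               stringsAsFactors = FALSE)
  }
  obs_links <- links_of(obs)
  mol_links <- links_of(mol)
  link_match <- function(ol, ml) {
    # observation link matches a molecular link of the same insect whose
    # plant node contains the observed species
    vapply(seq_len(nrow(ol)), function(i) {
      hit <- ml$insect == ol$insect[i] &
        vapply(ml$plant, function(p) ol$plant[i] %in% mol_members[[p]],
               logical(1))
      any(hit)
    }, logical(1))
  }
  count_scope <- function(ol, ml, scope) {
    if (!nrow(ol) && !nrow(ml)) return(overlap_row(0, 0, 0, scope, level))
    om <- if (nrow(ol)) link_match(ol, ml) else logical()
    mm <- if (nrow(ml)) vapply(seq_len(nrow(ml)), function(j) {
      any(ol$insect == ml$insect[j] &
            ol$plant %in% mol_members[[ml$plant[j]]])
    }, logical(1)) else logical()
    overlap_row(sum(om), sum(!om), sum(!mm), scope, level)
  }

  all_links <- count_scope(obs_links, mol_links, "links_all_nodes")

  shared_obs <- covered_obs
  mol_shared_cols <- names(mol_members)[vapply(mol_members, function(m) {
    any(m %in% obs_nodes)
  }, logical(1))]
  shared <- count_scope(obs_links[obs_links$plant %in% shared_obs, , drop = FALSE],
                        mol_links[mol_links$plant %in% mol_shared_cols, , drop = FALSE],
                        "links_shared_nodes")
  rbind(nodes, shared, all_links)
}

#' Overlap percentages from printed counts
#'
#' The percentage convention of the overlap tables (count / total,
#' half-up to one decimal), applied directly to counts.
#'
#' @param both,obs_only,mol_only counts of shared / observation-only /
#'   molecular-only nodes or links.
#' @return data.frame with counts, total and percentages.
#' @export
overlap_percentages <- function(both, obs_only, mol_only) {
  overlap_row(both, obs_only, mol_only, scope = "counts", level = NA)
}

#' Read/write an interaction matrix as CSV
#'
#' First column holds insect labels; the header row holds plant labels.
#'
#' @param web a `bipartite_web` matrix.
#' @param path file path.
#' @return `write_web()` returns `path` invisibly; `read_web()` returns
#'   a `bipartite_web`.
#' @export
write_web <- function(web, path) {
  df <- data.frame(insect = rownames(web), as.data.frame(unclass(web)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_web
#' @param level taxonomic level to record on the web read back.
#' @export
read_web <- function(path, level = "species") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  storage.mode(w) <- "integer"
  attr(w, "level") <- level
  class(w) <- c("bipartite_web", class(w))
  w
}

#' Export a web as an edge list
#'
#' @param web a `bipartite_web` matrix.
#' @return data.frame (insect, plant, count) for nonzero cells.
#' @export
web_edgelist <- function(web) {
  idx <- which(web > 0, arr.ind = TRUE)
  data.frame(insect = rownames(web)[idx[, 1]],
             plant = colnames(web)[idx[, 2]],
             count = web[idx],
             stringsAsFactors = FALSE)
}
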