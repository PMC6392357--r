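# Sequence QC, p-distances, OTU delimitation, taxonomy assignment.

#' Expected amplicon lengths per marker
#'
#' Houses the per-marker expected lengths used by the 80%-length QC rule.
#' ITS2 amplicons span a range in practice; its expected length is set to
#' the lower bound of that range so the rule is well defined. COI is
#' configurable because mini-barcodes of various lengths are in use.
#'
#' @param coi_length expected COI length in bp.
#' @return data.frame with columns `marker`, `expected_length_bp`.
#' @export
marker_spec <- function(coi_length = 658) {
  data.frame(
    marker = c("COI", "rbcLa", "trnL", "ITS2"),
    expected_length_bp = c(as.integer(coi_length), 540L, 500L, 350L),
    stringsAsFactors = FALSE
  )
}

#' Length-based quality filter
#'
#' Keeps a sequence iff its ungapped length is at least 80% of the
#' marker's expected length (the boundary is inclusive).
#'
#' @param seq character; nucleotide sequence (gaps `-` allowed).
#' @param marker one of `"COI"`, `"rbcLa"`, `"trnL"`, `"ITS2"`.
#' @param spec a [marker_spec()] table.
#' @param min_frac minimum fraction of expected length.
#' @return Logical: keep (`TRUE`) or drop.
#' @export
qc_filter <- function(seq, marker, spec = marker_spec(), min_frac = 0.8) {
  row <- spec[spec$marker == marker, ]
  if (nrow(row) != 1) stopf("unknown marker '%s'", marker)
  ungapped <- nchar(gsub("-", "", seq, fixed = TRUE))
  ungapped >= min_frac * row$expected_length_bp
}

seq_to_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1]]

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching sites among comparable sites, with pairwise
#' deletion: positions where either sequence has a gap (`-`) or `N` are
#' excluded. No model correction is applied, matching the barcoding
#' convention behind divergence-threshold OTU delimitation.
#'
#' @param a,b aligned sequences of equal length.
#' @return Divergence fraction in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  ca <- seq_to_chars(a)
  cb <- seq_to_chars(b)
  if (length(ca) != length(cb)) {
    stopf("sequences must be aligned to equal length (%d vs %d)",
          length(ca), length(cb))
  }
  ok <- !(ca %in% c("-", "N")) & !(cb %in% c("-", "N"))
  if (!any(ok)) stopf("no comparable sites (all gapped or ambiguous)")
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Pairwise p-distance matrix
#'
#' Vectorized all-against-all [p_distance()] for a set of equal-length
#' aligned sequences.
#'
#' @param seqs named character vector of aligned sequences.
#' @return Symmetric matrix of divergence fractions with zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0) return(matrix(numeric(), 0, 0))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stopf("sequences must share one length")
  m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
              nrow = lens[1], ncol = n)
  valid <- m != "-" & m != "N"
  # pairwise comparable-site and same-base counts via crossproducts of
  # per-symbol indicator matrices (fast BLAS path)
  storage.mode(valid) <- "double"
  comp <- crossprod(valid)
  if (any(comp == 0)) stopf("no comparable sites between some sequences")
  same <- matrix(0, n, n)
  for (b in setdiff(unique(as.vector(m)), c("-", "N"))) {
    xb <- (m == b) * valid
    same <- same + crossprod(xb)
  }
  d <- (comp - same) / comp
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Identity fraction of a query against each reference sequence
#'
#' Matches / comparable sites over the full query, pairwise deletion as
#' in [p_distance()].
#'
#' @param query aligned query sequence.
#' @param refs named character vector of equal-length references.
#' @return Named numeric vector of identity fractions.
#' @export
identity_fractions <- function(query, refs) {
  1 - vapply(refs, function(r) p_distance(query, r), numeric(1))
}

#' Delimit OTUs by agglomerative clustering at a divergence threshold
#'
#' Hierarchical clustering of the p-distance matrix (average linkage by
#' default), cut so that clusters whose linkage height is at most the
#' threshold are merged. OTU labels are assigned deterministically in
#' order of each cluster's lexicographically smallest member id.
#'
#' @param dm symmetric distance matrix with dimnames.
#' @param threshold divergence threshold (default 0.02, i.e. 2%).
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return Named character vector mapping sequence id to OTU id.
#' @export
cluster_otus <- function(dm, threshold = 0.02,
                         linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(dm)
  if (is.null(n) || n == 0) return(character())
  ids <- rownames(dm)
  if (n == 1) return(stats::setNames("OTU0001", ids))
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  cl <- stats::cutree(hc, h = threshold)
  # relabel clusters by smallest member id
  first <- vapply(split(ids, cl), min, character(1))
  ord <- rank(first)
  stats::setNames(sprintf("OTU%04d", ord[as.character(cl)]), ids)
}

#' Assign a taxonomic label to an OTU from ranked reference hits
#'
#' Applies family-consistency rules: the best hit's species label is
#' accepted when its family agrees with the morphological family (or no
#' morphological family is available); otherwise the highest-ranked
#' top-5 hit in the morphological family is used; if none agrees the OTU
#' is discarded as a cross-family conflict. OTUs whose hits fall outside
#' the target order are discarded outright, and best hits below the
#' species-level identity floor yield a family-level label.
#'
#' @param hits data.frame with columns `taxon`, `family`, `order`,
#'   `identity` and optionally `aln_length`; ranked or rankable.
#' @param morph_family optional morphological family.
#' @param target_order taxonomic order retained (default Lepidoptera).
#' @param min_species_identity identity below which only a family-level
#'   label is assigned.
#' @return List with `label`, `family`, `level` and `status` (one of
#'   `accepted`, `discarded_other_family_conflict`,
#'   `discarded_other_order`, `unidentified`).
#' @export
assign_taxonomy <- function(hits, morph_family = NULL,
                            target_order = "Lepidoptera",
                            min_species_identity = 0.95) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(label = NA_character_, family = NA_character_,
                level = NA_character_, status = "unidentified"))
  }
  if (is.null(hits$aln_length)) hits$aln_length <- 0L
  ord <- order(-hits$identity, -hits$aln_length, hits$taxon)
  hits <- hits[ord, , drop = FALSE]
  top5 <- utils::head(hits, 5)
  if (!any(top5$order == target_order)) {
    return(list(label = NA_character_, family = NA_character_,
                level = NA_character_, status = "discarded_other_order"))
  }
  best <- hits[1, ]
  pick <- function(hit) {
    if (hit$identity < min_species_identity) {
      list(label = hit$family, family = hit$family,
           level = "family", status = "accepted")
    } else {
      list(label = hit$taxon, family = hit$family,
           level = "species", status = "accepted")
    }
  }
  if (is.null(morph_family) || is.na(morph_family) ||
      best$family == morph_family) {
    return(pick(best))
  }
  in_fam <- which(top5$family == morph_family)
  if (length(in_fam)) return(pick(top5[in_fam[1], ]))
  list(label = NA_character_, family = morph_family, level = NA_character_,
       status = "discarded_other_family_conflict")
}

#' Search a reference library for the best hits of a query sequence
#'
#' Exact identity-fraction search within the local library (stands in
#' for a remote similarity search): every reference is scored by
#' [identity_fractions()] and returned ranked.
#'
#' @param query aligned query sequence.
#' @param refs named character vector of reference sequences.
#' @param taxonomy data.frame keyed by the names of `refs` with at least
#'   `taxon`, `family`, `order` columns.
#' @param top number of hits to return.
#' @return Ranked data.frame of hits with an `identity` column.
#' @export
reference_hits <- function(query, refs, taxonomy, top = 5) {
  if (!length(refs)) stopf("empty reference library")
  ident <- identity_fractions(query, refs)
  df <- taxonomy[match(names(refs), taxonomy$taxon), , drop = FALSE]
  df$identity <- ident
  df <- df[order(-df$identity, df$taxon), , drop = FALSE]
  utils::head(df, top)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (plain or gzip).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(x, as.character, character(1))), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(seqs), names = names(seqs), file.out = path,
                      nbchar = 70)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm symmetric distance matrix with dimnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(formatC(rownames(dm)[i], width = -10),
                       sprintf("%.6f", dm[i, ])), collapse = "  "), con)
  }
  invisible(path)
}
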