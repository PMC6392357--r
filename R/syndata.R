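# Synthetic community, larva, and barcode-sequence generator.
#
# Emulates the sampling design the analysis assumes: a fully mapped forest
# plot, a subset of focal (fogged) tree species, unsampled nontree taxa
# (bamboos, lianas, bryophytes, parasites), larvae whose true diet is the
# focal tree, a near (<= 2 m) neighbour, a far neighbour, or a nontree
# taxon, per-marker amplification/sequencing failure, and per-taxon
# species-level distinguishability limits (congeneric species complexes).

#' Parameters for the synthetic community generator
#'
#' Defaults mirror the field design the package targets: a 50-ha
#' (1000 x 500 m) mapped plot with 213 tree/shrub species of which 72 are
#' fogged, 15 unsampled nontree taxa, and 2235 larvae. The four diet
#' location probabilities must sum to one; their defaults place a quarter
#' of larvae on their collection tree, with most mismatch coming from far
#' neighbours. Per-marker amplification probabilities are calibrated so
#' per-marker sequence yields keep the rbcLa : trnL : ITS2 ratio of a
#' typical Sanger gut-content study and overall diet recovery lands near
#' 36% of larvae.
#'
#' @param n_tree_species number of mapped tree/shrub species.
#' @param n_sampled_species number of fogged (focal) species; at most
#'   `n_tree_species`.
#' @param n_nontree_taxa number of unsampled nontree taxa (no stems in
#'   the map; diets only).
#' @param plot_width_m,plot_height_m plot dimensions in metres.
#' @param stems_per_species mean number of mapped stems per tree species
#'   (Poisson, truncated so every species keeps at least one stem).
#' @param n_insect_species number of Lepidoptera species.
#' @param n_larvae total number of larvae collected.
#' @param diet_breadth_distribution list; `list(name = "unrestricted")`
#'   (default) lets every insect species feed on any plant, or
#'   `list(name = "poisson", lambda = k)` caps each insect's far-diet
#'   host pool at a drawn breadth.
#' @param p_stay_on_host,p_near_drop,p_far_disperse,p_nontree_diet true
#'   diet location probabilities (focal tree / neighbour within 2 m /
#'   neighbour beyond 2 m / nontree taxon); must sum to 1.
#' @param marker_amplify_prob named per-marker probability that a gut
#'   marker amplifies and is sequenced for a larva.
#' @param p_low_quality probability an amplified sequence is too short
#'   after trimming and fails the 80%-length QC rule.
#' @param p_species_indistinguishable probability a tree species shares
#'   identical plant-marker sequences with a congener (species complex).
#' @param intraspecific_div expected within-species sequence divergence
#'   (fraction of sites) for generated sequences.
#' @param interspecific_div minimum between-species divergence the
#'   generator is expected to honour (random ancestors give far more);
#'   must exceed the OTU threshold for the well-separated regime.
#' @param coi_length length in bp of generated COI sequences.
#' @param point_process `"poisson"` (homogeneous) or `"thomas"`
#'   (clustered) stem placement.
#' @param thomas_sd,thomas_parents cluster spread (m) and mean parents
#'   per species for the Thomas process.
#' @param near_radius_m radius separating near from far neighbours.
#' @param rng_seed integer root seed; all generator randomness derives
#'   from it.
#' @return A validated list of class `community_params`.
#' @export
community_params <- function(n_tree_species = 213,
                             n_sampled_species = 72,
                             n_nontree_taxa = 15,
                             plot_width_m = 1000,
                             plot_height_m = 500,
                             stems_per_species = 20,
                             n_insect_species = 60,
                             n_larvae = 2235,
                             diet_breadth_distribution = list(name = "unrestricted"),
                             p_stay_on_host = 0.25,
                             p_near_drop = 0.11,
                             p_far_disperse = 0.52,
                             p_nontree_diet = 0.12,
                             marker_amplify_prob = c(rbcLa = 0.19, trnL = 0.14, ITS2 = 0.075),
                             p_low_quality = 0.05,
                             p_species_indistinguishable = 0.12,
                             intraspecific_div = 0.004,
                             interspecific_div = 0.03,
                             coi_length = 658,
                             point_process = c("poisson", "thomas"),
                             thomas_sd = 20,
                             thomas_parents = 4,
                             near_radius_m = 2,
                             rng_seed = 1) {
  point_process <- match.arg(point_process)
  p <- list(
    n_tree_species = as.integer(n_tree_species),
    n_sampled_species = as.integer(n_sampled_species),
    n_nontree_taxa = as.integer(n_nontree_taxa),
    plot_width_m = plot_width_m, plot_height_m = plot_height_m,
    stems_per_species = stems_per_species,
    n_insect_species = as.integer(n_insect_species),
    n_larvae = as.integer(n_larvae),
    diet_breadth_distribution = diet_breadth_distribution,
    p_stay_on_host = p_stay_on_host, p_near_drop = p_near_drop,
    p_far_disperse = p_far_disperse, p_nontree_diet = p_nontree_diet,
    marker_amplify_prob = marker_amplify_prob,
    p_low_quality = p_low_quality,
    p_species_indistinguishable = p_species_indistinguishable,
    intraspecific_div = intraspecific_div,
    interspecific_div = interspecific_div,
    coi_length = as.integer(coi_length),
    point_process = point_process,
    thomas_sd = thomas_sd, thomas_parents = thomas_parents,
    near_radius_m = near_radius_m,
    rng_seed = as.integer(rng_seed)
  )
  class(p) <- "community_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  probs <- c(p$p_stay_on_host, p$p_near_drop, p$p_far_disperse, p$p_nontree_diet)
  if (any(probs < 0 | probs > 1)) {
    stopf("diet location probabilities must lie in [0, 1]")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stopf("diet location probabilities must sum to 1 (got %.12f)", sum(probs))
  }
  if (p$n_sampled_species > p$n_tree_species) {
    stopf("n_sampled_species (%d) exceeds n_tree_species (%d)",
          p$n_sampled_species, p$n_tree_species)
  }
  other <- c(p$marker_amplify_prob, p$p_low_quality,
             p$p_species_indistinguishable)
  if (any(other < 0 | other > 1)) stopf("probabilities must lie in [0, 1]")
  if (p$intraspecific_div < 0 || p$intraspecific_div >= 1 ||
      p$interspecific_div < 0 || p$interspecific_div >= 1) {
    stopf("divergence fractions must lie in [0, 1)")
  }
  if (p$n_tree_species < 1 || p$n_larvae < 0 || p$n_insect_species < 1) {
    stopf("community sizes must be positive")
  }
  invisible(p)
}

plant_markers <- function() c("rbcLa", "trnL", "ITS2")

#' Generate a mapped plant community and reference library
#'
#' Creates the plant taxon table (tree species grouped into genera and
#' families, plus unsampled nontree taxa) and a mapped stem layout from a
#' homogeneous Poisson or clustered Thomas point process. Species flagged
#' indistinguishable are paired with a congener with which they will
#' share identical plant-marker sequences.
#'
#' @param params a [community_params()] object.
#' @return A list of class `community` with elements `reflib` (taxon_id,
#'   taxon_name, genus, family, growth_form, sampled, complex_with) and
#'   `stems` (stem_id, taxon_id, x_m, y_m).
#' @export
generate_community <- function(params) {
  stopifnot(inherits(params, "community_params"))
  validate_params(params)
  with_seed(params$rng_seed, {
    nt <- params$n_tree_species
    nn <- params$n_nontree_taxa

    # genus/family scaffolding: ~1.65 species per genus, ~2.15 genera per
    # family, the richness ratios of a diverse subtropical plot
    n_gen <- max(1L, as.integer(round(nt / 1.65)))
    n_fam <- max(1L, as.integer(round(n_gen / 2.15)))
    genus_of <- c(seq_len(min(nt, n_gen)),
                  sample.int(n_gen, max(0L, nt - n_gen), replace = TRUE))
    fam_of_gen <- c(seq_len(min(n_gen, n_fam)),
                    sample.int(n_fam, max(0L, n_gen - n_fam), replace = TRUE))
    genus <- sprintf("Genus%03d", genus_of)
    family <- sprintf("Family%02d", fam_of_gen[genus_of])
    # species epithet index within genus
    epi <- stats::ave(seq_len(nt), genus_of, FUN = seq_along)
    taxon_name <- sprintf("%s sp%02d", genus, epi)

    sampled <- rep(FALSE, nt)
    sampled[sample.int(nt, params$n_sampled_species)] <- TRUE

    reflib <- data.frame(
      taxon_id = sprintf("P%03d", seq_len(nt + nn)),
      taxon_name = c(taxon_name,
                     if (nn) sprintf("NontreeGenus%02d sp01", seq_len(nn)) else character()),
      genus = c(genus, if (nn) sprintf("NontreeGenus%02d", seq_len(nn)) else character()),
      family = c(family, if (nn) sprintf("NontreeFamily%02d", seq_len(nn)) else character()),
      growth_form = c(rep("tree", nt), rep("nontree", nn)),
      sampled = c(sampled, rep(FALSE, nn)),
      complex_with = NA_character_,
      stringsAsFactors = FALSE
    )

    # pair indistinguishable congeners (tree species only)
    if (params$p_species_indistinguishable > 0) {
      for (g in unique(genus_of)) {
        members <- which(genus_of == g)
        while (length(members) >= 2 &&
               stats::runif(1) < params$p_species_indistinguishable * length(members) / 2) {
          pair <- sample(members, 2)
          reflib$complex_with[pair] <- reflib$taxon_id[rev(pair)]
          members <- setdiff(members, pair)
        }
      }
    }

    # stem map (tree species only; nontree taxa are unmapped by design)
    counts <- pmax(1L, stats::rpois(nt, params$stems_per_species))
    xy <- lapply(seq_len(nt), function(i) {
      n <- counts[i]
      if (params$point_process == "poisson") {
        cbind(stats::runif(n, 0, params$plot_width_m),
              stats::runif(n, 0, params$plot_height_m))
      } else {
        npar <- max(1L, stats::rpois(1, params$thomas_parents))
        px <- stats::runif(npar, 0, params$plot_width_m)
        py <- stats::runif(npar, 0, params$plot_height_m)
        k <- sample.int(npar, n, replace = TRUE)
        x <- stats::rnorm(n, px[k], params$thomas_sd) %% params$plot_width_m
        y <- stats::rnorm(n, py[k], params$thomas_sd) %% params$plot_height_m
        cbind(x, y)
      }
    })
    xy <- do.call(rbind, xy)
    stems <- data.frame(
      stem_id = sprintf("S%05d", seq_len(nrow(xy))),
      taxon_id = rep(reflib$taxon_id[seq_len(nt)], counts),
      x_m = xy[, 1], y_m = xy[, 2],
      stringsAsFactors = FALSE
    )
    structure(list(reflib = reflib, stems = stems, params = params),
              class = "community")
  })
}

# distances from one point to every stem
dist_to_stems <- function(x, y, stems) {
  sqrt((stems$x_m - x)^2 + (stems$y_m - y)^2)
}

#' Generate larvae with planted diet ground truth
#'
#' Each larva is assigned a collection stem among fogged species, a true
#' diet drawn by the four-way location probability, and independent
#' per-marker amplification/quality outcomes. Observable fields and
#' ground truth are returned separately: larva records carry no truth.
#'
#' Larvae whose planted class is "near" draw their collection stem from
#' stems that actually have a heterospecific neighbour within the near
#' radius, and far diets are drawn among species whose nearest stem lies
#' beyond it, so the planted class always agrees with the realized stem
#' geometry.
#'
#' @param params a [community_params()] object.
#' @param reflib,stems community tables from [generate_community()].
#' @return List with `larvae` (larva_id, collection stem/taxon,
#'   coordinates, body size, per-marker outcome) and `truth` (true insect
#'   species, diet taxon, diet class, per-marker amplification).
#' @export
generate_larvae <- function(params, reflib, stems) {
  stopifnot(inherits(params, "community_params"))
  with_seed(derive_seed(params$rng_seed, 1000003L), {
    n <- params$n_larvae
    markers <- plant_markers()
    tree <- reflib[reflib$growth_form == "tree", ]
    nontree_ids <- reflib$taxon_id[reflib$growth_form == "nontree"]
    sampled_ids <- reflib$taxon_id[reflib$sampled]
    focal_stems <- stems[stems$taxon_id %in% sampled_ids, ]
    if (nrow(focal_stems) == 0) stopf("no stems of sampled species")
    if (params$p_nontree_diet > 0 && !length(nontree_ids)) {
      stopf("p_nontree_diet > 0 but no nontree taxa in the community")
    }

    # insect community: lognormal relative loads
    insects <- sprintf("Insect%03d", seq_len(params$n_insect_species))
    load <- stats::rlnorm(params$n_insect_species, 0, 1)
    breadth_cfg <- params$diet_breadth_distribution
    host_pool <- NULL
    if (!identical(breadth_cfg$name %||% "unrestricted", "unrestricted")) {
      lam <- breadth_cfg$lambda %||% 5
      host_pool <- lapply(seq_along(insects), function(i) {
        b <- min(nrow(tree), max(1L, stats::rpois(1, lam)))
        sample(tree$taxon_id, b)
      })
      names(host_pool) <- insects
    }

    # precompute, per focal stem, its near-neighbour species and the
    # species whose nearest stem is beyond the near radius
    near_sets <- vector("list", nrow(focal_stems))
    far_sets <- vector("list", nrow(focal_stems))
    for (i in seq_len(nrow(focal_stems))) {
      d <- dist_to_stems(focal_stems$x_m[i], focal_stems$y_m[i], stems)
      within <- d <= params$near_radius_m
      near_tax <- setdiff(unique(stems$taxon_id[within]), focal_stems$taxon_id[i])
      near_sets[[i]] <- near_tax
      far_sets[[i]] <- setdiff(tree$taxon_id,
                               c(unique(stems$taxon_id[within]), focal_stems$taxon_id[i]))
    }
    has_near <- lengths(near_sets) > 0
    if (params$p_near_drop > 0 && !any(has_near)) {
      stopf("no focal stem has a neighbour within %.1f m; increase stem density",
            params$near_radius_m)
    }

    classes <- c("focal", "near", "far", "nontree")
    cls <- sample(classes, n, replace = TRUE,
                  prob = c(params$p_stay_on_host, params$p_near_drop,
                           params$p_far_disperse, params$p_nontree_diet))
    insect <- sample(insects, n, replace = TRUE, prob = load)

    stem_idx <- integer(n)
    diet <- character(n)
    near_ok <- which(has_near)
    for (i in seq_len(n)) {
      if (cls[i] == "near") {
        s <- if (length(near_ok) == 1) near_ok else sample(near_ok, 1)
        pool <- near_sets[[s]]
      } else {
        s <- sample.int(nrow(focal_stems), 1)
        pool <- switch(cls[i],
          focal = focal_stems$taxon_id[s],
          far = far_sets[[s]],
          nontree = nontree_ids
        )
        if (cls[i] == "far" && !is.null(host_pool)) {
          restricted <- intersect(pool, host_pool[[insect[i]]])
          if (length(restricted)) pool <- restricted
        }
      }
      stem_idx[i] <- s
      diet[i] <- if (length(pool) == 1) pool else sample(pool, 1)
    }

    amp <- sapply(markers, function(m) {
      stats::runif(n) < params$marker_amplify_prob[[m]]
    })
    lowq <- matrix(stats::runif(n * length(markers)) < params$p_low_quality,
                   n, dimnames = list(NULL, markers))
    outcome <- matrix("no_amplification", n, length(markers),
                      dimnames = list(NULL, markers))
    outcome[amp & !lowq] <- "sequence"
    outcome[amp & lowq] <- "discarded_low_quality"

    larvae <- data.frame(
      larva_id = sprintf("L%04d", seq_len(n)),
      collection_stem = focal_stems$stem_id[stem_idx],
      collection_taxon = focal_stems$taxon_id[stem_idx],
      x_m = focal_stems$x_m[stem_idx],
      y_m = focal_stems$y_m[stem_idx],
      body_size_mm = round(stats::rlnorm(n, log(8), 0.5), 1),
      stringsAsFactors = FALSE
    )
    for (m in markers) larvae[[paste0("marker_", m)]] <- outcome[, m]

    truth <- data.frame(
      larva_id = larvae$larva_id,
      insect_species = insect,
      diet_taxon = diet,
      diet_class = cls,
      stringsAsFactors = FALSE
    )
    for (m in markers) truth[[paste0("amplified_", m)]] <- amp[, m]
    list(larvae = larvae, truth = truth)
  })
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# replace the tail of a sequence with gaps so its ungapped length falls
# below the QC threshold (models a low-quality truncated read)
truncate_seq <- function(seq, keep_frac = 0.6) {
  len <- nchar(seq)
  keep <- max(1L, as.integer(floor(len * keep_frac)))
  paste0(substr(seq, 1, keep), strrep("-", len - keep))
}

#' Generate toy barcode sequences for a synthetic community
#'
#' Plant reference sequences are independent uniform-random ancestors per
#' taxon per marker (so heterospecific divergence is far above any OTU
#' threshold), with indistinguishable congeners sharing byte-identical
#' plant-marker sequences. When larvae and ground truth are supplied,
#' per-larva COI sequences (species ancestor plus i.i.d. substitutions)
#' and gut marker sequences (true diet taxon's reference plus
#' substitutions; low-quality reads gap-truncated) are generated too.
#'
#' @param community a [generate_community()] result (or its `reflib`).
#' @param larvae,truth optional tables from [generate_larvae()].
#' @param intraspecific_div expected conspecific divergence fraction.
#' @param seed integer seed.
#' @param coi_length COI sequence length in bp.
#' @return List with `ref` (named character vectors per plant marker,
#'   names = taxon ids), and when larvae are given `coi` (per larva) and
#'   `gut` (per marker, named by larva id).
#' @export
generate_sequences <- function(community, larvae = NULL, truth = NULL,
                               intraspecific_div = 0.004, seed = 1,
                               coi_length = 658) {
  reflib <- if (inherits(community, "community")) community$reflib else community
  if (intraspecific_div < 0 || intraspecific_div >= 1) {
    stopf("divergence fractions must lie in [0, 1)")
  }
  with_seed(seed, {
    lens <- marker_spec()$expected_length_bp
    names(lens) <- marker_spec()$marker
    ref <- lapply(plant_markers(), function(m) {
      s <- vapply(seq_len(nrow(reflib)), function(i) random_seq(lens[[m]]),
                  character(1))
      names(s) <- reflib$taxon_id
      # complexes share identical sequences: copy from the partner with
      # the smaller taxon id so the copy direction is well defined
      paired <- which(!is.na(reflib$complex_with))
      for (i in paired) {
        j <- match(reflib$complex_with[i], reflib$taxon_id)
        if (reflib$taxon_id[j] < reflib$taxon_id[i]) s[i] <- s[j]
      }
      s
    })
    names(ref) <- plant_markers()
    out <- list(ref = ref)

    if (!is.null(larvae)) {
      stopifnot(!is.null(truth), identical(larvae$larva_id, truth$larva_id))
      rate <- intraspecific_div / 2
      insects <- sort(unique(truth$insect_species))
      anc <- vapply(insects, function(i) random_seq(coi_length), character(1))
      coi <- vapply(seq_len(nrow(larvae)), function(i) {
        mutate_seq(anc[[truth$insect_species[i]]], rate)
      }, character(1))
      names(coi) <- larvae$larva_id
      gut <- lapply(plant_markers(), function(m) {
        keep <- larvae[[paste0("marker_", m)]] != "no_amplification"
        idx <- which(keep)
        s <- vapply(idx, function(i) {
          q <- mutate_seq(ref[[m]][[truth$diet_taxon[i]]], rate)
          if (larvae[[paste0("marker_", m)]][i] == "discarded_low_quality") {
            q <- truncate_seq(q)
          }
          q
        }, character(1))
        names(s) <- larvae$larva_id[idx]
        s
      })
      names(gut) <- plant_markers()
      out$coi <- coi
      out$gut <- gut
    }
    out
  })
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates [generate_community()], [generate_larvae()] and
#' [generate_sequences()] under a single root seed.
#'
#' @param params a [community_params()] object.
#' @return List of class `syndata` with `params`, `reflib`, `stems`,
#'   `larvae`, `truth` and `seqs`.
#' @export
simulate_dataset <- function(params = community_params()) {
  comm <- generate_community(params)
  lv <- generate_larvae(params, comm$reflib, comm$stems)
  seqs <- generate_sequences(comm, lv$larvae, lv$truth,
                             intraspecific_div = params$intraspecific_div,
                             seed = derive_seed(params$rng_seed, 2000003L),
                             coi_length = params$coi_length)
  structure(list(params = params, reflib = comm$reflib, stems = comm$stems,
                 larvae = lv$larvae, truth = lv$truth, seqs = seqs),
            class = "syndata")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits one FASTA per plant marker (reference library and gut reads),
#' a larval COI FASTA, and CSV tables (stems, larvae, reference library,
#' ground truth) plus the parameters echoed to JSON.
#'
#' @param sim a [simulate_dataset()] result.
#' @param outdir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(sim, outdir) {
  stopifnot(inherits(sim, "syndata"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(x, name) {
    path <- file.path(outdir, name)
    utils::write.csv(x, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(sim$reflib, "reflib.csv")
  wr(sim$stems, "stems.csv")
  wr(sim$larvae, "larvae.csv")
  wr(sim$truth, "ground_truth.csv")
  for (m in names(sim$seqs$ref)) {
    path <- file.path(outdir, sprintf("ref_%s.fasta", m))
    write_fasta(sim$seqs$ref[[m]], path)
    files <- c(files, path)
    if (!is.null(sim$seqs$gut) && length(sim$seqs$gut[[m]])) {
      path <- file.path(outdir, sprintf("gut_%s.fasta", m))
      write_fasta(sim$seqs$gut[[m]], path)
      files <- c(files, path)
    }
  }
  if (!is.null(sim$seqs$coi)) {
    path <- file.path(outdir, "larvae_COI.fasta")
    write_fasta(sim$seqs$coi, path)
    files <- c(files, path)
  }
  path <- file.path(outdir, "params.json")
  jsonlite::write_json(unclass(sim$params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, path)
  invisible(files)
}
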