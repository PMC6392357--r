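# Shared fixtures, built in code at test time.

# A small, fast community configuration for pipeline-level tests.
small_params <- function(seed = 1, ...) {
  args <- list(
    n_tree_species = 40, n_sampled_species = 25, n_nontree_taxa = 5,
    stems_per_species = 30, n_insect_species = 12, n_larvae = 400,
    coi_length = 300, rng_seed = seed
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(community_params, args)
}

# A minimal hand-built reference library with two congeners, a second
# genus, a second family, and one nontree taxon.
toy_reflib <- function() {
  data.frame(
    taxon_id = c("P001", "P002", "P003", "P004", "P005"),
    taxon_name = c("Genus001 sp01", "Genus001 sp02", "Genus002 sp01",
                   "Genus003 sp01", "NontreeGenus01 sp01"),
    genus = c("Genus001", "Genus001", "Genus002", "Genus003",
              "NontreeGenus01"),
    family = c("Family01", "Family01", "Family01", "Family02",
               "NontreeFamily01"),
    growth_form = c("tree", "tree", "tree", "tree", "nontree"),
    sampled = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    complex_with = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Stems laid out on a line so near/far distances are exact by hand:
# collection stem of P001 at x = 0; P002 at 1.4 m; P003 at 3.7 m;
# P004 at 50 m.
toy_stems <- function() {
  data.frame(
    stem_id = c("S1", "S2", "S3", "S4"),
    taxon_id = c("P001", "P002", "P003", "P004"),
    x_m = c(0, 1.4, 3.7, 50),
    y_m = c(0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

toy_larva <- function() {
  data.frame(larva_id = "L1", collection_stem = "S1",
             collection_taxon = "P001", x_m = 0, y_m = 0,
             body_size_mm = 8, stringsAsFactors = FALSE)
}

diet_item <- function(taxa, reflib = toy_reflib(), markers = "rbcLa") {
  list(taxa = taxa,
       level = barcoweb:::item_level(taxa, reflib),
       nontree = barcoweb:::item_nontree(taxa, reflib),
       markers = markers)
}

diet_call <- function(...) {
  structure(list(items = list(...)), class = "diet_call")
}
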