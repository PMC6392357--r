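# Diet identification and resolution scoring.

test_that("marker resolution returns maximal-identity candidate sets", {
  refs <- c(P001 = "ACGTACGTAC", P002 = "ACGTACGTAG", P003 = "TTTTACGTAC")
  # exact match to one species
  r <- resolve_marker("ACGTACGTAC", refs)
  expect_identical(r$outcome, "sequence")
  expect_identical(r$candidates, "P001")
  expect_equal(r$identity, 1)
  # two identical references form a species complex
  refs2 <- c(refs, P004 = "ACGTACGTAC")
  r <- resolve_marker("ACGTACGTAC", refs2)
  expect_identical(r$candidates, c("P001", "P004"))
  # equidistant query keeps both candidates
  r <- resolve_marker("ACGTACGTAT", refs[1:2], min_identity = 0.85)
  expect_identical(r$candidates, c("P001", "P002"))
  expect_equal(r$identity, 0.9)
  # identity floor
  r <- resolve_marker("TTTTTTTTTT", refs, min_identity = 0.95)
  expect_identical(r$outcome, "unidentified")
  expect_length(r$candidates, 0)
  expect_error(resolve_marker("ACGT", character()), "empty reference")
})

test_that("marker combination intersects overlapping candidate sets", {
  reflib <- toy_reflib()
  mk <- function(marker, cand) {
    list(marker = marker, outcome = "sequence", candidates = cand,
         identity = 1)
  }
  # intersection sharpens to species
  call <- combine_markers(list(mk("rbcLa", c("P001", "P002")),
                               mk("ITS2", "P001")), reflib)
  expect_length(call$items, 1)
  expect_identical(call$items[[1]]$taxa, "P001")
  expect_identical(call$items[[1]]$level, "species")
  expect_setequal(call$items[[1]]$markers, c("rbcLa", "ITS2"))
  # disjoint sets make two diet items
  call <- combine_markers(list(mk("rbcLa", "P001"), mk("trnL", "P003")),
                          reflib)
  expect_length(call$items, 2)
  # single marker kept as-is
  call <- combine_markers(list(mk("trnL", c("P001", "P002"))), reflib)
  expect_identical(call$items[[1]]$taxa, c("P001", "P002"))
  expect_identical(call$items[[1]]$level, "genus")
  # all markers failed: empty call
  failed <- list(marker = "rbcLa", outcome = "discarded_low_quality",
                 candidates = character(), identity = NA_real_)
  expect_length(combine_markers(list(failed), reflib)$items, 0)
})

test_that("resolution scores follow the local-distinguishability rule", {
  reflib <- toy_reflib()
  # singleton species: fully resolved everywhere
  it <- diet_item("P001")
  expect_equal(score_resolution(it, reflib, "species"), 1)
  expect_equal(score_resolution(it, reflib, "genus"), 1)
  expect_equal(score_resolution(it, reflib, "family"), 1)
  # congeneric two-species complex: 0 / 1 / 1
  it <- diet_item(c("P001", "P002"))
  expect_equal(score_resolution(it, reflib, "species"), 0)
  expect_equal(score_resolution(it, reflib, "genus"), 1)
  expect_equal(score_resolution(it, reflib, "family"), 1)
  # confamilial cross-genus ambiguity: 0 / 0 / 1
  it <- diet_item(c("P001", "P003"))
  expect_equal(score_resolution(it, reflib, "species"), 0)
  expect_equal(score_resolution(it, reflib, "genus"), 0)
  expect_equal(score_resolution(it, reflib, "family"), 1)
  # nontree taxon: conservative 0.5 at species, resolvable above
  it <- diet_item("P005")
  expect_equal(score_resolution(it, reflib, "species"), 0.5)
  expect_equal(score_resolution(it, reflib, "genus"), 1)
})

test_that("resolution summary averages over diet individuals", {
  reflib <- toy_reflib()
  mk <- function(cand) list(marker = "rbcLa", outcome = "sequence",
                            candidates = cand, identity = 1)
  entry <- function(cand) {
    list(marker_results = list(rbcLa = mk(cand)),
         call = combine_markers(list(mk(cand)), reflib))
  }
  # three individuals with species scores 1, 0.5, 0 -> mean 50%
  resolved <- list(L1 = entry("P001"), L2 = entry("P005"),
                   L3 = entry(c("P001", "P002")))
  s <- resolution_summary(resolved, reflib)
  expect_equal(s$species_pct[s$marker == "rbcLa"], 50)
  expect_equal(s$family_pct[s$marker == "rbcLa"], 100)
  expect_equal(s$n_sequences[s$marker == "rbcLa"], 3L)

  # individual weighting: one ambiguous + ten resolved individuals
  resolved10 <- c(list(L0 = entry(c("P001", "P002"))),
                  setNames(replicate(10, entry("P003"), simplify = FALSE),
                           paste0("L", 1:10)))
  s10 <- resolution_summary(resolved10, reflib)
  expect_equal(s10$species_pct[s10$marker == "rbcLa"],
               round_half_up(100 * 10 / 11, 1))

  # fully resolved individuals give 100% at every level
  allres <- list(L1 = entry("P001"), L2 = entry("P003"))
  sall <- resolution_summary(allres, reflib)
  expect_true(all(sall[sall$marker %in% c("rbcLa", "combined"),
                       c("family_pct", "genus_pct", "species_pct")] == 100))
})

test_that("combined markers never resolve worse than a single cpDNA marker", {
  p <- small_params(seed = 37, n_larvae = 300,
                    p_species_indistinguishable = 0.6,
                    marker_amplify_prob = c(rbcLa = 0.9, trnL = 0.6,
                                            ITS2 = 0.6))
  sim <- simulate_dataset(p)
  resolved <- resolve_diets(sim$larvae, sim$seqs$gut, sim$seqs$ref,
                            sim$reflib)
  # restrict the comparison to larvae with an rbcLa sequence and a
  # single-item combined call (intersection can only shrink the set)
  score <- function(taxa) {
    it <- list(taxa = taxa, nontree = barcoweb:::item_nontree(taxa, sim$reflib))
    score_resolution(it, sim$reflib, "species")
  }
  n <- 0
  for (r in resolved) {
    mr <- r$marker_results[["rbcLa"]]
    if (is.null(mr) || !identical(mr$outcome, "sequence")) next
    if (length(r$call$items) != 1) next
    n <- n + 1
    expect_gte(score(r$call$items[[1]]$taxa), score(mr$candidates))
  }
  expect_gt(n, 20)
})

test_that("recovery rate arithmetic reports one-decimal percentages", {
  expect_equal(diet_recovery(1, 3), 33.3)
  expect_error(diet_recovery(1, 0), "positive")
})
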