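# QC rule, p-distances, OTU clustering, taxonomy assignment.

test_that("length QC keeps sequences at or above 80% of expected length", {
  rbcla_432 <- strrep("A", 432)  # exactly 0.8 * 540
  expect_true(qc_filter(rbcla_432, "rbcLa"))
  expect_false(qc_filter(strrep("A", 300), "rbcLa"))
  expect_true(qc_filter(strrep("G", 280), "ITS2"))   # 0.8 * 350 boundary
  expect_false(qc_filter(strrep("G", 279), "ITS2"))
  # gaps do not count toward length
  expect_false(qc_filter(paste0(strrep("A", 300), strrep("-", 200)), "trnL"))
  expect_error(qc_filter("ACGT", "16S"), "unknown marker")
})

test_that("p-distance uses pairwise deletion of gaps and Ns", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)   # 3 comparable, 0 mismatch
  expect_equal(p_distance("ANGT", "ACCT"), 1 / 3)
  expect_error(p_distance("ACG", "ACGT"), "equal length")
  expect_error(p_distance("----", "ACGT"), "comparable")
})

test_that("distance matrix agrees with pairwise calls and with ape", {
  skip_if_not_installed("ape")
  set.seed(4)
  seqs <- replicate(10, paste(
    sample(c("A", "C", "G", "T", "-", "N"), 60, replace = TRUE,
           prob = c(0.22, 0.22, 0.22, 0.22, 0.06, 0.06)), collapse = ""))
  names(seqs) <- paste0("s", 1:10)
  dm <- p_distance_matrix(seqs)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  for (k in 1:10) {
    i <- sample(10, 1)
    j <- sample(setdiff(1:10, i), 1)
    expect_equal(dm[i, j], p_distance(seqs[[i]], seqs[[j]]))
  }
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm), unname(ref[names(seqs), names(seqs)]),
               tolerance = 1e-12)
})

test_that("OTU delimitation matches simple threshold cases", {
  d2 <- matrix(c(0, 0.01, 0.01, 0), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_length(unique(cluster_otus(d2)), 1)
  d2[1, 2] <- d2[2, 1] <- 0.03
  expect_length(unique(cluster_otus(d2)), 2)

  # AB merge at 0.015, then AB-C average 0.0225 > 0.02 keeps C apart
  d3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d3["A", "B"] <- d3["B", "A"] <- 0.015
  d3["B", "C"] <- d3["C", "B"] <- 0.015
  d3["A", "C"] <- d3["C", "A"] <- 0.030
  cl <- cluster_otus(d3)
  expect_identical(cl[["A"]], cl[["B"]])
  expect_false(cl[["C"]] == cl[["A"]])

  expect_identical(cluster_otus(matrix(numeric(), 0, 0)), character())
})

test_that("clustering equals the brute-force average-linkage oracle", {
  set.seed(9)
  for (k in 1:40) {
    n <- sample(3:8, 1)
    dm <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
    vals <- runif(n * (n - 1) / 2, 0, 0.06)
    dm[lower.tri(dm)] <- vals
    dm <- dm + t(dm)
    mine <- cluster_otus(dm, threshold = 0.02)
    oracle <- avg_linkage_oracle(dm, threshold = 0.02)
    expect_true(same_partition(mine, oracle), info = paste("case", k))
  }
})

test_that("raising the threshold never increases the OTU count", {
  set.seed(13)
  n <- 12
  dm <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  vals <- runif(n * (n - 1) / 2, 0, 0.08)
  dm[lower.tri(dm)] <- vals
  dm <- dm + t(dm)
  counts <- vapply(c(0.005, 0.01, 0.02, 0.04, 0.08),
                   function(th) length(unique(cluster_otus(dm, th))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("OTU count equals planted species count on well-separated data", {
  p <- small_params(seed = 19, n_larvae = 150)
  sim <- simulate_dataset(p)
  cl <- cluster_otus(p_distance_matrix(sim$seqs$coi))
  expect_equal(length(unique(cl)),
               length(unique(sim$truth$insect_species)))
  # and the OTU partition matches the planted species partition
  expect_true(same_partition(
    cl, setNames(sim$truth$insect_species, sim$truth$larva_id)[names(cl)]))
})

test_that("taxonomy assignment follows the family-consistency rules", {
  hits <- data.frame(
    taxon = c("Species X", "Species Y", "Species Z", "Species W", "Species V"),
    family = c("Geometridae", "Noctuidae", "Geometridae", "Erebidae",
               "Noctuidae"),
    order = "Lepidoptera",
    identity = c(0.99, 0.985, 0.98, 0.97, 0.96),
    stringsAsFactors = FALSE
  )
  # consistent best hit
  res <- assign_taxonomy(hits, morph_family = "Geometridae")
  expect_identical(res$label, "Species X")
  expect_identical(res$status, "accepted")
  # no morphological family: best hit wins
  expect_identical(assign_taxonomy(hits)$label, "Species X")
  # best-hit family conflicts; highest-ranked hit in the morph family wins
  res <- assign_taxonomy(hits, morph_family = "Noctuidae")
  expect_identical(res$label, "Species Y")
  # nothing in the top 5 matches the morphological family
  res <- assign_taxonomy(hits, morph_family = "Limacodidae")
  expect_identical(res$status, "discarded_other_family_conflict")
  # hits outside the target order are discarded
  beetle <- transform(hits, order = "Coleoptera")
  expect_identical(assign_taxonomy(beetle)$status, "discarded_other_order")
  # low identity only supports a family-level label
  weak <- transform(hits, identity = identity - 0.1)
  res <- assign_taxonomy(weak)
  expect_identical(res$level, "family")
  expect_identical(res$label, "Geometridae")
  # empty hit list
  expect_identical(assign_taxonomy(hits[0, ])$status, "unidentified")
})

test_that("fasta round-trip preserves sequences and phylip output parses", {
  seqs <- c(a = "ACGTACGT", b = "ACGT-CGT")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)
  dm <- p_distance_matrix(c(a = "ACGT", b = "ACGA"))
  pf <- withr::local_tempfile(fileext = ".phy")
  write_phylip(dm, pf)
  lines <- readLines(pf)
  expect_equal(as.integer(trimws(lines[1])), 2L)
  expect_length(lines, 3)
})
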