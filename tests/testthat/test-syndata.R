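# Synthetic community / larva / sequence generator.

test_that("parameter validation rejects malformed inputs", {
  expect_error(community_params(p_stay_on_host = 0.5, p_near_drop = 0.5,
                                p_far_disperse = 0.5, p_nontree_diet = 0),
               "sum to 1")
  expect_error(community_params(p_stay_on_host = -0.1, p_near_drop = 0.4,
                                p_far_disperse = 0.5, p_nontree_diet = 0.2),
               "\\[0, 1\\]")
  expect_error(community_params(n_tree_species = 5, n_sampled_species = 6),
               "exceeds")
  expect_error(community_params(intraspecific_div = 1.2), "\\[0, 1\\)")
})

test_that("generation is byte-identical under a fixed seed", {
  p <- small_params(seed = 11)
  sim1 <- simulate_dataset(p)
  sim2 <- simulate_dataset(p)
  expect_identical(sim1, sim2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(sim1, d1)
  write_dataset(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("community respects bounds, stems and sampled flags", {
  p <- small_params(seed = 3)
  comm <- generate_community(p)
  expect_true(all(comm$stems$x_m >= 0 & comm$stems$x_m <= p$plot_width_m))
  expect_true(all(comm$stems$y_m >= 0 & comm$stems$y_m <= p$plot_height_m))
  # every tree species keeps at least one stem; nontree taxa are unmapped
  tree_ids <- comm$reflib$taxon_id[comm$reflib$growth_form == "tree"]
  expect_setequal(unique(comm$stems$taxon_id), tree_ids)
  expect_true(all(!comm$reflib$sampled[comm$reflib$growth_form == "nontree"]))
  expect_equal(sum(comm$reflib$sampled), p$n_sampled_species)
})

test_that("degenerate diet settings behave as configured", {
  p_stay <- small_params(seed = 5, p_stay_on_host = 1, p_near_drop = 0,
                         p_far_disperse = 0, p_nontree_diet = 0)
  comm <- generate_community(p_stay)
  lv <- generate_larvae(p_stay, comm$reflib, comm$stems)
  expect_identical(lv$truth$diet_taxon, lv$larvae$collection_taxon)
  expect_true(all(lv$truth$diet_class == "focal"))

  p_non <- small_params(seed = 5, p_stay_on_host = 0, p_near_drop = 0,
                        p_far_disperse = 0, p_nontree_diet = 1)
  lvn <- generate_larvae(p_non, comm$reflib, comm$stems)
  nontree_ids <- comm$reflib$taxon_id[comm$reflib$growth_form == "nontree"]
  expect_true(all(lvn$truth$diet_taxon %in% nontree_ids))

  # no nontree taxa and zero nontree probability: no nontree diets possible
  p0 <- small_params(seed = 5, n_nontree_taxa = 0, p_stay_on_host = 0.3,
                     p_near_drop = 0.1, p_far_disperse = 0.6,
                     p_nontree_diet = 0)
  comm0 <- generate_community(p0)
  lv0 <- generate_larvae(p0, comm0$reflib, comm0$stems)
  expect_true(all(lv0$truth$diet_class != "nontree"))
})

test_that("planted class frequencies match configuration within 3 sigma", {
  probs <- c(focal = 0.25, near = 0.11, far = 0.52, nontree = 0.12)
  p <- small_params(seed = 17, n_larvae = 2000,
                    p_stay_on_host = probs[["focal"]],
                    p_near_drop = probs[["near"]],
                    p_far_disperse = probs[["far"]],
                    p_nontree_diet = probs[["nontree"]])
  comm <- generate_community(p)
  lv <- generate_larvae(p, comm$reflib, comm$stems)
  freq <- table(factor(lv$truth$diet_class, levels = names(probs))) / 2000
  for (k in names(probs)) {
    sigma <- sqrt(probs[[k]] * (1 - probs[[k]]) / 2000)
    expect_lt(abs(freq[[k]] - probs[[k]]), 3 * sigma)
  }
})

test_that("ground-truth class agrees with realized stem geometry", {
  p <- small_params(seed = 23, n_larvae = 300)
  comm <- generate_community(p)
  lv <- generate_larvae(p, comm$reflib, comm$stems)
  st <- comm$stems
  for (i in sample.int(nrow(lv$larvae), 60)) {
    la <- lv$larvae[i, ]
    tr <- lv$truth[i, ]
    if (tr$diet_class == "nontree") next
    sub <- st[st$taxon_id == tr$diet_taxon, ]
    dmin <- min(sqrt((sub$x_m - la$x_m)^2 + (sub$y_m - la$y_m)^2))
    expected <- switch(tr$diet_class,
      focal = TRUE,  # collection stem itself is at distance zero
      near = dmin <= p$near_radius_m && tr$diet_taxon != la$collection_taxon,
      far = dmin > p$near_radius_m
    )
    expect_true(expected, info = sprintf("larva %s class %s dmin %.2f",
                                         la$larva_id, tr$diet_class, dmin))
  }
})

test_that("Poisson stem map matches the closed-form nearest-neighbour mean", {
  # mean NN distance for a homogeneous Poisson process is 1/(2*sqrt(lambda));
  # measured with the minimum-image convention so the closed form is exact
  p <- community_params(n_tree_species = 100, n_sampled_species = 50,
                        stems_per_species = 20, rng_seed = 1)
  means <- vapply(1:20, function(r) {
    pr <- p
    pr$rng_seed <- r
    comm <- generate_community(pr)
    mean_nn_torus(comm$stems$x_m, comm$stems$y_m,
                  p$plot_width_m, p$plot_height_m)
  }, numeric(1))
  lambda_mean <- 100 * 20 / (p$plot_width_m * p$plot_height_m)
  expect_lt(abs(mean(means) - 0.5 / sqrt(lambda_mean)) /
              (0.5 / sqrt(lambda_mean)), 0.05)
})

test_that("generated sequences honour the divergence regimes", {
  p <- small_params(seed = 31, n_larvae = 60)
  sim <- simulate_dataset(p)
  coi <- sim$seqs$coi
  sp <- sim$truth$insect_species[match(names(coi), sim$truth$larva_id)]
  # all conspecific pairs below the OTU threshold, heterospecific far above
  idx <- sample(length(coi), 30)
  for (i in idx[1:15]) {
    j <- which(sp == sp[i])
    j <- j[j != i][1]
    if (is.na(j)) next
    expect_lt(p_distance(coi[[i]], coi[[j]]), 0.02)
  }
  for (i in idx) {
    j <- which(sp != sp[i])[1]
    expect_gte(p_distance(coi[[i]], coi[[j]]), 0.03)
  }

  # zero intraspecific divergence means identical conspecific sequences
  comm <- generate_community(p)
  lv <- generate_larvae(p, comm$reflib, comm$stems)
  s0 <- generate_sequences(comm, lv$larvae, lv$truth,
                           intraspecific_div = 0, seed = 2, coi_length = 120)
  sp0 <- lv$truth$insect_species[match(names(s0$coi), lv$truth$larva_id)]
  one <- split(s0$coi, sp0)[[1]]
  expect_true(all(one == one[[1]]))
})

test_that("indistinguishable congeners share byte-identical marker sequences", {
  p <- small_params(seed = 41, p_species_indistinguishable = 0.9)
  comm <- generate_community(p)
  paired <- which(!is.na(comm$reflib$complex_with))
  expect_gt(length(paired), 0)
  seqs <- generate_sequences(comm, seed = 7)
  i <- paired[1]
  j <- match(comm$reflib$complex_with[i], comm$reflib$taxon_id)
  for (m in c("rbcLa", "trnL", "ITS2")) {
    expect_identical(seqs$ref[[m]][[i]], seqs$ref[[m]][[j]])
  }
  # partners are congeners
  expect_identical(comm$reflib$genus[i], comm$reflib$genus[j])
})
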