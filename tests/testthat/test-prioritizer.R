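make_coords <- function(genes, chrom = "chr1", spacing = 1000) {
  data.frame(gene = genes, chrom = chrom,
             start = seq_along(genes) * spacing,
             end = seq_along(genes) * spacing + 100,
             midpoint = seq_along(genes) * spacing + 50)
}

test_that("linkage intervals pick the 99 nearest eligible genes", {
  genes <- sprintf("g%03d", 1:200)
  coords <- make_coords(genes)
  target <- "g100"
  iv <- build_linkage_interval(target, coords, seed_set = character(0),
                               universe = genes)
  expect_length(iv$candidates, 100)
  expect_identical(iv$candidates[1], target)
  # brute-force distance sort oracle
  dist <- abs(coords$midpoint - coords$midpoint[coords$gene == target])
  names(dist) <- genes
  oracle <- names(sort(dist[setdiff(genes, target)]))[1:99]
  expect_setequal(iv$candidates[-1], oracle)
  # roughly centered around the target
  idx <- as.integer(sub("g", "", iv$candidates[-1]))
  expect_true(sum(idx < 100) %in% 49:50)
})

test_that("linkage intervals exclude seed genes and validate inputs", {
  genes <- sprintf("g%03d", 1:120)
  coords <- make_coords(genes)
  seed_set <- c("g059", "g061")                 # adjacent to the target
  iv <- build_linkage_interval("g060", coords, seed_set, genes)
  expect_false(any(seed_set %in% iv$candidates))

  # exactly 99 eligible neighbours are all selected
  genes2 <- sprintf("h%03d", 1:100)
  iv2 <- build_linkage_interval("h050", make_coords(genes2),
                                character(0), genes2)
  expect_setequal(iv2$candidates, genes2)

  expect_error(build_linkage_interval("g001", coords, character(0),
                                      genes[1:50]),
               class = "gcnprio_validation")
  expect_error(build_linkage_interval("absent", coords, character(0), genes),
               class = "gcnprio_validation")
})

test_that("cross-chromosome fill only engages when a chromosome runs short", {
  genes <- sprintf("g%03d", 1:150)
  coords <- make_coords(genes)
  coords$chrom <- rep(c("chr1", "chr2"), c(50, 100))
  iv <- build_linkage_interval("g010", coords, character(0), genes)
  # all 49 same-chromosome genes come first, then 50 nearest from chr2
  expect_true(all(sprintf("g%03d", setdiff(1:50, 10)) %in% iv$candidates))
  expect_equal(sum(coords$chrom[match(iv$candidates, coords$gene)] == "chr2"),
               50)
})

test_that("candidate ranking averages namespaces and breaks ties by ID", {
  genes <- sprintf("c%02d", 1:5)
  iv <- structure(list(target_gene = "c03", candidates = genes,
                       disease_id = "d"), class = "linkage_interval")
  s <- matrix(c(1, 0, 0, 0, 0,
                0, 0, 0, 0, 0,
                0, 0, 0, 0, 0), 5, 3,
              dimnames = list(genes, c("MF", "CC", "BP")))
  rl <- rank_candidates(s, iv)
  expect_identical(rl$ranking[1], "c01")

  tied <- matrix(0.5, 5, 3, dimnames = list(genes, NULL))
  rl2 <- rank_candidates(tied, iv)
  expect_identical(rl2$ranking, sort(genes))     # lexicographic on full tie
  expect_equal(rl2$target_rank, 3L)

  set.seed(14)
  s3 <- matrix(runif(15), 5, 3, dimnames = list(genes, NULL))
  rl3 <- rank_candidates(s3, iv)
  expect_identical(rl3$ranking, genes[order(-rowMeans(s3), genes)])
  # permuting namespace columns changes nothing
  rl4 <- rank_candidates(s3[, c(3, 1, 2)], iv)
  expect_identical(rl3$ranking, rl4$ranking)
  # non-finite scores refuse to rank
  s3[2, 2] <- NA
  expect_error(rank_candidates(s3, iv), class = "gcnprio_validation")
})

test_that("raising one namespace score never worsens the final rank", {
  genes <- sprintf("c%02d", 1:6)
  iv <- structure(list(target_gene = "c01", candidates = genes,
                       disease_id = "d"), class = "linkage_interval")
  set.seed(25)
  for (rep in 1:20) {
    s <- matrix(runif(18), 6, 3, dimnames = list(genes, NULL))
    r1 <- rank_candidates(s, iv)
    pick <- sample(6, 1)
    col <- sample(3, 1)
    s2 <- s
    s2[pick, col] <- s2[pick, col] + runif(1)
    r2 <- rank_candidates(s2, iv)
    expect_lte(match(genes[pick], r2$ranking), match(genes[pick], r1$ranking))
  }
})

test_that("symmetric untrained class weights score every candidate 0.5", {
  tp <- tiny_problem(n = 6, m = 5, seed = 6)
  cfg <- model_config(layer_sizes = c(4, 3), l1 = 1, l2 = 1)
  params <- init_params(cfg, 5, 2, 6, seed = 1)
  params$Wy <- matrix(0.2, nrow(params$Wy), 2)
  model <- structure(list(params = params, classes = c("disease", "other"),
                          config = cfg), class = "gcn_model")
  iv <- structure(list(target_gene = tp$genes[1],
                       candidates = tp$genes[1:4], disease_id = "d"),
                  class = "linkage_interval")
  models <- list(MF = model, CC = model, BP = model)
  feats <- list(MF = tp$X, CC = tp$X, BP = tp$X)
  s <- score_candidates(models, feats, tp$network, iv)
  expect_true(all(abs(s - 0.5) < 1e-12))
})

test_that("random-score ranking centres the target near the middle", {
  genes <- sprintf("c%03d", 1:100)
  iv <- structure(list(target_gene = "c050", candidates = genes,
                       disease_id = "d"), class = "linkage_interval")
  set.seed(31)
  ranks <- replicate(400, {
    s <- matrix(runif(300), 100, 3, dimnames = list(genes, NULL))
    rank_candidates(s, iv)$target_rank
  })
  expect_lt(abs(mean(ranks) - 50.5), 3 * sqrt(9999 / 12) / sqrt(400))
})

test_that("leave-one-out produces one rank list per disease gene", {
  cfg_fx <- fixture_config(n_genes = 130, n_disease = 2, p_in = 1,
                           p_out = 0.05, n_terms_per_namespace = 12,
                           n_enriched_terms = 4, seed = 5)
  fx <- load_fixture(cfg_fx)
  expect_length(fx$disease, 2L)   # p_in = 1 keeps both module genes connected
  cfg <- model_config(layer_sizes = c(4, 4), l1 = 1, l2 = 1,
                      max_epochs = 10, patience = 10, seed = 3)
  rls <- suppressMessages(
    loocv_evaluate(fx$disease, fx$features, fx$network, fx$coords, cfg))
  expect_length(rls, 2L)
  for (rl in rls) {
    expect_s3_class(rl, "rank_list")
    expect_setequal(rl$ranking, rl$interval$candidates)   # permutation
    expect_equal(rl$ranking[rl$target_rank], rl$interval$target_gene)
  }
  expect_error(loocv_evaluate(fx$disease[1], fx$features, fx$network,
                              fx$coords, cfg),
               class = "gcnprio_validation")
})
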