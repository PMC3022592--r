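jc_model <- hky_params(kappa = 1, pi = rep(0.25, 4), gamma_shape = Inf)

test_that("ML distances match the Jukes-Cantor closed form", {
  tr <- parse_newick("(A:0.2,B:0.2);")
  aln <- simulate_alignment(tr, 5000, jc_model, seed = 2)
  dm <- ml_pairwise_distances(aln, jc_model)
  p <- mean(aln$seqs["A", ] != aln$seqs["B", ])
  expect_equal(dm["A", "B"], -3 / 4 * log(1 - 4 * p / 3), tolerance = 1e-4)
})

test_that("ML distances handle identical, saturated and absent pairs", {
  s <- matrix(c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L), 2, 4, byrow = TRUE,
              dimnames = list(c("x", "y"), NULL))
  expect_equal(ml_pairwise_distances(gene_alignment(s), jc_model)["x", "y"], 0)
  # no overlap -> absent entry
  s2 <- rbind(x = c(1L, 2L, NA, NA), y = c(NA, NA, 3L, 4L))
  dm <- ml_pairwise_distances(gene_alignment(s2), jc_model)
  expect_true(is.na(dm["x", "y"]))
  # max disagreement -> clamped with warning
  s3 <- rbind(x = rep(1L, 60), y = rep(2L, 60))
  expect_warning(dm3 <- ml_pairwise_distances(gene_alignment(s3), jc_model),
                 "saturated")
  expect_equal(dm3["x", "y"], 10)
})

test_that("ML distance estimation is consistent in a round trip", {
  m <- hky_params(kappa = 4, pi = c(A = .3, C = .2, G = .2, T = .3),
                  gamma_shape = 1)
  tr <- parse_newick("(A:0.15,B:0.15);")
  aln <- simulate_alignment(tr, 30000, m, seed = 7)
  dm <- ml_pairwise_distances(aln, m)
  expect_lt(abs(dm["A", "B"] - 0.3), 0.02)
})

test_that("distance estimation is permutation-equivariant", {
  m <- hky_params(kappa = 2, gamma_shape = 1)
  set.seed(8)
  tr <- ape::rtree(5)
  aln <- simulate_alignment(tr, 800, m, seed = 9)
  dm <- ml_pairwise_distances(aln, m)
  perm <- sample(rownames(aln$seqs))
  aln2 <- gene_alignment(aln$seqs[perm, ], gene = "p")
  dm2 <- ml_pairwise_distances(aln2, m)
  expect_equal(dm2[rownames(dm), colnames(dm)], dm, ignore_attr = TRUE)
})

test_that("average_consensus averages available entries", {
  set.seed(3)
  tr <- ape::rtree(6)
  D <- cophenetic(tr)
  avd <- average_consensus(list(D, D, D))
  expect_equal(avd[rownames(D), colnames(D)], D, ignore_attr = TRUE)
  g1 <- D; g1["t1", "t2"] <- g1["t2", "t1"] <- 2
  g2 <- D; g2["t1", "t2"] <- g2["t2", "t1"] <- 4
  expect_equal(average_consensus(list(g1, g2))["t1", "t2"], 3)
  # pair covered by no gene stays absent
  p1 <- D[1:4, 1:4]; p2 <- D[3:6, 3:6]
  av <- average_consensus(list(p1, p2))
  expect_true(is.na(av[rownames(D)[1], rownames(D)[6]]))
})

test_that("SDM recovers exact scalings and never loses to plain averaging", {
  set.seed(4)
  tr <- ape::rtree(6); tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  D <- cophenetic(tr)
  sol <- suppressWarnings(sdm_combine(list(D, 2 * D), shifts = FALSE))
  expect_equal(unname(sol$alpha), c(4 / 3, 2 / 3), tolerance = 1e-8)
  expect_lt(sol$objective, 1e-12)
  sol2 <- suppressWarnings(sdm_combine(list(D, D, D)))
  expect_equal(unname(sol2$alpha), rep(1, 3), tolerance = 1e-6)
  expect_lt(sol2$objective, 1e-12)
  # random sparse collections: SDM objective <= AvCon objective
  for (i in 1:10) {
    mats <- lapply(1:4, function(g) {
      keep <- sort(sample(6, sample(4:6, 1)))
      m <- (stats::runif(1, 0.5, 2) * D)[keep, keep]
      m + stats::runif(length(m), 0, 0.05) * (1 - diag(length(keep)))
    })
    mats <- lapply(mats, function(m) (m + t(m)) / 2)
    sol <- suppressWarnings(sdm_combine(mats))
    expect_lte(sol$objective, sol$objective_avcon + 1e-9)
  }
})

test_that("fm_tree fits additive matrices exactly, with or without gaps", {
  set.seed(5)
  tr <- ape::rtree(6); tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  D <- cophenetic(tr)
  f <- fm_tree(D, search_config(seed = 1))
  expect_equal(rf_distance(f, tr), 0)
  expect_lt(attr(f, "objective"), 1e-12)
  # branch lengths recovered too (patristic distances match)
  expect_equal(cophenetic(f)[rownames(D), colnames(D)], D, tolerance = 1e-6)
  # 20% of entries deleted, coverage still connected
  Dm <- D
  Dm[1, 4] <- Dm[4, 1] <- NA; Dm[2, 5] <- Dm[5, 2] <- NA; Dm[3, 6] <- Dm[6, 3] <- NA
  expect_equal(rf_distance(fm_tree(Dm, search_config(seed = 1)), tr), 0)
  # flat matrix: runs and returns a valid tree
  flat <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(flat) <- 0
  expect_s3_class(fm_tree(flat, search_config(seed = 1)), "phylo")
})

test_that("disconnected coverage is reported with its components", {
  D <- matrix(NA_real_, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  D["a", "b"] <- D["b", "a"] <- 1
  D["c", "d"] <- D["d", "c"] <- 1
  expect_error(fm_tree(D), "disconnected")
  expect_error(impute_distances(D), "a,b")
})

test_that("nj_tree recovers additive trees and survives degenerate input", {
  set.seed(6)
  tr <- ape::rtree(5); tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.5)
  D <- cophenetic(tr)
  expect_equal(rf_distance(nj_tree(D), tr), 0)
  flat <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(flat) <- 0
  t4 <- nj_tree(flat)
  expect_true(all(t4$edge.length >= 0))
  # n = 3 closed form
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  expect_equal(unname(cophenetic(t3)[c("a", "b", "c"), c("a", "b", "c")]),
               unname(d3), tolerance = 1e-10)
  Dm <- D; Dm[1, 2] <- Dm[2, 1] <- NA
  expect_error(nj_tree(Dm), "impute")
})

test_that("concatenate builds the gap-filled superalignment", {
  s1 <- gene_alignment(matrix(1L, 3, 100, dimnames = list(c("a", "b", "c"), NULL)),
                       gene = "g1")
  s2 <- gene_alignment(matrix(2L, 3, 250, dimnames = list(c("b", "c", "d"), NULL)),
                       gene = "g2")
  sa <- concatenate(list(s1, s2))
  expect_equal(ncol(sa$seqs), 350L)
  expect_setequal(rownames(sa$seqs), c("a", "b", "c", "d"))
  expect_true(all(is.na(sa$seqs["a", 101:350])))
  expect_true(all(is.na(sa$seqs["d", 1:100])))
  map <- attr(sa, "gene_map")
  expect_equal(map$end - map$start + 1L, c(100L, 250L))
  expect_error(concatenate(list(s1, s1)), "duplicate")
  expect_error(concatenate(list(s1, s2), taxa = c("a", "z")), "no gene")
})

test_that("superalignment of one gene equals that gene's distance tree", {
  m <- hky_params(kappa = 2, gamma_shape = 1)
  set.seed(10)
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length * 0.05
  aln <- simulate_alignment(tr, 2000, m, seed = 11, gene = "g1")
  single <- fm_tree(ml_pairwise_distances(aln, m), search_config(seed = 2))
  sa <- superalignment_tree(list(aln), m, search_config(seed = 2))
  expect_equal(rf_distance(sa, single), 0)
  # duplicated gene: same tree (weighting sanity)
  aln2 <- gene_alignment(aln$seqs, gene = "g2")
  sa2 <- superalignment_tree(list(aln, aln2), m, search_config(seed = 2))
  expect_equal(rf_distance(sa2, single), 0)
})

test_that("distance matrix files round-trip including absent entries", {
  set.seed(12)
  D <- cophenetic(ape::rtree(5))
  D[1, 3] <- D[3, 1] <- NA
  f <- tempfile(fileext = ".dist")
  write_distmatrix(D, f)
  D2 <- read_distmatrix(f)
  expect_equal(D2, D, tolerance = 1e-6)
})
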