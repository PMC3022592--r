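src4 <- parse_newick("(B,(C,(A,D)));")

test_that("Baum/Ragan coding reproduces the worked 4-taxon example", {
  m <- encode_br(list(src4))
  expect_equal(dim(m$mat), c(4L, 2L))
  rows <- apply(m$mat, 1L, function(r) paste(sort(r, decreasing = TRUE), collapse = ""))
  expect_equal(unname(rows[c("A", "B", "D")]), c("11", "00", "11"))
  expect_setequal(m$mat["C", ], c(1L, 0L))
})

test_that("Purvis coding codes sister groups with '?' elsewhere", {
  m <- encode_pu(list(src4))
  expect_equal(dim(m$mat), c(4L, 2L))
  expect_equal(unname(rowSums(m$mat == 1L, na.rm = TRUE)[c("A", "D")]), c(2L, 2L))
  expect_setequal(as.vector(m$mat["B", ]), c(0L, NA))
  expect_setequal(m$mat["C", ], c(1L, 0L))
  expect_error(encode_pu(list(parse_newick("((a,b),c,d);"))), "rooted")
})

test_that("coding column counts and '?' structure follow the leaf sets", {
  # single 3-leaf rooted tree: one column
  m3 <- encode_br(list(parse_newick("(a,(b,c));")))
  expect_equal(ncol(m3$mat), 1L)
  expect_equal(sort(m3$mat[, 1]), c(a = 0L, b = 1L, c = 1L)[order(names(m3$mat[, 1]))],
               ignore_attr = TRUE)
  # disjoint taxon sets: '?' blocks
  md <- encode_br(lapply(c("((a,b),(c,d));", "((e,f),(g,h));"), parse_newick))
  expect_equal(nrow(md$mat), 8L)
  expect_true(all(colSums(is.na(md$mat)) == 4L))
  # k binary rooted trees with n_t leaves: sum(n_t - 2) BR columns
  set.seed(11)
  trees <- lapply(c(5, 7, 8), function(n) rand_rooted(letters[1:n]))
  expect_equal(ncol(encode_br(trees)$mat), sum(c(5, 7, 8) - 2L))
  # PU: sum(n_t - 1) columns before filtering; root column is dropped
  expect_equal(ncol(encode_pu(trees)$mat), sum(c(5, 7, 8) - 2L))
  # PU has at least as many '?' as BR on the same trees
  set.seed(12)
  for (i in 1:5) {
    tt <- list(rand_rooted(letters[1:8]))
    expect_gte(sum(is.na(encode_pu(tt)$mat)), sum(is.na(encode_br(tt)$mat)))
  }
})

test_that("mr_score objectives agree with their definitions", {
  m <- encode_br(list(src4))
  # each BR column of a tree fits its own source: fitch 1 per column,
  # flip 0, full compatibility
  expect_equal(mr_score(m, src4, "fitch"), 2)
  expect_equal(mr_score(m, src4, "flip"), 0)
  expect_equal(mr_score(m, src4, "compat"), 2)
  expect_equal(mr_score(m, src4, "camin_sokal"), 2)
  expect_error(mr_score(m, ape::unroot(src4), "camin_sokal"), "rooted")
  m5 <- rand_mr_matrix(letters[1:5], 6)
  tr5 <- parse_newick("((a,b),(c,d),e);")
  expect_error(mr_score(m5, parse_newick("((a,b),(c,f),e);")), "match")
  # fitch >= number of non-constant columns
  expect_gte(mr_score(m5, tr5, "fitch"),
             sum(apply(m5$mat, 2, function(x) length(unique(stats::na.omit(x))) > 1)))
})

test_that("scores are invariant under taxon and column permutation", {
  set.seed(21)
  m <- rand_mr_matrix(letters[1:6], 8)
  tr <- rand_topology(letters[1:6])
  perm <- sample(6)
  m2 <- mr_matrix(m$mat[perm, sample(8), drop = FALSE])
  for (obj in c("fitch", "flip", "compat")) {
    expect_equal(mr_score(m2, tr, obj), mr_score(m, tr, obj))
  }
})

test_that("mr_score matches independent oracles on random instances", {
  set.seed(31)
  for (i in 1:6) {
    m <- rand_mr_matrix(letters[1:6], 8)
    tr <- rand_topology(letters[1:6])
    expect_equal(mr_score(m, tr, "fitch"), as.numeric(oracle_fitch(tr, m$mat)))
    expect_equal(mr_score(m, tr, "flip"), oracle_flip(tr, m$mat))
    expect_equal(mr_score(m, tr, "compat"), oracle_flip(tr, m$mat, compat = TRUE))
    rt <- rand_rooted(letters[1:5])
    m5 <- rand_mr_matrix(letters[1:5], 6)
    expect_equal(mr_score(m5, rt, "camin_sokal"),
                 oracle_camin_sokal(rt, m5$mat))
  }
})

test_that("flip zero coincides with full compatibility", {
  set.seed(41)
  for (i in 1:10) {
    m <- rand_mr_matrix(letters[1:6], 5, na_frac = 0.3)
    tr <- rand_topology(letters[1:6])
    fl <- mr_score(m, tr, "flip")
    cp <- mr_score(m, tr, "compat")
    expect_equal(fl == 0, cp == ncol(m$mat))
  }
})

test_that("mr_supertree recovers single and compatible sources", {
  set.seed(51)
  tr <- rand_topology(letters[1:7])
  m <- encode_br(list(tr))
  for (obj in c("fitch", "flip", "compat")) {
    st <- mr_supertree(m, obj, search_config(n_restarts = 2, seed = 5))
    expect_equal(rf_distance(st, tr), 0)
  }
  # deterministic given seed
  s1 <- mr_supertree(m, "fitch", search_config(n_restarts = 2, seed = 9))
  s2 <- mr_supertree(m, "fitch", search_config(n_restarts = 2, seed = 9))
  expect_identical(write_newick(s1), write_newick(s2))
  # empty matrix -> star with warning
  empty <- mr_matrix(matrix(integer(0), 5, 0, dimnames = list(letters[1:5], NULL)))
  expect_warning(st0 <- mr_supertree(empty, "fitch"), "star")
  expect_length(splits_of(st0), 0L)
})

test_that("camin_sokal supertree search returns a rooted tree", {
  set.seed(61)
  tr <- rand_rooted(letters[1:6])
  m <- encode_br(list(tr))
  st <- mr_supertree(m, "camin_sokal", search_config(n_restarts = 2, seed = 3))
  expect_true(ape::is.rooted(st))
  expect_equal(rf_distance(ape::unroot(st), ape::unroot(tr)), 0)
})

test_that("matrix import/export round-trips", {
  set.seed(71)
  m <- rand_mr_matrix(letters[1:6], 7)
  tsv <- tempfile(fileext = ".tsv")
  write_mr_tsv(m, tsv)
  m2 <- read_mr_tsv(tsv)
  expect_equal(unname(m2$mat), unname(m$mat))
  expect_equal(m2$taxa, m$taxa)
  nex <- tempfile(fileext = ".nex")
  write_mr_nexus(m, nex)
  txt <- readLines(nex)
  expect_true(any(grepl("NTAX=6 NCHAR=7", txt)))
  expect_true(any(grepl("MISSING=\\?", txt)))
})
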