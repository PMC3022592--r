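test_that("Newick parsing round-trips and validates", {
  tr <- parse_newick("((A,D),C,B);")
  expect_s3_class(tr, "phylo")
  expect_false(ape::is.rooted(tr))
  expect_true(ape::is.rooted(parse_newick("(B,(C,(A,D)));")))
  rt <- parse_newick(write_newick(tr))
  expect_equal(rf_distance(tr, rt), 0)
  expect_error(parse_newick("((A,B);"), "parse error")
  expect_error(parse_newick("(A,B));"), "parse error")
  expect_error(parse_newick("((A,A),B,C);"), "duplicate")
})

test_that("splits_of returns exactly the non-trivial splits", {
  s <- splits_of(parse_newick("((A,D),C,B);"))
  expect_length(s, 1L)
  expect_setequal(s[[1]], c("A", "D"))
  star <- parse_newick("(a,b,c,d,e);")
  expect_length(splits_of(star), 0L)
  cat6 <- parse_newick("(a,(b,(c,(d,(e,f)))));")
  expect_length(splits_of(cat6), 3L)
  set.seed(1)
  for (n in 4:12) {
    tr <- rand_topology(letters[1:n])
    expect_length(splits_of(tr), n - 3L)
  }
})

test_that("rf_distance matches hand-derived values and handles polytomies", {
  t1 <- parse_newick("((A,B),(C,D),E);")
  expect_equal(rf_distance(t1, t1), 0)
  # one NNI away: raw 2, normalized 0.5
  t2 <- parse_newick("((A,C),(B,D),E);")
  expect_equal(rf_distance(t1, t2, normalized = FALSE), 4)
  t3 <- parse_newick("(((A,B),C),D,E);")  # shares split {A,B}
  expect_equal(rf_distance(t1, t3, normalized = FALSE), 2)
  expect_equal(rf_distance(t1, t3), 0.5)
  # binary vs star on n leaves: normalized 0.5
  for (n in c(5, 8)) {
    set.seed(n)
    bt <- rand_topology(letters[1:n])
    star <- parse_newick(paste0("(", paste(letters[1:n], collapse = ","), ");"))
    expect_equal(rf_distance(bt, star), 0.5)
  }
  expect_error(rf_distance(t1, parse_newick("((A,B),(C,F),E);")), "D.*F|F.*D")
  expect_error(rf_distance(parse_newick("(A,B,C);"), parse_newick("(A,B,C);")),
               "at least 4")
})

test_that("rf_distance is a metric and agrees with phangorn", {
  set.seed(42)
  trees <- replicate(12, rand_topology(letters[1:6]), simplify = FALSE)
  for (i in 1:11) {
    a <- trees[[i]]; b <- trees[[i + 1]]
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_equal(rf_distance(a, b, normalized = FALSE),
                 as.numeric(phangorn::RF.dist(a, b)))
    cc <- trees[[sample.int(12, 1)]]
    expect_gte(rf_distance(a, cc) + rf_distance(cc, b) - rf_distance(a, b),
               -1e-12)
  }
})

test_that("consensus trees keep exactly the splits above threshold", {
  t1 <- parse_newick("((A,B),(C,D),E);")
  t2 <- parse_newick("((A,B),(C,E),D);")
  t3 <- parse_newick("((A,B),(C,D),E);")
  expect_equal(rf_distance(majority_consensus(list(t1, t1, t1)), t1), 0)
  maj <- majority_consensus(list(t1, t2, t3))
  keys <- vapply(splits_of(maj), paste, "", collapse = ",")
  expect_setequal(keys, c("A,B", "C,D"))   # {C,E} is in only 1 of 3
  # split in exactly half the trees is excluded
  maj2 <- majority_consensus(list(t1, t2))
  expect_setequal(vapply(splits_of(maj2), paste, "", collapse = ","), "A,B")
  # disjoint split sets -> star
  u1 <- parse_newick("((A,B),(C,D),E);")
  u2 <- parse_newick("((A,C),(B,E),D);")
  expect_length(splits_of(strict_consensus(list(u1, u2))), 0L)
  # strict subset of majority
  st <- strict_consensus(list(t1, t2, t3))
  expect_true(all(vapply(splits_of(st), paste, "", collapse = ",") %in% keys))
  expect_error(majority_consensus(list(t1, parse_newick("((A,B),(C,F),E);"))),
               "identical leaf sets")
  # cross-check with ape on a tie-free instance
  ac <- ape::consensus(c(t1, t2, t3), p = 0.5)
  expect_equal(rf_distance(maj, ac), 0)
})

test_that("root_at separates the outgroup and preserves splits", {
  tr <- parse_newick("((A,D),C,B);")
  r <- root_at(tr, "B")
  expect_true(ape::is.rooted(r))
  expect_equal(rf_distance(ape::unroot(r), tr), 0)
  expect_error(root_at(tr, "Z"), "not a leaf")
})

test_that("restrict_to induces the subtree and preserves path lengths", {
  tr <- parse_newick("(B,(C,(A,D)));")
  r <- restrict_to(tr, c("A", "C", "D"))
  expect_setequal(r$tip.label, c("A", "C", "D"))
  set.seed(5)
  big <- ape::rtree(8)
  keep <- sample(big$tip.label, 5)
  small <- restrict_to(big, keep)
  expect_equal(cophenetic(small)[keep, keep], cophenetic(big)[keep, keep],
               tolerance = 1e-10)
  expect_identical(restrict_to(big, big$tip.label), big)
  expect_error(restrict_to(tr, c("A", "Z")), "not in tree")
})

test_that("extract_triplets enumerates resolved rooted triplets", {
  tr <- parse_newick("(B,(C,(A,D)));")
  expect_setequal(extract_triplets(tr),
                  c("A,D|C", "A,D|B", "A,C|B", "C,D|B"))
  expect_equal(extract_triplets(parse_newick("(a,(b,c));")), "b,c|a")
  # polytomies leave their triplets unresolved
  expect_setequal(extract_triplets(parse_newick("((a,b,c),d);")),
                  c("a,b|d", "a,c|d", "b,c|d"))
  set.seed(3)
  rt <- rand_rooted(letters[1:6])
  expect_length(extract_triplets(rt), choose(6, 3))
  expect_error(extract_triplets(parse_newick("(a,b,(c,d));")), "rooted")
})

test_that("rooting then unrooting is the identity on split sets", {
  set.seed(9)
  for (i in 1:5) {
    tr <- rand_topology(letters[1:7])
    r <- root_at(tr, sample(tr$tip.label, 1))
    expect_equal(rf_distance(ape::unroot(r), tr), 0)
  }
})
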