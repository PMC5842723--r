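test_that("pairwise DP aligns identical sequences without gaps", {
  for (nm in c("blosum30", "blosum45", "blosum62")) {
    m <- load_blosum(nm)
    aln <- pairwise_affine_align("ACDE", "ACDE", m, 10, 1)
    expect_equal(as.vector(unclass(aln)), c("ACDE", "ACDE"))
    expect_equal(attr(aln, "score"),
                 sum(vapply(c("A", "C", "D", "E"), function(ch) {
                   matrix_score(m, ch, ch)
                 }, numeric(1))))
  }
  expect_error(pairwise_affine_align("A", "", load_blosum("blosum62"), 10, 1),
               "empty")
  expect_warning(
    pairwise_affine_align("ACD", "ACD", load_blosum("blosum62"), 1, 2),
    "GOP > GEP")
})

test_that("pairwise DP score equals exhaustive enumeration on short pairs", {
  b62 <- load_blosum("blosum62")
  S <- unclass(b62)
  # every ordered pair of strings of length 1..3 over a 2-letter alphabet
  pool <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")
  }))
  for (a in pool) {
    for (b in pool) {
      got <- attr(pairwise_affine_align(a, b, b62, 5, 1), "score")
      expect_equal(got, brute_affine_score(a, b, S, 5, 1))
    }
  }
  # random longer pairs over a 4-letter reduced alphabet, random penalties
  set.seed(410)
  for (i in 1:12) {
    a <- random_seq(sample(4:6, 1), c("A", "C", "D", "W"))
    b <- random_seq(sample(4:6, 1), c("A", "C", "D", "W"))
    gop <- sample(2:12, 1); gep <- stats::runif(1, 0, gop)
    got <- attr(pairwise_affine_align(a, b, b62, gop, gep), "score")
    expect_equal(got, brute_affine_score(a, b, S, gop, gep))
  }
})

test_that("the reported DP score matches the alignment it returns", {
  b45 <- load_blosum("blosum45")
  set.seed(411)
  for (i in 1:10) {
    a <- random_seq(sample(5:20, 1)); b <- random_seq(sample(5:20, 1))
    gop <- sample(3:12, 1); gep <- stats::runif(1, 0.1, gop / 2)
    aln <- pairwise_affine_align(a, b, b45, gop, gep)
    expect_equal(attr(aln, "score"),
                 naive_sp_score(aln, unclass(b45), gop, gep)$score)
  }
})

test_that("guide tree joins closest sequences first, deterministically", {
  b62 <- load_blosum("blosum62")
  two <- sequence_set(c(a = "ACDEF", b = "ACDEW"))
  gt2 <- build_guide_tree(two, b62, 10, 1)
  expect_length(gt2$merges, 1)
  expect_setequal(c(gt2$merges[[1]]$left, gt2$merges[[1]]$right), c("a", "b"))

  three <- sequence_set(c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKL",
                          s3 = "WYWYWYWYWY"))
  gt3 <- build_guide_tree(three, b62, 10, 1)
  expect_setequal(c(gt3$merges[[1]]$left, gt3$merges[[1]]$right),
                  c("s1", "s2"))
})

test_that("UPGMA agglomeration matches hclust average linkage", {
  # continuous random distances: ties (where the implementations may
  # legitimately differ by tie rule) have probability zero
  set.seed(412)
  n <- 6
  D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  D[lower.tri(D)] <- stats::runif(n * (n - 1) / 2, 0.1, 1)
  D <- D + t(D)
  ours <- msaparam:::upgma_merge(D)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # same merge heights in the same order
  expect_equal(vapply(ours$merges, `[[`, numeric(1), "height"),
               hc$height / 2)
  # same partition at every agglomeration step
  memb_ours <- lapply(ours$merges, function(s) sort(c(s$left, s$right)))
  for (step in seq_len(n - 1)) {
    labs <- stats::cutree(hc, k = n - step)
    new_cluster <- sort(names(labs)[labs == labs[memb_ours[[step]][1]]])
    expect_equal(memb_ours[[step]], new_cluster)
  }
})

test_that("progressive alignment round-trips, reduces and is deterministic", {
  b62 <- load_blosum("blosum62")
  same <- sequence_set(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL",
                         c = "ACDEFGHIKL"))
  aln <- progressive_align(same, b62, 10, 1)
  expect_equal(alignment_length(aln), 10)
  triv <- alignment(stats::setNames(unclass(same), names(same)))
  expect_equal(sps(aln, triv), 1)

  two <- sequence_set(c(a = "HEAGAWGHEE", b = "PAWHEAE"))
  pw <- pairwise_affine_align(two[1], two[2], b62, 10, 1)
  attr(pw, "score") <- NULL
  expect_equal(unclass(progressive_align(two, b62, 10, 1)), unclass(pw))

  set.seed(413)
  fam <- simulate_family(family_config(m = 5, root_len = 40,
                                       target_iden = 0.4))
  a1 <- progressive_align(fam$seqs, b62, 10, 1)
  a2 <- progressive_align(fam$seqs, b62, 10, 1)
  expect_identical(unclass(a1), unclass(a2))
  expect_identical(unclass(ungap(a1)), unclass(fam$seqs))
})

test_that("progressive alignment beats a left-flushed strawman", {
  set.seed(414)
  fam <- simulate_family(family_config(m = 4, root_len = 50,
                                       target_iden = 0.5))
  aln <- progressive_align(fam$seqs, load_blosum("blosum62"), 10, 1)
  # strawman: ignore homology, flush every sequence left and pad with gaps
  L <- alignment_length(fam$truth)
  straw <- alignment(vapply(unclass(fam$seqs), function(s) {
    paste0(s, strrep("-", L - nchar(s)))
  }, character(1)))
  expect_gt(sps(aln, fam$truth), sps(straw, fam$truth))
})
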