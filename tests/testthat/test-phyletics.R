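tmp_tree <- function(txt) {
  f <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(txt, f)
  f
}

test_that("newick reading validates structure and leaf uniqueness", {
  tree <- read_newick(tmp_tree("((A,B),(C,D));"))
  expect_s3_class(tree, "phylo")
  expect_equal(sort(tree$tip.label), c("A", "B", "C", "D"))
  expect_error(read_newick(tmp_tree("((A,B),(A,C));")), "duplicate.*A")
  expect_error(read_newick(tmp_tree("((A,B),(C,D);")), "unbalanced")
  expect_error(read_newick(tmp_tree("(A,B)),C;")), "character 6")
})

test_that("newick write/read round-trips topology on 50 seeded random trees", {
  withr::local_seed(99)
  for (i in 1:50) {
    tree <- ape::rtree(sample(3:20, 1))
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tree, f)
    back <- read_newick(f)
    expect_true(ape::all.equal.phylo(tree, back, use.edge.length = FALSE))
  }
})

test_that("Dollo places a single gain at the MRCA and minimal losses", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  # all present: gain at root, no loss
  rec <- dollo_reconstruct(tree, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(rec$gain_node, 5)  # the root in ape numbering
  expect_equal(rec$n_losses, 0)
  # one absent tip: one loss on its edge (value confirmed by exhaustive
  # enumeration of single-gain labelings below)
  st <- c(A = 1, B = 1, C = 0, D = 1)
  rec <- dollo_reconstruct(tree, st)
  expect_equal(rec$n_losses, 1)
  expect_equal(rec$loss_edges$child_label, "C")
  expect_equal(rec$n_losses, brute_dollo_losses(tree, st))
  # all absent: no gain, no loss
  rec0 <- dollo_reconstruct(tree, c(A = 0, B = 0, C = 0, D = 0))
  expect_true(is.na(rec0$gain_node))
  expect_equal(rec0$n_losses, 0)
})

test_that("missing data never forces a loss", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  rec <- dollo_reconstruct(tree, c(A = 1, B = 1, C = "?", D = 1))
  expect_equal(rec$n_losses, 0)
  # a definite absence behind missing data is still charged once
  tree2 <- ape::read.tree(text = "((A,B),((C1,C2),D));")
  rec2 <- dollo_reconstruct(tree2, c(A = 1, B = 1, C1 = "?", C2 = 0, D = 1))
  expect_equal(rec2$n_losses, 1)
})

test_that("Dollo equals a brute-force single-gain minimizer on 25 seeded small trees", {
  withr::local_seed(55)
  for (i in 1:25) {
    ntip <- sample(4:7, 1)
    tree <- ape::rtree(ntip)
    states <- setNames(sample(c("0", "1", "?"), ntip, replace = TRUE,
                              prob = c(0.4, 0.5, 0.1)), tree$tip.label)
    if (!any(states == "1")) states[sample(ntip, 1)] <- "1"
    expect_equal(dollo_reconstruct(tree, states)$n_losses,
                 brute_dollo_losses(tree, states),
                 info = paste(ape::write.tree(tree), toString(states)))
  }
})

test_that("Dollo loss counts are invariant under leaf reordering", {
  withr::local_seed(70)
  for (i in 1:10) {
    tree <- ape::rtree(8)
    states <- setNames(sample(c("0", "1"), 8, replace = TRUE), tree$tip.label)
    states[sample(8, 1)] <- "1"
    rotated <- ape::read.tree(text = ape::write.tree(ape::ladderize(tree)))
    expect_equal(dollo_reconstruct(tree, states)$n_losses,
                 dollo_reconstruct(rotated, states)$n_losses)
  }
})

test_that("Fitch handles the textbook cases", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_count(tree, c(A = "x", B = "x", C = "y", D = "y"))$n_changes, 1)
  expect_equal(fitch_count(tree, c(A = "x", B = "x", C = "x", D = "x"))$n_changes, 0)
  # a cherry with identical states needs no change
  cherry <- ape::read.tree(text = "(A,B);")
  expect_equal(fitch_count(cherry, c(A = "x", B = "x"))$n_changes, 0)
  expect_equal(fitch_count(cherry, c(A = "x", B = "y"))$n_changes, 1)
  # returned labeling is a valid minimum-change extension
  res <- fitch_count(tree, c(A = "x", B = "x", C = "y", D = "y"))
  changes <- sum(res$labeling[tree$edge[, 1]] != res$labeling[tree$edge[, 2]])
  expect_equal(changes, res$n_changes)
})

test_that("Fitch equals brute-force minima on random binary and polytomous trees", {
  withr::local_seed(66)
  for (i in 1:20) {
    ntip <- sample(4:6, 1)
    tree <- ape::rtree(ntip)
    k <- sample(2:3, 1)
    states <- setNames(sample(letters[1:k], ntip, replace = TRUE),
                       tree$tip.label)
    got <- fitch_count(tree, states)
    expect_equal(got$n_changes, brute_fitch_changes(tree, states),
                 info = paste(ape::write.tree(tree), toString(states)))
    # the returned labeling attains the optimum
    changes <- sum(got$labeling[tree$edge[, 1]] != got$labeling[tree$edge[, 2]])
    expect_equal(changes, got$n_changes)
  }
  # explicit polytomies
  for (txt in c("(A,B,C,D);", "((A,B,C),(D,E));", "((A,B),(C,D,E),F);")) {
    tree <- ape::read.tree(text = txt)
    ntip <- ape::Ntip(tree)
    for (rep in 1:10) {
      states <- setNames(sample(c("x", "y", "z"), ntip, replace = TRUE),
                         tree$tip.label)
      expect_equal(fitch_count(tree, states)$n_changes,
                   brute_fitch_changes(tree, states),
                   info = paste(txt, toString(states)))
    }
  }
})

test_that("Fitch agrees with phangorn on binary trees", {
  skip_if_not_installed("phangorn")
  withr::local_seed(77)
  for (i in 1:20) {
    ntip <- sample(5:12, 1)
    tree <- ape::rtree(ntip)
    states <- setNames(sample(c("a", "b", "c"), ntip, replace = TRUE),
                       tree$tip.label)
    dat <- phangorn::phyDat(as.matrix(states), type = "USER",
                            levels = c("a", "b", "c"))
    expect_equal(fitch_count(tree, states)$n_changes,
                 as.integer(phangorn::parsimony(tree, dat)))
  }
})

test_that("Fitch change count is bounded and zero iff uniform", {
  withr::local_seed(88)
  for (i in 1:15) {
    ntip <- sample(3:10, 1)
    tree <- ape::rtree(ntip)
    states <- setNames(sample(c("x", "y"), ntip, replace = TRUE),
                       tree$tip.label)
    n <- fitch_count(tree, states)$n_changes
    expect_lte(n, ntip - 1)
    expect_equal(n == 0, length(unique(states)) == 1)
  }
})

test_that("unknown tips in the state table are an error naming the tip", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(dollo_reconstruct(tree, c(A = 1, Z = 0)), "Z")
  expect_error(fitch_count(tree, c(A = "x", Q = "y")), "Q")
})

test_that("per-character loss totals are additive over columns", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  mat <- data.frame(rheb = c(1, 1, 1, 1), fyve = c(1, 1, 0, 1),
                    row.names = c("A", "B", "C", "D"))
  res <- count_total_losses(tree, mat)
  expect_equal(res$total_losses, 1)
  expect_equal(res$per_character$n_losses, c(0, 1))
  # duplicated column doubles the total
  mat2 <- cbind(mat, fyve2 = mat$fyve)
  expect_equal(count_total_losses(tree, mat2)$total_losses, 2)
  # all-present single column: zero
  expect_equal(count_total_losses(tree, mat["rheb"])$total_losses, 0)
})

test_that("planted non-nested losses are recovered exactly on a 40-leaf tree", {
  withr::local_seed(123)
  tree <- ape::rtree(40)
  root <- ape::Ntip(tree) + 1
  kids <- rhebanchor:::node_children(tree)
  desc_tips <- function(node) {
    d <- .descend(tree$edge, node)
    d[d <= ape::Ntip(tree)]
  }
  for (k in 1:6) {
    # choose k loss tips such that every loss edge's parent retains presence
    # through another descendant and every root child keeps a present tip,
    # so the planted losses are non-nested and the gain stays at the root
    repeat {
      losers <- sample(ape::Ntip(tree), k)
      parents <- tree$edge[match(losers, tree$edge[, 2]), 1]
      parents_retain <- all(vapply(parents, function(p)
        length(setdiff(desc_tips(p), losers)) > 0, TRUE))
      root_retains <- all(vapply(kids[[root]], function(ch)
        length(setdiff(desc_tips(ch), losers)) > 0, TRUE))
      if (parents_retain && root_retains) break
    }
    states <- setNames(rep(1, 40), tree$tip.label)
    states[losers] <- 0
    rec <- dollo_reconstruct(tree, states)
    expect_equal(rec$n_losses, k)
    expect_setequal(rec$loss_edges$child, losers)
    expect_equal(rec$gain_node, root)
  }
})

test_that("state tables round-trip through TSV", {
  mat <- data.frame(rheb = c("1", "0", "?"), form = c("A", "K", "?"),
                    row.names = c("t1", "t2", "t3"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_states(mat, f)
  back <- read_states(f)
  expect_equal(back, mat)
})
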