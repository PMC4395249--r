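# deterministic two-level block-model distance matrix: 2 groups x 2 leaves
nestedD <- function(L = 16) {
  leaf <- rep(1:4, each = L / 4)
  group <- (leaf + 1) %/% 2
  D <- matrix(0.9, L, L)
  D[outer(group, group, `==`)] <- 0.45
  D[outer(leaf, leaf, `==`)] <- 0.15
  diag(D) <- 0
  dimnames(D) <- list(1:L, 1:L)
  list(D = D, leaf = leaf, group = group)
}

test_that("buildTree recovers a nested block model exactly", {
  nd <- nestedD()
  tree <- buildTree(nd$D, seed = 2L)
  expect_s4_class(tree, "NetworkTree")
  expect_true(validObject(tree))
  expect_equal(tree@root$K, 2L)
  l2 <- scaleLabels(tree, 2)
  l3 <- scaleLabels(tree, 3)
  expect_equal(truthAdjustedRand(l2, nd$group), 1)
  expect_equal(truthAdjustedRand(l3, nd$leaf), 1)
})

test_that("tiny clusters become leaves", {
  D <- matrix(0.5, 2, 2); diag(D) <- 0
  tree <- buildTree(D, minSize = 3L)
  expect_length(tree@root$children, 0L)
  expect_equal(nScales(tree), 1L)
  expect_equal(unname(scaleLabels(tree, 1)), c(1L, 1L))
  # scale cuts beyond the tree depth persist the leaves
  expect_equal(scaleLabels(tree, 5), scaleLabels(tree, 1))
})

test_that("maxDepth truncates recursion", {
  nd <- nestedD()
  tree <- buildTree(nd$D, maxDepth = 2L, seed = 2L)
  expect_equal(nScales(tree), 2L)
  expect_equal(length(unique(scaleLabels(tree, 2))), 2L)
})

test_that("every scale refines the previous one", {
  nd <- nestedD()
  tree <- buildTree(nd$D, seed = 2L)
  for (s in seq_len(nScales(tree) - 1L)) {
    a <- scaleLabels(tree, s)
    b <- scaleLabels(tree, s + 1L)
    # each finer block maps into exactly one coarser block
    expect_true(all(rowSums(table(b, a) > 0) == 1L))
  }
})

test_that("identical seed and input give an identical tree", {
  nd <- nestedD()
  t1 <- treeToJSON(buildTree(nd$D, seed = 9L))
  t2 <- treeToJSON(buildTree(nd$D, seed = 9L))
  expect_identical(as.character(t1), as.character(t2))
})

test_that("tree serialization round-trips through JSON", {
  nd <- nestedD()
  tree <- buildTree(nd$D, seed = 2L)
  path <- file.path(tempdir(), "tree.json")
  treeToJSON(tree, path)
  tree2 <- treeFromJSON(path)
  expect_equal(scaleLabels(tree2, 2), scaleLabels(tree, 2))
  expect_equal(scaleLabels(tree2, 3), scaleLabels(tree, 3))
  expect_equal(tree2@root$delta, tree@root$delta, tolerance = 1e-12)
  nw <- treeToNewick(tree)
  expect_match(nw, ";$")
  expect_equal(length(gregexpr("L[0-9]+", nw)[[1]]), 16L)
})

test_that("consistency profile averages within-block distances", {
  nd <- nestedD()
  tree <- buildTree(nd$D, seed = 2L)
  G <- nd$D; P <- nd$D    # identical features: curve equals mean of D
  f <- new("GroupFeature", G = G / max(G), P = P / max(P),
           D = 0.5 * G / max(G) + 0.5 * P / max(P),
           alpha = 0.5, nSubjects = 1L)
  pr <- consistencyProfile(tree, f)
  off <- upper.tri(nd$D)
  expect_equal(pr$curve$consistency[1],
               mean((G / max(G))[off]), tolerance = 1e-12)
  expect_true(all(diff(pr$curve$consistency) <= 1e-12))
  expect_equal(pr$curve$nBlocks, c(1L, 2L, 4L))
})

test_that("label transfer follows ids, not positions", {
  nd <- nestedD()
  tree <- buildTree(nd$D, seed = 2L)
  tl <- transferLabels(tree, landmarkSet(sample(200L, 16L), ids = 1:16))
  expect_equal(tl$scale2, scaleLabels(tree, 2))
  # permuted id order: labels follow the ids
  permIds <- c(3L, 1L, 2L, 4:16)
  lsPerm <- new("LandmarkSet", ids = permIds,
                centerVertex = seq_len(16L), patchRadius = 5)
  tlp <- transferLabels(tree, lsPerm)
  expect_equal(tlp$scale2[as.character(3)],
               scaleLabels(tree, 2)[as.character(3)])
  expect_equal(names(tlp$scale2), as.character(permIds))
})

test_that("label transfer names the missing ids", {
  nd <- nestedD()
  tree <- buildTree(nd$D, seed = 2L)
  expect_error(transferLabels(tree, setdiff(1:16, 7L)),
               "missing landmark id\\(s\\): 7")
  expect_error(transferLabels(tree, 1:17), "unknown landmark id")
})

test_that("sub-network displacement finds representatives by brute
           force", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(10, 0, 0))
  rownames(coords) <- 1:3
  labels <- c("1" = 1L, "2" = 1L, "3" = 1L)
  # mean distances: id1: (2+10)/2 = 6; id2: (2+8)/2 = 5; id3: 9 -> rep 2
  disp <- subnetworkDisplacement(coords, coords, labels)
  expect_equal(disp$perBlock$repModel, "2")
  expect_equal(disp$perBlock$distance, 0)
  # uniform translation moves every displacement by |t|
  t <- c(3, -4, 12)
  shifted <- sweep(coords, 2, t, `+`)
  rownames(shifted) <- rownames(coords)
  disp2 <- subnetworkDisplacement(coords, shifted, labels)
  expect_equal(disp2$perBlock$distance, sqrt(sum(t^2)), tolerance = 1e-12)
  expect_equal(disp2$average, sqrt(sum(t^2)), tolerance = 1e-12)
  # singleton blocks are their own representative
  labs2 <- c("1" = 1L, "2" = 1L, "3" = 2L)
  disp3 <- subnetworkDisplacement(coords, shifted, labs2)
  expect_equal(disp3$perBlock$repModel[2], "3")
})
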