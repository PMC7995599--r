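simFrom <- function(v, nm) {
  dimnames(v) <- list(nm, nm)
  SimilarityMatrix(v)
}

test_that("network assembly places MD edges exactly at the 1-entries", {
  a <- matrix(0, 2, 3, dimnames = list(c("m1", "m2"),
                                       c("d1", "d2", "d3")))
  a["m1", "d2"] <- 1
  am <- AssociationMatrix(a)
  sm <- simFrom(diag(2), c("m1", "m2"))
  sd <- simFrom(diag(3), c("d1", "d2", "d3"))
  ## unattainable threshold: no similarity edges at all
  net <- buildHetNet(am, sm, sd, "threshold", tau = 1.01)
  expect_equal(length(net@nodeNames), 5)
  expect_equal(nrow(netEdges(net)), 1)
  expect_equal(netEdges(net)$type, "MD")

  bad <- simFrom(diag(2), c("mX", "m2"))
  expect_error(buildHetNet(am, bad, sd), "inconsistent")
})

test_that("top-k edge rule keeps each node's strongest neighbors,
          union-symmetrized", {
  nm <- c("m1", "m2", "m3")
  v <- matrix(c(1, .9, .2,
                .9, 1, .5,
                .2, .5, 1), 3, dimnames = list(nm, nm))
  a <- matrix(0, 3, 2, dimnames = list(nm, c("d1", "d2")))
  a[1, 1] <- 1
  net <- buildHetNet(AssociationMatrix(a), simFrom(v, nm),
                     simFrom(diag(2), c("d1", "d2")), "topk", k = 1)
  mm <- subset(netEdges(net), type == "MM")
  ## brute force: per node strongest neighbor, union of directed picks
  want <- unique(t(apply(rbind(c(1, 2), c(2, 1), c(3, 2)), 1, sort)))
  got <- as.matrix(mm[, c("from", "to")])
  expect_equal(nrow(got), nrow(want))
  expect_true(all(paste(want[, 1], want[, 2]) %in%
                  paste(got[, 1], got[, 2])))
})

test_that("direct-edge-only pair yields the single length-1 instance", {
  fx <- makeToyNetworkFixture()
  inst <- enumerateMetaPaths(fx$net, "m2", "d2", lMax = 1)
  expect_length(inst, 1)
  expect_equal(inst[[1]]$type, "M,D")
  expect_equal(inst[[1]]$nodes, c("m2", "d2"))
})

test_that("toy fixture enumeration matches its hand-worked instances", {
  fx <- makeToyNetworkFixture()
  inst <- enumerateMetaPaths(fx$net, fx$pair[1], fx$pair[2], lMax = 3)
  expect_equal(lapply(inst, `[[`, "nodes"),
               lapply(fx$expected, `[[`, "nodes"))
  expect_equal(vapply(inst, `[[`, integer(1), "length"),
               vapply(fx$expected, `[[`, integer(1), "length"))
  ## contains a 2-length instance through a DD edge and a 3-length one
  lens <- vapply(inst, `[[`, integer(1), "length")
  expect_true(any(lens == 2) && any(lens == 3))
  ## fixture also equals the independent DFS oracle
  orc <- oracleMetaPaths(fx$net, fx$pair[1], fx$pair[2], 3)
  expect_equal(lapply(inst, `[[`, "nodes"), lapply(orc, `[[`, "nodes"))
})

test_that("enumeration equals the exhaustive DFS oracle on random
          networks", {
  set.seed(31)
  for (i in 1:30) {
    nM <- sample(3:7, 1); nD <- sample(3:7, 1)
    net <- randomHetNet(nM, nD, p = stats::runif(1, 0.15, 0.4))
    r <- sprintf("m%d", sample(nM, 1))
    d <- sprintf("d%d", sample(nD, 1))
    lMax <- sample(1:4, 1)
    mine <- enumerateMetaPaths(net, r, d, lMax)
    orc <- oracleMetaPaths(net, r, d, lMax)
    expect_equal(lapply(mine, `[[`, "nodes"), lapply(orc, `[[`, "nodes"))
  }
})

test_that("every instance is a valid r-to-d walk along existing edges", {
  set.seed(32)
  net <- randomHetNet(6, 6, p = 0.3)
  ekey <- with(netEdges(net), paste(pmin(from, to), pmax(from, to)))
  inst <- enumerateMetaPaths(net, "m1", "d1", 3)
  for (x in inst) {
    ids <- match(x$nodes, net@nodeNames)
    expect_equal(x$nodes[1], "m1")
    expect_equal(x$nodes[length(x$nodes)], "d1")
    expect_equal(length(ids) - 1L, x$length)
    for (t in seq_len(length(ids) - 1L))
      expect_true(paste(min(ids[t], ids[t + 1]),
                        max(ids[t], ids[t + 1])) %in% ekey)
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("instance count is monotone in the length cap", {
  set.seed(33)
  for (i in 1:10) {
    net <- randomHetNet(5, 5, p = 0.3)
    counts <- vapply(1:4, function(l)
      length(enumerateMetaPaths(net, "m1", "d1", l)), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("interior association edges can be disallowed", {
  set.seed(34)
  net <- randomHetNet(5, 5, p = 0.35)
  inst <- enumerateMetaPaths(net, "m1", "d1", 3, mdIntermediate = FALSE)
  for (x in inst)
    expect_false(grepl("D,M", x$type))
  orc <- oracleMetaPaths(net, "m1", "d1", 3, mdIntermediate = FALSE)
  expect_equal(lapply(inst, `[[`, "nodes"), lapply(orc, `[[`, "nodes"))
})

test_that("grouping by type partitions the instance list", {
  fx <- makeToyNetworkFixture()
  inst <- enumerateMetaPaths(fx$net, "m2", "d2", 3)
  grp <- groupByType(inst)
  ## hand count on the fixture: one instance per distinct type
  expect_setequal(names(grp), c("M,D", "M,D,D", "M,M,D", "M,M,D,D"))
  expect_equal(sum(lengths(grp)), length(inst))
  expect_true(all(lengths(grp) > 0))
  expect_equal(length(groupByType(list())), 0)
  ## missing nodes raise errors
  expect_error(enumerateMetaPaths(fx$net, "mX", "d2", 3), "not in")
})
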