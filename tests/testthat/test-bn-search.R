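twoContNodes <- function() {
  data.frame(name = c("A", "B"), kind = "continuous")
}

test_that("constraint construction rejects inconsistent rule sets", {
  expect_error(bnConstraints(whitelist = c("A", "B"),
                             blacklist = rbind(c("A", "B"))), "overlap")
  expect_error(bnConstraints(whitelist = c("A", "B"), noParents = "B"),
               "no-parent")
  expect_error(bnConstraints(whitelist = rbind(c("A", "B"),
                                               c("B", "A"))), "cycle")
})

test_that("validateDag reports every violated rule", {
  nodes <- data.frame(name = c("TG2", "TG4", "cg1", "rs1"),
                      kind = "continuous")
  cons <- gaw20Constraints(snps = "rs1", cpgs = "cg1",
                           discreteCovariates = character())
  # blacklisted CpG -> TG2 edge plus missing whitelist edge
  bad <- bnDag(nodes, edges = rbind(c("cg1", "TG2"), c("TG2", "rs1")))
  v <- validateDag(bad, cons)
  expect_true(any(grepl("blacklisted", v)))
  expect_true(any(grepl("missing whitelist", v)))
  expect_true(any(grepl("no-parent", v)))

  ok <- bnDag(nodes, edges = c("TG2", "TG4"))
  expect_length(validateDag(ok, cons), 0)
  expect_length(validateDag(bnDag(twoContNodes())), 0)

  # the CG restriction is a structural violation; build the offending
  # graph by raw slot surgery since the constructor refuses it
  mixed <- data.frame(name = c("x", "d"),
                      kind = c("continuous", "discrete"))
  dag <- bnDag(mixed, levels = list(d = c("a", "b")))
  dag@edges <- lipidBN:::.asEdgeMatrix(rbind(c("x", "d")))
  expect_true(any(grepl("CG restriction", validateDag(dag))))
})

test_that("neighbourhood enumeration is valid, constrained, ordered", {
  empty <- bnDag(twoContNodes())
  ops <- dagNeighbors(empty)
  expect_identical(ops$op, c("add", "add"))
  expect_identical(sort(paste(ops$from, ops$to)), c("A B", "B A"))

  # no operation may point into a no-parent node
  nodes3 <- data.frame(name = c("A", "B", "S"), kind = "continuous")
  consS <- bnConstraints(noParents = "S")
  for (edges in list(NULL, rbind(c("S", "A")), rbind(c("A", "B")))) {
    ops <- dagNeighbors(bnDag(nodes3, edges = edges), consS)
    into <- ops$to[ops$op != "delete"]
    expect_false("S" %in% into)
    rev <- ops[ops$op == "reverse", ]
    expect_false("S" %in% rev$from)  # reversing S->x would parent S
  }

  # complete 3-node dag: no adds, 3 deletes, reverses only where acyclic
  full <- bnDag(nodes3, edges = rbind(c("A", "B"), c("A", "S"),
                                      c("B", "S")))
  ops <- dagNeighbors(full)
  expect_identical(sum(ops$op == "add"), 0L)
  expect_identical(sum(ops$op == "delete"), 3L)
  revs <- ops[ops$op == "reverse", ]
  expect_identical(paste(revs$from, revs$to), c("A B", "B S"))

  # whitelist edges are never deleted or reversed
  consW <- bnConstraints(whitelist = c("A", "B"))
  opsW <- dagNeighbors(bnDag(nodes3, edges = rbind(c("A", "B"))), consW)
  expect_false(any(opsW$from == "A" & opsW$to == "B" &
                     opsW$op != "add"))

  # deterministic enumeration order: add < delete < reverse, then names
  dag <- bnDag(nodes3, edges = rbind(c("B", "A")))
  o1 <- dagNeighbors(dag); o2 <- dagNeighbors(dag)
  expect_identical(o1, o2)
  expect_true(!is.unsorted(match(o1$op, c("add", "delete", "reverse"))))
})

test_that("DAG enumeration matches brute force over digraphs", {
  nodes2 <- data.frame(name = c("A", "B"), kind = "continuous")
  expect_length(enumerateDags(nodes2), 3)
  nodes3 <- data.frame(name = c("A", "B", "S"), kind = "continuous")
  all3 <- enumerateDags(nodes3)
  expect_length(all3, 25)

  # constrained enumeration agrees with filtering all 2^6 digraphs
  cons <- bnConstraints(noParents = "S")
  got <- sort(vapply(enumerateDags(nodes3, cons), edgeFingerprint, ""))
  want <- sort(unlist(bruteForceDags(c("A", "B", "S"),
                                     forbidInto = "S")))
  expect_identical(got, want)

  # CG restriction: no enumerated dag points a continuous node at a
  # discrete one
  mixed <- data.frame(name = c("x", "d"),
                      kind = c("continuous", "discrete"))
  dags <- enumerateDags(bnDag(mixed, levels = list(d = c("a", "b"))))
  for (d in dags) expect_length(validateDag(d), 0)
  expect_length(dags, 2)  # empty and d -> x

  expect_error(enumerateDags(data.frame(name = letters[1:6],
                                        kind = "continuous")), "5 nodes")
})

test_that("hill climbing recovers the chain equivalence class", {
  set.seed(71)
  ct <- makeChain(2000)
  fit <- hillClimb(ct, restarts = 2)
  ex <- exhaustiveBest(ct)
  expect_equal(networkScore(fit), networkScore(ex), tolerance = 1e-9)
  e <- dagEdges(networkDag(fit))
  skel <- sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_identical(skel, c("X Y", "Y Z"))
  # no v-structure X -> Y <- Z: that dag is not score-equivalent
  expect_false(all(c("X", "Z") %in% e[e[, 2] == "Y", 1]))
  expect_length(validateDag(networkDag(fit)), 0)
})

test_that("hill climbing degenerates gracefully and obeys constraints", {
  set.seed(72)
  one <- cohortTable(data.frame(x = rnorm(30)), c(x = "continuous"))
  fit <- hillClimb(one, restarts = 0)
  expect_identical(nrow(dagEdges(networkDag(fit))), 0L)
  expect_equal(networkScore(fit),
               as.numeric(localScore("x", character(), one)),
               tolerance = 1e-12)

  gw <- gawStyleNetworkCohort(n = 300, h2Scale = 3)
  fit <- hillClimb(gw$cohort, gw$constraints, restarts = 1)
  e <- dagEdges(networkDag(fit))
  expect_true(any(e[, 1] == "TG2" & e[, 2] == "TG4"))
  expect_false(any(e[, 2] %in% gw$snps))
  expect_false(any(e[, 1] %in% gw$cpgs & e[, 2] == "TG2"))
  expect_length(validateDag(networkDag(fit), gw$constraints), 0)

  expect_error(hillClimb(gw$cohort, bnConstraints(noParents = "nope")),
               "unknown node")
})

test_that("restarts never lose score and the trace is monotone", {
  set.seed(73)
  ct <- makeChain(400)
  start <- sum(sapply(c("X", "Y", "Z"), function(v)
    as.numeric(localScore(v, character(), ct))))
  f0 <- hillClimb(ct, restarts = 0)
  f20 <- hillClimb(ct, restarts = 20)
  expect_gte(networkScore(f0), start)
  expect_gte(networkScore(f20), networkScore(f0) - 1e-9)
})

test_that("exhaustive search prefers sparsity and true dependence", {
  set.seed(74)
  indep <- contData <- data.frame(X = rnorm(800), Y = rnorm(800))
  ct <- cohortTable(indep, c(X = "continuous", Y = "continuous"))
  ex <- exhaustiveBest(ct)
  expect_identical(nrow(dagEdges(networkDag(ex))), 0L)

  dep <- makeBivariate(800, 0.9)
  exd <- exhaustiveBest(dep)
  expect_identical(nrow(dagEdges(networkDag(exd))), 1L)

  # the whitelist is kept even on independent data
  consW <- bnConstraints(whitelist = c("X", "Y"))
  exw <- exhaustiveBest(ct, consW)
  expect_true(any(dagEdges(networkDag(exw))[, 1] == "X"))
})

test_that("hill climbing matches the exhaustive oracle on random problems", {
  set.seed(75)
  agree <- 0L
  for (i in 1:20) {
    ct <- randomMixedCohort(n = 150)
    hc <- hillClimb(ct, restarts = 20)
    ex <- exhaustiveBest(ct)
    if (abs(networkScore(hc) - networkScore(ex)) < 1e-9)
      agree <- agree + 1L
    expect_length(validateDag(networkDag(hc)), 0)
  }
  expect_gte(agree, 19L)
})

test_that("DAG files and DOT exports round-trip the structure", {
  gw <- gawStyleNetworkCohort(n = 200, h2Scale = 3)
  set.seed(76)
  fit <- hillClimb(gw$cohort, gw$constraints, restarts = 0)
  td <- withr::local_tempdir()
  p <- file.path(td, "net.tsv")
  writeDag(networkDag(fit), p)
  back <- readDag(p)
  expect_identical(edgeFingerprint(back),
                   edgeFingerprint(networkDag(fit)))
  expect_identical(dagNodes(back), dagNodes(networkDag(fit)))

  dot <- file.path(td, "net.dot")
  writeDot(fit, dot)
  lines <- readLines(dot)
  expect_true(any(grepl("\"sex\" \\[shape=box\\]", lines)))
  expect_true(any(grepl("\"TG2\" \\[shape=ellipse\\]", lines)))
  expect_true(any(grepl("\"TG2\" -> \"TG4\"", lines)))
})
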