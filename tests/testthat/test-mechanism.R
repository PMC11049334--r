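# fixture: target - bridge - disease chain plus an off-path target
# T1 -ppi- B1 -ppi- D1 ; T2 isolated from the disease side; F1 annotated
# to B1 only.
chainNet <- function() {
  buildNetwork(
    data.frame(id = c("B1", "D1", "F1", "T1", "T2", "X1"),
               kind = c("protein", "protein", "function", "protein",
                        "protein", "protein"), label = ""),
    data.frame(source = c("T1", "B1", "B1", "T2"),
               target = c("B1", "D1", "F1", "X1"),
               kind = c("ppi", "ppi", "annotation", "ppi")))
}

test_that("topKNodes sorts by probability with id tie-breaks", {
  r <- c(b = 0.3, a = 0.3, c = 0.2, d = 0.15, e = 0.05)
  expect_identical(topKNodes(r, 2), c("a", "b"))       # tie broken by id
  expect_identical(topKNodes(r, 3), c("a", "b", "c"))
  expect_identical(topKNodes(r, 99), c("a", "b", "c", "d", "e"))
  expect_identical(topKNodes(r, 2, exclude = "a"), c("b", "c"))
  expect_error(topKNodes(r, 0), ">= 1")
  # |top-k| == min(k, available) on random profiles
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    r <- stats::setNames(stats::runif(n), sprintf("n%02d", 1:n))
    k <- sample(1:35, 1)
    expect_length(topKNodes(r, k), min(k, n))
  }
  # the default cutoff is 20
  expect_identical(eval(formals(topKNodes)$k), 20L)
})

test_that("mechanism extraction keeps linked targets and omits unlinked ones", {
  net <- chainNet()
  tm <- buildTransitionMatrix(net)
  params <- diffusionParams(epsilon = 1e-10)
  rc <- diffusePower(tm, makeRestartVector(net, c("T1", "T2")), params)
  rd <- diffusePower(tm, makeRestartVector(net, "D1"), params)
  sub <- extractMechanism(net, rc, rd, c("T1", "T2"), "D1", k = 1,
                          compoundId = "cmp", diseaseName = "dis")
  nd <- sub@nodes
  # T1 reaches the disease context through B1 (top-1 of either profile
  # or adjacent function); T2 only touches X1 and must be omitted
  expect_true("T1" %in% nd$id)
  expect_false("T2" %in% nd$id)
  expect_true("D1" %in% nd$id)
  expect_true(all(nzchar(nd$origins)))
  expect_true(grepl("compound-target", nd$origins[nd$id == "T1"]))
  expect_true(grepl("disease-protein", nd$origins[nd$id == "D1"]))
  # induced edges only between selected nodes
  expect_true(all(c(sub@edges$source, sub@edges$target) %in% nd$id))
  # exactly one primary mechanism candidate
  expect_identical(sum(nd$primary), 1L)
})

test_that("a target adjacent to a disease protein is retained with both origins", {
  net <- buildNetwork(
    data.frame(id = c("D1", "T1"), kind = "protein", label = ""),
    data.frame(source = "D1", target = "T1", kind = "ppi"))
  tm <- buildTransitionMatrix(net)
  p <- diffusionParams(epsilon = 1e-10)
  rc <- diffusePower(tm, makeRestartVector(net, "T1"), p)
  rd <- diffusePower(tm, makeRestartVector(net, "D1"), p)
  sub <- extractMechanism(net, rc, rd, "T1", "D1", k = 1)
  nd <- sub@nodes
  expect_setequal(nd$id, c("D1", "T1"))
  oT <- strsplit(nd$origins[nd$id == "T1"], ",")[[1]]
  expect_true("compound-target" %in% oT)
  expect_true("top-k-of-compound" %in% oT)
})

test_that("the filter removes only compound-target-origin nodes", {
  net <- chainNet()
  tm <- buildTransitionMatrix(net)
  p <- diffusionParams(epsilon = 1e-10)
  rc <- diffusePower(tm, makeRestartVector(net, c("T1", "T2")), p)
  rd <- diffusePower(tm, makeRestartVector(net, "D1"), p)
  for (k in 1:4) {
    sub <- extractMechanism(net, rc, rd, c("T1", "T2"), "D1", k = k)
    nd <- sub@nodes
    expect_true("D1" %in% nd$id)        # disease protein never removed
    dTop <- topKNodes(rd, k)
    expect_true(all(dTop %in% nd$id))   # top-k disease nodes never removed
  }
})

test_that("a fully disconnected compound raises an explicit error", {
  net <- buildNetwork(
    data.frame(id = c("D1", "D2", "T1", "T2"), kind = "protein",
               label = ""),
    data.frame(source = c("D1", "T1"), target = c("D2", "T2"),
               kind = "ppi"))
  tm <- buildTransitionMatrix(net)
  p <- diffusionParams(epsilon = 1e-10)
  rc <- diffusePower(tm, makeRestartVector(net, "T1"), p)
  rd <- diffusePower(tm, makeRestartVector(net, "D1"), p)
  # the compound's component never touches the disease component: every
  # compound-target node is omitted, the disease side survives
  sub <- extractMechanism(net, rc, rd, "T1", "D1", k = 1)
  expect_false("T1" %in% sub@nodes$id)
  expect_true("D1" %in% sub@nodes$id)
})

test_that("SIF and GraphML exports are deterministic and round-trip", {
  net <- chainNet()
  tm <- buildTransitionMatrix(net)
  p <- diffusionParams(epsilon = 1e-10)
  rc <- diffusePower(tm, makeRestartVector(net, "T1"), p)
  rd <- diffusePower(tm, makeRestartVector(net, "D1"), p)
  sub <- extractMechanism(net, rc, rd, "T1", "D1", k = 2)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.sif"); f2 <- file.path(d, "b.sif")
  exportSubnetwork(sub, f1, "sif")
  exportSubnetwork(sub, f2, "sif")
  expect_identical(readLines(f1), readLines(f2))
  # SIF rows = induced edges (plus any isolated selected nodes)
  expect_gte(length(readLines(f1)), nrow(sub@edges))
  # companion node table carries kinds and origins
  ndt <- utils::read.delim(paste0(f1, ".nodes.tsv"))
  expect_setequal(ndt$id, sub@nodes$id)
  # GraphML round-trip preserves node and edge counts
  g1 <- file.path(d, "a.graphml")
  exportSubnetwork(sub, g1, "graphml")
  g <- igraph::read_graph(g1, format = "graphml")
  expect_identical(as.integer(igraph::vcount(g)), nrow(sub@nodes))
  expect_identical(as.integer(igraph::ecount(g)), nrow(sub@edges))
  expect_error(exportSubnetwork(sub, file.path(d, "x.foo"), "foo"))
})

test_that("a 3-node chain exports as a 2-row SIF path", {
  net <- buildNetwork(
    data.frame(id = c("B1", "D1", "T1"), kind = "protein", label = ""),
    data.frame(source = c("T1", "B1"), target = c("B1", "D1"),
               kind = "ppi"))
  tm <- buildTransitionMatrix(net)
  p <- diffusionParams(epsilon = 1e-10)
  rc <- diffusePower(tm, makeRestartVector(net, "T1"), p)
  rd <- diffusePower(tm, makeRestartVector(net, "D1"), p)
  sub <- extractMechanism(net, rc, rd, "T1", "D1", k = 1)
  expect_setequal(sub@nodes$id, c("B1", "D1", "T1"))
  f <- file.path(withr::local_tempdir(), "chain.sif")
  exportSubnetwork(sub, f, "sif")
  expect_length(readLines(f), 2L)
})
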