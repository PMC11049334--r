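smallCfg <- function(seed = 1, ...) {
  syntheticConfig(nProteins = 80, nFunctions = 20, diseaseSize = 8,
                  nCompounds = 10, nPositives = 3,
                  targetRange = c(3L, 10L), seed = seed, ...)
}

test_that("generation is deterministic under the seed and distinct across seeds", {
  n1 <- generateNetwork(smallCfg(seed = 1))
  n2 <- generateNetwork(smallCfg(seed = 1))
  n3 <- generateNetwork(smallCfg(seed = 2))
  expect_identical(edgeTable(n1), edgeTable(n2))
  expect_false(identical(edgeTable(n1), edgeTable(n3)))
  b1 <- generateBenchmark(smallCfg(seed = 5))
  b2 <- generateBenchmark(smallCfg(seed = 5))
  expect_identical(edgeTable(b1@network), edgeTable(b2@network))
  expect_identical(b1@disease@proteins, b2@disease@proteins)
  expect_identical(b1@compounds@targets, b2@compounds@targets)
  expect_identical(b1@labels, b2@labels)
})

test_that("generated networks validate and the hierarchy is acyclic", {
  for (seed in 1:5) {
    net <- generateNetwork(smallCfg(seed = seed))
    expect_true(validObject(net))     # includes the DAG check
    expect_identical(sort(unique(nodeTable(net)$kind)),
                     c("function", "protein"))
    # all three edge classes present
    expect_setequal(unique(edgeTable(net)$kind),
                    c("ppi", "annotation", "hierarchy"))
  }
})

test_that("the PPI degree distribution is heavy-tailed at scale", {
  maxOverMedian <- vapply(1:10, function(seed) {
    net <- generateNetwork(syntheticConfig(nProteins = 500, seed = seed))
    ppi <- edgeTable(net)[edgeTable(net)$kind == "ppi", ]
    deg <- table(c(ppi$source, ppi$target))
    max(deg) / stats::median(deg)
  }, numeric(1))
  expect_true(all(maxOverMedian > 3))
})

test_that("disease modules are connected and compact in the PPI layer", {
  cfg <- smallCfg(seed = 3)
  net <- generateNetwork(cfg)
  dis <- generateDisease(net, cfg)
  expect_length(dis@proteins, cfg$diseaseSize)
  ppi <- edgeTable(net)[edgeTable(net)$kind == "ppi", ]
  g <- igraph::graph_from_data_frame(ppi[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = data.frame(name = proteinIds(net)))
  sg <- igraph::induced_subgraph(g, dis@proteins)
  expect_true(igraph::is_connected(sg))
  # module size 1 degenerates to the anchor alone
  cfg1 <- smallCfg(seed = 3); cfg1$diseaseSize <- 1L
  expect_length(generateDisease(net, cfg1)@proteins, 1L)
  # mean pairwise distance inside the module < network-wide mean
  dAll <- igraph::distances(g)
  dMod <- dAll[dis@proteins, dis@proteins]
  expect_lt(mean(dMod[upper.tri(dMod)]),
            mean(dAll[upper.tri(dAll)]))
})

test_that("planted positives sit closer to the disease module than negatives", {
  meanDist <- function(seed) {
    cfg <- smallCfg(seed = seed)
    b <- generateBenchmark(cfg)
    ppi <- edgeTable(b@network)[edgeTable(b@network)$kind == "ppi", ]
    g <- igraph::graph_from_data_frame(
      ppi[, c("source", "target")], directed = FALSE,
      vertices = data.frame(name = proteinIds(b@network)))
    d <- igraph::distances(g, to = b@disease@proteins)
    dmin <- apply(d, 1, min)
    byId <- function(ids) mean(vapply(
      ids, function(i) mean(dmin[b@compounds@targets[[i]]]), numeric(1)))
    pos <- b@labels$compound_id[b@labels$label == 1]
    neg <- b@labels$compound_id[b@labels$label == 0]
    c(pos = byId(pos), neg = byId(neg))
  }
  dists <- vapply(1:10, meanDist, numeric(2))
  expect_lt(mean(dists["pos", ]), mean(dists["neg", ]))
})

test_that("target counts respect the configured range for all compounds", {
  for (seed in 1:5) {
    cfg <- smallCfg(seed = seed)
    b <- generateBenchmark(cfg)
    sizes <- lengths(b@compounds@targets)
    expect_true(all(sizes >= cfg$targetRange[1] &
                      sizes <= cfg$targetRange[2]))
  }
})

test_that("locality 0 with no noise plants targets inside the disease module", {
  cfg <- smallCfg(seed = 4, locality = 0L, noise = 0)
  cfg$targetRange <- c(3L, 6L)   # module has 8 proteins
  b <- generateBenchmark(cfg)
  pos <- b@labels$compound_id[b@labels$label == 1]
  for (id in pos)
    expect_true(all(b@compounds@targets[[id]] %in% b@disease@proteins))
})

test_that("benchmark files round-trip through the io readers and hide the labels", {
  d <- withr::local_tempdir()
  b <- generateBenchmark(smallCfg(seed = 6), dir = d)
  expect_setequal(list.files(d),
                  c("nodes.tsv", "edges.tsv", "compounds.tsv",
                    "disease_proteins.txt", "truth_labels.tsv",
                    "provenance.json"))
  net <- buildNetwork(readNodeTable(file.path(d, "nodes.tsv")),
                      readEdgeTable(file.path(d, "edges.tsv")))
  expect_identical(nodeTable(net), nodeTable(b@network))
  expect_identical(edgeTable(net), edgeTable(b@network))
  cmp <- readCompoundTable(file.path(d, "compounds.tsv"))
  expect_identical(cmp@targets, b@compounds@targets)
  dis <- readDiseaseProteins(file.path(d, "disease_proteins.txt"))
  expect_identical(dis@proteins, b@disease@proteins)
  expect_identical(readTruthLabels(file.path(d, "truth_labels.tsv")),
                   b@labels)
  # labels appear only in the truth file
  for (f in c("nodes.tsv", "edges.tsv", "compounds.tsv",
              "disease_proteins.txt"))
    expect_false(any(grepl("label\\b.*[01]$",
                           readLines(file.path(d, f))[-1])))
  expect_false("label" %in% names(utils::read.delim(
    file.path(d, "compounds.tsv"))))
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(nPositives = 40, nCompounds = 40),
               "nPositives")
  expect_error(syntheticConfig(targetRange = c(10, 3)), "targetRange")
  expect_error(syntheticConfig(noise = 1.5), "noise")
  expect_error(syntheticConfig(diseaseSize = 0), "disease")
  expect_error(syntheticConfig(targetRange = c(3, 600)), "exceeds")
})
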